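# Small fixtures shared across tests. All geometry is generated in code;
# nothing is read from disk.

# label volume holding one or two rasterized spheres at given centers
# (voxel units) and radii (voxel units); label 2 (PHB) unless stated
sphere_volume_fixture <- function(centers, radii, dims,
                                  labels = rep(2L, length(radii)),
                                  voxel_size = 1) {
  vol <- integer(prod(dims))
  dim(vol) <- as.integer(dims)
  granulemetrics:::.fill_spheres(vol, dim(vol),
                                 matrix(centers, ncol = 3, byrow = TRUE),
                                 radii, as.integer(labels))
  label_volume(vol, voxel_size)
}

# axis-aligned solid cuboid volume
cube_volume_fixture <- function(side, margin = 3L, voxel_size = 1,
                                label = 2L) {
  n <- as.integer(side + 2 * margin)
  a <- array(0L, c(n, n, n))
  idx <- (margin + 1L):(margin + side)
  a[idx, idx, idx] <- label
  label_volume(a, voxel_size)
}

# capsule mask rotated by `angle_deg` about the z axis, built directly
# from the distance-to-segment definition (independent of the C++ fill)
rotated_capsule_mask <- function(length_nm, radius_nm, voxel_size,
                                 angle_deg = 0) {
  th <- angle_deg * pi / 180
  half <- (length_nm / 2 - radius_nm) / voxel_size
  r <- radius_nm / voxel_size
  dir <- c(cos(th), sin(th), 0)
  ext <- ceiling(half * abs(dir) + r) + 2
  cen <- ext + 1
  dims <- as.integer(2 * ext + 3)
  a <- cen - half * dir
  b <- cen + half * dir
  co <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                              z = seq_len(dims[3])))
  ab <- b - a
  t <- pmin(1, pmax(0, (sweep(co, 2, a) %*% ab) / sum(ab^2)))
  d2 <- rowSums((sweep(co, 2, a) - t %*% t(ab))^2)
  arr <- array(as.integer(d2 <= r^2), dim = dims)
  label_volume(arr, voxel_size)
}

# two-granule objects at a known surface gap (nm), voxel units size 1
object_pair_fixture <- function(r1 = 8, r2 = 5, gap = 6) {
  d <- r1 + r2 + gap
  dims <- c(ceiling(d + 2 * max(r1, r2)) + 8L, 2L * ceiling(max(r1, r2)) + 8L,
            2L * ceiling(max(r1, r2)) + 8L)
  c1 <- c(max(r1, r2) + 4, dims[2] / 2, dims[3] / 2)
  c2 <- c1 + c(d, 0, 0)
  vol <- sphere_volume_fixture(c(c1, c2), c(r1, r2), dims)
  extract_objects(vol, "PHB")
}

expect_rel_error <- function(object, expected, tol) {
  expect_lt(abs(object / expected - 1), tol)
}
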