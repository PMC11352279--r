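# Object extraction, surface/volume/diameter measurement, cell length,
# per-cell aggregation

test_that("disjoint spheres are separated and measured exactly", {
  vol <- sphere_volume_fixture(c(15, 15, 15, 45, 15, 15), c(8, 5),
                               dims = c(60, 30, 30))
  objs <- extract_objects(vol, "PHB")
  expect_length(objs, 2L)
  counts <- sort(vapply(objs, function(o) o$voxel_count, 0L))
  # voxel counts equal direct center-in-sphere enumeration
  enum <- function(c0, r) {
    co <- as.matrix(expand.grid(0:59, 0:29, 0:29))
    sum(rowSums(sweep(co, 2, c0)^2) <= r^2)
  }
  expect_identical(counts,
                   sort(c(enum(c(15, 15, 15), 8), enum(c(45, 15, 15), 5))))
  # volume identity and eq_diameter definition hold per object
  for (o in objs) {
    expect_equal(o$volume_nm3, o$voxel_count * vol$voxel_size^3)
    expect_equal(o$eq_diameter_nm, (6 * o$volume_nm3 / pi)^(1 / 3))
  }
})

test_that("volumes without the class yield an empty list, unknown errors", {
  a <- array(0L, c(8, 8, 8)); a[4, 4, 4] <- 1L
  vol <- label_volume(a, 1)
  expect_identical(extract_objects(vol, "PHB"), list())
  expect_error(extract_objects(vol, "lipid"), "absent from label_map")
})

test_that("face-touching blobs merge under 26-connectivity", {
  a <- array(0L, c(12, 8, 8))
  a[2:4, 2:4, 2:4] <- 2L
  a[5:7, 2:4, 2:4] <- 2L  # shares a face plane with the first block
  objs <- extract_objects(label_volume(a, 1), "PHB", min_voxels = 1L)
  expect_length(objs, 1L)
  # even a single shared corner merges under 26-connectivity
  b <- array(0L, c(12, 12, 12))
  b[2:4, 2:4, 2:4] <- 2L
  b[5:7, 5:7, 5:7] <- 2L
  expect_length(extract_objects(label_volume(b, 1), "PHB",
                                min_voxels = 1L), 1L)
})

test_that("small components are filtered with a message", {
  a <- array(0L, c(20, 10, 10))
  a[2:5, 2:5, 2:5] <- 2L   # 64 voxels
  a[15, 5, 5] <- 2L        # 1 voxel speck
  expect_message(objs <- extract_objects(label_volume(a, 1), "PHB"),
                 "discarded")
  expect_length(objs, 1L)
  expect_identical(objs[[1]]$voxel_count, 64L)
})

test_that("surface area matches sphere and cube oracles", {
  for (d in c(20, 33.3, 48)) {
    vol <- sphere_volume_fixture(c(0, 0, 0) + d / 2 + 4.3, d / 2,
                                 dims = rep(ceiling(d) + 9L, 3))
    o <- extract_objects(vol, "PHB")[[1]]
    expect_rel_error(o$surface_area_nm2, pi * d^2, 0.04)
    expect_rel_error(o$volume_nm3, pi / 6 * d^3, 0.02)
    expect_rel_error(o$eq_diameter_nm, d, 0.01)
  }
  cube <- cube_volume_fixture(10)
  o <- extract_objects(cube, "PHB")[[1]]
  # marching over the binary mask chamfers the edges; documented 10% band
  expect_rel_error(o$surface_area_nm2, 600, 0.10)
})

test_that("surface area scales as the square of linear size", {
  a1 <- measure_surface_area(sphere_volume_fixture(c(16, 16, 16), 10,
                                                   c(32, 32, 32))$data, 1)
  a2 <- measure_surface_area(sphere_volume_fixture(c(26, 26, 26), 20,
                                                   c(52, 52, 52))$data, 1)
  expect_rel_error(a2 / a1, 4, 0.02)
  # voxel_size enters quadratically by definition
  m <- sphere_volume_fixture(c(12, 12, 12), 8, c(24, 24, 24))$data
  expect_equal(measure_surface_area(m, 3), 9 * measure_surface_area(m, 1))
  expect_error(measure_surface_area(array(0L, c(3, 3, 3)), 1), "empty")
})

test_that("equivalent_diameter inverts the sphere volume", {
  expect_equal(equivalent_diameter(4.18879e6), 200, tolerance = 1e-5)
  expect_equal(equivalent_diameter(pi / 6), 1)
  expect_error(equivalent_diameter(0), "> 0")
  expect_error(equivalent_diameter(-5), "> 0")
})

test_that("cell length recovers capsule length, spheres, and rotations", {
  spec <- cell_phantom(2000, 350, voxel_size_nm = 8,
                       populations = list(), seed = 1)
  ph <- generate_phantom(spec)
  expect_lt(abs(cell_length(ph$volume) - 2000), 2 * 8)

  sph <- sphere_volume_fixture(c(20, 20, 20), 12, c(40, 40, 40),
                               labels = 1L)
  expect_lt(abs(cell_length(sph) - 24), 2)

  straight <- rotated_capsule_mask(1500, 300, 10, 0)
  tilted <- rotated_capsule_mask(1500, 300, 10, 30)
  expect_rel_error(cell_length(tilted), cell_length(straight), 0.01)
})

test_that("cell length requires a single connected mask", {
  a <- array(0L, c(30, 10, 10))
  a[2:5, 2:5, 2:5] <- 1L
  a[20:25, 2:5, 2:5] <- 1L
  expect_error(cell_length(label_volume(a, 1)), "crop")
})

test_that("aggregate_cell sums its objects and rejects mixed cells", {
  vol <- sphere_volume_fixture(
    c(12, 12, 12, 34, 12, 12, 34, 34, 34), c(6, 5, 4),
    labels = c(2L, 2L, 3L), dims = c(48, 48, 48))
  objs <- c(extract_objects(vol, "PHB"), extract_objects(vol, "PP"))
  rec <- aggregate_cell(objs, cell_length_nm = 100)
  expect_identical(rec$n_phb, 2L)
  expect_identical(rec$n_pp, 1L)
  cls <- vapply(objs, function(o) o$granule_class, "")
  expect_equal(rec$phb_volume_total_nm3,
               sum(vapply(objs[cls == "PHB"],
                          function(o) o$volume_nm3, 0)))
  expect_equal(rec$phb_surface_total_nm2,
               sum(vapply(objs[cls == "PHB"],
                          function(o) o$surface_area_nm2, 0)))

  empty <- aggregate_cell(list())
  expect_identical(empty$n_phb, 0L)
  expect_equal(empty$phb_volume_total_nm3, 0)

  objs[[2]]$cell_id <- 99L
  expect_error(aggregate_cell(objs), "multiple cell_ids")
})

test_that("seven extracted granules count as seven", {
  spec <- cell_phantom(2600, 420, voxel_size_nm = 8,
                       populations = list(
                         granule_population("PHB", 7, 179, 40,
                                            "polar_cluster")),
                       seed = 14)
  ph <- generate_phantom(spec)
  objs <- extract_objects(ph$volume, "PHB", measure_surface = FALSE)
  expect_length(objs, 7L)
  rec <- aggregate_cell(objs)
  expect_identical(rec$n_phb, 7L)
})
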