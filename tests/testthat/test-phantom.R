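# Phantom generator: rasterization accuracy, placement rules,
# determinism, and ground-truth conservation

test_that("zero-granule spec yields only background and cell", {
  spec <- cell_phantom(1000, 300, voxel_size_nm = 10,
                       populations = list(), seed = 3)
  ph <- generate_phantom(spec)
  expect_identical(sort(unique(as.vector(ph$volume$data))), c(0L, 1L))
  expect_identical(nrow(ph$truth), 0L)
})

test_that("a rasterized 200 nm sphere recovers the analytic volume", {
  spec <- cell_phantom(1200, 300, voxel_size_nm = 0.9202,
                       populations = list(
                         granule_population("PHB", 1, 200, 0,
                                            "polar_cluster")),
                       seed = 11)
  ph <- generate_phantom(spec)
  vox_vol <- ph$truth$raster_voxels * 0.9202^3
  expect_rel_error(vox_vol, pi / 6 * 200^3, 0.02)
})

test_that("sampled diameters follow the requested truncated normal", {
  set.seed(4)
  d <- granulemetrics:::rtrunc_normal(5000, 179, 55.6, lower = 2)
  expect_gt(min(d), 2)
  expect_rel_error(mean(d), 179, 0.03)
  expect_rel_error(sd(d), 55.6, 0.05)
})

test_that("volume labels conserve the per-granule raster counts exactly", {
  spec <- cell_phantom(1600, 350, voxel_size_nm = 8,
                       populations = list(
                         granule_population("PHB", 4, 170, 40,
                                            "polar_cluster"),
                         granule_population("PP", 2, 110, 20,
                                            "near_other_class")),
                       seed = 21)
  ph <- generate_phantom(spec)
  for (cl in c("PHB", "PP")) {
    lab <- default_label_map()[[cl]]
    expect_identical(sum(ph$volume$data == lab),
                     sum(ph$truth$raster_voxels[ph$truth$class == cl]))
  }
  # analytic truth columns obey their defining identities
  expect_equal(ph$truth$true_volume_nm3, pi / 6 * ph$truth$diameter_nm^3)
  expect_equal(ph$truth$true_surface_nm2, pi * ph$truth$diameter_nm^2)
})

test_that("identical seed and spec give identical output", {
  spec <- cell_phantom(1400, 320, voxel_size_nm = 8,
                       populations = list(
                         granule_population("PHB", 5, 160, 30,
                                            "polar_cluster")),
                       seed = 77)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth, b$truth)
})

test_that("polar clusters respect the pairwise surface-gap cap", {
  spec <- cell_phantom(2400, 420, voxel_size_nm = 8,
                       populations = list(
                         granule_population("PHB", 6, 150, 30,
                                            "polar_cluster",
                                            cluster_max_spacing_nm = 400)),
                       seed = 9)
  tr <- generate_phantom(spec)$truth
  cen <- as.matrix(tr[, c("center_x_nm", "center_y_nm", "center_z_nm")])
  r <- tr$diameter_nm / 2
  for (i in 1:5) for (j in (i + 1):6) {
    gap <- sqrt(sum((cen[i, ] - cen[j, ])^2)) - r[i] - r[j]
    expect_gte(gap, 0)
    expect_lte(gap, 400)
  }
  # all centers share one polar ball: same nearest axis endpoint for
  # every granule, within one cell radius of it
  pad <- 2 * 8; Rc <- 420
  poles <- rbind(c(pad + Rc, pad + Rc, pad + Rc),
                 c(pad + 2400 - Rc, pad + Rc, pad + Rc))
  dpole <- apply(cen, 1, function(p)
    sqrt(colSums((t(poles) - p)^2)))
  expect_length(unique(apply(dpole, 2, which.min)), 1L)
  expect_true(all(apply(dpole, 2, min) <= Rc))
})

test_that("co-localization placement hits the target gap and rate", {
  hits <- 0L; n <- 60L
  gaps <- numeric(0)
  for (s in seq_len(n)) {
    spec <- cell_phantom(1400, 320, voxel_size_nm = 8,
                         populations = list(
                           granule_population("PHB", 1, 170, 0,
                                              "polar_cluster"),
                           granule_population("PP", 1, 100, 0,
                                              "near_other_class",
                                              coloc_prob = 0.55,
                                              coloc_gap_nm = 12,
                                              noncoloc_min_gap_nm = 150)),
                         seed = 1000 + s)
    tr <- generate_phantom(spec)$truth
    cen <- as.matrix(tr[, c("center_x_nm", "center_y_nm", "center_z_nm")])
    gap <- sqrt(sum((cen[1, ] - cen[2, ])^2)) - sum(tr$diameter_nm) / 2
    if (gap < 75) { hits <- hits + 1L; gaps <- c(gaps, gap) }
    else expect_gte(gap, 150)
  }
  expect_equal(gaps, rep(12, length(gaps)), tolerance = 0.67)  # 8 nm voxel
  expect_gt(hits / n, 0.55 - 0.20)
  expect_lt(hits / n, 0.55 + 0.20)
})

test_that("impossible placements raise informative errors", {
  expect_error(generate_phantom(
    cell_phantom(1200, 300, voxel_size_nm = 8,
                 populations = list(
                   granule_population("PHB", 1, 650, 0, "polar_cluster")),
                 seed = 2)),
    "exceeds cell diameter")
  expect_error(generate_phantom(
    cell_phantom(900, 220, voxel_size_nm = 8,
                 populations = list(
                   granule_population("PHB", 40, 180, 5, "polar_cluster",
                                      cluster_max_spacing_nm = 400)),
                 seed = 2)),
    "placement failed")
})

test_that("mean sphere volume matches the truncated-normal moment", {
  # for diameters ~ N(mu, sigma) with sigma << mu, E[pi/6 d^3] is
  # pi/6 (mu^3 + 3 mu sigma^2)
  set.seed(10)
  d <- granulemetrics:::rtrunc_normal(1e4, 179, 55.6, lower = 0)
  mc <- mean(sphere_volume(d))
  closed <- pi / 6 * (179^3 + 3 * 179 * 55.6^2)
  se <- sd(sphere_volume(d)) / sqrt(length(d))
  expect_lt(abs(mc - closed), 4 * se)
})
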