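# Surface-to-surface distances, nearest neighbors, co-localization,
# PHB spacing

test_that("two spheres at known center distance measure the gap", {
  # r = 100 and 50 nm, centers 300 nm apart, 5 nm voxels -> gap 150 nm
  vol <- sphere_volume_fixture(c(25, 35, 35, 85, 35, 35), c(20, 10),
                               dims = c(120, 70, 70), voxel_size = 5)
  objs <- extract_objects(vol, "PHB")
  d <- surface_distance(objs[[1]], objs[[2]])
  expect_lt(abs(d - 150), 5)
  # symmetric exactly
  expect_identical(d, surface_distance(objs[[2]], objs[[1]]))
  expect_error(surface_distance(objs[[1]], objs[[1]]), "distinct")
})

test_that("face-adjacent and overlapping objects have distance zero", {
  a <- array(0L, c(16, 8, 8))
  a[2:5, 2:5, 2:5] <- 2L
  a[6:9, 2:5, 2:5] <- 3L   # face-adjacent PP block
  vol <- label_volume(a, 1)
  o1 <- extract_objects(vol, "PHB", min_voxels = 1L)[[1]]
  o2 <- extract_objects(vol, "PP", min_voxels = 1L)[[1]]
  expect_identical(surface_distance(o1, o2), 0)
})

test_that("mesh distance agrees with the brute-force voxel oracle", {
  set.seed(31)
  for (i in 1:20) {
    r1 <- runif(1, 4, 9); r2 <- runif(1, 4, 9)
    gap <- runif(1, 0, 14)
    d <- r1 + r2 + gap
    th <- runif(1, 0, pi / 2)
    c1 <- c(14, 26, 26)
    c2 <- c1 + d * c(cos(th), sin(th), 0)
    vol <- sphere_volume_fixture(c(c1, c2), c(r1, r2), c(60, 60, 52))
    objs <- extract_objects(vol, "PHB", min_voxels = 1L)
    if (length(objs) != 2L) next  # tiny gap can merge rasterizations
    dm <- surface_distance(objs[[1]], objs[[2]], method = "mesh")
    dv <- surface_distance(objs[[1]], objs[[2]], method = "voxel")
    expect_lt(abs(dm - dv), 1)  # voxel_size = 1
  }
})

test_that("triangle consistency holds on spherical phantoms", {
  vol <- sphere_volume_fixture(c(20, 25, 25, 58, 25, 25), c(12, 8),
                               dims = c(78, 50, 50))
  objs <- extract_objects(vol, "PHB")
  d <- surface_distance(objs[[1]], objs[[2]])
  center_d <- 38
  expect_lt(abs(center_d - d - 12 - 8), 2)
})

test_that("nearest-neighbor table picks the closer partner per granule", {
  # one PP between two PHB at different gaps
  vol <- sphere_volume_fixture(
    c(20, 25, 25, 47, 25, 25, 80, 25, 25), c(10, 6, 10),
    labels = c(2L, 3L, 2L), dims = c(105, 50, 50))
  objs <- c(extract_objects(vol, "PHB"), extract_objects(vol, "PP"))
  nn <- nearest_neighbor_table(objs, "PP", "PHB")
  expect_identical(nrow(nn), 1L)
  # gaps: left 47-20-16=11, right 80-47-16=17
  expect_lt(abs(nn$surface_distance_nm - 11), 1.5)
  expect_equal(nn$pp_width_nm,
               objs[[3]]$eq_diameter_nm)
  expect_error(nearest_neighbor_table(objs, "PP", "ribosome"),
               "unknown")
})

test_that("cells lacking a class contribute no record", {
  vol <- sphere_volume_fixture(c(16, 16, 16), 8, c(32, 32, 32),
                               labels = 3L)
  objs <- extract_objects(vol, "PP")
  expect_identical(nrow(nearest_neighbor_table(objs, "PP", "PHB")), 0L)
})

test_that("colocalization fraction counts, errors empty, and is monotone", {
  recs <- data.frame(surface_distance_nm = c(rep(10, 7), rep(60, 5)))
  cf <- colocalization_fraction(recs, 25)
  expect_identical(cf$k, 7L)
  expect_identical(cf$n, 12L)
  expect_equal(cf$fraction, 7 / 12, tolerance = 1e-12)

  all0 <- data.frame(surface_distance_nm = rep(0, 5))
  expect_equal(colocalization_fraction(all0, 25)$fraction, 1)

  expect_error(colocalization_fraction(
    data.frame(surface_distance_nm = numeric(0))), "undefined")

  set.seed(8)
  rnd <- data.frame(surface_distance_nm = runif(200, 0, 100))
  fr <- vapply(c(5, 25, 50, 80),
               function(t) colocalization_fraction(rnd, t)$fraction, 0)
  expect_true(all(diff(fr) >= 0))
})

test_that("generator co-localization gap is recovered by measurement", {
  spec <- cell_phantom(1400, 320, voxel_size_nm = 6,
                       populations = list(
                         granule_population("PHB", 2, 170, 20,
                                            "polar_cluster"),
                         granule_population("PP", 1, 100, 10,
                                            "near_other_class",
                                            coloc_prob = 1,
                                            coloc_gap_nm = 12)),
                       seed = 19)
  ph <- generate_phantom(spec)
  objs <- c(extract_objects(ph$volume, "PHB"),
            extract_objects(ph$volume, "PP"))
  nn <- nearest_neighbor_table(objs, "PP", "PHB")
  expect_identical(nrow(nn), 1L)
  expect_lt(abs(nn$surface_distance_nm - 12), 6)  # within one voxel
})

test_that("phb spacing enumerates pairs and respects the cluster cap", {
  spec <- cell_phantom(2600, 420, voxel_size_nm = 8,
                       populations = list(
                         granule_population("PHB", 7, 160, 30,
                                            "polar_cluster",
                                            cluster_max_spacing_nm = 400)),
                       seed = 23)
  ph <- generate_phantom(spec)
  objs <- extract_objects(ph$volume, "PHB")
  sp <- phb_spacing_summary(objs)
  expect_identical(nrow(sp$pairs), 21L)      # 7 choose 2
  expect_identical(sp$per_cell$n_pairs, 21L)
  # measured surface distances respect the generator cap (+1 voxel)
  expect_true(all(sp$pairs$surface_distance_nm <= 400 + 8))
  expect_equal(sp$per_cell$max_spacing_nm,
               max(sp$pairs$surface_distance_nm))

  # two granules -> a single pair
  two <- objs[1:2]
  expect_identical(nrow(phb_spacing_summary(two)$pairs), 1L)
  # a lone granule yields no pairs
  expect_identical(nrow(phb_spacing_summary(objs[1])$pairs), 0L)
})
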