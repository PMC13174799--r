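test_that("analytic_metrics matches closed forms for spheres and capsules", {
  s <- analytic_metrics(sphere_spec(c(0, 0, 0), 5))
  expect_equal(s$V, 523.5988, tolerance = 1e-6)
  expect_equal(s$SA, 314.1593, tolerance = 1e-6)
  expect_equal(s$sphericity, 1.0, tolerance = 1e-12)

  # sphericity of a sphere is 1 for any radius
  for (r in c(0.3, 1, 2.5, 17))
    expect_equal(analytic_metrics(sphere_spec(c(0, 0, 0), r))$sphericity, 1,
                 tolerance = 1e-12)

  cp <- analytic_metrics(capsule_spec(c(0, 0, 0), r = 1, L = 4))
  expect_equal(cp$V, pi * 4 + 4 / 3 * pi, tolerance = 1e-12)   # 16.7552
  expect_equal(cp$SA, 2 * pi * 4 + 4 * pi, tolerance = 1e-12)  # 37.6991
  expect_equal(cp$V, 16.7552, tolerance = 1e-5)
  expect_equal(cp$SA, 37.6991, tolerance = 1e-5)
})

test_that("ellipsoid truth uses exact volume and Thomsen surface area", {
  e <- analytic_metrics(ellipsoid_spec(c(0, 0, 0), 3, 2, 1))
  expect_equal(e$V, 4 / 3 * pi * 6, tolerance = 1e-12)
  p <- 1.6075
  expect_equal(e$SA, 4 * pi * ((6^p + 3^p + 2^p) / 3)^(1 / p), tolerance = 1e-12)
  # degenerates to the sphere exactly when a = b = c
  e2 <- analytic_metrics(ellipsoid_spec(c(0, 0, 0), 2, 2, 2))
  expect_equal(e2$SA, 16 * pi, tolerance = 1e-12)
  expect_equal(e2$sphericity, 1, tolerance = 1e-12)
})

test_that("invalid primitive specs are rejected", {
  expect_error(sphere_spec(c(0, 0, 0), -1), "size parameter")
  expect_error(capsule_spec(c(0, 0, 0), r = 1, L = 0), "size parameter")
  expect_error(capsule_spec(c(0, 0, 0), r = 1, L = 1, axis = c(1, 1, 0)),
               "unit")
})

test_that("object truth satisfies MCI_sq * sphericity^3 = 9/(4*pi)", {
  set.seed(11)
  for (i in 1:20) {
    spec <- switch(sample(3, 1),
      sphere_spec(c(0, 0, 0), runif(1, 0.2, 8)),
      capsule_spec(c(0, 0, 0), runif(1, 0.2, 2), runif(1, 0.5, 10)),
      ellipsoid_spec(c(0, 0, 0), runif(1, 0.5, 4), runif(1, 0.5, 4),
                     runif(1, 0.5, 4)))
    tr <- analytic_metrics(spec)
    expect_equal(tr$mci_sq * tr$sphericity^3, 9 / (4 * pi), tolerance = 1e-9)
  }
})

test_that("rasterize handles identity cases and enforces its contract", {
  empty <- rasterize(list(), spacing = c(1, 1, 1), shape = c(5, 5, 5))
  expect_equal(n_objects(empty$labels), 0L)
  expect_equal(nrow(empty$truth), 0L)

  two <- rasterize(list(sphere_spec(c(3, 3, 3), 1.5),
                        sphere_spec(c(3, 3, 9), 1.5)),
                   spacing = c(0.5, 0.5, 0.5), shape = c(12, 12, 24))
  expect_equal(n_objects(two$labels), 2L)
  expect_setequal(two$truth$id, 1:2)
  # truth ids and label ids agree
  expect_setequal(setdiff(unique(as.vector(two$labels$labels)), 0L),
                  two$truth$id)

  expect_error(rasterize(list(sphere_spec(c(3, 3, 3), 1.5),
                              sphere_spec(c(3, 3, 4), 1.5)),
                         spacing = c(0.5, 0.5, 0.5), shape = c(12, 12, 24)),
               "overlap")
  expect_error(rasterize(list(sphere_spec(c(1, 3, 3), 1.5)),
                         spacing = c(0.5, 0.5, 0.5), shape = c(12, 12, 12)),
               "bounds")
})

test_that("rasterized voxel volume converges to the analytic volume", {
  # voxel-center inclusion: relative error < 2% at r = 10 voxels, < 1% at 20
  for (cfg in list(list(r = 10, tol = 0.02), list(r = 20, tol = 0.01))) {
    ph <- digitized_ball(cfg$r)
    v_vox <- voxel_volume(ph$labels, 1)
    expect_lt(abs(v_vox / ph$truth$V - 1), cfg$tol)
  }
})

test_that("voxel-center inclusion matches an independent R oracle", {
  sp <- c(0.5, 0.4, 0.3)
  ph <- rasterize(list(sphere_spec(c(2.5, 2.4, 2.1), 1.3)),
                  spacing = sp, shape = c(10, 12, 14))
  # direct oracle: enumerate every voxel center
  cnt <- 0L
  for (i in 1:10) for (j in 1:12) for (k in 1:14) {
    p <- (c(i, j, k) - 0.5) * sp
    if (sum((p - c(2.5, 2.4, 2.1))^2) <= 1.3^2) cnt <- cnt + 1L
  }
  expect_identical(sum(ph$labels$labels == 1L), cnt)
})

test_that("add_noise is exact for sd = 0 and reproducible under a seed", {
  g <- voxel_grid(array(runif(4 * 5 * 6), c(4, 5, 6)), c(1, 1, 1))
  expect_identical(add_noise(g, 0, 0, seed = 1)$values, g$values)
  b <- add_noise(g, background_offset = 2.5, gaussian_sd = 0, seed = 1)
  expect_equal(b$values, g$values + 2.5, tolerance = 0)
  n1 <- add_noise(g, 1, 0.3, seed = 99)
  n2 <- add_noise(g, 1, 0.3, seed = 99)
  expect_identical(n1$values, n2$values)
  expect_error(add_noise(g, 0, -1, seed = 1), "gaussian_sd")
  # caller RNG state untouched
  set.seed(5); x1 <- runif(3)
  set.seed(5); invisible(add_noise(g, 0, 1, seed = 7)); x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("voxel_count_phantom builds connected objects with exact counts", {
  sizes <- c(115L, 121L, 125L, 1L, 7L)
  lv <- voxel_count_phantom(sizes)
  sz <- object_sizes(lv)
  expect_setequal(as.integer(sz), sizes)
  # each object is one 6-connected component
  seg <- segment_volume(voxel_grid((lv$labels > 0) * 1, lv$spacing),
                        segmentation_params(threshold = "fixed",
                                            threshold_value = 0.5,
                                            connectivity = 6))
  expect_equal(n_objects(seg), length(sizes))
})

test_that("make_cell_scene realizes its target fractions", {
  # all mass in the outermost zone
  out <- make_cell_scene(cell_scene_spec(fractions = c(0, 0, 1),
                                         n_puncta = 500, seed = 3))
  expect_equal(unname(out$profile$fractions[3]), 1.0, tolerance = 0)
  expect_equal(sum(out$profile$fractions), 1, tolerance = 0)

  # knockdown-like preset: realized distal fraction ~ 75%
  kd <- make_cell_scene(scene_preset("knockdown-like", seed = 7))
  expect_equal(unname(kd$profile$fractions[["distal"]]), 0.75,
               tolerance = 1 / sqrt(2000) * 3)
  # realized fractions are a multinomial draw of the target
  expect_lt(max(abs(kd$profile$fractions - kd$target)), 3 / sqrt(2000))
})

test_that("make_cell_scene is deterministic and validates fractions", {
  a <- make_cell_scene(scene_preset("control-like", seed = 12))
  b <- make_cell_scene(scene_preset("control-like", seed = 12))
  expect_identical(a$scene$intensity, b$scene$intensity)
  expect_identical(a$profile$fractions, b$profile$fractions)
  expect_error(cell_scene_spec(fractions = c(0.5, 0.5, 0.5)), "summing to 1")
  expect_error(cell_scene_spec(irregularity = 0.4), "irregularity")
})

test_that("random_phantom places the requested non-overlapping objects", {
  ph <- random_phantom(6, seed = 21, shape = c(90, 100, 100))
  expect_equal(n_objects(ph$labels), 6L)
  expect_equal(nrow(ph$truth), 6L)
  ph2 <- random_phantom(6, seed = 21, shape = c(90, 100, 100))
  expect_identical(ph$labels$labels, ph2$labels$labels)
})
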