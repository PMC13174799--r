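test_that("subtract_background removes a flat offset exactly", {
  g <- voxel_grid(array(7.5, c(8, 8, 8)), c(1, 1, 1))
  out <- subtract_background(g, radius = 3)
  expect_equal(max(abs(out$values)), 0)
})

test_that("subtract_background matches a direct morphology oracle", {
  # compact 3-voxel bright object on flat offset b
  b <- 10; peak <- 60
  vals <- array(b, c(9, 9, 9))
  vals[5, 5, 4:6] <- peak
  g <- voxel_grid(vals, c(1, 1, 1))
  out <- subtract_background(g, radius = 2.5)

  # independent oracle: brute-force opening with the same ball in plain R
  offs <- as.matrix(expand.grid(dz = -2:2, dy = -2:2, dx = -2:2))
  offs <- offs[rowSums(offs^2) <= 2.5^2, ]
  morph <- function(a, f) {
    r <- array(NA_real_, dim(a))
    for (z in 1:9) for (y in 1:9) for (x in 1:9) {
      p <- cbind(z + offs[, 1], y + offs[, 2], x + offs[, 3])
      p <- p[p[, 1] >= 1 & p[, 1] <= 9 & p[, 2] >= 1 & p[, 2] <= 9 &
               p[, 3] >= 1 & p[, 3] <= 9, , drop = FALSE]
      r[z, y, x] <- f(a[p])
    }
    r
  }
  opening <- morph(morph(vals, min), max)
  expect_equal(out$values, pmax(vals - opening, 0), tolerance = 1e-12)
  # offset removed, object peak reduced by exactly b
  expect_equal(max(out$values), peak - b, tolerance = 1e-6)
  expect_equal(out$values[1, 1, 1], 0)
})

test_that("subtract_background warns and no-ops below one voxel", {
  g <- voxel_grid(array(runif(27), c(3, 3, 3)), c(1, 1, 1))
  expect_warning(out <- subtract_background(g, radius = 0.5), "below one voxel")
  expect_identical(out$values, g$values)
  expect_error(subtract_background(g, radius = -1), "> 0")
})

test_that("segmentation defaults reproduce the published parameters", {
  p <- segmentation_params()
  expect_equal(p$background_radius, 37.1)
  expect_equal(p$smoothing_width, 0.129)
  expect_equal(p$min_voxels, 121L)
  expect_equal(p$connectivity, 26L)
})

test_that("smooth_gaussian preserves constants and total intensity", {
  g <- voxel_grid(array(3.3, c(8, 9, 10)), c(0.1, 0.1, 0.1))
  out <- smooth_gaussian(g, width = 0.2)
  expect_equal(out$values, g$values, tolerance = 1e-12)

  # interior delta spike: intensity conserved
  v <- array(0, c(21, 21, 21)); v[11, 11, 11] <- 5
  d <- voxel_grid(v, c(0.0645, 0.0645, 0.0645))
  sm <- smooth_gaussian(d, width = 0.129)   # sigma = 2 voxels per axis
  expect_equal(sum(sm$values), 5, tolerance = 1e-6)
  # the impulse response is the normalized discrete Gaussian at sigma = 2:
  # one-voxel offset ratio exp(-1/8)
  expect_equal(sm$values[12, 11, 11] / sm$values[11, 11, 11], exp(-1 / 8),
               tolerance = 1e-9)
  expect_equal(sm$values[11, 13, 11] / sm$values[11, 11, 11], exp(-4 / 8),
               tolerance = 1e-9)
})

test_that("smooth_gaussian commutes with global intensity scaling", {
  set.seed(4)
  g <- voxel_grid(array(runif(10 * 11 * 12), c(10, 11, 12)), c(0.1, 0.2, 0.1))
  a <- smooth_gaussian(voxel_grid(g$values * 3.7, g$spacing), 0.25)
  b <- smooth_gaussian(g, 0.25)
  expect_equal(a$values, 3.7 * b$values, tolerance = 1e-9)
})

test_that("segment_volume labels phantoms and handles empty volumes", {
  ph <- rasterize(list(sphere_spec(c(3, 3, 3), 1.5),
                       sphere_spec(c(3, 3, 9), 1.5)),
                  spacing = c(0.5, 0.5, 0.5), shape = c(12, 12, 24))
  lab <- segment_volume(ph$intensity,
                        segmentation_params(threshold = "fixed",
                                            threshold_value = 0.5))
  expect_equal(n_objects(lab), 2L)
  # noiseless phantom: segmentation recovers the ground-truth voxel sets
  expect_equal(sum(lab$labels > 0), sum(ph$labels$labels > 0))

  zero <- voxel_grid(array(0, c(5, 5, 5)), c(1, 1, 1))
  expect_equal(n_objects(segment_volume(zero)), 0L)
})

test_that("otsu threshold separates a bimodal phantom", {
  ph <- rasterize(list(sphere_spec(c(3, 3, 3), 1.5)),
                  spacing = c(0.5, 0.5, 0.5), shape = c(12, 12, 12))
  noisy <- add_noise(ph$intensity, background_offset = 0.1,
                     gaussian_sd = 0.05, seed = 8)
  # threshold falls between the background mode (0.1) and object mode (1.1)
  thr <- otsu_threshold(noisy$values)
  expect_gt(thr, 0.1); expect_lt(thr, 1.1)
  lab <- segment_volume(noisy)
  expect_equal(n_objects(lab), 1L)
  # classification is exact on this well-separated phantom
  expect_equal(sum(lab$labels > 0), sum(ph$labels$labels > 0))
})

test_that("corner-sharing voxels merge at 26- but not 6-connectivity", {
  v <- array(0, c(3, 3, 3))
  v[1, 1, 1] <- 1; v[2, 2, 2] <- 1
  g <- voxel_grid(v, c(1, 1, 1))
  p26 <- segmentation_params(threshold = "fixed", threshold_value = 0.5,
                             connectivity = 26)
  p6 <- segmentation_params(threshold = "fixed", threshold_value = 0.5,
                            connectivity = 6)
  expect_equal(n_objects(segment_volume(g, p26)), 1L)
  expect_equal(n_objects(segment_volume(g, p6)), 2L)
})

test_that("filter_small applies a strict 'smaller than' cutoff", {
  lv <- voxel_count_phantom(c(120L, 121L))
  out <- filter_small(lv, 121L)
  expect_equal(n_objects(out), 1L)
  expect_equal(unname(object_sizes(out)), 121L)

  # min_voxels = 1 is the identity up to relabeling
  expect_equal(sort(unname(object_sizes(filter_small(lv, 1L)))),
               sort(unname(object_sizes(lv))))

  empty <- label_volume(array(0L, c(4, 4, 4)), c(1, 1, 1))
  expect_equal(n_objects(filter_small(empty, 121L)), 0L)
  expect_error(filter_small(lv, 0), "min_voxels")
})

test_that("filter_small is idempotent and never increases object count", {
  set.seed(31)
  for (i in 1:5) {
    g <- add_noise(voxel_grid(array(0, c(14, 14, 14)), c(1, 1, 1)),
                   gaussian_sd = 1, seed = 100 + i)
    lab <- segment_volume(g, segmentation_params(threshold = "fixed",
                                                 threshold_value = 1.2))
    cut <- sample(2:6, 1)
    f1 <- filter_small(lab, cut)
    f2 <- filter_small(f1, cut)
    expect_lte(n_objects(f1), n_objects(lab))
    expect_identical(f1$labels, f2$labels)
  }
})

test_that("preprocess_and_segment recovers phantom object counts", {
  ph <- rasterize(list(sphere_spec(c(2, 2, 2), 0.9),
                       sphere_spec(c(2, 2, 6), 0.9),
                       sphere_spec(c(6, 6, 4), 0.9)),
                  spacing = c(0.1, 0.1, 0.1), shape = c(80, 80, 80))
  noisy <- add_noise(ph$intensity, background_offset = 0.05,
                     gaussian_sd = 0.05, seed = 2)
  lab <- suppressMessages(
    preprocess_and_segment(noisy, segmentation_params(min_voxels = 121L)))
  expect_equal(n_objects(lab), 3L)
  # stage messages are emitted
  expect_message(
    preprocess_and_segment(noisy, segmentation_params(min_voxels = 121L)),
    "size filter")
})
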