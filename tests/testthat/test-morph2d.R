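test_that("single-pixel perimeter is the marching-squares diamond", {
  m <- matrix(0, 5, 5); m[3, 3] <- 1
  tp <- trace_perimeter(m, spacing = 1)
  # enumeration of the 1-pixel case: four segments through edge midpoints
  expect_equal(tp$metrics$perimeter_um, 2 * sqrt(2), tolerance = 1e-9)
  expect_equal(tp$metrics$n_holes, 0L)
})

test_that("disc perimeter matches the independent marching-squares oracle", {
  # Frozen from scikit-image find_contours on the identical mask (an
  # independent implementation of the same algorithm): P = 134.710678 for
  # a binary r = 20 px disc. Binary marching squares carries a known
  # upward bias of ~6-9% on digitized smooth convex boundaries, so the
  # analytic circle is an upper-bias sanity bound, not an equality target.
  m <- disc_mask(20) * 1
  tp <- trace_perimeter(m, spacing = 1)
  expect_equal(tp$metrics$perimeter_um, 134.710678, tolerance = 1e-7)
  expect_gt(tp$metrics$perimeter_um, 2 * pi * 20)          # bias is upward
  expect_lt(tp$metrics$perimeter_um / (2 * pi * 20), 1.10) # and bounded
})

test_that("perimeter is scale consistent", {
  # residual digitization bias drifts with resolution, so scale
  # consistency is asserted where the estimator is in its asymptotic
  # regime (r >= 40 px)
  p1 <- trace_perimeter(disc_mask(40) * 1, spacing = 1)$metrics$perimeter_um
  p2 <- trace_perimeter(disc_mask(80) * 1, spacing = 0.5)$metrics$perimeter_um
  expect_lt(abs(p2 / p1 - 1), 0.01)
})

test_that("holes contribute to hole perimeter, not the outer perimeter", {
  m <- matrix(0, 20, 20); m[4:17, 4:17] <- 1; m[9:12, 9:12] <- 0
  tp <- trace_perimeter(m, spacing = 1)
  expect_equal(tp$metrics$n_holes, 1L)
  full <- trace_perimeter({mm <- matrix(0, 20, 20); mm[4:17, 4:17] <- 1; mm},
                          spacing = 1)
  expect_equal(tp$metrics$perimeter_um, full$metrics$perimeter_um,
               tolerance = 1e-9)
  expect_gt(tp$metrics$hole_perimeter_um, 0)
})

test_that("empty masks yield empty results", {
  tp <- trace_perimeter(matrix(0, 4, 4), spacing = 1)
  expect_equal(nrow(tp$metrics), 0L)
  expect_equal(nrow(measure_sections(matrix(0, 4, 4))), 0L)
})

test_that("length_and_area matches the stated conventions", {
  m <- matrix(0L, 5, 60); m[3, 6:55] <- 1L    # 1 x 50 px strip
  la <- length_and_area(m, spacing = 0.1, id = 1L)
  expect_equal(la$length, 4.9, tolerance = 1e-9)   # 49 inter-center units
  expect_equal(la$area, 0.50, tolerance = 1e-12)

  d <- label2d(disc_mask(20))
  la2 <- length_and_area(d, spacing = 1, id = 1L)
  expect_lt(abs(la2$length / 40 - 1), 0.05)

  # area is exactly k * spacing^2
  set.seed(9)
  m2 <- matrix(0L, 10, 10); m2[sample(100, 17)] <- 1L
  tot <- count_and_total_area(m2, spacing = 0.25)
  expect_equal(tot$total_area, 17 * 0.25^2, tolerance = 1e-12)
  expect_error(length_and_area(m, 0.1, 42L), "not present")
})

test_that("reported Feret equals the brute-force pairwise oracle", {
  set.seed(14)
  for (i in 1:4) {
    m <- matrix(0L, 30, 30)
    m[sample(900, 60)] <- 1L
    lab <- label2d(m)
    for (id in setdiff(unique(as.vector(lab)), 0L)) {
      pts <- mitomorph:::boundary_pixel_centers(lab, id)
      la <- length_and_area(lab, spacing = 1, id = id)
      expect_equal(la$length, brute_feret(pts), tolerance = 1e-12)
    }
  }
})

test_that("count_and_total_area is additive and permutation invariant", {
  m <- matrix(0L, 10, 12)
  m[2:3, 2:4] <- 1L   # 6 px
  m[7:8, 6:9] <- 2L   # 8 px... but spec example: 5 and 7
  m[7:8, 6:9] <- 0L
  m[7, 6:9] <- 2L; m[8, 6:8] <- 2L  # 7 px
  m[2:3, 2:4] <- 0L
  m[2, 2:4] <- 1L; m[3, 2:3] <- 1L  # 5 px
  out <- count_and_total_area(m, spacing = 1)
  expect_equal(out$count, 2L)
  expect_equal(out$total_area, 12)
  # label permutation
  mp <- m; mp[m == 1L] <- 2L; mp[m == 2L] <- 1L
  outp <- count_and_total_area(mp, spacing = 1)
  expect_identical(out, outp)
  # additivity against per-object areas
  a1 <- length_and_area(m, 1, 1L)$area
  a2 <- length_and_area(m, 1, 2L)$area
  expect_equal(out$total_area, a1 + a2, tolerance = 1e-12)
  empty <- count_and_total_area(matrix(0L, 5, 5), 1)
  expect_equal(empty$count, 0L)
  expect_equal(empty$total_area, 0)
})

test_that("2D isoperimetric inequality holds with discretization allowance", {
  shapes <- list(disc_mask(12) * 1,
                 {m <- matrix(0, 20, 40); m[5:15, 5:35] <- 1; m},
                 {m <- matrix(0, 25, 25); m[5:20, 5:20] <- 1; m[10:15, 1:12] <- 0; m})
  for (m in shapes) {
    lab <- label2d(m)
    tp <- trace_perimeter(lab, spacing = 1)
    for (i in seq_len(nrow(tp$metrics))) {
      la <- length_and_area(lab, 1, tp$metrics$id[i])
      expect_gte(tp$metrics$perimeter_um[i]^2, 4 * pi * la$area * 0.98)
    }
  }
})

test_that("crista metrics report per-crista areas and density", {
  mito <- matrix(0, 12, 12); mito[2:11, 2:11] <- 1  # 100 px
  cr <- matrix(0L, 12, 12)
  cr[3:4, 3:7] <- 1L                                 # 10 px
  cr[7:9, 3:7] <- 2L                                 # 15 px
  out <- crista_metrics(mito, cr, spacing = 1)
  expect_equal(unname(out$areas), c(10, 15))
  expect_equal(out$density, 0.25, tolerance = 1e-12)
  expect_equal(out$n, 2L)

  # no cristae -> density 0; full coverage -> density 1
  expect_equal(crista_metrics(mito, matrix(0L, 12, 12))$density, 0)
  full <- matrix(0L, 12, 12); full[mito == 1] <- 1L
  expect_equal(crista_metrics(mito, full)$density, 1, tolerance = 1e-12)

  # containment violation
  bad <- cr; bad[1, 1] <- 3L
  expect_error(crista_metrics(mito, bad), "outside")

  # optional volume needs a section thickness
  v <- crista_metrics(mito, cr, spacing = 1, section_thickness = 0.07)
  expect_equal(unname(v$volumes), c(10, 15) * 0.07, tolerance = 1e-12)
})

test_that("measure_sections combines the per-object metrics", {
  m <- matrix(0L, 20, 20); m[3:8, 3:8] <- 1L; m[12:18, 12:14] <- 2L
  tab <- measure_sections(m, spacing = 0.5)
  expect_equal(nrow(tab), 2L)
  expect_named(tab, c("id", "perimeter_um", "length_um", "area_um2"))
  expect_equal(tab$area_um2, c(36, 21) * 0.25, tolerance = 1e-12)
  expect_true(all(tab$length_um <= tab$perimeter_um / 2 + 1e-9))
})
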