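# Synthetic scene and cohort generator: rendering physics, determinism,
# ground-truth consistency.

test_that("rendered fibers have the declared peak, additivity and FWHM support", {
  cv <- matrix(0, 60, 60)
  f <- fiber_spec(rbind(c(30, 5), c(30, 55)), thickness_px = 3, peak_intensity = 100)
  cv1 <- render_fiber(f, cv)
  expect_equal(max(cv1), 100)
  expect_equal(cv1[30, 30], 100)          # centerline reaches the peak
  cv2 <- render_fiber(f, cv1)
  expect_equal(cv2[30, 30], 200)          # additive across renders

  # half-peak support of an arc-length-50 fiber covers ~ length x thickness
  cv <- matrix(0, 70, 70)
  f50 <- fiber_spec(rbind(c(35, 10), c(35, 60)), thickness_px = 3, peak_intensity = 100)
  n_half <- sum(render_fiber(f50, cv) >= 50)
  expect_lt(abs(n_half - 50 * 3) / (50 * 3), 0.2)

  expect_error(render_fiber(fiber_spec(rbind(c(-3, 5), c(30, 55)), 3, 100),
                            cv), class = "collprof_bounds_error")
})

test_that("fiber and scene specs validate their inputs", {
  expect_error(fiber_spec(rbind(c(1, 1)), 3, 10), "n >= 2")
  expect_error(fiber_spec(rbind(c(1, 1), c(5, 5)), 0.5, 10), "thickness")
  expect_error(scene_spec(shape_px = c(0, 10)))
  expect_error(cohort_spec(hazard_ratio = -1), class = "collprof_input_error")
  expect_error(cohort_spec(planted_percentile = 35), "grid")
})

test_that("scenes are bit-reproducible from their seed", {
  spec <- random_scene_spec(n_isolated = 4, seed = 7L)
  s1 <- generate_scene(spec)
  s2 <- generate_scene(spec)
  expect_identical(s1$image$shg, s2$image$shg)
  expect_identical(s1$image$tpe, s2$image$tpe)
  expect_identical(s1$truth, s2$truth)
})

test_that("background-only scenes have an empty collagen mask", {
  s <- generate_scene(scene_spec(shape_px = c(64L, 64L), seed = 3L))
  expect_false(any(s$truth$collagen_mask))
  expect_equal(sum(s$truth$noiseless_shg), 0)
})

test_that("noiseless SHG equals the sum of per-fiber tube integrals", {
  spec <- random_scene_spec(n_isolated = 5, seed = 11L)
  s <- generate_scene(spec)
  acc <- matrix(0, 256, 256)
  for (f in spec$fibers) acc <- render_fiber(f, acc)
  expect_equal(s$truth$noiseless_shg, acc, tolerance = 1e-12)
})

test_that("clustered fibers produce one connected aggregate in the ground truth", {
  spec <- random_scene_spec(n_isolated = 6,
                            clusters = list(list(center = c(90, 90), radius = 35,
                                                 n_fibers = 30)),
                            seed = 5L)
  s <- generate_scene(spec)
  lab <- EBImage::bwlabel(s$truth$atc_mask * 1)
  expect_equal(max(lab), 1)
})

test_that("planted junctions match an independent segment-intersection oracle", {
  spec <- random_scene_spec(n_isolated = 7, seed = 13L)
  s <- generate_scene(spec)
  # independent brute-force oracle over all segment pairs
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- p2 - p1; d2 <- p4 - p3
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(NULL)
    t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
    u <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
    if (t < 0 || t > 1 || u < 0 || u > 1) return(NULL)
    p1 + t * d1
  }
  pts <- NULL
  fb <- spec$fibers
  for (i in seq_along(fb)) for (j in seq_along(fb)) {
    if (j <= i) next
    x <- seg_int(fb[[i]]$control_points[1, ], fb[[i]]$control_points[2, ],
                 fb[[j]]$control_points[1, ], fb[[j]]$control_points[2, ])
    if (!is.null(x)) pts <- rbind(pts, x)
  }
  got <- s$truth$true_junctions
  if (is.null(pts)) {
    expect_equal(nrow(got), 0)
  } else {
    expect_equal(nrow(got), nrow(pts))
    ord1 <- order(got[, 1], got[, 2]); ord2 <- order(pts[, 1], pts[, 2])
    expect_equal(unname(got[ord1, , drop = FALSE]),
                 unname(pts[ord2, , drop = FALSE]), tolerance = 1e-9)
  }
  # per-fiber ground-truth lengths are polyline arc lengths
  for (f in spec$fibers)
    expect_equal(s$truth$per_fiber$true_length_px[s$truth$per_fiber$id == f$id],
                 fiber_length(f))
})

test_that("cohorts respect censoring, determinism and the planted hazard ratio", {
  co <- generate_cohort(cohort_spec(n_patients = 50, censoring_rate = 0, seed = 2L))
  expect_true(all(co$event))
  co2 <- generate_cohort(cohort_spec(n_patients = 50, censoring_rate = 0, seed = 2L))
  expect_identical(co, co2)
  co3 <- generate_cohort(cohort_spec(n_patients = 400, censoring_rate = 0.3, seed = 4L))
  expect_gt(mean(!co3$event), 0.2); expect_lt(mean(!co3$event), 0.4)

  # exponential medians: ratio of group medians ~ hazard ratio
  rats <- vapply(1:60, function(r) {
    co <- generate_cohort(cohort_spec(n_patients = 200, hazard_ratio = 2.5,
                                      planted_percentile = 40,
                                      censoring_rate = 0, seed = 4000L + r))
    thr <- attr(co, "planted_threshold")
    median(co$time[co$feature <= thr]) / median(co$time[co$feature > thr])
  }, numeric(1))
  expect_equal(mean(rats), 2.5, tolerance = 0.1)
})

test_that("null cohorts show no survival separation at any cutpoint", {
  ps <- vapply(1:40, function(r) {
    co <- generate_cohort(cohort_spec(n_patients = 120, hazard_ratio = 1,
                                      censoring_rate = 0, seed = 8000L + r))
    thr <- quantile(co$feature, 0.5)
    log_rank_test(co$time, co$event, co$feature > thr)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
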