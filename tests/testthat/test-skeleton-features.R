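# Skeletonization, junction/branch topology and the fiber features.

test_that("thinning reduces bars and single pixels to their centerlines", {
  sk <- skeletonize(bar_mask(50, 3))
  expect_equal(sk$n_junctions, 0)
  expect_equal(length(sk$branches), 1)
  expect_lt(abs(sk$total_length_px - 48), 3)

  px <- matrix(FALSE, 9, 9); px[5, 5] <- TRUE
  skp <- skeletonize(px)
  expect_equal(sum(skp$skeleton), 1)
  expect_equal(skp$total_length_px, 0)

  empty <- skeletonize(matrix(FALSE, 10, 10))
  expect_equal(sum(empty$skeleton), 0)
  expect_equal(length(empty$branches), 0)
})

test_that("a filled disk degenerates to a near-point skeleton", {
  d <- matrix(FALSE, 61, 61)
  d[(row(d) - 31)^2 + (col(d) - 31)^2 <= 400] <- TRUE
  sk <- skeletonize(d)
  expect_lte(sk$total_length_px, 45)
})

test_that("junction topology: plus-cross, straight fiber, planted crossings", {
  skx <- skeletonize(plus_mask())
  expect_equal(skx$n_junctions, 1)
  expect_equal(length(skx$branches), 4)

  skl <- skeletonize(bar_mask(60, 1))
  expect_equal(skl$n_junctions, 0)
  expect_equal(measure_cri(skl$n_junctions, skl$total_length_px), 0)

  # k well-separated planted X crossings -> exactly k junction clusters
  for (k in c(3L, 6L)) {
    mask <- matrix(FALSE, 420, 420)
    centers <- expand.grid(r = c(70, 210, 350), c = c(70, 210, 350))[seq_len(k), ]
    for (i in seq_len(k)) {
      ctr <- c(centers$r[i], centers$c[i])
      cv <- matrix(0, 420, 420)
      cv <- render_fiber(fiber_spec(rbind(ctr - 40, ctr + 40), 3, 60), cv)
      cv <- render_fiber(fiber_spec(rbind(ctr + c(-40, 40), ctr + c(40, -40)), 3, 60), cv)
      mask <- mask | (cv >= 30)
    }
    expect_equal(skeletonize(mask)$n_junctions, k)
  }
})

test_that("branch lengths use the (1, sqrt 2) geodesic metric", {
  m <- matrix(FALSE, 15, 15)
  for (i in 0:10) m[3 + i, 3 + i] <- TRUE   # 10 diagonal steps
  expect_equal(skeletonize(m)$total_length_px, 10 * sqrt(2), tolerance = 1e-12)
})

test_that("CFL recovers planted lengths; median of two branches is their mean", {
  one <- skeletonize(bar_mask(100, 3))
  expect_lt(abs(measure_cfl(one)$mean - 100) / 100, 0.05)

  m <- matrix(FALSE, 60, 200)
  m[19:21, 6:55] <- TRUE      # 50 px
  m[39:41, 6:155] <- TRUE     # 150 px
  cfl <- measure_cfl(skeletonize(m))
  expect_equal(cfl$n_branches, 2L)
  expect_lt(abs(cfl$mean - 100) / 100, 0.05)
  expect_equal(cfl$median, cfl$mean)   # even count: median = mean of the two

  expect_true(measure_cfl(skeletonize(matrix(FALSE, 8, 8)))$empty)
})

test_that("CFT tracks bar widths with the discretization floor at 1 px", {
  b5 <- bar_mask(50, 5)
  expect_lt(abs(measure_cft(b5, skeletonize(b5)) - 5), 1)
  b1 <- bar_mask(50, 1)
  cft1 <- measure_cft(b1, skeletonize(b1))
  expect_gte(cft1, 1); expect_lte(cft1, 2)
  m <- matrix(FALSE, 60, 120)
  m[10:12, 11:110] <- TRUE   # width 3
  m[30:38, 11:110] <- TRUE   # width 9
  expect_lt(abs(measure_cft(m, skeletonize(m)) - 6), 1)
  expect_true(is.na(measure_cft(matrix(FALSE, 5, 5),
                                skeletonize(matrix(FALSE, 5, 5)))))
})

test_that("CFD is the mean collagen signal and is linear in intensity", {
  map <- bar_mask(30, 3)
  img <- matrix(0, nrow(map), ncol(map)); img[map] <- 80
  expect_identical(measure_cfd(img, map), 80)
  expect_identical(measure_cfd(2 * img, map), 160)
  expect_true(is.na(measure_cfd(img, matrix(FALSE, nrow(map), ncol(map)))))
  # planted peak-200 vs peak-100 scenes differ twofold
  mk <- function(peak) {
    cv <- render_fiber(fiber_spec(rbind(c(30, 10), c(30, 90)), 4, peak),
                       matrix(0, 60, 100))
    measure_cfd(cv, cv >= peak / 2)
  }
  expect_equal(mk(200) / mk(100), 2, tolerance = 0.05)
})

test_that("CAR counts pixels exactly and CRI is junctions per unit length", {
  region <- matrix(TRUE, 100, 100)
  map <- matrix(FALSE, 100, 100); map[sample.int(10000, 1234)] <- TRUE
  expect_equal(measure_car(map, region), 0.1234)
  expect_equal(measure_car(region, region), 1)
  expect_equal(measure_car(matrix(FALSE, 100, 100), region), 0)
  expect_error(measure_car(map, matrix(FALSE, 100, 100)),
               class = "collprof_undefined_ratio_error")

  expect_equal(measure_cri(1, 200), 0.005)
  expect_equal(measure_cri(0, 0), 0)

  # fiber grid: junction count and CRI against the planted crossing count
  g <- matrix(FALSE, 120, 120)
  for (p in c(20, 45, 70, 95)) { g[p + 0:1, 10:110] <- TRUE; g[10:110, p + 0:1] <- TRUE }
  sk <- skeletonize(g)
  expect_equal(sk$n_junctions, 16)
  expect_lt(abs(measure_cri(sk$n_junctions, sk$total_length_px) -
                16 / sk$total_length_px), 1e-12)
})

test_that("measured CFL and CFT regress onto planted values with slope near 1", {
  pl <- do.call(rbind, lapply(1:20, function(s) {
    sf <- single_fiber_scene(s)
    gt <- sf$scene$truth$collagen_mask
    sk <- skeletonize(gt)
    data.frame(L = sf$L, f = sf$f, cfl = measure_cfl(sk)$mean,
               cft = measure_cft(gt, sk))
  }))
  expect_gt(coef(lm(cfl ~ L, pl))[2], 0.9); expect_lt(coef(lm(cfl ~ L, pl))[2], 1.1)
  expect_gt(coef(lm(cft ~ f, pl))[2], 0.9); expect_lt(coef(lm(cft ~ f, pl))[2], 1.1)
})

test_that("per-region profiling satisfies its accounting identities", {
  sc <- generate_scene(cluster_scene_spec(17L))
  seg <- segment_scene(sc)
  cft0 <- measure_cft(seg$collagen, skeletonize(seg$collagen), stat = "median")
  cmap <- split_atc_dtc(seg$img$shg, seg$collagen, seg$mask, cft0)
  fv <- profile_sample(seg$img, seg$mask, seg$collagen, cmap)
  reg <- fv$regions
  a <- reg[reg$region == "ATC", ]; d <- reg[reg$region == "DTC", ]
  al <- reg[reg$region == "ALL", ]
  # exact integer partition of collagen area
  expect_identical(al$collagen_area_px, a$collagen_area_px + d$collagen_area_px)
  # ALL CAR is the region-area-weighted mean of the compartment CARs
  expect_equal(al$car, (a$car * a$region_area_px + d$car * d$region_area_px) /
                         (a$region_area_px + d$region_area_px), tolerance = 1e-12)
  # brighter aggregated collagen: ATC CFD above DTC CFD
  expect_gt(a$cfd, d$cfd)

  # all-dispersed sample: ATC empty-flagged, ALL equals DTC
  sc2 <- generate_scene(random_scene_spec(n_isolated = 6, seed = 18L))
  seg2 <- segment_scene(sc2)
  cft2 <- measure_cft(seg2$collagen, skeletonize(seg2$collagen), stat = "median")
  cmap2 <- split_atc_dtc(seg2$img$shg, seg2$collagen, seg2$mask, cft2)
  fv2 <- profile_sample(seg2$img, seg2$mask, seg2$collagen, cmap2)
  r2 <- fv2$regions
  expect_true(r2$empty[r2$region == "ATC"])
  expect_equal(r2[r2$region == "ALL", c("car", "cfd", "cfl_mean", "cft_mean")],
               r2[r2$region == "DTC", c("car", "cfd", "cfl_mean", "cft_mean")],
               ignore_attr = TRUE)
})

test_that("features are stable under a 90-degree rotation", {
  frame <- matrix(TRUE, 320, 320)
  feats <- function(m, img) {
    sk <- skeletonize(m)
    c(cfl = measure_cfl(sk)$mean, cft = measure_cft(m, sk),
      car = measure_car(m, frame), cfd = measure_cfd(img, m),
      cri = measure_cri(sk$n_junctions, sk$total_length_px))
  }
  for (s in 1:3) {
    sc <- rotation_probe_scene(s)
    gt <- sc$truth$collagen_mask; shg <- sc$image$shg
    f0 <- feats(gt, shg); f1 <- feats(rot90(gt), rot90(shg))
    rel <- abs(f1 - f0) / abs(f0)
    expect_lt(rel[["cfl"]], 0.01); expect_lt(rel[["cft"]], 0.01)
    expect_lt(rel[["car"]], 0.01); expect_lt(rel[["cfd"]], 0.01)
    expect_lt(rel[["cri"]], 0.05)
  }
})

test_that("CFD ignores added collagen-free area while CAR dilutes", {
  map <- bar_mask(40, 3)
  img <- matrix(0, nrow(map), ncol(map)); img[map] <- 55
  big_map <- rbind(map, matrix(FALSE, 30, ncol(map)))
  big_img <- rbind(img, matrix(0, 30, ncol(img)))
  expect_identical(measure_cfd(img, map), measure_cfd(big_img, big_map))
  expect_lt(measure_car(big_map, matrix(TRUE, nrow(big_map), ncol(big_map))),
            measure_car(map, matrix(TRUE, nrow(map), ncol(map))))
})
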