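# Survival machinery: product-limit curves, log-rank, the percentile
# cutpoint scan, four-group stratification, ANOVA/Tukey comparisons.

test_that("the product-limit estimator matches hand computation", {
  km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$surv, c(2/3, 1/3, 0))

  expect_equal(km_estimate(c(2, 5, 9), c(FALSE, FALSE, FALSE))$surv,
               c(1, 1, 1))

  # mixed 6-subject toy, risk sets enumerated by hand:
  # t=1 (6 at risk, 1 event) -> 5/6; t=3 (4, 1) -> 5/8; t=4 (3, 2) -> 5/24
  km6 <- km_estimate(c(1, 2, 3, 4, 4, 5), c(1, 0, 1, 1, 1, 0))
  expect_equal(km6$surv[km6$time == 1], 5/6)
  expect_equal(km6$surv[km6$time == 3], 5/8)
  expect_equal(km6$surv[km6$time == 4], 5/24)

  expect_error(km_estimate(c(-1, 2), c(1, 1)), class = "collprof_input_error")
})

test_that("log-rank matches the hand observed-minus-expected form", {
  # identical groups: statistic exactly 0
  expect_equal(log_rank_test(c(1, 2, 3, 1, 2, 3), rep(1, 6),
                             rep(c("a", "b"), each = 3))$statistic, 0)
  # complete separation, 4 subjects: O_A = 2, E_A = 5/6, V = 17/36
  # -> chi-square = (7/6)^2 / (17/36) = 49/17
  lr <- log_rank_test(c(1, 2, 3, 4), rep(1, 4), c("a", "a", "b", "b"))
  expect_equal(lr$statistic, 49/17, tolerance = 1e-12)
  expect_equal(lr$df, 1L)
  expect_error(log_rank_test(c(1, 2), c(1, 1), c("a", "a")),
               class = "collprof_degenerate_grouping_error")
})

test_that("log-rank p-values are uniform under label permutation", {
  set.seed(9)
  times <- rexp(40); events <- rep(TRUE, 40)
  ps <- vapply(1:500, function(i)
    log_rank_test(times, events, sample(rep(c("a", "b"), 20)))$p_value,
    numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("the percentile scan recovers a planted cutpoint", {
  hits <- vapply(1:30, function(r) {
    co <- generate_cohort(cohort_spec(n_patients = 200, planted_percentile = 40,
                                      hazard_ratio = 2.5, censoring_rate = 0,
                                      seed = 100L + r))
    dichotomize_best_separation(co$feature, co$time, co$event)$selected_percentile
  }, numeric(1))
  expect_gte(mean(hits == 40), 0.8)
})

test_that("scan guards: constant features, small n, multiplicity disclosure", {
  co <- generate_cohort(cohort_spec(n_patients = 100, seed = 1L))
  expect_error(dichotomize_best_separation(rep(1, 100), co$time, co$event),
               class = "collprof_no_cutpoint_error")
  expect_error(dichotomize_best_separation(co$feature[1:10], co$time[1:10],
                                           co$event[1:10]),
               class = "collprof_input_error")
  ts <- dichotomize_best_separation(co$feature, co$time, co$event)
  expect_match(ts$multiplicity_warning, "anti-conservative")
  expect_true(ts$selected_percentile %in% seq(10, 90, 10))
  # both resulting groups nonempty
  n_high <- ts$scan$n_high[ts$scan$percentile == ts$selected_percentile]
  expect_gt(n_high, 0); expect_lt(n_high, ts$n)
})

test_that("the scan is invariant to strictly monotone feature transforms", {
  co <- generate_cohort(cohort_spec(n_patients = 150, planted_percentile = 30,
                                    hazard_ratio = 3, seed = 6L))
  s1 <- dichotomize_best_separation(co$feature, co$time, co$event)
  s2 <- dichotomize_best_separation(log(co$feature), co$time, co$event)
  s3 <- dichotomize_best_separation(rank(co$feature), co$time, co$event)
  expect_equal(s1$selected_percentile, s2$selected_percentile)
  expect_equal(s1$selected_percentile, s3$selected_percentile)
  expect_equal(s1$scan$p, s2$scan$p, tolerance = 1e-9)
})

test_that("cutpoint recovery improves with the planted hazard ratio", {
  acc <- vapply(c(1.5, 2.5, 4), function(hr) {
    mean(vapply(1:25, function(r) {
      co <- generate_cohort(cohort_spec(n_patients = 200, planted_percentile = 40,
                                        hazard_ratio = hr, censoring_rate = 0,
                                        seed = 300L + r))
      dichotomize_best_separation(co$feature, co$time, co$event)$selected_percentile == 40
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
})

test_that("under the null the selected minimum p is anti-conservative", {
  minp <- vapply(1:60, function(r) {
    co <- generate_cohort(cohort_spec(n_patients = 120, hazard_ratio = 1,
                                      censoring_rate = 0, seed = 700L + r))
    dichotomize_best_separation(co$feature, co$time, co$event)$selected_p
  }, numeric(1))
  # stochastically smaller than uniform
  expect_lt(median(minp), 0.5)
  expect_gt(mean(minp < 0.05), 0.1)
})

test_that("four-group stratification labels, sizes and planted risk ordering", {
  set.seed(12)
  n <- 400
  a <- rnorm(n); b <- rnorm(n)
  # only the (-,+) cell carries triple hazard
  risk <- a < 0 & b >= 0
  times <- rexp(n, 0.1 * ifelse(risk, 3, 1))
  rec <- data.frame(patient_id = sprintf("P%03d", 1:n), atc_cfd = a, dtc_cfl = b,
                    dfs_time = times, dfs_event = TRUE)
  fg <- four_group_stratify(rec, thr_a = 0, thr_b = 0)
  expect_equal(sum(fg$group_sizes), n)
  expect_true(all(abs(fg$group_sizes - n / 4) < 4 * sqrt(n * 3 / 16)))
  lr <- fg$endpoints$dfs$logrank
  expect_equal(lr$df, 3L)
  expect_lt(lr$p_value, 0.01)
  # the high-risk cell has the lowest curve at its median follow-up
  km <- fg$endpoints$dfs$km
  s_at <- function(k, t) { i <- findInterval(t, k$time); if (i == 0) 1 else k$surv[i] }
  tref <- median(times)
  s <- vapply(km, s_at, numeric(1), t = tref)
  expect_equal(names(which.min(s)), "-+")

  # a threshold below every value empties the two "-" cells; flagged, no error
  fg2 <- four_group_stratify(rec, thr_a = min(a) - 1, thr_b = 0)
  expect_length(fg2$empty_groups, 2)
  expect_setequal(fg2$empty_groups, c("-+", "--"))
})

test_that("group comparisons run ANOVA + Tukey with the paper-style stars", {
  set.seed(5)
  g1 <- rnorm(30); g2 <- rnorm(30) + 5  # 5 SD shift
  cg <- compare_groups(c(g1, g2), rep(c("a", "b"), each = 30))
  expect_lt(cg$pairwise$p_adj[1], 1e-4)
  expect_equal(cg$pairwise$stars[1], "****")

  cg0 <- compare_groups(rep(c(1, 2, 3), 4), rep(c("x", "y"), each = 6))
  expect_lt(cg0$anova_F, 1e-10)

  expect_warning(
    cg1 <- compare_groups(c(rnorm(10), rnorm(10), 1),
                          rep(c("a", "b", "c"), c(10, 10, 1))),
    "dropping")
  expect_equal(cg1$dropped_groups, "c")
  expect_equal(nrow(cg1$pairwise), 1)
})

test_that("cox and log-rank scan metrics select compatible cutpoints", {
  co <- generate_cohort(cohort_spec(n_patients = 200, planted_percentile = 50,
                                    hazard_ratio = 3, seed = 42L))
  s_cox <- dichotomize_best_separation(co$feature, co$time, co$event, metric = "cox_p")
  s_lr <- dichotomize_best_separation(co$feature, co$time, co$event, metric = "logrank_p")
  expect_equal(s_cox$selected_percentile, s_lr$selected_percentile)
})
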