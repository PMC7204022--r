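# Simulated patient cohorts with a planted feature cutpoint: survival times
# are exponential with a hazard that jumps by a known ratio when the imaging
# feature exceeds a planted quantile. Used to validate the percentile-grid
# cutpoint scan.

#' Specify a synthetic survival cohort
#'
#' @param n_patients cohort size (>= 2).
#' @param feature_distribution list with `name` ("lognormal" or "normal")
#'   and its parameters (`meanlog`/`sdlog` or `mean`/`sd`).
#' @param planted_percentile cutpoint quantile, one of 10, 20, ..., 90.
#' @param hazard_ratio hazard multiplier (> 0) for patients whose feature
#'   exceeds the planted quantile.
#' @param baseline_hazard events per unit time for the below-cutpoint group.
#' @param censoring_rate expected fraction of independently censored
#'   subjects, in [0, 1).
#' @param seed integer.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 200L,
                        feature_distribution = list(name = "lognormal", meanlog = 0, sdlog = 0.5),
                        planted_percentile = 40, hazard_ratio = 2.5,
                        baseline_hazard = 0.1, censoring_rate = 0,
                        seed = 1L) {
  if (n_patients < 2L) stop("n_patients must be >= 2")
  if (!planted_percentile %in% seq(10, 90, 10))
    stop("planted_percentile must lie on the 10% grid")
  if (hazard_ratio <= 0)
    stop_collprof("collprof_input_error", "hazard_ratio must be > 0")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must be in [0, 1)")
  structure(list(n_patients = as.integer(n_patients),
                 feature_distribution = feature_distribution,
                 planted_percentile = planted_percentile,
                 hazard_ratio = hazard_ratio,
                 baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with a planted survival cutpoint
#'
#' Event times are exponential with rate
#' `baseline_hazard * hazard_ratio^(feature > planted quantile)`; censored
#' subjects (a seeded Bernoulli draw at `censoring_rate`) are observed at a
#' uniform fraction of their event time, keeping censoring independent of
#' group membership.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame (patient_id, feature, time, event) with the realized
#'   planted threshold in attribute `"planted_threshold"`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  fd <- spec$feature_distribution
  feature <- switch(fd$name,
    lognormal = rlnorm(n, fd$meanlog, fd$sdlog),
    normal = rnorm(n, fd$mean, fd$sd),
    stop("unknown feature_distribution"))
  thr <- quantile(feature, spec$planted_percentile / 100, names = FALSE)
  rate <- spec$baseline_hazard * ifelse(feature > thr, spec$hazard_ratio, 1)
  t_event <- rexp(n, rate)
  censored <- runif(n) < spec$censoring_rate
  time <- ifelse(censored, t_event * runif(n), t_event)
  out <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                    feature = feature, time = time, event = !censored)
  attr(out, "planted_threshold") <- thr
  out
}

#' Write a cohort table as CSV (patient_id, feature, time, event)
#' @param cohort data.frame from [generate_cohort()].
#' @param path output path.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
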