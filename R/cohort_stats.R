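# Cohort-level survival statistics: Kaplan-Meier estimation, log-rank
# tests, percentile-grid optimal-cutpoint dichotomization of imaging
# features, the two-feature four-group prognostic stratification, and
# one-way ANOVA / Tukey HSD group comparisons. Standard estimators are
# delegated to the survival package and stats; this module owns the scan
# and stratification logic.

#' Kaplan-Meier (product-limit) survival curve
#'
#' @param times non-negative follow-up times.
#' @param events logical/0-1 event indicators (FALSE = censored).
#' @return object of class `km_curve`: time, surv, n_risk, n_event,
#'   n_censor (one row per distinct observed time).
#' @export
km_estimate <- function(times, events) {
  if (any(times < 0))
    stop_collprof("collprof_input_error", "negative survival time")
  stopifnot(length(times) == length(events), length(times) >= 1L)
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1,
                           conf.type = "none")
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 n = length(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d event times, final S(t) = %.3f\n",
              x$n, sum(x$n_event > 0), tail_or(x$surv, 1)))
  invisible(x)
}

tail_or <- function(v, default) if (length(v)) v[length(v)] else default

#' @export
plot.km_curve <- function(x, ..., col = 1, add = FALSE, xlab = "Time",
                          ylab = "Survival probability") {
  t0 <- c(0, rep(x$time, each = 2))
  s0 <- c(1, 1, rep(x$surv[-length(x$surv)], each = 2), tail_or(x$surv, 1))
  if (length(x$time) == 0) { t0 <- c(0, 1); s0 <- c(1, 1) }
  if (!add) plot(t0, s0, type = "l", col = col, ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, ...)
  else lines(t0, s0, col = col, ...)
  invisible(x)
}

#' Log-rank test across groups
#'
#' Standard (unweighted) log-rank chi-square with k - 1 degrees of freedom.
#'
#' @param times,events as in [km_estimate()].
#' @param groups group labels (>= 2 non-empty groups).
#' @return list(statistic, df, p_value, n_groups).
#' @export
log_rank_test <- function(times, events, groups) {
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L)
    stop_collprof("collprof_degenerate_grouping_error",
                  "log-rank needs at least two non-empty groups")
  sd_ <- survival::survdiff(survival::Surv(times, as.integer(events)) ~ groups)
  df <- nlevels(groups) - 1L
  list(statistic = unname(sd_$chisq), df = df,
       p_value = pchisq(sd_$chisq, df, lower.tail = FALSE),
       n_groups = nlevels(groups))
}

# Separation p-value for a binary split: Cox proportional-hazards score
# test (default; asymptotically the log-rank for a binary covariate) or
# the log-rank test itself.
.separation_p <- function(times, events, high, metric) {
  if (metric == "cox_p") {
    fit <- survival::coxph(survival::Surv(times, as.integer(events)) ~ high)
    sct <- summary(fit)$sctest
    unname(sct["pvalue"])
  } else {
    log_rank_test(times, events, high)$p_value
  }
}

#' Dichotomize a feature at its best-separating percentile
#'
#' Candidate thresholds are the feature's percentiles on a 10% grid
#' (10th...90th by default). For each candidate the cohort is split at the
#' threshold and a survival-separation p-value is computed (univariate Cox
#' score test by default, or log-rank). The candidate with the smallest
#' p-value wins; ties go to the lower threshold. Candidates leaving a group
#' smaller than `min_group_frac` of the cohort are skipped.
#'
#' Because the winning p-value is a minimum over the grid it is
#' anti-conservative under the null; the returned object carries an
#' explicit multiplicity warning and the per-candidate table so the
#' selection effect is visible.
#'
#' @param values numeric feature values.
#' @param times,events survival outcome.
#' @param metric "cox_p" (default) or "logrank_p".
#' @param percentiles candidate grid (percent units).
#' @param min_group_frac smallest admissible group as a fraction of n.
#' @param min_n minimum number of complete cases.
#' @return object of class `threshold_scan`: scan table (percentile,
#'   threshold, n_high, p), selected_percentile, selected_threshold,
#'   selection rule, multiplicity_warning.
#' @export
dichotomize_best_separation <- function(values, times, events,
                                        metric = c("cox_p", "logrank_p"),
                                        percentiles = seq(10, 90, 10),
                                        min_group_frac = 0.1, min_n = 20L) {
  metric <- match.arg(metric)
  ok <- complete.cases(values, times, events)
  values <- values[ok]; times <- times[ok]; events <- events[ok]
  n <- length(values)
  if (n < min_n)
    stop_collprof("collprof_input_error",
                  sprintf("only %d complete cases; need >= %d", n, min_n))
  scan <- data.frame(percentile = percentiles,
                     threshold = quantile(values, percentiles / 100, names = FALSE),
                     n_high = NA_integer_, p = NA_real_, skipped = TRUE)
  for (i in seq_len(nrow(scan))) {
    high <- values >= scan$threshold[i]
    nh <- sum(high)
    scan$n_high[i] <- nh
    if (nh < min_group_frac * n || (n - nh) < min_group_frac * n) next
    scan$p[i] <- .separation_p(times, events, high, metric)
    scan$skipped[i] <- FALSE
  }
  if (all(scan$skipped))
    stop_collprof("collprof_no_cutpoint_error",
                  "no percentile candidate yields two admissible groups")
  usable <- which(!scan$skipped)
  best <- usable[which.min(scan$p[usable])]   # which.min ties -> earliest = lower threshold
  structure(list(scan = scan,
                 selected_percentile = scan$percentile[best],
                 selected_threshold = scan$threshold[best],
                 selected_p = scan$p[best],
                 metric = metric, n = n,
                 multiplicity_warning = paste(
                   "selected p-value is the minimum over", length(usable),
                   "candidate cutpoints and is anti-conservative under the null;",
                   "interpret as descriptive, not as a calibrated test")),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("<threshold_scan> n = %d, metric = %s\n", x$n, x$metric))
  print(x$scan, row.names = FALSE, digits = 4)
  cat(sprintf("selected: %dth percentile (threshold %.4g, p = %.3g)\n",
              x$selected_percentile, x$selected_threshold, x$selected_p))
  cat("note:", x$multiplicity_warning, "\n")
  invisible(x)
}

#' Four-group stratification on two dichotomized features
#'
#' Each patient is labelled by the sign pair of the two features relative
#' to their thresholds ("+" means feature >= threshold), yielding groups
#' (+,+), (+,-), (-,+), (-,-). Kaplan-Meier curves and a 3-df log-rank
#' test are computed per endpoint.
#'
#' @param records data.frame holding the two feature columns and, per
#'   endpoint, `<endpoint>_time` and `<endpoint>_event` columns.
#' @param feature_a,feature_b column names of the two features (defaults:
#'   ATC CFD and DTC CFL, the prognostic pair).
#' @param thr_a,thr_b finite thresholds.
#' @param endpoints character vector of endpoint prefixes.
#' @return object of class `four_group_model`: labels, group_sizes,
#'   empty_groups, thresholds, per-endpoint list(km = per-group
#'   `km_curve`s, logrank).
#' @export
four_group_stratify <- function(records, thr_a, thr_b,
                                feature_a = "atc_cfd", feature_b = "dtc_cfl",
                                endpoints = c("dfs", "os")) {
  stopifnot(is.finite(thr_a), is.finite(thr_b),
            all(c(feature_a, feature_b) %in% names(records)))
  ok <- complete.cases(records[[feature_a]], records[[feature_b]])
  rec <- records[ok, , drop = FALSE]
  a_plus <- rec[[feature_a]] >= thr_a
  b_plus <- rec[[feature_b]] >= thr_b
  lab <- factor(paste0(ifelse(a_plus, "+", "-"), ifelse(b_plus, "+", "-")),
                levels = c("++", "+-", "-+", "--"))
  sizes <- table(lab)
  endpoint_out <- list()
  for (ep in endpoints) {
    tcol <- paste0(ep, "_time"); ecol <- paste0(ep, "_event")
    if (!all(c(tcol, ecol) %in% names(rec))) next
    km <- lapply(levels(lab), function(l) {
      sel <- lab == l
      if (!any(sel)) return(NULL)
      km_estimate(rec[[tcol]][sel], rec[[ecol]][sel])
    })
    names(km) <- levels(lab)
    nonempty <- lab[, drop = TRUE]
    lr <- if (nlevels(droplevels(lab)) >= 2L)
      log_rank_test(rec[[tcol]], rec[[ecol]], lab) else NULL
    endpoint_out[[ep]] <- list(km = km, logrank = lr)
  }
  pid <- rec$patient_id
  if (is.null(pid)) pid <- rec$sample_id
  if (is.null(pid)) pid <- as.character(seq_len(nrow(rec)))
  structure(list(labels = lab, patient_id = pid,
                 group_sizes = as.integer(sizes),
                 group_names = names(sizes),
                 empty_groups = names(sizes)[sizes == 0],
                 thresholds = c(setNames(thr_a, feature_a),
                                setNames(thr_b, feature_b)),
                 features = c(feature_a, feature_b),
                 endpoints = endpoint_out, n = nrow(rec)),
            class = "four_group_model")
}

#' @export
print.four_group_model <- function(x, ...) {
  cat(sprintf("<four_group_model> n = %d, features %s (thr %.4g) x %s (thr %.4g)\n",
              x$n, x$features[1], x$thresholds[1], x$features[2], x$thresholds[2]))
  cat("group sizes:", paste(sprintf("%s: %d", x$group_names, x$group_sizes),
                            collapse = ", "), "\n")
  if (length(x$empty_groups))
    cat("WARNING: empty groups:", paste(x$empty_groups, collapse = ", "), "\n")
  for (ep in names(x$endpoints)) {
    lr <- x$endpoints[[ep]]$logrank
    if (!is.null(lr))
      cat(sprintf("%s: log-rank chi-sq %.3f (df %d), p = %.4g\n",
                  toupper(ep), lr$statistic, lr$df, lr$p_value))
  }
  invisible(x)
}

#' @export
plot.four_group_model <- function(x, endpoint = names(x$endpoints)[1],
                                  col = c("blue", "black", "green4", "red"),
                                  ...) {
  km <- x$endpoints[[endpoint]]$km
  first <- TRUE
  for (i in seq_along(km)) {
    if (is.null(km[[i]])) next
    plot(km[[i]], col = col[i], add = !first,
         xlab = sprintf("%s time", toupper(endpoint)), ...)
    first <- FALSE
  }
  legend("bottomleft", legend = paste0("(", substr(names(km), 1, 1), ",",
                                       substr(names(km), 2, 2), ")"),
         col = col, lty = 1, bty = "n")
  invisible(x)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' @param values numeric response.
#' @param groups group labels; groups with fewer than 2 values are dropped
#'   with a warning.
#' @return list(anova_F, anova_p, pairwise = data.frame(comparison, diff,
#'   p_adj, stars), dropped_groups).
#' @export
compare_groups <- function(values, groups) {
  groups <- as.factor(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  counts <- table(groups)
  dropped <- names(counts)[counts < 2L]
  if (length(dropped)) {
    warning("dropping groups with < 2 values: ", paste(dropped, collapse = ", "))
    keep <- !groups %in% dropped
    values <- values[keep]; groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2L)
    stop_collprof("collprof_degenerate_grouping_error",
                  "need at least two groups with >= 2 values")
  fit <- aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$groups
  stars <- function(p) ifelse(p < 1e-4, "****", ifelse(p < 1e-3, "***",
            ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))))
  pw <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                   p_adj = tk[, "p adj"], stars = stars(tk[, "p adj"]),
                   row.names = NULL)
  list(anova_F = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
       pairwise = pw, dropped_groups = dropped)
}
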