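# Two-component Gaussian mixture intensity model. Pixel intensities inside
# the sample mask are modelled as a background mode plus a signal mode; the
# binarization threshold is the Bayes-optimal boundary where the two
# weighted component densities are equal (posterior probability 0.5).
#
# The EM is written out rather than delegated: initialization (median
# split), the convergence rule, component ordering and the threshold
# functional are all part of the pipeline contract and must be
# deterministic given the data.

#' Fit a two-mode Gaussian mixture to pixel intensities
#'
#' Expectation-maximization with deterministic initialization: the sample is
#' split at its median and each half provides the starting mean/variance.
#' Components are reported sorted by mean. Convergence when the relative
#' log-likelihood change falls below `tol` (default 1e-6) or after
#' `max_iter` iterations. Samples larger than `subsample_above` pixels are
#' uniformly subsampled (seeded) before fitting.
#'
#' @param intensities numeric vector of masked pixel intensities (>= 100).
#' @param seed integer, used only when subsampling triggers.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap.
#' @param subsample_above pixel count above which uniform subsampling to
#'   this size is applied.
#' @return object of class `gmm_fit`: weights, means (low, high),
#'   variances, threshold, threshold_fallback flag, log_likelihood, n_iter,
#'   converged, n_used.
#' @export
fit_two_mode_gmm <- function(intensities, seed = 1L, tol = 1e-6,
                             max_iter = 500L, subsample_above = 1e6) {
  x <- as.numeric(intensities)
  x <- x[is.finite(x)]
  if (length(x) < 100L)
    stop_collprof("collprof_input_error", "need at least 100 pixels to fit the mixture")
  if (var(x) == 0 || diff(range(x)) < .Machine$double.eps^0.5)
    stop_collprof("collprof_unimodal_error", "constant intensities: mixture is degenerate")
  if (length(x) > subsample_above) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    x <- x[sample.int(length(x), subsample_above)]
  }
  med <- median(x)
  lo <- x[x <= med]; hi <- x[x > med]
  if (!length(hi)) { lo <- x[x < med]; hi <- x[x >= med] }
  var_floor <- max(var(x) * 1e-6, .Machine$double.eps)
  mu <- c(mean(lo), mean(hi))
  s2 <- pmax(c(var(lo), var(hi)), var_floor)
  s2[is.na(s2)] <- var_floor
  w <- c(length(lo), length(hi)) / length(x)
  ll_old <- -Inf; converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], sqrt(s2[1]))
    d2 <- w[2] * dnorm(x, mu[2], sqrt(s2[2]))
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    r2 <- d2 / tot
    r1 <- 1 - r2
    n1 <- sum(r1); n2 <- sum(r2)
    if (n1 < 1e-8 || n2 < 1e-8)
      stop_collprof("collprof_unimodal_error", "one mixture component collapsed")
    w <- c(n1, n2) / length(x)
    mu <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
    s2 <- pmax(c(sum(r1 * (x - mu[1])^2) / n1, sum(r2 * (x - mu[2])^2) / n2), var_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) { converged <- TRUE; break }
    ll_old <- ll
  }
  ord <- order(mu)
  fit <- structure(list(weights = w[ord], means = mu[ord], variances = s2[ord],
                        log_likelihood = ll, n_iter = it, converged = converged,
                        n_used = length(x)),
                   class = "gmm_fit")
  thr <- gmm_threshold(fit)
  fit$threshold <- thr
  fit$threshold_fallback <- attr(thr, "fallback")
  fit$threshold <- as.numeric(thr)
  fit
}

# save/restore .Random.seed so seeded subsampling does not disturb the
# caller's RNG stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Bayes-boundary threshold of a fitted two-mode mixture
#'
#' The intensity between the two component means at which the weighted
#' densities are equal (equivalently, posterior probability 0.5 for each
#' component). If the weighted densities do not cross between the means
#' (pathological overlap), the midpoint of the means is returned and the
#' result carries attribute `fallback = TRUE`.
#'
#' @param fit a `gmm_fit`.
#' @return numeric threshold with attribute `fallback`.
#' @export
gmm_threshold <- function(fit) {
  stopifnot(inherits(fit, "gmm_fit"))
  m <- fit$means; s <- sqrt(fit$variances); w <- fit$weights
  f <- function(x) log(w[1]) + dnorm(x, m[1], s[1], log = TRUE) -
                   log(w[2]) - dnorm(x, m[2], s[2], log = TRUE)
  lo <- m[1]; hi <- m[2]
  if (hi - lo < .Machine$double.eps^0.5)
    return(structure(mean(m), fallback = FALSE))
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    return(structure(mean(m), fallback = TRUE))
  root <- uniroot(f, c(lo, hi), tol = 1e-10)$root
  structure(root, fallback = FALSE)
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf(paste0("<gmm_fit> two-mode Gaussian mixture (n = %d)\n",
                     "  low  mode: mean %8.3f  sd %7.3f  weight %.3f\n",
                     "  high mode: mean %8.3f  sd %7.3f  weight %.3f\n",
                     "  threshold %.3f%s | logLik %.1f | %d EM iterations%s\n"),
              x$n_used, x$means[1], sqrt(x$variances[1]), x$weights[1],
              x$means[2], sqrt(x$variances[2]), x$weights[2],
              x$threshold, if (isTRUE(x$threshold_fallback)) " (midpoint fallback)" else "",
              x$log_likelihood, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
summary.gmm_fit <- function(object, ...) {
  out <- with(object, data.frame(
    component = c("low", "high"), weight = weights, mean = means,
    sd = sqrt(variances)))
  attr(out, "threshold") <- object$threshold
  out
}

#' Binarize a channel at a threshold within the sample mask
#'
#' Pure pixelwise comparison: a pixel is positive iff it lies in the mask
#' and its intensity is >= the threshold. No morphological cleanup.
#'
#' @param channel numeric intensity matrix.
#' @param mask a [compute_sample_mask()] result or logical matrix.
#' @param threshold finite numeric.
#' @param source_channel "shg" or "tpe" (provenance).
#' @return object of class `binary_map`: list(map, source_channel,
#'   threshold_used).
#' @export
binarize <- function(channel, mask, threshold, source_channel = "shg") {
  assert_matrix_like(channel, "channel")
  if (inherits(mask, "sample_mask")) mask <- mask$mask
  if (!identical(dim(channel), dim(mask)))
    stop_collprof("collprof_format_error", "channel/mask shape mismatch")
  if (!is.finite(threshold)) stop("threshold must be finite")
  structure(list(map = (channel >= threshold) & mask,
                 source_channel = source_channel,
                 threshold_used = threshold),
            class = "binary_map")
}

#' @export
print.binary_map <- function(x, ...) {
  cat(sprintf("<binary_map> %s channel, threshold %.3f, %d positive px\n",
              x$source_channel, x$threshold_used, sum(x$map)))
  invisible(x)
}
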