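# Two-channel TMA image container, TIFF reading, and the tissue sample mask.

#' Two-channel TMA image
#'
#' @param shg,tpe numeric intensity matrices of equal shape (SHG = collagen
#'   signal, TPE = tissue autofluorescence).
#' @param pixel_size_um microns per pixel.
#' @param sample_id identifier string.
#' @return object of class `tma_image`.
#' @export
tma_image <- function(shg, tpe, pixel_size_um = NA_real_, sample_id = "sample") {
  assert_matrix_like(shg, "shg"); assert_matrix_like(tpe, "tpe")
  if (!identical(dim(shg), dim(tpe)))
    stop_collprof("collprof_format_error", "SHG and TPE channels differ in shape")
  if (min(shg) < 0 || min(tpe) < 0)
    stop_collprof("collprof_format_error", "intensities must be non-negative")
  structure(list(shg = shg, tpe = tpe, pixel_size_um = pixel_size_um,
                 sample_id = sample_id), class = "tma_image")
}

#' @export
print.tma_image <- function(x, ...) {
  cat(sprintf("<tma_image> %s: %d x %d px, pixel size %s um\n  SHG range [%.1f, %.1f], TPE range [%.1f, %.1f]\n",
              x$sample_id, nrow(x$shg), ncol(x$shg),
              ifelse(is.na(x$pixel_size_um), "?", format(x$pixel_size_um)),
              min(x$shg), max(x$shg), min(x$tpe), max(x$tpe)))
  invisible(x)
}

#' Read a two-channel TMA image from TIFF
#'
#' Accepts either a single multi-page TIFF (two pages) or a pair of
#' single-page files. 16-bit scenes written by [write_scene()] round-trip
#' bit-exactly on the 0..65535 integer scale.
#'
#' @param path TIFF path (or first channel's path when `path2` given).
#' @param path2 optional second single-page TIFF.
#' @param channel_order "shg_first" or "tpe_first".
#' @param pixel_size_um metadata override (TIFF tags rarely carry it).
#' @param sample_id defaults to the file base name.
#' @param intensity_scale multiply the 0..1 normalized values read by tiff
#'   by this factor; default 65535 restores the stored integer scale.
#' @return a [tma_image()].
#' @export
read_tma_image <- function(path, path2 = NULL,
                           channel_order = c("shg_first", "tpe_first"),
                           pixel_size_um = NA_real_, sample_id = NULL,
                           intensity_scale = 65535) {
  channel_order <- match.arg(channel_order)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop_collprof("collprof_format_error",
                      sprintf("cannot read TIFF '%s': %s", path, conditionMessage(e))))
  if (!is.null(path2)) {
    p2 <- tryCatch(tiff::readTIFF(path2, all = TRUE),
                   error = function(e) stop_collprof("collprof_format_error",
                     sprintf("cannot read TIFF '%s': %s", path2, conditionMessage(e))))
    pages <- c(pages[1], p2[1])
  }
  if (length(pages) < 2L)
    stop_collprof("collprof_format_error",
                  "need two channels: a 2-page TIFF or a pair of single-page files")
  as_mat <- function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]   # drop extra samples if any
    p * intensity_scale
  }
  ch1 <- as_mat(pages[[1]]); ch2 <- as_mat(pages[[2]])
  if (!identical(dim(ch1), dim(ch2)))
    stop_collprof("collprof_format_error", "channel shape mismatch")
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  if (channel_order == "shg_first")
    tma_image(ch1, ch2, pixel_size_um, sample_id)
  else
    tma_image(ch2, ch1, pixel_size_um, sample_id)
}

#' Compute the tissue sample mask
#'
#' The mask covers the area occupied by tissue: a two-mode Gaussian mixture
#' is fitted to the TPE channel and its density-equality threshold separates
#' tissue from background; SHG-positive pixels (same mixture scheme, when
#' the SHG histogram is bimodal) are added so collagen lying over faint
#' autofluorescence is retained. The union is closed with a 5-px-radius
#' disc, hole-filled, and reduced to its largest connected component.
#'
#' @param img a [tma_image()].
#' @param min_area_frac smallest acceptable mask area as a fraction of the
#'   frame; below it an empty-mask error is raised.
#' @param closing_radius_px radius of the smoothing disc.
#' @param seed passed to the mixture fit (used only if pixel subsampling
#'   kicks in).
#' @return object of class `sample_mask`: list(mask, area_px, tpe_threshold).
#' @export
compute_sample_mask <- function(img, min_area_frac = 0.01,
                                closing_radius_px = 5, seed = 1L) {
  stopifnot(inherits(img, "tma_image"))
  # a fit only defines a tissue/background split when its modes genuinely
  # separate; a near-unimodal histogram (homogeneous frame) does not
  # A two-mode fit only defines a tissue/background split when it beats a
  # single Gaussian by BIC; the EM will happily split a homogeneous frame
  # at its median, but with essentially no likelihood gain.
  fit_if_bimodal <- function(x) {
    fit <- tryCatch(fit_two_mode_gmm(x, seed = seed),
                    collprof_unimodal_error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    ll1 <- sum(dnorm(x, mean(x), sd(x), log = TRUE))
    n_ratio <- fit$n_used / length(x)   # fit may have subsampled
    dbic <- 2 * (fit$log_likelihood / n_ratio - ll1) - 3 * log(length(x))
    if (dbic > 0 && min(fit$weights) > 0.001) fit else NULL
  }
  fit <- fit_if_bimodal(as.vector(img$tpe))
  shg_fit <- fit_if_bimodal(as.vector(img$shg))
  if (is.null(fit) && is.null(shg_fit))
    stop_collprof("collprof_empty_mask_error",
                  "neither channel shows tissue/background contrast")
  if (!is.null(fit)) {
    raw <- img$tpe >= fit$threshold
  } else {
    # homogeneous TPE but clear collagen signal: tissue spans the frame
    raw <- matrix(TRUE, nrow(img$tpe), ncol(img$tpe))
  }
  if (!is.null(shg_fit)) raw <- raw | (img$shg >= shg_fit$threshold)
  tpe_threshold <- if (!is.null(fit)) fit$threshold else -Inf
  k <- disc_brush(2 * closing_radius_px + 1)
  m <- as_logical_matrix(EBImage::closing(raw * 1, k) > 0.5)
  m <- as_logical_matrix(EBImage::fillHull(m * 1) > 0.5)
  lab <- label_components(m, 8L)
  if (max(lab) == 0L)
    stop_collprof("collprof_empty_mask_error", "no tissue detected")
  tab <- tabulate(lab[lab > 0])
  m <- lab == which.max(tab)
  if (sum(m) < min_area_frac * length(m))
    stop_collprof("collprof_empty_mask_error",
                  sprintf("mask covers %.2f%% of frame, below the %.0f%% floor",
                          100 * sum(m) / length(m), 100 * min_area_frac))
  structure(list(mask = m, area_px = sum(m), tpe_threshold = tpe_threshold),
            class = "sample_mask")
}

#' @export
print.sample_mask <- function(x, ...) {
  cat(sprintf("<sample_mask> %d px (%.1f%% of frame), TPE threshold %.2f\n",
              x$area_px, 100 * x$area_px / length(x$mask), x$tpe_threshold))
  invisible(x)
}

#' Export a binary mask as a 1-bit-style PNG for QC
#' @param mask logical matrix or `sample_mask`.
#' @param path output PNG path.
#' @export
write_mask_png <- function(mask, path) {
  if (inherits(mask, "sample_mask")) mask <- mask$mask
  png::writePNG(mask * 1, path)
  invisible(path)
}
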