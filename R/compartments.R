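# ATC/DTC compartment separation. Aggregated thick collagen (ATC) is
# detected by grayscale morphological opening of the SHG channel with a
# disc whose diameter is a multiple (> 3, default 3.5) of the estimated
# collagen fiber thickness: structures thinner than the disc vanish under
# opening, so isolated fibers can never enter ATC, while aggregated regions
# survive. Everything else inside the sample mask is dispersed thin
# collagen (DTC).

#' Split the sample mask into ATC and DTC compartments
#'
#' Grayscale opening of the SHG channel with a disc of diameter
#' `se_scale * cft_estimate_px`; the opened image is re-thresholded at the
#' collagen threshold and intersected with the sample mask to form ATC; the
#' remainder of the mask is DTC. No dilation is applied after
#' re-thresholding: grayscale opening already preserves the full envelope
#' of any bright region that can contain the disc, so the re-thresholded
#' image covers whole aggregated structures (an extra dilation would push
#' the ATC boundary one disc radius into the dispersed compartment).
#'
#' @param shg SHG intensity matrix.
#' @param collagen a `binary_map` from [binarize()] (supplies the
#'   threshold).
#' @param mask a `sample_mask` or logical matrix.
#' @param cft_estimate_px preliminary collagen fiber thickness estimate in
#'   pixels (> 0), typically from [measure_cft()] on the whole binary.
#' @param se_scale multiple of the fiber thickness giving the disc
#'   diameter; must be >= 3.
#' @return object of class `compartment_map`: labels matrix (0 outside
#'   mask, 1 = ATC, 2 = DTC), se_diameter_px, atc_area_px, dtc_area_px.
#' @export
split_atc_dtc <- function(shg, collagen, mask, cft_estimate_px,
                          se_scale = 3.5) {
  assert_matrix_like(shg, "shg")
  if (inherits(mask, "sample_mask")) mask <- mask$mask
  stopifnot(inherits(collagen, "binary_map"))
  if (!is.finite(cft_estimate_px) || cft_estimate_px <= 0)
    stop("cft_estimate_px must be > 0")
  if (se_scale < 3) stop("se_scale must be >= 3")
  d <- se_scale * cft_estimate_px
  if (d < 3)
    stop_collprof("collprof_resolution_error",
                  sprintf("structuring element diameter %.2f px < 3 px: image too coarse", d))
  k <- disc_brush(d)
  # EBImage grayscale morphology expects [0, 1]; min/max filters commute
  # with positive scaling, so normalizing by the image maximum is exact
  scale <- max(shg, 1)
  opened <- EBImage::opening(shg / scale, k) * scale
  atc <- as_logical_matrix(opened >= collagen$threshold_used) & mask
  labels <- matrix(0L, nrow(shg), ncol(shg))
  labels[mask] <- 2L
  labels[atc] <- 1L
  structure(list(labels = labels, se_diameter_px = ncol(k),
                 atc_area_px = sum(labels == 1L),
                 dtc_area_px = sum(labels == 2L)),
            class = "compartment_map")
}

#' @export
print.compartment_map <- function(x, ...) {
  tot <- x$atc_area_px + x$dtc_area_px
  cat(sprintf("<compartment_map> SE disc %d px | ATC %d px (%.1f%%), DTC %d px (%.1f%%)\n",
              x$se_diameter_px, x$atc_area_px, 100 * x$atc_area_px / max(tot, 1),
              x$dtc_area_px, 100 * x$dtc_area_px / max(tot, 1)))
  invisible(x)
}

#' ATC area ratio
#'
#' Fraction of the total tissue area occupied by the aggregated-collagen
#' compartment: `atc_area_px / (atc_area_px + dtc_area_px)`.
#'
#' @param cmap a `compartment_map`.
#' @return numeric in [0, 1].
#' @export
atc_area_ratio <- function(cmap) {
  stopifnot(inherits(cmap, "compartment_map"))
  tot <- cmap$atc_area_px + cmap$dtc_area_px
  if (tot == 0)
    stop_collprof("collprof_undefined_ratio_error", "empty sample mask")
  cmap$atc_area_px / tot
}

#' Export a compartment map as a three-color QC PNG
#'
#' ATC red, DTC blue, background black.
#'
#' @param cmap a `compartment_map`.
#' @param path output path.
#' @export
write_compartment_png <- function(cmap, path) {
  a <- array(0, c(nrow(cmap$labels), ncol(cmap$labels), 3))
  a[, , 1][cmap$labels == 1L] <- 1
  a[, , 3][cmap$labels == 2L] <- 1
  png::writePNG(a, path)
  invisible(path)
}
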