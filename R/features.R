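# Per-region fiber morphometry. All features are measured three times, on
# the ATC and DTC compartments and on ALL (their union): collagen area
# ratio (CAR), collagen fiber density (CFD), fiber length (CFL, per
# skeleton branch), fiber thickness (CFT, distance transform at skeleton
# pixels), reticular index (CRI, junctions per unit skeleton length) and
# junction count. Empty regions yield NA ("missing"), never zero, so
# cohort statistics are not biased by blank compartments.

#' Mean and median collagen fiber length
#'
#' Branch lengths of the skeleton network (geodesic: orthogonal step 1,
#' diagonal step sqrt(2)); branches shorter than `min_branch_px` are
#' pruned as thinning spurs before aggregation.
#'
#' @param sk a `skeleton_graph`.
#' @param min_branch_px spur-pruning floor in pixels.
#' @return list(mean, median, n_branches); all NA with `empty = TRUE` when
#'   no branch survives.
#' @export
measure_cfl <- function(sk, min_branch_px = 3) {
  stopifnot(inherits(sk, "skeleton_graph"))
  len <- sk$branch_lengths[sk$branch_lengths >= min_branch_px]
  if (!length(len))
    return(list(mean = NA_real_, median = NA_real_, n_branches = 0L, empty = TRUE))
  list(mean = mean(len), median = median(len), n_branches = length(len),
       empty = FALSE)
}

#' Mean collagen fiber thickness
#'
#' Twice the Euclidean distance-transform value of the collagen binary
#' image sampled at skeleton pixels (junction clusters excluded), minus
#' one pixel so the estimate refers to the structure's edge-to-edge width
#' rather than the background-pixel-center distance: a bar of odd width w
#' gives exactly w. At each skeleton pixel the distance transform is read
#' at its medial ridge (the maximum over the pixel's 8-neighborhood),
#' which compensates the one-pixel placement freedom of the thinned
#' centerline on diagonal structures.
#'
#' @param collagen a `binary_map` or logical matrix.
#' @param sk a `skeleton_graph`.
#' @param stat "mean" (the reported feature) or "median" (robust variant
#'   used internally to size the compartment-opening disc, where thick
#'   aggregate blobs would inflate the mean).
#' @return numeric thickness in pixels, or NA when the skeleton is empty.
#' @export
measure_cft <- function(collagen, sk, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  map <- if (inherits(collagen, "binary_map")) collagen$map else collagen
  stopifnot(inherits(sk, "skeleton_graph"))
  sel <- sk$skeleton & sk$junction_label == 0L
  if (!any(sel)) {
    sel <- sk$skeleton           # junction-only skeleton: fall back to all px
    if (!any(sel)) return(NA_real_)
  }
  d <- EBImage::distmap(map * 1)
  d <- matrix(as.numeric(d), nrow(map), ncol(map))
  # ridge value: neighborhood max of the distance transform
  pad <- matrix(0, nrow(d) + 2L, ncol(d) + 2L)
  pad[2:(nrow(d) + 1L), 2:(ncol(d) + 1L)] <- d
  nr <- nrow(pad); nc <- ncol(pad)
  sh <- function(dr, dc) pad[(2L + dr):(nr - 1L + dr), (2L + dc):(nc - 1L + dc)]
  dmax <- pmax(sh(-1, -1), sh(-1, 0), sh(-1, 1), sh(0, -1), sh(0, 0),
               sh(0, 1), sh(1, -1), sh(1, 0), sh(1, 1))
  agg <- if (stat == "mean") mean(dmax[sel]) else median(dmax[sel])
  max(2 * agg - 1, 1)
}

#' Collagen fiber density
#'
#' Sum of SHG intensity over the collagen-positive pixels divided by their
#' count: the mean collagen signal within the binary image, a proxy for
#' fibril packing density.
#'
#' @param shg SHG intensity matrix.
#' @param collagen a `binary_map` or logical matrix.
#' @return numeric (intensity units), NA when the binary map is empty.
#' @export
measure_cfd <- function(shg, collagen) {
  map <- if (inherits(collagen, "binary_map")) collagen$map else collagen
  assert_matrix_like(shg, "shg")
  n <- sum(map)
  if (n == 0L) return(NA_real_)
  sum(shg[map]) / n
}

#' Collagen area ratio
#'
#' Collagen-positive pixels within a region divided by the region area.
#'
#' @param collagen a `binary_map` or logical matrix.
#' @param region logical region mask.
#' @return numeric in [0, 1].
#' @export
measure_car <- function(collagen, region) {
  map <- if (inherits(collagen, "binary_map")) collagen$map else collagen
  area <- sum(region)
  if (area == 0L)
    stop_collprof("collprof_undefined_ratio_error", "empty region")
  sum(map & region) / area
}

#' Collagen reticular index
#'
#' Junction count divided by total skeleton length; 0 when both are zero.
#'
#' @param n_junctions integer.
#' @param total_length_px numeric >= 0.
#' @return numeric.
#' @export
measure_cri <- function(n_junctions, total_length_px) {
  stopifnot(total_length_px >= 0)
  if (total_length_px == 0) return(0)
  n_junctions / total_length_px
}

.empty_region_features <- function(region, region_area) {
  data.frame(region = region, car = NA_real_, cfd = NA_real_,
             cfl_mean = NA_real_, cfl_median = NA_real_, cft_mean = NA_real_,
             cri = NA_real_, n_junctions = NA_integer_,
             region_area_px = region_area, collagen_area_px = 0L,
             empty = TRUE)
}

.region_features <- function(region_name, shg, collagen_map, region_mask,
                             min_branch_px) {
  area <- sum(region_mask)
  if (area == 0L) return(.empty_region_features(region_name, 0L))
  cmap <- collagen_map & region_mask
  if (!any(cmap)) return(.empty_region_features(region_name, area))
  sk <- skeletonize(cmap, prune_spurs_px = min_branch_px)
  cfl <- measure_cfl(sk, min_branch_px)
  data.frame(region = region_name,
             car = sum(cmap) / area,
             cfd = measure_cfd(shg, cmap),
             cfl_mean = cfl$mean, cfl_median = cfl$median,
             cft_mean = measure_cft(cmap, sk),
             cri = measure_cri(sk$n_junctions, sk$total_length_px),
             n_junctions = sk$n_junctions,
             region_area_px = area, collagen_area_px = sum(cmap),
             empty = FALSE)
}

#' Profile a sample: all features in the ATC, DTC and ALL regions
#'
#' Each feature is computed by restricting the collagen binary image to the
#' region and re-deriving the skeleton of the restricted binary, so
#' branches crossing a compartment boundary are split at the boundary.
#'
#' @param img a [tma_image()].
#' @param mask a `sample_mask` or logical matrix.
#' @param collagen a `binary_map`.
#' @param cmap a `compartment_map`.
#' @param min_branch_px spur-pruning floor for CFL.
#' @return object of class `feature_vector`: sample_id, regions
#'   (3-row data.frame), atc_area_ratio, threshold provenance, pixel size.
#' @export
profile_sample <- function(img, mask, collagen, cmap, min_branch_px = 3) {
  stopifnot(inherits(img, "tma_image"), inherits(collagen, "binary_map"),
            inherits(cmap, "compartment_map"))
  if (inherits(mask, "sample_mask")) mask <- mask$mask
  atc <- cmap$labels == 1L
  dtc <- cmap$labels == 2L
  all_r <- atc | dtc
  regions <- rbind(
    .region_features("ATC", img$shg, collagen$map, atc, min_branch_px),
    .region_features("DTC", img$shg, collagen$map, dtc, min_branch_px),
    .region_features("ALL", img$shg, collagen$map, all_r, min_branch_px))
  structure(list(sample_id = img$sample_id, regions = regions,
                 atc_area_ratio = atc_area_ratio(cmap),
                 gmm_threshold = collagen$threshold_used,
                 pixel_size_um = img$pixel_size_um),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %s | ATC area ratio %.3f | collagen threshold %.2f\n",
              x$sample_id, x$atc_area_ratio, x$gmm_threshold))
  print(x$regions, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Flatten a feature vector to one wide data.frame row
#'
#' Columns are `<region>_<feature>` in lower case plus `sample_id` and
#' `atc_area_ratio`; the standard cohort-table schema.
#'
#' @param x a `feature_vector`.
#' @param row.names,optional,... ignored (data.frame method signature).
#' @return 1-row data.frame.
#' @export
as.data.frame.feature_vector <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  out <- data.frame(sample_id = x$sample_id)
  feats <- c("car", "cfd", "cfl_mean", "cfl_median", "cft_mean", "cri",
             "n_junctions", "region_area_px", "collagen_area_px")
  for (i in seq_len(nrow(x$regions))) {
    reg <- tolower(x$regions$region[i])
    for (f in feats) out[[paste(reg, f, sep = "_")]] <- x$regions[[f]][i]
  }
  out$atc_area_ratio <- x$atc_area_ratio
  out$gmm_threshold <- x$gmm_threshold
  out
}

#' QC overlay: skeleton (white) and junctions (yellow) over the SHG image
#' @param img a `tma_image`.
#' @param sk a `skeleton_graph`.
#' @param path output PNG path.
#' @export
write_skeleton_png <- function(img, sk, path) {
  g <- img$shg / max(img$shg, 1)
  a <- array(rep(g, 3), c(nrow(g), ncol(g), 3))
  for (ch in 1:3) a[, , ch][sk$skeleton] <- 1
  a[, , 3][sk$junction_label > 0L] <- 0   # yellow = R+G
  for (ch in 1:2) a[, , ch][sk$junction_label > 0L] <- 1
  png::writePNG(a, path)
  invisible(path)
}
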