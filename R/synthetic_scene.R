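# Synthetic two-channel SHG/TPE scene generator with per-fiber ground truth.
# Fibers are curvilinear tubes with a Gaussian cross-section whose full width
# at half maximum equals the planted thickness, so the half-peak contour of a
# rendered fiber is exactly `thickness_px` wide. Scenes are bit-reproducible
# from their seed.

#' Specify a single collagen fiber
#'
#' @param control_points numeric matrix with columns (row, col), at least two
#'   points; the fiber centerline is the polyline through them (1-based pixel
#'   coordinates).
#' @param thickness_px full width at half maximum of the Gaussian
#'   cross-section, in pixels (>= 1).
#' @param peak_intensity SHG brightness at the centerline, arbitrary units.
#' @param id integer fiber identifier.
#' @return An object of class `fiber_spec`.
#' @export
fiber_spec <- function(control_points, thickness_px, peak_intensity, id = 1L) {
  control_points <- as.matrix(control_points)
  if (nrow(control_points) < 2L || ncol(control_points) != 2L)
    stop("control_points must be an n x 2 matrix with n >= 2")
  if (thickness_px < 1) stop("thickness_px must be >= 1")
  if (peak_intensity <= 0) stop("peak_intensity must be > 0")
  structure(list(control_points = control_points,
                 thickness_px = as.numeric(thickness_px),
                 peak_intensity = as.numeric(peak_intensity),
                 id = as.integer(id)),
            class = "fiber_spec")
}

#' Arc length of a fiber's control polyline
#' @param fiber a `fiber_spec`.
#' @return length in pixels.
#' @export
fiber_length <- function(fiber) {
  p <- fiber$control_points
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Specify a synthetic SHG/TPE scene
#'
#' @param shape_px integer vector (rows, cols).
#' @param fibers list of [fiber_spec()] objects (may be empty).
#' @param clusters list of lists with elements `center` (row, col), `radius`
#'   (pixels) and `fiber_ids` (ids of fibers belonging to the aggregate);
#'   fibers not referenced by any cluster are treated as isolated.
#' @param pixel_size_um microns per pixel.
#' @param background_mean,background_sd Gaussian background noise model for
#'   both channels.
#' @param tissue_mask_shape "full" (whole frame is tissue) or "disk"
#'   (centered disk of radius 0.45 * min(shape)).
#' @param tpe_tissue_level mean TPE autofluorescence inside the tissue.
#' @param i_max intensity ceiling (255 for 8-bit, 65535 for 16-bit).
#' @param poisson_noise if TRUE, shot noise is added to the fiber signal.
#' @param seed integer; fixes the scene bit-exactly.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(shape_px = c(256L, 256L), fibers = list(),
                       clusters = list(), pixel_size_um = 0.5,
                       background_mean = 20, background_sd = 6,
                       tissue_mask_shape = c("full", "disk"),
                       tpe_tissue_level = 120, i_max = 255,
                       poisson_noise = FALSE, seed = 1L) {
  tissue_mask_shape <- match.arg(tissue_mask_shape)
  stopifnot(length(shape_px) == 2L, all(shape_px > 0), pixel_size_um > 0,
            background_sd >= 0, i_max > 0)
  structure(list(shape_px = as.integer(shape_px), fibers = fibers,
                 clusters = clusters, pixel_size_um = pixel_size_um,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 tissue_mask_shape = tissue_mask_shape,
                 tpe_tissue_level = tpe_tissue_level, i_max = i_max,
                 poisson_noise = poisson_noise, seed = as.integer(seed)),
            class = "scene_spec")
}

# Minimum distance from each of a set of points to a segment (a -> b).
.point_segment_dist <- function(pr, pc, a, b) {
  vr <- b[1] - a[1]; vc <- b[2] - a[2]
  L2 <- vr^2 + vc^2
  if (L2 == 0) return(sqrt((pr - a[1])^2 + (pc - a[2])^2))
  t <- ((pr - a[1]) * vr + (pc - a[2]) * vc) / L2
  t <- pmin(1, pmax(0, t))
  sqrt((pr - (a[1] + t * vr))^2 + (pc - (a[2] + t * vc))^2)
}

# Distance from every pixel of a (rows x cols) window to a polyline.
.polyline_dist <- function(rows, cols, points) {
  pr <- rep(rows, times = length(cols))
  pc <- rep(cols, each = length(rows))
  d <- rep(Inf, length(pr))
  for (i in seq_len(nrow(points) - 1L))
    d <- pmin(d, .point_segment_dist(pr, pc, points[i, ], points[i + 1L, ]))
  matrix(d, nrow = length(rows))
}

#' Render one fiber onto an intensity canvas
#'
#' Adds a tube of Gaussian cross-section around the fiber's polyline;
#' the intensity at perpendicular distance d from the centerline is
#' `peak * 2^(-(2 d / thickness)^2)`, so the profile reaches half its peak
#' exactly at d = thickness/2 (FWHM = thickness). Contributions from
#' different fibers are additive; a single fiber never self-accumulates
#' because the minimum distance to its whole polyline is used.
#'
#' @param fiber a [fiber_spec()].
#' @param canvas numeric matrix to increment.
#' @param truncate_sd render only within this many thickness units of the
#'   centerline (intensity support cutoff).
#' @return The incremented canvas.
#' @export
render_fiber <- function(fiber, canvas, truncate_sd = 3) {
  assert_matrix_like(canvas, "canvas")
  p <- fiber$control_points
  if (any(p[, 1] < 1 | p[, 1] > nrow(canvas) | p[, 2] < 1 | p[, 2] > ncol(canvas)))
    stop_collprof("collprof_bounds_error", "fiber control point outside canvas")
  pad <- ceiling(truncate_sd * fiber$thickness_px)
  r0 <- max(1L, floor(min(p[, 1])) - pad); r1 <- min(nrow(canvas), ceiling(max(p[, 1])) + pad)
  c0 <- max(1L, floor(min(p[, 2])) - pad); c1 <- min(ncol(canvas), ceiling(max(p[, 2])) + pad)
  rows <- r0:r1; cols <- c0:c1
  d <- .polyline_dist(rows, cols, p)
  contrib <- fiber$peak_intensity * 2^(-(2 * d / fiber$thickness_px)^2)
  contrib[d > pad] <- 0
  canvas[rows, cols] <- canvas[rows, cols] + contrib
  canvas
}

# Noiseless per-fiber tube and its half-peak support mask.
.fiber_tube <- function(fiber, shape) {
  canvas <- matrix(0, shape[1], shape[2])
  render_fiber(fiber, canvas)
}

.tissue_silhouette <- function(spec) {
  if (spec$tissue_mask_shape == "full") {
    matrix(TRUE, spec$shape_px[1], spec$shape_px[2])
  } else {
    r <- 0.45 * min(spec$shape_px)
    ctr <- (spec$shape_px + 1) / 2
    rr <- matrix(seq_len(spec$shape_px[1]), spec$shape_px[1], spec$shape_px[2])
    cc <- matrix(seq_len(spec$shape_px[2]), spec$shape_px[1], spec$shape_px[2], byrow = TRUE)
    (rr - ctr[1])^2 + (cc - ctr[2])^2 <= r^2
  }
}

# Brute-force pairwise polyline intersection points between distinct fibers.
.polyline_intersections <- function(fibers) {
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- p2 - p1; d2 <- p4 - p3
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(NULL)
    t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
    u <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
    if (t < 0 || t > 1 || u < 0 || u > 1) return(NULL)
    p1 + t * d1
  }
  out <- NULL
  n <- length(fibers)
  if (n < 2L) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pi_ <- fibers[[i]]$control_points; pj <- fibers[[j]]$control_points
    for (a in seq_len(nrow(pi_) - 1L)) for (b in seq_len(nrow(pj) - 1L)) {
      x <- seg_int(pi_[a, ], pi_[a + 1L, ], pj[b, ], pj[b + 1L, ])
      if (!is.null(x)) out <- rbind(out, x)
    }
  }
  if (is.null(out)) out <- matrix(numeric(0), 0, 2)
  dimnames(out) <- list(NULL, c("row", "col"))
  out
}

#' Generate a synthetic two-channel scene with ground truth
#'
#' The SHG channel is the additive sum of all rendered fiber tubes plus
#' Gaussian background noise, clipped to (0, i_max); the TPE channel is the
#' tissue silhouette at `tpe_tissue_level` plus the same noise model. The
#' ground truth records, per fiber, the half-peak collagen support (union of
#' per-fiber masks, so mask width equals the planted thickness), the ATC
#' aggregate region (morphological closing of the clustered-fiber tube
#' union by the cluster radius), planted lengths/thicknesses, and all
#' pairwise centerline intersections.
#'
#' @param spec a [scene_spec()].
#' @return list with elements `image` (a `tma_image`) and `truth` (list:
#'   `collagen_mask`, `atc_mask`, `tissue_mask`, `per_fiber` data.frame,
#'   `true_junctions` matrix, `noiseless_shg`).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  shape <- spec$shape_px
  set.seed(spec$seed)
  shg0 <- matrix(0, shape[1], shape[2])
  collagen <- matrix(FALSE, shape[1], shape[2])
  clustered_union <- matrix(FALSE, shape[1], shape[2])
  cluster_ids <- unlist(lapply(spec$clusters, `[[`, "fiber_ids"))
  per_fiber <- data.frame(id = integer(0), true_length_px = numeric(0),
                          thickness_px = numeric(0), peak_intensity = numeric(0),
                          clustered = logical(0))
  for (f in spec$fibers) {
    tube <- .fiber_tube(f, shape)
    shg0 <- shg0 + tube
    fmask <- tube >= f$peak_intensity / 2
    collagen <- collagen | fmask
    if (f$id %in% cluster_ids) clustered_union <- clustered_union | fmask
    per_fiber <- rbind(per_fiber, data.frame(
      id = f$id, true_length_px = fiber_length(f),
      thickness_px = f$thickness_px, peak_intensity = f$peak_intensity,
      clustered = f$id %in% cluster_ids))
  }
  tissue <- .tissue_silhouette(spec)
  # ground-truth aggregate: the clustered-fiber tube union with
  # inter-fiber gaps filled by a morphological closing scaled to the
  # cluster (half its radius); this is the filled region a reader would
  # outline as "aggregated collagen" without extending beyond it
  atc <- matrix(FALSE, shape[1], shape[2])
  if (length(spec$clusters) && any(clustered_union)) {
    radii <- vapply(spec$clusters, `[[`, numeric(1), "radius")
    k <- disc_brush(max(7, 0.5 * max(radii)))
    atc <- as_logical_matrix(EBImage::closing(clustered_union * 1, k) > 0.5)
  }
  atc <- atc & tissue
  collagen <- collagen & tissue

  # channels are quantized to integer grey levels, as a photon-counting
  # detector would deliver; this also makes TIFF round-trips bit-exact
  noisy <- function(base) {
    x <- base + rnorm(length(base), spec$background_mean, spec$background_sd)
    matrix(round(pmin(spec$i_max, pmax(0, x))), shape[1], shape[2])
  }
  shg_sig <- shg0
  if (spec$poisson_noise) shg_sig <- matrix(stats::rpois(length(shg0), shg0), shape[1], shape[2])
  shg <- noisy(shg_sig)
  tpe <- noisy(ifelse(tissue, spec$tpe_tissue_level, 0))

  img <- tma_image(shg = shg, tpe = tpe, pixel_size_um = spec$pixel_size_um,
                   sample_id = sprintf("synthetic-seed%d", spec$seed))
  truth <- list(collagen_mask = collagen, atc_mask = atc, tissue_mask = tissue,
                per_fiber = per_fiber,
                true_junctions = .polyline_intersections(spec$fibers),
                noiseless_shg = shg0)
  list(image = img, truth = truth)
}

#' Randomly populate a scene with isolated and clustered fibers
#'
#' Convenience constructor used throughout validation: places `n_isolated`
#' fibers uniformly (avoiding cluster footprints) and, per cluster,
#' `n_fibers` chords through a disk so the aggregate is dense enough to form
#' a contiguous bright region.
#'
#' @param n_isolated number of isolated fibers.
#' @param clusters list of lists with `center`, `radius`, `n_fibers`.
#' @param length_range,thickness_range,peak_range uniform sampling ranges
#'   for isolated-fiber geometry and brightness.
#' @param cluster_peak_range peak range for clustered fibers (brighter by
#'   default, emulating aggregated thick collagen).
#' @param seed integer; drives both placement and, via [scene_spec()], noise.
#' @param ... forwarded to [scene_spec()].
#' @return a `scene_spec`.
#' @export
random_scene_spec <- function(n_isolated = 6, clusters = list(),
                              length_range = c(60, 140),
                              thickness_range = c(3, 5),
                              peak_range = c(45, 65),
                              cluster_peak_range = c(60, 90),
                              cluster_thickness_range = c(4, 6.5),
                              shape_px = c(256L, 256L), seed = 1L, ...) {
  set.seed(seed + 1000003L)
  shape <- as.integer(shape_px)
  fibers <- list(); id <- 0L
  in_cluster <- function(r, c) {
    for (cl in clusters)
      if ((r - cl$center[1])^2 + (c - cl$center[2])^2 <= (1.6 * cl$radius)^2) return(TRUE)
    FALSE
  }
  margin <- 12
  for (i in seq_len(n_isolated)) {
    repeat {
      len <- runif(1, length_range[1], length_range[2])
      ang <- runif(1, 0, pi)
      ctr <- c(runif(1, margin + len / 2, shape[1] - margin - len / 2),
               runif(1, margin + len / 2, shape[2] - margin - len / 2))
      a <- ctr - len / 2 * c(sin(ang), cos(ang))
      b <- ctr + len / 2 * c(sin(ang), cos(ang))
      mid <- (a + b) / 2
      if (!in_cluster(a[1], a[2]) && !in_cluster(b[1], b[2]) &&
          !in_cluster(mid[1], mid[2])) break
    }
    id <- id + 1L
    fibers[[id]] <- fiber_spec(rbind(a, b),
                               thickness_px = runif(1, thickness_range[1], thickness_range[2]),
                               peak_intensity = runif(1, peak_range[1], peak_range[2]),
                               id = id)
  }
  cluster_defs <- list()
  for (cl in clusters) {
    ids <- integer(0)
    for (i in seq_len(cl$n_fibers)) {
      ang <- runif(1, 0, pi)
      off <- runif(1, -0.85, 0.85) * cl$radius
      u <- c(sin(ang), cos(ang)); nvec <- c(-u[2], u[1])
      half <- sqrt(max(cl$radius^2 - off^2, 1))
      a <- cl$center + off * nvec - half * u
      b <- cl$center + off * nvec + half * u
      clamp <- function(p) c(min(max(p[1], 2), shape[1] - 1), min(max(p[2], 2), shape[2] - 1))
      id <- id + 1L
      fibers[[id]] <- fiber_spec(rbind(clamp(a), clamp(b)),
                                 thickness_px = runif(1, cluster_thickness_range[1], cluster_thickness_range[2]),
                                 peak_intensity = runif(1, cluster_peak_range[1], cluster_peak_range[2]),
                                 id = id)
      ids <- c(ids, id)
    }
    cluster_defs[[length(cluster_defs) + 1L]] <-
      list(center = cl$center, radius = cl$radius, fiber_ids = ids)
  }
  scene_spec(shape_px = shape, fibers = fibers, clusters = cluster_defs,
             seed = seed, ...)
}

#' Write a scene to disk (two-page TIFF + ground-truth JSON sidecar)
#'
#' Page 1 is the SHG channel, page 2 the TPE channel, stored as 16-bit
#' grayscale. The sidecar records masks (run-length encoded), the per-fiber
#' table and the true junction list.
#'
#' @param scene output of [generate_scene()].
#' @param path TIFF path; the sidecar is written at `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  img <- scene$image
  scale <- 65535
  pages <- list(img$shg / scale, img$tpe / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  rle_pack <- function(m) {
    r <- rle(as.logical(as.vector(m)))
    list(dim = dim(m), lengths = r$lengths, values = r$values)
  }
  sidecar <- list(
    sample_id = img$sample_id, pixel_size_um = img$pixel_size_um,
    collagen_mask = rle_pack(scene$truth$collagen_mask),
    atc_mask = rle_pack(scene$truth$atc_mask),
    tissue_mask = rle_pack(scene$truth$tissue_mask),
    per_fiber = scene$truth$per_fiber,
    true_junctions = scene$truth$true_junctions)
  jsonlite::write_json(sidecar, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ground-truth sidecar written by [write_scene()]
#' @param path the TIFF path (sidecar found at `<path>.truth.json`).
#' @return the ground-truth list with masks decoded to logical matrices.
#' @export
read_scene_truth <- function(path) {
  s <- jsonlite::read_json(paste0(path, ".truth.json"), simplifyVector = TRUE)
  unpack <- function(p) matrix(inverse.rle(structure(
    list(lengths = as.integer(p$lengths), values = as.logical(p$values)),
    class = "rle")), p$dim[1], p$dim[2])
  s$collagen_mask <- unpack(s$collagen_mask)
  s$atc_mask <- unpack(s$atc_mask)
  s$tissue_mask <- unpack(s$tissue_mask)
  s
}
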