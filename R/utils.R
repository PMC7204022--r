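# Shared low-level helpers: disc structuring elements, connected components,
# and small validators used across the pipeline stages.

#' Disc-shaped structuring element
#'
#' @param diameter_px Diameter in pixels; coerced to the nearest odd integer
#'   not smaller than 3 so the element has a well-defined center.
#' @return A binary matrix usable as an EBImage kernel.
#' @keywords internal
disc_brush <- function(diameter_px) {
  d <- max(3L, as.integer(round(diameter_px)))
  if (d %% 2L == 0L) d <- d + 1L
  EBImage::makeBrush(d, shape = "disc")
}

#' 8- or 4-connected component labelling of a logical matrix
#'
#' EBImage::bwlabel is used for speed; it labels 4-connected sets, so for
#' 8-connectivity labels are merged across diagonal contacts with a
#' union-find pass.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of labels (0 = background).
#' @keywords internal
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 4L || max(lab) <= 1L) return(lab)
  # union-find over diagonal neighbor label pairs
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nc]),  as.vector(lab[-nr, -1]))   # up-right
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) unite(pairs[k, 1], pairs[k, 2])
    root <- vapply(seq_len(n), find, integer(1))
    # compact labels
    uroot <- sort(unique(root))
    remap <- integer(n); remap[uroot] <- seq_along(uroot)
    newlab <- integer(n); newlab <- remap[root]
    nz <- lab > 0
    lab[nz] <- newlab[lab[nz]]
  }
  lab
}

#' Count of 8-neighbors that are TRUE, per pixel
#' @keywords internal
neighbor_count <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask * 1L
  nr <- nrow(m); nc <- ncol(m)
  core <- function(dr, dc) m[(2L + dr):(nr - 1L + dr), (2L + dc):(nc - 1L + dc)]
  core(-1L, -1L) + core(-1L, 0L) + core(-1L, 1L) +
    core(0L, -1L)              + core(0L, 1L) +
    core(1L, -1L) + core(1L, 0L) + core(1L, 1L)
}

#' Coerce an EBImage Image or array to a plain logical matrix
#' @keywords internal
as_logical_matrix <- function(x) {
  matrix(as.logical(x), dim(x)[1], dim(x)[2])
}

#' @keywords internal
stop_collprof <- function(class, msg) {
  stop(structure(class = c(class, "collprof_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' @keywords internal
assert_matrix_like <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", name))
  invisible(x)
}
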