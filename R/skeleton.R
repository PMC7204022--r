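# Skeletonization of the collagen binary image and decomposition of the
# resulting centerline network into junction clusters and branches.
#
# Thinning is Zhang-Suen (two-subiteration, topology preserving, yields an
# 8-connected unit-width skeleton). Junction pixels are skeleton pixels with
# >= 3 skeleton neighbors, merged into clusters by 8-adjacency; branches are
# the connected components of the skeleton with junction pixels removed.
# Branch length is geodesic: orthogonal steps count 1, diagonal steps
# sqrt(2), with diagonal shortcuts that skip an orthogonal path dropped so
# a traced path has exactly (#pixels - 1) steps.

# One Guo-Hall pass; sub = 1 or 2. Operates on a 0/1 matrix with a
# 1-pixel zero border already added. Guo-Hall is preferred over Zhang-Suen
# because it leaves diagonal runs strictly one pixel wide (no staircase
# doubling), which keeps the branch graph clean.
.gh_pass <- function(m, sub) {
  nr <- nrow(m); nc <- ncol(m)
  sh <- function(dr, dc) m[(2L + dr):(nr - 1L + dr), (2L + dc):(nc - 1L + dc)]
  p  <- m[2:(nr - 1L), 2:(nc - 1L)]
  # neighbors clockwise from north (row - 1)
  p2 <- sh(-1L, 0L); p3 <- sh(-1L, 1L); p4 <- sh(0L, 1L); p5 <- sh(1L, 1L)
  p6 <- sh(1L, 0L); p7 <- sh(1L, -1L); p8 <- sh(0L, -1L); p9 <- sh(-1L, -1L)
  C  <- ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
        ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2))
  N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
  N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
  N  <- pmin(N1, N2)
  m_cond <- if (sub == 1L) ((p6 | p7 | (!p9)) & p8) else ((p2 | p3 | (!p5)) & p4)
  cond <- p == 1 & C == 1 & N >= 2 & N <= 3 & m_cond == 0
  m[2:(nr - 1L), 2:(nc - 1L)][cond] <- 0L
  m
}

#' Topology-preserving thinning of a binary image
#'
#' Guo-Hall two-subiteration thinning, iterated to stability.
#'
#' @param mask logical matrix.
#' @return logical matrix: 1-pixel-wide, 8-connected skeleton.
#' @export
thin_binary <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- (mask > 0) * 1L
  repeat {
    before <- sum(m)
    m <- .gh_pass(m, 1L)
    m <- .gh_pass(m, 2L)
    if (sum(m) == before) break
  }
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] == 1L
}

# Crossing number per pixel: the count of 0 -> 1 transitions around the
# ordered 8-neighbor ring. Equals the number of distinct branches leaving
# the pixel; the junction criterion (>= 3) that is robust to staircase
# corners, where the raw 8-neighbor count over-fires.
.crossing_number <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- (mask > 0) * 1L
  nr <- nrow(m); nc <- ncol(m)
  sh <- function(dr, dc) m[(2L + dr):(nr - 1L + dr), (2L + dc):(nc - 1L + dc)]
  p2 <- sh(-1L, 0L); p3 <- sh(-1L, 1L); p4 <- sh(0L, 1L); p5 <- sh(1L, 1L)
  p6 <- sh(1L, 0L); p7 <- sh(1L, -1L); p8 <- sh(0L, -1L); p9 <- sh(-1L, -1L)
  (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
    (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
    (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
}

# Build the pruned adjacency edge list for a set of skeleton pixels given
# as linear indices into a logical raster. Returns a data.frame(from, to,
# w) of unique undirected edges. Diagonal edges are dropped when either
# orthogonal corner pixel of the step is itself in the set (staircase
# shortcut) or is a blocked pixel (junction): two branch arms must not be
# connected diagonally around the junction pixel that separates them.
.skeleton_edges <- function(px_lin, dim, blocked = NULL) {
  nr <- dim[1]
  inset <- logical(prod(dim)); inset[px_lin] <- TRUE
  rr <- ((px_lin - 1L) %% nr) + 1L
  cc <- ((px_lin - 1L) %/% nr) + 1L
  off <- rbind(c(-1L, 0L, 1), c(1L, 0L, 1), c(0L, -1L, 1), c(0L, 1L, 1),
               c(-1L, -1L, sqrt(2)), c(-1L, 1L, sqrt(2)),
               c(1L, -1L, sqrt(2)), c(1L, 1L, sqrt(2)))
  edges <- NULL
  for (k in seq_len(nrow(off))) {
    r2 <- rr + off[k, 1]; c2 <- cc + off[k, 2]
    ok <- r2 >= 1L & r2 <= dim[1] & c2 >= 1L & c2 <= dim[2]
    to <- (c2[ok] - 1L) * nr + r2[ok]
    from <- px_lin[ok]
    hit <- inset[to]
    if (any(hit)) {
      e <- cbind(from = from[hit], to = to[hit], w = off[k, 3])
      edges <- rbind(edges, e)
    }
  }
  if (is.null(edges)) return(data.frame(from = integer(0), to = integer(0), w = numeric(0)))
  # undirected: keep from < to
  keep <- edges[, "from"] < edges[, "to"]
  edges <- edges[keep, , drop = FALSE]
  e <- as.data.frame(edges)
  diag_e <- e$w > 1
  if (any(diag_e)) {
    fr <- e$from[diag_e]; to <- e$to[diag_e]
    fr_r <- ((fr - 1L) %% nr) + 1L; fr_c <- ((fr - 1L) %/% nr) + 1L
    to_r <- ((to - 1L) %% nr) + 1L; to_c <- ((to - 1L) %/% nr) + 1L
    # the two orthogonal corner pixels of the diagonal step
    c1 <- (fr_c - 1L) * nr + to_r   # (to_r, fr_c)
    c2 <- (to_c - 1L) * nr + fr_r   # (fr_r, to_c)
    shortcut <- inset[c1] | inset[c2]
    if (!is.null(blocked)) shortcut <- shortcut | blocked[c1] | blocked[c2]
    drop_idx <- which(diag_e)[shortcut]
    if (length(drop_idx)) e <- e[-drop_idx, , drop = FALSE]
  }
  e
}

#' Skeletonize a collagen binary image into a centerline network
#'
#' Thinning artifacts (short side twigs ending in a free endpoint next to a
#' junction) are pruned iteratively before the final graph is assembled, so
#' a single ragged-edged fiber yields one long branch rather than many
#' junction-separated fragments.
#'
#' @param collagen a `binary_map` (or logical matrix).
#' @param prune_spurs_px prune endpoint twigs shorter than this (0 = off).
#' @return object of class `skeleton_graph`: skeleton (logical matrix),
#'   junction_label (integer matrix, 0 = none), junctions (data.frame of
#'   cluster centroids and sizes), branches (list of integer pixel-index
#'   vectors), branch_lengths (numeric), total_length_px, n_junctions.
#' @export
skeletonize <- function(collagen, prune_spurs_px = 3) {
  map <- if (inherits(collagen, "binary_map")) collagen$map else collagen
  sk <- thin_binary(map)
  if (prune_spurs_px > 0) sk <- prune_spurs(sk, prune_spurs_px)
  build_skeleton_graph(sk)
}

#' Remove skeleton spurs (short endpoint twigs at junctions)
#'
#' A spur is a branch shorter than `max_len` that ends in a free endpoint
#' (a pixel with exactly one skeleton neighbor) and is attached to a
#' junction cluster. Removal is iterated because deleting a twig can turn
#' its junction into a plain path pixel, merging the branches it used to
#' separate. Isolated short components (no junction contact) are kept.
#'
#' @param sk logical skeleton matrix.
#' @param max_len prune branches with geodesic length below this.
#' @param max_iter safety cap on pruning rounds.
#' @return logical skeleton matrix.
#' @export
prune_spurs <- function(sk, max_len = 3, max_iter = 20L) {
  dimv <- dim(sk)
  for (iter in seq_len(max_iter)) {
    g <- build_skeleton_graph(sk)
    if (!length(g$branches)) break
    nb <- neighbor_count(sk)
    junction_px <- which(g$junction_label > 0L)
    if (!length(junction_px)) break
    jset <- logical(prod(dimv)); jset[junction_px] <- TRUE
    has_free_end <- vapply(g$branches, function(px) any(nb[px] == 1L), logical(1))
    touches_junction <- vapply(g$branches, function(px) {
      nr <- dimv[1]
      rr <- ((px - 1L) %% nr) + 1L; cc <- ((px - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        r2 <- rr + dr; c2 <- cc + dc
        ok <- r2 >= 1L & r2 <= dimv[1] & c2 >= 1L & c2 <= dimv[2]
        if (any(jset[(c2[ok] - 1L) * nr + r2[ok]])) return(TRUE)
      }
      FALSE
    }, logical(1))
    drop <- g$branch_lengths < max_len & has_free_end & touches_junction
    if (!any(drop)) break
    sk[unlist(g$branches[drop])] <- FALSE
  }
  sk
}

#' Assemble the junction/branch graph of a 1-px skeleton
#'
#' Junction pixels (crossing number >= 3) are first clustered by
#' 8-adjacency; clusters whose centroids lie within `merge_radius_px` are
#' then merged into one junction, since a single physical fiber crossing
#' can thin into two nearby T-points depending on its orientation.
#'
#' @param sk logical skeleton matrix.
#' @param merge_radius_px merge junction clusters closer than this.
#' @return a `skeleton_graph` (see [skeletonize()]).
#' @export
build_skeleton_graph <- function(sk, merge_radius_px = 5) {
  dimv <- dim(sk)
  cn <- .crossing_number(sk)
  junction_px <- sk & cn >= 3L
  jlab <- label_components(junction_px, 8L)
  nraw <- max(jlab)
  junctions <- if (nraw > 0) {
    idx <- which(jlab > 0)
    rr <- ((idx - 1L) %% dimv[1]) + 1L
    cc <- ((idx - 1L) %/% dimv[1]) + 1L
    lab <- jlab[idx]
    cent <- data.frame(cluster = seq_len(nraw),
                       row = as.numeric(tapply(rr, lab, mean)),
                       col = as.numeric(tapply(cc, lab, mean)),
                       n_px = as.integer(tabulate(lab, nraw)))
    if (nraw > 1L && merge_radius_px > 0) {
      parent <- seq_len(nraw)
      find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
      d2 <- as.matrix(dist(cent[, c("row", "col")]))
      close <- which(d2 <= merge_radius_px & upper.tri(d2), arr.ind = TRUE)
      for (k in seq_len(nrow(close))) {
        ra <- find(close[k, 1]); rb <- find(close[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(nraw), find, integer(1))
      newid <- match(root, unique(root))
      jlab[jlab > 0] <- newid[jlab[jlab > 0]]
      lab2 <- newid[lab]
      cent <- data.frame(cluster = seq_len(max(newid)),
                         row = as.numeric(tapply(rr, lab2, mean)),
                         col = as.numeric(tapply(cc, lab2, mean)),
                         n_px = as.integer(tabulate(lab2, max(newid))))
    }
    cent
  } else {
    data.frame(cluster = integer(0), row = numeric(0), col = numeric(0),
               n_px = integer(0))
  }
  njunc <- nrow(junctions)
  body <- sk & !junction_px
  body_lin <- which(body)
  branches <- list()
  branch_lengths <- numeric(0)
  if (length(body_lin)) {
    e <- .skeleton_edges(body_lin, dimv, blocked = as.vector(junction_px))
    # connected components over the pruned edge list (union-find)
    idmap <- integer(prod(dimv)); idmap[body_lin] <- seq_along(body_lin)
    parent <- seq_along(body_lin)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    if (nrow(e)) {
      ef <- idmap[e$from]; et <- idmap[e$to]
      for (k in seq_len(nrow(e))) {
        ra <- find(ef[k]); rb <- find(et[k])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
    root <- vapply(seq_along(body_lin), find, integer(1))
    comp <- match(root, unique(root))
    branches <- split(body_lin, comp)
    names(branches) <- NULL
    branch_lengths <- numeric(length(branches))
    if (nrow(e)) {
      ecomp <- comp[idmap[e$from]]
      lens <- tapply(e$w, ecomp, sum)
      branch_lengths[as.integer(names(lens))] <- as.numeric(lens)
    }
  }
  structure(list(skeleton = sk, junction_label = jlab, junctions = junctions,
                 branches = branches, branch_lengths = branch_lengths,
                 total_length_px = sum(branch_lengths),
                 n_junctions = njunc),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d skeleton px, %d junction clusters, %d branches, total length %.1f px\n",
              sum(x$skeleton), x$n_junctions, length(x$branches),
              x$total_length_px))
  invisible(x)
}

#' Junction clusters of a skeleton
#'
#' Skeleton pixels with at least three 8-connected skeleton neighbors,
#' merged into clusters by adjacency. The cluster count is the junction
#' count used by the reticular index.
#'
#' @param sk a `skeleton_graph`.
#' @return data.frame of cluster centroids (row, col) and pixel counts.
#' @export
detect_junctions <- function(sk) {
  stopifnot(inherits(sk, "skeleton_graph"))
  sk$junctions
}
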