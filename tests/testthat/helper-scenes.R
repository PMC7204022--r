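# Shared fixtures, all generated in code.

# straight horizontal bar mask of given width (odd) and length
bar_mask <- function(length_px = 50, width_px = 3, pad = 10) {
  m <- matrix(FALSE, width_px + 2 * pad, length_px + 2 * pad)
  r0 <- pad + 1
  m[r0:(r0 + width_px - 1), (pad + 1):(pad + length_px)] <- TRUE
  m
}

# plus-shaped crossing of two 1-px fibers
plus_mask <- function(arm = 25) {
  n <- 2 * arm + 11
  ctr <- arm + 6
  m <- matrix(FALSE, n, n)
  m[ctr, 6:(n - 5)] <- TRUE
  m[6:(n - 5), ctr] <- TRUE
  m
}

# single randomly-oriented fiber scene; returns list(scene, L, f)
single_fiber_scene <- function(seed, length_range = c(30, 200),
                               thickness_range = c(2, 8), peak = 60) {
  set.seed(seed + 7000L)
  L <- runif(1, length_range[1], length_range[2])
  f <- runif(1, thickness_range[1], thickness_range[2])
  ang <- runif(1, 0, pi)
  ctr <- c(128, 128)
  a <- ctr - L / 2 * c(sin(ang), cos(ang))
  b <- ctr + L / 2 * c(sin(ang), cos(ang))
  fb <- fiber_spec(rbind(a, b), f, peak)
  list(scene = generate_scene(scene_spec(fibers = list(fb), seed = seed)),
       L = L, f = f)
}

# standard cluster + isolated-fiber scene used for compartment tests
cluster_scene_spec <- function(seed) {
  random_scene_spec(
    n_isolated = 5,
    clusters = list(list(center = c(90, 90), radius = 40, n_fibers = 55)),
    seed = seed)
}

# run segment stage: mask + GMM threshold + binary map
segment_scene <- function(sc) {
  img <- sc$image
  m <- compute_sample_mask(img)
  fit <- fit_two_mode_gmm(img$shg[m$mask])
  list(img = img, mask = m, fit = fit,
       collagen = binarize(img$shg, m, fit$threshold))
}

# 90-degree rotation of a matrix
rot90 <- function(m) t(m)[, nrow(m):1]

# rotation-stability probe: four cells, two holding a near-perpendicular
# fiber crossing, two a single fiber; long fibers so end effects are small
rotation_probe_scene <- function(seed) {
  set.seed(seed)
  fibers <- list(); id <- 0
  cells <- expand.grid(r = c(80, 240), c = c(80, 240))
  for (i in 1:4) {
    ctr <- c(cells$r[i], cells$c[i]) + runif(2, -8, 8)
    ang <- runif(1, 0, pi); L <- runif(1, 110, 150)
    u <- c(sin(ang), cos(ang))
    id <- id + 1
    fibers[[id]] <- fiber_spec(rbind(ctr - L / 2 * u, ctr + L / 2 * u),
                               runif(1, 4, 6), 60, id)
    if (i <= 2) {
      ang2 <- ang + pi / 2 + runif(1, -0.3, 0.3)
      u2 <- c(sin(ang2), cos(ang2))
      id <- id + 1
      fibers[[id]] <- fiber_spec(rbind(ctr - L / 2 * u2, ctr + L / 2 * u2),
                                 runif(1, 4, 6), 60, id)
    }
  }
  generate_scene(scene_spec(shape_px = c(320L, 320L), fibers = fibers,
                            seed = seed))
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
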