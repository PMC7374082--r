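# Shared fixtures and independent oracles, all built in code at test time.

# tiny three-channel set for container-level tests
tiny_channels <- function() channel_set(c(438, 549, 676), c(29.5, 17.6, 39.9))

# exhaustive grid-search oracle for two-dye NNLS problems:
# minimizes ||E c - a||^2 over c in [0, upper]^2 at the given step,
# via the quadratic form so the full grid is actually enumerated
grid_nnls_oracle <- function(E, a, upper = 3, step = 1e-3) {
  stopifnot(ncol(E) == 2)
  G <- crossprod(E)
  h <- crossprod(E, a)
  c1 <- seq(0, upper, by = step)
  c2 <- seq(0, upper, by = step)
  best <- c(NA, NA)
  bestf <- Inf
  f2 <- G[2, 2] * c2^2 - 2 * h[2] * c2
  for (i in seq_along(c1)) {
    f <- G[1, 1] * c1[i]^2 - 2 * h[1] * c1[i] + 2 * G[1, 2] * c1[i] * c2 + f2
    j <- which.min(f)
    if (f[j] < bestf) {
      bestf <- f[j]
      best <- c(c1[i], c2[j])
    }
  }
  best
}

# single-stain calibration section: every nucleus carries only the one
# chromogen (as in single-stain control slides), dense enough that the
# whole-image median absorbance is dominated by the stained region, as
# on a heavily stained control section; returns the absorbance stack
# seen through the full channel set of E
single_stain_stack <- function(E, chromogen, detector, seed,
                               width = 72, height = 72, n_cells = 120,
                               od = c(0.6, 1.0)) {
  E1 <- subset_matrix(E, chromogens = chromogen)
  sc <- make_scene(width = width, height = height, n_cells = n_cells,
                   E = E1, counterstain = chromogen, counterstain_od = od,
                   nucleus_radius = c(4, 6.5), cell_radius = c(6.5, 8),
                   seed = seed)
  fm <- forward_model(sc, detector)
  to_absorbance(to_transmission(fm$tissue, fm$blank))
}

# the standard noisy 4-plex validation phantom: NSCLC-style markers plus
# weakened hematoxylin counterstain under the given detector
noisy_fourplex <- function(E, detector, seed, width = 256, height = 256,
                           n_cells = 200) {
  Ep <- subset_matrix(E, chromogens = c("dabsyl", "Rhod110", "TAMRA", "HTX", "Cy5"))
  scene <- make_scene(width = width, height = height, n_cells = n_cells,
                      E = Ep, seed = seed, marker_fraction = 0.6)
  fm <- forward_model(scene, detector)
  absorb <- to_absorbance(to_transmission(fm$tissue, fm$blank))
  list(scene = scene, absorbance = absorb, E = Ep)
}

# per-chromogen relative error of the median recovered abundance over
# each chromogen's stained region
median_recovery_error <- function(scene, fit) {
  vapply(scene$chromogens, function(k) {
    tt <- scene$truth[, , k]
    rr <- coef(fit)[, , k]
    pos <- tt > 0
    abs(stats::median(rr[pos]) / stats::median(tt[pos]) - 1)
  }, numeric(1))
}
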