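test_that("identity basis returns the spectrum itself", {
  cs <- channel_set(c(450, 550), 20)
  E <- extinction_matrix(diag(2), cs, c("a", "b"))
  expect_equal(unname(unmix_pixel(c(0.3, 0.7), E)), c(0.3, 0.7), tolerance = 1e-12)
})

test_that("a noiseless one-dye pixel unmixes to a unit vector", {
  E <- tungsten_table()
  a <- unclass(E) %*% c(1, 0, 0, 0, 0, 0)
  cc <- unmix_pixel(as.vector(a), E)
  expect_lt(max(abs(cc - c(dabsyl = 1, Rhod110 = 0, TAMRA = 0,
                           SRhod101 = 0, HTX = 0, Cy5 = 0))), 1e-9)
  cp <- unmix_pixel(as.vector(a), E, method = "pinv")
  expect_lt(max(abs(cp - cc)), 1e-9)
})

test_that("NNLS matches the exhaustive grid-search oracle on a two-dye problem", {
  E2 <- subset_matrix(tungsten_table(), chromogens = c("dabsyl", "TAMRA"))
  a <- rep(0.5, 6)
  oracle <- grid_nnls_oracle(unclass(E2), a)
  cc <- unmix_pixel(a, E2)
  expect_lt(max(abs(cc - oracle)), 2e-3)
})

test_that("NNLS agrees with an independent active-set implementation", {
  skip_if_not_installed("pracma")
  E <- unclass(tungsten_table())
  set.seed(31)
  for (i in 1:25) {
    a <- runif(6, 0, 2) * rbinom(6, 1, 0.8)
    mine <- chromix:::nnls_cols(E, matrix(a, ncol = 1))
    ref <- pracma::lsqnonneg(E, a)$x
    expect_lt(max(abs(mine - ref)), 1e-8)
  }
})

test_that("pinv and NNLS coincide where the constrained solution is interior", {
  E <- tungsten_table()
  cs <- channels_of_matrix(E)
  truth <- c(0.5, 0.4, 0.7, 0.3, 0.6, 0.8)
  a <- as.vector(unclass(E) %*% truth)
  stack <- image_stack(array(rep(a, each = 1), c(1, 1, 6)), "absorbance", cs)
  nn <- unmix(stack, E)
  pv <- unmix(stack, E, method = "pinv")
  expect_true(all(coef(nn) > 0))
  expect_lt(max(abs(coef(nn) - coef(pv))), 1e-9)
  expect_lt(max(abs(coef(nn)[1, 1, ] - truth)), 1e-9)
})

test_that("unmixing is linear for interior noiseless mixtures", {
  E <- tungsten_table()
  cs <- channels_of_matrix(E)
  c1 <- c(0.3, 0.1, 0.2, 0.1, 0.4, 0.2)
  c2 <- c(0.1, 0.3, 0.1, 0.2, 0.1, 0.3)
  st <- function(v) image_stack(array(as.vector(unclass(E) %*% v), c(1, 1, 6)),
                                "absorbance", cs)
  expect_equal(coef(unmix(st(c1 + c2), E))[1, 1, ],
               coef(unmix(st(c1), E))[1, 1, ] + coef(unmix(st(c2), E))[1, 1, ],
               tolerance = 1e-9)
})

test_that("permuting basis columns permutes abundance planes identically", {
  E <- tungsten_table()
  perm <- c("TAMRA", "Cy5", "dabsyl", "HTX", "SRhod101", "Rhod110")
  Ep <- subset_matrix(E, chromogens = perm)
  scene <- make_scene(width = 32, height = 32, n_cells = 6, E = E, seed = 4)
  fm <- forward_model(scene, detector_model(noise = "none", quantize = FALSE))
  ab <- to_absorbance(to_transmission(fm$tissue, fm$blank))
  f1 <- unmix(ab, E)
  f2 <- unmix(ab, Ep)
  expect_identical(dimnames(coef(f2))[[3]], perm)
  expect_equal(coef(f2), coef(f1)[, , perm], tolerance = 1e-9)
})

test_that("abundances are non-negative for arbitrary absorbance inputs", {
  E <- tungsten_table()
  cs <- channels_of_matrix(E)
  set.seed(77)
  px <- array(runif(8 * 8 * 6, 0, 2), c(8, 8, 6))
  fit <- unmix(image_stack(px, "absorbance", cs), E)
  expect_true(all(coef(fit) >= 0))
  expect_true(all(coef(unmix(image_stack(px, "absorbance", cs), E,
                             method = "pinv")) >= 0))
})

test_that("rank-deficient bases are rejected naming the collinear columns", {
  cs <- tiny_channels()
  Em <- cbind(a = c(1, 0.5, 0.2), b = c(1, 0.5, 0.2), c = c(0.1, 1, 0.3))
  E <- extinction_matrix(Em, cs, check_normalized = FALSE)
  expect_error(unmix_pixel(c(0.5, 0.5, 0.5), E), "collinear")
})

test_that("declared channel subsets restrict both stack and basis", {
  E <- tungsten_table()
  cs <- channels_of_matrix(E)
  E3 <- subset_matrix(E, chromogens = c("dabsyl", "TAMRA", "Cy5"))
  truth <- c(0.4, 0.8, 0.2)
  a <- as.vector(unclass(E3) %*% truth)
  stack <- image_stack(array(a, c(1, 1, 6)), "absorbance", cs)
  sub <- c("438", "549", "580", "676")
  fit <- unmix(stack, E3, channels = sub)
  expect_lt(max(abs(coef(fit)[1, 1, ] - truth)), 1e-9)
  expect_error(unmix(stack, subset_matrix(E3, channels = c("438", "549")),
                     channels = c("438", "549")),
               "at least as many channels")
})

test_that("the noiseless phantom pipeline recovers ground truth to 1e-6", {
  E <- tungsten_table()
  scene <- make_scene(width = 64, height = 64, n_cells = 20, E = E, seed = 11)
  fm <- forward_model(scene, detector_model(noise = "none", quantize = FALSE))
  ab <- to_absorbance(to_transmission(fm$tissue, fm$blank))
  fit <- unmix(ab, E)
  expect_lt(max(abs(coef(fit) - scene$truth)), 1e-6)
  expect_lt(max(fit$residual), 1e-9)
})

test_that("an all-zero stack unmixes to zero abundance and zero residual", {
  E <- tungsten_table()
  stack <- image_stack(array(0, c(4, 4, 6)), "absorbance", channels_of_matrix(E))
  fit <- unmix(stack, E)
  expect_true(all(coef(fit) == 0))
  expect_true(all(fit$residual == 0))
})

test_that("median abundance recovery under shot noise at 12-bit depth is within 5%", {
  det <- detector_model(bit_depth = 12, full_scale = 3500, noise = "poisson")
  ph <- noisy_fourplex(led_table(), det, seed = 21, width = 160, height = 160,
                       n_cells = 90)
  fit <- unmix(ph$absorbance, ph$E)
  errs <- median_recovery_error(ph$scene, fit)
  expect_true(all(errs < 0.05))
})

test_that("clipped pseudo-inverse unmixing is never more accurate than NNLS on noisy data", {
  det <- detector_model(noise = "poisson")
  ph <- noisy_fourplex(tungsten_table(), det, seed = 33, width = 96, height = 96,
                       n_cells = 40)
  nn <- unmix(ph$absorbance, ph$E)
  pv <- unmix(ph$absorbance, ph$E, method = "pinv")
  expect_gte(mean(abs(coef(pv) - ph$scene$truth)),
             mean(abs(coef(nn) - ph$scene$truth)))
})

test_that("residual metrics report closed-form values", {
  E <- tungsten_table()
  cs <- channels_of_matrix(E)
  scene <- make_scene(width = 32, height = 32, n_cells = 8, E = E, seed = 2)
  fm <- forward_model(scene, detector_model(noise = "none", quantize = FALSE))
  ab <- to_absorbance(to_transmission(fm$tissue, fm$blank))
  fit <- unmix(ab, E)
  rm0 <- residual_metrics(ab, fit)
  expect_lte(rm0$mean_abs_error, 1e-9)
  expect_lte(rm0$relative_error_pct, 1e-7)

  # all-zero abundances leave the whole stack as residual
  zero <- fit
  zero$values[] <- 0
  rmz <- residual_metrics(ab, zero)
  expect_equal(rmz$mean_abs_error, mean(ab$pixels), tolerance = 1e-12)
  expect_identical(length(rmz$per_channel_mae), 6L)

  allflag <- fit
  allflag$flags <- matrix(TRUE, 32, 32)
  expect_error(residual_metrics(ab, allflag), "flagged")
})

test_that("fitted and residuals methods reconstruct the measured stack", {
  E <- tungsten_table()
  cs <- channels_of_matrix(E)
  set.seed(8)
  px <- array(runif(4 * 4 * 6, 0, 1), c(4, 4, 6))
  stack <- image_stack(px, "absorbance", cs)
  fit <- unmix(stack, E)
  recon <- fitted(fit)
  expect_identical(recon$domain, "absorbance")
  manual <- apply(abs(recon$pixels - px), c(1, 2), mean)
  expect_equal(manual, residuals(fit), tolerance = 1e-12)
})
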