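test_that("auto-exposure converges on a linear noiseless detector", {
  cap <- function(e) matrix(pmin(round(12 * e), 255), 32, 32)
  r <- auto_exposure(cap)
  expect_lt(abs(r$mean_intensity - 0.875 * 255), 0.02 * 255)
  expect_lte(r$saturated_fraction, 1e-4)
  expect_lte(r$iterations, 50)
})

test_that("auto-exposure returns after one capture when already on target", {
  r <- auto_exposure(function(e) matrix(223, 8, 8))
  expect_identical(r$iterations, 1L)
  expect_identical(r$exposure_ms, 10)
})

test_that("auto-exposure lands within 2% of target for seeded Poisson detectors", {
  for (s in 1:5) {
    set.seed(400 + s)
    gain <- runif(1, 50, 400)
    cap <- function(e) matrix(pmin(rpois(4096, gain * e), 4095), 64, 64)
    r <- auto_exposure(cap, bit_depth = 12)
    expect_lt(abs(r$mean_intensity / (0.875 * 4095) - 1), 0.02)
    expect_lte(r$saturated_fraction, 1e-4)
  }
})

test_that("auto-exposure errors on a hopelessly saturated detector and reports a trace", {
  expect_error(auto_exposure(function(e) matrix(255, 8, 8)), "saturated")
  # unreachable target: detector stuck below target at any exposure
  expect_error(auto_exposure(function(e) matrix(50, 8, 8)), "trace")
})

test_that("flat-field RMSD matches closed forms and the phantom's vignetting scale", {
  cs <- channel_set(550, 20)
  flat <- image_stack(array(100, c(8, 8, 1)), "counts", cs, 8)
  expect_identical(unname(flatness_rmsd(flat)), 0)

  half <- image_stack(array(rep(c(0, 2), each = 32), c(8, 8, 1)), "counts", cs, 8)
  expect_equal(unname(flatness_rmsd(half)), 1)

  E <- tungsten_table()
  blank <- forward_model(make_scene(width = 96, height = 96, n_cells = 0,
                                    E = E, seed = 1),
                         detector_model())$blank
  rmsd <- flatness_rmsd(blank)
  expect_true(all(rmsd > 10 & rmsd < 30))

  # translation invariance: shifting the pattern does not change the RMSD
  shifted <- blank
  shifted$pixels <- blank$pixels[c(20:96, 1:19), , , drop = FALSE]
  expect_equal(unname(flatness_rmsd(shifted)), unname(flatness_rmsd(blank)))
})

test_that("knife-edge MTF matches the closed-form Gaussian transfer function", {
  cs <- channel_set(550, 20)
  det <- detector_model(noise = "none", vignetting = 0, quantize = FALSE)
  edge <- make_knife_edge(det, cs, width = 128, height = 32,
                          edge_position = 64.3, blur_sigma = 2)
  mtf <- knife_edge_mtf(edge)
  expect_identical(mtf$contrast[1], 1)
  sel <- mtf$frequency <= 0.25
  oracle <- exp(-2 * pi^2 * 4 * mtf$frequency[sel]^2)
  expect_lt(max(abs(mtf$contrast[sel] - oracle)), 0.02)
})

test_that("an ideal step's MTF stays above the pixel-aperture sinc envelope", {
  cs <- channel_set(550, 20)
  det <- detector_model(noise = "none", vignetting = 0, quantize = FALSE)
  edge <- make_knife_edge(det, cs, width = 64, height = 16,
                          edge_position = 32.25, blur_sigma = 0)
  mtf <- knife_edge_mtf(edge)
  sel <- mtf$frequency <= 0.5
  sinc <- abs(sin(pi * mtf$frequency[sel]) / (pi * mtf$frequency[sel]))
  sinc[mtf$frequency[sel] == 0] <- 1
  expect_true(all(mtf$contrast[sel] >= sinc - 0.05))
})

test_that("MTF estimation refuses edge-free images", {
  cs <- channel_set(550, 20)
  flat <- image_stack(array(200, c(32, 32, 1)), "counts", cs, 8)
  expect_error(knife_edge_mtf(flat), "no detectable edge")
})

test_that("the 3% cutoff resolution matches the Gaussian closed form within 2%", {
  cs <- channel_set(550, 20)
  det <- detector_model(noise = "none", vignetting = 0, quantize = FALSE)
  edge <- make_knife_edge(det, cs, width = 128, height = 32,
                          edge_position = 64.3, blur_sigma = 2)
  r <- resolution_from_mtf(knife_edge_mtf(edge), 0.03, pixel_pitch = 0.28)
  fc <- sqrt(log(1 / 0.03) / (2 * pi^2 * 2^2))
  expect_lt(abs(r$cutoff_frequency / fc - 1), 0.02)
  expect_lt(abs(r$resolution / (0.28 / fc) - 1), 0.02)

  # halving sigma doubles the cutoff frequency (slanted so the projected
  # ESF is genuinely oversampled at the higher cutoff)
  rs <- vapply(c(2, 1), function(sig) {
    e <- make_knife_edge(det, cs, width = 128, height = 32,
                         edge_position = 64.3, blur_sigma = sig, angle_deg = 3)
    resolution_from_mtf(knife_edge_mtf(e), 0.03)$cutoff_frequency
  }, numeric(1))
  expect_lt(abs(rs[2] / (2 * rs[1]) - 1), 0.03)
})

test_that("resolution is invariant to edge placement and small tilts", {
  cs <- channel_set(550, 20)
  det <- detector_model(noise = "none", vignetting = 0, quantize = FALSE)
  fc <- sqrt(log(1 / 0.03) / (2 * pi^2 * 2^2))
  for (ang in c(-5, -2, 0, 3, 5)) {
    for (pos in c(58.1, 64.5, 70.8)) {
      edge <- make_knife_edge(det, cs, width = 128, height = 64,
                              edge_position = pos, blur_sigma = 2,
                              angle_deg = ang)
      r <- resolution_from_mtf(knife_edge_mtf(edge), 0.03)
      expect_lt(abs(r$cutoff_frequency / fc - 1), 0.02)
    }
  }
})

test_that("degenerate cutoffs are rejected", {
  cs <- channel_set(550, 20)
  det <- detector_model(noise = "none", vignetting = 0, quantize = FALSE)
  edge <- make_knife_edge(det, cs, width = 128, height = 32, blur_sigma = 2)
  mtf <- knife_edge_mtf(edge)
  expect_error(resolution_from_mtf(mtf, 1.0), "between 0 and 1")
  never <- structure(list(frequency = c(0, 0.1, 0.2), contrast = c(1, 0.9, 0.8)),
                     class = "mtf_curve")
  expect_error(resolution_from_mtf(never, 0.03), "never drops")
})
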