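# Optical-system characterization: auto-exposure tuning, flat-field
# statistics, and slanted-knife-edge MTF / resolution estimation.

#' Auto-exposure tuning against a capture function
#'
#' Iteratively adjusts one channel's exposure time until the mean blank
#' intensity sits near the top of the detector's dynamic range while
#' keeping the fraction of saturated pixels within budget. The update is
#' a capped multiplicative step (assuming approximate linearity of counts
#' in exposure) refined by bisection once the target is bracketed; any
#' monotone detector converges within the iteration bound.
#'
#' @param capture function taking an exposure time (ms) and returning a
#'   matrix (or array) of counts; must be monotone nondecreasing in
#'   exposure.
#' @param target_fraction desired mean intensity as a fraction of full
#'   scale (default 0.875 — near the maximum, leaving headroom against
#'   saturation).
#' @param max_saturated_fraction saturation budget (default `1e-4`, "very
#'   few" pixels).
#' @param bit_depth detector bit depth defining full scale.
#' @param tol convergence half-width on the mean, as a fraction of full
#'   scale.
#' @param initial_exposure starting exposure (ms).
#' @param max_iter iteration bound.
#' @return object of class `exposure_result`: list with `exposure_ms`,
#'   `mean_intensity`, `saturated_fraction`, `iterations`, `trace` (one
#'   row per capture).
#' @export
auto_exposure <- function(capture, target_fraction = 0.875,
                          max_saturated_fraction = 1e-4, bit_depth = 8,
                          tol = 0.02, initial_exposure = 10, max_iter = 50) {
  if (target_fraction <= 0 || target_fraction >= 1)
    stop("target_fraction must lie in (0, 1)")
  full <- 2^bit_depth - 1
  target <- target_fraction * full
  e <- initial_exposure
  lo <- 0
  hi <- Inf
  trace <- matrix(NA_real_, max_iter, 4,
                  dimnames = list(NULL, c("exposure_ms", "mean", "saturated_fraction", "n")))
  for (iter in seq_len(max_iter)) {
    img <- capture(e)
    m <- mean(img)
    sat <- mean(img >= full)
    trace[iter, ] <- c(e, m, sat, iter)
    ok_mean <- abs(m - target) <= tol * full
    if (ok_mean && sat <= max_saturated_fraction) {
      return(structure(list(exposure_ms = e, mean_intensity = m,
                            saturated_fraction = sat, iterations = iter,
                            trace = trace[seq_len(iter), , drop = FALSE]),
                       class = "exposure_result"))
    }
    if (sat >= 1 && e <= initial_exposure * 1e-9)
      stop("detector fully saturated even at negligible exposure")
    if (m > target || sat > max_saturated_fraction) hi <- e else lo <- e
    if (is.finite(hi) && lo > 0) {
      e <- (lo + hi) / 2
    } else if (sat > max_saturated_fraction || m >= full * 0.99) {
      e <- e / 2
    } else {
      step <- target / max(m, 1e-9)
      e <- e * min(4, max(0.25, step))
    }
  }
  stop(paste0("auto-exposure failed to converge in ", max_iter,
              " iterations; trace:\n",
              paste(utils::capture.output(print(round(trace, 4))), collapse = "\n")))
}

#' @export
print.exposure_result <- function(x, ...) {
  cat(sprintf(
    "<exposure_result> %.4g ms: mean %.1f counts, %.3g%% saturated, %d iteration(s)\n",
    x$exposure_ms, x$mean_intensity, 100 * x$saturated_fraction, x$iterations))
  invisible(x)
}

#' Flat-field root-mean-square deviation
#'
#' Per-channel RMSD of a blank field about its channel mean, a scalar
#' surrogate for the overall flatness of the illumination profile:
#' zero for a perfectly flat field, and growing with vignetting. It is
#' invariant to where the pattern sits on the detector.
#'
#' @param blank a counts-domain [image_stack()].
#' @return named numeric vector of per-channel RMSD in counts.
#' @export
flatness_rmsd <- function(blank) {
  if (!inherits(blank, "image_stack") || blank$domain != "counts")
    stop("flatness_rmsd expects a counts-domain image_stack")
  if (prod(dim(blank$pixels)[1:2]) < 1) stop("empty image")
  rmsd <- apply(blank$pixels, 3, function(p) sqrt(mean((p - mean(p))^2)))
  stats::setNames(rmsd, blank$channel_set$label)
}

#' Knife-edge MTF estimation
#'
#' Estimates one channel's modulation transfer function from an image of
#' a sharp, near-vertical dark/bright edge, by the slanted-edge method:
#'
#' 1. a subpixel edge position is found per row (centroid of the row's
#'    absolute derivative) and a straight edge is fitted through them to
#'    get the edge angle;
#' 2. every pixel is projected onto the edge-normal axis and averaged in
#'    0.25-pixel bins, yielding an oversampled edge-spread function (ESF;
#'    empty bins are filled by linear interpolation);
#' 3. the ESF is differentiated into the line-spread function (LSF), which
#'    for this optical system doubles as the point-spread profile;
#' 4. the LSF is tapered by a Hann window centered on its peak and Fourier
#'    transformed; the magnitude, normalized to 1 at zero frequency, is
#'    the MTF.
#'
#' @param edge a counts-domain [image_stack()] containing the edge target.
#' @param channel channel label or index to analyze.
#' @param bin projection bin width in pixels (0.25 oversamples 4x).
#' @param max_frequency highest spatial frequency to keep (cycles/pixel).
#' @return object of class `mtf_curve`: list with ascending `frequency`
#'   (cycles/pixel, starting at 0) and `contrast` (MTF, `contrast[1] = 1`).
#' @export
knife_edge_mtf <- function(edge, channel = 1, bin = 0.25, max_frequency = 1) {
  if (!inherits(edge, "image_stack")) stop("expected an image_stack")
  if (is.character(channel)) {
    channel <- match(channel, edge$channel_set$label)
    if (is.na(channel)) stop("unknown channel label")
  }
  img <- edge$pixels[, , channel]
  h <- nrow(img)
  w <- ncol(img)
  rng <- max(img) - min(img)
  if (rng < 0.1 * max(img, 1))
    stop("no detectable edge: image contrast below 10% of its range")
  # per-row subpixel edge location: centroid of the absolute derivative
  xs <- seq_len(w - 1) + 0.5
  pos <- vapply(seq_len(h), function(y) {
    drow <- abs(diff(img[y, ]))
    drow[drow < 0.05 * max(drow)] <- 0  # suppress far-field noise
    sum(xs * drow) / sum(drow)
  }, numeric(1))
  fit <- stats::lm.fit(cbind(1, seq_len(h)), pos)
  a0 <- fit$coefficients[1]
  b <- fit$coefficients[2]
  cosang <- 1 / sqrt(1 + b^2)
  # project pixel centers onto the edge-normal axis
  xg <- matrix(seq_len(w), h, w, byrow = TRUE)
  yg <- matrix(seq_len(h), h, w)
  dist <- (xg - (a0 + b * yg)) * cosang
  half <- floor(min(abs(min(dist)), max(dist)) / bin) - 1L
  if (half < 8L) stop("edge too close to the image border for MTF estimation")
  centers <- seq(-half, half) * bin
  idx <- round(dist / bin)
  keep <- abs(idx) <= half
  esf_sum <- tapply(img[keep], idx[keep], mean)
  esf <- rep(NA_real_, length(centers))
  esf[match(as.integer(names(esf_sum)), seq(-half, half))] <- esf_sum
  miss <- is.na(esf)
  if (any(miss))
    esf[miss] <- stats::approx(centers[!miss], esf[!miss], centers[miss],
                               rule = 2)$y
  lsf <- diff(esf) / bin
  n <- length(lsf)
  peak <- which.max(abs(lsf))
  wnd <- 0.5 * (1 + cos(2 * pi * (seq_len(n) - peak) / n))
  lsf <- lsf * wnd
  spec <- Mod(stats::fft(lsf))
  freq <- (seq_len(n) - 1) / (n * bin)
  if (spec[1] <= 0) stop("degenerate edge profile: zero net step")
  keepf <- freq <= max_frequency
  structure(list(frequency = freq[keepf], contrast = spec[keepf] / spec[1]),
            class = "mtf_curve")
}

#' @export
print.mtf_curve <- function(x, ...) {
  cat(sprintf("<mtf_curve> %d frequencies up to %.3g cycles/pixel\n",
              length(x$frequency), max(x$frequency)))
  invisible(x)
}

#' @export
plot.mtf_curve <- function(x, cutoff = 0.03, ...) {
  graphics::plot(x$frequency, x$contrast, type = "l",
                 xlab = "spatial frequency (cycles/pixel)", ylab = "MTF", ...)
  graphics::abline(h = cutoff, lty = 2)
  invisible(x)
}

#' Resolution from the MTF cutoff frequency
#'
#' Defines the system resolution as one full cycle at the frequency where
#' the MTF first drops to the cutoff contrast (3% by default): the first
#' crossing frequency `f_c` is found by linear interpolation and the
#' resolution is `pixel_pitch / f_c` in the units of `pixel_pitch`.
#'
#' @param curve an [knife_edge_mtf()] result.
#' @param cutoff_contrast cutoff in (0, 1).
#' @param pixel_pitch object-space pixel pitch (e.g. micrometers/pixel).
#' @return list with `cutoff_frequency` (cycles/pixel) and `resolution`
#'   (units of `pixel_pitch`).
#' @export
resolution_from_mtf <- function(curve, cutoff_contrast = 0.03, pixel_pitch = 1) {
  if (cutoff_contrast <= 0 || cutoff_contrast >= 1)
    stop("cutoff contrast must lie strictly between 0 and 1 (a cutoff at full contrast has no crossing)")
  below <- which(curve$contrast < cutoff_contrast)
  if (!length(below))
    stop("MTF never drops below the cutoff in the measured frequency range")
  i <- below[1]
  if (i == 1L) stop("MTF starts below the cutoff; invalid curve")
  f1 <- curve$frequency[i - 1]; f2 <- curve$frequency[i]
  c1 <- curve$contrast[i - 1]; c2 <- curve$contrast[i]
  fc <- f1 + (c1 - cutoff_contrast) / (c1 - c2) * (f2 - f1)
  list(cutoff_frequency = fc, resolution = pixel_pitch / fc)
}
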