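#' Spectral unmixing of an absorbance stack
#'
#' The central estimator of the package. Under Beer-Lambert mixing the
#' absorbance spectrum of a pixel is `a = E c`, where `E` is the
#' channels x chromogens matrix of normalized extinction coefficients and
#' `c >= 0` the vector of relative chromogen concentrations (proportional
#' to optical density). `unmix()` solves, per pixel,
#'
#'   `c = argmin || E c - a ||_2  subject to  c >= 0`
#'
#' by an exact Lawson-Hanson active-set iteration (`method = "nnls"`), or
#' alternatively by unconstrained least squares through the pseudo-inverse
#' of `E` with negatives clipped to zero afterward (`method = "pinv"`,
#' provided for comparison — on pixels where the constrained solution is
#' strictly positive the two agree to machine precision). The counterstain
#' (hematoxylin) is a regular column of `E`, so unmixing is always joint
#' over stains and counterstain.
#'
#' @param a absorbance-domain [image_stack()], C channels.
#' @param E an [extinction_matrix()] whose channel set matches the stack's
#'   (or a superset of it: `channels` may declare the acquired subset).
#' @param channels optional character vector of channel labels to use; the
#'   stack and matrix are restricted to this subset (the basis may
#'   oversample the spectrum). Must leave at least as many channels as
#'   chromogens.
#' @param method `"nnls"` (constrained, the default) or `"pinv"`.
#' @return an object of class `abundance_map`: a list with `values`
#'   (H x W x K non-negative array of relative concentrations),
#'   `chromogens`, `residual` (H x W mean absolute residual per pixel, in
#'   absorbance units), the basis `E`, `method`, and the carried-forward
#'   pixel `flags`.
#' @seealso [residual_metrics()], [unmix_pixel()], [render_brightfield()]
#' @examples
#' E <- tungsten_table()
#' cs <- channels_of_matrix(E)
#' a <- array(rep(unclass(E)[, "TAMRA"], each = 4), c(2, 2, 6))
#' fit <- unmix(image_stack(a, "absorbance", cs), E)
#' round(coef(fit)[1, 1, ], 6)  # unit TAMRA, nothing else
#' @export
unmix <- function(a, E, channels = NULL, method = c("nnls", "pinv")) {
  method <- match.arg(method)
  if (!inherits(a, "image_stack") || a$domain != "absorbance")
    stop("unmix expects an absorbance-domain image_stack")
  if (!is.null(channels)) {
    E <- subset_matrix(E, channels = channels)
    keep <- match(channels_of(E)$label, a$channel_set$label)
    if (anyNA(keep)) stop("declared channels are not all present in the stack")
    cs <- a$channel_set
    sub <- channel_set(cs$center_nm[keep], cs$fwhm_nm[keep], cs$label[keep])
    a <- image_stack(a$pixels[, , keep, drop = FALSE], "absorbance", sub,
                     flags = a$flags)
  }
  if (!same_channels(a$channel_set, channels_of(E)))
    stop("stack and extinction matrix use different channel sets")
  Em <- unclass(E)
  k <- ncol(Em)
  if (nrow(Em) < k)
    stop("unmixing needs at least as many channels as chromogens")
  qrE <- qr(Em)
  if (qrE$rank < k) {
    bad <- colnames(Em)[qrE$pivot[seq.int(qrE$rank + 1L, k)]]
    stop("extinction matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  d <- dim(a$pixels)
  # pixels as columns of a C x N matrix; aperm keeps pixel order stable
  A <- matrix(aperm(a$pixels, c(3, 1, 2)), nrow = d[3])
  cc <- switch(method,
    nnls = nnls_cols(Em, A),
    pinv = {
      z <- qr.coef(qrE, A)
      z[z < 0] <- 0
      z
    })
  res_pix <- colMeans(abs(Em %*% cc - A))
  values <- aperm(array(cc, c(k, d[1], d[2])), c(2, 3, 1))
  dimnames(values) <- list(NULL, NULL, colnames(Em))
  structure(list(values = values, chromogens = colnames(Em),
                 residual = matrix(res_pix, d[1], d[2]),
                 E = E, method = method, flags = a$flags),
            class = "abundance_map")
}

#' Unmix a single absorbance spectrum
#'
#' Vector form of [unmix()] for one pixel.
#'
#' @param a numeric absorbance vector, one entry per channel of `E`.
#' @param E an [extinction_matrix()].
#' @param method `"nnls"` or `"pinv"`.
#' @return named non-negative concentration vector, one entry per chromogen.
#' @export
unmix_pixel <- function(a, E, method = c("nnls", "pinv")) {
  method <- match.arg(method)
  Em <- unclass(E)
  if (length(a) != nrow(Em))
    stop("spectrum length must equal the number of channels")
  if (nrow(Em) < ncol(Em))
    stop("unmixing needs at least as many channels as chromogens")
  qrE <- qr(Em)
  if (qrE$rank < ncol(Em)) {
    bad <- colnames(Em)[qrE$pivot[seq.int(qrE$rank + 1L, ncol(Em))]]
    stop("extinction matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  cc <- switch(method,
    nnls = nnls_cols(Em, matrix(as.numeric(a), ncol = 1)),
    pinv = {
      z <- qr.coef(qrE, matrix(as.numeric(a), ncol = 1))
      z[z < 0] <- 0
      z
    })
  stats::setNames(as.numeric(cc), colnames(Em))
}

#' Helper: channel set attached to an extinction matrix
#' @param E an [extinction_matrix()].
#' @return the [channel_set()] of the matrix.
#' @export
channels_of_matrix <- function(E) channels_of(E)

#' @export
print.abundance_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<abundance_map> %d x %d pixels, %d chromogens (%s)\n",
              d[1], d[2], d[3], x$method))
  cat("  chromogens:", paste(x$chromogens, collapse = ", "), "\n")
  cat(sprintf("  mean |residual| %.4g absorbance units\n", mean(x$residual)))
  invisible(x)
}

#' @export
summary.abundance_map <- function(object, ...) {
  d <- dim(object$values)
  stats <- t(apply(object$values, 3, function(p)
    c(mean = mean(p), median = stats::median(p), max = max(p),
      positive_frac = mean(p > 0))))
  out <- list(dim = d, chromogens = object$chromogens, method = object$method,
              abundance = stats, mean_abs_residual = mean(object$residual),
              max_residual = max(object$residual))
  class(out) <- "summary.abundance_map"
  out
}

#' @export
print.summary.abundance_map <- function(x, ...) {
  cat(sprintf("Spectral unmixing (%s), %d x %d pixels, %d chromogens\n",
              x$method, x$dim[1], x$dim[2], x$dim[3]))
  print(round(x$abundance, 4))
  cat(sprintf("mean |residual| %.4g, max pixel residual %.4g absorbance units\n",
              x$mean_abs_residual, x$max_residual))
  invisible(x)
}

#' @export
coef.abundance_map <- function(object, ...) object$values

#' @export
fitted.abundance_map <- function(object, ...) {
  d <- dim(object$values)
  Em <- unclass(object$E)
  cc <- matrix(aperm(object$values, c(3, 1, 2)), nrow = d[3])
  A <- Em %*% cc
  px <- aperm(array(A, c(nrow(Em), d[1], d[2])), c(2, 3, 1))
  image_stack(px, "absorbance", channels_of(object$E), flags = object$flags)
}

#' @export
residuals.abundance_map <- function(object, ...) object$residual

#' @export
plot.abundance_map <- function(x, mode = c("brightfield", "fluorescence"),
                               colors = default_palette(x$chromogens),
                               gamma = 1, ...) {
  mode <- match.arg(mode)
  nm <- normalize_abundance(x)
  img <- if (mode == "brightfield") render_brightfield(nm, colors, gamma = gamma)
         else render_fluorescence(nm, colors, gamma = gamma)
  op <- graphics::par(mar = c(0.5, 0.5, 1.5, 0.5))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1), asp = dim(img)[2] / dim(img)[1])
  graphics::rasterImage(img, 0, 0, 1, 1)
  graphics::title(main = sprintf("%s composite", mode))
  invisible(img)
}

#' Read / write an abundance map as multipage float TIFF
#'
#' One 32-bit float page per chromogen plane plus a final page holding the
#' per-pixel mean absolute residual, with a YAML sidecar (`<path>.yml`)
#' naming the planes and carrying the basis so a re-read map can be
#' rendered and summarized like a fresh fit.
#'
#' @param map an `abundance_map` from [unmix()].
#' @param path TIFF file path.
#' @return `write_abundance_map` returns `path` invisibly;
#'   `read_abundance_map` returns an `abundance_map`.
#' @export
write_abundance_map <- function(map, path) {
  scale <- max(1, max(map$values), max(map$residual))
  pages <- c(lapply(seq_along(map$chromogens), function(k) map$values[, , k] / scale),
             list(map$residual / scale))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  cs <- channels_of(map$E)
  f <- tempfile()
  write_coefficient_table(map$E, f, digits = 9)
  meta <- list(planes = c(map$chromogens, ".residual"), scale = scale,
               method = map$method, basis = readLines(f))
  unlink(f)
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_abundance_map
#' @export
read_abundance_map <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  chrom <- utils::head(meta$planes, -1L)
  f <- tempfile()
  writeLines(unlist(meta$basis), f)
  # a channel-subset basis may legitimately lack unit column maxima
  E <- suppressWarnings(read_coefficient_table(f))
  unlink(f)
  d <- dim(pages[[1]])
  values <- array(0, c(d[1], d[2], length(chrom)),
                  dimnames = list(NULL, NULL, chrom))
  for (k in seq_along(chrom)) values[, , k] <- pages[[k]] * meta$scale
  structure(list(values = values, chromogens = chrom,
                 residual = pages[[length(pages)]] * meta$scale,
                 E = E, method = meta$method, flags = NULL),
            class = "abundance_map")
}

#' Unmixing residual metrics
#'
#' Quantifies how well the fitted mixture explains the measured stack: the
#' mean absolute residual `|E c - a|` over all pixels and channels (in
#' absorbance units), the same expressed as a percentage of the stack's
#' maximum absorbance, and the per-channel mean absolute error (crosstalk
#' that the basis cannot explain concentrates in the center wavelengths,
#' where neighboring chromogens overlap most).
#'
#' @param a the absorbance-domain [image_stack()] that was unmixed.
#' @param map the [unmix()] result.
#' @param exclude_flagged drop pixels carrying a validity flag.
#' @return list with `mean_abs_error`, `relative_error_pct`,
#'   `per_channel_mae` (named by channel label).
#' @export
residual_metrics <- function(a, map, exclude_flagged = TRUE) {
  if (!inherits(a, "image_stack") || a$domain != "absorbance")
    stop("residual_metrics expects an absorbance-domain image_stack")
  d <- dim(a$pixels)
  if (!identical(d[1:2], dim(map$values)[1:2]))
    stop("stack and abundance map differ in shape")
  Em <- unclass(map$E)
  if (d[3] != nrow(Em)) stop("stack channels do not match the unmixing basis")
  keep <- rep(TRUE, d[1] * d[2])
  if (exclude_flagged && !is.null(map$flags)) keep <- !as.vector(map$flags)
  if (!any(keep)) stop("no valid pixels: every pixel is flagged")
  A <- matrix(aperm(a$pixels, c(3, 1, 2)), nrow = d[3])[, keep, drop = FALSE]
  cc <- matrix(aperm(map$values, c(3, 1, 2)), nrow = ncol(Em))[, keep, drop = FALSE]
  err <- abs(Em %*% cc - A)
  amax <- max(A)
  if (amax <= 0) stop("stack holds no absorbance signal")
  list(mean_abs_error = mean(err),
       relative_error_pct = 100 * mean(err) / amax,
       per_channel_mae = stats::setNames(rowMeans(err), rownames(Em)))
}
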