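#' Multichannel image stack
#'
#' The pixel container used throughout the pipeline: an H x W x C array of
#' per-channel grayscale values together with a declared radiometric
#' domain. `counts` holds raw detector output (integers up to
#' `2^bit_depth - 1`), `transmission` the blank-corrected fraction of
#' transmitted light in \[0, 1\], and `absorbance` the optical density
#' `-log10(T)`. A per-pixel logical `flags` matrix marks invalid pixels
#' (saturated counts, zero-count blanks, clamped transmissions); flagged
#' pixels are processed like any other but carry the flag forward so that
#' downstream metrics can exclude them.
#'
#' @param pixels numeric H x W x C array (a matrix is promoted to one
#'   channel).
#' @param domain one of `"counts"`, `"transmission"`, `"absorbance"`.
#' @param channels a [channel_set()] with C entries.
#' @param bit_depth detector bit depth; required for the counts domain.
#' @param flags optional H x W logical matrix of invalid pixels.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(pixels, domain = c("counts", "transmission", "absorbance"),
                        channels, bit_depth = NULL, flags = NULL) {
  domain <- match.arg(domain)
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  if (length(dim(pixels)) != 3L) stop("'pixels' must be an H x W x C array")
  stopifnot_channel_set(channels)
  if (dim(pixels)[3L] != n_channels(channels))
    stop("third array dimension must equal the number of channels")
  if (domain == "counts") {
    if (is.null(bit_depth)) stop("bit_depth is required for counts stacks")
    if (max(pixels) > 2^bit_depth - 1 + 1e-9)
      stop("counts exceed the detector full scale 2^bit_depth - 1")
    if (min(pixels) < 0) stop("counts must be non-negative")
  }
  if (domain == "transmission" && (min(pixels) < 0 || max(pixels) > 1 + 1e-12))
    stop("transmission values must lie in [0, 1]")
  if (domain == "absorbance" && min(pixels) < -1e-12)
    stop("absorbance values must be non-negative")
  if (!is.null(flags)) {
    if (!is.logical(flags) || !identical(dim(flags), dim(pixels)[1:2]))
      stop("'flags' must be an H x W logical matrix")
  }
  structure(list(pixels = pixels, domain = domain, channel_set = channels,
                 bit_depth = if (domain == "counts") as.integer(bit_depth) else NULL,
                 flags = flags),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_stack> %d x %d pixels, %d channels, domain '%s'%s\n",
              d[1], d[2], d[3], x$domain,
              if (!is.null(x$bit_depth)) sprintf(", %d-bit", x$bit_depth) else ""))
  cat(sprintf("  value range [%.4g, %.4g]%s\n", min(x$pixels), max(x$pixels),
              if (!is.null(x$flags)) sprintf(", %d flagged pixel(s)", sum(x$flags)) else ""))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$pixels)

check_same_geometry <- function(a, b) {
  if (!identical(dim(a$pixels), dim(b$pixels)))
    stop("image stacks differ in shape")
  if (!same_channels(a$channel_set, b$channel_set))
    stop("image stacks were acquired under different channel sets")
  invisible(TRUE)
}

merge_flags <- function(...) {
  fl <- Filter(Negate(is.null), list(...))
  if (!length(fl)) return(NULL)
  Reduce(`|`, fl)
}

#' Read / write an image stack as multipage TIFF with a YAML sidecar
#'
#' One TIFF page per channel in acquisition order. Counts are stored at
#' the native bit depth (8 or 16 bits per sample); transmission and
#' absorbance stacks are stored as 32-bit float. Channel metadata, the
#' domain and the bit depth travel in a YAML sidecar next to the TIFF
#' (`<path>.yml`), so a stack re-read is a faithful reconstruction.
#'
#' @param stack an [image_stack()].
#' @param path TIFF file path; the sidecar is written to `paste0(path, ".yml")`.
#' @return `write_image_stack` returns `path` invisibly;
#'   `read_image_stack` returns an [image_stack()].
#' @export
write_image_stack <- function(stack, path) {
  d <- dim(stack$pixels)
  pages <- lapply(seq_len(d[3]), function(c) stack$pixels[, , c])
  scale <- 1
  if (stack$domain == "counts") {
    bps <- if (stack$bit_depth <= 8) 8L else 16L
    full <- 2^bps - 1
    pages <- lapply(pages, function(p) p / full)  # writeTIFF stores [0,1] scaled
    tiff::writeTIFF(pages, path, bits.per.sample = bps)
  } else {
    # float pages must sit in [0,1]; rescale by the stack maximum
    scale <- max(1, max(stack$pixels))
    pages <- lapply(pages, function(p) p / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  meta <- list(domain = stack$domain,
               scale = scale,
               bit_depth = stack$bit_depth,
               channels = list(label = stack$channel_set$label,
                               center_nm = stack$channel_set$center_nm,
                               fwhm_nm = stack$channel_set$fwhm_nm))
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  px <- array(0, c(dim(pages[[1]]), length(pages)))
  for (c in seq_along(pages)) px[, , c] <- pages[[c]]
  cs <- channel_set(meta$channels$center_nm, meta$channels$fwhm_nm,
                    meta$channels$label)
  if (identical(meta$domain, "counts")) {
    bps <- if (meta$bit_depth <= 8) 8L else 16L
    px <- round(px * (2^bps - 1))
    image_stack(px, "counts", cs, bit_depth = meta$bit_depth)
  } else {
    scale <- if (is.null(meta$scale)) 1 else meta$scale
    image_stack(px * scale, meta$domain, cs)
  }
}
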