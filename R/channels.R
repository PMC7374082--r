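#' Define a set of illumination channels
#'
#' A channel set is the ordered list of narrow-band illumination channels
#' used to acquire a multispectral brightfield stack, one grayscale frame
#' per channel. Each channel is described by the center wavelength of its
#' bandpass filter and the filter FWHM; the order given here is the
#' acquisition order and is preserved through every image stack and
#' coefficient matrix built on top of it.
#'
#' @param center_nm numeric vector of filter center wavelengths in nm;
#'   must lie in the visible range (300, 800).
#' @param fwhm_nm numeric vector of filter FWHM in nm, all positive.
#'   Recycled if length 1.
#' @param label character labels, unique; defaults to the center wavelength
#'   printed without trailing zeros.
#' @return An object of class `channel_set`: a data frame with columns
#'   `label`, `center_nm`, `fwhm_nm`.
#' @examples
#' channel_set(c(438, 549, 676), c(29.5, 17.6, 39.9))
#' @export
channel_set <- function(center_nm, fwhm_nm, label = NULL) {
  center_nm <- as.numeric(center_nm)
  fwhm_nm <- rep_len(as.numeric(fwhm_nm), length(center_nm))
  if (is.null(label)) label <- sprintf("%g", center_nm)
  label <- as.character(label)
  if (length(label) != length(center_nm))
    stop("'label' must match the number of channels")
  if (anyDuplicated(label))
    stop("channel labels must be unique")
  if (any(!is.finite(center_nm)) || any(center_nm <= 300) || any(center_nm >= 800))
    stop("center wavelengths must lie in (300, 800) nm")
  if (any(!is.finite(fwhm_nm)) || any(fwhm_nm <= 0))
    stop("channel FWHM must be positive")
  out <- data.frame(label = label, center_nm = center_nm, fwhm_nm = fwhm_nm,
                    stringsAsFactors = FALSE)
  class(out) <- c("channel_set", "data.frame")
  out
}

#' @export
print.channel_set <- function(x, ...) {
  cat(sprintf("<channel_set> %d illumination channels\n", nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

n_channels <- function(cs) nrow(cs)

#' Test two channel sets for identity
#'
#' Channel sets match when they have the same labels in the same order and
#' the same center wavelengths; stacks acquired under different channel
#' sets must never be combined.
#'
#' @param a,b `channel_set` objects.
#' @return logical scalar.
#' @export
same_channels <- function(a, b) {
  nrow(a) == nrow(b) &&
    all(a$label == b$label) &&
    isTRUE(all.equal(a$center_nm, b$center_nm))
}

stopifnot_channel_set <- function(x, what = "channel_set") {
  if (!inherits(x, "channel_set"))
    stop(sprintf("expected a %s object", what))
  invisible(x)
}
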