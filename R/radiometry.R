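#' Blank-field correction: raw counts to transmission
#'
#' Divides each tissue frame by the matching blank frame (an image of a
#' clear, tissue-free slide region, which defines 100% transmission per
#' pixel per channel). Because both frames see the same illumination
#' pattern, the ratio is flattened both spectrally and spatially by
#' construction. The ratio is clamped to `[eps_t, 1]`; pixels needing a
#' clamp on the bright side (tissue brighter than blank), zero-count blank
#' pixels, and saturated raw counts are flagged in the validity mask
#' rather than raising errors, so whole-field processing never aborts on
#' isolated dead pixels.
#'
#' @param tissue,blank counts-domain [image_stack()]s of identical shape
#'   and channel set.
#' @param eps_t lower transmission clamp (default `1e-4`, an absorbance
#'   ceiling of 4 — deeper optical densities are unmeasurable at 8–12 bit
#'   detector depth).
#' @return a transmission-domain [image_stack()] with a validity mask.
#' @export
to_transmission <- function(tissue, blank, eps_t = 1e-4) {
  if (tissue$domain != "counts" || blank$domain != "counts")
    stop("to_transmission expects counts-domain stacks")
  check_same_geometry(tissue, blank)
  full <- 2^tissue$bit_depth - 1
  sat <- apply(tissue$pixels >= full, c(1, 2), any) |
    apply(blank$pixels >= 2^blank$bit_depth - 1, c(1, 2), any)
  dead <- apply(blank$pixels <= 0, c(1, 2), any)
  b <- blank$pixels
  b[b <= 0] <- 1  # placeholder; pixel is forced to eps_t below
  tr <- tissue$pixels / b
  dead3 <- array(rep(dead, dim(tr)[3]), dim(tr))
  tr[dead3] <- eps_t
  over <- apply(tr > 1, c(1, 2), any)
  tr[tr > 1] <- 1
  tr[tr < eps_t] <- eps_t
  flags <- merge_flags(tissue$flags, blank$flags, sat | dead | over)
  image_stack(tr, "transmission", tissue$channel_set, flags = flags)
}

#' Transmission to absorbance (optical density)
#'
#' `A = -log10(T)`, the standard optical-density convention, so that
#' co-deposited absorbers add linearly (Beer-Lambert). Full transmission
#' maps to `A = 0`; the transmission clamp `eps_t = 1e-4` gives an
#' absorbance ceiling of 4.
#'
#' @param x a transmission-domain [image_stack()].
#' @return an absorbance-domain [image_stack()]; flags are carried over.
#' @export
to_absorbance <- function(x) {
  if (x$domain != "transmission")
    stop("to_absorbance expects a transmission-domain stack")
  a <- -log10(x$pixels)
  a[a < 0] <- 0  # guard against -0 and rounding at T = 1
  image_stack(a, "absorbance", x$channel_set, flags = x$flags)
}

#' Absorbance back to transmission
#'
#' The exact inverse of [to_absorbance()]: `T = 10^(-A)`. Used for
#' brightfield-like re-rendering of composite planes.
#'
#' @param x an absorbance-domain [image_stack()].
#' @return a transmission-domain [image_stack()].
#' @export
to_transmission_from_absorbance <- function(x) {
  if (x$domain != "absorbance")
    stop("to_transmission_from_absorbance expects an absorbance-domain stack")
  image_stack(10^(-x$pixels), "transmission", x$channel_set, flags = x$flags)
}
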