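#' Build a normalized extinction matrix from single-stain calibration stacks
#'
#' Chromogen spectra shift somewhat on deposition, so the unmixing basis
#' is calibrated from on-slide single-stain sections rather than solution
#' spectra. For each chromogen this routine (1) finds its peak channel —
#' the channel with the largest median absorbance over all pixels, ties
#' broken toward the shorter wavelength; (2) builds a mask of pixels whose
#' absorbance in that peak channel exceeds `mask_threshold`, delineating
#' the stained regions; (3) takes the median absorbance of the masked
#' pixels in every channel; and (4) normalizes the column to the median of
#' the most strongly absorbing channel, so every column's maximum is
#' exactly 1.
#'
#' @param stacks list of absorbance-domain [image_stack()]s, one per
#'   chromogen, all sharing `channels`.
#' @param channels the common [channel_set()].
#' @param chromogens character names, one per stack.
#' @param mask_threshold absorbance threshold delineating the stained
#'   region on the peak channel. Default 0.2 OD: well above blank-field
#'   noise at 8-bit quantization, well below typical stain densities.
#' @return an [extinction_matrix()] with column maxima exactly 1.
#' @export
build_reference_matrix <- function(stacks, channels, chromogens,
                                   mask_threshold = 0.2) {
  if (length(stacks) != length(chromogens))
    stop("one calibration stack per chromogen is required")
  stopifnot_channel_set(channels)
  ord <- order(channels$center_nm)
  cols <- matrix(0, n_channels(channels), length(chromogens),
                 dimnames = list(channels$label, chromogens))
  for (i in seq_along(stacks)) {
    s <- stacks[[i]]
    if (!inherits(s, "image_stack") || s$domain != "absorbance")
      stop("calibration stacks must be absorbance-domain image_stacks")
    if (!same_channels(s$channel_set, channels))
      stop(sprintf("calibration stack for '%s' uses a different channel set",
                   chromogens[i]))
    med_all <- apply(s$pixels, 3, stats::median)
    peak <- ord[which.max(med_all[ord])]
    mask <- s$pixels[, , peak] > mask_threshold
    if (!any(mask))
      stop(sprintf(
        "calibration failed for chromogen '%s': no pixels above the mask threshold %.3g on its peak channel (%s)",
        chromogens[i], mask_threshold, channels$label[peak]))
    med_masked <- apply(s$pixels, 3, function(p) stats::median(p[mask]))
    cols[, i] <- med_masked / max(med_masked)
  }
  extinction_matrix(cols, channels, chromogens, check_normalized = FALSE)
}
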