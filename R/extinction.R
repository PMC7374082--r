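#' Construct a normalized extinction-coefficient matrix
#'
#' The extinction matrix is the unmixing basis: one row per illumination
#' channel, one column per chromogen, holding each chromogen's relative
#' absorbance in each channel scaled so that its most strongly absorbing
#' channel equals 1. Measured matrices may contain slightly negative
#' entries (blank-division noise); these are preserved, not clipped —
#' non-negativity is enforced on unmixed concentrations, never on the
#' basis itself.
#'
#' @param E numeric matrix, channels x chromogens. Column names are taken
#'   as chromogen names; if absent, `chromogens` must be given.
#' @param channels a [channel_set()] with one entry per row of `E`.
#' @param chromogens optional character vector of chromogen names.
#' @param check_normalized warn when a column maximum differs from 1 by
#'   more than `1e-9` (the matrix is accepted but flagged un-normalized).
#' @return An object of class `extinction_matrix`: the numeric matrix with
#'   `dimnames` set and the channel set attached as an attribute.
#' @seealso [read_coefficient_table()], [crosstalk_stats()],
#'   [build_reference_matrix()]
#' @export
extinction_matrix <- function(E, channels, chromogens = NULL,
                              check_normalized = TRUE) {
  E <- as.matrix(E)
  storage.mode(E) <- "double"
  stopifnot_channel_set(channels)
  if (nrow(E) != n_channels(channels))
    stop("number of matrix rows must equal the number of channels")
  if (is.null(chromogens)) chromogens <- colnames(E)
  if (is.null(chromogens) || length(chromogens) != ncol(E))
    stop("chromogen names are required, one per column")
  if (ncol(E) < 1L) stop("at least one chromogen column is required")
  dimnames(E) <- list(channels$label, as.character(chromogens))
  peaks <- apply(E, 2L, max)
  if (any(peaks <= 0))
    stop("every chromogen column must have a positive peak coefficient")
  if (check_normalized && any(abs(peaks - 1) > 1e-9))
    warning(sprintf(
      "matrix is not normalized: column maxima of %s differ from 1.0",
      paste(chromogens[abs(peaks - 1) > 1e-9], collapse = ", ")))
  structure(E, channel_set = channels, class = c("extinction_matrix", "matrix"))
}

#' @export
print.extinction_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<extinction_matrix> %d channels x %d chromogens\n",
              nrow(x), ncol(x)))
  m <- unclass(x)
  attr(m, "channel_set") <- NULL
  print(round(m, digits))
  invisible(x)
}

channels_of <- function(E) attr(E, "channel_set")

#' Peak channel of each chromogen
#'
#' The peak channel is the illumination channel in which a chromogen
#' absorbs maximally, i.e. the row holding the column's maximum
#' coefficient. Ties are broken toward the shorter wavelength.
#'
#' @param E an [extinction_matrix()].
#' @return named character vector of channel labels, one per chromogen.
#' @export
peak_channels <- function(E) {
  cs <- channels_of(E)
  ord <- order(cs$center_nm)
  idx <- apply(unclass(E)[ord, , drop = FALSE], 2L, which.max)
  stats::setNames(cs$label[ord][idx], colnames(E))
}

#' Subset an extinction matrix
#'
#' Restrict the basis to a subset of channels and/or chromogens, keeping
#' acquisition order of the retained channels. Used both for marker-subset
#' views and for unmixing with a declared channel subset (the matrix may
#' deliberately oversample the spectrum).
#'
#' @param E an [extinction_matrix()].
#' @param channels character labels of channels to keep (default all).
#' @param chromogens character names of chromogens to keep (default all).
#' @return an `extinction_matrix` over the subset.
#' @export
subset_matrix <- function(E, channels = NULL, chromogens = NULL) {
  cs <- channels_of(E)
  if (is.null(channels)) channels <- cs$label
  if (is.null(chromogens)) chromogens <- colnames(E)
  bad <- setdiff(channels, cs$label)
  if (length(bad)) stop("unknown channel label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(chromogens, colnames(E))
  if (length(bad)) stop("unknown chromogen(s): ", paste(bad, collapse = ", "))
  keep <- cs$label %in% channels
  sub_cs <- channel_set(cs$center_nm[keep], cs$fwhm_nm[keep], cs$label[keep])
  extinction_matrix(unclass(E)[keep, chromogens, drop = FALSE], sub_cs,
                    chromogens, check_normalized = FALSE)
}

#' Read / write a coefficient table as CSV
#'
#' The on-disk form is one row per channel with header
#' `label,center_nm,fwhm_nm,<chromogen...>`. Writing uses a fixed number of
#' decimals (3 by default, matching how such tables are printed); a write
#' followed by a read reproduces the matrix exactly at that precision.
#'
#' @param path file path of the CSV.
#' @return `read_coefficient_table` returns an [extinction_matrix()];
#'   `write_coefficient_table` returns `path` invisibly.
#' @examples
#' E <- tungsten_table()
#' f <- tempfile(fileext = ".csv")
#' write_coefficient_table(E, f)
#' all.equal(unclass(read_coefficient_table(f)), unclass(E))
#' @export
read_coefficient_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("coefficient table needs a header and at least one channel row")
  hdr <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  if (length(hdr) < 4L || !identical(trimws(hdr[1:3]), c("label", "center_nm", "fwhm_nm")))
    stop("malformed header: expected 'label,center_nm,fwhm_nm,<chromogen...>'")
  chrom <- trimws(hdr[-(1:3)])
  body <- strsplit(lines[-1L], ",", fixed = TRUE)
  for (i in seq_along(body)) {
    if (length(body[[i]]) != length(hdr))
      stop(sprintf("malformed coefficient table at line %d: expected %d fields, found %d",
                   i + 1L, length(hdr), length(body[[i]])))
  }
  tab <- do.call(rbind, body)
  num <- suppressWarnings(apply(tab[, -1L, drop = FALSE], 2L, as.numeric))
  num <- matrix(num, nrow = length(body))
  bad <- which(rowSums(is.na(num)) > 0)
  if (length(bad))
    stop(sprintf("malformed numeric field at line %d", bad[1L] + 1L))
  cs <- channel_set(num[, 1L], num[, 2L], trimws(tab[, 1L]))
  extinction_matrix(num[, -(1:2), drop = FALSE], cs, chrom)
}

#' @rdname read_coefficient_table
#' @param E an [extinction_matrix()].
#' @param digits decimals written for the coefficients.
#' @export
write_coefficient_table <- function(E, path, digits = 3) {
  cs <- channels_of(E)
  hdr <- paste(c("label", "center_nm", "fwhm_nm", colnames(E)), collapse = ",")
  rows <- vapply(seq_len(nrow(E)), function(i) {
    paste(c(cs$label[i], sprintf("%g", cs$center_nm[i]), sprintf("%g", cs$fwhm_nm[i]),
            sprintf(paste0("%.", digits, "f"), unclass(E)[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Packaged reference coefficient tables
#'
#' Normalized extinction-coefficient matrices for the six chromogens
#' (dabsyl, Rhod110, TAMRA, SRhod101, hematoxylin, Cy5) measured under the
#' two illumination systems: six filtered-tungsten channels
#' (`tungsten_table`) and twelve filtered-LED channels (`led_table`).
#'
#' @return an [extinction_matrix()].
#' @export
tungsten_table <- function() {
  read_coefficient_table(system.file("extdata", "table1_tungsten.csv",
                                     package = "chromix", mustWork = TRUE))
}

#' @rdname tungsten_table
#' @export
led_table <- function() {
  read_coefficient_table(system.file("extdata", "table2_led.csv",
                                     package = "chromix", mustWork = TRUE))
}

#' Neighboring-chromogen crosstalk statistics
#'
#' Spectral crosstalk between chromogens that are adjacent in peak
#' wavelength limits how well unmixing can separate them. For each
#' adjacent pair (i, i+1) of the requested chromogens (ordered by peak
#' wavelength), this reports two coefficients: chromogen i's coefficient
#' at chromogen i+1's peak channel, and chromogen i+1's coefficient at
#' chromogen i's peak channel — each dye's normalized absorbance at its
#' neighbor's peak.
#'
#' @param E an [extinction_matrix()].
#' @param chromogens character vector (length >= 2) of chromogen names,
#'   ordered by peak wavelength.
#' @return A list of class `crosstalk_stats` with elements `pairs` (data
#'   frame of the reported coefficients), `min`, `max`, `mean`.
#' @examples
#' crosstalk_stats(tungsten_table(), c("dabsyl", "TAMRA", "Cy5"))
#' @export
crosstalk_stats <- function(E, chromogens) {
  if (length(chromogens) < 2L)
    stop("crosstalk requires at least two chromogens")
  bad <- setdiff(chromogens, colnames(E))
  if (length(bad))
    stop("chromogen(s) not in matrix: ", paste(bad, collapse = ", "))
  pk <- peak_channels(E)[chromogens]
  if (anyDuplicated(pk))
    stop("chromogens must have unique peak channels")
  cs <- channels_of(E)
  wl <- cs$center_nm[match(pk, cs$label)]
  if (is.unsorted(wl))
    stop("chromogens must be ordered by increasing peak wavelength")
  rows <- list()
  for (i in seq_len(length(chromogens) - 1L)) {
    a <- chromogens[i]; b <- chromogens[i + 1L]
    rows[[length(rows) + 1L]] <- data.frame(
      chromogen = c(a, b), at_peak_of = c(b, a), channel = c(pk[[b]], pk[[a]]),
      coefficient = c(unclass(E)[pk[[b]], a], unclass(E)[pk[[a]], b]),
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  structure(list(pairs = pairs,
                 min = min(pairs$coefficient),
                 max = max(pairs$coefficient),
                 mean = mean(pairs$coefficient)),
            class = "crosstalk_stats")
}

#' @export
print.crosstalk_stats <- function(x, ...) {
  cat("<crosstalk_stats> neighboring-chromogen coefficients\n")
  print(x$pairs, row.names = FALSE)
  cat(sprintf("min %.3f  max %.3f  mean %.3f\n", x$min, x$max, x$mean))
  invisible(x)
}
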