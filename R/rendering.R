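#' Default display palette for chromogen abundance planes
#'
#' Named RGB triples (rows of a K x 3 matrix in \[0, 1\]) for the packaged
#' chromogens, echoing typical display choices for these stains: warm
#' yellow for dabsyl, green for Rhod110, purple for TAMRA, orange-red for
#' SRhod101, blue for hematoxylin, far-red for Cy5. Unknown chromogens
#' receive evenly spaced hues; swap colors freely — a display color
#' carries no physics, it only labels a plane.
#'
#' @param chromogens character vector of plane names.
#' @return K x 3 numeric matrix with rownames `chromogens`.
#' @export
default_palette <- function(chromogens) {
  known <- rbind(
    dabsyl   = c(1.00, 0.85, 0.10),
    Rhod110  = c(0.15, 0.80, 0.25),
    TAMRA    = c(0.60, 0.20, 0.75),
    SRhod101 = c(0.95, 0.45, 0.10),
    HTX      = c(0.25, 0.35, 0.85),
    Cy5      = c(0.85, 0.10, 0.30))
  out <- matrix(0, length(chromogens), 3, dimnames = list(chromogens, c("r", "g", "b")))
  extra <- 0L
  for (i in seq_along(chromogens)) {
    if (chromogens[i] %in% rownames(known)) {
      out[i, ] <- known[chromogens[i], ]
    } else {
      extra <- extra + 1L
      out[i, ] <- as.vector(grDevices::col2rgb(grDevices::hcl(30 + 47 * extra, 80, 60)) / 255)
    }
  }
  out
}

check_palette <- function(colors, chromogens) {
  colors <- as.matrix(colors)
  if (ncol(colors) != 3 || nrow(colors) < length(chromogens))
    stop("palette must provide an RGB triple per chromogen")
  if (!is.null(rownames(colors))) {
    bad <- setdiff(chromogens, rownames(colors))
    if (length(bad)) stop("palette lacks color(s) for: ", paste(bad, collapse = ", "))
    colors <- colors[chromogens, , drop = FALSE]
  }
  if (min(colors) < 0 || max(colors) > 1) stop("palette entries must lie in [0, 1]")
  colors
}

#' Normalize abundance planes for display
#'
#' Divides each chromogen plane by a normalization statistic so planes are
#' color-balanced before compositing: the plane maximum (default, so every
#' plane peaks at 1) or an upper percentile with values above it clipped
#' to 1 (robust when single hot pixels would otherwise dim an entire
#' plane). All-zero planes pass through as zeros.
#'
#' @param map an `abundance_map` from [unmix()].
#' @param method `"max"` or `"percentile"`.
#' @param p percentile (in percent) for `method = "percentile"`.
#' @return the map with planes scaled into \[0, 1\] and an attribute
#'   `normalized = TRUE`.
#' @export
normalize_abundance <- function(map, method = c("max", "percentile"), p = 99) {
  method <- match.arg(method)
  v <- map$values
  for (k in seq_len(dim(v)[3])) {
    s <- if (method == "max") max(v[, , k])
         else stats::quantile(v[, , k], p / 100, names = FALSE)
    if (s > 0) {
      v[, , k] <- v[, , k] / s
      v[, , k][v[, , k] > 1] <- 1
    }
  }
  map$values <- v
  attr(map, "normalized") <- TRUE
  map
}

is_normalized <- function(map) {
  isTRUE(attr(map, "normalized")) || max(map$values) <= 1 + 1e-9
}

#' Restrict an abundance map to a marker subset
#'
#' Drops the planes of all chromogens outside `subset`, preserving plane
#' order; used for reduced-complexity views showing only the markers of
#' one phenotype.
#'
#' @param map an `abundance_map`.
#' @param subset character vector of chromogen names to keep (non-empty).
#' @return the restricted `abundance_map`.
#' @export
select_markers <- function(map, subset) {
  if (length(subset) < 1L) stop("marker subset must not be empty")
  bad <- setdiff(subset, map$chromogens)
  if (length(bad)) stop("unknown marker(s): ", paste(bad, collapse = ", "))
  keep <- map$chromogens[map$chromogens %in% subset]
  map$values <- map$values[, , keep, drop = FALSE]
  map$E <- subset_matrix(map$E, chromogens = keep)
  map$chromogens <- keep
  map
}

#' Brightfield-like pseudo-color composite
#'
#' Renders normalized abundances as they would appear in transmitted
#' light. Each chromogen's display color defines its RGB extinction
#' vector as the color's complement `(1 - color)`, scaled by abundance and
#' a global density scale; per RGB channel the optical densities of all
#' stains add (Beer-Lambert), and the displayed intensity is the reverse
#' log transform `10^(-OD)`. Zero abundance therefore renders as a white
#' background, and overlapping stains multiply their transmissions into a
#' darker mixed hue, exactly as co-deposited absorbers behave on a slide.
#'
#' @param map a normalized `abundance_map` (see [normalize_abundance()]).
#' @param colors K x 3 RGB palette, rows named by chromogen
#'   (default [default_palette()]).
#' @param scale global density scale applied to all stains.
#' @param gamma display gamma passed to [apply_gamma()]; 1 leaves the
#'   rendering linear in transmission.
#' @return H x W x 3 array in \[0, 1\].
#' @export
render_brightfield <- function(map, colors = default_palette(map$chromogens),
                               scale = 1, gamma = 1) {
  if (!is_normalized(map))
    stop("abundance map must be normalized before rendering (normalize_abundance)")
  colors <- check_palette(colors, map$chromogens)
  d <- dim(map$values)
  od <- array(0, c(d[1], d[2], 3))
  for (k in seq_len(d[3])) {
    ext <- (1 - colors[k, ]) * scale
    for (j in 1:3) od[, , j] <- od[, , j] + map$values[, , k] * ext[j]
  }
  apply_gamma(10^(-od), gamma)
}

#' Fluorescence-like pseudo-color composite
#'
#' Dark-field rendering of the same abundances: black background, each
#' chromogen contributing `abundance * color` additively, clipped at 1.
#' Useful for viewers accustomed to multiplex immunofluorescence.
#'
#' @inheritParams render_brightfield
#' @return H x W x 3 array in \[0, 1\].
#' @export
render_fluorescence <- function(map, colors = default_palette(map$chromogens),
                                gamma = 1) {
  if (!is_normalized(map))
    stop("abundance map must be normalized before rendering (normalize_abundance)")
  colors <- check_palette(colors, map$chromogens)
  d <- dim(map$values)
  img <- array(0, c(d[1], d[2], 3))
  for (k in seq_len(d[3])) {
    for (j in 1:3) img[, , j] <- img[, , j] + map$values[, , k] * colors[k, j]
  }
  img[img > 1] <- 1
  apply_gamma(img, gamma)
}

#' Gamma correction
#'
#' `out = in^(1/gamma)` on \[0, 1\]; `gamma = 1` is the identity. Applied
#' for screen display so that linear concentration values are perceived
#' linearly; quantitative export should keep `gamma = 1`.
#'
#' @param image numeric array with values in \[0, 1\].
#' @param gamma positive real.
#' @return the corrected array.
#' @export
apply_gamma <- function(image, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("gamma must be a positive scalar")
  if (gamma == 1) return(image)
  image^(1 / gamma)
}

#' Write an RGB composite as PNG
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_composite <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}
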