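# Synthetic phantoms: ground-truth stained scenes plus a Beer-Lambert
# forward model of acquisition (illumination vignetting, shot noise,
# quantization), so the whole pipeline is testable without slide data.

# A single user seed fans out to independent per-stage seeds so adding a
# stage never perturbs the draws of an earlier one. Offsets are arbitrary
# fixed constants; results stay below 2^31.
stage_seed <- function(seed, stage) {
  (as.integer(seed) + 104729L * match(stage, c("scene", "blank", "tissue",
                                               "edge", "profile"))) %% 2147483647L
}

#' Detector and illumination model for the forward simulator
#'
#' Describes the virtual camera: bit depth, the mean blank level
#' (`full_scale`, in counts — by default about 86% of the 8-bit range,
#' the level an auto-exposure routine targeting the top of the dynamic
#' range settles at), optional Poisson shot noise, integer quantization,
#' and a smooth illumination profile. The profile is radially symmetric
#' quadratic vignetting with a given edge falloff and a small per-channel
#' jitter of the pattern center, emulating how each LED projects a
#' slightly different pattern onto the detector.
#'
#' @param bit_depth 8 or 12.
#' @param full_scale mean blank level in counts at the profile center.
#' @param noise `"none"` or `"poisson"`.
#' @param vignetting relative falloff at the nearest image edge
#'   (0 = flat field).
#' @param center_jitter per-channel jitter of the vignetting center, as a
#'   fraction of the image size.
#' @param quantize round simulated counts to integers (disable for exact
#'   round-trip tests).
#' @return an object of class `detector_model`.
#' @export
detector_model <- function(bit_depth = 8, full_scale = 220,
                           noise = c("none", "poisson"),
                           vignetting = 0.15, center_jitter = 0.1,
                           quantize = TRUE) {
  noise <- match.arg(noise)
  if (!bit_depth %in% c(8, 12)) stop("bit_depth must be 8 or 12")
  if (full_scale > 2^bit_depth - 1) stop("full_scale exceeds the detector range")
  if (vignetting < 0 || vignetting >= 1) stop("vignetting must lie in [0, 1)")
  structure(list(bit_depth = as.integer(bit_depth), full_scale = full_scale,
                 noise = noise, vignetting = vignetting,
                 center_jitter = center_jitter, quantize = quantize),
            class = "detector_model")
}

# Per-channel illumination profiles in (0, 1], value 1 at the pattern
# center; quadratic falloff reaching `vignetting` at the nearest image
# edge (so a square image corner sits at twice that falloff).
illumination_profiles <- function(detector, h, w, n_chan, seed) {
  set.seed(stage_seed(seed, "profile"))
  prof <- array(0, c(h, w, n_chan))
  rmax <- (min(h, w) - 1) / 2
  for (c in seq_len(n_chan)) {
    cy <- (h + 1) / 2 + stats::runif(1, -1, 1) * detector$center_jitter * h
    cx <- (w + 1) / 2 + stats::runif(1, -1, 1) * detector$center_jitter * w
    r2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`)
    p <- 1 - detector$vignetting * r2 / rmax^2
    prof[, , c] <- pmax(p, 1e-3)
  }
  prof
}

#' Generate a ground-truth stained scene
#'
#' Lays out a population of synthetic cells and paints exact chromogen
#' concentration fields (in OD-scaled units) for every column of the
#' extinction matrix. Every nucleus receives hematoxylin counterstain.
#' The remaining chromogens act as phenotype markers: consecutive markers
#' are paired into phenotype classes (mirroring assays whose marker pairs
#' distinguish mutually exclusive tumor phenotypes), each marker-positive
#' cell draws one phenotype and expresses that class's markers, and
#' marker morphology cycles through nuclear disks (Ki-67/TTF-1-like),
#' cytoplasmic rings (cytokeratin-like), and membrane annuli (CD8-like).
#' Phenotype exclusivity keeps co-deposited optical densities within the
#' range a brightfield detector can actually measure, as the real assays
#' are designed to do. All randomness is fixed by `seed`, and the truth
#' fields are reported exactly for use as oracles.
#'
#' @param width,height scene size in pixels.
#' @param n_cells number of cells.
#' @param E the [extinction_matrix()] whose chromogen columns the scene
#'   must cover.
#' @param counterstain name of the counterstain column present in every
#'   nucleus (`"HTX"` if present, else the last column).
#' @param marker_fraction fraction of cells that are marker-positive at
#'   all; a positive cell draws one phenotype class and expresses each of
#'   that class's markers with probability 0.9.
#' @param nucleus_radius,cell_radius radius ranges in pixels.
#' @param od_range range of peak optical densities assigned to marker
#'   stains.
#' @param counterstain_od range of counterstain optical densities; kept
#'   below the marker range because in practice the counterstain is
#'   deliberately weakened to limit interference with neighboring
#'   chromogens, and so that co-deposited structures stay within the
#'   absorbance ceiling measurable at 8-bit depth.
#' @param seed integer fixing all randomness.
#' @return object of class `phantom_scene`: list with `truth`
#'   (H x W x K array), `chromogens`, `E`, `seed`.
#' @export
make_scene <- function(width = 96, height = 96, n_cells = 30, E,
                       counterstain = NULL, marker_fraction = 0.45,
                       nucleus_radius = c(2.5, 4.5), cell_radius = c(5, 8),
                       od_range = c(0.4, 1.2), counterstain_od = c(0.25, 0.5),
                       seed = 1) {
  chrom <- colnames(E)
  k <- length(chrom)
  if (is.null(counterstain))
    counterstain <- if ("HTX" %in% chrom) "HTX" else chrom[k]
  if (!counterstain %in% chrom) stop("counterstain not among the chromogens")
  truth <- array(0, c(height, width, k), dimnames = list(NULL, NULL, chrom))
  if (n_cells > 0) {
    if (max(cell_radius) * 2 + 2 > min(width, height))
      stop("cell geometry exceeds the image bounds")
    set.seed(stage_seed(seed, "scene"))
    markers <- setdiff(chrom, counterstain)
    styles <- rep(c("nuclear", "cytoplasm", "membrane"), length.out = length(markers))
    rmax <- max(cell_radius)
    cx <- stats::runif(n_cells, rmax + 1, width - rmax - 1)
    cy <- stats::runif(n_cells, rmax + 1, height - rmax - 1)
    rn <- stats::runif(n_cells, nucleus_radius[1], nucleus_radius[2])
    rc <- stats::runif(n_cells, cell_radius[1], cell_radius[2])
    # phenotype classes: consecutive marker pairs; a marker-positive cell
    # expresses the markers of its phenotype only
    pheno_of <- ceiling(seq_along(markers) / 2)
    n_pheno <- max(pheno_of, 1L)
    cell_pheno <- sample.int(n_pheno, n_cells, replace = TRUE)
    cell_pheno[stats::runif(n_cells) >= marker_fraction] <- 0L  # negative cells
    pos <- matrix(FALSE, n_cells, length(markers))
    for (m in seq_along(markers))
      pos[, m] <- cell_pheno == pheno_of[m] & stats::runif(n_cells) < 0.9
    xg <- matrix(seq_len(width), height, width, byrow = TRUE)
    yg <- matrix(seq_len(height), height, width)
    for (i in seq_len(n_cells)) {
      d2 <- (xg - cx[i])^2 + (yg - cy[i])^2
      nuc <- d2 <= rn[i]^2
      cyto <- d2 <= rc[i]^2 & d2 > rn[i]^2
      memb <- d2 <= rc[i]^2 & d2 > (0.85 * rc[i])^2
      od_n <- stats::runif(1, counterstain_od[1], counterstain_od[2])
      pl <- truth[, , counterstain]
      pl[nuc] <- pmax(pl[nuc], od_n)
      truth[, , counterstain] <- pl
      for (m in seq_along(markers)) {
        if (!pos[i, m]) next
        od_m <- stats::runif(1, od_range[1], od_range[2])
        region <- switch(styles[m], nuclear = nuc, cytoplasm = cyto, membrane = memb)
        pl <- truth[, , markers[m]]
        pl[region] <- pmax(pl[region], od_m)
        truth[, , markers[m]] <- pl
      }
    }
  }
  structure(list(truth = truth, chromogens = chrom, E = E, seed = seed),
            class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  d <- dim(x$truth)
  cat(sprintf("<phantom_scene> %d x %d pixels, %d chromogens, seed %d\n",
              d[1], d[2], d[3], x$seed))
  invisible(x)
}

#' Forward-model the acquisition of a phantom scene
#'
#' Simulates what the camera records: per pixel the absorbance spectrum is
#' `A = E c` (Beer-Lambert mixing of the ground-truth concentrations), the
#' transmitted fraction `T = 10^(-A)`, and the recorded counts are
#' `T x profile x full_scale` for the tissue frame and
#' `profile x full_scale` for the matching blank frame, with optional
#' Poisson shot noise, integer quantization, and clipping at the detector
#' full scale.
#'
#' @param scene a [make_scene()] result.
#' @param detector a [detector_model()].
#' @return list with counts-domain [image_stack()]s `tissue` and `blank`.
#' @export
forward_model <- function(scene, detector = detector_model()) {
  d <- dim(scene$truth)
  Em <- unclass(scene$E)
  cs <- channels_of(scene$E)
  n_chan <- nrow(Em)
  cc <- matrix(aperm(scene$truth, c(3, 1, 2)), nrow = d[3])
  A <- Em %*% cc
  tr <- aperm(array(10^(-A), c(n_chan, d[1], d[2])), c(2, 3, 1))
  prof <- illumination_profiles(detector, d[1], d[2], n_chan, scene$seed)
  blank <- prof * detector$full_scale
  tissue <- tr * blank
  if (detector$noise == "poisson") {
    set.seed(stage_seed(scene$seed, "blank"))
    blank <- array(stats::rpois(length(blank), blank), dim(blank))
    set.seed(stage_seed(scene$seed, "tissue"))
    tissue <- array(stats::rpois(length(tissue), tissue), dim(tissue))
  }
  if (detector$quantize) {
    blank <- round(blank)
    tissue <- round(tissue)
  }
  full <- 2^detector$bit_depth - 1
  blank[blank > full] <- full
  tissue[tissue > full] <- full
  list(tissue = image_stack(tissue, "counts", cs, bit_depth = detector$bit_depth),
       blank = image_stack(blank, "counts", cs, bit_depth = detector$bit_depth))
}

#' Simulate a knife-edge target
#'
#' Produces the stack a camera would record of a sharp dark/bright edge:
#' an ideal step (dark on the left of `edge_position`, bright on the
#' right) convolved with a per-channel Gaussian point-spread function of
#' width `blur_sigma`, sampled at pixel centers, optionally slanted a few
#' degrees from vertical, then passed through the detector model. Used to
#' exercise the knife-edge MTF estimator against closed forms.
#'
#' @param detector a [detector_model()].
#' @param channels a [channel_set()].
#' @param width,height image size in pixels.
#' @param edge_position subpixel column of the edge at mid-height.
#' @param blur_sigma Gaussian PSF sigma in pixels, recycled per channel;
#'   0 gives a pure step.
#' @param angle_deg edge tilt from vertical, degrees.
#' @param dark_fraction transmitted fraction on the dark side.
#' @param seed integer for the noise draws.
#' @return a counts-domain [image_stack()].
#' @export
make_knife_edge <- function(detector = detector_model(), channels,
                            width = 64, height = 64,
                            edge_position = width / 2 + 0.25,
                            blur_sigma = 2, angle_deg = 0,
                            dark_fraction = 0.02, seed = 1) {
  if (edge_position <= 0 || edge_position >= width)
    stop("edge_position must lie inside the image")
  n_chan <- n_channels(channels)
  blur_sigma <- rep_len(blur_sigma, n_chan)
  if (any(blur_sigma < 0)) stop("blur_sigma must be non-negative")
  prof <- illumination_profiles(detector, height, width, n_chan, seed)
  px <- array(0, c(height, width, n_chan))
  slope <- tan(angle_deg * pi / 180)
  for (c in seq_len(n_chan)) {
    for (y in seq_len(height)) {
      xe <- edge_position + slope * (y - (height + 1) / 2)
      x <- seq_len(width)
      tr <- if (blur_sigma[c] == 0) as.numeric(x >= xe)
            else stats::pnorm((x - xe) / blur_sigma[c])
      px[y, , c] <- dark_fraction + (1 - dark_fraction) * tr
    }
  }
  counts <- px * prof * detector$full_scale
  if (detector$noise == "poisson") {
    set.seed(stage_seed(seed, "edge"))
    counts <- array(stats::rpois(length(counts), counts), dim(counts))
  }
  if (detector$quantize) counts <- round(counts)
  full <- 2^detector$bit_depth - 1
  counts[counts > full] <- full
  image_stack(counts, "counts", channels, bit_depth = detector$bit_depth)
}
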