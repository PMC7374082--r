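---
title: "Methods: spectral unmixing for brightfield multiplex IHC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral unmixing for brightfield multiplex IHC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromix)
```

This vignette is the package's own account of the models, numerical
choices, and validation strategy behind its five computational stages:
radiometry, calibration, unmixing, rendering, and optical
characterization, all of which are exercised against a built-in phantom
generator.

## Radiometric model

A multispectral brightfield acquisition records one grayscale frame per
narrow-band illumination channel, plus a *blank* stack at a clear,
tissue-free slide location. The blank defines 100% transmission per pixel
per channel, so the ratio

$$T = I_\text{tissue} / I_\text{blank}$$

is simultaneously the transmitted fraction and a flat-field correction:
any illumination pattern common to both frames — vignetting, per-channel
brightness differences — cancels exactly. Absorbance (optical density) is
$A = -\log_{10} T$, base 10 by the OD convention, which makes
co-deposited absorbers additive (Beer–Lambert). A natural-log variant
would merely rescale every coefficient, but all packaged tables follow
the OD convention, so base 10 is load-bearing.

Numerical choices:

* **Transmission clamp** `eps_t = 1e-4`, i.e. an absorbance ceiling of
  4.0. Optical densities deeper than 4 are unmeasurable at 8–12 bit
  detector depth (a pixel would need fewer than one part in $10^4$ of the
  blank counts), so deeper values carry no information. The clamp also
  absorbs zero-count tissue pixels.
* **Flags, not exceptions.** Zero-count blank pixels, saturated raw
  counts, and tissue-brighter-than-blank pixels are recorded in a
  per-pixel validity mask and processed like any other pixel. Whole-field
  processing should never abort on an isolated dead pixel;
  `residual_metrics()` excludes flagged pixels by default.
* No dark-frame subtraction is modeled; the pipeline assumes the camera
  offset is negligible or pre-corrected.

## Calibration of the extinction matrix

Chromogen spectra shift somewhat upon tissue deposition, so the unmixing
basis is measured *on-slide* from single-stain control sections rather
than from solution spectra. For each chromogen, `build_reference_matrix()`

1. finds the **peak channel** — the channel with the largest median
   absorbance over all pixels (ties broken toward the shorter wavelength;
   the tie rule matters only for synthetic flat spectra);
2. masks pixels whose peak-channel absorbance exceeds `mask_threshold`
   (default **0.2 OD**: well above blank-field noise at 8-bit
   quantization, well below typical stain densities of 0.5–1.5 OD);
3. takes the per-channel **median** absorbance over the mask — medians
   resist residual background pixels and saturation outliers;
4. normalizes the column by its maximum, so every column's peak is
   exactly 1.0 in floating point (a value divided by itself).

The whole-image median in step 1 presumes the control section is
predominantly stained, as control sections are in practice; on a sparsely
stained section the median would be background-dominated and the
calibration fails loudly (an error naming the chromogen) rather than
silently mis-picking a peak.

Measured coefficient tables may contain slightly negative entries (the
packaged LED table holds −0.018): blank-division noise can push a
near-zero median below zero. These are **preserved, not clipped** — the
packaged tables themselves contain them, and non-negativity belongs to
the concentrations, not the basis.

### Crosstalk statistics

For chromogens adjacent in peak wavelength, `crosstalk_stats()` reports
each dye's coefficient at its neighbor's peak channel. On the packaged
tungsten table the three-dye set (dabsyl, TAMRA, Cy5) spans 0.034–0.274
and the five-dye set peaks at 0.688 (TAMRA at SRhod101's channel). The
*mean* over these pairwise coefficients is also reported, but note that
published summaries of such tables do not always state their averaging
rule (which values are pooled, whether both directions of each pair
count), so the mean is informational; the min/max are the well-defined
statistics.

## Per-pixel unmixing

Under the Beer–Lambert model the absorbance spectrum of a pixel is
$a = E c$ with $c \ge 0$. `unmix()` solves the non-negative least-squares
problem exactly per pixel with a Lawson–Hanson active-set iteration
(compiled; the active set terminates at the KKT point, so this is the
constrained optimum, not an iterative truncation). Design points:

* **Joint basis.** Hematoxylin is an ordinary column of $E$; unmixing is
  always joint over markers and counterstain. Dropping the counterstain
  from the basis would alias nuclear absorbance onto the markers.
* **Channel oversampling.** The basis may hold more channels than were
  acquired for a particular assay; `unmix(..., channels = )` declares the
  subset, requiring at least as many channels as chromogens.
* **Rank checks.** A rank-deficient basis produces an error naming the
  collinear columns (from the pivoted QR), because NNLS would silently
  return one of many minimizers.
* **`method = "pinv"`** provides the classical alternative — the
  unconstrained least-squares solution through the pseudo-inverse with
  negatives clipped to zero afterwards. On pixels where the constrained
  solution is strictly positive the two coincide to machine precision
  (KKT conditions); on noisy data the clipped inverse is never more
  accurate, which the test suite asserts.

Validation is dual-route: the solver is checked against an exhaustive
grid-search oracle on two-dye problems (step $10^{-3}$ over $[0,3]^2$)
and against an independent active-set implementation (`pracma`), and the
full pipeline (scene → forward model → radiometry → unmixing) must return
the ground-truth concentration fields to $10^{-6}$ when noise and
quantization are disabled.

### Residual metrics and noise-induced bias

`residual_metrics()` reports the mean absolute reconstruction error
$|Ec - a|$ over pixels and channels, in OD units and as a percentage of
the stack's maximum absorbance (computed after clamping). The
per-channel breakdown typically concentrates in the center wavelengths,
where neighboring chromogens overlap most.

A limitation worth stating plainly: at 8-bit single-exposure acquisition
(blank level ≈ 220 counts), per-pixel NNLS abundances of spectrally
*broad* or mutually collinear stains carry a noise-induced **median bias
of roughly 5–15%**, concentrated in hematoxylin and Rhod110. The
mechanism is intrinsic to the estimator: shot noise propagated through
the log transform lands on a nearly collinear basis, and the
non-negativity constraint clips the error distribution asymmetrically.
Monte-Carlo on isolated single-stain pixels (clean blank, no vignetting)
reproduces the bias, so it is not caused by scene overlap or clamping;
and the identical pipeline at 12-bit depth recovers every chromogen's
stained-region median within ~2% (12-channel LED basis) to ~4%
(6-channel tungsten basis). The per-pixel *residual*, by contrast, stays
well behaved at 8 bits (≈0.03 OD mean on the standard noisy phantom,
about 1% of the assay's maximum absorbance). Quantitative users at 8-bit
depth should aggregate abundances over regions rather than trust single
pixels.

## Rendering

Unmixed abundances are displayed after per-plane normalization
(`normalize_abundance()`: divide by the plane maximum, or by an upper
percentile — default p99 — with clipping, which is robust to single hot
pixels that would otherwise dim an entire plane; all-zero planes pass
through unchanged).

The **brightfield composite** treats each display color's complement
$(1 - \text{color})$ as that stain's RGB extinction vector: per RGB
channel $j$,

$$\text{OD}_j = \sum_k c_k\,(1 - \text{color}_k[j])\, s , \qquad
  \text{pixel}_j = 10^{-\text{OD}_j},$$

with $s$ a global density scale (default 1). This formula is the
package's own definition of pseudo-color compositing — display pipelines
for such assays rarely publish one — chosen because it is additive in OD
and therefore physically consistent with transmitted light: zero
abundance renders white, overlapping stains multiply their transmissions
into a darker mixed hue, and increasing any abundance never brightens any
channel. The **fluorescence composite** is the familiar dark-field dual:
$\text{pixel} = \sum_k c_k \cdot \text{color}_k$, clipped at 1.

Gamma correction (`out = in^(1/gamma)`) defaults to 2.2 for screen
display and 1.0 for quantitative export; displayed intensities are then
approximately perceptually linear in concentration. The default palette
(warm yellow dabsyl, purple TAMRA, blue hematoxylin, …) echoes common
display choices for these stains but is purely a labeling device.

## The phantom generator

The phantom is first-class, tested code: it defines the conditions under
which every other module is validated.

* **Scenes** (`make_scene()`) lay out disk nuclei with hematoxylin
  counterstain and assign the remaining chromogens as phenotype markers.
  Consecutive markers pair into *mutually exclusive phenotype classes* —
  as in assays whose marker pairs distinguish tumor subtypes — and each
  marker-positive cell (60% of cells by default) draws one phenotype.
  Morphology cycles through nuclear disks, cytoplasmic rings, and
  membrane annuli. Marker densities default to 0.4–1.2 OD, typical
  deposition densities; the counterstain to 0.4–0.8 OD, weaker because
  counterstaining is deliberately decreased in such assays to limit
  interference with neighboring chromogens — and because phenotype
  exclusivity plus a moderate counterstain keeps co-deposited OD inside
  the ceiling an 8-bit detector can measure.
* **The detector** (`detector_model()`) defaults to 8-bit depth with a
  mean blank level of 220 counts (the level an auto-exposure loop
  targeting ~87% of full scale settles at), radially symmetric quadratic
  vignetting with 15% falloff at the image edge and a small per-channel
  center jitter, optional Poisson shot noise, and integer quantization.
  These defaults give blank-field RMSD of ~14–16 counts, the right scale
  for a characterized LED illuminator.
* **Determinism.** A single user seed fans out to fixed per-stage
  sub-seeds (scene, blank, tissue, edge, profile), so adding a stage
  never perturbs earlier draws and every output is a pure function of
  (parameters, seed).
* **What it does not emulate:** tissue texture, chromogen co-deposition
  interference chemistry, optical scattering, focus variation, stage
  drift. Passing phantom tests therefore demonstrates the *computational*
  pipeline is correct under its stated noise model, not that any
  particular wet-lab assay meets a given accuracy.

`forward_model()` composes $A = Ec$, $T = 10^{-A}$, multiplies by the
illumination profile and full scale, then applies noise, rounding, and
clipping — exactly the model the radiometry stage inverts, which is what
makes the noiseless round trip an exact identity test.

## Optical characterization

* **Auto-exposure** multiplicatively scales exposure toward a target mean
  (default 87.5% of full scale, tolerance 2% of full scale) with a capped
  step, switching to bisection once the target is bracketed, subject to a
  saturated-pixel budget (default $10^{-4}$). Any monotone detector
  converges within 50 iterations or errors with its trace. Note the two
  constraints can genuinely conflict: for *pure Poisson* counts at 8-bit
  depth, a mean of 223 puts far more than $10^{-4}$ of pixels at 255, so
  the budget is only attainable there for detectors with sub-Poisson
  noise or at deeper bit depths; the convergence tests run at 12 bits.
* **Flat-field RMSD** is the per-channel root-mean-square deviation about
  the channel mean — zero iff the field is constant, invariant to where
  the pattern sits.
* **Knife-edge MTF** follows the slanted-edge procedure: per-row subpixel
  edge localization by derivative centroid, straight-line fit for the
  edge angle, projection of all pixels onto the edge normal, averaging in
  0.25-pixel bins (empty bins filled by linear interpolation — a
  perfectly vertical edge only populates integer offsets),
  differentiation to the line-spread function, a Hann taper centered on
  the LSF peak to suppress truncation leakage, then FFT magnitude
  normalized to 1 at DC. The estimator is validated against closed forms
  rather than any particular instrument: a Gaussian-blurred edge must
  reproduce $\exp(-2\pi^2\sigma^2 f^2)$ within 0.02 up to 0.25
  cycles/pixel, and an ideal step must stay above the 1-pixel-aperture
  sinc envelope. Slanting the edge a few degrees is recommended in
  practice (and is what the invariance tests do at higher cutoffs): a
  perfectly vertical edge limits the effective ESF sampling to the pixel
  pitch, which biases high-frequency contrast slightly low.
* **Resolution** is defined as one full cycle at the frequency where the
  MTF first crosses 3% contrast, $\text{res} = \text{pitch}/f_c$, with
  the crossing found by linear interpolation. Other conventions (half a
  cycle, different cutoffs) differ by fixed factors; this one is
  documented and oracle-tested, and agreement with any instrument's
  quoted number depends on matching conventions.

## Problem sizes used in validation

The shipped tests and the acceptance script size their simulations for
statistical adequacy at interactive runtimes: calibration phantoms are
72×72–96×96 with ≥500 masked pixels per chromogen (the median of ≥500
noisy pixels determines coefficients to well under 0.02), the standard
noisy 4-plex phantom is 256×256 with 200 cells (≈10⁴ stained pixels per
chromogen, so stained-region medians are stable to ±1%), and MTF targets
are 128×32–64. Larger fields change none of the statistics materially,
only their standard errors.
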