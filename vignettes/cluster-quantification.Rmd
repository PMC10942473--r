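---
title: "Quantifying transcription-factor clusters as concentration sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcription-factor clusters as concentration sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(clustersense)
```

## The scientific problem

Morphogen transcription factors such as Bicoid (Bcd) form an exponential
concentration gradient along the anterior-posterior (AP) axis of the early
fly embryo, and nuclei read this gradient precisely enough to resolve
neighbouring positions. Inside nuclei, however, the factor is not uniformly
distributed: it accumulates in transient sub-micron clusters. The question
this package addresses is whether the measurable properties of those
clusters — their intensity, size and frequency — themselves preserve the
positional information of the gradient, and whether a cluster, read as a
concentration sensor, outperforms a single enhancer binding site.

`clustersense` implements the full quantitative chain: a seeded
synthetic-embryo image generator with known ground truth; pixel
autocorrelation and FFT pair-correlation statistics; iterative local-maxima
detection with persistence (dwell-time) statistics; morphological nucleus
segmentation; 3D cluster detection with per-cluster 2D Gaussian fitting;
gradient binning with bootstrap errors, decay constants and
positional-error propagation; transcription-hotspot colocalization; and the
Berg–Purcell-style sensing-time model.

## The synthetic embryo and what it emulates

No raw image data accompany the measurements this package models, so every
stage is driven by `generate_nucleus_stack()`, `generate_embryo_field()`,
`generate_timelapse()`, `generate_two_channel()`, `generate_point_pattern()`
and `generate_bead_field()`. The generators are pure functions of
`(parameters, seed)`; sub-draws use one RNG stream per call, split from the
seed by a fixed affine hash, so results are bit-reproducible.

The calibrated defaults (see `preset_bcd()`) encode the statistical
structure the analysis assumes:

* nuclear mean intensity `Inuc = I0 exp(-x/lambda)` with `lambda = 0.23 L`
  and 14% multiplicative nucleus-to-nucleus noise;
* a per-nucleus cluster census linear in `Inuc` (~55 clusters in anterior
  nuclei, dropping roughly two-fold across the anterior 60%);
* apparent cluster sizes `d = sqrt(sigma1^2 + sigma2^2) ~ N(400, 140) nm`,
  truncated at the 150 nm candidate cutoff, drawn independently of
  amplitude;
* amplitude ratios `Ia/Ibg ~ N(2.2, 0.8)`, with `Ibg` the local diffuse
  level at the cluster position;
* telegraph blinking with mean dwells `Ton = 2.4 s`, `Toff = 1.6 s`;
* one transcription hotspot per nucleus in a second channel, with a
  configurable fraction of nuclei whose nearest cluster lies within the
  accumulation radius `r0 = 0.44 um`;
* a Gaussian PSF whose lateral sigma (169 nm) is calibrated so that the
  package's own pixel-correlation pipeline applied to purely diffuse
  nuclei returns the 0.20 um diffraction-limited reference length. This is
  an *effective* PSF of processed images, which are smoother than the raw
  optical PSF; the axial sigma is 2.5x the lateral one, matching the
  >500 nm axial vs ~200 nm lateral widths of high-NA confocal imaging.

Three generator choices deserve explanation because the design was open:

* **Sizes are apparent sizes.** The size histogram being emulated is a
  measured histogram, so the generator draws the *apparent* (image-plane)
  effective diameter and renders each cluster with exactly those in-plane
  Gaussian widths. A perfect detector therefore recovers the configured
  distribution by construction, and the detection/fitting stages can be
  audited for bias against it.
* **Axial extent of a cluster.** Clusters are modelled as isotropic
  objects: the apparent axial sigma is
  `sqrt(sigma_intrinsic^2 + psf_axial^2)` with the intrinsic size obtained
  by deconvolving the lateral PSF from the apparent lateral width. Scaling
  the apparent lateral width by the PSF anisotropy instead would balloon
  the axial extent of above-PSF objects (~730 nm instead of ~470 nm) and
  overstate how much neighbouring clusters contaminate each fitting plane.
* **Hard-core placement.** Cluster centres keep a minimum 3D separation
  (0.45 um by default): clusters occupy distinct chromatin loci and do not
  interpenetrate. Without a hard core, chance co-axial clumps of planted
  Gaussians merge into blobs whose fits pin at the width bound — a
  morphology real size histograms do not show.

A diffuse-pool fluctuation field (PSF-correlated, 10% of the nuclear mean)
models the ~90% of molecules outside clusters. At this level,
control nuclei without clusters look homogeneous — their intensity maxima
are found by the 2D maxima detector but rejected by the 3D 18-voxel size
rule — while the field still dominates the pixel-correlation signal that
the correlation-length measurement relies on. Shot noise is Poisson on
photon counts plus Gaussian read noise; the audit trail for every planted
object (position, widths, amplitude, blink trace, coupling label) is
returned as ground truth.

What the generator deliberately does *not* emulate: optical physics beyond
a Gaussian PSF, detector artefacts of Airyscan reconstruction,
chromatin-motion blur, and any correlation between cluster size and
nuclear intensity (the analysis tests for exactly this independence, so it
is planted as exactly independent). Passing tests on synthetic data
therefore demonstrate correctness of the *measurement chain*, not of the
biological model; on real images, segmentation quality and the effective
PSF would need recalibration.

## Correlation statistics

`pixel_autocorrelation()` computes the biased (1/T-normalised) lagged
autocorrelation of pixel rows and columns restricted to a mask, averaging
per axis and then combining; each maximal contiguous in-mask run of at
least 8 pixels is one series. `fit_correlation_length()` fits
`a + b exp(-c x)` and reports `lambda = x0 + log(2)/c`, with `x0` the
smallest lag included. The wrapper `measure_correlation_length()` excludes
the zero lag by default: the lag-0 point carries the full uncorrelated
shot/read-noise variance and would otherwise steepen the fitted decay. The
correlation length is invariant under affine intensity rescaling.

`pair_correlation_map()` estimates `g(r)` of a 2D point pattern by FFT:
the point raster's autocorrelation divided by the window's autocorrelation
(edge correction) and by the squared density, self-pairs removed, radially
averaged in 1-pixel bins. The window raster uses fractional pixel coverage
(4x4 subsampling) so boundary pixels enter the edge correction with their
true area; with a binary raster the estimator is biased low by several
percent on disc windows. `fit_pair_correlation()` fits
`g(r) = rho' exp(-(r/sigma)^2) + 1`; the confinement radius `xi_pair` is
reported as the fitted `sigma` (the half-width definition was the open
choice; the full fit is always returned alongside). For a Gaussian scatter
of per-axis standard deviation `s`, the planted pair-correlation width is
exactly `2s`, which fixes the confinement preset (`s = 185 nm` for a
370 nm width).

## Maxima detection and persistence

`detect_local_maxima_2d()` follows the two-step scheme: Otsu thresholding
of nuclear pixels, then iterated local thresholding with a 25x25 moving
mean + moving standard deviation (computed over all Otsu-valid nuclear
pixels — zeroed pixels count, otherwise the threshold self-escalates and
only the brightest spot survives), each iterate binarised and compared to
the first by SSIM. The stopping rule operationalises "plateau" as a change
below 1e-3 for three consecutive iterations, capped at `m_max = 20`. On
synthetic nuclei the plateau typically occurs after 4–16 iterations
depending on the noise realisation; where it lands depends on the noise
structure of the images, so the iteration count itself is not a calibrated
quantity.

`persistence_stats()` turns presence traces (a maximum within a radius of
a confinement centre, per frame) into mean run lengths. One subtlety
matters at the ~0.5 s frame interval: off-periods shorter than a frame are
invisible, so adjacent on-runs merge, and the estimator measures the
*sampled-chain* (effective) dwells rather than the underlying continuous
ones. The sampled telegraph is a two-state Markov chain with geometric run
lengths, giving closed forms
`ton_eff = dt / ((1-p)(1-e^{-lambda dt}))` (and symmetrically for
`toff_eff`) with `p = ton/(ton+toff)`; the run-length estimator lands
within a few percent of these. The detection probability `ton/(ton+toff)`
is unaffected by the merging, which is why the dwell-time ratio and the
raw occupancy agree (~0.6) even when individual dwells are inflated.
First and last runs of every trace are dropped as censored.

## Nucleus segmentation

`segment_filled_nuclei()` implements the morphological chain for bright
nuclei (contrast stretch, median + Gaussian smoothing, erosion,
reconstruction, dilation, complement, blur, closing, erosion, Otsu
binarisation); `segment_hollow_nuclei()` the dark-nucleus variant
(bright-background binarisation, inversion, box-kernel majority filter,
opening, hole filling). Structuring elements are cuboids of roughly one
tenth the nucleus diameter in xy and one z-slice. Touching nuclei are
split by a watershed on the 2D distance map of the xy occupancy
projection, with labels extended along z — surface-layer nuclei form
non-overlapping xy columns, so a 2D split is sufficient and far cheaper
than a full 3D watershed. `match_nuclei()` greedily pairs the two
labelings under the half-nuclear-length rule; `nucleus_position()` maps
stage-coordinate centroids to fractional AP position by projecting onto
the anterior-posterior axis (exactly invariant under rigid motions of the
stage frame, and symmetric about the axis).

## Cluster detection and fitting

`detect_clusters_3d()` applies per-plane disk top-hat filtering, selects
the top 1-percentile of in-nucleus voxels of the transformed image,
separates joined spots by a seeded split on raw-intensity local maxima,
and enforces the size rule: at least 3x3 pixels laterally, 2 z-slices
axially, 18 voxels of support (an effective minimum diameter of
`(6/pi * 18)^(1/3) = 3.25` pixels). Because the voxel budget of a
percentile threshold is fixed, detection preferentially returns the
brighter part of the amplitude distribution when nuclei carry many
clusters; since size and amplitude are independent, size statistics are
unaffected, but the population mean of fitted amplitude ratios is
selection-biased upward under full crowding — a known limitation shared by
any per-nucleus percentile rule.

`fit_cluster_2d()` performs the Levenberg–Marquardt fit of the rotated 2D
Gaussian plus constant background in the centroid z-plane, initialised
from the centre pixel, nuclear mean, `sigma = w/2` and `theta = 0`, with
`0 < theta < pi/4`. Because `theta` is degenerate at `sigma1 = sigma2`,
a second asymmetric mid-angle start is tried and the better optimum kept.
The width bound is `sigma <= w` (516 nm at the default window): a `w/2`
bound would cap the size measure at 365 nm and reject most of a 400 nm
population, which is inconsistent with the expected <2% discard rate.
Fits are discarded when they fail to converge, end pinned at a bound,
drift more than 4 px from their candidate, or collapse the background
below 10% of the nuclear mean.

Three crowded-field refinements keep the population size measure unbiased
at study-condition densities (~45 clusters per nucleus): candidate
fragments split by noise are re-merged and re-centred duplicates
deduplicated (keeping the best-centred fit); pixels near *other* detected
candidates are masked out of each window; and a second pass subtracts the
first-pass fits of neighbours (attenuated axially by the isotropic-cluster
model) before refitting. Fits are also restricted to in-nucleus pixels:
windows of peripheral clusters otherwise reach into the blurred rim and
bias the background estimate. The residual imperfections are a ~2%
upward size bias and a ~3–5% downward background bias (the constant-
background model under-reads a locally curved diffuse background); both
are documented by the round-trip tests.

Derived properties follow the closed forms: effective size
`d = sqrt(sigma1^2 + sigma2^2)` (reported directly; the multiplier between
this and other size conventions is configurable but defaults to 1),
amplification `Ia/Ibg`, and integrated intensity `Ic = 2 pi Ia sigma1
sigma2` — with the factor pi, the 2D-Gaussian volume above background; the
pi-less variant that sometimes appears in summaries is treated as a typo.

## Gradient precision and molecule budgets

`bin_and_bootstrap()` partitions per-nucleus records into 0.05-wide x/L
bins over the anterior analysis zone and reports bootstrap means and
standard deviations (resampling nuclei within bins; 1000 draws by
default, seeded). `fit_gradient()` obtains decay constants from log-linear
regression, `lambda = -1/slope`, `sigma_lambda = sigma_slope/slope^2`.
`positional_error()` propagates per-bin variability through the
exponential-gradient error formula `sigma_x/L = CV(x) * lambda`, which for
an exponential equals the general `delta_c |dc/dx|^{-1}` exactly.
`estimation_errors()` gives the closed-form uncertainties for
concentration and position readouts, validated against Monte-Carlo
propagation.

`molecules_from_flat()` converts a flat-expression calibration count into
the anterior gradient amplitude, `N0 = N0flat L / lambda` (8000 and 0.2 L
give 40000); the exact integral form `N0flat (L/lambda)/(1 - e^{-L/lambda})`
is returned as a diagnostic. `molecule_budget()` chains nuclear density
(~600 molecules/um^3 for a 5 um nucleus), in-cluster concentration
(amplification x density), cluster volume and molecules per cluster; the
unrounded chain value is returned (the chain with rounded intermediates —
1320 x 0.03 — under-reads the unrounded product by ~10%, so consumers
should round only at presentation time). The clustered fraction of nuclear
molecules lands in the 5–10% band at the calibrated defaults.

## Colocalization

`detect_hotspots()` enhances the mRNA channel by a difference-of-Gaussians
reweighted by the raw image (an elementwise product — a literal
convolution of the DoG response *with the raw image* would blur the very
spots being sought), then keeps voxels above the per-nucleus
`mean + 4 sd` rule and masks of at least 18 voxels.
`radial_profile()` ring-averages TF intensity in 0.1 um annuli on the
hotspot's z-plane using in-nucleus pixels only; `fit_accumulation()` fits
the double Gaussian and defines the accumulation radius `r0` as the FWHM
of the central component (`2 a0 sqrt(ln 2)`); a configuration switch
doubles it for compatibility with the alternative "twice the FWHM"
convention seen in some figure captions. `coupling_fraction()` evaluates
the empirical CDF of anisotropy-corrected nearest-cluster distances at
`r0`; `coupling_boundary_alt()` fits the distance histogram with a double
Gaussian and takes the crossing between the component means as the
boundary `r0'`, falling back (with a warning) to the threshold method when
the histogram is not bimodal enough for a crossing to exist.

## The sensing model

`t_cluster()` and `t_site()` implement the concentration-sensing times
`T_clust = 6/(D d c_clust) (dN/N)^{-2}` and
`T_site = 1/(D a c_nuc) (dN/N)^{-2}`; their ratio
`d/(6a) * c_clust/c_nuc` (`sensing_ratio()`) is independent of the
diffusion constant and the accuracy. The prefactor of the cluster time is
the reading consistent with this ratio; the alternative reading (6 in the
denominator) is documented here but not exported, because it contradicts
the printed ratio formula. The diffusion constant is a required user
input — no default is assumed, as no value is pinned by the calibration.
At the quoted anterior values (d = 0.4 um, a = 3.4 nm, 2.2-fold
amplification) the point-estimate ratio is ~43; position-averaged
estimates over measured bin-wise diameters and amplifications
(`ratio_profile()`) are smaller and land in the 30–50 band.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale: single
nuclei are 140x140x30 voxel stacks at the native 43x43x200 nm voxel size,
segmentation tests use a coarser 200 nm lateral voxel so that a 20-nucleus
field fits in a 179x132x18 stack, gradient statistics use 150–4000
truth-level nuclei with 200–1000 bootstrap draws, and the size-recovery
analysis plants ~2000 clusters across ~60 nuclei. These sizes were chosen
so that every stage's estimator noise is several times smaller than the
tolerances being asserted. Nonlinear fits use Levenberg–Marquardt
(`minpack.lm`) with bounded parameters, 200 iterations, and explicit
failure flagging — no silent defaults; ties in the Gaussian orientation at
`sigma1 = sigma2` are broken by the second start; degenerate inputs
(zero-variance regions, empty masks, unimodal distance histograms,
all-absent presence traces) return flagged results or typed errors rather
than numbers.

## Known limitations

* The percentile-budget detector under-detects dim clusters in crowded
  nuclei; amplitude-ratio population means from full-crowding runs are
  selection-biased high even though size statistics are not.
* The constant-background Gaussian fit under-reads locally curved diffuse
  backgrounds by a few percent.
* Run-length dwell times at ~0.5 s frames are effective (sampled-chain)
  quantities; converting them to underlying rates requires the Markov
  inversion given above.
* The generator's diffuse-pool fluctuation amplitude and the cytoplasmic
  contrast are plausibility choices, not calibrated measurements; analyses
  that depend on them (false-positive rates, segmentation contrast) should
  be re-examined before applying the pipeline to real images.
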