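# clustersense

Quantifying transcription-factor clusters as concentration sensors in the
early embryo.

## The problem

Morphogen transcription factors such as Bicoid form an exponential
anterior-posterior (AP) concentration gradient, `c(x) = c0 exp(-x/λ)`, that
nuclei read with near single-cell precision. Inside each nucleus the factor
is heterogeneously distributed, accumulating in transient sub-micron
clusters. `clustersense` is for quantitative microscopists and biophysicists
who want to ask, on live-imaging data or on fully controlled synthetic data:

* Do cluster properties — integrated intensity `Ic = 2π Ia σ1 σ2`, apparent
  size `d = sqrt(σ1² + σ2²)`, amplitude ratio `Ia/Ibg`, count — preserve the
  positional information of the gradient? The positional error of a readout
  with per-position variability `CV(x)` is `σx/L = CV(x)·λ`.
* Are clusters physically coupled to the transcription sites of target
  genes (nearest-cluster distance below the accumulation radius `r0`)?
* Is a cluster a faster concentration sensor than a single binding site?
  The Berg–Purcell-style times are `T_clust = 6/(D·d·c_clust)·(δN/N)⁻²` and
  `T_site = 1/(D·a·c_nuc)·(δN/N)⁻²`, with ratio `d/(6a)·c_clust/c_nuc`.

Because no raw embryo images ship with the package, a seeded
synthetic-embryo generator with full ground truth drives every analysis
stage: nucleus segmentation, iterative local-maxima detection with
dwell-time statistics, FFT pair-correlation of maxima maps, 3D cluster
detection with per-cluster 2D Gaussian fitting, gradient binning with
bootstrap errors, hotspot colocalization, and the sensing-time model.

## Worked example

Simulate a calibrated cluster-intensity gradient, bin it, extract the decay
constant and the positional error, and price the cluster as a sensor:

```r
library(clustersense)

preset <- preset_bcd()
g <- simulate_nuclear_gradient(300, c(0.1, 0.65),
                               lambda = preset$gradient$Ic$lambda,
                               cv = preset$gradient$Ic$cv,
                               amplitude = preset$gradient$Ic$amplitude,
                               seed = 1, quantity = "Ic")
tab <- bin_and_bootstrap(g, "Ic", bin_edges = seq(0.1, 0.65, 0.05), seed = 1)
fit <- fit_gradient(tab, "Ic")
fit
#> <gradient_fit> slope = -3.945 +/- 0.08, R^2 = 0.996, lambda = 0.2535 +/- 0.0051 L

pe <- positional_error(tab, fit$lambda, quantity = "Ic")
round(100 * pe$mean, 2)   # positional error, % of embryo length
#> [1] 5.96

budget <- molecule_budget(molecules_from_flat(8000, 0.2)$n0,
                          nucleus_diameter_um = 5, amplification = 2.2,
                          cluster_diameter_um = 0.4, clusters_per_nucleus = 55)
budget
#> <molecule_budget>
#>   nuclear density: 611 molecules/um^3
#>   in-cluster concentration: 1345 molecules/um^3
#>   cluster volume: 0.034 um^3
#>   molecules per cluster: 45.1
#>   clustered fraction of nuclear molecules: 6.2%

p <- sensing_params(D = 4, d_um = 0.4,
                    c_clust = budget$cluster_concentration,
                    c_nuc = budget$nuclear_density)
round(sensing_ratio(p), 1)  # cluster reads the gradient this much faster
#> [1] 43.1
```

Reading the output: the simulated per-nucleus mean cluster intensity decays
with `λ ≈ 0.25 L`; its ~22% nucleus-to-nucleus variability propagates to a
positional error of ~6% of embryo length (about three cell diameters).
Converting a flat-expression calibration of 8000 molecules per nucleus into
the gradient amplitude gives 40000 molecules in an anterior nucleus, ~600
molecules/µm³ of nucleoplasm, ~1350 molecules/µm³ inside a 2.2-fold
amplified cluster, and a cluster that senses the nuclear concentration ~43x
faster than a single 3.4 nm binding site.

Image-level analyses follow the same pattern — generate, detect, fit:

```r
sim <- embryo_sim_params(); acq <- acquisition_params()
nuc <- generate_nucleus_stack(sim, acq, x_over_L = 0.15, seed = 1)
clusters <- quantify_clusters(nuc$stack, nucleus_mask = with(nuc$truth$nuclei,
  clustersense:::sphere_mask(dim(nuc$stack$channels$tf),
                             c(cx_px, cy_px, cz_px), r_xy_px, r_z_px)))
dplyr::glimpse(clusters)
```

`run_pipeline(pipeline_config(seed = 1))` chains all stages and returns a
report bundle; with `out_dir` set it also writes per-stage CSV/JSON
artifacts and a provenance log.

## Testing

```r
devtools::test()          # or
testthat::test_dir("tests/testthat")
```

The suite builds all fixtures programmatically from the seeded generators;
oracle checks include a brute-force pair-distance estimator, closed-form
Gaussian autocorrelations, Monte-Carlo error propagation, and the sampled
two-state Markov chain behind the dwell-time statistics.

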