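# Shared fixtures: small calibrated parameter sets and independent oracles.

acq_default <- function(...) acquisition_params(...)

# coarse-voxel acquisition for fast segmentation-scale tests
acq_coarse <- function() {
  acquisition_params(voxel_xy = 200, voxel_z = 400,
                     psf_sigma_lateral = 300, psf_sigma_axial = 600)
}

sphere_mask_of <- function(gen) {
  tr <- gen$truth$nuclei
  dims <- dim(gen$stack$channels[[1]])
  if (length(dims) == 2L) {
    clustersense:::sphere_mask(dims, c(tr$cx_px, tr$cy_px), tr$r_xy_px)
  } else {
    clustersense:::sphere_mask(dims, c(tr$cx_px, tr$cy_px, tr$cz_px),
                               tr$r_xy_px, tr$r_z_px)
  }
}

# Independent O(n^2) pair-correlation oracle: pair-distance histogram with a
# Monte-Carlo edge correction from a dense uniform reference pattern.
brute_force_pair_correlation <- function(points, window, dr = 0.1,
                                         r_max = NULL, n_ref = 4000,
                                         ref_seed = 999) {
  pts <- as.matrix(points[, c("x_um", "y_um")])
  n <- nrow(pts)
  r_max <- r_max %||% (clustersense:::window_scale(window) / 4)
  breaks <- seq(0, r_max, by = dr)
  d <- as.numeric(dist(pts))
  h_data <- hist(d[d < r_max], breaks = breaks, plot = FALSE)$counts
  ref <- withr::with_seed(ref_seed, clustersense:::sample_window(n_ref, window))
  dref <- as.numeric(dist(as.matrix(ref)))
  h_ref <- hist(dref[dref < r_max], breaks = breaks, plot = FALSE)$counts
  g <- (h_data / (n * (n - 1))) / (h_ref / (n_ref * (n_ref - 1)))
  tibble::tibble(r_um = breaks[-1] - dr / 2, g = g)
}

# Closed-form autocorrelation scale of Gaussian-blurred white noise:
# c(k) = exp(-k^2 / (4 sigma^2)).
gaussian_noise_autocorr <- function(k, sigma_px) exp(-k^2 / (4 * sigma_px^2))

# Effective (sampled-chain) telegraph dwell means at frame interval dt:
# the sampled process is a 2-state Markov chain with geometric run lengths.
effective_dwells <- function(ton, toff, dt) {
  p_on <- ton / (ton + toff)
  lam <- 1 / ton + 1 / toff
  decay <- 1 - exp(-lam * dt)
  c(ton = dt / ((1 - p_on) * decay), toff = dt / (p_on * decay))
}
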