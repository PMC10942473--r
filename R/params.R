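#' Acquisition parameters for synthetic imaging
#'
#' Describes the virtual microscope used by the synthetic-embryo generators:
#' voxel geometry, frame timing, the Gaussian point-spread function (PSF) and
#' the noise model. Defaults correspond to fast-Airyscan live imaging of the
#' early fly embryo: 43 x 43 x 200 nm voxels and ~497 ms frames.
#'
#' @param voxel_xy Lateral voxel size (nm). Default 43.
#' @param voxel_z Axial voxel size (nm). Default 200.
#' @param frame_time Frame interval for time-lapse imaging (s). Default 0.497.
#' @param psf_sigma_lateral Lateral Gaussian PSF sigma (nm). The default is
#'   calibrated so that the pixel-correlation length of PSF-blurred
#'   homogeneous signal (the diffraction-limited reference measured from
#'   sub-resolution beads) is 0.20 um.
#' @param psf_sigma_axial Axial Gaussian PSF sigma (nm); the axial PSF of a
#'   high-NA confocal is roughly 2.5x wider than lateral.
#' @param noise_read_sd Gaussian read-noise standard deviation (intensity
#'   units). Default 1.
#' @param photon_scale Intensity units per detected photon; shot noise is
#'   Poisson on `intensity / photon_scale`. Default 1.
#'
#' @return An object of class `acquisition_params` (a validated list).
#' @export
#' @examples
#' acq <- acquisition_params()
#' acq$voxel_xy
acquisition_params <- function(voxel_xy = 43,
                               voxel_z = 200,
                               frame_time = 0.497,
                               psf_sigma_lateral = 169,
                               psf_sigma_axial = 422,
                               noise_read_sd = 1,
                               photon_scale = 1) {
  assert_scalar_pos(voxel_xy, "voxel_xy")
  assert_scalar_pos(voxel_z, "voxel_z")
  assert_scalar_pos(frame_time, "frame_time")
  assert_scalar_pos(psf_sigma_lateral, "psf_sigma_lateral")
  assert_scalar_pos(psf_sigma_axial, "psf_sigma_axial")
  assert_scalar_pos(photon_scale, "photon_scale")
  if (!is.numeric(noise_read_sd) || noise_read_sd < 0) {
    abort("`noise_read_sd` must be >= 0")
  }
  if (voxel_z < voxel_xy) {
    abort("`voxel_z` must be >= `voxel_xy` (axial sampling is the coarse axis)")
  }
  structure(
    list(
      voxel_xy = voxel_xy, voxel_z = voxel_z, frame_time = frame_time,
      psf_sigma_lateral = psf_sigma_lateral,
      psf_sigma_axial = psf_sigma_axial,
      noise_read_sd = noise_read_sd, photon_scale = photon_scale
    ),
    class = "acquisition_params"
  )
}

#' Embryo simulation parameters
#'
#' Ground-truth statistical structure of the synthetic embryo: the exponential
#' anterior-posterior (AP) nuclear-intensity gradient, the per-nucleus cluster
#' census and its linear dependence on nuclear intensity, the apparent-size
#' and amplitude-ratio distributions of clusters, telegraph blinking dwell
#' times, and hotspot-coupling geometry.
#'
#' Cluster sizes are *apparent* (image-plane) effective diameters
#' d = sqrt(sigma1^2 + sigma2^2): the generator draws apparent d from a
#' truncated normal (floor `d_floor`) and renders each cluster with exactly
#' those in-plane widths, so the size distribution seen by a perfect
#' detector matches the configured one by construction.
#'
#' @param embryo_length_um Embryo length L (um). Default 500.
#' @param lambda_gradient Exponential decay constant of the nuclear intensity
#'   gradient, as a fraction of L. Default 0.23.
#' @param I0_anterior Nuclear mean intensity extrapolated to x/L = 0. Default 200.
#' @param nucleus_diameter_um Nucleus diameter (um). Default 5.
#' @param cluster_count_intercept,cluster_count_slope Mean cluster count per
#'   nucleus is `intercept + slope * Inuc` (a linear census model). Defaults
#'   give ~55 clusters in anterior nuclei falling to ~27 at x/L = 0.65.
#' @param amp_ratio_mean,amp_ratio_sd Mean and sd of the cluster amplitude
#'   ratio Ia/Ibg (truncated > 0.1). Defaults 2.2 and 0.8.
#' @param d_mean,d_sd Mean and sd of the apparent cluster size d (nm).
#'   Defaults 400 and 140.
#' @param d_floor Candidate-size cutoff (nm) applied as the truncation floor
#'   of the size distribution. Default 150.
#' @param sigma_ratio Fixed anisotropy sigma1/sigma2 of planted clusters.
#'   Default 1 (circular).
#' @param cluster_min_sep_um Hard-core minimum distance between planted
#'   cluster centres (um); clusters occupy distinct chromatin loci and do
#'   not interpenetrate. Default 0.45.
#' @param ton,toff Mean telegraph dwell times (s) of the cluster "on" and
#'   "off" states. Defaults 2.4 and 1.6.
#' @param coupling_fraction Probability that the cluster nearest to a
#'   transcription hotspot is planted within the accumulation radius.
#'   Default 0.57.
#' @param accumulation_radius_um Accumulation radius r0 (um) used by the
#'   two-channel generator. Default 0.44.
#' @param noise_cv Multiplicative nucleus-to-nucleus intensity noise
#'   (coefficient of variation). Default 0.14.
#' @param fluct_cv Amplitude (as a fraction of the nuclear mean) of the
#'   PSF-correlated intranuclear fluctuation field that models freely
#'   diffusing, unclustered fluorophore. Default 0.10.
#' @param cyto_frac Cytoplasmic intensity as a fraction of the nuclear mean
#'   in "filled"-nucleus renderings. Default 0.3.
#'
#' @return An object of class `embryo_sim_params`.
#' @export
embryo_sim_params <- function(embryo_length_um = 500,
                              lambda_gradient = 0.23,
                              I0_anterior = 200,
                              nucleus_diameter_um = 5,
                              cluster_count_intercept = 24,
                              cluster_count_slope = 0.24,
                              amp_ratio_mean = 2.2,
                              amp_ratio_sd = 0.8,
                              d_mean = 400,
                              d_sd = 140,
                              d_floor = 150,
                              sigma_ratio = 1,
                              cluster_min_sep_um = 0.45,
                              ton = 2.4,
                              toff = 1.6,
                              coupling_fraction = 0.57,
                              accumulation_radius_um = 0.44,
                              noise_cv = 0.14,
                              fluct_cv = 0.10,
                              cyto_frac = 0.3) {
  assert_scalar_pos(embryo_length_um, "embryo_length_um")
  if (lambda_gradient <= 0 || lambda_gradient >= 1) {
    abort("`lambda_gradient` must lie in (0, 1) (a fraction of embryo length)")
  }
  assert_scalar_pos(I0_anterior, "I0_anterior")
  assert_scalar_pos(nucleus_diameter_um, "nucleus_diameter_um")
  assert_scalar_pos(amp_ratio_mean, "amp_ratio_mean")
  assert_scalar_pos(d_mean, "d_mean")
  assert_scalar_pos(d_sd, "d_sd")
  # Inf is a valid dwell mean (a state that never exits)
  if (!is.numeric(ton) || length(ton) != 1L || ton <= 0 || is.na(ton)) {
    abort("`ton` must be a single positive number (Inf allowed)")
  }
  if (!is.numeric(toff) || length(toff) != 1L || toff <= 0 || is.na(toff)) {
    abort("`toff` must be a single positive number (Inf allowed)")
  }
  assert_scalar_pos(sigma_ratio, "sigma_ratio")
  if (coupling_fraction < 0 || coupling_fraction > 1) {
    abort("`coupling_fraction` must lie in [0, 1]")
  }
  if (noise_cv < 0) abort("`noise_cv` must be >= 0")
  structure(
    list(
      embryo_length_um = embryo_length_um,
      lambda_gradient = lambda_gradient,
      I0_anterior = I0_anterior,
      nucleus_diameter_um = nucleus_diameter_um,
      cluster_count_intercept = cluster_count_intercept,
      cluster_count_slope = cluster_count_slope,
      amp_ratio_mean = amp_ratio_mean,
      amp_ratio_sd = amp_ratio_sd,
      d_mean = d_mean, d_sd = d_sd, d_floor = d_floor,
      sigma_ratio = sigma_ratio,
      cluster_min_sep_um = cluster_min_sep_um,
      ton = ton, toff = toff,
      coupling_fraction = coupling_fraction,
      accumulation_radius_um = accumulation_radius_um,
      noise_cv = noise_cv,
      fluct_cv = fluct_cv,
      cyto_frac = cyto_frac
    ),
    class = "embryo_sim_params"
  )
}

#' Calibrated Bcd-GFP simulation presets
#'
#' Parameter sets matching the population statistics measured for Bcd-GFP in
#' NC14 fly embryos: apparent cluster size 400 +/- 140 nm, amplitude ratio
#' 2.2 +/- 0.8, nuclear-gradient decay constant 0.23 L with 14% nuclear
#' variability, cluster-intensity gradient decay constant 0.26 L with 22%
#' variability, telegraph dwell times 2.4 s / 1.6 s, confinement-area scatter
#' planting a 370 nm pair-correlation width, and a PSF preset whose
#' pixel-correlation length is the 0.20 um diffraction-limited reference.
#'
#' @return A list with elements `sim` ([embryo_sim_params()]), `acq`
#'   ([acquisition_params()]), and `gradient`, a list of per-quantity
#'   exponential presets (`lambda`, fraction of L; `cv`; `amplitude`), with
#'   entries `Inuc` and `Ic`, plus `confinement`, a list with the projected
#'   maxima-map presets (`sigma_scatter_um`, `rho_prime`, `occupancy`,
#'   `n_frames`).
#' @export
#' @examples
#' p <- preset_bcd()
#' p$gradient$Ic$lambda
preset_bcd <- function() {
  list(
    sim = embryo_sim_params(),
    acq = acquisition_params(),
    gradient = list(
      Inuc = list(lambda = 0.23, cv = 0.14, amplitude = 200),
      Ic = list(lambda = 0.26, cv = 0.22, amplitude = 60)
    ),
    confinement = list(
      # Eq.-4-fitted width of a Gaussian scatter with per-axis sd s is 2s,
      # so a 0.185 um scatter plants a 0.37 um pair-correlation width.
      sigma_scatter_um = 0.185,
      rho_prime = 8,
      occupancy = 2.4 / (2.4 + 1.6),
      n_frames = 60,
      n_clumps = 4
    )
  )
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat("<acquisition_params>\n")
  cat(sprintf("  voxel: %g x %g x %g nm, frame %g s\n",
              x$voxel_xy, x$voxel_xy, x$voxel_z, x$frame_time))
  cat(sprintf("  PSF sigma: %g (lateral) / %g (axial) nm\n",
              x$psf_sigma_lateral, x$psf_sigma_axial))
  cat(sprintf("  noise: read sd %g, photon scale %g\n",
              x$noise_read_sd, x$photon_scale))
  invisible(x)
}

#' @export
print.embryo_sim_params <- function(x, ...) {
  cat("<embryo_sim_params>\n")
  cat(sprintf("  gradient: I0 %g, lambda %g L, nucleus-to-nucleus CV %g\n",
              x$I0_anterior, x$lambda_gradient, x$noise_cv))
  cat(sprintf("  clusters: d %g +/- %g nm (floor %g), Ia/Ibg %g +/- %g\n",
              x$d_mean, x$d_sd, x$d_floor, x$amp_ratio_mean, x$amp_ratio_sd))
  cat(sprintf("  census: %g + %g * Inuc per nucleus\n",
              x$cluster_count_intercept, x$cluster_count_slope))
  cat(sprintf("  dynamics: Ton %g s, Toff %g s\n", x$ton, x$toff))
  invisible(x)
}
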