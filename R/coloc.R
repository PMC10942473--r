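# Transcription-hotspot detection, radial TF accumulation profiles with the
# double-Gaussian model, and cluster-gene coupling fractions.

#' Detect transcription hotspots in an mRNA channel
#'
#' Difference-of-Gaussians spot enhancement on the raw voxels, elementwise
#' reweighting by the raw image, rescaling, then a per-nucleus intensity
#' threshold: voxels below `mu(Inuc) + 4 sigma(Inuc)` (nuclear-pixel mean
#' and sd of the mRNA channel) are discarded. Candidate masks smaller than
#' `min_vox` voxels are rejected; surviving masks yield intensity-weighted
#' centroids.
#'
#' @param stack An [image_stack()] or 3D array (mRNA channel).
#' @param nucleus_labels Integer label array (e.g. from
#'   [segment_hollow_nuclei()]) or logical mask for a single nucleus.
#' @param channel Channel to use when `stack` is an `image_stack`.
#' @param dog_sigmas Length-2 DoG sigmas in pixels. Default `c(1, 2)`.
#' @param min_vox Minimum voxel support. Default 18.
#' @param k_sigma Threshold multiplier. Default 4.
#' @return Tibble of hotspots: `nucleus`, centroid (`x_px`, `y_px`, `z_px`),
#'   `n_vox`, `intensity` (integrated raw intensity).
#' @export
detect_hotspots <- function(stack, nucleus_labels, channel = "mrna",
                            dog_sigmas = c(1, 2), min_vox = 18L, k_sigma = 4) {
  arr <- if (inherits(stack, "image_stack")) {
    ch <- if (channel %in% names(stack$channels)) channel else 1L
    stack$channels[[ch]]
  } else {
    stack
  }
  stopifnot(length(dim(arr)) == 3L)
  if (is.logical(nucleus_labels)) {
    labels <- array(0L, dim(arr))
    labels[nucleus_labels] <- 1L
  } else {
    labels <- nucleus_labels
  }
  g1 <- gauss_blur_3d(arr, dog_sigmas[1], dog_sigmas[1] / 2)
  g2 <- gauss_blur_3d(arr, dog_sigmas[2], dog_sigmas[2] / 2)
  dog <- pmax(g1 - g2, 0)
  enhanced <- rescale01(dog * arr)
  ids <- sort(unique(labels[labels > 0]))
  rows <- list()
  for (nuc in ids) {
    inn <- labels == nuc
    mu <- mean(arr[inn])
    sg <- sd(arr[inn])
    cand <- inn & arr >= mu + k_sigma * sg & enhanced > 0
    idx <- which(cand, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    comp <- label_sparse_voxels(idx, dim(arr))
    for (ci in unique(comp)) {
      vi <- idx[comp == ci, , drop = FALSE]
      if (nrow(vi) < min_vox) next
      w <- arr[vi]
      rows[[length(rows) + 1L]] <- tibble(
        nucleus = nuc,
        x_px = sum(vi[, 1] * w) / sum(w),
        y_px = sum(vi[, 2] * w) / sum(w),
        z_px = sum(vi[, 3] * w) / sum(w),
        n_vox = nrow(vi),
        intensity = sum(w)
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(nucleus = integer(0), x_px = numeric(0), y_px = numeric(0),
                  z_px = numeric(0), n_vox = integer(0), intensity = numeric(0)))
  }
  list_rbind(rows)
}

#' Radial TF intensity profile around a hotspot
#'
#' Ring-averaged TF-channel intensity in annuli of width `dr_um` on the
#' xy-plane through the hotspot centroid, restricted to in-nucleus pixels.
#' Profiles from several hotspots can be aggregated with
#' [aggregate_profiles()].
#'
#' @param tf_channel 2D matrix (the hotspot z-plane of the TF channel) or an
#'   [image_stack()]/3D array from which the plane at `hotspot$z_px` is taken.
#' @param hotspot One-row data frame with `x_px`, `y_px` (and `z_px` for 3D
#'   input).
#' @param r_max_um Profile extent. Default 1.5.
#' @param mask Logical matrix (or 3D array) of nuclear pixels; rings use
#'   in-mask pixels only.
#' @param pixel_nm Lateral pixel size (nm). Default 43.
#' @param dr_um Ring width (um). Default 0.1.
#' @return A `radial_profile` tibble: `r_um` (ring midpoint), `Ir`, `n_px`.
#' @export
radial_profile <- function(tf_channel, hotspot, r_max_um = 1.5, mask = NULL,
                           pixel_nm = 43, dr_um = 0.1) {
  if (inherits(tf_channel, "image_stack")) {
    pixel_nm <- tf_channel$acq$voxel_xy
    tf_channel <- tf_channel$channels[[1]]
  }
  if (length(dim(tf_channel)) == 3L) {
    zi <- max(1L, min(dim(tf_channel)[3], round(hotspot$z_px)))
    plane <- tf_channel[, , zi]
    msk <- if (!is.null(mask) && length(dim(mask)) == 3L) mask[, , zi] else mask
  } else {
    plane <- tf_channel
    msk <- mask
  }
  if (is.null(msk)) msk <- array(TRUE, dim(plane))
  vx_um <- pixel_nm / 1000
  dx <- (seq_len(nrow(plane)) - hotspot$x_px) * vx_um
  dy <- (seq_len(ncol(plane)) - hotspot$y_px) * vx_um
  r <- sqrt(outer(dx^2, dy^2, `+`))
  ring <- floor(r / dr_um)
  keep <- msk & r <= r_max_um
  if (!any(keep)) abort("no in-mask pixels within `r_max_um` of the hotspot")
  Ir <- tapply(plane[keep], ring[keep], mean)
  n_px <- tapply(rep(1, sum(keep)), ring[keep], sum)
  out <- tibble(
    r_um = (as.numeric(names(Ir)) + 0.5) * dr_um,
    Ir = as.numeric(Ir),
    n_px = as.numeric(n_px)
  ) |> arrange(.data$r_um)
  structure(out, class = c("radial_profile", class(out)), dr_um = dr_um)
}

#' Aggregate radial profiles across hotspots
#'
#' Pixel-weighted mean of ring intensities across a list of
#' [radial_profile()] tibbles (rings matched by radius).
#'
#' @param profiles List of `radial_profile` tibbles.
#' @return A single `radial_profile` tibble.
#' @export
aggregate_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  all <- list_rbind(map(profiles, as_tibble))
  out <- all |>
    group_by(.data$r_um) |>
    summarise(Ir = sum(.data$Ir * .data$n_px) / sum(.data$n_px),
              n_px = sum(.data$n_px), .groups = "drop") |>
    arrange(.data$r_um)
  structure(out, class = c("radial_profile", class(out)),
            dr_um = attr(profiles[[1]], "dr_um"))
}

#' Fit the double-Gaussian accumulation model to a radial profile
#'
#' Least-squares fit of
#' `f(x) = k0 exp(-((x - x0) / a0)^2) + k1 exp(-((x - x1) / a1)^2)`.
#' The accumulation radius `r0` is the full width at half maximum of the
#' first (central) component, `2 a0 sqrt(ln 2)`; a config switch doubles it
#' for compatibility with the alternative "twice the FWHM" convention.
#'
#' @param profile A `radial_profile` (or data frame with `r_um`, `Ir`).
#' @param r0_definition `"fwhm"` (default) or `"2fwhm"`.
#' @return An `accumulation_fit`: coefficients, `r0_um`, `se_r0_um`,
#'   `converged`, `central_component` (FALSE when the central amplitude is
#'   indistinguishable from 0, flagging an unreliable `r0`).
#' @export
fit_accumulation <- function(profile, r0_definition = c("fwhm", "2fwhm")) {
  r0_definition <- match.arg(r0_definition)
  df <- as.data.frame(profile)
  stopifnot(all(c("r_um", "Ir") %in% names(df)))
  df <- df[is.finite(df$Ir), ]
  if (nrow(df) < 8) abort("need at least 8 rings to fit the accumulation model")
  base <- min(df$Ir)
  amp <- max(df$Ir) - base
  rmax <- max(df$r_um)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      Ir ~ k0 * exp(-((r_um - x0) / a0)^2) + k1 * exp(-((r_um - x1) / a1)^2),
      data = df,
      start = list(k0 = max(amp, 1e-6), x0 = 0, a0 = rmax / 4,
                   k1 = base, x1 = rmax, a1 = rmax),
      lower = c(k0 = 0, x0 = -rmax / 2, a0 = 1e-3,
                k1 = 0, x1 = 0, a1 = 1e-3),
      upper = c(k0 = Inf, x0 = rmax / 2, a0 = 2 * rmax,
                k1 = Inf, x1 = 3 * rmax, a1 = 10 * rmax),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(list(converged = FALSE), class = "accumulation_fit"))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) setNames(rep(NA_real_, 6), names(cf)))
  fw <- 2 * cf[["a0"]] * sqrt(log(2))
  mult <- if (r0_definition == "2fwhm") 2 else 1
  central <- is.finite(se[["k0"]]) && cf[["k0"]] > 2 * se[["k0"]] &&
    cf[["k0"]] > 0.05 * max(df$Ir)
  structure(list(
    k0 = cf[["k0"]], x0 = cf[["x0"]], a0 = cf[["a0"]],
    k1 = cf[["k1"]], x1 = cf[["x1"]], a1 = cf[["a1"]],
    r0_um = mult * fw,
    se_r0_um = mult * 2 * sqrt(log(2)) * se[["a0"]],
    r0_definition = r0_definition,
    central_component = central,
    converged = TRUE, fit = fit
  ), class = "accumulation_fit")
}

#' @export
print.accumulation_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<accumulation_fit> fit did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("<accumulation_fit> r0 = %.3f +/- %.3f um (%s)%s\n",
              x$r0_um, x$se_r0_um, x$r0_definition,
              if (!x$central_component) " [central component unreliable]" else ""))
  invisible(x)
}

#' Cluster-gene coupling fraction
#'
#' For every hotspot, the 3D anisotropy-corrected distance to its nearest
#' accepted cluster in the same nucleus; the coupling fraction is the
#' empirical cumulative probability of these distances evaluated at the
#' accumulation radius `r0`. The median distance carries a bootstrap error.
#'
#' @param hotspots Tibble with `nucleus` and either micron coordinates
#'   (`x_um`, `y_um`, `z_um`) or voxel ones (`x_px`, `y_px`, `z_px`).
#' @param clusters Tibble of cluster centroids, same conventions.
#' @param r0_um Accumulation radius (um).
#' @param acq Acquisition parameters, required to convert voxel coordinates.
#' @param n_boot Bootstrap draws for the median error. Default 500.
#' @param seed Seed for the bootstrap. Default 1.
#' @return A `coupling_result`: `distances` tibble (per hotspot),
#'   `coupling_fraction`, `median_um`, `median_se_um`, `r0_um`, and the
#'   empirical CDF function `cdf`.
#' @export
coupling_fraction <- function(hotspots, clusters, r0_um, acq = NULL,
                              n_boot = 500, seed = 1) {
  if (r0_um < 0) abort("`r0_um` must be >= 0")
  hs <- to_um_coords(as_tibble(hotspots), acq)
  cl <- to_um_coords(as_tibble(clusters), acq)
  rows <- list()
  for (i in seq_len(nrow(hs))) {
    sub <- cl[cl$nucleus == hs$nucleus[i], ]
    if (nrow(sub) == 0) next  # nucleus without clusters excluded
    d <- sqrt((sub$x_um - hs$x_um[i])^2 + (sub$y_um - hs$y_um[i])^2 +
                (sub$z_um - hs$z_um[i])^2)
    rows[[length(rows) + 1L]] <- tibble(
      nucleus = hs$nucleus[i], hotspot = i,
      nearest_um = min(d), n_clusters = nrow(sub)
    )
  }
  if (length(rows) < 10) abort("need at least 10 hotspot-cluster pairs")
  dist <- list_rbind(rows)
  d <- dist$nearest_um
  cdf <- stats::ecdf(d)
  med_boot <- with_seed(local_seed(seed, 9L), {
    vapply(seq_len(n_boot),
           function(i) median(d[sample.int(length(d), replace = TRUE)]),
           numeric(1))
  })
  structure(list(
    distances = dist,
    coupling_fraction = cdf(r0_um),
    median_um = median(d),
    median_se_um = sd(med_boot),
    r0_um = r0_um,
    cdf = cdf
  ), class = "coupling_result")
}

to_um_coords <- function(df, acq) {
  if (all(c("x_um", "y_um", "z_um") %in% names(df))) return(df)
  if (is.null(acq)) abort("`acq` needed to convert voxel coordinates to um")
  df$x_um <- df$x_px * acq$voxel_xy / 1000
  df$y_um <- df$y_px * acq$voxel_xy / 1000
  df$z_um <- df$z_px * acq$voxel_z / 1000
  df
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("<coupling_result> %d hotspots; median nearest distance %.3f +/- %.3f um; coupling fraction %.2f at r0 = %.2f um\n",
              nrow(x$distances), x$median_um, x$median_se_um,
              x$coupling_fraction, x$r0_um))
  invisible(x)
}

#' Alternative coupling boundary from the distance histogram
#'
#' Fits the nearest-distance histogram with a double Gaussian; the boundary
#' `r0'` is the abscissa where the two components cross between their means
#' (coupled population below, uncoupled above). When the histogram is not
#' bimodal enough for a crossing to exist between the means, the result is
#' flagged and callers should fall back to the `r0`-threshold method.
#'
#' @param distances Numeric vector of nearest-cluster distances (um),
#'   or a `coupling_result`.
#' @param n_bins Histogram bin count. Default 20.
#' @return A `coupling_boundary`: `r0_prime_um`, `converged`,
#'   `crossing_found`, component parameters, and the coupled fraction of the
#'   input distances under `r0'`.
#' @export
coupling_boundary_alt <- function(distances, n_bins = 20) {
  if (inherits(distances, "coupling_result")) {
    distances <- distances$distances$nearest_um
  }
  d <- distances[is.finite(distances)]
  if (length(d) < 30) abort("need at least 30 distances")
  h <- graphics::hist(d, breaks = n_bins, plot = FALSE)
  df <- tibble(x = h$mids, y = h$density)
  q <- quantile(d, c(0.25, 0.75), names = FALSE)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ k0 * exp(-((x - m0) / a0)^2) + k1 * exp(-((x - m1) / a1)^2),
      data = df,
      start = list(k0 = max(df$y), m0 = q[1], a0 = diff(q) / 2,
                   k1 = max(df$y) / 2, m1 = q[2], a1 = diff(q) / 2),
      lower = c(k0 = 0, m0 = 0, a0 = 1e-3, k1 = 0, m1 = 0, a1 = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(list(converged = FALSE, crossing_found = FALSE),
                     class = "coupling_boundary"))
  }
  cf <- as.list(coef(fit))
  if (cf$m1 < cf$m0) {
    cf <- list(k0 = cf$k1, m0 = cf$m1, a0 = cf$a1,
               k1 = cf$k0, m1 = cf$m0, a1 = cf$a0)
  }
  g0 <- function(x) cf$k0 * exp(-((x - cf$m0) / cf$a0)^2)
  g1 <- function(x) cf$k1 * exp(-((x - cf$m1) / cf$a1)^2)
  crossing <- NA_real_
  found <- FALSE
  # require genuine bimodality: component means separated by more than the
  # sum of the component widths, else a single mode split in two also
  # "crosses" between its halves
  if (cf$m1 - cf$m0 > (cf$a0 + cf$a1) && cf$k0 > 0 && cf$k1 > 0) {
    h_diff <- function(x) g0(x) - g1(x)
    if (h_diff(cf$m0) > 0 && h_diff(cf$m1) < 0) {
      crossing <- stats::uniroot(h_diff, c(cf$m0, cf$m1))$root
      found <- TRUE
    }
  }
  if (!found) {
    warn("no crossing between component means; fall back to the r0-threshold method")
  }
  structure(list(
    r0_prime_um = crossing,
    converged = TRUE, crossing_found = found,
    components = cf,
    coupled_fraction = if (found) mean(d < crossing) else NA_real_,
    fit = fit
  ), class = "coupling_boundary")
}

#' @export
print.coupling_boundary <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<coupling_boundary> histogram fit did not converge\n")
  } else if (!x$crossing_found) {
    cat("<coupling_boundary> no crossing between means (unimodal histogram?)\n")
  } else {
    cat(sprintf("<coupling_boundary> r0' = %.3f um, coupled fraction %.2f\n",
                x$r0_prime_um, x$coupled_fraction))
  }
  invisible(x)
}
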