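# Synthetic-embryo generators. Every generator is a pure function of
# (parameters, seed); ground truth is returned alongside the rendered voxels
# so downstream stages always have an oracle.

#' Construct an image stack container
#'
#' A thin container for one or more channels of voxel data plus the
#' acquisition parameters that give the voxels physical meaning.
#'
#' @param channels Named list of numeric arrays (2D plane, 3D stack, or
#'   2D+time with time as the third dimension when `kind = "2dt"`).
#' @param acq An [acquisition_params()] object.
#' @param kind One of `"3d"`, `"2d"`, `"2dt"`.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, acq, kind = c("3d", "2d", "2dt")) {
  kind <- match.arg(kind)
  stopifnot(is.list(channels), length(channels) >= 1, inherits(acq, "acquisition_params"))
  dims <- lapply(channels, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    abort("all channels must share dimensions")
  }
  if (any(vapply(channels, function(ch) any(ch < 0), logical(1)))) {
    abort("image intensities must be non-negative")
  }
  structure(list(channels = channels, acq = acq, kind = kind),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_stack> %s, %s, channels: %s\n", x$kind,
              paste(d, collapse = " x "),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# Spherical (or circular, in 2D) nucleus mask on the voxel grid.
sphere_mask <- function(dims, center_px, r_xy_px, r_z_px = NULL) {
  if (length(dims) == 2L) {
    dx <- (seq_len(dims[1]) - center_px[1]) / r_xy_px
    dy <- (seq_len(dims[2]) - center_px[2]) / r_xy_px
    return(outer(dx^2, dy^2, `+`) <= 1)
  }
  dx <- (seq_len(dims[1]) - center_px[1]) / r_xy_px
  dy <- (seq_len(dims[2]) - center_px[2]) / r_xy_px
  dz <- (seq_len(dims[3]) - center_px[3]) / r_z_px
  r2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
  r2 <= 1
}

# Draw per-cluster truth rows. Sizes are apparent (PSF-convolved) effective
# diameters; intrinsic widths are deconvolved analytically.
draw_cluster_truth <- function(n, sim, acq) {
  q <- sim$sigma_ratio
  psf <- acq$psf_sigma_lateral
  floor_nm <- sim$d_floor
  if (floor_nm >= sim$d_mean + 4 * sim$d_sd) {
    abort("cluster size floor is at or above the size distribution; degenerate truncation")
  }
  d_app <- rtruncnorm(n, sim$d_mean, sim$d_sd, lower = floor_nm)
  s1_app <- d_app * q / sqrt(1 + q^2)
  s2_app <- d_app / sqrt(1 + q^2)
  ratio <- rtruncnorm(n, sim$amp_ratio_mean, sim$amp_ratio_sd, lower = 0.1)
  tibble(
    d_app_nm = d_app,
    sigma1_app_nm = s1_app,
    sigma2_app_nm = s2_app,
    sigma1_int_nm = sqrt(pmax(s1_app^2 - psf^2, 1)),
    sigma2_int_nm = sqrt(pmax(s2_app^2 - psf^2, 1)),
    theta = runif(n, 0.01, pi / 4 - 0.01),
    amp_ratio = ratio
  )
}

# Apparent axial sigma of an isotropic cluster: the intrinsic size is the
# lateral apparent width deconvolved of the lateral PSF, and the axial
# appearance convolves that same intrinsic size with the axial PSF.
cluster_axial_sigma <- function(sigma_lat_app_nm, acq) {
  s_int <- sqrt(pmax(sigma_lat_app_nm^2 - acq$psf_sigma_lateral^2, 0))
  sqrt(s_int^2 + acq$psf_sigma_axial^2)
}

# Add one apparent (already PSF-convolved) anisotropic Gaussian to a 3D array
# in place, evaluated on a +/- 4 sigma local window.
add_gaussian_spot <- function(arr, cx, cy, cz, amp, s1_px, s2_px, theta, sz_px) {
  d3 <- length(dim(arr)) == 3L
  ext <- ceiling(4 * max(s1_px, s2_px))
  xs <- max(1L, floor(cx - ext)):min(dim(arr)[1], ceiling(cx + ext))
  ys <- max(1L, floor(cy - ext)):min(dim(arr)[2], ceiling(cy + ext))
  dx <- xs - cx
  dy <- ys - cy
  # same rotated quadratic form as the cluster fitter, so render -> fit
  # round-trips are exact
  ab <- gauss2d_abc(s1_px, s2_px, theta)
  g2 <- exp(-(ab$a * outer(dx^2, rep(1, length(dy))) +
                2 * ab$b * outer(dx, dy) +
                ab$c * outer(rep(1, length(dx)), dy^2)))
  if (!d3) {
    arr[xs, ys] <- arr[xs, ys] + amp * g2
    return(arr)
  }
  extz <- ceiling(4 * sz_px)
  zs <- max(1L, floor(cz - extz)):min(dim(arr)[3], ceiling(cz + extz))
  gz <- exp(-((zs - cz)^2) / (2 * sz_px^2))
  for (i in seq_along(zs)) {
    arr[xs, ys, zs[i]] <- arr[xs, ys, zs[i]] + amp * gz[i] * g2[, ]
  }
  arr
}

apply_noise <- function(arr, acq) {
  n <- length(arr)
  photons <- pmax(arr, 0) / acq$photon_scale
  out <- rpois(n, photons) * acq$photon_scale
  if (acq$noise_read_sd > 0) out <- out + rnorm(n, 0, acq$noise_read_sd)
  array(pmax(out, 0), dim(arr))
}

#' Generate a single synthetic nucleus stack with planted clusters
#'
#' Renders one spherical nucleus at fractional anterior-posterior position
#' `x_over_L`. The nuclear mean intensity follows the exponential gradient
#' `I0 * exp(-x / lambda)`; the number of planted clusters is Poisson with a
#' mean linear in the nuclear intensity; cluster apparent sizes are drawn from
#' the configured truncated normal independently of intensity; amplitudes are
#' `ratio * Ibg` with `ratio` truncated-normal. A PSF-correlated fluctuation
#' field models the freely diffusing pool, and the stack is corrupted by
#' Poisson shot noise plus Gaussian read noise (unless `noise = FALSE`).
#'
#' @param sim An [embryo_sim_params()] object.
#' @param acq An [acquisition_params()] object.
#' @param x_over_L Fractional AP position in `[0, 1]`.
#' @param seed Integer seed; identical `(params, seed)` give identical output.
#' @param n_clusters Optional fixed cluster count (overrides the census model).
#' @param mode `"clusters"` (default) or `"homogeneous"` (no clusters, only
#'   the diffuse fluctuation field, as for an NLS-GFP-like control).
#' @param noise Logical; apply shot + read noise. Default `TRUE`.
#' @param dim_2d Logical; render a single 2D cross-section through the
#'   nucleus mid-plane instead of a 3D stack. Default `FALSE`.
#' @param margin_um Field margin around the nucleus (um). Default 0.5.
#'
#' @return A list with `stack` (an [image_stack()]) and `truth`, a list with
#'   `nuclei` (one-row tibble: centre, radius, true mean intensity) and
#'   `clusters` (one row per planted cluster: voxel-grid centroid, apparent
#'   and intrinsic widths, amplitude, background, true integrated intensity
#'   `Ic = 2 * pi * Ia * sigma1 * sigma2`).
#' @export
generate_nucleus_stack <- function(sim, acq, x_over_L, seed,
                                   n_clusters = NULL,
                                   mode = c("clusters", "homogeneous"),
                                   noise = TRUE,
                                   dim_2d = FALSE,
                                   margin_um = 0.5) {
  mode <- match.arg(mode)
  stopifnot(x_over_L >= 0, x_over_L <= 1)
  vx <- acq$voxel_xy / 1000   # um per lateral pixel
  vz <- acq$voxel_z / 1000
  R_um <- sim$nucleus_diameter_um / 2
  n_xy <- as.integer(ceiling((sim$nucleus_diameter_um + 2 * margin_um) / vx))
  n_z <- as.integer(ceiling((sim$nucleus_diameter_um + 2 * margin_um) / vz))
  cen_xy <- (n_xy + 1) / 2
  cen_z <- (n_z + 1) / 2
  r_xy <- R_um / vx
  r_z <- R_um / vz
  psf_xy_px <- acq$psf_sigma_lateral / acq$voxel_xy
  psf_z_px <- acq$psf_sigma_axial / acq$voxel_z

  with_seed(local_seed(seed, 1L), {
    inuc <- sim$I0_anterior * exp(-x_over_L / sim$lambda_gradient)
    if (sim$noise_cv > 0) {
      s <- sqrt(log(1 + sim$noise_cv^2))
      inuc <- inuc * rlnorm(1, -s^2 / 2, s)
    }
    dims <- if (dim_2d) c(n_xy, n_xy) else c(n_xy, n_xy, n_z)
    mask <- if (dim_2d) {
      sphere_mask(dims, c(cen_xy, cen_xy), r_xy)
    } else {
      sphere_mask(dims, c(cen_xy, cen_xy, cen_z), r_xy, r_z)
    }
    base <- array(sim$cyto_frac * inuc, dims)
    base[mask] <- inuc
    base <- gauss_blur_3d(base, psf_xy_px, if (dim_2d) 0 else psf_z_px)
    if (sim$fluct_cv > 0) {
      fl <- array(rnorm(prod(dims)), dims)
      fl <- gauss_blur_3d(fl, psf_xy_px, if (dim_2d) 0 else psf_z_px)
      # blurring shrinks the sd; rescale so the planted fluctuation CV holds
      fl <- fl / sd(fl)
      base <- pmax(base * (1 + sim$fluct_cv * fl * (base / inuc)), 0)
      base <- array(base, dims)
    }

    clusters <- tibble()
    if (mode == "clusters") {
      n_cl <- if (is.null(n_clusters)) {
        rpois(1, pmax(sim$cluster_count_intercept +
                        sim$cluster_count_slope * inuc, 0))
      } else {
        n_clusters
      }
      if (n_cl > 0) {
        tr <- draw_cluster_truth(n_cl, sim, acq)
        # keep clusters inside 85% of the nuclear radius so fit windows stay
        # within the bright interior; hard-core separation between centres
        u <- runif_hardcore_ball(n_cl, radius = 0.85,
                                 min_sep = sim$cluster_min_sep_um / R_um)
        if (dim_2d) {
          # a 2D cross-section (~1 um thick) only shows clusters whose z
          # position falls within the section
          in_section <- abs(u[, 3]) * R_um <= 0.5
          u <- u[in_section, , drop = FALSE]
          tr <- tr[in_section, , drop = FALSE]
          n_cl <- nrow(tr)
        }
        tr$x_px <- cen_xy + u[, 1] * r_xy
        tr$y_px <- cen_xy + u[, 2] * r_xy
        tr$z_px <- if (dim_2d) NA_real_ else cen_z + u[, 3] * r_z
        # the true local background is the rendered diffuse level at the
        # cluster position (lower than the nominal nuclear mean near the
        # blurred rim); amplitudes scale with the local diffuse level
        pos_idx <- cbind(round(tr$x_px), round(tr$y_px),
                         if (dim_2d) NULL else round(tr$z_px))
        tr$Ibg <- base[pos_idx]
        tr$Ia <- tr$amp_ratio * tr$Ibg
        s1_um <- tr$sigma1_app_nm / 1000
        s2_um <- tr$sigma2_app_nm / 1000
        tr$Ic_true <- 2 * pi * tr$Ia * s1_um * s2_um
        sz_app_nm <- cluster_axial_sigma(
          (tr$sigma1_app_nm + tr$sigma2_app_nm) / 2, acq)
        for (i in seq_len(n_cl)) {
          base <- add_gaussian_spot(
            base, tr$x_px[i], tr$y_px[i], tr$z_px[i], tr$Ia[i],
            tr$sigma1_app_nm[i] / acq$voxel_xy,
            tr$sigma2_app_nm[i] / acq$voxel_xy,
            tr$theta[i], sz_app_nm[i] / acq$voxel_z
          )
        }
        clusters <- tr
      }
    }
    if (noise) base <- apply_noise(base, acq)
    stack <- image_stack(list(tf = base), acq, kind = if (dim_2d) "2d" else "3d")
    nuc <- tibble(
      nucleus = 1L, x_over_L = x_over_L, Inuc_true = inuc,
      cx_px = cen_xy, cy_px = cen_xy,
      cz_px = if (dim_2d) NA_real_ else cen_z,
      r_xy_px = r_xy, r_z_px = if (dim_2d) NA_real_ else r_z,
      n_clusters = nrow(clusters)
    )
    list(stack = stack, truth = list(nuclei = nuc, clusters = clusters, seed = seed))
  })
}

#' Generate a multi-nucleus embryo field
#'
#' Nuclei are placed at random fractional positions within `x_range`; each
#' nuclear intensity follows the exponential AP gradient with multiplicative
#' lognormal nucleus-to-nucleus noise of CV `sim$noise_cv`. By default only
#' ground truth (nucleus- and cluster-level tibbles) is produced; with
#' `render = TRUE` a single stack containing all nuclei on a jittered
#' hexagonal grid is rendered (use a coarse voxel size to keep this small).
#'
#' @inheritParams generate_nucleus_stack
#' @param n_nuclei Number of nuclei (>= 2 unless 1 is explicitly wanted).
#' @param x_range Length-2 numeric range of x/L, within `[0, 1]`.
#' @param render Logical; render voxels. Default `FALSE` (truth only).
#' @param render_clusters Logical; include planted clusters in the rendering.
#' @return A list with `nuclei` (tibble), `clusters` (tibble) and, when
#'   rendered, `stack` (an [image_stack()]).
#' @export
generate_embryo_field <- function(sim, acq, n_nuclei, x_range, seed,
                                  render = FALSE, render_clusters = FALSE,
                                  margin_um = 1) {
  if (length(x_range) != 2 || diff(range(x_range)) <= 0) {
    abort("`x_range` must be a non-empty interval")
  }
  if (any(x_range < 0) || any(x_range > 1)) abort("`x_range` must lie within [0, 1]")
  if (n_nuclei < 1) abort("`n_nuclei` must be >= 1")

  with_seed(local_seed(seed, 2L), {
    x <- sort(runif(n_nuclei, x_range[1], x_range[2]))
    s <- sqrt(log(1 + sim$noise_cv^2))
    eta <- if (sim$noise_cv > 0) rlnorm(n_nuclei, -s^2 / 2, s) else rep(1, n_nuclei)
    inuc <- sim$I0_anterior * exp(-x / sim$lambda_gradient) * eta
    n_cl <- rpois(n_nuclei, pmax(sim$cluster_count_intercept +
                                   sim$cluster_count_slope * inuc, 0))
    nuclei <- tibble(
      nucleus = seq_len(n_nuclei), x_over_L = x,
      Inuc_true = inuc, n_clusters = n_cl
    )
    clusters <- draw_cluster_truth(sum(n_cl), sim, acq)
    clusters$nucleus <- rep(nuclei$nucleus, n_cl)
    clusters$Ibg <- rep(inuc, n_cl)
    clusters$Ia <- clusters$amp_ratio * clusters$Ibg
    clusters$Ic_true <- 2 * pi * clusters$Ia *
      (clusters$sigma1_app_nm / 1000) * (clusters$sigma2_app_nm / 1000)
    out <- list(nuclei = nuclei, clusters = clusters, seed = seed)

    if (render) {
      vx <- acq$voxel_xy / 1000
      vz <- acq$voxel_z / 1000
      R_um <- sim$nucleus_diameter_um / 2
      pitch <- sim$nucleus_diameter_um * 1.35
      n_col <- ceiling(sqrt(n_nuclei))
      n_row <- ceiling(n_nuclei / n_col)
      fw <- n_col * pitch + 2 * margin_um
      fh <- n_row * pitch * 0.9 + 2 * margin_um
      n_x <- as.integer(ceiling(fw / vx))
      n_y <- as.integer(ceiling(fh / vx))
      n_z <- as.integer(ceiling((sim$nucleus_diameter_um + 2 * margin_um) / vz))
      dims <- c(n_x, n_y, n_z)
      base <- array(0, dims)
      maskall <- array(FALSE, dims)
      cen_z <- (n_z + 1) / 2
      r_xy <- R_um / vx
      r_z <- R_um / vz
      centers <- matrix(NA_real_, n_nuclei, 3)
      for (i in seq_len(n_nuclei)) {
        rr <- (i - 1) %/% n_col
        cc <- (i - 1) %% n_col
        cx_um <- margin_um + (cc + 0.5 + 0.25 * (rr %% 2)) * pitch +
          runif(1, -0.05, 0.05) * pitch
        cy_um <- margin_um + (rr + 0.5) * pitch * 0.9 + runif(1, -0.05, 0.05) * pitch
        cx <- cx_um / vx; cy <- cy_um / vx
        m <- sphere_mask(dims, c(cx, cy, cen_z), r_xy, r_z)
        base[m] <- inuc[i]
        maskall <- maskall | m
        centers[i, ] <- c(cx, cy, cen_z)
      }
      cyto <- sim$cyto_frac * mean(inuc)
      base[!maskall] <- cyto
      psf_xy_px <- acq$psf_sigma_lateral / acq$voxel_xy
      psf_z_px <- acq$psf_sigma_axial / acq$voxel_z
      base <- gauss_blur_3d(base, psf_xy_px, psf_z_px)
      if (render_clusters && nrow(clusters) > 0) {
        idx <- 0L
        clusters$x_px <- NA_real_; clusters$y_px <- NA_real_; clusters$z_px <- NA_real_
        for (i in seq_len(n_nuclei)) {
          ni <- n_cl[i]
          if (ni == 0) next
          rows <- idx + seq_len(ni)
          u <- runif_hardcore_ball(ni, radius = 0.8,
                                   min_sep = sim$cluster_min_sep_um / R_um)
          clusters$x_px[rows] <- centers[i, 1] + u[, 1] * r_xy
          clusters$y_px[rows] <- centers[i, 2] + u[, 2] * r_xy
          clusters$z_px[rows] <- centers[i, 3] + u[, 3] * r_z
          sz_app_nm <- cluster_axial_sigma(
            (clusters$sigma1_app_nm[rows] + clusters$sigma2_app_nm[rows]) / 2, acq)
          for (j in seq_along(rows)) {
            k <- rows[j]
            base <- add_gaussian_spot(
              base, clusters$x_px[k], clusters$y_px[k], clusters$z_px[k],
              clusters$Ia[k],
              clusters$sigma1_app_nm[k] / acq$voxel_xy,
              clusters$sigma2_app_nm[k] / acq$voxel_xy,
              clusters$theta[k], sz_app_nm[j] / acq$voxel_z
            )
          }
          idx <- idx + ni
        }
        out$clusters <- clusters
      }
      base <- apply_noise(base, acq)
      out$stack <- image_stack(list(tf = base), acq, kind = "3d")
      out$nuclei$cx_px <- centers[, 1]
      out$nuclei$cy_px <- centers[, 2]
      out$nuclei$cz_px <- centers[, 3]
      out$nuclei$r_xy_px <- r_xy
      out$nuclei$r_z_px <- r_z
    }
    out
  })
}

#' Simulate per-nucleus gradient quantities directly
#'
#' Truth-level emulation of a nuclear-average quantity (e.g. the mean cluster
#' intensity Ic, or the nuclear intensity Inuc) along the AP axis: an
#' exponential of decay constant `lambda` (fraction of L) with multiplicative
#' lognormal noise of coefficient of variation `cv`. This is the generator
#' behind gradient-precision analyses when voxel-level rendering is not
#' needed.
#'
#' @param n Number of nuclei.
#' @param x_range Range of x/L positions (uniform random within).
#' @param lambda Exponential decay constant (fraction of L).
#' @param cv Multiplicative noise CV.
#' @param amplitude Value extrapolated to x/L = 0.
#' @param seed Integer seed.
#' @param quantity Column name for the simulated quantity. Default `"value"`.
#' @return A tibble with `nucleus`, `x_over_L` and the quantity column.
#' @export
#' @examples
#' g <- simulate_nuclear_gradient(100, c(0.1, 0.65), lambda = 0.26,
#'                                cv = 0.22, amplitude = 60, seed = 1)
simulate_nuclear_gradient <- function(n, x_range, lambda, cv, amplitude, seed,
                                      quantity = "value") {
  if (n < 1) abort("`n` must be >= 1")
  stopifnot(lambda > 0, cv >= 0, amplitude > 0)
  with_seed(local_seed(seed, 3L), {
    x <- runif(n, x_range[1], x_range[2])
    s <- sqrt(log(1 + cv^2))
    eta <- if (cv > 0) rlnorm(n, -s^2 / 2, s) else rep(1, n)
    out <- tibble(nucleus = seq_len(n), x_over_L = x)
    out[[quantity]] <- amplitude * exp(-x / lambda) * eta
    out
  })
}

# Continuous-time two-state telegraph trace sampled at frame times.
telegraph_trace <- function(n_frames, frame_time, ton, toff) {
  p_on <- if (is.infinite(ton)) 1 else ton / (ton + toff)
  state <- runif(1) < p_on
  t_end <- n_frames * frame_time
  times <- (seq_len(n_frames) - 0.5) * frame_time
  out <- logical(n_frames)
  t <- 0
  i <- 1L
  while (t < t_end && i <= n_frames) {
    dwell <- if (state) {
      if (is.infinite(ton)) Inf else rexp(1, 1 / ton)
    } else {
      if (is.infinite(toff)) Inf else rexp(1, 1 / toff)
    }
    upto <- t + dwell
    while (i <= n_frames && times[i] < upto) {
      out[i] <- state
      i <- i + 1L
    }
    t <- upto
    state <- !state
  }
  out
}

#' Generate a 2D time-lapse of blinking clusters
#'
#' A single 2D nuclear cross-section imaged for `n_frames` frames. Clusters
#' sit at fixed confinement centres and blink according to a two-state
#' telegraph process with exponential dwell times (means `sim$ton`,
#' `sim$toff`) sampled at the frame interval.
#'
#' @inheritParams generate_nucleus_stack
#' @param n_frames Number of frames (>= 2).
#' @param n_clusters Number of confinement centres. Default 6.
#' @param render Logical; render frames (otherwise traces only).
#' @return A list with `truth` (confinement centres tibble, logical on/off
#'   `traces` matrix of dimension frames x clusters) and, when rendered,
#'   `stack` (kind `"2dt"`).
#' @export
generate_timelapse <- function(sim, acq, n_frames, seed, n_clusters = 6,
                               render = TRUE, margin_um = 0.5) {
  if (n_frames < 2) abort("`n_frames` must be >= 2")
  with_seed(local_seed(seed, 4L), {
    vx <- acq$voxel_xy / 1000
    R_um <- sim$nucleus_diameter_um / 2
    n_xy <- as.integer(ceiling((sim$nucleus_diameter_um + 2 * margin_um) / vx))
    cen <- (n_xy + 1) / 2
    r_px <- R_um / vx
    inuc <- sim$I0_anterior
    ang <- runif(n_clusters, 0, 2 * pi)
    rad <- sqrt(runif(n_clusters)) * 0.7 * r_px
    centers <- tibble(
      cluster = seq_len(n_clusters),
      x_px = cen + rad * cos(ang),
      y_px = cen + rad * sin(ang)
    )
    traces <- vapply(
      seq_len(n_clusters),
      function(i) telegraph_trace(n_frames, acq$frame_time, sim$ton, sim$toff),
      logical(n_frames)
    )
    traces <- matrix(traces, nrow = n_frames)
    out <- list(truth = list(
      centers = centers, traces = traces,
      occupancy = colMeans(traces), seed = seed
    ))
    if (render) {
      tr_cl <- draw_cluster_truth(n_clusters, sim, acq)
      psf_xy_px <- acq$psf_sigma_lateral / acq$voxel_xy
      mask <- sphere_mask(c(n_xy, n_xy), c(cen, cen), r_px)
      frames <- array(0, c(n_xy, n_xy, n_frames))
      for (f in seq_len(n_frames)) {
        base <- array(sim$cyto_frac * inuc, c(n_xy, n_xy))
        base[mask] <- inuc
        base <- gauss_blur_3d(base, psf_xy_px)
        if (sim$fluct_cv > 0) {
          fl <- gauss_blur_3d(array(rnorm(n_xy^2), c(n_xy, n_xy)), psf_xy_px)
          fl <- fl / sd(fl)
          base <- pmax(base * (1 + sim$fluct_cv * fl * (base / inuc)), 0)
          base <- array(base, c(n_xy, n_xy))
        }
        for (i in seq_len(n_clusters)) {
          if (!traces[f, i]) next
          base <- add_gaussian_spot(
            base, centers$x_px[i], centers$y_px[i], NA, tr_cl$amp_ratio[i] * inuc,
            tr_cl$sigma1_app_nm[i] / acq$voxel_xy,
            tr_cl$sigma2_app_nm[i] / acq$voxel_xy,
            tr_cl$theta[i], NA
          )
        }
        frames[, , f] <- apply_noise(base, acq)
      }
      out$stack <- image_stack(list(tf = frames), acq, kind = "2dt")
      out$truth$mask <- mask
      out$truth$nucleus <- tibble(cx_px = cen, cy_px = cen, r_px = r_px)
    }
    out
  })
}

#' Generate a two-channel (TF + transcription hotspot) data set
#'
#' Channel 1 carries TF clusters, channel 2 one transcription hotspot per
#' active nucleus. With probability `sim$coupling_fraction` the cluster
#' nearest to the hotspot is planted within the accumulation radius `r0`
#' (coupled); otherwise all clusters are kept beyond `r0` (uncoupled). In
#' `"nontarget"` mode clusters are placed independently of the hotspot.
#'
#' @inheritParams generate_nucleus_stack
#' @param gene_mode `"target-strong"`, `"target-weak"`, or `"nontarget"`.
#'   The weak mode lowers hotspot intensity 3.2-fold and widens the coupled
#'   distance distribution.
#' @param n_nuclei Number of nuclei.
#' @param render Logical; render per-nucleus two-channel stacks (small
#'   fields). Default `FALSE` (truth level).
#' @param clusters_per_nucleus Cluster count per nucleus. Default 12.
#' @return A list with `nuclei`, `hotspots`, `clusters` tibbles (positions in
#'   um within each nucleus frame, coupling labels) and optionally `stacks`,
#'   a list of two-channel [image_stack()] objects.
#' @export
generate_two_channel <- function(sim, acq, gene_mode = c("target-strong", "target-weak", "nontarget"),
                                 n_nuclei, seed, render = FALSE,
                                 clusters_per_nucleus = 12) {
  gene_mode <- match.arg(gene_mode)
  r0 <- sim$accumulation_radius_um
  R <- sim$nucleus_diameter_um / 2
  with_seed(local_seed(seed, 5L), {
    hot_amp_scale <- if (gene_mode == "target-weak") 1 / 3.2 else 1
    nuclei <- tibble(nucleus = seq_len(n_nuclei), Inuc_true = sim$I0_anterior)
    hs <- tibble(
      nucleus = seq_len(n_nuclei),
      # hotspot sits in the central region of the nucleus
      hx_um = runif(n_nuclei, -0.3, 0.3) * R,
      hy_um = runif(n_nuclei, -0.3, 0.3) * R,
      hz_um = runif(n_nuclei, -0.3, 0.3) * R,
      intensity_scale = hot_amp_scale
    )
    cl <- vector("list", n_nuclei)
    coupled <- logical(n_nuclei)
    for (i in seq_len(n_nuclei)) {
      n_cl <- clusters_per_nucleus
      # positions uniform in the 0.85 R sphere
      pos <- runif_in_ball(n_cl) * 0.85 * R
      h <- c(hs$hx_um[i], hs$hy_um[i], hs$hz_um[i])
      dist_h <- sqrt(colSums((t(pos) - h)^2))
      if (gene_mode != "nontarget") {
        # push every cluster outside r0 first
        too_close <- dist_h < r0 * 1.1
        while (any(too_close)) {
          pos[too_close, ] <- runif_in_ball(sum(too_close)) * 0.85 * R
          dist_h <- sqrt(colSums((t(pos) - h)^2))
          too_close <- dist_h < r0 * 1.1
        }
        coupled[i] <- runif(1) < sim$coupling_fraction
        if (coupled[i]) {
          # place the nearest cluster inside r0
          dd <- runif(1, 0.15, 0.9) * r0 *
            (if (gene_mode == "target-weak") runif(1, 0.8, 1.1) else 1)
          dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
          pos[1, ] <- h + dir * dd
        }
      }
      cl[[i]] <- tibble(
        nucleus = i, cluster = seq_len(n_cl),
        x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
        dist_hotspot_um = sqrt(rowSums((pos - matrix(h, n_cl, 3, byrow = TRUE))^2))
      )
    }
    clusters <- list_rbind(cl)
    nuclei$coupled_true <- if (gene_mode == "nontarget") NA else coupled
    out <- list(nuclei = nuclei, hotspots = hs, clusters = clusters,
                gene_mode = gene_mode, seed = seed)

    if (render) {
      vx <- acq$voxel_xy / 1000
      vz <- acq$voxel_z / 1000
      margin_um <- 0.5
      n_xy <- as.integer(ceiling((sim$nucleus_diameter_um + 2 * margin_um) / vx))
      n_z <- as.integer(ceiling((sim$nucleus_diameter_um + 2 * margin_um) / vz))
      cen_xy <- (n_xy + 1) / 2
      cen_z <- (n_z + 1) / 2
      psf_xy_px <- acq$psf_sigma_lateral / acq$voxel_xy
      psf_z_px <- acq$psf_sigma_axial / acq$voxel_z
      stacks <- vector("list", n_nuclei)
      mask <- sphere_mask(c(n_xy, n_xy, n_z), c(cen_xy, cen_xy, cen_z),
                          R / vx, R / vz)
      for (i in seq_len(n_nuclei)) {
        inuc <- nuclei$Inuc_true[i]
        tf <- array(sim$cyto_frac * inuc, c(n_xy, n_xy, n_z))
        tf[mask] <- inuc
        tf <- gauss_blur_3d(tf, psf_xy_px, psf_z_px)
        rows <- clusters[clusters$nucleus == i, ]
        trc <- draw_cluster_truth(nrow(rows), sim, acq)
        sz_app_nm <- cluster_axial_sigma(
          (trc$sigma1_app_nm + trc$sigma2_app_nm) / 2, acq)
        for (j in seq_len(nrow(rows))) {
          tf <- add_gaussian_spot(
            tf, cen_xy + rows$x_um[j] / vx, cen_xy + rows$y_um[j] / vx,
            cen_z + rows$z_um[j] / vz, trc$amp_ratio[j] * inuc,
            trc$sigma1_app_nm[j] / acq$voxel_xy,
            trc$sigma2_app_nm[j] / acq$voxel_xy,
            trc$theta[j], sz_app_nm[j] / acq$voxel_z
          )
        }
        # hotspot channel: inverted nuclear contrast (MCP-like) + one bright spot
        mr_in <- 0.4 * inuc
        mr <- array(inuc, c(n_xy, n_xy, n_z))
        mr[mask] <- mr_in
        mr <- gauss_blur_3d(mr, psf_xy_px, psf_z_px)
        mr <- add_gaussian_spot(
          mr, cen_xy + hs$hx_um[i] / vx, cen_xy + hs$hy_um[i] / vx,
          cen_z + hs$hz_um[i] / vz, 8 * inuc * hs$intensity_scale[i],
          300 / acq$voxel_xy, 300 / acq$voxel_xy, 0, 350 / acq$voxel_z
        )
        tf <- apply_noise(tf, acq)
        mr <- apply_noise(mr, acq)
        stacks[[i]] <- image_stack(list(tf = tf, mrna = mr), acq, kind = "3d")
      }
      out$stacks <- stacks
      out$mask <- mask
      out$geometry <- list(cen_xy = cen_xy, cen_z = cen_z, vx = vx, vz = vz)
    }
    out
  })
}

#' Generate a clustered 2D point pattern
#'
#' Superposition of a homogeneous Poisson background of density
#' `rho_poisson` and `n_clumps` Gaussian clumps, parameterised by the
#' pair-correlation curve it plants: the pattern's true pair correlation is
#' `g(r) = rho_prime * exp(-(r / sigma_clump)^2) + 1`, i.e. `rho_prime` is
#' the relative excess pair density at zero separation and `sigma_clump` the
#' width of the focal accumulation. (Points within a clump are scattered
#' with per-axis sd `sigma_clump / 2`; the mean point count per clump that
#' realises the requested amplitude is solved from the pair-density
#' identity.)
#'
#' @param rho_poisson Background density (points per um^2).
#' @param rho_prime Planted pair-correlation amplitude at r = 0 (>= 0).
#' @param sigma_clump Planted pair-correlation width (um).
#' @param n_clumps Number of clumps.
#' @param window A list `list(shape = "disc", radius_um = r)` or
#'   `list(shape = "rect", width_um = w, height_um = h)`.
#' @param seed Integer seed.
#' @return A list with `points` (tibble `x_um`, `y_um`, `type`), `window`,
#'   `clump_centers`, and `mu_per_clump` (the solved mean count).
#' @export
generate_point_pattern <- function(rho_poisson, rho_prime, sigma_clump,
                                   n_clumps, window, seed) {
  if (rho_poisson < 0 || rho_prime < 0) abort("densities must be >= 0")
  assert_scalar_pos(sigma_clump, "sigma_clump")
  area <- window_area(window)
  if (area <= 0) abort("empty window")
  s <- sigma_clump / 2  # per-axis scatter planting pair width sigma_clump
  with_seed(local_seed(seed, 6L), {
    bg <- sample_window(rpois(1, rho_poisson * area), window)
    bg$type <- "poisson"
    pts <- bg
    centers <- tibble(x_um = numeric(0), y_um = numeric(0))
    mu <- 0
    if (rho_prime > 0 && n_clumps > 0) {
      # Excess ordered-pair density at lag 0 of n_clumps Gaussian clumps with
      # Poisson(mu) points each: n_clumps * mu^2 / (4 pi s^2 A); amplitude
      # rho_prime relative to rho_tot^2 with rho_tot = rho_bg + n_clumps mu / A.
      # Solve the quadratic for mu.
      A <- area
      k <- rho_prime * 4 * pi * s^2
      aa <- n_clumps - k * n_clumps^2 / A
      bb <- -k * 2 * rho_poisson * n_clumps
      cc <- -k * A * rho_poisson^2
      disc <- bb^2 - 4 * aa * cc
      if (aa <= 0 || disc < 0) {
        abort("requested pair-correlation amplitude is unattainable with these clump settings")
      }
      mu <- (-bb + sqrt(disc)) / (2 * aa)
      centers <- sample_window(n_clumps, window, shrink = 1 - 4 * s /
                                 window_scale(window))
      n_per <- rpois(n_clumps, mu)
      cp <- tibble(
        x_um = rep(centers$x_um, n_per) + rnorm(sum(n_per), 0, s),
        y_um = rep(centers$y_um, n_per) + rnorm(sum(n_per), 0, s),
        type = "clump"
      )
      cp <- cp[in_window(cp$x_um, cp$y_um, window), ]
      pts <- bind_rows(pts, cp)
    }
    list(points = pts, window = window, clump_centers = centers,
         mu_per_clump = mu, seed = seed)
  })
}

window_area <- function(window) {
  switch(window$shape,
    disc = pi * window$radius_um^2,
    rect = window$width_um * window$height_um,
    abort("unknown window shape")
  )
}

window_scale <- function(window) {
  switch(window$shape,
    disc = 2 * window$radius_um,
    rect = min(window$width_um, window$height_um)
  )
}

in_window <- function(x, y, window) {
  switch(window$shape,
    disc = x^2 + y^2 <= window$radius_um^2,
    rect = abs(x) <= window$width_um / 2 & abs(y) <= window$height_um / 2
  )
}

sample_window <- function(n, window, shrink = 1) {
  shrink <- max(min(shrink, 1), 0.1)
  if (window$shape == "disc") {
    r <- window$radius_um * shrink * sqrt(runif(n))
    a <- runif(n, 0, 2 * pi)
    tibble(x_um = r * cos(a), y_um = r * sin(a))
  } else {
    tibble(
      x_um = runif(n, -window$width_um / 2, window$width_um / 2) * shrink,
      y_um = runif(n, -window$height_um / 2, window$height_um / 2) * shrink
    )
  }
}

#' Simulate a time-projected maxima map with confinement areas
#'
#' Emulates the projection of per-frame local maxima over a short video:
#' `n_clumps` confinement areas, each occupied per frame with probability
#' `occupancy` and scattered with per-axis sd `sigma_scatter_um`, over a
#' Poisson background whose density is set by the relative peak density
#' `rho_prime`.
#'
#' @param n_frames Number of frames projected.
#' @param occupancy Per-frame presence probability of each confinement area.
#' @param sigma_scatter_um Per-axis scatter of maxima within a confinement
#'   area (um); the pair-correlation width this plants is
#'   `2 * sigma_scatter_um`.
#' @param n_clumps Number of confinement areas.
#' @param rho_prime Target pair-correlation amplitude of the confinement
#'   signal over the Poisson background; sets the background density.
#' @param radius_um Nuclear cross-section radius (disc window).
#' @param seed Integer seed.
#' @return As [generate_point_pattern()]; the per-frame occupancy draws are
#'   binomial, and the planted pair-correlation width is
#'   `2 * sigma_scatter_um`.
#' @export
simulate_projection_map <- function(n_frames = 60, occupancy = 0.6,
                                    sigma_scatter_um = 0.185, n_clumps = 4,
                                    rho_prime = 8, radius_um = 2.5, seed = 1) {
  window <- list(shape = "disc", radius_um = radius_um)
  A <- window_area(window)
  mu <- occupancy * n_frames
  s <- sigma_scatter_um
  # pair-density identity: amplitude = n_clumps mu^2 / (4 pi s^2 A rho_tot^2)
  rho_tot <- sqrt(n_clumps * mu^2 / (4 * pi * s^2 * A * rho_prime))
  rho_bg <- rho_tot - n_clumps * mu / A
  if (rho_bg <= 0) {
    abort("confinement preset leaves no room for a Poisson background; lower `rho_prime` or `occupancy`")
  }
  with_seed(local_seed(seed, 6L), {
    bg <- sample_window(rpois(1, rho_bg * A), window)
    bg$type <- "poisson"
    centers <- sample_window(n_clumps, window, shrink = 1 - 4 * s /
                               window_scale(window))
    n_per <- rbinom(n_clumps, n_frames, occupancy)
    cp <- tibble(
      x_um = rep(centers$x_um, n_per) + rnorm(sum(n_per), 0, s),
      y_um = rep(centers$y_um, n_per) + rnorm(sum(n_per), 0, s),
      type = "clump"
    )
    cp <- cp[in_window(cp$x_um, cp$y_um, window), ]
    list(points = bind_rows(bg, cp), window = window,
         clump_centers = centers, mu_per_clump = mu, seed = seed)
  })
}

#' Generate a 2D field of sub-resolution beads
#'
#' Well-separated point emitters blurred by the PSF on a single plane, for
#' PSF calibration via pixel correlation. Beads closer than 3x the PSF sigma
#' are re-drawn.
#'
#' @param acq An [acquisition_params()] object.
#' @param n_beads Number of beads (>= 1).
#' @param seed Integer seed.
#' @param fov_um Square field of view (um). Default 10.
#' @param amplitude Peak bead intensity. Default 80.
#' @param noise Apply shot/read noise. Default `TRUE`.
#' @return A list with `stack` (kind `"2d"`) and `truth` (bead positions).
#' @export
generate_bead_field <- function(acq, n_beads, seed, fov_um = 10,
                                amplitude = 80, noise = TRUE) {
  if (n_beads < 1) abort("`n_beads` must be >= 1")
  with_seed(local_seed(seed, 7L), {
    vx <- acq$voxel_xy / 1000
    n_px <- as.integer(ceiling(fov_um / vx))
    psf_px <- acq$psf_sigma_lateral / acq$voxel_xy
    min_sep <- 3 * psf_px
    pos <- matrix(runif(2 * n_beads, 1 + 4 * psf_px, n_px - 4 * psf_px), ncol = 2)
    repeat {
      if (n_beads == 1) break
      dmat <- as.matrix(stats::dist(pos))
      diag(dmat) <- Inf
      clash <- which(apply(dmat, 1, min) < min_sep)
      if (length(clash) == 0) break
      pos[clash, ] <- matrix(runif(2 * length(clash), 1 + 4 * psf_px,
                                   n_px - 4 * psf_px), ncol = 2)
    }
    img <- array(1, c(n_px, n_px)) # faint uniform offset
    for (i in seq_len(n_beads)) {
      img <- add_gaussian_spot(img, pos[i, 1], pos[i, 2], NA, amplitude,
                               psf_px, psf_px, 0, NA)
    }
    if (noise) img <- apply_noise(img, acq)
    list(
      stack = image_stack(list(beads = img), acq, kind = "2d"),
      truth = tibble(bead = seq_len(n_beads), x_px = pos[, 1], y_px = pos[, 2])
    )
  })
}

#' Write an image stack to TIFF
#'
#' Writes each channel as a multi-page 32-bit float TIFF (one page per
#' z-slice or frame) next to a JSON sidecar with the acquisition parameters.
#' Requires the `tiff` package.
#'
#' @param stack An [image_stack()].
#' @param dir Output directory.
#' @param prefix File-name prefix. Default `"stack"`.
#' @return Invisibly, the written file paths.
#' @export
write_stack_tiff <- function(stack, dir, prefix = "stack") {
  stopifnot(inherits(stack, "image_stack"))
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required for TIFF export")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (ch in names(stack$channels)) {
    arr <- stack$channels[[ch]]
    sc <- max(arr)
    pages <- if (length(dim(arr)) == 3L) {
      lapply(seq_len(dim(arr)[3]), function(k) t(arr[, , k]) / sc)
    } else {
      list(t(arr) / sc)
    }
    p <- file.path(dir, sprintf("%s_%s.tif", prefix, ch))
    tiff::writeTIFF(pages, p, bits.per.sample = 32L)
    paths <- c(paths, p)
  }
  meta <- file.path(dir, paste0(prefix, "_acq.json"))
  jsonlite::write_json(unclass(stack$acq), meta, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, meta))
}
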