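# Pixel autocorrelation with correlation-length extraction, and FFT-based
# pair correlation of 2D point patterns with Gaussian-clump model fits.

#' Pixel autocorrelation of an image region
#'
#' Computes the lagged autocorrelation of pixel rows (and columns) restricted
#' to a mask, averages over rows, then columns, then combines the two axes.
#' Each maximal contiguous in-mask run of at least `min_run` pixels is treated
#' as one series; the estimator is the biased (1/T-normalised) sample
#' autocorrelation, so `c(0) = 1`.
#'
#' @param image 2D numeric matrix.
#' @param mask Logical matrix of the same size selecting the region
#'   (e.g. nuclear pixels), or `NULL` for the whole image.
#' @param max_lag Maximum lag in pixels. Default 30.
#' @param invert_mask If `TRUE`, use pixels outside the mask (e.g. cytoplasm).
#' @param pixel_nm Physical pixel size (nm) used to report lags in nm;
#'   default 43.
#' @param min_run Minimum contiguous run length used. Default 8.
#'
#' @return A `corr_curve`: a tibble with `lag_px`, `lag_nm`, `c` (combined
#'   correlation) and `n` (number of contributing series), with per-axis
#'   curves in `attr(, "by_axis")`.
#' @export
pixel_autocorrelation <- function(image, mask = NULL, max_lag = 30,
                                  invert_mask = FALSE, pixel_nm = 43,
                                  min_run = 8) {
  stopifnot(is.matrix(image))
  if (is.null(mask)) mask <- array(TRUE, dim(image))
  if (invert_mask) mask <- !mask
  if (sd(image[mask]) == 0) {
    warn("zero-variance region: correlation curve undefined")
    out <- tibble(lag_px = 0:max_lag, lag_nm = (0:max_lag) * pixel_nm,
                  c = NA_real_, n = 0L)
    return(structure(out, class = c("corr_curve", class(out)),
                     degenerate = TRUE, pixel_nm = pixel_nm))
  }
  axis_curve <- function(im, ms) {
    acc <- numeric(max_lag + 1)
    cnt <- numeric(max_lag + 1)
    for (i in seq_len(nrow(im))) {
      r <- rle(ms[i, ])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (s in which(r$values & r$lengths >= min_run)) {
        x <- im[i, starts[s]:ends[s]]
        lm <- min(max_lag, length(x) - 1)
        a <- acf(x, lag.max = lm, plot = FALSE, demean = TRUE)$acf[, 1, 1]
        idx <- seq_len(lm + 1)
        acc[idx] <- acc[idx] + a
        cnt[idx] <- cnt[idx] + 1
      }
    }
    list(c = ifelse(cnt > 0, acc / cnt, NA_real_), n = cnt)
  }
  cx <- axis_curve(image, mask)          # along rows of the matrix (x axis)
  cy <- axis_curve(t(image), t(mask))    # along columns (y axis)
  if (all(cx$n == 0) && all(cy$n == 0)) {
    abort("degenerate mask: no contiguous runs of the required length")
  }
  comb <- rowMeans(cbind(cx$c, cy$c), na.rm = TRUE)
  out <- tibble(
    lag_px = 0:max_lag, lag_nm = (0:max_lag) * pixel_nm,
    c = comb, n = as.integer(cx$n + cy$n)
  )
  out <- out[out$n > 0 & is.finite(out$c), ]
  structure(out, class = c("corr_curve", class(out)),
            by_axis = list(
              x = tibble(lag_px = 0:max_lag, c = cx$c, n = cx$n),
              y = tibble(lag_px = 0:max_lag, c = cy$c, n = cy$n)
            ),
            pixel_nm = pixel_nm, degenerate = FALSE)
}

#' Fit an exponential correlation length to a correlation curve
#'
#' Least-squares fit of `y(x) = a + b * exp(-c * x)` to a decaying
#' correlation curve. The correlation length is
#' `lambda = x0 + log(2) / c`, where `x0` is the smallest lag included in the
#' fit (0 when lag zero is included), and its error is
#' `sigma_lambda = lambda * sigma_c / c`.
#'
#' @param curve A `corr_curve` from [pixel_autocorrelation()], or any data
#'   frame with columns `lag_px` (or `lag`) and `c`.
#' @param max_lag_px Optional upper lag limit for the fit.
#' @param min_lag_px Smallest lag included (default 0; becomes `x0`).
#' @return A `corr_length_fit` object: coefficients `a`, `b`, `c`,
#'   `lambda_px` / `lambda_nm`, `sigma_lambda_px` / `sigma_lambda_nm`,
#'   `converged`, and the underlying `nls` fit.
#' @export
fit_correlation_length <- function(curve, max_lag_px = NULL, min_lag_px = 0) {
  df <- as.data.frame(curve)
  if (!"lag_px" %in% names(df) && "lag" %in% names(df)) df$lag_px <- df$lag
  stopifnot(all(c("lag_px", "c") %in% names(df)))
  df <- df[is.finite(df$c) & df$lag_px >= min_lag_px, ]
  if (!is.null(max_lag_px)) df <- df[df$lag_px <= max_lag_px, ]
  if (nrow(df) < 5) abort("need at least 5 lags to fit a correlation length")
  pixel_nm <- attr(curve, "pixel_nm") %||% NA_real_
  x0 <- min(df$lag_px)
  span <- diff(range(df$lag_px))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      c ~ a + b * exp(-cc * lag_px),
      data = df,
      start = list(a = min(df$c), b = max(df$c) - min(df$c), cc = 4 / span),
      lower = c(a = -Inf, b = 1e-12, cc = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(list(converged = FALSE), class = "corr_length_fit"))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  lambda_px <- x0 + log(2) / cf[["cc"]]
  sigma_lambda_px <- lambda_px * se[[3]] / cf[["cc"]]
  structure(list(
    a = cf[["a"]], b = cf[["b"]], c = cf[["cc"]],
    sigma_c = se[[3]], x0 = x0,
    lambda_px = lambda_px, sigma_lambda_px = sigma_lambda_px,
    lambda_nm = lambda_px * pixel_nm, sigma_lambda_nm = sigma_lambda_px * pixel_nm,
    converged = TRUE, fit = fit
  ), class = "corr_length_fit")
}

#' @export
print.corr_length_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<corr_length_fit> fit did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("<corr_length_fit> lambda = %.3f px", x$lambda_px))
  if (is.finite(x$lambda_nm)) {
    cat(sprintf(" (%.1f +/- %.1f nm)", x$lambda_nm, x$sigma_lambda_nm))
  }
  cat(sprintf("; y = %.3g + %.3g exp(-%.3g x)\n", x$a, x$b, x$c))
  invisible(x)
}

#' Measure the correlation length of an image region
#'
#' Convenience wrapper: [pixel_autocorrelation()] followed by
#' [fit_correlation_length()]. By default the zero lag is excluded from the
#' fit (it carries the uncorrelated shot/read-noise variance), so the first
#' fitted lag becomes `x0` in `lambda = x0 + log(2) / c`.
#'
#' @inheritParams pixel_autocorrelation
#' @param min_lag_px Smallest lag included in the fit. Default 1.
#' @return A `corr_length_fit`.
#' @export
measure_correlation_length <- function(image, mask = NULL, max_lag = 25,
                                       invert_mask = FALSE, pixel_nm = 43,
                                       min_lag_px = 1) {
  curve <- pixel_autocorrelation(image, mask, max_lag = max_lag,
                                 invert_mask = invert_mask, pixel_nm = pixel_nm)
  if (isTRUE(attr(curve, "degenerate"))) {
    return(structure(list(converged = FALSE), class = "corr_length_fit"))
  }
  fit_correlation_length(curve, min_lag_px = min_lag_px)
}

# Wrap-around lag components of an FFT-periodic array.
fft_lags <- function(n) {
  k <- seq_len(n) - 1
  ifelse(k > n / 2, k - n, k)
}

#' FFT pair-correlation of a 2D point pattern
#'
#' Rasterises the points onto a pixel grid, computes
#' `g = IFFT(|FFT(I)|^2) / (rho^2 * IFFT(|FFT(W)|^2))` with `W` the window
#' indicator (edge correction), removes the self-pair contribution at zero
#' lag, and radially averages with 1-pixel bins.
#'
#' @param points Data frame with `x_um`, `y_um` (or the list returned by
#'   [generate_point_pattern()]).
#' @param window Window specification as in [generate_point_pattern()];
#'   taken from the input list if present.
#' @param pixel_um Raster pixel size (um). Default 0.05.
#' @param r_max_um Maximum radius retained (default: half the window scale).
#' @return A `pair_corr` object: tibble with `r_um`, `g`, `n_px`; the point
#'   count and density are kept as attributes.
#' @export
pair_correlation_map <- function(points, window = NULL, pixel_um = 0.05,
                                 r_max_um = NULL) {
  if (is.list(points) && !is.data.frame(points) && !is.null(points$points)) {
    window <- window %||% points$window
    points <- points$points
  }
  if (is.null(window)) abort("`window` must be supplied")
  pts <- as.data.frame(points)
  keep <- in_window(pts$x_um, pts$y_um, window)
  pts <- pts[keep, ]
  n_pts <- nrow(pts)
  if (n_pts < 10) abort("need at least 10 points inside the window")
  half <- window_scale(window) / 2
  n_px <- as.integer(ceiling(2 * half / pixel_um)) + 1L
  # indicator rasters on the window bounding box
  ix <- pmin(pmax(floor((pts$x_um + half) / pixel_um) + 1L, 1L), n_px)
  iy <- pmin(pmax(floor((pts$y_um + half) / pixel_um) + 1L, 1L), n_px)
  # fractional-coverage window raster (4x4 subpixel sampling): boundary
  # pixels enter the edge-correction denominator with their true area
  sub <- 4L
  fine <- ((seq_len(n_px * sub)) - 0.5) * pixel_um / sub - half
  Wf <- outer(fine, fine, function(a, b) in_window(a, b, window)) * 1
  W <- matrix(0, n_px, n_px)
  for (i in seq_len(sub)) {
    for (j in seq_len(sub)) {
      W <- W + Wf[seq(i, n_px * sub, by = sub), seq(j, n_px * sub, by = sub)]
    }
  }
  W <- W / sub^2
  I <- matrix(0, n_px, n_px)
  for (k in seq_len(n_pts)) I[ix[k], iy[k]] <- I[ix[k], iy[k]] + 1
  # zero-pad 2x to kill wrap-around
  np <- 2L * n_px
  Ip <- matrix(0, np, np); Ip[1:n_px, 1:n_px] <- I
  Wp <- matrix(0, np, np); Wp[1:n_px, 1:n_px] <- W
  num <- Re(fft(Mod(fft(Ip))^2, inverse = TRUE)) / (np * np)
  den <- Re(fft(Mod(fft(Wp))^2, inverse = TRUE)) / (np * np)
  num[1, 1] <- num[1, 1] - n_pts  # remove self-pairs
  rho_px <- n_pts / sum(W)        # points per window pixel
  g <- ifelse(den > 0.5, num / (rho_px^2 * den), NA_real_)
  lag <- fft_lags(np)
  r_px <- sqrt(outer(lag^2, lag^2, `+`))
  rb <- floor(r_px + 0.5)
  r_max_um <- r_max_um %||% half
  keep <- is.finite(g) & rb <= r_max_um / pixel_um
  gm <- tapply(g[keep], rb[keep], mean)
  nn <- tapply(rep(1, sum(keep)), rb[keep], sum)
  out <- tibble(
    r_um = as.numeric(names(gm)) * pixel_um,
    g = as.numeric(gm),
    n_px = as.numeric(nn)
  ) |> arrange(.data$r_um)
  if (any(out$g > 100, na.rm = TRUE)) {
    warn("pair correlation diverges near r = 0 (degenerate point pattern?)")
  }
  structure(out, class = c("pair_corr", class(out)),
            n_points = n_pts, rho_um2 = n_pts / window_area(window),
            pixel_um = pixel_um)
}

#' Fit the Gaussian-clump model to a pair-correlation curve
#'
#' Least-squares fit of `g(r) = rho_prime * exp(-(r / sigma)^2) + 1`. The
#' effective confinement radius `xi_pair` is reported as the fitted `sigma`.
#'
#' @param pc A `pair_corr` object (or data frame with `r_um`, `g`).
#' @param r_max_um Optional fit range limit.
#' @param r_min_um Smallest radius included (default 0; the r = 0 bin is
#'   excluded automatically by the estimator).
#' @return A `pair_corr_fit`: `rho_prime`, `sigma_um`, `xi_pair_um`,
#'   standard errors, `converged`, and the `nls` fit.
#' @export
fit_pair_correlation <- function(pc, r_max_um = NULL, r_min_um = 0) {
  df <- as.data.frame(pc)
  stopifnot(all(c("r_um", "g") %in% names(df)))
  df <- df[is.finite(df$g) & df$r_um >= r_min_um, ]
  if (!is.null(r_max_um)) df <- df[df$r_um <= r_max_um, ]
  if (nrow(df) < 5) abort("too few radial bins to fit")
  g0 <- max(df$g[df$r_um <= quantile(df$r_um, 0.2)], na.rm = TRUE)
  sig0 <- max(df$r_um[which(df$g > 1 + (g0 - 1) / 2)], df$r_um[2], na.rm = TRUE)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      g ~ rho_p * exp(-(r_um / sigma)^2) + 1,
      data = df,
      start = list(rho_p = max(g0 - 1, 0.1), sigma = sig0),
      lower = c(rho_p = 0, sigma = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(list(converged = FALSE), class = "pair_corr_fit"))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 2))
  structure(list(
    rho_prime = cf[["rho_p"]], sigma_um = cf[["sigma"]],
    xi_pair_um = cf[["sigma"]],
    se_rho_prime = se[[1]], se_sigma = se[[2]],
    converged = TRUE, fit = fit
  ), class = "pair_corr_fit")
}

#' @export
print.pair_corr_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<pair_corr_fit> fit did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("<pair_corr_fit> rho' = %.2f, sigma (xi_pair) = %.3f um\n",
              x$rho_prime, x$sigma_um))
  invisible(x)
}
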