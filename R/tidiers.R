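# broom-style tidiers for the package's fitted objects.

#' Tidy a correlation-length fit
#'
#' @param x A `corr_length_fit`.
#' @param ... Unused.
#' @return One row per coefficient (`a`, `b`, `c`) plus the derived
#'   correlation length.
#' @export
tidy.corr_length_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    return(tibble(term = character(0), estimate = numeric(0),
                  std.error = numeric(0)))
  }
  tibble(
    term = c("a", "b", "c", "lambda_px"),
    estimate = c(x$a, x$b, x$c, x$lambda_px),
    std.error = c(NA, NA, x$sigma_c, x$sigma_lambda_px)
  )
}

#' @rdname tidy.corr_length_fit
#' @export
glance.corr_length_fit <- function(x, ...) {
  tibble(
    lambda_px = x$lambda_px %||% NA_real_,
    lambda_nm = x$lambda_nm %||% NA_real_,
    sigma_lambda_nm = x$sigma_lambda_nm %||% NA_real_,
    converged = isTRUE(x$converged)
  )
}

#' Tidy a pair-correlation fit
#'
#' @param x A `pair_corr_fit`.
#' @param ... Unused.
#' @export
tidy.pair_corr_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    return(tibble(term = character(0), estimate = numeric(0),
                  std.error = numeric(0)))
  }
  tibble(
    term = c("rho_prime", "sigma_um"),
    estimate = c(x$rho_prime, x$sigma_um),
    std.error = c(x$se_rho_prime, x$se_sigma)
  )
}

#' @rdname tidy.pair_corr_fit
#' @export
glance.pair_corr_fit <- function(x, ...) {
  tibble(
    rho_prime = x$rho_prime %||% NA_real_,
    xi_pair_um = x$xi_pair_um %||% NA_real_,
    converged = isTRUE(x$converged)
  )
}

#' Tidy a gradient fit
#'
#' @param x A `gradient_fit`.
#' @param ... Unused.
#' @export
tidy.gradient_fit <- function(x, ...) {
  terms <- c("intercept", "slope")
  est <- c(x$intercept, x$slope)
  se <- c(NA_real_, x$sigma_slope)
  if (!is.null(x$lambda)) {
    terms <- c(terms, "lambda")
    est <- c(est, x$lambda)
    se <- c(se, x$sigma_lambda)
  }
  tibble(term = terms, estimate = est, std.error = se)
}

#' @rdname tidy.gradient_fit
#' @export
glance.gradient_fit <- function(x, ...) {
  tibble(
    slope = x$slope, sigma_slope = x$sigma_slope,
    r.squared = x$r_squared,
    lambda = x$lambda %||% NA_real_,
    sigma_lambda = x$sigma_lambda %||% NA_real_,
    n = x$n
  )
}

#' Tidy an accumulation fit
#'
#' @param x An `accumulation_fit`.
#' @param ... Unused.
#' @export
tidy.accumulation_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    return(tibble(term = character(0), estimate = numeric(0)))
  }
  tibble(
    term = c("k0", "x0", "a0", "k1", "x1", "a1", "r0_um"),
    estimate = c(x$k0, x$x0, x$a0, x$k1, x$x1, x$a1, x$r0_um)
  )
}

#' @rdname tidy.accumulation_fit
#' @export
glance.accumulation_fit <- function(x, ...) {
  tibble(
    r0_um = x$r0_um %||% NA_real_,
    se_r0_um = x$se_r0_um %||% NA_real_,
    central_component = isTRUE(x$central_component),
    converged = isTRUE(x$converged)
  )
}

#' Tidy persistence statistics
#'
#' @param x A `persistence_stats`.
#' @param ... Unused.
#' @export
tidy.persistence_stats <- function(x, ...) {
  tibble(
    term = c("ton_s", "toff_s", "detection_probability", "occupancy_raw"),
    estimate = c(x$ton, x$toff, x$detection_probability, x$occupancy_raw)
  )
}

#' Tidy a molecule budget
#'
#' @param x A `molecule_budget`.
#' @param ... Unused.
#' @export
tidy.molecule_budget <- function(x, ...) {
  tibble(
    term = c("n0", "nuclear_density", "cluster_concentration",
             "cluster_volume_um3", "molecules_per_cluster", "cluster_fraction"),
    estimate = c(x$n0, x$nuclear_density, x$cluster_concentration,
                 x$cluster_volume_um3, x$molecules_per_cluster,
                 x$cluster_fraction)
  )
}
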