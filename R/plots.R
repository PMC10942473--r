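# ggplot2 display methods for the package's result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_col labs theme_minimal stat_function geom_errorbar scale_y_log10
NULL

#' @export
ggplot2::autoplot

#' Plot a pixel-correlation curve
#'
#' @param object A `corr_curve` from [pixel_autocorrelation()].
#' @param fit Optional `corr_length_fit` overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.corr_curve <- function(object, fit = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot(df, aes(x = .data$lag_px, y = .data$c)) +
    geom_point(size = 1) +
    geom_line(alpha = 0.4) +
    labs(x = "lag (px)", y = "pixel correlation c") +
    theme_minimal()
  if (!is.null(fit) && isTRUE(fit$converged)) {
    p <- p + stat_function(
      fun = function(x) fit$a + fit$b * exp(-fit$c * x),
      colour = "firebrick"
    )
  }
  p
}

#' Plot a pair-correlation curve
#'
#' @param object A `pair_corr` from [pair_correlation_map()].
#' @param fit Optional `pair_corr_fit` overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pair_corr <- function(object, fit = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot(df, aes(x = .data$r_um, y = .data$g)) +
    geom_point(size = 1) +
    geom_hline(yintercept = 1, linetype = "dashed") +
    labs(x = "r (um)", y = "g(r)") +
    theme_minimal()
  if (!is.null(fit) && isTRUE(fit$converged)) {
    p <- p + stat_function(
      fun = function(x) fit$rho_prime * exp(-(x / fit$sigma_um)^2) + 1,
      colour = "firebrick"
    )
  }
  p
}

#' Plot a binned gradient table
#'
#' Per-bin bootstrap means with error bars, on a log scale for exponential
#' gradients.
#'
#' @param object A `gradient_table` from [bin_and_bootstrap()].
#' @param log_scale Use a log y-axis. Default `TRUE`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gradient_table <- function(object, log_scale = TRUE, ...) {
  df <- as_tibble(object)
  p <- ggplot(df, aes(x = .data$x_mid, y = .data$mean, colour = .data$quantity)) +
    geom_point() +
    geom_errorbar(aes(ymin = .data$mean - .data$sd_boot,
                      ymax = .data$mean + .data$sd_boot), width = 0.01) +
    labs(x = "x / L", y = "bin mean (bootstrap +/- sd)") +
    theme_minimal()
  if (log_scale) p <- p + scale_y_log10()
  p
}

#' Plot a radial accumulation profile
#'
#' @param object A `radial_profile`.
#' @param fit Optional `accumulation_fit` overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.radial_profile <- function(object, fit = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot(df, aes(x = .data$r_um, y = .data$Ir)) +
    geom_point() +
    geom_line(alpha = 0.4) +
    labs(x = "r (um)", y = "mean TF intensity") +
    theme_minimal()
  if (!is.null(fit) && isTRUE(fit$converged)) {
    p <- p + stat_function(
      fun = function(x) {
        fit$k0 * exp(-((x - fit$x0) / fit$a0)^2) +
          fit$k1 * exp(-((x - fit$x1) / fit$a1)^2)
      },
      colour = "firebrick"
    )
  }
  p
}

#' Plot nearest-cluster distance distribution and coupling threshold
#'
#' @param object A `coupling_result` from [coupling_fraction()].
#' @param ... Unused.
#' @return A ggplot of the empirical CDF with the `r0` threshold marked.
#' @export
autoplot.coupling_result <- function(object, ...) {
  d <- sort(object$distances$nearest_um)
  df <- tibble(r_um = d, cdf = seq_along(d) / length(d))
  ggplot(df, aes(x = .data$r_um, y = .data$cdf)) +
    geom_line() +
    ggplot2::geom_vline(xintercept = object$r0_um, linetype = "dashed") +
    geom_hline(yintercept = object$coupling_fraction, linetype = "dotted") +
    labs(x = "nearest-cluster distance (um)", y = "cumulative probability") +
    theme_minimal()
}
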