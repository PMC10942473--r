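# Position binning with bootstrap errors, exponential-gradient fits,
# positional/concentration error propagation, and absolute molecule budgets.

#' Bin per-nucleus quantities along x/L with bootstrap errors
#'
#' Partitions nucleus records into position bins and reports, for each
#' requested quantity, the bootstrap mean and standard deviation obtained by
#' resampling nuclei within the bin (an equal number of resamples per draw).
#' Bins with fewer than `min_n` nuclei are dropped with a warning.
#'
#' @param records Data frame with `x_over_L` and the quantity columns.
#' @param quantities Character vector of column names to summarise.
#' @param bin_edges Numeric vector of bin edges over x/L. Default
#'   `seq(0.1, 0.7, by = 0.05)`.
#' @param n_boot Number of bootstrap draws. Default 1000.
#' @param seed Integer seed for the bootstrap.
#' @param min_n Minimum occupancy of a retained bin. Default 3.
#' @return A `gradient_table`: tibble with `bin`, `x_mid`, `n`, and per
#'   quantity `mean`, `sd` (bootstrap) and `cv = sd_sample / mean` columns
#'   in long format (`quantity`, `mean`, `sd_boot`, `sd_sample`, `cv`).
#' @export
bin_and_bootstrap <- function(records, quantities, bin_edges = seq(0.1, 0.7, 0.05),
                              n_boot = 1000, seed = 1, min_n = 3) {
  df <- as_tibble(records)
  stopifnot("x_over_L" %in% names(df), all(quantities %in% names(df)))
  if (n_boot < 100) abort("`n_boot` must be >= 100")
  if (any(diff(bin_edges) <= 0)) abort("`bin_edges` must be strictly increasing")
  df$bin <- cut(df$x_over_L, bin_edges, include.lowest = TRUE, labels = FALSE)
  df <- df[!is.na(df$bin), ]
  occup <- table(df$bin)
  drop_bins <- as.integer(names(occup)[occup < min_n])
  if (length(drop_bins) > 0) {
    warn(sprintf("dropping %d bin(s) with fewer than %d nuclei", length(drop_bins), min_n))
    df <- df[!df$bin %in% drop_bins, ]
  }
  if (nrow(df) == 0) {
    out <- tibble(bin = integer(0), x_mid = numeric(0), n = integer(0),
                  quantity = character(0), mean = numeric(0),
                  sd_boot = numeric(0), sd_sample = numeric(0), cv = numeric(0))
    return(structure(out, class = c("gradient_table", class(out)),
                     bin_edges = bin_edges))
  }
  rows <- list()
  with_seed(local_seed(seed, 8L), {
    for (b in sort(unique(df$bin))) {
      sub <- df[df$bin == b, ]
      n <- nrow(sub)
      for (q in quantities) {
        v <- sub[[q]]
        v <- v[is.finite(v)]
        if (length(v) == 0) next
        bm <- vapply(seq_len(n_boot),
                     function(i) mean(v[sample.int(length(v), replace = TRUE)]),
                     numeric(1))
        rows[[length(rows) + 1L]] <- tibble(
          bin = b,
          x_mid = (bin_edges[b] + bin_edges[b + 1]) / 2,
          n = n, quantity = q,
          mean = mean(bm), sd_boot = sd(bm),
          sd_sample = sd(v),
          cv = sd(v) / mean(v)
        )
      }
    }
  })
  out <- list_rbind(rows)
  structure(out, class = c("gradient_table", class(out)), bin_edges = bin_edges)
}

#' Fit an exponential gradient to binned data
#'
#' Ordinary least squares of `ln(mean)` (when `log_transform = TRUE`) or of
#' the raw mean against the bin midpoint `x/L` (or against another
#' predictor). For log fits the decay constant is `lambda = -1 / slope` with
#' `sigma_lambda = sigma_slope / slope^2`.
#'
#' @param table A `gradient_table` (or any data frame with `x_mid`/`x` and
#'   `mean`/value columns; a `quantity` column is filtered when present).
#' @param quantity Which quantity to fit (when the table is long).
#' @param log_transform Fit `ln(value)` vs x. Default `TRUE`.
#' @param predictor,response Optional explicit column names.
#' @return A `gradient_fit`: `slope`, `sigma_slope`, `intercept`,
#'   `r_squared`, and (for log fits) `lambda`, `sigma_lambda`.
#' @export
fit_gradient <- function(table, quantity = NULL, log_transform = TRUE,
                         predictor = NULL, response = NULL) {
  df <- as_tibble(table)
  if (!is.null(quantity) && "quantity" %in% names(df)) {
    df <- df[df$quantity == quantity, ]
  }
  xcol <- predictor %||% (if ("x_mid" %in% names(df)) "x_mid" else "x_over_L")
  ycol <- response %||% (if ("mean" %in% names(df)) "mean" else "value")
  stopifnot(xcol %in% names(df), ycol %in% names(df))
  x <- df[[xcol]]
  y <- df[[ycol]]
  ok <- is.finite(x) & is.finite(y)
  if (log_transform) {
    bad <- ok & y <= 0
    if (any(bad)) warn(sprintf("excluding %d non-positive value(s) from log fit", sum(bad)))
    ok <- ok & y > 0
  }
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) abort("need at least 4 bins to fit a gradient")
  yy <- if (log_transform) log(y) else y
  fit <- lm(yy ~ x)
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  slope <- cf[2, 1]
  sigma_slope <- cf[2, 2]
  out <- list(
    slope = slope, sigma_slope = sigma_slope,
    intercept = cf[1, 1],
    r_squared = sm$r.squared,
    log_transform = log_transform,
    n = length(x), fit = fit
  )
  if (log_transform) {
    out$lambda <- -1 / slope
    out$sigma_lambda <- sigma_slope / slope^2
  }
  structure(out, class = "gradient_fit")
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat(sprintf("<gradient_fit> slope = %.4g +/- %.2g, R^2 = %.3f",
              x$slope, x$sigma_slope, x$r_squared))
  if (!is.null(x$lambda)) {
    cat(sprintf(", lambda = %.4g +/- %.2g L", x$lambda, x$sigma_lambda))
  }
  cat("\n")
  invisible(x)
}

#' Positional error from gradient variability
#'
#' For an exponential gradient read out with per-bin coefficient of
#' variation `CV(x)`, simple error propagation through
#' `sigma(x) = delta_c(x) * |dc/dx|^(-1)` gives `sigma_x / L = CV(x) * lambda`.
#' Reported per bin and pooled (mean +/- sd across bins).
#'
#' @param cv Numeric vector of per-bin CVs, or a `gradient_table` (with
#'   `quantity` to select).
#' @param lambda Exponential decay constant (fraction of L).
#' @param quantity Quantity name when `cv` is a `gradient_table`.
#' @return A list: `per_bin` tibble (`cv`, `sigma_x`), `mean`, `sd`
#'   (pooled), all as fractions of L (multiply by 100 for %L).
#' @export
positional_error <- function(cv, lambda, quantity = NULL) {
  if (lambda <= 0) abort("`lambda` must be > 0")
  if (inherits(cv, "gradient_table") || is.data.frame(cv)) {
    df <- as_tibble(cv)
    if (!is.null(quantity) && "quantity" %in% names(df)) {
      df <- df[df$quantity == quantity, ]
    }
    cvv <- df$cv
  } else {
    cvv <- as.numeric(cv)
  }
  cvv <- cvv[is.finite(cvv)]
  sigma_x <- cvv * lambda
  list(
    per_bin = tibble(cv = cvv, sigma_x = sigma_x),
    mean = mean(sigma_x),
    sd = if (length(sigma_x) > 1) sd(sigma_x) else 0
  )
}

#' Errors in nuclear property estimation from cluster readouts
#'
#' Closed-form error propagation for using a cluster property `i` to
#' estimate (a) the nuclear concentration, via the slope `s` of the linear
#' property-vs-Inuc relation: `sigma_c = sigma_i / s` with
#' `sigma_sigma_c = sigma_c * sqrt((sigma_sigma_i / sigma_i)^2 + (sigma_s / s)^2)`;
#' and (b) the nuclear position, via the exponential decay constant:
#' `sigma_p = lambda * sigma_i / i` with
#' `sigma_sigma_p = sigma_p * sqrt((sigma_sigma_i / sigma_i)^2 +
#' (sigma_i / i)^2 + (sigma_lambda / lambda)^2)`.
#'
#' @param sigma_i Per-bin spread of the cluster property.
#' @param i_mean Per-bin mean of the cluster property.
#' @param s,sigma_s Slope of property vs nuclear intensity and its error.
#' @param lambda,sigma_lambda Decay constant (fraction of L) and its error.
#' @param sigma_sigma_i Error of `sigma_i` itself (default 0).
#' @return A `sensing_errors` tibble: `sigma_c`, `sigma_sigma_c`,
#'   `sigma_p`, `sigma_sigma_p` (vectorised over bins).
#' @export
estimation_errors <- function(sigma_i, i_mean, s, sigma_s, lambda,
                              sigma_lambda = 0, sigma_sigma_i = 0) {
  if (any(s == 0)) abort("slope `s` must be nonzero")
  if (any(i_mean <= 0)) abort("`i_mean` must be > 0")
  if (any(lambda <= 0)) abort("`lambda` must be > 0")
  sigma_c <- sigma_i / s
  sigma_sigma_c <- abs(sigma_c) *
    sqrt((sigma_sigma_i / sigma_i)^2 + (sigma_s / s)^2)
  sigma_p <- lambda * sigma_i / i_mean
  sigma_sigma_p <- abs(sigma_p) *
    sqrt((sigma_sigma_i / sigma_i)^2 + (sigma_i / i_mean)^2 +
           (sigma_lambda / lambda)^2)
  tibble(
    sigma_c = sigma_c, sigma_sigma_c = sigma_sigma_c,
    sigma_p = sigma_p, sigma_sigma_p = sigma_sigma_p
  )
}

#' Anterior molecule count from a flat-expression calibration
#'
#' A flat-expressing line with per-nucleus count `N0flat` carries the same
#' total as an exponential gradient `N0 * exp(-x / lambda)`; equating the
#' integrals over the embryo gives the widely used simplification
#' `N0 = N0flat * L / lambda`. The exact integral solution
#' `N0flat * (L / lambda) / (1 - exp(-L / lambda))` is returned as a
#' diagnostic.
#'
#' @param n0_flat Per-nucleus molecule count of the flat line.
#' @param lambda Gradient decay constant, in units of `L`.
#' @param L Embryo length in the same units (default 1, i.e. `lambda` as a
#'   fraction of L).
#' @return List with `n0` (simplified) and `n0_exact`.
#' @export
#' @examples
#' molecules_from_flat(8000, 0.2)$n0  # 40000
molecules_from_flat <- function(n0_flat, lambda, L = 1) {
  assert_scalar_pos(lambda, "lambda")
  assert_scalar_pos(L, "L")
  ratio <- L / lambda
  list(
    n0 = n0_flat * ratio,
    n0_exact = n0_flat * ratio / (1 - exp(-ratio))
  )
}

#' Molecules per cluster and the clustered fraction
#'
#' Budget chain from the anterior nuclear count: nuclear density
#' `N0 / ((pi/6) d_nuc^3)`, in-cluster concentration `amplification x
#' density`, cluster volume `(pi/6) d_clust^3`, molecules per cluster
#' `concentration x volume`, and the fraction of nuclear molecules residing
#' in clusters.
#'
#' @param n0 Molecules per anterior nucleus.
#' @param nucleus_diameter_um Nucleus diameter (um).
#' @param amplification In-cluster concentration amplification (Ia/Ibg).
#' @param cluster_diameter_um Average cluster diameter (um).
#' @param clusters_per_nucleus Average cluster count per nucleus.
#' @return A `molecule_budget` list: `nuclear_density`, `cluster_concentration`
#'   (molecules/um^3), `cluster_volume_um3`, `molecules_per_cluster`,
#'   `cluster_fraction`.
#' @export
#' @examples
#' molecule_budget(40000, 5, 2.2, 0.4, 55)
molecule_budget <- function(n0, nucleus_diameter_um, amplification,
                            cluster_diameter_um, clusters_per_nucleus) {
  for (v in c(n0, nucleus_diameter_um, amplification, cluster_diameter_um,
              clusters_per_nucleus)) {
    if (!is.numeric(v) || v <= 0) abort("all budget inputs must be positive")
  }
  nuclear_density <- n0 / (pi / 6 * nucleus_diameter_um^3)
  cluster_concentration <- amplification * nuclear_density
  cluster_volume <- pi / 6 * cluster_diameter_um^3
  mpc <- cluster_concentration * cluster_volume
  structure(list(
    n0 = n0,
    nuclear_density = nuclear_density,
    cluster_concentration = cluster_concentration,
    cluster_volume_um3 = cluster_volume,
    molecules_per_cluster = mpc,
    cluster_fraction = clusters_per_nucleus * mpc / n0
  ), class = "molecule_budget")
}

#' @export
print.molecule_budget <- function(x, ...) {
  cat("<molecule_budget>\n")
  cat(sprintf("  nuclear density: %.0f molecules/um^3\n", x$nuclear_density))
  cat(sprintf("  in-cluster concentration: %.0f molecules/um^3\n",
              x$cluster_concentration))
  cat(sprintf("  cluster volume: %.3f um^3\n", x$cluster_volume_um3))
  cat(sprintf("  molecules per cluster: %.1f\n", x$molecules_per_cluster))
  cat(sprintf("  clustered fraction of nuclear molecules: %.1f%%\n",
              100 * x$cluster_fraction))
  invisible(x)
}
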