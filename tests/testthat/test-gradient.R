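# Binning with bootstrap errors, exponential fits, error propagation, and
# the molecule budget.

test_that("bootstrap bin errors behave like standard errors of the mean", {
  # constant values: zero spread
  df0 <- tibble::tibble(x_over_L = runif(30, 0.3, 0.35), v = 5)
  t0 <- bin_and_bootstrap(df0, "v", bin_edges = c(0.3, 0.35), n_boot = 200, seed = 1)
  expect_equal(t0$sd_boot, 0)
  expect_equal(t0$cv, 0)
  # normal values: bootstrap sd ~ sigma / sqrt(n)
  set.seed(4)
  n <- 80
  df1 <- tibble::tibble(x_over_L = runif(n, 0.3, 0.35), v = rnorm(n, 10, 2))
  reps <- vapply(1:15, function(s) {
    bin_and_bootstrap(df1, "v", bin_edges = c(0.3, 0.35), n_boot = 400, seed = s)$sd_boot
  }, numeric(1))
  se_expect <- sd(df1$v) / sqrt(n)
  expect_lt(abs(mean(reps) - se_expect) / se_expect, 0.1)
  # determinism under a fixed seed
  ta <- bin_and_bootstrap(df1, "v", bin_edges = c(0.3, 0.35), n_boot = 300, seed = 7)
  tb <- bin_and_bootstrap(df1, "v", bin_edges = c(0.3, 0.35), n_boot = 300, seed = 7)
  expect_identical(ta, tb)
  # under-occupied bins are dropped with a warning
  df2 <- tibble::tibble(x_over_L = c(0.31, 0.32, 0.41), v = 1:3)
  expect_warning(bin_and_bootstrap(df2, "v", bin_edges = c(0.3, 0.4, 0.5),
                                   n_boot = 100, seed = 1), "dropping")
})

test_that("gradient fits recover exact and noisy decay constants", {
  x <- seq(0.1, 0.6, by = 0.05)
  tab <- tibble::tibble(x_mid = x, mean = 50 * exp(-x / 0.23), quantity = "Inuc")
  f <- fit_gradient(tab, "Inuc")
  expect_equal(f$lambda, 0.23, tolerance = 1e-9)
  expect_lt(f$sigma_lambda, 1e-9)
  expect_equal(f$r_squared, 1)
  # direct formula: s = -4 +/- 0.2 -> lambda 0.25 +/- 0.0125
  expect_equal(-1 / -4, 0.25)
  expect_equal(0.2 / (-4)^2, 0.0125)
  # non-positive values excluded from log fits with a warning
  tab_bad <- tibble::tibble(x_mid = x, mean = c(-1, tab$mean[-1]))
  expect_warning(fit_gradient(tab_bad), "non-positive")
})

test_that("calibrated synthetic fields return the planted decay constant", {
  lams <- vapply(1:8, function(s) {
    g <- simulate_nuclear_gradient(250, c(0.1, 0.65), lambda = 0.26, cv = 0.22,
                                   amplitude = 60, seed = s, quantity = "Ic")
    tab <- bin_and_bootstrap(g, "Ic", bin_edges = seq(0.1, 0.65, 0.05),
                             n_boot = 200, seed = s)
    fit_gradient(tab, "Ic")$lambda
  }, numeric(1))
  expect_lt(abs(mean(lams) - 0.26), 2 * sd(lams) / sqrt(length(lams)) + 0.005)
})

test_that("positional error is the product of CV and decay constant", {
  expect_equal(positional_error(0.10, 0.2)$mean, 0.02)
  expect_equal(positional_error(0, 0.2)$mean, 0)
  pe <- positional_error(c(0.2, 0.25, 0.22), 0.26)
  expect_equal(pe$per_bin$sigma_x, c(0.2, 0.25, 0.22) * 0.26)
  expect_error(positional_error(0.1, -1), "lambda")
  # product rule equals numerical error propagation on the fitted exponential
  lambda <- 0.26; cv <- 0.22; x <- 0.3
  cfun <- function(x) 50 * exp(-x / lambda)
  dc_dx <- (cfun(x + 1e-7) - cfun(x - 1e-7)) / 2e-7
  sigma_numeric <- cv * cfun(x) / abs(dc_dx)
  expect_equal(cv * lambda, sigma_numeric, tolerance = 1e-6)
})

test_that("closed-form estimation errors match Monte-Carlo propagation", {
  expect_equal(estimation_errors(1, 10, 2, 0, 0.25)$sigma_c, 0.5)
  expect_equal(estimation_errors(1, 10, 2, 0, 0.25, sigma_sigma_i = 0)$sigma_sigma_c, 0)
  # MC oracle: draw (sigma_i, s) ensembles and propagate by brute force
  set.seed(11)
  n_mc <- 1e4
  si <- rnorm(n_mc, 1, 0.08); sl <- rnorm(n_mc, 2, 0.1)
  mc_sd <- sd(si / sl)
  closed <- estimation_errors(1, 10, 2, 0.1, 0.25, sigma_sigma_i = 0.08)$sigma_sigma_c
  expect_lt(abs(mc_sd - closed) / closed, 0.05)
  expect_error(estimation_errors(1, 10, 0, 0, 0.25), "nonzero")
})

test_that("flat-line conversion and the molecule budget reproduce the worked chain", {
  mf <- molecules_from_flat(8000, 0.2)
  expect_equal(mf$n0, 40000)
  expect_equal(mf$n0_exact, 40000 / (1 - exp(-5)), tolerance = 1e-12)
  expect_equal(molecules_from_flat(3000, 1, L = 1)$n0, 3000)

  b <- molecule_budget(40000, 5, 2.2, 0.4, 55)
  expect_equal(round(b$nuclear_density, -2), 600)
  expect_equal(2.2 * 600, 1320)
  expect_equal(round(b$cluster_volume_um3, 2), 0.03)
  expect_equal(b$cluster_concentration, 2.2 * b$nuclear_density)
  # monotone: doubling amplification doubles molecules per cluster
  b2 <- molecule_budget(40000, 5, 4.4, 0.4, 55)
  expect_equal(b2$molecules_per_cluster, 2 * b$molecules_per_cluster)
  # clustered fraction in the expected 5-10% band at calibrated defaults
  expect_gt(b$cluster_fraction, 0.05)
  expect_lt(b$cluster_fraction, 0.10)
  expect_error(molecule_budget(-1, 5, 2, 0.4, 55), "positive")
})
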