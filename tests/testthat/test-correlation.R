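# Pixel autocorrelation, correlation-length fits, and FFT pair correlation
# against closed-form and brute-force oracles.

test_that("white noise decorrelates beyond lag zero and the curve is affine-invariant", {
  set.seed(2)
  img <- matrix(rnorm(150 * 150, 100, 10), 150, 150)
  cc <- pixel_autocorrelation(img, max_lag = 10)
  expect_equal(cc$c[1], 1)
  expect_lt(max(abs(cc$c[-1])), 0.03)
  cc2 <- pixel_autocorrelation(3.7 * img + 55, max_lag = 10)
  expect_equal(cc$c, cc2$c)
})

test_that("blurred white noise matches the closed-form Gaussian autocorrelation", {
  set.seed(4)
  sigma <- 3
  img <- EBImage::gblur(matrix(rnorm(256 * 256), 256, 256), sigma = sigma)
  cc <- pixel_autocorrelation(img, max_lag = 12)
  expect_lt(max(abs(cc$c - gaussian_noise_autocorr(cc$lag_px, sigma))), 0.05)
  # isotropy: x-axis and y-axis correlation lengths agree within 5%
  ax <- attr(cc, "by_axis")
  fx <- fit_correlation_length(ax$x)
  fy <- fit_correlation_length(ax$y)
  expect_lt(abs(fx$lambda_px - fy$lambda_px) / fx$lambda_px, 0.05)
})

test_that("correlation-length fit is exact on an analytic exponential curve", {
  x <- seq(0, 3, by = 0.05)
  curve <- data.frame(lag_px = x, c = 0.1 + 0.9 * exp(-x / 0.3))
  f <- fit_correlation_length(curve)
  expect_equal(f$lambda_px, log(2) * 0.3, tolerance = 1e-6)
  expect_equal(f$a, 0.1, tolerance = 1e-6)
  # x0 convention: dropping lag zero shifts x0 to the first retained lag
  f1 <- fit_correlation_length(curve, min_lag_px = 0.05)
  expect_equal(f1$x0, 0.05)
  expect_equal(f1$lambda_px, 0.05 + log(2) * 0.3, tolerance = 1e-4)
})

test_that("degenerate regions are flagged instead of fitted", {
  flat <- matrix(5, 40, 40)
  expect_warning(cc <- pixel_autocorrelation(flat, max_lag = 5), "zero-variance")
  expect_true(attr(cc, "degenerate"))
  f <- measure_correlation_length(flat)
  expect_false(f$converged)
})

test_that("bead fields recover the configured PSF correlation scale", {
  acq <- acquisition_params()
  psf_px <- acq$psf_sigma_lateral / acq$voxel_xy
  fits <- vapply(1:6, function(s) {
    bf <- generate_bead_field(acq, 25, seed = s)
    measure_correlation_length(bf$stack$channels$beads)$lambda_px
  }, numeric(1))
  # oracle: the same estimator applied to the closed-form autocorrelation
  # curve of a Gaussian of the configured PSF scale
  k <- 0:25
  oracle <- fit_correlation_length(
    data.frame(lag_px = k, c = gaussian_noise_autocorr(k, psf_px)),
    min_lag_px = 1
  )$lambda_px
  expect_lt(abs(mean(fits) - oracle) / oracle, 0.15)
})

test_that("clustered nuclei have longer correlation lengths than diffuse ones", {
  sim <- embryo_sim_params()
  acq <- acquisition_params()
  diff_len <- vapply(1:5, function(s) {
    g <- generate_nucleus_stack(sim, acq, 0.2, seed = s, mode = "homogeneous",
                                dim_2d = TRUE)
    f_clu <- measure_correlation_length(
      generate_nucleus_stack(sim, acq, 0.2, seed = s, dim_2d = TRUE)$stack$channels$tf,
      sphere_mask_of(g)
    )
    f_hom <- measure_correlation_length(g$stack$channels$tf, sphere_mask_of(g))
    f_clu$lambda_nm - f_hom$lambda_nm
  }, numeric(1))
  expect_gt(mean(diff_len), 0)
})

test_that("homogeneous Poisson patterns have flat pair correlation", {
  win <- list(shape = "disc", radius_um = 2.5)
  gm <- vapply(1:8, function(s) {
    pp <- generate_point_pattern(20, 0, 0.3, 0, win, seed = s)
    pc <- pair_correlation_map(pp, pixel_um = 0.05)
    mean(pc$g[pc$r_um > 0.3 & pc$r_um < 2])
  }, numeric(1))
  expect_lt(abs(mean(gm) - 1), 0.03)
})

test_that("FFT pair correlation agrees with the brute-force pair-distance oracle", {
  win <- list(shape = "disc", radius_um = 2.5)
  pp <- generate_point_pattern(6, 5, 0.4, 3, win, seed = 7)
  expect_lte(nrow(pp$points), 500)
  pc <- pair_correlation_map(pp, pixel_um = 0.05)
  bf <- brute_force_pair_correlation(pp$points, win, dr = 0.1, r_max = 1.3)
  # compare on matched radial bins over the structured range
  g_fft <- approx(pc$r_um, pc$g, xout = bf$r_um)$y
  keep <- bf$r_um > 0.1 & bf$r_um <= 1.25
  rel <- abs(g_fft[keep] - bf$g[keep]) / bf$g[keep]
  expect_lt(mean(rel), 0.05)
})

test_that("the Gaussian-clump fit is exact on analytic curves and flags degeneracy", {
  r <- seq(0.05, 2, by = 0.05)
  g <- 8 * exp(-(r / 0.37)^2) + 1
  f <- fit_pair_correlation(data.frame(r_um = r, g = g))
  expect_equal(f$rho_prime, 8, tolerance = 1e-8)
  expect_equal(f$sigma_um, 0.37, tolerance = 1e-8)
  expect_equal(f$rho_prime + 1, 9, tolerance = 1e-8)  # g(0) = rho' + 1
  # Poisson pattern through the estimator: amplitude ~ 0
  pp0 <- generate_point_pattern(25, 0, 0.3, 0, list(shape = "disc", radius_um = 2.5),
                                seed = 3)
  f0 <- fit_pair_correlation(pair_correlation_map(pp0, pixel_um = 0.05),
                             r_max_um = 1.6)
  expect_true(!isTRUE(f0$converged) || f0$rho_prime < 0.3)
  # coincident points diverge and warn
  pts <- data.frame(x_um = rep(0, 12), y_um = rep(0, 12))
  expect_warning(pair_correlation_map(pts, win <- list(shape = "disc", radius_um = 1)),
                 "diverges")
})

test_that("planted clump parameters are recovered by the full FFT pipeline", {
  res <- vapply(1:10, function(s) {
    pp <- simulate_projection_map(seed = s)
    f <- fit_pair_correlation(pair_correlation_map(pp, pixel_um = 0.05),
                              r_max_um = 1.6)
    c(f$rho_prime, f$sigma_um)
  }, numeric(2))
  expect_lt(abs(mean(res[1, ]) - 8) / 8, 0.2)
  expect_lt(abs(mean(res[2, ]) - 0.37) / 0.37, 0.2)
})
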