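# Generators: determinism, planted-statistics recovery, degenerate inputs,
# and the intensity-conservation identity.

test_that("nucleus stacks are deterministic and place the cluster at the voxel argmax", {
  sim <- embryo_sim_params(noise_cv = 0, fluct_cv = 0)
  acq <- acquisition_params(noise_read_sd = 0)
  g1 <- generate_nucleus_stack(sim, acq, 0.2, seed = 3, n_clusters = 1, noise = FALSE)
  g2 <- generate_nucleus_stack(sim, acq, 0.2, seed = 3, n_clusters = 1, noise = FALSE)
  expect_identical(g1$stack$channels$tf, g2$stack$channels$tf)
  expect_identical(g1$truth$clusters, g2$truth$clusters)
  am <- which(g1$stack$channels$tf == max(g1$stack$channels$tf), arr.ind = TRUE)[1, ]
  tc <- g1$truth$clusters
  expect_lt(abs(am[1] - tc$x_px), 1)
  expect_lt(abs(am[2] - tc$y_px), 1)
  expect_lt(abs(am[3] - tc$z_px), 1)

  # different seeds give different stacks
  g3 <- generate_nucleus_stack(sim, acq, 0.2, seed = 4, n_clusters = 1, noise = FALSE)
  expect_false(identical(g1$stack$channels$tf, g3$stack$channels$tf))
})

test_that("planted cluster statistics match the configured distributions", {
  sim <- embryo_sim_params()
  acq <- acquisition_params()
  f <- generate_embryo_field(sim, acq, n_nuclei = 500, x_range = c(0.2, 0.2001),
                             seed = 11)
  d <- f$clusters$d_app_nm
  # truncated-normal mean of the planted sizes (floor 150 lifts the mean a bit)
  alpha <- (sim$d_floor - sim$d_mean) / sim$d_sd
  mu_trunc <- sim$d_mean + sim$d_sd * dnorm(alpha) / (1 - pnorm(alpha))
  expect_lt(abs(mean(d) - mu_trunc), 2 * sd(d) / sqrt(length(d)))
  expect_lt(abs(sd(d) - sim$d_sd) / sim$d_sd, 0.1)
  r <- f$clusters$amp_ratio
  expect_lt(abs(mean(r) - sim$amp_ratio_mean), 2 * sd(r) / sqrt(length(r)) + 0.02)
  # independence of size and amplitude
  expect_lt(abs(cor(d, r)), 0.1)
  # census: mean count linear in Inuc
  expect_gt(cor(f$nuclei$Inuc_true, f$nuclei$n_clusters), 0)
})

test_that("degenerate truncation and empty inputs are rejected", {
  acq <- acquisition_params()
  expect_error(
    generate_nucleus_stack(embryo_sim_params(d_mean = 100, d_sd = 10, d_floor = 150),
                           acq, 0.2, seed = 1),
    "degenerate truncation"
  )
  expect_error(generate_embryo_field(embryo_sim_params(), acq, 0, c(0.1, 0.5), seed = 1))
  expect_error(generate_embryo_field(embryo_sim_params(), acq, 5, c(0.3, 0.3), seed = 1),
               "non-empty interval")
  expect_error(generate_timelapse(embryo_sim_params(), acq, n_frames = 1, seed = 1))
})

test_that("embryo-field gradient is exact without noise and recoverable with it", {
  acq <- acquisition_params()
  sim0 <- embryo_sim_params(lambda_gradient = 0.23, noise_cv = 0)
  f0 <- generate_embryo_field(sim0, acq, 50, c(0.1, 0.6), seed = 2)
  fit0 <- lm(log(Inuc_true) ~ x_over_L, data = f0$nuclei)
  expect_equal(unname(coef(fit0)[2]), -1 / 0.23, tolerance = 1e-10)

  sim1 <- embryo_sim_params(lambda_gradient = 0.23, noise_cv = 0.14)
  f1 <- generate_embryo_field(sim1, acq, 200, c(0.1, 0.6), seed = 2)
  fit1 <- lm(log(Inuc_true) ~ x_over_L, data = f1$nuclei)
  lam <- -1 / unname(coef(fit1)[2])
  expect_lt(abs(lam - 0.23) / 0.23, 0.1)
})

test_that("telegraph dynamics honour the dwell-time presets", {
  acq <- acquisition_params()
  # ton -> Inf: always on
  sim_inf <- embryo_sim_params(ton = Inf, toff = 1.6)
  tl <- generate_timelapse(sim_inf, acq, 40, seed = 1, n_clusters = 3, render = FALSE)
  expect_true(all(tl$truth$traces))
  # occupancy matches ton / (ton + toff)
  sim <- embryo_sim_params()
  occ <- mean(vapply(1:40, function(s) {
    mean(generate_timelapse(sim, acq, 60, seed = s, n_clusters = 4,
                            render = FALSE)$truth$traces)
  }, numeric(1)))
  p <- sim$ton / (sim$ton + sim$toff)
  expect_lt(abs(occ - p), 3 * sqrt(p * (1 - p) / (40 * 4 * 60)) + 0.02)
  # seeded traces identical
  t1 <- generate_timelapse(sim, acq, 30, seed = 9, render = FALSE)$truth$traces
  t2 <- generate_timelapse(sim, acq, 30, seed = 9, render = FALSE)$truth$traces
  expect_identical(t1, t2)
})

test_that("two-channel coupling labels are honoured and recoverable", {
  sim <- embryo_sim_params(coupling_fraction = 1)
  acq <- acquisition_params()
  tc1 <- generate_two_channel(sim, acq, "target-strong", n_nuclei = 30, seed = 5)
  nearest <- tapply(tc1$clusters$dist_hotspot_um, tc1$clusters$nucleus, min)
  expect_true(all(nearest < sim$accumulation_radius_um))

  sim2 <- embryo_sim_params(coupling_fraction = 0.57)
  tc2 <- generate_two_channel(sim2, acq, "target-strong", n_nuclei = 200, seed = 6)
  frac <- mean(tc2$nuclei$coupled_true)
  expect_lt(abs(frac - 0.57), 2 * sqrt(0.57 * 0.43 / 200))
  # planted labels consistent with the r0 geometry
  nearest2 <- tapply(tc2$clusters$dist_hotspot_um, tc2$clusters$nucleus, min)
  expect_equal(as.logical(nearest2 < sim2$accumulation_radius_um),
               tc2$nuclei$coupled_true)
})

test_that("point patterns span the Poisson and clustered classes", {
  win <- list(shape = "disc", radius_um = 2.5)
  pp0 <- generate_point_pattern(20, 0, 0.3, 0, win, seed = 1)
  expect_true(all(pp0$points$type == "poisson"))
  pp00 <- generate_point_pattern(20, 8, 0.3, 0, win, seed = 1)
  expect_true(all(pp00$points$type == "poisson"))  # n_clumps = 0 same class
  expect_error(generate_point_pattern(20, 0, 0.3, 0,
                                      list(shape = "rect", width_um = 0, height_um = 1),
                                      seed = 1), "empty window")
})

test_that("bead fields keep beads separated and symmetric", {
  acq <- acquisition_params()
  bf <- generate_bead_field(acq, 20, seed = 4)
  psf_px <- acq$psf_sigma_lateral / acq$voxel_xy
  dmat <- as.matrix(dist(as.matrix(bf$truth[, c("x_px", "y_px")])))
  diag(dmat) <- Inf
  expect_gte(min(dmat), 3 * psf_px)
  # single noiseless bead: circularly symmetric second moments
  b1 <- generate_bead_field(acq, 1, seed = 2, noise = FALSE)
  img <- b1$stack$channels$beads - 1  # remove the uniform offset
  cx <- b1$truth$x_px; cy <- b1$truth$y_px
  xs <- (round(cx) - 15):(round(cx) + 15)
  ys <- (round(cy) - 15):(round(cy) + 15)
  win <- img[xs, ys]
  wx <- rowSums(win); wy <- colSums(win)
  sd_x <- sqrt(sum(wx * (xs - cx)^2) / sum(wx))
  sd_y <- sqrt(sum(wy * (ys - cy)^2) / sum(wy))
  expect_equal(sd_x, sd_y, tolerance = 0.05)
  expect_equal(sd_x, psf_px, tolerance = 0.05)
})

test_that("noiseless voxel sums conserve background plus planted cluster volumes", {
  sim <- embryo_sim_params(noise_cv = 0, fluct_cv = 0)
  acq <- acquisition_params(noise_read_sd = 0)
  g_cl <- generate_nucleus_stack(sim, acq, 0.2, seed = 8, n_clusters = 12, noise = FALSE)
  g_bg <- generate_nucleus_stack(sim, acq, 0.2, seed = 8, mode = "homogeneous", noise = FALSE)
  tc <- g_cl$truth$clusters
  vx <- acq$voxel_xy
  s1 <- tc$sigma1_app_nm / vx
  s2 <- tc$sigma2_app_nm / vx
  sz <- clustersense:::cluster_axial_sigma((tc$sigma1_app_nm + tc$sigma2_app_nm) / 2, acq) /
    acq$voxel_z
  expected <- sum(tc$Ia * 2 * pi * s1 * s2 * sqrt(2 * pi) * sz)
  measured <- sum(g_cl$stack$channels$tf) - sum(g_bg$stack$channels$tf)
  expect_equal(measured, expected, tolerance = 0.02)
})

test_that("gradient quantity simulator matches its exponential model", {
  g <- simulate_nuclear_gradient(400, c(0.1, 0.65), lambda = 0.26, cv = 0,
                                 amplitude = 60, seed = 5, quantity = "Ic")
  fit <- lm(log(Ic) ~ x_over_L, data = g)
  expect_equal(unname(coef(fit)[2]), -1 / 0.26, tolerance = 1e-10)
  g2 <- simulate_nuclear_gradient(400, c(0.1, 0.65), lambda = 0.26, cv = 0.22,
                                  amplitude = 60, seed = 5)
  cvs <- sd(g2$value / (60 * exp(-g2$x_over_L / 0.26)))
  expect_lt(abs(cvs - 0.22), 0.03)
})
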