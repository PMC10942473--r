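# Iterative local-maxima detection, projection maps, and persistence
# statistics.

test_that("isolated spots are localised to within a pixel", {
  img <- matrix(1, 80, 80)
  img <- clustersense:::add_gaussian_spot(img, 40.3, 35.7, NA, 5, 3, 3, 0.01, NA)
  msk <- clustersense:::sphere_mask(c(80, 80), c(40, 40), 38)
  mm <- detect_local_maxima_2d(img, msk)
  expect_equal(nrow(mm), 1)
  expect_lt(abs(mm$x_px - 40.3), 1)
  expect_lt(abs(mm$y_px - 35.7), 1)
})

test_that("well-separated spots yield one centroid each", {
  img <- matrix(1, 120, 120)
  pos <- rbind(c(30, 30), c(30, 90), c(90, 30), c(90, 90), c(60, 60))
  for (i in 1:5) {
    img <- clustersense:::add_gaussian_spot(img, pos[i, 1], pos[i, 2], NA, 4, 3, 3, 0.01, NA)
  }
  mm <- detect_local_maxima_2d(img, matrix(TRUE, 120, 120))
  expect_equal(nrow(mm), 5)
  for (i in 1:5) {
    expect_lt(min(sqrt((mm$x_px - pos[i, 1])^2 + (mm$y_px - pos[i, 2])^2)), 2)
  }
})

test_that("detection is invariant under affine intensity rescaling", {
  sim <- embryo_sim_params()
  acq <- acquisition_params()
  g <- generate_nucleus_stack(sim, acq, 0.2, seed = 17, dim_2d = TRUE)
  msk <- sphere_mask_of(g)
  m1 <- detect_local_maxima_2d(g$stack$channels$tf, msk)
  m2 <- detect_local_maxima_2d(4.2 * g$stack$channels$tf + 100, msk)
  # identical binary maps; centroid weights shift by the affine offset only
  expect_equal(nrow(m1), nrow(m2))
  expect_equal(m1$n_px, m2$n_px)
  expect_equal(m1$x_px, m2$x_px, tolerance = 1e-3)
  expect_equal(m1$y_px, m2$y_px, tolerance = 1e-3)
})

test_that("the SSIM stopping rule plateaus within the iteration cap", {
  sim <- embryo_sim_params()
  acq <- acquisition_params()
  for (s in c(21, 22)) {
    g <- generate_nucleus_stack(sim, acq, 0.2, seed = s, dim_2d = TRUE)
    mm <- detect_local_maxima_2d(g$stack$channels$tf, sphere_mask_of(g), m_max = 20)
    m <- attr(mm, "m")
    trace <- attr(mm, "ssim_trace")
    expect_gte(m, 2)
    expect_lte(m, 20)
    # SSIM vs the first binary image decreases (or plateaus) with iteration
    expect_true(all(diff(trace) < 1e-3))
    expect_gt(nrow(mm), 0)
  }
})

test_that("all-subthreshold images give an empty, valid map", {
  img <- matrix(rnorm(50 * 50, 10, 0.01), 50, 50)
  img[1, 1] <- 100  # single bright pixel outside the mask drives Otsu up
  msk <- matrix(FALSE, 50, 50); msk[10:40, 10:40] <- TRUE
  mm <- detect_local_maxima_2d(img, msk)
  expect_s3_class(mm, "maxima_map")
  expect_error(detect_local_maxima_2d(img, matrix(FALSE, 50, 50)), "empty nucleus mask")
})

test_that("projection maps accumulate per-frame detections of a blinking spot", {
  # uniformly bright sites: dim clusters are legitimately missed by the
  # iterative thresholding (that is what the detection probability measures)
  sim <- embryo_sim_params(nucleus_diameter_um = 4, I0_anterior = 200,
                           noise_cv = 0, amp_ratio_mean = 2.5,
                           amp_ratio_sd = 0.3)
  acq <- acquisition_params()
  tl <- generate_timelapse(sim, acq, n_frames = 24, seed = 5, n_clusters = 3,
                           render = TRUE)
  pm <- project_maxima(tl$stack, tl$truth$mask)
  expect_true(all(c("frame", "x_px", "y_px") %in% names(pm)))
  expect_equal(attr(pm, "n_frames"), 24)
  # on-frames of each site carry a nearby maximum (noise maxima elsewhere in
  # the nucleus are expected and are rejected later by the size rules)
  cen <- tl$truth$centers
  for (i in seq_len(nrow(cen))) {
    on_frames <- which(tl$truth$traces[, i])
    hit <- vapply(on_frames, function(f) {
      sub <- pm[pm$frame == f, ]
      any((sub$x_px - cen$x_px[i])^2 + (sub$y_px - cen$y_px[i])^2 < (370 / 43)^2)
    }, logical(1))
    expect_gte(mean(hit), 0.75)
  }
})

test_that("persistence run lengths recover the sampled-chain dwell means", {
  sim <- embryo_sim_params()
  acq <- acquisition_params()
  traces <- do.call(cbind, lapply(1:40, function(s) {
    generate_timelapse(sim, acq, n_frames = 60, seed = s, n_clusters = 5,
                       render = FALSE)$truth$traces
  }))
  ps <- persistence_stats(presence = traces, frame_time = acq$frame_time)
  eff <- effective_dwells(sim$ton, sim$toff, acq$frame_time)
  expect_lt(abs(ps$ton - eff["ton"]) / eff["ton"], 0.15)
  expect_lt(abs(ps$toff - eff["toff"]) / eff["toff"], 0.15)
  # detection probability matches the calibrated occupancy
  expect_gt(ps$detection_probability, 0.55)
  expect_lt(ps$detection_probability, 0.65)
  expect_lt(abs(ps$occupancy_raw - 0.6), 0.03)
})

test_that("long dwells are recovered without sampling distortion", {
  sim <- embryo_sim_params(ton = 24, toff = 16)
  acq <- acquisition_params()
  traces <- do.call(cbind, lapply(1:30, function(s) {
    generate_timelapse(sim, acq, n_frames = 600, seed = s, n_clusters = 4,
                       render = FALSE)$truth$traces
  }))
  ps <- persistence_stats(presence = traces, frame_time = acq$frame_time)
  expect_lt(abs(ps$ton - 24) / 24, 0.15)
  expect_lt(abs(ps$toff - 16) / 16, 0.15)
})

test_that("persistence handles trivial and degenerate traces", {
  always <- matrix(TRUE, 40, 3)
  always[c(1, 40), 1:3] <- c(FALSE)  # bracket so interior runs exist
  ps <- persistence_stats(presence = always, frame_time = 0.5)
  expect_equal(ps$detection_probability, 1)
  # an all-absent trace is excluded with a warning
  mixed <- cbind(always[, 1], rep(FALSE, 40))
  expect_warning(ps2 <- persistence_stats(presence = mixed, frame_time = 0.5),
                 "excluded")
  expect_equal(ps2$n_areas, 1)
  expect_error(persistence_stats(presence = matrix(TRUE, 5, 2), frame_time = 0.5),
               "at least 10 frames")
})

test_that("confinement centres are found by mode seeking", {
  set.seed(3)
  pts <- data.frame(
    x_px = c(rnorm(40, 20, 2), rnorm(40, 60, 2), runif(10, 5, 75)),
    y_px = c(rnorm(40, 30, 2), rnorm(40, 55, 2), runif(10, 5, 75))
  )
  cen <- find_confinement_centers(pts, bandwidth = 8, min_points = 10)
  expect_gte(nrow(cen), 2)
  expect_lt(min(sqrt((cen$x_px - 20)^2 + (cen$y_px - 30)^2)), 3)
  expect_lt(min(sqrt((cen$x_px - 60)^2 + (cen$y_px - 55)^2)), 3)
})
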