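# 3D cluster detection rules, 2D Gaussian fitting, and derived properties.

test_that("the voxel-count rule corresponds to a 3.25-pixel effective diameter", {
  expect_equal(threshold_effective_diameter(18), (6 / pi * 18)^(1 / 3))
  expect_equal(round(threshold_effective_diameter(18), 2), 3.25)
})

test_that("noiseless planted Gaussians are recovered to high precision", {
  plane <- matrix(1, 41, 41)
  plane <- clustersense:::add_gaussian_spot(plane, 21.2, 20.6, NA, 5, 3, 2, 0.3, NA)
  f <- fit_cluster_2d(plane, c(21, 21), w = 12, inuc = 1)
  expect_true(f$accepted)
  expect_equal(f$Ia, 5, tolerance = 1e-4)
  expect_equal(f$Ibg, 1, tolerance = 1e-4)
  expect_equal(f$x0_px, 21.2, tolerance = 1e-4)
  expect_equal(f$y0_px, 20.6, tolerance = 1e-4)
  expect_equal(f$sigma1_px, 3, tolerance = 1e-4)
  expect_equal(f$sigma2_px, 2, tolerance = 1e-4)
  expect_equal(f$theta, 0.3, tolerance = 1e-3)
})

test_that("amplitude and background are separately identified", {
  plane <- matrix(2, 41, 41)
  plane <- clustersense:::add_gaussian_spot(plane, 21, 21, NA, 6, 2.5, 2.5, 0.01, NA)
  f1 <- fit_cluster_2d(plane, c(21, 21), w = 10, inuc = 2)
  f2 <- fit_cluster_2d(plane + 7.5, c(21, 21), w = 10, inuc = 9.5)
  expect_equal(f2$Ibg - f1$Ibg, 7.5, tolerance = 1e-5)
  expect_equal(f2$Ia, f1$Ia, tolerance = 1e-5)
})

test_that("windows clipped by the image edge are discarded", {
  plane <- matrix(1, 30, 30)
  f <- fit_cluster_2d(plane, c(5, 15), w = 12)
  expect_false(f$converged)
  expect_false(f$accepted)
})

test_that("derived properties follow their closed forms", {
  rec <- tibble::tibble(Ia = 1, Ibg = 0.5, sigma1_px = 3, sigma2_px = 4,
                        x0_px = 0, y0_px = 0, theta = 0)
  out <- cluster_properties(rec, pixel_nm = 1000)  # 1 um pixels for round numbers
  expect_equal(out$d_um, 5)          # 3-4-5
  expect_equal(out$amp_ratio, 2)
  expect_equal(out$Ic, 2 * pi * 12)  # 2 pi Ia sigma1 sigma2
  rec2 <- tibble::tibble(Ia = 1, Ibg = 1, sigma1_px = 1, sigma2_px = 1,
                         x0_px = 0, y0_px = 0, theta = 0)
  expect_equal(cluster_properties(rec2, pixel_nm = 1000)$Ic, 2 * pi)
})

test_that("single-slice speckles fail the z-extent rule", {
  arr <- array(1, c(60, 60, 12))
  arr[28:32, 28:32, 6] <- 50  # bright but confined to one z-slice
  msk <- clustersense:::sphere_mask(c(60, 60, 12), c(30, 30, 6), 28, 5.6)
  cand <- detect_clusters_3d(arr, msk)
  expect_true(all(cand$ext_z[cand$n_vox > 5] == 1))
  expect_false(any(cand$accepted))
})

test_that("planted spots at good SNR are detected and recovered without bias", {
  # axially resolvable suite: a 1 um hard core keeps planted spots separable
  # in principle at the 200 nm slice spacing
  sim <- embryo_sim_params(noise_cv = 0, cluster_min_sep_um = 1.0)
  acq <- acquisition_params()
  n_planted <- 0; n_found <- 0
  pairs <- NULL
  for (s in 1:12) {
    g <- generate_nucleus_stack(sim, acq, 0.15, seed = 40 + s, n_clusters = 8)
    tcl <- g$truth$clusters
    cl <- quantify_clusters(g$stack, sphere_mask_of(g))
    n_planted <- n_planted + nrow(tcl)
    for (i in seq_len(nrow(tcl))) {
      d2 <- (cl$x0_px - tcl$x_px[i])^2 + (cl$y0_px - tcl$y_px[i])^2
      dz <- abs(cl$z_px - tcl$z_px[i])
      j <- which(d2 < 9 & dz < 4)
      if (length(j) > 0) {
        n_found <- n_found + 1
        j <- j[which.min(d2[j])]
        pairs <- rbind(pairs, c(cl$d_nm[j], tcl$d_app_nm[i],
                                cl$Ia[j], tcl$Ia[i],
                                cl$Ibg[j], tcl$Ibg[i]))
      }
    }
  }
  expect_gte(n_planted, 90)
  expect_gte(n_found / n_planted, 0.9)
  # round-trip bias of size, amplitude and background measures < 5%
  expect_lt(abs(mean(pairs[, 1] / pairs[, 2]) - 1), 0.05)
  expect_lt(abs(mean(pairs[, 3] / pairs[, 4]) - 1), 0.05)
  expect_lt(abs(median(pairs[, 5] / pairs[, 6]) - 1), 0.05)
  # size-amplitude independence preserved through the pipeline
  expect_lt(abs(cor(pairs[, 1], pairs[, 3])), 0.15)
})

test_that("pure-noise nuclei yield few accepted candidates", {
  # pure noise = shot/read noise only; the diffuse-pool fluctuation field is
  # structured signal, not noise
  sim <- embryo_sim_params(fluct_cv = 0)
  acq <- acquisition_params()
  fp <- vapply(1:3, function(s) {
    g <- generate_nucleus_stack(sim, acq, 0.15, seed = 70 + s, mode = "homogeneous")
    cand <- detect_clusters_3d(g$stack, sphere_mask_of(g))
    sum(cand$accepted)
  }, numeric(1))
  # planted-spot density at this position is ~45 per nucleus
  expect_lt(mean(fp), 0.1 * 45)
})

test_that("per-nucleus summaries aggregate counts and means", {
  cl <- tibble::tibble(
    nucleus = c(1, 1, 1, 2),
    d_um = c(2, 4, 6, 1), Ia = c(1, 2, 3, 4), Ibg = 1, Ic = c(1, 1, 1, 2)
  )
  nuc <- tibble::tibble(nucleus = 1:3, Inuc = c(10, 8, 6), x_over_L = c(0.1, 0.2, 0.3))
  s <- nuclear_cluster_summary(cl, nuc)
  expect_equal(s$n_clusters, c(3L, 1L, 0L))
  expect_equal(s$mean_d_um[1], 4)
  expect_true(is.na(s$mean_d_um[3]))
})

test_that("per-nucleus mean cluster intensity is linear in nuclear intensity", {
  sim <- embryo_sim_params()
  acq <- acquisition_params()
  f <- generate_embryo_field(sim, acq, 150, c(0.1, 0.6), seed = 13)
  per_nuc <- dplyr::summarise(dplyr::group_by(f$clusters, nucleus),
                              mean_Ic = mean(Ic_true), .groups = "drop")
  df <- dplyr::left_join(f$nuclei, per_nuc, by = "nucleus")
  fit <- lm(mean_Ic ~ Inuc_true, data = df)
  expect_gte(summary(fit)$r.squared, 0.6)
})
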