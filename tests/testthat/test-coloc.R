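# Hotspot detection, radial accumulation profiles, and coupling fractions.

coarse_tc <- function(mode = "target-strong", n = 4, seed = 3, ...) {
  sim <- embryo_sim_params(nucleus_diameter_um = 4, ...)
  acq <- acquisition_params(voxel_xy = 86, voxel_z = 300,
                            psf_sigma_lateral = 200, psf_sigma_axial = 500)
  generate_two_channel(sim, acq, mode, n_nuclei = n, seed = seed, render = TRUE)
}

test_that("planted hotspots are detected with sub-pixel accuracy", {
  tc <- coarse_tc()
  geom <- tc$geometry
  for (i in seq_along(tc$stacks)) {
    hs <- detect_hotspots(tc$stacks[[i]], tc$mask)
    expect_equal(nrow(hs), 1)
    tx <- geom$cen_xy + tc$hotspots$hx_um[i] / geom$vx
    ty <- geom$cen_xy + tc$hotspots$hy_um[i] / geom$vx
    expect_lt(sqrt((hs$x_px - tx)^2 + (hs$y_px - ty)^2), 1)
  }
})

test_that("the 4-sigma threshold and 18-voxel size rule reject weak or small spots", {
  arr <- array(100, c(50, 50, 10)) + array(rnorm(50 * 50 * 10, 0, 5), c(50, 50, 10))
  msk <- clustersense:::sphere_mask(c(50, 50, 10), c(25, 25, 5), 23, 4.6)
  # a spot only ~2 sigma above the nuclear mean stays undetected
  weak <- clustersense:::add_gaussian_spot(arr, 25, 25, 5, 10, 3, 3, 0.01, 1.5)
  expect_equal(nrow(detect_hotspots(weak, msk)), 0)
  # a bright but 1-voxel speckle fails the size rule
  tiny <- arr; tiny[25, 25, 5] <- 1e4
  expect_equal(nrow(detect_hotspots(tiny, msk)), 0)
  # a bright extended spot is kept
  strong <- clustersense:::add_gaussian_spot(arr, 25, 25, 5, 200, 3, 3, 0.01, 1.8)
  expect_equal(nrow(detect_hotspots(strong, msk)), 1)
})

test_that("radial profiles reproduce planted intensity structure", {
  # planted Gaussian centred on the hotspot: monotone decay from the centre
  plane <- matrix(1, 61, 61)
  plane <- clustersense:::add_gaussian_spot(plane, 31, 31, NA, 10, 4, 4, 0.01, NA)
  rp <- radial_profile(plane, data.frame(x_px = 31, y_px = 31), r_max_um = 1,
                       pixel_nm = 43)
  expect_equal(which.max(rp$Ir), 1)
  expect_true(all(diff(rp$Ir) < 0))
  # uniform image: constant profile
  rp_u <- radial_profile(matrix(7, 61, 61), data.frame(x_px = 31, y_px = 31),
                         r_max_um = 1, pixel_nm = 43)
  expect_lt(diff(range(rp_u$Ir)), 1e-12)
})

test_that("non-target controls give flat aggregated profiles", {
  tc <- coarse_tc(mode = "nontarget", n = 30, seed = 8)
  geom <- tc$geometry
  profs <- lapply(seq_along(tc$stacks), function(i) {
    radial_profile(
      tc$stacks[[i]]$channels$tf,
      data.frame(
        x_px = geom$cen_xy + tc$hotspots$hx_um[i] / geom$vx,
        y_px = geom$cen_xy + tc$hotspots$hy_um[i] / geom$vx,
        z_px = geom$cen_z + tc$hotspots$hz_um[i] / geom$vz
      ),
      r_max_um = 1, mask = tc$mask, pixel_nm = 86
    )
  })
  agg <- aggregate_profiles(profs)
  expect_lt(max(agg$Ir) / min(agg$Ir), 1.2)
})

test_that("accumulation fits recover the closed-form width and flag flat profiles", {
  r <- seq(0.05, 1.5, by = 0.1)
  prof <- data.frame(r_um = r, Ir = 3 * exp(-(r / 0.26)^2) + 1)
  f <- fit_accumulation(prof)
  expect_equal(f$r0_um, 2 * 0.26 * sqrt(log(2)), tolerance = 5e-3)
  expect_true(f$central_component)
  f2 <- fit_accumulation(prof, r0_definition = "2fwhm")
  expect_equal(f2$r0_um, 2 * f$r0_um, tolerance = 1e-6)
  # pure-noise profile: central component flagged unreliable
  set.seed(2)
  flatp <- data.frame(r_um = r, Ir = 5 + rnorm(length(r), 0, 0.05))
  f3 <- fit_accumulation(flatp)
  expect_false(isTRUE(f3$central_component))
})

test_that("coupling fractions follow the planted labels and are monotone in r0", {
  sim <- embryo_sim_params(coupling_fraction = 0.73)
  acq <- acquisition_params()
  tc <- generate_two_channel(sim, acq, "target-strong", n_nuclei = 200, seed = 12)
  hs <- dplyr::transmute(tc$hotspots, nucleus = nucleus,
                         x_um = hx_um, y_um = hy_um, z_um = hz_um)
  cp <- coupling_fraction(hs, tc$clusters, r0_um = sim$accumulation_radius_um)
  planted <- mean(tc$nuclei$coupled_true)
  expect_lt(abs(cp$coupling_fraction - planted), 2 * sqrt(0.73 * 0.27 / 200) + 1e-9)
  expect_equal(coupling_fraction(hs, tc$clusters, r0_um = 0)$coupling_fraction, 0)
  expect_equal(coupling_fraction(hs, tc$clusters, r0_um = 10)$coupling_fraction, 1)
  # monotone non-decreasing in r0
  fr <- vapply(c(0.2, 0.4, 0.6, 0.8),
               function(r0) coupling_fraction(hs, tc$clusters, r0_um = r0)$coupling_fraction,
               numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("strong enhancers give shorter median distances than weak ones", {
  acq <- acquisition_params()
  wins <- vapply(1:20, function(s) {
    strong <- generate_two_channel(embryo_sim_params(coupling_fraction = 0.31),
                                   acq, "target-strong", 160, seed = s)
    weak <- generate_two_channel(embryo_sim_params(coupling_fraction = 0.13),
                                 acq, "target-weak", 160, seed = s + 1000)
    ms <- median(tapply(strong$clusters$dist_hotspot_um, strong$clusters$nucleus, min))
    mw <- median(tapply(weak$clusters$dist_hotspot_um, weak$clusters$nucleus, min))
    ms < mw
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("the histogram-intersection boundary lands between planted modes", {
  set.seed(2)
  d <- c(rnorm(150, 0.3, 0.1), rnorm(150, 0.9, 0.1))
  cb <- coupling_boundary_alt(d)
  expect_true(cb$crossing_found)
  expect_lt(abs(cb$r0_prime_um - 0.6), 0.08)
  # agreement with truth labels within 5 percentage points
  truth_frac <- 0.5
  expect_lt(abs(cb$coupled_fraction - truth_frac), 0.05)
  # unimodal distances trigger the fallback
  set.seed(3)
  expect_warning(cb2 <- coupling_boundary_alt(rnorm(200, 0.5, 0.08)), "fall back")
  expect_false(cb2$crossing_found)
})
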