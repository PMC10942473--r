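# Morphological nucleus segmentation (filled and hollow), matching, and
# anterior-posterior positioning.

make_field <- function(seed = 5, n = 20) {
  generate_embryo_field(embryo_sim_params(noise_cv = 0.05), acq_coarse(),
                        n, c(0.2, 0.25), seed = seed, render = TRUE)
}

test_that("filled nuclei are segmented with sub-voxel centroid accuracy", {
  f <- make_field()
  seg <- segment_filled_nuclei(f$stack)
  expect_equal(nrow(seg$records), 20)
  errs <- vapply(seq_len(20), function(i) {
    min(sqrt((seg$records$cx_px - f$nuclei$cx_px[i])^2 +
               (seg$records$cy_px - f$nuclei$cy_px[i])^2))
  }, numeric(1))
  expect_lt(max(errs), 1)
  # equivalent diameters near the planted 5 um
  expect_lt(max(abs(seg$records$diameter_um - 5)), 1.5)
  # labels disjoint by construction; all labelled voxels carry one id
  expect_true(all(seg$labels >= 0))
  # Inuc ordering tracks planted intensities
  ord <- vapply(seq_len(20), function(i) {
    which.min((seg$records$cx_px - f$nuclei$cx_px[i])^2 +
                (seg$records$cy_px - f$nuclei$cy_px[i])^2)
  }, integer(1))
  expect_gt(cor(f$nuclei$Inuc_true, seg$records$Inuc[ord]), 0.8)
})

test_that("blank stacks yield no nuclei", {
  arr <- array(1, c(40, 40, 8)) + array(rnorm(40 * 40 * 8, 0, 0.01), c(40, 40, 8))
  seg <- segment_filled_nuclei(arr, acq = acq_coarse())
  expect_equal(nrow(seg$records), 0)
})

test_that("touching nuclei are split by the watershed", {
  acq <- acq_coarse()
  vx <- acq$voxel_xy / 1000
  dims <- c(60, 34, 16)
  base <- array(0.1, dims)
  # two spheres 22 px apart (4.4 um: closer than one diameter, blurred together)
  m1 <- clustersense:::sphere_mask(dims, c(19, 17, 8), 12.5, 6.25)
  m2 <- clustersense:::sphere_mask(dims, c(41, 17, 8), 12.5, 6.25)
  base[m1] <- 1; base[m2] <- 1
  base <- clustersense:::gauss_blur_3d(base, 1.5, 0.8)
  seg <- segment_filled_nuclei(base, acq = acq)
  expect_equal(nrow(seg$records), 2)
  expect_lt(min(abs(seg$records$cx_px - 19)), 2)
  expect_lt(min(abs(seg$records$cx_px - 41)), 2)
})

test_that("hollow segmentation agrees with filled segmentation on twin renderings", {
  f <- make_field(seed = 6)
  arr <- f$stack$channels$tf
  inv <- max(arr) * 1.05 - arr
  seg_f <- segment_filled_nuclei(f$stack)
  seg_h <- segment_hollow_nuclei(inv, acq = acq_coarse())
  expect_gte(nrow(seg_h$records), 19)  # >= 95% of planted nuclei
  m <- match_nuclei(seg_f, seg_h, nuclear_length_um = 5)
  matched <- m[m$matched, ]
  expect_gte(nrow(matched), 19)
  expect_lt(max(matched$distance_um), 2 * 0.2)  # centroids within 2 voxels
  # uniform image: nothing found
  segu <- segment_hollow_nuclei(array(1, c(40, 40, 8)) +
                                  array(rnorm(40 * 40 * 8, 0, 0.01), c(40, 40, 8)),
                                acq = acq_coarse())
  expect_equal(nrow(segu$records), 0)
})

test_that("nucleus matching honours the half-length threshold", {
  a <- tibble::tibble(label = 1:5, x_um = seq(0, 40, 10), y_um = 0, z_um = 0)
  m_id <- match_nuclei(a, a, nuclear_length_um = 5)
  expect_equal(sum(m_id$matched), 5)
  expect_equal(m_id$distance_um[m_id$matched], rep(0, 5))
  # shift by 0.6 nuclear lengths: no matches
  b <- dplyr::mutate(a, x_um = x_um + 3)
  m_far <- match_nuclei(a, b, nuclear_length_um = 5)
  expect_equal(sum(m_far$matched), 0)
  # small jitter: perfect pairing
  set.seed(1)
  c_ <- dplyr::mutate(a, x_um = x_um + rnorm(5, 0, 0.2), y_um = rnorm(5, 0, 0.2))
  m_j <- match_nuclei(a, c_, nuclear_length_um = 5)
  expect_equal(sum(m_j$matched), 5)
  expect_equal(m_j$label_filled[m_j$matched], m_j$label_hollow[m_j$matched])
})

test_that("AP positioning is exact at the tips and rigid-motion invariant", {
  g <- embryo_geometry(c(12, -4), c(412, 296))
  expect_equal(nucleus_position(matrix(c(12, -4), 1), g), 0)
  expect_equal(nucleus_position(matrix(c(412, 296), 1), g), 1)
  set.seed(7)
  pts <- matrix(runif(40, -100, 500), ncol = 2)
  x0 <- nucleus_position(pts, g)
  # apply a rigid rotation + translation to everything
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  move <- function(m) sweep(m %*% t(R), 2, c(55, -31), `+`)
  g2 <- embryo_geometry(move(matrix(c(12, -4), 1)), move(matrix(c(412, 296), 1)))
  x1 <- nucleus_position(move(pts), g2)
  expect_equal(x0, x1, tolerance = 1e-12)
  # mirror symmetry about the AP axis
  g3 <- embryo_geometry(c(0, 0), c(100, 0))
  expect_equal(nucleus_position(matrix(c(30, 12), 1), g3),
               nucleus_position(matrix(c(30, -12), 1), g3))
  expect_error(embryo_geometry(c(1, 1), c(1, 1)), "distinct")
})
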