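# 3D cluster detection (top-hat, per-nucleus percentile, seeded split,
# voxel-count rule) and per-cluster 2D Gaussian fitting with derived
# properties d, Ia, Ibg, Ic.

#' Effective diameter of the voxel-count threshold
#'
#' The minimum accepted cluster support of `n_vox` voxels corresponds to a
#' sphere of effective diameter `(6 / pi * n_vox)^(1/3)` pixels.
#'
#' @param n_vox Voxel count. Default 18 (a 3 x 3 x 2 footprint).
#' @return Effective diameter in pixels.
#' @export
#' @examples
#' threshold_effective_diameter()  # 3.25 px
threshold_effective_diameter <- function(n_vox = 18) {
  (6 / pi * n_vox)^(1 / 3)
}

#' Detect cluster candidates in a 3D nucleus stack
#'
#' Morphological top-hat filtering (disk element, applied per z-plane) on the
#' raw voxels, selection of the top `1 - percentile` quantile of in-nucleus
#' voxels of the transformed image, separation of joined spots by a seeded
#' split on raw-intensity local maxima, mapping of spot masks back to the raw
#' image for intensity-weighted 3D centroids, and a size rule: a spot is
#' accepted only if its xy cross-section spans at least `min_xy` pixels in
#' both directions, its z depth at least `min_z` slices, and its support at
#' least `min_vox` voxels.
#'
#' @param stack An [image_stack()] or 3D array.
#' @param nucleus_mask Logical 3D array (one nucleus), or an integer label
#'   array from segmentation (each label treated as one nucleus).
#' @param channel Channel to use. Default first.
#' @param tophat_radius Disk radius (px) of the top-hat element. Default 5.
#' @param percentile In-nucleus quantile defining candidate voxels.
#'   Default 0.99 (top 1 percentile).
#' @param min_xy,min_z,min_vox Size-rule cutoffs. Defaults 3, 2, 18.
#' @return Tibble of candidates: `nucleus`, voxel centroid (`x_px`, `y_px`,
#'   `z_px`), support `n_vox`, extents, and `accepted`.
#' @export
detect_clusters_3d <- function(stack, nucleus_mask, channel = 1L,
                               tophat_radius = 5L, percentile = 0.99,
                               min_xy = 3L, min_z = 2L, min_vox = 18L) {
  arr <- if (inherits(stack, "image_stack")) stack$channels[[channel]] else stack
  stopifnot(length(dim(arr)) == 3L)
  if (is.logical(nucleus_mask)) {
    labels <- array(0L, dim(arr))
    labels[nucleus_mask] <- 1L
  } else {
    labels <- nucleus_mask
  }
  if (!any(labels > 0)) abort("empty nucleus mask")
  brush <- EBImage::makeBrush(2L * tophat_radius + 1L, "disc")
  th <- apply_slices(arr / max(arr), function(m) EBImage::whiteTopHat(m, brush))
  ids <- sort(unique(labels[labels > 0]))
  rows <- vector("list", 0L)
  for (nuc in ids) {
    inn <- labels == nuc
    vals <- th[inn]
    thr <- quantile(vals, percentile, names = FALSE)
    if (thr <= 0) {
      pos <- vals[vals > 0]
      if (length(pos) == 0) next
      thr <- min(pos)
    }
    cand <- inn & th >= thr
    idx <- which(cand, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    comp <- label_sparse_voxels(idx, dim(arr))
    comp <- split_joined_spots(idx, comp, arr, dim(arr))
    comp <- merge_split_fragments(idx, comp, arr)
    for (ci in sort(unique(comp))) {
      vi <- idx[comp == ci, , drop = FALSE]
      w <- arr[vi]
      ext <- apply(vi, 2, function(v) diff(range(v)) + 1L)
      accepted <- ext[1] >= min_xy && ext[2] >= min_xy &&
        ext[3] >= min_z && nrow(vi) >= min_vox
      rows[[length(rows) + 1L]] <- tibble(
        nucleus = nuc,
        x_px = sum(vi[, 1] * w) / sum(w),
        y_px = sum(vi[, 2] * w) / sum(w),
        z_px = sum(vi[, 3] * w) / sum(w),
        n_vox = nrow(vi),
        ext_x = ext[1], ext_y = ext[2], ext_z = ext[3],
        peak = max(w),
        accepted = accepted
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(nucleus = integer(0), x_px = numeric(0), y_px = numeric(0),
                  z_px = numeric(0), n_vox = integer(0), ext_x = integer(0),
                  ext_y = integer(0), ext_z = integer(0), peak = numeric(0),
                  accepted = logical(0)))
  }
  list_rbind(rows)
}

# Split a connected candidate component that contains several raw-intensity
# local maxima: voxels are re-assigned to the nearest seed (a watershed
# approximation on the sparse voxel set). Seeds closer than `min_sep_px`
# are merged.
split_joined_spots <- function(idx, comp, arr, dims, min_sep_px = 7) {
  out <- comp
  next_id <- max(comp) + 1L
  for (ci in unique(comp)) {
    sel <- which(comp == ci)
    if (length(sel) < 4) next
    vi <- idx[sel, , drop = FALSE]
    vals <- arr[vi]
    # local maxima within the component (26-neighbourhood)
    key <- (vi[, 1] - 1) + dims[1] * ((vi[, 2] - 1) + dims[2] * (vi[, 3] - 1))
    ord <- order(key)
    skey <- key[ord]
    is_max <- rep(TRUE, length(sel))
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
    for (o in seq_len(nrow(offs))) {
      nb <- vi + matrix(offs[o, ], nrow(vi), 3, byrow = TRUE)
      nkey <- (nb[, 1] - 1) + dims[1] * ((nb[, 2] - 1) + dims[2] * (nb[, 3] - 1))
      pos <- findInterval(nkey, skey)
      hit <- pos > 0 & skey[pmax(pos, 1)] == nkey
      nbval <- rep(-Inf, length(sel))
      nbval[hit] <- vals[ord[pos[hit]]]
      is_max <- is_max & vals >= nbval
    }
    seeds <- which(is_max)
    if (length(seeds) < 2) next
    # merge seeds that are close (anisotropy-free pixel distance)
    sp <- vi[seeds, , drop = FALSE]
    keep <- rep(TRUE, length(seeds))
    o <- order(-vals[seeds])
    for (a in seq_along(o)) {
      if (!keep[o[a]]) next
      for (b in seq_along(o)) {
        if (b <= a || !keep[o[b]]) next
        if (sqrt(sum((sp[o[a], ] - sp[o[b], ])^2)) < min_sep_px) keep[o[b]] <- FALSE
      }
    }
    seeds <- seeds[keep]
    if (length(seeds) < 2) next
    sp <- vi[seeds, , drop = FALSE]
    d2 <- vapply(seq_len(nrow(sp)), function(s) {
      (vi[, 1] - sp[s, 1])^2 + (vi[, 2] - sp[s, 2])^2 + (vi[, 3] - sp[s, 3])^2
    }, numeric(length(sel)))
    assign <- max.col(-matrix(d2, ncol = nrow(sp)))
    new_ids <- c(ci, next_id + seq_len(nrow(sp) - 1L) - 1L)
    out[sel] <- new_ids[assign]
    next_id <- next_id + nrow(sp) - 1L
  }
  out
}

# z-plane of a nucleus mask (logical or labelled) for mask-aware fitting.
mask_plane <- function(nucleus_mask, nucleus, zi) {
  if (is.logical(nucleus_mask)) {
    nucleus_mask[, , zi]
  } else {
    nucleus_mask[, , zi] == nucleus
  }
}

# Re-unite fragments of one spot that noise split into nearby components:
# components whose intensity-weighted centroids are within `xy_px` laterally
# and `z_px` axially are merged.
merge_split_fragments <- function(idx, comp, arr, xy_px = 5, z_px = 3.5) {
  repeat {
    ids <- sort(unique(comp))
    if (length(ids) < 2) return(comp)
    cen <- t(vapply(ids, function(ci) {
      vi <- idx[comp == ci, , drop = FALSE]
      w <- arr[vi]
      c(sum(vi[, 1] * w), sum(vi[, 2] * w), sum(vi[, 3] * w)) / sum(w)
    }, numeric(3)))
    merged <- FALSE
    for (a in seq_along(ids)) {
      if (merged) break
      for (b in seq_along(ids)) {
        if (b <= a) next
        if (sqrt((cen[a, 1] - cen[b, 1])^2 + (cen[a, 2] - cen[b, 2])^2) < xy_px &&
            abs(cen[a, 3] - cen[b, 3]) < z_px) {
          comp[comp == ids[b]] <- ids[a]
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) return(comp)
  }
}

# Rotated-Gaussian quadratic-form coefficients.
gauss2d_abc <- function(s1, s2, theta) {
  ct2 <- cos(theta)^2; st2 <- sin(theta)^2; s2t <- sin(2 * theta)
  list(
    a = ct2 / (2 * s1^2) + st2 / (2 * s2^2),
    b = -s2t / (4 * s1^2) + s2t / (4 * s2^2),
    c = st2 / (2 * s1^2) + ct2 / (2 * s2^2)
  )
}

#' Fit a 2D rotated Gaussian to one cluster
#'
#' Least-squares fit (Levenberg-Marquardt) of
#' `f(x, y) = Ia * exp(-(a dx^2 + 2 b dx dy + c dy^2)) + Ibg` on a square
#' window of half-width `w` centred on the candidate, in the z-plane of the
#' candidate centroid. Initialisation: `Ia` from the centre pixel, `Ibg`
#' from the nuclear mean, `sigma1 = sigma2 = w/2`, `theta = 0`. Bounds:
#' `sigma <= w` (a `sigma <= w/2` reading would reject most genuine clusters
#' of the calibrated size population, inconsistent with the expected < 2%
#' discard rate), centre shift `<= w`, `0 < theta < pi/4`. Fits that do not
#' converge or end pinned at a bound are flagged `accepted = FALSE`.
#'
#' @param plane 2D numeric matrix (the raw z-plane).
#' @param center Length-2 candidate centroid `(x_px, y_px)`.
#' @param w Window half-width in pixels. Default 12.
#' @param inuc Nuclear mean intensity used to initialise `Ibg`.
#' @return One-row tibble: `Ia`, `Ibg`, `x0_px`, `y0_px`, `sigma1_px >=
#'   sigma2_px`, `theta`, `resid_norm`, `converged`, `accepted`.
#' @export
fit_cluster_2d <- function(plane, center, w = 12L, inuc = NULL,
                           neighbors = NULL, neighbor_radius = 10,
                           mask = NULL) {
  cx <- round(center[1]); cy <- round(center[2])
  bad <- tibble(Ia = NA_real_, Ibg = NA_real_, x0_px = NA_real_,
                y0_px = NA_real_, sigma1_px = NA_real_, sigma2_px = NA_real_,
                theta = NA_real_, resid_norm = NA_real_,
                converged = FALSE, accepted = FALSE)
  if (cx - w < 1 || cx + w > nrow(plane) || cy - w < 1 || cy + w > ncol(plane)) {
    return(bad)  # window not fully inside the image
  }
  xs <- (cx - w):(cx + w)
  ys <- (cy - w):(cy + w)
  z <- plane[xs, ys]
  dx <- matrix(rep(xs - cx, length(ys)), ncol = length(ys))
  dy <- matrix(rep(ys - cy, each = length(xs)), ncol = length(ys))
  use <- rep(TRUE, length(z))
  if (!is.null(mask)) {
    # out-of-nucleus pixels (blurred rim, cytoplasm) would bias the local
    # background; fit on in-mask pixels only
    use <- as.logical(mask[xs, ys])
    if (mean(use) < 0.4) use <- rep(TRUE, length(z))
  }
  if (!is.null(neighbors) && nrow(neighbors) > 0) {
    # pixels belonging to other detected spots would bias the fit; drop them
    gx <- matrix(rep(xs, length(ys)), ncol = length(ys))
    gy <- matrix(rep(ys, each = length(xs)), ncol = length(ys))
    for (k in seq_len(nrow(neighbors))) {
      use <- use & ((gx - neighbors[k, 1])^2 + (gy - neighbors[k, 2])^2 >
                      neighbor_radius^2)
    }
    if (mean(use) < 0.25) use <- rep(TRUE, length(z))  # too little left; fit all
  }
  inuc <- inuc %||% median(z)
  p0 <- c(Ia = max(z[w + 1, w + 1] - inuc, 1e-3), Ibg = inuc,
          x0 = 0, y0 = 0, s1 = w / 2, s2 = w / 2, th = 1e-3)
  lower <- c(1e-9, 0, -w, -w, 0.3, 0.3, 1e-6)
  upper <- c(Inf, Inf, w, w, w, w, pi / 4 - 1e-6)
  model <- function(p) {
    ab <- gauss2d_abc(p[5], p[6], p[7])
    ddx <- dx - p[3]; ddy <- dy - p[4]
    p[1] * exp(-(ab$a * ddx^2 + 2 * ab$b * ddx * ddy + ab$c * ddy^2)) + p[2]
  }
  run_lm <- function(par0) {
    tryCatch(
      minpack.lm::nls.lm(
        par = par0, lower = lower, upper = upper,
        fn = function(p) as.numeric(z - model(p))[use],
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }
  res <- run_lm(p0)
  # theta is degenerate at sigma1 = sigma2, so the symmetric start can pin
  # theta at a bound; retry from an asymmetric mid-angle start and keep the
  # better optimum
  p1 <- p0
  p1[["s1"]] <- w / 3; p1[["s2"]] <- w / 5; p1[["th"]] <- pi / 8
  res2 <- run_lm(p1)
  pick <- function(r) if (is.null(r) || !r$info %in% 1:4) Inf else r$deviance
  if (pick(res2) < pick(res)) res <- res2
  if (is.null(res) || !res$info %in% 1:4) return(bad)
  p <- res$par
  at_bound <- p[["s1"]] >= w - 1e-6 || p[["s2"]] >= w - 1e-6 ||
    abs(p[["x0"]]) >= w - 1e-6 || abs(p[["y0"]]) >= w - 1e-6 ||
    p[["s1"]] <= 0.3 + 1e-6 || p[["s2"]] <= 0.3 + 1e-6 ||
    p[["Ibg"]] < 0.1 * inuc  # collapsed background: contaminated window
  s1 <- max(p[["s1"]], p[["s2"]])
  s2 <- min(p[["s1"]], p[["s2"]])
  tibble(
    Ia = p[["Ia"]], Ibg = p[["Ibg"]],
    x0_px = cx + p[["x0"]], y0_px = cy + p[["y0"]],
    sigma1_px = s1, sigma2_px = s2, theta = p[["th"]],
    resid_norm = sqrt(res$deviance / sum(use)),
    converged = TRUE, accepted = !at_bound
  )
}

#' Derived cluster properties
#'
#' Adds the effective size `d = sqrt(sigma1^2 + sigma2^2)` (the apparent
#' effective diameter, in um and nm), the amplification ratio `Ia / Ibg`,
#' and the integrated cluster intensity `Ic = 2 * pi * Ia * sigma1 * sigma2`
#' (um^2 x intensity) to a table of fitted clusters.
#'
#' @param fits Tibble from [fit_cluster_2d()] rows (needs `sigma1_px`,
#'   `sigma2_px`, `Ia`, `Ibg`).
#' @param pixel_nm Lateral pixel size (nm). Default 43.
#' @return The input with `d_um`, `d_nm`, `amp_ratio`, `Ic` columns added.
#' @export
cluster_properties <- function(fits, pixel_nm = 43) {
  vx_um <- pixel_nm / 1000
  mutate(as_tibble(fits),
    d_um = sqrt(.data$sigma1_px^2 + .data$sigma2_px^2) * vx_um,
    d_nm = .data$d_um * 1000,
    amp_ratio = .data$Ia / .data$Ibg,
    Ic = 2 * pi * .data$Ia * (.data$sigma1_px * vx_um) * (.data$sigma2_px * vx_um)
  )
}

#' Detect, fit and characterise clusters in a nucleus stack
#'
#' Convenience wrapper: [detect_clusters_3d()] on the accepted candidates,
#' [fit_cluster_2d()] in the centroid z-plane of each, and
#' [cluster_properties()] on the accepted fits.
#'
#' @inheritParams detect_clusters_3d
#' @param w Fit window half-width (px). Default 12.
#' @param inuc Optional per-nucleus named vector of mean intensities for fit
#'   initialisation (else the in-mask mean is used).
#' @param size_floor_nm Candidate size cutoff applied to fitted sizes
#'   (`NULL` to keep all).
#' @return Tibble of fitted clusters with derived properties; rejected
#'   candidates and discarded fits are counted in attributes
#'   `n_candidates`, `n_rejected_size`, `n_discarded_fit`.
#' @export
quantify_clusters <- function(stack, nucleus_mask, channel = 1L, w = 12L,
                              tophat_radius = 5L, percentile = 0.99,
                              inuc = NULL, size_floor_nm = 150,
                              two_pass = TRUE) {
  arr <- if (inherits(stack, "image_stack")) stack$channels[[channel]] else stack
  acq <- if (inherits(stack, "image_stack")) stack$acq else acquisition_params()
  cand <- detect_clusters_3d(stack, nucleus_mask, channel = channel,
                             tophat_radius = tophat_radius,
                             percentile = percentile)
  acc <- cand[cand$accepted, ]
  if (is.logical(nucleus_mask)) {
    inuc_tab <- c(`1` = mean(arr[nucleus_mask]))
  } else if (is.null(inuc)) {
    ids <- sort(unique(nucleus_mask[nucleus_mask > 0]))
    inuc_tab <- vapply(ids, function(i) mean(arr[nucleus_mask == i]), numeric(1))
    names(inuc_tab) <- ids
  } else {
    inuc_tab <- inuc
  }
  fits <- vector("list", nrow(acc))
  for (i in seq_len(nrow(acc))) {
    zi <- max(1L, min(dim(arr)[3], round(acc$z_px[i])))
    nb <- cand[-0, ]
    nb <- cand[seq_len(nrow(cand)) != which(cand$accepted)[i] &
                 abs(cand$z_px - zi) < 3 &
                 sqrt((cand$x_px - acc$x_px[i])^2 +
                        (cand$y_px - acc$y_px[i])^2) > 4, , drop = FALSE]
    fits[[i]] <- fit_cluster_2d(arr[, , zi], c(acc$x_px[i], acc$y_px[i]),
                                w = w, inuc = inuc_tab[[as.character(acc$nucleus[i])]],
                                neighbors = as.matrix(nb[, c("x_px", "y_px")]),
                                mask = mask_plane(nucleus_mask, acc$nucleus[i], zi))
    fits[[i]]$nucleus <- acc$nucleus[i]
    fits[[i]]$z_px <- acc$z_px[i]
    fits[[i]]$n_vox <- acc$n_vox[i]
    fits[[i]]$cand_x_px <- acc$x_px[i]
    fits[[i]]$cand_y_px <- acc$y_px[i]
  }
  fits <- if (length(fits) > 0) list_rbind(fits) else tibble()
  fits0 <- fits
  if (two_pass && nrow(fits) > 1 && any(fits$accepted, na.rm = TRUE)) {
    # crowded-field refinement: subtract every other accepted first-pass fit
    # (with axial attenuation from the isotropic-cluster model) from the fit
    # plane, then refit each candidate on the cleaned window
    ok <- which(fits$accepted %in% TRUE)
    psf_ratio_sz <- function(s_lat_px) {
      cluster_axial_sigma(s_lat_px * acq$voxel_xy, acq) / acq$voxel_z
    }
    for (i in seq_len(nrow(acc))) {
      zi <- max(1L, min(dim(arr)[3], round(acc$z_px[i])))
      others <- setdiff(ok, i)
      # never subtract a duplicate fit of this same physical spot (dedupe
      # has not run yet): skip fits re-centred onto this candidate
      if (length(others) > 0) {
        dup <- sqrt((fits$x0_px[others] - acc$x_px[i])^2 +
                      (fits$y0_px[others] - acc$y_px[i])^2) < 4 &
          abs(fits$z_px[others] - acc$z_px[i]) < 6
        others <- others[!dup]
      }
      if (length(others) == 0) next
      plane <- arr[, , zi]
      for (j in others) {
        sz_px <- psf_ratio_sz((fits$sigma1_px[j] + fits$sigma2_px[j]) / 2)
        att <- exp(-((zi - fits$z_px[j])^2) / (2 * sz_px^2))
        if (att < 0.05) next
        plane <- add_gaussian_spot(plane, fits$x0_px[j], fits$y0_px[j], NA,
                                   -att * fits$Ia[j], fits$sigma1_px[j],
                                   fits$sigma2_px[j], fits$theta[j], NA)
      }
      plane <- pmax(plane, 0)
      refit <- fit_cluster_2d(plane, c(acc$x_px[i], acc$y_px[i]), w = w,
                              inuc = inuc_tab[[as.character(acc$nucleus[i])]],
                              mask = mask_plane(nucleus_mask, acc$nucleus[i], zi))
      if (isTRUE(refit$converged)) {
        refit$nucleus <- acc$nucleus[i]
        refit$z_px <- acc$z_px[i]
        refit$n_vox <- acc$n_vox[i]
        refit$cand_x_px <- acc$x_px[i]
        refit$cand_y_px <- acc$y_px[i]
        fits[i, names(refit)] <- refit
      }
    }
  }
  n_disc <- if (nrow(fits) > 0) sum(!fits$accepted) else 0L
  out <- fits[fits$accepted %in% TRUE, ]
  # candidates from fragments of the same spot re-centre onto one position
  # when fitted; keep the best fit (lowest residual) per physical spot
  if (nrow(out) > 1) {
    # rank duplicates by how well-centred the fit window was: the fit whose
    # converged centre agrees with its candidate centroid is the trustworthy one
    out$center_shift <- sqrt((out$x0_px - out$cand_x_px)^2 +
                               (out$y0_px - out$cand_y_px)^2)
    # a fit that drifted far from its candidate was fitting something else
    out <- out[out$center_shift <= 4, ]
    out <- arrange(out, .data$center_shift)
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))) {
      if (!keep[i]) next
      later <- which(keep & seq_len(nrow(out)) > i)
      dup <- later[
        out$nucleus[later] == out$nucleus[i] &
          sqrt((out$x0_px[later] - out$x0_px[i])^2 +
                 (out$y0_px[later] - out$y0_px[i])^2) < 4 &
          abs(out$z_px[later] - out$z_px[i]) < 6
      ]
      keep[dup] <- FALSE
    }
    out <- out[keep, ]
  }
  out <- cluster_properties(out, pixel_nm = acq$voxel_xy)
  if (!is.null(size_floor_nm) && nrow(out) > 0) {
    out <- out[out$d_nm >= size_floor_nm, ]
  }
  attr(out, "n_candidates") <- nrow(cand)
  attr(out, "n_rejected_size") <- sum(!cand$accepted)
  attr(out, "n_discarded_fit") <- n_disc
  out
}

#' Per-nucleus cluster summaries
#'
#' Counts and means of the derived cluster properties per nucleus, joined to
#' the nucleus records (mean intensity `Inuc`, position `x_over_L` when
#' available). Zero-cluster nuclei carry count 0 and `NA` means.
#'
#' @param clusters Tibble of fitted clusters (with a `nucleus` column and
#'   [cluster_properties()] columns).
#' @param nuclei Tibble of nucleus records (column `nucleus` or `label`).
#' @return Tibble with one row per nucleus: `n_clusters`, `mean_d_um`,
#'   `mean_Ia`, `mean_Ibg`, `mean_Ic`, plus nucleus columns.
#' @export
nuclear_cluster_summary <- function(clusters, nuclei) {
  nuc <- as_tibble(nuclei)
  if (!"nucleus" %in% names(nuc) && "label" %in% names(nuc)) {
    nuc <- dplyr::rename(nuc, nucleus = "label")
  }
  cl <- as_tibble(clusters)
  summ <- if (nrow(cl) > 0) {
    cl |>
      group_by(.data$nucleus) |>
      summarise(
        n_clusters = dplyr::n(),
        mean_d_um = mean(.data$d_um),
        mean_Ia = mean(.data$Ia),
        mean_Ibg = mean(.data$Ibg),
        mean_Ic = mean(.data$Ic),
        .groups = "drop"
      )
  } else {
    tibble(nucleus = integer(0), n_clusters = integer(0), mean_d_um = numeric(0),
           mean_Ia = numeric(0), mean_Ibg = numeric(0), mean_Ic = numeric(0))
  }
  out <- left_join(nuc, summ, by = "nucleus")
  out$n_clusters[is.na(out$n_clusters)] <- 0L
  out
}
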