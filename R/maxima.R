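# Two-step local-maxima detection (Otsu, then iterative 25x25 local
# thresholding with an SSIM-based stopping rule), time-projection maps, and
# cluster persistence statistics (Ton, Toff, detection probability).

# Otsu threshold of a numeric vector (256-bin histogram).
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(
    pmin(as.integer((values - rng[1]) / diff(rng) * n_bins) + 1L, n_bins),
    nbins = n_bins
  )
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + k / n_bins * diff(rng)
}

#' Detect local intensity maxima in a 2D nuclear image
#'
#' Two-step detection. Step 1: Otsu thresholding of the in-mask pixels;
#' sub-threshold pixels are invalidated and the survivors rescaled to
#' `[0, 1]`. Step 2: iterated local thresholding — a mask-aware moving mean
#' and moving standard deviation over a `window x window` region are
#' computed, pixels below `mean + sd` are zeroed, and the image rescaled;
#' each iterate is binarised and compared to the first binarised image by
#' the structural similarity index (SSIM). Iteration stops when the SSIM
#' trace plateaus (change below `ssim_tol` for `ssim_run` consecutive
#' iterations) or at `m_max`. Centroids of connected components of the final
#' binary image are returned, intensity-weighted on the original image.
#'
#' @param image 2D numeric matrix.
#' @param nucleus_mask Logical matrix selecting nuclear pixels.
#' @param m_max Maximum number of local-thresholding iterations. Default 20.
#' @param window Local-threshold window size in pixels. Default 25.
#' @param ssim_tol Plateau tolerance on successive SSIM changes. Default 1e-3.
#' @param ssim_run Number of consecutive sub-tolerance changes that define
#'   the plateau. Default 3.
#' @return A `maxima_map`: tibble with `x_px`, `y_px`, `label`, `n_px`;
#'   the iteration count `m` and the SSIM trace are attributes.
#' @export
detect_local_maxima_2d <- function(image, nucleus_mask, m_max = 20L,
                                   window = 25L, ssim_tol = 1e-3,
                                   ssim_run = 3L) {
  stopifnot(is.matrix(image), all(dim(image) == dim(nucleus_mask)))
  if (!any(nucleus_mask)) abort("empty nucleus mask")
  if (m_max < 1) abort("`m_max` must be >= 1")
  vals <- image[nucleus_mask]
  thr <- otsu_threshold(vals)
  valid <- nucleus_mask & image >= thr
  empty_map <- function(m, trace) {
    structure(tibble(x_px = numeric(0), y_px = numeric(0),
                     label = integer(0), n_px = integer(0)),
              class = c("maxima_map", class(tibble())),
              m = m, ssim_trace = trace)
  }
  if (!any(valid)) return(empty_map(0L, numeric(0)))

  cur <- array(0, dim(image))
  cur[valid] <- image[valid]
  cur <- rescale01_masked(cur, valid)
  bin1 <- (cur > 0 & valid) * 1
  trace <- numeric(0)
  below <- 0L
  m <- 1L
  final_bin <- bin1
  while (m < m_max) {
    if (!any(valid & cur > 0)) break
    # moving stats over all Otsu-valid nuclear pixels; zeroed pixels count
    # (only out-of-nucleus / sub-Otsu pixels are excluded)
    st <- box_stats(cur, valid, k = window)
    thr_mat <- st$mean + st$sd
    nxt <- cur
    nxt[!valid | cur < thr_mat] <- 0
    if (!any(nxt > 0)) break
    nxt <- rescale01_masked(nxt, nxt > 0)
    m <- m + 1L
    cur <- nxt
    bin_m <- (cur > 0) * 1
    s <- ssim_index(bin_m, bin1)
    if (length(trace) > 0) {
      below <- if (abs(s - trace[length(trace)]) < ssim_tol) below + 1L else 0L
    }
    trace <- c(trace, s)
    final_bin <- bin_m
    if (below >= ssim_run) break
  }
  lab <- EBImage::bwlabel(final_bin)
  n_comp <- max(lab)
  if (n_comp == 0) return(empty_map(m, trace))
  rows <- vector("list", n_comp)
  for (l in seq_len(n_comp)) {
    idx <- which(lab == l, arr.ind = TRUE)
    wts <- image[idx]
    rows[[l]] <- tibble(
      x_px = sum(idx[, 1] * wts) / sum(wts),
      y_px = sum(idx[, 2] * wts) / sum(wts),
      label = l, n_px = nrow(idx)
    )
  }
  structure(list_rbind(rows),
            class = c("maxima_map", class(tibble())),
            m = m, ssim_trace = trace)
}

# Rescale in-mask values to [0, 1]; out-of-mask stays 0.
rescale01_masked <- function(x, mask) {
  v <- x[mask]
  rng <- range(v)
  out <- array(0, dim(x))
  if (diff(rng) > 0) {
    out[mask] <- (v - rng[1]) / diff(rng)
  } else {
    out[mask] <- 1
  }
  out
}

#' Project per-frame maxima into a single map
#'
#' Runs [detect_local_maxima_2d()] on every frame of a 2D time-lapse and
#' unions the centroids in the common coordinate frame (nuclei are assumed
#' stationary; no registration).
#'
#' @param video An [image_stack()] of kind `"2dt"`, or a 3D array with time
#'   as the third dimension.
#' @param nucleus_mask Logical matrix (shared across frames) or a list of
#'   per-frame masks.
#' @param channel Channel name when `video` is an `image_stack`.
#' @param ... Passed to [detect_local_maxima_2d()].
#' @return A tibble with `frame`, `x_px`, `y_px`, `n_px`.
#' @export
project_maxima <- function(video, nucleus_mask, channel = 1L, ...) {
  arr <- if (inherits(video, "image_stack")) video$channels[[channel]] else video
  stopifnot(length(dim(arr)) == 3L)
  n_frames <- dim(arr)[3]
  if (n_frames < 2) abort("need at least 2 frames")
  per_frame <- function(f) {
    msk <- if (is.list(nucleus_mask)) nucleus_mask[[f]] else nucleus_mask
    mm <- detect_local_maxima_2d(arr[, , f], msk, ...)
    if (nrow(mm) == 0) return(NULL)
    tibble(frame = f, x_px = mm$x_px, y_px = mm$y_px, n_px = mm$n_px)
  }
  out <- list_rbind(purrr::compact(map(seq_len(n_frames), per_frame)))
  if (nrow(out) == 0) {
    out <- tibble(frame = integer(0), x_px = numeric(0), y_px = numeric(0),
                  n_px = integer(0))
  }
  attr(out, "n_frames") <- n_frames
  out
}

#' Find confinement centres in a projected maxima map
#'
#' Mean-shift-style mode finding: every point is iterated to the centroid of
#' its neighbours within `bandwidth` until convergence; converged positions
#' closer than `bandwidth / 2` are merged into one centre.
#'
#' @param points Data frame with `x_px`, `y_px` (or `x_um`, `y_um`).
#' @param bandwidth Kernel radius, in the same units as the coordinates
#'   (use the pair-correlation width `xi_pair`).
#' @param min_points Minimum points attracted to a mode for it to count.
#' @return Tibble of centres with the member count of each.
#' @export
find_confinement_centers <- function(points, bandwidth, min_points = 5L) {
  df <- as.data.frame(points)
  cols <- if (all(c("x_px", "y_px") %in% names(df))) c("x_px", "y_px") else c("x_um", "y_um")
  P <- as.matrix(df[, cols])
  if (nrow(P) == 0) return(tibble(x = numeric(0), y = numeric(0), n = integer(0)))
  M <- P
  for (it in seq_len(50)) {
    moved <- FALSE
    for (i in seq_len(nrow(M))) {
      d2 <- (P[, 1] - M[i, 1])^2 + (P[, 2] - M[i, 2])^2
      nb <- d2 <= bandwidth^2
      nm <- c(mean(P[nb, 1]), mean(P[nb, 2]))
      if (sum((nm - M[i, ])^2) > (1e-4 * bandwidth)^2) moved <- TRUE
      M[i, ] <- nm
    }
    if (!moved) break
  }
  # merge modes
  assigned <- rep(0L, nrow(M))
  centers <- list()
  for (i in seq_len(nrow(M))) {
    hit <- FALSE
    for (j in seq_along(centers)) {
      if (sum((M[i, ] - centers[[j]])^2) < (bandwidth / 2)^2) {
        assigned[i] <- j
        hit <- TRUE
        break
      }
    }
    if (!hit) {
      centers[[length(centers) + 1L]] <- M[i, ]
      assigned[i] <- length(centers)
    }
  }
  out <- tibble(
    x = vapply(centers, `[`, numeric(1), 1),
    y = vapply(centers, `[`, numeric(1), 2),
    n = as.integer(tabulate(assigned, nbins = length(centers)))
  )
  names(out)[1:2] <- cols
  out[out$n >= min_points, ]
}

#' Cluster persistence statistics from presence traces
#'
#' Builds a per-frame binary presence sequence for each confinement area (a
#' maximum within `radius` of the centre counts as present), then estimates
#' the mean on-dwell `Ton` and off-dwell `Toff` as mean run lengths times the
#' frame interval. The first and last run of every trace are dropped (they
#' are censored). The detection probability is reported both as
#' `Ton / (Ton + Toff)` and as the raw occupancy of the traces.
#'
#' @param projected Tibble from [project_maxima()] (`frame`, `x_px`, `y_px`),
#'   or `NULL` when `presence` is given directly.
#' @param centers Data frame of confinement centres (`x_px`, `y_px`).
#' @param radius Matching radius in pixels.
#' @param frame_time Frame interval in seconds.
#' @param n_frames Total frame count (defaults to the attribute left by
#'   [project_maxima()], else `max(frame)`).
#' @param presence Optional logical matrix (frames x areas) of presence
#'   traces, bypassing the maxima matching.
#' @return A `persistence_stats` object: `ton`, `toff` (s),
#'   `detection_probability` (from the dwell times), `occupancy_raw`,
#'   `n_areas`, and the per-area tibble in `$areas`.
#' @export
persistence_stats <- function(projected = NULL, centers = NULL, radius = NULL,
                              frame_time, n_frames = NULL, presence = NULL) {
  if (is.null(presence)) {
    stopifnot(!is.null(projected), !is.null(centers), !is.null(radius))
    n_frames <- n_frames %||% attr(projected, "n_frames") %||% max(projected$frame)
    if (n_frames < 10) abort("need at least 10 frames")
    if (nrow(centers) < 1) abort("need at least one confinement area")
    presence <- matrix(FALSE, n_frames, nrow(centers))
    for (a in seq_len(nrow(centers))) {
      d2 <- (projected$x_px - centers$x_px[a])^2 +
        (projected$y_px - centers$y_px[a])^2
      hit <- projected$frame[d2 <= radius^2]
      presence[unique(hit), a] <- TRUE
    }
  } else {
    presence <- as.matrix(presence)
    if (nrow(presence) < 10) abort("need at least 10 frames")
  }
  per_area <- function(a) {
    tr <- presence[, a]
    if (!any(tr)) return(NULL)  # Toff undefined
    r <- rle(tr)
    k <- length(r$lengths)
    if (k > 2) {
      r$lengths <- r$lengths[2:(k - 1)]  # drop censored first/last runs
      r$values <- r$values[2:(k - 1)]
    } else {
      return(NULL)  # nothing uncensored
    }
    tibble(
      area = a,
      on_runs = list(r$lengths[r$values]),
      off_runs = list(r$lengths[!r$values]),
      ton_frames = mean(r$lengths[r$values]),
      toff_frames = mean(r$lengths[!r$values]),
      occupancy = mean(tr)
    )
  }
  areas <- purrr::compact(map(seq_len(ncol(presence)), per_area))
  if (length(areas) < ncol(presence)) {
    warn(sprintf("%d confinement area(s) excluded (all-absent or fully censored traces)",
                 ncol(presence) - length(areas)))
  }
  if (length(areas) == 0) abort("no usable presence traces")
  areas <- list_rbind(areas)
  # pool runs across areas: short traces hold few runs each, and a mean of
  # per-area means is biased for run-length statistics
  on_all <- unlist(areas$on_runs)
  off_all <- unlist(areas$off_runs)
  ton <- mean(on_all) * frame_time
  toff <- if (length(off_all) > 0) mean(off_all) * frame_time else 0
  if (!is.finite(ton)) abort("no interior on-runs in any trace")
  structure(list(
    ton = ton, toff = toff,
    detection_probability = ton / (ton + toff),
    occupancy_raw = mean(presence),
    n_areas = nrow(areas),
    frame_time = frame_time,
    areas = select(areas, -"on_runs", -"off_runs")
  ), class = "persistence_stats")
}

#' @export
print.persistence_stats <- function(x, ...) {
  cat(sprintf("<persistence_stats> Ton = %.2f s, Toff = %.2f s, p(detect) = %.2f (raw occupancy %.2f), %d areas\n",
              x$ton, x$toff, x$detection_probability, x$occupancy_raw, x$n_areas))
  invisible(x)
}
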