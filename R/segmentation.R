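# Morphological segmentation of bright ("filled") and dark ("hollow")
# nuclei in 3D stacks, matching between the two labelings, and mapping of
# centroids to fractional anterior-posterior position.

# Percentile contrast stretch (default 0.5-99.5%), clipping and rescaling
# to [0, 1].
contrast_stretch <- function(arr, probs = c(0.005, 0.995)) {
  q <- quantile(arr, probs, names = FALSE)
  if (diff(q) <= 0) return(array(0, dim(arr)))
  array(pmin(pmax((arr - q[1]) / diff(q), 0), 1), dim(arr))
}

apply_slices <- function(arr, f) {
  if (length(dim(arr)) == 2L) return(f(arr))
  for (k in seq_len(dim(arr)[3])) arr[, , k] <- f(arr[, , k])
  arr
}

# Greyscale morphological reconstruction by iterative geodesic dilation:
# dilate the marker, clamp under the mask image, repeat to stability.
morph_reconstruct <- function(marker, mask_img, brush, max_iter = 200L) {
  cur <- pmin(marker, mask_img)
  for (i in seq_len(max_iter)) {
    nxt <- pmin(apply_slices(cur, function(m) EBImage::dilate(m, brush)), mask_img)
    if (max(abs(nxt - cur)) < 1e-9) return(nxt)
    cur <- nxt
  }
  cur
}

# Fill holes slice-wise using EBImage::fillHull on a binary array.
fill_holes <- function(bin) {
  apply_slices(bin, function(m) EBImage::fillHull(m))
}

# Split touching nuclei: watershed on the 2D distance map of the xy
# occupancy projection, labels then extended along z (surface-layer nuclei
# form non-overlapping xy columns).
split_label_3d <- function(bin, tolerance = 2) {
  d3 <- length(dim(bin)) == 3L
  proj <- if (d3) apply(bin, c(1, 2), max) else bin
  if (!any(proj > 0)) {
    return(array(0L, dim(bin)))
  }
  dm <- EBImage::distmap(proj)
  lab2 <- EBImage::watershed(dm, tolerance = tolerance, ext = 1)
  lab2 <- EBImage::imageData(lab2)
  out <- array(0L, dim(bin))
  if (d3) {
    for (k in seq_len(dim(bin)[3])) {
      out[, , k] <- lab2 * (bin[, , k] > 0)
    }
  } else {
    out <- lab2 * (bin > 0)
  }
  storage.mode(out) <- "integer"
  out
}

label_records <- function(labels, raw, acq, min_voxels = 27L) {
  vx <- acq$voxel_xy / 1000
  vz <- acq$voxel_z / 1000
  d3 <- length(dim(labels)) == 3L
  ids <- sort(unique(labels[labels > 0]))
  rows <- vector("list", length(ids))
  dims <- dim(labels)
  for (i in seq_along(ids)) {
    idx <- which(labels == ids[i], arr.ind = TRUE)
    if (nrow(idx) < min_voxels) next
    vol_um3 <- nrow(idx) * vx * vx * (if (d3) vz else 1)
    border <- any(idx[, 1] %in% c(1L, dims[1])) || any(idx[, 2] %in% c(1L, dims[2]))
    rows[[i]] <- tibble(
      label = ids[i],
      cx_px = mean(idx[, 1]), cy_px = mean(idx[, 2]),
      cz_px = if (d3) mean(idx[, 3]) else NA_real_,
      x_um = mean(idx[, 1]) * vx, y_um = mean(idx[, 2]) * vx,
      z_um = if (d3) mean(idx[, 3]) * vz else NA_real_,
      n_voxels = nrow(idx),
      volume_um3 = vol_um3,
      diameter_um = if (d3) (6 * vol_um3 / pi)^(1 / 3) else 2 * sqrt(vol_um3 / pi),
      Inuc = mean(raw[labels == ids[i]]),
      on_border = border
    )
  }
  out <- list_rbind(purrr::compact(rows))
  if (nrow(out) == 0) {
    out <- tibble(
      label = integer(0), cx_px = numeric(0), cy_px = numeric(0),
      cz_px = numeric(0), x_um = numeric(0), y_um = numeric(0),
      z_um = numeric(0), n_voxels = integer(0), volume_um3 = numeric(0),
      diameter_um = numeric(0), Inuc = numeric(0), on_border = logical(0)
    )
  }
  out
}

#' Segment bright ("filled") nuclei in a 3D stack
#'
#' Morphological pipeline for nuclei that are brighter than the surrounding
#' cytoplasm (a GFP-enriched transcription factor): contrast adjustment,
#' median and Gaussian smoothing, erosion followed by morphological
#' reconstruction and dilation (flattening intranuclear texture such as
#' clusters), complementing, blurring, closing and a final erosion, Otsu
#' binarisation, and a watershed split of touching nuclei.
#'
#' @param stack An [image_stack()] (single-channel 3D or 2D) or numeric array.
#' @param acq Acquisition parameters (taken from the stack when available).
#' @param channel Channel to segment. Default first.
#' @param nucleus_diameter_um Expected nucleus diameter, sets structuring
#'   element sizes (xy brush ~ diameter/10). Default 5.
#' @param min_volume_um3 Minimum accepted nucleus volume. Default 8.
#' @return A list of class `nuclei_seg`: `records` (tibble of
#'   per-nucleus centroid, equivalent diameter, mean intensity `Inuc`,
#'   border flag) and `labels` (integer label array).
#' @export
segment_filled_nuclei <- function(stack, acq = NULL, channel = 1L,
                                  nucleus_diameter_um = 5,
                                  min_volume_um3 = 8) {
  arr <- if (inherits(stack, "image_stack")) stack$channels[[channel]] else stack
  acq <- acq %||% (if (inherits(stack, "image_stack")) stack$acq else NULL)
  if (is.null(acq)) abort("`acq` must be supplied when `stack` is a bare array")
  raw <- arr
  vx <- acq$voxel_xy / 1000
  d3 <- length(dim(arr)) == 3L
  # degenerate-contrast guard: a stack without genuine structure would have
  # its noise amplified to full range by the contrast stretch
  q <- quantile(arr, c(0.005, 0.5, 0.995), names = FALSE)
  if ((q[3] - q[1]) < 0.1 * max(q[2], .Machine$double.eps)) {
    return(structure(list(records = label_records(array(0L, dim(arr)), raw, acq),
                          labels = array(0L, dim(arr)),
                          mode = "filled"),
                     class = "nuclei_seg"))
  }
  brush_px <- max(3L, round(nucleus_diameter_um / 10 / vx))
  if (brush_px %% 2 == 0) brush_px <- brush_px + 1L
  box <- EBImage::makeBrush(brush_px, "box")

  img <- contrast_stretch(arr)
  img <- apply_slices(img, function(m) EBImage::medianFilter(m, 2))
  img <- gauss_blur_3d(img, sigma_xy_px = 2, sigma_z_px = if (d3) 1 else 0)
  er <- apply_slices(img, function(m) EBImage::erode(m, box))
  rec <- morph_reconstruct(er, img, box)
  dil <- apply_slices(rec, function(m) EBImage::dilate(m, box))
  comp <- max(dil) - dil
  comp <- gauss_blur_3d(comp, sigma_xy_px = 2, sigma_z_px = if (d3) 1 else 0)
  comp <- apply_slices(comp, function(m) EBImage::closing(m, box))
  comp <- apply_slices(comp, function(m) EBImage::erode(m, box))
  thr <- otsu_threshold(as.numeric(comp))
  bin <- (comp < thr) * 1  # nuclei are dark in the complemented image
  bin <- fill_holes(bin)
  labels <- split_label_3d(bin)
  min_vox <- max(27L, round(min_volume_um3 / (vx * vx * (if (d3) acq$voxel_z / 1000 else 1))))
  records <- label_records(labels, raw, acq, min_voxels = min_vox)
  keep <- labels %in% records$label
  labels[!keep] <- 0L
  structure(list(records = records, labels = labels, mode = "filled"),
            class = "nuclei_seg")
}

#' Segment dark ("hollow") nuclei in a 3D stack
#'
#' Pipeline for channels where the nucleoplasm is darker than the
#' internuclear space (an MCP-type label excluded from nuclei): contrast
#' adjustment, median and Gaussian smoothing, bright-background binarisation
#' (extended-maxima style), inversion so nuclei become foreground, box-kernel
#' convolution with a majority threshold (removing thin bright seams),
#' watershed splitting, opening, and hole filling.
#'
#' @inheritParams segment_filled_nuclei
#' @return A `nuclei_seg` list, as [segment_filled_nuclei()].
#' @export
segment_hollow_nuclei <- function(stack, acq = NULL, channel = 1L,
                                  nucleus_diameter_um = 5,
                                  min_volume_um3 = 8) {
  arr <- if (inherits(stack, "image_stack")) stack$channels[[channel]] else stack
  acq <- acq %||% (if (inherits(stack, "image_stack")) stack$acq else NULL)
  if (is.null(acq)) abort("`acq` must be supplied when `stack` is a bare array")
  raw <- arr
  vx <- acq$voxel_xy / 1000
  d3 <- length(dim(arr)) == 3L
  # degenerate-contrast guard: a stack without genuine structure would have
  # its noise amplified to full range by the contrast stretch
  q <- quantile(arr, c(0.005, 0.5, 0.995), names = FALSE)
  if ((q[3] - q[1]) < 0.1 * max(q[2], .Machine$double.eps)) {
    return(structure(list(records = label_records(array(0L, dim(arr)), raw, acq),
                          labels = array(0L, dim(arr)),
                          mode = "hollow"),
                     class = "nuclei_seg"))
  }
  brush_px <- max(3L, round(nucleus_diameter_um / 10 / vx))
  if (brush_px %% 2 == 0) brush_px <- brush_px + 1L
  box <- EBImage::makeBrush(brush_px, "box")

  img <- contrast_stretch(arr)
  img <- apply_slices(img, function(m) EBImage::medianFilter(m, 2))
  img <- gauss_blur_3d(img, sigma_xy_px = 2, sigma_z_px = if (d3) 1 else 0)
  thr <- otsu_threshold(as.numeric(img))
  bright <- (img >= thr) * 1          # internuclear space
  inv <- 1 - bright                   # nuclei foreground
  # box-kernel convolution + majority threshold: suppress thin seams/speckle
  k <- matrix(1 / (brush_px^2), brush_px, brush_px)
  sm <- apply_slices(inv, function(m) EBImage::filter2(m, k))
  bin <- (sm > 0.5) * 1
  bin <- apply_slices(bin, function(m) EBImage::opening(m, box))
  bin <- fill_holes(bin)
  labels <- split_label_3d(bin)
  min_vox <- max(27L, round(min_volume_um3 / (vx * vx * (if (d3) acq$voxel_z / 1000 else 1))))
  records <- label_records(labels, raw, acq, min_voxels = min_vox)
  # drop the background component: a hollow-channel "nucleus" touching the
  # full frame border is the inter-nuclear sea
  if (nrow(records) > 0) {
    frame_area <- prod(dim(arr)[1:2]) * vx * vx
    too_big <- records$volume_um3 > 0.5 * frame_area * (if (d3) acq$voxel_z / 1000 * dim(arr)[3] else 1)
    records <- records[!too_big, ]
  }
  keep <- labels %in% records$label
  labels[!keep] <- 0L
  structure(list(records = records, labels = labels, mode = "hollow"),
            class = "nuclei_seg")
}

#' @export
print.nuclei_seg <- function(x, ...) {
  cat(sprintf("<nuclei_seg> %s mode, %d nuclei\n", x$mode, nrow(x$records)))
  invisible(x)
}

#' Match two nucleus labelings by centroid proximity
#'
#' Greedy nearest-centroid matching between a filled-channel and a
#' hollow-channel segmentation. Pairs are accepted while their centroid
#' distance is below half a nuclear length; unmatched records are flagged.
#'
#' @param filled,hollow Tibbles of nucleus records (with `x_um`, `y_um` and
#'   optionally `z_um`), or `nuclei_seg` objects.
#' @param nuclear_length_um Nuclear length scale; the acceptance threshold is
#'   half of it. Default 5.
#' @return A tibble with `label_filled`, `label_hollow`, `distance_um`, and
#'   a `matched` flag; unmatched records appear with `NA` partners.
#' @export
match_nuclei <- function(filled, hollow, nuclear_length_um = 5) {
  f <- if (inherits(filled, "nuclei_seg")) filled$records else as_tibble(filled)
  h <- if (inherits(hollow, "nuclei_seg")) hollow$records else as_tibble(hollow)
  if (nrow(f) == 0 || nrow(h) == 0) abort("both nucleus lists must be non-empty")
  use_z <- all(c("z_um") %in% names(f)) && all(c("z_um") %in% names(h)) &&
    !anyNA(f$z_um) && !anyNA(h$z_um)
  D <- outer(f$x_um, h$x_um, `-`)^2 + outer(f$y_um, h$y_um, `-`)^2
  if (use_z) D <- D + outer(f$z_um, h$z_um, `-`)^2
  D <- sqrt(D)
  thr <- nuclear_length_um / 2
  pairs <- list()
  Dw <- D
  repeat {
    m <- which.min(Dw)
    if (length(m) == 0 || !is.finite(Dw[m]) || Dw[m] >= thr) break
    i <- (m - 1) %% nrow(Dw) + 1
    j <- (m - 1) %/% nrow(Dw) + 1
    pairs[[length(pairs) + 1L]] <- tibble(
      label_filled = f$label[i], label_hollow = h$label[j],
      distance_um = Dw[m], matched = TRUE
    )
    Dw[i, ] <- Inf
    Dw[, j] <- Inf
  }
  matched <- if (length(pairs) > 0) list_rbind(pairs) else
    tibble(label_filled = integer(0), label_hollow = integer(0),
           distance_um = numeric(0), matched = logical(0))
  un_f <- setdiff(f$label, matched$label_filled)
  un_h <- setdiff(h$label, matched$label_hollow)
  bind_rows(
    matched,
    tibble(label_filled = un_f, label_hollow = NA_integer_,
           distance_um = NA_real_, matched = FALSE),
    tibble(label_filled = NA_integer_, label_hollow = un_h,
           distance_um = NA_real_, matched = FALSE)
  )
}

#' Embryo coordinate geometry
#'
#' Anterior and posterior tip positions in microscope stage coordinates
#' define the anterior-posterior axis; the embryo length is their distance.
#'
#' @param anterior,posterior Numeric length-2 vectors `(x, y)` in stage
#'   coordinates (um).
#' @return An `embryo_geometry` object with `anterior`, `posterior`, `L`.
#' @export
embryo_geometry <- function(anterior, posterior) {
  stopifnot(length(anterior) == 2, length(posterior) == 2)
  L <- sqrt(sum((posterior - anterior)^2))
  if (L <= 0) abort("anterior and posterior tips must be distinct")
  structure(list(anterior = as.numeric(anterior),
                 posterior = as.numeric(posterior), L = L),
            class = "embryo_geometry")
}

#' Fractional anterior-posterior position of nuclei
#'
#' Projects stage-coordinate centroids onto the anterior-posterior axis:
#' with `r_i` the distance from the anterior tip and `theta_i` the angle
#' between that displacement and the AP axis, the embryo-frame coordinate is
#' `x_i' = r_i * cos(theta_i)`, returned as a fraction of the embryo length.
#' The result is invariant under rigid motions of the stage frame, and
#' nuclei on either side of the axis map to the same `x'`.
#'
#' @param centroids Data frame with stage coordinates `x_um`, `y_um` (or a
#'   numeric matrix with two columns).
#' @param geom An [embryo_geometry()].
#' @return Numeric vector of `x/L` values.
#' @export
#' @examples
#' g <- embryo_geometry(c(0, 0), c(500, 0))
#' nucleus_position(data.frame(x_um = 250, y_um = 30), g)
nucleus_position <- function(centroids, geom) {
  stopifnot(inherits(geom, "embryo_geometry"))
  M <- if (is.matrix(centroids)) centroids else
    as.matrix(as.data.frame(centroids)[, c("x_um", "y_um")])
  dx <- M[, 1] - geom$anterior[1]
  dy <- M[, 2] - geom$anterior[2]
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx) -
    atan2(geom$posterior[2] - geom$anterior[2],
          geom$posterior[1] - geom$anterior[1])
  xprime <- r * cos(theta)
  xprime[r == 0] <- 0
  xprime / geom$L
}
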