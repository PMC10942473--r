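# Internal numeric and image helpers shared across modules.

# Deterministic stream splitting: every generator call owns one RNG stream
# derived from (seed, salt) by a fixed affine hash, so sub-draws are
# reproducible independently of call order. Keeps results < 2^31.
local_seed <- function(seed, salt = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 48271 + salt * 1299721) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Truncated-normal draws by rejection sampling; `lower` is a hard floor.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (lower >= mean + 6 * sd) {
    abort("degenerate truncation: lower bound is at or above the distribution body")
  }
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw > lower & draw < upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# Separable Gaussian blur. Lateral passes use EBImage's 2D filter per z-plane;
# the axial pass is a short explicit kernel with edge renormalisation (no
# wrap-around bias at the top/bottom slices).
gauss_blur_3d <- function(arr, sigma_xy_px, sigma_z_px = 0) {
  if (sigma_xy_px > 0) {
    if (length(dim(arr)) == 2L) {
      arr <- EBImage::gblur(arr, sigma = sigma_xy_px)
    } else {
      for (k in seq_len(dim(arr)[3])) {
        arr[, , k] <- EBImage::gblur(arr[, , k], sigma = sigma_xy_px)
      }
    }
  }
  if (sigma_z_px > 0 && length(dim(arr)) == 3L) {
    nz <- dim(arr)[3]
    half <- max(1L, ceiling(3 * sigma_z_px))
    w <- exp(-((-half:half)^2) / (2 * sigma_z_px^2))
    out <- array(0, dim(arr))
    norm <- numeric(nz)
    for (j in -half:half) {
      src <- seq_len(nz) + j
      keep <- src >= 1 & src <= nz
      wt <- w[j + half + 1]
      out[, , keep] <- out[, , keep] + wt * arr[, , src[keep]]
      norm[keep] <- norm[keep] + wt
    }
    for (k in seq_len(nz)) out[, , k] <- out[, , k] / norm[k]
    arr <- out
  }
  arr
}

rescale01 <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[2] <= rng[1]) {
    return(x * 0)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

# Mask-aware moving box statistics over a k x k window via integral images.
# Out-of-mask pixels contribute neither to the mean nor to the sd; windows
# shrink at mask edges instead of zero-padding.
box_stats <- function(img, mask, k = 25L) {
  stopifnot(all(dim(img) == dim(mask)))
  v <- ifelse(mask, img, 0)
  v2 <- v^2
  m <- mask * 1
  half <- (k - 1L) %/% 2L
  boxsum <- function(x) {
    nx <- nrow(x); ny <- ncol(x)
    S <- matrix(0, nx + 1L, ny + 1L)
    S[-1, -1] <- t(apply(apply(x, 2, cumsum), 1, cumsum))
    i1 <- pmax(seq_len(nx) - half, 1L); i2 <- pmin(seq_len(nx) + half, nx)
    j1 <- pmax(seq_len(ny) - half, 1L); j2 <- pmin(seq_len(ny) + half, ny)
    S[i2 + 1L, j2 + 1L] - S[i1, j2 + 1L] - S[i2 + 1L, j1] + S[i1, j1]
  }
  s1 <- boxsum(v); s2 <- boxsum(v2); cnt <- boxsum(m)
  mu <- ifelse(cnt > 0, s1 / cnt, NA_real_)
  varr <- ifelse(cnt > 1, pmax(0, (s2 - cnt * mu^2) / (cnt - 1)), 0)
  list(mean = mu, sd = sqrt(varr), n = cnt)
}

# Structural similarity index (mean SSIM) with the conventional Gaussian
# 11 x 11, sigma 1.5 local window and K1 = 0.01, K2 = 0.03 on dynamic range L.
ssim_index <- function(x, y, L = 1) {
  stopifnot(all(dim(x) == dim(y)))
  g <- outer(
    exp(-((-5:5)^2) / (2 * 1.5^2)),
    exp(-((-5:5)^2) / (2 * 1.5^2))
  )
  g <- g / sum(g)
  f <- function(z) EBImage::filter2(z, g)
  mx <- f(x); my <- f(y)
  sxx <- f(x^2) - mx^2; syy <- f(y^2) - my^2; sxy <- f(x * y) - mx * my
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  s <- ((2 * mx * my + c1) * (2 * sxy + c2)) /
    ((mx^2 + my^2 + c1) * (sxx + syy + c2))
  mean(s)
}

# Connected components of a sparse voxel set (26-connectivity), by union-find
# on linear voxel keys. `idx` is an integer matrix with columns x, y, z.
label_sparse_voxels <- function(idx, dims) {
  n <- nrow(idx)
  if (n == 0L) return(integer(0))
  key <- (idx[, 1] - 1) + dims[1] * ((idx[, 2] - 1) + dims[2] * (idx[, 3] - 1))
  ord <- order(key)
  skey <- key[ord]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  for (o in seq_len(nrow(offs))) {
    nb <- idx + matrix(offs[o, ], n, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nkey <- (nb[, 1] - 1) + dims[1] * ((nb[, 2] - 1) + dims[2] * (nb[, 3] - 1))
    pos <- findInterval(nkey, skey)
    hit <- ok & pos > 0 & skey[pmax(pos, 1)] == nkey
    for (i in which(hit)) {
      ri <- find(i); rj <- find(ord[pos[i]])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Uniform points in the unit 3-ball (rejection sampling, vectorised).
runif_in_ball <- function(n) {
  if (n == 0L) return(matrix(numeric(0), ncol = 3))
  out <- matrix(NA_real_, n, 3)
  need <- n
  while (need > 0) {
    draw <- matrix(runif(3 * ceiling(need * 2.2), -1, 1), ncol = 3)
    ok <- draw[rowSums(draw^2) <= 1, , drop = FALSE]
    take <- min(nrow(ok), need)
    if (take > 0) {
      out[(n - need + 1):(n - need + take), ] <- ok[seq_len(take), , drop = FALSE]
      need <- need - take
    }
  }
  out
}

# Uniform points in the unit ball with a hard-core minimum separation
# (rejection sampling in scaled coordinates; `min_sep` in the same units as
# `radius`). Gives up gracefully by relaxing the core if the request cannot
# be packed.
runif_hardcore_ball <- function(n, radius = 1, min_sep = 0) {
  out <- matrix(NA_real_, n, 3)
  k <- 0L
  tries <- 0L
  sep <- min_sep
  while (k < n) {
    cand <- runif_in_ball(1) * radius
    ok <- k == 0L ||
      min(sqrt(colSums((t(out[seq_len(k), , drop = FALSE]) - as.numeric(cand))^2))) >= sep
    if (ok) {
      k <- k + 1L
      out[k, ] <- cand
    }
    tries <- tries + 1L
    if (tries > 200L * n) {
      sep <- sep * 0.8  # cannot pack at this core; relax
      tries <- 0L
    }
  }
  out
}

# Radially averaged profile of a centred 2D map. Bin width = 1 pixel.
radial_average <- function(mapmat, center, max_r = NULL) {
  nx <- nrow(mapmat); ny <- ncol(mapmat)
  dx <- (seq_len(nx) - center[1])
  dy <- (seq_len(ny) - center[2])
  r <- sqrt(outer(dx^2, dy^2, `+`))
  rb <- floor(r + 0.5)
  keep <- is.finite(mapmat)
  if (!is.null(max_r)) keep <- keep & rb <= max_r
  agg <- tapply(mapmat[keep], rb[keep], mean)
  tibble(
    r_px = as.numeric(names(agg)),
    value = as.numeric(agg),
    n_px = as.numeric(tapply(rep(1, sum(keep)), rb[keep], sum))
  ) |> arrange(.data$r_px)
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(paste0("`", name, "` must be a single positive number"))
  }
  invisible(x)
}
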