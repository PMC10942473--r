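# Berg-Purcell-style concentration-sensing times for a cluster versus a
# single enhancer binding site, and their profile along the AP axis.

#' Sensing parameters
#'
#' @param D Diffusion constant of the transcription factor (um^2/s).
#'   Required; no default is assumed.
#' @param a_nm Binding-site linear size (nm). Default 3.4.
#' @param d_um Cluster effective diameter (um). Default 0.4.
#' @param c_clust In-cluster concentration (molecules/um^3).
#' @param c_nuc Nuclear concentration (molecules/um^3).
#' @param accuracy Fractional counting accuracy dN/N. Default 0.10.
#' @return A `sensing_params` list.
#' @export
sensing_params <- function(D, a_nm = 3.4, d_um = 0.4,
                           c_clust = 1320, c_nuc = 600, accuracy = 0.10) {
  assert_scalar_pos(D, "D")
  assert_scalar_pos(a_nm, "a_nm")
  assert_scalar_pos(d_um, "d_um")
  assert_scalar_pos(c_clust, "c_clust")
  assert_scalar_pos(c_nuc, "c_nuc")
  if (accuracy <= 0 || accuracy >= 1) abort("`accuracy` must lie in (0, 1)")
  structure(list(D = D, a_nm = a_nm, d_um = d_um, c_clust = c_clust,
                 c_nuc = c_nuc, accuracy = accuracy),
            class = "sensing_params")
}

#' Cluster sensing time
#'
#' Time for a cluster of diameter `d` holding concentration `c_clust` to
#' mirror the nuclear concentration with fractional accuracy `dN/N`:
#' `T_clust = 6 / (D d c_clust) * (dN/N)^-2`, the prefactor reading that is
#' consistent with the site/cluster ratio `d/(6a) * c_clust/c_nuc`.
#'
#' @param p A [sensing_params()] object.
#' @return Time in seconds.
#' @export
#' @examples
#' t_cluster(sensing_params(D = 1))
t_cluster <- function(p) {
  stopifnot(inherits(p, "sensing_params"))
  6 / (p$D * p$d_um * p$c_clust) * p$accuracy^-2
}

#' Binding-site sensing time
#'
#' Analogous time for a single binding site of linear size `a` reading the
#' nuclear concentration: `T_site = 1 / (D a c_nuc) * (dN/N)^-2`.
#'
#' @inheritParams t_cluster
#' @return Time in seconds.
#' @export
t_site <- function(p) {
  stopifnot(inherits(p, "sensing_params"))
  a_um <- p$a_nm / 1000
  1 / (p$D * a_um * p$c_nuc) * p$accuracy^-2
}

#' Site-to-cluster sensing-time ratio
#'
#' `T_site / T_clust = d / (6 a) * c_clust / c_nuc`; independent of the
#' diffusion constant and of the accuracy.
#'
#' @inheritParams t_cluster
#' @return Dimensionless ratio.
#' @export
#' @examples
#' sensing_ratio(sensing_params(D = 1))
sensing_ratio <- function(p) {
  stopifnot(inherits(p, "sensing_params"))
  a_um <- p$a_nm / 1000
  p$d_um / (6 * a_um) * (p$c_clust / p$c_nuc)
}

#' Sensing-time ratio profile along the AP axis
#'
#' Evaluates the site/cluster ratio per position bin using bin-wise cluster
#' diameter and concentration amplification (`c_clust / c_nuc = Ia/Ibg`),
#' e.g. from a [bin_and_bootstrap()] table of `mean_d_um` and
#' `mean_amp_ratio`; bins missing either input are skipped.
#'
#' @param table Data frame with one row per bin and columns for diameter and
#'   amplification.
#' @param p A [sensing_params()] (supplies `a_nm`; `d_um`, `c_clust`,
#'   `c_nuc` are overridden bin-wise).
#' @param d_col,amp_col Column names. Defaults `"mean_d_um"`,
#'   `"mean_amp_ratio"`.
#' @return A tibble with per-bin `ratio` plus `mean` and `sd` attributes;
#'   also accessible via the returned `summary` attribute.
#' @export
ratio_profile <- function(table, p, d_col = "mean_d_um",
                          amp_col = "mean_amp_ratio") {
  df <- as_tibble(table)
  stopifnot(all(c(d_col, amp_col) %in% names(df)))
  keep <- is.finite(df[[d_col]]) & is.finite(df[[amp_col]])
  if (!all(keep)) {
    warn(sprintf("skipping %d bin(s) with missing inputs", sum(!keep)))
  }
  df <- df[keep, ]
  a_um <- p$a_nm / 1000
  df$ratio <- df[[d_col]] / (6 * a_um) * df[[amp_col]]
  structure(df, summary = list(mean = mean(df$ratio), sd = sd(df$ratio)))
}
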