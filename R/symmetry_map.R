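# Per-subject functional-symmetry mapping: homotopic Pearson correlation,
# Fisher r-to-z transform, effective degrees of freedom under temporal
# autocorrelation, and the df-corrected z score
#
#   z_f = arctanh(r),      z = z_f * sqrt(df - 3),
#
# where the effective df of a correlation between two autocorrelated
# series x, y of length N is estimated by the autocorrelation plug-in
#
#   1/df = 1/N + (2/N) * sum_{j>=1} ((N - j)/N) * rho_xx(j) * rho_yy(j).

#' Homotopic correlation map of a 4D series
#'
#' Pearson correlation of each voxel's time series with its homotopic
#' (x-mirrored) partner.  The resulting map is exactly mirror-symmetric:
#' a pair has one correlation, stored at both members.
#'
#' @param series a `series_volume` with even x-dimension and >= 3
#'   timepoints.
#' @return a `symmetry_map` with fields `r` (3D array, `NA` outside the
#'   mask), `mask` (logical 3D array; zero-variance voxels excluded),
#'   `n_timepoints`, `voxel_mm`.
#' @export
homotopic_correlation_map <- function(series) {
  d <- grid_dim(series)
  nt <- dim(series$data)[4L]
  if (nt < 3L) stopf("need at least 3 timepoints")
  idx <- homotopic_indices(d)
  y <- series_matrix(series)
  yl <- y[, idx$left, drop = FALSE]
  yr <- y[, idx$right, drop = FALSE]
  r <- pair_correlation(yl, yr)
  if (all(is.na(r))) warning("all voxel pairs have zero variance: empty mask")
  rmap <- array(NA_real_, d)
  rmap[idx$left] <- r
  rmap[idx$right] <- r
  structure(list(r = rmap, z_f = NULL, z = NULL,
                 mask = !is.na(rmap), df = NULL,
                 n_timepoints = nt, voxel_mm = series$voxel_mm),
            class = "symmetry_map")
}

# Columnwise Pearson correlation of two matrices; zero-variance columns
# give NA.
pair_correlation <- function(a, b) {
  n <- nrow(a)
  a <- sweep(a, 2L, colMeans(a))
  b <- sweep(b, 2L, colMeans(b))
  sa <- sqrt(colSums(a^2))
  sb <- sqrt(colSums(b^2))
  r <- colSums(a * b) / (sa * sb)
  r[sa == 0 | sb == 0] <- NA_real_
  r
}

#' @export
print.symmetry_map <- function(x, ...) {
  cat(sprintf(
    "<symmetry_map> %s voxels, %d in mask, N = %d%s\n",
    paste(dim(x$r), collapse = " x "), sum(x$mask), x$n_timepoints,
    if (is.null(x$df)) "" else sprintf(", df = %.1f", x$df)))
  invisible(x)
}

#' Fisher r-to-z transform
#'
#' The variance-stabilizing transform `atanh(r)`; its sampling
#' distribution is approximately normal with variance 1/(df - 3).  A
#' literal `atan` variant is provided for replication of sources that
#' print the transform that way, but `atanh` is the standard form.
#'
#' @param r correlations in (-1, 1); values with |r| >= 1 return `NA`
#'   (flagged with a warning) rather than an infinite score.
#' @param variant `"arctanh"` (default) or `"arctan"`.
#' @return transformed values, same shape as `r`.
#' @export
fisher_z <- function(r, variant = c("arctanh", "arctan")) {
  variant <- match.arg(variant)
  bad <- !is.na(r) & abs(r) >= 1
  if (any(bad)) {
    warning(sprintf("%d correlation(s) with |r| >= 1 masked out", sum(bad)))
    r[bad] <- NA_real_
  }
  if (variant == "arctanh") atanh(r) else atan(r)
}

#' Effective degrees of freedom of one autocorrelated pair
#'
#' Plug-in estimate from the sample autocorrelations (biased estimator,
#' divisor N) of the two series.  The result is clipped into (3, N]: a
#' white pair has df = N; heavy shared autocorrelation reduces df.
#'
#' @param x,y numeric series of equal length N >= 10.
#' @param max_lag largest lag in the sum (default N - 1).
#' @return scalar df.
#' @export
effective_df_pair <- function(x, y, max_lag = NULL) {
  n <- length(x)
  if (length(y) != n) stopf("series lengths differ")
  if (n < 10L) stopf("need at least 10 timepoints")
  if (sd(x) == 0 || sd(y) == 0)
    stopf("constant series: autocorrelation undefined")
  if (is.null(max_lag)) max_lag <- n - 1L
  max_lag <- min(max_lag, n - 1L)
  rx <- acf_biased(x, max_lag)
  ry <- acf_biased(y, max_lag)
  j <- seq_len(max_lag)
  inv <- 1 / n + (2 / n) * sum(((n - j) / n) * rx * ry)
  clip_df(1 / inv, n)
}

clip_df <- function(df, n) {
  df[!is.finite(df) | df < 0] <- n  # negative inverse: autocorr sum < -1/2
  pmin(pmax(df, 3 + 1e-8), n)
}

# Biased sample autocorrelations at lags 1..max_lag (divisor N), one
# series.
acf_biased <- function(x, max_lag) {
  acf_biased_matrix(matrix(x, ncol = 1L), max_lag)[, 1L]
}

# FFT-based biased autocorrelations for each column of a matrix;
# returns max_lag x ncol matrix of lags 1..max_lag.
acf_biased_matrix <- function(y, max_lag) {
  n <- nrow(y)
  y <- sweep(y, 2L, colMeans(y))
  m <- nextn(2L * n, c(2L, 3L, 5L))
  pad <- rbind(y, matrix(0, m - n, ncol(y)))
  f <- mvfft(pad)
  s <- Re(mvfft(f * Conj(f), inverse = TRUE)) / m
  acov <- s[seq_len(max_lag + 1L), , drop = FALSE] / n
  sweep(acov[-1L, , drop = FALSE], 2L, acov[1L, ], "/")
}

#' Study-level effective degrees of freedom
#'
#' Samples `n_pairs` homotopic voxel pairs uniformly from the valid mask
#' of a series, computes the plug-in df for each pair, and averages the
#' estimates.  With several subjects, call per subject and average the
#' per-subject means again.
#'
#' @param series a `series_volume`.
#' @param n_pairs pairs to sample (default 1000); if fewer valid pairs
#'   exist, all are used and the result is flagged.
#' @param seed integer seed for pair sampling.
#' @param max_lag largest lag in the plug-in sum (default N - 1).
#' @return an `effective_df` object: `df` (the mean), `per_pair`,
#'   `n_pairs`, `n_timepoints`, `all_pairs_used`, `seed`.
#' @export
estimate_effective_df <- function(series, n_pairs = 1000L, seed = 1L,
                                  max_lag = NULL) {
  d <- grid_dim(series)
  idx <- homotopic_indices(d)
  y <- series_matrix(series)
  n <- nrow(y)
  if (is.null(max_lag)) max_lag <- n - 1L
  max_lag <- min(max_lag, n - 1L)
  ok <- apply_sd_ok(y, idx)
  if (!any(ok)) stopf("no homotopic pair has positive variance")
  all_used <- sum(ok) <= n_pairs
  pick <- with_seed(seed, {
    if (all_used) which(ok)
    else sample(which(ok), n_pairs)
  })
  rx <- acf_biased_matrix(y[, idx$left[pick], drop = FALSE], max_lag)
  ry <- acf_biased_matrix(y[, idx$right[pick], drop = FALSE], max_lag)
  j <- seq_len(max_lag)
  inv <- 1 / n + (2 / n) * colSums(((n - j) / n) * rx * ry)
  per_pair <- clip_df(1 / inv, n)
  structure(list(df = mean(per_pair), per_pair = per_pair,
                 n_pairs = length(pick), n_timepoints = n,
                 all_pairs_used = all_used, seed = seed),
            class = "effective_df")
}

apply_sd_ok <- function(y, idx) {
  v <- matrixStats_colVars(y)
  v[idx$left] > 0 & v[idx$right] > 0
}

matrixStats_colVars <- function(y) {
  n <- nrow(y)
  colSums(sweep(y, 2L, colMeans(y))^2) / (n - 1L)
}

#' @export
print.effective_df <- function(x, ...) {
  cat(sprintf("<effective_df> df = %.1f over %d pairs (N = %d)%s\n",
              x$df, x$n_pairs, x$n_timepoints,
              if (x$all_pairs_used) " [all pairs used]" else ""))
  invisible(x)
}

#' df-corrected z score
#'
#' Divides the Fisher z by its standard error 1/sqrt(df - 3).
#'
#' @param z_f Fisher-transformed correlation(s).
#' @param df effective degrees of freedom, > 3.
#' @return z scores, same shape as `z_f`.
#' @export
corrected_z <- function(z_f, df) {
  if (any(df <= 3)) stopf("'df' must exceed 3")
  z_f * sqrt(df - 3)
}

#' Full per-subject symmetry map
#'
#' Convenience wrapper: homotopic correlation, Fisher z, study df, and
#' the corrected z in one object.
#'
#' @param series a `series_volume`.
#' @param df effective degrees of freedom to use; `NULL` estimates it
#'   from this series via [estimate_effective_df()].
#' @param n_pairs,seed passed to [estimate_effective_df()] when `df` is
#'   `NULL`.
#' @param variant Fisher transform variant, see [fisher_z()].
#' @return a `symmetry_map` with `r`, `z_f`, `z`, `mask`, `df`.
#' @export
symmetry_map <- function(series, df = NULL, n_pairs = 1000L, seed = 1L,
                         variant = "arctanh") {
  m <- homotopic_correlation_map(series)
  if (is.null(df))
    df <- estimate_effective_df(series, n_pairs = n_pairs, seed = seed)$df
  m$z_f <- suppressWarnings(fisher_z(m$r, variant = variant))
  m$mask <- m$mask & !is.na(m$z_f)
  m$z <- corrected_z(m$z_f, df)
  m$df <- df
  m
}
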