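# Temporal preprocessing of 4D series: run concatenation with initial
# sample discard, spline detrending, temporal Gaussian filtering, and
# nuisance regression.

#' Concatenate runs after discarding initial samples
#'
#' Drops the first `n_discard` volumes of each run (defaults to 4, the
#' usual guard against initial magnetization transients) and concatenates
#' the remainder along time.
#'
#' @param runs list of `series_volume` objects on the same grid and TR.
#' @param n_discard volumes removed from the start of every run.
#' @return a `series_volume`.
#' @export
concatenate_runs <- function(runs, n_discard = 4) {
  if (!length(runs)) stopf("'runs' must be a non-empty list")
  n_discard <- as.integer(n_discard)
  if (n_discard < 0) stopf("'n_discard' must be >= 0")
  ref <- runs[[1L]]
  parts <- lapply(runs, function(r) {
    if (!inherits(r, "series_volume")) stopf("all runs must be series_volume")
    if (!same_grid(r, ref) || abs(r$tr_s - ref$tr_s) > 1e-9)
      stopf("runs must share grid, voxel size and repetition interval")
    nt <- dim(r$data)[4L]
    if (nt <= n_discard)
      stopf("run of %d timepoints is not longer than n_discard = %d",
            nt, n_discard)
    r$data[, , , (n_discard + 1L):nt, drop = FALSE]
  })
  series_volume(array(unlist(parts),
                      c(grid_dim(ref), sum(vapply(parts, function(p)
                        dim(p)[4L], integer(1))))),
                voxel_mm = ref$voxel_mm, tr_s = ref$tr_s)
}

#' Remove slow drift with a cubic-spline trend
#'
#' Fits, per voxel, a cubic B-spline with interior knots every
#' `knot_spacing_s` seconds (plus an intercept) and subtracts it, leaving
#' a zero-mean residual series.
#'
#' @param series a `series_volume`.
#' @param knot_spacing_s knot spacing of the trend model, seconds
#'   (default 128 s, a conventional high-pass scale).
#' @return detrended `series_volume`.
#' @export
detrend_series <- function(series, knot_spacing_s = 128) {
  nt <- dim(series$data)[4L]
  if (nt < 4L) stopf("detrending needs at least 4 timepoints")
  if (knot_spacing_s <= 0) stopf("'knot_spacing_s' must be positive")
  if (knot_spacing_s >= nt * series$tr_s)
    stopf("knot spacing (%g s) must be shorter than the series (%g s)",
          knot_spacing_s, nt * series$tr_s)
  tt <- (seq_len(nt) - 1) * series$tr_s
  interior <- if (max(tt) - 1e-9 > knot_spacing_s)
    seq(knot_spacing_s, max(tt) - 1e-9, by = knot_spacing_s) else NULL
  basis <- cbind(1, splines::bs(tt, knots = interior, degree = 3L))
  qrb <- qr(basis)
  y <- series_matrix(series)
  res <- qr.resid(qrb, y)
  matrix_to_series(res, series)
}

#' Temporal Gaussian filtering
#'
#' Convolves each voxel time series with a discrete Gaussian kernel whose
#' width is given as FWHM in seconds (the SPM convention for "kernel
#' width"); near the series edges the kernel is renormalized over the
#' available samples, which preserves constants everywhere.
#'
#' @param series a `series_volume`.
#' @param kernel_fwhm_s kernel width (FWHM), seconds; default 4.
#' @param interpret how to read `kernel_fwhm_s`: `"fwhm"` (default) or
#'   `"sigma"`.
#' @return filtered `series_volume`.
#' @export
temporal_filter <- function(series, kernel_fwhm_s = 4,
                            interpret = c("fwhm", "sigma")) {
  interpret <- match.arg(interpret)
  check_scalar_num(kernel_fwhm_s, "kernel_fwhm_s", 0, strict_lower = TRUE)
  sigma_s <- if (interpret == "fwhm") fwhm_to_sigma(kernel_fwhm_s)
             else kernel_fwhm_s
  sigma <- sigma_s / series$tr_s
  nt <- dim(series$data)[4L]
  half <- max(1L, ceiling(4 * sigma))
  lags <- -half:half
  k <- exp(-lags^2 / (2 * sigma^2))
  k <- k / sum(k)
  # banded convolution matrix with edge renormalization
  K <- matrix(0, nt, nt)
  for (j in seq_along(lags)) {
    i <- which(seq_len(nt) + lags[j] >= 1L & seq_len(nt) + lags[j] <= nt)
    K[cbind(i, i + lags[j])] <- K[cbind(i, i + lags[j])] + k[j]
  }
  K <- K / rowSums(K)
  matrix_to_series(K %*% series_matrix(series), series)
}

#' Project nuisance regressors out of every voxel series
#'
#' Least-squares residual after regressing on the supplied regressors
#' plus an intercept; with no regressors this mean-centres the series.
#'
#' @param series a `series_volume`.
#' @param regressors numeric matrix with one row per timepoint, or `NULL`.
#' @return residual `series_volume`.
#' @export
nuisance_regress <- function(series, regressors = NULL) {
  nt <- dim(series$data)[4L]
  X <- if (is.null(regressors)) matrix(1, nt, 1L)
       else cbind(1, as.matrix(regressors))
  if (nrow(X) != nt)
    stopf("regressors have %d rows but the series has %d timepoints",
          nrow(X), nt)
  qrx <- qr(X)
  if (qrx$rank < ncol(X))
    stopf("regressor matrix (plus intercept) is rank deficient")
  matrix_to_series(qr.resid(qrx, series_matrix(series)), series)
}
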