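# Template symmetrization: fit the polynomial coordinate transform that
# minimizes the mean squared intensity error between homotopic voxels,
#
#   cost(a) = mean over left-hemisphere voxels x of
#             [ b(f_a(r(x))) - b(x) ]^2,
#
# where r mirrors across the midsagittal plane, b samples the template by
# trilinear interpolation, and f_a is a trivariate polynomial transform.
# Minimization uses the derivative-free Nelder-Mead simplex with random
# restarts around the identity transform.

#' Mirror a physical coordinate across the midsagittal plane
#'
#' The mirror plane is x = 0 in template physical coordinates.
#'
#' @param point length-3 vector or n x 3 matrix of coordinates (mm).
#' @return same shape with the x coordinate negated.
#' @export
mirror_coordinates <- function(point) {
  if (is.matrix(point)) {
    point[, 1L] <- -point[, 1L]
    point
  } else {
    c(-point[1L], point[2L], point[3L])
  }
}

left_voxel_centers <- function(volume) {
  d <- grid_dim(volume)
  check_even_x(d)
  pts <- voxel_centers(volume)
  pts[homotopic_indices(d)$left, , drop = FALSE]
}

#' Homotopic symmetrization cost of a warp on a template
#'
#' Mean squared difference between the template and its warped mirror,
#' evaluated over left-hemisphere voxel centres.  Samples falling outside
#' the domain take `fill` and, under the default contract, are included in
#' the mean; set `exclude_oob = TRUE` to drop them instead.
#'
#' @param warp `warp_parameters`.
#' @param template `volume_grid` with even x-dimension.
#' @param fill out-of-domain fill value.
#' @param exclude_oob drop out-of-domain samples from the mean?
#' @return non-negative scalar (squared intensity units).
#' @export
symmetrization_cost <- function(warp, template, fill = 0,
                                exclude_oob = FALSE) {
  if (all(template$data == 0))
    warning("constant-zero template: symmetrization cost is trivially 0")
  pts <- left_voxel_centers(template)
  target <- template$data[homotopic_indices(grid_dim(template))$left]
  mapped <- evaluate_warp(warp, mirror_coordinates(pts))
  if (exclude_oob) {
    d <- grid_dim(template); v <- template$voxel_mm
    lim <- (d - 1) / 2 * v
    ok <- abs(mapped[, 1L]) <= lim[1L] & abs(mapped[, 2L]) <= lim[2L] &
      abs(mapped[, 3L]) <= lim[3L]
    if (!any(ok)) return(NA_real_)
    mapped <- mapped[ok, , drop = FALSE]
    target <- target[ok]
  }
  got <- trilinear_sample(template, mapped, fill = fill)
  mean((got - target)^2)
}

#' Hemispheric mean squared error of a volume
#'
#' Mean squared difference between a volume and its x-flipped image,
#' averaged over one hemisphere.  Zero iff the volume is exactly
#' mirror-symmetric.
#'
#' @param volume `volume_grid` (or bare 3D array) with even x-dimension.
#' @return non-negative scalar.
#' @export
hemispheric_mse <- function(volume) {
  dat <- if (inherits(volume, "volume_grid")) volume$data else volume
  idx <- homotopic_indices(dim(dat))
  mean((dat[idx$left] - dat[idx$right])^2)
}

#' Fit the symmetrizing polynomial warp of a template
#'
#' Runs Nelder-Mead minimization of [symmetrization_cost()] from the
#' identity transform plus small random coefficient jitter, once per
#' restart, and returns the restart with the lowest converged cost.
#'
#' @param template `volume_grid` with even x-dimension.
#' @param degree polynomial degree of the warp family (default 5; fits at
#'   degree 5 have 168 free coefficients and are slow — tests use <= 2).
#' @param n_restarts number of randomized restarts (>= 1).
#' @param seed integer seed controlling the restart jitter.
#' @param options list of overrides: `maxit` (iteration cap, default
#'   `2000 * n_params`), `reltol` (default 1e-8), `jitter_sd` (default
#'   0.01 on normalized coordinates), `fill`, `exclude_oob`.
#' @return a `symmetrization_result`: fitted `warp`, `initial_mse`,
#'   `final_cost`, per-restart `restart_costs`, `cost_trace` (best cost so
#'   far at each function evaluation of the winning restart), `converged`
#'   flag, and `chosen_restart`.
#' @export
fit_symmetrization <- function(template, degree = 5, n_restarts = 5,
                               seed = 1, options = list()) {
  if (n_restarts < 1) stopf("'n_restarts' must be >= 1")
  opt <- modifyList(list(maxit = NULL, reltol = 1e-8, jitter_sd = 1e-2,
                         fill = 0, exclude_oob = FALSE), options)
  w0 <- identity_warp(template, degree)
  n_par <- length(w0$coefficients)
  maxit <- if (is.null(opt$maxit)) 2000L * n_par else opt$maxit
  make_warp <- function(par)
    warp_parameters(degree, matrix(par, ncol = 3L), w0$bounds)
  initial_mse <- hemispheric_mse(template)

  runs <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(k) {
      par0 <- as.vector(w0$coefficients)
      if (k > 1L) par0 <- par0 + rnorm(n_par, sd = opt$jitter_sd)
      trace_env <- new.env()
      trace_env$best <- Inf
      trace_env$trace <- numeric(0)
      fn <- function(par) {
        val <- symmetrization_cost(make_warp(par), template,
                                   fill = opt$fill,
                                   exclude_oob = opt$exclude_oob)
        trace_env$best <- min(trace_env$best, val)
        trace_env$trace <- c(trace_env$trace, trace_env$best)
        val
      }
      fit <- stats::optim(par0, fn, method = "Nelder-Mead",
                          control = list(maxit = maxit,
                                         reltol = opt$reltol))
      list(par = fit$par, value = fit$value,
           converged = fit$convergence == 0L, trace = trace_env$trace)
    })
  })

  costs <- vapply(runs, `[[`, numeric(1), "value")
  best <- which.min(costs)
  res <- runs[[best]]
  structure(list(warp = make_warp(res$par),
                 initial_mse = initial_mse,
                 final_cost = res$value,
                 restart_costs = costs,
                 cost_trace = res$trace,
                 converged = res$converged,
                 chosen_restart = best,
                 seed = seed),
            class = "symmetrization_result")
}

#' @export
print.symmetrization_result <- function(x, ...) {
  cat(sprintf(paste0("<symmetrization_result> degree %d, %d restart(s)\n",
                     "  initial hemispheric MSE: %.6g\n",
                     "  final cost:              %.6g  (restart %d%s)\n"),
              x$warp$degree, length(x$restart_costs), x$initial_mse,
              x$final_cost, x$chosen_restart,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Resample a series (or volume) through the symmetrizing warp
#'
#' Each timepoint volume is resampled through the fitted warp composed
#' with the mirror map: output voxel at x takes the input intensity at
#' f(r(x)), the convention under which [symmetrization_cost()] compares
#' intensities.  With `mirror = FALSE` the warp is applied alone.
#'
#' @param series a `series_volume` or `volume_grid` in the frame the warp
#'   was fitted on.
#' @param warp `warp_parameters`.
#' @param mirror compose with the midsagittal mirror map (default TRUE).
#' @param fill out-of-domain fill value.
#' @return object of the same class as `series`.
#' @export
apply_symmetrization <- function(series, warp, mirror = TRUE, fill = 0) {
  if (inherits(series, "volume_grid")) {
    ref <- series
  } else if (inherits(series, "series_volume")) {
    ref <- volume_grid(array(0, grid_dim(series)), series$voxel_mm)
  } else stopf("'series' must be a volume_grid or series_volume")
  if (max(abs(volume_bounds(ref) - warp$bounds)) > 1e-6)
    stopf("coordinate frame mismatch: warp was fitted on a different grid")
  pts <- voxel_centers(ref)
  if (mirror) pts <- mirror_coordinates(pts)
  mapped <- evaluate_warp(warp, pts)
  if (inherits(series, "volume_grid")) {
    out <- trilinear_sample(series, mapped, fill = fill)
    return(volume_grid(array(out, grid_dim(series)), series$voxel_mm))
  }
  d <- dim(series$data)
  out <- array(0, d)
  for (t in seq_len(d[4L])) {
    vol <- volume_grid(array(series$data[, , , t], d[1:3]), series$voxel_mm)
    out[, , , t] <- trilinear_sample(vol, mapped, fill = fill)
  }
  series_volume(out, series$voxel_mm, series$tr_s)
}
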