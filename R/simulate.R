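# Synthetic-data generators: mirror-symmetric smooth templates, 4D series
# in which homotopic voxel pairs share a common signal yielding a target
# correlation rho, group datasets with a planted homotopic-correlation
# increase, and corpus-callosum volume tables.
#
# Target-correlation construction: with S, U1, U2 independent standardized
# AR(1) processes with the same coefficient phi,
#   left  = sqrt(rho) S + sqrt(1 - rho) U1
#   right = sqrt(rho) S + sqrt(1 - rho) U2
# has population correlation exactly rho between the pair members,
# independent of phi.  Optional 3D Gaussian smoothing is applied after
# pair construction, per timepoint; it raises realized neighbourhood
# correlations, so the per-pair target is a pre-smoothing ground truth.

#' Simulation configuration
#'
#' @param grid_shape three positive integers (x must be even).
#' @param voxel_size_mm voxel edge length, mm.
#' @param n_timepoints number of timepoints.
#' @param tr_s repetition interval, seconds.
#' @param ar_coefficient AR(1) coefficient phi of the temporal noise,
#'   |phi| < 1.
#' @param rho_map target homotopic correlation: a scalar in [0, 1) or a
#'   mirror-symmetric 3D array on `grid_shape`.
#' @param smoothing_fwhm_mm spatial Gaussian FWHM applied per timepoint
#'   after pair construction; 0 (the default) disables smoothing.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(grid_shape = c(16L, 16L, 16L), voxel_size_mm = 2,
                       n_timepoints = 702L, tr_s = 2,
                       ar_coefficient = 0, rho_map = 0,
                       smoothing_fwhm_mm = 0, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stopf("'grid_shape' must be three positive integers")
  check_even_x(grid_shape)
  check_scalar_num(voxel_size_mm, "voxel_size_mm", 0, strict_lower = TRUE)
  check_scalar_num(n_timepoints, "n_timepoints", 1)
  check_scalar_num(ar_coefficient, "ar_coefficient", -1, 1,
                   strict_lower = TRUE, strict_upper = TRUE)
  check_scalar_num(smoothing_fwhm_mm, "smoothing_fwhm_mm", 0)
  rho_map <- expand_rho_map(rho_map, grid_shape)
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 n_timepoints = as.integer(n_timepoints), tr_s = tr_s,
                 ar_coefficient = ar_coefficient, rho_map = rho_map,
                 smoothing_fwhm_mm = smoothing_fwhm_mm,
                 seed = as.integer(seed)),
            class = "sim_config")
}

expand_rho_map <- function(rho_map, grid_shape) {
  if (length(rho_map) == 1L)
    rho_map <- array(rho_map, grid_shape)
  if (!identical(dim(rho_map), as.integer(grid_shape)))
    stopf("'rho_map' must be scalar or an array matching grid_shape")
  if (any(rho_map < 0) || any(rho_map >= 1))
    stopf("target correlations must lie in [0, 1)")
  if (!identical(rho_map, flip_x(rho_map)))
    stopf("'rho_map' must be mirror-symmetric: each homotopic pair has one rho")
  rho_map
}

#' Generate a mirror-symmetric smooth random template
#'
#' A Gaussian random field is smoothed, windowed by a smooth radial taper
#' (so the 'brain' sits in a near-zero background), and averaged with its
#' own x-flip, which makes the result exactly mirror-symmetric.
#'
#' @param config a `sim_config`.
#' @param fwhm_mm smoothness of the field, mm FWHM (default 8, the typical
#'   smoothing applied to normalized functional data).
#' @return a `volume_grid` with `hemispheric_mse()` exactly 0.
#' @export
generate_symmetric_template <- function(config, fwhm_mm = 8) {
  d <- config$grid_shape
  check_even_x(d)
  with_seed(config$seed, {
    field <- array(rnorm(prod(d)), d)
    field <- smooth_gaussian(field, fwhm_mm, config$voxel_size_mm)
    field <- (field - mean(field)) / sd(field)
    tpl <- (100 + 25 * field) * radial_taper(d, config$voxel_size_mm)
    tpl <- (tpl + flip_x(tpl)) / 2
    volume_grid(tpl, voxel_mm = config$voxel_size_mm)
  })
}

# Smooth super-Gaussian window centred on the grid, symmetric in x.
radial_taper <- function(d, voxel_mm) {
  ax <- lapply(1:3, function(i) axis_coords(d[i], voxel_mm))
  r2 <- outer(outer(ax[[1L]]^2, ax[[2L]]^2, "+"), ax[[3L]]^2, "+")
  rmax2 <- max(ax[[1L]])^2
  w <- exp(-(r2 / (0.65^2 * rmax2))^3)
  dim(w) <- d
  w
}

# Matrix of m independent standardized AR(1) series of length n, one per
# column; stationary initialization.
ar1_matrix <- function(n, m, phi) {
  x <- matrix(rnorm(n * m), n, m)
  if (phi != 0 && n > 1L) {
    # innovations scaled so the stationary variance is 1; the first row
    # is already a stationary draw, so the recursion starts there
    x[-1L, ] <- x[-1L, ] * sqrt(1 - phi^2)
    x <- matrix(stats::filter(x, phi, method = "recursive"), n, m)
  }
  x
}

#' Generate a 4D series with known homotopic correlation structure
#'
#' @param config a `sim_config`; `rho_map`, `ar_coefficient`,
#'   `smoothing_fwhm_mm` and `seed` control the generative model.
#' @return a `series_volume`.
#' @export
generate_homotopic_series <- function(config) {
  d <- config$grid_shape
  idx <- homotopic_indices(d)
  npair <- length(idx$left)
  nt <- config$n_timepoints
  rho <- config$rho_map[idx$left]
  with_seed(config$seed, {
    shared <- ar1_matrix(nt, npair, config$ar_coefficient)
    u1 <- ar1_matrix(nt, npair, config$ar_coefficient)
    u2 <- ar1_matrix(nt, npair, config$ar_coefficient)
    a <- sqrt(rho); b <- sqrt(1 - rho)
    left <- sweep(shared, 2L, a, "*") + sweep(u1, 2L, b, "*")
    right <- sweep(shared, 2L, a, "*") + sweep(u2, 2L, b, "*")
    dat <- array(0, c(d, nt))
    m <- matrix(0, prod(d), nt)
    m[idx$left, ] <- t(left)
    m[idx$right, ] <- t(right)
    dat <- array(m, c(d, nt))
    if (config$smoothing_fwhm_mm > 0)
      dat <- Re(fft3(fft3(dat + 0i) *
                       array(gaussian_transfer(
                         d, rep(fwhm_to_sigma(config$smoothing_fwhm_mm) /
                                  config$voxel_size_mm, 3L)), c(d, nt)),
                     inverse = TRUE))
    series_volume(dat, voxel_mm = config$voxel_size_mm, tr_s = config$tr_s)
  })
}

#' Group specification for two-group simulations
#'
#' @param n_subjects_per_group subjects per group.
#' @param baseline_rho homotopic correlation outside the effect region.
#' @param effect_region logical 3D array or n x 3 integer matrix of voxel
#'   indices; it is symmetrized (union with its mirror image) so every
#'   planted pair is homotopic.
#' @param effect_delta_rho added correlation inside the region for group A
#'   (baseline + delta must stay below 1).
#' @param seed master seed; subject s of the study uses `seed + s`.
#' @return a `group_spec` list.
#' @export
group_spec <- function(n_subjects_per_group, baseline_rho = 0.2,
                       effect_region = NULL, effect_delta_rho = 0,
                       seed = 1L) {
  check_scalar_num(n_subjects_per_group, "n_subjects_per_group", 1)
  check_scalar_num(baseline_rho, "baseline_rho", 0, 1, strict_upper = TRUE)
  check_scalar_num(effect_delta_rho, "effect_delta_rho")
  if (baseline_rho + effect_delta_rho >= 1 ||
      baseline_rho + effect_delta_rho < 0)
    stopf("baseline_rho + effect_delta_rho must lie in [0, 1)")
  structure(list(n_subjects_per_group = as.integer(n_subjects_per_group),
                 baseline_rho = baseline_rho,
                 effect_region = effect_region,
                 effect_delta_rho = effect_delta_rho,
                 seed = as.integer(seed)),
            class = "group_spec")
}

region_mask <- function(effect_region, d) {
  mask <- array(FALSE, d)
  if (is.null(effect_region)) return(mask)
  if (is.logical(effect_region)) {
    if (!identical(dim(effect_region), as.integer(d)))
      stopf("logical effect_region must match the grid")
    mask <- effect_region
  } else {
    effect_region <- matrix(as.integer(effect_region), ncol = 3L)
    if (any(effect_region < 1L) ||
        any(sweep(effect_region, 2L, d, ">")))
      stopf("effect_region indices outside the grid")
    mask[effect_region] <- TRUE
  }
  mask | flip_x(mask)
}

#' Generate a two-group synthetic dataset
#'
#' Group A subjects carry `baseline_rho + effect_delta_rho` inside the
#' (mirror-symmetrized) effect region and `baseline_rho` elsewhere; group
#' B subjects carry the baseline everywhere.  Subject-level seeds are
#' `spec$seed + subject index` (group A first), so the draw is
#' reproducible and subjects are independent.
#'
#' @param spec a `group_spec`.
#' @param config a `sim_config` providing grid, timepoints, AR
#'   coefficient, smoothing.
#' @return list with elements `A` and `B` (lists of `series_volume`) and
#'   `effect_mask` (logical 3D array of the planted region).
#' @export
generate_group_dataset <- function(spec, config) {
  d <- config$grid_shape
  mask <- region_mask(spec$effect_region, d)
  rho_a <- array(spec$baseline_rho, d)
  rho_a[mask] <- spec$baseline_rho + spec$effect_delta_rho
  rho_b <- array(spec$baseline_rho, d)
  n <- spec$n_subjects_per_group
  gen <- function(rho, offset) {
    lapply(seq_len(n), function(s) {
      cfg <- config
      cfg$rho_map <- rho
      cfg$seed <- spec$seed + offset + s
      generate_homotopic_series(cfg)
    })
  }
  list(A = gen(rho_a, 0L), B = gen(rho_b, n), effect_mask = mask)
}

#' Generate a synthetic corpus-callosum volume table
#'
#' Segment volumes are drawn from per-group normal distributions
#' truncated at zero; total brain volume is built from a shared factor so
#' that its population correlation with total callosal volume equals
#' `cc_brain_r`.
#'
#' @param n_per_group subjects per group (named groups A and B).
#' @param group_means 2 x 5 matrix (rows: groups A, B) of segment volume
#'   means in mm^3, order posterior, mid-posterior, central, mid-anterior,
#'   anterior; a single row is recycled to both groups.
#' @param group_sds like `group_means`, segment standard deviations.
#' @param seed integer seed.
#' @param brain_mean,brain_sd total brain volume distribution, mm^3.
#' @param cc_brain_r target correlation between total CC volume and total
#'   brain volume (default 0.46).
#' @return data.frame with columns subject_id, group, cc_posterior,
#'   cc_midposterior, cc_central, cc_midanterior, cc_anterior,
#'   brain_volume.
#' @export
generate_callosal_table <- function(n_per_group = 18L,
                                    group_means = c(950, 450, 450, 500, 900),
                                    group_sds = 0.15 * c(950, 450, 450, 500, 900),
                                    seed = 1L,
                                    brain_mean = 1150000, brain_sd = 110000,
                                    cc_brain_r = 0.46) {
  check_scalar_num(n_per_group, "n_per_group", 1)
  mk2x5 <- function(x, name) {
    if (is.null(dim(x))) x <- matrix(x, 2L, 5L, byrow = TRUE)
    x <- as.matrix(x)
    if (!all(dim(x) == c(2L, 5L)))
      stopf("'%s' must be length 5 or a 2 x 5 matrix", name)
    if (any(x <= 0)) stopf("'%s' must be strictly positive", name)
    x
  }
  mu <- mk2x5(group_means, "group_means")
  sig <- mk2x5(group_sds, "group_sds")
  check_scalar_num(cc_brain_r, "cc_brain_r", -1, 1,
                   strict_lower = TRUE, strict_upper = TRUE)
  n <- as.integer(n_per_group)
  with_seed(seed, {
    rows <- lapply(1:2, function(g) {
      seg <- sapply(1:5, function(s)
        truncnorm0(n, mu[g, s], sig[g, s]))
      seg <- matrix(seg, n, 5L)
      total <- rowSums(seg)
      zt <- if (sd(total) > 0) (total - mean(total)) / sd(total)
            else rep(0, n)
      brain <- truncnorm0_from(
        brain_mean + brain_sd * (cc_brain_r * zt +
                                   sqrt(1 - cc_brain_r^2) * rnorm(n)))
      data.frame(subject_id = sprintf("%s%02d", c("A", "B")[g], seq_len(n)),
                 group = c("A", "B")[g],
                 cc_posterior = seg[, 1L], cc_midposterior = seg[, 2L],
                 cc_central = seg[, 3L], cc_midanterior = seg[, 4L],
                 cc_anterior = seg[, 5L], brain_volume = brain,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

# Normal draws truncated at zero by resampling (volumes are far from 0 in
# realistic settings, so the loop almost never iterates).
truncnorm0 <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

truncnorm0_from <- function(x) {
  pmax(x, .Machine$double.eps)
}
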