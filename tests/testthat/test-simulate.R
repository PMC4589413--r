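test_that("sim_config enforces parity, rho range and symmetry", {
  expect_error(sim_config(grid_shape = c(15, 16, 16)), "even")
  expect_error(sim_config(rho_map = 1), "\\[0, 1\\)")
  expect_error(sim_config(ar_coefficient = 1), "<")
  bad_rho <- array(0, c(4, 4, 4)); bad_rho[1, 1, 1] <- 0.5
  expect_error(sim_config(grid_shape = c(4, 4, 4), rho_map = bad_rho),
               "mirror-symmetric")
})

test_that("symmetric templates are exactly symmetric and seed-driven", {
  cfg <- sim_config(grid_shape = c(16, 16, 16), seed = 1)
  tpl <- generate_symmetric_template(cfg)
  expect_identical(hemispheric_mse(tpl), 0)
  expect_identical(tpl$data, flip_x(tpl$data))
  expect_identical(tpl$data, generate_symmetric_template(cfg)$data)
  cfg2 <- cfg; cfg2$seed <- 2L
  tpl2 <- generate_symmetric_template(cfg2)
  expect_gt(mean(tpl$data != tpl2$data), 0.5)
})

test_that("polynomial warps: identity, translation and round-trip", {
  cfg <- sim_config(grid_shape = c(12, 12, 12), voxel_size_mm = 1, seed = 3)
  tpl <- generate_symmetric_template(cfg)
  w_id <- identity_warp(tpl, 2)
  expect_identical(apply_polynomial_warp(tpl, w_id)$data, tpl$data)

  # pure +1-voxel x-translation on a linear ramp: interior shifts one step
  d <- c(8L, 6L, 6L)
  ramp <- volume_grid(array(rep(seq_len(d[1L]), prod(d[2:3])), d))
  w <- identity_warp(ramp, 1)
  co <- w$coefficients
  # +1 voxel in physical mm, converted to normalized units of the x axis
  co[rowSums(w$exponents) == 0, 1L] <- 2 / (d[1L] - 1)
  wt <- warp_parameters(1, co, w$bounds)
  shifted <- apply_polynomial_warp(ramp, wt)
  expect_equal(shifted$data[1:(d[1L] - 1), , ],
               ramp$data[2:d[1L], , ], tolerance = 1e-8)

  # small affine warp then its inverse: below an interpolation-error bound
  # estimated on the same volume by a half-voxel shuttle
  wd <- make_distortion(tpl, tx = 0.04, sxy = 0.03)
  fwd <- apply_polynomial_warp(tpl, wd)
  co_inv <- identity_warp(tpl, 2)$coefficients
  co_inv[rowSums(w$exponents) == 0, 1L] <- 0  # solved below
  # invert the affine x' = x + tx + sxy*y analytically: x = x' - tx - sxy*y
  wi <- identity_warp(tpl, 2)
  ci <- wi$coefficients
  ci[rowSums(wi$exponents) == 0, 1L] <- -0.04
  ci[wi$exponents[, 1L] == 0 & wi$exponents[, 2L] == 1 &
       wi$exponents[, 3L] == 0, 1L] <- -0.03
  back <- apply_polynomial_warp(fwd, warp_parameters(2, ci, wi$bounds))
  half <- identity_warp(tpl, 1)
  ch <- half$coefficients
  ch[rowSums(half$exponents) == 0, 1L] <- 1 / (dim(tpl)[1L] - 1)
  there <- apply_polynomial_warp(tpl, warp_parameters(1, ch, half$bounds))
  ch[rowSums(half$exponents) == 0, 1L] <- -1 / (dim(tpl)[1L] - 1)
  shuttle <- apply_polynomial_warp(there,
                                   warp_parameters(1, ch, half$bounds))
  interp_floor <- mean((shuttle$data - tpl$data)^2)
  inner <- 3:(dim(tpl)[1L] - 2)
  expect_lt(mean((back$data[inner, inner, inner] -
                    tpl$data[inner, inner, inner])^2),
            4 * interp_floor + 1e-8)

  # coefficient count must match the declared degree
  expect_error(warp_parameters(2, matrix(0, 4, 3), w$bounds), "10 x 3")
})

test_that("homotopic series hit their target correlation", {
  for (rho in c(0, 0.5)) {
    cfg <- sim_config(grid_shape = c(10, 10, 8), n_timepoints = 5000,
                      ar_coefficient = 0, rho_map = rho, seed = 7 + rho)
    m <- homotopic_correlation_map(generate_homotopic_series(cfg))
    expect_equal(mean(m$r, na.rm = TRUE), rho, tolerance = 0.02)
  }
})

test_that("AR(1) temporal structure is realized", {
  lag1 <- function(phi, seed) {
    cfg <- sim_config(grid_shape = c(4, 4, 4), n_timepoints = 2000,
                      ar_coefficient = phi, seed = seed)
    x <- generate_homotopic_series(cfg)$data[2, 2, 2, ]
    cor(x[-1], x[-length(x)])
  }
  expect_equal(lag1(0.9, 21), 0.9, tolerance = 0.05)
  expect_equal(lag1(0, 22), 0, tolerance = 0.05)
})

test_that("spatial smoothing raises realized correlations above the target", {
  # the per-pair target is a pre-smoothing ground truth: kernels leak
  # across the midline, so smoothing inflates the realized homotopic
  # correlation rather than preserving it
  base <- sim_config(grid_shape = c(10, 10, 8), n_timepoints = 1500,
                     rho_map = 0.4, voxel_size_mm = 2, seed = 13)
  m0 <- homotopic_correlation_map(generate_homotopic_series(base))
  expect_equal(mean(m0$r, na.rm = TRUE), 0.4, tolerance = 0.03)
  smoothed <- base; smoothed$smoothing_fwhm_mm <- 6
  ms <- homotopic_correlation_map(generate_homotopic_series(smoothed))
  expect_gt(mean(ms$r, na.rm = TRUE), mean(m0$r, na.rm = TRUE))
  expect_lt(max(ms$r, na.rm = TRUE), 1)
})

test_that("group datasets plant the effect where stated", {
  grid <- c(8L, 8L, 8L)
  block <- array(FALSE, grid); block[2:3, 4:5, 4:5] <- TRUE
  spec <- group_spec(2, baseline_rho = 0.1, effect_region = block,
                     effect_delta_rho = 0.5, seed = 5)
  cfg <- sim_config(grid_shape = grid, n_timepoints = 1200, seed = 5)
  dat <- generate_group_dataset(spec, cfg)
  expect_length(dat$A, 2)
  expect_identical(dat$effect_mask, block | flip_x(block))
  rA <- homotopic_correlation_map(dat$A[[1]])$r
  rB <- homotopic_correlation_map(dat$B[[1]])$r
  expect_equal(mean(rA[dat$effect_mask]), 0.6, tolerance = 0.06)
  expect_equal(mean(rA[!dat$effect_mask]), 0.1, tolerance = 0.05)
  expect_equal(mean(rB[dat$effect_mask]), 0.1, tolerance = 0.08)
  # boundary: single-subject groups generate (downstream stages reject)
  one <- generate_group_dataset(group_spec(1, seed = 2), cfg)
  expect_length(one$A, 1)
  # out-of-grid region rejected
  expect_error(generate_group_dataset(
    group_spec(2, effect_region = cbind(9, 1, 1), seed = 1), cfg),
    "outside")
})

test_that("callosal tables are deterministic, positive and correlated", {
  t1 <- generate_callosal_table(n_per_group = 18, seed = 3)
  t2 <- generate_callosal_table(n_per_group = 18, seed = 3)
  expect_identical(t1, t2)
  expect_true(all(as.matrix(t1[, 3:8]) > 0))
  big <- generate_callosal_table(n_per_group = 500, seed = 4)
  s <- regroup_segments(big)
  expect_lt(abs(cc_brain_correlation(s)$r - 0.46), 0.08)
  expect_error(generate_callosal_table(0), ">= 1")
  expect_error(generate_callosal_table(5, group_means = c(-1, 1, 1, 1, 1)),
               "positive")
})
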