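test_that("mirror_coordinates negates x only and is an involution", {
  expect_equal(mirror_coordinates(c(0, 5, -2)), c(0, 5, -2))
  expect_equal(mirror_coordinates(c(3, 1, 1)), c(-3, 1, 1))
  set.seed(1)
  p <- matrix(rnorm(30), ncol = 3)
  expect_equal(mirror_coordinates(mirror_coordinates(p)), p)
})

test_that("trilinear sampling: nodes, midpoints, exact linear fields", {
  d <- c(4L, 4L, 4L)
  vol <- volume_grid(array(rnorm(prod(d)), d), voxel_mm = 2)
  pts <- voxel_centers(vol)
  expect_equal(trilinear_sample(vol, pts), as.vector(vol$data))

  # midpoint of an x-edge between intensities 2 and 6 -> 4
  v2 <- volume_grid(array(0, d), voxel_mm = 1)
  v2$data[2, 2, 2] <- 2; v2$data[3, 2, 2] <- 6
  p22 <- c(mean(axis_coords(4, 1)[2:3]), axis_coords(4, 1)[2],
           axis_coords(4, 1)[2])
  expect_equal(trilinear_sample(v2, p22), 4)

  # linear fields are reproduced exactly at random interior points
  lin <- volume_grid(array(0, d), voxel_mm = 2)
  cts <- voxel_centers(lin)
  lin$data <- array(2 + 0.5 * cts[, 1] - 1.25 * cts[, 2] + 3 * cts[, 3], d)
  set.seed(2)
  q <- cbind(runif(50, -2.9, 2.9), runif(50, -2.9, 2.9),
             runif(50, -2.9, 2.9))
  expect_equal(trilinear_sample(lin, q),
               2 + 0.5 * q[, 1] - 1.25 * q[, 2] + 3 * q[, 3],
               tolerance = 1e-12)
  # outside the grid: fill value
  expect_equal(trilinear_sample(lin, c(100, 0, 0), fill = -7), -7)
})

test_that("hemispheric_mse matches hand computation and flip symmetry", {
  toy <- volume_grid(array(c(1, 3), c(2, 1, 1)))
  expect_equal(hemispheric_mse(toy), 4)
  set.seed(3)
  v <- array(rnorm(4 * 3 * 3), c(4, 3, 3))
  expect_equal(hemispheric_mse(v), hemispheric_mse(flip_x(v)))
})

test_that("symmetrization cost: symmetric zero, identity equals hemispheric MSE", {
  tpl <- make_template(c(12, 12, 12))
  expect_lt(symmetrization_cost(identity_warp(tpl, 1), tpl), 1e-18)
  asym <- tpl
  set.seed(4)
  asym$data <- asym$data + array(rnorm(length(asym$data)), dim(asym$data))
  expect_equal(symmetrization_cost(identity_warp(asym, 1), asym),
               hemispheric_mse(asym), tolerance = 1e-10)
  zero <- volume_grid(array(0, c(4, 4, 4)))
  expect_warning(cz <- symmetrization_cost(identity_warp(zero, 1), zero),
                 "constant-zero")
  expect_equal(cz, 0)
})

test_that("cost at the generating warp is near the interpolation floor", {
  tpl <- make_template(c(12, 12, 12))
  wd <- make_distortion(tpl, tx = 0.05, sxy = 0.04)
  dist <- apply_polynomial_warp(tpl, wd)
  # evaluating at a warp consistent with the construction must be far
  # below the identity-warp cost
  consistent <- consistent_warp <- local({
    # f = g^{-1} m g m in normalized coordinates for affine g
    # g: u' = u + tx + s v ; m: u -> -u
    # f(u,v,w) = -(u) - 2*tx - 2*s*v  on the x output
    w <- identity_warp(tpl, 2)
    co <- w$coefficients
    expo <- w$exponents
    co[expo[, 1] == 1 & rowSums(expo) == 1, 1] <- 1
    co[rowSums(expo) == 0, 1] <- -2 * 0.05
    co[expo[, 2] == 1 & rowSums(expo) == 1, 1] <- -2 * 0.04
    warp_parameters(2, co, w$bounds)
  })
  # compose with mirror inside the cost: cost uses f(r(x)); with the
  # analytic f above the residual is interpolation error only
  expect_lt(symmetrization_cost(consistent, dist),
            0.05 * symmetrization_cost(identity_warp(dist, 2), dist))
})

test_that("fit_symmetrization recovers a known degree-2 distortion", {
  tpl <- make_template(c(12, 12, 12))
  wd <- make_distortion(tpl, tx = 0.05, sxy = 0.04)
  dist <- apply_polynomial_warp(tpl, wd)
  fit <- fit_symmetrization(dist, degree = 1, n_restarts = 2, seed = 11,
                            options = list(maxit = 2500))
  expect_s3_class(fit, "symmetrization_result")
  expect_lte(fit$final_cost, fit$initial_mse)
  expect_lt(fit$final_cost / fit$initial_mse, 0.5)
  # best-so-far trace is non-increasing
  expect_true(all(diff(fit$cost_trace) <= 0))
  # restart supersets can only improve
  fit1 <- fit_symmetrization(dist, degree = 1, n_restarts = 1, seed = 11,
                             options = list(maxit = 2500))
  expect_lte(fit$final_cost, fit1$final_cost + 1e-12)
})

test_that("already-symmetric template: identity is (near-)optimal", {
  tpl <- make_template(c(12, 12, 12))
  fit <- fit_symmetrization(tpl, degree = 1, n_restarts = 1, seed = 2,
                            options = list(maxit = 500))
  expect_lt(fit$final_cost, 1e-10)
  expect_equal(fit$warp$coefficients,
               identity_warp(tpl, 1)$coefficients, tolerance = 0.05)
})

test_that("apply_symmetrization honours identity, time and round-trips", {
  tpl <- make_template(c(8, 8, 8))
  ser <- series_volume(array(rep(tpl$data, 3), c(dim(tpl), 3)),
                       voxel_mm = tpl$voxel_mm)
  w <- identity_warp(tpl, 1)
  # identity warp + mirror twice returns the original (flip is exact on
  # voxel centres)
  once <- apply_symmetrization(ser, w)
  expect_equal(once$data, flip_x(ser$data), tolerance = 1e-12)
  twice <- apply_symmetrization(once, w)
  expect_equal(twice$data, ser$data, tolerance = 1e-12)
  # pure warp, no mirror: identity in, identity out
  expect_equal(apply_symmetrization(ser, w, mirror = FALSE)$data, ser$data)
  # constant-in-time series stays constant in time
  expect_true(all(once$data[, , , 1] == once$data[, , , 3]))
  # frame mismatch rejected
  small <- make_template(c(6, 6, 6))
  expect_error(apply_symmetrization(ser, identity_warp(small, 1)),
               "frame mismatch")
})

test_that("warp parameters serialize losslessly to JSON", {
  dir <- withr::local_tempdir()
  tpl <- make_template(c(8, 8, 8))
  wd <- make_distortion(tpl)
  p <- file.path(dir, "warp.json")
  write_warp(wd, p)
  back <- read_warp(p)
  expect_equal(back$coefficients, wd$coefficients)
  expect_equal(back$bounds, wd$bounds)
  expect_identical(back$degree, wd$degree)
})
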