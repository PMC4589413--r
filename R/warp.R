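# Trivariate polynomial coordinate transforms and trilinear resampling.
#
# A warp is a mapping f(p) from physical coordinates to physical
# coordinates.  Internally both input and output are expressed in
# normalized coordinates on [-1, 1]^3 (per-axis, from the stored bounds)
# so that the monomial design matrix is well conditioned for the simplex
# optimizer.  Monomials of total degree <= `degree` are ordered graded
# lexicographically in (x, y, z): degree 0 first, then within each total
# degree the x exponent decreases first, then y.

#' Exponent table of the trivariate monomial basis
#'
#' @param degree maximum total degree (>= 1).
#' @return integer matrix with one row per monomial and columns ex, ey, ez,
#'   in graded lexicographic order; `choose(degree + 3, 3)` rows.
#' @export
monomial_exponents <- function(degree) {
  if (degree < 1) stopf("'degree' must be >= 1")
  rows <- list()
  for (g in 0:degree)
    for (ex in g:0)
      for (ey in (g - ex):0)
        rows[[length(rows) + 1L]] <- c(ex, ey, g - ex - ey)
  out <- do.call(rbind, rows)
  colnames(out) <- c("ex", "ey", "ez")
  out
}

#' Construct polynomial warp parameters
#'
#' @param degree polynomial total degree (default 5).
#' @param coefficients numeric matrix, one row per monomial (graded lex
#'   order) and one column per output axis; `NULL` for the identity warp.
#' @param bounds 2 x 3 matrix of physical lower/upper bounds used for
#'   coordinate normalization during fitting and evaluation.
#' @return an object of class `warp_parameters`.
#' @export
warp_parameters <- function(degree = 5, coefficients = NULL, bounds) {
  degree <- as.integer(degree)
  if (degree < 1) stopf("'degree' must be >= 1")
  expo <- monomial_exponents(degree)
  m <- nrow(expo)
  if (is.null(coefficients)) {
    coefficients <- matrix(0, m, 3L)
    for (ax in 1:3) {
      e <- integer(3L); e[ax] <- 1L
      coefficients[which(expo[, 1L] == e[1L] & expo[, 2L] == e[2L] &
                           expo[, 3L] == e[3L]), ax] <- 1
    }
  }
  coefficients <- as.matrix(coefficients)
  if (nrow(coefficients) != m || ncol(coefficients) != 3L)
    stopf("coefficient matrix must be %d x 3 for degree %d (got %d x %d)",
          m, degree, nrow(coefficients), ncol(coefficients))
  bounds <- matrix(as.numeric(bounds), 2L, 3L)
  if (any(bounds[2L, ] <= bounds[1L, ])) stopf("invalid normalization bounds")
  structure(list(degree = degree, coefficients = coefficients,
                 bounds = bounds, exponents = expo),
            class = "warp_parameters")
}

#' Identity warp for a given volume
#'
#' @param volume a `volume_grid` (or `series_volume`) fixing the bounds.
#' @param degree polynomial degree.
#' @return `warp_parameters` reproducing input coordinates exactly.
#' @export
identity_warp <- function(volume, degree = 5) {
  warp_parameters(degree, NULL, volume_bounds(volume))
}

#' Physical bounding box of a volume's voxel centres
#'
#' @param volume a `volume_grid` or `series_volume`.
#' @return 2 x 3 matrix of lower/upper bounds, mm.
#' @export
volume_bounds <- function(volume) {
  d <- grid_dim(volume)
  v <- volume$voxel_mm
  rbind(-(d - 1) / 2 * v, (d - 1) / 2 * v)
}

# Design matrix of monomial values at normalized points (n x 3 matrix u).
monomial_design <- function(u, expo) {
  n <- nrow(u)
  out <- matrix(1, n, nrow(expo))
  # build power tables once per axis
  maxdeg <- max(expo)
  pow <- lapply(1:3, function(ax) {
    p <- matrix(1, n, maxdeg + 1L)
    for (k in seq_len(maxdeg)) p[, k + 1L] <- p[, k] * u[, ax]
    p
  })
  for (j in seq_len(nrow(expo)))
    out[, j] <- pow[[1L]][, expo[j, 1L] + 1L] *
      pow[[2L]][, expo[j, 2L] + 1L] * pow[[3L]][, expo[j, 3L] + 1L]
  out
}

normalize_points <- function(p, bounds) {
  sweep(sweep(p, 2L, bounds[1L, ]), 2L,
        (bounds[2L, ] - bounds[1L, ]) / 2, "/") - 1
}

denormalize_points <- function(u, bounds) {
  sweep(sweep(u + 1, 2L, (bounds[2L, ] - bounds[1L, ]) / 2, "*"),
        2L, bounds[1L, ], "+")
}

#' Evaluate a polynomial warp at physical points
#'
#' @param warp `warp_parameters`.
#' @param points n x 3 matrix of physical coordinates (mm).
#' @return n x 3 matrix of mapped physical coordinates.
#' @export
evaluate_warp <- function(warp, points) {
  points <- matrix(points, ncol = 3L)
  u <- normalize_points(points, warp$bounds)
  denormalize_points(monomial_design(u, warp$exponents) %*% warp$coefficients,
                     warp$bounds)
}

#' Trilinear interpolation of a volume at physical points
#'
#' Samples outside the grid of voxel centres take `fill`.
#'
#' @param volume a `volume_grid`.
#' @param points n x 3 matrix of physical coordinates (mm), or a length-3
#'   vector for a single point.
#' @param fill value returned for out-of-domain points.
#' @return numeric vector of sampled intensities.
#' @export
trilinear_sample <- function(volume, points, fill = 0) {
  points <- matrix(points, ncol = 3L)
  d <- grid_dim(volume)
  v <- volume$voxel_mm
  # continuous voxel index: physical 0 sits at index (n+1)/2
  ix <- points[, 1L] / v[1L] + (d[1L] + 1) / 2
  iy <- points[, 2L] / v[2L] + (d[2L] + 1) / 2
  iz <- points[, 3L] / v[3L] + (d[3L] + 1) / 2
  ok <- ix >= 1 & ix <= d[1L] & iy >= 1 & iy <= d[2L] & iz >= 1 & iz <= d[3L]
  out <- rep(as.numeric(fill), nrow(points))
  if (!any(ok)) return(out)
  x0 <- pmin(floor(ix[ok]), d[1L] - 1); fx <- ix[ok] - x0
  y0 <- pmin(floor(iy[ok]), d[2L] - 1); fy <- iy[ok] - y0
  z0 <- pmin(floor(iz[ok]), d[3L] - 1); fz <- iz[ok] - z0
  nx <- d[1L]; nxy <- d[1L] * d[2L]
  base <- x0 + nx * (y0 - 1) + nxy * (z0 - 1)
  dat <- volume$data
  c000 <- dat[base];             c100 <- dat[base + 1]
  c010 <- dat[base + nx];        c110 <- dat[base + nx + 1]
  c001 <- dat[base + nxy];       c101 <- dat[base + nxy + 1]
  c011 <- dat[base + nx + nxy];  c111 <- dat[base + nx + nxy + 1]
  out[ok] <-
    c000 * (1 - fx) * (1 - fy) * (1 - fz) + c100 * fx * (1 - fy) * (1 - fz) +
    c010 * (1 - fx) * fy * (1 - fz)       + c110 * fx * fy * (1 - fz) +
    c001 * (1 - fx) * (1 - fy) * fz       + c101 * fx * (1 - fy) * fz +
    c011 * (1 - fx) * fy * fz             + c111 * fx * fy * fz
  out
}

#' Resample a volume through a polynomial warp
#'
#' Output voxel at physical position p takes the trilinearly interpolated
#' intensity of the input at f(p).
#'
#' @param volume a `volume_grid`.
#' @param warp `warp_parameters`.
#' @param fill fill value for samples mapped outside the domain.
#' @return a `volume_grid` on the same grid.
#' @export
apply_polynomial_warp <- function(volume, warp, fill = 0) {
  pts <- voxel_centers(volume)
  mapped <- evaluate_warp(warp, pts)
  out <- trilinear_sample(volume, mapped, fill = fill)
  volume_grid(array(out, grid_dim(volume)), voxel_mm = volume$voxel_mm)
}

#' Physical coordinates of every voxel centre
#'
#' @param volume a `volume_grid` or `series_volume`.
#' @return n x 3 matrix of centre coordinates, mm.
#' @export
voxel_centers <- function(volume) {
  d <- grid_dim(volume)
  v <- volume$voxel_mm
  cbind(rep(axis_coords(d[1L], v[1L]), times = d[2L] * d[3L]),
        rep(rep(axis_coords(d[2L], v[2L]), each = d[1L]), times = d[3L]),
        rep(axis_coords(d[3L], v[3L]), each = d[1L] * d[2L]))
}

#' Serialize warp parameters to JSON
#'
#' The coefficient array is written in documented graded-lexicographic
#' monomial order, column-major over output axes.
#'
#' @param warp `warp_parameters`.
#' @param path output file.
#' @export
write_warp <- function(warp, path) {
  jsonlite::write_json(
    list(degree = warp$degree,
         bounds = as.vector(warp$bounds),
         monomial_order = "graded_lexicographic_xyz",
         coefficients = as.vector(warp$coefficients)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read warp parameters from JSON
#' @param path file written by [write_warp()].
#' @return `warp_parameters`.
#' @export
read_warp <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- choose(j$degree + 3, 3)
  warp_parameters(j$degree,
                  matrix(unlist(j$coefficients), m, 3L),
                  matrix(unlist(j$bounds), 2L, 3L))
}
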