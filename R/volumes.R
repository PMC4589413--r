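# S3 containers for 3D volumes and 4D time-series volumes.
#
# Geometry convention: voxel i along x sits at physical coordinate
# (i - (nx + 1) / 2) * vx millimetres, so for an even x-dimension the
# midsagittal mirror plane x = 0 lies between the two central voxel
# columns and every voxel has a distinct homotopic partner (nx + 1 - i).
# The same centring is used for y and z.

#' Construct a 3D intensity volume
#'
#' @param data numeric 3D array of intensities.
#' @param voxel_mm voxel edge length(s) in mm; scalar or length 3.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(data, voxel_mm = 1) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("'data' must be a 3D array")
  voxel_mm <- rep(as.numeric(voxel_mm), length.out = 3L)
  if (any(!is.finite(voxel_mm)) || any(voxel_mm <= 0))
    stopf("'voxel_mm' must be positive")
  structure(list(data = data, voxel_mm = voxel_mm), class = "volume_grid")
}

#' Construct a 4D time-series volume
#'
#' @param data numeric 4D array, spatial dimensions first, time last.
#' @param voxel_mm voxel edge length(s) in mm.
#' @param tr_s repetition interval between timepoints, seconds.
#' @return an object of class `series_volume`.
#' @export
series_volume <- function(data, voxel_mm = 1, tr_s = 2) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stopf("'data' must be a 4D array (x, y, z, time)")
  voxel_mm <- rep(as.numeric(voxel_mm), length.out = 3L)
  if (any(!is.finite(voxel_mm)) || any(voxel_mm <= 0))
    stopf("'voxel_mm' must be positive")
  check_scalar_num(tr_s, "tr_s", lower = 0, strict_lower = TRUE)
  structure(list(data = data, voxel_mm = voxel_mm, tr_s = tr_s),
            class = "series_volume")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3]))
  invisible(x)
}

#' @export
print.series_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<series_volume> %d x %d x %d voxels x %d timepoints, TR = %.3g s\n",
    d[1], d[2], d[3], d[4], x$tr_s))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' @export
dim.series_volume <- function(x) dim(x$data)

grid_dim <- function(x) {
  if (inherits(x, "series_volume")) dim(x$data)[1:3]
  else if (inherits(x, "volume_grid")) dim(x$data)
  else if (is.array(x) && length(dim(x)) >= 3L) dim(x)[1:3]
  else stopf("not a volume object")
}

check_even_x <- function(d) {
  if (d[1L] %% 2L != 0L)
    stopf(paste("x-dimension must be even so that every voxel has a",
                "distinct mirror partner (got nx = %d)"), d[1L])
  invisible(d)
}

same_grid <- function(a, b, tol = 1e-9) {
  identical(grid_dim(a), grid_dim(b)) &&
    max(abs(a$voxel_mm - b$voxel_mm)) < tol
}

#' Physical coordinates of voxel centres along one axis
#'
#' @param n number of voxels along the axis.
#' @param voxel voxel edge length, mm.
#' @return numeric vector of centre coordinates, mm, centred on 0.
#' @export
axis_coords <- function(n, voxel) (seq_len(n) - (n + 1) / 2) * voxel

#' Flip a 3D or 4D array across the midsagittal (first) dimension
#'
#' @param x 3D or 4D array.
#' @return array of the same shape with the x axis reversed.
#' @export
flip_x <- function(x) {
  d <- dim(x)
  idx <- rev(seq_len(d[1L]))
  if (length(d) == 3L) x[idx, , , drop = FALSE]
  else x[idx, , , , drop = FALSE]
}

#' Linear indices of homotopic voxel pairs
#'
#' Left-hemisphere voxels (x index 1..nx/2) and their mirror partners.
#'
#' @param d grid dimension (length 3, even x).
#' @return list with integer vectors `left` and `right`.
#' @export
homotopic_indices <- function(d) {
  check_even_x(d)
  nx <- d[1L]; ny <- d[2L]; nz <- d[3L]
  half <- nx %/% 2L
  i <- rep(seq_len(half), times = ny * nz)
  jk <- rep(seq_len(ny * nz) - 1L, each = half)
  left <- i + nx * jk
  right <- (nx + 1L - i) + nx * jk
  list(left = left, right = right)
}

# Time-by-voxel matrix view of a series_volume.
series_matrix <- function(series) {
  d <- dim(series$data)
  t(matrix(series$data, prod(d[1:3]), d[4L]))
}

matrix_to_series <- function(m, template) {
  d <- dim(template$data)
  series_volume(array(t(m), d), voxel_mm = template$voxel_mm,
                tr_s = template$tr_s)
}
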