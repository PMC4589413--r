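# Volume and table I/O.
#
# NIfTI-1 support is a deliberately minimal single-file (.nii, optionally
# gzipped) codec: 348-byte header, uint8/int16/int32/float32/float64
# data, dim/pixdim geometry, scl_slope/scl_inter scaling, little-endian
# or big-endian input.  It exists because the package's compute stack
# carries no NIfTI reader; volumes written here round-trip exactly and
# are readable by standard neuroimaging tools (validated against
# nibabel in the test suite).

#' Write a volume as NIfTI-1
#'
#' @param volume a `volume_grid` (3D) or `series_volume` (4D).
#' @param path output file; a `.gz` suffix writes gzip-compressed.
#' @param datatype `"float64"` (default, lossless round-trip for R
#'   doubles) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, datatype = c("float64", "float32")) {
  datatype <- match.arg(datatype)
  code <- if (datatype == "float64") 64L else 16L
  size <- if (code == 64L) 8L else 4L
  if (inherits(volume, "volume_grid")) {
    dat <- volume$data; nd <- 3L; tr <- 0
  } else if (inherits(volume, "series_volume")) {
    dat <- volume$data; nd <- 4L; tr <- volume$tr_s
  } else stopf("'volume' must be a volume_grid or series_volume")
  d <- dim(dat)
  dimfield <- rep(1L, 8L); dimfield[1L] <- nd
  dimfield[1L + seq_len(nd)] <- d
  pixdim <- rep(0, 8L)
  pixdim[2:4] <- volume$voxel_mm
  pixdim[5L] <- tr

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, sz) writeBin(as.integer(x), con, size = sz,
                                 endian = "little")
  wf <- function(x, sz = 4L) writeBin(as.double(x), con, size = sz,
                                      endian = "little")
  zeros <- function(n) writeBin(raw(n), con)
  wi(348L, 4L)                      # sizeof_hdr
  zeros(36L)                        # data_type..dim_info
  wi(dimfield, 2L)                  # dim[8]
  wf(rep(0, 3))                     # intent_p1..3
  wi(0L, 2L)                        # intent_code
  wi(code, 2L)                      # datatype
  wi(8L * size, 2L)                 # bitpix
  wi(0L, 2L)                        # slice_start
  wf(pixdim)                        # pixdim[8]
  wf(352)                           # vox_offset
  wf(1)                             # scl_slope
  wf(0)                             # scl_inter
  wi(0L, 2L)                        # slice_end
  zeros(2L)                         # slice_code, xyzt_units
  wf(rep(0, 4))                     # cal_max, cal_min, slice_duration,
                                    # toffset
  wi(rep(0L, 2L), 4L)               # glmax, glmin
  zeros(104L)                       # descrip[80], aux_file[24]
  wi(rep(0L, 2L), 2L)               # qform_code, sform_code
  wf(rep(0, 18))                    # quaternion + srow matrix
  zeros(16L)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  zeros(4L)                         # extension flag
  writeBin(as.double(dat), con, size = size, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @param expect `"any"`, `"3d"` or `"4d"`: reading a file whose
#'   dimensionality differs from the expectation is an error.
#' @return a `volume_grid` for 3D data, a `series_volume` for 4D.
#' @export
read_volume <- function(path, expect = c("any", "3d", "4d")) {
  expect <- match.arg(expect)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stopf("malformed NIfTI header: file too short")
  rd_i <- function(off, sz, n = 1L, endian = "little")
    readBin(hdr[(off + 1L):(off + sz * n)], "integer", n = n, size = sz,
            endian = endian)
  endian <- "little"
  if (rd_i(0L, 4L) != 348L) {
    if (readBin(hdr[1:4], "integer", size = 4L, endian = "big") == 348L)
      endian <- "big"
    else stopf("malformed NIfTI header: sizeof_hdr is not 348")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stopf("not a NIfTI-1 file (bad magic)")
  rd_f <- function(off, n = 1L)
    readBin(hdr[(off + 1L):(off + 4L * n)], "double", n = n, size = 4L,
            endian = endian)
  dimfield <- rd_i(40L, 2L, 8L, endian)
  nd <- dimfield[1L]
  if (nd < 3L || nd > 4L) stopf("unsupported NIfTI dimensionality: %d", nd)
  d <- dimfield[1L + seq_len(nd)]
  code <- rd_i(70L, 2L, 1L, endian)
  spec <- switch(as.character(code),
                 `2` = list(what = "integer", size = 1L, signed = FALSE),
                 `4` = list(what = "integer", size = 2L, signed = TRUE),
                 `8` = list(what = "integer", size = 4L, signed = TRUE),
                 `16` = list(what = "double", size = 4L, signed = TRUE),
                 `64` = list(what = "double", size = 8L, signed = TRUE),
                 stopf("unsupported NIfTI datatype code %d", code))
  pixdim <- rd_f(76L, 8L)
  vox_offset <- rd_f(108L)
  scl_slope <- rd_f(112L)
  scl_inter <- rd_f(116L)
  skip <- vox_offset - 348L
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(d)
  dat <- readBin(con, spec$what, n = n, size = spec$size,
                 signed = spec$signed, endian = endian)
  if (length(dat) != n) stopf("truncated NIfTI data section")
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    dat <- dat * scl_slope + scl_inter
  dat <- array(as.double(dat), d)
  voxel_mm <- pixdim[2:4]
  if (nd == 3L) {
    if (expect == "4d") stopf("expected a 4D series but '%s' is 3D", path)
    volume_grid(dat, voxel_mm = voxel_mm)
  } else {
    if (expect == "3d") stopf("expected a 3D volume but '%s' is 4D", path)
    tr <- pixdim[5L]
    series_volume(dat, voxel_mm = voxel_mm, tr_s = if (tr > 0) tr else 2)
  }
}

#' Write a callosal-volume table as CSV
#'
#' Header: subject_id,group,cc_posterior,cc_midposterior,cc_central,
#' cc_midanterior,cc_anterior,brain_volume.
#'
#' @param records data.frame in the layout of
#'   [generate_callosal_table()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_callosal_table <- function(records, path) {
  cols <- c("subject_id", "group", seg_cols, "brain_volume")
  miss <- setdiff(cols, names(records))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  write.csv(records[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a callosal-volume table
#'
#' @param path CSV written by [write_callosal_table()] (or FreeSurfer
#'   aseg volumes exported to that layout).
#' @return data.frame.
#' @export
read_callosal_table <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("subject_id", "group", seg_cols, "brain_volume"),
                  names(out))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  out
}
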