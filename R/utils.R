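# Internal helpers shared across modules.

#' Evaluate code with a temporarily seeded RNG
#'
#' Seeds the generator, runs `code`, and restores the caller's RNG state so
#' that seeded package functions do not perturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to run unseeded.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (strict_lower && x <= lower) stopf("'%s' must be > %g", name, lower)
  if (!strict_lower && x < lower) stopf("'%s' must be >= %g", name, lower)
  if (strict_upper && x >= upper) stopf("'%s' must be < %g", name, upper)
  if (!strict_upper && x > upper) stopf("'%s' must be <= %g", name, upper)
  invisible(x)
}

# Batched 3D FFT over the 4th margin of a 4D array (or a plain 3D array).
# Forward transform is unnormalized; inverse divides by the number of
# spatial elements, matching stats::fft conventions.
fft3 <- function(x, inverse = FALSE) {
  d <- dim(x)
  if (length(d) == 3L) {
    out <- fft(x, inverse = inverse)
    if (inverse) out <- out / prod(d)
    return(out)
  }
  stopifnot(length(d) == 4L)
  out <- array(0i, d)
  scale <- if (inverse) prod(d[1:3]) else 1
  for (t in seq_len(d[4L]))
    out[, , , t] <- fft(array(x[, , , t], d[1:3]), inverse = inverse) / scale
  out
}

# Frequency-domain transfer function of an isotropic Gaussian blur with the
# given standard deviation in voxels, on a periodic grid of dimension d.
gaussian_transfer <- function(d, sigma_vox) {
  axes <- lapply(seq_along(d), function(i) {
    k <- c(0:(d[i] %/% 2), -((d[i] - d[i] %/% 2 - 1):1))
    if (d[i] == 1L) k <- 0
    exp(-2 * pi^2 * sigma_vox[i]^2 * (k / d[i])^2)
  })
  g <- outer(outer(axes[[1L]], axes[[2L]]), axes[[3L]])
  dim(g) <- d
  g
}

# Periodic isotropic Gaussian smoothing of a 3D array (or each 3D frame of a
# 4D array) with FWHM given in millimetres.
smooth_gaussian <- function(x, fwhm_mm, voxel_mm) {
  if (fwhm_mm <= 0) return(x)
  sigma_vox <- fwhm_mm / sqrt(8 * log(2)) / voxel_mm
  d <- dim(x)
  g <- gaussian_transfer(d[1:3], rep(sigma_vox, length.out = 3L))
  if (length(d) == 4L) g <- array(g, d)
  Re(fft3(fft3(x + 0i) * g, inverse = TRUE))
}

fwhm_to_sigma <- function(fwhm) fwhm / sqrt(8 * log(2))

# Apply a Hermitian-symmetric frequency-domain filter to every 3D frame
# of a real 4D array.  Two frames are packed into one complex transform
# (their filtered images are the real and imaginary parts of the
# inverse), halving the FFT count.
filter_frames <- function(x, transfer) {
  d <- dim(x)
  n3 <- prod(d[1:3])
  nt <- d[4L]
  out <- array(0, d)
  t <- 1L
  while (t <= nt) {
    if (t < nt) {
      z <- array(complex(real = x[, , , t], imaginary = x[, , , t + 1L]),
                 d[1:3])
      y <- fft(fft(z) * transfer, inverse = TRUE) / n3
      out[, , , t] <- Re(y)
      out[, , , t + 1L] <- Im(y)
      t <- t + 2L
    } else {
      y <- fft(fft(array(x[, , , t], d[1:3])) * transfer,
               inverse = TRUE) / n3
      out[, , , t] <- Re(y)
      t <- t + 1L
    }
  }
  out
}
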