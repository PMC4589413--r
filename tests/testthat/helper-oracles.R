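# Independent oracles used across tests.  These deliberately avoid the
# package's own code paths.

# Brute-force connected components by breadth-first search over an
# explicit neighbour enumeration.
brute_components <- function(mask, connectivity) {
  d <- dim(mask)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  manh <- rowSums(abs(off))
  off <- off[manh > 0 &
               ((connectivity == 6 & manh == 1) |
                  (connectivity == 18 & manh <= 2) |
                  connectivity == 26), , drop = FALSE]
  labs <- array(0L, d)
  cur <- 0L
  for (start in which(mask)) {
    if (labs[start] > 0L) next
    cur <- cur + 1L
    queue <- matrix(arrayInd(start, d), ncol = 3L)
    labs[start] <- cur
    while (nrow(queue)) {
      v <- queue[1L, ]
      queue <- queue[-1L, , drop = FALSE]
      nb <- sweep(off, 2L, v, function(o, p) o + p)
      ok <- nb[, 1L] >= 1 & nb[, 1L] <= d[1L] &
        nb[, 2L] >= 1 & nb[, 2L] <= d[2L] &
        nb[, 3L] >= 1 & nb[, 3L] <= d[3L]
      nb <- nb[ok, , drop = FALSE]
      for (i in seq_len(nrow(nb))) {
        if (mask[nb[i, 1L], nb[i, 2L], nb[i, 3L]] &&
            labs[nb[i, 1L], nb[i, 2L], nb[i, 3L]] == 0L) {
          labs[nb[i, 1L], nb[i, 2L], nb[i, 3L]] <- cur
          queue <- rbind(queue, nb[i, , drop = FALSE])
        }
      }
    }
  }
  labs
}

# Sorted component sizes from a label array.
component_sizes <- function(labs) sort(tabulate(labs[labs > 0L]))

# Closed-form effective df for two independent AR(1) series with common
# coefficient phi, from the autocorrelation plug-in with population
# autocorrelations phi^j.
ar1_effective_df <- function(n, phi) {
  j <- seq_len(n - 1L)
  1 / (1 / n + (2 / n) * sum(((n - j) / n) * phi^(2 * j)))
}

# Small symmetric template shared by symmetrization tests.
make_template <- function(shape = c(16L, 16L, 16L), seed = 42L,
                          voxel = 2) {
  generate_symmetric_template(
    sim_config(grid_shape = shape, voxel_size_mm = voxel, seed = seed))
}

# A known affine distortion expressed in the degree-2 warp family:
# normalized x-translation `tx` plus an x-shear with y of strength `sxy`.
make_distortion <- function(template, tx = 0.06, sxy = 0.05) {
  w <- identity_warp(template, 2)
  co <- w$coefficients
  expo <- w$exponents
  co[rowSums(expo) == 0, 1L] <- tx
  co[expo[, 1L] == 0 & expo[, 2L] == 1 & expo[, 3L] == 0, 1L] <- sxy
  warp_parameters(2, co, w$bounds)
}
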