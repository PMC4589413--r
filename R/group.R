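# Group inference on corrected symmetry maps: directional two-sample
# t-maps, phase-scrambled surrogate nulls, spatial-ACF kernel estimation,
# and the Monte-Carlo cluster-size null distribution.

#' Directional two-sample t-map
#'
#' Pooled-variance unpaired t statistic per voxel, testing the stated
#' direction (`"A_gt_B"` computes mean(A) - mean(B)).  Voxels with zero
#' pooled variance or missing values are masked (`NA`).
#'
#' @param maps_A,maps_B lists of 3D arrays (one corrected-z map per
#'   subject), at least 2 per group, on a shared grid.
#' @param tail `"A_gt_B"` (default) or `"B_gt_A"`.
#' @param voxel_mm voxel edge length(s), mm.
#' @param threshold voxel-forming threshold carried on the map (z scale,
#'   default 2.32, the one-tailed p = 0.01 point).
#' @return a `stat_map` with `df = nA + nB - 2`.
#' @export
two_sample_tmap <- function(maps_A, maps_B, tail = c("A_gt_B", "B_gt_A"),
                            voxel_mm = 1, threshold = 2.32) {
  tail <- match.arg(tail)
  nA <- length(maps_A); nB <- length(maps_B)
  if (nA < 2L || nB < 2L) stopf("need at least 2 subjects per group")
  d <- dim(maps_A[[1L]])
  for (m in c(maps_A, maps_B))
    if (!identical(dim(m), d)) stopf("all maps must share one grid")
  ya <- vapply(maps_A, as.vector, numeric(prod(d)))
  yb <- vapply(maps_B, as.vector, numeric(prod(d)))
  ma <- rowMeans(ya); mb <- rowMeans(yb)
  ssa <- rowSums((ya - ma)^2)
  ssb <- rowSums((yb - mb)^2)
  sp2 <- (ssa + ssb) / (nA + nB - 2L)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  tval <- (ma - mb) / se
  if (tail == "B_gt_A") tval <- -tval
  tval[!is.finite(tval)] <- NA_real_
  stat_map(array(tval, d), df = nA + nB - 2L, tail = tail,
           voxel_mm = voxel_mm, threshold = threshold)
}

#' Convert t statistics to z-equivalents
#'
#' Maps each t to the standard-normal deviate with the same upper-tail
#' probability, so subject-level and null-image thresholds share the z
#' scale.
#'
#' @param tval t statistics (vector or array).
#' @param df degrees of freedom.
#' @return z-equivalents, same shape.
#' @export
t_to_z <- function(tval, df) {
  out <- qnorm(pt(tval, df, lower.tail = FALSE, log.p = TRUE),
               lower.tail = FALSE, log.p = TRUE)
  if (!is.null(dim(tval))) dim(out) <- dim(tval)
  out
}

#' Convert a t-map to a z-map
#'
#' @param map a `stat_map` with finite `df`.
#' @return a `stat_map` on the z scale (`df = NA`).
#' @export
tmap_to_zmap <- function(map) {
  if (!is.finite(map$df)) stopf("map has no t degrees of freedom")
  out <- map
  out$stat <- t_to_z(map$stat, map$df)
  out$df <- NA_real_
  out
}

#' Phase-scramble a 3D volume
#'
#' Replaces the Fourier phases of the volume with random phases carrying
#' Hermitian symmetry (drawn as the phases of a white-noise field), while
#' preserving every Fourier amplitude; the DC phase is pinned so the mean
#' is preserved, and the output is real.
#'
#' @param volume 3D numeric array (or `volume_grid`).
#' @param seed integer seed, or `NULL` when `phases` is supplied.
#' @param phases optional precomputed phase field (complex 3D array of
#'   unit-modulus values with Hermitian symmetry), e.g. from
#'   [random_phase_field()]; lets one draw be reused across timepoints.
#' @return scrambled volume, same class as the input.
#' @export
phase_scramble <- function(volume, seed = NULL, phases = NULL) {
  dat <- if (inherits(volume, "volume_grid")) volume$data else volume
  d <- dim(dat)
  if (is.null(phases))
    phases <- with_seed(seed, random_phase_field(d))
  f <- fft(dat) * phases
  out <- Re(fft(f, inverse = TRUE)) / prod(d)
  if (inherits(volume, "volume_grid"))
    volume_grid(out, volume$voxel_mm)
  else out
}

#' Random unit-modulus phase field with Hermitian symmetry
#'
#' @param d grid dimension (length 3).
#' @return complex 3D array; multiplying a volume's FFT by it randomizes
#'   phases while keeping the inverse transform real and the DC bin
#'   untouched.
#' @export
random_phase_field <- function(d) {
  g <- fft(array(rnorm(prod(d)), d))
  ph <- g / Mod(g)
  ph[!is.finite(ph)] <- 1 + 0i
  ph[1, 1, 1] <- 1 + 0i  # preserve the mean
  ph
}

#' Null group t-map from flipped, phase-scrambled series
#'
#' Builds surrogate symmetry maps by correlating each subject's series
#' with its flipped and phase-scrambled image — destroying homotopic
#' spatial alignment while preserving each series' temporal structure and
#' spatial spectrum — then forms the two-group t-map of the corrected-z
#' surrogates.
#'
#' @param series_A,series_B lists of `series_volume` per group.
#' @param df study-level effective degrees of freedom used to correct the
#'   surrogate Fisher-z maps.
#' @param seed integer seed (one independent phase draw per subject).
#' @param per_timepoint_phases draw an independent phase field per
#'   timepoint instead of one per subject (default FALSE).
#' @param tail,threshold passed to [two_sample_tmap()].
#' @return a z-scale `stat_map` (t converted via [t_to_z()]).
#' @export
null_symmetry_tmap <- function(series_A, series_B, df, seed = 1L,
                               per_timepoint_phases = FALSE,
                               tail = "A_gt_B", threshold = 2.32) {
  all_series <- c(series_A, series_B)
  nA <- length(series_A)
  maps <- with_seed(seed, {
    lapply(all_series, function(s)
      null_symmetry_map(s, df = df,
                        per_timepoint_phases = per_timepoint_phases))
  })
  tm <- two_sample_tmap(maps[seq_len(nA)], maps[-seq_len(nA)],
                        tail = tail,
                        voxel_mm = all_series[[1L]]$voxel_mm,
                        threshold = threshold)
  tmap_to_zmap(tm)
}

# Surrogate corrected-z map of one subject: correlate the series with its
# flipped, phase-scrambled image, Fisher-transform, scale by sqrt(df-3).
# Uses the caller's RNG stream.
null_symmetry_map <- function(series, df, per_timepoint_phases = FALSE) {
  d <- grid_dim(series)
  nt <- dim(series$data)[4L]
  flipped <- flip_x(series$data)
  if (per_timepoint_phases) {
    scr <- array(0, dim(series$data))
    for (t in seq_len(nt))
      scr[, , , t] <- phase_scramble(array(flipped[, , , t], d),
                                     phases = random_phase_field(d))
  } else {
    scr <- filter_frames(flipped, random_phase_field(d))
  }
  y <- series_matrix(series)
  ys <- t(matrix(scr, prod(d), nt))
  r <- pair_correlation(y, ys)
  z <- suppressWarnings(fisher_z(r)) * sqrt(df - 3)
  array(z, d)
}

#' Estimate the spatial ACF kernel of statistic maps
#'
#' Empirical 3D spatial autocorrelation function (computed via the power
#' spectrum) of each supplied map, averaged over maps, normalized to 1 at
#' zero lag, and truncated where its magnitude falls below `floor`.  The
#' kernel is returned in wrap-around order (zero lag at `[1, 1, 1]`),
#' ready for Fourier-domain convolution.
#'
#' @param stat_maps a `stat_map`/3D array or a list of them (e.g. 10 null
#'   t-map runs).
#' @param floor truncation floor on |ACF| (default 0.05).
#' @return an `acf_kernel`: `kernel` (3D array), `n_runs`, `floor`.
#' @export
estimate_acf_kernel <- function(stat_maps, floor = 0.05) {
  if (inherits(stat_maps, "stat_map") || is.array(stat_maps))
    stat_maps <- list(stat_maps)
  acfs <- lapply(stat_maps, function(m) {
    dat <- if (inherits(m, "stat_map")) m$stat else m
    dat[is.na(dat)] <- 0
    dat <- dat - mean(dat)
    if (sd(as.vector(dat)) == 0) stopf("constant map: ACF undefined")
    f <- fft(dat)
    a <- Re(fft(f * Conj(f), inverse = TRUE))
    a / a[1, 1, 1]
  })
  avg <- Reduce(`+`, acfs) / length(acfs)
  avg[abs(avg) < floor] <- 0
  structure(list(kernel = avg, n_runs = length(acfs), floor = floor),
            class = "acf_kernel")
}

#' Monte-Carlo cluster-size null distribution
#'
#' Generates `n_images` white-noise images convolved with the kernel (in
#' the Fourier domain), standardizes each to zero mean and unit variance,
#' thresholds at the voxel-forming threshold, and pools the sizes of the
#' resulting connected clusters.  The critical size is the smallest k
#' whose null tail probability P(CS >= k) falls below `cluster_p`.
#'
#' @param kernel an `acf_kernel` or bare 3D array (wrap-around order).
#' @param grid_shape image dimensions (defaults to the kernel's grid).
#' @param threshold voxel-forming z threshold (default 2.32).
#' @param n_images number of null images (>= 100; the reference analysis
#'   uses 10000).
#' @param cluster_p cluster-size significance level (default 0.001).
#' @param connectivity cluster connectivity (default 18).
#' @param seed integer seed.
#' @return a `cluster_null`: `sizes` (all null cluster sizes), `k_crit`,
#'   `n_images`, `threshold`, `cluster_p`, `no_clusters` flag.
#' @export
simulate_cluster_null <- function(kernel, grid_shape = NULL,
                                  threshold = 2.32, n_images = 10000L,
                                  cluster_p = 0.001, connectivity = 18,
                                  seed = 1L) {
  k <- if (inherits(kernel, "acf_kernel")) kernel$kernel else kernel
  if (is.null(grid_shape)) grid_shape <- dim(k)
  if (!identical(as.integer(dim(k)), as.integer(grid_shape)))
    stopf("kernel grid does not match 'grid_shape'")
  if (n_images < 100L) stopf("'n_images' must be >= 100")
  kf <- fft(k)
  nvox <- prod(grid_shape)
  cluster_sizes <- function(img) {
    img <- (img - mean(img)) / sd(img)
    labs <- .label_components(as.vector(img > threshold),
                              as.integer(grid_shape),
                              as.integer(connectivity))
    if (max(labs) > 0L) tabulate(labs[labs > 0L]) else integer(0)
  }
  size_list <- with_seed(seed, {
    # two white-noise images per complex transform (Re/Im split)
    lapply(seq_len((n_images + 1L) %/% 2L), function(i) {
      z <- array(complex(real = rnorm(nvox), imaginary = rnorm(nvox)),
                 grid_shape)
      y <- fft(fft(z) * kf, inverse = TRUE) / nvox
      second <- if (2L * i <= n_images) cluster_sizes(Im(y)) else integer(0)
      c(cluster_sizes(Re(y)), second)
    })
  })
  sizes <- unlist(size_list)
  no_clusters <- length(sizes) == 0L
  k_crit <- if (no_clusters) 1L else {
    ks <- sort(unique(sizes))
    tailp <- vapply(ks, function(k0) mean(sizes >= k0), numeric(1))
    hit <- ks[tailp < cluster_p]
    if (length(hit)) min(hit) else max(ks) + 1L
  }
  structure(list(sizes = sizes, k_crit = as.integer(k_crit),
                 n_images = as.integer(n_images), threshold = threshold,
                 cluster_p = cluster_p, connectivity = connectivity,
                 no_clusters = no_clusters, seed = seed),
            class = "cluster_null")
}

#' @export
print.cluster_null <- function(x, ...) {
  cat(sprintf(
    "<cluster_null> %d images, %d null clusters, k_crit = %d at p < %g%s\n",
    x$n_images, length(x$sizes), x$k_crit, x$cluster_p,
    if (x$no_clusters) " [no clusters formed]" else ""))
  invisible(x)
}

#' Cohen's d map and supra-0.8 effect volumes
#'
#' Pooled-SD standardized mean difference (A - B) per voxel, with the
#' physical volume (cm^3) where d strictly exceeds 0.8 in each direction.
#'
#' @param maps_A,maps_B lists of 3D arrays, >= 2 per group.
#' @param voxel_mm voxel edge length(s), mm.
#' @param d_threshold effect-size threshold (default 0.8).
#' @return list: `d` (3D array, `NA` where the pooled SD is 0),
#'   `volume_A_gt_B_cm3`, `volume_B_gt_A_cm3`, `d_threshold`.
#' @export
cohens_d_map <- function(maps_A, maps_B, voxel_mm = 1, d_threshold = 0.8) {
  nA <- length(maps_A); nB <- length(maps_B)
  if (nA < 2L || nB < 2L) stopf("need at least 2 subjects per group")
  d <- dim(maps_A[[1L]])
  ya <- vapply(maps_A, as.vector, numeric(prod(d)))
  yb <- vapply(maps_B, as.vector, numeric(prod(d)))
  ma <- rowMeans(ya); mb <- rowMeans(yb)
  sp <- sqrt((rowSums((ya - ma)^2) + rowSums((yb - mb)^2)) /
               (nA + nB - 2L))
  dval <- (ma - mb) / sp
  dval[sp == 0] <- NA_real_
  voxvol_cm3 <- prod(rep(voxel_mm, length.out = 3L)) / 1000
  list(d = array(dval, d),
       volume_A_gt_B_cm3 = sum(dval > d_threshold, na.rm = TRUE) * voxvol_cm3,
       volume_B_gt_A_cm3 = sum(dval < -d_threshold, na.rm = TRUE) * voxvol_cm3,
       d_threshold = d_threshold)
}
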