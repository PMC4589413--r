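rand_maps <- function(n, d = c(8, 8, 8), mean = 0) {
  lapply(seq_len(n), function(i) array(rnorm(prod(d), mean), d))
}

test_that("two_sample_tmap matches a long-hand pooled t", {
  set.seed(1)
  A <- rand_maps(3); B <- rand_maps(3)
  tm <- two_sample_tmap(A, B)
  a <- sapply(A, function(m) m[2, 3, 4])
  b <- sapply(B, function(m) m[2, 3, 4])
  sp <- sqrt((2 * var(a) + 2 * var(b)) / 4)
  expect_equal(tm$stat[2, 3, 4], (mean(a) - mean(b)) / (sp * sqrt(2 / 3)),
               tolerance = 1e-12)
  expect_identical(tm$df, 4L)
  # identical groups -> t = 0
  t0 <- two_sample_tmap(A, A)
  expect_true(all(abs(t0$stat) < 1e-12 | is.na(t0$stat)))
  # direction flip negates
  expect_equal(two_sample_tmap(A, B, tail = "B_gt_A")$stat, -tm$stat)
  expect_error(two_sample_tmap(A[1], B), "2 subjects")
})

test_that("null calibration of the supra-threshold voxel fraction", {
  set.seed(2)
  d <- c(20, 25, 20)
  A <- rand_maps(8, d); B <- rand_maps(8, d)
  zm <- tmap_to_zmap(two_sample_tmap(A, B))
  n_over <- sum(zm$stat > 2.32, na.rm = TRUE)
  ci <- binom.test(n_over, prod(d))$conf.int
  p_nom <- pnorm(2.32, lower.tail = FALSE)
  expect_true(p_nom >= ci[1] && p_nom <= ci[2])
})

test_that("t_to_z preserves tail probabilities including extremes", {
  t <- c(-8, -1, 0, 1.5, 12)
  z <- t_to_z(t, df = 10)
  expect_equal(pnorm(z, lower.tail = FALSE),
               pt(t, 10, lower.tail = FALSE), tolerance = 1e-10)
  expect_true(all(is.finite(z)))
})

test_that("phase scrambling preserves spectrum and mean, randomizes phase", {
  set.seed(3)
  v <- array(rnorm(16^3), c(16, 16, 16))
  vs <- phase_scramble(v, seed = 4)
  expect_equal(Mod(fft(vs)), Mod(fft(v)), tolerance = 1e-9)
  expect_equal(mean(vs), mean(v), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(vs, v)))
  expect_true(max(abs(Im(fft(fft(vs), inverse = TRUE)))) < 1e-6)
  # volume_grid passthrough keeps class and geometry
  vg <- phase_scramble(volume_grid(v, 2), seed = 5)
  expect_s3_class(vg, "volume_grid")

  # Wiener-Khinchin: spatial ACF preserved (spectral estimator), checked
  # at radial lags <= 4 averaged over 20 seeds
  sm <- vmhc:::smooth_gaussian(v, fwhm_mm = 6, voxel_mm = 2)
  acf_of <- function(x) {
    x <- x - mean(x)
    a <- Re(fft(fft(x) * Conj(fft(x)), inverse = TRUE))
    a / a[1, 1, 1]
  }
  ref <- acf_of(sm)
  lag_idx <- cbind(1 + 1:4, 1, 1)
  acc <- rowMeans(vapply(1:20, function(s)
    acf_of(phase_scramble(sm, seed = s))[lag_idx], numeric(4)))
  expect_equal(acc, ref[lag_idx], tolerance = 0.05)
})

test_that("ACF kernels recover known smoothness", {
  set.seed(6)
  # white noise -> near-delta kernel
  wk <- estimate_acf_kernel(array(rnorm(20^3), c(20, 20, 20)))
  off <- wk$kernel; off[1, 1, 1] <- 0
  expect_lt(sum(abs(off)), 0.05)

  # Gaussian-smoothed map: ACF FWHM ~ sqrt(2) x image FWHM
  d <- c(32, 32, 32)
  sm <- vmhc:::smooth_gaussian(array(rnorm(prod(d)), d), fwhm_mm = 4,
                               voxel_mm = 1)
  k <- estimate_acf_kernel(sm, floor = 0.01)$kernel
  prof <- k[1:12, 1, 1]
  half <- which(prof < 0.5)[1] - 1
  # linear interpolation of the half crossing, doubled for full width
  hw <- half - 1 + (prof[half] - 0.5) / (prof[half] - prof[half + 1])
  expect_equal(2 * hw, sqrt(2) * 4, tolerance = 0.15 * sqrt(2) * 4)

  # averaging over runs reduces variance
  one <- replicate(8, {
    m <- vmhc:::smooth_gaussian(array(rnorm(16^3), c(16, 16, 16)), 4, 1)
    estimate_acf_kernel(m)$kernel[2, 1, 1]
  })
  ten <- replicate(8, {
    ms <- lapply(1:10, function(i)
      vmhc:::smooth_gaussian(array(rnorm(16^3), c(16, 16, 16)), 4, 1))
    estimate_acf_kernel(ms)$kernel[2, 1, 1]
  })
  expect_lt(var(ten), var(one))
  expect_error(estimate_acf_kernel(array(1, c(4, 4, 4))), "constant")
})

test_that("cluster-size null: delta kernel, monotone in width, reproducible", {
  delta <- array(0, c(16, 16, 16)); delta[1, 1, 1] <- 1
  cn <- simulate_cluster_null(delta, threshold = 2.32, n_images = 300,
                              cluster_p = 0.001, seed = 7)
  expect_true(all(cn$sizes >= 1))
  # independent-voxel oracle: threshold iid normal fields directly
  set.seed(77)
  osizes <- unlist(lapply(1:300, function(i) {
    labs <- vmhc:::.label_components(rnorm(16^3) > 2.32,
                                     c(16L, 16L, 16L), 18L)
    if (max(labs) > 0) tabulate(labs[labs > 0]) else integer(0)
  }))
  k_oracle <- min(which(vapply(1:10, function(k)
    mean(osizes >= k), numeric(1)) < 0.001))
  expect_lte(abs(cn$k_crit - k_oracle), 1)
  expect_lt(abs(mean(cn$sizes == 1) - mean(osizes == 1)), 0.02)
  cn2 <- simulate_cluster_null(delta, threshold = 2.32, n_images = 300,
                               cluster_p = 0.001, seed = 7)
  expect_identical(cn$sizes, cn2$sizes)

  smooth_kernel <- vmhc:::gaussian_transfer(c(16, 16, 16), rep(1.2, 3))
  ks <- Re(fft(smooth_kernel, inverse = TRUE)); ks <- ks / ks[1, 1, 1]
  cw <- simulate_cluster_null(ks, threshold = 2.32, n_images = 300,
                              cluster_p = 0.001, seed = 8)
  q99 <- function(x) quantile(x$sizes, 0.99)
  expect_gt(q99(cw), q99(cn))

  # threshold too high for any cluster: flagged, k_crit 1
  ch <- simulate_cluster_null(delta, threshold = 9, n_images = 100, seed = 9)
  expect_true(ch$no_clusters)
  expect_identical(ch$k_crit, 1L)
  expect_error(simulate_cluster_null(delta, n_images = 50), ">= 100")
})

test_that("cluster extraction matches the brute-force oracle", {
  set.seed(10)
  for (i in 1:12) {
    mask <- array(runif(8^3) < 0.25, c(8, 8, 8))
    stat <- array(0, c(8, 8, 8))
    stat[mask] <- 3 + runif(sum(mask))
    for (conn in c(6, 18, 26)) {
      rep <- extract_clusters(stat_map(stat, voxel_mm = 1, threshold = 2),
                              connectivity = conn)
      oracle <- brute_components(mask, conn)
      expect_identical(sort(rep$table$k, decreasing = TRUE),
                       sort(component_sizes(oracle), decreasing = TRUE))
      # identical partition, not just identical sizes
      expect_identical(rep$labels > 0, oracle > 0)
      match_tab <- table(rep$labels[oracle > 0], oracle[oracle > 0])
      expect_true(all(rowSums(match_tab > 0) == 1))
    }
  }
})

test_that("edge-sharing voxels merge under 18- but not 6-connectivity", {
  stat <- array(0, c(5, 5, 5))
  stat[2, 2, 2] <- 5; stat[3, 3, 2] <- 5   # share an edge
  expect_identical(nrow(extract_clusters(stat, threshold = 2,
                                         connectivity = 18)$table), 1L)
  expect_identical(nrow(extract_clusters(stat, threshold = 2,
                                         connectivity = 6)$table), 2L)
  # two separated blobs of sizes 7 and 4, size-ordered report
  stat2 <- array(0, c(5, 5, 5))
  stat2[1:2, 1:2, 1] <- 5            # 4 voxels
  stat2[4:5, 4:5, 4] <- 5; stat2[4:5, 4:5, 5][1:3] <- 5  # 7 voxels
  tab <- extract_clusters(stat2, threshold = 2, connectivity = 18)$table
  expect_equal(tab$k, c(7, 4))
  # thresholding above the global max: empty report
  empty <- extract_clusters(stat2, threshold = 99)
  expect_identical(nrow(empty$table), 0L)
})

test_that("cluster-extent correction applies the critical-size rule", {
  stat <- array(0, c(10, 10, 10))
  stat[1:5, 1:5, 1:5] <- 5              # 125-voxel cluster
  stat[8:10, 8:10, 8] <- 5              # 9-voxel cluster
  rep <- extract_clusters(stat, threshold = 2)
  out <- apply_cluster_correction(rep, 56)
  expect_equal(out$table$k, 125)
  expect_true(all(out$labels[stat == 0] == 0))
  # k_crit = 1 is the identity
  expect_equal(apply_cluster_correction(rep, 1)$table$k, rep$table$k)
  # threshold mismatch between report and null is flagged
  cn <- simulate_cluster_null({d <- array(0, c(10, 10, 10)); d[1] <- 1; d},
                              threshold = 3, n_images = 100, seed = 1)
  expect_error(apply_cluster_correction(rep, cn), "mismatch")
})

test_that("group-mean masking: identity for strong maps, calibrated on noise", {
  stat <- array(0, c(8, 8, 8)); stat[2:4, 2:4, 2:4] <- 5
  rep <- extract_clusters(stat, threshold = 2)
  strong <- rand_maps(6, c(8, 8, 8), mean = 10)
  kept <- mask_by_group_mean(rep, strong, 5e-4)
  expect_equal(kept$table$k, rep$table$k)

  set.seed(11)
  d <- c(25, 20, 20)
  noise_maps <- rand_maps(10, d)
  y <- vapply(noise_maps, as.vector, numeric(prod(d)))
  tv <- rowMeans(y) / (apply(y, 1, sd) / sqrt(10))
  frac <- mean(pt(tv, 9, lower.tail = FALSE) < 5e-4)
  ci <- binom.test(sum(pt(tv, 9, lower.tail = FALSE) < 5e-4),
                   prod(d))$conf.int
  expect_true(5e-4 >= ci[1] && 5e-4 <= ci[2])

  # masking away half the effect leaves the active half
  stat2 <- array(0, c(8, 8, 8)); stat2[2:5, 2:5, 2:5] <- 5
  rep2 <- extract_clusters(stat2, threshold = 2)
  half_on <- lapply(1:6, function(i) {
    m <- array(rnorm(8^3, 0), c(8, 8, 8))
    m[2:5, 2:5, 2:3] <- 12
    m
  })
  surv <- mask_by_group_mean(rep2, half_on, 5e-4)
  expect_true(all(surv$labels[, , 4:5] == 0))
  expect_gt(sum(surv$labels[2:5, 2:5, 2:3] > 0), 0)
})

test_that("Cohen's d maps and supra-threshold volumes behave", {
  A <- rand_maps(4); B <- A
  cd <- cohens_d_map(A, B, voxel_mm = 2)
  expect_true(all(cd$d == 0, na.rm = TRUE))
  expect_identical(cd$volume_A_gt_B_cm3, 0)

  # hand computation: means 1.8 vs 1.0 with pooled SD exactly 1 gives
  # d = 0.8 on the boundary, excluded by the strict inequality
  mk <- function(vals) lapply(vals, function(v) array(v, c(2, 2, 2)))
  cd1 <- cohens_d_map(mk(c(1.8, 2.8, 0.8)), mk(c(1.0, 2.0, 0.0)),
                      voxel_mm = 10)
  expect_equal(cd1$d[1, 1, 1], 0.8, tolerance = 1e-12)
  # strictly below the boundary: excluded; strictly above: included
  below <- cohens_d_map(mk(c(1.8, 2.8, 0.8) - 1e-6), mk(c(1, 2, 0)),
                        voxel_mm = 10)
  expect_identical(below$volume_A_gt_B_cm3, 0)
  above <- cohens_d_map(mk(c(1.8, 2.8, 0.8) + 1e-6), mk(c(1, 2, 0)),
                        voxel_mm = 10)
  expect_identical(above$volume_A_gt_B_cm3, 8)
})

test_that("anatomical labelling counts sub-regions and drops slivers", {
  stat <- array(0, c(6, 6, 6))
  stat[2:4, 2:4, 2] <- 5   # 9-voxel cluster
  rep <- extract_clusters(stat, threshold = 2)
  labels <- array(1L, c(6, 6, 6))
  labels[2:4, 2:4, 2][1:2] <- 2L   # 2-voxel sliver of region 2
  lab <- label_clusters(rep, labels, c(`1` = "regionA", `2` = "regionB"))
  expect_identical(nrow(lab$regions), 1L)
  expect_identical(lab$regions$region, "regionA")
  expect_identical(lab$regions$k, 7L)
  # uniform label volume: one region with full k
  lab2 <- label_clusters(rep, array(3L, c(6, 6, 6)))
  expect_identical(lab2$regions$k, 9L)
  # pass-through without a label volume
  expect_identical(label_clusters(rep, NULL), rep)
  expect_error(label_clusters(rep, array(1L, c(2, 2, 2))), "grid")
})
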