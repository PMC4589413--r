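# Cluster extraction, cluster-extent correction and anatomical labelling
# of thresholded statistic maps.

#' Construct a statistic map
#'
#' @param stat 3D array of voxelwise statistics (`NA` outside the mask).
#' @param df degrees of freedom of the contrast (NA for z maps).
#' @param tail `"A_gt_B"` or `"B_gt_A"`, the tested direction.
#' @param voxel_mm voxel edge length(s), mm.
#' @param threshold voxel-forming threshold on the z scale.
#' @return a `stat_map`.
#' @export
stat_map <- function(stat, df = NA_real_, tail = "A_gt_B", voxel_mm = 1,
                     threshold = 2.32) {
  if (!is.array(stat) || length(dim(stat)) != 3L)
    stopf("'stat' must be a 3D array")
  structure(list(stat = stat, df = df, tail = tail,
                 voxel_mm = rep(as.numeric(voxel_mm), length.out = 3L),
                 threshold = threshold),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s, tail %s, threshold z = %.3g\n",
              paste(dim(x$stat), collapse = " x "), x$tail, x$threshold))
  invisible(x)
}

#' Extract supra-threshold clusters
#'
#' Maximal connected components of voxels with statistic strictly above
#' `threshold`, under 6-, 18- or 26-connectivity (default 18: voxels
#' sharing a face or an edge are connected).
#'
#' @param map a `stat_map`, or a bare 3D array (then `voxel_mm = 1`).
#' @param threshold voxel-forming threshold; defaults to the map's.
#' @param connectivity 6, 18 or 26.
#' @return a `cluster_report`: `table` (data.frame with cluster id, size
#'   k, peak statistic, peak voxel indices and physical mm coordinates),
#'   `labels` (integer 3D array of cluster ids), plus the threshold and
#'   connectivity used.  Clusters are ordered by decreasing size.
#' @export
extract_clusters <- function(map, threshold = NULL, connectivity = 18) {
  if (is.array(map)) map <- stat_map(map, threshold = threshold %||% 2.32)
  if (is.null(threshold)) threshold <- map$threshold
  d <- dim(map$stat)
  fg <- !is.na(map$stat) & map$stat > threshold
  labs <- .label_components(as.logical(fg), as.integer(d),
                            as.integer(connectivity))
  ncl <- max(labs)
  if (ncl == 0L) {
    tab <- data.frame(cluster = integer(0), k = integer(0),
                      peak = numeric(0), ix = integer(0), iy = integer(0),
                      iz = integer(0), x_mm = numeric(0), y_mm = numeric(0),
                      z_mm = numeric(0))
  } else {
    rows <- lapply(seq_len(ncl), function(cl) {
      vox <- which(labs == cl)
      peak_at <- vox[which.max(map$stat[vox])]
      ijk <- arrayInd(peak_at, d)
      data.frame(cluster = cl, k = length(vox), peak = map$stat[peak_at],
                 ix = ijk[1L], iy = ijk[2L], iz = ijk[3L],
                 x_mm = axis_coords(d[1L], map$voxel_mm[1L])[ijk[1L]],
                 y_mm = axis_coords(d[2L], map$voxel_mm[2L])[ijk[2L]],
                 z_mm = axis_coords(d[3L], map$voxel_mm[3L])[ijk[3L]])
    })
    tab <- do.call(rbind, rows)
    ord <- order(-tab$k, tab$cluster)
    tab <- tab[ord, , drop = FALSE]
    rownames(tab) <- NULL
  }
  structure(list(table = tab, labels = labs, threshold = threshold,
                 connectivity = connectivity, voxel_mm = map$voxel_mm,
                 stat = map$stat),
            class = "cluster_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> %d cluster(s) above z = %.3g (%d-connectivity)\n",
              nrow(x$table), x$threshold, x$connectivity))
  if (nrow(x$table)) print(head(x$table, 10L))
  invisible(x)
}

#' Remove clusters smaller than the critical size
#'
#' Keeps clusters whose size k satisfies the survival rule calibrated by
#' a Monte-Carlo cluster-size null: by default k >= k_crit, where k_crit
#' is the smallest size whose null tail probability is below the cluster
#' p (equivalently, k strictly greater than the largest non-significant
#' size).
#'
#' @param report a `cluster_report`.
#' @param cluster_null a `cluster_null` from [simulate_cluster_null()],
#'   or a bare critical size.
#' @return filtered `cluster_report` (labels of removed clusters zeroed).
#' @export
apply_cluster_correction <- function(report, cluster_null) {
  k_crit <- if (inherits(cluster_null, "cluster_null")) {
    if (!is.null(report$threshold) &&
        abs(cluster_null$threshold - report$threshold) > 1e-9)
      stopf("voxel-forming threshold mismatch between report (%g) and null (%g)",
            report$threshold, cluster_null$threshold)
    cluster_null$k_crit
  } else as.numeric(cluster_null)
  keep <- report$table$k >= k_crit
  drop_ids <- report$table$cluster[!keep]
  report$table <- report$table[keep, , drop = FALSE]
  rownames(report$table) <- NULL
  report$labels[report$labels %in% drop_ids] <- 0L
  report$k_crit <- k_crit
  report
}

#' Mask clusters by group-mean significance
#'
#' One-sample right-tailed t-test of the favoured group's corrected-z
#' maps at each voxel; voxels with p >= `p_threshold` are removed and the
#' surviving voxels are re-clustered (same threshold and connectivity).
#'
#' @param report a `cluster_report`.
#' @param group_maps list of 3D corrected-z arrays (the favoured group).
#' @param p_threshold one-sided significance level (default 0.0005).
#' @return re-measured `cluster_report` restricted to the mask.
#' @export
mask_by_group_mean <- function(report, group_maps, p_threshold = 5e-4) {
  if (length(group_maps) < 2L) stopf("need >= 2 maps to test the group mean")
  d <- dim(group_maps[[1L]])
  y <- vapply(group_maps, function(m) as.vector(m), numeric(prod(d)))
  n <- ncol(y)
  mu <- rowMeans(y)
  s <- sqrt(rowSums((y - mu)^2) / (n - 1L))
  tval <- mu / (s / sqrt(n))
  pval <- pt(tval, df = n - 1L, lower.tail = FALSE)
  pass <- array(!is.na(pval) & pval < p_threshold, d)
  masked <- report$stat
  masked[!pass | report$labels == 0L] <- NA_real_
  out <- extract_clusters(stat_map(masked, voxel_mm = report$voxel_mm,
                                   threshold = report$threshold),
                          connectivity = report$connectivity)
  out$mask_p <- p_threshold
  out
}

#' Attach anatomical labels to clusters
#'
#' For each cluster, counts voxels per region of a user-supplied label
#' volume and records the peak statistic and peak coordinate per region.
#' Sub-regions with fewer than `min_k` voxels inside the cluster are
#' dropped from the table (small encroachments).
#'
#' @param report a `cluster_report`.
#' @param label_volume integer 3D array of region codes on the same grid,
#'   or `NULL` (pass-through: report returned unchanged).
#' @param label_names optional named character vector mapping codes to
#'   region names.
#' @param min_k smallest reported sub-region size (default 5).
#' @return the report with a `regions` data.frame (cluster, label, region,
#'   k, peak, x_mm, y_mm, z_mm).
#' @export
label_clusters <- function(report, label_volume = NULL, label_names = NULL,
                           min_k = 5L) {
  if (is.null(label_volume)) return(report)
  if (!identical(dim(label_volume), dim(report$labels)))
    stopf("label volume grid does not match the statistic grid")
  d <- dim(report$labels)
  rows <- list()
  for (cl in report$table$cluster) {
    vox <- which(report$labels == cl)
    codes <- label_volume[vox]
    for (code in sort(unique(codes))) {
      sub <- vox[codes == code]
      if (length(sub) < min_k) next
      peak_at <- sub[which.max(report$stat[sub])]
      ijk <- arrayInd(peak_at, d)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, label = code,
        region = if (!is.null(label_names) &&
                     as.character(code) %in% names(label_names))
          unname(label_names[as.character(code)]) else as.character(code),
        k = length(sub), peak = report$stat[peak_at],
        x_mm = axis_coords(d[1L], report$voxel_mm[1L])[ijk[1L]],
        y_mm = axis_coords(d[2L], report$voxel_mm[2L])[ijk[2L]],
        z_mm = axis_coords(d[3L], report$voxel_mm[3L])[ijk[3L]])
    }
  }
  report$regions <- if (length(rows)) do.call(rbind, rows)
  else data.frame(cluster = integer(0), label = integer(0),
                  region = character(0), k = integer(0), peak = numeric(0),
                  x_mm = numeric(0), y_mm = numeric(0), z_mm = numeric(0))
  report
}
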