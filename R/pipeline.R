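# End-to-end orchestration: a single configuration object carrying the
# analysis constants, a staged runner writing artifacts plus a
# machine-readable manifest, and a small command-line front end.

#' Pipeline configuration
#'
#' Defaults equal the reference analysis constants: 4 discarded samples
#' per run, 1000 df pairs, one-tailed alpha 0.01 with voxel-forming
#' z = 2.32, cluster p 0.001 from 10000 null images, ACF averaged over 10
#' runs, group-mean mask p 0.0005, 18-connectivity, polynomial degree 5.
#'
#' @param ... overrides of any default (unknown names are an error).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # stage toggles
    run_simulate = TRUE, run_symmetrize = FALSE, run_vmhc = TRUE,
    run_group = TRUE, run_morpho = TRUE,
    # synthetic data
    grid_shape = c(16L, 16L, 16L), voxel_size_mm = 2, n_timepoints = 702L,
    tr_s = 2, ar_coefficient = 0.3, baseline_rho = 0.2,
    effect_delta_rho = 0.3, effect_block = 5L, n_subjects_per_group = 10L,
    smoothing_fwhm_mm = 0,
    # analysis constants
    n_discard = 4L, n_pairs = 1000L, alpha = 0.01, voxel_z = 2.32,
    cluster_p = 0.001, n_null_images = 10000L, acf_runs = 10L,
    mask_p = 5e-4, connectivity = 18L, degree = 5L, n_restarts = 5L,
    tail = "A_gt_B",
    # misc
    seed = 1L, out_dir = "vmhc-out")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stopf("unknown configuration field(s): %s",
          paste(unknown, collapse = ", "))
  structure(modifyList(cfg, dots), class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' @param path JSON file.
#' @param config a `pipeline_config`.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, j)
}

#' Run the full synthetic-data pipeline
#'
#' Executes the enabled stages — simulate, symmetrize, vmhc (per-subject
#' symmetry maps with study-level effective df), group (directional
#' t-map, phase-scrambled ACF null, Monte-Carlo cluster correction,
#' group-mean masking, effect sizes), morpho (callosal statistics) — and
#' writes artifacts plus a JSON manifest with parameters, seeds, package
#' version and per-file MD5 hashes.  Re-running with the same
#' configuration reproduces identical artifact hashes.
#'
#' @param config a `pipeline_config`.
#' @return (invisibly) a list with the in-memory stage results and the
#'   manifest path.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "vmhc",
                   version = as.character(utils::packageVersion("vmhc")),
                   config = unclass(config), stages = list())
  t0 <- proc.time()[["elapsed"]]
  stage_done <- function(name) {
    manifest$stages[[name]] <<- list(
      complete = TRUE,
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
    message(sprintf("[vmhc] stage '%s' complete (%.1f s total)", name,
                    proc.time()[["elapsed"]] - t0))
  }
  res <- list()
  fail <- function(name, e)
    stopf("pipeline stage '%s' failed: %s (partial outputs retained in %s)",
          name, conditionMessage(e), config$out_dir)

  # --- simulate ------------------------------------------------------
  scfg <- sim_config(grid_shape = config$grid_shape,
                     voxel_size_mm = config$voxel_size_mm,
                     n_timepoints = config$n_timepoints, tr_s = config$tr_s,
                     ar_coefficient = config$ar_coefficient,
                     smoothing_fwhm_mm = config$smoothing_fwhm_mm,
                     seed = config$seed)
  if (config$run_simulate) {
    tryCatch({
      region <- centered_block(config$grid_shape, config$effect_block)
      spec <- group_spec(config$n_subjects_per_group,
                         baseline_rho = config$baseline_rho,
                         effect_region = region,
                         effect_delta_rho = config$effect_delta_rho,
                         seed = config$seed)
      res$data <- generate_group_dataset(spec, scfg)
      res$cc_table <- generate_callosal_table(
        n_per_group = max(config$n_subjects_per_group, 4L),
        seed = config$seed)
      write_callosal_table(res$cc_table,
                           file.path(config$out_dir, "callosal_volumes.csv"))
      stage_done("simulate")
    }, error = function(e) fail("simulate", e))
  }

  # --- symmetrize ----------------------------------------------------
  if (config$run_symmetrize) {
    tryCatch({
      tpl <- generate_symmetric_template(scfg)
      res$symmetrization <- fit_symmetrization(
        tpl, degree = config$degree, n_restarts = config$n_restarts,
        seed = config$seed)
      write_warp(res$symmetrization$warp,
                 file.path(config$out_dir, "symmetrization_warp.json"))
      stage_done("symmetrize")
    }, error = function(e) fail("symmetrize", e))
  }

  # --- vmhc ----------------------------------------------------------
  if (config$run_vmhc) {
    tryCatch({
      dfs <- vapply(c(res$data$A, res$data$B), function(s)
        estimate_effective_df(s, n_pairs = config$n_pairs,
                              seed = config$seed)$df, numeric(1))
      res$df <- mean(dfs)
      res$maps_A <- lapply(res$data$A, function(s)
        symmetry_map(s, df = res$df)$z)
      res$maps_B <- lapply(res$data$B, function(s)
        symmetry_map(s, df = res$df)$z)
      write_volume(volume_grid(res$maps_A[[1L]], config$voxel_size_mm),
                   file.path(config$out_dir, "subjectA01_z.nii"))
      jsonlite::write_json(list(df = res$df, n_pairs = config$n_pairs,
                                N = config$n_timepoints,
                                seed = config$seed),
                           file.path(config$out_dir, "effective_df.json"),
                           digits = NA, auto_unbox = TRUE)
      stage_done("vmhc")
    }, error = function(e) fail("vmhc", e))
  }

  # --- group ---------------------------------------------------------
  if (config$run_group) {
    tryCatch({
      res$group <- group_contrast(
        res$data$A, res$data$B, res$maps_A, res$maps_B, df = res$df,
        tail = config$tail, voxel_z = config$voxel_z,
        cluster_p = config$cluster_p, n_null_images = config$n_null_images,
        acf_runs = config$acf_runs, mask_p = config$mask_p,
        connectivity = config$connectivity, voxel_mm = config$voxel_size_mm,
        seed = config$seed)
      write_cluster_table(res$group$clusters,
                          file.path(config$out_dir, "clusters.tsv"))
      jsonlite::write_json(
        list(k_crit = res$group$cluster_null$k_crit,
             n_images = res$group$cluster_null$n_images,
             threshold = config$voxel_z, cluster_p = config$cluster_p,
             n_null_clusters = length(res$group$cluster_null$sizes)),
        file.path(config$out_dir, "cluster_null.json"),
        digits = NA, auto_unbox = TRUE)
      stage_done("group")
    }, error = function(e) fail("group", e))
  }

  # --- morpho --------------------------------------------------------
  if (config$run_morpho) {
    tryCatch({
      summ <- regroup_segments(res$cc_table)
      res$morpho <- list(
        posterior = cc_group_test(summ, "posterior", "A_gt_B"),
        anterior = cc_group_test(summ, "anterior", "A_gt_B"),
        correlation = cc_brain_correlation(summ))
      mt <- data.frame(
        test = c("posterior_A_gt_B", "anterior_A_gt_B", "cc_brain_r"),
        statistic = c(res$morpho$posterior$t, res$morpho$anterior$t,
                      res$morpho$correlation$r),
        p = c(res$morpho$posterior$p, res$morpho$anterior$p,
              res$morpho$correlation$p))
      utils::write.table(mt, file.path(config$out_dir, "morphometry.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      stage_done("morpho")
    }, error = function(e) fail("morpho", e))
  }

  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$artifacts <- lapply(stats::setNames(files, basename(files)),
                               function(f) unname(tools::md5sum(f)))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, digits = NA,
                       auto_unbox = TRUE)
  invisible(c(res, list(manifest = manifest, manifest_path = manifest_path)))
}

# A mirror-symmetric block of side `side` planted off-centre in the left
# hemisphere (plus its mirror image).
centered_block <- function(grid_shape, side) {
  d <- as.integer(grid_shape)
  side <- as.integer(side)
  x0 <- max(1L, d[1L] %/% 4L - side %/% 2L + 1L)
  y0 <- (d[2L] - side) %/% 2L + 1L
  z0 <- (d[3L] - side) %/% 2L + 1L
  idx <- as.matrix(expand.grid(x = x0:(x0 + side - 1L),
                               y = y0:(y0 + side - 1L),
                               z = z0:(z0 + side - 1L)))
  mask <- array(FALSE, d)
  mask[idx] <- TRUE
  mask | flip_x(mask)
}

#' Two-group contrast with full cluster-extent correction
#'
#' The group-inference stage as one call: directional t-map on the
#' corrected-z maps, conversion to the z scale, surrogate null t-maps
#' from flipped phase-scrambled series, spatial-ACF kernel averaged over
#' `acf_runs` runs, Monte-Carlo cluster-size null, cluster-extent
#' correction, and group-mean masking of the surviving clusters.
#'
#' @param series_A,series_B per-subject series (for the surrogate null).
#' @param maps_A,maps_B per-subject corrected-z maps.
#' @param df study-level effective degrees of freedom.
#' @param tail tested direction.
#' @param voxel_z voxel-forming z threshold.
#' @param cluster_p cluster-size significance level.
#' @param n_null_images Monte-Carlo images for the cluster null.
#' @param acf_runs surrogate runs averaged into the ACF kernel.
#' @param mask_p group-mean mask significance level.
#' @param connectivity cluster connectivity.
#' @param voxel_mm voxel size, mm.
#' @param seed integer seed.
#' @return list: `tmap` (z-scale `stat_map`), `cluster_null`,
#'   `clusters` (final masked `cluster_report`), `clusters_unmasked`,
#'   `effect_size` (from [cohens_d_map()]).
#' @export
group_contrast <- function(series_A, series_B, maps_A, maps_B, df,
                           tail = "A_gt_B", voxel_z = 2.32,
                           cluster_p = 0.001, n_null_images = 10000L,
                           acf_runs = 10L, mask_p = 5e-4,
                           connectivity = 18L, voxel_mm = 1, seed = 1L) {
  tmap <- tmap_to_zmap(two_sample_tmap(maps_A, maps_B, tail = tail,
                                       voxel_mm = voxel_mm,
                                       threshold = voxel_z))
  null_maps <- lapply(seq_len(acf_runs), function(k)
    null_symmetry_tmap(series_A, series_B, df = df,
                       seed = seed + 1000L * k, tail = tail,
                       threshold = voxel_z))
  kern <- estimate_acf_kernel(null_maps)
  cnull <- simulate_cluster_null(kern, threshold = voxel_z,
                                 n_images = n_null_images,
                                 cluster_p = cluster_p,
                                 connectivity = connectivity,
                                 seed = seed + 77L)
  rep0 <- extract_clusters(tmap, connectivity = connectivity)
  rep1 <- apply_cluster_correction(rep0, cnull)
  favoured <- if (tail == "A_gt_B") maps_A else maps_B
  rep2 <- mask_by_group_mean(rep1, favoured, p_threshold = mask_p)
  rep2 <- apply_cluster_correction(rep2, cnull)
  list(tmap = tmap, cluster_null = cnull, clusters = rep2,
       clusters_unmasked = rep1,
       effect_size = cohens_d_map(maps_A, maps_B, voxel_mm = voxel_mm))
}

#' Write a cluster table as TSV
#'
#' Columns mirror the usual reporting layout: cluster, region (if
#' labelled), k, peak statistic and peak coordinates in mm.
#'
#' @param report a `cluster_report`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(report, path) {
  tab <- if (!is.null(report$regions)) report$regions else report$table
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `symmetrize`, `vmhc`, `group`, `morpho`,
#' `run`.  Each takes `--config config.json` (see
#' [write_pipeline_config()]) plus optional `--seed` and `--out`
#' overrides; stages other than the named one are toggled off (the `run`
#' subcommand enables all).  Installed alongside the package as
#' `inst/cli/vmhc`.
#'
#' @param args character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly.
#' @export
vmhc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: vmhc <simulate|symmetrize|vmhc|group|morpho|run>",
                 "[--config FILE] [--seed S] [--out DIR]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  sub <- args[[1L]]
  stages <- c("simulate", "symmetrize", "vmhc", "group", "morpho")
  if (!sub %in% c(stages, "run")) { message(usage); return(invisible(1L)) }
  opt <- list(config = NULL, seed = NULL, out = NULL)
  rest <- args[-1L]
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[[i]])
    if (!key %in% names(opt) || i == length(rest))
      stopf("unrecognized or incomplete option '%s'\n%s", rest[[i]], usage)
    opt[[key]] <- rest[[i + 1L]]
    i <- i + 2L
  }
  cfg <- if (is.null(opt$config)) pipeline_config()
         else read_pipeline_config(opt$config)
  if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
  if (!is.null(opt$out)) cfg$out_dir <- opt$out
  if (sub != "run") {
    for (st in stages)
      cfg[[paste0("run_", st)]] <- st == sub ||
        (sub %in% c("vmhc", "group", "morpho") && st == "simulate") ||
        (sub == "group" && st == "vmhc")
  } else {
    for (st in stages) cfg[[paste0("run_", st)]] <- TRUE
  }
  run_pipeline(cfg)
  invisible(0L)
}
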