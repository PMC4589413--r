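# Corpus-callosum volume statistics: regrouping of the five FreeSurfer
# segments into posterior/anterior sections, allometric normalization by
# the two-thirds power of total brain volume, directional group tests,
# and the CC-brain volume correlation.

seg_cols <- c("cc_posterior", "cc_midposterior", "cc_central",
              "cc_midanterior", "cc_anterior")

#' Regroup the five callosal segments into two sections
#'
#' Posterior section = posterior + mid-posterior + central; anterior
#' section = mid-anterior + anterior.  Accepts the full per-subject table
#' (as written by [generate_callosal_table()] or
#' [read_callosal_table()]).
#'
#' @param records data.frame with columns `subject_id`, `group`, the five
#'   segment columns and `brain_volume` (mm^3, all strictly positive).
#' @return a `callosal_summary` data.frame: subject_id, group, posterior,
#'   anterior, total_cc, brain_volume, rel_posterior, rel_anterior (the
#'   relative sizes, section / brain^(2/3)).
#' @export
regroup_segments <- function(records) {
  need <- c("subject_id", "group", seg_cols, "brain_volume")
  miss <- setdiff(need, names(records))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  seg <- as.matrix(records[, seg_cols])
  if (any(!is.finite(seg)) || any(seg <= 0) ||
      any(records$brain_volume <= 0))
    stopf("all segment and brain volumes must be strictly positive")
  posterior <- rowSums(seg[, 1:3, drop = FALSE])
  anterior <- rowSums(seg[, 4:5, drop = FALSE])
  out <- data.frame(subject_id = records$subject_id,
                    group = records$group,
                    posterior = posterior, anterior = anterior,
                    total_cc = posterior + anterior,
                    brain_volume = records$brain_volume,
                    stringsAsFactors = FALSE)
  out$rel_posterior <- relative_callosal_size(out$posterior, out$brain_volume)
  out$rel_anterior <- relative_callosal_size(out$anterior, out$brain_volume)
  class(out) <- c("callosal_summary", "data.frame")
  out
}

#' Relative callosal size
#'
#' Section volume divided by total brain volume to the two-thirds power —
#' the allometric normalization under which a cross-sectional (area-like)
#' quantity is compared across head sizes.  Note the ratio is not
#' dimensionless: under isotropic scaling of the whole head by s (all
#' volumes times s^3) the relative size scales by s.
#'
#' @param section_volume section volume(s), mm^3.
#' @param brain_volume total brain volume(s), mm^3, strictly positive.
#' @return section_volume / brain_volume^(2/3).
#' @export
relative_callosal_size <- function(section_volume, brain_volume) {
  if (any(brain_volume <= 0)) stopf("brain volume must be positive")
  section_volume / brain_volume^(2 / 3)
}

#' Directional group test on a callosal section
#'
#' One-tailed two-sample t-test on the relative section sizes, in the
#' stated direction, plus the percent difference of the group means
#' (computed as (mean A - mean B) / mean B * 100 for direction A > B).
#'
#' @param summaries a `callosal_summary` with exactly two groups.
#' @param section `"posterior"` or `"anterior"`.
#' @param contrast `"A_gt_B"` or `"B_gt_A"`; group labels are taken in
#'   sorted order unless `groups` names them explicitly.
#' @param groups optional character vector of length 2 naming (A, B).
#' @param var_equal pooled variance (default TRUE) or Welch.
#' @return list: `t`, `df`, `p` (one-tailed), `percent_difference`,
#'   `section`, `contrast`, group means.
#' @export
cc_group_test <- function(summaries, section = c("posterior", "anterior"),
                          contrast = c("A_gt_B", "B_gt_A"), groups = NULL,
                          var_equal = TRUE) {
  section <- match.arg(section)
  contrast <- match.arg(contrast)
  col <- paste0("rel_", section)
  if (is.null(groups)) groups <- sort(unique(summaries$group))
  if (length(groups) != 2L) stopf("need exactly two groups")
  if (contrast == "B_gt_A") groups <- rev(groups)
  xa <- summaries[[col]][summaries$group == groups[1L]]
  xb <- summaries[[col]][summaries$group == groups[2L]]
  if (length(xa) < 2L || length(xb) < 2L)
    stopf("need at least 2 subjects per group")
  if (sd(xa) == 0 && sd(xb) == 0) stopf("degenerate (zero-variance) data")
  tt <- t.test(xa, xb, alternative = "greater", var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       percent_difference = (mean(xa) - mean(xb)) / mean(xb) * 100,
       section = section, contrast = contrast,
       mean_favoured = mean(xa), mean_other = mean(xb))
}

#' Correlation between total callosal and total brain volume
#'
#' Pearson correlation (raw volumes) with a two-sided p-value.
#'
#' @param summaries a `callosal_summary` (>= 4 subjects).
#' @return list with `r`, `p`, `n`.
#' @export
cc_brain_correlation <- function(summaries) {
  x <- summaries$total_cc
  y <- summaries$brain_volume
  if (length(x) < 4L) stopf("need at least 4 subjects")
  if (sd(x) == 0 || sd(y) == 0) stopf("zero variance")
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
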