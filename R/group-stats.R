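#' Per-analyte level comparison between outcome groups
#'
#' Compares each analyte's concentration between two outcome groups by the
#' two-sided Wilcoxon rank-sum test (exact when group sizes permit and there
#' are no ties, normal approximation with continuity and tie correction
#' otherwise), without multiple-comparison correction. Medians and ranges are
#' reported on the raw concentration scale. If gestational ages are supplied,
#' a GA-corrected p-value is computed by rank-sum testing the standardized GA
#' regression residuals ([residualize()]).
#'
#' @param matrix a `timepoint_matrix` of log10 concentrations.
#' @param group_labels two-level factor/character of group membership, named
#'   by subject_id or aligned with matrix rows.
#' @param ga optional gestational ages for the corrected comparison.
#' @param outcome_group which label is the outcome ("up"/"down" direction is
#'   relative to it); default the first level encountered.
#' @return data.frame with per-analyte medians and ranges per group (raw
#'   units), `p_raw`, `p_corrected` (NA without `ga`) and `direction`
#'   (`"up"`/`"down"` in the outcome group).
#' @export
wilcoxon_levels <- function(matrix, group_labels, ga = NULL,
                            outcome_group = NULL) {
  m <- unclass(matrix)
  if (!is.null(names(group_labels))) group_labels <- group_labels[rownames(m)]
  if (length(group_labels) != nrow(m))
    stopf("group_labels must cover every matrix subject")
  g <- as.character(group_labels)
  lev <- unique(g)
  if (length(lev) != 2) stopf("exactly two outcome groups are required")
  outcome_group <- outcome_group %||% lev[1]
  if (!outcome_group %in% lev) stopf("unknown outcome group '%s'", outcome_group)
  other <- setdiff(lev, outcome_group)
  inA <- g == outcome_group
  if (!any(inA) || all(inA)) stopf("one outcome group is empty")
  if (nrow(m) < 4) stopf("need at least 4 subjects in total")

  res <- NULL
  if (!is.null(ga)) {
    fits <- fit_ga_regressions(matrix, ga)
    res <- residualize(matrix, fits, ga)
  }
  rows <- lapply(colnames(m), function(a) {
    raw <- 10^m[, a]
    pr <- suppressWarnings(
      stats::wilcox.test(m[inA, a], m[!inA, a], exact = NULL, correct = TRUE)$p.value)
    pc <- if (is.null(res)) NA_real_ else suppressWarnings(
      stats::wilcox.test(res[inA, a], res[!inA, a], exact = NULL,
                         correct = TRUE)$p.value)
    medA <- stats::median(raw[inA]); medB <- stats::median(raw[!inA])
    data.frame(analyte = a,
               median_outcome = medA, min_outcome = min(raw[inA]),
               max_outcome = max(raw[inA]),
               median_reference = medB, min_reference = min(raw[!inA]),
               max_reference = max(raw[!inA]),
               p_raw = pr, p_corrected = pc,
               direction = if (medA >= medB) "up" else "down",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "outcome_group") <- outcome_group
  attr(out, "reference_group") <- other
  out
}

#' Two-sided Fisher's exact test on a 2x2 count table
#'
#' Exact test for count data at fixed margins; the two-sided p-value is the
#' sum of hypergeometric point probabilities not exceeding that of the
#' observed table (the standard two-sided convention).
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(3, 28, 0, 17), 2, byrow = TRUE))
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) stopf("table must be 2x2")
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab)))
    stopf("counts must be nonnegative integers")
  if (sum(tab) == 0) stopf("table has no observations")
  stats::fisher.test(tab)$p.value
}
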