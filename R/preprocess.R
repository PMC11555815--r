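#' Replace below-detection-limit values by LOD/8
#'
#' Each record flagged `below_lod` receives the value
#' `detection_limit / 8` for its analyte and status `imputed_lod`; all other
#' records are returned unchanged. High out-of-range statuses are not handled
#' (none occur in the assays this pipeline targets) and raise an error if
#' present.
#'
#' @param panel long-format measurement panel (columns `subject_id`,
#'   `analyte`, `day`, `value`, `status`).
#' @param analytes analyte table with `name` and `detection_limit`.
#' @return The panel with below-LOD records imputed.
#' @export
replace_below_lod <- function(panel, analytes) {
  if (any(panel$status == "high_oor"))
    stopf("high out-of-range records are not supported")
  idx <- which(panel$status == "below_lod")
  if (!length(idx)) return(panel)
  dl <- analytes$detection_limit[match(panel$analyte[idx], analytes$name)]
  if (anyNA(dl)) {
    bad <- unique(panel$analyte[idx][is.na(dl)])
    stopf("no detection limit available for analyte(s): %s",
          paste(bad, collapse = ", "))
  }
  panel$value[idx] <- dl / 8
  panel$status[idx] <- "imputed_lod"
  panel
}

#' Log10-transform panel concentrations
#'
#' Replaces every present value by its log10; statuses are preserved and the
#' panel is marked as being on the log10 scale.
#'
#' @param panel measurement panel with raw-scale values.
#' @return The panel with `value = log10(value)` and attribute
#'   `scale = "log10"`.
#' @export
log_transform <- function(panel) {
  if (identical(attr(panel, "scale"), "log10"))
    stopf("panel is already log10-transformed")
  present <- !is.na(panel$value)
  if (any(panel$value[present] <= 0)) {
    k <- which(present & panel$value <= 0)[1]
    stopf("non-positive value for subject %s, analyte %s, day %s",
          panel$subject_id[k], panel$analyte[k], panel$day[k])
  }
  panel$value[present] <- log10(panel$value[present])
  attr(panel, "scale") <- "log10"
  panel
}

#' Interpolate missing samples between neighbouring timepoints
#'
#' For each `missing` record whose subject-analyte series has a present log
#' value at a nearest earlier day `t0` and a nearest later day `t1`, fills the
#' record with the linear-in-day interpolation of the two log values (i.e.
#' geometric interpolation on the raw scale) and status `interpolated`.
#' Missing records at the first or last sampled day remain missing.
#'
#' @param panel a log10-transformed panel.
#' @return list with `panel` (interpolated) and `n_interpolated` (count of
#'   records filled).
#' @export
interpolate_missing <- function(panel) {
  if (!identical(attr(panel, "scale"), "log10"))
    stopf("panel must be log10-transformed before interpolation")
  n_int <- 0L
  miss <- which(panel$status == "missing")
  if (length(miss)) {
    key <- paste(panel$subject_id, panel$analyte, sep = "\r")
    for (k in miss) {
      series <- which(key == key[k] & !is.na(panel$value))
      if (!length(series)) next
      d <- panel$day[series]
      before <- series[d < panel$day[k]]
      after <- series[d > panel$day[k]]
      if (!length(before) || !length(after)) next
      k0 <- before[which.max(panel$day[before])]
      k1 <- after[which.min(panel$day[after])]
      t0 <- panel$day[k0]; t1 <- panel$day[k1]
      w <- (panel$day[k] - t0) / (t1 - t0)
      panel$value[k] <- panel$value[k0] + w * (panel$value[k1] - panel$value[k0])
      panel$status[k] <- "interpolated"
      n_int <- n_int + 1L
    }
  }
  list(panel = panel, n_interpolated = n_int)
}

#' Exclude analytes that are mostly below the detection limit in any subgroup
#'
#' An analyte is excluded when, in at least one subgroup, strictly more than
#' `threshold` of its measured values (statuses `below_lod` or `imputed_lod`
#' among non-missing records) are below the detection limit. Apply per
#' analysis timepoint by passing a panel restricted to that timepoint's days.
#'
#' @param panel measurement panel (any scale).
#' @param subgroups named vector mapping every panel subject_id to a subgroup
#'   label (e.g. the outcome grouping under analysis).
#' @param threshold exclusion threshold in (0, 1); default 3/4.
#' @return list with `panel` (excluded analytes removed) and `excluded`
#'   (character vector of analyte names).
#' @export
exclude_sparse_analytes <- function(panel, subgroups, threshold = 3 / 4) {
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0, 1)")
  subj <- unique(panel$subject_id)
  if (!all(subj %in% names(subgroups)))
    stopf("subgroups must cover every panel subject")
  sg <- subgroups[subj]
  counts <- table(sg)  # factor inputs keep declared (possibly empty) levels
  if (any(counts == 0)) stopf("empty subgroup: %s",
                              paste(names(counts)[counts == 0], collapse = ", "))
  grp_of_row <- subgroups[panel$subject_id]
  measured <- panel$status != "missing"
  lodish <- panel$status %in% c("below_lod", "imputed_lod")
  excluded <- character(0)
  for (a in unique(panel$analyte)) {
    rows <- measured & panel$analyte == a
    if (!any(rows)) next
    prop <- tapply(lodish[rows], grp_of_row[rows], mean)
    if (any(prop > threshold, na.rm = TRUE)) excluded <- c(excluded, a)
  }
  list(panel = panel[!(panel$analyte %in% excluded), , drop = FALSE],
       excluded = excluded)
}

#' First-month summary: AUC/time over days 7-28
#'
#' Summarises each subject-analyte series over the given days by the
#' trapezoidal area under the raw concentration-versus-day curve divided by
#' the day span, then log10-transformed ("average concentration" over the
#' first month). Subject-analytes with any absent value among the required
#' days are omitted from the output (they will later fail the complete-case
#' rule).
#'
#' @param panel log10-transformed panel (interpolation already applied).
#' @param days the days integrated over; default `c(7, 14, 28)`.
#' @return data.frame `subject_id`, `analyte`, `value` (log10 of AUC/time),
#'   `status = "summary"`, with attribute `scale = "log10"`.
#' @export
first_month_summary <- function(panel, days = c(7, 14, 28)) {
  if (length(days) < 2) stopf("need at least 2 days to integrate over")
  if (!identical(attr(panel, "scale"), "log10"))
    stopf("panel must be log10-transformed before summarisation")
  days <- sort(days)
  sub <- panel[panel$day %in% days & !is.na(panel$value), , drop = FALSE]
  key <- paste(sub$subject_id, sub$analyte, sep = "\r")
  keep <- names(which(table(key) == length(days)))
  sub <- sub[key %in% keep, , drop = FALSE]
  if (!nrow(sub)) {
    out <- data.frame(subject_id = character(0), analyte = character(0),
                      value = numeric(0), status = character(0))
    attr(out, "scale") <- "log10"
    return(out)
  }
  o <- order(sub$subject_id, sub$analyte, sub$day)
  sub <- sub[o, , drop = FALSE]
  raw <- matrix(10^sub$value, ncol = length(days), byrow = TRUE)
  w <- diff(days)
  auc <- as.vector((raw[, -length(days), drop = FALSE] +
                      raw[, -1, drop = FALSE]) %*% (w / 2))
  first <- seq(1, nrow(sub), by = length(days))
  out <- data.frame(subject_id = sub$subject_id[first],
                    analyte = sub$analyte[first],
                    value = log10(auc / (max(days) - min(days))),
                    status = "summary",
                    stringsAsFactors = FALSE)
  attr(out, "scale") <- "log10"
  out
}

#' Assemble a complete-case subjects-by-analytes matrix
#'
#' Retains only subjects with a present value for every analyte at the
#' required day(s) and returns the log10 values as a matrix (subjects in
#' rows, analytes in columns).
#'
#' @param panel log10-transformed panel, or a [first_month_summary()] output.
#' @param timepoint_label label attached to the matrix, e.g. `"cord"`,
#'   `"day_one"`, `"first_month"`.
#' @param days day(s) defining the timepoint; `NULL` for a summary input
#'   (one value per subject-analyte).
#' @return A `timepoint_matrix`: numeric matrix with subject_id rownames,
#'   analyte colnames, and a `timepoint_label` attribute.
#' @export
complete_case <- function(panel, timepoint_label, days = NULL) {
  if (!identical(attr(panel, "scale"), "log10"))
    stopf("panel must be log10-transformed")
  if (!is.null(days)) panel <- panel[panel$day %in% days, , drop = FALSE]
  analytes <- unique(panel$analyte)
  if (length(analytes) < 2) stopf("need at least 2 analytes")
  subjects <- unique(panel$subject_id)
  ok <- vapply(subjects, function(s) {
    rows <- panel[panel$subject_id == s & !is.na(panel$value), , drop = FALSE]
    all(analytes %in% rows$analyte) &&
      !anyNA(rows$value[match(analytes, rows$analyte)])
  }, logical(1))
  kept <- subjects[ok]
  if (length(kept) < 4)
    stopf("fewer than 4 complete-case subjects at timepoint '%s'",
          timepoint_label)
  m <- matrix(NA_real_, length(kept), length(analytes),
              dimnames = list(kept, analytes))
  sub <- panel[panel$subject_id %in% kept & !is.na(panel$value), , drop = FALSE]
  m[cbind(match(sub$subject_id, kept), match(sub$analyte, analytes))] <- sub$value
  if (anyNA(m)) stopf("internal error: incomplete matrix after complete-case")
  structure(m, timepoint_label = timepoint_label, class = c("timepoint_matrix", "matrix"))
}

#' One-call preprocessing of a raw panel to a timepoint matrix
#'
#' Applies, in order: LOD/8 imputation, log10 transform, linear-in-day
#' interpolation of missing samples, sparse-analyte exclusion within the
#' given subgrouping, then either direct day extraction (`cord`, `day_one`)
#' or first-month AUC/time summarisation, and finally the complete-case rule.
#'
#' @param panel raw-scale measurement panel.
#' @param analytes analyte table with detection limits.
#' @param subgroups named subject -> subgroup vector for the exclusion rule
#'   (typically the outcome grouping under analysis).
#' @param timepoint one of `"cord"` (day 0), `"day_one"` (day 1) or
#'   `"first_month"` (AUC/time over days 7, 14, 28).
#' @param threshold sparse-analyte exclusion threshold (default 3/4).
#' @return list with `matrix` (a `timepoint_matrix`), `excluded` analytes and
#'   `n_interpolated`.
#' @export
preprocess_panel <- function(panel, analytes, subgroups,
                             timepoint = c("cord", "day_one", "first_month"),
                             threshold = 3 / 4) {
  timepoint <- match.arg(timepoint)
  panel <- replace_below_lod(panel, analytes)
  panel <- log_transform(panel)
  ip <- interpolate_missing(panel)
  days <- switch(timepoint, cord = 0L, day_one = 1L, first_month = c(7L, 14L, 28L))
  tp_panel <- ip$panel[ip$panel$day %in% days, , drop = FALSE]
  attr(tp_panel, "scale") <- "log10"
  ex <- exclude_sparse_analytes(tp_panel, subgroups, threshold)
  if (timepoint == "first_month") {
    summ <- first_month_summary(ex$panel, days = days)
    m <- complete_case(summ, timepoint)
  } else {
    m <- complete_case(ex$panel, timepoint, days = days)
  }
  list(matrix = m, excluded = ex$excluded, n_interpolated = ip$n_interpolated)
}
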