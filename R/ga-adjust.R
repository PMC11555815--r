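#' Per-analyte linear regression on gestational age
#'
#' Fits, for every analyte column, an ordinary least-squares regression of
#' log10 concentration on gestational age across all subjects in the matrix
#' (both outcome groups pooled), the basis for confound removal by
#' residualization.
#'
#' @param matrix a `timepoint_matrix` (subjects x analytes, log10 scale).
#' @param ga gestational ages in weeks, either named by subject_id or aligned
#'   with the matrix rows.
#' @return data.frame of class `ga_fits`: `analyte`, `intercept`, `slope`
#'   (log10 units per week), `residual_sd`, `n`.
#' @export
fit_ga_regressions <- function(matrix, ga) {
  ga <- align_ga(matrix, ga)
  if (nrow(matrix) < 3) stopf("need at least 3 subjects to fit GA regressions")
  if (length(unique(ga)) < 3) stopf("need at least 3 distinct GA values")
  if (stats::sd(ga) == 0) stopf("GA is constant; slope unidentifiable")
  X <- cbind(1, ga)
  fits <- apply(matrix, 2, function(y) {
    f <- stats::lm.fit(X, y)
    c(intercept = unname(f$coefficients[1]), slope = unname(f$coefficients[2]),
      residual_sd = stats::sd(f$residuals))
  })
  out <- data.frame(analyte = colnames(matrix),
                    intercept = fits["intercept", ],
                    slope = fits["slope", ],
                    residual_sd = fits["residual_sd", ],
                    n = nrow(matrix),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("ga_fits", "data.frame")
  out
}

#' Standardized residuals after gestational-age regression
#'
#' Subtracts each analyte's fitted GA regression line and divides by the
#' sample SD of the residuals, yielding a dimensionless residual matrix with
#' unit column SDs and (by OLS orthogonality) zero correlation with GA. If a
#' column fits exactly (all residuals zero), a zero column is returned.
#'
#' @param matrix a `timepoint_matrix`.
#' @param fits `ga_fits` from [fit_ga_regressions()] covering all matrix
#'   analytes.
#' @param ga gestational ages as in [fit_ga_regressions()].
#' @return A `residual_matrix` (same shape and dimnames as `matrix`).
#' @export
residualize <- function(matrix, fits, ga) {
  ga <- align_ga(matrix, ga)
  miss <- setdiff(colnames(matrix), fits$analyte)
  if (length(miss))
    stopf("fits do not cover analyte(s): %s", paste(miss, collapse = ", "))
  out <- matrix
  for (a in colnames(matrix)) {
    k <- match(a, fits$analyte)
    r <- matrix[, a] - fits$intercept[k] - fits$slope[k] * ga
    s <- stats::sd(r)
    if (s < 1e-10 * max(1, max(abs(matrix[, a])))) {
      if (max(abs(r)) > 1e-8 * max(1, max(abs(matrix[, a]))))
        stopf("constant nonzero residuals for %s cannot be standardized", a)
      out[, a] <- 0
    } else {
      out[, a] <- r / s
    }
  }
  structure(out, timepoint_label = attr(matrix, "timepoint_label"),
            class = c("residual_matrix", "timepoint_matrix", "matrix"))
}

align_ga <- function(matrix, ga) {
  if (!is.null(names(ga))) {
    miss <- setdiff(rownames(matrix), names(ga))
    if (length(miss))
      stopf("GA missing for subject(s): %s", paste(miss, collapse = ", "))
    ga <- ga[rownames(matrix)]
  } else if (length(ga) != nrow(matrix)) {
    stopf("ga must be named by subject_id or match the number of subjects")
  }
  as.numeric(ga)
}
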