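#' Build a group-specific latent correlation matrix with planted edges
#'
#' Starting from a base correlation matrix, sets selected off-diagonal entries
#' to requested values ("planted" differential edges) and, if planting breaks
#' positive semidefiniteness, repairs the matrix to the nearest PSD matrix by
#' clipping negative eigenvalues at zero and rescaling the diagonal back to
#' one. If the repair moves any planted entry by more than 0.05 from its
#' requested value, a warning lists the affected edges and the moved entries
#' are recorded in the `"moved_edges"` attribute of the result.
#'
#' @param base symmetric correlation matrix with unit diagonal; dimnames give
#'   the analyte names.
#' @param planted_edges `NULL`, or a data.frame with columns `i`, `j` (analyte
#'   names) and `rho` (values in (-1, 1)).
#' @return A symmetric PSD correlation matrix with unit diagonal (minimum
#'   eigenvalue >= -1e-10).
#' @export
#' @examples
#' base <- diag(3); dimnames(base) <- list(LETTERS[1:3], LETTERS[1:3])
#' R <- make_group_correlation(base, data.frame(i = "A", j = "B", rho = 0.9))
#' R["A", "B"]
make_group_correlation <- function(base, planted_edges = NULL) {
  if (!is.matrix(base) || nrow(base) != ncol(base))
    stopf("base must be a square matrix")
  if (max(abs(base - t(base))) > 1e-8)
    stopf("base must be symmetric")
  if (max(abs(diag(base) - 1)) > 1e-8)
    stopf("base must have unit diagonal")
  nm <- rownames(base) %||% colnames(base)
  if (is.null(nm)) {
    nm <- paste0("V", seq_len(nrow(base)))
    dimnames(base) <- list(nm, nm)
  }
  M <- base
  if (!is.null(planted_edges) && nrow(as.data.frame(planted_edges)) > 0) {
    pe <- as.data.frame(planted_edges)
    if (!all(c("i", "j", "rho") %in% names(pe)))
      stopf("planted_edges needs columns i, j, rho")
    unknown <- setdiff(unique(c(pe$i, pe$j)), nm)
    if (length(unknown))
      stopf("planted edge references unknown analyte(s): %s",
            paste(unknown, collapse = ", "))
    if (any(abs(pe$rho) >= 1))
      stopf("planted |rho| must be < 1")
    for (k in seq_len(nrow(pe))) {
      M[pe$i[k], pe$j[k]] <- pe$rho[k]
      M[pe$j[k], pe$i[k]] <- pe$rho[k]
    }
  }
  R <- psd_repair(M)
  if (!is.null(planted_edges) && nrow(as.data.frame(planted_edges)) > 0) {
    pe <- as.data.frame(planted_edges)
    got <- mapply(function(i, j) R[i, j], pe$i, pe$j)
    moved <- abs(got - pe$rho) > 0.05
    if (any(moved)) {
      mv <- data.frame(i = pe$i[moved], j = pe$j[moved],
                       requested = pe$rho[moved], attained = got[moved])
      attr(R, "moved_edges") <- mv
      warnf("PSD repair moved %d planted edge(s) by more than 0.05: %s",
            sum(moved),
            paste(sprintf("%s-%s (%.2f -> %.2f)", mv$i, mv$j,
                          mv$requested, mv$attained), collapse = "; "))
    }
  }
  R
}

# Nearest-PSD repair: clip negative eigenvalues at 0, then rescale the
# diagonal to 1. Deterministic; identity on matrices that are already PSD
# with unit diagonal.
psd_repair <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (min(e$values) >= -1e-10) {
    diag(M) <- 1
    return((M + t(M)) / 2)
  }
  lam <- pmax(e$values, 0)
  R <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(pmax(diag(R), .Machine$double.eps))
  R <- R / tcrossprod(d)
  diag(R) <- 1
  dimnames(R) <- dimnames(M)
  (R + t(R)) / 2
}
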