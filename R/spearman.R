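#' Spearman correlation network for one group
#'
#' Computes all pairwise Spearman rank correlations (Pearson correlation of
#' mid-ranks, average ranks on ties) among the matrix columns, with per-edge
#' two-sided p-values from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' (`p = 0` when `|rho| = 1`). Constant columns yield undefined edges (NA rho
#' and p) with a warning.
#'
#' @param matrix a `timepoint_matrix` or `residual_matrix` (subjects x
#'   analytes); any numeric matrix with dimnames works.
#' @param group_label label of the group the network describes, e.g.
#'   `"severe_ROP"`.
#' @return An object of class `correlation_network`: list with `analytes`,
#'   `rho` and `p` (symmetric matrices), `n`, `group_label`.
#' @export
#' @examples
#' m <- cbind(a = 1:6, b = c(2, 1, 4, 3, 6, 5), c = 6:1)
#' rownames(m) <- paste0("S", 1:6)
#' net <- spearman_network(m, "demo")
#' round(net$rho, 2)
spearman_network <- function(matrix, group_label = "group") {
  m <- unclass(matrix)
  if (nrow(m) < 4) stopf("need at least 4 subjects for a network")
  if (ncol(m) < 2) stopf("need at least 2 analytes")
  n <- nrow(m)
  constant <- apply(m, 2, function(x) length(unique(x)) == 1)
  ranks <- apply(m, 2, midranks)
  rho <- suppressWarnings(stats::cor(ranks))
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  diag(rho) <- 1
  if (any(constant))
    warnf("constant column(s) yield undefined correlations: %s",
          paste(colnames(m)[constant], collapse = ", "))
  r <- pmin(pmax(rho, -1), 1)
  p <- matrix(NA_real_, ncol(m), ncol(m), dimnames = dimnames(rho))
  finite <- !is.na(r)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p[finite] <- 2 * stats::pt(-abs(tstat[finite]), df = n - 2)
  p[finite & abs(r) >= 1] <- 0
  diag(p) <- NA_real_
  structure(list(analytes = colnames(m), rho = rho, p = p, n = n,
                 group_label = group_label),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  alpha <- 0.05
  nsig <- sum(x$p[upper.tri(x$p)] < alpha, na.rm = TRUE)
  cat(sprintf("Spearman network '%s': %d analytes, n = %d, %d/%d edges with p < %.2f\n",
              x$group_label, length(x$analytes), x$n, nsig,
              sum(upper.tri(x$p)), alpha))
  invisible(x)
}
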