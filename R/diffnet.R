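#' Differential correlation network between two outcome groups
#'
#' For every unordered analyte pair, tests whether the Spearman correlation
#' differs between two groups. Three methods are available:
#'
#' * `fisher_z` (default): `z = (atanh(r_A) - atanh(r_B)) /
#'   sqrt(c/(n_A - 3) + c/(n_B - 3))` with `c = 1.06`, the Fieller variance
#'   factor for Spearman correlations, referred to a two-sided normal.
#' * `permutation`: group labels are permuted `n_resample` times;
#'   `p = (1 + #\{|drho_perm| >= |drho_obs|\}) / (n_resample + 1)`.
#' * `bootstrap_rank`: `n_resample` bootstrap resamples per group give two
#'   distributions of rho, compared by a two-sided rank-sum test. These
#'   p-values depend on `n_resample` and are flagged heuristic.
#'
#' No multiple-testing correction is applied to the `significant` flag (by
#' design of the analysis this implements); a Benjamini-Hochberg column
#' `p_diff_bh` is emitted for information only.
#'
#' @param matrix_A,matrix_B subjects x analytes matrices (same analytes) for
#'   the two groups, e.g. from [complete_case()] or [residualize()].
#' @param method `"fisher_z"`, `"permutation"` or `"bootstrap_rank"`.
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @param n_resample resamples for the resampling methods (default 2000).
#' @param seed master seed for resampling; each edge uses a deterministic
#'   substream so results do not depend on edge order.
#' @param group_labels labels of the two groups, e.g.
#'   `c("severe_ROP", "no_ROP")`.
#' @return A data.frame of class `differential_network` with one row per
#'   unordered pair (`analyte_i < analyte_j` lexicographically): `rho_A`,
#'   `p_A`, `rho_B`, `p_B`, `p_diff`, `p_diff_bh`, `significant`; attributes
#'   `alpha`, `method`, `n_A`, `n_B`, `group_labels`.
#' @export
compare_networks <- function(matrix_A, matrix_B,
                             method = c("fisher_z", "permutation", "bootstrap_rank"),
                             alpha = 0.05, n_resample = 2000, seed = 1L,
                             group_labels = c("A", "B")) {
  method <- match.arg(method)
  A <- unclass(matrix_A); B <- unclass(matrix_B)
  if (!setequal(colnames(A), colnames(B)))
    stopf("the two matrices must share the same analyte set")
  B <- B[, colnames(A), drop = FALSE]
  nA <- nrow(A); nB <- nrow(B)
  if (nA < 4 || nB < 4) {
    if (method == "fisher_z")
      stopf("fisher_z requires n > 3 in both groups (variance undefined)")
    stopf("need at least 4 subjects per group")
  }
  netA <- spearman_network(A, group_labels[1])
  netB <- spearman_network(B, group_labels[2])
  nms <- sort(colnames(A))
  pairs <- which(upper.tri(diag(length(nms))), arr.ind = TRUE)
  ai <- nms[pairs[, 1]]; aj <- nms[pairs[, 2]]
  rho_A <- netA$rho[cbind(ai, aj)]; p_A <- netA$p[cbind(ai, aj)]
  rho_B <- netB$rho[cbind(ai, aj)]; p_B <- netB$p[cbind(ai, aj)]

  p_diff <- switch(method,
    fisher_z = fisher_z_p(rho_A, rho_B, nA, nB),
    permutation = vapply(seq_along(ai), function(k) {
      permutation_edge_p(A[, ai[k]], A[, aj[k]], B[, ai[k]], B[, aj[k]],
                         n_resample, edge_seed(seed, pairs[k, 1], pairs[k, 2]))
    }, numeric(1)),
    bootstrap_rank = {
      warnf("bootstrap_rank p-values are heuristic: they depend on n_resample")
      vapply(seq_along(ai), function(k) {
        bootstrap_rank_edge_p(A[, ai[k]], A[, aj[k]], B[, ai[k]], B[, aj[k]],
                              n_resample,
                              edge_seed(seed, pairs[k, 1], pairs[k, 2]))
      }, numeric(1))
    })

  out <- data.frame(analyte_i = ai, analyte_j = aj,
                    rho_A = rho_A, p_A = p_A, rho_B = rho_B, p_B = p_B,
                    p_diff = p_diff,
                    p_diff_bh = stats::p.adjust(p_diff, method = "BH"),
                    significant = !is.na(p_diff) & p_diff < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$analyte_i, out$analyte_j), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, alpha = alpha, method = method, n_A = nA, n_B = nB,
            group_labels = group_labels,
            class = c("differential_network", "data.frame"))
}

# two-sided Fisher-z p for a Spearman correlation difference,
# Fieller variance factor c = 1.06
fisher_z_p <- function(rA, rB, nA, nB) {
  zA <- atanh(pmin(pmax(rA, -1 + 1e-12), 1 - 1e-12))
  zB <- atanh(pmin(pmax(rB, -1 + 1e-12), 1 - 1e-12))
  se <- sqrt(1.06 / (nA - 3) + 1.06 / (nB - 3))
  2 * stats::pnorm(-abs((zA - zB) / se))
}

spearman_pair <- function(x, y) stats::cor(midranks(x), midranks(y))

permutation_edge_p <- function(xA, yA, xB, yB, n_resample, seed) {
  nA <- length(xA)
  x <- c(xA, xB); y <- c(yA, yB); n <- length(x)
  d_obs <- abs(spearman_pair(xA, yA) - spearman_pair(xB, yB))
  if (is.na(d_obs)) return(NA_real_)
  with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_resample)) {
      idx <- sample.int(n)
      iA <- idx[seq_len(nA)]; iB <- idx[-seq_len(nA)]
      d <- abs(spearman_pair(x[iA], y[iA]) - spearman_pair(x[iB], y[iB]))
      if (!is.na(d) && d >= d_obs - 1e-12) hits <- hits + 1L
    }
    (1 + hits) / (n_resample + 1)
  })
}

bootstrap_rank_edge_p <- function(xA, yA, xB, yB, n_resample, seed) {
  with_seed(seed, {
    rA <- vapply(seq_len(n_resample), function(b) {
      i <- sample.int(length(xA), replace = TRUE)
      spearman_pair(xA[i], yA[i])
    }, numeric(1))
    rB <- vapply(seq_len(n_resample), function(b) {
      i <- sample.int(length(xB), replace = TRUE)
      spearman_pair(xB[i], yB[i])
    }, numeric(1))
    rA <- rA[!is.na(rA)]; rB <- rB[!is.na(rB)]
    if (!length(rA) || !length(rB)) return(NA_real_)
    suppressWarnings(stats::wilcox.test(rA, rB)$p.value)
  })
}

#' Hub ranking by summed correlation z-scores
#'
#' Ranks analytes by the total strength of their network involvement. For a
#' per-group [spearman_network()], each analyte's score is the sum of
#' `|atanh(rho)|` over its edges with `p < alpha` (the "entire network" heat
#' map; with `mode = "all"`, over all defined edges). For a
#' [compare_networks()] result, the score sums
#' `|atanh(rho_A) - atanh(rho_B)|` over the analyte's significant
#' differential edges (the "difference" heat map). Edges with `|rho| = 1`
#' contribute a capped `atanh(0.999)` with a warning.
#'
#' @param x a `correlation_network` or `differential_network`.
#' @param mode `"significant_only"` (default) or `"all"` (per-group networks
#'   only).
#' @param alpha significance level in (0, 1) used to qualify edges.
#' @return data.frame `analyte`, `z_sum`, `n_sig`, `rank`, ordered by rank
#'   (descending `z_sum`).
#' @export
hub_scores <- function(x, mode = c("significant_only", "all"), alpha = 0.05) {
  mode <- match.arg(mode)
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  if (inherits(x, "correlation_network")) {
    rho <- x$rho; p <- x$p
    diag(rho) <- NA_real_
    if (any(abs(rho) >= 1, na.rm = TRUE))
      warnf("edges with |rho| = 1 contribute the capped value atanh(0.999)")
    z <- abs(atanh(pmin(pmax(rho, -0.999), 0.999)))
    qual <- if (mode == "significant_only") !is.na(p) & p < alpha else !is.na(rho)
    diag(qual) <- FALSE
    z_sum <- rowSums(z * qual, na.rm = TRUE)
    n_sig <- rowSums(qual)
    analyte <- x$analytes
  } else if (inherits(x, "differential_network")) {
    sig <- x[x$significant & !is.na(x$significant), , drop = FALSE]
    analyte <- sort(unique(c(x$analyte_i, x$analyte_j)))
    if (any(abs(c(sig$rho_A, sig$rho_B)) >= 1, na.rm = TRUE))
      warnf("edges with |rho| = 1 contribute the capped value atanh(0.999)")
    dz <- abs(atanh(pmin(pmax(sig$rho_A, -0.999), 0.999)) -
                atanh(pmin(pmax(sig$rho_B, -0.999), 0.999)))
    z_sum <- vapply(analyte, function(a) {
      sum(dz[sig$analyte_i == a | sig$analyte_j == a], na.rm = TRUE)
    }, numeric(1))
    n_sig <- vapply(analyte, function(a) {
      sum(sig$analyte_i == a | sig$analyte_j == a)
    }, numeric(1))
  } else {
    stopf("x must be a correlation_network or differential_network")
  }
  out <- data.frame(analyte = analyte, z_sum = unname(z_sum),
                    n_sig = as.integer(unname(n_sig)),
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$z_sum, ties.method = "min")
  out[order(out$rank, out$analyte), , drop = FALSE]
}

#' Re-test differential edges within confounder strata
#'
#' For each listed edge (no new edge discovery), computes the Spearman
#' correlation separately in the two strata of a binary confounder split
#' (e.g. HCA/FIRS exposure, or a BW-SDS [median_split()]) and tests the
#' between-stratum difference with the chosen [compare_networks()] method. An
#' edge whose strata have fewer than 4 subjects is reported not-evaluable
#' (no p-value).
#'
#' @param edges a `differential_network` or data.frame with `analyte_i`,
#'   `analyte_j` (typically the significant outcome-related edges).
#' @param matrix subjects x analytes matrix covering the edge analytes.
#' @param stratum binary (0/1 or logical) per-subject labels, named by
#'   subject_id or aligned with matrix rows.
#' @param method `"fisher_z"` (default) or `"permutation"`.
#' @param alpha significance level for the `flagged` indicator.
#' @param n_resample,seed as in [compare_networks()].
#' @return data.frame with per-edge `n1`, `n0`, `rho_stratum1`,
#'   `rho_stratum0`, `p_diff`, `flagged`, `evaluable`.
#' @export
stratified_edges <- function(edges, matrix, stratum,
                             method = c("fisher_z", "permutation"),
                             alpha = 0.05, n_resample = 2000, seed = 1L) {
  method <- match.arg(method)
  m <- unclass(matrix)
  ed <- as.data.frame(edges)[, c("analyte_i", "analyte_j")]
  bad <- setdiff(unique(c(ed$analyte_i, ed$analyte_j)), colnames(m))
  if (length(bad))
    stopf("edge analyte(s) not in matrix: %s", paste(bad, collapse = ", "))
  if (!is.null(names(stratum))) {
    miss <- setdiff(rownames(m), names(stratum))
    if (length(miss))
      stopf("stratum undefined for subject(s): %s", paste(miss, collapse = ", "))
    stratum <- stratum[rownames(m)]
  } else if (length(stratum) != nrow(m)) {
    stopf("stratum must be named by subject_id or match the number of subjects")
  }
  if (!is_binary01(stratum)) stopf("stratum must be binary (0/1 or logical)")
  s1 <- as.logical(stratum)
  n1 <- sum(s1); n0 <- sum(!s1)
  out <- ed
  out$n1 <- n1; out$n0 <- n0
  out$rho_stratum1 <- NA_real_; out$rho_stratum0 <- NA_real_
  out$p_diff <- NA_real_
  out$evaluable <- n1 >= 4 & n0 >= 4
  for (k in seq_len(nrow(ed))) {
    i <- ed$analyte_i[k]; j <- ed$analyte_j[k]
    if (n1 >= 2) out$rho_stratum1[k] <- spearman_pair(m[s1, i], m[s1, j])
    if (n0 >= 2) out$rho_stratum0[k] <- spearman_pair(m[!s1, i], m[!s1, j])
    if (!out$evaluable[k]) next
    out$p_diff[k] <- if (method == "fisher_z") {
      fisher_z_p(out$rho_stratum1[k], out$rho_stratum0[k], n1, n0)
    } else {
      permutation_edge_p(m[s1, i], m[s1, j], m[!s1, i], m[!s1, j],
                         n_resample,
                         edge_seed(seed, match(i, colnames(m)),
                                   match(j, colnames(m))))
    }
  }
  out$flagged <- ifelse(out$evaluable, !is.na(out$p_diff) & out$p_diff < alpha, NA)
  rownames(out) <- NULL
  out
}

#' Median split of a continuous covariate into two strata
#'
#' Labels subjects 1 if the value is strictly above the sample median and 0
#' otherwise; values equal to the median go to the "below or equal" stratum
#' (the documented tie rule). Used for the BW-SDS growth-restriction split.
#'
#' @param values numeric per-subject values (names preserved).
#' @return Integer 0/1 labels.
#' @export
#' @examples
#' median_split(c(-2, -1, 0, 1))
median_split <- function(values) {
  if (length(values) < 2) stopf("need at least 2 subjects")
  med <- stats::median(values)
  out <- as.integer(values > med)
  names(out) <- names(values)
  out
}
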