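# Independent brute-force Spearman oracle: mid-ranks by counting, Pearson by
# explicit sums. Deliberately avoids rank() and cor().
brute_spearman <- function(x, y) {
  midrank <- function(v) {
    vapply(seq_along(v), function(i) {
      smaller <- sum(v < v[i])
      ties <- sum(v == v[i])
      smaller + (ties + 1) / 2
    }, numeric(1))
  }
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  mx <- sum(rx) / n; my <- sum(ry) / n
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  num / den
}

# minimal analyte table for fast simulations (no censoring unless asked)
tiny_analytes <- function(p = 4, lod_quantile = 0, noise_sd = 0.4,
                          ga_slope = 0, base_mean = 1) {
  data.frame(name = LETTERS[seq_len(p)],
             class = "cytokine",
             detection_limit = 1e-12,
             base_mean = base_mean, ga_slope = ga_slope,
             noise_sd = noise_sd, lod_quantile = lod_quantile,
             stringsAsFactors = FALSE)
}

# a small hand-built raw-scale panel
demo_panel <- function() {
  data.frame(
    subject_id = rep(c("S1", "S2"), each = 3),
    analyte = rep("A", 6),
    day = rep(c(7L, 14L, 28L), 2),
    value = c(4, NA, 16, 10, 10, 40),
    status = c("observed", "missing", "observed",
               "observed", "observed", "observed"),
    stringsAsFactors = FALSE
  )
}

# two group matrices with a latent Gaussian correlation rho on edge (X, Y)
# in group A and independence in group B; extra independent columns optional
latent_pair_matrices <- function(rho, n, seed, extra = 0) {
  dcornet:::with_seed(seed, {
    p <- 2 + extra
    zA <- matrix(rnorm(n * p), n, p)
    zB <- matrix(rnorm(n * p), n, p)
    zA[, 2] <- rho * zA[, 1] + sqrt(1 - rho^2) * zA[, 2]
    nms <- c("X", "Y", if (extra > 0) paste0("N", seq_len(extra)))
    dimnames(zA) <- list(paste0("a", seq_len(n)), nms)
    dimnames(zB) <- list(paste0("b", seq_len(n)), nms)
    list(A = zA, B = zB)
  })
}
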