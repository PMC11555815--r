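test_that("Spearman rho is exact on monotone, reversed and worked examples", {
  x <- c(0.2, 1.1, 2.5, 3.7, 5.2, 8.8)
  m <- cbind(a = x, b = x^3, c = -x)
  rownames(m) <- sprintf("S%d", 1:6)
  net <- spearman_network(m)
  expect_equal(net$rho["a", "b"], 1)
  expect_equal(net$rho["a", "c"], -1)
  expect_equal(net$p["a", "b"], 0)

  m2 <- cbind(x = 1:5, y = c(3, 1, 2, 5, 4), z = rnorm(5))
  rownames(m2) <- sprintf("S%d", 1:5)
  expect_equal(spearman_network(m2)$rho["x", "y"], 0.6)
})

test_that("rho and p are exactly invariant under strictly increasing transforms", {
  set.seed(3)
  m <- matrix(rnorm(40), 10, 4, dimnames = list(sprintf("S%d", 1:10), LETTERS[1:4]))
  net <- spearman_network(m)
  m2 <- m
  m2[, 1] <- exp(m2[, 1])
  m2[, 2] <- m2[, 2]^3
  m2[, 3] <- 10 * m2[, 3] - 4
  net2 <- spearman_network(m2)
  expect_identical(net$rho, net2$rho)
  expect_identical(net$p, net2$p)
})

test_that("rho agrees with the brute-force rank-Pearson oracle, ties included", {
  set.seed(9)
  for (rep in 1:25) {
    x <- sample(1:5, 8, replace = TRUE)  # ties certain
    y <- rnorm(8)
    m <- cbind(x = x, y = y, pad = rnorm(8))
    rownames(m) <- sprintf("S%d", 1:8)
    expect_equal(spearman_network(m)$rho["x", "y"], brute_spearman(x, y),
                 tolerance = 1e-12)
  }
})

test_that("constant columns give undefined edges with a warning", {
  m <- cbind(a = 1:6, b = rep(2, 6), c = rnorm(6))
  rownames(m) <- sprintf("S%d", 1:6)
  expect_warning(net <- spearman_network(m), "constant")
  expect_true(is.na(net$rho["a", "b"]))
  expect_true(is.na(net$p["b", "c"]))
  expect_false(is.na(net$rho["a", "c"]))
})

test_that("the Fisher z difference test matches its closed form", {
  # sample rho 0.9 vs 0.0 at n = 40/40: z = atanh(0.9)/sqrt(2*1.06/37) ~ 6.15
  p <- dcornet:::fisher_z_p(0.9, 0.0, 40, 40)
  expect_equal(p, 2 * pnorm(-atanh(0.9) / sqrt(2 * 1.06 / 37)), tolerance = 1e-12)
  expect_lt(p, 1e-9)
})

test_that("compare_networks is symmetric in its arguments for fisher_z", {
  d <- latent_pair_matrices(0.6, 25, seed = 5, extra = 2)
  ab <- compare_networks(d$A, d$B, group_labels = c("A", "B"))
  ba <- compare_networks(d$B, d$A, group_labels = c("B", "A"))
  expect_equal(ab$p_diff, ba$p_diff, tolerance = 1e-12)
  expect_equal(ab$rho_A, ba$rho_B)
})

test_that("permutation p is 1 when both groups are the same data", {
  d <- latent_pair_matrices(0.5, 12, seed = 7, extra = 1)
  A2 <- d$A; rownames(A2) <- paste0("c", 1:12)
  diff <- compare_networks(d$A, A2, method = "permutation", n_resample = 199,
                           seed = 11)
  expect_true(all(diff$p_diff == 1))
  expect_false(any(diff$significant))
})

test_that("resampling results are reproducible and edge-order independent", {
  d <- latent_pair_matrices(0.7, 15, seed = 13, extra = 2)
  d1 <- compare_networks(d$A, d$B, method = "permutation", n_resample = 99, seed = 5)
  d2 <- compare_networks(d$A, d$B, method = "permutation", n_resample = 99, seed = 5)
  expect_identical(d1$p_diff, d2$p_diff)
  # column reordering must not change any edge's p-value
  perm <- c(3, 1, 4, 2)
  d3 <- compare_networks(d$A[, perm], d$B[, perm], method = "permutation",
                         n_resample = 99, seed = 5)
  key <- paste(d1$analyte_i, d1$analyte_j)
  expect_identical(d1$p_diff, d3$p_diff[match(key, paste(d3$analyte_i, d3$analyte_j))])
})

test_that("unknown methods and undersized groups are rejected", {
  d <- latent_pair_matrices(0.5, 10, seed = 1)
  expect_error(compare_networks(d$A, d$B, method = "anova"))
  expect_error(compare_networks(d$A[1:3, ], d$B), "n > 3|at least 4")
})

test_that("bootstrap_rank warns that its p-values are heuristic", {
  d <- latent_pair_matrices(0.5, 10, seed = 3)
  expect_warning(compare_networks(d$A, d$B, method = "bootstrap_rank",
                                  n_resample = 50, seed = 2),
                 "heuristic")
})

test_that("evidence against equal correlations grows with the true difference", {
  # detection rates saturate at 1 for the heuristic bootstrap method at these
  # sizes, so power ordering is checked on the p-values themselves
  mean_p <- function(method, rho, n_rep = 15, n = 20) {
    ps <- vapply(seq_len(n_rep), function(s) {
      d <- latent_pair_matrices(rho, n, seed = 100 * rho + s)
      suppressWarnings(
        compare_networks(d$A, d$B, method = method, n_resample = 100,
                         seed = s))$p_diff[1]
    }, numeric(1))
    mean(ps)
  }
  for (method in c("fisher_z", "permutation", "bootstrap_rank")) {
    expect_lt(mean_p(method, 0.9), mean_p(method, 0.5))
  }
  # and the detection rate itself is ordered for the calibrated methods
  rate <- function(method, rho, n_rep = 15, n = 20) {
    mean(vapply(seq_len(n_rep), function(s) {
      d <- latent_pair_matrices(rho, n, seed = 100 * rho + s)
      compare_networks(d$A, d$B, method = method, n_resample = 100,
                       seed = s)$significant[1]
    }, logical(1)))
  }
  expect_gt(rate("fisher_z", 0.9), rate("fisher_z", 0.5))
  expect_gt(rate("permutation", 0.9), rate("permutation", 0.5))
})

test_that("hub z-sums follow the stated arithmetic", {
  # one analyte with 5 significant edges of rho 0.9 -> z_sum = 5 * atanh(0.9)
  p <- 6
  rho <- diag(p); rho[1, 2:p] <- 0.9; rho[2:p, 1] <- 0.9
  pm <- matrix(0.5, p, p); pm[1, ] <- pm[, 1] <- 0.001; diag(pm) <- NA
  nms <- LETTERS[1:p]
  dimnames(rho) <- dimnames(pm) <- list(nms, nms)
  net <- structure(list(analytes = nms, rho = rho, p = pm, n = 50,
                        group_label = "demo"), class = "correlation_network")
  hs <- hub_scores(net, alpha = 0.05)
  expect_equal(hs$z_sum[hs$analyte == "A"], 5 * atanh(0.9), tolerance = 1e-9)
  expect_equal(hs$n_sig[hs$analyte == "A"], 5L)
  expect_equal(hs$rank[hs$analyte == "A"], 1L)
})

test_that("an analyte with no significant edges scores zero", {
  rho <- diag(3); rho[1, 2] <- rho[2, 1] <- 0.8
  pm <- matrix(0.9, 3, 3); diag(pm) <- NA; pm[1, 2] <- pm[2, 1] <- 0.001
  dimnames(rho) <- dimnames(pm) <- list(c("A", "B", "C"), c("A", "B", "C"))
  net <- structure(list(analytes = c("A", "B", "C"), rho = rho, p = pm, n = 30,
                        group_label = "demo"), class = "correlation_network")
  hs <- hub_scores(net)
  expect_equal(hs$z_sum[hs$analyte == "C"], 0)
  expect_equal(hs$n_sig[hs$analyte == "C"], 0L)
  expect_error(hub_scores(net, alpha = 1.2), "alpha")
})

test_that("differential hub scores sum |atanh(rho_A) - atanh(rho_B)| over significant edges", {
  diff <- structure(
    data.frame(analyte_i = c("A", "A", "B"), analyte_j = c("B", "C", "C"),
               rho_A = c(0.9, 0.5, 0.1), rho_B = c(0.0, 0.4, 0.0),
               p_A = 0.01, p_B = 0.5,
               p_diff = c(0.001, 0.6, 0.7), p_diff_bh = NA,
               significant = c(TRUE, FALSE, FALSE)),
    class = c("differential_network", "data.frame"), alpha = 0.05)
  hs <- hub_scores(diff)
  expect_equal(hs$z_sum[hs$analyte == "A"], abs(atanh(0.9)), tolerance = 1e-9)
  expect_equal(hs$z_sum[hs$analyte == "C"], 0)
  expect_equal(hs$n_sig[hs$analyte == "B"], 1L)
})

test_that("a star-correlated analyte is ranked first", {
  an <- tiny_analytes(10)
  base <- diag(10); dimnames(base) <- list(an$name, an$name)
  pe <- data.frame(i = "A", j = an$name[-1], rho = 0.8)
  R <- suppressWarnings(make_group_correlation(base, pe))
  cfg <- cohort_config(analytes = an, n_per_group = 50, timepoints = 0L,
                       missing_rate = 0, group_correlations = R, seed = 17)
  coh <- generate_cohort(cfg)
  sg <- setNames(coh$subjects$group, coh$subjects$subject_id)
  pp <- preprocess_panel(coh$panel, coh$analytes, sg, timepoint = "cord")
  hs <- hub_scores(spearman_network(pp$matrix, "all"))
  expect_equal(hs$analyte[hs$rank == 1], "A")
})

test_that("stratified edges are calibrated under a null stratum and powered under effects", {
  # null: stratum independent of the data-generating process
  flags <- 0; total <- 0
  for (s in 1:50) {
    d <- latent_pair_matrices(0, 40, seed = 300 + s, extra = 3)
    edges <- data.frame(
      analyte_i = c("X", "X", "N1", "N1", "N2"),
      analyte_j = c("Y", "N1", "N2", "N3", "N3"))
    stratum <- setNames(rep(c(1L, 0L), each = 20), rownames(d$A))
    se <- stratified_edges(edges, d$A, stratum)
    flags <- flags + sum(se$flagged, na.rm = TRUE)
    total <- total + sum(se$evaluable)
  }
  expect_lt(abs(flags / total - 0.05), 0.03)

  # power: rho 0.9 in stratum 1, 0 in stratum 0 (n = 40/40)
  hits <- 0
  for (s in 1:30) {
    d <- latent_pair_matrices(0.9, 40, seed = 600 + s)
    m <- rbind(d$A, d$B)
    stratum <- setNames(rep(c(1L, 0L), each = 40), rownames(m))
    se <- stratified_edges(data.frame(analyte_i = "X", analyte_j = "Y"),
                           m, stratum)
    hits <- hits + se$flagged
  }
  expect_gte(hits / 30, 0.8)
})

test_that("strata smaller than 4 are reported not-evaluable without a p-value", {
  d <- latent_pair_matrices(0.5, 10, seed = 19)
  stratum <- setNames(c(1L, 1L, 1L, rep(0L, 7)), rownames(d$A))
  se <- stratified_edges(data.frame(analyte_i = "X", analyte_j = "Y"),
                         d$A, stratum)
  expect_false(se$evaluable)
  expect_true(is.na(se$p_diff))
  expect_true(is.na(se$flagged))
  expect_error(stratified_edges(data.frame(analyte_i = "X", analyte_j = "Q"),
                                d$A, stratum), "Q")
})

test_that("median_split applies the documented tie rule", {
  expect_equal(median_split(c(-2, -1, 0, 1)), c(0L, 0L, 1L, 1L))
  expect_equal(median_split(c(-1, 0, 1)), c(0L, 0L, 1L))
  expect_equal(median_split(rep(2, 5)), rep(0L, 5))
  expect_error(median_split(1), "2 subjects")
})
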