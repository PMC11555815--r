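#' Configure a synthetic preterm cohort simulation
#'
#' Defines the generative model behind [generate_cohort()]: a latent-Gaussian
#' copula with log-normal marginals. For each subject, gestational age (GA) is
#' drawn uniformly over `ga_range`; for each timepoint, a latent Gaussian
#' vector with the subject's group correlation matrix is mapped to log10
#' concentrations as `base_mean + ga_slope * (GA - ga_ref) + noise_sd * latent`.
#' Values below an analyte's detection limit are left-censored (flagged
#' `below_lod`, value withheld) and whole scheduled samples are dropped at
#' `missing_rate` (flagged `missing`).
#'
#' Per-analyte marginal parameters (`base_mean`, `ga_slope`, `noise_sd`,
#' `lod_quantile`, `detection_limit`) are taken from columns of `analytes`;
#' any passed as arguments override the table (recycled across analytes).
#' When an analyte's `lod_quantile` is positive, its detection limit is
#' derived by inverting the marginal mixture CDF of its log10 concentration
#' (normal conditional on GA, GA uniform) so that the expected below-LOD
#' fraction equals `lod_quantile`; otherwise the table's `detection_limit` is
#' used as-is.
#'
#' @param analytes analyte table as from [preterm_panel()].
#' @param n_per_group subjects per outcome group (>= 4).
#' @param groups character vector of two group labels; defaults to the names
#'   of `group_correlations`, else `c("case", "control")`.
#' @param timepoints ordered integer day offsets of scheduled samples.
#' @param ga_range gestational-age range in weeks, drawn uniformly.
#' @param ga_ref reference GA (weeks) at which `base_mean` applies.
#' @param group_correlations a single correlation matrix (shared by both
#'   groups) or a named list of one matrix per group, on the latent Gaussian
#'   scale; repaired to PSD if needed. Default: identity.
#' @param base_mean,ga_slope,noise_sd,lod_quantile optional per-analyte
#'   overrides of the table columns.
#' @param missing_rate probability in `[0, 1)` that a scheduled sample
#'   (subject x day, all analytes) is absent.
#' @param ar1 optional AR(1) coefficient linking a subject's latent vectors
#'   across consecutive scheduled days (0 = independent days). The
#'   cross-sectional correlation matrix is preserved at every timepoint.
#' @param ga_outcome_beta optional log-odds of the outcome per GA week; if
#'   set, group labels are assigned by a logistic link to GA (centred at
#'   `ga_ref`) instead of by block, to let tests exercise GA confounding.
#' @param seed integer seed; identical configs with identical seeds generate
#'   identical cohorts.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(analytes = preterm_panel(),
                          n_per_group = 36,
                          groups = NULL,
                          timepoints = c(0L, 1L, 7L, 14L, 28L),
                          ga_range = c(22, 27.9),
                          ga_ref = 24,
                          group_correlations = NULL,
                          base_mean = NULL, ga_slope = NULL,
                          noise_sd = NULL, lod_quantile = NULL,
                          missing_rate = 0.05,
                          ar1 = 0,
                          ga_outcome_beta = NULL,
                          seed = 1L) {
  validate_analytes(analytes)
  p <- nrow(analytes)
  for (col in c("base_mean", "ga_slope", "noise_sd", "lod_quantile")) {
    ov <- get(col)
    if (!is.null(ov)) analytes[[col]] <- rep_len(ov, p)
    if (is.null(analytes[[col]]))
      analytes[[col]] <- switch(col, base_mean = 1, ga_slope = 0,
                                noise_sd = 0.4, lod_quantile = 0)
  }
  if (n_per_group < 4)
    stopf("n_per_group must be >= 4 (correlation-difference variance requires n > 3)")
  if (any(analytes$lod_quantile < 0 | analytes$lod_quantile >= 1))
    stopf("lod_quantile must lie in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1)
    stopf("missing_rate must lie in [0, 1)")
  if (abs(ar1) >= 1) stopf("ar1 must lie in (-1, 1)")
  if (length(ga_range) != 2 || diff(ga_range) <= 0)
    stopf("ga_range must be (low, high) with low < high")
  timepoints <- sort(as.integer(timepoints))
  if (anyDuplicated(timepoints)) stopf("timepoints must be distinct days")

  if (is.null(group_correlations)) {
    R <- diag(p)
    dimnames(R) <- list(analytes$name, analytes$name)
    group_correlations <- list(R, R)
  }
  if (is.matrix(group_correlations))
    group_correlations <- list(group_correlations, group_correlations)
  if (length(group_correlations) != 2)
    stopf("group_correlations must give one matrix per outcome group")
  if (is.null(groups))
    groups <- names(group_correlations) %||% c("case", "control")
  names(group_correlations) <- groups
  group_correlations <- lapply(group_correlations, function(R) {
    if (is.null(rownames(R))) dimnames(R) <- list(analytes$name, analytes$name)
    if (!setequal(rownames(R), analytes$name))
      stopf("group correlation matrix names do not match the analyte panel")
    R <- R[analytes$name, analytes$name, drop = FALSE]
    if (max(abs(R - t(R))) > 1e-8 || max(abs(diag(R) - 1)) > 1e-8)
      stopf("group correlation matrices must be symmetric with unit diagonal")
    R
  })

  structure(list(analytes = analytes, n_per_group = as.integer(n_per_group),
                 groups = groups, timepoints = timepoints,
                 ga_range = ga_range, ga_ref = ga_ref,
                 group_correlations = group_correlations,
                 missing_rate = missing_rate, ar1 = ar1,
                 ga_outcome_beta = ga_outcome_beta,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Detection limit achieving an expected below-LOD fraction q for a marginal
# that is normal conditional on GA with GA ~ U(ga_range): solve F(x) = q by
# bisection on the log10 scale, averaging the conditional CDF over a GA grid.
marginal_lod <- function(base_mean, ga_slope, noise_sd, ga_range, ga_ref, q) {
  ga <- seq(ga_range[1], ga_range[2], length.out = 201)
  mu <- base_mean + ga_slope * (ga - ga_ref)
  F <- function(x) mean(pnorm((x - mu) / noise_sd))
  lo <- min(mu) - 8 * noise_sd
  hi <- max(mu) + 8 * noise_sd
  10^uniroot(function(x) F(x) - q, c(lo, hi), tol = 1e-9)$root
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws a cohort under a [cohort_config()]: a subject table (GA, BW-SDS,
#' sex, prenatal-inflammation flag, SGA flag, outcome group) and a long-format
#' measurement panel with one record per subject x analyte x scheduled day and
#' a status flag (`observed`, `below_lod`, `missing`). Identical config and
#' seed give identical output.
#'
#' @param config a [cohort_config()].
#' @return An object of class `cohort`: list with `subjects`, `panel`,
#'   `analytes` (detection limits as actually applied), and `config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_per_group = 8, seed = 7)
#' coh <- generate_cohort(cfg)
#' head(coh$panel)
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stopf("config must be a cohort_config")
  an <- config$analytes
  p <- nrow(an)
  n <- config$n_per_group
  tps <- config$timepoints

  Rs <- lapply(config$group_correlations, psd_repair)
  for (R in Rs) {
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stopf("group correlation matrix is not PSD after repair tolerance")
  }
  chols <- lapply(Rs, function(R) chol(R + diag(1e-10, p)))

  # resolve detection limits (derived from lod_quantile where requested)
  dl <- an$detection_limit
  for (a in seq_len(p)) {
    if (an$lod_quantile[a] > 0)
      dl[a] <- marginal_lod(an$base_mean[a], an$ga_slope[a], an$noise_sd[a],
                            config$ga_range, config$ga_ref, an$lod_quantile[a])
  }
  an$detection_limit <- dl

  ids <- sprintf("S%03d", seq_len(2 * n))
  out <- with_seed(config$seed, {
    ga <- runif(2 * n, config$ga_range[1], config$ga_range[2])
    bw_sds <- rnorm(2 * n)
    sex <- rbinom(2 * n, 1, 0.5)
    hca_firs <- rbinom(2 * n, 1, 0.5)
    if (is.null(config$ga_outcome_beta)) {
      grp <- rep(config$groups, each = n)
    } else {
      pr <- plogis(config$ga_outcome_beta * (ga - config$ga_ref))
      grp <- ifelse(rbinom(2 * n, 1, pr) == 1, config$groups[1],
                    config$groups[2])
    }
    # latent Gaussian draws, group by group in declared group order
    logc <- array(NA_real_, dim = c(2 * n, length(tps), p))
    for (g in config$groups) {
      idx <- which(grp == g)
      if (!length(idx)) next
      L <- chols[[g]]
      latent <- NULL
      for (t in seq_along(tps)) {
        eps <- matrix(rnorm(length(idx) * p), length(idx), p) %*% L
        latent <- if (is.null(latent) || config$ar1 == 0) eps else
          config$ar1 * latent + sqrt(1 - config$ar1^2) * eps
        logc[idx, t, ] <- sweep(latent, 2, an$noise_sd, `*`) +
          matrix(an$base_mean, length(idx), p, byrow = TRUE) +
          outer(ga[idx] - config$ga_ref, an$ga_slope)
      }
    }
    absent <- matrix(runif(2 * n * length(tps)) < config$missing_rate,
                     2 * n, length(tps))
    list(ga = ga, bw_sds = bw_sds, sex = sex, hca_firs = hca_firs,
         grp = grp, logc = logc, absent = absent)
  })

  subjects <- data.frame(
    subject_id = ids, group = out$grp,
    ga_weeks = out$ga, bw_sds = out$bw_sds,
    sex = ifelse(out$sex == 1, "male", "female"),
    hca_firs = out$hca_firs,
    sga = as.integer(out$bw_sds < -2),
    stringsAsFactors = FALSE
  )

  nrec <- 2 * n * length(tps) * p
  panel <- data.frame(
    subject_id = rep(ids, each = length(tps) * p),
    analyte = rep(rep(an$name, times = length(tps)), times = 2 * n),
    day = rep(rep(tps, each = p), times = 2 * n),
    value = NA_real_,
    status = rep("observed", nrec),
    stringsAsFactors = FALSE
  )
  val <- 10^aperm(out$logc, c(3, 2, 1))  # analyte fastest, then day, subject
  panel$value <- as.vector(val)
  below <- panel$value < an$detection_limit[match(panel$analyte, an$name)]
  panel$status[below] <- "below_lod"
  panel$value[below] <- NA_real_
  miss <- out$absent[cbind(match(panel$subject_id, ids),
                           match(panel$day, tps))]
  panel$status[miss] <- "missing"
  panel$value[miss] <- NA_real_

  structure(list(subjects = subjects, panel = panel, analytes = an,
                 config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%s), %d analytes, days {%s}\n",
              nrow(x$subjects),
              paste(sprintf("%d %s", as.vector(table(x$subjects$group)[x$config$groups]),
                            x$config$groups), collapse = " / "),
              nrow(x$analytes),
              paste(x$config$timepoints, collapse = ", ")))
  st <- table(x$panel$status)
  cat("Record status: ",
      paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n", sep = "")
  invisible(x)
}
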