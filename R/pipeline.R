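#' Configure an end-to-end pipeline run
#'
#' A pipeline run consumes either on-disk CSVs (panel, subjects, analytes) or
#' a simulation block, analyses one binary outcome at one or more timepoints,
#' and writes all result tables under an output directory.
#'
#' @param panel,subjects,analytes input CSV paths (all three together), or
#'   `NULL` when simulating.
#' @param simulate a [cohort_config()], or `NULL` when reading files.
#' @param outcome name of the binary outcome column in the subject table
#'   (default `"group"`); subjects with `NA` outcome are excluded (this is
#'   how clinical filters such as "ROP grade 0 vs grade 3 only" or the BPD
#'   borderline-oxygen exclusions are expressed - as metadata, not
#'   computation).
#' @param timepoints subset of `c("cord", "day_one", "first_month")`.
#' @param ga_correction build networks from standardized GA-regression
#'   residuals (`TRUE`, default) or from log concentrations directly.
#' @param method edge-difference test, see [compare_networks()].
#' @param alpha significance level (default 0.05).
#' @param n_resample resamples for resampling methods.
#' @param confounders subject-table columns to stratify significant edges by;
#'   binary columns are used as-is, continuous ones are median-split.
#' @param seed master seed for all resampling.
#' @param out_dir output directory (created if absent).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(panel = NULL, subjects = NULL, analytes = NULL,
                            simulate = NULL, outcome = "group",
                            timepoints = c("cord", "day_one", "first_month"),
                            ga_correction = TRUE,
                            method = "fisher_z", alpha = 0.05,
                            n_resample = 2000,
                            confounders = c("hca_firs", "bw_sds"),
                            seed = 1L, out_dir = tempfile("dcornet_run_")) {
  have_paths <- !is.null(panel) || !is.null(subjects) || !is.null(analytes)
  if (have_paths && !is.null(simulate))
    stopf("give either input paths or a simulate block, not both")
  if (!have_paths && is.null(simulate))
    stopf("give either input paths (panel, subjects, analytes) or a simulate block")
  if (have_paths && (is.null(panel) || is.null(subjects) || is.null(analytes)))
    stopf("panel, subjects and analytes paths are all required")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  timepoints <- match.arg(timepoints, c("cord", "day_one", "first_month"),
                          several.ok = TRUE)
  structure(list(panel = panel, subjects = subjects, analytes = analytes,
                 simulate = simulate, outcome = outcome,
                 timepoints = timepoints, ga_correction = ga_correction,
                 method = method, alpha = alpha, n_resample = n_resample,
                 confounders = confounders, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Analyse one timepoint matrix for one binary outcome
#'
#' The in-memory core of the pipeline: splits a (residual) matrix by outcome
#' group, builds the two Spearman networks, the differential network, the
#' entire-network and difference hub rankings, the per-analyte level
#' comparisons, and the confounder-stratified re-tests of significant edges.
#'
#' @param matrix a `timepoint_matrix` of log10 concentrations.
#' @param subjects subject table covering the matrix rows (columns
#'   `subject_id`, the outcome column, `ga_weeks`, and any confounders).
#' @param outcome outcome column name (two non-NA levels).
#' @param ga_correction,method,alpha,n_resample,confounders,seed see
#'   [pipeline_config()].
#' @return list with `networks` (per group), `diff`, `hubs_entire`,
#'   `hubs_diff`, `levels`, `strata`, `groups`, `fits` (GA fits or NULL).
#' @export
analyze_timepoint <- function(matrix, subjects, outcome = "group",
                              ga_correction = TRUE, method = "fisher_z",
                              alpha = 0.05, n_resample = 2000,
                              confounders = character(0), seed = 1L) {
  sub <- subjects[match(rownames(matrix), subjects$subject_id), , drop = FALSE]
  if (anyNA(sub$subject_id))
    stopf("subject table does not cover every matrix subject")
  grp <- sub[[outcome]]
  keep <- !is.na(grp)
  matrix <- matrix[keep, , drop = FALSE]
  sub <- sub[keep, , drop = FALSE]
  grp <- as.character(grp[keep])
  lev <- unique(grp)
  if (length(lev) != 2)
    stopf("outcome '%s' must have exactly two non-NA levels", outcome)
  ga <- stats::setNames(sub$ga_weeks, sub$subject_id)

  fits <- NULL
  net_input <- matrix
  if (ga_correction) {
    fits <- fit_ga_regressions(matrix, ga)
    net_input <- residualize(matrix, fits, ga)
  }
  mA <- net_input[grp == lev[1], , drop = FALSE]
  mB <- net_input[grp == lev[2], , drop = FALSE]
  if (nrow(mA) < 4 || nrow(mB) < 4)
    stopf("outcome group smaller than 4 at timepoint '%s'",
          attr(matrix, "timepoint_label") %||% "?")
  netA <- spearman_network(mA, lev[1])
  netB <- spearman_network(mB, lev[2])
  diff <- compare_networks(mA, mB, method = method, alpha = alpha,
                           n_resample = n_resample, seed = seed,
                           group_labels = lev)
  hubs_entire <- stats::setNames(
    list(hub_scores(netA, alpha = alpha), hub_scores(netB, alpha = alpha)), lev)
  hubs_diff <- hub_scores(diff, alpha = alpha)
  levels_tab <- wilcoxon_levels(matrix, stats::setNames(grp, sub$subject_id),
                                ga = ga, outcome_group = lev[1])
  sig_edges <- diff[diff$significant, , drop = FALSE]
  strata <- list()
  for (cf in confounders) {
    v <- sub[[cf]]
    if (is.null(v)) stopf("confounder column '%s' not in subject table", cf)
    lab <- if (is_binary01(v)) as.integer(v) else median_split(v)
    strata[[cf]] <- if (nrow(sig_edges)) {
      stratified_edges(sig_edges, net_input,
                       stats::setNames(lab, sub$subject_id),
                       method = if (method == "bootstrap_rank") "fisher_z" else method,
                       alpha = alpha, n_resample = n_resample, seed = seed)
    } else {
      NULL
    }
  }
  list(networks = stats::setNames(list(netA, netB), lev), diff = diff,
       hubs_entire = hubs_entire, hubs_diff = hubs_diff,
       levels = levels_tab, strata = strata, groups = lev, fits = fits)
}

#' Run the full pipeline and write all artifacts
#'
#' Loads or simulates the cohort, preprocesses each requested timepoint
#' (LOD/8 imputation, log transform, interpolation, sparse-analyte exclusion,
#' complete-case assembly, first-month AUC/time summary), optionally
#' residualizes on gestational age, builds per-group and differential
#' networks, hub rankings, level comparisons and confounder strata, and
#' writes everything under `config$out_dir`:
#' `<tp>/matrix.csv`, `<tp>/edges.csv`, `<tp>/network_<group>.graphml`,
#' `<tp>/hubs_entire_<group>.csv`, `<tp>/hubs_difference.csv`,
#' `<tp>/levels.csv`, `<tp>/strata_<confounder>.csv`,
#' `<tp>/preprocess.json`, plus a top-level `manifest.json` and `report.md`.
#' Identical config and seed produce identical files.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the per-timepoint result lists.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$simulate)) {
    coh <- generate_cohort(config$simulate)
    subjects <- coh$subjects; panel <- coh$panel; analytes <- coh$analytes
  } else {
    panel <- read_panel(config$panel)
    subjects <- read_table_csv(config$subjects)
    analytes <- validate_analytes(read_table_csv(config$analytes))
  }
  if (!config$outcome %in% names(subjects))
    stopf("outcome column '%s' not in subject table", config$outcome)
  keep <- !is.na(subjects[[config$outcome]])
  subjects <- subjects[keep, , drop = FALSE]
  panel <- panel[panel$subject_id %in% subjects$subject_id, , drop = FALSE]

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$simulate)) {
    write_table_csv(subjects, file.path(config$out_dir, "subjects.csv"),
                    seed = config$simulate$seed)
    write_table_csv(panel, file.path(config$out_dir, "panel.csv"),
                    seed = config$simulate$seed)
    write_table_csv(analytes, file.path(config$out_dir, "analytes.csv"))
  }

  subgroups <- stats::setNames(as.character(subjects[[config$outcome]]),
                               subjects$subject_id)
  results <- list()
  counts <- list()
  for (tp in config$timepoints) {
    pp <- preprocess_panel(panel, analytes, subgroups, timepoint = tp)
    res <- analyze_timepoint(pp$matrix, subjects, outcome = config$outcome,
                             ga_correction = config$ga_correction,
                             method = config$method, alpha = config$alpha,
                             n_resample = config$n_resample,
                             confounders = config$confounders,
                             seed = config$seed)
    tp_dir <- file.path(config$out_dir, tp)
    dir.create(tp_dir, showWarnings = FALSE)
    mdf <- data.frame(subject_id = rownames(pp$matrix),
                      as.data.frame(unclass(pp$matrix)), check.names = FALSE)
    write_table_csv(mdf, file.path(tp_dir, "matrix.csv"))
    write_edge_list(res$diff, file.path(tp_dir, "edges.csv"))
    for (g in res$groups) {
      write_network_graphml(res$networks[[g]],
                            file.path(tp_dir, sprintf("network_%s.graphml", g)),
                            analytes = analytes, alpha = config$alpha)
      write_table_csv(res$hubs_entire[[g]],
                      file.path(tp_dir, sprintf("hubs_entire_%s.csv", g)))
    }
    write_table_csv(res$hubs_diff, file.path(tp_dir, "hubs_difference.csv"))
    write_table_csv(res$levels, file.path(tp_dir, "levels.csv"))
    for (cf in names(res$strata)) {
      if (!is.null(res$strata[[cf]]))
        write_table_csv(res$strata[[cf]],
                        file.path(tp_dir, sprintf("strata_%s.csv", cf)))
    }
    jsonlite::write_json(
      list(timepoint = tp, n_subjects = nrow(pp$matrix),
           n_analytes = ncol(pp$matrix),
           excluded_analytes = pp$excluded,
           n_interpolated = pp$n_interpolated,
           n_significant_edges = sum(res$diff$significant)),
      file.path(tp_dir, "preprocess.json"), auto_unbox = TRUE, pretty = TRUE)
    counts[[tp]] <- list(n_subjects = nrow(pp$matrix),
                         n_analytes = ncol(pp$matrix),
                         n_interpolated = pp$n_interpolated,
                         excluded = pp$excluded,
                         n_significant_edges = sum(res$diff$significant))
    results[[tp]] <- c(res, list(preprocess = pp))
  }
  manifest <- list(
    package = "dcornet",
    version = as.character(utils::packageVersion("dcornet")),
    outcome = config$outcome, timepoints = config$timepoints,
    ga_correction = config$ga_correction, method = config$method,
    alpha = config$alpha, n_resample = config$n_resample,
    seed = config$seed,
    simulated = !is.null(config$simulate),
    simulation_seed = if (!is.null(config$simulate)) config$simulate$seed,
    counts = counts)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_report(results, config)
  invisible(results)
}

# Markdown summary collating the run: counts, significant edges, top hubs.
write_report <- function(results, config) {
  lines <- c("# Differential correlation network report", "")
  for (tp in names(results)) {
    res <- results[[tp]]
    lines <- c(lines, sprintf("## Timepoint: %s", tp), "")
    pp <- res$preprocess
    lines <- c(lines,
               sprintf("- complete-case subjects: %d", nrow(pp$matrix)),
               sprintf("- analytes analysed: %d (excluded: %s)",
                       ncol(pp$matrix),
                       if (length(pp$excluded)) paste(pp$excluded, collapse = ", ")
                       else "none"),
               sprintf("- values interpolated: %d", pp$n_interpolated), "")
    sig <- res$diff[res$diff$significant, , drop = FALSE]
    if (nrow(sig) == 0) {
      lines <- c(lines, "No significant edges in the differential network.", "")
    } else {
      lines <- c(lines,
                 sprintf("%d significant differential edge(s) (%s vs %s, alpha = %g):",
                         nrow(sig), res$groups[1], res$groups[2], config$alpha),
                 "",
                 "| analyte_i | analyte_j | rho_A | rho_B | p_diff |",
                 "|---|---|---|---|---|",
                 sprintf("| %s | %s | %.2f | %.2f | %.4f |",
                         sig$analyte_i, sig$analyte_j, sig$rho_A, sig$rho_B,
                         sig$p_diff), "")
      top <- utils::head(res$hubs_diff[res$hubs_diff$z_sum > 0, ], 3)
      if (nrow(top))
        lines <- c(lines, sprintf(
          "Top difference-network hubs: %s.",
          paste(sprintf("%s (z-sum %.2f: %d)", top$analyte, top$z_sum,
                        top$n_sig), collapse = ", ")), "")
    }
  }
  writeLines(lines, file.path(config$out_dir, "report.md"))
  invisible(NULL)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]'s arguments; a `simulate:` block
#' mirrors [cohort_config()]'s scalar arguments (its `analytes:` entry, if
#' present, is a CSV path; otherwise the default panel is used).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    sim <- y$simulate
    if (!is.null(sim$analytes)) sim$analytes <- read_table_csv(sim$analytes)
    y$simulate <- do.call(cohort_config, sim)
  }
  do.call(pipeline_config, y)
}
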