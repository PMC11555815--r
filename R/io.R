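#' Read / write tidy panel and subject tables
#'
#' CSV I/O for the pipeline's long-format tables. Writers can prepend a
#' `# seed: <n>` comment line recording the generating seed; readers skip
#' comment lines. All files are UTF-8, comma-delimited, with a header row.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @param seed optional integer recorded as a header comment.
#' @return `read_table_csv` returns a data.frame; writers return the path
#'   invisibly.
#' @export
write_table_csv <- function(x, path, seed = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read and validate a long-format measurement panel CSV
#'
#' Expects columns `subject_id`, `analyte`, `day`, `value`, `status`.
#' Rows violating the schema (unknown status, or a value present/absent
#' inconsistently with its status) raise an error listing the offending row
#' numbers.
#'
#' @param path CSV path.
#' @return A validated panel data.frame.
#' @export
read_panel <- function(path) {
  panel <- read_table_csv(path)
  validate_panel(panel)
}

#' @rdname read_panel
#' @param panel an in-memory panel to validate.
#' @export
validate_panel <- function(panel) {
  req <- c("subject_id", "analyte", "day", "value", "status")
  miss <- setdiff(req, names(panel))
  if (length(miss))
    stopf("panel lacks column(s): %s", paste(miss, collapse = ", "))
  ok_status <- c("observed", "below_lod", "missing", "imputed_lod",
                 "interpolated", "summary")
  bad <- which(!panel$status %in% ok_status)
  need_value <- panel$status %in% c("observed", "imputed_lod", "interpolated", "summary")
  bad <- union(bad, which(need_value & is.na(panel$value)))
  bad <- union(bad, which(!need_value & !is.na(panel$value)))
  if (length(bad))
    stopf("panel schema violation in row(s): %s",
          paste(utils::head(sort(bad), 10), collapse = ", "))
  if (anyDuplicated(panel[, c("subject_id", "analyte", "day")]))
    stopf("(subject_id, analyte, day) must be unique")
  panel
}

#' Export a differential network as a long CSV edge list
#'
#' Writes one row per unordered analyte pair with per-group rho and p, the
#' difference p-value and the significance flag - the tabular content behind
#' the "difference" bubble plots.
#'
#' @param diff a [compare_networks()] result.
#' @param path CSV path.
#' @export
write_edge_list <- function(diff, path) {
  write_table_csv(as.data.frame(diff), path)
}

#' Export a correlation network as GraphML
#'
#' Nodes carry the analyte class (`cytokine`/`growth_factor`) when an analyte
#' table is supplied; edges carry the Spearman rho as `weight`, its `sign`,
#' and the edge p-value. By default only edges with `p < alpha` are exported.
#'
#' @param net a [spearman_network()] result.
#' @param path output path.
#' @param analytes optional analyte table with `name` and `class`.
#' @param alpha edge inclusion threshold; `NULL` exports all defined edges.
#' @export
write_network_graphml <- function(net, path, analytes = NULL, alpha = 0.05) {
  stopifnot(inherits(net, "correlation_network"))
  idx <- which(upper.tri(net$rho) & !is.na(net$rho), arr.ind = TRUE)
  if (!is.null(alpha)) {
    keep <- net$p[idx] < alpha & !is.na(net$p[idx])
    idx <- idx[keep, , drop = FALSE]
  }
  edges <- data.frame(from = net$analytes[idx[, 1]],
                      to = net$analytes[idx[, 2]],
                      weight = net$rho[idx],
                      sign = ifelse(net$rho[idx] >= 0, "positive", "negative"),
                      p = net$p[idx],
                      stringsAsFactors = FALSE)
  nodes <- data.frame(name = net$analytes, stringsAsFactors = FALSE)
  if (!is.null(analytes))
    nodes$class <- analytes$class[match(nodes$name, analytes$name)]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
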