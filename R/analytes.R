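#' Default serum analyte panel for a preterm-infant cohort
#'
#' A panel of 17 cytokines (Bio-Plex 17-plex style) and 5 growth factors
#' (IGF-1, BDNF, VEGF-A, PDGF-BB, EPO), each with an assay detection limit and
#' the marginal parameters used by [generate_cohort()]: mean log10
#' concentration at the reference gestational age (`base_mean`), slope of mean
#' log10 concentration per gestational week (`ga_slope`), residual SD on the
#' log10 scale (`noise_sd`), and the target fraction of values below the
#' detection limit (`lod_quantile`).
#'
#' Concentrations are in pg/mL except IGF-1 (ng/mL). The detection limits and
#' marginal parameters are synthetic defaults chosen to give realistic
#' right-skewed serum concentration distributions; they are not assay-sheet
#' values. Growth factors carry positive gestational-age slopes (IGF-1 in
#' particular is strongly GA-dependent in preterm infants); cytokines default
#' to GA-independent means. Five low-abundance cytokines (IL-4, IL-7, IL-12,
#' IL-13, GM-CSF) default to heavy left-censoring so that the
#' sparse-analyte exclusion rule is exercised on simulated cohorts just as it
#' was on the clinical panel.
#'
#' @param heavy_censoring logical; if `FALSE`, all analytes get
#'   `lod_quantile = 0` (no intended censoring). Default `TRUE`.
#' @return A data.frame with columns `name`, `class`
#'   (`"cytokine"`/`"growth_factor"`), `detection_limit`, `base_mean`,
#'   `ga_slope`, `noise_sd`, `lod_quantile`.
#' @export
#' @examples
#' panel <- preterm_panel()
#' table(panel$class)
preterm_panel <- function(heavy_censoring = TRUE) {
  cyt <- c("IL-1b", "IL-2", "IL-4", "IL-5", "IL-6", "IL-7", "IL-8", "IL-10",
           "IL-12", "IL-13", "IL-17", "G-CSF", "GM-CSF", "IFN-g", "MCP-1",
           "MIP-1b", "TNF-a")
  gf <- c("IGF-1", "BDNF", "VEGF-A", "PDGF-BB", "EPO")
  panel <- data.frame(
    name = c(cyt, gf),
    class = c(rep("cytokine", length(cyt)), rep("growth_factor", length(gf))),
    stringsAsFactors = FALSE
  )
  panel$detection_limit <- 0.5
  panel$base_mean <- 1.0          # ~10 pg/mL
  panel$ga_slope <- 0.0
  panel$noise_sd <- 0.45
  panel$lod_quantile <- 0
  # growth factors: higher abundance, GA-dependent
  gf_means <- c("IGF-1" = 1.2, "BDNF" = 3.4, "VEGF-A" = 2.2,
                "PDGF-BB" = 3.0, "EPO" = 1.0)
  panel$base_mean[match(names(gf_means), panel$name)] <- unname(gf_means)
  panel$ga_slope[panel$class == "growth_factor"] <- 0.05
  panel$noise_sd[panel$class == "growth_factor"] <- 0.35
  if (heavy_censoring) {
    sparse <- c("IL-4", "IL-7", "IL-12", "IL-13", "GM-CSF")
    panel$lod_quantile[panel$name %in% sparse] <- 0.85
    panel$lod_quantile[panel$class == "cytokine" &
                         !(panel$name %in% sparse)] <- 0.05
  }
  validate_analytes(panel)
  panel
}

#' Validate an analyte definition table
#'
#' Checks the invariants required of an analyte table: unique names, positive
#' detection limits, recognised classes.
#'
#' @param analytes data.frame with at least `name`, `class`, `detection_limit`.
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_analytes <- function(analytes) {
  req <- c("name", "class", "detection_limit")
  miss <- setdiff(req, names(analytes))
  if (length(miss))
    stopf("analyte table lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(analytes$name))
    stopf("analyte names must be unique within a panel")
  if (any(!is.finite(analytes$detection_limit) | analytes$detection_limit <= 0))
    stopf("detection limits must be positive")
  bad <- setdiff(unique(analytes$class), c("cytokine", "growth_factor"))
  if (length(bad))
    stopf("unknown analyte class(es): %s", paste(bad, collapse = ", "))
  invisible(analytes)
}
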