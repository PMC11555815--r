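---
title: "Differential correlation networks for neonatal biomarker panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential correlation networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcornet)
```

## The analysis problem

Serum cytokines regulate each other's production and release, and they
negatively regulate growth factors; a disease process can therefore shift
the *joint* behaviour of a panel while leaving every marginal concentration
within its usual range. This package operationalises that idea for
longitudinal immunoassay panels in extremely preterm infants (< 28 weeks
gestation), where the outcomes of interest — severe retinopathy of
prematurity and bronchopulmonary dysplasia — are diagnosed weeks after the
blood samples that might carry early signatures. The analysis object is a
group-wise Spearman correlation network over ~22 analytes at a handful of
timepoints (cord blood, day one, and a "first month" summary), and the
result of interest is the set of edges whose correlation *differs* between
infants with and without the outcome, together with a ranking of the
analytes ("hub factors") that carry those differences.

## Preprocessing model

Raw panels are long tables of (subject, analyte, day, concentration,
status). The pipeline applies, in order:

1. **Left-censoring imputation.** Immunoassays report "low out of range"
   below an analyte-specific detection limit (LOD). Censored values are set
   to LOD/8 — a conventional small constant that keeps censored values
   strictly below all observed ones — and flagged `imputed_lod` so
   downstream rules can still see them.
2. **log10 transform.** Serum concentrations are right-skewed; all analysis
   happens on the log scale. Base 10 is a display choice only: the
   interpolation below is base-invariant, and every rank statistic in the
   package is invariant to any monotone transform.
3. **Interpolation.** A missing sample bridged by present values at an
   earlier and a later sampled day is filled linearly in day on the log
   scale (geometric interpolation of concentrations). Anchors are the
   *nearest* present days, so a missing day 14 can be bridged from days 7
   and 28; a missing first or last sample is never extrapolated.
4. **Sparse-analyte exclusion.** An analyte with strictly more than 3/4 of
   its measured values censored in any subgroup at the analysis timepoint is
   dropped: its ranks would mostly be ties at LOD/8 and correlations would
   reflect the imputation constant, not biology. The rule is evaluated per
   timepoint within the outcome grouping under analysis (whether the
   original analysis evaluated it per timepoint or once globally is not
   documented; per-timepoint is the stricter reading and the default here).
   On simulated cohorts with realistic censoring this removes the same
   low-abundance cytokines (IL-4, IL-7, IL-12, IL-13, GM-CSF) that fall to
   the rule on real panels.
5. **First-month summary.** Days 7, 14 and 28 are collapsed to one value
   per subject-analyte: trapezoidal area under the raw concentration-day
   curve divided by the 21-day span, then log10. Integrating on the raw
   scale is the standard reading of "average concentration as AUC/time";
   the constant function is its fixed point for any day spacing, which the
   tests assert.
6. **Complete-case rule.** A subject enters a timepoint matrix only with a
   present value for every retained analyte. Fewer than 4 complete subjects
   is an error, since every downstream variance formula needs n > 3.

## Gestational-age correction

GA is the dominant confounder: many growth factors (IGF-1 in particular)
rise with GA, and both outcomes are more frequent at lower GA, so a pair of
GA-dependent analytes acquires a spurious correlation. Correction is by
per-analyte OLS of log10 concentration on GA across the *pooled* cohort at
the timepoint (not per group — pooling reflects the assumption that the
GA dependence is physiological, not outcome-specific), followed by
standardization of the residuals to unit SD. The normalizing SD is the SD
of that analyte's residuals within the analyzed matrix; the alternative
(raw-value SD) differs only by a positive per-column factor, which rank
correlations ignore — the choice affects exported residual magnitudes, not
any network statistic. Residualization is idempotent and leaves residuals
exactly uncorrelated with GA (OLS orthogonality), both asserted in tests.

## Network construction and edge-difference testing

Spearman rho is computed as the Pearson correlation of mid-ranks (average
ranks on ties); per-edge p-values use the t approximation with n − 2
degrees of freedom, adequate at the n ≥ 10 group sizes this analysis is
meant for (an exact reference is impractical beyond n = 10 and the edges
that matter are re-tested by the difference test anyway). Constant columns
give undefined edges with a warning rather than an error, since censoring
can produce them legitimately.

Three difference tests are offered:

- **fisher_z** (default): the z statistic on atanh-transformed
  correlations with variance c/(n − 3) per group and c = 1.06, Fieller's
  variance inflation for Spearman correlations of bivariate-normal ranks.
  Under the two-group Gaussian null at n = 30/group its measured type-I
  error is within [0.03, 0.07] at α = 0.05 (asserted over 1000 seeded
  replicates).
- **permutation**: group labels permuted, two-sided p from the add-one
  estimator (1 + #extreme)/(B + 1). Exact in level up to resampling
  granularity; the recommended robustness check, at B ≥ 200 for α = 0.05.
- **bootstrap_rank**: per-group bootstrap distributions of rho compared by
  a rank-sum test. This reproduces a literal "Wilcoxon test on
  correlations" reading, but its p-value sharpens indefinitely as B grows,
  so it is *not* calibration-guaranteed; the package flags it heuristic at
  every use and the calibration tests deliberately exclude it.

Edges with p_diff < α = 0.05 are flagged significant with **no**
multiple-testing correction — a deliberate property of the analysis this
package implements, whose output is a ranked shortlist for mechanistic
follow-up, not a confirmatory claim; a BH-adjusted column accompanies every
edge list for readers who want it. Resampling uses a master seed that
spawns a deterministic substream per edge, so per-edge results are
independent of edge evaluation order and of which other analytes are
present.

## Hub scores and confounder strata

An analyte's hub score sums |atanh rho| over its qualifying edges —
significant within-group edges for "entire network" rankings, or
|atanh rho_A − atanh rho_B| over significant differential edges for
"difference" rankings — with n_sig counting the summed edges. Absolute
values are used (a strong negative correlation is as much "involvement" as
a positive one) and only qualifying edges are summed; both are exposed as
toggles since the convention is not uniquely determined. |rho| = 1 edges
contribute atanh(0.999) ≈ 3.8 with a warning, keeping scores finite.

Confounder analysis re-tests *only* the already-identified differential
edges across a binary stratification (prenatal inflammation, or a
median split of birth-weight SDS with ties assigned to the lower stratum);
strata under 4 subjects make an edge not-evaluable rather than an error.
No new discovery happens inside strata, mirroring the original design and
keeping the multiplicity burden fixed.

## The synthetic cohort generator

The generator is a latent-Gaussian copula with log-normal marginals:
log10 concentration = base_mean + ga_slope · (GA − ga_ref) + noise_sd ·
latent, with the latent vector drawn per timepoint with a per-group
correlation matrix, GA uniform over 22–27.9 weeks (ga_ref 24), and
defaults of 36 subjects per group, sampling days {0, 1, 7, 14, 28} and 5%
sample-level missingness (whole blood draws go missing, not single
analytes). The default panel carries plausible detection limits and
marginal parameters — they are synthetic, not assay-sheet values — with
heavy censoring (85% below LOD) for the five low-abundance cytokines and
light censoring (5%) for the rest. A requested below-LOD fraction is
honoured by inverting the marginal mixture CDF (normal conditional on GA,
GA uniform) for the implied detection limit. Planted correlation
structures that break positive semidefiniteness (e.g. a 0.8 star, which is
PSD only up to 1/√k for k leaves) are repaired by eigenvalue clipping and
diagonal rescaling — the simplest deterministic repair — with a warning
whenever a planted edge moves more than 0.05.

Under this model a planted latent correlation ρ appears as a Spearman rho
of (6/π)·asin(ρ/2) (≈ 0.777 for ρ = 0.8), which the calibration tests use.
An optional AR(1) parameter couples a subject's latent vectors across
days while preserving each day's cross-sectional correlation matrix; no
default autocorrelation is claimed because longitudinal cytokine
autocorrelation in this population is not characterised. Outcome labels
are assigned by block (first n subjects vs rest), with an optional
logistic GA link used by the confounding tests.

What the generator does **not** emulate: assay batch effects and plate
drift, treatment interventions (transfusions, steroids) that perturb real
trajectories, heavy-tailed or bimodal marginals, outcome-dependent
missingness, and the correlated confounder structure of a real NICU cohort
(its confounder flags are independent coin flips). Passing tests therefore
demonstrate that the *machinery* is correct and well calibrated under the
stated generative model, not that the pipeline's findings on any real
cohort are biologically valid.

## Numerical and testing choices

- PSD repair tolerance: matrices with minimum eigenvalue ≥ −1e−10 are
  accepted as-is; a 1e−10 diagonal jitter stabilises the Cholesky draw.
- atanh arguments are clamped to ±(1 − 1e−12) in the Fisher-z statistic so
  |rho| = 1 gives a finite, extreme z rather than NaN.
- Exact-fit detection in residualization uses a relative 1e−10 threshold on
  the residual SD, returning a zero column (the degenerate-but-legal case)
  and erroring only on constant *nonzero* residuals.
- Wilcoxon and Fisher tests delegate to `stats::wilcox.test` /
  `stats::fisher.test`, whose conventions (exact small-sample enumeration,
  tie-corrected normal approximation; two-sided "sum of point probabilities
  ≤ observed") match the published clinical tables to all printed decimals.
- Simulation sizes in the test suite were chosen so that each asserted
  proportion has comfortable binomial headroom at its threshold: 1000
  replicates for type-I error bands of ±0.02, 200 cohorts for the ≥ 80%
  planted-edge recovery, 100 cohorts at 300 subjects/group for the ≥ 95%
  GA-ablation criterion (at a few hundred subjects total the null Spearman
  SD of ~1/√n would make |rho| < 0.1 itself a coin flip, so the cohort size
  is what makes that bound meaningful), and 100 cohorts for star-hub
  recovery. The full suite runs in well under two minutes on one core.

## Known limitations

- The difference test assumes approximately elliptical dependence within
  groups; the permutation method is the fallback when that is doubtful.
- The per-edge p from the t approximation is mildly anticonservative below
  n ≈ 10; such small strata are reported not-evaluable in stratified
  re-tests but per-group networks will still print p-values at n ≥ 4.
- GA correction is linear and single-covariate by design; other confounders
  are handled by stratification, not joint regression.
- Interpolation assumes log-linear kinetics between sampled days, which is
  a modelling convenience, not pharmacokinetics.
- With ~231 edges per network and no multiplicity correction, every
  differential edge list contains an expected α-fraction of false
  positives; the package surfaces BH-adjusted p-values but never uses them
  for flagging.
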