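# dcornet

Differential Spearman correlation networks for longitudinal biomarker
panels, built for the setting where they were first applied: serum cytokine
and growth-factor (GF) profiles of extremely preterm infants at risk of
retinopathy of prematurity (ROP) and bronchopulmonary dysplasia (BPD). The
premise is that small but *coordinated* shifts in inflammatory proteins can
mark disease mechanisms that single-analyte level comparisons miss, so the
unit of analysis is the correlation structure of the panel, compared between
infants with and without an outcome.

Because such neonatal datasets are typically restricted by ethical permits,
the package ships a seeded synthetic-cohort generator with the same
statistical anatomy (gestational-age-dependent log-normal analyte levels,
group-specific correlation structure, detection-limit censoring, sporadic
missingness), so the entire pipeline is testable and demonstrable without
any patient data.

## The method

For each outcome group *g* and analyte pair *(i, j)*, the edge weight is the
Spearman rank correlation &rho;<sub>ij</sub><sup>(g)</sup> (Pearson
correlation of mid-ranks), with a per-edge p-value from the t
approximation *t = &rho;&radic;((n&minus;2)/(1&minus;&rho;&sup2;))*. An edge
is *differential* when its correlation differs between the groups; the
default test is the Fisher-z statistic

&nbsp;&nbsp;&nbsp;&nbsp;z = (atanh &rho;<sub>A</sub> &minus; atanh &rho;<sub>B</sub>) / &radic;(c/(n<sub>A</sub>&minus;3) + c/(n<sub>B</sub>&minus;3)), &nbsp; c = 1.06,

where *c* is the Fieller variance factor appropriate for Spearman
correlations; a seeded permutation test and a bootstrap rank-sum variant
(flagged heuristic) are alternatives. Edges with p &lt; 0.05 are flagged
without multiple-testing correction, by design of the analysis; a
Benjamini–Hochberg column is emitted for information.

Around that core:

- **Preprocessing** per the study's rules: below-detection values imputed as
  LOD/8, log10 transform, missing samples interpolated linearly in day on
  the log scale, analytes that are &gt;3/4 below-LOD in any subgroup
  excluded, complete-case assembly per timepoint, and a "first month"
  summary as trapezoidal AUC/time over days 7–28.
- **Gestational-age correction**: per-analyte OLS of log concentration on GA
  over the pooled cohort, networks rebuilt from standardized residuals.
- **Hub ranking**: each analyte scored by the sum of |atanh &rho;| over its
  significant edges (entire network) or |atanh &rho;<sub>A</sub> &minus;
  atanh &rho;<sub>B</sub>| over its differential edges (difference network).
- **Confounder strata**: differential edges re-tested across binary splits
  (prenatal inflammation HCA/FIRS; birth-weight SDS median split).
- **Level comparisons**: per-analyte Wilcoxon rank-sum tests, raw and
  GA-corrected, plus Fisher's exact test for clinical 2×2 count tables.

## Worked example

Simulate a 60-infant cohort in which EPO, G-CSF and IL-8 form a correlated
triangle only in the severe-ROP group, then run the full pipeline on cord
blood:

```r
library(dcornet)

panel <- preterm_panel()                       # 17 cytokines + 5 GFs
base <- diag(nrow(panel)); dimnames(base) <- list(panel$name, panel$name)
rop_R <- make_group_correlation(base, data.frame(
  i = c("EPO", "G-CSF", "EPO"), j = c("IL-8", "IL-8", "G-CSF"),
  rho = c(0.8, 0.8, 0.64)))

cfg <- cohort_config(analytes = panel, n_per_group = 30,
                     groups = c("severe_ROP", "no_ROP"),
                     group_correlations = list(severe_ROP = rop_R, no_ROP = base),
                     seed = 2024)
generate_cohort(cfg)
#> Synthetic cohort: 60 subjects (30 severe_ROP / 30 no_ROP), 22 analytes, days {0, 1, 7, 14, 28}
#> Record status: below_lod=1341, missing=396, observed=4863

run <- run_pipeline(pipeline_config(simulate = cfg, outcome = "group",
                                    timepoints = "cord", seed = 11,
                                    out_dir = "rop_run"))
edges <- run$cord$diff
edges[edges$significant, c("analyte_i", "analyte_j", "rho_A", "rho_B", "p_diff")]
#>     analyte_i analyte_j  rho_A   rho_B   p_diff
#> 17        EPO     G-CSF  0.682  0.1833 2.33e-02
#> 26        EPO      IL-8  0.784 -0.0227 1.61e-04
#> 40      G-CSF      IL-8  0.832 -0.1655 1.91e-06
#> ...
head(run$cord$hubs_diff, 4)
#>    analyte z_sum n_sig rank
#> 12    IL-8  5.14     6    1
#> 3    G-CSF  2.84     3    2
#> 2      EPO  2.38     3    3
#> 16   TNF-a  1.50     2    4
```

All three planted edges are recovered (rho ≈ 0.68–0.83 in the severe-ROP
group versus ≈ 0 in the no-ROP group, p_diff well below 0.05), and the
difference-network hub ranking puts IL-8 — the analyte shared by both
planted edges — at rank 1; the remaining flagged edges are the expected
~5% false positives among the 231 pairs tested at α = 0.05. The run
directory contains the edge list (`cord/edges.csv`), per-group GraphML
networks, hub rankings, level comparisons, confounder strata, a
`preprocess.json` report (e.g. the five heavily censored cytokines IL-4,
IL-7, IL-12, IL-13 and GM-CSF dropped by the 3/4 rule), a `manifest.json`
sufficient to reproduce the run, and a human-readable `report.md`.

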