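# File schemas

All CSVs are UTF-8, comma-delimited, with a header row. Writers may prepend
`# seed: <int>` comment lines; readers skip lines starting with `#`.

## panel.csv (long-format measurements)

| column | type | notes |
|---|---|---|
| subject_id | string | |
| analyte | string | must appear in analytes.csv |
| day | integer | day offset (0 = cord, 1 = day one, ...) |
| value | number or empty | concentration in assay units (raw) or log10 (matrices) |
| status | enum | observed, below_lod, missing, imputed_lod, interpolated, summary |

`value` is present iff status is observed/imputed_lod/interpolated/summary.
(subject_id, analyte, day) is unique.

## subjects.csv

| column | type | notes |
|---|---|---|
| subject_id | string | |
| group | string | outcome label, e.g. severe_ROP / no_ROP |
| ga_weeks | number | gestational age, weeks |
| bw_sds | number | birth-weight SD score |
| sex | string | male/female |
| hca_firs | 0/1 | prenatal inflammation flag |
| sga | 0/1 | small-for-gestational-age flag |

## analytes.csv

| column | type | notes |
|---|---|---|
| name | string | unique |
| class | enum | cytokine, growth_factor |
| detection_limit | number > 0 | assay units |
| base_mean, ga_slope, noise_sd, lod_quantile | number | generator parameters (optional for real data) |

## <timepoint>/matrix.csv

`subject_id` column plus one numeric column per analyte (log10 scale,
complete-case).

## <timepoint>/edges.csv (differential network)

`analyte_i, analyte_j` (lexicographic, each unordered pair once), `rho_A,
p_A, rho_B, p_B` (per-group Spearman rho and p), `p_diff`, `p_diff_bh`
(Benjamini-Hochberg, informational only), `significant` (p_diff < alpha).

## <timepoint>/hubs_entire_<group>.csv and hubs_difference.csv

`analyte, z_sum, n_sig, rank` — summed |atanh rho| (or |atanh rho_A −
atanh rho_B|) over qualifying edges, their count, and rank by descending
z_sum.

## <timepoint>/levels.csv

`analyte`, `median_outcome, min_outcome, max_outcome`, `median_reference,
min_reference, max_reference` (raw concentration units), `p_raw`,
`p_corrected` (GA residuals), `direction` (up/down in the outcome group).

## <timepoint>/strata_<confounder>.csv

`analyte_i, analyte_j, n1, n0, rho_stratum1, rho_stratum0, p_diff, flagged,
evaluable` — significant differential edges re-tested across the binary
confounder split.

## <timepoint>/network_<group>.graphml

Undirected graph; node attribute `class` (cytokine/growth_factor); edge
attributes `weight` (Spearman rho), `sign` (positive/negative), `p`. Edges
with p < alpha only.

## manifest.json / preprocess.json

Run metadata: package version, outcome, timepoints, method, alpha,
n_resample, seeds, and per-timepoint counts (subjects, analytes, values
interpolated, analytes excluded, significant edges). No timestamps, so
identical config + seed reproduces byte-identical output.
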