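# File formats

All artifacts are plain text (CSV via `data.table::fwrite`, YAML for
metadata) except fitted models, which persist as RDS at run time.

## Voltage traces (`write_trace_csv`)
Two columns: `time_ms` (uniform grid, ms), `vm_mV` (membrane voltage, mV).

## Simulation libraries (`write_library`, one directory)
- `theta.csv` — one row per simulation, 13 columns named as `param_names()`:
  `C` (uF/cm2), `Rinput` (MOhm), `tau` (ms), `gNat`, `gNa`, `gKd`, `gM`,
  `gKv31`, `gL` (mS/cm2), `Eleak` (mV), `tau_max` (ms), `VT` (mV),
  `rSS` (dimensionless).
- `features_raw.csv` — 23 columns named as `feature_names()`; voltages in
  mV, widths/latency/ISIs in ms, counts dimensionless; `NA` = undefined.
- `features_transformed.csv` — same columns after the Gaussianizing
  transforms, plus a logical `defined` column.
- `meta.yaml` — prior box, protocol fields, seed.

## Cohorts (`write_cohort`, one directory)
- `truth_theta.csv` — ground-truth parameters, columns as above.
- `features.csv` — raw features plus `well_defined` (logical) and `family`.
- `expression.csv` — negative-binomial counts, one column per gene.
- `truth_loadings.csv` — `gene`, `loading_1`, `loading_2`, `active`.
- `cohort.yaml` — generator configuration and seed.

## Pipeline outputs (`run_pipeline`, under `out_dir`)
- cohort files as above; `library/` as above.
- `posterior_model.rds`, `srrr_model.rds` — fitted models.
- `fit_per_cell.csv` — `cell`, `map_defined`, `map_distance` (Z units),
  `post_fail_rate` (fraction), `post_distance` (Z units), `entropy`
  (nats, Monte-Carlo posterior entropy).
- `fit_aggregate.csv` — `map_fail_pct`, `map_dist_mean`, `map_dist_sd`,
  `post_fail_pct`, `post_dist_mean`, `post_dist_sd`.
- `cv_curve.csv` — `lambda`, `r2_mean`, `r2_sd`, `n_genes_mean`.
- `r2_per_parameter.csv` — `parameter`, `r2`.
- `latent.csv` — two latent coordinates per cell.
- `group_distances.csv` — per-family contribution and total Z-space
  distance between group-averaged fitted and predicted parameters.
- `run_info.yaml` — package version, seed, resolved config, config hash.
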