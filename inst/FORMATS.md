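# File formats

All files are UTF-8 text with `.` as the decimal separator.

## Taylorgram CSV

Header required. One row per detector sample.

| column      | type    | meaning                          |
|-------------|---------|----------------------------------|
| `time_s`    | numeric | detector time, s; strictly increasing, uniform |
| `signal_au` | numeric | fluorescence, arbitrary units    |

Read/write: `readTaylorgram()`, `writeTaylorgram()`. Run metadata
(capillary geometry, protocol) is not stored in the CSV; it is supplied
when reading, or via the run configuration.

## Binding-curve CSV

| column      | type    | meaning                               |
|-------------|---------|---------------------------------------|
| `conc`      | numeric | analyte concentration (>= 0)          |
| `unit`      | string  | concentration unit tag, single value per file (`ug_per_ml`, `mg_per_ml`) |
| `r_app_nm`  | numeric | apparent hydrodynamic radius, nm      |
| `replicate` | integer | replicate index                       |

Read/write: `readBindingCurve()`, `writeBindingCurve()`.

## Cohort CSV

One row per sample. Required columns:

| column      | type    | meaning                               |
|-------------|---------|---------------------------------------|
| `sample_id` | string  | unique sample identifier              |
| `group`     | string  | `control`, `trauma`, `sepsis`, `septic_shock` |
| `r_capmix`  | numeric | capillary-mix hydrodynamic radius, nm |
| `r_capdis`  | numeric | complex-dissociation radius, nm       |

Optional columns used by the analysis when present: `sofa` (integer),
`ventilated`, `survived` (logical), `crp` (mg/L), `lcms_frac_hsa`,
`lcms_frac_hdl` (fractions in [0, 1]), `delta_rh` (recomputed by the
analysis). The generator writes additional latent columns (`*_true`,
`kd_hsa_eff_ug_ml`, ...) that pass through unchanged.

Read/write: `readCohort()`, `writeCohort()`.

## Run configuration YAML

Produced by `writeRunConfig(defaultRunConfig(), path)`; nested keys
`seed`, `capillary` (radius m, length m, temperature K, viscosity Pa s,
residence_time s), `protocols` (indicator nM per method), `fitting`
(target S/N, sampling step), `flip_sign`, `skip_taylorgrams`,
`profiles` (the group-profile table, column-wise) and `coupling`
(outcome-link and noise parameters). Round-trips losslessly through
`readRunConfig()`.

## Pipeline report

`runPipeline()` writes TSV summary tables (`group_summary.tsv`,
`sofa_summary.tsv`, `pairwise_tests.tsv`, `correlations.tsv`,
`outcomes.tsv`), the cohort CSV, a copy of the configuration, a
structured `pipeline.log`, and `report.json` mirroring the tables.
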