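# fidashift

Flow-induced dispersion analysis (FIDA) of sphingosine 1-phosphate (S1P)
carrier partitioning, and the hydrodynamic-radius shift statistic used as
a sepsis-outcome marker.

S1P circulates bound to albumin (HSA) and to the ApoM protein of HDL; in
systemic inflammation the partition shifts from HSA toward HDL, and very
low S1P–HDL complex formation marks septic-shock patients at risk. FIDA
measures the partition directly in diluted plasma: a fluorescent S1P
analog is dispersed in laminar capillary flow, and the width of the
detector-time peak (the *Taylorgram*) encodes the diffusion coefficient
`D` of the complex it sits in, via the Taylor–Aris relation

    sigma_t^2 = r_c^2 * t_R / (24 * D),

and hence the hydrodynamic radius through Stokes–Einstein,
`R_h = k_B T / (6 pi eta D)`. Two protocol variants separate the
carriers kinetically — the capillary-mix method (CapMix, 50 nM
indicator) sees only the fast-associating HSA complex, while the
complex-dissociation method (CapDis, 500 nM, pre-equilibrated) also sees
the slowly forming HDL complex — so the carrier-shift statistic

    delta R_h = R_h(CapDis) - R_h(CapMix)

cancels the shared HSA contribution and indexes S1P reallocation toward
HDL.

The package implements, end to end:

* **physics** — Taylorgram simulation from first principles, regime
  checks, and a brute-force Langevin dispersion oracle;
* **fitting** — baseline correction, single- and two-species
  shared-center Gaussian fits, polydispersity index, signal-to-noise;
* **binding** — 1:1 fast-exchange isotherm fits (`K_D`), two-carrier
  competition with the CapMix kinetic attenuation, and mass/molar
  affinity conversions;
* **carrier_shift** — the cohort pipeline: `delta R_h`, SOFA
  reclassification, exact/approximate Mann–Whitney tests, Spearman
  correlation against LC-MS/MS carrier fractions, and outcome
  association in the severe subgroups;
* **synthetic_data** — a seeded cohort generator (the study's group
  sizes, carrier-concentration medians and outcome couplings) plus an
  isotope-dilution LC-MS/MS emulation;
* **io** — CSV/YAML/JSON interchange (see `inst/FORMATS.md`) and
  `runPipeline()`, with a thin CLI wrapper in `inst/scripts/`.

## Worked example

Simulate a Taylorgram of the S1P–HSA complex (3.5 nm) with baseline
drift at assay-level signal-to-noise, and fit it back:

```r
library(fidashift)
tg <- simulateTaylorgram(data.frame(rH = 3.5, fraction = 1),
                         capMixProtocol(), CapillarySetup(),
                         baseline = c(2, 0.003), noiseSd = 0.023, seed = 7)
fitSingleSpecies(tg)
#> FitReport (1 species, converged)
#>   rH = 3.499 nm  sigma = 8.652 s  area = 100.0%
#>   PDI = 0  S/N = 103.6  RSS = 1.278
```

The fitted radius recovers the 3.5 nm truth to 0.03%, the peak width of
8.65 s is what the Taylor–Aris relation predicts for that size in the
default capillary, and the S/N of ~104 is above the instrument's
interpretability floor of 30.

Fit a seeded HSA titration generated at `K_D = 20` µg/mL with 1% noise,
and convert to molar units:

```r
conc <- rep(c(0, 2, 5, 10, 20, 40, 80, 160, 320, 640, 1280, 2560), each = 3)
set.seed(11)
rapp <- isothermRapp(conc, 20, 1, 3.5) * (1 + rnorm(length(conc), 0, 0.01))
fitBindingCurve(BindingCurve(conc, rapp, rep(1:3, 12)))
#> BindingFit: K_D = 20.67 ug_per_ml (SE 0.209)
#>   r_free = 1.003 nm, r_complex = 3.493 nm, RSS = 0.001421
round(massToMolarKd(20, 66.5))   # 301 nM
round(apomEquivalentKd(1.25), 1) # 1.8 uM per ApoM for the HDL affinity
```

Generate a synthetic cohort (14 controls, 11 trauma, 36 sepsis, 16
septic shock) and run the full analysis:

```r
cohort <- generateCohort(seed = 1)
res <- runCohortAnalysis(cohort)
subset(groupSummary(res), variable == "delta_rh")
#>           group variable  n       mean         sd
#>         control delta_rh 14 0.08846848 0.08756901
#>          trauma delta_rh 11 0.88007499 0.31818956
#>          sepsis delta_rh 36 0.73804545 0.31763930
#>    septic_shock delta_rh 16 0.81906403 0.70952230
```

Every patient group sits well above the controls (the carrier shift
toward HDL), and the septic-shock group has by far the largest spread —
its low-`delta R_h` tail is the poor-outcome subgroup. The outcome table
makes that explicit:

```r
subset(cohortOutcomes(res), subgroup == "septic_shock")
#>    measure    outcome nYes nNo  medianYes   medianNo  U            p
#>   r_capdis ventilated   10   6   3.324005   4.701291  1 0.0004995005
#>   r_capdis   deceased    6  10   3.250291   4.346088  2 0.0009990010
#>        crp ventilated   10   6 270.509314  58.993782 60 0.0002497502
#>        crp   deceased    6  10 318.646314 109.133289 47 0.0726773227
```

The CapDis radius separates both ventilation and survival (exact
Mann–Whitney p < 0.001), while CRP tracks ventilation but fails to
separate survivors from the deceased (p = 0.073) — the contrast the
shift statistic is valuable for. `runPipeline(defaultRunConfig(seed = 1),
"report/")` writes the same analysis as TSV/JSON reports.

## Documentation

The methods vignette (`vignettes/fida-carrier-shift.Rmd`) describes the
dispersion model and its regime of validity, the fitting and binding
conventions (PDI definition, detection-limit guard, effective in-plasma
affinities), the statistics, what the synthetic generator does and does
not emulate, and the package's numerical choices. File formats are
specified in `inst/FORMATS.md`.
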