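---
title: "Methods: FIDA-based measurement of S1P carrier partitioning"
author: "fidashift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FIDA-based measurement of S1P carrier partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fidashift)
```

## The measurement problem

Sphingosine 1-phosphate (S1P) circulates bound to two carriers: albumin
(HSA) and the ApoM protein of HDL particles. Which carrier holds the
lipid matters clinically — HDL-bound S1P drives the endothelial-protective
signaling, and in systemic inflammation the partition shifts. Flow-induced
dispersion analysis (FIDA) probes the partition directly in diluted
plasma: a fluorescent S1P analog (S1P-FITC) is dispersed in laminar
capillary flow, and the width of the detector-time peak (the *Taylorgram*)
encodes the diffusion coefficient, hence the hydrodynamic radius $R_h$, of
whatever complex the indicator sits in. Free indicator is small
($\approx 1$ nm), the HSA complex intermediate ($\approx 3.5$ nm), the
HDL complex large ($\approx 6$ nm), so the apparent radius is a
population-weighted readout of the partition.

Two protocol variants separate the carriers kinetically:

* **capillary mix (CapMix)** — indicator and analyte meet inside the
  capillary during mobilization. Only the fast-associating HSA complex
  forms before detection; HDL association is too slow. Indicator 50 nM.
* **complex dissociation (CapDis)** — indicator and analyte are
  pre-equilibrated (>10 min) and the plug is mobilized with buffer, so the
  equilibrated mixture, including the HDL complex, is observed.
  Indicator 500 nM (the higher concentration overcomes the HSA
  autofluorescence background).

The *carrier-shift statistic* is
$\Delta R_h = R_h^{\mathrm{CapDis}} - R_h^{\mathrm{CapMix}}$: HSA affects
both methods about equally and cancels, HDL only enters CapDis, so a
positive shift indexes S1P reallocation toward HDL. The sign convention
is configurable (`flipSign`) because the opposite order is equally
defensible; the default makes the patient-side shift positive.

## Dispersion physics

The Taylor–Aris model gives, for a species with diffusion coefficient $D$
in a capillary of radius $r_c$ and residence time $t_R$, a Gaussian
detector peak of temporal variance

$$\sigma_t^2 = \frac{r_c^2\, t_R}{24\, D},$$

and the Stokes–Einstein relation converts $D$ to the hydrodynamic radius
$R_h = k_B T / (6 \pi \eta D)$. Axial molecular diffusion is neglected
(pure Taylor regime); `taylorValidity()` guards the two standard regime
conditions, the dimensionless residence time $\tau = D t_R / r_c^2 \ge
1.4$ and the Péclet number $Pe = u r_c / D \ge 69$ (both inclusive,
thresholds configurable). For every complex size this assay works with
(1–12 nm) the default geometry is comfortably inside the regime
($\tau \approx 8$ at 3.5 nm).

`langevinDispersionVariance()` provides an independent numerical route:
random walkers diffuse over the capillary cross-section (reflecting wall)
while advected by the parabolic Poiseuille profile, and the variance of
their axial positions estimates the same quantity. Because the closed
form is the *asymptotic* dispersion rate, the walkers are pre-equilibrated
for one residence time and the variance accrued over the following
residence time is reported, which cancels the $O(r_c^2/15D)$ start-up
transient (at $\tau = 1.4$ that transient alone is a $\sim 5\%$ effect).
The oracle shares no code with `temporalVariance()` and the test suite
holds the two routes to 5% agreement.

### Instrument defaults

The assay's capillary geometry is not published, so the package uses
typical single-capillary FIDA values, all configurable through
`CapillarySetup()`: inner radius 37.5 µm, 0.84 m to the detector,
residence time 120 s (consistent with a 400 mbar / 200 s mobilization
step reaching the detector before the step ends). Temperature is
310.15 K — the capillary is thermostatted at 37 °C — with the viscosity
of water at that temperature, 6.913e-4 Pa s. Because the instrument's
effective calibration is unknown, exact numerical agreement with vendor
software output is not claimed; all downstream statistics are relative.

## Fitting Taylorgrams

`fitSingleSpecies()` fits $A \exp(-(t-t_R)^2/2\sigma^2)$ by
Levenberg–Marquardt least squares (`minpack.lm`), after removing a linear
baseline fitted to the samples outside the apex ± 4 initial-σ window
(`correctBaseline()`; the slight baseline drift seen with plasma analytes
is exactly this kind of nuisance). Numerical choices:

* width parameterized as $\log\sigma$, so negative widths cannot occur;
* initialization from the argmax (center), FWHM/2.355 (width) and the
  maximum (amplitude), computed on an edge-detrended copy of the trace;
* three width-jittered restarts (×1, ×0.7, ×1.4), lowest RSS wins;
* convergence tolerance 1e-10 on the relative RSS change, 500 iterations
  maximum; non-convergence is flagged in the report, never raised.

`fitTwoSpecies()` is the multiple-species analysis: two Gaussians with a
shared center and distinct widths, the narrower (smaller-radius)
component interpreted as free indicator, optionally pinned to a known
free radius. Three guards flag the fit *degenerate* — the single-species
result is then returned instead: width ratio below 1.05
(indistinguishable components), residual sum of squares above the
single-species fit, or any component amplitude at or below 3× the
baseline noise SD. The last rule is a standard limit of detection: an
unconstrained second Gaussian will happily park a sub-noise "species" at
an extreme radius, which is a noise artifact, not a detection, and would
corrupt the polydispersity index. Because the single-species solution is
among the two-species starting points, the two-species RSS never exceeds
the single-species RSS.

The **polydispersity index** uses the area-weighted relative variance of
the fitted radii (the dynamic light scattering convention, which the
monodispersity threshold language implies; the vendor definition is
unpublished):
$\mathrm{PDI} = \sum_i f_i (r_i - \bar r)^2 / \bar r^2$ with
$\bar r = \sum_i f_i r_i$; below 0.5 counts as monodisperse. The
**signal-to-noise ratio** is the corrected peak amplitude over the
baseline noise SD, the latter estimated from first differences
(`sd(diff)/√2`) outside an apex ± 6σ window so the smooth residual peak
tail does not count as noise; S/N ≥ 30 is flagged interpretable and a
noise-free trace reports `Inf`.

## Binding models

Titrations are fitted with the fast-exchange population-weighted radius
for 1:1 binding with analyte in excess (the functional form the vendor
fits is not printed; this is the standard FIDA-literature closure):

$$r_{app}(c) = \left(1 - \frac{c}{K_D + c}\right) r_{free} +
  \frac{c}{K_D + c}\, r_{complex}.$$

`fitBindingCurve()` fits $\log K_D$ (positivity by parameterization) with
inverse replicate-variance weights when replicates exist, reports
standard errors, and flags a $K_D$ beyond 3× the largest tested
concentration as extrapolated. Indicator depletion is ignored (the
indicator is far below the binding-site concentrations at the assay's
50–500 nM).

The two-carrier competition (`mixtureRapp()`) partitions trace indicator
between free solution, HSA and HDL:

$$f_{free} = \frac{1}{1 + C_{HSA}/K_{HSA} + \beta\, C_{HDL}/K_{HDL}},$$

with $f_{HSA}, f_{HDL}$ the corresponding saturation terms times
$f_{free}$, and $r_{app}$ the fraction-weighted radius. $\beta$ encodes
the kinetic asymmetry of the methods: $\beta = 1$ for the
pre-equilibrated CapDis method, and $\beta = \alpha$ (default 0,
configurable in $(0,1]$) for CapMix, where the slow S1P–HDL association
has no time to act. This reproduces the assay's discrimination logic:
CapMix responds to HSA only; CapDis to both carriers.

Unit conversions are first-class operations because the assay reports
mass-concentration affinities: `massToMolarKd(20, 66.5)` ≈ 300 nM for
the HSA complex (HSA 66.5 kDa), and `apomEquivalentKd(1.25, 30, 21)` ≈
1.8 µM expresses the 1.25 mg/mL HDL-protein affinity per ApoM (30 mg
ApoM per g HDL protein, 21 kDa). The constants are configurable
arguments.

## Cohort statistics

Group comparisons use the two-sided Mann–Whitney U test with average-rank
ties. The null is enumerated exactly when the smaller group has ≤ 8
observations *and* the number of rank assignments is at most 2×10⁶
(exactness where feasible at desk scale; beyond the cap — e.g. 8 vs 36 —
the tie-corrected normal approximation with continuity correction is
used). All-tied data return p = 1 with a warning. Spearman correlations
are computed as Pearson on average ranks with pairwise deletion and a
t-approximate p-value; fewer than 4 complete pairs are refused. No
multiple-testing correction is applied — the analysis mirrors
per-contrast reporting, and the per-analysis n is always reported
alongside, since missing values are deleted pairwise.

`outcomeAssociation()` restricts to the septic-shock group (or the
reclassified SOFA ≥ 8 bin) and contrasts the CapDis radius and CRP
between ventilated/non-ventilated and survivors/deceased. The salient
pattern the pipeline is built to expose: the CapDis radius separates both
outcomes, while CRP tracks ventilation but not survival.

## The synthetic cohort generator

No patient-level data are public, so `generateCohort()` produces cohorts
with the statistical structure the analysis assumes; its defaults *are*
the study conditions (group sizes 14/11/36/16; HSA medians 43/25/22/17
g/L; HDL cholesterol 61/61/34/13 mg/dL, the trauma group keeping the
control HDL level; SOFA medians and IQRs 4 (3–5), 4 (2–6), 8 (7–11)).
Concentrations are log-normal (positive, right-skewed clinical analytes)
with IQR-matched spread where an IQR is stated; within-group radius
variances are free parameters, not reported facts.

One modeling decision deserves emphasis. At 10% plasma the HSA
concentration (1.7–4.3 mg/mL) saturates the 1:1 isotherm at
$K_D = 20$ µg/mL: concentration differences alone move the CapMix radius
by ~0.01 nm, far below the assay noise, and so cannot generate the
group separations the assay actually resolves. (The same tension shows up
in the free-indicator fractions: the plain isotherm predicts ~20% free
indicator at 5 mg/mL HDL where the instrument reports 2%.) The measured
radius in plasma reflects more than carrier concentration — carrier
modifications and competition by endogenous S1P both weaken the apparent
affinity. The generator therefore draws a per-sample *effective*
in-plasma HSA affinity (group medians 20/150/180/300 µg/mL, log-normal)
and a per-sample latent HDL-bound indicator fraction (logit-normal around
group medians 0.04/0.30/0.25/0.22, with a wide logit-SD of 1.2 in septic
shock that produces the heterogeneous low-complex subgroup). Both latent
radii still come out of `mixtureRapp()` with these per-sample effective
constants, so the generator and the analysis share one binding model.

Outcomes are minimal-mechanism logistic links on the latent CapDis
radius (negative coupling, slopes 2 for ventilation and 7 for death per
nm below 3.75 nm, intercepts set so a default cohort has roughly half
its shock patients ventilated and 3–4 deceased). CRP is log-normal
conditional on ventilation only (medians 220 vs 100 mg/L, sdlog 0.6), so
it is survival-uncoupled *by construction*; any residual CRP–survival
association in a finite cohort is leakage through the
ventilation–death correlation. Measurement noise: 1.5% CV on radii
(bracketing the assay's 0.4–1.6% replicate precision) and 20% CV on the
LC-MS emulation, deliberately noisier than FIDA, consistent with the
higher variation of processed-sample S1P measurements.

The LC-MS/MS emulation (`emulateLcms()`, `quantifyS1p()`) models
isotope-dilution quantification against 100 pmol of C17-S1P internal
standard through a linear area-ratio standard curve, with fraction-wise
recovery factors and multiplicative noise. Carrier fractions are reported
relative to the summed quantified fractions, so they never exceed 1.
What the generator does **not** emulate: chromatographic peak shapes,
ultracentrifugation and precipitation chemistry, serum-vs-plasma matrix
effects (the assay found none), photobleaching, detector nonlinearity, or
injection-plug width. Passing tests therefore demonstrate the pipeline's
statistical behavior under the assumed structure, not instrument-level
fidelity on real plasma.

## Problem sizes and reproducibility

The validation suite uses desk-scale sizes chosen as the package's own
test conditions: 200 seeded single-species fits for the precision
envelope and the 1–12 nm recovery sweep; 100 seeded titrations for the
K_D recovery bias/RMSE; 100 seeded cohorts for the directional clinical
patterns; 4×10⁴ walkers for the Langevin dispersion oracle. Every
stochastic routine takes an explicit seed and restores the caller's RNG
state, so identical inputs and seeds give identical outputs end to end
(`runPipeline()` writes byte-identical reports on reruns).

## Known limitations

* Only one- and two-species Gaussian models are provided; no N > 2
  deconvolution or regularized size-distribution inversion.
* The binding layer is 1:1 fast-exchange with effective constants;
  cooperative or multi-site binding and explicit kinetic (k_on/k_off)
  modeling are out of scope.
* The effective-affinity mechanism in the generator is a minimal
  plausible account of the in-plasma signal, not a validated biophysical
  model; magnitudes of group separations on synthetic data are design
  choices, and only directions and orderings are treated as testable.
* Survival-time modeling (Cox, Kaplan–Meier) and ROC benchmarking against
  CRP are deliberately absent.
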