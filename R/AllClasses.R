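#' @import methods
NULL

# ---------------------------------------------------------------------------
# CapillarySetup
# ---------------------------------------------------------------------------

#' Capillary geometry and run conditions
#'
#' Describes the fused-silica capillary and flow conditions of a FIDA run:
#' inner radius, length to the detection window, temperature, solvent
#' viscosity and mean flow velocity. The residence time is `length/velocity`.
#'
#' Instrument geometry is not published for the assay this package models;
#' the defaults (37.5 um radius, 0.84 m to detector, 120 s residence time)
#' are typical single-capillary FIDA values and are fully configurable. The
#' default temperature is 310.15 K (capillary thermostatted at 37 degC) with
#' the viscosity of water at that temperature.
#'
#' @slot radius Inner capillary radius, m.
#' @slot length Capillary length to the detector, m.
#' @slot temperature Absolute temperature, K.
#' @slot viscosity Dynamic viscosity of the run buffer, Pa s.
#' @slot meanVelocity Mean (cross-section averaged) flow velocity, m/s.
#' @name CapillarySetup-class
#' @rdname CapillarySetup
#' @exportClass CapillarySetup
setClass("CapillarySetup",
  representation(
    radius = "numeric",
    length = "numeric",
    temperature = "numeric",
    viscosity = "numeric",
    meanVelocity = "numeric"
  )
)

setValidity("CapillarySetup", function(object) {
  vals <- c(radius = object@radius, length = object@length,
            temperature = object@temperature, viscosity = object@viscosity,
            meanVelocity = object@meanVelocity)
  if (any(lengths(list(object@radius, object@length, object@temperature,
                       object@viscosity, object@meanVelocity)) != 1)) {
    return("all slots must be length-1 numerics")
  }
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    return("all capillary parameters must be strictly positive")
  }
  TRUE
})

#' @param radius,length,temperature,viscosity As the slots.
#' @param residenceTime Residence time to the detector, s. Exactly one of
#'   `residenceTime` and `meanVelocity` should be given; the other is derived
#'   via `residenceTime = length / meanVelocity`.
#' @param meanVelocity Mean flow velocity, m/s.
#' @return `CapillarySetup()` returns a validated object.
#' @examples
#' cap <- CapillarySetup()
#' residenceTime(cap)
#' @rdname CapillarySetup
#' @export
CapillarySetup <- function(radius = 37.5e-6, length = 0.84,
                           temperature = 310.15, viscosity = 6.913e-4,
                           residenceTime = 120, meanVelocity = NULL) {
  if (is.null(meanVelocity)) {
    .checkPositive(residenceTime = residenceTime)
    meanVelocity <- length / residenceTime
  } else if (!is.null(residenceTime)) {
    # Both given: they must agree.
    if (.relDiff(residenceTime, length / meanVelocity) > 1e-9) {
      stop("residenceTime is inconsistent with length/meanVelocity",
           call. = FALSE)
    }
  }
  new("CapillarySetup", radius = radius, length = length,
      temperature = temperature, viscosity = viscosity,
      meanVelocity = meanVelocity)
}

#' @param object,x A `CapillarySetup`.
#' @return `residenceTime()` returns the residence time in seconds.
#' @rdname CapillarySetup
#' @export
residenceTime <- function(object) object@length / object@meanVelocity

#' @rdname CapillarySetup
#' @export
capRadius <- function(object) object@radius

setMethod("show", "CapillarySetup", function(object) {
  cat("CapillarySetup\n")
  cat(sprintf("  radius: %.1f um  length: %.3g m  t_R: %.4g s\n",
              object@radius * 1e6, object@length, residenceTime(object)))
  cat(sprintf("  T: %.2f K  eta: %.4g Pa s  u: %.4g m/s\n",
              object@temperature, object@viscosity, object@meanVelocity))
})

# ---------------------------------------------------------------------------
# AssayProtocol
# ---------------------------------------------------------------------------

#' FIDA assay protocol
#'
#' The two assay modes differ in what fills the capillary during the final
#' mobilization step and in the indicator concentration:
#' \describe{
#'   \item{capillary_mix (CapMix)}{indicator and analyte mix inside the
#'     capillary during mobilization with analyte solution; only fast
#'     associating carriers (HSA) form complexes before detection.
#'     Default indicator 50 nM.}
#'   \item{complex_dissociation (CapDis)}{indicator and analyte are
#'     pre-equilibrated (>10 min) and the plug is mobilized with buffer;
#'     equilibrated complexes, including the slowly associating HDL
#'     complex, are detected. Default indicator 500 nM.}
#' }
#' Step tables carry the rinse/equilibration/fill/inject/mobilize sequence
#' (fluid, pressure in mbar, duration in s).
#'
#' @slot method `"capillary_mix"` or `"complex_dissociation"`.
#' @slot indicatorConc Indicator (S1P-FITC) concentration, nM.
#' @slot steps `data.frame` with columns `fluid`, `pressure_mbar`,
#'   `duration_s`.
#' @name AssayProtocol-class
#' @rdname AssayProtocol
#' @exportClass AssayProtocol
setClass("AssayProtocol",
  representation(
    method = "character",
    indicatorConc = "numeric",
    steps = "data.frame"
  )
)

setValidity("AssayProtocol", function(object) {
  if (!object@method %in% c("capillary_mix", "complex_dissociation")) {
    return("method must be 'capillary_mix' or 'complex_dissociation'")
  }
  if (length(object@indicatorConc) != 1 || !is.finite(object@indicatorConc) ||
      object@indicatorConc <= 0) {
    return("indicatorConc must be a positive scalar (nM)")
  }
  need <- c("fluid", "pressure_mbar", "duration_s")
  if (!all(need %in% names(object@steps)) || nrow(object@steps) < 1) {
    return("steps must have columns fluid, pressure_mbar, duration_s")
  }
  final <- object@steps$fluid[nrow(object@steps)]
  wantFinal <- if (object@method == "capillary_mix") "analyte" else "buffer"
  if (!identical(final, wantFinal)) {
    return(sprintf("final (mobilization) step fluid must be '%s' for %s",
                   wantFinal, object@method))
  }
  TRUE
})

# Shared capillary-conditioning steps of both protocols:
# NaOH rinse 3500 mbar 45 s, PBS equilibration 3500 mbar 75 s, analyte fill
# 3500 mbar 30 s, indicator injection 50 mbar 10 s, mobilization 400 mbar
# 200 s (with analyte for CapMix, with buffer for CapDis).
.protocolSteps <- function(mobilizeWith) {
  data.frame(
    fluid = c("NaOH_1M", "PBS", "analyte", "indicator", mobilizeWith),
    pressure_mbar = c(3500, 3500, 3500, 50, 400),
    duration_s = c(45, 75, 30, 10, 200),
    stringsAsFactors = FALSE
  )
}

#' @param indicatorConc Indicator concentration in nM.
#' @return `capMixProtocol()` / `capDisProtocol()` return ready-made
#'   `AssayProtocol` objects for the two modes.
#' @examples
#' capMixProtocol()
#' @rdname AssayProtocol
#' @export
capMixProtocol <- function(indicatorConc = 50) {
  new("AssayProtocol", method = "capillary_mix",
      indicatorConc = indicatorConc, steps = .protocolSteps("analyte"))
}

#' @rdname AssayProtocol
#' @export
capDisProtocol <- function(indicatorConc = 500) {
  new("AssayProtocol", method = "complex_dissociation",
      indicatorConc = indicatorConc, steps = .protocolSteps("buffer"))
}

setMethod("show", "AssayProtocol", function(object) {
  cat(sprintf("AssayProtocol: %s, indicator %g nM, %d steps\n",
              object@method, object@indicatorConc, nrow(object@steps)))
})

# ---------------------------------------------------------------------------
# Taylorgram
# ---------------------------------------------------------------------------

#' A Taylorgram: detector-time fluorescence trace
#'
#' The raw signal of a FIDA run: fluorescence versus time as the dispersed
#' indicator plug passes the detector. Sampling must be uniform; the peak
#' width encodes the diffusion coefficient of the fluorescent species.
#'
#' @slot time Time vector, s; strictly increasing, uniformly spaced
#'   (relative jitter below 1e-9).
#' @slot signal Fluorescence, arbitrary units; same length as `time`.
#' @slot capillary The [CapillarySetup] of the run.
#' @slot protocol The [AssayProtocol] of the run.
#' @slot noiseSd Additive white-noise SD used when simulated (AU; `NA` for
#'   measured data).
#' @slot baselineRemoved Offset and slope already subtracted from the trace
#'   (zero for raw data); updated by [correctBaseline()].
#' @slot seed Simulation seed (`NA` for measured data).
#' @name Taylorgram-class
#' @rdname Taylorgram
#' @exportClass Taylorgram
setClass("Taylorgram",
  representation(
    time = "numeric",
    signal = "numeric",
    capillary = "CapillarySetup",
    protocol = "AssayProtocol",
    noiseSd = "numeric",
    baselineRemoved = "numeric",
    seed = "numeric"
  )
)

setValidity("Taylorgram", function(object) {
  n <- length(object@time)
  if (n < 2) return("at least 2 samples required")
  if (length(object@signal) != n) return("time and signal lengths differ")
  dt <- diff(object@time)
  if (any(dt <= 0)) return("time must be strictly increasing")
  if (n > 2 && max(.relDiff(dt, mean(dt))) > 1e-9) {
    return("sampling interval must be uniform (relative jitter < 1e-9)")
  }
  if (length(object@baselineRemoved) != 2) {
    return("baselineRemoved must be length 2 (offset, slope)")
  }
  TRUE
})

#' @param time,signal,capillary,protocol,noiseSd,seed As the slots.
#' @return `Taylorgram()` returns a validated object.
#' @rdname Taylorgram
#' @export
Taylorgram <- function(time, signal, capillary = CapillarySetup(),
                       protocol = capMixProtocol(), noiseSd = NA_real_,
                       seed = NA_real_) {
  new("Taylorgram", time = as.numeric(time), signal = as.numeric(signal),
      capillary = capillary, protocol = protocol, noiseSd = noiseSd,
      baselineRemoved = c(0, 0), seed = seed)
}

setMethod("show", "Taylorgram", function(object) {
  n <- length(object@time)
  cat(sprintf("Taylorgram: %d samples, t = [%.4g, %.4g] s, dt = %.4g s\n",
              n, object@time[1], object@time[n],
              if (n > 1) object@time[2] - object@time[1] else NA))
  cat(sprintf("  method: %s, indicator %g nM\n",
              object@protocol@method, object@protocol@indicatorConc))
})

#' @rdname Taylorgram
#' @export
setGeneric("signalTime", function(x) standardGeneric("signalTime"))

#' @rdname Taylorgram
#' @export
setMethod("signalTime", "Taylorgram", function(x) x@time)

#' @rdname Taylorgram
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))

#' @rdname Taylorgram
#' @export
setMethod("signalValues", "Taylorgram", function(x) x@signal)

# ---------------------------------------------------------------------------
# FitReport
# ---------------------------------------------------------------------------

#' Result of fitting Gaussian species to a Taylorgram
#'
#' Holds the fitted species table (one row per species: center, width,
#' amplitude, area fraction, diffusion coefficient, hydrodynamic radius),
#' the removed baseline, polydispersity index, signal-to-noise ratio,
#' residual sum of squares, and convergence/degeneracy flags.
#'
#' @slot species `data.frame` with columns `tR` (s), `sigmaT` (s),
#'   `amplitude` (AU), `areaFraction`, `D` (m^2/s), `rH` (nm); rows sorted
#'   by `rH` ascending.
#' @slot baseline Removed `(offset, slope)`.
#' @slot pdi Polydispersity index (area-weighted relative variance of rH).
#' @slot snr Signal-to-noise ratio (peak amplitude over baseline SD).
#' @slot rss Residual sum of squares, AU^2.
#' @slot converged Optimizer convergence flag.
#' @slot degenerate `TRUE` when a two-species fit collapsed (width ratio
#'   below 1.05) and the single-species result was returned instead.
#' @slot nSpecies Number of species requested (1 or 2).
#' @name FitReport-class
#' @rdname FitReport
#' @exportClass FitReport
setClass("FitReport",
  representation(
    species = "data.frame",
    baseline = "numeric",
    pdi = "numeric",
    snr = "numeric",
    rss = "numeric",
    converged = "logical",
    degenerate = "logical",
    nSpecies = "numeric"
  )
)

setValidity("FitReport", function(object) {
  need <- c("tR", "sigmaT", "amplitude", "areaFraction", "D", "rH")
  if (!all(need %in% names(object@species))) {
    return("species table missing required columns")
  }
  if (nrow(object@species) >= 1) {
    if (any(object@species$sigmaT <= 0)) return("sigmaT must be positive")
    if (abs(sum(object@species$areaFraction) - 1) > 1e-6) {
      return("area fractions must sum to 1 (tolerance 1e-6)")
    }
  }
  if (length(object@pdi) == 1 && is.finite(object@pdi) && object@pdi < 0) {
    return("pdi must be non-negative")
  }
  TRUE
})

setMethod("show", "FitReport", function(object) {
  cat(sprintf("FitReport (%d species%s%s)\n", nrow(object@species),
              if (object@converged) ", converged" else ", NOT converged",
              if (object@degenerate) ", degenerate" else ""))
  sp <- object@species
  for (i in seq_len(nrow(sp))) {
    cat(sprintf("  rH = %.3f nm  sigma = %.3f s  area = %.1f%%\n",
                sp$rH[i], sp$sigmaT[i], 100 * sp$areaFraction[i]))
  }
  cat(sprintf("  PDI = %.4g  S/N = %.4g  RSS = %.4g\n",
              object@pdi, object@snr, object@rss))
})

#' @param object A `FitReport`.
#' @return `fittedSpecies()` returns the species table; `fittedRh()` the
#'   fitted radii (nm).
#' @rdname FitReport
#' @export
fittedSpecies <- function(object) object@species

#' @rdname FitReport
#' @export
fittedRh <- function(object) object@species$rH

# ---------------------------------------------------------------------------
# BindingCurve / BindingFit
# ---------------------------------------------------------------------------

#' Binding titration data
#'
#' Apparent hydrodynamic radius of the indicator as a function of analyte
#' concentration, possibly with replicates.
#'
#' @slot conc Analyte concentrations (>= 0), in `unit`.
#' @slot unit Concentration unit tag, e.g. `"ug_per_ml"` or `"mg_per_ml"`.
#' @slot rApp Apparent radii, nm.
#' @slot replicate Integer replicate index per observation.
#' @slot method Assay method the curve was acquired with.
#' @name BindingCurve-class
#' @rdname BindingCurve
#' @exportClass BindingCurve
setClass("BindingCurve",
  representation(
    conc = "numeric",
    unit = "character",
    rApp = "numeric",
    replicate = "integer",
    method = "character"
  )
)

setValidity("BindingCurve", function(object) {
  n <- length(object@conc)
  if (length(object@rApp) != n || length(object@replicate) != n) {
    return("conc, rApp and replicate must have equal length")
  }
  if (any(object@conc < 0)) return("concentrations must be >= 0")
  if (length(unique(object@conc)) < 5) {
    return("at least 5 distinct concentration levels required")
  }
  TRUE
})

#' @param conc,rApp,replicate,unit,method As the slots.
#' @return A validated `BindingCurve`.
#' @rdname BindingCurve
#' @export
BindingCurve <- function(conc, rApp, replicate = rep(1L, length(conc)),
                         unit = "ug_per_ml", method = "capillary_mix") {
  new("BindingCurve", conc = as.numeric(conc), rApp = as.numeric(rApp),
      replicate = as.integer(replicate), unit = unit, method = method)
}

setMethod("show", "BindingCurve", function(object) {
  cat(sprintf("BindingCurve: %d points, %d levels, unit %s, method %s\n",
              length(object@conc), length(unique(object@conc)),
              object@unit, object@method))
})

#' Fitted binding isotherm
#'
#' @slot kD Dissociation constant in the curve's concentration unit.
#' @slot kDse Standard error of `kD`.
#' @slot rFree,rComplex Free-indicator and complex radii, nm, with standard
#'   errors `rFreeSe`, `rComplexSe`.
#' @slot unit Concentration unit of `kD`.
#' @slot rss Residual sum of squares.
#' @slot converged Convergence flag.
#' @slot extrapolated `TRUE` when the fitted `kD` exceeds 3x the largest
#'   tested concentration (the estimate is an extrapolation).
#' @name BindingFit-class
#' @rdname BindingFit
#' @exportClass BindingFit
setClass("BindingFit",
  representation(
    kD = "numeric", kDse = "numeric",
    rFree = "numeric", rFreeSe = "numeric",
    rComplex = "numeric", rComplexSe = "numeric",
    unit = "character", rss = "numeric",
    converged = "logical", extrapolated = "logical"
  )
)

setMethod("show", "BindingFit", function(object) {
  cat(sprintf("BindingFit: K_D = %.4g %s (SE %.3g)%s%s\n",
              object@kD, object@unit, object@kDse,
              if (!object@converged) " [NOT converged]" else "",
              if (object@extrapolated) " [extrapolated]" else ""))
  cat(sprintf("  r_free = %.3f nm, r_complex = %.3f nm, RSS = %.4g\n",
              object@rFree, object@rComplex, object@rss))
})

# ---------------------------------------------------------------------------
# CarrierMixture
# ---------------------------------------------------------------------------

#' Two-carrier competitive binding mixture
#'
#' Parameters of the HSA/HDL competition for the fluorescent S1P indicator:
#' carrier concentrations, per-carrier dissociation constants, the radii of
#' the free indicator and of each complex, and the CapMix HDL attenuation
#' `alpha`. Because S1P association with HDL is much slower than with HSA,
#' the short in-capillary mixing time of the CapMix method yields little or
#' no HDL complex; `alpha` scales the effective HDL occupancy in that mode
#' (0 = none, the default; 1 = full equilibrium).
#'
#' Units are fixed by convention: `hsaConc` in mg/mL with `kdHsa` in ug/mL;
#' `hdlProteinConc` and `kdHdl` both in mg/mL HDL protein.
#'
#' @slot hsaConc HSA concentration, mg/mL.
#' @slot hdlProteinConc HDL protein concentration, mg/mL.
#' @slot kdHsa Indicator-HSA dissociation constant, ug/mL.
#' @slot kdHdl Indicator-HDL dissociation constant, mg/mL protein.
#' @slot rFree,rHsaComplex,rHdlComplex Hydrodynamic radii, nm.
#' @slot capmixHdlAttenuation `alpha` in `[0, 1]`.
#' @name CarrierMixture-class
#' @rdname CarrierMixture
#' @exportClass CarrierMixture
setClass("CarrierMixture",
  representation(
    hsaConc = "numeric",
    hdlProteinConc = "numeric",
    kdHsa = "numeric",
    kdHdl = "numeric",
    rFree = "numeric",
    rHsaComplex = "numeric",
    rHdlComplex = "numeric",
    capmixHdlAttenuation = "numeric"
  )
)

setValidity("CarrierMixture", function(object) {
  if (object@hsaConc < 0 || object@hdlProteinConc < 0) {
    return("carrier concentrations must be >= 0")
  }
  if (object@kdHsa <= 0 || object@kdHdl <= 0) return("K_D values must be > 0")
  if (object@capmixHdlAttenuation < 0 || object@capmixHdlAttenuation > 1) {
    return("capmixHdlAttenuation must be in [0, 1]")
  }
  if (any(c(object@rFree, object@rHsaComplex, object@rHdlComplex) <= 0)) {
    return("radii must be positive")
  }
  TRUE
})

#' @param hsaConc,hdlProteinConc,kdHsa,kdHdl,rFree,rHsaComplex,rHdlComplex
#'   As the slots. Default K_Ds are the fitted assay values (20 ug/mL HSA,
#'   1.25 mg/mL HDL protein); default radii are 1.0 nm (free S1P-FITC),
#'   3.5 nm (HSA complex) and 6.0 nm (HDL complex).
#' @param capmixHdlAttenuation CapMix HDL attenuation `alpha`, default 0.
#' @return A validated `CarrierMixture`.
#' @examples
#' mix <- CarrierMixture(hsaConc = 4, hdlProteinConc = 0.05)
#' mixtureRapp(mix, "complex_dissociation")
#' @rdname CarrierMixture
#' @export
CarrierMixture <- function(hsaConc, hdlProteinConc, kdHsa = 20,
                           kdHdl = 1.25, rFree = 1.0, rHsaComplex = 3.5,
                           rHdlComplex = 6.0, capmixHdlAttenuation = 0) {
  new("CarrierMixture", hsaConc = hsaConc, hdlProteinConc = hdlProteinConc,
      kdHsa = kdHsa, kdHdl = kdHdl, rFree = rFree,
      rHsaComplex = rHsaComplex, rHdlComplex = rHdlComplex,
      capmixHdlAttenuation = capmixHdlAttenuation)
}

setMethod("show", "CarrierMixture", function(object) {
  cat(sprintf(
    "CarrierMixture: HSA %.3g mg/mL (K_D %.3g ug/mL), HDL %.3g mg/mL (K_D %.3g mg/mL), alpha = %.2f\n",
    object@hsaConc, object@kdHsa, object@hdlProteinConc, object@kdHdl,
    object@capmixHdlAttenuation))
})

# ---------------------------------------------------------------------------
# CohortResult
# ---------------------------------------------------------------------------

#' Cohort analysis result
#'
#' Container for the end-to-end cohort analysis: per-group summaries of the
#' capillary-mix radius, complex-dissociation radius and their difference;
#' pairwise Mann-Whitney tests; FIDA vs LC-MS/MS Spearman correlations; and
#' outcome associations in the severe subgroups.
#'
#' @slot groupSummary `data.frame`: group, variable, n, mean, sd.
#' @slot pairwiseTests `data.frame`: variable, groupA, groupB, nA, nB, U, p.
#' @slot sofaSummary `data.frame` like `groupSummary` but over SOFA bins.
#' @slot correlations `data.frame`: comparison, rho, n, p.
#' @slot outcomes `data.frame` from [outcomeAssociation()] over subgroups.
#' @slot notes Character log of skipped or degenerate comparisons.
#' @name CohortResult-class
#' @rdname CohortResult
#' @exportClass CohortResult
setClass("CohortResult",
  representation(
    groupSummary = "data.frame",
    pairwiseTests = "data.frame",
    sofaSummary = "data.frame",
    correlations = "data.frame",
    outcomes = "data.frame",
    notes = "character"
  )
)

setMethod("show", "CohortResult", function(object) {
  cat("CohortResult\n")
  cat(sprintf("  %d group summaries, %d pairwise tests, %d correlations, %d outcome rows\n",
              nrow(object@groupSummary), nrow(object@pairwiseTests),
              nrow(object@correlations), nrow(object@outcomes)))
  if (length(object@notes)) cat("  notes:", length(object@notes), "entries\n")
})

#' @param object A `CohortResult`.
#' @return Accessors return the corresponding table.
#' @rdname CohortResult
#' @export
groupSummary <- function(object) object@groupSummary

#' @rdname CohortResult
#' @export
pairwiseTests <- function(object) object@pairwiseTests

#' @rdname CohortResult
#' @export
cohortCorrelations <- function(object) object@correlations

#' @rdname CohortResult
#' @export
cohortOutcomes <- function(object) object@outcomes
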