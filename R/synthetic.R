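# Synthetic cohort generator and LC-MS/MS emulation. Stands in for the
# non-public patient plasma; the defaults encode the study conditions the
# analysis is meant to face (group sizes, carrier-concentration medians,
# SOFA distributions, outcome couplings).

# HDL protein (mg/mL) per HDL cholesterol (mg/dL): ~0.5 mg/mL protein at a
# healthy 61 mg/dL, so 10% plasma of a healthy control carries ~0.05 mg/mL.
.HDL_PROTEIN_PER_CHOL <- 0.5 / 61

#' Default group profiles for the synthetic cohort
#'
#' One row per group with the group size, carrier-concentration medians
#' and log-normal dispersions, the effective in-plasma HSA affinity of the
#' indicator, the latent HDL-bound indicator fraction (logit-normal), and
#' the SOFA score median/IQR. Defaults:
#' \itemize{
#'   \item group sizes 14 / 11 / 36 / 16 (control, trauma, sepsis,
#'     septic shock);
#'   \item HSA medians 43 / 25 / 22 / 17 g/L; HDL cholesterol medians
#'     61 / 61 / 34 / 13 mg/dL (the trauma group keeps the control HDL
#'     level);
#'   \item SOFA median (IQR): trauma 4 (3-5), sepsis 4 (2-6), shock
#'     8 (7-11);
#'   \item effective in-plasma HSA K_D medians 20 / 150 / 180 / 300
#'     ug/mL: disease weakens apparent HSA binding beyond what the falling
#'     HSA concentration alone explains (carrier modification and
#'     endogenous competition), which is what shifts the capillary-mix
#'     radius down in patients;
#'   \item HDL-bound indicator fraction medians 0.04 / 0.30 / 0.25 /
#'     0.22, with a wide logit-SD of 1.2 in septic shock producing the
#'     heterogeneous low-complex subgroup.
#' }
#'
#' @return A `data.frame`, one row per group.
#' @export
defaultGroupProfiles <- function() {
  data.frame(
    group = c("control", "trauma", "sepsis", "septic_shock"),
    n = c(14L, 11L, 36L, 16L),
    hsaMedian = c(43, 25, 22, 17),          # g/L
    hsaSdlog = c(0.08, 0.10, 0.12, 0.12),
    hdlMedian = c(61, 61, 34, 13),          # mg/dL cholesterol
    hdlSdlog = c(0.12, 0.15, 0.20, 0.30),
    kdHsaEffMedian = c(20, 150, 180, 300),  # ug/mL
    kdHsaEffSdlog = c(0.20, 0.30, 0.30, 0.30),
    fracHdlMedian = c(0.04, 0.30, 0.25, 0.22),
    fracHdlSdLogit = c(0.35, 0.50, 0.60, 1.20),
    sofaMedian = c(NA, 4, 4, 8),
    sofaQ1 = c(NA, 3, 2, 7),
    sofaQ3 = c(NA, 5, 6, 11),
    stringsAsFactors = FALSE
  )
}

#' Default outcome-coupling and noise parameters
#'
#' Logistic links of mechanical ventilation and death on the latent
#' complex-dissociation radius (negative coupling: the less HDL complex a
#' patient forms, the likelier ventilation and death), CRP distributions
#' conditional on ventilation only (so CRP tracks ventilation but is
#' survival-uncoupled by construction), and measurement noise levels
#' (FIDA radius CV 1.5%, bracketing the assay's 0.4-1.6% precision;
#' LC-MS CV 20%, deliberately noisier than FIDA).
#'
#' @return A named list of parameters.
#' @export
defaultOutcomeCoupling <- function() {
  list(
    rhCenter = 3.75,       # nm; anchor of the logistic links
    ventIntercept = 0.2, ventSlope = 2,    # per nm below rhCenter
    deathIntercept = -2.2, deathSlope = 7,
    crpVentMedian = 220, crpNoVentMedian = 100,  # mg/L
    crpSdlog = 0.6,
    rhNoiseCv = 0.015,
    lcmsCv = 0.20,
    s1pTotalMedian = 400,  # pmol per processed sample
    s1pTotalSdlog = 0.25
  )
}

.logit <- function(p) log(p / (1 - p))

# Discretized log-normal matched to a median and IQR.
.drawSofa <- function(n, med, q1, q3) {
  sdlog <- (log(q3) - log(q1)) / (2 * stats::qnorm(0.75))
  pmin(24, pmax(0, round(stats::rlnorm(n, log(med), sdlog))))
}

#' Generate a synthetic patient cohort
#'
#' Draws, per sample: carrier concentrations (log-normal around the group
#' medians), the effective in-plasma HSA affinity and the latent HDL-bound
#' indicator fraction; converts to 10%-plasma assay concentrations;
#' derives the true capillary-mix and complex-dissociation radii through
#' [mixtureRapp()] with the per-sample effective dissociation constants;
#' adds multiplicative measurement noise; draws SOFA, then ventilation and
#' survival through logistic links on the latent complex-dissociation
#' radius, and CRP conditional on ventilation only; and emulates the
#' LC-MS/MS fractionation readout of endogenous S1P. Fully determined by
#' `(profiles, coupling, seed)`.
#'
#' @param profiles Group profile table, as [defaultGroupProfiles()].
#' @param coupling Coupling/noise parameters, as
#'   [defaultOutcomeCoupling()].
#' @param seed Integer seed.
#' @param lcms Also emulate the LC-MS/MS readout (default `TRUE`).
#' @return A `data.frame`, one row per sample, with true (latent) and
#'   observed radii, clinical covariates and LC-MS fractions.
#' @examples
#' cohort <- generateCohort(seed = 1)
#' table(cohort$group)
#' @export
generateCohort <- function(profiles = defaultGroupProfiles(),
                           coupling = defaultOutcomeCoupling(),
                           seed = NULL, lcms = TRUE) {
  need <- c("group", "n", "hsaMedian", "hsaSdlog", "hdlMedian", "hdlSdlog",
            "kdHsaEffMedian", "kdHsaEffSdlog", "fracHdlMedian",
            "fracHdlSdLogit", "sofaMedian", "sofaQ1", "sofaQ3")
  if (!is.data.frame(profiles) || !all(need %in% names(profiles))) {
    stop("invalid profiles: missing columns", call. = FALSE)
  }
  if (any(profiles$n <= 0)) stop("group n must be positive", call. = FALSE)
  if (any(profiles$hsaMedian <= 0) || any(profiles$hdlMedian <= 0)) {
    stop("concentration medians must be positive", call. = FALSE)
  }
  if (any(profiles$fracHdlMedian <= 0 | profiles$fracHdlMedian >= 1)) {
    stop("fracHdlMedian must be inside (0, 1)", call. = FALSE)
  }

  withSeed(seed, {
    rows <- list()
    for (i in seq_len(nrow(profiles))) {
      p <- profiles[i, ]
      n <- p$n
      isControl <- p$group == "control"

      hsa <- stats::rlnorm(n, log(p$hsaMedian), p$hsaSdlog)     # g/L
      hdl <- stats::rlnorm(n, log(p$hdlMedian), p$hdlSdlog)     # mg/dL
      kdEff <- stats::rlnorm(n, log(p$kdHsaEffMedian), p$kdHsaEffSdlog)
      fHdl <- stats::plogis(stats::rnorm(n, .logit(p$fracHdlMedian),
                                         p$fracHdlSdLogit))
      fHdl <- pmin(0.95, pmax(1e-4, fHdl))

      # 10% plasma assay concentrations.
      hsaAssay <- hsa * 0.1                              # mg/mL
      hdlAssay <- hdl * .HDL_PROTEIN_PER_CHOL * 0.1      # mg/mL protein

      rCmTrue <- rCdTrue <- bHsa <- numeric(n)
      for (k in seq_len(n)) {
        xHsa <- hsaAssay[k] * 1000 / kdEff[k]
        bHsa[k] <- xHsa / (1 + xHsa)
        # Effective HDL K_D reproducing the latent equilibrium HDL-bound
        # fraction at this sample's concentrations.
        xHdl <- fHdl[k] / (1 - fHdl[k]) * (1 + xHsa)
        mix <- CarrierMixture(hsaConc = hsaAssay[k],
                              hdlProteinConc = hdlAssay[k],
                              kdHsa = kdEff[k],
                              kdHdl = hdlAssay[k] / xHdl,
                              capmixHdlAttenuation = 0)
        rCmTrue[k] <- mixtureRapp(mix, "capillary_mix")
        rCdTrue[k] <- mixtureRapp(mix, "complex_dissociation")
      }

      rCm <- rCmTrue * (1 + stats::rnorm(n, 0, coupling$rhNoiseCv))
      rCd <- rCdTrue * (1 + stats::rnorm(n, 0, coupling$rhNoiseCv))

      if (isControl) {
        sofa <- rep(NA_integer_, n)
        vent <- surv <- rep(NA, n)
        crp <- rep(NA_real_, n)
      } else {
        sofa <- as.integer(.drawSofa(n, p$sofaMedian, p$sofaQ1, p$sofaQ3))
        lpV <- coupling$ventIntercept +
          coupling$ventSlope * (coupling$rhCenter - rCdTrue)
        vent <- stats::runif(n) < stats::plogis(lpV)
        lpD <- coupling$deathIntercept +
          coupling$deathSlope * (coupling$rhCenter - rCdTrue)
        surv <- stats::runif(n) >= stats::plogis(lpD)
        crpMed <- ifelse(vent, coupling$crpVentMedian,
                         coupling$crpNoVentMedian)
        crp <- stats::rlnorm(n, log(crpMed), coupling$crpSdlog)
      }

      # Endogenous S1P partition, noisily coupled to the indicator latents.
      endogHdl <- stats::plogis(.logit(fHdl) + stats::rnorm(n, 0, 0.4))
      pHsa <- stats::plogis(.logit(pmin(bHsa, 1 - 1e-6)) - 1.2 +
                              stats::rnorm(n, 0, 0.5))
      endogHsa <- (1 - endogHdl) * pHsa
      s1pTotal <- stats::rlnorm(n, log(coupling$s1pTotalMedian),
                                coupling$s1pTotalSdlog)

      rows[[i]] <- data.frame(
        sample_id = sprintf("%s_%02d", p$group, seq_len(n)),
        group = p$group,
        hsa_g_l = hsa, hdl_mg_dl = hdl,
        hsa_assay_mg_ml = hsaAssay, hdl_assay_mg_ml = hdlAssay,
        kd_hsa_eff_ug_ml = kdEff,
        frac_hdl_true = fHdl, frac_hsa_bound_true = bHsa,
        r_capmix_true = rCmTrue, r_capdis_true = rCdTrue,
        r_capmix = rCm, r_capdis = rCd,
        sofa = sofa, ventilated = vent, survived = surv, crp = crp,
        s1p_total_pmol = s1pTotal,
        endog_frac_hsa = endogHsa, endog_frac_hdl = endogHdl,
        stringsAsFactors = FALSE)
    }
    cohort <- do.call(rbind, rows)
    rownames(cohort) <- NULL
    cohort$delta_rh <- deltaRh(cohort$r_capmix, cohort$r_capdis)

    if (lcms) {
      fracHsa <- fracHdl <- numeric(nrow(cohort))
      for (k in seq_len(nrow(cohort))) {
        other <- max(0, 1 - cohort$endog_frac_hsa[k] -
                       cohort$endog_frac_hdl[k])
        em <- emulateLcms(
          c(hsa = cohort$s1p_total_pmol[k] * cohort$endog_frac_hsa[k],
            hdl = cohort$s1p_total_pmol[k] * cohort$endog_frac_hdl[k],
            other = cohort$s1p_total_pmol[k] * other),
          cv = coupling$lcmsCv)
        fracHsa[k] <- em$fractions["hsa"]
        fracHdl[k] <- em$fractions["hdl"]
      }
      cohort$lcms_frac_hsa <- fracHsa
      cohort$lcms_frac_hdl <- fracHdl
    }
    cohort
  })
}

#' Default LC-MS/MS standard curve
#'
#' Linear area-ratio vs amount calibration: `ratio = slope * pmol +
#' intercept`, against 100 pmol of internal standard.
#'
#' @param slope,intercept Curve coefficients (per pmol).
#' @return A list with `slope`, `intercept`, `r2`.
#' @export
defaultStandardCurve <- function(slope = 0.01, intercept = 0) {
  list(slope = slope, intercept = intercept, r2 = 1)
}

#' Fit an isotope-dilution standard curve
#'
#' Linear regression of the analyte/internal-standard area ratio on the
#' spiked amount; at least 4 levels are required and the coefficient of
#' determination is reported.
#'
#' @param pmol Spiked S1P amounts, pmol.
#' @param areaRatio Observed area ratios.
#' @return A list with `slope`, `intercept`, `r2`.
#' @export
fitStandardCurve <- function(pmol, areaRatio) {
  stopifnot(length(pmol) == length(areaRatio))
  if (length(unique(pmol)) < 4) {
    stop("at least 4 standard levels required", call. = FALSE)
  }
  fit <- stats::lm(areaRatio ~ pmol)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = suppressWarnings(summary(fit)$r.squared))
}

#' Quantify S1P from MRM peak areas by isotope dilution
#'
#' `pmol = (analyteArea / isArea - intercept) / slope` from the standard
#' curve. Negative results are clipped to zero and flagged via the
#' `"clipped"` attribute.
#'
#' @param analyteArea Analyte (S1P, MRM 380/264) peak area.
#' @param isArea Internal standard (C17-S1P, MRM 366/250) peak area.
#' @param standardCurve As [defaultStandardCurve()] / [fitStandardCurve()].
#' @return Quantified amount, pmol (vectorized).
#' @examples
#' quantifyS1p(1.0, 1.0, defaultStandardCurve(slope = 0.01))  # 100 pmol
#' @export
quantifyS1p <- function(analyteArea, isArea,
                        standardCurve = defaultStandardCurve()) {
  if (any(isArea == 0)) {
    stop("internal standard area must be non-zero", call. = FALSE)
  }
  pmol <- (analyteArea / isArea - standardCurve$intercept) /
    standardCurve$slope
  clipped <- pmol < 0
  pmol[clipped] <- 0
  attr(pmol, "clipped") <- any(clipped)
  pmol
}

#' Emulate an LC-MS/MS fractionation readout
#'
#' Given the true S1P amounts in the precipitated plasma fractions,
#' produces noisy MRM peak areas for the analyte and the 100-pmol C17-S1P
#' internal standard (fraction-wise recovery factors times multiplicative
#' log-normal noise at the given CV), quantifies each fraction through the
#' standard curve, and derives carrier-bound fractions relative to the
#' summed quantified amounts. Reported HSA and HDL fractions therefore
#' never sum above 1. With zero noise and unit recovery the derived
#' fractions equal the true ones.
#'
#' @param trueAmounts Named numeric vector of true amounts (pmol), e.g.
#'   `c(hsa = ..., hdl = ..., other = ...)`.
#' @param standardCurve Calibration, as [defaultStandardCurve()].
#' @param cv Multiplicative noise CV (default 0.20 - deliberately noisier
#'   than the FIDA radius noise).
#' @param recovery Named per-fraction recovery factors in (0, 1].
#' @param isPmol Internal standard amount, pmol.
#' @param seed Integer seed.
#' @return A list with `areas` (per-fraction analyte and IS areas),
#'   `quantified` (pmol) and `fractions` (of the summed quantified
#'   amount).
#' @export
emulateLcms <- function(trueAmounts, standardCurve = defaultStandardCurve(),
                        cv = 0.20, recovery = NULL, isPmol = 100,
                        seed = NULL) {
  stopifnot(all(trueAmounts >= 0))
  frac <- names(trueAmounts)
  if (is.null(frac)) frac <- paste0("fraction", seq_along(trueAmounts))
  if (is.null(recovery)) {
    recovery <- stats::setNames(rep(1, length(trueAmounts)), frac)
    recovery[frac == "hdl"] <- 0.85
    recovery[frac == "hsa"] <- 0.95
  }
  sdlog <- sqrt(log(1 + cv^2))
  rfAnalyte <- 500                            # counts per pmol, arbitrary
  rfIs <- rfAnalyte / (standardCurve$slope * isPmol)
  withSeed(seed, {
    noiseA <- if (cv > 0) stats::rlnorm(length(trueAmounts), 0, sdlog) else 1
    noiseI <- if (cv > 0) stats::rlnorm(length(trueAmounts), 0, sdlog / 2)
              else 1
    analyteArea <- rfAnalyte * trueAmounts * recovery[frac] * noiseA
    isArea <- rfIs * isPmol * noiseI
    q <- as.numeric(quantifyS1p(analyteArea, isArea, standardCurve))
    tot <- sum(q)
    fractions <- if (tot > 0) q / tot else rep(0, length(q))
    names(fractions) <- frac
    list(
      areas = data.frame(fraction = frac,
                         analyte_area = as.numeric(analyteArea),
                         is_area = as.numeric(isArea),
                         stringsAsFactors = FALSE),
      quantified = stats::setNames(as.numeric(q), frac),
      fractions = fractions)
  })
}

#' Measure a radius through the full simulate-and-fit path
#'
#' Simulates a single-species Taylorgram at the given true radius and
#' signal-to-noise ratio and fits it back, returning the fitted radius.
#' Used by the full pipeline path (and as a consistency check against the
#' fast path that perturbs latent radii directly).
#'
#' @param rTrue True radius, nm.
#' @param protocol,capillary Assay configuration.
#' @param snr Target signal-to-noise ratio (peak amplitude over noise SD).
#' @param seed Integer seed.
#' @param timeStep Sampling interval, s.
#' @return Fitted radius, nm.
#' @export
measureRhByFida <- function(rTrue, protocol = capMixProtocol(),
                            capillary = CapillarySetup(), snr = 100,
                            seed = NULL, timeStep = 0.1) {
  D <- diffusionFromRh(rTrue, capillary@temperature, capillary@viscosity)
  sig <- sqrt(temporalVariance(D, residenceTime(capillary),
                               capillary@radius))
  amp <- protocol@indicatorConc / (sig * sqrt(2 * pi))
  tg <- simulateTaylorgram(data.frame(rH = rTrue, fraction = 1),
                           protocol, capillary, noiseSd = amp / snr,
                           seed = seed, timeStep = timeStep)
  fittedRh(fitSingleSpecies(tg))[1]
}
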