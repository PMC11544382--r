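# Equilibrium binding models: single-carrier isotherm, K_D estimation from
# titrations, two-carrier competition, and unit conversions.

#' Apparent radius of a 1:1 binding isotherm
#'
#' Fast-exchange population-weighted radius with 1:1 stoichiometry and the
#' analyte in excess over the indicator: the bound fraction is
#' `f_b = c / (K_D + c)` and `r_app = (1 - f_b) r_free + f_b r_complex`.
#' At `c = 0` it returns `r_free`, at `c = K_D` the midpoint, and
#' approaches `r_complex` as `c` grows.
#'
#' @param conc Analyte concentration(s), same unit as `kD`.
#' @param kD Dissociation constant.
#' @param rFree,rComplex Radii of the free indicator and the complex, nm.
#' @return Apparent radius, nm (vectorized over `conc`).
#' @examples
#' isothermRapp(c(0, 20, 1e6), kD = 20, rFree = 1, rComplex = 3.5)
#' @export
isothermRapp <- function(conc, kD, rFree, rComplex) {
  stopifnot(all(conc >= 0), kD > 0)
  fb <- conc / (kD + conc)
  (1 - fb) * rFree + fb * rComplex
}

#' Fit a binding isotherm to a titration curve
#'
#' Weighted nonlinear least squares of [isothermRapp()] against a
#' [BindingCurve]. `K_D` is fitted on the log scale (positivity by
#' parameterization); when replicates exist, concentration levels are
#' weighted by the inverse replicate variance, otherwise the fit is
#' unweighted. A fitted `K_D` beyond 3x the largest tested concentration
#' is flagged as extrapolated; a response with no concentration dependence
#' (e.g. all-zero) is flagged as non-converged with `K_D = NA`.
#'
#' @param curve A [BindingCurve] with at least 5 concentration levels.
#' @return A [BindingFit].
#' @examples
#' conc <- c(0, 5, 10, 20, 40, 80, 160, 320)
#' curve <- BindingCurve(conc, isothermRapp(conc, 20, 1, 3.5))
#' fitBindingCurve(curve)
#' @export
fitBindingCurve <- function(curve) {
  stopifnot(is(curve, "BindingCurve"))
  dat <- data.frame(conc = curve@conc, r = curve@rApp)

  failed <- function() {
    new("BindingFit", kD = NA_real_, kDse = NA_real_,
        rFree = NA_real_, rFreeSe = NA_real_,
        rComplex = NA_real_, rComplexSe = NA_real_,
        unit = curve@unit, rss = NA_real_, converged = FALSE,
        extrapolated = FALSE)
  }
  if (stats::sd(dat$r) < .Machine$double.eps * max(1, mean(abs(dat$r)))) {
    return(failed())  # flat (e.g. all-zero) response: no K_D identifiable
  }

  # Inverse replicate-variance weights per concentration level, when
  # replicate spread exists; unweighted otherwise.
  lvlVar <- tapply(dat$r, dat$conc, stats::var)
  if (all(is.finite(lvlVar)) && all(lvlVar > 0)) {
    w <- 1 / lvlVar[as.character(dat$conc)]
    w <- as.numeric(w / mean(w))
  } else {
    w <- rep(1, nrow(dat))
  }

  rFree0 <- mean(dat$r[dat$conc == min(dat$conc)])
  rComplex0 <- mean(dat$r[dat$conc == max(dat$conc)])
  half <- (rFree0 + rComplex0) / 2
  kd0 <- dat$conc[which.min(abs(dat$r - half))]
  if (kd0 <= 0) kd0 <- stats::median(dat$conc[dat$conc > 0])
  starts <- lapply(c(1, 0.3, 3), function(j) {
    list(lk = log(kd0 * j), rf = rFree0, rc = rComplex0)
  })

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        r ~ (1 - conc / (exp(lk) + conc)) * rf +
            (conc / (exp(lk) + conc)) * rc,
        data = dat, start = st, weights = w, control = .lmControl())),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || stats::deviance(fit) < stats::deviance(best)) {
      best <- fit
    }
  }
  if (is.null(best)) return(failed())

  cf <- stats::coef(best)
  se <- tryCatch(sqrt(diag(stats::vcov(best))),
                 error = function(e) rep(NA_real_, 3))
  kD <- exp(unname(cf["lk"]))
  kDse <- kD * unname(se[1])  # delta method from log scale
  new("BindingFit", kD = kD, kDse = kDse,
      rFree = unname(cf["rf"]), rFreeSe = unname(se[2]),
      rComplex = unname(cf["rc"]), rComplexSe = unname(se[3]),
      unit = curve@unit, rss = stats::deviance(best),
      converged = isTRUE(best$convInfo$isConv),
      extrapolated = kD > 3 * max(dat$conc))
}

#' Indicator partition fractions in a two-carrier mixture
#'
#' Competitive 1:1 partition of a trace indicator between free solution,
#' HSA and HDL, with the indicator far below the binding-site
#' concentrations:
#' `f_free = 1 / (1 + C_HSA/K_HSA + beta C_HDL/K_HDL)`,
#' `f_HSA = (C_HSA/K_HSA) f_free`, `f_HDL = beta (C_HDL/K_HDL) f_free`.
#' `beta` is the CapMix HDL attenuation `alpha` for the capillary-mix
#' method (default 0: the slow S1P-HDL association yields no complex
#' within the in-capillary mixing time) and 1 for the pre-equilibrated
#' complex-dissociation method. The fractions sum to 1 for all inputs.
#'
#' @param mix A [CarrierMixture].
#' @param method `"capillary_mix"` or `"complex_dissociation"`.
#' @return `mixtureFractions()`: a list with `fFree`, `fHsa`, `fHdl`;
#'   `mixtureRapp()`: the population-weighted apparent radius in nm.
#' @examples
#' mix <- CarrierMixture(hsaConc = 4, hdlProteinConc = 0.05)
#' mixtureFractions(mix, "complex_dissociation")
#' @export
mixtureFractions <- function(mix,
                             method = c("complex_dissociation",
                                        "capillary_mix")) {
  stopifnot(is(mix, "CarrierMixture"))
  method <- match.arg(method)
  beta <- if (method == "capillary_mix") mix@capmixHdlAttenuation else 1
  # hsaConc is mg/mL, kdHsa ug/mL: 1 mg/mL = 1000 ug/mL.
  xHsa <- (mix@hsaConc * 1000) / mix@kdHsa
  xHdl <- beta * mix@hdlProteinConc / mix@kdHdl
  fFree <- 1 / (1 + xHsa + xHdl)
  list(fFree = fFree, fHsa = xHsa * fFree, fHdl = xHdl * fFree)
}

#' @rdname mixtureFractions
#' @export
mixtureRapp <- function(mix,
                        method = c("complex_dissociation",
                                   "capillary_mix")) {
  f <- mixtureFractions(mix, method)
  f$fFree * mix@rFree + f$fHsa * mix@rHsaComplex + f$fHdl * mix@rHdlComplex
}

#' Convert a mass-concentration K_D to molar units
#'
#' `massToMolarKd()` divides a mass-per-volume dissociation constant by the
#' binder's molar mass; `molarToMassKd()` inverts it. For the assay's HSA
#' affinity, 20 ug/mL at 66.5 kDa gives ~300 nM.
#'
#' @param kdMass K_D in ug/mL.
#' @param kdNm K_D in nM.
#' @param molarMassKda Molar mass, kDa.
#' @return `massToMolarKd()`: K_D in nM; `molarToMassKd()`: K_D in ug/mL.
#' @examples
#' massToMolarKd(20, 66.5)  # ~300 nM
#' @export
massToMolarKd <- function(kdMass, molarMassKda) {
  .checkPositive(kdMass = kdMass, molarMassKda = molarMassKda)
  # ug/mL = mg/L = 1e-3 g/L; molar mass kDa = 1e3 g/mol.
  # (kdMass * 1e-3 g/L) / (molarMassKda * 1e3 g/mol) = mol/L * 1e-6/kDa
  # -> in nM: * 1e9.
  kdMass / molarMassKda * 1e3
}

#' @rdname massToMolarKd
#' @export
molarToMassKd <- function(kdNm, molarMassKda) {
  .checkPositive(kdNm = kdNm, molarMassKda = molarMassKda)
  kdNm * molarMassKda / 1e3
}

#' ApoM-equivalent molar K_D from an HDL-protein mass K_D
#'
#' HDL binds S1P through apolipoprotein M. Scaling an HDL-protein mass
#' `K_D` by the ApoM content of HDL (default 30 mg ApoM per g HDL protein)
#' and dividing by the ApoM molar mass (default 21 kDa) expresses the
#' affinity per ApoM: 1.25 mg/mL HDL protein corresponds to ~1.8 uM.
#'
#' @param kdHdlProtein K_D in mg/mL HDL protein.
#' @param apomMassFraction ApoM content, mg per g HDL protein.
#' @param apomMolarMassKda ApoM molar mass, kDa.
#' @return ApoM-equivalent K_D in uM.
#' @examples
#' apomEquivalentKd(1.25)  # ~1.8 uM
#' @export
apomEquivalentKd <- function(kdHdlProtein, apomMassFraction = 30,
                             apomMolarMassKda = .APOM_KDA) {
  .checkPositive(kdHdlProtein = kdHdlProtein,
                 apomMassFraction = apomMassFraction,
                 apomMolarMassKda = apomMolarMassKda)
  # mg/mL HDL protein * (mg ApoM / g HDL) / 1000 = mg/mL ApoM = g/L ApoM;
  # divide by molar mass (kDa -> g/mol * 1e3) -> mol/L; report uM.
  apom_g_per_l <- kdHdlProtein * apomMassFraction / 1000
  apom_g_per_l / (apomMolarMassKda * 1e3) * 1e6
}
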