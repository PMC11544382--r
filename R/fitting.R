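# Recovery of species parameters (t_R, sigma, amplitude -> D -> r_h) from
# Taylorgrams by nonlinear least squares (Levenberg-Marquardt via minpack.lm).

# Moment-based initial estimates from the trace: center from the argmax,
# width from the full width at half maximum, amplitude from the max.
# A coarse line through the edge regions (first/last 10% of samples) is
# removed first so an uncorrected baseline cannot inflate the FWHM.
.peakInit <- function(tt, yy) {
  n <- length(yy)
  m <- max(10L, ceiling(0.1 * n))
  edge <- c(seq_len(min(m, n)), seq(max(1L, n - m + 1L), n))
  co <- stats::lm.fit(cbind(1, tt[edge]), yy[edge])$coefficients
  yy <- yy - (co[1] + co[2] * tt)
  iMax <- which.max(yy)
  amp <- yy[iMax]
  half <- amp / 2
  above <- yy >= half
  idx <- which(above)
  # Contiguous run containing the apex.
  lo <- iMax
  while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- iMax
  while (hi < length(yy) && above[hi + 1]) hi <- hi + 1
  fwhm <- tt[hi] - tt[lo]
  if (fwhm <= 0) fwhm <- 4 * (tt[2] - tt[1])
  list(tR = tt[iMax], amplitude = amp, sigma = fwhm / 2.355)
}

# Indices outside the peak exclusion window (apex +/- 4 initial sigma by
# default); used for baseline fitting and noise estimation.
.baselineIdx <- function(tt, yy, exclusionWindow = NULL) {
  if (is.null(exclusionWindow)) {
    init <- .peakInit(tt, yy)
    exclusionWindow <- c(init$tR - 4 * init$sigma, init$tR + 4 * init$sigma)
  }
  left <- which(tt < exclusionWindow[1])
  right <- which(tt > exclusionWindow[2])
  if (length(left) < 10 || length(right) < 10) {
    stop("fewer than 10 baseline samples on a side of the exclusion window",
         call. = FALSE)
  }
  c(left, right)
}

#' Correct linear baseline drift in a Taylorgram
#'
#' Fits a least-squares line to the samples outside the peak exclusion
#' window (apex +/- 4 initial-sigma by default, the convention of the
#' analysis software the assay relies on) and subtracts it. The removed
#' `(offset, slope)` accumulates in the `baselineRemoved` slot, so applying
#' the correction twice is a no-op up to numerical precision.
#'
#' @param taylorgram A [Taylorgram].
#' @param exclusionWindow Numeric `(from, to)` in s around the peak to
#'   exclude from the baseline fit; `NULL` for the automatic window. At
#'   least 10 samples must remain on each side.
#' @return The corrected [Taylorgram].
#' @export
correctBaseline <- function(taylorgram, exclusionWindow = NULL) {
  tt <- taylorgram@time
  yy <- taylorgram@signal
  idx <- .baselineIdx(tt, yy, exclusionWindow)
  fit <- stats::lm.fit(cbind(1, tt[idx]), yy[idx])
  co <- fit$coefficients
  taylorgram@signal <- yy - (co[1] + co[2] * tt)
  taylorgram@baselineRemoved <- taylorgram@baselineRemoved + unname(co)
  taylorgram
}

#' Signal-to-noise ratio of a Taylorgram
#'
#' The peak amplitude of the baseline-corrected trace divided by the
#' noise SD of the baseline region, estimated from first differences
#' (`sd(diff)/sqrt(2)`) so that the smooth residual peak tail does not
#' count as noise. The noise region excludes apex +/- 6 initial-sigma
#' where enough samples remain (falling back to the 4-sigma window). The
#' instrument's guidance considers runs with S/N >= 30 interpretable.
#'
#' @inheritParams correctBaseline
#' @param correct Apply [correctBaseline()] first (default).
#' @return A list with `snr` (`Inf` for a noise-free trace), `interpretable`
#'   (`snr >= 30`) and `noiseFree`.
#' @export
computeSnr <- function(taylorgram, exclusionWindow = NULL, correct = TRUE) {
  if (correct) taylorgram <- correctBaseline(taylorgram, exclusionWindow)
  tt <- taylorgram@time
  yy <- taylorgram@signal
  if (is.null(exclusionWindow)) {
    init <- .peakInit(tt, yy)
    wide <- c(init$tR - 6 * init$sigma, init$tR + 6 * init$sigma)
    idx <- tryCatch(.baselineIdx(tt, yy, wide),
                    error = function(e) .baselineIdx(tt, yy, NULL))
  } else {
    idx <- .baselineIdx(tt, yy, exclusionWindow)
  }
  amp <- max(yy)
  # Per-side first-difference noise estimator; contiguous runs only.
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  d2 <- unlist(lapply(runs, function(r) {
    if (length(r) > 1) diff(yy[r])^2 else numeric(0)
  }))
  noise <- sqrt(mean(d2) / 2)
  if (!is.finite(noise) || noise < 1e-7 * max(1, abs(amp))) {
    return(list(snr = Inf, interpretable = TRUE, noiseFree = TRUE))
  }
  snr <- amp / noise
  list(snr = snr, interpretable = snr >= 30, noiseFree = FALSE)
}

# Build the species data.frame of a FitReport, sorted by rH ascending.
.speciesTable <- function(tR, sigma, amplitude, capillary) {
  area <- amplitude * sigma
  D <- diffusionFromVariance(sigma^2, tR, capillary@radius)
  rH <- stokesEinstein(D, capillary@temperature, capillary@viscosity)
  df <- data.frame(tR = rep(tR, length(sigma)), sigmaT = sigma,
                   amplitude = amplitude, areaFraction = area / sum(area),
                   D = D, rH = rH)
  df[order(df$rH), , drop = FALSE]
}

.lmControl <- function() {
  minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10, ptol = 1e-10)
}

# Run nlsLM over a list of start values, return the converged fit with the
# lowest RSS (or NULL when every start fails).
.bestFit <- function(formula, data, starts, lower = NULL) {
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(formula, data = data, start = st,
                                         control = .lmControl())),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || stats::deviance(fit) < stats::deviance(best)) {
      best <- fit
    }
  }
  best
}

#' Fit a single Gaussian species to a Taylorgram
#'
#' Nonlinear least squares of `A exp(-(t - t_R)^2 / (2 sigma^2))` on the
#' baseline-corrected trace, with the width parameterized as `log sigma` so
#' negative widths are impossible. The diffusion coefficient follows from
#' the fitted width via the Taylor-Aris relation and the radius via
#' Stokes-Einstein. Initialization: center from the argmax, width from
#' FWHM/2.355, amplitude from the maximum; three width-jittered restarts,
#' lowest RSS wins. Non-convergence is flagged, not raised.
#'
#' @param taylorgram A [Taylorgram] with at least 50 samples.
#' @param capillary The [CapillarySetup] to interpret widths with; defaults
#'   to the trace's own.
#' @param correct Apply [correctBaseline()] first (default).
#' @return A [FitReport] with one species.
#' @examples
#' tg <- simulateTaylorgram(data.frame(rH = 3.5, fraction = 1))
#' fittedRh(fitSingleSpecies(tg))
#' @export
fitSingleSpecies <- function(taylorgram, capillary = taylorgram@capillary,
                             correct = TRUE) {
  if (length(taylorgram@time) < 50) {
    stop("at least 50 samples are required for fitting", call. = FALSE)
  }
  if (correct) taylorgram <- correctBaseline(taylorgram)
  dat <- data.frame(t = taylorgram@time, y = taylorgram@signal)
  init <- .peakInit(dat$t, dat$y)
  ls0 <- log(init$sigma)
  starts <- list(
    list(A = init$amplitude, c = init$tR, ls = ls0),
    list(A = init$amplitude, c = init$tR, ls = ls0 + log(0.7)),
    list(A = init$amplitude, c = init$tR, ls = ls0 + log(1.4))
  )
  fit <- .bestFit(y ~ A * exp(-(t - c)^2 / (2 * exp(2 * ls))), dat, starts)
  if (is.null(fit)) {
    sp <- .speciesTable(init$tR, init$sigma, init$amplitude, capillary)
    snr <- computeSnr(taylorgram, correct = FALSE)
    return(new("FitReport", species = sp,
               baseline = taylorgram@baselineRemoved, pdi = 0,
               snr = snr$snr, rss = sum(dat$y^2), converged = FALSE,
               degenerate = FALSE, nSpecies = 1))
  }
  cf <- stats::coef(fit)
  sp <- .speciesTable(unname(cf["c"]), exp(unname(cf["ls"])),
                      unname(cf["A"]), capillary)
  snr <- computeSnr(taylorgram, correct = FALSE)
  rep <- new("FitReport", species = sp,
             baseline = taylorgram@baselineRemoved,
             pdi = 0, snr = snr$snr, rss = stats::deviance(fit),
             converged = isTRUE(fit$convInfo$isConv), degenerate = FALSE,
             nSpecies = 1)
  rep@pdi <- as.numeric(computePdi(rep))
  rep
}

#' Fit two Gaussian species with a shared center
#'
#' Multiple-species analysis for a trace containing a bound complex plus
#' free indicator: two Gaussians with a common center and distinct widths.
#' The smaller-radius (narrower) component is interpreted as free
#' indicator; its radius can optionally be pinned to a known value (e.g.
#' from an indicator-only run), in which case its width is tied to the
#' fitted center through the Taylor-Aris relation. When the two fitted
#' widths are indistinguishable (ratio < 1.05), a component's amplitude
#' collapses, or a component sits below the detection limit (amplitude
#' under 3x the baseline noise SD - such a "species" is a noise artifact,
#' not a detection), the fit is flagged degenerate and the single-species
#' result is returned. The two-species fit never has a larger residual sum of
#' squares than the single-species fit on the same trace (the single
#' solution is among its starting points).
#'
#' @inheritParams fitSingleSpecies
#' @param rhFreeFixed Radius (nm) to pin the free-indicator species to, or
#'   `NULL` to fit it.
#' @return A [FitReport]; species sorted by radius ascending, so the free
#'   indicator fraction is `fittedSpecies(x)$areaFraction[1]`.
#' @export
fitTwoSpecies <- function(taylorgram, capillary = taylorgram@capillary,
                          rhFreeFixed = NULL, correct = TRUE) {
  if (length(taylorgram@time) < 50) {
    stop("at least 50 samples are required for fitting", call. = FALSE)
  }
  if (correct) taylorgram <- correctBaseline(taylorgram)
  single <- fitSingleSpecies(taylorgram, capillary, correct = FALSE)
  dat <- data.frame(t = taylorgram@time, y = taylorgram@signal)
  s1 <- single@species
  A0 <- s1$amplitude[1]
  ls0 <- log(s1$sigmaT[1])
  c0 <- s1$tR[1]

  degenerateReport <- function() {
    rep <- single
    rep@degenerate <- TRUE
    rep@nSpecies <- 2
    rep
  }

  if (is.null(rhFreeFixed)) {
    starts <- list(
      # Near the single-species solution: guarantees RSS <= single RSS.
      list(A1 = 1e-8 * A0, A2 = A0, c = c0, ls1 = ls0 - log(2), ls2 = ls0),
      list(A1 = 0.1 * A0, A2 = 0.9 * A0, c = c0,
           ls1 = ls0 - log(2.5), ls2 = ls0),
      list(A1 = 0.3 * A0, A2 = 0.7 * A0, c = c0,
           ls1 = ls0 - log(1.6), ls2 = ls0 + log(1.1))
    )
    fit <- .bestFit(
      y ~ A1 * exp(-(t - c)^2 / (2 * exp(2 * ls1))) +
          A2 * exp(-(t - c)^2 / (2 * exp(2 * ls2))), dat, starts)
    if (is.null(fit)) return(degenerateReport())
    cf <- stats::coef(fit)
    amps <- unname(c(cf["A1"], cf["A2"]))
    sigs <- exp(unname(c(cf["ls1"], cf["ls2"])))
    cc <- unname(cf["c"])
  } else {
    # Pinned free species: its width follows the fitted center.
    Dfree <- diffusionFromRh(rhFreeFixed, capillary@temperature,
                             capillary@viscosity)
    kFree <- capillary@radius^2 / (24 * Dfree)  # sigma1^2 = kFree * c
    starts <- list(
      list(A1 = 1e-8 * A0, A2 = A0, c = c0, ls2 = ls0),
      list(A1 = 0.1 * A0, A2 = 0.9 * A0, c = c0, ls2 = ls0)
    )
    fit <- .bestFit(
      y ~ A1 * exp(-(t - c)^2 / (2 * kFree * c)) +
          A2 * exp(-(t - c)^2 / (2 * exp(2 * ls2))),
      cbind(dat, kFree = kFree), starts)
    if (is.null(fit)) return(degenerateReport())
    cf <- stats::coef(fit)
    cc <- unname(cf["c"])
    amps <- unname(c(cf["A1"], cf["A2"]))
    sigs <- c(sqrt(kFree * cc), exp(unname(cf["ls2"])))
  }

  ratio <- max(sigs) / min(sigs)
  rss <- stats::deviance(fit)
  # Detection limit: the baseline noise SD from the first-difference
  # estimator (zero for a noise-free trace).
  snrInfo <- computeSnr(taylorgram, correct = FALSE)
  noiseSd <- if (snrInfo$noiseFree) 0 else
    max(taylorgram@signal) / snrInfo$snr
  if (ratio < 1.05 || any(amps <= 3 * noiseSd) || any(amps <= 0) ||
      rss > single@rss) {
    return(degenerateReport())
  }
  sp <- .speciesTable(cc, sigs, amps, capillary)
  rep <- new("FitReport", species = sp,
             baseline = taylorgram@baselineRemoved, pdi = 0,
             snr = single@snr, rss = rss,
             converged = isTRUE(fit$convInfo$isConv), degenerate = FALSE,
             nSpecies = 2)
  rep@pdi <- as.numeric(computePdi(rep))
  rep
}

#' Polydispersity index of a fit
#'
#' Area-weighted relative variance of the fitted radii (the dynamic light
#' scattering convention): `PDI = sum_i f_i (r_i - rbar)^2 / rbar^2` with
#' `rbar = sum_i f_i r_i`. A single species gives exactly 0; values below
#' 0.5 are classified monodisperse.
#'
#' @param fit A [FitReport], or a `data.frame` with columns `rH` and
#'   `areaFraction`.
#' @return The PDI; the `"monodisperse"` attribute holds the
#'   classification at the 0.5 threshold.
#' @examples
#' computePdi(data.frame(rH = c(2, 6), areaFraction = c(0.5, 0.5))) # 0.25
#' @export
computePdi <- function(fit) {
  sp <- if (is(fit, "FitReport")) fit@species else fit
  stopifnot(nrow(sp) >= 1)
  f <- sp$areaFraction
  r <- sp$rH
  if (nrow(sp) == 1) {
    pdi <- 0
  } else {
    rbar <- sum(f * r)
    pdi <- sum(f * (r - rbar)^2) / rbar^2
  }
  attr(pdi, "monodisperse") <- pdi < 0.5
  pdi
}
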