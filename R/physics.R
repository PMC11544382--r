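# Analytic Taylor-Aris dispersion model: molecular size <-> Taylorgram shape.

#' Stokes-Einstein conversions between diffusion coefficient and radius
#'
#' `stokesEinstein()` converts a translational diffusion coefficient to the
#' hydrodynamic (equivalent-sphere) radius, `r_h = k_B T / (6 pi eta D)`;
#' `diffusionFromRh()` is its exact algebraic inverse.
#'
#' @param D Diffusion coefficient, m^2/s.
#' @param rH Hydrodynamic radius, nm.
#' @param temperature Absolute temperature, K.
#' @param viscosity Dynamic viscosity, Pa s.
#' @return `stokesEinstein()`: radius in nm; `diffusionFromRh()`: diffusion
#'   coefficient in m^2/s. Vectorized over the first argument.
#' @examples
#' stokesEinstein(2.0e-10, temperature = 298.15, viscosity = 8.9e-4) # ~1.227
#' @export
stokesEinstein <- function(D, temperature = 310.15, viscosity = 6.913e-4) {
  .checkPositive(D = D, temperature = temperature, viscosity = viscosity)
  1e9 * .kB * temperature / (6 * pi * viscosity * D)
}

#' @rdname stokesEinstein
#' @export
diffusionFromRh <- function(rH, temperature = 310.15, viscosity = 6.913e-4) {
  .checkPositive(rH = rH, temperature = temperature, viscosity = viscosity)
  .kB * temperature / (6 * pi * viscosity * rH * 1e-9)
}

#' Temporal peak variance under Taylor-Aris dispersion
#'
#' In the Taylor regime the detector-time peak variance of a species with
#' diffusion coefficient `D` is `sigma_t^2 = r_c^2 t_R / (24 D)`: slower
#' diffusion (larger molecules) gives broader peaks. Axial molecular
#' diffusion is neglected (pure Taylor regime); [taylorValidity()] guards
#' the assumption.
#'
#' @param D Diffusion coefficient, m^2/s.
#' @param tR Residence time, s.
#' @param rC Capillary inner radius, m.
#' @return `temporalVariance()`: the peak variance sigma_t^2 in s^2;
#'   `diffusionFromVariance()` inverts it, returning `D` in m^2/s.
#' @examples
#' temporalVariance(4.0e-11, tR = 120, rC = 37.5e-6) # ~175.8 s^2
#' @export
temporalVariance <- function(D, tR, rC) {
  .checkPositive(D = D, tR = tR, rC = rC)
  rC^2 * tR / (24 * D)
}

#' @param sigmaT2 Temporal peak variance, s^2.
#' @rdname temporalVariance
#' @export
diffusionFromVariance <- function(sigmaT2, tR, rC) {
  .checkPositive(sigmaT2 = sigmaT2, tR = tR, rC = rC)
  rC^2 * tR / (24 * sigmaT2)
}

#' Validity of the Taylor dispersion regime
#'
#' The closed-form variance assumes (i) radial equilibration, measured by
#' the dimensionless residence time `tau = D t_R / r_c^2`, and (ii)
#' advection dominating axial diffusion, measured by the Peclet number
#' `Pe = u r_c / D`. Standard criteria require `tau >= 1.4` and
#' `Pe >= 69` (both boundaries inclusive; thresholds configurable).
#'
#' @param D Diffusion coefficient, m^2/s.
#' @param tR Residence time, s.
#' @param rC Capillary radius, m.
#' @param u Mean flow velocity, m/s.
#' @param tauMin,peMin Acceptance thresholds.
#' @return A list with `tau`, `pe` and logical `ok`.
#' @examples
#' cap <- CapillarySetup()
#' D <- diffusionFromRh(3.5, cap@temperature, cap@viscosity)
#' taylorValidity(D, residenceTime(cap), capRadius(cap), cap@meanVelocity)
#' @export
taylorValidity <- function(D, tR, rC, u, tauMin = 1.4, peMin = 69) {
  .checkPositive(D = D, tR = tR, rC = rC, u = u)
  tau <- D * tR / rC^2
  pe <- u * rC / D
  list(tau = tau, pe = pe, ok = (tau >= tauMin) & (pe >= peMin))
}

#' Simulate a Taylorgram for a species mixture
#'
#' Generates the detector trace of a mixture of species sharing the
#' residence time `t_R`: a sum of Gaussians centered at `t_R`, each with
#' variance from [temporalVariance()] for that species' size, on a linear
#' baseline, plus additive white Gaussian noise. The total Gaussian area is
#' proportional to the protocol's indicator concentration, split according
#' to the amplitude fractions, so that the area is invariant to the species
#' radii.
#'
#' @param mixture `data.frame` with columns `rH` (nm) and `fraction`
#'   (amplitude/area fractions summing to 1 within 1e-9).
#' @param protocol An [AssayProtocol].
#' @param capillary A [CapillarySetup].
#' @param baseline Numeric `(offset, slope)` of the linear baseline drift.
#' @param noiseSd SD of the additive white noise, AU.
#' @param seed Integer seed; a fixed seed gives bit-identical traces.
#' @param timeStep Sampling interval, s.
#' @param window Time window `(from, to)` in s; defaults to `(0, 2 t_R)`.
#' @param areaScale Total Gaussian area per nM of indicator (AU s / nM).
#' @return A [Taylorgram].
#' @examples
#' tg <- simulateTaylorgram(data.frame(rH = 3.5, fraction = 1),
#'                          capMixProtocol(), CapillarySetup())
#' @export
simulateTaylorgram <- function(mixture, protocol = capMixProtocol(),
                               capillary = CapillarySetup(),
                               baseline = c(0, 0), noiseSd = 0, seed = NULL,
                               timeStep = 0.1, window = NULL, areaScale = 1) {
  if (!is.data.frame(mixture) || nrow(mixture) == 0) {
    stop("mixture must be a non-empty data.frame with columns rH, fraction",
         call. = FALSE)
  }
  stopifnot(all(c("rH", "fraction") %in% names(mixture)))
  if (abs(sum(mixture$fraction) - 1) > 1e-9) {
    stop("mixture fractions must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  if (any(mixture$rH <= 0)) stop("species radii must be positive",
                                 call. = FALSE)
  tR <- residenceTime(capillary)
  if (is.null(window)) window <- c(0, 2 * tR)
  tt <- seq(window[1], window[2], by = timeStep)

  D <- diffusionFromRh(mixture$rH, capillary@temperature,
                       capillary@viscosity)
  sig2 <- temporalVariance(D, tR, capillary@radius)
  # Area of species i: indicatorConc * fraction_i * areaScale, so the
  # amplitude is area / (sigma sqrt(2 pi)).
  amp <- protocol@indicatorConc * mixture$fraction * areaScale /
    sqrt(2 * pi * sig2)

  clean <- baseline[1] + baseline[2] * tt
  for (i in seq_len(nrow(mixture))) {
    clean <- clean + amp[i] * exp(-(tt - tR)^2 / (2 * sig2[i]))
  }
  y <- withSeed(seed, clean + if (noiseSd > 0) {
    stats::rnorm(length(tt), 0, noiseSd)
  } else 0)
  Taylorgram(tt, y, capillary = capillary, protocol = protocol,
             noiseSd = noiseSd, seed = if (is.null(seed)) NA_real_ else seed)
}

#' Brute-force Langevin simulation of Taylor dispersion
#'
#' Independent numerical route to the temporal peak variance: random
#' walkers start uniformly over the capillary cross-section, diffuse
#' radially (reflecting at the wall) and are advected by the parabolic
#' Poiseuille profile `u(r) = 2 u_mean (1 - (r/r_c)^2)` for one residence
#' time. The variance of their axial positions, divided by `u_mean^2`,
#' estimates the temporal variance that [temporalVariance()] gives in
#' closed form. Axial molecular diffusion is omitted, matching the closed
#' form's assumption. Shares no code with the analytic model; used as a
#' physics oracle in validation.
#'
#' The closed form gives the *asymptotic* dispersion rate; a plug started
#' from a uniform cross-section needs a relaxation time of order
#' `r_c^2 / (15 D)` before reaching it. With `equilibrate = TRUE` (the
#' default) the walkers are therefore advanced for one residence time
#' before measurement and the variance accrued over the following
#' residence time is reported, cancelling the start-up transient; with
#' `equilibrate = FALSE` the raw variance at `t_R` is returned, which
#' undershoots the closed form by roughly `1/(15 tau)`.
#'
#' @param D Diffusion coefficient, m^2/s.
#' @param capillary A [CapillarySetup].
#' @param nWalkers Number of walkers.
#' @param nSteps Number of time steps per residence time (chosen so the
#'   per-step radial RMS displacement is well below the capillary radius
#'   when `NULL`).
#' @param equilibrate Pre-equilibrate for one residence time (see above).
#' @param seed Integer seed.
#' @return Estimated temporal variance, s^2.
#' @export
langevinDispersionVariance <- function(D, capillary = CapillarySetup(),
                                       nWalkers = 1e4, nSteps = NULL,
                                       equilibrate = TRUE, seed = NULL) {
  .checkPositive(D = D, nWalkers = nWalkers)
  rc <- capillary@radius
  u <- capillary@meanVelocity
  tR <- residenceTime(capillary)
  if (is.null(nSteps)) {
    # Keep per-step radial RMS displacement <= ~7% of the radius.
    nSteps <- max(500, ceiling(tR / (0.005 * rc^2 / D)))
    nSteps <- min(nSteps, 2e4)
  }
  dt <- tR / nSteps
  step <- sqrt(2 * D * dt)
  withSeed(seed, {
    # Uniform start over the disk.
    r0 <- rc * sqrt(stats::runif(nWalkers))
    th <- stats::runif(nWalkers, 0, 2 * pi)
    x <- r0 * cos(th)
    y <- r0 * sin(th)
    z <- numeric(nWalkers)
    advance <- function() {
      for (k in seq_len(nSteps)) {
        x <<- x + stats::rnorm(nWalkers, 0, step)
        y <<- y + stats::rnorm(nWalkers, 0, step)
        r <- sqrt(x^2 + y^2)
        out <- r > rc
        if (any(out)) {
          # Radial reflection at the wall.
          rNew <- 2 * rc - r[out]
          scale <- rNew / r[out]
          x[out] <<- x[out] * scale
          y[out] <<- y[out] * scale
          r[out] <- rNew
        }
        z <<- z + 2 * u * (1 - (r / rc)^2) * dt
      }
    }
    if (equilibrate) {
      advance()
      v0 <- stats::var(z)
      advance()
      (stats::var(z) - v0) / u^2
    } else {
      advance()
      stats::var(z) / u^2
    }
  })
}
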