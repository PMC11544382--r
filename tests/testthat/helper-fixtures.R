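# Shared fixtures and independent oracles for the test suite.

# Amplitude of a simulated single-species peak (AU), used to set noise for
# a target signal-to-noise ratio.
peakAmplitude <- function(rH, protocol = capMixProtocol(),
                          capillary = CapillarySetup()) {
  D <- diffusionFromRh(rH, capillary@temperature, capillary@viscosity)
  sig <- sqrt(temporalVariance(D, residenceTime(capillary),
                               capillary@radius))
  protocol@indicatorConc / (sig * sqrt(2 * pi))
}

# Single-species trace at a target S/N (Inf for noise-free).
simSingle <- function(rH, protocol = capMixProtocol(),
                      capillary = CapillarySetup(), snr = Inf,
                      baseline = c(0, 0), seed = NULL, timeStep = 0.1) {
  noiseSd <- if (is.finite(snr)) peakAmplitude(rH, protocol, capillary) / snr
             else 0
  simulateTaylorgram(data.frame(rH = rH, fraction = 1), protocol,
                     capillary, baseline = baseline, noiseSd = noiseSd,
                     seed = seed, timeStep = timeStep)
}

# Brute-force first/second temporal moments of a (baseline-free) trace,
# independent of the Gaussian fitting route.
traceMoments <- function(tg) {
  tt <- tg@time
  yy <- tg@signal
  w <- yy / sum(yy)
  m1 <- sum(w * tt)
  m2 <- sum(w * (tt - m1)^2)
  list(center = m1, sigma = sqrt(m2))
}

# Independent exact Mann-Whitney oracle: U by direct pairwise counting
# (wins + half-ties), null distribution by enumerating every assignment of
# the pooled observations to group A, two-sided p as the doubled smaller
# tail (capped at 1).
mwBruteForce <- function(a, b) {
  uStat <- function(x, y) {
    sum(vapply(x, function(xi) sum(xi > y) + 0.5 * sum(xi == y),
               numeric(1)))
  }
  pooled <- c(a, b)
  n1 <- length(a)
  U <- uStat(a, b)
  picks <- utils::combn(length(pooled), n1)
  Us <- apply(picks, 2, function(idx) {
    uStat(pooled[idx], pooled[-idx])
  })
  pLe <- mean(Us <= U + 1e-9)
  pGe <- mean(Us >= U - 1e-9)
  list(U = U, p = min(1, 2 * min(pLe, pGe)))
}

# Small synthetic cohort reused by carrier-shift tests.
testCohort <- function(seed = 101) generateCohort(seed = seed)
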