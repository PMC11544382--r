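test_that("baseline correction recovers and removes linear drift", {
  cap <- CapillarySetup()
  # Pure line, no peak area to speak of: corrected trace ~ 0.
  tt <- seq(0, 240, by = 0.1)
  flat <- Taylorgram(tt, 5 + 0.01 * tt, capillary = cap)
  corr <- correctBaseline(flat, exclusionWindow = c(100, 140))
  expect_lt(max(abs(signalValues(corr))), 1e-9 * 5)

  # Simulated Gaussian plus drift: fitted (offset, slope) recover inputs.
  tg <- simSingle(3.5, baseline = c(2, 0.003), snr = 200, seed = 4)
  corr <- correctBaseline(tg)
  expect_equal(corr@baselineRemoved[1], 2, tolerance = 0.01)
  expect_equal(corr@baselineRemoved[2], 0.003, tolerance = 0.01)

  # Idempotence: a second pass changes nothing measurable.
  corr2 <- correctBaseline(corr)
  expect_equal(signalValues(corr2), signalValues(corr), tolerance = 1e-9)

  # A window covering the whole trace is refused.
  expect_error(correctBaseline(tg, exclusionWindow = c(-10, 500)),
               "baseline samples")
})

test_that("single-species fit recovers a noise-free species exactly", {
  tg <- simSingle(3.5)
  fit <- fitSingleSpecies(tg)
  expect_true(fit@converged)
  expect_equal(fittedRh(fit), 3.5, tolerance = 1e-3)
  expect_equal(fit@pdi, 0)
  # Fitted center and width equal the trace's brute-force moments (the
  # discrete moment estimate on the finite window carries ~1e-5 relative
  # truncation error of its own).
  mom <- traceMoments(tg)
  sp <- fittedSpecies(fit)
  expect_equal(sp$tR, mom$center, tolerance = 1e-4)
  expect_equal(sp$sigmaT, mom$sigma, tolerance = 1e-4)
})

test_that("fit -> simulate -> fit is closed under the optimizer tolerance", {
  tg <- simSingle(5, snr = 150, seed = 9)
  f1 <- fitSingleSpecies(tg)
  tg2 <- simulateTaylorgram(
    data.frame(rH = fittedRh(f1), fraction = 1))
  f2 <- fitSingleSpecies(tg2)
  expect_equal(fittedRh(f2), fittedRh(f1), tolerance = 1e-4)
})

test_that("radius recovery stays under 2% median error across sizes", {
  # 200 seeded simulations spanning 1-12 nm at the interpretability floor
  # S/N = 30.
  rhs <- rep(seq(1, 12, length.out = 40), each = 5)
  errs <- vapply(seq_along(rhs), function(i) {
    tg <- simSingle(rhs[i], snr = 30, seed = 1000 + i, timeStep = 0.2)
    abs(fittedRh(fitSingleSpecies(tg)) - rhs[i]) / rhs[i]
  }, numeric(1))
  expect_lt(stats::median(errs), 0.02)
})

test_that("two-species fit resolves a 90/10 mixture and sorts by radius", {
  mix <- data.frame(rH = c(1.0, 3.5), fraction = c(0.1, 0.9))
  tg <- simulateTaylorgram(mix, capDisProtocol())
  fit <- fitTwoSpecies(tg)
  expect_false(fit@degenerate)
  sp <- fittedSpecies(fit)
  expect_true(all(diff(sp$rH) > 0))  # ascending radius
  expect_equal(sp$areaFraction, c(0.1, 0.9), tolerance = 0.01)
  expect_equal(sp$rH, c(1.0, 3.5), tolerance = 0.01)
  # Pinning the free-indicator radius keeps the fractions.
  fitP <- fitTwoSpecies(tg, rhFreeFixed = 1.0)
  expect_equal(fittedSpecies(fitP)$areaFraction[1], 0.1, tolerance = 0.01)
  expect_equal(fittedSpecies(fitP)$rH[1], 1.0, tolerance = 1e-6)
})

test_that("a collapsed mixture is flagged degenerate", {
  tg <- simSingle(3.5, snr = 100, seed = 5)
  fit <- fitTwoSpecies(tg)
  expect_true(fit@degenerate)
  expect_equal(nrow(fittedSpecies(fit)), 1)
})

test_that("two-species RSS never exceeds single-species RSS", {
  for (s in 1:5) {
    tg <- simulateTaylorgram(
      data.frame(rH = c(1, 3.5), fraction = c(0.15, 0.85)),
      capDisProtocol(), noiseSd = peakAmplitude(3.5, capDisProtocol()) / 80,
      seed = s)
    f1 <- fitSingleSpecies(tg)
    f2 <- fitTwoSpecies(tg)
    expect_lte(f2@rss, f1@rss * (1 + 1e-9))
  }
})

test_that("PDI follows the area-weighted relative variance convention", {
  # One species: exactly zero.
  expect_equal(computePdi(data.frame(rH = 4, areaFraction = 1)), 0,
               ignore_attr = TRUE)
  # 50/50 at 2 and 6 nm: rbar = 4, PDI = 4/16 = 0.25.
  pdi <- computePdi(data.frame(rH = c(2, 6), areaFraction = c(0.5, 0.5)))
  expect_equal(as.numeric(pdi), 0.25)
  expect_true(attr(pdi, "monodisperse"))  # 0.25 < 0.5 threshold
  # Above the 0.5 threshold -> polydisperse.
  pdi2 <- computePdi(data.frame(rH = c(1, 40), areaFraction = c(0.5, 0.5)))
  expect_false(attr(pdi2, "monodisperse"))
  # Invariant to overall amplitude scaling of the underlying fit.
  tg <- simulateTaylorgram(data.frame(rH = c(1, 3.5),
                                      fraction = c(0.2, 0.8)),
                           capDisProtocol())
  f <- fitTwoSpecies(tg)
  tgBig <- Taylorgram(signalTime(tg), 50 * signalValues(tg),
                      capillary = tg@capillary, protocol = tg@protocol)
  fBig <- fitTwoSpecies(tgBig)
  expect_equal(fBig@pdi, f@pdi, tolerance = 1e-6)
})

test_that("signal-to-noise is amplitude over baseline SD with flags", {
  tg <- simSingle(3.5, snr = 100, seed = 6)
  s <- computeSnr(tg)
  expect_equal(s$snr, 100, tolerance = 0.15)
  expect_true(s$interpretable)
  expect_false(s$noiseFree)
  # Noise-free trace: +Inf, flagged.
  s0 <- computeSnr(simSingle(3.5))
  expect_identical(s0$snr, Inf)
  expect_true(s0$noiseFree)
})
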