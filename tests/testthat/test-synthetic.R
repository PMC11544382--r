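test_that("cohort generation is seed-deterministic and validates input", {
  a <- generateCohort(seed = 7)
  b <- generateCohort(seed = 7)
  expect_identical(a, b)
  expect_false(identical(a$r_capdis, generateCohort(seed = 8)$r_capdis))
  # Group sizes follow the profiles.
  expect_equal(as.vector(table(a$group)[c("control", "trauma", "sepsis",
                                          "septic_shock")]),
               c(14L, 11L, 36L, 16L))
  bad <- defaultGroupProfiles()
  bad$n[2] <- 0L
  expect_error(generateCohort(bad), "positive")
  bad2 <- defaultGroupProfiles()[, -3]
  expect_error(generateCohort(bad2), "missing columns")
})

test_that("drawn carrier concentrations center on the group medians", {
  # Pooled over 100 cohorts, the per-group HSA medians sit within 10% of
  # 43 / 25 / 22 / 17 g/L (and HDL on 61 / 61 / 34 / 13 mg/dL).
  hsa <- list()
  hdl <- list()
  for (s in 1:100) {
    co <- generateCohort(seed = 400 + s, lcms = FALSE)
    hsa[[s]] <- tapply(co$hsa_g_l, co$group, stats::median)
    hdl[[s]] <- tapply(co$hdl_mg_dl, co$group, stats::median)
  }
  hsaMed <- apply(do.call(rbind, hsa), 2, mean)
  hdlMed <- apply(do.call(rbind, hdl), 2, mean)
  want <- c(control = 43, trauma = 25, sepsis = 22, septic_shock = 17)
  for (g in names(want)) {
    expect_lt(abs(hsaMed[g] - want[g]) / want[g], 0.10)
  }
  wantHdl <- c(control = 61, trauma = 61, sepsis = 34, septic_shock = 13)
  for (g in names(wantHdl)) {
    expect_lt(abs(hdlMed[g] - wantHdl[g]) / wantHdl[g], 0.10)
  }
})

test_that("latent radii derive from the competitive partition model", {
  co <- generateCohort(seed = 12, lcms = FALSE)
  # Recompute one sample's radii from its stored latent parameters.
  k <- which(co$group == "sepsis")[1]
  xHsa <- co$hsa_assay_mg_ml[k] * 1000 / co$kd_hsa_eff_ug_ml[k]
  xHdl <- co$frac_hdl_true[k] / (1 - co$frac_hdl_true[k]) * (1 + xHsa)
  mix <- CarrierMixture(co$hsa_assay_mg_ml[k], co$hdl_assay_mg_ml[k],
                        kdHsa = co$kd_hsa_eff_ug_ml[k],
                        kdHdl = co$hdl_assay_mg_ml[k] / xHdl)
  expect_equal(co$r_capmix_true[k], mixtureRapp(mix, "capillary_mix"))
  expect_equal(co$r_capdis_true[k],
               mixtureRapp(mix, "complex_dissociation"))
  # The CapDis HDL-bound fraction equals the drawn latent fraction.
  expect_equal(mixtureFractions(mix, "complex_dissociation")$fHdl,
               co$frac_hdl_true[k], tolerance = 1e-12)
})

test_that("the shock group harbors a low-complex subgroup of non-survivors", {
  # Pool shock patients over seeded cohorts: deceased have lower latent
  # complex-dissociation radii than survivors.
  dec <- sur <- c()
  for (s in 1:20) {
    co <- generateCohort(seed = 600 + s, lcms = FALSE)
    sh <- co[co$group == "septic_shock", ]
    dec <- c(dec, sh$r_capdis_true[!sh$survived])
    sur <- c(sur, sh$r_capdis_true[sh$survived])
  }
  expect_gt(length(dec), 10)
  expect_lt(stats::median(dec), stats::median(sur))
})

test_that("standard curves and isotope-dilution quantification invert", {
  # Ratio exactly on the default curve: 1.0 / 0.01 = 100 pmol.
  expect_equal(as.numeric(quantifyS1p(1.0, 1.0)), 100)
  # Negative extrapolation clips to zero with a flag.
  crv <- defaultStandardCurve(slope = 0.01, intercept = 0.5)
  q <- quantifyS1p(0.2, 1.0, crv)
  expect_equal(as.numeric(q), 0)
  expect_true(attr(q, "clipped"))
  expect_error(quantifyS1p(1, 0), "non-zero")
  # Refit on noise-free synthetic standards: exact slope, r^2 = 1.
  pmol <- c(0, 25, 50, 100, 200)
  fit <- fitStandardCurve(pmol, 0.5 + 0.01 * pmol)
  expect_equal(fit$slope, 0.01)
  expect_equal(fit$intercept, 0.5)
  expect_equal(fit$r2, 1)
  expect_error(fitStandardCurve(c(0, 1, 2), c(0, 1, 2)), "4 standard")
})

test_that("the LC-MS emulation is exact at zero noise and bounded", {
  truth <- c(hsa = 200, hdl = 100, other = 100)
  em <- emulateLcms(truth, cv = 0, recovery = c(hsa = 1, hdl = 1,
                                                other = 1))
  expect_equal(em$quantified, truth)
  expect_equal(em$fractions, truth / sum(truth))
  # With noise and recovery losses, reported carrier fractions never sum
  # above 1.
  for (s in 1:20) {
    em <- emulateLcms(truth, cv = 0.2, seed = s)
    expect_lte(em$fractions[["hsa"]] + em$fractions[["hdl"]], 1)
    expect_true(all(em$fractions >= 0))
  }
  # Seed determinism.
  expect_identical(emulateLcms(truth, seed = 5), emulateLcms(truth, seed = 5))
})

test_that("noise-free pipeline preserves the latent group ordering", {
  cpl <- defaultOutcomeCoupling()
  cpl$rhNoiseCv <- 0
  co <- generateCohort(coupling = cpl, seed = 15, lcms = FALSE)
  expect_equal(co$r_capdis, co$r_capdis_true)
  res <- runCohortAnalysis(co)
  gs <- groupSummary(res)
  d <- stats::setNames(gs$mean[gs$variable == "delta_rh"],
                       gs$group[gs$variable == "delta_rh"])
  # Controls lowest; every patient group clearly above.
  expect_true(all(d[c("trauma", "sepsis", "septic_shock")] > d["control"]))
})

test_that("the simulate-and-fit measurement path matches the fast path", {
  # At high S/N, measuring a latent radius through a simulated Taylorgram
  # returns it within the assay precision envelope.
  for (r in c(3.3, 4.2)) {
    rFit <- measureRhByFida(r, snr = 200, seed = 44, timeStep = 0.2)
    expect_equal(rFit, r, tolerance = 0.01)
  }
})
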