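test_that("the isotherm obeys its limiting identities", {
  expect_equal(isothermRapp(0, 20, 1, 3.5), 1)
  expect_equal(isothermRapp(20, 20, 1, 3.5), (1 + 3.5) / 2)  # c = K_D
  expect_equal(isothermRapp(1e9, 20, 1, 3.5), 3.5, tolerance = 1e-6)
})

test_that("binding-curve fits recover the generating parameters", {
  conc <- c(0, 2, 5, 10, 20, 40, 80, 160, 320, 640)
  # Noise-free: exact recovery to optimizer tolerance.
  curve <- BindingCurve(conc, isothermRapp(conc, 20, 1, 3.5))
  fit <- fitBindingCurve(curve)
  expect_true(fit@converged)
  expect_equal(fit@kD, 20, tolerance = 1e-6)
  expect_equal(fit@rFree, 1, tolerance = 1e-6)
  expect_equal(fit@rComplex, 3.5, tolerance = 1e-6)
  expect_false(fit@extrapolated)
  # All-zero response: flagged failure, no K_D.
  flat <- BindingCurve(conc, rep(0, length(conc)))
  ff <- fitBindingCurve(flat)
  expect_false(ff@converged)
  expect_true(is.na(ff@kD))
})

test_that("K_D estimation is unbiased at realistic noise (100 titrations)", {
  conc <- rep(c(0, 2, 5, 10, 20, 40, 80, 160, 320, 640, 1280, 2560),
              each = 3)
  kds <- vapply(1:100, function(s) {
    r <- withr::with_seed(3000 + s,
      isothermRapp(conc, 20, 1, 3.5) *
        (1 + stats::rnorm(length(conc), 0, 0.01)))
    fitBindingCurve(BindingCurve(conc, r,
                                 rep(1:3, times = 12)))@kD
  }, numeric(1))
  expect_lt(abs(mean(kds) - 20) / 20, 0.05)             # bias < 5%
  expect_lt(sqrt(mean((kds - 20)^2)) / 20, 0.15)        # RMSE < 15%
})

test_that("optimizer minimum agrees with a brute-force grid search", {
  conc <- rep(c(0, 2, 5, 10, 20, 40, 80, 160, 320, 640), each = 3)
  r <- withr::with_seed(77,
    isothermRapp(conc, 20, 1, 3.5) *
      (1 + stats::rnorm(length(conc), 0, 0.01)))
  fit <- fitBindingCurve(BindingCurve(conc, r, rep(1:3, times = 10)))
  # Independent route: profile RSS over a (K_D, r_complex) grid with
  # r_free fixed at the fitted value.
  kdGrid <- seq(10, 35, by = 0.25)
  rcGrid <- seq(3.2, 3.8, by = 0.01)
  rss <- outer(kdGrid, rcGrid, Vectorize(function(kd, rc) {
    sum((r - isothermRapp(conc, kd, fit@rFree, rc))^2)
  }))
  best <- which(rss == min(rss), arr.ind = TRUE)
  expect_equal(fit@kD, kdGrid[best[1]], tolerance = 0.25 / 20)
  expect_equal(fit@rComplex, rcGrid[best[2]], tolerance = 0.01 / 3.5)
})

test_that("mixture partition reproduces the two-method competition logic", {
  mk <- function(hsa, hdl, alpha = 0) {
    CarrierMixture(hsaConc = hsa, hdlProteinConc = hdl,
                   capmixHdlAttenuation = alpha)
  }
  # Capillary mix with alpha = 0: HDL invisible, HSA drop lowers r_app.
  expect_equal(mixtureRapp(mk(4, 0.01), "capillary_mix"),
               mixtureRapp(mk(4, 0.05), "capillary_mix"))
  expect_lt(mixtureRapp(mk(1, 0.05), "capillary_mix"),
            mixtureRapp(mk(4, 0.05), "capillary_mix"))
  # Complex dissociation: r_app rises with HDL, falls with lower HSA.
  expect_gt(mixtureRapp(mk(4, 0.05), "complex_dissociation"),
            mixtureRapp(mk(4, 0.01), "complex_dissociation"))
  expect_lt(mixtureRapp(mk(1, 0.05), "complex_dissociation"),
            mixtureRapp(mk(4, 0.05), "complex_dissociation"))
  # No carriers: free indicator radius.
  expect_equal(mixtureRapp(mk(0, 0), "complex_dissociation"), 1.0)
})

test_that("mixture fractions sum to 1 and bound the apparent radius", {
  set.seed(21)
  for (i in 1:50) {
    mix <- CarrierMixture(hsaConc = stats::runif(1, 0, 6),
                          hdlProteinConc = stats::runif(1, 0, 0.2),
                          capmixHdlAttenuation = stats::runif(1))
    for (m in c("capillary_mix", "complex_dissociation")) {
      f <- mixtureFractions(mix, m)
      expect_equal(f$fFree + f$fHsa + f$fHdl, 1, tolerance = 1e-12)
      r <- mixtureRapp(mix, m)
      expect_gte(r, mix@rFree)
      expect_lte(r, max(mix@rHsaComplex, mix@rHdlComplex))
    }
  }
})

test_that("r_app is monotone in each carrier concentration", {
  hsaSeq <- seq(0, 6, length.out = 12)
  rs <- vapply(hsaSeq, function(h) {
    mixtureRapp(CarrierMixture(h, 0.05), "complex_dissociation")
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
  hdlSeq <- seq(0, 0.3, length.out = 12)
  rs <- vapply(hdlSeq, function(h) {
    mixtureRapp(CarrierMixture(2, h), "complex_dissociation")
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("without HDL the mixture reduces to the HSA isotherm", {
  for (hsa in c(0.002, 0.02, 0.2, 2)) {
    mix <- CarrierMixture(hsaConc = hsa, hdlProteinConc = 0)
    expect_equal(mixtureRapp(mix, "complex_dissociation"),
                 isothermRapp(hsa * 1000, 20, 1, 3.5), tolerance = 1e-12)
  }
})

test_that("mass/molar K_D conversions match the assay's reported values", {
  # 20 ug/mL at 66.5 kDa -> 300 nM (nearest 10 nM).
  expect_equal(round(massToMolarKd(20, 66.5), -1), 300)
  # 1 g/L at 1 kDa -> 1 mM = 1e6 nM.
  expect_equal(massToMolarKd(1000, 1), 1e6)
  # Roundtrip.
  expect_equal(molarToMassKd(massToMolarKd(20, 66.5), 66.5), 20,
               tolerance = 1e-12)
  expect_error(massToMolarKd(20, 0), "positive")
})

test_that("ApoM-equivalent K_D scales the HDL-protein affinity correctly", {
  # 1.25 mg/mL HDL protein at 30 mg ApoM/g, 21 kDa -> 1.8 uM.
  expect_equal(round(apomEquivalentKd(1.25, 30, 21), 1), 1.8)
  # Linearity.
  expect_equal(round(apomEquivalentKd(2.5, 30, 21), 1), 3.6)
  # Mass fraction 1000 mg/g reduces to the plain mass->molar conversion
  # (uM vs nM scale).
  expect_equal(apomEquivalentKd(1.25, 1000, 21) * 1e3,
               massToMolarKd(1250, 21), tolerance = 1e-12)
})
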