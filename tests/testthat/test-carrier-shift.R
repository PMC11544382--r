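test_that("the carrier-shift statistic is a signed difference", {
  expect_equal(deltaRh(3.5, 3.5), 0)
  expect_equal(deltaRh(3.5, 6.0), 2.5)
  # Antisymmetry under swapping inputs; sign-flip option.
  expect_equal(deltaRh(3.5, 6.0), -deltaRh(6.0, 3.5))
  expect_equal(deltaRh(3.5, 6.0, flipSign = TRUE), -2.5)
  expect_true(is.na(deltaRh(NA, 6.0)))
})

test_that("SOFA reclassification uses the printed closed bins", {
  cohort <- data.frame(
    group = c("control", "sepsis", "sepsis", "sepsis", "sepsis",
              "septic_shock"),
    sofa = c(NA, 3, 4, 7, 8, 12))
  bins <- sofaReclassify(cohort)
  expect_equal(as.character(bins),
               c("control", "<=3", "4-7", "4-7", ">=8", ">=8"))
  # Controls stay controls even with a stray SOFA value.
  cohort$sofa[1] <- 5
  expect_equal(as.character(sofaReclassify(cohort))[1], "control")
  expect_error(sofaReclassify(data.frame(group = "sepsis", sofa = -1)),
               "negative")
  # Conservation over a synthetic cohort: bins partition the patients.
  co <- testCohort()
  bins <- sofaReclassify(co)
  pat <- co$group != "control" & !is.na(co$sofa)
  expect_equal(sum(table(bins)[c("<=3", "4-7", ">=8")]), sum(pat))
})

test_that("Mann-Whitney matches hand-derived exact cases", {
  # Complete separation at n = 3 vs 3: U = 0, doubled tail 2/20 = 0.1.
  res <- groupCompare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)
  expect_identical(res$method, "exact")
  # Symmetry in the arguments.
  a <- c(1.2, 3.1, 0.4, 5)
  b <- c(2.2, 4.1, 6.5)
  expect_equal(groupCompare(a, b)$p, groupCompare(b, a)$p)
  # Identical multisets: p = 1.
  expect_equal(groupCompare(c(1, 2, 3), c(3, 1, 2))$p, 1)
  # All-tied data: p = 1 with a warning.
  expect_warning(res <- groupCompare(rep(2, 4), rep(2, 5)), "tied")
  expect_equal(res$p, 1)
  expect_error(groupCompare(1:2, 1:5), "at least 3")
})

test_that("exact Mann-Whitney agrees with brute-force enumeration", {
  set.seed(31)
  sizes <- expand.grid(n1 = 3:6, n2 = 3:6)
  for (k in seq_len(nrow(sizes))) {
    a <- round(stats::rnorm(sizes$n1[k]), 1)
    b <- round(stats::rnorm(sizes$n2[k], mean = 0.5), 1)
    mine <- groupCompare(a, b)
    oracle <- mwBruteForce(a, b)
    expect_equal(mine$U, oracle$U, info = paste(sizes[k, ], collapse = "x"))
    expect_equal(mine$p, oracle$p, info = paste(sizes[k, ], collapse = "x"))
  }
  # Tie-free case also cross-checked against stats::wilcox.test.
  a <- c(0.3, 1.7, 2.9, 4.2, 5.5)
  b <- c(1.1, 2.3, 3.6, 6.8)
  expect_equal(groupCompare(a, b)$p,
               stats::wilcox.test(a, b, exact = TRUE)$p.value)
})

test_that("large tie-free groups fall back to the normal approximation", {
  set.seed(32)
  a <- stats::rnorm(30)
  b <- stats::rnorm(25, 0.8)
  res <- groupCompare(a, b)
  expect_identical(res$method, "normal")
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
})

test_that("Spearman equals Pearson on ranks and handles missing pairs", {
  set.seed(33)
  x <- stats::rnorm(40)
  y <- x + stats::rnorm(40)
  res <- spearmanRho(x, y)
  expect_equal(res$rho, stats::cor(x, y, method = "spearman"),
               tolerance = 1e-15)
  expect_equal(res$rho, stats::cor(rank(x), rank(y)), tolerance = 1e-15)
  # Monotone and anti-monotone extremes.
  expect_equal(spearmanRho(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearmanRho(1:10, -(1:10))$rho, -1)
  # Pairwise deletion with per-analysis n.
  x[3] <- NA
  y[7] <- NA
  expect_equal(spearmanRho(x, y)$n, 38)
  expect_error(spearmanRho(1:3, 3:1), "fewer than 4")
})

test_that("synthetic cohorts show the expected carrier-shift pattern", {
  co <- testCohort()
  res <- runCohortAnalysis(co)
  gs <- groupSummary(res)
  dMeans <- stats::setNames(
    gs$mean[gs$variable == "delta_rh"], gs$group[gs$variable == "delta_rh"])
  # Patients shift toward HDL relative to controls.
  expect_gt(dMeans["sepsis"], dMeans["control"])
  expect_gt(dMeans["trauma"], dMeans["control"])
  expect_gt(dMeans["septic_shock"], dMeans["control"])
  # Reported n's equal the non-missing counts.
  expect_equal(gs$n[gs$variable == "delta_rh" & gs$group == "control"],
               sum(co$group == "control" & !is.na(co$delta_rh)))
  # FIDA radii correlate positively with the LC-MS carrier fractions.
  cors <- cohortCorrelations(res)
  expect_true(all(cors$rho > 0))
  expect_true(all(cors$rho < 1))
})

test_that("outcome association reports the severe-subgroup contrasts", {
  co <- testCohort()
  oa <- outcomeAssociation(co, "septic_shock")
  # Lower complex-dissociation radius among the deceased (the strongly
  # coupled contrast; the ventilation coupling is weaker and only holds
  # in distribution, not per cohort).
  dec <- oa[oa$measure == "r_capdis" & oa$outcome == "deceased", ]
  if (nrow(dec) > 0) {
    expect_true(all(dec$medianYes < dec$medianNo))
  }
  expect_true(all(c("measure", "outcome", "nYes", "nNo", "U", "p")
                  %in% names(oa)))
  # Empty subgroup is skipped with a log entry, not an error.
  empty <- outcomeAssociation(co[co$group == "control", ], "septic_shock")
  expect_equal(nrow(empty), 0)
  expect_match(attr(empty, "skipped"), "n = 0")
})

test_that("the cohort analysis is a pure function of its inputs", {
  co <- testCohort()
  r1 <- runCohortAnalysis(co)
  r2 <- runCohortAnalysis(co)
  expect_identical(groupSummary(r1), groupSummary(r2))
  expect_identical(pairwiseTests(r1), pairwiseTests(r2))
  expect_identical(cohortOutcomes(r1), cohortOutcomes(r2))
})
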