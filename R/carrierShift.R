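# Cohort pipeline: the carrier-shift statistic, group comparisons, SOFA
# reclassification, FIDA vs LC-MS correlation, and outcome association.

.GROUPS <- c("control", "trauma", "sepsis", "septic_shock")
.SOFA_BINS <- c("control", "<=3", "4-7", ">=8")

#' Carrier-shift statistic
#'
#' Difference between the complex-dissociation radius (sensitive to HDL
#' and HSA association) and the capillary-mix radius (sensitive to HSA
#' only). With the default sign convention a positive value indexes S1P
#' reallocation toward HDL. Missing inputs propagate to `NA`.
#'
#' @param rCapmix,rCapdis Radii from the two methods, nm (vectorized).
#' @param flipSign Use the opposite convention (`CapMix - CapDis`).
#' @return `rCapdis - rCapmix` in nm (negated when `flipSign`).
#' @examples
#' deltaRh(3.5, 6.0)  # 2.5
#' @export
deltaRh <- function(rCapmix, rCapdis, flipSign = FALSE) {
  d <- rCapdis - rCapmix
  if (flipSign) -d else d
}

#' Reclassify a cohort by SOFA score
#'
#' Bins patients into SOFA `<=3`, `4-7` and `>=8`; controls keep their own
#' level regardless of any SOFA field. Bin counts conserve the number of
#' patients with a SOFA score.
#'
#' @param cohort A cohort `data.frame` with columns `group` and `sofa`.
#' @return A factor with levels `control`, `<=3`, `4-7`, `>=8` (`NA` for
#'   patients without a SOFA score).
#' @export
sofaReclassify <- function(cohort) {
  stopifnot(all(c("group", "sofa") %in% names(cohort)))
  sofa <- cohort$sofa
  if (any(!is.na(sofa) & sofa < 0)) {
    stop("negative SOFA score", call. = FALSE)
  }
  bin <- rep(NA_character_, nrow(cohort))
  ctl <- cohort$group == "control"
  bin[ctl] <- "control"
  pat <- !ctl & !is.na(sofa)
  bin[pat & sofa <= 3] <- "<=3"
  bin[pat & sofa >= 4 & sofa <= 7] <- "4-7"
  bin[pat & sofa >= 8] <- ">=8"
  factor(bin, levels = .SOFA_BINS)
}

# Exact two-sided Mann-Whitney p by enumerating all assignments of the
# pooled ranks to group A; handles ties through average ranks.
.mwExact <- function(ra, n1, n2, U) {
  N <- n1 + n2
  pick <- utils::combn(N, min(n1, n2))
  tot <- sum(ra)
  if (n1 <= n2) {
    sumsA <- colSums(matrix(ra[pick], nrow = min(n1, n2)))
  } else {
    sumsA <- tot - colSums(matrix(ra[pick], nrow = min(n1, n2)))
  }
  Us <- sumsA - n1 * (n1 + 1) / 2
  tol <- 1e-9
  pLe <- mean(Us <= U + tol)
  pGe <- mean(Us >= U - tol)
  min(1, 2 * min(pLe, pGe))
}

#' Mann-Whitney U test for two groups
#'
#' Two-sided Mann-Whitney U with average-rank tie handling. The null
#' distribution is enumerated exactly when the smaller group has at most
#' `exactMax` observations and the number of rank assignments is
#' manageable (at most `maxCombinations`); otherwise the tie-corrected
#' normal approximation with continuity correction is used. All-tied data
#' yield `p = 1` with a warning.
#'
#' @param a,b Numeric vectors, each with at least 3 non-missing values.
#' @param exactMax Largest min-group size for exact enumeration.
#' @param maxCombinations Cap on the number of enumerated assignments.
#' @return A list with `U` (for group `a`), `p`, and `method`
#'   (`"exact"` or `"normal"`).
#' @examples
#' groupCompare(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
groupCompare <- function(a, b, exactMax = 8, maxCombinations = 2e6) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  n1 <- length(a)
  n2 <- length(b)
  if (n1 < 3 || n2 < 3) {
    stop("each group needs at least 3 non-missing values", call. = FALSE)
  }
  pooled <- c(a, b)
  rr <- rank(pooled)  # average ranks for ties
  U <- sum(rr[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (length(unique(pooled)) == 1) {
    warning("all observations tied; p = 1")
    return(list(U = U, p = 1, method = "degenerate"))
  }

  doExact <- min(n1, n2) <= exactMax &&
    choose(n1 + n2, min(n1, n2)) <= maxCombinations
  if (doExact) {
    p <- .mwExact(rr, n1, n2, U)
    return(list(U = U, p = p, method = "exact"))
  }
  # Normal approximation with tie-corrected variance and continuity
  # correction.
  N <- n1 + n2
  ties <- table(pooled)
  tieCorr <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * (N + 1 - tieCorr)
  mu <- n1 * n2 / 2
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
  list(U = U, p = p, method = "normal")
}

#' Spearman rank correlation with pairwise deletion
#'
#' Spearman rho computed as the Pearson correlation of average ranks, with
#' pairwise deletion of missing data; the p-value uses the t
#' approximation. Refuses fewer than 4 complete pairs.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list with `rho`, `n` (complete pairs) and `p` (two-sided).
#' @export
spearmanRho <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 4) stop("fewer than 4 complete pairs", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  tStat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- if (!is.finite(tStat)) 0 else {
    2 * stats::pt(abs(tStat), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, n = n, p = p)
}

#' Correlate FIDA radii with LC-MS/MS carrier fractions
#'
#' The complex-dissociation radius is compared with the LC-MS HDL-bound
#' S1P fraction, and the capillary-mix radius with the HSA-bound fraction,
#' by Spearman rank correlation with pairwise deletion.
#'
#' @param cohort Cohort `data.frame` with columns `r_capdis`, `r_capmix`,
#'   `lcms_frac_hdl`, `lcms_frac_hsa`.
#' @return `data.frame` with one row per comparison: `comparison`, `rho`,
#'   `n`, `p`.
#' @export
correlateWithLcms <- function(cohort) {
  need <- c("r_capdis", "r_capmix", "lcms_frac_hdl", "lcms_frac_hsa")
  stopifnot(all(need %in% names(cohort)))
  a <- spearmanRho(cohort$r_capdis, cohort$lcms_frac_hdl)
  b <- spearmanRho(cohort$r_capmix, cohort$lcms_frac_hsa)
  data.frame(
    comparison = c("r_capdis_vs_hdl_frac", "r_capmix_vs_hsa_frac"),
    rho = c(a$rho, b$rho), n = c(a$n, b$n), p = c(a$p, b$p),
    stringsAsFactors = FALSE)
}

# One Mann-Whitney contrast of `value` between the two levels of a logical
# outcome; NULL when a class is empty.
.outcomeContrast <- function(value, outcome, measure, outcomeName) {
  ok <- !is.na(value) & !is.na(outcome)
  v <- value[ok]
  o <- outcome[ok]
  nYes <- sum(o)
  nNo <- sum(!o)
  if (nYes < 3 || nNo < 3) return(NULL)
  cmp <- groupCompare(v[o], v[!o])
  data.frame(measure = measure, outcome = outcomeName,
             nYes = nYes, nNo = nNo,
             medianYes = stats::median(v[o]),
             medianNo = stats::median(v[!o]),
             U = cmp$U, p = cmp$p, stringsAsFactors = FALSE)
}

#' Outcome association in a severe subgroup
#'
#' Within the septic-shock group (or the reclassified SOFA >= 8 bin),
#' compares the complex-dissociation radius and CRP between ventilated and
#' non-ventilated patients and between survivors and non-survivors, by
#' Mann-Whitney tests. The scientifically salient contrast: the
#' complex-dissociation radius separates both outcomes, while CRP tracks
#' ventilation but not survival. Comparisons with a single outcome class
#' (or fewer than 3 per class) are skipped and logged in the
#' `"skipped"` attribute.
#'
#' @param cohort Cohort `data.frame` with columns `group`, `sofa`,
#'   `r_capdis`, `ventilated`, `survived`, `crp`.
#' @param subgroup `"septic_shock"` or `"sofa_ge8"`.
#' @return `data.frame` with one row per performed contrast.
#' @export
outcomeAssociation <- function(cohort,
                               subgroup = c("septic_shock", "sofa_ge8")) {
  subgroup <- match.arg(subgroup)
  sel <- if (subgroup == "septic_shock") {
    cohort$group == "septic_shock"
  } else {
    !is.na(cohort$sofa) & cohort$sofa >= 8 & cohort$group != "control"
  }
  sub <- cohort[sel, , drop = FALSE]
  skipped <- character(0)
  if (nrow(sub) < 5) {
    out <- data.frame(measure = character(0), outcome = character(0),
                      nYes = integer(0), nNo = integer(0),
                      medianYes = numeric(0), medianNo = numeric(0),
                      U = numeric(0), p = numeric(0))
    attr(out, "skipped") <- sprintf("subgroup %s: n = %d < 5",
                                    subgroup, nrow(sub))
    return(out)
  }
  rows <- list()
  specs <- list(
    list(v = sub$r_capdis, o = sub$ventilated, m = "r_capdis",
         n = "ventilated"),
    list(v = sub$r_capdis, o = !sub$survived, m = "r_capdis",
         n = "deceased"),
    list(v = sub$crp, o = sub$ventilated, m = "crp", n = "ventilated"),
    list(v = sub$crp, o = !sub$survived, m = "crp", n = "deceased"))
  for (s in specs) {
    row <- .outcomeContrast(s$v, s$o, s$m, s$n)
    if (is.null(row)) {
      skipped <- c(skipped,
                   sprintf("%s by %s: single class or too few per class",
                           s$m, s$n))
    } else {
      row$subgroup <- subgroup
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(measure = character(0), outcome = character(0),
               nYes = integer(0), nNo = integer(0),
               medianYes = numeric(0), medianNo = numeric(0),
               U = numeric(0), p = numeric(0),
               subgroup = character(0))
  }
  attr(out, "skipped") <- skipped
  out
}

# n/mean/sd summary of the three radius variables over a grouping factor.
.summaryBy <- function(cohort, groupVar) {
  vars <- c("r_capmix", "r_capdis", "delta_rh")
  rows <- list()
  for (g in levels(groupVar)) {
    sel <- !is.na(groupVar) & groupVar == g
    for (v in vars) {
      x <- cohort[[v]][sel]
      x <- x[!is.na(x)]
      rows[[length(rows) + 1]] <- data.frame(
        group = g, variable = v, n = length(x),
        mean = if (length(x)) mean(x) else NA_real_,
        sd = if (length(x) > 1) stats::sd(x) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the full cohort analysis
#'
#' Computes the carrier-shift statistic per sample, per-group and per-SOFA
#' bin summaries, pairwise Mann-Whitney tests between groups for each
#' radius variable, the FIDA vs LC-MS Spearman correlations, and the
#' outcome associations in the septic-shock and SOFA >= 8 subgroups.
#' Missing values are handled by pairwise deletion with per-analysis n
#' reporting; p-values are unadjusted, mirroring per-contrast reporting
#' practice for this assay.
#'
#' @param cohort Cohort `data.frame`; see [generateCohort()] for the
#'   column schema.
#' @param flipSign Sign convention flag passed to [deltaRh()].
#' @return A [CohortResult].
#' @export
runCohortAnalysis <- function(cohort, flipSign = FALSE) {
  stopifnot(all(c("group", "r_capmix", "r_capdis") %in% names(cohort)))
  cohort$group <- factor(as.character(cohort$group), levels = .GROUPS)
  cohort$delta_rh <- deltaRh(cohort$r_capmix, cohort$r_capdis,
                             flipSign = flipSign)
  notes <- character(0)

  grpSummary <- .summaryBy(cohort, cohort$group)
  sofaBin <- sofaReclassify(cohort)
  sofaSummary <- .summaryBy(cohort, sofaBin)

  vars <- c("r_capmix", "r_capdis", "delta_rh")
  pairs <- utils::combn(.GROUPS, 2)
  rows <- list()
  for (v in vars) {
    for (j in seq_len(ncol(pairs))) {
      ga <- pairs[1, j]
      gb <- pairs[2, j]
      xa <- cohort[[v]][cohort$group == ga]
      xb <- cohort[[v]][cohort$group == gb]
      xa <- xa[!is.na(xa)]
      xb <- xb[!is.na(xb)]
      if (length(xa) < 3 || length(xb) < 3) {
        notes <- c(notes, sprintf("%s %s vs %s: too few values", v, ga, gb))
        next
      }
      cmp <- groupCompare(xa, xb)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, groupA = ga, groupB = gb,
        nA = length(xa), nB = length(xb), U = cmp$U, p = cmp$p,
        method = cmp$method, stringsAsFactors = FALSE)
    }
  }
  pairwise <- do.call(rbind, rows)

  correlations <- if (all(c("lcms_frac_hdl", "lcms_frac_hsa") %in%
                          names(cohort))) {
    tryCatch(correlateWithLcms(cohort), error = function(e) {
      notes <<- c(notes, paste("LC-MS correlation skipped:",
                               conditionMessage(e)))
      data.frame(comparison = character(0), rho = numeric(0),
                 n = integer(0), p = numeric(0))
    })
  } else {
    data.frame(comparison = character(0), rho = numeric(0),
               n = integer(0), p = numeric(0))
  }

  outcomes <- list()
  if (all(c("ventilated", "survived", "crp") %in% names(cohort))) {
    for (sg in c("septic_shock", "sofa_ge8")) {
      oa <- outcomeAssociation(cohort, sg)
      notes <- c(notes, attr(oa, "skipped"))
      outcomes[[sg]] <- oa
    }
  }
  outcomes <- if (length(outcomes)) do.call(rbind, outcomes) else {
    data.frame()
  }
  rownames(outcomes) <- NULL

  new("CohortResult", groupSummary = grpSummary, pairwiseTests = pairwise,
      sofaSummary = sofaSummary, correlations = correlations,
      outcomes = outcomes, notes = notes)
}
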