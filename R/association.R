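#' @include AllClasses.R
NULL

#' Pearson chi-square test of a case-control contingency table
#'
#' Wraps the standard Pearson test with df = (r-1)(c-1). Yates continuity
#' correction is off by default (the study's Wald machinery and tiny
#' p-values indicate uncorrected Pearson statistics) and, when enabled,
#' applies to 2x2 tables only.
#'
#' @param tab matrix/table of non-negative counts, outcomes in rows.
#' @param yates apply continuity correction to 2x2 tables.
#' @return list with `statistic`, `df`, `p`.
#' @export
chisqAssoc <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || sum(tab) <= 0) stopf("counts must be >= 0 with a positive total")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stopf("degenerate table: a row or column margin is zero")
  }
  correct <- yates && all(dim(tab) == c(2L, 2L))
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Odds ratio with Wald confidence interval
#'
#' OR = (a d)/(b c) with the normal-approximation interval
#' exp(log OR +/- z sqrt(1/a + 1/b + 1/c + 1/d)). If any cell is zero the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied and flagged.
#' The exact normal quantile (e.g. 1.959964 at 95%) is used.
#'
#' @param a,b,c,d counts: exposed cases, unexposed cases, exposed controls,
#'   unexposed controls.
#' @param level confidence level (default 0.95).
#' @return list with `or`, `ciLow`, `ciHigh`, `corrected`, `level`.
#' @examples
#' oddsRatioCI(59, 414, 20, 694)  # OR about 4.9
#' @export
oddsRatioCI <- function(a, b, c, d, level = 0.95) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stopf("counts must be >= 0")
  if ((a == 0 && d == 0) || (b == 0 && c == 0)) {
    stopf("odds ratio undefined: zero cells on a diagonal")
  }
  corrected <- any(counts == 0)
  if (corrected) counts <- counts + 0.5
  or <- (counts[1] * counts[4]) / (counts[2] * counts[3])
  z <- qnorm(1 - (1 - level) / 2)
  selog <- sqrt(sum(1 / counts))
  list(or = or,
       ciLow = exp(log(or) - z * selog),
       ciHigh = exp(log(or) + z * selog),
       corrected = corrected, level = level)
}

#' Maximum-likelihood logistic regression with separation guard
#'
#' Fits a binomial GLM by iteratively reweighted least squares (convergence
#' tolerance 1e-8, at most 25 iterations) and returns Wald per-term tests.
#' Rank-deficient designs are rejected, and complete separation is reported
#' as a non-convergence error naming the offending predictor rather than
#' returning meaningless estimates.
#'
#' @param outcome binary vector (0/1 or logical).
#' @param predictors numeric matrix or data.frame of coded predictors
#'   (columns named; intercept added internally).
#' @param tol IRLS deviance tolerance.
#' @param maxIter maximum IRLS iterations.
#' @return a [LogisticFit-class].
#' @export
fitRiskLogistic <- function(outcome, predictors, tol = 1e-8, maxIter = 25L) {
  y <- as.integer(outcome)
  if (!all(y %in% 0:1)) stopf("outcome must be binary")
  if (sum(y) == 0L || sum(y) == length(y)) {
    stopf("need at least one case and one control")
  }
  X <- as.matrix(as.data.frame(predictors))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  design <- cbind("(Intercept)" = 1, X)
  if (qr(design)$rank < ncol(design)) {
    stopf("design error: predictor matrix is rank deficient")
  }
  dat <- data.frame(.y = y, X, check.names = FALSE)
  fml <- stats::as.formula(paste(".y ~", paste0("`", colnames(X), "`",
                                                collapse = " + ")))
  fit <- suppressWarnings(
    glm(fml, data = dat, family = binomial(),
        control = glm.control(epsilon = tol, maxit = maxIter))
  )
  est <- coef(fit)
  names(est) <- gsub("`", "", names(est), fixed = TRUE)
  if (!fit$converged || any(abs(est[-1]) > 15)) {
    worst <- names(est[-1])[which.max(abs(est[-1]))]
    stopf("logistic fit did not converge (complete or quasi-separation on predictor '%s')",
          worst)
  }
  se <- sqrt(diag(vcov(fit)))
  names(se) <- names(est)
  z <- est / se
  note <- character()
  fitted <- fit$fitted.values
  if (any(fitted < 1e-8) || any(fitted > 1 - 1e-8)) {
    note <- "some fitted probabilities are numerically 0 or 1"
  }
  new("LogisticFit", coefficients = est, se = se, z = z,
      p = 2 * pnorm(-abs(z)), converged = fit$converged,
      iterations = as.integer(fit$iter), note = note)
}

codeDosage <- function(dosage, mode) {
  switch(mode,
         dominant = as.integer(dosage >= 1L),
         recessive = as.integer(dosage == 2L),
         stopf("unknown inheritance mode '%s'", mode))
}

#' Test MSH5 x HLA effect independence by a logistic cross-term
#'
#' Codes rs3130484 as carrier (dominant: dosage >= 1) or homozygote
#' (recessive: dosage = 2), codes HLA as the DQ2.5 risk-diplotype indicator,
#' and fits `status ~ MSH5 + HLA + MSH5:HLA` on CD cases vs unrelated
#' controls. A non-significant cross-term is the study's marker of
#' independent (multiplicative) effects.
#'
#' @param cohort genotype table; diplotypes are called on the fly when absent.
#' @param mode `"dominant"` or `"recessive"`.
#' @param caseGroup,controlGroup group labels to contrast.
#' @return a [LogisticFit-class]; the cross-term row is named `msh5:hla`.
#' @export
interactionTest <- function(cohort, mode = c("dominant", "recessive"),
                            caseGroup = "CD", controlGroup = "control") {
  mode <- match.arg(mode)
  if (!"is_risk" %in% colnames(cohort)) cohort <- callCohortDiplotypes(cohort)
  dat <- cohort[cohort$group %in% c(caseGroup, controlGroup), , drop = FALSE]
  y <- as.integer(dat$group == caseGroup)
  msh5 <- codeDosage(dat$rs3130484, mode)
  hla <- as.integer(dat$is_risk)
  X <- cbind(msh5 = msh5, hla = hla, "msh5:hla" = msh5 * hla)
  fit <- fitRiskLogistic(y, X)
  cells <- table(msh5, hla)
  if (any(cells == 0L)) {
    fit@note <- c(fit@note, "empty coded cell(s): interaction estimate is fragile")
  }
  fit
}

#' Case-control contrast for one SNP between two groups
#'
#' The replication analysis: a genotype-frequency chi-square (2 x 3), an
#' allele-frequency chi-square (2 x 2) and the allelic odds ratio with Wald
#' CI for the named SNP between two cohort groups.
#'
#' @param cohort genotype table.
#' @param groupA,groupB group labels (A is the "exposed" outcome group, e.g.
#'   `"CD"` or `"family"`; B the reference, e.g. `"control"`).
#' @param snp dosage column name (e.g. `"rs3130484"`).
#' @param yates passed to [chisqAssoc()].
#' @return list with `genotype` (chi-square on genotype counts), `allele`
#'   (chi-square on allele counts), `or` (allelic [oddsRatioCI()]) and the
#'   underlying `genotypeCounts` matrix.
#' @export
replicationContrast <- function(cohort, groupA = "CD", groupB = "control",
                                snp = "rs3130484", yates = FALSE) {
  for (g in c(groupA, groupB)) {
    if (!any(cohort$group == g)) stopf("no samples with group label '%s'", g)
  }
  if (!snp %in% colnames(cohort)) stopf("unknown SNP column '%s'", snp)
  dat <- cohort[cohort$group %in% c(groupA, groupB), c("group", snp)]
  dat <- dat[!is.na(dat[[snp]]), , drop = FALSE]
  counts <- matrix(0L, 2L, 3L,
                   dimnames = list(c(groupA, groupB), c("0", "1", "2")))
  for (g in rownames(counts)) {
    tab <- table(factor(dat[[snp]][dat$group == g], levels = 0:2))
    counts[g, ] <- as.integer(tab)
  }
  gkeep <- colSums(counts) > 0L
  genotype <- chisqAssoc(counts[, gkeep, drop = FALSE], yates = yates)
  minor <- counts %*% c(0L, 1L, 2L)
  major <- counts %*% c(2L, 1L, 0L)
  alleles <- cbind(minor = as.integer(minor), major = as.integer(major))
  rownames(alleles) <- rownames(counts)
  allele <- chisqAssoc(alleles, yates = yates)
  orci <- oddsRatioCI(alleles[groupA, "minor"], alleles[groupA, "major"],
                      alleles[groupB, "minor"], alleles[groupB, "major"])
  list(genotype = genotype, allele = allele, or = orci,
       genotypeCounts = counts)
}
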