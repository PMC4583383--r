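#' @include AllClasses.R
NULL

#' Construct a risk rule
#'
#' @param name rule label.
#' @param predicate `function(diplotype, msh5, dqa1)` returning a logical
#'   vector; must be pure and total over valid inputs.
#' @return a [RiskRule-class].
#' @export
riskRule <- function(name, predicate) {
  new("RiskRule", name = name, predicate = predicate)
}

carrierIndicator <- function(dosage, carrier) {
  switch(carrier,
         atLeastOne = dosage >= 1L,
         exactlyOne = dosage == 1L,
         stopf("unknown carrier semantics '%s'", carrier))
}

#' The HLA-only risk rule
#'
#' Positive iff the diplotype is one of the three DQ2.5-containing risk
#' genotypes. On the study's published frequency table this rule attains
#' 45.5% sensitivity at 92.9% specificity.
#'
#' @return a [RiskRule-class].
#' @export
ruleHlaOnly <- function() {
  riskRule("HLA-only", function(diplotype, msh5, dqa1) {
    labelRisk(diplotype)
  })
}

#' The HLA-or-MSH5 combination rule
#'
#' Positive iff the HLA-only rule fires or the sample carries the rs3130484
#' minor allele. "Carries a single minor allele" is read as at-least-one
#' (dominant) by default; an exactly-one dialect is available.
#'
#' @param carrier `"atLeastOne"` (default) or `"exactlyOne"`.
#' @return a [RiskRule-class].
#' @export
ruleHlaOrMsh5 <- function(carrier = c("atLeastOne", "exactlyOne")) {
  carrier <- match.arg(carrier)
  riskRule(paste0("HLA-or-MSH5", if (carrier == "exactlyOne") " (het only)"),
           function(diplotype, msh5, dqa1) {
    if (any(is.na(msh5))) stopf("missing rs3130484 dosage")
    labelRisk(diplotype) | carrierIndicator(msh5, carrier)
  })
}

#' The MSH5-and-DQA1 combination rule
#'
#' Positive iff the sample carries the rs3130484 minor allele and the
#' rs9272346 minor allele.
#'
#' @param carrier `"atLeastOne"` (default) or `"exactlyOne"`.
#' @return a [RiskRule-class].
#' @export
ruleMsh5AndDqa1 <- function(carrier = c("atLeastOne", "exactlyOne")) {
  carrier <- match.arg(carrier)
  riskRule(paste0("MSH5-and-DQA1", if (carrier == "exactlyOne") " (het only)"),
           function(diplotype, msh5, dqa1) {
    if (any(is.na(msh5))) stopf("missing rs3130484 dosage")
    if (any(is.na(dqa1))) stopf("missing rs9272346 dosage")
    carrierIndicator(msh5, carrier) & carrierIndicator(dqa1, carrier)
  })
}

#' Apply a risk rule to a cohort
#'
#' @param rule a [RiskRule-class].
#' @param cohort genotype table with a `diplotype` column (call
#'   [callCohortDiplotypes()] first if needed) and the rs3130484/rs9272346
#'   dosage columns the rule requires.
#' @return logical vector, one element per row of `cohort`.
#' @export
applyRule <- function(rule, cohort) {
  if (!"diplotype" %in% colnames(cohort)) {
    stopf("cohort has no 'diplotype' column; run callCohortDiplotypes() first")
  }
  rule@predicate(cohort$diplotype,
                 cohort$rs3130484 %||% rep(NA_integer_, nrow(cohort)),
                 cohort$rs9272346 %||% rep(NA_integer_, nrow(cohort)))
}

#' Evaluate a risk rule against disease status
#'
#' Counts true/false positives and negatives of the rule's prediction
#' against case/control status. Family members (any group other than the
#' case and control labels) are excluded, matching the study's evaluation on
#' patients vs unrelated controls.
#'
#' @param rule a [RiskRule-class].
#' @param cohort genotype table with diplotypes.
#' @param caseGroup,controlGroup group labels.
#' @return a [ConfusionMatrix-class].
#' @export
evaluateRule <- function(rule, cohort, caseGroup = "CD",
                         controlGroup = "control") {
  dat <- cohort[cohort$group %in% c(caseGroup, controlGroup), , drop = FALSE]
  if (!any(dat$group == caseGroup) || !any(dat$group == controlGroup)) {
    stopf("need at least one case and one control to evaluate a rule")
  }
  pred <- applyRule(rule, dat)
  case <- dat$group == caseGroup
  new("ConfusionMatrix", rule = rule@name,
      tp = sum(pred & case), fn = sum(!pred & case),
      fp = sum(pred & !case), tn = sum(!pred & !case))
}

#' Constrained search for the best risk rule
#'
#' Evaluates every candidate rule and, among those meeting the minimum
#' specificity (default 80%, the study's constraint), returns the
#' sensitivity-maximising rule; ties are broken by higher specificity, then
#' by rule name. The full audit table of all candidates is always returned.
#'
#' @param candidates list of [RiskRule-class] objects.
#' @param cohort genotype table with diplotypes.
#' @param minSpecificity constraint in \[0,1\] (default 0.80).
#' @param ... passed to [evaluateRule()].
#' @return list with `best` (a [ConfusionMatrix-class], or NULL when no
#'   candidate meets the constraint) and `audit` (data.frame over all
#'   candidates with a `meets_constraint` column).
#' @export
searchBestRule <- function(candidates, cohort, minSpecificity = 0.80, ...) {
  if (!length(candidates)) stopf("need at least one candidate rule")
  cms <- lapply(candidates, evaluateRule, cohort = cohort, ...)
  audit <- do.call(rbind, lapply(cms, as.data.frame))
  audit$meets_constraint <- audit$specificity >= minSpecificity
  eligible <- which(audit$meets_constraint)
  if (!length(eligible)) {
    return(list(best = NULL, audit = audit))
  }
  ord <- eligible[order(-audit$sensitivity[eligible],
                        -audit$specificity[eligible],
                        audit$rule[eligible])]
  list(best = cms[[ord[1L]]], audit = audit)
}
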