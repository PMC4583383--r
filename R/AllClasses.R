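#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

#' DQ diplotype category levels
#'
#' The seven diplotype categories used throughout: the six genotype classes
#' built from the HLA-DQ2.5, DQ8 and DQ2.2 haplotypes, plus `OTHER` for
#' samples carrying fewer than two typed haplotype copies.
#'
#' @return character vector of length 7, in fixed order.
#' @export
dqCategories <- function() {
  c("DQ2.5/DQ2.5", "DQ2.5/DQ2.2", "DQ2.5/DQ8",
    "DQ8/DQ2.2", "DQ8/DQ8", "DQ2.2/DQ2.2", "OTHER")
}

#' Diplotype categories that carry HLA risk
#'
#' The three DQ2.5-containing genotypes found at elevated frequency in CD
#' patients; every risk rule treats exactly these as HLA-positive.
#'
#' @return character vector of length 3.
#' @export
hlaRiskCategories <- function() {
  c("DQ2.5/DQ2.5", "DQ2.5/DQ2.2", "DQ2.5/DQ8")
}

## the six non-OTHER categories, i.e. the rows of the diplotype frequency table
tableCategories <- function() setdiff(dqCategories(), "OTHER")

#' CohortSpec: parameters of the synthetic cohort generator
#'
#' Describes a case/control(/family) cohort by its diplotype category
#' frequencies, the group-specific minor-allele frequency of the MSH5 variant
#' rs3130484, and the squared correlation between rs9272346 carriage and
#' DQ2.5 carriage. Frequencies over the six named diplotype categories may sum
#' to less than one; the remainder is the `OTHER` category, which carries zero
#' dosage at all four HLA tag SNPs.
#'
#' @slot nCases,nControls,nFamily cohort sizes (non-negative integers).
#' @slot caseFreqs,controlFreqs,familyFreqs named fractions over the six
#'   diplotype categories; each sums to at most 1.
#' @slot msh5MafCases,msh5MafControls,msh5MafFamily rs3130484 minor-allele
#'   frequencies per group (Hardy-Weinberg sampling).
#' @slot dqa1R2 squared correlation in \[0,1\] between rs9272346 carriage and
#'   DQ2.5 carriage.
#' @slot dqa1HomFrac probability that an rs9272346 carrier is homozygous.
#' @slot seed integer RNG seed.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(
    nCases = "integer", nControls = "integer", nFamily = "integer",
    caseFreqs = "numeric", controlFreqs = "numeric", familyFreqs = "numeric",
    msh5MafCases = "numeric", msh5MafControls = "numeric",
    msh5MafFamily = "numeric",
    dqa1R2 = "numeric", dqa1HomFrac = "numeric", seed = "integer"
  )
)

validCohortSpec <- function(object) {
  msg <- character()
  for (nm in c("nCases", "nControls", "nFamily")) {
    if (slot(object, nm) < 0L) msg <- c(msg, paste(nm, "must be >= 0"))
  }
  for (nm in c("caseFreqs", "controlFreqs", "familyFreqs")) {
    f <- slot(object, nm)
    if (!identical(sort(names(f)), sort(tableCategories()))) {
      msg <- c(msg, paste(nm, "must be named by the six diplotype categories"))
    } else {
      if (any(f < 0) || any(f > 1)) msg <- c(msg, paste(nm, "outside [0,1]"))
      if (sum(f) > 1 + 1e-12) msg <- c(msg, paste(nm, "sums to more than 1"))
    }
  }
  for (nm in c("msh5MafCases", "msh5MafControls", "msh5MafFamily",
               "dqa1R2", "dqa1HomFrac")) {
    v <- slot(object, nm)
    if (v < 0 || v > 1) msg <- c(msg, paste(nm, "must lie in [0,1]"))
  }
  if (length(msg)) msg else TRUE
}
setValidity("CohortSpec", validCohortSpec)

#' PoolDesign: assignment of samples to DNA pools
#'
#' @slot poolIds array/pool identifiers.
#' @slot poolGroup named character; `"case"` or `"control"` per pool.
#' @slot poolMembers named list of sample-id vectors, disjoint across pools.
#' @exportClass PoolDesign
setClass("PoolDesign",
  representation(poolIds = "character", poolGroup = "character",
                 poolMembers = "list")
)

setValidity("PoolDesign", function(object) {
  msg <- character()
  if (!identical(object@poolIds, names(object@poolMembers)) ||
      !identical(object@poolIds, names(object@poolGroup))) {
    msg <- c(msg, "poolIds, poolGroup and poolMembers must agree")
  }
  if (!all(object@poolGroup %in% c("case", "control"))) {
    msg <- c(msg, "poolGroup values must be 'case' or 'control'")
  }
  members <- unlist(object@poolMembers, use.names = FALSE)
  if (anyDuplicated(members)) {
    msg <- c(msg, "a sample belongs to more than one pool")
  }
  if (length(msg)) msg else TRUE
})

#' ArrayNoiseModel: measurement noise of the pooled arrays
#'
#' Additive noise on the relative allele signal (RAS): an independent
#' per-SNP-per-array Gaussian term plus a shared per-array offset; simulated
#' RAS is truncated to \[0,1\].
#'
#' @slot rasNoiseSd standard deviation of the per-SNP-per-array term.
#' @slot arrayBiasSd standard deviation of the per-array offset.
#' @slot seed integer RNG seed.
#' @exportClass ArrayNoiseModel
setClass("ArrayNoiseModel",
  representation(rasNoiseSd = "numeric", arrayBiasSd = "numeric",
                 seed = "integer")
)

setValidity("ArrayNoiseModel", function(object) {
  if (object@rasNoiseSd < 0 || object@arrayBiasSd < 0) {
    "noise standard deviations must be >= 0"
  } else TRUE
})

#' PoolIntensityExperiment: two-channel pooled-array signals
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] with assays `A` and
#' `B` (non-negative channel signals, SNP x array), SNP coordinates as row
#' ranges, and per-array `pool_id` and `group` in `colData`.
#'
#' @exportClass PoolIntensityExperiment
setClass("PoolIntensityExperiment", contains = "RangedSummarizedExperiment")

setValidity("PoolIntensityExperiment", function(object) {
  msg <- character()
  if (!all(c("A", "B") %in% SummarizedExperiment::assayNames(object))) {
    msg <- c(msg, "assays 'A' and 'B' are required")
  } else {
    if (any(SummarizedExperiment::assay(object, "A") < 0, na.rm = TRUE) ||
        any(SummarizedExperiment::assay(object, "B") < 0, na.rm = TRUE)) {
      msg <- c(msg, "channel signals must be >= 0")
    }
  }
  if (!all(c("pool_id", "group") %in%
           colnames(SummarizedExperiment::colData(object)))) {
    msg <- c(msg, "colData must carry 'pool_id' and 'group'")
  } else if (!all(object$group %in% c("case", "control"))) {
    msg <- c(msg, "array group labels must be 'case' or 'control'")
  }
  if (length(msg)) msg else TRUE
})

#' RasExperiment: relative allele signals per SNP per array
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] with a single `ras`
#' assay holding A/(A+B) in \[0,1\] (NA where both channels were zero), SNP
#' coordinates as row ranges and per-array `group` labels.
#'
#' @exportClass RasExperiment
setClass("RasExperiment", contains = "RangedSummarizedExperiment")

setValidity("RasExperiment", function(object) {
  msg <- character()
  if (!"ras" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'ras' is required")
  } else {
    r <- SummarizedExperiment::assay(object, "ras")
    if (any(r < 0 | r > 1, na.rm = TRUE)) msg <- c(msg, "RAS outside [0,1]")
  }
  if (!"group" %in% colnames(SummarizedExperiment::colData(object))) {
    msg <- c(msg, "colData must carry 'group'")
  } else if (!all(object$group %in% c("case", "control"))) {
    msg <- c(msg, "array group labels must be 'case' or 'control'")
  }
  if (length(msg)) msg else TRUE
})

#' RiskRule: a deterministic risk predicate
#'
#' A named, pure predicate over (diplotype category, rs3130484 dosage,
#' rs9272346 dosage), vectorised over samples.
#'
#' @slot name rule label used in reports.
#' @slot predicate `function(diplotype, msh5, dqa1)` returning a logical
#'   vector.
#' @exportClass RiskRule
setClass("RiskRule",
  representation(name = "character", predicate = "function")
)

#' ConfusionMatrix: rule performance against disease status
#'
#' @slot rule rule label.
#' @slot tp,fp,tn,fn integer counts; `tp + fn` is the number of evaluable
#'   cases and `tn + fp` the number of evaluable controls.
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
  representation(rule = "character", tp = "integer", fp = "integer",
                 tn = "integer", fn = "integer")
)

setValidity("ConfusionMatrix", function(object) {
  if (any(c(object@tp, object@fp, object@tn, object@fn) < 0L)) {
    "counts must be >= 0"
  } else TRUE
})

#' LogisticFit: a converged logistic-regression fit
#'
#' Thin container for a binomial GLM fit: per-term estimates, Wald standard
#' errors, z statistics and p-values, with convergence metadata.
#'
#' @slot coefficients named estimates on the log-odds scale.
#' @slot se,z,p per-term Wald standard errors, z statistics, p-values.
#' @slot converged logical convergence flag.
#' @slot iterations IRLS iterations used.
#' @slot note diagnostic notes (e.g. sparse coded cells).
#' @exportClass LogisticFit
setClass("LogisticFit",
  representation(coefficients = "numeric", se = "numeric", z = "numeric",
                 p = "numeric", converged = "logical", iterations = "integer",
                 note = "character")
)
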