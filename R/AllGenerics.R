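#' @include AllClasses.R
NULL

#' @rdname ConfusionMatrix-class
#' @param object a `ConfusionMatrix`.
#' @export
setGeneric("sensitivity", function(object) standardGeneric("sensitivity"))

#' @rdname ConfusionMatrix-class
#' @export
setGeneric("specificity", function(object) standardGeneric("specificity"))

#' @rdname ConfusionMatrix-class
#' @export
setGeneric("ppv", function(object) standardGeneric("ppv"))

#' @rdname ConfusionMatrix-class
#' @export
setGeneric("npv", function(object) standardGeneric("npv"))

#' @rdname RiskRule-class
#' @param object a `RiskRule`.
#' @export
setGeneric("ruleName", function(object) standardGeneric("ruleName"))

#' @rdname LogisticFit-class
#' @param object a `LogisticFit`.
#' @export
setGeneric("waldP", function(object) standardGeneric("waldP"))

setMethod("sensitivity", "ConfusionMatrix",
          function(object) object@tp / (object@tp + object@fn))
setMethod("specificity", "ConfusionMatrix",
          function(object) object@tn / (object@tn + object@fp))
setMethod("ppv", "ConfusionMatrix",
          function(object) object@tp / (object@tp + object@fp))
setMethod("npv", "ConfusionMatrix",
          function(object) object@tn / (object@tn + object@fn))
setMethod("ruleName", "RiskRule", function(object) object@name)
setMethod("waldP", "LogisticFit", function(object) object@p)

#' @describeIn ConfusionMatrix-class counts and half-up rounded percentage
#'   rates, in the formatting convention of the study tables.
#' @export
setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix for rule '%s'\n", object@rule))
  cat(sprintf("  TP %d  FN %d   (cases    %d)\n",
              object@tp, object@fn, object@tp + object@fn))
  cat(sprintf("  FP %d  TN %d   (controls %d)\n",
              object@fp, object@tn, object@fp + object@tn))
  cat(sprintf("  sensitivity %.1f%%  specificity %.1f%%\n",
              roundHalfUp(100 * sensitivity(object), 1),
              roundHalfUp(100 * specificity(object), 1)))
})

setMethod("show", "RiskRule", function(object) {
  cat(sprintf("RiskRule: %s\n", object@name))
})

setMethod("show", "LogisticFit", function(object) {
  cat(sprintf("LogisticFit (%sconverged, %d iterations)\n",
              if (object@converged) "" else "NOT ", object@iterations))
  print(data.frame(estimate = object@coefficients, se = object@se,
                   z = object@z, p = object@p))
  if (length(object@note)) cat("note:", object@note, sep = "\n  ")
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d cases, %d controls, %d family members\n",
              object@nCases, object@nControls, object@nFamily))
  cat(sprintf("  rs3130484 MAF case/control/family: %.3f/%.3f/%.3f\n",
              object@msh5MafCases, object@msh5MafControls,
              object@msh5MafFamily))
  cat(sprintf("  rs9272346 ~ DQ2.5 carriage r^2: %.2f\n", object@dqa1R2))
})

setMethod("show", "PoolDesign", function(object) {
  sizes <- lengths(object@poolMembers)
  cat(sprintf("PoolDesign: %d case + %d control pools, sizes %d-%d\n",
              sum(object@poolGroup == "case"),
              sum(object@poolGroup == "control"),
              min(sizes), max(sizes)))
})

#' @describeIn ConfusionMatrix-class one-row data.frame of counts and rates
#'   (rates both as fractions and as half-up one-decimal percentages).
#' @param x a `ConfusionMatrix`.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "ConfusionMatrix", function(x, ...) {
  data.frame(
    rule = x@rule, tp = x@tp, fp = x@fp, tn = x@tn, fn = x@fn,
    sensitivity = sensitivity(x), specificity = specificity(x),
    ppv = ppv(x), npv = npv(x),
    sensitivity_pct = roundHalfUp(100 * sensitivity(x), 1),
    specificity_pct = roundHalfUp(100 * specificity(x), 1),
    stringsAsFactors = FALSE
  )
})
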