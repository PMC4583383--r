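#' @importFrom stats pt pnorm qnorm rnorm rbinom runif median p.adjust
#'   chisq.test glm glm.control binomial coef vcov setNames complete.cases
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

## keep x first so matrix dims survive pmin/pmax
clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves going up (the convention used
#' for the percentage tables in the study output), unlike [base::round()]'s
#' round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector.
#' @export
roundHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## seed must stay a 32-bit integer after offsetting
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
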