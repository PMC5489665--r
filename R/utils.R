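## Internal helpers shared across the package.

## Classed errors so callers (and tests) can distinguish failure modes.
.err <- function(class, msg) {
  stop(errorCondition(msg, class = c(paste0("stableRG_", class), "stableRG_error")))
}

#' Geometric mean
#'
#' Geometric mean of a vector of positive values, the aggregation used for
#' multi-gene normalization factors and calibrator baselines.
#'
#' @param x Numeric vector of positive values.
#' @return A single positive number.
#' @examples
#' geomMean(c(1, 4)) # 2
#' @export
geomMean <- function(x) {
  if (length(x) == 0L) .err("empty_input", "geometric mean of an empty vector")
  if (anyNA(x) || any(x <= 0)) {
    .err("nonpositive_quantity", "geometric mean requires positive, non-missing values")
  }
  exp(mean(log(x)))
}

## Coerce a CtExperiment or bare matrix to the numeric Ct grid.
.ctMatrix <- function(x) {
  if (is(x, "CtExperiment")) {
    SummarizedExperiment::assay(x, "ct")
  } else {
    m <- as.matrix(x)
    if (!is.numeric(m)) .err("non_numeric", "Ct values must be numeric")
    m
  }
}

## Deterministic 1..n ranks: ties broken by gene id so permuting input rows
## never changes a gene's rank.
.strictRank <- function(score, ids) {
  r <- integer(length(score))
  r[order(score, ids)] <- seq_along(score)
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a
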