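## Genome-scale candidate mining: the transcriptome screen that nominates
## putative reference genes before any qPCR is run. A candidate must show
## medium expression in EVERY condition (default window 200-2000 RPKM) and a
## coefficient of variation at or below the threshold (default 0.35).

#' Relative expression across conditions
#'
#' Divide a gene's expression values by their arithmetic mean, so the output
#' averages exactly 1 and profiles of differently expressed genes become
#' comparable on one axis.
#'
#' @param values Non-negative numeric vector with positive mean.
#' @return Numeric vector of the same length with mean 1.
#' @examples
#' relativeExpression(c(1, 2, 3)) # 0.5 1.0 1.5
#' @export
relativeExpression <- function(values) {
  if (any(values < 0)) .err("negative_value", "expression values must be >= 0")
  m <- mean(values)
  if (!is.finite(m) || m <= 0) .err("zero_mean", "mean expression must be > 0")
  values / m
}

#' Coefficient of variation
#'
#' Sample (n-1) standard deviation divided by the mean; scale-free, so it is
#' identical on raw and on relative expression values.
#'
#' @param values Numeric vector, length >= 2, positive mean.
#' @return Non-negative scalar.
#' @examples
#' coefficientOfVariation(c(1, 2, 3)) # 0.5
#' @export
coefficientOfVariation <- function(values) {
  if (length(values) < 2L) .err("too_few_values", "CV needs at least 2 values")
  m <- mean(values)
  if (!is.finite(m) || m <= 0) .err("zero_mean", "mean expression must be > 0")
  stats::sd(values) / m
}

#' Expression-window filter
#'
#' Flag genes whose expression lies inside \code{[lo, hi]} (inclusive
#' bounds) in \emph{every} condition column.
#'
#' @param m Numeric matrix, genes x conditions (or an object coercible to
#'   one).
#' @param lo,hi Window bounds, \code{lo < hi}.
#' @return Named logical vector, one flag per gene.
#' @export
expressionWindowFilter <- function(m, lo = 200, hi = 2000) {
  if (!(lo < hi)) .err("bad_window", "window requires lo < hi")
  m <- as.matrix(m)
  flags <- rowSums(m < lo | m > hi) == 0L
  names(flags) <- rownames(m)
  flags
}

#' Screen an expression matrix for reference-gene candidates
#'
#' Apply the expression window and the CV threshold and report, per gene,
#' the mean expression, the CV and all three pass flags. \code{selected} is
#' true exactly when the gene passes both filters.
#'
#' @param m Numeric matrix, genes x conditions.
#' @param exprMin,exprMax Inclusive expression window (default 200-2000).
#' @param cvMax CV threshold; pass means \code{cv <= cvMax} (default 0.35).
#' @return A data.frame with columns gene, meanExpression, cv, inWindow,
#'   passesCv, selected; attribute \code{"nSelected"} carries the count.
#' @examples
#' m <- matrix(c(500, 510, 490, 480, 100, 900, 1500, 300), nrow = 2,
#'             byrow = TRUE, dimnames = list(c("stable", "wild"), NULL))
#' screenCandidates(m)
#' @export
screenCandidates <- function(m, exprMin = 200, exprMax = 2000, cvMax = 0.35) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) .err("too_few_values", "screening needs >= 2 condition columns")
  if (any(m < 0)) .err("negative_value", "expression values must be >= 0")
  if (cvMax <= 0) .err("bad_threshold", "cvMax must be > 0")
  genes <- rownames(m) %||% sprintf("gene%03d", seq_len(nrow(m)))
  inWindow <- unname(expressionWindowFilter(m, exprMin, exprMax))
  cv <- apply(m, 1, coefficientOfVariation)
  res <- data.frame(
    gene = genes,
    meanExpression = rowMeans(m),
    cv = unname(cv),
    inWindow = inWindow,
    passesCv = unname(cv <= cvMax),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  res$selected <- res$inWindow & res$passesCv
  attr(res, "nSelected") <- sum(res$selected)
  res
}
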