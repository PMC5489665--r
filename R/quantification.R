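## Standard-curve efficiency fitting, multi-gene normalization factors and
## 2^-ddCt relative quantification.

#' Fit a standard curve to a dilution series
#'
#' Ordinary least-squares regression of Ct on log10 relative template
#' amount. The amplification efficiency follows from the slope as
#' \code{E = 10^(-1/slope) - 1}; a 10-fold series of a perfectly doubling
#' primer pair has slope -3.3219 and E = 1.
#'
#' @param dilutionLog10 Numeric, log10 relative template amounts (>= 3
#'   distinct values).
#' @param ct Numeric Ct values, same length.
#' @return A [StandardCurve-class].
#' @examples
#' x <- c(0, -1, -2, -3)
#' sc <- fitStandardCurve(x, 30 - log2(10) * x)
#' efficiency(sc) # 1
#' @export
fitStandardCurve <- function(dilutionLog10, ct) {
  if (length(dilutionLog10) != length(ct)) {
    .err("length_mismatch", "dilution and Ct vectors differ in length")
  }
  if (length(ct) < 3L) .err("too_few_values", "standard curve needs >= 3 points")
  if (length(unique(dilutionLog10)) < 2L) {
    .err("degenerate_design", "all dilution values are equal")
  }
  fit <- stats::lm(ct ~ dilutionLog10)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r2 <- if (stats::var(ct) == 0) 1 else stats::cor(ct, stats::fitted(fit))^2
  new("StandardCurve",
      dilutionLog10 = dilutionLog10, ct = ct,
      slope = slope, intercept = intercept,
      efficiency = 10^(-1 / slope) - 1,
      rSquared = r2)
}

#' @describeIn StandardCurve-class The fitted amplification efficiency.
#' @export
setMethod("efficiency", "StandardCurve", function(x) x@efficiency)

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf("StandardCurve: slope = %.4g, E = %.4g, R^2 = %.4g (%d points)\n",
              object@slope, object@efficiency, object@rSquared,
              length(object@ct)))
})

#' Per-sample normalization factor from reference genes
#'
#' The geometric mean, across the chosen reference genes, of each sample's
#' relative quantities (see [ctToQuantity()]). With a single gene the
#' normalization factor is that gene's quantity vector.
#'
#' @param x A [CtExperiment-class] or complete Ct matrix.
#' @param rgGenes Character, reference genes (subset of rownames).
#' @param ampFactor Amplification factor(s) for the quantity transform.
#' @param collapseTech Collapse technical replicates first (default TRUE;
#'   ignored for bare matrices).
#' @return Named positive numeric, one normalization factor per sample.
#' @export
normalizationFactor <- function(x, rgGenes, ampFactor = 2, collapseTech = TRUE) {
  if (is(x, "CtExperiment") && collapseTech) x <- collapseTechReps(x)
  ct <- .ctMatrix(x)
  missing <- setdiff(rgGenes, rownames(ct))
  if (length(missing)) {
    .err("unknown_gene", paste0("reference gene(s) not in matrix: ",
                                paste(missing, collapse = ", ")))
  }
  sub <- ct[rgGenes, , drop = FALSE]
  if (anyNA(sub)) .err("missing_ct", "reference genes must have complete Ct values")
  q <- ctToQuantity(sub, if (length(ampFactor) > 1) ampFactor[rgGenes] else ampFactor)
  nf <- exp(colMeans(log(q)))
  names(nf) <- colnames(ct)
  nf
}

#' Relative quantification by the 2^-ddCt method
#'
#' Normalized quantity per sample: \code{u(s) = A^(-ct(s)) / NF(s)} (up to a
#' per-gene constant); fold change: \code{u(s)} divided by the geometric
#' mean of \code{u} over the calibrator samples, so calibrator fold changes
#' have geometric mean exactly 1. With \code{A = 2} and a single reference
#' gene this is the textbook
#' \code{2^-[(Ct_t - Ct_r)_sample - (Ct_t - Ct_r)_calibrator]}.
#' Per-stage summaries are arithmetic means across biological replicates,
#' matching common reporting.
#'
#' @param targetCt Named numeric, the target gene's Ct per sample (no
#'   missing values).
#' @param nf Named positive numeric from [normalizationFactor()], same
#'   samples.
#' @param calibrator Sample names (or logical/integer index) forming the
#'   calibrator set, e.g. the immature-stage samples.
#' @param ampFactor Amplification factor for the target (default 2).
#' @param stage Optional per-sample stage labels for the per-stage summary.
#' @return A [QuantificationResult-class].
#' @examples
#' ctTarget <- c(s1 = 25, s2 = 20)   # 5 cycles earlier = 32-fold more
#' nf <- c(s1 = 1, s2 = 1)
#' foldChanges(relativeQuantification(ctTarget, nf, "s1"))
#' @export
relativeQuantification <- function(targetCt, nf, calibrator, ampFactor = 2,
                                   stage = NULL) {
  if (length(targetCt) != length(nf)) {
    .err("length_mismatch", "target Ct and NF cover different samples")
  }
  if (anyNA(targetCt)) .err("missing_ct", "target Ct values must be complete")
  if (is.null(names(targetCt))) names(targetCt) <- names(nf)
  if (is.character(calibrator)) {
    bad <- setdiff(calibrator, names(targetCt))
    if (length(bad)) .err("unknown_sample", paste0("unknown calibrator sample: ",
                                                   paste(bad, collapse = ", ")))
    calIdx <- which(names(targetCt) %in% calibrator)
  } else if (is.logical(calibrator)) {
    calIdx <- which(calibrator)
  } else {
    calIdx <- as.integer(calibrator)
  }
  if (length(calIdx) == 0L) .err("empty_calibrator", "calibrator set is empty")
  u <- ampFactor^(-targetCt) / nf
  f <- u / geomMean(u[calIdx])
  stageSummary <- data.frame(stage = character(0), meanFold = numeric(0),
                             sdFold = numeric(0), n = integer(0))
  if (!is.null(stage)) {
    stage <- as.character(stage)
    lv <- unique(stage)
    stageSummary <- data.frame(
      stage = lv,
      meanFold = vapply(lv, function(s) mean(f[stage == s]), numeric(1)),
      sdFold = vapply(lv, function(s) stats::sd(f[stage == s]), numeric(1)),
      n = vapply(lv, function(s) sum(stage == s), integer(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  new("QuantificationResult",
      foldChange = f,
      stageSummary = stageSummary,
      calibrator = names(targetCt)[calIdx],
      params = list(ampFactor = ampFactor))
}

#' @describeIn QuantificationResult-class Per-sample fold changes.
#' @export
setMethod("foldChanges", "QuantificationResult", function(x) x@foldChange)

#' @describeIn QuantificationResult-class Per-stage fold-change summary.
#' @export
setMethod("stageSummary", "QuantificationResult", function(x) x@stageSummary)

setMethod("show", "QuantificationResult", function(object) {
  cat("QuantificationResult:", length(object@foldChange), "samples,",
      length(object@calibrator), "calibrator sample(s)\n")
  if (nrow(object@stageSummary)) {
    s <- object@stageSummary
    cat(paste0("  ", s$stage, ": mean fold ", signif(s$meanFold, 4),
               collapse = "\n"), "\n")
  }
})

#' Correlation of expression with a trait series
#'
#' Pearson correlation between per-stage mean fold changes and a measured
#' trait series (for instance a metabolite concentration across the same
#' stages), making an "expression tracks the trait" claim checkable.
#'
#' @param stageMeans Numeric fold-change series (>= 3 values).
#' @param trait Numeric trait series of equal length.
#' @return Correlation coefficient in [-1, 1].
#' @export
traitCorrelation <- function(stageMeans, trait) {
  if (length(stageMeans) != length(trait)) {
    .err("length_mismatch", "series differ in length")
  }
  if (length(stageMeans) < 3L) .err("too_few_values", "correlation needs >= 3 points")
  if (stats::sd(stageMeans) == 0 || stats::sd(trait) == 0) {
    .err("zero_variance", "a series with zero variance has no defined correlation")
  }
  stats::cor(stageMeans, trait)
}
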