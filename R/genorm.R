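## The geNorm family: relative quantities from Ct, pairwise variation V,
## per-gene stability M, stepwise-exclusion ranking and the V(n, n+1) curve
## that decides how many reference genes a normalization factor needs.

#' Ct to relative quantity
#'
#' Convert Ct values to relative quantities anchored at each gene's minimum
#' Ct: \code{q = A^(ctMin - ct)}, so the highest-expression sample of every
#' gene has quantity 1. \code{A} is the per-cycle amplification factor --
#' 2 by default (perfect doubling, the efficiency-agnostic convention), or a
#' per-gene vector \code{1 + E} from standard curves.
#'
#' @param x A [CtExperiment-class] or numeric Ct matrix with no missing
#'   values (collapse technical replicates or handle missing wells first).
#' @param ampFactor Scalar or per-gene amplification factor, all > 1.
#' @return Numeric matrix of positive quantities; per gene, max = 1.
#' @examples
#' ctToQuantity(matrix(c(20, 21, 23), 1)) # 1 0.5 0.125
#' @export
ctToQuantity <- function(x, ampFactor = 2) {
  ct <- .ctMatrix(x)
  if (anyNA(ct)) {
    .err("missing_ct", paste0(
      "Ct matrix has missing entries; collapse technical replicates, drop ",
      "the affected genes, or impute before computing quantities"))
  }
  if (!all(is.finite(ampFactor)) || any(ampFactor <= 1)) {
    .err("bad_amp_factor", "amplification factor(s) must be finite and > 1")
  }
  if (!length(ampFactor) %in% c(1L, nrow(ct))) {
    .err("bad_amp_factor", "ampFactor must be scalar or one value per gene")
  }
  delta <- apply(ct, 1, min) - ct   # per-gene anchor, recycled down columns
  if (length(ampFactor) == 1L) {
    ampFactor^delta
  } else {
    exp(log(ampFactor) * delta)
  }
}

#' geNorm pairwise variation between two genes
#'
#' The sample standard deviation, over samples, of the log2 expression ratio
#' of two genes. Two ideal reference genes keep an identical ratio in every
#' sample, giving V = 0; V grows as the genes' expression patterns diverge.
#' Symmetric in its arguments.
#'
#' @param qj,qk Positive quantity vectors of equal length >= 2.
#' @return Non-negative scalar.
#' @export
pairwiseVariation <- function(qj, qk) {
  if (length(qj) != length(qk)) .err("length_mismatch", "quantity vectors differ in length")
  if (length(qj) < 2L) .err("too_few_values", "pairwise variation needs >= 2 samples")
  if (any(qj <= 0) || any(qk <= 0)) .err("nonpositive_quantity", "quantities must be > 0")
  stats::sd(log2(qj / qk))
}

## Gene x gene matrix of pairwise variations via the covariance identity
## sd(Lj - Lk)^2 = var(Lj) + var(Lk) - 2 cov(Lj, Lk); L = log2 quantities.
.pairwiseVMatrix <- function(L) {
  C <- stats::cov(t(L))
  v <- diag(C)
  V2 <- outer(v, v, "+") - 2 * C
  V <- sqrt(pmax(V2, 0))
  diag(V) <- 0
  dimnames(V) <- list(rownames(L), rownames(L))
  V
}

.qMatrix <- function(q) {
  q <- as.matrix(q)
  if (any(q <= 0) || anyNA(q)) .err("nonpositive_quantity", "quantities must be > 0")
  if (ncol(q) < 2L) .err("too_few_values", "need >= 2 samples")
  if (is.null(rownames(q))) rownames(q) <- sprintf("gene%03d", seq_len(nrow(q)))
  q
}

#' geNorm expression-stability measure M
#'
#' For each gene, the mean pairwise variation with every other candidate:
#' genes with the lowest M are the most stably expressed. With exactly two
#' genes, both share their mutual pairwise variation.
#'
#' @param q Positive quantity matrix, genes x samples (see
#'   [ctToQuantity()]); >= 2 genes.
#' @return Named numeric vector of M values.
#' @export
geNormM <- function(q) {
  q <- .qMatrix(q)
  n <- nrow(q)
  if (n < 2L) .err("too_few_genes", "geNorm M needs at least 2 genes")
  V <- .pairwiseVMatrix(log2(q))
  if (n == 2L) {
    m <- rep(V[1, 2], 2)
    names(m) <- rownames(q)
    return(m)
  }
  rowSums(V) / (n - 1)
}

#' geNorm stepwise-exclusion ranking
#'
#' Iteratively remove the gene with the highest M (recomputing M on the
#' remaining set) until two genes remain; those two form the most stable
#' pair and share their mutual pairwise variation as M. Ties on the worst M
#' are broken deterministically by excluding the lexicographically last gene
#' id, so smaller ids rank better among exact ties.
#'
#' @param q Positive quantity matrix, genes x samples; >= 3 genes.
#' @param computeV If \code{TRUE} (default), also compute the V(n, n+1)
#'   curve along the resulting best-first ranking.
#' @return A [GeNormResult-class].
#' @examples
#' ct <- rbind(G1 = c(20, 21, 22, 23), G2 = c(25, 26, 27, 28),
#'             G3 = c(20, 20, 20, 20))
#' res <- geNormRank(ctToQuantity(ct))
#' finalPair(res)  # G1, G2 (their ratio is constant)
#' @export
geNormRank <- function(q, computeV = TRUE) {
  q <- .qMatrix(q)
  n <- nrow(q)
  if (n < 3L) .err("too_few_genes", "stepwise exclusion needs at least 3 genes")
  ids <- rownames(q)
  V <- .pairwiseVMatrix(log2(q))
  remaining <- ids
  exclusionOrder <- character(0)
  mRec <- numeric(0)
  while (length(remaining) > 2L) {
    sub <- V[remaining, remaining, drop = FALSE]
    M <- rowSums(sub) / (length(remaining) - 1)
    worstM <- max(M)
    tied <- remaining[M == worstM]
    worst <- tied[order(tied)][length(tied)]
    exclusionOrder <- c(exclusionOrder, worst)
    mRec[worst] <- worstM
    remaining <- setdiff(remaining, worst)
  }
  finalPair <- sort(remaining)
  mutualV <- V[finalPair[1], finalPair[2]]
  mRec[finalPair] <- mutualV
  ranking <- c(finalPair, rev(exclusionOrder))
  vc <- if (computeV) geNormVCurve(q, ranking) else numeric(0)
  new("GeNormResult",
      mValues = mRec[ids],
      ranking = ranking,
      exclusionOrder = exclusionOrder,
      finalPair = finalPair,
      vCurve = vc)
}

#' geNorm V curve: pairwise variation between successive normalization factors
#'
#' For n = 2..N-1, build normalization factors as the per-sample geometric
#' mean of the top-n and top-(n+1) genes' quantities (best-first ranking)
#' and record the sample standard deviation of their log2 ratio. A value of
#' V(n, n+1) below the working threshold (conventionally 0.15) means n genes
#' already normalize as well as n+1.
#'
#' @param q Positive quantity matrix, genes x samples; >= 3 genes.
#' @param ranking Character, genes best-first (defaults to the
#'   [geNormRank()] order).
#' @return Named numeric vector \code{V2/3, V3/4, ...}.
#' @export
geNormVCurve <- function(q, ranking = NULL) {
  q <- .qMatrix(q)
  if (nrow(q) < 3L) .err("too_few_genes", "V curve needs at least 3 genes")
  if (is.null(ranking)) ranking <- geNormRank(q, computeV = FALSE)@ranking
  if (!setequal(ranking, rownames(q)) || anyDuplicated(ranking)) {
    .err("bad_ranking", "ranking must list every gene exactly once")
  }
  L <- log2(q)[ranking, , drop = FALSE]
  N <- nrow(L)
  ## log2 of the geometric-mean NF is the running mean of log2 quantities
  cum <- apply(L, 2, cumsum)
  nfLog <- cum / seq_len(N)
  v <- vapply(2:(N - 1), function(n) stats::sd(nfLog[n, ] - nfLog[n + 1, ]),
              numeric(1))
  names(v) <- paste0("V", 2:(N - 1), "/", 3:N)
  v
}

#' Run the full geNorm analysis on Ct data
#'
#' Convenience wrapper: collapse technical replicates (optional), transform
#' Ct to relative quantities, rank by stepwise exclusion and compute the V
#' curve.
#'
#' @param x A [CtExperiment-class] or complete Ct matrix.
#' @param ampFactor Amplification factor(s), see [ctToQuantity()].
#' @param collapseTech Collapse technical replicates first (default TRUE;
#'   ignored for bare matrices).
#' @return A [GeNormResult-class].
#' @export
geNorm <- function(x, ampFactor = 2, collapseTech = TRUE) {
  if (is(x, "CtExperiment") && collapseTech) x <- collapseTechReps(x)
  geNormRank(ctToQuantity(x, ampFactor))
}

#' Minimal number of reference genes from a V curve
#'
#' The smallest n whose V(n, n+1) falls below the threshold; when no entry
#' does, the largest n evaluated is returned with \code{met = FALSE} and a
#' warning.
#'
#' @param v Named numeric V curve from [geNormVCurve()].
#' @param threshold Working threshold on V (default 0.15).
#' @return List with \code{n} (integer) and \code{met} (logical).
#' @examples
#' minimalRGCount(c(`V2/3` = 0.05, `V3/4` = 0.04)) # n = 2
#' @export
minimalRGCount <- function(v, threshold = 0.15) {
  if (length(v) == 0L) .err("empty_input", "V curve is empty")
  if (threshold <= 0 || threshold >= 1) .err("bad_threshold", "threshold must be in (0, 1)")
  ns <- seq.int(2L, length.out = length(v))
  hit <- which(v < threshold)
  if (length(hit)) {
    list(n = ns[hit[1]], met = TRUE)
  } else {
    warning(sprintf(
      "no V(n, n+1) below %.3g; even %d reference genes may not suffice",
      threshold, ns[length(ns)]), call. = FALSE)
    list(n = ns[length(ns)], met = FALSE)
  }
}

#' @describeIn GeNormResult-class Per-gene M values at exclusion.
#' @export
setMethod("mValues", "GeNormResult", function(x) x@mValues)

#' @describeIn GeNormResult-class The V(n, n+1) curve.
#' @export
setMethod("vCurve", "GeNormResult", function(x) x@vCurve)

#' @describeIn GeNormResult-class The two most stable genes.
#' @export
setMethod("finalPair", "GeNormResult", function(x) x@finalPair)

#' @describeIn GeNormResult-class All genes, best-first.
#' @export
setMethod("rankedGenes", "GeNormResult", function(x) x@ranking)

setMethod("show", "GeNormResult", function(object) {
  cat("GeNormResult:", length(object@mValues), "genes\n")
  cat("  most stable pair:", paste(object@finalPair, collapse = ", "),
      sprintf("(mutual V = %.4g)\n", object@mValues[object@finalPair[1]]))
  if (length(object@vCurve)) {
    cat(sprintf("  %s = %.4g\n", names(object@vCurve)[1], object@vCurve[1]))
  }
})
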