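## The boxplot-derived whisker D statistic, the combined three-method
## stability report, and the consensus/QC selection rule.

#' Whisker D-value of a Ct vector
#'
#' The spread statistic read off a boxplot whose whisker caps sit at the
#' minimum and maximum: \code{max(ct) - min(ct)} over non-missing values.
#' Translation-invariant; never decreases when an observation is added.
#'
#' @param ct Numeric vector with >= 2 non-missing values.
#' @return Non-negative scalar.
#' @examples
#' whiskerD(c(20.1, 20.5, 21.0)) # 0.9
#' @export
whiskerD <- function(ct) {
  v <- ct[!is.na(ct)]
  if (length(v) == 0L) .err("all_missing", "all Ct values are missing")
  if (length(v) < 2L) .err("too_few_values", "whisker D needs >= 2 values")
  max(v) - min(v)
}

#' @rdname whiskerD
#' @param x A [CtExperiment-class] or Ct matrix; per-gene D values are
#'   computed over non-missing entries (pairwise-complete by design, since
#'   only the observed extremes enter).
#' @export
whiskerDValues <- function(x) {
  ct <- .ctMatrix(x)
  apply(ct, 1, whiskerD)
}

#' Five-number summary for boxplot rendering
#'
#' Minimum, lower quartile, median, upper quartile and maximum of a Ct
#' vector. Quartiles use linear interpolation between order statistics
#' (the spreadsheet-style inclusive method, \code{stats::quantile} type 7)
#' by default; the convention is configurable and never affects gene
#' selection, since only the extremes enter the whisker D-value.
#'
#' @param ct Numeric vector, >= 2 non-missing values.
#' @param qtype Quantile algorithm type (see [stats::quantile()]).
#' @return Named numeric of length 5: min, q1, median, q3, max.
#' @export
boxplotSummary <- function(ct, qtype = 7) {
  v <- ct[!is.na(ct)]
  if (length(v) < 2L) .err("too_few_values", "boxplot summary needs >= 2 values")
  out <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), type = qtype, names = FALSE)
  names(out) <- c("min", "q1", "median", "q3", "max")
  out
}

#' Score a Ct experiment with all three stability methods
#'
#' Runs the whisker D-value, geNorm (stepwise-exclusion M and V curve) and
#' NormFinder (grouped by stage) on the same technical-replicate-collapsed
#' Ct matrix, assembles per-gene ranks (ties broken by gene id for
#' determinism), and records per-gene QC evidence: the mean Ct and, when
#' supplied, the primer amplification efficiency. Consensus columns are
#' left \code{NA} until [consensusSelect()] fills them.
#'
#' @param x A [CtExperiment-class] with no missing Ct after technical
#'   collapse.
#' @param ampFactor Amplification factor for the quantity transform
#'   (default 2; a per-gene vector \code{1 + E} is accepted).
#' @param collapseTech Collapse technical replicates first (default TRUE).
#' @param groups NormFinder group labels (default: stage labels).
#' @param efficiency Optional named numeric of per-gene amplification
#'   efficiencies (fractions; 1 = perfect doubling) used only as QC
#'   evidence.
#' @return A [StabilityReport-class].
#' @examples
#' cte <- simulateCtExperiment(nGenes = 10, seed = 3)
#' rep <- evaluateStability(cte)
#' head(scoreTable(rep))
#' @export
evaluateStability <- function(x, ampFactor = 2, collapseTech = TRUE,
                              groups = NULL, efficiency = NULL) {
  if (!is(x, "CtExperiment")) .err("bad_input", "x must be a CtExperiment")
  if (collapseTech) x <- collapseTechReps(x)
  ct <- assay(x, "ct")
  genes <- rownames(ct)

  wd <- whiskerDValues(ct)
  q <- ctToQuantity(ct, ampFactor)
  gn <- geNormRank(q)
  nf <- normFinder(ct, groups = groups %||% as.character(stages(x)),
                   ampFactor = ampFactor, collapseTech = FALSE)

  gnRank <- match(genes, gn@ranking)
  eff <- rep(NA_real_, length(genes))
  if (!is.null(efficiency)) {
    if (is.null(names(efficiency))) .err("bad_input", "efficiency must be named by gene")
    eff <- unname(efficiency[genes])
  }
  tb <- data.frame(
    gene = genes,
    whiskerD = unname(wd),
    geNormM = unname(gn@mValues[genes]),
    normFinderStability = unname(nf@stability[genes]),
    whiskerRank = .strictRank(unname(wd), genes),
    geNormRank = gnRank,
    normFinderRank = .strictRank(unname(nf@stability[genes]), genes),
    meanCt = unname(rowMeans(ct, na.rm = TRUE)),
    efficiency = eff,
    consensusCount = NA_integer_,
    qcPass = NA,
    selected = NA,
    stringsAsFactors = FALSE
  )
  new("StabilityReport", table = tb, geNorm = gn, normFinder = nf,
      params = list(ampFactor = ampFactor, collapseTech = collapseTech,
                    nSamples = ncol(ct)))
}

#' @rdname consensusSelect
#' @param kTop Depth of each method's top list (default 12).
#' @param minMethods Minimum number of method top lists a gene must appear
#'   in (default 2).
#' @param meanCt Optional named numeric of per-gene mean Ct values (QC).
#' @param effic Optional named numeric of per-gene amplification
#'   efficiencies (QC).
#' @param ctMeanMax Mean-Ct QC ceiling (default 28 cycles).
#' @param effMin,effMax Acceptable efficiency window (default 0.9--1.1).
#' @export
setMethod("consensusSelect", "list", function(x, kTop = 12, minMethods = 2,
                                              meanCt = NULL, effic = NULL,
                                              ctMeanMax = 28,
                                              effMin = 0.9, effMax = 1.1) {
  if (!length(x)) .err("empty_input", "no method rankings supplied")
  if (kTop > min(lengths(x))) {
    .err("bad_threshold", "kTop exceeds the number of ranked genes in a method")
  }
  tops <- lapply(x, utils::head, kTop)
  genes <- sort(unique(unlist(tops)))
  count <- vapply(genes, function(g) {
    sum(vapply(tops, function(t) g %in% t, logical(1)))
  }, integer(1))
  candidates <- genes[count >= minMethods]
  qcCt <- !vapply(candidates, function(g) {
    isTRUE(unname(meanCt[g]) > ctMeanMax)
  }, logical(1))
  qcEff <- !vapply(candidates, function(g) {
    e <- unname(effic[g])
    isTRUE(e < effMin) || isTRUE(e > effMax)
  }, logical(1))
  list(selected = candidates[qcCt & qcEff],
       candidates = candidates,
       consensusCount = count,
       qcCt = qcCt,
       qcEff = qcEff)
})

#' @rdname consensusSelect
#' @export
setMethod("consensusSelect", "StabilityReport",
          function(x, kTop = 12, minMethods = 2, ctMeanMax = 28,
                   effMin = 0.9, effMax = 1.1) {
  tb <- x@table
  rankings <- list(
    whisker = tb$gene[order(tb$whiskerRank)],
    geNorm = tb$gene[order(tb$geNormRank)],
    normFinder = tb$gene[order(tb$normFinderRank)]
  )
  meanCt <- stats::setNames(tb$meanCt, tb$gene)
  effic <- stats::setNames(tb$efficiency, tb$gene)
  sel <- consensusSelect(rankings, kTop = kTop, minMethods = minMethods,
                         meanCt = meanCt, effic = effic,
                         ctMeanMax = ctMeanMax, effMin = effMin,
                         effMax = effMax)
  cc <- sel$consensusCount[tb$gene]
  cc[is.na(cc)] <- 0L
  tb$consensusCount <- as.integer(unname(cc))
  qc <- rep(NA, nrow(tb))
  idx <- match(sel$candidates, tb$gene)
  qc[idx] <- unname(sel$qcCt & sel$qcEff)
  tb$qcPass <- qc
  tb$selected <- tb$gene %in% sel$selected
  x@table <- tb
  x@params <- c(x@params[setdiff(names(x@params),
                                 c("kTop", "minMethods", "ctMeanMax",
                                   "effMin", "effMax"))],
                list(kTop = kTop, minMethods = minMethods,
                     ctMeanMax = ctMeanMax, effMin = effMin, effMax = effMax))
  x
})

#' @describeIn StabilityReport-class The per-gene score table.
#' @export
setMethod("scoreTable", "StabilityReport", function(x) x@table)

#' @describeIn StabilityReport-class Genes passing consensus + QC (empty
#'   until [consensusSelect()] has been applied).
#' @export
setMethod("selectedGenes", "StabilityReport", function(x) {
  sel <- x@table$selected
  if (all(is.na(sel))) character(0) else x@table$gene[which(sel)]
})

#' @describeIn StabilityReport-class geNorm M values (per-gene, exclusion
#'   convention).
#' @export
setMethod("mValues", "StabilityReport", function(x) x@geNorm@mValues)

#' @describeIn StabilityReport-class The geNorm V curve.
#' @export
setMethod("vCurve", "StabilityReport", function(x) x@geNorm@vCurve)

setMethod("show", "StabilityReport", function(object) {
  tb <- object@table
  cat("StabilityReport:", nrow(tb), "genes\n")
  cat("  geNorm best pair:", paste(object@geNorm@finalPair, collapse = ", "), "\n")
  best <- tb$gene[which.min(tb$normFinderStability)]
  cat("  NormFinder best: ", best, "\n")
  sel <- selectedGenes(object)
  if (length(sel)) {
    cat("  selected (", length(sel), "): ",
        paste(sel, collapse = ", "), "\n", sep = "")
  } else {
    cat("  consensus selection not yet applied (see consensusSelect())\n")
  }
})
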