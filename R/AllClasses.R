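#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData colData<- assays
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' CtExperiment: qPCR Ct values with sample metadata
#'
#' A \linkS4class{SummarizedExperiment} holding one assay \code{"ct"}
#' (genes x samples, PCR cycle-threshold values, \code{NA} allowed) whose
#' \code{colData} carries the experimental design: \code{stage} (developmental
#' stage or any user-defined condition label), \code{bioRep} (biological
#' replicate index) and \code{techRep} (technical replicate index). The
#' (stage, bioRep, techRep) triple must be unique per sample and gene ids
#' must be unique.
#'
#' @seealso [CtExperiment()] for construction, [collapseTechReps()],
#'   [readCtTable()]
#' @name CtExperiment-class
#' @aliases CtExperiment-class
#' @exportClass CtExperiment
setClass("CtExperiment", contains = "SummarizedExperiment")

setValidity("CtExperiment", function(object) {
  msgs <- character()
  if (!"ct" %in% assayNames(object)) {
    msgs <- c(msgs, "assay 'ct' is required")
  } else {
    ct <- assay(object, "ct")
    if (!is.numeric(ct)) msgs <- c(msgs, "assay 'ct' must be numeric")
    else if (any(is.infinite(ct))) msgs <- c(msgs, "Ct values must be finite or NA")
  }
  cd <- colData(object)
  need <- c("stage", "bioRep", "techRep")
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) {
    msgs <- c(msgs, paste0("colData must contain: ", paste(miss, collapse = ", ")))
  } else if (ncol(object) > 0) {
    key <- paste(cd$stage, cd$bioRep, cd$techRep, sep = "\r")
    if (anyDuplicated(key)) {
      msgs <- c(msgs, "(stage, bioRep, techRep) triples must be unique across samples")
    }
  }
  rn <- rownames(object)
  if (!is.null(rn) && anyDuplicated(rn)) msgs <- c(msgs, "gene ids must be unique")
  if (length(msgs)) msgs else TRUE
})

#' GeNormResult: geNorm stability ranking
#'
#' Result of the geNorm stepwise-exclusion analysis: the expression-stability
#' measure M recorded for each gene at the step it was excluded (the final
#' pair shares its mutual pairwise variation as M), the best-first ranking,
#' the worst-first exclusion order, the final most-stable pair, and the
#' pairwise-variation curve V(n, n+1) used to choose how many reference genes
#' are needed.
#'
#' @slot mValues Named numeric, per-gene M at exclusion (>= 0).
#' @slot ranking Character, all genes best-first.
#' @slot exclusionOrder Character, excluded genes worst-first.
#' @slot finalPair Character(2), the two most stable genes.
#' @slot vCurve Named numeric, V(n, n+1) for n = 2..N-1.
#'
#' @seealso [geNorm()], [mValues()], [vCurve()], [minimalRGCount()]
#' @name GeNormResult-class
#' @exportClass GeNormResult
setClass("GeNormResult",
  representation(
    mValues = "numeric",
    ranking = "character",
    exclusionOrder = "character",
    finalPair = "character",
    vCurve = "numeric"
  )
)

setValidity("GeNormResult", function(object) {
  msgs <- character()
  all_genes <- sort(c(object@exclusionOrder, object@finalPair))
  if (!identical(all_genes, sort(names(object@mValues)))) {
    msgs <- c(msgs, "exclusionOrder plus finalPair must cover exactly the scored genes")
  }
  if (!setequal(object@ranking, names(object@mValues))) {
    msgs <- c(msgs, "ranking must cover exactly the scored genes")
  }
  if (length(object@finalPair) != 2L) msgs <- c(msgs, "finalPair must name two genes")
  if (any(object@vCurve < 0)) msgs <- c(msgs, "V curve entries must be >= 0")
  if (any(object@mValues < 0)) msgs <- c(msgs, "M values must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' NormFinderResult: model-based stability decomposition
#'
#' Per-gene NormFinder stability values together with the underlying variance
#' decomposition: shrunken inter-group expression differences (one column per
#' group) and the centering-corrected intra-group variances.
#'
#' @slot stability Named numeric >= 0, lower = more stable.
#' @slot groupDifference Matrix (gene x group) of shrunken group deviations.
#' @slot intraGroupVariance Matrix (gene x group) of variances, >= 0.
#' @slot groups Character, group labels (column order of the matrices).
#'
#' @seealso [normFinder()], [stabilityValues()]
#' @name NormFinderResult-class
#' @exportClass NormFinderResult
setClass("NormFinderResult",
  representation(
    stability = "numeric",
    groupDifference = "matrix",
    intraGroupVariance = "matrix",
    groups = "character"
  )
)

setValidity("NormFinderResult", function(object) {
  msgs <- character()
  if (any(object@stability < 0)) msgs <- c(msgs, "stability values must be >= 0")
  if (any(object@intraGroupVariance < 0)) {
    msgs <- c(msgs, "intra-group variances must be >= 0 after flooring")
  }
  if (length(msgs)) msgs else TRUE
})

#' StabilityReport: combined three-method stability scores
#'
#' Per-gene scores and ranks for the three stability methods (whisker
#' D-value, geNorm M, NormFinder stability), per-gene QC evidence (mean Ct,
#' amplification efficiency), and -- once [consensusSelect()] has run --
#' the consensus membership count, QC pass flags and final selection.
#'
#' @slot table data.frame, one row per gene (see [scoreTable()]).
#' @slot geNorm The full [GeNormResult-class].
#' @slot normFinder The full [NormFinderResult-class].
#' @slot params List of analysis parameters used.
#'
#' @seealso [evaluateStability()], [consensusSelect()], [selectedGenes()]
#' @name StabilityReport-class
#' @exportClass StabilityReport
setClass("StabilityReport",
  representation(
    table = "data.frame",
    geNorm = "GeNormResult",
    normFinder = "NormFinderResult",
    params = "list"
  )
)

setValidity("StabilityReport", function(object) {
  msgs <- character()
  tb <- object@table
  need <- c("gene", "whiskerD", "geNormM", "normFinderStability",
            "whiskerRank", "geNormRank", "normFinderRank",
            "meanCt", "efficiency", "consensusCount", "qcPass", "selected")
  miss <- setdiff(need, colnames(tb))
  if (length(miss)) {
    msgs <- c(msgs, paste0("score table lacks columns: ", paste(miss, collapse = ", ")))
  } else {
    n <- nrow(tb)
    for (col in c("whiskerRank", "geNormRank", "normFinderRank")) {
      if (!setequal(tb[[col]], seq_len(n))) {
        msgs <- c(msgs, paste0(col, " must be a permutation of 1..N"))
      }
    }
    if (anyDuplicated(tb$gene)) msgs <- c(msgs, "gene ids must be unique")
  }
  if (length(msgs)) msgs else TRUE
})

#' StandardCurve: dilution-series efficiency fit
#'
#' Ordinary least-squares fit of Ct against log10 relative template amount
#' for a serial-dilution series, with the amplification efficiency derived
#' from the slope as E = 10^(-1/slope) - 1 (E = 1 is perfect doubling).
#'
#' @slot dilutionLog10 Numeric, log10 relative template amounts.
#' @slot ct Numeric, observed Ct values.
#' @slot slope,intercept Numeric(1), regression coefficients.
#' @slot efficiency Numeric(1), fractional per-cycle gain.
#' @slot rSquared Numeric(1) in [0, 1].
#'
#' @seealso [fitStandardCurve()], [efficiency()]
#' @name StandardCurve-class
#' @exportClass StandardCurve
setClass("StandardCurve",
  representation(
    dilutionLog10 = "numeric",
    ct = "numeric",
    slope = "numeric",
    intercept = "numeric",
    efficiency = "numeric",
    rSquared = "numeric"
  )
)

setValidity("StandardCurve", function(object) {
  msgs <- character()
  if (length(object@slope) != 1L || length(object@efficiency) != 1L) {
    msgs <- c(msgs, "slope and efficiency must be scalars")
  } else if (is.finite(object@slope) && is.finite(object@efficiency)) {
    e <- 10^(-1 / object@slope) - 1
    if (abs(e - object@efficiency) > 1e-8) {
      msgs <- c(msgs, "efficiency must equal 10^(-1/slope) - 1")
    }
  }
  if (length(object@rSquared) == 1L && is.finite(object@rSquared) &&
      (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12)) {
    msgs <- c(msgs, "R-squared must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' QuantificationResult: relative expression by 2^-ddCt
#'
#' Per-sample fold changes of a target gene relative to a calibrator
#' stage/sample set, normalized by a (multi-)reference-gene normalization
#' factor, plus per-stage summaries across biological replicates.
#'
#' @slot foldChange Named numeric, per-sample fold change (> 0).
#' @slot stageSummary data.frame with columns stage, meanFold, sdFold, n.
#' @slot calibrator Character, the calibrator sample names.
#' @slot params List (amplification factor, reference genes used, ...).
#'
#' @seealso [relativeQuantification()]
#' @name QuantificationResult-class
#' @exportClass QuantificationResult
setClass("QuantificationResult",
  representation(
    foldChange = "numeric",
    stageSummary = "data.frame",
    calibrator = "character",
    params = "list"
  )
)

setValidity("QuantificationResult", function(object) {
  if (any(object@foldChange <= 0)) "fold changes must be positive" else TRUE
})

#' PipelineRun: one orchestrated screen-to-quantification run
#'
#' Container for a full pipeline execution: the configuration snapshot,
#' the screening table (if an expression matrix was supplied), the
#' [StabilityReport-class], the minimal reference-gene count from the V
#' curve, the quantification result (if a target gene was named) and a
#' plain-text log of every threshold applied.
#'
#' @slot config List, the [rgConfig()] snapshot.
#' @slot screening data.frame or NULL.
#' @slot report [StabilityReport-class].
#' @slot minimalRG List with elements \code{n} and \code{met}.
#' @slot quantification [QuantificationResult-class] or NULL.
#' @slot traitCorrelation Numeric (length 0 if no trait series given).
#' @slot log Character, one entry per pipeline event.
#'
#' @seealso [runPipeline()], [writeReport()]
#' @name PipelineRun-class
#' @exportClass PipelineRun
setClass("PipelineRun",
  representation(
    config = "list",
    screening = "ANY",
    report = "StabilityReport",
    minimalRG = "list",
    quantification = "ANY",
    traitCorrelation = "numeric",
    log = "character"
  )
)
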