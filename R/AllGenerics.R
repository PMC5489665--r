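#' @rdname CtExperiment
#' @export
setGeneric("collapseTechReps", function(x) standardGeneric("collapseTechReps"))

#' @rdname CtExperiment
#' @export
setGeneric("ctValues", function(x) standardGeneric("ctValues"))

#' @rdname CtExperiment
#' @export
setGeneric("stages", function(x) standardGeneric("stages"))

#' @rdname CtExperiment
#' @export
setGeneric("bioReps", function(x) standardGeneric("bioReps"))

#' @rdname CtExperiment
#' @export
setGeneric("techReps", function(x) standardGeneric("techReps"))

#' @rdname GeNormResult-class
#' @param x A result object.
#' @export
setGeneric("mValues", function(x) standardGeneric("mValues"))

#' @rdname GeNormResult-class
#' @export
setGeneric("vCurve", function(x) standardGeneric("vCurve"))

#' @rdname GeNormResult-class
#' @export
setGeneric("finalPair", function(x) standardGeneric("finalPair"))

#' @rdname GeNormResult-class
#' @export
setGeneric("rankedGenes", function(x) standardGeneric("rankedGenes"))

#' @rdname NormFinderResult-class
#' @param x A result object.
#' @export
setGeneric("stabilityValues", function(x) standardGeneric("stabilityValues"))

#' @rdname StabilityReport-class
#' @param x A result object.
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @rdname StabilityReport-class
#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))

#' Consensus selection across stability methods
#'
#' Rank each stability method, take each method's top-k genes, keep genes
#' present in at least \code{minMethods} of the lists, then drop genes
#' failing quality control: mean Ct above \code{ctMeanMax} or amplification
#' efficiency outside \code{[effMin, effMax]}. Genes with no QC evidence
#' (missing mean Ct or efficiency) pass by default: quality control only
#' acts on available evidence.
#'
#' @param x A [StabilityReport-class], or a named list of character vectors
#'   (rankings, best gene first), one per method.
#' @param ... Passed between methods.
#' @return For a list input, a list with elements \code{selected},
#'   \code{candidates} (the consensus set before QC), \code{consensusCount},
#'   \code{qcCt} and \code{qcEff}. For a [StabilityReport-class], the report
#'   with its consensus/QC/selection columns filled in.
#' @seealso [evaluateStability()], [selectedGenes()]
#' @export
setGeneric("consensusSelect", function(x, ...) standardGeneric("consensusSelect"))

#' @rdname StandardCurve-class
#' @param x A result object.
#' @export
setGeneric("efficiency", function(x) standardGeneric("efficiency"))

#' @rdname QuantificationResult-class
#' @param x A result object.
#' @export
setGeneric("foldChanges", function(x) standardGeneric("foldChanges"))

#' @rdname QuantificationResult-class
#' @export
setGeneric("stageSummary", function(x) standardGeneric("stageSummary"))

#' Write report files for an analysis result
#'
#' Emits a delimited-text per-gene score table plus a human-readable text
#' summary and a machine-readable JSON summary (ranked lists, chosen
#' reference-gene set, V curve, thresholds applied).
#'
#' @param x A [StabilityReport-class] or [PipelineRun-class].
#' @param dir Output directory (created if needed).
#' @param ... Unused.
#' @return Invisibly, a named character vector of the files written.
#' @export
setGeneric("writeReport", function(x, dir, ...) standardGeneric("writeReport"))
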