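#' Pipeline configuration
#'
#' Bundle and validate every threshold the pipeline applies. Defaults are
#' the working values for a fruit-development reference-gene study:
#' expression window 200--2000 (RPKM-like units), CV threshold 0.35,
#' top-12 lists intersected across >= 2 methods, mean-Ct ceiling 28 cycles
#' (within the 15--30 usability guideline), efficiency window 0.9--1.1,
#' V threshold 0.15, amplification factor 2.
#'
#' @param exprMin,exprMax Inclusive screening expression window.
#' @param cvMax Screening CV threshold (pass is \code{cv <= cvMax}).
#' @param kTop Per-method top-list depth for consensus.
#' @param minMethods Minimum method lists a consensus gene must appear in.
#' @param ctMeanMax Mean-Ct QC ceiling, cycles.
#' @param effMin,effMax Amplification-efficiency QC window.
#' @param vThreshold V(n, n+1) threshold for the minimal RG count.
#' @param ampFactor Amplification factor for quantity transforms.
#' @param collapseTech Collapse technical replicates before stability
#'   analysis.
#' @param calibratorStage Calibrator stage for quantification
#'   (default: the first stage present).
#' @param seed Optional integer recorded with the run.
#' @return A validated list of class \code{"rgConfig"}.
#' @export
rgConfig <- function(exprMin = 200, exprMax = 2000, cvMax = 0.35,
                     kTop = 12, minMethods = 2,
                     ctMeanMax = 28, effMin = 0.9, effMax = 1.1,
                     vThreshold = 0.15, ampFactor = 2,
                     collapseTech = TRUE, calibratorStage = NULL,
                     seed = NULL) {
  if (!(exprMin < exprMax)) .err("bad_config", "exprMin must be < exprMax")
  if (cvMax <= 0) .err("bad_config", "cvMax must be > 0")
  if (!(effMin < effMax)) .err("bad_config", "effMin must be < effMax")
  if (vThreshold <= 0 || vThreshold >= 1) .err("bad_config", "vThreshold in (0, 1)")
  if (ampFactor <= 1) .err("bad_config", "ampFactor must be > 1")
  structure(list(exprMin = exprMin, exprMax = exprMax, cvMax = cvMax,
                 kTop = kTop, minMethods = minMethods,
                 ctMeanMax = ctMeanMax, effMin = effMin, effMax = effMax,
                 vThreshold = vThreshold, ampFactor = ampFactor,
                 collapseTech = collapseTech,
                 calibratorStage = calibratorStage, seed = seed),
            class = "rgConfig")
}

#' Run the full reference-gene pipeline
#'
#' Orchestrates screen -> stability -> consensus -> minimal-set -> quantify
#' as one reproducible, deterministic run. Screening is skipped (and marked
#' so in the log) when no expression matrix is given. When a target gene is
#' named, the minimal reference-gene count from the V curve decides how
#' many of the top-ranked geNorm genes build the normalization factor.
#'
#' @param ct A [CtExperiment-class] with the candidate genes (and the
#'   target gene, if quantification is wanted).
#' @param expression Optional numeric matrix (genes x conditions) for the
#'   transcriptome screen.
#' @param config An [rgConfig()] list.
#' @param efficiency Optional named numeric of per-gene amplification
#'   efficiencies (QC evidence for consensus selection).
#' @param targetGene Optional target gene id present in \code{ct}; it is
#'   excluded from the stability candidate set.
#' @param trait Optional numeric trait series, one value per stage in stage
#'   order, correlated with the target's per-stage mean fold changes.
#' @return A [PipelineRun-class].
#' @examples
#' cte <- simulateCtExperiment(nGenes = 12, fracStable = 0.5, seed = 11)
#' run <- runPipeline(cte, config = rgConfig(kTop = 5))
#' selectedGenes(run)
#' @export
runPipeline <- function(ct, expression = NULL, config = rgConfig(),
                        efficiency = NULL, targetGene = NULL, trait = NULL) {
  if (!is(ct, "CtExperiment")) .err("bad_input", "ct must be a CtExperiment")
  if (!inherits(config, "rgConfig")) .err("bad_config", "config must come from rgConfig()")
  log <- c(sprintf("config: window [%g, %g], cvMax %g, kTop %d, minMethods %d",
                   config$exprMin, config$exprMax, config$cvMax,
                   config$kTop, config$minMethods),
           sprintf("config: ctMeanMax %g, efficiency window [%g, %g], vThreshold %g, ampFactor %g",
                   config$ctMeanMax, config$effMin, config$effMax,
                   config$vThreshold, config$ampFactor))

  screening <- NULL
  if (!is.null(expression)) {
    screening <- screenCandidates(expression, config$exprMin, config$exprMax,
                                  config$cvMax)
    log <- c(log, sprintf("screening: %d/%d genes selected",
                          attr(screening, "nSelected"), nrow(screening)))
  } else {
    log <- c(log, "screening: skipped (no expression matrix supplied)")
  }

  candCt <- ct
  if (!is.null(targetGene)) {
    if (!targetGene %in% rownames(ct)) {
      .err("unknown_gene", paste0("target gene not in Ct matrix: ", targetGene))
    }
    candCt <- ct[setdiff(rownames(ct), targetGene), ]
  }
  report <- evaluateStability(candCt, ampFactor = config$ampFactor,
                              collapseTech = config$collapseTech,
                              efficiency = efficiency)
  report <- consensusSelect(report, kTop = min(config$kTop, nrow(candCt)),
                            minMethods = config$minMethods,
                            ctMeanMax = config$ctMeanMax,
                            effMin = config$effMin, effMax = config$effMax)
  sel <- selectedGenes(report)
  log <- c(log, sprintf("stability: %d genes scored; %d selected by consensus+QC",
                        nrow(scoreTable(report)), length(sel)))
  minimalRG <- withCallingHandlers(
    minimalRGCount(vCurve(report), config$vThreshold),
    warning = function(w) invokeRestart("muffleWarning"))
  log <- c(log, sprintf("minimal RG count: %d (threshold %s)", minimalRG$n,
                        if (minimalRG$met) "met" else "NOT met"))

  quant <- NULL
  traitCor <- numeric(0)
  if (!is.null(targetGene)) {
    collapsed <- if (config$collapseTech) collapseTechReps(ct) else ct
    rgs <- rankedGenes(report@geNorm)[seq_len(minimalRG$n)]
    nf <- normalizationFactor(collapsed, rgs, ampFactor = config$ampFactor,
                              collapseTech = FALSE)
    targetCt <- assay(collapsed, "ct")[targetGene, ]
    stage <- as.character(stages(collapsed))
    calStage <- config$calibratorStage %||% stage[1]
    quant <- relativeQuantification(targetCt, nf,
                                    calibrator = colnames(collapsed)[stage == calStage],
                                    ampFactor = config$ampFactor,
                                    stage = stage)
    log <- c(log, sprintf("quantification: target %s over RGs {%s}, calibrator %s",
                          targetGene, paste(rgs, collapse = ", "), calStage))
    if (!is.null(trait)) {
      sm <- stageSummary(quant)
      traitCor <- traitCorrelation(sm$meanFold, trait)
      log <- c(log, sprintf("trait correlation: r = %.4f", traitCor))
    }
  }

  new("PipelineRun", config = unclass(config), screening = screening,
      report = report, minimalRG = minimalRG, quantification = quant,
      traitCorrelation = traitCor, log = log)
}

#' @describeIn PipelineRun-class Genes passing consensus + QC.
#' @param x A \code{PipelineRun}.
#' @export
setMethod("selectedGenes", "PipelineRun", function(x) selectedGenes(x@report))

setMethod("show", "PipelineRun", function(object) {
  cat("PipelineRun\n")
  for (l in object@log) cat(" ", l, "\n")
})

.writeScoreTable <- function(tb, path) {
  out <- tb
  for (col in c("whiskerD", "geNormM", "normFinderStability", "meanCt",
                "efficiency")) {
    out[[col]] <- .fmtNum(tb[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  path
}

.reportSummaryList <- function(report, extra = list()) {
  tb <- scoreTable(report)
  c(list(
    nGenes = nrow(tb),
    whiskerRanking = tb$gene[order(tb$whiskerRank)],
    geNormRanking = rankedGenes(report@geNorm),
    normFinderRanking = tb$gene[order(tb$normFinderRank)],
    geNormFinalPair = finalPair(report@geNorm),
    vCurve = as.list(vCurve(report)),
    selected = selectedGenes(report),
    params = report@params
  ), extra)
}

#' @rdname writeReport
#' @export
setMethod("writeReport", "StabilityReport", function(x, dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scorePath <- file.path(dir, "stability_scores.tsv")
  .writeScoreTable(scoreTable(x), scorePath)
  summary <- .reportSummaryList(x)
  jsonPath <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, jsonPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  txtPath <- file.path(dir, "summary.txt")
  lines <- c(
    sprintf("Genes scored: %d", summary$nGenes),
    sprintf("geNorm most stable pair: %s",
            paste(summary$geNormFinalPair, collapse = ", ")),
    sprintf("V curve: %s",
            paste(sprintf("%s = %.4g", names(vCurve(x)), vCurve(x)),
                  collapse = "; ")),
    sprintf("Selected reference genes (%d): %s", length(summary$selected),
            if (length(summary$selected)) paste(summary$selected, collapse = ", ")
            else "(consensus not applied)")
  )
  writeLines(lines, txtPath)
  invisible(c(scores = scorePath, json = jsonPath, text = txtPath))
})

#' @rdname writeReport
#' @export
setMethod("writeReport", "PipelineRun", function(x, dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- writeReport(x@report, dir)
  if (!is.null(x@screening)) {
    scrPath <- file.path(dir, "screening.tsv")
    out <- x@screening
    for (col in c("meanExpression", "cv")) out[[col]] <- .fmtNum(out[[col]])
    utils::write.table(out, scrPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    paths <- c(paths, screening = scrPath)
  }
  extra <- list(minimalRGCount = x@minimalRG$n,
                vThresholdMet = x@minimalRG$met,
                config = x@config, log = x@log)
  if (!is.null(x@quantification)) {
    extra$foldChange <- as.list(foldChanges(x@quantification))
    extra$stageSummary <- stageSummary(x@quantification)
  }
  if (length(x@traitCorrelation)) extra$traitCorrelation <- x@traitCorrelation
  runPath <- file.path(dir, "run.json")
  jsonlite::write_json(.reportSummaryList(x@report, extra), runPath,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  writeLines(x@log, file.path(dir, "run.log"))
  invisible(c(paths, run = runPath, log = file.path(dir, "run.log")))
})
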