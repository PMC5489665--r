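## Synthetic-data generators with recorded ground truth, so every pipeline
## stage is testable without any download. All generators are deterministic
## functions of (parameters, seed). Noise is Gaussian on the Ct (log) scale
## -- the standard qPCR error model -- and log-normal on the expression
## scale for RPKM-like values.

#' Simulate a stage-structured expression matrix with planted stable genes
#'
#' Stable genes get a flat profile with multiplicative log-normal noise
#' calibrated so the expected CV matches \code{cvTarget} (sigma =
#' sqrt(log(1 + cv^2))); unstable genes additionally get a monotone
#' geometric trend across stages whose fold span pushes the CV above the
#' screening threshold. Baselines are drawn log-uniformly inside the
#' expression window for a \code{fracInWindow} share of genes and outside
#' it (low or high) for the rest.
#'
#' @param nGenes Number of genes.
#' @param stages Character, stage labels (columns).
#' @param fracStable Fraction of genes planted as stable (0..1).
#' @param window Expression window emulating the screening target
#'   (default 200--2000).
#' @param fracInWindow Fraction of baselines drawn inside the window.
#' @param cvTarget Expected CV of stable genes (must be > 0 and below the
#'   unstable regime).
#' @param unstableFoldRange Range of total fold span for unstable genes'
#'   trends (default 2.5--6, enough to push CV past 0.35 over 4 stages).
#' @param seed Integer seed; same seed, same matrix.
#' @return List with \code{rpkm} (numeric matrix) and \code{truth} (list:
#'   \code{stableGenes}, per-gene \code{foldSpan}, \code{cvTarget},
#'   \code{seed}).
#' @examples
#' sim <- simulateExpressionMatrix(nGenes = 20, seed = 1)
#' screenCandidates(sim$rpkm)[1:3, ]
#' @export
simulateExpressionMatrix <- function(nGenes = 200,
                                     stages = c("IM", "MG", "B", "MR"),
                                     fracStable = 0.5,
                                     window = c(200, 2000),
                                     fracInWindow = 0.8,
                                     cvTarget = 0.15,
                                     unstableFoldRange = c(2.5, 6),
                                     seed = NULL) {
  if (cvTarget <= 0) .err("bad_threshold", "cvTarget must be > 0")
  if (fracStable < 0 || fracStable > 1) .err("bad_threshold", "fracStable in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  S <- length(stages)
  genes <- sprintf("gene%04d", seq_len(nGenes))
  nStable <- round(fracStable * nGenes)
  stableGenes <- sort(sample(genes, nStable))
  isStable <- genes %in% stableGenes

  inWindow <- stats::runif(nGenes) < fracInWindow
  baseline <- numeric(nGenes)
  baseline[inWindow] <- exp(stats::runif(sum(inWindow),
                                         log(window[1]), log(window[2])))
  lowHigh <- stats::runif(sum(!inWindow)) < 0.5
  out <- numeric(sum(!inWindow))
  out[lowHigh] <- exp(stats::runif(sum(lowHigh), log(window[1] / 20),
                                   log(window[1] * 0.99)))
  out[!lowHigh] <- exp(stats::runif(sum(!lowHigh), log(window[2] * 1.01),
                                    log(window[2] * 20)))
  baseline[!inWindow] <- out

  sigma <- sqrt(log(1 + cvTarget^2))
  foldSpan <- rep(1, nGenes)
  foldSpan[!isStable] <- exp(stats::runif(sum(!isStable),
                                          log(unstableFoldRange[1]),
                                          log(unstableFoldRange[2])))
  trend <- outer(log(foldSpan), seq(0, 1, length.out = S))
  trend <- trend - rowMeans(trend)              # keep the baseline the mean
  noise <- matrix(stats::rnorm(nGenes * S, -sigma^2 / 2, sigma), nGenes, S)
  rpkm <- baseline * exp(trend + noise)
  dimnames(rpkm) <- list(genes, stages)
  list(rpkm = rpkm,
       truth = list(stableGenes = stableGenes,
                    baseline = stats::setNames(baseline, genes),
                    foldSpan = stats::setNames(foldSpan, genes),
                    cvTarget = cvTarget, fracInWindow = fracInWindow,
                    window = window, seed = seed))
}

#' Simulate a Ct experiment with planted stable genes
#'
#' Emulates a qPCR validation panel across developmental stages:
#' \code{Ct(g, stage, b, t) = baseline_g + stageEffect_g(stage) +
#' bioNoise(g, stage, b) + techNoise(g, stage, b, t)}. Planted stable genes
#' have stage effect identically 0; unstable genes get a monotone ramp or a
#' single-stage bump (chosen at random per gene, recorded in the truth)
#' with amplitude drawn from \code{[stageAmplitude, 2 * stageAmplitude]}
#' cycles and random sign.
#'
#' @param nGenes Number of genes.
#' @param stages Stage labels (default the four ripening stages IM, MG, B,
#'   MR).
#' @param nBio,nTech Biological / technical replicates per stage
#'   (default 3 x 3, the standard validation design).
#' @param fracStable Fraction of genes planted stable.
#' @param stageAmplitude Minimum drift amplitude of unstable genes, cycles.
#' @param bioNoiseSd,techNoiseSd Replicate noise standard deviations,
#'   cycles.
#' @param baselineRange Per-gene baseline Ct range (default 20--28).
#' @param seed Integer seed.
#' @return A [CtExperiment-class]; \code{metadata(x)$truth} records the
#'   planted stable set, per-gene amplitudes/shapes, noise parameters and
#'   seed.
#' @examples
#' cte <- simulateCtExperiment(nGenes = 10, seed = 42)
#' S4Vectors::metadata(cte)$truth$stableGenes
#' @export
simulateCtExperiment <- function(nGenes = 35,
                                 stages = c("IM", "MG", "B", "MR"),
                                 nBio = 3, nTech = 3,
                                 fracStable = 0.3,
                                 stageAmplitude = 1.5,
                                 bioNoiseSd = 0.15,
                                 techNoiseSd = 0.1,
                                 baselineRange = c(20, 28),
                                 seed = NULL) {
  if (nBio < 1 || nTech < 1 || !length(stages)) {
    .err("bad_design", "design needs >= 1 stage, bio rep and tech rep")
  }
  if (bioNoiseSd < 0 || techNoiseSd < 0) .err("bad_threshold", "noise sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  S <- length(stages)
  genes <- sprintf("gene%04d", seq_len(nGenes))
  nStable <- round(fracStable * nGenes)
  stableGenes <- sort(sample(genes, nStable))
  isStable <- genes %in% stableGenes

  baseline <- stats::runif(nGenes, baselineRange[1], baselineRange[2])
  ## drift amplitudes spread over [1x, 3x] the minimum: planted truth must be
  ## identifiable, so genes sharing a drift pattern must differ enough in
  ## magnitude that no co-drifting class mimics a stable set under
  ## ratio-based statistics
  amplitude <- numeric(nGenes)
  amplitude[!isStable] <- stats::runif(sum(!isStable), stageAmplitude,
                                       3 * stageAmplitude) *
    sample(c(-1, 1), sum(!isStable), replace = TRUE)
  ## each unstable gene draws its drift pattern uniformly from the whole
  ## pattern set -- a monotone ramp (either direction) or a signed bump at
  ## any single stage -- so drift can set in anywhere in development and no
  ## single co-drifting class grows much beyond its share. Ramps get
  ## idiosyncratic per-gene stage increments for the same reason: real
  ## trajectories share a direction, not one kinetic, and a large block of
  ## collinear genes would look spuriously co-regulated to ratio-based
  ## stability measures.
  nPattern <- 2 * S          # S signed bumps per direction pair + 2 ramps
  shape <- rep("flat", nGenes)
  shape[!isStable] <- ifelse(sample(nPattern, sum(!isStable), replace = TRUE) <= 2,
                             "ramp", "bump")

  effect <- matrix(0, nGenes, S, dimnames = list(genes, stages))
  for (g in which(!isStable)) {
    if (shape[g] == "ramp") {
      gaps <- stats::rexp(S - 1)
      effect[g, ] <- amplitude[g] * c(0, cumsum(gaps) / sum(gaps))
    } else {
      effect[g, sample(S, 1)] <- amplitude[g]
    }
  }

  design <- expand.grid(techRep = seq_len(nTech), bioRep = seq_len(nBio),
                        stage = stages, stringsAsFactors = FALSE)
  design <- design[, c("stage", "bioRep", "techRep")]
  nS <- nrow(design)
  bioKey <- paste(design$stage, design$bioRep)
  uBio <- unique(bioKey)
  bioNoise <- matrix(stats::rnorm(nGenes * length(uBio), 0, bioNoiseSd),
                     nGenes, length(uBio))
  ct <- baseline +
    effect[, match(design$stage, stages), drop = FALSE] +
    bioNoise[, match(bioKey, uBio), drop = FALSE] +
    matrix(stats::rnorm(nGenes * nS, 0, techNoiseSd), nGenes, nS)
  dimnames(ct) <- list(genes,
                       paste(design$stage, design$bioRep, design$techRep,
                             sep = "_"))
  cte <- CtExperiment(ct, stage = design$stage, bioRep = design$bioRep,
                      techRep = design$techRep)
  metadata(cte)$truth <- list(
    stableGenes = stableGenes,
    amplitude = stats::setNames(amplitude, genes),
    shape = stats::setNames(shape, genes),
    baseline = stats::setNames(baseline, genes),
    stageEffect = effect,
    bioNoiseSd = bioNoiseSd, techNoiseSd = techNoiseSd, seed = seed
  )
  cte
}

#' Simulate a target-gene profile over flat reference genes
#'
#' Builds a small Ct experiment containing one target gene whose Ct encodes
#' a requested log2 fold-change profile across stages, plus flat reference
#' genes. Running [normalizationFactor()] and [relativeQuantification()] on
#' the result recovers the planted profile (exactly at zero noise).
#'
#' @param profileLog2 Named numeric, log2 fold change per stage relative to
#'   the first (calibrator) stage; e.g. \code{c(IM = 0, MG = 5, B = 4,
#'   MR = 2)}.
#' @param nBio Biological replicates per stage.
#' @param noiseSd Gaussian Ct noise, cycles.
#' @param targetBaseline Target-gene Ct at the calibrator stage.
#' @param rgBaselines Numeric, one baseline Ct per reference gene.
#' @param seed Integer seed.
#' @return A [CtExperiment-class] with genes \code{TARGET, RG1, RG2, ...};
#'   \code{metadata(x)$truth} records the planted profile.
#' @examples
#' cte <- simulateTargetProfile()
#' rownames(cte)
#' @export
simulateTargetProfile <- function(profileLog2 = c(IM = 0, MG = 5, B = 4, MR = 2),
                                  nBio = 3, noiseSd = 0,
                                  targetBaseline = 26,
                                  rgBaselines = c(21, 22.5),
                                  seed = NULL) {
  if (is.null(names(profileLog2))) .err("bad_input", "profileLog2 must be named by stage")
  if (!is.null(seed)) set.seed(seed)
  stages <- names(profileLog2)
  design <- expand.grid(bioRep = seq_len(nBio), stage = stages,
                        stringsAsFactors = FALSE)[, c("stage", "bioRep")]
  nS <- nrow(design)
  nRG <- length(rgBaselines)
  genes <- c("TARGET", paste0("RG", seq_len(nRG)))
  ## higher expression = lower Ct, so subtract the profile
  ct <- rbind(
    targetBaseline - profileLog2[design$stage],
    matrix(rep(rgBaselines, each = nS), nrow = nRG, byrow = TRUE)
  )
  ct <- ct + matrix(stats::rnorm(length(genes) * nS, 0, noiseSd),
                    nrow = length(genes))
  dimnames(ct) <- list(genes, paste(design$stage, design$bioRep, sep = "_"))
  cte <- CtExperiment(ct, stage = design$stage, bioRep = design$bioRep,
                      techRep = rep(1L, nS))
  metadata(cte)$truth <- list(profileLog2 = profileLog2, noiseSd = noiseSd,
                              seed = seed)
  cte
}

#' Simulate a serial-dilution series
#'
#' \code{Ct = intercept - dilutionLog10 / log10(1 + E) + noise}, the line a
#' primer pair with true efficiency E produces over a fold-step dilution
#' series, so fitting with [fitStandardCurve()] inverts the generator.
#'
#' @param trueEfficiency True fractional efficiency E > 0 (1 = doubling).
#' @param nPoints Number of dilution points (>= 3).
#' @param foldStep Dilution factor between successive points (default 10).
#' @param noiseSd Gaussian Ct noise, cycles.
#' @param intercept Ct at the undiluted point.
#' @param seed Integer seed.
#' @return List with \code{dilutionLog10}, \code{ct} and
#'   \code{trueEfficiency}.
#' @examples
#' ds <- simulateDilutionSeries(trueEfficiency = 0.9)
#' efficiency(fitStandardCurve(ds$dilutionLog10, ds$ct)) # 0.9
#' @export
simulateDilutionSeries <- function(trueEfficiency = 1, nPoints = 5,
                                   foldStep = 10, noiseSd = 0,
                                   intercept = 30, seed = NULL) {
  if (trueEfficiency <= 0) .err("bad_threshold", "true efficiency must be > 0")
  if (nPoints < 3L) .err("too_few_values", "dilution series needs >= 3 points")
  if (!is.null(seed)) set.seed(seed)
  dilutionLog10 <- -(seq_len(nPoints) - 1) * log10(foldStep)
  ct <- intercept - dilutionLog10 / log10(1 + trueEfficiency) +
    stats::rnorm(nPoints, 0, noiseSd)
  list(dilutionLog10 = dilutionLog10, ct = ct, trueEfficiency = trueEfficiency)
}
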