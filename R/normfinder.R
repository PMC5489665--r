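#' NormFinder model-based stability values
#'
#' Variance-decomposition estimate of expression stability across sample
#' groups (here typically developmental stages). Working on log-scale
#' expression \code{y = -ct * log2(A)} (per-gene constants cancel), the
#' procedure:
#' \enumerate{
#'   \item centers each sample across genes, removing sample-specific
#'     offsets such as template-load differences;
#'   \item computes, per gene and group, the group-mean deviation
#'     \code{d_ig} from the gene's overall mean and the intra-group sample
#'     variance;
#'   \item corrects the intra-group variance for the covariance introduced
#'     by sample centering -- with k genes the unbiased estimate is
#'     \code{k/(k-2) * (v_ig - mean_i(v_ig)/(k-1))} -- and floors it at 0;
#'   \item estimates the inter-group variance of \code{d_ig} by the method
#'     of moments and shrinks each \code{d_ig} toward 0 by its sampling
#'     variance relative to that estimate;
#'   \item reports \code{stability_i = mean_g(|d~_ig| +
#'     sqrt(var_ig / n_g))} -- small when a gene neither shifts between
#'     groups nor scatters within them.
#' }
#' With a single group the stability value reduces to the corrected
#' intra-group standard deviation.
#'
#' @param x A [CtExperiment-class] (technical replicates collapsed first by
#'   default) or a complete numeric Ct matrix.
#' @param groups Per-sample group labels; defaults to the stage labels when
#'   \code{x} is a \code{CtExperiment}. Every group needs >= 2 samples.
#' @param ampFactor Amplification factor used for the log scale (default 2).
#' @param collapseTech Collapse technical replicates first (default TRUE;
#'   ignored for bare matrices).
#' @return A [NormFinderResult-class]; lower stability = more stable.
#' @examples
#' cte <- simulateCtExperiment(nGenes = 8, seed = 7)
#' res <- normFinder(cte)
#' head(sort(stabilityValues(res)))
#' @export
normFinder <- function(x, groups = NULL, ampFactor = 2, collapseTech = TRUE) {
  if (is(x, "CtExperiment")) {
    if (collapseTech) x <- collapseTechReps(x)
    if (is.null(groups)) groups <- as.character(stages(x))
    ct <- assay(x, "ct")
  } else {
    ct <- .ctMatrix(x)
    if (is.null(groups)) .err("missing_groups", "groups are required for a bare Ct matrix")
  }
  if (anyNA(ct)) .err("missing_ct", "NormFinder requires a complete Ct matrix")
  k <- nrow(ct)
  if (k < 3L) .err("too_few_genes", "NormFinder needs at least 3 genes")
  groups <- as.character(groups)
  if (length(groups) != ncol(ct)) {
    .err("dim_mismatch", "one group label per sample is required")
  }
  sizes <- table(groups)
  if (any(sizes < 2L)) .err("small_group", "every group needs at least 2 samples")
  if (is.null(rownames(ct))) rownames(ct) <- sprintf("gene%03d", seq_len(k))

  y <- -ct * log2(ampFactor)
  z <- sweep(y, 2, colMeans(y))            # sample centering
  gl <- sort(unique(groups))
  G <- length(gl)
  ng <- as.numeric(sizes[gl])

  zbar <- vapply(gl, function(g) rowMeans(z[, groups == g, drop = FALSE]),
                 numeric(k))
  v <- vapply(gl, function(g) apply(z[, groups == g, drop = FALSE], 1, stats::var),
              numeric(k))
  zbar <- matrix(zbar, nrow = k, dimnames = list(rownames(ct), gl))
  v <- matrix(v, nrow = k, dimnames = list(rownames(ct), gl))

  ## centering-covariance correction, floored at 0
  sigma2 <- sweep(v, 2, colMeans(v) / (k - 1)) * k / (k - 2)
  sigma2 <- pmax(sigma2, 0)

  if (G == 1L) {
    stab <- sqrt(sigma2[, 1])
    names(stab) <- rownames(ct)
    dShrunk <- matrix(0, k, 1, dimnames = list(rownames(ct), gl))
    return(new("NormFinderResult", stability = stab, groupDifference = dShrunk,
               intraGroupVariance = sigma2, groups = gl))
  }

  overall <- as.vector(zbar %*% ng) / sum(ng)   # sample-weighted gene mean
  d <- zbar - overall
  sampVar <- sweep(sigma2, 2, ng, "/")          # Var(d_ig) from within-group noise
  gamma2 <- pmax(rowSums(d^2) / (G - 1) - rowMeans(sampVar), 0)
  denom <- gamma2 + sampVar                     # gamma2 recycled down columns
  shrink <- ifelse(denom > 0, gamma2 / denom, 0)
  dShrunk <- d * shrink
  stab <- rowMeans(abs(dShrunk) + sqrt(sampVar))
  names(stab) <- rownames(ct)
  new("NormFinderResult", stability = stab, groupDifference = dShrunk,
      intraGroupVariance = sigma2, groups = gl)
}

#' @describeIn NormFinderResult-class Named per-gene stability values.
#' @export
setMethod("stabilityValues", "NormFinderResult", function(x) x@stability)

setMethod("show", "NormFinderResult", function(object) {
  cat("NormFinderResult:", length(object@stability), "genes,",
      length(object@groups), "group(s)\n")
  best <- names(sort(object@stability))[1]
  cat(sprintf("  most stable: %s (stability = %.4g)\n",
              best, min(object@stability)))
})
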