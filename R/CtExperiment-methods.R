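#' Construct a CtExperiment
#'
#' Bundle a gene x sample grid of qPCR Ct values with its experimental
#' design. Ct values outside the plausible 5--45 cycle range trigger a
#' warning (not an error): such values occur with failed wells but are
#' physically representable.
#'
#' @param ct Numeric matrix, genes x samples; rownames are gene ids
#'   (generated as \code{gene001...} when absent), \code{NA} marks missing
#'   reactions.
#' @param stage Character/factor, per-sample stage (condition) label.
#' @param bioRep Integer, per-sample biological replicate index.
#' @param techRep Integer, per-sample technical replicate index
#'   (default all 1).
#' @param x A \code{CtExperiment}.
#' @return A [CtExperiment-class].
#' @examples
#' ct <- matrix(c(20, 21, 20.5, 25, 25.2, 24.8), nrow = 2, byrow = TRUE,
#'              dimnames = list(c("g1", "g2"), NULL))
#' cte <- CtExperiment(ct, stage = c("IM", "IM", "MG"),
#'                     bioRep = c(1, 2, 1), techRep = c(1, 1, 1))
#' stages(cte)
#' @export
CtExperiment <- function(ct, stage, bioRep, techRep = rep(1L, ncol(ct))) {
  ct <- as.matrix(ct)
  if (!is.numeric(ct)) .err("non_numeric", "Ct values must be numeric")
  if (is.null(rownames(ct))) {
    rownames(ct) <- sprintf("gene%03d", seq_len(nrow(ct)))
  }
  stage <- as.character(stage)
  bioRep <- as.integer(bioRep)
  techRep <- as.integer(techRep)
  if (length(stage) != ncol(ct) || length(bioRep) != ncol(ct) ||
      length(techRep) != ncol(ct)) {
    .err("dim_mismatch", "stage/bioRep/techRep must have one entry per sample")
  }
  if (is.null(colnames(ct))) {
    colnames(ct) <- paste(stage, bioRep, techRep, sep = "_")
  }
  out <- range(ct[is.finite(ct)])
  if (length(out) == 2L && (out[1] < 5 || out[2] > 45)) {
    warning("Ct values outside the typical 5-45 cycle range", call. = FALSE)
  }
  new("CtExperiment",
      SummarizedExperiment(
        assays = list(ct = ct),
        colData = DataFrame(stage = stage, bioRep = bioRep, techRep = techRep,
                            row.names = colnames(ct))))
}

#' @rdname CtExperiment
#' @export
setMethod("ctValues", "CtExperiment", function(x) assay(x, "ct"))

#' @rdname CtExperiment
#' @export
setMethod("stages", "CtExperiment", function(x) colData(x)$stage)

#' @rdname CtExperiment
#' @export
setMethod("bioReps", "CtExperiment", function(x) colData(x)$bioRep)

#' @rdname CtExperiment
#' @export
setMethod("techReps", "CtExperiment", function(x) colData(x)$techRep)

#' @describeIn CtExperiment Average technical replicates: one sample per
#'   (stage, biological replicate), Ct the arithmetic mean of non-missing
#'   technical replicates; a triple with only missing reactions stays
#'   missing. Idempotent.
#' @export
setMethod("collapseTechReps", "CtExperiment", function(x) {
  cd <- colData(x)
  key <- paste(cd$stage, cd$bioRep, sep = "\r")
  ukey <- unique(key)
  ct <- assay(x, "ct")
  collapsed <- matrix(NA_real_, nrow = nrow(ct), ncol = length(ukey),
                      dimnames = list(rownames(ct), NULL))
  for (i in seq_along(ukey)) {
    m <- rowMeans(ct[, key == ukey[i], drop = FALSE], na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    collapsed[, i] <- m
  }
  idx <- match(ukey, key)
  colnames(collapsed) <- paste(cd$stage[idx], cd$bioRep[idx], sep = "_")
  suppressWarnings(
    CtExperiment(collapsed, stage = cd$stage[idx], bioRep = cd$bioRep[idx],
                 techRep = rep(1L, length(idx)))
  )
})

setMethod("show", "CtExperiment", function(object) {
  cd <- colData(object)
  cat("CtExperiment:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  stages:  ", paste(unique(cd$stage), collapse = ", "), "\n")
  cat("  design:  ", length(unique(cd$stage)), "stage(s) x",
      length(unique(cd$bioRep)), "biological rep(s) x",
      length(unique(cd$techRep)), "technical rep(s)\n")
  nmiss <- sum(is.na(assay(object, "ct")))
  cat("  missing Ct entries:", nmiss, "\n")
})
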