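## Delimited-text I/O for the pipeline's tables. TSV is the default dialect;
## ".csv" paths switch to comma. UTF-8, "." decimal separator throughout.

.sepForPath <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

## Full-precision numeric formatting so read/write round trips are
## value-exact; missing values become "NA".
.fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.parseNum <- function(x, what, path) {
  x <- trimws(x)
  x[x == "" | x == "NA"] <- NA
  num <- suppressWarnings(as.numeric(x))
  bad <- is.na(num) & !is.na(x)
  if (any(bad)) {
    .err("non_numeric", sprintf("non-numeric %s value '%s' in %s",
                                what, x[bad][1], path))
  }
  num
}

.checkFile <- function(path) {
  if (!file.exists(path)) {
    .err("missing_file", paste0("file not found: ", path))
  }
}

#' Read and write gene x condition expression tables
#'
#' Expression tables are delimited text with a header row naming the
#' conditions (stages/tissues) and the first column naming the genes;
#' values are non-negative expression measures (RPKM-like units).
#'
#' @param path File path; a \code{.csv} extension selects comma separation,
#'   anything else tab. Override with \code{sep}.
#' @param sep Field separator, \code{NULL} for extension-based choice.
#' @return \code{readExpressionTable} returns a numeric matrix with gene
#'   rownames and condition colnames; \code{writeExpressionTable} returns
#'   \code{path} invisibly.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(1:6 * 100, nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("IM", "MG", "B")))
#' writeExpressionTable(m, tf)
#' all.equal(readExpressionTable(tf), m)
#' @export
readExpressionTable <- function(path, sep = NULL) {
  .checkFile(path)
  sep <- .sepForPath(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) .err("bad_table", "expression table needs gene column plus >= 1 condition")
  genes <- df[[1]]
  if (anyDuplicated(genes)) {
    .err("duplicate_gene", sprintf("duplicate gene id '%s' in %s",
                                   genes[duplicated(genes)][1], path))
  }
  vals <- vapply(df[-1], .parseNum, numeric(nrow(df)), what = "expression", path = path)
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(genes, colnames(df)[-1]))
  if (anyNA(vals) || any(!is.finite(vals))) {
    .err("non_finite", "expression values must be finite and non-missing")
  }
  if (any(vals < 0)) .err("negative_value", "expression values must be >= 0")
  vals
}

#' @rdname readExpressionTable
#' @param m Numeric matrix, genes x conditions, with dimnames.
#' @export
writeExpressionTable <- function(m, path, sep = NULL) {
  sep <- .sepForPath(path, sep)
  out <- data.frame(gene = rownames(m), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) out[[colnames(m)[j]]] <- .fmtNum(m[, j])
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write long-format Ct tables
#'
#' The canonical Ct interchange format is long delimited text with columns
#' \code{gene, sample, stage, bio_rep, tech_rep, ct} (one row per
#' gene/sample pair; an empty or \code{NA} ct field marks a missing
#' reaction -- never 0, which is a legal cycle number). A wide gene x
#' sample dialect is also read: header row of sample ids, then metadata
#' rows whose gene field is \code{#stage}, \code{#bio_rep} and
#' \code{#tech_rep}, then one row per gene.
#'
#' @param path File path (\code{.csv} selects comma separation).
#' @param sep Field separator, \code{NULL} for extension-based choice.
#' @return \code{readCtTable}/\code{readCtTableWide} return a
#'   [CtExperiment-class]; the writers return their paths invisibly.
#' @examples
#' cte <- simulateCtExperiment(nGenes = 3, seed = 1)
#' tf <- tempfile(fileext = ".tsv")
#' writeCtTable(cte, tf)
#' cte2 <- readCtTable(tf)
#' all.equal(ctValues(cte2), ctValues(cte))
#' @export
readCtTable <- function(path, sep = NULL) {
  .checkFile(path)
  sep <- .sepForPath(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", stringsAsFactors = FALSE)
  need <- c("gene", "sample", "stage", "bio_rep", "tech_rep", "ct")
  extra <- setdiff(colnames(df), need)
  if (length(extra)) {
    .err("unknown_column", paste0("unknown column(s): ", paste(extra, collapse = ", ")))
  }
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    .err("unknown_column", paste0("missing required column(s): ",
                                  paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(df[c("gene", "sample")])) {
    dup <- df[duplicated(df[c("gene", "sample")]), ]
    .err("duplicate_entry", sprintf("duplicated (gene, sample) pair: (%s, %s)",
                                    dup$gene[1], dup$sample[1]))
  }
  genes <- unique(df$gene)
  samples <- unique(df$sample)
  meta <- df[!duplicated(df$sample), c("sample", "stage", "bio_rep", "tech_rep")]
  chk <- unique(df[c("sample", "stage", "bio_rep", "tech_rep")])
  if (anyDuplicated(chk$sample)) {
    .err("inconsistent_metadata",
         "a sample id carries conflicting stage/replicate metadata")
  }
  ct <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
               dimnames = list(genes, samples))
  ct[cbind(match(df$gene, genes), match(df$sample, samples))] <-
    .parseNum(df$ct, "ct", path)
  CtExperiment(ct,
               stage = meta$stage[match(samples, meta$sample)],
               bioRep = as.integer(meta$bio_rep[match(samples, meta$sample)]),
               techRep = as.integer(meta$tech_rep[match(samples, meta$sample)]))
}

#' @rdname readCtTable
#' @param x A [CtExperiment-class].
#' @export
writeCtTable <- function(x, path, sep = NULL) {
  sep <- .sepForPath(path, sep)
  ct <- assay(x, "ct")
  cd <- colData(x)
  long <- data.frame(
    gene = rep(rownames(ct), times = ncol(ct)),
    sample = rep(colnames(ct), each = nrow(ct)),
    stage = rep(cd$stage, each = nrow(ct)),
    bio_rep = rep(cd$bioRep, each = nrow(ct)),
    tech_rep = rep(cd$techRep, each = nrow(ct)),
    ct = .fmtNum(as.vector(ct)),
    stringsAsFactors = FALSE
  )
  utils::write.table(long, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname readCtTable
#' @export
readCtTableWide <- function(path, sep = NULL) {
  .checkFile(path)
  sep <- .sepForPath(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", stringsAsFactors = FALSE)
  metaRows <- c("#stage", "#bio_rep", "#tech_rep")
  if (!all(metaRows %in% df[[1]])) {
    .err("unknown_column",
         "wide Ct table needs '#stage', '#bio_rep' and '#tech_rep' metadata rows")
  }
  meta <- df[match(metaRows, df[[1]]), -1, drop = FALSE]
  body <- df[!df[[1]] %in% metaRows, , drop = FALSE]
  genes <- body[[1]]
  if (anyDuplicated(genes)) {
    .err("duplicate_gene", sprintf("duplicate gene id '%s'",
                                   genes[duplicated(genes)][1]))
  }
  ct <- vapply(body[-1], .parseNum, numeric(nrow(body)), what = "ct", path = path)
  ct <- matrix(ct, nrow = nrow(body), dimnames = list(genes, colnames(df)[-1]))
  CtExperiment(ct,
               stage = as.character(meta[1, ]),
               bioRep = as.integer(meta[2, ]),
               techRep = as.integer(meta[3, ]))
}

#' @rdname readCtTable
#' @export
writeCtTableWide <- function(x, path, sep = NULL) {
  sep <- .sepForPath(path, sep)
  ct <- assay(x, "ct")
  cd <- colData(x)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(ct)), collapse = sep), con)
  writeLines(paste(c("#stage", cd$stage), collapse = sep), con)
  writeLines(paste(c("#bio_rep", cd$bioRep), collapse = sep), con)
  writeLines(paste(c("#tech_rep", cd$techRep), collapse = sep), con)
  for (i in seq_len(nrow(ct))) {
    writeLines(paste(c(rownames(ct)[i], .fmtNum(ct[i, ])), collapse = sep), con)
  }
  invisible(path)
}
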