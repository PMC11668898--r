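## Single-sample gene-set enrichment (ssGSEA): per-sample score from the gap
## between the rank-weighted ECDF of in-set genes and the uniform ECDF of
## out-of-set genes, walked down the sample's expression ranking.

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate genes within a line are collapsed.
#'
#' @param path File path.
#' @return Named list of character vectors (set name -> genes).
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields")
    out[[f[[1L]]]] <- unique(f[-(1:2)])
  }
  out
}

#' @rdname readGmt
#' @param geneSets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @export
writeGmt <- function(geneSets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(geneSets))
  lines <- vapply(seq_along(geneSets), function(i)
    paste(c(names(geneSets)[i], descriptions[i], geneSets[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Per-sample ssGSEA enrichment scores
#'
#' For each sample, genes are ranked by expression (average ranks on ties)
#' and walked in decreasing order; the score is the sum over positions of the
#' difference between the rank-weighted cumulative fraction of in-set genes
#' (weights \code{rank^alpha}) and the uniform cumulative fraction of
#' out-of-set genes. Scores depend only on within-sample ranks. When
#' \code{normalize} is on (the default), all scores are divided by the range
#' (max minus min) of the raw scores across the scored samples, so scores are
#' only comparable within one scored cohort.
#'
#' @param expr Numeric matrix, genes x samples, with rownames.
#' @param geneSet Character vector of set genes; members absent from the
#'   matrix are dropped with a warning.
#' @param alpha Rank weighting exponent (default 0.25).
#' @param normalize Divide by the across-sample score range (default TRUE).
#' @return data.frame with columns sample, score.
#' @export
ssgseaScores <- function(expr, geneSet, alpha = 0.25, normalize = TRUE) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), alpha >= 0)
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids in matrix")
  geneSet <- unique(geneSet)
  present <- intersect(geneSet, rownames(expr))
  if (!length(present))
    stop("no gene-set gene present in the expression matrix")
  if (length(present) < length(geneSet))
    warning(length(geneSet) - length(present),
            " gene-set gene(s) absent from the matrix; dropped")
  if (length(present) == nrow(expr))
    stop("gene set covers the whole matrix; no out-of-set genes to compare")

  inSet <- rownames(expr) %in% present
  raw <- vapply(seq_len(ncol(expr)), function(j) {
    r <- rank(expr[, j], ties.method = "average")
    ord <- order(-r, rownames(expr))        # decreasing; ties by gene id
    ins <- inSet[ord]
    w <- (r[ord]^alpha) * ins
    pin <- cumsum(w) / sum(w)
    pout <- cumsum(!ins) / sum(!ins)
    sum(pin - pout)
  }, numeric(1))
  score <- raw
  if (normalize) {
    rng <- max(raw) - min(raw)
    if (rng > 0) score <- raw / rng
  }
  data.frame(sample = colnames(expr), score = score,
             stringsAsFactors = FALSE)
}

#' Read / write an expression matrix TSV
#'
#' @param path File path; first column \code{gene}, then one column per
#'   sample.
#' @return Numeric matrix with gene rownames.
#' @export
readExpressionMatrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "gene") stop("first column must be 'gene'")
  if (anyDuplicated(df$gene)) stop("duplicate gene ids")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene
  m
}

#' @rdname readExpressionMatrix
#' @param expr Numeric matrix genes x samples.
#' @export
writeExpressionMatrix <- function(expr, path) {
  write.table(data.frame(gene = rownames(expr), expr, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
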