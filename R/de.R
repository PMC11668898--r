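## Differential expression between irradiation-derived (RR) and parental (WT)
## samples: a deliberately simple negative-binomial Wald test (median-of-ratios
## normalisation, method-of-moments dispersion, no shrinkage), followed by
## direction-consistent intersection across cell lines and hypergeometric
## over-representation analysis.

#' Median-of-ratios size factors
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return Numeric vector of per-sample size factors.
#' @export
sizeFactors <- function(counts) {
  logGeo <- rowMeans(log(counts))
  use <- is.finite(logGeo)
  if (!any(use)) stop("no gene has positive counts in every sample")
  apply(counts, 2, function(col) exp(median(log(col[use]) - logGeo[use])))
}

#' Negative-binomial Wald test, RR versus WT
#'
#' A simplified differential-expression engine for one cell line: counts are
#' normalised by median-of-ratios size factors; the gene-wise NB dispersion is
#' estimated by method of moments from the pooled within-group variance and
#' floored at the median dispersion across genes (a conservative moderation
#' against the instability of per-gene estimates at small n); the Wald
#' statistic is the log2 fold change over its delta-method standard error,
#' with a two-sided normal p-value and Benjamini-Hochberg adjustment over all
#' tested genes. Genes with all-zero counts are excluded (their number is
#' carried in the \code{"n_zero_excluded"} attribute).
#'
#' @param counts Integer matrix genes x samples.
#' @param colData data.frame with one row per sample, columns
#'   \code{cell_line} and \code{phenotype} (\code{"RR"} or \code{"WT"}).
#' @param cellLine Cell line to test; defaults to the only one present.
#' @param pseudo Pseudo-count added to group means for the fold change.
#' @return data.frame with columns gene, base_mean, log2fc, se, p, p_adj,
#'   sorted by p.
#' @export
nbWaldDE <- function(counts, colData, cellLine = NULL, pseudo = 0.5) {
  stopifnot(nrow(colData) == ncol(counts))
  if (is.null(cellLine)) {
    cellLine <- unique(colData$cell_line)
    if (length(cellLine) != 1L)
      stop("several cell lines present; pick one via `cellLine`")
  }
  sel <- colData$cell_line == cellLine
  counts <- counts[, sel, drop = FALSE]
  pheno <- colData$phenotype[sel]
  nR <- sum(pheno == "RR"); nW <- sum(pheno == "WT")
  if (nR < 2L || nW < 2L)
    stop("need at least 2 RR and 2 WT samples for cell line ", cellLine)

  nz <- rowSums(counts) > 0
  nZero <- sum(!nz)
  counts <- counts[nz, , drop = FALSE]
  sf <- sizeFactors(counts)
  norm <- sweep(counts, 2, sf, "/")

  nm <- norm[, pheno == "RR", drop = FALSE]
  wm <- norm[, pheno == "WT", drop = FALSE]
  muR <- rowMeans(nm); muW <- rowMeans(wm)
  vR <- apply(nm, 1, var); vW <- apply(wm, 1, var)
  pooledVar <- ((nR - 1) * vR + (nW - 1) * vW) / (nR + nW - 2)
  muBar <- (nR * muR + nW * muW) / (nR + nW)
  disp <- (pooledVar - muBar) / muBar^2
  disp[!is.finite(disp)] <- NA
  central <- max(median(disp[disp > 0], na.rm = TRUE), 1e-8)
  # gene-wise MoM estimates carry very few degrees of freedom at typical
  # replicate counts; floor at the central dispersion and shrink the
  # remainder geometrically toward it (equal weights on the log scale)
  disp[is.na(disp)] <- central
  disp <- sqrt(pmax(disp, central) * central)

  log2fc <- log2((muR + pseudo) / (muW + pseudo))
  varLogR <- (1 / (muR + pseudo) + disp) / nR
  varLogW <- (1 / (muW + pseudo) + disp) / nW
  se <- sqrt(varLogR + varLogW) / log(2)
  z <- log2fc / se
  p <- 2 * pnorm(-abs(z))
  res <- data.frame(
    gene = rownames(counts),
    base_mean = muBar,
    log2fc = log2fc,
    se = se,
    p = p,
    p_adj = p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$p), ]
  rownames(res) <- NULL
  attr(res, "n_zero_excluded") <- nZero
  attr(res, "cell_line") <- cellLine
  res
}

#' Read an externally produced differential-expression table
#'
#' Accepts any tab-delimited table with columns \code{gene, log2fc, p, p_adj}
#' (e.g. an export of a full DESeq2 run), so the intersection stage is
#' agnostic to the DE engine.
#'
#' @param path File path.
#' @return data.frame with the four required columns.
#' @export
readDeTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "p", "p_adj")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Select differentially expressed genes
#'
#' Genes with BH-adjusted p strictly below \code{alpha}; direction is the
#' sign of the log2 fold change, and genes with a fold change of exactly
#' zero are excluded.
#'
#' @param results data.frame from [nbWaldDE()] or [readDeTable()].
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return data.frame with columns gene, direction ("up"/"down"), log2fc.
#' @export
selectDegs <- function(results, alpha = 0.05) {
  keep <- results$p_adj < alpha & results$log2fc != 0
  keep[is.na(keep)] <- FALSE
  data.frame(
    gene = results$gene[keep],
    direction = ifelse(results$log2fc[keep] > 0, "up", "down"),
    log2fc = results$log2fc[keep],
    stringsAsFactors = FALSE
  )
}

#' Direction-consistent intersection of DEG sets across cell lines
#'
#' A gene is a common DEG when it is significant in every cell line of the
#' scope with the same direction of dysregulation. Also reports the fraction
#' of common genes whose fold change exceeds \code{fcThreshold} in magnitude
#' in every scope member (the "large fold change" fraction).
#'
#' @param degSets Named list (cell line -> data.frame from [selectDegs()]).
#' @param scope Cell lines to intersect over; default all of \code{degSets}.
#' @param fcThreshold Magnitude threshold on log2 fold change (default 1,
#'   i.e. a two-fold linear change).
#' @return List with \code{genes} (data.frame: gene, direction, one log2fc
#'   column per cell line), \code{n_up}, \code{n_down}, and
#'   \code{frac_large_fc}.
#' @export
intersectCommonDegs <- function(degSets, scope = names(degSets),
                                fcThreshold = 1) {
  if (!length(scope)) stop("scope must name at least one cell line")
  miss <- setdiff(scope, names(degSets))
  if (length(miss)) stop("unknown cell line(s): ", paste(miss, collapse = ", "))
  sets <- degSets[scope]
  common <- Reduce(intersect, lapply(sets, `[[`, "gene"))
  rows <- lapply(common, function(g) {
    dirs <- vapply(sets, function(s) s$direction[match(g, s$gene)], character(1))
    if (length(unique(dirs)) != 1L) return(NULL)
    lfc <- vapply(sets, function(s) s$log2fc[match(g, s$gene)], numeric(1))
    c(list(gene = g, direction = dirs[[1L]]), as.list(lfc))
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    genes <- data.frame(gene = character(), direction = character(),
                        stringsAsFactors = FALSE)
    for (cl in scope) genes[[cl]] <- numeric(0)
  } else {
    genes <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    names(genes) <- c("gene", "direction", scope)
    genes <- genes[order(genes$gene), ]
    rownames(genes) <- NULL
  }
  lfcMat <- as.matrix(genes[, scope, drop = FALSE])
  largeAll <- if (nrow(genes)) rowSums(abs(lfcMat) > fcThreshold) == length(scope)
              else logical(0)
  list(
    genes = genes,
    scope = scope,
    n_up = sum(genes$direction == "up"),
    n_down = sum(genes$direction == "down"),
    frac_large_fc = if (nrow(genes)) mean(largeAll) else NA_real_
  )
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set with at least \code{minSize} listed genes by the
#' hypergeometric upper tail P(X >= k), where k is the overlap of the
#' selected genes with the term inside the universe, with BH adjustment over
#' the tested terms. The rich factor is k divided by the total number of
#' genes listed in the term (not restricted to the universe). Terms with
#' \code{fdr < fdrCutoff} are flagged significant. Overlapping terms are
#' reported as-is (no ontology-aware simplification).
#'
#' @param selected Character vector of selected genes (subset of universe).
#' @param universe Character vector of all genes eligible for selection.
#' @param geneSets Named list of character vectors (term -> genes), e.g.
#'   from [readGmt()].
#' @param minSize Minimum listed term size to test (default 20).
#' @param fdrCutoff FDR significance flag threshold (default 0.1).
#' @return data.frame with columns term, k, K, K_listed, n, N, p, fdr,
#'   rich_factor, significant; sorted by p.
#' @export
oraEnrich <- function(selected, universe, geneSets, minSize = 20L,
                      fdrCutoff = 0.1) {
  universe <- unique(universe)
  if (!length(universe)) stop("universe must be non-empty")
  selected <- unique(selected)
  if (length(setdiff(selected, universe)))
    stop("selected genes must be a subset of the universe")
  n <- length(selected); N <- length(universe)
  rows <- lapply(names(geneSets), function(term) {
    listed <- unique(geneSets[[term]])
    if (length(listed) < minSize) return(NULL)
    inUniverse <- intersect(listed, universe)
    K <- length(inUniverse)
    k <- length(intersect(selected, inUniverse))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, K_listed = length(listed),
               n = n, N = N, p = p,
               rich_factor = k / length(listed),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(term = character(), k = integer(), K = integer(),
                      K_listed = integer(), n = integer(), N = integer(),
                      p = numeric(), fdr = numeric(), rich_factor = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, method = "BH")
  out$significant <- out$fdr < fdrCutoff
  out <- out[order(out$p), c("term", "k", "K", "K_listed", "n", "N", "p",
                             "fdr", "rich_factor", "significant")]
  rownames(out) <- NULL
  out
}

#' Read / write a counts matrix with sample metadata sidecar
#'
#' The counts TSV has a \code{gene} column followed by one column per sample;
#' the sidecar TSV has columns \code{sample_id, cell_line, phenotype} (and
#' optionally \code{passage}).
#'
#' @param countsPath,metaPath File paths.
#' @return List with \code{counts} (integer matrix) and \code{colData}.
#' @export
readCountsMatrix <- function(countsPath, metaPath) {
  df <- read.delim(countsPath, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "gene") stop("first column must be 'gene'")
  if (anyDuplicated(df$gene)) stop("duplicate gene ids")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene
  meta <- read.delim(metaPath, stringsAsFactors = FALSE)
  need <- c("sample_id", "cell_line", "phenotype")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing: ", paste(miss, collapse = ", "))
  if (!identical(colnames(m), meta$sample_id))
    stop("sample columns must match metadata sample_id order")
  list(counts = m, colData = meta)
}

#' @rdname readCountsMatrix
#' @param counts Integer matrix genes x samples.
#' @param colData Sample metadata data.frame.
#' @export
writeCountsMatrix <- function(counts, colData, countsPath, metaPath) {
  write.table(data.frame(gene = rownames(counts), counts, check.names = FALSE),
              countsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(colData, metaPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(countsPath, metaPath))
}
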