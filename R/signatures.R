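## COSMIC-style SBS signature refitting: iterative forward selection of
## signatures against the normalised catalogue spectrum, a weight cutoff with
## re-optimisation on the retained support, and a guard that prunes fits of
## very sparse catalogues to their dominant signature.

#' Read / write a signature reference matrix
#'
#' Tab-delimited, first column the 96 context labels (any order; reordered to
#' COSMIC order on read), one column per signature. Each signature column is
#' a probability distribution over the 96 classes.
#'
#' @param path File path.
#' @return Numeric matrix, 96 rows in COSMIC order, one named column per
#'   signature.
#' @export
readSignatureMatrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ctx <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ctx
  validateSignatureMatrix(m[cosmicContexts(), , drop = FALSE])
}

#' @rdname readSignatureMatrix
#' @param sigs Signature matrix as returned by [readSignatureMatrix()].
#' @export
writeSignatureMatrix <- function(sigs, path) {
  df <- data.frame(context = rownames(sigs), sigs, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validateSignatureMatrix <- function(sigs) {
  if (nrow(sigs) != 96L || !identical(rownames(sigs), cosmicContexts()))
    stop("signature matrix must have the 96 COSMIC context rows")
  if (any(sigs < 0)) stop("signature probabilities must be non-negative")
  s <- colSums(sigs)
  if (any(abs(s - 1) > 1e-6))
    stop("signature columns must each sum to 1 (off by up to ",
         format(max(abs(s - 1))), ")")
  sigs
}

## squared error of the convex reconstruction S w against spectrum p
sseOf <- function(p, S, w) {
  recon <- if (length(w)) as.vector(S[, names(w), drop = FALSE] %*% w) else 0
  sum((p - recon)^2)
}

## Euclidean projection onto {x >= 0, sum(x) <= 1}
projCappedSimplex <- function(v) {
  x <- pmax(v, 0)
  if (sum(x) <= 1) return(x)
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  pmax(v - (css[rho] - 1) / rho, 0)
}

## projected-gradient least squares on the capped simplex: minimises
## ||p - S w||^2 subject to w >= 0 and sum(w) <= 1 (the feasible region of
## weights on the normalised-spectrum scale); convex, so the fixed point is
## the constrained optimum on the given support
cappedSimplexLS <- function(p, S, w, tol = 1e-13, maxIter = 50000L) {
  if (!length(w)) return(w)
  Ssub <- S[, names(w), drop = FALSE]
  G <- crossprod(Ssub)
  L <- 2 * max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  b <- as.vector(crossprod(Ssub, p))
  x <- projCappedSimplex(unname(w))
  for (it in seq_len(maxIter)) {
    grad <- 2 * (as.vector(G %*% x) - b)
    xn <- projCappedSimplex(x - grad / L)
    moved <- max(abs(xn - x))
    x <- xn
    if (moved < tol) break
  }
  setNames(x, names(w))
}

#' Refit signature weights to a mutation catalogue
#'
#' Greedy forward selection against the catalogue spectrum normalised to sum
#' 1. Starting from zero weights, each step evaluates every unselected
#' signature by a bounded line search on \[0, 1\] for the single weight that
#' most reduces the sum of squared errors of the reconstruction, adds the
#' signature with the largest reduction (ties broken by the lexicographically
#' smallest id), and re-optimises all selected weights by constrained least
#' squares on the capped simplex (non-negative, summing to at most 1).
#' Selection stops when the relative SSE improvement falls below \code{tol}.
#' Finally, weights below \code{weightCutoff} are zeroed and the remaining
#' support is re-optimised (repeated until all surviving weights are at least
#' the cutoff). Weights are reported on the normalised-spectrum scale; the
#' mass \code{1 - sum(weights)} is unexplained residual.
#'
#' @param catalogue A [MutationCatalogue-class] with positive total.
#' @param sigs Signature matrix (96 x K, columns summing to 1).
#' @param weightCutoff Minimum reportable weight (default 0.06, the
#'   refitting method's conventional default).
#' @param tol Relative SSE improvement below which selection stops.
#' @return A [SignatureFit-class].
#' @export
refitSignatures <- function(catalogue, sigs, weightCutoff = 0.06, tol = 1e-3) {
  stopifnot(is(catalogue, "MutationCatalogue"))
  sigs <- validateSignatureMatrix(sigs)
  total <- totalMutations(catalogue)
  if (total <= 0) stop("catalogue total must be positive")
  p <- catalogueCounts(catalogue) / total

  w <- setNames(numeric(0), character(0))
  sse <- sum(p^2)              # zero-weight reconstruction
  ssePath <- sse
  candidates <- sort(colnames(sigs))

  repeat {
    remaining <- setdiff(candidates, names(w))
    if (!length(remaining)) break
    fixed <- if (length(w)) as.vector(sigs[, names(w), drop = FALSE] %*% w) else 0
    headroom <- max(0, 1 - sum(w))
    if (headroom <= 0) break
    best <- NULL
    bestSse <- sse
    for (s in remaining) {
      col <- sigs[, s]
      opt <- optimize(function(a) sum((p - fixed - a * col)^2),
                      interval = c(0, headroom))
      if (opt$objective < bestSse - 1e-15) {
        bestSse <- opt$objective
        best <- list(id = s, a = opt$minimum)
      }
    }
    if (is.null(best)) break
    relImprove <- (sse - bestSse) / sse
    if (length(w) && relImprove < tol) break
    w[best$id] <- best$a
    w <- cappedSimplexLS(p, sigs, w, tol = 1e-10, maxIter = 2000L)
    sse <- sseOf(p, sigs, w)
    ssePath <- c(ssePath, sse)
    if (sse < 1e-14) break
  }

  removed <- character(0)
  w <- cappedSimplexLS(p, sigs, w)
  repeat {
    low <- names(w)[w < weightCutoff]
    if (!length(low) || !length(w)) break
    removed <- c(removed, low)
    w <- w[setdiff(names(w), low)]
    w <- cappedSimplexLS(p, sigs, w)
  }
  w <- w[order(names(w))]

  new("SignatureFit",
      weights = w,
      residualSse = sseOf(p, sigs, w),
      nMutations = total,
      flaggedOverfit = FALSE,
      ssePath = ssePath,
      removed = removed)
}

#' Reconstruction error of an exposure
#'
#' SSE between the normalised catalogue spectrum and the convex
#' reconstruction implied by the exposure's weights. With all-zero weights
#' the reconstruction is the zero vector, so the error is the squared norm of
#' the spectrum.
#'
#' @param exposure A [SignatureFit-class].
#' @param sigs Signature matrix containing every exposed signature.
#' @param catalogue The catalogue the exposure was fitted to.
#' @return The sum of squared errors.
#' @export
reconstructError <- function(exposure, sigs, catalogue) {
  sigs <- validateSignatureMatrix(sigs)
  w <- signatureWeights(exposure)
  miss <- setdiff(names(w), colnames(sigs))
  if (length(miss)) stop("signature(s) absent from matrix: ",
                         paste(miss, collapse = ", "))
  total <- totalMutations(catalogue)
  if (total <= 0) stop("catalogue total must be positive")
  p <- catalogueCounts(catalogue) / total
  sseOf(p, sigs, w)
}

#' Guard against overfitting sparse catalogues
#'
#' Catalogues built from very few SNVs do not constrain a multi-signature
#' fit; below \code{minMutations} (strictly) the fit is pruned to its single
#' largest-weight signature, the overfit flag is set and the removed
#' signatures are recorded.
#'
#' @param exposure A [SignatureFit-class].
#' @param minMutations Mutation count below which the guard fires
#'   (default 50; a fit on exactly \code{minMutations} is unchanged).
#' @return The (possibly pruned) [SignatureFit-class].
#' @export
applyOverfitGuard <- function(exposure, minMutations = 50L) {
  if (exposure@nMutations >= minMutations) return(exposure)
  w <- signatureWeights(exposure)
  if (length(w) > 1L) {
    keep <- names(w)[order(-w, names(w))][1L]
    exposure@removed <- c(exposure@removed, setdiff(names(w), keep))
    exposure@weights <- w[keep]
  }
  exposure@flaggedOverfit <- TRUE
  exposure
}

#' Write an exposure as TSV plus JSON
#'
#' @param exposure A [SignatureFit-class].
#' @param path Output path stem; \code{<path>.tsv} and \code{<path>.json}
#'   are written.
#' @return Character vector of the two paths, invisibly.
#' @export
writeExposure <- function(exposure, path) {
  tsv <- paste0(path, ".tsv")
  json <- paste0(path, ".json")
  w <- signatureWeights(exposure)
  write.table(data.frame(signature = names(w), weight = unname(w)),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    weights = as.list(w),
    residual_sse = residualSse(exposure),
    n_mutations = exposure@nMutations,
    flagged_overfit = isOverfitFlagged(exposure),
    removed = exposure@removed
  ), json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, json))
}
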