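#' @import methods
#' @importFrom stats median quantile rnorm rexp runif rpois rgamma rmultinom
#'   rbinom pnorm phyper p.adjust t.test density sd var setNames optimize
#'   coef rlnorm
#' @importFrom utils read.delim write.table combn head write.csv
#'   capture.output str
NULL

#' MutationCatalogue: 96-context single-base-substitution counts
#'
#' Counts of single-nucleotide variants binned into the 96 pyrimidine-centred
#' trinucleotide context classes (e.g. \code{A[C>T]G}), in conventional COSMIC
#' order: the six substitution classes C>A, C>G, C>T, T>A, T>C, T>G, each
#' crossed with the 16 flanking-base combinations.
#'
#' @slot counts Named non-negative numeric vector of length 96; names are the
#'   context class labels in COSMIC order.
#' @export
setClass("MutationCatalogue", representation(counts = "numeric"))

setValidity("MutationCatalogue", function(object) {
  cnt <- object@counts
  if (length(cnt) != 96L)
    return("counts must have length 96")
  if (!identical(names(cnt), cosmicContexts()))
    return("counts must be named by the 96 COSMIC context classes, in order")
  if (any(is.na(cnt)) || any(cnt < 0))
    return("counts must be non-negative and non-missing")
  TRUE
})

#' SignatureFit: refitted signature exposure for one catalogue
#'
#' Result of refitting a fixed signature reference to a mutation catalogue by
#' iterative forward selection. Weights live on the normalised-spectrum scale
#' (each is the fraction of the catalogue's spectrum attributed to a
#' signature); they are non-negative and sum to at most 1.
#'
#' @slot weights Named numeric vector, one entry per retained signature.
#' @slot residualSse Sum of squared errors between the normalised catalogue
#'   and the reconstruction.
#' @slot nMutations Total mutations in the fitted catalogue.
#' @slot flaggedOverfit Logical; \code{TRUE} when the sparse-catalogue guard
#'   pruned the fit to its single dominant signature.
#' @slot ssePath Numeric vector of the SSE after each forward-selection step
#'   (non-increasing).
#' @slot removed Character vector of signatures removed by the cutoff or the
#'   overfit guard.
#' @export
setClass("SignatureFit", representation(
  weights        = "numeric",
  residualSse    = "numeric",
  nMutations     = "numeric",
  flaggedOverfit = "logical",
  ssePath        = "numeric",
  removed        = "character"
))

setValidity("SignatureFit", function(object) {
  w <- object@weights
  if (length(w) && is.null(names(w))) return("weights must be named")
  if (any(w < -1e-12)) return("weights must be non-negative")
  if (sum(w) > 1 + 1e-8) return("weights must sum to at most 1")
  if (object@residualSse < -1e-12) return("residualSse must be non-negative")
  TRUE
})

#' ClonogenicFit: surviving-fraction curve with linear-quadratic parameters
#'
#' @slot pe data.frame of per-replicate plating efficiencies
#'   (arm, dose, replicate, pe).
#' @slot sf data.frame of surviving fractions per (arm, dose).
#' @slot b1 Linear coefficient of the LQ model, per Gy (NA when not fitted).
#' @slot b2 Quadratic coefficient, per Gy^2.
#' @slot clamped Logical; TRUE when the non-negativity clamp was active.
#' @export
setClass("ClonogenicFit", representation(
  pe = "data.frame", sf = "data.frame",
  b1 = "numeric", b2 = "numeric", clamped = "logical"
))

#' KdeAuc: kernel density with tail mass above an intensity threshold
#'
#' @slot grid Increasing grid the density was evaluated on.
#' @slot density Non-negative density values on the grid.
#' @slot threshold Intensity threshold (mean gray value units).
#' @slot aucAbove Fraction of the density mass at or above the threshold.
#' @export
setClass("KdeAuc", representation(
  grid = "numeric", density = "numeric",
  threshold = "numeric", aucAbove = "numeric"
))

setValidity("KdeAuc", function(object) {
  if (is.unsorted(object@grid)) return("grid must be increasing")
  if (any(object@density < 0)) return("density must be non-negative")
  if (object@aucAbove < 0 || object@aucAbove > 1)
    return("aucAbove must lie in [0, 1]")
  TRUE
})

#' CutoffScan: stepwise quantile cutoff scan for survival stratification
#'
#' All candidate thresholds (interior quantiles of the median, tertile,
#' quartile and quintile schemes, deduplicated by value) with their two-group
#' log-rank p-values, and the selected minimum-p cutoff. Candidate p-values
#' are reported unadjusted; the scan is a multiple-look procedure.
#'
#' @slot candidates data.frame with columns scheme, level, threshold,
#'   n_high, n_low, valid, logrank_p.
#' @slot selected Integer row index of the selected candidate.
#' @export
setClass("CutoffScan", representation(
  candidates = "data.frame", selected = "integer"
))

setValidity("CutoffScan", function(object) {
  cand <- object@candidates
  need <- c("scheme", "level", "threshold", "n_high", "n_low", "valid",
            "logrank_p")
  if (!all(need %in% names(cand)))
    return(paste("candidates must contain columns:", paste(need, collapse = ", ")))
  sel <- object@selected
  if (length(sel) != 1L || is.na(sel) || sel < 1L || sel > nrow(cand))
    return("selected must index one candidate row")
  ok <- which(cand$valid)
  if (length(ok) && abs(cand$logrank_p[sel] - min(cand$logrank_p[ok])) > 1e-12)
    return("selected candidate must attain the minimal log-rank p among valid candidates")
  TRUE
})

## ---- accessors ----

#' @describeIn MutationCatalogue-class total mutation count
#' @param object A \code{MutationCatalogue}.
#' @export
setGeneric("totalMutations", function(object) standardGeneric("totalMutations"))

#' @rdname MutationCatalogue-class
#' @export
setMethod("totalMutations", "MutationCatalogue", function(object) sum(object@counts))

#' Catalogue counts accessor
#' @param object A \code{MutationCatalogue}.
#' @return Named numeric vector of 96 context counts.
#' @export
setGeneric("catalogueCounts", function(object) standardGeneric("catalogueCounts"))

#' @rdname catalogueCounts
#' @export
setMethod("catalogueCounts", "MutationCatalogue", function(object) object@counts)

#' Signature weights accessor
#' @param object A \code{SignatureFit}.
#' @return Named numeric vector of fitted signature weights.
#' @export
setGeneric("signatureWeights", function(object) standardGeneric("signatureWeights"))

#' @rdname signatureWeights
#' @export
setMethod("signatureWeights", "SignatureFit", function(object) object@weights)

#' Residual SSE accessor
#' @param object A \code{SignatureFit}.
#' @export
setGeneric("residualSse", function(object) standardGeneric("residualSse"))

#' @rdname residualSse
#' @export
setMethod("residualSse", "SignatureFit", function(object) object@residualSse)

#' Overfit flag accessor
#' @param object A \code{SignatureFit}.
#' @export
setGeneric("isOverfitFlagged", function(object) standardGeneric("isOverfitFlagged"))

#' @rdname isOverfitFlagged
#' @export
setMethod("isOverfitFlagged", "SignatureFit", function(object) object@flaggedOverfit)

#' Linear-quadratic coefficients accessor
#' @param object A \code{ClonogenicFit}.
#' @return Named numeric vector \code{c(b1 = ..., b2 = ...)}.
#' @export
setGeneric("lqCoefficients", function(object) standardGeneric("lqCoefficients"))

#' @rdname lqCoefficients
#' @export
setMethod("lqCoefficients", "ClonogenicFit",
          function(object) c(b1 = object@b1, b2 = object@b2))

#' Surviving fractions accessor
#' @param object A \code{ClonogenicFit}.
#' @export
setGeneric("survivingFractionTable",
           function(object) standardGeneric("survivingFractionTable"))

#' @rdname survivingFractionTable
#' @export
setMethod("survivingFractionTable", "ClonogenicFit", function(object) object@sf)

#' Tail mass above the threshold
#' @param object A \code{KdeAuc}.
#' @export
setGeneric("aucAbove", function(object) standardGeneric("aucAbove"))

#' @rdname aucAbove
#' @export
setMethod("aucAbove", "KdeAuc", function(object) object@aucAbove)

#' Scan candidates accessor
#' @param object A \code{CutoffScan}.
#' @export
setGeneric("scanCandidates", function(object) standardGeneric("scanCandidates"))

#' @rdname scanCandidates
#' @export
setMethod("scanCandidates", "CutoffScan", function(object) object@candidates)

#' Selected cutoff accessor
#' @param object A \code{CutoffScan}.
#' @return One-row data.frame: the selected candidate.
#' @export
setGeneric("selectedCutoff", function(object) standardGeneric("selectedCutoff"))

#' @rdname selectedCutoff
#' @export
setMethod("selectedCutoff", "CutoffScan",
          function(object) object@candidates[object@selected, , drop = FALSE])

## ---- show methods ----

setMethod("show", "MutationCatalogue", function(object) {
  cnt <- object@counts
  cls <- sub("^[ACGT]\\[([A-Z>]+)\\][ACGT]$", "\\1", names(cnt))
  bysub <- tapply(cnt, cls, sum)
  cat("MutationCatalogue with", sum(cnt), "SNVs over 96 context classes\n")
  cat(" by substitution:",
      paste(names(bysub), bysub, sep = "=", collapse = "  "), "\n")
})

setMethod("show", "SignatureFit", function(object) {
  cat("SignatureFit on", object@nMutations, "mutations\n")
  w <- sort(object@weights, decreasing = TRUE)
  if (length(w))
    cat(" weights:", paste(names(w), sprintf("%.3f", w), collapse = "  "), "\n")
  cat(sprintf(" residual SSE: %.4g; unexplained weight: %.3f\n",
              object@residualSse, max(0, 1 - sum(w))))
  if (object@flaggedOverfit)
    cat(" flagged: sparse catalogue, pruned to dominant signature (removed:",
        paste(object@removed, collapse = ", "), ")\n")
})

setMethod("show", "ClonogenicFit", function(object) {
  cat("ClonogenicFit:", length(unique(object@sf$arm)), "arm(s),",
      length(unique(object@sf$dose)), "dose level(s)\n")
  if (!is.na(object@b1))
    cat(sprintf(" LQ: b1 = %.4g /Gy, b2 = %.4g /Gy^2%s\n", object@b1, object@b2,
                if (isTRUE(object@clamped)) " (non-negativity clamp active)" else ""))
})

setMethod("show", "KdeAuc", function(object) {
  cat(sprintf("KdeAuc: P(intensity >= %g) = %.4f (%d grid points)\n",
              object@threshold, object@aucAbove, length(object@grid)))
})

setMethod("show", "CutoffScan", function(object) {
  sel <- selectedCutoff(object)
  cat("CutoffScan over", nrow(object@candidates), "candidate thresholds\n")
  cat(sprintf(" selected: %s split at %.4g (level %.3g), log-rank p = %.3g [unadjusted], %d high / %d low\n",
              sel$scheme, sel$threshold, sel$level, sel$logrank_p,
              sel$n_high, sel$n_low))
})
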