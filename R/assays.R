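## Radiobiology assay statistics: clonogenic plating efficiency and surviving
## fractions with the linear-quadratic model SF(d) = exp(-(b1*d + b2*d^2)),
## replicate-paired foci summaries, kernel-density tail mass of per-cell
## intensities, and delta-delta-Ct qPCR fold changes.

#' Plating efficiencies and surviving fractions
#'
#' PE = colonies / cells plated per replicate; SF(d) = mean PE at dose d over
#' mean PE at the control dose, per arm; SF at the control dose is exactly 1.
#' A PE above 1 (more colonies than cells plated) raises a warning.
#'
#' @param records data.frame with columns arm, dose, cells_plated, colonies,
#'   replicate. Colonies are counted upstream only when they exceed 50 cells;
#'   that rule is metadata here.
#' @param controlDose Reference (unirradiated) dose, default 0 Gy.
#' @return A [ClonogenicFit-class] with pe and sf filled and the LQ slots
#'   unset (see [fitLQ()]).
#' @export
survivingFractions <- function(records, controlDose = 0) {
  need <- c("arm", "dose", "cells_plated", "colonies", "replicate")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(records$dose < 0)) stop("doses must be non-negative")
  pe <- records[, c("arm", "dose", "replicate")]
  pe$pe <- records$colonies / records$cells_plated
  if (any(pe$pe > 1)) warning("plating efficiency above 1 for some replicates")
  sf <- do.call(rbind, lapply(split(pe, pe$arm), function(a) {
    ctrl <- a$pe[a$dose == controlDose]
    if (!length(ctrl)) stop("arm ", a$arm[1L], " lacks the control dose")
    if (mean(ctrl) == 0) stop("control plating efficiency is zero for arm ",
                              a$arm[1L])
    byDose <- tapply(a$pe, a$dose, mean)
    data.frame(arm = a$arm[1L], dose = as.numeric(names(byDose)),
               sf = as.numeric(byDose) / mean(ctrl),
               stringsAsFactors = FALSE)
  }))
  sf$sf[sf$dose == controlDose] <- 1
  rownames(sf) <- NULL
  new("ClonogenicFit", pe = pe, sf = sf,
      b1 = NA_real_, b2 = NA_real_, clamped = FALSE)
}

#' Fit the linear-quadratic survival model
#'
#' Fits SF(d) = exp(-(b1*d + b2*d^2)) by least squares of -log(SF) on
#' (d, d^2) through the origin — linear in (b1, b2), so noiseless LQ data are
#' recovered exactly. A linear-space nonlinear fit of the same model is
#' available via \code{space = "linear"}. Negative coefficients are clamped
#' to zero on request, with the clamp reported.
#'
#' @param doses Dose vector (Gy); at least two distinct nonzero doses.
#' @param sf Surviving fractions in (0, 1], same length.
#' @param space \code{"log"} (default) or \code{"linear"}.
#' @param nonneg Clamp negative coefficients at zero (default TRUE).
#' @return List with b1, b2, clamped.
#' @export
fitLQ <- function(doses, sf, space = c("log", "linear"), nonneg = TRUE) {
  space <- match.arg(space)
  stopifnot(length(doses) == length(sf))
  nz <- doses > 0
  if (length(unique(doses[nz])) < 2L)
    stop("need at least two distinct nonzero doses")
  if (any(sf <= 0) || any(sf > 1 + 1e-9))
    stop("surviving fractions must lie in (0, 1]")
  d <- doses[nz]; y <- -log(sf[nz])
  if (space == "log") {
    fit <- stats::lm(y ~ 0 + I(d) + I(d^2))
    b <- unname(coef(fit))
  } else {
    start <- coef(stats::lm(y ~ 0 + I(d) + I(d^2)))
    nl <- stats::nls(s ~ exp(-(b1 * d + b2 * d^2)),
                     data = data.frame(d = d, s = sf[nz]),
                     start = list(b1 = unname(start[1]), b2 = unname(start[2])),
                     control = stats::nls.control(warnOnly = TRUE))
    b <- unname(coef(nl))
  }
  clamped <- FALSE
  if (nonneg && any(b < 0)) {
    clamped <- TRUE
    # refit with the negative coefficient pinned at zero
    if (b[1] < 0 && b[2] < 0) b <- c(0, 0)
    else if (b[1] < 0) b <- c(0, sum(y * d^2) / sum(d^4))
    else b <- c(sum(y * d) / sum(d^2), 0)
    b <- pmax(b, 0)
  }
  list(b1 = b[1], b2 = b[2], clamped = clamped)
}

#' Attach an LQ fit to a clonogenic result
#'
#' @param result A [ClonogenicFit-class] from [survivingFractions()].
#' @param arm Arm to fit; defaults to the only arm present.
#' @param ... Passed to [fitLQ()].
#' @return The [ClonogenicFit-class] with b1/b2/clamped filled.
#' @export
fitClonogenic <- function(result, arm = NULL, ...) {
  sf <- result@sf
  if (is.null(arm)) {
    arm <- unique(sf$arm)
    if (length(arm) != 1L) stop("several arms present; pick one")
  }
  sub <- sf[sf$arm == arm, ]
  lq <- fitLQ(sub$dose, sub$sf, ...)
  result@b1 <- lq$b1; result@b2 <- lq$b2; result@clamped <- lq$clamped
  result
}

#' Ratio of surviving fractions at one dose
#'
#' @param resultA,resultB [ClonogenicFit-class] objects (one arm each, or
#'   specify \code{armA}/\code{armB}).
#' @param dose Dose (Gy) present in both results.
#' @param armA,armB Optional arm selectors.
#' @return \code{sf_a(dose) / sf_b(dose)}.
#' @export
sfRatio <- function(resultA, resultB, dose, armA = NULL, armB = NULL) {
  pick <- function(res, arm) {
    sf <- res@sf
    if (!is.null(arm)) sf <- sf[sf$arm == arm, ]
    v <- sf$sf[sf$dose == dose]
    if (!length(v)) stop("dose ", dose, " absent from a result")
    mean(v)
  }
  a <- pick(resultA, armA); b <- pick(resultB, armB)
  if (b == 0) stop("denominator surviving fraction is zero")
  a / b
}

#' Foci summary with replicate-paired t-test
#'
#' Summarises per-cell foci counts for two conditions and compares them by a
#' paired two-tailed t-test on per-replicate means (the pairing unit is the
#' replicate; per-cell pairing across conditions is not meaningful).
#' Replicates with fewer than \code{minCells} cells are flagged.
#'
#' @param records data.frame with columns cell_id, condition, foci,
#'   replicate (and optionally timepoint).
#' @param groupA,groupB Condition labels to compare.
#' @param minCells Minimum cells per (condition, replicate) before a
#'   data-sufficiency warning (default 50).
#' @return List with per-group mean/sd of cell-level counts, the per-replicate
#'   means, and the paired t-test p-value.
#' @export
fociSummary <- function(records, groupA, groupB, minCells = 50L) {
  need <- c("condition", "foci", "replicate")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  sub <- records[records$condition %in% c(groupA, groupB), ]
  cellsPer <- table(sub$condition, sub$replicate)
  if (any(cellsPer > 0 & cellsPer < minCells))
    warning("some condition/replicate groups have fewer than ", minCells,
            " cells")
  repMeans <- tapply(sub$foci, list(sub$condition, sub$replicate), mean)
  a <- repMeans[groupA, ]; b <- repMeans[groupB, ]
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2L) stop("need at least 2 paired replicates")
  if (var(a - b) == 0)
    stop("replicate differences have zero variance; paired t-test undefined")
  tt <- t.test(a, b, paired = TRUE)
  list(
    mean_a = mean(sub$foci[sub$condition == groupA]),
    sd_a = sd(sub$foci[sub$condition == groupA]),
    mean_b = mean(sub$foci[sub$condition == groupB]),
    sd_b = sd(sub$foci[sub$condition == groupB]),
    replicate_means_a = a,
    replicate_means_b = b,
    p = tt$p.value
  )
}

#' Kernel-density tail mass of per-cell intensities
#'
#' Gaussian kernel density with Silverman's rule-of-thumb bandwidth on a
#' 512-point grid spanning the data plus three bandwidths each side; the
#' reported statistic is the fraction of the density mass at or above the
#' intensity threshold (trapezoidal integration, normalised so that the
#' above/below masses partition exactly). At least 80 cells at or above the
#' threshold are expected for a stable tail estimate; fewer raises a
#' data-sufficiency warning, not an error.
#'
#' @param intensities Numeric vector of per-cell mean gray values; at least
#'   two distinct values.
#' @param threshold Intensity threshold (default 40 MGV).
#' @param bw Optional bandwidth override.
#' @param minCellsAbove Data-sufficiency warning threshold (default 80).
#' @return A [KdeAuc-class].
#' @export
intensityKdeAuc <- function(intensities, threshold = 40, bw = NULL,
                            minCellsAbove = 80L) {
  x <- intensities[is.finite(intensities)]
  if (length(unique(x)) < 2L)
    stop("need at least two distinct intensities (zero bandwidth otherwise)")
  if (sum(x >= threshold) < minCellsAbove)
    warning("fewer than ", minCellsAbove, " cells at or above the threshold")
  if (is.null(bw)) bw <- stats::bw.nrd0(x)
  den <- density(x, bw = bw, n = 512, cut = 3)
  g <- den$x; f <- den$y
  trap <- function(gx, gy) if (length(gx) < 2L) 0 else
    sum((gy[-1] + gy[-length(gy)]) / 2 * diff(gx))
  total <- trap(g, f)
  if (threshold <= g[1L]) above <- total
  else if (threshold >= g[length(g)]) above <- 0
  else {
    fThr <- stats::approx(g, f, xout = threshold)$y
    idx <- g > threshold
    above <- trap(c(threshold, g[idx]), c(fThr, f[idx]))
  }
  auc <- min(1, max(0, above / total))
  new("KdeAuc", grid = g, density = f, threshold = threshold, aucAbove = auc)
}

#' Delta-delta-Ct qPCR fold changes
#'
#' Per sample, delta-Ct = Ct(target) - Ct(reference); delta-delta-Ct
#' subtracts the mean delta-Ct of the control-condition samples; the fold
#' change is 2^(-delta-delta-Ct). The mean fold change of the control
#' condition is 1 by construction.
#'
#' @param records data.frame with columns sample, gene, ct, is_control_condition.
#' @param targetGene,referenceGene Gene ids; both Ct values must be present
#'   for every sample.
#' @return data.frame with columns sample, is_control_condition, delta_ct,
#'   delta_delta_ct, fold_change.
#' @export
ddctFoldChange <- function(records, targetGene, referenceGene) {
  need <- c("sample", "gene", "ct", "is_control_condition")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  samples <- unique(records$sample)
  getCt <- function(s, g) {
    v <- records$ct[records$sample == s & records$gene == g]
    if (!length(v)) stop("missing Ct for sample ", s, ", gene ", g)
    mean(v)
  }
  dct <- vapply(samples, function(s)
    getCt(s, targetGene) - getCt(s, referenceGene), numeric(1))
  isCtrl <- vapply(samples, function(s)
    any(records$is_control_condition[records$sample == s]), logical(1))
  if (!any(isCtrl)) stop("no control-condition samples")
  ddct <- dct - mean(dct[isCtrl])
  data.frame(sample = samples, is_control_condition = isCtrl,
             delta_ct = dct, delta_delta_ct = ddct,
             fold_change = 2^(-ddct), row.names = NULL,
             stringsAsFactors = FALSE)
}
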