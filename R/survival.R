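## Survival stratification of score-annotated cohorts: Kaplan-Meier and
## reverse-KM follow-up, log-rank comparison, Cox proportional hazards, and
## the stepwise quantile cutoff scan (median / tertile / quartile / quintile
## interior quantiles, minimum log-rank p) used to dichotomise gene-set
## activity. The standard estimators are delegated to the survival package
## (Efron tie handling for Cox).

#' @importFrom survival Surv survfit survdiff coxph
NULL

checkRecords <- function(records, needScore = FALSE) {
  need <- c("time", "event")
  if (needScore) need <- c(need, "score")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(records)) stop("no survival records")
  if (any(records$time <= 0)) stop("times must be positive")
  if (!all(records$event %in% c(0, 1))) stop("event must be 0/1")
  records
}

#' Kaplan-Meier product-limit estimate
#'
#' @param records data.frame with columns \code{time} (months) and
#'   \code{event} (1 = event, 0 = censored). Subjects censored at an event
#'   time count as at risk at that time.
#' @return data.frame with columns time, at_risk, n_event, survival
#'   (one row per observed time).
#' @export
kmEstimate <- function(records) {
  records <- checkRecords(records)
  fit <- survfit(Surv(time, event) ~ 1, data = records)
  data.frame(time = fit$time, at_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

#' Median follow-up by reverse Kaplan-Meier
#'
#' Flips the event indicator (censoring becomes the event) and reads the
#' median of the resulting curve. Returns \code{NA} when the flipped curve
#' never reaches 0.5 (median follow-up not reached).
#'
#' @param records data.frame with \code{time} and \code{event}.
#' @return Median follow-up time, or \code{NA_real_} if not reached.
#' @export
reverseKmFollowup <- function(records) {
  records <- checkRecords(records)
  records$event <- 1 - records$event
  fit <- survfit(Surv(time, event) ~ 1, data = records)
  med <- unname(summary(fit)$table["median"])
  if (is.na(med)) NA_real_ else med
}

#' Log-rank test between groups
#'
#' Standard (O - E)^2 / V chi-square comparison with \code{length(groups) -
#' 1} degrees of freedom; the two-group case uses the variance-based form.
#'
#' @param groups List of survival record data.frames, one per group.
#' @return List with \code{statistic}, \code{df}, \code{p}.
#' @export
logrankTest <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(!vapply(groups, nrow, integer(1)))) stop("empty group")
  df <- do.call(rbind, lapply(seq_along(groups), function(i) {
    g <- checkRecords(groups[[i]])
    data.frame(time = g$time, event = g$event, group = i)
  }))
  sd <- survdiff(Surv(time, event) ~ group, data = df)
  k <- length(groups) - 1L
  list(statistic = unname(sd$chisq), df = k,
       p = stats::pchisq(sd$chisq, df = k, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie correction; reports the hazard
#' ratio with its 95 percent Wald confidence interval. Monotone-likelihood /
#' separation cases are reported with \code{converged = FALSE}.
#'
#' @param records data.frame with \code{time} and \code{event}.
#' @param covariate Numeric vector, one value per record; must not be
#'   constant.
#' @return List with beta, hr, se, ci95 (length-2), p, converged.
#' @export
coxFit <- function(records, covariate) {
  records <- checkRecords(records)
  stopifnot(length(covariate) == nrow(records))
  if (length(unique(covariate)) < 2L) stop("covariate is constant")
  records$x <- covariate
  diverged <- FALSE
  fit <- withCallingHandlers(
    coxph(Surv(time, event) ~ x, data = records, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w)))
        diverged <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  converged <- !diverged && is.finite(beta) && abs(beta) < 15 && se < 100
  list(beta = beta,
       hr = exp(beta),
       se = se,
       ci95 = exp(beta + c(-1, 1) * 1.96 * se),
       p = 2 * pnorm(-abs(beta / se)),
       converged = converged)
}

#' Stepwise quantile cutoff scan for score stratification
#'
#' Candidate thresholds are every interior quantile of the median, tertile,
#' quartile and quintile schemes (levels 1/2; 1/3, 2/3; 1/4, 2/4, 3/4; 1/5,
#' 2/5, 3/5, 4/5), deduplicated by threshold value, with quantiles computed
#' by the linear-interpolation convention (R type 7). Each candidate
#' dichotomises the cohort as high = score strictly above the threshold and
#' is scored by the two-group log-rank p-value. Candidates leaving either
#' arm below \code{minGroupFrac} of the cohort are invalid. The selected
#' cutoff minimises the log-rank p over valid candidates; ties go to the
#' quantile level nearest the median. All candidate p-values are reported
#' unadjusted — the scan is a multiple-look procedure and its minimum p must
#' not be read as a calibrated significance level.
#'
#' @param records data.frame with \code{time}, \code{event}, \code{score};
#'   at least 20 records.
#' @param minGroupFrac Minimum fraction of the cohort per arm (default 0.1).
#' @return A [CutoffScan-class].
#' @export
scanCutoffs <- function(records, minGroupFrac = 0.1) {
  records <- checkRecords(records, needScore = TRUE)
  if (nrow(records) < 20L) stop("need at least 20 records for the scan")
  if (length(unique(records$score)) < 2L)
    stop("scores are constant; no valid split")
  schemes <- list(median = 1 / 2, tertile = (1:2) / 3, quartile = (1:3) / 4,
                  quintile = (1:4) / 5)
  cand <- do.call(rbind, lapply(names(schemes), function(s)
    data.frame(scheme = s, level = schemes[[s]], stringsAsFactors = FALSE)))
  cand$threshold <- quantile(records$score, cand$level, type = 7, names = FALSE)
  cand <- cand[!duplicated(cand$threshold), , drop = FALSE]

  n <- nrow(records)
  res <- lapply(seq_len(nrow(cand)), function(i) {
    high <- records$score > cand$threshold[i]
    nh <- sum(high); nl <- n - nh
    valid <- min(nh, nl) >= minGroupFrac * n
    p <- NA_real_
    if (valid)
      p <- logrankTest(list(records[high, , drop = FALSE],
                            records[!high, , drop = FALSE]))$p
    data.frame(n_high = nh, n_low = nl, valid = valid, logrank_p = p)
  })
  cand <- cbind(cand, do.call(rbind, res))
  rownames(cand) <- NULL
  ok <- which(cand$valid)
  if (!length(ok)) stop("no candidate satisfies the minimum group size")
  best <- ok[cand$logrank_p[ok] <= min(cand$logrank_p[ok]) + 1e-15]
  sel <- best[which.min(abs(cand$level[best] - 0.5))]
  new("CutoffScan", candidates = cand, selected = as.integer(sel))
}

#' Read / write a clinical table
#'
#' Tab-delimited with columns \code{patient_id, time_months, event} and an
#' optional \code{score}.
#'
#' @param path File path.
#' @return data.frame with a \code{time} alias column for the survival
#'   functions.
#' @export
readClinicalTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_months", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df$time <- df$time_months
  df
}

#' @rdname readClinicalTable
#' @param clinical data.frame with the clinical columns.
#' @export
writeClinicalTable <- function(clinical, path) {
  cols <- intersect(c("patient_id", "time_months", "event", "score"),
                    names(clinical))
  write.table(clinical[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
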