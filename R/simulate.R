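## Seeded generators for every pipeline input, each emitting machine-readable
## ground truth alongside the data. Every generator is a pure function of
## (parameters, seed): the global RNG state is saved and restored.

withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed), seed >= 0)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

randomContext <- function(ref) {
  paste0(sample(BASES, length(ref), replace = TRUE), ref,
         sample(BASES, length(ref), replace = TRUE))
}

#' Simulate per-caller, per-replicate somatic SNV call tables
#'
#' Plants \code{nTrue} true somatic SNVs and emits one call table per
#' (caller, replicate): each true variant is reported by caller c in
#' replicate r independently with probability \code{sens[c]}, and each
#' (caller, replicate) table additionally contains \code{fp[c]} unique false
#' sites. All sites carry a 3-mer context (middle base = ref), a gene label
#' and a functional effect.
#'
#' @param nTrue Number of true somatic SNVs (> 0).
#' @param sens Named numeric vector of per-caller sensitivities in \[0, 1\].
#' @param fp Named integer vector of false-positive sites per caller and
#'   replicate (same names as \code{sens}).
#' @param nReplicates Number of replicates (default 3).
#' @param seed Non-negative integer seed.
#' @param sampleId Sample label for the tables.
#' @return List with \code{calls} (data.frame in the variant-table layout)
#'   and \code{truth} (data.frame of the true variants with
#'   \code{is_true_somatic = TRUE}).
#' @export
simCallerCalls <- function(nTrue, sens, fp = setNames(rep(0L, length(sens)),
                                                      names(sens)),
                           nReplicates = 3L, seed = 1L,
                           sampleId = "sample1") {
  if (nTrue <= 0) stop("nTrue must be positive")
  stopifnot(nReplicates >= 1L, all(sens >= 0 & sens <= 1),
            !is.null(names(sens)), all(names(sens) %in% names(fp)))
  callers <- names(sens)
  withSeed(seed, {
    nFp <- sum(fp[callers]) * nReplicates
    pos <- sample.int(1e8L, nTrue + nFp)
    mk <- function(idx) {
      ref <- sample(BASES, length(idx), replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), character(1))
      data.frame(
        chrom = paste0("chr", sample(1:22, length(idx), replace = TRUE)),
        pos = pos[idx], ref = ref, alt = alt,
        gene = paste0("GENE", sample.int(2000L, length(idx), replace = TRUE)),
        effect = sample(c("synonymous", "non_synonymous", "other"),
                        length(idx), replace = TRUE, prob = c(0.7, 0.25, 0.05)),
        context = randomContext(ref),
        stringsAsFactors = FALSE
      )
    }
    truth <- mk(seq_len(nTrue))
    truth$is_true_somatic <- TRUE
    calls <- list()
    nextFp <- nTrue
    for (cl in callers) {
      for (r in seq_len(nReplicates)) {
        det <- runif(nTrue) < sens[[cl]]
        rows <- truth[det, c("chrom", "pos", "ref", "alt", "gene", "effect",
                             "context")]
        if (fp[[cl]] > 0) {
          fpRows <- mk(nextFp + seq_len(fp[[cl]]))
          nextFp <- nextFp + fp[[cl]]
          rows <- rbind(rows, fpRows)
        }
        if (nrow(rows)) {
          rows <- cbind(data.frame(sample_id = sampleId,
                                   replicate_id = paste0("rep", r),
                                   caller_id = cl,
                                   stringsAsFactors = FALSE), rows)
          calls[[paste(cl, r)]] <- rows
        }
      }
    }
    calls <- if (length(calls)) do.call(rbind, calls) else
      data.frame(sample_id = character(), replicate_id = character(),
                 caller_id = character(), chrom = character(), pos = integer(),
                 ref = character(), alt = character(), gene = character(),
                 effect = character(), context = character(),
                 stringsAsFactors = FALSE)
    rownames(calls) <- NULL
    list(calls = calls, truth = truth)
  })
}

#' Simulate a synthetic signature reference matrix
#'
#' Random sparse spectra: each signature column is a normalised
#' gamma(\code{concentration}) draw over the 96 context classes, giving the
#' peaked profiles typical of substitution signatures. Purely synthetic; not
#' a reference signature set.
#'
#' @param nSignatures Number of signature columns.
#' @param seed Seed.
#' @param concentration Gamma shape; smaller means sparser spectra.
#' @return 96 x nSignatures matrix, columns summing to 1, named
#'   \code{SBSsyn1...}.
#' @export
simSignatureMatrix <- function(nSignatures = 6L, seed = 1L,
                               concentration = 0.2) {
  withSeed(seed, {
    m <- matrix(rgamma(96L * nSignatures, shape = concentration), nrow = 96L)
    m <- sweep(m, 2, colSums(m), "/")
    rownames(m) <- cosmicContexts()
    colnames(m) <- paste0("SBSsyn", seq_len(nSignatures))
    m
  })
}

#' Simulate a mutation catalogue from a signature mixture
#'
#' Draws \code{nMutations} substitutions multinomially from the mixture
#' spectrum implied by the weights.
#'
#' @param weights Named weights over signatures present in \code{sigs};
#'   must sum to 1 within 1e-9.
#' @param nMutations Total mutations (>= 0).
#' @param sigs Signature matrix (96 x K).
#' @param seed Seed.
#' @return A [MutationCatalogue-class].
#' @export
simCatalogue <- function(weights, nMutations, sigs, seed = 1L) {
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  miss <- setdiff(names(weights), colnames(sigs))
  if (length(miss)) stop("unknown signature(s): ", paste(miss, collapse = ", "))
  sigs <- validateSignatureMatrix(sigs)
  mix <- as.vector(sigs[, names(weights), drop = FALSE] %*% weights)
  withSeed(seed, {
    counts <- if (nMutations > 0)
      as.vector(rmultinom(1L, nMutations, mix)) else numeric(96)
    newCatalogue(setNames(counts, cosmicContexts()))
  })
}

#' Simulate negative-binomial count matrices for several cell lines
#'
#' Baseline expression per gene is lognormal (meanlog 5, sdlog 1); counts are
#' gamma-Poisson with the given dispersion. Planted genes get a
#' \code{2^log2fc} multiplier in the RR group: genes flagged \code{shared}
#' with the same sign in every cell line; others only in their designated
#' \code{cell_line}.
#'
#' @param nGenes Gene universe size.
#' @param nPerGroup Samples per phenotype per cell line (>= 2).
#' @param cellLines Character vector of cell line labels.
#' @param planted data.frame with columns gene, log2fc, shared and, for
#'   non-shared genes, cell_line. NULL for a global null.
#' @param dispersion NB dispersion (> 0), default 0.05.
#' @param seed Seed.
#' @return List with \code{counts} (named list of matrices), \code{colData}
#'   (named list of sample metadata), and \code{truth} (the planted table).
#' @export
simCounts <- function(nGenes = 5000L, nPerGroup = 3L,
                      cellLines = paste0("CL", 1:4), planted = NULL,
                      dispersion = 0.05, seed = 1L) {
  if (nPerGroup < 2L) stop("nPerGroup must be at least 2")
  if (dispersion <= 0) stop("dispersion must be positive")
  genes <- paste0("G", seq_len(nGenes))
  if (!is.null(planted)) {
    if (length(setdiff(planted$gene, genes)))
      stop("planted genes outside the gene universe")
    if (is.null(planted$cell_line)) planted$cell_line <- NA_character_
  }
  withSeed(seed, {
    base <- stats::rlnorm(nGenes, meanlog = 5, sdlog = 1)
    names(base) <- genes
    if (!is.null(planted) && nrow(planted)) {
      # plant effects in quantifiably expressed genes (upper half of the
      # baseline distribution): fold changes at near-zero counts sit below
      # the Poisson detection limit of any engine and would make recovery a
      # statement about sequencing depth, not about the analysis
      base[planted$gene] <- exp(5 + stats::qnorm(runif(nrow(planted), 0.5, 1)))
    }
    countsList <- list(); metaList <- list()
    for (cl in cellLines) {
      fc <- setNames(rep(1, nGenes), genes)
      if (!is.null(planted)) {
        apply_ <- planted$shared | (!is.na(planted$cell_line) &
                                      planted$cell_line == cl)
        fc[planted$gene[apply_]] <- 2^planted$log2fc[apply_]
      }
      pheno <- rep(c("RR", "WT"), each = nPerGroup)
      mu <- outer(base, ifelse(pheno == "RR", 1, 1))    # genes x samples
      mu[, pheno == "RR"] <- mu[, pheno == "RR"] * fc
      lam <- matrix(rgamma(length(mu), shape = 1 / dispersion,
                           rate = 1 / (dispersion * mu)), nrow = nGenes)
      cnt <- matrix(rpois(length(lam), lam), nrow = nGenes)
      rownames(cnt) <- genes
      colnames(cnt) <- paste(cl, pheno, rep(seq_len(nPerGroup), 2), sep = "_")
      countsList[[cl]] <- cnt
      metaList[[cl]] <- data.frame(sample_id = colnames(cnt),
                                   cell_line = cl, phenotype = pheno,
                                   stringsAsFactors = FALSE)
    }
    list(counts = countsList, colData = metaList, truth = planted)
  })
}

#' Simulate a score-stratified survival cohort
#'
#' Patients carry a latent activity that shifts the expression of the
#' gene-set genes, so their ssGSEA score tracks the activity. Event times are
#' exponential; patients whose score exceeds its
#' \code{thresholdQuantile}-quantile have their hazard multiplied by
#' \code{exp(logHr)}. Censoring is independent: each patient is censored
#' with probability \code{censoringFraction} at a uniform time before their
#' event.
#'
#' @param nPatients Cohort size (>= 20).
#' @param geneSet Non-empty character vector of set genes.
#' @param logHr True log hazard ratio of high versus low.
#' @param thresholdQuantile True threshold quantile in (0, 1).
#' @param censoringFraction Expected censored fraction in \[0, 1).
#' @param seed Seed.
#' @param nBackground Background (out-of-set) genes.
#' @param shift Activity-to-expression shift for set genes.
#' @param baselineHazard Events per month in the low group.
#' @return List with \code{expr}, \code{clinical} (patient_id, time_months,
#'   event, score and a \code{time} alias), and \code{truth}.
#' @export
simCohort <- function(nPatients, geneSet, logHr = log(2),
                      thresholdQuantile = 0.6, censoringFraction = 0.3,
                      seed = 1L, nBackground = 200L, shift = 1,
                      baselineHazard = 0.02) {
  if (nPatients < 20L) stop("nPatients must be at least 20")
  if (!length(geneSet)) stop("gene set is empty")
  stopifnot(thresholdQuantile > 0, thresholdQuantile < 1,
            censoringFraction >= 0, censoringFraction < 1)
  withSeed(seed, {
    genes <- c(geneSet, paste0("BG", seq_len(nBackground)))
    activity <- rnorm(nPatients)
    expr <- matrix(rnorm(length(genes) * nPatients), nrow = length(genes),
                   dimnames = list(genes, paste0("P", seq_len(nPatients))))
    expr[geneSet, ] <- expr[geneSet, ] +
      matrix(shift * activity, nrow = length(geneSet), ncol = nPatients,
             byrow = TRUE)
    score <- ssgseaScores(expr, geneSet)$score
    thr <- quantile(score, thresholdQuantile, type = 7, names = FALSE)
    high <- score > thr
    rate <- baselineHazard * exp(logHr * high)
    time <- rexp(nPatients, rate)
    cens <- runif(nPatients) < censoringFraction
    time[cens] <- runif(sum(cens), 0, time[cens])
    clinical <- data.frame(
      patient_id = colnames(expr),
      time_months = time, event = as.integer(!cens), score = score,
      stringsAsFactors = FALSE
    )
    clinical$time <- clinical$time_months
    list(expr = expr, clinical = clinical,
         truth = list(log_hazard_ratio = logHr,
                      threshold_quantile = thresholdQuantile,
                      threshold = thr, high = high,
                      censoring_fraction = censoringFraction))
  })
}

#' Simulate a clonogenic colony-count table
#'
#' Colony counts are Poisson around
#' \code{cellsPlated * pe0 * exp(-(b1 d + b2 d^2))}; with
#' \code{poisson = FALSE} the exact expected counts are emitted
#' (variance-free mode, useful for checking the LQ fit as a linear-algebra
#' identity).
#'
#' @param b1,b2 LQ coefficients (per Gy, per Gy^2).
#' @param pe0 Plating efficiency at 0 Gy, in (0, 1].
#' @param doses Dose levels (Gy, >= 0; must include 0 for a control).
#' @param cellsPlated Cells plated per well.
#' @param nReplicates Replicates per dose.
#' @param seed Seed.
#' @param poisson Draw Poisson noise (default TRUE).
#' @param arm Arm label.
#' @return data.frame with columns arm, dose, cells_plated, colonies,
#'   replicate, plus a \code{truth} attribute carrying (b1, b2, pe0).
#' @export
simClonogenic <- function(b1 = 0.3, b2 = 0.03, pe0 = 0.5,
                          doses = c(0, 1, 2, 4, 6, 8), cellsPlated = 1000L,
                          nReplicates = 3L, seed = 1L, poisson = TRUE,
                          arm = "armA") {
  if (any(doses < 0)) stop("doses must be non-negative")
  if (pe0 <= 0 || pe0 > 1) stop("pe0 must lie in (0, 1]")
  withSeed(seed, {
    grid <- expand.grid(dose = doses, replicate = paste0("rep", seq_len(nReplicates)),
                        stringsAsFactors = FALSE)
    mu <- cellsPlated * pe0 * exp(-(b1 * grid$dose + b2 * grid$dose^2))
    colonies <- if (poisson) rpois(nrow(grid), mu) else mu
    out <- data.frame(arm = arm, dose = grid$dose,
                      cells_plated = cellsPlated, colonies = colonies,
                      replicate = grid$replicate, stringsAsFactors = FALSE)
    attr(out, "truth") <- list(b1 = b1, b2 = b2, pe0 = pe0)
    out
  })
}

#' Simulate per-cell foci counts and intensity measurements
#'
#' Foci counts are Poisson with a per-condition mean, \code{nCells} cells per
#' (condition, replicate). Intensities are drawn from a normal mixture with
#' each component truncated at 0 (mean gray values are non-negative).
#'
#' @param nCells Cells per condition and replicate (>= 1).
#' @param fociMeans Named numeric vector, condition -> mean foci per cell.
#' @param intensityMixture data.frame with columns weight, mean, sd; weights
#'   must sum to 1.
#' @param nReplicates Replicates (default 3).
#' @param seed Seed.
#' @return List with \code{foci} (cell_id, condition, replicate, foci) and
#'   \code{intensity} (cell_id, replicate, intensity).
#' @export
simCellMeasurements <- function(nCells = 50L,
                                fociMeans = c(irradiated = 2.4,
                                              control = 0.28),
                                intensityMixture = data.frame(
                                  weight = c(0.5, 0.5),
                                  mean = c(25, 50), sd = c(6, 8)),
                                nReplicates = 3L, seed = 1L) {
  if (nCells < 1L) stop("nCells must be at least 1")
  if (abs(sum(intensityMixture$weight) - 1) > 1e-9)
    stop("mixture weights must sum to 1")
  if (any(intensityMixture$sd <= 0)) stop("mixture sds must be positive")
  withSeed(seed, {
    foci <- do.call(rbind, lapply(names(fociMeans), function(cond) {
      do.call(rbind, lapply(seq_len(nReplicates), function(r)
        data.frame(cell_id = paste0(cond, "_r", r, "_c", seq_len(nCells)),
                   condition = cond, replicate = paste0("rep", r),
                   foci = rpois(nCells, fociMeans[[cond]]),
                   stringsAsFactors = FALSE)))
    }))
    nInt <- nCells * nReplicates
    comp <- sample.int(nrow(intensityMixture), nInt, replace = TRUE,
                       prob = intensityMixture$weight)
    m <- intensityMixture$mean[comp]; s <- intensityMixture$sd[comp]
    u <- runif(nInt, pnorm(0, m, s), 1)
    intensity <- data.frame(
      cell_id = paste0("cell", seq_len(nInt)),
      replicate = paste0("rep", rep(seq_len(nReplicates), each = nCells)),
      intensity = stats::qnorm(u, m, s),
      stringsAsFactors = FALSE
    )
    list(foci = foci, intensity = intensity)
  })
}

#' Tail probability of a truncated normal mixture
#'
#' Closed-form P(X >= threshold) for the intensity model used by
#' [simCellMeasurements()] (each normal component truncated at 0).
#'
#' @param intensityMixture data.frame with weight, mean, sd.
#' @param threshold Non-negative threshold.
#' @return The tail probability.
#' @export
mixtureTailProbability <- function(intensityMixture, threshold = 40) {
  stopifnot(threshold >= 0)
  with(intensityMixture,
       sum(weight * pnorm(threshold, mean, sd, lower.tail = FALSE) /
             pnorm(0, mean, sd, lower.tail = FALSE)))
}
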