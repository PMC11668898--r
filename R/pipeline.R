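## Orchestration: a single YAML (or list) config drives seeded end-to-end
## runs of the synthetic generators and every analysis stage, producing
## per-stage output files, a checksummed file manifest and a human- plus
## machine-readable run report.

#' Default pipeline configuration
#'
#' The full configuration tree with every stage enabled and the package's
#' default parameters. User configs are validated against this tree: unknown
#' keys are rejected.
#'
#' @return Nested list.
#' @export
defaultConfig <- function() {
  list(
    seed = 1L,
    stages = list(
      variants = list(
        enabled = TRUE, n_true = 150L,
        sensitivity = list(mutect = 0.9, strelka = 0.85, lancet = 0.8),
        false_positives = list(mutect = 5L, strelka = 5L, lancet = 5L),
        n_replicates = 3L, min_callers = 2L, min_replicates = 2L
      ),
      signatures = list(
        enabled = TRUE, n_signatures = 6L,
        weights = list(SBSsyn1 = 0.6, SBSsyn2 = 0.4),
        n_mutations = 2000L, weight_cutoff = 0.06, min_mutations = 50L
      ),
      de = list(
        enabled = TRUE, n_genes = 2000L, n_per_group = 3L,
        cell_lines = c("CL1", "CL2", "CL3", "CL4"),
        n_shared_up = 5L, n_shared_down = 13L, log2fc = 2,
        dispersion = 0.05, alpha = 0.05, fc_threshold = 1
      ),
      ora = list(
        enabled = TRUE, n_sets = 25L, set_size = 40L,
        min_size = 20L, fdr_cutoff = 0.1
      ),
      survival = list(
        enabled = TRUE, n_patients = 400L, gene_set_size = 50L,
        log_hr = 0.6931, threshold_quantile = 0.6,
        censoring_fraction = 0.3, min_group_frac = 0.1
      ),
      assays = list(
        enabled = TRUE, b1 = 0.3, b2 = 0.03, pe0 = 0.5,
        doses = c(0, 1, 2, 4, 6, 8), cells_plated = 1000L,
        n_cells = 50L, intensity_threshold = 40
      )
    )
  )
}

mergeConfig <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user) || !is.list(defaults)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  for (k in names(user))
    defaults[[k]] <- mergeConfig(defaults[[k]], user[[k]],
                                 paste0(path, ".", k))
  defaults
}

#' Load and validate a pipeline configuration
#'
#' @param config A YAML file path or a nested list; entries override
#'   [defaultConfig()]. Unknown keys are rejected by name.
#' @return Validated configuration list.
#' @export
loadConfig <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  mergeConfig(defaultConfig(), config)
}

stageSeed <- function(seed, k) (as.integer(seed) * 113L + k * 7919L) %% 2147483647L

#' Run the full synthetic pipeline
#'
#' Executes the enabled stages in dependency order (simulate feeds variants
#' feeds signatures; simulate feeds DE feeds intersection feeds ORA;
#' simulate feeds scoring feeds survival; simulate feeds assay statistics),
#' writes every output as plain text under \code{outDir} and returns a run
#' report listing per-stage summaries, captured warnings, timings and an
#' md5-checksummed file manifest. Two runs with the same config produce
#' identical numerical outputs.
#'
#' @param config YAML path or list, see [loadConfig()].
#' @param outDir Output directory (created if absent).
#' @return The run report (list), invisibly also written via [writeReport()]
#'   when \code{reportPath} is given.
#' @param reportPath Optional path stem for the report files.
#' @export
runPipeline <- function(config = NULL, outDir = tempfile("radresist_run"),
                        reportPath = NULL) {
  cfg <- loadConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  report <- list(seed = seed, config = cfg, stages = list())
  files <- character(0)
  addFile <- function(p) files <<- c(files, p)

  runStage <- function(name, fun) {
    if (!isTRUE(cfg$stages[[name]]$enabled)) return(NULL)
    warnings <- character(0)
    t0 <- proc.time()[["elapsed"]]
    summary <- withCallingHandlers(
      tryCatch(fun(cfg$stages[[name]]),
               error = function(e)
                 stop("stage '", name, "' failed: ", conditionMessage(e),
                      call. = FALSE)),
      warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    summary$warnings <- warnings
    summary$elapsed_s <- round(proc.time()[["elapsed"]] - t0, 3)
    report$stages[[name]] <<- summary
    summary
  }

  ## --- variants: simulate caller tables, consensus, catalogue ---
  consensusCatalogue <- NULL
  runStage("variants", function(p) {
    sim <- simCallerCalls(p$n_true, unlist(p$sensitivity),
                          unlist(p$false_positives), p$n_replicates,
                          seed = stageSeed(seed, 1L))
    callsPath <- file.path(outDir, "variant_calls.tsv")
    writeVariantTable(sim$calls, callsPath); addFile(callsPath)
    truthPath <- file.path(outDir, "variant_truth.tsv")
    write.table(sim$truth, truthPath, sep = "\t", quote = FALSE,
                row.names = FALSE); addFile(truthPath)
    cons <- consensusFilter(sim$calls, p$min_callers, p$min_replicates)
    consPath <- file.path(outDir, "consensus_variants.tsv")
    flat <- cons[, c("chrom", "pos", "ref", "alt", "n_supporting_replicates")]
    flat$callers_by_replicate <- vapply(cons$callers_by_replicate, function(x)
      paste(names(x), vapply(x, paste, character(1), collapse = ","),
            sep = ":", collapse = ";"), character(1))
    write.table(flat, consPath, sep = "\t", quote = FALSE, row.names = FALSE)
    addFile(consPath)
    ctx <- setNames(sim$calls$context, variantKey(sim$calls))
    cat96 <- build96Catalogue(cons, ctx)
    catPath <- file.path(outDir, "consensus_catalogue.tsv")
    writeCatalogue(cat96, catPath); addFile(catPath)
    consensusCatalogue <<- cat96
    effects <- countByEffect(cons, sim$calls)
    trueKeys <- paste(sim$truth$chrom, sim$truth$pos, sim$truth$ref,
                      sim$truth$alt, sep = ":")
    consKeys <- variantKey(cons)
    list(n_calls = nrow(sim$calls), n_consensus = nrow(cons),
         n_true = p$n_true,
         recall = mean(trueKeys %in% consKeys),
         precision = if (nrow(cons)) mean(consKeys %in% trueKeys) else NA,
         effects = as.list(effects))
  })

  ## --- signatures: mixture catalogue refit (+ consensus catalogue fit) ---
  runStage("signatures", function(p) {
    sigs <- simSignatureMatrix(p$n_signatures, seed = stageSeed(seed, 2L))
    sigPath <- file.path(outDir, "signature_matrix.tsv")
    writeSignatureMatrix(sigs, sigPath); addFile(sigPath)
    w <- unlist(p$weights)
    catal <- simCatalogue(w, p$n_mutations, sigs, seed = stageSeed(seed, 3L))
    fit <- applyOverfitGuard(
      refitSignatures(catal, sigs, weightCutoff = p$weight_cutoff),
      p$min_mutations)
    expPath <- file.path(outDir, "signature_exposure")
    addFile(writeExposure(fit, expPath))
    out <- list(true_weights = as.list(w),
                fitted_weights = as.list(signatureWeights(fit)),
                residual_sse = residualSse(fit),
                flagged_overfit = isOverfitFlagged(fit))
    if (!is.null(consensusCatalogue) && totalMutations(consensusCatalogue) > 0) {
      consFit <- applyOverfitGuard(
        refitSignatures(consensusCatalogue, sigs,
                        weightCutoff = p$weight_cutoff), p$min_mutations)
      out$consensus_catalogue_fit <- list(
        weights = as.list(signatureWeights(consFit)),
        flagged_overfit = isOverfitFlagged(consFit))
    }
    out
  })

  ## --- differential expression + intersection (+ ORA downstream) ---
  commonDegs <- NULL; deUniverse <- NULL; deCfg <- cfg$stages$de
  runStage("de", function(p) {
    nUp <- p$n_shared_up; nDown <- p$n_shared_down
    planted <- data.frame(
      gene = paste0("G", seq_len(nUp + nDown)),
      log2fc = c(rep(p$log2fc, nUp), rep(-p$log2fc, nDown)),
      shared = TRUE, stringsAsFactors = FALSE)
    sim <- simCounts(p$n_genes, p$n_per_group, p$cell_lines, planted,
                     p$dispersion, seed = stageSeed(seed, 4L))
    degSets <- list()
    for (cl in p$cell_lines) {
      res <- nbWaldDE(sim$counts[[cl]], sim$colData[[cl]], cl)
      dePath <- file.path(outDir, paste0("de_", cl, ".tsv"))
      write.table(res, dePath, sep = "\t", quote = FALSE, row.names = FALSE)
      addFile(dePath)
      degSets[[cl]] <- selectDegs(res, p$alpha)
    }
    common <- intersectCommonDegs(degSets, fcThreshold = p$fc_threshold)
    commonPath <- file.path(outDir, "common_degs.tsv")
    write.table(common$genes, commonPath, sep = "\t", quote = FALSE,
                row.names = FALSE); addFile(commonPath)
    commonDegs <<- common
    deUniverse <<- rownames(sim$counts[[1L]])
    recovered <- intersect(common$genes$gene, planted$gene)
    list(n_planted = nrow(planted),
         n_common = nrow(common$genes),
         n_up = common$n_up, n_down = common$n_down,
         frac_large_fc = common$frac_large_fc,
         planted_recovery = length(recovered) / nrow(planted))
  })

  ## --- over-representation of the common DEGs ---
  runStage("ora", function(p) {
    if (is.null(commonDegs)) stop("requires the de stage")
    selected <- commonDegs$genes$gene
    gs <- withSeed(stageSeed(seed, 5L), {
      sets <- lapply(seq_len(p$n_sets), function(i)
        sample(deUniverse, p$set_size))
      names(sets) <- paste0("SET", seq_len(p$n_sets))
      sets$SET_planted <- unique(c(selected,
                                   sample(deUniverse, p$set_size)))[
                                     seq_len(max(p$set_size, length(selected)))]
      sets
    })
    gmtPath <- file.path(outDir, "gene_sets.gmt")
    writeGmt(gs, gmtPath); addFile(gmtPath)
    ora <- oraEnrich(selected, deUniverse, gs, p$min_size, p$fdr_cutoff)
    oraPath <- file.path(outDir, "ora_results.tsv")
    write.table(ora, oraPath, sep = "\t", quote = FALSE, row.names = FALSE)
    addFile(oraPath)
    list(n_tested = nrow(ora), n_significant = sum(ora$significant),
         top_term = if (nrow(ora)) ora$term[1L] else NA,
         top_rich_factor = if (nrow(ora)) ora$rich_factor[1L] else NA)
  })

  ## --- cohort scoring + survival stratification ---
  runStage("survival", function(p) {
    gset <- paste0("HET", seq_len(p$gene_set_size))
    sim <- simCohort(p$n_patients, gset, p$log_hr, p$threshold_quantile,
                     p$censoring_fraction, seed = stageSeed(seed, 6L))
    exprPath <- file.path(outDir, "cohort_expression.tsv")
    writeExpressionMatrix(sim$expr, exprPath); addFile(exprPath)
    clinPath <- file.path(outDir, "cohort_clinical.tsv")
    writeClinicalTable(sim$clinical, clinPath); addFile(clinPath)
    scan <- scanCutoffs(sim$clinical, p$min_group_frac)
    sel <- selectedCutoff(scan)
    high <- sim$clinical$score > sel$threshold
    cox <- coxFit(sim$clinical, as.numeric(high))
    scanPath <- file.path(outDir, "cutoff_scan.tsv")
    write.table(scanCandidates(scan), scanPath, sep = "\t", quote = FALSE,
                row.names = FALSE); addFile(scanPath)
    km <- kmEstimate(sim$clinical)
    kmPath <- file.path(outDir, "km_curve.tsv")
    write.table(km, kmPath, sep = "\t", quote = FALSE, row.names = FALSE)
    addFile(kmPath)
    list(selected_scheme = sel$scheme, selected_level = sel$level,
         selected_threshold = sel$threshold,
         selected_logrank_p = sel$logrank_p,
         true_threshold = sim$truth$threshold,
         hr = cox$hr, hr_ci95 = cox$ci95, cox_converged = cox$converged,
         median_followup = reverseKmFollowup(sim$clinical))
  })

  ## --- radiobiology assay statistics ---
  runStage("assays", function(p) {
    colonies <- simClonogenic(p$b1, p$b2, p$pe0, p$doses, p$cells_plated,
                              seed = stageSeed(seed, 7L))
    colPath <- file.path(outDir, "colonies.csv")
    write.csv(colonies, colPath, row.names = FALSE); addFile(colPath)
    lq <- fitClonogenic(survivingFractions(colonies))
    cells <- simCellMeasurements(p$n_cells, seed = stageSeed(seed, 8L))
    fociPath <- file.path(outDir, "foci.csv")
    write.csv(cells$foci, fociPath, row.names = FALSE); addFile(fociPath)
    intPath <- file.path(outDir, "intensity.csv")
    write.csv(cells$intensity, intPath, row.names = FALSE); addFile(intPath)
    foci <- fociSummary(cells$foci, "irradiated", "control",
                        minCells = p$n_cells)
    kde <- intensityKdeAuc(cells$intensity$intensity, p$intensity_threshold)
    qpcr <- withSeed(stageSeed(seed, 9L), data.frame(
      sample = rep(paste0("s", 1:6), each = 2),
      gene = rep(c("TARGET", "REF"), 6),
      ct = c(rbind(25 + rep(c(0, -1), each = 3) + rnorm(6, 0, 0.05),
                   20 + rnorm(6, 0, 0.05))),
      is_control_condition = rep(rep(c(TRUE, FALSE), each = 3), each = 2),
      stringsAsFactors = FALSE))
    qpcrPath <- file.path(outDir, "qpcr.csv")
    write.csv(qpcr, qpcrPath, row.names = FALSE); addFile(qpcrPath)
    fc <- ddctFoldChange(qpcr, "TARGET", "REF")
    list(lq = as.list(lqCoefficients(lq)), lq_truth = attr(colonies, "truth"),
         foci_mean_a = foci$mean_a, foci_mean_b = foci$mean_b,
         foci_p = foci$p,
         kde_auc_above = aucAbove(kde),
         mean_treated_fold_change = mean(fc$fold_change[!fc$is_control_condition]))
  })

  report$files <- data.frame(
    path = files, md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(reportPath)) writeReport(report, reportPath)
  report
}

#' Write a run report
#'
#' Writes the machine-readable JSON twin (\code{<path>.json}) and a
#' human-readable text summary (\code{<path>.txt}).
#'
#' @param report Report list from [runPipeline()].
#' @param path Path stem.
#' @return The two paths, invisibly.
#' @export
writeReport <- function(report, path) {
  json <- paste0(path, ".json"); txt <- paste0(path, ".txt")
  jsonlite::write_json(report, json, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  con <- file(txt, "w"); on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("radresist run report")
  w("seed: ", report$seed)
  for (s in names(report$stages)) {
    st <- report$stages[[s]]
    w("\n== stage: ", s, " (", st$elapsed_s, " s) ==")
    for (k in setdiff(names(st), c("warnings", "elapsed_s")))
      w("  ", k, ": ", paste(utils::capture.output(str(st[[k]],
        give.attr = FALSE, vec.len = 8)), collapse = " "))
    if (length(st$warnings))
      w("  warnings: ", paste(st$warnings, collapse = " | "))
  }
  w("\n== files ==")
  if (!is.null(report$files))
    for (i in seq_len(nrow(report$files)))
      w("  ", report$files$md5[i], "  ", report$files$path[i])
  invisible(c(json, txt))
}
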