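test_that("caller simulation honours degenerate sensitivity and FP settings", {
  sens1 <- c(m = 1, s = 1, l = 1)
  sim <- simCallerCalls(10, sens1, c(m = 0, s = 0, l = 0), 3, seed = 1)
  perTable <- table(sim$calls$caller_id, sim$calls$replicate_id)
  expect_true(all(perTable == 10))
  expect_equal(nrow(sim$truth), 10L)

  sim0 <- simCallerCalls(10, c(m = 0, s = 0, l = 0), c(m = 5, s = 5, l = 5),
                         3, seed = 2)
  expect_equal(nrow(sim0$calls), 45L)
  trueKeys <- paste(sim0$truth$chrom, sim0$truth$pos)
  expect_false(any(paste(sim0$calls$chrom, sim0$calls$pos) %in% trueKeys))
  expect_error(simCallerCalls(0, sens1, c(m = 0, s = 0, l = 0)), "positive")
})

test_that("generators are pure functions of parameters and seed", {
  a <- simCallerCalls(20, c(m = 0.8, s = 0.7), c(m = 3, s = 2), seed = 7)
  b <- simCallerCalls(20, c(m = 0.8, s = 0.7), c(m = 3, s = 2), seed = 7)
  expect_identical(a, b)
  sigs <- simSignatureMatrix(4, seed = 3)
  expect_identical(simCatalogue(c(SBSsyn1 = 1), 100, sigs, seed = 4),
                   simCatalogue(c(SBSsyn1 = 1), 100, sigs, seed = 4))
  expect_identical(simCounts(100, 2, "A", seed = 5),
                   simCounts(100, 2, "A", seed = 5))
  expect_identical(simCohort(30, paste0("g", 1:5), seed = 6),
                   simCohort(30, paste0("g", 1:5), seed = 6))
  expect_identical(simClonogenic(seed = 8), simClonogenic(seed = 8))
  expect_identical(simCellMeasurements(seed = 9),
                   simCellMeasurements(seed = 9))
  # and the global RNG stream is left untouched
  set.seed(123); before <- .Random.seed
  invisible(simCounts(50, 2, "A", seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("catalogue simulation draws from the stated mixture", {
  sigs <- simSignatureMatrix(4, seed = 10)
  cat96 <- simCatalogue(c(SBSsyn2 = 1), 100000, sigs, seed = 11)
  spec <- catalogueCounts(cat96) / totalMutations(cat96)
  expect_lt(max(abs(spec - sigs[, "SBSsyn2"])), 0.01)
  expect_equal(totalMutations(simCatalogue(c(SBSsyn1 = 1), 0, sigs, 1)), 0)
  expect_error(simCatalogue(c(SBSsyn1 = 0.5), 10, sigs, 1), "sum to 1")
  expect_error(simCatalogue(c(nope = 1), 10, sigs, 1), "unknown")
})

test_that("count simulation plants shared and line-specific effects as declared", {
  planted <- data.frame(gene = c("G1", "G2", "G3"),
                        log2fc = c(2, -2, 2),
                        shared = c(TRUE, TRUE, FALSE),
                        cell_line = c(NA, NA, "B"))
  sim <- simCounts(200, 20, c("A", "B"), planted, 0.05, seed = 12)
  for (cl in c("A", "B")) {
    cnt <- sim$counts[[cl]]
    ph <- sim$colData[[cl]]$phenotype
    ratio <- rowMeans(cnt[, ph == "RR"]) / rowMeans(cnt[, ph == "WT"])
    expect_gt(ratio["G1"], 2.5); expect_lt(ratio["G2"], 0.4)
    if (cl == "B") expect_gt(ratio["G3"], 2.5) else
      expect_lt(abs(log2(ratio["G3"])), 0.8)
  }
  expect_error(simCounts(100, 1, "A"), "at least 2")
  expect_error(simCounts(100, 3, "A", data.frame(gene = "NOPE", log2fc = 1,
                                                 shared = TRUE)), "universe")
})

test_that("cohort simulation ties hazard to the score threshold and censors as asked", {
  sim <- simCohort(200, paste0("g", 1:20), logHr = log(3),
                   thresholdQuantile = 0.5, censoringFraction = 0,
                   seed = 13)
  expect_true(all(sim$clinical$event == 1))
  high <- sim$clinical$score > sim$truth$threshold
  expect_lt(median(sim$clinical$time[high]), median(sim$clinical$time[!high]))
  cens <- simCohort(300, paste0("g", 1:20), censoringFraction = 0.4, seed = 14)
  expect_equal(mean(cens$clinical$event == 0), 0.4, tolerance = 0.08)
  expect_error(simCohort(10, "g1"), "at least 20")
  expect_error(simCohort(30, character(0)), "empty")
})

test_that("null cohorts give nominal log-rank rejection at a fixed median split", {
  rej <- vapply(1:200, function(s) {
    sim <- simCohort(60, paste0("g", 1:10), logHr = 0, seed = 900 + s)
    cl <- sim$clinical
    high <- cl$score > median(cl$score)
    logrankTest(list(cl[high, ], cl[!high, ]))$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.01); expect_lt(mean(rej), 0.1)
})

test_that("clonogenic generator matches its expectations and rejects bad input", {
  col <- simClonogenic(b1 = 0, b2 = 0, pe0 = 0.4, doses = c(0, 2, 4),
                       poisson = FALSE, seed = 15)
  expect_true(all(col$colonies == 1000 * 0.4))
  expect_error(simClonogenic(doses = c(-1, 2)), "non-negative")
  expect_error(simClonogenic(pe0 = 0), "\\(0, 1\\]")
})

test_that("intensity mixture respects truncation and its tail formula", {
  narrow <- data.frame(weight = 1, mean = 20, sd = 3)
  cm <- simCellMeasurements(nCells = 2000, intensityMixture = narrow,
                            nReplicates = 1, seed = 16)
  expect_true(all(cm$intensity$intensity >= 0))
  expect_lt(mean(cm$intensity$intensity >= 40), 0.001)
  expect_equal(mixtureTailProbability(narrow, 40),
               pnorm(40, 20, 3, lower.tail = FALSE) /
                 pnorm(0, 20, 3, lower.tail = FALSE))
  mix <- data.frame(weight = c(0.5, 0.5), mean = c(25, 50), sd = c(6, 8))
  cm2 <- simCellMeasurements(nCells = 20000, intensityMixture = mix,
                             nReplicates = 1, seed = 17)
  expect_equal(mean(cm2$intensity$intensity >= 40),
               mixtureTailProbability(mix, 40), tolerance = 0.01)
  expect_error(simCellMeasurements(0), "at least 1")
  expect_error(simCellMeasurements(10, intensityMixture = data.frame(
    weight = c(0.6, 0.6), mean = c(1, 2), sd = c(1, 1))), "sum to 1")
})
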