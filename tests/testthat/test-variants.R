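test_that("variant reader keeps SNVs, skips indels/MNVs, validates columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(sample_id = "s1", replicate_id = "rep1", caller_id = "m",
                   chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
                   ref = c("A", "AT", "C", "G"), alt = c("G", "A", "T", "GA"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  suppressMessages(calls <- readVariantTable(path))
  expect_equal(nrow(calls), 2L)
  expect_equal(attr(calls, "skipped"), 2L)

  bad <- df[, setdiff(names(df), "pos")]
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readVariantTable(path), "pos")
})

test_that("consensus rule keeps >=2 callers in >=2 replicates and drops the rest", {
  mk <- function(rep, caller) data.frame(
    sample_id = "s1", replicate_id = rep, caller_id = caller,
    chrom = "chr1", pos = 100L, ref = "C", alt = "T")
  # two callers in two replicates: retained
  kept <- consensusFilter(rbind(mk("r1", "M"), mk("r1", "S"),
                                mk("r2", "M"), mk("r2", "S")))
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$n_supporting_replicates, 2L)
  # all three callers but a single replicate: dropped
  dropped <- consensusFilter(rbind(mk("r1", "M"), mk("r1", "S"), mk("r1", "L")))
  expect_equal(nrow(dropped), 0L)
  # mixed samples rejected
  two <- rbind(mk("r1", "M"), mk("r1", "S"))
  two$sample_id <- c("s1", "s2")
  expect_error(consensusFilter(two), "single sample")
})

test_that("consensus matches brute-force enumeration on random call sets", {
  for (seed in 1:100) {
    calls <- randomCallTable(nVariants = sample(3:50, 1), seed = seed)
    if (is.null(calls)) next
    got <- consensusFilter(calls)
    gotKeys <- sort(paste(got$chrom, got$pos, got$ref, got$alt, sep = ":"))
    expect_identical(gotKeys, bruteForceConsensus(calls), info = paste("seed", seed))
  }
})

test_that("raising vote thresholds never grows the consensus set", {
  calls <- randomCallTable(40, seed = 7)
  keysOf <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
  base <- keysOf(consensusFilter(calls, 2, 2))
  expect_true(all(keysOf(consensusFilter(calls, 3, 2)) %in% base))
  expect_true(all(keysOf(consensusFilter(calls, 2, 3)) %in% base))
  expect_true(all(base %in% unique(keysOf(calls))))
})

test_that("same-callers consensus mode is at least as strict as per-replicate", {
  for (seed in 11:20) {
    calls <- randomCallTable(20, seed = seed)
    if (is.null(calls)) next
    keysOf <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
    perRep <- keysOf(consensusFilter(calls, mode = "per_replicate"))
    samePair <- keysOf(consensusFilter(calls, mode = "same_callers"))
    expect_true(all(samePair %in% perRep))
  }
})

test_that("effect counts partition the consensus total with majority voting", {
  mk <- function(pos, rep, caller, effect) data.frame(
    sample_id = "s1", replicate_id = rep, caller_id = caller,
    chrom = "chr1", pos = pos, ref = "C", alt = "T", effect = effect)
  calls <- rbind(
    mk(1, "r1", "M", "synonymous"), mk(1, "r1", "S", "synonymous"),
    mk(1, "r2", "M", "non_synonymous"), mk(1, "r2", "S", "synonymous"),
    mk(2, "r1", "M", "non_synonymous"), mk(2, "r1", "S", "synonymous"),
    mk(2, "r2", "M", "non_synonymous"), mk(2, "r2", "S", "synonymous"))
  cons <- consensusFilter(calls)
  counts <- countByEffect(cons, calls)
  expect_equal(unname(counts["synonymous"]), 1)     # 3-1 majority at pos 1
  expect_equal(unname(counts["other"]), 1)          # 2-2 tie at pos 2
  expect_equal(unname(counts["total"]), 2)
  expect_equal(sum(counts[c("synonymous", "non_synonymous", "other")]),
               unname(counts["total"]))
  empty <- consensusFilter(calls[0, ])
  expect_true(all(countByEffect(empty, calls) == 0))
})

test_that("96-context binning uses the pyrimidine strand and matches the naive oracle", {
  cons <- data.frame(chrom = "chr1", pos = c(1L, 2L), ref = c("C", "G"),
                     alt = c("T", "A"), context = c("ACA", "TGT"))
  cat96 <- build96Catalogue(cons)
  cnt <- catalogueCounts(cat96)
  expect_equal(unname(cnt["A[C>T]A"]), 2)  # G>A in TGT reverse-complements here
  expect_equal(totalMutations(cat96), 2)

  set.seed(3)
  n <- 200
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  ctx <- paste0(sample(c("A", "C", "G", "T"), n, TRUE), ref,
                sample(c("A", "C", "G", "T"), n, TRUE))
  cons <- data.frame(chrom = "chr1", pos = seq_len(n), ref = ref, alt = alt,
                     context = ctx)
  cat96 <- build96Catalogue(cons)
  expect_equal(totalMutations(cat96), n)
  oracle <- table(factor(mapply(naiveBinLabel, ref, alt, ctx),
                         levels = cosmicContexts()))
  expect_equal(unname(catalogueCounts(cat96)), as.numeric(oracle))

  bad <- data.frame(chrom = "chr1", pos = 1L, ref = "C", alt = "T",
                    context = "AAA")
  expect_error(build96Catalogue(bad), "middle base")
})

test_that("catalogue TSV round-trips", {
  cat96 <- simCatalogue(c(SBSsyn1 = 1), 500, simSignatureMatrix(2, seed = 1),
                        seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeCatalogue(cat96, path)
  expect_equal(catalogueCounts(readCatalogue(path)), catalogueCounts(cat96))
})
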