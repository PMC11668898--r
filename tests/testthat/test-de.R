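makeSim <- function(planted = NULL, nGenes = 800, seed = 1, lines = "CL1") {
  simCounts(nGenes, 3, lines, planted, 0.05, seed = seed)
}

test_that("flat genes give near-zero fold change and large p", {
  sim <- makeSim(seed = 2)
  res <- nbWaldDE(sim$counts$CL1, sim$colData$CL1)
  expect_true(all(c("gene", "log2fc", "p", "p_adj") %in% names(res)))
  expect_true(all(res$p_adj >= res$p - 1e-12))
  expect_lt(median(abs(res$log2fc)), 0.3)
  expect_gt(median(res$p), 0.2)
  # identical counts in both groups: fold change ~0 (exactly 0 up to the
  # per-sample size-factor normalisation), p near 1
  cnt <- sim$counts$CL1
  cnt["G1", ] <- rep(c(40L, 55L, 70L), 2)
  res1 <- nbWaldDE(cnt, sim$colData$CL1)
  expect_lt(abs(res1$log2fc[res1$gene == "G1"]), 0.05)
  expect_gt(res1$p[res1$gene == "G1"], 0.9)
})

test_that("a planted 4-fold gene is detected in most seeds", {
  planted <- data.frame(gene = "G10", log2fc = 2, shared = TRUE)
  hits <- vapply(1:20, function(s) {
    sim <- makeSim(planted, nGenes = 500, seed = s)
    res <- nbWaldDE(sim$counts$CL1, sim$colData$CL1)
    res$p_adj[res$gene == "G10"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("selection respects the strict adjusted-p boundary and fold-change sign", {
  res <- data.frame(gene = paste0("g", 1:5),
                    log2fc = c(1, -2, 0.5, 0, -1),
                    p = c(0.001, 0.002, 0.01, 0.001, 0.04),
                    p_adj = c(0.049, 0.05, 0.02, 0.01, 0.2))
  sel <- selectDegs(res)
  expect_setequal(sel$gene, c("g1", "g3"))   # 0.05 excluded; lfc 0 excluded
  expect_equal(sel$direction[sel$gene == "g1"], "up")
  expect_equal(nrow(selectDegs(res[0, ])), 0L)
})

test_that("BH adjustment matches the hand computation on four p-values", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  sim <- makeSim(seed = 3, nGenes = 300)
  res <- nbWaldDE(sim$counts$CL1, sim$colData$CL1)
  expect_equal(res$p_adj, p.adjust(res$p, "BH"))
})

test_that("direction conflicts are removed from the common DEG intersection", {
  A <- data.frame(gene = c("g1", "g2"), direction = c("up", "down"),
                  log2fc = c(1.2, -2))
  B <- data.frame(gene = c("g1", "g2"), direction = c("up", "up"),
                  log2fc = c(2.1, 1))
  common <- intersectCommonDegs(list(a = A, b = B))
  expect_equal(common$genes$gene, "g1")
  expect_equal(common$n_up, 1)
  expect_equal(common$n_down, 0)
  expect_equal(common$frac_large_fc, 1)  # both |log2fc| > 1
  expect_error(intersectCommonDegs(list(a = A, b = B), scope = character(0)),
               "scope")
})

test_that("intersection is invariant to input and scope order", {
  planted <- data.frame(gene = paste0("G", 1:6),
                        log2fc = c(2, 2, -2, -2, -2, -2), shared = TRUE)
  sim <- simCounts(600, 3, c("A", "B", "C"), planted, 0.05, seed = 4)
  degs <- lapply(c("A", "B", "C"), function(cl)
    selectDegs(nbWaldDE(sim$counts[[cl]], sim$colData[[cl]], cl)))
  names(degs) <- c("A", "B", "C")
  g1 <- intersectCommonDegs(degs, scope = c("A", "B", "C"))$genes$gene
  g2 <- intersectCommonDegs(rev(degs), scope = c("C", "A", "B"))$genes$gene
  expect_setequal(g1, g2)
})

test_that("under a global null almost no gene passes the adjusted threshold", {
  fps <- vapply(1:20, function(s) {
    sim <- simCounts(1000, 3, "CL1", NULL, 0.05, seed = 400 + s)
    res <- nbWaldDE(sim$counts$CL1, sim$colData$CL1)
    mean(res$p_adj < 0.05)
  }, numeric(1))
  expect_lt(mean(fps), 0.005)
})

test_that("hypergeometric ORA matches exact enumeration and applies the size filter", {
  # closed-case check: N=100, K=20, n=10, k=5
  expect_equal(phyper(4, 20, 80, 10, lower.tail = FALSE),
               enumHyperTail(5, 20, 100, 10), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:25) {
    N <- sample(10:30, 1)
    universe <- paste0("g", seq_len(N))
    K <- sample(2:N, 1)
    n <- sample(1:N, 1)
    term <- sample(universe, K)
    selected <- sample(universe, n)
    ora <- oraEnrich(selected, universe, setNames(list(term), "T1"),
                     minSize = 1)
    k <- length(intersect(selected, term))
    expect_equal(ora$p, enumHyperTail(k, K, N, n), tolerance = 1e-12)
    expect_equal(ora$rich_factor, k / K)
  }
  # terms below the minimum listed size are not tested
  universe <- paste0("g", 1:100)
  sets <- list(small = universe[1:19], big = universe[1:20])
  ora <- oraEnrich(universe[1:10], universe, sets, minSize = 20)
  expect_equal(ora$term, "big")
  expect_error(oraEnrich("g1", character(0), sets), "universe")
})

test_that("rich factor uses the full listed term size", {
  universe <- paste0("u", 1:50)
  term <- c(universe[1:10], paste0("x", 1:10))   # 20 listed, 10 in universe
  ora <- oraEnrich(universe[1:5], universe, list(T = term), minSize = 20)
  expect_equal(ora$K_listed, 20)
  expect_equal(ora$K, 10)
  expect_equal(ora$rich_factor, ora$k / 20)
})

test_that("counts matrices and DE tables round-trip through their readers", {
  sim <- makeSim(seed = 6, nGenes = 50)
  cp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  writeCountsMatrix(sim$counts$CL1, sim$colData$CL1, cp, mp)
  back <- readCountsMatrix(cp, mp)
  expect_equal(back$counts, sim$counts$CL1)
  expect_equal(back$colData, sim$colData$CL1)

  res <- nbWaldDE(sim$counts$CL1, sim$colData$CL1)
  dp <- withr::local_tempfile(fileext = ".tsv")
  write.table(res, dp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(readDeTable(dp)$p_adj, res$p_adj, tolerance = 1e-12)
})

test_that("the simplified NB Wald engine agrees with DESeq2 on effect direction and ranking", {
  planted <- data.frame(gene = paste0("G", 1:8),
                        log2fc = c(2, 2, 2, 2, -2, -2, -2, -2), shared = TRUE)
  sim <- makeSim(planted, nGenes = 300, seed = 8)
  mine <- nbWaldDE(sim$counts$CL1, sim$colData$CL1)
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      sim$counts$CL1,
      S4Vectors::DataFrame(condition = factor(sim$colData$CL1$phenotype,
                                              levels = c("WT", "RR"))),
      ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- as.data.frame(DESeq2::results(dds))
  })
  shared <- intersect(mine$gene, rownames(ref))
  m <- mine[match(shared, mine$gene), ]
  r <- ref[shared, ]
  expect_gt(cor(m$log2fc, r$log2FoldChange, use = "complete.obs"), 0.9)
  planted_sig_mine <- mine$gene[mine$p_adj < 0.05]
  planted_sig_ref <- rownames(ref)[!is.na(ref$padj) & ref$padj < 0.05]
  expect_true(all(planted$gene %in% planted_sig_mine))
  expect_gt(length(intersect(planted_sig_mine, planted_sig_ref)) /
              max(1, length(planted_sig_mine)), 0.7)
})
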