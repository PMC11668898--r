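test_that("plating efficiency and surviving fractions follow their definitions", {
  rec <- data.frame(arm = "A", dose = c(0, 0, 2, 2),
                    cells_plated = c(500, 500, 1000, 1000),
                    colonies = c(50, 50, 50, 50),
                    replicate = c("r1", "r2", "r1", "r2"))
  res <- survivingFractions(rec)
  expect_equal(res@pe$pe, c(0.1, 0.1, 0.05, 0.05))
  sf <- survivingFractionTable(res)
  expect_equal(sf$sf[sf$dose == 0], 1)
  expect_equal(sf$sf[sf$dose == 2], 0.5)
  zero <- rec; zero$colonies[zero$dose == 0] <- 0
  expect_error(survivingFractions(zero), "zero")
  over <- rec; over$colonies[1] <- 600
  expect_warning(survivingFractions(over), "above 1")
})

test_that("LQ fit is exact on noiseless data and handles degenerate inputs", {
  d <- c(1, 2, 4)
  sf <- exp(-(0.3 * d + 0.03 * d^2))
  fit <- fitLQ(d, sf)
  expect_equal(fit$b1, 0.3, tolerance = 1e-12)
  expect_equal(fit$b2, 0.03, tolerance = 1e-12)
  expect_false(fit$clamped)
  flat <- fitLQ(c(1, 2, 4), c(1, 1, 1))
  expect_equal(flat$b1, 0)
  expect_equal(flat$b2, 0)
  expect_error(fitLQ(c(0, 2), c(1, 0.5)), "two distinct nonzero")
  expect_error(fitLQ(c(1, 2), c(1.2, 0.5)), "\\(0, 1\\]")
  # variance-free generator feeds an exact recovery
  col <- simClonogenic(b1 = 0.3, b2 = 0.03, poisson = FALSE, seed = 1)
  lq <- lqCoefficients(fitClonogenic(survivingFractions(col)))
  expect_equal(unname(lq), c(0.3, 0.03), tolerance = 1e-10)
})

test_that("Poisson-noised LQ recovery keeps the median b1 error under 15%", {
  relerr <- vapply(1:100, function(s) {
    col <- simClonogenic(seed = s)
    lq <- lqCoefficients(fitClonogenic(survivingFractions(col)))
    abs(lq[["b1"]] - 0.3) / 0.3
  }, numeric(1))
  expect_lt(median(relerr), 0.15)
})

test_that("surviving-fraction ratios divide the right arms", {
  rec <- function(arm, sf2) data.frame(
    arm = arm, dose = c(0, 2), cells_plated = 1000,
    colonies = c(100, 100 * sf2), replicate = "r1")
  a <- survivingFractions(rec("a", 0.2))
  b <- survivingFractions(rec("b", 0.4))
  expect_equal(sfRatio(a, b, 2), 0.5)
  expect_equal(sfRatio(a, a, 2), 1)
  expect_error(sfRatio(a, b, 9), "absent")
})

test_that("foci summary pairs replicate means and flags degenerate differences", {
  cells <- simCellMeasurements(nCells = 50, seed = 40)
  res <- fociSummary(cells$foci, "irradiated", "control")
  expect_gt(res$mean_a, res$mean_b)
  expect_length(res$replicate_means_a, 3L)
  expect_lt(res$p, 1)
  # paired t-test on per-replicate means, verified against stats::t.test
  expect_equal(res$p,
               t.test(res$replicate_means_a, res$replicate_means_b,
                      paired = TRUE)$p.value)
  # zero-variance differences are an error, not a silent p-value
  degen <- data.frame(
    cell_id = 1:12, condition = rep(c("a", "b"), each = 6),
    replicate = rep(rep(c("r1", "r2", "r3"), each = 2), 2),
    foci = rep(c(2, 1), each = 6))
  expect_error(fociSummary(degen, "a", "b", minCells = 1), "zero variance")
})

test_that("irradiated versus control foci differ significantly in most seeds", {
  hits <- vapply(1:40, function(s) {
    cells <- simCellMeasurements(nCells = 50, seed = 500 + s)
    fociSummary(cells$foci, "irradiated", "control")$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("KDE tail mass behaves at the extremes and partitions to one", {
  set.seed(41)
  low <- rnorm(400, 8, 1)
  resLow <- suppressWarnings(intensityKdeAuc(low, threshold = 40))
  expect_lt(aucAbove(resLow), 0.01)
  sym <- rnorm(5000, 40, 5)
  resSym <- intensityKdeAuc(sym, threshold = 40)
  expect_equal(aucAbove(resSym), 0.5, tolerance = 0.02)
  for (s in 1:5) {
    x <- rgamma(300, shape = 4, scale = 10)
    res <- suppressWarnings(intensityKdeAuc(x, threshold = 40))
    g <- res@grid; f <- res@density
    total <- sum((f[-1] + f[-length(f)]) / 2 * diff(g))
    expect_equal(total, 1, tolerance = 1e-3)
    expect_true(all(f >= 0))
    expect_gte(aucAbove(res), 0); expect_lte(aucAbove(res), 1)
  }
  expect_error(intensityKdeAuc(rep(5, 10)), "distinct")
})

test_that("delta-delta-Ct fold changes follow the 2^-ddCt arithmetic", {
  mk <- function(sample, ctT, ctR, ctrl) data.frame(
    sample = sample, gene = c("T", "R"), ct = c(ctT, ctR),
    is_control_condition = ctrl)
  rec <- rbind(mk("c1", 25, 20, TRUE), mk("t1", 24, 20, FALSE),
               mk("t2", 27, 20, FALSE))
  fc <- ddctFoldChange(rec, "T", "R")
  expect_equal(fc$fold_change[fc$sample == "c1"], 1)
  expect_equal(fc$fold_change[fc$sample == "t1"], 2)   # ddCt = -1
  expect_equal(fc$fold_change[fc$sample == "t2"], 0.25) # ddCt = +2
  expect_error(ddctFoldChange(rec[rec$gene != "R", ], "T", "R"), "missing Ct")
  # monotone: fold change strictly decreasing in ddCt
  expect_true(all(diff(fc$fold_change[order(fc$delta_delta_ct)]) < 0))
})
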