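# radresist

Statistical pipeline for comparative radioresistance studies of paired
tumour cell models, for researchers who derive radioresistant (RR) cell
lines from parental wild-type (WT) lines by fractionated irradiation and
want to (i) characterise the acquired genomic and transcriptomic changes,
(ii) distil them into a gene-set activity score, and (iii) test that score
against patient survival after radiotherapy — together with the standard
radiobiology bench statistics.

## What it computes

* **Consensus somatic SNVs** across multiple callers and replicates: a site
  counts as a variant when ≥ 2 distinct callers report it within a
  replicate, in ≥ 2 replicates; consensus SNVs are binned into the 96
  pyrimidine-centred trinucleotide classes of a mutation catalogue.
* **Signature refitting**: the catalogue spectrum *p* is explained as a
  sparse non-negative mixture *Sw* of reference substitution signatures by
  greedy forward selection with a 0.06 weight cutoff and a capped-simplex
  least-squares refit (*w* ≥ 0, Σ*w* ≤ 1); catalogues with fewer than 50
  mutations are pruned to their dominant signature and flagged (overfit
  guard).
* **Differential expression and intersection**: a simplified NB Wald test
  per cell line (median-of-ratios size factors, moderated method-of-moments
  dispersion, BH adjustment), then the direction-consistent intersection of
  DEGs across all cell lines, and hypergeometric over-representation
  analysis with rich factors (k / listed term size).
* **ssGSEA**: per-sample enrichment score
  ES = Σᵢ [P_in^w(i) − P_out(i)] with rank^α weighting (α = 0.25),
  range-normalised across samples.
* **Survival stratification**: Kaplan-Meier, reverse-KM median follow-up,
  log-rank, Cox PH (Efron ties) via the `survival` package, plus a stepwise
  quantile cutoff scan (median/tertile/quartile/quintile interior
  quantiles, minimum unadjusted log-rank p) to dichotomise a score.
* **Assay statistics**: plating efficiency / surviving fractions with the
  linear-quadratic fit SF(d) = exp(−(β₁d + β₂d²)); replicate-paired foci
  t-tests; Gaussian-KDE tail mass P(intensity ≥ 40); ΔΔCt qPCR fold
  changes.
* **Seeded synthetic-data generators** for every input above, each with
  machine-readable ground truth, so the whole pipeline runs and is tested
  without any external data.

## Worked example

```r
library(radresist)

## refit a 2000-mutation catalogue drawn from a known 0.6/0.4 mixture
sigs  <- simSignatureMatrix(6, seed = 1)
catal <- simCatalogue(c(SBSsyn1 = 0.6, SBSsyn2 = 0.4), 2000, sigs, seed = 2)
refitSignatures(catal, sigs)
#> SignatureFit on 2000 mutations
#>  weights: SBSsyn1 0.588  SBSsyn2 0.412
#>  residual SSE: 0.0004691; unexplained weight: 0.000

## scan a 400-patient cohort whose hazard doubles above the 60th score percentile
cohort <- simCohort(400, paste0("HET", 1:50), logHr = log(2),
                    thresholdQuantile = 0.6, censoringFraction = 0.3, seed = 3)
scan <- scanCutoffs(cohort$clinical)
scan
#> CutoffScan over 9 candidate thresholds
#>  selected: quintile split at 0.1358 (level 0.6), log-rank p = 5.62e-13 [unadjusted], 160 high / 240 low

high <- cohort$clinical$score > selectedCutoff(scan)$threshold
cox  <- coxFit(cohort$clinical, as.numeric(high))
sprintf("HR %.2f (95%% CI %.2f-%.2f)", cox$hr, cox$ci95[1], cox$ci95[2])
#> "HR 2.52 (95% CI 1.95-3.27)"

## clonogenic survival with a linear-quadratic fit (truth: b1 = 0.3, b2 = 0.03)
col <- simClonogenic(b1 = 0.3, b2 = 0.03, seed = 4)
fitClonogenic(survivingFractions(col))
#> ClonogenicFit: 1 arm(s), 6 dose level(s)
#>  LQ: b1 = 0.2731 /Gy, b2 = 0.03688 /Gy^2
```

The fitted weights recover the simulated mixture within multinomial error;
the scan lands on the planted 60th-percentile threshold; the Cox hazard
ratio estimates the planted two-fold hazard on the *selected* (minimum-p)
split, so it is biased upward relative to HR = 2 — the vignette discusses
why the scan's p-values are reported unadjusted.

An end-to-end run of every stage on synthetic data:

```r
report <- runPipeline(system.file("extdata", "demo_config.yaml",
                                  package = "radresist"),
                      outDir = "demo_out", reportPath = "demo_out/report")
```

## Vignette

`vignettes/radioresistance-pipeline.Rmd` documents the models, their
assumptions, every tunable parameter with its default and rationale, the
numerical conventions (tie-breaks, quantile type, integration grid), what
the synthetic generators do and do not emulate, and known limitations.
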