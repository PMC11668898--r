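# Independent oracles, deliberately naive and loop-based, used to check the
# package implementations on small instances.

# consensus voting by explicit enumeration over (key, replicate, caller)
bruteForceConsensus <- function(calls, minCallers = 2, minReplicates = 2) {
  keys <- unique(paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":"))
  kept <- character(0)
  for (k in keys) {
    parts <- strsplit(k, ":")[[1]]
    nGoodReps <- 0
    for (r in unique(calls$replicate_id)) {
      n <- 0
      for (cl in unique(calls$caller_id)) {
        hit <- any(calls$chrom == parts[1] & calls$pos == as.integer(parts[2]) &
                     calls$ref == parts[3] & calls$alt == parts[4] &
                     calls$replicate_id == r & calls$caller_id == cl)
        if (hit) n <- n + 1
      }
      if (n >= minCallers) nGoodReps <- nGoodReps + 1
    }
    if (nGoodReps >= minReplicates) kept <- c(kept, k)
  }
  sort(kept)
}

# per-variant context binning without the package's vectorised path
naiveBinLabel <- function(ref, alt, context) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (ref %in% c("A", "G")) {
    context <- paste0(comp[substr(context, 3, 3)], comp[substr(context, 2, 2)],
                      comp[substr(context, 1, 1)])
    ref <- comp[[ref]]
    alt <- comp[[alt]]
  }
  paste0(substr(context, 1, 1), "[", ref, ">", alt, "]",
         substr(context, 3, 3))
}

# running-sum ssGSEA score, one position at a time
naiveSsgseaSample <- function(values, genes, set, alpha) {
  r <- rank(values, ties.method = "average")
  ord <- order(-r, genes)
  inSet <- genes[ord] %in% set
  wTot <- sum(r[ord][inSet]^alpha)
  nOut <- sum(!inSet)
  pin <- 0; pout <- 0; score <- 0
  for (i in seq_along(ord)) {
    if (inSet[i]) pin <- pin + r[ord][i]^alpha / wTot
    else pout <- pout + 1 / nOut
    score <- score + (pin - pout)
  }
  score
}

# exact hypergeometric upper tail by combinatorial summation
enumHyperTail <- function(k, K, N, n) {
  tot <- 0
  for (i in k:min(n, K))
    tot <- tot + choose(K, i) * choose(N - K, n - i)
  tot / choose(N, n)
}

randomCallTable <- function(nVariants, seed) {
  set.seed(seed)
  keys <- data.frame(
    chrom = sample(c("chr1", "chr2"), nVariants, replace = TRUE),
    pos = sample.int(1000, nVariants),
    ref = sample(c("A", "C", "G", "T"), nVariants, replace = TRUE)
  )
  keys$alt <- vapply(keys$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  rows <- list()
  for (i in seq_len(nVariants))
    for (r in paste0("rep", 1:3))
      for (cl in c("m", "s", "l"))
        if (runif(1) < 0.45)
          rows[[length(rows) + 1]] <- cbind(
            data.frame(sample_id = "s1", replicate_id = r, caller_id = cl),
            keys[i, ])
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
nnlsCappedOracle <- function(S, p) {
  x <- pracma::lsqnonneg(S, p)$x
  if (sum(x) > 1) {
    lam <- 1e6
    x <- pracma::lsqnonneg(rbind(S, rep(lam, ncol(S))), c(p, lam))$x
  }
  x
}
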