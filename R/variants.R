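## Multi-caller SNV consensus: the voting rule keeps a site when at least
## `minCallers` distinct callers report it within a replicate, in at least
## `minReplicates` replicates ("detected by at least two tools, consensus in
## at least duplicates").

VARIANT_COLUMNS <- c("sample_id", "replicate_id", "caller_id",
                     "chrom", "pos", "ref", "alt")

#' Read a MAF-like variant table
#'
#' Reads a tab-delimited variant table with mandatory columns
#' \code{sample_id, replicate_id, caller_id, chrom, pos, ref, alt} and
#' optional \code{gene, effect, context}. Only single-nucleotide variants are
#' retained: rows whose ref or alt allele is not a single A/C/G/T base
#' (indels, MNVs) are skipped and counted in the \code{"skipped"} attribute.
#' Coordinates are 1-based (MAF convention).
#'
#' @param path Path to the tab-delimited file.
#' @return data.frame of variant calls with attribute \code{skipped} (number
#'   of non-SNV rows dropped).
#' @export
readVariantTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(VARIANT_COLUMNS, names(df))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  snv <- df$ref %in% BASES & df$alt %in% BASES & df$ref != df$alt
  skipped <- sum(!snv)
  if (skipped) message("skipped ", skipped, " non-SNV record(s)")
  out <- df[snv, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Write a variant table
#'
#' @param calls data.frame of variant calls.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeVariantTable <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

variantKey <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

#' Consensus filter over callers and replicates
#'
#' Applies the caller-vote / replicate-consensus rule to a set of per-caller,
#' per-replicate SNV calls from one sample. Under the default
#' \code{mode = "per_replicate"} a variant key is kept iff the number of
#' replicates in which at least \code{minCallers} distinct callers report it
#' is at least \code{minReplicates}. The alternative reading
#' \code{mode = "same_callers"} requires one fixed combination of
#' \code{minCallers} callers to co-report the key in at least
#' \code{minReplicates} replicates.
#'
#' @param calls data.frame as returned by [readVariantTable()]; one sample.
#' @param minCallers Minimum distinct callers per replicate (default 2, of
#'   the three callers used upstream).
#' @param minReplicates Minimum supporting replicates (default 2 of
#'   triplicates).
#' @param mode Consensus reading, see Details.
#' @return data.frame of consensus variants sorted by (chrom, pos, ref, alt)
#'   with columns chrom, pos, ref, alt, n_supporting_replicates and a
#'   \code{callers_by_replicate} list-column (replicate -> callers).
#' @export
consensusFilter <- function(calls, minCallers = 2L, minReplicates = 2L,
                            mode = c("per_replicate", "same_callers")) {
  mode <- match.arg(mode)
  stopifnot(minCallers >= 1L, minReplicates >= 1L)
  if (length(unique(calls$sample_id)) > 1L)
    stop("calls must come from a single sample; found: ",
         paste(unique(calls$sample_id), collapse = ", "))
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), n_supporting_replicates = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(calls)) return(empty)

  calls <- unique(calls[, c("chrom", "pos", "ref", "alt",
                            "replicate_id", "caller_id")])
  key <- variantKey(calls)
  keep <- character(0)
  support <- list()
  nrep <- integer(0)
  for (k in unique(key)) {
    sub <- calls[key == k, , drop = FALSE]
    byrep <- split(sub$caller_id, sub$replicate_id)
    byrep <- lapply(byrep, function(x) sort(unique(x)))
    if (mode == "per_replicate") {
      supp <- sum(lengths(byrep) >= minCallers)
      ok <- supp >= minReplicates
    } else {
      callers <- sort(unique(sub$caller_id))
      ok <- FALSE
      supp <- 0L
      if (length(callers) >= minCallers) {
        combos <- combn(callers, minCallers, simplify = FALSE)
        counts <- vapply(combos, function(cc)
          sum(vapply(byrep, function(r) all(cc %in% r), logical(1))),
          integer(1))
        supp <- max(counts)
        ok <- supp >= minReplicates
      }
    }
    if (ok) {
      keep <- c(keep, k)
      support[[k]] <- byrep
      nrep <- c(nrep, supp)
    }
  }
  if (!length(keep)) return(empty)
  parts <- strsplit(keep, ":", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, character(1), 1L),
    pos   = as.integer(vapply(parts, `[`, character(1), 2L)),
    ref   = vapply(parts, `[`, character(1), 3L),
    alt   = vapply(parts, `[`, character(1), 4L),
    n_supporting_replicates = nrep,
    stringsAsFactors = FALSE
  )
  ord <- order(out$chrom, out$pos, out$ref, out$alt)
  out <- out[ord, , drop = FALSE]
  out$callers_by_replicate <- support[keep][ord]
  rownames(out) <- NULL
  out
}

#' Count consensus variants by functional effect
#'
#' Tallies consensus variants into synonymous / non-synonymous / other using
#' the \code{effect} annotations carried by the underlying calls. Conflicting
#' annotations for a key are resolved by majority vote across callers; ties
#' and missing annotations resolve to \code{"other"}.
#'
#' @param consensus data.frame from [consensusFilter()].
#' @param calls The original calls the consensus was derived from.
#' @return Named numeric vector \code{c(synonymous, non_synonymous, other,
#'   total)}; the first three partition the total.
#' @export
countByEffect <- function(consensus, calls) {
  out <- c(synonymous = 0, non_synonymous = 0, other = 0, total = 0)
  if (!nrow(consensus)) return(out)
  ckey <- variantKey(consensus)
  if (is.null(calls$effect)) calls$effect <- NA_character_
  kkey <- variantKey(calls)
  for (k in ckey) {
    eff <- calls$effect[kkey == k]
    eff <- eff[!is.na(eff) & eff %in% c("synonymous", "non_synonymous")]
    cls <- "other"
    if (length(eff)) {
      tab <- sort(table(eff), decreasing = TRUE)
      if (length(tab) == 1L || tab[1L] > tab[2L]) cls <- names(tab)[1L]
    }
    out[cls] <- out[cls] + 1
  }
  out["total"] <- sum(out[c("synonymous", "non_synonymous", "other")])
  out
}

#' Build the 96-context catalogue of a consensus set
#'
#' Bins each consensus SNV into its pyrimidine-centred trinucleotide context
#' class; purine-reference variants are reverse-complemented first. The
#' catalogue total equals the number of consensus variants.
#'
#' @param consensus data.frame from [consensusFilter()].
#' @param contexts Named character vector mapping variant keys
#'   (\code{"chrom:pos:ref:alt"}) to 3-mer contexts whose middle base is the
#'   ref allele. May be omitted when \code{consensus} carries a
#'   \code{context} column.
#' @return A [MutationCatalogue-class].
#' @export
build96Catalogue <- function(consensus, contexts = NULL) {
  if (!nrow(consensus)) return(newCatalogue())
  key <- variantKey(consensus)
  if (is.null(contexts)) {
    if (is.null(consensus$context))
      stop("provide `contexts` or a context column")
    contexts <- setNames(consensus$context, key)
  }
  miss <- setdiff(key, names(contexts))
  if (length(miss)) stop("no context for key(s): ", paste(miss, collapse = ", "))
  labs <- vapply(seq_len(nrow(consensus)), function(i)
    contextClass(consensus$ref[i], consensus$alt[i], contexts[[key[i]]]),
    character(1))
  tab <- table(factor(labs, levels = cosmicContexts()))
  newCatalogue(setNames(as.numeric(tab), names(tab)))
}

#' Write / read a 96-row catalogue TSV (COSMIC context order)
#'
#' @param catalogue A [MutationCatalogue-class].
#' @param path Output path.
#' @return The path (writer) or a \code{MutationCatalogue} (reader).
#' @export
writeCatalogue <- function(catalogue, path) {
  df <- data.frame(context = cosmicContexts(),
                   count = catalogueCounts(catalogue))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCatalogue
#' @export
readCatalogue <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("context", "count") %in% names(df)))
    stop("catalogue file needs columns context, count")
  newCatalogue(setNames(df$count, df$context))
}
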