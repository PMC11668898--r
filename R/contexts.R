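## Trinucleotide context machinery for SBS catalogues.
## Convention: pyrimidine-centred classes "X[R>A]Y"; purine-reference variants
## are reverse-complemented onto the pyrimidine strand before binning.

BASES <- c("A", "C", "G", "T")
SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 COSMIC trinucleotide context classes
#'
#' Labels of the 96 single-base-substitution classes in conventional COSMIC
#' order: substitution-major (C>A, C>G, C>T, T>A, T>C, T>G), then the 16
#' flanking-base pairs in alphabetical order.
#'
#' @return Character vector of length 96, e.g. \code{"A[C>A]A"}.
#' @export
cosmicContexts <- function() {
  unlist(lapply(SUBSTITUTIONS, function(s)
    as.vector(t(outer(BASES, BASES, function(f5, f3)
      paste0(f5, "[", s, "]", f3))))))
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA strings (A/C/G/T only).
#' @return Character vector of reverse complements.
#' @export
reverseComplement <- function(x) {
  vapply(strsplit(toupper(x), ""), function(b) {
    paste(rev(chartr("ACGT", "TGCA", b)), collapse = "")
  }, character(1))
}

#' Context class of a single SNV
#'
#' Maps one substitution with its 3-mer context onto its pyrimidine-centred
#' 96-class label. Purine reference alleles (A/G) are reverse-complemented.
#'
#' @param ref,alt Single reference/alternate bases.
#' @param context 3-mer centred on the variant position; its middle base must
#'   equal \code{ref}.
#' @return One of the 96 labels from [cosmicContexts()].
#' @export
contextClass <- function(ref, alt, context) {
  stopifnot(length(ref) == 1L, length(alt) == 1L, length(context) == 1L)
  ref <- toupper(ref); alt <- toupper(alt); context <- toupper(context)
  if (nchar(context) != 3L || substr(context, 2, 2) != ref)
    stop("context middle base must equal ref (got context '", context,
         "' for ref '", ref, "')")
  if (ref %in% c("A", "G")) {
    context <- reverseComplement(context)
    ref <- chartr("AG", "TC", ref)
    alt <- chartr("ACGT", "TGCA", alt)
  }
  lab <- paste0(substr(context, 1, 1), "[", ref, ">", alt, "]",
                substr(context, 3, 3))
  if (!lab %in% cosmicContexts()) stop("invalid substitution: ", lab)
  lab
}

#' Construct a MutationCatalogue from named counts
#'
#' @param counts Numeric vector; either length 96 in COSMIC order (names
#'   optional) or a named vector of counts for a subset of classes.
#' @return A [MutationCatalogue-class] object.
#' @export
newCatalogue <- function(counts = NULL) {
  ctx <- cosmicContexts()
  full <- setNames(numeric(96), ctx)
  if (!is.null(counts)) {
    if (is.null(names(counts))) {
      stopifnot(length(counts) == 96L)
      full[] <- as.numeric(counts)
    } else {
      bad <- setdiff(names(counts), ctx)
      if (length(bad)) stop("unknown context classes: ", paste(bad, collapse = ", "))
      full[names(counts)] <- full[names(counts)] + as.numeric(counts)
    }
  }
  new("MutationCatalogue", counts = full)
}
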