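## Core containers: a genome is a list of contigs (data.frame), optional
## contig sequences, and a CDS feature table.  Coordinates are 1-based
## inclusive throughout; reported cluster lengths use the end - start
## convention of the packaged strain table.

AA_ALPHABET_OK <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")

#' Construct a contig record
#'
#' @param id Contig identifier.
#' @param length Contig length in bases (>= 1).
#' @param topology `"circular"` or `"linear"`.
#' @param replicon_class `"chromosome"`, `"plasmid"` or `"unknown"`.
#' @return A one-row `data.frame` describing the contig.
#' @export
contig <- function(id, length, topology = c("linear", "circular"),
                   replicon_class = c("unknown", "chromosome", "plasmid")) {
  topology <- match.arg(topology)
  replicon_class <- match.arg(replicon_class)
  stopifnot(is.character(id), length(id) == 1L, nchar(id) > 0L)
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("contig length must be >= 1")
  data.frame(id = id, length = length, topology = topology,
             replicon_class = replicon_class, stringsAsFactors = FALSE)
}

#' Construct a CDS feature table
#'
#' Builds the feature `data.frame` used inside [genome()] objects.  All
#' arguments are recycled to a common length.
#'
#' @param contig_id Contig each feature lives on.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @param locus_tag Unique feature identifiers.
#' @param gene_name Optional gene symbols (`NA` allowed).
#' @param product Free-text functional annotation.
#' @param protein Optional amino-acid sequences (20-letter alphabet plus
#'   `X` and `*`); `NA` when no translation is stored.
#' @return A `data.frame` with one row per feature.
#' @export
gene_feature <- function(contig_id, start, end, strand, locus_tag,
                         gene_name = NA_character_, product = "",
                         protein = NA_character_) {
  df <- data.frame(contig_id = contig_id, start = as.integer(start),
                   end = as.integer(end), strand = strand,
                   locus_tag = locus_tag, gene_name = gene_name,
                   product = product, protein = protein,
                   stringsAsFactors = FALSE)
  if (any(df$start < 1L | df$start > df$end))
    stop("feature coordinates must satisfy 1 <= start <= end")
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  bad <- !is.na(df$protein) &
    vapply(strsplit(df$protein, ""), function(x)
      any(!x %in% AA_ALPHABET_OK), logical(1))
  if (any(bad))
    stop("protein sequences may only use the 20-letter alphabet plus X/*: ",
         paste(df$locus_tag[bad], collapse = ", "))
  df
}

empty_features <- function() {
  gene_feature(character(), integer(), integer(), character(),
               character(), character(), character(), character())
}

#' Construct an annotated genome
#'
#' @param id Genome/strain identifier.
#' @param species Species label (free text).
#' @param contigs One or more contig rows from [contig()] (rbind-ed).
#' @param features CDS table from [gene_feature()]; may be empty.
#' @param sequences Optional named character vector of contig nucleotide
#'   sequences; names must match contig ids and lengths must agree with
#'   the contig table.
#' @return An object of class `"genome"`.
#' @export
genome <- function(id, species = "", contigs, features = empty_features(),
                   sequences = NULL) {
  g <- structure(list(id = id, species = species, contigs = contigs,
                      features = features, sequences = sequences),
                 class = "genome")
  validate_genome(g)
  g
}

#' Validate genome invariants
#'
#' Checks contig lengths, feature coordinates against their contig,
#' locus_tag uniqueness and sequence/length agreement.  Called by
#' [genome()] and before [write_genome()].
#'
#' @param g A `"genome"` object.
#' @return `g`, invisibly; stops on violation.
#' @export
validate_genome <- function(g) {
  stopifnot(inherits(g, "genome"))
  ct <- g$contigs
  if (nrow(ct) < 1L) stop("genome must have at least one contig")
  if (anyDuplicated(ct$id)) stop("duplicate contig ids")
  f <- g$features
  if (nrow(f) > 0L) {
    miss <- setdiff(unique(f$contig_id), ct$id)
    if (length(miss))
      stop("features reference unknown contigs: ", paste(miss, collapse = ", "))
    clen <- setNames(ct$length, ct$id)
    if (any(f$end > clen[f$contig_id]))
      stop("feature end beyond contig length")
    if (anyDuplicated(f$locus_tag))
      stop("duplicate locus_tags: ",
           paste(unique(f$locus_tag[duplicated(f$locus_tag)]), collapse = ", "))
  }
  if (!is.null(g$sequences)) {
    if (is.null(names(g$sequences)) || !all(names(g$sequences) %in% ct$id))
      stop("sequence names must match contig ids")
    clen <- setNames(ct$length, ct$id)
    if (any(nchar(g$sequences) != clen[names(g$sequences)]))
      stop("sequence length disagrees with contig length field")
  }
  invisible(g)
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s (%s)\n", x$id,
              if (nzchar(x$species)) x$species else "species unknown"))
  cat(sprintf("  contigs:  %d (%s bp total)\n", nrow(x$contigs),
              format(sum(x$contigs$length), big.mark = ",")))
  cat(sprintf("  features: %d CDS\n", nrow(x$features)))
  invisible(x)
}

## features sorted by (contig_id, start); stable within ties
sort_features <- function(f) f[order(f$contig_id, f$start, f$end), , drop = FALSE]

#' Translate a CDS span with the bacterial genetic code
#'
#' Extracts `start..end` from the contig sequence, reverse-complements on
#' the minus strand, and translates with translation table 11.  Ambiguous
#' codons give `X`; internal stops are kept as `*` (pseudogene candidates),
#' a trailing stop is removed.
#'
#' @param seq Contig nucleotide sequence (character).
#' @param start,end 1-based inclusive CDS span.
#' @param strand `"+"` or `"-"`.
#' @return Amino-acid string.
#' @export
translate_cds <- function(seq, start, end, strand) {
  nt <- substr(seq, start, end)
  d <- Biostrings::DNAString(nt)
  if (strand == "-") d <- Biostrings::reverseComplement(d)
  aa <- as.character(Biostrings::translate(
    d, genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
  sub("\\*$", "", aa)
}
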