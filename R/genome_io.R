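#' Read an annotated genome
#'
#' Reads a Bakta-style annotated genome from a GenBank flat file or a
#' GFF3 file with a sibling FASTA (`.fna`/`.fa`/`.fasta`).  All CDS
#' features are captured with their product string and protein
#' translation; a CDS lacking a stored translation is translated from
#' the nucleotide span using the bacterial genetic code (table 11).
#' Coordinates are normalised to 1-based inclusive.
#'
#' @param path Path to the GenBank or GFF3 file.
#' @param format `"genbank"` or `"gff3"`; guessed from the file
#'   extension when missing.
#' @return A [genome()] object.
#' @export
read_annotated_genome <- function(path, format = c("auto", "genbank", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gb", "gbk", "gbff", "genbank")) "genbank"
              else if (ext %in% c("gff", "gff3")) "gff3"
              else stop("cannot guess format from extension '", ext, "'")
  }
  switch(format, genbank = read_genbank(path), gff3 = read_gff3_genome(path))
}

#' Write an annotated genome
#'
#' Emits a genome as a GenBank flat file or GFF3(+FASTA when contig
#' sequences are present).  The emitted file re-reads to an equivalent
#' genome (round-trip property).  Genome invariants are validated before
#' writing.
#'
#' @param g A [genome()] object.
#' @param path Output path.
#' @param format `"genbank"` or `"gff3"`.
#' @return Invisibly, `NULL`.
#' @export
write_genome <- function(g, path, format = c("genbank", "gff3")) {
  format <- match.arg(format)
  validate_genome(g)
  switch(format, genbank = write_genbank(g, path),
         gff3 = write_gff3_genome(g, path))
}

#' Load the packaged strain table
#'
#' Returns the machine-readable strain survey packaged with cwpstyper:
#' 28 strains of two *Pseudolactococcus* species with their cwps
#' genotype (letters E-L), eps genotype (roman numerals I-XI, absent for
#' three strains), cluster fragment coordinates and printed lengths.
#' Printed lengths follow the table's `end - start` convention; split
#' cwps loci (strains T2G5 and T2H4) carry two fragments.
#'
#' @return A `data.frame` of class `"strain_table"` with columns
#'   `species`, `strain`, `locus_kind`, `genotype`, `fragment_index`,
#'   `start`, `end`, `printed_length`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_strains.tsv", package = "cwpstyper",
                      mustWork = TRUE)
  tb <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  bad <- tb$end - tb$start != tb$printed_length
  if (any(bad))
    stop("corrupted strain-table fixture: length mismatch for ",
         paste(tb$strain[bad], collapse = ", "))
  if (length(unique(tb$strain)) != 28L)
    stop("corrupted strain-table fixture: expected 28 strains, found ",
         length(unique(tb$strain)))
  class(tb) <- c("strain_table", "data.frame")
  tb
}

#' Convert the strain table to per-strain records
#'
#' @param tb Output of [load_table1_fixture()].
#' @return A list of records, one per strain, each with `species`,
#'   `strain`, `cwps_genotype`, `cwps_fragments` (matrix of start/end),
#'   `eps_genotype` (`NA` when absent), `eps_fragments` and
#'   `printed_lengths`.
#' @export
strain_records <- function(tb = load_table1_fixture()) {
  out <- list()
  for (s in unique(tb$strain)) {
    rows <- tb[tb$strain == s, , drop = FALSE]
    cw <- rows[rows$locus_kind == "cwps", , drop = FALSE]
    ep <- rows[rows$locus_kind == "eps", , drop = FALSE]
    out[[s]] <- list(
      species = rows$species[1], strain = s,
      cwps_genotype = cw$genotype[1],
      cwps_fragments = cbind(start = cw$start, end = cw$end),
      eps_genotype = if (nrow(ep)) ep$genotype[1] else NA_character_,
      eps_fragments = if (nrow(ep)) cbind(start = ep$start, end = ep$end)
                      else cbind(start = integer(), end = integer()),
      printed_lengths = rows$printed_length)
  }
  out
}
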