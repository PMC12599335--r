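## GFF3 + FASTA input/output, delegated to rtracklayer and Biostrings.
## Contig topology and replicon class travel on per-contig "region"
## features; CDS features carry locus_tag/gene/product/translation
## attributes (Bakta emits the same shape).

fasta_sibling <- function(path) {
  base <- tools::file_path_sans_ext(path)
  cands <- paste0(base, c(".fna", ".fa", ".fasta"))
  hit <- cands[file.exists(cands)]
  if (length(hit)) hit[1] else cands[1]
}

read_gff3_genome <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  fa <- fasta_sibling(path)
  seqs <- NULL
  if (file.exists(fa)) {
    ss <- Biostrings::readDNAStringSet(fa)
    names(ss) <- sub("\\s.*$", "", names(ss))
    seqs <- setNames(as.character(ss), names(ss))
  }

  is_region <- mc$type == "region"
  genome_id <- NA_character_
  species <- ""
  contigs <- NULL
  region_meta <- list()
  if (any(is_region)) {
    rr <- gr[is_region]
    rmc <- S4Vectors::mcols(rr)
    for (i in seq_along(rr)) {
      cid <- as.character(GenomicRanges::seqnames(rr))[i]
      topo <- if (!is.null(rmc$topology) && !is.na(rmc$topology[i]))
        rmc$topology[i] else "linear"
      repl <- if (!is.null(rmc$replicon_class) && !is.na(rmc$replicon_class[i]))
        rmc$replicon_class[i] else "unknown"
      contigs <- rbind(contigs, contig(cid, GenomicRanges::end(rr)[i], topo, repl))
      if (!is.null(rmc$strain) && !is.na(rmc$strain[i])) genome_id <- rmc$strain[i]
      if (!is.null(rmc$organism) && !is.na(rmc$organism[i])) species <- rmc$organism[i]
    }
  }
  ## contigs not described by a region feature: fall back to FASTA/pragma
  seen <- if (is.null(contigs)) character() else contigs$id
  allseq <- unique(as.character(GenomicRanges::seqnames(gr)))
  for (cid in setdiff(union(allseq, names(seqs)), seen)) {
    len <- if (!is.null(seqs) && cid %in% names(seqs)) nchar(seqs[[cid]])
           else max(GenomicRanges::end(gr[as.character(GenomicRanges::seqnames(gr)) == cid]))
    contigs <- rbind(contigs, contig(cid, len))
  }

  is_cds <- mc$type == "CDS"
  feats <- empty_features()
  if (any(is_cds)) {
    cds <- gr[is_cds]
    cmc <- S4Vectors::mcols(cds)
    getq <- function(nm, default = NA_character_) {
      if (!is.null(cmc[[nm]])) {
        v <- as.character(cmc[[nm]])
        ifelse(is.na(v), default, v)
      } else rep(default, length(cds))
    }
    feats <- gene_feature(
      contig_id = as.character(GenomicRanges::seqnames(cds)),
      start = GenomicRanges::start(cds), end = GenomicRanges::end(cds),
      strand = as.character(GenomicRanges::strand(cds)),
      locus_tag = {
        lt <- getq("locus_tag")
        lt2 <- getq("ID")
        ifelse(is.na(lt), ifelse(is.na(lt2),
               sprintf("cds%04d", seq_along(cds)), lt2), lt)
      },
      gene_name = getq("gene"),
      product = getq("product", ""),
      protein = getq("translation"))
  }
  feats <- sort_features(feats)
  need <- which(is.na(feats$protein))
  for (i in need) {
    s <- seqs[[feats$contig_id[i]]]
    if (!is.null(s) && !is.na(s))
      feats$protein[i] <- translate_cds(s, feats$start[i], feats$end[i],
                                        feats$strand[i])
  }
  if (is.na(genome_id)) genome_id <- tools::file_path_sans_ext(basename(path))
  genome(genome_id, species, contigs, feats, sequences = seqs)
}

write_gff3_genome <- function(g, path) {
  ct <- g$contigs
  reg <- GenomicRanges::GRanges(
    seqnames = ct$id, ranges = IRanges::IRanges(1L, ct$length), strand = "*")
  S4Vectors::mcols(reg)$type <- "region"
  S4Vectors::mcols(reg)$topology <- ct$topology
  S4Vectors::mcols(reg)$replicon_class <- ct$replicon_class
  S4Vectors::mcols(reg)$strain <- g$id
  S4Vectors::mcols(reg)$organism <- g$species

  f <- sort_features(g$features)
  all <- reg
  if (nrow(f) > 0L) {
    cds <- GenomicRanges::GRanges(
      seqnames = f$contig_id,
      ranges = IRanges::IRanges(f$start, f$end), strand = f$strand)
    S4Vectors::mcols(cds)$type <- "CDS"
    S4Vectors::mcols(cds)$phase <- 0L
    S4Vectors::mcols(cds)$ID <- f$locus_tag
    S4Vectors::mcols(cds)$locus_tag <- f$locus_tag
    S4Vectors::mcols(cds)$gene <- f$gene_name
    S4Vectors::mcols(cds)$product <- f$product
    S4Vectors::mcols(cds)$translation <- f$protein
    suppressWarnings(all <- c(reg, cds))
  }
  GenomeInfoDb::seqlengths(all) <- setNames(ct$length, ct$id)
  rtracklayer::export(all, path, format = "gff3")
  if (!is.null(g$sequences)) {
    ss <- Biostrings::DNAStringSet(unlist(g$sequences))
    Biostrings::writeXStringSet(ss, fasta_sibling(path))
  }
  invisible(NULL)
}
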