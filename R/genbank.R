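## Minimal GenBank flat-file reader/writer for Bakta-style annotated
## genomes.  Supports LOCUS/DEFINITION/FEATURES(source, CDS)/ORIGIN and
## the qualifiers this package needs (organism, strain, plasmid,
## locus_tag, gene, product, translation).  Origin-spanning (join) CDS
## locations are rejected.

read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^//\\s*$", lines)
  if (length(ends) == 0L)
    stop("GenBank parse error in ", path, ": no record terminator '//'")
  starts <- c(1L, head(ends, -1L) + 1L)
  recs <- Map(function(s, e) list(lines = lines[s:(e - 1L)], offset = s),
              starts, ends)

  contigs <- NULL
  seqs <- character()
  feats <- list()
  genome_id <- NA_character_
  species <- ""

  for (rec in recs) {
    rl <- rec$lines
    rl <- rl[nzchar(trimws(rl)) | seq_along(rl) > 1L]
    loc <- grep("^LOCUS", rl)
    if (length(loc) != 1L)
      stop("GenBank parse error near line ", rec$offset,
           ": record must have exactly one LOCUS line")
    toks <- strsplit(trimws(sub("^LOCUS", "", rl[loc])), "\\s+")[[1]]
    cid <- toks[1]
    len <- suppressWarnings(as.integer(toks[2]))
    if (is.na(len))
      stop("GenBank parse error near line ", rec$offset + loc - 1L,
           ": cannot read contig length from LOCUS line")
    topo <- if (any(grepl("circular", toks))) "circular" else "linear"

    defline <- ""
    di <- grep("^DEFINITION", rl)
    if (length(di)) {
      j <- di[1]
      defline <- trimws(sub("^DEFINITION", "", rl[j]))
      while (j + 1L <= length(rl) && grepl("^\\s{5,}", rl[j + 1L]) &&
             !grepl("^FEATURES|^ACCESSION|^VERSION|^SOURCE|^KEYWORDS", rl[j + 1L])) {
        j <- j + 1L
        defline <- paste(defline, trimws(rl[j]))
      }
    }

    fi <- grep("^FEATURES", rl)
    oi <- grep("^ORIGIN", rl)
    fend <- if (length(oi)) oi[1] - 1L else length(rl)
    repl <- "unknown"
    if (grepl("plasmid", defline, ignore.case = TRUE)) repl <- "plasmid"
    else if (grepl("chromosome", defline, ignore.case = TRUE)) repl <- "chromosome"

    if (length(fi)) {
      block <- rl[(fi[1] + 1L):fend]
      keyidx <- grep("^\\s{5}\\S", block)
      for (k in seq_along(keyidx)) {
        i0 <- keyidx[k]
        i1 <- if (k < length(keyidx)) keyidx[k + 1L] - 1L else length(block)
        fl <- block[i0:i1]
        key <- sub("^\\s+", "", substr(fl[1], 1, 20))
        key <- trimws(key)
        locstr <- trimws(substr(fl[1], 21, nchar(fl[1])))
        ## continuation lines of the location (no qualifier yet)
        j <- 2L
        while (j <= length(fl) && !grepl("^\\s+/", fl[j])) {
          locstr <- paste0(locstr, trimws(fl[j])); j <- j + 1L
        }
        quals <- parse_qualifiers(if (j <= length(fl)) fl[j:length(fl)] else character())
        if (key == "source") {
          if (!is.null(quals$organism)) species <- quals$organism
          if (!is.null(quals$strain) && is.na(genome_id)) genome_id <- quals$strain
          if (!is.null(quals$plasmid)) repl <- "plasmid"
        } else if (key == "CDS") {
          pl <- parse_gb_location(locstr, rec$offset)
          feats[[length(feats) + 1L]] <- gene_feature(
            contig_id = cid, start = pl$start, end = pl$end,
            strand = pl$strand,
            locus_tag = if (!is.null(quals$locus_tag)) quals$locus_tag
                        else sprintf("%s_cds%04d", cid, length(feats) + 1L),
            gene_name = if (!is.null(quals$gene)) quals$gene else NA_character_,
            product = if (!is.null(quals$product)) quals$product else "",
            protein = if (!is.null(quals$translation))
                        gsub("\\s", "", quals$translation) else NA_character_)
        }
      }
    }

    if (length(oi)) {
      sq <- rl[(oi[1] + 1L):length(rl)]
      sq <- gsub("[^A-Za-z]", "", sq)
      sq <- toupper(paste(sq, collapse = ""))
      if (nzchar(sq)) seqs[cid] <- sq
    }
    contigs <- rbind(contigs, contig(cid, len, topo, repl))
  }

  if (is.na(genome_id))
    genome_id <- tools::file_path_sans_ext(basename(path))
  f <- if (length(feats)) sort_features(do.call(rbind, feats)) else empty_features()
  ## translate CDS lacking a stored translation when sequence available
  need <- which(is.na(f$protein))
  for (i in need) {
    s <- seqs[f$contig_id[i]]
    if (!is.na(s))
      f$protein[i] <- translate_cds(s, f$start[i], f$end[i], f$strand[i])
  }
  genome(genome_id, species, contigs, f,
         sequences = if (length(seqs)) seqs else NULL)
}

parse_qualifiers <- function(lines) {
  quals <- list()
  cur <- NULL
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s+/([A-Za-z_]+)(=(.*))?$", ln))[[1]]
    if (length(m)) {
      if (!is.null(cur)) quals[[cur$name]] <- cur$val
      val <- if (length(m) >= 4 && nzchar(m[3])) m[4] else "true"
      cur <- list(name = m[2], val = val)
    } else if (!is.null(cur)) {
      sep <- if (cur$name == "translation") "" else " "
      cur$val <- paste(cur$val, trimws(ln), sep = sep)
    }
  }
  if (!is.null(cur)) quals[[cur$name]] <- cur$val
  lapply(quals, function(v) gsub('^"|"$', "", v))
}

parse_gb_location <- function(locstr, offset) {
  if (grepl("join|order", locstr))
    stop("unsupported feature: origin-spanning/compound location '",
         locstr, "' (record near line ", offset, ")")
  strand <- "+"
  s <- locstr
  if (grepl("^complement\\(", s)) {
    strand <- "-"
    s <- sub("^complement\\((.*)\\)$", "\\1", s)
  }
  m <- regmatches(s, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", s))[[1]]
  if (length(m) != 3)
    stop("GenBank parse error near line ", offset,
         ": cannot parse location '", locstr, "'")
  list(start = as.integer(m[2]), end = as.integer(m[3]), strand = strand)
}

write_genbank <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ci in seq_len(nrow(g$contigs))) {
    ct <- g$contigs[ci, ]
    wl <- function(...) writeLines(sprintf(...), con)
    wl("LOCUS       %-16s %10d bp    DNA     %-8s BCT 01-JAN-2026",
       ct$id, ct$length, ct$topology)
    defin <- trimws(sprintf("%s strain %s %s.", g$species, g$id,
                            if (ct$replicon_class == "unknown") "" else ct$replicon_class))
    wl("DEFINITION  %s", defin)
    wl("ACCESSION   %s", ct$id)
    wl("FEATURES             Location/Qualifiers")
    wl("     source          1..%d", ct$length)
    wl("                     /organism=\"%s\"", g$species)
    wl("                     /strain=\"%s\"", g$id)
    if (ct$replicon_class == "plasmid")
      wl("                     /plasmid=\"%s\"", ct$id)
    f <- g$features[g$features$contig_id == ct$id, , drop = FALSE]
    f <- sort_features(f)
    for (i in seq_len(nrow(f))) {
      locstr <- if (f$strand[i] == "+")
        sprintf("%d..%d", f$start[i], f$end[i])
      else sprintf("complement(%d..%d)", f$start[i], f$end[i])
      wl("     CDS             %s", locstr)
      wl("                     /locus_tag=\"%s\"", f$locus_tag[i])
      if (!is.na(f$gene_name[i]))
        wl("                     /gene=\"%s\"", f$gene_name[i])
      for (ln in wrap_qualifier("product", f$product[i]))
        writeLines(ln, con)
      if (!is.na(f$protein[i]))
        for (ln in wrap_qualifier("translation", f$protein[i]))
          writeLines(ln, con)
    }
    sq <- g$sequences[[ct$id]]
    if (!is.null(sq) && !is.na(sq)) {
      writeLines("ORIGIN", con)
      pos <- seq(1L, nchar(sq), by = 60L)
      for (p in pos) {
        chunk <- substr(sq, p, min(p + 59L, nchar(sq)))
        blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                            pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
        wl("%9d %s", p, tolower(paste(blocks, collapse = " ")))
      }
    }
    writeLines("//", con)
  }
  invisible(NULL)
}

wrap_qualifier <- function(name, value) {
  text <- sprintf("/%s=\"%s\"", name, value)
  out <- character()
  width <- 58L
  while (nchar(text) > width) {
    cut <- width
    ## avoid splitting inside a word for free-text qualifiers
    if (name != "translation") {
      sp <- gregexpr(" ", substr(text, 1, width))[[1]]
      if (any(sp > 0)) {
        cut <- max(sp)
        out <- c(out, substr(text, 1, cut - 1L))
      } else out <- c(out, substr(text, 1, cut))
    } else out <- c(out, substr(text, 1, cut))
    text <- substr(text, cut + 1L, nchar(text))
  }
  paste0(strrep(" ", 21), c(out, text))
}
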