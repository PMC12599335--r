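## Locus detection: anchor on conserved marker genes (rml/rgp vocabulary
## for cwps, eps proximal/terminal vocabulary for eps), grow regions
## gene-by-gene over the polysaccharide vocabulary, and stop after a run
## of non-matching genes.  Fragment coordinates are the outermost
## included genes' edges; lengths use the end - start convention.

#' Locus finder parameters
#'
#' @param stop_after Consecutive non-matching genes that terminate
#'   region growth (default 2).
#' @param min_genes Minimum matching genes for a reported region
#'   (default 4; guards against isolated vocabulary hits).
#' @param refdb Optional role-labelled reference proteins (named
#'   character vector, names `role|name`) used as a similarity fallback
#'   for genes with uninformative products.
#' @param fallback_threshold Combined-score threshold for the
#'   similarity fallback (default 40).
#' @param vocab Vocabulary table ([role_vocabulary()]).
#' @param align [align_params()] for the fallback route.
#' @return A list of class `"locus_params"`.
#' @export
locus_params <- function(stop_after = 2L, min_genes = 4L, refdb = NULL,
                         fallback_threshold = 40, vocab = role_vocabulary(),
                         align = align_params()) {
  structure(list(stop_after = stop_after, min_genes = min_genes,
                 refdb = refdb, fallback_threshold = fallback_threshold,
                 vocab = vocab, align = align), class = "locus_params")
}

new_locus_region <- function(genome_id, kind, genes, anchor_hits) {
  frag_tab <- do.call(rbind, lapply(split(genes, genes$contig_id), function(g)
    data.frame(contig_id = g$contig_id[1], start = min(g$start),
               end = max(g$end), stringsAsFactors = FALSE)))
  rownames(frag_tab) <- NULL
  structure(list(genome_id = genome_id, kind = kind, fragments = frag_tab,
                 genes = genes, anchor_hits = anchor_hits),
            class = "locus_region")
}

#' Total length of a locus region
#'
#' Sum of `end - start` over fragments (the strain table's printed
#' length convention, not `end - start + 1`).
#' @param locus A `"locus_region"`.
#' @return Integer length in bases.
#' @export
locus_length <- function(locus) {
  sum(locus$fragments$end - locus$fragments$start)
}

#' @export
print.locus_region <- function(x, ...) {
  cat(sprintf("<locus_region> %s %s: %d gene(s), %d fragment(s), %s bp\n",
              x$genome_id, x$kind, nrow(x$genes), nrow(x$fragments),
              format(locus_length(x), big.mark = ",")))
  invisible(x)
}

#' Detect cwps / eps loci in an annotated genome
#'
#' Seeds regions at anchor marker genes (for cwps the rmlABCD precursor
#' and rhamnosyltransferase vocabulary; for eps the epsRXABCD / epsL /
#' orfY vocabulary), then grows each seed over adjacent genes whose
#' products match the polysaccharide vocabulary or are hypothetical,
#' terminating after `stop_after` consecutive non-matching genes.
#' Transposases count as matching (they occur inside loci).  Overlapping
#' regions are merged.  Genomes without anchors return an empty list.
#'
#' @param g A [genome()].
#' @param kind `"cwps"` or `"eps"`.
#' @param params [locus_params()].
#' @return List of `"locus_region"` objects.
#' @export
find_locus <- function(g, kind = c("cwps", "eps"), params = locus_params()) {
  kind <- match.arg(kind)
  stopifnot(inherits(g, "genome"))
  out <- list()
  for (cid in g$contigs$id) {
    f <- sort_features(g$features[g$features$contig_id == cid, , drop = FALSE])
    if (nrow(f) == 0L) next
    m <- match_vocab_row(f$product, params$vocab, kind)
    matched <- !is.na(m$row)
    anchor <- matched & m$vocab$anchor[m$row] == 1L
    anchor[is.na(anchor)] <- FALSE
    ## similarity fallback: uninformative products scored against
    ## role-labelled reference proteins
    if (!is.null(params$refdb)) {
      unk <- which(!matched & is_hypothetical(f$product) & !is.na(f$protein))
      for (i in unk) {
        bh <- best_hit(f$protein[i], params$refdb, params$align)
        if (bh$score >= params$fallback_threshold) {
          matched[i] <- TRUE
          role <- sub("\\|.*$", "", bh$subject_id)
          kinds <- params$vocab$kind[params$vocab$role == role]
          if (any(params$vocab$anchor[params$vocab$role == role] == 1L &
                  kinds %in% c(kind, "both")))
            anchor[i] <- TRUE
        }
      }
    }
    grows <- matched | is_hypothetical(f$product)
    if (!any(anchor)) next
    regions <- lapply(which(anchor), function(i)
      grow_region(i, grows, params$stop_after))
    ## merge overlapping [lo, hi] index intervals
    regions <- regions[order(vapply(regions, `[`, integer(1), 1L))]
    merged <- list(regions[[1]])
    for (r in regions[-1]) {
      last <- merged[[length(merged)]]
      if (r[1] <= last[2] + 1L)
        merged[[length(merged)]] <- c(last[1], max(last[2], r[2]))
      else merged[[length(merged) + 1L]] <- r
    }
    for (iv in merged) {
      idx <- iv[1]:iv[2]
      n_match <- sum(matched[idx])
      if (n_match < params$min_genes) next
      genes <- f[idx, , drop = FALSE]
      ah <- data.frame(locus_tag = f$locus_tag[idx][anchor[idx]],
                       marker = m$vocab$role[m$row[idx]][anchor[idx]],
                       stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- new_locus_region(g$id, kind, genes, ah)
    }
  }
  out
}

## expand index i over the grows mask; region bounds are the outermost
## matching genes reached before stop_after consecutive misses
grow_region <- function(i, grows, stop_after) {
  n <- length(grows)
  lo <- hi <- i
  miss <- 0L; k <- i + 1L
  while (k <= n && miss < stop_after) {
    if (grows[k]) { hi <- k; miss <- 0L } else miss <- miss + 1L
    k <- k + 1L
  }
  miss <- 0L; k <- i - 1L
  while (k >= 1L && miss < stop_after) {
    if (grows[k]) { lo <- k; miss <- 0L } else miss <- miss + 1L
    k <- k - 1L
  }
  c(lo, hi)
}

#' Advisory locus quality metrics
#'
#' Report-only: evaluates the observed cwps cluster size and gene-count
#' ranges (18,445-30,217 bp; 16-28 genes) without rejecting anything.
#'
#' @param locus A `"locus_region"`.
#' @return A list of class `"locus_qc"`.
#' @export
qc_locus <- function(locus) {
  stopifnot(inherits(locus, "locus_region"))
  len <- locus_length(locus)
  n <- nrow(locus$genes)
  structure(list(
    total_length = len, gene_count = n,
    length_in_expected_range = len >= 18445L && len <= 30217L,
    gene_count_in_expected_range = n >= 16L && n <= 28L),
    class = "locus_qc")
}

#' Partition a typed cwps locus into rhamnan and PSP regions
#'
#' The PSP-encoding region starts at the first gene called as the
#' priming glycosyltransferase (wpsA-like); everything before it is the
#' rhamnan-encoding region.  Loci with no priming-glycosyltransferase
#' call return `NA` and are flagged as non-canonical organisation
#' (the talan-producing arrangement).
#'
#' @param typed A `"typed_locus"` (see [assign_roles()]).
#' @return The input with `partition` (gene index or `NA`) and
#'   `organization` updated.
#' @export
partition_cwps <- function(typed) {
  stopifnot(inherits(typed, "typed_locus"))
  if (nrow(typed$roles) == 0L) stop("cannot partition an empty locus")
  idx <- which(typed$roles$role == "priming_gt")
  typed$partition <- if (length(idx)) idx[1] else NA_integer_
  typed$organization <- locus_organization(typed$roles)
  typed
}
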