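## Genomic context of a locus: keyword census of mobile-genetic-element
## annotations in the flanking windows, a density-based genomic-island
## heuristic, ICE component detection (relaxase + T4SS + T4CP without an
## origin of transfer), replicon and split flags.  The island boundaries
## are estimates; curated boundaries are out of scope.

MGE_CATEGORIES <- c("transposase", "integrase", "phage", "relaxase",
                    "t4ss", "t4cp", "conjugal", "defense", "amr")

count_mge <- function(products, mge) {
  counts <- setNames(integer(length(MGE_CATEGORIES)), MGE_CATEGORIES)
  if (!length(products)) return(counts)
  for (i in seq_len(nrow(mge))) {
    counts[mge$category[i]] <- counts[mge$category[i]] +
      sum(grepl(mge$pattern[i], products, ignore.case = TRUE))
  }
  counts
}

is_mge_product <- function(products, mge) {
  hit <- rep(FALSE, length(products))
  for (i in seq_len(nrow(mge)))
    hit <- hit | grepl(mge$pattern[i], products, ignore.case = TRUE)
  hit
}

#' Scan the genomic context of a locus
#'
#' Counts MGE-annotated genes by category in the up- and downstream
#' flanks, flags a genomic island when either flank reaches the MGE
#' density threshold (or the locus sits on a plasmid), estimates the
#' island span by extending from the locus edges over MGE-annotated
#' genes, and reports ICE components (relaxase + T4SS + T4CP) together
#' with the origin-of-transfer keyword check — all three components
#' without an OriT is noted as a non-self-transmissible element.
#'
#' @param g The [genome()] containing the locus.
#' @param locus A `"locus_region"`.
#' @param flank Flank window size in bases (default 30000, so a
#'   45-55 kb island around a locus is observable).
#' @param min_density Island threshold: MGE hits per 10 flank genes
#'   (default 3).
#' @param mge MGE keyword table ([mge_vocabulary()]).
#' @return A list of class `"mobility_report"`.
#' @export
scan_context <- function(g, locus, flank = 30000L, min_density = 3,
                         mge = mge_vocabulary()) {
  stopifnot(inherits(g, "genome"), inherits(locus, "locus_region"))
  fr <- locus$fragments[1, ]  # context of the primary fragment
  cid <- fr$contig_id
  clen <- g$contigs$length[g$contigs$id == cid]
  f <- sort_features(g$features[g$features$contig_id == cid, , drop = FALSE])
  up_win <- c(max(1L, fr$start - flank), max(1L, fr$start - 1L))
  dn_win <- c(min(clen, fr$end + 1L), min(clen, fr$end + flank))
  clamped <- (fr$start - flank) < 1L || (fr$end + flank) > clen
  in_locus <- f$locus_tag %in% locus$genes$locus_tag
  up <- f[!in_locus & f$end >= up_win[1] & f$start <= up_win[2], , drop = FALSE]
  dn <- f[!in_locus & f$end >= dn_win[1] & f$start <= dn_win[2], , drop = FALSE]
  hits_up <- count_mge(up$product, mge)
  hits_dn <- count_mge(dn$product, mge)
  dens <- function(hits, genes)
    if (nrow(genes) == 0L) 0 else 10 * sum(hits) / nrow(genes)
  repl <- g$contigs$replicon_class[g$contigs$id == cid]
  island <- dens(hits_up, up) >= min_density ||
    dens(hits_dn, dn) >= min_density || repl == "plasmid"

  span <- NA_integer_
  if (island) {
    ## extend from locus edges over MGE-annotated genes (allowing short
    ## interruptions) to estimate the island span
    mge_up <- is_mge_product(up$product, mge)
    mge_dn <- is_mge_product(dn$product, mge)
    ext <- function(flags) {
      miss <- 0L; last <- 0L
      for (i in seq_along(flags)) {
        if (flags[i]) { last <- i; miss <- 0L }
        else { miss <- miss + 1L; if (miss > 2L) break }
      }
      last
    }
    k_up <- ext(rev(mge_up))   # walk upstream away from the locus
    k_dn <- ext(mge_dn)
    lo <- if (k_up > 0L) up$start[nrow(up) - k_up + 1L] else fr$start
    hi <- if (k_dn > 0L) dn$end[k_dn] else fr$end
    span <- as.integer(hi - lo)
  }

  all_hits <- hits_up + hits_dn
  orit <- any(grepl("oriT|origin of transfer|nic site", c(up$product, dn$product),
                    ignore.case = TRUE))
  ice_no_orit <- all(all_hits[c("relaxase", "t4ss", "t4cp")] > 0L) && !orit
  structure(list(
    upstream_window = up_win, downstream_window = dn_win,
    mge_hits_up = hits_up, mge_hits_down = hits_dn,
    island_flag = island,
    island_span_estimate = if (island) span else NA_integer_,
    split_locus = nrow(locus$fragments) > 1L,
    replicon = repl, orit_found = orit,
    ice_without_orit = ice_no_orit,
    flank_clamped = clamped), class = "mobility_report")
}

#' @export
print.mobility_report <- function(x, ...) {
  cat(sprintf("<mobility_report> island: %s%s, replicon: %s%s\n",
              x$island_flag,
              if (!is.na(x$island_span_estimate))
                sprintf(" (~%s bp)", format(x$island_span_estimate,
                                            big.mark = ",")) else "",
              x$replicon,
              if (x$ice_without_orit) ", ICE without OriT" else ""))
  cat("  MGE hits up:  ",
      paste(sprintf("%s=%d", names(x$mge_hits_up),
                    x$mge_hits_up)[x$mge_hits_up > 0], collapse = " "), "\n")
  cat("  MGE hits down:",
      paste(sprintf("%s=%d", names(x$mge_hits_down),
                    x$mge_hits_down)[x$mge_hits_down > 0], collapse = " "), "\n")
  invisible(x)
}

#' Merge split locus fragments
#'
#' Two same-kind regions of one genome are merged into a two-fragment
#' locus iff both contain locus vocabulary, at least one carries a
#' transposase within `tnp_window` genes of its breakpoint-facing edge,
#' and their role sets are complementary (the union covers at least
#' `min_roles` distinct canonical roles).  More than two candidates are
#' reported with the best pair merged and a warning.  Merging is
#' symmetric in fragment order; a single region is returned unchanged.
#'
#' @param regions List of `"locus_region"` objects (one genome, one
#'   kind).
#' @param g The [genome()].
#' @param tnp_window Genes from the fragment edge within which a
#'   transposase counts as breakpoint-associated (default 3).
#' @param min_roles Minimum distinct canonical roles in the union
#'   (default 6).
#' @param vocab Keyword vocabulary.
#' @return List of `"locus_region"` objects after merging.
#' @export
detect_split_locus <- function(regions, g, tnp_window = 3L, min_roles = 6L,
                               vocab = role_vocabulary()) {
  if (length(regions) <= 1L) return(regions)
  kind <- unique(vapply(regions, `[[`, character(1), "kind"))
  stopifnot(length(kind) == 1L)
  if (length(regions) > 2L)
    warning("more than two candidate fragments; merging the best pair")

  roleset <- function(r) {
    rl <- match_product_role(r$genes$product, kind, vocab)
    unique(rl[!is.na(rl) & rl != "transposase"])
  }
  edge_tnp <- function(r, g) {
    ## transposase within tnp_window genes of either edge, inside the
    ## fragment or immediately beyond it on the contig
    f <- sort_features(g$features[g$features$contig_id ==
                                    r$fragments$contig_id[1], , drop = FALSE])
    idx <- which(f$locus_tag %in% r$genes$locus_tag)
    i0 <- min(idx); i1 <- max(idx)
    lo <- max(1L, i0 - tnp_window); hi <- min(nrow(f), i1 + tnp_window)
    near <- f$product[unique(c(lo:min(i0 + tnp_window - 1L, nrow(f)),
                               max(1L, i1 - tnp_window + 1L):hi))]
    any(grepl("transposase|insertion sequence|IS[0-9]", near,
              ignore.case = TRUE))
  }

  best <- NULL; best_cover <- -1L
  for (i in seq_along(regions)) for (j in seq_along(regions)) {
    if (i >= j) next
    a <- regions[[i]]; b <- regions[[j]]
    ra <- roleset(a); rb <- roleset(b)
    if (!length(ra) || !length(rb)) next
    if (!(edge_tnp(a, g) || edge_tnp(b, g))) next
    cover <- length(union(ra, rb))
    if (cover >= min_roles && cover > best_cover) {
      best <- c(i, j); best_cover <- cover
    }
  }
  if (is.null(best)) return(regions)
  a <- regions[[best[1]]]; b <- regions[[best[2]]]
  genes <- rbind(a$genes, b$genes)
  merged <- new_locus_region(a$genome_id, kind, genes,
                             rbind(a$anchor_hits, b$anchor_hits))
  ## keep fragment order by genomic position but both fragments distinct
  merged$fragments <- rbind(a$fragments, b$fragments)
  merged$fragments <- merged$fragments[order(merged$fragments$contig_id,
                                             merged$fragments$start), ,
                                       drop = FALSE]
  rownames(merged$fragments) <- NULL
  merged$genes <- sort_features(merged$genes)
  c(list(merged), regions[-best])
}
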