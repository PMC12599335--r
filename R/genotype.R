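## Genotype classification.  cwps genotypes are letters assigned by
## three explicit criteria (polymerase/co-polymerase presence, flippase
## presence, and >= 2 PSP genes under 30% combined similarity to a
## profile's exemplars); eps genotypes are roman numerals assigned by
## variable-region cluster similarity plus pathway-class identity.
## Unmatched loci mint the next label in the established series.

#' Create a genotype profile
#'
#' @param label Letter (cwps) or roman-numeral (eps) label.
#' @param kind `"cwps"` or `"eps"`.
#' @param has_polymerase,has_copolymerase,has_flippase Signature flags.
#' @param psp_exemplars Named character vector of exemplar proteins
#'   (PSP genes for cwps, variable-region genes for eps); flippase,
#'   polymerase and co-polymerase sequences are excluded by the callers.
#' @param pathway_class eps assembly pathway (`NA` for cwps).
#' @return A list of class `"genotype_profile"`.
#' @export
genotype_profile <- function(label, kind, has_polymerase, has_copolymerase,
                             has_flippase, psp_exemplars = character(),
                             pathway_class = NA_character_) {
  structure(list(label = label, kind = kind,
                 has_polymerase = has_polymerase,
                 has_copolymerase = has_copolymerase,
                 has_flippase = has_flippase,
                 psp_exemplars = psp_exemplars,
                 pathway_class = pathway_class),
            class = "genotype_profile")
}

#' Create a genotype database
#'
#' @param profiles List of [genotype_profile()] objects (insertion
#'   order is preserved; novel labels continue the series).
#' @param kind `"cwps"` or `"eps"`.
#' @return A list of class `"genotype_db"`.
#' @export
genotype_db <- function(profiles = list(), kind = c("cwps", "eps")) {
  kind <- match.arg(kind)
  labs <- vapply(profiles, `[[`, character(1), "label")
  if (anyDuplicated(labs)) stop("duplicate profile labels")
  structure(list(profiles = profiles, kind = kind), class = "genotype_db")
}

#' Historical cwps genotype profiles (flag level)
#'
#' The four previously described lactococcal cwps genotypes A-D,
#' packaged as presence/absence flags only (no exemplar proteins; users
#' may supply their own reference sequences).  With empty exemplar sets
#' these profiles can never satisfy the PSP-similarity criterion, so
#' novel label minting starts at E, continuing the established series.
#'
#' @return A `"genotype_db"` with profiles A-D.
#' @export
default_cwps_db <- function() {
  genotype_db(list(
    genotype_profile("A", "cwps", FALSE, FALSE, TRUE),
    genotype_profile("B", "cwps", TRUE, FALSE, TRUE),
    genotype_profile("C", "cwps", TRUE, TRUE, TRUE),
    genotype_profile("D", "cwps", TRUE, TRUE, TRUE)), "cwps")
}

#' @export
print.genotype_db <- function(x, ...) {
  cat(sprintf("<genotype_db> %s, %d profile(s): %s\n", x$kind,
              length(x$profiles),
              paste(vapply(x$profiles, `[[`, character(1), "label"),
                    collapse = ", ")))
  invisible(x)
}

letter_index <- function(label) {
  ch <- rev(strsplit(label, "")[[1]])
  sum((match(ch, LETTERS)) * 26^(seq_along(ch) - 1L))
}

index_letter <- function(i) {
  out <- character()
  while (i > 0L) {
    r <- (i - 1L) %% 26L + 1L
    out <- c(LETTERS[r], out)
    i <- (i - r) %/% 26L
  }
  paste(out, collapse = "")
}

#' Mint the next genotype label
#'
#' cwps labels continue the letter series after the maximum existing
#' label (A..Z then AA..); eps labels are successive roman numerals.
#'
#' @param db A `"genotype_db"`.
#' @return The next unused label.
#' @export
mint_label <- function(db) {
  labs <- vapply(db$profiles, `[[`, character(1), "label")
  if (db$kind == "cwps") {
    if (!length(labs)) return("A")
    index_letter(max(vapply(labs, letter_index, numeric(1))) + 1L)
  } else {
    if (!length(labs)) return("I")
    as.character(utils::as.roman(max(vapply(
      labs, function(l) as.integer(utils::as.roman(l)), integer(1))) + 1L))
  }
}

role_flags <- function(typed) {
  has <- function(r) any(typed$roles$role == r)
  list(pol = has("polymerase"), copol = has("copolymerase"),
       flip = has("flippase"))
}

#' Assign a cwps genotype
#'
#' Each profile in the database is tested with three criteria: (i) the
#' polymerase/co-polymerase presence flags differ, (ii) the flippase
#' presence differs, (iii) two or more of the locus's PSP genes
#' (excluding flippase, polymerase and co-polymerase) score below
#' `sim_threshold` (combined query cover x identity) against the
#' profile's exemplars.  The locus matches a profile iff no criterion
#' fires; among matches the highest mean best-hit similarity wins (ties
#' go to the earliest profile).  If every profile is rejected the locus
#' is novel: the next letter label is minted and a profile built from
#' the locus is appended to the database.
#'
#' @param typed A `"typed_locus"` with role calls (run [assign_roles()]
#'   and [partition_cwps()] first).
#' @param db A `"genotype_db"` of kind cwps (default [default_cwps_db()]).
#' @param sim_threshold Criterion-iii similarity threshold (default 30).
#' @param align [align_params()].
#' @return A `"genotype_call"`: `label`, `is_novel`, `matched_profile`,
#'   `criteria_fired` (list per rejected profile), `mean_similarity`,
#'   and the (possibly grown) database in `$db`.
#' @export
assign_cwps_genotype <- function(typed, db = default_cwps_db(),
                                 sim_threshold = 30, align = align_params()) {
  stopifnot(inherits(typed, "typed_locus"), db$kind == "cwps")
  if (nrow(typed$roles) == 0L || all(is.na(typed$roles$evidence) &
                                     typed$roles$role == "unknown"))
    stop("typed locus must carry role calls")
  fl <- role_flags(typed)
  psp <- psp_genes(typed)
  fired <- list(); means <- numeric()
  for (p in db$profiles) {
    crit <- character()
    if (fl$pol != p$has_polymerase || fl$copol != p$has_copolymerase)
      crit <- c(crit, "i")
    if (fl$flip != p$has_flippase) crit <- c(crit, "ii")
    if (length(p$psp_exemplars) == 0L) {
      sims <- rep(0, length(psp))
    } else if (length(psp)) {
      sims <- vapply(psp, function(q)
        best_hit(q, p$psp_exemplars, align)$score, numeric(1))
    } else sims <- numeric()
    if (sum(sims < sim_threshold) >= 2L) crit <- c(crit, "iii")
    fired[[p$label]] <- crit
    means[p$label] <- if (length(sims)) mean(sims) else 0
  }
  ok <- names(fired)[vapply(fired, length, integer(1)) == 0L]
  if (length(ok)) {
    best <- ok[order(-means[ok], match(ok, names(fired)))][1]
    call <- list(label = best, is_novel = FALSE, matched_profile = best,
                 criteria_fired = fired[setdiff(names(fired), best)],
                 mean_similarity = unname(means[best]), db = db)
  } else {
    lab <- mint_label(db)
    prof <- genotype_profile(lab, "cwps", fl$pol, fl$copol, fl$flip,
                             psp_exemplars = psp)
    db$profiles <- c(db$profiles, list(prof))
    call <- list(label = lab, is_novel = TRUE, matched_profile = NA_character_,
                 criteria_fired = fired,
                 mean_similarity = if (length(means)) max(means) else 0,
                 db = db)
  }
  class(call) <- "genotype_call"
  call
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("<genotype_call> %s%s (mean similarity %.1f)\n", x$label,
              if (x$is_novel) " [novel]" else "", x$mean_similarity))
  invisible(x)
}

#' Variable-region genes of a typed eps locus
#'
#' Genes after the conserved proximal block (epsRXABCD-style genes,
#' identified by the vocabulary's eps_block rows); when no conserved
#' block is present (the ABC-transporter genotypes) all genes except
#' regulators and transposases are used.
#'
#' @param typed A `"typed_locus"` of kind eps.
#' @param vocab Keyword vocabulary.
#' @return Named character vector of proteins.
#' @export
eps_variable_region <- function(typed, vocab = role_vocabulary()) {
  stopifnot(typed$kind == "eps")
  f <- typed$region$genes
  m <- match_vocab_row(f$product, vocab, "eps")
  blk <- !is.na(m$row) & m$vocab$eps_block[m$row] == 1L
  blk[is.na(blk)] <- FALSE
  first <- seq_len(nrow(f)) <= 8L
  keep <- if (any(blk & first)) seq_len(nrow(f)) > max(which(blk & first))
          else rep(TRUE, nrow(f))
  keep <- keep & !typed$roles$role %in% c("regulator", "transposase")
  prot <- f$protein[keep]
  names(prot) <- f$locus_tag[keep]
  prot[!is.na(prot)]
}

#' Assign an eps genotype
#'
#' The variable region of the locus is compared against each profile's
#' exemplars with [cluster_similarity()]; a profile matches iff the
#' length-weighted mean best-hit score reaches `match_threshold` and
#' the assembly pathway class is identical.  The best mean wins;
#' otherwise a novel roman-numeral label is minted.  The numeric
#' threshold is an explicit stand-in for an unstated boundary and is
#' reported with the call.
#'
#' @param typed A `"typed_locus"` of kind eps with role calls.
#' @param db A `"genotype_db"` of kind eps.
#' @param match_threshold Mean-similarity threshold (default 80).
#' @param align [align_params()].
#' @param vocab Keyword vocabulary.
#' @return A `"genotype_call"` with the updated database in `$db`.
#' @export
assign_eps_genotype <- function(typed, db = genotype_db(kind = "eps"),
                                match_threshold = 80, align = align_params(),
                                vocab = role_vocabulary()) {
  stopifnot(inherits(typed, "typed_locus"), typed$kind == "eps",
            db$kind == "eps")
  vr <- eps_variable_region(typed, vocab)
  if (length(vr) == 0L) {
    call <- list(label = NA_character_, is_novel = FALSE,
                 matched_profile = NA_character_, criteria_fired = list(),
                 mean_similarity = NA_real_, warning = "no variable-region genes",
                 db = db)
    class(call) <- "genotype_call"
    return(call)
  }
  pc <- typed$pathway_class
  means <- numeric()
  for (p in db$profiles) {
    if (!identical(p$pathway_class, pc) || length(p$psp_exemplars) == 0L) {
      means[p$label] <- -1  # pathway mismatch can never match
      next
    }
    means[p$label] <- cluster_similarity(vr, p$psp_exemplars,
                                         align)$mean_best_hit_score
  }
  ok <- names(means)[means >= match_threshold]
  if (length(ok)) {
    best <- ok[order(-means[ok], match(ok, names(means)))][1]
    call <- list(label = best, is_novel = FALSE, matched_profile = best,
                 criteria_fired = list(),
                 mean_similarity = unname(means[best]), db = db)
  } else {
    lab <- mint_label(db)
    prof <- genotype_profile(lab, "eps",
                             any(typed$roles$role == "polymerase"),
                             any(typed$roles$role == "copolymerase"),
                             any(typed$roles$role == "flippase"),
                             psp_exemplars = vr, pathway_class = pc)
    db$profiles <- c(db$profiles, list(prof))
    call <- list(label = lab, is_novel = TRUE, matched_profile = NA_character_,
                 criteria_fired = list(),
                 mean_similarity = if (any(means >= 0)) max(means[means >= 0])
                                   else NA_real_,
                 db = db)
  }
  class(call) <- "genotype_call"
  call
}
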