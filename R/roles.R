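## Per-gene functional role calls.  Rule precedence mirrors the
## inference order used for polysaccharide-locus gene maps: similarity
## against role-labelled exemplars first, annotation keywords second,
## membrane-topology heuristics as the fallback.

ROLE_LEVELS <- c("precursor_rmlA", "precursor_rmlB", "precursor_rmlC",
                 "precursor_rmlD", "rhamnosyltransferase", "abc_transporter",
                 "priming_gt", "membrane_anchor", "flippase", "polymerase",
                 "copolymerase", "psp_transferase", "glycosyltransferase",
                 "modification_acetylase", "modification_epimerase",
                 "modification_dehydratase", "modification_oxidoreductase",
                 "modification_other", "regulator", "transposase", "unknown")

RHAMNAN_CORE_ROLES <- c("precursor_rmlA", "precursor_rmlB", "precursor_rmlC",
                        "precursor_rmlD", "rhamnosyltransferase",
                        "abc_transporter")

#' Assign functional roles to every gene of a locus
#'
#' For each gene the first matching rule wins: (1) best hit with
#' combined score >= `role_sim_threshold` against the role-labelled
#' reference proteins; (2) keyword match on the product string; (3)
#' membrane-topology class (flippase-like -> flippase, polymerase-like
#' -> polymerase, co-polymerase-like -> copolymerase); otherwise
#' `unknown`.  Deterministic for fixed inputs.
#'
#' @param locus A `"locus_region"`.
#' @param refdb Named character vector of reference proteins; names are
#'   `role|name` (see [reference_proteins()]).  `NULL` disables the
#'   similarity rule.
#' @param topo Optional named list of `"tmh_profile"` objects keyed by
#'   locus_tag; computed from the proteins when missing.
#' @param role_sim_threshold Combined-score threshold for rule 1
#'   (default 40).
#' @param vocab Keyword vocabulary ([role_vocabulary()]).
#' @param align [align_params()].
#' @return A `"typed_locus"`: the region plus a `roles` data.frame
#'   (locus_tag, product, role, evidence, score, note), a partition
#'   placeholder, an `organization` flag and (for eps) `pathway_class`.
#' @export
assign_roles <- function(locus, refdb = reference_proteins(locus$kind),
                         topo = NULL, role_sim_threshold = 40,
                         vocab = role_vocabulary(), align = align_params()) {
  stopifnot(inherits(locus, "locus_region"))
  f <- locus$genes
  if (nrow(f) == 0L) stop("locus has no genes")
  n <- nrow(f)
  role <- rep("unknown", n); evid <- rep(NA_character_, n)
  score <- rep(NA_real_, n); note <- rep("", n)
  kw <- match_product_role(f$product, locus$kind, vocab)
  for (i in seq_len(n)) {
    if (!is.null(refdb) && length(refdb) && !is.na(f$protein[i])) {
      bh <- best_hit(f$protein[i], refdb, align)
      if (bh$score >= role_sim_threshold) {
        role[i] <- sub("\\|.*$", "", bh$subject_id)
        evid[i] <- "similarity"; score[i] <- bh$score
        next
      }
    }
    if (!is.na(kw[i])) {
      role[i] <- kw[i]; evid[i] <- "keyword"
      next
    }
    prof <- if (!is.null(topo) && f$locus_tag[i] %in% names(topo))
      topo[[f$locus_tag[i]]]
    else if (!is.na(f$protein[i]) && nchar(f$protein[i]) >= 15L)
      predict_tmh(f$protein[i]) else NULL
    if (!is.null(prof)) {
      hints <- if (grepl("DUF2142", f$product[i], ignore.case = TRUE))
        "DUF2142" else character()
      tc <- classify_topology(prof, hints)
      mapped <- switch(tc$label, flippase_like = "flippase",
                       polymerase_like = "polymerase",
                       copolymerase_like = "copolymerase", NA_character_)
      if (!is.na(mapped)) {
        role[i] <- mapped; evid[i] <- "topology"; note[i] <- tc$evidence
      }
    }
  }
  roles <- data.frame(locus_tag = f$locus_tag, product = f$product,
                      role = role, evidence = evid, score = score,
                      note = note, stringsAsFactors = FALSE)
  typed <- structure(list(region = locus, kind = locus$kind, roles = roles,
                          partition = NA_integer_,
                          organization = "undetermined",
                          pathway_class = NA_character_),
                     class = "typed_locus")
  if (locus$kind == "eps") typed$pathway_class <- classify_eps_pathway(typed)
  typed
}

#' @export
print.typed_locus <- function(x, ...) {
  cat(sprintf("<typed_locus> %s %s: %d genes, organization %s%s\n",
              x$region$genome_id, x$kind, nrow(x$roles), x$organization,
              if (!is.na(x$pathway_class))
                paste0(", pathway ", x$pathway_class) else ""))
  tab <- table(x$roles$role)
  cat("  roles:", paste(sprintf("%s x%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

locus_organization <- function(roles) {
  has <- function(r) any(roles$role == r)
  if (has("priming_gt")) {
    if (has("polymerase") || has("copolymerase")) "canonical_rhamnan_psp"
    else "oligomeric"
  } else "non_canonical"
}

#' Resolve DUF2142 polymerase / PSP-transferase ambiguity by position
#'
#' DUF2142-hinted membrane glycosyltransferases immediately adjacent to
#' a co-polymerase call are labelled `polymerase`; DUF2142 genes in a
#' locus with no co-polymerase anywhere are labelled `psp_transferase`
#' (YcaA-like ambiguity, recorded in the note field since the function
#' is not experimentally validated).  Loci without DUF2142 genes are
#' returned unchanged.
#'
#' @param typed A `"typed_locus"`.
#' @return The updated `"typed_locus"`.
#' @export
positional_disambiguation <- function(typed) {
  stopifnot(inherits(typed, "typed_locus"))
  r <- typed$roles
  ## only keyword/topology calls are ambiguous; similarity calls stand
  duf <- (grepl("DUF2142", r$product, ignore.case = TRUE) |
            (r$role == "polymerase" & !is.na(r$evidence) &
               r$evidence == "topology")) &
    !(!is.na(r$evidence) & r$evidence == "similarity")
  if (!any(duf)) return(typed)
  copol <- which(r$role == "copolymerase")
  for (i in which(duf)) {
    if (length(copol) && any(abs(copol - i) == 1L)) {
      r$role[i] <- "polymerase"
    } else if (!length(copol)) {
      r$role[i] <- "psp_transferase"
      r$note[i] <- trimws(paste(r$note[i], "ambiguous_ycaA_like"))
    }
  }
  typed$roles <- r
  if (typed$kind == "eps") typed$pathway_class <- classify_eps_pathway(typed)
  typed
}

#' Classify the eps assembly pathway
#'
#' `wzx_wzy` when both a flippase and a polymerase are called;
#' `abc_transporter` when an ABC-transporter role is present and both
#' Wzx/Wzy signature roles are absent; `undetermined` otherwise.
#'
#' @param typed A `"typed_locus"` of kind eps.
#' @return `"wzx_wzy"`, `"abc_transporter"` or `"undetermined"`.
#' @export
classify_eps_pathway <- function(typed) {
  stopifnot(inherits(typed, "typed_locus"), typed$kind == "eps")
  has <- function(role) any(typed$roles$role == role)
  if (has("flippase") && has("polymerase")) "wzx_wzy"
  else if (has("abc_transporter") && !has("flippase") && !has("polymerase"))
    "abc_transporter"
  else "undetermined"
}

#' PSP-encoding genes of a typed cwps locus
#'
#' For canonical loci, the genes from the partition (first priming
#' glycosyltransferase) onward; for non-canonical loci, all genes whose
#' roles are outside the conserved rhamnan core.  Flippase, polymerase,
#' co-polymerase, transposase and regulator genes are excluded in both
#' cases (the genotype criteria treat them separately).
#'
#' @param typed A partitioned `"typed_locus"`.
#' @return Named character vector of PSP proteins (names are
#'   locus_tags).
#' @export
psp_genes <- function(typed) {
  stopifnot(inherits(typed, "typed_locus"))
  r <- typed$roles
  keep <- if (!is.na(typed$partition))
    seq_len(nrow(r)) >= typed$partition
  else !r$role %in% RHAMNAN_CORE_ROLES
  keep <- keep & !r$role %in% c("flippase", "polymerase", "copolymerase",
                                "transposase", "regulator", "unknown")
  prot <- typed$region$genes$protein[keep]
  names(prot) <- r$locus_tag[keep]
  prot[!is.na(prot)]
}
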