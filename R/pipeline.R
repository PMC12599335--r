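## Cohort orchestration: per strain, locus detection -> split merging ->
## role assignment -> partitioning -> genotype calls -> context scan ->
## structure features, aggregated into a strain-table-style summary.

#' Pipeline configuration
#'
#' Named defaults for every tunable threshold in the pipeline.
#'
#' @param role_sim_threshold Similarity threshold for role calls
#'   (default 40).
#' @param cwps_sim_threshold Criterion-iii threshold (default 30).
#' @param eps_match_threshold eps genotype match threshold (default 80).
#' @param flank Context-scan window (default 30000 bases).
#' @param locus [locus_params()].
#' @param align [align_params()].
#' @param cwps_db Starting cwps genotype database
#'   (default [default_cwps_db()], the historical A-D profiles).
#' @param eps_db Starting eps genotype database (default empty, so the
#'   first eps genotype minted is I).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(role_sim_threshold = 40, cwps_sim_threshold = 30,
                            eps_match_threshold = 80, flank = 30000L,
                            locus = locus_params(), align = align_params(),
                            cwps_db = default_cwps_db(),
                            eps_db = genotype_db(kind = "eps")) {
  structure(list(role_sim_threshold = role_sim_threshold,
                 cwps_sim_threshold = cwps_sim_threshold,
                 eps_match_threshold = eps_match_threshold, flank = flank,
                 locus = locus, align = align, cwps_db = cwps_db,
                 eps_db = eps_db), class = "pipeline_config")
}

pick_main_region <- function(regions) {
  if (!length(regions)) return(NULL)
  regions[[order(-vapply(regions, function(r) nrow(r$genes), integer(1)))[1]]]
}

#' Run the full typing pipeline on a cohort of genomes
#'
#' Per strain: [find_locus()] for both kinds, [detect_split_locus()],
#' [assign_roles()], [positional_disambiguation()], [partition_cwps()],
#' [assign_cwps_genotype()] / [assign_eps_genotype()] (with
#' [classify_eps_pathway()]), [scan_context()] and
#' [predict_structure_features()].  Per-strain failures are logged and
#' reported as undetermined rows; the cohort never aborts.  The result
#' is deterministic for fixed inputs and configuration.
#'
#' @param genomes A list of [genome()] objects (or a single genome).
#' @param config A [pipeline_config()].
#' @return A `"cohort_summary"`; per-strain detail (typed loci, calls,
#'   mobility reports) is kept in the `details` field, the grown
#'   genotype databases in `cwps_db` / `eps_db`.
#' @export
run_pipeline <- function(genomes, config = pipeline_config()) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  if (!length(genomes)) stop("at least one genome is required")
  refdb_cw <- reference_proteins("cwps")
  refdb_ep <- reference_proteins("eps")
  cwps_db <- config$cwps_db
  eps_db <- config$eps_db
  rows <- list(); details <- list()

  for (g in genomes) {
    row <- data.frame(
      species = g$species, strain = g$id, cwps_label = NA_character_,
      cwps_fragments = 0L, cwps_length = NA_integer_, cwps_genes = NA_integer_,
      cwps_novel = NA, split_cwps = FALSE, organization = NA_character_,
      eps_label = NA_character_, eps_length = NA_integer_,
      pathway_class = NA_character_, island_flag = NA, ice_without_orit = NA,
      error = NA_character_, stringsAsFactors = FALSE)
    det <- list()
    res <- tryCatch({
      cw <- detect_split_locus(find_locus(g, "cwps", config$locus), g)
      cw_locus <- pick_main_region(cw)
      if (!is.null(cw_locus)) {
        typed <- assign_roles(cw_locus, refdb_cw,
                              role_sim_threshold = config$role_sim_threshold,
                              align = config$align)
        typed <- positional_disambiguation(typed)
        typed <- partition_cwps(typed)
        call <- assign_cwps_genotype(typed, cwps_db,
                                     sim_threshold = config$cwps_sim_threshold,
                                     align = config$align)
        cwps_db <- call$db
        mob <- scan_context(g, cw_locus, flank = config$flank)
        row$cwps_label <- call$label
        row$cwps_fragments <- nrow(cw_locus$fragments)
        row$cwps_length <- locus_length(cw_locus)
        row$cwps_genes <- nrow(cw_locus$genes)
        row$cwps_novel <- call$is_novel
        row$split_cwps <- mob$split_locus
        row$organization <- typed$organization
        det$cwps <- list(typed = typed, call = call, mobility = mob,
                         qc = qc_locus(cw_locus),
                         features = predict_structure_features(typed))
      }
      ep <- detect_split_locus(find_locus(g, "eps", config$locus), g)
      ep_locus <- pick_main_region(ep)
      if (!is.null(ep_locus)) {
        etyped <- assign_roles(ep_locus, refdb_ep,
                               role_sim_threshold = config$role_sim_threshold,
                               align = config$align)
        etyped <- positional_disambiguation(etyped)
        ecall <- assign_eps_genotype(etyped, eps_db,
                                     match_threshold = config$eps_match_threshold,
                                     align = config$align)
        eps_db <- ecall$db
        emob <- scan_context(g, ep_locus, flank = config$flank)
        row$eps_label <- ecall$label
        row$eps_length <- locus_length(ep_locus)
        row$pathway_class <- etyped$pathway_class
        row$island_flag <- emob$island_flag
        row$ice_without_orit <- emob$ice_without_orit
        det$eps <- list(typed = etyped, call = ecall, mobility = emob)
      }
      TRUE
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$error <- conditionMessage(res)
      message("strain ", g$id, " failed: ", row$error)
    }
    rows[[g$id]] <- row
    details[[g$id]] <- det
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  out <- summarize_rows(tab)
  out$details <- details
  out$cwps_db <- cwps_db
  out$eps_db <- eps_db
  out
}

summarize_rows <- function(tab) {
  cw_labs <- sort(unique(tab$cwps_label[!is.na(tab$cwps_label)]))
  ep_labs <- unique(tab$eps_label[!is.na(tab$eps_label)])
  per_species <- lapply(split(tab, tab$species), function(s)
    list(cwps = sort(unique(s$cwps_label[!is.na(s$cwps_label)])),
         eps = sort(unique(s$eps_label[!is.na(s$eps_label)]))))
  cw_by_sp <- lapply(per_species, `[[`, "cwps")
  shared <- cw_labs[vapply(cw_labs, function(l)
    sum(vapply(cw_by_sp, function(s) l %in% s, logical(1))) >= 2L, logical(1))]
  exclusive <- lapply(cw_by_sp, function(s) setdiff(s, shared))
  lens <- tab$cwps_length[!is.na(tab$cwps_length)]
  structure(list(
    rows = tab,
    n_strains = nrow(tab),
    n_with_cwps = sum(!is.na(tab$cwps_label)),
    n_with_eps = sum(!is.na(tab$eps_label)),
    distinct_cwps_labels = cw_labs,
    distinct_eps_labels = ep_labs,
    per_species_label_sets = per_species,
    shared_cwps_labels = shared,
    exclusive_cwps_labels = exclusive,
    cwps_length_min = if (length(lens)) min(lens) else NA_integer_,
    cwps_length_max = if (length(lens)) max(lens) else NA_integer_),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d strain(s)\n", x$n_strains))
  cat(sprintf("  cwps: %d/%d typed, %d genotype(s): %s\n", x$n_with_cwps,
              x$n_strains, length(x$distinct_cwps_labels),
              paste(x$distinct_cwps_labels, collapse = ", ")))
  cat(sprintf("  eps:  %d/%d typed, %d genotype(s): %s\n", x$n_with_eps,
              x$n_strains, length(x$distinct_eps_labels),
              paste(x$distinct_eps_labels, collapse = ", ")))
  if (!is.na(x$cwps_length_min))
    cat(sprintf("  cwps cluster lengths: %s - %s bp\n",
                format(x$cwps_length_min, big.mark = ","),
                format(x$cwps_length_max, big.mark = ",")))
  if (length(x$shared_cwps_labels))
    cat(sprintf("  shared cwps genotypes: %s\n",
                paste(x$shared_cwps_labels, collapse = ", ")))
  invisible(x)
}

#' Summarise the packaged strain table
#'
#' Computes the cohort summary directly from the printed genotype
#' labels and fragment coordinates (bypassing all sequence stages):
#' distinct genotype counts, eps presence, per-strain cluster lengths
#' (`end - start`, summed over split fragments), species-shared and
#' species-exclusive labels, and length extremes.
#'
#' @param tb Output of [load_table1_fixture()] (default loads it).
#' @return A `"cohort_summary"`.
#' @export
summarize_fixture <- function(tb = load_table1_fixture()) {
  recs <- strain_records(tb)
  rows <- do.call(rbind, lapply(recs, function(r) {
    cw_len <- sum(r$cwps_fragments[, "end"] - r$cwps_fragments[, "start"])
    ep_len <- if (nrow(r$eps_fragments))
      sum(r$eps_fragments[, "end"] - r$eps_fragments[, "start"]) else NA_integer_
    data.frame(species = r$species, strain = r$strain,
               cwps_label = r$cwps_genotype,
               cwps_fragments = nrow(r$cwps_fragments),
               cwps_length = cw_len, cwps_genes = NA_integer_,
               cwps_novel = NA, split_cwps = nrow(r$cwps_fragments) > 1L,
               organization = NA_character_,
               eps_label = r$eps_genotype, eps_length = ep_len,
               pathway_class = NA_character_, island_flag = NA,
               ice_without_orit = NA, error = NA_character_,
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  summarize_rows(rows)
}

#' Adjusted Rand index between two labellings
#'
#' Small self-contained implementation of the permutation-model
#' adjusted Rand index, used to compare recovered genotype partitions
#' against generator truth.
#'
#' @param a,b Two label vectors of equal length (`NA`-free).
#' @return The adjusted Rand index (1 for identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
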