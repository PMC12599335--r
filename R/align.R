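## Pairwise protein similarity.  The similarity of two
## proteins is reported as query cover x percent identity (both in
## percent, combined score scaled back to 0-100).  Alignments are
## Smith-Waterman local alignments with BLOSUM62 and BLAST-like affine
## gap penalties, computed in-process via Biostrings.

#' Alignment parameters
#'
#' @param matrix Substitution matrix name (only `"BLOSUM62"` is packaged).
#' @param gap_open,gap_extend Affine gap penalties (positive costs); a gap
#'   of length k costs `gap_open + k * gap_extend`.
#' @param sim_threshold Default similarity threshold used by the
#'   genotyping rules (combined score, percent).
#' @return A list of class `"align_params"`.
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                         sim_threshold = 30) {
  stopifnot(matrix == "BLOSUM62")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, sim_threshold = sim_threshold),
            class = "align_params")
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

check_protein <- function(x, what = "sequence") {
  if (length(x) != 1L || is.na(x) || !nzchar(x))
    stop(what, " must be a non-empty protein string")
  chars <- strsplit(x, "")[[1]]
  bad <- setdiff(chars, AA_ALPHABET_OK)
  if (length(bad))
    stop(what, " contains non-amino-acid symbols: ",
         paste(unique(bad), collapse = ""))
  invisible(x)
}

#' Align two proteins and score query cover x identity
#'
#' Computes the optimal Smith-Waterman local alignment of `query`
#' against `subject` and reports percent identity over alignment columns
#' (gaps included, BLAST convention), query coverage as the aligned
#' query span over the query length, and the combined score
#' `pid * qcov / 100`.  A pair with no positive-scoring local alignment
#' scores 0.  `qcov` (and hence the score) is direction-dependent; `pid`
#' is not for symmetric sequences.
#'
#' @param query,subject Protein strings (20-letter alphabet plus X/*).
#' @param params [align_params()].
#' @param query_id,subject_id Optional labels carried into the result.
#' @return A list of class `"alignment_result"` with fields `query_id`,
#'   `subject_id`, `identities`, `alignment_columns`,
#'   `aligned_query_span`, `query_length`, `subject_length`, `raw_score`,
#'   `pid`, `qcov`, `score`.
#' @export
align_proteins <- function(query, subject, params = align_params(),
                           query_id = "query", subject_id = "subject") {
  check_protein(query, "query")
  check_protein(subject, "subject")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  raw <- BiocGenerics::score(aln)
  if (raw <= 0) {
    res <- list(query_id = query_id, subject_id = subject_id,
                identities = 0L, alignment_columns = 0L,
                aligned_query_span = 0L,
                query_length = nchar(query), subject_length = nchar(subject),
                raw_score = 0, pid = 0, qcov = 0, score = 0)
    class(res) <- "alignment_result"
    return(res)
  }
  idn <- Biostrings::nmatch(aln)
  cols <- Biostrings::nchar(aln)  # alignment length including gaps
  qspan <- BiocGenerics::end(Biostrings::pattern(aln)) -
    BiocGenerics::start(Biostrings::pattern(aln)) + 1L
  pid <- 100 * idn / cols
  qcov <- 100 * qspan / nchar(query)
  res <- list(query_id = query_id, subject_id = subject_id,
              identities = as.integer(idn), alignment_columns = as.integer(cols),
              aligned_query_span = as.integer(qspan),
              query_length = nchar(query), subject_length = nchar(subject),
              raw_score = raw, pid = pid, qcov = qcov,
              score = pid * qcov / 100)
  class(res) <- "alignment_result"
  res
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment> %s vs %s: pid %.1f%%, qcov %.1f%%, score %.1f\n",
              x$query_id, x$subject_id, x$pid, x$qcov, x$score))
  invisible(x)
}

#' Best hit of a query against a set of subjects
#'
#' Ties on the combined score are broken by higher percent identity,
#' then by lexicographic subject id.  A query with only zero-scoring
#' subjects still returns a (zero-score) result.
#'
#' @param query Protein string.
#' @param subjects Named character vector (or list) of protein strings.
#' @param params [align_params()].
#' @return An `"alignment_result"` for the best subject.
#' @export
best_hit <- function(query, subjects, params = align_params()) {
  if (length(subjects) == 0L) stop("subject list must be non-empty")
  tab <- score_against_set(query, subjects, params)
  ord <- order(-tab$score, -tab$pid, tab$subject_id)
  i <- ord[1]
  res <- list(query_id = "query", subject_id = tab$subject_id[i],
              identities = tab$identities[i],
              alignment_columns = tab$alignment_columns[i],
              aligned_query_span = tab$aligned_query_span[i],
              query_length = nchar(query),
              subject_length = tab$subject_length[i],
              raw_score = tab$raw_score[i], pid = tab$pid[i],
              qcov = tab$qcov[i], score = tab$score[i])
  class(res) <- "alignment_result"
  res
}

## Vectorized scoring of one query against a set of subjects: one
## pairwiseAlignment call with the subjects as the (vectorised) pattern
## and the query as the single Biostrings subject.  Query-side spans are
## therefore read from the Biostrings subject() accessor.
score_against_set <- function(query, subjects, params = align_params()) {
  check_protein(query, "query")
  subjects <- unlist(subjects)
  ids <- names(subjects)
  if (is.null(ids)) ids <- sprintf("subject%d", seq_along(subjects))
  for (s in subjects) check_protein(s, "subject")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(subjects), Biostrings::AAString(query),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  raw <- BiocGenerics::score(aln)
  idn <- Biostrings::nmatch(aln)
  cols <- Biostrings::nchar(aln)
  qaln <- Biostrings::subject(aln)
  qspan <- BiocGenerics::end(qaln) - BiocGenerics::start(qaln) + 1L
  pid <- ifelse(raw > 0, 100 * idn / cols, 0)
  qcov <- ifelse(raw > 0, 100 * qspan / nchar(query), 0)
  data.frame(subject_id = ids,
             identities = ifelse(raw > 0, as.integer(idn), 0L),
             alignment_columns = ifelse(raw > 0, as.integer(cols), 0L),
             aligned_query_span = ifelse(raw > 0, as.integer(qspan), 0L),
             subject_length = nchar(subjects),
             raw_score = pmax(raw, 0), pid = pid, qcov = qcov,
             score = pid * qcov / 100, stringsAsFactors = FALSE)
}

#' Gene-set similarity between two clusters
#'
#' For every gene in `genes_a`, the best hit against `genes_b` is
#' computed; the cluster score is the query-length-weighted mean of the
#' best-hit combined scores.  The fraction of reciprocal best-hit pairs
#' is reported alongside.  Gene order does not affect the result.
#'
#' @param genes_a,genes_b Named character vectors of proteins (query set
#'   and subject set).
#' @param params [align_params()].
#' @return A list of class `"cluster_similarity"` with
#'   `mean_best_hit_score`, `per_gene_best` (data.frame) and
#'   `reciprocal_fraction`.
#' @export
cluster_similarity <- function(genes_a, genes_b, params = align_params()) {
  if (length(genes_a) == 0L || length(genes_b) == 0L)
    stop("both gene sets must be non-empty")
  genes_a <- unlist(genes_a); genes_b <- unlist(genes_b)
  if (is.null(names(genes_a))) names(genes_a) <- sprintf("a%d", seq_along(genes_a))
  if (is.null(names(genes_b))) names(genes_b) <- sprintf("b%d", seq_along(genes_b))
  best_ab <- lapply(names(genes_a), function(n) {
    tab <- score_against_set(genes_a[[n]], genes_b, params)
    tab[order(-tab$score, -tab$pid, tab$subject_id)[1], ]
  })
  per_gene <- data.frame(
    gene = names(genes_a),
    partner = vapply(best_ab, function(r) r$subject_id, character(1)),
    score = vapply(best_ab, function(r) r$score, numeric(1)),
    stringsAsFactors = FALSE)
  w <- nchar(genes_a)
  mean_score <- sum(per_gene$score * w) / sum(w)
  ## reciprocal: gene a's best partner b has a as its own best partner
  best_ba <- vapply(names(genes_b), function(n)
    best_hit(genes_b[[n]], genes_a, params)$subject_id, character(1))
  recip <- mean(best_ba[per_gene$partner] == per_gene$gene, na.rm = TRUE)
  structure(list(mean_best_hit_score = mean_score, per_gene_best = per_gene,
                 reciprocal_fraction = recip),
            class = "cluster_similarity")
}
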