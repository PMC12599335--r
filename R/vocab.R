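## Packaged keyword vocabularies.  Both tables are plain TSV and can be
## replaced by the user (paths accepted everywhere a vocabulary is used).

#' Load the role keyword vocabulary
#'
#' @param path TSV with columns `role`, `kind`, `anchor`, `eps_block`,
#'   `pattern`; defaults to the packaged vocabulary.
#' @return A `data.frame`; row order defines match precedence.
#' @export
role_vocabulary <- function(path = system.file("extdata", "role_keywords.tsv",
                                               package = "cwpstyper",
                                               mustWork = TRUE)) {
  v <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("role", "kind", "anchor", "eps_block", "pattern") %in% names(v)))
  v
}

#' Load the mobile-genetic-element keyword model
#'
#' @param path TSV with columns `category`, `pattern`.
#' @return A `data.frame`.
#' @export
mge_vocabulary <- function(path = system.file("extdata", "mge_keywords.tsv",
                                              package = "cwpstyper",
                                              mustWork = TRUE)) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

## First matching vocabulary row for each product string (or NA).
## kind filters rows to that locus kind plus "both" rows.
match_vocab_row <- function(products, vocab, kind = NULL) {
  if (!is.null(kind)) vocab <- vocab[vocab$kind %in% c(kind, "both"), , drop = FALSE]
  out <- rep(NA_integer_, length(products))
  todo <- seq_along(products)
  for (i in seq_len(nrow(vocab))) {
    if (!length(todo)) break
    hit <- grepl(vocab$pattern[i], products[todo], ignore.case = TRUE)
    out[todo[hit]] <- i
    todo <- todo[!hit]
  }
  ## map back to row index in the filtered table
  list(row = out, vocab = vocab)
}

#' Match product strings to functional roles by keyword
#'
#' @param products Character vector of product annotations.
#' @param kind `"cwps"`, `"eps"` or `NULL` (no kind filter).
#' @param vocab Vocabulary table from [role_vocabulary()].
#' @return Character vector of roles (`NA` where no row matches).
#' @export
match_product_role <- function(products, kind = NULL, vocab = role_vocabulary()) {
  m <- match_vocab_row(products, vocab, kind)
  ifelse(is.na(m$row), NA_character_, m$vocab$role[m$row])
}

is_hypothetical <- function(products) {
  grepl("hypothetical protein|uncharacteri[sz]ed protein", products,
        ignore.case = TRUE)
}
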