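# Independent oracles used across the suite.  These are deliberately
# naive implementations (quadratic dynamic programming, per-codon
# translation) kept separate from the package's own code paths.

get_blosum62 <- local({
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

# Smith-Waterman optimal local score with affine gaps (a gap of length
# k costs open + k*ext), straight quadratic DP over three states.
sw_oracle_score <- function(query, subject, open = 11, ext = 1) {
  b <- get_blosum62()
  q <- strsplit(query, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  n <- length(q); m <- length(s)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    sub <- b[q[i - 1], s[j - 1]]
    M[i, j] <- max(0, sub + max(M[i - 1, j - 1], X[i - 1, j - 1],
                                Y[i - 1, j - 1]))
    best <- max(best, M[i, j])
  }
  best
}

# Re-score an alignment result from its aligned strings: positional
# identity count and column count must agree with what the package
# reported, and the re-derived BLOSUM62/affine score must equal the
# reported raw score.
rescore_alignment <- function(pat, sub, open = 11, ext = 1) {
  b <- get_blosum62()
  p <- strsplit(pat, "")[[1]]
  s <- strsplit(sub, "")[[1]]
  stopifnot(length(p) == length(s))
  sc <- 0; idn <- 0L
  in_gap <- FALSE
  for (k in seq_along(p)) {
    if (p[k] == "-" || s[k] == "-") {
      sc <- sc - ext - if (in_gap) 0 else open
      in_gap <- TRUE
    } else {
      sc <- sc + b[p[k], s[k]]
      if (p[k] == s[k]) idn <- idn + 1L
      in_gap <- FALSE
    }
  }
  list(score = sc, identities = idn, columns = length(p))
}

# per-codon translation oracle (bacterial table 11), independent of
# Biostrings::translate
CODON_TABLE11 <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  g <- expand.grid(b3 = bases, b2 = bases, b1 = bases,
                   stringsAsFactors = FALSE)
  codons <- paste0(g$b1, g$b2, g$b3)
  setNames(aas, codons)
})

translate_oracle <- function(nt, strand = "+") {
  nt <- toupper(nt)
  if (strand == "-") {
    comp <- chartr("ACGT", "TGCA", nt)
    nt <- paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }
  codons <- substring(nt, seq(1, nchar(nt) - 2, 3), seq(3, nchar(nt), 3))
  aa <- unname(CODON_TABLE11[codons])
  aa[is.na(aa)] <- "X"
  aa <- paste(aa, collapse = "")
  sub("\\*$", "", aa)
}

random_aa <- function(n, seed) {
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

random_nt <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# constructed k-helix protein: charged tails, 21-Leu helices separated
# by 15-residue EK loops
k_helix_protein <- function(k) {
  tail20 <- paste(rep(c("E", "K"), 10), collapse = "")
  loop15 <- substr(paste(rep(c("E", "K"), 8), collapse = ""), 1, 15)
  helix <- strrep("L", 21)
  if (k == 0) return(strrep(paste0(tail20, loop15), 3))
  mid <- paste(rep(helix, k), collapse = loop15)
  paste0(tail20, mid, tail20)
}
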