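## Membrane-topology heuristics in the TMHMM-era style: Kyte-Doolittle
## hydropathy over a sliding window calls transmembrane helices; a
## simple n-region/h-region rule calls Sec-type signal peptides.  The
## class rules (flippase 12-14 TMHs, DUF2142 polymerase 10-12 TMHs,
## co-polymerase signal + large outer loop + <=2 TMHs) mirror the
## structural signatures used to type polysaccharide-locus proteins.

KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2,
  X = 0, `*` = -4.5)

#' Predict transmembrane helices by windowed hydropathy
#'
#' Residues whose centred mean Kyte-Doolittle hydropathy over `window`
#' positions exceeds `threshold` seed helix calls; windows are expanded
#' to their full span, runs separated by at most `merge_gap` residues
#' are merged, spans shorter than `min_helix` are dropped and spans
#' longer than `max_helix` are trimmed symmetrically.  Deterministic.
#'
#' @param protein Amino-acid string (length >= 15 for any call).
#' @param window Sliding window width (odd; default 19).
#' @param threshold Mean-hydropathy cutoff (default 1.6).
#' @param merge_gap Maximum gap between merged spans (default 3).
#' @param min_helix,max_helix Span length bounds (default 15 and 35).
#' @return A list of class `"tmh_profile"`: `helices` (matrix of
#'   start/end residue spans), `count`, `signal_peptide`,
#'   `max_outer_loop` (longest non-membrane stretch), `too_short`
#'   (warning flag for inputs shorter than the window).
#' @export
predict_tmh <- function(protein, window = 19L, threshold = 1.6,
                        merge_gap = 3L, min_helix = 15L, max_helix = 35L) {
  check_protein(protein, "protein")
  n <- nchar(protein)
  aa <- strsplit(protein, "")[[1]]
  h <- KYTE_DOOLITTLE[aa]
  h[is.na(h)] <- 0
  if (n < window) {
    prof <- list(helices = cbind(start = integer(), end = integer()),
                 count = 0L, signal_peptide = FALSE,
                 max_outer_loop = n, too_short = TRUE)
    class(prof) <- "tmh_profile"
    return(prof)
  }
  half <- (window - 1L) %/% 2L
  means <- as.numeric(stats::filter(h, rep(1 / window, window), sides = 2))
  centers <- which(!is.na(means) & means > threshold)
  spans <- NULL
  if (length(centers)) {
    runs <- split(centers, cumsum(c(1L, diff(centers) > 1L)))
    spans <- do.call(rbind, lapply(runs, function(r)
      c(start = max(1L, min(r) - half), end = min(n, max(r) + half))))
    spans <- spans[order(spans[, 1]), , drop = FALSE]
    ## merge spans separated by <= merge_gap
    merged <- spans[1, , drop = FALSE]
    if (nrow(spans) > 1) for (i in 2:nrow(spans)) {
      last <- nrow(merged)
      if (spans[i, 1] - merged[last, 2] - 1L <= merge_gap)
        merged[last, 2] <- max(merged[last, 2], spans[i, 2])
      else merged <- rbind(merged, spans[i, , drop = FALSE])
    }
    spans <- merged
    keep <- spans[, 2] - spans[, 1] + 1L >= min_helix
    spans <- spans[keep, , drop = FALSE]
    if (nrow(spans)) for (i in seq_len(nrow(spans))) {
      len <- spans[i, 2] - spans[i, 1] + 1L
      if (len > max_helix) {
        trim <- len - max_helix
        spans[i, 1] <- spans[i, 1] + trim %/% 2L
        spans[i, 2] <- spans[i, 1] + max_helix - 1L
      }
    }
    rownames(spans) <- NULL
  }
  if (is.null(spans)) spans <- cbind(start = integer(), end = integer())
  ## longest non-membrane stretch (N-terminal, inter-helix or C-terminal)
  if (nrow(spans) == 0L) loop <- n
  else {
    bounds <- c(0L, as.vector(t(spans)), n + 1L)
    gaps <- diff(bounds)[seq(1, by = 2, length.out = nrow(spans) + 1L)] - 1L
    loop <- max(gaps)
  }
  prof <- list(helices = spans, count = nrow(spans),
               signal_peptide = detect_signal_peptide_spans(protein, spans),
               max_outer_loop = as.integer(loop), too_short = FALSE)
  class(prof) <- "tmh_profile"
  prof
}

#' @export
print.tmh_profile <- function(x, ...) {
  cat(sprintf("<tmh_profile> %d helices%s, max outer loop %d aa\n", x$count,
              if (x$signal_peptide) " + signal peptide" else "",
              x$max_outer_loop))
  invisible(x)
}

#' Detect a Sec-type signal peptide heuristically
#'
#' True iff the first 30 residues contain a positively charged n-region
#' (a K/R within the first 7 residues) followed by a hydrophobic
#' h-region of at least 7 consecutive residues with Kyte-Doolittle
#' hydropathy > 1.5, and no predicted transmembrane helix starts within
#' residues 31-60.  Proteins shorter than 25 residues return `FALSE`.
#'
#' @param protein Amino-acid string.
#' @return Logical.
#' @export
detect_signal_peptide <- function(protein) {
  prof_spans <- tryCatch(predict_tmh(protein)$helices,
                         error = function(e) cbind(start = integer(),
                                                   end = integer()))
  detect_signal_peptide_spans(protein, prof_spans)
}

detect_signal_peptide_spans <- function(protein, spans) {
  n <- nchar(protein)
  if (n < 25L) return(FALSE)
  aa <- strsplit(substr(protein, 1, 30), "")[[1]]
  npos <- which(aa[seq_len(min(7L, length(aa)))] %in% c("K", "R"))
  if (!length(npos)) return(FALSE)
  h <- KYTE_DOOLITTLE[aa]
  h[is.na(h)] <- 0
  hydro <- h > 1.5
  hydro[seq_len(max(npos))] <- FALSE  # h-region must follow the n-region
  r <- rle(hydro)
  if (!any(r$values & r$lengths >= 7L)) return(FALSE)
  ## no further helix starting in 31..60
  !any(spans[, 1] >= 31L & spans[, 1] <= 60L)
}

#' Classify membrane topology into polysaccharide-locus roles
#'
#' Deterministic rule set over a [predict_tmh()] profile and domain
#' hints (annotation substrings or an ingested domain table):
#' `polymerase_like` for a DUF2142 hint with 10-12 helices (takes
#' precedence over the flippase rule at 12 helices), `flippase_like`
#' for 12-14 helices without the hint, `copolymerase_like` for a signal
#' peptide with at most 2 helices and an outer loop of at least 100
#' residues, `soluble` for no helices, otherwise `membrane_enzyme`.
#'
#' @param profile A `"tmh_profile"`.
#' @param domain_hints Character vector of domain names (e.g.
#'   `"DUF2142"`).
#' @return A list of class `"topology_class"` with `label` and
#'   `evidence`.
#' @export
classify_topology <- function(profile, domain_hints = character()) {
  stopifnot(inherits(profile, "tmh_profile"))
  has_duf <- any(grepl("DUF2142", domain_hints, ignore.case = TRUE))
  n <- profile$count
  if (has_duf && n >= 10L && n <= 12L)
    lab <- list("polymerase_like",
                sprintf("DUF2142 hint with %d TMHs", n))
  else if (n >= 12L && n <= 14L && !has_duf)
    lab <- list("flippase_like", sprintf("%d TMHs, MOP-exporter-like", n))
  else if (profile$signal_peptide && n <= 2L && profile$max_outer_loop >= 100L)
    lab <- list("copolymerase_like",
                sprintf("signal peptide, %d TMH(s), %d-residue outer loop",
                        n, profile$max_outer_loop))
  else if (n == 0L)
    lab <- list("soluble", "no predicted TMH")
  else
    lab <- list("membrane_enzyme", sprintf("%d TMHs", n))
  structure(list(label = lab[[1]], evidence = lab[[2]]),
            class = "topology_class")
}
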