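## Glycan composition masses and genotype -> structure-feature
## prediction.  Masses are neutral-molecule masses built from residue
## (anhydro) masses plus one water, with phosphate (HPO3) and O-acetyl
## (C2H2O) increments; borohydride reduction of the reducing end adds
## two hydrogens, each deuterium label replacing one of them with D.

MONO_MASS <- c(hex = 162.0528, dhex = 146.0579, hexnac = 203.0794,
               water = 18.0106, phosphate = 79.9663, acetyl = 42.0106,
               H = 1.00783, D = 2.01410)
## average masses from standard atomic weights (C 12.011, H 1.008,
## N 14.007, O 15.999, P 30.974)
AVG_MASS <- c(hex = 162.141, dhex = 146.142, hexnac = 203.194,
              water = 18.015, phosphate = 79.980, acetyl = 42.037,
              H = 1.008, D = 2.014)

#' Construct a glycan composition
#'
#' @param hex,dhex,hexnac Residue counts (hexose, 6-deoxyhexose such as
#'   rhamnose or 6-deoxytalose, N-acetylhexosamine).
#' @param phosphate Phosphate monoester count.
#' @param acetyl O-acetyl count.
#' @param reduced `TRUE` for a borohydride-reduced reducing end.
#' @param deuterium_labels Number of deuterium labels (NaBD4 reduction);
#'   requires `reduced`.
#' @return A list of class `"glycan_composition"`.
#' @export
glycan_composition <- function(hex = 0L, dhex = 0L, hexnac = 0L,
                               phosphate = 0L, acetyl = 0L, reduced = FALSE,
                               deuterium_labels = 0L) {
  counts <- c(hex = hex, dhex = dhex, hexnac = hexnac,
              phosphate = phosphate, acetyl = acetyl,
              deuterium_labels = deuterium_labels)
  if (any(counts < 0)) stop("composition counts must be >= 0")
  if (deuterium_labels > 0L && !reduced)
    stop("deuterium labels require a reduced composition")
  structure(list(hex = as.integer(hex), dhex = as.integer(dhex),
                 hexnac = as.integer(hexnac),
                 phosphate = as.integer(phosphate),
                 acetyl = as.integer(acetyl), reduced = isTRUE(reduced),
                 deuterium_labels = as.integer(deuterium_labels)),
            class = "glycan_composition")
}

#' Parse a compact composition string
#'
#' Grammar: whitespace-separated tokens `Hex<n>`, `dHex<n>`,
#' `HexNAc<n>`, `P<n>` (phosphate), `Ac<n>` (O-acetyl), `red`
#' (reduced), `red+D` or `D<n>` (deuterium labels, implying `red`).
#' Counts default to 1 when omitted.  Example: `"Hex6 P1 red+D"`.
#'
#' @param x Composition string.
#' @return A `"glycan_composition"`.
#' @export
parse_composition <- function(x) {
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  args <- list(hex = 0L, dhex = 0L, hexnac = 0L, phosphate = 0L,
               acetyl = 0L, reduced = FALSE, deuterium_labels = 0L)
  cnt <- function(tok, prefix) {
    v <- sub(paste0("^", prefix), "", tok)
    if (v == "") 1L else as.integer(v)
  }
  for (tok in toks) {
    if (grepl("^HexNAc[0-9]*$", tok)) args$hexnac <- args$hexnac + cnt(tok, "HexNAc")
    else if (grepl("^dHex[0-9]*$", tok)) args$dhex <- args$dhex + cnt(tok, "dHex")
    else if (grepl("^Hex[0-9]*$", tok)) args$hex <- args$hex + cnt(tok, "Hex")
    else if (grepl("^P[0-9]*$", tok)) args$phosphate <- args$phosphate + cnt(tok, "P")
    else if (grepl("^Ac[0-9]*$", tok)) args$acetyl <- args$acetyl + cnt(tok, "Ac")
    else if (tok == "red") args$reduced <- TRUE
    else if (grepl("^red\\+D[0-9]*$", tok)) {
      args$reduced <- TRUE
      args$deuterium_labels <- args$deuterium_labels + cnt(tok, "red\\+D")
    } else if (grepl("^D[0-9]*$", tok)) {
      args$reduced <- TRUE
      args$deuterium_labels <- args$deuterium_labels + cnt(tok, "D")
    } else stop("cannot parse composition token '", tok, "'")
  }
  do.call(glycan_composition, args)
}

#' Neutral mass of a glycan composition
#'
#' Monoisotopic and average neutral-molecule masses: the sum of residue
#' masses plus one water, phosphate and acetyl increments, and for
#' reduced compositions two added hydrogens with one H replaced by D
#' per deuterium label.  The printed-precision comparison used in
#' reports is the nearest-integer monoisotopic mass.
#'
#' @param comp A `"glycan_composition"` or composition string for
#'   [parse_composition()].
#' @return Named numeric vector `c(monoisotopic=, average=)` in u.
#' @export
composition_mass <- function(comp) {
  if (is.character(comp)) comp <- parse_composition(comp)
  stopifnot(inherits(comp, "glycan_composition"))
  nres <- comp$hex + comp$dhex + comp$hexnac
  if (nres < 1L) stop("composition must contain at least one residue")
  m <- function(tab) {
    mass <- comp$hex * tab["hex"] + comp$dhex * tab["dhex"] +
      comp$hexnac * tab["hexnac"] + tab["water"] +
      comp$phosphate * tab["phosphate"] + comp$acetyl * tab["acetyl"]
    if (comp$reduced)
      mass <- mass + (2L - comp$deuterium_labels) * tab["H"] +
        comp$deuterium_labels * tab["D"]
    unname(mass)
  }
  c(monoisotopic = m(MONO_MASS), average = m(AVG_MASS))
}

#' Predict precursor and structure features from a typed cwps locus
#'
#' Rule set linking role calls to sugar precursors and modifications:
#' rml precursor roles imply dTDP-rhamnose; a talose 4-dehydrogenase
#' annotation additionally implies dTDP-6-deoxy-talose (the dehydrogenase
#' acts on the rhamnose-pathway intermediate, so it requires the rml
#' genes); an NAD-dependent epimerase implies UDP-galactose; UDP-glucose
#' is always listed as the baseline; an acetylase implies O-acetylation.
#' The organisation note reflects canonical vs non-canonical assembly.
#'
#' @param typed A `"typed_locus"` with role calls.
#' @return A list of class `"structure_features"` with `precursors`,
#'   `modifications` and `organization_note`.
#' @export
predict_structure_features <- function(typed) {
  stopifnot(inherits(typed, "typed_locus"))
  r <- typed$roles
  prec <- "UDP-Glc"
  mods <- character()
  has_rml <- any(r$role %in% c("precursor_rmlA", "precursor_rmlB",
                               "precursor_rmlC", "precursor_rmlD"))
  if (has_rml) prec <- c(prec, "dTDP-Rha")
  if (has_rml && any(grepl("talose 4-dehydrogenase", r$product,
                           ignore.case = TRUE)))
    prec <- c(prec, "dTDP-6dTal")
  if (any(r$role == "modification_epimerase")) prec <- c(prec, "UDP-Gal")
  if (any(r$role == "modification_acetylase")) mods <- c(mods, "O-acetylation")
  if (any(grepl("phosphotransferase|kinase", r$product, ignore.case = TRUE)))
    mods <- c(mods, "phosphorylation_candidate")
  note <- switch(typed$organization,
    canonical_rhamnan_psp = "canonical rhamnan-PSP dual-chain assembly",
    oligomeric = "priming glycosyltransferase without polymerase/co-polymerase: PSP likely oligomeric",
    non_canonical = "no priming glycosyltransferase/flippase homologs: assembly pathway distinct from the dual-chain model",
    "undetermined organization")
  structure(list(precursors = sort(unique(prec)), modifications = mods,
                 organization_note = note), class = "structure_features")
}
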