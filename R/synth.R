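## Synthetic annotated genomes with implantable cwps/eps loci of known
## genotype, controlled protein divergence, transposase insertions and
## split loci, and MGE-rich island flanks -- plus truth tables, so every
## pipeline stage is testable without downloads.  Template proteins are
## synthetic (composition-biased random sequences with role-appropriate
## membrane architectures), not copies of real proteins.

## -- seeded RNG plumbing ----------------------------------------------------

## splittable deterministic seeds: fold a label into a 31-bit integer
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  h <- as.numeric(seed) %% 2147483563
  for (v in utf8ToInt(parts)) h <- (h * 31 + v) %% 2147483563
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

POLAR_AA <- strsplit("DEKRQNSTGH", "")[[1]]
HYDRO_AA <- strsplit("LIVFAM", "")[[1]]
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## soluble enzyme-like protein: starts with M, mixed composition
soluble_protein <- function(len, seed) {
  with_seed(seed, paste0("M", paste(sample(AA20, len - 1L, replace = TRUE),
                                    collapse = "")))
}

## membrane protein with n_tmh hydrophobic helices; optional Sec signal
## peptide and a large N-proximal outer loop (co-polymerase shape)
membrane_protein <- function(n_tmh, seed, loop_len = 18L, helix_len = 21L,
                             signal = FALSE, big_loop = 0L, tail_len = 20L) {
  with_seed(seed, {
    seg <- function(n, pool) paste(sample(pool, n, replace = TRUE), collapse = "")
    parts <- if (signal) paste0("MKK", seg(10L, c("L", "I", "V", "A")), "AQA")
             else paste0("M", seg(tail_len, POLAR_AA))
    if (big_loop > 0L) parts <- c(parts, seg(big_loop, POLAR_AA))
    for (k in seq_len(n_tmh)) {
      parts <- c(parts, seg(helix_len, HYDRO_AA))
      if (k < n_tmh) parts <- c(parts, seg(loop_len, POLAR_AA))
    }
    parts <- c(parts, seg(tail_len, POLAR_AA))
    paste(parts, collapse = "")
  })
}

## -- divergence -------------------------------------------------------------

#' Diverge a protein to a target identity
#'
#' Applies BLOSUM-weighted substitutions (and optionally sparse indels)
#' so that the ungapped identity to the original lands within +/- 5
#' points of `target_identity`.  Deterministic per seed.
#'
#' @param seq Protein string of length >= 30.
#' @param target_identity Target percent identity in (0, 100].
#' @param seed Integer seed.
#' @param indels Number of single-residue indels to sprinkle in
#'   (default 0; identity is measured on the substituted positions
#'   before indels are applied).
#' @return The diverged protein string.
#' @export
diverge_protein <- function(seq, target_identity, seed, indels = 0L) {
  n <- nchar(seq)
  if (n < 30L) stop("sequence too short to diverge (need >= 30 residues)")
  if (target_identity <= 0 || target_identity > 100)
    stop("target_identity must be in (0, 100]")
  if (target_identity == 100 && indels == 0L) return(seq)
  k <- round(n * (1 - target_identity / 100))
  if (n - k < 1L) k <- n - 1L
  b <- blosum62()[AA20, AA20]
  with_seed(seed, {
    aa <- strsplit(seq, "")[[1]]
    pos <- sample(n, k)
    for (p in pos) {
      orig <- aa[p]
      if (!orig %in% AA20) next
      alts <- setdiff(AA20, orig)
      w <- exp(b[orig, alts] / 2)
      aa[p] <- sample(alts, 1L, prob = w)
    }
    if (indels > 0L) for (i in seq_len(indels)) {
      if (stats::runif(1) < 0.5 && length(aa) > 30L) {
        aa <- aa[-sample(length(aa), 1L)]
      } else {
        at <- sample(length(aa), 1L)
        aa <- append(aa, sample(AA20, 1L), after = at)
      }
    }
    paste(aa, collapse = "")
  })
}

## -- template library -------------------------------------------------------

TEMPLATE_MASTER_SEED <- 777001L

tpl_gene <- function(slot, role, product, gene_name = NA_character_,
                     maker = c("soluble", "membrane"), len = 240L,
                     n_tmh = 0L, signal = FALSE, big_loop = 0L) {
  list(slot = slot, role = role, product = product, gene_name = gene_name,
       maker = match.arg(maker), len = len, n_tmh = n_tmh, signal = signal,
       big_loop = big_loop)
}

cwps_core_slots <- function() list(
  tpl_gene("rmlA", "precursor_rmlA", "glucose-1-phosphate thymidylyltransferase RmlA", "rmlA", len = 290L),
  tpl_gene("rmlB", "precursor_rmlB", "dTDP-glucose 4,6-dehydratase RmlB", "rmlB", len = 330L),
  tpl_gene("rmlC", "precursor_rmlC", "dTDP-4-dehydrorhamnose 3,5-epimerase RmlC", "rmlC", len = 190L),
  tpl_gene("rmlD", "precursor_rmlD", "dTDP-4-dehydrorhamnose reductase RmlD", "rmlD", len = 280L),
  tpl_gene("rgpA", "rhamnosyltransferase", "rhamnosyltransferase RgpA", "rgpA", len = 380L),
  tpl_gene("rgpB", "rhamnosyltransferase", "rhamnosyltransferase RgpB", "rgpB", len = 380L),
  tpl_gene("rgpC", "abc_transporter", "polysaccharide ABC transporter ATP-binding protein RgpC", "rgpC", len = 250L),
  tpl_gene("rgpD", "abc_transporter", "polysaccharide ABC transporter permease RgpD", "rgpD", "membrane", n_tmh = 6L))

## shorthand builders for variable PSP / eps genes
gt_slot <- function(i) tpl_gene(sprintf("gt%d", i), "glycosyltransferase",
                                "glycosyltransferase", len = 320L)
duf_pol_slot <- function() tpl_gene("wpsI", "polymerase",
  "glycosyltransferase, DUF2142 domain-containing protein", "wpsI",
  "membrane", n_tmh = 11L)
copol_slot <- function() tpl_gene("wpsH", "copolymerase",
  "bactoprenol glycosyltransferase", "wpsH", "membrane", n_tmh = 2L,
  signal = TRUE, big_loop = 170L)
flippase_slot <- function() tpl_gene("wpsG", "flippase",
  "polysaccharide flippase WpsG", "wpsG", "membrane", n_tmh = 13L)
priming_slot <- function() tpl_gene("wpsA", "priming_gt",
  "priming glycosyltransferase WpsA", "wpsA", len = 230L)
anchor_slot <- function() tpl_gene("wpsB", "membrane_anchor",
  "PSP membrane anchor WpsB", "wpsB", "membrane", n_tmh = 4L)

cwps_template_slots <- function(label) {
  core <- cwps_core_slots()
  psp <- switch(label,
    E = list(  # non-canonical talan organisation
      tpl_gene("rgpE", "rhamnosyltransferase", "rhamnosyltransferase RgpE", "rgpE", len = 360L),
      tpl_gene("tal", "modification_oxidoreductase",
               "dTDP-6-deoxy-L-talose 4-dehydrogenase (EC 1.1.1.134)", "tld", len = 300L),
      gt_slot(1),
      tpl_gene("oafA", "modification_acetylase", "OafA superfamily O-acetylase",
               "oafA", "membrane", n_tmh = 10L),
      tpl_gene("sulf", "modification_other", "sulfatase-like hydrolase/transferase",
               "wpsS", "membrane", n_tmh = 11L),
      duf_pol_slot(), copol_slot()),
    F = list(priming_slot(), anchor_slot(), gt_slot(1), gt_slot(2), gt_slot(3),
             flippase_slot(),
             tpl_gene("epi", "modification_epimerase", "NAD-dependent epimerase", len = 310L),
             tpl_gene("oafA", "modification_acetylase", "O-acetylase OafA family", len = 200L),
             duf_pol_slot(), copol_slot(),
             tpl_gene("wpsJ", "psp_transferase",
                      "PSP transferase WpsJ, DUF2142 domain-containing protein", "wpsJ",
                      "membrane", n_tmh = 11L)),
    G = list(gt_slot(1), gt_slot(2),
             tpl_gene("epi", "modification_epimerase", "NAD-dependent epimerase", len = 310L),
             tpl_gene("pyr", "modification_other", "polysaccharide pyruvyl transferase", len = 280L),
             duf_pol_slot(), copol_slot()),
    H = list(priming_slot(), anchor_slot(), gt_slot(1), gt_slot(2), gt_slot(3),
             gt_slot(4), flippase_slot(),
             tpl_gene("oafA", "modification_acetylase", "O-acetyltransferase", len = 210L),
             duf_pol_slot(), copol_slot()),
    I = list(priming_slot(), gt_slot(1), gt_slot(2), gt_slot(3), gt_slot(4),
             gt_slot(5),
             tpl_gene("epi", "modification_epimerase", "NAD-dependent epimerase", len = 310L),
             flippase_slot(), duf_pol_slot(), copol_slot()),
    J = list(priming_slot(), anchor_slot(), gt_slot(1), gt_slot(2), gt_slot(3),
             flippase_slot(),
             tpl_gene("deh", "modification_dehydratase", "polysaccharide dehydratase", len = 290L)),
    K = list(priming_slot(), anchor_slot(), gt_slot(1), gt_slot(2), gt_slot(3),
             flippase_slot(),
             tpl_gene("wpsI", "polymerase",
                      "polysaccharide polymerase WpsI, DUF2142 domain-containing protein",
                      "wpsI", "membrane", n_tmh = 11L),
             tpl_gene("wpsH", "copolymerase", "co-polymerase WpsH", "wpsH",
                      "membrane", n_tmh = 1L, signal = TRUE, big_loop = 170L)),
    L = list(priming_slot(), anchor_slot(), gt_slot(1), gt_slot(2), gt_slot(3),
             gt_slot(4), gt_slot(5),
             tpl_gene("deh", "modification_dehydratase", "polysaccharide dehydratase", len = 290L),
             flippase_slot(), duf_pol_slot(), copol_slot()),
    stop("unknown cwps template '", label, "'"))
  c(core, psp)
}

eps_core_block <- function(which = c("full", "abc_only", "none")) {
  which <- match.arg(which)
  full <- list(
    tpl_gene("epsR", "regulator", "transcriptional regulator EpsR", "epsR", len = 180L),
    tpl_gene("epsX", "regulator", "polysaccharide biosynthesis protein EpsX", "epsX", len = 200L),
    tpl_gene("epsA", "membrane_anchor", "capsular polysaccharide biosynthesis protein EpsA", "epsA", len = 240L),
    tpl_gene("epsB", "regulator", "tyrosine-protein kinase EpsB", "epsB", len = 230L),
    tpl_gene("epsC", "regulator", "phosphotyrosine-protein phosphatase EpsC", "epsC", len = 240L),
    tpl_gene("epsD", "regulator", "capsular polysaccharide biosynthesis protein EpsD", "epsD", len = 230L))
  switch(which, full = full, abc_only = full[3:5], none = list())
}

eps_wzx_slot <- function(named) {
  if (named) tpl_gene("wzx", "flippase", "polysaccharide flippase Wzx", "wzx",
                      "membrane", n_tmh = 13L)
  else tpl_gene("wzx", "flippase", "hypothetical protein", "wzx",
                "membrane", n_tmh = 13L)
}

eps_wzy_slot <- function(named) {
  if (named) tpl_gene("wzy", "polymerase", "oligosaccharide repeat unit polymerase Wzy",
                      "wzy", "membrane", n_tmh = 11L)
  else tpl_gene("wzy", "polymerase",
                "hypothetical protein, DUF2142 domain-containing", "wzy",
                "membrane", n_tmh = 11L)
}

eps_terminal <- function() list(
  tpl_gene("epsL", "regulator", "polysaccharide biosynthesis protein EpsL", "epsL", len = 190L),
  tpl_gene("orfY", "regulator", "modulator OrfY", "orfY", len = 170L))

eps_template_slots <- function(label) {
  mod <- function(slot, role, prod, len = 260L) tpl_gene(slot, role, prod, len = len)
  gts <- function(n) lapply(seq_len(n), gt_slot)
  switch(label,
    I = c(eps_core_block("full"), list(eps_wzx_slot(TRUE)), gts(3),
          list(eps_wzy_slot(FALSE)), eps_terminal()),
    II = c(eps_core_block("abc_only"), list(eps_wzx_slot(TRUE)), gts(4),
           list(mod("ac", "modification_acetylase", "polysaccharide O-acetyltransferase"),
                eps_wzy_slot(FALSE)), eps_terminal()),
    III = c(eps_core_block("full"), list(eps_wzx_slot(FALSE)), gts(8),
            list(mod("pt", "modification_other", "putative phosphotransferase"),
                 eps_wzy_slot(FALSE)), eps_terminal()),
    IV = c(eps_core_block("full"), list(eps_wzx_slot(TRUE)), gts(5),
           list(mod("epi", "modification_epimerase", "NAD-dependent epimerase"),
                eps_wzy_slot(FALSE)), eps_terminal()),
    V = c(eps_core_block("full"), list(eps_wzx_slot(FALSE)), gts(4),
          list(mod("deh", "modification_dehydratase", "sugar epimerase/dehydratase"),
               eps_wzy_slot(TRUE)), eps_terminal()),
    VI = c(eps_core_block("abc_only"), list(eps_wzx_slot(FALSE)), gts(4),
           list(mod("ac", "modification_acetylase", "polysaccharide O-acetyltransferase"),
                mod("deh", "modification_dehydratase", "dTDP-sugar dehydratase"),
                mod("epi", "modification_epimerase", "UDP-glucose 4-epimerase"),
                eps_wzy_slot(FALSE)), eps_terminal()),
    VII = c(eps_core_block("abc_only"), list(eps_wzx_slot(FALSE)), gts(3),
            list(eps_wzy_slot(TRUE),
                 mod("pt", "modification_other", "glycerophosphotransferase")),
            eps_terminal()),
    VIII = c(eps_core_block("abc_only"), list(eps_wzx_slot(FALSE)), gts(4),
             list(mod("epi", "modification_epimerase", "NAD-dependent epimerase"),
                  eps_wzy_slot(FALSE)), eps_terminal()),
    IX = c(eps_core_block("full"), list(eps_wzx_slot(FALSE)), gts(5),
           list(mod("ac", "modification_acetylase", "O-acetyltransferase"),
                eps_wzy_slot(FALSE)), eps_terminal()),
    X = c(eps_terminal(), list(
          tpl_gene("kpsT", "abc_transporter", "capsular polysaccharide ABC transporter ATP-binding protein", len = 230L),
          tpl_gene("kpsM", "abc_transporter", "capsular polysaccharide ABC transporter permease",
                   maker = "membrane", n_tmh = 6L)),
          gts(5), list(mod("pt", "modification_other", "putative phosphotransferase"))),
    XI = c(eps_terminal(), list(
          tpl_gene("kpsT", "abc_transporter", "capsular polysaccharide ABC transporter ATP-binding protein", len = 230L),
          tpl_gene("kpsM", "abc_transporter", "capsular polysaccharide ABC transporter permease",
                   maker = "membrane", n_tmh = 6L)),
          gts(4), list(mod("epi", "modification_epimerase", "NAD-dependent epimerase"),
                       mod("deh", "modification_dehydratase", "polysaccharide dehydratase"))),
    stop("unknown eps template '", label, "'"))
}

## slots whose protein is shared across templates (conserved genes)
SHARED_SLOTS <- c("rmlA", "rmlB", "rmlC", "rmlD", "rgpA", "rgpB", "rgpC",
                  "rgpD", "epsR", "epsX", "epsA", "epsB", "epsC", "epsD",
                  "epsL", "orfY")

make_template_protein <- function(kind, label, i, slot) {
  scope <- if (slot$slot %in% SHARED_SLOTS) "shared" else label
  sd <- derive_seed(TEMPLATE_MASTER_SEED, kind, scope, slot$slot, i)
  if (slot$maker == "membrane")
    membrane_protein(slot$n_tmh, sd, signal = slot$signal,
                     big_loop = slot$big_loop)
  else soluble_protein(slot$len, sd)
}

#' The packaged locus template library
#'
#' Canonical role layouts for the cwps genotypes E-L and eps genotypes
#' I-XI, with deterministic synthetic proteins (shared sequences for the
#' conserved rml/rgp and eps proximal/terminal genes).  Each template is
#' a data.frame with columns `slot`, `role`, `product`, `gene_name`,
#' `protein`.
#'
#' @return A list with elements `cwps` and `eps` (named lists of
#'   data.frames).
#' @export
template_library <- function() {
  cached <- .pkg_cache$templates
  if (!is.null(cached)) return(cached)
  build <- function(kind, labels, slots_fun) {
    out <- list()
    for (lab in labels) {
      slots <- slots_fun(lab)
      out[[lab]] <- data.frame(
        slot = vapply(slots, `[[`, character(1), "slot"),
        role = vapply(slots, `[[`, character(1), "role"),
        product = vapply(slots, `[[`, character(1), "product"),
        gene_name = vapply(slots, `[[`, character(1), "gene_name"),
        protein = vapply(seq_along(slots), function(i)
          make_template_protein(kind, lab, i, slots[[i]]), character(1)),
        stringsAsFactors = FALSE)
    }
    out
  }
  lib <- list(cwps = build("cwps", c("E", "F", "G", "H", "I", "J", "K", "L"),
                           cwps_template_slots),
              eps = build("eps", as.character(utils::as.roman(1:11)),
                          eps_template_slots))
  .pkg_cache$templates <- lib
  lib
}

.pkg_cache <- new.env(parent = emptyenv())

#' Role-labelled reference proteins
#'
#' Exemplar proteins for the similarity route of [assign_roles()] and
#' [find_locus()], drawn from the template library.  Names follow the
#' `role|name` convention; duplicated conserved sequences are collapsed.
#'
#' @param kind `"cwps"`, `"eps"` or `"both"`.
#' @return Named character vector of proteins.
#' @export
reference_proteins <- function(kind = c("both", "cwps", "eps")) {
  kind <- match.arg(kind)
  key <- paste0("refdb_", kind)
  cached <- .pkg_cache[[key]]
  if (!is.null(cached)) return(cached)
  lib <- template_library()
  take <- function(k) {
    out <- character()
    for (lab in names(lib[[k]])) {
      t <- lib[[k]][[lab]]
      v <- setNames(t$protein, sprintf("%s|%s.%s", t$role, lab, t$slot))
      out <- c(out, v)
    }
    out
  }
  db <- switch(kind, both = c(take("cwps"), take("eps")), cwps = take("cwps"),
               eps = take("eps"))
  db <- db[!duplicated(db)]
  .pkg_cache[[key]] <- db
  db
}

## -- strain generation ------------------------------------------------------

HOUSEKEEPING <- c(
  "30S ribosomal protein S4", "50S ribosomal protein L2",
  "translation elongation factor Tu", "chaperonin GroEL",
  "co-chaperonin GroES", "septation ring formation regulator EzrA",
  "N-acetylmuramoyl-L-alanine amidase", "glutamyl aminopeptidase",
  "DNA gyrase subunit A", "preprotein translocase subunit SecA")

MGE_PRODUCTS <- c(
  "IS6 family transposase", "site-specific integrase",
  "phage portal protein", "phage tail protein", "relaxase MobA",
  "type IV secretion system protein VirB4",
  "type IV coupling protein TraG", "conjugal transfer protein",
  "abortive infection protein AbiV", "enterocin A immunity protein")

#' Specify a synthetic strain
#'
#' @param strain_id,species_label Identifiers.
#' @param cwps_template,eps_template Template labels (or `NA` for no
#'   implant).
#' @param divergence_identity Target percent identity of the implanted
#'   proteins to their templates (default 85, the within-genotype
#'   divergence regime).
#' @param split_cwps Split the cwps locus into two distant fragments
#'   with breakpoint transposases.
#' @param implant_island Surround the eps locus with a 45-55 kb
#'   MGE-annotated genomic island.
#' @param transposase_insertions Extra transposase genes inserted into
#'   the cwps locus interior.
#' @param seed Integer seed.
#' @return A list of class `"strain_spec"`.
#' @export
strain_spec <- function(strain_id, species_label = "Synthetic sp.",
                        cwps_template = NA_character_,
                        eps_template = NA_character_,
                        divergence_identity = 97, split_cwps = FALSE,
                        implant_island = FALSE, transposase_insertions = 0L,
                        seed = 1L) {
  if (split_cwps && is.na(cwps_template))
    stop("split_cwps requires a cwps template")
  if (divergence_identity <= 0 || divergence_identity > 100)
    stop("divergence_identity must be in (0, 100]")
  structure(list(strain_id = strain_id, species_label = species_label,
                 cwps_template = cwps_template, eps_template = eps_template,
                 divergence_identity = divergence_identity,
                 split_cwps = split_cwps, implant_island = implant_island,
                 transposase_insertions = as.integer(transposase_insertions),
                 seed = as.integer(seed)), class = "strain_spec")
}

## internal builder: rows of (product, gene_name, protein, role, block)
filler_rows <- function(n, seed, block) {
  pool_seed <- derive_seed(TEMPLATE_MASTER_SEED, "filler-pool")
  pool <- .pkg_cache$filler_pool
  if (is.null(pool)) {
    pool <- vapply(seq_along(HOUSEKEEPING), function(i)
      soluble_protein(300L, derive_seed(pool_seed, i)), character(1))
    .pkg_cache$filler_pool <- pool
  }
  idx <- ((seq_len(n) - 1L) %% length(pool)) + 1L
  data.frame(product = HOUSEKEEPING[idx], gene_name = NA_character_,
             protein = pool[idx], role = "filler", block = block,
             stringsAsFactors = FALSE)
}

mge_rows <- function(n, seed, block) {
  idx <- ((seq_len(n) - 1L) %% length(MGE_PRODUCTS)) + 1L
  prot <- vapply(seq_len(n), function(i)
    soluble_protein(280L, derive_seed(seed, "mge", block, i)), character(1))
  data.frame(product = MGE_PRODUCTS[idx], gene_name = NA_character_,
             protein = prot, role = "mge", block = block,
             stringsAsFactors = FALSE)
}

tnp_row <- function(seed, block, i = 1L) {
  data.frame(product = "IS30 family transposase", gene_name = NA_character_,
             protein = soluble_protein(270L, derive_seed(seed, "tnp", block, i)),
             role = "transposase", block = block, stringsAsFactors = FALSE)
}

locus_rows <- function(kind, label, divergence, seed, block) {
  t <- template_library()[[kind]][[label]]
  prot <- vapply(seq_len(nrow(t)), function(i)
    diverge_protein(t$protein[i], divergence,
                    derive_seed(seed, kind, label, t$slot[i], i)),
    character(1))
  data.frame(product = t$product, gene_name = t$gene_name, protein = prot,
             role = t$role, block = block, stringsAsFactors = FALSE)
}

#' Generate one synthetic annotated genome
#'
#' Builds a single circular chromosome of housekeeping filler genes
#' with the requested implants at recorded positions: a cwps locus
#' (optionally split into two fragments >= 100 kb apart with breakpoint
#' transposases), an eps locus (optionally embedded in a 45-55 kb
#' MGE-rich genomic island), and extra transposase insertions.  Gene
#' coordinates, per-gene roles, genotype labels, island spans and split
#' breakpoints are returned as the truth table.
#'
#' @param spec A [strain_spec()].
#' @return A list with elements `genome` ([genome()]) and `truth`.
#' @export
generate_strain <- function(spec) {
  stopifnot(inherits(spec, "strain_spec"))
  lib <- template_library()
  if (!is.na(spec$cwps_template) && is.null(lib$cwps[[spec$cwps_template]]))
    stop("unknown cwps template '", spec$cwps_template, "'")
  if (!is.na(spec$eps_template) && is.null(lib$eps[[spec$eps_template]]))
    stop("unknown eps template '", spec$eps_template, "'")
  sd <- spec$seed

  rows <- filler_rows(25L, sd, "lead")
  if (!is.na(spec$cwps_template)) {
    cw <- locus_rows("cwps", spec$cwps_template, spec$divergence_identity,
                     sd, "cwps")
    if (spec$transposase_insertions > 0L) {
      at <- min(10L, nrow(cw) - 1L)  # inside the PSP-encoding region
      for (i in seq_len(spec$transposase_insertions))
        cw <- rbind(cw[seq_len(at + i - 1L), ], tnp_row(sd, "cwps", i),
                    cw[(at + i):nrow(cw), ])
    }
    if (spec$split_cwps) {
      cut <- ceiling(nrow(cw) / 2)
      frag1 <- rbind(cw[seq_len(cut), ], tnp_row(sd, "cwps_bk1"))
      frag2 <- rbind(tnp_row(sd, "cwps_bk2"), cw[(cut + 1L):nrow(cw), ])
      frag1$block <- "cwps"; frag2$block <- "cwps2"
      rows <- rbind(rows, frag1, filler_rows(120L, sd, "sep"), frag2)
    } else {
      rows <- rbind(rows, cw)
    }
  }
  rows <- rbind(rows, filler_rows(30L, sd, "mid"))
  if (!is.na(spec$eps_template)) {
    ep <- locus_rows("eps", spec$eps_template, spec$divergence_identity,
                     sd, "eps")
    if (spec$implant_island) {
      rows <- rbind(rows, mge_rows(24L, sd, "island_up"), ep,
                    mge_rows(12L, sd, "island_down"))
    } else {
      rows <- rbind(rows, ep)
    }
  }
  rows <- rbind(rows, filler_rows(25L, sd, "tail"))

  ## lay genes on the chromosome: 3*len+3 bp per CDS, jittered gaps
  n <- nrow(rows)
  gaps <- with_seed(derive_seed(sd, "gaps"), sample(60:140, n, replace = TRUE))
  lens <- 3L * nchar(rows$protein) + 3L
  starts <- integer(n); ends <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    starts[i] <- pos + gaps[i]
    ends[i] <- starts[i] + lens[i] - 1L
    pos <- ends[i]
  }
  clen <- pos + 200L
  tags <- sprintf("%s_%05d", gsub("[^A-Za-z0-9]", "", spec$strain_id),
                  seq_len(n) * 5L)
  feats <- gene_feature(contig_id = "chromosome", start = starts, end = ends,
                        strand = "+", locus_tag = tags,
                        gene_name = rows$gene_name, product = rows$product,
                        protein = rows$protein)
  g <- genome(spec$strain_id, spec$species_label,
              contig("chromosome", clen, "circular", "chromosome"), feats)

  blk <- rows$block
  span <- function(sel) if (any(sel)) c(min(starts[sel]), max(ends[sel])) else NULL
  cw_sel1 <- blk == "cwps"; cw_sel2 <- blk == "cwps2"
  ep_sel <- blk == "eps"
  isl_sel <- blk %in% c("island_up", "eps", "island_down")
  roles <- setNames(rows$role, tags)
  truth <- list(
    strain_id = spec$strain_id, species = spec$species_label,
    cwps_label = spec$cwps_template, eps_label = spec$eps_template,
    cwps_fragments = do.call(rbind, Filter(Negate(is.null),
                                           list(span(cw_sel1), span(cw_sel2)))),
    eps_fragments = if (any(ep_sel)) rbind(span(ep_sel)) else NULL,
    cwps_locus_tags = tags[cw_sel1 | cw_sel2],
    eps_locus_tags = tags[ep_sel],
    roles = roles[!(roles %in% c("filler", "mge"))],
    island_span = if (any(blk == "island_up")) span(isl_sel) else NULL,
    split_cwps = spec$split_cwps)
  list(genome = g, truth = truth)
}

#' Default cohort composition
#'
#' Mirrors the packaged strain survey: 21 strains of species 1 (19 F-like,
#' one E-like, one G-like; eps templates V/I/VI/IV/III/VII/II with one
#' eps-less strain; two strains with split cwps loci) and 7 strains of
#' species 2 (H, I, G, E, J, K, L cwps; VIII/IX/X/XI eps with two
#' eps-less strains).  All eps loci sit in genomic islands.
#'
#' @return A data.frame with one row per strain.
#' @export
default_cohort_composition <- function() {
  l <- "Synthetic laudensis-like"
  r <- "Synthetic raffinolactis-like"
  df <- data.frame(
    species = c(rep(l, 21), rep(r, 7)),
    cwps = c("E", rep("F", 18), "G", "F",
             "H", "I", "G", "E", "J", "K", "L"),
    eps = c("V",
            "I", "VI", "I", "I", "IV", "VI", "I", "I", NA, "VI",
            "I", "VI", "VI", "I", "III", "IV", "VII", "VI",
            "II", "VII",
            "VIII", "IX", "X", NA, "XI", "XI", NA),
    split = FALSE, stringsAsFactors = FALSE)
  df$split[df$eps %in% "VII"] <- TRUE  # the two split-cwps strains
  df$strain_id <- sprintf("SYN%02d", seq_len(nrow(df)))
  df
}

#' Generate a seeded synthetic cohort
#'
#' @param composition A data.frame with columns `strain_id`, `species`,
#'   `cwps`, `eps`, `split` (see [default_cohort_composition()]).
#' @param seed Integer master seed; every strain derives its own
#'   sub-seed, so cohorts are reproducible and strains independent.
#' @param divergence_identity Within-genotype divergence target
#'   (default 97 percent identity to the template).
#' @return A list with `genomes` (named list of [genome()]) and
#'   `truth` (named list of per-strain truth tables).
#' @export
generate_cohort <- function(composition = default_cohort_composition(),
                            seed = 1L, divergence_identity = 97) {
  genomes <- list(); truth <- list()
  for (i in seq_len(nrow(composition))) {
    row <- composition[i, ]
    sp <- strain_spec(
      strain_id = row$strain_id, species_label = row$species,
      cwps_template = row$cwps, eps_template = row$eps,
      divergence_identity = divergence_identity,
      split_cwps = isTRUE(row$split),
      implant_island = !is.na(row$eps),
      transposase_insertions = if (identical(row$cwps, "F")) 1L else 0L,
      seed = derive_seed(seed, "strain", row$strain_id))
    gs <- generate_strain(sp)
    genomes[[row$strain_id]] <- gs$genome
    truth[[row$strain_id]] <- gs$truth
  }
  list(genomes = genomes, truth = truth)
}
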