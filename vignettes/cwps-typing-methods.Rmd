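---
title: "Typing polysaccharide biosynthesis gene clusters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing polysaccharide biosynthesis gene clusters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwpstyper)
```

# The problem

Lactococci and the related pseudolactococci decorate their cell walls with
two families of surface polysaccharides. The cell-wall polysaccharide
(CWPS) typically combines a conserved, peptidoglycan-embedded rhamnan with
a strain-variable, surface-exposed polysaccharide pellicle (PSP) — the
receptor most lactococcal phages attach to. Exopolysaccharides (EPS) are
encoded by separate *eps* clusters and are frequently mobile. Both kinds
of locus are 10–30 kb runs of co-located genes: sugar-precursor enzymes
(*rmlABCD* for dTDP-rhamnose), rhamnosyltransferases and an ABC
transporter (*rgpABCD*), a priming glycosyltransferase, a battery of
glycosyltransferases and modification enzymes, and — in Wzx/Wzy-type
clusters — a flippase, a polymerase and a co-polymerase.

`cwpstyper` implements the comparative-genomics workflow for these
loci, shaped around *Pseudolactococcus laudensis* and *P. raffinolactis*: locus
detection from annotated genomes, per-gene functional role inference,
genotype classification with automatic minting of new genotype labels,
genomic-context characterisation (mobile elements, genomic islands, split
loci), and genotype-to-structure feature prediction including glycan
composition masses. A seeded synthetic-genome generator with full truth
tables makes every stage testable without downloading assemblies.

# Similarity: query cover × percent identity

Throughout, "amino-acid similarity" between two proteins is the product of
query coverage and percent identity, on a 0–100 scale:

$$\mathrm{score} = \frac{\mathrm{qcov} \times \mathrm{pid}}{100},\qquad
  \mathrm{pid} = 100\,\frac{\text{identities}}{\text{alignment columns}},\qquad
  \mathrm{qcov} = 100\,\frac{\text{aligned query span}}{\text{query length}}.$$

Alignments are Smith–Waterman local alignments under BLOSUM62 with
BLAST-like affine gaps (open 11, extend 1), computed in-process. Percent
identity uses alignment columns including gaps (the BLAST convention);
coverage is the spanned fraction of the *query*, so the score is
direction-dependent and the pipeline always aligns candidate genes
(query) against reference exemplars (subject). `score(a, a) = 100` and
`score ≤ min(pid, qcov)` always; pairs with no positive-scoring local
alignment score 0. The suite verifies optimal scores against an
independent quadratic dynamic-programming oracle and re-derives the
reported identity/column counts from the returned alignment strings.

The classification threshold "below 30% similarity" is interpreted on this
combined scale (the same definition the similarity reporting uses), and is
configurable (`sim_threshold`).

# Membrane topology heuristics

Structure-based role signatures use transmembrane helix (TMH) counts:

* flippase-like: 12–14 TMHs (MOP-exporter shape), no DUF2142 hint;
* polymerase-like: DUF2142 domain hint with 10–12 TMHs
  (this rule takes precedence at 12 TMHs when the hint is present);
* co-polymerase-like: a signal peptide, at most 2 TMHs, and an outer loop
  of ≥ 100 residues;
* otherwise membrane enzyme (1–11 TMHs) or soluble (0).

TMHs are called with a classical hydropathy heuristic: Kyte–Doolittle
values averaged over a 19-residue sliding window, helix seeds where the
mean exceeds 1.6, expansion to the window span, merging of runs separated
by ≤ 3 residues, spans bounded to 15–35 residues. Signal peptides use an
n-region/h-region rule (a K/R in the first 7 residues followed by ≥ 7
consecutive hydrophobic residues within the first 30, and no helix
starting in residues 31–60). These are deliberately simple, deterministic
stand-ins for neural-network predictors; an ingestion path for
precomputed per-protein TMH/domain tables lets users substitute external
predictions. Constructed proteins with k helices (k = 0..14) are recovered
exactly by the suite. The outer-loop length includes the stretch before
the first helix: the co-polymerase archetype carries its large loop
between the N-terminal signal peptide and a single C-terminal helix, and
the signal peptide itself is too short to be called as a helix.

# Locus detection and split loci

Detection is anchor-and-grow. Anchors are conserved marker genes matched
by a packaged, user-replaceable keyword vocabulary: for *cwps* the
rhamnan precursor/transferase vocabulary (*rmlABCD*, rhamnosyltransferases)
plus the Wps marker products; for *eps* the conserved proximal
(*epsRXABCD*) and terminal (*epsL*, *orfY*) vocabulary. From each anchor
the region grows over adjacent genes whose products match the
polysaccharide vocabulary or are hypothetical, stopping after
`stop_after = 2` consecutive non-matching genes; transposases count as
matching because they occur inside real loci. Overlapping regions merge;
regions with fewer than `min_genes = 4` matching genes are dropped. A
similarity fallback against packaged exemplars covers loci whose products
are uninformative. Growing is symmetric, so scanning direction does not
change the result.

Reported locus boundaries are the outermost included genes' edges, and
**cluster length is `end − start`**, not `end − start + 1`: the packaged
strain table's printed lengths obey that convention (e.g. 201332 − 182887
= 18445), and bit-compatibility with the printed table was chosen over
the usual inclusive-span arithmetic. Split loci (two same-kind regions
with locus vocabulary, a transposase within 3 genes of a breakpoint edge,
and complementary role sets covering ≥ 6 canonical roles) merge into one
two-fragment locus whose length is the sum of the fragments' `end − start`
values. At most one merge (two fragments) is performed, matching the
split arrangements the typing rules need to handle.

# Role inference

Per gene, the first matching rule wins:

1. **similarity** — best hit ≥ 40 against role-labelled exemplars (the
   threshold sits comfortably below within-genotype similarities and
   above the cross-genotype regime; a reported cross-species
   identification at 56.3% similarity would pass it);
2. **keyword** — the packaged product-string vocabulary, ordered specific
   → generic;
3. **topology** — the class rules above, mapped to flippase / polymerase /
   co-polymerase.

A positional pass then resolves the DUF2142 ambiguity: DUF2142 membrane
glycosyltransferases adjacent to a co-polymerase call are polymerases;
isolated DUF2142 genes in loci with no co-polymerase are PSP-transferases
(YcaA-like), tagged `ambiguous_ycaA_like` because that function is not
experimentally validated. This pass deliberately leaves similarity-based
calls untouched: a gene confidently matched to a PSP-transferase exemplar
should not be relabelled by adjacency alone.

Locus organisation falls out of the role calls: canonical rhamnan–PSP
(priming glycosyltransferase present with a polymerase/co-polymerase),
oligomeric (priming glycosyltransferase but no polymerase — the PSP is
likely a short oligomer), or non-canonical (no priming
glycosyltransferase/flippase homologs at all — the talan-type
arrangement, which implies an assembly route distinct from the dual-chain
model). *eps* pathway class is Wzx/Wzy when both flippase and polymerase
are called, ABC-transporter when ABC components are present and both
signature roles absent, otherwise undetermined.

# Genotype classification

*cwps* genotypes are letters. A locus is compared against every profile in
the database with three criteria; it matches a profile only if none fires:

* **(i)** the polymerase/co-polymerase presence flags differ;
* **(ii)** the flippase presence differs;
* **(iii)** two or more of the locus's PSP genes — excluding the flippase,
  polymerase and co-polymerase — score below 30 against the profile's
  exemplars. The threshold count is strict: one divergent gene is not
  enough, so criterion iii is monotone in the similarity threshold.

Among matches the highest mean similarity wins (ties go to the earliest
profile). An unmatched locus mints the next letter and its profile joins
the database, so discovery order determines labels; processing strains in
table order reproduces the E–L series because the historical A–D profiles
are packaged flag-level only (no exemplar sequences, so criterion iii
always rejects them). Criterion iii is evaluated per profile and
asymmetrically (query = the new locus), matching the framing of a new
locus sharing < 30% with an existing genotype.

*eps* genotypes are roman numerals. No numeric criteria exist in the
source material for *eps* boundaries, so the rule here is an explicit
stand-in: the locus's variable region (genes after the conserved
proximal block) must reach a length-weighted mean best-hit score of
`match_threshold = 80` against a profile's exemplars *and* share its
pathway class. Pathway-class identity gates matching so that an
ABC-transporter locus can never match a Wzx/Wzy profile however similar
its glycosyltransferases.

# Genomic context

Flanking windows (default 30 kb each side, clamped at contig edges — wide
enough that a 45–55 kb island around a locus is observable) are scanned
with a keyword model of mobile-element categories (transposase,
integrase, phage, relaxase, T4SS, T4CP, conjugal transfer, defense
systems, bacteriocin immunity). A genomic island is flagged when either
flank reaches 3 MGE hits per 10 genes, or the locus sits on a plasmid;
the island span is estimated by extending from the locus edges over
MGE-annotated genes (tolerating ≤ 2 consecutive interruptions).
Relaxase + T4SS + T4CP with no origin-of-transfer keyword is reported as
an ICE-like element unable to self-transmit. These heuristics replace
dedicated island/prophage/ICE tools by design; estimated boundaries are
never claimed to reproduce manually curated ones.

# Glycan masses and structure features

Composition masses are neutral-molecule masses: anhydro residue masses
(hexose 162.0528 u, 6-deoxyhexose 146.0579 u, HexNAc 203.0794 u) plus one
water, phosphate (HPO₃, 79.9663 u) and O-acetyl (42.0106 u) increments;
borohydride reduction adds two hydrogens, each deuterium label replacing
one H with D. Both monoisotopic and average masses are reported to
0.001 u; printed-precision comparisons use the nearest-integer
monoisotopic mass, which reproduces the worked example — a NaBD₄-reduced,
phosphate-bearing glucose/galactose hexasaccharide:

```{r mass}
composition_mass("Hex6 P1 red+D")
```

Structure features are precursor-level only: rml roles imply dTDP-Rha;
a dTDP-6-deoxy-L-talose 4-dehydrogenase annotation upgrades the rhamnose
pathway to dTDP-6dTal (the enzyme interconverts the dTDP-activated
rhamnose-pathway intermediate, so it requires the rml genes); an
NAD-dependent epimerase implies UDP-Gal alongside the UDP-Glc baseline;
acetylases imply O-acetylation. No linkage, anomericity or NMR-level
prediction is attempted.

# The synthetic-data generator

The generator emulates the survey conditions so the pipeline can be tested
end-to-end. Templates encode canonical role layouts for cwps genotypes
E–L (including the non-canonical E/G talan arrangement and the
polymerase-free J layout) and eps genotypes I–XI (IX Wzx/Wzy layouts with
full or reduced proximal blocks; X/XI ABC-transporter layouts sharing only
the terminal *epsL*/*orfY* genes). Template proteins are synthetic:
composition-biased random sequences, with membrane roles built to the
role-appropriate TMH architectures so the topology rules are genuinely
exercised. Conserved genes (rml/rgp core, eps proximal/terminal block)
share sequences across templates; variable genes are independent draws,
which puts cross-genotype similarity near zero.

The default 28-strain cohort mirrors the packaged survey's composition: 21 species-1
strains (19 F-like, one E-like, one G-like; two strains with the cwps
locus split into fragments > 100 kb apart with breakpoint transposases;
one strain without an eps locus) and 7 species-2 strains (H–L plus shared
E and G; two without eps loci), 25 eps loci in total drawn from 11
templates, every eps locus embedded in a 45–55 kb MGE-annotated island.
Within-genotype divergence defaults to 97% identity to the template:
observed same-genotype clusters are near-identical (the species-1
strains derive from one starter culture, and cross-genus comparisons of
one genotype showed > 99.5% nucleotide similarity). Divergence is
BLOSUM-weighted substitution to a target identity (± 5 points), seeded
and reproducible; a single master seed splits into per-strain and
per-protein seeds, so cohorts are byte-identical across runs.

What the generator does *not* emulate: real nucleotide evolution (no
codon-level model; genomes are laid out as protein-backed CDS ladders),
annotation noise (products are informative unless a template says
otherwise), origin-spanning features, plasmid biology, and realistic
intergenic structure. Passing the recovery tests therefore shows the
rules behave as specified under controlled divergence — not that the
heuristics would survive arbitrary real-world annotation quality.

# Numerical and degenerate-input choices

* Coordinates are 1-based inclusive; origin-spanning (join) features are
  rejected rather than mis-handled.
* Ambiguous codons translate to X; internal stops are kept as `*` and
  tolerated by the alignment alphabet (pseudogene candidates), and
  translations are literal per-codon translations (no initiator-codon
  conversion), so they equal an independent codon-table oracle.
* Alignment ties in `best_hit` break by higher identity, then
  lexicographic subject id; genotype-match ties break toward the earliest
  profile in database order. Both are documented, deterministic choices.
* Zero-scoring alignments report pid = qcov = score = 0 rather than NA,
  and a query whose subjects all score zero still returns a result.
* Proteins shorter than the hydropathy window yield a zero-helix profile
  with a warning flag rather than an error.
* Loci with no variable-region genes produce an "undetermined" eps call
  with a warning, not a failure; per-strain pipeline errors become
  undetermined rows and never abort a cohort.

# Problem sizes

The packaged test suite and the acceptance script run entirely on
generated data: the cohort-level checks use the 28-strain default cohort
(~150 genes per genome, 2 implanted loci each), unit tests use single
strains or small sub-cohorts, and the alignment oracle corpus is 50
30-residue pairs. These sizes keep the full suite at desk scale while
still exercising every rule on cohort-shaped input.

# Known limitations

* The *eps* genotype boundary (mean similarity 80) is a stand-in for an
  unstated rule and is reported as such with every call.
* Island spans are density-based estimates; curated boundaries are out of
  scope, as are prophage completeness scoring and cross-strain island
  comparison.
* Topology heuristics are TMHMM-era approximations; borderline helix
  counts (11 vs 12) can flip a topology-only role call, which is why
  similarity and keyword evidence take precedence.
* Genome-wide discovery of three-component glycosylation systems outside
  the passed-in loci is not implemented (noted as a future extension).
* Subtype resolution below the genotype level is out of scope; the
  within-genotype mean similarity retained on each call is the hook for
  future subtyping.
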