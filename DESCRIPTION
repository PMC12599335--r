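Package: cwpstyper
Title: Typing of Cell Wall and Exopolysaccharide Biosynthesis Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection, functional typing and genotype classification of
    bacterial cell-wall polysaccharide (cwps) and exopolysaccharide (eps)
    biosynthesis gene clusters from annotated genomes. Provides GenBank and
    GFF3 genome input/output, Smith-Waterman protein similarity scored as
    query coverage times percent identity, hydropathy-based transmembrane
    topology heuristics, marker-gene locus detection with split-locus
    assembly, rule-based genotype assignment with novel-label minting,
    mobile-genetic-element context scanning, glycan composition mass
    calculation, and a seeded synthetic-genome generator with truth tables
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
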