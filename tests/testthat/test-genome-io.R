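test_that("a minimal hand-written GenBank record parses correctly", {
  gb <- c(
    "LOCUS       ctg1                 1200 bp    DNA     circular BCT 01-JAN-2026",
    "DEFINITION  Synthetic sp. strain demo chromosome.",
    "FEATURES             Location/Qualifiers",
    "     source          1..1200",
    "                     /organism=\"Synthetic sp.\"",
    "                     /strain=\"demo\"",
    "     CDS             101..403",
    "                     /locus_tag=\"demo_0001\"",
    "                     /gene=\"rmlA\"",
    "                     /product=\"glucose-1-phosphate thymidylyltransferase RmlA\"",
    "                     /translation=\"MKGIILAGGSGTRLYPVTMAVSKQLLPIYDKPMIYYPLSTLMLAGIRDI",
    "                     LIISTPQDTPRFQQLLGDGSQWGLNLQYKVQPSPDGLAQAFIIGEEFIGHDDCALVLGDN",
    "                     IFYGHDLPKLMEAAVNKESGATVFAYHVQDPERYGVVEFDKNGTAISLEEKPLEPKSN\"",
    "//")
  f <- tempfile(fileext = ".gbk")
  writeLines(gb, f)
  g <- read_annotated_genome(f)
  expect_s3_class(g, "genome")
  expect_equal(nrow(g$contigs), 1L)
  expect_equal(g$contigs$length, 1200L)
  expect_equal(g$contigs$topology, "circular")
  expect_equal(g$id, "demo")
  expect_equal(nrow(g$features), 1L)
  expect_equal(g$features$start, 101L)
  expect_equal(g$features$end, 403L)
  expect_equal(g$features$strand, "+")
  expect_equal(g$features$gene_name, "rmlA")
  expect_match(g$features$product, "thymidylyltransferase")
  expect_match(g$features$protein, "^MKGIILAGG")
})

test_that("GenBank write/read round-trips a synthetic multi-gene genome", {
  gs <- generate_strain(strain_spec("RT1", cwps_template = "G", seed = 3))
  g <- gs$genome
  f <- tempfile(fileext = ".gbk")
  write_genome(g, f, "genbank")
  g2 <- read_annotated_genome(f, "genbank")
  expect_equal(g2$id, g$id)
  expect_equal(g2$species, g$species)
  expect_equal(g2$contigs, g$contigs)
  expect_equal(g2$features, g$features)
  ## a second round trip is byte-identical
  f2 <- tempfile(fileext = ".gbk")
  write_genome(g2, f2, "genbank")
  expect_identical(readLines(f), readLines(f2))
})

test_that("GFF3+FASTA round-trips and minus-strand CDS are translated", {
  ## hand-construct a two-gene genome with real nucleotide sequence
  nt1 <- "ATGGCTAAAGGTGAAGAACTGTTCACCGGTGTTGTTCCGATTCTGGTTGAACTGTAA"
  nt2 <- "ATGAAACGTCTGGCTGACGATCCGAATTTTGGTCTGTGCTACGCATATTCTGGTTGA"
  rc2 <- chartr("ACGT", "TGCA", nt2)
  rc2 <- paste(rev(strsplit(rc2, "")[[1]]), collapse = "")
  filler <- random_nt(86, seed = 9)
  seqnt <- paste0(strrep("A", 10), nt1, strrep("T", 10), rc2, filler)
  contigs <- contig("c1", nchar(seqnt), "linear", "chromosome")
  feats <- gene_feature(
    contig_id = "c1", start = c(11L, 11L + nchar(nt1) + 10L),
    end = c(10L + nchar(nt1), 10L + nchar(nt1) + 10L + nchar(nt2)),
    strand = c("+", "-"), locus_tag = c("g1", "g2"),
    product = c("protein one", "protein two"))
  g <- genome("gff-demo", "Synthetic sp.", contigs, feats,
              sequences = c(c1 = seqnt))
  f <- tempfile(fileext = ".gff3")
  write_genome(g, f, "gff3")
  g2 <- read_annotated_genome(f, "gff3")
  expect_equal(g2$contigs$length, g$contigs$length)
  expect_equal(nrow(g2$features), 2L)
  ## translations must equal the independent per-codon oracle
  expect_equal(g2$features$protein[g2$features$locus_tag == "g1"],
               translate_oracle(nt1))
  expect_equal(g2$features$protein[g2$features$locus_tag == "g2"],
               translate_oracle(nt2))
  ## round trip again preserves features (now with translations)
  f2 <- tempfile(fileext = ".gff3")
  write_genome(g2, f2, "gff3")
  g3 <- read_annotated_genome(f2, "gff3")
  expect_equal(g3$features, g2$features)
})

test_that("CDS translation agrees with the per-codon oracle on both strands", {
  set.seed(42)
  for (i in 1:10) {
    len <- 3 * sample(40:80, 1)
    nt <- random_nt(len, seed = 1000 + i)
    strand <- if (i %% 2 == 0) "+" else "-"
    expect_equal(translate_cds(nt, 1L, len, strand),
                 translate_oracle(nt, strand), info = paste("case", i))
  }
})

test_that("genome invariants are enforced", {
  ct <- contig("c1", 1000L)
  expect_error(genome("x", "", ct,
                      gene_feature("c1", 1, 1200, "+", "t1")),
               "beyond contig length")
  expect_error(genome("x", "", ct,
                      gene_feature(c("c1", "c1"), c(1, 50), c(30, 90),
                                   c("+", "+"), c("t1", "t1"))),
               "duplicate locus_tags")
  expect_error(gene_feature("c1", 10, 5, "+", "t1"),
               "start <= end")
  expect_error(gene_feature("c1", 1, 30, "+", "t1", protein = "MKLO"),
               "non-amino-acid|alphabet")
  expect_error(genome("x", "", ct, empty_features(),
                      sequences = c(c1 = "ACGT")),
               "length disagrees")
  ## duplicate locus tags block writing too
  g <- genome("x", "", ct, gene_feature("c1", 1, 30, "+", "t1"))
  g$features <- rbind(g$features, g$features)
  expect_error(write_genome(g, tempfile(), "genbank"), "duplicate")
})

test_that("origin-spanning (join) locations are rejected", {
  gb <- c("LOCUS       c1                 500 bp    DNA     circular BCT 01-JAN-2026",
          "FEATURES             Location/Qualifiers",
          "     CDS             join(450..500,1..60)",
          "                     /locus_tag=\"t1\"",
          "//")
  f <- tempfile(fileext = ".gbk")
  writeLines(gb, f)
  expect_error(read_annotated_genome(f), "origin-spanning|unsupported")
})

test_that("an empty-feature genome writes contig records only", {
  g <- genome("empty", "Synthetic sp.", contig("c1", 500L))
  f <- tempfile(fileext = ".gbk")
  write_genome(g, f, "genbank")
  g2 <- read_annotated_genome(f)
  expect_equal(nrow(g2$features), 0L)
  expect_equal(g2$contigs$length, 500L)
})

test_that("the packaged strain table satisfies its printed-length invariants", {
  tb <- load_table1_fixture()
  expect_equal(length(unique(tb$strain)), 28L)
  ## every fragment: printed length equals end - start
  expect_true(all(tb$end - tb$start == tb$printed_length))
  recs <- strain_records(tb)
  expect_equal(length(recs), 28L)
  ## split cwps loci carry two fragments
  expect_equal(nrow(recs[["T2G5"]]$cwps_fragments), 2L)
  expect_equal(nrow(recs[["T2H4"]]$cwps_fragments), 2L)
  ## strains without an eps record
  no_eps <- names(Filter(function(r) is.na(r$eps_genotype), recs))
  expect_setequal(no_eps, c("T2E11", "Lr_19_5", "APC3967"))
  ## spot checks against printed rows
  expect_equal(unname(recs[["DSM28961"]]$cwps_fragments[1, ]),
               c(182887L, 201332L))
  expect_equal(recs[["DSM28961"]]$printed_lengths[1], 18445L)
  expect_equal(length(unique(tb$species)), 2L)
})
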