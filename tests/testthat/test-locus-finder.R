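make_plain_genome <- function(n = 50, seed = 1) {
  gs <- generate_strain(strain_spec("PLAIN", seed = seed))
  gs$genome
}

test_that("an implanted locus is recovered exactly, with no flanking genes", {
  gs <- generate_strain(strain_spec("ONE", cwps_template = "F",
                                    transposase_insertions = 1L, seed = 8))
  regs <- find_locus(gs$genome, "cwps")
  expect_length(regs, 1L)
  expect_setequal(regs[[1]]$genes$locus_tag, gs$truth$cwps_locus_tags)
  expect_equal(unname(as.matrix(regs[[1]]$fragments[, c("start", "end")])),
               unname(gs$truth$cwps_fragments))
  expect_gt(nrow(regs[[1]]$anchor_hits), 0L)
})

test_that("a genome of housekeeping genes yields no locus", {
  g <- make_plain_genome()
  expect_length(find_locus(g, "cwps"), 0L)
  expect_length(find_locus(g, "eps"), 0L)
})

test_that("region growing is insensitive to scan direction", {
  ## reversing the feature table must not change the detected regions
  gs <- generate_strain(strain_spec("DIR", cwps_template = "I",
                                    eps_template = "IX", seed = 13))
  g <- gs$genome
  fwd <- find_locus(g, "cwps")
  g2 <- g
  g2$features <- g$features[rev(seq_len(nrow(g$features))), ]
  bwd <- find_locus(g2, "cwps")
  expect_equal(lapply(fwd, function(r) sort(r$genes$locus_tag)),
               lapply(bwd, function(r) sort(r$genes$locus_tag)))
})

test_that("split loci merge into one two-fragment locus matching truth", {
  gs <- generate_strain(strain_spec("SPL", cwps_template = "F",
                                    split_cwps = TRUE, seed = 21))
  regs <- find_locus(gs$genome, "cwps")
  expect_length(regs, 2L)
  merged <- detect_split_locus(regs, gs$genome)
  expect_length(merged, 1L)
  expect_equal(nrow(merged[[1]]$fragments), 2L)
  expect_equal(unname(as.matrix(merged[[1]]$fragments[, c("start", "end")])),
               unname(gs$truth$cwps_fragments))
  ## fragments are >= 100 kb apart
  expect_gt(merged[[1]]$fragments$start[2] - merged[[1]]$fragments$end[1],
            100000L)
  ## merging is symmetric in fragment order
  merged2 <- detect_split_locus(rev(regs), gs$genome)
  expect_equal(merged2[[1]]$fragments, merged[[1]]$fragments)
  ## a single region passes through unchanged
  expect_identical(detect_split_locus(regs[1], gs$genome), regs[1])
})

test_that("two complete independent loci are not merged", {
  ## two full F-like loci in one genome: overlapping role sets and no
  ## breakpoint transposase at the inner edges
  gs1 <- generate_strain(strain_spec("DUP", cwps_template = "H", seed = 31))
  g <- gs1$genome
  ## duplicate the locus genes at a distant position
  f <- g$features
  locus <- f[f$locus_tag %in% gs1$truth$cwps_locus_tags, ]
  shift <- max(f$end) + 5000L
  dup <- locus
  dup$start <- dup$start + shift; dup$end <- dup$end + shift
  dup$locus_tag <- paste0(dup$locus_tag, "_2")
  g$contigs$length <- max(dup$end) + 500L
  g$features <- sort_features(rbind(f, dup))
  regs <- find_locus(g, "cwps")
  expect_length(regs, 2L)
  merged <- detect_split_locus(regs, g)
  expect_length(merged, 2L)
})

test_that("locus QC reports the advisory ranges without rejecting", {
  gs <- generate_strain(strain_spec("QC1", cwps_template = "F", seed = 41))
  locus <- find_locus(gs$genome, "cwps")[[1]]
  qc <- qc_locus(locus)
  expect_equal(qc$total_length, locus_length(locus))
  expect_equal(qc$gene_count, nrow(locus$genes))
  expect_type(qc$length_in_expected_range, "logical")
  ## a fragment with the coordinates of a printed row is in range
  fake <- locus
  fake$fragments <- data.frame(contig_id = "chromosome",
                               start = 182887L, end = 201332L)
  qcf <- qc_locus(fake)
  expect_equal(qcf$total_length, 18445L)
  expect_true(qcf$length_in_expected_range)
})

test_that("summed fragment lengths follow the end - start convention", {
  ## split-locus arithmetic mirrors the printed strain table: the two
  ## fragments of one strain sum their end - start lengths
  tb <- load_table1_fixture()
  t2g5 <- tb[tb$strain == "T2G5" & tb$locus_kind == "cwps", ]
  expect_equal(sum(t2g5$end - t2g5$start), 12847L + 11834L)
  expect_equal(sum(t2g5$end - t2g5$start), 24681L)
})

test_that("partitioning splits canonical loci at the priming glycosyltransferase", {
  gs <- generate_strain(strain_spec("PAR", cwps_template = "F", seed = 51))
  typed <- assign_roles(find_locus(gs$genome, "cwps")[[1]])
  typed <- partition_cwps(positional_disambiguation(typed))
  expect_false(is.na(typed$partition))
  expect_equal(typed$roles$role[typed$partition], "priming_gt")
  expect_equal(typed$organization, "canonical_rhamnan_psp")
  ## all genes before the partition belong to the rhamnan core or are
  ## transposase insertions
  before <- typed$roles$role[seq_len(typed$partition - 1L)]
  expect_true(all(before %in% c(RHAMNAN_CORE_ROLES, "transposase")))

  ## non-canonical locus: no priming glycosyltransferase
  gs2 <- generate_strain(strain_spec("PAR2", cwps_template = "E", seed = 52))
  typed2 <- assign_roles(find_locus(gs2$genome, "cwps")[[1]])
  typed2 <- partition_cwps(positional_disambiguation(typed2))
  expect_true(is.na(typed2$partition))
  expect_equal(typed2$organization, "non_canonical")

  ## empty locus errors
  typed3 <- typed
  typed3$roles <- typed3$roles[0, ]
  expect_error(partition_cwps(typed3), "empty")
})
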