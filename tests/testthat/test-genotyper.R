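type_locus <- function(strain, template, seed, ...) {
  gs <- generate_strain(strain_spec(strain, cwps_template = template,
                                    seed = seed, ...))
  locus <- detect_split_locus(find_locus(gs$genome, "cwps"), gs$genome)[[1]]
  partition_cwps(positional_disambiguation(assign_roles(locus)))
}

test_that("label minting continues the established series", {
  expect_equal(mint_label(default_cwps_db()), "E")
  expect_equal(mint_label(genotype_db(kind = "cwps")), "A")
  expect_equal(mint_label(genotype_db(kind = "eps")), "I")
  db <- genotype_db(lapply(as.character(utils::as.roman(1:11)), function(l)
    genotype_profile(l, "eps", TRUE, FALSE, TRUE)), "eps")
  expect_equal(mint_label(db), "XII")
  ## letter series wraps into two-letter labels after Z
  dbz <- genotype_db(list(genotype_profile("Z", "cwps", TRUE, TRUE, TRUE)),
                     "cwps")
  expect_equal(mint_label(dbz), "AA")
})

test_that("a locus identical to a minted profile matches it (idempotence)", {
  typed <- type_locus("GT1", "F", seed = 81)
  first <- assign_cwps_genotype(typed)
  expect_true(first$is_novel)
  expect_equal(first$label, "E")  # next letter after the historical A-D
  again <- assign_cwps_genotype(typed, first$db)
  expect_false(again$is_novel)
  expect_equal(again$label, "E")
  expect_equal(again$mean_similarity, 100)
  expect_length(again$criteria_fired[[again$label]], 0L)
})

test_that("criterion semantics: single edits flip novelty exactly as specified", {
  typed <- type_locus("GT2", "F", seed = 91)
  db <- assign_cwps_genotype(typed)$db  # profile minted from this locus

  ## deleting the flippase gene fires criterion ii against every profile
  no_flip <- typed
  keep <- no_flip$roles$role != "flippase"
  no_flip$roles <- no_flip$roles[keep, ]
  no_flip$region$genes <- no_flip$region$genes[keep, ]
  no_flip <- partition_cwps(no_flip)
  call_ii <- assign_cwps_genotype(no_flip, db)
  expect_true(call_ii$is_novel)
  ## every profile in the database carries a flippase, so ii fires on all
  expect_true(all(vapply(call_ii$criteria_fired, function(cr)
    "ii" %in% cr, logical(1))))

  ## diverging exactly TWO PSP genes below the threshold fires criterion iii
  two_off <- typed
  targets <- names(psp_genes(typed))[1:2]
  gi <- match(targets, two_off$region$genes$locus_tag)
  two_off$region$genes$protein[gi] <-
    vapply(seq_along(gi), function(k)
      cwpstyper:::soluble_protein(300L, 90210L + k), character(1))
  call_iii <- assign_cwps_genotype(two_off, db)
  expect_true(call_iii$is_novel)
  fired_on_match <- call_iii$criteria_fired[["E"]]
  expect_true("iii" %in% fired_on_match)
  expect_false("i" %in% fired_on_match)
  expect_false("ii" %in% fired_on_match)

  ## diverging only ONE PSP gene is not enough: the locus still matches
  one_off <- typed
  gi1 <- match(targets[1], one_off$region$genes$locus_tag)
  one_off$region$genes$protein[gi1] <-
    cwpstyper:::soluble_protein(300L, 777L)
  call_one <- assign_cwps_genotype(one_off, db)
  expect_false(call_one$is_novel)
  expect_equal(call_one$label, "E")
})

test_that("criterion iii is monotone in the similarity threshold", {
  typed <- type_locus("GT3", "H", seed = 101)
  db <- assign_cwps_genotype(typed)$db
  other <- type_locus("GT4", "H", seed = 102)
  for (thr in c(30, 20, 10, 5)) {
    call <- assign_cwps_genotype(other, db, sim_threshold = thr)
    expect_false(call$is_novel, label = sprintf("threshold %g", thr))
  }
})

test_that("loci without role calls are rejected", {
  typed <- type_locus("GT5", "F", seed = 111)
  typed$roles$role <- "unknown"
  typed$roles$evidence <- NA_character_
  expect_error(assign_cwps_genotype(typed), "role calls")
})

test_that("eps genotyping matches identical loci and separates pathways", {
  mk_eps <- function(strain, template, seed) {
    gs <- generate_strain(strain_spec(strain, eps_template = template,
                                      seed = seed))
    locus <- find_locus(gs$genome, "eps")[[1]]
    positional_disambiguation(assign_roles(locus))
  }
  t1 <- mk_eps("EP1", "VI", 121)
  c1 <- assign_eps_genotype(t1)
  expect_true(c1$is_novel)
  expect_equal(c1$label, "I")  # empty database: roman series starts at I
  ## the same locus re-assigned matches
  c2 <- assign_eps_genotype(t1, c1$db)
  expect_false(c2$is_novel)
  expect_equal(c2$label, "I")
  ## another strain of the same template matches too
  t1b <- mk_eps("EP1B", "VI", 122)
  c2b <- assign_eps_genotype(t1b, c1$db)
  expect_false(c2b$is_novel)
  ## an ABC-pathway locus can never match a wzx_wzy profile, even if
  ## genes were similar: pathway class gates the match
  t2 <- mk_eps("EP2", "X", 123)
  expect_equal(t2$pathway_class, "abc_transporter")
  c3 <- assign_eps_genotype(t2, c1$db)
  expect_true(c3$is_novel)
  expect_equal(c3$label, "II")
})

test_that("genotype flags drive criteria i and ii for mismatched organisations", {
  ## J-like locus (no polymerase/co-polymerase, flippase present) vs a
  ## profile minted from F (all three present): criterion i must fire
  typedF <- type_locus("GTF", "F", seed = 131)
  db <- assign_cwps_genotype(typedF)$db
  typedJ <- type_locus("GTJ", "J", seed = 132)
  expect_equal(typedJ$organization, "oligomeric")
  call <- assign_cwps_genotype(typedJ, db)
  expect_true(call$is_novel)
  expect_true("i" %in% call$criteria_fired[["E"]])
})
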