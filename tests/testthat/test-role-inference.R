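test_that("keyword route maps annotation strings to roles", {
  expect_equal(match_product_role("dTDP-glucose 4,6-dehydratase RmlB", "cwps"),
               "precursor_rmlB")
  expect_equal(match_product_role("bactoprenol glycosyltransferase", "cwps"),
               "copolymerase")
  expect_equal(match_product_role("IS30 family transposase", "cwps"),
               "transposase")
  expect_equal(match_product_role("NAD-dependent epimerase", "cwps"),
               "modification_epimerase")
  expect_equal(match_product_role("30S ribosomal protein S4", "cwps"),
               NA_character_)
  ## specific rows win over the generic glycosyltransferase row
  expect_equal(match_product_role("priming glycosyltransferase WpsA", "cwps"),
               "priming_gt")
})

test_that("similarity then keyword then topology precedence holds", {
  gs <- generate_strain(strain_spec("RP", cwps_template = "F", seed = 61))
  locus <- find_locus(gs$genome, "cwps")[[1]]
  typed <- assign_roles(locus)
  tr <- gs$truth$roles
  common <- intersect(typed$roles$locus_tag, names(tr))
  hit <- typed$roles$role[match(common, typed$roles$locus_tag)] == tr[common]
  expect_true(all(hit))
  expect_true(all(typed$roles$evidence[typed$roles$role != "unknown"] %in%
                    c("similarity", "keyword", "topology")))
  ## determinism
  typed2 <- assign_roles(locus)
  expect_identical(typed$roles, typed2$roles)
})

test_that("topology is the fallback for hypothetical membrane proteins", {
  ## a 13-TMH hypothetical with no reference hit must be called flippase
  prot <- cwpstyper:::membrane_protein(13L, seed = 4242L)
  f <- gene_feature("c1", 1L, 3L * nchar(prot) + 3L, "+", "hy1",
                    product = "hypothetical protein", protein = prot)
  ct <- contig("c1", nchar(prot) * 3L + 500L)
  locus <- cwpstyper:::new_locus_region("t", "eps", f,
                                        data.frame(locus_tag = "hy1",
                                                   marker = "none"))
  typed <- assign_roles(locus, refdb = NULL)
  expect_equal(typed$roles$role, "flippase")
  expect_equal(typed$roles$evidence, "topology")
  expect_true(is.na(typed$roles$score))
})

test_that("roles are recovered on strongly diverged implants", {
  ## 60% identity to the templates: similarity route still carries
  gs <- generate_strain(strain_spec("DIV60", cwps_template = "I",
                                    divergence_identity = 60, seed = 71))
  locus <- find_locus(gs$genome, "cwps")[[1]]
  typed <- assign_roles(locus)
  tr <- gs$truth$roles
  common <- intersect(typed$roles$locus_tag, names(tr))
  rate <- mean(typed$roles$role[match(common, typed$roles$locus_tag)] ==
                 tr[common])
  expect_gte(rate, 0.95)
})

test_that("eps pathway classification follows the signature-gene rules", {
  mk_typed <- function(roles) {
    f <- gene_feature("c1", seq_along(roles) * 100L,
                      seq_along(roles) * 100L + 50L, "+",
                      sprintf("g%d", seq_along(roles)))
    locus <- cwpstyper:::new_locus_region("t", "eps", f,
                                          data.frame(locus_tag = character(),
                                                     marker = character()))
    structure(list(region = locus, kind = "eps",
                   roles = data.frame(locus_tag = f$locus_tag,
                                      product = "", role = roles,
                                      evidence = "keyword", score = NA_real_,
                                      note = "", stringsAsFactors = FALSE),
                   partition = NA_integer_, organization = "undetermined",
                   pathway_class = NA_character_), class = "typed_locus")
  }
  expect_equal(classify_eps_pathway(
    mk_typed(c("flippase", "polymerase", "regulator"))), "wzx_wzy")
  expect_equal(classify_eps_pathway(
    mk_typed(c("abc_transporter", "glycosyltransferase"))), "abc_transporter")
  expect_equal(classify_eps_pathway(
    mk_typed(rep("glycosyltransferase", 3))), "undetermined")
  ## flippase alone is not enough for either class
  expect_equal(classify_eps_pathway(
    mk_typed(c("flippase", "glycosyltransferase"))), "undetermined")
})

test_that("positional disambiguation resolves DUF2142 ambiguity", {
  mk <- function(products, roles, evidence) {
    f <- gene_feature("c1", seq_along(roles) * 100L,
                      seq_along(roles) * 100L + 50L, "+",
                      sprintf("g%d", seq_along(roles)), product = products)
    locus <- cwpstyper:::new_locus_region("t", "cwps", f,
                                          data.frame(locus_tag = character(),
                                                     marker = character()))
    structure(list(region = locus, kind = "cwps",
                   roles = data.frame(locus_tag = f$locus_tag,
                                      product = products, role = roles,
                                      evidence = evidence, score = NA_real_,
                                      note = "", stringsAsFactors = FALSE),
                   partition = NA_integer_, organization = "undetermined",
                   pathway_class = NA_character_), class = "typed_locus")
  }
  ## DUF2142 keyword call adjacent to a co-polymerase -> polymerase
  t1 <- mk(c("glycosyltransferase, DUF2142 domain-containing protein",
             "bactoprenol glycosyltransferase"),
           c("glycosyltransferase", "copolymerase"), c("keyword", "keyword"))
  expect_equal(positional_disambiguation(t1)$roles$role[1], "polymerase")
  ## isolated DUF2142 gene with no co-polymerase -> psp_transferase
  t2 <- mk(c("glycosyltransferase, DUF2142 domain-containing protein",
             "glycosyltransferase"),
           c("glycosyltransferase", "glycosyltransferase"),
           c("keyword", "keyword"))
  out2 <- positional_disambiguation(t2)
  expect_equal(out2$roles$role[1], "psp_transferase")
  expect_match(out2$roles$note[1], "ambiguous_ycaA_like")
  ## no DUF2142 genes: identity
  t3 <- mk(c("glycosyltransferase", "NAD-dependent epimerase"),
           c("glycosyltransferase", "modification_epimerase"),
           c("keyword", "keyword"))
  expect_identical(positional_disambiguation(t3), t3)
})
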