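# atomic-mass summation oracle for neutral sugars
atomic_mono <- c(C = 12, H = 1.0078250319, O = 15.9949146221,
                 N = 14.0030740052, P = 30.97376151, D = 2.0141017780)
formula_mass <- function(C = 0, H = 0, O = 0, N = 0, P = 0, D = 0) {
  sum(atomic_mono * c(C = C, H = H, O = O, N = N, P = P, D = D))
}

test_that("free monosaccharide masses match the atomic oracle", {
  ## glucose C6H12O6
  expect_equal(composition_mass(glycan_composition(hex = 1))[["monoisotopic"]],
               formula_mass(C = 6, H = 12, O = 6), tolerance = 1e-4)
  ## 6-deoxyhexose C6H12O5
  expect_equal(composition_mass(glycan_composition(dhex = 1))[["monoisotopic"]],
               formula_mass(C = 6, H = 12, O = 5), tolerance = 1e-4)
  ## HexNAc C8H15NO6
  expect_equal(composition_mass(glycan_composition(hexnac = 1))[["monoisotopic"]],
               formula_mass(C = 8, H = 15, O = 6, N = 1), tolerance = 1e-4)
  ## printed-precision values
  expect_equal(round(composition_mass(glycan_composition(hex = 1))[["monoisotopic"]], 3),
               180.063)
  expect_equal(round(composition_mass(glycan_composition(dhex = 1))[["monoisotopic"]], 3),
               164.068)
})

test_that("the reduced phosphorylated hexasaccharide calculates to 1073", {
  ## NaBD4-reduced, phosphate-bearing Glc/Gal hexasaccharide repeating
  ## unit: nearest-integer monoisotopic neutral mass is the printed value
  m <- composition_mass(glycan_composition(hex = 6, phosphate = 1,
                                           reduced = TRUE,
                                           deuterium_labels = 1))
  expect_equal(round(m[["monoisotopic"]]), 1073)
  ## oracle: 6 anhydro-hexoses + water + HPO3 + H + D
  oracle <- 6 * formula_mass(C = 6, H = 10, O = 5) +
    formula_mass(H = 2, O = 1) + formula_mass(H = 1, O = 3, P = 1) +
    formula_mass(H = 1) + formula_mass(D = 1)
  expect_equal(m[["monoisotopic"]], oracle, tolerance = 1e-4)
  ## the compact grammar expresses the same composition
  expect_equal(composition_mass("Hex6 P1 red+D"), m)
})

test_that("mass additivity holds under glycosidic condensation", {
  for (case in list(c(2, 1, 0), c(3, 0, 1), c(1, 1, 1))) {
    a <- glycan_composition(hex = case[1], dhex = case[2], hexnac = case[3])
    b <- glycan_composition(hex = 1, dhex = 2)
    ab <- glycan_composition(hex = case[1] + 1, dhex = case[2] + 2,
                             hexnac = case[3])
    ## condensing two glycans releases one water
    expect_equal(composition_mass(ab)[["monoisotopic"]],
                 composition_mass(a)[["monoisotopic"]] +
                   composition_mass(b)[["monoisotopic"]] -
                   formula_mass(H = 2, O = 1),
                 tolerance = 1e-6)
  }
})

test_that("monoisotopic mass never exceeds the average mass", {
  grid <- expand.grid(hex = 0:3, dhex = 0:2, hexnac = 0:2,
                      phosphate = 0:1, acetyl = 0:1)
  grid <- grid[rowSums(grid[, 1:3]) >= 1, ]
  for (i in seq_len(nrow(grid))) {
    m <- composition_mass(do.call(glycan_composition, as.list(grid[i, ])))
    expect_lte(m[["monoisotopic"]], m[["average"]])
  }
})

test_that("composition invariants and the mini-grammar are enforced", {
  expect_error(composition_mass(glycan_composition()), "at least one residue")
  expect_error(glycan_composition(hex = -1), ">= 0")
  expect_error(glycan_composition(hex = 1, deuterium_labels = 1),
               "require a reduced")
  p <- parse_composition("Hex2 dHex1 HexNAc1 Ac2 P1 red")
  expect_equal(p$hex, 2L); expect_equal(p$dhex, 1L)
  expect_equal(p$hexnac, 1L); expect_equal(p$acetyl, 2L)
  expect_true(p$reduced); expect_equal(p$deuterium_labels, 0L)
  expect_error(parse_composition("Hex2 Zzz1"), "cannot parse")
})

test_that("structure features follow the genotype-structure link rules", {
  ## talan-type locus: rml precursors + talose dehydrogenase + acetylase
  gs <- generate_strain(strain_spec("GLY1", cwps_template = "E", seed = 181))
  typed <- partition_cwps(positional_disambiguation(
    assign_roles(find_locus(gs$genome, "cwps")[[1]])))
  sf <- predict_structure_features(typed)
  expect_true(all(c("dTDP-Rha", "dTDP-6dTal", "UDP-Glc") %in% sf$precursors))
  expect_true("O-acetylation" %in% sf$modifications)
  expect_match(sf$organization_note, "distinct from the dual-chain")

  ## canonical locus with an epimerase gains UDP-Gal, no talose sugar
  gs2 <- generate_strain(strain_spec("GLY2", cwps_template = "I", seed = 182))
  typed2 <- partition_cwps(positional_disambiguation(
    assign_roles(find_locus(gs2$genome, "cwps")[[1]])))
  sf2 <- predict_structure_features(typed2)
  expect_true("UDP-Gal" %in% sf2$precursors)
  expect_false("dTDP-6dTal" %in% sf2$precursors)

  ## empty role set: baseline only
  typed3 <- typed2
  typed3$roles$role <- "unknown"
  typed3$organization <- "undetermined"
  sf3 <- predict_structure_features(typed3)
  expect_equal(sf3$precursors, "UDP-Glc")
  expect_length(sf3$modifications, 0L)
})
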