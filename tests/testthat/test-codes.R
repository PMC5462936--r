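test_that("translate_codon matches the standard genetic code", {
  expect_identical(translate_codon("ATG"), "M")
  expect_identical(translate_codon("TAA"), "*")
  expect_identical(translate_codon("TTT"), "F")
  expect_identical(translate_codon("atg"), "M") # case-insensitive
  # full agreement with an independent translation route
  codons <- names(Biostrings::GENETIC_CODE)
  expect_identical(
    translate_codon(codons),
    vapply(codons, oracle_translate, character(1), USE.NAMES = FALSE)
  )
  expect_error(translate_codon("ATN"), "Invalid")
  expect_error(translate_codon("AT"), "3 bases")
})

test_that("codon_consequence resolves the four categories", {
  expect_identical(codon_consequence("TTT", 3, "C"), "synonymous")
  expect_identical(codon_consequence("ATG", 2, "C"), "missense")
  expect_identical(codon_consequence("TAC", 3, "A"), "stopgain")
  expect_identical(codon_consequence("TAA", 2, "T"), "stoploss") # TAA -> TTA (Leu)
  expect_identical(codon_consequence("TAA", 3, "G"), "synonymous") # stop -> stop
  expect_error(codon_consequence("TTT", 3, "T"), "differ")
  expect_error(codon_consequence("TTT", 4, "C"), "position")
})

test_that("codon_consequence is a total function over all 576 changes", {
  codons <- names(Biostrings::GENETIC_CODE)
  grid <- expand.grid(
    codon = codons, position = 1:3,
    alt = c("A", "C", "G", "T"), stringsAsFactors = FALSE
  )
  grid$ref <- substr(grid$codon, grid$position, grid$position)
  grid <- grid[grid$ref != grid$alt, ]
  expect_identical(nrow(grid), 576L) # 9 alternatives per codon
  res <- codon_consequence(grid$codon, grid$position, grid$alt)
  expect_false(anyNA(res))
  expect_true(all(
    res %in% c("synonymous", "missense", "stopgain", "stoploss")
  ))
  # synonymous iff the translated product is unchanged
  mutated <- mapply(function(codon, pos, alt) {
    substr(codon, pos, pos) <- alt
    codon
  }, grid$codon, grid$position, grid$alt, USE.NAMES = FALSE)
  expect_identical(
    res == "synonymous",
    translate_codon(grid$codon) == translate_codon(mutated)
  )
})

test_that("hydrophobicity follows the 9-residue set", {
  expect_true(is_hydrophobic("Leu"))
  expect_true(is_hydrophobic("Trp"))
  expect_false(is_hydrophobic("Lys"))
  expect_false(is_hydrophobic("*")) # stop is not a residue
  expect_identical(
    is_hydrophobic(c("A", "G", "I", "L", "F", "V", "P", "M", "W")),
    rep(TRUE, 9)
  )
  expect_identical(is_hydrophobic(c("ala", "SER")), c(TRUE, FALSE))
  expect_error(is_hydrophobic("B"), "Unknown")
  expect_error(is_hydrophobic("Xyz"), "Unknown")
})

test_that("hydrophobic codon census partitions the 64 codons", {
  census <- hydrophobic_codon_census()
  expect_identical(census$ntn_hydrophobic, 16L)
  expect_identical(census$ntn_total, 16L)
  expect_identical(census$other_hydrophobic, 13L)
  expect_identical(census$other_total, 48L)
  expect_identical(census$ntn_total + census$other_total, 64L)
  # every NTN codon encodes Ile, Met, Leu, Val or Phe
  codons <- names(Biostrings::GENETIC_CODE)
  ntn <- codons[substr(codons, 2, 2) == "T"]
  expect_setequal(unique(translate_codon(ntn)), c("I", "M", "L", "V", "F"))
})

test_that("hydrophobic_fraction averages residue membership", {
  expect_identical(hydrophobic_fraction("KKK"), 0)
  expect_identical(hydrophobic_fraction("LLLL"), 1)
  expect_identical(hydrophobic_fraction("KL"), 0.5)
  expect_identical(hydrophobic_fraction(c("K", "L")), 0.5)
  expect_error(hydrophobic_fraction(""), "at least one")
})

test_that("synonymous class distribution equals brute-force enumeration", {
  dist <- synonymous_class_distribution()
  expect_identical(dist$class, substitution_classes("6"))
  expect_equal(sum(dist$proportion), 1)
  # frozen counts from an exhaustive enumeration over all 576 codon changes
  expect_identical(dist$count, c(19L, 16L, 33L, 18L, 33L, 19L))
  expect_identical(sum(dist$count), 138L)
  # the code's redundancy is most prominent for C>T and T>C
  prop <- setNames(dist$proportion, dist$class)
  expect_gt(prop[["C>T"]], prop[["C>G"]])
  expect_identical(
    names(sort(prop, decreasing = TRUE))[1:2] %in% c("C>T", "T>C"),
    c(TRUE, TRUE)
  )
})
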