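test_that("single-codon site spectra match hand enumeration", {
  totals <- spectrum_totals(site_spectra(toy_genes()))
  # all 9 changes to ATG are non-synonymous; only TTT->TTC is synonymous
  expect_identical(totals$N[totals$gene_id == "one_codon"], 9L)
  expect_identical(totals$S[totals$gene_id == "one_codon"], 0L)
  expect_identical(totals$N[totals$gene_id == "phe"], 8L)
  expect_identical(totals$S[totals$gene_id == "phe"], 1L)
})

test_that("every gene yields N + S = 9 x codons when context is defined", {
  genes <- simulate_genes(10, n_codons = c(5, 40), seed = 42)
  totals <- spectrum_totals(site_spectra(genes))
  expect_identical(
    totals$N + totals$S,
    3L * nchar(genes$cds[match(totals$gene_id, genes$gene_id)])
  )
})

test_that("N flanks drop terminal positions from the spectrum", {
  g <- tibble::tibble(gene_id = "g", cds = "TTTAAA", flank5 = "N", flank3 = "N")
  totals <- spectrum_totals(suppressWarnings(site_spectra(g)))
  # first and last position skipped: (6 - 2) * 3 changes remain
  expect_identical(totals$N + totals$S, 12L)
  sites <- suppressWarnings(enumerate_sites(g))
  expect_identical(attr(sites, "n_skipped_positions"), 2L)
  expect_false(any(sites$cds_position %in% c(1L, 6L)))
})

test_that("site spectra agree with the naive brute-force oracle", {
  genes <- simulate_genes(8, n_codons = c(4, 25), ntn_fraction = c(0.1, 0.8),
    seed = 99
  )
  for (i in seq_len(nrow(genes))) {
    expect_spectrum_matches_oracle(genes[i, ])
  }
})

test_that("spectrum classes all come from the canonical 96-class list", {
  genes <- simulate_genes(3, n_codons = 30, seed = 5)
  sites <- enumerate_sites(genes)
  expect_true(all(sites$class %in% substitution_classes("96")))
  sp <- site_spectra(genes)
  expect_identical(nrow(sp), 3L * 96L)
})

test_that("malformed gene tables are rejected", {
  expect_error(
    validate_genes(tibble::tibble(gene_id = "g", cds = "ATGA")),
    "multiple of 3"
  )
  expect_error(
    validate_genes(tibble::tibble(gene_id = "g", cds = "ATGNNN")),
    "A, C, G, T"
  )
  expect_warning(
    validate_genes(tibble::tibble(gene_id = "g", cds = "TAAATG")),
    "Internal stop"
  )
  expect_error(
    validate_genes(
      tibble::tibble(gene_id = "g", cds = "TAAATG"),
      stop_handling = "error"
    ),
    "Internal stop"
  )
  expect_error(
    validate_genes(tibble::tibble(gene_id = c("g", "g"), cds = "ATGTTT")),
    "Duplicated"
  )
})

test_that("annotation attaches class and consequence and deduplicates", {
  genes <- toy_genes()
  raw <- tibble::tibble(
    sample_id = c("s1", "s1", "s2", "s3", "s4", "s5"),
    gene_id = c("phe", "phe", "phe", "nope", "phe", "one_codon"),
    cds_position = c(3L, 3L, 3L, 1L, 2L, 1L),
    ref = c("T", "T", "T", "A", "A", "A"),
    alt = c("C", "C", "G", "G", "G", "G")
  )
  ann <- suppressMessages(annotate_mutations(raw, genes))
  # duplicate s1 line collapsed; unknown gene and ref mismatch rejected
  expect_identical(nrow(ann), 3L)
  rej <- attr(ann, "rejections")
  expect_setequal(rej$reason, c("duplicate_line", "unknown_gene", "ref_mismatch"))
  expect_identical(sum(rej$n), 3L)
  phe3 <- ann[ann$gene_id == "phe" & ann$sample_id == "s1", ]
  expect_identical(phe3$consequence, "synonymous") # TTT -> TTC
  expect_identical(phe3$class, "T[T>C]C") # context T_ T, downstream flank C
  expect_identical(
    ann$impact[ann$gene_id == "one_codon"],
    "nonsynonymous"
  )
})

test_that("non-point and out-of-range records are rejected, not fatal", {
  genes <- toy_genes()
  raw <- tibble::tibble(
    sample_id = c("s1", "s2", "s3", "s4"),
    gene_id = "phe",
    cds_position = c(1L, 9L, 2L, 1L),
    ref = c("TT", "T", "T", "T"),
    alt = c("AA", "A", "T", "A")
  )
  ann <- suppressMessages(annotate_mutations(raw, genes))
  expect_identical(nrow(ann), 1L)
  expect_identical(ann$sample_id, "s4")
  rej <- attr(ann, "rejections")
  expect_setequal(
    rej$reason,
    c("not_point_substitution", "position_outside_cds")
  )
})

test_that("supplied context columns override the derived context", {
  genes <- tibble::tibble(gene_id = "g", cds = "TTTTTT", flank5 = "A", flank3 = "A")
  raw <- tibble::tibble(
    sample_id = "s1", gene_id = "g", cds_position = 3L,
    ref = "T", alt = "C", upstream = "G", downstream = "G"
  )
  ann <- annotate_mutations(raw, genes, quiet = TRUE)
  expect_identical(ann$class, classify_substitution("T", "C", "G", "G"))
})

test_that("the mutation-count gene filter is inclusive at the threshold", {
  mut <- tibble::tibble(
    gene_id = c(rep("nine", 9), rep("ten", 10), rep("many", 25))
  )
  expect_identical(filter_analyzable_genes(mut, 10), c("many", "ten"))
  expect_identical(
    filter_analyzable_genes(mut, 0),
    c("many", "nine", "ten")
  )
})
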