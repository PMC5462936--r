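test_that("basic dN/dS evaluates the site-normalized ratio", {
  expect_equal(dnds_basic(20, 10, 200, 100), 1)
  expect_equal(dnds_basic(10, 10, 300, 100), 1 / 3)
  expect_true(is.na(dnds_basic(5, 0, 300, 100))) # undefined, not infinite
  expect_error(dnds_basic(5, 5, 0, 100), "positive")
})

test_that("expected counts weight the spectrum by class probabilities", {
  # two-class toy in 96-class space: all non-synonymous sites in one class,
  # all synonymous sites in another, probabilities 0.9 / 0.1
  spectra <- tibble::tibble(
    gene_id = "g",
    class = substitution_classes("96"),
    nonsyn = ifelse(substitution_classes("96") == "A[C>A]A", 10L, 0L),
    syn = ifelse(substitution_classes("96") == "A[C>G]A", 10L, 0L)
  )
  sig <- as_signature(c("A[C>A]A" = 0.9, "A[C>G]A" = 0.1))
  exp_counts <- expected_mutation_counts(spectra, sig)
  expect_equal(exp_counts$N_ms, 9)
  expect_equal(exp_counts$S_ms, 1)
  # corrected dN/dS of the toy: (9/1) / (9/1) = 1
  expect_equal(dnds_corrected(9, 1, exp_counts$N_ms, exp_counts$S_ms), 1)
  # simulated dN/dS of the toy: (9/1) / (10/10) = 9
  expect_equal(dnds_simulated(exp_counts$N_ms, exp_counts$S_ms, 10, 10), 9)
  # uniform weights cancel: N_ms/S_ms = N/S
  u <- expected_mutation_counts(spectra, uniform_signature("96"))
  expect_equal(u$N_ms / u$S_ms, 1)
  expect_equal(u$N_ms, 10 / 96)
})

test_that("degenerate expected counts yield the undefined marker", {
  expect_true(is.na(dnds_corrected(9, 1, 5, 0)))
  expect_true(is.na(dnds_corrected(9, 0, 5, 5)))
  expect_true(is.na(dnds_simulated(5, 0, 10, 10)))
})

test_that("under a uniform profile the corrected dN/dS is the basic dN/dS", {
  genes <- simulate_genes(50, n_codons = c(20, 120), seed = 314)
  spectra <- site_spectra(genes)
  totals <- spectrum_totals(spectra)
  exp_counts <- expected_mutation_counts(spectra, uniform_signature("96")) |>
    dplyr::inner_join(totals, by = "gene_id")
  n <- 17
  s <- 5
  expect_equal(
    dnds_corrected(n, s, exp_counts$N_ms, exp_counts$S_ms),
    dnds_basic(n, s, exp_counts$N, exp_counts$S)
  )
  expect_equal(
    dnds_simulated(exp_counts$N_ms, exp_counts$S_ms, exp_counts$N, exp_counts$S),
    rep(1, 50)
  )
})

test_that("corrected = basic / simulated wherever all are defined", {
  cohort <- simulate_cohort(
    n_genes = 30, n_codons = c(50, 150),
    mutations_per_gene = 80, seed = 21
  )
  res <- tidy(dnds_select(cohort$mutations, cohort$genes, quiet = TRUE))
  defined <- !is.na(res$dnds_corrected) & !is.na(res$dnds_basic)
  expect_gt(sum(defined), 0)
  expect_equal(
    res$dnds_corrected[defined],
    res$dnds_basic[defined] / res$dnds_simulated[defined]
  )
})

test_that("class-probability sweep reproduces the C>T-driven drop", {
  genes <- simulate_genes(5, n_codons = c(80, 120), seed = 8)
  spectra <- site_spectra(genes)
  # p = 1/6 for any class equals the uniform case exactly
  for (cl in substitution_classes("6")) {
    sw <- signature_sweep(spectra, cl, 1 / 6)
    expect_equal(sw$dnds_simulated, 1)
  }
  grid <- seq(0.1, 0.9, 0.1)
  ct <- signature_sweep(spectra, "C>T", grid)
  expect_true(all(diff(ct$dnds_simulated) < 0)) # monotone drop
  ca <- signature_sweep(spectra, "C>A", grid)
  # C>A carries little synonymous opportunity: flat-to-increasing trend
  expect_gt(ca$dnds_simulated[9], ca$dnds_simulated[1] - 0.05)
  expect_lt(
    ct$dnds_simulated[9],
    ca$dnds_simulated[9]
  )
  expect_error(signature_sweep(spectra, "C>T", 1.2), "0, 1")
  expect_error(signature_sweep(spectra, "G>T", 0.5), "6 main")
})

test_that("proportional renormalization preserves the other classes' ratios", {
  genes <- simulate_genes(3, n_codons = 60, seed = 9)
  spectra <- site_spectra(genes)
  base <- melanoma_like_signature("6")
  sw <- signature_sweep(spectra, "C>T", 0.876,
    renormalization = "proportional", base_signature = base
  )
  # at the base profile's own probability the sweep reproduces the base
  exp_counts <- expected_mutation_counts(spectra, base) |>
    dplyr::inner_join(spectrum_totals(spectra), by = "gene_id")
  expect_equal(
    sw$dnds_simulated,
    median(dnds_simulated(
      exp_counts$N_ms, exp_counts$S_ms, exp_counts$N, exp_counts$S
    ))
  )
})

test_that("the binomial selection test has the closed-form lower tail", {
  expect_equal(binom_selection_test(0, 10, 75, 25), 0.25^10)
  # observed proportion at the null keeps p above one half
  expect_gte(binom_selection_test(75, 25, 75, 25), 0.5)
  # full support: all mutations non-synonymous gives the whole CDF
  expect_equal(binom_selection_test(10, 0, 75, 25), 1)
  # agreement with stats::binom.test as an independent oracle
  p_pkg <- binom_selection_test(12, 28, 300, 100)
  p_bt <- binom.test(12, 40, 0.75, alternative = "less")$p.value
  expect_equal(p_pkg, p_bt)
  p_pkg_g <- binom_selection_test(39, 1, 300, 100, alternative = "greater")
  p_bt_g <- binom.test(39, 40, 0.75, alternative = "greater")$p.value
  expect_equal(p_pkg_g, p_bt_g)
  expect_error(binom_selection_test(0, 0, 1, 1), "at least one")
  expect_error(binom_selection_test(1, 1, 0, 1), "positive")
})

test_that("BH adjustment is the step-up procedure", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  q <- bh_adjust(p)
  expect_identical(sum(q < 0.05), 4L) # all four pass i*q/m
  expect_equal(q, p.adjust(p, method = "BH"))
  expect_equal(bh_adjust(0.03), 0.03) # m = 1
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p_rand <- runif(20)
  q_rand <- bh_adjust(p_rand)
  expect_true(all(q_rand >= p_rand & q_rand <= 1)) # step-up never lowers p
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("Fisher enrichment builds the right 2x2 tables", {
  background <- sprintf("g%03d", 1:100)
  hits <- background[1:20]
  # identical proportions: no association
  sets <- list(balanced = background[seq(1, 100, 5)])
  res <- fisher_enrichment(hits, background, sets)
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p_value, 1)
  # table (10, 10, 10, 70): sample odds ratio 7, p from the exact test
  sets2 <- list(half_in = background[c(1:10, 21:30)])
  res2 <- fisher_enrichment(hits, background, sets2)
  expect_identical(res2$n_hit_in_set, 10L)
  expect_equal(res2$odds_ratio, 7)
  expect_equal(
    res2$p_value,
    fisher.test(matrix(c(10, 10, 10, 70), 2))$p.value
  )
  # depletion shows an odds ratio below 1
  sets3 <- list(depleted = background[c(21:60)])
  res3 <- fisher_enrichment(hits, background, sets3)
  expect_lt(res3$odds_ratio, 1)
  # empty intersection is skipped with a warning, not an error
  expect_warning(
    res4 <- fisher_enrichment(hits, background,
      list(ghost = c("zz1"), real = background[1:10])
    ),
    "Skipping"
  )
  expect_identical(res4$set, "real")
  expect_error(fisher_enrichment(c("zz9"), background, sets), "subset")
})
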