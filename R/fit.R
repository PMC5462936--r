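#' Signature-aware per-gene selection analysis
#'
#' The full analysis chain: annotate and deduplicate the mutation catalog,
#' keep genes with at least `min_mutations` coding point mutations,
#' enumerate each gene's site spectrum, estimate the mutational signature
#' from the catalog (or use a supplied profile), and compute for every gene
#' the basic, corrected and simulated dN/dS together with a one-tailed
#' binomial test for purifying selection and BH FDR control across genes.
#'
#' @param mutations Raw or annotated mutation tibble. Raw tables are passed
#'   through [annotate_mutations()] first.
#' @param genes Gene tibble (see [validate_genes()]).
#' @param signature Optional signature tibble (6- or 96-class). By default
#'   the signature is estimated from the same catalog being tested, which
#'   assumes selection does not materially distort the signature;
#'   supplying an external profile (e.g. from whole-genome data) avoids
#'   that assumption.
#' @param mode `"96"` (default) or `"6"`: class space used when estimating
#'   the signature. All expected-count computation happens in 96-class
#'   space (6-class profiles are expanded uniformly over contexts).
#' @param min_mutations Gene inclusion threshold (default 10 coding point
#'   mutations).
#' @param test_metric Which metric the binomial null targets:
#'   `"corrected"` (default, null proportion `N_ms / (N_ms + S_ms)`) or
#'   `"basic"` (null proportion `N / (N + S)`).
#' @param alternative `"less"` (purifying selection, default) or
#'   `"greater"`.
#' @param fdr FDR threshold used for the `significant` flag (default 0.05).
#' @param quiet Suppress progress messages.
#' @inheritParams validate_genes
#'
#' @return A `dnds_fit` object; see [tidy.dnds_fit()] for the per-gene
#'   table and [glance.dnds_fit()] for the one-row summary.
#' @examples
#' cohort <- simulate_cohort(
#'   n_genes = 20, n_codons = c(80, 120),
#'   mutations_per_gene = 40, seed = 1
#' )
#' fit <- dnds_select(cohort$mutations, cohort$genes, quiet = TRUE)
#' glance(fit)
#' @export
dnds_select <- function(mutations, genes, signature = NULL,
                        mode = c("96", "6"), min_mutations = 10,
                        test_metric = c("corrected", "basic"),
                        alternative = c("less", "greater"),
                        fdr = 0.05, quiet = FALSE,
                        stop_handling = c("warn", "error")) {
  mode <- match.arg(as.character(mode), c("96", "6"))
  test_metric <- match.arg(test_metric)
  alternative <- match.arg(alternative)
  genes <- validate_genes(genes, stop_handling)
  if (!all(c("class", "impact") %in% names(mutations))) {
    mutations <- annotate_mutations(mutations, genes, quiet = quiet)
  }
  if (is.null(signature)) {
    if (nrow(mutations) == 0) {
      abort("No usable mutations: cannot estimate a signature.")
    }
    signature <- estimate_signature(mutations, mode = mode)
  } else {
    signature <- as_signature(signature)
  }

  keep <- filter_analyzable_genes(mutations, min_mutations)
  config <- list(
    mode = mode, min_mutations = min_mutations, test_metric = test_metric,
    alternative = alternative, fdr = fdr
  )
  if (length(keep) == 0) {
    empty <- tibble::tibble(
      gene_id = character(0), n = integer(0), s = integer(0),
      N = integer(0), S = integer(0), N_ms = numeric(0), S_ms = numeric(0),
      dnds_basic = numeric(0), dnds_corrected = numeric(0),
      dnds_simulated = numeric(0), p_value = numeric(0),
      q_value = numeric(0), significant = logical(0)
    )
    return(new_dnds_fit(empty, signature, config, nrow(mutations)))
  }

  mut_kept <- mutations[mutations$gene_id %in% keep, , drop = FALSE]
  spectra <- site_spectra(genes[genes$gene_id %in% keep, , drop = FALSE],
    stop_handling
  )
  observed <- mut_kept |>
    dplyr::count(.data$gene_id, .data$impact) |>
    tidyr::pivot_wider(
      names_from = "impact", values_from = "n", values_fill = 0L
    )
  for (col in c("nonsynonymous", "synonymous")) {
    if (!col %in% names(observed)) observed[[col]] <- 0L
  }
  observed <- dplyr::rename(observed, n = "nonsynonymous", s = "synonymous")

  res <- observed |>
    dplyr::inner_join(spectrum_totals(spectra), by = "gene_id") |>
    dplyr::inner_join(
      expected_mutation_counts(spectra, signature),
      by = "gene_id"
    ) |>
    dplyr::mutate(
      dnds_basic = dnds_basic(.data$n, .data$s, .data$N, .data$S),
      dnds_corrected = dnds_corrected(
        .data$n, .data$s, .data$N_ms, .data$S_ms
      ),
      dnds_simulated = dnds_simulated(
        .data$N_ms, .data$S_ms, .data$N, .data$S
      ),
      p_value = if (test_metric == "corrected") {
        binom_selection_test(
          .data$n, .data$s, .data$N_ms, .data$S_ms, alternative
        )
      } else {
        binom_selection_test(.data$n, .data$s, .data$N, .data$S, alternative)
      },
      q_value = bh_adjust(.data$p_value),
      significant = .data$q_value < fdr
    ) |>
    dplyr::arrange(.data$gene_id)
  new_dnds_fit(res, signature, config, nrow(mutations))
}

new_dnds_fit <- function(gene_results, signature, config, n_mutations) {
  structure(
    list(
      gene_results = gene_results,
      signature = signature,
      config = config,
      n_mutations = n_mutations
    ),
    class = "dnds_fit"
  )
}

#' @export
print.dnds_fit <- function(x, ...) {
  g <- glance(x)
  cat("Signature-aware dN/dS selection analysis\n")
  cat(sprintf(
    "  %d mutations; %d genes with >= %d mutations\n",
    x$n_mutations, g$n_genes, x$config$min_mutations
  ))
  cat(sprintf(
    "  median dN/dS: basic %.3f, corrected %.3f, simulated %.3f\n",
    g$median_dnds_basic, g$median_dnds_corrected, g$median_dnds_simulated
  ))
  cat(sprintf(
    "  %d gene(s) significant at %g%% FDR (%s metric, one-tailed '%s')\n",
    g$n_significant, 100 * x$config$fdr, x$config$test_metric,
    x$config$alternative
  ))
  invisible(x)
}

#' Per-gene results of a selection analysis
#'
#' @param x A `dnds_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per analyzed gene: observed counts `n`,
#'   `s`; site counts `N`, `S`; signature-expected counts `N_ms`, `S_ms`;
#'   `dnds_basic`, `dnds_corrected`, `dnds_simulated`; `p_value`,
#'   `q_value`, `significant`.
#' @exportS3Method generics::tidy
#' @export
tidy.dnds_fit <- function(x, ...) {
  x$gene_results
}

#' One-row summary of a selection analysis
#'
#' Medians are taken over genes with defined ratios; genes with undefined
#' ratios (`s == 0` or degenerate expected counts) are counted in
#' `n_undefined`.
#'
#' @inheritParams tidy.dnds_fit
#' @return A one-row tibble.
#' @exportS3Method generics::glance
#' @export
glance.dnds_fit <- function(x, ...) {
  g <- x$gene_results
  tibble::tibble(
    n_genes = nrow(g),
    n_mutations = x$n_mutations,
    median_dnds_basic = median(g$dnds_basic, na.rm = TRUE),
    median_dnds_corrected = median(g$dnds_corrected, na.rm = TRUE),
    median_dnds_simulated = median(g$dnds_simulated, na.rm = TRUE),
    n_undefined = sum(is.na(g$dnds_corrected)),
    n_significant = sum(g$significant, na.rm = TRUE),
    fdr = x$config$fdr
  )
}
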