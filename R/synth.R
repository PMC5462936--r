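#' Simulate in-frame coding sequences with controlled NTN-codon content
#'
#' Generates random CDSs without internal stop codons. Each codon is, with
#' probability `ntn_fraction`, drawn uniformly from the 16 NTN codons
#' (thymine at the second position — all encoding hydrophobic amino acids,
#' as in transmembrane segments) and otherwise uniformly from the 45
#' non-NTN sense codons. Per-gene `ntn_fraction` values allow mixed
#' cohorts, e.g. a "membrane-like" NTN-rich group against a "soluble-like"
#' NTN-poor group. Flanking bases are drawn uniformly.
#'
#' @param n_genes Number of genes.
#' @param n_codons Integer length range `c(min, max)` (codons, uniform), or
#'   a single fixed length.
#' @param ntn_fraction Target NTN-codon fraction, scalar or length
#'   `n_genes` (recycled). The number of NTN codons per gene is the
#'   rounded target count, placed at random positions, so the realized
#'   fraction matches the target to within rounding.
#' @param seed Optional integer seed for reproducibility.
#' @return A gene tibble (`gene_id`, `cds`, `flank5`, `flank3`) with the
#'   extra columns `ntn_target` and `ntn_realized`.
#' @examples
#' simulate_genes(3, n_codons = c(50, 80), ntn_fraction = 0.5, seed = 1)
#' @export
simulate_genes <- function(n_genes, n_codons = c(100, 300),
                           ntn_fraction = 0.25, seed = NULL) {
  if (n_genes < 1) abort("`n_genes` must be at least 1.")
  if (!is.null(seed)) set.seed(seed)
  if (length(n_codons) == 1L) n_codons <- rep(n_codons, 2)
  if (n_codons[1] < 2) abort("Genes must have at least 2 codons.")
  frac <- rep_len(ntn_fraction, n_genes)
  if (any(frac < 0 | frac > 1)) {
    abort("`ntn_fraction` must lie in [0, 1].")
  }
  gc <- .genetic_code()
  ntn_pool <- names(gc)[substr(names(gc), 2, 2) == "T"]
  other_pool <- names(gc)[substr(names(gc), 2, 2) != "T" & gc != "*"]
  lens <- sample(seq(n_codons[1], n_codons[2]), n_genes, replace = TRUE)
  rows <- purrr::map(seq_len(n_genes), function(i) {
    n_ntn <- round(frac[i] * lens[i])
    is_ntn <- sample(rep(c(TRUE, FALSE), c(n_ntn, lens[i] - n_ntn)))
    codons <- character(lens[i])
    codons[is_ntn] <- sample(ntn_pool, sum(is_ntn), replace = TRUE)
    codons[!is_ntn] <- sample(other_pool, sum(!is_ntn), replace = TRUE)
    tibble::tibble(
      gene_id = sprintf("g%04d", i),
      cds = paste(codons, collapse = ""),
      flank5 = sample(.BASES, 1),
      flank3 = sample(.BASES, 1),
      ntn_target = frac[i],
      ntn_realized = mean(is_ntn)
    )
  })
  purrr::list_rbind(rows)
}

#' Simulate a signature-driven somatic mutation catalog
#'
#' Implements the generative model underlying the simulated-dN/dS
#' diagnostic: mutations arise neutrally from the mutational signature,
#' optionally thinned by purifying selection. For each gene, a mutation
#' count is drawn (Poisson with mean `mutations_per_gene`, or negative
#' binomial when `dispersion` is finite), and each mutation picks one of
#' the gene's possible single-base changes with sampling weight equal to
#' the signature probability of that change's substitution class. Under
#' this site-level weighting the expected non-synonymous fraction of a
#' gene is exactly `N_ms / (N_ms + S_ms)`, so the corrected dN/dS of a
#' neutral cohort is centered at 1 by construction. Purifying selection
#' then discards each non-synonymous event independently with probability
#' `selection_strength`, so the expected corrected dN/dS is
#' `1 - selection_strength`.
#'
#' Each retained mutation is assigned a sample barcode drawn from
#' `n_samples` synthetic samples; duplicate (sample, gene, position)
#' records are dropped, matching the deduplication applied to real
#' catalogs.
#'
#' @param genes Gene tibble (see [validate_genes()] / [simulate_genes()]).
#' @param signature Signature tibble (6-class profiles are expanded to 96).
#' @param mutations_per_gene Mean pre-selection mutation count per gene.
#' @param dispersion Negative-binomial size parameter; `Inf` (default)
#'   gives Poisson counts.
#' @param selection_strength Probability `f` in `[0, 1]` that a
#'   non-synonymous event is removed before observation.
#' @param n_samples Number of synthetic sample barcodes.
#' @param seed Optional integer seed.
#' @return A raw mutation tibble (`sample_id`, `gene_id`, `cds_position`,
#'   `ref`, `alt`). Genes with no site in any positive-probability class
#'   are skipped with a warning.
#' @export
simulate_mutations <- function(genes, signature,
                               mutations_per_gene = 200,
                               dispersion = Inf,
                               selection_strength = 0,
                               n_samples = 400, seed = NULL) {
  if (selection_strength < 0 || selection_strength > 1) {
    abort("`selection_strength` must lie in [0, 1].")
  }
  if (!is.null(seed)) set.seed(seed)
  genes <- validate_genes(genes)
  sig <- expand_signature(signature)
  p <- setNames(sig$probability, sig$class)
  barcodes <- sprintf("S%04d", seq_len(n_samples))
  rows <- purrr::map(seq_len(nrow(genes)), function(i) {
    sites <- .sites_one_gene(
      genes$cds[i], genes$flank5[i], genes$flank3[i]
    )
    w <- unname(p[sites$class])
    if (nrow(sites) == 0 || sum(w) <= 0) {
      warn(sprintf(
        "Gene %s has no mutable site under the signature; skipped.",
        genes$gene_id[i]
      ))
      return(NULL)
    }
    m <- if (is.finite(dispersion)) {
      rnbinom(1, size = dispersion, mu = mutations_per_gene)
    } else {
      rpois(1, mutations_per_gene)
    }
    if (m == 0) {
      return(NULL)
    }
    idx <- sample.int(nrow(sites), m, replace = TRUE, prob = w)
    drawn <- sites[idx, , drop = FALSE]
    nonsyn <- drawn$consequence != "synonymous"
    keep <- !nonsyn | runif(m) >= selection_strength
    drawn <- drawn[keep, , drop = FALSE]
    if (nrow(drawn) == 0) {
      return(NULL)
    }
    drawn$sample_id <- sample(barcodes, nrow(drawn), replace = TRUE)
    drawn$gene_id <- genes$gene_id[i]
    drawn[
      !duplicated(drawn[c("sample_id", "cds_position")]),
      c("sample_id", "gene_id", "cds_position", "ref", "alt")
    ]
  })
  purrr::list_rbind(rows)
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper: generates genes, then a signature-driven mutation
#' catalog, with independent random substreams derived from one global
#' seed. The default signature is the stylized melanoma-like 96-class
#' profile, giving a cohort whose basic dN/dS is biased below 1 while the
#' true (corrected) selection level is `1 - selection_strength`.
#'
#' @inheritParams simulate_genes
#' @inheritParams simulate_mutations
#' @param signature Signature tibble (default
#'   `melanoma_like_signature("96")`).
#' @param seed Integer seed governing both generation stages.
#' @return A list with elements `genes`, `mutations`, `signature`,
#'   `selection_strength` and `seed`.
#' @export
simulate_cohort <- function(n_genes = 200, n_codons = c(100, 300),
                            ntn_fraction = 0.25,
                            signature = melanoma_like_signature("96"),
                            mutations_per_gene = 200, dispersion = Inf,
                            selection_strength = 0, n_samples = 400,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, 2)
  genes <- simulate_genes(n_genes, n_codons, ntn_fraction, seed = subseeds[1])
  mutations <- simulate_mutations(
    genes, signature,
    mutations_per_gene = mutations_per_gene, dispersion = dispersion,
    selection_strength = selection_strength, n_samples = n_samples,
    seed = subseeds[2]
  )
  list(
    genes = genes, mutations = mutations,
    signature = as_signature(signature),
    selection_strength = selection_strength, seed = seed
  )
}
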