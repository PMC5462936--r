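#' Basic (uniform-model) dN/dS
#'
#' The classic site-count normalization: the ratio of observed
#' non-synonymous to synonymous mutations, normalized to the ratio of
#' non-synonymous to synonymous sites,
#' \deqn{dN/dS = (n/N) / (s/S) = (n/s) (S/N).}
#' It assumes every possible substitution is equally likely — an assumption
#' violated in tumors with skewed mutational signatures, which is what the
#' corrected estimator addresses.
#'
#' @param n,s Observed non-synonymous and synonymous mutation counts.
#' @param N,S Non-synonymous and synonymous site counts (must be positive).
#' @return Numeric vector; `NA` where `s == 0` (undefined ratio, excluded
#'   from medians).
#' @examples
#' dnds_basic(10, 10, 300, 100)
#' @export
dnds_basic <- function(n, s, N, S) {
  if (any(N <= 0) || any(S <= 0)) {
    abort("`N` and `S` must be positive (degenerate gene).")
  }
  r <- (n / s) * (S / N)
  r[rep_len(s, length(r)) == 0] <- NA_real_
  r
}

#' Expected mutation counts under a mutational signature
#'
#' Weights each gene's per-class site counts by the signature class
#' probabilities: `N_ms = sum_i N_i P_i` and `S_ms = sum_i S_i P_i`, the
#' expected numbers of non-synonymous and synonymous mutations in the gene
#' if mutations were driven purely by the signature with no selection.
#'
#' @param spectra Site spectra from [site_spectra()].
#' @param signature Signature tibble; a 6-class profile is expanded
#'   uniformly over contexts ([expand_signature()]).
#' @return A tibble with columns `gene_id`, `N_ms`, `S_ms`.
#' @export
expected_mutation_counts <- function(spectra, signature) {
  sig <- expand_signature(signature)
  spectra |>
    dplyr::inner_join(sig, by = "class") |>
    dplyr::summarise(
      N_ms = sum(.data$nonsyn * .data$probability),
      S_ms = sum(.data$syn * .data$probability),
      .by = "gene_id"
    )
}

#' Signature-corrected dN/dS
#'
#' Replaces the site counts of the basic estimator with the expected
#' mutation counts under the tumor's mutational signature:
#' \deqn{corrected\ dN/dS = (n/s) / (N_{ms}/S_{ms}).}
#' Under a uniform signature this reduces exactly to the basic dN/dS.
#'
#' @inheritParams dnds_basic
#' @param N_ms,S_ms Expected mutation counts from
#'   [expected_mutation_counts()].
#' @return Numeric vector; `NA` where `s == 0` or `S_ms == 0` or
#'   `N_ms == 0` (undefined).
#' @export
dnds_corrected <- function(n, s, N_ms, S_ms) {
  if (any(N_ms < 0) || any(S_ms < 0)) {
    abort("Expected counts must be non-negative.")
  }
  r <- (n / s) * (S_ms / N_ms)
  undef <- rep_len(s, length(r)) == 0 |
    rep_len(S_ms, length(r)) == 0 | rep_len(N_ms, length(r)) == 0
  r[undef] <- NA_real_
  r
}

#' Simulated (signature-bias) dN/dS
#'
#' The dN/dS value a gene is *expected* to show under the signature alone,
#' with no selection: the expected mutation-count ratio normalized to the
#' site-count ratio,
#' \deqn{simulated\ dN/dS = (N_{ms}/S_{ms}) / (N/S).}
#' Values below 1 quantify how strongly the signature mimics purifying
#' selection in that gene. The three estimators satisfy
#' `corrected = basic / simulated` wherever all are defined.
#'
#' @inheritParams dnds_corrected
#' @return Numeric vector; `NA` where any denominator is degenerate.
#' @export
dnds_simulated <- function(N_ms, S_ms, N, S) {
  if (any(N <= 0) || any(S <= 0)) {
    abort("`N` and `S` must be positive (degenerate gene).")
  }
  r <- (N_ms / S_ms) / (N / S)
  r[rep_len(S_ms, length(r)) == 0] <- NA_real_
  r
}

#' Sweep one substitution-class probability and track the simulated dN/dS
#'
#' Builds, for each grid value `p`, a 6-class signature with the chosen
#' class at probability `p` and — under `"equal"` renormalization — the
#' other five classes at `(1 - p) / 5`; under `"proportional"`, the other
#' classes keep their relative proportions from `base_signature`. The
#' profile is expanded to 96 classes and the median simulated dN/dS across
#' the supplied genes is computed. Increasing C>T (and to a lesser extent
#' T>C) probability depresses simulated dN/dS, because the genetic code's
#' redundancy concentrates synonymous opportunity in those classes.
#'
#' @param spectra Site spectra from [site_spectra()].
#' @param sweep_class One of the 6 main classes, e.g. `"C>T"`.
#' @param probabilities Numeric grid in `[0, 1]`.
#' @param renormalization `"equal"` (default) or `"proportional"`.
#' @param base_signature 6-class signature used by `"proportional"`
#'   renormalization (default uniform).
#' @return A tibble with columns `sweep_class`, `probability`,
#'   `dnds_simulated` (median across genes), `n_genes`.
#' @export
signature_sweep <- function(spectra, sweep_class, probabilities = seq(0, 1, 0.1),
                            renormalization = c("equal", "proportional"),
                            base_signature = NULL) {
  renormalization <- match.arg(renormalization)
  six <- substitution_classes("6")
  if (!sweep_class %in% six) {
    abort("`sweep_class` must be one of the 6 main substitution classes.")
  }
  if (any(probabilities < 0 | probabilities > 1)) {
    abort("`probabilities` must lie in [0, 1].")
  }
  base <- if (is.null(base_signature)) {
    uniform_signature("6")
  } else {
    marginalize_signature(as_signature(base_signature))
  }
  p_base <- setNames(base$probability, base$class)
  totals <- spectrum_totals(spectra)
  rows <- purrr::map(probabilities, function(p) {
    prof <- setNames(numeric(6), six)
    others <- setdiff(six, sweep_class)
    if (renormalization == "equal") {
      prof[others] <- (1 - p) / 5
    } else {
      rest <- p_base[others]
      prof[others] <- if (sum(rest) > 0) (1 - p) * rest / sum(rest) else 0
    }
    prof[sweep_class] <- p
    if (sum(prof) <= 0) {
      return(tibble::tibble(
        sweep_class = sweep_class, probability = p,
        dnds_simulated = NA_real_, n_genes = 0L
      ))
    }
    sig <- as_signature(prof)
    res <- expected_mutation_counts(spectra, sig) |>
      dplyr::inner_join(totals, by = "gene_id")
    sim <- dnds_simulated(res$N_ms, res$S_ms, res$N, res$S)
    tibble::tibble(
      sweep_class = sweep_class, probability = p,
      dnds_simulated = median(sim, na.rm = TRUE),
      n_genes = sum(!is.na(sim))
    )
  })
  purrr::list_rbind(rows)
}

#' One-tailed binomial test for purifying selection
#'
#' Tests whether the observed proportion of non-synonymous mutations among
#' all coding mutations of a gene is lower than expected. With `n + s`
#' coding mutations and expected non-synonymous proportion
#' `pi = N_exp / (N_exp + S_exp)` (site counts for the basic metric,
#' signature-expected counts for the corrected metric), the lower-tail
#' p-value is `P(X <= n)` for `X ~ Binomial(n + s, pi)` — a deficit of
#' non-synonymous mutations indicates dN/dS below 1.
#'
#' @inheritParams dnds_basic
#' @param N_exp,S_exp Expected non-synonymous / synonymous weights defining
#'   the null proportion; must be positive.
#' @param alternative `"less"` (purifying selection, default) or
#'   `"greater"` (positive selection).
#' @return Numeric vector of p-values.
#' @examples
#' binom_selection_test(0, 10, 75, 25) # 0.25^10
#' @export
binom_selection_test <- function(n, s, N_exp, S_exp,
                                 alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  if (any(N_exp <= 0) || any(S_exp <= 0)) {
    abort("Expected counts must be positive.")
  }
  size <- n + s
  if (any(size < 1)) {
    abort("Each gene needs at least one observed mutation (`n + s >= 1`).")
  }
  prob <- N_exp / (N_exp + S_exp)
  if (alternative == "less") {
    pbinom(n, size, prob)
  } else {
    pbinom(n - 1, size, prob, lower.tail = FALSE)
  }
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values), monotone in rank and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Fisher's exact test for gene-set enrichment
#'
#' For each gene set, builds the 2x2 table of hit/non-hit versus in-set /
#' out-of-set genes over the background universe and applies a two-sided
#' Fisher's exact test; q-values are BH-adjusted across the tested sets.
#' Odds ratios above 1 indicate enrichment of the set among hits, below 1
#' depletion (as for essential genes among low-dN/dS melanoma genes).
#'
#' @param hits Character vector of hit genes (must be a subset of
#'   `background`).
#' @param background Character vector: the gene universe.
#' @param gene_sets Named list of character vectors, or a tibble with
#'   columns `set` and `gene` (see [read_gene_sets()]).
#' @return A tibble with one row per tested set: `set`, `n_set`,
#'   `n_hit_in_set`, `odds_ratio` (sample odds ratio `ad/bc`), `p_value`,
#'   `q_value`. Sets with no member in the background are skipped with a
#'   warning.
#' @export
fisher_enrichment <- function(hits, background, gene_sets) {
  hits <- unique(hits)
  background <- unique(background)
  if (!all(hits %in% background)) {
    abort("`hits` must be a subset of `background`.")
  }
  if (is.data.frame(gene_sets)) {
    gene_sets <- split(gene_sets$gene, gene_sets$set)
  }
  if (is.null(names(gene_sets)) || any(names(gene_sets) == "")) {
    abort("`gene_sets` must be named.")
  }
  members <- purrr::map(gene_sets, ~ intersect(unique(.x), background))
  empty <- lengths(members) == 0
  if (any(empty)) {
    warn(sprintf(
      "Skipping %d gene set(s) with no member in the background: %s.",
      sum(empty), paste(names(members)[empty], collapse = ", ")
    ))
    members <- members[!empty]
  }
  rows <- purrr::imap(members, function(set_genes, set_name) {
    a <- length(intersect(hits, set_genes))
    b <- length(hits) - a
    c_ <- length(set_genes) - a
    d <- length(background) - length(hits) - c_
    tab <- matrix(c(a, b, c_, d), nrow = 2)
    tibble::tibble(
      set = set_name,
      n_set = length(set_genes),
      n_hit_in_set = a,
      odds_ratio = (a * d) / (b * c_),
      p_value = fisher.test(tab)$p.value
    )
  })
  out <- purrr::list_rbind(rows)
  out$q_value <- bh_adjust(out$p_value)
  out
}
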