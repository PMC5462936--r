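# Independent, deliberately naive re-implementations used as oracles.
# They share nothing with the package's lookup-table machinery: plain
# nested loops, translation through Biostrings, explicit strand logic.

oracle_translate <- function(codon) {
  as.character(Biostrings::translate(
    Biostrings::DNAString(codon),
    no.init.codon = TRUE
  ))
}

# Per-class synonymous / non-synonymous site counts for one gene by brute
# force: loop over positions and alternates, mutate the codon string,
# translate both, normalize the class by hand.
oracle_spectrum <- function(cds, flank5, flank3) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- c("A", "C", "G", "T")
  gc_tab <- vapply(
    names(Biostrings::GENETIC_CODE),
    oracle_translate,
    character(1)
  )
  counts <- list()
  len <- nchar(cds)
  for (p in seq_len(len)) {
    ref <- substr(cds, p, p)
    up <- if (p == 1) flank5 else substr(cds, p - 1, p - 1)
    down <- if (p == len) flank3 else substr(cds, p + 1, p + 1)
    if (!up %in% bases || !down %in% bases) next
    codon_start <- 3 * ((p - 1) %/% 3) + 1
    codon <- substr(cds, codon_start, codon_start + 2)
    pos_in_codon <- (p - 1) %% 3 + 1
    for (alt in setdiff(bases, ref)) {
      mut <- codon
      substr(mut, pos_in_codon, pos_in_codon) <- alt
      syn <- gc_tab[[codon]] == gc_tab[[mut]]
      r <- ref
      a <- alt
      u <- up
      d <- down
      if (r %in% c("A", "G")) {
        r <- comp[[ref]]
        a <- comp[[alt]]
        u <- comp[[down]]
        d <- comp[[up]]
      }
      label <- paste0(u, "[", r, ">", a, "]", d)
      key <- paste(label, if (syn) "syn" else "nonsyn")
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  counts
}

# Compare a site_spectra() result for one gene against the oracle counts.
expect_spectrum_matches_oracle <- function(gene_row) {
  spectrum <- site_spectra(gene_row)
  oracle <- oracle_spectrum(gene_row$cds, gene_row$flank5, gene_row$flank3)
  for (i in seq_len(nrow(spectrum))) {
    cls <- spectrum$class[i]
    expect_identical(
      spectrum$syn[i],
      oracle[[paste(cls, "syn")]] %||% 0L,
      label = sprintf("syn count for %s (%s)", cls, gene_row$gene_id)
    )
    expect_identical(
      spectrum$nonsyn[i],
      oracle[[paste(cls, "nonsyn")]] %||% 0L,
      label = sprintf("nonsyn count for %s (%s)", cls, gene_row$gene_id)
    )
  }
  invisible(spectrum)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

kl_divergence <- function(p, q) {
  keep <- p > 0
  sum(p[keep] * log(p[keep] / q[keep]))
}

# Small deterministic gene set reused across tests.
toy_genes <- function() {
  tibble::tibble(
    gene_id = c("one_codon", "phe"),
    cds = c("ATG", "TTT"),
    flank5 = c("C", "C"),
    flank3 = c("C", "C")
  )
}
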