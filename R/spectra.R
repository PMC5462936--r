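#' Validate a table of gene coding sequences
#'
#' Genes are represented as a tibble with one row per gene: `gene_id`, the
#' in-frame coding sequence `cds` (length a positive multiple of 3, bases
#' A/C/G/T), and single-base flanks `flank5` / `flank3` giving the
#' transcript-adjacent base on each side (`"N"` when unavailable, in which
#' case the terminal CDS positions have undefined context and are skipped).
#'
#' @param genes A data frame with columns `gene_id`, `cds`, and optionally
#'   `flank5`, `flank3` (defaulted to `"N"`).
#' @param stop_handling What to do when a CDS contains an internal stop
#'   codon: `"warn"` (default) or `"error"`.
#' @return The validated gene tibble.
#' @export
validate_genes <- function(genes, stop_handling = c("warn", "error")) {
  stop_handling <- match.arg(stop_handling)
  if (!all(c("gene_id", "cds") %in% names(genes))) {
    abort("`genes` must have columns `gene_id` and `cds`.")
  }
  genes <- tibble::as_tibble(genes)
  if (!"flank5" %in% names(genes)) genes$flank5 <- "N"
  if (!"flank3" %in% names(genes)) genes$flank3 <- "N"
  genes$cds <- toupper(genes$cds)
  genes$flank5 <- toupper(genes$flank5)
  genes$flank3 <- toupper(genes$flank3)
  if (anyDuplicated(genes$gene_id)) {
    abort("Duplicated `gene_id` in `genes`.")
  }
  bad_len <- nchar(genes$cds) < 3L | nchar(genes$cds) %% 3L != 0L
  if (any(bad_len)) {
    abort(sprintf(
      "CDS length must be a positive multiple of 3: %s.",
      paste(genes$gene_id[bad_len], collapse = ", ")
    ))
  }
  if (any(grepl("[^ACGT]", genes$cds))) {
    abort("CDS sequences may only contain A, C, G, T.")
  }
  if (any(!genes$flank5 %in% c(.BASES, "N")) ||
    any(!genes$flank3 %in% c(.BASES, "N"))) {
    abort("Flanks must be a single base or N.")
  }
  has_internal_stop <- vapply(genes$cds, function(cds) {
    n_codon <- nchar(cds) %/% 3L
    starts <- 3L * seq_len(n_codon) - 2L
    aa <- translate_codon(substring(cds, starts, starts + 2L))
    any(aa[-n_codon] == "*")
  }, logical(1))
  if (any(has_internal_stop)) {
    msg <- sprintf(
      "Internal stop codon in CDS of: %s.",
      paste(genes$gene_id[has_internal_stop], collapse = ", ")
    )
    if (stop_handling == "error") abort(msg) else warn(msg)
  }
  genes
}

# Site-level enumeration for a single CDS string: one row per possible
# single-base change (3 per position), with class and consequence.
.sites_one_gene <- function(cds, flank5, flank3) {
  b <- strsplit(cds, "")[[1]]
  len <- length(b)
  up <- c(flank5, b[-len])
  down <- c(b[-1], flank3)
  ok <- up %in% .BASES & down %in% .BASES
  codon_index <- (seq_len(len) - 1L) %/% 3L
  codon_pos <- (seq_len(len) - 1L) %% 3L + 1L
  codons <- substring(cds, codon_index * 3L + 1L, codon_index * 3L + 3L)
  idx <- rep(seq_len(len), each = 3L)
  alts <- as.vector(.alt_matrix()[, b])
  keep <- rep(ok, each = 3L)
  tibble::tibble(
    cds_position = idx[keep],
    ref = b[idx][keep],
    alt = alts[keep],
    class = unname(.class_lookup()[
      paste0(b[idx], alts, up[idx], down[idx])[keep]
    ]),
    consequence = unname(.conseq_lookup()[
      paste0(codons[idx], codon_pos[idx], alts)[keep]
    ]),
    n_skipped_positions = sum(!ok)
  )
}

#' Enumerate every possible single-base change of each gene
#'
#' Simulates the three possible point mutations at every CDS position and
#' annotates each with its substitution class (trinucleotide context from
#' the neighboring CDS bases, flanks at the termini) and coding
#' consequence. Positions whose context contains `N` are skipped; their
#' count is available as attribute `n_skipped_positions`.
#'
#' @param genes Gene tibble (see [validate_genes()]).
#' @inheritParams validate_genes
#' @return A tibble with columns `gene_id`, `cds_position`, `ref`, `alt`,
#'   `class`, `consequence`, `impact`.
#' @export
enumerate_sites <- function(genes, stop_handling = c("warn", "error")) {
  genes <- validate_genes(genes, stop_handling)
  out <- purrr::pmap(
    list(genes$gene_id, genes$cds, genes$flank5, genes$flank3),
    function(id, cds, f5, f3) {
      s <- .sites_one_gene(cds, f5, f3)
      s$gene_id <- id
      s
    }
  ) |>
    purrr::list_rbind()
  skipped <- sum(out$n_skipped_positions[!duplicated(out$gene_id)])
  out <- dplyr::mutate(out,
    impact = consequence_impact(.data$consequence),
    n_skipped_positions = NULL
  ) |>
    dplyr::relocate("gene_id")
  attr(out, "n_skipped_positions") <- skipped
  out
}

#' Per-gene site spectrum over the 96 substitution classes
#'
#' Counts, for every gene and every 96-class, the number of possible
#' non-synonymous (`nonsyn`, the N_i) and synonymous (`syn`, the S_i)
#' single-base changes. Summing over classes gives the non-synonymous and
#' synonymous site totals N and S of the basic dN/dS; weighting the sums by
#' signature probabilities gives the expected mutation counts of the
#' corrected dN/dS.
#'
#' @inheritParams enumerate_sites
#' @return A tibble with columns `gene_id`, `class`, `nonsyn`, `syn`
#'   (96 rows per gene, zero-filled).
#' @examples
#' g <- tibble::tibble(gene_id = "g1", cds = "TTT", flank5 = "C", flank3 = "C")
#' sp <- site_spectra(g)
#' sum(sp$nonsyn) # 8
#' sum(sp$syn) # 1
#' @export
site_spectra <- function(genes, stop_handling = c("warn", "error")) {
  sites <- enumerate_sites(genes, stop_handling)
  out <- sites |>
    dplyr::count(.data$gene_id, .data$class, .data$impact) |>
    tidyr::pivot_wider(
      names_from = "impact", values_from = "n", values_fill = 0L
    )
  for (col in c("nonsynonymous", "synonymous")) {
    if (!col %in% names(out)) out[[col]] <- 0L
  }
  out |>
    dplyr::rename(nonsyn = "nonsynonymous", syn = "synonymous") |>
    tidyr::complete(
      gene_id = unique(sites$gene_id),
      class = substitution_classes("96"),
      fill = list(nonsyn = 0L, syn = 0L)
    ) |>
    dplyr::mutate(
      class = factor(.data$class, levels = substitution_classes("96"))
    ) |>
    dplyr::arrange(.data$gene_id, .data$class) |>
    dplyr::mutate(class = as.character(.data$class))
}

#' Per-gene totals of a site spectrum
#'
#' @param spectra Output of [site_spectra()].
#' @return A tibble with columns `gene_id`, `N` (non-synonymous sites) and
#'   `S` (synonymous sites).
#' @export
spectrum_totals <- function(spectra) {
  spectra |>
    dplyr::summarise(
      N = sum(.data$nonsyn), S = sum(.data$syn),
      .by = "gene_id"
    )
}

#' Annotate, deduplicate and quality-filter a somatic mutation catalog
#'
#' Takes a raw mutation table (columns `sample_id`, `gene_id`,
#' `cds_position`, `ref`, `alt`; optional `upstream` / `downstream` columns
#' override the context derived from the CDS) and returns one annotated
#' record per retained mutation, with its substitution class and coding
#' consequence.
#'
#' Records are rejected individually (never failing the whole catalog) when
#' they name an unknown gene, are not single-base substitutions, fall
#' outside the CDS, disagree with the CDS reference base, or have undefined
#' (`N`) context. Duplicate lines — same sample barcode, gene and position —
#' are collapsed to the first occurrence. A summary of rejections is
#' attached as attribute `rejections` and reported as a message.
#'
#' @param mutations Raw mutation tibble.
#' @param genes Gene tibble (see [validate_genes()]).
#' @param quiet Suppress the rejection summary message.
#' @inheritParams validate_genes
#' @return Annotated mutation tibble with added columns `class`,
#'   `consequence`, `impact`.
#' @export
annotate_mutations <- function(mutations, genes, quiet = FALSE,
                               stop_handling = c("warn", "error")) {
  required <- c("sample_id", "gene_id", "cds_position", "ref", "alt")
  if (!all(required %in% names(mutations))) {
    abort(sprintf(
      "`mutations` must have columns %s.",
      paste(required, collapse = ", ")
    ))
  }
  genes <- validate_genes(genes, stop_handling)
  mut <- tibble::as_tibble(mutations)
  mut$ref <- toupper(mut$ref)
  mut$alt <- toupper(mut$alt)
  mut$cds_position <- suppressWarnings(as.integer(mut$cds_position))
  rejections <- character(0)

  drop <- function(mut, bad, reason) {
    if (any(bad)) {
      rejections <<- c(rejections, rep(reason, sum(bad)))
    }
    mut[!bad, , drop = FALSE]
  }

  mut <- drop(mut, !mut$gene_id %in% genes$gene_id, "unknown_gene")
  is_point <- nchar(mut$ref) == 1L & nchar(mut$alt) == 1L &
    mut$ref %in% .BASES & mut$alt %in% .BASES & mut$ref != mut$alt
  mut <- drop(mut, !is_point, "not_point_substitution")

  mut <- dplyr::left_join(
    mut,
    dplyr::select(genes, "gene_id", "cds", "flank5", "flank3"),
    by = "gene_id"
  )
  in_cds <- !is.na(mut$cds_position) & mut$cds_position >= 1L &
    mut$cds_position <= nchar(mut$cds)
  mut <- drop(mut, !in_cds, "position_outside_cds")

  cds_ref <- substr(mut$cds, mut$cds_position, mut$cds_position)
  mut <- drop(mut, cds_ref != mut$ref, "ref_mismatch")

  dup <- duplicated(mut[c("sample_id", "gene_id", "cds_position")])
  mut <- drop(mut, dup, "duplicate_line")

  # context: derived from the CDS and flanks unless supplied
  len <- nchar(mut$cds)
  derived_up <- ifelse(mut$cds_position == 1L, mut$flank5,
    substr(mut$cds, mut$cds_position - 1L, mut$cds_position - 1L)
  )
  derived_down <- ifelse(mut$cds_position == len, mut$flank3,
    substr(mut$cds, mut$cds_position + 1L, mut$cds_position + 1L)
  )
  up <- if ("upstream" %in% names(mut)) {
    dplyr::coalesce(toupper(mut$upstream), derived_up)
  } else {
    derived_up
  }
  down <- if ("downstream" %in% names(mut)) {
    dplyr::coalesce(toupper(mut$downstream), derived_down)
  } else {
    derived_down
  }
  defined <- up %in% .BASES & down %in% .BASES
  up <- up[defined]
  down <- down[defined]
  mut <- drop(mut, !defined, "undefined_context")

  if (nrow(mut) > 0) {
    codon_index <- (mut$cds_position - 1L) %/% 3L
    codon_pos <- (mut$cds_position - 1L) %% 3L + 1L
    codon <- substring(mut$cds, codon_index * 3L + 1L, codon_index * 3L + 3L)
    mut$class <- classify_substitution(mut$ref, mut$alt, up, down)
    mut$consequence <- codon_consequence(codon, codon_pos, mut$alt)
    mut$impact <- consequence_impact(mut$consequence)
  } else {
    mut$class <- character(0)
    mut$consequence <- character(0)
    mut$impact <- character(0)
  }
  mut <- dplyr::select(mut, -"cds", -"flank5", -"flank3")

  tab <- table(rejections)
  rej <- tibble::tibble(
    reason = names(tab), n = as.integer(tab)
  )
  if (!quiet && nrow(rej) > 0) {
    inform(sprintf(
      "annotate_mutations: %d record(s) removed (%s).",
      sum(rej$n),
      paste(sprintf("%s: %d", rej$reason, rej$n), collapse = ", ")
    ))
  }
  attr(mut, "rejections") <- rej
  mut
}

#' Genes with enough mutations to estimate dN/dS
#'
#' dN/dS is only meaningful when a gene carries a minimal number of somatic
#' point mutations across samples; the conventional threshold is 10 coding
#' point mutations (synonymous plus non-synonymous), applied inclusively.
#'
#' @param mutations Annotated mutation tibble.
#' @param min_mutations Minimum number of coding point mutations (default
#'   10).
#' @return Character vector of gene ids passing the filter.
#' @export
filter_analyzable_genes <- function(mutations, min_mutations = 10) {
  counts <- dplyr::count(mutations, .data$gene_id)
  sort(counts$gene_id[counts$n >= min_mutations])
}
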