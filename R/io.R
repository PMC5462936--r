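#' Read coding sequences with flanks from FASTA
#'
#' One record per gene; the header carries the gene id and, optionally,
#' single-base flanks as `flank5=X flank3=Y` tokens (defaulting to `N`,
#' i.e. unavailable context at the termini).
#'
#' @param path FASTA file path.
#' @return A gene tibble (`gene_id`, `cds`, `flank5`, `flank3`).
#' @export
read_cds_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- names(seqs)
  grab <- function(token) {
    m <- stringr::str_match(headers, paste0(token, "=([ACGTNacgtn])"))[, 2]
    toupper(dplyr::coalesce(m, "N"))
  }
  validate_genes(tibble::tibble(
    gene_id = stringr::str_split_i(headers, "\\s+", 1),
    cds = unname(toupper(as.character(seqs))),
    flank5 = grab("flank5"),
    flank3 = grab("flank3")
  ))
}

#' Write coding sequences with flanks to FASTA
#'
#' @param genes Gene tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(genes, path) {
  genes <- validate_genes(genes)
  seqs <- Biostrings::DNAStringSet(genes$cds)
  names(seqs) <- sprintf(
    "%s flank5=%s flank3=%s", genes$gene_id, genes$flank5, genes$flank3
  )
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read / write the minimal mutation table dialect
#'
#' Tab-separated, `#`-comments allowed, columns `sample_id`, `gene_id`,
#' `cds_position` (1-based within the CDS), `ref`, `alt`; optional
#' `upstream` / `downstream` columns override the context derived from the
#' CDS.
#'
#' @param path File path.
#' @return A raw mutation tibble.
#' @export
read_mutations_tsv <- function(path) {
  out <- readr::read_tsv(
    path,
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  required <- c("sample_id", "gene_id", "cds_position", "ref", "alt")
  if (!all(required %in% names(out))) {
    abort(sprintf(
      "Mutation table must have columns %s.", paste(required, collapse = ", ")
    ))
  }
  out$cds_position <- as.integer(out$cds_position)
  out
}

#' @rdname read_mutations_tsv
#' @param mutations Mutation tibble.
#' @export
write_mutations_tsv <- function(mutations, path) {
  readr::write_tsv(mutations, path)
  invisible(path)
}

#' Read a mutational signature from TSV
#'
#' Two columns: canonical class label (`"C>T"` or `"T[C>T]C"` style) and
#' probability. Probabilities are validated to sum to 1 (tolerance 1e-6)
#' and renormalized with a warning otherwise.
#'
#' @param path File path.
#' @return A signature tibble.
#' @export
read_signature_tsv <- function(path) {
  df <- readr::read_tsv(
    path,
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      class = readr::col_character(), probability = readr::col_double()
    )
  )
  as_signature(df, source = path)
}

#' Write a mutational signature to TSV
#'
#' @param signature Signature tibble.
#' @param path File path.
#' @export
write_signature_tsv <- function(signature, path) {
  readr::write_tsv(as_signature(signature), path)
  invisible(path)
}

#' Read gene sets from a GMT-style file
#'
#' One set per line: name, tab, description, tab-separated member genes.
#'
#' @param path File path.
#' @return A tibble with columns `set`, `description`, `gene`.
#' @export
read_gene_sets <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- purrr::map(lines, function(line) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      abort("Each GMT line needs a name, a description and >= 1 member.")
    }
    tibble::tibble(
      set = parts[1], description = parts[2], gene = parts[-(1:2)]
    )
  })
  purrr::list_rbind(rows)
}

#' Write per-gene selection results to TSV
#'
#' Writes the per-gene table of a [dnds_select()] fit with a commented
#' provenance header recording the package version and configuration;
#' undefined ratios are written as `NA`.
#'
#' @param fit A `dnds_fit` object (or a plain tibble, written as-is).
#' @param path File path.
#' @param timestamp Include a timestamp line (default `FALSE`, keeping
#'   reruns byte-identical).
#' @export
write_results_tsv <- function(fit, path, timestamp = FALSE) {
  header <- character(0)
  tbl <- fit
  if (inherits(fit, "dnds_fit")) {
    cfg <- fit$config
    header <- c(
      sprintf(
        "# sigdnds %s",
        as.character(utils::packageVersion("sigdnds"))
      ),
      sprintf(
        "# mode=%s min_mutations=%s test_metric=%s alternative=%s fdr=%s",
        cfg$mode, cfg$min_mutations, cfg$test_metric, cfg$alternative, cfg$fdr
      )
    )
    tbl <- tidy(fit)
  }
  if (timestamp) {
    header <- c(header, sprintf("# written=%s", format(Sys.time())))
  }
  readr::write_lines(header, path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE, na = "NA")
  invisible(path)
}

#' Map standard MAF columns into the minimal mutation dialect
#'
#' Accepts a table with the conventional MAF columns (`Hugo_Symbol`,
#' `Tumor_Sample_Barcode`, `Start_position`, `Reference_Allele`,
#' `Tumor_Seq_Allele2`, `Variant_Type`), drops non-SNP rows, and converts
#' genomic positions to CDS positions through a user-supplied coordinate
#' adapter, since this package works in transcript coordinates and carries
#' no genome build.
#'
#' @param maf Data frame with MAF columns (`Start_Position` accepted as a
#'   spelling of `Start_position`).
#' @param adapter Function `(gene_id, genomic_position) -> cds_position`
#'   returning the 1-based CDS position (NA to drop a record). Required.
#' @return A raw mutation tibble.
#' @export
maf_to_mutations <- function(maf, adapter) {
  if (missing(adapter) || !is.function(adapter)) {
    abort(paste(
      "A coordinate adapter is required to map genomic positions",
      "to CDS positions."
    ))
  }
  nm <- names(maf)
  if ("Start_Position" %in% nm && !"Start_position" %in% nm) {
    names(maf)[nm == "Start_Position"] <- "Start_position"
  }
  required <- c(
    "Hugo_Symbol", "Tumor_Sample_Barcode", "Start_position",
    "Reference_Allele", "Tumor_Seq_Allele2", "Variant_Type"
  )
  if (!all(required %in% names(maf))) {
    abort(sprintf(
      "MAF input must have columns %s.", paste(required, collapse = ", ")
    ))
  }
  maf <- tibble::as_tibble(maf)
  n_dropped <- sum(maf$Variant_Type != "SNP")
  if (n_dropped > 0) {
    inform(sprintf("Dropped %d non-SNP MAF row(s).", n_dropped))
  }
  maf <- maf[maf$Variant_Type == "SNP", , drop = FALSE]
  out <- tibble::tibble(
    sample_id = maf$Tumor_Sample_Barcode,
    gene_id = maf$Hugo_Symbol,
    cds_position = as.integer(adapter(maf$Hugo_Symbol, maf$Start_position)),
    ref = maf$Reference_Allele,
    alt = maf$Tumor_Seq_Allele2
  )
  out[!is.na(out$cds_position), , drop = FALSE]
}
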