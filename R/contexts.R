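#' Canonical substitution classes
#'
#' The 6 main substitution classes (C>A, C>G, C>T, T>A, T>C, T>G, always
#' referenced by the pyrimidine of the mutated base pair) or their 96
#' trinucleotide refinements obtained by adding the immediate 5' and 3'
#' bases, labelled `"A[C>A]A"` ... `"T[T>G]T"`. The order is fixed
#' lexicographically — substitution class first, then upstream base, then
#' downstream base — so that profile vectors are reproducible across runs.
#'
#' @param mode `"6"` or `"96"` (numbers accepted).
#' @return Character vector of class labels, length 6 or 96.
#' @examples
#' substitution_classes("6")
#' head(substitution_classes("96"))
#' @export
substitution_classes <- function(mode = "96") {
  mode <- as.character(mode)
  six <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  if (mode == "6") {
    return(six)
  }
  if (mode != "96") {
    abort("`mode` must be \"6\" or \"96\".")
  }
  unlist(lapply(six, function(cl) {
    as.vector(t(outer(.BASES, .BASES, function(u, d) {
      paste0(u, "[", cl, "]", d)
    })))
  }))
}

#' Classify a substitution into its pyrimidine-normalized class
#'
#' When the reference allele is a purine, the substitution is converted to
#' its complementary-base representation: reference and alternate alleles
#' are complemented and, because the strand flip reverses 5' and 3', the
#' upstream and downstream context bases are complemented *and* swapped.
#' Context bases are taken from the same strand as the reported alleles.
#'
#' @param ref,alt Reference and alternate alleles (single bases, `ref !=
#'   alt`). Vectorized.
#' @param upstream,downstream Immediate 5' and 3' bases on the reported
#'   strand. Pass `NULL` (default) to obtain 6-class labels; `"N"` marks
#'   unavailable context and yields `NA`.
#'
#' @return Character vector of class labels (`"T[C>T]C"` style for 96-class,
#'   `"C>T"` style when context is omitted), `NA` where context is
#'   unavailable.
#' @examples
#' classify_substitution("C", "T", "T", "C") # "T[C>T]C"
#' classify_substitution("G", "A", "G", "A") # same class, other strand
#' classify_substitution("G", "A") # "C>T"
#' @export
classify_substitution <- function(ref, alt, upstream = NULL, downstream = NULL) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  .stop_if_not_bases(ref, "`ref`")
  .stop_if_not_bases(alt, "`alt`")
  if (any(ref == alt)) {
    abort("`ref` and `alt` must differ.")
  }
  if (is.null(upstream) || is.null(downstream)) {
    if (!is.null(upstream) || !is.null(downstream)) {
      abort("Supply both `upstream` and `downstream`, or neither.")
    }
    flip <- !ref %in% .PYRIMIDINES
    ref[flip] <- .COMPLEMENT[ref[flip]]
    alt[flip] <- .COMPLEMENT[alt[flip]]
    return(paste0(ref, ">", alt))
  }
  upstream <- toupper(as.character(upstream))
  downstream <- toupper(as.character(downstream))
  n <- max(length(ref), length(alt), length(upstream), length(downstream))
  ref <- rep_len(ref, n)
  alt <- rep_len(alt, n)
  upstream <- rep_len(upstream, n)
  downstream <- rep_len(downstream, n)
  ok <- upstream %in% .BASES & downstream %in% .BASES
  bad <- !ok & !(upstream %in% c(.BASES, "N") & downstream %in% c(.BASES, "N"))
  if (any(bad)) {
    abort("Context bases must be A, C, G, T or N (unavailable).")
  }
  out <- rep(NA_character_, n)
  key <- paste0(ref[ok], alt[ok], upstream[ok], downstream[ok])
  out[ok] <- unname(.class_lookup()[key])
  out
}

#' Project a 96-class label onto its 6-class parent
#'
#' @param class Character vector of class labels; 6-class labels pass
#'   through unchanged.
#' @return Character vector of 6-class labels.
#' @examples
#' six_class_of(c("T[C>T]C", "A[T>G]A", "C>A"))
#' @export
six_class_of <- function(class) {
  out <- ifelse(grepl("\\[", class),
    sub("^.\\[(.>.)\\].$", "\\1", class),
    class
  )
  bad <- !out %in% substitution_classes("6")
  if (any(bad)) {
    abort(sprintf(
      "Invalid substitution class label: %s.",
      paste(unique(class[bad]), collapse = ", ")
    ))
  }
  out
}
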