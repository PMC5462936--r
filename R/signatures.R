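#' Build a signature tibble from a named probability vector
#'
#' A mutational signature is a probability distribution over the 6 or 96
#' substitution classes, stored as a tibble with columns `class` and
#' `probability` in canonical class order.
#'
#' @param probabilities Named numeric vector (names are class labels) or
#'   unnamed vector of length 6 or 96 in canonical order. Values must be
#'   non-negative; they are renormalized to sum to 1 (with a warning if the
#'   input sum deviates from 1 by more than `1e-6`).
#' @param source Optional free-text provenance string, stored as an
#'   attribute.
#' @return A signature tibble.
#' @examples
#' as_signature(c("C>T" = 0.9, "T>C" = 0.1))
#' @export
as_signature <- function(probabilities, source = NULL) {
  if (is.data.frame(probabilities)) {
    df <- probabilities
    if (!all(c("class", "probability") %in% names(df))) {
      abort("A signature data frame needs `class` and `probability` columns.")
    }
    probabilities <- setNames(df$probability, df$class)
  }
  p <- as.numeric(probabilities)
  labels <- names(probabilities)
  if (is.null(labels)) {
    if (!length(p) %in% c(6L, 96L)) {
      abort("Unnamed probabilities must have length 6 or 96.")
    }
    labels <- substitution_classes(if (length(p) == 6L) "6" else "96")
  }
  mode <- if (any(grepl("\\[", labels))) "96" else "6"
  classes <- substitution_classes(mode)
  if (any(!labels %in% classes)) {
    abort(sprintf(
      "Unknown class label(s): %s.",
      paste(setdiff(labels, classes), collapse = ", ")
    ))
  }
  if (anyDuplicated(labels)) {
    abort("Duplicated class labels in signature.")
  }
  if (any(is.na(p)) || any(p < 0)) {
    abort("Signature probabilities must be non-negative and non-missing.")
  }
  full <- setNames(numeric(length(classes)), classes)
  full[labels] <- p
  total <- sum(full)
  if (total <= 0) {
    abort("Signature probabilities must have positive total mass.")
  }
  if (abs(total - 1) > 1e-6) {
    warn(sprintf("Signature probabilities sum to %.6g; renormalizing.", total))
  }
  out <- tibble::tibble(class = classes, probability = unname(full) / total)
  attr(out, "signature_mode") <- mode
  if (!is.null(source)) attr(out, "source") <- source
  out
}

#' Signature mode (6 or 96 classes)
#'
#' @param signature A signature tibble.
#' @return `"6"` or `"96"`.
#' @export
signature_mode <- function(signature) {
  if (nrow(signature) == 96L) "96" else "6"
}

#' Uniform signature
#'
#' All classes equally probable; under this profile the corrected dN/dS
#' reduces exactly to the basic dN/dS.
#'
#' @param mode `"6"` or `"96"`.
#' @return A signature tibble.
#' @export
uniform_signature <- function(mode = "96") {
  classes <- substitution_classes(mode)
  as_signature(setNames(rep(1 / length(classes), length(classes)), classes),
    source = "uniform"
  )
}

#' Expand a 6-class signature to 96 classes
#'
#' Each class mass is spread uniformly over its 16 trinucleotide contexts,
#' so all downstream computation can run in 96-class space. A 96-class
#' input passes through unchanged.
#'
#' @param signature A signature tibble.
#' @return A 96-class signature tibble.
#' @export
expand_signature <- function(signature) {
  signature <- as_signature(signature)
  if (signature_mode(signature) == "96") {
    return(signature)
  }
  p6 <- setNames(signature$probability, signature$class)
  cls96 <- substitution_classes("96")
  as_signature(setNames(p6[six_class_of(cls96)] / 16, cls96),
    source = attr(signature, "source")
  )
}

#' Marginalize a 96-class signature to the 6 main classes
#'
#' @param signature A signature tibble.
#' @return A 6-class signature tibble.
#' @export
marginalize_signature <- function(signature) {
  signature <- as_signature(signature)
  if (signature_mode(signature) == "6") {
    return(signature)
  }
  signature |>
    dplyr::mutate(class = six_class_of(.data$class)) |>
    dplyr::summarise(probability = sum(.data$probability), .by = "class") |>
    as_signature(source = attr(signature, "source"))
}

#' Estimate a mutational signature from an annotated mutation catalog
#'
#' The maximum-likelihood estimate: the observed proportion of mutations in
#' each substitution class. Classes not observed get probability 0.
#'
#' @param mutations Annotated mutation tibble (see [annotate_mutations()])
#'   with a `class` column of 96-class labels.
#' @param mode `"6"` or `"96"`.
#' @return A signature tibble.
#' @export
estimate_signature <- function(mutations, mode = "96") {
  mode <- as.character(mode)
  if (!"class" %in% names(mutations)) {
    abort("`mutations` must carry a `class` column; run annotate_mutations().")
  }
  cls <- mutations$class[!is.na(mutations$class)]
  if (length(cls) == 0L) {
    abort("Cannot estimate a signature from an empty mutation catalog.")
  }
  if (mode == "6") cls <- six_class_of(cls)
  tab <- table(factor(cls, levels = substitution_classes(mode)))
  as_signature(setNames(as.numeric(tab) / length(cls), names(tab)),
    source = sprintf("estimated from %d mutations", length(cls))
  )
}

#' Stylized melanoma-like mutational signature
#'
#' A UV-exposure-like profile built from the reported class proportions of
#' cutaneous melanoma exomes: the 6-class version places 87.6% of the mass
#' on C>T (2.5% C>A, 1.5% C>G, 2.3% T>A, 4.1% T>C, 2.0% T>G). The 96-class
#' version additionally concentrates the C>T mass at dipyrimidine contexts:
#' 53.1% of all mutations at T[C>T]N contexts, of which 23.3% at T[C>T]C,
#' with the remaining mass of each class spread uniformly over its other
#' contexts. This is a stylized reconstruction from published marginal
#' proportions, intended for simulation, not a fitted signature.
#'
#' @param mode `"6"` or `"96"`.
#' @return A signature tibble.
#' @examples
#' marginalize_signature(melanoma_like_signature("96"))
#' @export
melanoma_like_signature <- function(mode = "96") {
  mode <- as.character(mode)
  p6 <- c(
    "C>A" = 0.025, "C>G" = 0.015, "C>T" = 0.876,
    "T>A" = 0.023, "T>C" = 0.041, "T>G" = 0.020
  )
  if (mode == "6") {
    return(as_signature(p6, source = "melanoma-like (6-class)"))
  }
  if (mode != "96") {
    abort("`mode` must be \"6\" or \"96\".")
  }
  cls96 <- substitution_classes("96")
  p <- setNames(p6[six_class_of(cls96)] / 16, cls96)
  # concentrate C>T at T[C>T]N (53.1% of all mutations; 23.3% at T[C>T]C)
  tcn <- paste0("T[C>T]", .BASES)
  p[tcn] <- (0.531 - 0.233) / 3
  p["T[C>T]C"] <- 0.233
  other_ct <- setdiff(grep("\\[C>T\\]", cls96, value = TRUE), tcn)
  p[other_ct] <- (p6[["C>T"]] - 0.531) / length(other_ct)
  as_signature(p, source = "melanoma-like (96-class)")
}
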