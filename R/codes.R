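#' Translate a codon under the standard genetic code
#'
#' @param codon Character vector of codons (3 bases over A/C/G/T, case
#'   insensitive).
#'
#' @return Character vector of 1-letter amino-acid symbols; `"*"` denotes a
#'   stop codon.
#' @examples
#' translate_codon(c("ATG", "TAA", "TTT"))
#' @export
translate_codon <- function(codon) {
  codon <- toupper(as.character(codon))
  if (any(nchar(codon) != 3L)) {
    abort("Every codon must be exactly 3 bases long.")
  }
  bad <- grepl("[^ACGT]", codon)
  if (any(bad)) {
    abort(sprintf(
      "Invalid codon sequence: %s.",
      paste(unique(codon[bad]), collapse = ", ")
    ))
  }
  unname(.genetic_code()[codon])
}

#' Consequence of a single-base codon change
#'
#' Compares the amino acid encoded before and after substituting one base of
#' a codon. A change that leaves the product unchanged (including
#' stop-to-stop) is `synonymous`; a change creating a stop is `stopgain`,
#' removing one is `stoploss`, and any other amino-acid change is
#' `missense`. In all dN/dS tallies the three non-synonymous categories are
#' pooled (see [consequence_impact()]).
#'
#' @param codon Character vector of reference codons.
#' @param position Integer vector, position of the substituted base within
#'   the codon (1, 2 or 3).
#' @param alt Character vector of alternate bases; must differ from the
#'   reference base at `position`.
#'
#' @return Character vector with values `"synonymous"`, `"missense"`,
#'   `"stopgain"` or `"stoploss"`.
#' @examples
#' codon_consequence("TTT", 3, "C") # synonymous (Phe -> Phe)
#' codon_consequence("ATG", 2, "C") # missense   (Met -> Thr)
#' codon_consequence("TAC", 3, "A") # stopgain   (Tyr -> stop)
#' @export
codon_consequence <- function(codon, position, alt) {
  codon <- toupper(as.character(codon))
  alt <- toupper(as.character(alt))
  position <- as.integer(position)
  n <- max(length(codon), length(position), length(alt))
  codon <- rep_len(codon, n)
  position <- rep_len(position, n)
  alt <- rep_len(alt, n)
  if (any(nchar(codon) != 3L) || any(grepl("[^ACGT]", codon))) {
    abort("Invalid codon sequence.")
  }
  if (any(!position %in% 1:3)) {
    abort("`position` must be 1, 2 or 3.")
  }
  .stop_if_not_bases(alt, "`alt`")
  ref <- substr(codon, position, position)
  if (any(ref == alt)) {
    abort("`alt` must differ from the reference base at `position`.")
  }
  unname(.conseq_lookup()[paste0(codon, position, alt)])
}

#' Collapse a consequence to the binary synonymous / non-synonymous split
#'
#' @param consequence Character vector of consequence categories as returned
#'   by [codon_consequence()].
#' @return Character vector with values `"synonymous"` or `"nonsynonymous"`.
#' @export
consequence_impact <- function(consequence) {
  valid <- c("synonymous", "missense", "stopgain", "stoploss")
  if (any(!consequence %in% valid)) {
    abort("Unknown consequence category.")
  }
  ifelse(consequence == "synonymous", "synonymous", "nonsynonymous")
}

#' Is an amino acid hydrophobic?
#'
#' Uses the 9-residue hydrophobic set relevant for transmembrane protein
#' composition: Ala, Gly, Ile, Leu, Phe, Val, Pro, Met and Trp. The stop
#' symbol is not a residue and returns `FALSE`.
#'
#' @param aa Character vector of amino acids, 1-letter (`"L"`) or 3-letter
#'   (`"Leu"`, case insensitive) symbols; `"*"` or `"Ter"` for stop.
#' @return Logical vector.
#' @examples
#' is_hydrophobic(c("Leu", "Lys", "W", "*"))
#' @export
is_hydrophobic <- function(aa) {
  aa <- as.character(aa)
  one <- toupper(aa)
  three <- nchar(aa) == 3L
  if (any(three)) {
    key <- paste0(
      toupper(substr(aa[three], 1, 1)),
      tolower(substr(aa[three], 2, 3))
    )
    mapped <- .AA_THREE_TO_ONE[key]
    if (any(is.na(mapped))) {
      abort(sprintf(
        "Unknown amino-acid symbol: %s.",
        paste(unique(aa[three][is.na(mapped)]), collapse = ", ")
      ))
    }
    one[three] <- unname(mapped)
  }
  known <- c(unname(.AA_THREE_TO_ONE), "*")
  if (any(!one %in% known)) {
    abort(sprintf(
      "Unknown amino-acid symbol: %s.",
      paste(unique(aa[!one %in% known]), collapse = ", ")
    ))
  }
  one %in% .HYDROPHOBIC_AA
}

#' Hydrophobic amino-acid census of NTN versus other codons
#'
#' Enumerates all 64 codons of the standard genetic code, splits them into
#' NTN codons (thymine at the second position) and all others, and counts
#' how many in each group encode a hydrophobic amino acid (stop codons count
#' as non-hydrophobic). All 16 NTN codons encode Phe, Leu, Ile, Met or Val
#' and are therefore hydrophobic, against 13 of the 48 remaining codons —
#' the combinatorial driver of the low simulated dN/dS of membrane-protein
#' genes under C>T-dominated mutagenesis.
#'
#' @return A one-row tibble with columns `ntn_hydrophobic`, `ntn_total`,
#'   `other_hydrophobic`, `other_total`.
#' @examples
#' hydrophobic_codon_census()
#' @export
hydrophobic_codon_census <- function() {
  gc <- .genetic_code()
  ntn <- substr(names(gc), 2, 2) == "T"
  hyd <- gc %in% .HYDROPHOBIC_AA # stops ("*") fall out automatically
  tibble::tibble(
    ntn_hydrophobic = sum(ntn & hyd),
    ntn_total = sum(ntn),
    other_hydrophobic = sum(!ntn & hyd),
    other_total = sum(!ntn)
  )
}

#' Fraction of hydrophobic residues in a protein sequence
#'
#' @param protein Character scalar (1-letter amino-acid string, stop symbols
#'   allowed and counted as non-hydrophobic residues are excluded from the
#'   denominator) or character vector of 1-letter symbols.
#' @return Numeric scalar in `[0, 1]`.
#' @examples
#' hydrophobic_fraction("KLLK")
#' @export
hydrophobic_fraction <- function(protein) {
  if (length(protein) == 1L && nchar(protein[1]) != 1L) {
    protein <- strsplit(protein, "")[[1]]
  }
  protein <- protein[protein != "*"]
  if (length(protein) == 0L) {
    abort("`protein` must contain at least one amino-acid residue.")
  }
  mean(is_hydrophobic(protein))
}

#' Distribution of synonymous codon changes over the 6 substitution classes
#'
#' Enumerates all 576 possible single-base codon changes (64 codons times 9
#' substitutions), keeps the synonymous ones, and tabulates them by
#' pyrimidine-normalized substitution class. The redundancy of the genetic
#' code concentrates synonymous opportunity in the C>T and T>C classes,
#' which is why a C>T-dominated mutational signature depresses the basic
#' dN/dS ratio.
#'
#' @return A 6-row tibble with columns `class`, `count` and `proportion`
#'   (proportions sum to 1).
#' @examples
#' synonymous_class_distribution()
#' @export
synonymous_class_distribution <- function() {
  lookup <- .conseq_lookup()
  syn <- names(lookup)[lookup == "synonymous"]
  pos <- as.integer(substr(syn, 4, 4))
  ref <- substr(syn, pos, pos)
  alt <- substr(syn, 5, 5)
  flip <- !ref %in% .PYRIMIDINES
  ref[flip] <- .COMPLEMENT[ref[flip]]
  alt[flip] <- .COMPLEMENT[alt[flip]]
  cls <- factor(paste0(ref, ">", alt), levels = substitution_classes("6"))
  tab <- table(cls)
  tibble::tibble(
    class = names(tab),
    count = as.integer(tab),
    proportion = as.integer(tab) / sum(tab)
  )
}
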