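#' Bar plot of a mutational signature
#'
#' 6-class profiles are drawn as a single bar chart; 96-class profiles are
#' faceted by substitution class with trinucleotide contexts on the x axis,
#' in the style usual for signature plots.
#'
#' @param signature Signature tibble.
#' @return A ggplot object.
#' @export
plot_signature <- function(signature) {
  signature <- as_signature(signature)
  if (signature_mode(signature) == "6") {
    return(
      ggplot2::ggplot(
        signature,
        ggplot2::aes(.data$class, .data$probability, fill = .data$class)
      ) +
        ggplot2::geom_col(show.legend = FALSE) +
        ggplot2::labs(x = "substitution class", y = "probability") +
        ggplot2::theme_minimal()
    )
  }
  df <- signature |>
    dplyr::mutate(
      six = six_class_of(.data$class),
      context = sub("\\[.>.\\]", ".", .data$class)
    )
  ggplot2::ggplot(
    df, ggplot2::aes(.data$context, .data$probability, fill = .data$six)
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_grid(. ~ six, scales = "free_x") +
    ggplot2::labs(x = "trinucleotide context", y = "probability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 5)
    )
}

#' Line plot of a substitution-class probability sweep
#'
#' @param sweep Output of [signature_sweep()].
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  ggplot2::ggplot(
    sweep,
    ggplot2::aes(.data$probability, .data$dnds_simulated,
      colour = .data$sweep_class
    )
  ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "class probability", y = "median simulated dN/dS",
      colour = "class"
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of basic versus corrected dN/dS across genes
#'
#' @param object A `dnds_fit` object.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.dnds_fit <- function(object, bins = 40, ...) {
  df <- tidy(object) |>
    dplyr::select("gene_id", "dnds_basic", "dnds_corrected") |>
    tidyr::pivot_longer(
      c("dnds_basic", "dnds_corrected"),
      names_to = "metric", values_to = "dnds", names_prefix = "dnds_"
    ) |>
    dplyr::filter(!is.na(.data$dnds))
  ggplot2::ggplot(df, ggplot2::aes(.data$dnds, fill = .data$metric)) +
    ggplot2::geom_histogram(
      bins = bins, alpha = 0.6, position = "identity"
    ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "dN/dS", y = "genes") +
    ggplot2::theme_minimal()
}
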