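#' Bar chart of class-code counts
#'
#' @param class_summary Tibble from [summarize_classes()].
#' @return A ggplot object.
#' @export
plot_class_summary <- function(class_summary) {
  ggplot2::ggplot(class_summary,
                  ggplot2::aes(x = factor(.data$class_code,
                                          levels = CLASS_CODES),
                               y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "class code", y = "transcripts") +
    ggplot2::theme_minimal()
}

#' Histogram of Jensen-Shannon specificity scores
#'
#' @param scores Tibble from [specificity_scores()].
#' @param binwidth Histogram bin width.
#' @return A ggplot object.
#' @export
plot_specificity <- function(scores, binwidth = 0.05) {
  ggplot2::ggplot(filter(scores, .data$scorable),
                  ggplot2::aes(x = .data$js_score)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "darkorange", color = "white") +
    ggplot2::labs(x = "maximal JS specificity score", y = "transcripts") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-chromosome lincRNA counts
#'
#' @param chrom_counts Tibble from [chromosome_counts()].
#' @return A ggplot object.
#' @export
plot_chromosome_counts <- function(chrom_counts) {
  ggplot2::ggplot(chrom_counts,
                  ggplot2::aes(x = stats::reorder(.data$chrom, -.data$n),
                               y = .data$n)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::labs(x = "chromosome", y = "lincRNAs") +
    ggplot2::theme_minimal()
}

#' Dot plot of enriched GO terms
#'
#' @param enrichment Tibble from [go_enrichment()].
#' @param top Number of terms to show per category.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, top = 10L) {
  shown <- enrichment |>
    group_by(.data$category) |>
    slice(seq_len(min(top, n()))) |>
    ungroup() |>
    mutate(label = if_else(is.na(.data$name), .data$term_id, .data$name))
  ggplot2::ggplot(shown,
                  ggplot2::aes(x = -log10(.data$adjusted_p),
                               y = stats::reorder(.data$label,
                                                  -.data$adjusted_p),
                               size = .data$k)) +
    ggplot2::geom_point(color = "firebrick") +
    ggplot2::facet_wrap(~category, scales = "free_y") +
    ggplot2::labs(x = "-log10 adjusted p", y = NULL, size = "genes") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Coefficient plot of a fitted coding-potential model
#'
#' @param object A `coding_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coding_model
#' @export
autoplot.coding_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "logistic coefficient", y = NULL) +
    ggplot2::theme_minimal()
}
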