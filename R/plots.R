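#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_text
#'   geom_vline labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Information-content logo of a motif model
#'
#' Letters stacked per position, each scaled by its share of that
#' position's information content (bits).
#'
#' @param object A `motif_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.motif_model <- function(object, ...) {
  df <- tidy(object) %>%
    dplyr::group_by(.data$position) %>%
    dplyr::arrange(.data$prob, .by_group = TRUE) %>%
    dplyr::mutate(
      height = .data$prob * .data$ic,
      ymax = cumsum(.data$height),
      ymin = .data$ymax - .data$height,
      ymid = (.data$ymin + .data$ymax) / 2
    ) %>%
    dplyr::ungroup()
  ggplot(df, aes(x = .data$position)) +
    geom_text(aes(y = .data$ymid, label = .data$base, size = .data$height,
                  colour = .data$base),
              fontface = "bold", show.legend = FALSE) +
    ggplot2::scale_size_continuous(range = c(1, 10)) +
    ggplot2::scale_x_continuous(breaks = seq_len(object$width)) +
    labs(x = "Motif position", y = "Information content (bits)",
         title = paste("Consensus:", object$consensus)) +
    theme_minimal()
}

#' Histogram of 5'UTR lengths
#'
#' @param object A `utr_stats`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.utr_stats <- function(object, ...) {
  ggplot(object$histogram, aes(x = .data$bin_start + 5, y = .data$n)) +
    geom_col(width = 9, fill = "steelblue") +
    geom_vline(xintercept = object$median, linetype = "dashed") +
    labs(x = "5'UTR length (nt, 10-nt bins)", y = "Primary TSS count",
         title = sprintf("Median %.0f nt; %.1f%% shorter than 100 nt",
                         object$median, 100 * object$fraction_lt_100)) +
    theme_minimal()
}

#' Cumulative GC-skew curve with origin/terminus markers
#'
#' @param object A `skew_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.skew_profile <- function(object, ...) {
  ot <- locate_origin_terminus(object)
  ggplot(as_tibble(object), aes(x = .data$midpoint, y = .data$cumulative)) +
    geom_line() +
    geom_vline(xintercept = c(ot$origin, ot$terminus),
               linetype = "dashed", colour = c("firebrick", "steelblue")) +
    labs(x = "Genome position (bp)", y = "Cumulative GC skew",
         title = sprintf("Origin %d (min), terminus %d (max)",
                         ot$origin, ot$terminus)) +
    theme_minimal()
}

#' Stacked per-genome category counts of a pan-genome
#'
#' @param object A `pan_genome`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pan_genome <- function(object, ...) {
  ggplot(object$per_genome_counts,
         aes(x = .data$genome, y = .data$n_proteins, fill = .data$category)) +
    geom_col() +
    labs(x = NULL, y = "Genes", fill = "Category") +
    theme_minimal()
}

#' Bar chart of TSS class counts
#'
#' @param summary Output of [summarize_classes()].
#' @return A ggplot.
#' @export
plot_class_counts <- function(summary) {
  ggplot(summary, aes(x = factor(.data$class, c("P", "S", "I", "A", "N")),
                      y = .data$n)) +
    geom_col(fill = "grey30") +
    labs(x = "TSS class", y = "Count") +
    theme_minimal()
}
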