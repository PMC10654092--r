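# ggplot2 views of the main result types.

#' Plot a conservation profile
#'
#' Per-column conservation with the smoothed trace and inferred WXG / linker
#' / TOX segments shaded.
#'
#' @param object A [conservation_profile()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot conservation_profile
#' @export
autoplot.conservation_profile <- function(object, ...) {
  df <- object$profile
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$conservation, fill = .data$segment),
                      width = 1, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), linewidth = 0.6) +
    ggplot2::labs(x = "Alignment column", y = "Conservation",
                  fill = "Segment") +
    ggplot2::theme_minimal()
}

#' Plot phage-like regions along contigs
#'
#' One horizontal segment per region, colored by its first class, faceted by
#' genome.
#'
#' @param regions Region tibble from [run_pipeline()] or
#'   [classify_regions()].
#' @return A ggplot object.
#' @export
plot_regions <- function(regions) {
  df <- regions %>%
    mutate(class = vapply(.data$classes, function(x) {
      if (length(x)) x[1] else "unclassified"
    }, character(1)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, xend = .data$end,
                                   y = .data$contig_id, yend = .data$contig_id,
                                   color = .data$class)) +
    ggplot2::geom_segment(linewidth = 3) +
    ggplot2::labs(x = "Position (bp)", y = NULL, color = "Class") +
    ggplot2::theme_minimal() +
    (if ("genome_id" %in% names(df))
      ggplot2::facet_wrap(~genome_id, scales = "free_y") else NULL)
}

#' Plot prophage counts per genome
#'
#' @param report A `prophage_report`.
#' @return A ggplot object.
#' @export
plot_prophage_counts <- function(report) {
  df <- count(report$kept, .data$genome_id, name = "n")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$genome_id, -.data$n),
                                   y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Kept prophages") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
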