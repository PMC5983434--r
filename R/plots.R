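#' Plot cohort composition
#'
#' Bar chart of the share of samples per breed.
#'
#' @param composition Output of [cohort_composition()].
#' @return A ggplot object.
#' @export
plot_cohort_composition <- function(composition) {
  ggplot2::ggplot(
    composition,
    ggplot2::aes(
      x = stats::reorder(.data$breed, -.data$percent),
      y = .data$percent
    )
  ) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f%%", .data$percent)),
      vjust = -0.4, size = 3
    ) +
    ggplot2::labs(x = NULL, y = "% of cohort", title = "Cohort composition") +
    ggplot2::theme_minimal()
}

#' Plot the filtration summary
#'
#' @param filtration Output of [filtration_summary()].
#' @return A ggplot object.
#' @export
plot_filtration_summary <- function(filtration) {
  ggplot2::ggplot(
    filtration,
    ggplot2::aes(x = .data$breed, y = .data$percent)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL, y = "% of SNPs retained",
      title = "SNPs surviving the within-breed filtration"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the largest Venn cells
#'
#' The full partition of 2^B - 1 cells is unreadable as a graphic for seven
#' breeds; this shows the `n_top` most populated cells as a bar chart.
#'
#' @param venn A `venn_table` from [venn_partition()].
#' @param n_top Number of cells to show.
#' @return A ggplot object.
#' @export
plot_venn_counts <- function(venn, n_top = 20) {
  top <- venn %>%
    arrange(dplyr::desc(.data$count)) %>%
    head(n_top) %>%
    filter(.data$count > 0)
  ggplot2::ggplot(
    top,
    ggplot2::aes(
      x = stats::reorder(.data$breed_set, .data$count),
      y = .data$count
    )
  ) +
    ggplot2::geom_col(fill = "darkorange3") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = "breed subset", y = "variants exclusive to subset",
      title = "Venn partition of fixed-SNP sets"
    ) +
    ggplot2::theme_minimal()
}

#' Plot consequence category percentages per breed
#'
#' @param summary Output of [consequence_summary()].
#' @return A ggplot object.
#' @export
plot_consequence_summary <- function(summary) {
  coding <- summary %>% filter(!is.na(.data$pct_coding))
  ggplot2::ggplot(
    coding,
    ggplot2::aes(x = .data$breed, y = .data$pct_coding, fill = .data$term)
  ) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(
      x = NULL, y = "% of coding-region calls", fill = "consequence",
      title = "Coding consequences of breed-specific SNPs"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_venn_counts
#' @param object A `venn_table`.
#' @param ... Passed to [plot_venn_counts()].
#' @method autoplot venn_table
#' @export
autoplot.venn_table <- function(object, ...) {
  plot_venn_counts(object, ...)
}

#' @rdname run_pipeline
#' @param object A `breed_pipeline`.
#' @method autoplot breed_pipeline
#' @export
autoplot.breed_pipeline <- function(object, ...) {
  plot_venn_counts(object$venn)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
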