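# ggplot2 views of cohort summaries: deposition trend, completeness trend,
# and partition bars.

#' Plot per-year deposition split by origin group
#'
#' Stacked bars of field-collected versus "other" (laboratory, commercial,
#' managed-colony and unknown origins combined) assemblies per submission
#' year.
#'
#' @param summary A `cohort_summary`.
#' @return A ggplot object.
#' @export
plot_year_trend <- function(summary) {
  d <- summary$per_year |>
    tidyr::pivot_longer(c("field", "other"), names_to = "origin_group", values_to = "count")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$year, y = .data$count, fill = .data$origin_group)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "Submission year", y = "Assemblies deposited", fill = "Origin",
      title = paste0("Genome assembly deposition (", summary$cohort_label, " cohort)")
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-year spatiotemporal completeness
#'
#' @param summary A `cohort_summary`.
#' @return A ggplot object.
#' @export
plot_completeness_trend <- function(summary) {
  d <- summary$per_year |>
    mutate(incomplete = .data$n - .data$complete) |>
    tidyr::pivot_longer(c("complete", "incomplete"), names_to = "status", values_to = "count")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$year, y = .data$count, fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "Submission year", y = "Assemblies",
      fill = "Spatiotemporal metadata",
      title = "Completeness of spatiotemporal metadata by submission year"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a category partition
#'
#' @param summary A `cohort_summary`.
#' @param partition Partition name (e.g. `"origin"`, `"spatial"`).
#' @return A ggplot object.
#' @export
plot_partition <- function(summary, partition = "origin") {
  d <- summary$partitions |> filter(.data$partition == !!partition)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$pct, "%")), vjust = -0.3, size = 3) +
    ggplot2::labs(x = partition, y = "Assemblies") +
    ggplot2::theme_minimal()
}

#' Autoplot a cohort summary
#'
#' @param object A `cohort_summary`.
#' @param type `"year"`, `"completeness"` or a partition name.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.cohort_summary <- function(object, type = "year", ...) {
  switch(type,
    year = plot_year_trend(object),
    completeness = plot_completeness_trend(object),
    plot_partition(object, type)
  )
}

#' @export
ggplot2::autoplot
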