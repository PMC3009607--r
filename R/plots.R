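#' Plot a critical region and its evidence trail
#'
#' Draws the surviving interval(s) of a critical region along the
#' chromosome, with one track per evidence step showing how the candidate
#' region shrank as deletion tests and recombination exclusions were
#' applied (top = initial search region, bottom = final critical region).
#'
#' @param x A `critical_region` from [map_mutation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_critical_region <- function(x, ...) {
  if (!inherits(x, "critical_region")) rlang::abort("`x` must be a critical_region.")
  steps <- dplyr::bind_rows(
    tibble::tibble(label = "initial", order = 0L, region = list(x$initial)),
    tibble::tibble(label = paste0(x$evidence$step, ": ", x$evidence$source),
                   order = x$evidence$step, region = x$evidence$region)
  )
  d <- tidyr::unnest(
    dplyr::mutate(steps, region = purrr::map(.data$region, interval_to_1based)),
    "region"
  )
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start_1based / 1e6, xend = .data$end_1based / 1e6,
                   y = stats::reorder(.data$label, -.data$order),
                   yend = stats::reorder(.data$label, -.data$order)),
      linewidth = 3, colour = "steelblue"
    ) +
    ggplot2::labs(
      x = "Position (Mb)", y = NULL,
      title = paste0("Critical region: ", x$mutation_id),
      subtitle = sprintf("%d interval(s), %d kb remaining",
                         nrow(x$region), interval_width_kb(x$region))
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_critical_region
#' @param object A `critical_region`.
#' @exportS3Method ggplot2::autoplot
autoplot.critical_region <- function(object, ...) plot_critical_region(object, ...)

#' Plot the pairwise complementation grid
#'
#' Renders [plan_tests()] output as the classic allelism grid: one tile
#' per unordered mutation pair, colored by whether allelism is excluded by
#' disjoint map positions, confirmed or refuted by an actual cross, or
#' still untested.
#'
#' @param classifications Tibble from [plan_tests()].
#' @return A ggplot object.
#' @export
plot_complementation_grid <- function(classifications) {
  need <- c("mutation_a", "mutation_b", "category")
  if (!all(need %in% names(classifications))) {
    rlang::abort("`classifications` must be plan_tests() output.")
  }
  ids <- sort(unique(c(classifications$mutation_a, classifications$mutation_b)))
  d <- dplyr::mutate(
    classifications,
    a = factor(.data$mutation_a, levels = ids),
    b = factor(.data$mutation_b, levels = ids)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$a, y = .data$b, fill = .data$category)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(
      DISJOINT_INFERRED_COMPLEMENT = "#b8e0b8",
      OVERLAP_COMPLEMENT = "#1b7837",
      OVERLAP_FAIL = "#d73027",
      OVERLAP_UNTESTED = "#fee08b"
    )) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pair status",
                  title = "Pairwise allelism triage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
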