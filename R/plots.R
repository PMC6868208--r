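#' Correlation-matrix heat map
#'
#' Basic correlogram of the mixed-method metric correlation matrix, with
#' coefficients printed in each cell.
#'
#' @param object A `shoal_corr` from [metric_correlations()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shoal_corr <- function(object, ...) {
  df <- as.data.frame(as.table(object$r))
  names(df) <- c("metric_a", "metric_b", "r")
  ggplot2::ggplot(df, ggplot2::aes(.data$metric_a, .data$metric_b, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 2.6) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Condition comparison of the tested responses
#'
#' Mean with SD error bars per condition for each continuous metric, and
#' presence proportion per condition for each behaviour, faceted by
#' response — the standard at-a-glance view of the condition differences.
#'
#' @param analysis A `shoal_analysis` from [run_full_analysis()].
#' @param responses Responses to show; defaults to the ones tested.
#' @return A ggplot object.
#' @export
plot_condition_means <- function(analysis, responses = NULL) {
  stopifnot(inherits(analysis, "shoal_analysis"))
  responses <- responses %||% analysis$provenance$responses
  kinds <- stats::setNames(analysis$catalogue$info$data_kind,
                           analysis$catalogue$info$name)
  levels <- condition_levels(analysis$metrics$condition)

  cont <- intersect(responses, names(kinds)[kinds == "continuous"])
  bin <- intersect(responses, names(kinds)[kinds == "binary"])
  pieces <- list()
  if (length(cont) > 0L) {
    pieces$cont <- analysis$metrics |>
      dplyr::select(dplyr::all_of(c("condition", cont))) |>
      tidyr::pivot_longer(-"condition", names_to = "response") |>
      dplyr::group_by(.data$condition, .data$response) |>
      dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                       .groups = "drop")
  }
  if (length(bin) > 0L) {
    pieces$bin <- analysis$behaviour_filter$behaviour |>
      dplyr::filter(.data$behaviour %in% bin) |>
      dplyr::group_by(.data$condition, response = .data$behaviour) |>
      dplyr::summarise(mean = mean(.data$present), sd = sd(.data$present),
                       .groups = "drop")
  }
  df <- dplyr::bind_rows(pieces) |>
    dplyr::mutate(condition = factor(.data$condition, levels = levels))

  ggplot2::ggplot(df, ggplot2::aes(.data$condition, .data$mean)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.15
    ) +
    ggplot2::facet_wrap(~response, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean ± SD") +
    ggplot2::theme_minimal()
}

#' @rdname plot_condition_means
#' @param object A `shoal_analysis`.
#' @param ... Unused.
#' @export
autoplot.shoal_analysis <- function(object, ...) plot_condition_means(object)
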