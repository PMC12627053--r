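#' Plot expression accuracy by emotion and BP group
#'
#' Grouped bar chart of per-cell accuracy percentages (the Table-2-style
#' figure of the analysis).
#'
#' @param accuracy_by_cell Tibble from [group_accuracy()] (or
#'   `run$accuracy$by_cell`).
#' @return A ggplot object.
#' @export
plot_group_accuracy <- function(accuracy_by_cell) {
  ggplot2::ggplot(
    accuracy_by_cell,
    ggplot2::aes(x = .data$emotion, y = .data$accuracy_pct, fill = .data$bp_group)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::labs(x = NULL, y = "Expression accuracy (%)", fill = "BP group") +
    ggplot2::theme_minimal()
}

#' Plot group-mean agreement indices by emotion
#'
#' Dot plot of the five agreement indices per BP group, faceted by emotion;
#' percent agreement is rescaled to \[0, 1\] so all indices share an axis.
#'
#' @param agreement Tibble from [group_mean_panel()] (or `run$agreement`).
#' @return A ggplot object.
#' @export
plot_agreement_indices <- function(agreement) {
  long <- agreement |>
    dplyr::select("bp_group", "emotion", dplyr::ends_with("_mean")) |>
    tidyr::pivot_longer(dplyr::ends_with("_mean"),
                        names_to = "index", values_to = "value") |>
    dplyr::mutate(
      index = sub("_mean$", "", .data$index),
      value = ifelse(.data$index == "percent_agreement",
                     .data$value / 100, .data$value)
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$index, y = .data$value,
                                     colour = .data$bp_group)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5), na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$emotion)) +
    ggplot2::labs(x = NULL, y = "Agreement (percent agreement / 100)",
                  colour = "BP group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot human vs machine expression intensity by group
#'
#' Mean of active prototype AUs for both raters across BP groups, faceted by
#' emotion (the Figure-2-style view of intensity dampening).
#'
#' @param intensity_summary Tibble `run$intensity$summary`.
#' @return A ggplot object.
#' @export
plot_intensity_profile <- function(intensity_summary) {
  long <- intensity_summary |>
    dplyr::select("bp_group", "emotion",
                  human = "human_mean_active_mean",
                  machine = "machine_mean_active_mean") |>
    tidyr::pivot_longer(c("human", "machine"),
                        names_to = "rater", values_to = "mean_active")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bp_group, y = .data$mean_active,
                                     group = .data$rater, colour = .data$rater)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$emotion)) +
    ggplot2::labs(x = NULL, y = "Mean intensity of active prototype AUs",
                  colour = "Rater") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot

#' Adjusted-means plot for a fitted ANCOVA
#'
#' @param object A `facedamp_ancova` fit.
#' @param ... Unused.
#' @return A ggplot object showing covariate-adjusted group means with
#'   approximate 95% intervals.
#' @export
autoplot.facedamp_ancova <- function(object, ...) {
  adj <- object$adjusted_means
  ggplot2::ggplot(adj, ggplot2::aes(x = .data$group, y = .data$adjusted_mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$adjusted_mean - 1.96 * .data$se,
                   ymax = .data$adjusted_mean + 1.96 * .data$se),
      width = 0.15
    ) +
    ggplot2::labs(x = NULL, y = paste("Adjusted mean of", object$outcome)) +
    ggplot2::theme_minimal()
}
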