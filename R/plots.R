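# ggplot2 views of the main result types.

#' Plot an acceptance heatmap
#'
#' Mean effort acceptance over the 4x4 offer grid per group, with an
#' optional stress-minus-control difference panel.
#'
#' @param trials Trial table with `group`.
#' @param include_diff Add the `MAST_EXP - MAST_PLC` panel (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_acceptance_heatmap <- function(trials, include_diff = TRUE) {
  per_group <- acceptance_heatmap(trials, by = "subject") |>
    dplyr::summarise(acceptance = mean(.data$acceptance),
                     .by = c("group", "effort_level", "incentive_level"))
  if (include_diff && all(study_groups() %in% per_group$group)) {
    diff <- per_group |>
      tidyr::pivot_wider(names_from = "group", values_from = "acceptance") |>
      dplyr::mutate(group = "MAST_EXP - MAST_PLC",
                    acceptance = .data$MAST_EXP - .data$MAST_PLC) |>
      dplyr::select("group", "effort_level", "incentive_level", "acceptance")
    per_group <- dplyr::bind_rows(per_group, diff)
  }
  ggplot2::ggplot(per_group,
                  ggplot2::aes(x = .data$effort_level,
                               y = .data$incentive_level,
                               fill = .data$acceptance)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Effort level", y = "Incentive level",
                  fill = "P(accept)") +
    ggplot2::theme_minimal()
}

#' Plot one force trace with its success epoch
#'
#' @param forces Long force table.
#' @param subject_id,trial_index Which trace to plot.
#' @param epoch_len Epoch length used to shade the success epoch.
#' @return A ggplot object.
#' @export
plot_force_trace <- function(forces, subject_id, trial_index,
                             epoch_len = 2.5) {
  d <- dplyr::filter(forces, .data$subject_id == !!subject_id,
                     .data$trial_index == !!trial_index)
  if (nrow(d) == 0) stop("no such trace", call. = FALSE)
  sm <- d
  sm$force <- moving_mean(sm$force, 6)
  ep <- find_success_epoch(sm, epoch_len)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$force)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_line(data = sm, color = "steelblue") +
    ggplot2::geom_hline(yintercept = d$required_threshold[1],
                        linetype = "dashed") +
    ggplot2::labs(x = "Time (s)", y = "Force (%MGF)") +
    ggplot2::theme_minimal()
  if (!is.null(ep)) {
    p <- p + ggplot2::annotate("rect", xmin = sm$t[ep$start],
                               xmax = sm$t[ep$end], ymin = -Inf, ymax = Inf,
                               alpha = 0.15, fill = "orange")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a BMS result
#'
#' Bar chart of expected model frequencies, exceedance and protected
#' exceedance probabilities per family.
#'
#' @param object A `bms_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bms_result
#' @export
autoplot.bms_result <- function(object, ...) {
  tidy(object) |>
    tidyr::pivot_longer(c("r_expected", "xp", "pxp"),
                        names_to = "quantity") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$family, y = .data$value,
                                 fill = .data$family)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~quantity) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a recovery report
#'
#' Tile plot of the generating-vs-selected confusion matrix (if present),
#' otherwise a bar chart of parameter-recovery correlations.
#'
#' @param object A `recovery_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot recovery_report
#' @export
autoplot.recovery_report <- function(object, ...) {
  if (!is.null(object$confusion)) {
    return(
      ggplot2::ggplot(object$confusion,
                      ggplot2::aes(x = .data$generating, y = .data$selected,
                                   fill = .data$n)) +
        ggplot2::geom_tile() +
        ggplot2::geom_text(ggplot2::aes(label = .data$n), color = "white") +
        ggplot2::scale_fill_viridis_c() +
        ggplot2::labs(x = "Generating family", y = "Selected family") +
        ggplot2::theme_minimal()
    )
  }
  ggplot2::ggplot(object$param_recovery,
                  ggplot2::aes(x = .data$parameter, y = .data$r,
                               fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Parameter", y = "Pearson r (true vs recovered)") +
    ggplot2::theme_minimal()
}
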