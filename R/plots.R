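#' Plot stance-normalized joint angle curves
#'
#' Grand mean with a +/- 1 SD band per group, per joint and rotation
#' component — the curve-level summary of a cohort's rearfoot motion
#' (components: dorsi/plantar flexion, eversion/inversion, external/internal
#' rotation; DF, EV, ER positive).
#'
#' @param normalized Tibble of stance-normalized angle curves with columns
#'   `subject_id`, `group`, `joint`, `stance_percent`, `df_pf`, `ev_iv`,
#'   `er_ir`.
#' @return A ggplot object.
#' @export
plot_angle_curves <- function(normalized) {
  long <- tidyr::pivot_longer(normalized,
                              cols = dplyr::any_of(c("df_pf", "ev_iv",
                                                     "er_ir")),
                              names_to = "component", values_to = "angle")
  summ <- dplyr::summarise(
    dplyr::group_by(long, .data$group, .data$joint, .data$component,
                    .data$stance_percent),
    mean = mean(.data$angle), sd = stats::sd(.data$angle), .groups = "drop"
  )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$stance_percent,
                                     y = .data$mean,
                                     colour = .data$group,
                                     fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(component ~ joint, scales = "free_y") +
    ggplot2::labs(x = "stance phase (%)", y = "angle (deg)",
                  colour = "group", fill = "group") +
    ggplot2::theme_minimal()
}

#' Plot a group summary table as an effect-size chart
#'
#' Dot chart of the per-measure effect sizes from [build_table1()], filled
#' by significance.
#'
#' @param table1 Tibble from [build_table1()].
#' @return A ggplot object.
#' @export
plot_effect_sizes <- function(table1) {
  ggplot2::ggplot(table1, ggplot2::aes(x = .data$es,
                                       y = stats::reorder(.data$measure,
                                                          .data$es),
                                       colour = .data$sig)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_vline(xintercept = 0.8, linetype = "dashed") +
    ggplot2::labs(x = "effect size (pooled-SD d)", y = NULL,
                  colour = "p < 0.05") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rf_anova <- function(object, ...) {
  ph <- attr(object, "posthoc")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$term,
                                            y = .data$statistic)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "F statistic") +
    ggplot2::theme_minimal()
  p
}
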