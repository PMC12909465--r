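# ggplot2 views of the result objects.  Each returns a ggplot for further
# styling; nothing is printed or written to disk here.

#' @describeIn habitual_distribution Weighted density of the estimated
#'   habitual-intake distribution, with the weighted mean marked.
#' @param object A `habitual_distribution`.
#' @param ... Unused.
#' @method autoplot habitual_distribution
#' @export
autoplot.habitual_distribution <- function(object, ...) {
  v <- object$values
  ggplot2::ggplot(v, ggplot2::aes(x = .data$value,
                                  weight = .data$weight / sum(.data$weight))) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4, colour = NA) +
    ggplot2::geom_vline(xintercept = object$summary$mean,
                        linetype = "dashed") +
    ggplot2::labs(
      title = sprintf("Habitual intake: %s (%s)", object$nutrient,
                      object$sex),
      x = object$nutrient, y = "density"
    )
}

#' Plot plant-protein shares against policy targets
#'
#' Bars of the plant-protein share per scenario, strategy and sex, with
#' horizontal lines at the current (~40%), short-term (50%) and long-term
#' (60%) policy levels.
#'
#' @param report A `scenario_report` from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_plant_protein_share <- function(report) {
  targets <- report$config$share_targets
  df <- report$plant_protein
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario, y = .data$share,
                                   fill = .data$strategy)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = unname(targets),
                        linetype = c("dotted", "dashed", "dashed")) +
    ggplot2::facet_wrap(~sex) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%",
                                                             100 * x)) +
    ggplot2::labs(title = "Plant-based share of habitual protein intake",
                  x = NULL, y = "plant-protein share") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot EAR inadequacy per scenario
#'
#' Proportion of the population below the EAR per nutrient, sex and
#' scenario, with bootstrap CIs when available and the 10%
#' public-health-concern threshold marked.
#'
#' @param report A `scenario_report` from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_adequacy <- function(report) {
  df <- report$adequacy
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario,
                                        y = .data$prop_below_ear,
                                        colour = .data$strategy)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.5)) +
    ggplot2::geom_hline(yintercept = report$config$ear_threshold,
                        linetype = "dashed") +
    ggplot2::facet_grid(nutrient ~ sex) +
    ggplot2::labs(title = "Population proportion below the EAR",
                  x = NULL, y = "proportion below EAR") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
  if (!all(is.na(df$lower))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      position = ggplot2::position_dodge(0.5), width = 0.2
    )
  }
  p
}

#' Plot relative footprint differences versus the reference diet
#'
#' @param report A `scenario_report` from [run_pipeline()].
#' @param slice Population slice to show (`"total"`, `"women"`, `"men"`).
#' @return A ggplot object.
#' @export
plot_footprint_diff <- function(report, slice = "total") {
  df <- report$footprints %>%
    filter(.data$slice == !!slice, .data$scenario != "reference") %>%
    tidyr::pivot_longer(all_of(paste0(footprint_day_cols(),
                                      "_rel_diff_pct")),
                        names_to = "indicator", values_to = "rel_diff") %>%
    mutate(indicator = sub("_rel_diff_pct", "", .data$indicator))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario, y = .data$rel_diff,
                                   fill = .data$strategy)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::facet_wrap(~indicator, scales = "free_y") +
    ggplot2::labs(
      title = sprintf("Footprint change vs reference (%s population)",
                      slice),
      x = NULL, y = "relative difference (%)"
    ) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
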