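# ggplot2 views of the result objects.

metric_labels <- function() {
  c(total_g = "total protein (g)",
    digestible_g = "digestible protein (g)",
    utilizable_g = "utilizable protein (g)",
    total_g_per_kg = "total protein (g/kg bw/day)",
    digestible_g_per_kg = "digestible protein (g/kg bw/day)",
    utilizable_g_per_kg = "utilizable protein (g/kg bw/day)")
}

#' Plot a habitual intake distribution
#'
#' Density of the person-level usual intakes (weighted), with the quartiles
#' marked.
#'
#' @param object A `usual_intake` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot usual_intake
#' @export
autoplot.usual_intake <- function(object, ...) {
  people <- object$people
  q <- percentile(object, c(0.25, 0.5, 0.75))
  ggplot2::ggplot(people, ggplot2::aes(x = .data$usual,
                                       weight = .data$weight)) +
    ggplot2::geom_density(fill = "grey80", colour = "grey30") +
    ggplot2::geom_vline(xintercept = q, linetype = c(2, 1, 2)) +
    ggplot2::labs(x = object$metric, y = "density",
                  title = sprintf("habitual %s, p50 (p25-p75): %.3g (%.3g-%.3g)",
                                  object$metric, q[2], q[1], q[3])) +
    ggplot2::theme_minimal()
}

#' Median daily protein intake by scenario
#'
#' Per-sex, per-scenario p50 with p25-p75 error bars for the three protein
#' metrics (the per-day panel of the population report).
#'
#' @param report An `adequacy_report` from [build_report()].
#' @param per_kg Plot g/kg bw/day metrics instead of grams.
#' @return A ggplot.
#' @export
plot_intake_by_scenario <- function(report, per_kg = FALSE) {
  stopifnot(inherits(report, "adequacy_report"))
  wanted <- if (per_kg) {
    paste0(c("total_g", "digestible_g", "utilizable_g"), "_per_kg")
  } else {
    c("total_g", "digestible_g", "utilizable_g")
  }
  d <- report$daily_intake %>%
    filter(.data$metric %in% wanted) %>%
    mutate(metric = metric_labels()[.data$metric],
           scenario = factor(.data$scenario, levels = scenario_ids()))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$scenario, y = .data$p50,
                                  fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$p25, ymax = .data$p75),
                           position = ggplot2::position_dodge(0.9),
                           width = 0.3) +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = NULL, y = if (per_kg) "g/kg bw/day" else "g/day",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Median protein intake per meal occasion
#'
#' Breakfast/lunch/dinner p50 with p25-p75 error bars for the three protein
#' metrics, per sex and scenario (the per-occasion panel of the report).
#'
#' @param report An `adequacy_report`.
#' @return A ggplot.
#' @export
plot_occasion_protein <- function(report) {
  stopifnot(inherits(report, "adequacy_report"))
  d <- report$occasions %>%
    mutate(metric = metric_labels()[.data$metric],
           scenario = factor(.data$scenario, levels = scenario_ids()),
           occasion = factor(.data$occasion,
                             levels = c("breakfast", "lunch", "dinner")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$scenario, y = .data$p50,
                                  fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$p25, ymax = .data$p75),
                           position = ggplot2::position_dodge(0.9),
                           width = 0.3) +
    ggplot2::facet_grid(occasion ~ sex) +
    ggplot2::labs(x = NULL, y = "g per occasion", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
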