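# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' Tidy a Pareto front
#'
#' @param x A `pareto_front`.
#' @param ... Unused.
#' @return A plain tibble of front members (decision columns +
#'   objectives).
#' @method tidy pareto_front
#' @export
tidy.pareto_front <- function(x, ...) {
  tibble::as_tibble(unclass_front(x))
}

unclass_front <- function(x) {
  class(x) <- setdiff(class(x), "pareto_front")
  attr(x, "config") <- NULL
  attr(x, "history") <- NULL
  attr(x, "scenario") <- NULL
  x
}

#' One-row summary of a Pareto front
#'
#' @param x A `pareto_front`.
#' @param ... Unused.
#' @return Tibble with the front size, per-objective bests and the
#'   knee-point objectives.
#' @method glance pareto_front
#' @export
glance.pareto_front <- function(x, ...) {
  kp <- knee_point(x)
  tibble::tibble(n_solutions = nrow(x),
                 min_cost = min(x$cost), min_emissions = min(x$emissions),
                 max_nutrition = max(x$nutrition),
                 knee_cost = kp$cost, knee_emissions = kp$emissions,
                 knee_nutrition = kp$nutrition)
}

#' Plot a Pareto front in cost-emissions space
#'
#' Points are front members, colored by the nutrition score; the knee
#' point is highlighted.
#'
#' @param object A `pareto_front`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pareto_front
#' @export
autoplot.pareto_front <- function(object, ...) {
  df <- tidy(object)
  kp <- knee_point(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$emissions, y = .data$cost,
                                   colour = .data$nutrition)) +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = kp, shape = 21, size = 3, stroke = 1.2,
                        colour = "black", fill = NA) +
    ggplot2::labs(x = "Emissions (kg CO2e/person/day)",
                  y = "Cost ($/person/day)", colour = "Nutrition",
                  title = attr(object, "scenario")) +
    ggplot2::theme_minimal()
}

#' Tidy a Monte Carlo result
#'
#' @param x A `monte_carlo_result`.
#' @param ... Unused.
#' @return The per-run long tibble (`run`, `seed`, `metric`, `value`).
#' @method tidy monte_carlo_result
#' @export
tidy.monte_carlo_result <- function(x, ...) x$per_run

#' Summary statistics of a Monte Carlo result
#'
#' @param x A `monte_carlo_result`.
#' @param ... Unused.
#' @return The per-metric summary tibble (mean, sd, cv, 95 % CI, n).
#' @method glance monte_carlo_result
#' @export
glance.monte_carlo_result <- function(x, ...) x$summary

#' Plot Monte Carlo metric distributions
#'
#' @param object A `monte_carlo_result`.
#' @param ... Unused.
#' @return A ggplot of per-metric histograms with the mean and 95 % CI.
#' @method autoplot monte_carlo_result
#' @export
autoplot.monte_carlo_result <- function(object, ...) {
  ggplot2::ggplot(object$per_run, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(data = object$summary,
                        ggplot2::aes(xintercept = .data$mean)) +
    ggplot2::geom_vline(data = object$summary,
                        ggplot2::aes(xintercept = .data$ci95_lo),
                        linetype = "dashed") +
    ggplot2::geom_vline(data = object$summary,
                        ggplot2::aes(xintercept = .data$ci95_hi),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::theme_minimal()
}

#' Tidy an OLS cost-emissions fit
#'
#' @param x An `ols_result`.
#' @param ... Unused.
#' @return One row per coefficient (term, estimate, conf.low/high for the
#'   slope, p.value).
#' @method tidy ols_result
#' @export
tidy.ols_result <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "emissions"),
                 estimate = c(x$intercept, x$slope),
                 conf.low = c(NA_real_, x$slope_ci95[1]),
                 conf.high = c(NA_real_, x$slope_ci95[2]),
                 p.value = c(NA_real_, x$p_value))
}

#' One-row summary of an OLS cost-emissions fit
#'
#' @param x An `ols_result`.
#' @param ... Unused.
#' @return Tibble with `r.squared`, `p.value`, `n`.
#' @method glance ols_result
#' @export
glance.ols_result <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, p.value = x$p_value, n = x$n)
}

#' Heatmap of relative emission changes by country and scenario
#'
#' @param bundle A `report_bundle` from [build_report()].
#' @return A ggplot tile chart of knee-point emission changes relative to
#'   the baseline scenario (percent).
#' @export
plot_scenario_heatmap <- function(bundle) {
  df <- dplyr::filter(bundle$comparisons, .data$metric == "emissions")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario, y = .data$country,
                                   fill = .data$relative_change_pct)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "white",
                                  high = "darkred", midpoint = 0) +
    ggplot2::labs(fill = "Emissions change (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
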