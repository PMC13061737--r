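# Scenario comparison statistics, cost-environment regression, correlation
# analysis and tabular report bundles.

#' Relative change of a scenario value against its baseline
#'
#' `100 * (scenario - baseline) / baseline` (percent; negative = reduction).
#'
#' @param baseline Baseline value(s), nonzero.
#' @param scenario Scenario value(s).
#' @return Percent change.
#' @export
relative_change <- function(baseline, scenario) {
  if (any(baseline == 0)) abort("baseline must be nonzero")
  100 * (scenario - baseline) / baseline
}

#' OLS regression of dietary cost on environmental impact
#'
#' Ordinary least squares of cost against emissions across candidate
#' solutions, with the slope's 95 % confidence interval and two-sided
#' p-value from its t statistic on n - 2 degrees of freedom, and
#' `R^2 = 1 - SSres / SStot`.
#'
#' @param points Tibble/data frame with columns `emissions` (predictor) and
#'   `cost` (response); at least 3 rows and nonzero emission variance.
#' @return An `ols_result`: list with `slope`, `intercept`, `r_squared`,
#'   `slope_ci95` (lo, hi), `p_value`, `n`, and the underlying `lm` fit.
#' @export
ols_cost_vs_environment <- function(points) {
  if (nrow(points) < 3) abort("need at least 3 points for OLS")
  if (sd(points$emissions) == 0) abort("degenerate predictor: zero emission variance")
  fit <- lm(cost ~ emissions, data = points)
  sm <- suppressWarnings(summary(fit))  # exact fits are legitimate inputs
  est <- sm$coefficients["emissions", ]
  tcrit <- qt(0.975, df = fit$df.residual)
  structure(
    list(slope = unname(est["Estimate"]),
         intercept = unname(coef(fit)[1]),
         r_squared = sm$r.squared,
         slope_ci95 = unname(est["Estimate"] + c(-1, 1) * tcrit * est["Std. Error"]),
         p_value = unname(est["Pr(>|t|)"]),
         n = nrow(points),
         fit = fit),
    class = "ols_result")
}

#' @export
print.ols_result <- function(x, ...) {
  cat("<ols_result> cost ~ emissions, n = ", x$n, "\n",
      "  slope ", signif(x$slope, 4), " [",
      signif(x$slope_ci95[1], 4), ", ", signif(x$slope_ci95[2], 4),
      "], R^2 = ", signif(x$r_squared, 4),
      ", p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric series of equal length >= 3 with nonzero variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y)) {
    abort("need two equal-length series with n >= 3")
  }
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance series")
  cor(x, y, method = "pearson")
}

#' Assemble the scenario comparison report bundle
#'
#' Summarizes each (country, scenario) Pareto front at its knee point and
#' compares it against the country's baseline scenario; fits the per-country
#' cost-emissions OLS; and emits the matrices behind the standard charts.
#'
#' @param fronts Nested named list `fronts[[country]][[scenario]]` of
#'   `pareto_front` objects (each country must include the baseline
#'   scenario).
#' @param baseline_scenario Name of the baseline scenario
#'   (default `"Baseline_FBDG"`).
#' @param regression_points Which points feed the per-country OLS:
#'   `"front"` (all front members of all scenarios, the candidate-solution
#'   cloud), `"knee"` (one knee point per scenario) or `"all"` (both
#'   reported).
#' @return A `report_bundle` list of tibbles: `comparisons` (long table of
#'   relative changes vs baseline per metric), `regressions`,
#'   `heatmap` (country x scenario relative emissions), and
#'   `summary_points` (the knee points used).
#' @export
build_report <- function(fronts, baseline_scenario = "Baseline_FBDG",
                         regression_points = c("front", "knee", "all")) {
  regression_points <- match.arg(regression_points)
  countries <- names(fronts)
  knees <- purrr::map_dfr(countries, function(ct) {
    purrr::map_dfr(names(fronts[[ct]]), function(sc) {
      dplyr::mutate(knee_point(fronts[[ct]][[sc]]), country = ct,
                    scenario = sc, .before = 1)
    })
  })
  missing_base <- setdiff(countries,
                          knees$country[knees$scenario == baseline_scenario])
  if (length(missing_base) > 0) {
    abort(paste0("missing baseline scenario for country: ",
                 paste(missing_base, collapse = ", ")))
  }
  base <- knees |>
    dplyr::filter(.data$scenario == baseline_scenario) |>
    dplyr::select("country", base_cost = "cost", base_emissions = "emissions",
                  base_nutrition = "nutrition")
  comparisons <- knees |>
    dplyr::select("country", "scenario", "cost", "emissions", "nutrition") |>
    tidyr::pivot_longer(c("cost", "emissions", "nutrition"),
                        names_to = "metric", values_to = "scenario_value") |>
    dplyr::left_join(
      tidyr::pivot_longer(base, -"country", names_to = "metric",
                          values_to = "baseline_value") |>
        dplyr::mutate(metric = sub("^base_", "", .data$metric)),
      by = c("country", "metric")) |>
    dplyr::mutate(relative_change_pct =
                    relative_change(.data$baseline_value, .data$scenario_value))

  regressions <- purrr::map_dfr(countries, function(ct) {
    pts <- switch(
      regression_points,
      front = purrr::map_dfr(fronts[[ct]],
                             ~ tibble::as_tibble(.x)[, c("emissions", "cost")]),
      knee = knees[knees$country == ct, c("emissions", "cost")],
      all = purrr::map_dfr(fronts[[ct]],
                           ~ tibble::as_tibble(.x)[, c("emissions", "cost")]))
    if (nrow(pts) < 3 || sd(pts$emissions) == 0) {
      return(tibble::tibble(country = ct, n = nrow(pts), slope = NA_real_,
                            intercept = NA_real_, r_squared = NA_real_,
                            slope_ci_lo = NA_real_, slope_ci_hi = NA_real_,
                            p_value = NA_real_))
    }
    o <- ols_cost_vs_environment(pts)
    tibble::tibble(country = ct, n = o$n, slope = o$slope,
                   intercept = o$intercept, r_squared = o$r_squared,
                   slope_ci_lo = o$slope_ci95[1], slope_ci_hi = o$slope_ci95[2],
                   p_value = o$p_value)
  })

  heatmap <- comparisons |>
    dplyr::filter(.data$metric == "emissions") |>
    dplyr::select("country", "scenario", "relative_change_pct") |>
    tidyr::pivot_wider(names_from = "scenario",
                       values_from = "relative_change_pct")

  structure(list(comparisons = comparisons, regressions = regressions,
                 heatmap = heatmap, summary_points = knees),
            class = "report_bundle")
}

#' Write a report bundle as delimited tables plus a JSON index
#'
#' @param bundle A `report_bundle` from [build_report()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("comparisons", "regressions", "heatmap", "summary_points")
  for (tb in tables) {
    readr::write_csv(bundle[[tb]], file.path(dir, paste0(tb, ".csv")),
                     progress = FALSE)
  }
  jsonlite::write_json(list(tables = paste0(tables, ".csv")),
                       file.path(dir, "index.json"), auto_unbox = TRUE)
  invisible(dir)
}
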