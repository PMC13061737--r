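# Monte Carlo uncertainty propagation, convergence checking, and graduated
# deterministic sensitivity/elasticity analysis.
#
# Uncertainty enters as multiplicative perturbations p' = p * (1 + eps),
# eps ~ N(0, sigma^2), applied independently to every element of the
# perturbed parameter groups, once per run.

#' Perturbation / Monte Carlo configuration
#'
#' @param sigma Standard deviation of the multiplicative perturbation
#'   (default 0.10, i.e. 10 % baseline uncertainty).
#' @param n_runs Number of independent Monte Carlo runs (default 500).
#' @param perturbed_parameters Names of the parameter groups to perturb
#'   (subset of the names of the `params` list handed to the runners; e.g.
#'   `"prices"`, `"emission_factors"`, `"fish_availability"`, `"rda"`).
#' @param seed Master seed; per-run seeds are a deterministic split of it
#'   (distinct integers sampled without replacement under the master seed).
#' @param levels Graduated deterministic perturbation levels for the
#'   sensitivity sweep (strictly increasing fractions).
#' @return A `perturbation_config` list.
#' @export
perturbation_config <- function(sigma = 0.10, n_runs = 500,
                                perturbed_parameters = "prices",
                                seed = 1L,
                                levels = c(0.05, 0.10, 0.15, 0.20, 0.25)) {
  stopifnot(sigma > 0, n_runs >= 2, all(diff(levels) > 0), all(levels > 0))
  structure(list(sigma = sigma, n_runs = as.integer(n_runs),
                 perturbed_parameters = perturbed_parameters,
                 seed = as.integer(seed), levels = levels),
            class = "perturbation_config")
}

#' Multiplicative parameter perturbation
#'
#' `p' = p * (1 + eps)`.  Perturbed values that fall below zero (possible
#' for large draws on small positive parameters) are clipped to zero with a
#' warning: negative prices or emission factors are not meaningful.
#'
#' @param p Numeric parameter value(s).
#' @param epsilon Perturbation draw(s), recycled against `p`.
#' @return Perturbed value(s).
#' @export
perturb <- function(p, epsilon) {
  out <- p * (1 + epsilon)
  if (any(out < 0)) {
    warn("perturbation produced negative value(s); clipped to 0")
    out <- pmax(out, 0)
  }
  out
}

# Deterministic split of the master seed into n distinct per-run seeds.
split_seeds <- function(master_seed, n) {
  withr::with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

# Perturb every numeric element of the selected parameter groups with iid
# N(0, sigma^2) draws (one eps per scalar parameter).
perturb_params <- function(params, which, sigma) {
  for (nm in which) {
    if (!nm %in% names(params)) {
      abort(paste0("unknown perturbed parameter group '", nm, "'"))
    }
    v <- params[[nm]]
    params[[nm]] <- perturb(v, rnorm(length(v), 0, sigma))
  }
  params
}

#' Monte Carlo uncertainty propagation
#'
#' Runs `metric_fn` `n_runs` times, each under an independently perturbed
#' copy of `params` (its own run seed, drawn deterministically from the
#' master seed, drives both the perturbations and any randomness inside
#' `metric_fn`).  Failed runs are caught, excluded and counted; more than
#' 5 % failures aborts.
#'
#' @param metric_fn Function `(params, seed) -> ` named numeric vector of
#'   summary metrics (e.g. knee-point cost and emissions of a re-optimized
#'   scenario).
#' @param params Named list of baseline parameter groups (numeric vectors).
#' @param config A [perturbation_config()].
#' @return A `monte_carlo_result` with `per_run` (long tibble: run, seed,
#'   metric, value), `summary` (per metric: mean, sd, cv, ci95 bounds as
#'   `mean +/- 1.96 sd/sqrt(n)`), and `n_failed`.
#' @export
run_monte_carlo <- function(metric_fn, params, config = perturbation_config()) {
  seeds <- split_seeds(config$seed, config$n_runs)
  rows <- vector("list", config$n_runs)
  n_failed <- 0L
  for (r in seq_len(config$n_runs)) {
    res <- tryCatch(
      withr::with_seed(seeds[r], {
        p <- perturb_params(params, config$perturbed_parameters, config$sigma)
        metric_fn(p, seeds[r])
      }),
      error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      next
    }
    rows[[r]] <- res
  }
  if (n_failed > 0.05 * config$n_runs) {
    abort(paste0("Monte Carlo aborted: ", n_failed, " of ", config$n_runs,
                 " runs failed (> 5 %)"))
  }
  ok <- !vapply(rows, is.null, logical(1))
  per_run <- tibble::tibble(
    run = rep(which(ok), times = lengths(rows[ok])),
    seed = rep(seeds[ok], times = lengths(rows[ok])),
    metric = unlist(lapply(rows[ok], names), use.names = FALSE),
    value = unlist(rows[ok], use.names = FALSE))
  summary <- per_run |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = sd(.data$value), .by = "metric") |>
    dplyr::mutate(cv = ifelse(.data$mean != 0, .data$sd / .data$mean, NA_real_),
                  ci95_lo = .data$mean - 1.96 * .data$sd / sqrt(.data$n),
                  ci95_hi = .data$mean + 1.96 * .data$sd / sqrt(.data$n))
  structure(list(per_run = per_run, summary = summary, n_failed = n_failed,
                 config = config),
            class = "monte_carlo_result")
}

#' @export
print.monte_carlo_result <- function(x, ...) {
  cat("<monte_carlo_result> ", max(x$per_run$run), " runs (",
      x$n_failed, " failed), sigma = ", x$config$sigma, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Monte Carlo convergence check
#'
#' Recomputes the per-metric mean at increasing run counts on a common run
#' stream (the runs of a smaller size are the leading runs of the larger,
#' so differences isolate the effect of sample size) and applies the rule:
#' convergence is adequate when the relative difference in means between
#' consecutive sizes stays below 1 %.
#'
#' @inheritParams run_monte_carlo
#' @param sizes Increasing run counts to compare (default 500, 1000, 2000).
#' @param tol Relative mean-difference threshold (default 0.01).
#' @return Tibble with one row per metric and consecutive size pair:
#'   `metric`, `n_small`, `n_large`, `mean_small`, `mean_large`,
#'   `rel_diff`, `pass`.
#' @export
convergence_check <- function(metric_fn, params, config = perturbation_config(),
                              sizes = c(500, 1000, 2000), tol = 0.01) {
  stopifnot(all(diff(sizes) > 0))
  big <- run_monte_carlo(metric_fn, params,
                         perturbation_config(
                           sigma = config$sigma, n_runs = max(sizes),
                           perturbed_parameters = config$perturbed_parameters,
                           seed = config$seed, levels = config$levels))
  purrr::map_dfr(seq_len(length(sizes) - 1), function(i) {
    big$per_run |>
      dplyr::filter(.data$run <= sizes[i + 1]) |>
      dplyr::summarise(
        mean_small = mean(.data$value[.data$run <= sizes[i]]),
        mean_large = mean(.data$value),
        .by = "metric") |>
      dplyr::mutate(n_small = sizes[i], n_large = sizes[i + 1],
                    rel_diff = abs(.data$mean_large - .data$mean_small) /
                      abs(.data$mean_small),
                    pass = .data$rel_diff < tol) |>
      dplyr::select("metric", "n_small", "n_large", "mean_small",
                    "mean_large", "rel_diff", "pass")
  })
}

#' Graduated sensitivity sweep with elasticity estimates
#'
#' For every perturbed parameter group and level `delta`, evaluates the
#' metric at `p * (1 + delta)` and `p * (1 - delta)` and reports the
#' symmetric elasticity
#' `(|Y+ - Y0| + |Y- - Y0|) / (2 * |Y0| * delta)`, which reduces to the
#' analytic log-derivative elasticity for smooth metrics.  A zero baseline
#' metric leaves the elasticity undefined (`NA`, flagged).
#'
#' @inheritParams run_monte_carlo
#' @return Tidy tibble: `parameter`, `level`, `metric`, `baseline`,
#'   `y_up`, `y_down`, `elasticity`, `flagged`.
#' @export
sensitivity_sweep <- function(metric_fn, params, config = perturbation_config()) {
  y0 <- metric_fn(params, config$seed)
  purrr::map_dfr(config$perturbed_parameters, function(nm) {
    purrr::map_dfr(config$levels, function(delta) {
      up <- params; up[[nm]] <- perturb(up[[nm]], delta)
      dn <- params; dn[[nm]] <- perturb(dn[[nm]], -delta)
      y_up <- metric_fn(up, config$seed)
      y_dn <- metric_fn(dn, config$seed)
      el <- (abs(y_up - y0) + abs(y_dn - y0)) / (2 * abs(y0) * delta)
      tibble::tibble(parameter = nm, level = delta, metric = names(y0),
                     baseline = unname(y0), y_up = unname(y_up),
                     y_down = unname(y_dn),
                     elasticity = unname(ifelse(y0 == 0, NA_real_, el)),
                     flagged = unname(y0 == 0))
    })
  })
}
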