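# End-to-end orchestration: generate/translate -> scenarios -> optimize ->
# robustness -> report, with a single master seed propagated to every
# stochastic stage and a JSON manifest for reproducibility.

#' Evaluate a pinned reference diet as a single-point front
#'
#' Baseline_FBDG and MaxProt are deterministic diets, not searches: this
#' evaluates the commodity-level diet directly on the three axes and wraps
#' it as a one-member `pareto_front`.
#'
#' @param diet A harmonized diet tibble.
#' @param commodities A complete commodity tibble.
#' @param profile The [country_profile()].
#' @param spec The [scenario_spec()].
#' @return A one-row `pareto_front`.
#' @export
evaluate_pinned_diet <- function(diet, commodities, profile, spec) {
  adequacy <- nutrient_adequacy(diet, commodities, profile$rda)
  tracked <- adequacy[adequacy$nutrient %in% TRACKED_NUTRIENTS, ]
  q <- asf_category_intakes(diet, commodities)
  out <- dplyr::bind_cols(
    tibble::as_tibble(as.list(setNames(q, paste0("q_", names(q))))),
    tibble::tibble(
      cost = dietary_cost(diet, commodities),
      emissions = dietary_emissions(diet, commodities),
      nutrition = nutrition_score(adequacy, spec$priority_nutrients),
      penalty = nutrient_penalty(tracked),
      violation = 0))
  front <- new_pareto_front(out)
  attr(front, "scenario") <- spec$name
  front
}

#' Run one scenario for one country
#'
#' Pinned scenarios (Baseline_FBDG, MaxProt) are evaluated directly;
#' search scenarios are compiled to constraints and optimized with
#' NSGA-II.
#'
#' @param profile A [country_profile()].
#' @param commodities A complete (imputed) commodity tibble.
#' @param spec A [scenario_spec()] (or scenario name).
#' @param config An [nsga_config()].
#' @param fish_availability Marine upper-bound multiplier.
#' @return A `pareto_front`.
#' @export
run_scenario <- function(profile, commodities, spec, config = nsga_config(),
                         fish_availability = 1) {
  if (is.character(spec)) spec <- scenario_spec(spec)
  if (spec$pinned) {
    diet <- allocate_groups(profile)
    if (spec$protein_mode == "who60") {
      diet <- scale_to_protein_target(diet, profile$who_protein_target,
                                      commodities)
    }
    return(evaluate_pinned_diet(diet, commodities, profile, spec))
  }
  constraints <- build_constraints(spec, profile, commodities,
                                   fish_availability = fish_availability)
  model <- build_diet_model(profile, commodities)
  nsga2_optimize(model, constraints, spec, config)
}

#' Pipeline configuration
#'
#' @param archetypes Archetype names to generate
#'   (default all four).
#' @param scenarios Scenario names to run (default all six).
#' @param out_dir Output directory for artifacts.
#' @param seed Master seed; every stochastic stage derives its seed from
#'   it.
#' @param nsga [nsga_config()] for the scenario searches.
#' @param robustness [perturbation_config()] for the Monte Carlo stage.
#' @param robustness_scenario Scenario re-optimized under perturbation.
#' @param robustness_nsga Reduced-budget [nsga_config()] used inside each
#'   Monte Carlo run.
#' @param missingness_rate,noise_scale Passed to [generator_config()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(archetypes = ARCHETYPES,
                            scenarios = SCENARIO_NAMES,
                            out_dir = tempfile("dietfront_run_"),
                            seed = 1L,
                            nsga = nsga_config(),
                            robustness = perturbation_config(n_runs = 100),
                            robustness_scenario = "MaxVitamins_Protein",
                            robustness_nsga = nsga_config(population_size = 50,
                                                          generations = 30),
                            missingness_rate = 0.1,
                            noise_scale = 0.05) {
  structure(list(archetypes = archetypes, scenarios = scenarios,
                 out_dir = out_dir, seed = as.integer(seed), nsga = nsga,
                 robustness = robustness,
                 robustness_scenario = robustness_scenario,
                 robustness_nsga = robustness_nsga,
                 missingness_rate = missingness_rate,
                 noise_scale = noise_scale),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) the country datasets, imputes missing nutrient
#' cells, translates the FBDGs into commodity diets, runs all configured
#' scenarios, performs the Monte Carlo robustness stage and the graduated
#' sensitivity sweep on the designated scenario, and writes the report
#' bundle plus a manifest (seed, configuration, session versions) under
#' `config$out_dir`.  Rerunning with the same configuration and master
#' seed reproduces every artifact.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `fronts`, `report`, `robustness`,
#'   `sensitivity`, `datasets` and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage_seeds <- split_seeds(config$seed, length(config$archetypes) + 2L)

  # generate + translate
  datasets <- list()
  for (i in seq_along(config$archetypes)) {
    at <- config$archetypes[i]
    ds <- generate_country_dataset(generator_config(
      seed = stage_seeds[i], archetype = at,
      missingness_rate = config$missingness_rate,
      noise_scale = config$noise_scale))
    ds$commodities <- impute_missing_nutrients(ds$commodities)
    diet <- allocate_groups(ds$profile)
    mb <- validate_mass_balance(diet, ds$profile)
    if (any(mb$flagged)) abort(paste0("mass balance violated for ", at))
    ds$diet <- diet
    datasets[[at]] <- ds
    write_country_dataset(ds, file.path(out_dir, "data", at))
  }

  # optimize all scenarios
  fronts <- purrr::map(datasets, function(ds) {
    purrr::map(setNames(config$scenarios, config$scenarios), function(sc) {
      run_scenario(ds$profile, ds$commodities, sc, config$nsga)
    })
  })
  for (ct in names(fronts)) {
    for (sc in names(fronts[[ct]])) {
      readr::write_csv(tibble::as_tibble(fronts[[ct]][[sc]]),
                       file.path(out_dir, paste0("front_", ct, "_", sc, ".csv")),
                       progress = FALSE)
    }
  }

  # robustness: re-optimize the designated scenario under price perturbation
  rb_seed <- stage_seeds[length(config$archetypes) + 1L]
  robustness <- purrr::imap(datasets, function(ds, at) {
    mc_cfg <- config$robustness
    mc_cfg$seed <- rb_seed
    metric_fn <- scenario_metric_fn(ds$profile, ds$commodities,
                                    config$robustness_scenario,
                                    config$robustness_nsga)
    mc <- run_monte_carlo(metric_fn, baseline_params(ds$commodities), mc_cfg)
    readr::write_csv(mc$per_run,
                     file.path(out_dir, paste0("mc_runs_", at, ".csv")),
                     progress = FALSE)
    mc
  })
  sens_cfg <- config$robustness
  sens_cfg$perturbed_parameters <- c("prices", "fish_availability")
  sensitivity <- purrr::imap_dfr(datasets, function(ds, at) {
    metric_fn <- scenario_metric_fn(ds$profile, ds$commodities,
                                    config$robustness_scenario,
                                    config$robustness_nsga)
    dplyr::mutate(sensitivity_sweep(metric_fn, baseline_params(ds$commodities),
                                    sens_cfg),
                  country = at, .before = 1)
  })
  readr::write_csv(sensitivity, file.path(out_dir, "sensitivity.csv"),
                   progress = FALSE)

  # report
  report <- build_report(fronts)
  write_report(report, file.path(out_dir, "report"))
  jsonlite::write_json(
    list(seed = config$seed,
         archetypes = config$archetypes,
         scenarios = config$scenarios,
         nsga = unclass(config$nsga),
         robustness = unclass(config$robustness)[c("sigma", "n_runs",
                                                   "perturbed_parameters")],
         r_version = as.character(getRversion()),
         mc_summaries = purrr::map(robustness, function(m) {
           setNames(as.list(m$summary$cv), m$summary$metric)
         })),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(fronts = fronts, report = report, robustness = robustness,
                 sensitivity = sensitivity, datasets = datasets,
                 out_dir = out_dir))
}

#' Shipped demonstration configuration
#'
#' The packaged end-to-end demonstration: all four country archetypes, all
#' six scenarios at a moderate search budget (population 100, 60
#' generations), the Monte Carlo robustness stage at the reduced
#' re-optimization budget (population 40, 20 generations, 20 runs) and the
#' full report -- sized to complete in a few minutes on one CPU while
#' exercising every pipeline stage.
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return A [pipeline_config()].
#' @export
demo_pipeline_config <- function(seed = 1L, out_dir = tempfile("dietfront_demo_")) {
  pipeline_config(
    out_dir = out_dir, seed = seed,
    nsga = nsga_config(population_size = 100, generations = 60),
    robustness = perturbation_config(n_runs = 20),
    robustness_nsga = nsga_config(population_size = 40, generations = 20))
}

# Baseline parameter groups exposed to perturbation for a commodity table.
baseline_params <- function(commodities) {
  list(prices = setNames(commodities$producer_price, commodities$commodity_id),
       emission_factors = setNames(commodities$emission_factor,
                                   commodities$commodity_id),
       fish_availability = 1)
}

#' Build a re-optimizing scenario metric function
#'
#' Returns a `metric_fn(params, seed)` for [run_monte_carlo()] /
#' [sensitivity_sweep()]: it installs the perturbed prices, emission
#' factors and fish-availability multiplier, re-runs the scenario search
#' at the given (reduced) NSGA-II budget, and reports the knee-point cost
#' and emissions.
#'
#' @param profile A [country_profile()].
#' @param commodities A complete commodity tibble.
#' @param scenario Scenario name to re-optimize.
#' @param config The (reduced-budget) [nsga_config()] per run.
#' @return A function `(params, seed) -> c(cost = , emissions = )`.
#' @export
scenario_metric_fn <- function(profile, commodities, scenario,
                               config = nsga_config(population_size = 50,
                                                    generations = 30)) {
  force(profile); force(commodities); force(scenario); force(config)
  function(params, seed) {
    cm <- commodities
    if (!is.null(params$prices)) {
      cm$producer_price <- unname(params$prices[cm$commodity_id])
    }
    if (!is.null(params$emission_factors)) {
      cm$emission_factor <- unname(params$emission_factors[cm$commodity_id])
    }
    fish_avail <- if (!is.null(params$fish_availability)) params$fish_availability else 1
    cfg <- config
    cfg$seed <- as.integer(seed %% .Machine$integer.max)
    front <- run_scenario(profile, cm, scenario, cfg,
                          fish_availability = fish_avail)
    kp <- knee_point(front)
    c(cost = kp$cost, emissions = kp$emissions)
  }
}
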