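# Six named scenarios compiled into explicit constraint sets over the
# 8-dimensional ASF intake vector.
#
# Two reference scenarios are pinned diets (no search): Baseline_FBDG is the
# translated guideline diet itself; MaxProt scales every protein-containing
# intake uniformly to the WHO 60 g/day protein reference.  The four
# nutrient-optimized scenarios (vitamin A/B12 or EPA/DHA priorities, each
# under FBDG-native or WHO-60 protein caps) open the EAT-Lancet intake
# ranges to NSGA-II search.

SCENARIO_NAMES <- c("Baseline_FBDG", "MaxProt",
                    "MaxVitamins_FBDG", "MaxVitamins_Protein",
                    "MaxFattyAcids_FBDG", "MaxFattyAcids_Protein")

#' Scenario specification
#'
#' The scenario name determines the protein mode and priority-nutrient set:
#' `*_Protein` scenarios and `MaxProt` use the WHO 60 g/day protein
#' reference (`who60`), the others keep the FBDG-native protein total;
#' `MaxVitamins_*` prioritize vitamin A and B12, `MaxFattyAcids_*`
#' prioritize EPA and DHA, and the two reference scenarios have an empty
#' priority set (scored over all four tracked nutrients).
#'
#' @param name One of `"Baseline_FBDG"`, `"MaxProt"`,
#'   `"MaxVitamins_FBDG"`, `"MaxVitamins_Protein"`,
#'   `"MaxFattyAcids_FBDG"`, `"MaxFattyAcids_Protein"`.
#' @return A `scenario_spec` with fields `name`, `protein_mode`
#'   (`"fbdg_native"` or `"who60"`), `priority_nutrients` and `pinned`.
#' @export
scenario_spec <- function(name) {
  if (!name %in% SCENARIO_NAMES) {
    abort(paste0("unknown scenario '", name, "'; must be one of: ",
                 paste(SCENARIO_NAMES, collapse = ", ")))
  }
  protein_mode <- if (name %in% c("MaxProt", "MaxVitamins_Protein",
                                  "MaxFattyAcids_Protein")) "who60" else "fbdg_native"
  priority <- switch(sub("_(FBDG|Protein)$", "", name),
                     MaxVitamins = c("vitamin_a", "vitamin_b12"),
                     MaxFattyAcids = c("epa", "dha"),
                     character(0))
  structure(list(name = name, protein_mode = protein_mode,
                 priority_nutrients = priority,
                 pinned = name %in% c("Baseline_FBDG", "MaxProt")),
            class = "scenario_spec")
}

#' All six canonical scenario presets
#'
#' @return Named list of [scenario_spec()] objects.
#' @export
scenario_presets <- function() {
  setNames(lapply(SCENARIO_NAMES, scenario_spec), SCENARIO_NAMES)
}

#' EAT-Lancet reference ranges and point targets
#'
#' Intake ranges (g/day) used as constraint bounds: red meat 0-28,
#' poultry 0-58, fish 0-100, dairy 0-500, eggs 0-25; and point targets used
#' for compliance ratios: fish 28, pork 7, eggs 13, poultry 29, beef 7,
#' milk 250 g/day.
#'
#' @return List with tibbles `ranges` (`category`, `lo`, `hi`) and
#'   `points` (`category`, `grams`).
#' @export
eat_lancet_reference <- function() {
  list(
    ranges = tibble::tibble(
      category = c("red_meat", "poultry", "fish", "dairy", "eggs"),
      lo = c(0, 0, 0, 0, 0),
      hi = c(28, 58, 100, 500, 25)),
    points = tibble::tibble(
      category = c("fish", "pork", "eggs", "poultry", "beef", "milk"),
      grams = c(28, 7, 13, 29, 7, 250)))
}

#' Scale a diet to a total-protein target
#'
#' Multiplies every protein-containing intake by `target/current` so total
#' protein equals the target exactly (e.g. the WHO 60 g/day reference of
#' the MaxProt scenario); zero-protein foods (e.g. oils) are untouched.
#'
#' @param diet A harmonized diet tibble.
#' @param target Target total protein, g/day.
#' @param commodities A commodity tibble.
#' @return The scaled diet.
#' @export
scale_to_protein_target <- function(diet, target, commodities) {
  dens <- lookup_coef(diet, commodities, "protein")
  current <- sum(diet$grams * dens) / 100
  if (current <= 0) abort("diet supplies no protein: scaling undefined")
  diet$grams <- as.numeric(ifelse(dens > 0, diet$grams * target / current,
                                  diet$grams))
  diet
}

#' Intake ratios against the EAT-Lancet point targets
#'
#' Category intakes divided by the point targets (1.0 = exact compliance).
#' Marine categories (fish + other aquatic) are compared against the fish
#' target, dairy against the milk target.  A zero target with nonzero
#' intake yields `Inf` (flagged).
#'
#' @param diet A harmonized diet tibble.
#' @param commodities A commodity tibble (for category lookup).
#' @param reference An [eat_lancet_reference()].
#' @return Tibble with `category`, `intake`, `target`, `ratio`, `flagged`.
#' @export
eat_lancet_ratio <- function(diet, commodities,
                             reference = eat_lancet_reference()) {
  cat_of <- prot_col(commodities, "category", diet$commodity_id)
  intake_of <- function(cats) sum(diet$grams[cat_of %in% cats])
  intakes <- c(fish = intake_of(c("fish", "aquatic_other")),
               pork = intake_of("pork"),
               eggs = intake_of("eggs"),
               poultry = intake_of("poultry"),
               beef = intake_of("beef"),
               milk = intake_of("dairy"))
  pts <- setNames(reference$points$grams, reference$points$category)
  out <- tibble::tibble(category = names(intakes),
                        intake = unname(intakes),
                        target = unname(pts[names(intakes)]))
  out$ratio <- ifelse(out$target > 0, out$intake / out$target,
                      ifelse(out$intake > 0, Inf, 0))
  out$flagged <- !is.finite(out$ratio)
  out
}

#' Compile a scenario into a constraint set
#'
#' Maps the EAT-Lancet ranges onto the eight ASF categories (the red-meat
#' range caps the beef + pork + other ruminant sum, the fish range caps the
#' fish + other aquatic sum, each member individually nonnegative), fixes
#' the isocaloric energy band at the profile's FBDG energy target
#' (tolerance +/- 2 %), and sets the protein cap/target: `who60` scenarios
#' cap and target total protein at the WHO reference, FBDG-native scenarios
#' cap it at the guideline's own total.  Pinned scenarios get degenerate
#' bounds at their reference diet.
#'
#' @param spec A [scenario_spec()].
#' @param profile A [country_profile()].
#' @param commodities A complete (imputed) commodity tibble.
#' @param reference An [eat_lancet_reference()].
#' @param fish_availability Multiplier on the marine upper bounds (the
#'   fish-availability sensitivity lever; default 1).
#' @param energy_tolerance Isocaloric band half-width as a fraction.
#' @return A `constraint_set`.
#' @export
build_constraints <- function(spec, profile, commodities,
                              reference = eat_lancet_reference(),
                              fish_availability = 1,
                              energy_tolerance = 0.02) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(profile, "country_profile"))
  diet <- allocate_groups(profile)
  fbdg_protein <- sum(diet$grams * lookup_coef(diet, commodities, "protein")) / 100
  energy_target <- profile$energy_target

  if (spec$pinned) {
    ref_diet <- diet
    if (spec$protein_mode == "who60") {
      ref_diet <- scale_to_protein_target(diet, profile$who_protein_target,
                                          commodities)
      energy_target <- sum(ref_diet$grams *
                             lookup_coef(ref_diet, commodities, "energy")) / 100
    }
    q <- unname(asf_category_intakes(ref_diet, commodities))
    bounds <- tibble::tibble(category = ASF_CATEGORIES, lo = q, hi = q)
    group_caps <- tibble::tibble(group = character(0), cap = numeric(0))
  } else {
    rng <- setNames(reference$ranges$hi, reference$ranges$category)
    needed <- c("red_meat", "poultry", "fish", "dairy", "eggs")
    if (!all(needed %in% names(rng))) {
      abort(paste0("reference ranges missing category: ",
                   paste(setdiff(needed, names(rng)), collapse = ", ")))
    }
    fish_cap <- rng[["fish"]] * fish_availability
    bounds <- tibble::tibble(
      category = ASF_CATEGORIES,
      lo = 0,
      hi = c(rng[["red_meat"]], rng[["red_meat"]], rng[["poultry"]],
             fish_cap, rng[["eggs"]], rng[["dairy"]], rng[["red_meat"]],
             fish_cap))
    group_caps <- tibble::tibble(group = c("red_meat", "marine"),
                                 cap = c(rng[["red_meat"]], fish_cap))
  }

  protein_cap <- if (spec$protein_mode == "who60") profile$who_protein_target else fbdg_protein
  protein_target <- if (spec$protein_mode == "who60") profile$who_protein_target else NA_real_

  structure(
    list(scenario = spec$name,
         bounds = bounds,
         group_caps = group_caps,
         energy_band = c(target = energy_target, tol = energy_tolerance),
         protein_cap = protein_cap,
         protein_target = protein_target,
         fill_target = protein_cap,
         rda_active = profile$rda[profile$rda$nutrient %in% TRACKED_NUTRIENTS, ],
         pinned = spec$pinned),
    class = "constraint_set")
}

# Members of the two grouped EAT-Lancet caps.
GROUP_CAP_MEMBERS <- list(red_meat = c("beef", "pork", "other_asf"),
                          marine = c("fish", "aquatic_other"))

# Sum a commodity-level diet into the 8 ASF category intakes (named vector,
# canonical order).
asf_category_intakes <- function(diet, commodities) {
  cat_of <- prot_col(commodities, "category", diet$commodity_id)
  q <- tapply(diet$grams, factor(cat_of, levels = ASF_CATEGORIES), sum)
  q[is.na(q)] <- 0
  setNames(as.numeric(q), ASF_CATEGORIES)
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("<constraint_set> scenario ", x$scenario,
      if (x$pinned) " (pinned)" else "", "\n", sep = "")
  cat("  protein cap ", round(x$protein_cap, 2), " g",
      if (!is.na(x$protein_target)) paste0(", target ", x$protein_target, " g"),
      " | energy ", round(x$energy_band[["target"]]), " kcal +/- ",
      100 * x$energy_band[["tol"]], "%\n", sep = "")
  invisible(x)
}
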