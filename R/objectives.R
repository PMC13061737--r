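# The three objective axes (cost, emissions, nutrition) and the quadratic
# nutrient-adequacy penalty, evaluated on commodity-level diets.
#
# Cost:       C(Q) = sum_i Q_i * price_i / 1000      [$ / person / day]
# Emissions:  E(Q) = sum_i Q_i * EF_i / 1000         [kg CO2e / person / day]
# Adequacy:   supply_j = sum_i Q_i * N_ij / 100, ratio_j = supply_j / RDA_j,
#             deficit d_j = max(0, RDA_j - supply_j)
# Penalty:    scale * sum_j (d_j / RDA_j)^2          (zero iff all RDAs met)

lookup_coef <- function(diet, commodities, col) {
  v <- prot_col(commodities, col, diet$commodity_id)
  missing <- diet$commodity_id[is.na(v)]
  if (length(missing) > 0) {
    abort(paste0("no ", col, " value for commodity: ",
                 paste(unique(missing), collapse = ", ")))
  }
  v
}

#' Daily dietary cost
#'
#' Total producer-side cost of a diet: intakes (g/day) times PPP-adjusted
#' producer prices ($/kg), divided by 1000.  Linear and homogeneous in the
#' intake vector; a commodity without a price is an error, never a silent
#' zero.
#'
#' @param diet A harmonized diet tibble (`commodity_id`, `grams`).
#' @param commodities A commodity tibble with `producer_price`.
#' @return Cost in $/person/day.
#' @export
dietary_cost <- function(diet, commodities) {
  sum(diet$grams * lookup_coef(diet, commodities, "producer_price")) / 1000
}

#' Daily dietary greenhouse-gas emissions
#'
#' Life-cycle emissions of a diet: intakes (g/day) times emission factors
#' (kg CO2e/kg, GWP20 mass allocation), divided by 1000.
#'
#' @inheritParams dietary_cost
#' @param commodities A commodity tibble with `emission_factor`.
#' @return Emissions in kg CO2e/person/day.
#' @export
dietary_emissions <- function(diet, commodities) {
  sum(diet$grams * lookup_coef(diet, commodities, "emission_factor")) / 1000
}

#' Nutrient supply, adequacy ratios and deficits
#'
#' Computes per-nutrient daily supply from intakes (g/day) and densities
#' (per 100 g), the adequacy ratio supply/RDA, and the deficit
#' `d = max(0, RDA - supply)` that feeds the quadratic penalty.
#'
#' @inheritParams dietary_cost
#' @param rda Tibble with columns `nutrient`, `rda`.
#' @return Tibble with columns `nutrient`, `supply`, `rda`, `ratio`,
#'   `deficit`.
#' @export
nutrient_adequacy <- function(diet, commodities, rda) {
  supply <- purrr::map_dbl(rda$nutrient, function(nutr) {
    sum(diet$grams * lookup_coef(diet, commodities, nutr)) / 100
  })
  allowance <- rda$rda
  tibble::tibble(nutrient = rda$nutrient,
                 supply = supply,
                 rda = allowance,
                 ratio = supply / allowance,
                 deficit = pmax(0, allowance - supply))
}

#' Quadratic nutrient-shortfall penalty
#'
#' `scale * sum_j (d_j / RDA_j)^2` over the adequacy rows: deficits are
#' normalized by their RDA before squaring so that micrograms and grams
#' contribute on a common dimensionless scale, then squared so that the
#' penalty grows with the severity of the violation.  Zero exactly when
#' every RDA is met.  `normalize = FALSE` gives the raw `scale * sum_j d_j^2`
#' variant for fidelity checks.
#'
#' @param adequacy An adequacy tibble from [nutrient_adequacy()].
#' @param scale Positive penalty coefficient.
#' @param normalize Divide deficits by their RDA before squaring?
#' @return Nonnegative penalty value.
#' @export
nutrient_penalty <- function(adequacy, scale = 1, normalize = TRUE) {
  if (scale <= 0) abort("penalty scale must be > 0")
  d <- if (normalize) adequacy$deficit / adequacy$rda else adequacy$deficit
  scale * sum(d^2)
}

#' Capped min-adequacy nutrition score
#'
#' The nutrition objective is the minimum over the scenario's priority
#' nutrients of `min(ratio_j, 1)`: capped so an over-supplied nutrient
#' cannot mask a deficit elsewhere, and equal to 1 only when every priority
#' RDA is met.  Baseline scenarios (empty priority set) score over all four
#' tracked nutrients (vitamin A, vitamin B12, EPA, DHA).
#'
#' @param adequacy An adequacy tibble from [nutrient_adequacy()].
#' @param priority Character vector of priority nutrients (may be empty).
#' @return Score in `[0, 1]`.
#' @export
nutrition_score <- function(adequacy, priority = character(0)) {
  if (nrow(adequacy) == 0) abort("empty adequacy table")
  if (length(priority) == 0) priority <- TRACKED_NUTRIENTS
  rows <- adequacy[adequacy$nutrient %in% priority, ]
  if (nrow(rows) < length(priority)) {
    abort(paste0("priority nutrient(s) absent from adequacy table: ",
                 paste(setdiff(priority, rows$nutrient), collapse = ", ")))
  }
  min(pmin(rows$ratio, 1))
}

#' Share of dietary protein from animal-source foods
#'
#' @inheritParams dietary_cost
#' @return Fraction in `[0, 1]`: protein supplied by ASF commodities over
#'   total protein.
#' @export
animal_protein_share <- function(diet, commodities) {
  prot <- diet$grams * lookup_coef(diet, commodities, "protein") / 100
  total <- sum(prot)
  if (total <= 0) abort("zero total protein: share undefined")
  cat_of <- prot_col(commodities, "category", diet$commodity_id)
  sum(prot[cat_of %in% ASF_CATEGORIES]) / total
}

#' Percentage excess over a reference intake
#'
#' `100 * (total - reference) / reference`, e.g. the excess of an FBDG
#' protein total over the WHO 60 g/day reference.
#'
#' @param total Observed value (g/day).
#' @param reference Reference value (g/day), > 0.
#' @return Percent excess (negative when below the reference).
#' @export
excess_over_reference <- function(total, reference) {
  if (any(reference <= 0)) abort("reference must be > 0")
  100 * (total - reference) / reference
}
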