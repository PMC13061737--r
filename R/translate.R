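# FBDG -> commodity translation: fractional allocation with mass balance,
# recipe disaggregation, and subcategory-mean nutrient imputation.

#' Allocate food-group recommendations across commodities
#'
#' Splits each FBDG group recommendation over its member commodities
#' according to the country-specific fractional composition, preserving mass
#' balance: within every group the allocated commodity intakes sum exactly
#' to the group-level recommendation.
#'
#' @param profile A [country_profile()].
#' @return A harmonized diet: tibble with columns `commodity_id`, `grams`
#'   (g/person/day) and `group_id` (provenance).
#' @export
allocate_groups <- function(profile) {
  stopifnot(inherits(profile, "country_profile"))
  profile$composition |>
    dplyr::inner_join(profile$fbdg_groups, by = "group_id") |>
    dplyr::transmute(commodity_id = .data$commodity_id,
                     grams = .data$grams * .data$fraction,
                     group_id = .data$group_id)
}

#' Disaggregate composite foods into primary ingredients
#'
#' Replaces every composite item in a diet by its recipe ingredients
#' (mass fractions summing to 1), recursing until no composite remains.
#' Total dietary mass is conserved.  Cyclic recipes are an error.
#'
#' @param diet A harmonized diet tibble (`commodity_id`, `grams`, and
#'   optionally `group_id`).
#' @param recipes Tibble with columns `composite_id`, `ingredient_id`,
#'   `fraction`; fractions within each composite must sum to 1
#'   (tolerance 1e-9).
#' @param composite_ids Optional character vector declaring which diet
#'   items are composite; any declared composite without a recipe is an
#'   error naming it.  When `NULL`, the composites are the ids that have
#'   recipes.
#' @return The diet with composites resolved, aggregated by commodity
#'   (and provenance group, when present).
#' @export
disaggregate_recipes <- function(diet, recipes, composite_ids = NULL) {
  diet <- tibble::as_tibble(diet)
  if (!is.null(composite_ids)) {
    orphan <- intersect(setdiff(composite_ids, recipes$composite_id),
                        diet$commodity_id)
    if (length(orphan) > 0) {
      abort(paste0("no recipe for composite(s): ",
                   paste(orphan, collapse = ", ")))
    }
  }
  if (nrow(diet) == 0 || nrow(recipes) == 0 ||
      !any(diet$commodity_id %in% recipes$composite_id)) {
    return(diet)
  }
  sums <- recipes |>
    dplyr::summarise(s = sum(.data$fraction), .by = "composite_id")
  bad <- sums$composite_id[abs(sums$s - 1) > 1e-9]
  if (length(bad) > 0) {
    abort(paste0("recipe fractions do not sum to 1 for composite(s): ",
                 paste(bad, collapse = ", ")))
  }
  has_group <- "group_id" %in% names(diet)
  if (!has_group) diet$group_id <- NA_character_
  composites <- unique(recipes$composite_id)
  max_depth <- length(composites) + 1L
  depth <- 0L
  while (any(diet$commodity_id %in% composites)) {
    depth <- depth + 1L
    if (depth > max_depth) {
      abort("cyclic recipe definitions: composite resolution does not terminate")
    }
    is_comp <- diet$commodity_id %in% composites
    resolved <- diet[!is_comp, ]
    expanded <- diet[is_comp, ] |>
      dplyr::inner_join(recipes, by = c(commodity_id = "composite_id"),
                        relationship = "many-to-many") |>
      dplyr::transmute(commodity_id = .data$ingredient_id,
                       grams = .data$grams * .data$fraction,
                       group_id = .data$group_id)
    diet <- dplyr::bind_rows(resolved, expanded)
  }
  out <- diet |>
    dplyr::summarise(grams = sum(.data$grams),
                     .by = c("commodity_id", "group_id"))
  if (!has_group) out$group_id <- NULL
  out
}

#' Impute missing nutrient densities from subcategory means
#'
#' Fills each missing nutrient cell with the unweighted arithmetic mean of
#' the non-missing values for the same nutrient among chemically similar
#' commodities (same `subcategory`).  Non-missing cells are untouched; a
#' subcategory with no donor for a needed nutrient is an error.
#'
#' @param commodities A commodity tibble, possibly with `NA` nutrient cells.
#' @return The commodity tibble with no missing nutrient cells.
#' @export
impute_missing_nutrients <- function(commodities) {
  validate_commodities(commodities)
  orphans <- character(0)
  for (col in NUTRIENTS) {
    v <- commodities[[col]]
    if (!anyNA(v)) next
    means <- tapply(v, commodities$subcategory, function(x) mean(x, na.rm = TRUE))
    fill <- means[commodities$subcategory]
    bad <- is.na(v) & !is.finite(fill)
    if (any(bad)) {
      orphans <- c(orphans,
                   paste0("(", unique(commodities$subcategory[bad]), ", ", col, ")"))
      next
    }
    commodities[[col]] <- ifelse(is.na(v), as.numeric(fill), v)
  }
  if (length(orphans) > 0) {
    abort(paste0("no imputation donors for: ", paste(orphans, collapse = ", ")))
  }
  validate_commodities(commodities, allow_missing = FALSE)
  commodities
}

#' Check mass balance between a diet and its source recommendations
#'
#' Reports, per FBDG group, the absolute discrepancy between the group
#' recommendation and the total mass allocated to that group in the diet,
#' flagging discrepancies above 1e-6 g (far below nutritional significance;
#' catches allocation logic errors).
#'
#' @param diet A harmonized diet tibble with a `group_id` provenance column.
#' @param profile The [country_profile()] the diet was derived from.
#' @param tol Flagging tolerance in grams.
#' @return Tibble with columns `group_id`, `recommended`, `allocated`,
#'   `discrepancy`, `flagged`.
#' @export
validate_mass_balance <- function(diet, profile, tol = 1e-6) {
  allocated <- diet |>
    dplyr::summarise(allocated = sum(.data$grams), .by = "group_id")
  profile$fbdg_groups |>
    dplyr::left_join(allocated, by = "group_id") |>
    dplyr::mutate(allocated = dplyr::coalesce(.data$allocated, 0),
                  discrepancy = abs(.data$allocated - .data$grams),
                  flagged = .data$discrepancy > tol) |>
    dplyr::select("group_id", recommended = "grams", "allocated",
                  "discrepancy", "flagged")
}
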