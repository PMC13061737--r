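#' Validate a commodity table
#'
#' A commodity table is a tibble with one row per food item carrying nutrient
#' densities (per 100 g edible mass), a life-cycle emission factor
#' (kg CO2e/kg, GWP20 mass allocation) and a PPP-adjusted producer price
#' (constant 2020 international $/kg).
#'
#' Required columns: `commodity_id`, `name`, `category` (one of the eight ASF
#' categories or `"plant_group"`), `subcategory` (grouping key for
#' imputation), the seven nutrient columns `protein`, `vitamin_a`,
#' `vitamin_b12`, `ala`, `epa`, `dha`, `energy`, plus `emission_factor` and
#' `producer_price`.  Missing nutrient values are `NA` (distinguishable from
#' a true zero).
#'
#' @param commodities A commodity tibble.
#' @param allow_missing Allow `NA` nutrient cells (pre-imputation tables)?
#' @return The validated table, invisibly.
#' @export
validate_commodities <- function(commodities, allow_missing = TRUE) {
  required <- c("commodity_id", "name", "category", "subcategory", NUTRIENTS,
                "emission_factor", "producer_price")
  missing_cols <- setdiff(required, names(commodities))
  if (length(missing_cols) > 0) {
    abort(paste0("commodity table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_cat <- setdiff(unique(commodities$category), ALL_CATEGORIES)
  if (length(bad_cat) > 0) {
    abort(paste0("unknown commodity category: ", paste(bad_cat, collapse = ", ")))
  }
  if (anyDuplicated(commodities$commodity_id)) {
    abort("duplicated commodity_id in commodity table")
  }
  num_cols <- c(NUTRIENTS, "emission_factor", "producer_price")
  for (col in num_cols) {
    v <- commodities[[col]]
    if (!allow_missing && anyNA(v)) {
      abort(paste0("missing values in column '", col, "'"))
    }
    if (any(v < 0, na.rm = TRUE)) {
      abort(paste0("negative values in column '", col, "'"))
    }
  }
  plant <- dplyr::filter(commodities, .data$category == "plant_group")
  for (col in c("vitamin_b12", "epa", "dha")) {
    if (any(plant[[col]] > 0, na.rm = TRUE)) {
      abort(paste0("plant_group commodities must have ", col, " = 0"))
    }
  }
  invisible(commodities)
}

#' Read / write a commodity table
#'
#' Plain UTF-8 CSV with the documented header; `NA` cells encode missing
#' nutrient values.
#'
#' @param path File path.
#' @param commodities A commodity tibble.
#' @return `read_commodities()` returns a validated tibble;
#'   `write_commodities()` returns `path` invisibly.
#' @export
read_commodities <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_commodities(tbl)
  tbl
}

#' @rdname read_commodities
#' @export
write_commodities <- function(commodities, path) {
  validate_commodities(commodities)
  readr::write_csv(commodities, path, progress = FALSE)
  invisible(path)
}
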