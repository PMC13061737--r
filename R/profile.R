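#' Construct a country profile
#'
#' A country profile bundles the national FBDG food-group recommendations
#' (g/person/day), the group-to-commodity composition fractions used for
#' allocation, the recommended daily allowances (RDAs) the adequacy ratios
#' are measured against, and the national energy and WHO protein targets.
#'
#' @param country_id Country identifier string.
#' @param fbdg_groups Tibble with columns `group_id`, `grams`
#'   (recommended g/person/day, all >= 0).
#' @param composition Tibble with columns `group_id`, `commodity_id`,
#'   `fraction`; fractions within each group must sum to 1 (tolerance 1e-9).
#' @param rda Tibble with columns `nutrient`, `rda` (all > 0); units match
#'   the commodity nutrient densities times grams.
#' @param energy_target National FBDG energy level, kcal/person/day.
#' @param who_protein_target WHO protein reference, g/person/day (default 60).
#' @return An object of class `country_profile`.
#' @export
country_profile <- function(country_id, fbdg_groups, composition, rda,
                            energy_target, who_protein_target = 60) {
  stopifnot(is.character(country_id), length(country_id) == 1)
  fbdg_groups <- tibble::as_tibble(fbdg_groups)
  composition <- tibble::as_tibble(composition)
  rda <- tibble::as_tibble(rda)
  if (any(fbdg_groups$grams < 0)) abort("FBDG group recommendations must be >= 0")
  if (any(rda$rda <= 0)) abort("RDA values must be > 0")
  if (anyDuplicated(fbdg_groups$group_id)) abort("duplicated group_id in fbdg_groups")
  sums <- composition |>
    dplyr::summarise(s = sum(.data$fraction), .by = "group_id")
  bad <- sums$group_id[abs(sums$s - 1) > 1e-9]
  if (length(bad) > 0) {
    abort(paste0("composition fractions do not sum to 1 for group(s): ",
                 paste(bad, collapse = ", ")))
  }
  missing_comp <- setdiff(fbdg_groups$group_id, composition$group_id)
  if (length(missing_comp) > 0) {
    abort(paste0("no composition row for group(s): ",
                 paste(missing_comp, collapse = ", ")))
  }
  structure(
    list(country_id = country_id,
         fbdg_groups = fbdg_groups,
         composition = composition,
         rda = rda,
         energy_target = as.numeric(energy_target),
         who_protein_target = as.numeric(who_protein_target)),
    class = "country_profile")
}

#' @export
print.country_profile <- function(x, ...) {
  cat("<country_profile> ", x$country_id, "\n", sep = "")
  cat("  groups: ", nrow(x$fbdg_groups),
      " | commodities mapped: ", length(unique(x$composition$commodity_id)),
      "\n  energy target: ", round(x$energy_target), " kcal/day",
      " | WHO protein target: ", x$who_protein_target, " g/day\n", sep = "")
  invisible(x)
}

#' Read / write a country profile
#'
#' A profile is stored as a directory of plain CSV tables
#' (`fbdg_groups.csv`, `composition.csv`, `rda.csv`) plus a `profile.json`
#' holding the scalar fields.
#'
#' @param profile A `country_profile`.
#' @param dir Directory path.
#' @return `read_country_profile()` returns a `country_profile`;
#'   `write_country_profile()` returns `dir` invisibly.
#' @export
write_country_profile <- function(profile, dir) {
  stopifnot(inherits(profile, "country_profile"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(profile$fbdg_groups, file.path(dir, "fbdg_groups.csv"), progress = FALSE)
  readr::write_csv(profile$composition, file.path(dir, "composition.csv"), progress = FALSE)
  readr::write_csv(profile$rda, file.path(dir, "rda.csv"), progress = FALSE)
  jsonlite::write_json(
    list(country_id = profile$country_id,
         energy_target = profile$energy_target,
         who_protein_target = profile$who_protein_target),
    file.path(dir, "profile.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_country_profile
#' @export
read_country_profile <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "profile.json"))
  country_profile(
    country_id = meta$country_id,
    fbdg_groups = readr::read_csv(file.path(dir, "fbdg_groups.csv"),
                                  show_col_types = FALSE, progress = FALSE),
    composition = readr::read_csv(file.path(dir, "composition.csv"),
                                  show_col_types = FALSE, progress = FALSE),
    rda = readr::read_csv(file.path(dir, "rda.csv"),
                          show_col_types = FALSE, progress = FALSE),
    energy_target = meta$energy_target,
    who_protein_target = meta$who_protein_target)
}
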