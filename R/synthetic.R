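# Seeded synthetic country datasets.
#
# Each archetype mimics the structure of a national FBDG dataset: food-group
# recommendations, group->commodity composition fractions, nutrient
# densities, GWP20 emission factors and PPP-adjusted producer prices.  The
# archetype means encode the empirical orderings real tables show (ruminant
# emission factors far above poultry/fish/plant; B12 and EPA/DHA confined to
# animal and marine foods) and each generated dataset is calibrated so its
# FBDG protein totals equal the archetype's (total, animal) protein pair.

ARCHETYPES <- c("us_like", "cn_like", "au_like", "nz_like")

# (total, animal) FBDG protein targets in g/person/day per archetype.
ARCHETYPE_PROTEIN <- list(
  us_like = c(total = 85, animal = 45),
  cn_like = c(total = 87, animal = 36),
  au_like = c(total = 85, animal = 43),
  nz_like = c(total = 88, animal = 43))

# Mean nutrient densities per 100 g, emission factor (kg CO2e/kg, GWP20) and
# producer price ($/kg).  Values are representative magnitudes for the
# commodity class, not any national database.
commodity_means <- function() {
  tibble::tribble(
    ~commodity_id, ~name,            ~category,       ~subcategory,
    ~protein, ~vitamin_a, ~vitamin_b12, ~ala,  ~epa,  ~dha,  ~energy, ~emission_factor, ~producer_price,
    "beef",       "Beef",            "beef",          "ruminant_meat",
    26,       15,        2.5,          0.03,  0.005, 0.001, 250,     95,               4.5,
    "sheep_goat", "Sheep & goat",    "other_asf",     "ruminant_meat",
    25,       10,        2.6,          0.05,  0.010, 0.005, 260,     85,               5.5,
    "pork",       "Pork",            "pork",          "monogastric_meat",
    25,       5,         0.7,          0.05,  0.005, 0.002, 242,     12,               1.8,
    "chicken",    "Chicken",         "poultry",       "monogastric_meat",
    27,       16,        0.4,          0.05,  0.010, 0.020, 239,     6,                1.5,
    "turkey",     "Turkey",          "poultry",       "monogastric_meat",
    28,       8,         1.0,          0.04,  0.010, 0.020, 190,     7,                2.0,
    "finfish",    "Finfish",         "fish",          "seafood",
    22,       30,        3.0,          0.05,  0.70,  1.10,  140,     5.5,              3.0,
    "shellfish",  "Shellfish",       "aquatic_other", "seafood",
    20,       25,        9.0,          0.02,  0.30,  0.25,  100,     7,                6.0,
    "milk",       "Milk",            "dairy",         "eggs_dairy",
    3.4,      46,        0.45,         0.01,  0.00,  0.00,  61,      4.2,              0.45,
    "cheese",     "Cheese",          "dairy",         "eggs_dairy",
    24,       260,       1.1,          0.10,  0.00,  0.00,  390,     28,               4.0,
    "eggs",       "Eggs",            "eggs",          "eggs_dairy",
    13,       160,       1.1,          0.10,  0.00,  0.06,  143,     4.8,              1.3,
    "grains",     "Grains",          "plant_group",   "plant_staple",
    10,       0,         0,            0.05,  0,     0,     350,     1.4,              0.30,
    "legumes_nuts", "Legumes & nuts", "plant_group",  "plant_protein_fat",
    20,       2,         0,            1.20,  0,     0,     340,     0.9,              0.90,
    "vegetables", "Vegetables",      "plant_group",   "plant_produce",
    2,        180,       0,            0.05,  0,     0,     35,      0.5,              0.50,
    "fruits",     "Fruits",          "plant_group",   "plant_produce",
    0.8,      20,        0,            0.02,  0,     0,     60,      0.4,              0.80,
    "oils",       "Vegetable oils",  "plant_group",   "plant_protein_fat",
    0,        0,         0,            7.0,   0,     0,     884,     3.0,              1.20,
    "tubers",     "Tubers",          "plant_group",   "plant_staple",
    2,        1,         0,            0.01,  0,     0,     77,      0.3,              0.35,
    "whole_grains", "Whole grains",  "plant_group",   "plant_staple",
    12,       0,         0,            0.08,  0,     0,     340,     1.2,              0.40,
    "nuts_seeds", "Nuts & seeds",    "plant_group",   "plant_protein_fat",
    20,       1,         0,            2.5,   0,     0,     600,     0.7,              2.5,
    "leafy_greens", "Leafy greens",  "plant_group",   "plant_produce",
    3,        240,       0,            0.15,  0,     0,     25,      0.4,              0.70,
    "berries",    "Berries",         "plant_group",   "plant_produce",
    1,        5,         0,            0.05,  0,     0,     50,      0.6,              1.50)
}

# Plant commodities in the order they are added as n_plant_commodities grows.
# grains and legumes_nuts come first: they back the energy/protein
# gap-filling degrees of freedom of the scenario engine.
PLANT_ORDER <- c("grains", "legumes_nuts", "vegetables", "fruits", "oils",
                 "tubers", "whole_grains", "nuts_seeds", "leafy_greens",
                 "berries")

# Archetype FBDG shape: pre-calibration group recommendations (g/day) and
# within-group commodity fractions, reflecting the dominant livestock mix of
# each archetype (beef/poultry heavy, pork/aquaculture heavy, ruminant/dairy
# heavy, dairy/sheep heavy).
archetype_shape <- function(archetype) {
  shapes <- list(
    us_like = list(
      asf = c(red_meat = 48, poultry = 55, seafood = 22, dairy = 230, eggs = 31),
      red_meat = c(beef = 0.55, pork = 0.40, sheep_goat = 0.05),
      poultry = c(chicken = 0.85, turkey = 0.15),
      seafood = c(finfish = 0.80, shellfish = 0.20),
      dairy = c(milk = 0.85, cheese = 0.15),
      plants = c(grains = 280, legumes_nuts = 60, vegetables = 350,
                 fruits = 250, oils = 35, tubers = 80, whole_grains = 90,
                 nuts_seeds = 20, leafy_greens = 40, berries = 30)),
    cn_like = list(
      asf = c(red_meat = 45, poultry = 30, seafood = 55, dairy = 140, eggs = 20),
      red_meat = c(beef = 0.20, pork = 0.75, sheep_goat = 0.05),
      poultry = c(chicken = 0.90, turkey = 0.10),
      seafood = c(finfish = 0.70, shellfish = 0.30),
      dairy = c(milk = 0.95, cheese = 0.05),
      plants = c(grains = 350, legumes_nuts = 80, vegetables = 450,
                 fruits = 200, oils = 30, tubers = 90, whole_grains = 60,
                 nuts_seeds = 25, leafy_greens = 60, berries = 15)),
    au_like = list(
      asf = c(red_meat = 55, poultry = 45, seafood = 22, dairy = 220, eggs = 40),
      red_meat = c(beef = 0.60, pork = 0.15, sheep_goat = 0.25),
      poultry = c(chicken = 0.88, turkey = 0.12),
      seafood = c(finfish = 0.85, shellfish = 0.15),
      dairy = c(milk = 0.82, cheese = 0.18),
      plants = c(grains = 270, legumes_nuts = 55, vegetables = 340,
                 fruits = 260, oils = 35, tubers = 75, whole_grains = 85,
                 nuts_seeds = 25, leafy_greens = 35, berries = 30)),
    nz_like = list(
      asf = c(red_meat = 52, poultry = 40, seafood = 25, dairy = 300, eggs = 36),
      red_meat = c(beef = 0.50, pork = 0.20, sheep_goat = 0.30),
      poultry = c(chicken = 0.90, turkey = 0.10),
      seafood = c(finfish = 0.85, shellfish = 0.15),
      dairy = c(milk = 0.85, cheese = 0.15),
      plants = c(grains = 275, legumes_nuts = 55, vegetables = 330,
                 fruits = 255, oils = 30, tubers = 85, whole_grains = 80,
                 nuts_seeds = 20, leafy_greens = 40, berries = 25)))
  shapes[[archetype]]
}

#' Configuration for the synthetic country generator
#'
#' @param seed Integer seed; a fixed seed yields byte-identical tables.
#' @param archetype One of `"us_like"`, `"cn_like"`, `"au_like"`,
#'   `"nz_like"`.
#' @param n_plant_commodities Number of aggregate plant groups forming the
#'   fixed plant background (4-10).
#' @param missingness_rate Fraction of maskable nutrient cells set missing
#'   (in `[0, 1)`); protein and energy are never masked.
#' @param noise_scale Log-normal dispersion of nutrient densities, emission
#'   factors and prices around the archetype means (mean-preserving).
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L, archetype = "us_like",
                             n_plant_commodities = 6L,
                             missingness_rate = 0, noise_scale = 0.05) {
  if (!archetype %in% ARCHETYPES) {
    abort(paste0("invalid archetype '", archetype, "'; must be one of: ",
                 paste(ARCHETYPES, collapse = ", ")))
  }
  if (missingness_rate < 0 || missingness_rate >= 1) {
    abort("missingness_rate must be in [0, 1)")
  }
  if (n_plant_commodities < 4 || n_plant_commodities > 10) {
    abort("n_plant_commodities must be between 4 and 10")
  }
  structure(
    list(seed = as.integer(seed), archetype = archetype,
         n_plant_commodities = as.integer(n_plant_commodities),
         missingness_rate = missingness_rate, noise_scale = noise_scale),
    class = "generator_config")
}

#' Generate a seeded synthetic country dataset
#'
#' Draws nutrient densities, emission factors and producer prices from
#' mean-preserving log-normal distributions around the archetype means, then
#' calibrates the FBDG group recommendations so that the translated diet's
#' total and animal FBDG protein exactly equal the archetype's reference
#' pair (us_like 85/45, cn_like 87/36, au_like 85/43, nz_like 88/43 g/day).
#' The profile's energy target is the calibrated diet's own energy content
#' (the isocaloric reference level).
#'
#' @param config A [generator_config()].
#' @return A list with elements `profile` (a [country_profile()]) and
#'   `commodities` (a commodity tibble, containing `NA` cells when
#'   `missingness_rate > 0`).
#' @export
generate_country_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  shape <- archetype_shape(config$archetype)
  plant_ids <- PLANT_ORDER[seq_len(config$n_plant_commodities)]
  means <- commodity_means()
  keep <- means$category != "plant_group" | means$commodity_id %in% plant_ids
  means <- means[keep, ]

  withr::with_seed(config$seed, {
    commodities <- perturb_lognormal(means, config$noise_scale)

    # Assemble pre-calibration group recommendations + composition.
    plant_grams <- shape$plants[plant_ids]
    fbdg_groups <- tibble::tibble(
      group_id = c(names(shape$asf), names(plant_grams)),
      grams = c(unname(shape$asf), unname(plant_grams)))
    comp_asf <- purrr::map_dfr(
      c("red_meat", "poultry", "seafood", "dairy"),
      function(g) tibble::tibble(group_id = g,
                                 commodity_id = names(shape[[g]]),
                                 fraction = unname(shape[[g]])))
    comp_rest <- tibble::tibble(
      group_id = c("eggs", names(plant_grams)),
      commodity_id = c("eggs", names(plant_grams)),
      fraction = 1)
    composition <- dplyr::bind_rows(comp_asf, comp_rest)

    # Calibrate group grams so FBDG protein totals hit the archetype pair.
    targets <- ARCHETYPE_PROTEIN[[config$archetype]]
    prot <- setNames(commodities$protein, commodities$commodity_id)
    grams_by_commodity <- composition |>
      dplyr::inner_join(fbdg_groups, by = "group_id") |>
      dplyr::mutate(grams = .data$grams * .data$fraction,
                    is_animal = !.data$commodity_id %in% plant_ids)
    # Eggs keep their archetype intake (they carry the characteristic
    # overconsumption relative to the EAT-Lancet point target); the other
    # animal groups absorb the protein calibration uniformly.
    protein_of <- function(rows) sum(rows$grams * prot[rows$commodity_id] / 100)
    eggs0 <- protein_of(grams_by_commodity[grams_by_commodity$group_id == "eggs", ])
    rest <- grams_by_commodity$is_animal & grams_by_commodity$group_id != "eggs"
    animal0 <- protein_of(grams_by_commodity[rest, ])
    plant0 <- protein_of(grams_by_commodity[!grams_by_commodity$is_animal, ])
    f_animal <- (targets[["animal"]] - eggs0) / animal0
    f_plant <- (targets[["total"]] - targets[["animal"]]) / plant0
    scaled_groups <- c("red_meat", "poultry", "seafood", "dairy")
    fbdg_groups <- fbdg_groups |>
      dplyr::mutate(grams = .data$grams * dplyr::case_when(
        .data$group_id %in% scaled_groups ~ f_animal,
        .data$group_id == "eggs" ~ 1,
        TRUE ~ f_plant))

    rda <- tibble::tibble(
      nutrient = c("protein", "vitamin_a", "vitamin_b12", "ala", "epa", "dha"),
      rda = c(60, 800, 2.4, 1.6, 0.10, 0.15))

    profile <- country_profile(
      country_id = config$archetype,
      fbdg_groups = fbdg_groups,
      composition = composition,
      rda = rda,
      energy_target = 1)  # placeholder, set from the calibrated diet below
    diet <- allocate_groups(profile)
    profile$energy_target <-
      sum(diet$grams * prot_col(commodities, "energy", diet$commodity_id) / 100)

    if (config$missingness_rate > 0) {
      commodities <- inject_missing_nutrients(
        commodities, config$missingness_rate,
        seed = sample.int(.Machine$integer.max, 1))
    }
    validate_commodities(commodities)
    list(profile = profile, commodities = commodities)
  })
}

# Mean-preserving log-normal jitter of the positive numeric columns; zero
# means stay exactly zero (structural zeros such as plant B12).
perturb_lognormal <- function(means, noise_scale) {
  cols <- c(NUTRIENTS, "emission_factor", "producer_price")
  out <- means
  if (noise_scale <= 0) return(out)
  s <- noise_scale
  for (col in cols) {
    v <- out[[col]]
    jitter <- rlnorm(length(v), meanlog = -s^2 / 2, sdlog = s)
    out[[col]] <- ifelse(v > 0, v * jitter, v)
  }
  out
}

# Look up a nutrient column for a vector of commodity ids.
prot_col <- function(commodities, col, ids) {
  setNames(commodities[[col]], commodities$commodity_id)[ids]
}

#' Mask nutrient cells at random
#'
#' Sets maskable nutrient cells (`vitamin_a`, `vitamin_b12`, `ala`, `epa`,
#' `dha`) to `NA` independently with probability `rate`, emulating
#' commodity-level gaps in real composition tables.  `protein` and `energy`
#' are needed by every scenario and are never masked.
#'
#' @param commodities A commodity tibble.
#' @param rate Masking probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The commodity tibble with `NA` holes.
#' @export
inject_missing_nutrients <- function(commodities, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) abort("rate must be in [0, 1)")
  if (rate == 0) return(commodities)
  withr::with_seed(seed, {
    for (col in MASKABLE_NUTRIENTS) {
      orig <- commodities[[col]]
      mask <- rbinom(nrow(commodities), 1, rate) == 1
      commodities[[col]][mask] <- NA_real_
      # keep at least one imputation donor per subcategory: a fully masked
      # (subcategory, nutrient) cell block gets one value restored
      for (sc in unique(commodities$subcategory[mask])) {
        rows <- which(commodities$subcategory == sc)
        if (all(is.na(commodities[[col]][rows]))) {
          r <- rows[sample.int(length(rows), 1)]
          commodities[[col]][r] <- orig[r]
        }
      }
    }
  })
  commodities
}

#' Write / read a generated country dataset
#'
#' The dataset is stored as a directory holding the commodity CSV and the
#' profile tables; see [write_country_profile()].
#'
#' @param dataset A list with `profile` and `commodities`, as returned by
#'   [generate_country_dataset()].
#' @param dir Directory path.
#' @return `read_country_dataset()` returns the dataset list;
#'   `write_country_dataset()` returns `dir` invisibly.
#' @export
write_country_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_commodities(dataset$commodities, file.path(dir, "commodities.csv"))
  write_country_profile(dataset$profile, dir)
  invisible(dir)
}

#' @rdname write_country_dataset
#' @export
read_country_dataset <- function(dir) {
  list(profile = read_country_profile(dir),
       commodities = read_commodities(file.path(dir, "commodities.csv")))
}
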