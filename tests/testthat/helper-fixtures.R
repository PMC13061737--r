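# Small in-code fixtures shared across the suite.

# A minimal complete commodity table: two ASF items and two plant groups.
toy_commodities <- function() {
  tibble::tribble(
    ~commodity_id, ~name,      ~category,     ~subcategory,
    ~protein, ~vitamin_a, ~vitamin_b12, ~ala, ~epa, ~dha, ~energy,
    ~emission_factor, ~producer_price,
    "beef",    "Beef",    "beef",        "meat",
    26,  15, 2.5, 0.03, 0.005, 0.001, 250, 100, 3,
    "chicken", "Chicken", "poultry",     "meat",
    27,  16, 0.4, 0.05, 0.010, 0.020, 239, 4,   2,
    "grains",  "Grains",  "plant_group", "plant",
    10,  0,  0,   0.05, 0,     0,     350, 1.4, 0.3,
    "beans",   "Beans",   "plant_group", "plant",
    20,  2,  0,   1.2,  0,     0,     340, 0.9, 0.9)
}

toy_diet <- function(beef = 100, chicken = 150, grains = 300, beans = 80) {
  tibble::tibble(
    commodity_id = c("beef", "chicken", "grains", "beans"),
    grams = c(beef, chicken, grains, beans),
    group_id = c("meat", "meat", "plants", "plants"))
}

toy_rda <- function() {
  tibble::tibble(nutrient = c("protein", "vitamin_a", "vitamin_b12",
                              "ala", "epa", "dha"),
                 rda = c(60, 800, 2.4, 1.6, 0.10, 0.15))
}

# A tiny, fully valid country profile over the toy commodities.
toy_profile <- function(meat = 250, plants = 380) {
  country_profile(
    country_id = "toyland",
    fbdg_groups = tibble::tibble(group_id = c("meat", "plants"),
                                 grams = c(meat, plants)),
    composition = tibble::tibble(
      group_id = c("meat", "meat", "plants", "plants"),
      commodity_id = c("beef", "chicken", "grains", "beans"),
      fraction = c(0.4, 0.6, 0.8, 0.2)),
    rda = toy_rda(),
    energy_target = 2000)
}

# Random valid profile over the toy commodities (used in property tests).
random_profile <- function(seed) {
  withr::with_seed(seed, {
    f_meat <- runif(1, 0.1, 0.9)
    f_plant <- runif(1, 0.1, 0.9)
    country_profile(
      country_id = paste0("rand", seed),
      fbdg_groups = tibble::tibble(group_id = c("meat", "plants"),
                                   grams = runif(2, 0, 500)),
      composition = tibble::tibble(
        group_id = c("meat", "meat", "plants", "plants"),
        commodity_id = c("beef", "chicken", "grains", "beans"),
        fraction = c(f_meat, 1 - f_meat, f_plant, 1 - f_plant)),
      rda = toy_rda(),
      energy_target = runif(1, 1500, 2500))
  })
}

# 2-commodity toy evaluator (beef vs chicken intakes, B12 nutrition axis)
# used by the optimizer oracle tests: cost/emissions linear, nutrition the
# capped B12 adequacy ratio.
toy_evaluate <- function(Q) {
  prices <- c(3, 2); efs <- c(100, 4); b12 <- c(2.5, 0.4); rda_b12 <- 2.4
  tibble::tibble(
    cost = as.numeric(Q %*% prices) / 1000,
    emissions = as.numeric(Q %*% efs) / 1000,
    nutrition = pmin(as.numeric(Q %*% b12) / 100 / rda_b12, 1),
    penalty = 0,
    violation = 0)
}

# Independent scalar-path recomputation of a completed candidate's totals:
# category intakes evaluated with an explicit loop over the coefficient
# rows, and the adjusted plant background evaluated through the
# commodity-level diet functions.
manual_completion_totals <- function(q, model, cons, ev) {
  plant <- model$plant_diet
  adj <- setNames(c(ev$legume_adjust, ev$grain_adjust),
                  model$filler_ids[c("protein", "energy")])
  for (id in names(adj)) {
    plant$grams[plant$commodity_id == id] <-
      plant$grams[plant$commodity_id == id] + adj[[id]]
  }
  rda <- tibble::tibble(nutrient = c("protein", "energy"), rda = c(60, 2000))
  plant_adq <- nutrient_adequacy(plant, model$commodities, rda)
  protein <- plant_adq$supply[plant_adq$nutrient == "protein"]
  energy <- plant_adq$supply[plant_adq$nutrient == "energy"]
  cost <- dietary_cost(plant, model$commodities)
  for (i in seq_along(q)) {
    cc <- rownames(model$coef)[i]
    protein <- protein + q[i] * model$coef[cc, "protein"] / 100
    energy <- energy + q[i] * model$coef[cc, "energy"] / 100
    cost <- cost + q[i] * model$coef[cc, "producer_price"] / 1000
  }
  list(protein = protein, energy = energy, cost = cost)
}
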