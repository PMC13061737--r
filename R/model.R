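# Diet model: the linear map from an 8-dimensional ASF category intake
# vector to cost, emissions and nutrient supplies, with the fixed plant
# background and the two-degree-of-freedom plant adjustment that keeps each
# candidate at the scenario protein level and the FBDG energy level.
#
# Category coefficients are baseline-share-weighted means of the member
# commodities (the optimizer reallocates mass between categories; within a
# category the commodity mix stays at its guideline proportions).

#' Build a diet model for scenario evaluation
#'
#' @param profile A [country_profile()].
#' @param commodities A complete (imputed) commodity tibble.
#' @return A `diet_model` holding the per-category coefficient matrix, the
#'   fixed plant background, the plant gap-filling coefficients and the
#'   baseline ASF intakes.
#' @export
build_diet_model <- function(profile, commodities) {
  validate_commodities(commodities, allow_missing = FALSE)
  diet <- allocate_groups(profile)
  cat_of <- prot_col(commodities, "category", diet$commodity_id)
  coef_cols <- c(NUTRIENTS, "emission_factor", "producer_price")

  # Per-category coefficient rows, weighted by baseline commodity grams
  # (equal weights for a category absent from the baseline).
  coef_mat <- matrix(0, length(ASF_CATEGORIES), length(coef_cols),
                     dimnames = list(ASF_CATEGORIES, coef_cols))
  for (cc in ASF_CATEGORIES) {
    members <- commodities[commodities$category == cc, ]
    if (nrow(members) == 0) next
    w <- diet$grams[match(members$commodity_id, diet$commodity_id)]
    w[is.na(w)] <- 0
    if (sum(w) <= 0) w <- rep(1, nrow(members))
    w <- w / sum(w)
    coef_mat[cc, ] <- colSums(w * as.matrix(members[, coef_cols]))
  }

  plant <- diet[cat_of == "plant_group", ]
  plant_mat <- as.matrix(
    commodities[match(plant$commodity_id, commodities$commodity_id), coef_cols])
  plant_base <- colSums(plant$grams * plant_mat)  # per-100g / per-kg units

  # Gap-filling degrees of freedom: the protein-dense and energy-dense plant
  # groups (legumes/nuts and grains when present).
  plant_tbl <- commodities[commodities$category == "plant_group", ]
  pick <- function(id, col) {
    if (id %in% plant_tbl$commodity_id) id else plant_tbl$commodity_id[which.max(plant_tbl[[col]])]
  }
  filler_ids <- c(protein = pick("legumes_nuts", "protein"),
                  energy = pick("grains", "energy"))
  filler_mat <- as.matrix(
    commodities[match(filler_ids, commodities$commodity_id), coef_cols])
  rownames(filler_mat) <- names(filler_ids)
  filler_base <- setNames(plant$grams[match(filler_ids, plant$commodity_id)],
                          names(filler_ids))
  filler_base[is.na(filler_base)] <- 0

  structure(
    list(coef = coef_mat,
         plant_base = plant_base,
         plant_diet = plant,
         filler_ids = filler_ids,
         filler = filler_mat,
         filler_base = filler_base,
         baseline_asf = asf_category_intakes(diet, commodities),
         rda = profile$rda,
         commodities = commodities,
         profile = profile),
    class = "diet_model")
}

# Evaluate a matrix of candidate ASF vectors (rows) under a constraint set.
#
# Each candidate is completed by the plant adjustment: solve the 2x2 system
# in (legume delta a, grain delta b) so total protein equals the scenario
# fill target and energy equals the band target; deltas are clipped so the
# filler intakes stay nonnegative and any residual shortfall counts as
# constraint violation.  Returns one row per candidate with raw objectives,
# penalty and aggregate violation.
evaluate_candidates <- function(Q, model, constraints,
                                priority = character(0),
                                penalty_scale = 1) {
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1)
  colnames(Q) <- ASF_CATEGORIES
  n <- nrow(Q)
  cm <- model$coef

  asf_supply <- Q %*% cm[, NUTRIENTS] / 100          # n x nutrients
  asf_cost <- as.numeric(Q %*% cm[, "producer_price"]) / 1000
  asf_emis <- as.numeric(Q %*% cm[, "emission_factor"]) / 1000

  pb <- model$plant_base
  e_target <- constraints$energy_band[["target"]]
  e_tol <- constraints$energy_band[["tol"]]
  p_target <- constraints$fill_target

  fl <- model$filler
  pL <- fl["protein", "protein"] / 100; eL <- fl["protein", "energy"] / 100
  pG <- fl["energy", "protein"] / 100;  eG <- fl["energy", "energy"] / 100
  det <- pL * eG - pG * eL

  dP <- p_target - (asf_supply[, "protein"] + pb[["protein"]] / 100)
  dE <- e_target - (asf_supply[, "energy"] + pb[["energy"]] / 100)
  a <- (dP * eG - dE * pG) / det
  b <- (pL * dE - eL * dP) / det
  # Clip so filler intakes stay nonnegative; re-solve the remaining degree
  # of freedom for energy, then clip again.
  aL <- -model$filler_base[["protein"]]
  bL <- -model$filler_base[["energy"]]
  clip_a <- a < aL
  a[clip_a] <- aL
  b[clip_a] <- (dE[clip_a] - a[clip_a] * eL) / eG
  clip_b <- b < bL
  b[clip_b] <- bL

  adj_supply <- outer(a, fl["protein", NUTRIENTS] / 100) +
    outer(b, fl["energy", NUTRIENTS] / 100)
  supply <- sweep(asf_supply + adj_supply, 2, pb[NUTRIENTS] / 100, "+")
  cost <- asf_cost + pb[["producer_price"]] / 1000 +
    (a * fl["protein", "producer_price"] + b * fl["energy", "producer_price"]) / 1000
  emissions <- asf_emis + pb[["emission_factor"]] / 1000 +
    (a * fl["protein", "emission_factor"] + b * fl["energy", "emission_factor"]) / 1000

  # Adequacy / penalty over the active RDAs.
  act <- constraints$rda_active
  ratios <- sweep(supply[, act$nutrient, drop = FALSE], 2, act$rda, "/")
  deficits <- pmax(1 - ratios, 0)                      # RDA-normalized d_j / RDA_j
  penalty <- penalty_scale * rowSums(deficits^2)
  score_nutrients <- if (length(priority) == 0) act$nutrient else priority
  nutrition <- apply(pmin(ratios[, score_nutrients, drop = FALSE], 1), 1, min)

  # Constraint violations (relative magnitudes).
  protein_total <- supply[, "protein"]
  energy_total <- supply[, "energy"]
  v_protein <- pmax(0, abs(protein_total - p_target) / p_target - 1e-9)
  if (!is.na(constraints$protein_cap)) {
    v_protein <- v_protein +
      pmax(0, (protein_total - constraints$protein_cap) / constraints$protein_cap - 1e-9)
  }
  v_energy <- pmax(0, abs(energy_total - e_target) / e_target - e_tol)
  v_bounds <- rowSums(pmax(sweep(Q, 2, constraints$bounds$hi, "-"), 0) +
                        pmax(sweep(-Q, 2, -constraints$bounds$lo, "+"), 0)) /
    max(constraints$bounds$hi, 1)
  v_groups <- 0
  if (nrow(constraints$group_caps) > 0) {
    for (k in seq_len(nrow(constraints$group_caps))) {
      g <- constraints$group_caps$group[k]
      cap <- constraints$group_caps$cap[k]
      tot <- rowSums(Q[, GROUP_CAP_MEMBERS[[g]], drop = FALSE])
      v_groups <- v_groups + pmax(0, (tot - cap) / max(cap, 1))
    }
  }
  violation <- v_protein + v_energy + v_bounds + v_groups

  tibble::tibble(
    cost = as.numeric(cost), emissions = as.numeric(emissions),
    nutrition = as.numeric(nutrition), penalty = as.numeric(penalty),
    violation = as.numeric(violation),
    protein_total = as.numeric(protein_total),
    energy_total = as.numeric(energy_total),
    legume_adjust = as.numeric(a), grain_adjust = as.numeric(b))
}

#' Check feasibility of a candidate ASF intake vector
#'
#' Evaluates one candidate against a constraint set: box bounds, grouped
#' EAT-Lancet caps, isocaloric energy band and protein cap/target (after
#' the automatic plant adjustment).
#'
#' @param Q Numeric 8-vector of ASF category intakes (g/day), in the order
#'   beef, pork, poultry, fish, eggs, dairy, other_asf, aquatic_other.
#' @param constraints A `constraint_set` from [build_constraints()].
#' @param model A `diet_model` from [build_diet_model()].
#' @return List with `feasible` (logical) and `violations` (tibble
#'   `constraint`, `magnitude` for each violated constraint).
#' @export
check_feasible <- function(Q, constraints, model) {
  Q <- setNames(as.numeric(Q), ASF_CATEGORIES)
  ev <- evaluate_candidates(matrix(Q, nrow = 1), model, constraints)
  viol <- list()
  b <- constraints$bounds
  tol <- 1e-9
  for (i in seq_along(ASF_CATEGORIES)) {
    over <- max(Q[i] - b$hi[i], b$lo[i] - Q[i])
    if (over > tol) {
      viol[[length(viol) + 1]] <- tibble::tibble(
        constraint = paste0("bound:", ASF_CATEGORIES[i]), magnitude = over)
    }
  }
  if (nrow(constraints$group_caps) > 0) {
    for (k in seq_len(nrow(constraints$group_caps))) {
      g <- constraints$group_caps$group[k]
      tot <- sum(Q[GROUP_CAP_MEMBERS[[g]]])
      over <- tot - constraints$group_caps$cap[k]
      if (over > tol) {
        viol[[length(viol) + 1]] <- tibble::tibble(
          constraint = paste0("group_cap:", g), magnitude = over)
      }
    }
  }
  e_target <- constraints$energy_band[["target"]]
  e_dev <- abs(ev$energy_total - e_target) / e_target - constraints$energy_band[["tol"]]
  if (e_dev > tol) {
    viol[[length(viol) + 1]] <- tibble::tibble(constraint = "energy_band",
                                               magnitude = e_dev)
  }
  p_dev <- abs(ev$protein_total - constraints$fill_target)
  if (p_dev / constraints$fill_target > 1e-6) {
    viol[[length(viol) + 1]] <- tibble::tibble(constraint = "protein",
                                               magnitude = p_dev)
  }
  violations <- if (length(viol) > 0) dplyr::bind_rows(viol) else
    tibble::tibble(constraint = character(0), magnitude = numeric(0))
  list(feasible = nrow(violations) == 0, violations = violations)
}
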