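test_that("scenario names map bijectively to protein mode and priorities", {
  presets <- scenario_presets()
  expect_length(presets, 6)
  expect_equal(presets$Baseline_FBDG$protein_mode, "fbdg_native")
  expect_equal(presets$MaxProt$protein_mode, "who60")
  expect_equal(presets$MaxVitamins_FBDG$priority_nutrients,
               c("vitamin_a", "vitamin_b12"))
  expect_equal(presets$MaxVitamins_Protein$protein_mode, "who60")
  expect_equal(presets$MaxFattyAcids_FBDG$priority_nutrients, c("epa", "dha"))
  expect_equal(presets$MaxFattyAcids_Protein$priority_nutrients, c("epa", "dha"))
  expect_length(presets$Baseline_FBDG$priority_nutrients, 0)
  expect_length(presets$MaxProt$priority_nutrients, 0)
  expect_true(presets$Baseline_FBDG$pinned && presets$MaxProt$pinned)
  expect_false(presets$MaxVitamins_FBDG$pinned)
  expect_error(scenario_spec("MaxEverything"), "unknown scenario")
})

test_that("constraint compilation maps the reference ranges onto the eight categories", {
  ds <- generate_country_dataset(generator_config(seed = 1, archetype = "us_like"))
  profile <- ds$profile; cm <- ds$commodities

  cons <- build_constraints(scenario_spec("MaxVitamins_FBDG"), profile, cm)
  hi <- setNames(cons$bounds$hi, cons$bounds$category)
  expect_equal(hi[["poultry"]], 58)
  expect_equal(hi[["dairy"]], 500)
  expect_equal(hi[["eggs"]], 25)
  expect_equal(hi[["fish"]], 100)
  expect_true(all(cons$bounds$lo == 0))
  expect_equal(cons$group_caps$cap[cons$group_caps$group == "red_meat"], 28)
  # FBDG-native: cap at the guideline's own protein total, no WHO target
  expect_equal(cons$protein_cap, 85, tolerance = 1e-9)
  expect_true(is.na(cons$protein_target))

  # who60 scenarios target and cap protein at 60 g
  cons60 <- build_constraints(scenario_spec("MaxProt"), profile, cm)
  expect_equal(cons60$protein_target, 60)
  expect_equal(cons60$protein_cap, 60)

  # fatty-acid priority rides with the scenario object, not the constraint set
  expect_equal(scenario_spec("MaxFattyAcids_FBDG")$priority_nutrients,
               c("epa", "dha"))
  cons_fa <- build_constraints(scenario_spec("MaxFattyAcids_FBDG"), profile, cm)
  expect_equal(cons_fa$protein_cap, 85, tolerance = 1e-9)

  # purity: identical inputs give identical constraint sets
  expect_identical(unclass(cons),
                   unclass(build_constraints(scenario_spec("MaxVitamins_FBDG"),
                                             profile, cm)))

  # fish-availability multiplier scales the marine caps
  half <- build_constraints(scenario_spec("MaxVitamins_FBDG"), profile, cm,
                            fish_availability = 0.5)
  expect_equal(half$bounds$hi[half$bounds$category == "fish"], 50)
  expect_equal(half$group_caps$cap[half$group_caps$group == "marine"], 50)
})

test_that("the baseline scenario pins its bounds to the translated guideline diet", {
  ds <- generate_country_dataset(generator_config(seed = 2, archetype = "cn_like"))
  diet <- allocate_groups(ds$profile)
  cons <- build_constraints(scenario_spec("Baseline_FBDG"), ds$profile,
                            ds$commodities)
  expect_equal(cons$bounds$lo, cons$bounds$hi)
  model <- build_diet_model(ds$profile, ds$commodities)
  expect_equal(cons$bounds$hi, unname(model$baseline_asf), tolerance = 1e-9)
  # the pinned point is feasible
  chk <- check_feasible(model$baseline_asf, cons, model)
  expect_true(chk$feasible)
})

test_that("protein scaling is uniform, exact and scale invariant", {
  cm <- toy_commodities()
  diet <- toy_diet()
  total <- sum(diet$grams * setNames(cm$protein, cm$commodity_id)[diet$commodity_id]) / 100
  scaled <- scale_to_protein_target(diet, 60, cm)
  new_total <- sum(scaled$grams * setNames(cm$protein, cm$commodity_id)[scaled$commodity_id]) / 100
  expect_equal(new_total, 60, tolerance = 1e-9)
  expect_equal(scaled$grams, diet$grams * 60 / total, tolerance = 1e-12)

  # 85 g down to the WHO 60 g reference: uniform factor 60/85
  d85 <- tibble::tibble(commodity_id = "beans", grams = 85 / 20 * 100)
  s85 <- scale_to_protein_target(d85, 60, cm)
  expect_equal(s85$grams / d85$grams, 60 / 85, tolerance = 1e-12)

  # target == current: identity
  expect_equal(scale_to_protein_target(diet, total, cm)$grams, diet$grams,
               tolerance = 1e-12)
  # doubling then scaling equals scaling the original
  doubled <- diet; doubled$grams <- 2 * doubled$grams
  expect_equal(scale_to_protein_target(doubled, 60, cm)$grams,
               scale_to_protein_target(diet, 60, cm)$grams, tolerance = 1e-9)
  zero <- tibble::tibble(commodity_id = "grains", grams = 0)
  expect_error(scale_to_protein_target(zero, 60, cm), "no protein")
})

test_that("EAT-Lancet compliance ratios divide intakes by the point targets", {
  cm <- toy_commodities()
  ref <- eat_lancet_reference()
  d <- tibble::tibble(commodity_id = c("beef", "chicken"), grams = c(7, 29))
  r <- eat_lancet_ratio(d, cm, ref)
  expect_equal(r$ratio[r$category == "beef"], 1)
  expect_equal(r$ratio[r$category == "poultry"], 1)
  expect_equal(r$ratio[r$category == "pork"], 0)

  # overconsumption shows as a multiple: 31.2 g eggs vs the 13 g target
  ds <- generate_country_dataset(generator_config(seed = 1))
  eggs <- tibble::tibble(commodity_id = "eggs", grams = 31.2)
  r2 <- eat_lancet_ratio(eggs, ds$commodities, ref)
  expect_equal(r2$ratio[r2$category == "eggs"], 2.4, tolerance = 1e-12)

  # zero target with nonzero intake flags an infinite ratio
  ref0 <- ref
  ref0$points$grams[ref0$points$category == "beef"] <- 0
  r3 <- eat_lancet_ratio(d, cm, ref0)
  expect_true(is.infinite(r3$ratio[r3$category == "beef"]))
  expect_true(r3$flagged[r3$category == "beef"])
})

test_that("feasibility checking agrees with an independent per-constraint recomputation", {
  ds <- generate_country_dataset(generator_config(seed = 3, archetype = "us_like"))
  cm <- ds$commodities
  spec <- scenario_spec("MaxVitamins_Protein")
  cons <- build_constraints(spec, ds$profile, cm)
  model <- build_diet_model(ds$profile, cm)

  # beef above its bound is infeasible with beef named
  q_bad <- setNames(rep(5, 8), c("beef", "pork", "poultry", "fish", "eggs",
                                 "dairy", "other_asf", "aquatic_other"))
  q_bad[["beef"]] <- 40
  chk <- check_feasible(q_bad, cons, model)
  expect_false(chk$feasible)
  expect_true(any(grepl("beef", chk$violations$constraint)))

  # seeded sweep: bound/group-cap verdicts match a brute-force recheck, and
  # the evaluator's protein/energy totals match an independent commodity-level
  # recomputation of the adjusted diet
  withr::with_seed(42, {
    for (i in 1:100) {
      q <- runif(8, 0, 60)
      chk <- check_feasible(q, cons, model)
      viol <- chk$violations$constraint
      hi <- cons$bounds$hi
      over_bounds <- which(q > hi + 1e-9)
      for (j in over_bounds) {
        expect_true(any(grepl(cons$bounds$category[j], viol)))
      }
      red <- q[1] + q[2] + q[7]
      expect_equal(red > 28 + 1e-9, any(grepl("red_meat", viol)))
      marine <- q[4] + q[8]
      expect_equal(marine > 100 + 1e-9, any(grepl("marine", viol)))

      ev <- dietfront:::evaluate_candidates(matrix(q, 1), model, cons)
      manual <- manual_completion_totals(q, model, cons, ev)
      expect_equal(ev$protein_total, manual$protein, tolerance = 1e-9)
      expect_equal(ev$energy_total, manual$energy, tolerance = 1e-9)
      expect_equal(ev$cost, manual$cost, tolerance = 1e-9)
    }
  })
})
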