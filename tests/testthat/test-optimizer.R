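obj_row <- function(cost, emissions, nutrition) {
  c(cost = cost, emissions = emissions, nutrition = nutrition)
}

test_that("dominance is strict-on-one, no-worse-on-all", {
  expect_true(dominates(obj_row(1, 1, 0.9), obj_row(2, 2, 0.5)))
  expect_false(dominates(obj_row(1, 1, 0.9), obj_row(1, 1, 0.9)))
  # genuine trade-off: neither dominates
  expect_false(dominates(obj_row(1, 3, 0.9), obj_row(2, 2, 0.9)))
  expect_false(dominates(obj_row(2, 2, 0.9), obj_row(1, 3, 0.9)))
  # higher nutrition is better
  expect_true(dominates(obj_row(1, 1, 0.9), obj_row(1, 1, 0.5)))
})

test_that("non-dominated sorting recovers fronts against a naive oracle", {
  three <- tibble::tibble(cost = c(1, 2, 3), emissions = c(3, 2, 1),
                          nutrition = c(0.5, 0.5, 0.5))
  expect_equal(non_dominated_sort(three), c(1, 1, 1))

  chain <- tibble::tibble(cost = c(1, 2, 3), emissions = c(1, 2, 3),
                          nutrition = c(0.9, 0.5, 0.1))
  expect_equal(non_dominated_sort(chain), c(1, 2, 3))

  expect_error(non_dominated_sort(tibble::tibble(cost = NA_real_,
                                                 emissions = 1,
                                                 nutrition = 1)), "NA")

  # 50 random points vs explicit O(n^2) peeling
  naive_fronts <- function(obj) {
    rank <- rep(NA_integer_, nrow(obj))
    r <- 0L
    while (anyNA(rank)) {
      r <- r + 1L
      open <- which(is.na(rank))
      front <- open[vapply(open, function(i) {
        !any(vapply(open, function(j) {
          j != i && dominates(obj[j, ], obj[i, ])
        }, logical(1)))
      }, logical(1))]
      rank[front] <- r
    }
    rank
  }
  pts <- withr::with_seed(5, tibble::tibble(
    cost = runif(50), emissions = runif(50), nutrition = runif(50)))
  expect_equal(non_dominated_sort(pts), naive_fronts(pts))
})

test_that("crowding distance marks boundaries infinite and matches hand computation", {
  expect_equal(crowding_distance(tibble::tibble(cost = 1, emissions = 1,
                                                nutrition = 1)), Inf)
  expect_equal(crowding_distance(tibble::tibble(cost = c(1, 2),
                                                emissions = c(2, 1),
                                                nutrition = c(1, 1))),
               c(Inf, Inf))

  # three collinear, equally spaced points varying on one axis
  col3 <- tibble::tibble(cost = c(1, 2, 3), emissions = 1, nutrition = 0.5)
  d3 <- crowding_distance(col3)
  expect_true(is.infinite(d3[1]) && is.infinite(d3[3]))
  expect_true(is.finite(d3[2]))

  # n = 4 on two active axes, checked against the formula by hand:
  # normalized neighbour gaps summed per axis
  f4 <- tibble::tibble(cost = c(0, 1, 3, 6), emissions = c(6, 3, 1, 0),
                       nutrition = 1)
  d4 <- crowding_distance(f4)
  expect_equal(d4[2], (3 - 0) / 6 + (6 - 1) / 6)
  expect_equal(d4[3], (6 - 1) / 6 + (3 - 0) / 6)
  expect_true(all(is.infinite(d4[c(1, 4)])))

  # permutation invariance
  perm <- c(3, 1, 4, 2)
  expect_equal(crowding_distance(f4[perm, ]), d4[perm])
})

test_that("brute-force enumeration returns the exact maximal non-dominated set", {
  Q1 <- matrix(c(10, 10), 1)
  f1 <- brute_force_pareto(Q1, toy_evaluate)
  expect_equal(nrow(f1), 1)

  # dominated point removed: less of both commodities is cheaper, cleaner
  # and (below the B12 cap) no better nourished -- but a nutrition gain
  # protects the bigger point, so test with both at the cap
  Q2 <- rbind(c(300, 0), c(400, 0))  # both reach B12 ratio 1
  f2 <- brute_force_pareto(Q2, toy_evaluate)
  expect_equal(nrow(f2), 1)
  expect_equal(f2$q_1, 300)

  # permutation invariance on a random grid
  Qr <- withr::with_seed(8, matrix(runif(2000, 0, 50), ncol = 2))
  fa <- brute_force_pareto(Qr, toy_evaluate) |> dplyr::arrange(cost)
  fb <- brute_force_pareto(Qr[sample(nrow(Qr)), ], toy_evaluate) |>
    dplyr::arrange(cost)
  expect_equal(tidy(fa), tidy(fb), tolerance = 1e-12)

  expect_error(brute_force_pareto(matrix(0, 2e6, 1), toy_evaluate),
               "too large")
})

test_that("hypervolume matches the analytic box volume for simple fronts", {
  one <- tibble::tibble(cost = 1, emissions = 2, nutrition = 0.5)
  ref <- c(cost = 3, emissions = 4, nutrition = 0)
  # dominated box: (3-1) * (4-2) * (0.5-0)
  expect_equal(hypervolume(one, ref), 2 * 2 * 0.5)

  # adding a dominated point changes nothing
  two <- dplyr::bind_rows(one, tibble::tibble(cost = 2, emissions = 3,
                                              nutrition = 0.25))
  expect_equal(hypervolume(two, ref), 2)

  # two incomparable points: inclusion-exclusion by hand
  pair <- tibble::tibble(cost = c(1, 2), emissions = c(3, 1),
                         nutrition = c(0.5, 0.5))
  # union area in (cost, emissions) at any nutrition slice:
  # (3-1)*(4-3) + (3-2)*(4-1) - overlap handled by staircase = 2*1 + 1*3 - 0
  expect_equal(hypervolume(pair, ref), (2 * 1 + 1 * 2) * 0.5)
})

test_that("the evolutionary search degenerates to the analytic vertex on a linear objective", {
  # emissions-only problem: cost and nutrition constant, so the whole box
  # collapses to the minimum-emission corner (0, 0)
  eval_lin <- function(Q, gen_frac = 0) {
    tibble::tibble(cost = 1, emissions = as.numeric(Q %*% c(100, 4)) / 1000,
                   nutrition = 0.5, penalty = 0, violation = 0)
  }
  front <- withr::with_seed(1, dietfront:::nsga2_core(
    eval_lin, lo = c(0, 0), hi = c(28, 58),
    config = nsga_config(population_size = 40, generations = 40, seed = 1)))
  expect_lt(max(front$emissions), 0.05)
  expect_lt(max(front$q_1), 0.5)
})

test_that("fixed seeds reproduce identical fronts", {
  cfg <- nsga_config(population_size = 30, generations = 15, seed = 99)
  f1 <- dietfront:::nsga2_core(function(Q, g) toy_evaluate(Q),
                               c(0, 0), c(28, 58), cfg)
  f2 <- dietfront:::nsga2_core(function(Q, g) toy_evaluate(Q),
                               c(0, 0), c(28, 58), cfg)
  expect_identical(tidy(f1), tidy(f2))
})

test_that("per-objective bests never worsen across generations (elitism)", {
  cfg <- nsga_config(population_size = 40, generations = 30, seed = 3)
  front <- dietfront:::nsga2_core(function(Q, g) toy_evaluate(Q),
                                  c(0, 0), c(28, 58), cfg)
  h <- attr(front, "history")
  expect_true(all(diff(h$best_cost) <= 1e-12))
  expect_true(all(diff(h$best_emissions) <= 1e-12))
  expect_true(all(diff(-h$best_nutrition) <= 1e-12))
})

test_that("penalty pressure drives the search to the only adequate commodity", {
  # only commodity 1 carries the nutrient; RDA needs >= 40 g of it.
  # penalty > 0 below that level, so every feasible front member keeps
  # commodity 1 at an adequate intake.
  eval_pen <- function(Q, gen_frac = 0) {
    supply <- Q[, 1] * 2.5 / 100           # only q1 supplies it; RDA 1.0
    deficit <- pmax(1 - supply, 0)
    tibble::tibble(cost = as.numeric(Q %*% c(3, 2)) / 1000,
                   emissions = as.numeric(Q %*% c(10, 4)) / 1000,
                   nutrition = pmin(supply, 1),
                   penalty = (1 + gen_frac) * deficit^2,
                   violation = 0)
  }
  front <- withr::with_seed(2, dietfront:::nsga2_core(
    eval_pen, c(0, 0), c(60, 60),
    nsga_config(population_size = 60, generations = 40, seed = 2)))
  adequate <- front[front$penalty <= 1e-9, ]
  expect_gt(nrow(adequate), 0)
  expect_true(all(adequate$q_1 >= 40 - 1e-6))
})

test_that("the search recovers the enumerated front on the two-commodity toy", {
  # beef vs poultry, 1 g grid; genuine three-way trade-off (beef is
  # B12-per-dollar efficient, poultry emission efficient)
  grid <- as.matrix(expand.grid(q_1 = 0:28, q_2 = 0:58))
  oracle <- brute_force_pareto(grid, toy_evaluate)
  cfg <- nsga_config(population_size = 80, generations = 60, seed = 4)
  front <- dietfront:::nsga2_core(function(Q, g) toy_evaluate(Q),
                                  c(0, 0), c(28, 58), cfg)
  ref <- c(cost = max(oracle$cost) * 1.1 + 0.01,
           emissions = max(oracle$emissions) * 1.1 + 0.01,
           nutrition = 0)
  hv_oracle <- hypervolume(oracle, ref)
  hv_front <- hypervolume(front, ref)
  expect_gte(hv_front / hv_oracle, 0.95)

  # every attained point sits within grid resolution of an oracle point
  om <- as.matrix(tidy(oracle)[, c("q_1", "q_2")])
  fm <- as.matrix(tidy(front)[, c("q_1", "q_2")])
  for (i in seq_len(nrow(fm))) {
    d <- pmax(abs(om[, 1] - fm[i, 1]), abs(om[, 2] - fm[i, 2]))
    expect_lte(min(d), 1)
  }
})

test_that("infeasible bounds are rejected before searching", {
  ds <- generate_country_dataset(generator_config(seed = 1))
  spec <- scenario_spec("MaxVitamins_FBDG")
  cons <- build_constraints(spec, ds$profile, ds$commodities)
  model <- build_diet_model(ds$profile, ds$commodities)
  cons$bounds$lo[1] <- cons$bounds$hi[1] + 1
  expect_error(nsga2_optimize(model, cons, spec), "lo > hi")
})

test_that("the knee point is the normalized closest-to-ideal member", {
  f <- tibble::tibble(cost = c(0, 1, 0.2), emissions = c(1, 0, 0.2),
                      nutrition = c(0.5, 0.5, 0.5))
  kp <- knee_point(f)
  expect_equal(kp$cost, 0.2)
  expect_equal(kp$emissions, 0.2)
})
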