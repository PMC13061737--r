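# Penalty-constrained NSGA-II over the ASF decision space, plus the exact
# Pareto machinery (dominance, non-dominated sorting, crowding distance,
# hypervolume) and a brute-force enumeration oracle.
#
# Canonical internal form: an objective matrix with every column minimized.
# The user-facing sense is (cost: min, emissions: min, nutrition: max);
# nutrition is negated on the way in.

OBJECTIVE_SENSE <- c(cost = "min", emissions = "min", nutrition = "max")

# Convert an objectives tibble/matrix to the minimization canonical form,
# folding the penalty in: added to both minimized axes and subtracted
# (RDA-normalized scale) from nutrition before dominance.
canonical_objectives <- function(obj, penalty = NULL) {
  m <- cbind(cost = obj$cost, emissions = obj$emissions,
             nutrition = -obj$nutrition)
  if (!is.null(penalty)) {
    m[, "cost"] <- m[, "cost"] + penalty
    m[, "emissions"] <- m[, "emissions"] + penalty
    m[, "nutrition"] <- m[, "nutrition"] + penalty
  }
  m
}

#' Pareto dominance between two objective vectors
#'
#' `a` dominates `b` iff `a` is no worse on every axis and strictly better
#' on at least one, under the sense (cost: minimize, emissions: minimize,
#' nutrition: maximize).
#'
#' @param a,b Numeric vectors with elements `cost`, `emissions`,
#'   `nutrition`.
#' @return Logical.
#' @export
dominates <- function(a, b) {
  ca <- c(a[["cost"]], a[["emissions"]], -a[["nutrition"]])
  cb <- c(b[["cost"]], b[["emissions"]], -b[["nutrition"]])
  all(ca <= cb) && any(ca < cb)
}

# Pairwise dominance matrix for a canonical (minimized) objective matrix:
# D[i, j] TRUE iff row i dominates row j.  O(n^2 m), vectorized per pair
# block via matrix comparisons.
dominance_matrix <- function(m) {
  n <- nrow(m)
  leq <- matrix(TRUE, n, n)
  lt <- matrix(FALSE, n, n)
  for (k in seq_len(ncol(m))) {
    dk <- outer(m[, k], m[, k], "-")
    leq <- leq & (dk <= 0)
    lt <- lt | (dk < 0)
  }
  leq & lt
}

#' Fast non-dominated sorting
#'
#' Partitions a set of evaluated points into dominance fronts: front 1 is
#' the maximal non-dominated set; front k is non-dominated once fronts
#' `< k` are removed.
#'
#' @param objectives A data frame / tibble with columns `cost`,
#'   `emissions`, `nutrition` (NAs are an error).
#' @return Integer vector of front ranks (1-based), one per row.
#' @export
non_dominated_sort <- function(objectives) {
  m <- canonical_objectives(objectives)
  if (anyNA(m)) abort("unevaluated individual: objectives contain NA")
  n <- nrow(m)
  D <- dominance_matrix(m)
  n_dominators <- colSums(D)
  rank <- integer(n)
  current <- which(n_dominators == 0)
  r <- 0L
  while (length(current) > 0) {
    r <- r + 1L
    rank[current] <- r
    n_dominators[current] <- -1L
    n_dominators <- n_dominators - colSums(D[current, , drop = FALSE])
    current <- which(n_dominators == 0)
  }
  rank
}

#' Crowding distance within one front
#'
#' Per objective, boundary points get infinite distance; interior points
#' accumulate the normalized gap between their neighbours.  Invariant to
#' the order of the input rows.
#'
#' @param objectives Objective rows of a single front (`cost`, `emissions`,
#'   `nutrition`).
#' @return Numeric vector of crowding distances.
#' @export
crowding_distance <- function(objectives) {
  m <- canonical_objectives(objectives)
  n <- nrow(m)
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (k in seq_len(ncol(m))) {
    o <- order(m[, k])
    span <- m[o[n], k] - m[o[1], k]
    if (span <= 0) next  # axis carries no information; skip it
    d[o[c(1, n)]] <- Inf
    d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
      (m[o[3:n], k] - m[o[1:(n - 2)], k]) / span
  }
  d
}

#' NSGA-II search configuration
#'
#' Defaults follow the standard configuration for this problem class:
#' population 200, 100 generations, crossover probability 0.7, mutation
#' probability 0.2, simulated binary crossover (eta 15) and polynomial
#' mutation (eta 20).
#'
#' @param population_size Even population size.
#' @param generations Number of generations.
#' @param crossover_prob Per-pair SBX probability.
#' @param mutation_prob Per-variable polynomial-mutation probability.
#' @param eta_crossover,eta_mutation Distribution indices.
#' @param penalty_scale Base quadratic-penalty coefficient; the effective
#'   scale ramps linearly with generation, `penalty_scale * (1 + g/G)`
#'   (adaptive penalty).
#' @param seed Integer seed; fixed seed gives identical fronts.
#' @return An `nsga_config` list.
#' @export
nsga_config <- function(population_size = 200, generations = 100,
                        crossover_prob = 0.7, mutation_prob = 0.2,
                        eta_crossover = 15, eta_mutation = 20,
                        penalty_scale = 1, seed = 1L) {
  stopifnot(population_size > 0, generations > 0,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 eta_crossover = eta_crossover,
                 eta_mutation = eta_mutation,
                 penalty_scale = penalty_scale,
                 seed = as.integer(seed)),
            class = "nsga_config")
}

# Simulated binary crossover on a pair of parent matrices, clipped to
# bounds.
sbx_crossover <- function(P1, P2, lo, hi, prob, eta) {
  n <- nrow(P1); d <- ncol(P1)
  do_cx <- runif(n) < prob
  u <- matrix(runif(n * d), n, d)
  beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta + 1)))
  beta[!do_cx, ] <- 1
  C1 <- 0.5 * ((1 + beta) * P1 + (1 - beta) * P2)
  C2 <- 0.5 * ((1 - beta) * P1 + (1 + beta) * P2)
  list(clip_bounds(C1, lo, hi), clip_bounds(C2, lo, hi))
}

# Polynomial mutation, per-variable probability, clipped to bounds.
poly_mutation <- function(C, lo, hi, prob, eta) {
  n <- nrow(C); d <- ncol(C)
  span <- matrix(hi - lo, n, d, byrow = TRUE)
  do_mut <- matrix(runif(n * d) < prob, n, d) & span > 0
  u <- matrix(runif(n * d), n, d)
  delta <- ifelse(u < 0.5, (2 * u)^(1 / (eta + 1)) - 1,
                  1 - (2 * (1 - u))^(1 / (eta + 1)))
  C[do_mut] <- C[do_mut] + (delta * span)[do_mut]
  clip_bounds(C, lo, hi)
}

clip_bounds <- function(M, lo, hi) {
  M <- pmax(M, matrix(lo, nrow(M), length(lo), byrow = TRUE))
  pmin(M, matrix(hi, nrow(M), length(hi), byrow = TRUE))
}

# Feasibility-first binary tournament over indices: a feasible candidate
# beats an infeasible one; two infeasible compare on violation; two
# feasible compare on rank then crowding.
tournament_select <- function(n_pick, rank, crowd, violation) {
  i <- sample.int(length(rank), n_pick, replace = TRUE)
  j <- sample.int(length(rank), n_pick, replace = TRUE)
  feas_i <- violation[i] <= 0; feas_j <- violation[j] <= 0
  pick_i <- (feas_i & !feas_j) |
    (!feas_i & !feas_j & violation[i] < violation[j]) |
    (feas_i & feas_j & (rank[i] < rank[j] |
                          (rank[i] == rank[j] & crowd[i] > crowd[j])))
  ifelse(pick_i, i, j)
}

#' Run the penalty-constrained NSGA-II search
#'
#' Real-coded NSGA-II over the box defined by `constraints$bounds`:
#' Latin-hypercube initialization seeded to include the baseline guideline
#' point, simulated binary crossover and polynomial mutation,
#' feasibility-first binary tournaments, and elitist (mu + lambda)
#' environmental selection by dominance rank and crowding distance.  The
#' quadratic nutrient penalty (ramped linearly over generations) is added
#' to both minimized axes and subtracted from nutrition before dominance.
#'
#' @param model A `diet_model` from [build_diet_model()].
#' @param constraints A `constraint_set` from [build_constraints()].
#' @param spec The [scenario_spec()] (supplies the priority nutrients).
#' @param config An [nsga_config()].
#' @return A `pareto_front`: tibble of non-dominated candidates with the
#'   eight ASF intakes, raw `cost`, `emissions`, `nutrition`, `penalty` and
#'   `violation` columns; attributes carry the config, the per-generation
#'   history (best single objectives and front hypervolume) and the
#'   scenario name.
#' @export
nsga2_optimize <- function(model, constraints, spec, config = nsga_config()) {
  lo <- constraints$bounds$lo
  hi <- constraints$bounds$hi
  if (any(lo > hi)) abort("infeasible bounds: lo > hi")
  evaluate <- function(Q, gen_frac) {
    evaluate_candidates(Q, model, constraints,
                        priority = spec$priority_nutrients,
                        penalty_scale = config$penalty_scale * (1 + gen_frac))
  }
  front <- nsga2_core(evaluate, lo, hi, config,
                      seed_points = clip_bounds(matrix(model$baseline_asf, 1),
                                                lo, hi))
  attr(front, "scenario") <- spec$name
  front
}

# Generic NSGA-II engine: evaluate(Q, gen_frac) must return a tibble with
# cost, emissions, nutrition, penalty, violation rows matching Q; its
# penalty column is expected to scale linearly with (1 + gen_frac) (the
# adaptive ramp), which the archive divides back out to compare candidates
# from different generations on a common footing.
#
# Alongside the evolving population, a bounded external archive keeps the
# best feasible non-dominated candidates seen in any generation; the
# returned front is the archive (the population's feasible front when the
# archive is empty), so attained quality never degrades across
# generations.
nsga2_core <- function(evaluate, lo, hi, config, seed_points = NULL,
                       archive_cap = 800L) {
  d <- length(lo)
  N <- config$population_size
  G <- config$generations
  span <- hi - lo
  withr::with_seed(config$seed, {
  Q <- lhs::randomLHS(N, d) * matrix(span, N, d, byrow = TRUE) +
    matrix(lo, N, d, byrow = TRUE)
  if (!is.null(seed_points)) {
    k <- min(nrow(seed_points), N)
    Q[seq_len(k), ] <- seed_points[seq_len(k), , drop = FALSE]
  }
  ev <- evaluate(Q, 0)
  history <- vector("list", G)
  arch_Q <- matrix(numeric(0), 0, d)
  arch_ev <- ev[0, ]
  arch_pen <- numeric(0)

  update_archive <- function(Qm, evm, gen_frac) {
    feas <- which(evm$violation <= 0)
    if (length(feas) == 0) return(invisible(NULL))
    aQ <- rbind(arch_Q, Qm[feas, , drop = FALSE])
    aev <- dplyr::bind_rows(arch_ev, evm[feas, ])
    apen <- c(arch_pen, evm$penalty[feas] / (1 + gen_frac))
    m <- canonical_objectives(aev, apen)
    keep <- !apply(dominance_matrix(m), 2, any) & !duplicated(round(m, 12))
    aQ <- aQ[keep, , drop = FALSE]
    aev <- aev[keep, ]
    apen <- apen[keep]
    if (nrow(aQ) > archive_cap) {
      crowd <- crowding_distance_canonical(canonical_objectives(aev, apen))
      top <- order(crowd, decreasing = TRUE)[seq_len(archive_cap)]
      top <- sort(top)
      aQ <- aQ[top, , drop = FALSE]
      aev <- aev[top, ]
      apen <- apen[top]
    }
    arch_Q <<- aQ; arch_ev <<- aev; arch_pen <<- apen
    invisible(NULL)
  }
  update_archive(Q, ev, 0)

  for (g in seq_len(G)) {
    pen <- canonical_objectives(ev, ev$penalty)
    rank <- non_dominated_sort_canonical(pen)
    crowd <- crowding_by_front(pen, rank)
    parents <- tournament_select(N, rank, crowd, ev$violation)
    pairs1 <- parents[seq(1, N, by = 2)]
    pairs2 <- parents[seq(2, N, by = 2)]
    kids <- sbx_crossover(Q[pairs1, , drop = FALSE], Q[pairs2, , drop = FALSE],
                          lo, hi, config$crossover_prob, config$eta_crossover)
    C <- rbind(kids[[1]], kids[[2]])
    C <- poly_mutation(C, lo, hi, config$mutation_prob, config$eta_mutation)
    ev_c <- evaluate(C, g / G)

    Q_all <- rbind(Q, C)
    ev_all <- dplyr::bind_rows(ev, ev_c)
    pen_all <- canonical_objectives(ev_all, ev_all$penalty)
    rank_all <- non_dominated_sort_canonical(pen_all)
    crowd_all <- crowding_by_front(pen_all, rank_all)
    # Feasibility-first elitist truncation: feasible before infeasible
    # (by violation), then rank, then crowding.
    ord <- order(ev_all$violation > 0, ev_all$violation, rank_all, -crowd_all)
    keep <- ord[seq_len(N)]
    Q <- Q_all[keep, , drop = FALSE]
    ev <- ev_all[keep, ]
    update_archive(Q, ev, g / G)

    if (nrow(arch_ev) > 0) {
      history[[g]] <- tibble::tibble(
        generation = g,
        best_cost = min(arch_ev$cost),
        best_emissions = min(arch_ev$emissions),
        best_nutrition = max(arch_ev$nutrition))
    } else {
      history[[g]] <- tibble::tibble(generation = g, best_cost = NA_real_,
                                     best_emissions = NA_real_,
                                     best_nutrition = NA_real_)
    }
  }

  if (nrow(arch_ev) > 0) {
    sel_Q <- arch_Q
    sel_ev <- arch_ev
  } else {
    # no feasible candidate was ever seen: return the final population's
    # non-dominated set as the least-violating approximation
    pen <- canonical_objectives(ev, ev$penalty)
    rank <- non_dominated_sort_canonical(pen)
    sel_Q <- Q[rank == 1, , drop = FALSE]
    sel_ev <- ev[rank == 1, ]
  }
  out <- dplyr::bind_cols(
    tibble::as_tibble(sel_Q, .name_repair = "minimal") |>
      setNames(paste0("q_", if (d == length(ASF_CATEGORIES)) ASF_CATEGORIES else seq_len(d))),
    sel_ev[, c("cost", "emissions", "nutrition", "penalty", "violation")])
  out <- dplyr::distinct(out)
  new_pareto_front(out, config = config,
                   history = dplyr::bind_rows(history))
  })
}

# Sorting/crowding working directly on a canonical matrix (avoids rebuilding
# tibbles in the hot loop).
non_dominated_sort_canonical <- function(m) {
  D <- dominance_matrix(m)
  n_dominators <- colSums(D)
  rank <- integer(nrow(m))
  current <- which(n_dominators == 0)
  r <- 0L
  while (length(current) > 0) {
    r <- r + 1L
    rank[current] <- r
    n_dominators[current] <- -1L
    n_dominators <- n_dominators - colSums(D[current, , drop = FALSE])
    current <- which(n_dominators == 0)
  }
  rank
}

crowding_by_front <- function(m, rank) {
  crowd <- numeric(nrow(m))
  for (r in unique(rank)) {
    idx <- which(rank == r)
    crowd[idx] <- crowding_distance_canonical(m[idx, , drop = FALSE])
  }
  crowd
}

crowding_distance_canonical <- function(m) {
  n <- nrow(m)
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (k in seq_len(ncol(m))) {
    o <- order(m[, k])
    span <- m[o[n], k] - m[o[1], k]
    if (span <= 0) next  # axis carries no information; skip it
    d[o[c(1, n)]] <- Inf
    d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
      (m[o[3:n], k] - m[o[1:(n - 2)], k]) / span
  }
  d
}

new_pareto_front <- function(tbl, config = NULL, history = NULL) {
  structure(tbl, class = c("pareto_front", class(tbl)),
            config = config, history = history)
}

#' @export
print.pareto_front <- function(x, ...) {
  cat("<pareto_front> ", nrow(x), " non-dominated solution(s)",
      if (!is.null(attr(x, "scenario"))) paste0(" [", attr(x, "scenario"), "]"),
      "\n", sep = "")
  NextMethod()
}

#' Exact Pareto front of an enumerated candidate grid
#'
#' Brute-force oracle: evaluates every candidate and keeps the maximal
#' non-dominated set by pairwise comparison.  Intended for small enumerable
#' grids (`<= 1e6` points); the result is independent of input order.
#'
#' @param Q Matrix of candidate decision vectors (rows).
#' @param evaluate Function mapping a candidate matrix to a tibble with
#'   `cost`, `emissions`, `nutrition` columns.
#' @return A `pareto_front` tibble (decision columns + objectives).
#' @export
brute_force_pareto <- function(Q, evaluate) {
  if (is.null(dim(Q))) Q <- matrix(Q, ncol = 1)
  if (nrow(Q) > 1e6) abort("grid too large to enumerate (> 1e6 points)")
  ev <- evaluate(Q)
  m <- canonical_objectives(ev)
  keep <- !apply(dominance_matrix(m), 2, any)
  out <- dplyr::bind_cols(
    tibble::as_tibble(Q[keep, , drop = FALSE], .name_repair = "minimal") |>
      setNames(paste0("q_", seq_len(ncol(Q)))),
    ev[keep, intersect(c("cost", "emissions", "nutrition", "penalty",
                         "violation"), names(ev))])
  new_pareto_front(dplyr::distinct(out))
}

#' Dominated hypervolume of a front
#'
#' Exact hypervolume (sweep over the third axis with 2-D staircase areas)
#' of the region dominated by the front relative to a reference point, in
#' the canonical minimization space (nutrition negated).  Larger is better.
#'
#' @param objectives Tibble/data frame with `cost`, `emissions`,
#'   `nutrition`.
#' @param ref Reference point, named vector (`cost`, `emissions`,
#'   `nutrition`) that every front member must dominate (worst corner).
#' @return Nonnegative hypervolume.
#' @export
hypervolume <- function(objectives, ref) {
  m <- canonical_objectives(objectives)
  r <- c(ref[["cost"]], ref[["emissions"]], -ref[["nutrition"]])
  m <- m[m[, 1] <= r[1] & m[, 2] <= r[2] & m[, 3] <= r[3], , drop = FALSE]
  if (nrow(m) == 0) return(0)
  zs <- sort(unique(m[, 3]))
  hv <- 0
  for (i in seq_along(zs)) {
    z_hi <- if (i < length(zs)) zs[i + 1] else r[3]
    slab <- m[m[, 3] <= zs[i], 1:2, drop = FALSE]
    hv <- hv + (z_hi - zs[i]) * staircase_area(slab, r[1:2])
  }
  unname(hv)
}

# Area dominated by 2-D (minimized) points within the box below ref.
staircase_area <- function(pts, ref) {
  o <- order(pts[, 1], pts[, 2])
  pts <- pts[o, , drop = FALSE]
  area <- 0
  y_prev <- ref[2]
  for (i in seq_len(nrow(pts))) {
    if (pts[i, 2] < y_prev) {
      area <- area + (ref[1] - pts[i, 1]) * (y_prev - pts[i, 2])
      y_prev <- pts[i, 2]
    }
  }
  area
}

#' Knee point of a Pareto front
#'
#' The front member closest (Euclidean distance on min-max normalized
#' axes) to the ideal point (best value of each objective), used as the
#' single summary solution of a scenario.
#'
#' @param front A `pareto_front` (or tibble with `cost`, `emissions`,
#'   `nutrition`).
#' @return The knee-point row as a one-row tibble.
#' @export
knee_point <- function(front) {
  m <- canonical_objectives(front)
  rng <- apply(m, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], 1e-12)
  norm <- sweep(sweep(m, 2, rng[1, ], "-"), 2, span, "/")
  dist <- sqrt(rowSums(norm^2))
  tibble::as_tibble(front[which.min(dist), , drop = FALSE])
}
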