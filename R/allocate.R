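#' Allocate a global test budget across subpopulations
#'
#' Spends a limited number of tests to minimize the total expected
#' misassignment cost over a heterogeneous population. Each subpopulation's
#' achievable set is its convex rate-cost frontier ([build_frontier()]);
#' allocation is the fractional-knapsack greedy over the merged frontier
#' segments: segments are taken in order of steepest cost reduction per
#' test, the marginal segment fractionally. By convexity of every frontier
#' this greedy is globally optimal among plans built from the enumerated
#' strategies and partial coverage.
#'
#' A plan assigns to each subpopulation a mixture of at most two adjacent
#' frontier strategies (plus an untested remainder at the cost-optimal
#' default status); coverage fractions are continuous, which for
#' population-scale scenarios introduces only an O(u/N) integrality error.
#'
#' @inheritParams enumerate_strategies
#' @param budget_tests Total number of tests available (>= 0). Defaults to
#'   the scenario's budget when `x` is a [scenario()].
#' @return An object of class `pc_allocation`: a list with
#'   \describe{
#'     \item{plan}{tibble with one row per (subpopulation, strategy) with
#'       positive coverage: `name`, `strategy`, `group_sizes`, `fraction`,
#'       `individuals`, `rate`, `cost_per_individual`, `tests`,
#'       `cost_total`, `expected_infected`, `default_status` (untested rows
#'       only).}
#'     \item{tests_used}{expected tests spent (<= budget).}
#'     \item{cost_per_individual}{population-wide expected cost.}
#'     \item{expected_infected}{expected number of individuals declared
#'       infected.}
#'   }
#'   plus the inputs and settings. See [tidy.pc_allocation()] and
#'   [glance.pc_allocation()].
#' @examples
#' sc <- example35_scenario()
#' alloc <- allocate_budget(sc, budget_tests = 2e4)
#' glance(alloc)
#' @export
allocate_budget <- function(x, budget_tests = NULL, max_k = NULL,
                            max_group = NULL,
                            strategies = c("ksg", "individual")) {
  sp <- as_subpops(x)
  if (inherits(x, "pc_scenario")) {
    budget_tests <- budget_tests %||% x$budget_tests
  }
  if (is.null(budget_tests) || !is.numeric(budget_tests) ||
      length(budget_tests) != 1 || is.na(budget_tests) || budget_tests < 0) {
    stop("`budget_tests` must be a single non-negative number.",
         call. = FALSE)
  }
  frontier <- build_frontier(x, max_k = max_k, max_group = max_group,
                             strategies = strategies)
  segs <- frontier_segments(frontier, sp)
  frac <- numeric(nrow(segs))
  remaining <- budget_tests
  for (s in seq_len(nrow(segs))) {
    if (remaining <= 1e-12) break
    take <- min(1, remaining / segs$d_tests[s])
    frac[s] <- take
    remaining <- remaining - take * segs$d_tests[s]
  }
  new_allocation(frontier, segs, frac, sp,
                 budget_tests = budget_tests,
                 settings = attr_settings(x, max_k, max_group, strategies))
}

#' Minimum tests needed to reach a target expected cost
#'
#' Inverts the merged rate-cost frontier: walks the frontier segments in
#' greedy order, accumulating cost reduction, and stops exactly where the
#' population-wide expected cost first reaches `target_cost`. Because the
#' merged frontier is piecewise linear the inversion is exact — no
#' iterative search. The expected test count is rounded up to a whole test
#' in `tests_required` (feasibility rounding).
#'
#' @inheritParams allocate_budget
#' @param target_cost Desired population-wide expected cost per individual;
#'   must lie between the cheapest achievable cost and the no-test cost
#'   (targets at or above the no-test cost need 0 tests).
#' @return A `pc_allocation` (see [allocate_budget()]) whose plan achieves
#'   `target_cost`, with the extra field `tests_required` (integer).
#' @examples
#' sc <- example35_scenario()
#' min_tests_for_cost(sc, target_cost = 0.25)$tests_required
#' @export
min_tests_for_cost <- function(x, target_cost, max_k = NULL,
                               max_group = NULL,
                               strategies = c("ksg", "individual")) {
  sp <- as_subpops(x)
  if (!is.numeric(target_cost) || length(target_cost) != 1 ||
      is.na(target_cost) || target_cost < 0) {
    stop("`target_cost` must be a single non-negative number.",
         call. = FALSE)
  }
  frontier <- build_frontier(x, max_k = max_k, max_group = max_group,
                             strategies = strategies)
  segs <- frontier_segments(frontier, sp)
  n_total <- sum(sp$size)
  no_test <- sum(sp$size * no_test_point(sp)$cost_per_individual)
  needed <- no_test - target_cost * n_total
  frac <- numeric(nrow(segs))
  if (needed > 0) {
    available <- sum(segs$d_reduction)
    if (needed > available + 1e-6) {
      stop(sprintf(
        "target cost %.6g is below the reachable minimum %.6g",
        target_cost, (no_test - available) / n_total), call. = FALSE)
    }
    for (s in seq_len(nrow(segs))) {
      take <- min(1, needed / segs$d_reduction[s])
      frac[s] <- take
      needed <- needed - take * segs$d_reduction[s]
      if (needed <= 1e-9) break
    }
  }
  alloc <- new_allocation(frontier, segs, frac, sp,
                          budget_tests = NA_real_,
                          settings = attr_settings(x, max_k, max_group,
                                                   strategies))
  alloc$target_cost <- target_cost
  alloc$tests_required <- as.integer(ceiling(alloc$tests_used - 1e-6))
  alloc
}

#' Expected number of individuals declared infected under a plan
#'
#' Every covered individual whose final-stage pool tests positive is
#' declared infected (probability `1 - (1 - p)^u_k`), as is every untested
#' individual in a subpopulation whose cost-optimal default is "infected".
#'
#' @param alloc A `pc_allocation` from [allocate_budget()] or
#'   [min_tests_for_cost()].
#' @return A tibble with one row per subpopulation (`name`,
#'   `expected_infected`); the population total is their sum (also stored
#'   in `alloc$expected_infected`).
#' @examples
#' expected_infected(allocate_budget(example35_scenario(), 1e4))
#' @export
expected_infected <- function(alloc) {
  stopifnot(inherits(alloc, "pc_allocation"))
  alloc$plan |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(expected_infected = sum(.data$expected_infected),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$name, alloc$subpops$name))
}

# -- internals ----------------------------------------------------------------

attr_settings <- function(x, max_k, max_group, strategies) {
  if (inherits(x, "pc_scenario")) {
    max_k <- max_k %||% x$max_k
    max_group <- max_group %||% x$max_group
  }
  list(max_k = max_k %||% 2, max_group = max_group %||% 100,
       strategies = match.arg(strategies, c("ksg", "individual")))
}

# Turn greedy segment fractions into a per-subpopulation plan of vertex
# weights: a prefix of fully-taken segments plus one partial segment means
# the subpopulation sits at a convex combination of two adjacent vertices.
new_allocation <- function(frontier, segs, frac, subpops, budget_tests,
                           settings) {
  segs$fraction_taken <- frac
  plan <- purrr::map_dfr(seq_len(nrow(subpops)), function(i) {
    nm <- subpops$name[i]
    fv <- frontier[frontier$name == nm, , drop = FALSE]
    si <- segs[segs$name == nm, , drop = FALSE]
    si <- si[order(si$vertex), ]
    f <- si$fraction_taken
    weights <- c(1 - (if (length(f)) f[1] else 0),
                 if (length(f)) -diff(c(f, 0)) else numeric(0))
    keep <- weights > 1e-12
    rows <- fv[keep, , drop = FALSE]
    w <- weights[keep]
    p <- subpops$prevalence[i]
    ntp <- no_test_point(subpops[i, , drop = FALSE])
    ind <- w * subpops$size[i]
    inf_prob <- vapply(rows$group_sizes, function(u) {
      if (length(u) == 0) {
        as.numeric(ntp$default_status == "infected")
      } else {
        positive_probability(p, u[length(u)])
      }
    }, numeric(1))
    tibble::tibble(
      name = nm,
      strategy = rows$strategy,
      group_sizes = rows$group_sizes,
      fraction = w,
      individuals = ind,
      rate = rows$rate,
      cost_per_individual = rows$cost,
      tests = ind * rows$rate,
      cost_total = ind * rows$cost,
      expected_infected = ind * inf_prob,
      default_status = ifelse(rows$strategy == "none",
                              ntp$default_status, NA_character_)
    )
  })
  n_total <- sum(subpops$size)
  structure(
    list(
      plan = plan,
      subpops = subpops,
      frontier = frontier,
      budget_tests = budget_tests,
      tests_used = sum(plan$tests),
      rate_tpi = sum(plan$tests) / n_total,
      cost_per_individual = sum(plan$cost_total) / n_total,
      expected_infected = sum(plan$expected_infected),
      settings = settings
    ),
    class = "pc_allocation"
  )
}

#' @export
print.pc_allocation <- function(x, ...) {
  n <- sum(x$subpops$size)
  cat(sprintf(
    "<pc_allocation> N = %s, tests = %.0f (%.4f TpI)%s\n",
    format(n, big.mark = " "), x$tests_used, x$rate_tpi,
    if (is.na(x$budget_tests)) "" else
      sprintf(", budget = %s", format(x$budget_tests, big.mark = " "))
  ))
  cat(sprintf("  expected cost per individual: %.4f\n",
              x$cost_per_individual))
  cat(sprintf("  expected declared infected:   %.0f\n",
              x$expected_infected))
  print(x$plan[, c("name", "strategy", "fraction", "individuals", "tests",
                   "cost_total")])
  invisible(x)
}
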