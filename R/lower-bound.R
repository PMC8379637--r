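#' Lower-bound point for a heterogeneous population
#'
#' Evaluates the information-theoretic lower bound on the rate-cost
#' trade-off for a population split into subpopulations with sizes
#' \eqn{N^{(i)}}, prevalences \eqn{p^{(i)}} and costs
#' \eqn{b^{(i)}, c^{(i)}}. At slope parameter `v` in `[0, 1]`,
#' \deqn{D(v) = \frac{1}{N}\sum_i N^{(i)} b^{(i)}
#'   \bar{D}(p^{(i)}, a^{(i)}, v^{b^{(i)}}), \qquad
#'   R(v) = \frac{1}{N}\sum_i N^{(i)}
#'   \bar{R}(p^{(i)}, a^{(i)}, v^{b^{(i)}})}
#' with \eqn{a^{(i)} = c^{(i)}/b^{(i)}} and [dbar()]/[rbar()] the
#' single-population parametric curve. No testing strategy using at most
#' `R(v) * N` tests can achieve expected cost below `D(v)` per individual.
#' Subpopulations whose effective parameter \eqn{v^{b^{(i)}}} exceeds their
#' critical value contribute their clamped (no-test) values.
#'
#' @inheritParams enumerate_strategies
#' @param v Numeric vector of slope parameters in `[0, 1]`.
#' @return A tibble with columns `v`, `rate_tpi` (`R(v)`) and
#'   `cost_per_individual` (`D(v)`).
#' @examples
#' bound_point(austria_nov2020(), v = c(0, 0.5, 1))
#' @export
bound_point <- function(x, v) {
  sp <- as_subpops(x)
  check_unit_interval(v, "v")
  n_total <- sum(sp$size)
  d_tot <- numeric(length(v))
  r_tot <- numeric(length(v))
  for (i in seq_len(nrow(sp))) {
    p <- sp$prevalence[i]
    b <- sp$fp_cost[i]
    a <- sp$fn_cost[i] / b
    v0 <- critical_v(p, a)
    w <- ifelse(v == 0, 0, v^b)
    d_tot <- d_tot + sp$size[i] * b * dbar(p, a, w, v0)
    r_tot <- r_tot + sp$size[i] * rbar(p, a, w, v0)
  }
  tibble::tibble(v = v, rate_tpi = r_tot / n_total,
                 cost_per_individual = d_tot / n_total)
}

#' Lower bound on achievable cost at a test budget
#'
#' The smallest expected cost per individual any testing strategy could
#' possibly achieve with `budget_tests` tests: inverts the aggregated rate
#' curve `R(v)` by bisection on `v` (after checking empirically on a dense
#' grid that `R` is monotone for this population; if not — which the
#' mixture of cost scales does not rule out a priori — a grid minimum is
#' used with a warning instead of a silent wrong answer).
#'
#' @inheritParams bound_point
#' @param budget_tests Number of tests available (>= 0). Defaults to the
#'   scenario's budget when `x` is a [scenario()].
#' @return Lower-bound expected cost per individual (a single number):
#'   0 when the budget reaches `R(0) * N` (enough information for perfect
#'   identification in the bound's accounting), the no-test cost at
#'   budget 0.
#' @examples
#' bound_cost_at_budget(austria_nov2020()) # ~0.609 at the historic budget
#' @export
bound_cost_at_budget <- function(x, budget_tests = NULL) {
  sp <- as_subpops(x)
  if (inherits(x, "pc_scenario")) {
    budget_tests <- budget_tests %||% x$budget_tests
  }
  if (is.null(budget_tests) || budget_tests < 0) {
    stop("`budget_tests` must be a single non-negative number.",
         call. = FALSE)
  }
  n_total <- sum(sp$size)
  r_target <- budget_tests / n_total
  r0 <- bound_point(sp, 0)$rate_tpi
  if (r_target >= r0) {
    return(0)
  }
  v <- invert_bound(sp, r_target, what = "rate_tpi", decreasing = TRUE)
  bound_point(sp, v)$cost_per_individual
}

#' Lower bound on tests needed for a target cost
#'
#' The smallest number of tests any strategy could use while achieving an
#' expected cost of `target_cost` per individual: inverts the aggregated
#' distortion curve `D(v)` by bisection and reports `N * R(v)`, rounded up
#' to a whole test.
#'
#' @inheritParams bound_point
#' @param target_cost Target expected cost per individual, between 0 and
#'   the no-test cost.
#' @return Integer number of tests (lower bound).
#' @examples
#' sc <- austria_nov2020()
#' bound_tests_for_cost(sc, 0.478) # roughly half the no-test cost
#' @export
bound_tests_for_cost <- function(x, target_cost) {
  sp <- as_subpops(x)
  if (!is.numeric(target_cost) || length(target_cost) != 1 ||
      is.na(target_cost) || target_cost < 0) {
    stop("`target_cost` must be a single non-negative number.",
         call. = FALSE)
  }
  n_total <- sum(sp$size)
  no_test <- sum(sp$size * no_test_point(sp)$cost_per_individual) / n_total
  if (target_cost >= no_test) {
    return(0L)
  }
  v <- invert_bound(sp, target_cost, what = "cost_per_individual",
                    decreasing = FALSE)
  as.integer(ceiling(n_total * bound_point(sp, v)$rate_tpi - 1e-6))
}

#' Sample the lower-bound curve
#'
#' Samples `(v, R(v), D(v))` on a grid that concentrates points near
#' `v = 0` (where the rate curve is steep) and adds the exact clamp
#' transition of every subpopulation (`v` such that
#' \eqn{v^{b^{(i)}}} equals that subpopulation's critical parameter), so
#' the curve's kinks are rendered exactly. With `n_samples = 2` only the
#' two endpoints are returned.
#'
#' @inheritParams bound_point
#' @param n_samples Number of grid points (>= 2, default 1000).
#' @return A tibble of class `pc_bound_curve` with columns `v`, `rate_tpi`,
#'   `cost_per_individual`, sorted by `v`. `R` is non-increasing and `D`
#'   non-decreasing in `v`; plotted over (rate, cost) this is the frontier
#'   no achievable plan can cross.
#' @examples
#' bound_curve(example35_scenario(), n_samples = 50)
#' @export
bound_curve <- function(x, n_samples = 1000) {
  sp <- as_subpops(x)
  if (n_samples < 2 || n_samples != floor(n_samples)) {
    stop("`n_samples` must be an integer >= 2.", call. = FALSE)
  }
  if (n_samples == 2) {
    grid <- c(0, 1)
  } else {
    transitions <- vapply(seq_len(nrow(sp)), function(i) {
      a <- sp$fn_cost[i] / sp$fp_cost[i]
      critical_v(sp$prevalence[i], a)^(1 / sp$fp_cost[i])
    }, numeric(1))
    grid <- sort(unique(c(
      0, 1, transitions,
      10^seq(-12, 0, length.out = n_samples - 2)
    )))
  }
  out <- bound_point(sp, grid)
  class(out) <- c("pc_bound_curve", class(out))
  attr(out, "subpops") <- sp
  out
}

# Bisection on v for a monotone aggregated bound coordinate. `decreasing`
# describes the coordinate as a function of v.
invert_bound <- function(sp, target, what, decreasing) {
  grid <- c(0, 10^seq(-12, 0, length.out = 1000))
  vals <- bound_point(sp, grid)[[what]]
  mono <- if (decreasing) all(diff(vals) <= 1e-9) else all(diff(vals) >= -1e-9)
  if (!mono) {
    warning(sprintf(
      "aggregated %s is not monotone in v; falling back to grid search",
      what), call. = FALSE)
    i <- which.min(abs(vals - target))
    return(grid[i])
  }
  lo <- 0
  hi <- 1
  for (iter in 1:100) {
    mid <- (lo + hi) / 2
    val <- bound_point(sp, mid)[[what]]
    above <- if (decreasing) val > target else val < target
    if (above) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  (lo + hi) / 2
}
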