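#' Tidy an allocation plan
#'
#' @param x A `pc_allocation`.
#' @param ... Unused.
#' @return The plan as a tibble: one row per (subpopulation, strategy) pair
#'   with positive coverage, including the untested remainders.
#' @export
tidy.pc_allocation <- function(x, ...) {
  x$plan
}

#' One-row summary of an allocation
#'
#' @param x A `pc_allocation`.
#' @param ... Unused.
#' @return A one-row tibble: population size `n`, `budget_tests`,
#'   expected `tests` spent, `rate_tpi`, `cost_per_individual`,
#'   `expected_infected`.
#' @export
glance.pc_allocation <- function(x, ...) {
  tibble::tibble(
    n = sum(x$subpops$size),
    budget_tests = x$budget_tests,
    tests = x$tests_used,
    rate_tpi = x$rate_tpi,
    cost_per_individual = x$cost_per_individual,
    expected_infected = x$expected_infected
  )
}

#' Tidy a scenario
#'
#' @param x A `pc_scenario`.
#' @param ... Unused.
#' @return The subpopulation tibble augmented with the derived cost ratio
#'   `a = fn_cost / fp_cost` and the cost-optimal `default_status` /
#'   `no_test_cost` of each subpopulation.
#' @export
tidy.pc_scenario <- function(x, ...) {
  ntp <- no_test_point(x$subpopulations)
  dplyr::mutate(
    x$subpopulations,
    a = .data$fn_cost / .data$fp_cost,
    default_status = ntp$default_status,
    no_test_cost = ntp$cost_per_individual
  )
}

#' One-row summary of a scenario
#'
#' @param x A `pc_scenario`.
#' @param ... Unused.
#' @return A one-row tibble: number of subpopulations, total population,
#'   budget (if any) and the population-wide no-test cost.
#' @export
glance.pc_scenario <- function(x, ...) {
  sp <- x$subpopulations
  ntp <- no_test_point(sp)
  tibble::tibble(
    name = x$name,
    subpopulations = nrow(sp),
    n = sum(sp$size),
    budget_tests = x$budget_tests %||% NA_real_,
    no_test_cost = sum(sp$size * ntp$cost_per_individual) / sum(sp$size)
  )
}
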