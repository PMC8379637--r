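#' k-stage group testing: expected rate
#'
#' Expected number of tests per individual (TpI) of the nested k-stage
#' group-testing strategy kSG(u1, ..., uk): the population is split into
#' pools of `u1`, every pool is tested, positive pools are split into equal
#' subpools of `u2` which are tested, and so on; members of a positive
#' final-stage subpool are declared infected, everyone else healthy.
#' Assuming perfect tests and independent Bernoulli(`p`) statuses,
#' \deqn{R = 1/u_1 + \sum_{\ell=1}^{k-1} \frac{1 - (1-p)^{u_\ell}}{u_{\ell+1}}.}
#' One-stage testing (k = 1) has rate `1/u1`; `group_sizes = 1` is
#' individual testing at rate 1.
#'
#' @param p Prevalence, a single probability strictly inside (0, 1).
#' @param group_sizes Integer vector `(u1, ..., uk)` of strictly decreasing
#'   pool sizes, each dividing its predecessor.
#' @return Expected tests per individual (a single number).
#' @examples
#' ksg_rate(0.01, c(66, 22)) # ~0.0372, the scarce-test optimum at p = 1%
#' ksg_rate(0.05, 33)        # one-stage pools of 33: exactly 1/33
#' @export
ksg_rate <- function(p, group_sizes) {
  check_prevalence(p)
  u <- check_group_sizes(group_sizes)
  k <- length(u)
  r <- 1 / u[1]
  if (k > 1) {
    r <- r + sum((1 - (1 - p)^u[-k]) / u[-1])
  }
  r
}

#' k-stage group testing: expected cost per individual
#'
#' Expected misassignment cost per individual of kSG(u1, ..., uk). With
#' perfect tests no false negatives occur (an infected individual's pools
#' all test positive), so the only cost is false positives: healthy members
#' of a positive final subpool. The cost depends on the final pool size only:
#' \deqn{D = b\,(1 - p - (1-p)^{u_k}).}
#'
#' @inheritParams ksg_rate
#' @param fp_cost Cost `b > 0` of one false-positive assignment.
#' @return Expected cost per individual, in the units of `fp_cost`.
#' @examples
#' ksg_cost(0.029, 1, 33)            # ~0.592
#' ksg_cost(0.01, 1, c(66, 22)) ==
#'   ksg_cost(0.01, 1, 22)           # final stage alone sets the cost
#' @export
ksg_cost <- function(p, fp_cost, group_sizes) {
  check_prevalence(p)
  check_positive(fp_cost, "fp_cost")
  u <- check_group_sizes(group_sizes)
  fp_cost * (1 - p - (1 - p)^u[length(u)])
}

#' Probability that a pooled test is positive
#'
#' `1 - (1 - p)^u`: the chance that a pool of `u` independent individuals
#' with prevalence `p` contains at least one infection. Under a kSG strategy
#' with final pool size `u` this is also the probability that any given
#' covered individual is declared infected.
#'
#' @inheritParams ksg_rate
#' @param u Pool size(s), positive integers (vectorized).
#' @return Probability vector.
#' @examples
#' positive_probability(0.029, 33) # ~0.621
#' @export
positive_probability <- function(p, u) {
  check_prevalence(p)
  if (any(u < 1 | u != floor(u))) {
    stop("`u` must contain positive integers.", call. = FALSE)
  }
  1 - (1 - p)^u
}

#' Cost-optimal default assignment for untested individuals
#'
#' Individuals not covered by any test must still be assigned a status. The
#' expected per-individual cost is `p * fn_cost` when defaulting to healthy
#' and `(1 - p) * fp_cost` when defaulting to infected; the cheaper default
#' is chosen, with ties resolved to healthy. Row order follows the input.
#'
#' @param subpops Data frame of subpopulations with columns `name`, `size`,
#'   `prevalence`, `fp_cost`, `fn_cost` (see [scenario()]).
#' @return A tibble with one row per subpopulation: `name`,
#'   `default_status` (`"healthy"` or `"infected"`), and
#'   `cost_per_individual` of the no-test point.
#' @examples
#' no_test_point(example35_scenario()$subpopulations) # 0.5, healthy
#' @export
no_test_point <- function(subpops) {
  sp <- check_subpops(subpops)
  healthy_cost <- sp$prevalence * sp$fn_cost
  infected_cost <- (1 - sp$prevalence) * sp$fp_cost
  tibble::tibble(
    name = sp$name,
    default_status = ifelse(healthy_cost <= infected_cost,
                            "healthy", "infected"),
    cost_per_individual = pmin(healthy_cost, infected_cost)
  )
}

#' Strategy notation
#'
#' Group-testing strategies are written `"1SG(33)"`, `"2SG(66,22)"`,
#' `"3SG(60,12,3)"`, ... with the pool sizes of each stage in parentheses;
#' `"individual"` abbreviates 1SG(1) and `"none"` means no testing (default
#' assignment only). `parse_strategy()` maps notation to integer pool-size
#' vectors (`integer(0)` for `"none"`); `format_strategy()` is its inverse.
#' A leading literal `k` (`"kSG(50,10)"`) is accepted on input.
#'
#' @param x Character vector of strategy labels.
#' @param group_sizes Integer vector of pool sizes, a list of such vectors,
#'   or `integer(0)` for the no-test strategy.
#' @return `parse_strategy()`: a list of integer vectors (unwrapped to a
#'   single vector for scalar input). `format_strategy()`: a character
#'   vector of labels.
#' @examples
#' parse_strategy("2SG(66,22)")
#' format_strategy(c(66, 22))
#' format_strategy(1) # "individual"
#' @export
parse_strategy <- function(x) {
  if (!is.character(x) || length(x) == 0) {
    stop("`x` must be a character vector of strategy labels.", call. = FALSE)
  }
  out <- lapply(x, function(s) {
    s <- trimws(s)
    if (identical(s, "none")) {
      return(integer(0))
    }
    if (identical(s, "individual")) {
      return(1L)
    }
    m <- regmatches(s, regexec("^([0-9]+|k)SG\\(([0-9]+(,\\s*[0-9]+)*)\\)$", s))[[1]]
    if (length(m) == 0) {
      stop(sprintf("cannot parse strategy label '%s'", s), call. = FALSE)
    }
    u <- as.integer(strsplit(m[3], ",")[[1]])
    if (m[2] != "k" && as.integer(m[2]) != length(u)) {
      stop(sprintf("stage count in '%s' does not match the %d pool size(s)",
                   s, length(u)), call. = FALSE)
    }
    check_group_sizes(u)
  })
  if (length(out) == 1) out[[1]] else out
}

#' @rdname parse_strategy
#' @export
format_strategy <- function(group_sizes) {
  if (is.list(group_sizes)) {
    return(vapply(group_sizes, format_strategy, character(1)))
  }
  if (length(group_sizes) == 0) {
    return("none")
  }
  u <- check_group_sizes(group_sizes)
  if (length(u) == 1 && u == 1) {
    return("individual")
  }
  sprintf("%dSG(%s)", length(u), paste(u, collapse = ","))
}

# Pool sizes must be positive integers, strictly decreasing, each stage
# dividing the previous one so pools split into equal disjoint subpools.
check_group_sizes <- function(u) {
  if (length(u) == 0 || anyNA(u) || !is.numeric(u) ||
      any(u < 1) || any(u != floor(u))) {
    stop("`group_sizes` must be a vector of positive integers.",
         call. = FALSE)
  }
  u <- as.integer(u)
  if (length(u) > 1) {
    if (any(diff(u) >= 0)) {
      stop("pool sizes must be strictly decreasing across stages.",
           call. = FALSE)
    }
    if (any(u[-length(u)] %% u[-1] != 0)) {
      stop("each stage's pool size must divide the previous stage's size.",
           call. = FALSE)
    }
  }
  u
}
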