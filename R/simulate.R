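#' Monte-Carlo simulation of a k-stage group-testing strategy
#'
#' Draws `n` independent Bernoulli(`p`) infection statuses and executes the
#' adaptive kSG pooling tree with perfect tests: consecutive pools of `u1`
#' are all tested; pools testing positive are split into subpools of `u2`
#' and so on; members of a positive final-stage subpool are declared
#' infected, everyone else healthy. A trailing remainder pool of fewer than
#' `u1` individuals still receives one test per stage it survives, so the
#' empirical rate can exceed the closed form by at most `1/n` per stage.
#' With perfect tests no false negatives can occur.
#'
#' The simulation uses R's Mersenne-Twister generator; when `seed` is
#' given, the global RNG state is saved and restored, so results are
#' reproducible and side-effect free.
#'
#' @param n Number of individuals to simulate.
#' @param p Prevalence in (0, 1).
#' @param fp_cost,fn_cost Misassignment costs `b`, `c` > 0.
#' @param group_sizes Pool sizes `(u1, ..., uk)`; see [ksg_rate()].
#' @param seed Optional integer seed.
#' @return A one-row tibble: `n`, `tests_used`, `empirical_rate`
#'   (`tests_used / n`), `empirical_cost`
#'   (`(fp_cost * FP + fn_cost * FN) / n`), `false_positives`,
#'   `false_negatives`, `declared_infected`, `seed`.
#' @examples
#' simulate_ksg(1e5, 0.029, 1, 33, c(33), seed = 1)
#' @export
simulate_ksg <- function(n, p, fp_cost, fn_cost, group_sizes, seed = NULL) {
  if (n < 1 || n != floor(n)) {
    stop("`n` must be a positive integer.", call. = FALSE)
  }
  check_prevalence(p)
  check_positive(fp_cost, "fp_cost")
  check_positive(fn_cost, "fn_cost")
  u <- check_group_sizes(group_sizes)
  with_preserved_seed(seed, {
    x <- stats::rbinom(n, 1L, p)
    res <- ksg_tree(x, u)
    summarise_sim(x, res$declared, res$tests, fp_cost, fn_cost, seed)
  })
}

#' Monte-Carlo simulation of an allocation plan
#'
#' End-to-end check of a `pc_allocation`: every subpopulation is simulated
#' at `round(scale * size)` individuals, the plan's strategies are applied
#' to their coverage fractions (counts by largest-remainder rounding) and
#' the untested remainder receives the plan's default status. One aggregate
#' result is returned; its empirical cost estimates the plan's expected
#' cost per individual.
#'
#' @param alloc A `pc_allocation` from [allocate_budget()] or
#'   [min_tests_for_cost()].
#' @param scale Fraction of each subpopulation to simulate (0 < scale <= 1);
#'   population-scale plans are usually validated on a 1% sample.
#' @param seed Optional integer seed.
#' @return A one-row tibble as in [simulate_ksg()].
#' @examples
#' sc <- example35_scenario(size = 1e5)
#' alloc <- allocate_budget(sc, budget_tests = 2000)
#' simulate_plan(alloc, seed = 7)
#' @export
simulate_plan <- function(alloc, scale = 1, seed = NULL) {
  stopifnot(inherits(alloc, "pc_allocation"))
  if (!is.numeric(scale) || length(scale) != 1 || is.na(scale) ||
      scale <= 0 || scale > 1) {
    stop("`scale` must be a single number in (0, 1].", call. = FALSE)
  }
  sp <- alloc$subpops
  with_preserved_seed(seed, {
    tot <- list(n = 0, tests = 0, fp = 0, fn = 0, declared = 0, cost = 0)
    for (i in seq_len(nrow(sp))) {
      m <- round(scale * sp$size[i])
      if (m < 1) {
        stop(sprintf(
          "subpopulation '%s': scaled size is zero; increase `scale`.",
          sp$name[i]), call. = FALSE)
      }
      rows <- alloc$plan[alloc$plan$name == sp$name[i], , drop = FALSE]
      counts <- largest_remainder(rows$fraction, m)
      p <- sp$prevalence[i]
      b <- sp$fp_cost[i]
      cc <- sp$fn_cost[i]
      default_infected <- isTRUE(any(
        rows$strategy == "none" & rows$default_status == "infected"
      ))
      for (j in seq_len(nrow(rows))) {
        nj <- counts[j]
        if (nj == 0) next
        x <- stats::rbinom(nj, 1L, p)
        u <- rows$group_sizes[[j]]
        if (length(u) == 0) {
          declared <- rep(default_infected, nj)
          tests <- 0L
        } else {
          r <- ksg_tree(x, u)
          declared <- r$declared
          tests <- r$tests
        }
        fp <- sum(declared & x == 0L)
        fn <- sum(!declared & x == 1L)
        tot$n <- tot$n + nj
        tot$tests <- tot$tests + tests
        tot$fp <- tot$fp + fp
        tot$fn <- tot$fn + fn
        tot$declared <- tot$declared + sum(declared)
        tot$cost <- tot$cost + b * fp + cc * fn
      }
    }
    tibble::tibble(
      n = tot$n,
      tests_used = tot$tests,
      empirical_rate = tot$tests / tot$n,
      empirical_cost = tot$cost / tot$n,
      false_positives = tot$fp,
      false_negatives = tot$fn,
      declared_infected = tot$declared,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    )
  })
}

# -- internals ----------------------------------------------------------------

# Execute the pooling tree on a fixed status vector. Pools at stage l are
# consecutive blocks of u[l] positions; because u[l] divides u[l-1], blocks
# nest, and a trailing remainder block is simply smaller. Returns the
# declared-infected logical vector and the number of tests used.
ksg_tree <- function(x, u) {
  n <- length(x)
  active <- seq_len(n) - 1L # 0-based positions still in play
  tests <- 0L
  for (l in seq_along(u)) {
    if (length(active) == 0) break
    g <- active %/% u[l]
    groups <- sort(unique(g))
    tests <- tests + length(groups)
    pos <- rowsum(x[active + 1L], g)[, 1] > 0L
    active <- active[pos[match(g, groups)]]
  }
  declared <- logical(n)
  declared[active + 1L] <- TRUE
  list(declared = declared, tests = tests)
}

summarise_sim <- function(x, declared, tests, fp_cost, fn_cost, seed) {
  fp <- sum(declared & x == 0L)
  fn <- sum(!declared & x == 1L)
  n <- length(x)
  tibble::tibble(
    n = n,
    tests_used = as.integer(tests),
    empirical_rate = tests / n,
    empirical_cost = (fp_cost * fp + fn_cost * fn) / n,
    false_positives = as.integer(fp),
    false_negatives = as.integer(fn),
    declared_infected = as.integer(sum(declared)),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
}

# Integer counts summing to m that best match the given fractions.
largest_remainder <- function(fractions, m) {
  raw <- fractions / sum(fractions) * m
  base <- floor(raw)
  left <- m - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}
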