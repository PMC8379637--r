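tiny_sub <- function(p = 0.01, b = 1, cc = 50, size = 1000) {
  data.frame(name = "x", size = size, prevalence = p,
             fp_cost = b, fn_cost = cc)
}

test_that("strategy enumeration is exhaustive on a tiny search space", {
  pts <- enumerate_strategies(tiny_sub(), max_k = 1, max_group = 3)
  expect_setequal(pts$strategy, c("none", "individual", "1SG(2)", "1SG(3)"))
  expect_equal(pts$rate[pts$strategy == "none"], 0)
  expect_equal(pts$rate[pts$strategy == "individual"], 1)
  expect_equal(pts$cost[pts$strategy == "individual"], 0)
})

test_that("two-stage enumeration count matches the divisor-sum oracle", {
  pts <- enumerate_strategies(tiny_sub(p = 0.013), max_k = 2, max_group = 12)
  proper_divisors <- vapply(1:12, function(u) {
    sum(u %% seq_len(u) == 0) - 1 # divisors of u strictly below u
  }, numeric(1))
  expect_equal(nrow(pts), 1 + 12 + sum(proper_divisors)) # + the no-test row
  expect_false(any(duplicated(
    data.frame(r = round(pts$rate, 12), c = round(pts$cost, 12))
  )))
  expect_true("2SG(66,22)" %in%
    enumerate_strategies(tiny_sub(), max_k = 2, max_group = 100)$strategy)
})

test_that("the frontier hull matches a gift-wrapping oracle on random clouds", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 50
    rate <- c(0, runif(n - 1))
    cost <- c(1, runif(n - 1))
    got <- poolcost:::lower_hull_decreasing(rate, cost)
    want <- oracle_lower_hull(rate, cost)
    expect_equal(rate[got], rate[want], tolerance = 1e-12)
    expect_equal(cost[got], cost[want], tolerance = 1e-12)
  }
})

test_that("frontiers start at no-test, decrease in cost and are convex", {
  sp <- random_subpops(3, seed = 7)
  fr <- build_frontier(sp, max_k = 2, max_group = 40)
  for (nm in sp$name) {
    f <- fr[fr$name == nm, ]
    expect_equal(f$rate[1], 0)
    expect_equal(f$strategy[1], "none")
    expect_true(all(diff(f$cost) < 0))
    slopes <- diff(f$cost) / diff(f$rate)
    expect_true(all(diff(slopes) > 0))
  }
})

test_that("the scarce-test frontier vertex at 1% prevalence is 2SG(66,22)", {
  fr <- build_frontier(tiny_sub(), max_k = 2, max_group = 100)
  expect_equal(fr$strategy[2], "2SG(66,22)")
  expect_equal(fr$rate[2], ksg_rate(0.01, c(66, 22)))
})

test_that("a single strategy point yields a two-vertex frontier", {
  fr <- build_frontier(tiny_sub(), max_k = 1, max_group = 1)
  expect_equal(fr$strategy, c("none", "individual"))
  expect_equal(fr$rate, c(0, 1))
})

test_that("budget allocation reduces to the no-test plan at budget zero", {
  sp <- random_subpops(3, seed = 1)
  a0 <- allocate_budget(sp, 0, max_k = 2, max_group = 30)
  ntp <- no_test_point(sp)
  expect_equal(a0$cost_per_individual,
               sum(sp$size * ntp$cost_per_individual) / sum(sp$size))
  expect_true(all(a0$plan$strategy == "none"))
  expect_equal(a0$tests_used, 0)
})

test_that("allocation cost is non-increasing in the budget and reaches zero", {
  sp <- random_subpops(2, seed = 3)
  budgets <- seq(0, sum(sp$size), length.out = 15)
  costs <- vapply(budgets, function(b) {
    allocate_budget(sp, b, max_k = 2, max_group = 20)$cost_per_individual
  }, numeric(1))
  expect_true(all(diff(costs) <= 1e-9))
  expect_equal(costs[length(costs)], 0, tolerance = 1e-9)
})

test_that("greedy merged-frontier allocation matches the exact two-subpopulation oracle", {
  for (seed in 1:6) {
    sp <- random_subpops(2, seed = 100 + seed)
    set.seed(seed)
    budget <- runif(1, 0, 0.6 * sum(sp$size))
    got <- allocate_budget(sp, budget, max_k = 2,
                           max_group = 6)$cost_per_individual
    want <- oracle_two_subpop_cost(sp, budget, max_group = 6)
    expect_equal(got, want, tolerance = 1e-8,
                 label = sprintf("allocation cost (seed %d)", seed))
  }
})

test_that("budget used never exceeds the budget and mixtures stay adjacent", {
  sp <- random_subpops(3, seed = 9)
  a <- allocate_budget(sp, 0.07 * sum(sp$size), max_k = 2, max_group = 25)
  expect_lte(a$tests_used, 0.07 * sum(sp$size) + 1e-9)
  expect_true(all(a$plan$fraction >= 0 & a$plan$fraction <= 1))
  per_sub <- table(a$plan$name[a$plan$strategy != "none"])
  expect_true(all(per_sub <= 2)) # at most two strategies mixed per subpop
  covered <- tapply(a$plan$fraction, a$plan$name, sum)
  expect_equal(as.numeric(covered), rep(1, length(covered)),
               tolerance = 1e-9)
})

test_that("min_tests_for_cost inverts allocate_budget along the frontier", {
  sp <- random_subpops(3, seed = 5)
  ntc <- sum(sp$size * no_test_point(sp)$cost_per_individual) / sum(sp$size)
  expect_equal(min_tests_for_cost(sp, ntc, max_group = 20)$tests_required, 0L)
  for (f in c(0.8, 0.5, 0.2)) {
    m <- min_tests_for_cost(sp, f * ntc, max_k = 2, max_group = 20)
    expect_equal(m$cost_per_individual, f * ntc, tolerance = 1e-9)
    # spending that many tests really does reach the target
    back <- allocate_budget(sp, m$tests_used, max_k = 2, max_group = 20)
    expect_equal(back$cost_per_individual, f * ntc, tolerance = 1e-9)
    expect_equal(m$tests_required, ceiling(m$tests_used - 1e-6))
  }
  expect_error(min_tests_for_cost(sp, -0.1), "non-negative")
})

test_that("expected infected counts follow declaration probabilities", {
  sp <- tiny_sub(p = 0.1, b = 1, cc = 2, size = 1000) # healthy default
  a0 <- allocate_budget(sp, 0, max_k = 1, max_group = 10)
  expect_equal(a0$expected_infected, 0)
  a <- allocate_budget(sp, 50, max_k = 1, max_group = 10)
  manual <- sum(vapply(seq_len(nrow(a$plan)), function(i) {
    u <- a$plan$group_sizes[[i]]
    if (length(u) == 0) 0 else {
      a$plan$individuals[i] * positive_probability(0.1, u[length(u)])
    }
  }, numeric(1)))
  expect_equal(a$expected_infected, manual)
  expect_equal(sum(expected_infected(a)$expected_infected),
               a$expected_infected)
})
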