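test_that("an all-healthy population uses one test per first-stage pool", {
  r <- simulate_ksg(1003, 1e-12, 1, 1, 10, seed = 1)
  expect_equal(r$tests_used, ceiling(1003 / 10))
  expect_equal(r$empirical_cost, 0)
  expect_equal(r$declared_infected, 0L)
  r2 <- simulate_ksg(100, 1e-12, 1, 1, c(10, 5), seed = 1)
  expect_equal(r2$tests_used, 10L) # stage 2 never reached
})

test_that("the pooling tree matches a recursive oracle on every tiny status vector", {
  # exhaustive: all 2^4 status vectors for a 2-stage strategy on one pool
  u <- c(4, 2)
  tests_sum <- 0
  fp_sum <- 0
  for (code in 0:15) {
    x <- as.integer(intToBits(code)[1:4])
    got <- poolcost:::ksg_tree(x, u)
    want <- oracle_tree(x, u)
    expect_identical(got$declared, want$declared)
    expect_identical(got$tests, want$tests)
    tests_sum <- tests_sum + got$tests
    fp_sum <- fp_sum + sum(got$declared & x == 0)
    expect_equal(sum(x == 1 & !got$declared), 0) # no false negatives, ever
  }
  # expectation over the uniform (p = 1/2) distribution equals the closed forms
  expect_equal(tests_sum / 16 / 4, ksg_rate(0.5, u))
  expect_equal(fp_sum / 16 / 4, ksg_cost(0.5, 1, u))
})

test_that("empirical rate and cost match the closed forms within 4 SE", {
  cases <- list(
    list(p = 0.029, u = 33),
    list(p = 0.01, u = c(66, 22)),
    list(p = 0.1, u = c(12, 4)),
    list(p = 0.25, u = c(8, 2)),
    list(p = 0.05, u = c(20, 5, 1))
  )
  n <- 2e4
  reps <- 12
  for (cs in cases) {
    b <- 1
    cc <- 10
    sim <- function(col) {
      replicate_sim(reps, col, function(r) {
        simulate_ksg(n, cs$p, b, cc, cs$u, seed = 1000 * r + length(cs$u))
      })
    }
    rate <- sim("empirical_rate")
    # remainder pools add at most one test per stage: k/n on the rate
    slack <- length(cs$u) / n
    expect_lte(abs(rate$mean - ksg_rate(cs$p, cs$u)), 4 * rate$se + slack)
    cost <- sim("empirical_cost")
    expect_lte(abs(cost$mean - ksg_cost(cs$p, b, cs$u)), 4 * cost$se)
    fn <- sim("false_negatives")
    expect_equal(fn$mean, 0)
  }
})

test_that("declared-infected frequency matches the pool positivity probability", {
  n <- 1e5
  r <- simulate_ksg(n, 0.029, 1, 33, 33, seed = 99)
  p_hat <- r$declared_infected / n
  se <- sqrt(p_hat * (1 - p_hat) / n) * 6 # pools are correlated; generous
  expect_lt(abs(p_hat - positive_probability(0.029, 33)), se + 33 / n)
})

test_that("simulations are reproducible from their seed", {
  a <- simulate_ksg(5000, 0.07, 1, 12, c(10, 5), seed = 7)
  b <- simulate_ksg(5000, 0.07, 1, 12, c(10, 5), seed = 7)
  expect_identical(a, b)
  expect_equal(a$seed, 7L)
  sc <- example35_scenario(size = 2e4)
  al <- allocate_budget(sc, budget_tests = 500)
  expect_identical(simulate_plan(al, seed = 3), simulate_plan(al, seed = 3))
})

test_that("plan simulation reproduces the plan's expected cost", {
  sc <- austria_nov2020()
  al <- allocate_budget(sc)
  got <- replicate_sim(8, "empirical_cost", function(r) {
    simulate_plan(al, scale = 0.002, seed = 500 + r)
  })
  expect_lt(abs(got$mean - al$cost_per_individual), 4 * got$se)
  # a no-test plan costs the no-test cost
  a0 <- allocate_budget(sc, budget_tests = 0)
  got0 <- replicate_sim(8, "empirical_cost", function(r) {
    simulate_plan(a0, scale = 0.002, seed = 700 + r)
  })
  expect_lt(abs(got0$mean - a0$cost_per_individual), 4 * got0$se)
})
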