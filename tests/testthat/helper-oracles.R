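# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths: hulls by gift wrapping, pooling trees by
# direct recursion, strategy enumeration by nested loops, allocation by
# candidate-point search.

# Gift-wrapping (Jarvis-march style) lower hull restricted to the
# strictly decreasing part, starting from the minimum-rate point.
oracle_lower_hull <- function(rate, cost) {
  n <- length(rate)
  start <- which(rate == min(rate))
  start <- start[which.min(cost[start])]
  hull <- start
  repeat {
    cur <- hull[length(hull)]
    cand <- which(rate > rate[cur] + 1e-15 & cost < cost[cur] - 1e-12)
    if (length(cand) == 0) break
    slopes <- (cost[cand] - cost[cur]) / (rate[cand] - rate[cur])
    nxt <- cand[order(slopes, rate[cand])][1]
    hull <- c(hull, nxt)
  }
  hull
}

# Direct formulas for the rate and cost of a nested pooling strategy,
# written independently of the package.
oracle_rate <- function(p, u) {
  k <- length(u)
  r <- 1 / u[1]
  if (k > 1) {
    for (l in 1:(k - 1)) r <- r + (1 - (1 - p)^u[l]) / u[l + 1]
  }
  r
}
oracle_cost <- function(p, b, u) b * (1 - p - (1 - p)^u[length(u)])

# All one- and two-stage pooling strategies up to a size cap, by loops.
oracle_points <- function(p, b, c_, max_group) {
  pts <- data.frame(rate = 0, cost = min((1 - p) * b, p * c_))
  for (u1 in 1:max_group) {
    pts <- rbind(pts, data.frame(rate = oracle_rate(p, u1),
                                 cost = oracle_cost(p, b, u1)))
    if (u1 > 1) {
      for (u2 in 1:(u1 - 1)) {
        if (u1 %% u2 == 0) {
          u <- c(u1, u2)
          pts <- rbind(pts, data.frame(rate = oracle_rate(p, u),
                                       cost = oracle_cost(p, b, u)))
        }
      }
    }
  }
  pts
}

# Cheapest expected cost for one subpopulation given a test allowance of
# `tests`, by brute force over all pairs of strategy points mixed by
# coverage fraction (partial testing). Returns total (not per-individual)
# cost.
oracle_subpop_cost <- function(pts, size, tests) {
  allow <- tests / size
  best <- Inf
  n <- nrow(pts)
  for (j in 1:n) {
    for (k in 1:n) {
      rj <- pts$rate[j]
      rk <- pts$rate[k]
      if (rj > rk) next
      if (allow >= rk) {
        val <- min(pts$cost[j], pts$cost[k])
      } else if (allow >= rj) {
        w <- if (rk > rj) (allow - rj) / (rk - rj) else 0
        val <- (1 - w) * pts$cost[j] + w * pts$cost[k]
      } else {
        next
      }
      best <- min(best, val)
    }
  }
  best * size
}

# Exact optimal cost for a two-subpopulation scenario at a test budget:
# the optimum sits at a breakpoint of one of the two piecewise-linear
# per-subpopulation cost functions, so searching candidate splits there
# is exact.
oracle_two_subpop_cost <- function(sp, budget, max_group) {
  stopifnot(nrow(sp) == 2)
  pts <- lapply(1:2, function(i) {
    oracle_points(sp$prevalence[i], sp$fp_cost[i], sp$fn_cost[i], max_group)
  })
  cand <- c(0, budget,
            sp$size[1] * pts[[1]]$rate,
            budget - sp$size[2] * pts[[2]]$rate)
  cand <- unique(pmin(pmax(cand, 0), budget))
  tot <- vapply(cand, function(t1) {
    oracle_subpop_cost(pts[[1]], sp$size[1], t1) +
      oracle_subpop_cost(pts[[2]], sp$size[2], budget - t1)
  }, numeric(1))
  min(tot) / sum(sp$size)
}

# Recursive pooling tree on a fixed status vector: splits a block, tests
# it, recurses into subblocks on a positive result. Independent of the
# package's vectorized implementation.
oracle_tree <- function(x, u) {
  tests <- 0L
  declared <- logical(length(x))
  run_block <- function(idx, level) {
    tests <<- tests + 1L
    if (sum(x[idx]) == 0) {
      return(invisible())
    }
    if (level == length(u)) {
      declared[idx] <<- TRUE
      return(invisible())
    }
    sub <- split(idx, (seq_along(idx) - 1) %/% u[level + 1])
    for (s in sub) run_block(s, level + 1)
  }
  blocks <- split(seq_along(x), (seq_along(x) - 1) %/% u[1])
  for (b in blocks) run_block(b, 1)
  list(declared = declared, tests = tests)
}

# Replicate a simulation and return the mean and standard error of a
# result column across independent replicate runs.
replicate_sim <- function(reps, col, fun) {
  vals <- vapply(seq_len(reps), function(r) fun(r)[[col]], numeric(1))
  list(mean = mean(vals), se = stats::sd(vals) / sqrt(reps))
}

# Small random scenario for property tests.
random_subpops <- function(n_sub, seed) {
  set.seed(seed)
  tibble::tibble(
    name = paste0("s", seq_len(n_sub)),
    size = sample(50:500, n_sub, replace = TRUE),
    prevalence = runif(n_sub, 0.02, 0.4),
    fp_cost = runif(n_sub, 0.5, 3),
    fn_cost = runif(n_sub, 5, 40)
  )
}
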