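#' Enumerate candidate testing strategies per subpopulation
#'
#' Generates every valid nested pooling strategy kSG(u1, ..., uk) with at
#' most `max_k` stages, first-stage pools of at most `max_group`, strictly
#' decreasing sizes and exact divisibility between stages — plus individual
#' testing (= 1SG(1)) and the no-test point — and evaluates each strategy's
#' expected rate ([ksg_rate()]) and cost ([ksg_cost()]) for every
#' subpopulation. Strategies landing on an identical (rate, cost) pair are
#' deduplicated, keeping the lexicographically smallest pool-size tuple.
#'
#' @param x A subpopulation data frame or a [scenario()] (whose `max_k` /
#'   `max_group` then provide the defaults).
#' @param max_k Maximum number of stages.
#' @param max_group Maximum first-stage pool size.
#' @param strategies Which families to include: `"ksg"` (all pooled
#'   strategies, individual testing included as 1SG(1)) or `"individual"`
#'   (individual testing only, for comparison curves). The no-test point is
#'   always included.
#' @return A tibble with one row per (subpopulation, strategy):
#'   `name`, `strategy` (label), `group_sizes` (list column), `rate`
#'   (tests per individual) and `cost` (expected cost per individual).
#' @examples
#' enumerate_strategies(example35_scenario(), max_k = 1, max_group = 3)
#' @export
enumerate_strategies <- function(x, max_k = NULL, max_group = NULL,
                                 strategies = c("ksg", "individual")) {
  sp <- as_subpops(x)
  if (inherits(x, "pc_scenario")) {
    max_k <- max_k %||% x$max_k
    max_group <- max_group %||% x$max_group
  }
  max_k <- max_k %||% 2
  max_group <- max_group %||% 100
  strategies <- match.arg(strategies)
  chains <- if (strategies == "individual") {
    list(1L)
  } else {
    strategy_chains(max_k, max_group)
  }
  labels <- vapply(chains, format_strategy, character(1))
  # lexicographic key on the pool-size tuple, for deterministic dedup
  keys <- vapply(chains, function(u) {
    paste(sprintf("%05d", u), collapse = ",")
  }, character(1))
  ntp <- no_test_point(sp)
  purrr::map_dfr(seq_len(nrow(sp)), function(i) {
    p <- sp$prevalence[i]
    b <- sp$fp_cost[i]
    rates <- vapply(chains, function(u) ksg_rate(p, u), numeric(1))
    costs <- vapply(chains, function(u) ksg_cost(p, b, u), numeric(1))
    pts <- tibble::tibble(
      name = sp$name[i],
      strategy = labels,
      group_sizes = chains,
      rate = rates,
      cost = costs,
      .key = keys
    )
    pts <- pts[order(round(pts$rate, 12), round(pts$cost, 12), pts$.key), ]
    dup <- duplicated(data.frame(r = round(pts$rate, 12),
                                 c = round(pts$cost, 12)))
    pts <- pts[!dup, ]
    pts$.key <- NULL
    none <- tibble::tibble(
      name = sp$name[i],
      strategy = "none",
      group_sizes = list(integer(0)),
      rate = 0,
      cost = ntp$cost_per_individual[i]
    )
    dplyr::bind_rows(none, pts)
  })
}

# All divisor chains u1 > u2 > ... > uk >= 1 with u_{l+1} | u_l,
# k <= max_k, u1 <= max_group.
strategy_chains <- function(max_k, max_group) {
  res <- list()
  grow <- function(chain) {
    res[[length(res) + 1L]] <<- chain
    if (length(chain) < max_k) {
      u <- chain[length(chain)]
      if (u > 1) {
        divs <- seq_len(u - 1L)
        divs <- divs[u %% divs == 0L]
        for (d in divs) grow(c(chain, d))
      }
    }
  }
  for (u1 in seq_len(max_group)) grow(as.integer(u1))
  res
}

#' Achievable rate-cost frontier of each subpopulation
#'
#' The lower convex hull of a subpopulation's strategy points over
#' (rate, cost), anchored at the no-test point at rate 0. Because any
#' strategy can be applied to only a fraction of a subpopulation (with the
#' cost-optimal default for the rest), every convex combination of two
#' strategy points is achievable, so the achievable set's lower boundary is
#' this hull. Only its strictly decreasing portion is kept: once the
#' minimum cost is reached, further tests buy nothing.
#'
#' @inheritParams enumerate_strategies
#' @return A tibble of class `pc_frontier` with columns `name`, `vertex`
#'   (0-based index along the frontier; vertex 0 is the no-test point),
#'   `strategy`, `group_sizes`, `rate`, `cost`. Costs strictly decrease and
#'   slopes strictly increase along each subpopulation's vertices.
#' @examples
#' build_frontier(example35_scenario(), max_k = 2, max_group = 100)
#' @export
build_frontier <- function(x, max_k = NULL, max_group = NULL,
                           strategies = c("ksg", "individual")) {
  pts <- enumerate_strategies(x, max_k = max_k, max_group = max_group,
                              strategies = strategies)
  out <- pts |>
    dplyr::group_by(.data$name) |>
    dplyr::group_modify(function(df, key) {
      keep <- lower_hull_decreasing(df$rate, df$cost)
      v <- df[keep, , drop = FALSE]
      v$vertex <- seq_len(nrow(v)) - 1L
      v
    }) |>
    dplyr::ungroup()
  # preserve the subpopulation order of the input
  sp <- as_subpops(x)
  out <- out[order(match(out$name, sp$name), out$vertex), ]
  out <- out[, c("name", "vertex", "strategy", "group_sizes", "rate", "cost")]
  class(out) <- c("pc_frontier", class(out))
  attr(out, "subpops") <- sp
  out
}

# Indices of the strictly-decreasing lower convex hull of (rate, cost),
# starting from the minimum-rate point (the rate-0 no-test anchor).
lower_hull_decreasing <- function(rate, cost) {
  ord <- order(rate, cost)
  # one point per rate: the cheapest
  ord <- ord[!duplicated(rate[ord])]
  hull <- integer(0)
  for (i in ord) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]
      b <- hull[length(hull)]
      cross <- (rate[b] - rate[a]) * (cost[i] - cost[a]) -
        (cost[b] - cost[a]) * (rate[i] - rate[a])
      if (cross <= 1e-15) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  # keep the decreasing prefix only
  last <- 1L
  while (last < length(hull) &&
         cost[hull[last + 1]] < cost[hull[last]] - 1e-12) {
    last <- last + 1L
  }
  hull[seq_len(last)]
}

# Frontier segments in global greedy order: steepest cost reduction per
# test first; ties broken by subpopulation order, then smaller first-stage
# pool of the segment's target strategy.
frontier_segments <- function(frontier, subpops) {
  segs <- frontier |>
    dplyr::group_by(.data$name) |>
    dplyr::arrange(.data$vertex, .by_group = TRUE) |>
    dplyr::mutate(
      to_rate = dplyr::lead(.data$rate),
      to_cost = dplyr::lead(.data$cost),
      to_strategy = dplyr::lead(.data$strategy),
      to_u1 = dplyr::lead(
        vapply(.data$group_sizes,
               function(u) if (length(u)) u[1] else NA_integer_, integer(1))
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$to_rate))
  idx <- match(segs$name, subpops$name)
  size <- subpops$size[idx]
  segs$subpop_index <- idx
  segs$d_tests <- size * (segs$to_rate - segs$rate)
  segs$d_reduction <- size * (segs$cost - segs$to_cost)
  segs$slope <- (segs$to_cost - segs$cost) / (segs$to_rate - segs$rate)
  segs[order(segs$slope, segs$subpop_index, segs$to_u1), ]
}
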