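#' Binary entropy function
#'
#' Shannon entropy of a Bernoulli(`p`) variable in bits,
#' \eqn{H_2(p) = -p \log_2 p - (1 - p) \log_2(1 - p)}, with the convention
#' \eqn{0 \cdot \log 0 = 0}. In this package entropies are the currency of
#' testing rates: \eqn{H_2(p)} tests per individual is the information content
#' of one infection status, and it is the rate at which the distortion-rate
#' lower bound reaches zero cost.
#'
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @return Numeric vector of entropies in bits, in `[0, 1]`.
#' @examples
#' binary_entropy(0.5)            # 1 bit
#' binary_entropy(c(0, 0.01, 1)) # endpoints are 0 by convention
#' @export
binary_entropy <- function(p) {
  if (!is.numeric(p) || anyNA(p)) {
    stop("`p` must be a numeric vector without missing values.", call. = FALSE)
  }
  if (any(p < 0 | p > 1)) {
    stop("`p` must lie in [0, 1].", call. = FALSE)
  }
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  pk <- p[ok]
  h[ok] <- -pk * log2(pk) - (1 - pk) * log2(1 - pk)
  h
}

#' Critical slope parameter of the distortion-rate curve
#'
#' The parametric distortion-rate curve for a Bernoulli(`p`) infection status
#' under asymmetric misassignment costs (false positive cost 1, false negative
#' cost `a`) is driven by a slope parameter `v` in `[0, 1]`: `1 / log2(v)` is
#' the slope dD/dR of the curve. `critical_v()` returns the smallest
#' \eqn{v_0 > 0} at which the curve hits zero rate, i.e. the smallest positive
#' solution of
#' \deqn{(p v^{a+1} + 1 - p - v)\,(p v^{-a-1} + 1 - p - v^{-1}) = 0.}
#' For `v >= v0` no tests are informative and the best default assignment
#' yields the clamped cost `min(1 - p, a p)`.
#'
#' The second factor is evaluated in the equivalent scaled form
#' \eqn{p + (1-p) v^{a+1} - v^a} (multiplied through by \eqn{v^{a+1} > 0}),
#' which is stable near `v = 0`. Each factor is bracketed by a sign-change
#' scan over a log-spaced grid on (1e-12, 1] and refined by root bisection;
#' `v = 1` solves both factors exactly and is the answer whenever neither
#' factor has an interior root.
#'
#' For the symmetric case `a = 1` the factors are quadratics and
#' `critical_v(p, 1)` equals `p / (1 - p)` for `p < 1/2` (the classical
#' Hamming-distortion value).
#'
#' @param p Prevalence, a single probability strictly inside (0, 1).
#' @param a Positive cost ratio (false-negative cost over false-positive
#'   cost), `a = c / b`.
#' @return The critical slope parameter `v0`, a single number in (0, 1].
#' @examples
#' critical_v(0.1, 1)   # = 0.1 / 0.9
#' critical_v(0.01, 50)
#' @export
critical_v <- function(p, a) {
  check_prevalence(p)
  check_positive(a, "a")
  f1 <- function(v) p * v^(a + 1) + 1 - p - v
  # p v^(-a-1) + 1 - p - 1/v, scaled by v^(a+1):
  f2 <- function(v) p + (1 - p) * v^(a + 1) - v^a
  grid <- c(1e-250, 10^seq(-12, 0, length.out = 1e4))
  root_of <- function(f) {
    y <- f(grid)
    flip <- which(y[-length(y)] > 0 & y[-1] <= 0)
    if (length(flip) == 0) {
      return(NA_real_)
    }
    i <- flip[[1]]
    if (y[i + 1] == 0 && grid[i + 1] < 1) {
      return(grid[i + 1])
    }
    stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-14)$root
  }
  v0 <- min(root_of(f1), root_of(f2), 1, na.rm = TRUE)
  if (!is.finite(v0) || v0 <= 0 ||
      min(abs(f1(v0)), abs(f2(v0))) > 1e-10) {
    stop(sprintf(
      "root finding for v0 failed at p = %g, a = %g (candidate %g)",
      p, a, v0
    ), call. = FALSE)
  }
  v0
}

#' Parametric distortion (expected cost) of the lower-bound curve
#'
#' Normalized distortion \eqn{\bar{D}(p, a, v)} of the information
#' distortion-rate curve for a Bernoulli(`p`) status under costs
#' \eqn{\rho(0,1) = 1} (false positive) and \eqn{\rho(1,0) = a} (false
#' negative), at slope parameter `v`. Costs are in units of the
#' false-positive cost `b`; multiply by `b` to recover scenario units.
#'
#' For `0 < v < v0` the value comes from the standard parametric solution of
#' the Bernoulli rate-distortion problem: with the reproduction distribution
#' \deqn{q_1 = \frac{p}{1-v} - \frac{v^a (1-p)}{1-v^a}, \qquad
#'       q_0 = \frac{1-p}{1-v^a} - \frac{v p}{1-v},}
#' the distortion is
#' \deqn{\bar{D} = v \frac{1-v^a}{1-v^{a+1}} q_1
#'       + a v^a \frac{1-v}{1-v^{a+1}} q_0.}
#' At `v = 0` the distortion is 0 (perfect identification) and for
#' `v >= v0` it is clamped at `min(1 - p, a p)`, the cost of the better
#' blanket default assignment; the curve is continuous at `v0`, where
#' `q0` or `q1` reaches zero.
#'
#' @inheritParams critical_v
#' @param v Numeric vector of slope parameters in `[0, 1]`.
#' @param v0 Critical parameter, precomputed with [critical_v()] (supplied
#'   automatically; pass it explicitly when evaluating many `v` in a loop).
#' @return Numeric vector of distortions in `[0, min(1 - p, a p)]`.
#' @seealso [rbar()] for the matching rate, [bound_point()] for the
#'   population-level aggregation.
#' @examples
#' dbar(0.2, 1, c(0, 0.1, 0.25)) # symmetric case: v / (1 + v) below v0
#' @export
dbar <- function(p, a, v, v0 = critical_v(p, a)) {
  check_prevalence(p)
  check_positive(a, "a")
  check_unit_interval(v, "v")
  clamp <- min(1 - p, a * p)
  d <- numeric(length(v))
  d[v >= v0] <- clamp
  mid <- v > 0 & v < v0
  if (any(mid)) {
    vm <- v[mid]
    va <- vm^a
    va1 <- vm^(a + 1)
    q1 <- p / (1 - vm) - va * (1 - p) / (1 - va)
    q0 <- (1 - p) / (1 - va) - vm * p / (1 - vm)
    d[mid] <- (vm * (1 - va) * q1 + a * va * (1 - vm) * q0) / (1 - va1)
  }
  pmin(pmax(d, 0), clamp)
}

#' Parametric rate of the lower-bound curve
#'
#' Rate \eqn{\bar{R}(p, a, v)} in bits (= tests per individual in the group
#' testing interpretation) of the information distortion-rate curve matching
#' [dbar()]:
#' \deqn{\bar{R} = \bar{D} \log_2 v + H_2(p)
#'   - \log_2\frac{1-v^{a+1}}{1-v^a} + p \log_2\frac{1-v}{1-v^a}}
#' for `0 < v < v0`, with the limit branches \eqn{\bar{R}(p,a,0) = H_2(p)}
#' (zero-cost endpoint) and \eqn{\bar{R}(p,a,v) = 0} for `v >= v0`.
#'
#' No testing strategy can achieve an expected cost below
#' `b * dbar(p, a, v)` per individual using fewer than `rbar(p, a, v)` tests
#' per individual.
#'
#' @inheritParams dbar
#' @return Numeric vector of rates in `[0, binary_entropy(p)]`.
#' @examples
#' rbar(0.2, 1, 0.1) # equals H2(0.2) - H2(dbar(0.2, 1, 0.1)) when a = 1
#' @export
rbar <- function(p, a, v, v0 = critical_v(p, a)) {
  check_prevalence(p)
  check_positive(a, "a")
  check_unit_interval(v, "v")
  h <- binary_entropy(p)
  r <- numeric(length(v))
  r[v == 0] <- h
  mid <- v > 0 & v < v0
  if (any(mid)) {
    vm <- v[mid]
    va <- vm^a
    va1 <- vm^(a + 1)
    d <- dbar(p, a, vm, v0)
    r[mid] <- d * log2(vm) + h -
      log2((1 - va1) / (1 - va)) + p * log2((1 - vm) / (1 - va))
  }
  pmin(pmax(r, 0), h)
}

# -- internal argument checks -------------------------------------------------

check_prevalence <- function(p) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p <= 0 || p >= 1) {
    stop("`p` must be a single probability strictly between 0 and 1.",
         call. = FALSE)
  }
  invisible(p)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number.", name),
         call. = FALSE)
  }
  invisible(x)
}

check_unit_interval <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    stop(sprintf("`%s` must lie in [0, 1].", name), call. = FALSE)
  }
  invisible(x)
}
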