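test_that("binary entropy handles endpoints and the maximum", {
  expect_equal(binary_entropy(0.5), 1)
  expect_equal(binary_entropy(c(0, 1)), c(0, 0))
  expect_equal(binary_entropy(0.25), -0.25 * log2(0.25) - 0.75 * log2(0.75))
  expect_error(binary_entropy(-0.1), "0, 1")
  expect_error(binary_entropy(1.5), "0, 1")
})

test_that("critical_v matches the quadratic factorization in the symmetric case", {
  for (p in c(0.05, 0.1, 0.3, 0.45)) {
    expect_equal(critical_v(p, 1), p / (1 - p), tolerance = 1e-10)
  }
  # above one half the other factor's root is smaller
  expect_equal(critical_v(0.55, 1), 0.45 / 0.55, tolerance = 1e-10)
  expect_equal(critical_v(0.5, 1), 1, tolerance = 1e-10)
})

test_that("critical_v agrees with an independent bisection oracle", {
  oracle_v0 <- function(p, a) {
    f1 <- function(v) p * v^(a + 1) + 1 - p - v
    f2 <- function(v) p * v^(-a - 1) + 1 - p - 1 / v # original unscaled form
    grid <- seq(1e-6, 1, length.out = 1e5)
    roots <- c(1)
    for (f in list(f1, f2)) {
      y <- f(grid)
      flips <- which(sign(y[-length(y)]) != sign(y[-1]))
      if (length(flips)) {
        lo <- grid[flips[1]]
        hi <- grid[flips[1] + 1]
        for (i in 1:200) {
          mid <- (lo + hi) / 2
          if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
        }
        roots <- c(roots, (lo + hi) / 2)
      }
    }
    min(roots)
  }
  cases <- expand.grid(p = c(0.01, 0.1, 0.3), a = c(0.5, 5.5, 33, 50))
  for (i in seq_len(nrow(cases))) {
    p <- cases$p[i]
    a <- cases$a[i]
    expect_equal(critical_v(p, a), oracle_v0(p, a), tolerance = 1e-8,
                 label = sprintf("v0(p=%g, a=%g)", p, a))
  }
})

test_that("the returned v0 is the smallest root and satisfies the defining equation", {
  for (seed in 1:5) {
    set.seed(seed)
    p <- runif(1, 0.01, 0.6)
    a <- runif(1, 0.3, 60)
    v0 <- critical_v(p, a)
    f1 <- function(v) p * v^(a + 1) + 1 - p - v
    f2 <- function(v) p + (1 - p) * v^(a + 1) - v^a
    expect_lte(min(abs(f1(v0)), abs(f2(v0))), 1e-10)
    # no sign change strictly below v0 on a dense grid
    below <- seq(1e-8, v0 * (1 - 1e-6), length.out = 2000)
    expect_true(all(f1(below) > 0))
    expect_true(all(f2(below) > 0))
  }
})

test_that("distortion and rate hit the exact endpoint identities", {
  grid <- expand.grid(p = c(0.01, 0.05, 0.2, 0.382, 0.45),
                      a = c(0.5, 1, 5.5, 33, 50))
  for (i in seq_len(nrow(grid))) {
    p <- grid$p[i]
    a <- grid$a[i]
    v0 <- critical_v(p, a)
    expect_equal(dbar(p, a, 0, v0), 0, tolerance = 1e-9)
    expect_equal(rbar(p, a, 0, v0), binary_entropy(p), tolerance = 1e-9)
    expect_equal(dbar(p, a, v0, v0), min(1 - p, a * p), tolerance = 1e-9)
    expect_equal(rbar(p, a, v0, v0), 0, tolerance = 1e-9)
    # continuity at the clamp
    expect_equal(dbar(p, a, v0 * (1 - 1e-9), v0), min(1 - p, a * p),
                 tolerance = 1e-6)
  }
})

test_that("the symmetric case reduces to the Hamming distortion-rate closed form", {
  for (p in c(0.05, 0.2, 0.35)) {
    v0 <- critical_v(p, 1)
    vs <- seq(0, v0, length.out = 21)
    d <- dbar(p, 1, vs, v0)
    r <- rbar(p, 1, vs, v0)
    # D = v / (1 + v) below the clamp, and R = H2(p) - H2(D)
    expect_equal(d[vs < v0], (vs / (1 + vs))[vs < v0], tolerance = 1e-9)
    expect_equal(r, binary_entropy(p) - binary_entropy(d), tolerance = 1e-9)
  }
})

test_that("1/log2(v) is the numerical slope of the distortion-rate curve", {
  cases <- list(c(0.05, 20), c(0.2, 1), c(0.029, 33), c(0.1, 3))
  for (cs in cases) {
    p <- cs[1]
    a <- cs[2]
    v0 <- critical_v(p, a)
    for (frac in c(0.2, 0.5, 0.8)) {
      v <- frac * v0
      delta <- 1e-6
      num <- dbar(p, a, v + delta, v0) - dbar(p, a, v - delta, v0)
      den <- rbar(p, a, v + delta, v0) - rbar(p, a, v - delta, v0)
      expect_equal(num / den, 1 / log2(v), tolerance = 1e-4,
                   label = sprintf("slope at p=%g a=%g v=%g", p, a, v))
    }
  }
})

test_that("rate decreases and distortion increases along the curve, within range", {
  grid <- expand.grid(p = c(0.02, 0.1, 0.3), a = c(0.8, 1, 10, 40))
  for (i in seq_len(nrow(grid))) {
    p <- grid$p[i]
    a <- grid$a[i]
    v0 <- critical_v(p, a)
    vs <- seq(0, v0, length.out = 200)
    d <- dbar(p, a, vs, v0)
    r <- rbar(p, a, vs, v0)
    expect_true(all(diff(r) <= 1e-12))
    expect_true(all(diff(d) >= -1e-12))
    expect_true(all(d >= 0 & d <= min(1 - p, a * p) + 1e-12))
    expect_true(all(r >= 0 & r <= binary_entropy(p) + 1e-12))
  }
})
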