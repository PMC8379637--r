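---
title: "Rate-cost methodology for pooled testing under scarce budgets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rate-cost methodology for pooled testing under scarce budgets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolcost)
```

## The model

`poolcost` treats surveillance testing as a lossy source-coding problem.
Each of $N$ individuals carries an independent Bernoulli($p$) infection
status $X_n$; a testing strategy may adaptively pool any subsets of
individuals (a pooled test is positive iff at least one member is
infected — tests are assumed perfect), and after $K$ tests *every*
individual must be assigned a status $Y_n$. Wrong assignments cost
$\rho(0,1) = b$ (false positive) and $\rho(1,0) = c$ (false negative);
correct assignments are free. The two currencies of the analysis are the
rate $R = K/N$ in tests per individual (TpI) and the expected cost per
individual $D = \mathbb{E}\,\tfrac1N\sum_n \rho(X_n, Y_n)$.

Three assumptions matter and are kept throughout: tests are error-free
(a pooled test of $u$ individuals is negative iff all are healthy),
statuses are independent across individuals, and the cost is additive and
fixed — it does not depend on how a status was assigned, and there is no
saturation when many people are quarantined at once.

## Achievable side: nested pooling strategies

A kSG$(u_1,\dots,u_k)$ strategy tests disjoint pools of $u_1$; positive
pools are split into equal subpools of $u_2$ and retested, and so on;
members of a positive stage-$k$ subpool are declared infected, everyone
else healthy. Under the model,
$$R_{kSG} = \frac{1}{u_1} + \sum_{\ell=1}^{k-1}
  \frac{1-(1-p)^{u_\ell}}{u_{\ell+1}}, \qquad
  D_{kSG} = b\bigl(1 - p - (1-p)^{u_k}\bigr),$$
so the cost depends only on the final pool size while the rate depends on
the whole chain. An infected individual can never be declared healthy —
all its pools test positive — so the entire cost is false positives:
healthy individuals sharing a positive final subpool. We require pool
sizes to be strictly decreasing with each stage dividing the previous one
($u_{\ell+1} \mid u_\ell$); without exact divisibility the closed forms
would hold only approximately. Untested individuals receive the blanket
status that is cheaper in expectation — healthy iff $pc \le (1-p)b$, with
ties resolved to healthy.

Note a limit of intuition here: the rate is *not* monotone in $u_1$.
Enlarging the first pool saves first-stage tests but inflates the retest
term $(1-(1-p)^{u_1})/u_2$, and past an optimum (e.g. $u_1 \approx 66$ for
$p = 0.01$, $u_2 = 22$) the rate rises again. The optimizer therefore
enumerates rather than ascends.

## Converse side: the distortion-rate lower bound

No strategy — pooled or otherwise — can beat the information
distortion-rate function of the Bernoulli source under the asymmetric
cost. For a single population (cost normalized to $b = 1$, $a = c/b$) the
parametric solution is implemented in closed form. With slope parameter
$v \in [0, v_0)$ and writing $q_1 = \frac{p}{1-v} - \frac{v^a(1-p)}{1-v^a}$,
$q_0 = \frac{1-p}{1-v^a} - \frac{vp}{1-v}$ for the optimal reproduction
distribution,
$$\bar D(p,a,v) = \frac{v(1-v^a)\,q_1 + a v^a (1-v)\,q_0}{1-v^{a+1}},
\qquad
\bar R(p,a,v) = \bar D \log_2 v + H_2(p)
 - \log_2\frac{1-v^{a+1}}{1-v^a} + p\log_2\frac{1-v}{1-v^a},$$
with limit branches $\bar D = 0,\ \bar R = H_2(p)$ at $v = 0$ and the
clamp $\bar D = \min(1-p,\,ap),\ \bar R = 0$ for $v \ge v_0$. The critical
$v_0$ is the smallest positive root of
$(p v^{a+1} + 1 - p - v)(p v^{-a-1} + 1 - p - v^{-1}) = 0$; the two
factors are exactly the conditions $q_0 = 0$ and $q_1 = 0$, i.e. the two
ways the reproduction distribution can degenerate, matching the two
candidate clamp values. These expressions were derived from the standard
parametric (variational) solution of the binary rate-distortion problem
and are pinned down by strong internal checks, all enforced in the test
suite:

- endpoints $\bar D(p,a,0)=0$, $\bar R(p,a,0)=H_2(p)$,
  $\bar D(p,a,v_0)=\min(1-p,ap)$, $\bar R(p,a,v_0)=0$;
- for $a = 1$ the curve collapses to the symmetric-Hamming closed form
  $\bar D = v/(1+v)$, $\bar R = H_2(p) - H_2(\bar D)$, and
  $v_0 = p/(1-p)$ for $p < \tfrac12$;
- $1/\log_2 v$ equals the numerical slope $d\bar D/d\bar R$ everywhere in
  the interior (central differences at $\delta = 10^{-6}$, tolerance
  $10^{-4}$);
- monotonicity and range on dense grids.

For a heterogeneous population split into subpopulations $i$ with
parameters $(N^{(i)}, p^{(i)}, b^{(i)}, c^{(i)})$, the bound aggregates as
$$D(v) = \frac1N \sum_i N^{(i)} b^{(i)}
  \bar D\!\left(p^{(i)}, a^{(i)}, v^{b^{(i)}}\right),\qquad
R(v) = \frac1N \sum_i N^{(i)}
  \bar R\!\left(p^{(i)}, a^{(i)}, v^{b^{(i)}}\right),$$
the common slope parameter entering each subpopulation through its own
cost scale $v^{b^{(i)}}$ (the curve has one global slope, and a
subpopulation's local slope in its own cost units is scaled by
$b^{(i)}$). Consistency of cost units across subpopulations is therefore
essential, and the single-subpopulation case reduces exactly to the
scalar curve.

## The optimizer

Each subpopulation's achievable set is built by enumerating every valid
kSG chain with $k \le$ `max_k` and $u_1 \le$ `max_group`, plus individual
testing and the no-test point. Because any strategy can be applied to a
fraction of a subpopulation (the rest defaulting), the lower boundary of
the achievable set is the lower convex hull over (rate, cost), kept only
on its strictly decreasing stretch. A global budget is then allocated by
the classic fractional-knapsack argument: merge all frontier segments,
sort by cost reduction per test (steepest first), and spend greedily with
the marginal segment taken fractionally. Convexity of each frontier makes
the greedy exactly optimal within the enumerated strategy class; a
subpopulation ends up mixing at most two adjacent frontier strategies.
`min_tests_for_cost()` inverts the same piecewise-linear walk exactly —
no iterative search is involved.

Defaults `max_k = 2`, `max_group = 100`: two-stage schemes already
capture almost all of the benefit while three or more stages multiply the
logistical bookkeeping, and 100 comfortably exceeds the largest pool any
studied scenario selects (66) while keeping enumeration instant. Both are
ordinary arguments (and scenario-file keys) and can be raised freely; no
upper bound on pool size is implied by the theory itself, though real
assays dilute.

Deterministic tie-breaking: equal-slope segments are taken in
subpopulation order, then by smaller first-stage pool; duplicate
(rate, cost) points keep the lexicographically smallest pool-size tuple.
Coverage fractions are continuous — with populations of $10^5$–$10^7$ the
integrality error is $O(u/N)$ — and reported test counts are rounded *up*
(`tests_required`) so a reported budget is always feasible.

## The simulator

`simulate_ksg()` draws i.i.d. Bernoulli statuses and executes the pooling
tree literally: consecutive blocks of $u_1$, one test per surviving
block per stage, remainder blocks (when $n$ is not a multiple of $u_1$)
tested as-is at their smaller size — so the empirical rate can exceed the
closed form by at most one test per stage per remainder block, i.e.
$k/n$. `simulate_plan()` scales a whole allocation down (default
validation uses a 1% sample of each subpopulation, counts by
largest-remainder rounding) and simulates every (strategy, coverage) row
plus the untested remainder. Seeds are explicit, recorded in every
result, and the global RNG state is restored afterwards.

What the simulator emulates is exactly the model: independence, perfect
tests, cost additivity. Real surveillance data violate all three in ways
the model deliberately ignores — household clustering inflates
within-pool correlation (which *helps* pooling), dilution degrades
sensitivity in large pools, and compliance likely drops when a whole pool
of 33 is quarantined on one positive assay. Passing simulation checks
therefore validates the arithmetic of the closed forms, not the realism
of the model; conclusions about a real campaign inherit the model's
assumptions.

Monte-Carlo agreement is asserted at 4 standard errors. Because outcomes
of individuals sharing a pool are positively correlated, the naive
binomial per-individual variance understates the sampling error of a
single run; the tests instead estimate the standard error empirically
across 8–12 independent replicate simulations of $2\times10^4$–$10^5$
individuals each (fixed seeds), which is both statistically correct and
fast. These problem sizes make the full suite run in well under a minute
while leaving the 4-SE bands a factor of several tighter than the effects
being checked.

## Numerical choices

- Logarithms are base 2 throughout (rates in bits = tests), with the
  convention $0\log 0 = 0$ handled by explicit limit branches — no
  `0^0` or `log(0)` is ever evaluated.
- Root finding for $v_0$: the second factor is used in the scaled form
  $p + (1-p)v^{a+1} - v^a$ (same roots on $(0,1]$, stable near 0); each
  factor is scanned for a sign change on $10^4$ log-spaced points in
  $(10^{-12}, 1]$ (prepended with $10^{-250}$ to catch roots below the
  grid when $a \ll 1$) and refined by `uniroot` to $10^{-14}$; $v = 1$
  solves both factors exactly and is returned when no interior root
  exists, so a root always exists; the residual is verified to
  $10^{-10}$.
- Bound inversion: monotonicity of the aggregated $R(v)$ (not guaranteed
  a priori for mixed cost scales) is checked empirically on a 1000-point
  grid before bisection ($10^{-12}$ in $v$); a failure falls back to a
  grid minimum with a warning rather than returning a silently wrong
  value.
- Hull construction: monotone-chain with cross-product tolerance
  $10^{-15}$ (collinear points dropped), verified against a
  gift-wrapping oracle on random clouds.
- Degenerate inputs: `dbar`/`rbar` clamp tiny negative round-off to
  their theoretical ranges; prevalences are required to be strictly
  inside $(0,1)$ and costs strictly positive, so every $a = c/b$ and
  every entropy is well defined.

## Reproduction precision of the case study

The packaged four-subpopulation scenario reproduces its historic headline
values deterministically: no-test cost 0.956, optimized cost 0.816 at the
103 621-test budget (partial 1SG(33) coverage of the low-prevalence
general population), individual-testing cost 0.944, lower bound 0.609,
and expected declared-infected counts 2 124 712 / 2 228 333 to the last
digit. The minimum-test counts for halving the cost (201 256 lower bound;
373 636 with 1SG(4) on high-prevalence health-care workers plus a
1SG(24)/1SG(23) mix; 4 447 461 with individual testing) depend on the
sixth decimal of the cost target, which is below the precision the
scenario's three-significant-figure prevalences support; they reproduce
here to within 0.005%, and the test suite asserts them at a $10^{-4}$
relative tolerance.

## Limitations

Beyond the model assumptions above: the optimizer is exact only within
the enumerated strategy class (nested equal-split pools; no array
designs, no pooling across subpopulations); the lower bound is a
converse, not an achievability result — it cannot always be approached,
even asymptotically (at $v = 0$ it claims rate $H_2(p) < 1$ for perfect
identification, which pooling cannot attain for
$p \ge \tfrac12(3-\sqrt5)$); and prevalences and costs are treated as
known constants, whereas in practice $p$ is estimated and $b$, $c$ encode
contestable policy judgements. A sensitivity sweep over $(b, c)$ is
cheap — the whole pipeline runs in well under a second per scenario — and
is the recommended way to use the package.
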