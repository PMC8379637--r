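# poolcost

Rate–cost analysis of pooled (group) testing for epidemic surveillance.

When tests are scarce, a public-health authority cannot determine every
individual's infection status — yet every individual still ends up treated as
either healthy or infected. `poolcost` plans that trade-off quantitatively.
Each individual has an independent Bernoulli(*p*) infection status and a cost
is incurred for wrong assignments: *b* for a false positive (a healthy person
treated as infected), *c* for a false negative. A testing strategy spends
*R* tests per individual (TpI) and yields an expected misassignment cost *D*
per individual; the package computes both sides of that trade-off:

- **Closed forms for nested pooling strategies.** kSG(u₁,…,u_k) pools u₁
  samples per test, splits positive pools into subpools of u₂, and so on;
  members of a positive final subpool are declared infected. With perfect
  tests,

  R = 1/u₁ + Σ_ℓ (1 − (1−p)^{u_ℓ}) / u_{ℓ+1},  D = b (1 − p − (1−p)^{u_k}),

  and no false negatives occur (`ksg_rate()`, `ksg_cost()`).

- **An information-theoretic lower bound.** The problem is a source-coding
  one: at rate R no strategy can beat the distortion-rate function of the
  Bernoulli source under the asymmetric cost (b, c). The package evaluates
  its parametric solution (D̄(v), R̄(v)), v the slope parameter with
  dD/dR = 1/log₂ v, clamped at the critical v₀ where testing stops paying
  (`dbar()`, `rbar()`, `critical_v()`), and aggregates it over heterogeneous
  subpopulations as D(v) = Σᵢ Nᵢ bᵢ D̄(pᵢ, aᵢ, v^{bᵢ})/N and the matching
  R(v) (`bound_point()`, `bound_curve()`, `bound_cost_at_budget()`).

- **Optimal budget allocation.** Per subpopulation, all kSG strategies up to
  a stage and pool-size cap are enumerated and reduced to the convex
  rate–cost frontier (partial coverage makes every convex combination
  achievable); a global budget is then spent greedily on the merged frontier
  segments, steepest cost reduction per test first — which is exactly optimal
  for this piecewise-linear problem (`build_frontier()`, `allocate_budget()`,
  `min_tests_for_cost()`).

- **A Monte-Carlo simulator** that executes the pooling tree on simulated
  populations and verifies every closed form (`simulate_ksg()`,
  `simulate_plan()`).

Everything is tibble-in/tibble-out with `tidy()`/`glance()` accessors and
`autoplot()` methods; scenarios are YAML/JSON files (`read_scenario()`), and
a thin command-line interface ships in `inst/cli/poolcost`.

## Worked example

The packaged scenario `austria_nov2020()` models Austria in mid November
2020: 8 916 845 people in four subpopulations (recently-tested vs not,
prevalence 0.196 vs 0.029; health-care workers vs not, false-positive cost 6
vs 1; false-negative cost 33 throughout) and a budget of 103 621 tests —
0.0116 TpI.

```r
library(poolcost)
sc <- austria_nov2020()
glance(sc)
#>   name            subpopulations       n budget_tests no_test_cost
#> 1 austria_nov2020              4 8916845       103621        0.956

alloc <- allocate_budget(sc)
glance(alloc)
#>         n budget_tests  tests rate_tpi cost_per_individual expected_infected
#> 1 8916845       103621 103621   0.0116               0.816          2228333.

tidy(alloc)[, c("name", "strategy", "fraction", "tests")]
#>   name                       strategy fraction  tests
#> 1 healthcare_high_prevalence none        1          0
#> 2 healthcare_low_prevalence  none        1          0
#> 3 general_high_prevalence    none        1          0
#> 4 general_low_prevalence     none        0.607      0
#> 5 general_low_prevalence     1SG(33)    0.393 103621

bound_cost_at_budget(sc)
#> [1] 0.609162
```

Reading: with no tests at all, assigning the cheap blanket status everywhere
(infected in the two high-prevalence subpopulations, healthy elsewhere)
costs 0.956 per individual. The optimal use of the historic budget is to
pool the low-prevalence general population 33 at a time — covering 39% of
it — which brings the expected cost down to 0.816, while individual testing
with the same budget only reaches 0.944
(`allocate_budget(sc, strategies = "individual")`). No conceivable strategy
could do better than 0.609 with this budget. The price of pooling is
over-quarantining: a pool of 33 is positive with probability 0.621, so about
2.23 million people end up declared infected. A Monte-Carlo check of the
plan on a 1% sample agrees with the closed forms:

```r
simulate_plan(alloc, scale = 0.01, seed = 1)
#>       n tests_used empirical_rate empirical_cost false_positives false_negatives
#> 1 89169       1037         0.0116          0.823           20513            1600
```

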