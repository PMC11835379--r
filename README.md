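# ctpdyn

Multiscale dynamics of epigenetically inherited drug persistence in cancer
cell populations.

## The problem

Tumors treated with cytotoxic or targeted drugs often relapse without any
resistance mutation: a small subpopulation of **drug-tolerant persister
(DTP) cells** survives through reversible, epigenetically inherited state
changes and later seeds stably resistant regrowth. `ctpdyn` is for
modelers and quantitative biologists who want a tested, reproducible
implementation of a population model of this process — for exploring dose
schedules (continuous vs intermittent therapy, drug holidays), the role of
epigenetic instability, and parameter estimation from clone-level trait
distributions and tumor-volume kinetics.

## The model

Cells carry two continuous traits on the unit square: a heritable
epigenetic trait *x* — the *chance to persist* (CTP) — and a phenotype *y*
describing adaptation to drug-induced apoptosis. The resting-cell density
Q(x, y, t) obeys

∂ₜQ = −∂ᵧ{v Q} + σ ∂ᵧ²Q − γ(y, c) Q + 2∫ β(z, Q̂) Q(z, y, t) p(x, z) dz − β(x, Q̂) Q

with reflecting boundaries in *y*, stress-adaptation drift
v = v₀ x c (y₀(c) − y), apoptosis γ = γ₀ + γ₁ c H(y* − y) (the drug kills
only cells with y < y* = 0.5), logistic proliferation re-entry
β = β₁(x)(1 − Q̂/K), and a Beta-distributed inheritance kernel p(x, z)
whose mean φ(z) = φ₀ + φ₁(αz)ⁿ/(1 + (αz)ⁿ) shifts toward high CTP with
dose through α = α₀ + k·c, at precision η₀ (epigenetic instability 1/η₀).
Cells are classed as drug-naive (y < 0.5), DTP (y > 0.5, x > 0.15) or
drug-resistant (y > 0.5, x < 0.15).

The package provides three cross-checked views of these dynamics — a
finite-volume PDE solver, a single-cell probability-density form
f = h(y; x) g(x), and a stochastic agent simulator — plus an
intermittent-treatment engine with min–max schedule optimization, and a
synthetic-data + calibration module (clone-level CTP histograms and
two-arm tumor-volume kinetics with multi-start least-squares fitting).

## Worked example

```r
library(ctpdyn)
ep <- epi_params()       # inheritance kernel (phi0, phi1, alpha0, k, n, eta0)
cp <- cell_params()      # rates (beta*, gamma*, v0, sigma, K, ...)

g  <- pop_grid(60, 60)
ph <- preheat(ep, cp, grid = g)     # drug-free burn-in; here T0 = 10 days

tr <- simulate_population(ep, cp, dose_schedule("constant", c_const = 0.3),
                          t_end = 60, grid = g, init = ph$state)
print(tr)
#> <pop_trajectory> 121 snapshots to t = 60 d (dt = 0.01)
#>   rel_size: start 1, min 0.266, end 7.55
#>   final fractions: naive 0.010, DTP 0.504, resistant 0.486

r <- run_intermittent(ep, cp, tau_on = 7, tau_off = 10, grid = g,
                      init = ph$state)
print(r)
#> <intermittent_run> 12 cycles; stable-cycle size in [0.781, 3.62], end-of-on 0.905 (feasible)
```

Reading the output: under constant dose 0.3 the relative tumor size falls
to 0.27 (day ~9), re-attains its pre-treatment size near day 20 and grows
toward a plateau ~7.5× by day 60, by which time essentially all cells are
tolerant (y > 0.5) and split between slow-cycling DTP and fast-cycling
resistant states. Under a 7-days-on / 10-days-off high-dose schedule the
population locks into a stable cycle oscillating between 0.78× and 3.6×,
with the end-of-treatment size below the pre-treatment size (a feasible
schedule in the min–max sense).

A command-line front end ships in `inst/cli/ctpdyn`
(`simulate-population`, `simulate-singlecell`, `simulate-agents`,
`optimize-schedule`, `make-synth`, `fit`).

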