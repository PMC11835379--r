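---
title: "A multiscale model of epigenetically inherited drug persistence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiscale model of epigenetically inherited drug persistence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`ctpdyn` simulates a cancer cell population structured by two continuous
traits on the unit square: a heritable epigenetic trait `x`, the *chance to
persist* (CTP), and a phenotype `y` describing adaptation to drug-induced
apoptosis. Writing `Q(x, y, t)` for the density of resting cells, the
population obeys an integro-PDE:

$$
\partial_t Q =
  -\partial_y\{v(x,y,c)\,Q\} + \sigma\,\partial_y^2 Q
  - \gamma(y,c)\,Q
  + 2\int_0^1 \beta(z,\hat Q)\,Q(z,y,t)\,p(x,z)\,dz
  - \beta(x,\hat Q)\,Q ,
$$

with zero-flux (reflecting) boundaries in `y` and total size
$\hat Q(t) = \iint Q\,dx\,dy$. The four mechanisms are:

* **Stress adaptation.** The phenotype drifts toward a dose-specific
  equilibrium at a speed proportional to the CTP:
  `v = v0·x·c·(y0_on − y)` under drug and `v0·x·(y0_off − y)` without, with
  `y0_on = 0.8`, `y0_off = 0.2`, plus diffusion of magnitude `sigma`.
* **Apoptosis.** `gamma(y, c) = gamma0 + gamma1·c·H(y* − y)`: the drug
  (dose `c` in [0,1], `c = 1` the maximum tolerated dose) kills only cells
  below the phenotype threshold `y* = 0.5`. We fix `H(0) = 0` so that the
  boundary joins the surviving (tolerant) side, consistent with the
  classification below.
* **Proliferation.** Resting cells re-enter the cycle at
  `beta(x, Q̂) = beta1(x)(1 − Q̂/K)` with
  `beta1(x) = beta0 + beta10(a1·x + (a2·x)^6)/(1 + (a3·x)^6)`; with the
  default constants the rate peaks at low CTP and decays at high CTP
  (a high chance to persist trades off against net growth). The logistic
  factor is clamped at zero when `Q̂` transiently overshoots `K`.
* **Epigenetic inheritance.** A division replaces the mother (CTP `z`) by
  two daughters whose CTP is drawn from a Beta distribution with mean
  `phi(z) = phi0 + phi1(αz)^n/(1 + (αz)^n)` and precision `eta0`
  (shapes `a = eta0·phi`, `b = eta0·(1 − phi)`), so
  `Var(x|z) = phi(1 − phi)/(1 + eta0) < 1/(4·eta0)`. The selection
  strength `α = alpha0 + k·c` rises with dose, biasing daughters toward
  high CTP under treatment. *Epigenetic instability* is `1/eta0`.

Cells are classified as drug-naive (`y < 0.5`), drug-tolerant persisters
(DTP: `y > 0.5, x > 0.15`) or drug-resistant (`y > 0.5, x < 0.15`).

Three views of the same dynamics are implemented and cross-checked:

1. a deterministic finite-volume solver for `Q` (`simulate_population()`),
2. a single-cell probability-density form `f = h(y; x)·g(x)` in which the
   conditional phenotype density `h` follows advection–diffusion with a
   *relative* death term and the CTP marginal `g` follows
   `dg/dt = 2∫β1 g p dz − g(β1 + ⟨β1⟩)` (`simulate_singlecell()`;
   cell–cell interaction is dropped at this scale, `β ≈ β1`), and
3. a stochastic agent simulation in which each cell divides, dies, or
   rests per time step, resting cells take an Euler–Maruyama phenotype
   step with noise amplitude `sqrt(2·sigma·dt)` (the Fokker–Planck
   correspondence to `σ∂_y^2`), and `y` is folded back into [0,1]
   (`run_agents()`).

## Treatment schedules and the min–max problem

`dose_schedule()` supports a constant dose switched on at the preheating
time and a periodic schedule: `c_on = 0.9` for `tau_on` days, then
`c_off = 0` for `tau_off` days, with half-open on-intervals.
`run_intermittent()` integrates cycle by cycle and declares the orbit
stable when consecutive cycle maxima change by < 1% twice in a row (at
most 40 cycles). `optimize_schedule()` minimizes the stable-cycle maximum
of the relative tumor size over a grid of integer-day schedules, subject
to the constraint that the end-of-treatment size on the converged cycle
stays below the pre-treatment size; ties are broken toward the longer
holiday (equal control with less drug exposure). The constraint is
evaluated on the converged cycle because the objective is phrased for the
periodic regime.

## Preheating and the pre-treatment size

The treatment clock starts at the preheating time `T0`, when the CTP
distribution has become stationary without drug. `preheat()` integrates
the *normalized* density (renormalizing to a negligible mass each step) and
reports `T0` when the CTP marginal changes by less than `tol` (L1) per
day. The marginal's stationary shape is invariant to the uniform crowding
factor, so burning in at negligible density changes nothing — and it
decouples the distributional burn-in from population growth. The absolute
pre-treatment size is then set by the config entry `q0 = Q̂(T0)/K`
(default 0.085). This deviates from an initial-mass-only convention on
purpose: with the calibrated rates, a burn-in started near `0.1·K`
saturates at the carrying capacity before the marginal settles, which
would make a ten-fold post-treatment expansion impossible by
construction. The stationary marginal is verified against an independent
route: the Perron eigenvector of the marginal dynamics
(`stationary_g()`), which agrees with the time-integrated marginal to
about 1e-3 (L1) on the default grid.

## Numerics

* Cell-centered grid, default `100 × 100`; nodes never coincide with the
  classification thresholds (even grid sizes), so no tie-breaking exists.
* Operator splitting per step: upwind advection in `y`, explicit
  zero-flux diffusion, Euler death, then mitosis redistribution through a
  precomputed kernel matrix (one per distinct dose). Each kernel column is
  renormalized so that `colSums(P)·dx = 1`, making the discrete mitosis
  operator conserve probability exactly (each division removes one mother
  and adds two daughters).
* The step must satisfy
  `dt ≤ min(dy/max|v|, dy²/(2σ), 1/max γ, 1/max β1)`; drivers cap the
  requested `dt` (default 0.01 d) at 90% of this bound, and
  `step_population()` refuses a violating step. At the default parameters
  the bound at `ny = 100` is ≈ 0.0103 d, so the default step is stable.
* The pure-R `step_population()` is the reference implementation; the
  compiled driver (`RcppArmadillo`) performs identical arithmetic and is
  tested to agree to 1e-12. Refinement from `50×50, dt = 0.02` to
  `100×100, dt = 0.01` changes the day-60 size by < 0.1%.
* Single-cell model: `h` is renormalized every step (the discretized
  relative-death term preserves its normalization only approximately);
  the population-averaged death rate uses the lagged `h, g` (explicit
  coupling, matching the splitting order); where `g` underflows (< 1e-12)
  the conditional density is left uniform (undefined on null sets). The
  Beta density is evaluated on interior nodes only and defined to vanish
  outside (0,1).
* Doses below 1e-12 take the drug-free branch of the piecewise drift
  (the schedules only use doses in {0, 0.3, 0.9}).

## Synthetic data and calibration

`generate_ctp_dataset()` emulates a clone-level CTP assay: control clones
are sampled from the drug-free stationary marginal, treated clones from
the marginal after 7 days at dose 0.9 (the main-text distribution
statement; an alternative 9-day reading is configurable), with uniform
jitter within grid cells. `generate_kinetics_dataset()` emulates relative
tumor-volume curves for a vehicle and a treated arm over days 0–45 with
multiplicative lognormal noise (volume error scales with size); each
observed arm is renormalized to start at 1. The 45-day window matters:
a 30-day window leaves the vehicle plateau — which pins `gamma0/β1` —
unresolved and degrades `gamma0` recovery beyond its tolerance.

`fit_epigenetic_params()` minimizes the squared distance between 20-bin
CTP histograms (both arms) and the model marginals over
`(phi0, phi1, k, n, eta0)` with a bounded multi-start L-BFGS-B search;
`alpha0` is held fixed because the control arm constrains it only weakly.
`fit_cellular_params()` least-squares fits both volume curves (log scale)
over `(beta0, beta10, gamma0)` by default — the three Hill-shape
constants `a1–a3` are left at their configured values because two volume
curves cannot identify them — and reports per-arm Pearson correlations.
Recovery at the defaults (median over 5 seeds): `eta0` within ~3%,
`phi0 + phi1` within ~6%, `gamma0` within ~22%.

What a green test does **not** establish: the generator draws from the
very model being fitted, so recovery tests certify the estimation
machinery and identifiability at the stated sample sizes — not that the
model describes any real clone assay or xenograft; real data carry
lineage effects, measurement artifacts and between-animal variability
that the generator does not emulate.

## Calibration of the default parameters

Only a handful of constants are fixed by the printed sources
(`y* = 0.5`, `y0_on = 0.8`, `y0_off = 0.2`, on-dose 0.9, thresholds
0.15/0.5, `eta0 = 25`). All remaining defaults are calibrated stand-ins,
chosen once so the model reproduces reference dynamics reported for
gefitinib-treated PC9 populations: under constant `c = 0.3` the relative
size falls to ~0.26 near day 9, recovers to 1 near day 20, and grows
toward a plateau (≈ 7–8× by day 45–60, vs the reported ≈ 10×); a
7-on/1-off high-dose schedule ratchets to a tolerant plateau of ≈ 3.5×;
constant high dose recovers far more slowly (day ~80) than low dose.

Known limitations of this calibration, asserted as red acceptance tests
rather than hidden:

* the day-45 plateau reaches ~7× rather than ~10× — the low-dose
  inheritance shift sustains a slow-growing DTP subpopulation that keeps
  the late composition mixed;
* the feasible min–max optimum lands at a 3–4-day holiday rather than a
  10-day one. In this parameterization the stable-cycle maximum is
  minimized at the shortest holiday that re-sensitizes the bulk
  (reversion time `0.693/(v0·x)`); an interior optimum at 10 days
  requires a resistant clan that persists *through* on-phases with
  noise-controlled retention, which conflicts with the dose-driven
  inheritance shift that is needed to control that same clan under
  constant high dose. For the same reason the resistant probability under
  intermittent treatment peaks near 0.4 rather than 0.8, and the
  tumor-recovery time under constant high dose is not monotone in the
  epigenetic noise.

The resistant probability *is* monotone decreasing in `eta0` and in the
selection-strength scale, matching the documented sweep directions.

## Reproducing the headline numbers

```r
library(ctpdyn)
ep <- epi_params(); cp <- cell_params()
g <- pop_grid(100, 100)
ph <- preheat(ep, cp, grid = g)$state
tr <- simulate_population(ep, cp, dose_schedule("constant", c_const = 0.3),
                          t_end = 60, grid = g, init = ph)
print(tr)
res <- optimize_schedule(ep, cp, tau_on_grid = 7, tau_off_grid = 2:14,
                         grid = pop_grid(60, 60))
print(res)
```

`scripts/acceptance.R` recomputes all reported quantities from scratch and
writes them to JSON.
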