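test_that("population states convert to normalized h/g densities", {
  g <- pop_grid(30, 30)
  set.seed(2)
  Q <- matrix(stats::rexp(g$nx * g$ny), g$nx, g$ny)
  st <- pop_state(Q, g)
  ds <- density_from_population(st)
  expect_equal(sum(ds$g) * g$dx, 1, tolerance = 1e-8)
  expect_equal(rowSums(ds$h) * g$dy, rep(1, g$nx), tolerance = 1e-8)
  ## f = h g integrates to 1 and the round trip recovers Q
  f <- ds$h * ds$g
  expect_equal(sum(f) * g$dx * g$dy, 1, tolerance = 1e-8)
  expect_equal(f * st$Q_hat, Q, tolerance = 1e-10)
  ## separable input: the conditional density is independent of x
  Qs <- outer(stats::runif(g$nx), stats::runif(g$ny))
  hs <- density_from_population(pop_state(Qs, g))$h
  expect_equal(hs[1, ], hs[g$nx %/% 2, ], tolerance = 1e-10)
  expect_error(density_from_population(pop_state(matrix(0, g$nx, g$ny), g)))
})

test_that("conditional phenotype step reduces to advection-diffusion for flat death", {
  g <- pop_grid(30, 30)
  ep <- ep_default()
  cp <- cell_params(gamma1 = 0)   # gamma constant in y
  ds <- equilibrium_density(ep, cp, g)
  h1 <- step_h(ds$h, ds$g, ep, cp, c = 0.9, dt = 0.005, grid = g)
  ## same advection-diffusion without any death term at all
  cp0 <- cell_params(gamma0 = 0, gamma1 = 0)
  h2 <- step_h(ds$h, ds$g, ep, cp0, c = 0.9, dt = 0.005, grid = g)
  expect_equal(h1, h2, tolerance = 1e-10)
})

test_that("diffusion-only conditional densities relax toward uniform", {
  g <- pop_grid(20, 20)
  ep <- ep_default()
  cp <- cp_inert(sigma = 0.02)
  h <- t(vapply(g$x, function(x) {
    v <- exp(-(g$y - 0.3)^2 / 0.005); v / (sum(v) * g$dy)
  }, numeric(g$ny)))
  gmar <- rep(1, g$nx)
  dt <- 0.4 * cfl_dt(g, cp, 0)
  for (i in 1:4000) h <- step_h(h, gmar, ep, cp, 0, dt, g)
  expect_lt(max(abs(h - 1)), 0.01)
})

test_that("sustained high dose concentrates the phenotype near y0_on", {
  g <- pop_grid(30, 30)
  ep <- ep_default(); cp <- cp_default()
  ds <- equilibrium_density(ep, cp, g)
  h <- ds$h
  dt <- 0.9 * cfl_dt(g, cp, 0.9)
  for (i in seq_len(ceiling(25 / dt))) h <- step_h(h, ds$g, ep, cp, 0.9, dt, g)
  ## high-CTP rows adapt fully; mean phenotype near 0.8
  i_hi <- which.min(abs(g$x - 0.5))
  expect_gt(sum(g$y * h[i_hi, ]) * g$dy, 0.7)
})

test_that("marginal CTP dynamics conserve probability and shift under drug", {
  g <- pop_grid(40, 40)
  ep <- ep_default(); cp <- cp_default()
  gm <- stationary_g(ep, cp, 0, g)
  expect_equal(sum(gm) * g$dx, 1, tolerance = 1e-8)
  ## conservation over 1000 Euler steps
  gg <- gm
  P <- kernel_matrix(g$x, alpha_of_dose(ep, 0.9), ep)
  for (i in 1:1000) gg <- step_g(gg, ep, cp, 0.9, 0.01, g, P = P)
  expect_equal(sum(gg) * g$dx, 1, tolerance = 1e-5)
  ## the 10-day treated marginal sits at higher CTP than the control
  expect_gt(sum(g$x * gg) * g$dx, sum(g$x * gm) * g$dx)
  ## the eigenvector marginal is a fixed point of the Euler step (the
  ## nonlinear term only rescales, so the RHS vanishes there)
  cpc <- cp_inert(beta0 = 0.3)
  gst <- stationary_g(ep, cpc, 0, g)
  g2 <- step_g(gst, ep, cpc, 0, 0.01, g)
  expect_equal(g2, gst, tolerance = 1e-8)
})

test_that("cell-type probabilities agree with the population classification", {
  g <- pop_grid(40, 40)
  ep <- ep_default(); cp <- cp_default()
  ## point mass in the DTP region
  gm <- numeric(g$nx); gm[which.min(abs(g$x - 0.3))] <- 1 / g$dx
  h <- matrix(0, g$nx, g$ny); h[, which.min(abs(g$y - 0.8))] <- 1 / g$dy
  ds <- density_state(gm, h, g)
  p <- cell_type_probabilities(ds)
  expect_equal(p[["dtp"]], 1)
  expect_equal(sum(p), 1, tolerance = 1e-8)
  ## generic state: matches classify_fractions of the matching population
  st <- initial_state(g, Q_hat = 1, x0 = 0.2, y0 = 0.6, w = 0.15)
  p2 <- cell_type_probabilities(density_from_population(st))
  fr <- classify_fractions(st)
  expect_equal(unname(p2), unname(fr), tolerance = 1e-10)
})

test_that("survival curves decay correctly and order by CTP", {
  ep <- ep_default(); cp <- cp_default()
  ## drug-free: pure natural death
  s0 <- survival_curve(0.3, ep, cp, dose = 0, t_end = 5)
  expect_equal(s0$S[1], 1)
  expect_equal(s0$S, exp(-cp$gamma0 * s0$t), tolerance = 1e-3)
  ## under high dose: survival is monotone nonincreasing and higher CTP
  ## (faster adaptation) survives better at late times
  s_lo <- survival_curve(0.05, ep, cp, dose = 0.9, t_end = 30)
  s_hi <- survival_curve(0.5, ep, cp, dose = 0.9, t_end = 30)
  expect_true(all(diff(s_lo$S) <= 1e-12))
  n <- nrow(s_hi)
  expect_gt(s_hi$S[n], s_lo$S[n])
})

test_that("single-cell and population models agree at low crowding", {
  ep <- ep_default(); cp <- cp_default()
  g <- grid60()
  init <- equilibrium_population(ep, cp, g)
  sched <- dose_schedule("constant", c_const = 0.3)
  tr <- simulate_population(ep, cp, sched, t_end = 20, grid = g,
                            init = init, q0 = 1e-4)  # Q_hat << K
  sc <- simulate_singlecell(ep, cp, sched, t_end = 20, grid = g,
                            init = density_from_population(init))
  sp <- tr$summary[nrow(tr$summary), ]
  ss <- sc$summary[nrow(sc$summary), ]
  expect_lt(abs(sp$frac_naive - ss$P_naive), 0.05)
  expect_lt(abs(sp$frac_dtp - ss$P_dtp), 0.05)
  expect_lt(abs(sp$frac_resistant - ss$P_resistant), 0.05)
})

test_that("tolerant probability rises during early high-dose treatment", {
  ep <- ep_default(); cp <- cp_default()
  sc <- simulate_singlecell(ep, cp, dose_schedule("constant", c_const = 0.9),
                            t_end = 10, grid = pop_grid(40, 40))
  tol <- sc$summary$P_dtp + sc$summary$P_resistant
  expect_true(all(diff(tol) >= -1e-8))
})
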