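test_that("dose_at evaluates constant and intermittent schedules", {
  s <- dose_schedule("intermittent", tau_on = 7, tau_off = 7, t0 = 0)
  expect_equal(dose_at(s, 3), 0.9)
  expect_equal(dose_at(s, 10), 0.0)
  expect_equal(dose_at(s, 17), 0.9)   # m = 1 on-phase
  expect_equal(dose_at(s, 0), 0.9)    # half-open on-interval start
  expect_equal(dose_at(s, 7), 0.0)    # half-open on-interval end

  sc <- dose_schedule("constant", c_const = 0.3, t0 = 5)
  expect_equal(dose_at(sc, c(0, 4.9, 5, 60)), c(0, 0, 0.3, 0.3))
  expect_error(dose_at(sc, -1), "negative")

  ## periodicity beyond t0
  tau <- s$tau_on + s$tau_off
  t <- seq(0, 100, by = 0.37)
  expect_equal(dose_at(s, t + tau), dose_at(s, t))
})

test_that("selection strength is affine and increasing in dose", {
  ep <- ep_default()
  expect_equal(alpha_of_dose(ep, 0), ep$alpha0)
  expect_equal(alpha_of_dose(ep, 1), ep$alpha0 + ep$k)
  expect_equal(alpha_of_dose(ep, 0.3), ep$alpha0 + 0.3 * ep$k)
  expect_true(all(diff(alpha_of_dose(ep, seq(0, 1, 0.1))) > 0))
})

test_that("kernel mean phi has the Hill form and its bounds", {
  ep <- ep_default()
  a <- alpha_of_dose(ep, 0.9)
  expect_equal(phi_ctp(0, a, ep), ep$phi0)
  ## saturation: (alpha z)^n >> 1
  ep_sat <- epi_params(phi0 = 0.1, phi1 = 0.4, alpha0 = 1e4, k = 1, n = 2)
  expect_equal(phi_ctp(1, 1e4, ep_sat), 0.5, tolerance = 1e-6)
  ## half-saturation point for n = 1: phi0 + phi1/2
  ep1 <- epi_params(phi0 = 0.1, phi1 = 0.4, alpha0 = 2, k = 1, n = 1)
  expect_equal(phi_ctp(1 / 2, 2, ep1), 0.1 + 0.4 / 2)
  ## monotone in z and alpha, and inside (phi0, phi0 + phi1)
  z <- seq(0, 1, length.out = 101)
  for (al in c(0.5, 2, 10)) {
    v <- phi_ctp(z, al, ep)
    expect_true(all(diff(v) >= 0))
    expect_true(all(v >= ep$phi0 & v <= ep$phi0 + ep$phi1))
    expect_true(all(phi_ctp(z, al * 2, ep) >= v))
  }
})

test_that("Beta shape parameters encode mean phi and precision eta0", {
  ep <- ep_default()
  z <- seq(0, 1, length.out = 11)
  sp <- beta_shape_params(z, alpha_of_dose(ep, 0.5), ep)
  expect_true(all(sp$a > 0 & sp$b > 0))
  expect_equal(sp$a + sp$b, rep(ep$eta0, length(z)))
  expect_equal(sp$a / (sp$a + sp$b),
               phi_ctp(z, alpha_of_dose(ep, 0.5), ep))
  ## symmetric case: phi = 0.5, eta0 = 25 -> (12.5, 12.5)
  ep_sym <- epi_params(phi0 = 0.5, phi1 = 0.25, alpha0 = 1, k = 1,
                       n = 2, eta0 = 25)
  sp0 <- beta_shape_params(0, 1, ep_sym)
  expect_equal(c(sp0$a, sp0$b), c(12.5, 12.5))
})

test_that("inheritance density is normalized with the analytic moments", {
  ep <- ep_default()
  al <- alpha_of_dose(ep, 0.9)
  xq <- (seq_len(2e5) - 0.5) / 2e5     # midpoint quadrature nodes
  h <- 1 / 2e5
  for (z in c(0, 0.5, 1)) {
    p <- inheritance_density(xq, z, al, ep)
    ph <- phi_ctp(z, al, ep)
    expect_equal(sum(p) * h, 1, tolerance = 1e-6)
    expect_equal(sum(xq * p) * h, ph, tolerance = 1e-6)
    expect_equal(sum((xq - ph)^2 * p) * h,
                 ph * (1 - ph) / (1 + ep$eta0), tolerance = 1e-6)
  }
  expect_equal(inheritance_density(c(-0.1, 0, 1, 1.5), 0.5, al, ep),
               rep(0, 4))
})

test_that("kernel variance respects the 1/(4 eta0) bound everywhere", {
  ep <- ep_default()
  for (al in alpha_of_dose(ep, c(0, 0.3, 0.9))) {
    ph <- phi_ctp(seq(0, 1, length.out = 101), al, ep)
    v <- ph * (1 - ph) / (1 + ep$eta0)
    expect_true(max(v) < 1 / (4 * ep$eta0))
  }
})

test_that("daughter-CTP sampling matches the kernel law", {
  ep <- ep_default()
  al <- alpha_of_dose(ep, 0.9)
  set.seed(11)
  x <- sample_daughter_ctp(1e5, 0.3, al, ep)
  ph <- phi_ctp(0.3, al, ep)
  se <- sqrt(ph * (1 - ph) / (1 + ep$eta0) / 1e5)
  expect_lt(abs(mean(x) - ph), 3 * se)
  expect_lt(var(x), 1 / (4 * ep$eta0))
  set.seed(42); d1 <- sample_daughter_ctp(5, 0.3, al, ep)
  set.seed(42); d2 <- sample_daughter_ctp(5, 0.3, al, ep)
  expect_identical(d1, d2)
})

test_that("proliferation rate beta1 follows its closed form", {
  cp <- cp_default()
  expect_equal(beta1(0, cp), cp$beta0)
  x <- seq(0, 1, length.out = 200)
  direct <- cp$beta0 + cp$beta10 * (cp$a1 * x + (cp$a2 * x)^6) /
    (1 + (cp$a3 * x)^6)
  expect_equal(beta1(x, cp), direct)
  expect_true(all(direct >= 0))
  ## high CTP grows slower than the low-CTP band under the defaults
  expect_lt(beta1(0.5, cp), beta1(0.1, cp))
})

test_that("crowding factor scales and clamps the entry rate", {
  cp <- cp_default()
  x <- c(0.05, 0.3, 0.8)
  expect_equal(beta_rate(x, cp$K, cp), rep(0, 3))
  expect_equal(beta_rate(x, 0, cp), beta1(x, cp))
  expect_equal(beta_rate(x, cp$K / 2, cp), beta1(x, cp) / 2)
  expect_equal(beta_rate(x, 2 * cp$K, cp), rep(0, 3))  # clamped
})

test_that("adaptation drift points toward the dose-specific equilibrium", {
  cp <- cp_default()
  expect_equal(adaptation_velocity(0.4, 0.8, 0.9, cp), 0)
  expect_equal(adaptation_velocity(0, 0.3, 0.9, cp), 0)
  expect_equal(adaptation_velocity(0.5, 0.2, 0.9, cp), cp$v0 * 0.27)
  ## tiny doses take the drug-free branch
  expect_equal(adaptation_velocity(0.5, 0.9, 1e-13, cp),
               cp$v0 * 0.5 * (cp$y0_off - 0.9))
  ## sign property: (y - y0(c)) * v <= 0 everywhere
  xy <- expand.grid(x = seq(0, 1, 0.1), y = seq(0, 1, 0.1))
  for (c_now in c(0, 0.3, 0.9)) {
    y0 <- if (c_now > 0) cp$y0_on else cp$y0_off
    v <- adaptation_velocity(xy$x, xy$y, c_now, cp)
    expect_true(all((xy$y - y0) * v <= 1e-15))
  }
})

test_that("drug kills only below the phenotype threshold (H(0) = 0)", {
  cp <- cp_default()
  expect_equal(death_rate(0.7, 0.9, cp), cp$gamma0)
  expect_equal(death_rate(0.3, 1, cp), cp$gamma0 + cp$gamma1)
  expect_equal(death_rate(cp$y_star, 1, cp), cp$gamma0)
})
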