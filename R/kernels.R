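#' Dose at a given time
#'
#' Evaluates the dosing schedule `c(t)`. Constant mode returns `c_const`
#' from `t0` on and 0 before. Intermittent mode returns `c_on` during the
#' first `tau_on` days of each cycle after `t0` and `c_off` otherwise, with
#' half-open on-intervals `[m*tau, m*tau + tau_on)` (cycle clock starts at
#' `t0`, `tau = tau_on + tau_off`).
#'
#' @param schedule A [dose_schedule()].
#' @param t Time(s) in days, >= 0 (vectorized).
#' @return Dose(s) in `[0,1]`.
#' @export
dose_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "dose_schedule"))
  if (any(t < 0)) stop("negative time rejected", call. = FALSE)
  s <- t - schedule$t0
  if (schedule$mode == "constant") {
    return(ifelse(s >= 0, schedule$c_const, 0))
  }
  tau <- schedule$tau_on + schedule$tau_off
  phase <- s %% tau
  ifelse(s < 0, 0,
         ifelse(phase < schedule$tau_on, schedule$c_on, schedule$c_off))
}

#' Selection strength as a function of dose
#'
#' `alpha = alpha0 + k * c`: the drug linearly increases the selective
#' pressure favoring high-CTP daughters.
#'
#' @param ep An [epi_params()].
#' @param c Dose(s) in `[0,1]`.
#' @return Selection strength(s), strictly increasing in `c`.
#' @export
alpha_of_dose <- function(ep, c) {
  stopifnot(inherits(ep, "epi_params"), all(c >= 0 & c <= 1))
  ep$alpha0 + ep$k * c
}

#' Expected daughter CTP given the mother CTP
#'
#' Hill-shaped conditional mean
#' `phi(z) = phi0 + phi1 * (alpha*z)^n / (1 + (alpha*z)^n)`, bounded in
#' `(phi0, phi0 + phi1)` and nondecreasing in both `z` and `alpha`.
#'
#' @param z Mother CTP value(s) in `[0,1]`.
#' @param alpha Selection strength (see [alpha_of_dose()]).
#' @param ep An [epi_params()].
#' @return Expected daughter CTP(s).
#' @export
phi_ctp <- function(z, alpha, ep) {
  stopifnot(all(z >= 0 & z <= 1))
  u <- (alpha * z)^ep$n
  ep$phi0 + ep$phi1 * u / (1 + u)
}

#' Beta shape parameters of the inheritance kernel
#'
#' `a(z) = eta0 * phi(z)`, `b(z) = eta0 * (1 - phi(z))`; both positive and
#' summing to `eta0`, so the kernel mean is `phi(z)` and its variance
#' `phi(z)(1-phi(z)) / (1 + eta0)`.
#'
#' @inheritParams phi_ctp
#' @return List with vectors `a` and `b`.
#' @export
beta_shape_params <- function(z, alpha, ep) {
  ph <- phi_ctp(z, alpha, ep)
  list(a = ep$eta0 * ph, b = ep$eta0 * (1 - ph))
}

#' Inheritance probability density p(x, z)
#'
#' Density of the daughter CTP `x` given the mother CTP `z`:
#' `Beta(a(z), b(z))` evaluated at `x`. Outside the open interval (0,1) the
#' density is 0 by convention; solvers only ever evaluate interior
#' cell-centered nodes.
#'
#' @param x Daughter CTP value(s).
#' @param z Mother CTP value (scalar).
#' @inheritParams phi_ctp
#' @return Density values.
#' @export
inheritance_density <- function(x, z, alpha, ep) {
  sp <- beta_shape_params(z, alpha, ep)
  out <- numeric(length(x))
  inside <- x > 0 & x < 1
  out[inside] <- stats::dbeta(x[inside], sp$a, sp$b)
  out
}

#' Sample daughter CTP values
#'
#' Draws from the inheritance kernel `Beta(a(z), b(z))`. Uses R's global
#' RNG stream; seed with [set.seed()] for reproducibility.
#'
#' @param n Number of draws.
#' @param z Mother CTP (scalar, or vector of length `n` for per-mother
#'   draws).
#' @inheritParams phi_ctp
#' @return Numeric vector of daughter CTP values in (0,1).
#' @export
sample_daughter_ctp <- function(n, z, alpha, ep) {
  sp <- beta_shape_params(z, alpha, ep)
  stats::rbeta(n, sp$a, sp$b)
}

#' CTP-regulated proliferation rate beta1(x)
#'
#' `beta1(x) = beta0 + beta10 * (a1*x + (a2*x)^6) / (1 + (a3*x)^6)`.
#' With the default constants the rate peaks at low CTP and decays for
#' high CTP, encoding that a high chance-to-persist trades off against net
#' growth.
#'
#' @param x CTP value(s) in `[0,1]`.
#' @param cp A [cell_params()].
#' @return Proliferation rate(s) (/day).
#' @export
beta1 <- function(x, cp) {
  stopifnot(all(x >= 0 & x <= 1))
  cp$beta0 + cp$beta10 * (cp$a1 * x + (cp$a2 * x)^6) / (1 + (cp$a3 * x)^6)
}

#' Effective proliferation-entry rate with crowding
#'
#' `beta(x, Q_hat) = beta1(x) * (1 - Q_hat/K)`, clamped at 0 when the
#' population transiently overshoots the carrying capacity (entry into
#' proliferation is a nonnegative rate).
#'
#' @inheritParams beta1
#' @param Q_hat Total population size, >= 0.
#' @return Rate(s) (/day).
#' @export
beta_rate <- function(x, Q_hat, cp) {
  stopifnot(Q_hat >= 0)
  beta1(x, cp) * max(0, 1 - Q_hat / cp$K)
}

#' Stress-adaptation drift of the phenotype
#'
#' `v(x, y, c) = v0 * x * c * (y0_on - y)` under drug and
#' `v0 * x * (y0_off - y)` drug-free: the phenotype drifts toward the
#' environment-specific equilibrium at a speed proportional to the CTP.
#' Doses below 1e-12 take the drug-free branch.
#'
#' @param x CTP value(s).
#' @param y Phenotype value(s).
#' @param c Dose (scalar).
#' @param cp A [cell_params()].
#' @return Drift velocity (/day); vectorized over `x` and `y`.
#' @export
adaptation_velocity <- function(x, y, c, cp) {
  stopifnot(c >= 0, c <= 1)
  if (c <= 1e-12) {
    cp$v0 * x * (cp$y0_off - y)
  } else {
    cp$v0 * x * c * (cp$y0_on - y)
  }
}

#' Apoptosis rate
#'
#' `gamma(y, c) = gamma0 + gamma1 * c * H(y_star - y)` with the Heaviside
#' convention `H(0) = 0`: the drug kills only cells strictly below the
#' phenotype threshold, so `y = y_star` joins the surviving side, matching
#' the resistant/tolerant classification at `y > y_star`.
#'
#' @param y Phenotype value(s).
#' @param c Dose (scalar).
#' @param cp A [cell_params()].
#' @return Death rate(s) (/day).
#' @export
death_rate <- function(y, c, cp) {
  stopifnot(c >= 0, c <= 1)
  cp$gamma0 + cp$gamma1 * c * as.numeric(y < cp$y_star)
}
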