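#' Default model parameters
#'
#' Returns the full set of default parameter values as a flat named list.
#'
#' The printed sources for this model report only a handful of numeric
#' values (the apoptosis threshold `y_star = 0.5`, the adaptation equilibria
#' `y0_on = 0.8` / `y0_off = 0.2`, the on-dose 0.9, the classification
#' thresholds 0.15 / 0.5, and `eta0 = 25`). All remaining rate and kernel
#' constants below are **calibrated stand-ins**, fixed once so that the
#' default simulation reproduces the reported reference dynamics: under
#' constant dose 0.3 the relative tumor size falls to ~0.3 near day 10,
#' recovers to 1 near day 20 and approaches a plateau several-fold above
#' the pre-treatment size by day 45-60; a 7-day-on / 1-day-off high-dose
#' schedule plateaus near 3x; constant high dose recovers much more slowly
#' than low dose. See the methods vignette for the calibration rationale
#' and for the reference behaviors this calibration does not reproduce.
#'
#' @return Named list of defaults covering [epi_params()], [cell_params()],
#'   [dose_schedule()] and the simulation controls (`q0`, grid sizes, `dt`).
#' @export
default_params <- function() {
  list(
    ## epigenetic inheritance kernel
    phi0   = 0.11,   # baseline daughter-CTP mean
    phi1   = 0.45,   # dose-driven CTP-shift amplitude (phi0 + phi1 < 1)
    alpha0 = 0.4,    # drug-free selection strength
    k      = 12.0,   # dose sensitivity of selection, alpha = alpha0 + k*c
    n      = 6.0,    # Hill exponent of the CTP shift
    eta0   = 25.0,   # inverse epigenetic noise (instability = 1/eta0)
    ## cellular rates
    beta0   = 0.13,  # baseline proliferation re-entry rate (/day)
    beta10  = 1.5,   # CTP-dependent proliferation amplitude (/day)
    a1      = 3.0,   # shape constants of beta1(x)
    a2      = 1.0,
    a3      = 8.0,
    K       = 1.0,   # carrying capacity (relative units)
    gamma0  = 0.095, # natural death rate (/day)
    gamma1  = 1.45,  # drug-induced death rate at full dose (/day)
    y_star  = 0.5,   # apoptosis phenotype threshold
    v0      = 1.1,   # stress-adaptation speed (/day)
    sigma   = 0.0012, # phenotype fluctuation magnitude (/day)
    y0_on   = 0.8,   # adaptation equilibrium under drug
    y0_off  = 0.2,   # adaptation equilibrium without drug
    ## dosing
    c_on    = 0.9,   # intermittent on-dose
    c_off   = 0.0,
    tau_on  = 7,
    tau_off = 7,
    ## simulation controls
    q0      = 0.085, # Q_hat(T0)/K: pre-treatment density fraction
    nx      = 100,
    ny      = 100,
    dt      = 0.01,   # capped by the CFL bound at run time
    init_x0 = 0.10,  # initial condition: Gaussian bump center/width
    init_y0 = 0.2,
    init_w  = 0.05
  )
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop(sprintf("`%s` = %g outside its valid range", name, x), call. = FALSE)
  as.numeric(x)
}

#' Epigenetic inheritance-kernel parameters
#'
#' Bundles the constants of the daughter-CTP inheritance kernel: the
#' conditional daughter CTP given a mother with CTP `z` is Beta-distributed
#' with mean `phi(z) = phi0 + phi1*(alpha*z)^n / (1 + (alpha*z)^n)` and
#' precision `eta0` (shape parameters `a = eta0*phi`, `b = eta0*(1-phi)`),
#' where the selection strength `alpha = alpha0 + k*c` grows with dose `c`.
#' Epigenetic instability is quantified as `1/eta0`.
#'
#' @param phi0 Baseline daughter-CTP mean, in (0,1).
#' @param phi1 CTP-shift amplitude; `phi0 + phi1` must stay below 1.
#' @param alpha0 Baseline (drug-free) selection strength, > 0.
#' @param k Dose sensitivity of the selection strength, > 0.
#' @param n Hill exponent, >= 1.
#' @param eta0 Inverse epigenetic noise, > 0 (both Beta shapes positive).
#' @return An object of class `epi_params`.
#' @export
epi_params <- function(phi0 = NULL, phi1 = NULL, alpha0 = NULL, k = NULL,
                       n = NULL, eta0 = NULL) {
  d <- default_params()
  p <- list(
    phi0   = check_scalar(phi0 %||% d$phi0, "phi0", 0, 1, TRUE, TRUE),
    phi1   = check_scalar(phi1 %||% d$phi1, "phi1", 0, 1, FALSE, TRUE),
    alpha0 = check_scalar(alpha0 %||% d$alpha0, "alpha0", 0, strict_lower = TRUE),
    k      = check_scalar(k %||% d$k, "k", 0, strict_lower = TRUE),
    n      = check_scalar(n %||% d$n, "n", 1),
    eta0   = check_scalar(eta0 %||% d$eta0, "eta0", 0, strict_lower = TRUE)
  )
  if (p$phi0 + p$phi1 >= 1)
    stop("phi0 + phi1 must be < 1 so the kernel mean stays inside (0,1)",
         call. = FALSE)
  structure(p, class = "epi_params")
}

#' Cellular-scale rate parameters
#'
#' Rates and shape constants of the population model: proliferation
#' re-entry `beta(x, Q_hat) = beta1(x) * (1 - Q_hat/K)` with
#' `beta1(x) = beta0 + beta10 * (a1*x + (a2*x)^6) / (1 + (a3*x)^6)`,
#' apoptosis `gamma(y, c) = gamma0 + gamma1 * c * H(y_star - y)`, and
#' phenotype drift `v = v0 * x * c * (y0_on - y)` under drug
#' (`v0 * x * (y0_off - y)` drug-free) with diffusion `sigma`.
#'
#' @param beta0,beta10,a1,a2,a3 Proliferation-rate constants.
#' @param K Carrying capacity (relative units), > 0.
#' @param gamma0,gamma1 Natural and drug-induced death rates (/day).
#' @param y_star Apoptosis phenotype threshold, in (0,1).
#' @param v0 Stress-adaptation speed (/day).
#' @param sigma Phenotype fluctuation magnitude (/day).
#' @param y0_on,y0_off Adaptation equilibria with / without drug, in (0,1).
#' @return An object of class `cell_params`.
#' @export
cell_params <- function(beta0 = NULL, beta10 = NULL, a1 = NULL, a2 = NULL,
                        a3 = NULL, K = NULL, gamma0 = NULL, gamma1 = NULL,
                        y_star = NULL, v0 = NULL, sigma = NULL,
                        y0_on = NULL, y0_off = NULL) {
  d <- default_params()
  p <- list(
    beta0  = check_scalar(beta0 %||% d$beta0, "beta0", 0),
    beta10 = check_scalar(beta10 %||% d$beta10, "beta10", 0),
    a1     = check_scalar(a1 %||% d$a1, "a1", 0),
    a2     = check_scalar(a2 %||% d$a2, "a2", 0),
    a3     = check_scalar(a3 %||% d$a3, "a3", 0),
    K      = check_scalar(K %||% d$K, "K", 0, strict_lower = TRUE),
    gamma0 = check_scalar(gamma0 %||% d$gamma0, "gamma0", 0),
    gamma1 = check_scalar(gamma1 %||% d$gamma1, "gamma1", 0),
    y_star = check_scalar(y_star %||% d$y_star, "y_star", 0, 1, TRUE, TRUE),
    v0     = check_scalar(v0 %||% d$v0, "v0", 0),
    sigma  = check_scalar(sigma %||% d$sigma, "sigma", 0),
    y0_on  = check_scalar(y0_on %||% d$y0_on, "y0_on", 0, 1, TRUE, TRUE),
    y0_off = check_scalar(y0_off %||% d$y0_off, "y0_off", 0, 1, TRUE, TRUE)
  )
  structure(p, class = "cell_params")
}

#' Dosing schedule
#'
#' Either a constant dose switched on at `t0`, or a periodic intermittent
#' schedule with `tau_on` dosed days followed by `tau_off` holiday days per
#' cycle, starting at `t0` (the preheating time). Intervals are half-open:
#' the on-phase of cycle m covers `[t0 + m*tau, t0 + m*tau + tau_on)`.
#'
#' @param mode `"constant"` or `"intermittent"`.
#' @param c_const Dose in `[0,1]` for constant mode.
#' @param tau_on Therapeutic days per cycle (> 0, intermittent mode).
#' @param tau_off Drug-holiday days per cycle (>= 0).
#' @param c_on,c_off On/off doses in `[0,1]` (defaults 0.9 and 0).
#' @param t0 Schedule start time in days (the preheating time T0).
#' @return An object of class `dose_schedule`.
#' @export
dose_schedule <- function(mode = c("constant", "intermittent"),
                          c_const = 0.3, tau_on = NULL, tau_off = NULL,
                          c_on = NULL, c_off = NULL, t0 = 0) {
  mode <- match.arg(mode)
  d <- default_params()
  s <- list(mode = mode,
            c_const = check_scalar(c_const, "c_const", 0, 1),
            tau_on  = check_scalar(tau_on %||% d$tau_on, "tau_on", 0,
                                   strict_lower = TRUE),
            tau_off = check_scalar(tau_off %||% d$tau_off, "tau_off", 0),
            c_on    = check_scalar(c_on %||% d$c_on, "c_on", 0, 1),
            c_off   = check_scalar(c_off %||% d$c_off, "c_off", 0, 1),
            t0      = check_scalar(t0, "t0", 0))
  structure(s, class = "dose_schedule")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.epi_params <- function(x, ...) {
  cat("<epi_params>  Beta inheritance kernel\n")
  cat(sprintf("  phi0=%.4g phi1=%.4g alpha0=%.4g k=%.4g n=%.4g eta0=%.4g\n",
              x$phi0, x$phi1, x$alpha0, x$k, x$n, x$eta0))
  cat(sprintf("  epigenetic instability 1/eta0 = %.4g\n", 1 / x$eta0))
  invisible(x)
}

#' @export
print.cell_params <- function(x, ...) {
  cat("<cell_params>  population rates\n")
  cat(sprintf("  beta0=%.3g beta10=%.3g a1=%.3g a2=%.3g a3=%.3g K=%.3g\n",
              x$beta0, x$beta10, x$a1, x$a2, x$a3, x$K))
  cat(sprintf("  gamma0=%.3g gamma1=%.3g y*=%.3g v0=%.3g sigma=%.3g y0=(%.2g on, %.2g off)\n",
              x$gamma0, x$gamma1, x$y_star, x$v0, x$sigma, x$y0_on, x$y0_off))
  invisible(x)
}

#' @export
print.dose_schedule <- function(x, ...) {
  if (x$mode == "constant") {
    cat(sprintf("<dose_schedule> constant c=%.3g from t0=%.3g\n", x$c_const, x$t0))
  } else {
    cat(sprintf("<dose_schedule> intermittent on=%.3g for %g d, off=%.3g for %g d, t0=%.3g\n",
                x$c_on, x$tau_on, x$c_off, x$tau_off, x$t0))
  }
  invisible(x)
}

#' Read a flat key-value configuration file
#'
#' Configs are flat JSON objects whose keys are the parameter symbols
#' (`eta0`, `gamma1`, `tau_on`, ...). Unknown keys are rejected; missing
#' keys fall back to [default_params()].
#'
#' @param path Path to a JSON config file.
#' @return A list with elements `ep` ([epi_params()]), `cp`
#'   ([cell_params()]) and `opts` (all remaining settings).
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- default_params()
  unknown <- setdiff(names(cfg), names(d))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  full <- utils::modifyList(d, cfg)
  config_to_params(full)
}

config_to_params <- function(full) {
  ep <- epi_params(phi0 = full$phi0, phi1 = full$phi1, alpha0 = full$alpha0,
                   k = full$k, n = full$n, eta0 = full$eta0)
  cp <- cell_params(beta0 = full$beta0, beta10 = full$beta10, a1 = full$a1,
                    a2 = full$a2, a3 = full$a3, K = full$K,
                    gamma0 = full$gamma0, gamma1 = full$gamma1,
                    y_star = full$y_star, v0 = full$v0, sigma = full$sigma,
                    y0_on = full$y0_on, y0_off = full$y0_off)
  opts <- full[setdiff(names(full), c(names(ep), names(cp)))]
  list(ep = ep, cp = cp, opts = opts)
}

#' Write a configuration file
#'
#' @param params Flat named list (e.g. [default_params()], possibly edited).
#' @param path Output path.
#' @export
write_config <- function(params, path) {
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
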