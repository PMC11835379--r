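#' Synthetic clone-level CTP dataset
#'
#' Emulates a clone-level CTP experiment: control clones are drawn from the
#' drug-free stationary CTP marginal, treated clones from the marginal
#' after `treat_days` days of exposure at `treat_dose` (single-cell
#' marginal dynamics, [step_g()]). Values are jittered uniformly within
#' their grid cell so the sample is continuous on (0,1). The treated
#' distribution shifts toward higher CTP.
#'
#' @param ep_true,cp_true Generating parameter objects.
#' @param n_control,n_treated Sample sizes (defaults mirror the 544 / 392
#'   clone design of the emulated experiment).
#' @param seed Integer seed.
#' @param treat_dose Dose applied to the treated arm.
#' @param treat_days Exposure duration in days.
#' @param grid A [pop_grid()].
#' @return List of class `ctp_dataset` with `control_ctps`,
#'   `treated_ctps`, and the generating settings.
#' @export
generate_ctp_dataset <- function(ep_true, cp_true, n_control = 544,
                                 n_treated = 392, seed = 1,
                                 treat_dose = 0.9, treat_days = 7,
                                 grid = pop_grid(60, 60)) {
  set.seed(seed)
  g_ctl <- stationary_g(ep_true, cp_true, dose = 0, grid = grid)
  g_trt <- evolve_g(g_ctl, ep_true, cp_true, treat_dose, treat_days, grid)
  draw <- function(n, g) {
    ix <- sample.int(grid$nx, n, replace = TRUE, prob = g)
    pmin(pmax(grid$x[ix] + stats::runif(n, -grid$dx / 2, grid$dx / 2),
              1e-9), 1 - 1e-9)
  }
  structure(list(control_ctps = draw(n_control, g_ctl),
                 treated_ctps = draw(n_treated, g_trt),
                 treat_dose = treat_dose, treat_days = treat_days,
                 seed = seed, grid = grid),
            class = "ctp_dataset")
}

## integrate the marginal dynamics for a fixed dose over `days`
evolve_g <- function(g, ep, cp, dose, days, grid, dt = 0.02) {
  if (days <= 0) return(g)
  P <- kernel_matrix(grid$x, alpha_of_dose(ep, dose), ep)
  nsteps <- ceiling(days / dt)
  dt <- days / nsteps
  for (s in seq_len(nsteps)) g <- step_g(g, ep, cp, dose, dt, grid, P = P)
  g / (sum(g) * grid$dx)
}

#' Synthetic tumor-volume kinetics dataset
#'
#' Relative tumor-volume series of a vehicle arm (no drug) and a treated
#' arm (constant dose from time 0 = preheating time), perturbed by
#' multiplicative lognormal observation noise and renormalized so the
#' first observation of each arm is exactly 1.
#'
#' @param ep_true,cp_true Generating parameter objects.
#' @param dose Treated-arm dose.
#' @param times Measurement days (increasing, from 0).
#' @param noise_sd Standard deviation of `log` observation noise.
#' @param seed Integer seed.
#' @param grid A [pop_grid()].
#' @return List of class `kinetics_dataset` with `times`,
#'   `vehicle_rel_volume`, `treated_rel_volume` and settings.
#' @export
generate_kinetics_dataset <- function(ep_true, cp_true, dose = 0.3,
                                      times = seq(0, 45, by = 3),
                                      noise_sd = 0.1, seed = 1,
                                      grid = pop_grid(60, 60)) {
  stopifnot(all(diff(times) > 0), times[1] >= 0)
  set.seed(seed)
  init <- equilibrium_population(ep_true, cp_true, grid)
  t_end <- max(times)
  rel_at <- function(cc) {
    tr <- simulate_population(ep_true, cp_true,
                              dose_schedule("constant", c_const = cc),
                              t_end = t_end, grid = grid, init = init)
    stats::approx(tr$t_fine, tr$Qhat_fine / tr$Q0, xout = times)$y
  }
  veh <- rel_at(0)
  trt <- rel_at(dose)
  noisy <- function(v) {
    obs <- v * exp(stats::rnorm(length(v), 0, noise_sd))
    obs / obs[1]
  }
  structure(list(times = times, vehicle_rel_volume = noisy(veh),
                 treated_rel_volume = noisy(trt), dose = dose,
                 noise_sd = noise_sd, seed = seed, grid = grid),
            class = "kinetics_dataset")
}

#' Drug-free equilibrium population state
#'
#' Closed-form stand-in for the time-integrated [preheat()]: the product
#' of the stationary CTP marginal (Perron eigenvector) and the exact
#' stationary phenotype density per CTP node. Used where many preheated
#' initializations are needed (fitting, sweeps).
#'
#' @param ep,cp Parameter objects.
#' @param grid A [pop_grid()].
#' @return A [pop_state()] with unit total mass.
#' @export
equilibrium_population <- function(ep, cp, grid = pop_grid(60, 60)) {
  eq <- equilibrium_density(ep, cp, grid)
  Q <- eq$g * eq$h                      # rows scaled by g
  pop_state(Q / (sum(Q) * grid$dx * grid$dy), grid, 0)
}

## 20 equal-width histogram bin probabilities of a grid density
bin_probs <- function(g, grid, nbins = 20) {
  stopifnot(grid$nx %% nbins == 0)
  per <- grid$nx / nbins
  colSums(matrix(g * grid$dx, nrow = per))
}

## sum-of-squares histogram loss over (phi0, phi1, k, n, eta0)
epi_histogram_loss <- function(data, cp_fixed, alpha0, grid, nbins = 20) {
  brks <- seq(0, 1, length.out = nbins + 1)
  emp_ctl <- as.vector(table(cut(data$control_ctps, brks))) /
    length(data$control_ctps)
  emp_trt <- as.vector(table(cut(data$treated_ctps, brks))) /
    length(data$treated_ctps)
  function(par) {
    ep <- try(epi_params(phi0 = par[1], phi1 = par[2], alpha0 = alpha0,
                         k = par[3], n = par[4], eta0 = par[5]),
              silent = TRUE)
    if (inherits(ep, "try-error")) return(1e6)
    g_ctl <- stationary_g(ep, cp_fixed, dose = 0, grid = grid)
    g_trt <- evolve_g(g_ctl, ep, cp_fixed, data$treat_dose,
                      data$treat_days, grid)
    sum((bin_probs(g_ctl, grid, nbins) - emp_ctl)^2) +
      sum((bin_probs(g_trt, grid, nbins) - emp_trt)^2)
  }
}

#' Fit the inheritance-kernel parameters to a clone CTP dataset
#'
#' Minimizes the sum of squared differences between the 20-bin empirical
#' CTP histograms (control + treated arms) and the model's stationary /
#' 7-day-treated marginals, with a bounded multi-start L-BFGS-B search
#' over `(phi0, phi1, k, n, eta0)`. The drug-free baseline `alpha0` is
#' held fixed (the control arm constrains it only weakly).
#'
#' @param data A `ctp_dataset`.
#' @param cp_fixed Cellular parameters (held fixed).
#' @param bounds Named list of `c(lower, upper)` per free parameter;
#'   defaults span generous biological ranges.
#' @param seed Seed for the multi-start draws.
#' @param n_starts Number of optimizer starts (>= 1).
#' @param alpha0 Fixed baseline selection strength.
#' @param grid Fitting grid (coarser than the data grid is fine).
#' @return List of class `calibration_result`: fitted `ep`, `loss`,
#'   `converged`, and all start results.
#' @export
fit_epigenetic_params <- function(data, cp_fixed, bounds = NULL, seed = 1,
                                  n_starts = 8, alpha0 = NULL,
                                  grid = pop_grid(40, 40)) {
  stopifnot(inherits(data, "ctp_dataset"),
            length(data$control_ctps) > 0, length(data$treated_ctps) > 0)
  alpha0 <- alpha0 %||% default_params()$alpha0
  bounds <- bounds %||% list(phi0 = c(0.01, 0.2), phi1 = c(0.1, 0.8),
                             k = c(5, 40), n = c(1, 8), eta0 = c(5, 100))
  loss_fn <- epi_histogram_loss(data, cp_fixed, alpha0, grid)

  lower <- vapply(bounds, `[`, numeric(1), 1)
  upper <- vapply(bounds, `[`, numeric(1), 2)
  set.seed(seed)
  starts <- rbind((lower + upper) / 2,
                  matrix(stats::runif((n_starts - 1) * 5,
                                      rep(lower, each = max(0, n_starts - 1)),
                                      rep(upper, each = max(0, n_starts - 1))),
                         ncol = 5))[seq_len(n_starts), , drop = FALSE]
  fits <- apply(starts, 1, function(p0) {
    stats::optim(p0, loss_fn, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = list(maxit = 60))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  ep_fit <- epi_params(phi0 = best$par[1], phi1 = best$par[2],
                       alpha0 = alpha0, k = best$par[3], n = best$par[4],
                       eta0 = best$par[5])
  structure(list(ep = ep_fit, loss = best$value,
                 converged = best$convergence == 0, starts = fits),
            class = "calibration_result")
}

## model relative-volume curves at the dataset's times for both arms
kinetics_model_curves <- function(data, ep_fixed, grid) {
  function(cp) {
    init <- equilibrium_population(ep_fixed, cp, grid)
    rel_at <- function(cc) {
      tr <- simulate_population(ep_fixed, cp,
                                dose_schedule("constant", c_const = cc),
                                t_end = max(data$times), grid = grid,
                                init = init)
      stats::approx(tr$t_fine, tr$Qhat_fine / tr$Q0, xout = data$times)$y
    }
    list(veh = rel_at(0), trt = rel_at(data$dose))
  }
}

## log-scale sum-of-squares loss over the free cellular parameters
cellular_curve_loss <- function(data, ep_fixed, free, cp_init, grid,
                                lower = -Inf, upper = Inf) {
  obs <- c(data$vehicle_rel_volume, data$treated_rel_volume)
  curves <- kinetics_model_curves(data, ep_fixed, grid)
  function(par) {
    if (any(par < lower) || any(par > upper)) return(1e6)
    args <- as.list(unclass(cp_init))
    args[free] <- as.list(par)
    cp <- try(do.call(cell_params, args), silent = TRUE)
    if (inherits(cp, "try-error")) return(1e6)
    mc <- try(curves(cp), silent = TRUE)
    if (inherits(mc, "try-error")) return(1e6)
    sum((log(c(mc$veh, mc$trt)) - log(obs))^2)
  }
}

#' Fit cellular-scale rates to tumor-volume kinetics
#'
#' Joint bounded least-squares fit of the vehicle and treated
#' relative-volume trajectories. By default `(beta0, beta10, gamma0)` are
#' free; the Hill-shape constants `a1`-`a3` are held at their configured
#' values (two volume curves leave them unidentifiable) but can be freed
#' via `free`. Goodness is reported as the per-arm Pearson correlation
#' between fit and data.
#'
#' @param data A `kinetics_dataset`.
#' @param ep_fixed Epigenetic parameters (held fixed).
#' @param bounds Named list `c(lower, upper)` per free parameter.
#' @param seed Seed for the multi-start draws.
#' @param n_starts Number of Nelder-Mead starts.
#' @param free Character vector of free [cell_params()] fields.
#' @param cp_init Baseline cellular parameters for the fixed fields.
#' @param grid Fitting grid (coarse by default; the loss is smooth in it).
#' @return List of class `calibration_result`: fitted `cp`, `loss`,
#'   per-arm correlations `R_vehicle` / `R_treatment`, `converged`.
#' @export
fit_cellular_params <- function(data, ep_fixed, bounds = NULL, seed = 1,
                                n_starts = 4,
                                free = c("beta0", "beta10", "gamma0"),
                                cp_init = cell_params(),
                                grid = pop_grid(30, 30)) {
  stopifnot(inherits(data, "kinetics_dataset"))
  all_bounds <- list(beta0 = c(0.01, 0.5), beta10 = c(0.2, 3),
                     gamma0 = c(0.005, 0.3), a1 = c(0.5, 20),
                     a2 = c(0.2, 5), a3 = c(2, 30))
  bounds <- bounds %||% all_bounds[free]
  stopifnot(all(free %in% names(bounds)))
  model_curves <- kinetics_model_curves(data, ep_fixed, grid)
  make_cp <- function(par) {
    args <- as.list(unclass(cp_init))
    args[free] <- as.list(par)
    do.call(cell_params, args)
  }
  lower <- vapply(bounds, `[`, numeric(1), 1)
  upper <- vapply(bounds, `[`, numeric(1), 2)
  loss_fn <- cellular_curve_loss(data, ep_fixed, free, cp_init, grid,
                                 lower, upper)
  set.seed(seed)
  np <- length(free)
  starts <- rbind((lower + upper) / 2,
                  matrix(stats::runif((n_starts - 1) * np,
                                      rep(lower, each = max(0, n_starts - 1)),
                                      rep(upper, each = max(0, n_starts - 1))),
                         ncol = np))[seq_len(n_starts), , drop = FALSE]
  fits <- apply(starts, 1, function(p0) {
    stats::optim(p0, loss_fn, method = "Nelder-Mead",
                 control = list(maxit = 200, reltol = 1e-6))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  cp_fit <- make_cp(pmin(pmax(best$par, lower), upper))
  mc <- model_curves(cp_fit)
  structure(list(cp = cp_fit, loss = best$value,
                 R_vehicle = stats::cor(mc$veh, data$vehicle_rel_volume),
                 R_treatment = stats::cor(mc$trt, data$treated_rel_volume),
                 fitted_curves = mc,
                 converged = best$convergence == 0, starts = fits),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> loss = %.4g%s\n", x$loss,
              if (x$converged) "" else " (optimizer not converged)"))
  if (!is.null(x$ep)) print(x$ep)
  if (!is.null(x$cp)) {
    print(x$cp)
    cat(sprintf("  R_vehicle = %.3f, R_treatment = %.3f\n",
                x$R_vehicle, x$R_treatment))
  }
  invisible(x)
}

#' One-at-a-time parameter sensitivity
#'
#' Perturbs each named parameter by `+-perturbation` (relative), reruns
#' the population model (day-`t_end` total size) and the single-cell model
#' (final resistant probability) under a constant dose, and reports the
#' relative changes.
#'
#' @param params Character vector of parameter names (fields of
#'   [epi_params()] or [cell_params()]).
#' @param cp,ep Baseline parameter objects.
#' @param dose Constant dose.
#' @param perturbation Relative perturbation (default 0.2).
#' @param t_end Horizon in days.
#' @param grid A [pop_grid()].
#' @return data.frame with one row per parameter: relative changes of
#'   `Q_hat(t_end)` and final `P_resistant` for the down/up perturbations.
#' @export
sensitivity_oat <- function(params, cp, ep, dose = 0.3, perturbation = 0.2,
                            t_end = 60, grid = pop_grid(40, 40)) {
  run_outputs <- function(ep_i, cp_i) {
    init <- equilibrium_population(ep_i, cp_i, grid)
    sched <- dose_schedule("constant", c_const = dose)
    tr <- simulate_population(ep_i, cp_i, sched, t_end = t_end,
                              grid = grid, init = init)
    sc <- simulate_singlecell(ep_i, cp_i, sched, t_end = t_end, grid = grid)
    c(Qhat = tr$Qhat_fine[length(tr$Qhat_fine)],
      P_res = sc$summary$P_resistant[nrow(sc$summary)])
  }
  base <- run_outputs(ep, cp)
  perturbed <- function(name, fac) {
    epl <- as.list(unclass(ep)); cpl <- as.list(unclass(cp))
    if (name %in% names(epl)) {
      epl[[name]] <- epl[[name]] * fac
      ep_i <- do.call(epi_params, epl); cp_i <- cp
    } else if (name %in% names(cpl)) {
      cpl[[name]] <- cpl[[name]] * fac
      cp_i <- do.call(cell_params, cpl); ep_i <- ep
    } else stop("unknown parameter: ", name, call. = FALSE)
    run_outputs(ep_i, cp_i)
  }
  rows <- lapply(params, function(nm) {
    up <- perturbed(nm, 1 + perturbation)
    dn <- perturbed(nm, 1 - perturbation)
    data.frame(param = nm,
               d_Qhat_up = up[["Qhat"]] / base[["Qhat"]] - 1,
               d_Qhat_down = dn[["Qhat"]] / base[["Qhat"]] - 1,
               d_Pres_up = up[["P_res"]] - base[["P_res"]],
               d_Pres_down = dn[["P_res"]] - base[["P_res"]])
  })
  do.call(rbind, rows)
}

#' Serialize a synthetic dataset to CSV
#'
#' `ctp_dataset`: columns `clone_id`, `ctp`, `arm`;
#' `kinetics_dataset`: columns `t`, `arm`, `rel_volume`.
#'
#' @param data A `ctp_dataset` or `kinetics_dataset`.
#' @param path Output file.
#' @export
write_dataset_csv <- function(data, path) {
  df <- if (inherits(data, "ctp_dataset")) {
    data.frame(clone_id = seq_len(length(data$control_ctps) +
                                    length(data$treated_ctps)),
               ctp = c(data$control_ctps, data$treated_ctps),
               arm = rep(c("control", "treated"),
                         c(length(data$control_ctps),
                           length(data$treated_ctps))))
  } else if (inherits(data, "kinetics_dataset")) {
    data.frame(t = rep(data$times, 2),
               arm = rep(c("vehicle", "treated"), each = length(data$times)),
               rel_volume = c(data$vehicle_rel_volume,
                              data$treated_rel_volume))
  } else stop("unsupported dataset class", call. = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a calibration result to JSON
#'
#' Parameter names match the flat config schema.
#'
#' @param fit A `calibration_result`.
#' @param path Output file.
#' @export
write_calibration_json <- function(fit, path) {
  pars <- c(if (!is.null(fit$ep)) unclass(fit$ep),
            if (!is.null(fit$cp)) unclass(fit$cp))
  jsonlite::write_json(c(pars, list(loss = fit$loss,
                                    converged = fit$converged)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
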