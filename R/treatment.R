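#' Simulate intermittent treatment to its stable cycle
#'
#' Runs the population model under the periodic schedule (`c_on` for
#' `tau_on` days, then `c_off` for `tau_off` days per cycle, starting at
#' the preheated state) cycle by cycle until the per-cycle maximum of the
#' relative tumor size changes by less than `conv_tol` (relative) for two
#' consecutive cycles. `tau_off = 0` degenerates to the constant high-dose
#' run. Feasibility of the schedule in the min-max sense is evaluated on
#' the converged cycle: the end-of-treatment size `Q_hat(m tau + tau_on)`
#' must be below the pre-treatment size `Q_hat(T0)`.
#'
#' @param ep,cp Parameter objects.
#' @param tau_on,tau_off Therapeutic / holiday days per cycle.
#' @param c_on,c_off On / off doses.
#' @param dt Time step; reduced to the stability bound if needed.
#' @param grid A [pop_grid()].
#' @param init Optional preheated [pop_state()] (skips the burn-in; it is
#'   rescaled to `q0 * K`).
#' @param q0 Pre-treatment density fraction.
#' @param max_cycles Convergence horizon.
#' @param conv_tol Relative change of cycle maxima declaring stability.
#' @return List of class `intermittent_run`: `summary` (`max_size`,
#'   `min_size`, `end_on_size`, `n_cycles_to_converge`, `converged`,
#'   `feasible`), `cycles` (per-cycle data.frame), `t`/`rel_size`
#'   (per-step trajectory) and the final [pop_state()].
#' @export
run_intermittent <- function(ep, cp, tau_on, tau_off, c_on = 0.9,
                             c_off = 0, dt = NULL, grid = pop_grid(60, 60),
                             init = NULL, q0 = NULL, max_cycles = 40,
                             conv_tol = 0.01) {
  q0 <- q0 %||% default_params()$q0
  if (is.null(init)) init <- preheat(ep, cp, grid = grid)$state
  g <- init$grid
  sched <- if (tau_off > 0) {
    dose_schedule("intermittent", tau_on = tau_on, tau_off = tau_off,
                  c_on = c_on, c_off = c_off, t0 = 0)
  } else {
    dose_schedule("constant", c_const = c_on, t0 = 0)
  }
  tau <- tau_on + tau_off
  dt <- min(dt %||% default_params()$dt,
            0.9 * cfl_dt(g, cp, c_max = max(c_on, c_off)))
  steps_cycle <- ceiling(tau / dt)
  dt <- tau / steps_cycle
  steps_on <- round(tau_on / dt)

  Q0 <- q0 * cp$K
  Q <- init$Q * (Q0 / (sum(init$Q) * g$dx * g$dy))
  rel_all <- 1
  cyc <- data.frame(cycle = integer(0), max_rel = numeric(0),
                    min_rel = numeric(0), end_on_rel = numeric(0))
  converged <- FALSE
  hit_prev <- FALSE
  m <- 0L
  while (m < max_cycles) {
    t_start <- m * tau
    doses <- dose_at(sched, t_start + (seq_len(steps_cycle) - 1) * dt)
    res <- evolve_core(Q, g, ep, cp, doses, dt, record_idx = integer(0))
    Q <- res$Q
    rel <- res$Qhat[-1] / Q0
    rel_all <- c(rel_all, rel)
    m <- m + 1L
    cyc <- rbind(cyc, data.frame(cycle = m, max_rel = max(rel),
                                 min_rel = min(rel),
                                 end_on_rel = rel[steps_on]))
    if (m >= 2L) {
      ch <- abs(cyc$max_rel[m] - cyc$max_rel[m - 1]) / cyc$max_rel[m - 1]
      if (ch < conv_tol) {
        if (hit_prev) { converged <- TRUE; break }
        hit_prev <- TRUE
      } else hit_prev <- FALSE
    }
  }
  last <- nrow(cyc)
  out <- list(
    summary = list(max_size = cyc$max_rel[last], min_size = cyc$min_rel[last],
                   end_on_size = cyc$end_on_rel[last],
                   n_cycles_to_converge = last, converged = converged,
                   feasible = converged && cyc$end_on_rel[last] < 1),
    cycles = cyc,
    t = (seq_along(rel_all) - 1) * dt,
    rel_size = rel_all,
    final = pop_state(Q, g, last * tau),
    schedule = sched, dt = dt
  )
  class(out) <- "intermittent_run"
  out
}

#' @export
print.intermittent_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<intermittent_run> %d cycles%s; stable-cycle size in [%.3g, %.3g], end-of-on %.3g (%s)\n",
              s$n_cycles_to_converge,
              if (s$converged) "" else " (NOT converged)",
              s$min_size, s$max_size, s$end_on_size,
              if (s$feasible) "feasible" else "infeasible"))
  invisible(x)
}

#' Min-max optimization of the intermittent schedule
#'
#' For every `(tau_on, tau_off)` grid point, runs [run_intermittent()] and
#' records the maximum relative tumor size over the converged cycle. The
#' optimum minimizes this maximum among feasible schedules (those whose
#' end-of-treatment size stays below the pre-treatment size); ties are
#' broken toward the larger holiday (equal tumor control with less drug).
#'
#' @param ep,cp Parameter objects.
#' @param tau_on_grid,tau_off_grid Integer-day grids.
#' @param ... Passed to [run_intermittent()] (`grid`, `dt`, `q0`, ...).
#' @param init Optional preheated [pop_state()]; computed once otherwise.
#' @param grid A [pop_grid()] used for all runs.
#' @return List of class `schedule_grid`: `table` (long data.frame
#'   `tau_on`, `tau_off`, `max_size`, `min_size`, `end_on_size`,
#'   `converged`, `feasible`) and `optimum` (row of the best feasible
#'   schedule, or NULL if the feasible set is empty).
#' @export
optimize_schedule <- function(ep, cp, tau_on_grid = 1:21,
                              tau_off_grid = 0:21, grid = pop_grid(60, 60),
                              init = NULL, ...) {
  if (is.null(init)) init <- preheat(ep, cp, grid = grid)$state
  rows <- vector("list", length(tau_on_grid) * length(tau_off_grid))
  k <- 0L
  for (ton in tau_on_grid) for (toff in tau_off_grid) {
    r <- run_intermittent(ep, cp, tau_on = ton, tau_off = toff,
                          grid = grid, init = init, ...)
    k <- k + 1L
    rows[[k]] <- data.frame(tau_on = ton, tau_off = toff,
                            max_size = r$summary$max_size,
                            min_size = r$summary$min_size,
                            end_on_size = r$summary$end_on_size,
                            converged = r$summary$converged,
                            feasible = r$summary$feasible)
  }
  tab <- do.call(rbind, rows)
  feas <- tab[tab$feasible, , drop = FALSE]
  optimum <- NULL
  if (nrow(feas)) {
    ## minimize max_size; ties toward larger tau_off
    feas <- feas[order(feas$max_size, -feas$tau_off), , drop = FALSE]
    optimum <- feas[1, ]
  }
  structure(list(table = tab, optimum = optimum), class = "schedule_grid")
}

#' @export
print.schedule_grid <- function(x, ...) {
  cat(sprintf("<schedule_grid> %d schedules, %d feasible\n",
              nrow(x$table), sum(x$table$feasible)))
  if (!is.null(x$optimum)) {
    cat(sprintf("  optimum: tau_on = %g d, tau_off = %g d, max size %.3g\n",
                x$optimum$tau_on, x$optimum$tau_off, x$optimum$max_size))
  } else cat("  feasible set empty\n")
  invisible(x)
}

## first time the relative size re-attains 1 after its nadir
recovery_time <- function(t, rel) {
  i_nadir <- which.min(rel)
  after <- which(rel[i_nadir:length(rel)] >= 1)
  if (!length(after)) return(NA_real_)
  t[i_nadir + after[1] - 1]
}

#' Epigenetic-noise sweep
#'
#' Reruns the population and single-cell models over a grid of `eta0`
#' values (epigenetic instability `1/eta0`). Under a constant dose the
#' population run reports the tumor recovery time (first return of the
#' relative size to 1 after the nadir); under an intermittent schedule it
#' reports the stable-cycle maximum size. The single-cell model reports
#' the final drug-resistant probability in both cases.
#'
#' @param ep_base,cp Parameter objects (`eta0` in `ep_base` is swept).
#' @param eta0_values Positive `eta0` grid.
#' @param schedule A [dose_schedule()] (constant or intermittent).
#' @param t_end Horizon for the constant-dose population run and the
#'   single-cell run.
#' @param grid A [pop_grid()].
#' @param dt Optional time step.
#' @return data.frame `eta0`, `recovery_time`, `max_size`,
#'   `P_resistant_final`.
#' @export
noise_sweep <- function(ep_base, cp, eta0_values, schedule, t_end = 120,
                        grid = pop_grid(60, 60), dt = NULL) {
  rows <- lapply(eta0_values, function(e0) {
    ep <- epi_params(phi0 = ep_base$phi0, phi1 = ep_base$phi1,
                     alpha0 = ep_base$alpha0, k = ep_base$k,
                     n = ep_base$n, eta0 = e0)
    ph <- preheat(ep, cp, grid = grid)$state
    if (schedule$mode == "constant") {
      tr <- simulate_population(ep, cp, schedule, t_end = t_end, dt = dt,
                                grid = grid, init = ph)
      rec <- recovery_time(tr$t_fine, tr$Qhat_fine / tr$Q0)
      mx <- NA_real_
    } else {
      ir <- run_intermittent(ep, cp, tau_on = schedule$tau_on,
                             tau_off = schedule$tau_off,
                             c_on = schedule$c_on, c_off = schedule$c_off,
                             dt = dt, grid = grid, init = ph)
      rec <- NA_real_
      mx <- ir$summary$max_size
    }
    sc <- simulate_singlecell(ep, cp, schedule, t_end = t_end, dt = dt,
                              grid = grid)
    data.frame(eta0 = e0, recovery_time = rec, max_size = mx,
               P_resistant_final = sc$summary$P_resistant[nrow(sc$summary)])
  })
  do.call(rbind, rows)
}

#' Selection-strength sweep
#'
#' Jointly scales `alpha0` and `k` (lowering the scale lowers the
#' inheritance probability of a high CTP level for daughters) and reports
#' the final drug-resistant probability of the single-cell model.
#'
#' @param ep_base,cp Parameter objects.
#' @param alpha_scale_values Positive scale factors (1 = baseline).
#' @param schedule A [dose_schedule()].
#' @param t_end Single-cell horizon in days.
#' @param grid A [pop_grid()].
#' @param dt Optional time step.
#' @return data.frame `alpha_scale`, `P_resistant_final`.
#' @export
alpha_sweep <- function(ep_base, cp, alpha_scale_values, schedule,
                        t_end = 120, grid = pop_grid(60, 60), dt = NULL) {
  rows <- lapply(alpha_scale_values, function(sc) {
    ep <- epi_params(phi0 = ep_base$phi0, phi1 = ep_base$phi1,
                     alpha0 = sc * ep_base$alpha0, k = sc * ep_base$k,
                     n = ep_base$n, eta0 = ep_base$eta0)
    tr <- simulate_singlecell(ep, cp, schedule, t_end = t_end, dt = dt,
                              grid = grid)
    data.frame(alpha_scale = sc,
               P_resistant_final = tr$summary$P_resistant[nrow(tr$summary)])
  })
  do.call(rbind, rows)
}
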