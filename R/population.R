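#' Cell-centered grid on the unit square
#'
#' Nodes `x_i = (i - 0.5)/nx`, `y_j = (j - 0.5)/ny` lie strictly inside
#' (0,1). With even `nx`, `ny` no node coincides with the classification
#' thresholds 0.15 and 0.5, so threshold ties never arise.
#'
#' @param nx,ny Number of CTP / phenotype nodes (even, >= 10).
#' @return An object of class `pop_grid` with nodes and spacings.
#' @export
pop_grid <- function(nx = 100, ny = 100) {
  stopifnot(nx >= 10, ny >= 10, nx %% 2 == 0, ny %% 2 == 0)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 x = (seq_len(nx) - 0.5) / nx, y = (seq_len(ny) - 0.5) / ny,
                 dx = 1 / nx, dy = 1 / ny),
            class = "pop_grid")
}

#' Population state Q(x, y, t)
#'
#' @param Q Nonnegative `nx x ny` matrix of cell numbers per unit (x,y)
#'   area (rows index CTP, columns phenotype).
#' @param grid A [pop_grid()] matching `dim(Q)`.
#' @param t Time in days.
#' @return An object of class `pop_state`; `Q_hat` is the total cell
#'   number (midpoint quadrature of Q).
#' @export
pop_state <- function(Q, grid, t = 0) {
  stopifnot(inherits(grid, "pop_grid"),
            is.matrix(Q), nrow(Q) == grid$nx, ncol(Q) == grid$ny,
            all(is.finite(Q)), all(Q >= 0))
  structure(list(Q = Q, grid = grid, t = t,
                 Q_hat = sum(Q) * grid$dx * grid$dy),
            class = "pop_state")
}

#' @export
print.pop_state <- function(x, ...) {
  cat(sprintf("<pop_state> %dx%d grid, t = %.3g d, Q_hat = %.6g\n",
              x$grid$nx, x$grid$ny, x$t, x$Q_hat))
  invisible(x)
}

#' Default initial condition
#'
#' Truncated Gaussian bump centered at the drug-free phenotype equilibrium
#' and a low CTP level, normalized to total mass `Q_hat`.
#'
#' @param grid A [pop_grid()].
#' @param Q_hat Total initial cell number.
#' @param x0,y0,w Bump center and width (defaults from [default_params()]).
#' @return A [pop_state()].
#' @export
initial_state <- function(grid, Q_hat = 1,
                          x0 = NULL, y0 = NULL, w = NULL) {
  d <- default_params()
  x0 <- x0 %||% d$init_x0; y0 <- y0 %||% d$init_y0; w <- w %||% d$init_w
  Q <- outer(exp(-(grid$x - x0)^2 / (2 * w^2)),
             exp(-(grid$y - y0)^2 / (2 * w^2)))
  Q <- Q * Q_hat / (sum(Q) * grid$dx * grid$dy)
  pop_state(Q, grid, t = 0)
}

#' Discrete inheritance-kernel matrix
#'
#' `P[i, l] = p(x_i, z_l)` on the grid nodes, with each column rescaled so
#' that `colSums(P) * dx = 1`: the discrete kernel then conserves
#' probability in the mitosis redistribution exactly, mirroring the
#' analytic normalization of the inheritance density.
#'
#' @param x Grid nodes (from [pop_grid()]).
#' @param alpha Selection strength at the current dose.
#' @param ep An [epi_params()].
#' @return `nx x nx` matrix (daughter index by mother index).
#' @export
kernel_matrix <- function(x, alpha, ep) {
  nx <- length(x)
  dx <- 1 / nx
  P <- vapply(x, function(z) inheritance_density(x, z, alpha, ep),
              numeric(nx))
  P / rep(colSums(P) * dx, each = nx)
}

#' Explicit-stability bound on the time step
#'
#' `dt <= min(dy / max|v|, dy^2 / (2 sigma), 1/max gamma, 1/max beta1)`:
#' upwind advection, explicit diffusion, and the Euler death/mitosis
#' factors all stay positivity-preserving below this bound.
#'
#' @param grid A [pop_grid()].
#' @param cp A [cell_params()].
#' @param c_max Largest dose the run will use.
#' @return Maximal stable `dt` in days.
#' @export
cfl_dt <- function(grid, cp, c_max = 1) {
  vmax <- cp$v0 * max(max(0, 1 - cp$y0_off), c_max * max(0, cp$y0_on))
  bounds <- c(if (vmax > 0) grid$dy / vmax,
              if (cp$sigma > 0) grid$dy^2 / (2 * cp$sigma),
              1 / max(death_rate(grid$y, c_max, cp)),
              1 / max(beta1(grid$x, cp)))
  min(bounds)
}

## One splitting substep each: upwind y-advection with reflecting walls.
advect_y <- function(Q, vface, dt, dy) {
  ny <- ncol(Q)
  Fl <- pmax(vface, 0) * Q[, -ny, drop = FALSE] +
        pmin(vface, 0) * Q[, -1, drop = FALSE]
  Q + (dt / dy) * (cbind(0, Fl) - cbind(Fl, 0))
}

## Zero-flux explicit diffusion in y.
diffuse_y <- function(Q, sigma, dt, dy) {
  if (sigma <= 0) return(Q)
  ny <- ncol(Q)
  lap <- cbind(Q[, 1], Q[, -ny, drop = FALSE]) - 2 * Q +
         cbind(Q[, -1, drop = FALSE], Q[, ny])
  Q + (sigma * dt / dy^2) * lap
}

#' Advance the population state by one time step
#'
#' Reference (pure R) implementation of the operator-split explicit scheme:
#' (i) upwind advection of the phenotype with the stress-adaptation drift,
#' (ii) explicit zero-flux diffusion, (iii) Euler death sink, (iv) mitosis
#' redistribution `2 P (beta * Q) - beta * Q` through the discrete
#' inheritance kernel. The compiled driver used by [simulate_population()]
#' performs the identical arithmetic; this function is its oracle and the
#' convenient single-step entry point.
#'
#' @param state A [pop_state()].
#' @param ep,cp Parameter objects.
#' @param schedule A [dose_schedule()] (dose is evaluated at `state$t`).
#' @param dt Time step in days; must satisfy [cfl_dt()].
#' @param P Optional precomputed [kernel_matrix()] for the current dose.
#' @return The advanced [pop_state()].
#' @export
step_population <- function(state, ep, cp, schedule, dt, P = NULL) {
  g <- state$grid
  c_now <- dose_at(schedule, state$t)
  if (dt > cfl_dt(g, cp, c_max = c_now) * (1 + 1e-9))
    stop(sprintf("dt = %g violates the stability bound %g", dt,
                 cfl_dt(g, cp, c_max = c_now)), call. = FALSE)
  if (is.null(P)) P <- kernel_matrix(g$x, alpha_of_dose(ep, c_now), ep)

  yface <- g$y[-g$ny] + g$dy / 2
  vface <- outer(g$x, yface, function(x, y) adaptation_velocity(x, y, c_now, cp))
  Q <- advect_y(state$Q, vface, dt, g$dy)
  Q <- diffuse_y(Q, cp$sigma, dt, g$dy)
  Q <- Q * rep(1 - dt * death_rate(g$y, c_now, cp), each = g$nx)
  Qhat <- sum(Q) * g$dx * g$dy
  b <- beta1(g$x, cp) * max(0, 1 - Qhat / cp$K)
  BQ <- Q * b
  Q <- Q + dt * (2 * g$dx * (P %*% BQ) - BQ)
  if (anyNA(Q) || min(Q) < -1e-12 * max(abs(Q)))
    stop("population step produced NaN or negative mass", call. = FALSE)
  Q[Q < 0] <- 0
  pop_state(Q, g, state$t + dt)
}

#' Analytic rate of change of the total population
#'
#' Midpoint quadrature of `(beta(x, Q_hat) - gamma(y, c)) * Q`: the mitosis
#' redistribution conserves the integral except for the net `+beta Q` from
#' each division (one mother removed, two daughters added), and the
#' reflecting barrier kills the flux terms.
#'
#' @inheritParams step_population
#' @return `dQ_hat/dt` (cells/day).
#' @export
total_population_derivative <- function(state, ep, cp, schedule) {
  g <- state$grid
  c_now <- dose_at(schedule, state$t)
  b <- beta1(g$x, cp) * max(0, 1 - state$Q_hat / cp$K)
  gam <- death_rate(g$y, c_now, cp)
  sum((b - rep(gam, each = g$nx)) * state$Q) * g$dx * g$dy
}

## Compiled multi-step driver shared by simulate/preheat/intermittent.
## Returns per-step Q_hat, recorded fractions/marginals, and the final Q.
evolve_core <- function(Q, grid, ep, cp, doses, dt, record_idx,
                        x_c = 0.15, y_c = 0.5, renorm_to = -1) {
  uq <- sort(unique(doses))
  Pcube <- array(0, dim = c(grid$nx, grid$nx, length(uq)))
  for (i in seq_along(uq))
    Pcube[, , i] <- kernel_matrix(grid$x, alpha_of_dose(ep, uq[i]), ep)
  dose_idx <- match(doses, uq)
  res <- evolve_pop_cpp(Q, grid$x, grid$y, dt, doses, dose_idx, Pcube,
                        beta1(grid$x, cp),
                        c(cp$gamma0, cp$gamma1, cp$y_star,
                          cp$v0, cp$sigma, cp$y0_on, cp$y0_off, cp$K),
                        as.integer(record_idx), x_c, y_c, renorm_to)
  res
}

#' Drug-free burn-in to the stationary CTP distribution
#'
#' Integrates the model without drug until the normalized CTP marginal
#' changes by less than `tol` (L1 norm) per day. The *normalized* density
#' is evolved (total mass is rescaled each day): the stationary marginal
#' shape is invariant to the uniform logistic crowding factor, and
#' decoupling the distributional burn-in from population growth lets
#' [simulate_population()] place the pre-treatment size `Q_hat(T0)`
#' independently (config `q0`). The preheating time `T0` is the elapsed
#' time at which stationarity is reached.
#'
#' @param ep,cp Parameter objects.
#' @param init Optional initial [pop_state()]; default [initial_state()].
#' @param tol L1 change of the CTP marginal per day declaring stationarity.
#' @param grid A [pop_grid()] (used when `init` is NULL).
#' @param dt Time step; default 90% of the stability bound.
#' @param max_days Give up (with a warning) after this horizon.
#' @return List with the settled `state` (unit total mass), `T0` in days,
#'   the stationary CTP `marginal` (density on `grid$x`), and `converged`.
#' @export
preheat <- function(ep, cp, init = NULL, tol = 1e-3, grid = pop_grid(),
                    dt = NULL, max_days = 400) {
  if (is.null(init)) init <- initial_state(grid, Q_hat = 1)
  g <- init$grid
  dt <- dt %||% (0.9 * cfl_dt(g, cp, c_max = 0))
  steps_day <- max(1L, ceiling(1 / dt))
  dt <- 1 / steps_day
  ## burn in at negligible density so the crowding factor stays ~1; the
  ## stationary marginal shape is invariant to that uniform factor
  mass_ref <- 1e-6 * cp$K
  Q <- init$Q * mass_ref / (sum(init$Q) * g$dx * g$dy)
  marg <- function(Q) {
    m <- rowSums(Q) * g$dy
    m / (sum(m) * g$dx)
  }
  m_prev <- marg(Q)
  ## quick exit for an already-stationary input: one-step drift, per day
  one <- evolve_core(Q, g, ep, cp, doses = 0, dt = dt,
                     record_idx = integer(0), renorm_to = mass_ref)
  if (sum(abs(marg(one$Q) - m_prev)) * g$dx / dt < tol) {
    return(list(state = pop_state(Q, g, 0), T0 = 0, marginal = m_prev,
                converged = TRUE))
  }
  t_el <- 0
  converged <- FALSE
  while (t_el < max_days) {
    res <- evolve_core(Q, g, ep, cp, doses = rep(0, steps_day), dt = dt,
                       record_idx = integer(0), renorm_to = mass_ref)
    Q <- res$Q
    t_el <- t_el + 1
    m_now <- marg(Q)
    if (sum(abs(m_now - m_prev)) * g$dx < tol) {
      converged <- TRUE
      m_prev <- m_now
      break
    }
    m_prev <- m_now
  }
  if (!converged)
    warning(sprintf("CTP marginal not stationary within %g days", max_days))
  list(state = pop_state(Q, g, 0), T0 = t_el, marginal = m_prev,
       converged = converged)
}

#' Simulate the population model under a dosing schedule
#'
#' Runs the finite-volume solver from the preheated drug-free state.
#' Time 0 is the preheating time `T0`: the preheated distribution is scaled
#' to `Q_hat(0) = q0 * K` and the relative tumor size is reported as
#' `Q_hat(t) / Q_hat(0)`.
#'
#' @param ep,cp Parameter objects.
#' @param schedule A [dose_schedule()] (its `t0` is relative to `T0`).
#' @param t_end Final time in days.
#' @param dt Requested step; reduced to the stability bound if needed.
#' @param record_every Spacing of recorded snapshots, days.
#' @param grid A [pop_grid()].
#' @param init Optional preheated [pop_state()] (any total mass; it is
#'   rescaled to `q0 * K`). Supplying it skips the burn-in.
#' @param q0 Pre-treatment density fraction `Q_hat(T0)/K`.
#' @param preheat_tol Tolerance passed to [preheat()].
#' @return An object of class `pop_trajectory`: a list with `summary`
#'   (data.frame `t`, `Q_hat`, `rel_size`, `frac_naive`, `frac_dtp`,
#'   `frac_resistant`), `marginals` (CTP marginal per snapshot), `t_fine`
#'   and `Qhat_fine` (per-step total size), `final` state, and `Q0`.
#' @export
simulate_population <- function(ep, cp, schedule, t_end, dt = NULL,
                                record_every = 0.5, grid = pop_grid(),
                                init = NULL, q0 = NULL,
                                preheat_tol = 1e-3) {
  q0 <- q0 %||% default_params()$q0
  if (is.null(init)) {
    init <- preheat(ep, cp, grid = grid, tol = preheat_tol)$state
  }
  g <- init$grid
  c_max <- switch(schedule$mode, constant = schedule$c_const,
                  intermittent = max(schedule$c_on, schedule$c_off))
  dt_max <- 0.9 * cfl_dt(g, cp, c_max = c_max)
  dt <- min(dt %||% default_params()$dt, dt_max)
  nsteps <- ceiling(t_end / dt)
  dt <- t_end / nsteps
  tgrid <- (seq_len(nsteps) - 1) * dt
  doses <- dose_at(schedule, tgrid)
  every <- max(1L, round(record_every / dt))
  record_idx <- unique(c(seq(every, nsteps, by = every), nsteps))

  Q0 <- q0 * cp$K
  Q <- init$Q * (Q0 / (sum(init$Q) * g$dx * g$dy))
  res <- evolve_core(Q, g, ep, cp, doses, dt, record_idx)

  t_rec <- record_idx * dt
  fr <- res$frac
  out <- list(
    summary = data.frame(t = c(0, t_rec),
                         Q_hat = c(Q0, res$Qhat[record_idx + 1]),
                         rel_size = c(Q0, res$Qhat[record_idx + 1]) / Q0,
                         frac_naive = c(classify_fractions(pop_state(Q, g))["naive"], fr[, 1]),
                         frac_dtp = c(classify_fractions(pop_state(Q, g))["dtp"], fr[, 2]),
                         frac_resistant = c(classify_fractions(pop_state(Q, g))["resistant"], fr[, 3]),
                         row.names = NULL),
    marginals = res$marg,
    t_fine = c(0, seq_len(nsteps) * dt),
    Qhat_fine = res$Qhat,
    final = pop_state(res$Q, g, t_end),
    Q0 = Q0, dt = dt
  )
  class(out) <- "pop_trajectory"
  out
}

#' @export
print.pop_trajectory <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<pop_trajectory> %d snapshots to t = %.4g d (dt = %.4g)\n",
              nrow(s), max(s$t), x$dt))
  cat(sprintf("  rel_size: start %.3g, min %.3g, end %.3g\n",
              s$rel_size[1], min(s$rel_size), s$rel_size[nrow(s)]))
  cat(sprintf("  final fractions: naive %.3f, DTP %.3f, resistant %.3f\n",
              s$frac_naive[nrow(s)], s$frac_dtp[nrow(s)],
              s$frac_resistant[nrow(s)]))
  invisible(x)
}

#' Classify the population into naive / DTP / resistant fractions
#'
#' Drug-naive: `y < y_c`; DTP: `y > y_c, x > x_c`; drug-resistant:
#' `y > y_c, x < x_c` (defaults `x_c = 0.15`, `y_c = 0.5`). Cell-centered
#' even grids place no node on a threshold.
#'
#' @param state A [pop_state()] with positive total mass.
#' @param thresholds Named vector with `x_c` and `y_c`.
#' @return Named numeric vector `naive`, `dtp`, `resistant` summing to 1.
#' @export
classify_fractions <- function(state, thresholds = c(x_c = 0.15, y_c = 0.5)) {
  if (state$Q_hat <= 0) stop("classification undefined for empty population",
                             call. = FALSE)
  g <- state$grid
  xc <- thresholds[["x_c"]]; yc <- thresholds[["y_c"]]
  lo_y <- g$y < yc
  hi_x <- g$x > xc
  tot <- sum(state$Q)
  naive <- sum(state$Q[, lo_y])
  dtp <- sum(state$Q[hi_x, !lo_y])
  res <- sum(state$Q[!hi_x, !lo_y])
  c(naive = naive, dtp = dtp, resistant = res) / tot
}

#' Write a trajectory summary to CSV
#'
#' Tidy columns `t, Q_hat, rel_size, frac_naive, frac_dtp, frac_resistant`.
#'
#' @param traj A `pop_trajectory`.
#' @param path Output file.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(traj$summary, path, row.names = FALSE)
  invisible(path)
}
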