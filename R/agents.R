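#' Agent population
#'
#' A stochastic population of individual cells carrying a CTP value `x` and
#' a phenotype `y`. `weight` maps cell counts onto the population-model
#' scale: the crowding feedback uses `Q_hat = N * weight`.
#'
#' @param x,y Numeric vectors of equal length with coordinates in (0,1) /
#'   `[0,1]`.
#' @param t Time in days.
#' @param weight Population mass per agent.
#' @return An object of class `agent_population`.
#' @export
agent_population <- function(x, y, t = 0, weight = 1) {
  stopifnot(length(x) == length(y), all(x > 0 & x < 1), all(y >= 0 & y <= 1))
  structure(list(x = x, y = y, t = t, weight = weight),
            class = "agent_population")
}

#' @export
print.agent_population <- function(x, ...) {
  cat(sprintf("<agent_population> %d cells at t = %.3g d (Q_hat = %.4g)\n",
              length(x$x), x$t, length(x$x) * x$weight))
  invisible(x)
}

## fold y back into [0,1]; at most a handful of folds are ever needed for
## CFL-scale steps, but loop until inside for safety
reflect01 <- function(y) {
  while (any(bad <- (y < 0 | y > 1))) {
    y[bad] <- ifelse(y[bad] < 0, -y[bad], 2 - y[bad])
  }
  y
}

#' Advance the agent population by one time step
#'
#' Synchronous update: with the start-of-step total `Q_hat = N * weight`,
#' each cell divides with probability `beta(x, Q_hat) dt`, dies with
#' probability `gamma(y, c) dt`, and otherwise rests. A dividing mother is
#' replaced by two daughters whose CTP values are drawn from the
#' inheritance kernel and whose phenotype is the mother's. A resting
#' cell's phenotype takes an Euler-Maruyama step
#' `y <- y + v dt + sqrt(2 sigma dt) xi` and is folded back into `[0,1]`
#' (the reflecting barrier). Uses R's global RNG.
#'
#' @param pop An [agent_population()].
#' @param ep,cp Parameter objects.
#' @param schedule A [dose_schedule()] (dose evaluated at `pop$t`).
#' @param dt Time step; `max(beta) dt + max(gamma) dt` must stay below 1.
#' @return The advanced [agent_population()].
#' @export
step_agents <- function(pop, ep, cp, schedule, dt) {
  c_now <- dose_at(schedule, pop$t)
  N <- length(pop$x)
  if (N == 0L) return(agent_population(numeric(0), numeric(0), pop$t + dt,
                                       pop$weight))
  Qhat <- N * pop$weight
  p_div <- beta_rate(pop$x, Qhat, cp) * dt
  p_die <- death_rate(pop$y, c_now, cp) * dt
  if (max(p_div) + max(p_die) >= 1)
    stop("dt too large: event probabilities exceed 1", call. = FALSE)
  u <- stats::runif(N)
  divides <- u < p_div
  dies <- !divides & u < p_div + p_die
  rests <- !divides & !dies

  ## resting cells: phenotype SDE with reflection
  xr <- pop$x[rests]; yr <- pop$y[rests]
  if (length(yr)) {
    yr <- yr + adaptation_velocity(xr, yr, c_now, cp) * dt +
      sqrt(2 * cp$sigma * dt) * stats::rnorm(length(yr))
    yr <- reflect01(yr)
  }

  ## dividing cells: two daughters each, phenotype inherited
  xm <- pop$x[divides]; ym <- pop$y[divides]
  if (length(xm)) {
    alpha <- alpha_of_dose(ep, c_now)
    xd <- sample_daughter_ctp(2 * length(xm), rep(xm, 2), alpha, ep)
    xd <- pmin(pmax(xd, 1e-12), 1 - 1e-12)
    yd <- rep(ym, 2)
  } else {
    xd <- numeric(0); yd <- numeric(0)
  }

  agent_population(c(xr, xd), c(yr, yd), pop$t + dt, pop$weight)
}

#' Run the agent-based simulation
#'
#' Full stochastic trajectory with the same classification thresholds as
#' the population model. Extinction is a valid terminal outcome and is
#' flagged.
#'
#' @param ep,cp Parameter objects.
#' @param schedule A [dose_schedule()].
#' @param n0 Initial number of cells (>= 1).
#' @param t_end Final time in days.
#' @param dt Time step (default 0.01 day).
#' @param seed Integer seed for reproducibility.
#' @param init Optional [agent_population()] (overrides `n0`); default
#'   cells are drawn from the drug-free equilibrium density.
#' @param weight Population mass per agent; default `q0 * K / n0` so the
#'   crowding feedback matches the PDE initial condition.
#' @param record_every Snapshot spacing, days.
#' @return List of class `agent_trajectory` with `summary` (data.frame
#'   `t`, `N`, `Q_hat`, `frac_naive`, `frac_dtp`, `frac_resistant`),
#'   `extinct` flag and the final [agent_population()].
#' @export
run_agents <- function(ep, cp, schedule, n0, t_end, dt = 0.01, seed = 1,
                       init = NULL, weight = NULL, record_every = 0.5) {
  set.seed(seed)
  if (is.null(init)) {
    eq <- equilibrium_density(ep, cp, grid = pop_grid(60, 60))
    gr <- eq$grid
    ix <- sample.int(gr$nx, n0, replace = TRUE, prob = eq$g)
    x0 <- gr$x[ix] + stats::runif(n0, -gr$dx / 2, gr$dx / 2)
    y0 <- vapply(ix, function(i)
      gr$y[sample.int(gr$ny, 1, prob = eq$h[i, ])], numeric(1))
    y0 <- y0 + stats::runif(n0, -gr$dy / 2, gr$dy / 2)
    init <- agent_population(pmin(pmax(x0, 1e-6), 1 - 1e-6),
                             reflect01(y0), 0,
                             weight %||% (default_params()$q0 * cp$K / n0))
  }
  pop <- init
  nsteps <- ceiling(t_end / dt)
  dt <- t_end / nsteps
  every <- max(1L, round(record_every / dt))
  frac_of <- function(pop) {
    N <- length(pop$x)
    if (N == 0L) return(c(NA_real_, NA_real_, NA_real_))
    hi <- pop$y > 0.5
    c(sum(!hi), sum(hi & pop$x > 0.15), sum(hi & pop$x < 0.15)) / N
  }
  rec <- data.frame(t = 0, N = length(pop$x),
                    Q_hat = length(pop$x) * pop$weight,
                    frac_naive = frac_of(pop)[1], frac_dtp = frac_of(pop)[2],
                    frac_resistant = frac_of(pop)[3])
  for (s in seq_len(nsteps)) {
    pop <- step_agents(pop, ep, cp, schedule, dt)
    if (s %% every == 0 || s == nsteps || length(pop$x) == 0L) {
      fr <- frac_of(pop)
      rec <- rbind(rec, data.frame(t = s * dt, N = length(pop$x),
                                   Q_hat = length(pop$x) * pop$weight,
                                   frac_naive = fr[1], frac_dtp = fr[2],
                                   frac_resistant = fr[3]))
      if (length(pop$x) == 0L) break
    }
  }
  out <- list(summary = rec, extinct = length(pop$x) == 0L, final = pop,
              seed = seed, dt = dt)
  class(out) <- "agent_trajectory"
  out
}

#' @export
print.agent_trajectory <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<agent_trajectory> %d -> %d cells over %.4g d%s\n",
              s$N[1], s$N[nrow(s)], max(s$t),
              if (x$extinct) " (extinct)" else ""))
  invisible(x)
}

#' Sample an agent population from a population-model state
#'
#' Draws cells proportionally to the density `Q` with uniform jitter inside
#' each grid cell, so agent runs can start from exactly the state a
#' deterministic run uses (e.g. the preheated state). Uses R's global RNG.
#'
#' @param state A [pop_state()].
#' @param n0 Number of agents.
#' @param Q_hat Total population mass the agents represent (sets the
#'   per-agent weight); defaults to `state$Q_hat`.
#' @return An [agent_population()].
#' @export
sample_agents_from_state <- function(state, n0, Q_hat = NULL) {
  g <- state$grid
  w <- as.vector(state$Q)
  idx <- sample.int(length(w), n0, replace = TRUE, prob = w)
  x <- g$x[row(state$Q)][idx] + stats::runif(n0, -g$dx / 2, g$dx / 2)
  y <- g$y[col(state$Q)][idx] + stats::runif(n0, -g$dy / 2, g$dy / 2)
  agent_population(pmin(pmax(x, 1e-9), 1 - 1e-9), pmin(pmax(y, 0), 1),
                   t = state$t,
                   weight = (Q_hat %||% state$Q_hat) / n0)
}
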