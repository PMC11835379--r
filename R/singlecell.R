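#' Single-cell density state
#'
#' Factorized probability density `f(x, y, t) = h(y, t; x) g(x, t)`:
#' `g` is the marginal CTP density (integrates to 1 over x) and each row of
#' `h` the conditional phenotype density at one CTP node (integrates to 1
#' over y).
#'
#' @param g Numeric vector of length `nx`.
#' @param h `nx x ny` matrix, rows conditional densities in y.
#' @param grid A [pop_grid()].
#' @param t Time in days.
#' @return An object of class `density_state`.
#' @export
density_state <- function(g, h, grid, t = 0) {
  stopifnot(length(g) == grid$nx, nrow(h) == grid$nx, ncol(h) == grid$ny,
            all(g >= 0), all(h >= 0))
  if (abs(sum(g) * grid$dx - 1) > 1e-6)
    stop("g must integrate to 1", call. = FALSE)
  if (max(abs(rowSums(h) * grid$dy - 1)) > 1e-6)
    stop("every h(. ; x) must integrate to 1", call. = FALSE)
  structure(list(g = g, h = h, grid = grid, t = t), class = "density_state")
}

#' @export
print.density_state <- function(x, ...) {
  p <- cell_type_probabilities(x)
  cat(sprintf("<density_state> %dx%d grid, t = %.3g d\n",
              x$grid$nx, x$grid$ny, x$t))
  cat(sprintf("  P(naive) = %.3f, P(DTP) = %.3f, P(resistant) = %.3f\n",
              p[["naive"]], p[["dtp"]], p[["resistant"]]))
  invisible(x)
}

#' Convert a population state to a single-cell density
#'
#' `f = Q / Q_hat`, then `g = int f dy` and `h = f / g`. Where `g`
#' underflows (< 1e-12) the conditional density is set to uniform (it is
#' undefined on null sets).
#'
#' @param state A [pop_state()] with `Q_hat > 0`.
#' @return A [density_state()].
#' @export
density_from_population <- function(state) {
  if (state$Q_hat <= 0) stop("Q_hat = 0: density undefined", call. = FALSE)
  g0 <- state$grid
  f <- state$Q / state$Q_hat
  gx <- rowSums(f) * g0$dy
  h <- matrix(1, g0$nx, g0$ny)        # uniform density in y
  ok <- gx > 1e-12
  h[ok, ] <- f[ok, , drop = FALSE] / gx[ok]
  h <- h / (rowSums(h) * g0$dy)
  gx <- gx / (sum(gx) * g0$dx)
  density_state(gx, h, g0, state$t)
}

## Gibbs form of the stationary drift-diffusion balance at fixed x.
stationary_h_row <- function(x, c, cp, grid) {
  y0 <- if (c <= 1e-12) cp$y0_off else cp$y0_on
  rate <- if (c <= 1e-12) cp$v0 * x else cp$v0 * x * c
  if (cp$sigma <= 0 || rate <= 0) {
    h <- as.numeric(abs(grid$y - y0) == min(abs(grid$y - y0)))
  } else {
    h <- exp(-rate * (grid$y - y0)^2 / (2 * cp$sigma))
  }
  h / (sum(h) * grid$dy)
}

#' Drug-free equilibrium single-cell density
#'
#' `g` from [stationary_g()] and, for each CTP node, the exact stationary
#' phenotype density of the drift-diffusion balance (a Gaussian centered at
#' the drug-free equilibrium with variance `sigma / (v0 x)`).
#'
#' @param ep,cp Parameter objects.
#' @param grid A [pop_grid()].
#' @return A [density_state()].
#' @export
equilibrium_density <- function(ep, cp, grid = pop_grid()) {
  g <- stationary_g(ep, cp, dose = 0, grid = grid)
  h <- t(vapply(grid$x, stationary_h_row, numeric(grid$ny),
                c = 0, cp = cp, grid = grid))
  density_state(g, h, grid, t = 0)
}

#' Advance the conditional phenotype densities by one step
#'
#' Advection + diffusion in y (the same upwind / zero-flux scheme as the
#' population solver) followed by the relative-death reweighting
#' `-h (gamma - <gamma>)` with the population-average death rate
#' `<gamma> = int int gamma h g dx dy` evaluated with the lagged densities.
#' Each row is renormalized afterwards (the discretized equation preserves
#' the conditional normalization only approximately).
#'
#' @param h `nx x ny` matrix of conditional densities (all CTP nodes).
#' @param g CTP marginal used to weight the average death rate.
#' @param ep,cp Parameter objects.
#' @param c Current dose.
#' @param dt Time step (must satisfy [cfl_dt()]).
#' @param grid A [pop_grid()].
#' @return Updated `h` matrix.
#' @export
step_h <- function(h, g, ep, cp, c, dt, grid) {
  if (dt > cfl_dt(grid, cp, c_max = c) * (1 + 1e-9))
    stop("dt violates the stability bound", call. = FALSE)
  yface <- grid$y[-grid$ny] + grid$dy / 2
  vface <- outer(grid$x, yface, function(x, y) adaptation_velocity(x, y, c, cp))
  h2 <- advect_y(h, vface, dt, grid$dy)
  h2 <- diffuse_y(h2, cp$sigma, dt, grid$dy)
  gam <- death_rate(grid$y, c, cp)
  mean_gam <- sum((g * grid$dx) * (h %*% gam) * grid$dy)
  h2 <- h2 - dt * h2 * rep(gam - mean_gam, each = grid$nx)
  h2[h2 < 0] <- 0
  h2 / (rowSums(h2) * grid$dy)
}

#' Advance the marginal CTP density by one step
#'
#' Euler step of the proliferation-selection / inheritance dynamics
#' `dg/dt = 2 int beta1(z) g(z) p(x,z) dz - g (beta1 + <beta1>)`, which
#' conserves `int g dx` exactly on the renormalized discrete kernel.
#'
#' @param g CTP marginal density on `grid$x`.
#' @param ep,cp Parameter objects.
#' @param dose Current dose (sets the kernel via [alpha_of_dose()]).
#' @param dt Time step.
#' @param grid A [pop_grid()].
#' @param P Optional precomputed [kernel_matrix()].
#' @return Updated `g` vector.
#' @export
step_g <- function(g, ep, cp, dose, dt, grid, P = NULL) {
  if (is.null(P)) P <- kernel_matrix(grid$x, alpha_of_dose(ep, dose), ep)
  b <- beta1(grid$x, cp)
  mean_b <- sum(b * g) * grid$dx
  gnew <- g + dt * (2 * grid$dx * drop(P %*% (b * g)) - g * (b + mean_b))
  gnew[gnew < 0] <- 0
  gnew
}

#' Stationary drug-free CTP marginal
#'
#' The stationary density of the marginal dynamics is the Perron
#' eigenvector of the linear operator `L g = 2 int beta1 g p dz - beta1 g`
#' (the nonlinear `<beta1> g` term only fixes the normalization).
#'
#' @param ep,cp Parameter objects.
#' @param dose Dose defining the kernel (0 for the control condition).
#' @param grid A [pop_grid()].
#' @return Density vector on `grid$x` integrating to 1.
#' @export
stationary_g <- function(ep, cp, dose = 0, grid = pop_grid()) {
  P <- kernel_matrix(grid$x, alpha_of_dose(ep, dose), ep)
  b <- beta1(grid$x, cp)
  A <- 2 * grid$dx * P * rep(b, each = grid$nx) - diag(b)
  e <- eigen(A)
  i <- which.max(Re(e$values))
  v <- abs(Re(e$vectors[, i]))
  v / (sum(v) * grid$dx)
}

#' Simulate the single-cell density model
#'
#' Evolves `g` (inheritance/selection) and `h` (adaptation/diffusion/
#' relative death) with explicit lagged coupling from the drug-free
#' equilibrium, under an arbitrary dosing schedule. Cell-cell interactions
#' are ignored at this scale (`beta ~ beta1`).
#'
#' @param ep,cp Parameter objects.
#' @param schedule A [dose_schedule()] (time 0 is the preheating time).
#' @param t_end Final time in days.
#' @param dt Requested step; reduced to the stability bound if needed.
#' @param record_every Snapshot spacing, days.
#' @param grid A [pop_grid()] (60 x 60 is ample for the density model).
#' @param init Optional initial [density_state()].
#' @return List of class `sc_trajectory` with `summary` (data.frame `t`,
#'   `P_naive`, `P_dtp`, `P_resistant`), the final [density_state()], and
#'   the mean CTP per snapshot.
#' @export
simulate_singlecell <- function(ep, cp, schedule, t_end, dt = NULL,
                                record_every = 0.5, grid = pop_grid(60, 60),
                                init = NULL) {
  if (is.null(init)) init <- equilibrium_density(ep, cp, grid)
  g <- init$g; h <- init$h
  c_max <- switch(schedule$mode, constant = schedule$c_const,
                  intermittent = max(schedule$c_on, schedule$c_off))
  dt_max <- 0.9 * cfl_dt(grid, cp, c_max = c_max)
  dt <- min(dt %||% default_params()$dt, dt_max)
  nsteps <- ceiling(t_end / dt)
  dt <- t_end / nsteps
  doses <- dose_at(schedule, (seq_len(nsteps) - 1) * dt)
  uq <- sort(unique(doses))
  Pl <- lapply(uq, function(cc) kernel_matrix(grid$x, alpha_of_dose(ep, cc), ep))
  di <- match(doses, uq)
  every <- max(1L, round(record_every / dt))
  rec_t <- numeric(0); rec_p <- NULL; rec_mx <- numeric(0)
  probs <- function(g, h) {
    f_hi <- rowSums(h[, grid$y > 0.5, drop = FALSE]) * grid$dy
    p_dtp <- sum(g[grid$x > 0.15] * f_hi[grid$x > 0.15]) * grid$dx
    p_res <- sum(g[grid$x < 0.15] * f_hi[grid$x < 0.15]) * grid$dx
    c(naive = 1 - p_dtp - p_res, dtp = p_dtp, resistant = p_res)
  }
  rec_p <- matrix(0, 0, 3)
  rec_t <- 0; rec_p <- rbind(rec_p, probs(g, h)); rec_mx <- sum(grid$x * g) * grid$dx
  for (s in seq_len(nsteps)) {
    cc <- doses[s]
    h_new <- step_h(h, g, ep, cp, cc, dt, grid)
    g <- step_g(g, ep, cp, cc, dt, grid, P = Pl[[di[s]]])
    h <- h_new
    if (s %% every == 0 || s == nsteps) {
      rec_t <- c(rec_t, s * dt)
      rec_p <- rbind(rec_p, probs(g, h))
      rec_mx <- c(rec_mx, sum(grid$x * g) * grid$dx)
    }
  }
  out <- list(summary = data.frame(t = rec_t, P_naive = rec_p[, 1],
                                   P_dtp = rec_p[, 2],
                                   P_resistant = rec_p[, 3],
                                   row.names = NULL),
              mean_ctp = rec_mx,
              final = density_state(g / (sum(g) * grid$dx), h, grid, t_end),
              dt = dt)
  class(out) <- "sc_trajectory"
  out
}

#' @export
print.sc_trajectory <- function(x, ...) {
  s <- x$summary
  n <- nrow(s)
  cat(sprintf("<sc_trajectory> to t = %.4g d; final P: naive %.3f, DTP %.3f, resistant %.3f\n",
              max(s$t), s$P_naive[n], s$P_dtp[n], s$P_resistant[n]))
  invisible(x)
}

#' Cell-type probabilities from a density state
#'
#' Integrals of `f = h g` over the three classification regions
#' (naive `y < y_c`; DTP `y > y_c, x > x_c`; resistant `y > y_c, x < x_c`).
#'
#' @param ds A [density_state()].
#' @param thresholds Named vector with `x_c` and `y_c`.
#' @return Named vector `naive`, `dtp`, `resistant` summing to 1.
#' @export
cell_type_probabilities <- function(ds, thresholds = c(x_c = 0.15, y_c = 0.5)) {
  g0 <- ds$grid
  xc <- thresholds[["x_c"]]; yc <- thresholds[["y_c"]]
  w_hi <- rowSums(ds$h[, g0$y > yc, drop = FALSE]) * g0$dy
  w_lo <- rowSums(ds$h[, g0$y < yc, drop = FALSE]) * g0$dy
  gm <- ds$g * g0$dx
  c(naive = sum(gm * w_lo),
    dtp = sum(gm[g0$x > xc] * w_hi[g0$x > xc]),
    resistant = sum(gm[g0$x < xc] * w_hi[g0$x < xc]))
}

#' Survival curve at a fixed CTP level
#'
#' Freezes the CTP at `x_fixed` and evolves the unnormalized phenotype
#' density with the absolute death rate (advection + diffusion - gamma u);
#' the survival probability is the remaining mass `S(t) = int u dy`,
#' starting from the drug-free stationary phenotype density.
#'
#' @param x_fixed CTP value in (0,1).
#' @param ep,cp Parameter objects.
#' @param dose Constant dose applied from time 0.
#' @param t_end Final time in days.
#' @param dt Step size; reduced to the stability bound if needed.
#' @param grid A [pop_grid()] (only the y-axis is used).
#' @return data.frame with columns `t` and `S` (monotone checks aside,
#'   `S(0) = 1`).
#' @export
survival_curve <- function(x_fixed, ep, cp, dose, t_end, dt = NULL,
                           grid = pop_grid(60, 60)) {
  stopifnot(x_fixed > 0, x_fixed < 1)
  dt <- min(dt %||% default_params()$dt, 0.9 * cfl_dt(grid, cp, c_max = dose))
  nsteps <- ceiling(t_end / dt)
  dt <- t_end / nsteps
  u <- matrix(stationary_h_row(x_fixed, 0, cp, grid), nrow = 1)
  yface <- grid$y[-grid$ny] + grid$dy / 2
  vface <- matrix(adaptation_velocity(x_fixed, yface, dose, cp), nrow = 1)
  gam <- death_rate(grid$y, dose, cp)
  S <- numeric(nsteps + 1); S[1] <- 1
  for (s in seq_len(nsteps)) {
    u <- advect_y(u, vface, dt, grid$dy)
    u <- diffuse_y(u, cp$sigma, dt, grid$dy)
    u <- u * rep(1 - dt * gam, each = 1)
    S[s + 1] <- sum(u) * grid$dy
  }
  data.frame(t = (0:nsteps) * dt, S = S)
}
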