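// Multi-step driver for the operator-split population solver.
// Mirrors step_population() in R/population.R substep for substep; the R
// function is kept as the reference implementation and tested against this
// driver.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// cpv: gamma0, gamma1, y_star, v0, sigma, y0_on, y0_off, K
// [[Rcpp::export]]
List evolve_pop_cpp(const arma::mat& Q0, const arma::vec& x,
                    const arma::vec& y, double dt,
                    const arma::vec& doses, const arma::ivec& dose_idx,
                    const arma::cube& Pcube, const arma::vec& beta1v,
                    const arma::vec& cpv, const arma::ivec& record_idx,
                    double x_c, double y_c, double renorm_to) {
  const arma::uword nx = Q0.n_rows, ny = Q0.n_cols;
  const arma::uword nsteps = doses.n_elem;
  const double dx = 1.0 / nx, dy = 1.0 / ny;
  const double gamma0 = cpv(0), gamma1 = cpv(1), y_star = cpv(2),
               v0 = cpv(3), sigma = cpv(4), y0_on = cpv(5),
               y0_off = cpv(6), K = cpv(7);

  // per-unique-dose caches: face velocities (nx x ny-1) and survival
  // factors (1 - gamma*dt) per phenotype column
  const arma::uword nd = Pcube.n_slices;
  std::vector<arma::mat> vpos(nd), vneg(nd);
  std::vector<arma::rowvec> surv(nd);
  arma::vec udose(nd, arma::fill::value(arma::datum::nan));
  for (arma::uword s = 0; s < nsteps; ++s) {
    arma::uword d = dose_idx(s) - 1;
    if (!arma::is_finite(udose(d))) udose(d) = doses(s);
  }
  for (arma::uword d = 0; d < nd; ++d) {
    if (!arma::is_finite(udose(d))) continue;
    double c = udose(d);
    arma::mat vf(nx, ny - 1);
    for (arma::uword j = 0; j + 1 < ny; ++j) {
      double yf = (j + 1) * dy;
      for (arma::uword i = 0; i < nx; ++i) {
        vf(i, j) = (c <= 1e-12) ? v0 * x(i) * (y0_off - yf)
                                : v0 * x(i) * c * (y0_on - yf);
      }
    }
    vpos[d] = arma::clamp(vf, 0.0, arma::datum::inf);
    vneg[d] = arma::clamp(vf, -arma::datum::inf, 0.0);
    arma::rowvec sv(ny);
    for (arma::uword j = 0; j < ny; ++j) {
      double gam = gamma0 + gamma1 * c * (y(j) < y_star ? 1.0 : 0.0);
      sv(j) = 1.0 - dt * gam;
    }
    surv[d] = sv;
  }

  // classification masks
  arma::uvec hix = arma::find(x > x_c);
  arma::uvec lox = arma::find(x < x_c);
  arma::uvec loy = arma::find(y < y_c);
  arma::uvec hiy = arma::find(y > y_c);

  arma::mat Q = Q0;
  arma::vec Qhat(nsteps + 1);
  Qhat(0) = arma::accu(Q) * dx * dy;
  const arma::uword nrec = record_idx.n_elem;
  arma::mat frac(nrec, 3, arma::fill::zeros);
  arma::mat marg(nrec, nx, arma::fill::zeros);
  arma::uword rpos = 0;

  arma::mat F(nx, ny - 1), lap(nx, ny), BQ(nx, ny);
  const double sfac = sigma * dt / (dy * dy);

  for (arma::uword s = 0; s < nsteps; ++s) {
    arma::uword d = dose_idx(s) - 1;

    // (i) upwind advection in y, zero flux through the walls
    F = vpos[d] % Q.head_cols(ny - 1) + vneg[d] % Q.tail_cols(ny - 1);
    Q.col(0) -= (dt / dy) * F.col(0);
    for (arma::uword j = 1; j + 1 < ny; ++j)
      Q.col(j) += (dt / dy) * (F.col(j - 1) - F.col(j));
    Q.col(ny - 1) += (dt / dy) * F.col(ny - 2);

    // (ii) explicit zero-flux diffusion in y
    if (sigma > 0) {
      lap.col(0) = Q.col(1) - Q.col(0);
      for (arma::uword j = 1; j + 1 < ny; ++j)
        lap.col(j) = Q.col(j - 1) - 2.0 * Q.col(j) + Q.col(j + 1);
      lap.col(ny - 1) = Q.col(ny - 2) - Q.col(ny - 1);
      Q += sfac * lap;
    }

    // (iii) Euler death sink
    Q.each_row() %= surv[d];

    // (iv) mitosis redistribution through the inheritance kernel
    double qh = arma::accu(Q) * dx * dy;
    double crowd = 1.0 - qh / K;
    if (crowd < 0) crowd = 0;
    BQ = Q.each_col() % (beta1v * crowd);
    Q += dt * (2.0 * dx * (Pcube.slice(d) * BQ) - BQ);

    Q.transform([](double v) { return v < 0 ? 0.0 : v; });
    if (renorm_to > 0) {
      double m = arma::accu(Q) * dx * dy;
      if (m <= 0) stop("population mass vanished during burn-in");
      Q *= renorm_to / m;
    }
    Qhat(s + 1) = arma::accu(Q) * dx * dy;
    if (!std::isfinite(Qhat(s + 1)))
      stop("population step produced non-finite mass (step %d)", (int)(s + 1));

    if (rpos < nrec && (arma::sword)(s + 1) == record_idx(rpos)) {
      double tot = arma::accu(Q);
      if (tot > 0) {
        double naive = arma::accu(Q.cols(loy));
        double dtp = arma::accu(Q.submat(hix, hiy));
        double resi = arma::accu(Q.submat(lox, hiy));
        frac(rpos, 0) = naive / tot;
        frac(rpos, 1) = dtp / tot;
        frac(rpos, 2) = resi / tot;
        arma::vec mx = arma::sum(Q, 1) * dy;
        marg.row(rpos) = (mx / (arma::accu(mx) * dx)).t();
      }
      ++rpos;
    }
  }

  return List::create(_["Qhat"] = Qhat, _["Q"] = Q, _["frac"] = frac,
                      _["marg"] = marg);
}
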