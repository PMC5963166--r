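#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the Poisson log-linear model with
// offset and a Leroux CAR spatial random effect:
//   O_i ~ Poisson(mu_i),  log mu_i = log E_i + x_i' beta + phi_i
//   phi ~ N(0, tau2 * Q(rho)^{-1}),  Q(rho) = rho (D - W) + (1 - rho) I
// Blocks: beta by adaptive blockwise random-walk Metropolis; each phi_i by
// univariate random-walk Metropolis against likelihood x CAR full
// conditional; tau2 by its conjugate inverse-gamma full conditional; rho by
// random-walk Metropolis using the eigenvalue form of log det Q(rho).
// Proposal scales adapt by Robbins-Monro during burn-in only. Uses R's RNG
// so set.seed() on the R side makes runs reproducible.

// in-place upper Cholesky of a small SPD matrix (row-major vector of
// vectors); returns false if a pivot fails
static bool chol_upper(std::vector< std::vector<double> >& A, int p) {
  for (int i = 0; i < p; ++i) {
    for (int j = 0; j < i; ++j) A[i][j] = 0.0;
    double d = A[i][i];
    for (int k = 0; k < i; ++k) d -= A[k][i] * A[k][i];
    if (d <= 0.0 || !std::isfinite(d)) return false;
    A[i][i] = std::sqrt(d);
    for (int j = i + 1; j < p; ++j) {
      double s = A[i][j];
      for (int k = 0; k < i; ++k) s -= A[k][i] * A[k][j];
      A[i][j] = s / A[i][i];
    }
  }
  return true;
}

static inline double phi_quad(const std::vector<double>& phi,
                              const IntegerMatrix& edges,
                              double rho, double& sdiff, double& sphi2) {
  sdiff = 0.0;
  const int m = edges.nrow();
  for (int e = 0; e < m; ++e) {
    const double d = phi[edges(e, 0)] - phi[edges(e, 1)];
    sdiff += d * d;
  }
  sphi2 = 0.0;
  for (size_t i = 0; i < phi.size(); ++i) sphi2 += phi[i] * phi[i];
  return rho * sdiff + (1.0 - rho) * sphi2;
}

// [[Rcpp::export]]
List leroux_mcmc_cpp(IntegerVector O, NumericVector logE, NumericMatrix X,
                     IntegerMatrix edges, IntegerVector degree,
                     NumericVector lambda,
                     int n_iter, int burn_in, int thin,
                     double beta_prior_var,
                     double tau2_shape, double tau2_scale,
                     NumericVector beta_init, NumericVector phi_init,
                     double tau2_init, double rho_init,
                     NumericMatrix beta_L,
                     bool spatial,
                     bool update_beta, bool update_phi,
                     bool update_tau2, bool update_rho,
                     bool store_loglik, bool store_phi) {
  const int n = O.size();
  const int p = X.ncol();
  const int m = edges.nrow();
  const double rho_max = 1.0 - 1e-6;

  // neighbor lists
  std::vector< std::vector<int> > nbr(n);
  for (int e = 0; e < m; ++e) {
    nbr[edges(e, 0)].push_back(edges(e, 1));
    nbr[edges(e, 1)].push_back(edges(e, 0));
  }

  std::vector<double> beta(p), phi(n, 0.0), eta(n, 0.0);
  for (int j = 0; j < p; ++j) beta[j] = beta_init[j];
  if (spatial) for (int i = 0; i < n; ++i) phi[i] = phi_init[i];
  double tau2 = tau2_init, rho = rho_init;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += X(i, j) * beta[j];
    eta[i] = s;
  }

  const int n_keep = (n_iter > burn_in) ? (n_iter - burn_in - 1) / thin + 1 : 0;
  NumericMatrix beta_out(n_keep, p);
  NumericVector tau2_out(n_keep), rho_out(n_keep);
  NumericMatrix ll_out(store_loglik ? n_keep : 0, store_loglik ? n : 0);
  NumericMatrix phi_out(store_phi ? n_keep : 0, store_phi ? n : 0);
  NumericVector phi_mean(n);

  // adaptive proposal scales (log parameterization)
  double ls_beta = std::log(2.38 / std::sqrt((double)p));
  double ls_phi = std::log(0.5), ls_rho = std::log(0.05), ls_iw = 0.0;
  const double targ_beta = 0.35, targ_uni = 0.44;
  int acc_beta_b = 0, try_beta_b = 0;           // within-batch counters
  long acc_phi_b = 0, try_phi_b = 0;
  int acc_rho_b = 0, try_rho_b = 0;
  long acc_iw_b = 0, try_iw_b = 0;
  long acc_beta = 0, try_beta = 0, acc_phi = 0, try_phi = 0;
  long acc_rho = 0, try_rho = 0;                // post burn-in counters
  long acc_iw = 0, try_iw = 0;
  int batch = 0;

  // per-coefficient base scales for the interweaving translations (the
  // marginal sd implied by the proposal Cholesky factor), and the edge
  // quadratic x_j' (D - W) x_j, fixed per run
  std::vector<double> iw_sd(p), xLx(p, 0.0);
  for (int j = 0; j < p; ++j) {
    double v = 0.0;
    for (int k = 0; k <= j; ++k) v += beta_L(k, j) * beta_L(k, j);
    iw_sd[j] = std::sqrt(v);
  }
  for (int j = 0; j < p; ++j) {
    for (int e = 0; e < m; ++e) {
      const double d = X(edges(e, 0), j) - X(edges(e, 1), j);
      xLx[j] += d * d;
    }
  }

  // Haario-style adaptation of the beta block proposal: accumulate the
  // empirical covariance of beta during burn-in and periodically reshape
  // the proposal Cholesky (with a small regularizer from the initial
  // GLM-based factor), frozen after burn-in.
  // the proposal factor is kept normalized to unit geometric-mean
  // diagonal so the Robbins-Monro scalar owns the overall scale and
  // covariance reshaping does not jump the acceptance rate
  std::vector< std::vector<double> > bU(p, std::vector<double>(p, 0.0));
  {
    double lg = 0.0;
    for (int j = 0; j < p; ++j) lg += std::log(beta_L(j, j));
    const double g0 = std::exp(lg / p);
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < p; ++j) bU[i][j] = beta_L(i, j) / g0;
    ls_beta += std::log(g0);
  }
  std::vector<double> bsum(p, 0.0);
  std::vector< std::vector<double> > bss(p, std::vector<double>(p, 0.0));
  long bcount = 0;
  const int adapt_start = std::min(200, burn_in / 4);

  std::vector<double> znew(p), delta(p), eta_star(n);
  double lgO = 0.0; // unused; per-region lgamma computed on store
  (void)lgO;

  int keep = 0;
  for (int it = 0; it < n_iter; ++it) {
    if (it % 1000 == 0) Rcpp::checkUserInterrupt();
    const bool burning = it < burn_in;

    // ---- beta block ----
    if (update_beta) {
      const double s = std::exp(ls_beta);
      for (int j = 0; j < p; ++j) znew[j] = norm_rand();
      // delta = s * t(U) %*% z, U upper-triangular Cholesky factor
      for (int j = 0; j < p; ++j) {
        double d = 0.0;
        for (int k = 0; k <= j; ++k) d += bU[k][j] * znew[k];
        delta[j] = s * d;
      }
      double lr = 0.0;
      for (int i = 0; i < n; ++i) {
        double de = 0.0;
        for (int j = 0; j < p; ++j) de += X(i, j) * delta[j];
        eta_star[i] = eta[i] + de;
        lr += O[i] * de
            - std::exp(logE[i] + eta_star[i] + phi[i])
            + std::exp(logE[i] + eta[i] + phi[i]);
      }
      for (int j = 0; j < p; ++j) {
        const double bn = beta[j] + delta[j];
        lr -= (bn * bn - beta[j] * beta[j]) / (2.0 * beta_prior_var);
      }
      ++try_beta_b; if (!burning) ++try_beta;
      if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
        for (int j = 0; j < p; ++j) beta[j] += delta[j];
        eta.swap(eta_star);
        ++acc_beta_b; if (!burning) ++acc_beta;
      }
    }

    // ---- phi block (univariate scans) ----
    if (spatial && update_phi) {
      const double s = std::exp(ls_phi);
      for (int i = 0; i < n; ++i) {
        double nsum = 0.0;
        for (size_t k = 0; k < nbr[i].size(); ++k) nsum += phi[nbr[i][k]];
        const double prec = rho * degree[i] + 1.0 - rho;
        const double pm = rho * nsum / prec;        // conditional prior mean
        const double pv = tau2 / prec;              // conditional prior var
        const double prop = phi[i] + s * norm_rand();
        const double Ee = std::exp(logE[i] + eta[i]);
        double lr = O[i] * (prop - phi[i])
                  - Ee * (std::exp(prop) - std::exp(phi[i]))
                  - ((prop - pm) * (prop - pm)
                     - (phi[i] - pm) * (phi[i] - pm)) / (2.0 * pv);
        ++try_phi_b; if (!burning) ++try_phi;
        if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
          phi[i] = prop;
          ++acc_phi_b; if (!burning) ++acc_phi;
        }
      }
    }

    // ---- interweaving block: likelihood-invariant translations ----
    // beta_j -> beta_j + delta, phi -> phi - delta * x_j leaves every
    // mu_i unchanged, so the Metropolis ratio involves only the priors.
    // This decorrelates beta from phi along spatially structured
    // covariate patterns (and the intercept from the phi level), which
    // plain blockwise updates mix through very slowly.
    if (spatial && update_beta && update_phi) {
      const double s = std::exp(ls_iw);
      for (int j = 0; j < p; ++j) {
        const double delta = s * iw_sd[j] * norm_rand();
        // x_j' Q x_j and x_j' Q phi with Q = rho (D - W) + (1 - rho) I
        double xQx = rho * xLx[j];
        double xQp = 0.0;
        for (int e = 0; e < m; ++e) {
          const int a = edges(e, 0), b = edges(e, 1);
          xQp += (X(a, j) - X(b, j)) * (phi[a] - phi[b]);
        }
        xQp *= rho;
        double xx = 0.0, xp = 0.0;
        for (int i = 0; i < n; ++i) {
          xx += X(i, j) * X(i, j);
          xp += X(i, j) * phi[i];
        }
        xQx += (1.0 - rho) * xx;
        xQp += (1.0 - rho) * xp;
        const double bn = beta[j] + delta;
        double lr = -(bn * bn - beta[j] * beta[j]) / (2.0 * beta_prior_var)
                    - (-2.0 * delta * xQp + delta * delta * xQx)
                      / (2.0 * tau2);
        ++try_iw_b; if (!burning) ++try_iw;
        if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
          beta[j] = bn;
          for (int i = 0; i < n; ++i) {
            phi[i] -= delta * X(i, j);
            eta[i] += delta * X(i, j);
          }
          ++acc_iw_b; if (!burning) ++acc_iw;
        }
      }
    }

    double sdiff = 0.0, sphi2 = 0.0;
    if (spatial && (update_tau2 || update_rho)) {
      phi_quad(phi, edges, rho, sdiff, sphi2);
    }

    // ---- tau2: conjugate inverse-gamma ----
    if (spatial && update_tau2) {
      const double quad = rho * sdiff + (1.0 - rho) * sphi2;
      const double shape = tau2_shape + 0.5 * n;
      const double rate = tau2_scale + 0.5 * quad;
      tau2 = 1.0 / R::rgamma(shape, 1.0 / rate);
    }

    // ---- rho: random-walk Metropolis with reflection into [0, rho_max] ----
    if (spatial && update_rho) {
      const double s = std::exp(ls_rho);
      double prop = rho + s * norm_rand();
      for (int r = 0; r < 100 && (prop < 0.0 || prop > rho_max); ++r) {
        if (prop < 0.0) prop = -prop;
        if (prop > rho_max) prop = 2.0 * rho_max - prop;
      }
      double lr = 0.0;
      for (int k = 0; k < n; ++k) {
        lr += 0.5 * (std::log(prop * lambda[k] + 1.0 - prop)
                   - std::log(rho * lambda[k] + 1.0 - rho));
      }
      lr -= ((prop - rho) * sdiff + (rho - prop) * sphi2) / (2.0 * tau2);
      ++try_rho_b; if (!burning) ++try_rho;
      if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
        rho = prop;
        ++acc_rho_b; if (!burning) ++acc_rho;
      }
    }

    // ---- empirical covariance accumulation / proposal reshaping ----
    if (burning && update_beta && it >= adapt_start) {
      ++bcount;
      for (int a = 0; a < p; ++a) {
        bsum[a] += beta[a];
        for (int b = a; b < p; ++b) bss[a][b] += beta[a] * beta[b];
      }
      if (bcount >= 10L * p && (it + 1) % 250 == 0) {
        std::vector< std::vector<double> > A(p, std::vector<double>(p));
        for (int a = 0; a < p; ++a) {
          for (int b = a; b < p; ++b) {
            double c = bss[a][b] / bcount
                     - (bsum[a] / bcount) * (bsum[b] / bcount);
            // shrink a little toward the GLM-based shape for stability
            double v0 = 0.0;
            for (int k = 0; k <= std::min(a, b); ++k)
              v0 += beta_L(k, a) * beta_L(k, b);
            c = c * (double)bcount / (bcount - 1) + 0.05 * v0;
            A[a][b] = c; A[b][a] = c;
          }
        }
        if (chol_upper(A, p)) {
          for (int j = 0; j < p; ++j) {
            double v = 0.0;
            for (int k = 0; k <= j; ++k) v += A[k][j] * A[k][j];
            iw_sd[j] = std::sqrt(v);   // true marginal sd, pre-normalization
          }
          double lg = 0.0;
          for (int j = 0; j < p; ++j) lg += std::log(A[j][j]);
          const double g = std::exp(lg / p);
          for (int a = 0; a < p; ++a)
            for (int b = 0; b < p; ++b) A[a][b] /= g;
          bU = A;
        }
      }
    }

    // ---- Robbins-Monro adaptation during burn-in, batches of 100 ----
    if (burning && (it + 1) % 100 == 0) {
      ++batch;
      const double step = std::min(0.25, 3.0 / std::sqrt((double)batch));
      if (try_beta_b > 0)
        ls_beta += step * ((double)acc_beta_b / try_beta_b - targ_beta);
      if (try_phi_b > 0)
        ls_phi += step * ((double)acc_phi_b / try_phi_b - targ_uni);
      if (try_rho_b > 0)
        ls_rho += step * ((double)acc_rho_b / try_rho_b - targ_uni);
      if (try_iw_b > 0)
        ls_iw += step * ((double)acc_iw_b / try_iw_b - targ_uni);
      acc_beta_b = try_beta_b = 0; acc_phi_b = 0; try_phi_b = 0;
      acc_rho_b = try_rho_b = 0; acc_iw_b = 0; try_iw_b = 0;
    }

    // ---- divergence guard ----
    if ((it + 1) % 500 == 0) {
      bool ok = std::isfinite(tau2) && std::isfinite(rho);
      for (int j = 0; ok && j < p; ++j) ok = std::isfinite(beta[j]);
      if (!ok) stop("divergent chain (non-finite state) at iteration %d", it + 1);
    }

    // ---- storage ----
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < p; ++j) beta_out(keep, j) = beta[j];
      tau2_out[keep] = spatial ? tau2 : NA_REAL;
      rho_out[keep] = spatial ? rho : NA_REAL;
      for (int i = 0; i < n; ++i) phi_mean[i] += phi[i];
      if (store_phi) for (int i = 0; i < n; ++i) phi_out(keep, i) = phi[i];
      if (store_loglik) {
        for (int i = 0; i < n; ++i) {
          const double lp = logE[i] + eta[i] + phi[i];
          ll_out(keep, i) = O[i] * lp - std::exp(lp) - R::lgammafn(O[i] + 1.0);
        }
      }
      ++keep;
    }
  }
  if (n_keep > 0) for (int i = 0; i < n; ++i) phi_mean[i] /= n_keep;

  return List::create(
    _["beta"] = beta_out,
    _["tau2"] = tau2_out,
    _["rho"] = rho_out,
    _["loglik"] = store_loglik ? (SEXP)ll_out : R_NilValue,
    _["phi"] = store_phi ? (SEXP)phi_out : R_NilValue,
    _["phi_mean"] = phi_mean,
    _["accept"] = List::create(
      _["beta"] = try_beta > 0 ? (double)acc_beta / try_beta : NA_REAL,
      _["phi"] = try_phi > 0 ? (double)acc_phi / try_phi : NA_REAL,
      _["rho"] = try_rho > 0 ? (double)acc_rho / try_rho : NA_REAL,
      _["interweave"] = try_iw > 0 ? (double)acc_iw / try_iw : NA_REAL),
    _["proposal_sd"] = List::create(
      _["beta"] = std::exp(ls_beta), _["phi"] = std::exp(ls_phi),
      _["rho"] = std::exp(ls_rho))
  );
}
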