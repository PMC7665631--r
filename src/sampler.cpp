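// Metropolis-within-Gibbs sampler for the four hierarchical count models:
// Poisson / negative-binomial likelihood, optional BYM (ICAR + iid) spatial
// effects, vague normal priors on coefficients, inverse-gamma on the spatial
// variances (conjugate updates), gamma on the NB dispersion. Coefficients
// move as one multivariate random-walk block (proposal covariance supplied
// from a weighted least-squares fit); spatial effects and dispersions move
// one at a time with per-element adaptive scales. Adaptation runs only
// during burn-in so the post-burn-in kernel leaves the posterior invariant.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline double seg_ll(int family, bool flat, double ys, double eta,
                            double r) {
  if (flat) return 0.0;
  double lam = std::exp(eta);
  if (family == 0) {
    return ys * eta - lam - R::lgammafn(ys + 1.0);
  }
  return R::lgammafn(ys + r) - R::lgammafn(r) - R::lgammafn(ys + 1.0) +
         r * std::log(r) - (ys + r) * std::log(lam + r) + ys * eta;
}

// [[Rcpp::export]]
List sc_mcmc(NumericVector y, NumericMatrix X, List nbr, IntegerVector comp,
             int family, bool spatial, bool shared_r, bool flat_lik,
             List priors, List init, List blocks, int n_iter, int burn_in,
             int thin, NumericMatrix coef_chol, double icar_df_val,
             List prop, bool adapt, int adapt_window, double target_accept) {
  const int S = X.nrow(), m = X.ncol();
  const double ak = priors["ak"], bk = priors["bk"], alpha0 = priors["alpha0"],
               b0 = priors["b0"], d0 = priors["d0"], q0 = priors["q0"],
               rho0 = priors["rho0"], x0 = priors["x0"], z0 = priors["z0"],
               e0 = priors["e0"], j0 = priors["j0"];
  const bool upd_coef = blocks["coefficients"], upd_sp = blocks["spatial"],
             upd_var = blocks["variances"], upd_disp = blocks["dispersion"];

  std::vector<std::vector<int>> nb(S);
  std::vector<double> deg(S, 0.0);
  for (int s = 0; s < S; ++s) {
    IntegerVector v = nbr[s];
    for (int j = 0; j < v.size(); ++j) nb[s].push_back(v[j] - 1);
    deg[s] = nb[s].size();
  }
  int G = 0;
  for (int s = 0; s < S; ++s) G = std::max(G, (int)comp[s]);

  NumericVector beta = clone(as<NumericVector>(init["beta"]));
  double a0 = init["a0"];
  NumericVector mu(S), vv(S);
  double sig_mu2 = 1.0, sig_v2 = 1.0;
  if (spatial) {
    mu = clone(as<NumericVector>(init["mu"]));
    vv = clone(as<NumericVector>(init["v"]));
    sig_mu2 = init["sigma_mu2"];
    sig_v2 = init["sigma_v2"];
  }
  int n_r = (family == 1) ? (shared_r ? 1 : S) : 0;
  NumericVector rr(std::max(n_r, 1), 1.0);
  if (family == 1) {
    NumericVector r0 = init["r"];
    for (int i = 0; i < n_r; ++i) rr[i] = r0[r0.size() == 1 ? 0 : i];
  }
  auto r_of = [&](int s) {
    return (family == 1) ? (shared_r ? rr[0] : rr[s]) : 1.0;
  };

  // linear predictor bookkeeping
  std::vector<double> xb(S), eta(S);
  auto recompute_eta = [&]() {
    for (int s = 0; s < S; ++s) {
      double t = 0.0;
      for (int k = 0; k < m; ++k) t += X(s, k) * beta[k];
      xb[s] = t;
      eta[s] = a0 + t + (spatial ? mu[s] + vv[s] : 0.0);
    }
  };
  recompute_eta();

  // proposal scales
  double sc_coef = prop["coef"];
  NumericVector sc_mu(S, as<double>(prop["mu"]));
  NumericVector sc_v(S, as<double>(prop["v"]));
  NumericVector sc_w(S, as<double>(prop["v"]));
  NumericVector sc_bx(m + 1, 0.1);
  double sc_rs = 0.5;
  NumericVector sc_r(std::max(n_r, 1), as<double>(prop["r"]));

  int n_par = m + 1 + (spatial ? 2 * S + 2 : 0) + n_r;
  int n_store = 0;
  for (int it = burn_in; it < n_iter; ++it)
    if ((it - burn_in) % thin == 0) ++n_store;
  NumericMatrix draws(n_store, n_par);
  NumericVector dev(n_store);

  // acceptance bookkeeping: window counts (adaptation) and post-burn totals
  int win_coef = 0, win_rs = 0;
  std::vector<int> win_mu(S, 0), win_v(S, 0), win_w(S, 0), win_bx(m + 1, 0),
      win_r(std::max(n_r, 1), 0);
  long tot_coef = 0, tot_rs = 0;
  std::vector<long> tot_mu(S, 0), tot_v(S, 0), tot_w(S, 0), tot_bx(m + 1, 0),
      tot_r(std::max(n_r, 1), 0);
  long post_iters = 0;

  RNGScope scope;
  std::vector<double> dcoef(m + 1), z(m + 1), etan(S);
  int row = 0;

  for (int it = 0; it < n_iter; ++it) {
    if (upd_coef) {
      for (int j = 0; j <= m; ++j) z[j] = R::norm_rand();
      for (int i = 0; i <= m; ++i) {
        double t = 0.0;
        for (int j = 0; j <= i; ++j) t += coef_chol(i, j) * z[j];
        dcoef[i] = sc_coef * t;
      }
      double lacc = 0.0;
      for (int k = 0; k < m; ++k) {
        double b1 = beta[k] + dcoef[k];
        lacc += (-(b1 - ak) * (b1 - ak) + (beta[k] - ak) * (beta[k] - ak)) /
                (2.0 * bk);
      }
      double a1 = a0 + dcoef[m];
      lacc += (-(a1 - alpha0) * (a1 - alpha0) +
               (a0 - alpha0) * (a0 - alpha0)) / (2.0 * b0);
      for (int s = 0; s < S; ++s) {
        double de = dcoef[m];
        for (int k = 0; k < m; ++k) de += X(s, k) * dcoef[k];
        etan[s] = eta[s] + de;
        lacc += seg_ll(family, flat_lik, y[s], etan[s], r_of(s)) -
                seg_ll(family, flat_lik, y[s], eta[s], r_of(s));
      }
      if (R_finite(lacc) && std::log(R::unif_rand()) < lacc) {
        for (int k = 0; k < m; ++k) beta[k] += dcoef[k];
        a0 += dcoef[m];
        for (int s = 0; s < S; ++s) {
          double de = dcoef[m];
          for (int k = 0; k < m; ++k) de += X(s, k) * dcoef[k];
          xb[s] += de - dcoef[m];
          eta[s] = etan[s];
        }
        ++win_coef;
        if (it >= burn_in) ++tot_coef;
      }
    }

    if (spatial && upd_sp) {
      for (int s = 0; s < S; ++s) {
        if (deg[s] == 0.0) continue;  // isolated: mu fixed at 0
        double d = sc_mu[s] * R::norm_rand();
        double mbar = 0.0;
        for (int x : nb[s]) mbar += mu[x];
        mbar /= deg[s];
        double e1 = eta[s] + d;
        double m1 = mu[s] + d;
        double lacc =
            seg_ll(family, flat_lik, y[s], e1, r_of(s)) -
            seg_ll(family, flat_lik, y[s], eta[s], r_of(s)) -
            deg[s] / (2.0 * sig_mu2) *
                ((m1 - mbar) * (m1 - mbar) - (mu[s] - mbar) * (mu[s] - mbar));
        if (R_finite(lacc) && std::log(R::unif_rand()) < lacc) {
          mu[s] = m1;
          eta[s] = e1;
          ++win_mu[s];
          if (it >= burn_in) ++tot_mu[s];
        }
      }
      for (int s = 0; s < S; ++s) {
        double d = sc_v[s] * R::norm_rand();
        double e1 = eta[s] + d;
        double v1 = vv[s] + d;
        double lacc = seg_ll(family, flat_lik, y[s], e1, r_of(s)) -
                      seg_ll(family, flat_lik, y[s], eta[s], r_of(s)) -
                      ((v1 - d0) * (v1 - d0) - (vv[s] - d0) * (vv[s] - d0)) /
                          (2.0 * sig_v2);
        if (R_finite(lacc) && std::log(R::unif_rand()) < lacc) {
          vv[s] = v1;
          eta[s] = e1;
          ++win_v[s];
          if (it >= burn_in) ++tot_v[s];
        }
      }
      // likelihood-neutral exchange: (mu_s + d, v_s - d) leaves eta fixed, so
      // the acceptance ratio is prior-only; this is what lets the weakly
      // identified mu/v split (and hence the variances) mix under a strong
      // likelihood
      for (int s = 0; s < S; ++s) {
        if (deg[s] == 0.0) continue;
        double d = sc_w[s] * R::norm_rand();
        double mbar = 0.0;
        for (int x : nb[s]) mbar += mu[x];
        mbar /= deg[s];
        double m1 = mu[s] + d, v1 = vv[s] - d;
        double lacc =
            -deg[s] / (2.0 * sig_mu2) *
                ((m1 - mbar) * (m1 - mbar) - (mu[s] - mbar) * (mu[s] - mbar)) -
            ((v1 - d0) * (v1 - d0) - (vv[s] - d0) * (vv[s] - d0)) /
                (2.0 * sig_v2);
        if (R_finite(lacc) && std::log(R::unif_rand()) < lacc) {
          mu[s] = m1;
          vv[s] = v1;
          ++win_w[s];
          if (it >= burn_in) ++tot_w[s];
        }
      }
      // likelihood-neutral confounding move: beta_k + d with v - X_k d (and
      // a0 + d with v - d) keeps eta fixed; accepted on priors only. This
      // carries the coefficients across the wide marginal ridge that spatial
      // confounding creates.
      if (upd_coef) {
        for (int k = 0; k <= m; ++k) {
          double d = sc_bx[k] * R::norm_rand();
          double lacc;
          if (k < m) {
            double b1 = beta[k] + d;
            lacc = (-(b1 - ak) * (b1 - ak) +
                    (beta[k] - ak) * (beta[k] - ak)) / (2.0 * bk);
          } else {
            double a1 = a0 + d;
            lacc = (-(a1 - alpha0) * (a1 - alpha0) +
                    (a0 - alpha0) * (a0 - alpha0)) / (2.0 * b0);
          }
          for (int s = 0; s < S; ++s) {
            double xk = (k < m) ? X(s, k) : 1.0;
            if (xk == 0.0) continue;
            double v1 = vv[s] - xk * d;
            lacc -= ((v1 - d0) * (v1 - d0) - (vv[s] - d0) * (vv[s] - d0)) /
                    (2.0 * sig_v2);
          }
          if (R_finite(lacc) && std::log(R::unif_rand()) < lacc) {
            for (int s = 0; s < S; ++s) {
              double xk = (k < m) ? X(s, k) : 1.0;
              if (xk != 0.0) vv[s] -= xk * d;
            }
            if (k < m) {
              beta[k] += d;
              for (int s = 0; s < S; ++s) xb[s] += X(s, k) * d;
            } else {
              a0 += d;
            }
            ++win_bx[k];
            if (it >= burn_in) ++tot_bx[k];
          }
        }
      }
      // re-center mu per component; global mean absorbed into the intercept
      std::vector<double> cm(G, 0.0);
      std::vector<int> cn(G, 0);
      double gm = 0.0;
      for (int s = 0; s < S; ++s) {
        if (deg[s] == 0.0) continue;
        cm[comp[s] - 1] += mu[s];
        cn[comp[s] - 1] += 1;
        gm += mu[s];
      }
      int nlive = 0;
      for (int g = 0; g < G; ++g) {
        if (cn[g] > 0) cm[g] /= cn[g];
        nlive += cn[g];
      }
      if (nlive > 0) {
        a0 += gm / nlive;
        for (int s = 0; s < S; ++s)
          if (deg[s] > 0.0) mu[s] -= cm[comp[s] - 1];
        for (int s = 0; s < S; ++s) eta[s] = a0 + xb[s] + mu[s] + vv[s];
      }
    }

    if (spatial && upd_var) {
      double quad = 0.0, sv = 0.0;
      for (int s = 0; s < S; ++s) {
        for (int x : nb[s])
          if (x > s) quad += (mu[s] - mu[x]) * (mu[s] - mu[x]);
        sv += (vv[s] - d0) * (vv[s] - d0);
      }
      sig_mu2 = 1.0 / R::rgamma(q0 + icar_df_val / 2.0,
                                1.0 / (rho0 + quad / 2.0));
      sig_v2 = 1.0 / R::rgamma(x0 + S / 2.0, 1.0 / (z0 + sv / 2.0));
    }

    if (spatial && upd_sp && upd_var) {
      // joint rescale (interweaving): mu' = c mu, sigma_mu2' = c^2 sigma_mu2,
      // v' = v + (1 - c) mu keeps eta fixed. The ICAR kernel is scale
      // invariant under this map and its log-Jacobian (df + 2) log c cancels
      // against it, leaving the inverse-gamma and v-prior terms. This move
      // jumps between the collapsed (mu ~ 0) and smooth-field modes that
      // single-site updates cannot travel between.
      double lc = sc_rs * R::norm_rand();
      double c = std::exp(lc);
      double lacc = -2.0 * q0 * lc -
                    rho0 * (1.0 / (c * c * sig_mu2) - 1.0 / sig_mu2);
      for (int s = 0; s < S; ++s) {
        if (deg[s] == 0.0) continue;
        double v1 = vv[s] + (1.0 - c) * mu[s];
        lacc -= ((v1 - d0) * (v1 - d0) - (vv[s] - d0) * (vv[s] - d0)) /
                (2.0 * sig_v2);
      }
      if (R_finite(lacc) && std::log(R::unif_rand()) < lacc) {
        for (int s = 0; s < S; ++s) {
          if (deg[s] == 0.0) continue;
          vv[s] += (1.0 - c) * mu[s];
          mu[s] *= c;
        }
        sig_mu2 *= c * c;
        ++win_rs;
        if (it >= burn_in) ++tot_rs;
      }
    }

    if (family == 1 && upd_disp) {
      if (shared_r) {
        double lr1 = std::log(rr[0]) + sc_r[0] * R::norm_rand();
        double r1 = std::exp(lr1);
        double lacc = e0 * (lr1 - std::log(rr[0])) - j0 * (r1 - rr[0]);
        for (int s = 0; s < S; ++s)
          lacc += seg_ll(family, flat_lik, y[s], eta[s], r1) -
                  seg_ll(family, flat_lik, y[s], eta[s], rr[0]);
        if (R_finite(lacc) && std::log(R::unif_rand()) < lacc) {
          rr[0] = r1;
          ++win_r[0];
          if (it >= burn_in) ++tot_r[0];
        }
      } else {
        for (int s = 0; s < S; ++s) {
          double lr1 = std::log(rr[s]) + sc_r[s] * R::norm_rand();
          double r1 = std::exp(lr1);
          double lacc = e0 * (lr1 - std::log(rr[s])) - j0 * (r1 - rr[s]) +
                        seg_ll(family, flat_lik, y[s], eta[s], r1) -
                        seg_ll(family, flat_lik, y[s], eta[s], rr[s]);
          if (R_finite(lacc) && std::log(R::unif_rand()) < lacc) {
            rr[s] = r1;
            ++win_r[s];
            if (it >= burn_in) ++tot_r[s];
          }
        }
      }
    }
    if (it >= burn_in) ++post_iters;

    if (adapt && it < burn_in && (it + 1) % adapt_window == 0) {
      auto tune = [&](double sc, int acc) {
        double rate = (double)acc / adapt_window;
        double s2 = sc * std::exp(rate - target_accept);
        return std::min(1e6, std::max(1e-8, s2));
      };
      if (upd_coef) sc_coef = tune(sc_coef, win_coef);
      win_coef = 0;
      if (spatial && upd_sp && upd_var) sc_rs = tune(sc_rs, win_rs);
      win_rs = 0;
      if (spatial && upd_sp)
        for (int s = 0; s < S; ++s) {
          sc_mu[s] = tune(sc_mu[s], win_mu[s]);
          sc_v[s] = tune(sc_v[s], win_v[s]);
          sc_w[s] = tune(sc_w[s], win_w[s]);
          win_mu[s] = win_v[s] = win_w[s] = 0;
        }
      if (spatial && upd_sp && upd_coef)
        for (int k = 0; k <= m; ++k) {
          sc_bx[k] = tune(sc_bx[k], win_bx[k]);
          win_bx[k] = 0;
        }
      if (family == 1 && upd_disp)
        for (int i = 0; i < n_r; ++i) {
          sc_r[i] = tune(sc_r[i], win_r[i]);
          win_r[i] = 0;
        }
    }

    if (it >= burn_in && (it - burn_in) % thin == 0) {
      int c = 0;
      for (int k = 0; k < m; ++k) draws(row, c++) = beta[k];
      draws(row, c++) = a0;
      if (spatial) {
        for (int s = 0; s < S; ++s) draws(row, c++) = mu[s];
        for (int s = 0; s < S; ++s) draws(row, c++) = vv[s];
        draws(row, c++) = sig_mu2;
        draws(row, c++) = sig_v2;
      }
      for (int i = 0; i < n_r; ++i) draws(row, c++) = rr[i];
      double ll = 0.0;
      for (int s = 0; s < S; ++s)
        ll += seg_ll(family, false, y[s], eta[s], r_of(s));
      dev[row] = -2.0 * ll;
      ++row;
    }
  }

  double denom = std::max((long)1, post_iters);
  NumericVector acc_mu(S), acc_v(S), acc_r(std::max(n_r, 1));
  for (int s = 0; s < S; ++s) {
    acc_mu[s] = tot_mu[s] / denom;
    acc_v[s] = tot_v[s] / denom;
  }
  for (int i = 0; i < std::max(n_r, 1); ++i) acc_r[i] = tot_r[i] / denom;

  List fin = List::create(
      _["beta"] = beta, _["a0"] = a0, _["mu"] = mu, _["v"] = vv,
      _["sigma_mu2"] = sig_mu2, _["sigma_v2"] = sig_v2, _["r"] = rr);
  List scales = List::create(_["coef"] = sc_coef, _["mu"] = sc_mu,
                             _["v"] = sc_v, _["r"] = sc_r);
  return List::create(
      _["draws"] = draws, _["deviance"] = dev, _["state"] = fin,
      _["accept"] = List::create(_["coef"] = tot_coef / denom,
                                 _["mu"] = acc_mu, _["v"] = acc_v,
                                 _["r"] = acc_r),
      _["scales"] = scales);
}
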