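#include <Rcpp.h>
using namespace Rcpp;

// Linear predictors are clipped at +/- clip before exponentiation; the
// number of clipped rows is reported so overflow guarding stays auditable.

// eta = X beta by cache-friendly column sweeps into the caller's workspace
static void lin_pred(const NumericMatrix& X, const double* beta,
                     std::vector<double>& eta) {
  const int n = X.nrow(), P = X.ncol();
  eta.assign(n, 0.0);
  for (int p = 0; p < P; ++p) {
    const double b = beta[p];
    if (b == 0.0) continue;
    const double* col = &X(0, p);
    for (int i = 0; i < n; ++i) eta[i] += col[i] * b;
  }
}

// log-likelihood WITHOUT the coefficient-free sum(z*log tau) term
static double pois_ll_kernel(const NumericMatrix& X, const NumericVector& z,
                             const NumericVector& tau, const double* beta,
                             double clip, int* nclip,
                             std::vector<double>& eta) {
  const int n = X.nrow();
  lin_pred(X, beta, eta);
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double e = eta[i];
    if (e > clip) { e = clip; if (nclip) ++*nclip; }
    else if (e < -clip) { e = -clip; if (nclip) ++*nclip; }
    ll += z[i] * e - tau[i] * std::exp(e);
  }
  return ll;
}

static double pois_ll(const NumericMatrix& X, const NumericVector& z,
                      const NumericVector& tau, const double* beta,
                      double clip, int* nclip) {
  const int n = X.nrow();
  std::vector<double> eta;
  double ll = pois_ll_kernel(X, z, tau, beta, clip, nclip, eta);
  for (int i = 0; i < n; ++i)
    if (z[i] != 0.0) ll += z[i] * std::log(tau[i]);
  return ll;
}

// [[Rcpp::export]]
List cpp_pois_loglik(NumericMatrix X, NumericVector z, NumericVector tau,
                     NumericVector beta, double clip = 35.0) {
  int nclip = 0;
  double ll = pois_ll(X, z, tau, REAL(beta), clip, &nclip);
  return List::create(_["loglik"] = ll, _["n_clipped"] = nclip);
}

// Blocked random-walk Metropolis for the hierarchical Poisson model.
//
// Data: per individual j a stacked design X_j (rows pooled over fit
// imputations), response z_j, offset tau_j, and a scalar row weight w_j
// (1 / M_fit) so the likelihood is the imputation average.
// Model: z ~ Poisson(tau * exp(x'beta_j)),
//        beta_j ~ N(mu, sigma2_beta * diag(phi)), phi_1 = 1,
//        log phi_p ~ N(0, phi_var) for p >= 2,
//        mu ~ N(0, sigma2_mu * I) (exact Gaussian full conditional).
// Adaptive proposal scaling runs only during the first n_adapt iterations
// (targets 0.23 for the beta vectors, 0.44 for the scalar phi blocks),
// then the scales are frozen; the first `burn` post-adaptation iterations
// are discarded and every `thin`-th retained. Uses R's RNG: seeded from R.
//
// [[Rcpp::export]]
List cpp_mcmc_hier(List Xs, List zs, List taus, NumericVector wts,
                   double sigma2_beta, double sigma2_mu, double phi_var,
                   int n_adapt, int n_main, int burn, int thin,
                   double clip = 35.0) {
  const int J = Xs.size();
  std::vector<NumericMatrix> X(J);
  std::vector<NumericVector> z(J), tau(J);
  for (int j = 0; j < J; ++j) {
    X[j] = as<NumericMatrix>(Xs[j]);
    z[j] = as<NumericVector>(zs[j]);
    tau[j] = as<NumericVector>(taus[j]);
  }
  const int P = X[0].ncol();

  std::vector<std::vector<double> > beta(J, std::vector<double>(P, 0.0));
  std::vector<double> mu(P, 0.0), lphi(P, 0.0); // lphi[0] fixed at 0
  std::vector<double> s_beta(J, 0.1), s_phi(P, 0.2);
  std::vector<double> cur_ll(J), eta;
  int nclip = 0;
  for (int j = 0; j < J; ++j)  // constants in beta cancel in the MH ratio
    cur_ll[j] = pois_ll_kernel(X[j], z[j], tau[j], beta[j].data(), clip,
                               &nclip, eta);

  const int batch = 50;
  std::vector<int> acc_beta(J, 0), acc_phi(P, 0);
  std::vector<int> acc_beta_tot(J, 0), acc_phi_tot(P, 0), try_tot(1, 0);

  const int n_keep = (n_main - burn) / thin;
  NumericVector draws_beta(n_keep * J * P), draws_mu(n_keep * P),
      draws_phi(n_keep * P);
  std::vector<double> prop(P);
  int kept = 0;

  RNGScope scope;
  const int n_iter = n_adapt + n_main;
  for (int it = 1; it <= n_iter; ++it) {
    const bool adapting = it <= n_adapt;
    // --- individual coefficient blocks ---
    for (int j = 0; j < J; ++j) {
      for (int p = 0; p < P; ++p) prop[p] = beta[j][p] + s_beta[j] * norm_rand();
      int nc = 0;
      double ll_prop = pois_ll_kernel(X[j], z[j], tau[j], prop.data(), clip,
                                      &nc, eta);
      double dprior = 0.0;
      for (int p = 0; p < P; ++p) {
        double v = sigma2_beta * std::exp(lphi[p]);
        double dn = prop[p] - mu[p], dc = beta[j][p] - mu[p];
        dprior += (dc * dc - dn * dn) / (2.0 * v);
      }
      double lr = wts[j] * (ll_prop - cur_ll[j]) + dprior;
      if (std::log(unif_rand()) < lr) {
        beta[j] = prop;
        cur_ll[j] = ll_prop;
        nclip += nc;
        ++acc_beta[j];
        if (!adapting) ++acc_beta_tot[j];
      }
    }
    // --- population mean: exact Gaussian full conditional ---
    for (int p = 0; p < P; ++p) {
      double v = sigma2_beta * std::exp(lphi[p]);
      double prec = J / v + 1.0 / sigma2_mu;
      double sum = 0.0;
      for (int j = 0; j < J; ++j) sum += beta[j][p];
      double m = (sum / v) / prec;
      mu[p] = m + norm_rand() / std::sqrt(prec);
    }
    // --- phi scalar blocks (p >= 2; phi_1 fixed at 1) ---
    for (int p = 1; p < P; ++p) {
      double lp_new = lphi[p] + s_phi[p] * norm_rand();
      double v_new = sigma2_beta * std::exp(lp_new);
      double v_old = sigma2_beta * std::exp(lphi[p]);
      double lr = 0.0;
      for (int j = 0; j < J; ++j) {
        double d = beta[j][p] - mu[p];
        lr += -0.5 * (lp_new - lphi[p]) - d * d / 2.0 * (1.0 / v_new - 1.0 / v_old);
      }
      lr += (lphi[p] * lphi[p] - lp_new * lp_new) / (2.0 * phi_var);
      if (std::log(unif_rand()) < lr) {
        lphi[p] = lp_new;
        ++acc_phi[p];
        if (!adapting) ++acc_phi_tot[p];
      }
    }
    // --- adaptation (frozen after n_adapt) ---
    if (adapting && it % batch == 0) {
      double step = std::min(0.25, 2.0 / std::sqrt((double) it / batch));
      for (int j = 0; j < J; ++j) {
        double r = acc_beta[j] / (double) batch;
        s_beta[j] *= std::exp(step * (r - 0.23));
        acc_beta[j] = 0;
      }
      for (int p = 1; p < P; ++p) {
        double r = acc_phi[p] / (double) batch;
        s_phi[p] *= std::exp(step * (r - 0.44));
        acc_phi[p] = 0;
      }
    }
    // --- storage ---
    if (!adapting) {
      int m = it - n_adapt;
      if (m > burn && (m - burn) % thin == 0 && kept < n_keep) {
        for (int j = 0; j < J; ++j)
          for (int p = 0; p < P; ++p)
            draws_beta[kept + n_keep * (j + J * p)] = beta[j][p];
        for (int p = 0; p < P; ++p) {
          draws_mu[kept + n_keep * p] = mu[p];
          draws_phi[kept + n_keep * p] = std::exp(lphi[p]);
        }
        ++kept;
      }
    }
  }
  draws_beta.attr("dim") = IntegerVector::create(n_keep, J, P);
  draws_mu.attr("dim") = IntegerVector::create(n_keep, P);
  draws_phi.attr("dim") = IntegerVector::create(n_keep, P);
  NumericVector ab(J), ap(P);
  for (int j = 0; j < J; ++j) ab[j] = acc_beta_tot[j] / (double) n_main;
  for (int p = 0; p < P; ++p) ap[p] = acc_phi_tot[p] / (double) n_main;
  NumericVector sb(J), sp(P);
  for (int j = 0; j < J; ++j) sb[j] = s_beta[j];
  for (int p = 0; p < P; ++p) sp[p] = s_phi[p];
  return List::create(_["beta"] = draws_beta, _["mu"] = draws_mu,
                      _["phi"] = draws_phi, _["accept_beta"] = ab,
                      _["accept_phi"] = ap, _["scale_beta"] = sb,
                      _["scale_phi"] = sp, _["n_clipped"] = nclip,
                      _["n_kept"] = kept);
}

// Gibbs sampler for one coordinate of the functional path model.
// Model: y ~ N(A c, so2 I) with A a grid-incidence matrix summarized by the
// per-grid-point precision w = diag(A'A)/so2 and b = A'y/so2;
// c | s2 ~ N(0, (K/s2)^-) with K the pentadiagonal RW2 structure matrix
// (rank n-2); s2 ~ InvGamma(shape0, rate0). The full conditional of c is
// N(Q^{-1} b, Q^{-1}) with banded Q = K/s2 + diag(w), factorized by a
// bandwidth-2 Cholesky; s2 | c is conjugate inverse-gamma with quadratic
// form sum of squared second differences of c.
//
// [[Rcpp::export]]
List cpp_rw2_gibbs(NumericVector b, NumericVector w, double shape0,
                   double rate0, double init_s2, int n_mcmc, int burn) {
  const int n = b.size();
  const int keep = n_mcmc - burn;
  NumericMatrix draws(n, keep);
  NumericVector sill(keep);
  std::vector<double> d(n), e(n), f(n), y(n), c(n), v(n);
  double s2 = init_s2;
  RNGScope scope;
  for (int it = 0; it < n_mcmc; ++it) {
    const double is2 = 1.0 / s2;
    // K bands: q0 = (1,5,6,...,6,5,1)/s2 + w ; q1 = (-2,-4,...,-4,-2)/s2 ;
    // q2 = 1/s2
    for (int i = 0; i < n; ++i) {
      double k0 = 6.0;
      if (i == 0 || i == n - 1) k0 = 1.0;
      else if (i == 1 || i == n - 2) k0 = 5.0;
      double q0 = k0 * is2 + w[i];
      double fi = 0.0, ei = 0.0;
      if (i >= 2) fi = is2 / d[i - 2];
      if (i >= 1) {
        double k1 = (i == 1 || i == n - 1) ? -2.0 : -4.0;
        ei = (k1 * is2 - e[i - 1] * fi) / d[i - 1];
      }
      f[i] = fi; e[i] = ei;
      d[i] = std::sqrt(q0 - ei * ei - fi * fi);
    }
    // forward solve L y = b, then back solve L' m = y (m stored in c)
    for (int i = 0; i < n; ++i) {
      double s = b[i];
      if (i >= 1) s -= e[i] * y[i - 1];
      if (i >= 2) s -= f[i] * y[i - 2];
      y[i] = s / d[i];
    }
    for (int i = n - 1; i >= 0; --i) {
      double s = y[i];
      if (i + 1 < n) s -= e[i + 1] * c[i + 1];
      if (i + 2 < n) s -= f[i + 2] * c[i + 2];
      c[i] = s / d[i];
    }
    // sample: c := mu + (L')^{-1} z
    for (int i = 0; i < n; ++i) v[i] = norm_rand();
    for (int i = n - 1; i >= 0; --i) {
      double s = v[i];
      if (i + 1 < n) s -= e[i + 1] * v[i + 1];
      if (i + 2 < n) s -= f[i + 2] * v[i + 2];
      v[i] = s / d[i];
      c[i] += v[i];
    }
    // conjugate sill update from the second differences of c
    double quad = 0.0;
    for (int i = 0; i + 2 < n; ++i) {
      double dd = c[i] - 2.0 * c[i + 1] + c[i + 2];
      quad += dd * dd;
    }
    s2 = 1.0 / R::rgamma(shape0 + (n - 2) / 2.0, 1.0 / (rate0 + quad / 2.0));
    if (it >= burn) {
      for (int i = 0; i < n; ++i) draws(i, it - burn) = c[i];
      sill[it - burn] = s2;
    }
  }
  return List::create(_["draws"] = draws, _["sill"] = sill);
}

// Per-row log pointwise predictive density: for each design row, the log of
// the posterior-draw average of the Poisson density of z given
// lambda = tau * exp(x'beta_d), with a configurable floor on the log
// density of a single draw.
//
// [[Rcpp::export]]
NumericVector cpp_row_lppd(NumericMatrix X, NumericVector z, NumericVector tau,
                           NumericMatrix B, double clip = 35.0,
                           double floor_log = -700.0) {
  const int n = X.nrow(), P = X.ncol(), D = B.nrow();
  NumericVector out(n);
  std::vector<double> ld((size_t) n * D), eta, bd(P);
  for (int d = 0; d < D; ++d) {
    for (int p = 0; p < P; ++p) bd[p] = B(d, p);
    lin_pred(X, bd.data(), eta);
    double* col = &ld[(size_t) d * n];
    for (int i = 0; i < n; ++i) {
      double e = eta[i];
      if (e > clip) e = clip;
      else if (e < -clip) e = -clip;
      double l = z[i] * (std::log(tau[i]) + e) - tau[i] * std::exp(e);
      col[i] = (l < floor_log) ? floor_log : l;
    }
  }
  for (int i = 0; i < n; ++i) {
    double mx = -HUGE_VAL;
    for (int d = 0; d < D; ++d) {
      double l = ld[(size_t) d * n + i];
      if (l > mx) mx = l;
    }
    double s = 0.0;
    for (int d = 0; d < D; ++d) s += std::exp(ld[(size_t) d * n + i] - mx);
    out[i] = mx + std::log(s / D);
  }
  return out;
}
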