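#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Partial log-likelihood, score and observed information of the Cox model.
// Rows must be sorted by ascending follow-up time. Ties are handled by the
// Breslow or Efron approximation; subjects censored at a death time remain
// in the risk set for that time. eta is centred internally so exp() cannot
// overflow for the |beta| range the Newton-Raphson guard allows.
// [[Rcpp::export]]
List cox_pl_cpp(const arma::mat& X, const arma::vec& beta,
                const arma::vec& time, const arma::ivec& status,
                bool efron, bool derivs) {
  const int n = X.n_rows, p = X.n_cols;
  arma::vec eta = X * beta;
  const double shift = eta.max();
  arma::vec w = arma::exp(eta - shift);

  double ll = 0.0;
  arma::vec g(p, arma::fill::zeros);
  arma::mat H(p, p, arma::fill::zeros);

  double S0 = 0.0;
  arma::vec S1(p, arma::fill::zeros);
  arma::mat S2(p, p, arma::fill::zeros);

  int i = n - 1;
  while (i >= 0) {
    const double t = time[i];
    int k = i;
    while (k >= 0 && time[k] == t) --k;   // tie group is (k, i]

    int d = 0;
    double S0d = 0.0, eta_d = 0.0;
    arma::vec S1d(p, arma::fill::zeros), xd(p, arma::fill::zeros);
    arma::mat S2d(p, p, arma::fill::zeros);

    for (int m = k + 1; m <= i; ++m) {
      const arma::rowvec xm = X.row(m);
      S0 += w[m];
      if (derivs) {
        S1 += w[m] * xm.t();
        S2 += w[m] * (xm.t() * xm);
      }
      if (status[m] == 1) {
        ++d;
        eta_d += eta[m] - shift;
        if (derivs) {
          S0d += w[m];
          S1d += w[m] * xm.t();
          S2d += w[m] * (xm.t() * xm);
          xd += xm.t();
        } else {
          S0d += w[m];
        }
      }
    }

    if (d > 0) {
      if (!efron) {
        ll += eta_d - d * std::log(S0);
        if (derivs) {
          const arma::vec m1 = S1 / S0;
          g += xd - d * m1;
          H -= d * (S2 / S0 - m1 * m1.t());
        }
      } else {
        ll += eta_d;
        if (derivs) g += xd;
        for (int l = 0; l < d; ++l) {
          const double f = static_cast<double>(l) / d;
          const double M0 = S0 - f * S0d;
          ll -= std::log(M0);
          if (derivs) {
            const arma::vec m1 = (S1 - f * S1d) / M0;
            g -= m1;
            H -= ((S2 - f * S2d) / M0 - m1 * m1.t());
          }
        }
      }
    }
    i = k;
  }

  if (derivs)
    return List::create(_["loglik"] = ll, _["grad"] = g, _["hess"] = H);
  return List::create(_["loglik"] = ll);
}

// Breslow partial log-likelihood for each column of a coefficient matrix
// (rows sorted by ascending time); used by the cross-validated deviance.
// [[Rcpp::export]]
arma::vec cox_loglik_path_cpp(const arma::mat& X, const arma::vec& time,
                              const arma::ivec& status, const arma::mat& Beta) {
  const int n = X.n_rows, L = Beta.n_cols;
  arma::vec out(L);
  for (int l = 0; l < L; ++l) {
    arma::vec eta = X * Beta.col(l);
    const double shift = eta.max();
    arma::vec ex = arma::exp(eta - shift);
    double ll = 0.0, S0 = 0.0;
    int i = n - 1;
    while (i >= 0) {
      const double t = time[i];
      int k = i;
      while (k >= 0 && time[k] == t) --k;
      int d = 0;
      double eta_d = 0.0;
      for (int m = k + 1; m <= i; ++m) {
        S0 += ex[m];
        if (status[m] == 1) { ++d; eta_d += eta[m] - shift; }
      }
      if (d > 0) ll += eta_d - d * std::log(S0);
      i = k;
    }
    out[l] = ll;
  }
  return out;
}

static inline double soft_threshold(double u, double thr) {
  if (u > thr) return u - thr;
  if (u < -thr) return u + thr;
  return 0.0;
}

// Elastic-net penalized Cox path by cyclic coordinate descent on the IRLS
// quadratic approximation of the Breslow partial likelihood (objective
// -loglik/n + lambda * sum_j [alpha|b_j| + (1-alpha) b_j^2 / 2]).
// X must be standardized and rows sorted by ascending time; solutions are
// warm-started down the (decreasing) lambda sequence.
// [[Rcpp::export]]
List coxnet_path_cpp(const arma::mat& X, const arma::vec& time,
                     const arma::ivec& status, const arma::vec& lambda,
                     double alpha, double tol, int maxit) {
  const int n = X.n_rows, p = X.n_cols;
  const int L = lambda.n_elem;
  arma::mat B(p, L, arma::fill::zeros);
  arma::ivec conv(L, arma::fill::zeros);
  arma::ivec iters(L, arma::fill::zeros);
  arma::vec beta(p, arma::fill::zeros);
  const arma::vec st = arma::conv_to<arma::vec>::from(status);

  for (int l = 0; l < L; ++l) {
    const double lam = lambda[l];
    bool ok = false;
    int it = 0;
    for (; it < maxit; ++it) {
      arma::vec eta = X * beta;
      const double shift = eta.max();
      arma::vec ex = arma::exp(eta - shift);

      // suffix risk sums, then cumulative event-time hazard increments
      arma::vec suffix(n + 1);
      suffix[n] = 0.0;
      for (int m = n - 1; m >= 0; --m) suffix[m] = suffix[m + 1] + ex[m];

      arma::vec A(n, arma::fill::zeros), Bq(n, arma::fill::zeros);
      double ha = 0.0, h2a = 0.0;
      int a = 0;
      while (a < n) {
        int b = a;
        while (b + 1 < n && time[b + 1] == time[a]) ++b;
        int d = 0;
        for (int m = a; m <= b; ++m) if (status[m] == 1) ++d;
        if (d > 0) {
          const double S0g = suffix[a];
          ha += d / S0g;
          h2a += d / (S0g * S0g);
        }
        for (int m = a; m <= b; ++m) { A[m] = ha; Bq[m] = h2a; }
        a = b + 1;
      }

      arma::vec gr = st - ex % A;             // d loglik / d eta
      arma::vec w = ex % A - arma::square(ex) % Bq;
      arma::vec z(n);
      for (int m = 0; m < n; ++m) {
        if (w[m] < 1e-10) { w[m] = 0.0; z[m] = eta[m]; }
        else z[m] = eta[m] + gr[m] / w[m];
      }

      arma::vec r = z - eta;                  // working residual at current beta
      arma::mat WX(n, p);
      for (int j = 0; j < p; ++j) WX.col(j) = X.col(j) % w;
      arma::vec wx2(p);
      for (int j = 0; j < p; ++j)
        wx2[j] = arma::dot(WX.col(j), X.col(j)) / n;

      // cyclic coordinate descent with an active-set strategy: full sweeps
      // admit new coordinates, then only the active set is iterated
      const arma::vec beta_outer = beta;
      auto update = [&](int j) -> double {
        if (wx2[j] <= 0.0) return 0.0;
        const double bj = beta[j];
        const double u = arma::dot(WX.col(j), r) / n + wx2[j] * bj;
        const double bn =
            soft_threshold(u, lam * alpha) / (wx2[j] + lam * (1.0 - alpha));
        if (bn != bj) {
          r -= X.col(j) * (bn - bj);
          beta[j] = bn;
          return std::fabs(bn - bj);
        }
        return 0.0;
      };
      for (int cycle = 0; cycle < 100; ++cycle) {
        double maxd = 0.0;
        for (int j = 0; j < p; ++j) maxd = std::max(maxd, update(j));
        if (maxd < tol) break;
        for (int sweep = 0; sweep < 1000; ++sweep) {
          double amax = 0.0;
          for (int j = 0; j < p; ++j)
            if (beta[j] != 0.0) amax = std::max(amax, update(j));
          if (amax < tol) break;
        }
      }

      if (arma::abs(beta - beta_outer).max() < tol) { ok = true; break; }
      if (arma::abs(beta).max() > 50.0) break;  // separation guard
    }
    conv[l] = ok ? 1 : 0;
    iters[l] = it + 1;
    B.col(l) = beta;
  }

  return List::create(_["beta"] = B, _["converged"] = conv,
                      _["iterations"] = iters);
}
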