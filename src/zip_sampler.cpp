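// Adaptive Metropolis-within-Gibbs sampler for the two-level zero-inflated
// Poisson mixed model.
//
// Zero component: logit(pi) = X beta + u[cont] + v[house]; pi is the
// productive-state probability, so the structural-zero probability is
// 1 - pi.  Count component: log(lambda) = X delta + w[cont] + z[house].
// Latent productive indicators S are drawn exactly for zero counts;
// fixed and random effects use scalar random-walk Metropolis with
// Robbins-Monro adaptation toward 0.44 acceptance (frozen after burn-in);
// random-effect precisions use conjugate gamma Gibbs updates.
//
// All randomness comes from R's RNG, so runs are reproducible via set.seed.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

struct Adapt {
  std::vector<double> ls;      // log proposal sd
  std::vector<long> acc, att;  // post-burn-in tallies
  void init(int k, double scale) {
    ls.assign(k, std::log(scale));
    acc.assign(k, 0); att.assign(k, 0);
  }
};

// [[Rcpp::export]]
List zip_sampler_cpp(IntegerVector y, NumericMatrix X,
                     IntegerVector cont, IntegerVector house,
                     int nC, int nH,
                     int burn_in, int n_iter, int thin,
                     double prior_prec_fixed,
                     double re_shape, double re_rate,
                     NumericVector init_beta, NumericVector init_delta,
                     double init_variance, double proposal_scale,
                     bool up_beta, bool up_delta, bool up_re, bool up_var) {
  const int n = y.size(), P = X.ncol();
  std::vector<double> beta(init_beta.begin(), init_beta.end());
  std::vector<double> delta(init_delta.begin(), init_delta.end());
  std::vector<double> u(nC, 0.0), v(nH, 0.0), w(nC, 0.0), z(nH, 0.0);
  double tau_u = 1.0 / init_variance, tau_v = tau_u,
         tau_w = tau_u, tau_z = tau_u;

  std::vector<std::vector<int> > rows_c(nC), rows_h(nH);
  for (int r = 0; r < n; ++r) {
    rows_c[cont[r]].push_back(r);
    rows_h[house[r]].push_back(r);
  }

  std::vector<double> eta0(n), etac(n);
  for (int r = 0; r < n; ++r) {
    double e0 = 0.0, ec = 0.0;
    for (int m = 0; m < P; ++m) { e0 += X(r, m) * beta[m]; ec += X(r, m) * delta[m]; }
    eta0[r] = e0 + u[cont[r]] + v[house[r]];
    etac[r] = ec + w[cont[r]] + z[house[r]];
  }
  std::vector<int> S(n, 1);

  // scalar-parameter layout for adaptation:
  // [0..3] beta, [4..7] delta, [8..8+nC) u, then v, w, z
  Adapt ad;
  const int off_u = 2 * P, off_v = off_u + nC, off_w = off_v + nH,
            off_z = off_w + nC, n_par = off_z + nH;
  ad.init(n_par, proposal_scale);

  const int n_store = n_iter / thin;
  NumericMatrix draws(n_store, 12 + 2 * nC + 2 * nH);
  int stored = 0;
  const int total_iter = burn_in + n_iter;

  // log-likelihood deltas for a scalar move ------------------------------
  // zero part over a row set with per-row predictor shift `step * coef(r)`
  // count part analogous, restricted to S == 1 rows.

  RNGScope scope;
  for (int it = 1; it <= total_iter; ++it) {
    const bool adapting = it <= burn_in;
    const double gamma = std::pow((double)it, -0.6);

    // --- latent productive indicators for zero counts
    for (int r = 0; r < n; ++r) {
      if (y[r] > 0) { S[r] = 1; continue; }
      double lam = std::exp(etac[r]);
      double lp1 = -softplus(-eta0[r]) - lam;   // log pi - lambda
      double lp0 = -softplus(eta0[r]);          // log(1 - pi)
      double pr = 1.0 / (1.0 + std::exp(lp0 - lp1));
      S[r] = (R::unif_rand() < pr) ? 1 : 0;
    }

    // --- zero-component fixed effects
    if (up_beta) {
      for (int m = 0; m < P; ++m) {
        const double sdp = std::exp(ad.ls[m]);
        const double step = sdp * R::norm_rand();
        double dll = 0.0;
        for (int r = 0; r < n; ++r) {
          const double d = step * X(r, m);
          if (d == 0.0) continue;
          dll += S[r] * d - softplus(eta0[r] + d) + softplus(eta0[r]);
        }
        const double bn = beta[m] + step;
        dll += -0.5 * prior_prec_fixed * (bn * bn - beta[m] * beta[m]);
        const bool acc = std::log(R::unif_rand()) < dll;
        if (acc) {
          beta[m] = bn;
          for (int r = 0; r < n; ++r) eta0[r] += step * X(r, m);
        }
        if (adapting) ad.ls[m] += gamma * ((acc ? 1.0 : 0.0) - 0.44);
        else { ad.att[m]++; if (acc) ad.acc[m]++; }
      }
    }

    // --- zero-component random effects
    if (up_re) {
      for (int i = 0; i < nC; ++i) {
        const int k = off_u + i;
        const double step = std::exp(ad.ls[k]) * R::norm_rand();
        double dll = 0.0;
        for (size_t a = 0; a < rows_c[i].size(); ++a) {
          const int r = rows_c[i][a];
          dll += S[r] * step - softplus(eta0[r] + step) + softplus(eta0[r]);
        }
        const double un = u[i] + step;
        dll += -0.5 * tau_u * (un * un - u[i] * u[i]);
        const bool acc = std::log(R::unif_rand()) < dll;
        if (acc) {
          u[i] = un;
          for (size_t a = 0; a < rows_c[i].size(); ++a) eta0[rows_c[i][a]] += step;
        }
        if (adapting) ad.ls[k] += gamma * ((acc ? 1.0 : 0.0) - 0.44);
        else { ad.att[k]++; if (acc) ad.acc[k]++; }
      }
      for (int j = 0; j < nH; ++j) {
        const int k = off_v + j;
        const double step = std::exp(ad.ls[k]) * R::norm_rand();
        double dll = 0.0;
        for (size_t a = 0; a < rows_h[j].size(); ++a) {
          const int r = rows_h[j][a];
          dll += S[r] * step - softplus(eta0[r] + step) + softplus(eta0[r]);
        }
        const double vn = v[j] + step;
        dll += -0.5 * tau_v * (vn * vn - v[j] * v[j]);
        const bool acc = std::log(R::unif_rand()) < dll;
        if (acc) {
          v[j] = vn;
          for (size_t a = 0; a < rows_h[j].size(); ++a) eta0[rows_h[j][a]] += step;
        }
        if (adapting) ad.ls[k] += gamma * ((acc ? 1.0 : 0.0) - 0.44);
        else { ad.att[k]++; if (acc) ad.acc[k]++; }
      }
    }

    // --- count-component fixed effects (Poisson likelihood on S == 1 rows)
    if (up_delta) {
      for (int m = 0; m < P; ++m) {
        const int k = P + m;
        const double step = std::exp(ad.ls[k]) * R::norm_rand();
        double dll = 0.0;
        for (int r = 0; r < n; ++r) {
          if (!S[r]) continue;
          const double d = step * X(r, m);
          if (d == 0.0) continue;
          const double lam = std::exp(etac[r]);
          dll += y[r] * d - lam * (std::exp(d) - 1.0);
        }
        const double dn = delta[m] + step;
        dll += -0.5 * prior_prec_fixed * (dn * dn - delta[m] * delta[m]);
        const bool acc = R_finite(dll) && std::log(R::unif_rand()) < dll;
        if (acc) {
          delta[m] = dn;
          for (int r = 0; r < n; ++r) etac[r] += step * X(r, m);
        }
        if (adapting) ad.ls[k] += gamma * ((acc ? 1.0 : 0.0) - 0.44);
        else { ad.att[k]++; if (acc) ad.acc[k]++; }
      }
    }

    // --- count-component random effects
    if (up_re) {
      for (int i = 0; i < nC; ++i) {
        const int k = off_w + i;
        const double step = std::exp(ad.ls[k]) * R::norm_rand();
        const double g = std::exp(step) - 1.0;
        double dll = 0.0;
        for (size_t a = 0; a < rows_c[i].size(); ++a) {
          const int r = rows_c[i][a];
          if (!S[r]) continue;
          dll += y[r] * step - std::exp(etac[r]) * g;
        }
        const double wn = w[i] + step;
        dll += -0.5 * tau_w * (wn * wn - w[i] * w[i]);
        const bool acc = R_finite(dll) && std::log(R::unif_rand()) < dll;
        if (acc) {
          w[i] = wn;
          for (size_t a = 0; a < rows_c[i].size(); ++a) etac[rows_c[i][a]] += step;
        }
        if (adapting) ad.ls[k] += gamma * ((acc ? 1.0 : 0.0) - 0.44);
        else { ad.att[k]++; if (acc) ad.acc[k]++; }
      }
      for (int j = 0; j < nH; ++j) {
        const int k = off_z + j;
        const double step = std::exp(ad.ls[k]) * R::norm_rand();
        const double g = std::exp(step) - 1.0;
        double dll = 0.0;
        for (size_t a = 0; a < rows_h[j].size(); ++a) {
          const int r = rows_h[j][a];
          if (!S[r]) continue;
          dll += y[r] * step - std::exp(etac[r]) * g;
        }
        const double zn = z[j] + step;
        dll += -0.5 * tau_z * (zn * zn - z[j] * z[j]);
        const bool acc = R_finite(dll) && std::log(R::unif_rand()) < dll;
        if (acc) {
          z[j] = zn;
          for (size_t a = 0; a < rows_h[j].size(); ++a) etac[rows_h[j][a]] += step;
        }
        if (adapting) ad.ls[k] += gamma * ((acc ? 1.0 : 0.0) - 0.44);
        else { ad.att[k]++; if (acc) ad.acc[k]++; }
      }
    }

    // --- conjugate gamma updates of the random-effect precisions
    if (up_var) {
      double ssu = 0, ssv = 0, ssw = 0, ssz = 0;
      for (int i = 0; i < nC; ++i) { ssu += u[i] * u[i]; ssw += w[i] * w[i]; }
      for (int j = 0; j < nH; ++j) { ssv += v[j] * v[j]; ssz += z[j] * z[j]; }
      tau_u = R::rgamma(re_shape + 0.5 * nC, 1.0 / (re_rate + 0.5 * ssu));
      tau_v = R::rgamma(re_shape + 0.5 * nH, 1.0 / (re_rate + 0.5 * ssv));
      tau_w = R::rgamma(re_shape + 0.5 * nC, 1.0 / (re_rate + 0.5 * ssw));
      tau_z = R::rgamma(re_shape + 0.5 * nH, 1.0 / (re_rate + 0.5 * ssz));
    }

    // --- storage
    if (it > burn_in && (it - burn_in) % thin == 0) {
      int c = 0;
      for (int m = 0; m < P; ++m) draws(stored, c++) = beta[m];
      for (int m = 0; m < P; ++m) draws(stored, c++) = delta[m];
      draws(stored, c++) = 1.0 / tau_u;
      draws(stored, c++) = 1.0 / tau_v;
      draws(stored, c++) = 1.0 / tau_w;
      draws(stored, c++) = 1.0 / tau_z;
      for (int i = 0; i < nC; ++i) draws(stored, c++) = u[i];
      for (int j = 0; j < nH; ++j) draws(stored, c++) = v[j];
      for (int i = 0; i < nC; ++i) draws(stored, c++) = w[i];
      for (int j = 0; j < nH; ++j) draws(stored, c++) = z[j];
      ++stored;
    }
    if (it % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  // block-averaged acceptance rates
  auto rate = [&](int from, int count) {
    double a = 0, t = 0;
    for (int k = from; k < from + count; ++k) { a += ad.acc[k]; t += ad.att[k]; }
    return t > 0 ? a / t : NA_REAL;
  };
  NumericVector accept = NumericVector::create(
    _["beta"] = rate(0, P), _["delta"] = rate(P, P),
    _["u"] = rate(off_u, nC), _["v"] = rate(off_v, nH),
    _["w"] = rate(off_w, nC), _["z"] = rate(off_z, nH));

  return List::create(_["draws"] = draws, _["accept"] = accept);
}
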