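#include <Rcpp.h>
using namespace Rcpp;

// Two-boundary Wiener first-passage machinery with diffusion coefficient 1 and
// unbiased start (relative start w = 1/2). All times are decision times, i.e.
// observed time minus nondecision time. "Upper" is the affirmative boundary.
//
// The density uses the standardized form f(t | mu, alpha) =
//   alpha^{-2} exp(mu*alpha*w - mu^2 t / 2) * f_std(t / alpha^2)
// with f_std evaluated through either the large-time sine series or the
// small-time Gaussian-mirror series, whichever needs fewer terms for the
// requested accuracy (the large-time series converges poorly near t = 0).

static const double W_HALF = 0.5;

// log of the standardized density at scaled time tau (> 0), w = 1/2
static double log_fstd(double tau) {
  const double eps = 1e-12;   // truncation tolerance on the f_std scale
  const double pi = M_PI;

  // terms needed by each representation (Navarro & Fuss style bounds)
  double kl, ks;
  if (pi * tau * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(pi * tau * eps) / (pi * pi * tau));
    kl = std::max(kl, 1.0 / (pi * std::sqrt(tau)));
  } else {
    kl = 1.0 / (pi * std::sqrt(tau));
  }
  if (2.0 * std::sqrt(2.0 * pi * tau) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tau * std::log(2.0 * eps * std::sqrt(2.0 * pi * tau)));
    ks = std::max(ks, std::sqrt(tau) + 1.0);
  } else {
    ks = 2.0;
  }

  if (ks < kl) {
    // small-time: sum over mirror images, leading term factored out so the
    // log never underflows
    int K = (int)std::ceil((ks - 1.0) / 2.0);
    if (K < 1) K = 1;
    double S = 0.0;
    for (int k = -K; k <= K; ++k) {
      double wk = W_HALF + 2.0 * k;
      S += wk * std::exp(-(wk * wk - W_HALF * W_HALF) / (2.0 * tau));
    }
    if (S <= 0.0) return R_NegInf;
    return -0.5 * std::log(2.0 * pi) - 1.5 * std::log(tau) -
           W_HALF * W_HALF / (2.0 * tau) + std::log(S);
  }
  // large-time: odd k only (sin(k*pi/2) vanishes for even k), leading
  // exponential factored out; hard cap of 500 terms
  int K = (int)std::ceil(kl);
  if (K > 500) K = 500;
  double S = 0.0;
  double sgn = 1.0;
  for (int k = 1; k <= K; k += 2) {
    S += sgn * k * std::exp(-((double)k * k - 1.0) * pi * pi * tau / 2.0);
    sgn = -sgn;
  }
  if (S <= 0.0) return R_NegInf;
  return std::log(pi) + std::log(S) - pi * pi * tau / 2.0;
}

// log joint defective density of hitting the boundary indicated by the sign
// of mu at decision time td: pass mu for the upper boundary, -mu for the lower
static double log_wfpt_pdf(double td, double mu, double alpha) {
  if (!(td > 0.0) || !(alpha > 0.0) || !R_finite(td)) return R_NegInf;
  double tau = td / (alpha * alpha);
  return log_fstd(tau) - 2.0 * std::log(alpha) + mu * alpha * W_HALF -
         mu * mu * td / 2.0;
}

// defective CDF of hitting the upper boundary by decision time td, drift mu
static double wfpt_cdf_upper(double td, double mu, double alpha) {
  double pup = 1.0 / (1.0 + std::exp(-alpha * mu));
  if (td <= 0.0) return 0.0;
  if (!R_finite(td)) return pup;
  const double pi = M_PI;
  // term-by-term integral of the large-time series for the survival part
  double C = std::exp(std::min(mu * alpha * W_HALF, 700.0)) / (alpha * alpha);
  double tail = 0.0;
  double sgn = 1.0;
  const int kmax = 100000;
  for (int k = 1; k <= kmax; k += 2) {
    double lam = mu * mu / 2.0 + (double)k * k * pi * pi / (2.0 * alpha * alpha);
    double decay = lam * td;
    double term = sgn * pi * (double)k * std::exp(-decay) / lam;
    tail += term;
    sgn = -sgn;
    if (decay > 45.0 && std::fabs(term) < 1e-14 * (1.0 + std::fabs(tail))) break;
  }
  double F = pup - C * tail;
  if (F < 0.0) F = 0.0;
  if (F > pup) F = pup;
  return F;
}

//' @noRd
// [[Rcpp::export(name = ".wfpt_logpdf_cpp")]]
NumericVector wfpt_logpdf_cpp(NumericVector td, NumericVector mu,
                              NumericVector alpha) {
  int n = std::max(td.size(), std::max(mu.size(), alpha.size()));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = log_wfpt_pdf(td[i % td.size()], mu[i % mu.size()],
                          alpha[i % alpha.size()]);
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".wfpt_cdf_cpp")]]
NumericVector wfpt_cdf_cpp(NumericVector td, NumericVector mu,
                           NumericVector alpha) {
  int n = std::max(td.size(), std::max(mu.size(), alpha.size()));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = wfpt_cdf_upper(td[i % td.size()], mu[i % mu.size()],
                            alpha[i % alpha.size()]);
  }
  return out;
}

// invert the defective upper CDF at target (0 < target < p_side) by bisection
static double wfpt_cdf_invert(double target, double mu, double alpha) {
  double lo = 0.0, hi = 1.0;
  int guard = 0;
  while (wfpt_cdf_upper(hi, mu, alpha) < target && guard++ < 60) hi *= 2.0;
  for (int it = 0; it < 80; ++it) {
    double mid = 0.5 * (lo + hi);
    if (wfpt_cdf_upper(mid, mu, alpha) < target) lo = mid; else hi = mid;
    if (hi - lo < 1e-10 * (1.0 + hi)) break;
  }
  return 0.5 * (lo + hi);
}

//' @noRd
// [[Rcpp::export(name = ".wfpt_sample_cpp")]]
List wfpt_sample_cpp(NumericVector mu, NumericVector alpha, NumericVector ter) {
  int n = std::max(mu.size(), std::max(alpha.size(), ter.size()));
  IntegerVector x(n);
  NumericVector t(n);
  for (int i = 0; i < n; ++i) {
    double m = mu[i % mu.size()];
    double a = alpha[i % alpha.size()];
    double t0 = ter[i % ter.size()];
    double pup = 1.0 / (1.0 + std::exp(-a * m));
    double u1 = unif_rand();
    int xi = (u1 <= pup) ? 1 : 0;
    double ms = xi ? m : -m;               // by symmetry invert the hit side's CDF
    double pside = xi ? pup : 1.0 - pup;
    double u2 = unif_rand() * pside;
    // keep the inversion away from the exact endpoints
    if (u2 <= 0.0) u2 = 1e-300;
    if (u2 >= pside) u2 = pside * (1.0 - 1e-12);
    double td = wfpt_cdf_invert(u2, ms, a);
    x[i] = xi;
    t[i] = td + t0;
  }
  return List::create(_["x"] = x, _["t"] = t);
}

// marginal likelihood pieces for the D-diffusion IRT model ------------------

// per-row log-likelihood on the tensor quadrature grid; shared by the nll and
// the EAP scorer. X: 0/1 (NA_INTEGER missing); TD: decision times (NA missing).
// The standardized-density part depends only on (item, gamma-node), so it is
// computed once per (h, r) and the theta loop reduces to cheap arithmetic.
static void row_grid_loglik(const IntegerMatrix &X, const NumericMatrix &TD,
                            int i, const NumericVector &v,
                            const NumericVector &a, const NumericVector &theta,
                            const NumericVector &gam, std::vector<double> &s) {
  int H = X.ncol();
  int Q = theta.size(), R = gam.size();
  std::vector<int> items;
  items.reserve(H);
  for (int h = 0; h < H; ++h)
    if (X(i, h) != NA_INTEGER && R_finite(TD(i, h))) items.push_back(h);
  int M = items.size();
  std::vector<double> base(M * R), alv(M * R);
  for (int m = 0; m < M; ++m) {
    int h = items[m];
    double td = TD(i, h);
    for (int r = 0; r < R; ++r) {
      double al = gam[r] / a[h];
      alv[m * R + r] = al;
      base[m * R + r] = log_fstd(td / (al * al)) - 2.0 * std::log(al);
    }
  }
  for (int q = 0; q < Q; ++q) {
    for (int r = 0; r < R; ++r) {
      double acc = 0.0;
      for (int m = 0; m < M; ++m) {
        int h = items[m];
        double mu = theta[q] - v[h];
        if (X(i, h) == 0) mu = -mu;
        acc += base[m * R + r] + mu * alv[m * R + r] * W_HALF -
               mu * mu * TD(i, h) / 2.0;
      }
      s[q * R + r] = acc;
    }
  }
}

//' @noRd
// [[Rcpp::export(name = ".diffirt_nll_cpp")]]
double diffirt_nll_cpp(IntegerMatrix X, NumericMatrix TD, NumericVector v,
                       NumericVector a, double sd_theta, double sd_lg,
                       NumericVector z, NumericVector wts) {
  int N = X.nrow();
  int Q = z.size();
  NumericVector theta(Q), gam(Q);
  for (int q = 0; q < Q; ++q) {
    theta[q] = sd_theta * z[q];
    gam[q] = std::exp(sd_lg * z[q]);
  }
  std::vector<double> lw(Q * Q), s(Q * Q);
  for (int q = 0; q < Q; ++q)
    for (int r = 0; r < Q; ++r) lw[q * Q + r] = std::log(wts[q] * wts[r]);
  double nll = 0.0;
  for (int i = 0; i < N; ++i) {
    row_grid_loglik(X, TD, i, v, a, theta, gam, s);
    double mx = R_NegInf;
    for (int j = 0; j < Q * Q; ++j) {
      double val = s[j] + lw[j];
      if (val > mx) mx = val;
    }
    if (!R_finite(mx)) { nll += 1e8; continue; }  // keep the optimizer moving
    double sum = 0.0;
    for (int j = 0; j < Q * Q; ++j) sum += std::exp(s[j] + lw[j] - mx);
    nll -= mx + std::log(sum);
  }
  return nll;
}

//' @noRd
// [[Rcpp::export(name = ".diffirt_eap_cpp")]]
NumericMatrix diffirt_eap_cpp(IntegerMatrix X, NumericMatrix TD,
                              NumericVector v, NumericVector a,
                              double sd_theta, double sd_lg, NumericVector z,
                              NumericVector wts) {
  int N = X.nrow();
  int Q = z.size();
  NumericVector theta(Q), gam(Q), lgam(Q);
  for (int q = 0; q < Q; ++q) {
    theta[q] = sd_theta * z[q];
    lgam[q] = sd_lg * z[q];
    gam[q] = std::exp(lgam[q]);
  }
  std::vector<double> lw(Q * Q), s(Q * Q);
  for (int q = 0; q < Q; ++q)
    for (int r = 0; r < Q; ++r) lw[q * Q + r] = std::log(wts[q] * wts[r]);
  NumericMatrix out(N, 2);
  for (int i = 0; i < N; ++i) {
    row_grid_loglik(X, TD, i, v, a, theta, gam, s);
    double mx = R_NegInf;
    for (int j = 0; j < Q * Q; ++j) {
      double val = s[j] + lw[j];
      if (val > mx) mx = val;
    }
    if (!R_finite(mx)) { out(i, 0) = NA_REAL; out(i, 1) = NA_REAL; continue; }
    double den = 0.0, nth = 0.0, nlg = 0.0;
    for (int q = 0; q < Q; ++q) {
      for (int r = 0; r < Q; ++r) {
        double wgt = std::exp(s[q * Q + r] + lw[q * Q + r] - mx);
        den += wgt;
        nth += wgt * theta[q];
        nlg += wgt * lgam[r];
      }
    }
    out(i, 0) = nth / den;
    out(i, 1) = nlg / den;
  }
  return out;
}
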