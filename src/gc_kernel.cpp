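// Batch per-window bivariate spectral Granger causality.
//
// Mirrors, step for step, the R reference path: detrend/demean ->
// ADF/KPSS stationarity gate -> (first difference + re-detrend + re-gate)
// -> BIC order selection on the common sample -> least-squares VAR fit ->
// closed-form 2x2 spectral causality on the frequency grid. The R
// implementations in R/preprocess.R and R/vargc.R are the documentation
// of record; this kernel exists because a cohort analysis touches ~10^5
// windows and the per-window cost must stay in microseconds.

#include <RcppArmadillo.h>
#include <cfloat>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void detrend_demean_ip(mat& w) {
  const uword n = w.n_rows;
  vec t0(n);
  for (uword i = 0; i < n; ++i) t0(i) = (double)(i + 1) - (double)(n + 1) / 2.0;
  const double stt = dot(t0, t0);
  for (uword j = 0; j < w.n_cols; ++j) {
    const double mu = mean(w.col(j));
    const double slope = dot(t0, w.col(j)) / stt;
    w.col(j) -= mu + slope * t0;
  }
}

// 5% Dickey-Fuller tau critical value (constant, no trend), interpolated in 1/n
static double adf_cv_5pct(const double n) {
  const double ns[6] = {25, 50, 100, 250, 500, 1e9};
  const double cv[6] = {-3.00, -2.93, -2.89, -2.88, -2.87, -2.86};
  const double x = 1.0 / std::max(n, 25.0);
  if (x >= 1.0 / ns[0]) return cv[0];
  for (int i = 0; i < 5; ++i) {
    const double x1 = 1.0 / ns[i + 1], x0 = 1.0 / ns[i];
    if (x >= x1) return cv[i + 1] + (x - x1) / (x0 - x1) * (cv[i] - cv[i + 1]);
  }
  return cv[5];
}

// ADF test with fixed lag 1: true = rejects the unit root
static bool adf_reject(const vec& y) {
  const uword n = y.n_elem;
  if (n < 11) return false;
  vec dy = diff(y);
  const uword lags = 1, m = n - 1 - lags;  // rows t = lags+1 .. n-1 of dy
  mat X(m, 3);
  vec yy(m);
  for (uword i = 0; i < m; ++i) {
    const uword t = lags + i;              // index into dy (0-based)
    X(i, 0) = 1.0;
    X(i, 1) = y(t);                        // lagged level y_{t-1} (1-based t)
    X(i, 2) = dy(t - 1);
    yy(i) = dy(t);
  }
  mat XtX = X.t() * X;
  if (rcond(XtX) < 1e-12) return false;
  vec b = solve(XtX, X.t() * yy, solve_opts::likely_sympd);
  vec e = yy - X * b;
  const double s2 = dot(e, e) / (double)(m - 3);
  mat XtXinv = inv(XtX);
  const double se = std::sqrt(s2 * XtXinv(1, 1));
  return (b(1) / se) < adf_cv_5pct((double)n);
}

// KPSS level-stationarity test: true = rejects stationarity
static bool kpss_reject(const vec& y) {
  const uword n = y.n_elem;
  vec e = y - mean(y);
  vec S = cumsum(e);
  const int l = (int)std::floor(4.0 * std::pow((double)n / 100.0, 0.25));
  double lrv = dot(e, e) / (double)n;
  const double g0 = lrv;
  for (int j = 1; j <= l; ++j) {
    const double w = 1.0 - (double)j / (double)(l + 1);
    double g = 0.0;
    for (uword t = j; t < n; ++t) g += e(t) * e(t - j);
    lrv += 2.0 * w * g / (double)n;
  }
  if (lrv <= 0) lrv = g0;
  if (lrv == 0) return false;
  const double stat = dot(S, S) / ((double)n * (double)n * lrv);
  return stat > 0.463;
}

// gate: rule 0 = "both" (ADF rejects AND KPSS does not), 1 = "either"
static bool gate_pass(const mat& w, const int rule) {
  if (w.n_rows < 20) return false;
  for (uword j = 0; j < w.n_cols; ++j) {
    const vec y = w.col(j);
    if (stddev(y) < 1e-12) return false;
    const bool a = adf_reject(y);
    const bool k = kpss_reject(y);
    const bool pass = rule == 0 ? (a && !k) : (a || !k);
    if (!pass) return false;
  }
  return true;
}

static mat lag_design(const mat& w, const uword p, const uword from) {
  // rows t = from..n (1-based), columns stacked by lag
  const uword n = w.n_rows, d = w.n_cols, m = n - from + 1;
  mat X(m, d * p);
  for (uword k = 1; k <= p; ++k) {
    X.cols((k - 1) * d, k * d - 1) = w.rows(from - 1 - k, n - 1 - k);
  }
  return X;
}

// [[Rcpp::export]]
Rcpp::List gc_pair_windows_cpp(const arma::mat& x,
                               const arma::uvec& starts,
                               const int len,
                               const int p_max,
                               const arma::vec& omega,
                               const int rule) {
  const uword nw = starts.n_elem, nf = omega.n_elem;
  mat f21(nw, nf, fill::value(datum::nan));
  mat f12(nw, nf, fill::value(datum::nan));
  Rcpp::IntegerVector order(nw, NA_INTEGER);
  imat flags(nw, 5, fill::zeros);  // differenced, nonstationary, usable, clip21, clip12

  // precompute exp(-i k omega) for k = 1..p_max
  cx_mat ph(nf, (uword)p_max);
  for (int k = 1; k <= p_max; ++k) {
    for (uword f = 0; f < nf; ++f) {
      ph(f, k - 1) = std::exp(std::complex<double>(0.0, -(double)k * omega(f)));
    }
  }

  for (uword wi = 0; wi < nw; ++wi) {
    mat w = x.rows(starts(wi) - 1, starts(wi) - 1 + len - 1);
    detrend_demean_ip(w);
    bool differenced = false, nonstat = false;
    if (!gate_pass(w, rule)) {
      w = diff(w);
      detrend_demean_ip(w);
      differenced = true;
      nonstat = !gate_pass(w, rule);
    }
    flags(wi, 0) = differenced;
    flags(wi, 1) = nonstat;
    const bool degenerate = stddev(w.col(0)) <= 1e-12 || stddev(w.col(1)) <= 1e-12;
    if (degenerate) { flags(wi, 2) = 0; continue; }

    // BIC order selection on the common sample
    const uword n = w.n_rows, d = 2;
    int pm = p_max;
    while (pm >= 1 && (int)n - pm <= (int)d * pm + 1) --pm;
    if (pm < 1) { flags(wi, 2) = 0; continue; }
    int best_p = -1;
    double best_bic = datum::inf;
    for (int p = 1; p <= pm; ++p) {
      mat Y = w.rows((uword)pm, n - 1);
      mat X = lag_design(w, (uword)p, (uword)pm + 1);
      mat XtX = X.t() * X;
      if (rcond(XtX) < 1e-12) continue;
      mat B = solve(XtX, X.t() * Y, solve_opts::likely_sympd);
      mat E = Y - X * B;
      const double N = (double)Y.n_rows;
      double dets = det(E.t() * E / N);
      if (dets < DBL_MIN) dets = DBL_MIN;
      const double bic = std::log(dets) + std::log(N) / N * (double)(p * 4);
      if (bic < best_bic) { best_bic = bic; best_p = p; }
    }
    if (best_p < 0) { flags(wi, 2) = 0; continue; }
    order[wi] = best_p;

    // final fit at the selected order on the maximal sample
    const uword p = (uword)best_p;
    mat Y = w.rows(p, n - 1);
    mat X = lag_design(w, p, p + 1);
    mat XtX = X.t() * X;
    if (rcond(XtX) < 1e-12) { flags(wi, 2) = 0; continue; }
    mat B = solve(XtX, X.t() * Y, solve_opts::likely_sympd);
    mat E = Y - X * B;
    const double N = (double)Y.n_rows, k = (double)(2 * p);
    mat Sigma = E.t() * E / (N - k);

    const double s11 = Sigma(0, 0), s22 = Sigma(1, 1), s12 = Sigma(0, 1);
    const double sig2g1 = s22 - s12 * s12 / s11;
    const double sig1g2 = s11 - s12 * s12 / s22;
    int clip21 = 0, clip12 = 0;
    bool any_ok = false;
    for (uword f = 0; f < nf; ++f) {
      std::complex<double> a11(1, 0), a12(0, 0), a21(0, 0), a22(1, 0);
      for (uword kk = 1; kk <= p; ++kk) {
        const std::complex<double> ek = ph(f, kk - 1);
        a11 -= B((kk - 1) * 2 + 0, 0) * ek;   // A[1,1,k] = B[(k-1)d+1, 1]
        a12 -= B((kk - 1) * 2 + 1, 0) * ek;   // A[1,2,k]
        a21 -= B((kk - 1) * 2 + 0, 1) * ek;   // A[2,1,k]
        a22 -= B((kk - 1) * 2 + 1, 1) * ek;
      }
      const std::complex<double> det = a11 * a22 - a12 * a21;
      if (std::abs(det) < 1e-12) continue;
      const std::complex<double> H11 = a22 / det, H12 = -a12 / det;
      const std::complex<double> H21 = -a21 / det, H22 = a11 / det;
      const double S11 = std::real(H11 * s11 * std::conj(H11) + H11 * s12 * std::conj(H12)
                                 + H12 * s12 * std::conj(H11) + H12 * s22 * std::conj(H12));
      const double S22 = std::real(H21 * s11 * std::conj(H21) + H21 * s12 * std::conj(H22)
                                 + H22 * s12 * std::conj(H21) + H22 * s22 * std::conj(H22));
      if (S11 <= 0 || S22 <= 0) continue;
      double v21 = -std::log(1.0 - sig2g1 * std::norm(H12) / S11);
      double v12 = -std::log(1.0 - sig1g2 * std::norm(H21) / S22);
      if (v21 < -1e-10) ++clip21;
      if (v12 < -1e-10) ++clip12;
      if (v21 < 0) v21 = 0;
      if (v12 < 0) v12 = 0;
      f21(wi, f) = v21;
      f12(wi, f) = v12;
      any_ok = true;
    }
    flags(wi, 2) = any_ok ? 1 : 0;
    flags(wi, 3) = clip21;
    flags(wi, 4) = clip12;
  }

  return Rcpp::List::create(Rcpp::Named("f21") = f21,
                            Rcpp::Named("f12") = f12,
                            Rcpp::Named("order") = order,
                            Rcpp::Named("flags") = flags);
}
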