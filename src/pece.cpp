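#include <Rcpp.h>
#include <cmath>
#include <functional>
using namespace Rcpp;

// Full-memory Adams-Bashforth-Moulton (PECE) stepper for the Caputo system
//   D^alpha y = f(y),  y(0) = y0,  on the uniform grid t_k = k*h.
//
// Predictor: product-rectangle rule on the Volterra integral form,
//   y^P_{k+1} = y0 + h^a/Gamma(a+1) * sum_{j=0}^{k} b_{k-j} f_j,
//   b_m = (m+1)^a - m^a.
// Corrector: product-trapezoid rule, applied `corrector_iters` times,
//   y_{k+1} = y0 + h^a/Gamma(a+2) * [ a0_k f_0 + sum_{j=1}^{k} c_{k+1-j} f_j
//                                     + f(y*) ],
//   a0_k = k^{a+1} - (k - a)(k+1)^a,
//   c_m  = (m+1)^{a+1} - 2 m^{a+1} + (m-1)^{a+1}.
// No memory truncation: cost is O(n^2) in the number of steps, which the
// precomputed power tables keep to a fused multiply-add per history point.

typedef std::function<void(const std::vector<double>&, std::vector<double>&)> field_fn;

static NumericMatrix pece_run(const field_fn& f, const NumericVector& y0,
                              double alpha, double h, int n,
                              int corrector_iters) {
  if (alpha <= 0.0 || alpha > 1.0) stop("alpha must be in (0, 1]");
  if (h <= 0.0) stop("step size must be positive");
  if (n < 1) stop("need at least one step");
  if (corrector_iters < 1) stop("corrector_iters must be >= 1");

  const int d = y0.size();
  NumericMatrix y(n + 1, d);
  // f history stored one contiguous array per component so the memory sums
  // are plain dot products the compiler can vectorize
  std::vector<std::vector<double>> fv(d, std::vector<double>(n + 1));
  const double ha = std::pow(h, alpha);
  const double wpred = ha / R::gammafn(alpha + 1.0);
  const double wcorr = ha / R::gammafn(alpha + 2.0);

  // power tables: pa[m] = m^alpha, pa1[m] = m^(alpha+1)
  std::vector<double> pa(n + 2), pa1(n + 2);
  for (int m = 0; m <= n + 1; ++m) {
    pa[m] = std::pow((double)m, alpha);
    pa1[m] = std::pow((double)m, alpha + 1.0);
  }

  std::vector<double> ycur(d), fcur(d), wb(n + 1), wc(n + 1);
  for (int c = 0; c < d; ++c) { y(0, c) = y0[c]; ycur[c] = y0[c]; }
  f(ycur, fcur);
  for (int c = 0; c < d; ++c) fv[c][0] = fcur[c];

  for (int k = 0; k < n; ++k) {
    // predictor weights  wb[j] = (k+1-j)^a - (k-j)^a,  j = 0..k
    // corrector weights  wc[0] = k^{a+1} - (k-a)(k+1)^a,
    //                    wc[j] = (k+2-j)^{a+1} - 2(k+1-j)^{a+1} + (k-j)^{a+1}
    for (int j = 0; j <= k; ++j) wb[j] = pa[k + 1 - j] - pa[k - j];
    wc[0] = pa1[k] - (k - alpha) * pa[k + 1];
    for (int j = 1; j <= k; ++j) {
      const int m = k + 1 - j;
      wc[j] = pa1[m + 1] - 2.0 * pa1[m] + pa1[m - 1];
    }

    std::vector<double> hist(d);
    for (int c = 0; c < d; ++c) {
      const double* fc = fv[c].data();
      double sp = 0.0, sc_ = 0.0;
      for (int j = 0; j <= k; ++j) {
        sp += wb[j] * fc[j];
        sc_ += wc[j] * fc[j];
      }
      ycur[c] = y0[c] + wpred * sp;   // predictor value
      hist[c] = sc_;
    }

    for (int it = 0; it < corrector_iters; ++it) {
      f(ycur, fcur);
      for (int c = 0; c < d; ++c)
        ycur[c] = y0[c] + wcorr * (hist[c] + fcur[c]);
    }

    for (int c = 0; c < d; ++c) {
      if (!std::isfinite(ycur[c]))
        stop("state became non-finite at step %d (t = %g), component %d",
             k + 1, (k + 1) * h, c + 1);
      y(k + 1, c) = ycur[c];
    }
    f(ycur, fcur);
    for (int c = 0; c < d; ++c) fv[c][k + 1] = fcur[c];
  }
  return y;
}

// Generic stepper: the field is an R closure taking the state vector
// (autonomous system).
// [[Rcpp::export]]
NumericMatrix pece_core(Function f, NumericVector y0, double alpha,
                        double h, int n, int corrector_iters) {
  const int d = y0.size();
  field_fn fld = [&](const std::vector<double>& yin, std::vector<double>& out) {
    NumericVector yv(yin.begin(), yin.end());
    NumericVector r = as<NumericVector>(f(yv));
    if (r.size() != d) stop("f must return a vector of the same length as y0");
    for (int c = 0; c < d; ++c) out[c] = r[c];
  };
  return pece_run(fld, y0, alpha, h, n, corrector_iters);
}

// Fast path for the 5-state cancer model: the (sigma-scaled) right-hand
// side is evaluated in compiled code, avoiding one R callback per
// evaluation.  `par` is the parameter vector in the canonical order of
// model_parameters(); `scale` is sigma^(1-alpha); `extended` switches on
// the g5/g6/g7 cross-recruitment terms.
// [[Rcpp::export]]
NumericMatrix pece_model_core(NumericVector par, NumericVector y0,
                              double alpha, double h, int n,
                              int corrector_iters, double scale,
                              bool extended) {
  if (par.size() != 27) stop("parameter vector must have 27 entries");
  if (y0.size() != 5) stop("model state has 5 components");
  const double g1 = par[0], g2 = par[1], g3 = par[2], g4 = par[3],
    delta = par[4], u1 = par[5], u2 = par[6], u3 = par[7],
    s1 = par[8], s2 = par[9], s3 = par[10], s4 = par[11],
    r1 = par[12], r2 = par[13], beta1 = par[14], omega = par[15],
    beta2 = par[16], beta3 = par[17], beta4 = par[18],
    d1 = par[19], d2 = par[20], d3 = par[21], vartheta = par[22],
    b = par[23], g5 = par[24], g6 = par[25], g7 = par[26];

  field_fn fld = [=](const std::vector<double>& y, std::vector<double>& out) {
    const double T = y[0], M = y[1], G = y[2], C = y[3], P = y[4];
    out[0] = g1 * T * (1.0 - T / s1) - beta1 * T * M / (s2 + T) -
             omega * T * C / (s4 + T) - u3 * T;
    out[1] = g2 * T / (s2 + T) - (beta2 + d1) * M;
    out[2] = r1 + g3 * T / (s3 + T) - (beta3 + d2) * G;
    out[3] = r2 + g4 * G - (beta4 + d3) * C + delta * P * C / (b + P) + u2 * C;
    out[4] = u1 - vartheta * P;
    if (extended) {
      out[1] += g5 * C / (s2 + C);
      out[2] += g6 * M / (s3 + M) + g7 * C / (s3 + C);
    }
    for (int c = 0; c < 5; ++c) out[c] *= scale;
  };
  return pece_run(fld, y0, alpha, h, n, corrector_iters);
}
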