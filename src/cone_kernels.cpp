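#include <Rcpp.h>
using namespace Rcpp;

// Ring amplitude of a phase-cone component at (x, y, t) sample points.
// par = (x0, y0, t0, speed, a, w); orientation > 0 expands the ring from
// radius zero at onset, orientation < 0 contracts it so the radius reaches
// zero at Tmax; the signal is gated to t >= t0.
// [[Rcpp::export]]
NumericVector cone_predict_cpp(NumericVector par, double orientation,
                               NumericVector x, NumericVector y,
                               NumericVector t, double Tmax) {
  const double x0 = par[0], y0 = par[1], t0 = par[2], s = par[3],
               a = par[4], w = par[5];
  const double inv2w2 = 1.0 / (2.0 * w * w);
  const R_xlen_t n = x.size();
  NumericVector g(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (t[i] < t0) continue;
    const double dx = x[i] - x0, dy = y[i] - y0;
    const double rho = std::sqrt(dx * dx + dy * dy);
    const double R = orientation > 0 ? s * (t[i] - t0) : s * (Tmax - t[i]);
    const double dev = rho - R;
    g[i] = a * std::exp(-dev * dev * inv2w2);
  }
  return g;
}

// Weighted sum of squared residuals sum_i w_i (amp_i - g_i)^2.
// [[Rcpp::export]]
double cone_wsse_cpp(NumericVector par, double orientation,
                     NumericVector x, NumericVector y, NumericVector t,
                     double Tmax, NumericVector w, NumericVector amp) {
  const double x0 = par[0], y0 = par[1], t0 = par[2], s = par[3],
               a = par[4], wd = par[5];
  const double inv2w2 = 1.0 / (2.0 * wd * wd);
  const R_xlen_t n = x.size();
  double sse = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double g = 0.0;
    if (t[i] >= t0) {
      const double dx = x[i] - x0, dy = y[i] - y0;
      const double rho = std::sqrt(dx * dx + dy * dy);
      const double R = orientation > 0 ? s * (t[i] - t0) : s * (Tmax - t[i]);
      const double dev = rho - R;
      g = a * std::exp(-dev * dev * inv2w2);
    }
    const double r = amp[i] - g;
    sse += w[i] * r * r;
  }
  return sse;
}

// One fused pass of the Gauss-Newton normal equations for the weighted
// residual r_i = sqrt(w_i) (amp_i - g_i): returns H = J'J, grad = J'r and
// the weighted SSE, for the parameter subset `cols` (1-based indices into
// x0, y0, t0, speed, a, w).  J = -sqrt(w) dg/dtheta; nothing of size n is
// allocated.
// [[Rcpp::export]]
List cone_gn_terms_cpp(NumericVector par, double orientation,
                       NumericVector x, NumericVector y, NumericVector t,
                       double Tmax, NumericVector w, NumericVector amp,
                       IntegerVector cols) {
  const double x0 = par[0], y0 = par[1], t0 = par[2], s = par[3],
               a = par[4], wd = par[5];
  const double w2 = wd * wd;
  const double inv2w2 = 1.0 / (2.0 * w2);
  const R_xlen_t n = x.size();
  const int p = cols.size();
  NumericMatrix H(p, p);
  NumericVector grad(p);
  double sse = 0.0;
  double d[6], jrow[6];
  for (R_xlen_t i = 0; i < n; ++i) {
    double g = 0.0;
    bool gated = t[i] >= t0;
    double dev = 0.0, E = 0.0, u = 0.0, dx = 0.0, dy = 0.0, inv_rho = 0.0;
    if (gated) {
      dx = x[i] - x0;
      dy = y[i] - y0;
      const double rho = std::sqrt(dx * dx + dy * dy);
      const double R = orientation > 0 ? s * (t[i] - t0) : s * (Tmax - t[i]);
      dev = rho - R;
      E = std::exp(-dev * dev * inv2w2);
      g = a * E;
      u = dev / w2;
      inv_rho = rho > 1e-12 ? 1.0 / rho : 0.0;
    }
    const double res = amp[i] - g;
    sse += w[i] * res * res;
    if (!gated || E == 0.0) continue;
    d[0] = g * u * dx * inv_rho;
    d[1] = g * u * dy * inv_rho;
    d[2] = orientation > 0 ? -s * g * u : 0.0;
    d[3] = orientation > 0 ? g * u * (t[i] - t0) : g * u * (Tmax - t[i]);
    d[4] = E;
    d[5] = g * dev * dev / (w2 * wd);
    for (int j = 0; j < p; ++j) jrow[j] = w[i] * d[cols[j] - 1];
    // H_{jk} += w d_j d_k ; grad_j += -w d_j * res
    for (int j = 0; j < p; ++j) {
      grad[j] -= jrow[j] * res;
      for (int k = j; k < p; ++k) H(j, k) += jrow[j] * d[cols[k] - 1];
    }
  }
  for (int j = 0; j < p; ++j)
    for (int k = 0; k < j; ++k) H(j, k) = H(k, j);
  return List::create(_["H"] = H, _["grad"] = grad, _["sse"] = sse);
}
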