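#include <Rcpp.h>
using namespace Rcpp;

// Model codes shared with R/dynamics.R (model_code):
// 0 double_well, 1 mutualistic, 2 gene_regulatory, 3 sis.
// Constants are passed as a flat vector in the order of model_constants().

static inline void drift_eval(int model, const NumericMatrix& W, double D,
                              const NumericVector& u, const NumericVector& k,
                              const std::vector<double>& x,
                              std::vector<double>& out) {
  const int n = W.nrow();
  switch (model) {
  case 0: { // double well: -(x-r1)(x-r2)(x-r3) + D sum w_ij x_j + u_i
    for (int i = 0; i < n; ++i) {
      double cpl = 0.0;
      for (int j = 0; j < n; ++j) cpl += W(i, j) * x[j];
      out[i] = -(x[i] - k[0]) * (x[i] - k[1]) * (x[i] - k[2]) + D * cpl + u[i];
    }
    break;
  }
  case 1: { // mutualistic: B_i + x(1-x/K)(x/C-1) + D sum w_ij x_i x_j/(Dt+E x_i+H x_j)
    const double B0 = k[0], C = k[1], Dt = k[2], E = k[3], H = k[4], K = k[5];
    for (int i = 0; i < n; ++i) {
      double cpl = 0.0;
      for (int j = 0; j < n; ++j) {
        if (W(i, j) != 0.0)
          cpl += W(i, j) * x[i] * x[j] / (Dt + E * x[i] + H * x[j]);
      }
      out[i] = (B0 + u[i]) + x[i] * (1.0 - x[i] / K) * (x[i] / C - 1.0) + D * cpl;
    }
    break;
  }
  case 2: { // gene regulatory: -B x^f + D sum w_ij x_j^h/(1+x_j^h) + u_i
    const double B = k[0], f = k[1], h = k[2];
    std::vector<double> hill(n);
    for (int j = 0; j < n; ++j) {
      double xh = std::pow(x[j], h);
      hill[j] = xh / (1.0 + xh);
    }
    for (int i = 0; i < n; ++i) {
      double cpl = 0.0;
      for (int j = 0; j < n; ++j) cpl += W(i, j) * hill[j];
      out[i] = -B * std::pow(x[i], f) + D * cpl + u[i];
    }
    break;
  }
  default: { // sis: lambda sum w_ij (1-x_i) x_j - mu x_i
    const double mu = k[0];
    for (int i = 0; i < n; ++i) {
      double cpl = 0.0;
      for (int j = 0; j < n; ++j) cpl += W(i, j) * x[j];
      out[i] = D * (1.0 - x[i]) * cpl - mu * x[i];
    }
  }
  }
}

// Euler-Maruyama integration: x <- x + drift dt + sigma_i sqrt(dt) xi_i,
// recording the state after the step indices listed in record_at (1-based,
// increasing). States are clamped at zero after each step when clamp is
// true (gene regulatory and SIS models).
// [[Rcpp::export]]
List em_integrate_cpp(int model, NumericMatrix W, double D, NumericVector u,
                      NumericVector sigma, NumericVector x0, double dt,
                      int n_steps, IntegerVector record_at, bool clamp,
                      NumericVector constants) {
  const int n = x0.size();
  const int n_rec = record_at.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> dx(n);
  NumericMatrix samples(n_rec, n);
  const double sdt = std::sqrt(dt);
  int rec = 0;
  for (int step = 1; step <= n_steps; ++step) {
    drift_eval(model, W, D, u, constants, x, dx);
    bool finite = true;
    for (int i = 0; i < n; ++i) {
      x[i] += dx[i] * dt + sigma[i] * sdt * norm_rand();
      if (clamp && x[i] < 0.0) x[i] = 0.0;
      if (!std::isfinite(x[i])) finite = false;
    }
    if (!finite)
      stop("state became non-finite at integration step %d", step);
    if (rec < n_rec && record_at[rec] == step) {
      for (int i = 0; i < n; ++i) samples(rec, i) = x[i];
      ++rec;
    }
  }
  return List::create(_["samples"] = samples,
                      _["final_state"] = NumericVector(x.begin(), x.end()));
}
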