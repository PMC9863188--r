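#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// EM for a latent class model with polytomous indicators.
//
// y:      n x J integer matrix of responses coded 1..K_j, 0 = missing
// K:      number of levels per item
// gamma0: length-C initial class prevalences
// rho0:   list of J matrices, each K_j x C, columns summing to 1
//         (P(response = k | class = c) for item j)
//
// Missing responses contribute nothing to the likelihood (MAR). Parameters
// are clipped to [eps, 1 - eps] and renormalised after every M-step.
// Convergence requires max |param change| < tol_param AND relative
// log-likelihood change < tol_ll. The E- and M-steps are fused into one
// pass over individuals; the log-likelihood reported for an iteration is
// evaluated at the parameters entering that iteration, so convergence
// leaves posteriors consistent with the returned parameters.

// [[Rcpp::export]]
List lca_em_cpp(const IntegerMatrix& y, const IntegerVector& K,
                const NumericVector& gamma0, const List& rho0,
                double tol_param, double tol_ll, int max_iter, double eps) {
  const int n = y.nrow(), J = y.ncol(), C = gamma0.size();

  std::vector<double> g(gamma0.begin(), gamma0.end());
  std::vector< std::vector<double> > R(J);   // rho[j][k + K_j * c]
  std::vector<int> offset(J);
  for (int j = 0; j < J; ++j) {
    NumericMatrix rj = rho0[j];
    R[j].assign(rj.begin(), rj.end());
  }
  // row-major copy of y for locality: yr[i * J + j]
  std::vector<int> yr(static_cast<size_t>(n) * J);
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < n; ++i) yr[static_cast<size_t>(i) * J + j] = y(i, j);

  NumericMatrix post(n, C);
  std::vector<double> logg(C), lp(C), pi(C);
  std::vector< std::vector<double> > LR(J), num(J);
  std::vector< std::vector<double> > den(J);
  std::vector<double> colsum(C);
  double ll = 0.0, ll_prev = R_NegInf;
  double min_increase = R_PosInf;
  double param_change = R_PosInf;
  bool converged = false, degenerate = false;
  int iter = 0;
  std::vector<double> ll_trace;
  ll_trace.reserve(256);

  for (iter = 1; iter <= max_iter; ++iter) {
    for (int c = 0; c < C; ++c) logg[c] = std::log(g[c]);
    for (int j = 0; j < J; ++j) {
      LR[j].resize(R[j].size());
      for (size_t t = 0; t < R[j].size(); ++t) LR[j][t] = std::log(R[j][t]);
      num[j].assign(R[j].size(), 0.0);
      den[j].assign(C, 0.0);
    }
    std::fill(colsum.begin(), colsum.end(), 0.0);
    ll = 0.0;

    // fused E-step + M-step accumulation
    for (int i = 0; i < n; ++i) {
      const int* yi = &yr[static_cast<size_t>(i) * J];
      for (int c = 0; c < C; ++c) lp[c] = logg[c];
      for (int j = 0; j < J; ++j) {
        const int yij = yi[j];
        if (yij > 0) {
          const int Kj = K[j];
          const double* lr = LR[j].data() + (yij - 1);
          for (int c = 0; c < C; ++c) lp[c] += lr[c * Kj];
        }
      }
      double m = lp[0];
      for (int c = 1; c < C; ++c) if (lp[c] > m) m = lp[c];
      double s = 0.0;
      for (int c = 0; c < C; ++c) { pi[c] = std::exp(lp[c] - m); s += pi[c]; }
      ll += m + std::log(s);
      for (int c = 0; c < C; ++c) {
        pi[c] /= s;
        post(i, c) = pi[c];
        colsum[c] += pi[c];
      }
      for (int j = 0; j < J; ++j) {
        const int yij = yi[j];
        if (yij > 0) {
          const int Kj = K[j];
          double* nm = num[j].data() + (yij - 1);
          double* dn = den[j].data();
          for (int c = 0; c < C; ++c) { nm[c * Kj] += pi[c]; dn[c] += pi[c]; }
        }
      }
    }
    ll_trace.push_back(ll);
    if (iter > 1) {
      double inc = ll - ll_prev;
      if (inc < min_increase) min_increase = inc;
      double rel = std::fabs(inc) / (std::fabs(ll_prev) + 1e-300);
      if (rel < tol_ll && param_change < tol_param) { converged = true; break; }
    }
    ll_prev = ll;

    for (int c = 0; c < C; ++c) if (colsum[c] < 1e-8) degenerate = true;
    if (degenerate) break;

    // M-step: closed-form update with boundary clipping
    param_change = 0.0;
    {
      double tot = 0.0;
      std::vector<double> gn(C);
      for (int c = 0; c < C; ++c) {
        gn[c] = colsum[c] / n;
        if (gn[c] < eps) gn[c] = eps;
        if (gn[c] > 1.0 - eps) gn[c] = 1.0 - eps;
        tot += gn[c];
      }
      for (int c = 0; c < C; ++c) {
        gn[c] /= tot;
        double d = std::fabs(gn[c] - g[c]);
        if (d > param_change) param_change = d;
        g[c] = gn[c];
      }
    }
    for (int j = 0; j < J; ++j) {
      const int Kj = K[j];
      for (int c = 0; c < C; ++c) {
        double tot = 0.0;
        for (int k = 0; k < Kj; ++k) {
          double v = (den[j][c] > 0.0) ? num[j][k + Kj * c] / den[j][c] : 1.0 / Kj;
          if (v < eps) v = eps;
          if (v > 1.0 - eps) v = 1.0 - eps;
          num[j][k + Kj * c] = v;
          tot += v;
        }
        for (int k = 0; k < Kj; ++k) {
          double v = num[j][k + Kj * c] / tot;
          double d = std::fabs(v - R[j][k + Kj * c]);
          if (d > param_change) param_change = d;
          R[j][k + Kj * c] = v;
        }
      }
    }
  }
  if (iter > max_iter) iter = max_iter;

  List rho_out(J);
  for (int j = 0; j < J; ++j) {
    NumericMatrix rj(K[j], C);
    std::copy(R[j].begin(), R[j].end(), rj.begin());
    rho_out[j] = rj;
  }
  return List::create(
    _["gamma"] = NumericVector(g.begin(), g.end()),
    _["rho"] = rho_out,
    _["posterior"] = post,
    _["loglik"] = ll,
    _["n_iter"] = iter,
    _["converged"] = converged,
    _["degenerate"] = degenerate,
    _["min_ll_increase"] = (min_increase == R_PosInf) ? NA_REAL : min_increase,
    _["ll_trace"] = NumericVector(ll_trace.begin(), ll_trace.end()));
}
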