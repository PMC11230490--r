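#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Likelihood data, pre-aggregated into unique (P, A, V) cells: n1/n0 count
// lottery/reference choices per cell; v_idx maps each cell to its unique
// outcome value so V^alpha is computed once per distinct value.
struct NllData {
  std::vector<double> P, A, n1, n0, vuniq;
  std::vector<int> v_idx;
  double vref;
};

// Weighted Bernoulli NLL under the subjective-value model with softmax
// choice, parameters on the natural scale. Choice probabilities are clipped
// to [1e-9, 1 - 1e-9]. Uses
//   -log P_V = log1p(exp(-z)),  -log(1 - P_V) = z + log1p(exp(-z))
// with z = gamma * (SV_L - SV_C), so each cell costs one exp and one log1p.
static double nll_eval(double alpha, double beta, double gamma,
                       const NllData& d, std::vector<double>& powv) {
  const double eps = 1e-9;
  const double p_hi = 1.0 - eps;             // upper clipped probability
  const double zmax = std::log(p_hi / eps);
  const double log_lo = std::log(eps);       // log of the lower clip
  const double log_hi = std::log(p_hi);      // log of the upper clip
  const double log_hi_c = std::log(1.0 - p_hi); // log of its complement,
                                                // with its rounding kept
  const double svc = std::pow(d.vref, alpha);
  const size_t nu = d.vuniq.size();
  for (size_t u = 0; u < nu; ++u) powv[u] = std::pow(d.vuniq[u], alpha);
  double nll = 0.0;
  const size_t n = d.P.size();
  for (size_t i = 0; i < n; ++i) {
    double sv = (d.P[i] - beta * d.A[i] / 2.0) * powv[d.v_idx[i]];
    double z = gamma * (sv - svc);
    if (z >= zmax) {        // P_V clipped at 1 - eps
      nll -= d.n1[i] * log_hi + d.n0[i] * log_hi_c;
    } else if (z <= -zmax) { // P_V clipped at eps
      nll -= d.n1[i] * log_lo + d.n0[i] * log_hi;
    } else {
      double l1p = std::log1p(std::exp(-z));
      nll += (d.n1[i] + d.n0[i]) * l1p + d.n0[i] * z;
    }
  }
  return nll;
}

static NllData make_data(const NumericVector& P, const NumericVector& A,
                         const NumericVector& V, double vref,
                         const NumericVector& n1, const NumericVector& n0) {
  NllData d;
  const int n = P.size();
  d.P.assign(P.begin(), P.end());
  d.A.assign(A.begin(), A.end());
  d.n1.assign(n1.begin(), n1.end());
  d.n0.assign(n0.begin(), n0.end());
  d.vref = vref;
  d.v_idx.resize(n);
  for (int i = 0; i < n; ++i) {
    int u = -1;
    for (size_t k = 0; k < d.vuniq.size(); ++k)
      if (d.vuniq[k] == V[i]) { u = (int)k; break; }
    if (u < 0) { d.vuniq.push_back(V[i]); u = (int)d.vuniq.size() - 1; }
    d.v_idx[i] = u;
  }
  return d;
}

// [[Rcpp::export]]
double nll_cpp(double alpha, double beta, double gamma,
               NumericVector P, NumericVector A, NumericVector V,
               double vref, NumericVector n1, NumericVector n0) {
  NllData d = make_data(P, A, V, vref, n1, n0);
  std::vector<double> powv(d.vuniq.size());
  return nll_eval(alpha, beta, gamma, d, powv);
}

// Objective on the unconstrained scale x = (log alpha, beta, log gamma);
// the log transforms keep alpha and gamma positive without penalties.
static inline double obj(const double* x, const NllData& d,
                         std::vector<double>& powv) {
  return nll_eval(std::exp(x[0]), x[1], std::exp(x[2]), d, powv);
}

// Derivative-free Nelder-Mead simplex minimization in 3 dimensions with the
// standard coefficients (reflection 1, expansion 2, contraction 0.5, shrink
// 0.5) and fminsearch-style initial simplex (5% perturbation per coordinate,
// 0.00025 when the coordinate is zero). Stops when both the objective spread
// and the coordinate spread across the simplex fall below tol, or at
// maxfeval evaluations.
static void nelder_mead(double* x0, const NllData& d,
                        double tol, int maxfeval,
                        double& fbest, bool& converged, int& nfeval,
                        std::vector<double>& powv) {
  const int n = 3;
  double S[4][3], F[4];
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j < n; ++j) S[i][j] = x0[j];
  for (int i = 0; i < n; ++i) {
    double xi = S[i + 1][i];
    S[i + 1][i] = (xi != 0.0) ? xi * 1.05 : 0.00025;
  }
  nfeval = 0;
  for (int i = 0; i <= n; ++i) { F[i] = obj(S[i], d, powv); ++nfeval; }

  int ord[4];
  double cen[3], xr[3], xe[3], xc[3];
  converged = false;
  while (nfeval < maxfeval) {
    for (int i = 0; i <= n; ++i) ord[i] = i;
    std::sort(ord, ord + n + 1, [&](int a, int b) { return F[a] < F[b]; });
    int lo = ord[0], hi = ord[n], nh = ord[n - 1];

    double fspread = 0.0, xspread = 0.0;
    for (int i = 0; i <= n; ++i) {
      fspread = std::max(fspread, std::fabs(F[i] - F[lo]));
      for (int j = 0; j < n; ++j)
        xspread = std::max(xspread, std::fabs(S[i][j] - S[lo][j]));
    }
    if (fspread <= tol && xspread <= tol) { converged = true; break; }

    for (int j = 0; j < n; ++j) cen[j] = 0.0;
    for (int i = 0; i <= n; ++i)
      if (i != hi) for (int j = 0; j < n; ++j) cen[j] += S[i][j] / n;

    for (int j = 0; j < n; ++j) xr[j] = cen[j] + (cen[j] - S[hi][j]);
    double fr = obj(xr, d, powv); ++nfeval;

    if (fr < F[lo]) {
      for (int j = 0; j < n; ++j) xe[j] = cen[j] + 2.0 * (cen[j] - S[hi][j]);
      double fe = obj(xe, d, powv); ++nfeval;
      if (fe < fr) { for (int j = 0; j < n; ++j) S[hi][j] = xe[j]; F[hi] = fe; }
      else         { for (int j = 0; j < n; ++j) S[hi][j] = xr[j]; F[hi] = fr; }
    } else if (fr < F[nh]) {
      for (int j = 0; j < n; ++j) S[hi][j] = xr[j]; F[hi] = fr;
    } else {
      bool outside = fr < F[hi];
      if (outside)
        for (int j = 0; j < n; ++j) xc[j] = cen[j] + 0.5 * (xr[j] - cen[j]);
      else
        for (int j = 0; j < n; ++j) xc[j] = cen[j] + 0.5 * (S[hi][j] - cen[j]);
      double fc = obj(xc, d, powv); ++nfeval;
      if (fc < std::min(fr, F[hi])) {
        for (int j = 0; j < n; ++j) S[hi][j] = xc[j]; F[hi] = fc;
      } else { // shrink toward the best vertex
        for (int i = 0; i <= n; ++i) {
          if (i == lo) continue;
          for (int j = 0; j < n; ++j)
            S[i][j] = S[lo][j] + 0.5 * (S[i][j] - S[lo][j]);
          F[i] = obj(S[i], d, powv); ++nfeval;
        }
      }
    }
  }
  int best = 0;
  for (int i = 1; i <= n; ++i) if (F[i] < F[best]) best = i;
  for (int j = 0; j < n; ++j) x0[j] = S[best][j];
  fbest = F[best];
}

// Multistart driver: runs Nelder-Mead from every start (natural-scale rows
// alpha, beta, gamma), returns the lowest-NLL solution; exact ties go to the
// lowest start index. Fully deterministic.
// [[Rcpp::export]]
List fit_multistart_cpp(NumericVector P, NumericVector A, NumericVector V,
                        double vref, NumericVector n1, NumericVector n0,
                        NumericMatrix starts, double tol = 1e-6,
                        int maxfeval = 2000) {
  const int ns = starts.nrow();
  NllData d = make_data(P, A, V, vref, n1, n0);
  std::vector<double> powv(d.vuniq.size());
  NumericVector start_nll(ns);
  double best_f = R_PosInf;
  int best_i = -1, best_nfeval = 0;
  bool best_conv = false;
  double best_x[3] = {0, 0, 0};
  for (int s = 0; s < ns; ++s) {
    double x[3] = {std::log(starts(s, 0)), starts(s, 1),
                   std::log(starts(s, 2))};
    double f; bool conv; int nfe;
    nelder_mead(x, d, tol, maxfeval, f, conv, nfe, powv);
    start_nll[s] = f;
    if (f < best_f) {
      best_f = f; best_i = s; best_conv = conv; best_nfeval = nfe;
      for (int j = 0; j < 3; ++j) best_x[j] = x[j];
    }
  }
  return List::create(
    _["alpha"] = std::exp(best_x[0]), _["beta"] = best_x[1],
    _["gamma"] = std::exp(best_x[2]), _["nll"] = best_f,
    _["start_index"] = best_i + 1, _["converged"] = best_conv,
    _["nfeval"] = best_nfeval, _["start_nll"] = start_nll);
}
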