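#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Banded DTW with power cost |a-b|^gamma.
// Band half-width w: cell (i, j) is feasible iff |i - j| <= w (1-based).
// Classic O(n * w) rolling dynamic programme; D(0,0) = 0 boundary so the
// first matched pair contributes its own cost.
// [[Rcpp::export(name = ".dtw_band_cpp")]]
double dtw_band_cpp(NumericVector s1, NumericVector s2, double gamma, int w) {
  const int n = s1.size(), m = s2.size();
  if (n < 1 || m < 1) stop("empty series");
  if (std::abs(n - m) > w)
    stop("band half-width %d cannot reach cell (%d, %d): |n - m| exceeds w", w, n, m);
  const double INF = R_PosInf;
  // rows indexed 0..n over template positions 0..m
  std::vector<double> prev(m + 1, INF), cur(m + 1, INF);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(1, i - w), jhi = std::min(m, i + w);
    std::fill(cur.begin(), cur.end(), INF);
    for (int j = jlo; j <= jhi; ++j) {
      double cost = std::pow(std::abs(s1[i - 1] - s2[j - 1]), gamma);
      double best = prev[j];                  // insertion: (i-1, j)
      if (cur[j - 1] < best) best = cur[j - 1];   // deletion: (i, j-1)
      if (prev[j - 1] < best) best = prev[j - 1]; // match: (i-1, j-1)
      cur[j] = (best == INF) ? INF : cost + best;
    }
    std::swap(prev, cur);
  }
  double d = prev[m];
  if (!R_finite(d)) stop("no feasible warping path inside the band");
  return d;
}

// Forward pass of a single-layer LSTM cell with scalar input per step and
// zero initial state. Weight vectors are length-u (input weights) and u x u
// matrices (recurrent weights); biases are zero. Returns the final hidden
// state h_T.
// Gate order: input i, forget f, candidate g, output o.
// [[Rcpp::export(name = ".lstm_forward_cpp")]]
NumericVector lstm_forward_cpp(NumericVector x,
                               NumericVector Wi, NumericVector Wf,
                               NumericVector Wg, NumericVector Wo,
                               NumericMatrix Ui, NumericMatrix Uf,
                               NumericMatrix Ug, NumericMatrix Uo) {
  const int T = x.size();
  if (T < 1) stop("empty series");
  const int u = Wi.size();
  std::vector<double> h(u, 0.0), c(u, 0.0), hn(u);
  for (int t = 0; t < T; ++t) {
    double xt = x[t];
    for (int k = 0; k < u; ++k) {
      double ai = Wi[k] * xt, af = Wf[k] * xt, ag = Wg[k] * xt, ao = Wo[k] * xt;
      for (int l = 0; l < u; ++l) {
        ai += Ui(k, l) * h[l];
        af += Uf(k, l) * h[l];
        ag += Ug(k, l) * h[l];
        ao += Uo(k, l) * h[l];
      }
      double gi = 1.0 / (1.0 + std::exp(-ai));
      double gf = 1.0 / (1.0 + std::exp(-af));
      double gg = std::tanh(ag);
      double go = 1.0 / (1.0 + std::exp(-ao));
      c[k] = gf * c[k] + gi * gg;
      hn[k] = go * std::tanh(c[k]);
    }
    h = hn;
  }
  return NumericVector(h.begin(), h.end());
}
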