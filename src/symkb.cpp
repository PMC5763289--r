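#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Longest common subsequence length over integer code points.
// Rolling single-row DP keeps memory at O(min length) regardless of input size.
// [[Rcpp::export]]
int lcs_length_cpp(IntegerVector a, IntegerVector b) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (a[i - 1] == b[j - 1]) cur[j] = prev[j - 1] + 1;
      else cur[j] = std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

static inline double logsumexp(const std::vector<double> &v) {
  double mx = v[0];
  for (size_t i = 1; i < v.size(); ++i) if (v[i] > mx) mx = v[i];
  double s = 0.0;
  for (size_t i = 0; i < v.size(); ++i) s += std::exp(v[i] - mx);
  return mx + std::log(s);
}

// Parameter layout (1-based feature ids from R):
//   emissions  w(f, y)  at (f-1)*L + (y-1)
//   transition T(y1,y2) at F*L + (y1-1)*L + (y2-1)
//   start s(y)          at F*L + L*L + (y-1)
//   end   e(y)          at F*L + L*L + L + (y-1)
// Feature matrices hold 0 for template slots whose feature fell outside the
// model's index (unseen at training time); those contribute nothing.

static void emission_scores(const double *par, const IntegerMatrix &feat,
                            int L, std::vector<double> &E) {
  int T = feat.nrow(), M = feat.ncol();
  E.assign((size_t)T * L, 0.0);
  for (int t = 0; t < T; ++t) {
    for (int m = 0; m < M; ++m) {
      int f = feat(t, m);
      if (f <= 0) continue;
      const double *w = par + (size_t)(f - 1) * L;
      for (int y = 0; y < L; ++y) E[(size_t)t * L + y] += w[y];
    }
  }
}

// [[Rcpp::export]]
List crf_nll_grad_cpp(NumericVector par, List feats, List labels,
                      int n_feat, int n_lab, double l2) {
  const int L = n_lab;
  const size_t off_trans = (size_t)n_feat * L;
  const size_t off_start = off_trans + (size_t)L * L;
  const size_t off_end = off_start + L;
  const double *p = par.begin();
  NumericVector grad(par.size());
  double *g = grad.begin();
  double nll = 0.0;
  int S = feats.size();
  std::vector<double> E, alpha, beta, tmp(L);

  for (int s = 0; s < S; ++s) {
    IntegerMatrix feat = feats[s];
    IntegerVector lab = labels[s];
    int T = feat.nrow(), M = feat.ncol();
    if (T == 0) continue;
    emission_scores(p, feat, L, E);

    // forward
    alpha.assign((size_t)T * L, 0.0);
    for (int y = 0; y < L; ++y) alpha[y] = p[off_start + y] + E[y];
    for (int t = 1; t < T; ++t) {
      for (int y = 0; y < L; ++y) {
        for (int y0 = 0; y0 < L; ++y0)
          tmp[y0] = alpha[(size_t)(t - 1) * L + y0] + p[off_trans + (size_t)y0 * L + y];
        alpha[(size_t)t * L + y] = logsumexp(tmp) + E[(size_t)t * L + y];
      }
    }
    for (int y = 0; y < L; ++y) tmp[y] = alpha[(size_t)(T - 1) * L + y] + p[off_end + y];
    double logZ = logsumexp(tmp);

    // backward
    beta.assign((size_t)T * L, 0.0);
    for (int y = 0; y < L; ++y) beta[(size_t)(T - 1) * L + y] = p[off_end + y];
    for (int t = T - 2; t >= 0; --t) {
      for (int y = 0; y < L; ++y) {
        for (int y1 = 0; y1 < L; ++y1)
          tmp[y1] = p[off_trans + (size_t)y * L + y1] + E[(size_t)(t + 1) * L + y1] +
                    beta[(size_t)(t + 1) * L + y1];
        beta[(size_t)t * L + y] = logsumexp(tmp);
      }
    }

    // gold path score
    double score = p[off_start + (lab[0] - 1)];
    for (int t = 0; t < T; ++t) score += E[(size_t)t * L + (lab[t] - 1)];
    for (int t = 1; t < T; ++t)
      score += p[off_trans + (size_t)(lab[t - 1] - 1) * L + (lab[t] - 1)];
    score += p[off_end + (lab[T - 1] - 1)];
    nll += logZ - score;

    // node marginals -> emission/start/end gradients (expected - empirical)
    for (int t = 0; t < T; ++t) {
      for (int y = 0; y < L; ++y) {
        double m1 = std::exp(alpha[(size_t)t * L + y] + beta[(size_t)t * L + y] - logZ);
        double d = m1 - (lab[t] - 1 == y ? 1.0 : 0.0);
        tmp[y] = d;  // reuse as per-position delta
      }
      for (int m = 0; m < M; ++m) {
        int f = feat(t, m);
        if (f <= 0) continue;
        double *gw = g + (size_t)(f - 1) * L;
        for (int y = 0; y < L; ++y) gw[y] += tmp[y];
      }
      if (t == 0) for (int y = 0; y < L; ++y) g[off_start + y] += tmp[y];
      if (t == T - 1) for (int y = 0; y < L; ++y) g[off_end + y] += tmp[y];
    }

    // edge marginals -> transition gradient
    for (int t = 1; t < T; ++t) {
      for (int y0 = 0; y0 < L; ++y0) {
        for (int y1 = 0; y1 < L; ++y1) {
          double m2 = std::exp(alpha[(size_t)(t - 1) * L + y0] +
                               p[off_trans + (size_t)y0 * L + y1] +
                               E[(size_t)t * L + y1] +
                               beta[(size_t)t * L + y1] - logZ);
          double d = m2 - ((lab[t - 1] - 1 == y0 && lab[t] - 1 == y1) ? 1.0 : 0.0);
          g[off_trans + (size_t)y0 * L + y1] += d;
        }
      }
    }
  }

  // L2 penalty
  double pen = 0.0;
  for (R_xlen_t i = 0; i < par.size(); ++i) {
    pen += p[i] * p[i];
    g[i] += l2 * p[i];
  }
  nll += 0.5 * l2 * pen;

  return List::create(Named("nll") = nll, Named("grad") = grad);
}

// [[Rcpp::export]]
IntegerVector crf_viterbi_cpp(NumericVector par, IntegerMatrix feat,
                              int n_feat, int n_lab) {
  const int L = n_lab;
  const size_t off_trans = (size_t)n_feat * L;
  const size_t off_start = off_trans + (size_t)L * L;
  const size_t off_end = off_start + L;
  const double *p = par.begin();
  int T = feat.nrow();
  IntegerVector path(T);
  if (T == 0) return path;
  std::vector<double> E;
  emission_scores(p, feat, L, E);
  std::vector<double> delta((size_t)T * L);
  std::vector<int> back((size_t)T * L, 0);
  for (int y = 0; y < L; ++y) delta[y] = p[off_start + y] + E[y];
  for (int t = 1; t < T; ++t) {
    for (int y = 0; y < L; ++y) {
      double best = -INFINITY;
      int arg = 0;
      for (int y0 = 0; y0 < L; ++y0) {
        double v = delta[(size_t)(t - 1) * L + y0] + p[off_trans + (size_t)y0 * L + y];
        if (v > best) { best = v; arg = y0; }
      }
      delta[(size_t)t * L + y] = best + E[(size_t)t * L + y];
      back[(size_t)t * L + y] = arg;
    }
  }
  double best = -INFINITY;
  int arg = 0;
  for (int y = 0; y < L; ++y) {
    double v = delta[(size_t)(T - 1) * L + y] + p[off_end + y];
    if (v > best) { best = v; arg = y; }
  }
  path[T - 1] = arg + 1;
  for (int t = T - 1; t >= 1; --t) {
    arg = back[(size_t)t * L + arg];
    path[t - 1] = arg + 1;
  }
  return path;
}
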