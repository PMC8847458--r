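// Dynamic time warping with Euclidean local cost, full window,
// boundary-anchored, symmetric match/insert/delete steps.
//
// gk_dtw       : O(nm) dynamic program + traceback (the implementation).
// gk_dtw_brute : explicit enumeration of every monotone alignment path,
//                taking the minimum of complete-path sums at the leaves.
//                Shares no recurrence/memoisation with gk_dtw; used as an
//                independent oracle on small instances.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static inline double local_cost(const NumericMatrix& a,
                                const NumericMatrix& b,
                                int i, int j) {
  double s = 0.0;
  for (int d = 0; d < a.ncol(); ++d) {
    double diff = a(i, d) - b(j, d);
    s += diff * diff;
  }
  return std::sqrt(s);
}

// [[Rcpp::export(name = ".gk_dtw")]]
List gk_dtw(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow();
  if (n == 0 || m == 0) stop("empty trajectory");
  if (a.ncol() != b.ncol()) stop("trajectories must share dimension");
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> D((size_t)n * m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double c = local_cost(a, b, i, j);
      double best;
      if (i == 0 && j == 0) best = 0.0;
      else {
        best = inf;
        if (i > 0) best = std::min(best, D[(size_t)(i - 1) * m + j]);
        if (j > 0) best = std::min(best, D[(size_t)i * m + j - 1]);
        if (i > 0 && j > 0)
          best = std::min(best, D[(size_t)(i - 1) * m + j - 1]);
      }
      D[(size_t)i * m + j] = c + best;
    }
  }
  // traceback for the alignment path length (diagonal preferred on ties)
  int i = n - 1, j = m - 1, len = 1;
  while (i > 0 || j > 0) {
    double diag = (i > 0 && j > 0) ? D[(size_t)(i - 1) * m + j - 1] : inf;
    double up = (i > 0) ? D[(size_t)(i - 1) * m + j] : inf;
    double left = (j > 0) ? D[(size_t)i * m + j - 1] : inf;
    if (diag <= up && diag <= left) { --i; --j; }
    else if (up <= left) { --i; }
    else { --j; }
    ++len;
  }
  return List::create(_["cost"] = D[(size_t)n * m - 1],
                      _["pathLength"] = len);
}

namespace {
struct BruteCtx {
  const NumericMatrix* a;
  const NumericMatrix* b;
  int n, m;
  double best;
};

void walk(BruteCtx& ctx, int i, int j, double acc) {
  acc += local_cost(*ctx.a, *ctx.b, i, j);
  if (acc >= ctx.best) return;  // prune: all costs nonnegative
  if (i == ctx.n - 1 && j == ctx.m - 1) {
    ctx.best = acc;
    return;
  }
  if (i + 1 < ctx.n && j + 1 < ctx.m) walk(ctx, i + 1, j + 1, acc);
  if (i + 1 < ctx.n) walk(ctx, i + 1, j, acc);
  if (j + 1 < ctx.m) walk(ctx, i, j + 1, acc);
}
}  // namespace

// [[Rcpp::export(name = ".gk_dtw_brute")]]
double gk_dtw_brute(NumericMatrix a, NumericMatrix b) {
  if (a.nrow() == 0 || b.nrow() == 0) stop("empty trajectory");
  BruteCtx ctx{&a, &b, (int)a.nrow(), (int)b.nrow(),
               std::numeric_limits<double>::infinity()};
  walk(ctx, 0, 0, 0.0);
  return ctx.best;
}

// Exhaustive comparison of the DP against the path-enumeration oracle
// over every unordered pair in seqs (1-D sequences). Returns the maximum
// absolute cost difference.
// [[Rcpp::export(name = ".gk_dtw_check_all")]]
double gk_dtw_check_all(List seqs) {
  const int N = seqs.size();
  std::vector<NumericMatrix> mats;
  mats.reserve(N);
  for (int i = 0; i < N; ++i) {
    NumericVector v = seqs[i];
    NumericMatrix m(v.size(), 1);
    for (int k = 0; k < v.size(); ++k) m(k, 0) = v[k];
    mats.push_back(m);
  }
  double worst = 0.0;
  for (int i = 0; i < N; ++i) {
    for (int j = i; j < N; ++j) {
      List r = gk_dtw(mats[i], mats[j]);
      double dp = as<double>(r["cost"]);
      double br = gk_dtw_brute(mats[i], mats[j]);
      double d = std::fabs(dp - br);
      if (d > worst) worst = d;
    }
  }
  return worst;
}
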