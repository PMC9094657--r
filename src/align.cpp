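#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Affine-gap pairwise alignment engines.
//
// Convention: a gap of length k costs gap_open + (k - 1) * gap_extend
// (both positive), i.e. the first gapped column pays gap_open and each
// further column pays gap_extend.
//
// Sequences arrive integer-coded, 1-based into the rows/columns of the
// score matrix S. For substitution-matrix alignment, codes index residue
// rows; for PSSM alignment the "a" codes are simply 1..L so that S row i
// holds the position-specific scores of model position i.

namespace {

const double NEG_INF = -1e30;

struct Aln {
  double score;
  int a_start, a_end, b_start, b_end;   // 1-based inclusive; 0 if empty
  std::vector<int> a_idx, b_idx;        // per column: position or 0 for gap
};

inline double max3(double x, double y, double z) {
  return std::max(x, std::max(y, z));
}

// Score-only local DP with rolling rows; O(n) memory.
// Returns best score and its end cell (1-based). mask[j-1] true => target
// position j is unavailable (substitution score forced to -inf).
void local_best_cell(const std::vector<int>& a, const std::vector<int>& b,
                     const NumericMatrix& S, double go, double ge,
                     const std::vector<char>& mask,
                     double& best, int& bi, int& bj) {
  const int m = (int)a.size(), n = (int)b.size();
  best = 0.0; bi = 0; bj = 0;
  std::vector<double> Mp(n + 1, NEG_INF), Xp(n + 1, NEG_INF), Yp(n + 1, NEG_INF);
  std::vector<double> Mc(n + 1, NEG_INF), Xc(n + 1, NEG_INF), Yc(n + 1, NEG_INF);
  for (int i = 1; i <= m; ++i) {
    Mc[0] = NEG_INF; Xc[0] = NEG_INF; Yc[0] = NEG_INF;
    const int ar = a[i - 1] - 1;
    for (int j = 1; j <= n; ++j) {
      const double s = mask[j - 1] ? NEG_INF : S(ar, b[j - 1] - 1);
      const double diag = std::max(0.0, max3(Mp[j - 1], Xp[j - 1], Yp[j - 1]));
      const double mij = s + diag;
      Mc[j] = mij;
      Xc[j] = max3(Mp[j] - go, Xp[j] - ge, Yp[j] - go);
      Yc[j] = max3(Mc[j - 1] - go, Xc[j - 1] - go, Yc[j - 1] - ge);
      if (mij > best) { best = mij; bi = i; bj = j; }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
}

// Full three-state DP with traceback over the window
// rows i0..i1, cols j0..j1 of the implicit matrix (all 1-based inclusive).
// local = true: free start (floor at 0 before each match) and the alignment
// is forced to end at the window's bottom-right corner in state M.
// local = false: global alignment of the full window with affine end gaps.
Aln traceback_dp(const std::vector<int>& a, const std::vector<int>& b,
                 const NumericMatrix& S, double go, double ge,
                 const std::vector<char>& mask,
                 int i0, int i1, int j0, int j1, bool local) {
  const int m = i1 - i0 + 1, n = j1 - j0 + 1;
  const size_t sz = (size_t)(m + 1) * (n + 1);
  std::vector<double> M(sz, NEG_INF), X(sz, NEG_INF), Y(sz, NEG_INF);
  // traceback: predecessor state 0=M,1=X,2=Y,3=start
  std::vector<unsigned char> tM(sz, 3), tX(sz, 0), tY(sz, 0);
  auto at = [n](int i, int j) { return (size_t)i * (n + 1) + j; };

  M[at(0, 0)] = local ? NEG_INF : 0.0;
  if (!local) {
    for (int i = 1; i <= m; ++i) { X[at(i, 0)] = -(go + (i - 1) * ge); tX[at(i, 0)] = (i == 1) ? 0 : 1; }
    for (int j = 1; j <= n; ++j) { Y[at(0, j)] = -(go + (j - 1) * ge); tY[at(0, j)] = (j == 1) ? 0 : 2; }
    // the initial X/Y border descends from the virtual M[0][0]
  }
  for (int i = 1; i <= m; ++i) {
    const int ar = a[i0 - 1 + i - 1] - 1;
    for (int j = 1; j <= n; ++j) {
      const int gj = j0 - 1 + j;  // 1-based global column
      const double s = mask[gj - 1] ? NEG_INF : S(ar, b[gj - 1] - 1);
      // M
      double dM = M[at(i - 1, j - 1)], dX = X[at(i - 1, j - 1)], dY = Y[at(i - 1, j - 1)];
      double diag = dM; unsigned char tm = 0;
      if (dX > diag) { diag = dX; tm = 1; }
      if (dY > diag) { diag = dY; tm = 2; }
      if (local && 0.0 > diag) { diag = 0.0; tm = 3; }
      M[at(i, j)] = s + diag; tM[at(i, j)] = tm;
      // X: gap in b (consume a)
      double xM = M[at(i - 1, j)] - go, xX = X[at(i - 1, j)] - ge, xY = Y[at(i - 1, j)] - go;
      double xv = xM; unsigned char tx = 0;
      if (xX > xv) { xv = xX; tx = 1; }
      if (xY > xv) { xv = xY; tx = 2; }
      X[at(i, j)] = xv; tX[at(i, j)] = tx;
      // Y: gap in a (consume b)
      double yM = M[at(i, j - 1)] - go, yX = X[at(i, j - 1)] - go, yY = Y[at(i, j - 1)] - ge;
      double yv = yM; unsigned char ty = 0;
      if (yX > yv) { yv = yX; ty = 1; }
      if (yY > yv) { yv = yY; ty = 2; }
      Y[at(i, j)] = yv; tY[at(i, j)] = ty;
    }
  }

  Aln out; out.score = 0; out.a_start = out.a_end = out.b_start = out.b_end = 0;
  int ci = m, cj = n, state;
  if (local) {
    state = 0;
    out.score = M[at(m, n)];
  } else {
    double vM = M[at(m, n)], vX = X[at(m, n)], vY = Y[at(m, n)];
    state = 0; out.score = vM;
    if (vX > out.score) { out.score = vX; state = 1; }
    if (vY > out.score) { out.score = vY; state = 2; }
    if (m == 0 && n == 0) { out.score = 0.0; return out; }
  }
  std::vector<int> acol, bcol;
  while (ci > 0 || cj > 0) {
    if (state == 0) {
      if (ci == 0 && cj == 0) break;
      unsigned char t = tM[at(ci, cj)];
      acol.push_back(i0 - 1 + ci); bcol.push_back(j0 - 1 + cj);
      --ci; --cj;
      if (t == 3) break;          // local start
      state = t;
      if (!local && ci == 0 && cj == 0) break;
    } else if (state == 1) {
      unsigned char t = tX[at(ci, cj)];
      acol.push_back(i0 - 1 + ci); bcol.push_back(0);
      --ci;
      state = t;
      if (!local && ci == 0 && cj == 0) break;
    } else {
      unsigned char t = tY[at(ci, cj)];
      acol.push_back(0); bcol.push_back(j0 - 1 + cj);
      --cj;
      state = t;
      if (!local && ci == 0 && cj == 0) break;
    }
  }
  std::reverse(acol.begin(), acol.end());
  std::reverse(bcol.begin(), bcol.end());
  out.a_idx = acol; out.b_idx = bcol;
  for (size_t k = 0; k < acol.size(); ++k) {
    if (acol[k] > 0) { if (out.a_start == 0) out.a_start = acol[k]; out.a_end = acol[k]; }
    if (bcol[k] > 0) { if (out.b_start == 0) out.b_start = bcol[k]; out.b_end = bcol[k]; }
  }
  return out;
}

// One best local alignment: score-only pass, then windowed traceback.
// window_a/window_b bound the span of the reported alignment in a and b.
Aln local_align_one(const std::vector<int>& a, const std::vector<int>& b,
                    const NumericMatrix& S, double go, double ge,
                    const std::vector<char>& mask,
                    int window_a, int window_b) {
  Aln out; out.score = 0; out.a_start = out.a_end = out.b_start = out.b_end = 0;
  double best; int bi, bj;
  local_best_cell(a, b, S, go, ge, mask, best, bi, bj);
  if (best <= 0.0 || bi == 0) return out;
  int wa = std::min(window_a, bi), wb = std::min(window_b, bj);
  for (;;) {
    Aln t = traceback_dp(a, b, S, go, ge, mask, bi - wa + 1, bi, bj - wb + 1, bj, true);
    if (std::fabs(t.score - best) < 1e-6 &&
        (t.a_start > bi - wa + 1 || wa == bi) &&
        (t.b_start > bj - wb + 1 || wb == bj)) {
      t.score = best;
      return t;
    }
    // window too small for the optimal path: widen and retry
    if (wa == bi && wb == bj) { t.score = best; return t; }
    wa = std::min(bi, wa * 2); wb = std::min(bj, wb * 2);
  }
}

List aln_to_list(const Aln& x) {
  return List::create(
    _["score"] = x.score,
    _["a_start"] = x.a_start, _["a_end"] = x.a_end,
    _["b_start"] = x.b_start, _["b_end"] = x.b_end,
    _["a_idx"] = IntegerVector(x.a_idx.begin(), x.a_idx.end()),
    _["b_idx"] = IntegerVector(x.b_idx.begin(), x.b_idx.end()));
}

std::vector<int> as_std(const IntegerVector& v) {
  return std::vector<int>(v.begin(), v.end());
}

}  // namespace

// [[Rcpp::export]]
List c_local_align(IntegerVector a, IntegerVector b, NumericMatrix S,
                   double gap_open, double gap_extend,
                   int window_a, int window_b) {
  std::vector<int> av = as_std(a), bv = as_std(b);
  std::vector<char> mask(bv.size(), 0);
  return aln_to_list(local_align_one(av, bv, S, gap_open, gap_extend, mask,
                                     window_a, window_b));
}

// Repeated best-hit extraction: after each accepted alignment the covered
// target span is masked and the scan repeats until the best score drops
// below min_score or max_hits is reached.
// [[Rcpp::export]]
List c_local_align_multi(IntegerVector a, IntegerVector b, NumericMatrix S,
                         double gap_open, double gap_extend,
                         double min_score, int max_hits,
                         int window_a, int window_b) {
  std::vector<int> av = as_std(a), bv = as_std(b);
  std::vector<char> mask(bv.size(), 0);
  List hits;
  for (int h = 0; h < max_hits; ++h) {
    Aln x = local_align_one(av, bv, S, gap_open, gap_extend, mask,
                            window_a, window_b);
    if (x.score < min_score || x.b_start == 0) break;
    hits.push_back(aln_to_list(x));
    for (int j = x.b_start; j <= x.b_end; ++j) mask[j - 1] = 1;
  }
  return hits;
}

// [[Rcpp::export]]
List c_global_align(IntegerVector a, IntegerVector b, NumericMatrix S,
                    double gap_open, double gap_extend) {
  std::vector<int> av = as_std(a), bv = as_std(b);
  std::vector<char> mask(bv.size(), 0);
  Aln x = traceback_dp(av, bv, S, gap_open, gap_extend, mask,
                       1, (int)av.size(), 1, (int)bv.size(), false);
  return aln_to_list(x);
}

// Global alignment on a dense per-cell score matrix (profile-profile
// merging). cell(i, j) scores aligning profile column i of A to column j
// of B. Returns indices as for the sequence version.
// [[Rcpp::export]]
List c_global_align_cells(NumericMatrix cell, double gap_open, double gap_extend) {
  const int m = cell.nrow(), n = cell.ncol();
  std::vector<int> av(m), bv(n);
  for (int i = 0; i < m; ++i) av[i] = i + 1;
  for (int j = 0; j < n; ++j) bv[j] = j + 1;
  std::vector<char> mask(n, 0);
  Aln x = traceback_dp(av, bv, cell, gap_open, gap_extend, mask, 1, m, 1, n, false);
  return aln_to_list(x);
}

// [[Rcpp::export]]
double c_local_score(IntegerVector a, IntegerVector b, NumericMatrix S,
                     double gap_open, double gap_extend) {
  std::vector<int> av = as_std(a), bv = as_std(b);
  std::vector<char> mask(bv.size(), 0);
  double best; int bi, bj;
  local_best_cell(av, bv, S, gap_open, gap_extend, mask, best, bi, bj);
  return best;
}
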