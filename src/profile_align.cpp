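#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global profile-profile alignment with affine gaps (Gotoh). Profiles are
// integer matrices (rows x columns): 0 = gap, 1..4 = A,C,G,T, 5 = N.
// Column-pair substitution score is the sum over all cross-profile row
// pairs: match / mismatch for two residues, 0 when either is a gap or N.
// Gap penalties are applied once per alignment-level gap: a gap of length k
// costs open + k * extend. Ties break deterministically (diagonal, then
// gap-in-B, then gap-in-A).
//
// Returns two integer vectors over the merged columns: 1-based source
// column in A (0 = new gap) and likewise for B.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List cpp_profile_align(IntegerMatrix A, IntegerMatrix B,
                       double match, double mismatch,
                       double gap_open, double gap_extend) {
  const int n = A.ncol(), m = B.ncol();
  const int ra = A.nrow(), rb = B.nrow();

  // per-column base counts (1..4) and residue totals (excluding gap and N)
  std::vector<std::array<double, 5>> ca(n), cb(m);
  std::vector<double> ta(n, 0.0), tb(m, 0.0);
  for (int j = 0; j < n; ++j) {
    ca[j].fill(0.0);
    for (int i = 0; i < ra; ++i) {
      int c = A(i, j);
      if (c >= 1 && c <= 4) { ca[j][c] += 1.0; ta[j] += 1.0; }
    }
  }
  for (int j = 0; j < m; ++j) {
    cb[j].fill(0.0);
    for (int i = 0; i < rb; ++i) {
      int c = B(i, j);
      if (c >= 1 && c <= 4) { cb[j][c] += 1.0; tb[j] += 1.0; }
    }
  }

  auto colscore = [&](int i, int j) {
    double same = 0.0;
    for (int b = 1; b <= 4; ++b) same += ca[i][b] * cb[j][b];
    return match * same + mismatch * (ta[i] * tb[j] - same);
  };

  const size_t sz = (size_t)(n + 1) * (m + 1);
  std::vector<double> M(sz, NEG_INF), X(sz, NEG_INF), Y(sz, NEG_INF);
  std::vector<unsigned char> tM(sz, 0), tX(sz, 0), tY(sz, 0);
  auto at = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = gap_open + i * gap_extend;
    tX[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = gap_open + j * gap_extend;
    tY[at(0, j)] = (j == 1) ? 0 : 1;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t d = at(i - 1, j - 1), u = at(i - 1, j),
                   l = at(i, j - 1), c = at(i, j);
      // M: consume one column of each
      double best = M[d]; unsigned char tb_ = 0;
      if (X[d] > best) { best = X[d]; tb_ = 1; }
      if (Y[d] > best) { best = Y[d]; tb_ = 2; }
      M[c] = best + colscore(i - 1, j - 1); tM[c] = tb_;
      // X: consume a column of A, gap in B
      double xo = M[u] + gap_open + gap_extend;
      double xe = X[u] + gap_extend;
      if (xo >= xe) { X[c] = xo; tX[c] = 0; } else { X[c] = xe; tX[c] = 1; }
      // Y: consume a column of B, gap in A
      double yo = M[l] + gap_open + gap_extend;
      double ye = Y[l] + gap_extend;
      if (yo >= ye) { Y[c] = yo; tY[c] = 0; } else { Y[c] = ye; tY[c] = 1; }
    }
  }

  // traceback
  std::vector<int> ai, bi;
  ai.reserve(n + m); bi.reserve(n + m);
  int i = n, j = m, state;
  {
    const size_t c = at(n, m);
    double best = M[c]; state = 0;
    if (X[c] > best) { best = X[c]; state = 1; }
    if (Y[c] > best) { best = Y[c]; state = 2; }
  }
  while (i > 0 || j > 0) {
    const size_t c = at(i, j);
    if (state == 0) {
      ai.push_back(i); bi.push_back(j);
      state = tM[c]; --i; --j;
    } else if (state == 1) {
      ai.push_back(i); bi.push_back(0);
      state = (tX[c] == 0) ? 0 : 1; --i;
    } else {
      ai.push_back(0); bi.push_back(j);
      state = (tY[c] == 0) ? 0 : 2; --j;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  double score;
  {
    const size_t c = at(n, m);
    score = std::max(M[c], std::max(X[c], Y[c]));
  }
  return List::create(_["ai"] = wrap(ai), _["bi"] = wrap(bi),
                      _["score"] = score);
}
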