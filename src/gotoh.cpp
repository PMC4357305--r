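#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh three-state
// recursion.  A gap of length L costs open + L * ext.  Explicit traceback
// pointers are stored during the forward pass; ties are broken
// deterministically, preferring the match/mismatch state, then the
// gap-in-b ("up") state, then the gap-in-a ("left") state.

static const double NEG_INF = -1e30;

// state codes: 0 = M (diagonal), 1 = X (up, consumes a), 2 = Y (left,
// consumes b)
static inline int pick3(double m, double x, double y) {
  if (m >= x && m >= y) return 0;
  if (x >= y) return 1;
  return 2;
}

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(IntegerVector a, IntegerVector b, NumericMatrix sub,
                 double open, double ext) {
  const int m = a.size(), n = b.size();
  NumericMatrix M(m + 1, n + 1), X(m + 1, n + 1), Y(m + 1, n + 1);
  IntegerMatrix pM(m + 1, n + 1), pX(m + 1, n + 1), pY(m + 1, n + 1);
  for (int i = 0; i <= m; ++i)
    for (int j = 0; j <= n; ++j) {
      M(i, j) = X(i, j) = Y(i, j) = NEG_INF;
    }
  M(0, 0) = 0.0;
  for (int i = 1; i <= m; ++i) {
    X(i, 0) = -(open + i * ext);
    pX(i, 0) = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= n; ++j) {
    Y(0, j) = -(open + j * ext);
    pY(0, j) = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int s = pick3(M(i - 1, j - 1), X(i - 1, j - 1), Y(i - 1, j - 1));
      double prev = (s == 0) ? M(i - 1, j - 1)
                  : (s == 1) ? X(i - 1, j - 1) : Y(i - 1, j - 1);
      M(i, j) = prev + sub(a[i - 1] - 1, b[j - 1] - 1);
      pM(i, j) = s;

      double xm = M(i - 1, j) - open - ext;
      double xx = X(i - 1, j) - ext;
      double xy = Y(i - 1, j) - open - ext;
      int sx = pick3(xm, xx, xy);
      X(i, j) = (sx == 0) ? xm : (sx == 1) ? xx : xy;
      pX(i, j) = sx;

      double ym = M(i, j - 1) - open - ext;
      double yx = X(i, j - 1) - open - ext;
      double yy = Y(i, j - 1) - ext;
      int sy = pick3(ym, yx, yy);
      Y(i, j) = (sy == 0) ? ym : (sy == 1) ? yx : yy;
      pY(i, j) = sy;
    }
  }

  double score = std::max(M(m, n), std::max(X(m, n), Y(m, n)));
  int state = pick3(M(m, n), X(m, n), Y(m, n));

  std::vector<int> pa, pb;  // 0 encodes a gap
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (state == 0) {
      pa.push_back(a[i - 1]);
      pb.push_back(b[j - 1]);
      state = pM(i, j);
      --i; --j;
    } else if (state == 1) {
      pa.push_back(a[i - 1]);
      pb.push_back(0);
      state = pX(i, j);
      --i;
    } else {
      pa.push_back(0);
      pb.push_back(b[j - 1]);
      state = pY(i, j);
      --j;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = score,
                      _["a_idx"] = IntegerVector(pa.begin(), pa.end()),
                      _["b_idx"] = IntegerVector(pb.begin(), pb.end()));
}
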