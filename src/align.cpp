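// Affine-gap pairwise alignment (Gotoh three-state DP) plus exhaustive
// path-enumeration oracles used by the test suite.
//
// Conventions shared with the R layer:
//  * a gap of length L costs open + (L-1)*extend (first gapped column pays
//    the full opening penalty, each further column pays the extension);
//  * tie-break order at every choice: diagonal, then gap-in-b (consume a),
//    then gap-in-a (consume b);
//  * scores are integers; the substitution score of residues (x, y) is
//    lookup[ascii(x)*128 + ascii(y)].
//
// Score rows are rolled; traceback uses byte matrices (3*(m+1)*(n+1) bytes),
// which keeps 10 kb x 10 kb global alignments within a few hundred MB.

#include <Rcpp.h>
#include <climits>
#include <vector>

using namespace Rcpp;

static const int NEG_INF = INT_MIN / 4;

enum State { ST_M = 0, ST_X = 1, ST_Y = 2 }; // X: gap in b (consume a)
static const unsigned char TB_START = 3;     // local-alignment path start

struct TB {
  std::vector<unsigned char> m, x, y;
  size_t ncol;
  TB(size_t rows, size_t cols)
      : m(rows * cols, TB_START), x(rows * cols, TB_START),
        y(rows * cols, TB_START), ncol(cols) {}
  unsigned char get(int state, size_t i, size_t j) const {
    size_t k = i * ncol + j;
    return state == ST_M ? m[k] : (state == ST_X ? x[k] : y[k]);
  }
  void set(int state, size_t i, size_t j, unsigned char v) {
    size_t k = i * ncol + j;
    (state == ST_M ? m[k] : (state == ST_X ? x[k] : y[k])) = v;
  }
};

// mode: 0 = global, 1 = local, 2 = global with free end gaps (overlap)
// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(std::string a, std::string b, IntegerVector lookup,
                    int gap_open, int gap_extend, int mode) {
  const size_t m = a.size(), n = b.size();
  const bool local = (mode == 1), free_ends = (mode == 2);
  const int *lk = INTEGER(lookup);

  std::vector<int> Mprev(n + 1), Xprev(n + 1), Yprev(n + 1);
  std::vector<int> Mcur(n + 1), Xcur(n + 1), Ycur(n + 1);
  TB tb(m + 1, n + 1);
  // column-n scores per row, for free-end selection
  std::vector<int> colM(m + 1, NEG_INF), colX(m + 1, NEG_INF),
      colY(m + 1, NEG_INF);

  // row 0
  Mprev[0] = 0;
  Xprev[0] = NEG_INF;
  Yprev[0] = NEG_INF;
  for (size_t j = 1; j <= n; ++j) {
    Mprev[j] = local ? 0 : NEG_INF;
    Xprev[j] = NEG_INF;
    if (local)
      Yprev[j] = NEG_INF;
    else if (free_ends)
      Yprev[j] = 0;
    else
      Yprev[j] = -gap_open - static_cast<int>(j - 1) * gap_extend;
    tb.set(ST_Y, 0, j, j == 1 ? ST_M : ST_Y);
  }
  if (n > 0) { colM[0] = Mprev[n]; colX[0] = Xprev[n]; colY[0] = Yprev[n]; }

  int loc_best = 0; // best local M value
  size_t loc_i = 0, loc_j = 0;

  for (size_t i = 1; i <= m; ++i) {
    Mcur[0] = local ? 0 : NEG_INF;
    Ycur[0] = NEG_INF;
    if (local)
      Xcur[0] = NEG_INF;
    else if (free_ends)
      Xcur[0] = 0;
    else
      Xcur[0] = -gap_open - static_cast<int>(i - 1) * gap_extend;
    tb.set(ST_X, i, 0, i == 1 ? ST_M : ST_X);

    const int arow =
        (static_cast<int>(static_cast<unsigned char>(a[i - 1])) & 127) * 128;
    for (size_t j = 1; j <= n; ++j) {
      const int s =
          lk[arow + (static_cast<int>(static_cast<unsigned char>(b[j - 1])) & 127)];

      // M: diagonal move; predecessor preference M > X > Y
      int bestprev = Mprev[j - 1];
      unsigned char code = ST_M;
      if (Xprev[j - 1] > bestprev) { bestprev = Xprev[j - 1]; code = ST_X; }
      if (Yprev[j - 1] > bestprev) { bestprev = Yprev[j - 1]; code = ST_Y; }
      int mval;
      if (local) {
        if (bestprev <= 0) { bestprev = 0; code = TB_START; } // fresh start
        mval = bestprev + s;
        if (mval < 0) { mval = 0; code = TB_START; }
      } else {
        mval = (bestprev <= NEG_INF) ? NEG_INF : bestprev + s;
      }
      Mcur[j] = mval;
      tb.set(ST_M, i, j, code);
      if (local && mval > loc_best) { loc_best = mval; loc_i = i; loc_j = j; }

      // X: consume a[i-1], gap in b
      int xval = (Mprev[j] <= NEG_INF) ? NEG_INF : Mprev[j] - gap_open;
      unsigned char xcode = ST_M;
      if (Xprev[j] > NEG_INF && Xprev[j] - gap_extend > xval) {
        xval = Xprev[j] - gap_extend; xcode = ST_X;
      }
      if (Yprev[j] > NEG_INF && Yprev[j] - gap_open > xval) {
        xval = Yprev[j] - gap_open; xcode = ST_Y;
      }
      Xcur[j] = xval;
      tb.set(ST_X, i, j, xcode);

      // Y: consume b[j-1], gap in a
      int yval = (Mcur[j - 1] <= NEG_INF) ? NEG_INF : Mcur[j - 1] - gap_open;
      unsigned char ycode = ST_M;
      if (Xcur[j - 1] > NEG_INF && Xcur[j - 1] - gap_open > yval) {
        yval = Xcur[j - 1] - gap_open; ycode = ST_X;
      }
      if (Ycur[j - 1] > NEG_INF && Ycur[j - 1] - gap_extend > yval) {
        yval = Ycur[j - 1] - gap_extend; ycode = ST_Y;
      }
      Ycur[j] = yval;
      tb.set(ST_Y, i, j, ycode);
    }
    colM[i] = Mcur[n]; colX[i] = Xcur[n]; colY[i] = Ycur[n];
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }
  // *prev now holds row m

  int final_score;
  size_t ti, tj;
  int state;

  if (local) {
    if (loc_best <= 0)
      return List::create(_["score"] = 0, _["aligned_a"] = "",
                          _["aligned_b"] = "", _["a_start"] = 0,
                          _["a_end"] = 0, _["b_start"] = 0, _["b_end"] = 0);
    final_score = loc_best; ti = loc_i; tj = loc_j; state = ST_M;
  } else if (free_ends) {
    // candidates: every cell of the last row and last column; scan row m
    // left to right, then column n top to bottom; strictly-greater replaces.
    final_score = NEG_INF; ti = m; tj = n; state = ST_M;
    for (size_t j = 0; j <= n; ++j) {
      int v = Mprev[j]; int st = ST_M;
      if (Xprev[j] > v) { v = Xprev[j]; st = ST_X; }
      if (Yprev[j] > v) { v = Yprev[j]; st = ST_Y; }
      if (v > final_score) { final_score = v; ti = m; tj = j; state = st; }
    }
    for (size_t i = 0; i < m; ++i) {
      int v = colM[i]; int st = ST_M;
      if (colX[i] > v) { v = colX[i]; st = ST_X; }
      if (colY[i] > v) { v = colY[i]; st = ST_Y; }
      if (v > final_score) { final_score = v; ti = i; tj = n; state = st; }
    }
  } else {
    int v = Mprev[n]; int st = ST_M;
    if (Xprev[n] > v) { v = Xprev[n]; st = ST_X; }
    if (Yprev[n] > v) { v = Yprev[n]; st = ST_Y; }
    final_score = v; ti = m; tj = n; state = st;
  }

  // traceback (built backwards, reversed at the end)
  std::string ra, rb;
  ra.reserve(m + n + 2); rb.reserve(m + n + 2);
  size_t i = ti, j = tj;

  if (free_ends) { // trailing free gaps
    for (size_t k = m; k > ti; --k) { ra.push_back(a[k - 1]); rb.push_back('-'); }
    for (size_t k = n; k > tj; --k) { ra.push_back('-'); rb.push_back(b[k - 1]); }
  }

  bool done = false;
  while (!done && (i > 0 || j > 0)) {
    if (free_ends && (i == 0 || j == 0)) break;
    unsigned char code = tb.get(state, i, j);
    switch (state) {
    case ST_M:
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j;
      if (code == TB_START) done = true; else state = code;
      break;
    case ST_X:
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i;
      state = code;
      break;
    default:
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j;
      state = code;
      break;
    }
  }

  size_t a_start, b_start, a_end, b_end;
  if (local) {
    a_start = i + 1; b_start = j + 1; a_end = ti; b_end = tj;
  } else {
    if (free_ends) { // leading free gaps
      for (size_t k = i; k > 0; --k) { ra.push_back(a[k - 1]); rb.push_back('-'); }
      for (size_t k = j; k > 0; --k) { ra.push_back('-'); rb.push_back(b[k - 1]); }
    }
    a_start = m > 0 ? 1 : 0; b_start = n > 0 ? 1 : 0; a_end = m; b_end = n;
  }

  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["score"] = final_score, _["aligned_a"] = ra,
                      _["aligned_b"] = rb,
                      _["a_start"] = static_cast<int>(a_start),
                      _["a_end"] = static_cast<int>(a_end),
                      _["b_start"] = static_cast<int>(b_start),
                      _["b_end"] = static_cast<int>(b_end));
}

// best local (Smith-Waterman) score only, rolling rows
// [[Rcpp::export(name = ".local_best_score_cpp")]]
int local_best_score_cpp(std::string a, std::string b, IntegerVector lookup,
                         int gap_open, int gap_extend) {
  const size_t m = a.size(), n = b.size();
  std::vector<int> Mrow(n + 1, 0), Xrow(n + 1, NEG_INF), Yrow(n + 1, NEG_INF);
  int best = 0;
  const int *lk = INTEGER(lookup);
  // encode b once
  std::vector<int> bi(n);
  for (size_t j = 0; j < n; ++j)
    bi[j] = static_cast<int>(static_cast<unsigned char>(b[j])) & 127;
  int *M = Mrow.data(), *X = Xrow.data(), *Y = Yrow.data();
  for (size_t i = 1; i <= m; ++i) {
    const int *as = lk + ((static_cast<int>(static_cast<unsigned char>(a[i - 1])) & 127) << 7);
    int m_diag = M[0], x_diag = X[0], y_diag = Y[0]; // prev row, col j-1
    int m_left = 0, x_left = NEG_INF, y_left = NEG_INF; // cur row, col j-1
    for (size_t j = 1; j <= n; ++j) {
      const int mpj = M[j], xpj = X[j], ypj = Y[j]; // prev row, col j
      int d = m_diag;
      if (x_diag > d) d = x_diag;
      if (y_diag > d) d = y_diag;
      if (d < 0) d = 0;
      int mv = d + as[bi[j - 1]];
      if (mv < 0) mv = 0;
      if (mv > best) best = mv;
      int xv = mpj - gap_open;
      const int xe = xpj - gap_extend, xy = ypj - gap_open;
      if (xe > xv) xv = xe;
      if (xy > xv) xv = xy;
      int yv = m_left - gap_open;
      const int yx = x_left - gap_open, ye = y_left - gap_extend;
      if (yx > yv) yv = yx;
      if (ye > yv) yv = ye;
      M[j] = mv; X[j] = xv; Y[j] = yv;       // overwrite in place
      m_diag = mpj; x_diag = xpj; y_diag = ypj; // becomes next diag
      m_left = mv; x_left = xv; y_left = yv;
    }
    M[0] = 0; X[0] = NEG_INF; Y[0] = NEG_INF;
  }
  return best;
}

// max over split points s of SW(p[0..s), p[s..n)) -- the off-diagonal
// self-similarity statistic used by self_compare and its permutation null
// [[Rcpp::export(name = ".split_best_scores_cpp")]]
IntegerVector split_best_scores_cpp(std::string p, IntegerVector lookup,
                                    int gap_open, int gap_extend,
                                    IntegerVector splits) {
  IntegerVector out(splits.size());
  for (R_xlen_t k = 0; k < splits.size(); ++k) {
    int s = splits[k];
    out[k] = local_best_score_cpp(p.substr(0, s), p.substr(s), lookup,
                                  gap_open, gap_extend);
  }
  return out;
}

// ---- exhaustive enumeration oracles (exponential; tiny inputs only) ----

struct EnumCtx {
  const char *a, *b;
  int m, n;
  const int *lk;
  int open, ext;
};

static int enum_global_rec(const EnumCtx &c, int i, int j, int prev) {
  if (i == c.m && j == c.n) return 0;
  int best = NEG_INF;
  if (i < c.m && j < c.n) {
    int s = c.lk[((static_cast<unsigned char>(c.a[i])) & 127) * 128 +
                 ((static_cast<unsigned char>(c.b[j])) & 127)];
    int v = enum_global_rec(c, i + 1, j + 1, ST_M);
    if (v > NEG_INF && s + v > best) best = s + v;
  }
  if (i < c.m) { // gap in b
    int cost = (prev == ST_X) ? c.ext : c.open;
    int v = enum_global_rec(c, i + 1, j, ST_X);
    if (v > NEG_INF && v - cost > best) best = v - cost;
  }
  if (j < c.n) { // gap in a
    int cost = (prev == ST_Y) ? c.ext : c.open;
    int v = enum_global_rec(c, i, j + 1, ST_Y);
    if (v > NEG_INF && v - cost > best) best = v - cost;
  }
  return best;
}

// [[Rcpp::export(name = ".enum_global_score_cpp")]]
int enum_global_score_cpp(std::string a, std::string b, IntegerVector lookup,
                          int gap_open, int gap_extend) {
  EnumCtx c{a.c_str(), b.c_str(), static_cast<int>(a.size()),
            static_cast<int>(b.size()), INTEGER(lookup), gap_open, gap_extend};
  return enum_global_rec(c, 0, 0, -1);
}

// best over all paths starting at (i,j) and stopping anywhere (prefix max)
static int enum_local_rec(const EnumCtx &c, int i, int j, int prev) {
  int best = 0; // stopping here contributes nothing further
  if (i < c.m && j < c.n) {
    int s = c.lk[((static_cast<unsigned char>(c.a[i])) & 127) * 128 +
                 ((static_cast<unsigned char>(c.b[j])) & 127)];
    int v = s + enum_local_rec(c, i + 1, j + 1, ST_M);
    if (v > best) best = v;
  }
  if (i < c.m) {
    int cost = (prev == ST_X) ? c.ext : c.open;
    int v = -cost + enum_local_rec(c, i + 1, j, ST_X);
    if (v > best) best = v;
  }
  if (j < c.n) {
    int cost = (prev == ST_Y) ? c.ext : c.open;
    int v = -cost + enum_local_rec(c, i, j + 1, ST_Y);
    if (v > best) best = v;
  }
  return best;
}

// [[Rcpp::export(name = ".enum_local_score_cpp")]]
int enum_local_score_cpp(std::string a, std::string b, IntegerVector lookup,
                         int gap_open, int gap_extend) {
  EnumCtx c{a.c_str(), b.c_str(), static_cast<int>(a.size()),
            static_cast<int>(b.size()), INTEGER(lookup), gap_open, gap_extend};
  int best = 0;
  for (int i = 0; i <= c.m; ++i)
    for (int j = 0; j <= c.n; ++j) {
      int v = enum_local_rec(c, i, j, -1);
      if (v > best) best = v;
    }
  return best;
}
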