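#include <Rcpp.h>
#include <vector>
#include <climits>
#include <algorithm>
using namespace Rcpp;

// Affine gap convention throughout: a gap of length k costs
// gap_open + k * gap_extend, with gap_open <= 0 and gap_extend <= 0.
// Residues are 0-based alphabet codes; code -1 is a wildcard scoring 0
// against anything (used for stop codons / unknown residues).

static inline double pair_score(const NumericMatrix& S, int a, int b) {
  if (a < 0 || b < 0) return 0.0;
  return S(a, b);
}

// Score-only Smith-Waterman (three-state affine), O(m) memory.
// [[Rcpp::export]]
double cpp_sw_score(IntegerVector a, IntegerVector b, NumericMatrix S,
                    double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double og = gap_open + gap_extend, eg = gap_extend;
  std::vector<double> pM(m + 1, R_NegInf), pX(m + 1, R_NegInf), pY(m + 1, R_NegInf);
  std::vector<double> cM(m + 1, R_NegInf), cX(m + 1, R_NegInf), cY(m + 1, R_NegInf);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    cM[0] = cX[0] = cY[0] = R_NegInf;
    for (int j = 1; j <= m; ++j) {
      double d = 0.0;
      if (pM[j - 1] > d) d = pM[j - 1];
      if (pX[j - 1] > d) d = pX[j - 1];
      if (pY[j - 1] > d) d = pY[j - 1];
      cM[j] = d + pair_score(S, a[i - 1], b[j - 1]);
      if (cM[j] > best) best = cM[j];
      cX[j] = std::max(pM[j] + og, pX[j] + eg);
      cY[j] = std::max(cM[j - 1] + og, cY[j - 1] + eg);
    }
    std::swap(pM, cM); std::swap(pX, cX); std::swap(pY, cY);
  }
  return best;
}

// Full Smith-Waterman with traceback and deterministic tie-breaking:
// among equal-scoring local alignments the one with the lexicographically
// smallest (a_start, b_start, a_end, b_end) is returned. Start coordinates
// are propagated through the DP so the tie-break is exact.
// [[Rcpp::export]]
List cpp_sw_align(IntegerVector a, IntegerVector b, NumericMatrix S,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double og = gap_open + gap_extend, eg = gap_extend;
  const size_t N = (size_t)(n + 1) * (m + 1);
  std::vector<double> M(N, R_NegInf), Ix(N, R_NegInf), Iy(N, R_NegInf);
  std::vector<int> siM(N, 0), sjM(N, 0), siX(N, 0), sjX(N, 0), siY(N, 0), sjY(N, 0);
  std::vector<signed char> tbM(N, 0), tbX(N, 0), tbY(N, 0);
  auto idx = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  double best = 0.0;
  int bi = -1, bj = -1, bsi = INT_MAX, bsj = INT_MAX;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = idx(i, j), d = idx(i - 1, j - 1);
      const size_t up = idx(i - 1, j), lf = idx(i, j - 1);
      const double s = pair_score(S, a[i - 1], b[j - 1]);
      // M state: restart or extend from any diagonal predecessor
      double sc = s; int si = i - 1, sj = j - 1; signed char tb = 0;
      if (M[d] + s > sc ||
          (M[d] + s == sc && (siM[d] < si || (siM[d] == si && sjM[d] < sj)))) {
        sc = M[d] + s; si = siM[d]; sj = sjM[d]; tb = 1;
      }
      if (Ix[d] + s > sc ||
          (Ix[d] + s == sc && (siX[d] < si || (siX[d] == si && sjX[d] < sj)))) {
        sc = Ix[d] + s; si = siX[d]; sj = sjX[d]; tb = 2;
      }
      if (Iy[d] + s > sc ||
          (Iy[d] + s == sc && (siY[d] < si || (siY[d] == si && sjY[d] < sj)))) {
        sc = Iy[d] + s; si = siY[d]; sj = sjY[d]; tb = 3;
      }
      M[c] = sc; siM[c] = si; sjM[c] = sj; tbM[c] = tb;
      if (sc > best ||
          (sc == best && sc > 0 &&
           (si < bsi || (si == bsi && (sj < bsj))))) {
        if (sc > 0) { best = sc; bi = i; bj = j; bsi = si; bsj = sj; }
      }
      // Ix: gap in b (consume a)
      double o = M[up] + og, e = Ix[up] + eg;
      if (o >= e) { Ix[c] = o; siX[c] = siM[up]; sjX[c] = sjM[up]; tbX[c] = 0; }
      else        { Ix[c] = e; siX[c] = siX[up]; sjX[c] = sjX[up]; tbX[c] = 1; }
      // Iy: gap in a (consume b)
      o = M[lf] + og; e = Iy[lf] + eg;
      if (o >= e) { Iy[c] = o; siY[c] = siM[lf]; sjY[c] = sjM[lf]; tbY[c] = 0; }
      else        { Iy[c] = e; siY[c] = siY[lf]; sjY[c] = sjY[lf]; tbY[c] = 1; }
    }
  }

  if (bi < 0) {
    return List::create(_["score"] = 0.0,
                        _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0,
                        _["a_idx"] = IntegerVector(0),
                        _["b_idx"] = IntegerVector(0));
  }

  // traceback from (bi, bj) in state M
  std::vector<int> ai, bjv;
  int i = bi, j = bj, state = 0;
  while (true) {
    const size_t c = idx(i, j);
    if (state == 0) {
      ai.push_back(i - 1); bjv.push_back(j - 1);
      signed char tb = tbM[c];
      --i; --j;
      if (tb == 0) break;
      state = (tb == 1) ? 0 : (tb == 2 ? 1 : 2);
    } else if (state == 1) {
      ai.push_back(i - 1); bjv.push_back(-1);
      signed char tb = tbX[c];
      --i;
      state = (tb == 0) ? 0 : 1;
    } else {
      ai.push_back(-1); bjv.push_back(j - 1);
      signed char tb = tbY[c];
      --j;
      state = (tb == 0) ? 0 : 2;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bjv.begin(), bjv.end());
  return List::create(_["score"] = best,
                      _["a_start"] = bsi, _["a_end"] = bi,
                      _["b_start"] = bsj, _["b_end"] = bj,
                      _["a_idx"] = wrap(ai), _["b_idx"] = wrap(bjv));
}

// Global affine alignment over a precomputed column-score matrix
// (rows = columns of profile 1, cols = columns of profile 2). Used both for
// pairwise global alignment (scores looked up from the substitution matrix)
// and for profile-profile alignment during progressive MSA construction.
// ops: 1 = column from both profiles, 2 = profile-1 column vs gap,
//      3 = gap vs profile-2 column.
// [[Rcpp::export]]
List cpp_nw_ops(NumericMatrix colscore, double gap_open, double gap_extend) {
  const int n = colscore.nrow(), m = colscore.ncol();
  const double og = gap_open + gap_extend, eg = gap_extend;
  const size_t N = (size_t)(n + 1) * (m + 1);
  std::vector<double> M(N, R_NegInf), Ix(N, R_NegInf), Iy(N, R_NegInf);
  std::vector<signed char> tbM(N, 0), tbX(N, 0), tbY(N, 0);
  auto idx = [m](int i, int j) { return (size_t)i * (m + 1) + j; };
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    const size_t c = idx(i, 0), up = idx(i - 1, 0);
    Ix[c] = std::max(M[up] + og, Ix[up] + eg);
    tbX[c] = (M[up] + og >= Ix[up] + eg) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    const size_t c = idx(0, j), lf = idx(0, j - 1);
    Iy[c] = std::max(M[lf] + og, Iy[lf] + eg);
    tbY[c] = (M[lf] + og >= Iy[lf] + eg) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = idx(i, j), d = idx(i - 1, j - 1);
      const size_t up = idx(i - 1, j), lf = idx(i, j - 1);
      double sc = M[d]; signed char tb = 1;
      if (Ix[d] > sc) { sc = Ix[d]; tb = 2; }
      if (Iy[d] > sc) { sc = Iy[d]; tb = 3; }
      M[c] = sc + colscore(i - 1, j - 1); tbM[c] = tb;
      double o = M[up] + og, e = Ix[up] + eg;
      if (o >= e) { Ix[c] = o; tbX[c] = 0; } else { Ix[c] = e; tbX[c] = 1; }
      o = M[lf] + og; e = Iy[lf] + eg;
      if (o >= e) { Iy[c] = o; tbY[c] = 0; } else { Iy[c] = e; tbY[c] = 1; }
    }
  }
  const size_t endc = idx(n, m);
  double score = M[endc]; int state = 0;
  if (Ix[endc] > score) { score = Ix[endc]; state = 1; }
  if (Iy[endc] > score) { score = Iy[endc]; state = 2; }
  std::vector<int> ops;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const size_t c = idx(i, j);
    if (state == 0) {
      ops.push_back(1);
      signed char tb = tbM[c];
      --i; --j;
      state = (tb == 1) ? 0 : (tb == 2 ? 1 : 2);
    } else if (state == 1) {
      ops.push_back(2);
      signed char tb = tbX[c];
      --i;
      state = (tb == 0) ? 0 : 1;
    } else {
      ops.push_back(3);
      signed char tb = tbY[c];
      --j;
      state = (tb == 0) ? 0 : 2;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = score, _["ops"] = wrap(ops));
}

// All window scores of an ungapped PSSM (L x 20) along a coded sequence.
// [[Rcpp::export]]
NumericVector cpp_pssm_scan(IntegerVector seq, NumericMatrix pssm) {
  const int n = seq.size(), L = pssm.nrow();
  if (n < L) return NumericVector(0);
  NumericVector out(n - L + 1);
  for (int w = 0; w + L <= n; ++w) {
    double s = 0.0;
    for (int k = 0; k < L; ++k) {
      int r = seq[w + k];
      if (r >= 0) s += pssm(k, r);
    }
    out[w] = s;
  }
  return out;
}

// Null distribution of the per-sequence maximum window score: n_shuffles
// random sequences of length `len` drawn i.i.d. from the background are
// scanned and the max window score of each is returned. Uses R's RNG.
// [[Rcpp::export]]
NumericVector cpp_pssm_null_max(int len, NumericMatrix pssm,
                                NumericVector bg_cum, int n_shuffles) {
  const int L = pssm.nrow();
  NumericVector out(n_shuffles);
  std::vector<int> seq(len);
  for (int s = 0; s < n_shuffles; ++s) {
    for (int i = 0; i < len; ++i) {
      double u = R::unif_rand();
      int r = 0;
      while (r < 19 && u > bg_cum[r]) ++r;
      seq[i] = r;
    }
    double best = R_NegInf;
    for (int w = 0; w + L <= len; ++w) {
      double sc = 0.0;
      for (int k = 0; k < L; ++k) sc += pssm(k, seq[w + k]);
      if (sc > best) best = sc;
    }
    out[s] = best;
  }
  return out;
}
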