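#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Bitset-based evaluation of five-range filters. One 64-bit word covers 64
// molecules; a filter's pass vector is the AND of its five per-range masks.

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
#endif
}

static inline double mcc_from_counts(double tp, double fp, double tn,
                                     double fn) {
  double prod = (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn);
  if (prod <= 0.0) return 0.0;  // zero-denominator convention
  return (tp * tn - fp * fn) / std::sqrt(prod);
}

// Per-descriptor, per-range molecule masks built from the value matrix.
struct MaskSet {
  int n, words;
  std::vector<std::vector<std::vector<uint64_t>>> masks;  // [desc][range][w]
  std::vector<uint64_t> active;
  int n_act, n_dec;
};

static MaskSet build_masks(const NumericMatrix &X, const IntegerVector &y,
                           const List &ranges) {
  MaskSet ms;
  ms.n = X.nrow();
  ms.words = (ms.n + 63) / 64;
  int D = ranges.size();
  ms.masks.resize(D);
  for (int d = 0; d < D; ++d) {
    NumericMatrix r = ranges[d];  // k x 2: low, high
    int k = r.nrow();
    ms.masks[d].assign(k, std::vector<uint64_t>(ms.words, 0));
    for (int j = 0; j < k; ++j) {
      double lo = r(j, 0), hi = r(j, 1);
      std::vector<uint64_t> &m = ms.masks[d][j];
      for (int i = 0; i < ms.n; ++i) {
        double v = X(i, d);
        if (v >= lo && v <= hi) m[i >> 6] |= (uint64_t(1) << (i & 63));
      }
    }
  }
  ms.active.assign(ms.words, 0);
  ms.n_act = 0;
  for (int i = 0; i < ms.n; ++i)
    if (y[i] == 1) { ms.active[i >> 6] |= (uint64_t(1) << (i & 63)); ++ms.n_act; }
  ms.n_dec = ms.n - ms.n_act;
  return ms;
}

// Exhaustively evaluate every combination of 5 distinct descriptors x one
// range each, in lexicographic enumeration order (descriptor indices
// ascending; range indices in catalog order). Returns columnar results.
// [[Rcpp::export]]
List cpp_exhaustive(NumericMatrix X, IntegerVector y, List ranges,
                    double max_results) {
  MaskSet ms = build_masks(X, y, ranges);
  int D = ranges.size();
  if (D < 5) stop("need at least 5 descriptors");
  std::vector<int> k(D);
  for (int d = 0; d < D; ++d) k[d] = ms.masks[d].size();

  // combination count via elementary symmetric polynomial e5
  std::vector<double> e(6, 0.0);
  e[0] = 1.0;
  for (int d = 0; d < D; ++d)
    for (int j = 5; j >= 1; --j) e[j] += e[j - 1] * k[d];
  double total = e[5];
  if (total > max_results)
    stop("catalog holds %.0f combinations, above the exhaustive limit %.0f",
         total, max_results);
  R_xlen_t m = (R_xlen_t)total;

  IntegerMatrix didx(m, 5), ridx(m, 5);
  IntegerVector tp(m), fp(m), tn(m), fn(m);
  NumericVector mcc(m);

  int W = ms.words;
  std::vector<uint64_t> p2(W), p3(W), p4(W);
  R_xlen_t out = 0;
  for (int a = 0; a <= D - 5; ++a)
   for (int ra = 0; ra < k[a]; ++ra) {
    const std::vector<uint64_t> &ma = ms.masks[a][ra];
    for (int b = a + 1; b <= D - 4; ++b)
     for (int rb = 0; rb < k[b]; ++rb) {
      const std::vector<uint64_t> &mb = ms.masks[b][rb];
      for (int w = 0; w < W; ++w) p2[w] = ma[w] & mb[w];
      for (int c = b + 1; c <= D - 3; ++c)
       for (int rc = 0; rc < k[c]; ++rc) {
        const std::vector<uint64_t> &mc = ms.masks[c][rc];
        for (int w = 0; w < W; ++w) p3[w] = p2[w] & mc[w];
        for (int d = c + 1; d <= D - 2; ++d)
         for (int rd = 0; rd < k[d]; ++rd) {
          const std::vector<uint64_t> &md = ms.masks[d][rd];
          for (int w = 0; w < W; ++w) p4[w] = p3[w] & md[w];
          for (int e5 = d + 1; e5 <= D - 1; ++e5)
           for (int re = 0; re < k[e5]; ++re) {
            const std::vector<uint64_t> &me = ms.masks[e5][re];
            int pass = 0, tpc = 0;
            for (int w = 0; w < W; ++w) {
              uint64_t p = p4[w] & me[w];
              pass += popcount64(p);
              tpc += popcount64(p & ms.active[w]);
            }
            int fpc = pass - tpc;
            didx(out, 0) = a + 1; didx(out, 1) = b + 1; didx(out, 2) = c + 1;
            didx(out, 3) = d + 1; didx(out, 4) = e5 + 1;
            ridx(out, 0) = ra + 1; ridx(out, 1) = rb + 1; ridx(out, 2) = rc + 1;
            ridx(out, 3) = rd + 1; ridx(out, 4) = re + 1;
            tp[out] = tpc; fp[out] = fpc;
            fn[out] = ms.n_act - tpc; tn[out] = ms.n_dec - fpc;
            mcc[out] = mcc_from_counts(tpc, fpc, ms.n_dec - fpc,
                                       ms.n_act - tpc);
            ++out;
           }
         }
       }
     }
   }
  return List::create(_["didx"] = didx, _["ridx"] = ridx, _["tp"] = tp,
                      _["fp"] = fp, _["tn"] = tn, _["fn"] = fn,
                      _["mcc"] = mcc);
}

// Uniformly sample t filters (5 distinct descriptors, one range each) and
// evaluate their MCC. Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
List cpp_sample_filters(NumericMatrix X, IntegerVector y, List ranges,
                        int t) {
  if (t < 1) stop("sample size must be >= 1");
  MaskSet ms = build_masks(X, y, ranges);
  int D = ranges.size();
  if (D < 5) stop("need at least 5 descriptors");
  std::vector<int> k(D);
  for (int d = 0; d < D; ++d) k[d] = ms.masks[d].size();

  IntegerMatrix didx(t, 5), ridx(t, 5);
  NumericVector mcc(t);
  int W = ms.words;
  std::vector<uint64_t> acc(W);
  int sel[5];
  for (int s = 0; s < t; ++s) {
    // 5 distinct descriptors by rejection
    int got = 0;
    while (got < 5) {
      int cand = (int)(unif_rand() * D);
      if (cand >= D) cand = D - 1;
      bool dup = false;
      for (int j = 0; j < got; ++j) if (sel[j] == cand) { dup = true; break; }
      if (!dup) sel[got++] = cand;
    }
    std::sort(sel, sel + 5);
    int pass = 0, tpc = 0;
    for (int j = 0; j < 5; ++j) {
      int d = sel[j];
      int r = (int)(unif_rand() * k[d]);
      if (r >= k[d]) r = k[d] - 1;
      didx(s, j) = d + 1;
      ridx(s, j) = r + 1;
      const std::vector<uint64_t> &m = ms.masks[d][r];
      if (j == 0) std::copy(m.begin(), m.end(), acc.begin());
      else for (int w = 0; w < W; ++w) acc[w] &= m[w];
    }
    for (int w = 0; w < W; ++w) {
      pass += popcount64(acc[w]);
      tpc += popcount64(acc[w] & ms.active[w]);
    }
    int fpc = pass - tpc;
    mcc[s] = mcc_from_counts(tpc, fpc, ms.n_dec - fpc, ms.n_act - tpc);
  }
  return List::create(_["didx"] = didx, _["ridx"] = ridx, _["mcc"] = mcc);
}

// Evaluate explicit filters (rows of didx/lo/hi) against a labelled table.
// didx is 1-based column indices into X.
// [[Rcpp::export]]
List cpp_eval_filters(NumericMatrix X, IntegerVector y, IntegerMatrix didx,
                      NumericMatrix lo, NumericMatrix hi) {
  int m = didx.nrow(), n = X.nrow(), K = didx.ncol();
  IntegerVector tp(m), fp(m), tn(m), fn(m);
  NumericVector mcc(m);
  for (int f = 0; f < m; ++f) {
    int tpc = 0, fpc = 0, tnc = 0, fnc = 0;
    for (int i = 0; i < n; ++i) {
      bool pass = true;
      for (int j = 0; j < K; ++j) {
        double v = X(i, didx(f, j) - 1);
        if (v < lo(f, j) || v > hi(f, j)) { pass = false; break; }
      }
      if (y[i] == 1) { if (pass) ++tpc; else ++fnc; }
      else           { if (pass) ++fpc; else ++tnc; }
    }
    tp[f] = tpc; fp[f] = fpc; tn[f] = tnc; fn[f] = fnc;
    mcc[f] = mcc_from_counts(tpc, fpc, tnc, fnc);
  }
  return List::create(_["tp"] = tp, _["fp"] = fp, _["tn"] = tn, _["fn"] = fn,
                      _["mcc"] = mcc);
}

// Score molecules on the [-1, +1] index: per filter, +w if the molecule
// passes all five ranges, -w otherwise; normalized by the total weight.
// [[Rcpp::export]]
List cpp_score_library(NumericMatrix X, IntegerMatrix didx, NumericMatrix lo,
                       NumericMatrix hi, NumericVector w) {
  int n = X.nrow(), m = didx.nrow(), K = didx.ncol();
  double wsum = 0.0;
  for (int f = 0; f < m; ++f) wsum += w[f];
  if (wsum <= 0) stop("total filter weight must be positive");
  NumericVector index(n);
  IntegerVector npass(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    int np = 0;
    for (int f = 0; f < m; ++f) {
      bool pass = true;
      for (int j = 0; j < K; ++j) {
        double v = X(i, didx(f, j) - 1);
        if (v < lo(f, j) || v > hi(f, j)) { pass = false; break; }
      }
      if (pass) { s += w[f]; ++np; } else s -= w[f];
    }
    index[i] = s / wsum;
    npass[i] = np;
  }
  return List::create(_["index"] = index, _["n_filters_passed"] = npass);
}
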