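// Exhaustive antiparallel Watson-Crick duplex enumeration and 10^L window
// scoring.  Bases are encoded 0=A, 1=C, 2=G, 3=T so that the complement of
// code x is 3-x.  All coordinates crossing the R boundary are 1-based.
//
// Inter-oligomer alignments are scanned along antiparallel diagonals
// d = p + q (a[p] paired with b[q]); consecutive pairs advance (p+1, q-1).
// Intra-oligomer pairs are the subset with both positions on one strand and
// p < q, so each unordered pairing is visited exactly once and the paired
// segments never overlap.
//
// A base pair (p on a, q on b) is "necessary" when the design's provenance
// places both bases at the same position of the same domain with opposite
// complement flags; runs/windows are necessary iff every pair is.

#include <Rcpp.h>
using namespace Rcpp;

static inline bool wc_match(int x, int y) { return x + y == 3; }

// score table lookup: stab[M] (1-based via stab[M-1]) = sum over windows of a
// maximal run of length M, already truncated at the caller's SLC.
static inline double run_score(const NumericVector& stab, int M) {
  if (M <= 0) return 0.0;
  if (M > stab.size()) M = stab.size(); // defensive; tables are sized to max length
  return stab[M - 1];
}

struct RunAcc {
  std::vector<int> start_a, start_b, len, nec;
};

// Scan one inter diagonal d over p in [pmin, pmax]; q = d - p.
// Emits maximal runs and, via stabs, accumulates scores.
// Template-free small helper kept inline for clarity.

// ---------------------------------------------------------------------------
// Run enumeration (list form, for reports/tests)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_inter_runs(IntegerVector a, IntegerVector b) {
  int n = a.size(), m = b.size();
  RunAcc acc;
  for (int d = 2; d <= n + m; ++d) {
    int pmin = std::max(1, d - m), pmax = std::min(n, d - 1);
    int L = 0, p0 = 0;
    for (int p = pmin; p <= pmax + 1; ++p) {
      bool ok = (p <= pmax) && wc_match(a[p - 1], b[d - p - 1]);
      if (ok) {
        if (L == 0) p0 = p;
        ++L;
      } else if (L > 0) {
        acc.start_a.push_back(p0);
        acc.start_b.push_back(d - p0 - L + 1); // 5'-most paired base on b
        acc.len.push_back(L);
        L = 0;
      }
    }
  }
  int k = acc.len.size();
  IntegerMatrix out(k, 3);
  for (int r = 0; r < k; ++r) {
    out(r, 0) = acc.start_a[r];
    out(r, 1) = acc.start_b[r];
    out(r, 2) = acc.len[r];
  }
  colnames(out) = CharacterVector::create("start_a", "start_b", "length");
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_intra_runs(IntegerVector s, int min_loop) {
  int n = s.size();
  RunAcc acc;
  for (int d = 3; d <= 2 * n - 1; ++d) {
    int pmin = std::max(1, d - n);
    int pmax = (d - min_loop - 1) / 2; // innermost pair keeps q - p > min_loop
    int L = 0, p0 = 0;
    for (int p = pmin; p <= pmax + 1; ++p) {
      bool ok = (p <= pmax) && wc_match(s[p - 1], s[d - p - 1]);
      if (ok) {
        if (L == 0) p0 = p;
        ++L;
      } else if (L > 0) {
        acc.start_a.push_back(p0);
        acc.start_b.push_back(d - p0 - L + 1);
        acc.len.push_back(L);
        L = 0;
      }
    }
  }
  int k = acc.len.size();
  IntegerMatrix out(k, 3);
  for (int r = 0; r < k; ++r) {
    out(r, 0) = acc.start_a[r];
    out(r, 1) = acc.start_b[r];
    out(r, 2) = acc.len[r];
  }
  colnames(out) = CharacterVector::create("start_a", "start_b", "length");
  return out;
}

// ---------------------------------------------------------------------------
// Run enumeration with necessary-pair classification
// ---------------------------------------------------------------------------

static inline bool nec_pair(int da, int pa, int ca, int db, int pb, int cb) {
  return da > 0 && da == db && ca != cb && pa == pb;
}

// Shared engine: emits runs (+ all-necessary flag) and the lengths of maximal
// all-necessary stretches inside runs (these generate the necessary windows).
static List enum_nec(IntegerVector a, IntegerVector b, bool intra, int min_loop,
                     IntegerVector dom_a, IntegerVector pos_a, IntegerVector cmp_a,
                     IntegerVector dom_b, IntegerVector pos_b, IntegerVector cmp_b) {
  int n = a.size(), m = b.size();
  RunAcc acc;
  std::vector<int> nec_len;
  int dlo = intra ? 3 : 2;
  int dhi = intra ? 2 * n - 1 : n + m;
  for (int d = dlo; d <= dhi; ++d) {
    int pmin = std::max(1, d - m);
    int pmax = intra ? (d - min_loop - 1) / 2 : std::min(n, d - 1);
    int L = 0, p0 = 0, necL = 0;
    bool allnec = true;
    for (int p = pmin; p <= pmax + 1; ++p) {
      bool ok = (p <= pmax) && wc_match(a[p - 1], b[d - p - 1]);
      if (ok) {
        if (L == 0) { p0 = p; allnec = true; necL = 0; }
        ++L;
        int q = d - p;
        if (nec_pair(dom_a[p - 1], pos_a[p - 1], cmp_a[p - 1],
                     dom_b[q - 1], pos_b[q - 1], cmp_b[q - 1])) {
          ++necL;
        } else {
          allnec = false;
          if (necL > 0) { nec_len.push_back(necL); necL = 0; }
        }
      } else if (L > 0) {
        if (necL > 0) nec_len.push_back(necL);
        acc.start_a.push_back(p0);
        acc.start_b.push_back(d - p0 - L + 1);
        acc.len.push_back(L);
        acc.nec.push_back(allnec ? 1 : 0);
        L = 0;
      }
    }
  }
  int k = acc.len.size();
  IntegerMatrix runs(k, 4);
  for (int r = 0; r < k; ++r) {
    runs(r, 0) = acc.start_a[r];
    runs(r, 1) = acc.start_b[r];
    runs(r, 2) = acc.len[r];
    runs(r, 3) = acc.nec[r];
  }
  colnames(runs) = CharacterVector::create("start_a", "start_b", "length", "necessary");
  return List::create(_["runs"] = runs, _["nec_stretches"] = wrap(nec_len));
}

// [[Rcpp::export]]
List cpp_inter_runs_nec(IntegerVector a, IntegerVector b,
                        IntegerVector dom_a, IntegerVector pos_a, IntegerVector cmp_a,
                        IntegerVector dom_b, IntegerVector pos_b, IntegerVector cmp_b) {
  return enum_nec(a, b, false, 0, dom_a, pos_a, cmp_a, dom_b, pos_b, cmp_b);
}

// [[Rcpp::export]]
List cpp_intra_runs_nec(IntegerVector s, int min_loop,
                        IntegerVector dom, IntegerVector pos, IntegerVector cmp) {
  return enum_nec(s, s, true, min_loop, dom, pos, cmp, dom, pos, cmp);
}

// ---------------------------------------------------------------------------
// Fast scoring (no run lists): total window score, necessary window score,
// largest run containing an unnecessary pair.
// ---------------------------------------------------------------------------

// The above-baseline ("unnecessary") score is accumulated per maximal run as
// stab[M] minus the window score of the run's all-necessary stretches.  This
// local difference is well conditioned; computing sum(total) - sum(necessary)
// globally instead would lose every unnecessary contribution smaller than
// the floating-point epsilon of a large intended duplex's score.
static void score_scan(const IntegerVector& a, const IntegerVector& b,
                       bool intra, int min_loop, const NumericVector& stab,
                       const int* dom_a, const int* pos_a, const int* cmp_a,
                       const int* dom_b, const int* pos_b, const int* cmp_b,
                       double& total, double& necessary, double& unnec,
                       int& max_unnec) {
  int n = a.size(), m = b.size();
  int dlo = intra ? 3 : 2;
  int dhi = intra ? 2 * n - 1 : n + m;
  for (int d = dlo; d <= dhi; ++d) {
    int pmin = std::max(1, d - m);
    int pmax = intra ? (d - min_loop - 1) / 2 : std::min(n, d - 1);
    int L = 0, necL = 0;
    double run_nec = 0.0;
    bool allnec = true;
    for (int p = pmin; p <= pmax + 1; ++p) {
      bool ok = (p <= pmax) && wc_match(a[p - 1], b[d - p - 1]);
      if (ok) {
        if (L == 0) { allnec = true; necL = 0; run_nec = 0.0; }
        ++L;
        bool np = false;
        if (dom_a) {
          int q = d - p;
          np = nec_pair(dom_a[p - 1], pos_a[p - 1], cmp_a[p - 1],
                        dom_b[q - 1], pos_b[q - 1], cmp_b[q - 1]);
        }
        if (np) {
          ++necL;
        } else {
          allnec = false;
          if (necL > 0) { run_nec += run_score(stab, necL); necL = 0; }
        }
      } else if (L > 0) {
        if (necL > 0) run_nec += run_score(stab, necL);
        necessary += run_nec;
        total += run_score(stab, L);
        double ru = run_score(stab, L) - run_nec;
        if (ru > 0.0) unnec += ru;
        if (!allnec && L > max_unnec) max_unnec = L;
        L = 0;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_pair_score(IntegerVector a, IntegerVector b, NumericVector stab,
                             IntegerVector dom_a, IntegerVector pos_a, IntegerVector cmp_a,
                             IntegerVector dom_b, IntegerVector pos_b, IntegerVector cmp_b) {
  double tot = 0.0, nec = 0.0, un = 0.0;
  int mx = 0;
  bool have_prov = dom_a.size() == a.size() && dom_b.size() == b.size();
  score_scan(a, b, false, 0, stab,
             have_prov ? INTEGER(dom_a) : (const int*)nullptr,
             have_prov ? INTEGER(pos_a) : nullptr,
             have_prov ? INTEGER(cmp_a) : nullptr,
             have_prov ? INTEGER(dom_b) : nullptr,
             have_prov ? INTEGER(pos_b) : nullptr,
             have_prov ? INTEGER(cmp_b) : nullptr,
             tot, nec, un, mx);
  return NumericVector::create(_["total"] = tot, _["necessary"] = nec,
                               _["unnecessary"] = un,
                               _["max_unnecessary"] = (double)mx);
}

// [[Rcpp::export]]
NumericVector cpp_intra_score(IntegerVector s, int min_loop, NumericVector stab,
                              IntegerVector dom, IntegerVector pos, IntegerVector cmp) {
  double tot = 0.0, nec = 0.0, un = 0.0;
  int mx = 0;
  bool have_prov = dom.size() == s.size();
  score_scan(s, s, true, min_loop, stab,
             have_prov ? INTEGER(dom) : (const int*)nullptr,
             have_prov ? INTEGER(pos) : nullptr,
             have_prov ? INTEGER(cmp) : nullptr,
             have_prov ? INTEGER(dom) : nullptr,
             have_prov ? INTEGER(pos) : nullptr,
             have_prov ? INTEGER(cmp) : nullptr,
             tot, nec, un, mx);
  return NumericVector::create(_["total"] = tot, _["necessary"] = nec,
                               _["unnecessary"] = un,
                               _["max_unnecessary"] = (double)mx);
}

// ---------------------------------------------------------------------------
// Random-network sampling used by the scaling study.  Bases are drawn from
// R's RNG (unif_rand) so results are governed by set.seed().  Returns one row
// per network: N, O, largest intra run, largest inter run.  Networks have no
// intentional duplexes, so every duplex is unnecessary and dN = N, dO = O.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_random_scores(int i, int j, int n,
                                NumericVector stab_inter, NumericVector stab_intra,
                                int min_loop) {
  RNGScope scope;
  NumericMatrix out(n, 4);
  std::vector<IntegerVector> oligs(i);
  for (int o = 0; o < i; ++o) oligs[o] = IntegerVector(j);
  for (int net = 0; net < n; ++net) {
    for (int o = 0; o < i; ++o) {
      IntegerVector& v = oligs[o];
      for (int p = 0; p < j; ++p) {
        int base = (int)(4.0 * unif_rand());
        v[p] = base > 3 ? 3 : base;
      }
    }
    double N = 0.0, O = 0.0;
    int max_intra = 0, max_inter = 0;
    for (int oa = 0; oa < i; ++oa) {
      for (int ob = oa; ob < i; ++ob) { // unordered species pairs incl. self
        double tot = 0.0, nec = 0.0, un = 0.0;
        int mx = 0;
        score_scan(oligs[oa], oligs[ob], false, 0, stab_inter,
                   nullptr, nullptr, nullptr, nullptr, nullptr, nullptr,
                   tot, nec, un, mx);
        N += tot;
        if (mx > max_inter) max_inter = mx;
      }
      double tot = 0.0, nec = 0.0, un = 0.0;
      int mx = 0;
      score_scan(oligs[oa], oligs[oa], true, min_loop, stab_intra,
                 nullptr, nullptr, nullptr, nullptr, nullptr, nullptr,
                 tot, nec, un, mx);
      O += tot;
      if (mx > max_intra) max_intra = mx;
    }
    out(net, 0) = N;
    out(net, 1) = O;
    out(net, 2) = (double)max_intra;
    out(net, 3) = (double)max_inter;
  }
  colnames(out) = CharacterVector::create("N", "O", "max_intra", "max_inter");
  return out;
}

// ---------------------------------------------------------------------------
// Bootstrap IQRNL helper: B resamples (with replacement, size n) of lnk,
// type-7 quartiles of each resample, IQR returned per resample.
// ---------------------------------------------------------------------------

static double quant7(std::vector<double>& x, double p) {
  // x must be sorted
  int n = x.size();
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  if (lo >= n - 1) return x[n - 1];
  return x[lo] + (h - lo) * (x[lo + 1] - x[lo]);
}

// [[Rcpp::export]]
NumericVector cpp_iqrnl_boot(NumericVector lnk, int n, int B) {
  RNGScope scope;
  int N = lnk.size();
  NumericVector out(B);
  std::vector<double> res(n);
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < n; ++t) {
      int idx = (int)(N * unif_rand());
      res[t] = lnk[idx >= N ? N - 1 : idx];
    }
    std::sort(res.begin(), res.end());
    out[b] = quant7(res, 0.75) - quant7(res, 0.25);
  }
  return out;
}
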