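// Brute-force enumeration reference for exact 2x2 inference, kept deliberately
// independent of fisher_exact.cpp: its own log-factorial table (accumulated
// sums of log(i), no lgamma), long-double tail sums over the full support, and
// plain fixed-count bisection for the conditional MLE and interval bounds.
// Intended for validation; quadratic-time-per-table and entirely naive.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static std::vector<long double> LFACT;  // LFACT[n] = log(n!)

static void ensure_lfact(int n) {
  if ((int)LFACT.size() > n) return;
  size_t from = LFACT.empty() ? 1 : LFACT.size();
  if (LFACT.empty()) LFACT.push_back(0.0L);
  for (size_t i = from; i <= (size_t)n; ++i)
    LFACT.push_back(LFACT[i - 1] + logl((long double)i));
}

static long double lbinom(int n, int k) {
  return LFACT[n] - LFACT[k] - LFACT[n - k];
}

struct Enum2x2 {
  int r1, r2, c1, lo, hi;
  // unnormalized log weight of cell value k at log-odds u
  long double lw(int k, long double u) const {
    return lbinom(r1, k) + lbinom(r2, c1 - k) + (long double)k * u;
  }
  long double mass_below(int a, long double u, bool upper) const {
    // normalized tail: sum_{k <= a} (or >= a) of weights
    long double m = -1e30L;
    for (int k = lo; k <= hi; ++k) { long double v = lw(k, u); if (v > m) m = v; }
    long double num = 0.0L, den = 0.0L;
    for (int k = lo; k <= hi; ++k) {
      long double w = expl(lw(k, u) - m);
      den += w;
      if (upper ? (k >= a) : (k <= a)) num += w;
    }
    return num / den;
  }
  long double mean(long double u) const {
    long double m = -1e30L;
    for (int k = lo; k <= hi; ++k) { long double v = lw(k, u); if (v > m) m = v; }
    long double num = 0.0L, den = 0.0L;
    for (int k = lo; k <= hi; ++k) {
      long double w = expl(lw(k, u) - m);
      den += w; num += (long double)k * w;
    }
    return num / den;
  }
};

// [[Rcpp::export(name = ".fisher2x2_enum_cpp")]]
DataFrame fisher2x2_enum_cpp(IntegerVector a, IntegerVector b, IntegerVector c,
                             IntegerVector d, double conf_level = 0.95) {
  int n = a.size();
  NumericVector pv(n), orest(n), lo95(n), hi95(n);
  long double tail = ((long double)1.0 - (long double)conf_level) / 2.0L;
  const long double ULIM = 250.0L;
  for (int i = 0; i < n; ++i) {
    if (a[i] < 0 || b[i] < 0 || c[i] < 0 || d[i] < 0)
      stop("negative cell in 2x2 table");
    Enum2x2 T;
    T.r1 = a[i] + b[i]; T.r2 = c[i] + d[i]; T.c1 = a[i] + c[i];
    T.lo = std::max(0, T.c1 - T.r2);
    T.hi = std::min(T.r1, T.c1);
    ensure_lfact(T.r1 + T.r2);
    int A = a[i];
    if (T.lo == T.hi) {
      pv[i] = 1.0; orest[i] = NA_REAL; lo95[i] = 0.0; hi95[i] = R_PosInf;
      continue;
    }
    // two-sided p at psi = 1: sum of masses <= observed * (1 + 1e-7)
    {
      long double m = -1e30L;
      for (int k = T.lo; k <= T.hi; ++k) {
        long double v = T.lw(k, 0.0L); if (v > m) m = v;
      }
      long double den = 0.0L;
      for (int k = T.lo; k <= T.hi; ++k) den += expl(T.lw(k, 0.0L) - m);
      long double obs = expl(T.lw(A, 0.0L) - m) / den;
      long double cut = obs * (1.0L + 1e-7L);
      long double p = 0.0L;
      for (int k = T.lo; k <= T.hi; ++k) {
        long double w = expl(T.lw(k, 0.0L) - m) / den;
        if (w <= cut) p += w;
      }
      pv[i] = (double)(p > 1.0L ? 1.0L : p);
    }
    // conditional MLE: mean(u) = A, mean increasing in u
    if (A == T.lo) orest[i] = 0.0;
    else if (A == T.hi) orest[i] = R_PosInf;
    else {
      long double ulo = -ULIM, uhi = ULIM;
      for (int it = 0; it < 300; ++it) {
        long double mid = (ulo + uhi) / 2.0L;
        if (mid <= ulo || mid >= uhi) break;
        if (T.mean(mid) < (long double)A) ulo = mid; else uhi = mid;
      }
      orest[i] = (double)expl((ulo + uhi) / 2.0L);
    }
    // lower bound: P_u(A >= a) = tail (increasing in u)
    if (A == T.lo) lo95[i] = 0.0;
    else {
      long double ulo = -ULIM, uhi = ULIM;
      for (int it = 0; it < 300; ++it) {
        long double mid = (ulo + uhi) / 2.0L;
        if (mid <= ulo || mid >= uhi) break;
        if (T.mass_below(A, mid, true) < tail) ulo = mid; else uhi = mid;
      }
      lo95[i] = (double)expl((ulo + uhi) / 2.0L);
    }
    // upper bound: P_u(A <= a) = tail (decreasing in u)
    if (A == T.hi) hi95[i] = R_PosInf;
    else {
      long double ulo = -ULIM, uhi = ULIM;
      for (int it = 0; it < 300; ++it) {
        long double mid = (ulo + uhi) / 2.0L;
        if (mid <= ulo || mid >= uhi) break;
        if (T.mass_below(A, mid, false) > tail) ulo = mid; else uhi = mid;
      }
      hi95[i] = (double)expl((ulo + uhi) / 2.0L);
    }
  }
  return DataFrame::create(_["p"] = pv, _["or"] = orest,
                           _["ci_lo"] = lo95, _["ci_hi"] = hi95);
}
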