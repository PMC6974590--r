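// Exact inference for 2x2 tables under the (noncentral) hypergeometric model:
// two-sided probability-mass p-value, conditional maximum-likelihood odds
// ratio, and exact conditional confidence interval by tail inversion.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Masses within a factor (1 + REL_TIE_TOL) of the observed mass are treated
// as tied when accumulating the two-sided p-value.
static const double REL_TIE_TOL = 1e-7;
// log(psi) search bracket; wide enough that conditional tails at the ends
// are far below any 0.025 quantile for tables with N <= a few hundred.
static const double TLIM = 250.0;

struct CondTable {
  int r1, r2, c1, lo, hi;
  std::vector<double> lp;  // lp[k - lo] = log C(r1, k) + log C(r2, c1 - k)
};

static void setup_table(int a, int b, int c, int d, CondTable &T) {
  T.r1 = a + b;
  T.r2 = c + d;
  T.c1 = a + c;
  T.lo = std::max(0, T.c1 - T.r2);
  T.hi = std::min(T.r1, T.c1);
  T.lp.resize(T.hi - T.lo + 1);
  for (int k = T.lo; k <= T.hi; ++k)
    T.lp[k - T.lo] = R::lchoose(T.r1, k) + R::lchoose(T.r2, T.c1 - k);
}

// Normalized weights w_k proportional to exp(lp_k + k * t).
static void weights_at(const CondTable &T, double t, std::vector<double> &w) {
  int n = (int)T.lp.size();
  w.resize(n);
  double m = R_NegInf;
  for (int i = 0; i < n; ++i) {
    w[i] = T.lp[i] + (double)(T.lo + i) * t;
    if (w[i] > m) m = w[i];
  }
  double s = 0.0;
  for (int i = 0; i < n; ++i) { w[i] = std::exp(w[i] - m); s += w[i]; }
  for (int i = 0; i < n; ++i) w[i] /= s;
}

static double cond_mean(const CondTable &T, double t) {
  std::vector<double> w;
  weights_at(T, t, w);
  double e = 0.0;
  for (size_t i = 0; i < w.size(); ++i) e += (double)(T.lo + (int)i) * w[i];
  return e;
}

// P_t(A <= a) if upper_tail is false, else P_t(A >= a).
static double cond_tail(const CondTable &T, double t, int a, bool upper_tail) {
  std::vector<double> w;
  weights_at(T, t, w);
  double s = 0.0;
  for (size_t i = 0; i < w.size(); ++i) {
    int k = T.lo + (int)i;
    if (upper_tail ? (k >= a) : (k <= a)) s += w[i];
  }
  return s;
}

// Bisection to floating-point resolution for a monotone function f on
// [tlo, thi] with f(tlo) and f(thi) of opposite sign; increasing says which.
template <typename F>
static double bisect(F f, double tlo, double thi, bool increasing) {
  for (int it = 0; it < 300; ++it) {
    double mid = 0.5 * (tlo + thi);
    if (mid <= tlo || mid >= thi) break;
    double fm = f(mid);
    bool go_right = increasing ? (fm < 0.0) : (fm > 0.0);
    if (go_right) tlo = mid; else thi = mid;
  }
  return 0.5 * (tlo + thi);
}

static double two_sided_p(const CondTable &T, int a) {
  std::vector<double> w;
  weights_at(T, 0.0, w);
  double obs = w[a - T.lo] * (1.0 + REL_TIE_TOL);
  double p = 0.0;
  for (size_t i = 0; i < w.size(); ++i)
    if (w[i] <= obs) p += w[i];
  return std::min(p, 1.0);
}

// [[Rcpp::export(name = ".fisher2x2_cpp")]]
DataFrame fisher2x2_cpp(IntegerVector a, IntegerVector b, IntegerVector c,
                        IntegerVector d, double conf_level = 0.95) {
  int n = a.size();
  NumericVector p(n), orest(n), lo95(n), hi95(n);
  double tail = (1.0 - conf_level) / 2.0;
  CondTable T;
  for (int i = 0; i < n; ++i) {
    if (a[i] < 0 || b[i] < 0 || c[i] < 0 || d[i] < 0)
      stop("negative cell in 2x2 table");
    setup_table(a[i], b[i], c[i], d[i], T);
    int A = a[i];
    if (T.lo == T.hi) {  // degenerate support: the table is fixed by margins
      p[i] = 1.0; orest[i] = NA_REAL; lo95[i] = 0.0; hi95[i] = R_PosInf;
      continue;
    }
    p[i] = two_sided_p(T, A);
    if (A == T.lo) orest[i] = 0.0;
    else if (A == T.hi) orest[i] = R_PosInf;
    else {
      double t = bisect([&](double x) { return cond_mean(T, x) - (double)A; },
                        -TLIM, TLIM, true);
      orest[i] = std::exp(t);
    }
    if (A == T.lo) lo95[i] = 0.0;
    else {
      double t = bisect([&](double x) { return cond_tail(T, x, A, true) - tail; },
                        -TLIM, TLIM, true);
      lo95[i] = std::exp(t);
    }
    if (A == T.hi) hi95[i] = R_PosInf;
    else {
      double t = bisect([&](double x) { return cond_tail(T, x, A, false) - tail; },
                        -TLIM, TLIM, false);
      hi95[i] = std::exp(t);
    }
  }
  return DataFrame::create(_["p"] = p, _["or"] = orest,
                           _["ci_lo"] = lo95, _["ci_hi"] = hi95);
}
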