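#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// log(exp(a) + exp(b)); -Inf safe, with an early exit for well-separated
// arguments (log1p(exp(-36)) underflows the double ulp of typical sums)
static inline double lse2(double a, double b) {
  double m, d;
  if (a >= b) { m = a; d = a - b; } else { m = b; d = b - a; }
  if (d > 36.0 || m == R_NegInf) return m;
  return m + log1p(std::exp(-d));
}

// Windowed pair-pattern log likelihood (max-over-edges approximation).
//
// The 4x4 noisy pattern table factorises over its rank classes: cells with
// both ranks in {0,1} carry the clean pattern table convolved with the
// error kernel; a cell with an error rank (2,3) at one site is
// (e/3) * (noisy single-site marginal of the other site), which depends on
// only one of the two mutation edges; a cell with error ranks at both
// sites is (e/3)^2 exactly.  Count tables are therefore decomposed once at
// preprocessing time into
//   main cells  (codes p*2+q, p,q in {0,1}; counts main_cnt),
//   err_i[p]    total counts with rank p in {0,1} at site i, error rank at
//               the reference,
//   err_c[q]    the converse,
//   err_both    counts with error ranks at both sites,
// and root states (r_i, r_c) act on main cells as index permutations.
//
// clades: (E+1) x n_tips 0/1, row 0 = "no mutation".
// Returns sum over windows of
//   max_v lse_{r_c} [ sum_i max_u lse_{r_i}( loglik + lpr_ri ) + lpr_rc ];
// multinomial coefficients are added back in R.
// [[Rcpp::export]]
double cpp_alignment_loglik(IntegerMatrix clades, NumericVector R, double e,
                            IntegerVector site_window,
                            IntegerVector main_off, IntegerVector main_code,
                            NumericVector main_cnt, NumericMatrix err_i,
                            NumericMatrix err_c, NumericVector err_both,
                            NumericMatrix lpr_ri, NumericMatrix lpr_rc,
                            int n_windows) {
  const int E1 = clades.nrow();
  const int nt = clades.ncol();
  const int S = site_window.size();
  const int W = n_windows;

  std::vector<double> csum(E1, 0.0), inter((size_t)E1 * E1, 0.0);
  for (int u = 0; u < E1; ++u) {
    double s = 0.0;
    for (int t = 0; t < nt; ++t) if (clades(u, t)) s += R[t];
    csum[u] = s;
  }
  for (int u = 0; u < E1; ++u)
    for (int v = u; v < E1; ++v) {
      double s = 0.0;
      for (int t = 0; t < nt; ++t)
        if (clades(u, t) && clades(v, t)) s += R[t];
      inter[(size_t)u * E1 + v] = s;
      inter[(size_t)v * E1 + u] = s;
    }

  // zero probabilities are represented by a very negative finite log so
  // that dense dot products with zero counts stay well-defined (0 * log(0)
  // must contribute 0); any positive count then drives the combination's
  // log likelihood to ~ -1e30, which max/lse treat as impossible
  const double NEG_BIG = -1e30;
  const double e1 = 1.0 - e, e3 = e / 3.0;
  const double l_e3 = e3 > 0.0 ? std::log(e3) : NEG_BIG;

  // log noisy main cells at root states (0,0): lp00[(u*E1+v)*4 + p*2+q]
  std::vector<double> lp00((size_t)E1 * E1 * 4);
  for (int u = 0; u < E1; ++u) {
    const double cu = csum[u];
    for (int v = 0; v < E1; ++v) {
      const double cv = csum[v];
      const double m11 = inter[(size_t)u * E1 + v];
      const double m10 = cu - m11, m01 = cv - m11;
      double m00 = 1.0 - m11 - m10 - m01;
      if (m00 < 0.0) m00 = 0.0;
      // clean00[p][q] = mass of tips with state (p, q)
      const double cl[2][2] = {{m00, m01}, {m10, m11}};
      double *dst = &lp00[((size_t)u * E1 + v) * 4];
      for (int p = 0; p < 2; ++p)
        for (int q = 0; q < 2; ++q) {
          const double s =
            cl[p][q] * e1 * e1 +
            (cl[p][1 - q] + cl[1 - p][q]) * e1 * e3 +
            cl[1 - p][1 - q] * e3 * e3;
          dst[p * 2 + q] = s > 0.0 ? std::log(s) : NEG_BIG;
        }
    }
  }

  // log((e/3) * noisy single-site marginal): lm[u][r][p], p in {0,1}
  std::vector<double> lm((size_t)E1 * 4);
  for (int u = 0; u < E1; ++u) {
    for (int r = 0; r < 2; ++r) {
      const double d = csum[u];               // mass in derived state 1-r
      const double marg1 = r == 0 ? d : 1.0 - d;
      const double m1 = marg1 * e1 + (1.0 - marg1) * e3;
      const double m0 = (1.0 - marg1) * e1 + marg1 * e3;
      lm[(size_t)(u * 2 + r) * 2 + 0] =
        m0 > 0.0 ? l_e3 + std::log(m0) : NEG_BIG;
      lm[(size_t)(u * 2 + r) * 2 + 1] =
        m1 > 0.0 ? l_e3 + std::log(m1) : NEG_BIG;
    }
  }

  std::vector<double> acc((size_t)W * E1 * 2, 0.0);
  std::vector<double> a((size_t)E1 * 2), b((size_t)E1 * 2);

  for (int s = 0; s < S; ++s) {
    const int w = site_window[s];
    const int from = main_off[s], to = main_off[s + 1];
    const double ei0 = err_i(0, s), ei1 = err_i(1, s);
    const double ec0 = err_c(0, s), ec1 = err_c(1, s);
    const double cb = err_both[s];
    const double const_b = cb > 0.0 ? cb * 2.0 * l_e3 : 0.0;
    // per-(u, r_i) and per-(v, r_c) error-cell terms
    for (int u = 0; u < E1; ++u)
      for (int r = 0; r < 2; ++r) {
        const double *l = &lm[(size_t)(u * 2 + r) * 2];
        a[u * 2 + r] = (ei0 > 0.0 ? ei0 * l[0] : 0.0) +
                       (ei1 > 0.0 ? ei1 * l[1] : 0.0);
        b[u * 2 + r] = (ec0 > 0.0 ? ec0 * l[0] : 0.0) +
                       (ec1 > 0.0 ? ec1 * l[1] : 0.0);
      }
    const double l0 = lpr_ri(0, s), l1 = lpr_ri(1, s);
    // dense main-cell count vectors, pre-permuted for each (r_i, r_c)
    double cm[4][4] = {{0, 0, 0, 0}, {0, 0, 0, 0},
                       {0, 0, 0, 0}, {0, 0, 0, 0}};
    for (int c = from; c < to; ++c) {
      const int code = main_code[c];
      const double n = main_cnt[c];
      cm[0][code] += n;            // (r_i, r_c) = (0, 0)
      cm[1][code ^ 1] += n;        // (0, 1): flip q bit
      cm[2][code ^ 2] += n;        // (1, 0): flip p bit
      cm[3][code ^ 3] += n;        // (1, 1)
    }
    for (int v = 0; v < E1; ++v)
      for (int rc = 0; rc < 2; ++rc) {
        const double bv = b[v * 2 + rc] + const_b;
        const double *c0 = cm[rc];          // r_i = 0
        const double *c1 = cm[2 | rc];      // r_i = 1
        double best = R_NegInf;
        for (int u = 0; u < E1; ++u) {
          const double *base = &lp00[((size_t)u * E1 + v) * 4];
          const double d0 = c0[0] * base[0] + c0[1] * base[1] +
                            c0[2] * base[2] + c0[3] * base[3];
          const double d1 = c1[0] * base[0] + c1[1] * base[1] +
                            c1[2] * base[2] + c1[3] * base[3];
          const double t = lse2(d0 + a[u * 2 + 0] + l0,
                                d1 + a[u * 2 + 1] + l1);
          if (t > best) best = t;
        }
        acc[((size_t)w * E1 + v) * 2 + rc] += best + bv;
      }
  }

  double total = 0.0;
  for (int w = 0; w < W; ++w) {
    double best = R_NegInf;
    for (int v = 0; v < E1; ++v) {
      const double t =
        lse2(acc[((size_t)w * E1 + v) * 2 + 0] + lpr_rc(0, w),
             acc[((size_t)w * E1 + v) * 2 + 1] + lpr_rc(1, w));
      if (t > best) best = t;
    }
    total += best;
  }
  return total;
}
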