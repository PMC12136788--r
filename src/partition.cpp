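#include <Rcpp.h>
using namespace Rcpp;

// Base-pair probabilities from a McCaskill-style inside/outside
// partition function over nested secondary structures.
//
// Energy model: a structure's Boltzmann weight is the product of its
// pair weights (exp(-E) with E in arbitrary units, temperature factor
// 1); a pair (i,j) is valid if the bases are complementary (AU, GC or
// GU wobble) and at least `minloop` unpaired bases separate them.
// No loop terms, no dangles.
//
// Bases are encoded 0=A, 1=C, 2=G, 3=U.

static inline double pair_w(int a, int b, double wAU, double wGC,
                            double wGU) {
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return wAU;
  if ((a == 1 && b == 2) || (a == 2 && b == 1)) return wGC;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return wGU;
  return 0.0;
}

// [[Rcpp::export(name = ".bpp_partition")]]
NumericVector bpp_partition(IntegerVector s, double wAU, double wGC,
                            double wGU, int minloop) {
  const int n = s.size();
  // 1-based (n+2)^2 matrices; Z(i,j)=1 for empty intervals (j < i)
  NumericMatrix Z(n + 2, n + 2), Zb(n + 2, n + 2), P(n + 2, n + 2);
  for (int i = 1; i <= n + 1; ++i)
    for (int j = 0; j <= n; ++j)
      if (j < i) Z(i, j) = 1.0;

  // inside: Zb(i,j) = w(i,j) Z(i+1,j-1) if pairable;
  //         Z(i,j)  = Z(i+1,j) + sum_k Zb(i,k) Z(k+1,j)
  for (int span = 1; span <= n; ++span) {
    for (int i = 1; i + span - 1 <= n; ++i) {
      const int j = i + span - 1;
      const double w = pair_w(s[i - 1], s[j - 1], wAU, wGC, wGU);
      if (w > 0.0 && j - i - 1 >= minloop) Zb(i, j) = w * Z(i + 1, j - 1);
      double z = Z(i + 1, j);
      for (int k = i + minloop + 1; k <= j; ++k)
        if (Zb(i, k) > 0.0) z += Zb(i, k) * Z(k + 1, j);
      Z(i, j) = z;
    }
  }
  const double Ztot = Z(1, n);

  // outside, by decreasing span. Zout(i,j) = outside weight for a pair
  // at (i,j): either no enclosing pair, or an innermost enclosing pair
  // (p,q) whose own outside is Zout(p,q).
  NumericMatrix Zout(n + 2, n + 2);
  for (int span = n; span >= minloop + 2; --span) {
    for (int i = 1; i + span - 1 <= n; ++i) {
      const int j = i + span - 1;
      if (Zb(i, j) <= 0.0) continue;
      double zo = Z(1, i - 1) * Z(j + 1, n);
      for (int p = 1; p < i; ++p) {
        for (int q = j + 1; q <= n; ++q) {
          if (Zb(p, q) > 0.0 && Zout(p, q) > 0.0) {
            const double w = pair_w(s[p - 1], s[q - 1], wAU, wGC, wGU);
            zo += w * Zout(p, q) * Z(p + 1, i - 1) * Z(j + 1, q - 1);
          }
        }
      }
      Zout(i, j) = zo;
      P(i, j) = Zb(i, j) * zo / Ztot;
    }
  }

  NumericVector p_paired(n);
  for (int i = 1; i <= n; ++i) {
    double acc = 0.0;
    for (int j = 1; j < i; ++j) acc += P(j, i);
    for (int j = i + 1; j <= n; ++j) acc += P(i, j);
    p_paired[i - 1] = acc;
  }
  return p_paired;
}
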