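#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Inside-outside computation of per-base unpaired probabilities under a
// Boltzmann ensemble of nested, pseudoknot-free secondary structures in
// which every Watson-Crick or G.U pair contributes a constant Boltzmann
// weight q, with a minimum hairpin loop of `minHairpin` unpaired bases.
//
// The structure space is generated by the unambiguous leftmost
// decomposition  S(i,j) -> i-unpaired S(i+1,j)
//                        | (i,k) S(i+1,k-1) S(k+1,j),  k >= i+minHairpin+1
// so the inside value Z(i,j) is the partition function of [i,j] and the
// outside value B(i,j) the ensemble weight of all contexts of span [i,j].
// P(i unpaired) = sum_j B(i,j) Z(i+1,j) / Z(0,n-1).
//
// Values are rescaled by s per base (Z_s = Z * s^len) to keep doubles in
// range; the caller-facing probabilities are scale-free.  The scale is
// adapted and the computation retried on over/underflow.

static inline bool canPair(int a, int b) {
  // bases: A=0, C=1, G=2, U/T=3
  int x = a < b ? a : b, y = a < b ? b : a;
  return (x == 0 && y == 3) ||   // A-U
         (x == 1 && y == 2) ||   // C-G
         (x == 2 && y == 3);     // G-U
}

// [[Rcpp::export(name = ".accessibility_unpaired")]]
NumericVector accessibility_unpaired(IntegerVector bases, double q,
                                     int minHairpin) {
  const int n = bases.size();
  NumericVector punp(n);
  if (n == 0) return punp;

  double s = n <= 150 ? 1.0 : 0.35;   // initial per-base rescale
  const int maxTries = 80;

  std::vector<double> Z((size_t)(n + 2) * (n + 2));
  std::vector<double> B((size_t)(n + 2) * (n + 2));
  // index helper over i in [0,n], j in [-1,n-1] stored with +1 offset
  auto ix = [n](int i, int j) { return (size_t)i * (n + 2) + (j + 1); };

  for (int attempt = 0; attempt < maxTries; ++attempt) {
    bool overflow = false;
    std::fill(Z.begin(), Z.end(), 0.0);
    // empty spans (j < i)
    for (int i = 0; i <= n; ++i)
      for (int j = i - 1; j >= -1; --j) Z[ix(i, j)] = 1.0;

    const double qs2 = q * s * s;
    for (int len = 1; len <= n && !overflow; ++len) {
      for (int i = 0; i + len - 1 < n; ++i) {
        int j = i + len - 1;
        double z = s * Z[ix(i + 1, j)];
        for (int k = i + minHairpin + 1; k <= j; ++k) {
          if (canPair(bases[i], bases[k]))
            z += qs2 * Z[ix(i + 1, k - 1)] * Z[ix(k + 1, j)];
        }
        if (z > 1e280 || !R_finite(z)) { overflow = true; break; }
        Z[ix(i, j)] = z;
      }
    }
    double Ztot = Z[ix(0, n - 1)];
    if (overflow || Ztot > 1e250) { s *= 0.6; continue; }
    if (Ztot < 1e-250)            { s *= 1.6; continue; }

    // outside pass, spans by decreasing length
    std::fill(B.begin(), B.end(), 0.0);
    B[ix(0, n - 1)] = 1.0;
    bool bad = false;
    for (int len = n; len >= 1 && !bad; --len) {
      for (int i = 0; i + len - 1 < n; ++i) {
        int j = i + len - 1;
        double b = B[ix(i, j)];
        if (b == 0.0) continue;
        if (b > 1e280 || !R_finite(b)) { bad = true; break; }
        B[ix(i + 1, j)] += b * s;
        for (int k = i + minHairpin + 1; k <= j; ++k) {
          if (!canPair(bases[i], bases[k])) continue;
          double w = b * qs2;
          B[ix(i + 1, k - 1)] += w * Z[ix(k + 1, j)];
          B[ix(k + 1, j)] += w * Z[ix(i + 1, k - 1)];
        }
      }
    }
    if (bad) { s *= 0.8; continue; }

    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int j = i; j < n; ++j)
        acc += B[ix(i, j)] * Z[ix(i + 1, j)];
      punp[i] = s * acc / Ztot;
    }
    return punp;
  }
  stop("accessibility computation failed to find a stable rescaling");
  return punp; // not reached
}
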