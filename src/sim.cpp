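#include <Rcpp.h>
using namespace Rcpp;

// Daily Lotka-Volterra updates over a full growing season at constant
// temperature.  B0, r, K are patch x species matrices; alpha is the common
// interspecific coefficient (alpha_ii = 1 implicitly), m the daily
// background loss rate.  With a single shared alpha the interaction sum for
// species s in patch p is alpha * (sum_j B_j/K_j - B_s/K_s), giving O(S)
// work per patch and day.  Negative excursions of the Euler step are
// clamped to zero each day; biomass below extinction_threshold is zeroed at
// season end to define local presence/absence.

// [[Rcpp::export]]
NumericMatrix cpp_run_season(NumericMatrix B0, NumericMatrix r, NumericMatrix K,
                             double alpha, double m, int days,
                             double extinction_threshold) {
  const int P = B0.nrow(), S = B0.ncol();
  if (r.nrow() != P || r.ncol() != S || K.nrow() != P || K.ncol() != S)
    stop("B, r and K must have identical dimensions");
  NumericMatrix B = clone(B0);
  std::vector<double> tot(P);
  for (int d = 0; d < days; ++d) {
    std::fill(tot.begin(), tot.end(), 0.0);
    for (int s = 0; s < S; ++s) {
      const double *b = &B(0, s);
      const double *k = &K(0, s);
      for (int p = 0; p < P; ++p) tot[p] += b[p] / k[p];
    }
    for (int s = 0; s < S; ++s) {
      double *b = &B(0, s);
      const double *k = &K(0, s);
      const double *rr = &r(0, s);
      for (int p = 0; p < P; ++p) {
        const double bk = b[p] / k[p];
        const double nb =
            b[p] + rr[p] * (1.0 - bk - alpha * (tot[p] - bk)) * b[p] - m * b[p];
        b[p] = nb > 0.0 ? nb : 0.0;
      }
    }
  }
  for (int s = 0; s < S; ++s)
    for (int p = 0; p < P; ++p)
      if (B(p, s) < extinction_threshold) B(p, s) = 0.0;
  return B;
}

// Deterministic seed redistribution: arriving[j, s] = sum_i seeds[i, s] *
// D[i, j, s] with one P x P arrival-probability matrix per species (stored
// as a P*P*S array).  Row sums of D may be < 1: seeds crossing the open
// landscape boundary are lost.

// [[Rcpp::export]]
NumericMatrix cpp_disperse(NumericMatrix seeds, NumericVector Dcube) {
  const int P = seeds.nrow(), S = seeds.ncol();
  if ((R_xlen_t)P * P * S != Dcube.size())
    stop("dispersal array dimensions do not match the seed matrix");
  NumericMatrix arriving(P, S);
  const double *D = Dcube.begin();
  for (int s = 0; s < S; ++s) {
    const double *seed = &seeds(0, s);
    const double *Ds = D + (R_xlen_t)s * P * P;
    double *arr = &arriving(0, s);
    for (int i = 0; i < P; ++i) {
      const double w = seed[i];
      if (w == 0.0) continue;
      const double *row = Ds + i;  // D[i, j, s] at row + j*P
      for (int j = 0; j < P; ++j) arr[j] += w * row[(R_xlen_t)j * P];
    }
  }
  return arriving;
}
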