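#include <Rcpp.h>
using namespace Rcpp;

// Spiking cortical model ignition counts.
//
// Per iteration n = 1..k:
//   U <- f*U + S .* (1 + beta * (W (*) Y))   (3x3 zero-padded convolution)
//   Y <- (U > Theta) ? 1 : 0                  (threshold fire)
//   Theta <- g*Theta + h*Y                    (refractory recharge)
// with U0 = 0, Y0 = 0, Theta0 = theta0. Returns the per-pixel spike total.
// [[Rcpp::export(name = ".scm_ignition_cpp")]]
IntegerMatrix scm_ignition_cpp(NumericMatrix S, double f, double g, double h,
                               double beta, NumericMatrix W, int k,
                               double theta0) {
  const int M = S.nrow(), N = S.ncol();
  std::vector<double> U(M * N, 0.0), Theta(M * N, theta0), Y(M * N, 0.0),
      conv(M * N);
  IntegerMatrix counts(M, N);
  const double *s = REAL(S);
  int *cnt = INTEGER(counts);
  // column-major: W(di+1, dj+1) applied to neighbor (i+di, j+dj)
  const double w00 = W(0, 0), w10 = W(1, 0), w20 = W(2, 0),
               w01 = W(0, 1), w11 = W(1, 1), w21 = W(2, 1),
               w02 = W(0, 2), w12 = W(1, 2), w22 = W(2, 2);

  for (int n = 0; n < k; ++n) {
    // W (*) Y with zero padding: border neurons see fewer neighbors
    for (int j = 0; j < N; ++j) {
      const double *yl = (j > 0) ? &Y[(j - 1) * M] : nullptr;
      const double *yc = &Y[j * M];
      const double *yr = (j < N - 1) ? &Y[(j + 1) * M] : nullptr;
      double *cv = &conv[j * M];
      for (int i = 0; i < M; ++i) {
        const bool up = i > 0, dn = i < M - 1;
        double acc = 0.0;
        if (yl) {
          if (up) acc += w00 * yl[i - 1];
          acc += w10 * yl[i];
          if (dn) acc += w20 * yl[i + 1];
        }
        if (up) acc += w01 * yc[i - 1];
        acc += w11 * yc[i];
        if (dn) acc += w21 * yc[i + 1];
        if (yr) {
          if (up) acc += w02 * yr[i - 1];
          acc += w12 * yr[i];
          if (dn) acc += w22 * yr[i + 1];
        }
        cv[i] = acc;
      }
    }
    for (int p = 0; p < M * N; ++p) {
      const double u = f * U[p] + s[p] * (1.0 + beta * conv[p]);
      U[p] = u;
      const double y = (u > Theta[p]) ? 1.0 : 0.0;
      Y[p] = y;
      Theta[p] = g * Theta[p] + h * y;
      if (y > 0.5) cnt[p] += 1;
    }
  }
  return counts;
}
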