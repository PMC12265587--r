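#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Expected signal for a single frame: background + midpoint-rule exposure
// integral of the defocus-broadened Gaussian PSF over K intraframe
// positions, pixel-integrated via error-function differences. Pixel index
// p = iy * npix + ix (x fastest), matching the R-side layout.
// [[Rcpp::export]]
NumericVector cpp_frame_u(NumericVector x, NumericVector y, NumericVector z,
                          int npix, double ds, double sigma_xy,
                          double sigma_z, double photon_rate, double tau,
                          double background_flux) {
  const int K = x.size();
  const int P = npix * npix;
  const double bg = background_flux * ds * ds * tau;
  NumericVector u(P, bg);
  if (photon_rate <= 0.0) return u;
  const double hk = photon_rate * tau / K;
  std::vector<double> cx(npix), cy(npix);
  for (int k = 0; k < K; ++k) {
    const double s = sigma_xy * std::sqrt(1.0 + (z[k] / sigma_z) * (z[k] / sigma_z));
    const double inv = 1.0 / (s * M_SQRT2);
    double fx_prev = 0.5 * (1.0 + std::erf((0.0 - x[k]) * inv));
    double fy_prev = 0.5 * (1.0 + std::erf((0.0 - y[k]) * inv));
    for (int i = 0; i < npix; ++i) {
      const double ex = (i + 1) * ds;
      const double fx = 0.5 * (1.0 + std::erf((ex - x[k]) * inv));
      const double fy = 0.5 * (1.0 + std::erf((ex - y[k]) * inv));
      cx[i] = fx - fx_prev;
      cy[i] = fy - fy_prev;
      fx_prev = fx;
      fy_prev = fy;
    }
    for (int iy = 0; iy < npix; ++iy) {
      const double cyk = hk * cy[iy];
      double *up = &u[iy * npix];
      for (int ix = 0; ix < npix; ++ix) up[ix] += cyk * cx[ix];
    }
  }
  return u;
}

// Gamma log-density sum for one frame's pixels:
// sum_p [ -w/scale + (shape - 1) log w - shape log scale - lgamma(shape) ]
// with shape = beta * u / 2. `logw` is precomputed log(w). Pixels with
// u == 0 are treated as a degenerate point mass at w == 0 (contribute 0
// when w == 0, -Inf otherwise).
// [[Rcpp::export]]
double cpp_gamma_loglik(NumericVector w, NumericVector logw, NumericVector u,
                        double beta, double scale) {
  const int P = w.size();
  const double ls = std::log(scale);
  double acc = 0.0;
  for (int p = 0; p < P; ++p) {
    const double k = 0.5 * beta * u[p];
    if (k <= 0.0) {
      if (w[p] != 0.0) acc += R_NegInf;
      continue;
    }
    acc += -w[p] / scale + (k - 1.0) * logw[p] - k * ls - R::lgammafn(k);
  }
  return acc;
}
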