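#include <Rcpp.h>
#include <complex>
#include <vector>
using namespace Rcpp;

typedef std::complex<double> cd;

// Specular reflectivity of a slab stack by the Parratt recursion with
// Nevot-Croce roughness factors. Units: q in 1/Angstrom, thickness d in
// Angstrom, scattering length densities rho in 1/Angstrom^2 (e.g. 6.4e-6).
// sigma has length n_layers + 1 (one value per interface, fronting|1 ...
// n|backing). Media are non-absorbing, so each kz is either purely real
// or purely imaginary; that structure is exploited for speed.
// [[Rcpp::export]]
NumericVector abeles_cpp(NumericVector q, NumericVector d, NumericVector rho,
                         double rho_front, double rho_back,
                         NumericVector sigma) {
  const int nq = q.size(), nl = d.size();
  if (sigma.size() != nl + 1) stop("sigma must have length(d) + 1");
  if (rho.size() != nl) stop("rho must have the same length as d");
  NumericVector R(nq);
  std::vector<double> four_pi_drho(nl + 1);
  for (int m = 0; m < nl; ++m)
    four_pi_drho[m] = 4.0 * M_PI * (rho[m] - rho_front);
  four_pi_drho[nl] = 4.0 * M_PI * (rho_back - rho_front);
  // kz stored as (re, im): each is purely real or purely imaginary
  std::vector<double> kre(nl + 2), kim(nl + 2);
  for (int i = 0; i < nq; ++i) {
    const double k0 = q[i] / 2.0;
    const double k0sq = k0 * k0;
    kre[0] = k0; kim[0] = 0.0;
    for (int m = 0; m <= nl; ++m) {
      const double arg = k0sq - four_pi_drho[m];
      if (arg >= 0.0) { kre[m + 1] = std::sqrt(arg); kim[m + 1] = 0.0; }
      else            { kre[m + 1] = 0.0; kim[m + 1] = std::sqrt(-arg); }
    }
    double Xr = 0.0, Xi = 0.0;
    for (int j = nl; j >= 0; --j) {
      const double ar = kre[j] - kre[j + 1], ai = kim[j] - kim[j + 1];
      const double br = kre[j] + kre[j + 1], bi = kim[j] + kim[j + 1];
      const double bn = br * br + bi * bi;
      double rr = (ar * br + ai * bi) / bn;   // rj = (k1-k2)/(k1+k2)
      double ri = (ai * br - ar * bi) / bn;
      if (sigma[j] != 0.0) {
        // Nevot-Croce: rj *= exp(-2 k1 k2 sigma^2)
        const double pr = kre[j] * kre[j + 1] - kim[j] * kim[j + 1];
        const double pi_ = kre[j] * kim[j + 1] + kim[j] * kre[j + 1];
        const double s2 = -2.0 * sigma[j] * sigma[j];
        const double mag = std::exp(s2 * pr);
        const double cr = mag * std::cos(s2 * pi_);
        const double ci = mag * std::sin(s2 * pi_);
        const double t1 = rr * cr - ri * ci;
        ri = rr * ci + ri * cr; rr = t1;
      }
      if (j == nl) {
        Xr = rr; Xi = ri;
      } else {
        // phase factor exp(2 i kz d) for layer j+1 (kz real or imaginary)
        double phr, phi_;
        if (kim[j + 1] == 0.0) {
          const double t = 2.0 * kre[j + 1] * d[j];
          phr = std::cos(t); phi_ = std::sin(t);
        } else {
          phr = std::exp(-2.0 * kim[j + 1] * d[j]); phi_ = 0.0;
        }
        const double Xpr = Xr * phr - Xi * phi_;
        const double Xpi = Xr * phi_ + Xi * phr;
        const double nr = rr + Xpr, ni = ri + Xpi;          // numerator
        const double dr = 1.0 + rr * Xpr - ri * Xpi;        // denominator
        const double di = rr * Xpi + ri * Xpr;
        const double dn = dr * dr + di * di;
        Xr = (nr * dr + ni * di) / dn;
        Xi = (ni * dr - nr * di) / dn;
      }
    }
    const double RR = Xr * Xr + Xi * Xi;
    R[i] = RR > 1.0 ? 1.0 : RR;  // Nevot-Croce can overshoot at the edge
  }
  return R;
}

// Gaussian resolution smearing: averages Rex (tabulated on the ascending
// grid qex) over a Gaussian of standard deviation sig[i] centred on q[i],
// with 21 nodes across +/- 3 sigma, linear interpolation, and one-sided
// renormalization where the kernel leaves the tabulated range.
// [[Rcpp::export]]
NumericVector gauss_smear_cpp(NumericVector qex, NumericVector Rex,
                              NumericVector q, NumericVector sig) {
  const int nq = q.size(), nx = qex.size(), nn = 21;
  NumericVector out(nq);
  double t[nn], w[nn];
  for (int j = 0; j < nn; ++j) {
    t[j] = -3.0 + 6.0 * j / (nn - 1);
    w[j] = std::exp(-0.5 * t[j] * t[j]);
  }
  const double qlo = qex[0], qhi = qex[nx - 1];
  for (int i = 0; i < nq; ++i) {
    if (sig[i] <= 0.0) {
      // no smearing: interpolate directly
      int k = std::upper_bound(qex.begin(), qex.end(), q[i]) - qex.begin();
      if (k <= 0) { out[i] = Rex[0]; continue; }
      if (k >= nx) { out[i] = Rex[nx - 1]; continue; }
      double f = (q[i] - qex[k - 1]) / (qex[k] - qex[k - 1]);
      out[i] = (1 - f) * Rex[k - 1] + f * Rex[k];
      continue;
    }
    double num = 0.0, den = 0.0;
    for (int j = 0; j < nn; ++j) {
      const double qq = q[i] + sig[i] * t[j];
      if (qq < qlo || qq > qhi) continue;
      int k = std::upper_bound(qex.begin(), qex.end(), qq) - qex.begin();
      if (k <= 0) k = 1;
      if (k >= nx) k = nx - 1;
      const double f = (qq - qex[k - 1]) / (qex[k] - qex[k - 1]);
      num += w[j] * ((1 - f) * Rex[k - 1] + f * Rex[k]);
      den += w[j];
    }
    out[i] = den > 0 ? num / den : NA_REAL;
  }
  return out;
}
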