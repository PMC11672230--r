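#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>
using namespace Rcpp;

typedef std::complex<double> cplx;

// exp(z) avoiding the general complex path when z is purely real or
// purely imaginary (the common cases for lossless layers).
static inline cplx cexp_fast(const cplx& z) {
  if (z.imag() == 0.0) return cplx(std::exp(z.real()), 0.0);
  if (z.real() == 0.0) return cplx(std::cos(z.imag()), std::sin(z.imag()));
  const double m = std::exp(z.real());
  return cplx(m * std::cos(z.imag()), m * std::sin(z.imag()));
}

// a / b without the overflow-guard scaling of std::complex division
// (magnitudes here are O(1)).
static inline cplx cdiv_fast(const cplx& a, const cplx& b) {
  const double d = b.real() * b.real() + b.imag() * b.imag();
  return cplx((a.real() * b.real() + a.imag() * b.imag()) / d,
              (a.imag() * b.real() - a.real() * b.imag()) / d);
}

// Specular neutron reflectivity of a stratified medium by the optical
// (Abeles) transfer-matrix method with Nevot-Croce roughness damping.
//
// q     : momentum transfer grid, 1/Angstrom
// sld   : real scattering length densities, 1/Angstrom^2, length
//         n_layers = n_slabs + 2 ordered fronting -> backing
// thick : layer thicknesses, Angstrom; entries for fronting and backing
//         (first and last) are ignored (semi-infinite media)
// rough : Gaussian interfacial widths sigma, Angstrom; rough[j] belongs to
//         the interface between layer j and layer j+1 (length n_layers - 1)
//
// Returns |r|^2 clipped to [0, 1] (clipping only removes ~1e-16 numerical
// overshoot in the total-reflection regime).
// [[Rcpp::export]]
NumericVector abeles_kernel(NumericVector q, NumericVector sld,
                            NumericVector thick, NumericVector rough) {
  const int nl = sld.size();
  const int nq = q.size();
  if (nl < 2) stop("need at least fronting and backing layers");
  if (thick.size() != nl) stop("thick must have one entry per layer");
  if (rough.size() != nl - 1) stop("rough must have one entry per interface");
  for (int j = 1; j < nl - 1; ++j)
    if (thick[j] < 0.0) stop("negative layer thickness");

  NumericVector out(nq);
  const double fourpi = 4.0 * M_PI;
  std::vector<double> dk2(nl);  // 4*pi*(rho_j - rho_fronting)
  for (int j = 0; j < nl; ++j) dk2[j] = fourpi * (sld[j] - sld[0]);

  for (int iq = 0; iq < nq; ++iq) {
    const double q2 = 0.25 * q[iq] * q[iq];  // (Q/2)^2, fronting kz^2
    cplx M00(1.0, 0.0), M01(0.0, 0.0), M10(0.0, 0.0), M11(1.0, 0.0);
    cplx kprev(std::sqrt(q2), 0.0);
    for (int j = 1; j < nl; ++j) {
      const double kk = q2 - dk2[j];
      // non-negative imaginary part keeps the decaying (evanescent) branch
      const cplx kj = (kk >= 0.0) ? cplx(std::sqrt(kk), 0.0)
                                  : cplx(0.0, std::sqrt(-kk));
      cplx r = cdiv_fast(kprev - kj, kprev + kj);
      const double s = rough[j - 1];
      if (s > 0.0) r *= cexp_fast(-2.0 * kprev * kj * (s * s));
      cplx eb(1.0, 0.0), ebi(1.0, 0.0);
      if (j > 1 && thick[j - 1] > 0.0) {
        eb = cexp_fast(cplx(0.0, 1.0) * kprev * thick[j - 1]);
        ebi = cdiv_fast(cplx(1.0, 0.0), eb);
      }
      const cplx a00 = eb, a01 = r * eb, a10 = r * ebi, a11 = ebi;
      const cplx n00 = M00 * a00 + M01 * a10;
      const cplx n01 = M00 * a01 + M01 * a11;
      const cplx n10 = M10 * a00 + M11 * a10;
      const cplx n11 = M10 * a01 + M11 * a11;
      M00 = n00; M01 = n01; M10 = n10; M11 = n11;
      kprev = kj;
    }
    double rr = std::norm(cdiv_fast(M10, M00));
    if (rr > 1.0) rr = 1.0;
    if (rr < 0.0) rr = 0.0;
    out[iq] = rr;
  }
  return out;
}
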