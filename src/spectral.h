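#ifndef SKULLWAVE_SPECTRAL_H
#define SKULLWAVE_SPECTRAL_H

#include "fft_core.h"
#include <vector>
#include <cmath>

namespace skw {

// angular wavenumbers for an n-point dimension with spacing dx (FFT order)
inline std::vector<double> k_angular(int n, double dx) {
  std::vector<double> k(n);
  const double dk = 2.0 * M_PI / (n * dx);
  for (int i = 0; i < n; ++i) {
    int f = (i <= n / 2) ? i : i - n;
    k[i] = f * dk;
  }
  // for even n the Nyquist component is its own conjugate partner; keep +k
  if (n % 2 == 0) k[n / 2] = (n / 2) * dk;
  return k;
}

// spectral derivative multipliers i*k*exp(+/- i k dx/2) (staggered shift)
inline void deriv_ops(const std::vector<double>& k, double dx,
                      std::vector<cplx>& pos, std::vector<cplx>& neg) {
  const int n = (int)k.size();
  pos.resize(n); neg.resize(n);
  for (int i = 0; i < n; ++i) {
    cplx ik(0.0, k[i]);
    cplx sh(std::cos(0.5 * k[i] * dx), std::sin(0.5 * k[i] * dx));
    pos[i] = ik * sh;
    neg[i] = ik * std::conj(sh);
  }
  // zero the Nyquist derivative (odd part unrepresentable on the grid)
  if (n % 2 == 0) { pos[n / 2] = cplx(0, 0); neg[n / 2] = cplx(0, 0); }
}

// k-space temporal correction sinc(c_ref |k| dt / 2), full 3-D field
inline std::vector<double> kappa_field(const std::vector<double>& kx,
                                       const std::vector<double>& ky,
                                       const std::vector<double>& kz,
                                       double c_ref, double dt) {
  const int n1 = (int)kx.size(), n2 = (int)ky.size(), n3 = (int)kz.size();
  std::vector<double> kap((size_t)n1 * n2 * n3);
  size_t idx = 0;
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2) {
      const double kyz2 = ky[i2] * ky[i2] + kz[i3] * kz[i3];
      for (int i1 = 0; i1 < n1; ++i1, ++idx) {
        const double kk = std::sqrt(kx[i1] * kx[i1] + kyz2);
        const double a = 0.5 * c_ref * kk * dt;
        kap[idx] = (a < 1e-12) ? 1.0 : std::sin(a) / a;
      }
    }
  return kap;
}

// quartic PML attenuation factors exp(-alpha dt/2), regular and staggered
inline void pml_profiles(int n, int pml, double alpha_max, double c_ref,
                         double dx, double dt,
                         std::vector<double>& reg, std::vector<double>& sg) {
  reg.assign(n, 1.0); sg.assign(n, 1.0);
  if (pml <= 0 || n < 2 * pml + 2) return;
  const double scale = alpha_max * c_ref / dx;
  for (int i = 0; i < n; ++i) {
    double dl = (pml - i) / (double)pml;           // distance into left layer
    double dr = (i - (n - 1 - pml)) / (double)pml; // into right layer
    double dls = (pml - i - 0.5) / (double)pml;
    double drs = (i + 0.5 - (n - 1 - pml)) / (double)pml;
    double a = 0.0, as = 0.0;
    if (dl > 0) a += scale * dl * dl * dl * dl;
    if (dr > 0) a += scale * dr * dr * dr * dr;
    if (dls > 0) as += scale * dls * dls * dls * dls;
    if (drs > 0) as += scale * drs * drs * drs * drs;
    reg[i] = std::exp(-a * dt / 2.0);
    sg[i] = std::exp(-as * dt / 2.0);
  }
}

// unpack spectrum of (a + i b) with a, b real into Fa, Fb
inline void unpack_herm(const cplx* z, int n1, int n2, int n3,
                        cplx* fa, cplx* fb) {
  const size_t n = (size_t)n1 * n2 * n3;
  std::vector<int> r1(n1), r2(n2), r3(n3);
  for (int i = 0; i < n1; ++i) r1[i] = (n1 - i) % n1;
  for (int i = 0; i < n2; ++i) r2[i] = (n2 - i) % n2;
  for (int i = 0; i < n3; ++i) r3[i] = (n3 - i) % n3;
  size_t idx = 0;
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2) {
      const size_t roff = (size_t)r3[i3] * n1 * n2 + (size_t)r2[i2] * n1;
      for (int i1 = 0; i1 < n1; ++i1, ++idx) {
        const cplx zr = std::conj(z[roff + r1[i1]]);
        fa[idx] = 0.5 * (z[idx] + zr);
        fb[idx] = cplx(0, -0.5) * (z[idx] - zr);
      }
    }
  (void)n;
}

} // namespace skw

#endif
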