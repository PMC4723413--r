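// Hot numerical kernels used by the source and metrics modules:
//  - monopole superposition (the discretized Rayleigh integral)
//  - band-limited (zero-padded spectral) upsampling of a 3-D field
//  - a direct interface to the internal 3-D FFT (exercised by the test suite)

#include <Rcpp.h>
#include "spectral.h"

using namespace Rcpp;
using skw::cplx;

// Sum of monopole terms amp_j * exp(i k r) / r over sources, evaluated at
// each field point.  Rayleigh/Huygens prefactors are folded into amp by the
// R callers.
// [[Rcpp::export]]
ComplexVector monopole_sum_cpp(NumericMatrix src, ComplexVector amp,
                               NumericMatrix pts, double k) {
  const int nsrc = src.nrow(), npt = pts.nrow();
  if (amp.size() != nsrc) stop("amp length must match source count");
  ComplexVector out(npt);
  std::vector<double> sx(nsrc), sy(nsrc), sz(nsrc), ar(nsrc), ai(nsrc);
  for (int j = 0; j < nsrc; ++j) {
    sx[j] = src(j, 0); sy[j] = src(j, 1); sz[j] = src(j, 2);
    ar[j] = amp[j].r; ai[j] = amp[j].i;
  }
  for (int i = 0; i < npt; ++i) {
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    double accr = 0.0, acci = 0.0;
    for (int j = 0; j < nsrc; ++j) {
      const double dxd = px - sx[j], dyd = py - sy[j], dzd = pz - sz[j];
      const double r = std::sqrt(dxd * dxd + dyd * dyd + dzd * dzd);
      if (r < 1e-12) stop("field point coincides with a source point");
      const double ph = k * r, inv = 1.0 / r;
      const double c = std::cos(ph), s = std::sin(ph);
      accr += inv * (ar[j] * c - ai[j] * s);
      acci += inv * (ar[j] * s + ai[j] * c);
    }
    out[i].r = accr; out[i].i = acci;
    if (i % 4096 == 4095) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Zero-padded spectral upsampling of a real 3-D field by integer factor m
// per axis (exact for band-limited periodic data; original samples are
// preserved on the fine grid).
// [[Rcpp::export]]
NumericVector spectral_upsample_cpp(NumericVector field, IntegerVector dims,
                                    int m) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const size_t n = (size_t)n1 * n2 * n3;
  if ((size_t)field.size() != n) stop("field length does not match dims");
  if (m < 1) stop("upsampling factor must be >= 1");
  const int N1 = n1 * m, N2 = n2 * m, N3 = n3 * m;
  const size_t N = (size_t)N1 * N2 * N3;

  std::vector<cplx> a(n);
  for (size_t i = 0; i < n; ++i) a[i] = cplx(field[i], 0.0);
  skw::fft3(a.data(), n1, n2, n3, -1);

  // frequency embedding with Nyquist splitting for even dims
  std::vector<int> m1(n1), m2(n2), m3(n3);
  std::vector<double> w1(n1, 1.0), w2(n2, 1.0), w3(n3, 1.0);
  auto build = [&](int nn, int NN, std::vector<int>& mp, std::vector<double>& wp) {
    for (int i = 0; i < nn; ++i) {
      int f = (i <= nn / 2) ? i : i - nn;
      if (nn % 2 == 0 && i == nn / 2) { mp[i] = nn / 2; wp[i] = 0.5; }
      else mp[i] = (f >= 0) ? f : NN + f;
    }
  };
  build(n1, N1, m1, w1); build(n2, N2, m2, w2); build(n3, N3, m3, w3);

  std::vector<cplx> big(N, cplx(0, 0));
  size_t idx = 0;
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2)
      for (int i1 = 0; i1 < n1; ++i1, ++idx) {
        const double w = w1[i1] * w2[i2] * w3[i3];
        const size_t I = (size_t)m3[i3] * N1 * N2 + (size_t)m2[i2] * N1 + m1[i1];
        big[I] += w * a[idx];
      }
  // enforce conjugate symmetry for the Nyquist-split bins: for real input
  // it is sufficient to also populate the mirrored negative bins
  if (n1 % 2 == 0 || n2 % 2 == 0 || n3 % 2 == 0) {
    idx = 0;
    for (int i3 = 0; i3 < n3; ++i3)
      for (int i2 = 0; i2 < n2; ++i2)
        for (int i1 = 0; i1 < n1; ++i1, ++idx) {
          const bool ny1 = (n1 % 2 == 0 && i1 == n1 / 2);
          const bool ny2 = (n2 % 2 == 0 && i2 == n2 / 2);
          const bool ny3 = (n3 % 2 == 0 && i3 == n3 / 2);
          if (!(ny1 || ny2 || ny3)) continue;
          const double w = w1[i1] * w2[i2] * w3[i3];
          // distribute over all +/- Nyquist combinations
          int c1 = ny1 ? 2 : 1, c2 = ny2 ? 2 : 1, c3 = ny3 ? 2 : 1;
          for (int b1 = 0; b1 < c1; ++b1)
            for (int b2 = 0; b2 < c2; ++b2)
              for (int b3 = 0; b3 < c3; ++b3) {
                if (b1 == 0 && b2 == 0 && b3 == 0) continue; // already placed
                size_t I1 = ny1 && b1 ? (size_t)(N1 - n1 / 2) : (size_t)m1[i1];
                size_t I2 = ny2 && b2 ? (size_t)(N2 - n2 / 2) : (size_t)m2[i2];
                size_t I3 = ny3 && b3 ? (size_t)(N3 - n3 / 2) : (size_t)m3[i3];
                big[I3 * N1 * N2 + I2 * N1 + I1] += w * a[idx];
              }
        }
  }

  skw::fft3(big.data(), N1, N2, N3, 1);
  // the inverse normalizes by the fine-grid size; interpolation requires
  // normalization by the coarse-grid size
  const double scale = (double)m * m * m;
  NumericVector out(N);
  for (size_t i = 0; i < N; ++i) out[i] = big[i].real() * scale;
  return out;
}

// Separable Catmull-Rom (cubic) upsampling of a real 3-D field by integer
// factor m per axis.  Interpolates through the samples without the spectral
// ringing that a zero-padded FFT produces on non-band-limited data such as
// max-pressure envelopes; edges are clamped.
// [[Rcpp::export]]
NumericVector cubic_upsample_cpp(NumericVector field, IntegerVector dims,
                                 int m) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  if (m < 1) stop("upsampling factor must be >= 1");
  auto upsample_dim = [&](const std::vector<double>& in, int len, int nb,
                          long estride, long bstride, std::vector<double>& out,
                          long oestride, long obstride) {
    // precompute kernel weights for the m sub-offsets
    std::vector<double> w((size_t)m * 4);
    for (int f = 0; f < m; ++f) {
      const double t = (double)f / m;
      w[f * 4 + 0] = 0.5 * (-t + 2 * t * t - t * t * t);
      w[f * 4 + 1] = 0.5 * (2 - 5 * t * t + 3 * t * t * t);
      w[f * 4 + 2] = 0.5 * (t + 4 * t * t - 3 * t * t * t);
      w[f * 4 + 3] = 0.5 * (-t * t + t * t * t);
    }
    for (int b = 0; b < nb; ++b) {
      const double* src = in.data() + (size_t)b * bstride;
      double* dst = out.data() + (size_t)b * obstride;
      for (int i = 0; i < len; ++i) {
        const int im1 = i > 0 ? i - 1 : 0;
        const int ip1 = i + 1 < len ? i + 1 : len - 1;
        const int ip2 = i + 2 < len ? i + 2 : len - 1;
        const double a = src[(size_t)im1 * estride],
                     bb = src[(size_t)i * estride],
                     c = src[(size_t)ip1 * estride],
                     d = src[(size_t)ip2 * estride];
        for (int f = 0; f < m; ++f) {
          const double* wf = w.data() + f * 4;
          dst[(size_t)(i * m + f) * oestride] =
              wf[0] * a + wf[1] * bb + wf[2] * c + wf[3] * d;
        }
      }
    }
  };
  const int N1 = n1 * m;
  std::vector<double> a(field.begin(), field.end());
  // dim 1: batches are the n2*n3 pencils
  std::vector<double> b1((size_t)N1 * n2 * n3);
  upsample_dim(a, n1, n2 * n3, 1, n1, b1, 1, N1);
  // dim 2: for each k3 slab, pencils along dim2 with stride N1
  const int N2 = n2 * m;
  std::vector<double> b2((size_t)N1 * N2 * n3);
  for (int k3 = 0; k3 < n3; ++k3) {
    std::vector<double> slab(b1.begin() + (size_t)k3 * N1 * n2,
                             b1.begin() + (size_t)(k3 + 1) * N1 * n2);
    std::vector<double> oslab((size_t)N1 * N2);
    upsample_dim(slab, n2, N1, N1, 1, oslab, N1, 1);
    std::copy(oslab.begin(), oslab.end(), b2.begin() + (size_t)k3 * N1 * N2);
  }
  // dim 3: pencils along dim3 with stride N1*N2
  const int N3 = n3 * m;
  NumericVector out((R_xlen_t)N1 * N2 * N3);
  std::vector<double> b3((size_t)N1 * N2 * N3);
  upsample_dim(b2, n3, N1 * N2, (long)N1 * N2, 1, b3, (long)N1 * N2, 1);
  std::copy(b3.begin(), b3.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
ComplexVector fft3_cpp(ComplexVector x, IntegerVector dims, bool inverse) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const size_t n = (size_t)n1 * n2 * n3;
  if ((size_t)x.size() != n) stop("length does not match dims");
  std::vector<cplx> a(n);
  for (size_t i = 0; i < n; ++i) a[i] = cplx(x[i].r, x[i].i);
  skw::fft3(a.data(), n1, n2, n3, inverse ? 1 : -1);
  ComplexVector out(n);
  for (size_t i = 0; i < n; ++i) { out[i].r = a[i].real(); out[i].i = a[i].imag(); }
  return out;
}

// [[Rcpp::export]]
int next_smooth_cpp(int n) { return skw::next_smooth5(n); }
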