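// Mixed-radix Stockham FFT with a tiled 3-D driver.  Written for the
// pseudospectral solvers in this package: grids are kept 5-smooth by the
// R layer (next_smooth5), though any factorization is handled (generic
// O(r^2) butterfly for primes > 5).

#include "fft_core.h"
#include <unordered_map>
#include <cmath>
#include <cstring>

namespace skw {

namespace {

const double TWO_PI = 6.283185307179586476925286766559;

struct Plan {
  int n;
  std::vector<int> radix;                  // factor per stage
  std::vector<std::vector<cplx> > tw;      // stage twiddles w_nstage^(p*j)
  std::vector<std::vector<cplx> > roots;   // DFT-r roots per stage (r*r table)
};

void factorize(int n, std::vector<int>& f) {
  while (n % 4 == 0) { f.push_back(4); n /= 4; }
  while (n % 2 == 0) { f.push_back(2); n /= 2; }
  for (int p = 3; (long)p * p <= n; p += 2)
    while (n % p == 0) { f.push_back(p); n /= p; }
  if (n > 1) f.push_back(n);
}

Plan make_plan(int n) {
  Plan pl;
  pl.n = n;
  factorize(n, pl.radix);
  int nn = n;
  for (size_t s = 0; s < pl.radix.size(); ++s) {
    int r = pl.radix[s], m = nn / r;
    std::vector<cplx> t((size_t)m * (r - 1));
    for (int p = 0; p < m; ++p)
      for (int j = 1; j < r; ++j) {
        double a = -TWO_PI * (double)p * j / nn;
        t[(size_t)p * (r - 1) + (j - 1)] = cplx(std::cos(a), std::sin(a));
      }
    pl.tw.push_back(t);
    std::vector<cplx> rt((size_t)r * r);
    for (int j = 0; j < r; ++j)
      for (int l = 0; l < r; ++l) {
        double a = -TWO_PI * (double)j * l / r;
        rt[(size_t)j * r + l] = cplx(std::cos(a), std::sin(a));
      }
    pl.roots.push_back(rt);
    nn = m;
  }
  return pl;
}

const Plan& get_plan(int n) {
  static std::unordered_map<int, Plan> cache;
  std::unordered_map<int, Plan>::iterator it = cache.find(n);
  if (it == cache.end())
    it = cache.insert(std::make_pair(n, make_plan(n))).first;
  return it->second;
}

// One Stockham DIF stage: n points, s interleaved transforms, x -> y.
void stage(const Plan& pl, int si, int n, int s, const cplx* x, cplx* y) {
  const int r = pl.radix[si];
  const int m = n / r;
  const cplx* tw = pl.tw[si].data();
  if (r == 2) {
    for (int p = 0; p < m; ++p) {
      const cplx w = tw[p];
      const cplx* x0 = x + (size_t)s * p;
      const cplx* x1 = x + (size_t)s * (p + m);
      cplx* y0 = y + (size_t)s * (2 * p);
      cplx* y1 = y + (size_t)s * (2 * p + 1);
      for (int q = 0; q < s; ++q) {
        const cplx a = x0[q], b = x1[q];
        y0[q] = a + b;
        y1[q] = (a - b) * w;
      }
    }
  } else if (r == 4) {
    for (int p = 0; p < m; ++p) {
      const cplx w1 = tw[p * 3], w2 = tw[p * 3 + 1], w3 = tw[p * 3 + 2];
      const cplx* x0 = x + (size_t)s * p;
      const cplx* x1 = x + (size_t)s * (p + m);
      const cplx* x2 = x + (size_t)s * (p + 2 * m);
      const cplx* x3 = x + (size_t)s * (p + 3 * m);
      cplx* yp = y + (size_t)s * (4 * p);
      for (int q = 0; q < s; ++q) {
        const cplx a = x0[q], b = x1[q], c = x2[q], d = x3[q];
        const cplx apc = a + c, amc = a - c;
        const cplx bpd = b + d;
        const cplx jbmd = cplx(std::imag(b) - std::imag(d),
                               std::real(d) - std::real(b)); // -i*(b-d)
        yp[q] = apc + bpd;
        yp[q + (size_t)s] = (amc + jbmd) * w1;
        yp[q + (size_t)s * 2] = (apc - bpd) * w2;
        yp[q + (size_t)s * 3] = (amc - jbmd) * w3;
      }
    }
  } else if (r == 3) {
    const double s3 = 0.86602540378443864676; // sin(pi/3)
    for (int p = 0; p < m; ++p) {
      const cplx w1 = tw[p * 2], w2 = tw[p * 2 + 1];
      const cplx* x0 = x + (size_t)s * p;
      const cplx* x1 = x + (size_t)s * (p + m);
      const cplx* x2 = x + (size_t)s * (p + 2 * m);
      cplx* yp = y + (size_t)s * (3 * p);
      for (int q = 0; q < s; ++q) {
        const cplx a = x0[q], b = x1[q], c = x2[q];
        const cplx u = b + c;
        const cplx v = a - 0.5 * u;
        const cplx d = b - c;
        const cplx jd(s3 * std::imag(d), -s3 * std::real(d)); // -i*s3*d
        yp[q] = a + u;
        yp[q + (size_t)s] = (v + jd) * w1;
        yp[q + (size_t)s * 2] = (v - jd) * w2;
      }
    }
  } else if (r == 5) {
    // radix-5 butterfly with the standard cyclotomic constants
    const double c1 = 0.30901699437494742410;  // cos(2pi/5)
    const double c2 = -0.80901699437494742410; // cos(4pi/5)
    const double s1 = 0.95105651629515357212;  // sin(2pi/5)
    const double s2 = 0.58778525229247312917;  // sin(4pi/5)
    for (int p = 0; p < m; ++p) {
      const cplx* xp[5];
      for (int j = 0; j < 5; ++j) xp[j] = x + (size_t)s * (p + (size_t)m * j);
      cplx* yp = y + (size_t)s * (5 * p);
      const cplx* twp = tw + (size_t)p * 4;
      for (int q = 0; q < s; ++q) {
        const cplx a0 = xp[0][q], a1 = xp[1][q], a2 = xp[2][q],
                   a3 = xp[3][q], a4 = xp[4][q];
        const cplx t1 = a1 + a4, t2 = a2 + a3;
        const cplx t3 = a1 - a4, t4 = a2 - a3;
        const cplx m1 = a0 + c1 * t1 + c2 * t2;
        const cplx m2 = a0 + c2 * t1 + c1 * t2;
        const cplx m3 = s1 * t3 + s2 * t4;
        const cplx m4 = s2 * t3 - s1 * t4;
        const cplx jm3(std::imag(m3), -std::real(m3)); // -i*m3
        const cplx jm4(std::imag(m4), -std::real(m4));
        yp[q] = a0 + t1 + t2;
        yp[q + (size_t)s] = (m1 + jm3) * twp[0];
        yp[q + (size_t)s * 2] = (m2 + jm4) * twp[1];
        yp[q + (size_t)s * 3] = (m2 - jm4) * twp[2];
        yp[q + (size_t)s * 4] = (m1 - jm3) * twp[3];
      }
    }
  } else {
    const cplx* rt = pl.roots[si].data();
    std::vector<cplx> t(r);
    for (int p = 0; p < m; ++p) {
      for (int q = 0; q < s; ++q) {
        for (int j = 0; j < r; ++j) t[j] = x[q + (size_t)s * (p + (size_t)m * j)];
        // DFT-r
        for (int j = 0; j < r; ++j) {
          cplx acc = t[0];
          for (int l = 1; l < r; ++l) acc += t[l] * rt[(size_t)j * r + l];
          if (j > 0) acc *= tw[(size_t)p * (r - 1) + (j - 1)];
          y[q + (size_t)s * ((size_t)r * p + j)] = acc;
        }
      }
    }
  }
}

// Full transform of nb interleaved sequences of length n living contiguously
// in buf as buf[b + nb*i]; work must hold n*nb.  Forward sign only; inverse
// handled by the callers via conjugation.
void stockham(int n, int nb, cplx* buf, cplx* work) {
  if (n == 1) return;
  const Plan& pl = get_plan(n);
  cplx* x = buf;
  cplx* y = work;
  int nn = n, s = nb;
  for (size_t si = 0; si < pl.radix.size(); ++si) {
    stage(pl, (int)si, nn, s, x, y);
    std::swap(x, y);
    s *= pl.radix[si];
    nn /= pl.radix[si];
  }
  if (x != buf) std::memcpy(buf, x, sizeof(cplx) * (size_t)n * nb);
}

const int TILE = 16;

} // anonymous namespace

bool smooth5(int n) {
  if (n < 1) return false;
  for (int p = 2; p <= 5; ++p) while (n % p == 0) n /= p;
  return n == 1;
}

int next_smooth5(int n) {
  if (n < 1) return 1;
  while (!smooth5(n)) ++n;
  return n;
}

void fft1_batch(cplx* a, int len, int nbatch, long elem_stride,
                long batch_stride, int sign) {
  if (len == 1) {
    if (sign > 0) { /* inverse of length-1 is identity */ }
    return;
  }
  std::vector<cplx> buf((size_t)TILE * len), work((size_t)TILE * len);
  for (int t0 = 0; t0 < nbatch; t0 += TILE) {
    int nb = nbatch - t0 < TILE ? nbatch - t0 : TILE;
    // gather (outer loop over batch keeps at least one side contiguous)
    for (int b = 0; b < nb; ++b) {
      const cplx* ab = a + (size_t)(t0 + b) * batch_stride;
      for (int i = 0; i < len; ++i)
        buf[(size_t)b + (size_t)nb * i] = ab[(size_t)i * elem_stride];
    }
    if (sign > 0)
      for (size_t k = 0; k < (size_t)nb * len; ++k) buf[k] = std::conj(buf[k]);
    stockham(len, nb, buf.data(), work.data());
    if (sign > 0) {
      const double inv = 1.0 / len;
      for (size_t k = 0; k < (size_t)nb * len; ++k)
        buf[k] = std::conj(buf[k]) * inv;
    }
    // scatter
    for (int b = 0; b < nb; ++b) {
      cplx* ab = a + (size_t)(t0 + b) * batch_stride;
      for (int i = 0; i < len; ++i)
        ab[(size_t)i * elem_stride] = buf[(size_t)b + (size_t)nb * i];
    }
  }
}

void fft3(cplx* a, int n1, int n2, int n3, int sign) {
  // dim 1: pencils contiguous, one per (i2,i3)
  fft1_batch(a, n1, n2 * n3, 1, n1, sign);
  // dim 2: pencil (i1,i3): base = i1 + i3*n1*n2, stride n1
  if (n2 > 1) {
    std::vector<cplx> buf((size_t)TILE * n2), work((size_t)TILE * n2);
    for (int i3 = 0; i3 < n3; ++i3) {
      cplx* slab = a + (size_t)i3 * n1 * n2;
      fft1_batch(slab, n2, n1, n1, 1, sign);
    }
    (void)buf; (void)work;
  }
  // dim 3: pencil t in [0, n1*n2), stride n1*n2
  if (n3 > 1) fft1_batch(a, n3, n1 * n2, (long)n1 * n2, 1, sign);
}

} // namespace skw
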