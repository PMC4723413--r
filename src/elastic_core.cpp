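// Kelvin-Voigt viscoelastic pseudospectral solver (velocity-stress leapfrog,
// spectrally staggered grids, multi-axis split-field PML).  Fluid voxels are
// carried with mu = 0, so fluid/solid coupling is implicit in the maps.
// The viscous terms use the time difference of the strain-rate gradients,
// which is first-order consistent with the Kelvin-Voigt stress rate.
// No k-space temporal correction is applied (plain PSTD; CFL is kept lower
// than in the acoustic solver to compensate).

#include <Rcpp.h>
#include "spectral.h"

using namespace Rcpp;
using skw::cplx;

namespace {
struct Field {
  const double* p;
  size_t s;
  double operator[](size_t i) const { return p[i * s]; }
};
Field make_field(const NumericVector& v, size_t n) {
  Field f;
  f.p = v.begin();
  if ((size_t)v.size() == n) f.s = 1;
  else if (v.size() == 1) f.s = 0;
  else stop("medium field has length %d, expected 1 or %d", (int)v.size(), (int)n);
  return f;
}
// harmonic mean of four values; zero if any vanishes (fluid edge)
inline double hmean4(double a, double b, double c, double d) {
  if (a <= 0 || b <= 0 || c <= 0 || d <= 0) return 0.0;
  return 4.0 / (1.0 / a + 1.0 / b + 1.0 / c + 1.0 / d);
}
} // namespace

// [[Rcpp::export]]
List run_elastic_core(IntegerVector dims, double dx, double dt, int nt,
                      NumericVector lambda, NumericVector mu,
                      NumericVector chi, NumericVector eta,
                      NumericVector rho0,
                      int pml_size, double pml_alpha, double c_ref,
                      IntegerVector src_idx, NumericVector src_re,
                      NumericVector src_im, double f0, double ramp_cycles,
                      int record_start, IntegerVector sensor_idx,
                      bool shear_diag, double stop_time) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const size_t n = (size_t)n1 * n2 * n3;
  const size_t n12 = (size_t)n1 * n2;
  const double omega = 2.0 * M_PI * f0;

  Field flam = make_field(lambda, n), fmu = make_field(mu, n),
        fchi = make_field(chi, n), feta = make_field(eta, n),
        frho = make_field(rho0, n);

  std::vector<double> kx = skw::k_angular(n1, dx), ky = skw::k_angular(n2, dx),
                      kz = skw::k_angular(n3, dx);
  std::vector<cplx> dxp, dxn, dyp, dyn, dzp, dzn;
  skw::deriv_ops(kx, dx, dxp, dxn);
  skw::deriv_ops(ky, dx, dyp, dyn);
  skw::deriv_ops(kz, dx, dzp, dzn);

  std::vector<double> px, pxs, py, pys, pz, pzs;
  skw::pml_profiles(n1, n1 > 1 ? pml_size : 0, pml_alpha, c_ref, dx, dt, px, pxs);
  skw::pml_profiles(n2, n2 > 1 ? pml_size : 0, pml_alpha, c_ref, dx, dt, py, pys);
  skw::pml_profiles(n3, n3 > 1 ? pml_size : 0, pml_alpha, c_ref, dx, dt, pz, pzs);

  // staggered medium values
  auto IDX = [&](int i1, int i2, int i3) {
    return (size_t)i3 * n12 + (size_t)i2 * n1 + i1;
  };
  std::vector<double> rsgx(n), rsgy(n), rsgz(n),
      musgxy(n), musgxz(n), musgyz(n), etsgxy(n), etsgxz(n), etsgyz(n);
  {
    size_t idx = 0;
    for (int i3 = 0; i3 < n3; ++i3)
      for (int i2 = 0; i2 < n2; ++i2)
        for (int i1 = 0; i1 < n1; ++i1, ++idx) {
          const int j1 = i1 + 1 < n1 ? i1 + 1 : i1;
          const int j2 = i2 + 1 < n2 ? i2 + 1 : i2;
          const int j3 = i3 + 1 < n3 ? i3 + 1 : i3;
          rsgx[idx] = 0.5 * (frho[idx] + frho[IDX(j1, i2, i3)]);
          rsgy[idx] = 0.5 * (frho[idx] + frho[IDX(i1, j2, i3)]);
          rsgz[idx] = 0.5 * (frho[idx] + frho[IDX(i1, i2, j3)]);
          musgxy[idx] = hmean4(fmu[idx], fmu[IDX(j1, i2, i3)],
                               fmu[IDX(i1, j2, i3)], fmu[IDX(j1, j2, i3)]);
          musgxz[idx] = hmean4(fmu[idx], fmu[IDX(j1, i2, i3)],
                               fmu[IDX(i1, i2, j3)], fmu[IDX(j1, i2, j3)]);
          musgyz[idx] = hmean4(fmu[idx], fmu[IDX(i1, j2, i3)],
                               fmu[IDX(i1, i2, j3)], fmu[IDX(i1, j2, j3)]);
          etsgxy[idx] = hmean4(feta[idx], feta[IDX(j1, i2, i3)],
                               feta[IDX(i1, j2, i3)], feta[IDX(j1, j2, i3)]);
          etsgxz[idx] = hmean4(feta[idx], feta[IDX(j1, i2, i3)],
                               feta[IDX(i1, i2, j3)], feta[IDX(j1, i2, j3)]);
          etsgyz[idx] = hmean4(feta[idx], feta[IDX(i1, j2, i3)],
                               feta[IDX(i1, i2, j3)], feta[IDX(i1, j2, j3)]);
        }
  }

  // state: velocity splits, stress splits, strain-rate gradients (+previous)
  std::vector<double> uxx(n, 0), uxy(n, 0), uxz(n, 0), uyx(n, 0), uyy(n, 0),
      uyz(n, 0), uzx(n, 0), uzy(n, 0), uzz(n, 0), vx(n, 0), vy(n, 0), vz(n, 0);
  std::vector<double> sxx_x(n, 0), sxx_y(n, 0), sxx_z(n, 0), syy_x(n, 0),
      syy_y(n, 0), syy_z(n, 0), szz_x(n, 0), szz_y(n, 0), szz_z(n, 0),
      sxy_x(n, 0), sxy_y(n, 0), sxz_x(n, 0), sxz_z(n, 0), syz_y(n, 0),
      syz_z(n, 0);
  std::vector<double> gxx(n, 0), gyy(n, 0), gzz(n, 0), gxy(n, 0), gyx(n, 0),
      gxz(n, 0), gzx(n, 0), gyz(n, 0), gzy(n, 0);
  std::vector<double> hxx(n, 0), hyy(n, 0), hzz(n, 0), hxy(n, 0), hyx(n, 0),
      hxz(n, 0), hzx(n, 0), hyz(n, 0), hzy(n, 0); // previous gradients
  std::vector<double> p(n, 0.0), pmax(n, 0.0), der(n);
  std::vector<cplx> W1(n), W2(n), W3(n), Fa(n), Fb(n), Fc(n);

  const int ns = sensor_idx.size();
  NumericMatrix traces(ns > 0 ? nt : 0, ns);
  const int nsrc = src_idx.size();
  const double ramp_T = (f0 > 0 && ramp_cycles > 0) ? ramp_cycles / f0 : 0.0;
  const size_t cidx = ((size_t)(n3 / 2) * n2 + n2 / 2) * n1 + n1 / 2;

  // helper lambdas for packed spectral derivative evaluation
  auto apply_pair = [&](const std::vector<cplx>& A, const std::vector<cplx>& B,
                        const std::vector<cplx>* opA1, const std::vector<cplx>* opA2,
                        const std::vector<cplx>* opA3,
                        const std::vector<cplx>* opB1, const std::vector<cplx>* opB2,
                        const std::vector<cplx>* opB3,
                        std::vector<double>& outA, std::vector<double>& outB) {
    // out = ifft(opA .* A) and ifft(opB .* B), packed into one inverse
    size_t idx = 0;
    for (int i3 = 0; i3 < n3; ++i3)
      for (int i2 = 0; i2 < n2; ++i2)
        for (int i1 = 0; i1 < n1; ++i1, ++idx) {
          cplx a = A[idx], b = B[idx];
          if (opA1) a *= (*opA1)[i1];
          if (opA2) a *= (*opA2)[i2];
          if (opA3) a *= (*opA3)[i3];
          if (opB1) b *= (*opB1)[i1];
          if (opB2) b *= (*opB2)[i2];
          if (opB3) b *= (*opB3)[i3];
          W1[idx] = a + cplx(0, 1) * b;
        }
    skw::fft3(W1.data(), n1, n2, n3, 1);
    for (size_t i = 0; i < n; ++i) { outA[i] = W1[i].real(); outB[i] = W1[i].imag(); }
  };
  auto apply_one = [&](const std::vector<cplx>& A,
                       const std::vector<cplx>* op1, const std::vector<cplx>* op2,
                       const std::vector<cplx>* op3, std::vector<double>& outA) {
    size_t idx = 0;
    for (int i3 = 0; i3 < n3; ++i3)
      for (int i2 = 0; i2 < n2; ++i2)
        for (int i1 = 0; i1 < n1; ++i1, ++idx) {
          cplx a = A[idx];
          if (op1) a *= (*op1)[i1];
          if (op2) a *= (*op2)[i2];
          if (op3) a *= (*op3)[i3];
          W1[idx] = a;
        }
    skw::fft3(W1.data(), n1, n2, n3, 1);
    for (size_t i = 0; i < n; ++i) outA[i] = W1[i].real();
  };

  std::vector<double> d1(n), d2(n), d3(n), d4(n), d5(n), d6(n), d7(n), d8(n),
      d9(n);

  for (int step = 0; step < nt; ++step) {
    // ---- stress spectra (pack pairs of totals) ----
    for (size_t i = 0; i < n; ++i)
      W2[i] = cplx(sxx_x[i] + sxx_y[i] + sxx_z[i],
                   syy_x[i] + syy_y[i] + syy_z[i]);
    skw::fft3(W2.data(), n1, n2, n3, -1);
    skw::unpack_herm(W2.data(), n1, n2, n3, Fa.data(), Fb.data()); // sxx, syy
    for (size_t i = 0; i < n; ++i)
      W2[i] = cplx(szz_x[i] + szz_y[i] + szz_z[i], sxy_x[i] + sxy_y[i]);
    skw::fft3(W2.data(), n1, n2, n3, -1);
    skw::unpack_herm(W2.data(), n1, n2, n3, Fc.data(), W3.data()); // szz, sxy
    // d1 = dsxxdx (pos x), d2 = dsyydy (pos y)
    apply_pair(Fa, Fb, &dxp, 0, 0, 0, &dyp, 0, d1, d2);
    // d3 = dszzdz (pos z), d4 = dsxydx (neg x)
    apply_pair(Fc, W3, 0, 0, &dzp, &dxn, 0, 0, d3, d4);
    // d5 = dsxydy (neg y)  [W3 still holds sxy spectrum]
    for (size_t i = 0; i < n; ++i)
      W2[i] = cplx(sxz_x[i] + sxz_z[i], syz_y[i] + syz_z[i]);
    skw::fft3(W2.data(), n1, n2, n3, -1);
    skw::unpack_herm(W2.data(), n1, n2, n3, Fa.data(), Fb.data()); // sxz, syz
    apply_pair(W3, Fa, 0, &dyn, 0, &dxn, 0, 0, d5, d6); // d6 = dsxzdx (neg x)
    apply_pair(Fa, Fb, 0, 0, &dzn, 0, &dyn, 0, d7, d8); // d7 = dsxzdz, d8 = dsyzdy
    apply_one(Fb, 0, 0, &dzn, d9);                      // d9 = dsyzdz (neg z)
    // ---- velocity update ----
    {
      size_t idx = 0;
      for (int i3 = 0; i3 < n3; ++i3)
        for (int i2 = 0; i2 < n2; ++i2)
          for (int i1 = 0; i1 < n1; ++i1, ++idx) {
            const double ax = dt / rsgx[idx], ay = dt / rsgy[idx],
                         az = dt / rsgz[idx];
            uxx[idx] = pxs[i1] * (pxs[i1] * uxx[idx] + ax * d1[idx]);
            uxy[idx] = py[i2] * (py[i2] * uxy[idx] + ax * d5[idx]);
            uxz[idx] = pz[i3] * (pz[i3] * uxz[idx] + ax * d7[idx]);
            uyx[idx] = px[i1] * (px[i1] * uyx[idx] + ay * d4[idx]);
            uyy[idx] = pys[i2] * (pys[i2] * uyy[idx] + ay * d2[idx]);
            uyz[idx] = pz[i3] * (pz[i3] * uyz[idx] + ay * d9[idx]);
            uzx[idx] = px[i1] * (px[i1] * uzx[idx] + az * d6[idx]);
            uzy[idx] = py[i2] * (py[i2] * uzy[idx] + az * d8[idx]);
            uzz[idx] = pzs[i3] * (pzs[i3] * uzz[idx] + az * d3[idx]);
            vx[idx] = uxx[idx] + uxy[idx] + uxz[idx];
            vy[idx] = uyx[idx] + uyy[idx] + uyz[idx];
            vz[idx] = uzx[idx] + uzy[idx] + uzz[idx];
          }
    }
    // ---- velocity gradients ----
    std::swap(gxx, hxx); std::swap(gyy, hyy); std::swap(gzz, hzz);
    std::swap(gxy, hxy); std::swap(gyx, hyx); std::swap(gxz, hxz);
    std::swap(gzx, hzx); std::swap(gyz, hyz); std::swap(gzy, hzy);
    for (size_t i = 0; i < n; ++i) W2[i] = cplx(vx[i], vy[i]);
    skw::fft3(W2.data(), n1, n2, n3, -1);
    skw::unpack_herm(W2.data(), n1, n2, n3, Fa.data(), Fb.data()); // vx, vy
    for (size_t i = 0; i < n; ++i) W2[i] = cplx(vz[i], 0.0);
    skw::fft3(W2.data(), n1, n2, n3, -1);
    for (size_t i = 0; i < n; ++i) Fc[i] = W2[i]; // vz spectrum
    apply_pair(Fa, Fb, &dxn, 0, 0, 0, &dyn, 0, gxx, gyy); // dvxdx, dvydy
    apply_pair(Fc, Fa, 0, 0, &dzn, 0, &dyp, 0, gzz, gxy); // dvzdz, dvxdy
    apply_pair(Fb, Fa, &dxp, 0, 0, 0, 0, &dzp, gyx, gxz); // dvydx, dvxdz
    apply_pair(Fc, Fb, &dxp, 0, 0, 0, 0, &dzp, gzx, gyz); // dvzdx, dvydz
    apply_one(Fc, 0, &dyp, 0, gzy);                       // dvzdy
    // ---- stress update (Kelvin-Voigt) ----
    {
      const double idt = 1.0 / dt;
      size_t idx = 0;
      for (int i3 = 0; i3 < n3; ++i3)
        for (int i2 = 0; i2 < n2; ++i2)
          for (int i1 = 0; i1 < n1; ++i1, ++idx) {
            const double lam = flam[idx], m = fmu[idx];
            const double ch = fchi[idx], et = feta[idx];
            const double l2m = lam + 2.0 * m, c2e = ch + 2.0 * et;
            const double rxx = (gxx[idx] - hxx[idx]) * idt;
            const double ryy = (gyy[idx] - hyy[idx]) * idt;
            const double rzz = (gzz[idx] - hzz[idx]) * idt;
            sxx_x[idx] = px[i1] * (px[i1] * sxx_x[idx] +
                                   dt * (l2m * gxx[idx] + c2e * rxx));
            sxx_y[idx] = py[i2] * (py[i2] * sxx_y[idx] +
                                   dt * (lam * gyy[idx] + ch * ryy));
            sxx_z[idx] = pz[i3] * (pz[i3] * sxx_z[idx] +
                                   dt * (lam * gzz[idx] + ch * rzz));
            syy_x[idx] = px[i1] * (px[i1] * syy_x[idx] +
                                   dt * (lam * gxx[idx] + ch * rxx));
            syy_y[idx] = py[i2] * (py[i2] * syy_y[idx] +
                                   dt * (l2m * gyy[idx] + c2e * ryy));
            syy_z[idx] = pz[i3] * (pz[i3] * syy_z[idx] +
                                   dt * (lam * gzz[idx] + ch * rzz));
            szz_x[idx] = px[i1] * (px[i1] * szz_x[idx] +
                                   dt * (lam * gxx[idx] + ch * rxx));
            szz_y[idx] = py[i2] * (py[i2] * szz_y[idx] +
                                   dt * (lam * gyy[idx] + ch * ryy));
            szz_z[idx] = pz[i3] * (pz[i3] * szz_z[idx] +
                                   dt * (l2m * gzz[idx] + c2e * rzz));
            const double mxy = musgxy[idx], exy = etsgxy[idx];
            sxy_x[idx] = pxs[i1] * (pxs[i1] * sxy_x[idx] +
                dt * (mxy * gyx[idx] + exy * (gyx[idx] - hyx[idx]) * idt));
            sxy_y[idx] = pys[i2] * (pys[i2] * sxy_y[idx] +
                dt * (mxy * gxy[idx] + exy * (gxy[idx] - hxy[idx]) * idt));
            const double mxz = musgxz[idx], exz = etsgxz[idx];
            sxz_x[idx] = pxs[i1] * (pxs[i1] * sxz_x[idx] +
                dt * (mxz * gzx[idx] + exz * (gzx[idx] - hzx[idx]) * idt));
            sxz_z[idx] = pzs[i3] * (pzs[i3] * sxz_z[idx] +
                dt * (mxz * gxz[idx] + exz * (gxz[idx] - hxz[idx]) * idt));
            const double myz = musgyz[idx], eyz = etsgyz[idx];
            syz_y[idx] = pys[i2] * (pys[i2] * syz_y[idx] +
                dt * (myz * gzy[idx] + eyz * (gzy[idx] - hzy[idx]) * idt));
            syz_z[idx] = pzs[i3] * (pzs[i3] * syz_z[idx] +
                dt * (myz * gyz[idx] + eyz * (gyz[idx] - hyz[idx]) * idt));
          }
    }
    // ---- pressure source (isotropic stress injection) ----
    if (nsrc > 0 && (stop_time <= 0.0 || step * dt <= stop_time)) {
      const double t = step * dt;
      const double env = (ramp_T <= 0.0 || t >= ramp_T)
                             ? 1.0
                             : 0.5 * (1.0 - std::cos(M_PI * t / ramp_T));
      const double cw = std::cos(omega * t), sw = std::sin(omega * t);
      for (int j = 0; j < nsrc; ++j) {
        const size_t idx = (size_t)src_idx[j];
        const double csq = (flam[idx] + 2.0 * fmu[idx]) / frho[idx];
        const double add = -csq * dt * env * (src_re[j] * cw + src_im[j] * sw);
        sxx_x[idx] += add; syy_x[idx] += add; szz_x[idx] += add;
      }
    }
    // ---- scalar pressure, recording ----
    for (size_t i = 0; i < n; ++i)
      p[i] = -(sxx_x[i] + sxx_y[i] + sxx_z[i] + syy_x[i] + syy_y[i] +
               syy_z[i] + szz_x[i] + szz_y[i] + szz_z[i]) / 3.0;
    if (!std::isfinite(p[cidx]))
      stop("elastic solver produced a non-finite field at step %d", step + 1);
    if (step >= record_start)
      for (size_t i = 0; i < n; ++i)
        if (p[i] > pmax[i]) pmax[i] = p[i];
    for (int sjj = 0; sjj < ns; ++sjj)
      traces(step, sjj) = p[(size_t)sensor_idx[sjj]];
    if (step % 50 == 49) Rcpp::checkUserInterrupt();
  }

  double chk = 0.0;
  for (size_t i = 0; i < n; ++i) chk += pmax[i];
  if (!std::isfinite(chk))
    stop("elastic solver produced a non-finite max-pressure field");

  double e_shear = NA_REAL, e_kin_solid = NA_REAL;
  if (shear_diag) {
    // local rotational vs dilatational content of the final velocity,
    // from centred finite differences: shear waves carry |curl v| =
    // k_s |v| and zero divergence, so rho |curl v|^2 / k_s^2 and
    // rho (div v)^2 / k_p^2 are kinetic-energy equivalents.  Local
    // differences (unlike global spectral derivatives) cannot leak the
    // steep field decay inside the PML into the solid region.
    std::vector<double> cxf(n, 0.0), cyf(n, 0.0), czf(n, 0.0), dvf(n, 0.0);
    {
      auto D = [&](const std::vector<double>& f, int i1, int i2, int i3,
                   int axis) {
        int a1 = i1, b1 = i1, a2 = i2, b2 = i2, a3 = i3, b3 = i3;
        if (axis == 0) { a1 = i1 > 0 ? i1 - 1 : 0; b1 = i1 + 1 < n1 ? i1 + 1 : n1 - 1; }
        if (axis == 1) { a2 = i2 > 0 ? i2 - 1 : 0; b2 = i2 + 1 < n2 ? i2 + 1 : n2 - 1; }
        if (axis == 2) { a3 = i3 > 0 ? i3 - 1 : 0; b3 = i3 + 1 < n3 ? i3 + 1 : n3 - 1; }
        double span = dx * ((axis == 0 ? b1 - a1 : axis == 1 ? b2 - a2
                                                             : b3 - a3));
        if (span <= 0) return 0.0;
        return (f[IDX(b1, b2, b3)] - f[IDX(a1, a2, a3)]) / span;
      };
      size_t id2 = 0;
      for (int i3 = 0; i3 < n3; ++i3)
        for (int i2 = 0; i2 < n2; ++i2)
          for (int i1 = 0; i1 < n1; ++i1, ++id2) {
            cxf[id2] = D(vz, i1, i2, i3, 1) - D(vy, i1, i2, i3, 2);
            cyf[id2] = D(vx, i1, i2, i3, 2) - D(vz, i1, i2, i3, 0);
            czf[id2] = D(vy, i1, i2, i3, 0) - D(vx, i1, i2, i3, 1);
            dvf[id2] = D(vx, i1, i2, i3, 0) + D(vy, i1, i2, i3, 1) +
                       D(vz, i1, i2, i3, 2);
          }
    }
    e_shear = 0.0;
    double e_comp = 0.0;
    const double w2 = omega * omega;
    // erode the solid mask: interface voxels mix fluid and solid motion
    const int er = 4;
    std::vector<char> solid(n);
    for (size_t i = 0; i < n; ++i) solid[i] = fmu[i] > 0 ? 1 : 0;
    std::vector<char> keep(solid);
    {
      size_t id2 = 0;
      for (int i3 = 0; i3 < n3; ++i3)
        for (int i2 = 0; i2 < n2; ++i2)
          for (int i1 = 0; i1 < n1; ++i1, ++id2) {
            if (!solid[id2]) continue;
            bool ok = true;
            // the split fields inside the PML are not physical
            if (n1 >= 2 * pml_size + 2 &&
                (i1 < pml_size || i1 >= n1 - pml_size)) ok = false;
            if (n2 >= 2 * pml_size + 2 &&
                (i2 < pml_size || i2 >= n2 - pml_size)) ok = false;
            if (n3 >= 2 * pml_size + 2 &&
                (i3 < pml_size || i3 >= n3 - pml_size)) ok = false;
            for (int o = 1; o <= er && ok; ++o) {
              if (n1 > 1) {
                int a = i1 - o < 0 ? 0 : i1 - o;
                int b = i1 + o >= n1 ? n1 - 1 : i1 + o;
                if (!solid[IDX(a, i2, i3)] || !solid[IDX(b, i2, i3)]) ok = false;
              }
              if (ok && n2 > 1) {
                int a = i2 - o < 0 ? 0 : i2 - o;
                int b = i2 + o >= n2 ? n2 - 1 : i2 + o;
                if (!solid[IDX(i1, a, i3)] || !solid[IDX(i1, b, i3)]) ok = false;
              }
              if (ok && n3 > 1) {
                int a = i3 - o < 0 ? 0 : i3 - o;
                int b = i3 + o >= n3 ? n3 - 1 : i3 + o;
                if (!solid[IDX(i1, i2, a)] || !solid[IDX(i1, i2, b)]) ok = false;
              }
            }
            keep[id2] = ok ? 1 : 0;
          }
    }
    for (size_t i = 0; i < n; ++i) {
      if (!keep[i]) continue;
      const double r0 = frho[i];
      const double ks2 = w2 * r0 / fmu[i];
      const double kp2 = w2 * r0 / (flam[i] + 2.0 * fmu[i]);
      const double c2 = cxf[i] * cxf[i] + cyf[i] * cyf[i] + czf[i] * czf[i];
      e_shear += 0.5 * r0 * c2 / ks2;
      e_comp += 0.5 * r0 * dvf[i] * dvf[i] / kp2;
    }
    e_kin_solid = e_shear + e_comp;
  }

  List out = List::create(_["pmax"] = NumericVector(pmax.begin(), pmax.end()),
                          _["traces"] = traces,
                          _["p_final"] = NumericVector(p.begin(), p.end()),
                          _["shear_energy"] = e_shear,
                          _["solid_kinetic_energy"] = e_kin_solid);
  return out;
}
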