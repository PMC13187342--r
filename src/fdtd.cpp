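// Time-domain solvers for single-frequency linear acoustics.
//
// First-order pressure/velocity formulation on a staggered grid with a
// split-field PML. A continuous sinusoidal source (per-element amplitude and
// phase, shared time envelope) is ramped to steady state and the complex
// amplitude at the drive frequency is recovered by quadrature demodulation
// over an integer number of cycles at the end of the run.
//
// Absorption alpha (Np/m) enters as a pressure relaxation rate
// gamma = 2*alpha*c, which for a plane wave gives spatial decay exp(-alpha*r)
// at the drive frequency (single-frequency model, not a dispersive power law).

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static std::vector<double> pml_profile(int n, int w, double dx, double c_ref,
                                       bool half) {
  // cubic-graded absorption, zero outside the layer
  std::vector<double> sig(n, 0.0);
  if (w <= 0) return sig;
  const double m = 3.0, R = 1e-6;
  double L = w * dx;
  double smax = (m + 1.0) * c_ref * std::log(1.0 / R) / (2.0 * L);
  for (int i = 0; i < n; ++i) {
    double x = i + (half ? 0.5 : 0.0);  // position in grid units
    double d = -1.0;
    if (x < w) d = (w - x) / w;
    else if (x > n - 1 - w) d = (x - (n - 1 - w)) / w;
    if (d > 0) sig[i] = smax * std::pow(d, m);
  }
  return sig;
}

// [[Rcpp::export(name = ".fdtd2d_cw")]]
List fdtd2d_cw(NumericMatrix cmap, NumericMatrix rhomap, NumericMatrix alphamap,
               double dx, double dt, int nt,
               IntegerVector src_i, IntegerVector src_j,
               NumericVector src_amp, NumericVector src_phase,
               double f0, NumericVector envelope,
               int pml_width, int record_n, bool energy_trace) {
  const int nx = cmap.nrow(), ny = cmap.ncol();
  const double w0 = 2.0 * M_PI * f0;
  const int ns = src_i.size();

  double c_ref = 0.0;
  for (int idx = 0; idx < nx * ny; ++idx) c_ref = std::max(c_ref, cmap[idx]);

  std::vector<double> sx  = pml_profile(nx, pml_width, dx, c_ref, false);
  std::vector<double> sy  = pml_profile(ny, pml_width, dx, c_ref, false);
  std::vector<double> sxh = pml_profile(nx, pml_width, dx, c_ref, true);
  std::vector<double> syh = pml_profile(ny, pml_width, dx, c_ref, true);

  // cell-centred coefficients
  std::vector<double> kap(nx * ny), Ax(nx * ny), Ay(nx * ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int id = i + nx * j;
      double c = cmap[id], rho = rhomap[id];
      kap[id] = rho * c * c;
      double gam = 2.0 * alphamap[id] * c;
      Ax[id] = std::exp(-(sx[i] + gam) * dt);
      Ay[id] = std::exp(-(sy[j] + gam) * dt);
    }
  std::vector<double> Avx(nx), Avy(ny);
  for (int i = 0; i < nx; ++i) Avx[i] = std::exp(-sxh[i] * dt);
  for (int j = 0; j < ny; ++j) Avy[j] = std::exp(-syh[j] * dt);

  // half-point inverse densities
  std::vector<double> irhx((nx - 1) * ny), irhy(nx * (ny - 1));
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx - 1; ++i)
      irhx[i + (nx - 1) * j] =
        2.0 / (rhomap[i + nx * j] + rhomap[i + 1 + nx * j]);
  for (int j = 0; j < ny - 1; ++j)
    for (int i = 0; i < nx; ++i)
      irhy[i + nx * j] = 2.0 / (rhomap[i + nx * j] + rhomap[i + nx * (j + 1)]);

  std::vector<double> px(nx * ny, 0.0), py(nx * ny, 0.0), p(nx * ny, 0.0);
  std::vector<double> vx((nx - 1) * ny, 0.0), vy(nx * (ny - 1), 0.0);
  std::vector<double> accI(nx * ny, 0.0), accQ(nx * ny, 0.0);
  std::vector<double> p_old;
  if (energy_trace) p_old.assign(nx * ny, 0.0);
  NumericVector energy(energy_trace ? nt : 0);

  const double dtdx = dt / dx;
  const int rec_start = nt - record_n;

  for (int n = 0; n < nt; ++n) {
    // velocity update
    for (int j = 0; j < ny; ++j) {
      const double *pj = &p[nx * j];
      double *vxj = &vx[(nx - 1) * j];
      const double *ir = &irhx[(nx - 1) * j];
      for (int i = 0; i < nx - 1; ++i)
        vxj[i] = Avx[i] * vxj[i] - dtdx * ir[i] * (pj[i + 1] - pj[i]);
    }
    for (int j = 0; j < ny - 1; ++j) {
      const double *pj = &p[nx * j], *pj1 = &p[nx * (j + 1)];
      double *vyj = &vy[nx * j];
      const double *ir = &irhy[nx * j];
      double a = Avy[j];
      for (int i = 0; i < nx; ++i)
        vyj[i] = a * vyj[i] - dtdx * ir[i] * (pj1[i] - pj[i]);
    }
    if (energy_trace) p_old = p;
    // pressure update (rigid wall behind the PML: outside velocities zero)
    for (int j = 0; j < ny; ++j) {
      double *pxj = &px[nx * j], *pyj = &py[nx * j];
      const double *vxj = &vx[(nx - 1) * j];
      const double *vyl = (j > 0) ? &vy[nx * (j - 1)] : nullptr;
      const double *vyr = (j < ny - 1) ? &vy[nx * j] : nullptr;
      const double *kj = &kap[nx * j], *axj = &Ax[nx * j], *ayj = &Ay[nx * j];
      for (int i = 0; i < nx; ++i) {
        double dvx = (i < nx - 1 ? vxj[i] : 0.0) - (i > 0 ? vxj[i - 1] : 0.0);
        double dvy = (vyr ? vyr[i] : 0.0) - (vyl ? vyl[i] : 0.0);
        pxj[i] = axj[i] * pxj[i] - dtdx * kj[i] * dvx;
        pyj[i] = ayj[i] * pyj[i] - dtdx * kj[i] * dvy;
      }
    }
    // source injection (soft, additive)
    double tnow = n * dt, env = envelope[n];
    if (env != 0.0)
      for (int s = 0; s < ns; ++s)
        px[src_i[s] + nx * src_j[s]] +=
          env * src_amp[s] * std::sin(w0 * tnow - src_phase[s]);
    for (int id = 0; id < nx * ny; ++id) p[id] = px[id] + py[id];

    if (n >= rec_start) {
      double cw = std::cos(w0 * tnow), sw = std::sin(w0 * tnow);
      for (int id = 0; id < nx * ny; ++id) {
        accI[id] += p[id] * cw;
        accQ[id] += p[id] * sw;
      }
    }
    if (energy_trace) {
      // conserved staggered-leapfrog functional: potential term pairs the
      // pressure across the half-step the velocity sits on
      double E = 0.0;
      for (int id = 0; id < nx * ny; ++id)
        E += p_old[id] * p[id] / (2.0 * kap[id]);
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx - 1; ++i) {
          double v = vx[i + (nx - 1) * j];
          E += v * v / (2.0 * irhx[i + (nx - 1) * j]);
        }
      for (int j = 0; j < ny - 1; ++j)
        for (int i = 0; i < nx; ++i) {
          double v = vy[i + nx * j];
          E += v * v / (2.0 * irhy[i + nx * j]);
        }
      energy[n] = E * dx * dx;
    }
  }

  NumericMatrix re(nx, ny), im(nx, ny);
  double sc = 2.0 / record_n;
  for (int id = 0; id < nx * ny; ++id) {
    re[id] = sc * accI[id];
    im[id] = sc * accQ[id];
  }
  List out = List::create(_["re"] = re, _["im"] = im);
  if (energy_trace) out["energy"] = energy;
  return out;
}

// [[Rcpp::export(name = ".fdtd3d_cw")]]
List fdtd3d_cw(NumericVector cmap, NumericVector rhomap, NumericVector alphamap,
               IntegerVector dims, double dx, double dt, int nt,
               IntegerVector src_i, IntegerVector src_j, IntegerVector src_k,
               NumericVector src_amp, NumericVector src_phase,
               double f0, NumericVector envelope,
               int pml_width, int record_n) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long N = (long)nx * ny * nz;
  const double w0 = 2.0 * M_PI * f0;
  const int ns = src_i.size();
  auto at = [nx, ny](int i, int j, int k) -> long {
    return i + (long)nx * (j + (long)ny * k);
  };

  double c_ref = 0.0;
  for (long id = 0; id < N; ++id) c_ref = std::max(c_ref, cmap[id]);
  std::vector<double> sx = pml_profile(nx, pml_width, dx, c_ref, false);
  std::vector<double> sy = pml_profile(ny, pml_width, dx, c_ref, false);
  std::vector<double> sz = pml_profile(nz, pml_width, dx, c_ref, false);
  std::vector<double> sxh = pml_profile(nx, pml_width, dx, c_ref, true);
  std::vector<double> syh = pml_profile(ny, pml_width, dx, c_ref, true);
  std::vector<double> szh = pml_profile(nz, pml_width, dx, c_ref, true);

  std::vector<double> kap(N), gam(N);
  for (long id = 0; id < N; ++id) {
    kap[id] = rhomap[id] * cmap[id] * cmap[id];
    gam[id] = 2.0 * alphamap[id] * cmap[id];
  }

  std::vector<double> px(N, 0.0), py(N, 0.0), pz(N, 0.0), p(N, 0.0);
  std::vector<double> vx(N, 0.0), vy(N, 0.0), vz(N, 0.0);  // v*(i+1/2 ...)
  std::vector<double> accI(N, 0.0), accQ(N, 0.0);

  const double dtdx = dt / dx;
  const int rec_start = nt - record_n;

  for (int n = 0; n < nt; ++n) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          long id = at(i, j, k);
          if (i < nx - 1)
            vx[id] = std::exp(-sxh[i] * dt) * vx[id] -
              dtdx * 2.0 / (rhomap[id] + rhomap[at(i + 1, j, k)]) *
              (p[at(i + 1, j, k)] - p[id]);
          if (j < ny - 1)
            vy[id] = std::exp(-syh[j] * dt) * vy[id] -
              dtdx * 2.0 / (rhomap[id] + rhomap[at(i, j + 1, k)]) *
              (p[at(i, j + 1, k)] - p[id]);
          if (k < nz - 1)
            vz[id] = std::exp(-szh[k] * dt) * vz[id] -
              dtdx * 2.0 / (rhomap[id] + rhomap[at(i, j, k + 1)]) *
              (p[at(i, j, k + 1)] - p[id]);
        }
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          long id = at(i, j, k);
          double dvx = (i < nx - 1 ? vx[id] : 0.0) -
                       (i > 0 ? vx[at(i - 1, j, k)] : 0.0);
          double dvy = (j < ny - 1 ? vy[id] : 0.0) -
                       (j > 0 ? vy[at(i, j - 1, k)] : 0.0);
          double dvz = (k < nz - 1 ? vz[id] : 0.0) -
                       (k > 0 ? vz[at(i, j, k - 1)] : 0.0);
          px[id] = std::exp(-(sx[i] + gam[id]) * dt) * px[id] -
                   dtdx * kap[id] * dvx;
          py[id] = std::exp(-(sy[j] + gam[id]) * dt) * py[id] -
                   dtdx * kap[id] * dvy;
          pz[id] = std::exp(-(sz[k] + gam[id]) * dt) * pz[id] -
                   dtdx * kap[id] * dvz;
        }
    double tnow = n * dt, env = envelope[n];
    if (env != 0.0)
      for (int s = 0; s < ns; ++s)
        px[at(src_i[s], src_j[s], src_k[s])] +=
          env * src_amp[s] * std::sin(w0 * tnow - src_phase[s]);
    for (long id = 0; id < N; ++id) p[id] = px[id] + py[id] + pz[id];
    if (n >= rec_start) {
      double cw = std::cos(w0 * tnow), sw = std::sin(w0 * tnow);
      for (long id = 0; id < N; ++id) {
        accI[id] += p[id] * cw;
        accQ[id] += p[id] * sw;
      }
    }
  }

  NumericVector re(N), im(N);
  double sc = 2.0 / record_n;
  for (long id = 0; id < N; ++id) {
    re[id] = sc * accI[id];
    im[id] = sc * accQ[id];
  }
  re.attr("dim") = dims;
  im.attr("dim") = dims;
  return List::create(_["re"] = re, _["im"] = im);
}

// Explicit Pennes bioheat stepper, 2D, zero-flux boundaries.
// rhoC dT/dt = div(k grad T) + q(t)*Q - wterm*T  with T the rise above
// arterial baseline; q(t) gates the source on for `on_time` out of every
// `period` seconds when `gated` (train-resolved mode), else stays 1.
// [[Rcpp::export(name = ".bioheat2d")]]
List bioheat2d(NumericMatrix kmap, NumericMatrix rhoC, NumericMatrix wterm,
               NumericMatrix Q, NumericMatrix T0,
               double dx, double dt, int nt,
               bool gated, double on_time, double period,
               int trace_i, int trace_j) {
  const int nx = kmap.nrow(), ny = kmap.ncol();
  std::vector<double> T(nx * ny), Tn(nx * ny);
  for (int id = 0; id < nx * ny; ++id) T[id] = T0[id];
  NumericVector trace(nt);
  double tmax = 0.0;
  int mi = 0, mj = 0;
  const double idx2 = 1.0 / (dx * dx);

  for (int n = 0; n < nt; ++n) {
    double qon = 1.0;
    if (gated) {
      double t = n * dt;
      double tin = t - std::floor(t / period) * period;
      qon = (tin < on_time) ? 1.0 : 0.0;
    }
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int id = i + nx * j;
        double Tc = T[id], kc = kmap[id], flux = 0.0;
        if (i > 0)
          flux += 0.5 * (kc + kmap[id - 1]) * (T[id - 1] - Tc);
        if (i < nx - 1)
          flux += 0.5 * (kc + kmap[id + 1]) * (T[id + 1] - Tc);
        if (j > 0)
          flux += 0.5 * (kc + kmap[id - nx]) * (T[id - nx] - Tc);
        if (j < ny - 1)
          flux += 0.5 * (kc + kmap[id + nx]) * (T[id + nx] - Tc);
        double Tnew = Tc + dt / rhoC[id] *
          (flux * idx2 + qon * Q[id] - wterm[id] * Tc);
        Tn[id] = Tnew;
        if (Tnew > tmax) { tmax = Tnew; mi = i; mj = j; }
      }
    std::swap(T, Tn);
    trace[n] = T[trace_i + nx * trace_j];
  }

  NumericMatrix Tfin(nx, ny);
  for (int id = 0; id < nx * ny; ++id) Tfin[id] = T[id];
  return List::create(_["max_rise"] = tmax, _["max_i"] = mi + 1,
                      _["max_j"] = mj + 1, _["final"] = Tfin,
                      _["trace"] = trace);
}
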