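// Inner loops of the two deterministic integrators:
//  - per-mode Nose-Hoover chain dynamics of harmonic modes (exact harmonic
//    rotation between symmetric Suzuki-Yoshida chain updates), and
//  - RK4 propagation of an n x n matrix field over an (R, P) phase-space grid
//    under the quantum-classical bracket with 4th-order central differences.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cplx;

// ---------------------------------------------------------------------------
// Nose-Hoover chains
// ---------------------------------------------------------------------------

// 7-point Suzuki-Yoshida composition weights (6th-order, sum to 1)
static const double SY7[7] = {
  0.784513610477560, 0.235573213359357, -1.17767998417887,
  1.3151863206839063, // 1 - 2*(w1+w2+w3)
  -1.17767998417887, 0.235573213359357, 0.784513610477560
};

// One symmetric NHC update of length tau for a single degree of freedom.
// Chain feedback: G_1 = p^2 - T, G_L = peta_{L-1}^2/Q_{L-1} - T (k_B = 1,
// unit particle mass).  Updates p (scaled), eta, p_eta in place.
static void nhc_update(double &p, double *eta, double *peta,
                       const double *q, double T, int M, double tau) {
  for (int cyc = 0; cyc < 7; ++cyc) {
    double wdt = SY7[cyc] * tau;
    // innermost factorization: outermost link first
    double G = (M == 1) ? (p * p - T) : (peta[M - 2] * peta[M - 2] / q[M - 2] - T);
    peta[M - 1] += 0.5 * wdt * G;
    for (int j = M - 2; j >= 0; --j) {
      double aa = std::exp(-0.25 * wdt * peta[j + 1] / q[j + 1]);
      G = (j == 0) ? (p * p - T) : (peta[j - 1] * peta[j - 1] / q[j - 1] - T);
      peta[j] = peta[j] * aa * aa + 0.5 * wdt * G * aa;
    }
    // scale the physical momentum, advance chain coordinates
    p *= std::exp(-wdt * peta[0] / q[0]);
    for (int j = 0; j < M; ++j) eta[j] += wdt * peta[j] / q[j];
    // reverse sweep
    for (int j = 0; j <= M - 2; ++j) {
      double aa = std::exp(-0.25 * wdt * peta[j + 1] / q[j + 1]);
      G = (j == 0) ? (p * p - T) : (peta[j - 1] * peta[j - 1] / q[j - 1] - T);
      peta[j] = peta[j] * aa * aa + 0.5 * wdt * G * aa;
    }
    G = (M == 1) ? (p * p - T) : (peta[M - 2] * peta[M - 2] / q[M - 2] - T);
    peta[M - 1] += 0.5 * wdt * G;
  }
}

static double ext_energy(const std::vector<double> &r,
                         const std::vector<double> &p,
                         const std::vector<double> &eta,
                         const std::vector<double> &peta,
                         const NumericVector &omega,
                         const NumericVector &cext,
                         const NumericVector &qmass,
                         const NumericVector &targ,
                         int nm, int M, bool thermo) {
  double e = 0.0;
  for (int j = 0; j < nm; ++j)
    e += 0.5 * p[j] * p[j] + 0.5 * omega[j] * omega[j] * r[j] * r[j]
         - cext[j] * r[j];
  if (thermo) {
    for (int j = 0; j < nm; ++j)
      for (int L = 0; L < M; ++L) {
        double pe = peta[j * M + L];
        e += 0.5 * pe * pe / qmass[j * M + L] + targ[j] * eta[j * M + L];
      }
  }
  return e;
}

// Integrate nm independent harmonic modes (frequencies omega, constant
// external forces cext so F_j = -omega_j^2 r_j + cext_j), each with its own
// NHC chain of length M.  Splitting: NHC(dt/2) . exact-harmonic(dt) . NHC(dt/2).
// Returns final state, the running time-average of p^2 accumulated at every
// step, min/max of the extended energy, and a sub-sampled trajectory.
// [[Rcpp::export]]
List nhc_integrate_cpp(NumericVector r0, NumericVector p0,
                       NumericVector eta0, NumericVector peta0,
                       NumericVector omega, NumericVector cext,
                       NumericVector qmass, NumericVector targ,
                       double dt, int n_steps, bool thermostat_on,
                       int record_every, double overflow_guard) {
  const int nm = r0.size();
  const int M = (nm > 0) ? eta0.size() / nm : 0;
  std::vector<double> r(r0.begin(), r0.end()), p(p0.begin(), p0.end());
  std::vector<double> eta(eta0.begin(), eta0.end());
  std::vector<double> peta(peta0.begin(), peta0.end());

  std::vector<double> cw(nm), sw(nm), rc(nm);
  for (int j = 0; j < nm; ++j) {
    cw[j] = std::cos(omega[j] * dt);
    sw[j] = std::sin(omega[j] * dt);
    rc[j] = cext[j] / (omega[j] * omega[j]);   // shifted rotation centre
  }

  std::vector<double> p2sum(nm, 0.0);
  double he0 = ext_energy(r, p, eta, peta, omega, cext, qmass, targ, nm, M,
                          thermostat_on);
  double hemin = he0, hemax = he0;

  int n_rec = (record_every > 0) ? n_steps / record_every : 0;
  NumericMatrix traj_r(n_rec, nm), traj_p(n_rec, nm);
  NumericVector traj_he(n_rec), traj_t(n_rec);
  int irec = 0;
  bool overflow = false;

  for (int s = 0; s < n_steps && !overflow; ++s) {
    if (thermostat_on)
      for (int j = 0; j < nm; ++j)
        nhc_update(p[j], &eta[j * M], &peta[j * M], &qmass[j * M],
                   targ[j], M, dt / 2.0);
    for (int j = 0; j < nm; ++j) {   // exact harmonic rotation about rc
      double x = r[j] - rc[j];
      double xn = x * cw[j] + (p[j] / omega[j]) * sw[j];
      double pn = p[j] * cw[j] - omega[j] * x * sw[j];
      r[j] = rc[j] + xn;
      p[j] = pn;
    }
    if (thermostat_on)
      for (int j = 0; j < nm; ++j)
        nhc_update(p[j], &eta[j * M], &peta[j * M], &qmass[j * M],
                   targ[j], M, dt / 2.0);

    for (int j = 0; j < nm; ++j) {
      p2sum[j] += p[j] * p[j];
      for (int L = 0; L < M; ++L)   // NaN also fails this test
        if (!(std::fabs(peta[j * M + L]) <= overflow_guard)) overflow = true;
    }
    double he = ext_energy(r, p, eta, peta, omega, cext, qmass, targ, nm, M,
                           thermostat_on);
    if (he < hemin) hemin = he;
    if (he > hemax) hemax = he;

    if (record_every > 0 && (s + 1) % record_every == 0 && irec < n_rec) {
      for (int j = 0; j < nm; ++j) { traj_r(irec, j) = r[j]; traj_p(irec, j) = p[j]; }
      traj_he[irec] = he;
      traj_t[irec] = (s + 1) * dt;
      ++irec;
    }
  }

  return List::create(
    _["r"] = NumericVector(r.begin(), r.end()),
    _["p"] = NumericVector(p.begin(), p.end()),
    _["eta"] = NumericVector(eta.begin(), eta.end()),
    _["p_eta"] = NumericVector(peta.begin(), peta.end()),
    _["p2_mean"] = NumericVector(p2sum.begin(), p2sum.end()) / double(n_steps),
    _["he0"] = he0, _["he_min"] = hemin, _["he_max"] = hemax,
    _["traj_t"] = traj_t, _["traj_r"] = traj_r, _["traj_p"] = traj_p,
    _["traj_he"] = traj_he, _["overflow"] = overflow);
}

// ---------------------------------------------------------------------------
// Quantum-classical bracket on an (R, P) grid, one classical mode
// ---------------------------------------------------------------------------

struct GridModel {
  int n, nr, np;
  std::vector<cplx> h0, chi;     // n x n, column-major
  double omega, coupling;
  std::vector<double> rg, pg;
  double hr, hp;
  double sign;                   // +1 Heisenberg (observable), -1 Schroedinger
};

static inline int idx(const GridModel &m, int a, int b, int ir, int ip) {
  return a + m.n * (b + m.n * (ir + m.nr * ip));
}

// 4th-order central difference along R or P with zero ghost nodes.
static void fd_deriv(const GridModel &m, const std::vector<cplx> &f,
                     std::vector<cplx> &out, bool along_r) {
  const int n2 = m.n * m.n;
  const double h = along_r ? m.hr : m.hp;
  const double c1 = 8.0 / (12.0 * h), c2 = 1.0 / (12.0 * h);
  for (int ip = 0; ip < m.np; ++ip)
    for (int ir = 0; ir < m.nr; ++ir) {
      int i = along_r ? ir : ip, nmax = along_r ? m.nr : m.np;
      int base = n2 * (ir + m.nr * ip);
      int sm1, sp1, sm2, sp2;  // strides to neighbours (or -1 => zero)
      int stride = along_r ? n2 : n2 * m.nr;
      sm1 = (i >= 1) ? base - stride : -1;
      sp1 = (i + 1 < nmax) ? base + stride : -1;
      sm2 = (i >= 2) ? base - 2 * stride : -1;
      sp2 = (i + 2 < nmax) ? base + 2 * stride : -1;
      for (int k = 0; k < n2; ++k) {
        cplx v(0.0, 0.0);
        if (sp1 >= 0) v += c1 * f[sp1 + k];
        if (sm1 >= 0) v -= c1 * f[sm1 + k];
        if (sp2 >= 0) v -= c2 * f[sp2 + k];
        if (sm2 >= 0) v += c2 * f[sm2 + k];
        out[base + k] = v;
      }
    }
}

// rhs = sign * ( i[h(R), f] + P dR f - omega^2 R dP f + (C/2){chi, dP f} )
static void qcle_rhs(const GridModel &m, const std::vector<cplx> &f,
                     std::vector<cplx> &df, std::vector<cplx> &dr,
                     std::vector<cplx> &dp) {
  const int n = m.n, n2 = n * n;
  fd_deriv(m, f, dr, true);
  fd_deriv(m, f, dp, false);
  std::vector<cplx> h(n2);
  const cplx I(0.0, 1.0);
  for (int ip = 0; ip < m.np; ++ip) {
    double P = m.pg[ip];
    for (int ir = 0; ir < m.nr; ++ir) {
      double R = m.rg[ir];
      int base = n2 * (ir + m.nr * ip);
      for (int k = 0; k < n2; ++k) h[k] = m.h0[k] - m.coupling * R * m.chi[k];
      for (int b = 0; b < n; ++b)
        for (int a = 0; a < n; ++a) {
          cplx comm(0.0, 0.0), anti(0.0, 0.0);
          for (int c = 0; c < n; ++c) {
            comm += h[a + n * c] * f[base + c + n * b]
                  - f[base + a + n * c] * h[c + n * b];
            anti += m.chi[a + n * c] * dp[base + c + n * b]
                  + dp[base + a + n * c] * m.chi[c + n * b];
          }
          df[base + a + n * b] = m.sign * (
            I * comm
            + P * dr[base + a + n * b]
            - m.omega * m.omega * R * dp[base + a + n * b]
            + 0.5 * m.coupling * anti);
        }
    }
  }
}

static GridModel make_model(ComplexMatrix h0, ComplexMatrix chi,
                            double omega, double coupling,
                            NumericVector rg, NumericVector pg, double sign) {
  GridModel m;
  m.n = h0.nrow(); m.nr = rg.size(); m.np = pg.size();
  m.h0.resize(m.n * m.n); m.chi.resize(m.n * m.n);
  for (int k = 0; k < m.n * m.n; ++k) {
    m.h0[k] = cplx(h0[k].r, h0[k].i);
    m.chi[k] = cplx(chi[k].r, chi[k].i);
  }
  m.omega = omega; m.coupling = coupling;
  m.rg.assign(rg.begin(), rg.end());
  m.pg.assign(pg.begin(), pg.end());
  m.hr = rg[1] - rg[0]; m.hp = pg[1] - pg[0];
  m.sign = sign;
  return m;
}

static std::vector<cplx> as_cplx_vec(ComplexVector v) {
  std::vector<cplx> out(v.size());
  for (int k = 0; k < (int)v.size(); ++k) out[k] = cplx(v[k].r, v[k].i);
  return out;
}

static ComplexVector to_rcomplex(const std::vector<cplx> &v) {
  ComplexVector out(v.size());
  for (size_t k = 0; k < v.size(); ++k) {
    out[k].r = v[k].real(); out[k].i = v[k].imag();
  }
  return out;
}

// Single evaluation of the bracket right-hand side on the grid.
// [[Rcpp::export]]
ComplexVector qcle_rhs_cpp(ComplexVector f, ComplexMatrix h0, ComplexMatrix chi,
                           double omega, double coupling,
                           NumericVector rg, NumericVector pg, double sign) {
  GridModel m = make_model(h0, chi, omega, coupling, rg, pg, sign);
  std::vector<cplx> ff = as_cplx_vec(f);
  std::vector<cplx> df(ff.size()), dr(ff.size()), dp(ff.size());
  qcle_rhs(m, ff, df, dr, dp);
  return to_rcomplex(df);
}

// RK4 propagation of the matrix field over n_steps, re-Hermitizing each
// step.  A thin absorbing layer (quadratic ramp over the outer `nb` cells,
// rate `absorb` at the very edge) suppresses the weak boundary instability
// of central differences with zero ghost nodes; the layer only touches
// cells where a well-resolved state carries negligible mass.
// [[Rcpp::export]]
ComplexVector qcle_propagate_cpp(ComplexVector f, ComplexMatrix h0,
                                 ComplexMatrix chi, double omega,
                                 double coupling, NumericVector rg,
                                 NumericVector pg, double dt, int n_steps,
                                 double sign, double absorb = 10.0) {
  GridModel m = make_model(h0, chi, omega, coupling, rg, pg, sign);
  const size_t sz = f.size();
  std::vector<cplx> y = as_cplx_vec(f);
  std::vector<cplx> k1(sz), k2(sz), k3(sz), k4(sz), tmp(sz), dr(sz), dp(sz);
  const int n = m.n, n2 = n * n;
  const int nb = 4;
  std::vector<double> mask_r(m.nr, 1.0), mask_p(m.np, 1.0);
  if (absorb > 0.0) {
    for (int i = 0; i < m.nr; ++i) {
      int d = std::min(i, m.nr - 1 - i);
      if (d < nb) {
        double w = double(nb - d) / nb;
        mask_r[i] = std::exp(-absorb * dt * w * w);
      }
    }
    for (int i = 0; i < m.np; ++i) {
      int d = std::min(i, m.np - 1 - i);
      if (d < nb) {
        double w = double(nb - d) / nb;
        mask_p[i] = std::exp(-absorb * dt * w * w);
      }
    }
  }
  for (int s = 0; s < n_steps; ++s) {
    qcle_rhs(m, y, k1, dr, dp);
    for (size_t k = 0; k < sz; ++k) tmp[k] = y[k] + 0.5 * dt * k1[k];
    qcle_rhs(m, tmp, k2, dr, dp);
    for (size_t k = 0; k < sz; ++k) tmp[k] = y[k] + 0.5 * dt * k2[k];
    qcle_rhs(m, tmp, k3, dr, dp);
    for (size_t k = 0; k < sz; ++k) tmp[k] = y[k] + dt * k3[k];
    qcle_rhs(m, tmp, k4, dr, dp);
    for (size_t k = 0; k < sz; ++k)
      y[k] += dt / 6.0 * (k1[k] + 2.0 * k2[k] + 2.0 * k3[k] + k4[k]);
    // re-Hermitize node by node and apply the absorbing mask
    for (int ip = 0; ip < m.np; ++ip)
      for (int ir = 0; ir < m.nr; ++ir) {
        int base = n2 * (ir + m.nr * ip);
        double msk = mask_r[ir] * mask_p[ip];
        for (int b = 0; b < n; ++b)
          for (int a = 0; a <= b; ++a) {
            cplx u = y[base + a + n * b], v = y[base + b + n * a];
            cplx avg = 0.5 * msk * (u + std::conj(v));
            y[base + a + n * b] = avg;
            y[base + b + n * a] = std::conj(avg);
          }
      }
  }
  return to_rcomplex(y);
}
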