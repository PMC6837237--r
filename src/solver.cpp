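// Discontinuous Galerkin solver for nonlinear 1D pulse-wave propagation on a
// branching arterial network.
//
// State per artery: modal coefficients of (A, u) in orthonormal Legendre
// polynomials of degree p on each of Ne uniform elements.  Interfaces use an
// upwind flux built from the characteristic variables W_{1,2} = u +- 4c with
// c = sqrt(B/(2 rho)) A^{1/4} (elastic tube law p = p_ext + B(sqrt A - sqrt A0)).
// Y-bifurcations are coupled by a 6x6 Newton solve enforcing mass flux and
// total-pressure continuity plus the three outgoing characteristics.  Time
// integration is second-order Adams-Bashforth bootstrapped by one forward
// Euler step.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdio>
using namespace Rcpp;

namespace {

struct Net {
  int n;
  std::vector<double> L, A0, B, sqrtA0, kc, h;  // kc = sqrt(B/(2 rho))
  std::vector<int> parent, child1, child2;      // -1 where absent
  int inlet;
  double rho, pext, Kr;                         // Kr = -22 mu pi
};

struct Basis {
  int Np, nq;
  std::vector<double> qw;            // quadrature weights (nq)
  std::vector<double> V, Vd;         // nq x Np, column-major: V[q + nq*k]
  std::vector<double> phiL, phiR;    // basis traces at xi = -1, +1 (Np)
};

inline double wave_eval(double t, double tau, const std::vector<double>& ca,
                        const std::vector<double>& cb) {
  double ang = 2.0 * M_PI * t / tau, s = ca[0];
  for (size_t k = 1; k < ca.size(); ++k)
    s += ca[k] * std::cos(k * ang) + cb[k] * std::sin(k * ang);
  return s;
}

// Solve M x = r in place (6x6, partial pivoting); returns false if singular.
inline bool solve6(double M[6][6], double r[6]) {
  int piv[6];
  for (int i = 0; i < 6; ++i) piv[i] = i;
  for (int col = 0; col < 6; ++col) {
    int best = col;
    double bv = std::fabs(M[piv[col]][col]);
    for (int i = col + 1; i < 6; ++i) {
      double v = std::fabs(M[piv[i]][col]);
      if (v > bv) { bv = v; best = i; }
    }
    if (bv <= 0.0 || !std::isfinite(bv)) return false;
    std::swap(piv[col], piv[best]);
    const int pc = piv[col];
    for (int i = col + 1; i < 6; ++i) {
      const int pi = piv[i];
      double f = M[pi][col] / M[pc][col];
      if (f != 0.0) {
        for (int j = col; j < 6; ++j) M[pi][j] -= f * M[pc][j];
        r[pi] -= f * r[pc];
      }
    }
  }
  double x[6];
  for (int col = 5; col >= 0; --col) {
    const int pc = piv[col];
    double s = r[pc];
    for (int j = col + 1; j < 6; ++j) s -= M[pc][j] * x[j];
    x[col] = s / M[pc][col];
  }
  for (int i = 0; i < 6; ++i) r[i] = x[i];
  return true;
}

// Junction Newton solve.  Unknowns x = (a1,u1,a2,u2,a3,u3) with a_i = A_i/A0_i.
// Equations: mass flux balance, two total-pressure continuities, and the three
// outgoing characteristic invariants (parent W1, child W2s).
struct JuncResult {
  double A[3], u[3];
  double res_mass, res_p2, res_p3;  // physical residuals (SI units)
  int iters;
  bool ok;
};

JuncResult junction_newton(const double A0[3], const double B[3],
                           const double kc[3], const double sA0[3],
                           double rho, double W1p, double W2a, double W2b,
                           double tol, int maxit, const double* warm) {
  JuncResult out;
  double x[6];
  if (warm) {
    for (int i = 0; i < 6; ++i) x[i] = warm[i];
  } else {
    x[0] = x[2] = x[4] = 1.0;
    x[1] = x[3] = x[5] = 0.0;
  }
  const double invQ = 1.0 / A0[0], invR = 1.0 / rho;
  double r[6];
  int it = 0;
  double rmax = 0.0;
  for (; it <= maxit; ++it) {
    double A[3], sq[3], qc[3];  // areas, sqrt(A), A^{1/4}-type terms
    for (int i = 0; i < 3; ++i) {
      A[i] = A0[i] * x[2 * i];
      if (!(A[i] > 0.0) || !std::isfinite(A[i])) { out.ok = false; out.iters = it; return out; }
      sq[i] = std::sqrt(A[i]);
      qc[i] = std::sqrt(sq[i]);  // A^{1/4}
    }
    const double u1 = x[1], u2 = x[3], u3 = x[5];
    const double p1 = B[0] * (sq[0] - sA0[0]);
    const double p2 = B[1] * (sq[1] - sA0[1]);
    const double p3 = B[2] * (sq[2] - sA0[2]);
    r[0] = (A[0] * u1 - A[1] * u2 - A[2] * u3) * invQ;
    r[1] = (p1 - p2 + 0.5 * rho * (u1 * u1 - u2 * u2)) * invR;
    r[2] = (p1 - p3 + 0.5 * rho * (u1 * u1 - u3 * u3)) * invR;
    r[3] = u1 + 4.0 * kc[0] * qc[0] - W1p;
    r[4] = u2 - 4.0 * kc[1] * qc[1] - W2a;
    r[5] = u3 - 4.0 * kc[2] * qc[2] - W2b;
    rmax = 0.0;
    for (int i = 0; i < 6; ++i) rmax = std::max(rmax, std::fabs(r[i]));
    if (rmax < tol || it == maxit) break;

    double J[6][6] = {{0}};
    // d sqrt(A_i)/da_i = A0_i / (2 sqrt(A_i)); d A_i^{1/4}/da_i = A0_i/(4 A^{3/4})
    double dsq[3], dqc[3];
    for (int i = 0; i < 3; ++i) {
      dsq[i] = A0[i] / (2.0 * sq[i]);
      dqc[i] = A0[i] / (4.0 * sq[i] * qc[i]);
    }
    J[0][0] = A0[0] * u1 * invQ;  J[0][1] = A[0] * invQ;
    J[0][2] = -A0[1] * u2 * invQ; J[0][3] = -A[1] * invQ;
    J[0][4] = -A0[2] * u3 * invQ; J[0][5] = -A[2] * invQ;
    J[1][0] = B[0] * dsq[0] * invR; J[1][1] = u1;
    J[1][2] = -B[1] * dsq[1] * invR; J[1][3] = -u2;
    J[2][0] = B[0] * dsq[0] * invR; J[2][1] = u1;
    J[2][4] = -B[2] * dsq[2] * invR; J[2][5] = -u3;
    J[3][0] = 4.0 * kc[0] * dqc[0]; J[3][1] = 1.0;
    J[4][2] = -4.0 * kc[1] * dqc[1]; J[4][3] = 1.0;
    J[5][4] = -4.0 * kc[2] * dqc[2]; J[5][5] = 1.0;

    double step[6];
    for (int i = 0; i < 6; ++i) step[i] = -r[i];
    if (!solve6(J, step)) { out.ok = false; out.iters = it; return out; }
    // damp steps that would drive any scaled area non-positive
    double lam = 1.0;
    for (int i = 0; i < 3; ++i) {
      double xn = x[2 * i] + step[2 * i];
      if (xn <= 0.0) lam = std::min(lam, -0.5 * x[2 * i] / step[2 * i]);
    }
    for (int i = 0; i < 6; ++i) x[i] += lam * step[i];
  }
  for (int i = 0; i < 3; ++i) {
    out.A[i] = A0[i] * x[2 * i];
    out.u[i] = x[2 * i + 1];
  }
  out.res_mass = out.A[0] * out.u[0] - out.A[1] * out.u[1] - out.A[2] * out.u[2];
  {
    double sq0 = std::sqrt(out.A[0]), sq1 = std::sqrt(out.A[1]), sq2 = std::sqrt(out.A[2]);
    double p1 = B[0] * (sq0 - sA0[0]), p2 = B[1] * (sq1 - sA0[1]), p3 = B[2] * (sq2 - sA0[2]);
    out.res_p2 = p1 + 0.5 * rho * out.u[0] * out.u[0] - p2 - 0.5 * rho * out.u[1] * out.u[1];
    out.res_p3 = p1 + 0.5 * rho * out.u[0] * out.u[0] - p3 - 0.5 * rho * out.u[2] * out.u[2];
  }
  out.iters = it;
  out.ok = (rmax < std::max(tol * 1e3, 1e-10));
  return out;
}

struct Diag {
  double junc_mass = 0.0, junc_press = 0.0, max_speed = 0.0;
  double blow_t = -1.0; int blow_art = -1, blow_elem = -1;
};

// Right-hand side of the semi-discrete DG system.
// Coefficients indexed [ (a*Ne + e)*Np + k ].
struct Solver {
  Net net;
  Basis bs;
  int Ne;
  double tau;
  std::vector<double> wa, wb;          // waveform harmonics
  double newton_tol;
  int newton_maxit;
  std::vector<double> warm;            // 6 per artery (junction warm starts)
  std::vector<char> has_warm;

  // scratch traces and interface fluxes, per (artery, element)
  std::vector<double> AL, AR, uL, uR;
  std::vector<double> f1L, f2L, f1R, f2R;

  inline double cspeed(int a, double A) const {
    return net.kc[a] * std::sqrt(std::sqrt(A));
  }
  inline void flux(int a, double A, double u, double& F1, double& F2) const {
    F1 = A * u;
    F2 = 0.5 * u * u + (net.pext + net.B[a] * (std::sqrt(A) - net.sqrtA0[a])) / net.rho;
  }
  // upwind state from characteristics; false on failure
  inline bool upwind(int a, double W1, double W2, double& A, double& u) const {
    u = 0.5 * (W1 + W2);
    double c = 0.125 * (W1 - W2);
    if (!(c > 0.0) || !std::isfinite(c)) return false;
    double s = c / net.kc[a];          // A^{1/4}
    double q = s * s;
    A = q * q;
    return true;
  }

  // returns false on blow-up (diag filled)
  bool rhs(const std::vector<double>& Ah, const std::vector<double>& uh, double t,
           std::vector<double>& RA, std::vector<double>& Ru,
           double& mass_rate, Diag& dg) {
    const int n = net.n, Np = bs.Np, nq = bs.nq;
    // element boundary traces
    for (int a = 0; a < n; ++a) {
      for (int e = 0; e < Ne; ++e) {
        const int off = (a * Ne + e) * Np;
        double al = 0, ar = 0, vl = 0, vr = 0;
        for (int k = 0; k < Np; ++k) {
          al += Ah[off + k] * bs.phiL[k];
          ar += Ah[off + k] * bs.phiR[k];
          vl += uh[off + k] * bs.phiL[k];
          vr += uh[off + k] * bs.phiR[k];
        }
        if (!(al > 0.0) || !(ar > 0.0) || !std::isfinite(vl) || !std::isfinite(vr)) {
          dg.blow_t = t; dg.blow_art = a; dg.blow_elem = e;
          return false;
        }
        const int ide = a * Ne + e;
        AL[ide] = al; AR[ide] = ar; uL[ide] = vl; uR[ide] = vr;
      }
    }

    mass_rate = 0.0;

    // interior interfaces
    for (int a = 0; a < n; ++a) {
      for (int e = 0; e + 1 < Ne; ++e) {
        const int il = a * Ne + e, ir = il + 1;
        double W1 = uR[il] + 4.0 * cspeed(a, AR[il]);
        double W2 = uL[ir] - 4.0 * cspeed(a, AL[ir]);
        double As, us;
        if (!upwind(a, W1, W2, As, us)) {
          dg.blow_t = t; dg.blow_art = a; dg.blow_elem = e; return false;
        }
        double F1, F2;
        flux(a, As, us, F1, F2);
        f1R[il] = F1; f2R[il] = F2;
        f1L[ir] = F1; f2L[ir] = F2;
      }
    }

    // inlet boundary (root artery, left end): prescribe u(t), area from the
    // outgoing (backward) characteristic -> reflection-free forcing.
    {
      const int a = net.inlet, i0 = a * Ne;
      double W2 = uL[i0] - 4.0 * cspeed(a, AL[i0]);
      double us = wave_eval(t, tau, wa, wb);
      double c = 0.25 * (us - W2);
      if (!(c > 0.0)) { dg.blow_t = t; dg.blow_art = a; dg.blow_elem = 0; return false; }
      double s = c / net.kc[a], q = s * s, As = q * q;
      double F1, F2;
      flux(a, As, us, F1, F2);
      f1L[i0] = F1; f2L[i0] = F2;
    }

    // terminal outlets: fully absorbing (incoming characteristic held at rest)
    for (int a = 0; a < n; ++a) {
      if (net.child1[a] >= 0) continue;
      const int il = a * Ne + (Ne - 1);
      double W1 = uR[il] + 4.0 * cspeed(a, AR[il]);
      double W2 = -4.0 * cspeed(a, net.A0[a]);
      double As, us;
      if (!upwind(a, W1, W2, As, us)) {
        dg.blow_t = t; dg.blow_art = a; dg.blow_elem = Ne - 1; return false;
      }
      double F1, F2;
      flux(a, As, us, F1, F2);
      f1R[il] = F1; f2R[il] = F2;
    }

    // junctions
    for (int a = 0; a < n; ++a) {
      int c1 = net.child1[a], c2 = net.child2[a];
      if (c1 < 0) continue;
      const int ip = a * Ne + (Ne - 1), i1 = c1 * Ne, i2 = c2 * Ne;
      double W1p = uR[ip] + 4.0 * cspeed(a, AR[ip]);
      double W2a = uL[i1] - 4.0 * cspeed(c1, AL[i1]);
      double W2b = uL[i2] - 4.0 * cspeed(c2, AL[i2]);
      double A0j[3] = {net.A0[a], net.A0[c1], net.A0[c2]};
      double Bj[3] = {net.B[a], net.B[c1], net.B[c2]};
      double kcj[3] = {net.kc[a], net.kc[c1], net.kc[c2]};
      double sA0j[3] = {net.sqrtA0[a], net.sqrtA0[c1], net.sqrtA0[c2]};
      double* wptr = has_warm[a] ? &warm[6 * a] : nullptr;
      JuncResult jr = junction_newton(A0j, Bj, kcj, sA0j, net.rho,
                                      W1p, W2a, W2b, newton_tol, newton_maxit, wptr);
      if (!jr.ok) {
        dg.blow_t = t; dg.blow_art = a; dg.blow_elem = Ne - 1; return false;
      }
      for (int i = 0; i < 3; ++i) {
        warm[6 * a + 2 * i] = jr.A[i] / A0j[i];
        warm[6 * a + 2 * i + 1] = jr.u[i];
      }
      has_warm[a] = 1;
      dg.junc_mass = std::max(dg.junc_mass, std::fabs(jr.res_mass));
      dg.junc_press = std::max(dg.junc_press,
                               std::max(std::fabs(jr.res_p2), std::fabs(jr.res_p3)));
      double F1, F2;
      flux(a, jr.A[0], jr.u[0], F1, F2);
      f1R[ip] = F1; f2R[ip] = F2;
      flux(c1, jr.A[1], jr.u[1], F1, F2);
      f1L[i1] = F1; f2L[i1] = F2;
      flux(c2, jr.A[2], jr.u[2], F1, F2);
      f1L[i2] = F1; f2L[i2] = F2;
    }

    // net mass influx rate (telescopes to boundary fluxes up to Newton tol)
    for (int a = 0; a < n; ++a)
      mass_rate += f1L[a * Ne] - f1R[a * Ne + (Ne - 1)];

    // volume terms + boundary lift + friction source
    const double Kr = net.Kr, rho = net.rho;
    for (int a = 0; a < n; ++a) {
      const double twoh = 2.0 / net.h[a];
      for (int e = 0; e < Ne; ++e) {
        const int ide = a * Ne + e, off = ide * Np;
        double volA[8] = {0}, volU[8] = {0}, srcU[8] = {0};
        for (int q = 0; q < nq; ++q) {
          double Aq = 0, uq = 0;
          for (int k = 0; k < Np; ++k) {
            Aq += Ah[off + k] * bs.V[q + nq * k];
            uq += uh[off + k] * bs.V[q + nq * k];
          }
          if (!(Aq > 0.0) || !std::isfinite(uq)) {
            dg.blow_t = t; dg.blow_art = a; dg.blow_elem = e; return false;
          }
          double F1, F2;
          flux(a, Aq, uq, F1, F2);
          double S2 = Kr * uq / (rho * Aq);
          const double w = bs.qw[q];
          for (int k = 0; k < Np; ++k) {
            volA[k] += w * F1 * bs.Vd[q + nq * k];
            volU[k] += w * F2 * bs.Vd[q + nq * k];
            srcU[k] += w * S2 * bs.V[q + nq * k];
          }
        }
        for (int k = 0; k < Np; ++k) {
          RA[off + k] = twoh * (volA[k] - (bs.phiR[k] * f1R[ide] - bs.phiL[k] * f1L[ide]));
          Ru[off + k] = twoh * (volU[k] - (bs.phiR[k] * f2R[ide] - bs.phiL[k] * f2L[ide]))
                        + srcU[k];
        }
      }
    }

    // track max signal speed from traces for CFL auditing
    for (int a = 0; a < n; ++a) {
      for (int e = 0; e < Ne; ++e) {
        const int ide = a * Ne + e;
        double s1 = std::fabs(uL[ide]) + cspeed(a, AL[ide]);
        double s2 = std::fabs(uR[ide]) + cspeed(a, AR[ide]);
        dg.max_speed = std::max(dg.max_speed, std::max(s1, s2));
      }
    }
    return true;
  }
};

Net make_net(const List& net_in) {
  Net nt;
  NumericVector L = net_in["length"], A0 = net_in["area"], B = net_in["stiffness"];
  IntegerVector parent = net_in["parent"], c1 = net_in["child1"], c2 = net_in["child2"];
  nt.n = L.size();
  nt.rho = as<double>(net_in["density"]);
  nt.pext = as<double>(net_in["p_ext"]);
  nt.Kr = as<double>(net_in["Kr"]);
  nt.inlet = as<int>(net_in["inlet"]);  // 0-based
  nt.L.assign(L.begin(), L.end());
  nt.A0.assign(A0.begin(), A0.end());
  nt.B.assign(B.begin(), B.end());
  nt.parent.assign(parent.begin(), parent.end());
  nt.child1.assign(c1.begin(), c1.end());
  nt.child2.assign(c2.begin(), c2.end());
  nt.sqrtA0.resize(nt.n);
  nt.kc.resize(nt.n);
  for (int a = 0; a < nt.n; ++a) {
    nt.sqrtA0[a] = std::sqrt(nt.A0[a]);
    nt.kc[a] = std::sqrt(nt.B[a] / (2.0 * nt.rho));
  }
  return nt;
}

Basis make_basis(const List& bs_in) {
  Basis bs;
  NumericMatrix V = bs_in["V"], Vd = bs_in["Vd"];
  NumericVector qw = bs_in["qw"], phiL = bs_in["phiL"], phiR = bs_in["phiR"];
  bs.nq = V.nrow();
  bs.Np = V.ncol();
  bs.qw.assign(qw.begin(), qw.end());
  bs.V.assign(V.begin(), V.end());
  bs.Vd.assign(Vd.begin(), Vd.end());
  bs.phiL.assign(phiL.begin(), phiL.end());
  bs.phiR.assign(phiR.begin(), phiR.end());
  return bs;
}

}  // namespace

// [[Rcpp::export]]
List cpp_run(List net_in, List wave_in, List cfg, List sens, List state0) {
  Solver sv;
  sv.net = make_net(net_in);
  sv.bs = make_basis(cfg["basis"]);
  sv.Ne = as<int>(cfg["elements"]);
  sv.newton_tol = as<double>(cfg["newton_tol"]);
  sv.newton_maxit = as<int>(cfg["newton_maxit"]);
  sv.tau = as<double>(wave_in["period"]);
  NumericVector ca = wave_in["cos_coef"], cb = wave_in["sin_coef"];
  sv.wa.assign(ca.begin(), ca.end());
  sv.wb.assign(cb.begin(), cb.end());
  const int n = sv.net.n, Np = sv.bs.Np, Ne = sv.Ne;
  if (Np > 8) stop("polynomial degree above 7 is not supported");
  sv.warm.assign(6 * n, 0.0);
  sv.has_warm.assign(n, 0);
  sv.AL.resize(n * Ne); sv.AR.resize(n * Ne);
  sv.uL.resize(n * Ne); sv.uR.resize(n * Ne);
  sv.f1L.resize(n * Ne); sv.f2L.resize(n * Ne);
  sv.f1R.resize(n * Ne); sv.f2R.resize(n * Ne);
  sv.net.h.resize(n);
  for (int a = 0; a < n; ++a) sv.net.h[a] = sv.net.L[a] / Ne;
  double hmin = sv.net.h[0];
  for (int a = 1; a < n; ++a) hmin = std::min(hmin, sv.net.h[a]);

  const double dt = as<double>(cfg["dt"]);
  const int n_steps = as<int>(cfg["n_steps"]);
  const int stride = as<int>(cfg["sample_stride"]);
  const int cfl_every = as<int>(cfg["check_cfl_every"]);
  const double cfl_limit = as<double>(cfg["cfl_limit"]);

  const int nc = n * Ne * Np;
  std::vector<double> Ah(nc), uh(nc), RA(nc), Ru(nc), RAp(nc), Rup(nc);
  double t = 0.0, mass_influx = 0.0, rate_prev = 0.0;
  int step = 0;
  bool has_prev = false;
  const double phi0 = sv.bs.phiL[0];  // constant-mode basis value 1/sqrt(2)

  if (state0.size() > 0) {
    NumericVector A_ = state0["Ah"], u_ = state0["uh"];
    std::copy(A_.begin(), A_.end(), Ah.begin());
    std::copy(u_.begin(), u_.end(), uh.begin());
    t = as<double>(state0["t"]);
    step = as<int>(state0["step"]);
    has_prev = as<bool>(state0["has_prev"]);
    mass_influx = as<double>(state0["mass_influx"]);
    if (has_prev) {
      NumericVector RA_ = state0["RA_prev"], Ru_ = state0["Ru_prev"];
      std::copy(RA_.begin(), RA_.end(), RAp.begin());
      std::copy(Ru_.begin(), Ru_.end(), Rup.begin());
      rate_prev = as<double>(state0["rate_prev"]);
    }
  } else {
    // rest: A = A0, u = 0 -> only the constant mode is populated
    for (int a = 0; a < n; ++a)
      for (int e = 0; e < Ne; ++e)
        Ah[(a * Ne + e) * Np] = sv.net.A0[a] / phi0;
  }

  // sensors: artery (0-based), element, and basis values at the local xi
  IntegerVector s_art = sens["artery"], s_elem = sens["element"];
  NumericMatrix s_phi = sens["phi"];  // Np x nsens
  const int nsens = s_art.size();
  const int nrec = (stride > 0) ? n_steps / stride : 0;
  NumericMatrix rec(nrec, nsens);
  NumericVector rec_t(nrec);
  int irec = 0;

  Diag dg;
  for (int s = 0; s < n_steps; ++s) {
    double rate = 0.0;
    if (!sv.rhs(Ah, uh, t, RA, Ru, rate, dg)) {
      stop("flow solver blow-up at t = %f s (artery %d, element %d)",
           dg.blow_t, dg.blow_art + 1, dg.blow_elem + 1);
    }
    if (!has_prev) {
      for (int i = 0; i < nc; ++i) { Ah[i] += dt * RA[i]; uh[i] += dt * Ru[i]; }
      mass_influx += dt * rate;
      has_prev = true;
    } else {
      for (int i = 0; i < nc; ++i) {
        Ah[i] += dt * (1.5 * RA[i] - 0.5 * RAp[i]);
        uh[i] += dt * (1.5 * Ru[i] - 0.5 * Rup[i]);
      }
      mass_influx += dt * (1.5 * rate - 0.5 * rate_prev);
    }
    std::swap(RAp, RA); std::swap(Rup, Ru);
    rate_prev = rate;
    t += dt;
    ++step;
    if (stride > 0 && step % stride == 0 && irec < nrec) {
      for (int j = 0; j < nsens; ++j) {
        const int off = (s_art[j] * Ne + s_elem[j]) * Np;
        double v = 0;
        for (int k = 0; k < Np; ++k) v += uh[off + k] * s_phi(k, j);
        rec(irec, j) = v;
      }
      rec_t[irec] = t;
      ++irec;
    }
    if (cfl_every > 0 && (s + 1) % cfl_every == 0) {
      if (dt > cfl_limit * hmin / dg.max_speed)
        stop("CFL bound violated at t = %f s: dt = %g exceeds %g",
             t, dt, cfl_limit * hmin / dg.max_speed);
    }
  }

  return List::create(
    _["times"] = rec_t, _["velocity"] = rec,
    _["state"] = List::create(
      _["Ah"] = NumericVector(Ah.begin(), Ah.end()),
      _["uh"] = NumericVector(uh.begin(), uh.end()),
      _["RA_prev"] = NumericVector(RAp.begin(), RAp.end()),
      _["Ru_prev"] = NumericVector(Rup.begin(), Rup.end()),
      _["rate_prev"] = rate_prev,
      _["t"] = t, _["step"] = step, _["has_prev"] = has_prev,
      _["mass_influx"] = mass_influx),
    _["diagnostics"] = List::create(
      _["junction_mass_residual"] = dg.junc_mass,
      _["junction_pressure_residual"] = dg.junc_press,
      _["max_signal_speed"] = dg.max_speed,
      _["mass_influx"] = mass_influx,
      _["n_steps"] = step, _["dt"] = dt));
}

// Standalone Y-junction coupling solve (same routine as the time stepper).
// geom: list with area0 (3), stiffness (3); characteristics W1p, W2a, W2b.
// [[Rcpp::export]]
List cpp_junction_solve(NumericVector area0, NumericVector stiffness,
                        double rho, double W1p, double W2a, double W2b,
                        double tol, int maxit) {
  if (area0.size() != 3 || stiffness.size() != 3)
    stop("junction solve needs exactly 3 arteries (parent, child, child)");
  double A0[3], B[3], kc[3], sA0[3];
  for (int i = 0; i < 3; ++i) {
    A0[i] = area0[i]; B[i] = stiffness[i];
    if (!(A0[i] > 0) || !(B[i] > 0)) stop("areas and stiffnesses must be positive");
    kc[i] = std::sqrt(B[i] / (2.0 * rho));
    sA0[i] = std::sqrt(A0[i]);
  }
  JuncResult jr = junction_newton(A0, B, kc, sA0, rho, W1p, W2a, W2b, tol, maxit, nullptr);
  if (!jr.ok)
    stop("junction Newton iteration failed to converge (%d iterations)", jr.iters);
  return List::create(
    _["area"] = NumericVector::create(jr.A[0], jr.A[1], jr.A[2]),
    _["velocity"] = NumericVector::create(jr.u[0], jr.u[1], jr.u[2]),
    _["residual_mass"] = jr.res_mass,
    _["residual_pressure"] = NumericVector::create(jr.res_p2, jr.res_p3),
    _["iterations"] = jr.iters);
}
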