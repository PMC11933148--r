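// Compiled core of the co-simulation framework:
//   - follower (closed-loop Norwood LPM) right-hand side and subdivided RK4
//   - leader (0D arch/shunt surrogate) implicit step with Newton junction solve
//   - monolithic reference integrator (follower + leader as one ODE system)
//   - CRC32 (for the in-package ZIP/FMU writer)
//
// Units throughout: mmHg, mL, s (R in mmHg.s/mL, C in mL/mmHg, L in mmHg.s^2/mL,
// quadratic loss k in mmHg.s^2/mL^2).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Parameter vector layout (follower).  Kept in one place; R side mirrors it
// in lpm_param_vector().
// ---------------------------------------------------------------------------
enum {
  P_EMAX = 0, P_EMIN, P_T, P_TPEAK, P_TSYS, P_V0SV,
  P_CA, P_V0A,
  P_RAV, P_RAO, P_EPS,
  P_CAO, P_RPAO,
  P_BED0,                       // 6 beds x (R_prox, C, R_dist) = 18 values
  P_CSVN = P_BED0 + 18, P_RSVR, P_LSVR,
  P_CPVN, P_RPVR, P_LPVR,
  NPAR_LPM
};
// state layout (follower), 13 entries
enum {
  S_VSV = 0, S_VA, S_PAO,
  S_PBED0,                      // 6 bed pressures: inn, car, sub, dao, lpa, rpa
  S_PSVN = S_PBED0 + 6, S_PPVN, S_QSVR, S_QPVR,
  NSTATE_LPM
};
// boundary order: aortic_root, innominate, l_carotid, l_subclavian, dao, lpa, rpa
static const double ORIENT[7] = { -1, 1, 1, 1, 1, 1, 1 };

static inline double activation(double t, double T, double tp, double ts) {
  double u = t - T * std::floor(t / T);   // periodic reduction
  if (u < 0) u += T;
  if (u >= T) u -= T;
  if (u < tp) return 0.5 * (1.0 - std::cos(M_PI * u / tp));
  if (u < ts) return 0.5 * (1.0 + std::cos(M_PI * (u - tp) / (ts - tp)));
  return 0.0;
}

static inline double elastance_at(double t, const double* p) {
  return p[P_EMIN] + (p[P_EMAX] - p[P_EMIN]) *
         activation(t, p[P_T], p[P_TPEAK], p[P_TSYS]);
}

// Ideal diode with optional smooth regularisation of width eps (mmHg).
static inline double valve_q(double dP, double R, double eps) {
  if (eps <= 0.0) return dP > 0.0 ? dP / R : 0.0;
  return (dP + std::sqrt(dP * dP + eps * eps)) / (2.0 * R);
}

static void lpm_rhs_c(const double* s, const double* q, double t,
                      const double* p, double* d) {
  const double Psv = elastance_at(t, p) * (s[S_VSV] - p[P_V0SV]);
  const double Pa  = (s[S_VA] - p[P_V0A]) / p[P_CA];
  const double Qav = valve_q(Pa - Psv, p[P_RAV], p[P_EPS]);
  const double Qao = valve_q(Psv - s[S_PAO], p[P_RAO], p[P_EPS]);

  d[S_VSV] = Qav - Qao;
  d[S_VA]  = s[S_QSVR] + s[S_QPVR] - Qav;
  d[S_PAO] = (Qao - q[0]) / p[P_CAO];      // orientation -1 at aortic root

  double sys_out = 0.0, pul_out = 0.0;
  for (int b = 0; b < 6; ++b) {
    const double C  = p[P_BED0 + 3 * b + 1];
    const double Rd = p[P_BED0 + 3 * b + 2];
    const double Pven = (b < 4) ? s[S_PSVN] : s[S_PPVN];
    const double out = (s[S_PBED0 + b] - Pven) / Rd;
    d[S_PBED0 + b] = (q[1 + b] - out) / C;
    if (b < 4) sys_out += out; else pul_out += out;
  }
  d[S_PSVN] = (sys_out - s[S_QSVR]) / p[P_CSVN];
  d[S_PPVN] = (pul_out - s[S_QPVR]) / p[P_CPVN];
  d[S_QSVR] = (s[S_PSVN] - Pa - p[P_RSVR] * s[S_QSVR]) / p[P_LSVR];
  d[S_QPVR] = (s[S_PPVN] - Pa - p[P_RPVR] * s[S_QPVR]) / p[P_LPVR];
}

// [[Rcpp::export(name = ".lpm_rhs_cpp")]]
NumericVector lpm_rhs_cpp(NumericVector state, NumericVector q, double t,
                          NumericVector par) {
  if (state.size() != NSTATE_LPM) stop("state must have %d entries", NSTATE_LPM);
  if (q.size() != 7) stop("q must have 7 entries (one per boundary)");
  if (par.size() != NPAR_LPM) stop("parameter vector must have %d entries", NPAR_LPM);
  NumericVector d(NSTATE_LPM);
  lpm_rhs_c(state.begin(), q.begin(), t, par.begin(), d.begin());
  return d;
}

// Boundary pressures plus monitored internals at a given state / held inputs.
// [[Rcpp::export(name = ".lpm_outputs_cpp")]]
NumericVector lpm_outputs_cpp(NumericVector state, NumericVector q, double t,
                              NumericVector par) {
  const double* s = state.begin();
  const double* p = par.begin();
  NumericVector out(12);
  const double E   = elastance_at(t, p);
  const double Psv = E * (s[S_VSV] - p[P_V0SV]);
  const double Pa  = (s[S_VA] - p[P_V0A]) / p[P_CA];
  out[0] = s[S_PAO] - q[0] * p[P_RPAO];     // leader-side aortic root pressure
  for (int b = 0; b < 6; ++b)
    out[1 + b] = s[S_PBED0 + b] + q[1 + b] * p[P_BED0 + 3 * b];
  out[7]  = Psv;
  out[8]  = Pa;
  out[9]  = valve_q(Pa - Psv, p[P_RAV], p[P_EPS]);
  out[10] = valve_q(Psv - s[S_PAO], p[P_RAO], p[P_EPS]);
  out[11] = E;
  return out;
}

// Subdivided classical RK4 over one macro step [t, t+dt].  Inputs are linearly
// interpolated from q0 (at t) to q1 (at t+dt); zero-order hold is q0 == q1.
// [[Rcpp::export(name = ".lpm_integrate_cpp")]]
NumericVector lpm_integrate_cpp(NumericVector state, double t, double dt,
                                double h_max, NumericVector q0,
                                NumericVector q1, NumericVector par) {
  if (dt <= 0) stop("dt must be positive");
  const int n = (int)std::ceil(dt / h_max - 1e-12);
  const double h = dt / n;
  const double* p = par.begin();
  double s[NSTATE_LPM], k1[NSTATE_LPM], k2[NSTATE_LPM], k3[NSTATE_LPM],
         k4[NSTATE_LPM], tmp[NSTATE_LPM];
  double qa[7], qb[7], qm[7];
  std::copy(state.begin(), state.end(), s);

  for (int i = 0; i < n; ++i) {
    const double ti = t + i * h;
    const double f0 = (i * h) / dt, f1 = ((i + 1) * h) / dt,
                 fm = ((i + 0.5) * h) / dt;
    for (int b = 0; b < 7; ++b) {
      qa[b] = q0[b] + (q1[b] - q0[b]) * f0;
      qm[b] = q0[b] + (q1[b] - q0[b]) * fm;
      qb[b] = q0[b] + (q1[b] - q0[b]) * f1;
    }
    lpm_rhs_c(s, qa, ti, p, k1);
    for (int j = 0; j < NSTATE_LPM; ++j) tmp[j] = s[j] + 0.5 * h * k1[j];
    lpm_rhs_c(tmp, qm, ti + 0.5 * h, p, k2);
    for (int j = 0; j < NSTATE_LPM; ++j) tmp[j] = s[j] + 0.5 * h * k2[j];
    lpm_rhs_c(tmp, qm, ti + 0.5 * h, p, k3);
    for (int j = 0; j < NSTATE_LPM; ++j) tmp[j] = s[j] + h * k3[j];
    lpm_rhs_c(tmp, qb, ti + h, p, k4);
    for (int j = 0; j < NSTATE_LPM; ++j)
      s[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
  }
  for (int j = 0; j < NSTATE_LPM; ++j)
    if (!std::isfinite(s[j]))
      stop("non-finite state component %d after integration", j + 1);
  NumericVector out(s, s + NSTATE_LPM);
  out.attr("names") = state.attr("names");
  out.attr("n_sub") = n;
  out.attr("h_sub") = h;
  return out;
}

// ---------------------------------------------------------------------------
// Leader surrogate: 9 branches, 3 internal junctions (arch, innominate, pulmonary).
// Branch ends: positive codes 1..3 are junctions, negative codes -1..-7 boundaries.
// ---------------------------------------------------------------------------
static const int BR_FROM[9] = { -1, 1, 2, 1, 1, 1, 2, 3, 3 };
static const int BR_TO[9]   = {  1, 2, -2, -3, -4, -5, 3, -6, -7 };
static const int B2BR[7]    = { 0, 2, 3, 4, 5, 7, 8 };   // boundary -> branch

static inline double end_pressure(int code, const double* Pj, const double* Pb) {
  return code > 0 ? Pj[code - 1] : Pb[-code - 1];
}

static void solve3(double A[3][3], double b[3], double x[3]) {
  // Gaussian elimination with partial pivoting on a 3x3 system.
  int idx[3] = { 0, 1, 2 };
  for (int c = 0; c < 3; ++c) {
    int piv = c;
    for (int r = c + 1; r < 3; ++r)
      if (std::fabs(A[idx[r]][c]) > std::fabs(A[idx[piv]][c])) piv = r;
    std::swap(idx[c], idx[piv]);
    const double d = A[idx[c]][c];
    for (int r = c + 1; r < 3; ++r) {
      const double f = A[idx[r]][c] / d;
      for (int cc = c; cc < 3; ++cc) A[idx[r]][cc] -= f * A[idx[c]][cc];
      b[idx[r]] -= f * b[idx[c]];
    }
  }
  for (int c = 2; c >= 0; --c) {
    double v = b[idx[c]];
    for (int cc = c + 1; cc < 3; ++cc) v -= A[idx[c]][cc] * x[cc];
    x[c] = v / A[idx[c]][c];
  }
}

// Implicit-Euler update of one branch for a trial pressure drop:
//   Qn + a*R*Qn + a*k*Qn|Qn| = Qold + a*dP,   a = dt/L.
// Returns Qn; writes dQn/d(dP) to *deriv.
static inline double branch_implicit(double Qold, double dP, double R, double L,
                                     double k, double dt, double* deriv) {
  const double a = dt / L;
  const double c = Qold + a * dP;
  const double b = 1.0 + a * R;
  double Qn;
  if (k <= 0.0) {
    Qn = c / b;
  } else {
    const double x = (-b + std::sqrt(b * b + 4.0 * a * k * std::fabs(c))) /
                     (2.0 * a * k);
    Qn = (c >= 0.0) ? x : -x;
  }
  *deriv = a / (b + 2.0 * a * k * std::fabs(Qn));
  return Qn;
}

// One implicit macro step of the surrogate: Newton iteration on the three
// junction pressures so that net junction flow vanishes (rigid junctions).
static int leader_substep(double* Q, double* Pj, const double* Pb, double dt,
                          const double* R, const double* L, const double* k,
                          double tol, int maxit, double* resid_out) {
  double Qn[9], dQ[9];
  int iter = 0;
  double maxres = 0.0;
  for (iter = 0; iter < maxit; ++iter) {
    double r[3] = { 0, 0, 0 };
    double scale = 0.0;
    for (int b = 0; b < 9; ++b) {
      const double dP = end_pressure(BR_FROM[b], Pj, Pb) -
                        end_pressure(BR_TO[b], Pj, Pb);
      Qn[b] = branch_implicit(Q[b], dP, R[b], L[b], k[b], dt, &dQ[b]);
      if (BR_TO[b] > 0)   r[BR_TO[b] - 1]   += Qn[b];
      if (BR_FROM[b] > 0) r[BR_FROM[b] - 1] -= Qn[b];
      scale += std::fabs(Qn[b]);
    }
    scale = scale / 9.0 + 1e-9;
    maxres = std::max(std::fabs(r[0]), std::max(std::fabs(r[1]), std::fabs(r[2])));
    if (maxres / scale < tol) break;

    double J[3][3] = { { 0, 0, 0 }, { 0, 0, 0 }, { 0, 0, 0 } };
    for (int b = 0; b < 9; ++b) {
      for (int m = 0; m < 3; ++m) {
        double dd = 0.0;
        if (BR_FROM[b] == m + 1) dd += dQ[b];
        if (BR_TO[b] == m + 1)   dd -= dQ[b];
        if (dd == 0.0) continue;
        if (BR_TO[b] > 0)   J[BR_TO[b] - 1][m]   += dd;
        if (BR_FROM[b] > 0) J[BR_FROM[b] - 1][m] -= dd;
      }
    }
    double rhs[3] = { -r[0], -r[1], -r[2] }, dPj[3];
    solve3(J, rhs, dPj);
    for (int m = 0; m < 3; ++m) Pj[m] += dPj[m];
  }
  std::copy(Qn, Qn + 9, Q);
  *resid_out = maxres;
  return iter + 1;
}

// Macro step with embedded step-doubling error estimate.  The accepted
// solution is the more accurate two-half-step one.
// [[Rcpp::export(name = ".leader_macro_cpp")]]
List leader_macro_cpp(NumericVector Q, NumericVector Pj, NumericVector Pb,
                      double dt, NumericVector R, NumericVector L,
                      NumericVector k, double tol, int maxit) {
  if (dt <= 0) stop("dt must be positive");
  double Qf[9], Pjf[3], Qh[9], Pjh[3];
  std::copy(Q.begin(), Q.end(), Qf);   std::copy(Pj.begin(), Pj.end(), Pjf);
  std::copy(Q.begin(), Q.end(), Qh);   std::copy(Pj.begin(), Pj.end(), Pjh);
  double res_f, res_h1, res_h2;
  int it = 0;
  it += leader_substep(Qf, Pjf, Pb.begin(), dt, R.begin(), L.begin(), k.begin(),
                       tol, maxit, &res_f);
  it += leader_substep(Qh, Pjh, Pb.begin(), dt / 2, R.begin(), L.begin(),
                       k.begin(), tol, maxit, &res_h1);
  it += leader_substep(Qh, Pjh, Pb.begin(), dt / 2, R.begin(), L.begin(),
                       k.begin(), tol, maxit, &res_h2);
  double err = 0.0, qmax = 1.0;
  for (int b = 0; b < 9; ++b) {
    err = std::max(err, std::fabs(Qf[b] - Qh[b]));
    qmax = std::max(qmax, std::fabs(Qh[b]));
  }
  const double resid = std::max(res_h1, res_h2);
  NumericVector Qb(7);
  for (int b = 0; b < 7; ++b) Qb[b] = Qh[B2BR[b]];
  return List::create(_["Q"] = NumericVector(Qh, Qh + 9),
                      _["Pj"] = NumericVector(Pjh, Pjh + 3),
                      _["Q_bound"] = Qb,
                      _["resid"] = resid, _["iterations"] = it,
                      _["err_est"] = err / qmax);
}

// Steady network solve (dQ/dt = 0) under fixed boundary pressures; used for
// leader initialisation and as the steady_flow_solve closure over the network.
// [[Rcpp::export(name = ".leader_steady_cpp")]]
List leader_steady_cpp(NumericVector Pb, NumericVector R, NumericVector L,
                       NumericVector k, double tol, int maxit) {
  double Pj[3];
  const double pm = mean(Pb);
  Pj[0] = pm; Pj[1] = pm; Pj[2] = pm;
  double Qn[9], dQ[9];
  double maxres = 0.0;
  int iter;
  for (iter = 0; iter < maxit; ++iter) {
    double r[3] = { 0, 0, 0 }, scale = 0.0;
    for (int b = 0; b < 9; ++b) {
      const double dP = end_pressure(BR_FROM[b], Pj, Pb.begin()) -
                        end_pressure(BR_TO[b], Pj, Pb.begin());
      if (k[b] <= 0.0) {
        Qn[b] = dP / R[b];
        dQ[b] = 1.0 / R[b];
      } else {
        const double x = (-R[b] + std::sqrt(R[b] * R[b] +
                          4.0 * k[b] * std::fabs(dP))) / (2.0 * k[b]);
        Qn[b] = dP >= 0 ? x : -x;
        dQ[b] = 1.0 / (R[b] + 2.0 * k[b] * std::fabs(Qn[b]));
      }
      if (BR_TO[b] > 0)   r[BR_TO[b] - 1]   += Qn[b];
      if (BR_FROM[b] > 0) r[BR_FROM[b] - 1] -= Qn[b];
      scale += std::fabs(Qn[b]);
    }
    scale = scale / 9.0 + 1e-9;
    maxres = std::max(std::fabs(r[0]), std::max(std::fabs(r[1]), std::fabs(r[2])));
    if (maxres / scale < tol) break;
    double J[3][3] = { { 0, 0, 0 }, { 0, 0, 0 }, { 0, 0, 0 } };
    for (int b = 0; b < 9; ++b)
      for (int m = 0; m < 3; ++m) {
        double dd = 0.0;
        if (BR_FROM[b] == m + 1) dd += dQ[b];
        if (BR_TO[b] == m + 1)   dd -= dQ[b];
        if (dd == 0.0) continue;
        if (BR_TO[b] > 0)   J[BR_TO[b] - 1][m]   += dd;
        if (BR_FROM[b] > 0) J[BR_FROM[b] - 1][m] -= dd;
      }
    double rhs[3] = { -r[0], -r[1], -r[2] }, dPj[3];
    solve3(J, rhs, dPj);
    for (int m = 0; m < 3; ++m) Pj[m] += dPj[m];
  }
  NumericVector Qb(7);
  for (int b = 0; b < 7; ++b) Qb[b] = Qn[B2BR[b]];
  return List::create(_["Q"] = NumericVector(Qn, Qn + 9),
                      _["Pj"] = NumericVector(Pj, Pj + 3),
                      _["Q_bound"] = Qb,
                      _["resid"] = maxres, _["iterations"] = iter + 1);
}

// ---------------------------------------------------------------------------
// Monolithic reference system: follower states + leader branch flows in one
// ODE system; rigid-junction constraint handled by index reduction (junction
// pressures solved from a 3x3 linear system each evaluation) with Baumgarte
// stabilisation of the flow-sum drift.
// ---------------------------------------------------------------------------
static void mono_rhs_c(const double* y, double t, const double* p,
                       const double* R, const double* L, const double* k,
                       double alpha, double* d, double* Pj_out,
                       double* Pb_out) {
  const double* s = y;               // 13 follower states
  const double* Q = y + NSTATE_LPM;  // 9 branch flows
  double q[7], Pb[7];
  for (int b = 0; b < 7; ++b) q[b] = Q[B2BR[b]];
  Pb[0] = s[S_PAO] - q[0] * p[P_RPAO];
  for (int b = 0; b < 6; ++b)
    Pb[1 + b] = s[S_PBED0 + b] + q[1 + b] * p[P_BED0 + 3 * b];

  // junction pressures from d/dt(sum of junction flows) = -alpha * sum
  double A[3][3] = { { 0, 0, 0 }, { 0, 0, 0 }, { 0, 0, 0 } };
  double rhs[3] = { 0, 0, 0 };
  static const double ZERO3[3] = { 0, 0, 0 };
  for (int b = 0; b < 9; ++b) {
    const double base = (end_pressure(BR_FROM[b], ZERO3, Pb) -
                         end_pressure(BR_TO[b], ZERO3, Pb) -
                         R[b] * Q[b] - k[b] * Q[b] * std::fabs(Q[b])) / L[b];
    for (int j = 0; j < 3; ++j) {
      double s_jb = 0.0;
      if (BR_TO[b] == j + 1)   s_jb = 1.0;
      if (BR_FROM[b] == j + 1) s_jb = -1.0;
      if (s_jb == 0.0) continue;
      rhs[j] -= s_jb * base;
      rhs[j] -= alpha * s_jb * Q[b];
      for (int m = 0; m < 3; ++m) {
        double u = 0.0;
        if (BR_FROM[b] == m + 1) u += 1.0;
        if (BR_TO[b] == m + 1)   u -= 1.0;
        A[j][m] += s_jb * u / L[b];
      }
    }
  }
  double Pj[3];
  solve3(A, rhs, Pj);

  for (int b = 0; b < 9; ++b)
    d[NSTATE_LPM + b] = (end_pressure(BR_FROM[b], Pj, Pb) -
                         end_pressure(BR_TO[b], Pj, Pb) -
                         R[b] * Q[b] - k[b] * Q[b] * std::fabs(Q[b])) / L[b];
  lpm_rhs_c(s, q, t, p, d);
  if (Pj_out) std::copy(Pj, Pj + 3, Pj_out);
  if (Pb_out) std::copy(Pb, Pb + 7, Pb_out);
}

// [[Rcpp::export(name = ".mono_rhs_cpp")]]
NumericVector mono_rhs_cpp(NumericVector y, double t, NumericVector par,
                           NumericVector R, NumericVector L, NumericVector k,
                           double alpha) {
  if (y.size() != NSTATE_LPM + 9) stop("state must have %d entries", NSTATE_LPM + 9);
  NumericVector d(NSTATE_LPM + 9);
  mono_rhs_c(y.begin(), t, par.begin(), R.begin(), L.begin(), k.begin(),
             alpha, d.begin(), nullptr, nullptr);
  return d;
}

// Fixed-step RK4 run of the monolithic system with periodic recording.
// Returns a matrix: t, 22 states, 3 junction pressures, 7 boundary pressures,
// P_sv, P_a, Q_av, Q_ao  (37 columns).
// [[Rcpp::export(name = ".mono_run_cpp")]]
NumericMatrix mono_run_cpp(NumericVector y0, double t0, double t_end,
                           double h_max, NumericVector par, NumericVector R,
                           NumericVector L, NumericVector k, double alpha,
                           int stride) {
  const int nst = NSTATE_LPM + 9;
  const long nsteps = (long)std::ceil((t_end - t0) / h_max - 1e-12);
  const double h = (t_end - t0) / nsteps;
  const long nrec = nsteps / stride + 1 + ((nsteps % stride) ? 1 : 0);
  NumericMatrix out(nrec, 1 + nst + 3 + 7 + 4);
  const double* p = par.begin();
  double y[nst], k1[nst], k2[nst], k3[nst], k4[nst], tmp[nst];
  double Pj[3], Pb[7];
  std::copy(y0.begin(), y0.end(), y);

  long row = 0;
  auto record = [&](double t) {
    mono_rhs_c(y, t, p, R.begin(), L.begin(), k.begin(), alpha, tmp, Pj, Pb);
    out(row, 0) = t;
    for (int j = 0; j < nst; ++j) out(row, 1 + j) = y[j];
    for (int j = 0; j < 3; ++j) out(row, 1 + nst + j) = Pj[j];
    for (int j = 0; j < 7; ++j) out(row, 1 + nst + 3 + j) = Pb[j];
    const double Psv = elastance_at(t, p) * (y[S_VSV] - p[P_V0SV]);
    const double Pa  = (y[S_VA] - p[P_V0A]) / p[P_CA];
    out(row, 1 + nst + 10) = Psv;
    out(row, 1 + nst + 11) = Pa;
    out(row, 1 + nst + 12) = valve_q(Pa - Psv, p[P_RAV], p[P_EPS]);
    out(row, 1 + nst + 13) = valve_q(Psv - y[S_PAO], p[P_RAO], p[P_EPS]);
    ++row;
  };
  record(t0);
  for (long i = 0; i < nsteps; ++i) {
    const double t = t0 + i * h;
    mono_rhs_c(y, t, p, R.begin(), L.begin(), k.begin(), alpha, k1, nullptr, nullptr);
    for (int j = 0; j < nst; ++j) tmp[j] = y[j] + 0.5 * h * k1[j];
    mono_rhs_c(tmp, t + 0.5 * h, p, R.begin(), L.begin(), k.begin(), alpha, k2, nullptr, nullptr);
    for (int j = 0; j < nst; ++j) tmp[j] = y[j] + 0.5 * h * k2[j];
    mono_rhs_c(tmp, t + 0.5 * h, p, R.begin(), L.begin(), k.begin(), alpha, k3, nullptr, nullptr);
    for (int j = 0; j < nst; ++j) tmp[j] = y[j] + h * k3[j];
    mono_rhs_c(tmp, t + h, p, R.begin(), L.begin(), k.begin(), alpha, k4, nullptr, nullptr);
    for (int j = 0; j < nst; ++j)
      y[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    {
      // project branch flows back onto the rigid-junction manifold
      // (minimal-norm correction: Q <- Q - S^T (S S^T)^{-1} S Q)
      double* Q = y + NSTATE_LPM;
      double c[3] = { 0, 0, 0 };
      double M[3][3] = { { 0, 0, 0 }, { 0, 0, 0 }, { 0, 0, 0 } };
      for (int b = 0; b < 9; ++b) {
        double s_b[3] = { 0, 0, 0 };
        if (BR_TO[b] > 0)   s_b[BR_TO[b] - 1]   = 1.0;
        if (BR_FROM[b] > 0) s_b[BR_FROM[b] - 1] = -1.0;
        for (int j = 0; j < 3; ++j) {
          c[j] += s_b[j] * Q[b];
          for (int m = 0; m < 3; ++m) M[j][m] += s_b[j] * s_b[m];
        }
      }
      double x[3];
      solve3(M, c, x);
      for (int b = 0; b < 9; ++b) {
        if (BR_TO[b] > 0)   Q[b] -= x[BR_TO[b] - 1];
        if (BR_FROM[b] > 0) Q[b] += x[BR_FROM[b] - 1];
      }
    }
    if (((i + 1) % stride == 0) || (i + 1 == nsteps)) {
      for (int j = 0; j < nst; ++j)
        if (!std::isfinite(y[j]))
          stop("non-finite state component %d at t=%g", j + 1, t + h);
      record(t0 + (i + 1) * h);
    }
  }
  return out(Range(0, row - 1), _);
}

// ---------------------------------------------------------------------------
// CRC32 (IEEE 802.3 polynomial), for ZIP archive writing.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".crc32_cpp")]]
double crc32_cpp(RawVector data) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int j = 0; j < 8; ++j)
        c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : (c >> 1);
      table[i] = c;
    }
    init = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFu);
}
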