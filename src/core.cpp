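// Fast core: coupled CPG + muscle + skeleton right-hand side and fixed-step
// RK4 integrator.  Mirrors the pure-R reference implementations in R/ (the
// two routes are cross-checked in the test suite).
//
// State vector y (length 84):
//   [0:29]   V   membrane potentials (mV), registry order
//   [30:51]  h   NaP slow inactivation, h-carrying populations
//   [52:65]  a   muscle activations (left IP GM VL TA SO BF GA, then right)
//   [66:74]  q   shoulder x,y (m), trunk pitch, 6 joint angles (rad)
//   [75:83]  qd  generalized velocities (SI per second)
// Neural time unit is ms; mechanics are SI, converted at the interface.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int NPOP = 30, NH = 22, NMUS = 14, NQ = 9;
static const int IV = 0, IH = 30, IA = 52, IQ = 66, IQD = 75, NY = 84;

struct Pack {
  // network
  NumericMatrix edgesE, edgesI;       // rows: dst, src, w (0-based)
  std::vector<double> gamma, gNaP, gLeak, ELeak, ESynI;
  double d, Cmem, ENa, ESynE, gSynE, gSynI, Vth, Vmax;
  std::vector<int> hpop;              // registry index per h slot
  std::vector<int> hslot;             // h slot per population (-1 if none)
  // muscles
  double tau_act, tau_dact;
  std::vector<double> Fmax, lmax, l0;
  NumericMatrix Dfrac;                // 14 x 9, fraction of lmax per rad
  std::vector<double> q_neutral;
  std::vector<int> mn_pop, is_flex;
  double fl_beta, fl_omega, fl_rho, vmax, fv_af, fv_ecc_gain, fv_ecc_sat;
  double fp_k, fp_c, fp_slack;
  // feedback
  double kFv, kFl, kEf, etav, etal, etaf, l_th;
  std::vector<int> tgt_F[2], tgt_E[2]; // per side: {RG-F,IN-F,PF-F}, {RG-E,IN-E,PF-E}
  // skeleton
  double m_tr, L_tr, c_tr, I_tr, m_th, L_th, c_th, I_th;
  double m_cr, L_cr, c_cr, I_cr, m_ft, L_ft, c_ft, I_ft;
  double L_fore, grav, joint_damp, lim_k, lim_c;
  std::vector<double> lim_lo, lim_hi;  // 6 joints, rad
  // contact
  double k_n, c_n, c_t, v_belt;
  double pf_h, pf_kh, pf_ch, pf_kv, pf_cv, pf_ax, pf_hl;
  bool gravity_on, contacts_on, limits_on;
};

static double getd(List L, const char* n) { return as<double>(L[n]); }

static Pack unpack(List pk) {
  Pack P;
  P.edgesE = as<NumericMatrix>(pk["edgesE"]);
  P.edgesI = as<NumericMatrix>(pk["edgesI"]);
  P.gamma = as<std::vector<double> >(pk["gamma"]);
  P.gNaP = as<std::vector<double> >(pk["gNaP"]);
  P.gLeak = as<std::vector<double> >(pk["gLeak"]);
  P.ELeak = as<std::vector<double> >(pk["ELeak"]);
  P.ESynI = as<std::vector<double> >(pk["ESynI"]);
  P.d = getd(pk, "d"); P.Cmem = getd(pk, "Cmem"); P.ENa = getd(pk, "ENa");
  P.ESynE = getd(pk, "ESynE"); P.gSynE = getd(pk, "gSynE");
  P.gSynI = getd(pk, "gSynI"); P.Vth = getd(pk, "Vth"); P.Vmax = getd(pk, "Vmax");
  P.hpop = as<std::vector<int> >(pk["hpop"]);
  P.hslot.assign(NPOP, -1);
  for (int s = 0; s < (int)P.hpop.size(); s++) P.hslot[P.hpop[s]] = s;
  P.tau_act = getd(pk, "tau_act"); P.tau_dact = getd(pk, "tau_dact");
  P.Fmax = as<std::vector<double> >(pk["Fmax"]);
  P.lmax = as<std::vector<double> >(pk["lmax"]);
  P.l0 = as<std::vector<double> >(pk["l0"]);
  P.Dfrac = as<NumericMatrix>(pk["Dfrac"]);
  P.q_neutral = as<std::vector<double> >(pk["q_neutral"]);
  P.mn_pop = as<std::vector<int> >(pk["mn_pop"]);
  P.is_flex = as<std::vector<int> >(pk["is_flex"]);
  P.fl_beta = getd(pk, "fl_beta"); P.fl_omega = getd(pk, "fl_omega");
  P.fl_rho = getd(pk, "fl_rho"); P.vmax = getd(pk, "vmax");
  P.fv_af = getd(pk, "fv_af"); P.fv_ecc_gain = getd(pk, "fv_ecc_gain");
  P.fv_ecc_sat = getd(pk, "fv_ecc_sat");
  P.fp_k = getd(pk, "fp_k"); P.fp_c = getd(pk, "fp_c"); P.fp_slack = getd(pk, "fp_slack");
  P.kFv = getd(pk, "kFv"); P.kFl = getd(pk, "kFl"); P.kEf = getd(pk, "kEf");
  P.etav = getd(pk, "etav"); P.etal = getd(pk, "etal"); P.etaf = getd(pk, "etaf");
  P.l_th = getd(pk, "l_th");
  IntegerMatrix tf = as<IntegerMatrix>(pk["tgtF"]);   // 2 x 3
  IntegerMatrix te = as<IntegerMatrix>(pk["tgtE"]);
  for (int s = 0; s < 2; s++)
    for (int k = 0; k < 3; k++) {
      P.tgt_F[s].push_back(tf(s, k)); P.tgt_E[s].push_back(te(s, k));
    }
  P.m_tr = getd(pk, "m_tr"); P.L_tr = getd(pk, "L_tr");
  P.c_tr = getd(pk, "c_tr"); P.I_tr = getd(pk, "I_tr");
  P.m_th = getd(pk, "m_th"); P.L_th = getd(pk, "L_th");
  P.c_th = getd(pk, "c_th"); P.I_th = getd(pk, "I_th");
  P.m_cr = getd(pk, "m_cr"); P.L_cr = getd(pk, "L_cr");
  P.c_cr = getd(pk, "c_cr"); P.I_cr = getd(pk, "I_cr");
  P.m_ft = getd(pk, "m_ft"); P.L_ft = getd(pk, "L_ft");
  P.c_ft = getd(pk, "c_ft"); P.I_ft = getd(pk, "I_ft");
  P.L_fore = getd(pk, "L_fore"); P.grav = getd(pk, "grav");
  P.joint_damp = getd(pk, "joint_damp");
  P.lim_k = getd(pk, "lim_k"); P.lim_c = getd(pk, "lim_c");
  P.lim_lo = as<std::vector<double> >(pk["lim_lo"]);
  P.lim_hi = as<std::vector<double> >(pk["lim_hi"]);
  P.k_n = getd(pk, "k_n"); P.c_n = getd(pk, "c_n"); P.c_t = getd(pk, "c_t");
  P.v_belt = getd(pk, "v_belt");
  P.pf_h = getd(pk, "pf_h"); P.pf_kh = getd(pk, "pf_kh"); P.pf_ch = getd(pk, "pf_ch");
  P.pf_kv = getd(pk, "pf_kv"); P.pf_cv = getd(pk, "pf_cv"); P.pf_ax = getd(pk, "pf_ax");
  P.pf_hl = getd(pk, "pf_hl");
  P.gravity_on = as<bool>(pk["gravity_on"]);
  P.contacts_on = as<bool>(pk["contacts_on"]);
  P.limits_on = as<bool>(pk["limits_on"]);
  return P;
}

static inline double fout(double V, double Vth, double Vmax) {
  if (V <= Vth) return 0.0;
  if (V >= Vmax) return 1.0;
  return (V - Vth) / (Vmax - Vth);
}
static inline double mNaP(double V) { return 1.0 / (1.0 + std::exp(-(V + 40.0) / 6.0)); }
static inline double hinf(double V) { return 1.0 / (1.0 + std::exp((V + 45.0) / 4.0)); }
static inline double tauh(double V) { return 320.0 + 320.0 / std::cosh((V + 35.0) / 15.0); }

static inline double f_l(const Pack& P, double l) {
  return std::exp(-std::pow(std::fabs((std::pow(l, P.fl_beta) - 1.0) / P.fl_omega), P.fl_rho));
}
static inline double f_v(const Pack& P, double v) {
  if (v < 0) {
    double s = -v; if (s > P.vmax) s = P.vmax;
    return (P.vmax - s) / (P.vmax + s / P.fv_af);
  }
  return 1.0 + P.fv_ecc_gain * v / (v + P.fv_ecc_sat);
}
static inline double f_p(const Pack& P, double l) {
  double e = l - P.fp_slack;
  return e > 0 ? P.fp_k * (std::exp(P.fp_c * e) - 1.0) : 0.0;
}

// --- planar chain geometry --------------------------------------------------

struct Ang { double val; int gi[4]; double gw[4]; int ng; };

struct Geom {
  Ang trunk_back, trunk, fore;
  Ang th[2], cr[2], ft[2];   // side 0 = left (dofs 3..5), 1 = right (6..8)
};

static Geom geometry(const Pack& P, const double* q) {
  Geom G;
  double theta = q[2];
  G.trunk_back.val = theta + M_PI; G.trunk_back.gi[0] = 2; G.trunk_back.gw[0] = 1; G.trunk_back.ng = 1;
  G.trunk.val = theta; G.trunk.gi[0] = 2; G.trunk.gw[0] = 1; G.trunk.ng = 1;
  G.fore.val = theta - M_PI / 2; G.fore.gi[0] = 2; G.fore.gw[0] = 1; G.fore.ng = 1;
  double off = 135.0 * M_PI / 180.0 - M_PI / 2;
  for (int s = 0; s < 2; s++) {
    int jh = 3 + 3 * s, jk = jh + 1, ja = jh + 2;
    Ang th; th.val = theta + off - q[jh];
    th.gi[0] = 2; th.gw[0] = 1; th.gi[1] = jh; th.gw[1] = -1; th.ng = 2;
    Ang cr; cr.val = th.val - M_PI + q[jk];
    cr.gi[0] = 2; cr.gw[0] = 1; cr.gi[1] = jh; cr.gw[1] = -1;
    cr.gi[2] = jk; cr.gw[2] = 1; cr.ng = 3;
    Ang ft; ft.val = cr.val + M_PI - q[ja];
    ft.gi[0] = 2; ft.gw[0] = 1; ft.gi[1] = jh; ft.gw[1] = -1;
    ft.gi[2] = jk; ft.gw[2] = 1; ft.gi[3] = ja; ft.gw[3] = -1; ft.ng = 4;
    G.th[s] = th; G.cr[s] = cr; G.ft[s] = ft;
  }
  return G;
}

struct Point {
  double pos[2], vel[2], bias[2];
  double J[2][NQ];
  void init(const double* q, const double* qd) {
    pos[0] = q[0]; pos[1] = q[1];
    for (int r = 0; r < 2; r++) for (int c = 0; c < NQ; c++) J[r][c] = 0;
    J[0][0] = 1; J[1][1] = 1;
    bias[0] = bias[1] = 0;
    vel[0] = qd[0]; vel[1] = qd[1];
  }
  void add(double coef, const Ang& a, const double* qd) {
    double cu = std::cos(a.val), su = std::sin(a.val);
    pos[0] += coef * cu; pos[1] += coef * su;
    double ad = 0;
    for (int k = 0; k < a.ng; k++) ad += a.gw[k] * qd[a.gi[k]];
    for (int k = 0; k < a.ng; k++) {
      J[0][a.gi[k]] += coef * (-su) * a.gw[k];
      J[1][a.gi[k]] += coef * cu * a.gw[k];
    }
    vel[0] += coef * (-su) * ad; vel[1] += coef * cu * ad;
    bias[0] -= coef * ad * ad * cu; bias[1] -= coef * ad * ad * su;
  }
};

// solve A x = b (n x n), Gaussian elimination with partial pivoting
static bool solve9(double A[NQ][NQ], double* b, double* x) {
  int idx[NQ];
  for (int i = 0; i < NQ; i++) idx[i] = i;
  for (int c = 0; c < NQ; c++) {
    int p = c; double best = std::fabs(A[idx[c]][c]);
    for (int r = c + 1; r < NQ; r++)
      if (std::fabs(A[idx[r]][c]) > best) { best = std::fabs(A[idx[r]][c]); p = r; }
    if (best < 1e-12) return false;
    std::swap(idx[c], idx[p]);
    double piv = A[idx[c]][c];
    for (int r = c + 1; r < NQ; r++) {
      double f = A[idx[r]][c] / piv;
      if (f == 0) continue;
      for (int k = c; k < NQ; k++) A[idx[r]][k] -= f * A[idx[c]][k];
      b[idx[r]] -= f * b[idx[c]];
    }
  }
  for (int c = NQ - 1; c >= 0; c--) {
    double s = b[idx[c]];
    for (int k = c + 1; k < NQ; k++) s -= A[idx[c]][k] * x[k];
    x[c] = s / A[idx[c]][c];
  }
  return true;
}

struct RhsDiag {
  double l[NMUS], v[NMUS], F[NMUS], u[NMUS], s[NPOP];
  double FnL, FtL, FnR, FtR, qdd[NQ], torque[6], hip_y, toeL[2], toeR[2];
};

// Full coupled right-hand side.  groundh: per-limb local ground height;
// holeL: left support absent; frozen: mechanics held (settle phase).
static bool rhs(const Pack& P, const double* y, double gL, double gR,
                bool holeL, bool frozen, double* dy, RhsDiag* diag) {
  const double* V = y + IV; const double* h = y + IH;
  const double* a = y + IA; const double* q = y + IQ; const double* qd = y + IQD;

  // muscle lengths / velocities (fraction of lmax, lmax/s)
  double l[NMUS], v[NMUS];
  for (int m = 0; m < NMUS; m++) {
    double li = P.l0[m], vi = 0;
    for (int c = 0; c < NQ; c++) {
      double dmc = P.Dfrac(m, c);
      if (dmc != 0) { li += dmc * (q[c] - P.q_neutral[c]); vi += dmc * qd[c]; }
    }
    l[m] = li; v[m] = frozen ? 0.0 : vi;
  }
  // motor commands and forces
  double u[NMUS], F[NMUS];
  for (int m = 0; m < NMUS; m++) {
    u[m] = fout(V[P.mn_pop[m]], P.Vth, P.Vmax);
    double f = P.Fmax[m] * (a[m] * f_l(P, l[m]) * f_v(P, v[m]) + f_p(P, l[m]));
    F[m] = f > 0 ? f : 0;
  }
  // afferent feedback (absent while the skeleton is frozen: the settle
  // phase lets the CPG reach its limit cycle in fictive conditions)
  double s[NPOP];
  for (int j = 0; j < NPOP; j++) s[j] = 0;
  for (int m = 0; m < NMUS && !frozen; m++) {
    int side = m / 7;
    if (P.is_flex[m]) {
      double vhat = v[m] > 0 ? v[m] : 0;
      double lhat = l[m] > P.l_th ? l[m] - P.l_th : 0;
      double vp = vhat > 0 ? std::pow(vhat, 0.6) : 0;
      double base = P.kFv * vp + P.kFl * lhat;
      for (int k = 0; k < 3; k++) s[P.tgt_F[side][k]] += base;
      s[P.mn_pop[m]] += P.etav * P.kFv * vp + P.etal * P.kFl * lhat;
    } else {
      double Fhat = F[m] > 0 ? F[m] / P.Fmax[m] : 0;
      for (int k = 0; k < 3; k++) s[P.tgt_E[side][k]] += P.kEf * Fhat;
      s[P.mn_pop[m]] += P.etaf * P.kEf * Fhat;
    }
  }
  // network derivatives
  double excit[NPOP], inhib[NPOP], fv[NPOP];
  for (int j = 0; j < NPOP; j++) {
    fv[j] = fout(V[j], P.Vth, P.Vmax);
    excit[j] = P.gamma[j] * P.d + s[j];
    inhib[j] = 0;
  }
  for (int e = 0; e < P.edgesE.nrow(); e++)
    excit[(int)P.edgesE(e, 0)] += P.edgesE(e, 2) * fv[(int)P.edgesE(e, 1)];
  for (int e = 0; e < P.edgesI.nrow(); e++)
    inhib[(int)P.edgesI(e, 0)] += P.edgesI(e, 2) * fv[(int)P.edgesI(e, 1)];
  for (int j = 0; j < NPOP; j++) {
    double ISynE = P.gSynE * (V[j] - P.ESynE) * excit[j];
    double ISynI = P.gSynI * (V[j] - P.ESynI[j]) * inhib[j];
    double ILeak = P.gLeak[j] * (V[j] - P.ELeak[j]);
    double INaP = 0;
    int slot = P.hslot[j];
    if (slot >= 0) {
      INaP = P.gNaP[j] * mNaP(V[j]) * h[slot] * (V[j] - P.ENa);
      dy[IH + slot] = (hinf(V[j]) - h[slot]) / tauh(V[j]);
    }
    dy[IV + j] = (-INaP - ILeak - ISynE - ISynI) / P.Cmem;
  }
  // activation filter (per ms)
  double r = P.tau_act / P.tau_dact;
  for (int m = 0; m < NMUS; m++)
    dy[IA + m] = u[m] / P.tau_act - (r + (1 - r) * u[m]) * a[m] / P.tau_act;

  // mechanics
  Geom G = geometry(P, q);
  double Q[NQ]; double M[NQ][NQ];
  for (int i = 0; i < NQ; i++) { Q[i] = 0; for (int j2 = 0; j2 < NQ; j2++) M[i][j2] = 0; }

  struct Body { double m, I; const Ang* own; Point pt; };
  Body bodies[7];
  // trunk
  bodies[0].m = P.m_tr; bodies[0].I = P.I_tr; bodies[0].own = &G.trunk;
  bodies[0].pt.init(q, qd); bodies[0].pt.add(P.c_tr * P.L_tr, G.trunk_back, qd);
  int bi = 1;
  for (int sdx = 0; sdx < 2; sdx++) {
    Body& bt = bodies[bi++];
    bt.m = P.m_th; bt.I = P.I_th; bt.own = &G.th[sdx];
    bt.pt.init(q, qd); bt.pt.add(P.L_tr, G.trunk_back, qd);
    bt.pt.add(P.c_th * P.L_th, G.th[sdx], qd);
    Body& bc = bodies[bi++];
    bc.m = P.m_cr; bc.I = P.I_cr; bc.own = &G.cr[sdx];
    bc.pt.init(q, qd); bc.pt.add(P.L_tr, G.trunk_back, qd);
    bc.pt.add(P.L_th, G.th[sdx], qd); bc.pt.add(P.c_cr * P.L_cr, G.cr[sdx], qd);
    Body& bf = bodies[bi++];
    bf.m = P.m_ft; bf.I = P.I_ft; bf.own = &G.ft[sdx];
    bf.pt.init(q, qd); bf.pt.add(P.L_tr, G.trunk_back, qd);
    bf.pt.add(P.L_th, G.th[sdx], qd); bf.pt.add(P.L_cr, G.cr[sdx], qd);
    bf.pt.add(P.c_ft * P.L_ft, G.ft[sdx], qd);
  }
  for (int b = 0; b < 7; b++) {
    Body& B = bodies[b];
    for (int i = 0; i < NQ; i++) {
      for (int j2 = i; j2 < NQ; j2++) {
        double mij = B.m * (B.pt.J[0][i] * B.pt.J[0][j2] + B.pt.J[1][i] * B.pt.J[1][j2]);
        M[i][j2] += mij;
      }
    }
    for (int ki = 0; ki < B.own->ng; ki++)
      for (int kj = 0; kj < B.own->ng; kj++) {
        int i = B.own->gi[ki], j2 = B.own->gi[kj];
        if (j2 >= i) M[i][j2] += B.I * B.own->gw[ki] * B.own->gw[kj];
        }
    for (int i = 0; i < NQ; i++) {
      double bx = -B.m * (B.pt.J[0][i] * B.pt.bias[0] + B.pt.J[1][i] * B.pt.bias[1]);
      if (P.gravity_on) bx += B.pt.J[1][i] * (-B.m * P.grav);
      Q[i] += bx;
    }
  }
  for (int i = 0; i < NQ; i++)
    for (int j2 = 0; j2 < i; j2++) M[i][j2] = M[j2][i];

  // muscle torques, damping, soft limits on the 6 joint coordinates
  double torque[6];
  for (int jj = 0; jj < 6; jj++) {
    int c = 3 + jj;
    double tq = 0;
    for (int m = 0; m < NMUS; m++) {
      double dmc = P.Dfrac(m, c);
      if (dmc != 0) tq -= dmc * P.lmax[m] * F[m];
    }
    tq -= P.joint_damp * qd[c];
    if (P.limits_on) {
      if (q[c] > P.lim_hi[jj]) tq += -P.lim_k * (q[c] - P.lim_hi[jj]) - P.lim_c * qd[c];
      if (q[c] < P.lim_lo[jj]) tq += -P.lim_k * (q[c] - P.lim_lo[jj]) - P.lim_c * qd[c];
    }
    torque[jj] = tq;
    Q[c] += tq;
  }

  // contact and platform forces
  double FnL = 0, FtL = 0, FnR = 0, FtR = 0;
  Point toe[2];
  for (int sdx = 0; sdx < 2; sdx++) {
    toe[sdx].init(q, qd);
    toe[sdx].add(P.L_tr, G.trunk_back, qd);
    toe[sdx].add(P.L_th, G.th[sdx], qd);
    toe[sdx].add(P.L_cr, G.cr[sdx], qd);
    toe[sdx].add(P.L_ft, G.ft[sdx], qd);
  }
  if (P.contacts_on) {
    for (int sdx = 0; sdx < 2; sdx++) {
      double gh = sdx == 0 ? gL : gR;
      bool hole = (sdx == 0) && holeL;
      double pen = gh - toe[sdx].pos[1];
      double fx = 0, fy = 0;
      if (!hole && pen > 0) {
        double ramp = pen < 0.001 ? pen / 0.001 : 1.0;
        fy = P.k_n * pen + P.c_n * (-toe[sdx].vel[1]) * ramp;
        if (fy < 0) fy = 0;
        fx = -P.c_t * (toe[sdx].vel[0] + P.v_belt) * ramp;
      }
      if (sdx == 0) { FnL = fy; FtL = fx; } else { FnR = fy; FtR = fx; }
      for (int i = 0; i < NQ; i++)
        Q[i] += toe[sdx].J[0][i] * fx + toe[sdx].J[1][i] * fy;
    }
    // forelimb tip
    Point fp; fp.init(q, qd); fp.add(P.L_fore, G.fore, qd);
    double fx = -P.pf_kh * (fp.pos[0] - P.pf_ax) - P.pf_ch * fp.vel[0];
    double fy = 0;
    double pen = P.pf_h - fp.pos[1];
    if (pen > 0) {
      double ramp = pen < 0.001 ? pen / 0.001 : 1.0;
      double edge = (P.pf_hl + 0.01 - std::fabs(fp.pos[0] - P.pf_ax)) / 0.01;
      if (edge > 1) edge = 1; if (edge < 0) edge = 0;
      fy = P.pf_kv * pen + P.pf_cv * (-fp.vel[1]) * ramp;
      if (fy < 0) fy = 0;
      fy *= edge;
    }
    for (int i = 0; i < NQ; i++) Q[i] += fp.J[0][i] * fx + fp.J[1][i] * fy;
  }

  double qdd[NQ];
  if (frozen) {
    for (int i = 0; i < NQ; i++) { dy[IQ + i] = 0; dy[IQD + i] = 0; qdd[i] = 0; }
  } else {
    double A[NQ][NQ], bvec[NQ];
    for (int i = 0; i < NQ; i++) { bvec[i] = Q[i]; for (int j2 = 0; j2 < NQ; j2++) A[i][j2] = M[i][j2]; }
    if (!solve9(A, bvec, qdd)) return false;
    for (int i = 0; i < NQ; i++) {
      dy[IQ + i] = qd[i] / 1000.0;    // per-ms time base
      dy[IQD + i] = qdd[i] / 1000.0;
    }
  }

  if (diag) {
    for (int m = 0; m < NMUS; m++) { diag->l[m] = l[m]; diag->v[m] = v[m]; diag->F[m] = F[m]; diag->u[m] = u[m]; }
    for (int j = 0; j < NPOP; j++) diag->s[j] = s[j];
    diag->FnL = FnL; diag->FtL = FtL; diag->FnR = FnR; diag->FtR = FtR;
    for (int i = 0; i < NQ; i++) diag->qdd[i] = qdd[i];
    for (int jj = 0; jj < 6; jj++) diag->torque[jj] = torque[jj];
    diag->hip_y = q[1] - P.L_tr * std::sin(q[2]);
    diag->toeL[0] = toe[0].pos[0]; diag->toeL[1] = toe[0].pos[1];
    diag->toeR[0] = toe[1].pos[0]; diag->toeR[1] = toe[1].pos[1];
  }
  return true;
}

// [[Rcpp::export]]
List cpp_rhs(List pk, NumericVector y, double gL, double gR,
             bool holeL, bool frozen) {
  Pack P = unpack(pk);
  std::vector<double> dy(NY, 0.0);
  RhsDiag d;
  bool ok = rhs(P, REAL(y), gL, gR, holeL, frozen, dy.data(), &d);
  if (!ok) stop("singular mass matrix");
  return List::create(_["dy"] = NumericVector(dy.begin(), dy.end()),
                      _["l"] = NumericVector(d.l, d.l + NMUS),
                      _["v"] = NumericVector(d.v, d.v + NMUS),
                      _["F"] = NumericVector(d.F, d.F + NMUS),
                      _["u"] = NumericVector(d.u, d.u + NMUS),
                      _["s"] = NumericVector(d.s, d.s + NPOP),
                      _["contact"] = NumericVector::create(d.FnL, d.FtL, d.FnR, d.FtR),
                      _["qdd"] = NumericVector(d.qdd, d.qdd + NQ),
                      _["torque"] = NumericVector(d.torque, d.torque + 6),
                      _["hip_y"] = d.hip_y);
}

// [[Rcpp::export]]
List cpp_simulate(List pk, NumericVector y0, List scen, double dt_ms,
                  double settle_ms, int stride, double cap_s,
                  double fall_hip, double airborne_factor,
                  double airborne_default, double debounce_ms) {
  Pack P = unpack(pk);
  int type = as<int>(scen["type"]);   // 0 flat, 1 random, 2 hole
  NumericVector drawsL = scen["drawsL"], drawsR = scen["drawsR"];
  double hole_on = as<double>(scen["hole_on"]), hole_off = as<double>(scen["hole_off"]);
  // trigger 1: the window opens at the first left-foot landing attempt
  // at or after hole_on (the foot steps "into" the hole)
  int hole_trigger = scen.containsElementNamed("trigger") ? as<int>(scen["trigger"]) : 0;
  double hole_len = hole_off - hole_on;
  bool hole_armed = (type == 2) && hole_trigger == 1;
  double hole_t0 = hole_on, hole_t1 = hole_trigger == 1 ? -1 : hole_off;

  std::vector<double> y(y0.begin(), y0.end()), k1(NY), k2(NY), k3(NY), k4(NY), tmp(NY);
  double gh[2] = {0.0, 0.0};
  int drawi[2] = {0, 0};
  long n_settle = (long)std::floor(settle_ms / dt_ms + 0.5);
  long n_run = (long)std::floor(cap_s * 1000.0 / dt_ms + 0.5);
  long n_log = n_run / stride + 2;

  NumericVector t_out(n_log);
  NumericMatrix Y(n_log, NY), Lm(n_log, NMUS), Vm(n_log, NMUS), Fm(n_log, NMUS),
                Sm(n_log, NPOP), Cm(n_log, 4), Gm(n_log, 2);
  std::vector<double> ev_t; std::vector<int> ev_limb, ev_type;

  bool inContact[2] = {false, false};
  bool pendVal[2] = {false, false}; bool pending[2] = {false, false};
  double pendSince[2] = {0, 0};
  double lastLiftoff[2] = {0, 0};    // airborne start (s)
  double lastTD[2] = {-1, -1};
  double cycle[2] = {-1, -1};
  double act_int = 0;
  double fall_time = NA_REAL;
  int status = 0;                     // 0 ok/cap, 1 fall, 2 numeric failure
  long logi = 0;
  RhsDiag dg;

  // settle: mechanics frozen
  for (long i = 0; i < n_settle; i++) {
    if (!rhs(P, y.data(), gh[0], gh[1], false, true, k1.data(), NULL)) { status = 2; break; }
    for (int j = 0; j < NY; j++) tmp[j] = y[j] + 0.5 * dt_ms * k1[j];
    rhs(P, tmp.data(), gh[0], gh[1], false, true, k2.data(), NULL);
    for (int j = 0; j < NY; j++) tmp[j] = y[j] + 0.5 * dt_ms * k2[j];
    rhs(P, tmp.data(), gh[0], gh[1], false, true, k3.data(), NULL);
    for (int j = 0; j < NY; j++) tmp[j] = y[j] + dt_ms * k3[j];
    rhs(P, tmp.data(), gh[0], gh[1], false, true, k4.data(), NULL);
    for (int j = 0; j < NY; j++)
      y[j] += dt_ms / 6.0 * (k1[j] + 2 * k2[j] + 2 * k3[j] + k4[j]);
  }

  double T_end = cap_s;
  long i = 0;
  if (status == 0) for (i = 0; i <= n_run; i++) {
    double t_s = i * dt_ms / 1000.0;
    bool holeL;
    if (hole_trigger == 1) {
      double toe_y = 0;
      if (type == 2 && (hole_armed || hole_t1 < 0) ) {
        Geom G = geometry(P, &y[IQ]);
        Point toe; toe.init(&y[IQ], &y[IQD]);
        toe.add(P.L_tr, G.trunk_back, &y[IQD]);
        toe.add(P.L_th, G.th[0], &y[IQD]);
        toe.add(P.L_cr, G.cr[0], &y[IQD]);
        toe.add(P.L_ft, G.ft[0], &y[IQD]);
        toe_y = toe.pos[1];
      }
      if (hole_armed && t_s >= hole_on && !inContact[0] && toe_y < gh[0]) {
        // the unsupported foot meets the hole: one missed contact
        hole_armed = false; hole_t0 = t_s;
      }
      if (!hole_armed && hole_t1 < 0) {
        // active until the foot is lifted clear of the surface (the hole
        // travels on with the belt), or at most hole_len as a safety cap
        if (toe_y > gh[0] + 0.005 || t_s > hole_t0 + hole_len)
          hole_t1 = t_s;
      }
      holeL = (type == 2) && !hole_armed && hole_t1 < 0;
    } else {
      holeL = (type == 2) && t_s >= hole_on && t_s < hole_off;
    }
    // evaluate diagnostics at current state (also first RK stage)
    if (!rhs(P, y.data(), gh[0], gh[1], holeL, false, k1.data(), &dg)) { status = 2; T_end = t_s; break; }
    bool bad = false;
    for (int j = 0; j < NY; j++) if (!std::isfinite(y[j])) bad = true;
    if (bad) { status = 2; T_end = t_s; break; }

    if (i % stride == 0 && logi < n_log) {
      t_out[logi] = t_s;
      for (int j = 0; j < NY; j++) Y(logi, j) = y[j];
      for (int m = 0; m < NMUS; m++) { Lm(logi, m) = dg.l[m]; Vm(logi, m) = dg.v[m]; Fm(logi, m) = dg.F[m]; }
      for (int j = 0; j < NPOP; j++) Sm(logi, j) = dg.s[j];
      Cm(logi, 0) = dg.FnL; Cm(logi, 1) = dg.FtL; Cm(logi, 2) = dg.FnR; Cm(logi, 3) = dg.FtR;
      Gm(logi, 0) = gh[0]; Gm(logi, 1) = gh[1];
      logi++;
    }
    // cost integrand (per s)
    double sa2 = 0;
    for (int m = 0; m < NMUS; m++) sa2 += y[IA + m] * y[IA + m];
    act_int += sa2 * dt_ms / 1000.0;

    // contact state machine (debounced)
    for (int sdx = 0; sdx < 2; sdx++) {
      bool raw = (sdx == 0 ? dg.FnL : dg.FnR) > 0;
      if (raw != inContact[sdx]) {
        if (!pending[sdx] || pendVal[sdx] != raw) {
          pending[sdx] = true; pendVal[sdx] = raw; pendSince[sdx] = t_s;
        } else if ((t_s - pendSince[sdx]) * 1000.0 >= debounce_ms) {
          inContact[sdx] = raw; pending[sdx] = false;
          double tev = pendSince[sdx];
          ev_t.push_back(tev); ev_limb.push_back(sdx); ev_type.push_back(raw ? 1 : 2);
          if (raw) {           // touchdown
            if (lastTD[sdx] >= 0) cycle[sdx] = tev - lastTD[sdx];
            lastTD[sdx] = tev;
          } else {             // liftoff: redraw the belt height for this limb
            lastLiftoff[sdx] = tev;
            if (type == 1) {
              NumericVector& dr = sdx == 0 ? drawsL : drawsR;
              if (drawi[sdx] < dr.size()) gh[sdx] = dr[drawi[sdx]++];
            }
          }
        }
      } else pending[sdx] = false;
    }
    // fall criteria
    if (dg.hip_y < fall_hip) { status = 1; fall_time = t_s; T_end = t_s; break; }
    for (int sdx = 0; sdx < 2; sdx++) {
      if (!inContact[sdx]) {
        double limit = cycle[sdx] > 0 ? airborne_factor * cycle[sdx] : airborne_default;
        double airborne = t_s - (lastLiftoff[sdx] > 0 ? lastLiftoff[sdx] : 0.0);
        if (airborne > limit) { status = 1; fall_time = t_s; T_end = t_s; break; }
      }
    }
    if (status == 1) break;
    if (i == n_run) { T_end = cap_s; break; }

    bool hL2 = holeL;  // hole flag evaluated at step start (dt is tiny)
    for (int j = 0; j < NY; j++) tmp[j] = y[j] + 0.5 * dt_ms * k1[j];
    if (!rhs(P, tmp.data(), gh[0], gh[1], hL2, false, k2.data(), NULL)) { status = 2; T_end = t_s; break; }
    for (int j = 0; j < NY; j++) tmp[j] = y[j] + 0.5 * dt_ms * k2[j];
    if (!rhs(P, tmp.data(), gh[0], gh[1], hL2, false, k3.data(), NULL)) { status = 2; T_end = t_s; break; }
    for (int j = 0; j < NY; j++) tmp[j] = y[j] + dt_ms * k3[j];
    if (!rhs(P, tmp.data(), gh[0], gh[1], hL2, false, k4.data(), NULL)) { status = 2; T_end = t_s; break; }
    for (int j = 0; j < NY; j++)
      y[j] += dt_ms / 6.0 * (k1[j] + 2 * k2[j] + 2 * k3[j] + k4[j]);
  }

  NumericMatrix events(ev_t.size(), 3);
  for (size_t e = 0; e < ev_t.size(); e++) {
    events(e, 0) = ev_t[e]; events(e, 1) = ev_limb[e]; events(e, 2) = ev_type[e];
  }
  return List::create(_["t"] = t_out[Range(0, std::max((long)0, logi - 1))],
                      _["Y"] = Y(Range(0, std::max((long)0, logi - 1)), _),
                      _["L"] = Lm(Range(0, std::max((long)0, logi - 1)), _),
                      _["Vmus"] = Vm(Range(0, std::max((long)0, logi - 1)), _),
                      _["Fmus"] = Fm(Range(0, std::max((long)0, logi - 1)), _),
                      _["S"] = Sm(Range(0, std::max((long)0, logi - 1)), _),
                      _["contact"] = Cm(Range(0, std::max((long)0, logi - 1)), _),
                      _["ground"] = Gm(Range(0, std::max((long)0, logi - 1)), _),
                      _["events"] = events,
                      _["fall_time"] = fall_time,
                      _["T_walked"] = T_end,
                      _["status"] = status,
                      _["hole_window"] = NumericVector::create(hole_t0, hole_t1),
                      _["act_integral"] = act_int,
                      _["y_end"] = NumericVector(y.begin(), y.end()));
}

// Network-only integrator (mechanics absent): used by the network tests
// and the nullcline machinery.  s is a constant external feedback vector.
// [[Rcpp::export]]
List cpp_network_sim(List pk, NumericVector V0, NumericVector h0,
                     NumericVector s, double dt_ms, double t_end_ms,
                     int stride) {
  Pack P = unpack(pk);
  std::vector<double> V(V0.begin(), V0.end()), h(h0.begin(), h0.end());
  long n = (long)std::floor(t_end_ms / dt_ms + 0.5);
  long n_log = n / stride + 2;
  NumericVector t_out(n_log);
  NumericMatrix Vout(n_log, NPOP), Hout(n_log, NH);
  long logi = 0;
  std::vector<double> dV(NPOP), dh(NH), dV2(NPOP), dh2(NH), dV3(NPOP), dh3(NH),
      dV4(NPOP), dh4(NH), Vt(NPOP), ht(NH);
  auto deriv = [&](const std::vector<double>& Vv, const std::vector<double>& hv,
                   std::vector<double>& oV, std::vector<double>& oh) {
    double excit[NPOP], inhib[NPOP], fv[NPOP];
    for (int j = 0; j < NPOP; j++) {
      fv[j] = fout(Vv[j], P.Vth, P.Vmax);
      excit[j] = P.gamma[j] * P.d + s[j];
      inhib[j] = 0;
    }
    for (int e = 0; e < P.edgesE.nrow(); e++)
      excit[(int)P.edgesE(e, 0)] += P.edgesE(e, 2) * fv[(int)P.edgesE(e, 1)];
    for (int e = 0; e < P.edgesI.nrow(); e++)
      inhib[(int)P.edgesI(e, 0)] += P.edgesI(e, 2) * fv[(int)P.edgesI(e, 1)];
    for (int j = 0; j < NPOP; j++) {
      double ISynE = P.gSynE * (Vv[j] - P.ESynE) * excit[j];
      double ISynI = P.gSynI * (Vv[j] - P.ESynI[j]) * inhib[j];
      double ILeak = P.gLeak[j] * (Vv[j] - P.ELeak[j]);
      double INaP = 0;
      int slot = P.hslot[j];
      if (slot >= 0) {
        INaP = P.gNaP[j] * mNaP(Vv[j]) * hv[slot] * (Vv[j] - P.ENa);
        oh[slot] = (hinf(Vv[j]) - hv[slot]) / tauh(Vv[j]);
      }
      oV[j] = (-INaP - ILeak - ISynE - ISynI) / P.Cmem;
    }
  };
  for (long i = 0; i <= n; i++) {
    if (i % stride == 0 && logi < n_log) {
      t_out[logi] = i * dt_ms;
      for (int j = 0; j < NPOP; j++) Vout(logi, j) = V[j];
      for (int j = 0; j < NH; j++) Hout(logi, j) = h[j];
      logi++;
    }
    if (i == n) break;
    deriv(V, h, dV, dh);
    for (int j = 0; j < NPOP; j++) Vt[j] = V[j] + 0.5 * dt_ms * dV[j];
    for (int j = 0; j < NH; j++) ht[j] = h[j] + 0.5 * dt_ms * dh[j];
    deriv(Vt, ht, dV2, dh2);
    for (int j = 0; j < NPOP; j++) Vt[j] = V[j] + 0.5 * dt_ms * dV2[j];
    for (int j = 0; j < NH; j++) ht[j] = h[j] + 0.5 * dt_ms * dh2[j];
    deriv(Vt, ht, dV3, dh3);
    for (int j = 0; j < NPOP; j++) Vt[j] = V[j] + dt_ms * dV3[j];
    for (int j = 0; j < NH; j++) ht[j] = h[j] + dt_ms * dh3[j];
    deriv(Vt, ht, dV4, dh4);
    for (int j = 0; j < NPOP; j++)
      V[j] += dt_ms / 6.0 * (dV[j] + 2 * dV2[j] + 2 * dV3[j] + dV4[j]);
    for (int j = 0; j < NH; j++)
      h[j] += dt_ms / 6.0 * (dh[j] + 2 * dh2[j] + 2 * dh3[j] + dh4[j]);
  }
  return List::create(_["t"] = t_out[Range(0, logi - 1)],
                      _["V"] = Vout(Range(0, logi - 1), _),
                      _["h"] = Hout(Range(0, logi - 1), _));
}
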