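// Pair kernels, system energy/force evaluation and the multiple-timestep
// stochastic-dynamics propagator.  All randomness is drawn from R's RNG
// (GetRNGstate/norm_rand) so trajectories are reproducible under set.seed().
//
// Internal units: length Å, time fs, mass g/mol, energy kJ/mol, charge e,
// dipole e·Å, temperature K, pressure atm.
// 1 kJ/mol = 1e-4 g/mol Å²/fs² (FCONV below).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double COUL  = 1389.35458;      // kJ Å / (mol e^2)
static const double KB    = 0.008314462618;  // kJ/mol/K
static const double FCONV = 1.0e-4;          // kJ/mol -> g/mol Å^2/fs^2
static const double KECONV = 1.0e4;          // g/mol (Å/fs)^2 -> kJ/mol
static const double PATM  = 16388.246;       // kJ/mol/Å^3 -> atm
static const double R_OVERLAP = 1.0e-6;      // Å, hard overlap threshold

// ---------------------------------------------------------------------------
// shifted-force radial kernels: value and derivative both vanish at rc
// ---------------------------------------------------------------------------

// 1/r kernel (charge-charge)
static inline void sf_g1(double r, double rc, double &g, double &dg) {
  g  = 1.0 / r - 1.0 / rc + (r - rc) / (rc * rc);
  dg = -1.0 / (r * r) + 1.0 / (rc * rc);
}
// 1/r^3 kernel (charge-dipole, dipole-dipole isotropic part)
static inline void sf_s3(double r, double rc, double &s, double &ds) {
  double rc3 = rc * rc * rc, rc4 = rc3 * rc;
  s  = 1.0 / (r * r * r) - 1.0 / rc3 + 3.0 * (r - rc) / rc4;
  ds = -3.0 / (r * r * r * r) + 3.0 / rc4;
}
// 1/r^5 kernel (dipole-dipole anisotropic part)
static inline void sf_s5(double r, double rc, double &s, double &ds) {
  double rc5 = pow(rc, 5), rc6 = rc5 * rc;
  s  = 1.0 / pow(r, 5) - 1.0 / rc5 + 5.0 * (r - rc) / rc6;
  ds = -5.0 / pow(r, 6) + 5.0 / rc6;
}

// plain LJ energy and radial derivative dU/dr
static inline void lj_plain(double r, double sig, double eps, double &u, double &du) {
  double sr = sig / r;
  double sr6 = sr * sr * sr; sr6 *= sr6;
  double sr12 = sr6 * sr6;
  u  = 4.0 * eps * (sr12 - sr6);
  du = -24.0 * eps * (2.0 * sr12 - sr6) / r;
}
// shifted-force LJ: U(r) - U(rc) - (r-rc) U'(rc); F_r = -(U'(r) - U'(rc))
static inline void lj_sf(double r, double rc, double sig, double eps,
                         double &u, double &fr) {
  double u0, du0, uc, duc;
  lj_plain(r, sig, eps, u0, du0);
  lj_plain(rc, sig, eps, uc, duc);
  u  = u0 - uc - (r - rc) * duc;
  fr = -(du0 - duc);
}

// ---------------------------------------------------------------------------
// single-pair evaluators (exported; the system loop reuses the same kernels)
// rvec = r_i - r_j (points from j to i); force returned acts on i.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List pair_lj_sf_cpp(NumericVector rvec, double sig_i, double eps_i,
                    double sig_j, double eps_j, double rcut) {
  double r2 = rvec[0]*rvec[0] + rvec[1]*rvec[1] + rvec[2]*rvec[2];
  double r = sqrt(r2);
  if (r < R_OVERLAP) stop("site overlap: |r| = %g Å", r);
  NumericVector f(3);
  double e = 0.0;
  if (r < rcut) {
    double sig = 0.5 * (sig_i + sig_j);
    double eps = sqrt(eps_i * eps_j);
    double fr;
    lj_sf(r, rcut, sig, eps, e, fr);
    for (int k = 0; k < 3; ++k) f[k] = fr * rvec[k] / r;
  }
  return List::create(_["energy"] = e, _["force_i"] = f);
}

// dipole-dipole, mu_i and mu_j full dipole vectors (e Å)
// [[Rcpp::export]]
List pair_dd_sf_cpp(NumericVector rvec, NumericVector mi, NumericVector mj,
                    double rcut) {
  double r2 = rvec[0]*rvec[0] + rvec[1]*rvec[1] + rvec[2]*rvec[2];
  double r = sqrt(r2);
  if (r < R_OVERLAP) stop("site overlap: |r| = %g Å", r);
  NumericVector f(3), ti(3), tj(3);
  double e = 0.0;
  if (r < rcut) {
    double s3, ds3, s5, ds5;
    sf_s3(r, rcut, s3, ds3);
    sf_s5(r, rcut, s5, ds5);
    double mm = mi[0]*mj[0] + mi[1]*mj[1] + mi[2]*mj[2];
    double mir = mi[0]*rvec[0] + mi[1]*rvec[1] + mi[2]*rvec[2];
    double mjr = mj[0]*rvec[0] + mj[1]*rvec[1] + mj[2]*rvec[2];
    e = COUL * (mm * s3 - 3.0 * mir * mjr * s5);
    // F_i = -dU/drvec
    for (int k = 0; k < 3; ++k) {
      double grad = mm * ds3 * rvec[k] / r
        - 3.0 * (mjr * mi[k] + mir * mj[k]) * s5
        - 3.0 * mir * mjr * ds5 * rvec[k] / r;
      f[k] = -COUL * grad;
    }
    // field at i from j: E_i = -dU/dmi
    double Ei[3], Ej[3];
    for (int k = 0; k < 3; ++k) {
      Ei[k] = -COUL * (mj[k] * s3 - 3.0 * rvec[k] * mjr * s5);
      Ej[k] = -COUL * (mi[k] * s3 - 3.0 * rvec[k] * mir * s5);
    }
    ti[0] = mi[1]*Ei[2] - mi[2]*Ei[1];
    ti[1] = mi[2]*Ei[0] - mi[0]*Ei[2];
    ti[2] = mi[0]*Ei[1] - mi[1]*Ei[0];
    tj[0] = mj[1]*Ej[2] - mj[2]*Ej[1];
    tj[1] = mj[2]*Ej[0] - mj[0]*Ej[2];
    tj[2] = mj[0]*Ej[1] - mj[1]*Ej[0];
  }
  return List::create(_["energy"] = e, _["force_i"] = f,
                      _["torque_i"] = ti, _["torque_j"] = tj);
}

// charge q at site j, dipole vector m at site i; rvec = r_i - r_j
// [[Rcpp::export]]
List pair_qd_sf_cpp(NumericVector rvec, double q, NumericVector m, double rcut) {
  double r2 = rvec[0]*rvec[0] + rvec[1]*rvec[1] + rvec[2]*rvec[2];
  double r = sqrt(r2);
  if (r < R_OVERLAP) stop("site overlap: |r| = %g Å", r);
  NumericVector f(3), tq(3);
  double e = 0.0;
  if (r < rcut && q != 0.0) {
    // U = -C q (m . rhat)/r^2 with rvec from the charge to the dipole
    double s3, ds3;
    sf_s3(r, rcut, s3, ds3);
    double mr = m[0]*rvec[0] + m[1]*rvec[1] + m[2]*rvec[2];
    e = -COUL * q * mr * s3;
    for (int k = 0; k < 3; ++k)
      f[k] = COUL * q * (m[k] * s3 + mr * ds3 * rvec[k] / r);
    double E[3];
    for (int k = 0; k < 3; ++k) E[k] = COUL * q * rvec[k] * s3;
    tq[0] = m[1]*E[2] - m[2]*E[1];
    tq[1] = m[2]*E[0] - m[0]*E[2];
    tq[2] = m[0]*E[1] - m[1]*E[0];
  }
  return List::create(_["energy"] = e, _["force_i"] = f, _["torque_i"] = tq);
}

// [[Rcpp::export]]
List pair_qq_sf_cpp(NumericVector rvec, double qi, double qj, double rcut) {
  double r2 = rvec[0]*rvec[0] + rvec[1]*rvec[1] + rvec[2]*rvec[2];
  double r = sqrt(r2);
  if (r < R_OVERLAP) stop("site overlap: |r| = %g Å", r);
  NumericVector f(3);
  double e = 0.0;
  if (r < rcut && qi != 0.0 && qj != 0.0) {
    double g, dg;
    sf_g1(r, rcut, g, dg);
    e = COUL * qi * qj * g;
    for (int k = 0; k < 3; ++k) f[k] = -COUL * qi * qj * dg * rvec[k] / r;
  }
  return List::create(_["energy"] = e, _["force_i"] = f);
}

// ---------------------------------------------------------------------------
// system container used by both the evaluator and the propagator
// ---------------------------------------------------------------------------

struct SysRef {
  int n;
  double *pos, *dip;                 // n x 3 column-major
  const double *sigma, *eps, *charge, *mu, *mass, *inertia;
  const int *iscg, *molid, *role;    // role: 0 solute, 1 solvent
  const double *bonds; int nb;       // nb x 4: i, j, r0, k (0-based already)
  double box[3];
  double rcut;
  double lambda_f;                   // scaling of solute-solvent energy
};

struct EvalOut {
  double e_ss, e_sv_raw, e_uu, e_bond, virial;
  void zero() { e_ss = e_sv_raw = e_uu = e_bond = virial = 0.0; }
};

static inline double mimg(double dx, double L) {
  return dx - L * nearbyint(dx / L);
}

// evaluate one nonbonded pair; accumulates into force/torque arrays (n x 3)
// split: 0 all, 1 outer (CG-CG only), 2 inner (everything else)
static inline void nb_pair(const SysRef &S, int i, int j, int split,
                           double *frc, double *trq, EvalOut &out) {
  bool cgpair = S.iscg[i] && S.iscg[j];
  if (split == 1 && !cgpair) return;
  if (split == 2 && cgpair) return;
  int n = S.n;
  double rv[3];
  for (int k = 0; k < 3; ++k)
    rv[k] = mimg(S.pos[i + k*n] - S.pos[j + k*n], S.box[k]);
  double r2 = rv[0]*rv[0] + rv[1]*rv[1] + rv[2]*rv[2];
  if (r2 >= S.rcut * S.rcut) return;
  double r = sqrt(r2);
  if (r < R_OVERLAP)
    stop("site overlap between sites %d and %d (|r| = %g Å)", i + 1, j + 1, r);

  bool sv = (S.role[i] != S.role[j]);
  bool ss = (S.role[i] == 1 && S.role[j] == 1);
  double scale = sv ? S.lambda_f : 1.0;

  double e = 0.0, fi[3] = {0, 0, 0};

  if (S.eps[i] > 0.0 && S.eps[j] > 0.0) {
    double sig = 0.5 * (S.sigma[i] + S.sigma[j]);
    double epsij = sqrt(S.eps[i] * S.eps[j]);
    double u, fr;
    lj_sf(r, S.rcut, sig, epsij, u, fr);
    e += u;
    for (int k = 0; k < 3; ++k) fi[k] += fr * rv[k] / r;
  }

  bool di = S.mu[i] > 0.0, dj = S.mu[j] > 0.0;
  double qi = S.charge[i], qj = S.charge[j];

  if (qi != 0.0 && qj != 0.0) {
    double g, dg;
    sf_g1(r, S.rcut, g, dg);
    e += COUL * qi * qj * g;
    for (int k = 0; k < 3; ++k) fi[k] += -COUL * qi * qj * dg * rv[k] / r;
  }

  if (di || dj) {
    double s3, ds3;
    sf_s3(r, S.rcut, s3, ds3);
    double mi[3] = {0,0,0}, mj[3] = {0,0,0};
    if (di) for (int k = 0; k < 3; ++k) mi[k] = S.mu[i] * S.dip[i + k*n];
    if (dj) for (int k = 0; k < 3; ++k) mj[k] = S.mu[j] * S.dip[j + k*n];

    if (di && dj) {
      double s5, ds5;
      sf_s5(r, S.rcut, s5, ds5);
      double mm  = mi[0]*mj[0] + mi[1]*mj[1] + mi[2]*mj[2];
      double mir = mi[0]*rv[0] + mi[1]*rv[1] + mi[2]*rv[2];
      double mjr = mj[0]*rv[0] + mj[1]*rv[1] + mj[2]*rv[2];
      e += COUL * (mm * s3 - 3.0 * mir * mjr * s5);
      for (int k = 0; k < 3; ++k) {
        double grad = mm * ds3 * rv[k] / r
          - 3.0 * (mjr * mi[k] + mir * mj[k]) * s5
          - 3.0 * mir * mjr * ds5 * rv[k] / r;
        fi[k] += -COUL * grad;
      }
      // torques tau = m x E, E = -dU/dm
      double Ei[3], Ej[3];
      for (int k = 0; k < 3; ++k) {
        Ei[k] = -COUL * (mj[k] * s3 - 3.0 * rv[k] * mjr * s5);
        Ej[k] = -COUL * (mi[k] * s3 - 3.0 * rv[k] * mir * s5);
      }
      trq[i + 0*n] += scale * (mi[1]*Ei[2] - mi[2]*Ei[1]);
      trq[i + 1*n] += scale * (mi[2]*Ei[0] - mi[0]*Ei[2]);
      trq[i + 2*n] += scale * (mi[0]*Ei[1] - mi[1]*Ei[0]);
      trq[j + 0*n] += scale * (mj[1]*Ej[2] - mj[2]*Ej[1]);
      trq[j + 1*n] += scale * (mj[2]*Ej[0] - mj[0]*Ej[2]);
      trq[j + 2*n] += scale * (mj[0]*Ej[1] - mj[1]*Ej[0]);
    } else if (di && qj != 0.0) {
      // dipole at i, charge at j; rv points from the charge to the dipole
      double mir = mi[0]*rv[0] + mi[1]*rv[1] + mi[2]*rv[2];
      e += -COUL * qj * mir * s3;
      for (int k = 0; k < 3; ++k)
        fi[k] += COUL * qj * (mi[k] * s3 + mir * ds3 * rv[k] / r);
      double E[3];
      for (int k = 0; k < 3; ++k) E[k] = COUL * qj * rv[k] * s3;
      trq[i + 0*n] += scale * (mi[1]*E[2] - mi[2]*E[1]);
      trq[i + 1*n] += scale * (mi[2]*E[0] - mi[0]*E[2]);
      trq[i + 2*n] += scale * (mi[0]*E[1] - mi[1]*E[0]);
    } else if (dj && qi != 0.0) {
      // dipole at j, charge at i; -rv points from the charge to the dipole
      double mjr = mj[0]*rv[0] + mj[1]*rv[1] + mj[2]*rv[2];
      e += COUL * qi * mjr * s3;
      for (int k = 0; k < 3; ++k)
        fi[k] += -COUL * qi * (mj[k] * s3 + mjr * ds3 * rv[k] / r);
      double E[3];
      for (int k = 0; k < 3; ++k) E[k] = -COUL * qi * rv[k] * s3;
      trq[j + 0*n] += scale * (mj[1]*E[2] - mj[2]*E[1]);
      trq[j + 1*n] += scale * (mj[2]*E[0] - mj[0]*E[2]);
      trq[j + 2*n] += scale * (mj[0]*E[1] - mj[1]*E[0]);
    }
  }

  for (int k = 0; k < 3; ++k) {
    frc[i + k*n] += scale * fi[k];
    frc[j + k*n] -= scale * fi[k];
  }
  out.virial += scale * (fi[0]*rv[0] + fi[1]*rv[1] + fi[2]*rv[2]);
  if (ss) out.e_ss += e;
  else if (sv) out.e_sv_raw += e;  // stored unscaled; total adds lambda_f * e
  else out.e_uu += e;
}

static void eval_bonds(const SysRef &S, int split, double *frc, EvalOut &out) {
  if (split == 1) return;  // bonded terms integrate on the inner timestep
  int n = S.n;
  for (int b = 0; b < S.nb; ++b) {
    int i = (int)S.bonds[b + 0*S.nb];
    int j = (int)S.bonds[b + 1*S.nb];
    double r0 = S.bonds[b + 2*S.nb], kk = S.bonds[b + 3*S.nb];
    double rv[3];
    for (int k = 0; k < 3; ++k)
      rv[k] = mimg(S.pos[i + k*n] - S.pos[j + k*n], S.box[k]);
    double r = sqrt(rv[0]*rv[0] + rv[1]*rv[1] + rv[2]*rv[2]);
    if (r < R_OVERLAP) stop("bonded sites %d and %d overlap", i + 1, j + 1);
    // E = k (r - r0)^2 (no 1/2); F on i = -2k(r - r0) rhat
    out.e_bond += kk * (r - r0) * (r - r0);
    double fr = -2.0 * kk * (r - r0);
    for (int k = 0; k < 3; ++k) {
      double f = fr * rv[k] / r;
      frc[i + k*n] += f;
      frc[j + k*n] -= f;
    }
    out.virial += fr * r;
  }
}

// full evaluation; method 0 = brute O(N^2), 1 = cell list
static void eval_system(const SysRef &S, int split, int method,
                        double *frc, double *trq, EvalOut &out) {
  int n = S.n;
  out.zero();
  std::fill(frc, frc + 3*n, 0.0);
  std::fill(trq, trq + 3*n, 0.0);

  int nc[3];
  bool cell_ok = true;
  for (int k = 0; k < 3; ++k) {
    nc[k] = (int)floor(S.box[k] / S.rcut);
    if (nc[k] < 3) cell_ok = false;
  }
  if (method == 0 || !cell_ok) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (S.molid[i] == S.molid[j]) continue;  // intramolecular excluded
        nb_pair(S, i, j, split, frc, trq, out);
      }
  } else {
    int ncell = nc[0] * nc[1] * nc[2];
    std::vector<int> head(ncell, -1), nxt(n, -1);
    for (int i = 0; i < n; ++i) {
      int c[3];
      for (int k = 0; k < 3; ++k) {
        double x = S.pos[i + k*n] / S.box[k];
        x -= floor(x);                       // wrap into [0,1)
        c[k] = (int)(x * nc[k]);
        if (c[k] >= nc[k]) c[k] = nc[k] - 1;
      }
      int ci = c[0] + nc[0] * (c[1] + nc[1] * c[2]);
      nxt[i] = head[ci];
      head[ci] = i;
    }
    for (int cz = 0; cz < nc[2]; ++cz)
      for (int cy = 0; cy < nc[1]; ++cy)
        for (int cx = 0; cx < nc[0]; ++cx) {
          int ci = cx + nc[0] * (cy + nc[1] * cz);
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                int ex = (cx + dx + nc[0]) % nc[0];
                int ey = (cy + dy + nc[1]) % nc[1];
                int ez = (cz + dz + nc[2]) % nc[2];
                int cj = ex + nc[0] * (ey + nc[1] * ez);
                if (cj < ci) continue;
                for (int i = head[ci]; i >= 0; i = nxt[i])
                  for (int j = head[cj]; j >= 0; j = nxt[j]) {
                    if (ci == cj && j >= i) continue;
                    if (S.molid[i] == S.molid[j]) continue;
                    nb_pair(S, i, j, split, frc, trq, out);
                  }
              }
        }
  }
  eval_bonds(S, split, frc, out);
}

static SysRef make_sysref(NumericMatrix &pos, NumericMatrix &dip,
                          NumericVector &box,
                          NumericVector &sigma, NumericVector &eps,
                          NumericVector &charge, NumericVector &mu,
                          NumericVector &mass, NumericVector &inertia,
                          IntegerVector &iscg, IntegerVector &molid,
                          IntegerVector &role, NumericMatrix &bonds,
                          double rcut, double lambda_f) {
  SysRef S;
  S.n = pos.nrow();
  S.pos = pos.begin(); S.dip = dip.begin();
  S.sigma = sigma.begin(); S.eps = eps.begin();
  S.charge = charge.begin(); S.mu = mu.begin();
  S.mass = mass.begin(); S.inertia = inertia.begin();
  S.iscg = iscg.begin(); S.molid = molid.begin(); S.role = role.begin();
  S.bonds = bonds.begin(); S.nb = bonds.nrow();
  for (int k = 0; k < 3; ++k) S.box[k] = box[k];
  S.rcut = rcut;
  S.lambda_f = lambda_f;
  return S;
}

// [[Rcpp::export]]
List ff_eval_cpp(NumericMatrix pos, NumericMatrix dip, NumericVector box,
                 NumericVector sigma, NumericVector eps, NumericVector charge,
                 NumericVector mu, NumericVector mass, NumericVector inertia,
                 IntegerVector iscg, IntegerVector molid, IntegerVector role,
                 NumericMatrix bonds, double rcut, double lambda_f,
                 int split, int method) {
  NumericMatrix p = clone(pos), d = clone(dip);
  SysRef S = make_sysref(p, d, box, sigma, eps, charge, mu, mass, inertia,
                         iscg, molid, role, bonds, rcut, lambda_f);
  int n = S.n;
  NumericMatrix frc(n, 3), trq(n, 3);
  EvalOut out;
  eval_system(S, split, method, frc.begin(), trq.begin(), out);
  double total = out.e_ss + S.lambda_f * out.e_sv_raw + out.e_uu + out.e_bond;
  return List::create(
    _["e_total"] = total, _["e_ss"] = out.e_ss,
    _["e_sv"] = S.lambda_f * out.e_sv_raw, _["e_sv_raw"] = out.e_sv_raw,
    _["e_solute"] = out.e_uu, _["e_bond"] = out.e_bond,
    _["forces"] = frc, _["torques"] = trq, _["virial"] = out.virial);
}

// ---------------------------------------------------------------------------
// SHAKE: iterative distance-constraint solver
// constraints: m x 3 (i, j, d) with 0-based indices
// ---------------------------------------------------------------------------

static int shake_core(const double *ref, double *pos, int n,
                      const double *cons, int m, const double *invmass,
                      const double *box, double tol, int maxit,
                      double *delta /* n x 3 accumulated corrections, may be NULL */) {
  for (int it = 0; it < maxit; ++it) {
    bool done = true;
    for (int c = 0; c < m; ++c) {
      int i = (int)cons[c + 0*m], j = (int)cons[c + 1*m];
      double d0 = cons[c + 2*m];
      double rij[3], sij[3];
      for (int k = 0; k < 3; ++k) {
        rij[k] = mimg(pos[i + k*n] - pos[j + k*n], box[k]);
        sij[k] = mimg(ref[i + k*n] - ref[j + k*n], box[k]);
      }
      double r2 = rij[0]*rij[0] + rij[1]*rij[1] + rij[2]*rij[2];
      double diff = r2 - d0 * d0;
      if (fabs(diff) > tol) {
        done = false;
        double rs = rij[0]*sij[0] + rij[1]*sij[1] + rij[2]*sij[2];
        if (fabs(rs) < 1e-12)
          stop("SHAKE failure: displaced bond orthogonal to reference (constraint %d)", c + 1);
        double g = diff / (2.0 * rs * (invmass[i] + invmass[j]));
        for (int k = 0; k < 3; ++k) {
          double di = -g * sij[k] * invmass[i];
          double dj =  g * sij[k] * invmass[j];
          pos[i + k*n] += di;
          pos[j + k*n] += dj;
          if (delta) { delta[i + k*n] += di; delta[j + k*n] += dj; }
        }
      }
    }
    if (done) return it;
  }
  // report worst constraint
  int worst = 0; double wdev = -1.0;
  for (int c = 0; c < m; ++c) {
    int i = (int)cons[c + 0*m], j = (int)cons[c + 1*m];
    double d0 = cons[c + 2*m], r2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      double dxk = mimg(pos[i + k*n] - pos[j + k*n], box[k]);
      r2 += dxk * dxk;
    }
    double dev = fabs(r2 - d0 * d0);
    if (dev > wdev) { wdev = dev; worst = c; }
  }
  stop("SHAKE did not converge in %d iterations (worst constraint %d, |d^2 - d0^2| = %g)",
       maxit, worst + 1, wdev);
  return -1;
}

// [[Rcpp::export]]
List shake_cpp(NumericMatrix ref, NumericMatrix pos, NumericMatrix constraints,
               NumericVector invmass, NumericVector box,
               double tol, int maxit) {
  NumericMatrix out = clone(pos);
  int iters = 0;
  if (constraints.nrow() > 0)
    iters = shake_core(ref.begin(), out.begin(), out.nrow(),
                       constraints.begin(), constraints.nrow(),
                       invmass.begin(), box.begin(), tol, maxit, NULL);
  return List::create(_["positions"] = out, _["iterations"] = iters);
}

// ---------------------------------------------------------------------------
// rigid-rotor helpers for the point-dipole orientation dynamics
// ---------------------------------------------------------------------------

static inline void rodrigues(double *u, const double *axis, double angle) {
  double ax = axis[0], ay = axis[1], az = axis[2];
  double nrm = sqrt(ax*ax + ay*ay + az*az);
  if (nrm < 1e-300) return;
  ax /= nrm; ay /= nrm; az /= nrm;
  double c = cos(angle), s = sin(angle);
  double dotau = ax*u[0] + ay*u[1] + az*u[2];
  double cx = ay*u[2] - az*u[1];
  double cy = az*u[0] - ax*u[2];
  double cz = ax*u[1] - ay*u[0];
  double v0 = u[0]*c + cx*s + ax*dotau*(1.0 - c);
  double v1 = u[1]*c + cy*s + ay*dotau*(1.0 - c);
  double v2 = u[2]*c + cz*s + az*dotau*(1.0 - c);
  double n2 = sqrt(v0*v0 + v1*v1 + v2*v2);
  u[0] = v0/n2; u[1] = v1/n2; u[2] = v2/n2;
}

// [[Rcpp::export]]
NumericVector rotate_unit_cpp(NumericVector u, NumericVector omega, double dt) {
  NumericVector v = clone(u);
  double w = sqrt(omega[0]*omega[0] + omega[1]*omega[1] + omega[2]*omega[2]);
  if (w > 0) {
    double ax[3] = {omega[0], omega[1], omega[2]};
    double uu[3] = {v[0], v[1], v[2]};
    rodrigues(uu, ax, w * dt);
    v[0] = uu[0]; v[1] = uu[1]; v[2] = uu[2];
  }
  return v;
}

// ---------------------------------------------------------------------------
// multiple-timestep stochastic-dynamics propagator
//
// Impulse (r-RESPA) splitting: CG-CG nonbonded forces kick at the outer
// timestep dt_inner * mts_ratio; all other forces (and torques) integrate
// with BAOAB Langevin steps at dt_inner.  Rotational degrees of freedom of
// dipolar beads use the same friction as translation.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List md_run_cpp(NumericMatrix pos0, NumericMatrix dip0, NumericMatrix vel0,
                NumericMatrix avel0, NumericVector box0,
                NumericVector sigma, NumericVector eps, NumericVector charge,
                NumericVector mu, NumericVector mass, NumericVector inertia,
                IntegerVector iscg, IntegerVector molid, IntegerVector role,
                NumericMatrix bonds, NumericMatrix constraints,
                double rcut, double dt_inner, int mts_ratio, int n_outer,
                bool thermostat, double temperature,
                double gamma_solute, double gamma_solvent,
                bool barostat, double p0, double tau_p, double kappa,
                double lambda_f, int sample_every, int method,
                double shake_tol, int shake_maxit) {
  NumericMatrix pos = clone(pos0), dip = clone(dip0);
  NumericMatrix vel = clone(vel0), avel = clone(avel0);
  NumericVector box = clone(box0);
  int n = pos.nrow();
  int m = constraints.nrow();
  double dt_outer = dt_inner * mts_ratio;

  SysRef S = make_sysref(pos, dip, box, sigma, eps, charge, mu, mass, inertia,
                         iscg, molid, role, bonds, rcut, lambda_f);

  std::vector<double> f_in(3*n), t_in(3*n), f_out(3*n), t_out(3*n);
  std::vector<double> invmass(n), ref(3*n), delta(3*n);
  for (int i = 0; i < n; ++i) invmass[i] = 1.0 / mass[i];

  std::vector<int> dipsite;
  for (int i = 0; i < n; ++i) if (mu[i] > 0.0) dipsite.push_back(i);
  int ndip = (int)dipsite.size();

  // molecule site lists for barostat center scaling
  int nmol = 0;
  for (int i = 0; i < n; ++i) if (molid[i] > nmol) nmol = molid[i];
  std::vector<std::vector<int> > mols(nmol);
  for (int i = 0; i < n; ++i) mols[molid[i] - 1].push_back(i);

  EvalOut out_in, out_out;
  eval_system(S, 2, method, f_in.data(), t_in.data(), out_in);
  eval_system(S, 1, method, f_out.data(), t_out.data(), out_out);

  double ndof_t = 3.0 * n - m;
  double ndof_r = 2.0 * ndip;

  int nsamp = (sample_every > 0) ? n_outer / sample_every : 0;
  NumericMatrix obs(nsamp, 12);
  CharacterVector obs_names = CharacterVector::create(
    "time_fs", "e_pot", "e_ss", "e_sv", "e_solute", "e_bond",
    "e_kin_trans", "e_kin_rot", "temperature", "pressure", "volume",
    "u_sv_raw");
  int isamp = 0;

  GetRNGstate();

  double c1t[2] = {1.0, 1.0}, c2t[2] = {0.0, 0.0};
  if (thermostat) {
    double gs[2] = {gamma_solute, gamma_solvent};
    for (int g = 0; g < 2; ++g) {
      c1t[g] = exp(-gs[g] * dt_inner);
      c2t[g] = sqrt(1.0 - c1t[g] * c1t[g]);
    }
  }
  double kT = KB * temperature;

  double ket_mid = 0.0, ker_mid = 0.0;  // half-step KE accumulators

  for (int step = 0; step < n_outer; ++step) {
    ket_mid = 0.0; ker_mid = 0.0;
    // outer half-kick (CG-CG impulse)
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        vel(i, k) += 0.5 * dt_outer * f_out[i + k*n] * FCONV * invmass[i];
    for (int d = 0; d < ndip; ++d) {
      int i = dipsite[d];
      for (int k = 0; k < 3; ++k)
        avel(i, k) += 0.5 * dt_outer * t_out[i + k*n] * FCONV / inertia[i];
      double dotu = avel(i,0)*dip(i,0) + avel(i,1)*dip(i,1) + avel(i,2)*dip(i,2);
      for (int k = 0; k < 3; ++k) avel(i, k) -= dotu * dip(i, k);
    }

    for (int sub = 0; sub < mts_ratio; ++sub) {
      // B: inner half-kick
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          vel(i, k) += 0.5 * dt_inner * f_in[i + k*n] * FCONV * invmass[i];
      for (int d = 0; d < ndip; ++d) {
        int i = dipsite[d];
        for (int k = 0; k < 3; ++k)
          avel(i, k) += 0.5 * dt_inner * t_in[i + k*n] * FCONV / inertia[i];
        double dotu = avel(i,0)*dip(i,0) + avel(i,1)*dip(i,1) + avel(i,2)*dip(i,2);
        for (int k = 0; k < 3; ++k) avel(i, k) -= dotu * dip(i, k);
      }
      // A: half-drift (+ SHAKE)
      for (int rep = 0; rep < 2; ++rep) {
        if (m > 0) std::copy(pos.begin(), pos.end(), ref.begin());
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < 3; ++k)
            pos(i, k) += 0.5 * dt_inner * vel(i, k);
        for (int d = 0; d < ndip; ++d) {
          int i = dipsite[d];
          double w[3] = {avel(i,0), avel(i,1), avel(i,2)};
          double wn = sqrt(w[0]*w[0] + w[1]*w[1] + w[2]*w[2]);
          if (wn > 0) {
            double u[3] = {dip(i,0), dip(i,1), dip(i,2)};
            rodrigues(u, w, wn * 0.5 * dt_inner);
            dip(i,0) = u[0]; dip(i,1) = u[1]; dip(i,2) = u[2];
          }
        }
        if (m > 0) {
          std::fill(delta.begin(), delta.end(), 0.0);
          shake_core(ref.data(), pos.begin(), n, constraints.begin(), m,
                     invmass.data(), box.begin(), shake_tol, shake_maxit,
                     delta.data());
          double inv_dt = 1.0 / (0.5 * dt_inner);
          for (int i = 0; i < n; ++i)
            for (int k = 0; k < 3; ++k)
              vel(i, k) += delta[i + k*n] * inv_dt;
        }
        // O: thermostat between the two half-drifts
        if (rep == 0 && thermostat) {
          for (int i = 0; i < n; ++i) {
            int g = role[i];
            double sv = sqrt(kT * FCONV * invmass[i]);
            for (int k = 0; k < 3; ++k)
              vel(i, k) = c1t[g] * vel(i, k) + c2t[g] * sv * norm_rand();
          }
          for (int d = 0; d < ndip; ++d) {
            int i = dipsite[d];
            int g = role[i];
            double sw = sqrt(kT * FCONV / inertia[i]);
            for (int k = 0; k < 3; ++k)
              avel(i, k) = c1t[g] * avel(i, k) + c2t[g] * sw * norm_rand();
            double dotu = avel(i,0)*dip(i,0) + avel(i,1)*dip(i,1) + avel(i,2)*dip(i,2);
            for (int k = 0; k < 3; ++k) avel(i, k) -= dotu * dip(i, k);
          }
        }
        // mid-step (between-kicks) kinetic energies: together with the
        // on-step values below these give the half-step-averaged kinetic
        // temperature, cancelling the leading finite-timestep bias
        if (rep == 0) {
          for (int i = 0; i < n; ++i)
            ket_mid += 0.5 * mass[i] * (vel(i,0)*vel(i,0) +
                                        vel(i,1)*vel(i,1) +
                                        vel(i,2)*vel(i,2));
          for (int d = 0; d < ndip; ++d) {
            int i = dipsite[d];
            ker_mid += 0.5 * inertia[i] * (avel(i,0)*avel(i,0) +
                                           avel(i,1)*avel(i,1) +
                                           avel(i,2)*avel(i,2));
          }
        }
      }
      // recompute inner forces, then B: inner half-kick
      eval_system(S, 2, method, f_in.data(), t_in.data(), out_in);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          vel(i, k) += 0.5 * dt_inner * f_in[i + k*n] * FCONV * invmass[i];
      for (int d = 0; d < ndip; ++d) {
        int i = dipsite[d];
        for (int k = 0; k < 3; ++k)
          avel(i, k) += 0.5 * dt_inner * t_in[i + k*n] * FCONV / inertia[i];
        double dotu = avel(i,0)*dip(i,0) + avel(i,1)*dip(i,1) + avel(i,2)*dip(i,2);
        for (int k = 0; k < 3; ++k) avel(i, k) -= dotu * dip(i, k);
      }
    }

    // recompute outer forces, outer half-kick
    eval_system(S, 1, method, f_out.data(), t_out.data(), out_out);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        vel(i, k) += 0.5 * dt_outer * f_out[i + k*n] * FCONV * invmass[i];
    for (int d = 0; d < ndip; ++d) {
      int i = dipsite[d];
      for (int k = 0; k < 3; ++k)
        avel(i, k) += 0.5 * dt_outer * t_out[i + k*n] * FCONV / inertia[i];
      double dotu = avel(i,0)*dip(i,0) + avel(i,1)*dip(i,1) + avel(i,2)*dip(i,2);
      for (int k = 0; k < 3; ++k) avel(i, k) -= dotu * dip(i, k);
    }

    // instantaneous kinetic energy / temperature / pressure
    double ket = 0.0, ker = 0.0;
    for (int i = 0; i < n; ++i)
      ket += 0.5 * mass[i] * (vel(i,0)*vel(i,0) + vel(i,1)*vel(i,1) +
                              vel(i,2)*vel(i,2));
    for (int d = 0; d < ndip; ++d) {
      int i = dipsite[d];
      ker += 0.5 * inertia[i] * (avel(i,0)*avel(i,0) + avel(i,1)*avel(i,1) +
                                 avel(i,2)*avel(i,2));
    }
    ket *= KECONV; ker *= KECONV;
    double ketm = ket_mid / mts_ratio * KECONV;
    double kerm = ker_mid / mts_ratio * KECONV;
    double Tinst = (ket + ketm + ker + kerm) / (KB * (ndof_t + ndof_r));
    double vol = box[0] * box[1] * box[2];
    double vir = out_in.virial + out_out.virial;
    double Pinst = (2.0 * ket + vir) / (3.0 * vol) * PATM;

    if (barostat) {
      double fac = 1.0 - (dt_outer / tau_p) * kappa * (p0 - Pinst);
      if (fac < 0.5) fac = 0.5;
      if (fac > 2.0) fac = 2.0;
      double musc = cbrt(fac);
      for (int k = 0; k < 3; ++k) {
        if (box[k] * musc < 2.0 * rcut)
          stop("barostat shrank the box below twice the cutoff; "
               "use a larger box or higher density");
        box[k] *= musc;
      }
      // scale molecule centers, preserve internal geometry
      for (int mmm = 0; mmm < nmol; ++mmm) {
        const std::vector<int> &sv2 = mols[mmm];
        int i0 = sv2[0];
        double cen[3];
        for (int k = 0; k < 3; ++k) {
          double c = 0.0;
          for (size_t a = 0; a < sv2.size(); ++a) {
            double rel = (a == 0) ? 0.0
              : mimg(pos(sv2[a], k) - pos(i0, k), box[k] / musc);
            c += pos(i0, k) + rel;
          }
          cen[k] = c / sv2.size();
        }
        for (int k = 0; k < 3; ++k) {
          double shift = (musc - 1.0) * cen[k];
          for (size_t a = 0; a < sv2.size(); ++a) pos(sv2[a], k) += shift;
        }
      }
      // energies/forces are recomputed next step; refresh now for sampling
      eval_system(S, 2, method, f_in.data(), t_in.data(), out_in);
      eval_system(S, 1, method, f_out.data(), t_out.data(), out_out);
    }

    if (sample_every > 0 && (step + 1) % sample_every == 0 && isamp < nsamp) {
      double ess = out_in.e_ss + out_out.e_ss;
      double esv_raw = out_in.e_sv_raw + out_out.e_sv_raw;
      double euu = out_in.e_uu + out_out.e_uu;
      double ebd = out_in.e_bond + out_out.e_bond;
      double epot = ess + lambda_f * esv_raw + euu + ebd;
      obs(isamp, 0) = (step + 1) * dt_outer;
      obs(isamp, 1) = epot;
      obs(isamp, 2) = ess;
      obs(isamp, 3) = lambda_f * esv_raw;
      obs(isamp, 4) = euu;
      obs(isamp, 5) = ebd;
      obs(isamp, 6) = ket;
      obs(isamp, 7) = ker;
      obs(isamp, 8) = Tinst;
      obs(isamp, 9) = Pinst;
      obs(isamp, 10) = vol;
      obs(isamp, 11) = esv_raw;
      ++isamp;
    }
  }

  PutRNGstate();

  colnames(obs) = obs_names;
  return List::create(
    _["positions"] = pos, _["dipoles"] = dip,
    _["velocities"] = vel, _["angular_velocities"] = avel,
    _["box"] = box, _["observables"] = obs);
}
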