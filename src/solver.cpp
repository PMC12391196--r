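// Quasi-static tibiofemoral equilibrium core.
//
// State: q = (VrVl, IE, ML, AP, SI) in radians / mm with flexion prescribed.
// Femur pose from joint coordinates (left-knee convention):
//   R = Rz(+IE) * Ry(-VrVl) * Rx(+FE)
//   p = -ML*e1 - AP*e2 - SI*e3,  e1 = R[,1], e3 = z, e2 = unit(z x e1)
// Energy in N*mm; torque loads arrive already converted to N*mm.
//
// Fibers matrix (n x 9):  ox oy oz ix iy iz L0 k eps_l
// Contacts matrix (m x 16): cx cy cz r px py pz nx ny nz dishR s1 s2 s3 b1 b2

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

typedef double vec3[3];
typedef double mat3[3][3];

static inline void mat_mul(const mat3 A, const mat3 B, mat3 C) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += A[i][k] * B[k][j];
      C[i][j] = s;
    }
}

static inline void mat_vec(const mat3 A, const double* v, double* out) {
  for (int i = 0; i < 3; ++i)
    out[i] = A[i][0] * v[0] + A[i][1] * v[1] + A[i][2] * v[2];
}

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static void rot_x(double a, mat3 R) {
  double c = std::cos(a), s = std::sin(a);
  R[0][0] = 1; R[0][1] = 0;  R[0][2] = 0;
  R[1][0] = 0; R[1][1] = c;  R[1][2] = -s;
  R[2][0] = 0; R[2][1] = s;  R[2][2] = c;
}
static void rot_y(double a, mat3 R) {
  double c = std::cos(a), s = std::sin(a);
  R[0][0] = c;  R[0][1] = 0; R[0][2] = s;
  R[1][0] = 0;  R[1][1] = 1; R[1][2] = 0;
  R[2][0] = -s; R[2][1] = 0; R[2][2] = c;
}
static void rot_z(double a, mat3 R) {
  double c = std::cos(a), s = std::sin(a);
  R[0][0] = c; R[0][1] = -s; R[0][2] = 0;
  R[1][0] = s; R[1][1] = c;  R[1][2] = 0;
  R[2][0] = 0; R[2][1] = 0;  R[2][2] = 1;
}
static void drot_y(double a, mat3 R) {
  double c = std::cos(a), s = std::sin(a);
  R[0][0] = -s; R[0][1] = 0; R[0][2] = c;
  R[1][0] = 0;  R[1][1] = 0; R[1][2] = 0;
  R[2][0] = -c; R[2][1] = 0; R[2][2] = -s;
}
static void drot_z(double a, mat3 R) {
  double c = std::cos(a), s = std::sin(a);
  R[0][0] = -s; R[0][1] = -c; R[0][2] = 0;
  R[1][0] = c;  R[1][1] = -s; R[1][2] = 0;
  R[2][0] = 0;  R[2][1] = 0;  R[2][2] = 0;
}

// tension-only fiber law: force and energy
static inline void fiber_law(double L, double L0, double k, double eps,
                             double& f, double& u) {
  double d = L - L0;
  if (d <= 0 || k <= 0) { f = 0; u = 0; return; }
  double dt = 2.0 * eps * L0;
  if (d <= dt) {
    f = k * d * d / (4.0 * eps * L0);
    u = k * d * d * d / (12.0 * eps * L0);
  } else {
    f = k * (d - eps * L0);
    double u_toe = k * dt * dt * dt / (12.0 * eps * L0);
    double a1 = d - eps * L0, a0 = dt - eps * L0;
    u = u_toe + 0.5 * k * (a1 * a1 - a0 * a0);
  }
}

// tri-linear contact law: force and energy as function of overclosure
static inline void contact_law(double d, const double* s, const double* b,
                               double& f, double& u) {
  if (d <= 0) { f = 0; u = 0; return; }
  double f1 = s[0] * b[0];
  double f2 = f1 + s[1] * (b[1] - b[0]);
  double u1 = 0.5 * s[0] * b[0] * b[0];
  double u2 = u1 + f1 * (b[1] - b[0]) + 0.5 * s[1] * (b[1] - b[0]) * (b[1] - b[0]);
  if (d <= b[0]) { f = s[0] * d; u = 0.5 * s[0] * d * d; }
  else if (d <= b[1]) {
    f = f1 + s[1] * (d - b[0]);
    u = u1 + f1 * (d - b[0]) + 0.5 * s[1] * (d - b[0]) * (d - b[0]);
  } else {
    f = f2 + s[2] * (d - b[1]);
    u = u2 + f2 * (d - b[1]) + 0.5 * s[2] * (d - b[1]) * (d - b[1]);
  }
}

struct Pose {
  mat3 R, dR_dvv, dR_die;
  vec3 e1, e2, p;
  vec3 de1_dvv, de1_die, de2_dvv, de2_die;
  vec3 dp[5];  // dp/d(vv, ie, ml, ap, si)
  bool singular;
};

static void build_pose(double fe, const double* q, Pose& P) {
  double vv = q[0], ie = q[1], ml = q[2], ap = q[3], si = q[4];
  mat3 Rzc, Ryb, Rxa, dRz, dRy, T1, T2;
  rot_z(ie, Rzc); rot_y(-vv, Ryb); rot_x(fe, Rxa);
  drot_z(ie, dRz); drot_y(-vv, dRy);
  mat_mul(Ryb, Rxa, T1);
  mat_mul(Rzc, T1, P.R);
  // dR/dvv = Rz * dRy/db * Rx * d(-vv)/dvv = -(Rz * dRy * Rx)
  mat_mul(dRy, Rxa, T2);
  mat3 T3; mat_mul(Rzc, T2, T3);
  for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j) P.dR_dvv[i][j] = -T3[i][j];
  mat_mul(dRz, T1, P.dR_die);

  for (int i = 0; i < 3; ++i) {
    P.e1[i] = P.R[i][0];
    P.de1_dvv[i] = P.dR_dvv[i][0];
    P.de1_die[i] = P.dR_die[i][0];
  }
  double u[3] = { -P.e1[1], P.e1[0], 0.0 };
  double n = std::sqrt(u[0] * u[0] + u[1] * u[1]);
  P.singular = (n < 1e-10);
  if (P.singular) return;
  for (int i = 0; i < 3; ++i) P.e2[i] = u[i] / n;

  // de2/dx = (du - e2 (e2 . du)) / n
  double du_vv[3] = { -P.de1_dvv[1], P.de1_dvv[0], 0.0 };
  double du_ie[3] = { -P.de1_die[1], P.de1_die[0], 0.0 };
  double c_vv = dot3(P.e2, du_vv), c_ie = dot3(P.e2, du_ie);
  for (int i = 0; i < 3; ++i) {
    P.de2_dvv[i] = (du_vv[i] - P.e2[i] * c_vv) / n;
    P.de2_die[i] = (du_ie[i] - P.e2[i] * c_ie) / n;
  }

  double e3[3] = { 0, 0, 1 };
  for (int i = 0; i < 3; ++i) {
    P.p[i] = -ml * P.e1[i] - ap * P.e2[i] - si * e3[i];
    P.dp[0][i] = -ml * P.de1_dvv[i] - ap * P.de2_dvv[i];
    P.dp[1][i] = -ml * P.de1_die[i] - ap * P.de2_die[i];
    P.dp[2][i] = -P.e1[i];
    P.dp[3][i] = -P.e2[i];
    P.dp[4][i] = (i == 2) ? -1.0 : 0.0;
  }
}

// energy and (optionally) gradient; returns energy
static double energy_grad(double fe, const double* q,
                          const NumericMatrix& fib, const NumericMatrix& con,
                          const double* loads, double* grad) {
  Pose P;
  build_pose(fe, q, P);
  if (P.singular) {
    if (grad) for (int x = 0; x < 5; ++x) grad[x] = NA_REAL;
    return R_PosInf;
  }
  double E = 0;
  if (grad) for (int x = 0; x < 5; ++x) grad[x] = 0;

  int nf = fib.nrow();
  for (int j = 0; j < nf; ++j) {
    double o[3] = { fib(j, 0), fib(j, 1), fib(j, 2) };
    double ins[3] = { fib(j, 3), fib(j, 4), fib(j, 5) };
    double L0 = fib(j, 6), k = fib(j, 7), eps = fib(j, 8);
    double Ro[3]; mat_vec(P.R, o, Ro);
    double w[3] = { Ro[0] + P.p[0] - ins[0], Ro[1] + P.p[1] - ins[1],
                    Ro[2] + P.p[2] - ins[2] };
    double L = std::sqrt(dot3(w, w));
    double f, u;
    fiber_law(L, L0, k, eps, f, u);
    E += u;
    if (grad && f > 0 && L > 1e-12) {
      double dRo_vv[3], dRo_ie[3];
      mat_vec(P.dR_dvv, o, dRo_vv);
      mat_vec(P.dR_die, o, dRo_ie);
      for (int x = 0; x < 5; ++x) {
        double dw[3];
        for (int i = 0; i < 3; ++i) {
          double dR_term = (x == 0) ? dRo_vv[i] : (x == 1) ? dRo_ie[i] : 0.0;
          dw[i] = dR_term + P.dp[x][i];
        }
        grad[x] += f * dot3(w, dw) / L;
      }
    }
  }

  int nc = con.nrow();
  for (int j = 0; j < nc; ++j) {
    double c[3] = { con(j, 0), con(j, 1), con(j, 2) };
    double r = con(j, 3);
    double pp[3] = { con(j, 4), con(j, 5), con(j, 6) };
    double nn[3] = { con(j, 7), con(j, 8), con(j, 9) };
    double dishR = con(j, 10);
    double s[3] = { con(j, 11), con(j, 12), con(j, 13) };
    double b[2] = { con(j, 14), con(j, 15) };
    double Rc[3]; mat_vec(P.R, c, Rc);
    double cw[3] = { Rc[0] + P.p[0], Rc[1] + P.p[1], Rc[2] + P.p[2] };
    double dRc_vv[3], dRc_ie[3];
    if (grad) { mat_vec(P.dR_dvv, c, dRc_vv); mat_vec(P.dR_die, c, dRc_ie); }
    double delta, f, u;
    if (R_finite(dishR)) {
      double m[3] = { pp[0] + nn[0] * dishR, pp[1] + nn[1] * dishR,
                      pp[2] + nn[2] * dishR };
      double v[3] = { cw[0] - m[0], cw[1] - m[1], cw[2] - m[2] };
      double dv = std::sqrt(dot3(v, v));
      delta = r + dv - dishR;
      contact_law(delta, s, b, f, u);
      E += u;
      if (grad && f > 0 && dv > 1e-12) {
        for (int x = 0; x < 5; ++x) {
          double dcw[3];
          for (int i = 0; i < 3; ++i) {
            double dR_term = (x == 0) ? dRc_vv[i] : (x == 1) ? dRc_ie[i] : 0.0;
            dcw[i] = dR_term + P.dp[x][i];
          }
          grad[x] += f * dot3(v, dcw) / dv;
        }
      }
    } else {
      double rel[3] = { cw[0] - pp[0], cw[1] - pp[1], cw[2] - pp[2] };
      delta = r - dot3(nn, rel);
      contact_law(delta, s, b, f, u);
      E += u;
      if (grad && f > 0) {
        for (int x = 0; x < 5; ++x) {
          double dcw[3];
          for (int i = 0; i < 3; ++i) {
            double dR_term = (x == 0) ? dRc_vv[i] : (x == 1) ? dRc_ie[i] : 0.0;
            dcw[i] = dR_term + P.dp[x][i];
          }
          grad[x] -= f * dot3(nn, dcw);
        }
      }
    }
  }

  // applied loads: loads = (f_ap N, f_si N, t_ie N*mm, t_vv N*mm)
  E -= loads[0] * q[3] + loads[1] * q[4] + loads[2] * q[1] + loads[3] * q[0];
  if (grad) {
    grad[0] -= loads[3];
    grad[1] -= loads[2];
    grad[3] -= loads[0];
    grad[4] -= loads[1];
  }
  return E;
}

// residual norm with rotational components expressed as force-equivalents
// over a 100 mm characteristic moment arm
static double residual_norm(const double* g) {
  const double Lc = 100.0;
  double r = 0;
  r += (g[0] / Lc) * (g[0] / Lc);
  r += (g[1] / Lc) * (g[1] / Lc);
  for (int x = 2; x < 5; ++x) r += g[x] * g[x];
  return std::sqrt(r);
}

// solve 5x5 symmetric linear system by Gaussian elimination with partial
// pivoting; returns false if singular
static bool solve5(double A[5][5], const double* bvec, double* x) {
  double M[5][6];
  for (int i = 0; i < 5; ++i) {
    for (int j = 0; j < 5; ++j) M[i][j] = A[i][j];
    M[i][5] = bvec[i];
  }
  for (int col = 0; col < 5; ++col) {
    int piv = col;
    for (int i = col + 1; i < 5; ++i)
      if (std::fabs(M[i][col]) > std::fabs(M[piv][col])) piv = i;
    if (std::fabs(M[piv][col]) < 1e-14) return false;
    if (piv != col)
      for (int j = 0; j < 6; ++j) std::swap(M[piv][j], M[col][j]);
    for (int i = col + 1; i < 5; ++i) {
      double fac = M[i][col] / M[col][col];
      for (int j = col; j < 6; ++j) M[i][j] -= fac * M[col][j];
    }
  }
  for (int i = 4; i >= 0; --i) {
    double s = M[i][5];
    for (int j = i + 1; j < 5; ++j) s -= M[i][j] * x[j];
    x[i] = s / M[i][i];
  }
  return true;
}

// [[Rcpp::export]]
double knee_energy_cpp(double fe_rad, NumericVector q, NumericMatrix fibers,
                       NumericMatrix contacts, NumericVector loads) {
  return energy_grad(fe_rad, REAL(q), fibers, contacts, REAL(loads), nullptr);
}

// [[Rcpp::export]]
NumericVector knee_gradient_cpp(double fe_rad, NumericVector q,
                                NumericMatrix fibers, NumericMatrix contacts,
                                NumericVector loads) {
  NumericVector g(5);
  energy_grad(fe_rad, REAL(q), fibers, contacts, REAL(loads), REAL(g));
  return g;
}

// [[Rcpp::export]]
List knee_state_cpp(double fe_rad, NumericVector q, NumericMatrix fibers,
                    NumericMatrix contacts) {
  Pose P;
  build_pose(fe_rad, REAL(q), P);
  if (P.singular) stop("singular pose");
  int nf = fibers.nrow(), nc = contacts.nrow();
  NumericVector lengths(nf), forces(nf), overclosures(nc), cforces(nc);
  for (int j = 0; j < nf; ++j) {
    double o[3] = { fibers(j, 0), fibers(j, 1), fibers(j, 2) };
    double ins[3] = { fibers(j, 3), fibers(j, 4), fibers(j, 5) };
    double Ro[3]; mat_vec(P.R, o, Ro);
    double w[3] = { Ro[0] + P.p[0] - ins[0], Ro[1] + P.p[1] - ins[1],
                    Ro[2] + P.p[2] - ins[2] };
    double L = std::sqrt(dot3(w, w));
    double f, u;
    fiber_law(L, fibers(j, 6), fibers(j, 7), fibers(j, 8), f, u);
    lengths[j] = L;
    forces[j] = f;
  }
  for (int j = 0; j < nc; ++j) {
    double c[3] = { contacts(j, 0), contacts(j, 1), contacts(j, 2) };
    double r = contacts(j, 3);
    double pp[3] = { contacts(j, 4), contacts(j, 5), contacts(j, 6) };
    double nn[3] = { contacts(j, 7), contacts(j, 8), contacts(j, 9) };
    double dishR = contacts(j, 10);
    double s[3] = { contacts(j, 11), contacts(j, 12), contacts(j, 13) };
    double b[2] = { contacts(j, 14), contacts(j, 15) };
    double Rc[3]; mat_vec(P.R, c, Rc);
    double cw[3] = { Rc[0] + P.p[0], Rc[1] + P.p[1], Rc[2] + P.p[2] };
    double delta;
    if (R_finite(dishR)) {
      double m[3] = { pp[0] + nn[0] * dishR, pp[1] + nn[1] * dishR,
                      pp[2] + nn[2] * dishR };
      double v[3] = { cw[0] - m[0], cw[1] - m[1], cw[2] - m[2] };
      delta = r + std::sqrt(dot3(v, v)) - dishR;
    } else {
      double rel[3] = { cw[0] - pp[0], cw[1] - pp[1], cw[2] - pp[2] };
      delta = r - dot3(nn, rel);
    }
    double f, u;
    contact_law(delta, s, b, f, u);
    overclosures[j] = delta;
    cforces[j] = f;
  }
  return List::create(_["lengths"] = lengths, _["forces"] = forces,
                      _["overclosures"] = overclosures,
                      _["contact_forces"] = cforces);
}

// Damped-Newton minimizer over the five free DOF with Levenberg
// regularization and an energy-decrease acceptance rule.
// [[Rcpp::export]]
List knee_minimize_cpp(double fe_rad, NumericVector q0, NumericMatrix fibers,
                       NumericMatrix contacts, NumericVector loads,
                       double tol = 1e-3, int max_iter = 200) {
  double q[5], g[5], gp[5];
  for (int i = 0; i < 5; ++i) q[i] = q0[i];
  const double* L = REAL(loads);
  double E = energy_grad(fe_rad, q, fibers, contacts, L, g);
  double lambda = 1e-3;
  bool converged = false;
  int iter = 0;
  const double hfd = 1e-5;
  // unit balancing for the Levenberg diagonal (rotations carry N*mm/rad)
  const double D[5] = { 1e4, 1e4, 1.0, 1.0, 1.0 };

  for (iter = 0; iter < max_iter; ++iter) {
    if (residual_norm(g) < tol) { converged = true; break; }
    // finite-difference Hessian from analytic gradient
    double H[5][5];
    for (int x = 0; x < 5; ++x) {
      double qs = q[x];
      q[x] = qs + hfd;
      energy_grad(fe_rad, q, fibers, contacts, L, gp);
      q[x] = qs;
      for (int y = 0; y < 5; ++y) H[y][x] = (gp[y] - g[y]) / hfd;
    }
    for (int i = 0; i < 5; ++i)
      for (int j = i + 1; j < 5; ++j) {
        double s = 0.5 * (H[i][j] + H[j][i]);
        H[i][j] = s; H[j][i] = s;
      }

    bool accepted = false;
    for (int attempt = 0; attempt < 40 && !accepted; ++attempt) {
      double A[5][5];
      for (int i = 0; i < 5; ++i)
        for (int j = 0; j < 5; ++j)
          A[i][j] = H[i][j] + ((i == j) ? lambda * D[i] : 0.0);
      double rhs[5], dq[5];
      for (int i = 0; i < 5; ++i) rhs[i] = -g[i];
      if (!solve5(A, rhs, dq)) { lambda *= 10; continue; }
      // trust region: cap rotation / translation step sizes
      double rot = std::sqrt(dq[0] * dq[0] + dq[1] * dq[1]);
      double trn = std::sqrt(dq[2] * dq[2] + dq[3] * dq[3] + dq[4] * dq[4]);
      double scale = 1.0;
      if (rot > 0.3) scale = std::min(scale, 0.3 / rot);
      if (trn > 5.0) scale = std::min(scale, 5.0 / trn);
      double qn[5];
      for (int i = 0; i < 5; ++i) qn[i] = q[i] + scale * dq[i];
      double En = energy_grad(fe_rad, qn, fibers, contacts, L, nullptr);
      if (R_finite(En) && En <= E + 1e-10 * (std::fabs(E) + 1.0)) {
        // accept
        double gn[5];
        En = energy_grad(fe_rad, qn, fibers, contacts, L, gn);
        for (int i = 0; i < 5; ++i) { q[i] = qn[i]; g[i] = gn[i]; }
        E = En;
        lambda = std::max(lambda / 3.0, 1e-8);
        accepted = true;
      } else {
        lambda *= 10;
      }
    }
    if (!accepted) break;  // stalled
  }

  NumericVector qout(5), gout(5);
  for (int i = 0; i < 5; ++i) { qout[i] = q[i]; gout[i] = g[i]; }
  return List::create(_["q"] = qout, _["energy"] = E, _["gradient"] = gout,
                      _["residual"] = residual_norm(g),
                      _["converged"] = converged, _["iterations"] = iter);
}
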