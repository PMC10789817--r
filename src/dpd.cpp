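// Groot-Warren DPD core: pairwise soft forces (conservative, dissipative,
// random), harmonic strand bonds, linked-cell neighbour search, modified
// velocity-Verlet integration and quaternion rigid-body motion of the rod.
// All randomness comes from R's RNG so set.seed() governs every run.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <stdexcept>
using namespace Rcpp;

static const double SQRT3 = 1.7320508075688772;

static inline double minimg(double d, double box) {
  return d - box * std::nearbyint(d / box);
}
static inline double wrap01(double x, double box) {
  double y = x - box * std::floor(x / box);
  if (y >= box) y -= box;   // guard against floor rounding at the edge
  return y;
}

struct PairParams {
  double rc, rc2, gamma, sigma, inv_sqrt_dt;
  bool use_cons, use_diss, use_rand;
};

// force magnitude along unit vector e for one pair; theta drawn inside when
// the random force is on so that the pair noise is symmetric by construction
static inline double pair_force_mag(double a, double r, const double *e,
                                    const double *vi, const double *vj,
                                    const PairParams &pp) {
  double w = 1.0 - r / pp.rc;
  double f = 0.0;
  if (pp.use_cons) f += a * w;
  if (pp.use_diss) {
    double rv = e[0] * (vi[0] - vj[0]) + e[1] * (vi[1] - vj[1]) +
                e[2] * (vi[2] - vj[2]);
    f += -pp.gamma * w * w * rv;
  }
  if (pp.use_rand) {
    double theta = SQRT3 * (2.0 * unif_rand() - 1.0);
    f += pp.sigma * w * theta * pp.inv_sqrt_dt;
  }
  return f;
}

// resolve a coincident pair: documented convention, seeded random direction
static inline void coincidence_dir(double *e) {
  double n2 = 0.0;
  do {
    n2 = 0.0;
    for (int d = 0; d < 3; ++d) { e[d] = 2.0 * unif_rand() - 1.0; n2 += e[d] * e[d]; }
  } while (n2 < 1e-12 || n2 > 1.0);
  double inv = 1.0 / std::sqrt(n2);
  for (int d = 0; d < 3; ++d) e[d] *= inv;
}

class Forces {
public:
  std::vector<double> F;           // 3N
  int N;
  Forces(int n) : F(3 * n, 0.0), N(n) {}
  void zero() { std::fill(F.begin(), F.end(), 0.0); }
};

static void accumulate_pair(int i, int j,
                            const std::vector<double> &pos,
                            const std::vector<double> &vel,
                            const std::vector<int> &spec,
                            const std::vector<char> &isrod,
                            const NumericMatrix &aij,
                            const double *box, const PairParams &pp,
                            Forces &out) {
  if (isrod[i] && isrod[j]) return;   // rigid body: no internal DPD pairs
  double d[3];
  for (int k = 0; k < 3; ++k) d[k] = minimg(pos[3 * i + k] - pos[3 * j + k], box[k]);
  double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
  if (r2 >= pp.rc2) return;
  double e[3], r;
  if (r2 < 1e-24) {                    // coincident beads
    coincidence_dir(e);
    r = 1e-6;
  } else {
    r = std::sqrt(r2);
    for (int k = 0; k < 3; ++k) e[k] = d[k] / r;
  }
  double f = pair_force_mag(aij(spec[i], spec[j]), r, e,
                            &vel[3 * i], &vel[3 * j], pp);
  for (int k = 0; k < 3; ++k) {
    out.F[3 * i + k] += f * e[k];
    out.F[3 * j + k] -= f * e[k];
  }
}

// linked-cell pair sweep; falls back to O(N^2) when the box holds < 3 cells
// along any edge (then the cell construction would double-count images)
static void pair_forces_sweep(const std::vector<double> &pos,
                              const std::vector<double> &vel,
                              const std::vector<int> &spec,
                              const std::vector<char> &isrod,
                              const NumericMatrix &aij,
                              const double *box, const PairParams &pp,
                              bool brute, Forces &out) {
  int N = out.N;
  int nc[3];
  bool ok = !brute;
  for (int k = 0; k < 3; ++k) {
    nc[k] = (int)std::floor(box[k] / pp.rc);
    if (nc[k] < 3) ok = false;
  }
  if (!ok) {
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j)
        accumulate_pair(i, j, pos, vel, spec, isrod, aij, box, pp, out);
    return;
  }
  int ncell = nc[0] * nc[1] * nc[2];
  std::vector<int> head(ncell, -1), nxt(N, -1), cellof(N);
  double cw[3];
  for (int k = 0; k < 3; ++k) cw[k] = box[k] / nc[k];
  for (int i = 0; i < N; ++i) {
    int c[3];
    for (int k = 0; k < 3; ++k) {
      double x = wrap01(pos[3 * i + k], box[k]);
      c[k] = (int)(x / cw[k]);
      if (c[k] >= nc[k]) c[k] = nc[k] - 1;
    }
    int ci = (c[2] * nc[1] + c[1]) * nc[0] + c[0];
    cellof[i] = ci;
    nxt[i] = head[ci];
    head[ci] = i;
  }
  // 13 forward neighbour offsets + self
  static const int off[13][3] = {
    {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
    {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
  for (int cz = 0; cz < nc[2]; ++cz)
    for (int cy = 0; cy < nc[1]; ++cy)
      for (int cx = 0; cx < nc[0]; ++cx) {
        int ci = (cz * nc[1] + cy) * nc[0] + cx;
        // within cell
        for (int i = head[ci]; i >= 0; i = nxt[i])
          for (int j = nxt[i]; j >= 0; j = nxt[j])
            accumulate_pair(i, j, pos, vel, spec, isrod, aij, box, pp, out);
        // neighbours
        for (int m = 0; m < 13; ++m) {
          int ax = (cx + off[m][0] + nc[0]) % nc[0];
          int ay = (cy + off[m][1] + nc[1]) % nc[1];
          int az = (cz + off[m][2] + nc[2]) % nc[2];
          int cj = (az * nc[1] + ay) * nc[0] + ax;
          if (cj == ci) continue;
          for (int i = head[ci]; i >= 0; i = nxt[i])
            for (int j = head[cj]; j >= 0; j = nxt[j])
              accumulate_pair(i, j, pos, vel, spec, isrod, aij, box, pp, out);
        }
      }
}

static void bond_forces_sweep(const std::vector<double> &pos,
                              const IntegerMatrix &bonds,
                              const double *box, double bond_k, double bond_r0,
                              Forces &out) {
  double halfmin = 0.5 * std::min(box[0], std::min(box[1], box[2]));
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    double d[3];
    for (int k = 0; k < 3; ++k) d[k] = minimg(pos[3 * i + k] - pos[3 * j + k], box[k]);
    double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (r > halfmin)
      stop("bond %d-%d spans more than half the box (length %.3f): broken topology",
           i + 1, j + 1, r);
    if (r < 1e-12) continue;          // rest force undefined at r=0; skip
    double f = -bond_k * (r - bond_r0);
    for (int k = 0; k < 3; ++k) {
      out.F[3 * i + k] += f * d[k] / r;
      out.F[3 * j + k] -= f * d[k] / r;
    }
  }
}

// ---------------- quaternion helpers ----------------
static inline void quat_to_mat(const double *q, double R[3][3]) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0][0] = 1 - 2 * (y * y + z * z); R[0][1] = 2 * (x * y - w * z); R[0][2] = 2 * (x * z + w * y);
  R[1][0] = 2 * (x * y + w * z); R[1][1] = 1 - 2 * (x * x + z * z); R[1][2] = 2 * (y * z - w * x);
  R[2][0] = 2 * (x * z - w * y); R[2][1] = 2 * (y * z + w * x); R[2][2] = 1 - 2 * (x * x + y * y);
}
static inline void quat_normalize(double *q) {
  double n = std::sqrt(q[0]*q[0]+q[1]*q[1]+q[2]*q[2]+q[3]*q[3]);
  for (int k = 0; k < 3 + 1; ++k) q[k] /= n;
}
// rotate q by lab-frame angular velocity omega over dt
static inline void quat_advance(double *q, const double *om, double dt) {
  double th = std::sqrt(om[0]*om[0]+om[1]*om[1]+om[2]*om[2]) * dt;
  if (th < 1e-300) return;
  double ax[3] = {om[0], om[1], om[2]};
  double n = th / dt;
  for (int k = 0; k < 3; ++k) ax[k] /= n;
  double c = std::cos(0.5 * th), s = std::sin(0.5 * th);
  double dq[4] = {c, s * ax[0], s * ax[1], s * ax[2]};
  double r[4] = {
    dq[0]*q[0] - dq[1]*q[1] - dq[2]*q[2] - dq[3]*q[3],
    dq[0]*q[1] + dq[1]*q[0] + dq[2]*q[3] - dq[3]*q[2],
    dq[0]*q[2] - dq[1]*q[3] + dq[2]*q[0] + dq[3]*q[1],
    dq[0]*q[3] + dq[1]*q[2] - dq[2]*q[1] + dq[3]*q[0]};
  for (int k = 0; k < 4; ++k) q[k] = r[k];
  quat_normalize(q);
}
// omega (lab) from angular momentum L (lab) through body-diagonal inertia;
// zero-inertia axes are ignored (axially symmetric bead layouts)
static inline void omega_from_L(const double *q, const double *Ibody,
                                const double *L, double *om) {
  double R[3][3];
  quat_to_mat(q, R);
  double Lb[3];
  for (int a = 0; a < 3; ++a)
    Lb[a] = R[0][a] * L[0] + R[1][a] * L[1] + R[2][a] * L[2];
  double wb[3];
  for (int a = 0; a < 3; ++a)
    wb[a] = (Ibody[a] > 1e-10) ? Lb[a] / Ibody[a] : 0.0;
  for (int a = 0; a < 3; ++a)
    om[a] = R[a][0] * wb[0] + R[a][1] * wb[1] + R[a][2] * wb[2];
}

struct RodState {
  bool present = false;
  std::vector<int> idx;              // 0-based bead indices
  std::vector<double> body;          // 3*nrod body-frame coordinates
  double mass = 0, Ibody[3] = {0,0,0};
  double com[3] = {0,0,0}, com_un[3] = {0,0,0};
  double quat[4] = {1,0,0,0}, vel[3] = {0,0,0}, angmom[3] = {0,0,0};
};

static void rod_set_beads(const RodState &rod, const double *om,
                          const double *box,
                          std::vector<double> &pos, std::vector<double> &vel) {
  double R[3][3];
  quat_to_mat(rod.quat, R);
  for (size_t m = 0; m < rod.idx.size(); ++m) {
    int i = rod.idx[m];
    double arm[3];
    for (int a = 0; a < 3; ++a)
      arm[a] = R[a][0] * rod.body[3*m] + R[a][1] * rod.body[3*m+1] +
               R[a][2] * rod.body[3*m+2];
    for (int a = 0; a < 3; ++a)
      pos[3*i+a] = wrap01(rod.com[a] + arm[a], box[a]);
    vel[3*i+0] = rod.vel[0] + om[1]*arm[2] - om[2]*arm[1];
    vel[3*i+1] = rod.vel[1] + om[2]*arm[0] - om[0]*arm[2];
    vel[3*i+2] = rod.vel[2] + om[0]*arm[1] - om[1]*arm[0];
  }
}

static void rod_reduce(const RodState &rod, const Forces &F, const double *box,
                       const std::vector<double> &pos,
                       double *Ftot, double *Ttot) {
  for (int a = 0; a < 3; ++a) { Ftot[a] = 0; Ttot[a] = 0; }
  for (size_t m = 0; m < rod.idx.size(); ++m) {
    int i = rod.idx[m];
    double arm[3];
    for (int a = 0; a < 3; ++a)
      arm[a] = minimg(pos[3*i+a] - wrap01(rod.com[a], box[a]), box[a]);
    const double *f = &F.F[3*i];
    for (int a = 0; a < 3; ++a) Ftot[a] += f[a];
    Ttot[0] += arm[1]*f[2] - arm[2]*f[1];
    Ttot[1] += arm[2]*f[0] - arm[0]*f[2];
    Ttot[2] += arm[0]*f[1] - arm[1]*f[0];
  }
}

static RodState rod_from_list(List rodL, int N) {
  RodState r;
  if (rodL.size() == 0) return r;
  r.present = true;
  IntegerVector idx = rodL["idx"];
  NumericMatrix body = rodL["body"];
  NumericVector Ib = rodL["inertia"], com = rodL["com"], com_un = rodL["com_un"];
  NumericVector q = rodL["quat"], v = rodL["vel"], L = rodL["angmom"];
  r.mass = as<double>(rodL["mass"]);
  r.idx.resize(idx.size());
  for (int i = 0; i < idx.size(); ++i) {
    r.idx[i] = idx[i] - 1;
    if (r.idx[i] < 0 || r.idx[i] >= N) stop("rod bead index out of range");
  }
  r.body.resize(3 * body.nrow());
  for (int i = 0; i < body.nrow(); ++i)
    for (int a = 0; a < 3; ++a) r.body[3*i+a] = body(i, a);
  for (int a = 0; a < 3; ++a) {
    r.Ibody[a] = Ib[a]; r.com[a] = com[a]; r.com_un[a] = com_un[a];
    r.vel[a] = v[a]; r.angmom[a] = L[a];
  }
  for (int a = 0; a < 4; ++a) r.quat[a] = q[a];
  return r;
}

static List rod_to_list(const RodState &r) {
  if (!r.present) return List::create();
  return List::create(
    _["idx"] = IntegerVector(r.idx.begin(), r.idx.end()) + 1,
    _["com"] = NumericVector(r.com, r.com + 3),
    _["com_un"] = NumericVector(r.com_un, r.com_un + 3),
    _["quat"] = NumericVector(r.quat, r.quat + 4),
    _["vel"] = NumericVector(r.vel, r.vel + 3),
    _["angmom"] = NumericVector(r.angmom, r.angmom + 3),
    _["mass"] = r.mass,
    _["inertia"] = NumericVector(r.Ibody, r.Ibody + 3));
}

// [[Rcpp::export]]
NumericMatrix cpp_pair_forces(NumericMatrix pos, NumericMatrix vel,
                              IntegerVector species, LogicalVector is_rod,
                              NumericMatrix aij, NumericVector box,
                              double rc, double gamma, double sigma, double dt,
                              bool use_cons, bool use_diss, bool use_rand,
                              bool brute) {
  int N = pos.nrow();
  std::vector<double> P(3 * N), V(3 * N);
  std::vector<int> S(N);
  std::vector<char> rodf(N);
  for (int i = 0; i < N; ++i) {
    for (int a = 0; a < 3; ++a) {
      P[3*i+a] = pos(i, a);
      if (!R_finite(P[3*i+a])) stop("non-finite position for bead %d", i + 1);
      V[3*i+a] = vel(i, a);
    }
    S[i] = species[i] - 1;
    rodf[i] = is_rod[i] ? 1 : 0;
  }
  PairParams pp{rc, rc * rc, gamma, sigma, 1.0 / std::sqrt(dt),
                use_cons, use_diss, use_rand};
  Forces F(N);
  pair_forces_sweep(P, V, S, rodf, aij, REAL(box), pp, brute, F);
  NumericMatrix out(N, 3);
  for (int i = 0; i < N; ++i)
    for (int a = 0; a < 3; ++a) out(i, a) = F.F[3*i+a];
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_bond_forces(NumericMatrix pos, IntegerMatrix bonds,
                              NumericVector box, double bond_k, double bond_r0) {
  int N = pos.nrow();
  std::vector<double> P(3 * N);
  for (int i = 0; i < N; ++i)
    for (int a = 0; a < 3; ++a) P[3*i+a] = pos(i, a);
  IntegerMatrix b0(bonds.nrow(), 2);
  for (int b = 0; b < bonds.nrow(); ++b) {
    b0(b, 0) = bonds(b, 0) - 1;
    b0(b, 1) = bonds(b, 1) - 1;
  }
  Forces F(N);
  bond_forces_sweep(P, b0, REAL(box), bond_k, bond_r0, F);
  NumericMatrix out(N, 3);
  for (int i = 0; i < N; ++i)
    for (int a = 0; a < 3; ++a) out(i, a) = F.F[3*i+a];
  return out;
}

// Full simulation loop. Records the rod pose (unwrapped COM + axis) and the
// instantaneous kinetic temperature of the free beads every record_every steps.
// [[Rcpp::export]]
List cpp_dpd_run(NumericMatrix pos0, NumericMatrix vel0, IntegerVector species,
                 LogicalVector is_rod, IntegerMatrix bonds1, NumericMatrix aij,
                 NumericVector boxv, double rc, double gamma, double sigma,
                 double dt, double lambda, double bond_k, double bond_r0,
                 List rodL, double t0, int n_steps, int record_every,
                 bool use_diss, bool use_rand, bool brute) {
  int N = pos0.nrow();
  std::vector<double> pos(3 * N), vel(3 * N);
  std::vector<int> spec(N);
  std::vector<char> rodf(N);
  double box[3] = {boxv[0], boxv[1], boxv[2]};
  for (int i = 0; i < N; ++i) {
    for (int a = 0; a < 3; ++a) {
      pos[3*i+a] = wrap01(pos0(i, a), box[a]);
      vel[3*i+a] = vel0(i, a);
    }
    spec[i] = species[i] - 1;
    rodf[i] = is_rod[i] ? 1 : 0;
  }
  IntegerMatrix bonds(bonds1.nrow(), 2);
  for (int b = 0; b < bonds1.nrow(); ++b) {
    bonds(b, 0) = bonds1(b, 0) - 1;
    bonds(b, 1) = bonds1(b, 1) - 1;
  }
  RodState rod = rod_from_list(rodL, N);
  int nfree = 0;
  for (int i = 0; i < N; ++i) if (!rodf[i]) ++nfree;

  PairParams pp{rc, rc * rc, gamma, sigma, 1.0 / std::sqrt(dt),
                true, use_diss, use_rand};
  Forces F(N), Fnew(N);
  double rodF[3] = {0,0,0}, rodT[3] = {0,0,0};

  // consistency: bead positions/velocities of the rod follow the rigid state
  if (rod.present) {
    double om[3];
    omega_from_L(rod.quat, rod.Ibody, rod.angmom, om);
    rod_set_beads(rod, om, box, pos, vel);
  }
  pair_forces_sweep(pos, vel, spec, rodf, aij, box, pp, brute, F);
  bond_forces_sweep(pos, bonds, box, bond_k, bond_r0, F);
  if (rod.present) rod_reduce(rod, F, box, pos, rodF, rodT);

  int n_rec = (record_every > 0) ? n_steps / record_every : 0;
  NumericMatrix traj(n_rec, 8);
  int irec = 0;
  double maxd2_limit = 0.25 * rc * rc;

  std::vector<double> vold(3 * N);
  for (int step = 0; step < n_steps; ++step) {
    // -- position update + predicted velocities ------------------------
    std::copy(vel.begin(), vel.end(), vold.begin());
    for (int i = 0; i < N; ++i) {
      if (rodf[i]) continue;
      const double *f = &F.F[3*i];
      for (int a = 0; a < 3; ++a) {
        double dr = dt * vel[3*i+a] + 0.5 * dt * dt * f[a];
        if (dr * dr > maxd2_limit)
          stop("unstable step: bead %d moved %.3f r_c in one step", i + 1,
               std::sqrt(dr * dr));
        pos[3*i+a] = wrap01(pos[3*i+a] + dr, box[a]);
        vel[3*i+a] = vold[3*i+a] + lambda * dt * f[a];   // predicted
      }
    }
    double acc[3] = {0,0,0}, om[3] = {0,0,0};
    double vcom_old[3], L_old[3];
    if (rod.present) {
      for (int a = 0; a < 3; ++a) {
        acc[a] = rodF[a] / rod.mass;
        vcom_old[a] = rod.vel[a];
        L_old[a] = rod.angmom[a];
        double dr = dt * rod.vel[a] + 0.5 * dt * dt * acc[a];
        rod.com_un[a] += dr;
        rod.com[a] = wrap01(rod.com_un[a], box[a]);
      }
      double Lhalf[3];
      for (int a = 0; a < 3; ++a) Lhalf[a] = L_old[a] + 0.5 * dt * rodT[a];
      omega_from_L(rod.quat, rod.Ibody, Lhalf, om);
      quat_advance(rod.quat, om, dt);
      // predicted COM velocity / angular momentum for the force pass
      double Lpred[3], ompred[3];
      for (int a = 0; a < 3; ++a) {
        rod.vel[a] = vcom_old[a] + lambda * dt * acc[a];
        Lpred[a] = L_old[a] + lambda * dt * rodT[a];
      }
      omega_from_L(rod.quat, rod.Ibody, Lpred, ompred);
      rod_set_beads(rod, ompred, box, pos, vel);
    }
    // -- single force evaluation per step ------------------------------
    Fnew.zero();
    pair_forces_sweep(pos, vel, spec, rodf, aij, box, pp, brute, Fnew);
    bond_forces_sweep(pos, bonds, box, bond_k, bond_r0, Fnew);
    double rodFn[3] = {0,0,0}, rodTn[3] = {0,0,0};
    if (rod.present) rod_reduce(rod, Fnew, box, pos, rodFn, rodTn);
    // -- velocity correction -------------------------------------------
    for (int i = 0; i < N; ++i) {
      if (rodf[i]) continue;
      for (int a = 0; a < 3; ++a)
        vel[3*i+a] = vold[3*i+a] + 0.5 * dt * (F.F[3*i+a] + Fnew.F[3*i+a]);
    }
    if (rod.present) {
      for (int a = 0; a < 3; ++a) {
        rod.vel[a] = vcom_old[a] + 0.5 * dt * (rodF[a] + rodFn[a]) / rod.mass;
        rod.angmom[a] = L_old[a] + 0.5 * dt * (rodT[a] + rodTn[a]);
        rodF[a] = rodFn[a]; rodT[a] = rodTn[a];
      }
      double omc[3];
      omega_from_L(rod.quat, rod.Ibody, rod.angmom, omc);
      // keep bead velocities consistent with the corrected rigid state
      double Rm[3][3];
      quat_to_mat(rod.quat, Rm);
      for (size_t m = 0; m < rod.idx.size(); ++m) {
        int i = rod.idx[m];
        double arm[3];
        for (int a = 0; a < 3; ++a)
          arm[a] = Rm[a][0]*rod.body[3*m] + Rm[a][1]*rod.body[3*m+1] +
                   Rm[a][2]*rod.body[3*m+2];
        vel[3*i+0] = rod.vel[0] + omc[1]*arm[2] - omc[2]*arm[1];
        vel[3*i+1] = rod.vel[1] + omc[2]*arm[0] - omc[0]*arm[2];
        vel[3*i+2] = rod.vel[2] + omc[0]*arm[1] - omc[1]*arm[0];
      }
    }
    std::swap(F.F, Fnew.F);
    // -- record ---------------------------------------------------------
    if (record_every > 0 && (step + 1) % record_every == 0 && irec < n_rec) {
      double t = t0 + (step + 1) * dt;
      double vb[3] = {0,0,0};
      for (int i = 0; i < N; ++i)
        if (!rodf[i]) for (int a = 0; a < 3; ++a) vb[a] += vel[3*i+a];
      double ke = 0.0;
      int nf = nfree > 0 ? nfree : 1;
      for (int i = 0; i < N; ++i) {
        if (rodf[i]) continue;
        for (int a = 0; a < 3; ++a) {
          double dv = vel[3*i+a] - vb[a] / nf;
          ke += dv * dv;
        }
      }
      double temp = (nfree > 0) ? ke / (3.0 * nfree) : NA_REAL;
      traj(irec, 0) = t;
      if (rod.present) {
        double Rm[3][3];
        quat_to_mat(rod.quat, Rm);
        traj(irec, 1) = rod.com_un[0];
        traj(irec, 2) = rod.com_un[1];
        traj(irec, 3) = rod.com_un[2];
        traj(irec, 4) = Rm[0][2];
        traj(irec, 5) = Rm[1][2];
        traj(irec, 6) = Rm[2][2];
      } else {
        for (int a = 1; a <= 6; ++a) traj(irec, a) = NA_REAL;
      }
      traj(irec, 7) = temp;
      ++irec;
    }
  }

  NumericMatrix posOut(N, 3), velOut(N, 3);
  for (int i = 0; i < N; ++i)
    for (int a = 0; a < 3; ++a) { posOut(i, a) = pos[3*i+a]; velOut(i, a) = vel[3*i+a]; }
  double mom[3] = {0,0,0};
  for (int i = 0; i < N; ++i)
    if (!rodf[i]) for (int a = 0; a < 3; ++a) mom[a] += vel[3*i+a];
  if (rod.present)
    for (int a = 0; a < 3; ++a) mom[a] += rod.mass * rod.vel[a];
  return List::create(
    _["pos"] = posOut, _["vel"] = velOut,
    _["rod"] = rod_to_list(rod),
    _["time"] = t0 + n_steps * dt,
    _["traj"] = traj,
    _["momentum"] = NumericVector(mom, mom + 3));
}

// Capped-displacement relaxation on conservative + bond forces; only beads
// with movable=TRUE are displaced. Used to remove placement overlaps.
// [[Rcpp::export]]
NumericMatrix cpp_relax(NumericMatrix pos0, IntegerVector species,
                        LogicalVector movable, IntegerMatrix bonds1,
                        NumericMatrix aij, NumericVector boxv, double rc,
                        int n_iter, double max_move, double step_scale,
                        double bond_k, double bond_r0) {
  int N = pos0.nrow();
  std::vector<double> pos(3 * N), vel(3 * N, 0.0);
  std::vector<int> spec(N);
  std::vector<char> rodf(N, 0);
  double box[3] = {boxv[0], boxv[1], boxv[2]};
  for (int i = 0; i < N; ++i) {
    for (int a = 0; a < 3; ++a) pos[3*i+a] = wrap01(pos0(i, a), box[a]);
    spec[i] = species[i] - 1;
  }
  IntegerMatrix bonds(bonds1.nrow(), 2);
  for (int b = 0; b < bonds1.nrow(); ++b) {
    bonds(b, 0) = bonds1(b, 0) - 1;
    bonds(b, 1) = bonds1(b, 1) - 1;
  }
  PairParams pp{rc, rc * rc, 0.0, 0.0, 1.0, true, false, false};
  Forces F(N);
  for (int it = 0; it < n_iter; ++it) {
    F.zero();
    pair_forces_sweep(pos, vel, spec, rodf, aij, box, pp, false, F);
    bond_forces_sweep(pos, bonds, box, bond_k, bond_r0, F);
    for (int i = 0; i < N; ++i) {
      if (!movable[i]) continue;
      for (int a = 0; a < 3; ++a) {
        double dr = step_scale * F.F[3*i+a];
        if (dr > max_move) dr = max_move;
        if (dr < -max_move) dr = -max_move;
        pos[3*i+a] = wrap01(pos[3*i+a] + dr, box[a]);
      }
    }
  }
  NumericMatrix out(N, 3);
  for (int i = 0; i < N; ++i)
    for (int a = 0; a < 3; ++a) out(i, a) = pos[3*i+a];
  return out;
}

// ------------------------------------------------------------------
// Gaussian-bridge Monte Carlo for the rod-network partition function.
// A strand of N bonds (Kuhn length b) pinned at endpoints ep1, ep2 is
// sampled as a discrete Gaussian bridge; a sample is rejected at rod
// centre z_c when any interior vertex lies inside the hard-core cylinder
// (axis along z through (x0, y0), half-length L/2, radius d/2).  The
// radial test does not depend on z_c, so each offending vertex excludes
// an interval of rod centres, evaluated for the whole z grid at once
// (common random numbers across the grid by construction).
// Returns an nz x n_blocks matrix of acceptance counts: the block split
// supports CRN-aware error estimates of profile differences.
// [[Rcpp::export]]
IntegerMatrix cpp_bridge_mc_blocks(NumericVector ep1, NumericVector ep2,
                                   int Nbonds, double b, int n_samples,
                                   double L, double d, double x0, double y0,
                                   NumericVector z_centers, double sigma_ep,
                                   int n_blocks) {
  int nz = z_centers.size();
  if (n_blocks < 1) n_blocks = 1;
  IntegerMatrix accept(nz, n_blocks);
  if (Nbonds < 1) stop("Nbonds must be >= 1");
  int nv = Nbonds + 1;
  double sd = b / std::sqrt(3.0);        // per-dimension step SD
  double zmin = z_centers[0], zmax = z_centers[nz - 1];
  double dz = nz > 1 ? (z_centers[1] - z_centers[0]) : 1.0;
  double rad2 = 0.25 * d * d;
  std::vector<double> w(3 * nv);
  std::vector<char> blocked(nz);
  // with crosslink smearing the (annealed) endpoints are tested too
  int kfirst = sigma_ep > 0 ? 0 : 1;
  int klast = sigma_ep > 0 ? nv - 1 : nv - 2;
  for (int s = 0; s < n_samples; ++s) {
    int blk = (int)(((long long)s * n_blocks) / n_samples);
    double e1[3], e2[3];
    for (int a = 0; a < 3; ++a) {
      e1[a] = ep1[a] + (sigma_ep > 0 ? sigma_ep * norm_rand() : 0.0);
      e2[a] = ep2[a] + (sigma_ep > 0 ? sigma_ep * norm_rand() : 0.0);
    }
    // free walk from e1
    w[0] = e1[0]; w[1] = e1[1]; w[2] = e1[2];
    for (int k = 1; k < nv; ++k)
      for (int a = 0; a < 3; ++a)
        w[3*k+a] = w[3*(k-1)+a] + sd * norm_rand();
    double corr[3];
    for (int a = 0; a < 3; ++a) corr[a] = (e2[a] - w[3*(nv-1)+a]) / Nbonds;
    std::fill(blocked.begin(), blocked.end(), 0);
    bool any = false;
    for (int k = kfirst; k <= klast; ++k) {
      double vx = w[3*k+0] + k * corr[0];
      double vy = w[3*k+1] + k * corr[1];
      double vz = w[3*k+2] + k * corr[2];
      double rx = vx - x0, ry = vy - y0;
      if (rx * rx + ry * ry >= rad2) continue;
      // vertex inside radius: excludes rod centres with |vz - zc| < L/2
      double lo = vz - 0.5 * L, hi = vz + 0.5 * L;
      if (hi <= zmin || lo >= zmax) continue;
      int i0 = 0, i1 = nz - 1;
      if (nz > 1) {
        i0 = (int)std::ceil((lo - zmin) / dz - 1e-9);
        i1 = (int)std::floor((hi - zmin) / dz + 1e-9);
        if (i0 < 0) i0 = 0;
        if (i1 > nz - 1) i1 = nz - 1;
      }
      for (int i = i0; i <= i1; ++i) {
        double zc = z_centers[i];
        if (zc > lo && zc < hi) { blocked[i] = 1; any = true; }
      }
    }
    if (!any) {
      for (int i = 0; i < nz; ++i) accept(i, blk) += 1;
    } else {
      for (int i = 0; i < nz; ++i) if (!blocked[i]) accept(i, blk) += 1;
    }
  }
  return accept;
}

// [[Rcpp::export]]
IntegerVector cpp_bridge_mc(NumericVector ep1, NumericVector ep2, int Nbonds,
                            double b, int n_samples, double L, double d,
                            double x0, double y0, NumericVector z_centers,
                            double sigma_ep) {
  IntegerMatrix m = cpp_bridge_mc_blocks(ep1, ep2, Nbonds, b, n_samples, L,
                                         d, x0, y0, z_centers, sigma_ep, 1);
  IntegerVector out(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) out[i] = m(i, 0);
  return out;
}
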