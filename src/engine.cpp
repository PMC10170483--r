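// Desk-scale coarse-grained MD engine: velocity-Verlet with Langevin
// thermostatting, rigid-body propagation of the nanoparticle cores
// (quaternions, body-frame inertia), Verlet-listed truncated nonbonded
// forces (LJ 9-6 / 12-4, damped shifted-force Coulomb), harmonic bonds
// and angles, and a centre-of-mass distance restraint with optional
// constant-velocity pulling.
//
// Units: nm, ps, amu, kJ/mol (consistent: 1 kJ/mol = 1 amu nm^2/ps^2).

#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <random>
#include <cmath>

using namespace Rcpp;

static const double KB = 0.0083144621; // kJ/mol/K

struct Vec3 {
  double x, y, z;
  Vec3(double a = 0, double b = 0, double c = 0) : x(a), y(b), z(c) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  Vec3& operator+=(const Vec3& o) { x += o.x; y += o.y; z += o.z; return *this; }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3& o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm() const { return std::sqrt(x * x + y * y + z * z); }
};

struct Quat {
  double w, x, y, z;
  Quat(double a = 1, double b = 0, double c = 0, double d = 0)
    : w(a), x(b), y(c), z(d) {}
  Quat mul(const Quat& o) const {
    return Quat(w * o.w - x * o.x - y * o.y - z * o.z,
                w * o.x + x * o.w + y * o.z - z * o.y,
                w * o.y - x * o.z + y * o.w + z * o.x,
                w * o.z + x * o.y - y * o.x + z * o.w);
  }
  void normalize() {
    double n = std::sqrt(w * w + x * x + y * y + z * z);
    w /= n; x /= n; y /= n; z /= n;
  }
};

// Rotation matrix (body -> lab) from a unit quaternion, row-major.
static void quat_to_R(const Quat& q, double R[3][3]) {
  double w = q.w, x = q.x, y = q.y, z = q.z;
  R[0][0] = 1 - 2 * (y * y + z * z); R[0][1] = 2 * (x * y - w * z); R[0][2] = 2 * (x * z + w * y);
  R[1][0] = 2 * (x * y + w * z); R[1][1] = 1 - 2 * (x * x + z * z); R[1][2] = 2 * (y * z - w * x);
  R[2][0] = 2 * (x * z - w * y); R[2][1] = 2 * (y * z + w * x); R[2][2] = 1 - 2 * (x * x + y * y);
}

static inline Vec3 matvec(const double M[3][3], const Vec3& v) {
  return Vec3(M[0][0] * v.x + M[0][1] * v.y + M[0][2] * v.z,
              M[1][0] * v.x + M[1][1] * v.y + M[1][2] * v.z,
              M[2][0] * v.x + M[2][1] * v.y + M[2][2] * v.z);
}
static inline Vec3 mattvec(const double M[3][3], const Vec3& v) { // M^T v
  return Vec3(M[0][0] * v.x + M[1][0] * v.y + M[2][0] * v.z,
              M[0][1] * v.x + M[1][1] * v.y + M[2][1] * v.z,
              M[0][2] * v.x + M[1][2] * v.y + M[2][2] * v.z);
}

static void invert3(const double A[3][3], double Ainv[3][3]) {
  double det =
    A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
    A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
    A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
  if (std::fabs(det) < 1e-18) stop("singular inertia tensor in rigid group");
  double id = 1.0 / det;
  Ainv[0][0] = (A[1][1] * A[2][2] - A[1][2] * A[2][1]) * id;
  Ainv[0][1] = (A[0][2] * A[2][1] - A[0][1] * A[2][2]) * id;
  Ainv[0][2] = (A[0][1] * A[1][2] - A[0][2] * A[1][1]) * id;
  Ainv[1][0] = (A[1][2] * A[2][0] - A[1][0] * A[2][2]) * id;
  Ainv[1][1] = (A[0][0] * A[2][2] - A[0][2] * A[2][0]) * id;
  Ainv[1][2] = (A[0][2] * A[1][0] - A[0][0] * A[1][2]) * id;
  Ainv[2][0] = (A[1][0] * A[2][1] - A[1][1] * A[2][0]) * id;
  Ainv[2][1] = (A[0][1] * A[2][0] - A[0][0] * A[2][1]) * id;
  Ainv[2][2] = (A[0][0] * A[1][1] - A[0][1] * A[1][0]) * id;
}

// Cholesky A = C C^T (lower C); A symmetric positive definite.
static void chol3(const double A[3][3], double C[3][3]) {
  for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j) C[i][j] = 0;
  C[0][0] = std::sqrt(std::max(A[0][0], 1e-18));
  C[1][0] = A[1][0] / C[0][0];
  C[1][1] = std::sqrt(std::max(A[1][1] - C[1][0] * C[1][0], 1e-18));
  C[2][0] = A[2][0] / C[0][0];
  C[2][1] = (A[2][1] - C[2][0] * C[1][0]) / C[1][1];
  C[2][2] = std::sqrt(std::max(A[2][2] - C[2][0] * C[2][0] - C[2][1] * C[2][1],
                               1e-18));
}

struct RigidGroup {
  std::vector<int> members;
  double M;
  Vec3 com, V, L;           // lab frame
  Quat q;
  std::vector<Vec3> body;   // member coordinates in the body frame
  double Ibody[3][3], IbodyInv[3][3], Ichol[3][3];
  double R[3][3];
};

struct PairTables {
  int ntype;
  std::vector<double> sigma, eps; // ntype*ntype, nm / kJ/mol
  std::vector<int> form;          // 0 = LJ 9-6, 1 = LJ 12-4
  std::vector<double> eshift;     // U(rc) per pair, for the shifted option
};

struct Nonbonded {
  double rc, rc2, skin;
  double ke;        // Coulomb prefactor incl. dielectric, kJ nm / mol e^2
  double alpha;     // DSF damping, 1/nm
  bool use_coulomb;
  bool lj_shift;    // subtract U(rc) so the pair energy is continuous
  double dsf_fshift, dsf_eshift;
};

class Engine {
public:
  int n;
  std::vector<Vec3> x, v, f;
  std::vector<double> mass, q;
  Vec3 box;
  std::vector<int> typ, rigid; // rigid id per bead, -1 free
  PairTables pt;
  Nonbonded nb;
  std::vector<RigidGroup> groups;
  std::unordered_set<long long> excl; // bonded 1-2 / 1-3 exclusions
  // bonded terms
  std::vector<int> b_i, b_j;
  std::vector<double> b_k, b_b0;
  std::vector<int> a_i, a_j, a_k;
  std::vector<double> a_kt, a_t0;
  // restraint
  bool has_rest = false;
  std::vector<int> rest_a, rest_b;
  double rest_k = 0, rest_r0 = 0, rest_vel = 0, rest_half = 1.0;
  // neighbour list
  std::vector<std::pair<int,int> > nlist;
  std::vector<Vec3> x_at_build;
  // energies of the last force evaluation
  double e_bond, e_angle, e_lj, e_coul, e_rest, rc_value;
  std::mt19937_64 rng;
  std::normal_distribution<double> gauss;

  Engine() : gauss(0.0, 1.0) {}

  inline Vec3 min_image(Vec3 d) const {
    d.x -= box.x * std::round(d.x / box.x);
    d.y -= box.y * std::round(d.y / box.y);
    d.z -= box.z * std::round(d.z / box.z);
    return d;
  }
  inline long long key(int i, int j) const {
    if (i > j) std::swap(i, j);
    return (long long)i * (long long)n + j;
  }

  void build_nlist() {
    nlist.clear();
    double rv = nb.rc + nb.skin, rv2 = rv * rv;
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (rigid[i] >= 0 && rigid[i] == rigid[j]) continue;
        Vec3 d = min_image(x[i] - x[j]);
        if (d.dot(d) < rv2) {
          if (excl.count(key(i, j))) continue;
          nlist.push_back(std::make_pair(i, j));
        }
      }
    x_at_build = x;
  }

  bool nlist_stale() const {
    double lim = 0.25 * nb.skin * nb.skin; // (skin/2)^2
    for (int i = 0; i < n; ++i) {
      Vec3 d = min_image(x[i] - x_at_build[i]);
      if (d.dot(d) > lim) return true;
    }
    return false;
  }

  // centre of mass of a bead set, unwrapped relative to its first member
  Vec3 group_center(const std::vector<int>& idx, double& Mtot) const {
    Vec3 ref = x[idx[0]], acc(0, 0, 0);
    Mtot = 0;
    for (size_t k = 0; k < idx.size(); ++k) {
      Vec3 d = min_image(x[idx[k]] - ref);
      acc += d * mass[idx[k]];
      Mtot += mass[idx[k]];
    }
    return ref + acc * (1.0 / Mtot);
  }

  void compute_forces() {
    for (int i = 0; i < n; ++i) f[i] = Vec3();
    e_bond = e_angle = e_lj = e_coul = e_rest = 0;
    rc_value = NA_REAL;
    // nonbonded
    for (size_t p = 0; p < nlist.size(); ++p) {
      int i = nlist[p].first, j = nlist[p].second;
      Vec3 d = min_image(x[i] - x[j]);
      double r2 = d.dot(d);
      if (r2 >= nb.rc2) continue;
      double r = std::sqrt(r2);
      if (r < 0.05)
        stop("overlapping particles below hard floor: beads %d and %d at %f nm",
             i + 1, j + 1, r);
      int ti = typ[i], tj = typ[j];
      double sg = pt.sigma[ti * pt.ntype + tj];
      double ep = pt.eps[ti * pt.ntype + tj];
      double fr = 0; // radial force magnitude (positive = repulsive)
      if (pt.form[ti * pt.ntype + tj] == 0) {
        double s3 = sg / r; s3 = s3 * s3 * s3;
        double s6 = s3 * s3, s9 = s6 * s3;
        e_lj += 6.75 * ep * (s9 - s6);
        fr += 6.75 * ep * (9 * s9 - 6 * s6) / r;
      } else {
        double s2 = sg * sg / r2;
        double s4 = s2 * s2, s12 = s4 * s4 * s4;
        double c = 2.598076211353316; // 3*sqrt(3)/2
        e_lj += c * ep * (s12 - s4);
        fr += c * ep * (12 * s12 - 4 * s4) / r;
      }
      if (nb.lj_shift) e_lj -= pt.eshift[ti * pt.ntype + tj];
      if (nb.use_coulomb) {
        double qq = q[i] * q[j];
        if (qq != 0) {
          double ar = nb.alpha * r;
          double er = std::erfc(ar) / r;
          double gausst = 2.0 * nb.alpha / std::sqrt(M_PI) *
            std::exp(-ar * ar);
          e_coul += nb.ke * qq *
            (er - nb.dsf_eshift + nb.dsf_fshift * (r - nb.rc));
          fr += nb.ke * qq * (er / r + gausst / r - nb.dsf_fshift);
        }
      }
      Vec3 fv = d * (fr / r);
      f[i] += fv;
      f[j] += fv * (-1.0);
    }
    // bonds
    for (size_t b = 0; b < b_i.size(); ++b) {
      Vec3 d = min_image(x[b_i[b]] - x[b_j[b]]);
      double r = d.norm();
      double dr = r - b_b0[b];
      e_bond += b_k[b] * dr * dr;
      double fr = -2.0 * b_k[b] * dr;
      Vec3 fv = d * (fr / r);
      f[b_i[b]] += fv;
      f[b_j[b]] += fv * (-1.0);
    }
    // angles
    for (size_t a = 0; a < a_i.size(); ++a) {
      Vec3 rij = min_image(x[a_i[a]] - x[a_j[a]]);
      Vec3 rkj = min_image(x[a_k[a]] - x[a_j[a]]);
      double nij = rij.norm(), nkj = rkj.norm();
      double ct = rij.dot(rkj) / (nij * nkj);
      ct = std::max(-1.0, std::min(1.0, ct));
      double th = std::acos(ct);
      double st = std::sqrt(std::max(1.0 - ct * ct, 1e-12));
      double dth = th - a_t0[a];
      e_angle += a_kt[a] * dth * dth;
      double dudt = 2.0 * a_kt[a] * dth;
      Vec3 ei = rij * (1.0 / nij), ek = rkj * (1.0 / nkj);
      // f_i = -dU/dtheta * dtheta/dr_i, with dtheta/dr_i = -(e_k - c e_i)/(|rij| s)
      Vec3 fi = (ek - ei * ct) * (dudt / (st * nij));
      Vec3 fk = (ei - ek * ct) * (dudt / (st * nkj));
      f[a_i[a]] += fi;
      f[a_k[a]] += fk;
      f[a_j[a]] += (fi + fk) * (-1.0);
    }
    // COM distance restraint
    if (has_rest) {
      double Ma, Mb;
      Vec3 ca = group_center(rest_a, Ma);
      Vec3 cb = group_center(rest_b, Mb);
      Vec3 d = min_image(ca - cb);
      double r = d.norm();
      rc_value = r;
      double dr = r - rest_r0;
      e_rest = rest_half * rest_k * dr * dr;
      double fmag = -2.0 * rest_half * rest_k * dr; // along +d on group a
      if (r > 1e-12) {
        Vec3 u = d * (1.0 / r);
        for (size_t m = 0; m < rest_a.size(); ++m)
          f[rest_a[m]] += u * (fmag * mass[rest_a[m]] / Ma);
        for (size_t m = 0; m < rest_b.size(); ++m)
          f[rest_b[m]] += u * (-fmag * mass[rest_b[m]] / Mb);
      }
    }
  }

  void init_groups(const std::vector<std::vector<int> >& gidx) {
    groups.clear();
    for (size_t g = 0; g < gidx.size(); ++g) {
      RigidGroup rg;
      rg.members = gidx[g];
      double M;
      rg.com = group_center(rg.members, M);
      rg.M = M;
      // unwrap members around the COM so body coordinates are coherent
      rg.body.resize(rg.members.size());
      for (size_t m = 0; m < rg.members.size(); ++m)
        rg.body[m] = min_image(x[rg.members[m]] - rg.com);
      // COM velocity and angular momentum from the bead velocities
      Vec3 V(0, 0, 0);
      for (size_t m = 0; m < rg.members.size(); ++m)
        V += v[rg.members[m]] * mass[rg.members[m]];
      rg.V = V * (1.0 / M);
      Vec3 L(0, 0, 0);
      for (size_t m = 0; m < rg.members.size(); ++m)
        L += rg.body[m].cross((v[rg.members[m]] - rg.V)) * mass[rg.members[m]];
      rg.L = L;
      // body-frame inertia (body frame = initial lab orientation)
      double I[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
      for (size_t m = 0; m < rg.members.size(); ++m) {
        const Vec3& b = rg.body[m];
        double mm = mass[rg.members[m]];
        double r2 = b.dot(b);
        I[0][0] += mm * (r2 - b.x * b.x); I[0][1] -= mm * b.x * b.y; I[0][2] -= mm * b.x * b.z;
        I[1][1] += mm * (r2 - b.y * b.y); I[1][2] -= mm * b.y * b.z;
        I[2][2] += mm * (r2 - b.z * b.z);
      }
      I[1][0] = I[0][1]; I[2][0] = I[0][2]; I[2][1] = I[1][2];
      for (int d = 0; d < 3; ++d) I[d][d] += 1e-12; // guard collinear groups
      for (int a = 0; a < 3; ++a) for (int b2 = 0; b2 < 3; ++b2)
        rg.Ibody[a][b2] = I[a][b2];
      invert3(rg.Ibody, rg.IbodyInv);
      chol3(rg.Ibody, rg.Ichol);
      rg.q = Quat();
      quat_to_R(rg.q, rg.R);
      // snap member positions onto the rigid model
      for (size_t m = 0; m < rg.members.size(); ++m)
        x[rg.members[m]] = rg.com + matvec(rg.R, rg.body[m]);
    }
  }

  void group_force_torque(const RigidGroup& rg, Vec3& F, Vec3& T) const {
    F = Vec3(); T = Vec3();
    for (size_t m = 0; m < rg.members.size(); ++m) {
      const Vec3& fi = f[rg.members[m]];
      F += fi;
      Vec3 arm = x[rg.members[m]] - rg.com; // exact: set from com + R b
      T += arm.cross(fi);
    }
  }

  void wrap(Vec3& p) const {
    p.x -= box.x * std::floor(p.x / box.x);
    p.y -= box.y * std::floor(p.y / box.y);
    p.z -= box.z * std::floor(p.z / box.z);
  }

  double kinetic_energy() const {
    double ke = 0;
    for (int i = 0; i < n; ++i)
      if (rigid[i] < 0) ke += 0.5 * mass[i] * v[i].dot(v[i]);
    for (size_t g = 0; g < groups.size(); ++g) {
      const RigidGroup& rg = groups[g];
      ke += 0.5 * rg.M * rg.V.dot(rg.V);
      Vec3 wb = matvec(rg.IbodyInv, mattvec(rg.R, rg.L));
      Vec3 Lb = mattvec(rg.R, rg.L);
      ke += 0.5 * wb.dot(Lb);
    }
    return ke;
  }

  int ndof() const {
    int nfree = 0;
    for (int i = 0; i < n; ++i) if (rigid[i] < 0) ++nfree;
    return 3 * nfree + 6 * (int)groups.size();
  }
};

static Engine make_engine(NumericMatrix pos, NumericMatrix vel,
                          NumericVector mass, NumericVector charge,
                          NumericVector box, IntegerVector typ,
                          NumericMatrix pairSigma, NumericMatrix pairEps,
                          IntegerMatrix pairForm,
                          IntegerMatrix bonds, NumericVector bondK,
                          NumericVector bondB0,
                          IntegerMatrix angles, NumericVector angleK,
                          NumericVector angleT0,
                          IntegerVector rigidId, List config,
                          Nullable<List> restraint) {
  Engine e;
  e.n = pos.nrow();
  e.x.resize(e.n); e.v.resize(e.n); e.f.resize(e.n);
  for (int i = 0; i < e.n; ++i) {
    e.x[i] = Vec3(pos(i, 0), pos(i, 1), pos(i, 2));
    e.v[i] = Vec3(vel(i, 0), vel(i, 1), vel(i, 2));
  }
  e.mass.assign(mass.begin(), mass.end());
  e.q.assign(charge.begin(), charge.end());
  e.box = Vec3(box[0], box[1], box[2]);
  e.typ.assign(typ.begin(), typ.end());
  e.pt.ntype = pairSigma.nrow();
  e.pt.sigma.resize(e.pt.ntype * e.pt.ntype);
  e.pt.eps.resize(e.pt.ntype * e.pt.ntype);
  e.pt.form.resize(e.pt.ntype * e.pt.ntype);
  for (int a = 0; a < e.pt.ntype; ++a)
    for (int b = 0; b < e.pt.ntype; ++b) {
      e.pt.sigma[a * e.pt.ntype + b] = pairSigma(a, b);
      e.pt.eps[a * e.pt.ntype + b] = pairEps(a, b);
      e.pt.form[a * e.pt.ntype + b] = pairForm(a, b);
    }
  for (int b = 0; b < bonds.nrow(); ++b) {
    e.b_i.push_back(bonds(b, 0)); e.b_j.push_back(bonds(b, 1));
    e.b_k.push_back(bondK[b]); e.b_b0.push_back(bondB0[b]);
    e.excl.insert(e.key(bonds(b, 0), bonds(b, 1)));
  }
  for (int a = 0; a < angles.nrow(); ++a) {
    e.a_i.push_back(angles(a, 0)); e.a_j.push_back(angles(a, 1));
    e.a_k.push_back(angles(a, 2));
    e.a_kt.push_back(angleK[a]); e.a_t0.push_back(angleT0[a]);
    e.excl.insert(e.key(angles(a, 0), angles(a, 1)));
    e.excl.insert(e.key(angles(a, 1), angles(a, 2)));
    e.excl.insert(e.key(angles(a, 0), angles(a, 2))); // 1-3 exclusion
  }
  e.rigid.assign(rigidId.begin(), rigidId.end());
  e.nb.rc = as<double>(config["cutoff"]);
  e.nb.rc2 = e.nb.rc * e.nb.rc;
  e.nb.lj_shift = as<bool>(config["lj_shift"]);
  e.pt.eshift.assign(e.pt.ntype * e.pt.ntype, 0.0);
  for (int a = 0; a < e.pt.ntype; ++a)
    for (int b = 0; b < e.pt.ntype; ++b) {
      double sg = e.pt.sigma[a * e.pt.ntype + b];
      double ep = e.pt.eps[a * e.pt.ntype + b];
      double u;
      if (e.pt.form[a * e.pt.ntype + b] == 0) {
        double s3 = sg / e.nb.rc; s3 = s3 * s3 * s3;
        u = 6.75 * ep * (s3 * s3 * s3 - s3 * s3);
      } else {
        double s2 = sg * sg / (e.nb.rc * e.nb.rc);
        double s4 = s2 * s2;
        u = 2.598076211353316 * ep * (s4 * s4 * s4 - s4);
      }
      e.pt.eshift[a * e.pt.ntype + b] = u;
    }
  e.nb.skin = as<double>(config["skin"]);
  e.nb.ke = as<double>(config["ke"]);
  e.nb.alpha = as<double>(config["dsf_alpha"]);
  e.nb.use_coulomb = e.nb.ke > 0;
  double arc = e.nb.alpha * e.nb.rc;
  e.nb.dsf_eshift = std::erfc(arc) / e.nb.rc;
  e.nb.dsf_fshift = std::erfc(arc) / (e.nb.rc * e.nb.rc) +
    2.0 * e.nb.alpha / std::sqrt(M_PI) * std::exp(-arc * arc) / e.nb.rc;
  if (restraint.isNotNull()) {
    List r(restraint);
    IntegerVector ga = r["group_a"], gb = r["group_b"];
    e.rest_a.assign(ga.begin(), ga.end());
    e.rest_b.assign(gb.begin(), gb.end());
    for (size_t m = 0; m < e.rest_a.size(); ++m) e.rest_a[m] -= 1;
    for (size_t m = 0; m < e.rest_b.size(); ++m) e.rest_b[m] -= 1;
    e.rest_k = as<double>(r["k"]);
    e.rest_r0 = as<double>(r["r0"]);
    e.rest_vel = as<double>(r["velocity"]);
    e.rest_half = as<bool>(r["half"]) ? 0.5 : 1.0;
    e.has_rest = true;
  }
  // rigid groups from ids
  int ng = 0;
  for (int i = 0; i < e.n; ++i) ng = std::max(ng, e.rigid[i] + 1);
  std::vector<std::vector<int> > gidx(ng);
  for (int i = 0; i < e.n; ++i)
    if (e.rigid[i] >= 0) gidx[e.rigid[i]].push_back(i);
  e.init_groups(gidx);
  e.rng.seed((unsigned long long)as<double>(config["seed"]));
  e.build_nlist();
  return e;
}

// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix pos, NumericVector box,
                                 double cutoff) {
  int n = pos.nrow();
  Vec3 b(box[0], box[1], box[2]);
  std::vector<std::pair<int,int> > out;
  double rc2 = cutoff * cutoff;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      Vec3 d(pos(i,0) - pos(j,0), pos(i,1) - pos(j,1), pos(i,2) - pos(j,2));
      d.x -= b.x * std::round(d.x / b.x);
      d.y -= b.y * std::round(d.y / b.y);
      d.z -= b.z * std::round(d.z / b.z);
      if (d.dot(d) < rc2) out.push_back(std::make_pair(i + 1, j + 1));
    }
  IntegerMatrix m(out.size(), 2);
  for (size_t k = 0; k < out.size(); ++k) {
    m(k, 0) = out[k].first; m(k, 1) = out[k].second;
  }
  return m;
}

// [[Rcpp::export]]
List cpp_compute_forces(NumericMatrix pos, NumericMatrix vel,
                        NumericVector mass, NumericVector charge,
                        NumericVector box, IntegerVector typ,
                        NumericMatrix pairSigma, NumericMatrix pairEps,
                        IntegerMatrix pairForm,
                        IntegerMatrix bonds, NumericVector bondK,
                        NumericVector bondB0,
                        IntegerMatrix angles, NumericVector angleK,
                        NumericVector angleT0,
                        IntegerVector rigidId, List config,
                        Nullable<List> restraint) {
  Engine e = make_engine(pos, vel, mass, charge, box, typ, pairSigma,
                         pairEps, pairForm, bonds, bondK, bondB0, angles,
                         angleK, angleT0, rigidId, config, restraint);
  e.compute_forces();
  NumericMatrix fm(e.n, 3);
  for (int i = 0; i < e.n; ++i) {
    fm(i, 0) = e.f[i].x; fm(i, 1) = e.f[i].y; fm(i, 2) = e.f[i].z;
  }
  return List::create(_["forces"] = fm,
                      _["bond"] = e.e_bond, _["angle"] = e.e_angle,
                      _["lj"] = e.e_lj, _["coulomb"] = e.e_coul,
                      _["restraint"] = e.e_rest,
                      _["reaction_coordinate"] = e.rc_value);
}

// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos, NumericMatrix vel,
                NumericVector mass, NumericVector charge,
                NumericVector box, IntegerVector typ,
                NumericMatrix pairSigma, NumericMatrix pairEps,
                IntegerMatrix pairForm,
                IntegerMatrix bonds, NumericVector bondK,
                NumericVector bondB0,
                IntegerMatrix angles, NumericVector angleK,
                NumericVector angleT0,
                IntegerVector rigidId, List config,
                Nullable<List> restraint,
                int nSteps, int stride) {
  Engine e = make_engine(pos, vel, mass, charge, box, typ, pairSigma,
                         pairEps, pairForm, bonds, bondK, bondB0, angles,
                         angleK, angleT0, rigidId, config, restraint);
  double dt = as<double>(config["dt"]);
  double temperature = as<double>(config["temperature"]);
  double gamma = as<double>(config["friction"]);
  bool thermostat = gamma > 0;
  double c1 = thermostat ? std::exp(-gamma * dt) : 1.0;
  double c2base = thermostat ? std::sqrt((1.0 - c1 * c1) * KB * temperature)
                             : 0.0;

  int nRec = nSteps / stride;
  NumericVector frames(Dimension(e.n, 3, nRec));
  NumericMatrix energies(nRec, 11);
  colnames(energies) = CharacterVector::create(
    "step", "time", "bond", "angle", "lj", "coulomb", "restraint",
    "kinetic", "total", "temperature", "reaction_coordinate");
  NumericVector times(nRec);

  e.compute_forces();
  int rec = 0;
  for (int step = 1; step <= nSteps; ++step) {
    // half-kick
    for (int i = 0; i < e.n; ++i)
      if (e.rigid[i] < 0) e.v[i] += e.f[i] * (0.5 * dt / e.mass[i]);
    for (size_t g = 0; g < e.groups.size(); ++g) {
      RigidGroup& rg = e.groups[g];
      Vec3 F, T;
      e.group_force_torque(rg, F, T);
      rg.V += F * (0.5 * dt / rg.M);
      rg.L += T * (0.5 * dt);
    }
    // drift
    for (int i = 0; i < e.n; ++i)
      if (e.rigid[i] < 0) {
        e.x[i] += e.v[i] * dt;
        e.wrap(e.x[i]);
      }
    for (size_t g = 0; g < e.groups.size(); ++g) {
      RigidGroup& rg = e.groups[g];
      rg.com += rg.V * dt;
      e.wrap(rg.com);
      Vec3 wb = matvec(rg.IbodyInv, mattvec(rg.R, rg.L));
      double wn = wb.norm();
      if (wn > 1e-14) {
        double half = 0.5 * wn * dt;
        double s = std::sin(half) / wn;
        Quat dq(std::cos(half), wb.x * s, wb.y * s, wb.z * s);
        rg.q = rg.q.mul(dq);
        rg.q.normalize();
        quat_to_R(rg.q, rg.R);
      }
      for (size_t m = 0; m < rg.members.size(); ++m)
        e.x[rg.members[m]] = rg.com + matvec(rg.R, rg.body[m]);
    }
    if (e.has_rest) e.rest_r0 += e.rest_vel * dt;
    if (e.nlist_stale()) e.build_nlist();
    e.compute_forces();
    // half-kick
    for (int i = 0; i < e.n; ++i)
      if (e.rigid[i] < 0) e.v[i] += e.f[i] * (0.5 * dt / e.mass[i]);
    for (size_t g = 0; g < e.groups.size(); ++g) {
      RigidGroup& rg = e.groups[g];
      Vec3 F, T;
      e.group_force_torque(rg, F, T);
      rg.V += F * (0.5 * dt / rg.M);
      rg.L += T * (0.5 * dt);
    }
    // Langevin (Ornstein-Uhlenbeck) step
    if (thermostat) {
      for (int i = 0; i < e.n; ++i)
        if (e.rigid[i] < 0) {
          double c2 = c2base / std::sqrt(e.mass[i]);
          e.v[i] = e.v[i] * c1 +
            Vec3(e.gauss(e.rng), e.gauss(e.rng), e.gauss(e.rng)) * c2;
        }
      for (size_t g = 0; g < e.groups.size(); ++g) {
        RigidGroup& rg = e.groups[g];
        double c2 = c2base / std::sqrt(rg.M);
        rg.V = rg.V * c1 +
          Vec3(e.gauss(e.rng), e.gauss(e.rng), e.gauss(e.rng)) * c2;
        Vec3 xi(e.gauss(e.rng), e.gauss(e.rng), e.gauss(e.rng));
        Vec3 nb_ = matvec(rg.Ichol, xi); // body-frame noise ~ N(0, Ibody)
        rg.L = rg.L * c1 + matvec(rg.R, nb_) *
          std::sqrt((1.0 - c1 * c1) * KB * temperature);
      }
    }
    if (step % stride == 0) {
      // member velocities for rigid groups (for reporting)
      for (size_t g = 0; g < e.groups.size(); ++g) {
        RigidGroup& rg = e.groups[g];
        Vec3 wl = matvec(rg.R, matvec(rg.IbodyInv, mattvec(rg.R, rg.L)));
        for (size_t m = 0; m < rg.members.size(); ++m)
          e.v[rg.members[m]] = rg.V + wl.cross(e.x[rg.members[m]] - rg.com);
      }
      double ke = e.kinetic_energy();
      double temp = 2.0 * ke / (e.ndof() * KB);
      double epot = e.e_bond + e.e_angle + e.e_lj + e.e_coul + e.e_rest;
      for (int i = 0; i < e.n; ++i) {
        frames[rec * e.n * 3 + 0 * e.n + i] = e.x[i].x;
        frames[rec * e.n * 3 + 1 * e.n + i] = e.x[i].y;
        frames[rec * e.n * 3 + 2 * e.n + i] = e.x[i].z;
      }
      energies(rec, 0) = step;
      energies(rec, 1) = step * dt;
      energies(rec, 2) = e.e_bond;
      energies(rec, 3) = e.e_angle;
      energies(rec, 4) = e.e_lj;
      energies(rec, 5) = e.e_coul;
      energies(rec, 6) = e.e_rest;
      energies(rec, 7) = ke;
      energies(rec, 8) = epot + ke;
      energies(rec, 9) = temp;
      energies(rec, 10) = e.rc_value;
      times[rec] = step * dt;
      ++rec;
    }
  }
  // final state
  NumericMatrix xf(e.n, 3), vf(e.n, 3);
  for (size_t g = 0; g < e.groups.size(); ++g) {
    RigidGroup& rg = e.groups[g];
    Vec3 wl = matvec(rg.R, matvec(rg.IbodyInv, mattvec(rg.R, rg.L)));
    for (size_t m = 0; m < rg.members.size(); ++m)
      e.v[rg.members[m]] = rg.V + wl.cross(e.x[rg.members[m]] - rg.com);
  }
  for (int i = 0; i < e.n; ++i) {
    xf(i, 0) = e.x[i].x; xf(i, 1) = e.x[i].y; xf(i, 2) = e.x[i].z;
    vf(i, 0) = e.v[i].x; vf(i, 1) = e.v[i].y; vf(i, 2) = e.v[i].z;
  }
  return List::create(_["frames"] = frames, _["times"] = times,
                      _["energies"] = energies,
                      _["positions"] = xf, _["velocities"] = vf,
                      _["r0_final"] = e.has_rest ? e.rest_r0 : NA_REAL);
}
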