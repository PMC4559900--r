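#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

// Coarse-grained C-alpha SBM force field.
//
// Terms (reduced units, energies in epsilon, lengths in Angstrom):
//   bond      V = 1/2 k_b (r - r0)^2
//   angle     V = 1/2 k_a (theta - theta0)^2
//   dihedral  V = k_d [ (1 - cos(phi - phi0)) + 1/2 (1 - cos 3(phi - phi0)) ]
//   contact   V = eps (sigma/r)^12 - A eps exp(-(r - r0)^2 / (2 w^2))
//   excluded  V = eps [ (sigma/r)^12 - (sigma/rc)^12 ]  for r < rc = 3 sigma
// Excluded volume acts on every pair not listed in `excl` (bonded
// neighbours and contact pairs carry their own short-range core).

struct Topo {
  NumericMatrix bonds;     // i j r0 k
  NumericMatrix angles;    // i j k th0 ka   (vertex j)
  NumericMatrix dihedrals; // i j k l phi0 kd
  NumericMatrix cn;        // native (intra-chain) contacts: i j r0 A w
  NumericMatrix cd;        // DCA (inter-chain) restraints:  i j r0 A w
  std::vector<char> excl;  // N*N mask of pairs excluded from generic EV
  double sigma, eps, rc;
  int N;
};

static inline double d3(const NumericMatrix &X, int i, int j, double *dx) {
  dx[0] = X(i, 0) - X(j, 0);
  dx[1] = X(i, 1) - X(j, 1);
  dx[2] = X(i, 2) - X(j, 2);
  return std::sqrt(dx[0] * dx[0] + dx[1] * dx[1] + dx[2] * dx[2]);
}

static void pair_add(NumericMatrix &F, int i, int j, const double *dx,
                     double fr /* dV/dr */, double r) {
  // force on i is -dV/dr * dx/r
  const double s = -fr / r;
  F(i, 0) += s * dx[0]; F(i, 1) += s * dx[1]; F(i, 2) += s * dx[2];
  F(j, 0) -= s * dx[0]; F(j, 1) -= s * dx[1]; F(j, 2) -= s * dx[2];
}

static double contact_pair(NumericMatrix &F, const NumericMatrix &X,
                           const NumericMatrix &C, double sigma, double eps) {
  double e = 0.0, dx[3];
  for (int t = 0; t < C.nrow(); ++t) {
    const int i = (int)C(t, 0), j = (int)C(t, 1);
    const double r0 = C(t, 2), A = C(t, 3), w = C(t, 4);
    const double r = d3(X, i, j, dx);
    if (r < 1e-6) stop("overlapping particles %d and %d", i + 1, j + 1);
    const double sr = std::pow(sigma / r, 12.0);
    const double g = std::exp(-(r - r0) * (r - r0) / (2.0 * w * w));
    e += eps * sr - A * eps * g;
    const double fr = -12.0 * eps * sr / r + A * eps * g * (r - r0) / (w * w);
    pair_add(F, i, j, dx, fr, r);
  }
  return e;
}

static inline void cross(const double *a, const double *b, double *c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double norm3(const double *a) { return std::sqrt(dot(a, a)); }

static NumericVector forces_energy(const NumericMatrix &X, const Topo &tp,
                                   NumericMatrix &F) {
  std::fill(F.begin(), F.end(), 0.0);
  double e_bond = 0, e_ang = 0, e_dih = 0, e_cn = 0, e_cd = 0, e_ev = 0;
  double dx[3];

  for (int t = 0; t < tp.bonds.nrow(); ++t) {
    const int i = (int)tp.bonds(t, 0), j = (int)tp.bonds(t, 1);
    const double r0 = tp.bonds(t, 2), k = tp.bonds(t, 3);
    const double r = d3(X, i, j, dx);
    if (r < 1e-6) stop("overlapping particles %d and %d", i + 1, j + 1);
    e_bond += 0.5 * k * (r - r0) * (r - r0);
    pair_add(F, i, j, dx, k * (r - r0), r);
  }

  for (int t = 0; t < tp.angles.nrow(); ++t) {
    const int i = (int)tp.angles(t, 0), j = (int)tp.angles(t, 1),
              k = (int)tp.angles(t, 2);
    const double th0 = tp.angles(t, 3), ka = tp.angles(t, 4);
    double u[3], v[3];
    u[0] = X(i, 0) - X(j, 0); u[1] = X(i, 1) - X(j, 1); u[2] = X(i, 2) - X(j, 2);
    v[0] = X(k, 0) - X(j, 0); v[1] = X(k, 1) - X(j, 1); v[2] = X(k, 2) - X(j, 2);
    const double nu = norm3(u), nv = norm3(v);
    double ct = dot(u, v) / (nu * nv);
    ct = std::max(-1.0, std::min(1.0, ct));
    const double th = std::acos(ct);
    const double st = std::sqrt(std::max(1.0 - ct * ct, 1e-12));
    e_ang += 0.5 * ka * (th - th0) * (th - th0);
    const double c = -ka * (th - th0) / st; // = -dV/dtheta / sin(theta)
    for (int d = 0; d < 3; ++d) {
      const double dti = (ct * u[d] / nu - v[d] / nv) / nu; // dtheta/dxi * (-st)
      const double dtk = (ct * v[d] / nv - u[d] / nu) / nv;
      const double fi = c * dti, fk = c * dtk;
      F(i, d) += fi; F(k, d) += fk; F(j, d) -= fi + fk;
    }
  }

  for (int t = 0; t < tp.dihedrals.nrow(); ++t) {
    const int i = (int)tp.dihedrals(t, 0), j = (int)tp.dihedrals(t, 1),
              k = (int)tp.dihedrals(t, 2), l = (int)tp.dihedrals(t, 3);
    const double phi0 = tp.dihedrals(t, 4), kd = tp.dihedrals(t, 5);
    double b1[3], b2[3], b3[3], n1[3], n2[3], m1[3];
    for (int d = 0; d < 3; ++d) {
      b1[d] = X(j, d) - X(i, d);
      b2[d] = X(k, d) - X(j, d);
      b3[d] = X(l, d) - X(k, d);
    }
    cross(b1, b2, n1);
    cross(b2, b3, n2);
    const double nb2 = norm3(b2);
    cross(n1, b2, m1);
    const double x = dot(n1, n2), y = dot(m1, n2) / nb2;
    const double phi = std::atan2(y, x);
    const double dphi = phi - phi0;
    e_dih += kd * ((1.0 - std::cos(dphi)) + 0.5 * (1.0 - std::cos(3.0 * dphi)));
    const double dV = kd * (std::sin(dphi) + 1.5 * std::sin(3.0 * dphi));
    const double n1sq = dot(n1, n1), n2sq = dot(n2, n2);
    if (n1sq < 1e-12 || n2sq < 1e-12) continue; // collinear, force undefined
    // dphi/dx_i = g1, dphi/dx_l = g4; the inner gradients follow from
    // translation invariance: dphi/dx_j = -(1+p) g1 + q g4,
    // dphi/dx_k = p g1 - (1+q) g4, with p = b1.b2/|b2|^2, q = b3.b2/|b2|^2
    const double p = dot(b1, b2) / (nb2 * nb2), qq = dot(b3, b2) / (nb2 * nb2);
    for (int d = 0; d < 3; ++d) {
      const double fi = -dV * nb2 / n1sq * n1[d];  // = -dV * g1
      const double fl = dV * nb2 / n2sq * n2[d];   // = -dV * g4
      const double fj = -(1.0 + p) * fi + qq * fl;
      const double fk = p * fi - (1.0 + qq) * fl;
      F(i, d) += fi; F(j, d) += fj; F(k, d) += fk; F(l, d) += fl;
    }
  }

  e_cn = contact_pair(F, X, tp.cn, tp.sigma, tp.eps);
  e_cd = contact_pair(F, X, tp.cd, tp.sigma, tp.eps);

  const double rc2 = tp.rc * tp.rc;
  const double shift = std::pow(tp.sigma / tp.rc, 12.0);
  for (int i = 0; i < tp.N; ++i)
    for (int j = i + 1; j < tp.N; ++j) {
      const double r2 = (X(i, 0) - X(j, 0)) * (X(i, 0) - X(j, 0)) +
                        (X(i, 1) - X(j, 1)) * (X(i, 1) - X(j, 1)) +
                        (X(i, 2) - X(j, 2)) * (X(i, 2) - X(j, 2));
      if (r2 < 1e-12) stop("overlapping particles %d and %d", i + 1, j + 1);
      if (tp.excl[i * tp.N + j]) continue;
      if (r2 >= rc2) continue;
      const double r = std::sqrt(r2);
      dx[0] = X(i, 0) - X(j, 0); dx[1] = X(i, 1) - X(j, 1); dx[2] = X(i, 2) - X(j, 2);
      const double sr = std::pow(tp.sigma / r, 12.0);
      e_ev += tp.eps * (sr - shift);
      pair_add(F, i, j, dx, -12.0 * tp.eps * sr / r, r);
    }

  return NumericVector::create(
      _["bond"] = e_bond, _["angle"] = e_ang, _["dihedral"] = e_dih,
      _["contact"] = e_cn, _["dca"] = e_cd, _["excluded"] = e_ev,
      _["total"] = e_bond + e_ang + e_dih + e_cn + e_cd + e_ev);
}

static Topo make_topo(NumericMatrix bonds, NumericMatrix angles,
                      NumericMatrix dihedrals, NumericMatrix cn,
                      NumericMatrix cd, IntegerMatrix excl_pairs,
                      double sigma, double eps, int N) {
  Topo tp{bonds, angles, dihedrals, cn, cd,
          std::vector<char>((size_t)N * N, 0), sigma, eps, 3.0 * sigma, N};
  for (int t = 0; t < excl_pairs.nrow(); ++t) {
    int i = excl_pairs(t, 0), j = excl_pairs(t, 1);
    tp.excl[i * N + j] = 1;
    tp.excl[j * N + i] = 1;
  }
  return tp;
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix X, NumericMatrix bonds, NumericMatrix angles,
                NumericMatrix dihedrals, NumericMatrix cn, NumericMatrix cd,
                IntegerMatrix excl_pairs, double sigma, double eps) {
  Topo tp = make_topo(bonds, angles, dihedrals, cn, cd, excl_pairs,
                      sigma, eps, X.nrow());
  NumericMatrix F(X.nrow(), 3);
  NumericVector e = forces_energy(X, tp, F);
  return List::create(_["forces"] = F, _["energy"] = e);
}

// BAOAB Langevin integrator (unit masses). gamma = 0 reduces to velocity
// Verlet (NVE). Gaussian noise via Box-Muller on mt19937_64 so that runs
// are bit-reproducible for a given seed.
// [[Rcpp::export]]
List cpp_run_md(NumericMatrix X0, NumericMatrix V0, NumericMatrix bonds,
                NumericMatrix angles, NumericMatrix dihedrals,
                NumericMatrix cn, NumericMatrix cd, IntegerMatrix excl_pairs,
                double sigma, double eps, double dt, double gamma,
                double temperature, int nsteps, int stride, int seed) {
  const int N = X0.nrow();
  Topo tp = make_topo(bonds, angles, dihedrals, cn, cd, excl_pairs,
                      sigma, eps, N);
  NumericMatrix X = clone(X0), V = clone(V0), F(N, 3);

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  bool have_spare = false;
  double spare = 0.0;
  auto gauss = [&]() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = 0.0;
    while (u1 <= 1e-300) u1 = unif(rng);
    const double u2 = unif(rng);
    const double rr = std::sqrt(-2.0 * std::log(u1));
    spare = rr * std::sin(2.0 * M_PI * u2);
    have_spare = true;
    return rr * std::cos(2.0 * M_PI * u2);
  };

  const double c1 = std::exp(-gamma * dt);
  const double c2 = (gamma > 0.0)
                        ? std::sqrt((1.0 - c1 * c1) * temperature)
                        : 0.0;

  const int nframes = (stride > 0) ? nsteps / stride : 0;
  NumericVector frames(Dimension(N, 3, std::max(nframes, 0)));
  NumericMatrix ener(std::max(nframes, 0), 7);
  int fr = 0;

  NumericVector e = forces_energy(X, tp, F);
  CharacterVector enames = e.names();

  for (int step = 1; step <= nsteps; ++step) {
    for (int i = 0; i < N; ++i)
      for (int d = 0; d < 3; ++d) V(i, d) += 0.5 * dt * F(i, d);
    for (int i = 0; i < N; ++i)
      for (int d = 0; d < 3; ++d) X(i, d) += 0.5 * dt * V(i, d);
    if (gamma > 0.0)
      for (int i = 0; i < N; ++i)
        for (int d = 0; d < 3; ++d) V(i, d) = c1 * V(i, d) + c2 * gauss();
    for (int i = 0; i < N; ++i)
      for (int d = 0; d < 3; ++d) X(i, d) += 0.5 * dt * V(i, d);
    e = forces_energy(X, tp, F);
    for (int i = 0; i < N; ++i)
      for (int d = 0; d < 3; ++d) V(i, d) += 0.5 * dt * F(i, d);

    for (int i = 0; i < N; ++i)
      for (int d = 0; d < 3; ++d)
        if (std::abs(X(i, d)) > 1e4)
          stop("coordinate explosion at step %d; reduce dt", step);

    if (stride > 0 && step % stride == 0 && fr < nframes) {
      for (int i = 0; i < N; ++i)
        for (int d = 0; d < 3; ++d)
          frames[(size_t)fr * N * 3 + d * N + i] = X(i, d);
      for (int c = 0; c < 7; ++c) ener(fr, c) = e[c];
      ++fr;
    }
  }

  double ke = 0.0;
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) ke += 0.5 * V(i, d) * V(i, d);

  colnames(ener) = enames;
  return List::create(_["X"] = X, _["V"] = V, _["frames"] = frames,
                      _["energies"] = ener, _["kinetic"] = ke,
                      _["n_frames"] = fr);
}
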