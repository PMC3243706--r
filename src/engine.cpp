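// Core mechanics engine: seven harmonic lattice interactions, analytic
// forces, and the velocity-Verlet relaxation loop with kinetic-energy
// rescaling. Hot path for every relaxation, so it lives in C++.
//
// Conventions (shared with the R wrappers):
//   * positions are N x 3 (nm), forces nN, masses kDa; energies nN*nm.
//   * all indices arriving from R are 0-based.
//   * energy components, in order:
//       0 longitudinal stretch, 1 lateral stretch, 2 diagonal stretch,
//       3 longitudinal bend,    4 lateral bend,
//       5 longitudinal dihedral, 6 lateral dihedral.
//   * bend terms store the supplementary angle of A-B-C with a per-term
//     equilibrium angle (radians, nucleotide dependent for class long).
//   * dihedral terms are defined on a monomer triple plus the radial
//     reference direction of its leading monomer(s) taken from the global
//     tube axis (the lab z axis):
//       long (A,B,C): angle between plane(A,B,C) and plane(A'-A-B),
//                     A'-A radial at A;
//       lat  (D,E,F): angle between plane(D'-D-E) and plane(E'-E-F).
//     Both are evaluated as the unsigned angle between plane normals; the
//     potential is quadratic about zero so the sign is energy-irrelevant.
//     Terms whose defining plane degenerates (collinear triple, e.g. a
//     perfectly straight protofilament) contribute zero energy and force.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

static const double DEGEN_EPS = 1e-9;

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
};
static inline Vec3 operator-(const Vec3& a, const Vec3& b) {
  return Vec3(a.x - b.x, a.y - b.y, a.z - b.z);
}
static inline Vec3 operator+(const Vec3& a, const Vec3& b) {
  return Vec3(a.x + b.x, a.y + b.y, a.z + b.z);
}
static inline Vec3 operator*(double s, const Vec3& a) {
  return Vec3(s * a.x, s * a.y, s * a.z);
}
static inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x);
}
static inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

// Unit radial direction of point p from the tube axis (parallel to lab z,
// through the conformation's xy centroid); false if degenerate. Anchoring
// the axis to the centroid keeps the potential translation invariant; the
// exact gradient correction for the centroid dependence is a mean-force
// subtraction (see eval()).
static inline bool radial_unit(const Vec3& p, double cx, double cy, Vec3& u,
                               double& rho) {
  double px = p.x - cx, py = p.y - cy;
  rho = std::sqrt(px * px + py * py);
  if (rho < DEGEN_EPS) return false;
  u = Vec3(px / rho, py / rho, 0.0);
  return true;
}

// Accumulate (d uhat_r / d p)^T g into out; uhat_r = (px, py, 0)/rho with
// px, py centroid-centered.
static inline void radial_jacobian_t(const Vec3& p, double cx, double cy,
                                     double rho, const Vec3& g, Vec3& out) {
  double px = p.x - cx, py = p.y - cy;
  double r3 = rho * rho * rho;
  out.x += g.x * (1.0 / rho - px * px / r3) - g.y * px * py / r3;
  out.y += -g.x * px * py / r3 + g.y * (1.0 / rho - py * py / r3);
}

class System {
public:
  int N;
  // stretch terms
  std::vector<int> p_i, p_j, p_comp;
  std::vector<double> p_k, p_r0;
  // bend terms (A,B,C; supplementary angle at B)
  std::vector<int> t_a, t_b, t_c, t_comp;
  std::vector<double> t_k, t_th0;
  // dihedral terms (A,B,C; class 0 = longitudinal, 1 = lateral)
  std::vector<int> d_a, d_b, d_c, d_comp;
  std::vector<double> d_k;
  std::vector<int> d_class;

  System(int N_, const IntegerMatrix& pairs, const NumericVector& pk,
         const NumericVector& pr0, const IntegerVector& pcomp,
         const IntegerMatrix& triples, const NumericVector& tk,
         const NumericVector& tth0, const IntegerVector& tcomp,
         const IntegerMatrix& dihs, const NumericVector& dk,
         const IntegerVector& dcomp)
      : N(N_) {
    int M = pairs.nrow();
    p_i.resize(M); p_j.resize(M); p_comp.resize(M);
    p_k.resize(M); p_r0.resize(M);
    for (int m = 0; m < M; ++m) {
      p_i[m] = pairs(m, 0); p_j[m] = pairs(m, 1);
      p_k[m] = pk[m]; p_r0[m] = pr0[m]; p_comp[m] = pcomp[m];
    }
    int T = triples.nrow();
    t_a.resize(T); t_b.resize(T); t_c.resize(T); t_comp.resize(T);
    t_k.resize(T); t_th0.resize(T);
    for (int m = 0; m < T; ++m) {
      t_a[m] = triples(m, 0); t_b[m] = triples(m, 1); t_c[m] = triples(m, 2);
      t_k[m] = tk[m]; t_th0[m] = tth0[m]; t_comp[m] = tcomp[m];
    }
    int D = dihs.nrow();
    d_a.resize(D); d_b.resize(D); d_c.resize(D); d_comp.resize(D);
    d_k.resize(D); d_class.resize(D);
    for (int m = 0; m < D; ++m) {
      d_a[m] = dihs(m, 0); d_b[m] = dihs(m, 1); d_c[m] = dihs(m, 2);
      d_k[m] = dk[m]; d_comp[m] = dcomp[m];
      d_class[m] = (dcomp[m] == 5) ? 0 : 1;
    }
  }

  // Evaluate energies and (optionally) forces / per-monomer attribution.
  // forces/permono may be NULL. Returns component energies in comp[7].
  double eval(const std::vector<Vec3>& x, double comp[7], Vec3* forces,
              double* permono) const {
    for (int c = 0; c < 7; ++c) comp[c] = 0.0;
    if (forces) for (int i = 0; i < N; ++i) forces[i] = Vec3();
    if (permono) std::memset(permono, 0, sizeof(double) * N);
    // tube-axis anchor: xy centroid
    double cx = 0.0, cy = 0.0;
    for (int i = 0; i < N; ++i) { cx += x[i].x; cy += x[i].y; }
    if (N > 0) { cx /= N; cy /= N; }

    // stretch
    for (size_t m = 0; m < p_i.size(); ++m) {
      const Vec3& a = x[p_i[m]];
      const Vec3& b = x[p_j[m]];
      Vec3 d = b - a;
      double r = norm(d);
      double dev = r - p_r0[m];
      double e = 0.5 * p_k[m] * dev * dev;
      comp[p_comp[m]] += e;
      if (permono) {
        permono[p_i[m]] += 0.5 * e;
        permono[p_j[m]] += 0.5 * e;
      }
      if (forces && r > DEGEN_EPS) {
        double f = p_k[m] * dev / r;  // dE/dr * 1/r
        Vec3 g = f * d;               // dE/db
        forces[p_j[m]] = forces[p_j[m]] - g;
        forces[p_i[m]] = forces[p_i[m]] + g;
      }
    }

    // bend: supplementary angle of interior angle at B
    for (size_t m = 0; m < t_a.size(); ++m) {
      const Vec3& A = x[t_a[m]];
      const Vec3& B = x[t_b[m]];
      const Vec3& C = x[t_c[m]];
      Vec3 u = A - B, v = C - B;
      double nu = norm(u), nv = norm(v);
      if (nu < DEGEN_EPS || nv < DEGEN_EPS) continue;  // corrupted; R guards
      double ci = dot(u, v) / (nu * nv);
      if (ci > 1.0) ci = 1.0;
      if (ci < -1.0) ci = -1.0;
      double interior = std::acos(ci);
      double theta = M_PI - interior;
      double dev = theta - t_th0[m];
      double e = 0.5 * t_k[m] * dev * dev;
      comp[t_comp[m]] += e;
      if (permono) {
        double e3 = e / 3.0;
        permono[t_a[m]] += e3; permono[t_b[m]] += e3; permono[t_c[m]] += e3;
      }
      if (forces) {
        // dE/d(interior) = -k * dev ; grad(interior) via unit-difference form
        double dEdi = -t_k[m] * dev;
        double si = std::sqrt(std::max(1.0 - ci * ci, 0.0));
        Vec3 uh = (1.0 / nu) * u, vh = (1.0 / nv) * v;
        Vec3 da = Vec3(ci * uh.x - vh.x, ci * uh.y - vh.y, ci * uh.z - vh.z);
        Vec3 dc = Vec3(ci * vh.x - uh.x, ci * vh.y - uh.y, ci * vh.z - uh.z);
        // |da| = |dc| = sin(interior); normalize robustly
        if (si < 1e-12) {
          // exactly collinear: direction undefined; use a deterministic
          // perpendicular (radial-leaning) so straight chains under a bent
          // equilibrium still feel a kick.
          Vec3 p = cross(u, Vec3(0, 0, 1));
          if (norm(p) < DEGEN_EPS) p = cross(u, Vec3(1, 0, 0));
          double np = norm(p);
          da = (1.0 / np) * p;
          dc = (-1.0 / np) * p;
          si = 1.0;
        }
        Vec3 gA = (dEdi / (nu * si)) * da;
        Vec3 gC = (dEdi / (nv * si)) * dc;
        Vec3 gB = Vec3(-gA.x - gC.x, -gA.y - gC.y, -gA.z - gC.z);
        forces[t_a[m]] = forces[t_a[m]] - gA;
        forces[t_b[m]] = forces[t_b[m]] - gB;
        forces[t_c[m]] = forces[t_c[m]] - gC;
      }
    }

    // dihedral: unsigned angle between plane normals, quadratic about 0
    for (size_t m = 0; m < d_a.size(); ++m) {
      const Vec3& A = x[d_a[m]];
      const Vec3& B = x[d_b[m]];
      const Vec3& C = x[d_c[m]];
      Vec3 n1, n2;
      // factors of each cross product, for gradient distribution
      // n = a x b
      Vec3 a1, b1, a2, b2;
      Vec3 urA, urD, urE;
      double rhoA = 0, rhoD = 0, rhoE = 0;
      if (d_class[m] == 0) {
        // plane(A,B,C) vs plane(A'-A-B)
        a1 = B - A; b1 = C - B;
        if (!radial_unit(A, cx, cy, urA, rhoA)) continue;
        a2 = urA; b2 = B - A;
      } else {
        // plane(D'-D-E) vs plane(E'-E-F); (A,B,C) = (D,E,F)
        if (!radial_unit(A, cx, cy, urD, rhoD)) continue;
        if (!radial_unit(B, cx, cy, urE, rhoE)) continue;
        a1 = urD; b1 = B - A;
        a2 = urE; b2 = C - B;
      }
      n1 = cross(a1, b1);
      n2 = cross(a2, b2);
      double l1 = norm(n1), l2 = norm(n2);
      double sa1 = dot(a1, a1), sb1 = dot(b1, b1);
      double sa2 = dot(a2, a2), sb2 = dot(b2, b2);
      double den1 = sa1 * sb1, den2 = sa2 * sb2;
      if (den1 < 1e-24 || den2 < 1e-24) continue;
      // smooth fade-out of the term as either defining plane degenerates
      // (e.g. a perfectly straight protofilament, whose twist is not
      // measurable from positions): w_i = u_i / (u_i + WEPS) with
      // u_i = sin^2 of the angle between the plane's spanning vectors.
      const double WEPS = 1e-6;
      double u1 = (l1 * l1) / den1, u2 = (l2 * l2) / den2;
      if (u1 < 1e-12 || u2 < 1e-12) continue;  // w < 1e-6: negligible
      double w1 = u1 / (u1 + WEPS), w2 = u2 / (u2 + WEPS);
      double w = w1 * w2;
      double c = dot(n1, n2) / (l1 * l2);
      if (c > 1.0) c = 1.0;
      if (c < -1.0) c = -1.0;
      double th = std::acos(c);
      double e0 = 0.5 * d_k[m] * th * th;  // unwindowed
      double e = e0 * w;
      comp[d_comp[m]] += e;
      if (permono) {
        double e3 = e / 3.0;
        permono[d_a[m]] += e3; permono[d_b[m]] += e3; permono[d_c[m]] += e3;
      }
      if (forces) {
        // dE/dc = -w * k * th / sin(th); smooth at th -> 0
        double s = std::sqrt(std::max(1.0 - c * c, 0.0));
        double fac;
        if (th < 1e-4) {
          fac = 1.0 + th * th / 6.0;  // th/sin(th)
        } else if (s < 1e-8) {
          fac = th / 1e-8;  // clamp near pi (practically unreachable)
        } else {
          fac = th / s;
        }
        double dEdc = -d_k[m] * fac * w;
        // dc/dn1 = (n2h - c*n1h)/l1, similarly for n2
        Vec3 n1h = (1.0 / l1) * n1, n2h = (1.0 / l2) * n2;
        Vec3 G1 = (dEdc / l1) * (n2h - c * n1h);
        Vec3 G2 = (dEdc / l2) * (n1h - c * n2h);
        // n = a x b: dE/da = b x G, dE/db = G x a
        Vec3 ga1 = cross(b1, G1), gb1 = cross(G1, a1);
        Vec3 ga2 = cross(b2, G2), gb2 = cross(G2, a2);
        // window gradient: dE += e0 * (w2 dw1 + w1 dw2)
        double dw1 = WEPS / ((u1 + WEPS) * (u1 + WEPS));
        double dw2 = WEPS / ((u2 + WEPS) * (u2 + WEPS));
        double f1 = e0 * w2 * dw1, f2 = e0 * w1 * dw2;
        // du1/da1 = 2 (b1 x n1)/den1 - 2 u1 a1/|a1|^2, etc.
        Vec3 du1a = (2.0 / den1) * cross(b1, n1) - (2.0 * u1 / sa1) * a1;
        Vec3 du1b = (2.0 / den1) * cross(n1, a1) - (2.0 * u1 / sb1) * b1;
        Vec3 du2a = (2.0 / den2) * cross(b2, n2) - (2.0 * u2 / sa2) * a2;
        Vec3 du2b = (2.0 / den2) * cross(n2, a2) - (2.0 * u2 / sb2) * b2;
        ga1 = ga1 + f1 * du1a; gb1 = gb1 + f1 * du1b;
        ga2 = ga2 + f2 * du2a; gb2 = gb2 + f2 * du2b;
        Vec3 gA(0, 0, 0), gB(0, 0, 0), gC(0, 0, 0);
        if (d_class[m] == 0) {
          // a1 = B-A, b1 = C-B, a2 = ur(A), b2 = B-A
          gB = gB + ga1; gA = gA - ga1;
          gC = gC + gb1; gB = gB - gb1;
          radial_jacobian_t(A, cx, cy, rhoA, ga2, gA);
          gB = gB + gb2; gA = gA - gb2;
        } else {
          // a1 = ur(D), b1 = E-D, a2 = ur(E), b2 = F-E
          radial_jacobian_t(A, cx, cy, rhoD, ga1, gA);
          gB = gB + gb1; gA = gA - gb1;
          radial_jacobian_t(B, cx, cy, rhoE, ga2, gB);
          gC = gC + gb2; gB = gB - gb2;
        }
        forces[d_a[m]] = forces[d_a[m]] - gA;
        forces[d_b[m]] = forces[d_b[m]] - gB;
        forces[d_c[m]] = forces[d_c[m]] - gC;
      }
    }

    if (forces) {
      // centroid chain rule: the radial references depend on the xy
      // centroid, whose exact gradient correction is the mean raw gradient
      // (difference-based contributions already sum to zero).
      Vec3 fm;
      for (int i = 0; i < N; ++i) fm = fm + forces[i];
      fm = (1.0 / N) * fm;
      for (int i = 0; i < N; ++i) forces[i] = forces[i] - fm;
    }
    double tot = 0.0;
    for (int c = 0; c < 7; ++c) tot += comp[c];
    return tot;
  }
};

static System make_system(const NumericMatrix& pos, const IntegerMatrix& pairs,
                          const NumericVector& pk, const NumericVector& pr0,
                          const IntegerVector& pcomp,
                          const IntegerMatrix& triples, const NumericVector& tk,
                          const NumericVector& tth0, const IntegerVector& tcomp,
                          const IntegerMatrix& dihs, const NumericVector& dk,
                          const IntegerVector& dcomp) {
  return System(pos.nrow(), pairs, pk, pr0, pcomp, triples, tk, tth0, tcomp,
                dihs, dk, dcomp);
}

static std::vector<Vec3> to_vecs(const NumericMatrix& pos) {
  std::vector<Vec3> x(pos.nrow());
  for (int i = 0; i < pos.nrow(); ++i)
    x[i] = Vec3(pos(i, 0), pos(i, 1), pos(i, 2));
  return x;
}

// [[Rcpp::export]]
List cpp_eval(NumericMatrix pos, IntegerMatrix pairs, NumericVector pk,
              NumericVector pr0, IntegerVector pcomp, IntegerMatrix triples,
              NumericVector tk, NumericVector tth0, IntegerVector tcomp,
              IntegerMatrix dihs, NumericVector dk, IntegerVector dcomp,
              bool want_forces, bool want_permono) {
  System sys = make_system(pos, pairs, pk, pr0, pcomp, triples, tk, tth0,
                           tcomp, dihs, dk, dcomp);
  std::vector<Vec3> x = to_vecs(pos);
  int N = pos.nrow();
  std::vector<Vec3> f(want_forces ? N : 0);
  std::vector<double> pm(want_permono ? N : 0);
  double comp[7];
  double tot = sys.eval(x, comp, want_forces ? f.data() : nullptr,
                        want_permono ? pm.data() : nullptr);
  NumericVector components(7);
  for (int c = 0; c < 7; ++c) components[c] = comp[c];
  List out = List::create(_["components"] = components, _["total"] = tot);
  if (want_forces) {
    NumericMatrix fm(N, 3);
    for (int i = 0; i < N; ++i) {
      fm(i, 0) = f[i].x; fm(i, 1) = f[i].y; fm(i, 2) = f[i].z;
    }
    out["forces"] = fm;
  }
  if (want_permono) {
    out["per_monomer"] = NumericVector(pm.begin(), pm.end());
  }
  return out;
}

// Velocity-Verlet relaxation with single-scalar kinetic-energy rescaling and
// the RMS(last 10) vs RMS(last 20) potential-energy convergence criterion.
// The kinetic target anneals (geometric decay) once the potential stops
// improving, so the criterion can terminate the run.
// [[Rcpp::export]]
List cpp_relax(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
               IntegerMatrix pairs, NumericVector pk, NumericVector pr0,
               IntegerVector pcomp, IntegerMatrix triples, NumericVector tk,
               NumericVector tth0, IntegerVector tcomp, IntegerMatrix dihs,
               NumericVector dk, IntegerVector dcomp, double dt,
               double ke_target, bool rescale, bool cap_only,
               int anneal_patience, double anneal_factor, double conv_tol,
               int max_steps, double divergence_factor, int trace_thin) {
  System sys = make_system(pos, pairs, pk, pr0, pcomp, triples, tk, tth0,
                           tcomp, dihs, dk, dcomp);
  int N = pos.nrow();
  std::vector<Vec3> x = to_vecs(pos);
  std::vector<Vec3> v(N);
  for (int i = 0; i < N; ++i) v[i] = Vec3(vel(i, 0), vel(i, 1), vel(i, 2));
  std::vector<Vec3> f(N);
  double comp[7];

  double e = sys.eval(x, comp, f.data(), nullptr);
  double e0 = e, peak = e, best = e;
  double div_bound = divergence_factor * std::max(std::fabs(e0), 1.0);
  double target_total = ke_target * N;

  std::vector<double> trace;
  trace.reserve(max_steps / std::max(trace_thin, 1) + 2);
  trace.push_back(e);
  double ring[20];
  int nring = 0;
  ring[nring++ % 20] = e;

  bool converged = false, diverged = false;
  int stall = 0;
  int step = 0;
  for (step = 1; step <= max_steps; ++step) {
    // velocity-Verlet
    for (int i = 0; i < N; ++i) {
      double hdt = 0.5 * dt / mass[i];
      v[i] = v[i] + hdt * f[i];
      x[i] = x[i] + dt * v[i];
    }
    e = sys.eval(x, comp, f.data(), nullptr);
    for (int i = 0; i < N; ++i) {
      double hdt = 0.5 * dt / mass[i];
      v[i] = v[i] + hdt * f[i];
    }
    if (!std::isfinite(e)) { diverged = true; break; }
    if (e > peak) peak = e;
    if (e > div_bound) { diverged = true; break; }

    if (rescale) {
      double ke = 0.0;
      for (int i = 0; i < N; ++i) ke += 0.5 * mass[i] * dot(v[i], v[i]);
      // cap_only: the thermostat only removes energy (kinetic ceiling);
      // otherwise rescale to the exact target every step.
      bool act = ke > 0.0 && (cap_only ? ke > target_total : true);
      if (act) {
        double lam = std::sqrt(target_total / ke);
        for (int i = 0; i < N; ++i) v[i] = lam * v[i];
      }
      // staged quench: decay the kinetic target when PE stops improving
      if (e < best - conv_tol) {
        best = e;
        stall = 0;
      } else if (++stall >= anneal_patience) {
        target_total *= anneal_factor;
        stall = 0;
      }
    }

    if (step % std::max(trace_thin, 1) == 0) trace.push_back(e);
    ring[nring++ % 20] = e;

    // the RMS criterion is only meaningful once the thermostat's kinetic
    // injection is below the energy tolerance (quench complete); without
    // the gate it can fire during the thermal dwell, short of the minimum
    bool quenched = !rescale || target_total <= conv_tol;
    if (quenched && nring >= 20) {
      double s10 = 0.0, s20 = 0.0;
      for (int k = 1; k <= 20; ++k) {
        double val = ring[(nring - k) % 20];
        s20 += val * val;
        if (k <= 10) s10 += val * val;
      }
      double rms10 = std::sqrt(s10 / 10.0), rms20 = std::sqrt(s20 / 20.0);
      if (std::fabs(rms10 - rms20) < conv_tol) {
        converged = true;
        break;
      }
    }
  }
  if (step > max_steps) step = max_steps;
  // ensure final energy is on the trace
  if (trace.back() != e) trace.push_back(e);

  NumericMatrix pout(N, 3), vout(N, 3);
  for (int i = 0; i < N; ++i) {
    pout(i, 0) = x[i].x; pout(i, 1) = x[i].y; pout(i, 2) = x[i].z;
    vout(i, 0) = v[i].x; vout(i, 1) = v[i].y; vout(i, 2) = v[i].z;
  }
  NumericVector comps(7);
  for (int c = 0; c < 7; ++c) comps[c] = comp[c];
  return List::create(
      _["pos"] = pout, _["vel"] = vout,
      _["trace"] = NumericVector(trace.begin(), trace.end()),
      _["converged"] = converged, _["diverged"] = diverged,
      _["steps"] = step, _["e_initial"] = e0, _["e_final"] = e,
      _["peak_energy"] = peak, _["components"] = comps);
}

// Plain velocity-Verlet steps without convergence checks; optional rescaling.
// Used by verlet_step() and the symplectic conservation checks.
// [[Rcpp::export]]
List cpp_verlet(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
                IntegerMatrix pairs, NumericVector pk, NumericVector pr0,
                IntegerVector pcomp, IntegerMatrix triples, NumericVector tk,
                NumericVector tth0, IntegerVector tcomp, IntegerMatrix dihs,
                NumericVector dk, IntegerVector dcomp, double dt, int n_steps,
                double ke_target, bool rescale) {
  System sys = make_system(pos, pairs, pk, pr0, pcomp, triples, tk, tth0,
                           tcomp, dihs, dk, dcomp);
  int N = pos.nrow();
  std::vector<Vec3> x = to_vecs(pos);
  std::vector<Vec3> v(N);
  for (int i = 0; i < N; ++i) v[i] = Vec3(vel(i, 0), vel(i, 1), vel(i, 2));
  std::vector<Vec3> f(N);
  double comp[7];
  double e = sys.eval(x, comp, f.data(), nullptr);
  NumericVector epot(n_steps), ekin(n_steps);
  double target_total = ke_target * N;
  for (int s = 0; s < n_steps; ++s) {
    for (int i = 0; i < N; ++i) {
      double hdt = 0.5 * dt / mass[i];
      v[i] = v[i] + hdt * f[i];
      x[i] = x[i] + dt * v[i];
    }
    e = sys.eval(x, comp, f.data(), nullptr);
    if (!std::isfinite(e)) stop("non-finite energy during integration");
    double ke = 0.0;
    for (int i = 0; i < N; ++i) {
      double hdt = 0.5 * dt / mass[i];
      v[i] = v[i] + hdt * f[i];
    }
    for (int i = 0; i < N; ++i) ke += 0.5 * mass[i] * dot(v[i], v[i]);
    if (rescale && ke > 0.0) {
      double lam = std::sqrt(target_total / ke);
      for (int i = 0; i < N; ++i) v[i] = lam * v[i];
      ke = target_total;
    }
    epot[s] = e;
    ekin[s] = ke;
  }
  NumericMatrix pout(N, 3), vout(N, 3);
  for (int i = 0; i < N; ++i) {
    pout(i, 0) = x[i].x; pout(i, 1) = x[i].y; pout(i, 2) = x[i].z;
    vout(i, 0) = v[i].x; vout(i, 1) = v[i].y; vout(i, 2) = v[i].z;
  }
  return List::create(_["pos"] = pout, _["vel"] = vout, _["e_pot"] = epot,
                      _["e_kin"] = ekin);
}
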