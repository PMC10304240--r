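// Core ray-transport engine: gyroid geometry, characteristic-matrix optics
// and the photon-splitting Monte Carlo loop. The R level owns the user-facing
// module surface; the stratified-optics R implementation doubles as an
// independent cross-check for the compiled copy used here.
#include <Rcpp.h>
#include <vector>
#include <complex>
#include <cmath>
#include <cstdint>
using namespace Rcpp;
typedef std::complex<double> cd;

static const double TWOPI = 6.283185307179586476925287;

struct V3 {
  double x, y, z;
};
static inline V3 v3(double x, double y, double z) { V3 r; r.x = x; r.y = y; r.z = z; return r; }
static inline V3 add(V3 a, V3 b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 sub(V3 a, V3 b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 scl(V3 a, double s) { return v3(a.x * s, a.y * s, a.z * s); }
static inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(V3 a, V3 b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm3(V3 a) { return std::sqrt(dot(a, a)); }
static inline V3 unit(V3 a) { double n = norm3(a); return v3(a.x / n, a.y / n, a.z / n); }

struct Model {
  double R;          // sphere radius, nm
  V3 center;
  double a;          // lattice constant, nm
  double rot[9];     // orientation, column-major: world = rot * lattice
  V3 phase;          // phase offset, lattice units
  double nA, nB, nExt;
  std::vector<double> wn, wd;  // wall stack, A-side first
  bool membranes;
};

static Model unpack_model(const List& m) {
  Model M;
  M.R = as<double>(m["radius"]);
  NumericVector ce = m["center"];
  M.center = v3(ce[0], ce[1], ce[2]);
  M.a = as<double>(m["lattice_a"]);
  NumericMatrix rot = m["orientation"];
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 3; ++i) M.rot[i + 3 * j] = rot(i, j);
  NumericVector ph = m["phase_offset"];
  M.phase = v3(ph[0], ph[1], ph[2]);
  M.nA = as<double>(m["n_A"]);
  M.nB = as<double>(m["n_B"]);
  M.nExt = as<double>(m["n_exterior"]);
  NumericVector wn = m["wall_n"], wd = m["wall_d"];
  M.wn.assign(wn.begin(), wn.end());
  M.wd.assign(wd.begin(), wd.end());
  M.membranes = as<bool>(m["membranes"]);
  return M;
}

// lattice coordinates u = 2*pi*(rot^T (p - center)/a + phase)
static inline void lattice_uvw(const Model& M, V3 p, double& u, double& v, double& w) {
  V3 q = sub(p, M.center);
  double qx = M.rot[0] * q.x + M.rot[1] * q.y + M.rot[2] * q.z;
  double qy = M.rot[3] * q.x + M.rot[4] * q.y + M.rot[5] * q.z;
  double qz = M.rot[6] * q.x + M.rot[7] * q.y + M.rot[8] * q.z;
  u = TWOPI * (qx / M.a + M.phase.x);
  v = TWOPI * (qy / M.a + M.phase.y);
  w = TWOPI * (qz / M.a + M.phase.z);
}

static inline double gyroid_g(const Model& M, V3 p) {
  double u, v, w;
  lattice_uvw(M, p, u, v, w);
  return std::sin(u) * std::cos(v) + std::sin(v) * std::cos(w) + std::sin(w) * std::cos(u);
}

static inline V3 gyroid_grad(const Model& M, V3 p) {
  double u, v, w;
  lattice_uvw(M, p, u, v, w);
  double gu = std::cos(u) * std::cos(v) - std::sin(w) * std::sin(u);
  double gv = -std::sin(u) * std::sin(v) + std::cos(v) * std::cos(w);
  double gw = -std::sin(v) * std::sin(w) + std::cos(w) * std::cos(u);
  double s = TWOPI / M.a;
  return v3(s * (M.rot[0] * gu + M.rot[3] * gv + M.rot[6] * gw),
            s * (M.rot[1] * gu + M.rot[4] * gv + M.rot[7] * gw),
            s * (M.rot[2] * gu + M.rot[5] * gv + M.rot[8] * gw));
}

// region: 0 exterior, 1 compartment A (g > 0, ties to A), 2 compartment B
static inline int classify(const Model& M, V3 p) {
  V3 q = sub(p, M.center);
  if (dot(q, q) > M.R * M.R) return 0;
  return gyroid_g(M, p) >= 0.0 ? 1 : 2;
}

// [[Rcpp::export]]
NumericVector cpp_gyroid_g(List model, NumericMatrix pts) {
  Model M = unpack_model(model);
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = gyroid_g(M, v3(pts(i, 0), pts(i, 1), pts(i, 2)));
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_classify(List model, NumericMatrix pts) {
  Model M = unpack_model(model);
  int n = pts.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = classify(M, v3(pts(i, 0), pts(i, 1), pts(i, 2)));
  return out;
}

// ---------------------------------------------------------------------------
// ray-surface intersection
// hit.type: 0 none, 1 sphere, 2 membrane mid-surface
struct Hit {
  int type;
  double s;        // path length from origin
  V3 pos;
  V3 normal;       // unit; membrane: grad g direction (towards A); sphere: outward radial
};

static bool sphere_roots(const Model& M, V3 p, V3 d, double& s0, double& s1) {
  V3 q = sub(p, M.center);
  double b = dot(q, d);
  double c = dot(q, q) - M.R * M.R;
  double disc = b * b - c;
  if (disc < 0) return false;
  double sq = std::sqrt(disc);
  s0 = -b - sq;
  s1 = -b + sq;
  return true;
}

// first crossing of the g = 0 mid-surface along p + s d for s in (smin, smax],
// where the packet currently sits in `region` (1 or 2). Sampled bracketing at
// step a/50, bisection to 0.1 nm. Returns s < 0 when there is no crossing.
static double membrane_crossing(const Model& M, V3 p, V3 d, int region, double smin, double smax) {
  const double h = M.a / 50.0;
  const double tol = 0.1;
  double slo = smin;
  auto crossed = [&](double s) {
    double g = gyroid_g(M, add(p, scl(d, s)));
    return region == 1 ? (g < 0.0) : (g >= 0.0);
  };
  // the start point should be un-crossed; if not (grazing roundoff), nudge
  while (crossed(slo)) {
    slo += 0.25;
    if (slo >= smax) return -1.0;
  }
  double s = slo;
  while (s < smax) {
    double snext = std::min(s + h, smax);
    if (crossed(snext)) {
      double lo = s, hi = snext;
      while (hi - lo > tol) {
        double mid = 0.5 * (lo + hi);
        if (crossed(mid)) hi = mid; else lo = mid;
      }
      return hi;
    }
    s = snext;
  }
  return -1.0;
}

// full intersection: packet in `region` at p moving along d; search begins smin past p
static Hit intersect_core(const Model& M, V3 p, V3 d, int region, double smin) {
  Hit h;
  h.type = 0;
  double s0, s1;
  if (region == 0) {
    if (!sphere_roots(M, p, d, s0, s1)) return h;
    if (s1 <= smin) return h;               // sphere behind
    double s = (s0 > smin) ? s0 : s1;       // entry (or inside-out safety)
    h.type = 1;
    h.s = s;
    h.pos = add(p, scl(d, s));
    h.normal = unit(sub(h.pos, M.center));
    return h;
  }
  sphere_roots(M, p, d, s0, s1);            // inside: always real roots
  double sexit = s1;
  if (M.membranes) {
    double sm = membrane_crossing(M, p, d, region, smin, sexit);
    if (sm > 0) {
      V3 pos = add(p, scl(d, sm));
      V3 gr = gyroid_grad(M, pos);
      double gn = norm3(gr);
      if (gn < 1e-12) {  // degenerate gradient: step past and re-search
        double sm2 = membrane_crossing(M, p, d, region, sm + 0.5, sexit);
        if (sm2 > 0) {
          pos = add(p, scl(d, sm2));
          gr = gyroid_grad(M, pos);
          gn = norm3(gr);
          sm = sm2;
        }
      }
      if (gn >= 1e-12) {
        h.type = 2;
        h.s = sm;
        h.pos = pos;
        h.normal = scl(gr, 1.0 / gn);
        return h;
      }
    }
  }
  h.type = 1;
  h.s = sexit;
  h.pos = add(p, scl(d, sexit));
  h.normal = unit(sub(h.pos, M.center));
  return h;
}

// [[Rcpp::export]]
List cpp_intersect(List model, NumericVector origin, NumericVector direction, double smin) {
  Model M = unpack_model(model);
  V3 p = v3(origin[0], origin[1], origin[2]);
  V3 d = v3(direction[0], direction[1], direction[2]);
  int region = classify(M, p);
  Hit h = intersect_core(M, p, d, region, smin);
  if (h.type == 0) return List::create(Named("type") = 0);
  // region on the far side (just past the hit)
  int to = classify(M, add(h.pos, scl(d, 0.5)));
  V3 nu = (dot(d, h.normal) > 0) ? scl(h.normal, -1.0) : h.normal;
  double ct = -dot(d, nu);
  if (ct > 1.0) ct = 1.0;
  return List::create(
    Named("type") = h.type,
    Named("s") = h.s,
    Named("position") = NumericVector::create(h.pos.x, h.pos.y, h.pos.z),
    Named("normal") = NumericVector::create(h.normal.x, h.normal.y, h.normal.z),
    Named("theta") = std::acos(ct),
    Named("from_region") = region,
    Named("to_region") = to);
}

// ---------------------------------------------------------------------------
// characteristic-matrix optics for one crossing (both polarizations at once)
struct RT {
  cd rs, tsf;   // s reflection amplitude; s flux-normalised transmission multiplier
  cd rp, tpf;   // p analogues (p field convention: right-handed s,p,k triads)
  double Rs, Ts, Rp, Tp;
  bool tir;
};

static RT stack_rt_core(double n0, double ns, const double* wn, const double* wd,
                        int nl, bool reversed, double cth0, double k0) {
  RT out;
  double sth0 = std::sqrt(std::max(0.0, 1.0 - cth0 * cth0));
  double snell = n0 * sth0;                  // invariant n sin(theta)
  cd m11s(1, 0), m12s(0, 0), m21s(0, 0), m22s(1, 0);
  cd m11p(1, 0), m12p(0, 0), m21p(0, 0), m22p(1, 0);
  for (int k = 0; k < nl; ++k) {
    int idx = reversed ? (nl - 1 - k) : k;
    double n = wn[idx], d = wd[idx];
    double sj = snell / n;
    cd cj = (sj <= 1.0) ? cd(std::sqrt(1.0 - sj * sj), 0.0)
                        : cd(0.0, std::sqrt(sj * sj - 1.0));
    cd ph = k0 * n * d * cj;
    cd cph = std::cos(ph), sph = std::sin(ph);
    cd gs = n * cj, gp = n / cj;
    cd i(0, 1);
    // multiply M <- M * layer
    cd a11 = cph, a12 = i * sph / gs, a21 = i * gs * sph, a22 = cph;
    cd t11 = m11s * a11 + m12s * a21, t12 = m11s * a12 + m12s * a22;
    cd t21 = m21s * a11 + m22s * a21, t22 = m21s * a12 + m22s * a22;
    m11s = t11; m12s = t12; m21s = t21; m22s = t22;
    a12 = i * sph / gp; a21 = i * gp * sph;
    t11 = m11p * a11 + m12p * a21; t12 = m11p * a12 + m12p * a22;
    t21 = m21p * a11 + m22p * a21; t22 = m21p * a12 + m22p * a22;
    m11p = t11; m12p = t12; m21p = t21; m22p = t22;
  }
  double ss = snell / ns;
  bool tir = ss > 1.0;
  cd cs = tir ? cd(0.0, std::sqrt(ss * ss - 1.0)) : cd(std::sqrt(1.0 - ss * ss), 0.0);
  double g0s = n0 * cth0, g0p = n0 / cth0;
  cd gss = ns * cs, gsp = ns / cs;
  cd Ds = g0s * m11s + g0s * gss * m12s + m21s + gss * m22s;
  cd Dp = g0p * m11p + g0p * gsp * m12p + m21p + gsp * m22p;
  out.rs = (g0s * m11s + g0s * gss * m12s - m21s - gss * m22s) / Ds;
  out.rp = -(g0p * m11p + g0p * gsp * m12p - m21p - gsp * m22p) / Dp;
  cd ts = 2.0 * g0s / Ds;                    // field ratio (s)
  cd tp_t = 2.0 * g0p / Dp;                  // tangential ratio (p)
  out.Rs = std::norm(out.rs);
  out.Rp = std::norm(out.rp);
  out.tir = tir;
  if (tir) {
    out.Ts = 0.0; out.Tp = 0.0;
    out.tsf = cd(0, 0); out.tpf = cd(0, 0);
  } else {
    double csr = cs.real();
    out.Ts = (ns * csr) / (n0 * cth0) * std::norm(ts);
    cd tp_field = tp_t * (cth0 / cs);
    out.Tp = (ns * csr) / (n0 * cth0) * std::norm(tp_field);
    double f = std::sqrt((ns * csr) / (n0 * cth0));  // flux normalisation
    out.tsf = ts * f;
    out.tpf = tp_field * f;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_stack_rt(double n0, double ns, NumericVector wn, NumericVector wd,
                  double theta0, double wavelength) {
  double k0 = TWOPI / wavelength;
  RT rt = stack_rt_core(n0, ns, wn.begin(), wd.begin(), wn.size(), false,
                        std::cos(theta0), k0);
  return List::create(
    Named("rs") = ComplexVector::create(Rcomplex{rt.rs.real(), rt.rs.imag()}),
    Named("rp") = ComplexVector::create(Rcomplex{rt.rp.real(), rt.rp.imag()}),
    Named("tsf") = ComplexVector::create(Rcomplex{rt.tsf.real(), rt.tsf.imag()}),
    Named("tpf") = ComplexVector::create(Rcomplex{rt.tpf.real(), rt.tpf.imag()}),
    Named("Rs") = rt.Rs, Named("Ts") = rt.Ts,
    Named("Rp") = rt.Rp, Named("Tp") = rt.Tp,
    Named("tir") = rt.tir);
}

// ---------------------------------------------------------------------------
// splitting Monte Carlo
struct Packet {
  V3 pos, dir, b1;   // b1: s-basis vector; b2 = dir x b1
  cd As, Ap;
  double phase;
  double energy;
  int depth;
  int region;
};

struct Ledger {
  double input = 0, exited_fwd = 0, exited_bwd = 0;
  double discarded_eps = 0, discarded_depth = 0;
  double n_events = 0, n_exits = 0, n_discard = 0;
};

struct Records {
  std::vector<double> px, py, pz, dx, dy, dz, bx, by, bz;
  std::vector<double> AsRe, AsIm, ApRe, ApIm, phase, energy;
  std::vector<int> depth, forward;
  double floor_energy;
  void push(const Packet& q, int fwd) {
    px.push_back(q.pos.x); py.push_back(q.pos.y); pz.push_back(q.pos.z);
    dx.push_back(q.dir.x); dy.push_back(q.dir.y); dz.push_back(q.dir.z);
    bx.push_back(q.b1.x); by.push_back(q.b1.y); bz.push_back(q.b1.z);
    AsRe.push_back(q.As.real()); AsIm.push_back(q.As.imag());
    ApRe.push_back(q.Ap.real()); ApIm.push_back(q.Ap.imag());
    phase.push_back(q.phase); energy.push_back(q.energy);
    depth.push_back(q.depth); forward.push_back(fwd);
  }
};

// splitmix64 counter-based stream: independent of scheduling
struct Rng {
  uint64_t state;
  Rng(uint64_t seed, uint64_t ray) {
    state = seed * 0x9E3779B97F4A7C15ULL ^ (ray + 1) * 0xBF58476D1CE4E5B9ULL;
  }
  double uniform() {
    state += 0x9E3779B97F4A7C15ULL;
    uint64_t z = state;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    z = z ^ (z >> 31);
    return (z >> 11) * (1.0 / 9007199254740992.0);
  }
};

static inline double region_n(const Model& M, int r) {
  return r == 0 ? M.nExt : (r == 1 ? M.nA : M.nB);
}

// [[Rcpp::export]]
List cpp_trace(List model, NumericMatrix origins, NumericVector dir0,
               ComplexVector jones, double wavelength,
               int strategy, double epsilon, int max_depth, double seed,
               double spacing, double record_floor, double max_records) {
  Model M = unpack_model(model);
  double k0 = TWOPI / wavelength;
  int nray = origins.nrow();
  V3 d0 = unit(v3(dir0[0], dir0[1], dir0[2]));
  // initial transverse basis: b1 as close to global y as possible
  V3 ref = std::fabs(d0.y) < 0.9 ? v3(0, 1, 0) : v3(0, 0, 1);
  V3 b10 = unit(sub(ref, scl(d0, dot(ref, d0))));
  cd As0(jones[0].r, jones[0].i), Ap0(jones[1].r, jones[1].i);
  double e0 = std::norm(As0) + std::norm(Ap0);
  if (e0 <= 0) stop("zero-energy source polarization");
  // normalise each ray to unit energy
  As0 /= std::sqrt(e0);
  Ap0 /= std::sqrt(e0);

  Ledger led;
  Records rec;
  std::vector<Packet> stk;
  stk.reserve(256);
  double eps_abs = epsilon * 1.0;  // per-ray initial energy is 1
  double dtheta = (strategy == 3 && spacing > 0) ? wavelength / (M_PI * spacing) : 0.0;

  for (int ir = 0; ir < nray; ++ir) {
    Rng rng((uint64_t)seed, (uint64_t)ir);
    Packet p0;
    p0.pos = v3(origins(ir, 0), origins(ir, 1), origins(ir, 2));
    p0.dir = d0;
    p0.b1 = b10;
    p0.As = As0; p0.Ap = Ap0;
    p0.phase = 0; p0.energy = 1.0; p0.depth = 0;
    p0.region = classify(M, p0.pos);
    led.input += 1.0;
    stk.push_back(p0);

    while (!stk.empty()) {
      Packet q = stk.back();
      stk.pop_back();
      if (q.energy < eps_abs) { led.discarded_eps += q.energy; led.n_discard++; continue; }
      if (q.depth >= max_depth) { led.discarded_depth += q.energy; led.n_discard++; continue; }
      Hit h = intersect_core(M, q.pos, q.dir, q.region, 0.5);
      if (h.type == 0) {
        // outside, never meets the sphere: free exit
        rec.push(q, q.dir.x > 0 ? 1 : 0);
        if (q.dir.x > 0) led.exited_fwd += q.energy; else led.exited_bwd += q.energy;
        led.n_exits++;
        continue;
      }
      led.n_events++;
      if (led.n_events > 5e8) stop("event budget exceeded");
      q.phase += k0 * region_n(M, q.region) * h.s;
      int to = classify(M, add(h.pos, scl(q.dir, 0.5)));
      if (h.type == 2 && to == q.region) {
        // tangential graze re-entering the same compartment: continue past
        q.pos = add(h.pos, scl(q.dir, 0.5));
        q.phase += k0 * region_n(M, q.region) * 0.5;
        stk.push_back(q);
        continue;
      }
      double n_from = region_n(M, q.region);
      double n_to = region_n(M, to);
      if (h.type == 1 && std::fabs(n_from - n_to) < 1e-12) {
        // index-matched spherical boundary: no interface, pass through
        q.pos = h.pos;
        q.region = to;
        if (to == 0) {
          if (q.energy >= record_floor) rec.push(q, q.dir.x > 0 ? 1 : 0);
          if (q.dir.x > 0) led.exited_fwd += q.energy; else led.exited_bwd += q.energy;
          led.n_exits++;
        } else {
          stk.push_back(q);
        }
        continue;
      }
      V3 nu = (dot(q.dir, h.normal) > 0) ? scl(h.normal, -1.0) : h.normal;
      double ct = -dot(q.dir, nu);
      if (ct > 1.0) ct = 1.0;
      if (ct < 1e-9) ct = 1e-9;
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      // local s basis; keep previous basis at normal incidence
      V3 shat;
      bool normal_inc = st < 1e-6;
      if (normal_inc) {
        shat = q.b1;
      } else {
        shat = unit(cross(q.dir, nu));
      }
      // rotate Jones amplitudes into the new s/p basis (p = d x s)
      V3 b2 = cross(q.dir, q.b1);
      V3 phat = cross(q.dir, shat);
      cd As = q.As * dot(q.b1, shat) + q.Ap * dot(b2, shat);
      cd Ap = q.As * dot(q.b1, phat) + q.Ap * dot(b2, phat);
      // optics of the crossing
      RT rt;
      bool wall = (h.type == 2) && M.wn.size() > 0;
      if (wall) {
        bool reversedStack = (q.region == 2);  // B-side entry traverses the stack reversed
        rt = stack_rt_core(n_from, n_to, M.wn.data(), M.wd.data(), (int)M.wn.size(),
                           reversedStack, ct, k0);
      } else {
        rt = stack_rt_core(n_from, n_to, nullptr, nullptr, 0, false, ct, k0);
      }
      // children
      V3 d_r = add(q.dir, scl(nu, 2.0 * ct));
      Packet refl = q;
      refl.dir = d_r;
      refl.b1 = normal_inc ? q.b1 : shat;
      refl.As = As * rt.rs;
      refl.Ap = Ap * rt.rp;
      refl.energy = std::norm(refl.As) + std::norm(refl.Ap);
      refl.pos = h.pos;
      refl.depth = q.depth + 1;
      Packet tra = q;
      bool has_t = !rt.tir;
      if (has_t) {
        double mu = n_from / n_to;
        double ctt = std::sqrt(std::max(0.0, 1.0 - mu * mu * st * st));
        V3 d_t = unit(add(scl(q.dir, mu), scl(nu, mu * ct - ctt)));
        tra.dir = d_t;
        tra.b1 = normal_inc ? q.b1 : shat;
        tra.As = As * rt.tsf;
        tra.Ap = Ap * rt.tpf;
        tra.energy = std::norm(tra.As) + std::norm(tra.Ap);
        tra.pos = h.pos;
        tra.depth = q.depth + 1;
        tra.region = to;
      } else {
        tra.energy = 0.0;
      }
      if (strategy == 1) {
        double etot = refl.energy + tra.energy;
        if (etot <= 0) { led.n_discard++; continue; }
        double pT = tra.energy / etot;
        bool takeT = rng.uniform() < pT;
        Packet keep = takeT ? tra : refl;
        double pr = takeT ? pT : (1.0 - pT);
        // Russian roulette: scale so the kept branch is unbiased in expectation
        keep.As *= std::sqrt(1.0 / pr);
        keep.Ap *= std::sqrt(1.0 / pr);
        keep.energy = std::norm(keep.As) + std::norm(keep.Ap);
        bool exiting = takeT ? (to == 0) : (q.region == 0);
        if (exiting) {
          rec.push(keep, keep.dir.x > 0 ? 1 : 0);
          if (keep.dir.x > 0) led.exited_fwd += keep.energy; else led.exited_bwd += keep.energy;
          led.n_exits++;
        } else {
          stk.push_back(keep);
        }
        continue;
      }
      // strategies ii / iii: pursue both, weaker branch on top of the stack
      // reflected child of a sphere hit from outside leaves immediately (convex)
      auto emit = [&](Packet& c, bool exits) {
        if (c.energy < 1e-30) return;   // numerically-zero branch (e.g. matched media)
        if (exits) {
          if (c.energy >= record_floor) rec.push(c, c.dir.x > 0 ? 1 : 0);
          if (c.dir.x > 0) led.exited_fwd += c.energy; else led.exited_bwd += c.energy;
          led.n_exits++;
          return;
        }
        if (c.energy < eps_abs) { led.discarded_eps += c.energy; led.n_discard++; return; }
        stk.push_back(c);
      };
      bool refl_exits = (q.region == 0);
      bool tra_exits = has_t && (to == 0);
      if (strategy == 3 && has_t && !tra_exits && h.type == 2 && dtheta > 0) {
        // symmetric 3-ray angular kernel about the transmitted direction,
        // tilted within the plane of incidence (weights 1/4, 1/2, 1/4)
        V3 axis = normal_inc ? q.b1 : shat;
        for (int kk = -1; kk <= 1; ++kk) {
          Packet c = tra;
          double wgt = (kk == 0) ? 0.5 : 0.25;
          double ang = kk * dtheta;
          if (kk != 0) {
            double ca = std::cos(ang), sa = std::sin(ang);
            V3 d = tra.dir;
            V3 dr = add(add(scl(d, ca), scl(cross(axis, d), sa)),
                        scl(axis, dot(axis, d) * (1 - ca)));
            c.dir = unit(dr);
          }
          c.As = tra.As * std::sqrt(wgt);
          c.Ap = tra.Ap * std::sqrt(wgt);
          c.energy = tra.energy * wgt;
          emit(c, false);
        }
        emit(refl, refl_exits);
        continue;
      }
      // push stronger first so the weaker is processed first (LIFO)
      if (has_t && tra.energy < refl.energy) {
        emit(refl, refl_exits);
        emit(tra, tra_exits);
      } else {
        emit(tra, tra_exits);
        emit(refl, refl_exits);
      }
      if ((double)rec.px.size() > max_records) stop("record budget exceeded");
    }
  }

  int n = (int)rec.px.size();
  NumericMatrix pos(n, 3), dirm(n, 3), b1m(n, 3);
  ComplexVector As(n), Ap(n);
  NumericVector phase(n), energy(n);
  IntegerVector depth(n), forward(n);
  for (int i = 0; i < n; ++i) {
    pos(i, 0) = rec.px[i]; pos(i, 1) = rec.py[i]; pos(i, 2) = rec.pz[i];
    dirm(i, 0) = rec.dx[i]; dirm(i, 1) = rec.dy[i]; dirm(i, 2) = rec.dz[i];
    b1m(i, 0) = rec.bx[i]; b1m(i, 1) = rec.by[i]; b1m(i, 2) = rec.bz[i];
    As[i] = Rcomplex{rec.AsRe[i], rec.AsIm[i]};
    Ap[i] = Rcomplex{rec.ApRe[i], rec.ApIm[i]};
    phase[i] = rec.phase[i]; energy[i] = rec.energy[i];
    depth[i] = rec.depth[i]; forward[i] = rec.forward[i];
  }
  List ledger = List::create(
    Named("input") = led.input,
    Named("exited_forward") = led.exited_fwd,
    Named("exited_backward") = led.exited_bwd,
    Named("discarded_eps") = led.discarded_eps,
    Named("discarded_depth") = led.discarded_depth,
    Named("n_events") = led.n_events,
    Named("n_exits") = led.n_exits,
    Named("n_discarded") = led.n_discard);
  return List::create(
    Named("position") = pos, Named("direction") = dirm, Named("basis_s") = b1m,
    Named("amplitude_s") = As, Named("amplitude_p") = Ap,
    Named("phase") = phase, Named("energy") = energy,
    Named("depth") = depth, Named("forward") = forward,
    Named("ledger") = ledger);
}
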