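// Voxel Monte Carlo photon-packet transport (hop-drop-spin) with
// Fresnel refraction at refractive-index mismatches, Henyey-Greenstein
// scattering, Russian roulette, and an optional homogeneous-region
// acceleration for the rectangular soft-tissue shells.
//
// Geometry types:
//   "radius": nested rectangular shells in the x-z plane
//             (dermis | subcutaneous | cortical | trabecular interior),
//             extruded along y; the trabecular interior is filled by
//             periodic tiling of a binary voxel mask.
//   "zslab":  layers stacked along z (used for slab fixtures and the
//             comparison against a layered Monte Carlo reference).
//
// Per-photon counter-based RNG streams make results independent of
// execution order.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----

static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0,1)
  inline double u01() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform in (0,1]
  inline double uopen() { return 1.0 - u01(); }
};

// ------------------------------------------------------------- physics ----

struct Material { double mua, mus, g, n, mut; };

// unpolarized Fresnel reflectance; also returns the refracted cosine
static inline double fresnel_R(double ni, double nt, double cosi,
                               double &cost) {
  if (cosi > 1.0) cosi = 1.0;
  if (ni == nt) { cost = cosi; return 0.0; }
  double sini2 = 1.0 - cosi * cosi;
  double sint2 = (ni / nt) * (ni / nt) * sini2;
  if (sint2 >= 1.0) { cost = 0.0; return 1.0; }  // total internal reflection
  cost = std::sqrt(1.0 - sint2);
  double a1 = ni * cosi, a2 = nt * cost;
  double b1 = ni * cost, b2 = nt * cosi;
  double rs = (a1 - a2) / (a1 + a2);
  double rp = (b1 - b2) / (b1 + b2);
  return 0.5 * (rs * rs + rp * rp);
}

static inline double hg_cos(double g, double xi) {
  if (std::fabs(g) < 1e-12) return 2.0 * xi - 1.0;
  double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * xi);
  return (1.0 + g * g - t * t) / (2.0 * g);
}

static inline void spin(double *u, double g, Xoshiro &rng) {
  double ct = hg_cos(g, rng.u01());
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 2.0 * M_PI * rng.u01();
  double cp = std::cos(phi), sp = std::sin(phi);
  double ux = u[0], uy = u[1], uz = u[2];
  if (std::fabs(uz) > 0.99999) {
    u[0] = st * cp;
    u[1] = st * sp;
    u[2] = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    u[0] = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    u[1] = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    u[2] = -st * cp * den + uz * ct;
  }
  double norm = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  u[0] /= norm; u[1] /= norm; u[2] /= norm;
}

// ------------------------------------------------------------ geometry ----

struct Model {
  int type;                  // 0 = radius, 1 = zslab
  double lv;
  int nx, ny, nz;
  int nd, ns, nc, off;       // radius shells (voxels); off = nd + ns
  int box_lo, box_hi;        // interior trabecular box in x and z (voxels)
  const int *mask;           // trabecular mask (radius), column-major
  int mdx, mdy, mdz;
  std::vector<int> zlab;     // zslab: label per z index
  std::vector<Material> mat; // material per label
  double n_ambient;

  inline int label(int ix, int iy, int iz) const {
    if (type == 1) return zlab[iz];
    int fx = ix < nx - 1 - ix ? ix : nx - 1 - ix;
    int fz = iz < nz - 1 - iz ? iz : nz - 1 - iz;
    int ring = fx < fz ? fx : fz;
    if (ring < nd) return 0;
    if (ring < nd + ns) return 1;
    if (ring < nd + ns + nc) return 2;
    int mx = (ix - off) % mdx; if (mx < 0) mx += mdx;
    int my = iy % mdy;         if (my < 0) my += mdy;
    int mz = (iz - off) % mdz; if (mz < 0) mz += mdz;
    return mask[mx + (size_t)mdx * (my + (size_t)mdy * mz)] ? 3 : 4;
  }
  inline bool in_interior(int ix, int iz) const {
    return type == 0 && ix >= box_lo && ix < box_hi &&
           iz >= box_lo && iz < box_hi;
  }
};

struct Photon {
  int a[3];        // voxel address
  double p[3];     // local position within voxel, in [-lv/2, lv/2]
  double u[3];     // unit direction
  double w;        // weight
  double s;        // remaining physical step length in current material
  int m;           // current material (label) index
  bool alive;
};

struct Tally {
  double absorbed = 0.0, specular = 0.0;
  std::vector<double> ex, ey, ez, eux, euy, euz, ew;
  std::vector<int> eface;
};

// face codes: 1 z_min, 2 z_max, 3 x_max, 4 x_min, 5 y_min, 6 y_max
static inline int face_code(int axis, int sgn) {
  if (axis == 2) return sgn > 0 ? 2 : 1;
  if (axis == 0) return sgn > 0 ? 3 : 4;
  return sgn > 0 ? 6 : 5;
}

static inline void global_pos(const Model &M, const Photon &ph, double *g) {
  for (int i = 0; i < 3; ++i)
    g[i] = (ph.a[i] + 0.5) * M.lv + ph.p[i];
}

static inline void clamp_local(Photon &ph, double half) {
  for (int i = 0; i < 3; ++i) {
    if (ph.p[i] > half)  ph.p[i] = half;
    if (ph.p[i] < -half) ph.p[i] = -half;
  }
}

// deposit + spin + roulette at a scattering site; draws the next step
static inline void scatter_event(const Model &M, Photon &ph, Tally &T,
                                 Xoshiro &rng, double thr, double chance) {
  const Material &mt = M.mat[ph.m];
  double dep = ph.w * mt.mua / mt.mut;
  T.absorbed += dep;
  ph.w -= dep;
  if (ph.w <= 0.0) {           // fully absorbed (mu_s = 0 voxel)
    ph.w = 0.0;
    ph.alive = false;
    return;
  }
  spin(ph.u, mt.g, rng);
  if (ph.w < thr) {
    if (rng.u01() < chance) {
      double boost = ph.w / chance - ph.w;
      ph.w += boost;
      T.absorbed -= boost;          // roulette-corrected accounting
    } else {
      T.absorbed += ph.w;
      ph.w = 0.0;
      ph.alive = false;
      return;
    }
  }
  ph.s = -std::log(rng.uopen()) / mt.mut;
}

// attempt escape through an outer face; returns true if the photon left
static inline bool try_escape(const Model &M, Photon &ph, Tally &T,
                              Xoshiro &rng, int axis, int sgn) {
  const Material &mt = M.mat[ph.m];
  double cosi = std::fabs(ph.u[axis]), cost;
  double R = fresnel_R(mt.n, M.n_ambient, cosi, cost);
  if (rng.u01() < R) {               // internal reflection at the surface
    ph.u[axis] = -ph.u[axis];
    return false;
  }
  double g[3];
  global_pos(M, ph, g);
  double scale = mt.n / M.n_ambient;
  double uo[3];
  for (int i = 0; i < 3; ++i) uo[i] = ph.u[i] * scale;
  uo[axis] = (sgn > 0 ? 1.0 : -1.0) * cost;
  double norm = std::sqrt(uo[0]*uo[0] + uo[1]*uo[1] + uo[2]*uo[2]);
  T.ex.push_back(g[0]); T.ey.push_back(g[1]); T.ez.push_back(g[2]);
  T.eux.push_back(uo[0]/norm); T.euy.push_back(uo[1]/norm);
  T.euz.push_back(uo[2]/norm);
  T.ew.push_back(ph.w);
  T.eface.push_back(face_code(axis, sgn));
  ph.alive = false;
  return true;
}

// one boundary crossing in the voxel frame (photon sits exactly on a voxel
// face); handles grid exit, Fresnel, transmission and step rescaling
static inline void cross_voxel_face(const Model &M, Photon &ph, Tally &T,
                                    Xoshiro &rng, int axis, int sgn,
                                    double half) {
  int na[3] = { ph.a[0], ph.a[1], ph.a[2] };
  na[axis] += sgn;
  const int dims[3] = { M.nx, M.ny, M.nz };
  if (na[axis] < 0 || na[axis] >= dims[axis]) {
    try_escape(M, ph, T, rng, axis, sgn);
    return;
  }
  int lab2 = M.label(na[0], na[1], na[2]);
  if (lab2 == ph.m) {                      // same material: free transfer
    ph.a[axis] = na[axis];
    ph.p[axis] = -sgn * half;
    return;
  }
  const Material &m1 = M.mat[ph.m];
  const Material &m2 = M.mat[lab2];
  if (m1.n != m2.n) {
    double cosi = std::fabs(ph.u[axis]), cost;
    double R = fresnel_R(m1.n, m2.n, cosi, cost);
    if (rng.u01() < R) {                   // internal reflection
      ph.u[axis] = -ph.u[axis];
      return;
    }
    double scale = m1.n / m2.n;
    for (int i = 0; i < 3; ++i) ph.u[i] *= scale;
    ph.u[axis] = (sgn > 0 ? 1.0 : -1.0) * cost;
    double norm = std::sqrt(ph.u[0]*ph.u[0] + ph.u[1]*ph.u[1] +
                            ph.u[2]*ph.u[2]);
    ph.u[0] /= norm; ph.u[1] /= norm; ph.u[2] /= norm;
  }
  ph.s *= m1.mut / m2.mut;                 // leftover step in the new medium
  ph.m = lab2;
  ph.a[axis] = na[axis];
  ph.p[axis] = -sgn * half;
}

// voxel-by-voxel propagation; if box_only, returns as soon as the photon
// leaves the interior trabecular box (crossing already applied)
static void voxel_loop(const Model &M, Photon &ph, Tally &T, Xoshiro &rng,
                       double thr, double chance, bool box_only) {
  const double half = 0.5 * M.lv;
  while (ph.alive) {
    // distance to the nearest voxel face along the direction of travel
    double db = std::numeric_limits<double>::infinity();
    int axis = -1, sgn = 0;
    for (int i = 0; i < 3; ++i) {
      double ui = ph.u[i];
      if (ui == 0.0) continue;
      double si = ui > 0 ? 1.0 : -1.0;
      double di = (half - ph.p[i] * si) / std::fabs(ui);
      if (di < db) { db = di; axis = i; sgn = (int)si; }
    }
    if (axis < 0) stop("photon with zero direction vector");
    if (db < 0) db = 0;
    if (ph.s < db) {                        // interaction inside the voxel
      for (int i = 0; i < 3; ++i) ph.p[i] += ph.u[i] * ph.s;
      clamp_local(ph, half);
      scatter_event(M, ph, T, rng, thr, chance);
    } else {                                // advance to the voxel face
      for (int i = 0; i < 3; ++i) ph.p[i] += ph.u[i] * db;
      ph.p[axis] = sgn * half;
      clamp_local(ph, half);
      ph.s -= db;
      cross_voxel_face(M, ph, T, rng, axis, sgn, half);
      if (box_only && ph.alive && !M.in_interior(ph.a[0], ph.a[2])) return;
    }
  }
}

// ------------------------------------------- region-accelerated tracing ----

// collect candidate region planes (mm) along one axis for the shell zone
static void region_planes(const Model &M, std::vector<double> &px,
                          std::vector<double> &pz, std::vector<double> &py) {
  double lv = M.lv;
  int c3 = M.off + M.nc;
  int cs[3] = { M.nd, M.off, c3 };
  px.clear(); pz.clear(); py.clear();
  px.push_back(0.0); px.push_back(M.nx * lv);
  pz.push_back(0.0); pz.push_back(M.nz * lv);
  for (int k = 0; k < 3; ++k) {
    px.push_back(cs[k] * lv); px.push_back((M.nx - cs[k]) * lv);
    pz.push_back(cs[k] * lv); pz.push_back((M.nz - cs[k]) * lv);
  }
  py.push_back(0.0); py.push_back(M.ny * lv);
}

static inline void to_voxel_frame(const Model &M, Photon &ph,
                                  const double *g) {
  for (int i = 0; i < 3; ++i) {
    int ai = (int)std::floor(g[i] / M.lv);
    int dims[3] = { M.nx, M.ny, M.nz };
    if (ai < 0) ai = 0;
    if (ai >= dims[i]) ai = dims[i] - 1;
    ph.a[i] = ai;
    ph.p[i] = g[i] - (ai + 0.5) * M.lv;
  }
  clamp_local(ph, 0.5 * M.lv);
}

static void region_loop(const Model &M, Photon &ph, Tally &T, Xoshiro &rng,
                        double thr, double chance) {
  std::vector<double> plx, plz, ply;
  region_planes(M, plx, plz, ply);
  const std::vector<double> *pl[3] = { &plx, &ply, &plz };
  const double nudge = 1e-9 * M.lv;
  double g[3];
  global_pos(M, ph, g);

  while (ph.alive) {
    if (M.in_interior(ph.a[0], ph.a[2])) {
      voxel_loop(M, ph, T, rng, thr, chance, true);
      if (!ph.alive) return;
      global_pos(M, ph, g);
      continue;
    }
    // photon is in a homogeneous shell: hop region-plane to region-plane
    double tmin = std::numeric_limits<double>::infinity();
    int axis = -1, sgn = 0;
    for (int i = 0; i < 3; ++i) {
      double ui = ph.u[i];
      if (ui == 0.0) continue;
      for (double c : *pl[i]) {
        double t = (c - g[i]) / ui;
        if (t > nudge && t < tmin) { tmin = t; axis = i; sgn = ui > 0 ? 1 : -1; }
      }
    }
    if (axis < 0) stop("region tracing found no candidate plane");
    if (ph.s < tmin) {
      for (int i = 0; i < 3; ++i) g[i] += ph.u[i] * ph.s;
      to_voxel_frame(M, ph, g);
      scatter_event(M, ph, T, rng, thr, chance);
      global_pos(M, ph, g);
      continue;
    }
    for (int i = 0; i < 3; ++i) g[i] += ph.u[i] * tmin;
    ph.s -= tmin;
    to_voxel_frame(M, ph, g);
    ph.p[axis] = sgn * 0.5 * M.lv;          // sit exactly on the face
    // address of the voxel we are leaving (to the low side of the plane)
    int c_idx = (int)std::llround(g[axis] / M.lv);
    ph.a[axis] = sgn > 0 ? c_idx - 1 : c_idx;
    int dims[3] = { M.nx, M.ny, M.nz };
    if (ph.a[axis] < 0) ph.a[axis] = 0;
    if (ph.a[axis] >= dims[axis]) ph.a[axis] = dims[axis] - 1;
    cross_voxel_face(M, ph, T, rng, axis, sgn, 0.5 * M.lv);
    if (!ph.alive) return;
    global_pos(M, ph, g);
    // nudge off the plane to avoid re-selecting it
    for (int i = 0; i < 3; ++i) g[i] += ph.u[i] * nudge;
    to_voxel_frame(M, ph, g);
    ph.m = M.label(ph.a[0], ph.a[1], ph.a[2]);
  }
}

// ------------------------------------------------------------ interface ----

static Model parse_model(const List &model, double ambient_n) {
  Model M;
  std::string type = as<std::string>(model["type"]);
  M.type = (type == "zslab") ? 1 : 0;
  M.lv = as<double>(model["lv"]);
  IntegerVector dims = model["dims"];
  M.nx = dims[0]; M.ny = dims[1]; M.nz = dims[2];
  M.n_ambient = ambient_n;
  NumericMatrix om = model["optics"];
  for (int i = 0; i < om.nrow(); ++i) {
    Material mt;
    mt.mua = om(i, 0); mt.mus = om(i, 1); mt.g = om(i, 2); mt.n = om(i, 3);
    mt.mut = mt.mua + mt.mus;
    if (mt.mut <= 0) stop("material %d has mu_a + mu_s = 0 (vacuum voxels unsupported)", i + 1);
    M.mat.push_back(mt);
  }
  if (M.type == 0) {
    M.nd = as<int>(model["n_dermis"]);
    M.ns = as<int>(model["n_subcut"]);
    M.nc = as<int>(model["n_cortical"]);
    M.off = M.nd + M.ns;
    M.box_lo = M.off + M.nc;
    M.box_hi = M.nx - M.box_lo;
    LogicalVector mk = model["mask_data"];
    M.mask = LOGICAL(mk);
    IntegerVector md = model["mask_dims"];
    M.mdx = md[0]; M.mdy = md[1]; M.mdz = md[2];
  } else {
    IntegerVector zb = model["z_bands"];
    M.zlab.resize(M.nz);
    int iz = 0;
    for (int k = 0; k < zb.size(); ++k)
      for (int j = 0; j < zb[k] && iz < M.nz; ++j) M.zlab[iz++] = k;
    while (iz < M.nz) M.zlab[iz++] = zb.size() - 1;
    M.nd = M.ns = M.nc = M.off = 0;
    M.box_lo = 0; M.box_hi = 0;
    M.mask = nullptr; M.mdx = M.mdy = M.mdz = 1;
  }
  return M;
}

// [[Rcpp::export]]
List cpp_run_transport(List model, double n_photons, int seed,
                       double roulette_threshold, double roulette_chance,
                       std::string mode, double ambient_n,
                       bool record_escapes) {
  Model M = parse_model(model, ambient_n);
  bool region_mode = (mode == "region") && M.type == 0;
  long N = (long)n_photons;
  if (N < 1) stop("n_photons must be >= 1");

  // launch: center of the entry (z = 0) face, direction +z
  double cx = 0.5 * M.nx * M.lv, cy = 0.5 * M.ny * M.lv;
  int ax0 = M.nx / 2, ay0 = M.ny / 2;
  double px0 = cx - (ax0 + 0.5) * M.lv;
  double py0 = cy - (ay0 + 0.5) * M.lv;
  int m0 = M.label(ax0, ay0, 0);
  double n1 = M.mat[m0].n;
  double rsp = ((ambient_n - n1) / (ambient_n + n1));
  rsp *= rsp;
  double w0 = 1.0 - rsp;

  Tally T;
  T.specular = rsp * (double)N;
  if (record_escapes) {
    size_t res = (size_t)std::min((double)N, 4e6);
    T.ex.reserve(res); T.ew.reserve(res);
  }

  for (long i = 0; i < N; ++i) {
    Xoshiro rng(((uint64_t)(uint32_t)seed << 32) ^ (uint64_t)(i + 1));
    Photon ph;
    ph.a[0] = ax0; ph.a[1] = ay0; ph.a[2] = 0;
    ph.p[0] = px0; ph.p[1] = py0; ph.p[2] = -0.5 * M.lv;
    ph.u[0] = 0.0; ph.u[1] = 0.0; ph.u[2] = 1.0;
    ph.w = w0;
    ph.m = m0;
    ph.alive = true;
    ph.s = -std::log(rng.uopen()) / M.mat[ph.m].mut;
    if (region_mode) region_loop(M, ph, T, rng, roulette_threshold, roulette_chance);
    else voxel_loop(M, ph, T, rng, roulette_threshold, roulette_chance, false);
    if ((i & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  List esc;
  if (record_escapes) {
    esc = List::create(
      _["x"] = wrap(T.ex), _["y"] = wrap(T.ey), _["z"] = wrap(T.ez),
      _["ux"] = wrap(T.eux), _["uy"] = wrap(T.euy), _["uz"] = wrap(T.euz),
      _["w"] = wrap(T.ew), _["face"] = wrap(T.eface));
  }
  double esc_w = 0.0;
  for (double w : T.ew) esc_w += w;
  return List::create(
    _["escapes"] = esc,
    _["absorbed"] = T.absorbed,
    _["specular"] = T.specular,
    _["escaped_weight"] = esc_w,
    _["n_launched"] = (double)N);
}

// [[Rcpp::export]]
NumericVector cpp_sample_hg(int n, double g, int seed) {
  Xoshiro rng((uint64_t)(uint32_t)seed * 0x9E3779B97F4A7C15ULL + 1ULL);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hg_cos(g, rng.u01());
  return out;
}

// [[Rcpp::export]]
List cpp_fresnel(double ni, double nt, double cosi) {
  double cost;
  double R = fresnel_R(ni, nt, cosi, cost);
  return List::create(_["R"] = R, _["cos_t"] = cost);
}

// ------------------------------------------ Euclidean distance transform ----

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher)
static void edt1d(const double *f, double *d, int n, int *v, double *z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(IntegerVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  const double BIG = 1e30;
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = mask[i] ? BIG : 0.0;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int kz = 0; kz < nz; ++kz)
    for (int ky = 0; ky < ny; ++ky) {
      size_t base = (size_t)nx * (ky + (size_t)ny * kz);
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      edt1d(f.data(), d.data(), nx, v.data(), z.data());
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // y pass
  for (int kz = 0; kz < nz; ++kz)
    for (int kx = 0; kx < nx; ++kx) {
      for (int j = 0; j < ny; ++j)
        f[j] = out[kx + (size_t)nx * (j + (size_t)ny * kz)];
      edt1d(f.data(), d.data(), ny, v.data(), z.data());
      for (int j = 0; j < ny; ++j)
        out[kx + (size_t)nx * (j + (size_t)ny * kz)] = d[j];
    }
  // z pass
  for (int ky = 0; ky < ny; ++ky)
    for (int kx = 0; kx < nx; ++kx) {
      for (int k = 0; k < nz; ++k)
        f[k] = out[kx + (size_t)nx * (ky + (size_t)ny * k)];
      edt1d(f.data(), d.data(), nz, v.data(), z.data());
      for (int k = 0; k < nz; ++k)
        out[kx + (size_t)nx * (ky + (size_t)ny * k)] = d[k];
    }
  return out;
}
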