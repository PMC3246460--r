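// Bond Fluctuation Model engine with dynamic cross-links (loops).
//
// Conventions used throughout:
//  * positions are unwrapped integer lattice coordinates; periodic wrapping
//    is applied only inside the site-occupancy hash, so all geometry seen by
//    the analysis code is free of box artefacts;
//  * each monomer occupies the 2x2x2 cube of lattice sites whose lower
//    corner is its position; excluded volume = no two cubes share a site;
//  * monomer indices are 0-based internally, 1-based at the R interface;
//  * one sweep = N attempted single-site moves, then link expiry, then
//    link formation; the sweep counter increments before the link update.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <cmath>
#include <random>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// BFM bond set: permutations and sign changes of the six base vectors
// (2,0,0) (2,1,0) (2,1,1) (2,2,1) (3,0,0) (3,1,0)  -> 108 distinct vectors
// ---------------------------------------------------------------------------

static bool bond_tab[7][7][7];
static bool bond_tab_ready = false;

static void build_bond_tab() {
  if (bond_tab_ready) return;
  std::memset(bond_tab, 0, sizeof(bond_tab));
  const int base[6][3] = {{2,0,0},{2,1,0},{2,1,1},{2,2,1},{3,0,0},{3,1,0}};
  const int perm[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
  for (int b = 0; b < 6; ++b)
    for (int p = 0; p < 6; ++p)
      for (int sx = -1; sx <= 1; sx += 2)
        for (int sy = -1; sy <= 1; sy += 2)
          for (int sz = -1; sz <= 1; sz += 2) {
            int vx = base[b][perm[p][0]] * sx;
            int vy = base[b][perm[p][1]] * sy;
            int vz = base[b][perm[p][2]] * sz;
            bond_tab[vx + 3][vy + 3][vz + 3] = true;
          }
  bond_tab_ready = true;
}

static inline bool bond_ok(int dx, int dy, int dz) {
  if (dx < -3 || dx > 3 || dy < -3 || dy > 3 || dz < -3 || dz > 3) return false;
  return bond_tab[dx + 3][dy + 3][dz + 3];
}

// [[Rcpp::export]]
IntegerMatrix cpp_bond_vectors() {
  build_bond_tab();
  std::vector<std::array<int, 3>> v;
  for (int dx = -3; dx <= 3; ++dx)
    for (int dy = -3; dy <= 3; ++dy)
      for (int dz = -3; dz <= 3; ++dz)
        if (bond_tab[dx + 3][dy + 3][dz + 3]) v.push_back({dx, dy, dz});
  IntegerMatrix out(v.size(), 3);
  for (size_t k = 0; k < v.size(); ++k) {
    out(k, 0) = v[k][0]; out(k, 1) = v[k][1]; out(k, 2) = v[k][2];
  }
  return out;
}

// [[Rcpp::export]]
bool cpp_is_bond_vector(IntegerVector d) {
  build_bond_tab();
  if (d.size() != 3) stop("bond vector must have 3 components");
  return bond_ok(d[0], d[1], d[2]);
}

// ---------------------------------------------------------------------------
// Site-occupancy hash: wrapped lattice site -> owning monomer.
// Open addressing, linear probing, backward-shift deletion.
// ---------------------------------------------------------------------------

struct SiteMap {
  static constexpr uint64_t EMPTY = ~0ULL;
  std::vector<uint64_t> keys;
  std::vector<int32_t> vals;
  uint64_t mask;

  void init(size_t min_cap) {
    size_t cap = 64;
    while (cap < min_cap) cap <<= 1;
    keys.assign(cap, EMPTY);
    vals.assign(cap, -1);
    mask = cap - 1;
  }
  static inline uint64_t hash(uint64_t x) {
    x += 0x9e3779b97f4a7c15ULL;
    x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
    x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
    return x ^ (x >> 31);
  }
  inline size_t slot(uint64_t k) const {
    size_t i = hash(k) & mask;
    while (keys[i] != EMPTY && keys[i] != k) i = (i + 1) & mask;
    return i;
  }
  inline int32_t get(uint64_t k) const {
    size_t i = slot(k);
    return keys[i] == EMPTY ? -1 : vals[i];
  }
  inline void insert(uint64_t k, int32_t v) {
    size_t i = slot(k);
    keys[i] = k;
    vals[i] = v;
  }
  inline void erase(uint64_t k) {
    size_t i = slot(k);
    if (keys[i] == EMPTY) return;
    size_t j = i;
    for (;;) {
      j = (j + 1) & mask;
      if (keys[j] == EMPTY) break;
      size_t h = hash(keys[j]) & mask;
      bool shift = (j > i) ? (h <= i || h > j) : (h <= i && h > j);
      if (shift) { keys[i] = keys[j]; vals[i] = vals[j]; i = j; }
    }
    keys[i] = EMPTY;
    vals[i] = -1;
  }
};

// ---------------------------------------------------------------------------
// Engine
// ---------------------------------------------------------------------------

struct Link { int i, j; double expiry; };

static const int DIRS[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};

struct Engine {
  int N = 0, box = 0, cutoff = 0, max_links = 0;
  double p_form = 0.0, lifetime = 0.0, force = 0.0;
  bool box_pow2 = false;
  uint64_t box_mask = 0;
  std::vector<int> x, y, z;                 // unwrapped coordinates
  SiteMap occ;
  std::vector<Link> links;
  std::vector<std::vector<int>> partners;   // cross-link partners per monomer
  double sweep = 0.0;
  std::mt19937_64 rng;
  std::uniform_real_distribution<double> unif{0.0, 1.0};

  void set_box(int b) {
    box = b;
    box_pow2 = (b & (b - 1)) == 0;
    box_mask = (uint64_t)(b - 1);
  }

  inline uint64_t site_key(int xi, int yi, int zi) const {
    uint64_t wx, wy, wz;
    if (box_pow2) {
      wx = (uint64_t)xi & box_mask;
      wy = (uint64_t)yi & box_mask;
      wz = (uint64_t)zi & box_mask;
    } else {
      wx = (uint64_t)(((xi % box) + box) % box);
      wy = (uint64_t)(((yi % box) + box) % box);
      wz = (uint64_t)(((zi % box) + box) % box);
    }
    return wx | (wy << 21) | (wz << 42);
  }

  void build_occupancy(bool check) {
    occ.init((size_t)N * 32);
    for (int m = 0; m < N; ++m)
      for (int a = 0; a < 2; ++a)
        for (int b = 0; b < 2; ++b)
          for (int c = 0; c < 2; ++c) {
            uint64_t k = site_key(x[m] + a, y[m] + b, z[m] + c);
            if (check) {
              int32_t v = occ.get(k);
              if (v >= 0 && v != m)
                stop("excluded volume violated between monomers %d and %d",
                     v + 1, m + 1);
            }
            occ.insert(k, m);
          }
  }

  inline bool has_partner(int i, int j) const {
    for (int q : partners[i]) if (q == j) return true;
    return false;
  }

  inline double ree() const {
    double dx = (double)x[N - 1] - x[0];
    double dy = (double)y[N - 1] - y[0];
    double dz = (double)z[N - 1] - z[0];
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  inline double ree2() const {
    double dx = (double)x[N - 1] - x[0];
    double dy = (double)y[N - 1] - y[0];
    double dz = (double)z[N - 1] - z[0];
    return dx * dx + dy * dy + dz * dz;
  }

  void attempt_move() {
    uint64_t r = rng();
    int m = (int)(r % (uint64_t)N);
    int d = (int)((r >> 32) % 6u);
    int nx = x[m] + DIRS[d][0];
    int ny = y[m] + DIRS[d][1];
    int nz = z[m] + DIRS[d][2];
    // bond constraints: backbone neighbours and cross-link partners
    if (m > 0 && !bond_ok(x[m - 1] - nx, y[m - 1] - ny, z[m - 1] - nz)) return;
    if (m < N - 1 && !bond_ok(x[m + 1] - nx, y[m + 1] - ny, z[m + 1] - nz)) return;
    for (int q : partners[m])
      if (!bond_ok(x[q] - nx, y[q] - ny, z[q] - nz)) return;
    // excluded volume: only the 4 leading-face sites are newly claimed
    // (the other 4 sites of the displaced cube belong to the old cube)
    const int axis = d >> 1;
    const int sign = (d & 1) ? -1 : 1;
    int fx[4], fy[4], fz[4];   // leading face (to check/insert)
    int gx[4], gy[4], gz[4];   // trailing face (to vacate)
    {
      int lead[3] = {nx, ny, nz};
      int trail[3] = {x[m], y[m], z[m]};
      if (sign > 0) lead[axis] += 1;   // far plane of the advanced cube
      else          trail[axis] += 1;  // far plane of the vacated cube
      int u = (axis + 1) % 3, v = (axis + 2) % 3;
      int idx = 0;
      for (int a = 0; a < 2; ++a)
        for (int b = 0; b < 2; ++b) {
          int s[3] = {lead[0], lead[1], lead[2]};
          s[u] += a; s[v] += b;
          fx[idx] = s[0]; fy[idx] = s[1]; fz[idx] = s[2];
          int t[3] = {trail[0], trail[1], trail[2]};
          t[u] += a; t[v] += b;
          gx[idx] = t[0]; gy[idx] = t[1]; gz[idx] = t[2];
          ++idx;
        }
    }
    for (int k = 0; k < 4; ++k) {
      int32_t v = occ.get(site_key(fx[k], fy[k], fz[k]));
      if (v >= 0 && v != m) return;
    }
    // constant stretching force on the end monomers: E = -F * |Ree|
    if (force > 0.0 && (m == 0 || m == N - 1)) {
      double r_old = ree();
      int ox = (m == 0) ? x[N - 1] : x[0];
      int oy = (m == 0) ? y[N - 1] : y[0];
      int oz = (m == 0) ? z[N - 1] : z[0];
      double dx = (double)nx - ox, dy = (double)ny - oy, dz = (double)nz - oz;
      double r_new = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dr = r_new - r_old;
      if (dr < 0.0 && unif(rng) >= std::exp(force * dr)) return;
    }
    // commit: vacate the trailing face, claim the leading face
    for (int k = 0; k < 4; ++k)
      occ.erase(site_key(gx[k], gy[k], gz[k]));
    for (int k = 0; k < 4; ++k)
      occ.insert(site_key(fx[k], fy[k], fz[k]), m);
    x[m] = nx; y[m] = ny; z[m] = nz;
  }

  void drop_partner(int i, int j) {
    std::vector<int> &v = partners[i];
    for (size_t k = 0; k < v.size(); ++k)
      if (v[k] == j) { v[k] = v.back(); v.pop_back(); return; }
  }

  void expire_links() {
    for (size_t k = 0; k < links.size();) {
      if (links[k].expiry <= sweep) {
        drop_partner(links[k].i, links[k].j);
        drop_partner(links[k].j, links[k].i);
        links[k] = links.back();
        links.pop_back();
      } else ++k;
    }
  }

  // Deterministic scan in ascending (i, j); a pair is a candidate when the
  // displacement is itself an allowed bond vector, the genomic separation is
  // in [2, cutoff], the pair is unlinked and both ends are below max_links.
  void form_links() {
    if (p_form <= 0.0) return;
    std::poisson_distribution<long> pois(lifetime);
    for (int i = 0; i < N; ++i) {
      if ((int)partners[i].size() >= max_links) continue;
      int jmax = std::min(N - 1, i + cutoff);
      for (int j = i + 2; j <= jmax; ++j) {
        if ((int)partners[i].size() >= max_links) break;
        if ((int)partners[j].size() >= max_links) continue;
        int dx = x[j] - x[i]; if (dx < -3 || dx > 3) continue;
        int dy = y[j] - y[i]; if (dy < -3 || dy > 3) continue;
        int dz = z[j] - z[i]; if (dz < -3 || dz > 3) continue;
        if (!bond_tab[dx + 3][dy + 3][dz + 3]) continue;
        if (has_partner(i, j)) continue;
        if (unif(rng) < p_form) {
          double ex = sweep + 1.0 + (double)pois(rng);
          links.push_back({i, j, ex});
          partners[i].push_back(j);
          partners[j].push_back(i);
        }
      }
    }
  }

  void one_sweep() {
    for (int k = 0; k < N; ++k) attempt_move();
    sweep += 1.0;
    if (!links.empty()) expire_links();
    form_links();
  }
};

// ---------------------------------------------------------------------------
// Conversion helpers (R <-> engine)
// ---------------------------------------------------------------------------

static void load_engine(Engine &e, const IntegerMatrix &positions,
                        const IntegerMatrix &links, double sweep,
                        const List &params, bool check) {
  build_bond_tab();
  e.N = positions.nrow();
  if (positions.ncol() != 3) stop("positions must be an N x 3 integer matrix");
  int box_in = as<int>(params["box"]);
  if (box_in < 8) stop("box edge must be at least 8");
  if (box_in > (1 << 20)) stop("box edge must be at most 2^20");
  e.set_box(box_in);
  e.cutoff = as<int>(params["cutoff"]);
  e.p_form = as<double>(params["p_form"]);
  e.lifetime = as<double>(params["lifetime"]);
  e.max_links = as<int>(params["max_links"]);
  e.force = as<double>(params["force"]);
  e.sweep = sweep;
  e.x.resize(e.N); e.y.resize(e.N); e.z.resize(e.N);
  for (int m = 0; m < e.N; ++m) {
    e.x[m] = positions(m, 0);
    e.y[m] = positions(m, 1);
    e.z[m] = positions(m, 2);
  }
  if (check) {
    for (int m = 0; m + 1 < e.N; ++m)
      if (!bond_ok(e.x[m + 1] - e.x[m], e.y[m + 1] - e.y[m], e.z[m + 1] - e.z[m]))
        stop("backbone bond %d is not an allowed bond vector", m + 1);
  }
  e.build_occupancy(check);
  e.partners.assign(e.N, std::vector<int>());
  e.links.clear();
  for (int k = 0; k < links.nrow(); ++k) {
    int i = links(k, 0) - 1, j = links(k, 1) - 1;
    double ex = (double)links(k, 2);
    if (i < 0 || j >= e.N || i >= j) stop("invalid cross-link (%d, %d)", i + 1, j + 1);
    if (check) {
      if (j - i < 2) stop("cross-link (%d, %d): genomic separation below 2", i + 1, j + 1);
      if (e.cutoff > 0 && j - i > e.cutoff)
        stop("cross-link (%d, %d): genomic separation exceeds cutoff", i + 1, j + 1);
      if (!bond_ok(e.x[j] - e.x[i], e.y[j] - e.y[i], e.z[j] - e.z[i]))
        stop("cross-link (%d, %d) is not an allowed bond vector", i + 1, j + 1);
    }
    e.links.push_back({i, j, ex});
    e.partners[i].push_back(j);
    e.partners[j].push_back(i);
  }
}

static IntegerMatrix dump_positions(const Engine &e) {
  IntegerMatrix out(e.N, 3);
  for (int m = 0; m < e.N; ++m) {
    out(m, 0) = e.x[m]; out(m, 1) = e.y[m]; out(m, 2) = e.z[m];
  }
  return out;
}

static IntegerMatrix dump_links(const Engine &e) {
  std::vector<Link> ls = e.links;
  std::sort(ls.begin(), ls.end(), [](const Link &a, const Link &b) {
    return a.i != b.i ? a.i < b.i : a.j < b.j;
  });
  IntegerMatrix out(ls.size(), 3);
  colnames(out) = CharacterVector::create("i", "j", "expiry");
  for (size_t k = 0; k < ls.size(); ++k) {
    out(k, 0) = ls[k].i + 1;
    out(k, 1) = ls[k].j + 1;
    out(k, 2) = (int)ls[k].expiry;
  }
  return out;
}

// Compact key encoding all backbone bond vectors (small chains only); used
// to compare Monte Carlo visit frequencies against exhaustive enumeration.
static double bond_key(const Engine &e) {
  double key = 0.0, scale = 1.0;
  for (int m = 0; m + 1 < e.N; ++m) {
    int code = (e.x[m + 1] - e.x[m] + 3) * 49 +
               (e.y[m + 1] - e.y[m] + 3) * 7 +
               (e.z[m + 1] - e.z[m] + 3);
    key += scale * code;
    scale *= 343.0;
  }
  return key;
}

// ---------------------------------------------------------------------------
// Exported engine entry points
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_advance(IntegerMatrix positions, IntegerMatrix links, double sweep,
                 List params, double nsweeps, int sample_stride,
                 bool record_frames, bool record_keys, int seed) {
  Engine e;
  load_engine(e, positions, links, sweep, params, true);
  if (e.N >= 8 && record_keys) stop("state keys are only recorded for chains of < 8 monomers");
  e.rng.seed((uint64_t)seed);

  long long ns = (long long)nsweeps;
  NumericVector ree2(ns);
  IntegerVector nlink(ns);
  NumericVector keys(record_keys ? ns : 0);
  List frames;
  std::vector<List> frame_acc;

  for (long long s = 0; s < ns; ++s) {
    e.one_sweep();
    ree2[s] = e.ree2();
    nlink[s] = (int)e.links.size();
    if (record_keys) keys[s] = bond_key(e);
    if (record_frames && sample_stride > 0 && ((s + 1) % sample_stride == 0)) {
      frame_acc.push_back(List::create(
        _["positions"] = dump_positions(e),
        _["links"] = dump_links(e),
        _["sweep"] = e.sweep));
    }
    if ((s & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }
  frames = wrap(frame_acc);

  return List::create(
    _["positions"] = dump_positions(e),
    _["links"] = dump_links(e),
    _["sweep"] = e.sweep,
    _["frames"] = frames,
    _["ree2"] = ree2,
    _["n_links"] = nlink,
    _["state_keys"] = keys);
}

// [[Rcpp::export]]
bool cpp_check_excluded_volume(IntegerMatrix positions, int box, int index,
                               IntegerVector proposed) {
  if (index < 1 || index > positions.nrow()) stop("monomer index out of range");
  if (proposed.size() != 3) stop("proposed position must have 3 components");
  build_bond_tab();
  Engine e;
  e.N = positions.nrow();
  e.set_box(box);
  e.x.resize(e.N); e.y.resize(e.N); e.z.resize(e.N);
  for (int m = 0; m < e.N; ++m) {
    e.x[m] = positions(m, 0); e.y[m] = positions(m, 1); e.z[m] = positions(m, 2);
  }
  e.build_occupancy(false);
  int m0 = index - 1;
  for (int a = 0; a < 2; ++a)
    for (int b = 0; b < 2; ++b)
      for (int c = 0; c < 2; ++c) {
        int32_t v = e.occ.get(e.site_key(proposed[0] + a, proposed[1] + b, proposed[2] + c));
        if (v >= 0 && v != m0) return false;
      }
  return true;
}

// [[Rcpp::export]]
IntegerMatrix cpp_find_candidates(IntegerMatrix positions, IntegerMatrix links,
                                  List params) {
  Engine e;
  load_engine(e, positions, links, 0.0, params, false);
  std::vector<std::pair<int, int>> out;
  for (int i = 0; i < e.N; ++i) {
    if ((int)e.partners[i].size() >= e.max_links) continue;
    int jmax = std::min(e.N - 1, i + e.cutoff);
    for (int j = i + 2; j <= jmax; ++j) {
      if ((int)e.partners[j].size() >= e.max_links) continue;
      if (!bond_ok(e.x[j] - e.x[i], e.y[j] - e.y[i], e.z[j] - e.z[i])) continue;
      if (e.has_partner(i, j)) continue;
      out.push_back({i + 1, j + 1});
    }
  }
  IntegerMatrix m(out.size(), 2);
  colnames(m) = CharacterVector::create("i", "j");
  for (size_t k = 0; k < out.size(); ++k) {
    m(k, 0) = out[k].first;
    m(k, 1) = out[k].second;
  }
  return m;
}

// [[Rcpp::export]]
IntegerMatrix cpp_attempt_links(IntegerMatrix positions, IntegerMatrix links,
                                double sweep, List params, int seed) {
  Engine e;
  load_engine(e, positions, links, sweep, params, true);
  e.rng.seed((uint64_t)seed);
  e.form_links();
  return dump_links(e);
}

// Runs the full invariant check; returns a character vector of problems
// (empty when the conformation is valid).
// [[Rcpp::export]]
CharacterVector cpp_validate(IntegerMatrix positions, IntegerMatrix links,
                             int box, int cutoff) {
  build_bond_tab();
  std::vector<std::string> msg;
  int N = positions.nrow();
  if (positions.ncol() != 3) return wrap(std::vector<std::string>{"positions must be N x 3"});
  std::vector<int> x(N), y(N), z(N);
  for (int m = 0; m < N; ++m) {
    x[m] = positions(m, 0); y[m] = positions(m, 1); z[m] = positions(m, 2);
  }
  for (int m = 0; m + 1 < N; ++m)
    if (!bond_ok(x[m + 1] - x[m], y[m + 1] - y[m], z[m + 1] - z[m]))
      msg.push_back("backbone bond " + std::to_string(m + 1) + " not in bond set");
  {
    Engine e;
    e.N = N; e.set_box(box);
    e.x = x; e.y = y; e.z = z;
    e.occ.init((size_t)N * 32);
    for (int m = 0; m < N; ++m)
      for (int a = 0; a < 2; ++a)
        for (int b = 0; b < 2; ++b)
          for (int c = 0; c < 2; ++c) {
            uint64_t k = e.site_key(x[m] + a, y[m] + b, z[m] + c);
            int32_t v = e.occ.get(k);
            if (v >= 0 && v != m)
              msg.push_back("excluded volume overlap between monomers " +
                            std::to_string(v + 1) + " and " + std::to_string(m + 1));
            e.occ.insert(k, m);
          }
  }
  for (int k = 0; k < links.nrow(); ++k) {
    int i = links(k, 0), j = links(k, 1);
    std::string tag = "cross-link (" + std::to_string(i) + ", " + std::to_string(j) + ")";
    if (i < 1 || j > N || i >= j) { msg.push_back(tag + ": invalid indices"); continue; }
    if (j - i < 2) msg.push_back(tag + ": genomic separation below 2");
    if (cutoff > 0 && j - i > cutoff) msg.push_back(tag + ": separation exceeds cutoff");
    if (!bond_ok(x[j - 1] - x[i - 1], y[j - 1] - y[i - 1], z[j - 1] - z[i - 1]))
      msg.push_back(tag + ": displacement not in bond set");
  }
  return wrap(msg);
}
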