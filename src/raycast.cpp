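// Ray-casting core: triangle scenes, watertight intersection, binned-SAH BVH,
// counter-based RNG streams and the Gaussian-cone ommatidial sampler.
#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>
using namespace Rcpp;

static const double T_MIN = 1e-6;   // self-intersection guard (mm)
static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------- vectors
struct V3 { double x, y, z; };
static inline V3 v3(double x, double y, double z) { return V3{x, y, z}; }
static inline V3 operator-(V3 a, V3 b) { return v3(a.x-b.x, a.y-b.y, a.z-b.z); }
static inline V3 operator+(V3 a, V3 b) { return v3(a.x+b.x, a.y+b.y, a.z+b.z); }
static inline V3 operator*(double s, V3 a) { return v3(s*a.x, s*a.y, s*a.z); }
static inline double dot(V3 a, V3 b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline V3 cross(V3 a, V3 b) {
  return v3(a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x);
}
static inline double len(V3 a) { return std::sqrt(dot(a, a)); }

// ---------------------------------------------------------------- scene
struct Tri {
  V3 v0, v1, v2;
  int mesh, tri;          // 0-based ids within the scene / mesh
  int mat;
  bool has_uv;
  double uv[6];           // u0,v0,u1,v1,u2,v2
};

struct Mat {
  double col[3];
  int texh = 0, texw = 0;
  std::vector<double> tex;   // R array layout: [row + H*col + H*W*channel]
  bool has_tex() const { return texh > 0; }
};

struct Node {
  double lo[3], hi[3];
  int left = -1, right = -1;  // internal children
  int start = 0, count = 0;   // leaf: range into order[]
};

struct SceneData {
  std::vector<Tri> tris;
  std::vector<Mat> mats;
  double bg[3];
  std::vector<Node> nodes;
  std::vector<int> order;                    // BVH leaf triangle ids
  std::vector<std::vector<int>> mesh_gid;    // (mesh, tri) -> global id, -1 if dropped
};

// ---------------------------------------------------------------- BVH build
static void tri_bounds(const Tri& t, double lo[3], double hi[3]) {
  const double xs[3] = {t.v0.x, t.v1.x, t.v2.x};
  const double ys[3] = {t.v0.y, t.v1.y, t.v2.y};
  const double zs[3] = {t.v0.z, t.v1.z, t.v2.z};
  lo[0] = std::min({xs[0], xs[1], xs[2]}); hi[0] = std::max({xs[0], xs[1], xs[2]});
  lo[1] = std::min({ys[0], ys[1], ys[2]}); hi[1] = std::max({ys[0], ys[1], ys[2]});
  lo[2] = std::min({zs[0], zs[1], zs[2]}); hi[2] = std::max({zs[0], zs[1], zs[2]});
}

static int build_node(SceneData& S, std::vector<int>& idx, int start, int count,
                      const std::vector<std::array<double, 3>>& cent) {
  Node nd;
  for (int a = 0; a < 3; ++a) { nd.lo[a] = INF; nd.hi[a] = -INF; }
  for (int i = start; i < start + count; ++i) {
    double lo[3], hi[3];
    tri_bounds(S.tris[idx[i]], lo, hi);
    for (int a = 0; a < 3; ++a) {
      nd.lo[a] = std::min(nd.lo[a], lo[a]);
      nd.hi[a] = std::max(nd.hi[a], hi[a]);
    }
  }
  int self = (int)S.nodes.size();
  S.nodes.push_back(nd);
  if (count <= 4) {
    S.nodes[self].start = start;
    S.nodes[self].count = count;
    return self;
  }
  // binned SAH on the widest centroid axis; fall back to median split
  double clo[3] = {INF, INF, INF}, chi[3] = {-INF, -INF, -INF};
  for (int i = start; i < start + count; ++i)
    for (int a = 0; a < 3; ++a) {
      clo[a] = std::min(clo[a], cent[idx[i]][a]);
      chi[a] = std::max(chi[a], cent[idx[i]][a]);
    }
  int axis = 0;
  double ext = -1;
  for (int a = 0; a < 3; ++a)
    if (chi[a] - clo[a] > ext) { ext = chi[a] - clo[a]; axis = a; }
  int mid;
  if (ext <= 0) {
    mid = start + count / 2;  // all centroids coincide
  } else {
    const int NB = 16;
    double binw = ext / NB;
    int    cnt[NB];
    double blo[NB][3], bhi[NB][3];
    for (int b = 0; b < NB; ++b) {
      cnt[b] = 0;
      for (int a = 0; a < 3; ++a) { blo[b][a] = INF; bhi[b][a] = -INF; }
    }
    auto bin_of = [&](int id) {
      int b = (int)((cent[id][axis] - clo[axis]) / binw);
      return std::min(std::max(b, 0), NB - 1);
    };
    for (int i = start; i < start + count; ++i) {
      int id = idx[i], b = bin_of(id);
      cnt[b]++;
      double lo[3], hi[3];
      tri_bounds(S.tris[id], lo, hi);
      for (int a = 0; a < 3; ++a) {
        blo[b][a] = std::min(blo[b][a], lo[a]);
        bhi[b][a] = std::max(bhi[b][a], hi[a]);
      }
    }
    auto area = [](const double lo[3], const double hi[3]) {
      double dx = std::max(0.0, hi[0]-lo[0]), dy = std::max(0.0, hi[1]-lo[1]),
             dz = std::max(0.0, hi[2]-lo[2]);
      return 2.0 * (dx*dy + dy*dz + dz*dx);
    };
    double best = INF;
    int bestb = -1;
    for (int b = 0; b < NB - 1; ++b) {  // split after bin b
      double llo[3] = {INF,INF,INF}, lhi[3] = {-INF,-INF,-INF};
      double rlo[3] = {INF,INF,INF}, rhi[3] = {-INF,-INF,-INF};
      int nl = 0, nr = 0;
      for (int k = 0; k <= b; ++k) {
        nl += cnt[k];
        for (int a = 0; a < 3; ++a) {
          llo[a] = std::min(llo[a], blo[k][a]); lhi[a] = std::max(lhi[a], bhi[k][a]);
        }
      }
      for (int k = b + 1; k < NB; ++k) {
        nr += cnt[k];
        for (int a = 0; a < 3; ++a) {
          rlo[a] = std::min(rlo[a], blo[k][a]); rhi[a] = std::max(rhi[a], bhi[k][a]);
        }
      }
      if (nl == 0 || nr == 0) continue;
      double c = area(llo, lhi) * nl + area(rlo, rhi) * nr;
      if (c < best) { best = c; bestb = b; }
    }
    if (bestb < 0) {
      mid = start + count / 2;
      std::nth_element(idx.begin() + start, idx.begin() + mid,
                       idx.begin() + start + count,
                       [&](int a, int b) {
                         if (cent[a][axis] != cent[b][axis])
                           return cent[a][axis] < cent[b][axis];
                         return a < b;
                       });
    } else {
      auto it = std::partition(idx.begin() + start, idx.begin() + start + count,
                               [&](int id) { return bin_of(id) <= bestb; });
      mid = (int)(it - idx.begin());
      if (mid == start || mid == start + count) mid = start + count / 2;
    }
  }
  int l = build_node(S, idx, start, mid - start, cent);
  int r = build_node(S, idx, mid, start + count - mid, cent);
  S.nodes[self].left = l;
  S.nodes[self].right = r;
  S.nodes[self].count = 0;
  return self;
}

static void build_bvh(SceneData& S) {
  int n = (int)S.tris.size();
  S.order.resize(n);
  for (int i = 0; i < n; ++i) S.order[i] = i;
  if (n == 0) return;
  std::vector<std::array<double, 3>> cent(n);
  for (int i = 0; i < n; ++i) {
    const Tri& t = S.tris[i];
    cent[i] = {(t.v0.x + t.v1.x + t.v2.x) / 3.0,
               (t.v0.y + t.v1.y + t.v2.y) / 3.0,
               (t.v0.z + t.v1.z + t.v2.z) / 3.0};
  }
  build_node(S, S.order, 0, n, cent);
}

// ---------------------------------------------------------------- intersect
struct RayPre {   // watertight test precomputation (Woop-style)
  V3 o, d;
  int kx, ky, kz;
  double Sx, Sy, Sz;
};

static RayPre pre_ray(V3 o, V3 d) {
  RayPre r;
  r.o = o; r.d = d;
  double ax = std::fabs(d.x), ay = std::fabs(d.y), az = std::fabs(d.z);
  int kz = 0;
  if (ay > ax && ay >= az) kz = 1; else if (az > ax && az > ay) kz = 2;
  int kx = (kz + 1) % 3, ky = (kz + 2) % 3;
  const double dv[3] = {d.x, d.y, d.z};
  if (dv[kz] < 0.0) std::swap(kx, ky);
  r.kx = kx; r.ky = ky; r.kz = kz;
  r.Sx = dv[kx] / dv[kz];
  r.Sy = dv[ky] / dv[kz];
  r.Sz = 1.0 / dv[kz];
  return r;
}

struct HitRec { bool hit = false; double t = INF; int gid = -1; double b1 = 0, b2 = 0; };

static inline void isect_tri(const RayPre& r, const Tri& tr, int gid, HitRec& best) {
  const V3 A = tr.v0 - r.o, B = tr.v1 - r.o, C = tr.v2 - r.o;
  const double Av[3] = {A.x, A.y, A.z}, Bv[3] = {B.x, B.y, B.z}, Cv[3] = {C.x, C.y, C.z};
  const double Ax = Av[r.kx] - r.Sx * Av[r.kz], Ay = Av[r.ky] - r.Sy * Av[r.kz];
  const double Bx = Bv[r.kx] - r.Sx * Bv[r.kz], By = Bv[r.ky] - r.Sy * Bv[r.kz];
  const double Cx = Cv[r.kx] - r.Sx * Cv[r.kz], Cy = Cv[r.ky] - r.Sy * Cv[r.kz];
  double U = Cx * By - Cy * Bx;
  double V = Ax * Cy - Ay * Cx;
  double W = Bx * Ay - By * Ax;
  if ((U < 0 || V < 0 || W < 0) && (U > 0 || V > 0 || W > 0)) return;
  double det = U + V + W;
  if (det == 0.0) return;
  const double Az = r.Sz * Av[r.kz], Bz = r.Sz * Bv[r.kz], Cz = r.Sz * Cv[r.kz];
  double t = (U * Az + V * Bz + W * Cz) / det;
  if (!(t > T_MIN)) return;
  if (t < best.t || (t == best.t && gid < best.gid)) {
    best.hit = true; best.t = t; best.gid = gid;
    best.b1 = V / det; best.b2 = W / det;
  }
}

static inline bool box_hit(const Node& nd, const RayPre& r, double tmax, double& tnear) {
  double t0 = T_MIN, t1 = tmax;
  const double ov[3] = {r.o.x, r.o.y, r.o.z}, dv[3] = {r.d.x, r.d.y, r.d.z};
  for (int a = 0; a < 3; ++a) {
    double inv = 1.0 / dv[a];
    double tn = (nd.lo[a] - ov[a]) * inv;
    double tf = (nd.hi[a] - ov[a]) * inv;
    t0 = std::fmax(t0, std::fmin(tn, tf));
    t1 = std::fmin(t1, std::fmax(tn, tf));
  }
  tnear = t0;
  return t0 <= t1;
}

static HitRec intersect_scene(const SceneData& S, V3 o, V3 d, bool brute) {
  HitRec best;
  RayPre r = pre_ray(o, d);
  if (brute || S.nodes.empty()) {
    for (int i = 0; i < (int)S.tris.size(); ++i) isect_tri(r, S.tris[i], i, best);
    return best;
  }
  int stack[128];
  int sp = 0;
  stack[sp++] = 0;
  while (sp > 0) {
    const Node& nd = S.nodes[stack[--sp]];
    double tn;
    if (!box_hit(nd, r, best.hit ? best.t : INF, tn)) continue;
    if (nd.count > 0) {
      for (int i = nd.start; i < nd.start + nd.count; ++i) {
        int gid = S.order[i];
        isect_tri(r, S.tris[gid], gid, best);
      }
    } else {
      double tl, tr_;
      bool hl = box_hit(S.nodes[nd.left], r, best.hit ? best.t : INF, tl);
      bool hr = box_hit(S.nodes[nd.right], r, best.hit ? best.t : INF, tr_);
      if (hl && hr) {  // near child popped first
        if (tl <= tr_) { stack[sp++] = nd.right; stack[sp++] = nd.left; }
        else           { stack[sp++] = nd.left;  stack[sp++] = nd.right; }
      } else if (hl) stack[sp++] = nd.left;
      else if (hr) stack[sp++] = nd.right;
    }
  }
  return best;
}

// ---------------------------------------------------------------- shading
static void shade_hit(const SceneData& S, const HitRec& h, double out[3]) {
  if (!h.hit) { out[0] = S.bg[0]; out[1] = S.bg[1]; out[2] = S.bg[2]; return; }
  const Tri& tr = S.tris[h.gid];
  const Mat& m = S.mats[tr.mat];
  if (m.has_tex() && tr.has_uv) {
    double b0 = 1.0 - h.b1 - h.b2;
    double u = b0 * tr.uv[0] + h.b1 * tr.uv[2] + h.b2 * tr.uv[4];
    double v = b0 * tr.uv[1] + h.b1 * tr.uv[3] + h.b2 * tr.uv[5];
    int W = m.texw, H = m.texh;
    double x = u * W - 0.5, y = v * H - 0.5;
    int j0 = (int)std::floor(x), i0 = (int)std::floor(y);
    double fx = x - j0, fy = y - i0;
    int j1 = std::min(std::max(j0 + 1, 0), W - 1);
    int i1 = std::min(std::max(i0 + 1, 0), H - 1);
    j0 = std::min(std::max(j0, 0), W - 1);
    i0 = std::min(std::max(i0, 0), H - 1);
    for (int c = 0; c < 3; ++c) {
      const double* T = m.tex.data() + (size_t)H * W * c;
      double c00 = T[i0 + (size_t)H * j0], c01 = T[i0 + (size_t)H * j1];
      double c10 = T[i1 + (size_t)H * j0], c11 = T[i1 + (size_t)H * j1];
      out[c] = (1 - fy) * ((1 - fx) * c00 + fx * c01) + fy * ((1 - fx) * c10 + fx * c11);
    }
  } else {
    out[0] = m.col[0]; out[1] = m.col[1]; out[2] = m.col[2];
  }
}

// ---------------------------------------------------------------- RNG
// splitmix64 chain keyed by (seed, frame, ommatidium, sample, draw): a
// stateless counter-based stream, so per-ommatidium sequences are independent
// of evaluation order.
static inline uint64_t sm64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Stream identity of an ommatidium: a hash of its own parameters (position,
// axis, acceptance angle, focal offset), so its random stream travels with it
// when the eye's ommatidial order changes.
static uint64_t omm_key(const double* vals, int n) {
  uint64_t h = 0x8f1bbcdcbfa53e0bULL;
  for (int i = 0; i < n; ++i) {
    uint64_t b;
    std::memcpy(&b, &vals[i], 8);
    h = sm64(h ^ b);
  }
  return h;
}

static inline double u01(uint64_t seed, uint64_t frame, uint64_t omm,
                         uint64_t sample, uint64_t draw) {
  uint64_t h = sm64(seed);
  h = sm64(h ^ frame);
  h = sm64(h ^ omm);
  h = sm64(h ^ sample);
  h = sm64(h ^ draw);
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);  // (0,1)
}

// Gaussian-cone direction sampler. measure 0: angular deviation theta drawn as
// |N(0, sigma)| (sigma = FWHM-derived), truncated at pi by resampling, unit
// weight. measure 1: theta uniform in solid angle within the full acceptance
// cone, Gaussian weight exp(-theta^2 / (2 sigma^2)).
static void sample_dir(const double ax[3], double acc, uint64_t seed,
                       uint64_t frame, uint64_t omm, uint64_t sample,
                       int measure, double out[3], double* weight) {
  *weight = 1.0;
  if (acc <= 0.0) { out[0] = ax[0]; out[1] = ax[1]; out[2] = ax[2]; return; }
  double sigma = acc / (2.0 * std::sqrt(2.0 * std::log(2.0)));
  double theta, phi;
  if (measure == 0) {
    uint64_t attempt = 0;
    do {
      double u1 = u01(seed, frame, omm, sample, 2 * attempt);
      theta = std::fabs(R::qnorm(u1, 0.0, 1.0, 1, 0)) * sigma;
      ++attempt;
    } while (theta > M_PI && attempt < 64);
    if (theta > M_PI) theta = M_PI;
    phi = 2.0 * M_PI * u01(seed, frame, omm, sample, 2 * attempt - 1);
  } else {
    double half = std::min(acc, M_PI);
    double u1 = u01(seed, frame, omm, sample, 0);
    double ct = 1.0 - u1 * (1.0 - std::cos(half));
    theta = std::acos(std::min(1.0, std::max(-1.0, ct)));
    phi = 2.0 * M_PI * u01(seed, frame, omm, sample, 1);
    *weight = std::exp(-0.5 * (theta / sigma) * (theta / sigma));
  }
  if (theta == 0.0) { out[0] = ax[0]; out[1] = ax[1]; out[2] = ax[2]; return; }
  // orthonormal basis about the axis (Duff et al. construction)
  double s = std::copysign(1.0, ax[2]);
  double c = -1.0 / (s + ax[2]);
  double b = ax[0] * ax[1] * c;
  double e1[3] = {1.0 + s * ax[0] * ax[0] * c, s * b, -s * ax[0]};
  double e2[3] = {b, s + ax[1] * ax[1] * c, -ax[1]};
  double st = std::sin(theta), ct2 = std::cos(theta);
  double cp = std::cos(phi), sp = std::sin(phi);
  double n2 = 0.0;
  for (int k = 0; k < 3; ++k) {
    out[k] = ct2 * ax[k] + st * (cp * e1[k] + sp * e2[k]);
    n2 += out[k] * out[k];
  }
  double inv = 1.0 / std::sqrt(n2);
  for (int k = 0; k < 3; ++k) out[k] *= inv;
}

// ---------------------------------------------------------------- R bindings

// [[Rcpp::export]]
SEXP cpp_build_accel(List scene) {
  SceneData* S = new SceneData();
  NumericVector bg = scene["background"];
  S->bg[0] = bg[0]; S->bg[1] = bg[1]; S->bg[2] = bg[2];
  List meshes = scene["meshes"];
  List materials = scene["materials"];
  int nm = meshes.size();
  S->mats.resize(nm);
  for (int k = 0; k < nm; ++k) {
    List mt = materials[k];
    NumericVector col = mt["base_colour"];
    S->mats[k].col[0] = col[0]; S->mats[k].col[1] = col[1]; S->mats[k].col[2] = col[2];
    if (mt.containsElementNamed("texture") && !Rf_isNull(mt["texture"])) {
      NumericVector tx = mt["texture"];
      IntegerVector dm = tx.attr("dim");
      S->mats[k].texh = dm[0];
      S->mats[k].texw = dm[1];
      S->mats[k].tex.assign(tx.begin(), tx.end());
    }
  }
  S->mesh_gid.resize(nm);
  for (int k = 0; k < nm; ++k) {
    List m = meshes[k];
    NumericMatrix Vm = m["vertices"];
    IntegerMatrix Fm = m["triangles"];
    bool has_uv = m.containsElementNamed("uv") && !Rf_isNull(m["uv"]);
    NumericMatrix UV;
    if (has_uv) UV = as<NumericMatrix>(m["uv"]);
    S->mesh_gid[k].assign(Fm.nrow(), -1);
    for (int f = 0; f < Fm.nrow(); ++f) {
      int i0 = Fm(f, 0) - 1, i1 = Fm(f, 1) - 1, i2 = Fm(f, 2) - 1;
      Tri t;
      t.v0 = v3(Vm(i0, 0), Vm(i0, 1), Vm(i0, 2));
      t.v1 = v3(Vm(i1, 0), Vm(i1, 1), Vm(i1, 2));
      t.v2 = v3(Vm(i2, 0), Vm(i2, 1), Vm(i2, 2));
      V3 e1 = t.v1 - t.v0, e2 = t.v2 - t.v0;
      double a = len(cross(e1, e2));
      if (a <= 1e-14 * len(e1) * len(e2)) continue;  // degenerate: excluded
      t.mesh = k; t.tri = f; t.mat = k;
      t.has_uv = has_uv;
      if (has_uv) {
        t.uv[0] = UV(i0, 0); t.uv[1] = UV(i0, 1);
        t.uv[2] = UV(i1, 0); t.uv[3] = UV(i1, 1);
        t.uv[4] = UV(i2, 0); t.uv[5] = UV(i2, 1);
      }
      S->mesh_gid[k][f] = (int)S->tris.size();
      S->tris.push_back(t);
    }
  }
  build_bvh(*S);
  XPtr<SceneData> p(S, true);
  return p;
}

// [[Rcpp::export]]
int cpp_n_triangles(SEXP accel) {
  XPtr<SceneData> S(accel);
  return (int)S->tris.size();
}

// [[Rcpp::export]]
List cpp_intersect(SEXP accel, NumericMatrix origins, NumericMatrix dirs, bool brute) {
  XPtr<SceneData> S(accel);
  int n = origins.nrow();
  LogicalVector hit(n);
  NumericVector t(n, NA_REAL), b1(n, NA_REAL), b2(n, NA_REAL);
  IntegerVector mesh(n, NA_INTEGER), tri(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    HitRec h = intersect_scene(*S, v3(origins(i,0), origins(i,1), origins(i,2)),
                               v3(dirs(i,0), dirs(i,1), dirs(i,2)), brute);
    hit[i] = h.hit;
    if (h.hit) {
      t[i] = h.t;
      mesh[i] = S->tris[h.gid].mesh + 1;
      tri[i] = S->tris[h.gid].tri + 1;
      b1[i] = h.b1; b2[i] = h.b2;
    }
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["hit"] = hit, _["t"] = t, _["mesh"] = mesh,
                      _["tri"] = tri, _["b1"] = b1, _["b2"] = b2);
}

// [[Rcpp::export]]
NumericMatrix cpp_shade(SEXP accel, LogicalVector hit, IntegerVector mesh,
                        IntegerVector tri, NumericVector b1, NumericVector b2) {
  XPtr<SceneData> S(accel);
  int n = hit.size();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    HitRec h;
    if (hit[i]) {
      int gid = S->mesh_gid[mesh[i] - 1][tri[i] - 1];
      if (gid < 0) stop("hit refers to a degenerate (excluded) triangle");
      h.hit = true; h.gid = gid; h.b1 = b1[i]; h.b2 = b2[i]; h.t = 1.0;
    }
    double c[3];
    shade_hit(*S, h, c);
    out(i, 0) = c[0]; out(i, 1) = c[1]; out(i, 2) = c[2];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_render_rays(SEXP accel, NumericMatrix origins, NumericMatrix dirs) {
  XPtr<SceneData> S(accel);
  int n = origins.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    HitRec h = intersect_scene(*S, v3(origins(i,0), origins(i,1), origins(i,2)),
                               v3(dirs(i,0), dirs(i,1), dirs(i,2)), false);
    double c[3];
    shade_hit(*S, h, c);
    out(i, 0) = c[0]; out(i, 1) = c[1]; out(i, 2) = c[2];
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
List cpp_sample_directions(NumericVector axis, double acceptance, int n,
                           double seed, double frame, double omm, int measure) {
  NumericMatrix dirs(n, 3);
  NumericVector w(n);
  double ax[3] = {axis[0], axis[1], axis[2]};
  for (int s = 0; s < n; ++s) {
    double d[3], wt;
    sample_dir(ax, acceptance, (uint64_t)seed, (uint64_t)frame, (uint64_t)omm,
               (uint64_t)s, measure, d, &wt);
    dirs(s, 0) = d[0]; dirs(s, 1) = d[1]; dirs(s, 2) = d[2];
    w[s] = wt;
  }
  return List::create(_["dirs"] = dirs, _["weights"] = w);
}

// Render an eye over one or more frames. Returns an (n_omm x 3 x frames)
// array. Frame f uses RNG frame index frame0 + f, so batching frames in one
// call or across calls yields identical streams.
// [[Rcpp::export]]
NumericVector cpp_render_eye(SEXP accel, NumericMatrix pos, NumericMatrix axes,
                             NumericVector acc, NumericVector focal,
                             NumericMatrix rot, NumericVector trans,
                             int samples, int frames, double seed,
                             double frame0, int measure) {
  XPtr<SceneData> S(accel);
  int n = pos.nrow();
  NumericVector out(Dimension(n, 3, frames));
  for (int f = 0; f < frames; ++f) {
    for (int i = 0; i < n; ++i) {
      // world-frame axis and ray origin (position + focal_offset * axis)
      double axl[3] = {axes(i,0), axes(i,1), axes(i,2)};
      double axw[3], ow[3];
      for (int r = 0; r < 3; ++r) {
        axw[r] = rot(r,0)*axl[0] + rot(r,1)*axl[1] + rot(r,2)*axl[2];
        double pl[3] = {pos(i,0) + focal[i]*axl[0],
                        pos(i,1) + focal[i]*axl[1],
                        pos(i,2) + focal[i]*axl[2]};
        ow[r] = rot(r,0)*pl[0] + rot(r,1)*pl[1] + rot(r,2)*pl[2] + trans[r];
      }
      const double kv[8] = {pos(i,0), pos(i,1), pos(i,2),
                            axl[0], axl[1], axl[2], acc[i], focal[i]};
      const uint64_t okey = omm_key(kv, 8);
      double sum[3] = {0, 0, 0}, wsum = 0.0, first[3] = {0, 0, 0};
      bool allsame = true;
      for (int s = 0; s < samples; ++s) {
        double d[3], wt, col[3];
        sample_dir(axw, acc[i], (uint64_t)seed, (uint64_t)(frame0 + f),
                   okey, (uint64_t)s, measure, d, &wt);
        HitRec h = intersect_scene(*S, v3(ow[0], ow[1], ow[2]),
                                   v3(d[0], d[1], d[2]), false);
        shade_hit(*S, h, col);
        if (s == 0) { first[0]=col[0]; first[1]=col[1]; first[2]=col[2]; }
        else if (col[0] != first[0] || col[1] != first[1] || col[2] != first[2])
          allsame = false;
        for (int c = 0; c < 3; ++c) sum[c] += wt * col[c];
        wsum += wt;
      }
      for (int c = 0; c < 3; ++c)
        out[i + (size_t)n * c + (size_t)3 * n * f] =
          allsame ? first[c] : sum[c] / wsum;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// BVH introspection for structural tests: node boxes, children, leaf ranges,
// triangle order and per-triangle bounds.
// [[Rcpp::export]]
List cpp_bvh_info(SEXP accel) {
  XPtr<SceneData> S(accel);
  int nn = (int)S->nodes.size(), nt = (int)S->tris.size();
  NumericMatrix lo(nn, 3), hi(nn, 3), tlo(nt, 3), thi(nt, 3);
  IntegerVector left(nn), right(nn), start(nn), count(nn);
  for (int i = 0; i < nn; ++i) {
    const Node& nd = S->nodes[i];
    for (int a = 0; a < 3; ++a) { lo(i, a) = nd.lo[a]; hi(i, a) = nd.hi[a]; }
    left[i] = nd.left + 1; right[i] = nd.right + 1;  // 1-based, 0 = none
    start[i] = nd.start + 1; count[i] = nd.count;
  }
  for (int i = 0; i < nt; ++i) {
    double l[3], h[3];
    tri_bounds(S->tris[i], l, h);
    for (int a = 0; a < 3; ++a) { tlo(i, a) = l[a]; thi(i, a) = h[a]; }
  }
  IntegerVector ord(S->order.begin(), S->order.end());
  return List::create(_["lo"] = lo, _["hi"] = hi, _["left"] = left,
                      _["right"] = right, _["start"] = start,
                      _["count"] = count, _["order"] = ord + 1,
                      _["tri_lo"] = tlo, _["tri_hi"] = thi);
}
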