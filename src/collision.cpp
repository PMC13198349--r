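// Geometric core: BVH-accelerated cylinder vs. closed-triangle-mesh solid
// overlap, ray-parity point-in-mesh, and exact segment/triangle distances.
//
// Conventions: coordinates in mm; face indices arrive 1-based from R and are
// stored 0-based here; all distance comparisons use GEOM_TOL (mm).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>

using namespace Rcpp;

static const double GEOM_TOL = 1e-6;

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
};
static inline V3 operator+(const V3 &a, const V3 &b) { return V3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 operator-(const V3 &a, const V3 &b) { return V3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 operator*(const V3 &a, double s) { return V3(a.x * s, a.y * s, a.z * s); }
static inline double dot(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(const V3 &a, const V3 &b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm(const V3 &a) { return std::sqrt(dot(a, a)); }
static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// ---------------------------------------------------------------------------
// Closest-point / distance primitives (Ericson, Real-Time Collision Detection)
// ---------------------------------------------------------------------------

static V3 closest_point_on_triangle(const V3 &p, const V3 &a, const V3 &b, const V3 &c) {
  V3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  V3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return a + ab * v;
  }
  V3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return a + ac * w;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + (c - b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + ab * v + ac * w;
}

// closest points between segments p1p2 and q1q2
static double seg_seg_dist(const V3 &p1, const V3 &p2, const V3 &q1, const V3 &q2) {
  V3 d1 = p2 - p1, d2 = q2 - q1, r = p1 - q1;
  double a = dot(d1, d1), e = dot(d2, d2), f = dot(d2, r);
  double s, t;
  if (a <= 1e-30 && e <= 1e-30) return norm(p1 - q1);
  if (a <= 1e-30) {
    s = 0.0;
    t = clampd(f / e, 0.0, 1.0);
  } else {
    double c = dot(d1, r);
    if (e <= 1e-30) {
      t = 0.0;
      s = clampd(-c / a, 0.0, 1.0);
    } else {
      double b = dot(d1, d2);
      double denom = a * e - b * b;
      if (denom > 1e-30) s = clampd((b * f - c * e) / denom, 0.0, 1.0);
      else s = 0.0;
      t = (b * s + f) / e;
      if (t < 0.0) { t = 0.0; s = clampd(-c / a, 0.0, 1.0); }
      else if (t > 1.0) { t = 1.0; s = clampd((b - c) / a, 0.0, 1.0); }
    }
  }
  V3 c1 = p1 + d1 * s, c2 = q1 + d2 * t;
  return norm(c1 - c2);
}

// ray r(t) = o + t*d vs triangle, Moller-Trumbore.
// Returns: 0 miss, 1 hit (t in (tmin, inf), interior), 2 degenerate/grazing.
static int ray_tri(const V3 &o, const V3 &d, const V3 &a, const V3 &b, const V3 &c,
                   double scale, double *t_out) {
  V3 e1 = b - a, e2 = c - a;
  V3 pv = cross(d, e2);
  double det = dot(e1, pv);
  double eps = 1e-12 * scale;
  if (std::fabs(det) < eps) {
    // parallel; if the ray could still graze the plane near the triangle we
    // flag degenerate so the caller retries with another direction
    V3 cp = closest_point_on_triangle(o, a, b, c);
    V3 w = cp - o;
    double along = dot(w, d);
    if (along > -GEOM_TOL) {
      V3 perp = w - d * along;
      if (norm(perp) < 10.0 * GEOM_TOL) return 2;
    }
    return 0;
  }
  double inv = 1.0 / det;
  V3 tv = o - a;
  double u = dot(tv, pv) * inv;
  double bary_eps = 1e-9;
  if (u < -bary_eps || u > 1.0 + bary_eps) return 0;
  V3 qv = cross(tv, e1);
  double v = dot(d, qv) * inv;
  if (v < -bary_eps || u + v > 1.0 + bary_eps) return 0;
  double t = dot(e2, qv) * inv;
  if (t <= GEOM_TOL) {
    if (t > -GEOM_TOL) return 2;  // origin on the surface: ambiguous
    return 0;
  }
  // near an edge/vertex: double counting risk -> degenerate
  if (u < bary_eps || v < bary_eps || u + v > 1.0 - bary_eps) return 2;
  if (t_out) *t_out = t;
  return 1;
}

// segment ab vs triangle: exact minimum distance
static double seg_tri_dist(const V3 &p, const V3 &q, const V3 &a, const V3 &b, const V3 &c) {
  // intersection test (segment crosses triangle plane inside triangle)
  V3 n = cross(b - a, c - a);
  double dp = dot(n, p - a), dq = dot(n, q - a);
  if ((dp <= 0 && dq >= 0) || (dp >= 0 && dq <= 0)) {
    double denom = dp - dq;
    if (std::fabs(denom) > 1e-30) {
      double t = dp / denom;
      V3 x = p + (q - p) * t;
      // inside-triangle test via barycentric signs
      double nn = dot(n, n);
      if (nn > 1e-30) {
        V3 c0 = cross(b - a, x - a);
        V3 c1 = cross(c - b, x - b);
        V3 c2 = cross(a - c, x - c);
        if (dot(c0, n) >= 0 && dot(c1, n) >= 0 && dot(c2, n) >= 0) return 0.0;
      }
    } else {
      // segment lies in the plane: handled by edge/endpoint cases below
      if (std::fabs(dp) < 1e-30) {
        // coplanar: fall through to edge distances (0 if overlapping)
      }
    }
  }
  double d = seg_seg_dist(p, q, a, b);
  d = std::min(d, seg_seg_dist(p, q, b, c));
  d = std::min(d, seg_seg_dist(p, q, c, a));
  d = std::min(d, norm(p - closest_point_on_triangle(p, a, b, c)));
  d = std::min(d, norm(q - closest_point_on_triangle(q, a, b, c)));
  return d;
}

// distance between segment p0p1 and the infinite line (b, dir a, unit)
static double seg_line_dist(const V3 &p0, const V3 &p1, const V3 &b, const V3 &a) {
  V3 u = p1 - p0, w0 = p0 - b;
  V3 up = u - a * dot(u, a);
  V3 wp = w0 - a * dot(w0, a);
  double uu = dot(up, up);
  double t = 0.0;
  if (uu > 1e-30) t = clampd(-dot(wp, up) / uu, 0.0, 1.0);
  V3 q = wp + up * t;
  return norm(q);
}

// ---------------------------------------------------------------------------
// Cylinder vs triangle: exact solid-intersection predicate.
// Clip the triangle to the slab 0 <= s <= L (s = axial coordinate), then the
// triangle meets the cylinder solid iff the clipped polygon comes within
// `radius` of the axis line.  This realizes the union of the lateral and
// end-cap tests in one exact computation.
// ---------------------------------------------------------------------------

static int clip_halfspace(const V3 *in, const double *sin_, int n, double keep_sign,
                          double bound, V3 *out, double *sout) {
  // keep points with keep_sign * (s - bound) <= 0
  int m = 0;
  for (int i = 0; i < n; i++) {
    int j = (i + 1) % n;
    double si = keep_sign * (sin_[i] - bound);
    double sj = keep_sign * (sin_[j] - bound);
    bool ini = si <= 0.0, inj = sj <= 0.0;
    if (ini) {
      out[m] = in[i];
      sout[m++] = sin_[i];
    }
    if (ini != inj) {
      double t = si / (si - sj);
      out[m] = in[i] + (in[j] - in[i]) * t;
      sout[m++] = sin_[i] + (sin_[j] - sin_[i]) * t;
    }
  }
  return m;
}

static bool tri_cyl_hit(const V3 &t0, const V3 &t1, const V3 &t2,
                        const V3 &base, const V3 &axis, double len, double radius) {
  V3 poly0[8], poly1[8];
  double s0[8], s1[8];
  poly0[0] = t0; poly0[1] = t1; poly0[2] = t2;
  s0[0] = dot(t0 - base, axis);
  s0[1] = dot(t1 - base, axis);
  s0[2] = dot(t2 - base, axis);
  int n = clip_halfspace(poly0, s0, 3, -1.0, 0.0, poly1, s1);       // s >= 0
  if (n == 0) return false;
  n = clip_halfspace(poly1, s1, n, 1.0, len, poly0, s0);            // s <= L
  if (n == 0) return false;
  // does the axis line pierce the (planar, convex) clipped polygon?
  V3 nrm = cross(t1 - t0, t2 - t0);
  double denom = dot(nrm, axis);
  if (std::fabs(denom) > 1e-12 * (norm(nrm) + 1e-30)) {
    double t = dot(nrm, t0 - base) / denom;
    V3 ip = base + axis * t;
    // convex-polygon containment: consistent cross-product signs
    int pos = 0, neg = 0;
    for (int i = 0; i < n; i++) {
      int j = (i + 1) % n;
      double side = dot(cross(poly0[j] - poly0[i], ip - poly0[i]), nrm);
      if (side > 0) pos++;
      else if (side < 0) neg++;
    }
    if (pos == 0 || neg == 0) {
      double ts = dot(ip - base, axis);
      if (ts >= -GEOM_TOL && ts <= len + GEOM_TOL) return radius > GEOM_TOL;
    }
  }
  double dmin = std::numeric_limits<double>::infinity();
  if (n == 1) {
    V3 wp = (poly0[0] - base) - axis * dot(poly0[0] - base, axis);
    dmin = norm(wp);
  } else {
    for (int i = 0; i < n; i++) {
      int j = (i + 1) % n;
      dmin = std::min(dmin, seg_line_dist(poly0[i], poly0[j], base, axis));
    }
  }
  return dmin < radius - GEOM_TOL;
}

// ---------------------------------------------------------------------------
// BVH over faces
// ---------------------------------------------------------------------------

struct BVHNode {
  double lo[3], hi[3];
  int left, right;   // children, or -1 if leaf
  int start, count;  // leaf: face range in `order`
};

struct MeshBVH {
  std::vector<V3> V;
  std::vector<int> F;       // 3*m, 0-based
  std::vector<V3> centroid; // per face
  std::vector<int> order;
  std::vector<BVHNode> nodes;
  double scale;             // bbox diagonal, for tolerance scaling

  int build(int start, int count) {
    BVHNode nd;
    for (int k = 0; k < 3; k++) {
      nd.lo[k] = std::numeric_limits<double>::infinity();
      nd.hi[k] = -std::numeric_limits<double>::infinity();
    }
    double clo[3], chi[3];
    for (int k = 0; k < 3; k++) { clo[k] = nd.lo[k]; chi[k] = nd.hi[k]; }
    for (int i = start; i < start + count; i++) {
      int f = order[i];
      for (int v = 0; v < 3; v++) {
        const V3 &p = V[F[3 * f + v]];
        double pc[3] = {p.x, p.y, p.z};
        for (int k = 0; k < 3; k++) {
          nd.lo[k] = std::min(nd.lo[k], pc[k]);
          nd.hi[k] = std::max(nd.hi[k], pc[k]);
        }
      }
      double cc[3] = {centroid[f].x, centroid[f].y, centroid[f].z};
      for (int k = 0; k < 3; k++) {
        clo[k] = std::min(clo[k], cc[k]);
        chi[k] = std::max(chi[k], cc[k]);
      }
    }
    nd.left = nd.right = -1;
    nd.start = start;
    nd.count = count;
    int idx = (int)nodes.size();
    nodes.push_back(nd);
    if (count <= 8) return idx;
    int ax = 0;
    double best = chi[0] - clo[0];
    for (int k = 1; k < 3; k++)
      if (chi[k] - clo[k] > best) { best = chi[k] - clo[k]; ax = k; }
    if (best < 1e-12) return idx;  // degenerate spread: keep as leaf
    int mid = start + count / 2;
    std::nth_element(order.begin() + start, order.begin() + mid,
                     order.begin() + start + count, [&](int a, int b) {
                       double ca = ax == 0 ? centroid[a].x : (ax == 1 ? centroid[a].y : centroid[a].z);
                       double cb = ax == 0 ? centroid[b].x : (ax == 1 ? centroid[b].y : centroid[b].z);
                       return ca < cb;
                     });
    int l = build(start, mid - start);
    int r = build(mid, start + count - mid);
    nodes[idx].left = l;
    nodes[idx].right = r;
    nodes[idx].start = -1;
    nodes[idx].count = 0;
    return idx;
  }
};

static MeshBVH *make_bvh(const NumericMatrix &Vm, const IntegerMatrix &Fm) {
  MeshBVH *h = new MeshBVH();
  int nv = Vm.nrow(), m = Fm.nrow();
  h->V.resize(nv);
  for (int i = 0; i < nv; i++) h->V[i] = V3(Vm(i, 0), Vm(i, 1), Vm(i, 2));
  h->F.resize(3 * m);
  h->centroid.resize(m);
  h->order.resize(m);
  for (int f = 0; f < m; f++) {
    for (int v = 0; v < 3; v++) h->F[3 * f + v] = Fm(f, v) - 1;
    const V3 &a = h->V[h->F[3 * f]], &b = h->V[h->F[3 * f + 1]], &c = h->V[h->F[3 * f + 2]];
    h->centroid[f] = (a + b + c) * (1.0 / 3.0);
    h->order[f] = f;
  }
  h->nodes.reserve(2 * m / 8 + 4);
  if (m > 0) h->build(0, m);
  double diag = 0;
  if (!h->nodes.empty()) {
    double s = 0;
    for (int k = 0; k < 3; k++) {
      double d = h->nodes[0].hi[k] - h->nodes[0].lo[k];
      s += d * d;
    }
    diag = std::sqrt(s);
  }
  h->scale = diag > 0 ? diag : 1.0;
  return h;
}

static inline bool box_overlap(const BVHNode &nd, const double lo[3], const double hi[3]) {
  for (int k = 0; k < 3; k++)
    if (nd.lo[k] > hi[k] || nd.hi[k] < lo[k]) return false;
  return true;
}

static inline bool box_sphere_overlap(const BVHNode &nd, const V3 &c, double r) {
  double d2 = 0, cc[3] = {c.x, c.y, c.z};
  for (int k = 0; k < 3; k++) {
    double v = clampd(cc[k], nd.lo[k], nd.hi[k]) - cc[k];
    d2 += v * v;
  }
  return d2 <= r * r;
}

// ray vs AABB slab test (ray to +inf)
static inline bool ray_box(const BVHNode &nd, const V3 &o, const V3 &d) {
  double tmin = 0.0, tmax = std::numeric_limits<double>::infinity();
  double oc[3] = {o.x, o.y, o.z}, dc[3] = {d.x, d.y, d.z};
  for (int k = 0; k < 3; k++) {
    if (std::fabs(dc[k]) < 1e-15) {
      if (oc[k] < nd.lo[k] - GEOM_TOL || oc[k] > nd.hi[k] + GEOM_TOL) return false;
    } else {
      double inv = 1.0 / dc[k];
      double t1 = (nd.lo[k] - oc[k]) * inv, t2 = (nd.hi[k] - oc[k]) * inv;
      if (t1 > t2) std::swap(t1, t2);
      tmin = std::max(tmin, t1);
      tmax = std::min(tmax, t2);
      if (tmin > tmax + GEOM_TOL) return false;
    }
  }
  return true;
}

// deterministic quasi-random direction generator for ray retries
static V3 retry_dir(int attempt) {
  static const double dirs[16][3] = {
      {0.577350269189626, 0.577350269189626, 0.577350269189626},
      {0.262891711531604, 0.525783423063208, 0.809059528236625},
      {-0.801783725737273, 0.267261241912424, 0.534522483824849},
      {0.371390676354104, -0.557086014531156, 0.742781352708207},
      {0.455842305838552, 0.569802882298190, -0.683763458757828},
      {-0.169030850945703, -0.507092552837110, 0.845154254728517},
      {0.688247201611685, -0.229415733870562, -0.688247201611685},
      {-0.408248290463863, 0.816496580927726, -0.408248290463863},
      {0.181071173092458, 0.905355865462290, 0.384776242821473},
      {-0.638284738504225, -0.212761579501408, 0.739823822864981},
      {0.717137165600636, 0.597614304667197, 0.358568582800318},
      {-0.267261241912424, 0.801783725737273, 0.534522483824849},
      {0.904534033733291, -0.301511344577764, 0.301511344577764},
      {-0.316227766016838, -0.948683298050514, 0.0},
      {0.0, 0.447213595499958, -0.894427190999916},
      {0.597022165037689, -0.099503719021999, 0.796029752175989}};
  const double *d = dirs[attempt & 15];
  return V3(d[0], d[1], d[2]);
}

// parity point-in-mesh with degeneracy retry
static bool point_in_mesh_h(const MeshBVH *h, const V3 &p, bool *ok_out) {
  std::vector<int> stack;
  for (int attempt = 0; attempt < 16; attempt++) {
    V3 d = retry_dir(attempt);
    int crossings = 0;
    bool degenerate = false;
    stack.clear();
    if (!h->nodes.empty()) stack.push_back(0);
    while (!stack.empty() && !degenerate) {
      int ni = stack.back();
      stack.pop_back();
      const BVHNode &nd = h->nodes[ni];
      if (!ray_box(nd, p, d)) continue;
      if (nd.left < 0) {
        for (int i = nd.start; i < nd.start + nd.count; i++) {
          int f = h->order[i];
          const V3 &a = h->V[h->F[3 * f]], &b = h->V[h->F[3 * f + 1]], &c = h->V[h->F[3 * f + 2]];
          int r = ray_tri(p, d, a, b, c, h->scale, NULL);
          if (r == 2) { degenerate = true; break; }
          if (r == 1) crossings++;
        }
      } else {
        stack.push_back(nd.left);
        stack.push_back(nd.right);
      }
    }
    if (!degenerate) {
      if (ok_out) *ok_out = true;
      return (crossings & 1) != 0;
    }
  }
  if (ok_out) *ok_out = false;
  return false;
}

// full cylinder-vs-mesh predicate; exclusion by face-centroid distance to the
// cylinder base (exclusion_radius <= 0 disables it).  The excluded-face
// vertex-containment pass keeps the containment tests on the full solid.
static bool cyl_mesh_hit(const MeshBVH *h, const V3 &base, const V3 &axis,
                         double len, double radius, double excl_radius,
                         std::vector<int> &stack, bool containment = true) {
  V3 tip = base + axis * len;
  double lo[3], hi[3];
  double bc[3] = {base.x, base.y, base.z}, tc[3] = {tip.x, tip.y, tip.z};
  for (int k = 0; k < 3; k++) {
    lo[k] = std::min(bc[k], tc[k]) - radius - GEOM_TOL;
    hi[k] = std::max(bc[k], tc[k]) + radius + GEOM_TOL;
  }
  // (a) surface-proximity: exact triangle-vs-cylinder over non-excluded faces
  stack.clear();
  if (!h->nodes.empty()) stack.push_back(0);
  double er2 = excl_radius * excl_radius;
  while (!stack.empty()) {
    int ni = stack.back();
    stack.pop_back();
    const BVHNode &nd = h->nodes[ni];
    if (!box_overlap(nd, lo, hi)) continue;
    if (nd.left < 0) {
      for (int i = nd.start; i < nd.start + nd.count; i++) {
        int f = h->order[i];
        if (excl_radius > 0) {
          V3 dcb = h->centroid[f] - base;
          if (dot(dcb, dcb) < er2) continue;
        }
        const V3 &a = h->V[h->F[3 * f]], &b = h->V[h->F[3 * f + 1]], &c = h->V[h->F[3 * f + 2]];
        if (tri_cyl_hit(a, b, c, base, axis, len, radius)) return true;
      }
    } else {
      stack.push_back(nd.left);
      stack.push_back(nd.right);
    }
  }
  // (c) thin-piercing guard: vertices of excluded faces inside the cylinder
  // (vertices of non-excluded faces are already covered exactly by (a))
  if (excl_radius > 0 && len > GEOM_TOL && radius > GEOM_TOL) {
    stack.clear();
    if (!h->nodes.empty()) stack.push_back(0);
    while (!stack.empty()) {
      int ni = stack.back();
      stack.pop_back();
      const BVHNode &nd = h->nodes[ni];
      if (!box_sphere_overlap(nd, base, excl_radius)) continue;
      if (nd.left < 0) {
        for (int i = nd.start; i < nd.start + nd.count; i++) {
          int f = h->order[i];
          V3 dcb = h->centroid[f] - base;
          if (dot(dcb, dcb) >= er2) continue;
          for (int v = 0; v < 3; v++) {
            const V3 &p = h->V[h->F[3 * f + v]];
            double s = dot(p - base, axis);
            if (s > GEOM_TOL && s < len - GEOM_TOL) {
              V3 rad = (p - base) - axis * s;
              if (norm(rad) < radius - GEOM_TOL) return true;
            }
          }
        }
      } else {
        stack.push_back(nd.left);
        stack.push_back(nd.right);
      }
    }
  }
  // (b) containment: axis midpoint inside the mesh solid
  if (containment && (len > 0 || radius > 0)) {
    V3 mid = base + axis * (0.5 * len);
    bool ok = true;
    if (point_in_mesh_h(h, mid, &ok) && ok) return true;
  }
  return false;
}

// ---------------------------------------------------------------------------
// Exported interface
// ---------------------------------------------------------------------------

static void bvh_finalizer(MeshBVH *h) { delete h; }

// [[Rcpp::export]]
SEXP cpp_bvh_build(NumericMatrix V, IntegerMatrix F) {
  XPtr<MeshBVH> p(make_bvh(V, F), true);
  return p;
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(SEXP bvh, NumericMatrix P) {
  XPtr<MeshBVH> h(bvh);
  int n = P.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; i++) {
    V3 p(P(i, 0), P(i, 1), P(i, 2));
    bool ok = true;
    bool in = point_in_mesh_h(h.get(), p, &ok);
    if (!ok) stop("point-in-mesh ray casting degenerate after retries");
    out[i] = in;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_seg_tri_dist(NumericVector a, NumericVector b, NumericMatrix tri) {
  V3 p(a[0], a[1], a[2]), q(b[0], b[1], b[2]);
  V3 t0(tri(0, 0), tri(0, 1), tri(0, 2));
  V3 t1(tri(1, 0), tri(1, 1), tri(1, 2));
  V3 t2(tri(2, 0), tri(2, 1), tri(2, 2));
  return seg_tri_dist(p, q, t0, t1, t2);
}

// [[Rcpp::export]]
bool cpp_tri_cyl_hit(NumericMatrix tri, NumericVector base, NumericVector axis,
                     double len, double radius) {
  V3 t0(tri(0, 0), tri(0, 1), tri(0, 2));
  V3 t1(tri(1, 0), tri(1, 1), tri(1, 2));
  V3 t2(tri(2, 0), tri(2, 1), tri(2, 2));
  return tri_cyl_hit(t0, t1, t2, V3(base[0], base[1], base[2]),
                     V3(axis[0], axis[1], axis[2]), len, radius);
}

// [[Rcpp::export]]
bool cpp_cyl_mesh_overlap(SEXP bvh, NumericVector base, NumericVector axis,
                          double len, double radius, double excl_radius,
                          bool containment = true) {
  XPtr<MeshBVH> h(bvh);
  std::vector<int> stack;
  return cyl_mesh_hit(h.get(), V3(base[0], base[1], base[2]),
                      V3(axis[0], axis[1], axis[2]), len, radius, excl_radius,
                      stack, containment);
}

// Batch: one frame, many sites.  bases/axes are n x 3.
// [[Rcpp::export]]
LogicalVector cpp_assess_frame(SEXP bvh, NumericMatrix bases, NumericMatrix axes,
                               double len, double radius, double excl_radius) {
  XPtr<MeshBVH> h(bvh);
  int n = bases.nrow();
  LogicalVector out(n);
  std::vector<int> stack;
  for (int i = 0; i < n; i++) {
    V3 b(bases(i, 0), bases(i, 1), bases(i, 2));
    V3 a(axes(i, 0), axes(i, 1), axes(i, 2));
    out[i] = cyl_mesh_hit(h.get(), b, a, len, radius, excl_radius, stack);
  }
  return out;
}

// minimum distance from each point to the mesh surface (for snapping checks)
// [[Rcpp::export]]
NumericVector cpp_points_mesh_dist(SEXP bvh, NumericMatrix P) {
  XPtr<MeshBVH> h(bvh);
  int n = P.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    V3 p(P(i, 0), P(i, 1), P(i, 2));
    // branch-and-bound nearest face
    double best = std::numeric_limits<double>::infinity();
    std::vector<std::pair<double, int> > stack;
    if (!h->nodes.empty()) stack.push_back(std::make_pair(0.0, 0));
    while (!stack.empty()) {
      std::pair<double, int> top = stack.back();
      stack.pop_back();
      if (top.first >= best) continue;
      const BVHNode &nd = h->nodes[top.second];
      if (nd.left < 0) {
        for (int k = nd.start; k < nd.start + nd.count; k++) {
          int f = h->order[k];
          const V3 &a = h->V[h->F[3 * f]], &b = h->V[h->F[3 * f + 1]], &c = h->V[h->F[3 * f + 2]];
          best = std::min(best, norm(p - closest_point_on_triangle(p, a, b, c)));
        }
      } else {
        for (int side = 0; side < 2; side++) {
          int ci = side == 0 ? nd.left : nd.right;
          const BVHNode &ch = h->nodes[ci];
          double d2 = 0, pc[3] = {p.x, p.y, p.z};
          for (int k = 0; k < 3; k++) {
            double v = clampd(pc[k], ch.lo[k], ch.hi[k]) - pc[k];
            d2 += v * v;
          }
          double d = std::sqrt(d2);
          if (d < best) stack.push_back(std::make_pair(d, ci));
        }
      }
    }
    out[i] = best;
  }
  return out;
}
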