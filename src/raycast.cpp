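#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Ray-parity membership test with an eps surface band.
//
// A query point is reported "in" when it lies strictly inside the closed
// mesh (odd number of ray crossings) or within eps of any triangle.
// Degenerate ray hits (edge/vertex grazing, coplanar rays) are detected and
// the ray is re-cast along the next direction of a fixed pseudo-random list,
// so the parity count is always taken from a clean ray.

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return Vec3{a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return Vec3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x};
}
inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

// Squared distance from point p to triangle (a,b,c).
// Ericson, Real-Time Collision Detection, closest-point-on-triangle.
double dist2_point_tri(const Vec3 &p, const Vec3 &a, const Vec3 &b,
                       const Vec3 &c) {
  Vec3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) {
    return dot(ap, ap);
  }
  Vec3 bp = sub(p, b);
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) {
    return dot(bp, bp);
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    Vec3 q{a.x + v * ab.x, a.y + v * ab.y, a.z + v * ab.z};
    Vec3 pq = sub(p, q);
    return dot(pq, pq);
  }
  Vec3 cp = sub(p, c);
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) {
    return dot(cp, cp);
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    Vec3 q{a.x + w * ac.x, a.y + w * ac.y, a.z + w * ac.z};
    Vec3 pq = sub(p, q);
    return dot(pq, pq);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    Vec3 q{b.x + w * (c.x - b.x), b.y + w * (c.y - b.y),
           b.z + w * (c.z - b.z)};
    Vec3 pq = sub(p, q);
    return dot(pq, pq);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  Vec3 q{a.x + ab.x * v + ac.x * w, a.y + ab.y * v + ac.y * w,
         a.z + ab.z * v + ac.z * w};
  Vec3 pq = sub(p, q);
  return dot(pq, pq);
}

// Moller-Trumbore. Returns: 1 hit, 0 miss, -1 degenerate (re-cast needed).
int ray_tri(const Vec3 &orig, const Vec3 &dir, const Vec3 &a, const Vec3 &b,
            const Vec3 &c, double scale) {
  const double eps_det = 1e-12;
  const double eps_bary = 1e-9;
  Vec3 e1 = sub(b, a), e2 = sub(c, a);
  Vec3 pv = cross(dir, e2);
  double det = dot(e1, pv);
  double tri_scale = std::max(norm(e1), norm(e2));
  if (std::fabs(det) <= eps_det * tri_scale * tri_scale) {
    // Ray nearly parallel to the triangle plane: only ambiguous when the
    // ray passes near the triangle; treat as degenerate conservatively if
    // the ray origin projects close to the plane.
    Vec3 n = cross(e1, e2);
    double nn = norm(n);
    if (nn <= 0.0) return 0;  // zero-area facet never intersects
    double h = std::fabs(dot(sub(orig, a), n)) / nn;
    return (h < 1e-7 * std::max(1.0, scale)) ? -1 : 0;
  }
  double inv = 1.0 / det;
  Vec3 tv = sub(orig, a);
  double u = dot(tv, pv) * inv;
  if (u < -eps_bary || u > 1.0 + eps_bary) return 0;
  Vec3 qv = cross(tv, e1);
  double v = dot(dir, qv) * inv;
  if (v < -eps_bary || u + v > 1.0 + eps_bary) return 0;
  double t = dot(e2, qv) * inv;
  if (t <= 0.0) {
    // Hits behind (or at) the origin do not count; an exact t == 0 means the
    // point sits on the surface, handled by the eps band, so ignore here.
    return (std::fabs(t) < 1e-12 * std::max(1.0, scale)) ? -1 : 0;
  }
  // Grazing an edge or vertex makes parity unreliable.
  if (u < eps_bary || v < eps_bary || u + v > 1.0 - eps_bary) return -1;
  return 1;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_points_in_mesh")]]
LogicalVector cpp_points_in_mesh(NumericMatrix verts, IntegerMatrix faces,
                                 NumericMatrix pts, double eps) {
  int nf = faces.nrow(), np = pts.nrow();
  std::vector<Vec3> V(verts.nrow());
  for (int i = 0; i < verts.nrow(); ++i)
    V[i] = Vec3{verts(i, 0), verts(i, 1), verts(i, 2)};

  // Per-face vertex triples and bounding boxes (cheap culling).
  std::vector<Vec3> A(nf), B(nf), C(nf);
  std::vector<double> bx0(nf), bx1(nf), by0(nf), by1(nf), bz0(nf), bz1(nf);
  double scale = 0.0;
  for (int f = 0; f < nf; ++f) {
    A[f] = V[faces(f, 0) - 1];
    B[f] = V[faces(f, 1) - 1];
    C[f] = V[faces(f, 2) - 1];
    bx0[f] = std::min({A[f].x, B[f].x, C[f].x});
    bx1[f] = std::max({A[f].x, B[f].x, C[f].x});
    by0[f] = std::min({A[f].y, B[f].y, C[f].y});
    by1[f] = std::max({A[f].y, B[f].y, C[f].y});
    bz0[f] = std::min({A[f].z, B[f].z, C[f].z});
    bz1[f] = std::max({A[f].z, B[f].z, C[f].z});
    scale = std::max({scale, std::fabs(bx1[f]), std::fabs(by1[f]),
                      std::fabs(bz1[f])});
  }

  // Fixed direction list; first entry is an arbitrary irrational-ish
  // direction, later entries only used on degenerate grazes.
  const int ndir = 16;
  double dirs[ndir][3];
  unsigned long long s = 88172645463325252ULL;
  for (int k = 0; k < ndir; ++k) {
    double d[3];
    for (int j = 0; j < 3; ++j) {
      s ^= s << 13; s ^= s >> 7; s ^= s << 17;
      d[j] = 2.0 * ((double)(s % 1000003) / 1000003.0) - 1.0;
    }
    double nn = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (nn < 1e-3) { nn = 1.0; d[0] = 1.0; d[1] = d[2] = 0.0; }
    dirs[k][0] = d[0] / nn; dirs[k][1] = d[1] / nn; dirs[k][2] = d[2] / nn;
  }

  double eps2 = eps * eps;
  LogicalVector out(np);
  for (int i = 0; i < np; ++i) {
    Vec3 p{pts(i, 0), pts(i, 1), pts(i, 2)};

    // Surface band first: within eps of any facet counts as "in".
    bool near = false;
    if (eps > 0.0) {
      for (int f = 0; f < nf && !near; ++f) {
        if (p.x < bx0[f] - eps || p.x > bx1[f] + eps ||
            p.y < by0[f] - eps || p.y > by1[f] + eps ||
            p.z < bz0[f] - eps || p.z > bz1[f] + eps)
          continue;
        if (dist2_point_tri(p, A[f], B[f], C[f]) <= eps2) near = true;
      }
    }
    if (near) { out[i] = true; continue; }

    bool inside = false;
    for (int k = 0; k < ndir; ++k) {
      Vec3 dir{dirs[k][0], dirs[k][1], dirs[k][2]};
      int crossings = 0;
      bool bad = false;
      for (int f = 0; f < nf; ++f) {
        int r = ray_tri(p, dir, A[f], B[f], C[f], scale);
        if (r < 0) { bad = true; break; }
        crossings += r;
      }
      if (!bad) { inside = (crossings % 2) == 1; break; }
      if (k == ndir - 1) inside = (crossings % 2) == 1;  // give up gracefully
    }
    out[i] = inside;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_min_dist_to_mesh")]]
NumericVector cpp_min_dist_to_mesh(NumericMatrix verts, IntegerMatrix faces,
                                   NumericMatrix pts) {
  int nf = faces.nrow(), np = pts.nrow();
  std::vector<Vec3> V(verts.nrow());
  for (int i = 0; i < verts.nrow(); ++i)
    V[i] = Vec3{verts(i, 0), verts(i, 1), verts(i, 2)};
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    Vec3 p{pts(i, 0), pts(i, 1), pts(i, 2)};
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      double d2 = dist2_point_tri(p, V[faces(f, 0) - 1], V[faces(f, 1) - 1],
                                  V[faces(f, 2) - 1]);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
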