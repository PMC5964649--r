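#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Incremental 3D convex hull of a point cloud (nucleus centers, micrometres).
// Returns the hull volume, the vertex index set, and the facet planes
// (outward unit normals n with n.x = offset on the plane), which downstream
// code uses for shell-distance classification of inner vs outer nuclei.

struct Facet {
  int a, b, c;         // 0-based point indices, counter-clockwise from outside
  double nx, ny, nz;   // outward normal (unnormalized)
  double off;          // dot(n, A)
  bool alive;
};

static inline void facet_normal(const NumericMatrix& P, Facet& f,
                                const double* interior) {
  double ax = P(f.a, 0), ay = P(f.a, 1), az = P(f.a, 2);
  double ux = P(f.b, 0) - ax, uy = P(f.b, 1) - ay, uz = P(f.b, 2) - az;
  double vx = P(f.c, 0) - ax, vy = P(f.c, 1) - ay, vz = P(f.c, 2) - az;
  f.nx = uy * vz - uz * vy;
  f.ny = uz * vx - ux * vz;
  f.nz = ux * vy - uy * vx;
  f.off = f.nx * ax + f.ny * ay + f.nz * az;
  // orient outward: interior point strictly below the plane
  double side = f.nx * interior[0] + f.ny * interior[1] + f.nz * interior[2] - f.off;
  if (side > 0) {
    int tmp = f.b; f.b = f.c; f.c = tmp;
    f.nx = -f.nx; f.ny = -f.ny; f.nz = -f.nz; f.off = -f.off;
  }
}

static inline double norm3(double x, double y, double z) {
  return std::sqrt(x * x + y * y + z * z);
}

// [[Rcpp::export(name = ".hull3d_cpp")]]
List hull3d_cpp(NumericMatrix P) {
  const int n = P.nrow();
  if (P.ncol() != 3) stop("points must be an n x 3 matrix");
  if (n < 4) stop("degenerate geometry: need at least 4 points");

  // coordinate scale for tolerances
  double scale = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j)
      scale = std::max(scale, std::fabs(P(i, j)));
  if (scale == 0.0) scale = 1.0;
  const double eps = 1e-9 * scale;

  // --- initial simplex: four affinely independent points ---
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  double best = -1.0;
  for (int i = 1; i < n; ++i) {
    double d = norm3(P(i,0)-P(i0,0), P(i,1)-P(i0,1), P(i,2)-P(i0,2));
    if (d > best) { best = d; i1 = i; }
  }
  if (best <= eps) stop("degenerate geometry: all points coincide");
  best = -1.0;
  double ex = P(i1,0)-P(i0,0), ey = P(i1,1)-P(i0,1), ez = P(i1,2)-P(i0,2);
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1) continue;
    double wx = P(i,0)-P(i0,0), wy = P(i,1)-P(i0,1), wz = P(i,2)-P(i0,2);
    double cx = ey*wz - ez*wy, cy = ez*wx - ex*wz, cz = ex*wy - ey*wx;
    double a = norm3(cx, cy, cz);
    if (a > best) { best = a; i2 = i; }
  }
  if (best <= eps * scale) stop("degenerate geometry: points are collinear");
  best = -1.0;
  double fx = P(i2,0)-P(i0,0), fy = P(i2,1)-P(i0,1), fz = P(i2,2)-P(i0,2);
  double nx0 = ey*fz - ez*fy, ny0 = ez*fx - ex*fz, nz0 = ex*fy - ey*fx;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2) continue;
    double v = std::fabs(nx0*(P(i,0)-P(i0,0)) + ny0*(P(i,1)-P(i0,1)) + nz0*(P(i,2)-P(i0,2)));
    if (v > best) { best = v; i3 = i; }
  }
  if (best <= eps * scale * scale) stop("degenerate geometry: points are coplanar");

  double interior[3];
  for (int j = 0; j < 3; ++j)
    interior[j] = (P(i0,j) + P(i1,j) + P(i2,j) + P(i3,j)) / 4.0;

  std::vector<Facet> facets;
  facets.reserve(8 * (size_t)n);
  int tet[4] = { i0, i1, i2, i3 };
  int tri[4][3] = { {0,1,2}, {0,1,3}, {0,2,3}, {1,2,3} };
  for (int k = 0; k < 4; ++k) {
    Facet f; f.a = tet[tri[k][0]]; f.b = tet[tri[k][1]]; f.c = tet[tri[k][2]];
    f.alive = true;
    facet_normal(P, f, interior);
    facets.push_back(f);
  }

  // --- incremental insertion ---
  std::vector<bool> used(n, false);
  used[i0] = used[i1] = used[i2] = used[i3] = true;
  for (int i = 0; i < n; ++i) {
    if (used[i]) continue;
    // visible facets: point strictly outside the supporting plane
    std::vector<int> visible;
    for (size_t k = 0; k < facets.size(); ++k) {
      Facet& f = facets[k];
      if (!f.alive) continue;
      double nn = norm3(f.nx, f.ny, f.nz);
      if (nn <= eps * scale) continue;  // degenerate sliver, never visible
      double d = (f.nx * P(i,0) + f.ny * P(i,1) + f.nz * P(i,2) - f.off) / nn;
      if (d > eps) visible.push_back((int)k);
    }
    if (visible.empty()) continue;  // inside or on the hull

    // horizon: directed edges of the visible set whose reverse is not visible
    std::map<std::pair<int,int>, int> edge;
    for (int vk : visible) {
      const Facet& f = facets[vk];
      int e[3][2] = { {f.a, f.b}, {f.b, f.c}, {f.c, f.a} };
      for (int t = 0; t < 3; ++t)
        edge[std::make_pair(e[t][0], e[t][1])] = 1;
    }
    for (int vk : visible) facets[vk].alive = false;
    for (std::map<std::pair<int,int>, int>::iterator it = edge.begin();
         it != edge.end(); ++it) {
      int u = it->first.first, v = it->first.second;
      if (edge.count(std::make_pair(v, u))) continue;  // interior edge
      Facet f; f.a = u; f.b = v; f.c = i; f.alive = true;
      facet_normal(P, f, interior);
      facets.push_back(f);
    }
  }

  // --- collect output ---
  int m = 0;
  for (size_t k = 0; k < facets.size(); ++k) if (facets[k].alive) ++m;
  IntegerMatrix F(m, 3);
  NumericMatrix N(m, 3);
  NumericVector off(m);
  std::vector<bool> is_vertex(n, false);
  double vol = 0.0;
  int r = 0;
  for (size_t k = 0; k < facets.size(); ++k) {
    const Facet& f = facets[k];
    if (!f.alive) continue;
    F(r, 0) = f.a + 1; F(r, 1) = f.b + 1; F(r, 2) = f.c + 1;
    is_vertex[f.a] = is_vertex[f.b] = is_vertex[f.c] = true;
    double nn = norm3(f.nx, f.ny, f.nz);
    if (nn > 0) {
      N(r, 0) = f.nx / nn; N(r, 1) = f.ny / nn; N(r, 2) = f.nz / nn;
      off[r] = f.off / nn;
    } else {
      N(r, 0) = N(r, 1) = N(r, 2) = NA_REAL; off[r] = NA_REAL;
    }
    // signed tetra volume against the interior point (outward orientation)
    double ax = P(f.a,0) - interior[0], ay = P(f.a,1) - interior[1], az = P(f.a,2) - interior[2];
    double bx = P(f.b,0) - interior[0], by = P(f.b,1) - interior[1], bz = P(f.b,2) - interior[2];
    double cx = P(f.c,0) - interior[0], cy = P(f.c,1) - interior[1], cz = P(f.c,2) - interior[2];
    vol += (ax * (by * cz - bz * cy) - ay * (bx * cz - bz * cx) + az * (bx * cy - by * cx)) / 6.0;
    ++r;
  }
  std::vector<int> verts;
  for (int i = 0; i < n; ++i) if (is_vertex[i]) verts.push_back(i + 1);

  return List::create(
    _["volume"]   = vol,
    _["vertices"] = wrap(verts),
    _["facets"]   = F,
    _["normals"]  = N,
    _["offsets"]  = off);
}
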