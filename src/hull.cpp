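#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Incremental 3D convex hull (quickhull-style horizon construction) over a
// point cloud, followed by half-space voxelisation: a voxel centre is inside
// the hull when it is on the inner side of every facet (within a small
// scale-relative tolerance, so boundary points count as inside).
//
// Degenerate clouds (rank < 3) are handled upstream in R.

struct Face {
  int a, b, c;
  double nx, ny, nz, d; // plane: n . x = d, n pointing outward
  bool alive;
};

static inline void plane(const std::vector<double> &px, const std::vector<double> &py,
                         const std::vector<double> &pz, Face &f) {
  double ux = px[f.b] - px[f.a], uy = py[f.b] - py[f.a], uz = pz[f.b] - pz[f.a];
  double vx = px[f.c] - px[f.a], vy = py[f.c] - py[f.a], vz = pz[f.c] - pz[f.a];
  f.nx = uy * vz - uz * vy;
  f.ny = uz * vx - ux * vz;
  f.nz = ux * vy - uy * vx;
  f.d = f.nx * px[f.a] + f.ny * py[f.a] + f.nz * pz[f.a];
}

// [[Rcpp::export(name = ".cpp_hull_mask")]]
LogicalVector cpp_hull_mask(NumericMatrix pts, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  LogicalVector out((R_xlen_t)nx * ny * nz, false);
  if (n == 0) return out;

  std::vector<double> px(n), py(n), pz(n);
  double scale = 1.0;
  for (int i = 0; i < n; ++i) {
    px[i] = pts(i, 0); py[i] = pts(i, 1); pz[i] = pts(i, 2);
    scale = std::max(scale, std::max(std::fabs(px[i]),
                     std::max(std::fabs(py[i]), std::fabs(pz[i]))));
  }
  const double eps = 1e-9 * scale; // tolerance on normalised signed distance

  // seed tetrahedron: extreme in x, farthest point, farthest from line,
  // farthest from plane (caller guarantees full rank)
  int i0 = 0;
  for (int i = 1; i < n; ++i) if (px[i] < px[i0]) i0 = i;
  int i1 = -1; double best = -1;
  for (int i = 0; i < n; ++i) {
    double dx = px[i] - px[i0], dy = py[i] - py[i0], dz = pz[i] - pz[i0];
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 > best) { best = d2; i1 = i; }
  }
  int i2 = -1; best = -1;
  {
    double ax = px[i1] - px[i0], ay = py[i1] - py[i0], az = pz[i1] - pz[i0];
    for (int i = 0; i < n; ++i) {
      double bx = px[i] - px[i0], by = py[i] - py[i0], bz = pz[i] - pz[i0];
      double cx = ay * bz - az * by, cy = az * bx - ax * bz, cz = ax * by - ay * bx;
      double d2 = cx * cx + cy * cy + cz * cz;
      if (d2 > best) { best = d2; i2 = i; }
    }
  }
  int i3 = -1; best = -1;
  {
    Face f0; f0.a = i0; f0.b = i1; f0.c = i2;
    plane(px, py, pz, f0);
    for (int i = 0; i < n; ++i) {
      double d = std::fabs(f0.nx * px[i] + f0.ny * py[i] + f0.nz * pz[i] - f0.d);
      if (d > best) { best = d; i3 = i; }
    }
  }

  double cx = (px[i0] + px[i1] + px[i2] + px[i3]) / 4.0;
  double cy = (py[i0] + py[i1] + py[i2] + py[i3]) / 4.0;
  double cz = (pz[i0] + pz[i1] + pz[i2] + pz[i3]) / 4.0;

  std::vector<Face> faces;
  int seed[4][3] = {{i0, i1, i2}, {i0, i1, i3}, {i0, i2, i3}, {i1, i2, i3}};
  for (int s = 0; s < 4; ++s) {
    Face f; f.a = seed[s][0]; f.b = seed[s][1]; f.c = seed[s][2]; f.alive = true;
    plane(px, py, pz, f);
    if (f.nx * cx + f.ny * cy + f.nz * cz - f.d > 0) { // flip outward
      std::swap(f.b, f.c);
      plane(px, py, pz, f);
    }
    faces.push_back(f);
  }

  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    std::vector<int> vis;
    for (int f = 0; f < (int)faces.size(); ++f) {
      if (!faces[f].alive) continue;
      double nn = std::sqrt(faces[f].nx * faces[f].nx + faces[f].ny * faces[f].ny +
                            faces[f].nz * faces[f].nz);
      if (nn <= 0) continue;
      if ((faces[f].nx * px[p] + faces[f].ny * py[p] + faces[f].nz * pz[p] -
           faces[f].d) / nn > eps)
        vis.push_back(f);
    }
    if (vis.empty()) continue;
    // horizon: directed edges of visible faces whose reverse is absent
    std::vector<std::pair<int, int> > edges;
    for (size_t t = 0; t < vis.size(); ++t) {
      const Face &f = faces[vis[t]];
      edges.push_back(std::make_pair(f.a, f.b));
      edges.push_back(std::make_pair(f.b, f.c));
      edges.push_back(std::make_pair(f.c, f.a));
    }
    for (size_t t = 0; t < vis.size(); ++t) faces[vis[t]].alive = false;
    for (size_t e = 0; e < edges.size(); ++e) {
      bool horizon = true;
      for (size_t e2 = 0; e2 < edges.size(); ++e2)
        if (edges[e2].first == edges[e].second && edges[e2].second == edges[e].first) {
          horizon = false;
          break;
        }
      if (!horizon) continue;
      Face f; f.a = edges[e].first; f.b = edges[e].second; f.c = p; f.alive = true;
      plane(px, py, pz, f);
      if (f.nx * cx + f.ny * cy + f.nz * cz - f.d > 0) {
        std::swap(f.b, f.c);
        plane(px, py, pz, f);
      }
      faces.push_back(f);
    }
  }

  std::vector<Face> live;
  for (size_t f = 0; f < faces.size(); ++f)
    if (faces[f].alive) live.push_back(faces[f]);

  // voxelisation restricted to the cloud's bounding box
  int lo[3] = {nx, ny, nz}, hi[3] = {-1, -1, -1};
  for (int i = 0; i < n; ++i) {
    lo[0] = std::min(lo[0], (int)std::floor(px[i]));
    lo[1] = std::min(lo[1], (int)std::floor(py[i]));
    lo[2] = std::min(lo[2], (int)std::floor(pz[i]));
    hi[0] = std::max(hi[0], (int)std::ceil(px[i]));
    hi[1] = std::max(hi[1], (int)std::ceil(py[i]));
    hi[2] = std::max(hi[2], (int)std::ceil(pz[i]));
  }
  for (int d = 0; d < 3; ++d) {
    lo[d] = std::max(lo[d], 0);
  }
  hi[0] = std::min(hi[0], nx - 1);
  hi[1] = std::min(hi[1], ny - 1);
  hi[2] = std::min(hi[2], nz - 1);

  const double veps = 1e-6 * scale;
  for (int k = lo[2]; k <= hi[2]; ++k)
    for (int j = lo[1]; j <= hi[1]; ++j)
      for (int i = lo[0]; i <= hi[0]; ++i) {
        bool inside = true;
        for (size_t f = 0; f < live.size(); ++f) {
          double nn = std::sqrt(live[f].nx * live[f].nx + live[f].ny * live[f].ny +
                                live[f].nz * live[f].nz);
          if (nn <= 0) continue;
          if ((live[f].nx * i + live[f].ny * j + live[f].nz * k - live[f].d) / nn >
              veps) {
            inside = false;
            break;
          }
        }
        if (inside)
          out[(R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k)] = true;
      }
  return out;
}
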