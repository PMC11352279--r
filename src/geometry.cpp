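#include <Rcpp.h>
#include <unordered_map>
#include <climits>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Volumes are R arrays with dim = c(nx, ny, nz), x fastest (MRC storage
// order). Voxel centers sit at 0-based integer coordinates in voxel units.

static inline R_xlen_t vidx(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
}

// 26-connected component labeling of the voxels equal to `value`
// (value < 0 labels every nonzero voxel). Run-length union-find: x-runs
// of foreground are merged with overlapping runs on the 4 neighboring
// lines already scanned, so the work is two sequential passes over the
// volume plus per-run bookkeeping — cache-friendly at tomogram scale,
// with no intermediate mask array. Returns an integer array of the
// same shape: 0 background, 1..k component id.

struct Run { int x0, x1, id; };

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  a = uf_find(parent, a); b = uf_find(parent, b);
  if (a != b) parent[b] = a;
}

// [[Rcpp::export(name = ".cc_label_26")]]
IntegerVector cc_label_26(IntegerVector mask, IntegerVector dims,
                          int value = -1) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  const int* mp = INTEGER(mask);
  auto is_fg = [&](R_xlen_t s) {
    return value < 0 ? mp[s] != 0 : mp[s] == value;
  };

  // pass 1: collect runs per (y, z) line and union across lines
  std::vector<std::vector<Run>> lines((R_xlen_t)ny * nz);
  std::vector<int> parent;
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
      std::vector<Run>& cur = lines[base / nx];
      int x = 0;
      while (x < nx) {
        if (!is_fg(base + x)) { ++x; continue; }
        int x0 = x;
        while (x < nx && is_fg(base + x)) ++x;
        int id = (int)parent.size();
        parent.push_back(id);
        cur.push_back({x0, x - 1, id});
      }
      if (cur.empty()) continue;
      // neighbors already scanned: (y-1, z), (y-1, z-1), (y, z-1),
      // (y+1, z-1); 26-connectivity joins runs whose x-ranges touch
      // within one voxel
      const int ndy[4] = {-1, -1, 0, 1};
      const int ndz[4] = {0, -1, -1, -1};
      for (int k = 0; k < 4; ++k) {
        int yy = y + ndy[k], zz = z + ndz[k];
        if (yy < 0 || yy >= ny || zz < 0) continue;
        const std::vector<Run>& prev =
          lines[(R_xlen_t)yy + (R_xlen_t)ny * zz];
        size_t i = 0, j = 0;
        while (i < cur.size() && j < prev.size()) {
          if (cur[i].x1 + 1 < prev[j].x0) ++i;
          else if (prev[j].x1 + 1 < cur[i].x0) ++j;
          else {
            uf_union(parent, cur[i].id, prev[j].id);
            if (cur[i].x1 < prev[j].x1) ++i; else ++j;
          }
        }
      }
    }
  }

  // compact root ids to 1..k
  std::vector<int> compact(parent.size(), 0);
  int next = 0;
  for (size_t i = 0; i < parent.size(); ++i) {
    int r = uf_find(parent, (int)i);
    if (compact[r] == 0) compact[r] = ++next;
  }

  // pass 2: paint runs
  IntegerVector lab(n, 0);
  int* lp = INTEGER(lab);
  for (R_xlen_t line = 0; line < (R_xlen_t)ny * nz; ++line) {
    R_xlen_t base = line * nx;
    for (const Run& r : lines[line]) {
      int l = compact[uf_find(parent, r.id)];
      for (int x = r.x0; x <= r.x1; ++x) lp[base + x] = l;
    }
  }
  lab.attr("dim") = dims;
  lab.attr("n_components") = next;
  return lab;
}

// Per-component voxel counts, centroids and bounding boxes (voxel
// units, 0-based inclusive) in one pass.
// [[Rcpp::export(name = ".component_stats")]]
List component_stats(IntegerVector lab, IntegerVector dims, int k) {
  const int nx = dims[0], ny = dims[1];
  const R_xlen_t n = lab.size();
  std::vector<double> cx(k, 0.0), cy(k, 0.0), cz(k, 0.0);
  std::vector<double> cnt(k, 0.0);
  IntegerMatrix bbox(k, 6);  // xmin xmax ymin ymax zmin zmax
  for (int i = 0; i < k; ++i) {
    bbox(i, 0) = bbox(i, 2) = bbox(i, 4) = INT_MAX;
    bbox(i, 1) = bbox(i, 3) = bbox(i, 5) = -1;
  }
  for (R_xlen_t s = 0; s < n; ++s) {
    int l = lab[s];
    if (l == 0) continue;
    int x = (int)(s % nx);
    int y = (int)((s / nx) % ny);
    int z = (int)(s / ((R_xlen_t)nx * ny));
    int i = l - 1;
    cx[i] += x; cy[i] += y; cz[i] += z;
    cnt[i] += 1.0;
    if (x < bbox(i, 0)) bbox(i, 0) = x;
    if (x > bbox(i, 1)) bbox(i, 1) = x;
    if (y < bbox(i, 2)) bbox(i, 2) = y;
    if (y > bbox(i, 3)) bbox(i, 3) = y;
    if (z < bbox(i, 4)) bbox(i, 4) = z;
    if (z > bbox(i, 5)) bbox(i, 5) = z;
  }
  NumericMatrix cent(k, 3);
  NumericVector count(k);
  for (int i = 0; i < k; ++i) {
    count[i] = cnt[i];
    if (cnt[i] > 0) {
      cent(i, 0) = cx[i] / cnt[i];
      cent(i, 1) = cy[i] / cnt[i];
      cent(i, 2) = cz[i] / cnt[i];
    }
  }
  return List::create(_["count"] = count, _["centroid"] = cent,
                      _["bbox"] = bbox);
}

// Extract the bounding-box crop of one labeled component as a 0/1
// integer array (avoids the large temporaries of an R-side subset).
// bbox holds 0-based inclusive xmin xmax ymin ymax zmin zmax.
// [[Rcpp::export(name = ".crop_component")]]
IntegerVector crop_component(IntegerVector lab, IntegerVector dims,
                             IntegerVector bbox, int comp) {
  const int nx = dims[0], ny = dims[1];
  const int cx0 = bbox[0], cx1 = bbox[1], cy0 = bbox[2], cy1 = bbox[3],
            cz0 = bbox[4], cz1 = bbox[5];
  const int sx = cx1 - cx0 + 1, sy = cy1 - cy0 + 1, sz = cz1 - cz0 + 1;
  IntegerVector out((R_xlen_t)sx * sy * sz);
  int* op = INTEGER(out);
  const int* lp = INTEGER(lab);
  R_xlen_t t = 0;
  for (int z = cz0; z <= cz1; ++z)
    for (int y = cy0; y <= cy1; ++y) {
      R_xlen_t base = (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
      for (int x = cx0; x <= cx1; ++x)
        op[t++] = lp[base + x] == comp ? 1 : 0;
    }
  out.attr("dim") = IntegerVector::create(sx, sy, sz);
  return out;
}

// Watertight quad mesh over the exposed voxel faces of mask != 0, split
// into triangles, with vertices merged on the voxel-corner grid.
// Vertices are voxel-unit coordinates (voxel centers at integers, so
// corners at half-integers). Taubin lambda/mu smoothing relaxes the
// staircase so that triangle areas estimate the smooth interface area.
// [[Rcpp::export(name = ".surface_mesh")]]
List surface_mesh(IntegerVector mask, IntegerVector dims,
                  double lambda, double mu, int iters) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  // corner grid is (nx+1) x (ny+1) x (nz+1)
  std::unordered_map<R_xlen_t, int> corner_id;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;  // 0-based triples
  const int face_dx[6] = {-1, 1, 0, 0, 0, 0};
  const int face_dy[6] = {0, 0, -1, 1, 0, 0};
  const int face_dz[6] = {0, 0, 0, 0, -1, 1};

  auto get_corner = [&](int cx2, int cy2, int cz2) -> int {
    // corner (i,j,k) with position (i-0.5, j-0.5, k-0.5)
    R_xlen_t key = (R_xlen_t)cx2 +
      (R_xlen_t)(nx + 1) * ((R_xlen_t)cy2 + (R_xlen_t)(ny + 1) * cz2);
    auto it = corner_id.find(key);
    if (it != corner_id.end()) return it->second;
    int id = (int)vx.size();
    corner_id.emplace(key, id);
    vx.push_back(cx2 - 0.5);
    vy.push_back(cy2 - 0.5);
    vz.push_back(cz2 - 0.5);
    return id;
  };

  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        if (mask[vidx(x, y, z, nx, ny)] == 0) continue;
        for (int f = 0; f < 6; ++f) {
          int xx = x + face_dx[f], yy = y + face_dy[f], zz = z + face_dz[f];
          bool outside = (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                          zz < 0 || zz >= nz);
          if (!outside && mask[vidx(xx, yy, zz, nx, ny)] != 0) continue;
          // exposed face: 4 corners of the voxel cube on that side
          int c[4];
          if (f < 2) {            // x faces
            int cx2 = x + (f == 1 ? 1 : 0);
            c[0] = get_corner(cx2, y,     z);
            c[1] = get_corner(cx2, y + 1, z);
            c[2] = get_corner(cx2, y + 1, z + 1);
            c[3] = get_corner(cx2, y,     z + 1);
          } else if (f < 4) {     // y faces
            int cy2 = y + (f == 3 ? 1 : 0);
            c[0] = get_corner(x,     cy2, z);
            c[1] = get_corner(x + 1, cy2, z);
            c[2] = get_corner(x + 1, cy2, z + 1);
            c[3] = get_corner(x,     cy2, z + 1);
          } else {                // z faces
            int cz2 = z + (f == 5 ? 1 : 0);
            c[0] = get_corner(x,     y,     cz2);
            c[1] = get_corner(x + 1, y,     cz2);
            c[2] = get_corner(x + 1, y + 1, cz2);
            c[3] = get_corner(x,     y + 1, cz2);
          }
          tri.push_back(c[0]); tri.push_back(c[1]); tri.push_back(c[2]);
          tri.push_back(c[0]); tri.push_back(c[2]); tri.push_back(c[3]);
        }
      }
    }
  }

  const int nv = (int)vx.size();
  const int nt = (int)tri.size() / 3;
  // vertex adjacency over triangle edges (CSR, deduplicated)
  std::vector<std::vector<int>> adj(nv);
  for (int t = 0; t < nt; ++t) {
    int a = tri[3 * t], b = tri[3 * t + 1], c = tri[3 * t + 2];
    adj[a].push_back(b); adj[a].push_back(c);
    adj[b].push_back(a); adj[b].push_back(c);
    adj[c].push_back(a); adj[c].push_back(b);
  }
  for (int i = 0; i < nv; ++i) {
    std::sort(adj[i].begin(), adj[i].end());
    adj[i].erase(std::unique(adj[i].begin(), adj[i].end()), adj[i].end());
  }

  // Taubin smoothing: shrink step lambda > 0, inflate step mu < 0
  std::vector<double> nx_(nv), ny_(nv), nz_(nv);
  for (int it = 0; it < iters; ++it) {
    for (int pass = 0; pass < 2; ++pass) {
      double f = (pass == 0) ? lambda : mu;
      for (int i = 0; i < nv; ++i) {
        const std::vector<int>& nb = adj[i];
        if (nb.empty()) { nx_[i] = vx[i]; ny_[i] = vy[i]; nz_[i] = vz[i]; continue; }
        double sx = 0, sy = 0, sz = 0;
        for (int j : nb) { sx += vx[j]; sy += vy[j]; sz += vz[j]; }
        double m = 1.0 / nb.size();
        nx_[i] = vx[i] + f * (sx * m - vx[i]);
        ny_[i] = vy[i] + f * (sy * m - vy[i]);
        nz_[i] = vz[i] + f * (sz * m - vz[i]);
      }
      vx.swap(nx_); vy.swap(ny_); vz.swap(nz_);
    }
  }

  double area = 0.0;
  for (int t = 0; t < nt; ++t) {
    int a = tri[3 * t], b = tri[3 * t + 1], c = tri[3 * t + 2];
    double ux = vx[b] - vx[a], uy = vy[b] - vy[a], uz = vz[b] - vz[a];
    double wx = vx[c] - vx[a], wy = vy[c] - vy[a], wz = vz[c] - vz[a];
    double cxv = uy * wz - uz * wy;
    double cyv = uz * wx - ux * wz;
    double czv = ux * wy - uy * wx;
    area += 0.5 * std::sqrt(cxv * cxv + cyv * cyv + czv * czv);
  }

  NumericMatrix verts(nv, 3);
  for (int i = 0; i < nv; ++i) {
    verts(i, 0) = vx[i]; verts(i, 1) = vy[i]; verts(i, 2) = vz[i];
  }
  IntegerMatrix tris(nt, 3);
  for (int t = 0; t < nt; ++t) {
    tris(t, 0) = tri[3 * t]; tris(t, 1) = tri[3 * t + 1]; tris(t, 2) = tri[3 * t + 2];
  }
  return List::create(_["vertices"] = verts, _["triangles"] = tris,
                      _["area"] = area);
}

// Minimum Euclidean distance between two 3D point sets (rows).
// Points of B are sorted by x; the inner scan prunes on the running best.
// [[Rcpp::export(name = ".min_point_distance")]]
double min_point_distance(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  if (na == 0 || nb == 0) stop("empty point set");
  std::vector<int> ord(nb);
  for (int i = 0; i < nb; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int i, int j) { return B(i, 0) < B(j, 0); });
  std::vector<double> bx(nb), by(nb), bz(nb);
  for (int i = 0; i < nb; ++i) {
    bx[i] = B(ord[i], 0); by[i] = B(ord[i], 1); bz[i] = B(ord[i], 2);
  }
  double best2 = R_PosInf;
  for (int i = 0; i < na; ++i) {
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    // position of ax in sorted bx
    int lo = (int)(std::lower_bound(bx.begin(), bx.end(), ax) - bx.begin());
    // scan outward
    int l = lo - 1, r = lo;
    while (l >= 0 || r < nb) {
      bool take_r;
      if (l < 0) take_r = true;
      else if (r >= nb) take_r = false;
      else take_r = (ax - bx[l]) > (bx[r] - ax);
      int j = take_r ? r : l;
      double dx = bx[j] - ax;
      if (dx * dx > best2) {
        if (take_r) { r = nb; } else { l = -1; }
        if (l < 0 && r >= nb) break;
        continue;
      }
      double dy = by[j] - ay, dz = bz[j] - az;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best2) best2 = d2;
      if (take_r) ++r; else --l;
    }
  }
  return std::sqrt(best2);
}

// Minimum Euclidean distance between two sets of unit cubes centered at
// the given points (the exact surface distance between two voxelized
// solids, restricted to their boundary voxels). Same sorted-x pruning
// as the point version; per-axis separation is max(0, |d| - 1).
// [[Rcpp::export(name = ".min_cube_distance")]]
double min_cube_distance(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  if (na == 0 || nb == 0) stop("empty voxel set");
  std::vector<int> ord(nb);
  for (int i = 0; i < nb; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int i, int j) { return B(i, 0) < B(j, 0); });
  std::vector<double> bx(nb), by(nb), bz(nb);
  for (int i = 0; i < nb; ++i) {
    bx[i] = B(ord[i], 0); by[i] = B(ord[i], 1); bz[i] = B(ord[i], 2);
  }
  auto axgap = [](double d) {
    double a = std::fabs(d) - 1.0;
    return a > 0 ? a : 0.0;
  };
  double best2 = R_PosInf;
  for (int i = 0; i < na; ++i) {
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    int lo = (int)(std::lower_bound(bx.begin(), bx.end(), ax) - bx.begin());
    int l = lo - 1, r = lo;
    while (l >= 0 || r < nb) {
      bool take_r;
      if (l < 0) take_r = true;
      else if (r >= nb) take_r = false;
      else take_r = (ax - bx[l]) > (bx[r] - ax);
      int j = take_r ? r : l;
      double dx = axgap(bx[j] - ax);
      if (dx * dx > best2) {
        if (take_r) { r = nb; } else { l = -1; }
        if (l < 0 && r >= nb) break;
        continue;
      }
      double dy = axgap(by[j] - ay), dz = axgap(bz[j] - az);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best2) best2 = d2;
      if (take_r) ++r; else --l;
    }
  }
  return std::sqrt(best2);
}

// Fill spheres into an existing integer volume (in place). Membership:
// voxel center inside or on the sphere. Centers/radii are voxel units.
// Spheres overwrite only background/cytoplasm labels (<= 1), so earlier
// granules win degenerate contact ties. Returns the number of voxels
// each sphere actually labeled (the rasterized volume ground truth).
// [[Rcpp::export(name = ".fill_spheres")]]
IntegerVector fill_spheres(IntegerVector vol, IntegerVector dims,
                           NumericMatrix centers, NumericVector radii,
                           IntegerVector labels) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector filled(centers.nrow());
  for (int s = 0; s < centers.nrow(); ++s) {
    double cx = centers(s, 0), cy = centers(s, 1), cz = centers(s, 2);
    double r = radii[s], r2 = r * r;
    int lab = labels[s];
    int nfill = 0;
    int x0 = std::max(0, (int)std::floor(cx - r)), x1 = std::min(nx - 1, (int)std::ceil(cx + r));
    int y0 = std::max(0, (int)std::floor(cy - r)), y1 = std::min(ny - 1, (int)std::ceil(cy + r));
    int z0 = std::max(0, (int)std::floor(cz - r)), z1 = std::min(nz - 1, (int)std::ceil(cz + r));
    for (int z = z0; z <= z1; ++z) {
      double dz = z - cz;
      for (int y = y0; y <= y1; ++y) {
        double dy = y - cy;
        double rem = r2 - dz * dz - dy * dy;
        if (rem < 0) continue;
        for (int x = x0; x <= x1; ++x) {
          double dx = x - cx;
          if (dx * dx <= rem) {
            R_xlen_t q = vidx(x, y, z, nx, ny);
            if (vol[q] <= 1) { vol[q] = lab; ++nfill; }
          }
        }
      }
    }
    filled[s] = nfill;
  }
  return filled;
}

// Fill a capsule (sphero-cylinder) with `label` where vol == 0.
// p0/p1 are the cylinder axis endpoints (sphere centers) in voxel units.
// [[Rcpp::export(name = ".fill_capsule")]]
IntegerVector fill_capsule(IntegerVector vol, IntegerVector dims,
                           NumericVector p0, NumericVector p1,
                           double radius, int label) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  double ax = p1[0] - p0[0], ay = p1[1] - p0[1], az = p1[2] - p0[2];
  double len2 = ax * ax + ay * ay + az * az;
  double r2 = radius * radius;
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        double wx = x - p0[0], wy = y - p0[1], wz = z - p0[2];
        double t = len2 > 0 ? (wx * ax + wy * ay + wz * az) / len2 : 0.0;
        t = std::max(0.0, std::min(1.0, t));
        double dx = wx - t * ax, dy = wy - t * ay, dz = wz - t * az;
        if (dx * dx + dy * dy + dz * dz <= r2) {
          R_xlen_t q = vidx(x, y, z, nx, ny);
          if (vol[q] == 0) vol[q] = label;
        }
      }
    }
  }
  return vol;
}

// Voxel-unit coordinates of voxels of mask != 0 with an exposed 6-face
// (the boundary voxels): the brute-force surface oracle works on these.
// [[Rcpp::export(name = ".boundary_voxels")]]
NumericMatrix boundary_voxels(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> px, py, pz;
  const int fdx[6] = {-1, 1, 0, 0, 0, 0};
  const int fdy[6] = {0, 0, -1, 1, 0, 0};
  const int fdz[6] = {0, 0, 0, 0, -1, 1};
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (mask[vidx(x, y, z, nx, ny)] == 0) continue;
        for (int f = 0; f < 6; ++f) {
          int xx = x + fdx[f], yy = y + fdy[f], zz = z + fdz[f];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz ||
              mask[vidx(xx, yy, zz, nx, ny)] == 0) {
            px.push_back(x); py.push_back(y); pz.push_back(z);
            break;
          }
        }
      }
  NumericMatrix out(px.size(), 3);
  for (size_t i = 0; i < px.size(); ++i) {
    out(i, 0) = px[i]; out(i, 1) = py[i]; out(i, 2) = pz[i];
  }
  return out;
}
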