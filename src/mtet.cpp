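#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Iso-surface of a scalar 3D array by marching tetrahedra on the Kuhn
// (6-tetrahedra) subdivision of each voxel cell. The subdivision is
// translation invariant and face-compatible between neighbouring cells, so
// the emitted triangle mesh is watertight whenever the iso-surface does not
// touch the array border. Sample points sit at voxel centres:
//   x_i = origin_x + (i + 0.5) * voxel.
// Triangles are wound so normals point from values above `iso` (inside)
// towards values below (outside).

struct Vec3 {
  double x, y, z;
};

static inline Vec3 vsub(const Vec3& a, const Vec3& b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline Vec3 vcross(const Vec3& a, const Vec3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double vdot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

// [[Rcpp::export(name = ".marching_tets")]]
List marching_tets(NumericVector vals, IntegerVector dims, double iso,
                   double voxel, NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  const uint64_t ntot = (uint64_t)nx * ny * nz;

  // the 6 Kuhn tetrahedra: vertex bit codes (x=1, y=2, z=4)
  const int axbit[3] = {1, 2, 4};
  const int perms[6][3] = {{0, 1, 2}, {0, 2, 1}, {1, 0, 2},
                           {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};
  int tets[6][4];
  for (int p = 0; p < 6; p++) {
    tets[p][0] = 0;
    tets[p][1] = axbit[perms[p][0]];
    tets[p][2] = tets[p][1] | axbit[perms[p][1]];
    tets[p][3] = 7;
  }

  std::unordered_map<uint64_t, int> edge_vert;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;

  uint64_t gidx[8];
  double gval[8];
  Vec3 gpos[8];

  auto edge_point = [&](int a, int b) -> int {
    uint64_t ia = gidx[a], ib = gidx[b];
    if (ia > ib) std::swap(ia, ib);
    uint64_t key = ia * ntot + ib;
    auto it = edge_vert.find(key);
    if (it != edge_vert.end()) return it->second;
    double va = gval[a], vb = gval[b];
    double t = (iso - va) / (vb - va);
    if (t < 0) t = 0;
    if (t > 1) t = 1;
    Vec3 p = {gpos[a].x + t * (gpos[b].x - gpos[a].x),
              gpos[a].y + t * (gpos[b].y - gpos[a].y),
              gpos[a].z + t * (gpos[b].z - gpos[a].z)};
    int id = (int)vx.size();
    vx.push_back(p.x);
    vy.push_back(p.y);
    vz.push_back(p.z);
    edge_vert[key] = id;
    return id;
  };

  auto emit = [&](int i1, int i2, int i3, const Vec3& outdir) {
    Vec3 p1 = {vx[i1], vy[i1], vz[i1]};
    Vec3 p2 = {vx[i2], vy[i2], vz[i2]};
    Vec3 p3 = {vx[i3], vy[i3], vz[i3]};
    Vec3 n = vcross(vsub(p2, p1), vsub(p3, p1));
    if (vdot(n, outdir) < 0) std::swap(i2, i3);
    tri.push_back(i1);
    tri.push_back(i2);
    tri.push_back(i3);
  };

  for (int cz = 0; cz < nz - 1; cz++)
    for (int cy = 0; cy < ny - 1; cy++)
      for (int cx = 0; cx < nx - 1; cx++) {
        bool any_in = false, any_out = false;
        for (int b = 0; b < 8; b++) {
          int x = cx + (b & 1), y = cy + ((b >> 1) & 1), z = cz + ((b >> 2) & 1);
          uint64_t idx = (uint64_t)z * sxy + (uint64_t)y * nx + x;
          gidx[b] = idx;
          gval[b] = vals[idx];
          gpos[b] = {origin[0] + (x + 0.5) * voxel,
                     origin[1] + (y + 0.5) * voxel,
                     origin[2] + (z + 0.5) * voxel};
          if (gval[b] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; t++) {
          int vi[4], ni = 0;
          int inside[4], outside[4];
          int nin = 0, nout = 0;
          for (int k = 0; k < 4; k++) {
            vi[k] = tets[t][k];
            if (gval[vi[k]] > iso) inside[nin++] = vi[k];
            else outside[nout++] = vi[k];
          }
          (void)ni;
          if (nin == 0 || nin == 4) continue;

          Vec3 cin = {0, 0, 0}, cout = {0, 0, 0};
          for (int k = 0; k < nin; k++) {
            cin.x += gpos[inside[k]].x; cin.y += gpos[inside[k]].y;
            cin.z += gpos[inside[k]].z;
          }
          for (int k = 0; k < nout; k++) {
            cout.x += gpos[outside[k]].x; cout.y += gpos[outside[k]].y;
            cout.z += gpos[outside[k]].z;
          }
          cin.x /= nin; cin.y /= nin; cin.z /= nin;
          cout.x /= nout; cout.y /= nout; cout.z /= nout;
          Vec3 outdir = vsub(cout, cin);

          if (nin == 1) {
            int a = inside[0];
            emit(edge_point(a, outside[0]), edge_point(a, outside[1]),
                 edge_point(a, outside[2]), outdir);
          } else if (nin == 3) {
            int a = outside[0];
            emit(edge_point(a, inside[0]), edge_point(a, inside[1]),
                 edge_point(a, inside[2]), outdir);
          } else {  // 2 in, 2 out: quad
            int a = inside[0], b = inside[1], c = outside[0], d = outside[1];
            int pac = edge_point(a, c), pad = edge_point(a, d);
            int pbd = edge_point(b, d), pbc = edge_point(b, c);
            emit(pac, pad, pbd, outdir);
            emit(pac, pbd, pbc, outdir);
          }
        }
      }

  int nv = (int)vx.size(), nt = (int)tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; i++) {
    V(i, 0) = vx[i];
    V(i, 1) = vy[i];
    V(i, 2) = vz[i];
  }
  IntegerMatrix T(nt, 3);
  for (int i = 0; i < nt; i++) {
    T(i, 0) = tri[3 * i] + 1;
    T(i, 1) = tri[3 * i + 1] + 1;
    T(i, 2) = tri[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["triangles"] = T);
}
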