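#include <Rcpp.h>
#include <vector>
#include <queue>

using namespace Rcpp;

// Connected-component labelling of a 3D logical array (column major),
// 6- or 26-connectivity. Returns integer array, 0 = background, components
// numbered 1..k in decreasing voxel count.
// [[Rcpp::export(name = ".label_components3d")]]
IntegerVector label_components3d(LogicalVector mask, IntegerVector dims,
                                 int connectivity = 6) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  R_xlen_t ntot = sz * nz;
  IntegerVector lab(ntot);

  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dx, dy, dz});
      }

  int next = 0;
  std::vector<R_xlen_t> sizes;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < ntot; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    next++;
    R_xlen_t csize = 0;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t cur = q.front();
      q.pop();
      csize++;
      int cz = (int)(cur / sz);
      int rem = (int)(cur % sz);
      int cy = rem / nx, cx = rem % nx;
      for (size_t o = 0; o < offs.size(); o++) {
        int x = cx + offs[o][0], y = cy + offs[o][1], z = cz + offs[o][2];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        R_xlen_t idx = (R_xlen_t)z * sz + (R_xlen_t)y * nx + x;
        if (mask[idx] && lab[idx] == 0) {
          lab[idx] = next;
          q.push(idx);
        }
      }
    }
    sizes.push_back(csize);
  }

  // relabel by decreasing size
  std::vector<int> order(next);
  for (int i = 0; i < next; i++) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return sizes[a] > sizes[b]; });
  std::vector<int> remap(next + 1, 0);
  for (int r = 0; r < next; r++) remap[order[r] + 1] = r + 1;
  for (R_xlen_t s = 0; s < ntot; s++)
    if (lab[s]) lab[s] = remap[lab[s]];

  lab.attr("dim") = dims;
  return lab;
}
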