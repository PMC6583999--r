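#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Solid voxelization of a closed triangle mesh by z-column ray parity.
// For every voxel-centre column (x_i, y_j) the z-values where the column
// pierces the surface are collected; voxel centres between an odd and the
// next even crossing are inside. Voxel centres are jittered by a tiny,
// deterministic epsilon to avoid edge/vertex coincidences.

// [[Rcpp::export(name = ".voxelize_mesh")]]
LogicalVector voxelize_mesh(NumericMatrix verts, IntegerMatrix faces,
                            NumericVector origin, NumericVector spacing,
                            IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  const double jit = 1e-6 * hx + 1e-9;

  std::vector< std::vector<double> > cross((R_xlen_t)nx * ny);

  const int nf = faces.nrow();
  for (int t = 0; t < nf; ++t) {
    const int a = faces(t, 0) - 1, b = faces(t, 1) - 1, c = faces(t, 2) - 1;
    const double ax = verts(a,0), ay = verts(a,1), az = verts(a,2);
    const double bx = verts(b,0), by = verts(b,1), bz = verts(b,2);
    const double cx = verts(c,0), cy = verts(c,1), cz = verts(c,2);

    double xmin = std::min(ax, std::min(bx, cx)), xmax = std::max(ax, std::max(bx, cx));
    double ymin = std::min(ay, std::min(by, cy)), ymax = std::max(ay, std::max(by, cy));
    int i0 = (int)std::ceil((xmin - ox - jit) / hx);
    int i1 = (int)std::floor((xmax - ox - jit) / hx);
    int j0 = (int)std::ceil((ymin - oy - jit) / hy);
    int j1 = (int)std::floor((ymax - oy - jit) / hy);
    if (i0 < 0) i0 = 0; if (i1 >= nx) i1 = nx - 1;
    if (j0 < 0) j0 = 0; if (j1 >= ny) j1 = ny - 1;

    const double d = (bx - ax) * (cy - ay) - (cx - ax) * (by - ay);
    if (d == 0.0) continue; // triangle vertical in z: no parity contribution

    for (int j = j0; j <= j1; ++j) {
      const double py = oy + j * hy + jit;
      for (int i = i0; i <= i1; ++i) {
        const double px = ox + i * hx + jit;
        const double w0 = ((bx - px) * (cy - py) - (cx - px) * (by - py)) / d;
        const double w1 = ((cx - px) * (ay - py) - (ax - px) * (cy - py)) / d;
        const double w2 = 1.0 - w0 - w1;
        if (w0 < 0.0 || w1 < 0.0 || w2 < 0.0) continue;
        cross[i + (R_xlen_t)nx * j].push_back(w0 * az + w1 * bz + w2 * cz);
      }
    }
  }

  LogicalVector out((R_xlen_t)nx * ny * nz, FALSE);
  int* O = LOGICAL(out);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      std::vector<double>& zs = cross[i + (R_xlen_t)nx * j];
      if (zs.empty()) continue;
      std::sort(zs.begin(), zs.end());
      // pair consecutive crossings
      for (size_t q = 0; q + 1 < zs.size(); q += 2) {
        int k0 = (int)std::ceil((zs[q] - oz) / hz);
        int k1 = (int)std::floor((zs[q + 1] - oz) / hz);
        if (k0 < 0) k0 = 0; if (k1 >= nz) k1 = nz - 1;
        for (int k = k0; k <= k1; ++k)
          O[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = TRUE;
      }
    }
  out.attr("dim") = dims;
  return out;
}
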