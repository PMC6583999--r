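#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Marching tetrahedra over a regular scalar grid.
// Each cell is split into a fan of 6 tetrahedra around the 0-6 main
// diagonal (VTK hexahedron corner ordering), which tessellates consistently
// across neighbouring cells, so the extracted surface is watertight
// wherever the iso-level crosses the field in the grid interior. Vertices
// are placed on tet edges by linear interpolation; triangles are oriented
// with the normal pointing from the inside (value >= level) outward.

// VTK hexahedron ordering: bottom ring 0..3 counter-clockwise, top 4..7
static const int CORNER[8][3] = {
  {0,0,0}, {1,0,0}, {1,1,0}, {0,1,0},
  {0,0,1}, {1,0,1}, {1,1,1}, {0,1,1}
};

// hexagonal fan of tets around the 0-6 diagonal (cycle 1,2,3,7,4,5)
static const int TET[6][4] = {
  {0, 6, 1, 2}, {0, 6, 2, 3}, {0, 6, 3, 7},
  {0, 6, 7, 4}, {0, 6, 4, 5}, {0, 6, 5, 1}
};

struct VBuf {
  std::vector<double> x, y, z;
  void tri(const double* a, const double* b, const double* c,
           const double* dir_from, const double* dir_to) {
    // orient so the normal points from inside (dir_from) to outside (dir_to)
    double u[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
    double v[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
    double n[3] = {u[1]*v[2]-u[2]*v[1], u[2]*v[0]-u[0]*v[2], u[0]*v[1]-u[1]*v[0]};
    double d[3] = {dir_to[0]-dir_from[0], dir_to[1]-dir_from[1],
                   dir_to[2]-dir_from[2]};
    bool flip = n[0]*d[0] + n[1]*d[1] + n[2]*d[2] < 0;
    const double* p1 = flip ? c : b;
    const double* p2 = flip ? b : c;
    x.push_back(a[0]);  y.push_back(a[1]);  z.push_back(a[2]);
    x.push_back(p1[0]); y.push_back(p1[1]); z.push_back(p1[2]);
    x.push_back(p2[0]); y.push_back(p2[1]); z.push_back(p2[2]);
  }
};

static inline void interp(double lvl,
                          const double* p0, double v0,
                          const double* p1, double v1,
                          double* out) {
  double t = (v1 == v0) ? 0.5 : (lvl - v0) / (v1 - v0);
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  out[0] = p0[0] + t * (p1[0] - p0[0]);
  out[1] = p0[1] + t * (p1[1] - p0[1]);
  out[2] = p0[2] + t * (p1[2] - p0[2]);
}

// [[Rcpp::export(name = ".mt_isosurface")]]
List mt_isosurface(NumericVector field, IntegerVector dims, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* f = REAL(field);
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;

  VBuf vb;
  double P[8][3], V[8];

  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        R_xlen_t base = i * sx + j * sy + k * sz;
        bool any_hi = false, any_lo = false;
        for (int c = 0; c < 8; ++c) {
          V[c] = f[base + CORNER[c][0] * sx + CORNER[c][1] * sy + CORNER[c][2] * sz];
          P[c][0] = i + CORNER[c][0];
          P[c][1] = j + CORNER[c][1];
          P[c][2] = k + CORNER[c][2];
          if (V[c] >= level) any_hi = true; else any_lo = true;
        }
        if (!any_hi || !any_lo) continue;

        for (int t = 0; t < 6; ++t) {
          int ids[4] = {TET[t][0], TET[t][1], TET[t][2], TET[t][3]};
          bool in[4];
          int nin = 0;
          for (int q = 0; q < 4; ++q) {
            in[q] = V[ids[q]] >= level;
            if (in[q]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;

          int ins[3], outs[3], mi = 0, mo = 0;
          for (int q = 0; q < 4; ++q) {
            if (in[q]) ins[mi++] = ids[q]; else outs[mo++] = ids[q];
          }
          double cin[3] = {0, 0, 0}, cout[3] = {0, 0, 0};
          for (int q = 0; q < mi; ++q)
            for (int d = 0; d < 3; ++d) cin[d] += P[ins[q]][d] / mi;
          for (int q = 0; q < mo; ++q)
            for (int d = 0; d < 3; ++d) cout[d] += P[outs[q]][d] / mo;

          if (nin == 1) {
            double e0[3], e1[3], e2[3];
            interp(level, P[ins[0]], V[ins[0]], P[outs[0]], V[outs[0]], e0);
            interp(level, P[ins[0]], V[ins[0]], P[outs[1]], V[outs[1]], e1);
            interp(level, P[ins[0]], V[ins[0]], P[outs[2]], V[outs[2]], e2);
            vb.tri(e0, e1, e2, cin, cout);
          } else if (nin == 3) {
            double e0[3], e1[3], e2[3];
            interp(level, P[ins[0]], V[ins[0]], P[outs[0]], V[outs[0]], e0);
            interp(level, P[ins[1]], V[ins[1]], P[outs[0]], V[outs[0]], e1);
            interp(level, P[ins[2]], V[ins[2]], P[outs[0]], V[outs[0]], e2);
            vb.tri(e0, e1, e2, cin, cout);
          } else { // nin == 2: quad split into two triangles
            double e00[3], e01[3], e10[3], e11[3];
            interp(level, P[ins[0]], V[ins[0]], P[outs[0]], V[outs[0]], e00);
            interp(level, P[ins[0]], V[ins[0]], P[outs[1]], V[outs[1]], e01);
            interp(level, P[ins[1]], V[ins[1]], P[outs[0]], V[outs[0]], e10);
            interp(level, P[ins[1]], V[ins[1]], P[outs[1]], V[outs[1]], e11);
            vb.tri(e00, e01, e10, cin, cout);
            vb.tri(e01, e11, e10, cin, cout);
          }
        }
      }

  const R_xlen_t nv = (R_xlen_t)vb.x.size();
  NumericMatrix verts(nv, 3);
  for (R_xlen_t q = 0; q < nv; ++q) {
    verts(q, 0) = vb.x[q]; verts(q, 1) = vb.y[q]; verts(q, 2) = vb.z[q];
  }
  IntegerMatrix faces(nv / 3, 3);
  for (R_xlen_t q = 0; q < nv / 3; ++q) {
    faces(q, 0) = 3 * q + 1; faces(q, 1) = 3 * q + 2; faces(q, 2) = 3 * q + 3;
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}
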