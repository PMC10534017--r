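// Affine resampling of 3D scalar grids. Used for isotropic resampling of
// CT volumes/masks and for geometric augmentation (rotation/scaling).
// Physical mapping: p_out = origin_out + (i_out * spacing_out);
// source continuous index = A * (p_out - center) + center_src, expressed
// directly in voxel units by the caller.

#include <Rcpp.h>
using namespace Rcpp;

static inline double sample_trilinear(const double* v, int nx, int ny, int nz,
                                      double x, double y, double z, double fill) {
  if (x < -0.5 || y < -0.5 || z < -0.5 || x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5)
    return fill;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double acc = 0.0;
  for (int dz = 0; dz <= 1; ++dz)
    for (int dy = 0; dy <= 1; ++dy)
      for (int dx = 0; dx <= 1; ++dx) {
        int xi = x0 + dx, yi = y0 + dy, zi = z0 + dz;
        double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
        if (w == 0.0) continue;
        double val;
        if (xi < 0 || yi < 0 || zi < 0 || xi >= nx || yi >= ny || zi >= nz)
          val = fill;
        else
          val = v[xi + (size_t)nx * (yi + (size_t)ny * zi)];
        acc += w * val;
      }
  return acc;
}

// Map each output voxel index (i,j,k) through the 3x4 voxel-space affine
// [A | t]: src = A %*% c(i,j,k) + t, then interpolate.
// method: 0 = trilinear, 1 = nearest neighbour.
// clamp: clamp source coordinates to the grid (edge replication) instead
// of filling with `fill` — appropriate for resampling, not for padding.
// [[Rcpp::export(name = ".affine_sample")]]
NumericVector affine_sample(NumericVector input, IntegerVector out_dim,
                            NumericMatrix affine, int method, double fill,
                            bool clamp) {
  IntegerVector din = input.attr("dim");
  if (din.size() != 3) stop("input must be a 3D array");
  if (affine.nrow() != 3 || affine.ncol() != 4) stop("affine must be 3x4");
  const int nx = din[0], ny = din[1], nz = din[2];
  const int mx = out_dim[0], my = out_dim[1], mz = out_dim[2];
  const double* v = REAL(input);
  NumericVector out((size_t)mx * my * mz);
  out.attr("dim") = IntegerVector::create(mx, my, mz);
  double* o = REAL(out);
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i) {
        double sx = affine(0, 0) * i + affine(0, 1) * j + affine(0, 2) * k + affine(0, 3);
        double sy = affine(1, 0) * i + affine(1, 1) * j + affine(1, 2) * k + affine(1, 3);
        double sz = affine(2, 0) * i + affine(2, 1) * j + affine(2, 2) * k + affine(2, 3);
        if (clamp) {
          sx = std::min(std::max(sx, 0.0), (double)(nx - 1));
          sy = std::min(std::max(sy, 0.0), (double)(ny - 1));
          sz = std::min(std::max(sz, 0.0), (double)(nz - 1));
        }
        double val;
        if (method == 1) {
          int xi = (int)std::lround(sx), yi = (int)std::lround(sy), zi = (int)std::lround(sz);
          if (xi < 0 || yi < 0 || zi < 0 || xi >= nx || yi >= ny || zi >= nz)
            val = fill;
          else
            val = v[xi + (size_t)nx * (yi + (size_t)ny * zi)];
        } else {
          val = sample_trilinear(v, nx, ny, nz, sx, sy, sz, fill);
        }
        o[i + (size_t)mx * (j + (size_t)my * k)] = val;
      }
  return out;
}
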