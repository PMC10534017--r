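// 3D convolution / pooling primitives for the U-Net encoder.
// Layout convention: channel-first arrays with dim = (C, X, Y, Z),
// column-major as stored by R. Convolutions are 3x3x3, stride 1,
// zero-padded ("same"); implemented as chunked im2col + sgemm so the
// heavy lifting runs through BLAS in single precision.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// weights dim: (Cout, Cin, 3, 3, 3); bias length Cout
// [[Rcpp::export(name = ".conv3d_same")]]
NumericVector conv3d_same(NumericVector input, NumericVector weights,
                          NumericVector bias, bool relu) {
  IntegerVector din = input.attr("dim");
  if (din.size() != 4) stop("input must be a 4D (C,X,Y,Z) array");
  const int Cin = din[0], NX = din[1], NY = din[2], NZ = din[3];
  IntegerVector dw = weights.attr("dim");
  if (dw.size() != 5 || dw[1] != Cin || dw[2] != 3 || dw[3] != 3 || dw[4] != 3)
    stop("weights must be (Cout, Cin, 3, 3, 3) with Cin matching input");
  const int Cout = dw[0];
  if (bias.size() != Cout) stop("bias length must equal Cout");

  const int K = Cin * 27;
  // weight matrix: Cout x K, K ordered as (c, kx, ky, kz) fastest-first
  arma::fmat W(Cout, K);
  for (int kz = 0; kz < 3; ++kz)
    for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx)
        for (int c = 0; c < Cin; ++c) {
          int col = c + Cin * (kx + 3 * (ky + 3 * kz));
          for (int co = 0; co < Cout; ++co)
            W(co, col) = (float)weights[co + Cout * (c + Cin * (kx + 3 * (ky + 3 * kz)))];
        }
  arma::fvec b(Cout);
  for (int co = 0; co < Cout; ++co) b[co] = (float)bias[co];

  // single-precision copy of the input
  std::vector<float> in((size_t)Cin * NX * NY * NZ);
  for (size_t i = 0; i < in.size(); ++i) in[i] = (float)input[i];

  NumericVector out((size_t)Cout * NX * NY * NZ);
  out.attr("dim") = IntegerVector::create(Cout, NX, NY, NZ);

  // chunk over z-slabs to bound im2col memory
  const size_t plane = (size_t)NX * NY;
  int slab = std::max(1, (int)(16 * 1024 * 1024 / (sizeof(float) * K * plane) + 1));
  slab = std::min(slab, NZ);

  arma::fmat col(K, slab * plane);
  for (int z0 = 0; z0 < NZ; z0 += slab) {
    const int nz = std::min(slab, NZ - z0);
    const size_t ncol = (size_t)nz * plane;
    if ((size_t)col.n_cols != ncol) col.set_size(K, ncol);
    col.zeros();
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          const int krow0 = Cin * ((dx + 1) + 3 * ((dy + 1) + 3 * (dz + 1)));
          for (int z = 0; z < nz; ++z) {
            const int sz = z0 + z + dz;
            if (sz < 0 || sz >= NZ) continue;
            for (int y = 0; y < NY; ++y) {
              const int sy = y + dy;
              if (sy < 0 || sy >= NY) continue;
              const int xlo = std::max(0, -dx), xhi = std::min(NX, NX - dx);
              if (xhi <= xlo) continue;
              const float* src = &in[(size_t)Cin * ((size_t)xlo + dx + NX * (sy + (size_t)NY * sz))];
              float* dst = col.colptr((size_t)xlo + NX * (y + (size_t)NY * z)) + krow0;
              for (int x = xlo; x < xhi; ++x) {
                std::memcpy(dst, src, sizeof(float) * Cin);
                src += Cin;
                dst += K;
              }
            }
          }
        }
    arma::fmat res = W * col;             // Cout x ncol
    res.each_col() += b;
    if (relu) res.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    double* optr = REAL(out) + (size_t)Cout * plane * z0;
    const float* rptr = res.memptr();
    const size_t n = (size_t)Cout * ncol;
    for (size_t i = 0; i < n; ++i) optr[i] = (double)rptr[i];
  }
  return out;
}

// 2x2x2 max pooling, stride 2; dims must be even
// [[Rcpp::export(name = ".maxpool3d")]]
NumericVector maxpool3d(NumericVector input) {
  IntegerVector din = input.attr("dim");
  if (din.size() != 4) stop("input must be a 4D (C,X,Y,Z) array");
  const int C = din[0], NX = din[1], NY = din[2], NZ = din[3];
  if (NX % 2 || NY % 2 || NZ % 2) stop("spatial dims must be even for 2x2x2 pooling");
  const int MX = NX / 2, MY = NY / 2, MZ = NZ / 2;
  NumericVector out((size_t)C * MX * MY * MZ);
  out.attr("dim") = IntegerVector::create(C, MX, MY, MZ);
  const double* in = REAL(input);
  double* o = REAL(out);
  for (int z = 0; z < MZ; ++z)
    for (int y = 0; y < MY; ++y)
      for (int x = 0; x < MX; ++x) {
        double* cell = &o[(size_t)C * (x + MX * (y + (size_t)MY * z))];
        for (int c = 0; c < C; ++c) cell[c] = -HUGE_VAL;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              const double* src =
                  &in[(size_t)C * ((2 * x + dx) + NX * ((2 * y + dy) + (size_t)NY * (2 * z + dz)))];
              for (int c = 0; c < C; ++c)
                if (src[c] > cell[c]) cell[c] = src[c];
            }
      }
  return out;
}
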