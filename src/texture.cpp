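// Texture-count matrices on discretized ROIs.
// Input: 3D integer array of bin indices 1..ng, with 0 marking voxels
// outside the mask. Directions are integer voxel offsets.

#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Symmetric grey-level co-occurrence counts at the given offset.
// [[Rcpp::export(name = ".glcm_counts")]]
IntegerMatrix glcm_counts(IntegerVector bins, int ng, IntegerVector offset) {
  IntegerVector d = bins.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const int dx = offset[0], dy = offset[1], dz = offset[2];
  IntegerMatrix M(ng, ng);
  const int* b = INTEGER(bins);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int g1 = b[x + (size_t)nx * (y + (size_t)ny * z)];
        if (g1 == 0) continue;
        int x2 = x + dx, y2 = y + dy, z2 = z + dz;
        if (x2 < 0 || y2 < 0 || z2 < 0 || x2 >= nx || y2 >= ny || z2 >= nz) continue;
        int g2 = b[x2 + (size_t)nx * (y2 + (size_t)ny * z2)];
        if (g2 == 0) continue;
        M(g1 - 1, g2 - 1) += 1;
        M(g2 - 1, g1 - 1) += 1;
      }
  return M;
}

// Run-length counts along the given direction; rows = grey level,
// columns = run length (up to the longest possible run).
// [[Rcpp::export(name = ".glrlm_counts")]]
IntegerMatrix glrlm_counts(IntegerVector bins, int ng, IntegerVector offset) {
  IntegerVector d = bins.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const int dx = offset[0], dy = offset[1], dz = offset[2];
  const int* b = INTEGER(bins);
  int maxlen = std::max(nx, std::max(ny, nz));
  IntegerMatrix R(ng, maxlen);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int g = b[x + (size_t)nx * (y + (size_t)ny * z)];
        if (g == 0) continue;
        // run start: predecessor along -offset absent or different
        int xp = x - dx, yp = y - dy, zp = z - dz;
        if (xp >= 0 && yp >= 0 && zp >= 0 && xp < nx && yp < ny && zp < nz &&
            b[xp + (size_t)nx * (yp + (size_t)ny * zp)] == g)
          continue;
        int len = 1;
        int xn = x + dx, yn = y + dy, zn = z + dz;
        while (xn >= 0 && yn >= 0 && zn >= 0 && xn < nx && yn < ny && zn < nz &&
               b[xn + (size_t)nx * (yn + (size_t)ny * zn)] == g) {
          ++len;
          xn += dx; yn += dy; zn += dz;
        }
        R(g - 1, len - 1) += 1;
      }
  return R;
}

// Size-zone counts under 26-connectivity; rows = grey level,
// columns = zone size (up to the ROI voxel count).
// [[Rcpp::export(name = ".glszm_counts")]]
IntegerMatrix glszm_counts(IntegerVector bins, int ng) {
  IntegerVector d = bins.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const int* b = INTEGER(bins);
  const size_t n = (size_t)nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<std::pair<int, int>> zones;  // (grey level, size)
  int maxsize = 0;
  for (size_t s = 0; s < n; ++s) {
    if (seen[s] || b[s] == 0) continue;
    int g = b[s];
    int size = 0;
    std::queue<size_t> q;
    q.push(s);
    seen[s] = 1;
    while (!q.empty()) {
      size_t cur = q.front(); q.pop();
      ++size;
      int x = cur % nx, y = (cur / nx) % ny, z = cur / ((size_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int x2 = x + dx, y2 = y + dy, z2 = z + dz;
            if (x2 < 0 || y2 < 0 || z2 < 0 || x2 >= nx || y2 >= ny || z2 >= nz) continue;
            size_t idx = x2 + (size_t)nx * (y2 + (size_t)ny * z2);
            if (!seen[idx] && b[idx] == g) {
              seen[idx] = 1;
              q.push(idx);
            }
          }
    }
    zones.emplace_back(g, size);
    if (size > maxsize) maxsize = size;
  }
  IntegerMatrix S(ng, std::max(maxsize, 1));
  for (auto& z : zones) S(z.first - 1, z.second - 1) += 1;
  return S;
}
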