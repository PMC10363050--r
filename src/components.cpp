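#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labelling, 26-connectivity, BFS in raster order so
// label numbering is deterministic. Returns an integer array of the same
// dimension with a "sizes" attribute (voxel count per label).
// [[Rcpp::export(name = ".labelComponentsCpp")]]
IntegerVector labelComponentsCpp(LogicalVector mask) {
  IntegerVector dim = mask.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dim;
  std::vector<int> sizes;
  std::vector<size_t> queue;
  int cur = 0;
  for (size_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start]) continue;
    ++cur;
    int count = 0;
    queue.clear();
    queue.push_back(start);
    lab[start] = cur;
    while (!queue.empty()) {
      size_t idx = queue.back();
      queue.pop_back();
      ++count;
      int z = idx / ((size_t)nx * ny);
      int rem = idx % ((size_t)nx * ny);
      int y = rem / nx, x = rem % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int X = x + dx, Y = y + dy, Z = z + dz;
            if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz)
              continue;
            size_t j = (size_t)Z * nx * ny + (size_t)Y * nx + X;
            if (mask[j] && !lab[j]) {
              lab[j] = cur;
              queue.push_back(j);
            }
          }
    }
    sizes.push_back(count);
  }
  lab.attr("sizes") = wrap(sizes);
  return lab;
}

// CRC32 (PNG/zlib polynomial) of a raw vector, for the 16-bit PNG writer.
// [[Rcpp::export(name = ".crc32Cpp")]]
double crc32Cpp(RawVector data) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[i] = c;
    }
    init = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFu);
}
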