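// Connected-component labeling of a 3D binary array by flood fill.
// Labels are assigned in lexicographic scan order (x fastest), so the
// labeling is deterministic. Used both as the in-memory labeler on whole
// small volumes and as the per-brick kernel of the brick-streaming
// two-pass labeling implemented in R.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t N = (size_t)nx * ny * nz;
  std::vector<int> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int nzc = (dx != 0) + (dy != 0) + (dz != 0);
        if (nzc == 0) continue;
        if (connectivity == 6 && nzc != 1) continue;
        off.push_back(dx); off.push_back(dy); off.push_back(dz);
      }

  IntegerVector lab(N, 0);
  std::vector<int> stack;
  int next = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t i = (size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z);
        if (!mask[i] || lab[i]) continue;
        ++next;
        lab[i] = next;
        stack.clear();
        stack.push_back(x); stack.push_back(y); stack.push_back(z);
        while (!stack.empty()) {
          int cz = stack.back(); stack.pop_back();
          int cy = stack.back(); stack.pop_back();
          int cx = stack.back(); stack.pop_back();
          for (size_t k = 0; k < off.size(); k += 3) {
            int qx = cx + off[k], qy = cy + off[k + 1], qz = cz + off[k + 2];
            if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz) continue;
            size_t j = (size_t)qx + (size_t)nx * ((size_t)qy + (size_t)ny * qz);
            if (!mask[j] || lab[j]) continue;
            lab[j] = next;
            stack.push_back(qx); stack.push_back(qy); stack.push_back(qz);
          }
        }
      }
  lab.attr("dim") = dims;
  return lab;
}
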