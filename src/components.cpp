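#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// Label connected components of a 3-D logical lattice (x, y, t).
// connectivity: 6 (faces), 18 (faces+edges) or 26 (all neighbours).
// Returns integer labels (0 = background), labelled in scan order.
// [[Rcpp::export(name = ".label_components_3d")]]
IntegerVector label_components_3d(LogicalVector vol, IntegerVector dims,
                                  int connectivity = 6) {
  const int nx = dims[0], ny = dims[1], nt = dims[2];
  const int n = nx * ny * nt;
  IntegerVector labels(n, 0);

  std::vector<std::array<int, 3>> offs;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs.push_back({dx, dy, dz});
      }

  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (!vol[i] || vol[i] == NA_LOGICAL || labels[i] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back(i);
    labels[i] = next;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int z = cur / (nx * ny);
      int rem = cur % (nx * ny);
      int y = rem / nx;
      int x = rem % nx;
      for (const auto &o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nt)
          continue;
        int j = xx + nx * (yy + ny * zz);
        if (vol[j] && vol[j] != NA_LOGICAL && labels[j] == 0) {
          labels[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return labels;
}

// Maximum component extent and maximum value above threshold, for
// permutation nulls: avoids materialising labels in R per permutation.
// [[Rcpp::export(name = ".max_cluster_stats")]]
NumericVector max_cluster_stats(NumericVector stat, IntegerVector dims,
                                double threshold, int connectivity = 6) {
  const int n = stat.size();
  LogicalVector supra(n);
  double max_peak = 0.0;
  for (int i = 0; i < n; ++i) {
    bool s = !ISNAN(stat[i]) && stat[i] > threshold;  // +Inf sentinels count
    supra[i] = s;
    if (!ISNAN(stat[i]) && stat[i] > max_peak) max_peak = stat[i];
  }
  IntegerVector lab = label_components_3d(supra, dims, connectivity);
  int nlab = 0;
  for (int i = 0; i < n; ++i) if (lab[i] > nlab) nlab = lab[i];
  std::vector<int> ext(nlab + 1, 0);
  for (int i = 0; i < n; ++i) if (lab[i] > 0) ++ext[lab[i]];
  int max_ext = 0;
  for (int k = 1; k <= nlab; ++k) if (ext[k] > max_ext) max_ext = ext[k];
  return NumericVector::create((double)max_ext, max_peak);
}
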