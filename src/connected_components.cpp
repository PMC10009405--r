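#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labelling of a logical volume by breadth-first
// search. connectivity: 6 (faces), 18 (faces+edges) or 26 (full
// neighborhood). Returns integer labels (0 = background) in the same
// flattened (column-major x,y,z) order as the input.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t V = (R_xlen_t)nx * ny * nz;
  if (mask.size() != V) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  std::vector<int> dx, dy, dz;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int s = std::abs(a) + std::abs(b) + std::abs(c);
        if (s == 0) continue;
        if ((connectivity == 6 && s > 1) || (connectivity == 18 && s > 2))
          continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
  const int noff = (int)dx.size();

  IntegerVector labels(V, 0);
  std::vector<R_xlen_t> queue;
  int current = 0;
  for (R_xlen_t seed = 0; seed < V; ++seed) {
    if (!mask[seed] || labels[seed] != 0) continue;
    ++current;
    labels[seed] = current;
    queue.clear();
    queue.push_back(seed);
    while (!queue.empty()) {
      R_xlen_t v = queue.back();
      queue.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (int o = 0; o < noff; ++o) {
        int xx = x + dx[o], yy = y + dy[o], zz = z + dz[o];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] && labels[w] == 0) {
          labels[w] = current;
          queue.push_back(w);
        }
      }
    }
  }
  return labels;
}

// Maximum connected-component size of a logical volume; the hot loop of
// permutation cluster inference (avoids allocating labels per permutation).
// [[Rcpp::export(name = ".max_component_size_cpp")]]
int max_component_size_cpp(LogicalVector mask, IntegerVector dims,
                           int connectivity) {
  IntegerVector labels = label_components_cpp(mask, dims, connectivity);
  int maxlab = 0;
  for (R_xlen_t i = 0; i < labels.size(); ++i)
    if (labels[i] > maxlab) maxlab = labels[i];
  if (maxlab == 0) return 0;
  std::vector<int> sizes(maxlab, 0);
  for (R_xlen_t i = 0; i < labels.size(); ++i)
    if (labels[i] > 0) ++sizes[labels[i] - 1];
  int best = 0;
  for (int s : sizes) if (s > best) best = s;
  return best;
}
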