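#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labelling on a 0/1 grid (column-major, as stored
// by R arrays). connectivity is 6, 18 or 26. Two-pass union-find: pass 1
// scans in storage order and unions each foreground voxel with its
// already-visited neighbours (half stencil); pass 2 resolves roots and
// compacts labels to 1..K in scan order of first appearance.
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(IntegerVector mask, IntegerVector dim,
                           int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // half stencil: neighbours that precede the voxel in scan order
  std::vector<int> dx, dy, dz;
  for (int c = -1; c <= 0; ++c)
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a) {
        if (c == 0 && (b > 0 || (b == 0 && a >= 0))) continue;
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if ((connectivity == 6 && m > 1) || (connectivity == 18 && m > 2))
          continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
  const int noff = (int)dx.size();
  std::vector<R_xlen_t> off(noff);
  for (int o = 0; o < noff; ++o)
    off[o] = dx[o] + (R_xlen_t)nx * (dy[o] + (R_xlen_t)ny * dz[o]);

  IntegerVector labels(n, 0);
  const int* m = INTEGER(mask);
  int* lab = INTEGER(labels);
  std::vector<int> parent;
  parent.reserve(1024);
  parent.push_back(0);  // provisional labels are 1-based

  auto find_root = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };

  R_xlen_t s = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++s) {
        if (m[s] == 0) continue;
        int best = 0;
        for (int o = 0; o < noff; ++o) {
          int ni = i + dx[o], nj = j + dy[o], nk = k + dz[o];
          if (ni < 0 || ni >= nx || nj < 0 || nj >= ny || nk < 0) continue;
          int l = lab[s + off[o]];
          if (l == 0) continue;
          int r = find_root(l);
          if (best == 0) best = r;
          else if (r != best) {
            if (r < best) { parent[best] = r; best = r; }
            else parent[r] = best;
          }
        }
        if (best == 0) {
          best = (int)parent.size();
          parent.push_back(best);
        }
        lab[s] = best;
      }

  // compact roots to 1..K in scan-order of first appearance
  std::vector<int> compact(parent.size(), 0);
  int next_label = 0;
  for (R_xlen_t t = 0; t < n; ++t) {
    if (lab[t] == 0) continue;
    int r = find_root(lab[t]);
    if (compact[r] == 0) compact[r] = ++next_label;
    lab[t] = compact[r];
  }
  return labels;
}
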