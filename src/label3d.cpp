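// 3D connected-component labeling of binary mask volumes (rows, cols, slices)
// under 6- or 26-connectivity, by iterative flood fill. Components are
// relabeled 1..K in decreasing volume order, ties broken by the linear index
// of the first voxel encountered in array order.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_label3d")]]
IntegerVector cpp_label3d(IntegerVector mask, int connectivity) {
  IntegerVector d = mask.attr("dim");
  if (d.size() != 3) stop("mask must be a 3D array");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  const int H = d[0], W = d[1], S = d[2];
  const size_t n = (size_t)H * W * S;

  std::vector<int> off_h, off_w, off_s;
  for (int ds = -1; ds <= 1; ++ds)
    for (int dw = -1; dw <= 1; ++dw)
      for (int dh = -1; dh <= 1; ++dh) {
        if (!dh && !dw && !ds) continue;
        if (connectivity == 6 && std::abs(dh) + std::abs(dw) + std::abs(ds) != 1)
          continue;
        off_h.push_back(dh); off_w.push_back(dw); off_s.push_back(ds);
      }

  IntegerVector lab(n);
  lab.attr("dim") = d;
  int next = 0;
  std::vector<size_t> stack;
  std::vector<size_t> first;   // first voxel of each component
  std::vector<size_t> vol;     // voxel count of each component

  for (size_t i = 0; i < n; ++i) {
    if (mask[i] == 0 || lab[i] != 0) continue;
    ++next;
    first.push_back(i);
    vol.push_back(0);
    stack.clear();
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      size_t v = stack.back();
      stack.pop_back();
      ++vol[next - 1];
      int s = (int)(v / ((size_t)H * W));
      int rem = (int)(v % ((size_t)H * W));
      int w = rem / H, h = rem % H;
      for (size_t q = 0; q < off_h.size(); ++q) {
        int nh = h + off_h[q], nw = w + off_w[q], ns = s + off_s[q];
        if (nh < 0 || nh >= H || nw < 0 || nw >= W || ns < 0 || ns >= S)
          continue;
        size_t u = (size_t)nh + (size_t)H * nw + (size_t)H * W * ns;
        if (mask[u] != 0 && lab[u] == 0) {
          lab[u] = next;
          stack.push_back(u);
        }
      }
    }
  }

  // relabel by decreasing volume, ties by first-voxel index
  std::vector<int> ord(next);
  for (int k = 0; k < next; ++k) ord[k] = k;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (vol[a] != vol[b]) return vol[a] > vol[b];
    return first[a] < first[b];
  });
  std::vector<int> newlab(next + 1, 0);
  for (int r = 0; r < next; ++r) newlab[ord[r] + 1] = r + 1;
  for (size_t i = 0; i < n; ++i)
    if (lab[i] != 0) lab[i] = newlab[lab[i]];
  return lab;
}
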