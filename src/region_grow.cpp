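#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Breadth-first front propagation on the positive part of a speed image.
// 6-connected (face) neighbors; one BFS layer counts as one iteration so
// max_iter bounds the front radius. Returns a logical mask plus an
// attribute flagging whether the iteration cap stopped the front early.
// [[Rcpp::export(name = ".region_grow_cpp")]]
LogicalVector region_grow_cpp(NumericVector speed, IntegerVector dims,
                              IntegerMatrix seeds, int max_iter) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector mask(n);
  std::queue<R_xlen_t> q;
  for (int s = 0; s < seeds.nrow(); ++s) {
    int i = seeds(s, 0) - 1, j = seeds(s, 1) - 1, k = seeds(s, 2) - 1;
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz)
      stop("seed %d is outside the volume", s + 1);
    R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
    if (!(speed[idx] > 0))
      stop("seed %d sits on non-positive speed", s + 1);
    if (!mask[idx]) { mask[idx] = true; q.push(idx); }
  }
  bool capped = false;
  int iter = 0;
  while (!q.empty()) {
    if (max_iter >= 0 && iter >= max_iter) { capped = true; break; }
    std::queue<R_xlen_t> next;
    while (!q.empty()) {
      R_xlen_t idx = q.front(); q.pop();
      int k = idx / ((R_xlen_t)nx * ny);
      int rem = idx - (R_xlen_t)k * nx * ny;
      int j = rem / nx, i = rem % nx;
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; ++d) {
        int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t nb = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (!mask[nb] && speed[nb] > 0) { mask[nb] = true; next.push(nb); }
      }
    }
    q.swap(next);
    ++iter;
  }
  mask.attr("capped") = capped;
  return mask;
}
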