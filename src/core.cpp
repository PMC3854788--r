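#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel arrays arrive as R arrays in column-major order with dim = (z, y, x).
// Linear index i maps to (z, y, x) as z = i % nz, y = (i / nz) % ny, x = i / (nz * ny).

static inline int lin(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

struct Offsets {
  std::vector<int> dz, dy, dx;
  std::vector<double> step;
  Offsets() {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          dz.push_back(a); dy.push_back(b); dx.push_back(c);
          step.push_back(std::sqrt((double)(a * a + b * b + c * c)));
        }
  }
};

// Competitive geodesic front propagation from seeds over a foreground mask.
// Each seed s propagates with per-voxel traversal cost
//   w(v) = 1 + lambda * max(0, I(seed_s) - I(v)),
// an edge into v costing euclidean_step * w(v). A voxel takes the label of
// the seed with minimal geodesic arrival cost; exact cost ties resolve to
// the smaller seed index. Seeds are 0-based linear indices into the array.
// [[Rcpp::export]]
IntegerVector propagate_labels_cpp(NumericVector intensity, LogicalVector foreground,
                                   IntegerVector dims, IntegerVector seed_idx,
                                   NumericVector seed_intensity, double lambda) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = intensity.size();
  const int L = seed_idx.size();
  Offsets off;

  std::vector<double> best(n, R_PosInf);
  std::vector<int> label(n, 0);
  std::vector<double> dist(n);

  typedef std::pair<double, int> QE; // (cost, voxel)
  for (int s = 0; s < L; ++s) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    const double Is = seed_intensity[s];
    std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
    int s0 = seed_idx[s];
    dist[s0] = 0.0;
    pq.push(QE(0.0, s0));
    while (!pq.empty()) {
      QE top = pq.top(); pq.pop();
      double d = top.first;
      int v = top.second;
      if (d > dist[v]) continue;
      int z = v % nz, y = (v / nz) % ny, x = v / (nz * ny);
      for (size_t k = 0; k < off.dz.size(); ++k) {
        int z2 = z + off.dz[k], y2 = y + off.dy[k], x2 = x + off.dx[k];
        if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx) continue;
        int u = lin(z2, y2, x2, nz, ny);
        if (!foreground[u]) continue;
        double slow = Is - intensity[u];
        double w = 1.0 + lambda * (slow > 0.0 ? slow : 0.0);
        double nd = d + off.step[k] * w;
        if (nd < dist[u]) {
          dist[u] = nd;
          pq.push(QE(nd, u));
        }
      }
    }
    for (R_xlen_t v = 0; v < n; ++v) {
      if (dist[v] < best[v]) { best[v] = dist[v]; label[v] = s + 1; }
      // ties keep the earlier (smaller) seed index
    }
  }

  IntegerVector out(n);
  for (R_xlen_t v = 0; v < n; ++v)
    out[v] = foreground[v] ? label[v] : 0;
  return out;
}

// Label connected components of a 3D logical mask under 26-connectivity.
// Components are numbered 1..K in order of first (column-major) occurrence.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = mask.size();
  Offsets off;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.push_back((int)i);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int z = v % nz, y = (v / nz) % ny, x = v / (nz * ny);
      for (size_t k = 0; k < off.dz.size(); ++k) {
        int z2 = z + off.dz[k], y2 = y + off.dy[k], x2 = x + off.dx[k];
        if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx) continue;
        int u = lin(z2, y2, x2, nz, ny);
        if (mask[u] && !lab[u]) { lab[u] = next; stack.push_back(u); }
      }
    }
  }
  return lab;
}

// 1D convolution along one axis of a 3D array with symmetric (reflect,
// edge-included) boundary handling. axis: 0 = z, 1 = y, 2 = x.
// [[Rcpp::export]]
NumericVector convolve_axis_cpp(NumericVector x, IntegerVector dims,
                                NumericVector kernel, int axis) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int kn = kernel.size();
  const int kr = kn / 2; // kernel assumed odd-length, centered
  NumericVector out(x.size());
  int nax = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int xx = 0; xx < nx; ++xx) {
        double acc = 0.0;
        for (int k = 0; k < kn; ++k) {
          int p = ((axis == 0) ? z : (axis == 1) ? y : xx) + k - kr;
          // symmetric reflection: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
          while (p < 0 || p >= nax) {
            if (p < 0) p = -p - 1;
            if (p >= nax) p = 2 * nax - p - 1;
          }
          int z2 = (axis == 0) ? p : z, y2 = (axis == 1) ? p : y,
              x2 = (axis == 2) ? p : xx;
          acc += kernel[k] * x[lin(z2, y2, x2, nz, ny)];
        }
        out[lin(z, y, xx, nz, ny)] = acc;
      }
  return out;
}
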