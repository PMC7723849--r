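#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Low-level raster primitives shared by the segmentation and Sholl code.
// All matrices are column-major (R layout); masks are LogicalMatrix.

static const double DT_INF = 1e20;

// 1-D squared distance transform of a sampled function f
// (Felzenszwalb & Huttenlocher lower-envelope algorithm).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)(q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance (in pixels^2) from every pixel to the
// nearest TRUE pixel of `mask`; NA where the mask is empty.
// [[Rcpp::export]]
NumericMatrix cpp_sqdist_transform(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));

  // column pass
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) f[i] = mask(i, j) ? 0.0 : DT_INF;
    dt1d(f, d, nr);
    for (int i = 0; i < nr; i++) out(i, j) = d[i];
  }
  // row pass
  for (int i = 0; i < nr; i++) {
    for (int j = 0; j < nc; j++) f[j] = out(i, j);
    dt1d(f, d, nc);
    for (int j = 0; j < nc; j++) out(i, j) = d[j] >= DT_INF ? NA_REAL : d[j];
  }
  return out;
}

// Connected-component labelling (BFS). connectivity is 4 or 8.
// Returns an integer matrix of labels, 0 = background; attribute "n" holds
// the number of components.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int n = 0;
  std::vector<int> stack;
  stack.reserve(1024);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nnb = (connectivity == 8) ? 8 : 4;

  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      n++;
      lab(i, j) = n;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int t = 0; t < nnb; t++) {
          int qi = pi + dr8[t], qj = pj + dc8[t];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && lab(qi, qj) == 0) {
            lab(qi, qj) = n;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  lab.attr("n") = n;
  return lab;
}

// Sequential directional thinning to a 1-pixel-wide skeleton.
// Pixels are removed one at a time (never in parallel batches), only when
// they are simple points (crossing number 1), not endpoints, and exposed on
// the current pass direction; this preserves connectivity and, unlike
// parallel Zhang-Suen, cannot erase 2-pixel-wide diagonal staircases.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<unsigned char> img(nr * nc);
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++) img[i + j * nr] = mask(i, j) ? 1 : 0;

  auto at = [&](int i, int j) -> unsigned char {
    if (i < 0 || i >= nr || j < 0 || j >= nc) return 0;
    return img[i + j * nr];
  };
  // direction offsets: N, S, W, E border exposure per subpass
  const int dri[4] = {-1, 1, 0, 0};
  const int dcj[4] = {0, 0, -1, 1};

  std::vector<int> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 4; pass++) {
      // candidates fixed at subpass start: pixels exposed on this side now;
      // deleting sequentially with re-checks preserves connectivity while
      // the fixed candidate set limits erosion to one layer per subpass
      cand.clear();
      for (int j = 0; j < nc; j++) {
        for (int i = 0; i < nr; i++) {
          if (img[i + j * nr] && !at(i + dri[pass], j + dcj[pass]))
            cand.push_back(i + j * nr);
        }
      }
      for (size_t t = 0; t < cand.size(); t++) {
        int i = cand[t] % nr, j = cand[t] / nr;
        if (!img[i + j * nr]) continue;
        unsigned char p2 = at(i - 1, j), p3 = at(i - 1, j + 1),
                      p4 = at(i, j + 1), p5 = at(i + 1, j + 1),
                      p6 = at(i + 1, j), p7 = at(i + 1, j - 1),
                      p8 = at(i, j - 1), p9 = at(i - 1, j - 1);
        int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
        // B <= 2 protects endpoints AND the corner pixels terminating a
        // 2-px-wide diagonal staircase, which no A/B rule alone recognizes
        // as an endpoint and which would otherwise erode away entirely
        if (B < 3 || B > 6) continue;
        int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
        if (A != 1) continue;                              // not simple
        img[i + j * nr] = 0;
        changed = true;
      }
    }
  }

  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++) out(i, j) = img[i + j * nr] != 0;
  return out;
}

// 3x3 median filter with replicated borders.
// [[Rcpp::export]]
NumericMatrix cpp_median3(NumericMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  double w[9];
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) {
      int k = 0;
      for (int dj = -1; dj <= 1; dj++) {
        for (int di = -1; di <= 1; di++) {
          int qi = std::min(std::max(i + di, 0), nr - 1);
          int qj = std::min(std::max(j + dj, 0), nc - 1);
          w[k++] = img(qi, qj);
        }
      }
      std::nth_element(w, w + 4, w + 9);
      out(i, j) = w[4];
    }
  }
  return out;
}
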