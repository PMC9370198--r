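#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <functional>
using namespace Rcpp;

// Cell-list nearest-neighbor search on a planar point set.
// Returns, for each point, the distance to and 1-based index of its nearest
// neighbor. O(n) expected for roughly homogeneous fields; used for point
// counts up to a few 10^6 (Poisson NN-law checks, scaffold pair matching).
// [[Rcpp::export(name = ".nn_info")]]
List nn_info(NumericVector x, NumericVector y) {
  const int n = x.size();
  NumericVector dist(n, R_PosInf);
  IntegerVector idx(n, NA_INTEGER);
  if (n < 2) return List::create(_["dist"] = dist, _["index"] = idx);

  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  double w = xmax - xmin, h = ymax - ymin;
  // ~2 points per cell
  int G = std::max(1, (int)std::floor(std::sqrt((double)n / 2.0)));
  int gx = (w > 0) ? G : 1;
  int gy = (h > 0) ? G : 1;
  double cw = (w > 0) ? w / gx : 1.0;
  double ch = (h > 0) ? h / gy : 1.0;
  double mincell = std::min(cw, ch);

  std::vector<std::vector<int> > cells((size_t)gx * gy);
  std::vector<int> cxs(n), cys(n);
  for (int i = 0; i < n; ++i) {
    int cx = (w > 0) ? std::min(gx - 1, (int)((x[i] - xmin) / cw)) : 0;
    int cy = (h > 0) ? std::min(gy - 1, (int)((y[i] - ymin) / ch)) : 0;
    cxs[i] = cx; cys[i] = cy;
    cells[(size_t)cy * gx + cx].push_back(i);
  }

  int maxr = std::max(gx, gy);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int besti = -1;
    for (int r = 0; r <= maxr; ++r) {
      // cells at Chebyshev ring r around (cxs[i], cys[i])
      int x0 = cxs[i] - r, x1 = cxs[i] + r;
      int y0 = cys[i] - r, y1 = cys[i] + r;
      for (int cy = y0; cy <= y1; ++cy) {
        if (cy < 0 || cy >= gy) continue;
        for (int cx = x0; cx <= x1; ++cx) {
          if (cx < 0 || cx >= gx) continue;
          if (r > 0 && cx != x0 && cx != x1 && cy != y0 && cy != y1) continue;
          const std::vector<int>& cell = cells[(size_t)cy * gx + cx];
          for (size_t k = 0; k < cell.size(); ++k) {
            int j = cell[k];
            if (j == i) continue;
            double dx = x[i] - x[j], dy = y[i] - y[j];
            double d = std::sqrt(dx * dx + dy * dy);
            if (d < best) { best = d; besti = j; }
          }
        }
      }
      // any point beyond ring r is at least r*mincell away
      if (besti >= 0 && best <= r * mincell) break;
    }
    dist[i] = best;
    idx[i] = besti + 1;
  }
  return List::create(_["dist"] = dist, _["index"] = idx);
}

// Connected-component labeling of a binary image with 8-connectivity
// (two-pass union-find). Input: logical/integer matrix; output: integer
// matrix of labels, 0 = background, components numbered from 1 in raster
// order of first occurrence.
// [[Rcpp::export(name = ".label8")]]
IntegerMatrix label8(LogicalMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);

  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };

  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!m(i, j)) continue;
      // neighbors already visited in column-major order:
      // (i-1, j), (i-1, j-1), (i, j-1), (i+1, j-1)
      int nb[4][2] = {{i - 1, j}, {i - 1, j - 1}, {i, j - 1}, {i + 1, j - 1}};
      int lmin = 0;
      for (int k = 0; k < 4; ++k) {
        int ni = nb[k][0], nj = nb[k][1];
        if (ni < 0 || ni >= nr || nj < 0) continue;
        int l = lab(ni, nj);
        if (l > 0) {
          if (lmin == 0) lmin = l;
          else unite(lmin, l);
          if (l < lmin) lmin = l;
        }
      }
      if (lmin == 0) {
        ++next;
        parent.push_back(next);
        lab(i, j) = next;
      } else {
        lab(i, j) = lmin;
      }
    }
  }
  // flatten and renumber in raster order of first occurrence
  std::vector<int> newlab(next + 1, 0);
  int outn = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) > 0) {
        int r = find(lab(i, j));
        if (newlab[r] == 0) newlab[r] = ++outn;
        lab(i, j) = newlab[r];
      }
  return lab;
}
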