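#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Polygon rasterization under the pixel-center even-odd rule: pixel (ix, iy)
// (0-based, origin top-left) belongs to the mask iff its center
// (ix + 0.5, iy + 0.5) lies inside the polygon set by even-odd crossing
// count. Multiple rings are combined even-odd, so rings may encode holes or
// disjoint parts. All boundary disputes are decided by strict comparisons,
// making the rule deterministic.

struct Edge { double x1, y1, x2, y2; };

struct Poly {
  std::vector<Edge> edges;
  double xmin, xmax, ymin, ymax;
};

static Poly collect(const List& rings) {
  Poly p;
  p.xmin = p.ymin = R_PosInf;
  p.xmax = p.ymax = R_NegInf;
  for (int r = 0; r < rings.size(); ++r) {
    NumericMatrix ring = rings[r];
    int k = ring.nrow();
    if (k < 3) stop("polygon ring with fewer than 3 vertices");
    for (int i = 0; i < k; ++i) {
      int j = (i + 1) % k;
      Edge e;
      e.x1 = ring(i, 0); e.y1 = ring(i, 1);
      e.x2 = ring(j, 0); e.y2 = ring(j, 1);
      p.edges.push_back(e);
      p.xmin = std::min(p.xmin, std::min(e.x1, e.x2));
      p.xmax = std::max(p.xmax, std::max(e.x1, e.x2));
      p.ymin = std::min(p.ymin, std::min(e.y1, e.y2));
      p.ymax = std::max(p.ymax, std::max(e.y1, e.y2));
    }
  }
  return p;
}

// x-coordinates where the horizontal line y = yc crosses the polygon edges
static void scan_row(const Poly& p, double yc, std::vector<double>& xs) {
  xs.clear();
  for (size_t e = 0; e < p.edges.size(); ++e) {
    const Edge& ed = p.edges[e];
    if ((ed.y1 > yc) == (ed.y2 > yc)) continue;
    double t = (yc - ed.y1) / (ed.y2 - ed.y1);
    xs.push_back(ed.x1 + t * (ed.x2 - ed.x1));
  }
  std::sort(xs.begin(), xs.end());
}

// visit all filled pixels; clipping to [0,W)x[0,H) optional (W,H < 0 = none)
template <typename F>
static void fill_pixels(const Poly& p, int W, int H, F visit) {
  if (p.edges.empty()) return;
  int iy0 = (int)std::floor(p.ymin - 0.5);
  int iy1 = (int)std::ceil(p.ymax);
  if (H >= 0) { iy0 = std::max(iy0, 0); iy1 = std::min(iy1, H - 1); }
  std::vector<double> xs;
  for (int iy = iy0; iy <= iy1; ++iy) {
    double yc = iy + 0.5;
    scan_row(p, yc, xs);
    for (size_t k = 0; k + 1 < xs.size(); k += 2) {
      // centers xc = ix + 0.5 with xs[k] <= xc < xs[k+1]
      int ix0 = (int)std::ceil(xs[k] - 0.5);
      int ix1 = (int)std::ceil(xs[k + 1] - 0.5) - 1;
      if (W >= 0) { ix0 = std::max(ix0, 0); ix1 = std::min(ix1, W - 1); }
      for (int ix = ix0; ix <= ix1; ++ix) visit(ix, iy);
    }
  }
}

// 0-based linear indices (ix + iy * W) of mask pixels, clipped to the frame
// [[Rcpp::export]]
IntegerVector cpp_poly_pixels(List rings, int W, int H) {
  Poly p = collect(rings);
  std::vector<int> out;
  fill_pixels(p, W, H, [&](int ix, int iy) { out.push_back(ix + iy * W); });
  return wrap(out);
}

// unclipped pixel count of the rasterized mask
// [[Rcpp::export]]
double cpp_poly_area(List rings) {
  Poly p = collect(rings);
  double n = 0;
  fill_pixels(p, -1, -1, [&](int, int) { ++n; });
  return n;
}

// tight bounds and pixel count of the frame-clipped raster:
// c(minx, miny, maxx, maxy, count); all -1 and count 0 when empty
// [[Rcpp::export]]
NumericVector cpp_mask_bounds(List rings, int W, int H) {
  Poly p = collect(rings);
  int minx = W, miny = H, maxx = -1, maxy = -1;
  double n = 0;
  fill_pixels(p, W, H, [&](int ix, int iy) {
    ++n;
    if (ix < minx) minx = ix;
    if (ix > maxx) maxx = ix;
    if (iy < miny) miny = iy;
    if (iy > maxy) maxy = iy;
  });
  if (n == 0) return NumericVector::create(-1, -1, -1, -1, 0);
  return NumericVector::create(minx, miny, maxx, maxy, n);
}

// intersection / areas of two frame-clipped rasters: c(inter, areaA, areaB)
// [[Rcpp::export]]
NumericVector cpp_mask_overlap(List ringsA, List ringsB, int W, int H) {
  Poly a = collect(ringsA), b = collect(ringsB);
  // window: union of the two polygon bounds, clipped to the frame
  int x0 = std::max(0, (int)std::floor(std::min(a.xmin, b.xmin) - 1));
  int y0 = std::max(0, (int)std::floor(std::min(a.ymin, b.ymin) - 1));
  int x1 = std::min(W - 1, (int)std::ceil(std::max(a.xmax, b.xmax) + 1));
  int y1 = std::min(H - 1, (int)std::ceil(std::max(a.ymax, b.ymax) + 1));
  if (x1 < x0 || y1 < y0) return NumericVector::create(0, 0, 0);
  int nx = x1 - x0 + 1, ny = y1 - y0 + 1;
  std::vector<char> bufA((size_t)nx * ny, 0);
  double nA = 0, nB = 0, inter = 0;
  fill_pixels(a, W, H, [&](int ix, int iy) {
    if (ix < x0 || ix > x1 || iy < y0 || iy > y1) return;
    bufA[(size_t)(ix - x0) + (size_t)(iy - y0) * nx] = 1;
    ++nA;
  });
  fill_pixels(b, W, H, [&](int ix, int iy) {
    if (ix < x0 || ix > x1 || iy < y0 || iy > y1) return;
    ++nB;
    if (bufA[(size_t)(ix - x0) + (size_t)(iy - y0) * nx]) ++inter;
  });
  return NumericVector::create(inter, nA, nB);
}

// pixel-set IoU of two masks rasterized at the frame size (0 on empty union)
// [[Rcpp::export]]
double cpp_mask_iou(List ringsA, List ringsB, int W, int H) {
  NumericVector o = cpp_mask_overlap(ringsA, ringsB, W, H);
  double uni = o[1] + o[2] - o[0];
  return uni > 0 ? o[0] / uni : 0.0;
}

// Painter's-model visibility for one frame: agents[i] is a list of rings;
// later agents occlude earlier ones. Returns an n x 7 matrix with columns
// total (unclipped raster px), inframe (clipped px), visible (clipped px not
// overpainted), minx, miny, maxx, maxy (clipped own-raster bounds, -1 when
// empty).
// [[Rcpp::export]]
NumericMatrix cpp_paint_visibility(List agents, int W, int H) {
  const int n = agents.size();
  NumericMatrix out(n, 7);
  std::vector<int> buf((size_t)W * H, 0);
  std::vector< std::vector<int> > own(n);
  for (int i = 0; i < n; ++i) {
    List rings = agents[i];
    Poly p = collect(rings);
    double total = 0;
    fill_pixels(p, -1, -1, [&](int, int) { ++total; });
    int minx = W, miny = H, maxx = -1, maxy = -1;
    std::vector<int>& px = own[i];
    fill_pixels(p, W, H, [&](int ix, int iy) {
      px.push_back(ix + iy * W);
      if (ix < minx) minx = ix;
      if (ix > maxx) maxx = ix;
      if (iy < miny) miny = iy;
      if (iy > maxy) maxy = iy;
    });
    for (size_t k = 0; k < px.size(); ++k) buf[px[k]] = i + 1;
    out(i, 0) = total;
    out(i, 1) = (double)px.size();
    if (px.empty()) { minx = miny = maxx = maxy = -1; }
    out(i, 3) = minx; out(i, 4) = miny; out(i, 5) = maxx; out(i, 6) = maxy;
  }
  for (int i = 0; i < n; ++i) {
    double vis = 0;
    for (size_t k = 0; k < own[i].size(); ++k)
      if (buf[own[i][k]] == i + 1) ++vis;
    out(i, 2) = vis;
  }
  return out;
}
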