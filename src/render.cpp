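#include <Rcpp.h>
using namespace Rcpp;

// Integer Bresenham rasterization of a set of strokes onto an H x W raster.
// Coordinates are 0-based (col, row) with row 0 at the top. Overlapping
// strokes keep the maximum intensity; no anti-aliasing, so re-rendering is
// bit-identical.
// [[Rcpp::export(name = ".draw_strokes_cpp")]]
NumericMatrix draw_strokes_cpp(int H, int W,
                               IntegerVector x0, IntegerVector y0,
                               IntegerVector x1, IntegerVector y1,
                               NumericVector intensity) {
  NumericMatrix img(H, W);
  int n = x0.size();
  for (int k = 0; k < n; ++k) {
    int xa = x0[k], ya = y0[k], xb = x1[k], yb = y1[k];
    double v = intensity[k];
    int dx = std::abs(xb - xa), sx = xa < xb ? 1 : -1;
    int dy = -std::abs(yb - ya), sy = ya < yb ? 1 : -1;
    int err = dx + dy;
    int x = xa, y = ya;
    while (true) {
      if (x >= 0 && x < W && y >= 0 && y < H) {
        if (img(y, x) < v) img(y, x) = v;
      }
      if (x == xb && y == yb) break;
      int e2 = 2 * err;
      if (e2 >= dy) { err += dy; x += sx; }
      if (e2 <= dx) { err += dx; y += sy; }
    }
  }
  return img;
}
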