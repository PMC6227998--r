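#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact ray-grid traversal of the occupancy grid. The occupied region is the
// union of closed unit squares: pixel (row r, col c) (1-based R indices)
// covers [c-1, c] x [r-1, r] in a continuous plane with x rightward and
// y downward; its centre is (c - 0.5, r - 0.5).
//
// march() advances from (x0, y0) along (dx, dy) cell crossing by cell
// crossing and returns the parameter t >= 0 at which the ray first enters an
// unoccupied cell or leaves the grid (chords are truncated at the raster
// edge). When a crossing passes exactly through a lattice corner (tMaxX ==
// tMaxY within tolerance) both coordinates advance together, so the ray
// steps to the diagonal cell: points on shared edges/corners of occupied
// squares count as inside the closed union.
static double march(const LogicalMatrix &occ, double x0, double y0,
                    double dx, double dy) {
  const int nr = occ.nrow(), nc = occ.ncol();
  const double eps = 1e-9, INF = 1e18;

  int cx = (int)std::floor(x0);  // 0-based column of current cell
  int cy = (int)std::floor(y0);  // 0-based row

  double tMaxX, tMaxY, tDX, tDY;
  int sx = 0, sy = 0;
  if (dx > eps) {
    sx = 1;  tDX = 1.0 / dx;  tMaxX = (std::floor(x0) + 1.0 - x0) / dx;
  } else if (dx < -eps) {
    sx = -1; tDX = -1.0 / dx; tMaxX = (std::floor(x0) - x0) / dx;
  } else {
    tDX = INF; tMaxX = INF;
  }
  if (dy > eps) {
    sy = 1;  tDY = 1.0 / dy;  tMaxY = (std::floor(y0) + 1.0 - y0) / dy;
  } else if (dy < -eps) {
    sy = -1; tDY = -1.0 / dy; tMaxY = (std::floor(y0) - y0) / dy;
  } else {
    tDY = INF; tMaxY = INF;
  }

  const int max_steps = 4 * (nr + nc) + 8;
  for (int step = 0; step < max_steps; ++step) {
    double t;
    if (tMaxX < tMaxY - eps) {
      t = tMaxX; cx += sx; tMaxX += tDX;
    } else if (tMaxY < tMaxX - eps) {
      t = tMaxY; cy += sy; tMaxY += tDY;
    } else {  // corner crossing: step diagonally
      t = std::min(tMaxX, tMaxY);
      cx += sx; tMaxX += tDX;
      cy += sy; tMaxY += tDY;
    }
    if (cx < 0 || cx >= nc || cy < 0 || cy >= nr) return t;
    if (!occ(cy, cx)) return t;
  }
  return 0.0;  // unreachable: the ray must leave the grid within max_steps
}

// [[Rcpp::export]]
NumericMatrix chord_lengths_cpp(LogicalMatrix occ, IntegerVector rows,
                                IntegerVector cols, NumericVector angles) {
  const int n = rows.size(), D = angles.size();
  NumericMatrix out(n, D);
  for (int i = 0; i < n; ++i) {
    const int r = rows[i], c = cols[i];
    if (r < 1 || r > occ.nrow() || c < 1 || c > occ.ncol() || !occ(r - 1, c - 1))
      stop("chord requested at an unoccupied or out-of-grid pixel (%d, %d)", r, c);
    const double x0 = c - 0.5, y0 = r - 0.5;
    for (int d = 0; d < D; ++d) {
      const double dx = std::cos(angles[d]), dy = std::sin(angles[d]);
      out(i, d) = march(occ, x0, y0, dx, dy) + march(occ, x0, y0, -dx, -dy);
    }
  }
  return out;
}
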