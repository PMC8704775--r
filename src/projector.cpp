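// Fan-beam projection geometry: point source rotating on a circle of radius
// src_to_center around the image origin, flat detector at center_to_det on
// the far side, oriented perpendicular to the source-center axis. Image is
// an n x n raster; R matrix row i / col j maps to physical coordinates
// x = (j - (n-1)/2) * pitch, y = ((n-1)/2 - i) * pitch (y up, mm).
// Line integrals are accumulated by stepped bilinear sampling along each
// source-bin ray clipped to the image square; back projection uses the
// standard equispaced (flat-detector) weighted fan-beam formula with the
// detector coordinate rescaled to the virtual detector through the
// isocenter. Filtering of the projections is done on the R side.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Clip parametric ray p(t) = S + t*u to the square [-h, h]^2; returns false
// when the ray misses.
static inline bool clip_box(double sx, double sy, double ux, double uy,
                            double h, double tmax, double& t0, double& t1) {
  t0 = 0.0; t1 = tmax;
  const double o[2] = {sx, sy}, u[2] = {ux, uy};
  for (int a = 0; a < 2; ++a) {
    if (std::fabs(u[a]) < 1e-12) {
      if (o[a] < -h || o[a] > h) return false;
    } else {
      double ta = (-h - o[a]) / u[a], tb = (h - o[a]) / u[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
      if (t0 >= t1) return false;
    }
  }
  return true;
}

// Exact intersection-length (Siddon-style) line integral of the
// piecewise-constant pixel image along one ray; avoids the interpolation
// blur a sampled integral would introduce.
static double siddon_ray(const double* im, int n, double pitch, double sx,
                         double sy, double ux, double uy, double t0,
                         double t1) {
  const double half = n * pitch / 2.0;
  const double eps = 1e-9 * pitch;
  double t = t0 + eps;
  // entry cell (col j from x, row i from y with row 0 at the top)
  double x = sx + t * ux, y = sy + t * uy;
  int j = (int)std::floor((x + half) / pitch);
  int i = (int)std::floor((half - y) / pitch);
  if (j < 0) j = 0; if (j > n - 1) j = n - 1;
  if (i < 0) i = 0; if (i > n - 1) i = n - 1;
  const int stepj = ux > 0 ? 1 : -1;
  const int stepi = uy > 0 ? -1 : 1;  // y decreasing moves down the rows
  const double dtx = std::fabs(ux) > 1e-14 ? pitch / std::fabs(ux) : HUGE_VAL;
  const double dty = std::fabs(uy) > 1e-14 ? pitch / std::fabs(uy) : HUGE_VAL;
  double tmx, tmy;
  if (std::fabs(ux) > 1e-14) {
    const double xb = -half + (ux > 0 ? (j + 1) : j) * pitch;
    tmx = (xb - sx) / ux;
  } else tmx = HUGE_VAL;
  if (std::fabs(uy) > 1e-14) {
    const double yb = half - (uy < 0 ? (i + 1) : i) * pitch;
    tmy = (yb - sy) / uy;
  } else tmy = HUGE_VAL;
  double acc = 0.0, tc = t0;
  while (tc < t1 - eps) {
    const double tn = std::min(std::min(tmx, tmy), t1);
    if (i >= 0 && i < n && j >= 0 && j < n) acc += im[i + n * j] * (tn - tc);
    tc = tn;
    if (tmx <= tmy) { j += stepj; tmx += dtx; }
    else { i += stepi; tmy += dty; }
    if (j < -1 || j > n || i < -1 || i > n) break;
  }
  return acc;
}

// [[Rcpp::export]]
NumericMatrix cpp_fan_forward(NumericMatrix mu, double pitch, double dso,
                              double dod, int nbins, double binpitch,
                              NumericVector angles, int oversample) {
  const int n = mu.nrow();
  if (mu.ncol() != n) stop("image must be square");
  const int nv = angles.size();
  if (oversample < 1) oversample = 1;
  NumericMatrix sino(nv, nbins);
  const double half = n * pitch / 2.0;
  const double* im = mu.begin();
  for (int v = 0; v < nv; ++v) {
    const double cb = std::cos(angles[v]), sb = std::sin(angles[v]);
    const double sx = dso * cb, sy = dso * sb;
    for (int bidx = 0; bidx < nbins; ++bidx) {
      double acc = 0.0;
      // average `oversample` sub-rays across the bin width
      for (int q = 0; q < oversample; ++q) {
        const double frac = oversample == 1 ? 0.0
          : (q + 0.5) / oversample - 0.5;
        const double s = (bidx - (nbins - 1) / 2.0 + frac) * binpitch;
        const double px = -dod * cb - s * sb, py = -dod * sb + s * cb;
        double ux = px - sx, uy = py - sy;
        const double len = std::sqrt(ux * ux + uy * uy);
        ux /= len; uy /= len;
        double t0, t1;
        if (!clip_box(sx, sy, ux, uy, half, len, t0, t1)) continue;
        acc += siddon_ray(im, n, pitch, sx, sy, ux, uy, t0, t1);
      }
      sino(v, bidx) = acc / oversample;
    }
  }
  return sino;
}

// pfilt: filtered projections (n_views x nbins) on the virtual detector with
// sample spacing dsv (mm at the isocenter); returns the n x n reconstruction.
// [[Rcpp::export]]
NumericMatrix cpp_fan_backproject(NumericMatrix pfilt, double dsv, double dso,
                                  NumericVector angles, int n, double pitch) {
  const int nv = angles.size();
  const int nbins = pfilt.ncol();
  NumericMatrix img(n, n);
  const double dbeta = 2.0 * M_PI / nv;
  std::vector<double> cb(nv), sb(nv);
  for (int v = 0; v < nv; ++v) { cb[v] = std::cos(angles[v]); sb[v] = std::sin(angles[v]); }
  for (int j = 0; j < n; ++j) {
    const double x = (j - (n - 1) / 2.0) * pitch;
    for (int i = 0; i < n; ++i) {
      const double y = ((n - 1) / 2.0 - i) * pitch;
      double acc = 0.0;
      for (int v = 0; v < nv; ++v) {
        const double daxis = dso - (x * cb[v] + y * sb[v]);
        if (daxis <= 1e-6) continue;
        const double t = dso * (-x * sb[v] + y * cb[v]) / daxis;
        const double bt = t / dsv + (nbins - 1) / 2.0;
        if (bt < 0 || bt > nbins - 1) continue;
        int b0 = (int)std::floor(bt);
        if (b0 > nbins - 2) b0 = nbins - 2;
        const double f = bt - b0;
        const double val = (1 - f) * pfilt(v, b0) + f * pfilt(v, b0 + 1);
        const double u = daxis / dso;
        acc += val / (u * u);
      }
      img(i, j) = acc * dbeta;
    }
  }
  return img;
}
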