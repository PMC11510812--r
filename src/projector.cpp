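// Fan-beam / parallel-beam projection operators for spectral image stacks.
//
// Conventions:
//  - image stack arrays are (E, H, W) column-major (channel index fastest);
//  - sinogram arrays are (E, A, D);
//  - pixel (i, j) (0-based row/col) is centred at
//      x = (j - (W-1)/2) * px,  y = (i - (H-1)/2) * px   [cm];
//  - the source at angle beta sits at R_so * (cos b, sin b); the flat detector
//    is centred at -R_od * (cos b, sin b) and runs along (-sin b, cos b).
//
// The forward projector samples each ray at a fixed step with bilinear
// interpolation; the adjoint is the exact transpose (same samples, scatter
// instead of gather), which is what the iterative reconstruction needs.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Geom {
  double r_so, r_od, pitch, px;
  int ndet, nang, h, w, ne;
  bool fan;
};

// entry/exit parameters of segment p0 + t*(p1-p0) clipped to the image box
inline bool clip_box(double x0, double y0, double dx, double dy,
                     double xmin, double xmax, double ymin, double ymax,
                     double &t0, double &t1) {
  t0 = 0.0; t1 = 1.0;
  const double p[4] = {-dx, dx, -dy, dy};
  const double q[4] = {x0 - xmin, xmax - x0, y0 - ymin, ymax - y0};
  for (int k = 0; k < 4; ++k) {
    if (std::fabs(p[k]) < 1e-14) {
      if (q[k] < 0) return false;
    } else {
      double t = q[k] / p[k];
      if (p[k] < 0) { if (t > t0) t0 = t; }
      else          { if (t < t1) t1 = t; }
    }
  }
  return t1 > t0;
}

// end points of the ray for angle index a, detector index d
inline void ray_endpoints(const Geom &g, double cb, double sb, int d,
                          double &x0, double &y0, double &x1, double &y1) {
  double s = (d - (g.ndet - 1) / 2.0) * g.pitch;
  if (g.fan) {
    x0 = g.r_so * cb;           y0 = g.r_so * sb;
    x1 = -g.r_od * cb - s * sb; y1 = -g.r_od * sb + s * cb;
  } else {
    // parallel: ray through s*(-sin b, cos b) with direction -(cos b, sin b)
    double span = 2.0 * (g.r_so + g.r_od);
    x0 = -s * sb + 0.5 * span * cb; y0 = s * cb + 0.5 * span * sb;
    x1 = -s * sb - 0.5 * span * cb; y1 = s * cb - 0.5 * span * sb;
  }
}

}  // namespace

// [[Rcpp::export(name = ".cpp_project")]]
NumericVector cpp_project(NumericVector image, IntegerVector dims,
                          NumericVector angles_rad,
                          double r_so, double r_od, double pitch_cm,
                          int ndet, double px_cm, bool fan,
                          double step_frac, bool adjoint_input_is_sino = false) {
  Geom g;
  g.ne = dims[0]; g.h = dims[1]; g.w = dims[2];
  g.r_so = r_so; g.r_od = r_od; g.pitch = pitch_cm; g.px = px_cm;
  g.ndet = ndet; g.nang = angles_rad.size(); g.fan = fan;
  const double half_w = 0.5 * g.w * g.px, half_h = 0.5 * g.h * g.px;
  const double step = step_frac * g.px;
  NumericVector out(
      adjoint_input_is_sino ? (R_xlen_t)g.ne * g.h * g.w
                            : (R_xlen_t)g.ne * g.nang * g.ndet);
  const double *img = image.begin();
  double *res = out.begin();
  const int ne = g.ne;

  for (int a = 0; a < g.nang; ++a) {
    const double cb = std::cos(angles_rad[a]), sb = std::sin(angles_rad[a]);
    for (int d = 0; d < g.ndet; ++d) {
      double x0, y0, x1, y1, t0, t1;
      ray_endpoints(g, cb, sb, d, x0, y0, x1, y1);
      const double dx = x1 - x0, dy = y1 - y0;
      if (!clip_box(x0, y0, dx, dy, -half_w, half_w, -half_h, half_h, t0, t1))
        continue;
      const double len = std::sqrt(dx * dx + dy * dy);
      const double seg = (t1 - t0) * len;
      const int nsamp = std::max(1, (int)std::ceil(seg / step));
      const double ds = seg / nsamp;  // cm per sample
      const R_xlen_t sino_base = (R_xlen_t)ne * (a + (R_xlen_t)g.nang * d);
      for (int k = 0; k < nsamp; ++k) {
        const double t = t0 + (t1 - t0) * (k + 0.5) / nsamp;
        const double x = x0 + t * dx, y = y0 + t * dy;
        const double gj = x / g.px + (g.w - 1) / 2.0;
        const double gi = y / g.px + (g.h - 1) / 2.0;
        const int j0 = (int)std::floor(gj), i0 = (int)std::floor(gi);
        const double fj = gj - j0, fi = gi - i0;
        // 4 neighbours with bilinear weights
        for (int c = 0; c < 4; ++c) {
          const int jj = j0 + (c & 1), ii = i0 + (c >> 1);
          if (jj < 0 || jj >= g.w || ii < 0 || ii >= g.h) continue;
          const double wgt = ((c & 1) ? fj : 1 - fj) *
                             ((c >> 1) ? fi : 1 - fi) * ds;
          const R_xlen_t img_base = (R_xlen_t)ne * (ii + (R_xlen_t)g.h * jj);
          if (!adjoint_input_is_sino) {
            for (int e = 0; e < ne; ++e)
              res[sino_base + e] += wgt * img[img_base + e];
          } else {
            for (int e = 0; e < ne; ++e)
              res[img_base + e] += wgt * img[sino_base + e];
          }
        }
      }
    }
  }
  return out;
}

// Pixel-driven backprojection of filtered projections.
// qsino: (E, A, D) filtered sinogram sampled on the *virtual* detector
// (isocentre plane) with pitch `pitch_v` for fan beams, or the physical
// detector for parallel beams.  Fan beams apply the R^2/U^2 distance weight.
// [[Rcpp::export(name = ".cpp_fbp_backproject")]]
NumericVector cpp_fbp_backproject(NumericVector qsino, IntegerVector sdims,
                                  NumericVector angles_rad,
                                  double r_so, double pitch_v,
                                  int h, int w, double px_cm, bool fan) {
  const int ne = sdims[0], nang = sdims[1], ndet = sdims[2];
  NumericVector out((R_xlen_t)ne * h * w);
  const double *q = qsino.begin();
  double *img = out.begin();
  const double cdet = (ndet - 1) / 2.0;

  for (int a = 0; a < nang; ++a) {
    const double cb = std::cos(angles_rad[a]), sb = std::sin(angles_rad[a]);
    for (int j = 0; j < w; ++j) {
      const double x = (j - (w - 1) / 2.0) * px_cm;
      for (int i = 0; i < h; ++i) {
        const double y = (i - (h - 1) / 2.0) * px_cm;
        double sv, wgt;
        if (fan) {
          const double U = r_so - x * cb - y * sb;
          if (U <= 1e-9) continue;
          sv = r_so * (y * cb - x * sb) / U;
          wgt = (r_so * r_so) / (U * U);
        } else {
          sv = y * cb - x * sb;
          wgt = 1.0;
        }
        const double gd = sv / pitch_v + cdet;
        const int d0 = (int)std::floor(gd);
        if (d0 < -1 || d0 > ndet - 1) continue;
        const double fd = gd - d0;
        const R_xlen_t base_img = (R_xlen_t)ne * (i + (R_xlen_t)h * j);
        if (d0 >= 0) {
          const R_xlen_t b0 = (R_xlen_t)ne * (a + (R_xlen_t)nang * d0);
          const double w0 = wgt * (1 - fd);
          for (int e = 0; e < ne; ++e) img[base_img + e] += w0 * q[b0 + e];
        }
        if (d0 + 1 <= ndet - 1) {
          const R_xlen_t b1 = (R_xlen_t)ne * (a + (R_xlen_t)nang * (d0 + 1));
          const double w1 = wgt * fd;
          for (int e = 0; e < ne; ++e) img[base_img + e] += w1 * q[b1 + e];
        }
      }
    }
  }
  return out;
}
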