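#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Matched ray-driven parallel-beam projector pair.
//
// Image convention: an n x n matrix; rows index the anterior->posterior
// (y) axis, columns the left->right (x) axis. The pixel (i, j) (0-based)
// has world coordinates
//   x = (j - (n-1)/2) * spacing,  y = (i - (n-1)/2) * spacing   [mm]
// A line of response at angle theta (radians, in [0, pi)) and radial
// offset s is the point set  p(t) = s * (cos t., sin t.) + t * dir,
// with normal (cos theta, sin theta) and direction (-sin theta, cos theta).
// Line integrals are accumulated by sampling the image bilinearly at a
// fixed step along the ray; the backprojector scatters with the identical
// weights, so the pair is adjoint by construction.

static inline double sampleHalfLength(int n, double spacing, double binWidth) {
  return 0.5 * n * spacing * M_SQRT2 + binWidth;
}

// [[Rcpp::export(name = ".cppForwardProject")]]
NumericMatrix cppForwardProject(NumericMatrix image, NumericVector angles,
                                int nBins, double binWidth, double spacing,
                                double step) {
  const int n = image.nrow();
  if (image.ncol() != n) stop("image must be square");
  const int nAng = angles.size();
  NumericMatrix sino(nAng, nBins);
  const double c0 = (n - 1) / 2.0;
  const double halfL = sampleHalfLength(n, spacing, binWidth);
  const int nSamp = (int)std::ceil(2.0 * halfL / step);
  const double sOff = (nBins - 1) / 2.0;

  for (int a = 0; a < nAng; ++a) {
    const double ct = std::cos(angles[a]);
    const double st = std::sin(angles[a]);
    for (int b = 0; b < nBins; ++b) {
      const double s = (b - sOff) * binWidth;
      double acc = 0.0;
      for (int k = 0; k < nSamp; ++k) {
        const double t = -halfL + (k + 0.5) * step;
        const double x = s * ct - t * st;
        const double y = s * st + t * ct;
        // continuous pixel coords (col = x, row = y)
        const double u = x / spacing + c0;
        const double v = y / spacing + c0;
        const int j0 = (int)std::floor(u);
        const int i0 = (int)std::floor(v);
        if (j0 < -1 || j0 > n - 1 || i0 < -1 || i0 > n - 1) continue;
        const double fu = u - j0;
        const double fv = v - i0;
        double val = 0.0;
        if (i0 >= 0 && j0 >= 0)       val += (1 - fu) * (1 - fv) * image(i0, j0);
        if (i0 >= 0 && j0 + 1 < n)     val += fu * (1 - fv) * image(i0, j0 + 1);
        if (i0 + 1 < n && j0 >= 0)     val += (1 - fu) * fv * image(i0 + 1, j0);
        if (i0 + 1 < n && j0 + 1 < n)  val += fu * fv * image(i0 + 1, j0 + 1);
        acc += val;
      }
      sino(a, b) = acc * step;
    }
  }
  return sino;
}

// [[Rcpp::export(name = ".cppBackProject")]]
NumericMatrix cppBackProject(NumericMatrix sino, NumericVector angles,
                             int n, double binWidth, double spacing,
                             double step) {
  const int nAng = sino.nrow();
  const int nBins = sino.ncol();
  if (nAng != angles.size()) stop("sinogram rows must match angle count");
  NumericMatrix image(n, n);
  const double c0 = (n - 1) / 2.0;
  const double halfL = sampleHalfLength(n, spacing, binWidth);
  const int nSamp = (int)std::ceil(2.0 * halfL / step);
  const double sOff = (nBins - 1) / 2.0;

  for (int a = 0; a < nAng; ++a) {
    const double ct = std::cos(angles[a]);
    const double st = std::sin(angles[a]);
    for (int b = 0; b < nBins; ++b) {
      const double w = sino(a, b) * step;
      if (w == 0.0) continue;
      const double s = (b - sOff) * binWidth;
      for (int k = 0; k < nSamp; ++k) {
        const double t = -halfL + (k + 0.5) * step;
        const double x = s * ct - t * st;
        const double y = s * st + t * ct;
        const double u = x / spacing + c0;
        const double v = y / spacing + c0;
        const int j0 = (int)std::floor(u);
        const int i0 = (int)std::floor(v);
        if (j0 < -1 || j0 > n - 1 || i0 < -1 || i0 > n - 1) continue;
        const double fu = u - j0;
        const double fv = v - i0;
        if (i0 >= 0 && j0 >= 0)       image(i0, j0)         += w * (1 - fu) * (1 - fv);
        if (i0 >= 0 && j0 + 1 < n)     image(i0, j0 + 1)     += w * fu * (1 - fv);
        if (i0 + 1 < n && j0 >= 0)     image(i0 + 1, j0)     += w * (1 - fu) * fv;
        if (i0 + 1 < n && j0 + 1 < n)  image(i0 + 1, j0 + 1) += w * fu * fv;
      }
    }
  }
  return image;
}
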