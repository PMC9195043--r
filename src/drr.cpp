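#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation of a 3D volume at a continuous 0-based voxel index.
// Points outside the grid contribute zero attenuation (air).
static inline double trilinear(const double* mu, int nx, int ny, int nz,
                               double fx, double fy, double fz) {
  int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy), z0 = (int)std::floor(fz);
  double wx = fx - x0, wy = fy - y0, wz = fz - z0;
  double acc = 0.0;
  for (int dz = 0; dz <= 1; ++dz) {
    int z = z0 + dz;
    if (z < 0 || z >= nz) continue;
    double wz_ = dz ? wz : 1.0 - wz;
    for (int dy = 0; dy <= 1; ++dy) {
      int y = y0 + dy;
      if (y < 0 || y >= ny) continue;
      double wy_ = dy ? wy : 1.0 - wy;
      for (int dx = 0; dx <= 1; ++dx) {
        int x = x0 + dx;
        if (x < 0 || x >= nx) continue;
        double wx_ = dx ? wx : 1.0 - wx;
        acc += wx_ * wy_ * wz_ * mu[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z)];
      }
    }
  }
  return acc;
}

// Path integral of attenuation along source->pixel rays through a posed volume.
//
// The volume lives in its own (phantom) frame; a rigid pose maps phantom
// coordinates to world coordinates, p_world = R p + t. Rays are defined in
// world coordinates and transformed into the phantom frame (no volume
// resampling). Integration is a fixed-step trapezoid rule along the segment
// of the ray inside the grid bounding box.
//
// mu:       3D array (dim attribute nx,ny,nz) of linear attenuation, 1/mm
// origin:   phantom-frame position (mm) of the centre of voxel [1,1,1]
// poseR/poseT: rigid pose (world = R * phantom + t)
// source:   world position of the x-ray source (mm)
// det00:    world position of the centre of detector pixel (row 0, col 0)
// duCol/dvRow: world steps (mm) per detector column / row
// step:     sampling step along the ray (mm)
// [[Rcpp::export]]
NumericMatrix drr_line_integrals(NumericVector mu, double spacing,
                                 NumericVector origin,
                                 NumericMatrix poseR, NumericVector poseT,
                                 NumericVector source, NumericVector det00,
                                 NumericVector duCol, NumericVector dvRow,
                                 int nCols, int nRows, double step) {
  IntegerVector dim = mu.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* pmu = mu.begin();

  // source in phantom frame: S_ph = R^T (S - t)
  double sw[3] = { source[0] - poseT[0], source[1] - poseT[1], source[2] - poseT[2] };
  double sp[3];
  for (int i = 0; i < 3; ++i)
    sp[i] = poseR(0, i) * sw[0] + poseR(1, i) * sw[1] + poseR(2, i) * sw[2];

  // grid bounding box in phantom frame (voxel edges, mm)
  double lo[3], hi[3];
  int nvox[3] = { nx, ny, nz };
  for (int i = 0; i < 3; ++i) {
    lo[i] = origin[i] - 0.5 * spacing;
    hi[i] = origin[i] + (nvox[i] - 0.5) * spacing;
  }

  NumericMatrix out(nRows, nCols);
  for (int c = 0; c < nCols; ++c) {
    for (int r = 0; r < nRows; ++r) {
      // pixel centre in world, then ray in phantom frame
      double pw[3], dw[3], dp[3];
      double len = 0.0;
      for (int i = 0; i < 3; ++i) {
        pw[i] = det00[i] + c * duCol[i] + r * dvRow[i];
        dw[i] = pw[i] - source[i];
        len += dw[i] * dw[i];
      }
      len = std::sqrt(len);
      for (int i = 0; i < 3; ++i) dw[i] /= len;
      for (int i = 0; i < 3; ++i)
        dp[i] = poseR(0, i) * dw[0] + poseR(1, i) * dw[1] + poseR(2, i) * dw[2];

      // clip ray to grid bounding box (slab method)
      double t0 = 0.0, t1 = len;
      bool miss = false;
      for (int i = 0; i < 3 && !miss; ++i) {
        if (std::fabs(dp[i]) < 1e-12) {
          if (sp[i] < lo[i] || sp[i] > hi[i]) miss = true;
        } else {
          double ta = (lo[i] - sp[i]) / dp[i];
          double tb = (hi[i] - sp[i]) / dp[i];
          if (ta > tb) std::swap(ta, tb);
          if (ta > t0) t0 = ta;
          if (tb < t1) t1 = tb;
          if (t0 >= t1) miss = true;
        }
      }
      if (miss) { out(r, c) = 0.0; continue; }

      int nstep = (int)std::ceil((t1 - t0) / step);
      if (nstep < 1) nstep = 1;
      double h = (t1 - t0) / nstep;
      double acc = 0.0;
      for (int k = 0; k <= nstep; ++k) {
        double tk = t0 + k * h;
        double fx = (sp[0] + tk * dp[0] - origin[0]) / spacing;
        double fy = (sp[1] + tk * dp[1] - origin[1]) / spacing;
        double fz = (sp[2] + tk * dp[2] - origin[2]) / spacing;
        double v = trilinear(pmu, nx, ny, nz, fx, fy, fz);
        acc += (k == 0 || k == nstep) ? 0.5 * v : v;
      }
      out(r, c) = acc * h;
    }
  }
  return out;
}

// Resample an image at positions displaced by (-dy, -dx) pixels, i.e. shift
// the image content by (+dx, +dy). Bilinear; out-of-bounds samples clamp to
// the nearest edge pixel. Integer shifts are exact relabelings.
// [[Rcpp::export]]
NumericMatrix bilinear_translate(NumericMatrix img, double dxPx, double dyPx) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    double sc = c - dxPx;
    if (sc < 0) sc = 0; else if (sc > nc - 1) sc = nc - 1;
    int c0 = (int)std::floor(sc);
    if (c0 > nc - 2) c0 = nc - 2;
    if (c0 < 0) c0 = 0;
    double wc = sc - c0;
    if (nc == 1) { c0 = 0; wc = 0.0; }
    for (int r = 0; r < nr; ++r) {
      double sr = r - dyPx;
      if (sr < 0) sr = 0; else if (sr > nr - 1) sr = nr - 1;
      int r0 = (int)std::floor(sr);
      if (r0 > nr - 2) r0 = nr - 2;
      if (r0 < 0) r0 = 0;
      double wr = sr - r0;
      if (nr == 1) { r0 = 0; wr = 0.0; }
      int r1 = (nr == 1) ? r0 : r0 + 1, c1 = (nc == 1) ? c0 : c0 + 1;
      out(r, c) = (1 - wr) * ((1 - wc) * img(r0, c0) + wc * img(r0, c1)) +
                  wr * ((1 - wc) * img(r1, c0) + wc * img(r1, c1));
    }
  }
  return out;
}
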