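#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Trilinear interpolation at continuous 0-based voxel coordinates.
// Returns `outside` for samples beyond the grid.
static inline double trilinear(const double *v, int nx, int ny, int nz,
                               double x, double y, double z, double outside) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return outside;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const double *p = v + (size_t)z0 * nx * ny + (size_t)y0 * nx + x0;
  size_t sx = 1, sy = nx, sz = (size_t)nx * ny;
  double c00 = p[0] * (1 - fx) + p[sx] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + sx] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + sx] * fx;
  double c11 = p[sz + sy] * (1 - fx) + p[sz + sy + sx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Ray / axis-aligned box intersection; returns false if the ray misses.
static inline bool rayBox(const double o[3], const double d[3],
                          const double lo[3], const double hi[3],
                          double &t0, double &t1) {
  t0 = 0.0;
  t1 = 1e30;
  for (int i = 0; i < 3; ++i) {
    if (std::fabs(d[i]) < 1e-12) {
      if (o[i] < lo[i] || o[i] > hi[i]) return false;
    } else {
      double a = (lo[i] - o[i]) / d[i], b = (hi[i] - o[i]) / d[i];
      if (a > b) std::swap(a, b);
      if (a > t0) t0 = a;
      if (b < t1) t1 = b;
      if (t0 > t1) return false;
    }
  }
  return true;
}

// Digital X-ray projection (DRR) of a posed volume onto a detector ROI.
//
// voxels:   3D HU array (dim attribute set), column-major x fastest
// spacing/origin: volume grid in world mm (LPS, 0-based indexing)
// src:      X-ray source position (world mm)
// dc:       detector centre position (world mm)
// uhat/vhat: detector in-plane unit vectors (world)
// cu, cv:   1-based (possibly fractional) pixel index of the detector centre
// ps:       detector pixel spacing mm
// u0..v1:   1-based inclusive ROI pixel index range
// trans/rotDeg/scale/centre: affine pose of the structure (Rz*Ry*Rx about centre)
// rayStep:  sampling step along rays, mm
// mode:     0 = hu_clamped (max(HU - huFloor, 0)/1000), 1 = binary mask
// Shared ray-casting core: fills img (nu x nv, column-major in u) with the
// DRR of the posed volume over the pixel ROI [u0..u1] x [v0..v1].
static void renderCore(const double *vox, int nx, int ny, int nz,
                       const double *spacing, const double *origin,
                       const double *src, const double *dc,
                       const double *uhat, const double *vhat, double cu,
                       double cv, double ps, int u0, int u1, int v0, int v1,
                       const double *trans, const double *rotDeg, double scale,
                       const double *centre, double rayStep, int mode,
                       double huFloor, double *img) {
  // rotation matrix R = Rz * Ry * Rx (degrees); we need the inverse map
  double d2r = M_PI / 180.0;
  double ax = rotDeg[0] * d2r, ay = rotDeg[1] * d2r, az = rotDeg[2] * d2r;
  double cx = std::cos(ax), sx = std::sin(ax);
  double cy = std::cos(ay), sy = std::sin(ay);
  double cz = std::cos(az), sz = std::sin(az);
  double R[3][3] = {
      {cz * cy, cz * sy * sx - sz * cx, cz * sy * cx + sz * sx},
      {sz * cy, sz * sy * sx + cz * cx, sz * sy * cx - cz * sx},
      {-sy, cy * sx, cy * cx}};

  // world AABB of the posed volume: transform the 8 grid corners forward
  double lo[3] = {1e30, 1e30, 1e30}, hi[3] = {-1e30, -1e30, -1e30};
  for (int c = 0; c < 8; ++c) {
    double p[3] = {origin[0] + ((c & 1) ? (nx - 1) * spacing[0] : 0.0),
                   origin[1] + ((c & 2) ? (ny - 1) * spacing[1] : 0.0),
                   origin[2] + ((c & 4) ? (nz - 1) * spacing[2] : 0.0)};
    double q[3];
    for (int i = 0; i < 3; ++i) {
      q[i] = centre[i] + trans[i];
      for (int j = 0; j < 3; ++j) q[i] += scale * R[i][j] * (p[j] - centre[j]);
    }
    for (int i = 0; i < 3; ++i) {
      if (q[i] < lo[i]) lo[i] = q[i];
      if (q[i] > hi[i]) hi[i] = q[i];
    }
  }

  int nu = u1 - u0 + 1, nv = v1 - v0 + 1;
  double invs = 1.0 / scale;

  for (int vi = 0; vi < nv; ++vi) {
    double vmm = ((v0 + vi) - cv) * ps;
    for (int ui = 0; ui < nu; ++ui) {
      double umm = ((u0 + ui) - cu) * ps;
      double P[3], dir[3], o[3];
      double len = 0.0;
      for (int i = 0; i < 3; ++i) {
        P[i] = dc[i] + umm * uhat[i] + vmm * vhat[i];
        dir[i] = P[i] - src[i];
        len += dir[i] * dir[i];
        o[i] = src[i];
      }
      len = std::sqrt(len);
      for (int i = 0; i < 3; ++i) dir[i] /= len;
      double t0, t1;
      double acc = 0.0, h = 0.0;
      if (rayBox(o, dir, lo, hi, t0, t1) && t1 > t0) {
        int nstep = (int)std::ceil((t1 - t0) / rayStep);
        if (nstep < 1) nstep = 1;
        h = (t1 - t0) / nstep;
        for (int s = 0; s <= nstep; ++s) {
          double t = t0 + s * h;
          double q[3] = {o[0] + t * dir[0], o[1] + t * dir[1],
                         o[2] + t * dir[2]};
          // inverse pose: p = centre + (1/s) R^T (q - centre - trans)
          double w[3];
          for (int i = 0; i < 3; ++i) {
            double a = 0.0;
            for (int j = 0; j < 3; ++j)
              a += R[j][i] * (q[j] - centre[j] - trans[j]);
            w[i] = centre[i] + invs * a;
          }
          double ix = (w[0] - origin[0]) / spacing[0];
          double iy = (w[1] - origin[1]) / spacing[1];
          double iz = (w[2] - origin[2]) / spacing[2];
          double val = trilinear(vox, nx, ny, nz, ix, iy, iz, 0.0);
          double g;
          if (mode == 1) {
            g = val;  // interpolated indicator
          } else {
            g = val - huFloor;
            if (g < 0) g = 0;
            g /= 1000.0;
          }
          acc += (s == 0 || s == nstep) ? 0.5 * g : g;  // trapezoid
        }
      }
      img[(size_t)vi * nu + ui] = acc * h;
    }
  }
}

// [[Rcpp::export(name = ".renderDRRcpp")]]
NumericMatrix renderDRRcpp(NumericVector voxels, NumericVector spacing,
                           NumericVector origin, NumericVector src,
                           NumericVector dc, NumericVector uhat,
                           NumericVector vhat, double cu, double cv, double ps,
                           int u0, int u1, int v0, int v1, NumericVector trans,
                           NumericVector rotDeg, double scale,
                           NumericVector centre, double rayStep, int mode,
                           double huFloor) {
  IntegerVector dim = voxels.attr("dim");
  int nu = u1 - u0 + 1, nv = v1 - v0 + 1;
  NumericMatrix out(nu, nv);
  renderCore(voxels.begin(), dim[0], dim[1], dim[2], spacing.begin(),
             origin.begin(), src.begin(), dc.begin(), uhat.begin(),
             vhat.begin(), cu, cv, ps, u0, u1, v0, v1, trans.begin(),
             rotDeg.begin(), scale, centre.begin(), rayStep, mode, huFloor,
             out.begin());
  return out;
}

// 3x3 binomial blur with replicated borders, matching the R helper.
static void blurInPlace(std::vector<double> &img, int nu, int nv, int passes) {
  if (nu < 3 || nv < 3) return;
  std::vector<double> tmp(img.size());
  for (int p = 0; p < passes; ++p) {
    for (int v = 0; v < nv; ++v) {
      const double *col = &img[(size_t)v * nu];
      double *t = &tmp[(size_t)v * nu];
      for (int u = 0; u < nu; ++u) {
        double a = col[u > 0 ? u - 1 : 0];
        double b = col[u];
        double c = col[u < nu - 1 ? u + 1 : nu - 1];
        t[u] = (a + 2 * b + c) / 4;
      }
    }
    for (int v = 0; v < nv; ++v) {
      int vm = v > 0 ? v - 1 : 0, vp = v < nv - 1 ? v + 1 : nv - 1;
      for (int u = 0; u < nu; ++u) {
        img[(size_t)v * nu + u] =
            (tmp[(size_t)vm * nu + u] + 2 * tmp[(size_t)v * nu + u] +
             tmp[(size_t)vp * nu + u]) / 4;
      }
    }
  }
}

// Gradient magnitude, central differences (one-sided borders), per mm;
// axes shorter than 3 pixels contribute zero, matching gradientMagnitude()
// in R (and avoiding out-of-bounds reads on degenerate ROIs).
static void gradMag(const std::vector<double> &img, int nu, int nv, double ps,
                    std::vector<double> &out) {
  for (int v = 0; v < nv; ++v) {
    for (int u = 0; u < nu; ++u) {
      double gu = 0.0, gv = 0.0;
      if (nu >= 3) {
        if (u == 0) gu = img[(size_t)v * nu + 1] - img[(size_t)v * nu];
        else if (u == nu - 1)
          gu = img[(size_t)v * nu + u] - img[(size_t)v * nu + u - 1];
        else
          gu = (img[(size_t)v * nu + u + 1] - img[(size_t)v * nu + u - 1]) / 2;
      }
      if (nv >= 3) {
        if (v == 0) gv = img[(size_t)nu + u] - img[u];
        else if (v == nv - 1)
          gv = img[(size_t)v * nu + u] - img[(size_t)(v - 1) * nu + u];
        else
          gv = (img[(size_t)(v + 1) * nu + u] - img[(size_t)(v - 1) * nu + u]) / 2;
      }
      out[(size_t)v * nu + u] = std::sqrt(gu * gu + gv * gv) / ps;
    }
  }
}

// Fused render + blur + gradient + correlation score for the search inner
// loop. scoreMode 0: Pearson correlation of the DRR edge strength against
// the reference strength over the whole ROI. scoreMode 1: correlation over
// the union of the percentile edge masks (the reported similarity score).
// refStrength/refMask are full-frame matrices at the evaluation level; the
// ROI indexes into them (1-based u0..v1).
// [[Rcpp::export(name = ".scoreDRRcpp")]]
double scoreDRRcpp(NumericVector voxels, NumericVector spacing,
                   NumericVector origin, NumericVector src, NumericVector dc,
                   NumericVector uhat, NumericVector vhat, double cu,
                   double cv, double ps, int u0, int u1, int v0, int v1,
                   NumericVector trans, NumericVector rotDeg, double scale,
                   NumericVector centre, double rayStep, int mode,
                   double huFloor, NumericMatrix refStrength,
                   LogicalMatrix refMask, int nblur, int scoreMode,
                   double qfrac) {
  IntegerVector dim = voxels.attr("dim");
  int nu = u1 - u0 + 1, nv = v1 - v0 + 1;
  size_t n = (size_t)nu * nv;
  std::vector<double> img(n);
  renderCore(voxels.begin(), dim[0], dim[1], dim[2], spacing.begin(),
             origin.begin(), src.begin(), dc.begin(), uhat.begin(),
             vhat.begin(), cu, cv, ps, u0, u1, v0, v1, trans.begin(),
             rotDeg.begin(), scale, centre.begin(), rayStep, mode, huFloor,
             img.data());
  blurInPlace(img, nu, nv, nblur);
  std::vector<double> sa(n);
  gradMag(img, nu, nv, ps, sa);

  int refNu = refStrength.nrow();
  const double *ref = refStrength.begin();
  const int *rmask = refMask.begin();

  auto pearson = [](const std::vector<double> &a, const std::vector<double> &b,
                    size_t m) -> double {
    double ma = 0, mb = 0;
    for (size_t i = 0; i < m; ++i) { ma += a[i]; mb += b[i]; }
    ma /= m; mb /= m;
    double saa = 0, sbb = 0, sab = 0;
    for (size_t i = 0; i < m; ++i) {
      double da = a[i] - ma, db = b[i] - mb;
      saa += da * da; sbb += db * db; sab += da * db;
    }
    if (saa < 1e-24 || sbb < 1e-24) return 0.0;
    return sab / std::sqrt(saa * sbb);
  };

  bool anyNz = false;
  for (size_t i = 0; i < n; ++i)
    if (sa[i] > 0) { anyNz = true; break; }
  if (!anyNz) return 0.0;

  if (scoreMode == 0) {
    std::vector<double> rv(n);
    for (int v = 0; v < nv; ++v)
      for (int u = 0; u < nu; ++u)
        rv[(size_t)v * nu + u] =
            ref[(size_t)(v0 - 1 + v) * refNu + (u0 - 1 + u)];
    return pearson(sa, rv, n);
  }

  // tighten the window to the DRR support (plus margin): the projected 3D
  // bounding box bulges well past the silhouette and would pull unrelated
  // neighbouring-vertebra edges into the mask union
  int su0 = nu, su1 = -1, sv0 = nv, sv1 = -1;
  for (int v = 0; v < nv; ++v)
    for (int u = 0; u < nu; ++u)
      if (img[(size_t)v * nu + u] > 1e-9) {
        if (u < su0) su0 = u;
        if (u > su1) su1 = u;
        if (v < sv0) sv0 = v;
        if (v > sv1) sv1 = v;
      }
  if (su1 < 0) return 0.0;
  su0 = std::max(0, su0 - 2); su1 = std::min(nu - 1, su1 + 2);
  sv0 = std::max(0, sv0 - 2); sv1 = std::min(nv - 1, sv1 + 2);

  // percentile (type-1 quantile) threshold of the nonzero strengths
  std::vector<double> nz;
  nz.reserve(n);
  for (int v = sv0; v <= sv1; ++v)
    for (int u = su0; u <= su1; ++u)
      if (sa[(size_t)v * nu + u] > 0) nz.push_back(sa[(size_t)v * nu + u]);
  if (nz.empty()) return 0.0;
  size_t k = (size_t)std::ceil(qfrac * nz.size());
  if (k < 1) k = 1;
  if (k > nz.size()) k = nz.size();
  std::nth_element(nz.begin(), nz.begin() + (k - 1), nz.end());
  double thr = nz[k - 1];

  std::vector<double> av, bv;
  av.reserve(n); bv.reserve(n);
  for (int v = sv0; v <= sv1; ++v) {
    for (int u = su0; u <= su1; ++u) {
      size_t i = (size_t)v * nu + u;
      size_t ri = (size_t)(v0 - 1 + v) * refNu + (u0 - 1 + u);
      if (sa[i] > thr || rmask[ri]) {
        av.push_back(sa[i]);
        bv.push_back(ref[ri]);
      }
    }
  }
  if (av.size() < 3) return 0.0;
  return pearson(av, bv, av.size());
}
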