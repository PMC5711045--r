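#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear sample of a volume at continuous 0-based index coordinates.
// Points outside the voxel-centre hull contribute 0 (object is padded by air).
static inline double sample3(const double *v, const int nx, const int ny,
                             const int nz, const double x, const double y,
                             const double z) {
  if (x < 0.0 || y < 0.0 || z < 0.0 ||
      x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0)
    return 0.0;
  int i0 = (int)x; if (i0 > nx - 2) i0 = nx - 2;
  int j0 = (int)y; if (j0 > ny - 2) j0 = ny - 2;
  int k0 = (int)z; if (k0 > nz - 2) k0 = nz - 2;
  const double fx = x - i0, fy = y - j0, fz = z - k0;
  const R_xlen_t s = i0 + (R_xlen_t)nx * (j0 + (R_xlen_t)ny * k0);
  const R_xlen_t dy = nx, dz = (R_xlen_t)nx * ny;
  const double c00 = v[s]          * (1 - fx) + v[s + 1]          * fx;
  const double c10 = v[s + dy]     * (1 - fx) + v[s + dy + 1]     * fx;
  const double c01 = v[s + dz]     * (1 - fx) + v[s + dz + 1]     * fx;
  const double c11 = v[s + dy + dz]* (1 - fx) + v[s + dy + dz + 1]* fx;
  return ((1 - fy) * c00 + fy * c10) * (1 - fz) +
         ((1 - fy) * c01 + fy * c11) * fz;
}

// Clip parametric interval [t0,t1] of ray p(t)=s+t*r against slab [lo,hi].
static inline bool clip1(const double s, const double r, const double lo,
                         const double hi, double &t0, double &t1) {
  if (std::fabs(r) < 1e-12) return s >= lo && s <= hi;
  const double ta = (lo - s) / r, tb = (hi - s) / r;
  const double tmin = ta < tb ? ta : tb, tmax = ta < tb ? tb : ta;
  if (tmin > t0) t0 = tmin;
  if (tmax < t1) t1 = tmax;
  return t0 < t1;
}

// Cone-beam line integrals of a (rigidly z-shifted) volume.
// Source at angle b: (sad cos b, sad sin b, 0); flat detector through the
// point -(sdd-sad)(cos b, sin b, 0), axes e_u = (-sin b, cos b, 0),
// e_v = (0,0,1); detector u offset by u_offset (displaced-detector half-fan).
// zshifts[a] is the phantom displacement at the a-th projection time.
// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector vol, IntegerVector vdim,
                                  NumericVector spacing, NumericVector origin,
                                  NumericVector angles, NumericVector zshifts,
                                  double sad, double sdd, int nu, int nv,
                                  double du, double dv, double u_offset,
                                  double step) {
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2];
  const double *v = REAL(vol);
  const int na = angles.size();
  NumericVector out((R_xlen_t)nu * nv * na);
  const double x0 = origin[0], y0 = origin[1], z0 = origin[2];
  const double sx_ = spacing[0], sy_ = spacing[1], sz_ = spacing[2];
  const double x1 = x0 + (nx - 1) * sx_;
  const double y1 = y0 + (ny - 1) * sy_;
  const double z1 = z0 + (nz - 1) * sz_;
  for (int a = 0; a < na; a++) {
    const double cb = std::cos(angles[a]), sb = std::sin(angles[a]);
    const double srcx = sad * cb, srcy = sad * sb;
    const double dcx = -(sdd - sad) * cb, dcy = -(sdd - sad) * sb;
    const double zs = zshifts[a];
    // shift the sampling bounds instead of the phantom: exact for rigid 1D motion
    const double zlo = z0 + zs, zhi = z1 + zs;
    for (int j = 0; j < nv; j++) {
      const double vv = (j - (nv - 1) / 2.0) * dv;
      for (int i = 0; i < nu; i++) {
        const double uu = (i - (nu - 1) / 2.0) * du + u_offset;
        const double px = dcx + uu * (-sb), py = dcy + uu * cb, pz = vv;
        double rx = px - srcx, ry = py - srcy, rz = pz;
        const double len = std::sqrt(rx * rx + ry * ry + rz * rz);
        rx /= len; ry /= len; rz /= len;
        double t0 = 0.0, t1 = len;
        double val = 0.0;
        if (clip1(srcx, rx, x0, x1, t0, t1) &&
            clip1(srcy, ry, y0, y1, t0, t1) &&
            clip1(0.0,  rz, zlo, zhi, t0, t1) && t1 > t0) {
          const int ns = (int)std::ceil((t1 - t0) / step);
          const double h = (t1 - t0) / ns;
          double acc = 0.0;
          for (int m = 0; m < ns; m++) {
            const double t = t0 + (m + 0.5) * h;
            acc += sample3(v, nx, ny, nz,
                           (srcx + t * rx - x0) / sx_,
                           (srcy + t * ry - y0) / sy_,
                           (t * rz - zs - z0) / sz_);
          }
          val = acc * h;
        }
        out[i + (R_xlen_t)nu * (j + (R_xlen_t)nv * a)] = val;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nu, nv, na);
  return out;
}

// Voxel-driven FDK backprojection of filtered, redundancy-weighted projections.
// Projections are indexed on the virtual detector through the isocentre:
// column i at u = u0 + i*du, row j at v = v0 + j*dv (mm at isocentre scale).
// wbeta[a] carries d(beta) and any trapezoid end weighting.
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector proj, IntegerVector pdim,
                              NumericVector angles, NumericVector wbeta,
                              double sad, double u0, double du, double v0,
                              double dv, IntegerVector gdim,
                              NumericVector spacing, NumericVector origin) {
  const int nu = pdim[0], nv = pdim[1], na = pdim[2];
  const int nx = gdim[0], ny = gdim[1], nz = gdim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  double *o = REAL(out);
  const double *p = REAL(proj);
  for (int a = 0; a < na; a++) {
    const double cb = std::cos(angles[a]), sb = std::sin(angles[a]);
    const double w = wbeta[a];
    const double *pa = p + (R_xlen_t)nu * nv * a;
    R_xlen_t idx = 0;
    for (int k = 0; k < nz; k++) {
      const double z = origin[2] + k * spacing[2];
      for (int j = 0; j < ny; j++) {
        const double y = origin[1] + j * spacing[1];
        for (int i = 0; i < nx; i++, idx++) {
          const double x = origin[0] + i * spacing[0];
          const double L = sad - (x * cb + y * sb);
          if (L < 1e-6) continue;
          const double ui = (sad * (-x * sb + y * cb) / L - u0) / du;
          const double vi = (sad * z / L - v0) / dv;
          if (ui < 0.0 || vi < 0.0 || ui > nu - 1.0 || vi > nv - 1.0)
            continue;
          int iu = (int)ui; if (iu > nu - 2) iu = nu - 2;
          int iv = (int)vi; if (iv > nv - 2) iv = nv - 2;
          const double fu = ui - iu, fv = vi - iv;
          const R_xlen_t s = iu + (R_xlen_t)nu * iv;
          const double val =
              (1 - fv) * ((1 - fu) * pa[s] + fu * pa[s + 1]) +
              fv * ((1 - fu) * pa[s + nu] + fu * pa[s + nu + 1]);
          o[idx] += w * (sad * sad) / (L * L) * val;
        }
      }
    }
  }
  out.attr("dim") = gdim;
  return out;
}
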