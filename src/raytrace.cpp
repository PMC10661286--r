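// Cone-beam projection operators.
//
// Coordinate convention (documented once, used everywhere):
//   - Right-handed world frame, isocenter at the volume center, units mm.
//   - Voxel (i,j,k) (0-based) has center ((i-(nx-1)/2)*p, (j-(ny-1)/2)*p,
//     (k-(nz-1)/2)*p) for isotropic pitch p.
//   - At view angle beta (radians, counterclockwise seen from +z) the source
//     sits at sid*(cos b, sin b, 0); the flat detector is centered on the ray
//     through the isocenter at distance sdd from the source, with in-plane
//     axis e_u = (-sin b, cos b, 0) and axial axis e_v = (0,0,1).
//   - Attenuation is in 1/cm; distances in mm, so line integrals carry a
//     factor 1/10.
//
// The forward projector samples each source->detector-cell ray at a fixed
// step (<= half the voxel pitch) with trilinear interpolation; the ray
// backprojector is its exact matrix transpose (scatter with the same sample
// positions and weights), which is what OS-SART and the adjoint identity
// require. FDK uses a separate voxel-driven backprojector with bilinear
// detector interpolation and the fan/cone distance weight.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

namespace {

struct Geom {
  int nx, ny, nz;
  double pitch;       // voxel pitch, mm
  int nu, nv;         // detector columns (in-plane) and rows (axial)
  double du, dv;      // detector pitch, mm
  double sid, sdd;    // source-isocenter, source-detector distances, mm
  double step;        // requested ray sampling step, mm
  double hx, hy, hz;  // half-extents of the volume box, mm
};

// Clip ray S + t*d (|d| = 1) against the volume box; returns false if no hit.
inline bool clip_box(const Geom& g, const double S[3], const double d[3],
                     double& t0, double& t1) {
  t0 = 0.0;
  t1 = 1e30;
  const double h[3] = {g.hx, g.hy, g.hz};
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-12) {
      if (S[a] < -h[a] || S[a] > h[a]) return false;
    } else {
      double ta = (-h[a] - S[a]) / d[a];
      double tb = (h[a] - S[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  return t1 > t0;
}

inline void ray_endpoints(const Geom& g, double cb, double sb,
                          int iu, int iv, double S[3], double P[3]) {
  const double u = (iu - (g.nu - 1) * 0.5) * g.du;
  const double v = (iv - (g.nv - 1) * 0.5) * g.dv;
  S[0] = g.sid * cb;
  S[1] = g.sid * sb;
  S[2] = 0.0;
  const double dc = g.sdd - g.sid;  // isocenter -> detector center
  P[0] = -dc * cb - u * sb;
  P[1] = -dc * sb + u * cb;
  P[2] = v;
}

inline Geom make_geom(const IntegerVector& dims, double pitch, int nu, int nv,
                      double du, double dv, double sid, double sdd,
                      double step) {
  Geom g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.pitch = pitch; g.nu = nu; g.nv = nv; g.du = du; g.dv = dv;
  g.sid = sid; g.sdd = sdd; g.step = step;
  g.hx = 0.5 * g.nx * pitch;
  g.hy = 0.5 * g.ny * pitch;
  g.hz = 0.5 * g.nz * pitch;
  return g;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector vol, IntegerVector dims,
                                  double pitch, NumericVector angles, int nu,
                                  int nv, double du, double dv, double sid,
                                  double sdd, double step) {
  const Geom g = make_geom(dims, pitch, nu, nv, du, dv, sid, sdd, step);
  const int nviews = angles.size();
  NumericVector out((R_xlen_t)nu * nv * nviews);
  const double* V = vol.begin();
  const double cx = (g.nx - 1) * 0.5, cy = (g.ny - 1) * 0.5,
               cz = (g.nz - 1) * 0.5;
  for (int w = 0; w < nviews; ++w) {
    const double cb = std::cos(angles[w]), sb = std::sin(angles[w]);
    for (int iv = 0; iv < nv; ++iv) {
      for (int iu = 0; iu < nu; ++iu) {
        double S[3], P[3];
        ray_endpoints(g, cb, sb, iu, iv, S, P);
        double d[3] = {P[0] - S[0], P[1] - S[1], P[2] - S[2]};
        const double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
        d[0] /= L; d[1] /= L; d[2] /= L;
        double t0, t1;
        if (!clip_box(g, S, d, t0, t1)) continue;
        const int n = (int)std::ceil((t1 - t0) / g.step);
        if (n <= 0) continue;
        const double dt = (t1 - t0) / n;
        double acc = 0.0;
        for (int m = 0; m < n; ++m) {
          const double t = t0 + (m + 0.5) * dt;
          const double gx = (S[0] + t * d[0]) / g.pitch + cx;
          const double gy = (S[1] + t * d[1]) / g.pitch + cy;
          const double gz = (S[2] + t * d[2]) / g.pitch + cz;
          const int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy),
                    k0 = (int)std::floor(gz);
          const double fx = gx - i0, fy = gy - j0, fz = gz - k0;
          for (int dk = 0; dk < 2; ++dk) {
            const int k = k0 + dk;
            if (k < 0 || k >= g.nz) continue;
            const double wz = dk ? fz : 1.0 - fz;
            for (int dj = 0; dj < 2; ++dj) {
              const int j = j0 + dj;
              if (j < 0 || j >= g.ny) continue;
              const double wy = dj ? fy : 1.0 - fy;
              for (int di = 0; di < 2; ++di) {
                const int i = i0 + di;
                if (i < 0 || i >= g.nx) continue;
                const double wx = di ? fx : 1.0 - fx;
                acc += wx * wy * wz *
                       V[(R_xlen_t)k * g.nx * g.ny + (R_xlen_t)j * g.nx + i];
              }
            }
          }
        }
        out[(R_xlen_t)w * nu * nv + (R_xlen_t)iv * nu + iu] =
            acc * dt * 0.1;  // mm -> cm
      }
    }
  }
  return out;
}

// Exact transpose of cpp_forward_project (same rays, same samples, same
// weights, scatter instead of gather).
// [[Rcpp::export]]
NumericVector cpp_backproject_ray(NumericVector proj, IntegerVector dims,
                                  double pitch, NumericVector angles, int nu,
                                  int nv, double du, double dv, double sid,
                                  double sdd, double step) {
  const Geom g = make_geom(dims, pitch, nu, nv, du, dv, sid, sdd, step);
  const int nviews = angles.size();
  NumericVector out((R_xlen_t)g.nx * g.ny * g.nz);
  double* V = out.begin();
  const double cx = (g.nx - 1) * 0.5, cy = (g.ny - 1) * 0.5,
               cz = (g.nz - 1) * 0.5;
  for (int w = 0; w < nviews; ++w) {
    const double cb = std::cos(angles[w]), sb = std::sin(angles[w]);
    for (int iv = 0; iv < nv; ++iv) {
      for (int iu = 0; iu < nu; ++iu) {
        const double pv =
            proj[(R_xlen_t)w * nu * nv + (R_xlen_t)iv * nu + iu];
        if (pv == 0.0) continue;
        double S[3], P[3];
        ray_endpoints(g, cb, sb, iu, iv, S, P);
        double d[3] = {P[0] - S[0], P[1] - S[1], P[2] - S[2]};
        const double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
        d[0] /= L; d[1] /= L; d[2] /= L;
        double t0, t1;
        if (!clip_box(g, S, d, t0, t1)) continue;
        const int n = (int)std::ceil((t1 - t0) / g.step);
        if (n <= 0) continue;
        const double dt = (t1 - t0) / n;
        const double val = pv * dt * 0.1;
        for (int m = 0; m < n; ++m) {
          const double t = t0 + (m + 0.5) * dt;
          const double gx = (S[0] + t * d[0]) / g.pitch + cx;
          const double gy = (S[1] + t * d[1]) / g.pitch + cy;
          const double gz = (S[2] + t * d[2]) / g.pitch + cz;
          const int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy),
                    k0 = (int)std::floor(gz);
          const double fx = gx - i0, fy = gy - j0, fz = gz - k0;
          for (int dk = 0; dk < 2; ++dk) {
            const int k = k0 + dk;
            if (k < 0 || k >= g.nz) continue;
            const double wz = dk ? fz : 1.0 - fz;
            for (int dj = 0; dj < 2; ++dj) {
              const int j = j0 + dj;
              if (j < 0 || j >= g.ny) continue;
              const double wy = dj ? fy : 1.0 - fy;
              for (int di = 0; di < 2; ++di) {
                const int i = i0 + di;
                if (i < 0 || i >= g.nx) continue;
                const double wx = di ? fx : 1.0 - fx;
                V[(R_xlen_t)k * g.nx * g.ny + (R_xlen_t)j * g.nx + i] +=
                    wx * wy * wz * val;
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// FDK voxel-driven backprojection of filtered projections resampled to the
// virtual detector through the isocenter (pitches du_iso, dv_iso). Applies
// the (sid / (sid - s))^2 distance weight; the caller multiplies by
// delta_beta / 2.
// [[Rcpp::export]]
NumericVector cpp_fdk_backproject(NumericVector q, int nu, int nv,
                                  NumericVector angles, double du_iso,
                                  double dv_iso, double sid,
                                  IntegerVector dims, double pitch) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nviews = angles.size();
  NumericVector out((R_xlen_t)nx * ny * nz);
  double* V = out.begin();
  const double* Q = q.begin();
  std::vector<double> xs(nx), ys(ny), zs(nz);
  for (int i = 0; i < nx; ++i) xs[i] = (i - (nx - 1) * 0.5) * pitch;
  for (int j = 0; j < ny; ++j) ys[j] = (j - (ny - 1) * 0.5) * pitch;
  for (int k = 0; k < nz; ++k) zs[k] = (k - (nz - 1) * 0.5) * pitch;
  for (int w = 0; w < nviews; ++w) {
    const double cb = std::cos(angles[w]), sb = std::sin(angles[w]);
    const double* Qw = Q + (R_xlen_t)w * nu * nv;
    for (int k = 0; k < nz; ++k) {
      const double z = zs[k];
      for (int j = 0; j < ny; ++j) {
        const double y = ys[j];
        for (int i = 0; i < nx; ++i) {
          const double x = xs[i];
          const double s = x * cb + y * sb;      // toward the source
          const double l = sid - s;
          if (l <= 1e-6) continue;
          const double wgt = (sid / l) * (sid / l);
          const double up = sid * (-x * sb + y * cb) / l;
          const double vp = sid * z / l;
          const double gu = up / du_iso + (nu - 1) * 0.5;
          const double gv = vp / dv_iso + (nv - 1) * 0.5;
          const int u0 = (int)std::floor(gu), v0 = (int)std::floor(gv);
          if (u0 < -1 || u0 > nu - 1 || v0 < -1 || v0 > nv - 1) continue;
          const double fu = gu - u0, fv = gv - v0;
          double acc = 0.0;
          for (int dvv = 0; dvv < 2; ++dvv) {
            const int vq = v0 + dvv;
            if (vq < 0 || vq >= nv) continue;
            const double wv = dvv ? fv : 1.0 - fv;
            for (int duu = 0; duu < 2; ++duu) {
              const int uq = u0 + duu;
              if (uq < 0 || uq >= nu) continue;
              const double wu = duu ? fu : 1.0 - fu;
              acc += wu * wv * Qw[(R_xlen_t)vq * nu + uq];
            }
          }
          V[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i] += wgt * acc;
        }
      }
    }
  }
  return out;
}

// 6-connected components of a logical 3D mask; labels 1..ncomp, 0 outside.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  int next = 0;
  std::vector<R_xlen_t> stack;
  const int di[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, 1, -1};
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t c = stack.back();
      stack.pop_back();
      const int i = (int)(c % nx);
      const int j = (int)((c / nx) % ny);
      const int k = (int)(c / ((R_xlen_t)nx * ny));
      for (int d = 0; d < 6; ++d) {
        const int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        const R_xlen_t cc = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
        if (mask[cc] && !lab[cc]) {
          lab[cc] = next;
          stack.push_back(cc);
        }
      }
    }
  }
  lab.attr("ncomp") = next;
  return lab;
}
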