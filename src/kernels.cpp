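// Low-level numerical kernels: half-spheroid voxelization, in-plane rotation
// (gather/scatter adjoint pair for the projector), affine trilinear
// resampling, separable Gaussian convolution, trilinear point sampling and
// 6-connected component labelling.
//
// Conventions: arrays are column-major nx x ny x nz; voxel (i,j,k) (0-based)
// has world position (i*vx, j*vy, k*vz) mm, i.e. the R-level 1-based voxel
// (1,1,1) sits at the world origin.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (long long)ny * k);
}

// Fractional voxel occupancy of a half prolate spheroid: the region
// { p : 0 <= (p - base).u <= c,  rho(p) <= a * sqrt(1 - (zeta/c)^2) }
// where u is the unit vector from the basal (valve) plane towards the apex.
// nsub^3 subsamples per voxel.
// [[Rcpp::export]]
NumericVector cpp_voxelize_halfspheroid(IntegerVector dim, NumericVector vox,
                                        NumericVector base_centre,
                                        NumericVector apex_dir,
                                        double a, double c, int nsub) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  if (a <= 0.0 || c <= 0.0) return out;
  const double ux = apex_dir[0], uy = apex_dir[1], uz = apex_dir[2];
  const double bx = base_centre[0], by = base_centre[1], bz = base_centre[2];
  // bounding box: segment base..base+c*u dilated by a (plus one voxel margin)
  double lo[3], hi[3];
  const double u3[3] = {ux, uy, uz}, b3[3] = {bx, by, bz};
  for (int d = 0; d < 3; ++d) {
    double e0 = b3[d], e1 = b3[d] + c * u3[d];
    lo[d] = std::min(e0, e1) - a - vox[d];
    hi[d] = std::max(e0, e1) + a + vox[d];
  }
  int i0 = std::max(0, (int)std::floor(lo[0] / vox[0]));
  int i1 = std::min(nx - 1, (int)std::ceil(hi[0] / vox[0]));
  int j0 = std::max(0, (int)std::floor(lo[1] / vox[1]));
  int j1 = std::min(ny - 1, (int)std::ceil(hi[1] / vox[1]));
  int k0 = std::max(0, (int)std::floor(lo[2] / vox[2]));
  int k1 = std::min(nz - 1, (int)std::ceil(hi[2] / vox[2]));
  std::vector<double> off(nsub);
  for (int s = 0; s < nsub; ++s) off[s] = (s + 0.5) / nsub - 0.5;
  const double inv_sub = 1.0 / (nsub * (double)nsub * nsub);
  for (int k = k0; k <= k1; ++k) {
    for (int j = j0; j <= j1; ++j) {
      for (int i = i0; i <= i1; ++i) {
        int inside = 0;
        const double cx = i * vox[0] - bx, cy = j * vox[1] - by,
                     cz = k * vox[2] - bz;
        for (int sk = 0; sk < nsub; ++sk) {
          const double pz = cz + off[sk] * vox[2];
          for (int sj = 0; sj < nsub; ++sj) {
            const double py = cy + off[sj] * vox[1];
            for (int si = 0; si < nsub; ++si) {
              const double px = cx + off[si] * vox[0];
              const double zeta = px * ux + py * uy + pz * uz;
              if (zeta < 0.0 || zeta > c) continue;
              const double rx = px - zeta * ux, ry = py - zeta * uy,
                           rz = pz - zeta * uz;
              const double rho2 = rx * rx + ry * ry + rz * rz;
              const double s = 1.0 - (zeta / c) * (zeta / c);
              if (rho2 <= a * a * s) ++inside;
            }
          }
        }
        if (inside) out[idx3(i, j, k, nx, ny)] = inside * inv_sub;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// In-plane rotation about the grid centre of every z-slice.
// gather: out(p) = in(centre + R(theta) * (p - centre))  (bilinear)
// scatter: exact adjoint of the gather (same weights, scattered).
// [[Rcpp::export]]
NumericVector cpp_rotate_z(NumericVector vol, double theta, bool scatter) {
  IntegerVector dim = vol.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double ct = std::cos(theta), st = std::sin(theta);
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  for (int k = 0; k < nz; ++k) {
    const double *in_s = &vol[(R_xlen_t)nx * ny * k];
    double *out_s = &out[(R_xlen_t)nx * ny * k];
    for (int j = 0; j < ny; ++j) {
      const double dy = j - cy;
      for (int i = 0; i < nx; ++i) {
        const double dx = i - cx;
        const double sx = cx + ct * dx - st * dy;
        const double sy = cy + st * dx + ct * dy;
        const int fx = (int)std::floor(sx), fy = (int)std::floor(sy);
        if (fx < -1 || fx > nx - 1 || fy < -1 || fy > ny - 1) continue;
        const double ax = sx - fx, ay = sy - fy;
        const double w00 = (1 - ax) * (1 - ay), w10 = ax * (1 - ay),
                     w01 = (1 - ax) * ay, w11 = ax * ay;
        const bool okx0 = fx >= 0, okx1 = fx + 1 <= nx - 1;
        const bool oky0 = fy >= 0, oky1 = fy + 1 <= ny - 1;
        if (!scatter) {
          double v = 0.0;
          if (okx0 && oky0) v += w00 * in_s[fx + nx * fy];
          if (okx1 && oky0) v += w10 * in_s[fx + 1 + nx * fy];
          if (okx0 && oky1) v += w01 * in_s[fx + nx * (fy + 1)];
          if (okx1 && oky1) v += w11 * in_s[fx + 1 + nx * (fy + 1)];
          out_s[i + nx * j] = v;
        } else {
          const double v = in_s[i + nx * j];
          if (v == 0.0) continue;
          if (okx0 && oky0) out_s[fx + nx * fy] += w00 * v;
          if (okx1 && oky0) out_s[fx + 1 + nx * fy] += w10 * v;
          if (okx0 && oky1) out_s[fx + nx * (fy + 1)] += w01 * v;
          if (okx1 && oky1) out_s[fx + 1 + nx * (fy + 1)] += w11 * v;
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// General affine trilinear resample:
// out(p) = in(centre_in + R * (p - centre_out)), coordinates in voxels.
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector vol, NumericMatrix R,
                                  NumericVector centre_out,
                                  NumericVector centre_in,
                                  IntegerVector out_dim) {
  IntegerVector dim = vol.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  for (int k = 0; k < oz; ++k) {
    const double dz = k - centre_out[2];
    for (int j = 0; j < oy; ++j) {
      const double dy = j - centre_out[1];
      for (int i = 0; i < ox; ++i) {
        const double dx = i - centre_out[0];
        const double sx = centre_in[0] + R(0,0)*dx + R(0,1)*dy + R(0,2)*dz;
        const double sy = centre_in[1] + R(1,0)*dx + R(1,1)*dy + R(1,2)*dz;
        const double sz = centre_in[2] + R(2,0)*dx + R(2,1)*dy + R(2,2)*dz;
        const int fx = (int)std::floor(sx), fy = (int)std::floor(sy),
                  fz = (int)std::floor(sz);
        if (fx < -1 || fx > nx - 1 || fy < -1 || fy > ny - 1 ||
            fz < -1 || fz > nz - 1) continue;
        const double ax = sx - fx, ay = sy - fy, az = sz - fz;
        double v = 0.0;
        for (int dk = 0; dk <= 1; ++dk) {
          const int zz = fz + dk;
          if (zz < 0 || zz > nz - 1) continue;
          const double wz = dk ? az : 1 - az;
          for (int dj = 0; dj <= 1; ++dj) {
            const int yy = fy + dj;
            if (yy < 0 || yy > ny - 1) continue;
            const double wy = dj ? ay : 1 - ay;
            for (int di = 0; di <= 1; ++di) {
              const int xx = fx + di;
              if (xx < 0 || xx > nx - 1) continue;
              const double wx = di ? ax : 1 - ax;
              v += wx * wy * wz * vol[idx3(xx, yy, zz, nx, ny)];
            }
          }
        }
        out[idx3(i, j, k, ox, oy)] = v;
      }
    }
  }
  out.attr("dim") = out_dim;
  return out;
}

// Separable Gaussian convolution, zero padding; sigma per axis in voxels.
// [[Rcpp::export]]
NumericVector cpp_gauss_sep(NumericVector vol, NumericVector sigma) {
  IntegerVector dim = vol.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector cur = clone(vol);
  const int n[3] = {nx, ny, nz};
  const int stride[3] = {1, nx, nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma[ax];
    if (s <= 0.0) continue;
    const int r = std::max(1, (int)std::ceil(4.0 * s));
    std::vector<double> ker(2 * r + 1);
    double sum = 0.0;
    for (int t = -r; t <= r; ++t) {
      ker[t + r] = std::exp(-0.5 * t * t / (s * s));
      sum += ker[t + r];
    }
    for (auto &w : ker) w /= sum;
    NumericVector nxt((R_xlen_t)nx * ny * nz);
    const int len = n[ax], str = stride[ax];
    // iterate over all lines along axis ax
    const int n1 = n[(ax + 1) % 3], n2 = n[(ax + 2) % 3];
    const int s1 = stride[(ax + 1) % 3], s2 = stride[(ax + 2) % 3];
    for (int b = 0; b < n2; ++b) {
      for (int a2 = 0; a2 < n1; ++a2) {
        const R_xlen_t base = (R_xlen_t)a2 * s1 + (R_xlen_t)b * s2;
        for (int t = 0; t < len; ++t) {
          double v = 0.0;
          const int lo = std::max(0, t - r), hi = std::min(len - 1, t + r);
          for (int q = lo; q <= hi; ++q)
            v += ker[q - t + r] * cur[base + (R_xlen_t)q * str];
          nxt[base + (R_xlen_t)t * str] = v;
        }
      }
    }
    cur = nxt;
  }
  cur.attr("dim") = dim;
  return cur;
}

// Trilinear sampling at arbitrary 0-based voxel coordinates (n x 3 matrix).
// Returns values; points outside the grid sample as 0 and are flagged.
// [[Rcpp::export]]
List cpp_trilinear_sample(NumericVector vol, NumericMatrix pts) {
  IntegerVector dim = vol.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  NumericVector val(n);
  LogicalVector inside(n);
  for (int p = 0; p < n; ++p) {
    const double sx = pts(p, 0), sy = pts(p, 1), sz = pts(p, 2);
    inside[p] = (sx >= 0 && sx <= nx - 1 && sy >= 0 && sy <= ny - 1 &&
                 sz >= 0 && sz <= nz - 1);
    const int fx = (int)std::floor(sx), fy = (int)std::floor(sy),
              fz = (int)std::floor(sz);
    if (fx < -1 || fx > nx - 1 || fy < -1 || fy > ny - 1 || fz < -1 ||
        fz > nz - 1) { val[p] = 0.0; continue; }
    const double ax = sx - fx, ay = sy - fy, az = sz - fz;
    double v = 0.0;
    for (int dk = 0; dk <= 1; ++dk) {
      const int zz = fz + dk;
      if (zz < 0 || zz > nz - 1) continue;
      const double wz = dk ? az : 1 - az;
      for (int dj = 0; dj <= 1; ++dj) {
        const int yy = fy + dj;
        if (yy < 0 || yy > ny - 1) continue;
        const double wy = dj ? ay : 1 - ay;
        for (int di = 0; di <= 1; ++di) {
          const int xx = fx + di;
          if (xx < 0 || xx > nx - 1) continue;
          const double wx = di ? ax : 1 - ax;
          v += wx * wy * wz * vol[idx3(xx, yy, zz, nx, ny)];
        }
      }
    }
    val[p] = v;
  }
  return List::create(_["values"] = val, _["inside"] = inside);
}

// 6-connected component labelling of a logical mask.
// [[Rcpp::export]]
IntegerVector cpp_label_cc(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab((R_xlen_t)nx * ny * nz);
  int next = 0;
  std::queue<int> q;
  const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int v0 = idx3(i, j, k, nx, ny);
        if (!mask[v0] || lab[v0]) continue;
        lab[v0] = ++next;
        q.push(v0);
        while (!q.empty()) {
          const int v = q.front(); q.pop();
          const int ck = v / (nx * ny), cj = (v / nx) % ny, ci = v % nx;
          for (int d = 0; d < 6; ++d) {
            const int ii = ci + d6[d][0], jj = cj + d6[d][1],
                      kk = ck + d6[d][2];
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 ||
                kk >= nz) continue;
            const int w = idx3(ii, jj, kk, nx, ny);
            if (mask[w] && !lab[w]) { lab[w] = next; q.push(w); }
          }
        }
      }
  lab.attr("dim") = dim;
  return lab;
}
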