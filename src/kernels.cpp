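// Numerical kernels: interpolation, separable filters, non-local-means,
// node-based local cross-correlation search, Jacobians and the neighborhood
// Taylor reconstruction used by the spatio-temporal regularizer.
//
// Conventions: 3D arrays are column-major (R layout), voxel indices 0-based,
// index = i + nx*(j + ny*k). Displacement vectors are world-space mm.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double getvox(const double* d, int nx, int ny, int nz,
                            int i, int j, int k) {
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0.0;
  return d[i + (size_t)nx * (j + (size_t)ny * k)];
}

// Keys cubic convolution kernel (a = -0.5), 4-point support.
static inline double cubwt(double t) {
  t = std::fabs(t);
  if (t < 1.0) return 1.0 + t * t * (-2.5 + 1.5 * t);
  if (t < 2.0) return 2.0 + t * (-4.0 + t * (2.5 - 0.5 * t));
  return 0.0;
}

static inline double interp_tri(const double* d, int nx, int ny, int nz,
                                double x, double y, double z) {
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double v = 0.0;
  for (int dk = 0; dk <= 1; ++dk)
    for (int dj = 0; dj <= 1; ++dj)
      for (int di = 0; di <= 1; ++di) {
        double w = (di ? fx : 1.0 - fx) * (dj ? fy : 1.0 - fy) *
                   (dk ? fz : 1.0 - fz);
        if (w != 0.0) v += w * getvox(d, nx, ny, nz, i0 + di, j0 + dj, k0 + dk);
      }
  return v;
}

static inline double interp_cub(const double* d, int nx, int ny, int nz,
                                double x, double y, double z) {
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double wx[4], wy[4], wz[4];
  for (int m = -1; m <= 2; ++m) {
    wx[m + 1] = cubwt(fx - m);
    wy[m + 1] = cubwt(fy - m);
    wz[m + 1] = cubwt(fz - m);
  }
  double v = 0.0;
  for (int dk = -1; dk <= 2; ++dk) {
    if (wz[dk + 1] == 0.0) continue;
    for (int dj = -1; dj <= 2; ++dj) {
      double wyz = wy[dj + 1] * wz[dk + 1];
      if (wyz == 0.0) continue;
      for (int di = -1; di <= 2; ++di)
        v += wx[di + 1] * wyz * getvox(d, nx, ny, nz, i0 + di, j0 + dj, k0 + dk);
    }
  }
  return v;
}

// Sample a 3D volume at world points. affinv is the 4x4 world-to-voxel
// (0-based) matrix of the volume, column-major. order: 1 = trilinear,
// 4 = cubic (4-point) convolution. Outside the extent the value is 0.
// [[Rcpp::export]]
NumericVector cpp_sample_volume(NumericVector data, IntegerVector dims,
                                NumericMatrix affinv, NumericMatrix pts,
                                int order) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = pts.nrow();
  NumericVector out(n);
  const double* d = data.begin();
  double a00 = affinv(0,0), a01 = affinv(0,1), a02 = affinv(0,2), a03 = affinv(0,3);
  double a10 = affinv(1,0), a11 = affinv(1,1), a12 = affinv(1,2), a13 = affinv(1,3);
  double a20 = affinv(2,0), a21 = affinv(2,1), a22 = affinv(2,2), a23 = affinv(2,3);
  for (size_t p = 0; p < n; ++p) {
    double wx = pts(p,0), wy = pts(p,1), wz = pts(p,2);
    double x = a00*wx + a01*wy + a02*wz + a03;
    double y = a10*wx + a11*wy + a12*wz + a13;
    double z = a20*wx + a21*wy + a22*wz + a23;
    out[p] = (order == 1) ? interp_tri(d, nx, ny, nz, x, y, z)
                          : interp_cub(d, nx, ny, nz, x, y, z);
  }
  return out;
}

// Separable Gaussian blur; sigma in voxels per axis; boundary: reflect
// (zeropad = false) or zero (zeropad = true).
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector data, IntegerVector dims,
                                NumericVector sigma, bool zeropad) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> buf(data.begin(), data.end()), tmp(n);
  int nd[3] = {nx, ny, nz};
  size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0.0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> w(2 * r + 1);
    double tot = 0.0;
    for (int m = -r; m <= r; ++m) { w[m + r] = std::exp(-0.5 * m * m / (s * s)); tot += w[m + r]; }
    for (int m = 0; m <= 2 * r; ++m) w[m] /= tot;
    int L = nd[ax];
    size_t st = stride[ax];
    // iterate over all lines along axis ax
    int o1 = (ax == 0) ? 1 : 0;           // other axes
    int o2 = (ax == 2) ? 1 : 2;
    for (int c2 = 0; c2 < nd[o2]; ++c2)
      for (int c1 = 0; c1 < nd[o1]; ++c1) {
        size_t base = (size_t)c1 * stride[o1] + (size_t)c2 * stride[o2];
        for (int i = 0; i < L; ++i) {
          double acc = 0.0;
          for (int m = -r; m <= r; ++m) {
            int ii = i + m;
            if (ii < 0 || ii >= L) {
              if (zeropad) continue;
              ii = (ii < 0) ? -ii - 1 : 2 * L - ii - 1;   // reflect
              if (ii < 0) ii = 0;
              if (ii >= L) ii = L - 1;
            }
            acc += w[m + r] * buf[base + (size_t)ii * st];
          }
          tmp[base + (size_t)i * st] = acc;
        }
      }
    buf.swap(tmp);
  }
  return NumericVector(buf.begin(), buf.end());
}

// Box mean over a (2r+1)^3 neighborhood, truncated at borders (mean over the
// voxels actually present). Separable pass with per-line counts.
// [[Rcpp::export]]
NumericVector cpp_boxmean(NumericVector data, IntegerVector dims, int r) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  if (r <= 0) return clone(data);
  std::vector<double> val(data.begin(), data.end()), cnt(n, 1.0), tv(n), tc(n);
  int nd[3] = {nx, ny, nz};
  size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    int L = nd[ax];
    size_t st = stride[ax];
    int o1 = (ax == 0) ? 1 : 0, o2 = (ax == 2) ? 1 : 2;
    for (int c2 = 0; c2 < nd[o2]; ++c2)
      for (int c1 = 0; c1 < nd[o1]; ++c1) {
        size_t base = (size_t)c1 * stride[o1] + (size_t)c2 * stride[o2];
        for (int i = 0; i < L; ++i) {
          double av = 0.0, ac = 0.0;
          int lo = std::max(0, i - r), hi = std::min(L - 1, i + r);
          for (int ii = lo; ii <= hi; ++ii) {
            av += val[base + (size_t)ii * st];
            ac += cnt[base + (size_t)ii * st];
          }
          tv[base + (size_t)i * st] = av;
          tc[base + (size_t)i * st] = ac;
        }
      }
    val.swap(tv); cnt.swap(tc);
  }
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = val[i] / cnt[i];
  return out;
}

// Non-local-means denoising. Patch radius pr, search radius sr, noise sd
// sigma. Weight: w = exp(-max(d2mean - 2*sigma^2, 0) / (h * sigma^2)) with
// d2mean the mean squared patch difference; the center voxel gets the
// maximum neighbor weight.
// [[Rcpp::export]]
NumericVector cpp_nlm(NumericVector data, IntegerVector dims, int pr, int sr,
                      double sigma, double h) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((size_t)nx * ny * nz);
  const double* d = data.begin();
  double h2 = h * sigma * sigma;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double wsum = 0.0, vsum = 0.0, wmax = 0.0;
        for (int ck = -sr; ck <= sr; ++ck)
          for (int cj = -sr; cj <= sr; ++cj)
            for (int ci = -sr; ci <= sr; ++ci) {
              if (ci == 0 && cj == 0 && ck == 0) continue;
              int ii = i + ci, jj = j + cj, kk = k + ck;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
                continue;
              double d2 = 0.0; int cntp = 0;
              for (int pk = -pr; pk <= pr; ++pk)
                for (int pj = -pr; pj <= pr; ++pj)
                  for (int pi = -pr; pi <= pr; ++pi) {
                    double va = getvox(d, nx, ny, nz, i + pi, j + pj, k + pk);
                    double vb = getvox(d, nx, ny, nz, ii + pi, jj + pj, kk + pk);
                    d2 += (va - vb) * (va - vb);
                    ++cntp;
                  }
              d2 /= cntp;
              double ex = d2 - 2.0 * sigma * sigma;
              double w = (ex <= 0.0) ? 1.0 : std::exp(-ex / h2);
              if (w > wmax) wmax = w;
              wsum += w;
              vsum += w * d[ii + (size_t)nx * (jj + (size_t)ny * kk)];
            }
        double wc = (wmax > 0.0) ? wmax : 1.0;   // center weight
        wsum += wc;
        vsum += wc * d[i + (size_t)nx * (j + (size_t)ny * k)];
        out[i + (size_t)nx * (j + (size_t)ny * k)] = vsum / wsum;
      }
  return out;
}

static inline double patch_cc(const double* a, const double* b, int nx, int ny,
                              int nz, int ci, int cj, int ck, double si,
                              double sj, double sk, const int* rad,
                              const int* stp) {
  // Pearson correlation of a around (ci,cj,ck) with b around the (possibly
  // fractionally) shifted center, over the neighborhood cube sampled with
  // the given stride; b is sampled with trilinear interpolation (direct
  // access for integer shifts). Voxels outside either extent are skipped.
  double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0; int n = 0;
  bool integral = (si == std::floor(si) && sj == std::floor(sj) &&
                   sk == std::floor(sk));
  int isi = (int)si, isj = (int)sj, isk = (int)sk;
  for (int dk = -rad[2]; dk <= rad[2]; dk += stp[2])
    for (int dj = -rad[1]; dj <= rad[1]; dj += stp[1])
      for (int di = -rad[0]; di <= rad[0]; di += stp[0]) {
        int ia = ci + di, ja = cj + dj, ka = ck + dk;
        if (ia < 0 || ja < 0 || ka < 0 || ia >= nx || ja >= ny || ka >= nz)
          continue;
        double va = a[ia + (size_t)nx * (ja + (size_t)ny * ka)];
        double vb;
        if (integral) {
          int ib = ia + isi, jb = ja + isj, kb = ka + isk;
          if (ib < 0 || jb < 0 || kb < 0 || ib >= nx || jb >= ny || kb >= nz)
            continue;
          vb = b[ib + (size_t)nx * (jb + (size_t)ny * kb)];
        } else {
          double xb = ia + si, yb = ja + sj, zb = ka + sk;
          if (xb < 0 || yb < 0 || zb < 0 || xb > nx - 1 || yb > ny - 1 ||
              zb > nz - 1)
            continue;
          vb = interp_tri(b, nx, ny, nz, xb, yb, zb);
        }
        sa += va; sb += vb; saa += va * va; sbb += vb * vb; sab += va * vb;
        ++n;
      }
  if (n < 8) return 0.0;
  double ca = saa - sa * sa / n, cb = sbb - sb * sb / n, cab = sab - sa * sb / n;
  if (ca <= 1e-12 || cb <= 1e-12) return 0.0;
  return cab / std::sqrt(ca * cb);
}

// Local displacement search on a node lattice: for each node, find the shift
// of the (already warped) source that maximizes local cross-correlation with
// the target over a neighborhood cube; one integer step per axis with
// per-axis quadratic refinement. Returns node displacements in voxel units
// (nnx x nny x nnz x 3, column-major).
// [[Rcpp::export]]
NumericVector cpp_node_search(NumericVector srcw, NumericVector tgt,
                              IntegerVector dims, IntegerVector stepvox,
                              NumericVector shiftvox, IntegerVector radvox,
                              IntegerVector stridevox, double min_sd,
                              double min_gain, double gain_soft) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int sx = stepvox[0], sy = stepvox[1], sz = stepvox[2];
  int nnx = (nx + sx - 1) / sx, nny = (ny + sy - 1) / sy, nnz = (nz + sz - 1) / sz;
  int rad[3] = {radvox[0], radvox[1], radvox[2]};
  int stp[3] = {stridevox[0], stridevox[1], stridevox[2]};
  double shift[3] = {shiftvox[0], shiftvox[1], shiftvox[2]};
  const double* a = tgt.begin();
  const double* b = srcw.begin();
  NumericVector out((size_t)nnx * nny * nnz * 3);
  size_t nn = (size_t)nnx * nny * nnz;
  for (int kk = 0; kk < nnz; ++kk)
    for (int jj = 0; jj < nny; ++jj)
      for (int ii = 0; ii < nnx; ++ii) {
        int ci = ii * sx, cj = jj * sy, ck = kk * sz;
        size_t idx = ii + (size_t)nnx * (jj + (size_t)nny * kk);
        // degenerate neighborhood check on target
        double s1 = 0, s2 = 0; int n = 0;
        for (int dk = -rad[2]; dk <= rad[2]; dk += std::max(1, rad[2]))
          for (int dj = -rad[1]; dj <= rad[1]; dj += std::max(1, rad[1]))
            for (int di = -rad[0]; di <= rad[0]; di += std::max(1, rad[0])) {
              double v = getvox(a, nx, ny, nz, ci + di, cj + dj, ck + dk);
              s1 += v; s2 += v * v; ++n;
            }
        if (n > 1 && (s2 - s1 * s1 / n) / (n - 1) < min_sd * min_sd) continue;
        double c0 = patch_cc(a, b, nx, ny, nz, ci, cj, ck, 0, 0, 0, rad, stp);
        for (int ax = 0; ax < 3; ++ax) {
          double sh[3] = {0, 0, 0};
          sh[ax] = shift[ax];
          double cp = patch_cc(a, b, nx, ny, nz, ci, cj, ck, sh[0], sh[1], sh[2], rad, stp);
          sh[ax] = -shift[ax];
          double cm = patch_cc(a, b, nx, ny, nz, ci, cj, ck, sh[0], sh[1], sh[2], rad, stp);
          double den = cm - 2.0 * c0 + cp;
          double off = 0.0;
          if (den < -1e-12) {
            // unimodal profile: quadratic vertex, verified by evaluating the
            // correlation at the fractional shift itself -- accept only a
            // real improvement over the centered position
            double v = 0.5 * (cm - cp) / den;
            if (v > 1.0) v = 1.0;
            if (v < -1.0) v = -1.0;
            if (std::fabs(v) > 1e-3) {
              sh[ax] = v * shift[ax];
              double cv = patch_cc(a, b, nx, ny, nz, ci, cj, ck, sh[0], sh[1],
                                   sh[2], rad, stp);
              double g = cv - c0;
              // soft confidence weight: marginal gains (tangential sliding,
              // the aperture problem) are damped, confident ones pass
              if (g > min_gain) off = (gain_soft > 0) ? v * g / (g + gain_soft) : v;
            }
          } else if (cp > c0 + min_gain && cp > cm + min_gain) {
            double g = cp - c0;
            off = (gain_soft > 0) ? g / (g + gain_soft) : 1.0;
          } else if (cm > c0 + min_gain && cm > cp + min_gain) {
            double g = cm - c0;
            off = (gain_soft > 0) ? -g / (g + gain_soft) : -1.0;
          }
          out[idx + ax * nn] = off * shift[ax];
        }
      }
  return out;
}

// Fixed-point inversion of a displacement field: iterate
// u_inv(x) = -u(x + u_inv(x)) until the max update falls below tol_mm.
// Field is (nx,ny,nz,3) on the grid given by affinv (world -> voxel).
// Returns a field of the same shape; the attribute handling (residual,
// converged) is done on the R side via the last element trick below.
// [[Rcpp::export]]
List cpp_invert_field(NumericVector field, IntegerVector dims,
                      NumericMatrix affinv, NumericMatrix world,
                      double tol_mm, int max_iter) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  const double* f = field.begin();
  NumericVector out(n * 3);
  std::vector<double> cur(n * 3);
  for (size_t i = 0; i < n * 3; ++i) cur[i] = -f[i];
  double a00 = affinv(0,0), a01 = affinv(0,1), a02 = affinv(0,2), a03 = affinv(0,3);
  double a10 = affinv(1,0), a11 = affinv(1,1), a12 = affinv(1,2), a13 = affinv(1,3);
  double a20 = affinv(2,0), a21 = affinv(2,1), a22 = affinv(2,2), a23 = affinv(2,3);
  double resid = 0.0;
  for (int it = 0; it < max_iter; ++it) {
    resid = 0.0;
    for (size_t p = 0; p < n; ++p) {
      double wx = world(p,0) + cur[p];
      double wy = world(p,1) + cur[p + n];
      double wz = world(p,2) + cur[p + 2 * n];
      double x = a00*wx + a01*wy + a02*wz + a03;
      double y = a10*wx + a11*wy + a12*wz + a13;
      double z = a20*wx + a21*wy + a22*wz + a23;
      for (int c = 0; c < 3; ++c) {
        double v = -interp_tri(f + c * n, nx, ny, nz, x, y, z);
        double d = std::fabs(v - cur[p + c * n]);
        if (d > resid) resid = d;
        out[p + c * n] = v;
      }
    }
    std::copy(out.begin(), out.end(), cur.begin());
    if (resid < tol_mm) break;
  }
  return List::create(Named("vectors") = out, Named("residual") = resid);
}

// Jacobian matrix of a displacement field: central differences inside,
// one-sided at the boundary; spacing in mm per axis. Output nvox x 9 with
// entry (r, c) = d u_r / d x_c stored at column r + 3*c.
// [[Rcpp::export]]
NumericMatrix cpp_jacobian(NumericVector field, IntegerVector dims,
                           NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  NumericMatrix out(n, 9);
  const double* f = field.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t idx = i + (size_t)nx * (j + (size_t)ny * k);
        for (int c = 0; c < 3; ++c) {        // derivative direction
          int ip = i, im = i, jp = j, jm = j, kp = k, km = k;
          if (c == 0) { ip = std::min(i + 1, nx - 1); im = std::max(i - 1, 0); }
          if (c == 1) { jp = std::min(j + 1, ny - 1); jm = std::max(j - 1, 0); }
          if (c == 2) { kp = std::min(k + 1, nz - 1); km = std::max(k - 1, 0); }
          int nstep = (c == 0) ? (ip - im) : (c == 1) ? (jp - jm) : (kp - km);
          double den = nstep * spacing[c];
          size_t idp = ip + (size_t)nx * (jp + (size_t)ny * kp);
          size_t idm = im + (size_t)nx * (jm + (size_t)ny * km);
          double* o = out.begin();
          for (int r = 0; r < 3; ++r)
            o[idx + (size_t)(r + 3 * c) * n] = (den > 0)
              ? (f[idp + r * n] - f[idm + r * n]) / den : 0.0;
        }
      }
  return out;
}

// Neighborhood Taylor reconstruction: for each voxel v and component r,
// mean over the (2rad+1)^3 neighborhood (truncated at borders) of
// T(u) + Jbar(u) . (v - u), offsets in mm. T is nvox x 3, Jbar nvox x 9
// (layout as cpp_jacobian).
// [[Rcpp::export]]
NumericMatrix cpp_taylor_reconstruct(NumericMatrix T, NumericMatrix Jbar,
                                     IntegerVector dims, int rad,
                                     NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  NumericMatrix out(n, 3);
  const double* tp = T.begin();
  const double* jp = Jbar.begin();
  double* op = out.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t idx = i + (size_t)nx * (j + (size_t)ny * k);
        double acc[3] = {0.0, 0.0, 0.0};
        int cnt = 0;
        for (int dk = -rad; dk <= rad; ++dk) {
          int kk = k + dk; if (kk < 0 || kk >= nz) continue;
          for (int dj = -rad; dj <= rad; ++dj) {
            int jj = j + dj; if (jj < 0 || jj >= ny) continue;
            for (int di = -rad; di <= rad; ++di) {
              int ii = i + di; if (ii < 0 || ii >= nx) continue;
              size_t u = ii + (size_t)nx * (jj + (size_t)ny * kk);
              double ox = -di * spacing[0], oy = -dj * spacing[1],
                     oz = -dk * spacing[2];     // v - u in mm
              for (int r = 0; r < 3; ++r)
                acc[r] += tp[u + r * n] + jp[u + r * n] * ox +
                          jp[u + (r + 3) * n] * oy + jp[u + (r + 6) * n] * oz;
              ++cnt;
            }
          }
        }
        for (int r = 0; r < 3; ++r) op[idx + r * n] = acc[r] / cnt;
      }
  return out;
}
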