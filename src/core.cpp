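// Numerical core: trilinear interpolation, backward warping, separable
// convolution, finite-difference gradients, the per-voxel weighted
// Lucas-Kanade 3x3 solve, affine resampling and the discretized 2D gamma
// search. All arrays use (z,y,x) dimension order, column-major as stored by
// R with dim = c(nz, ny, nx); linear index = z + nz*(y + ny*x).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline size_t idx3(int z, int y, int x, int nz, int ny) {
  return (size_t)z + (size_t)nz * ((size_t)y + (size_t)ny * (size_t)x);
}

// Edge-clamped trilinear interpolation at continuous 0-based voxel coords.
static double tri_sample(const double* v, int nz, int ny, int nx,
                         double z, double y, double x) {
  z = clampd(z, 0.0, (double)(nz - 1));
  y = clampd(y, 0.0, (double)(ny - 1));
  x = clampd(x, 0.0, (double)(nx - 1));
  int z0 = (int)std::floor(z), y0 = (int)std::floor(y), x0 = (int)std::floor(x);
  if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
  if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
  if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
  int z1 = (nz > 1) ? z0 + 1 : z0;
  int y1 = (ny > 1) ? y0 + 1 : y0;
  int x1 = (nx > 1) ? x0 + 1 : x0;
  double fz = z - z0, fy = y - y0, fx = x - x0;
  double c000 = v[idx3(z0, y0, x0, nz, ny)], c100 = v[idx3(z1, y0, x0, nz, ny)];
  double c010 = v[idx3(z0, y1, x0, nz, ny)], c110 = v[idx3(z1, y1, x0, nz, ny)];
  double c001 = v[idx3(z0, y0, x1, nz, ny)], c101 = v[idx3(z1, y0, x1, nz, ny)];
  double c011 = v[idx3(z0, y1, x1, nz, ny)], c111 = v[idx3(z1, y1, x1, nz, ny)];
  double c00 = c000 * (1 - fz) + c100 * fz;
  double c10 = c010 * (1 - fz) + c110 * fz;
  double c01 = c001 * (1 - fz) + c101 * fz;
  double c11 = c011 * (1 - fz) + c111 * fz;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fx) + c1 * fx;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dim,
                            NumericMatrix pts) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int n = pts.nrow();
  NumericVector out(n);
  const double* v = vol.begin();
  for (int i = 0; i < n; ++i)
    out[i] = tri_sample(v, nz, ny, nx, pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}

// Backward warp: out(x) = vol(x + disp(x)), displacements in voxel units.
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector vol, IntegerVector dim,
                       NumericVector dz, NumericVector dy, NumericVector dx) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t n = (size_t)nz * ny * nx;
  NumericVector out(n);
  const double* v = vol.begin();
  size_t i = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z, ++i)
        out[i] = tri_sample(v, nz, ny, nx,
                            z + dz[i], y + dy[i], x + dx[i]);
  return out;
}

// Zero-padded separable convolution with odd-length kernels per axis.
// A length-1 kernel of value 1 is the identity along that axis.
static void conv_axis(std::vector<double>& a, std::vector<double>& b,
                      int nz, int ny, int nx, const NumericVector& k, int axis) {
  int kl = k.size(), r = (kl - 1) / 2;
  if (kl == 1 && k[0] == 1.0) { return; }
  std::fill(b.begin(), b.end(), 0.0);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double s = 0.0;
        for (int t = -r; t <= r; ++t) {
          int zz = z, yy = y, xx = x;
          if (axis == 0) zz += t; else if (axis == 1) yy += t; else xx += t;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          s += k[t + r] * a[idx3(zz, yy, xx, nz, ny)];
        }
        b[idx3(z, y, x, nz, ny)] = s;
      }
  a.swap(b);
}

// [[Rcpp::export]]
NumericVector cpp_sepconv(NumericVector vol, IntegerVector dim,
                          NumericVector kz, NumericVector ky, NumericVector kx) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t n = (size_t)nz * ny * nx;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  conv_axis(a, b, nz, ny, nx, kz, 0);
  conv_axis(a, b, nz, ny, nx, ky, 1);
  conv_axis(a, b, nz, ny, nx, kx, 2);
  NumericVector out(n);
  std::copy(a.begin(), a.end(), out.begin());
  return out;
}

// Central differences on the interior, one-sided at borders, per axis.
// [[Rcpp::export]]
List cpp_gradients(NumericVector vol, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t n = (size_t)nz * ny * nx;
  NumericVector gz(n), gy(n), gx(n);
  const double* v = vol.begin();
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        size_t i = idx3(z, y, x, nz, ny);
        int zp = z + 1 < nz ? z + 1 : z, zm = z - 1 >= 0 ? z - 1 : z;
        int yp = y + 1 < ny ? y + 1 : y, ym = y - 1 >= 0 ? y - 1 : y;
        int xp = x + 1 < nx ? x + 1 : x, xm = x - 1 >= 0 ? x - 1 : x;
        gz[i] = (v[idx3(zp, y, x, nz, ny)] - v[idx3(zm, y, x, nz, ny)]) / (zp - zm);
        gy[i] = (v[idx3(z, yp, x, nz, ny)] - v[idx3(z, ym, x, nz, ny)]) / (yp - ym);
        gx[i] = (v[idx3(z, y, xp, nz, ny)] - v[idx3(z, y, xm, nz, ny)]) / (xp - xm);
      }
  return List::create(_["gz"] = gz, _["gy"] = gy, _["gx"] = gx);
}

// Jacobi eigendecomposition of a symmetric 3x3 matrix: A = V diag(w) V^T.
static void eig_sym3(double a[3][3], double w[3], double V[3][3]) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) V[i][j] = (i == j) ? 1.0 : 0.0;
  for (int sweep = 0; sweep < 30; ++sweep) {
    double off = std::fabs(a[0][1]) + std::fabs(a[0][2]) + std::fabs(a[1][2]);
    if (off == 0.0) break;
    for (int p = 0; p < 2; ++p)
      for (int q = p + 1; q < 3; ++q) {
        if (std::fabs(a[p][q]) < 1e-300) continue;
        double theta = (a[q][q] - a[p][p]) / (2.0 * a[p][q]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        double app = a[p][p], aqq = a[q][q], apq = a[p][q];
        a[p][p] = app - t * apq;
        a[q][q] = aqq + t * apq;
        a[p][q] = a[q][p] = 0.0;
        for (int k = 0; k < 3; ++k) {
          if (k != p && k != q) {
            double akp = a[k][p], akq = a[k][q];
            a[k][p] = a[p][k] = c * akp - s * akq;
            a[k][q] = a[q][k] = s * akp + c * akq;
          }
          double vkp = V[k][p], vkq = V[k][q];
          V[k][p] = c * vkp - s * vkq;
          V[k][q] = s * vkp + c * vkq;
        }
      }
  }
  for (int i = 0; i < 3; ++i) w[i] = a[i][i];
}

// Per-voxel solve of (S) v = -B by truncated eigendecomposition:
// eigencomponents of the normal matrix below eig_thresh are zeroed (the
// aperture-problem guard: a rank-deficient window constrains only part of
// the flow, and a fully homogeneous window constrains none), the remaining
// ones are inverted; then an L-infinity clip on the update.
// [[Rcpp::export]]
List cpp_lk_solve(NumericVector S11, NumericVector S12, NumericVector S13,
                  NumericVector S22, NumericVector S23, NumericVector S33,
                  NumericVector B1, NumericVector B2, NumericVector B3,
                  double eig_thresh, double clip) {
  size_t n = S11.size();
  NumericVector vz(n), vy(n), vx(n);
  for (size_t i = 0; i < n; ++i) {
    double a[3][3] = {{S11[i], S12[i], S13[i]},
                      {S12[i], S22[i], S23[i]},
                      {S13[i], S23[i], S33[i]}};
    double w[3], V[3][3];
    eig_sym3(a, w, V);
    double b[3] = {-B1[i], -B2[i], -B3[i]};
    double v[3] = {0.0, 0.0, 0.0};
    for (int k = 0; k < 3; ++k) {
      if (!(w[k] > eig_thresh)) continue;
      double proj = (V[0][k] * b[0] + V[1][k] * b[1] + V[2][k] * b[2]) / w[k];
      v[0] += V[0][k] * proj;
      v[1] += V[1][k] * proj;
      v[2] += V[2][k] * proj;
    }
    if (R_finite(clip))
      for (int k = 0; k < 3; ++k) v[k] = clampd(v[k], -clip, clip);
    vz[i] = v[0]; vy[i] = v[1]; vx[i] = v[2];
  }
  return List::create(_["vz"] = vz, _["vy"] = vy, _["vx"] = vx);
}

// Backward affine resample variant for the registration metric: output
// voxels whose source position falls outside the input grid become NA
// instead of edge-clamped (the overlap-domain convention).
// [[Rcpp::export]]
NumericVector cpp_affine_resample_na(NumericVector vol, IntegerVector dim_in,
                                     NumericVector sp_in, NumericVector or_in,
                                     IntegerVector dim_out, NumericVector sp_out,
                                     NumericVector or_out, NumericMatrix A,
                                     NumericVector b) {
  int nzi = dim_in[0], nyi = dim_in[1], nxi = dim_in[2];
  int nzo = dim_out[0], nyo = dim_out[1], nxo = dim_out[2];
  NumericVector out((size_t)nzo * nyo * nxo);
  const double* v = vol.begin();
  size_t i = 0;
  for (int x = 0; x < nxo; ++x)
    for (int y = 0; y < nyo; ++y)
      for (int z = 0; z < nzo; ++z, ++i) {
        double wz = or_out[0] + z * sp_out[0];
        double wy = or_out[1] + y * sp_out[1];
        double wx = or_out[2] + x * sp_out[2];
        double qz = A(0, 0) * wz + A(0, 1) * wy + A(0, 2) * wx + b[0];
        double qy = A(1, 0) * wz + A(1, 1) * wy + A(1, 2) * wx + b[1];
        double qx = A(2, 0) * wz + A(2, 1) * wy + A(2, 2) * wx + b[2];
        double vz = (qz - or_in[0]) / sp_in[0];
        double vy = (qy - or_in[1]) / sp_in[1];
        double vx = (qx - or_in[2]) / sp_in[2];
        if (vz < 0 || vz > nzi - 1 || vy < 0 || vy > nyi - 1 ||
            vx < 0 || vx > nxi - 1) {
          out[i] = NA_REAL;
        } else {
          out[i] = tri_sample(v, nzi, nyi, nxi, vz, vy, vx);
        }
      }
  return out;
}

// Backward affine resample: for each output voxel, world point
// w = origin_out + v * spacing_out, source world q = A w + b (all in
// (z,y,x) component order), sampled trilinearly (edge-clamped) in the
// input grid.
// [[Rcpp::export]]
NumericVector cpp_affine_resample(NumericVector vol, IntegerVector dim_in,
                                  NumericVector sp_in, NumericVector or_in,
                                  IntegerVector dim_out, NumericVector sp_out,
                                  NumericVector or_out, NumericMatrix A,
                                  NumericVector b) {
  int nzi = dim_in[0], nyi = dim_in[1], nxi = dim_in[2];
  int nzo = dim_out[0], nyo = dim_out[1], nxo = dim_out[2];
  NumericVector out((size_t)nzo * nyo * nxo);
  const double* v = vol.begin();
  size_t i = 0;
  for (int x = 0; x < nxo; ++x)
    for (int y = 0; y < nyo; ++y)
      for (int z = 0; z < nzo; ++z, ++i) {
        double wz = or_out[0] + z * sp_out[0];
        double wy = or_out[1] + y * sp_out[1];
        double wx = or_out[2] + x * sp_out[2];
        double qz = A(0, 0) * wz + A(0, 1) * wy + A(0, 2) * wx + b[0];
        double qy = A(1, 0) * wz + A(1, 1) * wy + A(1, 2) * wx + b[1];
        double qx = A(2, 0) * wz + A(2, 1) * wy + A(2, 2) * wx + b[2];
        out[i] = tri_sample(v, nzi, nyi, nxi,
                            (qz - or_in[0]) / sp_in[0],
                            (qy - or_in[1]) / sp_in[1],
                            (qx - or_in[2]) / sp_in[2]);
      }
  return out;
}

static double bi_sample(const NumericMatrix& m, double y, double x) {
  int ny = m.nrow(), nx = m.ncol();
  y = clampd(y, 0.0, ny - 1.0);
  x = clampd(x, 0.0, nx - 1.0);
  int y0 = (int)std::floor(y); if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
  int x0 = (int)std::floor(x); if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
  int y1 = (ny > 1) ? y0 + 1 : y0, x1 = (nx > 1) ? x0 + 1 : x0;
  double fy = y - y0, fx = x - x0;
  return m(y0, x0) * (1 - fy) * (1 - fx) + m(y1, x0) * fy * (1 - fx) +
         m(y0, x1) * (1 - fy) * fx + m(y1, x1) * fy * fx;
}

// Discretized 2D gamma map: minimum over a polar-sorted offset grid with an
// early break once the pure distance term exceeds the current best.
// Returns NA for pixels outside the mask or below low_cut.
// [[Rcpp::export]]
NumericMatrix cpp_gamma_slice(NumericMatrix ref, NumericMatrix ev,
                              LogicalMatrix mask, double sy, double sx,
                              double dist_crit, double dose_frac, bool local,
                              double global_denom, double search_radius,
                              double step, double low_cut, double local_floor) {
  int ny = ref.nrow(), nx = ref.ncol();
  NumericMatrix gmap(ny, nx);
  std::fill(gmap.begin(), gmap.end(), NA_REAL);
  // build offsets within the search disc, sorted by distance
  int nstep = (int)std::floor(search_radius / step + 1e-9);
  std::vector<std::pair<double, std::pair<double, double> > > offs;
  for (int iy = -nstep; iy <= nstep; ++iy)
    for (int ix = -nstep; ix <= nstep; ++ix) {
      double dy = iy * step, dx = ix * step;
      double d2 = dy * dy + dx * dx;
      if (d2 <= search_radius * search_radius + 1e-12)
        offs.push_back(std::make_pair(d2, std::make_pair(dy, dx)));
    }
  std::sort(offs.begin(), offs.end());
  double dc2 = dist_crit * dist_crit;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      if (!mask(y, x)) continue;
      double rv = ref(y, x);
      if (std::fabs(rv) < low_cut) continue;
      double denom = local ? dose_frac * std::max(std::fabs(rv), local_floor)
                           : global_denom;
      double best = R_PosInf;
      for (size_t k = 0; k < offs.size(); ++k) {
        double dterm = offs[k].first / dc2;
        if (dterm >= best) break;
        double evv = bi_sample(ev, y + offs[k].second.first / sy,
                               x + offs[k].second.second / sx);
        double dd = (evv - rv) / denom;
        double g = dterm + dd * dd;
        if (g < best) best = g;
      }
      gmap(y, x) = std::sqrt(best);
    }
  return gmap;
}
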