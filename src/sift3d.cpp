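#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Volumes are passed as flat numeric vectors in R's column-major layout:
// index = x + nx*(y + ny*z), 0-based.

static inline R_xlen_t vidx(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)z);
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Separable Gaussian smoothing with edge-replicate padding. sigma in voxels.
// Passes accumulate whole contiguous x-rows per kernel tap (cache-friendly,
// auto-vectorizable); intermediate buffers are single precision, which is
// far below the accuracy the DoG detector needs.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector vol, IntegerVector dim, double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (sigma <= 0) return clone(vol);

  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) r = 1;
  std::vector<float> k(2 * r + 1);
  double ksum = 0.0;
  for (int i = -r; i <= r; ++i) {
    const double kv = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    k[i + r] = (float)kv;
    ksum += kv;
  }
  for (float &kv : k) kv = (float)(kv / ksum);

  const double *src = REAL(vol);
  std::vector<float> a(n), b(n);
  for (R_xlen_t i = 0; i < n; ++i) a[i] = (float)src[i];

  // pass along x: a -> b (per-row direct convolution, contiguous reads)
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const float *row = &a[vidx(0, y, z, nx, ny)];
      float *orow = &b[vidx(0, y, z, nx, ny)];
      for (int x = 0; x < nx; ++x) {
        float s = 0.0f;
        const int i0 = std::max(-r, -x), i1 = std::min(r, nx - 1 - x);
        for (int i = -r; i < i0; ++i) s += k[i + r] * row[0];
        for (int i = i0; i <= i1; ++i) s += k[i + r] * row[x + i];
        for (int i = i1 + 1; i <= r; ++i) s += k[i + r] * row[nx - 1];
        orow[x] = s;
      }
    }
  // pass along y: b -> a (accumulate shifted contiguous rows)
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      float *orow = &a[vidx(0, y, z, nx, ny)];
      std::fill(orow, orow + nx, 0.0f);
      for (int i = -r; i <= r; ++i) {
        const float kv = k[i + r];
        const float *irow = &b[vidx(0, clampi(y + i, 0, ny - 1), z, nx, ny)];
        for (int x = 0; x < nx; ++x) orow[x] += kv * irow[x];
      }
    }
  // pass along z: a -> b
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      float *orow = &b[vidx(0, y, z, nx, ny)];
      std::fill(orow, orow + nx, 0.0f);
      for (int i = -r; i <= r; ++i) {
        const float kv = k[i + r];
        const float *irow = &a[vidx(0, y, clampi(z + i, 0, nz - 1), nx, ny)];
        for (int x = 0; x < nx; ++x) orow[x] += kv * irow[x];
      }
    }
  NumericVector out(n);
  double *o = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) o[i] = (double)b[i];
  return out;
}

// Keep every second voxel along each axis (0, 2, 4, ...).
// [[Rcpp::export]]
NumericVector cpp_downsample2(NumericVector vol, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int mx = (nx + 1) / 2, my = (ny + 1) / 2, mz = (nz + 1) / 2;
  NumericVector out((R_xlen_t)mx * my * mz);
  const double *src = REAL(vol);
  double *dst = REAL(out);
  for (int z = 0; z < mz; ++z)
    for (int y = 0; y < my; ++y)
      for (int x = 0; x < mx; ++x)
        dst[vidx(x, y, z, mx, my)] = src[vidx(2 * x, 2 * y, 2 * z, nx, ny)];
  return out;
}

// Scan interior DoG voxels of levels 1..L-2 for strict extrema over the
// 3x3x3x3 scale-space neighbourhood (80 neighbours).
// [[Rcpp::export]]
IntegerMatrix cpp_dog_extrema(List dogs, IntegerVector dim, double prethresh) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int L = dogs.size();
  std::vector<const double *> d(L);
  for (int l = 0; l < L; ++l) d[l] = REAL((SEXP)dogs[l]);

  std::vector<int> cx, cy, cz, cl;
  for (int l = 1; l <= L - 2; ++l) {
    for (int z = 1; z < nz - 1; ++z)
      for (int y = 1; y < ny - 1; ++y)
        for (int x = 1; x < nx - 1; ++x) {
          const double v = d[l][vidx(x, y, z, nx, ny)];
          if (std::fabs(v) < prethresh) continue;
          bool ismax = v > 0, ismin = v < 0;
          for (int dl = -1; dl <= 1 && (ismax || ismin); ++dl)
            for (int dz = -1; dz <= 1 && (ismax || ismin); ++dz)
              for (int dy = -1; dy <= 1 && (ismax || ismin); ++dy)
                for (int dx = -1; dx <= 1; ++dx) {
                  if (dx == 0 && dy == 0 && dz == 0 && dl == 0) continue;
                  const double w = d[l + dl][vidx(x + dx, y + dy, z + dz, nx, ny)];
                  if (w >= v) ismax = false;
                  if (w <= v) ismin = false;
                  if (!ismax && !ismin) break;
                }
          if (ismax || ismin) { cx.push_back(x); cy.push_back(y); cz.push_back(z); cl.push_back(l); }
        }
  }
  IntegerMatrix out(cx.size(), 4);
  for (size_t i = 0; i < cx.size(); ++i) {
    out(i, 0) = cx[i]; out(i, 1) = cy[i]; out(i, 2) = cz[i]; out(i, 3) = cl[i];
  }
  return out;
}

// Solve a small dense linear system in place by Gaussian elimination with
// partial pivoting; returns false when near-singular.
static bool solve_small(double A[4][4], double bvec[4], double xvec[4], int m) {
  int piv[4];
  for (int i = 0; i < m; ++i) piv[i] = i;
  for (int c = 0; c < m; ++c) {
    int best = c;
    for (int rr = c + 1; rr < m; ++rr)
      if (std::fabs(A[rr][c]) > std::fabs(A[best][c])) best = rr;
    if (std::fabs(A[best][c]) < 1e-12) return false;
    if (best != c) {
      for (int j = 0; j < m; ++j) std::swap(A[c][j], A[best][j]);
      std::swap(bvec[c], bvec[best]);
    }
    for (int rr = c + 1; rr < m; ++rr) {
      const double f = A[rr][c] / A[c][c];
      for (int j = c; j < m; ++j) A[rr][j] -= f * A[c][j];
      bvec[rr] -= f * bvec[c];
    }
  }
  for (int rr = m - 1; rr >= 0; --rr) {
    double s = bvec[rr];
    for (int j = rr + 1; j < m; ++j) s -= A[rr][j] * xvec[j];
    xvec[rr] = s / A[rr][rr];
  }
  return true;
}

// Eigenvalues of a symmetric 3x3 matrix by cyclic Jacobi rotations.
static void eig_sym3(double M[3][3], double ev[3]) {
  double a[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) a[i][j] = M[i][j];
  for (int sweep = 0; sweep < 30; ++sweep) {
    double off = std::fabs(a[0][1]) + std::fabs(a[0][2]) + std::fabs(a[1][2]);
    if (off < 1e-14) break;
    for (int p = 0; p < 2; ++p)
      for (int q = p + 1; q < 3; ++q) {
        if (std::fabs(a[p][q]) < 1e-15) continue;
        const double theta = (a[q][q] - a[p][p]) / (2.0 * a[p][q]);
        const double t = (theta >= 0 ? 1.0 : -1.0) /
          (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        const double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int kk = 0; kk < 3; ++kk) {
          const double akp = a[kk][p], akq = a[kk][q];
          a[kk][p] = c * akp - s * akq;
          a[kk][q] = s * akp + c * akq;
        }
        for (int kk = 0; kk < 3; ++kk) {
          const double apk = a[p][kk], aqk = a[q][kk];
          a[p][kk] = c * apk - s * aqk;
          a[q][kk] = s * apk + c * aqk;
        }
      }
  }
  ev[0] = a[0][0]; ev[1] = a[1][1]; ev[2] = a[2][2];
}

// Quadratic sub-voxel refinement of DoG extremum candidates (position and
// scale), contrast test on the interpolated response, and a plate/edge
// rejection on the spatial Hessian: a genuine 3D blob extremum has spatial
// curvatures of one sign with bounded anisotropy.
// [[Rcpp::export]]
NumericMatrix cpp_refine_keypoints(List dogs, IntegerVector dim, IntegerMatrix cand,
                                   double contrast_threshold, double edge_threshold) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int L = dogs.size();
  std::vector<const double *> d(L);
  for (int l = 0; l < L; ++l) d[l] = REAL((SEXP)dogs[l]);

  const int n = cand.nrow();
  NumericMatrix out(n, 6);  // x, y, z, level (all refined), response, ok
  for (int i = 0; i < n; ++i) {
    int x = cand(i, 0), y = cand(i, 1), z = cand(i, 2), l = cand(i, 3);
    double dx = 0, dy = 0, dz = 0, ds = 0, value = 0;
    double g[4] = {0, 0, 0, 0};
    bool ok = false;
    for (int iter = 0; iter < 5; ++iter) {
      const double *D0 = d[l - 1], *D1 = d[l], *D2 = d[l + 1];
      const R_xlen_t c = vidx(x, y, z, nx, ny);
      const double v = D1[c];
      g[0] = 0.5 * (D1[vidx(x + 1, y, z, nx, ny)] - D1[vidx(x - 1, y, z, nx, ny)]);
      g[1] = 0.5 * (D1[vidx(x, y + 1, z, nx, ny)] - D1[vidx(x, y - 1, z, nx, ny)]);
      g[2] = 0.5 * (D1[vidx(x, y, z + 1, nx, ny)] - D1[vidx(x, y, z - 1, nx, ny)]);
      g[3] = 0.5 * (D2[c] - D0[c]);
      double H[4][4];
      H[0][0] = D1[vidx(x + 1, y, z, nx, ny)] + D1[vidx(x - 1, y, z, nx, ny)] - 2 * v;
      H[1][1] = D1[vidx(x, y + 1, z, nx, ny)] + D1[vidx(x, y - 1, z, nx, ny)] - 2 * v;
      H[2][2] = D1[vidx(x, y, z + 1, nx, ny)] + D1[vidx(x, y, z - 1, nx, ny)] - 2 * v;
      H[3][3] = D2[c] + D0[c] - 2 * v;
      H[0][1] = H[1][0] = 0.25 * (D1[vidx(x + 1, y + 1, z, nx, ny)] - D1[vidx(x - 1, y + 1, z, nx, ny)]
                                - D1[vidx(x + 1, y - 1, z, nx, ny)] + D1[vidx(x - 1, y - 1, z, nx, ny)]);
      H[0][2] = H[2][0] = 0.25 * (D1[vidx(x + 1, y, z + 1, nx, ny)] - D1[vidx(x - 1, y, z + 1, nx, ny)]
                                - D1[vidx(x + 1, y, z - 1, nx, ny)] + D1[vidx(x - 1, y, z - 1, nx, ny)]);
      H[1][2] = H[2][1] = 0.25 * (D1[vidx(x, y + 1, z + 1, nx, ny)] - D1[vidx(x, y - 1, z + 1, nx, ny)]
                                - D1[vidx(x, y + 1, z - 1, nx, ny)] + D1[vidx(x, y - 1, z - 1, nx, ny)]);
      H[0][3] = H[3][0] = 0.25 * (D2[vidx(x + 1, y, z, nx, ny)] - D2[vidx(x - 1, y, z, nx, ny)]
                                - D0[vidx(x + 1, y, z, nx, ny)] + D0[vidx(x - 1, y, z, nx, ny)]);
      H[1][3] = H[3][1] = 0.25 * (D2[vidx(x, y + 1, z, nx, ny)] - D2[vidx(x, y - 1, z, nx, ny)]
                                - D0[vidx(x, y + 1, z, nx, ny)] + D0[vidx(x, y - 1, z, nx, ny)]);
      H[2][3] = H[3][2] = 0.25 * (D2[vidx(x, y, z + 1, nx, ny)] - D2[vidx(x, y, z - 1, nx, ny)]
                                - D0[vidx(x, y, z + 1, nx, ny)] + D0[vidx(x, y, z - 1, nx, ny)]);
      double bvec[4] = {-g[0], -g[1], -g[2], -g[3]};
      double delta[4];
      double Hc[4][4];
      for (int r2 = 0; r2 < 4; ++r2) for (int c2 = 0; c2 < 4; ++c2) Hc[r2][c2] = H[r2][c2];
      if (!solve_small(Hc, bvec, delta, 4)) { ok = false; break; }
      dx = delta[0]; dy = delta[1]; dz = delta[2]; ds = delta[3];
      value = v;
      if (std::fabs(dx) <= 0.5 && std::fabs(dy) <= 0.5 &&
          std::fabs(dz) <= 0.5 && std::fabs(ds) <= 0.5) { ok = true; break; }
      x += (dx > 0.5) - (dx < -0.5);
      y += (dy > 0.5) - (dy < -0.5);
      z += (dz > 0.5) - (dz < -0.5);
      l += (ds > 0.5) - (ds < -0.5);
      if (x < 1 || x > nx - 2 || y < 1 || y > ny - 2 || z < 1 || z > nz - 2 ||
          l < 1 || l > L - 2) { ok = false; break; }
    }
    if (ok) {
      const double resp = value + 0.5 * (g[0] * dx + g[1] * dy + g[2] * dz + g[3] * ds);
      if (std::fabs(resp) < contrast_threshold) ok = false;
      if (ok) {
        // spatial Hessian at the final integer location
        const double *D1 = d[l];
        const R_xlen_t c = vidx(x, y, z, nx, ny);
        const double v = D1[c];
        double S[3][3];
        S[0][0] = D1[vidx(x + 1, y, z, nx, ny)] + D1[vidx(x - 1, y, z, nx, ny)] - 2 * v;
        S[1][1] = D1[vidx(x, y + 1, z, nx, ny)] + D1[vidx(x, y - 1, z, nx, ny)] - 2 * v;
        S[2][2] = D1[vidx(x, y, z + 1, nx, ny)] + D1[vidx(x, y, z - 1, nx, ny)] - 2 * v;
        S[0][1] = S[1][0] = 0.25 * (D1[vidx(x + 1, y + 1, z, nx, ny)] - D1[vidx(x - 1, y + 1, z, nx, ny)]
                                  - D1[vidx(x + 1, y - 1, z, nx, ny)] + D1[vidx(x - 1, y - 1, z, nx, ny)]);
        S[0][2] = S[2][0] = 0.25 * (D1[vidx(x + 1, y, z + 1, nx, ny)] - D1[vidx(x - 1, y, z + 1, nx, ny)]
                                  - D1[vidx(x + 1, y, z - 1, nx, ny)] + D1[vidx(x - 1, y, z - 1, nx, ny)]);
        S[1][2] = S[2][1] = 0.25 * (D1[vidx(x, y + 1, z + 1, nx, ny)] - D1[vidx(x, y - 1, z + 1, nx, ny)]
                                  - D1[vidx(x, y + 1, z - 1, nx, ny)] + D1[vidx(x, y - 1, z - 1, nx, ny)]);
        double ev[3];
        eig_sym3(S, ev);
        double amax = 0, amin = 1e300;
        bool pos = false, neg = false;
        for (int kk = 0; kk < 3; ++kk) {
          const double a2 = std::fabs(ev[kk]);
          if (a2 > amax) amax = a2;
          if (a2 < amin) amin = a2;
          if (ev[kk] > 0) pos = true;
          if (ev[kk] < 0) neg = true;
        }
        if ((pos && neg) || amin <= 0 || amax / amin > edge_threshold) ok = false;
      }
      out(i, 0) = x + dx; out(i, 1) = y + dy; out(i, 2) = z + dz;
      out(i, 3) = l + ds; out(i, 4) = resp;
    }
    out(i, 5) = ok ? 1.0 : 0.0;
  }
  return out;
}

// Gradient-histogram descriptors on one Gaussian level. coords are 0-based
// continuous voxel positions; dirs is 3 x n_orientations (unit vectors);
// sigma_vox is the keypoint scale in this grid's voxels. Each descriptor is
// nsub^3 spatial subregions x n_orientations bins, trilinearly shared across
// subregions, Gaussian-weighted over the window, clipped and renormalised.
// [[Rcpp::export]]
List cpp_descriptors(NumericVector gauss, IntegerVector dim, NumericMatrix coords,
                     double sigma_vox, NumericMatrix dirs, int nsub, double clip) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *G = REAL(gauss);
  const int n = coords.nrow();
  const int nori = dirs.ncol();
  const int dlen = nsub * nsub * nsub * nori;
  const double subw = 3.0 * sigma_vox;            // subregion width (voxels)
  const double half = 0.5 * nsub * subw;          // window half-extent
  const double wsig2 = 2.0 * half * half;         // Gaussian window weight

  NumericMatrix desc(n, dlen);
  LogicalVector keep(n);
  std::vector<double> hist(dlen);

  for (int i = 0; i < n; ++i) {
    const double cx = coords(i, 0), cy = coords(i, 1), cz = coords(i, 2);
    std::fill(hist.begin(), hist.end(), 0.0);
    const int x0 = std::max(1, (int)std::ceil(cx - half));
    const int x1 = std::min(nx - 2, (int)std::floor(cx + half));
    const int y0 = std::max(1, (int)std::ceil(cy - half));
    const int y1 = std::min(ny - 2, (int)std::floor(cy + half));
    const int z0 = std::max(1, (int)std::ceil(cz - half));
    const int z1 = std::min(nz - 2, (int)std::floor(cz + half));
    if (x0 > x1 || y0 > y1 || z0 > z1) { keep[i] = false; continue; }
    keep[i] = true;

    for (int z = z0; z <= z1; ++z)
      for (int y = y0; y <= y1; ++y)
        for (int x = x0; x <= x1; ++x) {
          const double gx = 0.5 * (G[vidx(x + 1, y, z, nx, ny)] - G[vidx(x - 1, y, z, nx, ny)]);
          const double gy = 0.5 * (G[vidx(x, y + 1, z, nx, ny)] - G[vidx(x, y - 1, z, nx, ny)]);
          const double gz = 0.5 * (G[vidx(x, y, z + 1, nx, ny)] - G[vidx(x, y, z - 1, nx, ny)]);
          const double mag = std::sqrt(gx * gx + gy * gy + gz * gz);
          if (mag < 1e-12) continue;
          const double ddx = x - cx, ddy = y - cy, ddz = z - cz;
          const double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
          const double w = std::exp(-r2 / wsig2) * mag;
          // orientation bin: direction of maximal alignment
          int b = 0; double bd = -1e300;
          for (int kk = 0; kk < nori; ++kk) {
            const double dp = gx * dirs(0, kk) + gy * dirs(1, kk) + gz * dirs(2, kk);
            if (dp > bd) { bd = dp; b = kk; }
          }
          // continuous subregion coordinates; centre bin index (nsub-1)/2
          const double ux = ddx / subw + 0.5 * (nsub - 1);
          const double uy = ddy / subw + 0.5 * (nsub - 1);
          const double uz = ddz / subw + 0.5 * (nsub - 1);
          const int ix0 = (int)std::floor(ux), iy0 = (int)std::floor(uy), iz0 = (int)std::floor(uz);
          const double fx = ux - ix0, fy = uy - iy0, fz = uz - iz0;
          for (int az = 0; az <= 1; ++az) {
            const int iz = iz0 + az;
            if (iz < 0 || iz >= nsub) continue;
            const double wz = az ? fz : 1.0 - fz;
            for (int ay = 0; ay <= 1; ++ay) {
              const int iy = iy0 + ay;
              if (iy < 0 || iy >= nsub) continue;
              const double wy = ay ? fy : 1.0 - fy;
              for (int ax = 0; ax <= 1; ++ax) {
                const int ix = ix0 + ax;
                if (ix < 0 || ix >= nsub) continue;
                const double wx = ax ? fx : 1.0 - fx;
                hist[(((size_t)iz * nsub + iy) * nsub + ix) * nori + b] += w * wx * wy * wz;
              }
            }
          }
        }

    double nrm = 0.0;
    for (int j = 0; j < dlen; ++j) nrm += hist[j] * hist[j];
    nrm = std::sqrt(nrm);
    if (nrm < 1e-12) {
      for (int j = 0; j < dlen; ++j) desc(i, j) = 0.0;  // degenerate flat window
      continue;
    }
    for (int j = 0; j < dlen; ++j) {
      double vv = hist[j] / nrm;
      if (vv > clip) vv = clip;
      hist[j] = vv;
    }
    nrm = 0.0;
    for (int j = 0; j < dlen; ++j) nrm += hist[j] * hist[j];
    nrm = std::sqrt(nrm);
    for (int j = 0; j < dlen; ++j) desc(i, j) = hist[j] / nrm;
  }
  return List::create(_["descriptors"] = desc, _["keep"] = keep);
}

// Sample a volume at continuous 0-based voxel coordinates.
// mode 0 = trilinear, 1 = nearest neighbour; outside the grid -> fill.
// [[Rcpp::export]]
NumericVector cpp_interp3(NumericVector vol, IntegerVector dim, NumericMatrix coords,
                          double fill, int mode) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *G = REAL(vol);
  const int n = coords.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double x = coords(i, 0), y = coords(i, 1), z = coords(i, 2);
    if (!(x >= 0 && x <= nx - 1 && y >= 0 && y <= ny - 1 && z >= 0 && z <= nz - 1)) {
      out[i] = fill;
      continue;
    }
    if (mode == 1) {
      out[i] = G[vidx((int)std::lround(x), (int)std::lround(y), (int)std::lround(z), nx, ny)];
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 >= nx - 1) x0 = nx - 2;
    if (y0 >= ny - 1) y0 = ny - 2;
    if (z0 >= nz - 1) z0 = nz - 2;
    if (x0 < 0 || y0 < 0 || z0 < 0) { out[i] = fill; continue; }  // degenerate 1-voxel axis
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    const double c000 = G[vidx(x0, y0, z0, nx, ny)];
    const double c100 = G[vidx(x0 + 1, y0, z0, nx, ny)];
    const double c010 = G[vidx(x0, y0 + 1, z0, nx, ny)];
    const double c110 = G[vidx(x0 + 1, y0 + 1, z0, nx, ny)];
    const double c001 = G[vidx(x0, y0, z0 + 1, nx, ny)];
    const double c101 = G[vidx(x0 + 1, y0, z0 + 1, nx, ny)];
    const double c011 = G[vidx(x0, y0 + 1, z0 + 1, nx, ny)];
    const double c111 = G[vidx(x0 + 1, y0 + 1, z0 + 1, nx, ny)];
    out[i] =
      c000 * (1 - fx) * (1 - fy) * (1 - fz) + c100 * fx * (1 - fy) * (1 - fz) +
      c010 * (1 - fx) * fy * (1 - fz)       + c110 * fx * fy * (1 - fz) +
      c001 * (1 - fx) * (1 - fy) * fz       + c101 * fx * (1 - fy) * fz +
      c011 * (1 - fx) * fy * fz             + c111 * fx * fy * fz;
  }
  return out;
}

// ---- phantom scene kernels -------------------------------------------------
// Sum of components evaluated at n x 3 physical points with bounding-box
// culling per component; used by the synthetic phantom generator.

static inline double soft_in_c(double m, double w) {
  const double v = (1.0 - m) / w;
  return v < 0 ? 0.0 : (v > 1 ? 1.0 : v);
}

// Gaussian blobs: value += amp_k * exp(-r^2 / (2 sigma_k^2)), support 3 sigma.
// [[Rcpp::export]]
NumericVector cpp_scene_blobs(NumericMatrix pts, NumericMatrix centers,
                              NumericVector sigma, NumericVector amp) {
  const int n = pts.nrow(), m = centers.nrow();
  NumericVector out(n);
  for (int k = 0; k < m; ++k) {
    const double cx = centers(k, 0), cy = centers(k, 1), cz = centers(k, 2);
    const double s = sigma[k], a = amp[k], s3 = 3.0 * s;
    const double inv2s2 = 1.0 / (2.0 * s * s);
    for (int i = 0; i < n; ++i) {
      const double dx = pts(i, 0) - cx;
      if (dx > s3 || dx < -s3) continue;
      const double dy = pts(i, 1) - cy;
      if (dy > s3 || dy < -s3) continue;
      const double dz = pts(i, 2) - cz;
      if (dz > s3 || dz < -s3) continue;
      out[i] += a * std::exp(-(dx * dx + dy * dy + dz * dz) * inv2s2);
    }
  }
  return out;
}

// Soft-edged ellipsoids: params columns cx,cy,cz,rx,ry,rz,amp; edge width w
// (relative to the unit radius).
// [[Rcpp::export]]
NumericVector cpp_scene_ellipsoids(NumericMatrix pts, NumericMatrix par,
                                   double w) {
  const int n = pts.nrow(), m = par.nrow();
  NumericVector out(n);
  for (int k = 0; k < m; ++k) {
    const double cx = par(k, 0), cy = par(k, 1), cz = par(k, 2);
    const double rx = par(k, 3), ry = par(k, 4), rz = par(k, 5), a = par(k, 6);
    const double bx = rx * (1 + w), by = ry * (1 + w), bz = rz * (1 + w);
    for (int i = 0; i < n; ++i) {
      const double dx = pts(i, 0) - cx;
      if (dx > bx || dx < -bx) continue;
      const double dy = pts(i, 1) - cy;
      if (dy > by || dy < -by) continue;
      const double dz = pts(i, 2) - cz;
      if (dz > bz || dz < -bz) continue;
      const double mm2 = (dx / rx) * (dx / rx) + (dy / ry) * (dy / ry) +
        (dz / rz) * (dz / rz);
      out[i] += a * soft_in_c(std::sqrt(mm2), w);
    }
  }
  return out;
}

// Soft-edged spheres: params columns cx,cy,cz,r,amp; edge width w relative.
// [[Rcpp::export]]
NumericVector cpp_scene_spheres(NumericMatrix pts, NumericMatrix par, double w) {
  const int n = pts.nrow(), m = par.nrow();
  NumericVector out(n);
  for (int k = 0; k < m; ++k) {
    const double cx = par(k, 0), cy = par(k, 1), cz = par(k, 2);
    const double r = par(k, 3), a = par(k, 4), b = r * (1 + w);
    for (int i = 0; i < n; ++i) {
      const double dx = pts(i, 0) - cx;
      if (dx > b || dx < -b) continue;
      const double dy = pts(i, 1) - cy;
      if (dy > b || dy < -b) continue;
      const double dz = pts(i, 2) - cz;
      if (dz > b || dz < -b) continue;
      const double rr = std::sqrt(dx * dx + dy * dy + dz * dz);
      out[i] += a * soft_in_c(rr / r, w);
    }
  }
  return out;
}

// Render a dense Gaussian-blob texture field directly onto a regular grid
// (identity direction matrix); each blob only touches its 3-sigma box.
// [[Rcpp::export]]
NumericVector cpp_render_blobs_grid(IntegerVector dim, NumericVector spacing,
                                    NumericVector origin, NumericMatrix centers,
                                    NumericVector sigma, NumericVector amp) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  double *o = REAL(out);
  for (int k = 0; k < centers.nrow(); ++k) {
    const double cx = centers(k, 0), cy = centers(k, 1), cz = centers(k, 2);
    const double s = sigma[k], a = amp[k];
    const double inv2s2 = 1.0 / (2.0 * s * s);
    const int x0 = clampi((int)std::ceil((cx - 3 * s - origin[0]) / spacing[0]), 0, nx - 1);
    const int x1 = clampi((int)std::floor((cx + 3 * s - origin[0]) / spacing[0]), 0, nx - 1);
    const int y0 = clampi((int)std::ceil((cy - 3 * s - origin[1]) / spacing[1]), 0, ny - 1);
    const int y1 = clampi((int)std::floor((cy + 3 * s - origin[1]) / spacing[1]), 0, ny - 1);
    const int z0 = clampi((int)std::ceil((cz - 3 * s - origin[2]) / spacing[2]), 0, nz - 1);
    const int z1 = clampi((int)std::floor((cz + 3 * s - origin[2]) / spacing[2]), 0, nz - 1);
    for (int z = z0; z <= z1; ++z) {
      const double dz = origin[2] + z * spacing[2] - cz;
      for (int y = y0; y <= y1; ++y) {
        const double dy = origin[1] + y * spacing[1] - cy;
        const double ryz = dy * dy + dz * dz;
        for (int x = x0; x <= x1; ++x) {
          const double dx = origin[0] + x * spacing[0] - cx;
          o[vidx(x, y, z, nx, ny)] += a * std::exp(-(dx * dx + ryz) * inv2s2);
        }
      }
    }
  }
  return out;
}
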