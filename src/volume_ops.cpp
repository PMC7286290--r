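// Low-level 3D volume kernels.
//
// Conventions (shared with the R layer):
//  - volumes are R arrays dim = c(nx, ny, nz), column-major, element (i,j,k)
//    0-based at i + nx*(j + ny*k);
//  - physical coordinates are micrometres, voxel centre of (i,j,k) at
//    (i*vx, j*vy, k*vz), i.e. 0-based indices, right-handed X,Y,Z.
#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

static inline R_xlen_t vidx(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

static inline double ramp01(double t) {
  return t <= 0.0 ? 0.0 : (t >= 1.0 ? 1.0 : t);
}

// Trilinear interpolation of a lattice of noise values; lattice is
// (ln x ln x ln) with coordinates u in [0, ln-1].
static inline double lattice_at(const double *lat, int ln, double u, double v, double w) {
  if (u < 0) u = 0; if (v < 0) v = 0; if (w < 0) w = 0;
  double mx = ln - 1.000001;
  if (u > mx) u = mx; if (v > mx) v = mx; if (w > mx) w = mx;
  int i0 = (int)u, j0 = (int)v, k0 = (int)w;
  double fu = u - i0, fv = v - j0, fw = w - k0;
  double acc = 0.0;
  for (int dk = 0; dk < 2; ++dk)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        double wgt = (di ? fu : 1 - fu) * (dj ? fv : 1 - fv) * (dk ? fw : 1 - fw);
        acc += wgt * lat[(i0 + di) + ln * ((j0 + dj) + ln * (k0 + dk))];
      }
  return acc;
}

// Rasterize phase-dependent nucleus densities into a volume.
//
// nuc columns: x, y, z (um), radius (um), phase (1=interphase, 2=prophase,
// 3=metaphase, 4=anaphase), ax, ay, az (unit division/plate axis),
// phase_frac (progress within current phase, 0..1).
//
// phase_par list fields (each numeric vector indexed by phase 1..4):
//   base  - chromatin density scale
//   amp   - multiplicative texture amplitude
//   grain - texture correlation length (um)
// Additional scalars: edge (soft edge width um).
//
// Uses the R RNG for per-nucleus texture lattices: deterministic when the
// caller has seeded the RNG. tex_rot maps raster-frame offsets into the
// world frame for texture lookup, so that both camera views sample the same
// world-anchored chromatin texture.
// [[Rcpp::export]]
NumericVector cpp_rasterize_nuclei(IntegerVector dim, NumericVector voxel,
                                   NumericMatrix nuc, List phase_par,
                                   NumericMatrix tex_rot) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double vx = voxel[0], vy = voxel[1], vz = voxel[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  NumericVector base = phase_par["base"], amp = phase_par["amp"],
                grain = phase_par["grain"];
  double edge = as<double>(phase_par["edge"]);
  RNGScope scope;

  for (int n = 0; n < nuc.nrow(); ++n) {
    double cx = nuc(n, 0), cy = nuc(n, 1), cz = nuc(n, 2);
    double r = nuc(n, 3);
    int ph = (int)nuc(n, 4);
    double ux = nuc(n, 5), uy = nuc(n, 6), uz = nuc(n, 7);
    double pf = nuc(n, 8);
    double b = base[ph - 1], a = amp[ph - 1], g = grain[ph - 1];

    // spatial extent of the object (anaphase lobes separate along the axis)
    double ext = r * 1.15;
    double sep = 0.0, lober = 0.0;
    if (ph == 4) {
      // chromatid masses are already separating at anaphase onset
      sep = (0.50 + 0.45 * pf) * r;   // lobe centre offset, per side
      lober = 0.65 * r;
      ext = sep + lober + 0.3;
    }

    // texture lattice spanning the bounding cube
    int ln = (int)std::ceil(2.0 * ext / g) + 3;
    if (ln < 4) ln = 4;
    std::vector<double> lat((size_t)ln * ln * ln);
    for (size_t q = 0; q < lat.size(); ++q) lat[q] = unif_rand();

    int i0 = std::max(0, (int)std::floor((cx - ext) / vx) - 1);
    int i1 = std::min(nx - 1, (int)std::ceil((cx + ext) / vx) + 1);
    int j0 = std::max(0, (int)std::floor((cy - ext) / vy) - 1);
    int j1 = std::min(ny - 1, (int)std::ceil((cy + ext) / vy) + 1);
    int k0 = std::max(0, (int)std::floor((cz - ext) / vz) - 1);
    int k1 = std::min(nz - 1, (int)std::ceil((cz + ext) / vz) + 1);

    for (int k = k0; k <= k1; ++k) {
      double pz = k * vz - cz;
      for (int j = j0; j <= j1; ++j) {
        double py = j * vy - cy;
        for (int i = i0; i <= i1; ++i) {
          double px = i * vx - cx;
          double m = 0.0;  // interior measure in [0,1]
          if (ph == 1 || ph == 2) {
            double rr = (ph == 2) ? 1.05 * r : r;
            double d = std::sqrt(px * px + py * py + pz * pz);
            m = ramp01((rr - d) / edge);
          } else if (ph == 3) {
            // oblate metaphase plate perpendicular to the division axis
            double ax = px * ux + py * uy + pz * uz;
            double qx = px - ax * ux, qy = py - ax * uy, qz = pz - ax * uz;
            double rho = std::sqrt(qx * qx + qy * qy + qz * qz);
            double ma = ramp01((0.28 * r - std::fabs(ax)) / edge);
            double mr = ramp01((0.85 * r - rho) / edge);
            m = ma * mr;
          } else {
            // anaphase: two condensed lobes plus a fainter chromatin bridge
            double d1x = px - sep * ux, d1y = py - sep * uy, d1z = pz - sep * uz;
            double d2x = px + sep * ux, d2y = py + sep * uy, d2z = pz + sep * uz;
            double m1 = ramp01((lober - std::sqrt(d1x * d1x + d1y * d1y + d1z * d1z)) / edge);
            double m2 = ramp01((lober - std::sqrt(d2x * d2x + d2y * d2y + d2z * d2z)) / edge);
            double ax = px * ux + py * uy + pz * uz;
            double qx = px - ax * ux, qy = py - ax * uy, qz = pz - ax * uz;
            double rho = std::sqrt(qx * qx + qy * qy + qz * qz);
            double mb = 0.0;
            if (std::fabs(ax) <= sep)
              mb = 0.72 * ramp01((0.28 * r - rho) / edge);
            m = std::max(std::max(m1, m2), mb);
          }
          if (m <= 0.0) continue;
          double wx = tex_rot(0,0)*px + tex_rot(0,1)*py + tex_rot(0,2)*pz;
          double wy = tex_rot(1,0)*px + tex_rot(1,1)*py + tex_rot(1,2)*pz;
          double wz = tex_rot(2,0)*px + tex_rot(2,1)*py + tex_rot(2,2)*pz;
          double u = (wx + ext) / g, v = (wy + ext) / g, w = (wz + ext) / g;
          double tex = 1.0 + a * 2.0 * (lattice_at(lat.data(), ln, u, v, w) - 0.5);
          if (tex < 0.05) tex = 0.05;
          out[vidx(i, j, k, nx, ny)] += b * m * tex;
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Add anisotropic Gaussian point sources (e.g. beads already convolved with
// the PSF) at exact continuous positions. sigma is per-axis in um.
// [[Rcpp::export]]
NumericVector cpp_add_points(NumericVector vol, IntegerVector dim, NumericVector voxel,
                             NumericMatrix pts, NumericVector amp, NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double vx = voxel[0], vy = voxel[1], vz = voxel[2];
  NumericVector out = clone(vol);
  double ex = 4.0 * sigma[0], ey = 4.0 * sigma[1], ez = 4.0 * sigma[2];
  double sx2 = 2.0 * sigma[0] * sigma[0];
  double sy2 = 2.0 * sigma[1] * sigma[1];
  double sz2 = 2.0 * sigma[2] * sigma[2];
  for (int n = 0; n < pts.nrow(); ++n) {
    double cx = pts(n, 0), cy = pts(n, 1), cz = pts(n, 2), A = amp[n];
    int i0 = std::max(0, (int)std::floor((cx - ex) / vx));
    int i1 = std::min(nx - 1, (int)std::ceil((cx + ex) / vx));
    int j0 = std::max(0, (int)std::floor((cy - ey) / vy));
    int j1 = std::min(ny - 1, (int)std::ceil((cy + ey) / vy));
    int k0 = std::max(0, (int)std::floor((cz - ez) / vz));
    int k1 = std::min(nz - 1, (int)std::ceil((cz + ez) / vz));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          double dx = i * vx - cx, dy = j * vy - cy, dz = k * vz - cz;
          out[vidx(i, j, k, nx, ny)] +=
            A * std::exp(-dx * dx / sx2 - dy * dy / sy2 - dz * dz / sz2);
        }
  }
  out.attr("dim") = dim;
  return out;
}

static void conv_axis(const std::vector<double> &in, std::vector<double> &out,
                      int nx, int ny, int nz, const NumericVector &ker, int axis) {
  int kl = ker.size(), half = kl / 2;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        for (int t = 0; t < kl; ++t) {
          int o = t - half;
          int ii = i, jj = j, kk = k;
          if (axis == 0) ii += o; else if (axis == 1) jj += o; else kk += o;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          acc += ker[t] * in[vidx(ii, jj, kk, nx, ny)];
        }
        out[vidx(i, j, k, nx, ny)] = acc;
      }
}

// Separable convolution (zero padding) with per-axis 1D kernels.
// [[Rcpp::export]]
NumericVector cpp_conv_sep(NumericVector vol, IntegerVector dim,
                           NumericVector kx, NumericVector ky, NumericVector kz) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  conv_axis(a, b, nx, ny, nz, kx, 0);
  conv_axis(b, a, nx, ny, nz, ky, 1);
  conv_axis(a, b, nx, ny, nz, kz, 2);
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = dim;
  return out;
}

// Direct 3D convolution (correlate = TRUE flips to cross-correlation, i.e.
// convolution with the mirrored kernel) with zero padding. Kernel taps with
// |value| < tap_eps are skipped.
// [[Rcpp::export]]
NumericVector cpp_conv3(NumericVector vol, IntegerVector dim,
                        NumericVector ker, IntegerVector kdim,
                        bool correlate, double tap_eps) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int mx = kdim[0], my = kdim[1], mz = kdim[2];
  int cx = mx / 2, cy = my / 2, cz = mz / 2;
  // gather non-negligible taps
  std::vector<int> oi, oj, ok; std::vector<double> ov;
  for (int c = 0; c < mz; ++c)
    for (int b = 0; b < my; ++b)
      for (int a = 0; a < mx; ++a) {
        double v = ker[vidx(a, b, c, mx, my)];
        if (std::fabs(v) < tap_eps) continue;
        int da = a - cx, db = b - cy, dc = c - cz;
        if (!correlate) { da = -da; db = -db; dc = -dc; }
        oi.push_back(da); oj.push_back(db); ok.push_back(dc); ov.push_back(v);
      }
  int nt = oi.size();
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double *pv = REAL(vol);
  double *po = REAL(out);
  // linear offsets and the interior box where no bounds checks are needed
  std::vector<R_xlen_t> loff(nt);
  int ilo = 0, ihi = nx - 1, jlo = 0, jhi = ny - 1, klo = 0, khi = nz - 1;
  for (int t = 0; t < nt; ++t) {
    loff[t] = (R_xlen_t)oi[t] + (R_xlen_t)nx * ((R_xlen_t)oj[t] + (R_xlen_t)ny * ok[t]);
    ilo = std::max(ilo, -oi[t]); ihi = std::min(ihi, nx - 1 - oi[t]);
    jlo = std::max(jlo, -oj[t]); jhi = std::min(jhi, ny - 1 - oj[t]);
    klo = std::max(klo, -ok[t]); khi = std::min(khi, nz - 1 - ok[t]);
  }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      bool rowInterior = k >= klo && k <= khi && j >= jlo && j <= jhi;
      R_xlen_t base = (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
      if (rowInterior && ilo <= ihi) {
        for (int i = ilo; i <= ihi; ++i) {
          double acc = 0.0;
          const double *src = pv + base + i;
          for (int t = 0; t < nt; ++t) acc += ov[t] * src[loff[t]];
          po[base + i] = acc;
        }
      }
      int iFrom = rowInterior ? 0 : 0;
      for (int i = iFrom; i < nx; ++i) {
        if (rowInterior && i >= ilo && i <= ihi) { i = ihi; continue; }
        double acc = 0.0;
        for (int t = 0; t < nt; ++t) {
          int ii = i + oi[t], jj = j + oj[t], kk = k + ok[t];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          acc += ov[t] * pv[vidx(ii, jj, kk, nx, ny)];
        }
        po[base + i] = acc;
      }
    }
  out.attr("dim") = dim;
  return out;
}

// Pull-back trilinear resampling.  For output voxel centre p (um on the
// output grid) the input is sampled at q = M p + t (um on the input grid).
// Returns the resampled volume and a validity mask (1 where all 8 support
// voxels were inside the input grid).
// [[Rcpp::export]]
List cpp_affine_resample(NumericVector vol, IntegerVector dim_in, NumericVector vox_in,
                         IntegerVector dim_out, NumericVector vox_out,
                         NumericMatrix M, NumericVector t) {
  int nx = dim_in[0], ny = dim_in[1], nz = dim_in[2];
  int ox = dim_out[0], oy = dim_out[1], oz = dim_out[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  IntegerVector msk((R_xlen_t)ox * oy * oz);
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i) {
        double px = i * vox_out[0], py = j * vox_out[1], pz = k * vox_out[2];
        double qx = M(0,0)*px + M(0,1)*py + M(0,2)*pz + t[0];
        double qy = M(1,0)*px + M(1,1)*py + M(1,2)*pz + t[1];
        double qz = M(2,0)*px + M(2,1)*py + M(2,2)*pz + t[2];
        double fi = qx / vox_in[0], fj = qy / vox_in[1], fk = qz / vox_in[2];
        int i0 = (int)std::floor(fi), j0 = (int)std::floor(fj), k0 = (int)std::floor(fk);
        R_xlen_t oidx = vidx(i, j, k, ox, oy);
        if (i0 < 0 || j0 < 0 || k0 < 0 || i0 >= nx - 1 || j0 >= ny - 1 || k0 >= nz - 1) {
          // boundary-exact case: allow sampling exactly on the last plane
          bool edge_ok = fi >= 0 && fj >= 0 && fk >= 0 &&
                         fi <= nx - 1 && fj <= ny - 1 && fk <= nz - 1;
          if (!edge_ok) { out[oidx] = 0.0; msk[oidx] = 0; continue; }
          if (i0 >= nx - 1) i0 = nx - 2;
          if (j0 >= ny - 1) j0 = ny - 2;
          if (k0 >= nz - 1) k0 = nz - 2;
        }
        double fu = fi - i0, fv = fj - j0, fw = fk - k0;
        double acc = 0.0;
        for (int dk = 0; dk < 2; ++dk)
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              double wgt = (di ? fu : 1 - fu) * (dj ? fv : 1 - fv) * (dk ? fw : 1 - fw);
              acc += wgt * vol[vidx(i0 + di, j0 + dj, k0 + dk, nx, ny)];
            }
        out[oidx] = acc;
        msk[oidx] = 1;
      }
  out.attr("dim") = dim_out;
  msk.attr("dim") = dim_out;
  return List::create(_["volume"] = out, _["mask"] = msk);
}

// Strict 26-neighbourhood local maxima above a threshold; returns 0-based
// voxel indices (one row per maximum).
// [[Rcpp::export]]
IntegerMatrix cpp_local_maxima(NumericVector vol, IntegerVector dim, double thresh) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> ri, rj, rk;
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 1; j < ny - 1; ++j)
      for (int i = 1; i < nx - 1; ++i) {
        double v = vol[vidx(i, j, k, nx, ny)];
        if (v < thresh) continue;
        bool ismax = true;
        for (int dk = -1; dk <= 1 && ismax; ++dk)
          for (int dj = -1; dj <= 1 && ismax; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (!di && !dj && !dk) continue;
              if (vol[vidx(i + di, j + dj, k + dk, nx, ny)] >= v) { ismax = false; break; }
            }
        if (ismax) { ri.push_back(i); rj.push_back(j); rk.push_back(k); }
      }
  IntegerMatrix out(ri.size(), 3);
  for (size_t n = 0; n < ri.size(); ++n) {
    out(n, 0) = ri[n]; out(n, 1) = rj[n]; out(n, 2) = rk[n];
  }
  return out;
}

// Connected-component labelling of a binary mask (26- or 6-connectivity).
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dim, int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    stack.clear(); stack.push_back(s); lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int i = cur % nx, j = (cur / nx) % ny, k = cur / ((R_xlen_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            if (connectivity == 6 && std::abs(di) + std::abs(dj) + std::abs(dk) != 1) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            R_xlen_t q = vidx(ii, jj, kk, nx, ny);
            if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// One binary erosion step with the 6-connected structuring element.
// [[Rcpp::export]]
IntegerVector cpp_erode6(IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector out((R_xlen_t)nx * ny * nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t s = vidx(i, j, k, nx, ny);
        if (!mask[s]) continue;
        bool keep = true;
        static const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
        for (int t = 0; t < 6 && keep; ++t) {
          int ii = i + off[t][0], jj = j + off[t][1], kk = k + off[t][2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) { keep = false; break; }
          if (!mask[vidx(ii, jj, kk, nx, ny)]) keep = false;
        }
        out[s] = keep ? 1 : 0;
      }
  out.attr("dim") = dim;
  return out;
}

// One binary dilation step with the 6-connected structuring element.
// [[Rcpp::export]]
IntegerVector cpp_dilate6(IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector out = clone(mask);
  static const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t s = vidx(i, j, k, nx, ny);
        if (mask[s]) continue;
        for (int t = 0; t < 6; ++t) {
          int ii = i + off[t][0], jj = j + off[t][1], kk = k + off[t][2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          if (mask[vidx(ii, jj, kk, nx, ny)]) { out[s] = 1; break; }
        }
      }
  out.attr("dim") = dim;
  return out;
}

// Multi-source BFS region growing: marker labels expand (6-connectivity,
// breadth-first, so roughly geodesic-distance ordered) until they fill the
// mask. Deterministic: at equal distance the voxel keeps the label that
// reached it first in queue order.
// [[Rcpp::export]]
IntegerVector cpp_geodesic_grow(IntegerVector markers, IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab = clone(markers);
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) if (lab[s] && mask[s]) q.push(s);
  static const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!q.empty()) {
    R_xlen_t cur = q.front(); q.pop();
    int i = cur % nx, j = (cur / nx) % ny, k = cur / ((R_xlen_t)nx * ny);
    for (int t = 0; t < 6; ++t) {
      int ii = i + off[t][0], jj = j + off[t][1], kk = k + off[t][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      R_xlen_t s = vidx(ii, jj, kk, nx, ny);
      if (mask[s] && !lab[s]) { lab[s] = lab[cur]; q.push(s); }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Symmetric grey-level co-occurrence accumulation for every segment at once.
// labels: 0 background, 1..K; q: per-voxel grey level 1..G (quantized within
// its own segment; 0 outside segments). offsets: m x 3 integer direction
// vectors. Pairs are counted only when both voxels carry the same label.
// Returns counts as a G*G*m*K vector (dim set R-side).
// [[Rcpp::export]]
NumericVector cpp_glcm_all(IntegerVector labels, IntegerVector q, IntegerVector dim,
                           IntegerMatrix offsets, int G, int K) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int m = offsets.nrow();
  NumericVector out((R_xlen_t)G * G * m * K);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t s = vidx(i, j, k, nx, ny);
        int L = labels[s];
        if (!L) continue;
        int a = q[s];
        for (int t = 0; t < m; ++t) {
          int ii = i + offsets(t, 0), jj = j + offsets(t, 1), kk = k + offsets(t, 2);
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          R_xlen_t s2 = vidx(ii, jj, kk, nx, ny);
          if (labels[s2] != L) continue;
          int b = q[s2];
          R_xlen_t off = ((R_xlen_t)(L - 1) * m + t) * G * G;
          out[off + (a - 1) + (R_xlen_t)G * (b - 1)] += 1.0;
          out[off + (b - 1) + (R_xlen_t)G * (a - 1)] += 1.0;  // symmetric
        }
      }
  out.attr("dim") = IntegerVector::create(G, G, m, K);
  return out;
}
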