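// Positron-range kernel machinery: voxel-traversal ray-mean densities,
// uniform and spatially variant (TDSV) annihilation kernels, and the
// per-voxel kernel bank used by the spatially variant blur operator.
//
// Voxel weights integrate the annihilation density over each voxel cell
// by midpoint sub-cell quadrature.  Sub-cells refine axes whose voxel
// edge is much longer than the shortest edge (thick-slab, quasi-2D
// volumes), so a 0.4 x 0.4 x 50 mm voxel receives the aPSF mass
// marginalized over its axial column rather than the central-plane cut.
// The 1/r^2 singularity at the source is absorbed by integrating the
// radial density over the half-voxel sphere (radius h = half the
// shortest voxel edge).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct DensityGrid {
  const double *d;
  int nx, ny, nz;
  double boundary; // density assumed outside the grid ("air" mode)
  bool clamp;      // edge-replicate instead (extruded/cropped objects)

  inline double at(int i, int j, int k) const {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) {
      if (!clamp) return boundary;
      i = std::min(std::max(i, 0), nx - 1);
      j = std::min(std::max(j, 0), ny - 1);
      k = std::min(std::max(k, 0), nz - 1);
    }
    return d[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)];
  }
};

// Length-weighted mean density along the segment joining the centres of
// voxel (ci,cj,ck) and voxel (ci+oi, cj+oj, ck+ok).  Amanatides-Woo
// traversal in index space; plane crossings are identical in physical
// space, so anisotropic voxels need no special handling (weights are
// fractions of total segment length).
double ray_mean(const DensityGrid &g, int ci, int cj, int ck,
                int oi, int oj, int ok) {
  if (oi == 0 && oj == 0 && ok == 0) return g.at(ci, cj, ck);
  const double dir[3] = {(double)oi, (double)oj, (double)ok};
  int cur[3] = {ci, cj, ck};
  int stp[3];
  double tMax[3], tDel[3];
  for (int a = 0; a < 3; ++a) {
    if (dir[a] > 0) {
      stp[a] = 1; tMax[a] = 0.5 / dir[a]; tDel[a] = 1.0 / dir[a];
    } else if (dir[a] < 0) {
      stp[a] = -1; tMax[a] = -0.5 / dir[a]; tDel[a] = -1.0 / dir[a];
    } else {
      stp[a] = 0; tMax[a] = 2.0; tDel[a] = 2.0;
    }
  }
  double t = 0.0, acc = 0.0;
  for (;;) {
    int ax = 0;
    if (tMax[1] < tMax[ax]) ax = 1;
    if (tMax[2] < tMax[ax]) ax = 2;
    if (tMax[ax] >= 1.0) {
      acc += (1.0 - t) * g.at(cur[0], cur[1], cur[2]);
      break;
    }
    acc += (tMax[ax] - t) * g.at(cur[0], cur[1], cur[2]);
    t = tMax[ax];
    cur[ax] += stp[ax];
    tMax[ax] += tDel[ax];
  }
  return acc;
}

// Radial-profile lookup.  B(u) = u^2 * aPSF(u) is bounded and smooth, so
// a uniform linear-interpolation table over [0, r0] is accurate at every
// distance including the 1/r^2 core; M(t) = int_0^t B(u) du handles the
// half-voxel sphere at the source.
struct Apsf {
  const double *B, *M;
  int n;
  double r0, h;

  inline double bval(double u) const {
    if (u < 0.0 || u >= r0) return 0.0;
    double p = u / r0 * (n - 1);
    int i0 = (int)p;
    if (i0 >= n - 1) return B[n - 1];
    double f = p - i0;
    return B[i0] * (1.0 - f) + B[i0 + 1] * f;
  }
  inline double mval(double t) const {
    if (t <= 0.0) return 0.0;
    if (t >= r0) return M[n - 1];
    double p = t / r0 * (n - 1);
    int i0 = (int)p;
    if (i0 >= n - 1) return M[n - 1];
    double f = p - i0;
    return M[i0] * (1.0 - f) + M[i0 + 1] * f;
  }
  // integral of the annihilation density over the half-voxel sphere:
  // int_0^h [B(r*rho)*rho/r^2] 4 pi r^2 dr = 4 pi M(rho*h)
  inline double w_center(double rho) const {
    if (rho <= 0.0) return 0.0;
    return 4.0 * M_PI * mval(rho * h);
  }
};

// Sub-cell quadrature scheme.  fine[a] sub-cells on axis a for stencil
// cells aligned with the source on that axis (where the integrand
// varies fastest), coarse[a] elsewhere.
struct Subdiv {
  int fine[3], coarse[3];
  double vox[3];
  static Subdiv make(const double *vox) {
    Subdiv s;
    double mn = std::min(vox[0], std::min(vox[1], vox[2]));
    for (int a = 0; a < 3; ++a) {
      s.vox[a] = vox[a];
      if (vox[a] <= 1.5 * mn) {
        s.fine[a] = s.coarse[a] = 1;
      } else {
        s.fine[a] = std::min((int)std::ceil(vox[a] / mn), 32);
        s.coarse[a] = std::max(1, std::min(
            (int)std::ceil(vox[a] / (8.0 * mn)), 4));
      }
    }
    return s;
  }
};

// Geometric annihilation mass assigned to stencil cell (oi,oj,ok) for a
// ray-mean relative density rho, by sub-cell midpoint quadrature.  The
// probability-conserving density of the straight-line transport model is
//   p(r) = B(r_eq) * rho_local / r^2,   r_eq = r * rho_ray,
// (B = u^2 aPSF(u): annihilations per water-equivalent path length over
// 4pi; the physical r^2 is the solid-angle Jacobian and the local
// density the annihilation rate, so a positron crossing an air cavity
// traverses it instead of annihilating inside, and the stencil total
// never exceeds 1).  This function returns the rho_local-independent
// part; callers multiply by the target's local density (equal to rho
// for the source cell and in homogeneous media, where the factor is
// constant and cancels under normalization).  The source cell integrates
// the half-voxel sphere and skips sub-cells inside it.
double cell_weight(const Apsf &f, const Subdiv &s, int oi, int oj, int ok,
                   double rho) {
  if (rho <= 0.0) return 0.0;
  const bool center = (oi == 0 && oj == 0 && ok == 0);
  const int nx = oi == 0 ? s.fine[0] : s.coarse[0];
  const int ny = oj == 0 ? s.fine[1] : s.coarse[1];
  const int nz = ok == 0 ? s.fine[2] : s.coarse[2];
  const double subV = s.vox[0] * s.vox[1] * s.vox[2] / (nx * ny * nz);
  double w = center ? f.w_center(rho) / rho : 0.0;
  for (int mz = 0; mz < nz; ++mz) {
    const double zc = (ok + (mz + 0.5) / nz - 0.5) * s.vox[2];
    for (int my = 0; my < ny; ++my) {
      const double yc = (oj + (my + 0.5) / ny - 0.5) * s.vox[1];
      for (int mx = 0; mx < nx; ++mx) {
        const double xc = (oi + (mx + 0.5) / nx - 0.5) * s.vox[0];
        const double d = std::sqrt(xc * xc + yc * yc + zc * zc);
        if (d < f.h) continue; // inside the source sphere
        const double u = d * rho;
        if (u >= f.r0) continue;
        w += f.bval(u) / (d * d) * subV;
      }
    }
  }
  return w;
}

// --- precomputed traversal patterns (thin-slab fast path) -------------------
// For volumes with few axial slices the per-(slab, offset) voxel
// traversal is shift-invariant in-plane; entries are merged per
// traversed (di, dj, resolved-k) voxel.  outLen accumulates the segment
// fraction spent outside the grid axially (air mode).
struct PatEntry { int di, dj, kk; double len; };

struct Patterns {
  int size, R, nz;
  bool clamp;
  std::vector<PatEntry> entries;
  std::vector<size_t> start; // per (k, offset), length nz*size^3+1
  std::vector<double> outLen;

  void build(int size_, int nz_, bool clamp_) {
    size = size_; R = size_ / 2; nz = nz_; clamp = clamp_;
    const size_t nOff = (size_t)size * size * size;
    start.assign((size_t)nz * nOff + 1, 0);
    outLen.assign((size_t)nz * nOff, 0.0);
    entries.clear();
    std::vector<PatEntry> local;
    size_t p = 0;
    for (int k = 0; k < nz; ++k)
      for (int ok = -R; ok <= R; ++ok)
        for (int oj = -R; oj <= R; ++oj)
          for (int oi = -R; oi <= R; ++oi, ++p) {
            start[p] = entries.size();
            local.clear();
            double out = 0.0;
            trace(k, oi, oj, ok, local, out);
            outLen[p] = out;
            for (const PatEntry &e : local) entries.push_back(e);
          }
    start[p] = entries.size();
  }

  void push(std::vector<PatEntry> &local, double &out, int di, int dj,
            int kk, double len) {
    if (kk < 0 || kk >= nz) {
      if (clamp) kk = std::min(std::max(kk, 0), nz - 1);
      else { out += len; return; }
    }
    for (PatEntry &e : local)
      if (e.di == di && e.dj == dj && e.kk == kk) { e.len += len; return; }
    local.push_back(PatEntry{di, dj, kk, len});
  }

  void trace(int k, int oi, int oj, int ok, std::vector<PatEntry> &local,
             double &out) {
    if (oi == 0 && oj == 0 && ok == 0) {
      push(local, out, 0, 0, k, 1.0);
      return;
    }
    const double dir[3] = {(double)oi, (double)oj, (double)ok};
    int cur[3] = {0, 0, k};
    int stp[3];
    double tMax[3], tDel[3];
    for (int a = 0; a < 3; ++a) {
      if (dir[a] > 0) { stp[a] = 1; tMax[a] = 0.5 / dir[a]; tDel[a] = 1.0 / dir[a]; }
      else if (dir[a] < 0) { stp[a] = -1; tMax[a] = -0.5 / dir[a]; tDel[a] = -1.0 / dir[a]; }
      else { stp[a] = 0; tMax[a] = 2.0; tDel[a] = 2.0; }
    }
    double t = 0.0;
    for (;;) {
      int ax = 0;
      if (tMax[1] < tMax[ax]) ax = 1;
      if (tMax[2] < tMax[ax]) ax = 2;
      if (tMax[ax] >= 1.0) {
        push(local, out, cur[0], cur[1], cur[2], 1.0 - t);
        break;
      }
      push(local, out, cur[0], cur[1], cur[2], tMax[ax] - t);
      t = tMax[ax];
      cur[ax] += stp[ax];
      tMax[ax] += tDel[ax];
    }
  }

  // ray-mean density at in-plane position (i, j), slab k, offset index p
  inline double mean(const DensityGrid &g, int i, int j, size_t p) const {
    double acc = outLen[p] * g.boundary;
    const size_t e0 = start[p], e1 = start[p + 1];
    const int nx = g.nx, ny = g.ny;
    for (size_t e = e0; e < e1; ++e) {
      const PatEntry &pe = entries[e];
      int ii = i + pe.di, jj = j + pe.dj;
      if (g.clamp) {
        ii = std::min(std::max(ii, 0), nx - 1);
        jj = std::min(std::max(jj, 0), ny - 1);
      } else if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) {
        acc += pe.len * g.boundary;
        continue;
      }
      acc += pe.len *
             g.d[(size_t)ii + (size_t)nx * ((size_t)jj + (size_t)ny * pe.kk)];
    }
    return acc;
  }
};

} // namespace

// [[Rcpp::export]]
double cppRayMeanDensity(NumericVector density, IntegerVector dims,
                         IntegerVector center0, IntegerVector offset,
                         double boundaryDensity, bool clampBoundary) {
  DensityGrid g{REAL(density), dims[0], dims[1], dims[2],
                boundaryDensity, clampBoundary};
  return ray_mean(g, center0[0], center0[1], center0[2],
                  offset[0], offset[1], offset[2]);
}

// [[Rcpp::export]]
NumericVector cppUniformKernel(int size, NumericVector vox,
                               NumericVector Bgrid, NumericVector Mgrid,
                               double r0, double h, double rho,
                               double rhoRef) {
  Apsf f{REAL(Bgrid), REAL(Mgrid), (int)Bgrid.size(), r0, h};
  Subdiv s = Subdiv::make(REAL(vox));
  const int R = size / 2;
  const double rrel = rho / rhoRef;
  NumericVector out((R_xlen_t)size * size * size);
  double *o = REAL(out);
  size_t idx = 0;
  for (int ok = -R; ok <= R; ++ok)
    for (int oj = -R; oj <= R; ++oj)
      for (int oi = -R; oi <= R; ++oi, ++idx)
        o[idx] = cell_weight(f, s, oi, oj, ok, rrel) * rrel;
  return out;
}

// [[Rcpp::export]]
NumericVector cppTdsvKernel(int size, NumericVector vox,
                            NumericVector Bgrid, NumericVector Mgrid,
                            double r0, double h,
                            NumericVector density, IntegerVector dims,
                            IntegerVector center0, double rhoRef,
                            double boundaryDensity, bool clampBoundary) {
  DensityGrid g{REAL(density), dims[0], dims[1], dims[2],
                boundaryDensity, clampBoundary};
  Apsf f{REAL(Bgrid), REAL(Mgrid), (int)Bgrid.size(), r0, h};
  Subdiv s = Subdiv::make(REAL(vox));
  const int R = size / 2;
  const int ci = center0[0], cj = center0[1], ck = center0[2];
  NumericVector out((R_xlen_t)size * size * size);
  double *o = REAL(out);
  size_t idx = 0;
  for (int ok = -R; ok <= R; ++ok)
    for (int oj = -R; oj <= R; ++oj)
      for (int oi = -R; oi <= R; ++oi, ++idx) {
        double rho = ray_mean(g, ci, cj, ck, oi, oj, ok) / rhoRef;
        double local = g.at(ci + oi, cj + oj, ck + ok) / rhoRef;
        o[idx] = cell_weight(f, s, oi, oj, ok, rho) * local;
      }
  return out;
}

// Per-voxel kernel bank for the spatially variant blur.  For every voxel
// the full size^3 stencil is evaluated (its sum is the normalization, so
// activity leaving the volume is modelled as lost), but only weights
// whose target voxel lies inside the volume are stored, in a fixed
// enumeration (ok, oj, oi ascending over the clipped ranges) shared with
// cppTdsvApply.  Degenerate all-zero stencils fall back to a delta
// kernel.  Volumes with at most 4 axial slices use precomputed traversal
// patterns (quasi-2D fast path); others fall back to per-ray traversal.
// [[Rcpp::export]]
List cppKernelBank(NumericVector density, IntegerVector dims, int size,
                   NumericVector vox, NumericVector Bgrid,
                   NumericVector Mgrid, double r0, double h, double rhoRef,
                   double boundaryDensity, bool clampBoundary,
                   bool sliceIndependent) {
  DensityGrid g{REAL(density), dims[0], dims[1], dims[2],
                boundaryDensity, clampBoundary};
  Apsf f{REAL(Bgrid), REAL(Mgrid), (int)Bgrid.size(), r0, h};
  Subdiv s = Subdiv::make(REAL(vox));
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int R = size / 2;
  const size_t nOff = (size_t)size * size * size;

  Patterns pat;
  const bool usePatterns = nz <= 4;
  if (usePatterns) pat.build(size, nz, clampBoundary);

  std::vector<double> buf(nOff);
  std::vector<double> store;
  // per-offset memo: ray means repeat across voxels wherever the local
  // density pattern repeats (homogeneous regions), so the quadrature can
  // be reused exactly
  std::vector<double> lastRho(nOff, -1.0), lastW(nOff, 0.0);
  int nFallback = 0;

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double total = 0.0;
        size_t idx = 0;
        const size_t pbase = usePatterns ? (size_t)k * nOff : 0;
        for (int ok = -R; ok <= R; ++ok)
          for (int oj = -R; oj <= R; ++oj)
            for (int oi = -R; oi <= R; ++oi, ++idx) {
              double rho = (usePatterns
                                ? pat.mean(g, i, j, pbase + idx)
                                : ray_mean(g, i, j, k, oi, oj, ok)) /
                           rhoRef;
              double w;
              if (rho == lastRho[idx]) {
                w = lastW[idx];
              } else {
                w = cell_weight(f, s, oi, oj, ok, rho);
                lastRho[idx] = rho;
                lastW[idx] = w;
              }
              w *= g.at(i + oi, j + oj, k + ok) / rhoRef;
              buf[idx] = w;
              total += w;
            }
        const int klo = sliceIndependent ? 0 : std::max(-R, -k);
        const int khi = sliceIndependent ? 0 : std::min(R, nz - 1 - k);
        const int jlo = std::max(-R, -j), jhi = std::min(R, ny - 1 - j);
        const int ilo = std::max(-R, -i), ihi = std::min(R, nx - 1 - i);
        if (total <= 1e-3) { // negligible yield: keep the emission local
          ++nFallback;
          for (int ok = klo; ok <= khi; ++ok)
            for (int oj = jlo; oj <= jhi; ++oj)
              for (int oi = ilo; oi <= ihi; ++oi)
                store.push_back((oi == 0 && oj == 0 && ok == 0) ? 1.0 : 0.0);
        } else {
          for (int ok = klo; ok <= khi; ++ok)
            for (int oj = jlo; oj <= jhi; ++oj)
              for (int oi = ilo; oi <= ihi; ++oi) {
                size_t b = (size_t)(oi + R) +
                           (size_t)size * ((size_t)(oj + R) +
                                           (size_t)size * (ok + R));
                store.push_back(buf[b] / total);
              }
        }
      }

  NumericVector w(store.size());
  std::copy(store.begin(), store.end(), REAL(w));
  return List::create(_["w"] = w, _["size"] = size,
                      _["dims"] = dims, _["nFallback"] = nFallback);
}

// Spatially variant blur: spread (adjoint = false) distributes each
// source voxel's value with that voxel's own kernel; gather
// (adjoint = true) is the exact transpose.
// [[Rcpp::export]]
NumericVector cppTdsvApply(NumericVector img, IntegerVector dims,
                           NumericVector w, int size, bool adjoint,
                           bool sliceIndependent) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int R = size / 2;
  const double *x = REAL(img);
  const double *wp = REAL(w);
  NumericVector out((R_xlen_t)nx * ny * nz);
  double *o = REAL(out);
  size_t p = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const size_t v = (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
        const int klo = sliceIndependent ? 0 : std::max(-R, -k);
        const int khi = sliceIndependent ? 0 : std::min(R, nz - 1 - k);
        const int jlo = std::max(-R, -j), jhi = std::min(R, ny - 1 - j);
        const int ilo = std::max(-R, -i), ihi = std::min(R, nx - 1 - i);
        if (adjoint) {
          double acc = 0.0;
          for (int ok = klo; ok <= khi; ++ok)
            for (int oj = jlo; oj <= jhi; ++oj) {
              const size_t base =
                  (size_t)(i + ilo) +
                  (size_t)nx * ((size_t)(j + oj) + (size_t)ny * (k + ok));
              const double *xr = x + base;
              for (int oi = 0; oi <= ihi - ilo; ++oi)
                acc += wp[p++] * xr[oi];
            }
          o[v] = acc;
        } else {
          const double xv = x[v];
          for (int ok = klo; ok <= khi; ++ok)
            for (int oj = jlo; oj <= jhi; ++oj) {
              const size_t base =
                  (size_t)(i + ilo) +
                  (size_t)nx * ((size_t)(j + oj) + (size_t)ny * (k + ok));
              double *orow = o + base;
              for (int oi = 0; oi <= ihi - ilo; ++oi)
                orow[oi] += wp[p++] * xv;
            }
        }
      }
  return out;
}

// Dense 3D convolution with a (possibly cropped) centred kernel; mass
// spread beyond the volume is dropped, matching the bank semantics.
// kdim entries are odd.  adjoint gathers with the flipped kernel.
// [[Rcpp::export]]
NumericVector cppConvolve3d(NumericVector img, IntegerVector dims,
                            NumericVector ker, IntegerVector kdim,
                            bool adjoint) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int Rx = kdim[0] / 2, Ry = kdim[1] / 2, Rz = kdim[2] / 2;
  const double *x = REAL(img);
  const double *kw = REAL(ker);
  NumericVector out((R_xlen_t)nx * ny * nz);
  double *o = REAL(out);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const size_t v = (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
        const int klo = std::max(-Rz, -k), khi = std::min(Rz, nz - 1 - k);
        const int jlo = std::max(-Ry, -j), jhi = std::min(Ry, ny - 1 - j);
        const int ilo = std::max(-Rx, -i), ihi = std::min(Rx, nx - 1 - i);
        if (adjoint) {
          double acc = 0.0;
          for (int ok = klo; ok <= khi; ++ok)
            for (int oj = jlo; oj <= jhi; ++oj) {
              const size_t base =
                  (size_t)(i + ilo) +
                  (size_t)nx * ((size_t)(j + oj) + (size_t)ny * (k + ok));
              const size_t kb = (size_t)(ilo + Rx) +
                                (size_t)kdim[0] * ((size_t)(oj + Ry) +
                                                   (size_t)kdim[1] * (ok + Rz));
              const double *xr = x + base;
              const double *kr = kw + kb;
              for (int oi = 0; oi <= ihi - ilo; ++oi) acc += kr[oi] * xr[oi];
            }
          o[v] = acc;
        } else {
          const double xv = x[v];
          if (xv == 0.0) continue;
          for (int ok = klo; ok <= khi; ++ok)
            for (int oj = jlo; oj <= jhi; ++oj) {
              const size_t base =
                  (size_t)(i + ilo) +
                  (size_t)nx * ((size_t)(j + oj) + (size_t)ny * (k + ok));
              const size_t kb = (size_t)(ilo + Rx) +
                                (size_t)kdim[0] * ((size_t)(oj + Ry) +
                                                   (size_t)kdim[1] * (ok + Rz));
              double *orow = o + base;
              const double *kr = kw + kb;
              for (int oi = 0; oi <= ihi - ilo; ++oi)
                orow[oi] += kr[oi] * xv;
            }
        }
      }
  return out;
}
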