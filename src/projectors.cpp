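// Ray-driven system-model kernels: Siddon traversal, non-TOF and TOF-resolved
// forward/back projection, the quadratic 26-neighbour penalty, and a separable
// Gaussian filter used by the SSIM metric.
//
// Conventions: axis-aligned voxel grid, `origin` is the coordinate (mm) of the
// lower corner of voxel (0,0,0), isotropic voxel size `voxel` (mm), column-major
// linear indexing ix + nx*(iy + ny*iz). LOR endpoints are given per row of the
// P1/P2 matrices; the TOF coordinate is zero at the midpoint of the P1->P2
// segment and positive toward P2 (time difference t = 2u/c).

#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double C_MM_PER_PS = 299.792 / 1000.0;  // speed of light
static const double GAUSS3_MASS = 0.9973002039367398; // Phi(3) - Phi(-3)

static inline double norm_cdf(double z) { return 0.5 * std::erfc(-z * M_SQRT1_2); }

// Walk the voxels intersected by segment p1->p2 clipped to the grid box.
// visit(ix, iy, iz, seg_len_mm, u_mid_mm) with u measured from the segment
// midpoint (signed, toward p2).
template <class F>
static inline void siddon_walk(const double* p1, const double* p2,
                               const double* origin, double vs,
                               const int* dim, F&& visit) {
  double d[3];
  double L2 = 0.0;
  for (int k = 0; k < 3; ++k) { d[k] = p2[k] - p1[k]; L2 += d[k] * d[k]; }
  double L = std::sqrt(L2);
  if (L <= 0.0) return;

  double tmin = 0.0, tmax = 1.0;
  for (int k = 0; k < 3; ++k) {
    double b0 = origin[k], b1 = origin[k] + vs * dim[k];
    if (std::fabs(d[k]) < 1e-12) {
      if (p1[k] < b0 || p1[k] > b1) return;
    } else {
      double t0 = (b0 - p1[k]) / d[k], t1 = (b1 - p1[k]) / d[k];
      if (t0 > t1) std::swap(t0, t1);
      if (t0 > tmin) tmin = t0;
      if (t1 < tmax) tmax = t1;
    }
  }
  if (tmax <= tmin) return;

  int iv[3];
  for (int k = 0; k < 3; ++k) {
    double pos = p1[k] + d[k] * (tmin + 1e-10);
    int i = (int)std::floor((pos - origin[k]) / vs);
    if (i < 0) i = 0;
    if (i >= dim[k]) i = dim[k] - 1;
    iv[k] = i;
  }
  double tnext[3];
  int step[3];
  for (int k = 0; k < 3; ++k) {
    if (d[k] > 1e-12) {
      step[k] = 1;
      tnext[k] = (origin[k] + (iv[k] + 1) * vs - p1[k]) / d[k];
    } else if (d[k] < -1e-12) {
      step[k] = -1;
      tnext[k] = (origin[k] + iv[k] * vs - p1[k]) / d[k];
    } else {
      step[k] = 0;
      tnext[k] = std::numeric_limits<double>::infinity();
    }
  }

  double t = tmin;
  while (t < tmax - 1e-12) {
    int kmin = 0;
    double tn = tnext[0];
    if (tnext[1] < tn) { tn = tnext[1]; kmin = 1; }
    if (tnext[2] < tn) { tn = tnext[2]; kmin = 2; }
    double tcell = tn < tmax ? tn : tmax;
    double seg = (tcell - t) * L;
    if (seg > 0.0) {
      double umid = (0.5 * (t + tcell) - 0.5) * L;
      visit(iv[0], iv[1], iv[2], seg, umid);
    }
    if (tn >= tmax) break;
    t = tn;
    tnext[kmin] += vs / std::fabs(d[kmin]);
    iv[kmin] += step[kmin];
    if (iv[kmin] < 0 || iv[kmin] >= dim[kmin]) break;
  }
}

// [[Rcpp::export]]
List cpp_siddon(NumericVector p1, NumericVector p2, NumericVector origin,
                double voxel, IntegerVector dim) {
  std::vector<int> idx;
  std::vector<double> len, uu;
  int dm[3] = {dim[0], dim[1], dim[2]};
  siddon_walk(&p1[0], &p2[0], &origin[0], voxel, dm,
              [&](int ix, int iy, int iz, double s, double u) {
                idx.push_back(1 + ix + dm[0] * (iy + dm[1] * iz));
                len.push_back(s);
                uu.push_back(u);
              });
  return List::create(_["index"] = wrap(idx), _["length"] = wrap(len),
                      _["u"] = wrap(uu));
}

// [[Rcpp::export]]
NumericVector cpp_forward(NumericMatrix P1, NumericMatrix P2, NumericVector img,
                          NumericVector origin, double voxel, IntegerVector dim) {
  int n = P1.nrow();
  NumericVector out(n);
  int dm[3] = {dim[0], dim[1], dim[2]};
  const double* im = &img[0];
  for (int i = 0; i < n; ++i) {
    double p1[3] = {P1(i, 0), P1(i, 1), P1(i, 2)};
    double p2[3] = {P2(i, 0), P2(i, 1), P2(i, 2)};
    double acc = 0.0;
    siddon_walk(p1, p2, &origin[0], voxel, dm,
                [&](int ix, int iy, int iz, double s, double) {
                  acc += s * im[ix + dm[0] * (iy + dm[1] * iz)];
                });
    out[i] = acc;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_back(NumericMatrix P1, NumericMatrix P2, NumericVector vals,
                       NumericVector origin, double voxel, IntegerVector dim) {
  int n = P1.nrow();
  int dm[3] = {dim[0], dim[1], dim[2]};
  NumericVector out((R_xlen_t)dm[0] * dm[1] * dm[2]);
  double* im = &out[0];
  for (int i = 0; i < n; ++i) {
    double v = vals[i];
    if (v == 0.0) continue;
    double p1[3] = {P1(i, 0), P1(i, 1), P1(i, 2)};
    double p2[3] = {P2(i, 0), P2(i, 1), P2(i, 2)};
    siddon_walk(p1, p2, &origin[0], voxel, dm,
                [&](int ix, int iy, int iz, double s, double) {
                  im[ix + dm[0] * (iy + dm[1] * iz)] += s * v;
                });
  }
  return out;
}

// Fused back projection of two per-LOR value vectors in one Siddon pass
// (numerator/denominator pairs of SQS updates).
// [[Rcpp::export]]
List cpp_back2(NumericMatrix P1, NumericMatrix P2, NumericVector v1,
               NumericVector v2, NumericVector origin, double voxel,
               IntegerVector dim) {
  int n = P1.nrow();
  int dm[3] = {dim[0], dim[1], dim[2]};
  NumericVector o1((R_xlen_t)dm[0] * dm[1] * dm[2]);
  NumericVector o2((R_xlen_t)dm[0] * dm[1] * dm[2]);
  double *a1 = &o1[0], *a2 = &o2[0];
  for (int i = 0; i < n; ++i) {
    double w1 = v1[i], w2 = v2[i];
    if (w1 == 0.0 && w2 == 0.0) continue;
    double p1[3] = {P1(i, 0), P1(i, 1), P1(i, 2)};
    double p2[3] = {P2(i, 0), P2(i, 1), P2(i, 2)};
    siddon_walk(p1, p2, &origin[0], voxel, dm,
                [&](int ix, int iy, int iz, double s, double) {
                  R_xlen_t j = ix + dm[0] * (iy + (R_xlen_t)dm[1] * iz);
                  a1[j] += s * w1;
                  a2[j] += s * w2;
                });
  }
  return List::create(_["b1"] = o1, _["b2"] = o2);
}

// TOF kernel weights: the bin-integrated Gaussian (FWHM = CTR, truncated at
// +/- 3 sigma, renormalized to unit mass) depends on the event time only
// through its fractional offset within the bin lattice, so the weights are
// tabulated once per (bin width, sigma) pair on a fine fractional grid.
// Rows sum to exactly 1, which makes TOF marginalization lossless away from
// the array edges; forward and back projection share the table, so the pair
// stays exactly adjoint.
struct TofTable {
  double bw = -1, sigma = -1;
  int K = 0;                  // bins on each side of the nearest bin
  static const int NF = 256;  // fractional-offset resolution
  std::vector<double> w;      // NF x (2K+1)
  void build(double bw_, double sigma_) {
    bw = bw_;
    sigma = sigma_;
    K = (int)std::ceil((3.0 * sigma + 0.5 * bw) / bw);
    w.assign((size_t)NF * (2 * K + 1), 0.0);
    for (int f = 0; f < NF; ++f) {
      double frac = (f + 0.5) / NF;  // event at n0 + frac (bin units)
      double sum = 0.0;
      for (int d = -K; d <= K; ++d) {
        double a = ((d - 0.5 - frac) * bw) / sigma;
        double b = ((d + 0.5 - frac) * bw) / sigma;
        if (a < -3.0) a = -3.0;
        if (b > 3.0) b = 3.0;
        double v = b > a ? (norm_cdf(b) - norm_cdf(a)) / GAUSS3_MASS : 0.0;
        w[(size_t)f * (2 * K + 1) + (d + K)] = v;
        sum += v;
      }
      for (int d = 0; d <= 2 * K; ++d) w[(size_t)f * (2 * K + 1) + d] /= sum;
    }
  }
  // row for an event time te (ps); n0 is the nearest-bin index offset by
  // the array half-length
  inline const double* row(double te, int ntof, int& n0) const {
    double u = te / bw + 0.5 * (ntof - 1);
    double fl = std::floor(u);
    n0 = (int)fl;
    int f = (int)((u - fl) * NF);
    if (f < 0) f = 0;
    if (f >= NF) f = NF - 1;
    return &w[(size_t)f * (2 * K + 1)];
  }
};

static TofTable g_tof_table;

static inline const TofTable& tof_table(double bw, double sigma) {
  if (g_tof_table.bw != bw || g_tof_table.sigma != sigma)
    g_tof_table.build(bw, sigma);
  return g_tof_table;
}

// [[Rcpp::export]]
NumericMatrix cpp_tof_forward(NumericMatrix P1, NumericMatrix P2,
                              NumericVector img, NumericVector origin,
                              double voxel, IntegerVector dim, double bw_ps,
                              int ntof, double sigma_ps) {
  int n = P1.nrow();
  NumericMatrix out(n, ntof);
  int dm[3] = {dim[0], dim[1], dim[2]};
  const double* im = &img[0];
  const TofTable& tt = tof_table(bw_ps, sigma_ps);
  for (int i = 0; i < n; ++i) {
    double p1[3] = {P1(i, 0), P1(i, 1), P1(i, 2)};
    double p2[3] = {P2(i, 0), P2(i, 1), P2(i, 2)};
    siddon_walk(p1, p2, &origin[0], voxel, dm,
                [&](int ix, int iy, int iz, double s, double u) {
                  double v = s * im[ix + dm[0] * (iy + dm[1] * iz)];
                  if (v == 0.0) return;
                  int n0;
                  const double* w = tt.row(2.0 * u / C_MM_PER_PS, ntof, n0);
                  int d0 = std::max(-tt.K, -n0);
                  int d1 = std::min(tt.K, ntof - 1 - n0);
                  for (int d = d0; d <= d1; ++d)
                    out(i, n0 + d) += v * w[d + tt.K];
                });
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_tof_back(NumericMatrix P1, NumericMatrix P2,
                           NumericMatrix sino, NumericVector origin,
                           double voxel, IntegerVector dim, double bw_ps,
                           int ntof, double sigma_ps) {
  int n = P1.nrow();
  int dm[3] = {dim[0], dim[1], dim[2]};
  NumericVector out((R_xlen_t)dm[0] * dm[1] * dm[2]);
  double* im = &out[0];
  const TofTable& tt = tof_table(bw_ps, sigma_ps);
  for (int i = 0; i < n; ++i) {
    double p1[3] = {P1(i, 0), P1(i, 1), P1(i, 2)};
    double p2[3] = {P2(i, 0), P2(i, 1), P2(i, 2)};
    siddon_walk(p1, p2, &origin[0], voxel, dm,
                [&](int ix, int iy, int iz, double s, double u) {
                  int n0;
                  const double* w = tt.row(2.0 * u / C_MM_PER_PS, ntof, n0);
                  int d0 = std::max(-tt.K, -n0);
                  int d1 = std::min(tt.K, ntof - 1 - n0);
                  double acc = 0.0;
                  for (int d = d0; d <= d1; ++d)
                    acc += sino(i, n0 + d) * w[d + tt.K];
                  im[ix + dm[0] * (iy + dm[1] * iz)] += s * acc;
                });
  }
  return out;
}

// Fused transmission SQS subset pass: one Siddon walk per LOR computes the
// 307 keV line integral, the Poisson transmission gradient H' and its
// optimal curvature, and deposits both the gradient and denominator terms.
// Returns the accumulated numerator sum_i l_ij eta H'_i and denominator
// sum_i l_ij eta^2 c_i L_i images.
// [[Rcpp::export]]
List cpp_mltr_subset(NumericMatrix P1, NumericMatrix P2, NumericVector mu,
                     NumericVector origin, double voxel, IntegerVector dim,
                     NumericVector B, NumericVector y, NumericVector r,
                     double eta, double epsilon) {
  int n = P1.nrow();
  int dm[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t nvox = (R_xlen_t)dm[0] * dm[1] * dm[2];
  NumericVector num(nvox), den(nvox);
  double *pn = &num[0], *pd = &den[0];
  const double* pm = &mu[0];
  int maxlen = dm[0] + dm[1] + dm[2] + 8;
  std::vector<int> bidx(maxlen);
  std::vector<double> blen(maxlen);
  for (int i = 0; i < n; ++i) {
    double p1[3] = {P1(i, 0), P1(i, 1), P1(i, 2)};
    double p2[3] = {P2(i, 0), P2(i, 1), P2(i, 2)};
    int m = 0;
    double z = 0.0, L = 0.0;
    siddon_walk(p1, p2, &origin[0], voxel, dm,
                [&](int ix, int iy, int iz, double s, double) {
                  if (m >= maxlen) Rcpp::stop("path buffer overflow");
                  int j = ix + dm[0] * (iy + dm[1] * iz);
                  if (j < 0 || j >= (int)nvox) Rcpp::stop("voxel index out of range");
                  bidx[m] = j;
                  blen[m] = s;
                  ++m;
                  z += s * pm[j];
                  L += s;
                });
    if (m == 0) continue;
    double Z = eta * z;
    double be = B[i] * std::exp(-Z);
    double yb = be + r[i];
    double Hp = y[i] * (yb > 0 ? be / yb : 1.0) - be;
    // optimal curvature of h(Z) = (B e^-Z + r) - y log(B e^-Z + r)
    double cv;
    if (Z > 1e-12) {
      double h0 = (B[i] + r[i]) -
        (y[i] > 0 ? y[i] * std::log(std::max(B[i] + r[i], 1e-300)) : 0.0);
      double hz = yb - (y[i] > 0 ? y[i] * std::log(std::max(yb, 1e-300)) : 0.0);
      cv = 2.0 * (h0 - hz + Z * Hp) / (Z * Z);
    } else {
      cv = (B[i] + r[i]) > 0 ?
        B[i] * (1.0 - y[i] * r[i] / ((B[i] + r[i]) * (B[i] + r[i]))) : 0.0;
    }
    if (cv < epsilon) cv = epsilon;
    double gn = eta * Hp;
    double gd = eta * eta * cv * L;
    for (int k = 0; k < m; ++k) {
      pn[bidx[k]] += blen[k] * gn;
      pd[bidx[k]] += blen[k] * gd;
    }
  }
  return List::create(_["num"] = num, _["den"] = den);
}

// Fused TOF-OSEM subset pass: one walk per LOR buffers the path, builds the
// TOF-resolved forward projection, forms the Poisson ratio against the
// measured counts and deposits the weighted ratio back projection. Returns
// the update numerator image (to be divided by the subset sensitivity).
// [[Rcpp::export]]
NumericVector cpp_osem_subset(NumericMatrix P1, NumericMatrix P2,
                              NumericVector lam, NumericVector origin,
                              double voxel, IntegerVector dim,
                              NumericMatrix ycounts, NumericVector w,
                              double s_it, double bw_ps, double sigma_ps) {
  int n = P1.nrow();
  int ntof = ycounts.ncol();
  int dm[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t nvox = (R_xlen_t)dm[0] * dm[1] * dm[2];
  NumericVector out(nvox);
  double* po = &out[0];
  const double* pl = &lam[0];
  const TofTable& tt = tof_table(bw_ps, sigma_ps);
  int maxlen = dm[0] + dm[1] + dm[2] + 8;
  std::vector<int> bidx(maxlen);
  std::vector<double> blen(maxlen);
  std::vector<int> bn0(maxlen);
  std::vector<const double*> brow(maxlen);
  std::vector<double> fp(ntof), ratio(ntof);
  for (int i = 0; i < n; ++i) {
    if (w[i] == 0.0) continue;
    double p1[3] = {P1(i, 0), P1(i, 1), P1(i, 2)};
    double p2[3] = {P2(i, 0), P2(i, 1), P2(i, 2)};
    int m = 0;
    siddon_walk(p1, p2, &origin[0], voxel, dm,
                [&](int ix, int iy, int iz, double s, double u) {
                  if (m >= maxlen) Rcpp::stop("path buffer overflow");
                  int j = ix + dm[0] * (iy + dm[1] * iz);
                  if (j < 0 || j >= (int)nvox) Rcpp::stop("voxel index out of range");
                  bidx[m] = j;
                  blen[m] = s;
                  brow[m] = tt.row(2.0 * u / C_MM_PER_PS, ntof, bn0[m]);
                  ++m;
                });
    if (m == 0) continue;
    std::fill(fp.begin(), fp.end(), 0.0);
    for (int k = 0; k < m; ++k) {
      double v = blen[k] * pl[bidx[k]];
      if (v == 0.0) continue;
      int n0 = bn0[k];
      const double* wr = brow[k];
      int d0 = std::max(-tt.K, -n0), d1 = std::min(tt.K, ntof - 1 - n0);
      for (int d = d0; d <= d1; ++d) fp[n0 + d] += v * wr[d + tt.K];
    }
    for (int t = 0; t < ntof; ++t) {
      double yb = fp[t] * w[i] + s_it;
      ratio[t] = yb > 0 ? ycounts(i, t) / yb : 0.0;
    }
    for (int k = 0; k < m; ++k) {
      int n0 = bn0[k];
      const double* wr = brow[k];
      int d0 = std::max(-tt.K, -n0), d1 = std::min(tt.K, ntof - 1 - n0);
      double acc = 0.0;
      for (int d = d0; d <= d1; ++d) acc += ratio[n0 + d] * wr[d + tt.K];
      po[bidx[k]] += blen[k] * acc * w[i];
    }
  }
  return out;
}

// Quadratic 26-neighbour roughness penalty with inverse-distance weights
// (face 1, edge 1/sqrt2, corner 1/sqrt3, in voxel units). Returns the gradient
// sum_k w_jk (mu_j - mu_k) and the per-voxel weight sum sum_k w_jk.
// [[Rcpp::export]]
List cpp_quad_penalty(NumericVector img, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector grad((R_xlen_t)nx * ny * nz), wsum((R_xlen_t)nx * ny * nz);
  const double* im = &img[0];
  double* g = &grad[0];
  double* ws = &wsum[0];
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        R_xlen_t j = ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
        double gj = 0.0, wj = 0.0, mj = im[j];
        for (int dz = -1; dz <= 1; ++dz) {
          int kz = iz + dz;
          if (kz < 0 || kz >= nz) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            int ky = iy + dy;
            if (ky < 0 || ky >= ny) continue;
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int kx = ix + dx;
              if (kx < 0 || kx >= nx) continue;
              double w = 1.0 / std::sqrt((double)(dx * dx + dy * dy + dz * dz));
              R_xlen_t k = kx + (R_xlen_t)nx * (ky + (R_xlen_t)ny * kz);
              gj += w * (mj - im[k]);
              wj += w;
            }
          }
        }
        g[j] = gj;
        ws[j] = wj;
      }
  return List::create(_["grad"] = grad, _["wsum"] = wsum);
}

// Separable Gaussian filter with nearest-neighbour (replicate) padding; kernel
// radius floor(truncate*sigma + 0.5), matching the usual scientific-python
// convention so SSIM can be pinned against an external oracle.
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector img, IntegerVector dim, double sigma,
                          double truncate) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int r = (int)(truncate * sigma + 0.5);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (i * i) / (sigma * sigma));
    s += k[i + r];
  }
  for (auto& v : k) v /= s;

  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  std::vector<double> buf(n);
  const double* src = &img[0];
  double* dst = &out[0];

  auto pass = [&](const double* in, double* ou, int axis) {
    int nd[3] = {nx, ny, nz};
    R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
    int na = nd[axis];
    R_xlen_t sa = stride[axis];
    int o1 = (axis + 1) % 3, o2 = (axis + 2) % 3;
    for (int i2 = 0; i2 < nd[o2]; ++i2)
      for (int i1 = 0; i1 < nd[o1]; ++i1) {
        R_xlen_t base = i1 * stride[o1] + i2 * stride[o2];
        for (int ia = 0; ia < na; ++ia) {
          double acc = 0.0;
          for (int t = -r; t <= r; ++t) {
            int ii = ia + t;
            if (ii < 0) ii = 0;
            if (ii >= na) ii = na - 1;
            acc += k[t + r] * in[base + (R_xlen_t)ii * sa];
          }
          ou[base + (R_xlen_t)ia * sa] = acc;
        }
      }
  };
  pass(src, dst, 0);
  pass(dst, buf.data(), 1);
  pass(buf.data(), dst, 2);
  return out;
}
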