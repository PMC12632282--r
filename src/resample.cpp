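#include <Rcpp.h>
using namespace Rcpp;

// Tricubic (Catmull-Rom) resampling of a cubic volume under a linear map of
// voxel-center coordinates about the volume center, with zero fill outside
// the grid. Sampling at integer coordinates reproduces stored values exactly
// (the cubic kernel interpolates), so the identity map is bit-exact.

static inline void cr_weights(double t, double w[4]) {
  // Catmull-Rom cubic, support points at offsets -1, 0, 1, 2
  double t2 = t * t, t3 = t2 * t;
  w[0] = 0.5 * (-t + 2.0 * t2 - t3);
  w[1] = 0.5 * (2.0 - 5.0 * t2 + 3.0 * t3);
  w[2] = 0.5 * (t + 4.0 * t2 - 3.0 * t3);
  w[3] = 0.5 * (-t2 + t3);
}

static inline double sample_tricubic(const double* v, int n,
                                     double x, double y, double z) {
  if (x < -1.0 || x > n || y < -1.0 || y > n || z < -1.0 || z > n)
    return 0.0;
  int ix = (int)std::floor(x), iy = (int)std::floor(y), iz = (int)std::floor(z);
  double wx[4], wy[4], wz[4];
  cr_weights(x - ix, wx);
  cr_weights(y - iy, wy);
  cr_weights(z - iz, wz);
  double acc = 0.0;
  for (int c = 0; c < 4; ++c) {
    int kz = iz - 1 + c;
    if (kz < 0 || kz >= n || wz[c] == 0.0) continue;
    double accy = 0.0;
    for (int b = 0; b < 4; ++b) {
      int ky = iy - 1 + b;
      if (ky < 0 || ky >= n || wy[b] == 0.0) continue;
      double accx = 0.0;
      for (int a = 0; a < 4; ++a) {
        int kx = ix - 1 + a;
        if (kx < 0 || kx >= n || wx[a] == 0.0) continue;
        accx += wx[a] * v[kx + n * (ky + n * kz)];
      }
      accy += wy[b] * accx;
    }
    acc += wz[c] * accy;
  }
  return acc;
}

// Resample vol at S (x - c) + c for one 3x3 matrix S (column-major).
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vol, NumericVector S) {
  IntegerVector dm = vol.attr("dim");
  if (dm.size() != 3 || dm[0] != dm[1] || dm[1] != dm[2])
    stop("volume must be a cubic 3D array");
  int n = dm[0];
  double c = 0.5 * (n - 1);
  const double* v = vol.begin();
  const double* s = S.begin();
  NumericVector out(vol.size());
  out.attr("dim") = dm;
  double* o = out.begin();
  for (int k = 0; k < n; ++k) {
    double zk = k - c;
    for (int j = 0; j < n; ++j) {
      double yj = j - c;
      for (int i = 0; i < n; ++i) {
        double xi = i - c;
        double px = s[0] * xi + s[3] * yj + s[6] * zk + c;
        double py = s[1] * xi + s[4] * yj + s[7] * zk + c;
        double pz = s[2] * xi + s[5] * yj + s[8] * zk + c;
        o[i + n * (j + n * k)] = sample_tricubic(v, n, px, py, pz);
      }
    }
  }
  return out;
}

// Resample vol under L maps; returns an (n^3) x L matrix, one map per column.
// Smat is 9 x L, each column the column-major 3x3 sampling matrix.
// [[Rcpp::export]]
NumericMatrix cpp_resample_batch(NumericVector vol, NumericMatrix Smat) {
  IntegerVector dm = vol.attr("dim");
  if (dm.size() != 3 || dm[0] != dm[1] || dm[1] != dm[2])
    stop("volume must be a cubic 3D array");
  if (Smat.nrow() != 9) stop("Smat must be 9 x L");
  int n = dm[0], L = Smat.ncol();
  double c = 0.5 * (n - 1);
  const double* v = vol.begin();
  NumericMatrix out((R_xlen_t)n * n * n, L);
  for (int l = 0; l < L; ++l) {
    const double* s = &Smat(0, l);
    double* o = &out(0, l);
    for (int k = 0; k < n; ++k) {
      double zk = k - c;
      for (int j = 0; j < n; ++j) {
        double yj = j - c;
        for (int i = 0; i < n; ++i) {
          double xi = i - c;
          double px = s[0] * xi + s[3] * yj + s[6] * zk + c;
          double py = s[1] * xi + s[4] * yj + s[7] * zk + c;
          double pz = s[2] * xi + s[5] * yj + s[8] * zk + c;
          o[i + n * (j + n * k)] = sample_tricubic(v, n, px, py, pz);
        }
      }
    }
  }
  return out;
}

// Weighted sum of resamplings: sum_l w[l] * resample(vol, S_l).
// Used by the EM M-step to back-rotate one observation onto all grid nodes
// while holding only one accumulator volume in memory.
// [[Rcpp::export]]
NumericVector cpp_resample_accum(NumericVector vol, NumericMatrix Smat,
                                 NumericVector w) {
  IntegerVector dm = vol.attr("dim");
  if (dm.size() != 3 || dm[0] != dm[1] || dm[1] != dm[2])
    stop("volume must be a cubic 3D array");
  if (Smat.nrow() != 9) stop("Smat must be 9 x L");
  if (w.size() != Smat.ncol()) stop("length(w) must equal ncol(Smat)");
  int n = dm[0], L = Smat.ncol();
  double c = 0.5 * (n - 1);
  const double* v = vol.begin();
  NumericVector out(vol.size());
  out.attr("dim") = dm;
  double* o = out.begin();
  for (int l = 0; l < L; ++l) {
    double wl = w[l];
    if (wl == 0.0) continue;
    const double* s = &Smat(0, l);
    for (int k = 0; k < n; ++k) {
      double zk = k - c;
      for (int j = 0; j < n; ++j) {
        double yj = j - c;
        for (int i = 0; i < n; ++i) {
          double xi = i - c;
          double px = s[0] * xi + s[3] * yj + s[6] * zk + c;
          double py = s[1] * xi + s[4] * yj + s[7] * zk + c;
          double pz = s[2] * xi + s[5] * yj + s[8] * zk + c;
          o[i + n * (j + n * k)] += wl * sample_tricubic(v, n, px, py, pz);
        }
      }
    }
  }
  return out;
}
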