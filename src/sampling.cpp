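// Hot loops for volume sampling and the masked registration metric.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double sample_one(const double* v, const int* d,
                                double x, double y, double z,
                                bool linear, double outside, bool clamp) {
  if (clamp) {
    x = std::min(std::max(x, 0.0), double(d[0] - 1));
    y = std::min(std::max(y, 0.0), double(d[1] - 1));
    z = std::min(std::max(z, 0.0), double(d[2] - 1));
  }
  if (!linear) {
    long i = lround(x), j = lround(y), k = lround(z);
    if (i < 0 || j < 0 || k < 0 || i >= d[0] || j >= d[1] || k >= d[2])
      return outside;
    return v[i + (long)d[0] * (j + (long)d[1] * k)];
  }
  if (x < 0 || y < 0 || z < 0 || x > d[0] - 1 || y > d[1] - 1 || z > d[2] - 1)
    return outside;
  long i0 = (long)std::floor(x), j0 = (long)std::floor(y), k0 = (long)std::floor(z);
  if (i0 == d[0] - 1) i0--;
  if (j0 == d[1] - 1) j0--;
  if (k0 == d[2] - 1) k0--;
  if (d[0] == 1) i0 = 0;
  if (d[1] == 1) j0 = 0;
  if (d[2] == 1) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  long i1 = std::min(i0 + 1, (long)d[0] - 1);
  long j1 = std::min(j0 + 1, (long)d[1] - 1);
  long k1 = std::min(k0 + 1, (long)d[2] - 1);
  auto at = [&](long i, long j, long k) {
    return v[i + (long)d[0] * (j + (long)d[1] * k)];
  };
  double c00 = at(i0, j0, k0) * (1 - fx) + at(i1, j0, k0) * fx;
  double c10 = at(i0, j1, k0) * (1 - fx) + at(i1, j1, k0) * fx;
  double c01 = at(i0, j0, k1) * (1 - fx) + at(i1, j0, k1) * fx;
  double c11 = at(i0, j1, k1) * (1 - fx) + at(i1, j1, k1) * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Sample a volume at continuous 0-based voxel indices.
// outside = NA requests edge clamping instead of an outside value.
// [[Rcpp::export]]
NumericVector cpp_sample_volume(NumericVector values, NumericMatrix pts,
                                bool linear, double outside) {
  IntegerVector dims = values.attr("dim");
  int d[3] = {dims[0], dims[1], dims[2]};
  bool clamp = NumericVector::is_na(outside);
  R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double* v = values.begin();
  for (R_xlen_t r = 0; r < n; r++)
    out[r] = sample_one(v, d, pts(r, 0), pts(r, 1), pts(r, 2),
                        linear, outside, clamp);
  return out;
}

// Pearson correlation between fixed intensities at mask points and the
// moving image sampled (trilinear) at T * point. pts are world mm (n x 3),
// T is the 4x4 fixed-world -> moving-world map. Moving geometry is given by
// spacing / origin / axes (orthonormal columns). Points mapping outside the
// moving grid take `outside` as the moving intensity.
// [[Rcpp::export]]
double cpp_ncc_metric(NumericVector fixed_vals, NumericMatrix pts,
                      NumericVector moving, NumericVector m_spacing,
                      NumericVector m_origin, NumericMatrix m_axes,
                      NumericMatrix T, double outside) {
  IntegerVector dims = moving.attr("dim");
  int d[3] = {dims[0], dims[1], dims[2]};
  const double* v = moving.begin();
  R_xlen_t n = pts.nrow();
  double a[3][3], t[3], sp[3], org[3];
  for (int i = 0; i < 3; i++) {
    for (int j = 0; j < 3; j++) a[i][j] = T(i, j);
    t[i] = T(i, 3);
    sp[i] = m_spacing[i];
    org[i] = m_origin[i];
  }
  double ax[3][3];  // moving axes, column-major access
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) ax[i][j] = m_axes(i, j);
  double sf = 0, sm = 0, sff = 0, smm = 0, sfm = 0;
  for (R_xlen_t r = 0; r < n; r++) {
    double p0 = pts(r, 0), p1 = pts(r, 1), p2 = pts(r, 2);
    double w0 = a[0][0] * p0 + a[0][1] * p1 + a[0][2] * p2 + t[0] - org[0];
    double w1 = a[1][0] * p0 + a[1][1] * p1 + a[1][2] * p2 + t[1] - org[1];
    double w2 = a[2][0] * p0 + a[2][1] * p1 + a[2][2] * p2 + t[2] - org[2];
    // continuous index: t(axes) %*% w / spacing
    double x = (ax[0][0] * w0 + ax[1][0] * w1 + ax[2][0] * w2) / sp[0];
    double y = (ax[0][1] * w0 + ax[1][1] * w1 + ax[2][1] * w2) / sp[1];
    double z = (ax[0][2] * w0 + ax[1][2] * w1 + ax[2][2] * w2) / sp[2];
    double m = sample_one(v, d, x, y, z, true, outside, false);
    double f = fixed_vals[r];
    sf += f; sm += m; sff += f * f; smm += m * m; sfm += f * m;
  }
  double nf = (double)n;
  double cov = sfm - sf * sm / nf;
  double vf = sff - sf * sf / nf;
  double vm = smm - sm * sm / nf;
  if (vf <= 0 || vm <= 0) return NA_REAL;
  return cov / std::sqrt(vf * vm);
}

// Iterative-Hough voting: for each direction (rows of dirs, unit vectors)
// project centered points onto the plane basis (u, v) orthogonal to the
// direction and vote into cells of width dx. Returns the best cell:
// (dir index 1-based, iu, iv, votes).
// [[Rcpp::export]]
NumericVector cpp_hough_vote(NumericMatrix pts, NumericMatrix dirs,
                             NumericMatrix ubasis, NumericMatrix vbasis,
                             double dx, int nrad) {
  int np = pts.nrow(), nd = dirs.nrow();
  int w = 2 * nrad + 1;
  std::vector<int> votes((size_t)w * w);
  int best_votes = -1, best_dir = -1, best_iu = 0, best_iv = 0;
  for (int di = 0; di < nd; di++) {
    std::fill(votes.begin(), votes.end(), 0);
    double ux = ubasis(di, 0), uy = ubasis(di, 1), uz = ubasis(di, 2);
    double vx = vbasis(di, 0), vy = vbasis(di, 1), vz = vbasis(di, 2);
    for (int p = 0; p < np; p++) {
      double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
      int iu = (int)lround((ux * x + uy * y + uz * z) / dx);
      int iv = (int)lround((vx * x + vy * y + vz * z) / dx);
      if (iu < -nrad || iu > nrad || iv < -nrad || iv > nrad) continue;
      votes[(size_t)(iu + nrad) * w + (iv + nrad)]++;
    }
    for (int iu = -nrad; iu <= nrad; iu++)
      for (int iv = -nrad; iv <= nrad; iv++) {
        int c = votes[(size_t)(iu + nrad) * w + (iv + nrad)];
        if (c > best_votes) {
          best_votes = c; best_dir = di; best_iu = iu; best_iv = iv;
        }
      }
  }
  return NumericVector::create(best_dir + 1, best_iu, best_iv, best_votes);
}
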