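// 3x3x3 convolution / pooling kernels for the volumetric U-Net.
// Feature maps are stored channels-first as C x N matrices, N = prod(dims),
// voxels in column-major (R array) order. Convolutions are zero-padded
// ("same"), implemented as 27 shifted GEMMs.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// gather x shifted by (di,dj,dk) into buf (zero outside)
static void gather(const arma::mat& x, arma::mat& buf, const int* d,
                   int di, int dj, int dk) {
  buf.zeros();
  int d0 = d[0], d1 = d[1], d2 = d[2];
  for (int k = 0; k < d2; k++) {
    int ks = k + dk;
    if (ks < 0 || ks >= d2) continue;
    for (int j = 0; j < d1; j++) {
      int js = j + dj;
      if (js < 0 || js >= d1) continue;
      int ilo = std::max(0, -di), ihi = std::min(d0, d0 - di);
      if (ilo >= ihi) continue;
      size_t vdst = (size_t)ilo + (size_t)d0 * (j + (size_t)d1 * k);
      size_t vsrc = (size_t)(ilo + di) + (size_t)d0 * (js + (size_t)d1 * ks);
      buf.cols(vdst, vdst + (ihi - ilo) - 1) = x.cols(vsrc, vsrc + (ihi - ilo) - 1);
    }
  }
}

// scatter-add buf (shifted by (di,dj,dk)) back into acc
static void scatter_add(arma::mat& acc, const arma::mat& buf, const int* d,
                        int di, int dj, int dk) {
  int d0 = d[0], d1 = d[1], d2 = d[2];
  for (int k = 0; k < d2; k++) {
    int ks = k + dk;
    if (ks < 0 || ks >= d2) continue;
    for (int j = 0; j < d1; j++) {
      int js = j + dj;
      if (js < 0 || js >= d1) continue;
      int ilo = std::max(0, -di), ihi = std::min(d0, d0 - di);
      if (ilo >= ihi) continue;
      size_t vdst = (size_t)ilo + (size_t)d0 * (j + (size_t)d1 * k);
      size_t vsrc = (size_t)(ilo + di) + (size_t)d0 * (js + (size_t)d1 * ks);
      acc.cols(vsrc, vsrc + (ihi - ilo) - 1) += buf.cols(vdst, vdst + (ihi - ilo) - 1);
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_conv3d_fwd(const arma::mat& x, IntegerVector dims,
                         const arma::mat& W, const arma::vec& b) {
  int d[3] = {dims[0], dims[1], dims[2]};
  int cin = x.n_rows, cout = W.n_cols;
  size_t n = x.n_cols;
  arma::mat y(cout, n, arma::fill::zeros);
  arma::mat buf(cin, n);
  int o = 0;
  for (int dk = -1; dk <= 1; dk++)
    for (int dj = -1; dj <= 1; dj++)
      for (int di = -1; di <= 1; di++, o++) {
        gather(x, buf, d, di, dj, dk);
        y += W.rows(o * cin, (o + 1) * cin - 1).t() * buf;
      }
  y.each_col() += b;
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(const arma::mat& x, IntegerVector dims,
                    const arma::mat& W, const arma::mat& dy) {
  int d[3] = {dims[0], dims[1], dims[2]};
  int cin = x.n_rows, cout = W.n_cols;
  size_t n = x.n_cols;
  arma::mat dx(cin, n, arma::fill::zeros);
  arma::mat dW(W.n_rows, cout, arma::fill::zeros);
  arma::mat buf(cin, n);
  int o = 0;
  for (int dk = -1; dk <= 1; dk++)
    for (int dj = -1; dj <= 1; dj++)
      for (int di = -1; di <= 1; di++, o++) {
        gather(x, buf, d, di, dj, dk);
        dW.rows(o * cin, (o + 1) * cin - 1) = buf * dy.t();
        buf = W.rows(o * cin, (o + 1) * cin - 1) * dy;  // Cin x N at shifted pos
        scatter_add(dx, buf, d, di, dj, dk);
      }
  arma::vec db = arma::sum(dy, 1);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 2x2x2 max pooling, stride 2; returns pooled map and 1-based argmax columns
// [[Rcpp::export]]
List cpp_maxpool_fwd(const arma::mat& x, IntegerVector dims) {
  int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  int o0 = d0 / 2, o1 = d1 / 2, o2 = d2 / 2;
  int c = x.n_rows;
  size_t no = (size_t)o0 * o1 * o2;
  arma::mat y(c, no);
  arma::umat am(c, no);
  for (int k = 0; k < o2; k++)
    for (int j = 0; j < o1; j++)
      for (int i = 0; i < o0; i++) {
        size_t vo = (size_t)i + (size_t)o0 * (j + (size_t)o1 * k);
        for (int ch = 0; ch < c; ch++) {
          double best = -1e300; size_t bidx = 0;
          for (int dk = 0; dk < 2; dk++)
            for (int dj = 0; dj < 2; dj++)
              for (int di = 0; di < 2; di++) {
                size_t vi = (size_t)(2 * i + di) +
                  (size_t)d0 * ((2 * j + dj) + (size_t)d1 * (2 * k + dk));
                double val = x(ch, vi);
                if (val > best) { best = val; bidx = vi; }
              }
          y(ch, vo) = best;
          am(ch, vo) = bidx + 1;
        }
      }
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool_bwd(const arma::mat& dy, const arma::umat& am,
                          int n_in) {
  int c = dy.n_rows;
  arma::mat dx(c, n_in, arma::fill::zeros);
  for (size_t v = 0; v < dy.n_cols; v++)
    for (int ch = 0; ch < c; ch++)
      dx(ch, am(ch, v) - 1) += dy(ch, v);
  return dx;
}
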