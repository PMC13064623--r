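// Minimal CPU convolution kernels for the U-Net generators and PatchGAN
// discriminators. Feature maps are arma::cube (height x width x channels);
// conv weights are (C_out x C_in*k*k), transposed-conv weights are
// (C_in x C_out*k*k). im2col column l enumerates output positions in
// column-major order (row fastest), matching R's array layout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col(const cube& x, int k, int s, int p, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat cols(C * k * k, Ho * Wo, fill::zeros);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int l = ho + Ho * wo;
      for (int c = 0; c < C; ++c) {
        const int base = c * k * k;
        for (int kj = 0; kj < k; ++kj) {
          const int wj = wo * s - p + kj;
          if (wj < 0 || wj >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int hi = ho * s - p + ki;
            if (hi < 0 || hi >= H) continue;
            cols(base + ki + k * kj, l) = x(hi, wj, c);
          }
        }
      }
    }
  }
  return cols;
}

static cube col2im(const mat& cols, int H, int W, int C, int k, int s, int p,
                   int Ho, int Wo) {
  cube x(H, W, C, fill::zeros);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int l = ho + Ho * wo;
      for (int c = 0; c < C; ++c) {
        const int base = c * k * k;
        for (int kj = 0; kj < k; ++kj) {
          const int wj = wo * s - p + kj;
          if (wj < 0 || wj >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int hi = ho * s - p + ki;
            if (hi < 0 || hi >= H) continue;
            x(hi, wj, c) += cols(base + ki + k * kj, l);
          }
        }
      }
    }
  }
  return x;
}

static int conv_out(int H, int k, int s, int p) { return (H + 2 * p - k) / s + 1; }

// Per-layer cache of the most recent forward's im2col matrix, so the
// backward pass can skip recomputing it. Keyed by a layer id assigned in R;
// id 0 disables caching. Cleared entry-by-entry on use.
static std::map<int, mat> col_cache;

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& W, int k, int s,
                      int p, int cid = 0) {
  const int Ho = conv_out(x.n_rows, k, s, p), Wo = conv_out(x.n_cols, k, s, p);
  mat cols = im2col(x, k, s, p, Ho, Wo);
  mat y = W * cols;                       // (C_out x L)
  if (cid > 0) col_cache[cid] = std::move(cols);
  cube out(Ho, Wo, W.n_rows);
  for (uword c = 0; c < W.n_rows; ++c)
    out.slice(c) = reshape(y.row(c), Ho, Wo);
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd(const arma::cube& x, const arma::mat& W,
                      const arma::cube& gy, int k, int s, int p, int cid = 0) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, Co = gy.n_slices;
  mat gym(Co, Ho * Wo);
  for (int c = 0; c < Co; ++c)
    gym.row(c) = vectorise(gy.slice(c)).t();
  mat cols;
  auto hit = col_cache.find(cid);
  if (cid > 0 && hit != col_cache.end()) {
    cols = std::move(hit->second);
    col_cache.erase(hit);
  } else {
    cols = im2col(x, k, s, p, Ho, Wo);
  }
  mat gW = gym * cols.t();
  mat gcols = W.t() * gym;
  cube gx = col2im(gcols, x.n_rows, x.n_cols, x.n_slices, k, s, p, Ho, Wo);
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gW") = gW);
}

// [[Rcpp::export]]
void clear_col_cache() { col_cache.clear(); }

// Transposed convolution: output (Ho,Wo) with Ho=(H-1)*s-2p+k+opad.
// [[Rcpp::export]]
arma::cube convt2d_fwd(const arma::cube& x, const arma::mat& M, int k, int s,
                       int p, int opad) {
  const int H = x.n_rows, Wd = x.n_cols, Ci = x.n_slices;
  const int Ho = (H - 1) * s - 2 * p + k + opad;
  const int Wo = (Wd - 1) * s - 2 * p + k + opad;
  const int Co = M.n_cols / (k * k);
  mat xm(Ci, H * Wd);
  for (int c = 0; c < Ci; ++c)
    xm.row(c) = vectorise(x.slice(c)).t();
  mat cols = M.t() * xm;                  // (C_out*k*k x H*W)
  return col2im(cols, Ho, Wo, Co, k, s, p, H, Wd);
}

// [[Rcpp::export]]
Rcpp::List convt2d_bwd(const arma::cube& x, const arma::mat& M,
                       const arma::cube& gy, int k, int s, int p) {
  const int H = x.n_rows, Wd = x.n_cols, Ci = x.n_slices;
  mat xm(Ci, H * Wd);
  for (int c = 0; c < Ci; ++c)
    xm.row(c) = vectorise(x.slice(c)).t();
  mat gcols = im2col(gy, k, s, p, H, Wd); // (C_out*k*k x H*W)
  mat gM = xm * gcols.t();
  mat gxm = M * gcols;                    // (C_in x H*W)
  cube gx(H, Wd, Ci);
  for (int c = 0; c < Ci; ++c)
    gx.slice(c) = reshape(gxm.row(c), H, Wd);
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gM") = gM);
}
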