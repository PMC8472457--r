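// Computational kernels for the spatio-spectral classifier and the
// segmentation morphology.
//
// Convolutions are evaluated as im2col gathers followed by a BLAS GEMM.
// Activation tensors are laid out exactly like column-major R arrays of
// dim c(H, W, B, C): flat feature index f = p + P*c with p the (h, w, b)
// position index (h fastest) and P = H'*W'*B'. The gather table factorizes
// as idx(e, p) = off[e] + base[p]: `off` enumerates kernel elements,
// `base` output positions (both 0-based, computed once per layer in R).
// The gather matrix is built transposed (P*N x E) so that both the reads
// and the writes of the inner loops are near-sequential.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat gather_cols(const arma::mat& X, const arma::ivec& off,
                             const arma::ivec& base) {
  const int E = off.n_elem, P = base.n_elem, N = X.n_cols;
  arma::mat Mt((size_t)P * N, E);
  for (int e = 0; e < E; ++e) {
    double* me = Mt.colptr(e);
    const int o = off[e];
    for (int n = 0; n < N; ++n) {
      const double* xn = X.colptr(n) + o;
      double* mn = me + (size_t)n * P;
      for (int p = 0; p < P; ++p) mn[p] = xn[base[p]];
    }
  }
  return Mt;
}

// Forward pass of one convolution layer, with the rectifier fused in.
// X: (Fin x N), W: (Cout x E), b: (Cout).
// Returns list(Y (P*Cout x N), Mt (P*N x E)); Mt is reused by the cached
// backward pass so the gather runs once per batch.
// [[Rcpp::export]]
List cc_conv_forward(const arma::mat& X, const arma::mat& W,
                     const arma::vec& b, const arma::ivec& off,
                     const arma::ivec& base, bool relu) {
  const int P = base.n_elem, N = X.n_cols, Cout = W.n_rows;
  arma::mat Mt = gather_cols(X, off, base);
  arma::mat Ot = Mt * W.t();                 // P*N x Cout
  arma::mat Y((size_t)P * Cout, N);
  for (int c = 0; c < Cout; ++c) {
    const double* oc = Ot.colptr(c);
    const double bc = b[c];
    for (int n = 0; n < N; ++n) {
      double* yn = Y.colptr(n) + (size_t)c * P;
      const double* on = oc + (size_t)n * P;
      if (relu)
        for (int p = 0; p < P; ++p) yn[p] = std::max(0.0, on[p] + bc);
      else
        for (int p = 0; p < P; ++p) yn[p] = on[p] + bc;
    }
  }
  return List::create(_["Y"] = Y, _["Mt"] = Mt);
}

// Backward pass reusing the cached gather matrix. dY: (P*Cout x N).
// Returns list(dX (Fin x N), dW (Cout x E), db (Cout)).
// [[Rcpp::export]]
List cc_conv_backward(const arma::mat& Mt, const arma::mat& W,
                      const arma::ivec& off, const arma::ivec& base,
                      const arma::mat& dY, int Fin) {
  const int E = off.n_elem, P = base.n_elem;
  const int Cout = W.n_rows, N = dY.n_cols;
  arma::mat dOt((size_t)P * N, Cout);
  for (int c = 0; c < Cout; ++c) {
    double* dc = dOt.colptr(c);
    for (int n = 0; n < N; ++n) {
      const double* dyn = dY.colptr(n) + (size_t)c * P;
      double* dn = dc + (size_t)n * P;
      for (int p = 0; p < P; ++p) dn[p] = dyn[p];
    }
  }
  arma::vec db = arma::sum(dOt, 0).t();
  arma::mat dW = dOt.t() * Mt;               // Cout x E
  arma::mat dMt = dOt * W;                   // P*N x E
  arma::mat dX(Fin, N, arma::fill::zeros);
  for (int e = 0; e < E; ++e) {
    const double* de = dMt.colptr(e);
    const int o = off[e];
    for (int n = 0; n < N; ++n) {
      double* dxn = dX.colptr(n) + o;
      const double* dn = de + (size_t)n * P;
      for (int p = 0; p < P; ++p) dxn[base[p]] += dn[p];
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

static inline int reflect_idx(int q, int n) {
  // mirror-with-edge ("symmetric") padding: ... 2 1 0 | 0 1 2 ... n-1 | n-1 ...
  while (q < 0 || q >= n) {
    if (q < 0) q = -q - 1;
    if (q >= n) q = 2 * n - q - 1;
  }
  return q;
}

// Extract win x win x B subvolumes centred at (rows[i], cols[i]) (1-based)
// from a cube of dim (H, W, B), with symmetric reflect padding at borders.
// Returns (win*win*B x n) with column-major (dh, dw, b) ordering.
// [[Rcpp::export]]
arma::mat cc_extract_subvols(const arma::cube& cube, const arma::ivec& rows,
                             const arma::ivec& cols, int win) {
  const int H = cube.n_rows, W = cube.n_cols, B = cube.n_slices;
  const int half = win / 2, n = rows.n_elem;
  arma::mat out((size_t)win * win * B, n);
  for (int i = 0; i < n; ++i) {
    double* oc = out.colptr(i);
    const int r0 = rows[i] - 1, c0 = cols[i] - 1;
    for (int b = 0; b < B; ++b) {
      const arma::mat& sl = cube.slice(b);
      for (int dw = 0; dw < win; ++dw) {
        const int cc = reflect_idx(c0 + dw - half, W);
        const double* sc = sl.colptr(cc);
        for (int dh = 0; dh < win; ++dh)
          oc[(size_t)b * win * win + dw * win + dh] =
            sc[reflect_idx(r0 + dh - half, H)];
      }
    }
  }
  return out;
}

// Connected-component labelling of a binary mask by flood fill.
// connectivity: 4 or 8. Returns integer matrix, 0 = background,
// components numbered 1..K in scan order.
// [[Rcpp::export]]
IntegerMatrix cc_label_components(const IntegerMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int>> nb =
    {{-1, 0}, {1, 0}, {0, -1}, {0, 1}};
  if (connectivity == 8) {
    nb.push_back({-1, -1}); nb.push_back({-1, 1});
    nb.push_back({1, -1});  nb.push_back({1, 1});
  } else if (connectivity != 4) {
    stop("connectivity must be 4 or 8");
  }
  int next = 0;
  std::vector<int> stack;
  stack.reserve((size_t)H * W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.push_back(r + c * H);
      lab(r, c) = next;
      while (!stack.empty()) {
        const int q = stack.back(); stack.pop_back();
        const int qr = q % H, qc = q / H;
        for (auto& d : nb) {
          const int rr = qr + d.first, cc = qc + d.second;
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(rr + cc * H);
          }
        }
      }
    }
  return lab;
}
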