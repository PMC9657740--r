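// Native forward/backward kernels for the FCN-32s layers.
//
// Conventions shared with the R side:
//  - feature maps are H x W x C cubes (R arrays, column-major);
//  - convolution weights are (kh*kw*Cin) x Cout matrices, patch element
//    order ((c*kw + dw)*kh + dh), i.e. the column-major flattening of an
//    R array with dim (kh, kw, Cin);
//  - deconvolution weights are vectors flattening an R array with dim
//    (k, k, Cin, Cout);
//  - all pooling is 2x2 stride-2 with ceil rounding (windows clipped at the
//    bottom/right edge), matching the reference FCN-32s feature-size trace.
//
// The patch matrix is kept transposed -- (Ho*Wo) x (kh*kw*Cin) -- so that
// every im2col/col2im transfer is a contiguous column copy.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static cube pad_cube(const cube& x, int pad) {
  if (pad == 0) return x;
  cube xp(x.n_rows + 2 * pad, x.n_cols + 2 * pad, x.n_slices, fill::zeros);
  xp.subcube(pad, pad, 0, pad + x.n_rows - 1, pad + x.n_cols - 1, x.n_slices - 1) = x;
  return xp;
}

// Transposed patch matrix of a (padded) input: row = output position
// (column-major over (i, j)), column = patch element (dh, dw, c).
static mat im2colT(const cube& xp, int k) {
  const int Ho = xp.n_rows - k + 1;
  const int Wo = xp.n_cols - k + 1;
  const int C = xp.n_slices;
  mat cols((uword)Ho * Wo, (uword)k * k * C);
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const uword r = ((uword)c * k + dw) * k + dh;
        cols.col(r) = vectorise(xp.slice(c).submat(dh, dw, dh + Ho - 1, dw + Wo - 1));
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
arma::cube cpp_conv_forward(const arma::cube& x, const arma::mat& w,
                            const arma::vec& b, int pad, bool relu) {
  const int Cin = x.n_slices;
  const int Cout = w.n_cols;
  const int k = (int)std::lround(std::sqrt((double)(w.n_rows / Cin)));
  cube xp = pad_cube(x, pad);
  const int Ho = xp.n_rows - k + 1;
  const int Wo = xp.n_cols - k + 1;
  if (Ho < 1 || Wo < 1) Rcpp::stop("convolution input too small for kernel");
  mat outm = im2colT(xp, k) * w;      // (Ho*Wo) x Cout
  outm.each_row() += b.t();
  cube out(Ho, Wo, Cout);
  for (int f = 0; f < Cout; ++f)
    out.slice(f) = reshape(outm.col(f), Ho, Wo);
  if (relu) out.transform([](double v) { return v > 0.0 ? v : 0.0; });
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_backward(const arma::cube& x, const arma::mat& w,
                             arma::cube dout, const arma::cube& out,
                             int pad, bool relu, bool need_dx) {
  const int Cin = x.n_slices;
  const int Cout = w.n_cols;
  const int k = (int)std::lround(std::sqrt((double)(w.n_rows / Cin)));
  if (relu) {
    for (uword i = 0; i < dout.n_elem; ++i)
      if (out(i) <= 0.0) dout(i) = 0.0;
  }
  const int Ho = dout.n_rows, Wo = dout.n_cols;
  mat doutm((uword)Ho * Wo, Cout);
  for (int f = 0; f < Cout; ++f)
    doutm.col(f) = vectorise(dout.slice(f));

  cube xp = pad_cube(x, pad);
  mat dW = im2colT(xp, k).t() * doutm;
  vec db = sum(doutm, 0).t();

  Rcpp::List res = Rcpp::List::create(Rcpp::Named("dx") = R_NilValue,
                                      Rcpp::Named("dW") = dW,
                                      Rcpp::Named("db") = db);
  if (need_dx) {
    mat dcols = doutm * w.t();        // (Ho*Wo) x (k*k*Cin)
    cube dxp(xp.n_rows, xp.n_cols, Cin, fill::zeros);
    for (int c = 0; c < Cin; ++c) {
      for (int dw_ = 0; dw_ < k; ++dw_) {
        for (int dh = 0; dh < k; ++dh) {
          const uword r = ((uword)c * k + dw_) * k + dh;
          dxp.slice(c).submat(dh, dw_, dh + Ho - 1, dw_ + Wo - 1) +=
            reshape(dcols.col(r), Ho, Wo);
        }
      }
    }
    cube dx = (pad == 0) ? dxp
      : cube(dxp.subcube(pad, pad, 0, pad + x.n_rows - 1, pad + x.n_cols - 1, Cin - 1));
    res["dx"] = dx;
  }
  return res;
}

// [[Rcpp::export]]
Rcpp::List cpp_maxpool_forward(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + 1) / 2, Wo = (W + 1) / 2;
  cube out(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C); // linear index into the input slice
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int i0 = 2 * i, j0 = 2 * j;
        const int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
        double best = x(i0, j0, c);
        uword bi = (uword)j0 * H + i0;
        for (int jj = j0; jj <= j1; ++jj) {
          for (int ii = i0; ii <= i1; ++ii) {
            if (x(ii, jj, c) > best) { best = x(ii, jj, c); bi = (uword)jj * H + ii; }
          }
        }
        out(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_backward(const arma::cube& dout, const arma::ucube& idx,
                                int H, int W) {
  const int C = dout.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* slice = dx.slice_memptr(c);
    for (uword e = 0; e < dout.n_rows * dout.n_cols; ++e)
      slice[idx.slice(c)(e)] += dout.slice(c)(e);
  }
  return dx;
}

// Transposed convolution, square kernel k, stride s, no padding:
// out side = (in - 1) * s + k.
// [[Rcpp::export]]
arma::cube cpp_deconv_forward(const arma::cube& x, const arma::vec& w,
                              int k, int stride, int cout) {
  const int Hi = x.n_rows, Wi = x.n_cols, Cin = x.n_slices;
  const int Ho = (Hi - 1) * stride + k, Wo = (Wi - 1) * stride + k;
  cube out(Ho, Wo, cout, fill::zeros);
  for (int co = 0; co < cout; ++co) {
    for (int ci = 0; ci < Cin; ++ci) {
      const mat K(const_cast<double*>(w.memptr()) +
                  ((uword)co * Cin + ci) * k * k, k, k, false, true);
      for (int j = 0; j < Wi; ++j) {
        for (int i = 0; i < Hi; ++i) {
          const double v = x(i, j, ci);
          if (v != 0.0)
            out.slice(co).submat(i * stride, j * stride,
                                 i * stride + k - 1, j * stride + k - 1) += v * K;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_deconv_backward(const arma::cube& x, const arma::vec& w,
                               const arma::cube& dout, int k, int stride) {
  const int Hi = x.n_rows, Wi = x.n_cols, Cin = x.n_slices;
  const int Cout = dout.n_slices;
  cube dx(Hi, Wi, Cin, fill::zeros);
  vec dW(w.n_elem, fill::zeros);
  for (int co = 0; co < Cout; ++co) {
    for (int ci = 0; ci < Cin; ++ci) {
      const mat K(const_cast<double*>(w.memptr()) +
                  ((uword)co * Cin + ci) * k * k, k, k, false, true);
      mat dK(dW.memptr() + ((uword)co * Cin + ci) * k * k, k, k, false, true);
      for (int j = 0; j < Wi; ++j) {
        for (int i = 0; i < Hi; ++i) {
          const mat win = dout.slice(co).submat(i * stride, j * stride,
                                                i * stride + k - 1, j * stride + k - 1);
          dx(i, j, ci) += accu(win % K);
          dK += x(i, j, ci) * win;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dW") = dW);
}
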