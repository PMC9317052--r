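// Dense 2-D layer primitives for the multi-stream U-Net engine.
//
// Tensor layout follows R's column-major array convention throughout:
// activations are [H, W, C, N] and convolution kernels [k, k, Cin, Cout],
// so an R array can be handed over without copying or permuting.
// Convolutions are stride-1 with 'same' zero padding and are evaluated as
// im2col + GEMM; the 2x2 transposed convolution has stride 2 (the U-Net
// upsampling step) and is evaluated as four sub-kernel GEMMs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

inline const double *tensor_ptr(const Rcpp::NumericVector &x) {
  return x.begin();
}

// im2col for one sample: output (k*k*Cin) x (H*W), row index i + k*j + k*k*c,
// column index h + H*w -- matches the column-major kernel layout [k,k,Cin,Cout].
void im2col(const double *x, int H, int W, int C, int k, int pad, mat &K) {
  const int HW = H * W;
  K.zeros();
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (std::size_t)c * HW;
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        const int row = i + k * j + k * k * c;
        for (int w = 0; w < W; ++w) {
          const int ws = w + j - pad;
          if (ws < 0 || ws >= W) continue;
          const double *col_src = xc + (std::size_t)ws * H;
          double *krow = K.memptr() + row;
          const int h_lo = std::max(0, pad - i);
          const int h_hi = std::min(H, H + pad - i);
          for (int h = h_lo; h < h_hi; ++h) {
            krow[(std::size_t)(h + H * w) * K.n_rows] = col_src[h + i - pad];
          }
        }
      }
    }
  }
}

void col2im_add(const mat &K, int H, int W, int C, int k, int pad, double *dx) {
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    double *xc = dx + (std::size_t)c * HW;
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        const int row = i + k * j + k * k * c;
        for (int w = 0; w < W; ++w) {
          const int ws = w + j - pad;
          if (ws < 0 || ws >= W) continue;
          double *col_dst = xc + (std::size_t)ws * H;
          const double *krow = K.memptr() + row;
          const int h_lo = std::max(0, pad - i);
          const int h_hi = std::min(H, H + pad - i);
          for (int h = h_lo; h < h_hi; ++h) {
            col_dst[h + i - pad] += krow[(std::size_t)(h + H * w) * K.n_rows];
          }
        }
      }
    }
  }
}


Rcpp::NumericVector alloc4d(int a, int b, int c, int d) {
  Rcpp::NumericVector v((std::size_t)a * b * c * d);
  v.attr("dim") = Rcpp::IntegerVector::create(a, b, c, d);
  return v;
}

Rcpp::IntegerVector alloc4i(int a, int b, int c, int d) {
  Rcpp::IntegerVector v((std::size_t)a * b * c * d);
  v.attr("dim") = Rcpp::IntegerVector::create(a, b, c, d);
  return v;
}

Rcpp::IntegerVector tensor_dims(const Rcpp::NumericVector &x, int need) {
  Rcpp::IntegerVector d = x.attr("dim");
  if (d.size() != need)
    Rcpp::stop("expected a %d-d array, got %d dims", need, (int)d.size());
  return d;
}

} // namespace

// [[Rcpp::export(name = ".conv2d_forward")]]
Rcpp::NumericVector conv2d_forward(Rcpp::NumericVector x, Rcpp::NumericVector W,
                                   Rcpp::NumericVector b) {
  Rcpp::IntegerVector dx = tensor_dims(x, 4), dw = tensor_dims(W, 4);
  const int H = dx[0], Wd = dx[1], C = dx[2], N = dx[3];
  const int k = dw[0], Cin = dw[2], Cout = dw[3];
  if (dw[1] != k) Rcpp::stop("kernel must be square");
  if (Cin != C) Rcpp::stop("channel mismatch: input %d vs kernel %d", C, Cin);
  if (k % 2 == 0) Rcpp::stop("stride-1 'same' convolution needs an odd kernel");
  const int pad = (k - 1) / 2, HW = H * Wd;

  Rcpp::NumericVector out = alloc4d(H, Wd, Cout, N);
  const mat Wm(const_cast<double *>(tensor_ptr(W)), k * k * Cin, Cout, false);
  const vec bv(const_cast<double *>(b.begin()), Cout, false);
  mat K(k * k * Cin, HW);

  for (int n = 0; n < N; ++n) {
    im2col(tensor_ptr(x) + (std::size_t)n * HW * C, H, Wd, C, k, pad, K);
    mat Y = Wm.t() * K; // Cout x HW
    Y.each_col() += bv;
    double *on = out.begin() + (std::size_t)n * HW * Cout;
    for (int c = 0; c < Cout; ++c)
      for (int p = 0; p < HW; ++p)
        on[(std::size_t)c * HW + p] = Y(c, p);
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
Rcpp::List conv2d_backward(Rcpp::NumericVector x, Rcpp::NumericVector W,
                           Rcpp::NumericVector dy) {
  Rcpp::IntegerVector dx_ = tensor_dims(x, 4), dw_ = tensor_dims(W, 4),
                      dy_ = tensor_dims(dy, 4);
  const int H = dx_[0], Wd = dx_[1], C = dx_[2], N = dx_[3];
  const int k = dw_[0], Cout = dw_[3];
  const int pad = (k - 1) / 2, HW = H * Wd;
  if (dy_[2] != Cout || dy_[3] != N || dy_[0] != H || dy_[1] != Wd)
    Rcpp::stop("gradient shape mismatch");

  Rcpp::NumericVector dx = alloc4d(H, Wd, C, N);
  Rcpp::NumericVector dW = alloc4d(k, k, C, Cout);
  Rcpp::NumericVector db(Cout);
  const mat Wm(const_cast<double *>(tensor_ptr(W)), k * k * C, Cout, false);
  mat dWm(dW.begin(), k * k * C, Cout, false, true);
  vec dbv(db.begin(), Cout, false, true);
  mat K(k * k * C, HW), dY(Cout, HW);

  for (int n = 0; n < N; ++n) {
    const double *dyn = dy.begin() + (std::size_t)n * HW * Cout;
    for (int c = 0; c < Cout; ++c)
      for (int p = 0; p < HW; ++p)
        dY(c, p) = dyn[(std::size_t)c * HW + p];
    im2col(tensor_ptr(x) + (std::size_t)n * HW * C, H, Wd, C, k, pad, K);
    dWm += K * dY.t();
    dbv += sum(dY, 1);
    mat dK = Wm * dY; // (k*k*C) x HW
    col2im_add(dK, H, Wd, C, k, pad, dx.begin() + (std::size_t)n * HW * C);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// 2x2 stride-2 transposed convolution: out[2h+i, 2w+j, o] += W[i,j,c,o] x[h,w,c]
// [[Rcpp::export(name = ".tconv2x2_forward")]]
Rcpp::NumericVector tconv2x2_forward(Rcpp::NumericVector x,
                                     Rcpp::NumericVector W,
                                     Rcpp::NumericVector b) {
  Rcpp::IntegerVector dx = tensor_dims(x, 4), dw = tensor_dims(W, 4);
  const int H = dx[0], Wd = dx[1], C = dx[2], N = dx[3];
  const int Cin = dw[2], Cout = dw[3];
  if (dw[0] != 2 || dw[1] != 2) Rcpp::stop("transposed kernel must be 2x2");
  if (Cin != C) Rcpp::stop("channel mismatch");
  const int Ho = 2 * H, Wo = 2 * Wd, HW = H * Wd, HWo = Ho * Wo;

  Rcpp::NumericVector out = alloc4d(Ho, Wo, Cout, N);
  // sub-kernel (i,j): Cout x Cin matrix
  std::vector<mat> Wsub(4, mat(Cout, Cin));
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int j = 0; j < 2; ++j)
        for (int i = 0; i < 2; ++i)
          Wsub[i + 2 * j](o, c) = W[i + 2 * (j + 2 * ((std::size_t)c + Cin * o))];

  for (int n = 0; n < N; ++n) {
    const mat X(const_cast<double *>(tensor_ptr(x)) + (std::size_t)n * HW * C,
                HW, C, false); // (h+H*w) x c
    double *on = out.begin() + (std::size_t)n * HWo * Cout;
    for (int s = 0; s < 4; ++s) {
      const int i = s % 2, j = s / 2;
      mat Y = X * Wsub[s].t(); // HW x Cout
      for (int o = 0; o < Cout; ++o) {
        double *oc = on + (std::size_t)o * HWo;
        const double *yc = Y.colptr(o);
        for (int w = 0; w < Wd; ++w)
          for (int h = 0; h < H; ++h)
            oc[(2 * h + i) + (std::size_t)Ho * (2 * w + j)] = yc[h + H * w];
      }
    }
    for (int o = 0; o < Cout; ++o) {
      double *oc = on + (std::size_t)o * HWo;
      const double bo = b[o];
      for (int p = 0; p < HWo; ++p) oc[p] += bo;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".tconv2x2_backward")]]
Rcpp::List tconv2x2_backward(Rcpp::NumericVector x, Rcpp::NumericVector W,
                             Rcpp::NumericVector dy) {
  Rcpp::IntegerVector dx_ = tensor_dims(x, 4), dw_ = tensor_dims(W, 4),
                      dy_ = tensor_dims(dy, 4);
  const int H = dx_[0], Wd = dx_[1], C = dx_[2], N = dx_[3];
  const int Cout = dw_[3];
  const int Ho = 2 * H, Wo = 2 * Wd, HW = H * Wd, HWo = Ho * Wo;
  if (dy_[0] != Ho || dy_[1] != Wo || dy_[2] != Cout || dy_[3] != N)
    Rcpp::stop("gradient shape mismatch");

  Rcpp::NumericVector dx = alloc4d(H, Wd, C, N);
  Rcpp::NumericVector dW = alloc4d(2, 2, C, Cout);
  Rcpp::NumericVector db(Cout);

  std::vector<mat> Wsub(4, mat(Cout, C)), dWsub(4, mat(Cout, C, fill::zeros));
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < 2; ++j)
        for (int i = 0; i < 2; ++i)
          Wsub[i + 2 * j](o, c) = W[i + 2 * (j + 2 * ((std::size_t)c + C * o))];

  mat dYs(HW, Cout);
  for (int n = 0; n < N; ++n) {
    const mat X(const_cast<double *>(tensor_ptr(x)) + (std::size_t)n * HW * C,
                HW, C, false);
    mat dX(dx.begin() + (std::size_t)n * HW * C, HW, C, false, true);
    const double *dyn = dy.begin() + (std::size_t)n * HWo * Cout;
    for (int o = 0; o < Cout; ++o) {
      const double *dc = dyn + (std::size_t)o * HWo;
      double s = 0;
      for (int p = 0; p < HWo; ++p) s += dc[p];
      db[o] += s;
    }
    for (int sidx = 0; sidx < 4; ++sidx) {
      const int i = sidx % 2, j = sidx / 2;
      for (int o = 0; o < Cout; ++o) {
        const double *dc = dyn + (std::size_t)o * HWo;
        double *yc = dYs.colptr(o);
        for (int w = 0; w < Wd; ++w)
          for (int h = 0; h < H; ++h)
            yc[h + H * w] = dc[(2 * h + i) + (std::size_t)Ho * (2 * w + j)];
      }
      dX += dYs * Wsub[sidx];
      dWsub[sidx] += dYs.t() * X;
    }
  }
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < 2; ++j)
        for (int i = 0; i < 2; ++i)
          dW[i + 2 * (j + 2 * ((std::size_t)c + C * o))] = dWsub[i + 2 * j](o, c);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export(name = ".maxpool2x2_forward")]]
Rcpp::List maxpool2x2_forward(Rcpp::NumericVector x) {
  Rcpp::IntegerVector d = tensor_dims(x, 4);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) Rcpp::stop("spatial dims must be even for 2x2 pooling");
  const int Ho = H / 2, Wo = W / 2;
  Rcpp::NumericVector out = alloc4d(Ho, Wo, C, N);
  Rcpp::IntegerVector idx = alloc4i(Ho, Wo, C, N); // 0-based into x
  const double *xp = x.begin();
  double *op = out.begin();
  int *ip = idx.begin();
  const std::size_t planes = (std::size_t)C * N;
  for (std::size_t pl = 0; pl < planes; ++pl) {
    const double *xc = xp + pl * H * W;
    double *oc = op + pl * Ho * Wo;
    int *ic = ip + pl * Ho * Wo;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        int best = 2 * h + H * (2 * w);
        double bv = xc[best];
        const int cand[3] = {2 * h + 1 + H * (2 * w), 2 * h + H * (2 * w + 1),
                             2 * h + 1 + H * (2 * w + 1)};
        for (int q = 0; q < 3; ++q)
          if (xc[cand[q]] > bv) { bv = xc[cand[q]]; best = cand[q]; }
        oc[h + Ho * w] = bv;
        ic[h + Ho * w] = (int)(pl * H * W) + best;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool2x2_backward")]]
Rcpp::NumericVector maxpool2x2_backward(Rcpp::NumericVector dy,
                                        Rcpp::IntegerVector idx,
                                        Rcpp::IntegerVector in_dim) {
  Rcpp::NumericVector dx = alloc4d(in_dim[0], in_dim[1], in_dim[2],
                                         in_dim[3]);
  const double *dp = dy.begin();
  const int *ip = idx.begin();
  double *xp = dx.begin();
  const std::size_t n = dy.size();
  for (std::size_t q = 0; q < n; ++q) xp[ip[q]] += dp[q];
  return dx;
}

// ---- fused per-channel elementwise helpers (batch-norm, ReLU) ----

// [[Rcpp::export(name = ".channel_sums")]]
Rcpp::NumericMatrix channel_sums(Rcpp::NumericVector x) {
  Rcpp::IntegerVector d = tensor_dims(x, 4);
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  Rcpp::NumericMatrix out(C, 2); // col 0: sum, col 1: sum of squares
  const double *xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *p = xp + ((std::size_t)n * C + c) * HW;
      double s = 0, q = 0;
      for (int i = 0; i < HW; ++i) { s += p[i]; q += p[i] * p[i]; }
      out(c, 0) += s; out(c, 1) += q;
    }
  return out;
}

// [[Rcpp::export(name = ".channel_dot")]]
Rcpp::NumericVector channel_dot(Rcpp::NumericVector x, Rcpp::NumericVector y) {
  Rcpp::IntegerVector d = tensor_dims(x, 4);
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  Rcpp::NumericVector out(C);
  const double *xp = x.begin(), *yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *p = xp + ((std::size_t)n * C + c) * HW;
      const double *q = yp + ((std::size_t)n * C + c) * HW;
      double s = 0;
      for (int i = 0; i < HW; ++i) s += p[i] * q[i];
      out[c] += s;
    }
  return out;
}

// y = a[c] * x + b[c] * y2 + d[c] per channel (y2 may be an empty vector)
// [[Rcpp::export(name = ".channel_affine")]]
Rcpp::NumericVector channel_affine(Rcpp::NumericVector x,
                                   Rcpp::NumericVector a,
                                   Rcpp::NumericVector d_,
                                   Rcpp::Nullable<Rcpp::NumericVector> y2 =
                                       R_NilValue,
                                   Rcpp::Nullable<Rcpp::NumericVector> b =
                                       R_NilValue) {
  Rcpp::IntegerVector d = tensor_dims(x, 4);
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  Rcpp::NumericVector out = alloc4d(d[0], d[1], C, N);
  const double *xp = x.begin();
  double *op = out.begin();
  const bool have2 = y2.isNotNull();
  const double *yp = have2 ? Rcpp::NumericVector(y2).begin() : nullptr;
  Rcpp::NumericVector bv = have2 ? Rcpp::NumericVector(b) :
                                   Rcpp::NumericVector(0);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t off = ((std::size_t)n * C + c) * HW;
      const double ac = a[c], dc = d_[c];
      if (have2) {
        const double bc = bv[c];
        for (int i = 0; i < HW; ++i)
          op[off + i] = ac * xp[off + i] + bc * yp[off + i] + dc;
      } else {
        for (int i = 0; i < HW; ++i) op[off + i] = ac * xp[off + i] + dc;
      }
    }
  return out;
}

// [[Rcpp::export(name = ".relu_forward")]]
Rcpp::NumericVector relu_forward(Rcpp::NumericVector z) {
  Rcpp::NumericVector out = Rcpp::clone(z);
  double *p = out.begin();
  const std::size_t n = out.size();
  for (std::size_t i = 0; i < n; ++i) if (p[i] < 0) p[i] = 0;
  return out;
}

// [[Rcpp::export(name = ".relu_backward")]]
Rcpp::NumericVector relu_backward(Rcpp::NumericVector dz,
                                  Rcpp::NumericVector z) {
  Rcpp::NumericVector out = Rcpp::clone(dz);
  double *p = out.begin();
  const double *zp = z.begin();
  const std::size_t n = out.size();
  for (std::size_t i = 0; i < n; ++i) if (zp[i] <= 0) p[i] = 0;
  return out;
}
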