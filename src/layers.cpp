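// Dense layer kernels for the boundary-detection network.
//
// All activation tensors are R arrays of dim (H, W, C, N), column-major,
// so sample n / channel c is a contiguous H*W block.  Convolution weights
// are arrays of dim (Cin, Cout, 9) where slice o holds the tap at offset
// (dy, dx) with dy = o %% 3 - 1 (fastest), dx = o %/% 3 - 1.  3x3 "same"
// convolution with zero padding is computed as nine shifted GEMMs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline void conv_windows(int dy, int dx, int H, int W,
                                int& hd0, int& hd1, int& wd0, int& wd1,
                                int& hs0, int& ws0) {
  // destination (output) window for which src = dst + (dy,dx) is in range
  hd0 = std::max(0, -dy); hd1 = std::min(H, H - dy) - 1;
  wd0 = std::max(0, -dx); wd1 = std::min(W, W - dx) - 1;
  hs0 = hd0 + dy; ws0 = wd0 + dx;
}

// [[Rcpp::export(name = ".conv3x3_fwd")]]
Rcpp::NumericVector conv3x3_fwd(const Rcpp::NumericVector& x,
                                const Rcpp::NumericVector& w,
                                const Rcpp::NumericVector& b) {
  Rcpp::IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  Rcpp::IntegerVector wd = w.attr("dim");
  const int Cout = wd[1];
  const int HW = H * W;
  Rcpp::NumericVector out(Rcpp::no_init((R_xlen_t)HW * Cout * N));
  out.attr("dim") = Rcpp::IntegerVector::create(H, W, Cout, N);

  const cube wc(const_cast<double*>(w.begin()), Cin, Cout, 9, false);
  mat T(HW, Cout);
  for (int n = 0; n < N; ++n) {
    mat X(const_cast<double*>(x.begin()) + (R_xlen_t)n * HW * Cin,
          HW, Cin, false);
    cube Y(out.begin() + (R_xlen_t)n * HW * Cout, H, W, Cout, false);
    Y.zeros();
    for (int o = 0; o < 9; ++o) {
      const int dy = o % 3 - 1, dx = o / 3 - 1;
      T = X * wc.slice(o);
      cube Tc(T.memptr(), H, W, Cout, false);
      int hd0, hd1, wd0_, wd1_, hs0, ws0;
      conv_windows(dy, dx, H, W, hd0, hd1, wd0_, wd1_, hs0, ws0);
      if (hd1 < hd0 || wd1_ < wd0_) continue;
      Y.subcube(hd0, wd0_, 0, hd1, wd1_, Cout - 1) +=
        Tc.subcube(hs0, ws0, 0, hs0 + (hd1 - hd0), ws0 + (wd1_ - wd0_),
                   Cout - 1);
    }
    for (int co = 0; co < Cout; ++co) Y.slice(co) += b[co];
  }
  return out;
}

// [[Rcpp::export(name = ".conv3x3_bwd")]]
Rcpp::List conv3x3_bwd(const Rcpp::NumericVector& x,
                       const Rcpp::NumericVector& w,
                       const Rcpp::NumericVector& dy_) {
  Rcpp::IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  Rcpp::IntegerVector wd = w.attr("dim");
  const int Cout = wd[1];
  const int HW = H * W;

  Rcpp::NumericVector dx_(Rcpp::no_init((R_xlen_t)HW * Cin * N));
  dx_.attr("dim") = xd;
  Rcpp::NumericVector dw(Rcpp::no_init((R_xlen_t)Cin * Cout * 9));
  dw.attr("dim") = Rcpp::IntegerVector::create(Cin, Cout, 9);
  Rcpp::NumericVector db(Cout);

  const cube wc(const_cast<double*>(w.begin()), Cin, Cout, 9, false);
  cube dwc(dw.begin(), Cin, Cout, 9, false);
  dwc.zeros();
  vec dbv(db.begin(), Cout, false);
  mat U(HW, Cin);

  for (int n = 0; n < N; ++n) {
    const R_xlen_t ox = (R_xlen_t)n * HW * Cin;
    const R_xlen_t oy = (R_xlen_t)n * HW * Cout;
    mat dYm(const_cast<double*>(dy_.begin()) + oy, HW, Cout, false);
    cube dYc(const_cast<double*>(dy_.begin()) + oy, H, W, Cout, false);
    cube Xc(const_cast<double*>(x.begin()) + ox, H, W, Cin, false);
    cube dXc(dx_.begin() + ox, H, W, Cin, false);
    dXc.zeros();
    dbv += sum(dYm, 0).t();
    for (int o = 0; o < 9; ++o) {
      const int dy = o % 3 - 1, dx = o / 3 - 1;
      int hd0, hd1, wd0_, wd1_, hs0, ws0;
      conv_windows(dy, dx, H, W, hd0, hd1, wd0_, wd1_, hs0, ws0);
      // tap entirely outside a degenerate (1-pixel) axis
      if (hd1 < hd0 || wd1_ < wd0_) continue;
      const int nh = hd1 - hd0 + 1, nw = wd1_ - wd0_ + 1;
      // input gradient: dX(dst + (dy,dx)) += [dY * W_o'](dst)
      U = dYm * wc.slice(o).t();
      cube Uc(U.memptr(), H, W, Cin, false);
      dXc.subcube(hs0, ws0, 0, hs0 + nh - 1, ws0 + nw - 1, Cin - 1) +=
        Uc.subcube(hd0, wd0_, 0, hd1, wd1_, Cin - 1);
      // weight gradient: dW_o = X(src win)' * dY(dst win)
      cube SX = Xc.subcube(hs0, ws0, 0, hs0 + nh - 1, ws0 + nw - 1, Cin - 1);
      cube SY = dYc.subcube(hd0, wd0_, 0, hd1, wd1_, Cout - 1);
      mat SXm(SX.memptr(), nh * nw, Cin, false);
      mat SYm(SY.memptr(), nh * nw, Cout, false);
      dwc.slice(o) += SXm.t() * SYm;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx_,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export(name = ".bn_relu_fwd")]]
Rcpp::List bn_relu_fwd(const Rcpp::NumericVector& x,
                       const Rcpp::NumericVector& gamma,
                       const Rcpp::NumericVector& beta,
                       const Rcpp::NumericVector& rmean,
                       const Rcpp::NumericVector& rvar,
                       const double momentum, const double eps,
                       const bool training) {
  Rcpp::IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const R_xlen_t HW = (R_xlen_t)H * W;
  const double M = (double)HW * N;

  Rcpp::NumericVector y(Rcpp::no_init(x.size()));
  y.attr("dim") = xd;
  Rcpp::NumericVector mean_out(C), invstd_out(C), nrmean(C), nrvar(C);

  for (int c = 0; c < C; ++c) {
    double m, v;
    if (training) {
      double s = 0.0, ss = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* p = x.begin() + HW * (c + (R_xlen_t)C * n);
        for (R_xlen_t i = 0; i < HW; ++i) { s += p[i]; ss += p[i] * p[i]; }
      }
      m = s / M;
      v = ss / M - m * m;
      if (v < 0) v = 0;
      nrmean[c] = momentum * rmean[c] + (1.0 - momentum) * m;
      nrvar[c]  = momentum * rvar[c]  + (1.0 - momentum) * v;
    } else {
      m = rmean[c]; v = rvar[c];
      nrmean[c] = rmean[c]; nrvar[c] = rvar[c];
    }
    const double invstd = 1.0 / std::sqrt(v + eps);
    const double g = gamma[c], b = beta[c];
    mean_out[c] = m; invstd_out[c] = invstd;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + HW * (c + (R_xlen_t)C * n);
      double* q = y.begin() + HW * (c + (R_xlen_t)C * n);
      for (R_xlen_t i = 0; i < HW; ++i) {
        const double z = g * (p[i] - m) * invstd + b;
        q[i] = z > 0 ? z : 0.0;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("mean") = mean_out,
                            Rcpp::Named("invstd") = invstd_out,
                            Rcpp::Named("rmean") = nrmean,
                            Rcpp::Named("rvar") = nrvar);
}

// [[Rcpp::export(name = ".bn_relu_bwd")]]
Rcpp::List bn_relu_bwd(const Rcpp::NumericVector& x,
                       const Rcpp::NumericVector& y,
                       const Rcpp::NumericVector& dy_,
                       const Rcpp::NumericVector& gamma,
                       const Rcpp::NumericVector& mean,
                       const Rcpp::NumericVector& invstd) {
  Rcpp::IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const R_xlen_t HW = (R_xlen_t)H * W;
  const double M = (double)HW * N;

  Rcpp::NumericVector dx_(Rcpp::no_init(x.size()));
  dx_.attr("dim") = xd;
  Rcpp::NumericVector dgamma(C), dbeta(C);

  for (int c = 0; c < C; ++c) {
    const double m = mean[c], is = invstd[c], g = gamma[c];
    double s1 = 0.0, s2 = 0.0, dg = 0.0, db = 0.0;
    for (int n = 0; n < N; ++n) {
      const R_xlen_t off = HW * (c + (R_xlen_t)C * n);
      const double* px = x.begin() + off;
      const double* py = y.begin() + off;
      const double* pd = dy_.begin() + off;
      for (R_xlen_t i = 0; i < HW; ++i) {
        const double dr = py[i] > 0 ? pd[i] : 0.0;   // through ReLU
        const double xh = (px[i] - m) * is;
        dg += dr * xh; db += dr;
        s1 += dr * g; s2 += dr * g * xh;
      }
    }
    dgamma[c] = dg; dbeta[c] = db;
    for (int n = 0; n < N; ++n) {
      const R_xlen_t off = HW * (c + (R_xlen_t)C * n);
      const double* px = x.begin() + off;
      const double* py = y.begin() + off;
      const double* pd = dy_.begin() + off;
      double* q = dx_.begin() + off;
      for (R_xlen_t i = 0; i < HW; ++i) {
        const double dr = py[i] > 0 ? pd[i] : 0.0;
        const double xh = (px[i] - m) * is;
        q[i] = is * (dr * g - (s1 + xh * s2) / M);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx_,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// [[Rcpp::export(name = ".maxpool2_fwd")]]
Rcpp::List maxpool2_fwd(const Rcpp::NumericVector& x) {
  Rcpp::IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int H2 = H / 2, W2 = W / 2;
  const int S = C * N;
  Rcpp::NumericVector y(Rcpp::no_init((R_xlen_t)H2 * W2 * S));
  Rcpp::IntegerVector idx(Rcpp::no_init((R_xlen_t)H2 * W2 * S));
  y.attr("dim") = Rcpp::IntegerVector::create(H2, W2, C, N);
  idx.attr("dim") = y.attr("dim");
  for (int s = 0; s < S; ++s) {
    const double* p = x.begin() + (R_xlen_t)s * H * W;
    double* q = y.begin() + (R_xlen_t)s * H2 * W2;
    int* qi = idx.begin() + (R_xlen_t)s * H2 * W2;
    for (int j = 0; j < W2; ++j) {
      for (int i = 0; i < H2; ++i) {
        double best = -1e300; int barg = 0;
        for (int dw = 0; dw < 2; ++dw)
          for (int dh = 0; dh < 2; ++dh) {
            const double v = p[(2 * i + dh) + (R_xlen_t)H * (2 * j + dw)];
            if (v > best) { best = v; barg = dh + 2 * dw; }
          }
        q[i + (R_xlen_t)H2 * j] = best;
        qi[i + (R_xlen_t)H2 * j] = barg;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
Rcpp::NumericVector maxpool2_bwd(const Rcpp::IntegerVector& idx,
                                 const Rcpp::NumericVector& dy_,
                                 const int H, const int W) {
  Rcpp::IntegerVector yd = dy_.attr("dim");
  const int H2 = yd[0], W2 = yd[1], C = yd[2], N = yd[3];
  const int S = C * N;
  Rcpp::NumericVector dx_((R_xlen_t)H * W * S);  // zero-filled
  dx_.attr("dim") = Rcpp::IntegerVector::create(H, W, C, N);
  for (int s = 0; s < S; ++s) {
    const double* pd = dy_.begin() + (R_xlen_t)s * H2 * W2;
    const int* pi = idx.begin() + (R_xlen_t)s * H2 * W2;
    double* q = dx_.begin() + (R_xlen_t)s * H * W;
    for (int j = 0; j < W2; ++j)
      for (int i = 0; i < H2; ++i) {
        const int a = pi[i + (R_xlen_t)H2 * j];
        const int dh = a % 2, dw = a / 2;
        q[(2 * i + dh) + (R_xlen_t)H * (2 * j + dw)] +=
          pd[i + (R_xlen_t)H2 * j];
      }
  }
  return dx_;
}

// Bilinear x2 upsampling, half-pixel convention with edge clamping:
// output index i samples source coordinate i/2 - 1/4.
static void up_axis(int n_out, std::vector<int>& l0, std::vector<int>& l1,
                    std::vector<double>& f) {
  l0.resize(n_out); l1.resize(n_out); f.resize(n_out);
  const int n_in = n_out / 2;
  for (int i = 0; i < n_out; ++i) {
    double s = 0.5 * i - 0.25;
    int lo = (int)std::floor(s);
    double fr = s - lo;
    int hi = lo + 1;
    if (lo < 0) lo = 0;
    if (hi > n_in - 1) hi = n_in - 1;
    if (lo > n_in - 1) lo = n_in - 1;
    l0[i] = lo; l1[i] = hi; f[i] = fr;
  }
}

// [[Rcpp::export(name = ".upsample2_fwd")]]
Rcpp::NumericVector upsample2_fwd(const Rcpp::NumericVector& x) {
  Rcpp::IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int H2 = 2 * H, W2 = 2 * W, S = C * N;
  std::vector<int> hl0, hl1, wl0, wl1;
  std::vector<double> hf, wf;
  up_axis(H2, hl0, hl1, hf);
  up_axis(W2, wl0, wl1, wf);
  Rcpp::NumericVector y(Rcpp::no_init((R_xlen_t)H2 * W2 * S));
  y.attr("dim") = Rcpp::IntegerVector::create(H2, W2, C, N);
  mat A(H2, W);
  for (int s = 0; s < S; ++s) {
    const mat X(const_cast<double*>(x.begin()) + (R_xlen_t)s * H * W,
                H, W, false);
    mat Y(y.begin() + (R_xlen_t)s * H2 * W2, H2, W2, false);
    for (int i = 0; i < H2; ++i)
      A.row(i) = (1.0 - hf[i]) * X.row(hl0[i]) + hf[i] * X.row(hl1[i]);
    for (int j = 0; j < W2; ++j)
      Y.col(j) = (1.0 - wf[j]) * A.col(wl0[j]) + wf[j] * A.col(wl1[j]);
  }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bwd")]]
Rcpp::NumericVector upsample2_bwd(const Rcpp::NumericVector& dy_) {
  Rcpp::IntegerVector yd = dy_.attr("dim");
  const int H2 = yd[0], W2 = yd[1], C = yd[2], N = yd[3];
  const int H = H2 / 2, W = W2 / 2, S = C * N;
  std::vector<int> hl0, hl1, wl0, wl1;
  std::vector<double> hf, wf;
  up_axis(H2, hl0, hl1, hf);
  up_axis(W2, wl0, wl1, wf);
  Rcpp::NumericVector dx_((R_xlen_t)H * W * S);  // zero-filled
  dx_.attr("dim") = Rcpp::IntegerVector::create(H, W, C, N);
  mat A(H2, W);
  for (int s = 0; s < S; ++s) {
    const mat dY(const_cast<double*>(dy_.begin()) + (R_xlen_t)s * H2 * W2,
                 H2, W2, false);
    mat dX(dx_.begin() + (R_xlen_t)s * H * W, H, W, false);
    A.zeros();
    for (int j = 0; j < W2; ++j) {
      A.col(wl0[j]) += (1.0 - wf[j]) * dY.col(j);
      A.col(wl1[j]) += wf[j] * dY.col(j);
    }
    for (int i = 0; i < H2; ++i) {
      dX.row(hl0[i]) += (1.0 - hf[i]) * A.row(i);
      dX.row(hl1[i]) += hf[i] * A.row(i);
    }
  }
  return dx_;
}
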