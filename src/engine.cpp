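// Convolutional compute kernels: im2col/GEMM convolution with exact
// backward passes, batch normalisation, SiLU, 2x nearest upsampling and
// stride-1 max pooling. Feature maps are arma::cube(H, W, C); convolution
// weights are (c_out) x (k*k*c_in/groups) matrices whose rows follow the
// (kh, kw, c) patch layout produced by im2col below.
//
// im2col uses the pixel-major layout col(N, K) with N = Ho*Wo output pixels
// (rows) and K = k*k*cg patch entries (columns), which makes both the patch
// copies and the GEMM outputs contiguous; 1x1 stride-1 convolutions skip
// im2col entirely and alias the feature-map memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// col(pixel, dh + k*dw + k*k*c); pixel = ow*Ho + oh
static void im2col(const arma::cube& x, int cg0, int cg, int k, int s, int p,
                   arma::mat& col) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = out_size(H, k, s, p), Wo = out_size(W, k, s, p);
  col.zeros(Ho * (size_t)Wo, k * k * cg);
  for (int c = 0; c < cg; ++c) {
    const arma::mat& sl = x.slice(cg0 + c);
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        double* dst0 = col.colptr(dh + k * dw + k * k * c);
        for (int ow = 0; ow < Wo; ++ow) {
          const int iw = ow * s - p + dw;
          if (iw < 0 || iw >= W) continue;
          const double* src = sl.colptr(iw);
          double* dst = dst0 + (size_t)ow * Ho;
          // oh range with valid ih = oh*s - p + dh
          int oh_lo = 0, oh_hi = Ho - 1;
          while (oh_lo * s - p + dh < 0) ++oh_lo;
          while (oh_hi * s - p + dh >= H) --oh_hi;
          if (s == 1) {
            const int ih0 = oh_lo - p + dh;
            std::copy(src + ih0, src + ih0 + (oh_hi - oh_lo + 1),
                      dst + oh_lo);
          } else {
            for (int oh = oh_lo; oh <= oh_hi; ++oh) {
              dst[oh] = src[oh * s - p + dh];
            }
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& col, int H, int W, int cg0, int cg,
                   int k, int s, int p, arma::cube& dx) {
  const int Ho = out_size(H, k, s, p), Wo = out_size(W, k, s, p);
  for (int c = 0; c < cg; ++c) {
    arma::mat& sl = dx.slice(cg0 + c);
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const double* src0 = col.colptr(dh + k * dw + k * k * c);
        for (int ow = 0; ow < Wo; ++ow) {
          const int iw = ow * s - p + dw;
          if (iw < 0 || iw >= W) continue;
          double* dst = sl.colptr(iw);
          const double* src = src0 + (size_t)ow * Ho;
          int oh_lo = 0, oh_hi = Ho - 1;
          while (oh_lo * s - p + dh < 0) ++oh_lo;
          while (oh_hi * s - p + dh >= H) --oh_hi;
          for (int oh = oh_lo; oh <= oh_hi; ++oh) {
            dst[oh * s - p + dh] += src[oh];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cpp_conv_fwd(const arma::cube& x, const arma::mat& Wt,
                        const arma::vec& bias, int k, int s, int p,
                        int groups) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = Wt.n_rows;
  const int cg_in = Cin / groups, cg_out = Cout / groups;
  const int Ho = out_size(H, k, s, p), Wo = out_size(W, k, s, p);
  const size_t N = (size_t)Ho * Wo;
  arma::cube out(Ho, Wo, Cout);
  const bool one_by_one = (k == 1 && s == 1 && p == 0);
  arma::mat col;
  for (int g = 0; g < groups; ++g) {
    // out block as alias: N x cg_out over the group's slices
    arma::mat omat(out.slice_memptr(g * cg_out), N, cg_out, false, true);
    if (one_by_one) {
      const arma::mat xmat(const_cast<double*>(x.slice_memptr(g * cg_in)),
                           N, cg_in, false, true);
      omat = xmat * Wt.rows(g * cg_out, (g + 1) * cg_out - 1).t();
    } else {
      im2col(x, g * cg_in, cg_in, k, s, p, col);
      omat = col * Wt.rows(g * cg_out, (g + 1) * cg_out - 1).t();
    }
  }
  if (bias.n_elem == (unsigned)Cout) {
    for (int c = 0; c < Cout; ++c) out.slice(c) += bias(c);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(const arma::cube& x, const arma::mat& Wt,
                  const arma::cube& gout, int k, int s, int p, int groups,
                  bool need_dx, bool need_db) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = Wt.n_rows;
  const int cg_in = Cin / groups, cg_out = Cout / groups;
  const size_t N = (size_t)gout.n_rows * gout.n_cols;
  const bool one_by_one = (k == 1 && s == 1 && p == 0);
  arma::mat dW(arma::size(Wt));
  arma::cube dx;
  if (need_dx) dx = arma::cube(H, W, Cin, arma::fill::zeros);
  arma::mat col;
  for (int g = 0; g < groups; ++g) {
    const arma::mat gmat(const_cast<double*>(gout.slice_memptr(g * cg_out)),
                         N, cg_out, false, true);
    const arma::mat Wg = Wt.rows(g * cg_out, (g + 1) * cg_out - 1);
    if (one_by_one) {
      const arma::mat xmat(const_cast<double*>(x.slice_memptr(g * cg_in)),
                           N, cg_in, false, true);
      dW.rows(g * cg_out, (g + 1) * cg_out - 1) = gmat.t() * xmat;
      if (need_dx) {
        arma::mat dxmat(dx.slice_memptr(g * cg_in), N, cg_in, false, true);
        dxmat = gmat * Wg;
      }
    } else {
      im2col(x, g * cg_in, cg_in, k, s, p, col);
      dW.rows(g * cg_out, (g + 1) * cg_out - 1) = gmat.t() * col;
      if (need_dx) {
        arma::mat dcol = gmat * Wg;  // N x K
        col2im(dcol, H, W, g * cg_in, cg_in, k, s, p, dx);
      }
    }
  }
  arma::vec db;
  if (need_db) {
    db.set_size(Cout);
    for (int c = 0; c < Cout; ++c) db(c) = arma::accu(gout.slice(c));
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// ---- batch norm (single image: statistics over H x W per channel) -------

// [[Rcpp::export]]
List cpp_bn_fwd(const arma::cube& x, const arma::vec& gamma,
                const arma::vec& beta, double eps) {
  const int C = x.n_slices;
  arma::cube y(arma::size(x));
  arma::vec mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    const double m = arma::accu(x.slice(c)) / x.slice(c).n_elem;
    arma::mat d = x.slice(c) - m;
    const double v = arma::accu(arma::square(d)) / d.n_elem;
    mean(c) = m; var(c) = v;
    y.slice(c) = d * (gamma(c) / std::sqrt(v + eps)) + beta(c);
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
arma::cube cpp_bn_eval(const arma::cube& x, const arma::vec& gamma,
                       const arma::vec& beta, const arma::vec& rmean,
                       const arma::vec& rvar, double eps) {
  arma::cube y(arma::size(x));
  for (unsigned c = 0; c < x.n_slices; ++c) {
    y.slice(c) = (x.slice(c) - rmean(c)) * (gamma(c) / std::sqrt(rvar(c) + eps))
               + beta(c);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_bn_bwd(const arma::cube& x, const arma::vec& gamma,
                const arma::vec& mean, const arma::vec& var,
                const arma::cube& gout, double eps) {
  const int C = x.n_slices;
  const double N = x.n_rows * x.n_cols;
  arma::cube dx(arma::size(x));
  arma::vec dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double istd = 1.0 / std::sqrt(var(c) + eps);
    arma::mat xc = (x.slice(c) - mean(c)) * istd;  // xhat
    const arma::mat& go = gout.slice(c);
    const double sg = arma::accu(go);
    const double sgx = arma::accu(go % xc);
    dgamma(c) = sgx;
    dbeta(c) = sg;
    dx.slice(c) = (gamma(c) * istd / N) * (N * go - sg - xc * sgx);
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// ---- SiLU -----------------------------------------------------------------

// [[Rcpp::export]]
arma::cube cpp_silu_fwd(const arma::cube& x) {
  arma::cube y(arma::size(x));
  const double* px = x.memptr();
  double* py = y.memptr();
  const size_t n = x.n_elem;
  for (size_t i = 0; i < n; ++i) {
    py[i] = px[i] / (1.0 + std::exp(-px[i]));
  }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_silu_bwd(const arma::cube& x, const arma::cube& gout) {
  arma::cube dx(arma::size(x));
  const double* px = x.memptr();
  const double* pg = gout.memptr();
  double* pd = dx.memptr();
  const size_t n = x.n_elem;
  for (size_t i = 0; i < n; ++i) {
    const double sg = 1.0 / (1.0 + std::exp(-px[i]));
    pd[i] = pg[i] * sg * (1.0 + px[i] * (1.0 - sg));
  }
  return dx;
}

// ---- max pooling (stride 1, odd kernel, same padding) ---------------------

// [[Rcpp::export]]
List cpp_maxpool_fwd(const arma::cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int p = k / 2;
  arma::cube y(H, W, C);
  arma::icube arg(H, W, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& sl = x.slice(c);
    for (int ow = 0; ow < W; ++ow) {
      for (int oh = 0; oh < H; ++oh) {
        double best = -arma::datum::inf; long long bi = 0;
        for (int dw = -p; dw <= p; ++dw) {
          const int iw = ow + dw;
          if (iw < 0 || iw >= W) continue;
          for (int dh = -p; dh <= p; ++dh) {
            const int ih = oh + dh;
            if (ih < 0 || ih >= H) continue;
            const double v = sl(ih, iw);
            if (v > best) { best = v; bi = ih + (long long)H * iw; }
          }
        }
        y(oh, ow, c) = best;
        arg(oh, ow, c) = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bwd(const arma::icube& arg, const arma::cube& gout) {
  const int H = gout.n_rows, W = gout.n_cols, C = gout.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* pd = dx.slice(c).memptr();
    for (int ow = 0; ow < W; ++ow) {
      for (int oh = 0; oh < H; ++oh) {
        pd[arg(oh, ow, c)] += gout(oh, ow, c);
      }
    }
  }
  return dx;
}

// ---- 2x nearest upsampling ------------------------------------------------

// [[Rcpp::export]]
arma::cube cpp_upsample2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c) {
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const double v = x(h, w, c);
        y(2 * h, 2 * w, c) = v;
        y(2 * h + 1, 2 * w, c) = v;
        y(2 * h, 2 * w + 1, c) = v;
        y(2 * h + 1, 2 * w + 1, c) = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bwd(const arma::cube& gout) {
  const int H = gout.n_rows / 2, W = gout.n_cols / 2, C = gout.n_slices;
  arma::cube dx(H, W, C);
  for (int c = 0; c < C; ++c) {
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        dx(h, w, c) = gout(2 * h, 2 * w, c) + gout(2 * h + 1, 2 * w, c)
                    + gout(2 * h, 2 * w + 1, c) + gout(2 * h + 1, 2 * w + 1, c);
      }
    }
  }
  return dx;
}

// ---- separable convolution (Gaussian smoothing; reflected edges) ----------

// [[Rcpp::export]]
arma::mat cpp_sepconv(const arma::mat& x, const arma::vec& kernel) {
  const int H = x.n_rows, W = x.n_cols;
  const int r = (kernel.n_elem - 1) / 2;
  arma::mat tmp(H, W), out(H, W);
  for (int w = 0; w < W; ++w) {            // vertical pass
    for (int h = 0; h < H; ++h) {
      double acc = 0;
      for (int d = -r; d <= r; ++d) {
        int ih = h + d;
        if (ih < 0) ih = -ih - 1;
        if (ih >= H) ih = 2 * H - ih - 1;
        acc += kernel(d + r) * x(ih, w);
      }
      tmp(h, w) = acc;
    }
  }
  for (int w = 0; w < W; ++w) {            // horizontal pass
    for (int h = 0; h < H; ++h) {
      double acc = 0;
      for (int d = -r; d <= r; ++d) {
        int iw = w + d;
        if (iw < 0) iw = -iw - 1;
        if (iw >= W) iw = 2 * W - iw - 1;
        acc += kernel(d + r) * tmp(h, iw);
      }
      out(h, w) = acc;
    }
  }
  return out;
}
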