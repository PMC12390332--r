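// Single-precision training fast path. The layer graph is executed entirely
// in C++ on float tensors: one call runs the forward pass (keeping every
// per-node cache in an external-pointer state), a second call runs the
// backward pass from the loss gradients and returns parameter gradients.
// Layouts mirror the double-precision kernels in engine.cpp exactly; the
// double path remains the numerical reference the tests compare against.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

enum OpCode { OP_INPUT = 0, OP_CONV = 1, OP_MAXPOOL = 2, OP_UPSAMPLE = 3,
              OP_CONCAT = 4, OP_ADD = 5, OP_SLICE = 6 };

struct NodeDesc {
  int op, c_out, k, s, p, groups, bn, act, bias, take;
  std::vector<int> from;  // 1-based node ids
};

struct NodeParams {
  arma::fmat W;
  arma::fvec b, gamma, beta;
  bool has_b = false, has_bn = false;
};

struct EngineState {
  std::vector<NodeDesc> nodes;
  std::vector<NodeParams> params;
  std::vector<arma::fcube> acts, zs, pres;
  std::vector<std::vector<arma::fmat>> cols;
  std::vector<arma::icube> args;
  std::vector<arma::fvec> means, vars;
  std::vector<int> out_ids;  // 1-based
};

const float BN_EPS_F = 1e-5f;

inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

void f_im2col(const arma::fcube& x, int cg0, int cg, int k, int s, int p,
              arma::fmat& col) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = out_size(H, k, s, p), Wo = out_size(W, k, s, p);
  col.zeros(Ho * (size_t)Wo, k * k * cg);
  for (int c = 0; c < cg; ++c) {
    const arma::fmat& sl = x.slice(cg0 + c);
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        float* dst0 = col.colptr(dh + k * dw + k * k * c);
        for (int ow = 0; ow < Wo; ++ow) {
          const int iw = ow * s - p + dw;
          if (iw < 0 || iw >= W) continue;
          const float* src = sl.colptr(iw);
          float* dst = dst0 + (size_t)ow * Ho;
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

void f_col2im(const arma::fmat& col, int H, int W, int cg0, int cg, int k,
              int s, int p, arma::fcube& dx) {
  const int Ho = out_size(H, k, s, p), Wo = out_size(W, k, s, p);
  for (int c = 0; c < cg; ++c) {
    arma::fmat& sl = dx.slice(cg0 + c);
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const float* src0 = col.colptr(dh + k * dw + k * k * c);
        for (int ow = 0; ow < Wo; ++ow) {
          const int iw = ow * s - p + dw;
          if (iw < 0 || iw >= W) continue;
          float* dst = sl.colptr(iw);
          const float* src = src0 + (size_t)ow * Ho;
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

arma::fcube conv_fwd(const arma::fcube& x, const NodeDesc& nd,
                     const NodeParams& np,
                     std::vector<arma::fmat>* cache_cols) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = np.W.n_rows;
  const int cg_in = Cin / nd.groups, cg_out = Cout / nd.groups;
  const int Ho = out_size(H, nd.k, nd.s, nd.p);
  const int Wo = out_size(W, nd.k, nd.s, nd.p);
  const size_t N = (size_t)Ho * Wo;
  arma::fcube out(Ho, Wo, Cout);
  const bool obo = (nd.k == 1 && nd.s == 1 && nd.p == 0);
  arma::fmat col;
  for (int g = 0; g < nd.groups; ++g) {
    arma::fmat omat(out.slice_memptr(g * cg_out), N, cg_out, false, true);
    if (obo) {
      const arma::fmat xmat(const_cast<float*>(x.slice_memptr(g * cg_in)),
                            N, cg_in, false, true);
      omat = xmat * np.W.rows(g * cg_out, (g + 1) * cg_out - 1).t();
    } else {
      f_im2col(x, g * cg_in, cg_in, nd.k, nd.s, nd.p, col);
      omat = col * np.W.rows(g * cg_out, (g + 1) * cg_out - 1).t();
      if (cache_cols) cache_cols->push_back(std::move(col));
    }
  }
  if (np.has_b) {
    for (int c = 0; c < Cout; ++c) out.slice(c) += np.b(c);
  }
  return out;
}

void conv_bwd(const arma::fcube& x, const NodeDesc& nd, const NodeParams& np,
              const arma::fcube& gout, bool need_dx, arma::fmat& dW,
              arma::fvec& db, arma::fcube& dx,
              const std::vector<arma::fmat>* cached) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = np.W.n_rows;
  const int cg_in = Cin / nd.groups, cg_out = Cout / nd.groups;
  const size_t N = (size_t)gout.n_rows * gout.n_cols;
  const bool obo = (nd.k == 1 && nd.s == 1 && nd.p == 0);
  dW.set_size(arma::size(np.W));
  if (need_dx) dx.zeros(H, W, Cin);
  arma::fmat col;
  for (int g = 0; g < nd.groups; ++g) {
    const arma::fmat gmat(const_cast<float*>(gout.slice_memptr(g * cg_out)),
                          N, cg_out, false, true);
    const arma::fmat Wg = np.W.rows(g * cg_out, (g + 1) * cg_out - 1);
    if (obo) {
      const arma::fmat xmat(const_cast<float*>(x.slice_memptr(g * cg_in)),
                            N, cg_in, false, true);
      dW.rows(g * cg_out, (g + 1) * cg_out - 1) = gmat.t() * xmat;
      if (need_dx) {
        arma::fmat dxmat(dx.slice_memptr(g * cg_in), N, cg_in, false, true);
        dxmat = gmat * Wg;
      }
    } else {
      const arma::fmat* cp;
      if (cached) {
        cp = &(*cached)[g];
      } else {
        f_im2col(x, g * cg_in, cg_in, nd.k, nd.s, nd.p, col);
        cp = &col;
      }
      dW.rows(g * cg_out, (g + 1) * cg_out - 1) = gmat.t() * (*cp);
      if (need_dx) {
        arma::fmat dcol = gmat * Wg;
        f_col2im(dcol, H, W, g * cg_in, cg_in, nd.k, nd.s, nd.p, dx);
      }
    }
  }
  if (nd.bias) {
    db.set_size(Cout);
    for (int c = 0; c < Cout; ++c) db(c) = arma::accu(gout.slice(c));
  }
}

void silu_inplace_fwd(const arma::fcube& pre, arma::fcube& out) {
  out.set_size(arma::size(pre));
  const float* px = pre.memptr();
  float* py = out.memptr();
  const size_t n = pre.n_elem;
  for (size_t i = 0; i < n; ++i) {
    py[i] = px[i] / (1.0f + std::exp(-px[i]));
  }
}

arma::fcube cube_from_sexp(SEXP s) {
  NumericVector v(s);
  IntegerVector d = v.attr("dim");
  arma::fcube c(d[0], d[1], d[2]);
  const double* p = v.begin();
  float* q = c.memptr();
  for (size_t i = 0; i < c.n_elem; ++i) q[i] = (float)p[i];
  return c;
}

SEXP cube_to_sexp(const arma::fcube& c) {
  NumericVector v(c.n_elem);
  const float* q = c.memptr();
  for (size_t i = 0; i < c.n_elem; ++i) v[i] = q[i];
  v.attr("dim") = IntegerVector::create(c.n_rows, c.n_cols, c.n_slices);
  return v;
}

arma::fmat mat_from_sexp(SEXP s) {
  NumericMatrix m(s);
  arma::fmat f(m.nrow(), m.ncol());
  const double* p = m.begin();
  float* q = f.memptr();
  for (size_t i = 0; i < f.n_elem; ++i) q[i] = (float)p[i];
  return f;
}

arma::fvec vec_from_sexp(SEXP s) {
  NumericVector v(s);
  arma::fvec f(v.size());
  for (int i = 0; i < v.size(); ++i) f(i) = (float)v[i];
  return f;
}

}  // namespace

// desc: list per node with integer fields; params: list per node (or NULL)
// [[Rcpp::export]]
List cpp32_forward(List desc, List params, NumericVector x_, IntegerVector out_ids) {
  XPtr<EngineState> st(new EngineState(), true);
  const int n = desc.size();
  st->nodes.resize(n);
  st->params.resize(n);
  st->acts.resize(n);
  st->cols.resize(n);
  st->zs.resize(n);
  st->pres.resize(n);
  st->args.resize(n);
  st->means.resize(n);
  st->vars.resize(n);
  st->out_ids = std::vector<int>(out_ids.begin(), out_ids.end());

  for (int i = 0; i < n; ++i) {
    List d = desc[i];
    NodeDesc& nd = st->nodes[i];
    nd.op = as<int>(d["op"]);
    nd.c_out = as<int>(d["c_out"]);
    nd.k = as<int>(d["k"]); nd.s = as<int>(d["s"]); nd.p = as<int>(d["p"]);
    nd.groups = as<int>(d["groups"]);
    nd.bn = as<int>(d["bn"]); nd.act = as<int>(d["act"]);
    nd.bias = as<int>(d["bias"]); nd.take = as<int>(d["take"]);
    IntegerVector fr = d["from"];
    nd.from = std::vector<int>(fr.begin(), fr.end());
    if (nd.op == OP_CONV) {
      List p = params[i];
      NodeParams& np = st->params[i];
      np.W = mat_from_sexp(p["W"]);
      if (p.containsElementNamed("b") && !Rf_isNull(p["b"])) {
        np.b = vec_from_sexp(p["b"]); np.has_b = true;
      }
      if (nd.bn) {
        np.gamma = vec_from_sexp(p["gamma"]);
        np.beta = vec_from_sexp(p["beta"]);
        np.has_bn = true;
      }
    }
  }

  // forward
  st->acts[0] = cube_from_sexp(x_);
  for (int i = 1; i < n; ++i) {
    const NodeDesc& nd = st->nodes[i];
    switch (nd.op) {
      case OP_CONV: {
        const arma::fcube& xin = st->acts[nd.from[0] - 1];
        NodeParams& np = st->params[i];
        arma::fcube z = conv_fwd(xin, nd, np, &st->cols[i]);
        if (nd.bn) {
          const int C = z.n_slices;
          arma::fvec mean(C), var(C);
          arma::fcube y(arma::size(z));
          for (int c = 0; c < C; ++c) {
            const float m = arma::accu(z.slice(c)) / z.slice(c).n_elem;
            arma::fmat dmat = z.slice(c) - m;
            const float v = arma::accu(arma::square(dmat)) / dmat.n_elem;
            mean(c) = m; var(c) = v;
            y.slice(c) = dmat * (np.gamma(c) / std::sqrt(v + BN_EPS_F))
                       + np.beta(c);
          }
          st->zs[i] = std::move(z);
          st->means[i] = mean; st->vars[i] = var;
          if (nd.act == 1) {
            st->pres[i] = std::move(y);
            silu_inplace_fwd(st->pres[i], st->acts[i]);
          } else {
            st->acts[i] = std::move(y);
          }
        } else {
          if (nd.act == 1) {
            st->pres[i] = std::move(z);
            silu_inplace_fwd(st->pres[i], st->acts[i]);
          } else {
            st->acts[i] = std::move(z);
          }
        }
        break;
      }
      case OP_MAXPOOL: {
        const arma::fcube& xin = st->acts[nd.from[0] - 1];
        const int H = xin.n_rows, W = xin.n_cols, C = xin.n_slices;
        const int p = nd.k / 2;
        arma::fcube y(H, W, C);
        arma::icube arg(H, W, C);
        for (int c = 0; c < C; ++c) {
          const arma::fmat& sl = xin.slice(c);
          for (int ow = 0; ow < W; ++ow) {
            for (int oh = 0; oh < H; ++oh) {
              float best = -arma::datum::inf; long long bi = 0;
              for (int dw = -p; dw <= p; ++dw) {
                const int iw = ow + dw;
                if (iw < 0 || iw >= W) continue;
                for (int dh = -p; dh <= p; ++dh) {
                  const int ih = oh + dh;
                  if (ih < 0 || ih >= H) continue;
                  const float v = sl(ih, iw);
                  if (v > best) { best = v; bi = ih + (long long)H * iw; }
                }
              }
              y(oh, ow, c) = best;
              arg(oh, ow, c) = bi;
            }
          }
        }
        st->acts[i] = std::move(y);
        st->args[i] = std::move(arg);
        break;
      }
      case OP_UPSAMPLE: {
        const arma::fcube& xin = st->acts[nd.from[0] - 1];
        const int H = xin.n_rows, W = xin.n_cols, C = xin.n_slices;
        arma::fcube y(2 * H, 2 * W, C);
        for (int c = 0; c < C; ++c) {
          for (int w = 0; w < W; ++w) {
            for (int h = 0; h < H; ++h) {
              const float v = xin(h, w, c);
              y(2 * h, 2 * w, c) = v;
              y(2 * h + 1, 2 * w, c) = v;
              y(2 * h, 2 * w + 1, c) = v;
              y(2 * h + 1, 2 * w + 1, c) = v;
            }
          }
        }
        st->acts[i] = std::move(y);
        break;
      }
      case OP_CONCAT: {
        const arma::fcube& first = st->acts[nd.from[0] - 1];
        int ctot = 0;
        for (int f : nd.from) ctot += st->acts[f - 1].n_slices;
        arma::fcube y(first.n_rows, first.n_cols, ctot);
        int at = 0;
        for (int f : nd.from) {
          const arma::fcube& a = st->acts[f - 1];
          y.slices(at, at + a.n_slices - 1) = a;
          at += a.n_slices;
        }
        st->acts[i] = std::move(y);
        break;
      }
      case OP_ADD:
        st->acts[i] = st->acts[nd.from[0] - 1] + st->acts[nd.from[1] - 1];
        break;
      case OP_SLICE:
        st->acts[i] = st->acts[nd.from[0] - 1].slices(0, nd.take - 1);
        break;
      default:
        stop("unknown op code");
    }
  }

  List outs(st->out_ids.size());
  for (size_t j = 0; j < st->out_ids.size(); ++j) {
    outs[j] = cube_to_sexp(st->acts[st->out_ids[j] - 1]);
  }
  List bn_mean, bn_var;
  for (int i = 0; i < n; ++i) {
    if (st->nodes[i].op == OP_CONV && st->nodes[i].bn) {
      bn_mean.push_back(NumericVector(st->means[i].begin(), st->means[i].end()));
      bn_var.push_back(NumericVector(st->vars[i].begin(), st->vars[i].end()));
    }
  }
  return List::create(_["outs"] = outs, _["state"] = st,
                      _["bn_mean"] = bn_mean, _["bn_var"] = bn_var);
}

// [[Rcpp::export]]
List cpp32_backward(SEXP state_, List gout) {
  XPtr<EngineState> st(state_);
  const int n = st->nodes.size();
  std::vector<arma::fcube> gacc(n);
  std::vector<bool> has_g(n, false);
  for (size_t j = 0; j < st->out_ids.size(); ++j) {
    const int i = st->out_ids[j] - 1;
    arma::fcube g = cube_from_sexp(gout[j]);
    if (has_g[i]) gacc[i] += g; else { gacc[i] = std::move(g); has_g[i] = true; }
  }
  List grads(n);
  auto push = [&](int to, arma::fcube&& g) {
    if (has_g[to]) gacc[to] += g;
    else { gacc[to] = std::move(g); has_g[to] = true; }
  };
  for (int i = n - 1; i >= 1; --i) {
    if (!has_g[i]) continue;
    const NodeDesc& nd = st->nodes[i];
    arma::fcube g = std::move(gacc[i]);
    has_g[i] = false;
    switch (nd.op) {
      case OP_CONV: {
        const NodeParams& np = st->params[i];
        if (nd.act == 1) {  // SiLU backward using cached pre-activation
          const arma::fcube& pre = st->pres[i];
          const float* px = pre.memptr();
          float* pg = g.memptr();
          const size_t m = g.n_elem;
          for (size_t t = 0; t < m; ++t) {
            const float sg = 1.0f / (1.0f + std::exp(-px[t]));
            pg[t] = pg[t] * sg * (1.0f + px[t] * (1.0f - sg));
          }
        }
        List gr;
        if (nd.bn) {
          const arma::fcube& z = st->zs[i];
          const int C = z.n_slices;
          const float N = z.n_rows * z.n_cols;
          arma::fvec dgamma(C), dbeta(C);
          arma::fcube dz(arma::size(z));
          for (int c = 0; c < C; ++c) {
            const float istd = 1.0f / std::sqrt(st->vars[i](c) + BN_EPS_F);
            arma::fmat xc = (z.slice(c) - st->means[i](c)) * istd;
            const arma::fmat& go = g.slice(c);
            const float sg = arma::accu(go);
            const float sgx = arma::accu(go % xc);
            dgamma(c) = sgx; dbeta(c) = sg;
            dz.slice(c) = (np.gamma(c) * istd / N) * (N * go - sg - xc * sgx);
          }
          gr["dgamma"] = NumericVector(dgamma.begin(), dgamma.end());
          gr["dbeta"] = NumericVector(dbeta.begin(), dbeta.end());
          g = std::move(dz);
        }
        const bool need_dx = nd.from[0] != 1;
        arma::fmat dW; arma::fvec db; arma::fcube dx;
        conv_bwd(st->acts[nd.from[0] - 1], nd, np, g, need_dx, dW, db, dx,
                 st->cols[i].empty() ? nullptr : &st->cols[i]);
        {
          NumericMatrix dWr(dW.n_rows, dW.n_cols);
          std::copy(dW.begin(), dW.end(), dWr.begin());
          gr["dW"] = dWr;
        }
        if (nd.bias) gr["db"] = NumericVector(db.begin(), db.end());
        grads[i] = gr;
        if (need_dx) push(nd.from[0] - 1, std::move(dx));
        break;
      }
      case OP_MAXPOOL: {
        const arma::icube& arg = st->args[i];
        const int H = g.n_rows, W = g.n_cols, C = g.n_slices;
        arma::fcube dx(H, W, C, arma::fill::zeros);
        for (int c = 0; c < C; ++c) {
          float* pd = dx.slice(c).memptr();
          for (int ow = 0; ow < W; ++ow) {
            for (int oh = 0; oh < H; ++oh) {
              pd[arg(oh, ow, c)] += g(oh, ow, c);
            }
          }
        }
        push(nd.from[0] - 1, std::move(dx));
        break;
      }
      case OP_UPSAMPLE: {
        const int H = g.n_rows / 2, W = g.n_cols / 2, C = g.n_slices;
        arma::fcube dx(H, W, C);
        for (int c = 0; c < C; ++c) {
          for (int w = 0; w < W; ++w) {
            for (int h = 0; h < H; ++h) {
              dx(h, w, c) = g(2 * h, 2 * w, c) + g(2 * h + 1, 2 * w, c)
                          + g(2 * h, 2 * w + 1, c) + g(2 * h + 1, 2 * w + 1, c);
            }
          }
        }
        push(nd.from[0] - 1, std::move(dx));
        break;
      }
      case OP_CONCAT: {
        int at = 0;
        for (int f : nd.from) {
          const int cf = st->acts[f - 1].n_slices;
          push(f - 1, arma::fcube(g.slices(at, at + cf - 1)));
          at += cf;
        }
        break;
      }
      case OP_ADD: {
        push(nd.from[1] - 1, arma::fcube(g));
        push(nd.from[0] - 1, std::move(g));
        break;
      }
      case OP_SLICE: {
        const arma::fcube& src = st->acts[nd.from[0] - 1];
        arma::fcube full(src.n_rows, src.n_cols, src.n_slices,
                         arma::fill::zeros);
        full.slices(0, nd.take - 1) = g;
        push(nd.from[0] - 1, std::move(full));
        break;
      }
    }
  }
  return grads;
}
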