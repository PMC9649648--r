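// Small convolutional backbone for tile classification.
//
// Architecture: N blocks of [3x3 conv (pad 1) -> ReLU -> 2x2 maxpool],
// then global average pooling and a dense softmax head.  Training is
// plain minibatch Adam on cross-entropy.  All randomness (init, shuffling,
// augmentation) lives on the R side, so given identical inputs the C++
// path is bit-deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Net {
  std::vector<arma::mat> Wc;  // (9*Cin) x Cout per conv layer
  std::vector<arma::vec> bc;
  arma::mat Wfc;              // Clast x K
  arma::vec bfc;
};

Net unpack(const List& weights) {
  Net net;
  List conv = weights["conv"];
  for (int l = 0; l < conv.size(); ++l) {
    List layer = conv[l];
    net.Wc.push_back(as<arma::mat>(layer["W"]));
    net.bc.push_back(as<arma::vec>(layer["b"]));
  }
  List fc = weights["fc"];
  net.Wfc = as<arma::mat>(fc["W"]);
  net.bfc = as<arma::vec>(fc["b"]);
  return net;
}

List pack(const Net& net) {
  List conv(net.Wc.size());
  for (size_t l = 0; l < net.Wc.size(); ++l)
    conv[l] = List::create(_["W"] = net.Wc[l], _["b"] = net.bc[l]);
  return List::create(_["conv"] = conv,
                      _["fc"] = List::create(_["W"] = net.Wfc, _["b"] = net.bfc));
}

// im2col for 3x3, pad 1: rows = output pixels (column-major), cols = ki + 3*kj + 9*c.
arma::mat im2col3(const arma::cube& x) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat out(H * W, 9 * C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c) {
    for (int kj = -1; kj <= 1; ++kj) {
      for (int ki = -1; ki <= 1; ++ki) {
        arma::uword col = (ki + 1) + 3 * (kj + 1) + 9 * c;
        arma::mat shifted(H, W, arma::fill::zeros);
        int i0 = std::max(0, -ki), i1 = std::min<int>(H, H - ki);
        int j0 = std::max(0, -kj), j1 = std::min<int>(W, W - kj);
        shifted.submat(i0, j0, i1 - 1, j1 - 1) =
          x.slice(c).submat(i0 + ki, j0 + kj, i1 - 1 + ki, j1 - 1 + kj);
        out.col(col) = arma::vectorise(shifted);
      }
    }
  }
  return out;
}

arma::cube col2im3(const arma::mat& dcols, arma::uword H, arma::uword W, arma::uword C) {
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c) {
    for (int kj = -1; kj <= 1; ++kj) {
      for (int ki = -1; ki <= 1; ++ki) {
        arma::uword col = (ki + 1) + 3 * (kj + 1) + 9 * c;
        arma::mat d(const_cast<double*>(dcols.colptr(col)), H, W, false, true);
        int i0 = std::max(0, -ki), i1 = std::min<int>(H, H - ki);
        int j0 = std::max(0, -kj), j1 = std::min<int>(W, W - kj);
        dx.slice(c).submat(i0 + ki, j0 + kj, i1 - 1 + ki, j1 - 1 + kj) +=
          d.submat(i0, j0, i1 - 1, j1 - 1);
      }
    }
  }
  return dx;
}

// 2x2 maxpool, stride 2; records linear argmax indices per output cell.
void maxpool2(const arma::cube& a, arma::cube& out, arma::ucube& idx) {
  const arma::uword H = a.n_rows, W = a.n_cols, C = a.n_slices;
  out.set_size(H / 2, W / 2, C);
  idx.set_size(H / 2, W / 2, C);
  for (arma::uword c = 0; c < C; ++c) {
    for (arma::uword j = 0; j < W / 2; ++j) {
      for (arma::uword i = 0; i < H / 2; ++i) {
        arma::uword base_i = 2 * i, base_j = 2 * j, best = base_i + H * base_j;
        double bv = a(base_i, base_j, c);
        const arma::uword cand_i[3] = {base_i + 1, base_i, base_i + 1};
        const arma::uword cand_j[3] = {base_j, base_j + 1, base_j + 1};
        for (int k = 0; k < 3; ++k) {
          double v = a(cand_i[k], cand_j[k], c);
          if (v > bv) { bv = v; best = cand_i[k] + H * cand_j[k]; }
        }
        out(i, j, c) = bv;
        idx(i, j, c) = best;
      }
    }
  }
}

struct Cache {
  std::vector<arma::mat>  cols;    // im2col of each layer input
  std::vector<arma::cube> pre;     // pre-ReLU conv output
  std::vector<arma::cube> pooled;  // post-pool activation
  std::vector<arma::ucube> poolidx;
  arma::vec f;                     // global-pooled features
  arma::uvec fidx;                 // argmax per channel (max-pool head)
  arma::vec probs;
};

// head_pool: 0 = global average pooling, 1 = global max pooling (better
// suited to presence-of-one-object classes such as ballooning).
void forward_one(const Net& net, const arma::cube& x0, Cache& cc, int head_pool) {
  const size_t L = net.Wc.size();
  cc.cols.resize(L); cc.pre.resize(L); cc.pooled.resize(L); cc.poolidx.resize(L);
  arma::cube x = x0;
  for (size_t l = 0; l < L; ++l) {
    const arma::uword H = x.n_rows, W = x.n_cols;
    cc.cols[l] = im2col3(x);
    arma::mat z = cc.cols[l] * net.Wc[l];
    z.each_row() += net.bc[l].t();
    const arma::uword Cout = net.Wc[l].n_cols;
    arma::cube pre(z.memptr(), H, W, Cout);
    cc.pre[l] = pre;
    arma::cube act = arma::clamp(pre, 0.0, arma::datum::inf);
    maxpool2(act, cc.pooled[l], cc.poolidx[l]);
    x = cc.pooled[l];
  }
  const arma::cube& last = cc.pooled[L - 1];
  arma::uword C = last.n_slices;
  cc.f.set_size(C);
  cc.fidx.set_size(C);
  for (arma::uword c = 0; c < C; ++c) {
    if (head_pool == 1) {
      cc.fidx(c) = last.slice(c).index_max();
      cc.f(c) = last.slice(c)(cc.fidx(c));
    } else {
      cc.f(c) = arma::accu(last.slice(c)) / (last.n_rows * last.n_cols);
    }
  }
  arma::vec z = net.Wfc.t() * cc.f + net.bfc;
  z -= z.max();
  arma::vec e = arma::exp(z);
  cc.probs = e / arma::accu(e);
}

void backward_one(const Net& net, const arma::cube& x0, const Cache& cc, int y,
                  Net& grad, int head_pool) {
  const size_t L = net.Wc.size();
  arma::vec dz = cc.probs;
  dz(y) -= 1.0;                       // d CE / d logits
  grad.Wfc += cc.f * dz.t();
  grad.bfc += dz;
  arma::vec df = net.Wfc * dz;
  const arma::cube& last = cc.pooled[L - 1];
  arma::cube dpool(last.n_rows, last.n_cols, last.n_slices);
  if (head_pool == 1) {
    dpool.zeros();
    for (arma::uword c = 0; c < last.n_slices; ++c)
      dpool.slice(c)(cc.fidx(c)) = df(c);
  } else {
    double scale = 1.0 / (last.n_rows * last.n_cols);
    for (arma::uword c = 0; c < last.n_slices; ++c) dpool.slice(c).fill(df(c) * scale);
  }

  for (int l = L - 1; l >= 0; --l) {
    const arma::cube& pre = cc.pre[l];
    arma::cube dact(pre.n_rows, pre.n_cols, pre.n_slices, arma::fill::zeros);
    const arma::ucube& idx = cc.poolidx[l];
    for (arma::uword c = 0; c < dact.n_slices; ++c)
      for (arma::uword j = 0; j < idx.n_cols; ++j)
        for (arma::uword i = 0; i < idx.n_rows; ++i)
          dact.slice(c)(idx(i, j, c)) += dpool(i, j, c);
    // ReLU gate
    for (arma::uword k = 0; k < dact.n_elem; ++k)
      if (pre(k) <= 0) dact(k) = 0;
    arma::mat dpre_mat(dact.memptr(), pre.n_rows * pre.n_cols, pre.n_slices, false, true);
    grad.Wc[l] += cc.cols[l].t() * dpre_mat;
    grad.bc[l] += arma::sum(dpre_mat, 0).t();
    if (l > 0) {
      arma::mat dcols = dpre_mat * net.Wc[l].t();
      const arma::cube& below = cc.pooled[l - 1];
      dpool = col2im3(dcols, below.n_rows, below.n_cols, below.n_slices);
    }
  }
}

arma::cube slab(const double* X, arma::uword H, arma::uword W, arma::uword C, arma::uword n) {
  return arma::cube(const_cast<double*>(X) + n * H * W * C, H, W, C, false, true);
}

void adam_update(arma::mat& w, arma::mat& m, arma::mat& v, const arma::mat& g,
                 double lr, double b1, double b2, double eps, double t) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * arma::square(g);
  arma::mat mh = m / (1 - std::pow(b1, t));
  arma::mat vh = v / (1 - std::pow(b2, t));
  w -= lr * mh / (arma::sqrt(vh) + eps);
}

}  // namespace

// [[Rcpp::export]]
arma::mat cpp_cnn_predict(List weights, NumericVector X, int head_pool = 0) {
  Net net = unpack(weights);
  IntegerVector d = X.attr("dim");
  const arma::uword H = d[0], W = d[1], C = d[2], N = d[3];
  arma::mat probs(N, net.bfc.n_elem);
  Cache cc;
  for (arma::uword n = 0; n < N; ++n) {
    forward_one(net, slab(X.begin(), H, W, C, n), cc, head_pool);
    probs.row(n) = cc.probs.t();
  }
  return probs;
}

// [[Rcpp::export]]
List cpp_cnn_features(List weights, NumericVector X, int head_pool = 0) {
  // probs plus the final convolutional-stage activation (post-pool) per sample
  Net net = unpack(weights);
  IntegerVector d = X.attr("dim");
  const arma::uword H = d[0], W = d[1], C = d[2], N = d[3];
  Cache cc;
  forward_one(net, slab(X.begin(), H, W, C, 0), cc, head_pool);
  const arma::uword fh = cc.pooled.back().n_rows, fw = cc.pooled.back().n_cols,
                    fc = cc.pooled.back().n_slices;
  NumericVector feats(fh * fw * fc * N);
  feats.attr("dim") = IntegerVector::create(fh, fw, fc, N);
  arma::mat probs(N, net.bfc.n_elem);
  for (arma::uword n = 0; n < N; ++n) {
    if (n > 0) forward_one(net, slab(X.begin(), H, W, C, n), cc, head_pool);
    probs.row(n) = cc.probs.t();
    std::copy(cc.pooled.back().begin(), cc.pooled.back().end(),
              feats.begin() + n * fh * fw * fc);
  }
  return List::create(_["probs"] = probs, _["features"] = feats);
}

// [[Rcpp::export]]
List cpp_cnn_train_epoch(List weights, List mstate, List vstate, double t0,
                         NumericVector X, IntegerVector y, IntegerVector order,
                         int batch, double lr, double b1, double b2, double eps,
                         int head_pool = 0) {
  Net net = unpack(weights), m = unpack(mstate), v = unpack(vstate);
  IntegerVector d = X.attr("dim");
  const arma::uword H = d[0], W = d[1], C = d[2];
  const int nobs = order.size();
  double loss_sum = 0; int correct = 0;
  double t = t0;
  Cache cc;
  for (int start = 0; start < nobs; start += batch) {
    int end = std::min(nobs, start + batch);
    int B = end - start;
    Net grad;
    for (size_t l = 0; l < net.Wc.size(); ++l) {
      grad.Wc.push_back(arma::mat(net.Wc[l].n_rows, net.Wc[l].n_cols, arma::fill::zeros));
      grad.bc.push_back(arma::vec(net.bc[l].n_elem, arma::fill::zeros));
    }
    grad.Wfc = arma::mat(net.Wfc.n_rows, net.Wfc.n_cols, arma::fill::zeros);
    grad.bfc = arma::vec(net.bfc.n_elem, arma::fill::zeros);
    for (int s = start; s < end; ++s) {
      int n = order[s];
      arma::cube x = slab(X.begin(), H, W, C, n);
      forward_one(net, x, cc, head_pool);
      int yy = y[n];
      loss_sum += -std::log(std::max(cc.probs(yy), 1e-12));
      if (cc.probs.index_max() == (arma::uword)yy) ++correct;
      backward_one(net, x, cc, yy, grad, head_pool);
    }
    t += 1.0;
    for (size_t l = 0; l < net.Wc.size(); ++l) {
      grad.Wc[l] /= B; grad.bc[l] /= B;
      adam_update(net.Wc[l], m.Wc[l], v.Wc[l], grad.Wc[l], lr, b1, b2, eps, t);
      arma::mat bg(grad.bc[l]);
      arma::mat bm(m.bc[l].memptr(), m.bc[l].n_elem, 1, false, true);
      arma::mat bv(v.bc[l].memptr(), v.bc[l].n_elem, 1, false, true);
      arma::mat bw(net.bc[l].memptr(), net.bc[l].n_elem, 1, false, true);
      adam_update(bw, bm, bv, bg, lr, b1, b2, eps, t);
    }
    grad.Wfc /= B; grad.bfc /= B;
    adam_update(net.Wfc, m.Wfc, v.Wfc, grad.Wfc, lr, b1, b2, eps, t);
    arma::mat bg(grad.bfc);
    arma::mat bm(m.bfc.memptr(), m.bfc.n_elem, 1, false, true);
    arma::mat bv(v.bfc.memptr(), v.bfc.n_elem, 1, false, true);
    arma::mat bw(net.bfc.memptr(), net.bfc.n_elem, 1, false, true);
    adam_update(bw, bm, bv, bg, lr, b1, b2, eps, t);
  }
  return List::create(_["weights"] = pack(net), _["m"] = pack(m), _["v"] = pack(v),
                      _["t"] = t, _["loss"] = loss_sum / nobs,
                      _["acc"] = (double)correct / nobs);
}
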