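// Shared-trunk multitask convolutional classifier.
//
// VGG-style trunk: 3x3 same-padding convolutions (stride 1) grouped in
// blocks, ReLU, max-pooling between blocks. Each task head is a stack of
// fully connected layers with ReLU and inverted dropout on the hidden
// layers and a 2-class linear output. Training is plain mini-batch
// gradient descent on the weighted sum of per-head softmax cross-entropies.
//
// Determinism: weight init and epoch shuffles are produced in R; the only
// randomness here is dropout, driven by one xorshift stream per head seeded
// from the config, so a head's mask sequence does not depend on how many
// other heads exist (single-task and w_ipsi=0 multitask runs coincide
// step for step).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed)
      : s(seed * 2685821657736338717ULL + 1442695040888963407ULL) {
    if (s == 0) s = 0x9E3779B97F4A7C15ULL;
  }
  double unif() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return static_cast<double>(s >> 11) / 9007199254740992.0;
  }
};

// im2col for a 3x3 same-padding convolution: (9*C) x (H*W)
mat im2col3(const cube& A) {
  const uword H = A.n_rows, W = A.n_cols, C = A.n_slices;
  mat P(9 * C, H * W);
  mat pad(H + 2, W + 2);
  for (uword c = 0; c < C; ++c) {
    pad.zeros();
    pad.submat(1, 1, H, W) = A.slice(c);
    for (uword kx = 0; kx < 3; ++kx)
      for (uword ky = 0; ky < 3; ++ky)
        P.row(c * 9 + kx * 3 + ky) =
            vectorise(pad.submat(ky, kx, ky + H - 1, kx + W - 1)).t();
  }
  return P;
}

cube col2im3(const mat& dP, uword H, uword W, uword C) {
  cube dA(H, W, C);
  mat pad(H + 2, W + 2);
  for (uword c = 0; c < C; ++c) {
    pad.zeros();
    for (uword kx = 0; kx < 3; ++kx)
      for (uword ky = 0; ky < 3; ++ky)
        pad.submat(ky, kx, ky + H - 1, kx + W - 1) +=
            reshape(dP.row(c * 9 + kx * 3 + ky), H, W);
    dA.slice(c) = pad.submat(1, 1, H, W);
  }
  return dA;
}

struct Trunk {
  std::vector<mat> W;   // (Cout, 9*Cin) per conv layer
  std::vector<vec> b;
  ivec block_sizes;     // conv layers per block
  ivec pool_sizes;      // pool window/stride per block
};

struct Head {
  std::vector<mat> W;
  std::vector<vec> b;
};

struct TrunkCache {
  std::vector<mat> P;          // im2col input per conv layer
  std::vector<cube> act;       // post-ReLU output per conv layer
  std::vector<umat> pool_arg;  // argmax (linear index in slice) per block
  std::vector<uvec> pool_in;   // (H, W, C) entering each pool
};

cube conv_relu(const Trunk& tr, uword layer, const cube& A, mat* P_out) {
  const uword H = A.n_rows, W = A.n_cols;
  mat P = im2col3(A);
  mat Out = tr.W[layer] * P;
  Out.each_col() += tr.b[layer];
  const uword Cout = Out.n_rows;
  cube Z(H, W, Cout);
  for (uword co = 0; co < Cout; ++co)
    Z.slice(co) = reshape(Out.row(co).t(), H, W);
  Z.transform([](double v) { return v > 0 ? v : 0.0; });
  if (P_out) *P_out = std::move(P);
  return Z;
}

cube maxpool(const cube& A, uword k, umat* argmax) {
  const uword H = A.n_rows, W = A.n_cols, C = A.n_slices;
  const uword Ho = H / k, Wo = W / k;
  cube O(Ho, Wo, C);
  if (argmax) argmax->set_size(Ho * Wo, C);
  for (uword c = 0; c < C; ++c) {
    const mat& S = A.slice(c);
    for (uword ox = 0; ox < Wo; ++ox)
      for (uword oy = 0; oy < Ho; ++oy) {
        uword best = 0;
        double bv = -datum::inf;
        for (uword dx = 0; dx < k; ++dx)
          for (uword dy = 0; dy < k; ++dy) {
            const uword r = oy * k + dy, cc = ox * k + dx;
            const double v = S(r, cc);
            if (v > bv) { bv = v; best = r + H * cc; }
          }
        O(oy, ox, c) = bv;
        if (argmax) (*argmax)(oy + Ho * ox, c) = best;
      }
  }
  return O;
}

vec trunk_forward(const Trunk& tr, const mat& img, TrunkCache* cache) {
  cube cur(img.n_rows, img.n_cols, 1);
  cur.slice(0) = img;
  uword layer = 0;
  for (uword bi = 0; bi < tr.block_sizes.n_elem; ++bi) {
    for (sword j = 0; j < tr.block_sizes(bi); ++j, ++layer) {
      mat P;
      cube Z = conv_relu(tr, layer, cur, cache ? &P : nullptr);
      if (cache) {
        cache->P.push_back(std::move(P));
        cache->act.push_back(Z);
      }
      cur = std::move(Z);
    }
    const uword k = static_cast<uword>(tr.pool_sizes(bi));
    umat arg;
    if (cache)
      cache->pool_in.push_back(
          uvec{cur.n_rows, cur.n_cols, cur.n_slices});
    cur = maxpool(cur, k, cache ? &arg : nullptr);
    if (cache) cache->pool_arg.push_back(std::move(arg));
  }
  return vectorise(cur);
}

// accumulate gradients for one sample; dFlat is d(loss)/d(flattened output)
void trunk_backward(const Trunk& tr, const TrunkCache& cache,
                    const vec& dFlat, std::vector<mat>& dW,
                    std::vector<vec>& db) {
  const uword nblocks = tr.block_sizes.n_elem;
  // output dims of the last pool
  uvec in = cache.pool_in[nblocks - 1];
  uword k = static_cast<uword>(tr.pool_sizes(nblocks - 1));
  cube grad(in(0) / k, in(1) / k, in(2));
  std::copy(dFlat.begin(), dFlat.end(), grad.begin());

  uword layer = tr.W.size();
  for (sword bi = nblocks - 1; bi >= 0; --bi) {
    // un-pool
    in = cache.pool_in[bi];
    const umat& arg = cache.pool_arg[bi];
    cube gin(in(0), in(1), in(2), fill::zeros);
    const uword Ho = grad.n_rows, Wo = grad.n_cols;
    for (uword c = 0; c < in(2); ++c) {
      double* dst = gin.slice(c).memptr();
      const mat& G = grad.slice(c);
      for (uword ox = 0; ox < Wo; ++ox)
        for (uword oy = 0; oy < Ho; ++oy)
          dst[arg(oy + Ho * ox, c)] += G(oy, ox);
    }
    grad = std::move(gin);
    // conv layers of the block, reversed
    for (sword j = tr.block_sizes(bi) - 1; j >= 0; --j) {
      --layer;
      const cube& A = cache.act[layer];  // post-ReLU output of this layer
      // ReLU derivative
      for (uword e = 0; e < grad.n_elem; ++e)
        if (A(e) <= 0) grad(e) = 0;
      const uword H = grad.n_rows, W = grad.n_cols, Cout = grad.n_slices;
      mat dOut(Cout, H * W);
      for (uword co = 0; co < Cout; ++co)
        dOut.row(co) = vectorise(grad.slice(co)).t();
      dW[layer] += dOut * cache.P[layer].t();
      db[layer] += sum(dOut, 1);
      if (layer > 0) {
        mat dP = tr.W[layer].t() * dOut;
        const uword Cin = tr.W[layer].n_cols / 9;
        grad = col2im3(dP, H, W, Cin);
      }
    }
    if (layer == 0) break;
  }
}

struct HeadCache {
  std::vector<mat> act;    // input to each layer (act[0] = features)
  std::vector<mat> dmask;  // combined ReLU-derivative x dropout mask
};

mat head_forward(const Head& hd, const mat& F, double dropout, bool train,
                 XorShift* rng, HeadCache* cache) {
  mat cur = F;
  if (cache) cache->act.push_back(cur);
  const uword L = hd.W.size();
  for (uword l = 0; l < L; ++l) {
    mat Z = hd.W[l] * cur;
    Z.each_col() += hd.b[l];
    if (l + 1 < L) {
      mat D(Z.n_rows, Z.n_cols);
      const double scale = dropout > 0 ? 1.0 / (1.0 - dropout) : 1.0;
      for (uword e = 0; e < Z.n_elem; ++e) {
        double keep = 1.0;
        if (train && dropout > 0)
          keep = (rng->unif() >= dropout) ? scale : 0.0;
        D(e) = (Z(e) > 0 ? 1.0 : 0.0) * keep;
        Z(e) = (Z(e) > 0 ? Z(e) : 0.0) * keep;
      }
      if (cache) cache->dmask.push_back(std::move(D));
    }
    cur = std::move(Z);
    if (cache && l + 1 < L) cache->act.push_back(cur);
  }
  return cur;  // logits (2 x B)
}

// returns d(loss)/d(features); fills per-layer gradient accumulators
mat head_backward(const Head& hd, const HeadCache& cache, mat dZ,
                  std::vector<mat>& dW, std::vector<vec>& db) {
  const uword L = hd.W.size();
  for (sword l = L - 1; l >= 0; --l) {
    dW[l] += dZ * cache.act[l].t();
    db[l] += sum(dZ, 1);
    mat dA = hd.W[l].t() * dZ;
    if (l > 0) dA %= cache.dmask[l - 1];
    dZ = std::move(dA);
  }
  return dZ;
}

mat softmax_cols(const mat& Z) {
  mat P = Z;
  P.each_row() -= max(P, 0);
  P = exp(P);
  P.each_row() /= sum(P, 0);
  return P;
}

Trunk parse_trunk(List trunk_W, List trunk_b, const ivec& block_sizes,
                  const ivec& pool_sizes) {
  Trunk tr;
  tr.block_sizes = block_sizes;
  tr.pool_sizes = pool_sizes;
  for (int i = 0; i < trunk_W.size(); ++i) {
    tr.W.push_back(Rcpp::as<mat>(trunk_W[i]));
    tr.b.push_back(Rcpp::as<vec>(trunk_b[i]));
  }
  return tr;
}

std::vector<Head> parse_heads(List heads) {
  std::vector<Head> out;
  for (int h = 0; h < heads.size(); ++h) {
    List hl = heads[h];
    List Wl = hl["W"], bl = hl["b"];
    Head hd;
    for (int l = 0; l < Wl.size(); ++l) {
      hd.W.push_back(Rcpp::as<mat>(Wl[l]));
      hd.b.push_back(Rcpp::as<vec>(bl[l]));
    }
    out.push_back(std::move(hd));
  }
  return out;
}

List pack_weights(const Trunk& tr, const std::vector<Head>& heads) {
  List tw(tr.W.size()), tb(tr.b.size());
  for (size_t i = 0; i < tr.W.size(); ++i) {
    tw[i] = tr.W[i];
    tb[i] = tr.b[i];
  }
  List hs(heads.size());
  for (size_t h = 0; h < heads.size(); ++h) {
    List Wl(heads[h].W.size()), bl(heads[h].b.size());
    for (size_t l = 0; l < heads[h].W.size(); ++l) {
      Wl[l] = heads[h].W[l];
      bl[l] = heads[h].b[l];
    }
    hs[h] = List::create(Rcpp::Named("W") = Wl, Rcpp::Named("b") = bl);
  }
  return List::create(Rcpp::Named("trunk_W") = tw,
                      Rcpp::Named("trunk_b") = tb,
                      Rcpp::Named("heads") = hs);
}

// forward pass without dropout; returns per-head class-probability matrices
std::vector<mat> predict_all(const Trunk& tr, const std::vector<Head>& heads,
                             const cube& X) {
  const uword N = X.n_slices;
  std::vector<mat> logits;
  mat F;
  for (uword i = 0; i < N; ++i) {
    vec f = trunk_forward(tr, X.slice(i), nullptr);
    if (i == 0) F.set_size(f.n_elem, N);
    F.col(i) = f;
  }
  std::vector<mat> probs;
  for (const Head& hd : heads)
    probs.push_back(softmax_cols(head_forward(hd, F, 0.0, false, nullptr,
                                              nullptr)));
  return probs;
}

}  // namespace

// [[Rcpp::export]]
List cpp_train(const arma::cube& Xtr, const arma::imat& Ytr,
               const arma::cube& Xte, const arma::imat& Yte,
               List trunk_W, List trunk_b,
               const arma::ivec& block_sizes, const arma::ivec& pool_sizes,
               List heads_in, const arma::vec& head_weights, double dropout,
               double lr, int epochs, int batch_size, double dropout_seed,
               const arma::imat& shuffle) {
  Trunk tr = parse_trunk(trunk_W, trunk_b, block_sizes, pool_sizes);
  std::vector<Head> heads = parse_heads(heads_in);
  const uword nheads = heads.size();
  const uword Ntr = Xtr.n_slices, Nte = Xte.n_slices;
  if (Ytr.n_rows < nheads || Yte.n_rows < nheads)
    Rcpp::stop("label matrix has fewer rows than heads");

  std::vector<XorShift> rng;
  for (uword h = 0; h < nheads; ++h)
    rng.emplace_back(static_cast<uint64_t>(dropout_seed) + 9973ULL * (h + 1));

  mat history(epochs, 1 + 2 * nheads);

  for (int e = 0; e < epochs; ++e) {
    double loss_sum = 0.0;
    vec correct_tr(nheads, fill::zeros);

    for (uword start = 0; start < Ntr; start += batch_size) {
      const uword end = std::min<uword>(start + batch_size, Ntr) - 1;
      const uword B = end - start + 1;
      // trunk forward
      std::vector<TrunkCache> caches(B);
      mat F;
      uvec idx(B);
      for (uword i = 0; i < B; ++i) {
        idx(i) = static_cast<uword>(shuffle(e, start + i));
        vec f = trunk_forward(tr, Xtr.slice(idx(i)), &caches[i]);
        if (i == 0) F.set_size(f.n_elem, B);
        F.col(i) = f;
      }
      // heads forward/backward
      mat dF(F.n_rows, B, fill::zeros);
      std::vector<std::vector<mat>> hdW(nheads);
      std::vector<std::vector<vec>> hdb(nheads);
      double batch_loss = 0.0;
      for (uword h = 0; h < nheads; ++h) {
        HeadCache hc;
        mat logits = head_forward(heads[h], F, dropout, true, &rng[h], &hc);
        mat P = softmax_cols(logits);
        mat G = P;
        double ce = 0.0;
        for (uword i = 0; i < B; ++i) {
          const uword y = static_cast<uword>(Ytr(h, idx(i)));
          ce -= std::log(std::max(P(y, i), 1e-300));
          G(y, i) -= 1.0;
          if ((P(0, i) > P(1, i) ? 0u : 1u) == y) correct_tr(h) += 1.0;
        }
        ce /= B;
        batch_loss += head_weights(h) * ce;
        for (auto& Wl : heads[h].W) hdW[h].push_back(mat(size(Wl), fill::zeros));
        for (auto& bl : heads[h].b) hdb[h].push_back(vec(size(bl), fill::zeros));
        G *= head_weights(h) / static_cast<double>(B);
        dF += head_backward(heads[h], hc, G, hdW[h], hdb[h]);
      }
      if (!std::isfinite(batch_loss))
        Rcpp::stop("non-finite training loss at epoch %d; reduce the learning rate", e + 1);
      loss_sum += batch_loss * B;
      // trunk backward
      std::vector<mat> tdW;
      std::vector<vec> tdb;
      for (auto& Wl : tr.W) tdW.push_back(mat(size(Wl), fill::zeros));
      for (auto& bl : tr.b) tdb.push_back(vec(size(bl), fill::zeros));
      for (uword i = 0; i < B; ++i)
        trunk_backward(tr, caches[i], dF.col(i), tdW, tdb);
      // SGD updates
      for (size_t l = 0; l < tr.W.size(); ++l) {
        tr.W[l] -= lr * tdW[l];
        tr.b[l] -= lr * tdb[l];
      }
      for (uword h = 0; h < nheads; ++h)
        for (size_t l = 0; l < heads[h].W.size(); ++l) {
          heads[h].W[l] -= lr * hdW[h][l];
          heads[h].b[l] -= lr * hdb[h][l];
        }
    }

    history(e, 0) = loss_sum / Ntr;
    for (uword h = 0; h < nheads; ++h)
      history(e, 1 + h) = correct_tr(h) / Ntr;
    // test accuracy per head
    std::vector<mat> probs = predict_all(tr, heads, Xte);
    for (uword h = 0; h < nheads; ++h) {
      double corr = 0;
      for (uword i = 0; i < Nte; ++i) {
        const uword pred = probs[h](0, i) > probs[h](1, i) ? 0u : 1u;
        if (pred == static_cast<uword>(Yte(h, i))) corr += 1.0;
      }
      history(e, 1 + nheads + h) = corr / Nte;
    }
    Rcpp::checkUserInterrupt();
  }

  List out = pack_weights(tr, heads);
  out["history"] = history;
  return out;
}

// [[Rcpp::export]]
List cpp_predict(const arma::cube& X, List trunk_W, List trunk_b,
                 const arma::ivec& block_sizes, const arma::ivec& pool_sizes,
                 List heads_in) {
  Trunk tr = parse_trunk(trunk_W, trunk_b, block_sizes, pool_sizes);
  std::vector<Head> heads = parse_heads(heads_in);
  std::vector<mat> probs = predict_all(tr, heads, X);
  List out(probs.size());
  for (size_t h = 0; h < probs.size(); ++h) out[h] = mat(probs[h].t());
  return out;
}
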