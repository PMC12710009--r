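// Point-cloud network engine: shared per-point MLPs with batch
// normalization and LeakyReLU, symmetric pooling over points, task heads,
// and SGD-with-momentum training for single- and multi-task losses
// (Huber / cross-entropy / homoscedastic-uncertainty fusion).
//
// Templated on the floating type: float for training speed, double for
// numerically strict checks. All randomness (init, dropout) comes from R's
// RNG so set.seed() governs the engine too.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static double r_norm() { return R::norm_rand(); }
static double r_unif() { return R::unif_rand(); }

template <typename T>
struct Dense {
  Mat<T> W; Row<T> b;
  Mat<T> gW; Row<T> gb;
  Mat<T> vW; Row<T> vb;
  Mat<T> Xc[2];
  bool decay = true;

  void init(int in, int out) {
    double sd = std::sqrt(2.0 / in);
    W.set_size(in, out);
    for (uword i = 0; i < W.n_elem; ++i) W(i) = (T)(r_norm() * sd);
    b.zeros(out);
    gW.zeros(in, out); gb.zeros(out);
    vW.zeros(in, out); vb.zeros(out);
  }
  Mat<T> fwd(const Mat<T>& X, bool training, int slot) {
    if (training) Xc[slot] = X;
    Mat<T> Y = X * W;
    Y.each_row() += b;
    return Y;
  }
  Mat<T> bwd(const Mat<T>& dY, int slot) {
    gW += Xc[slot].t() * dY;
    gb += sum(dY, 0);
    return dY * W.t();
  }
  void step(T lr, T mom, T wd) {
    vW = mom * vW - lr * (gW + (decay ? wd : (T)0) * W);
    vb = mom * vb - lr * gb;
    W += vW; b += vb;
    gW.zeros(); gb.zeros();
  }
  size_t nparams() const { return W.n_elem + b.n_elem; }
};

template <typename T>
struct BatchNorm {
  // weights are shared across use slots; running statistics are kept per
  // slot so the multi-task trunk normalizes its mean- and max-pooled
  // paths with path-specific statistics
  Row<T> gamma, beta, rmean[2], rvar[2];
  Row<T> ggamma, gbeta, vgamma, vbeta;
  Mat<T> xhat[2]; Row<T> istd[2];
  T eps = (T)1e-5, momentum = (T)0.1;

  void init(int c) {
    gamma.ones(c); beta.zeros(c);
    for (int s = 0; s < 2; ++s) { rmean[s].zeros(c); rvar[s].ones(c); }
    ggamma.zeros(c); gbeta.zeros(c);
    vgamma.zeros(c); vbeta.zeros(c);
  }
  Mat<T> fwd(const Mat<T>& X, bool training, int slot) {
    if (training) {
      Row<T> mu = mean(X, 0);
      Mat<T> Xc = X.each_row() - mu;
      Row<T> var = mean(square(Xc), 0);
      rmean[slot] = ((T)1 - momentum) * rmean[slot] + momentum * mu;
      rvar[slot] = ((T)1 - momentum) * rvar[slot] + momentum * var;
      istd[slot] = (T)1 / sqrt(var + eps);
      xhat[slot] = Xc.each_row() % istd[slot];
      Mat<T> Y = xhat[slot].each_row() % gamma;
      Y.each_row() += beta;
      return Y;
    }
    Mat<T> Y = X.each_row() - rmean[slot];
    Y.each_row() %= (T)1 / sqrt(rvar[slot] + eps);
    Y.each_row() %= gamma;
    Y.each_row() += beta;
    return Y;
  }
  Mat<T> bwd(const Mat<T>& dY, int slot) {
    ggamma += sum(dY % xhat[slot], 0);
    gbeta += sum(dY, 0);
    Mat<T> dxhat = dY.each_row() % gamma;
    T N = (T)dY.n_rows;
    Row<T> s1 = sum(dxhat, 0);
    Row<T> s2 = sum(dxhat % xhat[slot], 0);
    Mat<T> dX = dxhat * N;
    dX.each_row() -= s1;
    dX -= xhat[slot].each_row() % s2;
    dX.each_row() %= istd[slot] / N;
    return dX;
  }
  void step(T lr, T mom) {
    vgamma = mom * vgamma - lr * ggamma;
    vbeta = mom * vbeta - lr * gbeta;
    gamma += vgamma; beta += vbeta;
    ggamma.zeros(); gbeta.zeros();
  }
  size_t nparams() const { return gamma.n_elem + beta.n_elem; }
};

template <typename T>
struct LeakyReLU {
  T slope;
  Mat<T> mask[2];
  Mat<T> fwd(const Mat<T>& X, bool training, int slot) {
    Mat<T> m = conv_to<Mat<T>>::from(X > (T)0);
    m += slope * ((T)1 - m);
    if (training) mask[slot] = m;
    return X % m;
  }
  Mat<T> bwd(const Mat<T>& dY, int slot) { return dY % mask[slot]; }
};

// CBR: pointwise dense + BN + LeakyReLU
template <typename T>
struct CBR {
  Dense<T> fc; BatchNorm<T> bn; LeakyReLU<T> act;
  void init(int in, int out, T slope) {
    fc.init(in, out); bn.init(out); act.slope = slope;
  }
  Mat<T> fwd(const Mat<T>& X, bool training, int slot) {
    return act.fwd(bn.fwd(fc.fwd(X, training, slot), training, slot), training, slot);
  }
  Mat<T> bwd(const Mat<T>& dY, int slot) {
    return fc.bwd(bn.bwd(act.bwd(dY, slot), slot), slot);
  }
  void step(T lr, T mom, T wd) { fc.step(lr, mom, wd); bn.step(lr, mom); }
  size_t nparams() const { return fc.nparams() + bn.nparams(); }
};

// Res-CBR: dimension-raising dense + BN + LeakyReLU, dimension-reducing
// dense + BN, residual sum (linear projection when widths differ), final
// LeakyReLU.
template <typename T>
struct ResCBR {
  Dense<T> up, down, proj;
  BatchNorm<T> bn1, bn2;
  LeakyReLU<T> act1, actout;
  bool has_proj;
  void init(int in, int out, int k, T slope) {
    int mid = in * k;
    up.init(in, mid); bn1.init(mid);
    down.init(mid, out); bn2.init(out);
    act1.slope = slope; actout.slope = slope;
    has_proj = (in != out);
    if (has_proj) proj.init(in, out);
  }
  Mat<T> fwd(const Mat<T>& X, bool training, int slot) {
    Mat<T> h = act1.fwd(bn1.fwd(up.fwd(X, training, slot), training, slot),
                        training, slot);
    Mat<T> y = bn2.fwd(down.fwd(h, training, slot), training, slot);
    if (has_proj) y += proj.fwd(X, training, slot);
    else y += X;
    return actout.fwd(y, training, slot);
  }
  Mat<T> bwd(const Mat<T>& dY, int slot) {
    Mat<T> dy = actout.bwd(dY, slot);
    Mat<T> dh = down.bwd(bn2.bwd(dy, slot), slot);
    Mat<T> dX = up.bwd(bn1.bwd(act1.bwd(dh, slot), slot), slot);
    if (has_proj) dX += proj.bwd(dy, slot);
    else dX += dy;
    return dX;
  }
  void step(T lr, T mom, T wd) {
    up.step(lr, mom, wd); down.step(lr, mom, wd);
    bn1.step(lr, mom); bn2.step(lr, mom);
    if (has_proj) proj.step(lr, mom, wd);
  }
  size_t nparams() const {
    size_t n = up.nparams() + down.nparams() + bn1.nparams() + bn2.nparams();
    if (has_proj) n += proj.nparams();
    return n;
  }
};

template <typename T>
struct Dropout {
  T rate;
  Mat<T> mask[2];
  Mat<T> fwd(const Mat<T>& X, bool training, int slot) {
    if (!training || rate <= (T)0) return X;
    Mat<T> m(X.n_rows, X.n_cols);
    T keep = (T)1 - rate;
    for (uword i = 0; i < m.n_elem; ++i)
      m(i) = (r_unif() < (double)keep) ? (T)1 / keep : (T)0;
    mask[slot] = m;
    return X % m;
  }
  Mat<T> bwd(const Mat<T>& dY, int slot) {
    if (rate <= (T)0) return dY;
    return dY % mask[slot];
  }
};

enum Variant { SOYNET = 0, SOYNET_RES = 1 };
enum Task { YIELD = 0, LODGING5 = 1, LODGING2 = 2, MULTITASK = 3 };
enum Pooling { MAXPOOL = 0, MEANPOOL = 1, PERTASK = 2 };

struct NetBase {
  virtual ~NetBase() {}
  virtual List forward(const mat& X, int B, bool training) = 0;
  virtual List train_batch(const mat& X, int B, const vec& y_yield,
                           const ivec& y5, const ivec& y2, double lr,
                           int weight_mode, const vec& wfixed,
                           double huber_delta) = 0;
  virtual List get_params() = 0;
  virtual void set_params(List p) = 0;
  virtual double nparams() = 0;
  virtual vec log_sigma() = 0;
  virtual int global_dim() = 0;
};

template <typename T>
struct Net : NetBase {
  int variant, task, pooling, n_pts, resk;
  T slope, dropout_rate, momentum, weight_decay;

  std::vector<CBR<T>> cbrs;       // SoyNet: all five pointwise layers
  CBR<T> stem;                    // SoyNet-Res stem
  std::vector<ResCBR<T>> res;     // three residual blocks
  std::vector<Dense<T>> trunk_fc; // post-pooling MLP (shared in MDL)
  std::vector<BatchNorm<T>> trunk_bn;
  std::vector<LeakyReLU<T>> trunk_act;
  Dropout<T> drop;
  Dense<T> head_yield, head5, head2;
  bool has_yield, has5, has2;
  int gdim;

  // pooling caches
  umat argmax_idx[2];

  Net(int variant_, int task_, int pooling_, int n_pts_, int resk_,
      double slope_, double dropout_, double momentum_, double wd_)
      : variant(variant_), task(task_), pooling(pooling_), n_pts(n_pts_),
        resk(resk_), slope((T)slope_), dropout_rate((T)dropout_),
        momentum((T)momentum_), weight_decay((T)wd_) {
    has_yield = task == YIELD || task == MULTITASK;
    has5 = task == LODGING5 || task == MULTITASK;
    has2 = task == LODGING2 || task == MULTITASK;
    if (variant == SOYNET) {
      int dims[6] = {13, 64, 64, 64, 128, 1024};
      cbrs.resize(5);
      for (int i = 0; i < 5; ++i) cbrs[i].init(dims[i], dims[i + 1], slope);
      gdim = 1024;
      trunk_fc.resize(2); trunk_bn.resize(2); trunk_act.resize(2);
      trunk_fc[0].init(1024, 512); trunk_fc[1].init(512, 256);
      trunk_bn[0].init(512); trunk_bn[1].init(256);
      trunk_act[0].slope = slope; trunk_act[1].slope = slope;
    } else {
      stem.init(13, 64, slope);
      res.resize(3);
      res[0].init(64, 64, resk, slope);
      res[1].init(64, 128, resk, slope);
      res[2].init(128, 256, resk, slope);
      gdim = 256;
      trunk_fc.resize(1); trunk_bn.resize(1); trunk_act.resize(1);
      trunk_fc[0].init(256, 256);
      trunk_bn[0].init(256);
      trunk_act[0].slope = slope;
    }
    drop.rate = (T)dropout_;
    if (has_yield) head_yield.init(256, 1);
    if (has5) head5.init(256, 5);
    if (has2) head2.init(256, 1);
    ls_.set_size(3);
    ls_.fill(1.0);  // log(sigma) initialized to 1.0
    vls_.zeros(3);
  }

  vec ls_, vls_;  // log_sigma per task (yield, lodging5, lodging2)

  Mat<T> backbone_fwd(const Mat<T>& X, bool training) {
    Mat<T> H = X;
    if (variant == SOYNET) {
      for (auto& l : cbrs) H = l.fwd(H, training, 0);
    } else {
      H = stem.fwd(H, training, 0);
      for (auto& l : res) H = l.fwd(H, training, 0);
    }
    return H;
  }
  Mat<T> backbone_bwd(const Mat<T>& dH) {
    Mat<T> d = dH;
    if (variant == SOYNET) {
      for (int i = 4; i >= 0; --i) d = cbrs[i].bwd(d, 0);
    } else {
      for (int i = 2; i >= 0; --i) d = res[i].bwd(d, 0);
      d = stem.bwd(d, 0);
    }
    return d;
  }

  Mat<T> pool(const Mat<T>& H, int B, bool maxpool, int slot) {
    int C = H.n_cols;
    Mat<T> out(B, C);
    if (maxpool) {
      argmax_idx[slot].set_size(B, C);
      for (int b = 0; b < B; ++b) {
        auto S = H.rows(b * n_pts, (b + 1) * n_pts - 1);
        argmax_idx[slot].row(b) = index_max(S, 0);
        out.row(b) = max(S, 0);
      }
    } else {
      for (int b = 0; b < B; ++b) {
        out.row(b) = mean(H.rows(b * n_pts, (b + 1) * n_pts - 1), 0);
      }
    }
    return out;
  }
  void pool_bwd(Mat<T>& dH, const Mat<T>& dP, int B, bool maxpool, int slot) {
    int C = dP.n_cols;
    if (maxpool) {
      for (int b = 0; b < B; ++b)
        for (int c = 0; c < C; ++c)
          dH(b * n_pts + argmax_idx[slot](b, c), c) += dP(b, c);
    } else {
      T inv = (T)1 / (T)n_pts;
      for (int b = 0; b < B; ++b)
        for (int r = 0; r < n_pts; ++r)
          dH.row(b * n_pts + r) += dP.row(b) * inv;
    }
  }

  Mat<T> trunk_fwd(const Mat<T>& G, bool training, int slot) {
    Mat<T> H = G;
    for (size_t i = 0; i < trunk_fc.size(); ++i) {
      H = trunk_act[i].fwd(
        trunk_bn[i].fwd(trunk_fc[i].fwd(H, training, slot), training, slot),
        training, slot);
    }
    return drop.fwd(H, training, slot);
  }
  Mat<T> trunk_bwd(const Mat<T>& dY, int slot) {
    Mat<T> d = drop.bwd(dY, slot);
    for (int i = (int)trunk_fc.size() - 1; i >= 0; --i) {
      d = trunk_fc[i].bwd(trunk_bn[i].bwd(trunk_act[i].bwd(d, slot), slot), slot);
    }
    return d;
  }

  // full forward; caches live in layers when training
  void forward_impl(const Mat<T>& Xin, int B, bool training, Col<T>& yield,
                    Mat<T>& logits5, Col<T>& logit2, Mat<T>& gfeat) {
    Mat<T> H = backbone_fwd(Xin, training);
    bool per_task = (task == MULTITASK && pooling == PERTASK);
    if (per_task) {
      Mat<T> gmean = pool(H, B, false, 0);
      Mat<T> gmax = pool(H, B, true, 1);
      gfeat = gmax;
      Mat<T> tmean = trunk_fwd(gmean, training, 0);
      Mat<T> tmax = trunk_fwd(gmax, training, 1);
      if (has_yield) yield = head_yield.fwd(tmean, training, 0).col(0);
      if (has5) logits5 = head5.fwd(tmax, training, 1);
      if (has2) logit2 = head2.fwd(tmax, training, 1).col(0);
    } else {
      bool maxp = (pooling == MAXPOOL);
      Mat<T> G = pool(H, B, maxp, 0);
      gfeat = G;
      Mat<T> Tr = trunk_fwd(G, training, 0);
      if (has_yield) yield = head_yield.fwd(Tr, training, 0).col(0);
      if (has5) logits5 = head5.fwd(Tr, training, 0);
      if (has2) logit2 = head2.fwd(Tr, training, 0).col(0);
    }
  }

  List forward(const mat& X, int B, bool training) override {
    Mat<T> Xin = conv_to<Mat<T>>::from(X);
    Col<T> yield; Mat<T> logits5; Col<T> logit2; Mat<T> gfeat;
    forward_impl(Xin, B, training, yield, logits5, logit2, gfeat);
    List out;
    if (has_yield) out["yield"] = conv_to<vec>::from(yield);
    if (has5) out["logits5"] = conv_to<mat>::from(logits5);
    if (has2) out["logit2"] = conv_to<vec>::from(logit2);
    out["global_feature"] = conv_to<mat>::from(gfeat);
    return out;
  }

  List train_batch(const mat& X, int B, const vec& y_yield, const ivec& y5,
                   const ivec& y2, double lr, int weight_mode,
                   const vec& wfixed, double huber_delta) override {
    Mat<T> Xin = conv_to<Mat<T>>::from(X);
    Col<T> yield; Mat<T> logits5; Col<T> logit2; Mat<T> gfeat;
    forward_impl(Xin, B, true, yield, logits5, logit2, gfeat);

    double Lyield = 0, L5 = 0, L2 = 0;
    Col<T> d_yield; Mat<T> d5; Col<T> d2;
    T invB = (T)1 / (T)B;

    if (has_yield) {
      Col<T> e = yield - conv_to<Col<T>>::from(y_yield);
      T delta = (T)huber_delta;
      d_yield.set_size(B);
      for (int i = 0; i < B; ++i) {
        T ei = e(i), a = std::abs(ei);
        if (a <= delta) { Lyield += 0.5 * a * a; d_yield(i) = ei * invB; }
        else { Lyield += delta * a - 0.5 * delta * delta;
               d_yield(i) = (ei > 0 ? delta : -delta) * invB; }
      }
      Lyield /= B;
    }
    if (has5) {
      Mat<T> m = logits5.each_col() - max(logits5, 1);
      Mat<T> ex = exp(m);
      Col<T> Z = sum(ex, 1);
      Mat<T> p = ex.each_col() / Z;
      d5 = p;
      for (int i = 0; i < B; ++i) {
        L5 -= std::log(std::max((double)p(i, y5(i)), 1e-12));
        d5(i, y5(i)) -= (T)1;
      }
      L5 /= B;
      d5 *= invB;
    }
    if (has2) {
      d2.set_size(B);
      for (int i = 0; i < B; ++i) {
        double p = 1.0 / (1.0 + std::exp(-(double)logit2(i)));
        double yi = (double)y2(i);
        L2 -= yi * std::log(std::max(p, 1e-12)) +
              (1 - yi) * std::log(std::max(1 - p, 1e-12));
        d2(i) = (T)((p - yi) / B);
      }
      L2 /= B;
    }

    // loss fusion weights
    double wy = 1, w5 = 1, w2 = 1, total;
    if (task == MULTITASK) {
      if (weight_mode == 1) {  // homoscedastic-uncertainty (dynamic)
        wy = 0.5 * std::exp(-2.0 * ls_(0));
        w5 = 0.5 * std::exp(-2.0 * ls_(1));
        w2 = 0.5 * std::exp(-2.0 * ls_(2));
        total = wy * Lyield + w5 * L5 + w2 * L2 + ls_(0) + ls_(1) + ls_(2);
        // d total / d log_sigma_i = -exp(-2 s_i) L_i + 1
        vec gls = { -std::exp(-2.0 * ls_(0)) * Lyield + 1.0,
                    -std::exp(-2.0 * ls_(1)) * L5 + 1.0,
                    -std::exp(-2.0 * ls_(2)) * L2 + 1.0 };
        vls_ = momentum * vls_ - lr * gls;
        ls_ += vls_;
      } else {
        wy = wfixed(0); w5 = wfixed(1); w2 = wfixed(2);
        total = wy * Lyield + w5 * L5 + w2 * L2;
      }
    } else {
      total = Lyield + L5 + L2;  // exactly one term is active
    }

    // backward
    bool per_task = (task == MULTITASK && pooling == PERTASK);
    Mat<T> dH;
    int N = B * n_pts;
    if (per_task) {
      Mat<T> dTmean, dTmax;
      if (has_yield) {
        Mat<T> dy(B, 1); dy.col(0) = d_yield * (T)wy;
        dTmean = head_yield.bwd(dy, 0);
      }
      if (has5) dTmax = head5.bwd(d5 * (T)w5, 1);
      if (has2) {
        Mat<T> db(B, 1); db.col(0) = d2 * (T)w2;
        Mat<T> add = head2.bwd(db, 1);
        if (dTmax.n_elem) dTmax += add; else dTmax = add;
      }
      Mat<T> dGmean = trunk_bwd(dTmean, 0);
      Mat<T> dGmax = trunk_bwd(dTmax, 1);
      dH.zeros(N, gdim);
      pool_bwd(dH, dGmean, B, false, 0);
      pool_bwd(dH, dGmax, B, true, 1);
    } else {
      Mat<T> dT;
      if (has_yield) {
        Mat<T> dy(B, 1); dy.col(0) = d_yield * (T)wy;
        dT = head_yield.bwd(dy, 0);
      }
      if (has5) {
        Mat<T> add = head5.bwd(d5 * (T)w5, 0);
        if (dT.n_elem) dT += add; else dT = add;
      }
      if (has2) {
        Mat<T> db(B, 1); db.col(0) = d2 * (T)w2;
        Mat<T> add = head2.bwd(db, 0);
        if (dT.n_elem) dT += add; else dT = add;
      }
      Mat<T> dG = trunk_bwd(dT, 0);
      dH.zeros(N, gdim);
      pool_bwd(dH, dG, B, pooling == MAXPOOL, 0);
    }
    backbone_bwd(dH);
    step((T)lr);

    return List::create(_["loss"] = total, _["loss_yield"] = Lyield,
                        _["loss_lodging5"] = L5, _["loss_lodging2"] = L2);
  }

  void step(T lr) {
    if (variant == SOYNET) {
      for (auto& l : cbrs) l.step(lr, momentum, weight_decay);
    } else {
      stem.step(lr, momentum, weight_decay);
      for (auto& l : res) l.step(lr, momentum, weight_decay);
    }
    for (auto& f : trunk_fc) f.step(lr, momentum, weight_decay);
    for (auto& b : trunk_bn) b.step(lr, momentum);
    if (has_yield) head_yield.step(lr, momentum, weight_decay);
    if (has5) head5.step(lr, momentum, weight_decay);
    if (has2) head2.step(lr, momentum, weight_decay);
  }

  // ---- parameter (de)serialization ----
  void collect_dense(List& out, std::string nm, Dense<T>& d) {
    out[nm + ".W"] = conv_to<mat>::from(d.W);
    out[nm + ".b"] = conv_to<vec>::from(conv_to<Col<T>>::from(d.b.t()));
  }
  void restore_dense(List& p, std::string nm, Dense<T>& d) {
    d.W = conv_to<Mat<T>>::from(as<mat>(p[nm + ".W"]));
    vec b = as<vec>(p[nm + ".b"]);
    d.b = conv_to<Row<T>>::from(conv_to<Col<T>>::from(b).t());
  }
  void collect_bn(List& out, std::string nm, BatchNorm<T>& b) {
    out[nm + ".gamma"] = conv_to<vec>::from(b.gamma.t());
    out[nm + ".beta"] = conv_to<vec>::from(b.beta.t());
    out[nm + ".rmean0"] = conv_to<vec>::from(b.rmean[0].t());
    out[nm + ".rvar0"] = conv_to<vec>::from(b.rvar[0].t());
    out[nm + ".rmean1"] = conv_to<vec>::from(b.rmean[1].t());
    out[nm + ".rvar1"] = conv_to<vec>::from(b.rvar[1].t());
  }
  void restore_bn(List& p, std::string nm, BatchNorm<T>& b) {
    b.gamma = conv_to<Row<T>>::from(as<vec>(p[nm + ".gamma"]).t() * 1.0);
    b.beta = conv_to<Row<T>>::from(as<vec>(p[nm + ".beta"]).t() * 1.0);
    b.rmean[0] = conv_to<Row<T>>::from(as<vec>(p[nm + ".rmean0"]).t() * 1.0);
    b.rvar[0] = conv_to<Row<T>>::from(as<vec>(p[nm + ".rvar0"]).t() * 1.0);
    b.rmean[1] = conv_to<Row<T>>::from(as<vec>(p[nm + ".rmean1"]).t() * 1.0);
    b.rvar[1] = conv_to<Row<T>>::from(as<vec>(p[nm + ".rvar1"]).t() * 1.0);
  }
  void collect_res(List& out, std::string nm, ResCBR<T>& r) {
    collect_dense(out, nm + ".up", r.up); collect_bn(out, nm + ".bn1", r.bn1);
    collect_dense(out, nm + ".down", r.down); collect_bn(out, nm + ".bn2", r.bn2);
    if (r.has_proj) collect_dense(out, nm + ".proj", r.proj);
  }
  void restore_res(List& p, std::string nm, ResCBR<T>& r) {
    restore_dense(p, nm + ".up", r.up); restore_bn(p, nm + ".bn1", r.bn1);
    restore_dense(p, nm + ".down", r.down); restore_bn(p, nm + ".bn2", r.bn2);
    if (r.has_proj) restore_dense(p, nm + ".proj", r.proj);
  }
  List get_params() override {
    List out;
    if (variant == SOYNET) {
      for (size_t i = 0; i < cbrs.size(); ++i) {
        std::string nm = "cbr" + std::to_string(i);
        collect_dense(out, nm + ".fc", cbrs[i].fc);
        collect_bn(out, nm + ".bn", cbrs[i].bn);
      }
    } else {
      collect_dense(out, "stem.fc", stem.fc); collect_bn(out, "stem.bn", stem.bn);
      for (size_t i = 0; i < res.size(); ++i)
        collect_res(out, "res" + std::to_string(i), res[i]);
    }
    for (size_t i = 0; i < trunk_fc.size(); ++i) {
      collect_dense(out, "trunk" + std::to_string(i), trunk_fc[i]);
      collect_bn(out, "trunkbn" + std::to_string(i), trunk_bn[i]);
    }
    if (has_yield) collect_dense(out, "head_yield", head_yield);
    if (has5) collect_dense(out, "head5", head5);
    if (has2) collect_dense(out, "head2", head2);
    out["log_sigma"] = ls_;
    return out;
  }
  void set_params(List p) override {
    if (variant == SOYNET) {
      for (size_t i = 0; i < cbrs.size(); ++i) {
        std::string nm = "cbr" + std::to_string(i);
        restore_dense(p, nm + ".fc", cbrs[i].fc);
        restore_bn(p, nm + ".bn", cbrs[i].bn);
      }
    } else {
      restore_dense(p, "stem.fc", stem.fc); restore_bn(p, "stem.bn", stem.bn);
      for (size_t i = 0; i < res.size(); ++i)
        restore_res(p, "res" + std::to_string(i), res[i]);
    }
    for (size_t i = 0; i < trunk_fc.size(); ++i) {
      restore_dense(p, "trunk" + std::to_string(i), trunk_fc[i]);
      restore_bn(p, "trunkbn" + std::to_string(i), trunk_bn[i]);
    }
    if (has_yield) restore_dense(p, "head_yield", head_yield);
    if (has5) restore_dense(p, "head5", head5);
    if (has2) restore_dense(p, "head2", head2);
    ls_ = as<vec>(p["log_sigma"]);
  }
  double nparams() override {
    size_t n = 0;
    if (variant == SOYNET) { for (auto& l : cbrs) n += l.nparams(); }
    else { n += stem.nparams(); for (auto& l : res) n += l.nparams(); }
    for (auto& f : trunk_fc) n += f.nparams();
    for (auto& b : trunk_bn) n += b.nparams();
    if (has_yield) n += head_yield.nparams();
    if (has5) n += head5.nparams();
    if (has2) n += head2.nparams();
    if (task == MULTITASK) n += 3;  // log_sigma
    return (double)n;
  }
  vec log_sigma() override { return ls_; }
  int global_dim() override { return gdim; }
};

static int variant_code(std::string v) {
  if (v == "soynet") return SOYNET;
  if (v == "soynet_res") return SOYNET_RES;
  stop("unknown variant: " + v);
}
static int task_code(std::string t) {
  if (t == "yield") return YIELD;
  if (t == "lodging5") return LODGING5;
  if (t == "lodging2") return LODGING2;
  if (t == "multitask") return MULTITASK;
  stop("unknown task: " + t);
}
static int pooling_code(std::string p) {
  if (p == "max") return MAXPOOL;
  if (p == "mean") return MEANPOOL;
  if (p == "per_task") return PERTASK;
  stop("unknown pooling: " + p);
}

// [[Rcpp::export]]
SEXP eng_create(std::string variant, std::string task, std::string pooling,
                int n_pts, int res_k, double slope, double dropout,
                double momentum, double weight_decay, std::string precision) {
  NetBase* net;
  int v = variant_code(variant), t = task_code(task), p = pooling_code(pooling);
  if (precision == "float") {
    net = new Net<float>(v, t, p, n_pts, res_k, slope, dropout, momentum,
                         weight_decay);
  } else {
    net = new Net<double>(v, t, p, n_pts, res_k, slope, dropout, momentum,
                          weight_decay);
  }
  XPtr<NetBase> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
List eng_forward(SEXP net, const arma::mat& X, int B, bool training) {
  XPtr<NetBase> p(net);
  if (X.n_cols != 13) stop("input must have exactly 13 channels, got %d",
                           (int)X.n_cols);
  return p->forward(X, B, training);
}

// [[Rcpp::export]]
List eng_train_batch(SEXP net, const arma::mat& X, int B,
                     const arma::vec& y_yield, const arma::ivec& y5,
                     const arma::ivec& y2, double lr, int weight_mode,
                     const arma::vec& wfixed, double huber_delta) {
  XPtr<NetBase> p(net);
  if (X.n_cols != 13) stop("input must have exactly 13 channels, got %d",
                           (int)X.n_cols);
  return p->train_batch(X, B, y_yield, y5, y2, lr, weight_mode, wfixed,
                        huber_delta);
}

// [[Rcpp::export]]
List eng_get_params(SEXP net) { XPtr<NetBase> p(net); return p->get_params(); }

// [[Rcpp::export]]
void eng_set_params(SEXP net, List params) {
  XPtr<NetBase> p(net); p->set_params(params);
}

// [[Rcpp::export]]
double eng_nparams(SEXP net) { XPtr<NetBase> p(net); return p->nparams(); }

// [[Rcpp::export]]
arma::vec eng_log_sigma(SEXP net) { XPtr<NetBase> p(net); return p->log_sigma(); }

// [[Rcpp::export]]
int eng_global_dim(SEXP net) { XPtr<NetBase> p(net); return p->global_dim(); }
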