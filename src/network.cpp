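// Fixed-topology 1D convolutional network with squeeze-and-excitation
// channel attention: conv stem -> BN -> ReLU -> SE -> 3 residual blocks
// (stride-2 downsampling, projection shortcuts) -> SE -> global average
// pool -> fully connected softmax bi-classifier.
//
// Forward, backward and the Adam training loop are hand-derived; all
// convolutions are valid (no zero padding) so that a constant input gives
// exactly length-invariant class probabilities under global average
// pooling. Activations are stored as C x (N*T) matrices, sample-major.
// Randomness (init, shuffling) goes through R's RNG, so results are
// reproducible from set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.1;

static inline int conv_len(int T, int k, int s) {
  return (T < k) ? 0 : (T - k) / s + 1;
}

// ----------------------------------------------------------------------
// parameter containers
// ----------------------------------------------------------------------
struct ConvP {
  mat W;  // Cout x (Cin*k), column j*Cin + c multiplies x[c, t*s + j]
  vec b;
  int k, s, cin, cout;
};
struct BNP {
  vec g, be, rm, rv;  // gamma, beta, running mean, running var
};
struct SEP {
  mat W1; vec b1; mat W2; vec b2;  // C/r x C, C/r, C x C/r, C
};

struct Spec {
  int c0, k0, s0, r;
  std::vector<int> rc;  // residual channels, length 3
  int n_classes;
};

static Spec read_spec(const List& s) {
  Spec sp;
  sp.c0 = as<int>(s["conv_channels"]);
  sp.k0 = as<int>(s["conv_kernel"]);
  sp.s0 = as<int>(s["conv_stride"]);
  sp.r = as<int>(s["se_reduction"]);
  IntegerVector rc = s["residual_channels"];
  sp.rc.assign(rc.begin(), rc.end());
  sp.n_classes = as<int>(s["n_classes"]);
  return sp;
}

struct Net {
  Spec sp;
  ConvP stem;
  BNP bn0;
  SEP se1;
  ConvP convA[3], convB[3], convS[3];
  BNP bnA[3], bnB[3], bnS[3];
  SEP se2;
  mat fcW; vec fcb;
};

// Enumerate trainable tensors in a fixed order (BN running stats excluded).
static void collect_trainable(Net& n, std::vector<mat*>& ms, std::vector<vec*>& vs) {
  ms.push_back(&n.stem.W); vs.push_back(&n.stem.b);
  vs.push_back(&n.bn0.g); vs.push_back(&n.bn0.be);
  ms.push_back(&n.se1.W1); vs.push_back(&n.se1.b1);
  ms.push_back(&n.se1.W2); vs.push_back(&n.se1.b2);
  for (int i = 0; i < 3; ++i) {
    ms.push_back(&n.convA[i].W); vs.push_back(&n.convA[i].b);
    vs.push_back(&n.bnA[i].g); vs.push_back(&n.bnA[i].be);
    ms.push_back(&n.convB[i].W); vs.push_back(&n.convB[i].b);
    vs.push_back(&n.bnB[i].g); vs.push_back(&n.bnB[i].be);
    ms.push_back(&n.convS[i].W); vs.push_back(&n.convS[i].b);
    vs.push_back(&n.bnS[i].g); vs.push_back(&n.bnS[i].be);
  }
  ms.push_back(&n.se2.W1); vs.push_back(&n.se2.b1);
  ms.push_back(&n.se2.W2); vs.push_back(&n.se2.b2);
  ms.push_back(&n.fcW); vs.push_back(&n.fcb);
}

// ----------------------------------------------------------------------
// (de)serialization to a named R list
// ----------------------------------------------------------------------
static void conv_to_list(List& L, const std::string& p, const ConvP& c) {
  L[p + ".W"] = wrap(c.W); L[p + ".b"] = wrap(c.b);
}
static void bn_to_list(List& L, const std::string& p, const BNP& b) {
  L[p + ".gamma"] = wrap(b.g); L[p + ".beta"] = wrap(b.be);
  L[p + ".rmean"] = wrap(b.rm); L[p + ".rvar"] = wrap(b.rv);
}
static void se_to_list(List& L, const std::string& p, const SEP& s) {
  L[p + ".W1"] = wrap(s.W1); L[p + ".b1"] = wrap(s.b1);
  L[p + ".W2"] = wrap(s.W2); L[p + ".b2"] = wrap(s.b2);
}
static mat getm(const List& L, const std::string& nm) { return as<mat>(L[nm]); }
static vec getv(const List& L, const std::string& nm) { return as<vec>(L[nm]); }

static List net_to_list(const Net& n) {
  List L;
  conv_to_list(L, "stem", n.stem);
  bn_to_list(L, "bn0", n.bn0);
  se_to_list(L, "se1", n.se1);
  const char* blk[3] = {"res1", "res2", "res3"};
  for (int i = 0; i < 3; ++i) {
    std::string p(blk[i]);
    conv_to_list(L, p + ".convA", n.convA[i]);
    bn_to_list(L, p + ".bnA", n.bnA[i]);
    conv_to_list(L, p + ".convB", n.convB[i]);
    bn_to_list(L, p + ".bnB", n.bnB[i]);
    conv_to_list(L, p + ".short", n.convS[i]);
    bn_to_list(L, p + ".bnS", n.bnS[i]);
  }
  se_to_list(L, "se2", n.se2);
  L["fc.W"] = wrap(n.fcW); L["fc.b"] = wrap(n.fcb);
  return L;
}

static void set_conv_dims(ConvP& c, int cin, int cout, int k, int s) {
  c.cin = cin; c.cout = cout; c.k = k; c.s = s;
}

static Net net_from_list(const List& L, const List& specL) {
  Net n; n.sp = read_spec(specL);
  n.stem.W = getm(L, "stem.W"); n.stem.b = getv(L, "stem.b");
  set_conv_dims(n.stem, 1, n.sp.c0, n.sp.k0, n.sp.s0);
  n.bn0.g = getv(L, "bn0.gamma"); n.bn0.be = getv(L, "bn0.beta");
  n.bn0.rm = getv(L, "bn0.rmean"); n.bn0.rv = getv(L, "bn0.rvar");
  n.se1.W1 = getm(L, "se1.W1"); n.se1.b1 = getv(L, "se1.b1");
  n.se1.W2 = getm(L, "se1.W2"); n.se1.b2 = getv(L, "se1.b2");
  const char* blk[3] = {"res1", "res2", "res3"};
  int cin = n.sp.c0;
  for (int i = 0; i < 3; ++i) {
    std::string p(blk[i]);
    int cout = n.sp.rc[i];
    n.convA[i].W = getm(L, p + ".convA.W"); n.convA[i].b = getv(L, p + ".convA.b");
    set_conv_dims(n.convA[i], cin, cout, 3, 2);
    n.bnA[i].g = getv(L, p + ".bnA.gamma"); n.bnA[i].be = getv(L, p + ".bnA.beta");
    n.bnA[i].rm = getv(L, p + ".bnA.rmean"); n.bnA[i].rv = getv(L, p + ".bnA.rvar");
    n.convB[i].W = getm(L, p + ".convB.W"); n.convB[i].b = getv(L, p + ".convB.b");
    set_conv_dims(n.convB[i], cout, cout, 3, 1);
    n.bnB[i].g = getv(L, p + ".bnB.gamma"); n.bnB[i].be = getv(L, p + ".bnB.beta");
    n.bnB[i].rm = getv(L, p + ".bnB.rmean"); n.bnB[i].rv = getv(L, p + ".bnB.rvar");
    n.convS[i].W = getm(L, p + ".short.W"); n.convS[i].b = getv(L, p + ".short.b");
    set_conv_dims(n.convS[i], cin, cout, 1, 2);
    n.bnS[i].g = getv(L, p + ".bnS.gamma"); n.bnS[i].be = getv(L, p + ".bnS.beta");
    n.bnS[i].rm = getv(L, p + ".bnS.rmean"); n.bnS[i].rv = getv(L, p + ".bnS.rvar");
    cin = cout;
  }
  n.se2.W1 = getm(L, "se2.W1"); n.se2.b1 = getv(L, "se2.b1");
  n.se2.W2 = getm(L, "se2.W2"); n.se2.b2 = getv(L, "se2.b2");
  n.fcW = getm(L, "fc.W"); n.fcb = getv(L, "fc.b");
  return n;
}

// He-normal init through R's RNG
static mat he_mat(int rows, int cols, double fan_in) {
  mat W(rows, cols);
  double sd = std::sqrt(2.0 / fan_in);
  for (arma::uword j = 0; j < W.n_cols; ++j)
    for (arma::uword i = 0; i < W.n_rows; ++i)
      W(i, j) = R::rnorm(0.0, sd);
  return W;
}
static void init_conv(ConvP& c, int cin, int cout, int k, int s) {
  set_conv_dims(c, cin, cout, k, s);
  c.W = he_mat(cout, cin * k, cin * k);
  c.b = vec(cout, arma::fill::zeros);
}
static void init_bn(BNP& b, int c) {
  b.g = vec(c, arma::fill::ones); b.be = vec(c, arma::fill::zeros);
  b.rm = vec(c, arma::fill::zeros); b.rv = vec(c, arma::fill::ones);
}
static void init_se(SEP& s, int c, int r) {
  int h = c / r;
  s.W1 = he_mat(h, c, c); s.b1 = vec(h, arma::fill::zeros);
  s.W2 = he_mat(c, h, h); s.b2 = vec(c, arma::fill::zeros);
}

// [[Rcpp::export]]
List cpp_init_params(List specL) {
  Net n; n.sp = read_spec(specL);
  init_conv(n.stem, 1, n.sp.c0, n.sp.k0, n.sp.s0);
  init_bn(n.bn0, n.sp.c0);
  init_se(n.se1, n.sp.c0, n.sp.r);
  int cin = n.sp.c0;
  for (int i = 0; i < 3; ++i) {
    int cout = n.sp.rc[i];
    init_conv(n.convA[i], cin, cout, 3, 2);
    init_bn(n.bnA[i], cout);
    init_conv(n.convB[i], cout, cout, 3, 1);
    init_bn(n.bnB[i], cout);
    init_conv(n.convS[i], cin, cout, 1, 2);
    init_bn(n.bnS[i], cout);
    cin = cout;
  }
  init_se(n.se2, cin, n.sp.r);
  n.fcW = he_mat(n.sp.n_classes, cin, cin);
  n.fcb = vec(n.sp.n_classes, arma::fill::zeros);
  return net_to_list(n);
}

// ----------------------------------------------------------------------
// layer forward/backward primitives
// ----------------------------------------------------------------------
static mat im2col(const mat& X, int N, int Tin, int k, int s, int Tout) {
  int cin = X.n_rows;
  mat cols(cin * k, (size_t)N * Tout);
  for (int n = 0; n < N; ++n)
    for (int t = 0; t < Tout; ++t) {
      size_t dst = (size_t)n * Tout + t;
      int src = n * Tin + t * s;
      for (int j = 0; j < k; ++j)
        cols.submat(j * cin, dst, (j + 1) * cin - 1, dst) = X.col(src + j);
    }
  return cols;
}

static mat col2im(const mat& dcols, int cin, int N, int Tin, int k, int s, int Tout) {
  mat dX(cin, (size_t)N * Tin, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int t = 0; t < Tout; ++t) {
      size_t src = (size_t)n * Tout + t;
      int dst = n * Tin + t * s;
      for (int j = 0; j < k; ++j)
        dX.col(dst + j) += dcols.submat(j * cin, src, (j + 1) * cin - 1, src);
    }
  return dX;
}

struct ConvCache { mat cols; int N, Tin, Tout; };

static mat conv_fwd(const ConvP& c, const mat& X, int N, int Tin, ConvCache* cc) {
  int Tout = conv_len(Tin, c.k, c.s);
  mat cols = im2col(X, N, Tin, c.k, c.s, Tout);
  mat Y = c.W * cols;
  Y.each_col() += c.b;
  if (cc) { cc->cols = std::move(cols); cc->N = N; cc->Tin = Tin; cc->Tout = Tout; }
  return Y;
}

static mat conv_bwd(const ConvP& c, const ConvCache& cc, const mat& dY,
                    mat& dW, vec& db) {
  dW = dY * cc.cols.t();
  db = arma::sum(dY, 1);
  mat dcols = c.W.t() * dY;
  return col2im(dcols, c.cin, cc.N, cc.Tin, c.k, c.s, cc.Tout);
}

struct BNCache { mat xhat; vec invstd; };

static mat bn_fwd(BNP& b, const mat& X, bool training, BNCache* bc) {
  if (!training) {
    mat Y = X;
    vec is = 1.0 / arma::sqrt(b.rv + BN_EPS);
    Y.each_col() -= b.rm;
    Y.each_col() %= is % b.g;
    Y.each_col() += b.be;
    return Y;
  }
  double M = (double)X.n_cols;
  vec mu = arma::mean(X, 1);
  mat Xc = X; Xc.each_col() -= mu;
  vec var = arma::mean(arma::square(Xc), 1);
  vec is = 1.0 / arma::sqrt(var + BN_EPS);
  mat xhat = Xc; xhat.each_col() %= is;
  mat Y = xhat;
  Y.each_col() %= b.g;
  Y.each_col() += b.be;
  b.rm = (1.0 - BN_MOMENTUM) * b.rm + BN_MOMENTUM * mu;
  double corr = M > 1.5 ? M / (M - 1.0) : 1.0;
  b.rv = (1.0 - BN_MOMENTUM) * b.rv + BN_MOMENTUM * (var * corr);
  if (bc) { bc->xhat = std::move(xhat); bc->invstd = is; }
  return Y;
}

static mat bn_bwd(const BNP& b, const BNCache& bc, const mat& dY,
                  vec& dg, vec& dbe) {
  double M = (double)dY.n_cols;
  dg = arma::sum(dY % bc.xhat, 1);
  dbe = arma::sum(dY, 1);
  mat dxhat = dY; dxhat.each_col() %= b.g;
  vec sum_dxhat = arma::sum(dxhat, 1);
  vec sum_dxhat_xhat = arma::sum(dxhat % bc.xhat, 1);
  mat dX = M * dxhat;
  dX.each_col() -= sum_dxhat;
  dX -= bc.xhat.each_col() % sum_dxhat_xhat;
  dX.each_col() %= bc.invstd / M;
  return dX;
}

struct SECache { mat s, h, e, x; int N, T; };

static mat se_fwd(const SEP& p, const mat& X, int N, int T, SECache* sc) {
  int C = X.n_rows;
  mat S(C, N), H, E;
  for (int n = 0; n < N; ++n)
    S.col(n) = arma::mean(X.cols((size_t)n * T, (size_t)(n + 1) * T - 1), 1);
  mat Z1 = p.W1 * S; Z1.each_col() += p.b1;
  H = arma::clamp(Z1, 0.0, arma::datum::inf);
  mat Z2 = p.W2 * H; Z2.each_col() += p.b2;
  E = 1.0 / (1.0 + arma::exp(-Z2));
  mat Y = X;
  for (int n = 0; n < N; ++n)
    Y.cols((size_t)n * T, (size_t)(n + 1) * T - 1).each_col() %= E.col(n);
  if (sc) { sc->s = std::move(S); sc->h = std::move(H); sc->e = std::move(E);
            sc->x = X; sc->N = N; sc->T = T; }
  return Y;
}

static mat se_bwd(const SEP& p, const SECache& sc, const mat& dY,
                  mat& dW1, vec& db1, mat& dW2, vec& db2) {
  int N = sc.N, T = sc.T, C = dY.n_rows;
  mat dE(C, N);
  mat dX = dY;
  for (int n = 0; n < N; ++n) {
    size_t a = (size_t)n * T, b = (size_t)(n + 1) * T - 1;
    dE.col(n) = arma::sum(dY.cols(a, b) % sc.x.cols(a, b), 1);
    dX.cols(a, b).each_col() %= sc.e.col(n);
  }
  mat dZ2 = dE % sc.e % (1.0 - sc.e);
  dW2 = dZ2 * sc.h.t();
  db2 = arma::sum(dZ2, 1);
  mat dH = p.W2.t() * dZ2;
  mat dZ1 = dH % arma::conv_to<mat>::from(sc.h > 0.0);
  dW1 = dZ1 * sc.s.t();
  db1 = arma::sum(dZ1, 1);
  mat dS = p.W1.t() * dZ1;
  for (int n = 0; n < N; ++n) {
    size_t a = (size_t)n * T, b = (size_t)(n + 1) * T - 1;
    dX.cols(a, b).each_col() += dS.col(n) / (double)T;
  }
  return dX;
}

// ----------------------------------------------------------------------
// full network forward (with tape) and backward
// ----------------------------------------------------------------------
struct ResCache {
  ConvCache ccA, ccB, ccS;
  BNCache bcA, bcB, bcS;
  arma::umat maskA;           // ReLU mask inside block
  arma::umat maskOut;         // ReLU mask after the add
  int Tin, Tmain, Tshort, N;
};

struct Tape {
  ConvCache cc0; BNCache bc0; arma::umat mask0;
  SECache se1c;
  ResCache res[3];
  SECache se2c;
  int N; int T0, T1;          // input length, post-stem length
  mat gapin;                  // activation entering GAP (C x N*T)
  int Tgap;
  mat feat;                   // pooled features C x N
  mat probs;                  // n_classes x N
};

static mat relu_fwd(const mat& X, arma::umat* mask) {
  if (mask) *mask = (X > 0.0);
  return arma::clamp(X, 0.0, arma::datum::inf);
}

// crop each sample's block of columns from length Tfrom to first Tto
static mat crop_cols(const mat& X, int N, int Tfrom, int Tto) {
  mat Y(X.n_rows, (size_t)N * Tto);
  for (int n = 0; n < N; ++n)
    Y.cols((size_t)n * Tto, (size_t)(n + 1) * Tto - 1) =
      X.cols((size_t)n * Tfrom, (size_t)n * Tfrom + Tto - 1);
  return Y;
}
static mat uncrop_cols(const mat& dY, int N, int Tfrom, int Tto) {
  mat dX(dY.n_rows, (size_t)N * Tfrom, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    dX.cols((size_t)n * Tfrom, (size_t)n * Tfrom + Tto - 1) =
      dY.cols((size_t)n * Tto, (size_t)(n + 1) * Tto - 1);
  return dX;
}

// forward through everything up to softmax probabilities
static mat net_forward(Net& net, const mat& X, int N, int T, bool training,
                       Tape* tp) {
  if (tp) { tp->N = N; tp->T0 = T; }
  mat a = conv_fwd(net.stem, X, N, T, tp ? &tp->cc0 : nullptr);
  int t = conv_len(T, net.stem.k, net.stem.s);
  a = bn_fwd(net.bn0, a, training, tp ? &tp->bc0 : nullptr);
  a = relu_fwd(a, tp ? &tp->mask0 : nullptr);
  a = se_fwd(net.se1, a, N, t, tp ? &tp->se1c : nullptr);
  if (tp) tp->T1 = t;
  for (int i = 0; i < 3; ++i) {
    ResCache* rc = tp ? &tp->res[i] : nullptr;
    int tin = t;
    mat m = conv_fwd(net.convA[i], a, N, tin, rc ? &rc->ccA : nullptr);
    int t1 = conv_len(tin, 3, 2);
    m = bn_fwd(net.bnA[i], m, training, rc ? &rc->bcA : nullptr);
    m = relu_fwd(m, rc ? &rc->maskA : nullptr);
    m = conv_fwd(net.convB[i], m, N, t1, rc ? &rc->ccB : nullptr);
    int t2 = conv_len(t1, 3, 1);
    m = bn_fwd(net.bnB[i], m, training, rc ? &rc->bcB : nullptr);
    mat sct = conv_fwd(net.convS[i], a, N, tin, rc ? &rc->ccS : nullptr);
    int ts = conv_len(tin, 1, 2);
    sct = bn_fwd(net.bnS[i], sct, training, rc ? &rc->bcS : nullptr);
    sct = crop_cols(sct, N, ts, t2);
    m += sct;
    m = relu_fwd(m, rc ? &rc->maskOut : nullptr);
    if (rc) { rc->Tin = tin; rc->Tmain = t2; rc->Tshort = ts; rc->N = N; }
    a = std::move(m);
    t = t2;
  }
  a = se_fwd(net.se2, a, N, t, tp ? &tp->se2c : nullptr);
  if (tp) { tp->gapin = a; tp->Tgap = t; }
  // global average pool
  int C = a.n_rows;
  mat F(C, N);
  for (int n = 0; n < N; ++n)
    F.col(n) = arma::mean(a.cols((size_t)n * t, (size_t)(n + 1) * t - 1), 1);
  mat logits = net.fcW * F; logits.each_col() += net.fcb;
  // softmax (columnwise)
  mat P = logits;
  for (int n = 0; n < N; ++n) {
    vec l = P.col(n);
    l -= l.max();
    vec e = arma::exp(l);
    P.col(n) = e / arma::accu(e);
  }
  if (tp) { tp->feat = std::move(F); tp->probs = P; }
  return P;
}

// backward from dlogits; accumulates gradients into gnet (same shapes)
static void net_backward(Net& net, Tape& tp, const mat& dlogits, Net& g) {
  int N = tp.N;
  g.fcW = dlogits * tp.feat.t();
  g.fcb = arma::sum(dlogits, 1);
  mat dF = net.fcW.t() * dlogits;               // C x N
  int t = tp.Tgap;
  mat da(tp.gapin.n_rows, (size_t)N * t);
  for (int n = 0; n < N; ++n)
    da.cols((size_t)n * t, (size_t)(n + 1) * t - 1) =
      arma::repmat(dF.col(n) / (double)t, 1, t);
  da = se_bwd(net.se2, tp.se2c, da, g.se2.W1, g.se2.b1, g.se2.W2, g.se2.b2);
  for (int i = 2; i >= 0; --i) {
    ResCache& rc = tp.res[i];
    da %= arma::conv_to<mat>::from(rc.maskOut);
    // shortcut branch
    mat dsc = uncrop_cols(da, N, rc.Tshort, rc.Tmain);
    dsc = bn_bwd(net.bnS[i], rc.bcS, dsc, g.bnS[i].g, g.bnS[i].be);
    mat dx_short = conv_bwd(net.convS[i], rc.ccS, dsc, g.convS[i].W, g.convS[i].b);
    // main branch
    mat dm = bn_bwd(net.bnB[i], rc.bcB, da, g.bnB[i].g, g.bnB[i].be);
    dm = conv_bwd(net.convB[i], rc.ccB, dm, g.convB[i].W, g.convB[i].b);
    dm %= arma::conv_to<mat>::from(rc.maskA);
    dm = bn_bwd(net.bnA[i], rc.bcA, dm, g.bnA[i].g, g.bnA[i].be);
    dm = conv_bwd(net.convA[i], rc.ccA, dm, g.convA[i].W, g.convA[i].b);
    da = dm + dx_short;
  }
  da = se_bwd(net.se1, tp.se1c, da, g.se1.W1, g.se1.b1, g.se1.W2, g.se1.b2);
  da %= arma::conv_to<mat>::from(tp.mask0);
  da = bn_bwd(net.bn0, tp.bc0, da, g.bn0.g, g.bn0.be);
  conv_bwd(net.stem, tp.cc0, da, g.stem.W, g.stem.b);  // dX not needed
}

// zero-shaped gradient holder
static Net grad_like(const Net& n) {
  Net g = n;  // copies shapes; values overwritten by backward
  return g;
}

// ----------------------------------------------------------------------
// exported entry points
// ----------------------------------------------------------------------

// Forward pass for a list of (normalized) signal vectors; variable lengths
// allowed. Uses BN running statistics (inference mode). Returns N x n_classes.
// [[Rcpp::export]]
NumericMatrix cpp_forward(List paramsL, List specL, List chunks) {
  Net net = net_from_list(paramsL, specL);
  int N = chunks.size();
  NumericMatrix out(N, net.sp.n_classes);
  int i = 0;
  while (i < N) {
    NumericVector x0 = chunks[i];
    int T = x0.size();
    int j = i + 1;
    while (j < N && j - i < 256 &&
           Rf_length(VECTOR_ELT(chunks, j)) == T) ++j;
    int nb = j - i;
    mat X(1, (size_t)nb * T);
    for (int n = 0; n < nb; ++n) {
      NumericVector xv = chunks[i + n];
      for (int tt = 0; tt < T; ++tt) X(0, (size_t)n * T + tt) = xv[tt];
    }
    mat P = net_forward(net, X, nb, T, false, nullptr);
    for (int n = 0; n < nb; ++n)
      for (int c = 0; c < net.sp.n_classes; ++c)
        out(i + n, c) = P(c, n);
    i = j;
  }
  return out;
}

// Adam training. X: N x T matrix of normalized chunks (rows = samples),
// y: integer class in 0..n_classes-1. Modifies a copy of params; returns
// list(params, loss, accuracy) with per-epoch curves. Shuffling uses R's RNG.
// [[Rcpp::export]]
List cpp_train(List paramsL, List specL, NumericMatrix X, IntegerVector y,
               int epochs, int batch_size, double lr,
               double beta1 = 0.9, double beta2 = 0.999, double adam_eps = 1e-8) {
  Net net = net_from_list(paramsL, specL);
  int N = X.nrow(), T = X.ncol();
  std::vector<mat*> pm; std::vector<vec*> pv;
  collect_trainable(net, pm, pv);
  std::vector<mat> m_m, v_m; std::vector<vec> m_v, v_v;
  for (auto* p : pm) { m_m.push_back(mat(p->n_rows, p->n_cols, arma::fill::zeros));
                       v_m.push_back(mat(p->n_rows, p->n_cols, arma::fill::zeros)); }
  for (auto* p : pv) { m_v.push_back(vec(p->n_elem, arma::fill::zeros));
                       v_v.push_back(vec(p->n_elem, arma::fill::zeros)); }
  NumericVector ep_loss(epochs), ep_acc(epochs);
  long step = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle through R RNG
    std::vector<int> idx(N);
    for (int i = 0; i < N; ++i) idx[i] = i;
    for (int i = N - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    double tot_loss = 0.0; long tot_correct = 0; long nb_batches = 0;
    for (int start = 0; start < N; start += batch_size) {
      int nb = std::min(batch_size, N - start);
      mat Xb(1, (size_t)nb * T);
      std::vector<int> yb(nb);
      for (int n = 0; n < nb; ++n) {
        int src = idx[start + n];
        yb[n] = y[src];
        for (int tt = 0; tt < T; ++tt) Xb(0, (size_t)n * T + tt) = X(src, tt);
      }
      Tape tp;
      mat P = net_forward(net, Xb, nb, T, true, &tp);
      double loss = 0.0;
      mat dlogits = P;
      for (int n = 0; n < nb; ++n) {
        loss += -std::log(std::max(P(yb[n], n), 1e-12));
        dlogits(yb[n], n) -= 1.0;
        arma::uword am = P.col(n).index_max();
        // tie toward the higher class index (target)
        if (P(1, n) >= P(0, n) && net.sp.n_classes == 2) am = 1;
        if ((int)am == yb[n]) ++tot_correct;
      }
      loss /= nb;
      dlogits /= (double)nb;
      Net g = grad_like(net);
      net_backward(net, tp, dlogits, g);
      std::vector<mat*> gm; std::vector<vec*> gv;
      collect_trainable(g, gm, gv);
      ++step;
      double bc1 = 1.0 - std::pow(beta1, (double)step);
      double bc2 = 1.0 - std::pow(beta2, (double)step);
      for (size_t i = 0; i < pm.size(); ++i) {
        m_m[i] = beta1 * m_m[i] + (1.0 - beta1) * (*gm[i]);
        v_m[i] = beta2 * v_m[i] + (1.0 - beta2) * arma::square(*gm[i]);
        *pm[i] -= lr * (m_m[i] / bc1) / (arma::sqrt(v_m[i] / bc2) + adam_eps);
      }
      for (size_t i = 0; i < pv.size(); ++i) {
        m_v[i] = beta1 * m_v[i] + (1.0 - beta1) * (*gv[i]);
        v_v[i] = beta2 * v_v[i] + (1.0 - beta2) * arma::square(*gv[i]);
        *pv[i] -= lr * (m_v[i] / bc1) / (arma::sqrt(v_v[i] / bc2) + adam_eps);
      }
      tot_loss += loss;
      ++nb_batches;
    }
    ep_loss[ep] = tot_loss / nb_batches;
    ep_acc[ep] = (double)tot_correct / N;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = net_to_list(net),
                      _["loss"] = ep_loss, _["accuracy"] = ep_acc);
}

// Cross-entropy loss and analytic parameter gradients for a batch, in
// training mode (batch statistics). Exposed for finite-difference
// verification of the hand-derived backward pass.
// [[Rcpp::export]]
List cpp_loss_grad(List paramsL, List specL, NumericMatrix X, IntegerVector y) {
  Net net = net_from_list(paramsL, specL);
  int N = X.nrow(), T = X.ncol();
  mat Xb(1, (size_t)N * T);
  for (int n = 0; n < N; ++n)
    for (int tt = 0; tt < T; ++tt) Xb(0, (size_t)n * T + tt) = X(n, tt);
  Tape tp;
  mat P = net_forward(net, Xb, N, T, true, &tp);
  double loss = 0.0;
  mat dlogits = P;
  for (int n = 0; n < N; ++n) {
    loss += -std::log(std::max(P(y[n], n), 1e-12));
    dlogits(y[n], n) -= 1.0;
  }
  loss /= N;
  dlogits /= (double)N;
  Net g = grad_like(net);
  net_backward(net, tp, dlogits, g);
  return List::create(_["loss"] = loss, _["grads"] = net_to_list(g),
                      _["probs"] = wrap(P.t()));
}

// Stand-alone squeeze-and-excitation block on a C x T feature map.
// [[Rcpp::export]]
NumericMatrix cpp_se_block(NumericMatrix x, NumericMatrix W1, NumericVector b1,
                           NumericMatrix W2, NumericVector b2) {
  SEP p;
  p.W1 = as<mat>(wrap(W1)); p.b1 = as<vec>(wrap(b1));
  p.W2 = as<mat>(wrap(W2)); p.b2 = as<vec>(wrap(b2));
  mat X = as<mat>(wrap(x));
  mat Y = se_fwd(p, X, 1, X.n_cols, nullptr);
  return wrap(Y);
}

// 5th-order (general (k-1)-mer state) Markov chain sequence sampler.
// trans_cum: S x 4 cumulative conditional probabilities; init_codes: the
// first k-1 base codes (0..3). Returns n base codes total.
// [[Rcpp::export]]
IntegerVector cpp_markov_chain(int n, NumericMatrix trans_cum,
                               IntegerVector init_codes) {
  int order = init_codes.size();
  int S = trans_cum.nrow();
  IntegerVector out(n);
  int state = 0;
  int reduce = S / 4;  // 4^(order-1)
  for (int i = 0; i < order && i < n; ++i) {
    out[i] = init_codes[i];
    state = state * 4 + init_codes[i];
  }
  for (int i = order; i < n; ++i) {
    double u = unif_rand();
    int b = 0;
    while (b < 3 && u > trans_cum(state, b)) ++b;
    out[i] = b;
    state = (state % reduce) * 4 + b;
  }
  return out;
}
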