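// Compiled training path for the graph-attention scoring model. The
// architecture matches the R reference implementation in R/nnet.R exactly
// (multi-head attention layers with linear shortcuts summed before the ELU,
// then an MLP regressor with a sigmoid head); this translation exists
// because training iterates thousands of small dense forward/backward
// passes, which is dominated by interpreter overhead in R. All randomness
// (sample order, dropout masks) is drawn from R's RNG so runs are
// reproducible from set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;

struct Conv {
  mat W, aSrc, aDst, V;
  vec b, c;
};
struct Dense {
  mat W;
  vec b;
};

struct ConvCache {
  mat X, Z, U;
  std::vector<mat> A, D, lgrad;
};
struct RegCache {
  mat H, U;
};

static std::vector<Conv> parseConv(const List& conv) {
  std::vector<Conv> out;
  for (int l = 0; l < conv.size(); ++l) {
    List L = conv[l];
    Conv c;
    c.W = as<mat>(L["W"]);
    c.aSrc = as<mat>(L["aSrc"]);
    c.aDst = as<mat>(L["aDst"]);
    c.V = as<mat>(L["V"]);
    c.b = as<vec>(L["b"]);
    c.c = as<vec>(L["c"]);
    out.push_back(c);
  }
  return out;
}

static std::vector<Dense> parseReg(const List& reg) {
  std::vector<Dense> out;
  for (int l = 0; l < reg.size(); ++l) {
    List L = reg[l];
    Dense d;
    d.W = as<mat>(L["W"]);
    d.b = as<vec>(L["b"]);
    out.push_back(d);
  }
  return out;
}

static List convToList(const std::vector<Conv>& conv) {
  List out(conv.size());
  for (size_t l = 0; l < conv.size(); ++l) {
    out[l] = List::create(_["W"] = conv[l].W, _["aSrc"] = conv[l].aSrc,
                          _["aDst"] = conv[l].aDst, _["b"] = conv[l].b,
                          _["V"] = conv[l].V, _["c"] = conv[l].c);
  }
  return out;
}

static List regToList(const std::vector<Dense>& reg) {
  List out(reg.size());
  for (size_t l = 0; l < reg.size(); ++l) {
    out[l] = List::create(_["W"] = reg[l].W, _["b"] = reg[l].b);
  }
  return out;
}

static mat elu(const mat& x) {
  mat y = x;
  y.transform([](double v) { return v > 0 ? v : std::exp(v) - 1.0; });
  return y;
}

static mat eluDeriv(const mat& x) {
  mat y = x;
  y.transform([](double v) { return v > 0 ? 1.0 : std::exp(v); });
  return y;
}

// forward pass; fills caches when they are supplied (training)
static vec gatForward(const std::vector<Conv>& conv,
                      const std::vector<Dense>& reg, const mat& X0,
                      const arma::umat& mask, const IntegerVector& channels,
                      int H, double slope, double dropout, bool training,
                      std::vector<ConvCache>* cc, std::vector<RegCache>* rc) {
  const int N = X0.n_rows;
  mat X = X0;
  for (size_t l = 0; l < conv.size(); ++l) {
    const Conv& L = conv[l];
    const int C = channels[l];
    mat Z = X * L.W;
    mat O(N, C * H, arma::fill::zeros);
    ConvCache cache;
    if (cc) {
      cache.X = X;
      cache.Z = Z;
    }
    for (int h = 0; h < H; ++h) {
      mat Zh = Z.cols(h * C, h * C + C - 1);
      vec f = Zh * L.aSrc.col(h);
      vec g = Zh * L.aDst.col(h);
      mat A(N, N, arma::fill::zeros);
      mat lg;
      if (cc) lg.zeros(N, N);
      for (int i = 0; i < N; ++i) {
        double mx = -arma::datum::inf;
        for (int j = 0; j < N; ++j) {
          if (!mask(i, j)) continue;
          double e = f[i] + g[j];
          double pre = e > 0 ? e : slope * e;
          A(i, j) = pre;
          if (cc) lg(i, j) = e > 0 ? 1.0 : slope;
          if (pre > mx) mx = pre;
        }
        double s = 0;
        for (int j = 0; j < N; ++j) {
          if (!mask(i, j)) continue;
          double w = std::exp(A(i, j) - mx);
          A(i, j) = w;
          s += w;
        }
        for (int j = 0; j < N; ++j) {
          if (mask(i, j)) A(i, j) /= s;
        }
      }
      mat Ad;
      mat D;
      if (training && dropout > 0) {
        D.set_size(N, N);
        const double keep = 1.0 - dropout;
        for (arma::uword k = 0; k < D.n_elem; ++k) {
          D[k] = (R::unif_rand() >= dropout) ? 1.0 / keep : 0.0;
        }
        Ad = A % D;
      } else {
        Ad = A;
      }
      O.cols(h * C, h * C + C - 1) = Ad * Zh;
      if (cc) {
        cache.A.push_back(A);
        cache.D.push_back(D);
        cache.lgrad.push_back(lg);
      }
    }
    mat U = O + X * L.V;
    U.each_row() += L.b.t() + L.c.t();
    if (cc) {
      cache.U = U;
      cc->push_back(cache);
    }
    X = elu(U);
  }
  mat Hn = X;
  for (size_t j = 0; j < reg.size(); ++j) {
    mat U = Hn * reg[j].W;
    U.each_row() += reg[j].b.t();
    if (rc) {
      RegCache r;
      r.H = Hn;
      r.U = U;
      rc->push_back(r);
    }
    Hn = (j + 1 < reg.size()) ? elu(U) : U;
  }
  return 1.0 / (1.0 + arma::exp(-Hn.col(0)));
}

// gradients of mean((p - y)^2); mirrors the backward derivation in R/nnet.R
static void gatBackward(const std::vector<Conv>& conv,
                        const std::vector<Dense>& reg,
                        const std::vector<ConvCache>& cc,
                        const std::vector<RegCache>& rc, const vec& p,
                        const vec& y, const IntegerVector& channels, int H,
                        std::vector<Conv>& gConv, std::vector<Dense>& gReg) {
  const int N = y.n_elem;
  mat dU = mat(2.0 / N * (p - y) % p % (1.0 - p));
  mat dY;
  for (int j = (int) reg.size() - 1; j >= 0; --j) {
    gReg[j].W = rc[j].H.t() * dU;
    gReg[j].b = arma::sum(dU, 0).t();
    if (j > 0) {
      mat dH = dU * reg[j].W.t();
      dU = dH % eluDeriv(rc[j - 1].U);
    } else {
      dY = dU * reg[0].W.t();
    }
  }
  for (int l = (int) conv.size() - 1; l >= 0; --l) {
    const Conv& L = conv[l];
    const ConvCache& c = cc[l];
    const int C = channels[l];
    mat dUc = dY % eluDeriv(c.U);
    gConv[l].b = arma::sum(dUc, 0).t();
    gConv[l].c = gConv[l].b;
    gConv[l].V = c.X.t() * dUc;
    mat dXlin = dUc * L.V.t();
    mat dZ(c.Z.n_rows, c.Z.n_cols, arma::fill::zeros);
    gConv[l].aSrc.zeros(C, H);
    gConv[l].aDst.zeros(C, H);
    for (int h = 0; h < H; ++h) {
      mat Zh = c.Z.cols(h * C, h * C + C - 1);
      mat dOh = dUc.cols(h * C, h * C + C - 1);
      mat dAd = dOh * Zh.t();
      mat Ad = c.D[h].n_elem ? mat(c.A[h] % c.D[h]) : c.A[h];
      mat dZh = Ad.t() * dOh;
      mat dA = c.D[h].n_elem ? mat(dAd % c.D[h]) : dAd;
      vec rs = arma::sum(c.A[h] % dA, 1);
      mat dPre = c.A[h] % (dA.each_col() - rs);
      mat dE = dPre % c.lgrad[h];
      vec df = arma::sum(dE, 1);
      vec dg = arma::sum(dE, 0).t();
      dZh += df * L.aSrc.col(h).t() + dg * L.aDst.col(h).t();
      gConv[l].aSrc.col(h) = Zh.t() * df;
      gConv[l].aDst.col(h) = Zh.t() * dg;
      dZ.cols(h * C, h * C + C - 1) = dZh;
    }
    gConv[l].W = c.X.t() * dZ;
    dY = dZ * L.W.t() + dXlin;
  }
}

// evaluation-mode forward pass
// [[Rcpp::export]]
NumericVector cpp_gat_forward(List conv, List reg, arma::mat X,
                              arma::umat mask, IntegerVector channels,
                              int heads, double slope) {
  std::vector<Conv> cv = parseConv(conv);
  std::vector<Dense> rg = parseReg(reg);
  vec p = gatForward(cv, rg, X, mask, channels, heads, slope, 0.0, false,
                     nullptr, nullptr);
  return wrap(p);
}

// evaluation-mode gradients (no dropout), used for gradient checking
// [[Rcpp::export]]
List cpp_gat_grad(List conv, List reg, arma::mat X, arma::umat mask,
                  arma::vec y, IntegerVector channels, int heads,
                  double slope) {
  std::vector<Conv> cv = parseConv(conv);
  std::vector<Dense> rg = parseReg(reg);
  std::vector<ConvCache> cc;
  std::vector<RegCache> rc;
  vec p = gatForward(cv, rg, X, mask, channels, heads, slope, 0.0, false,
                     &cc, &rc);
  std::vector<Conv> gConv(cv.size());
  std::vector<Dense> gReg(rg.size());
  gatBackward(cv, rg, cc, rc, p, y, channels, heads, gConv, gReg);
  return List::create(_["conv"] = convToList(gConv),
                      _["reg"] = regToList(gReg),
                      _["loss"] = arma::mean(arma::square(p - y)));
}

// full training loop: Adam on mean squared error, one graph per step.
// tensors is a list of list(X, mask, y); RNG state comes from R.
// [[Rcpp::export]]
List cpp_gat_train(List conv, List reg, List tensors, IntegerVector channels,
                   int heads, double slope, double dropout, double lr,
                   int epochs) {
  std::vector<Conv> cv = parseConv(conv);
  std::vector<Dense> rg = parseReg(reg);
  const int nS = tensors.size();

  std::vector<mat> Xs;
  std::vector<arma::umat> masks;
  std::vector<vec> ys;
  for (int i = 0; i < nS; ++i) {
    List t = tensors[i];
    Xs.push_back(as<mat>(t["X"]));
    masks.push_back(as<arma::umat>(t["mask"]));
    ys.push_back(as<vec>(t["y"]));
  }

  // Adam state, zero-initialised with the parameter shapes
  std::vector<Conv> mC(cv.size()), vC(cv.size());
  std::vector<Dense> mR(rg.size()), vR(rg.size());
  for (size_t l = 0; l < cv.size(); ++l) {
    mC[l].W.zeros(arma::size(cv[l].W));
    mC[l].aSrc.zeros(arma::size(cv[l].aSrc));
    mC[l].aDst.zeros(arma::size(cv[l].aDst));
    mC[l].V.zeros(arma::size(cv[l].V));
    mC[l].b.zeros(cv[l].b.n_elem);
    mC[l].c.zeros(cv[l].c.n_elem);
    vC[l] = mC[l];
  }
  for (size_t l = 0; l < rg.size(); ++l) {
    mR[l].W.zeros(arma::size(rg[l].W));
    mR[l].b.zeros(rg[l].b.n_elem);
    vR[l] = mR[l];
  }

  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
  NumericVector lossHist(epochs);

  auto adam = [&](mat& p, const mat& g, mat& m, mat& v, double c1, double c2) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    p -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
  };
  auto adamVec = [&](vec& p, const vec& g, vec& m, vec& v, double c1,
                     double c2) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    p -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
  };

  for (int epoch = 0; epoch < epochs; ++epoch) {
    IntegerVector ord = Rcpp::sample(nS, nS, false);
    double tot = 0;
    for (int oi = 0; oi < nS; ++oi) {
      const int i = ord[oi] - 1;
      std::vector<ConvCache> cc;
      std::vector<RegCache> rc;
      vec p = gatForward(cv, rg, Xs[i], masks[i], channels, heads, slope,
                         dropout, true, &cc, &rc);
      tot += arma::mean(arma::square(p - ys[i]));
      std::vector<Conv> gConv(cv.size());
      std::vector<Dense> gReg(rg.size());
      gatBackward(cv, rg, cc, rc, p, ys[i], channels, heads, gConv, gReg);
      ++step;
      const double c1 = 1 - std::pow(b1, (double) step);
      const double c2 = 1 - std::pow(b2, (double) step);
      for (size_t l = 0; l < cv.size(); ++l) {
        adam(cv[l].W, gConv[l].W, mC[l].W, vC[l].W, c1, c2);
        adam(cv[l].aSrc, gConv[l].aSrc, mC[l].aSrc, vC[l].aSrc, c1, c2);
        adam(cv[l].aDst, gConv[l].aDst, mC[l].aDst, vC[l].aDst, c1, c2);
        adam(cv[l].V, gConv[l].V, mC[l].V, vC[l].V, c1, c2);
        adamVec(cv[l].b, gConv[l].b, mC[l].b, vC[l].b, c1, c2);
        adamVec(cv[l].c, gConv[l].c, mC[l].c, vC[l].c, c1, c2);
      }
      for (size_t l = 0; l < rg.size(); ++l) {
        adam(rg[l].W, gReg[l].W, mR[l].W, vR[l].W, c1, c2);
        adamVec(rg[l].b, gReg[l].b, mR[l].b, vR[l].b, c1, c2);
      }
    }
    lossHist[epoch] = tot / nS;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["conv"] = convToList(cv), _["reg"] = regToList(rg),
                      _["loss"] = lossHist);
}
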