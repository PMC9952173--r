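// Batched forward / backward kernels for the spatial-temporal transformer.
// Layout conventions:
//   feats cube: featChannels x d x N (one slice per epoch, RMS-normalized)
//   big matrices stack epochs row-block-wise: rows [n*C, (n+1)*C) of M hold
//   epoch n's feature matrix; same for the patch stage with f2 rows/epoch.
//   Dropout masks arrive pre-scaled by 1/(1-p) in the same big layout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static const double POOL_EPS = 1e-8;  // must match the R head
static const double LN_EPS = 1e-5;

struct Dims {
  int d, k1, f1, f2, k2, h, C, L1, L2;
};

static Dims readDims(const List& dimsL) {
  Dims dm;
  dm.d = as<int>(dimsL["d"]);
  dm.k1 = as<int>(dimsL["conv1Kernel"]);
  dm.f1 = as<int>(dimsL["conv1Filters"]);
  dm.f2 = as<int>(dimsL["conv2Filters"]);
  dm.k2 = as<int>(dimsL["conv2Stride"]);
  dm.h = as<int>(dimsL["heads"]);
  dm.C = as<int>(dimsL["featChannels"]);
  dm.L1 = dm.d - dm.k1 + 1;
  dm.L2 = dm.L1 / dm.k2;
  if (dm.L1 <= 0 || dm.L1 % dm.k2 != 0 || dm.f2 != 2 * dm.h)
    stop("inconsistent architecture dimensions");
  return dm;
}

static void softmaxRowsInPlace(mat& x) {
  for (uword i = 0; i < x.n_rows; ++i) {
    rowvec r = x.row(i);
    r -= r.max();
    r = exp(r);
    x.row(i) = r / accu(r);
  }
}

// core worker: forward always; backward when grads is non-null
static double run(const List& params, const cube& feats, const ivec& y,
                  const mat* maskB, const mat* maskF, const Dims& dm,
                  mat& probs, List* grads) {
  const mat Wq = params["Wq"], Wk = params["Wk"], Wv = params["Wv"];
  const mat c1W = params["c1W"];
  const vec c1b = params["c1b"];
  const mat c2W = params["c2W"];
  const vec c2b = params["c2b"];
  const cube Wtq = params["Wtq"], Wtk = params["Wtk"], Wtv = params["Wtv"];
  const mat Wo = params["Wo"];
  const vec gamma = params["gamma"], beta = params["beta"];
  const mat fcW = params["fcW"];
  const vec fcb = params["fcb"];

  const int N = feats.n_slices, C = dm.C, d = dm.d, f1 = dm.f1, f2 = dm.f2;
  const int k1 = dm.k1, k2 = dm.k2, h = dm.h, L1 = dm.L1, L2 = dm.L2;
  const double sqd = std::sqrt((double)d), sqL2 = std::sqrt((double)L2);
  const bool wantGrad = grads != nullptr;
  const bool training = maskB != nullptr;

  mat M(C * N, d);
  for (int n = 0; n < N; ++n) M.rows(n * C, n * C + C - 1) = feats.slice(n);

  mat Q = M * Wq.t(), K = M * Wk.t(), V = M * Wv.t();
  mat Bd(C * N, d);
  cube Aatt(C, C, wantGrad ? N : 0);
  for (int n = 0; n < N; ++n) {
    const int r0 = n * C, r1 = r0 + C - 1;
    mat sc = Q.rows(r0, r1) * K.rows(r0, r1).t() / sqd;
    softmaxRowsInPlace(sc);
    if (wantGrad) Aatt.slice(n) = sc;
    Bd.rows(r0, r1) = sc * V.rows(r0, r1);
  }
  if (training) Bd %= *maskB;

  // The two convolutions compose into one linear map: conv2's stride equals
  // its kernel width, so patch (f, t) sees input columns [t*k2, t*k2+K) with
  // K = k1 + k2 - 1, weighted by the convolution of the two kernels. Fold
  // them into an effective kernel Weff (f2 x C*K) and bias, and run the
  // embedding as one GEMM per epoch over an im2col gather of Bd.
  const int ncolW = f1 * C * k2;
  const int Kw = k1 + k2 - 1;
  mat Weff(f2, C * Kw, fill::zeros);
  vec biasEff = c2b;
  for (int u2 = 0; u2 < k2; ++u2)
    for (int ch = 0; ch < C; ++ch)
      for (int dd = 0; dd < f1; ++dd) {
        const int wcol = dd + f1 * ch + f1 * C * u2;
        for (int f = 0; f < f2; ++f) {
          const double w2 = c2W(f, wcol);
          for (int u1 = 0; u1 < k1; ++u1)
            Weff(f, ch * Kw + u1 + u2) += w2 * c1W(u1, dd);
          biasEff(f) += w2 * c1b(dd);
        }
      }
  mat Pbig(f2 * N, L2);
  auto gatherX = [&](int n, mat& X) {
    for (int ch = 0; ch < C; ++ch) {
      const int br = n * C + ch;
      for (int t = 0; t < L2; ++t)
        for (int u = 0; u < Kw; ++u)
          X(ch * Kw + u, t) = Bd(br, t * k2 + u);
    }
  };
  mat Xtmp(C * Kw, L2);
  for (int n = 0; n < N; ++n) {
    gatherX(n, Xtmp);
    Pbig.rows(n * f2, n * f2 + f2 - 1) = Weff * Xtmp;
    Pbig.rows(n * f2, n * f2 + f2 - 1).each_col() += biasEff;
  }

  // temporal multi-head attention
  mat Fbig(f2 * N, L2), Ccbig(f2 * N, L2);
  cube A2all(2, 2, wantGrad ? (size_t)(h * N) : 0);
  for (int n = 0; n < N; ++n) {
    const int p0 = n * f2;
    mat Cc(f2, L2);
    for (int i = 0; i < h; ++i) {
      mat E = Pbig.rows(p0 + 2 * i, p0 + 2 * i + 1);
      mat Qi = Wtq.slice(i) * E, Ki = Wtk.slice(i) * E, Vi = Wtv.slice(i) * E;
      mat sc = Qi * Ki.t() / sqL2;
      softmaxRowsInPlace(sc);
      if (wantGrad) A2all.slice(n * h + i) = sc;
      Cc.rows(2 * i, 2 * i + 1) = sc * Vi;
    }
    Ccbig.rows(p0, p0 + f2 - 1) = Cc;
    Fbig.rows(p0, p0 + f2 - 1) = Wo * Cc;
  }
  if (training) Fbig %= *maskF;

  // pooled, normalized head
  mat Zs(f2, N), Ps(f2, N), Yv(f2, N), MS(f2, N);
  vec sigs(N);
  double loss = 0.0;
  for (int n = 0; n < N; ++n) {
    const int p0 = n * f2;
    vec ms(f2);
    for (int kk = 0; kk < f2; ++kk) {
      const rowvec r = Fbig.row(p0 + kk);
      ms(kk) = dot(r, r) / L2;
    }
    vec p = log(ms + POOL_EPS);
    const double mu = mean(p);
    const double sig = std::sqrt(mean(square(p - mu)) + LN_EPS);
    vec z = (p - mu) / sig;
    vec yv = gamma % z + beta;
    vec logits = fcW * yv + fcb;
    logits -= logits.max();
    vec e = exp(logits);
    vec pr = e / accu(e);
    probs.row(n) = pr.t();
    MS.col(n) = ms; Zs.col(n) = z; Yv.col(n) = yv; sigs(n) = sig;
    if (y.n_elem > 0) loss += -std::log(std::max(pr(y(n) - 1), 1e-300));
  }
  if (y.n_elem > 0) loss /= N;
  if (!wantGrad) return loss;

  // ------------------------------------------------------------- backward
  mat gWq(d, d, fill::zeros), gWk(d, d, fill::zeros), gWv(d, d, fill::zeros);
  mat gc1W(k1, f1, fill::zeros);
  vec gc1b(f1, fill::zeros);
  mat gc2W(f2, ncolW, fill::zeros);
  vec gc2b(f2, fill::zeros);
  cube gWtq(2, 2, h, fill::zeros), gWtk(2, 2, h, fill::zeros),
       gWtv(2, 2, h, fill::zeros);
  mat gWo(f2, f2, fill::zeros);
  vec ggamma(f2, fill::zeros), gbeta(f2, fill::zeros);
  mat gfcW(3, f2, fill::zeros);
  vec gfcb(3, fill::zeros);

  mat gWeff(f2, C * Kw, fill::zeros);
  vec gbiasEff(f2, fill::zeros);
  mat dBd(C * N, d, fill::zeros);
  mat dQ(C * N, d), dK(C * N, d), dV(C * N, d);

  mat dXtmp(C * Kw, L2);
  for (int n = 0; n < N; ++n) {
    const int p0 = n * f2;
    vec pr = probs.row(n).t();
    vec dlog = pr;
    dlog(y(n) - 1) -= 1.0;
    dlog /= N;
    gfcW += dlog * Yv.col(n).t();
    gfcb += dlog;
    vec dy = fcW.t() * dlog;
    ggamma += dy % Zs.col(n);
    gbeta += dy;
    vec dz = dy % gamma;
    vec z = Zs.col(n);
    vec dp = (dz - mean(dz) - z * mean(dz % z)) / sigs(n);
    vec dms = dp / (MS.col(n) + POOL_EPS);

    mat dFd(f2, L2);
    for (int kk = 0; kk < f2; ++kk)
      dFd.row(kk) = Fbig.row(p0 + kk) * (2.0 / L2 * dms(kk));
    if (training) dFd %= maskF->rows(p0, p0 + f2 - 1);

    gWo += dFd * Ccbig.rows(p0, p0 + f2 - 1).t();
    mat dCc = Wo.t() * dFd;

    mat dP0(f2, L2);
    for (int i = 0; i < h; ++i) {
      mat E = Pbig.rows(p0 + 2 * i, p0 + 2 * i + 1);
      mat Ki = Wtk.slice(i) * E, Qi = Wtq.slice(i) * E, Vi = Wtv.slice(i) * E;
      mat A2 = A2all.slice(n * h + i);
      mat dHi = dCc.rows(2 * i, 2 * i + 1);
      mat dA2 = dHi * Vi.t();
      mat dVi = A2.t() * dHi;
      mat dsc(2, 2);
      for (int r = 0; r < 2; ++r) {
        rowvec a = A2.row(r);
        rowvec t = dA2.row(r);
        dsc.row(r) = a % (t - dot(t, a));
      }
      mat dQi = dsc * Ki / sqL2;
      mat dKi = dsc.t() * Qi / sqL2;
      gWtq.slice(i) += dQi * E.t();
      gWtk.slice(i) += dKi * E.t();
      gWtv.slice(i) += dVi * E.t();
      dP0.rows(2 * i, 2 * i + 1) = Wtq.slice(i).t() * dQi +
        Wtk.slice(i).t() * dKi + Wtv.slice(i).t() * dVi;
    }

    // patch-embedding backward through the effective kernel
    gatherX(n, Xtmp);
    gWeff += dP0 * Xtmp.t();
    gbiasEff += sum(dP0, 1);
    dXtmp = Weff.t() * dP0;
    for (int ch = 0; ch < C; ++ch) {
      const int br = n * C + ch;
      for (int t = 0; t < L2; ++t)
        for (int u = 0; u < Kw; ++u)
          dBd(br, t * k2 + u) += dXtmp(ch * Kw + u, t);
    }
  }

  // chain rule from the effective kernel/bias to the two conv layers:
  //   Weff(f, ch*K + u1+u2) = sum_dd c2W(f, dd + f1*ch + f1*C*u2) c1W(u1, dd)
  //   biasEff(f) = c2b(f) + sum_{dd,ch,u2} c2W(f, ...) c1b(dd)
  for (int u2 = 0; u2 < k2; ++u2)
    for (int ch = 0; ch < C; ++ch)
      for (int dd = 0; dd < f1; ++dd) {
        const int wcol = dd + f1 * ch + f1 * C * u2;
        for (int f = 0; f < f2; ++f) {
          const double w2 = c2W(f, wcol);
          double acc2 = gbiasEff(f) * c1b(dd);
          for (int u1 = 0; u1 < k1; ++u1) {
            const double ge = gWeff(f, ch * Kw + u1 + u2);
            acc2 += ge * c1W(u1, dd);
            gc1W(u1, dd) += ge * w2;
          }
          gc2W(f, wcol) += acc2;
          gc1b(dd) += gbiasEff(f) * w2;
        }
      }
  gc2b = gbiasEff;
  if (training) dBd %= *maskB;

  // spatial attention backward (input gradient below CSP is not needed)
  for (int n = 0; n < N; ++n) {
    const int r0 = n * C, r1 = r0 + C - 1;
    mat dBs = dBd.rows(r0, r1);
    mat A = Aatt.slice(n);
    mat dA = dBs * V.rows(r0, r1).t();
    dV.rows(r0, r1) = A.t() * dBs;
    mat dsc(C, C);
    for (int i = 0; i < C; ++i) {
      rowvec a = A.row(i);
      rowvec t = dA.row(i);
      dsc.row(i) = a % (t - dot(t, a));
    }
    dQ.rows(r0, r1) = dsc * K.rows(r0, r1) / sqd;
    dK.rows(r0, r1) = dsc.t() * Q.rows(r0, r1) / sqd;
  }
  gWq = dQ.t() * M;
  gWk = dK.t() * M;
  gWv = dV.t() * M;

  *grads = List::create(
    Named("Wq") = gWq, Named("Wk") = gWk, Named("Wv") = gWv,
    Named("c1W") = gc1W, Named("c1b") = gc1b,
    Named("c2W") = gc2W, Named("c2b") = gc2b,
    Named("Wtq") = gWtq, Named("Wtk") = gWtk, Named("Wtv") = gWtv,
    Named("Wo") = gWo, Named("gamma") = ggamma, Named("beta") = gbeta,
    Named("fcW") = gfcW, Named("fcb") = gfcb);
  return loss;
}

// [[Rcpp::export]]
arma::mat tstn_forward_cpp(List params, arma::cube feats, List dims) {
  Dims dm = readDims(dims);
  mat probs(feats.n_slices, 3);
  ivec y;
  run(params, feats, y, nullptr, nullptr, dm, probs, nullptr);
  return probs;
}

// [[Rcpp::export]]
List tstn_loss_cpp(List params, arma::cube feats, arma::ivec y, List dims) {
  Dims dm = readDims(dims);
  mat probs(feats.n_slices, 3);
  double loss = run(params, feats, y, nullptr, nullptr, dm, probs, nullptr);
  return List::create(Named("loss") = loss, Named("probs") = probs);
}

// [[Rcpp::export]]
List tstn_fwd_bwd_cpp(List params, arma::cube feats, arma::ivec y,
                      arma::mat maskB, arma::mat maskF, List dims) {
  Dims dm = readDims(dims);
  mat probs(feats.n_slices, 3);
  List grads;
  double loss = run(params, feats, y, &maskB, &maskF, dm, probs, &grads);
  return List::create(Named("loss") = loss, Named("probs") = probs,
                      Named("grads") = grads);
}

// In-place Adam update: params, m and v are modified without copying.
// Caller owns all three lists (they are never user-visible aliases).
// [[Rcpp::export]]
void adam_step_cpp(List params, List grads, List m, List v,
                   double lr, double b1, double b2, double eps, int t) {
  CharacterVector nms = params.names();
  const double c1 = 1.0 - std::pow(b1, t);
  const double c2 = 1.0 - std::pow(b2, t);
  for (int i = 0; i < nms.size(); ++i) {
    std::string nm = as<std::string>(nms[i]);
    NumericVector p = params[nm], g = grads[nm], mm = m[nm], vv = v[nm];
    const R_xlen_t n = p.size();
    for (R_xlen_t j = 0; j < n; ++j) {
      mm[j] = b1 * mm[j] + (1.0 - b1) * g[j];
      vv[j] = b2 * vv[j] + (1.0 - b2) * g[j] * g[j];
      p[j] -= lr * (mm[j] / c1) / (std::sqrt(vv[j] / c2) + eps);
    }
  }
}
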