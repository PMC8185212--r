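// Fast path for the gated graph attention network: full forward and
// analytic backward pass over one interface graph.  Mirrors the reference
// R implementation (R/gat.R, R/network.R) exactly; the R path stays the
// documentation-grade reference and the two are compared in the tests.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOGIT_CLIP = 50.0;

struct GatCache {
  mat H, Xp, P, a, A, Xagg, out;
  umat sup, clip;
  vec cg;
};

struct GatGrad {
  mat dH, dW, dE, dA;
  vec dD;
  double db;
};

static GatCache gat_forward(const mat& H, const mat& A, const umat& sup,
                            const mat& W, const mat& E, const vec& D,
                            double b) {
  GatCache c;
  c.H = H;
  c.A = A;
  c.sup = sup;
  c.Xp = H * W.t();
  mat S = c.Xp * E * c.Xp.t();
  mat L = S + S.t();
  c.clip = abs(L) > LOGIT_CLIP;
  L = clamp(L, -LOGIT_CLIP, LOGIT_CLIP);
  L.elem(find(sup == 0)).fill(-datum::inf);
  vec m = max(L, 1);
  mat Z = exp(L.each_col() - m);
  Z.elem(find(sup == 0)).zeros();
  c.P = Z.each_col() / sum(Z, 1);
  c.a = c.P % A;
  c.Xagg = c.a * c.Xp;
  vec z = join_rows(H, c.Xagg) * D + b;
  c.cg = 1.0 / (1.0 + exp(-z));
  c.out = H.each_col() % c.cg + c.Xagg.each_col() % (1.0 - c.cg);
  return c;
}

static GatGrad gat_backward(const mat& dOut, const GatCache& c,
                            const mat& W, const mat& E, const vec& D) {
  const uword F = c.H.n_cols;
  GatGrad g;
  vec dc = sum(dOut % (c.H - c.Xagg), 1);
  mat dH = dOut.each_col() % c.cg;
  mat dXagg = dOut.each_col() % (1.0 - c.cg);
  vec dz = dc % c.cg % (1.0 - c.cg);
  g.dD = join_rows(c.H, c.Xagg).t() * dz;
  g.db = accu(dz);
  mat dG = dz * D.t();
  dH += dG.cols(0, F - 1);
  dXagg += dG.cols(F, 2 * F - 1);
  mat da = dXagg * c.Xp.t();
  mat dXp = c.a.t() * dXagg;
  mat dP = da % c.A;
  g.dA = da % c.P;
  vec rs = sum(c.P % dP, 1);
  mat dL = c.P % (dP.each_col() - rs);
  dL.elem(find(c.clip == 1 || c.sup == 0)).zeros();
  mat dS = dL + dL.t();
  dXp += dS * c.Xp * E.t() + dS.t() * c.Xp * E;
  g.dE = c.Xp.t() * dS * c.Xp;
  g.dW = dXp.t() * c.H;
  g.dH = dH + dXp * W;
  return g;
}

static mat drop_mask(uword r, uword cidx, double p) {
  mat m(r, cidx);
  for (uword j = 0; j < cidx; ++j)
    for (uword i = 0; i < r; ++i)
      m(i, j) = (R::unif_rand() >= p) ? 1.0 / (1.0 - p) : 0.0;
  return m;
}

// forward + (optionally) backward on one graph.
// params: named list with Wemb, bemb, W<l>, E<l>, D<l>, b<l>, mu, sigma,
// Wf<k>, bf<k>.  crossD holds cross-molecular distances, non-finite
// (encoded as negative) entries mean "no cross pair".
// [[Rcpp::export(name = ".gdRunC")]]
Rcpp::List gd_run(const arma::mat& X, const arma::mat& A1,
                  const arma::mat& crossD, Rcpp::List params,
                  int nGat, int nFc, double dropout, bool training,
                  double label, bool wantGrad) {
  const mat Wemb = params["Wemb"];
  const vec bemb = params["bemb"];
  const double muP = params["mu"];
  double sigma = params["sigma"];
  if (sigma < 1e-6) sigma = 1e-6;
  const uword n = X.n_rows;
  const uword F = Wemb.n_rows;

  umat crossOk = (crossD >= 0);
  umat sup1 = (A1 > 0);
  umat sup2 = sup1 || crossOk;
  mat A2 = A1;
  uvec ic = find(crossOk);
  A2.elem(ic) = exp(-square(crossD.elem(ic) - muP) / sigma);

  std::vector<mat> Wl(nGat), El(nGat);
  std::vector<vec> Dl(nGat);
  std::vector<double> bl(nGat);
  for (int l = 0; l < nGat; ++l) {
    std::string s = std::to_string(l + 1);
    Wl[l] = Rcpp::as<mat>(params["W" + s]);
    El[l] = Rcpp::as<mat>(params["E" + s]);
    Dl[l] = Rcpp::as<vec>(params["D" + s]);
    bl[l] = Rcpp::as<double>(params["b" + s]);
  }
  std::vector<mat> Wf(nFc);
  std::vector<vec> bf(nFc);
  for (int k = 0; k < nFc; ++k) {
    std::string s = std::to_string(k + 1);
    Wf[k] = Rcpp::as<mat>(params["Wf" + s]);
    bf[k] = Rcpp::as<vec>(params["bf" + s]);
  }

  const double p = training ? dropout : 0.0;
  mat H = X * Wemb.t();
  H.each_row() += bemb.t();
  mat m0;
  if (p > 0) { m0 = drop_mask(n, F, p); H %= m0; }

  std::vector<GatCache> c1v(nGat), c2v(nGat);
  std::vector<mat> masks(nGat);
  for (int l = 0; l < nGat; ++l) {
    c2v[l] = gat_forward(H, A2, sup2, Wl[l], El[l], Dl[l], bl[l]);
    c1v[l] = gat_forward(H, A1, sup1, Wl[l], El[l], Dl[l], bl[l]);
    H = c2v[l].out - c1v[l].out;
    if (p > 0) { masks[l] = drop_mask(n, F, p); H %= masks[l]; }
  }
  vec g = sum(H, 0).t();

  std::vector<vec> zs(nFc), hs(nFc), fcmask(nFc);
  vec h = g;
  for (int k = 0; k < nFc; ++k) {
    vec z = Wf[k] * h + bf[k];
    zs[k] = z;
    if (k < nFc - 1) {
      h = clamp(z, 0.0, datum::inf);
      if (p > 0) {
        vec mk(h.n_elem);
        for (uword i = 0; i < h.n_elem; ++i)
          mk(i) = (R::unif_rand() >= p) ? 1.0 / (1.0 - p) : 0.0;
        fcmask[k] = mk;
        h %= mk;
      }
      hs[k] = h;
    } else {
      hs[k] = z;
    }
  }
  double logit = zs[nFc - 1](0);
  double prob = 1.0 / (1.0 + std::exp(-logit));

  Rcpp::List out = Rcpp::List::create(Rcpp::Named("prob") = prob,
                                      Rcpp::Named("logit") = logit);
  if (!wantGrad) return out;

  // ---- backward from d(loss)/d(logit) = prob - label ----
  double dlogit = prob - label;
  Rcpp::List gr;
  vec dh(1);
  dh(0) = dlogit;
  for (int k = nFc - 1; k >= 0; --k) {
    vec hin = (k == 0) ? g : hs[k - 1];
    vec dz = dh;
    if (k < nFc - 1) {
      if (p > 0) dz %= fcmask[k];
      dz %= conv_to<vec>::from(zs[k] > 0);
    }
    gr["Wf" + std::to_string(k + 1)] = mat(dz * hin.t());
    gr["bf" + std::to_string(k + 1)] = dz;
    dh = Wf[k].t() * dz;
  }
  mat dH = repmat(dh.t(), n, 1);
  double dmu = 0, dsigma = 0;
  for (int l = nGat - 1; l >= 0; --l) {
    if (p > 0) dH %= masks[l];
    GatGrad b2 = gat_backward(dH, c2v[l], Wl[l], El[l], Dl[l]);
    GatGrad b1 = gat_backward(-dH, c1v[l], Wl[l], El[l], Dl[l]);
    std::string s = std::to_string(l + 1);
    gr["W" + s] = mat(b2.dW + b1.dW);
    gr["E" + s] = mat(b2.dE + b1.dE);
    gr["D" + s] = vec(b2.dD + b1.dD);
    gr["b" + s] = b2.db + b1.db;
    if (!ic.is_empty()) {
      vec dA2 = b2.dA.elem(ic);
      vec A2v = A2.elem(ic);
      vec dd = crossD.elem(ic) - muP;
      dmu += accu(dA2 % A2v % (2.0 * dd) / sigma);
      dsigma += accu(dA2 % A2v % square(dd) / (sigma * sigma));
    }
    dH = b2.dH + b1.dH;
  }
  if (p > 0) dH %= m0;
  gr["mu"] = dmu;
  gr["sigma"] = dsigma;
  gr["Wemb"] = mat(dH.t() * X);
  gr["bemb"] = vec(sum(dH, 0).t());
  out["grads"] = gr;
  return out;
}
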