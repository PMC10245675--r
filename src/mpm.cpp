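// Marginal likelihood of the move-persistence mixed-effects model.
//
// Step process (planar km, fixed interval): s_j = gamma_j * s_{j-1} + e_j,
// e_j ~ N(0, sigma_p^2 I2), with
//   logit(gamma_j) = x_j' beta + b_k + eps_j,  eps_j ~ N(0, sigma_gamma^2),
//   b_k ~ N(0, sigma_b^2) one intercept per individual.
// The per-step latent eps is integrated by fixed Gauss-Hermite quadrature;
// the per-individual intercept by adaptive (mode-centred) Gauss-Hermite,
// with the mode found by an analytic-derivative Newton iteration.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double logsumexp(const std::vector<double>& v) {
  double m = v[0];
  for (size_t i = 1; i < v.size(); ++i) if (v[i] > m) m = v[i];
  double s = 0.0;
  for (size_t i = 0; i < v.size(); ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

struct Unit {
  std::vector<double> sx, sy, eta0;  // steps and fixed-effect predictor
  int n, ind;
};

static std::vector<Unit> buildUnits(const List& S, const List& X,
                                    const IntegerVector& ind,
                                    const NumericVector& beta) {
  int nu = S.size();
  std::vector<Unit> units(nu);
  for (int u = 0; u < nu; ++u) {
    NumericMatrix s = S[u];
    NumericMatrix x = X[u];
    int n = s.nrow(), p = x.ncol();
    Unit& U = units[u];
    U.n = n; U.ind = ind[u];
    U.sx.resize(n); U.sy.resize(n); U.eta0.resize(n);
    for (int j = 0; j < n; ++j) {
      U.sx[j] = s(j, 0); U.sy[j] = s(j, 1);
      double e = 0.0;
      for (int c = 0; c < p; ++c) e += x(j, c) * beta[c];
      U.eta0[j] = e;
    }
  }
  return units;
}

// conditional log-likelihood of individual k given intercept b, plus its
// first and second derivative in b (analytic, via the softmax over the
// step-level quadrature nodes); derivatives skipped when wantD is false.
static void condLogLik(const std::vector<Unit>& units, int k, double b,
                       double sigP, double sigG,
                       const NumericVector& ghx, const NumericVector& ghw,
                       bool wantD, double& ll, double& d1, double& d2) {
  const int Q = ghx.size();
  const double log2pis2 = std::log(2.0 * M_PI * sigP * sigP);
  const double inv_s2 = 1.0 / (sigP * sigP);
  const double sq2sg = M_SQRT2 * sigG;
  std::vector<double> lq(Q), aq(Q), apq(Q), lw(Q);
  for (int q = 0; q < Q; ++q) lw[q] = std::log(ghw[q]) - 0.5 * std::log(M_PI);
  ll = 0.0; d1 = 0.0; d2 = 0.0;
  for (size_t u = 0; u < units.size(); ++u) {
    const Unit& U = units[u];
    if (U.ind != k) continue;
    for (int j = 1; j < U.n; ++j) {
      double eta = U.eta0[j] + b;
      double px = U.sx[j - 1], py = U.sy[j - 1];
      double ox = U.sx[j], oy = U.sy[j];
      double p2 = px * px + py * py;
      for (int q = 0; q < Q; ++q) {
        double g = 1.0 / (1.0 + std::exp(-(eta + sq2sg * ghx[q])));
        double rx = ox - g * px, ry = oy - g * py;
        lq[q] = lw[q] - log2pis2 - 0.5 * (rx * rx + ry * ry) * inv_s2;
        if (wantD) {
          double gp = g * (1.0 - g);          // dgamma/deta
          double rp = rx * px + ry * py;      // (s_j - g p) . p
          aq[q] = rp * gp * inv_s2;
          double gpp = gp * (1.0 - 2.0 * g);  // d2gamma/deta2
          apq[q] = (-gp * gp * p2 + rp * gpp) * inv_s2;
        }
      }
      double lse = logsumexp(lq);
      ll += lse;
      if (wantD) {
        double m1 = 0.0, m2 = 0.0;
        for (int q = 0; q < Q; ++q) {
          double w = std::exp(lq[q] - lse);
          m1 += w * aq[q];
          m2 += w * (apq[q] + aq[q] * aq[q]);
        }
        d1 += m1;
        d2 += m2 - m1 * m1;
      }
    }
  }
}

// [[Rcpp::export(name = ".mpm_nll")]]
List mpm_nll(NumericVector theta, List S, List X, IntegerVector ind,
             int nInd, NumericVector ghx, NumericVector ghw,
             NumericVector ghxB, NumericVector ghwB,
             NumericVector bstart) {
  int p = theta.size() - 3;
  NumericVector beta(theta.begin(), theta.begin() + p);
  double sigP = std::exp(theta[p]);
  double sigB = std::exp(theta[p + 1]);
  double sigG = std::exp(theta[p + 2]);
  std::vector<Unit> units = buildUnits(S, X, ind, beta);

  const int QB = ghxB.size();
  NumericVector bhat(nInd), bsd(nInd);
  double nll = 0.0;
  const double pr_c = -0.5 * std::log(2.0 * M_PI * sigB * sigB);
  const double inv_b2 = 1.0 / (sigB * sigB);
  for (int k = 0; k < nInd; ++k) {
    double b = (bstart.size() == nInd) ? bstart[k] : 0.0;
    double ll, d1, d2, g0 = 0.0;
    for (int it = 0; it < 50; ++it) {
      condLogLik(units, k, b, sigP, sigG, ghx, ghw, true, ll, d1, d2);
      double gd1 = d1 - b * inv_b2;
      double gd2 = d2 - inv_b2;          // <= -1/sigB^2 unless pathological
      g0 = ll + pr_c - 0.5 * b * b * inv_b2;
      double step = (gd2 < -1e-12) ? -gd1 / gd2
        : ((gd1 > 0 ? 1.0 : -1.0) * std::min(1.0, std::fabs(gd1)));
      if (step > 1.5) step = 1.5;
      if (step < -1.5) step = -1.5;
      if (std::fabs(step) < 1e-8) break;
      b += step;
    }
    condLogLik(units, k, b, sigP, sigG, ghx, ghw, true, ll, d1, d2);
    g0 = ll + pr_c - 0.5 * b * b * inv_b2;
    double gd2 = d2 - inv_b2;
    if (gd2 >= -1e-10) gd2 = -inv_b2;
    double shat = std::sqrt(-1.0 / gd2);
    bhat[k] = b; bsd[k] = shat;
    // adaptive Gauss-Hermite around the mode
    std::vector<double> terms(QB);
    double du1, du2;
    for (int m = 0; m < QB; ++m) {
      double gv;
      if (ghxB[m] == 0.0) gv = g0;
      else {
        double bm = b + M_SQRT2 * shat * ghxB[m];
        condLogLik(units, k, bm, sigP, sigG, ghx, ghw, false, gv, du1, du2);
        gv += pr_c - 0.5 * bm * bm * inv_b2;
      }
      terms[m] = std::log(ghwB[m]) + ghxB[m] * ghxB[m] + gv;
    }
    nll -= 0.5 * std::log(2.0) + std::log(shat) + logsumexp(terms);
  }
  return List::create(_["nll"] = nll, _["bhat"] = bhat, _["bsd"] = bsd);
}
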