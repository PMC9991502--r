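// Gibbs samplers for the sparse-factor whole-genome regression model and the
// univariate BayesC baseline. Single-site systematic-scan updates with
// incremental residual bookkeeping; all randomness comes from R's RNG so
// set.seed() in R makes runs reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double rinvgamma(double shape, double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// One spike-slab site update. `xty` must include the add-back of the current
// coefficient (i.e. x' r with r the residual excluding this coefficient).
// Returns the new coefficient; sets `ind`. When xtx = 0 the Bayes factor is
// exactly 1 and the indicator follows the prior odds.
static inline double spike_slab_site(double xtx, double xty, double s2e,
                                     double s2b, double pi, int &ind) {
  if (pi >= 1.0) { ind = 0; return 0.0; }
  double v = 1.0 / (xtx / s2e + 1.0 / s2b);
  double m = v * xty / s2e;
  double pIncl;
  if (pi <= 0.0) {
    pIncl = 1.0;
  } else {
    double logBF = 0.5 * std::log(v / s2b) + 0.5 * m * m / v;
    // P(include) = (1-pi) BF / ((1-pi) BF + pi)
    double logOdds = std::log1p(-pi) - std::log(pi) + logBF;
    pIncl = 1.0 / (1.0 + std::exp(-logOdds));
  }
  if (unif_rand() < pIncl) {
    ind = 1;
    return m + norm_rand() * std::sqrt(v);
  }
  ind = 0;
  return 0.0;
}

// [[Rcpp::export]]
List mega_gibbs_cpp(arma::mat Y, arma::umat Ymiss, arma::mat X1, arma::mat X2F,
                    arma::mat X2R,
                    arma::mat F, arma::mat Lambda, arma::umat LambdaInd,
                    arma::mat B1, arma::mat B2F, arma::umat B2FInd,
                    arma::mat B2R, arma::umat B2RInd,
                    arma::vec sigma2R, arma::vec sigma2B2F, arma::vec sigma2B2R,
                    arma::vec sigma2F, arma::vec delta,
                    arma::vec piLambda, arma::vec piF, arma::vec piR,
                    arma::umat LambdaFixed, arma::uvec freeSigma2F,
                    double aDelta, double bDelta, double aSigma, double bSigma,
                    double piLambdaA, double piLambdaB,
                    double piFA, double piFB, double piRA, double piRB,
                    double nuB2F, arma::vec scaleB2F,
                    double nuB2R, arma::vec scaleB2R,
                    bool samplePiF, bool samplePiLambda,
                    bool sampleSigma2R, bool sampleSigma2B2F,
                    int focal, int nIter, int burnin, int thin, bool storeU) {
  const int n = Y.n_rows, t = Y.n_cols, K = F.n_cols;
  const int p = X2F.n_cols, pR = X2R.n_cols, b1 = X1.n_cols;
  const bool hasR = pR > 0;

  arma::vec xtx1 = arma::sum(arma::square(X1), 0).t();
  arma::vec xtxF = arma::sum(arma::square(X2F), 0).t();
  // For moderate p, precompute X'X so each factor's marker scan works on
  // p-dimensional cross-product updates instead of n-dimensional residual
  // reads (identical full conditionals, far less memory traffic).
  const bool useXtX = (p > 0) && (p <= 3000);
  arma::mat XtXF;
  if (useXtX) XtXF = X2F.t() * X2F;
  arma::vec xtxR = hasR ? arma::vec(arma::sum(arma::square(X2R), 0).t())
                        : arma::vec();

  // residuals: E = Y - X1 B1 - F Lambda - X2R B2R ; Fres = F - X2F B2F
  arma::mat E = Y - X1 * B1;
  if (K > 0) E -= F * Lambda;
  if (hasR) E -= X2R * B2R;
  arma::mat Fres = (K > 0) ? arma::mat(F - X2F * B2F) : arma::mat(n, 0);

  const int nStore = (nIter > burnin) ? (nIter - burnin) / thin : 0;
  arma::mat alphaFDraws(p, nStore), LambdaDraws(K * t, nStore),
      piFDraws(K, nStore), piLDraws(K, nStore), sigma2RDraws(t, nStore),
      deltaDraws(K, nStore);
  arma::mat uDraws(storeU ? n : 0, storeU ? nStore : 0);
  arma::vec genVarDraws(nStore), logJoint(nIter);
  arma::mat B2Fsum(p, std::max(K, 1), arma::fill::zeros);
  arma::mat B2Rsum(pR, hasR ? t : 0, arma::fill::zeros);
  arma::vec uSum(n, arma::fill::zeros);
  int stored = 0;

  arma::vec tau = (K > 0) ? arma::cumprod(delta) : arma::vec();

  for (int iter = 0; iter < nIter; ++iter) {
    // (a) fixed-effect coefficients, flat prior
    for (int j = 0; j < t; ++j) {
      for (int c = 0; c < b1; ++c) {
        if (xtx1(c) <= 0) continue;
        double xty = arma::dot(X1.col(c), E.col(j)) + xtx1(c) * B1(c, j);
        double mean = xty / xtx1(c);
        double newb = mean + norm_rand() * std::sqrt(sigma2R(j) / xtx1(c));
        E.col(j) -= X1.col(c) * (newb - B1(c, j));
        B1(c, j) = newb;
      }
    }

    if (K > 0) {
      tau = arma::cumprod(delta);
      arma::vec ftf = arma::sum(arma::square(F), 0).t();

      // (b) loadings, spike-slab with slab variance sigma2R_j / tau_k
      for (int k = 0; k < K; ++k) {
        for (int j = 0; j < t; ++j) {
          if (LambdaFixed(k, j)) continue;
          double old = Lambda(k, j);
          double xty = arma::dot(F.col(k), E.col(j)) + ftf(k) * old;
          int ind;
          double newl = spike_slab_site(ftf(k), xty, sigma2R(j),
                                        sigma2R(j) / tau(k), piLambda(k), ind);
          if (newl != old) E.col(j) -= F.col(k) * (newl - old);
          Lambda(k, j) = newl;
          LambdaInd(k, j) = ind;
        }
      }

      // (c) loading exclusion probabilities
      if (samplePiLambda) {
        for (int k = 0; k < K; ++k) {
          int nIn = 0, nFree = 0;
          for (int j = 0; j < t; ++j) {
            if (LambdaFixed(k, j)) continue;
            ++nFree;
            nIn += LambdaInd(k, j);
          }
          if (nFree > 0)
            piLambda(k) = R::rbeta(piLambdaA + (nFree - nIn), piLambdaB + nIn);
        }
      }

      // (d) multiplicative shrinkage chain (delta_1 = 1 fixed)
      for (int h = 1; h < K; ++h) {
        tau = arma::cumprod(delta);
        double shape = aDelta, rate = bDelta;
        for (int k = h; k < K; ++k) {
          double ss = 0.0; int mk = 0;
          for (int j = 0; j < t; ++j) {
            if (LambdaFixed(k, j) || !LambdaInd(k, j)) continue;
            ++mk;
            ss += Lambda(k, j) * Lambda(k, j) / sigma2R(j);
          }
          shape += 0.5 * mk;
          rate += 0.5 * (tau(k) / delta(h)) * ss;
        }
        delta(h) = R::rgamma(shape, 1.0 / rate);
      }
      tau = arma::cumprod(delta);

      // (e) factor scores, joint normal conditional per row
      arma::mat M = F - Fres;                       // X2F B2F, tracked
      arma::mat Eno = E + F * Lambda;               // residual without factors
      arma::mat P = arma::diagmat(1.0 / sigma2F) +
                    Lambda * arma::diagmat(1.0 / sigma2R) * Lambda.t();
      arma::mat RHS = Eno * arma::diagmat(1.0 / sigma2R) * Lambda.t() +
                      M * arma::diagmat(1.0 / sigma2F);
      arma::mat L = arma::chol(P, "lower");
      arma::mat Fmean = arma::solve(P, RHS.t()).t();
      arma::mat Z(n, K);
      for (arma::uword i = 0; i < Z.n_elem; ++i) Z(i) = norm_rand();
      // rows of Z * L^{-T} have covariance P^{-1}
      F = Fmean + arma::solve(arma::trimatu(L.t()), Z.t()).t();
      E = Eno - F * Lambda;
      Fres = F - M;

      // (f) factor marker effects, BayesC
      for (int k = 0; k < K; ++k) {
        double s2e = sigma2F(k), s2b = sigma2B2F(k), pik = piF(k);
        if (useXtX) {
          arma::vec d = X2F.t() * Fres.col(k);  // x_m' r for every marker
          std::vector<int> chgIdx; std::vector<double> chgDelta;
          for (int m = 0; m < p; ++m) {
            double old = B2F(m, k);
            double xty = d(m) + xtxF(m) * old;
            int ind;
            double newb = spike_slab_site(xtxF(m), xty, s2e, s2b, pik, ind);
            if (newb != old) {
              double dl = newb - old;
              d -= XtXF.col(m) * dl;
              chgIdx.push_back(m); chgDelta.push_back(dl);
            }
            B2F(m, k) = newb;
            B2FInd(m, k) = ind;
          }
          for (size_t c = 0; c < chgIdx.size(); ++c)
            Fres.col(k) -= X2F.col(chgIdx[c]) * chgDelta[c];
        } else {
          for (int m = 0; m < p; ++m) {
            double old = B2F(m, k);
            double xty = arma::dot(X2F.col(m), Fres.col(k)) + xtxF(m) * old;
            int ind;
            double newb = spike_slab_site(xtxF(m), xty, s2e, s2b, pik, ind);
            if (newb != old) Fres.col(k) -= X2F.col(m) * (newb - old);
            B2F(m, k) = newb;
            B2FInd(m, k) = ind;
          }
        }
      }

      // (g) marker-effect variances, inclusion probabilities, free factor
      // residual variances
      for (int k = 0; k < K; ++k) {
        int mk = arma::accu(B2FInd.col(k));
        if (sampleSigma2B2F) {
          double ssb = arma::dot(B2F.col(k), B2F.col(k));
          sigma2B2F(k) = rinvgamma(0.5 * (nuB2F + mk),
                                   0.5 * (nuB2F * scaleB2F(k) + ssb));
        }
        if (samplePiF) piF(k) = R::rbeta(piFA + (p - mk), piFB + mk);
        if (freeSigma2F(k))
          sigma2F(k) = rinvgamma(aSigma + 0.5 * n,
                                 bSigma + 0.5 * arma::dot(Fres.col(k), Fres.col(k)));
      }
    }

    // (h) trait-specific marker effects (optional)
    if (hasR) {
      for (int j = 0; j < t; ++j) {
        double s2e = sigma2R(j), s2b = sigma2B2R(j), pij = piR(j);
        for (int m = 0; m < pR; ++m) {
          double old = B2R(m, j);
          double xty = arma::dot(X2R.col(m), E.col(j)) + xtxR(m) * old;
          int ind;
          double newb = spike_slab_site(xtxR(m), xty, s2e, s2b, pij, ind);
          if (newb != old) E.col(j) -= X2R.col(m) * (newb - old);
          B2R(m, j) = newb;
          B2RInd(m, j) = ind;
        }
        int mj = arma::accu(B2RInd.col(j));
        double ssb = arma::dot(B2R.col(j), B2R.col(j));
        sigma2B2R(j) = rinvgamma(0.5 * (nuB2R + mj),
                                 0.5 * (nuB2R * scaleB2R(j) + ssb));
        piR(j) = R::rbeta(piRA + (pR - mj), piRB + mj);
      }
    }

    // (i) trait residual variances (loadings contribute through their
    // sigma2R-scaled slab)
    if (sampleSigma2R) {
      for (int j = 0; j < t; ++j) {
        double shape = aSigma + 0.5 * n, rate = bSigma + 0.5 * arma::dot(E.col(j), E.col(j));
        for (int k = 0; k < K; ++k) {
          if (LambdaFixed(k, j) || !LambdaInd(k, j)) continue;
          shape += 0.5;
          rate += 0.5 * tau(k) * Lambda(k, j) * Lambda(k, j);
        }
        sigma2R(j) = rinvgamma(shape, rate);
      }
    }

    // (j) impute missing trait values from their predictive normal
    for (int j = 0; j < t; ++j) {
      double sd = std::sqrt(sigma2R(j));
      for (int i = 0; i < n; ++i) {
        if (!Ymiss(i, j)) continue;
        double fitted = Y(i, j) - E(i, j);
        double eps = norm_rand() * sd;
        Y(i, j) = fitted + eps;
        E(i, j) = eps;
      }
    }

    // log joint (main Gaussian + mixture-prior terms), finiteness guard
    double lj = 0.0;
    for (int j = 0; j < t; ++j)
      lj += -0.5 * n * std::log(2 * M_PI * sigma2R(j)) -
            0.5 * arma::dot(E.col(j), E.col(j)) / sigma2R(j);
    for (int k = 0; k < K; ++k) {
      lj += -0.5 * n * std::log(2 * M_PI * sigma2F(k)) -
            0.5 * arma::dot(Fres.col(k), Fres.col(k)) / sigma2F(k);
      int mk = arma::accu(B2FInd.col(k));
      double ssb = arma::dot(B2F.col(k), B2F.col(k));
      lj += -0.5 * mk * std::log(2 * M_PI * sigma2B2F(k)) - 0.5 * ssb / sigma2B2F(k);
      if (piF(k) > 0 && piF(k) < 1)
        lj += mk * std::log1p(-piF(k)) + (p - mk) * std::log(piF(k));
      for (int j = 0; j < t; ++j) {
        if (LambdaFixed(k, j) || !LambdaInd(k, j)) continue;
        double s2 = sigma2R(j) / tau(k);
        lj += -0.5 * std::log(2 * M_PI * s2) -
              0.5 * Lambda(k, j) * Lambda(k, j) / s2;
      }
    }
    logJoint(iter) = lj;
    if (!std::isfinite(lj))
      stop("non-finite state at iteration %d", iter + 1);

    if (iter + 1 > burnin && (iter + 1 - burnin) % thin == 0 && stored < nStore) {
      arma::vec alphaF = (K > 0) ? arma::vec(B2F * Lambda.col(focal))
                                 : arma::vec(p, arma::fill::zeros);
      arma::vec u = X2F * alphaF;
      alphaFDraws.col(stored) = alphaF;
      if (storeU) uDraws.col(stored) = u;
      uSum += u;
      genVarDraws(stored) = (n > 1) ? arma::var(u) : 0.0;
      if (K > 0) {
        LambdaDraws.col(stored) = arma::vectorise(Lambda);
        piFDraws.col(stored) = piF;
        piLDraws.col(stored) = piLambda;
        deltaDraws.col(stored) = delta;
      }
      sigma2RDraws.col(stored) = sigma2R;
      if (K > 0) B2Fsum += B2F;
      if (hasR) B2Rsum += B2R;
      ++stored;
    }
  }

  List finalState = List::create(
      _["F"] = F, _["Lambda"] = Lambda, _["LambdaInd"] = LambdaInd,
      _["B1"] = B1, _["B2F"] = B2F, _["B2FInd"] = B2FInd, _["B2R"] = B2R,
      _["B2RInd"] = B2RInd, _["sigma2R"] = sigma2R,
      _["sigma2B2F"] = sigma2B2F, _["sigma2B2R"] = sigma2B2R,
      _["sigma2F"] = sigma2F, _["delta"] = delta, _["piLambda"] = piLambda,
      _["piF"] = piF, _["piR"] = piR, _["Ywork"] = Y);
  double denom = std::max(stored, 1);
  return List::create(
      _["alphaF"] = alphaFDraws, _["Lambda"] = LambdaDraws,
      _["genVar"] = genVarDraws, _["piF"] = piFDraws, _["piLambda"] = piLDraws,
      _["sigma2R"] = sigma2RDraws, _["delta"] = deltaDraws, _["u"] = uDraws,
      _["uMean"] = uSum / denom, _["B2FMean"] = B2Fsum / denom,
      _["B2RMean"] = B2Rsum / denom, _["logJoint"] = logJoint,
      _["finalState"] = finalState);
}

// Univariate BayesC: y = mu + X b + e, spike-slab on b with shared slab
// variance, sampled pi and variances.
// [[Rcpp::export]]
List st_bayesc_cpp(arma::vec y, arma::mat X, double nu, double scaleB,
                   double aSigma, double bSigma, double piA, double piB,
                   double piFix, int nIter, int burnin, int thin) {
  const int n = y.n_elem, p = X.n_cols;
  arma::vec xtx = arma::sum(arma::square(X), 0).t();
  const bool useXtX = (p > 0) && (p <= 3000);
  arma::mat XtX;
  if (useXtX) XtX = X.t() * X;
  double mu = arma::mean(y);
  arma::vec b(p, arma::fill::zeros);
  arma::ivec ind(p, arma::fill::zeros);
  arma::vec r = y - mu;
  double sigma2e = arma::var(r);
  if (sigma2e <= 0) stop("constant response");
  double sigma2b = scaleB;
  double pi = R_finite(piFix) ? piFix : 0.5;
  const int nStore = (nIter > burnin) ? (nIter - burnin) / thin : 0;
  arma::mat bDraws(p, nStore);
  arma::vec piDraws(nStore), s2eDraws(nStore), s2bDraws(nStore), muDraws(nStore);
  int stored = 0;
  for (int iter = 0; iter < nIter; ++iter) {
    // intercept, flat prior
    double muNew = arma::mean(r) + mu + norm_rand() * std::sqrt(sigma2e / n);
    r -= (muNew - mu);
    mu = muNew;
    if (useXtX) {
      arma::vec d = X.t() * r;
      std::vector<int> chgIdx; std::vector<double> chgDelta;
      for (int m = 0; m < p; ++m) {
        double old = b(m);
        double xty = d(m) + xtx(m) * old;
        int im;
        double newb = spike_slab_site(xtx(m), xty, sigma2e, sigma2b, pi, im);
        if (newb != old) {
          double dl = newb - old;
          d -= XtX.col(m) * dl;
          chgIdx.push_back(m); chgDelta.push_back(dl);
        }
        b(m) = newb;
        ind(m) = im;
      }
      for (size_t c = 0; c < chgIdx.size(); ++c)
        r -= X.col(chgIdx[c]) * chgDelta[c];
    } else {
      for (int m = 0; m < p; ++m) {
        double old = b(m);
        double xty = arma::dot(X.col(m), r) + xtx(m) * old;
        int im;
        double newb = spike_slab_site(xtx(m), xty, sigma2e, sigma2b, pi, im);
        if (newb != old) r -= X.col(m) * (newb - old);
        b(m) = newb;
        ind(m) = im;
      }
    }
    int mIn = arma::accu(ind);
    double ssb = arma::dot(b, b);
    sigma2b = 1.0 / R::rgamma(0.5 * (nu + mIn),
                              1.0 / (0.5 * (nu * scaleB + ssb)));
    if (!R_finite(piFix)) pi = R::rbeta(piA + (p - mIn), piB + mIn);
    sigma2e = 1.0 / R::rgamma(aSigma + 0.5 * n,
                              1.0 / (bSigma + 0.5 * arma::dot(r, r)));
    if (iter + 1 > burnin && (iter + 1 - burnin) % thin == 0 && stored < nStore) {
      bDraws.col(stored) = b;
      piDraws(stored) = pi;
      s2eDraws(stored) = sigma2e;
      s2bDraws(stored) = sigma2b;
      muDraws(stored) = mu;
      ++stored;
    }
  }
  return List::create(_["b"] = bDraws, _["pi"] = piDraws,
                      _["sigma2e"] = s2eDraws, _["sigma2b"] = s2bDraws,
                      _["mu"] = muDraws);
}
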