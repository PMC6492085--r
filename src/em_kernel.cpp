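// Inner loops of the EM algorithm for the one-stage joint meta-analysis
// model: posterior moments of the shared random effects on the
// pseudo-adaptive Gauss-Hermite grid (E-step) and the score/Hessian of the
// Breslow-profiled expected survival log-likelihood (M-step Newton update).
//
// Subjects are sorted by study (contiguous blocks of sizes nk).  Inner
// (individual-level) nodes are per subject; outer (study-level) nodes per
// study.  The study-level random-effect contribution to both the
// longitudinal mean and the survival log-hazard of subject i at outer node o
// is c3 = B3a[k,o] + B3b[k,o] * treat_i (the Z design of the study effects
// is identical in the two sub-models).
//
// The association is time-varying on the hazard scale:
//   log lambda_i(t) = log lambda0(t) + x2'beta2 + alpha2*(b0 + b1 t)
//                                    + alpha3*c3,
// so the cumulative hazard at the subject's survival time is
//   exp(x2'beta2 + alpha2*b0 + alpha3*c3) * sum_{t_r <= T_i} lam_r
//                                           exp(alpha2*b1*t_r)
// with Breslow increments lam_r at the observed event times of the
// subject's hazard stratum.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093453;

// G[i,q] = sum_{t_r <= T_i} lam_r exp(alpha2 * B1[i,q] * t_r), the
// baseline-weighted time sum of the subject's cumulative hazard.
static void cumhaz_weights(const IntegerVector &stratum,
                           const IntegerVector &cumpos,
                           const NumericVector &ue, const NumericVector &lam,
                           const IntegerVector &str_off,
                           const NumericMatrix &B1, double alpha2,
                           NumericMatrix &G) {
  const int n = stratum.size();
  const int Q2 = B1.ncol();
  for (int i = 0; i < n; ++i) {
    const int s0 = str_off[stratum[i]];
    const int R = cumpos[i];
    for (int q = 0; q < Q2; ++q) {
      const double s = alpha2 * B1(i, q);
      double g = 0.0;
      for (int r = 0; r < R; ++r)
        g += lam[s0 + r] * std::exp(s * ue[s0 + r]);
      G(i, q) = g;
    }
  }
}

// [[Rcpp::export]]
List mjm_estep_kernel(IntegerVector nk,
                      NumericVector m, NumericVector St, NumericVector Stt,
                      NumericVector Sr, NumericVector Srt, NumericVector Srr,
                      NumericVector treat, NumericVector Tsurv,
                      NumericVector delta, NumericVector logh0,
                      NumericVector xb2,
                      IntegerVector stratum, IntegerVector cumpos,
                      NumericVector ue, NumericVector lam,
                      IntegerVector str_off,
                      NumericMatrix B0, NumericMatrix B1,
                      NumericMatrix logw2,
                      NumericMatrix B3a, NumericMatrix B3b,
                      NumericMatrix logw3,
                      double sigma2, double alpha2, double alpha3) {
  const int K = nk.size();
  const int n = m.size();
  const int Q2 = B0.ncol();
  const int Q3 = B3a.ncol();

  NumericMatrix G(n, Q2);
  cumhaz_weights(stratum, cumpos, ue, lam, str_off, B1, alpha2, G);

  std::vector<double> logSbuf(Q2);
  // conditional inner weights p(q | i, o): q fastest, then i, then o
  NumericVector CW((R_xlen_t)n * Q2 * Q3);
  NumericMatrix logm(n, Q3);
  NumericMatrix P(K, Q3);
  NumericMatrix mom(n, 9);   // Eb0 Eb1 Eb00 Eb01 Eb11 Ec3 Ec3sq Eb0c3 Eb1c3
  NumericMatrix Eb3(K, 2), Eb3b3(K, 3);
  double loglik = 0.0;

  int off = 0;
  for (int k = 0; k < K; ++k) {
    const int nks = nk[k];
    for (int o = 0; o < Q3; ++o) {
      for (int ii = 0; ii < nks; ++ii) {
        const int i = off + ii;
        const double c3 = B3a(k, o) + B3b(k, o) * treat[i];
        const double Sa  = Sr[i]  - m[i] * c3;
        const double Sat = Srt[i] - St[i] * c3;
        const double Saa = Srr[i] - 2.0 * c3 * Sr[i] + m[i] * c3 * c3;
        const double cll = -0.5 * m[i] * (LOG2PI + std::log(sigma2));
        const double e3 = xb2[i] + alpha3 * c3;
        double mx = R_NegInf;
        for (int q = 0; q < Q2; ++q) {
          const double b0 = B0(i, q), b1 = B1(i, q);
          const double llL = cll - 0.5 / sigma2 *
            (Saa - 2.0 * b0 * Sa - 2.0 * b1 * Sat +
             b0 * b0 * m[i] + 2.0 * b0 * b1 * St[i] + b1 * b1 * Stt[i]);
          // event density at the subject's own survival time + cumulative
          const double ecst = e3 + alpha2 * b0;
          double llS;
          if (ecst > 690.0) {
            llS = R_NegInf;
          } else {
            llS = delta[i] * (logh0[i] + ecst + alpha2 * b1 * Tsurv[i]) -
              std::exp(ecst) * G(i, q);
          }
          const double ls = logw2(i, q) + llL + llS;
          logSbuf[q] = ls;
          if (ls > mx) mx = ls;
        }
        double s = 0.0;
        if (R_finite(mx))
          for (int q = 0; q < Q2; ++q) s += std::exp(logSbuf[q] - mx);
        const double lm = R_finite(mx) ? mx + std::log(s) : R_NegInf;
        logm(i, o) = lm;
        double *cw = &CW[((R_xlen_t)o * n + i) * Q2];
        if (R_finite(lm)) {
          for (int q = 0; q < Q2; ++q) cw[q] = std::exp(logSbuf[q] - lm);
        } else {
          for (int q = 0; q < Q2; ++q) cw[q] = 0.0;
        }
      }
    }
    // study-level integration
    double mxo = R_NegInf;
    std::vector<double> logM(Q3);
    for (int o = 0; o < Q3; ++o) {
      double lM = logw3(k, o);
      for (int ii = 0; ii < nks; ++ii) lM += logm(off + ii, o);
      logM[o] = lM;
      if (lM > mxo) mxo = lM;
    }
    double so = 0.0;
    if (R_finite(mxo))
      for (int o = 0; o < Q3; ++o) so += std::exp(logM[o] - mxo);
    const double llk = R_finite(mxo) ? mxo + std::log(so) : R_NegInf;
    loglik += llk;
    for (int o = 0; o < Q3; ++o)
      P(k, o) = R_finite(llk) ? std::exp(logM[o] - llk) : NA_REAL;

    // moments
    for (int o = 0; o < Q3; ++o) {
      const double Po = P(k, o);
      if (!R_finite(Po) || Po <= 0.0) continue;
      const double b3a = B3a(k, o), b3b = B3b(k, o);
      Eb3(k, 0) += Po * b3a;
      Eb3(k, 1) += Po * b3b;
      Eb3b3(k, 0) += Po * b3a * b3a;
      Eb3b3(k, 1) += Po * b3a * b3b;
      Eb3b3(k, 2) += Po * b3b * b3b;
      for (int ii = 0; ii < nks; ++ii) {
        const int i = off + ii;
        if (!R_finite(logm(i, o))) continue;
        const double c3 = b3a + b3b * treat[i];
        const double *cw = &CW[((R_xlen_t)o * n + i) * Q2];
        double eb0 = 0, eb1 = 0, eb00 = 0, eb01 = 0, eb11 = 0;
        for (int q = 0; q < Q2; ++q) {
          const double w = cw[q];
          const double b0 = B0(i, q), b1 = B1(i, q);
          eb0 += w * b0; eb1 += w * b1;
          eb00 += w * b0 * b0; eb01 += w * b0 * b1; eb11 += w * b1 * b1;
        }
        mom(i, 0) += Po * eb0;
        mom(i, 1) += Po * eb1;
        mom(i, 2) += Po * eb00;
        mom(i, 3) += Po * eb01;
        mom(i, 4) += Po * eb11;
        mom(i, 5) += Po * c3;
        mom(i, 6) += Po * c3 * c3;
        mom(i, 7) += Po * eb0 * c3;
        mom(i, 8) += Po * eb1 * c3;
      }
    }
    off += nks;
  }

  return List::create(_["loglik"] = loglik, _["P"] = P, _["CW"] = CW,
                      _["mom"] = mom, _["Eb3"] = Eb3, _["Eb3b3"] = Eb3b3);
}

// Risk part of the profiled expected survival log-likelihood: for the
// parameter vector psi = (beta2 [via xb2 and X2], alpha2, alpha3), returns
// sum_r d_r log S0_r, the score and Hessian contributions of the risk-set
// sums, and S0 itself (for the Breslow update).  Event-term contributions
// (linear in psi) are assembled in R.
// [[Rcpp::export]]
List mjm_surv_score(IntegerVector nk, NumericVector treat,
                    NumericVector Tsurv, NumericVector xb2,
                    NumericMatrix X2,
                    IntegerVector stratum, IntegerVector str_off,
                    NumericVector ue, NumericVector dr,
                    NumericMatrix B0, NumericMatrix B1,
                    NumericMatrix B3a, NumericMatrix B3b,
                    NumericMatrix P, NumericVector CW,
                    double alpha2, double alpha3, int d3) {
  const int K = nk.size();
  const int n = treat.size();
  const int Q2 = B0.ncol();
  const int Q3 = P.ncol();
  const int p2 = X2.ncol();
  const int p = p2 + 1 + (d3 > 0 ? 1 : 0);
  const int Rtot = ue.size();
  const int nstr = str_off.size() - 1;

  // per-(i,q) outer-node aggregates: g0 = sum_o P_o p(q|i,o) e^{a3 c3},
  // g1 = ... c3 e^{a3 c3}, g2 = ... c3^2 e^{a3 c3}
  NumericMatrix g0(n, Q2), g1(n, Q2), g2(n, Q2);
  {
    int off = 0;
    for (int k = 0; k < K; ++k) {
      const int nks = nk[k];
      for (int o = 0; o < Q3; ++o) {
        const double Po = P(k, o);
        if (!R_finite(Po) || Po <= 0.0) continue;
        const double b3a = B3a(k, o), b3b = B3b(k, o);
        for (int ii = 0; ii < nks; ++ii) {
          const int i = off + ii;
          const double c3 = b3a + b3b * treat[i];
          const double w = Po * std::exp(alpha3 * c3);
          const double *cw = &CW[((R_xlen_t)o * n + i) * Q2];
          for (int q = 0; q < Q2; ++q) {
            const double pw = w * cw[q];
            g0(i, q) += pw;
            g1(i, q) += pw * c3;
            g2(i, q) += pw * c3 * c3;
          }
        }
      }
      off += nks;
    }
  }

  // group subjects by stratum, sorted by descending survival time
  std::vector<std::vector<int>> subj_desc(nstr);
  for (int s = 0; s < nstr; ++s) subj_desc[s].reserve(n / nstr + 1);
  for (int i = 0; i < n; ++i) subj_desc[stratum[i]].push_back(i);
  for (int s = 0; s < nstr; ++s)
    std::sort(subj_desc[s].begin(), subj_desc[s].end(),
              [&](int a, int b) { return Tsurv[a] > Tsurv[b]; });

  NumericVector S0(Rtot);
  arma::vec score(p, arma::fill::zeros);
  arma::mat hess(p, p, arma::fill::zeros);
  double lp_risk = 0.0;
  bool bad = false;

  arma::vec S1(p);
  arma::mat S2(p, p);

  for (int s = 0; s < nstr && !bad; ++s) {
    const int r0 = str_off[s], r1 = str_off[s + 1];
    const std::vector<int> &sd = subj_desc[s];
    // event times descending; risk set grows as r decreases
    int next = 0;                      // subjects already in the risk set
    for (int r = r1 - 1; r >= r0; --r) {
      const double tr = ue[r];
      while (next < (int)sd.size() && Tsurv[sd[next]] >= tr) ++next;
      S1.zeros(); S2.zeros();
      double s0 = 0.0;
      for (int jj = 0; jj < next; ++jj) {
        const int i = sd[jj];
        const double eb = std::exp(xb2[i]);
        double c0 = 0, c1 = 0, c2 = 0, d0 = 0, d1 = 0, f0 = 0;
        for (int q = 0; q < Q2; ++q) {
          const double w = B0(i, q) + B1(i, q) * tr;
          const double e = std::exp(alpha2 * w);
          const double a = g0(i, q) * e;
          c0 += a; c1 += a * w; c2 += a * w * w;
          if (d3 > 0) {
            const double b = g1(i, q) * e;
            d0 += b; d1 += b * w;
            f0 += g2(i, q) * e;
          }
        }
        s0 += eb * c0;
        // score/Hessian pieces: beta2 block then alpha2 (and alpha3)
        for (int j = 0; j < p2; ++j) {
          const double xj = X2(i, j);
          S1[j] += xj * eb * c0;
          for (int l = j; l < p2; ++l)
            S2(j, l) += xj * X2(i, l) * eb * c0;
          S2(j, p2) += xj * eb * c1;
          if (d3 > 0) S2(j, p2 + 1) += xj * eb * d0;
        }
        S1[p2] += eb * c1;
        S2(p2, p2) += eb * c2;
        if (d3 > 0) {
          S1[p2 + 1] += eb * d0;
          S2(p2, p2 + 1) += eb * d1;
          S2(p2 + 1, p2 + 1) += eb * f0;
        }
      }
      if (!(s0 > 0.0) || !R_finite(s0)) { bad = true; break; }
      S0[r] = s0;
      lp_risk += dr[r] * std::log(s0);
      const arma::vec u = S1 / s0;
      score += dr[r] * u;
      arma::mat S2f = arma::symmatu(S2);
      hess += dr[r] * (S2f / s0 - u * u.t());
    }
  }

  return List::create(_["ok"] = !bad, _["lp_risk"] = lp_risk,
                      _["score_risk"] = NumericVector(score.begin(),
                                                      score.end()),
                      _["hess_risk"] = wrap(hess), _["S0"] = S0);
}
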