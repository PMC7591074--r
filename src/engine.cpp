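// Compiled engine for the belief-model session log-likelihood and the
// factorial grid scan used to seed MAP fitting. Mirrors the exported R
// operations exactly (same sharpened-binomial construction, same update,
// carry-over and scoring rules); the R path is the definitional reference
// and the two are tested for agreement.
//
// The session evaluation exploits that within a dictator block the
// posterior after t trials is prior * prod(policy slices) up to
// normalization, so each trial costs one dot product over the 81 cells
// instead of a renormalized update; the result is algebraically identical
// to the trial-by-trial recursion.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static const double PROB_FLOOR = 1e-30;

// Bin(k; p, size)^u over k = 0..size, renormalized (softmax in log space).
static void nb_pmf(double p, double u, int size, double* out) {
  const int n = size + 1;
  double mx = R_NegInf;
  for (int k = 0; k < n; ++k) {
    const double lw = u * R::dbinom(k, size, p, 1);
    out[k] = lw;
    if (lw > mx) mx = lw;
  }
  double s = 0.0;
  for (int k = 0; k < n; ++k) {
    out[k] = std::exp(out[k] - mx);
    s += out[k];
  }
  for (int k = 0; k < n; ++k) out[k] /= s;
}

// Attribute-level marginal preferences of the raw policy template:
// marg[a*n + k] = sharpened binomial over return index k for level a.
static void template_marginals(int n, double p_init, double u_init,
                               double delta_p, std::vector<double>& marg) {
  marg.resize((size_t)n * n);
  for (int a = 0; a < n; ++a) {
    const double p_a = 1.0 - p_init - delta_p * a;
    const double u_a = u_init - 2.0 * delta_p * (a + 1);
    if (u_a <= 0.0)
      stop("policy template exponent non-positive; constants inconsistent");
    nb_pmf(p_a, u_a, n - 1, &marg[(size_t)a * n]);
  }
}

// log of the normalized joint template rows:
// logt[(i*n + j)*n + r] = log pi_gen(r; i, j)
static void log_template(int n, const std::vector<double>& marg,
                         std::vector<double>& logt) {
  logt.resize((size_t)n * n * n);
  std::vector<double> row(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int r = 0; r < n; ++r) {
        row[r] = marg[(size_t)i * n + r] * marg[(size_t)j * n + r];
        s += row[r];
      }
      double* out = &logt[((size_t)i * n + j) * n];
      for (int r = 0; r < n; ++r) out[r] = std::log(row[r] / s);
    }
}

// Uncertainty-applied policy from the log template:
// pol[cell*n + r] = normalize_r( exp(logt/u_pi) + xi )
static void policy_from_logt(int n, const std::vector<double>& logt,
                             double u_pi, double xi,
                             std::vector<double>& pol) {
  const double inv_u = 1.0 / u_pi;
  const int C = n * n;
  pol.resize((size_t)C * n);
  for (int c = 0; c < C; ++c) {
    const double* lt = &logt[(size_t)c * n];
    double* out = &pol[(size_t)c * n];
    double s = 0.0;
    for (int r = 0; r < n; ++r) {
      out[r] = std::exp(inv_u * lt[r]) + xi;
      s += out[r];
    }
    for (int r = 0; r < n; ++r) out[r] /= s;
  }
}

// Joint prior over the lattice: outer product of the two sharpened-binomial
// marginals with exponents 1/uHI0, 1/uSI0, renormalized.
// prior[i*n + j] for HI level i, SI level j.
static void joint_prior(int n, const double* hi, const double* si,
                        std::vector<double>& prior) {
  prior.resize((size_t)n * n);
  double s = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      prior[(size_t)i * n + j] = hi[i] * si[j];
      s += prior[(size_t)i * n + j];
    }
  for (size_t c = 0; c < prior.size(); ++c) prior[c] /= s;
}

static void build_prior(int n, double pHI0, double uHI0, double pSI0,
                        double uSI0, std::vector<double>& prior) {
  std::vector<double> hi(n), si(n);
  nb_pmf(pHI0, 1.0 / uHI0, n - 1, hi.data());
  nb_pmf(pSI0, 1.0 / uSI0, n - 1, si.data());
  joint_prior(n, hi.data(), si.data(), prior);
}

struct Trials {
  const int *r, *hi, *si, *blk;
  int T;
  // block start/end (half-open) indices in encounter order
  std::vector<int> b0, b1;
  void find_blocks() {
    b0.clear(); b1.clear();
    int t = 0;
    while (t < T) {
      const int b = blk[t];
      b0.push_back(t);
      while (t < T && blk[t] == b) ++t;
      b1.push_back(t);
    }
  }
};

// Cumulative within-block products of policy slices:
// S[t*C + c] = prod_{s in block, s <= t} pol[c*n + r_s]
static void cumulative_slices(int n, const std::vector<double>& pol,
                              const Trials& d, std::vector<double>& S) {
  const int C = n * n;
  S.resize((size_t)d.T * C);
  for (size_t b = 0; b < d.b0.size(); ++b) {
    for (int t = d.b0[b]; t < d.b1[b]; ++t) {
      const int r = d.r[t] - 1;
      double* cur = &S[(size_t)t * C];
      if (t == d.b0[b]) {
        for (int c = 0; c < C; ++c) cur[c] = pol[(size_t)c * n + r];
      } else {
        const double* prev = &S[(size_t)(t - 1) * C];
        for (int c = 0; c < C; ++c) cur[c] = prev[c] * pol[(size_t)c * n + r];
      }
    }
  }
}

// One block given its starting prior: per-trial log-likelihoods into out,
// the block's final posterior into posterior. Returns the block total.
static double eval_block(int n, const double* prior,
                         const std::vector<double>& S, const Trials& d,
                         int t0, int t1, bool score_post, double* out,
                         double* posterior) {
  const int C = n * n;
  double total = 0.0, Zprev = 1.0;
  const double* Sprev = NULL;
  for (int t = t0; t < t1; ++t) {
    const double* St = &S[(size_t)t * C];
    double Z = 0.0;
    for (int c = 0; c < C; ++c) Z += prior[c] * St[c];
    const int cell = d.hi[t] * n + d.si[t];
    double pcell;
    if (score_post) pcell = prior[cell] * St[cell] / Z;
    else pcell = (t == t0) ? prior[cell] : prior[cell] * Sprev[cell] / Zprev;
    const double ll = std::log(std::max(pcell, PROB_FLOOR));
    if (out) out[t] = ll;
    total += ll;
    Zprev = Z;
    Sprev = St;
  }
  for (int c = 0; c < C; ++c) posterior[c] = prior[c] * Sprev[c] / Zprev;
  return total;
}

// next-block prior: convex mixture of the block's starting prior and its
// final posterior, renormalized
static void mix_prior(int n, const double* prior, const double* posterior,
                      double eta, double* out) {
  const int C = n * n;
  double s = 0.0;
  for (int c = 0; c < C; ++c) {
    out[c] = (1.0 - eta) * prior[c] + eta * posterior[c];
    s += out[c];
  }
  for (int c = 0; c < C; ++c) out[c] /= s;
}

// Full session; writes per-trial log-likelihoods, returns the total.
static double run_session(int n, const std::vector<double>& prior0,
                          const std::vector<double>& S, const Trials& d,
                          double eta, bool score_post, double* out) {
  const int C = n * n;
  std::vector<double> prior(prior0), posterior(C), next(C);
  double total = 0.0;
  for (size_t b = 0; b < d.b0.size(); ++b) {
    total += eval_block(n, prior.data(), S, d, d.b0[b], d.b1[b], score_post,
                        out, posterior.data());
    mix_prior(n, prior.data(), posterior.data(), eta, next.data());
    prior.swap(next);
  }
  return total;
}

static Trials make_trials(IntegerVector& r, IntegerVector& hi,
                          IntegerVector& si, IntegerVector& blk) {
  Trials d;
  d.r = INTEGER(r); d.hi = INTEGER(hi); d.si = INTEGER(si);
  d.blk = INTEGER(blk); d.T = r.size();
  d.find_blocks();
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_session_loglik(NumericVector par, IntegerVector return_bin,
                                 IntegerVector hi_bin, IntegerVector si_bin,
                                 IntegerVector block, int n_pi, double p_init,
                                 double u_init, double delta_p, double xi,
                                 bool score_post) {
  Trials d = make_trials(return_bin, hi_bin, si_bin, block);
  std::vector<double> marg, logt, pol, prior, S;
  template_marginals(n_pi, p_init, u_init, delta_p, marg);
  log_template(n_pi, marg, logt);
  policy_from_logt(n_pi, logt, par[4], xi, pol);
  build_prior(n_pi, par[0], par[1], par[2], par[3], prior);
  cumulative_slices(n_pi, pol, d, S);
  NumericVector out(d.T);
  run_session(n_pi, prior, S, d, par[5], score_post, REAL(out));
  return out;
}

// log of the normalized joint policy template (cacheable across calls)
// [[Rcpp::export]]
NumericVector cpp_log_template(int n_pi, double p_init, double u_init,
                               double delta_p) {
  std::vector<double> marg, logt;
  template_marginals(n_pi, p_init, u_init, delta_p, marg);
  log_template(n_pi, marg, logt);
  return NumericVector(logt.begin(), logt.end());
}

// Session total log-likelihood with a precomputed log template (the
// optimizer's objective path).
// [[Rcpp::export]]
double cpp_session_total(NumericVector par, NumericVector logt,
                         IntegerVector return_bin, IntegerVector hi_bin,
                         IntegerVector si_bin, IntegerVector block, int n_pi,
                         double xi, bool score_post) {
  Trials d = make_trials(return_bin, hi_bin, si_bin, block);
  std::vector<double> lt(logt.begin(), logt.end()), pol, prior, S;
  policy_from_logt(n_pi, lt, par[4], xi, pol);
  build_prior(n_pi, par[0], par[1], par[2], par[3], prior);
  cumulative_slices(n_pi, pol, d, S);
  return run_session(n_pi, prior, S, d, par[5], score_post, NULL);
}

// Total log-likelihood at every point of the factorial parameter grid.
// Nesting order of the returned vector: u_pi slowest, then pHI0, uHI0,
// pSI0, uSI0, and eta fastest (matching
// expand.grid(eta, uSI0, pSI0, uHI0, pHI0, u_pi) on the R side).
// The first block is shared across the eta values, which cannot affect it.
// [[Rcpp::export]]
NumericVector cpp_grid_loglik(NumericVector pHI0s, NumericVector uHI0s,
                              NumericVector pSI0s, NumericVector uSI0s,
                              NumericVector upis, NumericVector etas,
                              IntegerVector return_bin, IntegerVector hi_bin,
                              IntegerVector si_bin, IntegerVector block,
                              int n_pi, double p_init, double u_init,
                              double delta_p, double xi, bool score_post) {
  Trials d = make_trials(return_bin, hi_bin, si_bin, block);
  const int n1 = pHI0s.size(), n2 = uHI0s.size(), n3 = pSI0s.size(),
            n4 = uSI0s.size(), nu = upis.size(), ne = etas.size();
  const int C = n_pi * n_pi;
  const size_t nb = d.b0.size();
  std::vector<double> marg, logt;
  template_marginals(n_pi, p_init, u_init, delta_p, marg);
  log_template(n_pi, marg, logt);

  // marginal caches for the prior
  std::vector<double> hi_marg((size_t)n1 * n2 * n_pi),
      si_marg((size_t)n3 * n4 * n_pi);
  for (int i = 0; i < n1; ++i)
    for (int j = 0; j < n2; ++j)
      nb_pmf(pHI0s[i], 1.0 / uHI0s[j], n_pi - 1,
             &hi_marg[((size_t)i * n2 + j) * n_pi]);
  for (int i = 0; i < n3; ++i)
    for (int j = 0; j < n4; ++j)
      nb_pmf(pSI0s[i], 1.0 / uSI0s[j], n_pi - 1,
             &si_marg[((size_t)i * n4 + j) * n_pi]);

  NumericVector out((R_xlen_t)nu * n1 * n2 * n3 * n4 * ne);
  std::vector<double> pol, S, prior(C), post1(C), postb(C), cur(C), next(C);
  R_xlen_t pos = 0;
  for (int iu = 0; iu < nu; ++iu) {
    policy_from_logt(n_pi, logt, upis[iu], xi, pol);
    cumulative_slices(n_pi, pol, d, S);
    for (int i1 = 0; i1 < n1; ++i1)
      for (int i2 = 0; i2 < n2; ++i2) {
        const double* hm = &hi_marg[((size_t)i1 * n2 + i2) * n_pi];
        for (int i3 = 0; i3 < n3; ++i3)
          for (int i4 = 0; i4 < n4; ++i4) {
            const double* sm = &si_marg[((size_t)i3 * n4 + i4) * n_pi];
            joint_prior(n_pi, hm, sm, prior);
            const double tot1 = eval_block(n_pi, prior.data(), S, d, d.b0[0],
                                           d.b1[0], score_post, NULL,
                                           post1.data());
            for (int ie = 0; ie < ne; ++ie) {
              double tot = tot1;
              mix_prior(n_pi, prior.data(), post1.data(), etas[ie],
                        cur.data());
              for (size_t b = 1; b < nb; ++b) {
                tot += eval_block(n_pi, cur.data(), S, d, d.b0[b], d.b1[b],
                                  score_post, NULL, postb.data());
                mix_prior(n_pi, cur.data(), postb.data(), etas[ie],
                          next.data());
                cur.swap(next);
              }
              out[pos++] = tot;
            }
          }
      }
  }
  return out;
}
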