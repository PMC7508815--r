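// Trial-by-trial likelihood kernels for cWCST cognitive models.
//
// Model codes: 1 = wP-RL, 2 = P-RL, 3 = MB-RL, 4 = AU.
// Parameter vector layouts (constrained scale):
//   wP-RL: alpha_mb_pos, alpha_mb_neg, gamma_mb, alpha_mf_pos, alpha_mf_neg,
//          gamma_mf, tau, w
//   P-RL : first 7 of the above
//   MB-RL: alpha_mb_pos, alpha_mb_neg, gamma_mb, tau
//   AU   : p_pos, p_neg, f, d
//
// Cards are triples of key indices (color, shape, number), pairwise distinct.
// Key v matches the card on the unique dimension whose attribute equals v,
// or on none (the "unmatched" key).

#include <Rcpp.h>
using namespace Rcpp;

namespace {

const double A_FLOOR = 1e-12; // attention floor before exponentiation

inline int match_dim(int c1, int c2, int c3, int key) {
  if (c1 == key) return 0;
  if (c2 == key) return 1;
  if (c3 == key) return 2;
  return -1;
}

struct RLPars {
  double ap, an, g, afp, afn, gf, tau, w;
  int model;
};

inline RLPars unpack_rl(const double* p, int model) {
  RLPars x;
  x.model = model;
  if (model == 3) {
    x.ap = p[0]; x.an = p[1]; x.g = p[2]; x.tau = p[3];
    x.afp = 0.0; x.afn = 0.0; x.gf = 1.0; x.w = 1.0;
  } else {
    x.ap = p[0]; x.an = p[1]; x.g = p[2];
    x.afp = p[3]; x.afn = p[4]; x.gf = p[5]; x.tau = p[6];
    x.w = (model == 1) ? p[7] : 1.0;
  }
  return x;
}

struct AUPars {
  double pp, pn, f, d;
};

inline AUPars unpack_au(const double* p) {
  AUPars x;
  x.pp = p[0]; x.pn = p[1]; x.f = p[2]; x.d = p[3];
  return x;
}

// log softmax of integrated feedback expectations, written into out[4]
inline void rl_logprobs(const double qc[3], const double qmf[4],
                        int c1, int c2, int c3, const RLPars& p,
                        double out[4]) {
  double x[4];
  for (int v = 0; v < 4; ++v) {
    int d = match_dim(c1, c2, c3, v + 1);
    double qmb = (d < 0) ? -1.0 : qc[d];
    double qsum;
    if (p.model == 1)
      qsum = p.w * qmb + (1.0 - p.w) * qmf[v];
    else if (p.model == 2)
      qsum = qmb + qmf[v];
    else
      qsum = qmb;
    x[v] = qsum / p.tau;
  }
  double m = x[0];
  for (int v = 1; v < 4; ++v) if (x[v] > m) m = x[v];
  double s = 0.0;
  for (int v = 0; v < 4; ++v) s += std::exp(x[v] - m);
  double ls = m + std::log(s);
  for (int v = 0; v < 4; ++v) out[v] = x[v] - ls;
}

// delta-rule update with inertia; feedback fb in {+1,-1}.
// When the response matches no category the category expectations only
// decay (no prediction error is defined); response expectations update
// normally.
inline void rl_step(double qc[3], double qmf[4], int c1, int c2, int c3,
                    int resp, int fb, const RLPars& p) {
  int u = match_dim(c1, c2, c3, resp);
  for (int k = 0; k < 3; ++k) qc[k] *= p.g;
  if (u >= 0) {
    double delta = fb - qc[u];
    qc[u] += ((fb > 0) ? p.ap : p.an) * delta;
  }
  if (p.model != 3) {
    for (int v = 0; v < 4; ++v) qmf[v] *= p.gf;
    double delta = fb - qmf[resp - 1];
    qmf[resp - 1] += ((fb > 0) ? p.afp : p.afn) * delta;
  }
}

// AU log response probabilities; the unmatched key gets -Inf (prob 0).
inline void au_logprobs(const double a[3], int c1, int c2, int c3,
                        double d, double out[4]) {
  double ad[3], s = 0.0;
  for (int k = 0; k < 3; ++k) {
    ad[k] = std::pow(std::max(a[k], A_FLOOR), d);
    s += ad[k];
  }
  double ls = std::log(s);
  for (int v = 0; v < 4; ++v) {
    int dim = match_dim(c1, c2, c3, v + 1);
    out[v] = (dim < 0) ? R_NegInf : std::log(ad[dim]) - ls;
  }
}

inline void au_step(double a[3], int c1, int c2, int c3, int resp, int fb,
                    const AUPars& p, int trial1based) {
  int u = match_dim(c1, c2, c3, resp);
  if (u < 0)
    stop("AU model: response matching no category at trial %d; "
         "remove such trials before fitting", trial1based);
  double s[3];
  if (fb > 0) {
    s[0] = s[1] = s[2] = 0.0;
    s[u] = 1.0;
  } else {
    double tot = 0.0;
    for (int k = 0; k < 3; ++k) {
      s[k] = (k == u) ? 0.0 : std::pow(std::max(a[k], A_FLOOR), p.f);
      tot += s[k];
    }
    for (int k = 0; k < 3; ++k) s[k] /= tot;
  }
  double pr = (fb > 0) ? p.pp : p.pn;
  for (int k = 0; k < 3; ++k) a[k] = (1.0 - pr) * a[k] + pr * s[k];
}

// walk one subject's sequence; returns total log-lik, optionally stores
// per-trial log-probabilities of the executed response in lp (may be NULL)
double walk_sequence(const int* c1, const int* c2, const int* c3,
                     const int* resp, const int* fb, int n,
                     const double* pars, int model, double* lp) {
  double total = 0.0;
  if (model == 4) {
    AUPars p = unpack_au(pars);
    double a[3] = {1.0 / 3.0, 1.0 / 3.0, 1.0 / 3.0};
    double logp[4];
    for (int t = 0; t < n; ++t) {
      au_logprobs(a, c1[t], c2[t], c3[t], p.d, logp);
      double l = logp[resp[t] - 1];
      if (!R_FINITE(l))
        stop("AU model: response matching no category at trial %d; "
             "remove such trials before fitting", t + 1);
      total += l;
      if (lp) lp[t] = l;
      au_step(a, c1[t], c2[t], c3[t], resp[t], fb[t], p, t + 1);
    }
  } else {
    RLPars p = unpack_rl(pars, model);
    double qc[3] = {0.0, 0.0, 0.0};
    double qmf[4] = {0.0, 0.0, 0.0, 0.0};
    double logp[4];
    for (int t = 0; t < n; ++t) {
      rl_logprobs(qc, qmf, c1[t], c2[t], c3[t], p, logp);
      double l = logp[resp[t] - 1];
      total += l;
      if (lp) lp[t] = l;
      rl_step(qc, qmf, c1[t], c2[t], c3[t], resp[t], fb[t], p);
    }
  }
  return total;
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_seq_logp(IntegerVector c1, IntegerVector c2,
                           IntegerVector c3, IntegerVector resp,
                           IntegerVector fb, NumericVector pars, int model) {
  int n = c1.size();
  NumericVector out(n);
  walk_sequence(&c1[0], &c2[0], &c3[0], &resp[0], &fb[0], n,
                &pars[0], model, n > 0 ? &out[0] : (double*)0);
  return out;
}

// Per-subject total log-likelihoods for trials grouped contiguously by
// subject (subj: 1-based index, nondecreasing). pars has one row per subject.
// [[Rcpp::export]]
NumericVector cpp_pooled_loglik(IntegerVector c1, IntegerVector c2,
                                IntegerVector c3, IntegerVector resp,
                                IntegerVector fb, IntegerVector subj,
                                NumericMatrix pars, int model) {
  int n = c1.size(), ns = pars.nrow();
  NumericVector out(ns);
  std::vector<double> pv(pars.ncol());
  int start = 0;
  while (start < n) {
    int s = subj[start];
    int end = start;
    while (end < n && subj[end] == s) ++end;
    if (s < 1 || s > ns) stop("subject index out of range");
    for (int j = 0; j < pars.ncol(); ++j) pv[j] = pars(s - 1, j);
    out[s - 1] = walk_sequence(&c1[start], &c2[start], &c3[start],
                               &resp[start], &fb[start], end - start,
                               pv.data(), model, (double*)0);
    start = end;
  }
  return out;
}

// Total log-likelihood of one subject's sequence under each row of pars.
// [[Rcpp::export]]
NumericVector cpp_loglik_by_row(IntegerVector c1, IntegerVector c2,
                                IntegerVector c3, IntegerVector resp,
                                IntegerVector fb, NumericMatrix pars,
                                int model) {
  int n = c1.size(), S = pars.nrow();
  NumericVector out(S);
  std::vector<double> pv(pars.ncol());
  for (int s = 0; s < S; ++s) {
    for (int j = 0; j < pars.ncol(); ++j) pv[j] = pars(s, j);
    out[s] = walk_sequence(&c1[0], &c2[0], &c3[0], &resp[0], &fb[0], n,
                           pv.data(), model, (double*)0);
  }
  return out;
}

// T x 4 matrix of response probabilities on each trial, with the latent
// state rebuilt from the observed history (probabilities on trial t depend
// on trials 1..t-1 only).
// [[Rcpp::export]]
NumericMatrix cpp_prob_trace(IntegerVector c1, IntegerVector c2,
                             IntegerVector c3, IntegerVector resp,
                             IntegerVector fb, NumericVector pars,
                             int model) {
  int n = c1.size();
  NumericMatrix out(n, 4);
  double logp[4];
  if (model == 4) {
    AUPars p = unpack_au(&pars[0]);
    double a[3] = {1.0 / 3.0, 1.0 / 3.0, 1.0 / 3.0};
    for (int t = 0; t < n; ++t) {
      au_logprobs(a, c1[t], c2[t], c3[t], p.d, logp);
      for (int v = 0; v < 4; ++v)
        out(t, v) = R_FINITE(logp[v]) ? std::exp(logp[v]) : 0.0;
      au_step(a, c1[t], c2[t], c3[t], resp[t], fb[t], p, t + 1);
    }
  } else {
    RLPars p = unpack_rl(&pars[0], model);
    double qc[3] = {0.0, 0.0, 0.0};
    double qmf[4] = {0.0, 0.0, 0.0, 0.0};
    for (int t = 0; t < n; ++t) {
      rl_logprobs(qc, qmf, c1[t], c2[t], c3[t], p, logp);
      for (int v = 0; v < 4; ++v) out(t, v) = std::exp(logp[v]);
      rl_step(qc, qmf, c1[t], c2[t], c3[t], resp[t], fb[t], p);
    }
  }
  return out;
}

// One-trial-ahead simulation: for each row of pars (one iteration), rebuild
// the latent state from the OBSERVED history and sample a response on every
// trial from the model's probabilities. Uses R's RNG.
// [[Rcpp::export]]
IntegerMatrix cpp_one_step_ahead(IntegerVector c1, IntegerVector c2,
                                 IntegerVector c3, IntegerVector resp,
                                 IntegerVector fb, NumericMatrix pars,
                                 int model) {
  int n = c1.size(), S = pars.nrow();
  IntegerMatrix out(S, n);
  double logp[4], pr[4];
  for (int s = 0; s < S; ++s) {
    std::vector<double> pv(pars.ncol());
    for (int j = 0; j < pars.ncol(); ++j) pv[j] = pars(s, j);
    double qc[3] = {0.0, 0.0, 0.0};
    double qmf[4] = {0.0, 0.0, 0.0, 0.0};
    double a[3] = {1.0 / 3.0, 1.0 / 3.0, 1.0 / 3.0};
    RLPars prl = unpack_rl(pv.data(), model == 4 ? 3 : model); // dummy for AU
    AUPars pau = unpack_au(pv.data());
    for (int t = 0; t < n; ++t) {
      if (model == 4)
        au_logprobs(a, c1[t], c2[t], c3[t], pau.d, logp);
      else
        rl_logprobs(qc, qmf, c1[t], c2[t], c3[t], prl, logp);
      double tot = 0.0;
      for (int v = 0; v < 4; ++v) {
        pr[v] = R_FINITE(logp[v]) ? std::exp(logp[v]) : 0.0;
        tot += pr[v];
      }
      double u = unif_rand() * tot, acc = 0.0;
      int pick = 3;
      for (int v = 0; v < 4; ++v) {
        acc += pr[v];
        if (u <= acc) { pick = v; break; }
      }
      out(s, t) = pick + 1;
      if (model == 4)
        au_step(a, c1[t], c2[t], c3[t], resp[t], fb[t], pau, t + 1);
      else
        rl_step(qc, qmf, c1[t], c2[t], c3[t], resp[t], fb[t], prl);
    }
  }
  return out;
}
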