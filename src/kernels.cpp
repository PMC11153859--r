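#include <Rcpp.h>
using namespace Rcpp;

// First-passage-time density of a unit-diffusion Wiener process at the LOWER
// boundary. Boundaries at 0 and a, start at w*a, drift v, shifted by t0.
// Series evaluation switches between the small-time and large-time expansions
// wherever each needs fewer terms for truncation error <= eps (error bounds in
// the style of the standard adaptive-truncation treatment of this density).
static double wfpt_lower_one(double t, double a, double v, double w,
                             double t0, double eps) {
  double tt = t - t0;
  if (tt <= 0.0) return 0.0;
  double u = tt / (a * a);  // time in boundary-normalised units

  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * u) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * std::sqrt(2.0 * M_PI * u) * eps));
    ks = std::max(ks, std::sqrt(u) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * u * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * u * eps) / (M_PI * M_PI * u));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(u)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(u));
  }

  double f1;
  if (ks < kl) {
    int K = (int)std::ceil(ks);
    int lo = -(int)std::floor((K - 1) / 2.0);
    int hi = (int)std::ceil((K - 1) / 2.0);
    double s = 0.0;
    for (int k = lo; k <= hi; ++k) {
      double wk = w + 2.0 * k;
      s += wk * std::exp(-wk * wk / (2.0 * u));
    }
    f1 = s / std::sqrt(2.0 * M_PI * u * u * u);
  } else {
    int K = (int)std::ceil(kl);
    double s = 0.0;
    for (int k = 1; k <= K; ++k) {
      s += k * std::exp(-k * k * M_PI * M_PI * u / 2.0) * std::sin(k * M_PI * w);
    }
    f1 = s * M_PI;
  }
  if (f1 < 0.0) f1 = 0.0;  // truncation can leave a tiny negative residue
  double dens = f1 * std::exp(-v * a * w - v * v * tt / 2.0) / (a * a);
  return dens > 0.0 ? dens : 0.0;
}

// [[Rcpp::export]]
NumericVector wfpt_lower_cpp(NumericVector t, double a, double v, double w,
                             double t0, double eps) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = wfpt_lower_one(t[i], a, v, w, t0, eps);
  return out;
}

// Response-coded diffusion log-likelihood over target-present trials.
// cond: 1 = reward, 2 = punishment, 3 = zero, indexing alpha/nu;
// upper: 1 if the response maps to the upper boundary, 0 otherwise.
// [[Rcpp::export]]
double ddm_loglik_cpp(NumericVector rt, IntegerVector upper, IntegerVector cond,
                      NumericVector alpha, NumericVector nu, double t0,
                      double w, double eps) {
  int n = rt.size();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    int c = cond[i] - 1;
    double a = alpha[c], v = nu[c];
    double d;
    if (upper[i] == 1) {
      d = wfpt_lower_one(rt[i], a, -v, 1.0 - w, t0, eps);
    } else {
      d = wfpt_lower_one(rt[i], a, v, w, t0, eps);
    }
    if (d <= 0.0) return R_NegInf;
    ll += std::log(d);
  }
  return ll;
}

// Single-condition variant: all trials share one (a, v).
// [[Rcpp::export]]
double wfpt_loglik_cpp(NumericVector rt, IntegerVector upper, double a,
                       double v, double t0, double w, double eps) {
  int n = rt.size();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = (upper[i] == 1)
      ? wfpt_lower_one(rt[i], a, -v, 1.0 - w, t0, eps)
      : wfpt_lower_one(rt[i], a, v, w, t0, eps);
    if (d <= 0.0) return R_NegInf;
    ll += std::log(d);
  }
  return ll;
}

// Euler-Maruyama simulation of the diffusion process with the Brownian-
// bridge crossing correction: between consecutive interior points the
// bridge crosses the lower boundary with probability exp(-2 x x' / dt)
// (mirror for the upper boundary), which removes the O(sqrt(dt)) overshoot
// bias of the naive scheme. Returns rt (seconds, including t0) and boundary
// (1 = upper, 0 = lower). Uses R's RNG so draws are reproducible under
// set.seed().
// [[Rcpp::export]]
DataFrame ddm_sim_cpp(int n, double a, double v, double t0, double w,
                      double dt) {
  NumericVector rt(n);
  IntegerVector up(n);
  double sdt = std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double x = w * a;
    R_xlen_t steps = 0;
    int hit = -1;
    while (hit < 0) {
      double xn = x + v * dt + sdt * norm_rand();
      ++steps;
      if (xn <= 0.0) {
        hit = 0;
      } else if (xn >= a) {
        hit = 1;
      } else {
        double p_lo = std::exp(-2.0 * x * xn / dt);
        double p_up = std::exp(-2.0 * (a - x) * (a - xn) / dt);
        double u = unif_rand();
        if (u < p_lo) hit = 0;
        else if (u < p_lo + p_up) hit = 1;
      }
      x = xn;
    }
    rt[i] = t0 + steps * dt;
    up[i] = hit;
  }
  return DataFrame::create(_["rt"] = rt, _["upper"] = up);
}

// Dual-learning-rate Rescorla-Wagner log-likelihood over a time-ordered trial
// sequence. cond: 1 = reward, 2 = punishment, 0 = zero (skipped). chose: 1 if
// the target face was chosen. outcome in {-1, 0, +1}. Four expected values
// (target/nontarget x reward/punishment) start at 0; only the chosen option's
// EV updates. Softmax via max-subtraction for stability at large tau.
// [[Rcpp::export]]
double rl_loglik_cpp(IntegerVector cond, IntegerVector chose,
                     NumericVector outcome, double eta_r, double eta_p,
                     double tau_r, double tau_p) {
  double ev[2][2] = {{0.0, 0.0}, {0.0, 0.0}};  // [cond-1][0=target,1=nontarget]
  int n = cond.size();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    int c = cond[i];
    if (c == 0) continue;
    int ci = c - 1;
    double tau = (c == 1) ? tau_r : tau_p;
    double eta = (c == 1) ? eta_r : eta_p;
    double et = tau * ev[ci][0], en = tau * ev[ci][1];
    double m = std::max(et, en);
    double lden = m + std::log(std::exp(et - m) + std::exp(en - m));
    int ch = (chose[i] == 1) ? 0 : 1;
    ll += (ch == 0 ? et : en) - lden;
    ev[ci][ch] += eta * (outcome[i] - ev[ci][ch]);
  }
  return ll;
}

// Batched single-condition RL log-likelihoods: participant j's trials sit in
// [off[j], off[j+1]) of the concatenated arrays (all one condition), with
// per-participant eta/tau. Returns one log-likelihood per participant.
// [[Rcpp::export]]
NumericVector rl_loglik_batch_cpp(IntegerVector off, IntegerVector chose,
                                  NumericVector outcome, NumericVector eta,
                                  NumericVector tau) {
  int J = off.size() - 1;
  NumericVector ll(J);
  for (int j = 0; j < J; ++j) {
    double ev0 = 0.0, ev1 = 0.0, s = 0.0;
    double e = eta[j], tj = tau[j];
    for (int i = off[j]; i < off[j + 1]; ++i) {
      double et = tj * ev0, en = tj * ev1;
      double m = std::max(et, en);
      double lden = m + std::log(std::exp(et - m) + std::exp(en - m));
      if (chose[i] == 1) {
        s += et - lden;
        ev0 += e * (outcome[i] - ev0);
      } else {
        s += en - lden;
        ev1 += e * (outcome[i] - ev1);
      }
    }
    ll[j] = s;
  }
  return ll;
}

// Batched single-condition Wiener log-likelihoods with per-participant
// (a, v) and shared t0.
// [[Rcpp::export]]
NumericVector wfpt_loglik_batch_cpp(IntegerVector off, NumericVector rt,
                                    IntegerVector upper, NumericVector a,
                                    NumericVector v, double t0, double w,
                                    double eps) {
  int J = off.size() - 1;
  NumericVector ll(J);
  for (int j = 0; j < J; ++j) {
    double s = 0.0;
    for (int i = off[j]; i < off[j + 1]; ++i) {
      double d = (upper[i] == 1)
        ? wfpt_lower_one(rt[i], a[j], -v[j], 1.0 - w, t0, eps)
        : wfpt_lower_one(rt[i], a[j], v[j], w, t0, eps);
      if (d <= 0.0) {
        s = R_NegInf;
        break;
      }
      s += std::log(d);
    }
    ll[j] = s;
  }
  return ll;
}

// Generative mirror of the RL model: walk a schedule of conditions, draw
// choices from the softmax, draw outcomes from the Bernoulli contingency.
// Returns chose (0/1) and outcome per trial. Zero-condition choices are
// uniform and always yield outcome 0. Uses R's RNG.
// [[Rcpp::export]]
DataFrame rl_sim_cpp(IntegerVector cond, double eta_r, double eta_p,
                     double tau_r, double tau_p, double contingency) {
  double ev[2][2] = {{0.0, 0.0}, {0.0, 0.0}};
  int n = cond.size();
  IntegerVector chose(n);
  NumericVector outcome(n);
  for (int i = 0; i < n; ++i) {
    int c = cond[i];
    if (c == 0) {
      chose[i] = (unif_rand() < 0.5) ? 1 : 0;
      outcome[i] = 0.0;
      continue;
    }
    int ci = c - 1;
    double tau = (c == 1) ? tau_r : tau_p;
    double eta = (c == 1) ? eta_r : eta_p;
    double et = tau * ev[ci][0], en = tau * ev[ci][1];
    double m = std::max(et, en);
    double pt = std::exp(et - m) / (std::exp(et - m) + std::exp(en - m));
    int ch = (unif_rand() < pt) ? 0 : 1;  // 0 = target
    chose[i] = (ch == 0) ? 1 : 0;
    // chosen-is-target gets the contingency, chosen-is-nontarget the reverse
    double p = (ch == 0) ? contingency : (1.0 - contingency);
    double val = (c == 1) ? 1.0 : -1.0;
    double out = (unif_rand() < p) ? val : 0.0;
    outcome[i] = out;
    ev[ci][ch] += eta * (out - ev[ci][ch]);
  }
  return DataFrame::create(_["chose_target"] = chose, _["outcome"] = outcome);
}
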