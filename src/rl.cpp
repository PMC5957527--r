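#include <Rcpp.h>
using namespace Rcpp;

// log(plogis(z)) computed stably for large |z|
static inline double log_plogis(double z) {
  if (z < 0.0) return z - log1p(std::exp(z));
  return -log1p(std::exp(-z));
}

// One pass through a session of the hybrid Rescorla-Wagner / Pearce-Hall
// avoidance learner with perceptual confusion and (optionally) Gaussian
// value generalization. Shared by the likelihood and the simulator.
//
// variant: 0 = perceptual confusion only, 1 = one spread width,
//          2 = separate aversive / neutral widths.
// stim:    1-based stimulus index per trial.
// is_gs:   1 if the trial's stimulus is a GS.
// adj:     1-based index of the adjacent CS+ (0 when none).
// sched:   scheduled outcome if unavoided (0 or -1).
// avoided: observed choices (ignored when simulate = true).
// pconf:   per-trial perceptual confusion probability.
static List rl_pass(const IntegerVector& stim, const IntegerVector& is_gs,
                    const IntegerVector& adj, const NumericVector& sched,
                    const IntegerVector& avoided_in, const NumericVector& rho,
                    const NumericVector& pconf,
                    double kappa, double eta, double beta, double bias,
                    double sigma_a, double sigma_n, int variant,
                    double alpha0, double cost,
                    bool simulate, bool want_trace) {
  const int n = stim.size();
  const int m = rho.size();
  std::vector<double> V(m, 0.0);
  double alpha = alpha0;
  double ll = 0.0;

  IntegerVector avoided(n);
  NumericVector outcome(n);
  NumericVector tr_veff, tr_pavoid, tr_pe, tr_alpha;
  if (want_trace) {
    tr_veff = NumericVector(n);
    tr_pavoid = NumericVector(n);
    tr_pe = NumericVector(n);
    tr_alpha = NumericVector(n);
  }

  for (int t = 0; t < n; ++t) {
    const int i = stim[t] - 1;
    double v_eff = V[i];
    if (is_gs[t] == 1) {
      const double pc = pconf[t];
      v_eff = (1.0 - pc) * V[i] + pc * V[adj[i] - 1];
    }
    const double z = beta * (0.0 - v_eff - cost - bias);
    const double p = 1.0 / (1.0 + std::exp(-z));

    int a;
    if (simulate) {
      a = (unif_rand() < p) ? 1 : 0;
    } else {
      a = avoided_in[t];
    }
    avoided[t] = a;
    ll += a == 1 ? log_plogis(z) : log_plogis(-z);
    if (want_trace) {
      tr_veff[t] = v_eff;
      tr_pavoid[t] = p;
      tr_alpha[t] = alpha;  // associability in force on this trial
    }

    double R = 0.0, pe = 0.0;
    if (a == 1) {
      // avoidance always cancels the outcome; PE = 0 by definition,
      // associability decays
      alpha = (1.0 - eta) * alpha;
    } else {
      R = sched[t];
      pe = R - V[i];
      if (variant == 0) {
        V[i] += kappa * alpha * pe;
      } else {
        const double sigma = (variant == 1) ? sigma_a
                              : (R == -1.0 ? sigma_a : sigma_n);
        const double denom = 2.0 * sigma * sigma;
        for (int j = 0; j < m; ++j) {
          const double d = rho[i] - rho[j];
          V[j] += kappa * alpha * pe * std::exp(-(d * d) / denom);
        }
      }
      alpha = eta * std::fabs(pe) + (1.0 - eta) * alpha;
    }
    outcome[t] = a == 1 ? 0.0 : R;
    if (want_trace) tr_pe[t] = pe;
  }

  List out = List::create(_["logLik"] = ll,
                          _["avoided"] = avoided,
                          _["outcome"] = outcome,
                          _["values"] = NumericVector(V.begin(), V.end()));
  if (want_trace) {
    out["trace"] = List::create(_["v_eff"] = tr_veff,
                                _["p_avoid"] = tr_pavoid,
                                _["pe"] = tr_pe,
                                _["alpha"] = tr_alpha);
  }
  return out;
}

// [[Rcpp::export]]
List rl_loglik_cpp(IntegerVector stim, IntegerVector is_gs, IntegerVector adj,
                   NumericVector sched, IntegerVector avoided,
                   NumericVector rho, NumericVector pconf,
                   double kappa, double eta, double beta, double bias,
                   double sigma_a, double sigma_n, int variant,
                   double alpha0, double cost, bool want_trace) {
  return rl_pass(stim, is_gs, adj, sched, avoided, rho, pconf,
                 kappa, eta, beta, bias, sigma_a, sigma_n, variant,
                 alpha0, cost, false, want_trace);
}

// [[Rcpp::export]]
List rl_simulate_cpp(IntegerVector stim, IntegerVector is_gs, IntegerVector adj,
                     NumericVector sched, NumericVector rho,
                     NumericVector pconf,
                     double kappa, double eta, double beta, double bias,
                     double sigma_a, double sigma_n, int variant,
                     double alpha0, double cost, bool want_trace) {
  RNGScope scope;  // draws choices from R's RNG stream
  IntegerVector dummy(stim.size());
  return rl_pass(stim, is_gs, adj, sched, dummy, rho, pconf,
                 kappa, eta, beta, bias, sigma_a, sigma_n, variant,
                 alpha0, cost, true, want_trace);
}
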