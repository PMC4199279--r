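#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of one electrical window for the whole network.
//
// State (v, u, filtered drives, calcium, previous-step spikes) is taken in
// and returned, so consecutive windows are seamless. Spike transmission has
// a one-step delay: spikes emitted at step t enter the postsynaptic drives
// used at step t+1. Noise is one Gaussian draw per neuron per step from R's
// global RNG (neurons with ext_sd == 0 draw nothing), so a run is
// reproducible from a single set.seed().
//
// W is column-presynaptic: W(i, j) = synapses from j onto i.
// [[Rcpp::export]]
List simulate_window_cpp(NumericVector v0, NumericVector u0,
                         NumericVector dr_ex0, NumericVector dr_in0,
                         NumericVector ca0, IntegerVector last0,
                         NumericMatrix W, LogicalVector is_ex,
                         NumericVector ext_mean, NumericVector ext_sd,
                         int n_steps, double dt, List prm) {
  const int n = v0.size();
  const double k1 = prm["k1"], k2 = prm["k2"], k3 = prm["k3"];
  const double a = prm["a"], b = prm["b"], c = prm["c"], d = prm["d"];
  const double v_spike = prm["v_spike"], syn = prm["syn_strength"];
  const double mu = prm["mu"], beta = prm["beta"], tau_ca = prm["tau_ca"];

  const double dec_syn = std::exp(-dt / mu);
  const double dec_ca = std::exp(-dt / tau_ca);

  NumericVector v_ = clone(v0), u_ = clone(u0);
  NumericVector dre_ = clone(dr_ex0), dri_ = clone(dr_in0);
  NumericVector ca_ = clone(ca0);
  IntegerVector last_ = clone(last0);
  IntegerVector counts_(n);

  double *v = REAL(v_), *u = REAL(u_), *dre = REAL(dre_), *dri = REAL(dri_);
  double *ca = REAL(ca_);
  int *last = INTEGER(last_), *counts = INTEGER(counts_);
  const double *Wp = REAL(W);
  const int *exv = LOGICAL(is_ex);
  const double *em = REAL(ext_mean), *es = REAL(ext_sd);

  for (int t = 0; t < n_steps; ++t) {
    // synaptic filtering: decay, then deliver last step's spikes
    for (int i = 0; i < n; ++i) {
      dre[i] *= dec_syn;
      dri[i] *= dec_syn;
    }
    for (int j = 0; j < n; ++j) {
      if (!last[j]) continue;
      const double *col = Wp + (std::size_t)j * n;
      double *tgt = exv[j] ? dre : dri;
      for (int i = 0; i < n; ++i) tgt[i] += syn * col[i];
    }
    // membrane update, reset, calcium
    for (int i = 0; i < n; ++i) {
      double I = dre[i] - dri[i] + em[i];
      if (es[i] > 0.0) I += es[i] * norm_rand();
      const double vi = v[i];
      double vn = vi + dt * (k1 * vi * vi + k2 * vi + k3 - u[i] + I);
      double un = u[i] + dt * a * (b * vi - u[i]);
      int sp = 0;
      if (vn >= v_spike) {
        vn = c;
        un += d;
        sp = 1;
      }
      v[i] = vn;
      u[i] = un;
      ca[i] = ca[i] * dec_ca + beta * sp;
      last[i] = sp;
      counts[i] += sp;
    }
  }

  for (int i = 0; i < n; ++i)
    if (!R_finite(v[i]) || !R_finite(u[i]))
      stop("non-finite membrane state at neuron %d", i + 1);

  return List::create(_["v"] = v_, _["u"] = u_, _["dr_ex"] = dre_,
                      _["dr_in"] = dri_, _["ca"] = ca_,
                      _["last_spikes"] = last_, _["spike_counts"] = counts_);
}
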