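#include <Rcpp.h>
using namespace Rcpp;

// Integrate a block of Euler steps for a leaky firing-rate network with
// optional per-step BCM plasticity.
//
// Dynamics (synchronous update, pre-step rates on the right-hand side):
//   V_i <- V_i + (dt/tau_i) * (-V_i + I_i + sum_j Weff_ij * F_j)
//   F_i <- [tanh(V_i)]^+            (clamped to 0 for silenced units)
// Plasticity, applied after each step with that step's rates:
//   W_ij <- clip(W_ij + alpha_k * (F_i - theta_k) * F_j, wmin_k, wmax_k)
//
// W is the stored weight matrix (rows = post, cols = pre); `scale` holds
// multiplicative factors from block/scale manipulations, so the effective
// weight used by the dynamics is W * scale while plasticity acts on W.
// [[Rcpp::export]]
List cpp_run_block(NumericVector V0, NumericMatrix W, NumericMatrix scale,
                   NumericVector I, NumericVector dt_over_tau, int n_steps,
                   IntegerVector silenced, IntegerVector plastic_post,
                   IntegerVector plastic_pre, NumericVector alpha,
                   NumericVector wmin, NumericVector wmax,
                   NumericVector theta, bool record) {
  const int n = V0.size();
  const int np = plastic_post.size();
  NumericVector V = clone(V0);
  NumericMatrix Wm = clone(W);
  std::vector<bool> quiet(n, false);
  for (int s = 0; s < silenced.size(); ++s) quiet[silenced[s]] = true;

  NumericVector F(n), Vnew(n);
  for (int i = 0; i < n; ++i) {
    double f = std::tanh(V[i]);
    F[i] = (quiet[i] || f < 0.0) ? 0.0 : f;
  }

  NumericMatrix trace(record ? n : 0, record ? n_steps : 0);

  for (int t = 0; t < n_steps; ++t) {
    for (int i = 0; i < n; ++i) {
      double input = I[i];
      for (int j = 0; j < n; ++j) input += Wm(i, j) * scale(i, j) * F[j];
      Vnew[i] = V[i] + dt_over_tau[i] * (-V[i] + input);
      if (!std::isfinite(Vnew[i]))
        stop("voltage diverged (non-finite) for unit index %d at step %d",
             i + 1, t + 1);
    }
    for (int i = 0; i < n; ++i) {
      V[i] = Vnew[i];
      double f = std::tanh(V[i]);
      F[i] = (quiet[i] || f < 0.0) ? 0.0 : f;
    }
    for (int k = 0; k < np; ++k) {
      const int po = plastic_post[k], pr = plastic_pre[k];
      double w = Wm(po, pr) + alpha[k] * (F[po] - theta[k]) * F[pr];
      if (w < wmin[k]) w = wmin[k];
      if (w > wmax[k]) w = wmax[k];
      Wm(po, pr) = w;
    }
    if (record)
      for (int i = 0; i < n; ++i) trace(i, t) = F[i];
  }

  return List::create(_["V"] = V, _["F"] = F, _["W"] = Wm,
                      _["trace"] = trace);
}
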