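#include <Rcpp.h>
using namespace Rcpp;

// Shared per-trial machinery for the Rescorla-Wagner family.
// All symbol indices arriving here are block-local and 0-based (0..2);
// chosen < 0 marks a lost trial. Values reset to v0 whenever the block id
// changes (each block introduces three fresh symbols).

static inline double softmax2(double v_self, double v_other, double beta) {
  return 1.0 / (1.0 + std::exp(-beta * (v_self - v_other)));
}

// Latent trajectory given observed (or simulated) choices and outcomes.
// Returns onset values per trial, prediction error, probability of the
// recorded choice, and the chosen-minus-other value difference (used by the
// grid search, where the trajectory is independent of beta).
// [[Rcpp::export]]
List cpp_run_model(IntegerVector block, IntegerVector a_loc, IntegerVector b_loc,
                   IntegerVector chosen_loc, IntegerVector outcome,
                   double alpha_pos, double alpha_neg, double beta, double v0) {
  int n = block.size();
  NumericMatrix V(n, 3);
  NumericVector pe(n, NA_REAL), p_chosen(n, NA_REAL), vdiff(n, NA_REAL);
  double v[3] = {v0, v0, v0};
  int cur_block = n > 0 ? block[0] : 0;
  for (int t = 0; t < n; ++t) {
    if (block[t] != cur_block) {
      v[0] = v[1] = v[2] = v0;
      cur_block = block[t];
    }
    V(t, 0) = v[0]; V(t, 1) = v[1]; V(t, 2) = v[2];
    int c = chosen_loc[t];
    if (c >= 0) {
      int other = (c == a_loc[t]) ? b_loc[t] : a_loc[t];
      double d = v[c] - v[other];
      vdiff[t] = d;
      p_chosen[t] = softmax2(v[c], v[other], beta);
      double delta = (double)outcome[t] - v[c];
      pe[t] = delta;
      v[c] += (outcome[t] == 1 ? alpha_pos : alpha_neg) * delta;
    }
  }
  return List::create(_["values"] = V, _["pe"] = pe,
                      _["p_chosen"] = p_chosen, _["vdiff"] = vdiff);
}

// Forward simulation of one agent over a schedule. draws holds the
// pre-drawn Bernoulli outcome of each block-local symbol on each trial, so
// the outcome of any choice is schedule-determined. Uses R's RNG (one
// uniform per non-lost trial), hence deterministic under set.seed().
// [[Rcpp::export]]
List cpp_simulate_agent(IntegerVector block, IntegerVector a_loc, IntegerVector b_loc,
                        IntegerMatrix draws, LogicalVector lost,
                        double alpha_pos, double alpha_neg, double beta, double v0,
                        bool uniform_choice) {
  int n = block.size();
  IntegerVector chosen(n, NA_INTEGER), outcome(n, NA_INTEGER);
  double v[3] = {v0, v0, v0};
  int cur_block = n > 0 ? block[0] : 0;
  for (int t = 0; t < n; ++t) {
    if (block[t] != cur_block) {
      v[0] = v[1] = v[2] = v0;
      cur_block = block[t];
    }
    if (lost[t]) continue;
    int a = a_loc[t], b = b_loc[t];
    double p_a = uniform_choice ? 0.5 : softmax2(v[a], v[b], beta);
    int c = (unif_rand() < p_a) ? a : b;
    int r = draws(t, c);
    chosen[t] = c;
    outcome[t] = r;
    if (!uniform_choice)
      v[c] += (r == 1 ? alpha_pos : alpha_neg) * ((double)r - v[c]);
  }
  return List::create(_["chosen_loc"] = chosen, _["outcome"] = outcome);
}

// Simulation-based predicted choice probabilities: n_sims forward
// simulations in which the model's own choices drive the value updates;
// per trial, the predicted probability of the OBSERVED choice is the mean
// over simulations of the SoftMax probability each simulation assigns to
// that choice. Trials lost in the observed session are skipped everywhere
// (no choice, no update) so simulated and observed histories stay aligned.
// [[Rcpp::export]]
NumericVector cpp_sim_choice_prob(IntegerVector block, IntegerVector a_loc,
                                  IntegerVector b_loc, IntegerMatrix draws,
                                  IntegerVector obs_chosen_loc, int n_sims,
                                  double alpha_pos, double alpha_neg,
                                  double beta, double v0) {
  int n = block.size();
  NumericVector pbar(n, NA_REAL);
  std::vector<double> v(3 * n_sims, v0);
  int cur_block = n > 0 ? block[0] : 0;
  for (int t = 0; t < n; ++t) {
    if (block[t] != cur_block) {
      std::fill(v.begin(), v.end(), v0);
      cur_block = block[t];
    }
    int c_obs = obs_chosen_loc[t];
    if (c_obs < 0) continue;
    int a = a_loc[t], b = b_loc[t];
    int o_obs = (c_obs == a) ? b : a;
    double acc = 0.0;
    for (int s = 0; s < n_sims; ++s) {
      double *vs = &v[3 * s];
      acc += softmax2(vs[c_obs], vs[o_obs], beta);
      double p_a = softmax2(vs[a], vs[b], beta);
      int c = (unif_rand() < p_a) ? a : b;
      int r = draws(t, c);
      vs[c] += (r == 1 ? alpha_pos : alpha_neg) * ((double)r - vs[c]);
    }
    pbar[t] = acc / n_sims;
  }
  return pbar;
}

// Value-difference trajectories for a batch of (alpha_pos, alpha_neg)
// pairs in one pass over the data; beta never enters the recursion, so the
// grid search evaluates all beta values analytically from these.
// Lost trials yield NA rows.
// [[Rcpp::export]]
NumericMatrix cpp_vdiff_grid(IntegerVector block, IntegerVector a_loc,
                             IntegerVector b_loc, IntegerVector chosen_loc,
                             IntegerVector outcome,
                             NumericVector alpha_pos, NumericVector alpha_neg,
                             double v0) {
  int n = block.size(), k = alpha_pos.size();
  NumericMatrix D(n, k);
  std::fill(D.begin(), D.end(), NA_REAL);
  std::vector<double> v(3 * k, v0);
  int cur_block = n > 0 ? block[0] : 0;
  for (int t = 0; t < n; ++t) {
    if (block[t] != cur_block) {
      std::fill(v.begin(), v.end(), v0);
      cur_block = block[t];
    }
    int c = chosen_loc[t];
    if (c < 0) continue;
    int other = (c == a_loc[t]) ? b_loc[t] : a_loc[t];
    for (int j = 0; j < k; ++j) {
      double *vj = &v[3 * j];
      D(t, j) = vj[c] - vj[other];
      double delta = (double)outcome[t] - vj[c];
      vj[c] += (outcome[t] == 1 ? alpha_pos[j] : alpha_neg[j]) * delta;
    }
  }
  return D;
}
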