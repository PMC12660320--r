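# Independent straight-line oracles, deliberately separate from the
# package's compiled implementation.

# Plain-R value recursion over a session generated by build_schedule()
# (symbol ids (block-1)*3 + 1..3).
oracle_trajectory <- function(alpha_pos, alpha_neg, beta, v0, trials) {
  n <- nrow(trials)
  V <- matrix(NA_real_, n, 3)
  pe <- rep(NA_real_, n)
  p <- rep(NA_real_, n)
  v <- rep(v0, 3)
  cur <- trials$block[1]
  for (t in seq_len(n)) {
    if (trials$block[t] != cur) {
      v <- rep(v0, 3)
      cur <- trials$block[t]
    }
    V[t, ] <- v
    if (!trials$lost[t]) {
      off <- (trials$block[t] - 1) * 3
      ch <- trials$chosen[t] - off
      a <- trials$sym_left[t] - off
      b <- trials$sym_right[t] - off
      other <- if (ch == a) b else a
      p[t] <- 1 / (1 + exp(-beta * (v[ch] - v[other])))
      pe[t] <- trials$outcome[t] - v[ch]
      rate <- if (trials$outcome[t] == 1) alpha_pos else alpha_neg
      v[ch] <- v[ch] + rate * pe[t]
    }
  }
  list(V = V, pe = pe, p = p)
}

oracle_loglik <- function(alpha_pos, alpha_neg, beta, v0, trials) {
  o <- oracle_trajectory(alpha_pos, alpha_neg, beta, v0, trials)
  sum(log(pmax(o$p[!trials$lost], 1e-12)))
}

# Small random session: one 20-trial block with frequent reversals,
# choices from a uniform agent.
random_session <- function(seed, n = 20, lost_rate = 0) {
  cfg <- task_config(block_lengths = n, reversal_period = 7)
  sched <- build_schedule(cfg, seed = seed)
  simulate_random_agent(sched, lost_rate = lost_rate, seed = seed + 1)
}

# Hand-built single-block trial table; syms are global ids 1..3, hp the
# current high-probability symbol per trial.
toy_trials <- function(left, right, chosen, outcome, hp,
                       lost = rep(FALSE, length(left))) {
  data.frame(block = 1L, trial = seq_along(left),
             sym_left = left, sym_right = right,
             chosen = ifelse(lost, NA_integer_, chosen),
             outcome = ifelse(lost, NA_integer_, outcome),
             lost = lost, hp_symbol = hp)
}
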