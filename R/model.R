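#' Rescorla-Wagner value update
#'
#' One step of the delta rule: `v + alpha * (outcome - v)`. With binary
#' outcomes and a learning rate in \[0, 1\] the result stays in \[0, 1\].
#'
#' @param v Current expected value(s) in \[0, 1\].
#' @param outcome Observed outcome(s), 0 (non-reward) or 1 (reward).
#' @param alpha Learning rate in \[0, 1\].
#' @return Updated value(s).
#' @examples
#' update_value(0.5, 1, 0.3) # 0.65
#' @export
update_value <- function(v, outcome, alpha) {
  if (any(alpha < 0 | alpha > 1 | is.na(alpha)))
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  stopifnot(all(v >= 0 & v <= 1), all(outcome %in% c(0, 1)))
  v + alpha * (outcome - v)
}

#' Reward prediction error
#'
#' @inheritParams update_value
#' @return `outcome - v`, in \[-1, 1\] for binary outcomes.
#' @examples
#' prediction_error(0, 0.7) # -0.7
#' @export
prediction_error <- function(outcome, v) {
  stopifnot(all(v >= 0 & v <= 1))
  outcome - v
}

#' SoftMax choice probability for a two-option trial
#'
#' Logistic of the scaled value difference:
#' `P(A) = 1 / (1 + exp(-beta * (v_a - v_b)))`. `beta` is the inverse
#' temperature; `beta = 0` yields indifference (0.5) regardless of values.
#'
#' @param v_a,v_b Expected values of the two shown options.
#' @param beta Inverse temperature, `>= 0`.
#' @return Probability of choosing option A; `P(A) + P(B) = 1`.
#' @examples
#' softmax_prob(0.7, 0.3, 5) # 1 / (1 + exp(-2))
#' @export
softmax_prob <- function(v_a, v_b, beta) {
  if (any(beta < 0 | is.na(beta)))
    stop("`beta` must be >= 0", call. = FALSE)
  plogis(beta * (v_a - v_b))
}

#' Agent / model parameters for the Rescorla-Wagner family
#'
#' `rw1` is the single-learning-rate Rescorla-Wagner model (parameters
#' `alpha`, `beta`); `rw2` the valence-asymmetric variant with separate
#' learning rates after reward (`alpha_pos`) and non-reward (`alpha_neg`).
#' `rw2` with `alpha_pos == alpha_neg` is exactly `rw1`. All symbols start
#' at the uninformative midpoint `v0 = 0.5` and reset there at each block
#' boundary, where three fresh symbols are introduced.
#'
#' Degenerate control agents (`alpha = 0`, `beta = 0`) are legal here; the
#' fitting constraints (`0.1 < alpha < 0.9`, `beta > 0`) are enforced only
#' during estimation.
#'
#' @param model `"rw1"` or `"rw2"`.
#' @param alpha Learning rate (rw1), in \[0, 1\].
#' @param alpha_pos,alpha_neg Learning rates after reward / non-reward
#'   (rw2), in \[0, 1\].
#' @param beta Inverse temperature, `>= 0`.
#' @param v0 Initial expected value in \[0, 1\].
#' @return Object of class `agent_params`.
#' @examples
#' agent_params("rw2", alpha_pos = 0.6, alpha_neg = 0.2, beta = 5)
#' @export
agent_params <- function(model = c("rw1", "rw2"), alpha = NULL,
                         alpha_pos = NULL, alpha_neg = NULL,
                         beta, v0 = 0.5) {
  model <- match.arg(model)
  if (model == "rw1") {
    if (is.null(alpha)) .stop_field("alpha", "required for model rw1")
    alpha_pos <- alpha_neg <- alpha
  } else {
    if (is.null(alpha_pos) || is.null(alpha_neg))
      .stop_field("alpha_pos/alpha_neg", "required for model rw2")
    alpha <- NULL
  }
  for (a in c(alpha_pos, alpha_neg))
    if (!is.numeric(a) || is.na(a) || a < 0 || a > 1)
      .stop_field("alpha", "learning rates must lie in [0, 1]")
  if (!is.numeric(beta) || is.na(beta) || beta < 0)
    .stop_field("beta", "must be >= 0")
  if (!is.numeric(v0) || is.na(v0) || v0 < 0 || v0 > 1)
    .stop_field("v0", "must lie in [0, 1]")
  structure(list(model = model, alpha = alpha,
                 alpha_pos = alpha_pos, alpha_neg = alpha_neg,
                 beta = beta, v0 = v0),
            class = "agent_params")
}

#' @method print agent_params
#' @export
print.agent_params <- function(x, ...) {
  if (x$model == "rw1")
    cat(sprintf("rw1 agent: alpha = %.3g, beta = %.3g, v0 = %.2f\n",
                x$alpha, x$beta, x$v0))
  else
    cat(sprintf("rw2 agent: alpha+ = %.3g, alpha- = %.3g, beta = %.3g, v0 = %.2f\n",
                x$alpha_pos, x$alpha_neg, x$beta, x$v0))
  invisible(x)
}

.as_agent_params <- function(params) {
  if (inherits(params, "agent_params")) return(params)
  do.call(agent_params, params)
}

#' Latent value / prediction-error trajectory over a session
#'
#' Iterates the Rescorla-Wagner recursion over a session's trials in order.
#' On each non-lost trial the SoftMax probability of the recorded choice is
#' computed from the two shown symbols' current values, the prediction
#' error from the recorded outcome, and only the chosen symbol's value is
#' updated -- with `alpha` (rw1), or `alpha_pos` after reward and
#' `alpha_neg` after non-reward (rw2). Lost trials propagate values
#' unchanged and carry `NA` latents. Values reset to `v0` at block
#' boundaries (each block has fresh symbols).
#'
#' @param params An [agent_params()] (or a list coercible to one).
#' @param trials Trial table for one session: columns `block`, `trial`,
#'   `sym_left`, `sym_right`, `chosen`, `outcome`, `lost`.
#' @return Data frame of class `latent_trajectory`: `trial`, `v_sym0`,
#'   `v_sym1`, `v_sym2` (values of the block's first/second/third symbol at
#'   trial onset), `pe`, `p_chosen`. The block-local to global symbol
#'   mapping is kept in `attr(, "symbols")`.
#' @examples
#' sched <- build_schedule(task_config(), seed = 1)
#' agent <- agent_params("rw1", alpha = 0.5, beta = 5)
#' trials <- simulate_agent(agent, sched, seed = 2)
#' traj <- run_model(agent, trials)
#' head(traj)
#' @export
run_model <- function(params, trials) {
  params <- .as_agent_params(params)
  stopifnot(all(c("block", "sym_left", "sym_right", "chosen", "outcome",
                  "lost") %in% names(trials)))
  if (any(!trials$lost & (is.na(trials$chosen) | is.na(trials$outcome))))
    stop("non-lost trials must carry a choice and an outcome", call. = FALSE)
  loc <- .localize(trials)
  outcome <- trials$outcome
  outcome[is.na(outcome)] <- 0L
  res <- cpp_run_model(as.integer(trials$block), loc$a_loc, loc$b_loc,
                       loc$chosen_loc, as.integer(outcome),
                       params$alpha_pos, params$alpha_neg,
                       params$beta, params$v0)
  out <- data.frame(trial = if (!is.null(trials$trial)) trials$trial
                            else seq_len(nrow(trials)),
                    v_sym0 = res$values[, 1L],
                    v_sym1 = res$values[, 2L],
                    v_sym2 = res$values[, 3L],
                    pe = res$pe, p_chosen = res$p_chosen)
  attr(out, "vdiff") <- res$vdiff
  attr(out, "symbols") <- loc$symbols
  attr(out, "params") <- params
  class(out) <- c("latent_trajectory", "data.frame")
  out
}

#' Expected value of the current high-probability symbol, per trial
#'
#' Convenience accessor for the model-based learning-curve variant: returns,
#' for every row of `trials`, the latent expected value that the model
#' assigns to the symbol currently carrying the high reward probability.
#'
#' @param latents A [run_model()] trajectory for `trials`.
#' @param trials The matching trial table (needs `block` and `hp_symbol`).
#' @return Numeric vector, one value per trial.
#' @export
hp_value <- function(latents, trials) {
  stopifnot(nrow(latents) == nrow(trials), !is.null(trials$hp_symbol))
  loc <- .localize(trials, check_chosen = FALSE)
  v <- as.matrix(latents[, c("v_sym0", "v_sym1", "v_sym2")])
  v[cbind(seq_len(nrow(v)), loc$hp_loc + 1L)]
}

#' Write a latent trajectory as a delimited table
#'
#' Columns `trial, v_sym0, v_sym1, v_sym2, pe, p_chosen` -- suitable as
#' parametric-regressor material for external (e.g. fMRI GLM) tools.
#'
#' @param latents A `latent_trajectory`.
#' @param path File path.
#' @export
write_latents <- function(latents, path) {
  write.csv(as.data.frame(latents)[, c("trial", "v_sym0", "v_sym1", "v_sym2",
                                       "pe", "p_chosen")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
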