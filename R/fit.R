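#' Parameter grid for the initial likelihood search
#'
#' The estimation constraints follow the original fitting procedure:
#' `beta > 0` and `0.1 < alpha < 0.9`. Learning-rate grid points are placed
#' strictly inside the open alpha interval; inverse-temperature points are
#' log-spaced over `beta_range`.
#'
#' @param alpha_range Open interval for learning rates.
#' @param alpha_steps Number of grid points per learning rate.
#' @param beta_range Interval for the inverse temperature; lower bound > 0.
#' @param beta_steps Number of (log-spaced) beta grid points.
#' @return Object of class `grid_spec` with `alpha_values` and
#'   `beta_values`.
#' @export
grid_spec <- function(alpha_range = c(0.1, 0.9), alpha_steps = 17L,
                      beta_range = c(0.1, 20), beta_steps = 20L) {
  if (length(alpha_range) != 2L || alpha_range[1] < 0 || alpha_range[2] > 1 ||
      alpha_range[1] >= alpha_range[2])
    .stop_field("alpha_range", "must be an interval inside [0, 1]")
  if (length(beta_range) != 2L || beta_range[1] <= 0 ||
      beta_range[1] >= beta_range[2])
    .stop_field("beta_range", "must be an interval with positive lower bound")
  alpha_steps <- as.integer(alpha_steps); beta_steps <- as.integer(beta_steps)
  if (alpha_steps < 2L) .stop_field("alpha_steps", "must be >= 2")
  if (beta_steps < 2L) .stop_field("beta_steps", "must be >= 2")
  alpha_values <- seq(alpha_range[1], alpha_range[2],
                      length.out = alpha_steps + 2L)[-c(1L, alpha_steps + 2L)]
  beta_values <- exp(seq(log(beta_range[1]), log(beta_range[2]),
                         length.out = beta_steps))
  structure(list(alpha_range = alpha_range, alpha_steps = alpha_steps,
                 beta_range = beta_range, beta_steps = beta_steps,
                 alpha_values = alpha_values, beta_values = beta_values),
            class = "grid_spec")
}

.check_session <- function(trials) {
  stopifnot(all(c("block", "sym_left", "sym_right", "chosen", "outcome",
                  "lost") %in% names(trials)))
  if (!any(!trials$lost))
    stop("session has no non-lost trials to fit", call. = FALSE)
  invisible(trials)
}

#' Log-likelihood of the observed choices
#'
#' Sum over non-lost trials of the log SoftMax probability that the model,
#' run on the participant's observed choices and outcomes, assigns to each
#' recorded choice. Probabilities are floored at 1e-12 before the log.
#'
#' @inheritParams run_model
#' @return Scalar log-likelihood (<= 0).
#' @export
loglik_observed <- function(params, trials) {
  .check_session(trials)
  traj <- run_model(params, trials)
  p <- traj$p_chosen[!trials$lost]
  sum(log(pmax(p, .PROB_FLOOR)))
}

#' Simulation-based predicted-choice-probability log-likelihood
#'
#' Runs `n_sims` forward simulations per parameter set in which the model's
#' own SoftMax choices (not the observed ones) drive the value updates,
#' drawing outcomes from the schedule's pre-drawn table. For each trial the
#' predicted probability of the participant's observed choice is the mean
#' across simulations of the SoftMax probability each simulation assigns to
#' that choice; the log-likelihood sums the logs of these (floored) means
#' over non-lost trials. Deterministic given `seed`.
#'
#' @inheritParams run_model
#' @param schedule The [build_schedule()] schedule the session was recorded
#'   on (block structure must match `trials`).
#' @param n_sims Number of forward simulations (the reference procedure
#'   uses 1000).
#' @param seed Optional integer seed.
#' @return Scalar log-likelihood.
#' @export
loglik_simulated <- function(params, schedule, trials, n_sims = 1000L,
                             seed = NULL) {
  params <- .as_agent_params(params)
  .check_session(trials)
  n_sims <- as.integer(n_sims)
  if (is.na(n_sims) || n_sims < 1L) .stop_field("n_sims", "must be >= 1")
  if (nrow(schedule) != nrow(trials) ||
      !all(schedule$block == trials$block) ||
      !all(schedule$sym_left == trials$sym_left) ||
      !all(schedule$sym_right == trials$sym_right))
    stop("`schedule` does not match the observed session's structure",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  df <- as.data.frame(schedule)
  df$chosen <- trials$chosen
  loc <- .localize(df)
  draws <- as.matrix(df[, c("draw_sym0", "draw_sym1", "draw_sym2")])
  storage.mode(draws) <- "integer"
  pbar <- cpp_sim_choice_prob(as.integer(df$block), loc$a_loc, loc$b_loc,
                              draws, loc$chosen_loc, n_sims,
                              params$alpha_pos, params$alpha_neg,
                              params$beta, params$v0)
  sum(log(pmax(pbar[!trials$lost], .PROB_FLOOR)))
}

# Alpha cells of the grid, ordered so that which.max() tie-breaks toward
# the smallest learning rate(s), then the smallest beta.
.grid_alpha_cells <- function(model, grid) {
  a <- grid$alpha_values
  if (model == "rw1")
    data.frame(alpha_pos = a, alpha_neg = a)
  else {
    cells <- expand.grid(alpha_neg = a, alpha_pos = a)[, c("alpha_pos", "alpha_neg")]
    cells[order(cells$alpha_pos, cells$alpha_neg), , drop = FALSE]
  }
}

#' Exhaustive grid search for starting parameters
#'
#' Evaluates the chosen likelihood over the full Cartesian parameter grid
#' (`alpha x beta` for rw1, `alpha_pos x alpha_neg x beta` for rw2) and
#' returns the maximising cell. Ties break toward the smallest learning
#' rate(s), then the smallest beta. In observed-likelihood mode the value
#' trajectory is independent of beta, so each learning-rate cell is
#' propagated once and all beta values are scored analytically.
#'
#' @inheritParams loglik_simulated
#' @param model `"rw1"` or `"rw2"`.
#' @param grid A [grid_spec()].
#' @param likelihood `"observed"` (analytic, default) or `"simulated"`.
#' @param v0 Initial value handed to the model.
#' @return List with `par` (named numeric), `logl`, and `cells` (the full
#'   grid with one log-likelihood per cell).
#' @export
grid_search <- function(trials, model = c("rw2", "rw1"), grid = grid_spec(),
                        likelihood = c("observed", "simulated"),
                        schedule = NULL, n_sims = 1000L, seed = NULL,
                        v0 = 0.5) {
  model <- match.arg(model)
  likelihood <- match.arg(likelihood)
  .check_session(trials)
  acells <- .grid_alpha_cells(model, grid)
  betas <- grid$beta_values
  if (likelihood == "observed") {
    loc <- .localize(trials)
    outcome <- trials$outcome
    outcome[is.na(outcome)] <- 0L
    D <- cpp_vdiff_grid(as.integer(trials$block), loc$a_loc, loc$b_loc,
                        loc$chosen_loc, as.integer(outcome),
                        acells$alpha_pos, acells$alpha_neg, v0)
    D <- D[!trials$lost, , drop = FALSE]
    LL <- vapply(betas, function(b)
      colSums(log(pmax(plogis(b * D), .PROB_FLOOR))),
      numeric(nrow(acells)))           # k_alpha x n_beta
  } else {
    if (is.null(schedule))
      stop("simulated likelihood needs the session's `schedule`", call. = FALSE)
    LL <- matrix(NA_real_, nrow(acells), length(betas))
    for (i in seq_len(nrow(acells)))
      for (j in seq_along(betas)) {
        p <- agent_params("rw2", alpha_pos = acells$alpha_pos[i],
                          alpha_neg = acells$alpha_neg[i],
                          beta = betas[j], v0 = v0)
        LL[i, j] <- loglik_simulated(p, schedule, trials, n_sims, seed = seed)
      }
  }
  cells <- data.frame(alpha_pos = rep(acells$alpha_pos, each = length(betas)),
                      alpha_neg = rep(acells$alpha_neg, each = length(betas)),
                      beta = rep(betas, times = nrow(acells)),
                      logl = as.vector(t(LL)))
  best <- which.max(cells$logl)
  par <- if (model == "rw1")
    c(alpha = cells$alpha_pos[best], beta = cells$beta[best])
  else
    c(alpha_pos = cells$alpha_pos[best], alpha_neg = cells$alpha_neg[best],
      beta = cells$beta[best])
  if (model == "rw1") {
    cells$alpha <- cells$alpha_pos
    cells <- cells[, c("alpha", "beta", "logl")]
  }
  list(par = par, logl = cells$logl[best], cells = cells)
}

# Constrained <-> unconstrained reparameterisation (logit for alpha into
# the open constraint interval, log for beta).
.to_unconstrained <- function(par, arange) {
  out <- par
  a <- grepl("^alpha", names(par))
  eps <- 1e-8
  frac <- pmin(pmax((par[a] - arange[1]) / diff(arange), eps), 1 - eps)
  out[a] <- qlogis(frac)
  out["beta"] <- log(max(par["beta"], 1e-8))
  out
}

.to_constrained <- function(theta, arange) {
  out <- theta
  a <- grepl("^alpha", names(theta))
  out[a] <- arange[1] + diff(arange) * plogis(theta[a])
  out["beta"] <- exp(theta[["beta"]])
  out
}

.params_from_vector <- function(par, model, v0) {
  if (model == "rw1")
    agent_params("rw1", alpha = par[["alpha"]], beta = par[["beta"]], v0 = v0)
  else
    agent_params("rw2", alpha_pos = par[["alpha_pos"]],
                 alpha_neg = par[["alpha_neg"]], beta = par[["beta"]], v0 = v0)
}

#' Simplex refinement of a likelihood maximum
#'
#' Derivative-free Nelder-Mead maximisation of the session likelihood,
#' started from `start` (usually the grid-search maximiser). Parameters are
#' smoothly reparameterised to enforce the constraint box (logit for the
#' learning rates into the open alpha interval, log for `beta > 0`), so the
#' simplex itself is unconstrained. The refined log-likelihood can never
#' fall below the start value.
#'
#' @inheritParams grid_search
#' @param start Named numeric starting parameters inside the constraint box
#'   (`alpha`+`beta`, or `alpha_pos`+`alpha_neg`+`beta`).
#' @param control Passed to [stats::optim()]; defaults to
#'   `maxit = 2000`, `reltol = 1e-6`.
#' @return An `rw_fit` object (see [rw_fit()]).
#' @export
refine_simplex <- function(start, trials, model = c("rw2", "rw1"),
                           likelihood = c("observed", "simulated"),
                           grid = grid_spec(), schedule = NULL,
                           n_sims = 1000L, seed = NULL, v0 = 0.5,
                           control = list()) {
  model <- match.arg(model)
  likelihood <- match.arg(likelihood)
  .check_session(trials)
  arange <- grid$alpha_range
  control <- utils::modifyList(list(maxit = 2000L, reltol = 1e-6), control)
  if (likelihood == "observed") {
    # hoist the data prep out of the objective: the simplex calls it
    # hundreds of times per session
    loc <- .localize(trials)
    outcome <- trials$outcome
    outcome[is.na(outcome)] <- 0L
    outcome <- as.integer(outcome)
    block <- as.integer(trials$block)
    nonlost <- !trials$lost
    ll_fun <- function(p) {
      res <- cpp_run_model(block, loc$a_loc, loc$b_loc, loc$chosen_loc,
                           outcome, p$alpha_pos, p$alpha_neg, p$beta, p$v0)
      sum(log(pmax(res$p_chosen[nonlost], .PROB_FLOOR)))
    }
  } else {
    ll_fun <- function(p) loglik_simulated(p, schedule, trials, n_sims,
                                           seed = seed)
  }
  negll <- function(theta) {
    par <- .to_constrained(setNames(theta, names(start)), arange)
    -ll_fun(.params_from_vector(par, model, v0))
  }
  theta0 <- .to_unconstrained(start, arange)
  opt <- optim(theta0, negll, method = "Nelder-Mead", control = control)
  par <- .to_constrained(setNames(opt$par, names(start)), arange)
  n <- sum(!trials$lost)
  d <- if (model == "rw1") 2L else 3L
  logl <- -opt$value
  structure(list(
    model = model,
    coefficients = par,
    logLik = logl,
    n = n, df = d,
    bic = bic_score(logl, d, n),
    converged = opt$convergence == 0L,
    likelihood = likelihood,
    v0 = v0,
    grid_best = list(par = start, logl = -negll(theta0)),
    n_sims = if (likelihood == "simulated") n_sims else NA_integer_,
    data = trials,
    schedule = schedule,
    call = match.call()),
    class = "rw_fit")
}

#' Fit a Rescorla-Wagner model to one session by maximum likelihood
#'
#' The canonical fitting entry point: an exhaustive [grid_search()]
#' determines reasonably good starting parameters under the constraints
#' `beta > 0`, `0.1 < alpha < 0.9`, which a Nelder-Mead simplex
#' ([refine_simplex()]) then refines to the final estimates. Goodness of
#' fit is the log-likelihood of the observed choices; alternatively the
#' simulation-based predicted-choice-probability likelihood
#' ([loglik_simulated()], 1000 forward simulations per parameter set by
#' default) reproduces the reference procedure at higher cost.
#'
#' @inheritParams grid_search
#' @param control Optimiser control, see [refine_simplex()].
#' @return An object of class `rw_fit` with components `model`,
#'   `coefficients`, `logLik`, `n` (non-lost trials), `df` (free
#'   parameters: 2 for rw1, 3 for rw2), `bic`, `converged`, `likelihood`
#'   (mode), and `grid_best`. Methods: [print()], [summary()], [coef()],
#'   [logLik()] (so [stats::BIC()] agrees with `$bic`), [predict()],
#'   [fitted()], [residuals()] (prediction errors), [simulate()] and
#'   [plot()].
#' @examples
#' sched <- build_schedule(task_config(), seed = 1)
#' trials <- simulate_agent(agent_params("rw1", alpha = 0.5, beta = 5),
#'                          sched, seed = 2)
#' fit <- rw_fit(trials, model = "rw1")
#' coef(fit); BIC(fit)
#' @export
rw_fit <- function(trials, model = c("rw2", "rw1"),
                   likelihood = c("observed", "simulated"),
                   grid = grid_spec(), schedule = NULL, n_sims = 1000L,
                   seed = NULL, v0 = 0.5, control = list()) {
  model <- match.arg(model)
  likelihood <- match.arg(likelihood)
  gs <- grid_search(trials, model = model, grid = grid,
                    likelihood = likelihood, schedule = schedule,
                    n_sims = n_sims, seed = seed, v0 = v0)
  fit <- refine_simplex(gs$par, trials, model = model,
                        likelihood = likelihood, grid = grid,
                        schedule = schedule, n_sims = n_sims, seed = seed,
                        v0 = v0, control = control)
  fit$grid_best <- list(par = gs$par, logl = gs$logl)
  fit$call <- match.call()
  fit
}

#' Bayesian Information Criterion
#'
#' `BIC = -2 logL + d log(n)`: the goodness of fit penalised by model
#' complexity, with `d` free parameters and `n` data points (non-lost
#' trials). Lower is better.
#'
#' @param logl Log-likelihood.
#' @param d Number of free parameters (>= 0).
#' @param n Number of data points (>= 1).
#' @return The BIC value.
#' @examples
#' bic_score(-100, 2, 320) # 200 + 2 * log(320)
#' @export
bic_score <- function(logl, d, n) {
  if (any(n < 1)) .stop_field("n", "must be >= 1")
  if (any(d < 0)) .stop_field("d", "must be >= 0")
  -2 * logl + d * log(n)
}

#' Latent trajectory implied by a fitted model
#'
#' Re-enters the fitted parameters into the learning algorithm, this time
#' driven by the participant's observed choices, yielding the trial-wise
#' expected values and prediction errors used by the model-based
#' behavioural analyses (and as fMRI-regressor material).
#'
#' @param fit An `rw_fit`.
#' @param trials Trial table; defaults to the fitted session.
#' @return A [run_model()] `latent_trajectory`.
#' @export
latents_from_fit <- function(fit, trials = fit$data) {
  stopifnot(inherits(fit, "rw_fit"))
  run_model(.params_from_vector(coef(fit), fit$model, fit$v0), trials)
}

# ---- S3 methods --------------------------------------------------------

#' @method print rw_fit
#' @export
print.rw_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Rescorla-Wagner fit (%s, %s likelihood)\n",
              x$model, x$likelihood))
  print(round(x$coefficients, digits))
  cat(sprintf("logLik %.*f on %d non-lost trials; BIC %.*f;%s converged\n",
              digits, x$logLik, x$n, digits, x$bic,
              if (x$converged) "" else " NOT"))
  invisible(x)
}

#' @method summary rw_fit
#' @export
summary.rw_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.rw_fit")
}

#' @method print summary.rw_fit
#' @export
print.summary.rw_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat("grid start: ")
  cat(paste(names(f$grid_best$par), round(f$grid_best$par, digits),
            sep = " = ", collapse = ", "),
      sprintf(" (logLik %.*f)\n", digits, f$grid_best$logl))
  pe <- residuals(f)
  cat(sprintf("prediction errors: mean %.3f, sd %.3f\n",
              mean(pe, na.rm = TRUE), sd(pe, na.rm = TRUE)))
  invisible(x)
}

#' @export
coef.rw_fit <- function(object, ...) object$coefficients

#' @export
logLik.rw_fit <- function(object, ...)
  structure(object$logLik, df = object$df, nobs = object$n, class = "logLik")

#' @export
nobs.rw_fit <- function(object, ...) object$n

#' @export
predict.rw_fit <- function(object, newdata = NULL,
                           type = c("p_chosen", "pe", "values"), ...) {
  type <- match.arg(type)
  traj <- latents_from_fit(object, if (is.null(newdata)) object$data else newdata)
  switch(type,
         p_chosen = traj$p_chosen,
         pe = traj$pe,
         values = as.matrix(traj[, c("v_sym0", "v_sym1", "v_sym2")]))
}

#' @export
fitted.rw_fit <- function(object, ...) predict(object, type = "p_chosen")

#' @export
residuals.rw_fit <- function(object, ...) predict(object, type = "pe")

#' @export
simulate.rw_fit <- function(object, nsim = 1, seed = NULL,
                            schedule = object$schedule, lost_rate = 0, ...) {
  if (is.null(schedule))
    stop("supply the `schedule` to simulate on", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- .params_from_vector(coef(object), object$model, object$v0)
  out <- lapply(seq_len(nsim), function(i)
    simulate_agent(p, schedule, lost_rate = lost_rate))
  if (nsim == 1) out[[1]] else out
}

#' @export
plot.rw_fit <- function(x, ...) {
  traj <- latents_from_fit(x)
  v <- as.matrix(traj[, c("v_sym0", "v_sym1", "v_sym2")])
  graphics::matplot(traj$trial, v, type = "l", lty = 1,
                    col = c("#1b9e77", "#d95f02", "#7570b3"),
                    xlab = "trial", ylab = "expected value V",
                    main = sprintf("fitted %s latent values", x$model), ...)
  graphics::abline(v = traj$trial[c(FALSE, diff(x$data$block) != 0)],
                   lty = 3, col = "grey60")
  invisible(x)
}

# ---- cohort-level fitting and model comparison -------------------------

#' Fit a model to every session of a cohort
#'
#' Fits [rw_fit()] independently to each group of trials -- by default per
#' subject x condition x block, the granularity of the reference analysis.
#' Dropping `"block"` from `by` gives the pooled per-subject x condition
#' convenience mode.
#'
#' @inheritParams rw_fit
#' @param trials Cohort trial table (needs the `by` columns).
#' @param by Grouping columns, a subset of
#'   `c("subject", "condition", "block")`.
#' @param ... Passed on to [rw_fit()].
#' @return Data frame with one row per fitted session and columns
#'   `subject, condition, block, model, alpha, alpha_pos, alpha_neg, beta,
#'   logl, n, d, bic, converged, mode`.
#' @export
fit_sessions <- function(trials, model = c("rw2", "rw1"),
                         by = c("subject", "condition", "block"), ...) {
  model <- match.arg(model)
  by <- intersect(by, names(trials))
  if (!length(by)) stop("no grouping columns found in `trials`", call. = FALSE)
  idx <- split(seq_len(nrow(trials)), trials[by], drop = TRUE, sep = "\r")
  rows <- lapply(idx, function(i) {
    g <- trials[i, , drop = FALSE]
    fit <- rw_fit(g, model = model, ...)
    cf <- coef(fit)
    data.frame(
      subject = if ("subject" %in% by) g$subject[1L] else NA,
      condition = if ("condition" %in% by) as.character(g$condition[1L]) else NA,
      block = if ("block" %in% by) g$block[1L] else NA,
      model = model,
      alpha = if (model == "rw1") cf[["alpha"]] else NA_real_,
      alpha_pos = if (model == "rw2") cf[["alpha_pos"]] else cf[["alpha"]],
      alpha_neg = if (model == "rw2") cf[["alpha_neg"]] else cf[["alpha"]],
      beta = cf[["beta"]],
      logl = fit$logLik, n = fit$n, d = fit$df, bic = fit$bic,
      converged = fit$converged, mode = fit$likelihood)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a fit table as a delimited file
#'
#' @param fits A [fit_sessions()] table.
#' @param path File path.
#' @export
write_fits <- function(fits, path) {
  cols <- c("subject", "condition", "block", "model", "alpha", "alpha_pos",
            "alpha_neg", "beta", "logl", "n", "d", "bic", "converged", "mode")
  write.csv(fits[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Compare models by summed subject-wise BIC
#'
#' Sums the per-session BIC over subjects for each candidate model and
#' declares the model with the smaller sum the winner (lower BIC indicates
#' better fit, complexity-penalised). An exact tie is reported explicitly.
#' The comparison requires the same subjects (and sessions) under every
#' model and is invariant to their ordering.
#'
#' @param ... Named [fit_sessions()] tables, one per model (names default
#'   to each table's `model` column).
#' @return Object of class `bic_comparison`: a `table` data frame
#'   (model, total bic, n sessions), the `winner` (or `NA` on a tie) and a
#'   `tie` flag.
#' @examples
#' \dontrun{
#' compare_models(rw1 = fits1, rw2 = fits2)
#' }
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1L]]) && !is.data.frame(fits[[1L]]))
    fits <- fits[[1L]]
  if (length(fits) < 2L) stop("need at least two models", call. = FALSE)
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- vapply(fits, function(f) as.character(f$model[1L]), "")
  keys <- lapply(fits, function(f)
    sort(paste(f$subject, f$condition, f$block, sep = "\r")))
  for (k in keys[-1L]) if (!identical(k, keys[[1L]]))
    stop("models were fitted to different subject/session sets", call. = FALSE)
  total <- vapply(fits, function(f) sum(f$bic), numeric(1))
  tab <- data.frame(model = names(fits), bic = unname(total),
                    n_sessions = vapply(fits, nrow, integer(1)),
                    row.names = NULL)
  tab <- tab[order(tab$bic), ]
  tie <- sum(tab$bic == min(tab$bic)) > 1L
  structure(list(table = tab,
                 winner = if (tie) NA_character_ else tab$model[1L],
                 tie = tie),
            class = "bic_comparison")
}

#' @method print bic_comparison
#' @export
print.bic_comparison <- function(x, ...) {
  cat("Model comparison (summed subject-wise BIC; lower is better)\n")
  print(x$table, row.names = FALSE)
  if (x$tie) cat("result: tie\n") else cat("winning model:", x$winner, "\n")
  invisible(x)
}
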