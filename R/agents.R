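#' Simulate a Rescorla-Wagner agent on a trial schedule
#'
#' On each non-lost trial the agent chooses between the two shown symbols by
#' the SoftMax rule over its current values, receives the schedule's
#' pre-drawn outcome for the chosen symbol, and updates only that symbol's
#' value. Lost trials (drawn i.i.d. at `lost_rate`, emulating responses
#' missed within the response window) trigger no choice and no update.
#'
#' @param params An [agent_params()].
#' @param schedule A [build_schedule()] trial schedule.
#' @param lost_rate Probability that a trial is lost, in \[0, 1).
#' @param seed Optional integer seed; identical seeds give identical runs.
#' @return Trial table (one session): `block`, `trial`, `sym_left`,
#'   `sym_right`, `chosen`, `outcome`, `lost`, `hp_symbol`. `chosen` and
#'   `outcome` are `NA` exactly on lost trials.
#' @examples
#' sched <- build_schedule(task_config(), seed = 1)
#' trials <- simulate_agent(agent_params("rw1", alpha = 0.5, beta = 5),
#'                          sched, seed = 2)
#' mean(trials$chosen == trials$hp_symbol, na.rm = TRUE)
#' @export
simulate_agent <- function(params, schedule, lost_rate = 0, seed = NULL) {
  params <- .as_agent_params(params)
  .simulate_on_schedule(schedule, lost_rate, seed,
                        params$alpha_pos, params$alpha_neg, params$beta,
                        params$v0, uniform_choice = FALSE)
}

#' Simulate a random (uniform-choice) control agent
#'
#' Chooses uniformly between the shown symbols and maintains no latent
#' values; used as a floor condition in model-recovery checks.
#'
#' @inheritParams simulate_agent
#' @return As [simulate_agent()].
#' @export
simulate_random_agent <- function(schedule, lost_rate = 0, seed = NULL) {
  .simulate_on_schedule(schedule, lost_rate, seed, 0, 0, 0, 0.5,
                        uniform_choice = TRUE)
}

.simulate_on_schedule <- function(schedule, lost_rate, seed,
                                  alpha_pos, alpha_neg, beta, v0,
                                  uniform_choice) {
  stopifnot(inherits(schedule, "trial_schedule") ||
              all(.SCHEDULE_COLS %in% names(schedule)))
  if (!is.numeric(lost_rate) || lost_rate < 0 || lost_rate >= 1)
    .stop_field("lost_rate", "must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n <- length(schedule$block)
  lost <- runif(n) < lost_rate
  loc <- .localize(schedule, check_chosen = FALSE)
  draws <- cbind(schedule$draw_sym0, schedule$draw_sym1, schedule$draw_sym2)
  storage.mode(draws) <- "integer"
  res <- cpp_simulate_agent(as.integer(schedule$block), loc$a_loc, loc$b_loc,
                            draws, lost, alpha_pos, alpha_neg, beta, v0,
                            uniform_choice)
  chosen <- rep(NA_integer_, n)
  ok <- !is.na(res$chosen_loc) & res$chosen_loc >= 0L
  for (b in names(loc$symbols)) {
    i <- ok & schedule$block == type.convert(b, as.is = TRUE)
    chosen[i] <- loc$symbols[[b]][res$chosen_loc[i] + 1L]
  }
  .fast_df(list(block = schedule$block, trial = schedule$trial,
                sym_left = schedule$sym_left, sym_right = schedule$sym_right,
                chosen = as.integer(chosen), outcome = res$outcome,
                lost = lost, hp_symbol = schedule$hp_symbol))
}

#' Specification of a synthetic multi-subject cohort
#'
#' Describes a within-subject design in which every subject performs the
#' task once per condition, emulating neuromodulation studies with three
#' conditions (e.g. active stimulation of the target region, an active
#' control site, and sham). Condition effects are additive shifts on the
#' generating agent parameters; the default preset raises the
#' reward-feedback learning rate `alpha_pos` in the first condition,
#' matching the direction in which targeted stimulation of reward circuitry
#' has been reported to act, without claiming mechanism.
#'
#' @param n_subjects Number of subjects (default 26).
#' @param conditions Character vector of condition labels.
#' @param base_params Generating [agent_params()] shared by all conditions.
#'   The default is a symmetric-rate agent (`alpha_pos = alpha_neg = 0.2`,
#'   `beta = 5`), in the range reported for human reversal-learning fits
#'   and calibrated so that the preset `alpha_pos` shift of +0.15 is
#'   detectable at the reference cohort size, as the empirical effect was.
#' @param condition_effects Named list: per condition, a named numeric
#'   vector of additive shifts on `alpha`, `alpha_pos`, `alpha_neg` or
#'   `beta`. Conditions not listed get no shift. Shifted parameters must
#'   stay inside their legal ranges.
#' @param lost_rate i.i.d. lost-trial probability, in \[0, 1).
#' @param counterbalance Rotate condition order across subjects?
#' @return Object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(condition_effects = list(NAcc = c(alpha_pos = 0.15)))
#' @export
cohort_spec <- function(n_subjects = 26L,
                        conditions = c("NAcc", "dACC", "Sham"),
                        base_params = agent_params("rw2", alpha_pos = 0.2,
                                                   alpha_neg = 0.2, beta = 5),
                        condition_effects = list(),
                        lost_rate = 0.02,
                        counterbalance = TRUE) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L)
    .stop_field("n_subjects", "must be >= 1")
  if (length(conditions) < 1L || anyDuplicated(conditions))
    .stop_field("conditions", "must be distinct labels")
  base_params <- .as_agent_params(base_params)
  if (!is.list(condition_effects) ||
      (length(condition_effects) && is.null(names(condition_effects))))
    .stop_field("condition_effects", "must be a named list of shifts")
  unknown <- setdiff(names(condition_effects), conditions)
  if (length(unknown))
    .stop_field("condition_effects", paste("unknown condition(s):",
                                           paste(unknown, collapse = ", ")))
  if (!is.numeric(lost_rate) || lost_rate < 0 || lost_rate >= 1)
    .stop_field("lost_rate", "must lie in [0, 1)")
  spec <- structure(list(n_subjects = n_subjects, conditions = conditions,
                         base_params = base_params,
                         condition_effects = condition_effects,
                         lost_rate = lost_rate,
                         counterbalance = isTRUE(counterbalance)),
                    class = "cohort_spec")
  for (cond in conditions) .shift_params(base_params, condition_effects[[cond]])
  spec
}

# Apply an additive parameter shift, validating the result stays legal.
.shift_params <- function(params, shift) {
  if (is.null(shift) || !length(shift)) return(params)
  allowed <- c("alpha", "alpha_pos", "alpha_neg", "beta")
  if (is.null(names(shift)) || !all(names(shift) %in% allowed))
    .stop_field("condition_effects",
                paste("shift names must be among:", paste(allowed, collapse = ", ")))
  p <- unclass(params)
  for (nm in names(shift)) {
    if (nm == "alpha") {
      if (params$model != "rw1")
        .stop_field("condition_effects", "`alpha` shift applies to rw1 only")
      p$alpha <- p$alpha + shift[[nm]]
      p$alpha_pos <- p$alpha_neg <- p$alpha
    } else {
      p[[nm]] <- p[[nm]] + shift[[nm]]
    }
  }
  args <- list(model = p$model, beta = p$beta, v0 = p$v0)
  if (p$model == "rw1") args$alpha <- p$alpha
  else { args$alpha_pos <- p$alpha_pos; args$alpha_neg <- p$alpha_neg }
  out <- tryCatch(do.call(agent_params, args), error = function(e)
    stop("condition effect pushes a parameter out of range: ",
         conditionMessage(e), call. = FALSE))
  out
}

#' Simulate a synthetic cohort with injected condition effects
#'
#' Every subject x condition cell receives a freshly built schedule (its own
#' seed, spawned from the master seed) and an agent whose parameters are the
#' cohort base parameters plus that condition's additive shift. With
#' `counterbalance = TRUE` the condition order rotates across subjects. The
#' generating ("ground truth") parameters are attached for recovery studies.
#'
#' @param spec A [cohort_spec()].
#' @param config A [task_config()].
#' @param seed Master integer seed for the whole cohort.
#' @return Trial table with columns `subject`, `condition`, `session`
#'   (position of the condition in the subject's counterbalanced order),
#'   `block`, `trial`, `sym_left`, `sym_right`, `chosen`, `outcome`,
#'   `lost`, `hp_symbol`. Ground truth is in `attr(, "truth")`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_subjects = 2), seed = 1)
#' table(cohort$subject, cohort$condition)
#' @export
simulate_cohort <- function(spec = cohort_spec(), config = task_config(),
                            seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  n_cond <- length(spec$conditions)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             2L * spec$n_subjects * n_cond),
                  ncol = 2L)
  cond_params <- lapply(setNames(spec$conditions, spec$conditions),
                        function(cond)
                          .shift_params(spec$base_params,
                                        spec$condition_effects[[cond]]))
  rows <- vector("list", spec$n_subjects * n_cond)
  truth <- vector("list", spec$n_subjects * n_cond)
  k <- 0L
  for (s in seq_len(spec$n_subjects)) {
    order_idx <- if (spec$counterbalance)
      ((seq_len(n_cond) + s - 2L) %% n_cond) + 1L else seq_len(n_cond)
    for (pos in seq_len(n_cond)) {
      cond <- spec$conditions[order_idx[pos]]
      k <- k + 1L
      p <- cond_params[[cond]]
      sched <- build_schedule(config, seed = seeds[k, 1L])
      tr <- simulate_agent(p, sched, lost_rate = spec$lost_rate,
                           seed = seeds[k, 2L])
      m <- length(tr$block)
      rows[[k]] <- c(list(subject = rep.int(s, m),
                          condition = rep.int(cond, m),
                          session = rep.int(pos, m)),
                     unclass(tr))
      truth[[k]] <- data.frame(subject = s, condition = cond,
                               model = p$model,
                               alpha = if (p$model == "rw1") p$alpha else NA_real_,
                               alpha_pos = p$alpha_pos, alpha_neg = p$alpha_neg,
                               beta = p$beta, v0 = p$v0)
    }
  }
  nms <- names(rows[[1L]])
  out <- .fast_df(lapply(setNames(nms, nms), function(nm)
    unlist(lapply(rows, `[[`, nm), use.names = FALSE)))
  out$condition <- factor(out$condition, levels = spec$conditions)
  attr(out, "truth") <- do.call(rbind, truth)
  attr(out, "config") <- config
  out
}
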