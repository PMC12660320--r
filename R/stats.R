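# Analyses of win-stay behaviour, learning curves and companion metrics.

.with_keys <- function(trials) {
  if (is.null(trials$subject)) trials$subject <- 1L
  if (is.null(trials$condition)) trials$condition <- "all"
  stopifnot(!is.null(trials$block), !is.null(trials$trial))
  trials
}

#' Win-stay coding of consecutive trial pairs
#'
#' For every pair of consecutive trials (t, t+1) within a block,
#' `winstay(t+1)` is coded +1 for win-stay (rewarded at t and the same
#' symbol chosen again at t+1), -1 for win-switch (rewarded at t, that
#' symbol shown at t+1 but not chosen) and 0 otherwise -- including
#' unrewarded trials and pairs where the fixed rotation removes the
#' previously chosen symbol from the screen (one third of trials).
#' Companion regressors: `reward(t)` (or the model prediction error at t
#' for the model-based variant), `stickiness(t)` (choice at t repeats the
#' choice at t-1; 0 on a block's first trial), and `is_hp_next` (a
#' high-probability symbol is on screen at t+1). Pairs touching a lost
#' trial are kept but flagged invalid; cross-block pairs are excluded.
#'
#' @param trials Trial table (single session or cohort); needs `block`,
#'   `trial`, `sym_left`, `sym_right`, `chosen`, `outcome`, `lost`,
#'   `hp_symbol` (and `subject`/`condition` for cohorts).
#' @param pe Numeric vector of prediction errors aligned with the rows of
#'   `trials` (see [model_latents()]); required when `source = "pe"`.
#' @param source Use the raw reward (`"reward"`) or the fitted-model
#'   prediction error (`"pe"`) as the outcome regressor.
#' @return Data frame of class `winstay_coding`: one row per codable pair,
#'   columns `subject`, `condition`, `block`, `trial` (= t), `winstay`,
#'   `reward`, `stickiness`, `is_hp_next`, `valid`.
#' @export
code_winstay <- function(trials, pe = NULL, source = c("reward", "pe")) {
  source <- match.arg(source)
  stopifnot(!is.null(trials$hp_symbol))
  if (source == "pe") {
    if (is.null(pe) || length(pe) != nrow(trials))
      stop("`pe` must align with the rows of `trials` when source = \"pe\"",
           call. = FALSE)
  }
  tr <- .with_keys(trials)
  ord <- order(tr$subject, tr$condition, tr$block, tr$trial)
  tr <- tr[ord, , drop = FALSE]
  if (source == "pe") pe <- pe[ord]
  n <- nrow(tr)
  if (n < 2L)
    return(structure(data.frame(subject = integer(0), condition = character(0),
                                block = integer(0), trial = integer(0),
                                winstay = numeric(0), reward = numeric(0),
                                stickiness = numeric(0), is_hp_next = numeric(0),
                                valid = logical(0)),
                     class = c("winstay_coding", "data.frame"), source = source))
  grp <- paste(tr$subject, tr$condition, tr$block, sep = "\r")
  same_next <- c(grp[-1L] == grp[-n], FALSE)
  same_prev <- c(FALSE, grp[-1L] == grp[-n])

  t0 <- which(same_next)            # index of trial t; t+1 = t0 + 1
  t1 <- t0 + 1L
  valid <- !tr$lost[t0] & !tr$lost[t1]
  rewarded <- tr$outcome[t0] == 1
  avail <- tr$chosen[t0] == tr$sym_left[t1] | tr$chosen[t0] == tr$sym_right[t1]
  stay <- tr$chosen[t1] == tr$chosen[t0]
  winstay <- ifelse(rewarded & avail, ifelse(stay, 1, -1), 0)

  prev_same <- same_prev[t0]
  prev_idx <- pmax(t0 - 1L, 1L)
  stick <- prev_same & !tr$lost[prev_idx] & !tr$lost[t0] &
    tr$chosen[t0] == tr$chosen[prev_idx]
  stick[is.na(stick)] <- FALSE

  hp_next <- tr$hp_symbol[t1] == tr$sym_left[t1] |
    tr$hp_symbol[t1] == tr$sym_right[t1]

  out <- data.frame(subject = tr$subject[t0],
                    condition = tr$condition[t0],
                    block = tr$block[t0],
                    trial = tr$trial[t0],
                    winstay = ifelse(valid, winstay, NA_real_),
                    reward = if (source == "pe") ifelse(valid, pe[t0], NA_real_)
                             else ifelse(valid, as.numeric(rewarded), NA_real_),
                    stickiness = as.numeric(stick),
                    is_hp_next = as.numeric(hp_next),
                    valid = valid)
  structure(out, class = c("winstay_coding", "data.frame"), source = source)
}

#' Per-session win-stay regression
#'
#' Ordinary least squares of `winstay(t+1)` on `reward(t)`,
#' `stickiness(t)` and `is_hp_next(t+1)`, fitted separately per
#' subject x condition x block on the valid coded pairs. A constant
#' (rank-deficient) regressor yields an `NA` coefficient with a warning
#' rather than an error; groups with fewer than `min_rows` valid pairs are
#' dropped with a warning.
#'
#' @param coding A [code_winstay()] table.
#' @param min_rows Minimum valid pairs per group.
#' @return Data frame: `subject`, `condition`, `block`, `intercept`,
#'   `beta_reward`, `beta_stickiness`, `beta_isHP`, `n_obs`. The regressor
#'   source is carried in `attr(, "source")`.
#' @export
winstay_regression <- function(coding, min_rows = 8L) {
  cd <- coding[coding$valid & !is.na(coding$winstay), , drop = FALSE]
  idx <- split(seq_len(nrow(cd)),
               list(cd$subject, cd$condition, cd$block),
               drop = TRUE, sep = "\r")
  dropped <- 0L; deficient <- 0L
  reward <- cd$reward; stick <- cd$stickiness; hp <- cd$is_hp_next
  y <- cd$winstay
  cf_rows <- vapply(idx, function(i) {
    if (length(i) < min_rows) { dropped <<- dropped + 1L; return(rep(NA_real_, 5L)) }
    x <- cbind(1, reward[i], stick[i], hp[i])
    cf <- lm.fit(x, y[i])$coefficients
    if (anyNA(cf)) deficient <<- deficient + 1L
    c(cf, length(i))
  }, numeric(5L))
  if (dropped) warning(dropped, " group(s) dropped: fewer than ", min_rows,
                       " valid pairs", call. = FALSE)
  if (deficient) warning(deficient, " group(s) had a constant regressor; ",
                         "its coefficient is NA", call. = FALSE)
  first <- vapply(idx, `[`, integer(1), 1L)
  keep <- !is.na(cf_rows[5L, ])
  out <- .fast_df(list(subject = cd$subject[first][keep],
                       condition = cd$condition[first][keep],
                       block = cd$block[first][keep],
                       intercept = cf_rows[1L, keep],
                       beta_reward = cf_rows[2L, keep],
                       beta_stickiness = cf_rows[3L, keep],
                       beta_isHP = cf_rows[4L, keep],
                       n_obs = as.integer(cf_rows[5L, keep])))
  attr(out, "source") <- attr(coding, "source")
  out
}

.paired_stats <- function(d) {
  # d: vector of paired differences
  m <- mean(d); s <- sd(d); n <- length(d)
  if (is.na(s) || s == 0) {
    if (isTRUE(all.equal(m, 0)) || is.na(m))
      return(list(t = 0, df = n - 1L, p = 1, d = 0))
    return(list(t = sign(m) * Inf, df = n - 1L, p = 0, d = sign(m) * Inf))
  }
  tt <- t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       d = m / s)
}

#' Condition-level ANOVA with paired post-hoc tests
#'
#' Averages a chosen regression coefficient over blocks per
#' subject x condition, runs a one-way ANOVA of those means on condition,
#' then all pairwise two-sided paired t-tests with Bonferroni correction
#' and the paired Cohen's D (mean difference divided by the standard
#' deviation of the differences). Subjects missing a condition are dropped
#' with a warning.
#'
#' @param betas A [winstay_regression()] table (or any data frame with
#'   `subject`, `condition`, `block` and the coefficient column).
#' @param coefficient Name of the column to analyse.
#' @return Object of class `group_comparison`: `anova` (`f_stat`,
#'   `df_between`, `df_within`, `p`), `posthoc` (per pair: `t_stat`, `df`,
#'   `p_raw`, `p_bonferroni`, `cohens_d`) and the per-subject condition
#'   `means`.
#' @export
condition_anova <- function(betas, coefficient = "beta_reward") {
  stopifnot(coefficient %in% names(betas))
  val <- betas[[coefficient]]
  agg <- aggregate(val, list(subject = betas$subject,
                             condition = betas$condition),
                   mean, na.rm = TRUE)
  names(agg)[3L] <- "value"
  conds <- unique(as.character(agg$condition))
  counts <- table(agg$subject)
  keep <- names(counts)[counts == length(conds)]
  if (length(keep) < length(counts))
    warning(length(counts) - length(keep),
            " subject(s) dropped: missing condition(s)", call. = FALSE)
  agg <- agg[agg$subject %in% keep, , drop = FALSE]
  agg$condition <- factor(as.character(agg$condition), levels = conds)
  a <- anova(lm(value ~ condition, data = agg))
  pairs <- utils::combn(conds, 2L)
  n_pairs <- ncol(pairs)
  post <- lapply(seq_len(n_pairs), function(j) {
    x <- agg$value[agg$condition == pairs[1L, j]][order(agg$subject[agg$condition == pairs[1L, j]])]
    y <- agg$value[agg$condition == pairs[2L, j]][order(agg$subject[agg$condition == pairs[2L, j]])]
    st <- .paired_stats(x - y)
    data.frame(pair = paste(pairs[1L, j], "vs", pairs[2L, j]),
               t_stat = st$t, df = st$df, p_raw = st$p,
               p_bonferroni = min(1, n_pairs * st$p), cohens_d = st$d)
  })
  structure(list(
    anova = list(f_stat = a[["F value"]][1L],
                 df_between = a[["Df"]][1L], df_within = a[["Df"]][2L],
                 p = a[["Pr(>F)"]][1L]),
    posthoc = do.call(rbind, post),
    means = agg,
    coefficient = coefficient,
    n_subjects = length(keep)),
    class = "group_comparison")
}

#' @method print group_comparison
#' @export
print.group_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("One-way condition ANOVA on `%s` (n = %d subjects)\n",
              x$coefficient, x$n_subjects))
  cat(sprintf("  F(%d,%d) = %.*g, p = %.*g\n", x$anova$df_between,
              x$anova$df_within, digits, x$anova$f_stat, digits, x$anova$p))
  cat("Paired post-hoc t-tests (Bonferroni corrected):\n")
  print(x$posthoc, row.names = FALSE, digits = digits)
  invisible(x)
}

#' Block-wise paired contrasts between two conditions
#'
#' Tests, separately for each block, the paired difference in a regression
#' coefficient between two conditions (two-sided paired t-test).
#' Deliberately uncorrected for multiple comparisons: the blocks index the
#' time course after the intervention and are examined under predefined
#' hypotheses.
#'
#' @inheritParams condition_anova
#' @param condition_a,condition_b Condition labels; differences are
#'   `a - b`.
#' @param alpha Significance flag threshold.
#' @return Data frame: `block`, `n`, `t_stat`, `df`, `p`, `significant`.
#'   Blocks with fewer than 3 paired subjects are skipped with a warning.
#' @export
blockwise_contrast <- function(betas, condition_a, condition_b,
                               coefficient = "beta_reward", alpha = 0.05) {
  stopifnot(coefficient %in% names(betas))
  blocks <- sort(unique(betas$block))
  skipped <- 0L
  rows <- lapply(blocks, function(b) {
    g <- betas[betas$block == b, , drop = FALSE]
    xa <- g[as.character(g$condition) == condition_a, ]
    xb <- g[as.character(g$condition) == condition_b, ]
    common <- intersect(xa$subject, xb$subject)
    if (length(common) < 3L) { skipped <<- skipped + 1L; return(NULL) }
    d <- xa[[coefficient]][match(common, xa$subject)] -
      xb[[coefficient]][match(common, xb$subject)]
    st <- .paired_stats(d)
    data.frame(block = b, n = length(common), t_stat = st$t, df = st$df,
               p = st$p, significant = st$p < alpha)
  })
  if (skipped) warning(skipped, " block(s) skipped: fewer than 3 paired subjects",
                       call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Learning curve across contingency periods
#'
#' Aligns trials by their position within a contingency period, averages
#' the high-probability-choice indicator (or, for the model-based variant,
#' the expected value of the high-probability symbol) across all periods
#' and subjects, and applies a centred running average (default 5 trials,
#' truncated at the period edges) to smooth trial-by-trial variability.
#'
#' @param trials Trial table (session or cohort) with `hp_symbol`.
#' @param values Optional numeric vector aligned with `trials` rows to
#'   average instead of the choice indicator (e.g. [hp_value()] output).
#' @param window Running-average width in trials (odd; 1 = no smoothing).
#' @return Data frame of class `learning_curve`: `position`, `raw`,
#'   `smoothed`, `sem`, `n` (periods x subjects contributing).
#' @export
learning_curve <- function(trials, values = NULL, window = 5L) {
  stopifnot(!is.null(trials$hp_symbol))
  window <- as.integer(window)
  tr <- .with_keys(trials)
  ord <- order(tr$subject, tr$condition, tr$block, tr$trial)
  tr <- tr[ord, , drop = FALSE]
  y <- if (is.null(values)) {
    ifelse(tr$lost, NA_real_, as.numeric(tr$chosen == tr$hp_symbol))
  } else {
    stopifnot(length(values) == nrow(trials))
    values[ord]
  }
  sess <- paste(tr$subject, tr$condition, tr$block, sep = "\r")
  new_period <- c(TRUE, sess[-1L] != sess[-length(sess)] |
                    diff(tr$hp_symbol) != 0)
  period_id <- cumsum(new_period)
  position <- stats::ave(seq_along(period_id), period_id, FUN = seq_along)
  max_pos <- max(position)
  if (window < 1L || window > max_pos)
    .stop_field("window", sprintf("must lie in [1, %d] (longest period)", max_pos))
  raw <- tapply(y, position, mean, na.rm = TRUE)
  nn <- tapply(!is.na(y), position, sum)
  sem <- tapply(y, position, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) NA_real_ else sd(v) / sqrt(length(v))
  })
  h <- window %/% 2L
  smoothed <- vapply(seq_len(max_pos), function(p)
    mean(raw[max(1L, p - h):min(max_pos, p + h)], na.rm = TRUE), numeric(1))
  structure(data.frame(position = seq_len(max_pos), raw = as.numeric(raw),
                       smoothed = smoothed, sem = as.numeric(sem),
                       n = as.integer(nn)),
            class = c("learning_curve", "data.frame"), window = window)
}

#' @export
plot.learning_curve <- function(x, col = "#1b9e77", ...) {
  graphics::plot(x$position, x$smoothed, type = "n", ylim = c(0, 1),
                 xlab = "trial within contingency period",
                 ylab = "high-probability choice rate", ...)
  ok <- !is.na(x$sem)
  graphics::polygon(c(x$position[ok], rev(x$position[ok])),
                    c((x$smoothed + x$sem)[ok], rev((x$smoothed - x$sem)[ok])),
                    col = grDevices::adjustcolor(col, 0.25), border = NA)
  graphics::lines(x$position, x$smoothed, col = col, lwd = 2)
  graphics::points(x$position, x$raw, pch = 16, cex = 0.5, col = "grey40")
  invisible(x)
}

#' Mixed-model contrast on high-probability choice
#'
#' Linear mixed model of the trial-level high-probability-choice indicator
#' on condition with a per-subject random intercept (REML, via
#' \pkg{lme4}). Fixed-effect p values use the normal approximation on t,
#' which is accurate at the trial-level sample sizes this analysis is
#' built for (residual dfs in the thousands). With a single subject the
#' model degenerates to ordinary regression, with a warning.
#'
#' @param trials Cohort trial table with `hp_symbol`.
#' @param conditions Optional subset (and ordering) of conditions to
#'   contrast; the first level is the reference.
#' @return Data frame of fixed effects (intercept excluded): `term`,
#'   `estimate`, `se`, `t`, `df` (residual), `p`. The fitted model is in
#'   `attr(, "model")`.
#' @export
hp_choice_mixed_model <- function(trials, conditions = NULL) {
  tr <- .with_keys(trials)
  tr <- tr[!tr$lost, , drop = FALSE]
  tr$hp <- as.numeric(tr$chosen == tr$hp_symbol)
  tr$condition <- as.character(tr$condition)
  if (!is.null(conditions)) {
    tr <- tr[tr$condition %in% conditions, , drop = FALSE]
    tr$condition <- factor(tr$condition, levels = conditions)
  } else tr$condition <- factor(tr$condition)
  tr$subject <- factor(tr$subject)
  if (nlevels(tr$subject) < 2L) {
    warning("single subject: falling back to ordinary regression",
            call. = FALSE)
    m <- lm(hp ~ condition, data = tr)
    cf <- summary(m)$coefficients
    df_resid <- m$df.residual
  } else {
    m <- lme4::lmer(hp ~ condition + (1 | subject), data = tr, REML = TRUE)
    cf <- summary(m)$coefficients
    df_resid <- nrow(tr) - nrow(cf)
  }
  keep <- rownames(cf) != "(Intercept)"
  out <- data.frame(term = rownames(cf)[keep],
                    estimate = cf[keep, 1L], se = cf[keep, 2L],
                    t = cf[keep, 3L], df = df_resid,
                    p = 2 * pnorm(-abs(cf[keep, 3L])))
  rownames(out) <- NULL
  attr(out, "model") <- m
  out
}

#' Maladaptive win-stay on low-probability pairs
#'
#' Win-stay is usually adaptive, but repeating a rewarded LOW-probability
#' choice when a better option is available is not. Restricted to trials
#' where both shown symbols carry the low reward probability and the choice
#' was rewarded, this measures whether the same symbol is chosen again at
#' the next trial on which it appears alongside the current
#' high-probability symbol (stay coded +1, switch -1). Per-subject rates
#' are tested against zero within each condition (one-sample two-sided t)
#' and compared across conditions by one-way ANOVA.
#'
#' @param trials Cohort trial table with `hp_symbol`.
#' @return Object of class `maladaptive_winstay`: per-subject `rates`,
#'   per-condition `tests` (`mean`, `t`, `df`, `p`, `n`), and the condition
#'   `anova`. Subjects without qualifying trials are excluded with a
#'   warning.
#' @export
maladaptive_winstay <- function(trials) {
  tr <- .with_keys(trials)
  idx <- split(seq_len(nrow(tr)), list(tr$subject, tr$condition),
               drop = TRUE, sep = "\r")
  rows <- lapply(idx, function(i) {
    g <- tr[i, , drop = FALSE]
    g <- g[order(g$block, g$trial), , drop = FALSE]
    lowlow <- !g$lost & g$outcome == 1 &
      g$hp_symbol != g$sym_left & g$hp_symbol != g$sym_right
    lowlow[is.na(lowlow)] <- FALSE
    codes <- numeric(0)
    for (t in which(lowlow)) {
      s <- g$chosen[t]
      later <- which(seq_len(nrow(g)) > t & g$block == g$block[t] & !g$lost &
                       (g$sym_left == s | g$sym_right == s) &
                       (g$sym_left == g$hp_symbol | g$sym_right == g$hp_symbol) &
                       g$hp_symbol != s)
      if (length(later))
        codes <- c(codes, if (g$chosen[later[1L]] == s) 1 else -1)
    }
    if (!length(codes)) return(NULL)
    data.frame(subject = g$subject[1L], condition = as.character(g$condition[1L]),
               rate = mean(codes), n_events = length(codes))
  })
  excluded <- sum(vapply(rows, is.null, logical(1)))
  if (excluded) warning(excluded, " subject x condition cell(s) excluded: ",
                        "no qualifying low-probability pairs", call. = FALSE)
  rates <- do.call(rbind, rows)
  rownames(rates) <- NULL
  tests <- do.call(rbind, lapply(split(rates, rates$condition), function(g) {
    st <- .paired_stats(g$rate)
    data.frame(condition = g$condition[1L], mean = mean(g$rate),
               t = st$t, df = st$df, p = st$p, n = nrow(g))
  }))
  rownames(tests) <- NULL
  av <- if (length(unique(rates$condition)) > 1L) {
    a <- anova(lm(rate ~ condition, data = rates))
    list(f_stat = a[["F value"]][1L], df_between = a[["Df"]][1L],
         df_within = a[["Df"]][2L], p = a[["Pr(>F)"]][1L])
  } else NULL
  structure(list(rates = rates, tests = tests, anova = av),
            class = "maladaptive_winstay")
}

#' @method print maladaptive_winstay
#' @export
print.maladaptive_winstay <- function(x, digits = 4, ...) {
  cat("Maladaptive win-stay on low-probability pairs (stay +1 / switch -1)\n")
  print(x$tests, row.names = FALSE, digits = digits)
  if (!is.null(x$anova))
    cat(sprintf("condition ANOVA: F(%d,%d) = %.*g, p = %.*g\n",
                x$anova$df_between, x$anova$df_within, digits, x$anova$f_stat,
                digits, x$anova$p))
  invisible(x)
}

#' Exploratory performance metrics
#'
#' Three descriptive indices per subject x condition:
#' post-learning accuracy (high-probability choice rate over the last
#' `window_post` trials of each contingency period), perseveration errors
#' (rate of choosing the immediately previous high-probability symbol,
#' when shown, during the first `window_persev` trials after a reversal)
#' and post-error adjustment (switch rate on trials following a non-reward,
#' among consecutive pairs where the previous choice is available again).
#' Windows are truncated, with a warning, in periods shorter than
#' `window_post`. Cells with no usable trials are reported as `NA`.
#'
#' @param trials Cohort trial table with `hp_symbol`.
#' @param window_post,window_persev Window sizes in trials.
#' @param tests Also run, per metric, a mixed-model condition contrast on
#'   the subject x condition values (`value ~ condition + (1 | subject)`)?
#' @return Data frame: `subject`, `condition`, `post_learning_acc`,
#'   `perseveration`, `post_error_adjust`; with `tests = TRUE`, a list of
#'   [hp_choice_mixed_model()]-style tables in `attr(, "tests")`.
#' @export
exploratory_metrics <- function(trials, window_post = 10L, window_persev = 5L,
                                tests = FALSE) {
  tr <- .with_keys(trials)
  idx <- split(seq_len(nrow(tr)), list(tr$subject, tr$condition),
               drop = TRUE, sep = "\r")
  truncated <- FALSE
  rows <- lapply(idx, function(i) {
    g <- tr[i, , drop = FALSE]
    g <- g[order(g$block, g$trial), , drop = FALSE]
    per <- contingency_periods(g)
    post <- numeric(0); persev <- numeric(0)
    for (r in seq_len(nrow(per))) {
      span <- per$start[r]:per$end[r]
      if (length(span) < window_post) truncated <<- TRUE
      last <- g[span[max(1L, length(span) - window_post + 1L):length(span)], ]
      hp_rate <- mean(last$chosen[!last$lost] == last$hp_symbol[!last$lost])
      if (!is.nan(hp_rate)) post <- c(post, hp_rate)
      if (r > 1L && per$block[r] == per$block[r - 1L]) {
        prev_hp <- per$hp_symbol[r - 1L]
        first <- g[span[seq_len(min(window_persev, length(span)))], ]
        shown <- !first$lost & (first$sym_left == prev_hp |
                                  first$sym_right == prev_hp)
        if (any(shown))
          persev <- c(persev, mean(first$chosen[shown] == prev_hp))
      }
    }
    nxt <- c(seq_len(nrow(g))[-1L], NA)
    ok <- !is.na(nxt) & g$block == c(g$block[-1L], NA) &
      !g$lost & !c(g$lost[-1L], NA) & g$outcome == 0 &
      (g$chosen == c(g$sym_left[-1L], NA) | g$chosen == c(g$sym_right[-1L], NA))
    ok[is.na(ok)] <- FALSE
    pea <- if (any(ok)) mean(g$chosen[which(ok) + 1L] != g$chosen[ok]) else NA_real_
    data.frame(subject = g$subject[1L], condition = as.character(g$condition[1L]),
               post_learning_acc = if (length(post)) mean(post) else NA_real_,
               perseveration = if (length(persev)) mean(persev) else NA_real_,
               post_error_adjust = pea)
  })
  if (truncated)
    warning("period(s) shorter than `window_post`; window truncated",
            call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (tests) {
    run_one <- function(metric) {
      d <- out[!is.na(out[[metric]]), ]
      d$value <- d[[metric]]
      d$condition <- factor(d$condition)
      d$subject <- factor(d$subject)
      if (nlevels(d$subject) < 2L || nlevels(d$condition) < 2L) return(NULL)
      m <- lme4::lmer(value ~ condition + (1 | subject), data = d, REML = TRUE)
      cf <- summary(m)$coefficients
      keep <- rownames(cf) != "(Intercept)"
      data.frame(term = rownames(cf)[keep], estimate = cf[keep, 1L],
                 se = cf[keep, 2L], t = cf[keep, 3L],
                 df = nrow(d) - nrow(cf), p = 2 * pnorm(-abs(cf[keep, 3L])))
    }
    attr(out, "tests") <- list(
      post_learning_acc = run_one("post_learning_acc"),
      perseveration = run_one("perseveration"),
      post_error_adjust = run_one("post_error_adjust"))
  }
  out
}

#' Two-group Mann-Whitney rank test
#'
#' Two-sided Mann-Whitney U comparison of two independent groups of
#' per-subject values: exact enumeration when both groups have at most 8
#' observations (and no ties), otherwise the normal approximation with tie
#' correction.
#'
#' @param group_a,group_b Numeric vectors of per-subject values.
#' @return List: `U` (statistic for `group_a`), `p`, `n_a`, `n_b`,
#'   `method`.
#' @examples
#' rank_test_groups(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
#' @export
rank_test_groups <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty", call. = FALSE)
  exact <- length(group_a) <= 8L && length(group_b) <= 8L
  res <- suppressWarnings(wilcox.test(group_a, group_b, exact = exact,
                                      correct = FALSE))
  list(U = unname(res$statistic), p = res$p.value,
       n_a = length(group_a), n_b = length(group_b), method = res$method)
}

#' Model latents aligned with a cohort trial table
#'
#' Re-runs each fitted session's model on its observed choices and returns
#' the per-row prediction error and the expected value of the current
#' high-probability symbol, aligned with `trials` -- the inputs for the
#' model-based variants of the win-stay and learning-curve analyses.
#'
#' @param trials Cohort trial table.
#' @param fits A [fit_sessions()] table whose grouping (subject, condition
#'   and possibly block) covers every row of `trials`.
#' @return Data frame with columns `pe` and `v_hp`, `nrow(trials)` rows.
#' @export
model_latents <- function(trials, fits) {
  tr <- .with_keys(trials)
  by <- c("subject", "condition", if (!all(is.na(fits$block))) "block")
  key_tr <- do.call(paste, c(tr[by], sep = "\r"))
  key_ft <- do.call(paste, c(lapply(by, function(c) fits[[c]]), sep = "\r"))
  pe <- rep(NA_real_, nrow(tr))
  v_hp <- rep(NA_real_, nrow(tr))
  for (j in seq_len(nrow(fits))) {
    i <- which(key_tr == key_ft[j])
    if (!length(i)) next
    f <- fits[j, ]
    p <- if (f$model == "rw1")
      agent_params("rw1", alpha = f$alpha, beta = f$beta)
    else
      agent_params("rw2", alpha_pos = f$alpha_pos, alpha_neg = f$alpha_neg,
                   beta = f$beta)
    g <- tr[i, , drop = FALSE]
    traj <- run_model(p, g)
    pe[i] <- traj$pe
    v_hp[i] <- hp_value(traj, g)
  }
  data.frame(pe = pe, v_hp = v_hp)
}
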