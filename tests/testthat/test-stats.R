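test_that("win-stay coding reproduces the worked 4-trial example", {
  # pairs AB, BC, CA, AB; choices B, B, C, B; rewards 1, 0, 1, -
  tr <- toy_trials(left = c(1L, 2L, 3L, 1L), right = c(2L, 3L, 1L, 2L),
                   chosen = c(2L, 2L, 3L, 2L), outcome = c(1L, 0L, 1L, 0L),
                   hp = 1L)
  cd <- code_winstay(tr)
  expect_identical(nrow(cd), 3L)
  # t=1 rewarded, B present at t=2 and chosen again -> +1
  # t=2 unrewarded -> 0; t=3 rewarded but C absent from pair AB -> 0
  expect_equal(cd$winstay, c(1, 0, 0))
  expect_equal(cd$reward, c(1, 0, 1))
  # stickiness: choice at t repeats choice at t-1 (first trial 0)
  expect_equal(cd$stickiness, c(0, 1, 0))
})

test_that("win-stay coding matches the exhaustive two-trial truth table", {
  # all combinations of reward at t, availability of the chosen symbol at
  # t+1, and stay/switch; symbols 1,2,3, choice at t is symbol 1 from (1,2)
  for (rewarded in c(0L, 1L)) for (avail in c(TRUE, FALSE)) {
    stays <- if (avail) c(TRUE, FALSE) else FALSE
    for (stay in stays) {
      pair2 <- if (avail) c(1L, 3L) else c(2L, 3L)
      chosen2 <- if (avail && stay) 1L else pair2[2L]
      tr <- toy_trials(left = c(1L, pair2[1L]), right = c(2L, pair2[2L]),
                       chosen = c(1L, chosen2), outcome = c(rewarded, 0L),
                       hp = 1L)
      cd <- code_winstay(tr)
      expected <- if (rewarded == 1L && avail) (if (stay) 1 else -1) else 0
      expect_equal(cd$winstay, expected,
                   label = sprintf("rewarded=%d avail=%d stay=%d",
                                   rewarded, avail, stay))
    }
  }
})

test_that("lost trials invalidate pairs and all-lost sessions code nothing", {
  tr <- toy_trials(left = c(1L, 2L, 3L), right = c(2L, 3L, 1L),
                   chosen = c(1L, 2L, 3L), outcome = c(1L, 1L, 1L), hp = 1L,
                   lost = c(FALSE, TRUE, FALSE))
  cd <- code_winstay(tr)
  expect_identical(cd$valid, c(FALSE, FALSE))
  all_lost <- toy_trials(left = c(1L, 2L), right = c(2L, 3L),
                         chosen = c(1L, 2L), outcome = c(1L, 1L), hp = 1L,
                         lost = c(TRUE, TRUE))
  expect_identical(sum(code_winstay(all_lost)$valid), 0L)
})

test_that("model-based coding substitutes the prediction error for reward", {
  tr <- toy_trials(left = c(1L, 1L), right = c(2L, 3L),
                   chosen = c(1L, 1L), outcome = c(1L, 1L), hp = 1L)
  pe <- c(0.5, 0.3)
  cd <- code_winstay(tr, pe = pe, source = "pe")
  expect_equal(cd$reward, 0.5)
  expect_error(code_winstay(tr, source = "pe"), "pe")
})

test_that("win-stay regression recovers a constructed design and matches normal equations", {
  set.seed(1)
  n <- 50
  reward <- rbinom(n, 1, 0.5)
  stick <- rbinom(n, 1, 0.5)
  hp <- rbinom(n, 1, 2 / 3)
  coding <- structure(
    data.frame(subject = 1L, condition = "all", block = 1L,
               trial = seq_len(n), winstay = as.numeric(reward),
               reward = as.numeric(reward), stickiness = as.numeric(stick),
               is_hp_next = as.numeric(hp), valid = TRUE),
    class = c("winstay_coding", "data.frame"), source = "reward")
  b <- winstay_regression(coding)
  expect_equal(b$beta_reward, 1, tolerance = 1e-10)
  expect_equal(b$beta_stickiness, 0, tolerance = 1e-10)
  expect_equal(b$beta_isHP, 0, tolerance = 1e-10)
  # arbitrary response: OLS must equal solve(X'X, X'y)
  coding$winstay <- rnorm(n)
  b2 <- winstay_regression(coding)
  X <- cbind(1, reward, stick, hp)
  ref <- solve(crossprod(X), crossprod(X, coding$winstay))
  expect_equal(unlist(b2[, c("intercept", "beta_reward", "beta_stickiness",
                             "beta_isHP")]),
               drop(ref), tolerance = 1e-8, ignore_attr = TRUE)
  # all-zero outcome gives all-zero coefficients
  coding$winstay <- 0
  b3 <- winstay_regression(coding)
  expect_equal(unlist(b3[, 4:7]), rep(0, 4), ignore_attr = TRUE)
})

test_that("constant regressors yield NA coefficients with a warning, not a crash", {
  coding <- structure(
    data.frame(subject = 1L, condition = "all", block = 1L, trial = 1:20,
               winstay = rnorm(20), reward = 1, stickiness = rbinom(20, 1, 0.5),
               is_hp_next = rbinom(20, 1, 0.5), valid = TRUE),
    class = c("winstay_coding", "data.frame"), source = "reward")
  expect_warning(b <- winstay_regression(coding), "constant regressor")
  expect_true(is.na(b$beta_reward) || is.na(b$beta_isHP))
})

test_that("condition ANOVA degenerates correctly on identical data", {
  betas <- expand.grid(subject = 1:8, condition = c("A", "B", "C"),
                       block = 1:2)
  betas$beta_reward <- rep(rnorm(8), times = 6)  # same values per subject
  a <- condition_anova(betas)
  expect_equal(a$anova$f_stat, 0)
  expect_equal(a$posthoc$cohens_d, rep(0, 3))
  expect_equal(a$posthoc$p_bonferroni, rep(1, 3))
  expect_identical(a$anova$df_between, 2L)
  expect_identical(a$anova$df_within, 21L)
})

test_that("condition ANOVA detects a one-SD shift and drops incomplete subjects", {
  set.seed(2)
  betas <- expand.grid(subject = 1:26, condition = c("A", "B", "C"))
  betas$block <- 1L
  betas$beta_reward <- rnorm(nrow(betas))
  betas$beta_reward[betas$condition == "A"] <-
    betas$beta_reward[betas$condition == "A"] + 1
  a <- condition_anova(betas)
  expect_lt(a$anova$p, 0.05)
  expect_identical(a$anova$df_within, 75L)
  expect_warning(condition_anova(betas[-1, ]), "dropped")
})

test_that("block-wise contrasts are antisymmetric and flag injected blocks", {
  set.seed(3)
  betas <- expand.grid(subject = 1:20, condition = c("A", "B"), block = 1:4)
  betas$beta_reward <- rnorm(nrow(betas), sd = 0.2)
  betas$beta_reward[betas$condition == "A" & betas$block %in% 2:3] <-
    betas$beta_reward[betas$condition == "A" & betas$block %in% 2:3] + 0.5
  ab <- blockwise_contrast(betas, "A", "B")
  ba <- blockwise_contrast(betas, "B", "A")
  expect_equal(ab$t_stat, -ba$t_stat, tolerance = 1e-12)
  expect_true(all(ab$significant[ab$block %in% 2:3]))
  expect_warning(blockwise_contrast(betas[betas$subject <= 2, ], "A", "B"),
                 "skipped")
})

test_that("identical conditions give zero block-wise t statistics", {
  betas <- expand.grid(subject = 1:10, condition = c("A", "B"), block = 1:2)
  betas$beta_reward <- rep(rnorm(10), times = 4)
  ab <- blockwise_contrast(betas, "A", "B")
  expect_equal(ab$t_stat, c(0, 0))
  expect_false(any(ab$significant))
})

test_that("learning curves align periods, smooth with truncation, and validate the window", {
  sched <- build_schedule(task_config(block_lengths = 100L), seed = 31)
  # omniscient agent: chooses the hp symbol whenever it is on screen
  on <- is_hp_on_screen(sched, seq_len(nrow(sched)))
  chosen <- ifelse(on, sched$hp_symbol,
                   ifelse(sched$sym_left != sched$hp_symbol,
                          sched$sym_left, sched$sym_right))
  tr <- data.frame(block = sched$block, trial = sched$trial,
                   sym_left = sched$sym_left, sym_right = sched$sym_right,
                   chosen = chosen, outcome = 1L, lost = FALSE,
                   hp_symbol = sched$hp_symbol)
  lc1 <- learning_curve(tr, window = 1)
  expect_identical(lc1$smoothed, lc1$raw)     # window 1 is the identity
  # per-trial indicator is 1 exactly where hp was on screen
  pos_on <- split(on, stats::ave(seq_along(on),
                                 cumsum(c(TRUE, diff(sched$hp_symbol) != 0)),
                                 FUN = seq_along))
  lc5 <- learning_curve(tr, window = 5)
  expect_true(all(lc5$raw >= 0 & lc5$raw <= 1))
  expect_true(all(lc5$smoothed >= 0 & lc5$smoothed <= 1))
  expect_lt(abs(mean(lc5$smoothed) - mean(lc5$raw)), 0.02)
  expect_error(learning_curve(tr, window = 26), "window")
})

test_that("learning agents show rising within-period learning curves", {
  rises <- vapply(1:60, function(seed) {
    sched <- build_schedule(task_config(block_lengths = 100L), seed = seed)
    tr <- simulate_agent(agent_params("rw1", alpha = 0.5, beta = 10), sched,
                         seed = seed + 7000)
    lc <- learning_curve(tr, window = 1)
    mean(lc$raw[20:25]) - mean(lc$raw[1:5])
  }, numeric(1))
  expect_gt(mean(rises), 0)
  # model-based variant: expected value of the hp symbol also rises
  sched <- build_schedule(task_config(block_lengths = 100L), seed = 3)
  tr <- simulate_agent(agent_params("rw1", alpha = 0.5, beta = 10), sched,
                       seed = 4)
  traj <- run_model(agent_params("rw1", alpha = 0.5, beta = 10), tr)
  lcv <- learning_curve(tr, values = hp_value(traj, tr), window = 1)
  expect_true(all(lcv$raw >= 0 & lcv$raw <= 1))
})

test_that("the mixed-model contrast degenerates to OLS without subject variance", {
  set.seed(5)
  n <- 400
  tr <- data.frame(subject = rep(1:4, each = n / 4),
                   condition = rep(rep(c("A", "B"), each = n / 8), times = 4),
                   block = 1L, trial = 1:n, sym_left = 1L, sym_right = 2L,
                   chosen = ifelse(rbinom(n, 1, 0.6) == 1, 1L, 2L),
                   outcome = 1L, lost = FALSE, hp_symbol = 1L)
  mm <- hp_choice_mixed_model(tr, conditions = c("A", "B"))
  ols <- coef(lm(I(chosen == hp_symbol) ~ factor(condition, c("A", "B")),
                 data = tr))[[2]]
  expect_equal(mm$estimate, ols, tolerance = 1e-6)
  expect_identical(nrow(mm), 1L)
  expect_warning(hp_choice_mixed_model(tr[tr$subject == 1, ],
                                       conditions = c("A", "B")),
                 "single subject")
})

test_that("the mixed-model contrast recovers an injected hp-choice shift", {
  set.seed(6)
  signs <- vapply(1:10, function(rep) {
    rows <- do.call(rbind, lapply(1:26, function(s) {
      icpt <- rnorm(1, 0.5, 0.05)
      data.frame(subject = s,
                 condition = rep(c("A", "B"), each = 100),
                 block = 1L, trial = 1:200, sym_left = 1L, sym_right = 2L,
                 chosen = NA_integer_, outcome = 1L, lost = FALSE,
                 hp_symbol = 1L,
                 p = c(rep(icpt + 0.1, 100), rep(icpt, 100)))
    }))
    rows$chosen <- ifelse(rbinom(nrow(rows), 1, pmin(pmax(rows$p, 0), 1)) == 1,
                          1L, 2L)
    mm <- hp_choice_mixed_model(rows, conditions = c("A", "B"))
    mm$estimate < 0   # B below A
  }, logical(1))
  expect_gte(mean(signs), 0.9)
})

test_that("maladaptive win-stay hits the stay and switch poles for deterministic agents", {
  # hp is symbol 3; trial 1 shows the two low-probability symbols (1,2)
  base <- list(left = c(1L, 1L, 2L), right = c(2L, 3L, 3L), hp = 3L)
  stay <- toy_trials(base$left, base$right, chosen = c(1L, 1L, 2L),
                     outcome = c(1L, 0L, 0L), hp = base$hp)
  out <- maladaptive_winstay(stay)
  expect_equal(out$rates$rate, 1)
  switch_ <- toy_trials(base$left, base$right, chosen = c(1L, 3L, 2L),
                        outcome = c(1L, 0L, 0L), hp = base$hp)
  out2 <- maladaptive_winstay(switch_)
  expect_equal(out2$rates$rate, -1)
})

test_that("high reward learning rates raise maladaptive repetition", {
  rates <- vapply(c(0.3, 0.85), function(ap) {
    per_run <- vapply(1:60, function(seed) {
      sched <- build_schedule(task_config(block_lengths = c(100L, 100L)),
                              seed = seed)
      tr <- simulate_agent(agent_params("rw2", alpha_pos = ap,
                                        alpha_neg = 0.3, beta = 5),
                           sched, seed = seed + 3000)
      out <- suppressWarnings(maladaptive_winstay(tr))
      if (is.null(out$rates)) NA_real_ else out$rates$rate
    }, numeric(1))
    mean(per_run, na.rm = TRUE)
  }, numeric(1))
  expect_gt(rates[2], rates[1])
})

test_that("exploratory metrics behave for a perfect tracker and an all-lost block", {
  sched <- build_schedule(task_config(block_lengths = 100L), seed = 41)
  per <- contingency_periods(sched)
  prev_hp <- rep(NA_integer_, nrow(sched))
  for (r in 2:nrow(per))
    prev_hp[per$start[r]:per$end[r]] <- per$hp_symbol[r - 1L]
  on <- is_hp_on_screen(sched, seq_len(nrow(sched)))
  other <- ifelse(sched$sym_left != sched$hp_symbol, sched$sym_left,
                  sched$sym_right)
  # perfect tracker: hp when shown; otherwise avoids the previous hp
  fallback <- ifelse(!is.na(prev_hp) & sched$sym_left == prev_hp,
                     sched$sym_right,
                     ifelse(!is.na(prev_hp) & sched$sym_right == prev_hp,
                            sched$sym_left, other))
  tr <- data.frame(block = sched$block, trial = sched$trial,
                   sym_left = sched$sym_left, sym_right = sched$sym_right,
                   chosen = ifelse(on, sched$hp_symbol, fallback),
                   outcome = 1L, lost = FALSE, hp_symbol = sched$hp_symbol)
  m <- exploratory_metrics(tr)
  expect_equal(m$post_learning_acc, mean(on[unlist(lapply(
    seq_len(nrow(per)), function(r) (per$end[r] - 9L):per$end[r]))]),
    tolerance = 1e-12)
  expect_equal(m$perseveration, 0)
  all_lost <- toy_trials(left = c(1L, 2L), right = c(2L, 3L),
                         chosen = c(1L, 2L), outcome = c(1L, 1L), hp = 1L,
                         lost = c(TRUE, TRUE))
  expect_warning(m2 <- exploratory_metrics(all_lost), "truncated")
  expect_true(is.na(m2$post_learning_acc))
  expect_true(is.na(m2$post_error_adjust))
})

test_that("a non-learning agent adjusts after errors no more than its base switch rate", {
  diffs <- vapply(1:40, function(seed) {
    sched <- build_schedule(task_config(block_lengths = 100L), seed = seed)
    tr <- simulate_random_agent(sched, seed = seed + 900)
    m <- exploratory_metrics(tr)
    g <- tr[order(tr$trial), ]
    stay <- g$chosen[-1] == g$chosen[-nrow(g)]
    avail <- g$chosen[-nrow(g)] == g$sym_left[-1] |
      g$chosen[-nrow(g)] == g$sym_right[-1]
    base_switch <- mean(!stay[avail])
    m$post_error_adjust - base_switch
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.02)
})

test_that("the rank test matches exact enumeration and is rank-invariant", {
  r <- rank_test_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  r2 <- rank_test_groups(exp(c(1, 2, 3)), exp(c(4, 5, 6)))
  expect_equal(r2$U, r$U)
  expect_equal(r2$p, r$p)
  same <- rank_test_groups(rep(1:5, 2), rep(1:5, 2))
  expect_equal(same$U, 50)      # n_a * n_b / 2 under mid-ranks
  expect_gt(same$p, 0.99)
  expect_error(rank_test_groups(numeric(0), 1:3), "non-empty")
})

test_that("model latents align with the cohort rows they were fitted on", {
  spec <- cohort_spec(n_subjects = 2, conditions = c("A", "B"), lost_rate = 0)
  co <- simulate_cohort(spec, task_config(block_lengths = c(40L, 40L)),
                        seed = 51)
  fits <- fit_sessions(co, model = "rw1", by = c("subject", "condition"))
  ml <- model_latents(co, fits)
  expect_identical(nrow(ml), nrow(co))
  expect_false(anyNA(ml$pe[!co$lost]))
  expect_true(all(ml$v_hp >= 0 & ml$v_hp <= 1))
  # spot-check one session against a direct run_model call
  i <- co$subject == 1 & co$condition == "A"
  f <- fits[fits$subject == 1 & fits$condition == "A", ]
  traj <- run_model(agent_params("rw1", alpha = f$alpha, beta = f$beta),
                    co[i, ])
  expect_equal(ml$pe[i], traj$pe)
})
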