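#' Task design parameters for the probabilistic reversal-learning task
#'
#' Describes the three-symbol reversal task: four blocks (100/100/60/60
#' trials by default, 320 in total), three symbols per block (12 over the
#' experiment), one symbol rewarded with probability `p_high` (70%) and the
#' other two with `p_low` (30%), a covert contingency reversal after every
#' `reversal_period` trials within a block, and the three symbol pairs
#' presented in the fixed cyclic order AB, BC, CA with randomised left/right
#' placement.
#'
#' @param block_lengths Integer vector of trials per block.
#' @param n_symbols_per_block Symbols per block; the fixed pair rotation
#'   requires 3.
#' @param p_high Reward probability of the high-probability symbol.
#' @param p_low Reward probability of each low-probability symbol;
#'   must satisfy `0 <= p_low < p_high <= 1`.
#' @param reversal_period Trials between contingency reversals within a
#'   block.
#' @param pair_rotation 3x2 integer matrix of block-local symbol pairs,
#'   cycled in row order trial by trial.
#' @param response_window Response deadline in seconds; only used to label
#'   lost (no-response) trials in simulation output.
#' @return An object of class `task_config`.
#' @examples
#' cfg <- task_config()
#' sum(cfg$block_lengths) # 320
#' @export
task_config <- function(block_lengths = c(100L, 100L, 60L, 60L),
                        n_symbols_per_block = 3L,
                        p_high = 0.70, p_low = 0.30,
                        reversal_period = 25L,
                        pair_rotation = rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L)),
                        response_window = 1.25) {
  block_lengths <- as.integer(block_lengths)
  if (length(block_lengths) < 1L || anyNA(block_lengths) || any(block_lengths < 1L))
    .stop_field("block_lengths", "all block lengths must be integers >= 1")
  if (!is.numeric(p_high) || length(p_high) != 1L || is.na(p_high) ||
      p_high < 0 || p_high > 1)
    .stop_field("p_high", "must be a probability in [0, 1]")
  if (!is.numeric(p_low) || length(p_low) != 1L || is.na(p_low) ||
      p_low < 0 || p_low >= p_high)
    .stop_field("p_low", "must satisfy 0 <= p_low < p_high")
  reversal_period <- as.integer(reversal_period)
  if (length(reversal_period) != 1L || is.na(reversal_period) || reversal_period < 1L)
    .stop_field("reversal_period", "must be an integer >= 1")
  n_symbols_per_block <- as.integer(n_symbols_per_block)
  if (n_symbols_per_block != 3L)
    .stop_field("n_symbols_per_block", "the fixed pair rotation requires 3 symbols per block")
  pair_rotation <- matrix(as.integer(pair_rotation), ncol = 2L)
  if (nrow(pair_rotation) < 1L ||
      any(pair_rotation < 1L | pair_rotation > n_symbols_per_block) ||
      any(pair_rotation[, 1L] == pair_rotation[, 2L]))
    .stop_field("pair_rotation", "rows must be distinct block-local symbol pairs")
  if (!is.numeric(response_window) || response_window <= 0)
    .stop_field("response_window", "must be a positive duration in seconds")
  structure(
    list(block_lengths = block_lengths,
         n_symbols_per_block = n_symbols_per_block,
         p_high = p_high, p_low = p_low,
         reversal_period = reversal_period,
         pair_rotation = pair_rotation,
         response_window = response_window),
    class = "task_config")
}

#' @method print task_config
#' @export
print.task_config <- function(x, ...) {
  cat("Probabilistic reversal-learning task configuration\n")
  cat("  blocks:          ", paste(x$block_lengths, collapse = "/"),
      " trials (", sum(x$block_lengths), " total)\n", sep = "")
  cat("  symbols:         ", x$n_symbols_per_block, "per block,",
      x$n_symbols_per_block * length(x$block_lengths), "overall\n")
  cat("  reward schedule: ", sprintf("%.0f%% (high) vs %.0f%% (low)",
                                     100 * x$p_high, 100 * x$p_low), "\n")
  cat("  reversal every:  ", x$reversal_period, "trials within a block\n")
  invisible(x)
}

#' Materialise a trial schedule for the reversal-learning task
#'
#' Builds the full per-trial schedule: block structure, the fixed pair
#' rotation with randomised left/right placement, the current
#' high-probability symbol (reassigned uniformly to one of the other two
#' block symbols at each reversal), and pre-drawn Bernoulli outcomes for
#' every block symbol on every trial. Pre-drawing makes any chosen symbol's
#' outcome schedule-determined, so simulated and re-analysed runs are
#' reproducible.
#'
#' Symbols are numbered 1..(3 x blocks) and are disjoint across blocks;
#' trials are numbered 1..N globally and 1..len within a block. Each block
#' starts with a fresh uniformly drawn high-probability symbol.
#'
#' @param config A [task_config()].
#' @param seed Optional integer seed; schedules built with the same seed are
#'   identical field for field.
#' @return A data frame of class `trial_schedule` with one row per trial and
#'   columns `block`, `trial`, `block_trial`, `sym_left`, `sym_right`,
#'   `hp_symbol`, `draw_sym0`, `draw_sym1`, `draw_sym2` (pre-drawn outcomes
#'   of the block's first/second/third symbol). The configuration is kept in
#'   `attr(, "config")`.
#' @examples
#' sched <- build_schedule(task_config(), seed = 1)
#' nrow(sched) # 320
#' @export
build_schedule <- function(config = task_config(), seed = NULL) {
  if (!inherits(config, "task_config"))
    config <- do.call(task_config, config)
  if (!is.null(seed)) set.seed(seed)
  rot <- config$pair_rotation
  n_rot <- nrow(rot)
  n_blocks <- length(config$block_lengths)
  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    len <- config$block_lengths[b]
    within <- seq_len(len)
    seg <- (within - 1L) %/% config$reversal_period
    n_seg <- max(seg) + 1L
    hp_loc <- integer(n_seg)
    hp_loc[1L] <- sample.int(3L, 1L)
    if (n_seg > 1L) for (s in 2:n_seg)
      hp_loc[s] <- sample(setdiff(1:3, hp_loc[s - 1L]), 1L)
    hp_trial <- hp_loc[seg + 1L]
    pair_idx <- ((within - 1L) %% n_rot) + 1L
    first <- rot[pair_idx, 1L]
    second <- rot[pair_idx, 2L]
    swap <- runif(len) < 0.5
    left <- first; left[swap] <- second[swap]
    right <- second; right[swap] <- first[swap]
    p <- matrix(config$p_low, len, 3L)
    p[cbind(within, hp_trial)] <- config$p_high
    d <- matrix(rbinom(len * 3L, 1L, as.vector(p)), len, 3L)
    offset <- (b - 1L) * 3L
    blocks[[b]] <- list(block = rep.int(b, len), block_trial = within,
                        sym_left = left + offset, sym_right = right + offset,
                        hp_symbol = hp_trial + offset,
                        draw_sym0 = d[, 1L], draw_sym1 = d[, 2L],
                        draw_sym2 = d[, 3L])
  }
  cols <- lapply(setNames(names(blocks[[1L]]), names(blocks[[1L]])),
                 function(nm) unlist(lapply(blocks, `[[`, nm), use.names = FALSE))
  out <- .fast_df(c(list(block = cols$block,
                         trial = seq_along(cols$block),
                         block_trial = cols$block_trial),
                    cols[c("sym_left", "sym_right", "hp_symbol",
                           "draw_sym0", "draw_sym1", "draw_sym2")]))
  attr(out, "config") <- config
  class(out) <- c("trial_schedule", "data.frame")
  out
}

#' Trials at which the reward contingency reverses
#'
#' @param schedule A `trial_schedule` (or any trial table with `block` and
#'   `hp_symbol` columns).
#' @return Sorted global trial indices of the first trial under each new
#'   within-block contingency; for every returned index, `block_trial - 1`
#'   is a multiple of the reversal period. Block starts are not reversals.
#' @examples
#' sched <- build_schedule(task_config(), seed = 1)
#' reversal_points(sched)
#' @export
reversal_points <- function(schedule) {
  stopifnot(all(c("block", "hp_symbol") %in% names(schedule)))
  n <- nrow(schedule)
  if (n < 2L) return(integer(0))
  changed <- diff(schedule$hp_symbol) != 0 & diff(schedule$block) == 0
  which(changed) + 1L
}

#' Contingency periods of a schedule
#'
#' Splits every block at its reversal points, yielding one row per
#' contingency period (the stretch during which one symbol carries the high
#' reward probability).
#'
#' @inheritParams reversal_points
#' @return Data frame with columns `block`, `period` (global counter),
#'   `start`, `end` (global trial indices) and `hp_symbol`.
#' @export
contingency_periods <- function(schedule) {
  stopifnot(all(c("block", "hp_symbol") %in% names(schedule)))
  key <- cumsum(c(TRUE, diff(schedule$hp_symbol) != 0 | diff(schedule$block) != 0))
  start <- which(!duplicated(key))
  end <- c(start[-1L] - 1L, nrow(schedule))
  data.frame(block = schedule$block[start],
             period = seq_along(start),
             start = start, end = end,
             hp_symbol = schedule$hp_symbol[start])
}

#' Is a high-probability symbol on screen?
#'
#' @inheritParams reversal_points
#' @param index Global trial index (vectorised).
#' @return Logical: does the trial's pair contain the current
#'   high-probability symbol? With the three-pair rotation this is true on
#'   two of every three trials.
#' @export
is_hp_on_screen <- function(schedule, index) {
  if (any(index < 1L | index > nrow(schedule) | is.na(index)))
    stop("`index` out of range: schedule has ", nrow(schedule), " trials",
         call. = FALSE)
  schedule$hp_symbol[index] == schedule$sym_left[index] |
    schedule$hp_symbol[index] == schedule$sym_right[index]
}

# -- schedule serialisation ---------------------------------------------

.SCHEDULE_COLS <- c("block", "trial", "sym_left", "sym_right", "hp_symbol",
                    "draw_sym0", "draw_sym1", "draw_sym2")

#' Write / read a trial schedule as a delimited table
#'
#' Comma-delimited UTF-8 with header; columns `block, trial, sym_left,
#' sym_right, hp_symbol, draw_sym0, draw_sym1, draw_sym2`.
#'
#' @param schedule A `trial_schedule`.
#' @param path File path.
#' @return `read_schedule()` returns a `trial_schedule`;
#'   `write_schedule()` returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  write.csv(as.data.frame(schedule)[, .SCHEDULE_COLS], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  out <- read.csv(path)
  missing <- setdiff(.SCHEDULE_COLS, names(out))
  if (length(missing))
    stop("schedule file misses column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- out[, .SCHEDULE_COLS]
  out$block_trial <- stats::ave(out$trial, out$block, FUN = seq_along)
  out <- out[, c("block", "trial", "block_trial", "sym_left", "sym_right",
                 "hp_symbol", "draw_sym0", "draw_sym1", "draw_sym2")]
  class(out) <- c("trial_schedule", "data.frame")
  out
}

# Map global symbol ids in a trial table to block-local 0-based indices for
# the C++ kernels. Errors if a chosen symbol is not in the shown pair.
.localize <- function(df, check_chosen = TRUE) {
  blocks <- df$block
  syms_by_block <- lapply(split(c(df$sym_left, df$sym_right),
                                c(blocks, blocks)),
                          function(s) sort(unique(s)))
  if (any(lengths(syms_by_block) != 3L))
    stop("each block must use exactly 3 symbols", call. = FALSE)
  loc <- function(sym) {
    out <- integer(length(sym))
    for (b in names(syms_by_block)) {
      i <- blocks == type.convert(b, as.is = TRUE)
      out[i] <- match(sym[i], syms_by_block[[b]]) - 1L
    }
    out
  }
  a_loc <- loc(df$sym_left)
  b_loc <- loc(df$sym_right)
  chosen_loc <- NULL
  if (!is.null(df$chosen)) {
    ok <- !is.na(df$chosen)
    if (check_chosen && any(ok & df$chosen != df$sym_left & df$chosen != df$sym_right)) {
      bad <- which(ok & df$chosen != df$sym_left & df$chosen != df$sym_right)
      stop("chosen symbol not in the shown pair at row(s) ",
           paste(head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    filled <- df$chosen
    filled[!ok] <- df$sym_left[!ok]
    chosen_loc <- loc(filled)
    chosen_loc[!ok] <- -1L
    chosen_loc <- as.integer(chosen_loc)
  }
  hp_loc <- if (!is.null(df$hp_symbol)) loc(df$hp_symbol) else NULL
  list(a_loc = a_loc, b_loc = b_loc, chosen_loc = chosen_loc,
       hp_loc = hp_loc, symbols = syms_by_block)
}
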