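# Synthetic TSWP cohorts: fixed-duration blocks, AAABBB alternation,
# condition-dependent preview visibility and mode-dependent preview use.
# The generator is a measurement-level emulator: it reproduces the
# statistical structure the analysis pipeline assumes, not a process model
# of cognition.

#' Per-mode generator parameters
#'
#' Single-task RTs are lognormal with parameters \code{base_log_mu} /
#' \code{base_log_sigma}; pure-repetition and pre-switch trials add small
#' constant offsets; non-prepared switch trials add a trial-varying switch
#' cost (gamma-distributed with mean \code{switch_cost_ms} and SD
#' \code{switch_cost_sd}, emulating the well-known volatility of residual
#' switch costs). When the preview was visible during the preceding run and
#' a Bernoulli draw at the \emph{latest visible position} succeeds, the
#' switch response is a preview-prepared one: its RT is drawn from the fast
#' floor of the single-task distribution (quantile uniform on
#' \code{(0, fast_quantile_max)}), matching the empirical signature of
#' extremely fast switches. With probability \code{q_comp} such preparation
#' costs compensatory time: \code{compensation_ms} is spread equally over
#' the three preceding trials. Preview-use probabilities vary between
#' participants, reflecting the stable individual differences the paradigm
#' is built to measure: at cohort level the position-3 probability is
#' assigned from a deterministic quantile grid -- either the explicit
#' \code{p_use_grid} (used for the serial mode, whose empirical analogue, a
#' no-preview reference distribution, is near zero for most individuals but
#' long-tailed to the right) or the quantiles of a Beta distribution with
#' mean \code{p_use[3]} and SD \code{p_use_sd}. Stratified assignment keeps
#' every simulated cohort representative of its mode, whatever the cohort
#' size; \code{\link{simulate_participant}} called standalone draws
#' randomly from the same Beta instead. Errors are independent Bernoulli.
#'
#' @param label one of \code{"serial"}, \code{"semi_overlapper"},
#'   \code{"overlapper"}; selects the defaults.
#' @param ... named overrides of any default parameter.
#' @return a list of class \code{tswp_mode_params}.
#' @export
mode_params <- function(label = c("serial", "semi_overlapper", "overlapper"),
                        ...) {
  label <- match.arg(label)
  p <- switch(label,
    serial = list(
      switch_cost_ms = 450, switch_cost_sd = 330,
      p_use = c(0, 0, 0.02), p_use_sd = 0.055,
      p_use_grid = c(rep(0, 14), 0.04, 0.28)),
    semi_overlapper = list(
      switch_cost_ms = 220, switch_cost_sd = 200,
      p_use = c(0, 0, 0.15), p_use_sd = 0.015, p_use_grid = NULL),
    overlapper = list(
      switch_cost_ms = 60, switch_cost_sd = 60,
      p_use = c(0, 0, 0.45), p_use_sd = 0.03, p_use_grid = NULL))
  defaults <- list(
    label = label,
    base_log_mu = log(650), base_log_sigma = 0.12,
    delta_repeat = 30, delta_preswitch = 50,
    fast_quantile_max = 0.01,
    compensation_ms = 100, q_comp = 0.10,
    error_rate = 0.045)
  p <- utils::modifyList(defaults, p, keep.null = TRUE)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown mode parameter(s): ",
                        paste(bad, collapse = ", "))
  p <- utils::modifyList(p, over, keep.null = TRUE)
  stopifnot(length(p$p_use) == 3L, all(p$p_use >= 0 & p$p_use <= 1),
            p$switch_cost_ms >= 0, p$error_rate >= 0, p$error_rate <= 1,
            p$fast_quantile_max > 0, p$fast_quantile_max < 1)
  class(p) <- "tswp_mode_params"
  p
}

#' Simulation configuration for a synthetic cohort
#'
#' The default block plan mirrors the experimental phase of the paradigm:
#' per condition, one 60-s warm-up switching block, two 120-s switching
#' blocks and one 60-s single-task block per task. Condition order follows a
#' Williams (balanced Latin square) design; in the four-condition layout the
#' full-preview condition always comes first (it is the classification
#' basis) and the square is applied to the remaining conditions.
#'
#' @param experiment \code{"exp1"} (preview-length conditions full / medium
#'   / short) or \code{"exp2"} (preview-position conditions full / early /
#'   middle / late).
#' @param n_per_mode participants per processing mode (default 16).
#' @param mode_params named list of \code{\link{mode_params}} objects for
#'   \code{serial}, \code{semi_overlapper}, \code{overlapper}.
#' @param block_plan data.frame with columns \code{block_kind} and
#'   \code{duration_s}, applied per condition run.
#' @param condition_order_scheme \code{"latin_square"} (default) or
#'   \code{"fixed"}.
#' @param seed mandatory integer master seed.
#' @return a list of class \code{tswp_sim_config}.
#' @export
sim_config <- function(experiment = c("exp2", "exp1"), n_per_mode = 16,
                       mode_params = NULL, block_plan = NULL,
                       condition_order_scheme = c("latin_square", "fixed"),
                       seed) {
  experiment <- match.arg(experiment)
  condition_order_scheme <- match.arg(condition_order_scheme)
  if (missing(seed) || is.null(seed)) stop("a master seed is required")
  if (is.null(mode_params)) {
    mode_params <- list(serial = mode_params_default("serial"),
                        semi_overlapper = mode_params_default("semi_overlapper"),
                        overlapper = mode_params_default("overlapper"))
  }
  stopifnot(all(c("serial", "semi_overlapper", "overlapper") %in%
                  names(mode_params)))
  if (is.null(block_plan)) {
    block_plan <- data.frame(
      block_kind = c("warmup_switching", "task_switching", "task_switching",
                     "single_task", "single_task"),
      duration_s = c(60, 120, 120, 60, 60),
      stringsAsFactors = FALSE)
  }
  if (any(block_plan$duration_s <= 0)) stop("block durations must be positive")
  structure(list(experiment = experiment, n_per_mode = n_per_mode,
                 mode_params = mode_params, block_plan = block_plan,
                 condition_order_scheme = condition_order_scheme,
                 conditions = TSWP_CONDITIONS[[experiment]],
                 seed = as.integer(seed)),
            class = "tswp_sim_config")
}

mode_params_default <- function(label) mode_params(label)

# Williams design (balanced Latin square) over m conditions.
williams_square <- function(m) {
  base <- numeric(m)
  base[1] <- 1
  lo <- 2; hi <- m
  for (i in 2:m) {
    if (i %% 2 == 0) { base[i] <- hi; hi <- hi - 1 } else {
      base[i] <- lo; lo <- lo + 1 }
  }
  rows <- lapply(seq_len(m), function(r) ((base + r - 2) %% m) + 1)
  sq <- do.call(rbind, rows)
  if (m %% 2 == 1) sq <- rbind(sq, sq[, m:1])
  sq
}

condition_order_for <- function(config, i) {
  conds <- config$conditions
  if (config$condition_order_scheme == "fixed") return(conds)
  if (config$experiment == "exp2") {
    # full-preview first (classification basis), Williams square over rest
    rest <- setdiff(conds, "full")
    sq <- williams_square(length(rest))
    c("full", rest[sq[(i - 1) %% nrow(sq) + 1, ]])
  } else {
    sq <- williams_square(length(conds))
    conds[sq[(i - 1) %% nrow(sq) + 1, ]]
  }
}

stim_pool <- list(letter = c("A", "E", "I", "U", "G", "K", "M", "R"),
                  digit = c("2", "4", "6", "8", "3", "5", "7", "9"))
key_pool <- list(letter = c("S", "A"), digit = c("K", "L"))

#' Simulate one participant
#'
#' Generates every block of the experimental phase for one participant under
#' fixed-time semantics: trials are drawn sequentially until the cumulative
#' response time reaches the block duration, and the trial that crosses the
#' boundary is kept.
#'
#' @param params a \code{\link{mode_params}} object.
#' @param config a \code{\link{sim_config}} object.
#' @param participant_id identifier string.
#' @param participant_seed integer seed for this participant's stream.
#' @param condition_index row of the Williams square to use.
#' @param p_use3 optional override of the position-3 preview-use
#'   probability (used by \code{\link{simulate_cohort}} for stratified
#'   cohort-level assignment); when NULL, the probability is drawn from the
#'   mode's Beta distribution.
#' @return a list: \code{trials} (a \code{tswp_trials} table) and
#'   \code{events} (latent ground truth, one row per switch trial of the
#'   switching blocks: whether a preview-use event was injected and whether
#'   it carried compensation), \code{p_use} (the participant's realised
#'   preview-use probabilities).
#' @export
simulate_participant <- function(params, config, participant_id,
                                 participant_seed, condition_index = 1,
                                 p_use3 = NULL) {
  set.seed(participant_seed)
  conds <- condition_order_for(config, condition_index)

  # participant-level preview-use probabilities
  p_use <- params$p_use
  if (!is.null(p_use3)) {
    p_use[3] <- p_use3
  } else if (params$p_use_sd > 0) {
    p_use <- vapply(params$p_use, function(pm) {
      if (pm <= 0) return(0)
      rbeta_mean_sd(1, pm, params$p_use_sd)
    }, numeric(1))
  }

  trials <- list()
  events <- list()
  block_id <- 0L
  for (ci in seq_along(conds)) {
    cond <- conds[ci]
    plan <- config$block_plan
    single_tasks <- rep(TSWP_TASKS, length.out = sum(plan$block_kind ==
                                                       "single_task"))
    if (ci %% 2 == 0) single_tasks <- rev(single_tasks)
    s_i <- 0L
    for (bi in seq_len(nrow(plan))) {
      block_id <- block_id + 1L
      kind <- plan$block_kind[bi]
      dur_ms <- plan$duration_s[bi] * 1000
      if (kind == "single_task") {
        s_i <- s_i + 1L
        blk <- sim_single_block(params, dur_ms, single_tasks[s_i])
      } else {
        blk <- sim_switching_block(params, dur_ms, cond, p_use)
      }
      n <- nrow(blk$df)
      trials[[length(trials) + 1L]] <- data.frame(
        participant_id = participant_id,
        experiment = config$experiment,
        phase = "experimental",
        condition = cond,
        run_index = ci,
        block_id = block_id,
        block_kind = kind,
        block_duration_s = plan$duration_s[bi],
        trial_index = seq_len(n) - 1L,
        blk$df,
        stringsAsFactors = FALSE)
      if (!is.null(blk$events) && nrow(blk$events)) {
        events[[length(events) + 1L]] <- data.frame(
          participant_id = participant_id, condition = cond,
          run_index = ci, block_id = block_id, block_kind = kind,
          blk$events, stringsAsFactors = FALSE)
      }
    }
  }
  trials <- do.call(rbind, trials)
  events <- if (length(events)) do.call(rbind, events) else NULL
  list(trials = trials, events = events, p_use = p_use)
}

# Beta draw parameterised by mean and SD (clamped to a proper Beta).
rbeta_mean_sd <- function(n, m, s) {
  v <- min(s^2, 0.95 * m * (1 - m))
  if (v <= 0) return(rep(m, n))
  a <- m * (m * (1 - m) / v - 1)
  b <- (1 - m) * (m * (1 - m) / v - 1)
  stats::rbeta(n, a, b)
}

# Deterministic per-mode assignment of the position-3 preview-use
# probability: the explicit grid when given, otherwise Beta quantiles at
# the stratified plotting positions (i - 0.5)/n.
mode_p_use3 <- function(params, n) {
  if (!is.null(params$p_use_grid)) {
    g <- sort(params$p_use_grid)
    idx <- ceiling((seq_len(n) - 0.5) / n * length(g))
    return(g[idx])
  }
  m <- params$p_use[3]
  if (m <= 0 || params$p_use_sd <= 0) return(rep(m, n))
  v <- min(params$p_use_sd^2, 0.95 * m * (1 - m))
  a <- m * (m * (1 - m) / v - 1)
  b <- (1 - m) * (m * (1 - m) / v - 1)
  stats::qbeta((seq_len(n) - 0.5) / n, a, b)
}

rt_base <- function(params, n) {
  stats::rlnorm(n, params$base_log_mu, params$base_log_sigma)
}

rt_fast <- function(params, n) {
  stats::qlnorm(stats::runif(n, 0, params$fast_quantile_max),
                params$base_log_mu, params$base_log_sigma)
}

rt_cost <- function(params, n) {
  m <- params$switch_cost_ms; s <- params$switch_cost_sd
  if (m == 0) return(rep(0, n))
  if (s <= 0) return(rep(m, n))
  stats::rgamma(n, shape = m^2 / s^2, scale = s^2 / m)
}

sim_single_block <- function(params, dur_ms, task) {
  n_gen <- ceiling(dur_ms / 250) + 10L
  rt <- rt_base(params, n_gen)
  keep <- c(TRUE, utils::head(cumsum(rt), -1L) < dur_ms)
  n <- sum(keep)
  rt <- rt[seq_len(n)]
  correct <- stats::runif(n) >= params$error_rate
  stim <- sample(stim_pool[[task]], n, replace = TRUE)
  list(df = data.frame(
    task = task, trial_type = "single", seq_position = NA_integer_,
    preview_visible = FALSE, rt_ms = rt, correct = correct,
    stimulus = stim,
    response = sample(key_pool[[task]], n, replace = TRUE),
    stringsAsFactors = FALSE), events = NULL)
}

sim_switching_block <- function(params, dur_ms, cond, p_use) {
  n_gen <- 3L * ceiling(dur_ms / 750) + 12L
  repeat {
    idx <- seq_len(n_gen) - 1L
    pos <- (idx %% 3L) + 1L
    first_task <- sample(TSWP_TASKS, 1L)
    task <- ifelse((idx %/% 3L) %% 2L == 0L, first_task,
                   setdiff(TSWP_TASKS, first_task))
    ttype <- c("switch", "repeat", "preswitch")[pos]

    rt <- rt_base(params, n_gen)
    rt[pos == 2L] <- rt[pos == 2L] + params$delta_repeat
    rt[pos == 3L] <- rt[pos == 3L] + params$delta_preswitch

    # preview use is decided per switch trial at the latest position where
    # the preview was visible during the preceding run
    vis <- preview_positions(cond)[[1]]
    latest <- max(vis)
    p <- p_use[latest]
    is_sw <- pos == 1L
    can_use <- is_sw & idx >= 3L
    used <- can_use & stats::runif(n_gen) < p
    n_sw <- sum(is_sw)

    cost <- rt_cost(params, n_gen)
    rt[is_sw & !used] <- rt[is_sw & !used] + cost[is_sw & !used]
    rt[used] <- rt_fast(params, sum(used))

    comp <- used & stats::runif(n_gen) < params$q_comp
    for (i in which(comp)) {
      rt[(i - 3L):(i - 1L)] <- rt[(i - 3L):(i - 1L)] +
        params$compensation_ms / 3
    }

    keep <- c(TRUE, utils::head(cumsum(rt), -1L) < dur_ms)
    if (sum(rt) >= dur_ms) {
      n <- sum(keep)
      break
    }
    n_gen <- n_gen * 2L  # extremely fast stream: draw a longer one
  }
  correct <- stats::runif(n_gen) >= params$error_rate
  stim <- vapply(task, function(tk) sample(stim_pool[[tk]], 1L), character(1))
  resp <- vapply(task, function(tk) sample(key_pool[[tk]], 1L), character(1))

  sel <- seq_len(n)
  sw_sel <- which(pos[sel] == 1L)
  events <- data.frame(trial_index = sw_sel - 1L,
                       used = used[sw_sel], comp = comp[sw_sel],
                       correct = correct[sw_sel])
  list(df = data.frame(
    task = task[sel], trial_type = ttype[sel], seq_position = pos[sel],
    preview_visible = preview_visible_at(rep(cond, n), pos[sel]),
    rt_ms = rt[sel], correct = correct[sel], stimulus = stim[sel],
    response = resp[sel], stringsAsFactors = FALSE),
    events = events)
}

#' Simulate a full TSWP cohort
#'
#' Generates \code{n_per_mode} participants per processing mode with
#' deterministic per-participant seeds derived from the master seed.
#' Identical configuration and seed give identical output.
#'
#' @param config a \code{\link{sim_config}} object.
#' @return a list of class \code{tswp_cohort}: \code{trials} (one
#'   \code{tswp_trials} table for the whole cohort), \code{modes} (one row
#'   per participant: true mode and realised preview-use probability),
#'   \code{events} (per switch trial: injected preview-use ground truth) and
#'   \code{truth} (per participant x condition: injected fast events among
#'   correct switches in the analysed switching blocks, and the true rate).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "tswp_sim_config"))
  modes <- rep(c("serial", "semi_overlapper", "overlapper"),
               each = config$n_per_mode)
  n <- length(modes)
  ids <- sprintf("P%03d", seq_len(n))
  p3_by_mode <- lapply(config$mode_params[unique(modes)], mode_p_use3,
                       n = config$n_per_mode)
  idx_in_mode <- stats::ave(seq_len(n), modes, FUN = seq_along)
  all_trials <- vector("list", n)
  all_events <- vector("list", n)
  mode_rows <- vector("list", n)
  for (i in seq_len(n)) {
    pseed <- (config$seed %% 100000L) * 10000L + i * 7L
    sim <- simulate_participant(config$mode_params[[modes[i]]], config,
                                ids[i], participant_seed = pseed,
                                condition_index = i,
                                p_use3 = p3_by_mode[[modes[i]]][idx_in_mode[i]])
    all_trials[[i]] <- sim$trials
    all_events[[i]] <- sim$events
    mode_rows[[i]] <- data.frame(participant_id = ids[i],
                                 mode = modes[i],
                                 p_use_3 = sim$p_use[3],
                                 stringsAsFactors = FALSE)
  }
  trials <- tswp_trials(do.call(rbind, all_trials))
  events <- do.call(rbind, all_events)
  modes_df <- do.call(rbind, mode_rows)

  # ground truth per participant x condition over the analysed (non-warm-up)
  # switching blocks: injected preview-use events among correct switches
  ev <- events[events$block_kind == "task_switching", , drop = FALSE]
  grp <- interaction(ev$participant_id, ev$condition, drop = TRUE,
                     sep = "\r")
  truth <- do.call(rbind, lapply(split(ev, grp), function(d) {
    den <- sum(d$correct)
    data.frame(participant_id = d$participant_id[1],
               condition = d$condition[1],
               n_correct_switches = den,
               n_injected = sum(d$used & d$correct),
               true_rate = if (den > 0) sum(d$used & d$correct) / den
                           else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  truth <- merge(truth, modes_df, by = "participant_id", sort = TRUE)

  structure(list(trials = trials, modes = modes_df, events = events,
                 truth = truth, config = config),
            class = "tswp_cohort")
}

#' @export
print.tswp_cohort <- function(x, ...) {
  cat(sprintf("Synthetic TSWP cohort (%s): %d participants, %d trials, seed %d\n",
              x$config$experiment, nrow(x$modes), nrow(x$trials),
              x$config$seed))
  print(table(x$modes$mode))
  invisible(x)
}
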