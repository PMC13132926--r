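# Hand-built fixtures: small trial tables with exactly known RT structure.

# One switching block of `rts` (length a multiple of 3), tasks alternating
# AAABBB starting with `first_task`.
fixture_switching_block <- function(pid, condition, block_id, rts,
                                    first_task = "letter",
                                    correct = TRUE, run_index = 1,
                                    block_kind = "task_switching",
                                    duration_s = 120) {
  n <- length(rts)
  stopifnot(n %% 3 == 0)
  idx <- seq_len(n) - 1L
  other <- setdiff(c("letter", "digit"), first_task)
  data.frame(
    participant_id = pid, experiment = "exp1", phase = "experimental",
    condition = condition, run_index = run_index, block_id = block_id,
    block_kind = block_kind, block_duration_s = duration_s,
    trial_index = idx,
    task = ifelse((idx %/% 3L) %% 2L == 0L, first_task, other),
    trial_type = c("switch", "repeat", "preswitch")[(idx %% 3L) + 1L],
    seq_position = (idx %% 3L) + 1L,
    preview_visible = tswp:::preview_visible_at(rep(condition, n),
                                                (idx %% 3L) + 1L),
    rt_ms = rts, correct = rep_len(correct, n),
    stimulus = "A", response = "S", stringsAsFactors = FALSE)
}

fixture_single_block <- function(pid, condition, block_id, rts, task,
                                 correct = TRUE, run_index = 1,
                                 duration_s = 60) {
  n <- length(rts)
  data.frame(
    participant_id = pid, experiment = "exp1", phase = "experimental",
    condition = condition, run_index = run_index, block_id = block_id,
    block_kind = "single_task", block_duration_s = duration_s,
    trial_index = seq_len(n) - 1L, task = task, trial_type = "single",
    seq_position = NA_integer_, preview_visible = FALSE,
    rt_ms = rts, correct = rep_len(correct, n),
    stimulus = "A", response = "S", stringsAsFactors = FALSE)
}

# A complete one-condition run for one participant: a switching block whose
# RTs are supplied, followed by one single-task block per task.
fixture_run <- function(pid = "p1", condition = "full", sw_rts,
                        letter_singles = c(1000, 1000, 1000, 1000),
                        digit_singles = c(400, 500, 600, 700),
                        sw_correct = TRUE, first_task = "letter",
                        run_index = 1, block_base = (run_index - 1) * 3) {
  rbind(
    fixture_switching_block(pid, condition, block_base + 1L, sw_rts,
                            first_task = first_task, correct = sw_correct,
                            run_index = run_index),
    fixture_single_block(pid, condition, block_base + 2L, letter_singles,
                         "letter", run_index = run_index),
    fixture_single_block(pid, condition, block_base + 3L, digit_singles,
                         "digit", run_index = run_index))
}

flagged <- function(df) flag_outliers(flag_long_rts(tswp_trials(df)))

# A small but complete synthetic cohort for end-to-end tests (shortened
# blocks keep it fast).
small_cohort <- function(seed, n_per_mode = 2, experiment = "exp2",
                         durations = c(30, 60, 60, 30, 30)) {
  plan <- data.frame(
    block_kind = c("warmup_switching", "task_switching", "task_switching",
                   "single_task", "single_task"),
    duration_s = durations, stringsAsFactors = FALSE)
  simulate_cohort(sim_config(experiment = experiment,
                             n_per_mode = n_per_mode, block_plan = plan,
                             seed = seed))
}
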