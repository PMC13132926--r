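# Fast-switch scoring: quantile reference, candidacy, compensation
# correction, FSR.

test_that("single-task reference interpolates the first quartile", {
  tr <- flagged(fixture_run(sw_rts = rep(600, 6),
                            digit_singles = c(400, 500, 600, 700)))
  ref <- single_task_reference(tr, "p1", "full", 1, task = "digit")
  expect_equal(ref$threshold_ms, 400 + 0.75 * (500 - 400))
  expect_equal(ref$mean_single_rt_ms, 550)
  expect_false(ref$low_n)

  # constant sample: threshold = mean = the constant
  tr2 <- flagged(fixture_run(sw_rts = rep(600, 6),
                             digit_singles = rep(500, 4)))
  ref2 <- single_task_reference(tr2, "p1", "full", 1, task = "digit")
  expect_equal(ref2$threshold_ms, 500)
  expect_equal(ref2$mean_single_rt_ms, 500)

  # single eligible RT: usable but flagged low_n, with a warning
  tr3 <- suppressWarnings(flagged(fixture_run(sw_rts = rep(600, 6),
                                              digit_singles = 500)))
  expect_warning(
    ref3 <- single_task_reference(tr3, "p1", "full", 1, task = "digit"),
    "fewer than 4")
  expect_equal(ref3$threshold_ms, 500)
  expect_true(ref3$low_n)
})

test_that("a run without a subsequent single-task block is an error", {
  df <- fixture_run(sw_rts = rep(600, 6))
  df <- df[df$block_kind != "single_task" | df$task != "digit", ]
  tr <- flagged(df)
  expect_error(annotate_fast_switches(tr), "no single-task reference")
})

test_that("the RT criterion is inclusive: at the threshold counts", {
  # digit threshold is 475; switches into digit at idx 3 and 9
  tr <- flagged(fixture_run(
    sw_rts = c(800, 600, 600, 1200, 600, 700, 1200, 600, 700, 475, 600, 700),
    digit_singles = c(400, 500, 600, 700)))
  ann <- annotate_fast_switches(tr)
  expect_equal(ann$threshold_ms[ann$trial_index == 9], 475)
  expect_true(ann$candidate[ann$trial_index == 9])
  expect_false(ann$candidate[ann$trial_index == 3])
})

test_that("compensatory prolongation declassifies per the quoted rule", {
  # Layout (one switching block, letter first):
  #   idx 0-2   letter run, RTs 800/600/600 (idx 0: truncated -> no interval)
  #   idx 3     switch into digit, RT 1200: non-candidate; interval 2000
  #             -> the baseline (only eligible non-candidate interval)
  #   idx 4-5   digit 600/700
  #   idx 6     switch into letter, ERROR trial, RT varies: excluded from
  #             baseline, its RT still counts into the next interval
  #   idx 7-8   letter 600/700
  #   idx 9     switch into digit, RT 450: candidate (threshold 475);
  #             benefit = 550 - 450 = 100
  build <- function(rt6) flagged(fixture_run(
    sw_rts = c(800, 600, 600, 1200, 600, 700, rt6, 600, 700, 450, 600, 700),
    sw_correct = c(rep(TRUE, 6), FALSE, rep(TRUE, 5)),
    digit_singles = c(400, 500, 600, 700)))

  # interval 2500, baseline 2000: prolongation 500 > benefit 100 -> not fast
  ann1 <- annotate_fast_switches(build(1200))
  row1 <- ann1[ann1$trial_index == 9, ]
  expect_equal(row1$preceding_interval_ms, 2500)
  expect_equal(row1$baseline_interval_ms, 2000)
  expect_true(row1$candidate)
  expect_false(row1$is_fast)

  # interval 2050: prolongation 50 <= benefit 100 -> fast
  ann2 <- annotate_fast_switches(build(750))
  row2 <- ann2[ann2$trial_index == 9, ]
  expect_equal(row2$prolongation_ms, 50)
  expect_equal(row2$benefit_ms, 100)
  expect_true(row2$is_fast)

  # the error switch is annotated but can never be fast
  err <- ann2[ann2$trial_index == 6, ]
  expect_false(err$candidate)
  expect_false(err$is_fast)
})

test_that("truncated runs and missing baselines skip the correction", {
  # all switches are candidates -> no baseline exists -> RT criterion only
  tr <- flagged(fixture_run(
    sw_rts = c(450, 600, 700, 460, 600, 700, 470, 600, 700, 450, 600, 700),
    letter_singles = c(900, 1000, 1100, 1200),
    digit_singles = c(400, 500, 600, 700)))
  ann <- annotate_fast_switches(tr)
  expect_true(all(is.na(ann$baseline_interval_ms)))
  expect_true(all(ann$is_fast == ann$candidate))
  # first switch of the block has no preceding interval
  expect_true(is.na(ann$preceding_interval_ms[ann$trial_index == 0]))
})

test_that("intervals containing an over-long trial are discarded", {
  tr <- flagged(fixture_run(
    sw_rts = c(800, 600, 600, 1200, 600, 5600, 450, 600, 700, 1300, 600, 700),
    digit_singles = c(400, 500, 600, 700)))
  ann <- annotate_fast_switches(tr)
  # idx 6 follows the run 3-5 which contains a > 5000 ms trial
  expect_true(is.na(ann$preceding_interval_ms[ann$trial_index == 6]))
})

test_that("FSR is the exact ratio of fast to correct switches", {
  ann <- data.frame(
    participant_id = "p1", condition = "full",
    correct = rep(TRUE, 20), flagged = FALSE,
    is_fast = rep(c(TRUE, FALSE), c(4, 16)))
  f <- compute_fsr(ann)
  expect_equal(f$fsr, 0.2)
  expect_equal(f$n_correct_switches, 20L)

  ann2 <- data.frame(participant_id = "p1", condition = "full",
                     correct = rep(TRUE, 30), flagged = FALSE,
                     is_fast = FALSE)
  expect_equal(compute_fsr(ann2)$fsr, 0)

  # no correct switches: undefined, never silently zero
  ann3 <- data.frame(participant_id = "p1", condition = "full",
                     correct = FALSE, flagged = FALSE, is_fast = FALSE)
  f3 <- compute_fsr(ann3)
  expect_true(is.na(f3$fsr))
  expect_match(f3$reason, "no correct switch")
})

test_that("brute-force oracle agrees exactly on small cohorts", {
  for (seed in c(101, 202)) {
    co <- small_cohort(seed = seed, n_per_mode = 1,
                       durations = c(30, 45, 45, 30, 30))
    tr <- flagged(as.data.frame(co$trials))
    ann <- annotate_fast_switches(tr)
    orc <- oracle_annotate(tr)
    ann <- ann[order(ann$participant_id, ann$condition, ann$block_id,
                     ann$trial_index), ]
    expect_equal(nrow(ann), nrow(orc))
    expect_equal(ann$threshold_ms, orc$threshold, tolerance = 1e-12)
    expect_equal(ann$candidate, orc$candidate)
    expect_equal(ann$preceding_interval_ms, orc$interval)
    expect_equal(ann$baseline_interval_ms, orc$baseline)
    expect_equal(ann$is_fast, orc$is_fast)
    fsr <- compute_fsr(ann)
    for (i in seq_len(nrow(fsr))) {
      expect_equal(fsr$fsr[i],
                   oracle_fsr(orc, fsr$participant_id[i], fsr$condition[i]))
    }
  }
})

test_that("uniform pre-switch slowing cannot buy fast switches", {
  co <- small_cohort(seed = 31, n_per_mode = 1)
  tr <- flagged(as.data.frame(co$trials))
  ann <- annotate_fast_switches(tr)
  n_before <- sum(ann$is_fast)
  expect_gt(n_before, 0)

  # add a constant (larger than any benefit) to the three trials preceding
  # every candidate switch
  cand <- ann[ann$candidate, ]
  slowed <- as.data.frame(co$trials)
  for (i in seq_len(nrow(cand))) {
    sel <- slowed$participant_id == cand$participant_id[i] &
      slowed$block_id == cand$block_id[i] &
      slowed$trial_index %in% (cand$trial_index[i] - 3):(cand$trial_index[i] - 1)
    slowed$rt_ms[sel] <- slowed$rt_ms[sel] + 600
  }
  ann2 <- annotate_fast_switches(flagged(slowed))
  expect_lte(sum(ann2$is_fast), n_before)
  # with the slowing in place, only truncated-run candidates can stay fast
  checked <- ann2[ann2$comp_checked &
                    paste(ann2$participant_id, ann2$block_id,
                          ann2$trial_index) %in%
                    paste(cand$participant_id, cand$block_id,
                          cand$trial_index), ]
  expect_true(all(!checked$is_fast | checked$benefit_ms >=
                    checked$prolongation_ms))
})

test_that("raising the threshold never loses fast switches", {
  # scale all single-task RTs up: thresholds and benefits both grow
  co <- small_cohort(seed = 33, n_per_mode = 1)
  base <- as.data.frame(co$trials)
  n1 <- sum(annotate_fast_switches(flagged(base))$candidate)
  scaled <- base
  sel <- scaled$block_kind == "single_task"
  scaled$rt_ms[sel] <- scaled$rt_ms[sel] * 1.3
  n2 <- sum(annotate_fast_switches(flagged(scaled))$candidate)
  expect_gte(n2, n1)
})
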