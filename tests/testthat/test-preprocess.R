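# Exclusion cascade: hard cutoff, outlier bands, discard accounting, QC.

test_that("the hard RT cutoff is a strict inequality", {
  df <- fixture_run(sw_rts = c(5000, 5001, 600, 600, 600, 600))
  tr <- flag_long_rts(tswp_trials(df))
  sw <- tr[tr$block_kind == "task_switching", ]
  expect_equal(sw$too_long[1:2], c(FALSE, TRUE))
  expect_equal(sum(tr$too_long), 1L)
})

test_that("outlier bands match hand-computed mean/SD cells", {
  # zero-SD cell: no outliers
  t1 <- flagged(fixture_run(sw_rts = rep(600, 6),
                            digit_singles = c(500, 500, 500, 500)))
  expect_false(any(t1$rt_outlier))

  # [400, 500, 600, 1500]: M = 750, SD ~ 505 -> nothing outside 2 SD
  cell <- fixture_single_block("p1", "full", 9, c(400, 500, 600, 1500),
                               "letter", run_index = 2)
  t2 <- flagged(rbind(fixture_run(sw_rts = rep(600, 6)), cell))
  expect_false(any(t2$rt_outlier[t2$block_id == 9]))

  # [400, 410, 420, 430, 440, 900]: M = 500, SD ~ 196.2 -> 900 flagged
  cell3 <- fixture_single_block("p1", "full", 9,
                                c(400, 410, 420, 430, 440, 900),
                                "letter", run_index = 2)
  t3 <- flagged(rbind(fixture_run(sw_rts = rep(600, 6)), cell3))
  expect_equal(t3$rt_outlier[t3$block_id == 9],
               c(rep(FALSE, 5), TRUE))

  # [400, 420, 440, 460, 480, 2000]: M = 700, SD = sqrt(2032000/5) = 637.5;
  # the extreme value inflates the SD, but 2000 - 700 = 1300 still exceeds
  # 2 SD = 1275.0, so it is flagged (single pass, no re-trimming)
  cell4 <- fixture_single_block("p1", "full", 9,
                                c(400, 420, 440, 460, 480, 2000),
                                "letter", run_index = 2)
  t4 <- flagged(rbind(fixture_run(sw_rts = rep(600, 6)), cell4))
  expect_equal(t4$rt_outlier[t4$block_id == 9],
               c(rep(FALSE, 5), TRUE))
})

test_that("cells with fewer than 3 eligible trials are never flagged", {
  cell <- fixture_single_block("p1", "full", 9, c(400, 4000), "letter",
                               run_index = 2)
  tr <- flagged(rbind(fixture_run(sw_rts = rep(600, 6)), cell))
  expect_false(any(tr$rt_outlier[tr$block_id == 9]))
})

test_that("only correct trials enter and receive outlier flags", {
  rts <- c(400, 410, 420, 430, 440, 900)
  cell <- fixture_single_block("p1", "full", 9, rts, "letter",
                               correct = c(rep(TRUE, 5), FALSE),
                               run_index = 2)
  tr <- flagged(rbind(fixture_run(sw_rts = rep(600, 6)), cell))
  # 900 is an error trial: it is excluded from the cell statistics and
  # cannot be flagged itself
  expect_false(any(tr$rt_outlier[tr$block_id == 9]))
})

test_that("flagging is monotone in the cutoff and in k", {
  co <- small_cohort(seed = 21, n_per_mode = 1)
  base <- flag_long_rts(co$trials, 5000)
  lower <- flag_long_rts(co$trials, 2000)
  expect_true(all(base$too_long <= lower$too_long))
  f2 <- flag_outliers(base, k = 2)
  f3 <- flag_outliers(base, k = 3)
  expect_true(all(f3$rt_outlier <= f2$rt_outlier))
})

test_that("flags do not depend on row order within a cell", {
  co <- small_cohort(seed = 22, n_per_mode = 1)
  f1 <- flagged(as.data.frame(co$trials))
  set.seed(1)
  shuf <- as.data.frame(co$trials)[sample(nrow(co$trials)), ]
  f2 <- flagged(shuf)
  key <- function(d) paste(d$participant_id, d$block_id, d$trial_index)
  m <- match(key(f1), key(f2))
  expect_equal(f1$rt_outlier, f2$rt_outlier[m])
  expect_equal(f1$too_long, f2$too_long[m])
})

test_that("discard accounting sums consistently under both conventions", {
  co <- small_cohort(seed = 23, n_per_mode = 1)
  tr <- flagged(as.data.frame(co$trials))
  ds <- discard_summary(tr, convention = "B")
  per <- ds$per_participant
  x <- analysis_trials(tr)
  for (i in seq_len(nrow(per))) {
    sel <- x$participant_id == per$participant_id[i] &
      x$condition == per$condition[i]
    kept <- sum(x$correct[sel] & !x$too_long[sel] & !x$rt_outlier[sel])
    # outliers are only ever correct trials, so the four classes partition
    expect_equal(per$n_total[i],
                 kept + per$n_too_long[i] + per$n_outlier[i] +
                   per$n_error[i])
  }
  expect_true(all(per$discard_rate >= 0 & per$discard_rate <= 100))
  expect_true(all(per$discard_rate_B >= per$discard_rate_A))
})

test_that("discard rates follow the arithmetic definition", {
  # no flags, no errors -> 0%
  tr <- flagged(fixture_run(sw_rts = rep(600, 6)))
  ds <- discard_summary(tr)
  expect_equal(ds$summary$mean_discard, 0)
  expect_error(discard_summary(tr, condition = "late"), "no trials")

  # 5 flagged of 100 -> 5%
  rts <- c(rep(500, 95), rep(5500, 5))
  big <- fixture_single_block("p1", "full", 9, rts, "letter", run_index = 2)
  tr2 <- flagged(rbind(fixture_run(sw_rts = rep(600, 6)), big))
  per <- discard_summary(tr2)$per_participant
  expect_equal(per$n_too_long, 5L)
  expect_equal(per$discard_rate, 100 * 5 / per$n_total)
})

test_that("synthetic cohorts discard a few percent, like real data", {
  co <- small_cohort(seed = 42, n_per_mode = 2,
                     durations = c(30, 120, 120, 60, 60))
  tr <- flagged(as.data.frame(co$trials))
  ds <- discard_summary(tr)
  expect_true(all(ds$summary$mean_discard > 3 &
                    ds$summary$mean_discard < 7))
})

test_that("participant QC applies the strict block-error and count bounds", {
  ok <- fixture_run(sw_rts = rep(600, 60),
                    letter_singles = rep(1000, 45),
                    digit_singles = rep(500, 45))
  qc1 <- qc_participants(tswp_trials(ok), min_trials = 30)
  expect_true(qc1$passed)

  # exactly 20% errors in one block fails ("less than 20%" is strict)
  bad <- fixture_run(sw_rts = rep(600, 60),
                     letter_singles = rep(1000, 45),
                     digit_singles = rep(500, 45),
                     sw_correct = rep(c(FALSE, TRUE, TRUE, TRUE, TRUE), 12))
  qc2 <- qc_participants(tswp_trials(bad), min_trials = 30)
  expect_false(qc2$passed)
  expect_match(qc2$reasons, "error rate")

  # 39 trials of one task in one condition fails the count bound
  few <- fixture_run(sw_rts = rep(600, 12),
                     letter_singles = rep(1000, 33),
                     digit_singles = rep(500, 45))
  qc3 <- qc_participants(tswp_trials(few))
  expect_false(qc3$passed)
  expect_match(qc3$reasons, "min trials")
})
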