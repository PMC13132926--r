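# Brute-force re-implementations of the fast-switch scoring chain, written
# as naive loops. These serve as the independent oracle: on any small
# dataset they must agree exactly with the vectorised pipeline.

# linear-interpolation (type 7) quantile, written out by hand
oracle_quantile25 <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  if (n == 1L) return(xs)
  h <- (n - 1) * 0.25 + 1
  lo <- floor(h)
  hi <- min(lo + 1, n)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# Full naive annotation of one flagged trial table (analysis set:
# experimental, non-warm-up switching blocks; task-matched references).
oracle_annotate <- function(trials) {
  trials <- as.data.frame(trials)
  trials <- trials[trials$phase == "experimental", ]
  out <- NULL
  for (pid in unique(trials$participant_id)) {
    tp <- trials[trials$participant_id == pid, ]
    for (cond in unique(tp$condition)) {
      tc <- tp[tp$condition == cond, ]
      sw_rows <- NULL
      for (b in unique(tc$block_id[tc$block_kind == "task_switching"])) {
        tb <- tc[tc$block_id == b, ]
        tb <- tb[order(tb$trial_index), ]
        run <- tb$run_index[1]
        for (i in seq_len(nrow(tb))) {
          if (tb$trial_type[i] != "switch") next
          # reference: correct unflagged single-task RTs of this run & task
          singles <- tc[tc$block_kind == "single_task" &
                          tc$run_index == run & tc$task == tb$task[i] &
                          tc$correct & !tc$too_long & !tc$rt_outlier, ]
          thr <- oracle_quantile25(singles$rt_ms)
          ms <- mean(singles$rt_ms)
          # preceding interval: the three trials right before, if they exist
          interval <- NA_real_
          if (tb$trial_index[i] >= 3) {
            prev <- tb[tb$trial_index %in%
                         (tb$trial_index[i] - 3):(tb$trial_index[i] - 1), ]
            if (nrow(prev) == 3 && !any(prev$too_long)) {
              interval <- sum(prev$rt_ms)
            }
          }
          eligible <- tb$correct[i] && !tb$too_long[i] && !tb$rt_outlier[i]
          sw_rows <- rbind(sw_rows, data.frame(
            participant_id = pid, condition = cond, block_id = b,
            trial_index = tb$trial_index[i], rt = tb$rt_ms[i],
            eligible = eligible,
            candidate = eligible && tb$rt_ms[i] <= thr,
            threshold = thr, mean_single = ms, interval = interval,
            stringsAsFactors = FALSE))
        }
      }
      if (is.null(sw_rows)) next
      # baseline: mean interval over eligible RT-criterion non-candidates
      base_vals <- c()
      for (i in seq_len(nrow(sw_rows))) {
        if (sw_rows$eligible[i] && !sw_rows$candidate[i] &&
            !is.na(sw_rows$interval[i])) {
          base_vals <- c(base_vals, sw_rows$interval[i])
        }
      }
      baseline <- if (length(base_vals)) mean(base_vals) else NA_real_
      sw_rows$baseline <- baseline
      sw_rows$is_fast <- FALSE
      for (i in seq_len(nrow(sw_rows))) {
        if (!sw_rows$candidate[i]) next
        if (is.na(sw_rows$interval[i]) || is.na(baseline)) {
          sw_rows$is_fast[i] <- TRUE
        } else {
          prolongation <- sw_rows$interval[i] - baseline
          benefit <- sw_rows$mean_single[i] - sw_rows$rt[i]
          sw_rows$is_fast[i] <- prolongation <= benefit
        }
      }
      out <- rbind(out, sw_rows)
    }
  }
  out[order(out$participant_id, out$condition, out$block_id,
            out$trial_index), ]
}

oracle_fsr <- function(oracle_ann, pid, cond) {
  d <- oracle_ann[oracle_ann$participant_id == pid &
                    oracle_ann$condition == cond, ]
  den <- sum(d$eligible)
  if (den == 0) return(NA_real_)
  sum(d$is_fast) / den
}
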