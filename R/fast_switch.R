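# Fast-switch scoring: single-task quantile threshold, compensatory
# prolongation correction, and the fast-switch rate (FSR).

#' Single-task reference for one switching block
#'
#' A switch response counts as "fast" when it is at least as fast as the 25%
#' fastest single-task responses in the upcoming single-task block(s) of the
#' same experimental run. Single-task blocks are repeated after each
#' switching block, so this reference tracks practice effects. The threshold
#' is the first RT quartile (linear-interpolation quantile, type 7) of the
#' eligible single-task responses; eligible responses are correct and
#' unflagged.
#'
#' @param trials a flagged \code{tswp_trials} table.
#' @param participant,condition,run identify the run the switching block
#'   belongs to.
#' @param task the task switched into (used under the task-matched policy).
#' @param policy \code{"task_matched"} (default): the threshold for a switch
#'   into the digit task uses digit single-task responses; \code{"pooled"}:
#'   both tasks' single-task responses are pooled.
#' @param quantile_type quantile convention passed to
#'   \code{\link[stats]{quantile}} (default 7, linear interpolation).
#' @return a list of class \code{tswp_reference}: \code{threshold_ms},
#'   \code{mean_single_rt_ms}, \code{n_eligible}, \code{low_n} (TRUE when
#'   fewer than 4 eligible responses), \code{source_blocks}, \code{task}.
#' @export
single_task_reference <- function(trials, participant, condition, run,
                                  task = NULL,
                                  policy = c("task_matched", "pooled"),
                                  quantile_type = 7) {
  policy <- match.arg(policy)
  refs <- build_references(trials, policy = policy,
                           quantile_type = quantile_type)
  sel <- refs$participant_id == participant & refs$condition == condition &
    refs$run_index == run
  if (policy == "task_matched") sel <- sel & refs$task == task
  r <- refs[sel, , drop = FALSE]
  if (!nrow(r)) {
    stop(sprintf("no single-task reference for participant %s, run %s",
                 participant, run))
  }
  structure(list(threshold_ms = r$threshold_ms[1],
                 mean_single_rt_ms = r$mean_single_rt_ms[1],
                 n_eligible = r$n_eligible[1], low_n = r$low_n[1],
                 source_blocks = strsplit(r$source_blocks[1], ",")[[1]],
                 task = r$task[1]),
            class = "tswp_reference")
}

# One reference row per participant x condition x run x task (or pooled).
build_references <- function(trials, policy = "task_matched",
                             quantile_type = 7) {
  if (is.null(trials$too_long) || is.null(trials$rt_outlier)) {
    stop("flags not set; run flag_long_rts() and flag_outliers() first")
  }
  x <- trials[trials$phase == "experimental", , drop = FALSE]
  singles <- x[x$block_kind == "single_task" & x$correct &
                 !x$too_long & !x$rt_outlier, , drop = FALSE]
  if (!nrow(singles)) {
    stop("no eligible single-task responses in the dataset")
  }
  grp <- if (policy == "task_matched") {
    paste(singles$participant_id, singles$condition, singles$run_index,
          singles$task, sep = "\r")
  } else {
    paste(singles$participant_id, singles$condition, singles$run_index,
          sep = "\r")
  }
  refs <- lapply(split(singles, grp), function(d) {
    low <- nrow(d) < 4L
    if (low) {
      warning(sprintf(
        "fewer than 4 eligible single-task RTs for participant %s, run %s",
        d$participant_id[1], d$run_index[1]), call. = FALSE)
    }
    data.frame(participant_id = d$participant_id[1],
               condition = d$condition[1], run_index = d$run_index[1],
               task = if (policy == "task_matched") d$task[1] else "pooled",
               threshold_ms = unname(stats::quantile(d$rt_ms, 0.25,
                                                     type = quantile_type)),
               mean_single_rt_ms = mean(d$rt_ms),
               n_eligible = nrow(d), low_n = low,
               source_blocks = paste(unique(d$block_id), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, refs)
  rownames(out) <- NULL
  out
}

#' Score every switch trial as fast or not fast
#'
#' Applies the two-part fast-switch criterion to each correct, unflagged
#' switch trial of the analysed switching blocks:
#' \enumerate{
#'   \item RT criterion: the switch RT is at least as fast as (\code{<=},
#'     inclusive) the first quartile of the eligible single-task responses in
#'     the run's subsequent single-task block(s) -- such switches are
#'     \emph{candidates};
#'   \item compensation correction: the three same-task trials immediately
#'     preceding the switch must not have been prolonged by more than the
#'     switch benefit. The preceding interval is the total response time of
#'     those three trials (error responses included -- it is time on task;
#'     intervals containing an over-long trial are discarded). The baseline
#'     is the mean interval preceding the participant's non-candidate
#'     switches in the same condition, candidacy judged by the RT criterion
#'     alone. A candidate stays fast iff
#'     \code{interval - baseline <= mean_single_rt - switch_rt}.
#' }
#' Candidates that fail the correction do not re-enter the baseline (single
#' pass). When the preceding run is truncated (first switch of a block) or no
#' baseline exists, the correction is skipped and the RT criterion decides.
#' Error switches are annotated \code{candidate = FALSE},
#' \code{is_fast = FALSE}.
#'
#' @param trials a flagged \code{tswp_trials} table.
#' @param policy reference matching policy, see
#'   \code{\link{single_task_reference}}.
#' @param quantile_type quantile convention for the threshold (default 7).
#' @param include_warmup whether warm-up switching blocks are scored
#'   (default FALSE).
#' @return a data.frame of class \code{tswp_annotations}, one row per switch
#'   trial, with the threshold, candidate flag, interval, baseline,
#'   prolongation, benefit and final verdict.
#' @export
annotate_fast_switches <- function(trials,
                                   policy = c("task_matched", "pooled"),
                                   quantile_type = 7,
                                   include_warmup = FALSE) {
  policy <- match.arg(policy)
  refs <- build_references(trials, policy, quantile_type)
  x <- analysis_trials(trials, include_warmup = include_warmup,
                       include_practice = FALSE)
  x <- x[order(x$participant_id, x$block_id, x$trial_index), , drop = FALSE]
  sw_blocks <- x$block_kind %in%
    (if (include_warmup) c("task_switching", "warmup_switching")
     else "task_switching")
  is_switch <- sw_blocks & x$trial_type == "switch"
  if (!any(is_switch)) {
    stop("no switch trials in the analysis set")
  }

  # Preceding interval: total RT of the three same-task trials right before
  # the switch; undefined for the first switch of a block, discarded when it
  # contains an over-long trial.
  row_of <- as.numeric(seq_len(nrow(x)))
  names(row_of) <- paste(x$participant_id, x$block_id, x$trial_index,
                         sep = "\r")
  sw <- which(is_switch)
  prev_rows <- vapply(1:3, function(off) {
    key <- paste(x$participant_id[sw], x$block_id[sw],
                 x$trial_index[sw] - off, sep = "\r")
    unname(row_of[key])
  }, numeric(length(sw)))
  if (length(sw) == 1L) prev_rows <- matrix(prev_rows, nrow = 1L)
  has_run <- !apply(prev_rows, 1L, anyNA)
  interval <- rep(NA_real_, length(sw))
  if (any(has_run)) {
    pr <- prev_rows[has_run, , drop = FALSE]
    sums <- matrix(x$rt_ms[pr], ncol = 3L)
    longs <- matrix(x$too_long[pr], ncol = 3L)
    s <- rowSums(sums)
    s[rowSums(longs) > 0] <- NA_real_
    interval[has_run] <- s
  }

  # Thresholds via the run's reference, matched to the task switched into.
  refkey <- if (policy == "task_matched") {
    paste(refs$participant_id, refs$condition, refs$run_index, refs$task,
          sep = "\r")
  } else {
    paste(refs$participant_id, refs$condition, refs$run_index, sep = "\r")
  }
  swkey <- if (policy == "task_matched") {
    paste(x$participant_id[sw], x$condition[sw], x$run_index[sw], x$task[sw],
          sep = "\r")
  } else {
    paste(x$participant_id[sw], x$condition[sw], x$run_index[sw], sep = "\r")
  }
  m <- match(swkey, refkey)
  if (anyNA(m)) {
    bad <- sw[which(is.na(m))[1]]
    stop(sprintf(
      "no single-task reference for participant %s, condition %s, run %d",
      x$participant_id[bad], x$condition[bad], x$run_index[bad]))
  }

  ann <- data.frame(
    participant_id = x$participant_id[sw],
    condition = x$condition[sw],
    run_index = x$run_index[sw],
    block_id = x$block_id[sw],
    trial_index = x$trial_index[sw],
    task = x$task[sw],
    rt_ms = x$rt_ms[sw],
    correct = x$correct[sw],
    flagged = x$too_long[sw] | x$rt_outlier[sw],
    threshold_ms = refs$threshold_ms[m],
    mean_single_rt_ms = refs$mean_single_rt_ms[m],
    preceding_interval_ms = interval,
    stringsAsFactors = FALSE)

  eligible <- ann$correct & !ann$flagged
  ann$candidate <- eligible & ann$rt_ms <= ann$threshold_ms

  base_grp <- paste(ann$participant_id, ann$condition, sep = "\r")
  base_means <- tapply(
    ifelse(eligible & !ann$candidate, ann$preceding_interval_ms, NA_real_),
    base_grp, mean, na.rm = TRUE)
  ann$baseline_interval_ms <- as.numeric(base_means[base_grp])
  ann$baseline_interval_ms[is.nan(ann$baseline_interval_ms)] <- NA_real_

  ann$prolongation_ms <- ann$preceding_interval_ms - ann$baseline_interval_ms
  ann$benefit_ms <- ann$mean_single_rt_ms - ann$rt_ms
  comp_applicable <- !is.na(ann$prolongation_ms)
  ann$comp_checked <- ann$candidate & comp_applicable
  ann$is_fast <- ann$candidate &
    (!comp_applicable | ann$prolongation_ms <= ann$benefit_ms)

  rownames(ann) <- NULL
  class(ann) <- c("tswp_annotations", "data.frame")
  ann
}

#' Fast-switch rate per participant and condition
#'
#' The FSR is the proportion of correct fast switches among all correct
#' (unflagged) switch trials of a participant in a condition.
#'
#' @param annotations a \code{tswp_annotations} table from
#'   \code{\link{annotate_fast_switches}}.
#' @return a data.frame of class \code{tswp_fsr}, one row per participant x
#'   condition: \code{n_correct_switches}, \code{n_fast}, \code{fsr}
#'   (proportion in [0, 1]; \code{NA} with a reason when a participant has
#'   no correct switches in a condition) and \code{fsr_pct}.
#' @export
compute_fsr <- function(annotations) {
  grp <- interaction(annotations$participant_id, annotations$condition,
                     drop = TRUE, sep = "\r")
  out <- lapply(split(annotations, grp), function(d) {
    den <- sum(d$correct & !d$flagged)
    num <- sum(d$is_fast)
    data.frame(participant_id = d$participant_id[1],
               condition = d$condition[1],
               n_correct_switches = den, n_fast = num,
               fsr = if (den > 0) num / den else NA_real_,
               reason = if (den > 0) "" else "no correct switch trials",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$fsr_pct <- 100 * out$fsr
  rownames(out) <- NULL
  class(out) <- c("tswp_fsr", "data.frame")
  out
}
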