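# Exclusion cascade and participant-level quality control.

#' Flag over-long response times
#'
#' Marks trials whose RT exceeds a hard cutoff. Trials in untimed paradigms
#' can run arbitrarily long, so responses slower than the cutoff (default
#' 5000 ms, strict inequality) are removed from all analyses. Flags only --
#' nothing is deleted.
#'
#' @param trials a \code{tswp_trials} table.
#' @param cutoff_ms positive cutoff in milliseconds; a trial is flagged iff
#'   \code{rt_ms > cutoff_ms}.
#' @return the table with a logical \code{too_long} column.
#' @export
flag_long_rts <- function(trials, cutoff_ms = 5000) {
  stopifnot(cutoff_ms > 0)
  trials$too_long <- trials$rt_ms > cutoff_ms
  trials
}

#' Flag participant-specific RT outliers
#'
#' Within each cell defined by trial type and experimental block (per
#' participant), flags correct, not-over-long trials whose RT deviates more
#' than \code{k} sample standard deviations from the cell mean (strict
#' inequality, single pass, no re-trimming). Only correct trials enter the
#' cell statistics and only correct trials can be flagged, since RT analyses
#' use correct trials only. Cells with fewer than three eligible trials are
#' left unflagged (their SD estimate is unreliable).
#'
#' @param trials a \code{tswp_trials} table with \code{too_long} flags set
#'   (see \code{\link{flag_long_rts}}).
#' @param k positive SD multiplier (default 2).
#' @return the table with a logical \code{rt_outlier} column.
#' @export
flag_outliers <- function(trials, k = 2) {
  stopifnot(k > 0)
  if (is.null(trials$too_long)) {
    stop("call flag_long_rts() before flag_outliers()")
  }
  eligible <- trials$correct & !trials$too_long
  cell <- paste(trials$participant_id, trials$block_id, trials$trial_type,
                sep = "\r")
  out <- rep(FALSE, nrow(trials))
  for (idx in split(which(eligible), cell[eligible])) {
    if (length(idx) < 3L) next
    m <- mean(trials$rt_ms[idx])
    s <- stats::sd(trials$rt_ms[idx])
    if (s == 0) next
    out[idx] <- abs(trials$rt_ms[idx] - m) > k * s
  }
  trials$rt_outlier <- out
  trials
}

#' Per-participant discard statistics
#'
#' Summarises, per participant and condition, how many trials the exclusion
#' cascade removed. Two accounting conventions are computed: convention A
#' counts over-long trials plus RT outliers over all trials of the
#' condition; convention B additionally counts error trials (which are
#' removed from RT analyses but kept for error analyses). The reported
#' \code{discard_rate} uses the selected convention.
#'
#' @param trials a flagged \code{tswp_trials} table (both flag columns set).
#' @param condition optional condition label(s) to restrict to.
#' @param convention \code{"A"} (default) or \code{"B"}.
#' @param include_warmup,include_practice whether warm-up switching blocks /
#'   practice-phase trials enter the accounting (default: excluded, matching
#'   the default analysis set).
#' @return an object of class \code{tswp_discard}: a list with
#'   \code{per_participant} (counts and rates per participant x condition)
#'   and \code{summary} (mean and SD of the discard rate across participants
#'   per condition).
#' @export
discard_summary <- function(trials, condition = NULL, convention = c("A", "B"),
                            include_warmup = FALSE,
                            include_practice = FALSE) {
  convention <- match.arg(convention)
  if (is.null(trials$too_long) || is.null(trials$rt_outlier)) {
    stop("flags not set; run flag_long_rts() and flag_outliers() first")
  }
  x <- analysis_trials(trials, include_warmup, include_practice)
  if (!is.null(condition)) x <- x[x$condition %in% condition, , drop = FALSE]
  if (!nrow(x)) stop("no trials for condition")

  agg <- function(v) {
    stats::aggregate(v, by = list(participant_id = x$participant_id,
                                  condition = x$condition), FUN = sum)$x
  }
  keys <- stats::aggregate(rep(1L, nrow(x)),
                           by = list(participant_id = x$participant_id,
                                     condition = x$condition), FUN = sum)
  per <- data.frame(participant_id = keys$participant_id,
                    condition = keys$condition,
                    n_total = keys$x,
                    n_too_long = agg(as.integer(x$too_long)),
                    n_outlier = agg(as.integer(x$rt_outlier)),
                    n_error = agg(as.integer(!x$correct & !x$too_long)),
                    stringsAsFactors = FALSE)
  per$discard_rate_A <- 100 * (per$n_too_long + per$n_outlier) / per$n_total
  per$discard_rate_B <- 100 * (per$n_too_long + per$n_outlier + per$n_error) /
    per$n_total
  per$discard_rate <- if (convention == "A") per$discard_rate_A else
    per$discard_rate_B

  smry <- do.call(rbind, lapply(split(per, per$condition), function(d) {
    data.frame(condition = d$condition[1], n_participants = nrow(d),
               mean_discard = mean(d$discard_rate),
               sd_discard = stats::sd(d$discard_rate),
               stringsAsFactors = FALSE)
  }))
  rownames(smry) <- NULL
  structure(list(per_participant = per, summary = smry,
                 convention = convention),
            class = "tswp_discard")
}

#' @export
print.tswp_discard <- function(x, ...) {
  cat(sprintf("Discard summary (convention %s: %s)\n", x$convention,
              if (x$convention == "A") "over-long + outliers"
              else "over-long + outliers + errors"))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Participant-level quality control
#'
#' A participant passes iff every block of every condition has an error rate
#' strictly below \code{max_block_error_pct} and every task x condition cell
#' has at least \code{min_trials} trials.
#'
#' @param trials a \code{tswp_trials} table.
#' @param max_block_error_pct block error-rate bound in percent (default 20;
#'   "less than" is strict, so exactly 20\% fails).
#' @param min_trials minimum trials per task and condition (default 40).
#' @param include_warmup whether warm-up blocks count toward the per-block
#'   error-rate check (default TRUE: the bound applies to any block) and the
#'   trial counts.
#' @return a data.frame with one row per participant: \code{passed},
#'   \code{max_block_error_rate}, \code{min_trials_per_task_condition} and a
#'   semicolon-separated \code{reasons} string (empty when passed).
#' @export
qc_participants <- function(trials, max_block_error_pct = 20,
                            min_trials = 40, include_warmup = TRUE) {
  x <- analysis_trials(trials, include_warmup = include_warmup,
                       include_practice = FALSE)
  out <- lapply(split(x, x$participant_id), function(d) {
    blk_err <- vapply(split(d, paste(d$block_id)), function(b) {
      100 * sum(!b$correct) / nrow(b)
    }, numeric(1))
    counts <- table(d$condition, d$task)
    min_ct <- min(counts)
    reasons <- character()
    if (max(blk_err) >= max_block_error_pct) {
      reasons <- c(reasons, sprintf("block error rate %.1f%% >= %g%%",
                                    max(blk_err), max_block_error_pct))
    }
    if (min_ct < min_trials) {
      reasons <- c(reasons, sprintf("min trials %d < %d", min_ct, min_trials))
    }
    data.frame(participant_id = d$participant_id[1],
               passed = !length(reasons),
               max_block_error_rate = max(blk_err),
               min_trials_per_task_condition = min_ct,
               reasons = paste(reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
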