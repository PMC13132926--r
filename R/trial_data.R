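# Trial-stream data model: long-format trial logs, one row per response.

TSWP_COLUMNS <- c(
  "participant_id", "experiment", "phase", "condition", "run_index",
  "block_id", "block_kind", "block_duration_s", "trial_index", "task",
  "trial_type", "seq_position", "preview_visible", "rt_ms", "correct",
  "stimulus", "response"
)

TSWP_CONDITIONS <- list(
  exp1 = c("full", "medium", "short"),
  exp2 = c("full", "early", "middle", "late")
)

TSWP_TASKS <- c("letter", "digit")
TSWP_TRIAL_TYPES <- c("single", "switch", "repeat", "preswitch")
TSWP_BLOCK_KINDS <- c("single_task", "warmup_switching", "task_switching")

#' Sequence positions at which the preview is visible, per condition
#'
#' Preview-length conditions (full/medium/short) show the upcoming task's
#' stimulus from a given position onwards; preview-position conditions
#' (early/middle/late) show it at exactly one position of the three-trial run.
#'
#' @param condition character vector of condition labels.
#' @return a named list mapping each condition to the sequence positions
#'   (subset of 1:3) at which the preview is visible.
#' @export
preview_positions <- function(condition) {
  map <- list(
    full = 1:3, medium = 2:3, short = 3L,
    early = 1L, middle = 2L, late = 3L
  )
  unknown <- setdiff(unique(condition), names(map))
  if (length(unknown)) {
    stop("unknown condition label(s): ", paste(unknown, collapse = ", "))
  }
  map[condition]
}

preview_visible_at <- function(condition, seq_position) {
  vapply(seq_along(condition), function(i) {
    sp <- seq_position[i]
    if (is.na(sp)) return(FALSE)
    sp %in% preview_positions(condition[i])[[1]]
  }, logical(1))
}

#' Construct a validated trial table
#'
#' Builds the package's canonical long-format trial container: one row per
#' behavioural response, carrying its block and condition context. Missing
#' derivable columns (\code{trial_index}, \code{trial_type},
#' \code{seq_position}, \code{preview_visible}, \code{run_index},
#' \code{phase}, \code{experiment}) are reconstructed; structural violations
#' of the AAABBB alternation are an error.
#'
#' @param df a data.frame with at least \code{participant_id},
#'   \code{condition}, \code{block_id}, \code{block_kind}, \code{task},
#'   \code{rt_ms} and \code{correct}.
#' @return a data.frame of class \code{tswp_trials} with the canonical
#'   columns, ordered by participant, block and trial index. Rows rejected
#'   for hard invariant violations (non-positive or missing RT) are kept in
#'   the \code{"rejected"} attribute together with a reason.
#' @export
tswp_trials <- function(df) {
  mandatory <- c("participant_id", "condition", "block_id", "block_kind",
                 "task", "rt_ms", "correct")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$participant_id <- as.character(df$participant_id)
  df$condition <- as.character(df$condition)
  df$block_kind <- as.character(df$block_kind)
  df$task <- as.character(df$task)
  df$rt_ms <- suppressWarnings(as.numeric(df$rt_ms))
  df$correct <- parse_logical(df$correct)
  df$block_id <- utils::type.convert(as.character(df$block_id),
                                     as.is = TRUE)
  if (!is.null(df$block_duration_s)) {
    df$block_duration_s <- suppressWarnings(as.numeric(df$block_duration_s))
  }
  if (!is.null(df$seq_position)) {
    df$seq_position <- suppressWarnings(as.integer(df$seq_position))
  }

  bad_kind <- setdiff(unique(df$block_kind), TSWP_BLOCK_KINDS)
  if (length(bad_kind)) {
    stop("unknown block_kind value(s): ", paste(bad_kind, collapse = ", "))
  }
  preview_positions(unique(df$condition))  # errors on unknown labels

  # Hard row-level invariant: rt_ms must be a positive number.
  bad_rt <- is.na(df$rt_ms) | df$rt_ms <= 0
  rejected <- NULL
  if (any(bad_rt)) {
    rejected <- df[bad_rt, , drop = FALSE]
    rejected$reason <- ifelse(is.na(rejected$rt_ms),
                              "non-numeric RT", "non-positive RT")
    df <- df[!bad_rt, , drop = FALSE]
  }

  if (is.null(df$phase)) df$phase <- "experimental"
  if (is.null(df$experiment)) {
    conds <- unique(df$condition)
    df$experiment <- if (any(conds %in% c("early", "middle", "late")))
      "exp2" else "exp1"
  }
  if (is.null(df$block_duration_s)) df$block_duration_s <- NA_real_
  if (is.null(df$stimulus)) df$stimulus <- NA_character_
  if (is.null(df$response)) df$response <- NA_character_

  # Preserve input order within blocks, then index trials.
  df$.ord <- seq_len(nrow(df))
  df <- df[order(df$participant_id, df$block_id, df$.ord), , drop = FALSE]
  if (is.null(df$trial_index)) {
    df$trial_index <- stats::ave(rep(0L, nrow(df)),
                                 df$participant_id, df$block_id,
                                 FUN = function(z) seq_along(z) - 1L)
  } else {
    df$trial_index <- as.integer(df$trial_index)
    df <- df[order(df$participant_id, df$block_id, df$trial_index), ,
             drop = FALSE]
  }
  df$.ord <- NULL

  had_trial_type <- !is.null(df$trial_type)
  key <- paste(df$participant_id, df$block_id, sep = "\r")
  derived <- unsplit(lapply(split(seq_len(nrow(df)), key), function(idx) {
    derive_block_structure(df$task[idx], df$block_kind[idx],
                           df$participant_id[idx][1], df$block_id[idx][1])
  }), key)
  if (!had_trial_type) {
    df$trial_type <- c("single", "switch", "repeat", "preswitch")[derived + 1L]
  }
  df$seq_position <- ifelse(derived == 0L, NA_integer_, derived)

  if (is.null(df$run_index)) df$run_index <- derive_run_index(df)
  df$run_index <- as.integer(df$run_index)
  if (is.null(df$preview_visible)) {
    df$preview_visible <- df$block_kind != "single_task" &
      preview_visible_at(df$condition, df$seq_position)
  } else {
    df$preview_visible <- parse_logical(df$preview_visible)
  }

  df <- df[, TSWP_COLUMNS]
  rownames(df) <- NULL
  class(df) <- c("tswp_trials", "data.frame")
  attr(df, "rejected") <- rejected
  df
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

# Returns, per trial of one block, its position in the three-trial run
# (1 = switch, 2 = repeat, 3 = preswitch), or 0 for single-task trials.
# Positions follow the task's run boundaries so that logs with isolated
# rejected rows remain ingestible; a same-task run longer than three trials
# breaks the AAABBB alternation and is a structural error.
derive_block_structure <- function(task, block_kind, participant, block) {
  n <- length(task)
  if (block_kind[1] == "single_task") {
    if (length(unique(task)) > 1) {
      stop(sprintf(
        "single-task block with mixed tasks (participant %s, block %s)",
        participant, block))
    }
    return(rep(0L, n))
  }
  runs <- rle(task)
  if (any(runs$lengths > 3L)) {
    bad_run <- which(runs$lengths > 3L)[1]
    bad_idx <- sum(runs$lengths[seq_len(bad_run - 1L)]) + 3L
    stop(sprintf(
      "inconsistent AAABBB structure (participant %s, block %s, trial %d)",
      participant, block, bad_idx))
  }
  pos <- sequence(runs$lengths)
  as.integer(pos)
}

# A run groups the consecutive blocks of one (phase, condition) pair.
derive_run_index <- function(df) {
  unsplit(lapply(split(seq_len(nrow(df)), df$participant_id), function(idx) {
    grp <- paste(df$phase[idx], df$condition[idx], sep = "\r")
    cumsum(c(TRUE, grp[-1] != grp[-length(grp)]))
  }), df$participant_id)
}

#' Read a long-format trial log
#'
#' Parses a delimited text file (comma or tab, auto-detected from the header
#' line) into a validated \code{\link{tswp_trials}} table. A column-mapping
#' schema adapts external column names and condition labels, so deposited
#' datasets can be ingested without code changes.
#'
#' @param path path to a delimited text file with a header row.
#' @param schema optional list with elements \code{columns} (named character
#'   vector mapping canonical names, e.g. \code{c(rt_ms = "RT")}) and
#'   \code{conditions} (named character vector mapping external condition
#'   labels to canonical ones, e.g. \code{c(noPreview = "full")}). May also
#'   be the path to a YAML file with those keys.
#' @return a \code{tswp_trials} table; rows violating hard invariants are in
#'   \code{attr(x, "rejected")} with reasons.
#' @export
read_trial_log <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(schema) && length(schema) == 1) {
    schema <- yaml::read_yaml(schema)
  }
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, encoding = "UTF-8",
                          colClasses = "character")
  if (!is.null(schema$columns)) {
    cmap <- unlist(schema$columns)
    for (canonical in names(cmap)) {
      ext <- cmap[[canonical]]
      if (!ext %in% names(df)) {
        stop("schema maps '", canonical, "' to missing column '", ext, "'")
      }
      names(df)[names(df) == ext] <- canonical
    }
  }
  if (!is.null(schema$conditions) && "condition" %in% names(df)) {
    amap <- unlist(schema$conditions)
    hit <- df$condition %in% names(amap)
    df$condition[hit] <- amap[df$condition[hit]]
  }
  tswp_trials(df)
}

#' Write a trial log
#'
#' Writes the canonical long format as tab-separated UTF-8 text with a header
#' row. \code{read_trial_log(write_trial_log(x, p))} reproduces \code{x}
#' field for field, and writing the same table twice is byte-identical.
#'
#' @param trials a \code{tswp_trials} table.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_trial_log <- function(trials, path) {
  stopifnot(inherits(trials, "tswp_trials"))
  out <- as.data.frame(trials)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(TSWP_COLUMNS, collapse = "\t"), con)
  if (nrow(out)) {
    cols <- lapply(out[TSWP_COLUMNS], function(x) {
      if (is.numeric(x)) {
        ifelse(is.na(x), "NA", format(x, digits = 15, trim = TRUE,
                                      scientific = FALSE))
      } else as.character(x)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Validate a trial table against the paradigm's structural invariants
#'
#' Checks every structural invariant of the trial stream and returns the
#' violations as data, not exceptions: positive RTs, the deterministic
#' switch/repeat/preswitch cycle with task alternation every three trials
#' (AAABBB), constant task within single-task blocks, consistency of
#' \code{seq_position} with \code{trial_type}, preview visibility consistent
#' with the condition, unique trial indices, and availability of a
#' subsequent single-task block for every experimental switching block
#' (required by the fast-switch reference).
#'
#' @param trials a \code{tswp_trials} table (or plain data.frame with the
#'   canonical columns).
#' @return a data.frame with one row per violation (participant, block,
#'   trial index, invariant, message); zero rows iff all invariants hold.
#' @export
validate_trials <- function(trials) {
  v <- list()
  add <- function(participant, block, trial, invariant, message) {
    v[[length(v) + 1L]] <<- data.frame(
      participant_id = as.character(participant), block_id = block,
      trial_index = trial, invariant = invariant, message = message,
      stringsAsFactors = FALSE)
  }

  bad_rt <- which(is.na(trials$rt_ms) | trials$rt_ms <= 0)
  for (i in bad_rt) {
    add(trials$participant_id[i], trials$block_id[i], trials$trial_index[i],
        "positive RT", "rt_ms must be > 0")
  }

  key <- paste(trials$participant_id, trials$block_id, sep = "\r")
  for (idx in split(seq_len(nrow(trials)), key)) {
    b <- trials[idx, , drop = FALSE]
    p <- b$participant_id[1]; blk <- b$block_id[1]
    if (anyDuplicated(b$trial_index)) {
      add(p, blk, b$trial_index[duplicated(b$trial_index)][1],
          "trial ordering", "duplicated trial_index within block")
      next
    }
    b <- b[order(b$trial_index), , drop = FALSE]
    if (b$block_kind[1] == "single_task") {
      if (length(unique(b$task)) > 1) {
        add(p, blk, b$trial_index[which(b$task != b$task[1])[1]],
            "single-task constancy", "task changes within single-task block")
      }
      if (any(b$trial_type != "single")) {
        add(p, blk, b$trial_index[which(b$trial_type != "single")[1]],
            "single-task trial type", "trial_type must be 'single'")
      }
    } else {
      pos <- ((seq_len(nrow(b)) - 1L) %% 3L) + 1L
      expected_type <- c("switch", "repeat", "preswitch")[pos]
      mismatch <- which(b$trial_type != expected_type)
      if (length(mismatch)) {
        add(p, blk, b$trial_index[mismatch[1]], "trial-type cycle",
            "trial_type must cycle switch-repeat-preswitch")
      }
      run <- (seq_len(nrow(b)) - 1L) %/% 3L
      want <- ifelse(run %% 2L == 0L, b$task[1],
                     setdiff(TSWP_TASKS, b$task[1]))
      bad <- which(b$task != want)
      if (length(bad)) {
        add(p, blk, b$trial_index[bad[1]], "AAABBB structure",
            "task must alternate every three trials")
      }
      sp_bad <- which(!is.na(b$seq_position) & b$seq_position != pos)
      if (length(sp_bad)) {
        add(p, blk, b$trial_index[sp_bad[1]], "seq_position consistency",
            "seq_position must match position in the three-trial run")
      }
      expect_prev <- preview_visible_at(b$condition, pos)
      pv_bad <- which(b$preview_visible != expect_prev)
      if (length(pv_bad)) {
        add(p, blk, b$trial_index[pv_bad[1]], "preview/condition consistency",
            sprintf("preview_visible inconsistent with condition '%s'",
                    b$condition[1]))
      }
    }
  }

  # Reference availability: every experimental switching block needs a later
  # single-task block in its run, for each task.
  blocks <- blocks_table(trials)
  sw <- blocks[blocks$block_kind == "task_switching" &
                 blocks$phase == "experimental", , drop = FALSE]
  for (i in seq_len(nrow(sw))) {
    run_blocks <- blocks[blocks$participant_id == sw$participant_id[i] &
                           blocks$run_index == sw$run_index[i], , drop = FALSE]
    singles <- run_blocks[run_blocks$block_kind == "single_task" &
                            run_blocks$block_id > sw$block_id[i], ,
                          drop = FALSE]
    for (tk in TSWP_TASKS) {
      if (!tk %in% singles$task) {
        add(sw$participant_id[i], sw$block_id[i], NA_integer_,
            "single-task reference availability",
            sprintf("no subsequent single-task block for task '%s' in run %d",
                    tk, sw$run_index[i]))
      }
    }
  }

  if (!length(v)) {
    return(data.frame(participant_id = character(), block_id = integer(),
                      trial_index = integer(), invariant = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

#' Summarise the blocks of a trial table
#'
#' @param trials a \code{tswp_trials} table.
#' @return one row per participant x block: kind, condition, phase, run,
#'   duration, trial count, dominant task (for single-task blocks) and the
#'   switching block each single-task block follows within its run.
#' @export
blocks_table <- function(trials) {
  key <- paste(trials$participant_id, trials$block_id, sep = "\r")
  first <- !duplicated(key)
  n_trials <- as.vector(table(key)[unique(key)])
  out <- data.frame(
    participant_id = trials$participant_id[first],
    block_id = trials$block_id[first],
    block_kind = trials$block_kind[first],
    condition = trials$condition[first],
    phase = trials$phase[first],
    run_index = trials$run_index[first],
    block_duration_s = trials$block_duration_s[first],
    task = ifelse(trials$block_kind[first] == "single_task",
                  trials$task[first], NA_character_),
    n_trials = n_trials,
    stringsAsFactors = FALSE)
  out$follows_block <- NA
  for (i in which(out$block_kind == "single_task")) {
    prior <- out[out$participant_id == out$participant_id[i] &
                   out$run_index == out$run_index[i] &
                   out$block_kind == "task_switching" &
                   out$block_id < out$block_id[i], , drop = FALSE]
    if (nrow(prior)) out$follows_block[i] <- max(prior$block_id)
  }
  rownames(out) <- NULL
  out
}

#' Restrict a trial table to the default analysis set
#'
#' The analyses operate on experimental-phase trials outside the warm-up
#' switching blocks (which exist to prepare participants for a condition).
#' Both exclusions are reversible here.
#'
#' @param trials a \code{tswp_trials} table.
#' @param include_warmup keep warm-up switching blocks?
#' @param include_practice keep practice-phase trials?
#' @return the filtered table.
#' @export
analysis_trials <- function(trials, include_warmup = FALSE,
                            include_practice = FALSE) {
  keep <- rep(TRUE, nrow(trials))
  if (!include_practice) keep <- keep & trials$phase == "experimental"
  if (!include_warmup) keep <- keep & trials$block_kind != "warmup_switching"
  trials[keep, , drop = FALSE]
}

#' @export
print.tswp_trials <- function(x, ...) {
  cat(sprintf("TSWP trial log: %d trials, %d participant(s), %s\n",
              nrow(x), length(unique(x$participant_id)),
              paste(unique(x$experiment), collapse = "/")))
  cat(sprintf("  conditions: %s\n",
              paste(sort(unique(x$condition)), collapse = ", ")))
  rej <- attr(x, "rejected")
  if (!is.null(rej)) cat(sprintf("  rejected rows: %d\n", nrow(rej)))
  n <- min(nrow(x), 6L)
  if (n > 0) print(as.data.frame(x)[seq_len(n), ])
  if (nrow(x) > n) cat(sprintf("  ... %d more trials\n", nrow(x) - n))
  invisible(x)
}
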