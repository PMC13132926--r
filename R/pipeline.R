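# Orchestration: QC -> exclusion cascade -> fast-switch scoring -> FSR ->
# classification -> summary tables and inferential statistics.

#' Analysis configuration
#'
#' Collects every analytic choice of the pipeline with its documented
#' default, so a run is fully described by its configuration (and seed).
#'
#' @param cutoff_ms hard RT cutoff in ms (default 5000, strict).
#' @param outlier_k SD multiplier for the outlier band (default 2, strict).
#' @param trim trimming proportion for all trimmed statistics (default 0.2).
#' @param quantile_type quantile convention for the fast-switch threshold
#'   (default 7, linear interpolation).
#' @param task_matching \code{"task_matched"} or \code{"pooled"} single-task
#'   reference policy.
#' @param discard_convention discard accounting convention, \code{"A"} or
#'   \code{"B"} (see \code{\link{discard_summary}}).
#' @param include_warmup,include_practice whether warm-up switching blocks /
#'   practice trials enter the analysis (default: no).
#' @param cutoffs explicit \code{\link{mode_cutoffs}} object (proportion
#'   scale), or NULL.
#' @param cutoffs_reference numeric vector of reference FSRs (proportion
#'   scale) from which to derive cutoffs, or the path of a one-column text
#'   file of such values; ignored when \code{cutoffs} is given.
#' @param basis_condition condition whose FSR is the classification basis
#'   (default \code{"full"}).
#' @param min_trials,max_block_error_pct participant QC bounds.
#' @param seed optional integer seed recorded in the manifest (the analysis
#'   itself is deterministic).
#' @return a list of class \code{tswp_analysis_config}.
#' @export
tswp_config <- function(cutoff_ms = 5000, outlier_k = 2, trim = 0.2,
                        quantile_type = 7,
                        task_matching = c("task_matched", "pooled"),
                        discard_convention = c("A", "B"),
                        include_warmup = FALSE, include_practice = FALSE,
                        cutoffs = NULL, cutoffs_reference = NULL,
                        basis_condition = "full",
                        min_trials = 40, max_block_error_pct = 20,
                        seed = NULL) {
  task_matching <- match.arg(task_matching)
  discard_convention <- match.arg(discard_convention)
  if (is.null(cutoffs) && !is.null(cutoffs_reference)) {
    if (is.character(cutoffs_reference)) {
      vals <- scan(cutoffs_reference, what = numeric(), quiet = TRUE)
      cutoffs <- derive_cutoffs(vals, provenance = cutoffs_reference)
    } else {
      cutoffs <- derive_cutoffs(cutoffs_reference)
    }
  }
  structure(list(cutoff_ms = cutoff_ms, outlier_k = outlier_k, trim = trim,
                 quantile_type = quantile_type,
                 task_matching = task_matching,
                 discard_convention = discard_convention,
                 include_warmup = include_warmup,
                 include_practice = include_practice,
                 cutoffs = cutoffs, basis_condition = basis_condition,
                 min_trials = min_trials,
                 max_block_error_pct = max_block_error_pct,
                 seed = seed),
            class = "tswp_analysis_config")
}

#' Run the full TSWP analysis
#'
#' Applies the complete pipeline to a trial log: participant quality
#' control, the exclusion cascade (hard RT cutoff, then 2-SD outlier bands
#' per trial type and block), single-task references, fast-switch
#' annotation with the compensatory-prolongation correction, FSR per
#' participant and condition, processing-mode classification on the
#' full-preview FSR, descriptive summary tables (trimmed means with trimmed
#' standard errors), and the inferential statistics of the design: a
#' heteroscedastic between-by-within trimmed-means ANOVA on the FSRs
#' (processing mode x condition) with robust effect sizes, and exploratory
#' classical one-way repeated-measures ANOVAs on FSR within each mode group.
#'
#' @param trials a \code{tswp_trials} table (see \code{\link{read_trial_log}}
#'   or \code{\link{simulate_cohort}}).
#' @param config a \code{\link{tswp_config}} object; it must carry mode
#'   cutoffs (explicit or derivable from a reference sample).
#' @return an object of class \code{tswp_analysis}; see
#'   \code{\link{summary.tswp_analysis}}.
#' @export
tswp_analysis <- function(trials, config = tswp_config()) {
  stopifnot(inherits(config, "tswp_analysis_config"))
  if (is.null(config$cutoffs)) {
    stop("no classification cutoffs configured: supply 'cutoffs' or ",
         "'cutoffs_reference' to tswp_config()")
  }
  if (!nrow(trials)) stop("no participants after QC: empty input")

  qc <- qc_participants(trials,
                        max_block_error_pct = config$max_block_error_pct,
                        min_trials = config$min_trials)
  excluded <- qc$participant_id[!qc$passed]
  kept <- trials[!trials$participant_id %in% excluded, , drop = FALSE]
  if (!nrow(kept)) stop("no participants after QC")

  kept <- flag_long_rts(kept, config$cutoff_ms)
  kept <- flag_outliers(kept, config$outlier_k)

  discard <- discard_summary(kept, convention = config$discard_convention,
                             include_warmup = config$include_warmup,
                             include_practice = config$include_practice)
  ann <- annotate_fast_switches(kept, policy = config$task_matching,
                                quantile_type = config$quantile_type,
                                include_warmup = config$include_warmup)
  fsr <- compute_fsr(ann)

  basis <- fsr[fsr$condition == config$basis_condition, , drop = FALSE]
  if (!nrow(basis)) {
    stop("basis condition '", config$basis_condition,
         "' not present in the data")
  }
  classification <- data.frame(
    participant_id = basis$participant_id,
    basis_fsr = basis$fsr,
    label = classify_mode(basis$fsr, config$cutoffs),
    stringsAsFactors = FALSE)
  unclass_ids <- classification$participant_id[
    classification$label == "unclassifiable"]

  fsr <- merge(fsr, classification[, c("participant_id", "label")],
               by = "participant_id", sort = TRUE)
  fsr_used <- fsr[!fsr$participant_id %in% unclass_ids, , drop = FALSE]
  fsr_used$label <- droplevels(fsr_used$label)

  tables <- summary_tables(kept, fsr_used, config)
  anovas <- pipeline_anovas(fsr_used, config)

  structure(list(
    tables = tables, anovas = anovas, fsr = fsr,
    classification = classification, cutoffs = config$cutoffs,
    annotations = ann, discard = discard, qc = qc,
    excluded = list(qc_failed = excluded, unclassifiable = unclass_ids),
    config = config),
    class = "tswp_analysis")
}

trimmed_cell <- function(x, trim) {
  ts <- trimmed_stats(x, trim)
  data.frame(n = ts$n, mt = ts$mt, se_trimmed = ts$se_trimmed)
}

summary_tables <- function(kept, fsr_used, config) {
  trim <- config$trim
  x <- analysis_trials(kept, config$include_warmup, config$include_practice)
  lab <- fsr_used[!duplicated(fsr_used$participant_id),
                  c("participant_id", "label")]
  x <- merge(x, lab, by = "participant_id", sort = TRUE)

  # FSR per mode x condition (trimmed over participants)
  fsr_tab <- do.call(rbind, lapply(
    split(fsr_used, list(fsr_used$label, fsr_used$condition), drop = TRUE),
    function(d) {
      ok <- !is.na(d$fsr)
      cbind(data.frame(label = d$label[1], condition = d$condition[1],
                       stringsAsFactors = FALSE),
            trimmed_cell(d$fsr[ok], trim))
    }))
  rownames(fsr_tab) <- NULL

  # RT per mode x condition x trial type: participant trimmed means of
  # correct unflagged RTs, then trimmed over participants
  rt_eligible <- x[x$correct & !x$too_long & !x$rt_outlier, , drop = FALSE]
  per_part <- do.call(rbind, lapply(
    split(rt_eligible,
          list(rt_eligible$participant_id, rt_eligible$condition,
               rt_eligible$trial_type), drop = TRUE),
    function(d) data.frame(participant_id = d$participant_id[1],
                           label = d$label[1], condition = d$condition[1],
                           trial_type = d$trial_type[1],
                           rt = trimmed_mean(d$rt_ms, trim),
                           stringsAsFactors = FALSE)))
  rt_tab <- do.call(rbind, lapply(
    split(per_part, list(per_part$label, per_part$condition,
                         per_part$trial_type), drop = TRUE),
    function(d) cbind(data.frame(label = d$label[1],
                                 condition = d$condition[1],
                                 trial_type = d$trial_type[1],
                                 stringsAsFactors = FALSE),
                      trimmed_cell(d$rt, trim))))
  rownames(rt_tab) <- NULL

  # switch prolongation Delta-hat per mode x condition, under both baselines
  delta_tab <- do.call(rbind, lapply(
    split(rt_tab, list(rt_tab$label, rt_tab$condition), drop = TRUE),
    function(d) {
      get <- function(tt) d$mt[d$trial_type == tt]
      sw <- get("switch")
      others_all <- c(get("single"), get("repeat"), get("preswitch"))
      others_sw <- c(get("repeat"), get("preswitch"))
      data.frame(label = d$label[1], condition = d$condition[1],
                 delta_hat = if (length(sw)) sw - mean(others_all)
                             else NA_real_,
                 delta_hat_switching_only =
                   if (length(sw)) sw - mean(others_sw) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  rownames(delta_tab) <- NULL

  # percentage errors per condition x block kind (single vs switching)
  pe_tab <- do.call(rbind, lapply(
    split(x, list(x$condition, x$block_kind, x$trial_type), drop = TRUE),
    function(d) {
      per <- tapply(!d$correct, d$participant_id, function(z) 100 * mean(z))
      data.frame(condition = d$condition[1], block_kind = d$block_kind[1],
                 trial_type = d$trial_type[1],
                 mean_pe = mean(per), sd_pe = stats::sd(per),
                 stringsAsFactors = FALSE)
    }))
  rownames(pe_tab) <- NULL

  list(fsr_by_group_condition = fsr_tab,
       rt_by_group_condition_trialtype = rt_tab,
       switch_prolongation = delta_tab,
       pe_by_condition_trialtype = pe_tab)
}

pipeline_anovas <- function(fsr_used, config) {
  out <- list()
  dat <- fsr_used[!is.na(fsr_used$fsr), , drop = FALSE]
  dat$label <- droplevels(dat$label)
  complete <- names(which(tapply(dat$condition, dat$participant_id,
                                 function(z) length(unique(z))) ==
                            length(unique(dat$condition))))
  dat <- dat[dat$participant_id %in% complete, , drop = FALSE]

  if (nlevels(dat$label) >= 2L && length(unique(dat$condition)) >= 2L) {
    out$fsr_robust <- tryCatch(
      bw_trimmed_anova(fsr ~ label * condition, id = "participant_id",
                       data = dat, trim = config$trim),
      error = function(e) e$message)
    if (inherits(out$fsr_robust, "tswp_anova")) {
      es <- robust_effect_sizes(dat, config$trim)
      out$fsr_robust$effect_size <- es$value
      out$fsr_robust$es_kind <- es$kind
    }
  }

  out$fsr_by_group <- lapply(split(dat, dat$label), function(d) {
    if (length(unique(d$participant_id)) < 3L ||
        length(unique(d$condition)) < 2L) return(NULL)
    rm_anova_gg(d$fsr, d$participant_id, d$condition)
  })
  out
}

# Omnibus robust effect sizes attached to the FSR ANOVA rows: KMS for the
# between factor (participant FSRs averaged over conditions), mean absolute
# pairwise paired AKP for the within factor, and AKP of the
# difference-of-differences for the interaction when both factors have two
# levels (NA otherwise).
robust_effect_sizes <- function(dat, trim) {
  pmean <- stats::aggregate(fsr ~ participant_id + label, data = dat,
                            FUN = mean)
  kms <- tryCatch(kms_effect(split(pmean$fsr, pmean$label), trim = trim),
                  error = function(e) NA_real_)

  wide <- stats::reshape(dat[, c("participant_id", "condition", "fsr")],
                         idvar = "participant_id", timevar = "condition",
                         direction = "wide")
  cols <- setdiff(names(wide), "participant_id")
  pairs <- utils::combn(cols, 2L, simplify = FALSE)
  akps <- vapply(pairs, function(pr) {
    tryCatch(abs(akp_effect(wide[[pr[1]]], wide[[pr[2]]], trim = trim,
                            paired = TRUE)),
             error = function(e) NA_real_)
  }, numeric(1))
  akp_within <- mean(akps, na.rm = TRUE)

  akp_int <- NA_real_
  labs <- unique(dat$label)
  if (length(labs) == 2L && length(cols) == 2L) {
    d1 <- wide[[cols[1]]] - wide[[cols[2]]]
    grp <- pmean$label[match(wide$participant_id, pmean$participant_id)]
    akp_int <- tryCatch(akp_effect(d1[grp == labs[1]], d1[grp == labs[2]],
                                   trim = trim),
                        error = function(e) NA_real_)
  }
  list(value = c(abs(kms), akp_within, akp_int),
       kind = c("KMS", "AKP", "AKP"))
}

#' @export
print.tswp_analysis <- function(x, ...) {
  cat("TSWP analysis\n")
  cat(sprintf("  participants analysed: %d (QC-failed: %d, unclassifiable: %d)\n",
              length(unique(x$fsr$participant_id)) -
                length(x$excluded$unclassifiable),
              length(x$excluded$qc_failed),
              length(x$excluded$unclassifiable)))
  cat("  mode counts: ")
  print(table(x$classification$label))
  cat("\nFSR (trimmed mean, by mode x condition):\n")
  print(x$tables$fsr_by_group_condition, row.names = FALSE)
  invisible(x)
}

#' Summarise a TSWP analysis
#'
#' @param object a \code{tswp_analysis} object.
#' @param ... unused.
#' @return the object, invisibly, after printing classification counts,
#'   discard statistics, FSR and RT summary tables, switch prolongation and
#'   the ANOVA tables.
#' @export
summary.tswp_analysis <- function(object, ...) {
  print(object)
  cat("\nSwitch prolongation (Delta-hat, ms):\n")
  print(object$tables$switch_prolongation, row.names = FALSE)
  cat("\nDiscard rates:\n")
  print(object$discard)
  if (inherits(object$anovas$fsr_robust, "tswp_anova")) {
    cat("\n")
    print(object$anovas$fsr_robust)
  }
  invisible(object)
}

#' Plot FSRs by processing mode and condition
#'
#' Draws individual participant FSRs (jittered points) with the trimmed
#' mean and +/- one trimmed standard error per mode x condition.
#'
#' @param x a \code{tswp_analysis} object.
#' @param ... passed to \code{plot}.
#' @export
plot.tswp_analysis <- function(x, ...) {
  fsr <- x$fsr[!is.na(x$fsr$fsr) & x$fsr$label != "unclassifiable", ,
               drop = FALSE]
  conds <- unique(fsr$condition)
  labs <- levels(droplevels(fsr$label))
  xpos <- seq_along(conds)
  off <- seq(-0.25, 0.25, length.out = length(labs))
  plot(NULL, xlim = c(0.5, length(conds) + 0.5), ylim = c(0, 100),
       xaxt = "n", xlab = "condition", ylab = "FSR (%)", ...)
  graphics::axis(1, at = xpos, labels = conds)
  cols <- grDevices::gray(c(0.75, 0.5, 0.2))[seq_along(labs)]
  for (i in seq_along(labs)) {
    for (j in seq_along(conds)) {
      d <- fsr[fsr$label == labs[i] & fsr$condition == conds[j], ]
      if (!nrow(d)) next
      px <- xpos[j] + off[i] + stats::runif(nrow(d), -0.04, 0.04)
      graphics::points(px, 100 * d$fsr, col = cols[i], pch = 1, cex = 0.7)
      ts <- trimmed_stats(d$fsr, x$config$trim)
      graphics::segments(xpos[j] + off[i], 100 * (ts$mt - ts$se_trimmed),
                         xpos[j] + off[i], 100 * (ts$mt + ts$se_trimmed),
                         col = cols[i], lwd = 2)
      graphics::points(xpos[j] + off[i], 100 * ts$mt, pch = 16,
                       col = cols[i], cex = 1.2)
    }
  }
  graphics::legend("topleft", legend = labs, col = cols, pch = 16,
                   bty = "n")
  invisible(x)
}

#' Write all analysis tables and a run manifest to a directory
#'
#' @param x a \code{tswp_analysis} object.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_analysis <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, name) {
    utils::write.table(as.data.frame(d), file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  }
  wt(x$tables$fsr_by_group_condition, "fsr_by_group_condition.tsv")
  wt(x$tables$rt_by_group_condition_trialtype,
     "rt_by_group_condition_trialtype.tsv")
  wt(x$tables$switch_prolongation, "switch_prolongation.tsv")
  wt(x$tables$pe_by_condition_trialtype, "pe_by_condition_trialtype.tsv")
  wt(x$fsr[, setdiff(names(x$fsr), character())], "fsr_per_participant.tsv")
  wt(x$classification, "classification.tsv")
  wt(x$annotations, "fast_switch_annotations.tsv")
  wt(x$discard$per_participant, "discard_per_participant.tsv")
  wt(x$discard$summary, "discard_summary.tsv")
  wt(x$qc, "qc_report.tsv")
  if (inherits(x$anovas$fsr_robust, "tswp_anova")) {
    wt(x$anovas$fsr_robust, "anova_fsr_robust.tsv")
  }
  manifest <- c(
    sprintf("tswp version: %s",
            as.character(utils::packageVersion("tswp"))),
    sprintf("generated: (run manifest; fields below describe the config)"),
    sprintf("seed: %s", ifelse(is.null(x$config$seed), "NA",
                               x$config$seed)),
    sprintf("cutoff_ms: %g", x$config$cutoff_ms),
    sprintf("outlier_k: %g", x$config$outlier_k),
    sprintf("trim: %g", x$config$trim),
    sprintf("quantile_type: %g", x$config$quantile_type),
    sprintf("task_matching: %s", x$config$task_matching),
    sprintf("discard_convention: %s", x$config$discard_convention),
    sprintf("basis_condition: %s", x$config$basis_condition),
    sprintf("cutoffs: c1=%g c3=%g (%s)", x$cutoffs$c1, x$cutoffs$c3,
            x$cutoffs$provenance),
    sprintf("qc_failed: %s",
            paste(x$excluded$qc_failed, collapse = ",")),
    sprintf("unclassifiable: %s",
            paste(x$excluded$unclassifiable, collapse = ",")))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
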