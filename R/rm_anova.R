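# Classical repeated-measures ANOVA with Greenhouse-Geisser correction and
# partial eta squared, for the two designs the pipeline needs: one within
# factor, optionally crossed with one between factor.

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fits the classical (least-squares) repeated-measures ANOVA for a single
#' within-participants factor, optionally crossed with one
#' between-participants factor, via the standard split-plot sums of squares.
#' The Greenhouse-Geisser epsilon is estimated from the (pooled
#' within-group) covariance matrix of the within-profiles and applied to the
#' degrees of freedom of every within-participant effect; for a two-level
#' within factor sphericity is vacuous and epsilon is exactly 1. Partial eta
#' squared is \eqn{SS_{effect} / (SS_{effect} + SS_{error})} with the
#' error term of the effect's stratum.
#'
#' @param y numeric response.
#' @param subject participant identifier, same length as \code{y}.
#' @param within within-participants factor, same length as \code{y}; every
#'   participant must contribute each level exactly once.
#' @param between optional between-participants factor (constant within
#'   participant).
#' @return an object of class \code{tswp_anova}: one row per effect with F,
#'   df1, df2 (epsilon-adjusted for within effects), p (GG-corrected for
#'   within effects), \code{partial_eta_sq} and \code{epsilon}.
#' @export
rm_anova_gg <- function(y, subject, within, between = NULL) {
  subject <- as.factor(subject)
  within <- as.factor(within)
  k <- nlevels(within)
  if (k < 2L) stop("within factor needs at least 2 levels")

  # Complete, balanced within-profiles.
  tab <- table(subject, within)
  bad <- rownames(tab)[apply(tab, 1L, function(r) any(r != 1L))]
  if (length(bad)) {
    stop("incomplete within-profile for participant ", bad[1])
  }
  if (!is.null(between)) {
    between <- as.factor(between)
    if (any(tapply(as.integer(between), subject,
                   function(z) length(unique(z))) != 1L)) {
      stop("between factor must be constant within participant")
    }
  }

  ord <- order(subject, within)
  y <- y[ord]; subject <- droplevels(subject[ord]); within <- within[ord]
  if (!is.null(between)) between <- droplevels(between[ord])

  wide <- matrix(y, nrow = nlevels(subject), ncol = k, byrow = TRUE)
  subj_group <- if (is.null(between)) {
    factor(rep("all", nlevels(subject)))
  } else {
    factor(tapply(as.character(between), subject, `[`, 1L)[levels(subject)])
  }

  eps <- gg_epsilon(wide, subj_group)

  df <- data.frame(y = y, subject = subject, within = within)
  if (is.null(between)) {
    fit <- stats::aov(y ~ within + Error(subject), data = df)
  } else {
    df$between <- between
    fit <- stats::aov(y ~ between * within + Error(subject), data = df)
  }
  s <- summary(fit)
  # stratum 1: between-subject effects; stratum 2: within-subject effects
  st1 <- as.data.frame(s[[1]][[1]])
  st2 <- as.data.frame(s[[2]][[1]])
  clean <- function(d) {
    d$term <- trimws(rownames(d))
    names(d)[names(d) == "Sum Sq"] <- "ss"
    names(d)[names(d) == "Df"] <- "df"
    d
  }
  st1 <- clean(st1); st2 <- clean(st2)

  rows <- list()
  err1 <- st1[st1$term == "Residuals", , drop = FALSE]
  if (!is.null(between)) {
    eff <- st1[st1$term == "between", , drop = FALSE]
    if (eff$ss < sqrt(.Machine$double.eps)) {
      rows[[length(rows) + 1L]] <- data.frame(
        effect = "between", statistic = 0, df1 = eff$df, df2 = err1$df,
        p = 1, partial_eta_sq = 0, epsilon = NA_real_,
        stringsAsFactors = FALSE)
    } else {
      f <- (eff$ss / eff$df) / (err1$ss / err1$df)
      rows[[length(rows) + 1L]] <- data.frame(
        effect = "between",
        statistic = f,
        df1 = eff$df, df2 = err1$df,
        p = stats::pf(f, eff$df, err1$df, lower.tail = FALSE),
        partial_eta_sq = eff$ss / (eff$ss + err1$ss),
        epsilon = NA_real_, stringsAsFactors = FALSE)
    }
  }
  err2 <- st2[st2$term == "Residuals", , drop = FALSE]
  for (term in setdiff(st2$term, "Residuals")) {
    eff <- st2[st2$term == term, , drop = FALSE]
    if (eff$ss < sqrt(.Machine$double.eps)) {
      # constant data: no effect, nothing to reject
      rows[[length(rows) + 1L]] <- data.frame(
        effect = term, statistic = 0, df1 = eff$df * eps,
        df2 = err2$df * eps, p = 1, partial_eta_sq = 0,
        epsilon = eps, stringsAsFactors = FALSE)
      next
    }
    f <- (eff$ss / eff$df) / (err2$ss / err2$df)
    rows[[length(rows) + 1L]] <- data.frame(
      effect = term,
      statistic = f,
      df1 = eff$df * eps, df2 = err2$df * eps,
      p = stats::pf(f, eff$df * eps, err2$df * eps, lower.tail = FALSE),
      partial_eta_sq = eff$ss / (eff$ss + err2$ss),
      epsilon = eps, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "heading") <-
    "Repeated-measures ANOVA (Greenhouse-Geisser corrected)"
  class(out) <- c("tswp_anova", "data.frame")
  out
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# within-profiles (rows of `wide`, grouped by `grp`).
gg_epsilon <- function(wide, grp) {
  k <- ncol(wide)
  if (k == 2L) return(1)
  grp <- droplevels(as.factor(grp))
  pool <- matrix(0, k, k)
  dfree <- 0
  for (g in levels(grp)) {
    m <- wide[grp == g, , drop = FALSE]
    if (nrow(m) > 1L) {
      pool <- pool + (nrow(m) - 1L) * stats::cov(m)
      dfree <- dfree + nrow(m) - 1L
    }
  }
  if (dfree == 0) return(1)
  s <- pool / dfree
  cm <- contr_orth(k)
  a <- t(cm) %*% s %*% cm
  tr <- sum(diag(a))
  denom <- (k - 1) * sum(diag(a %*% a))
  if (denom <= 0) return(1)
  eps <- tr^2 / denom
  min(1, max(eps, 1 / (k - 1)))
}

# k x (k-1) orthonormal contrast matrix.
contr_orth <- function(k) {
  h <- stats::contr.helmert(k)
  sweep(h, 2L, sqrt(colSums(h^2)), "/")
}
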