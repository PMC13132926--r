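# Robust statistics: trimmed means, winsorized variances, the
# heteroscedastic between-by-within trimmed-means ANOVA (Johansen-type
# adjusted F), and the AKP / KMS robust effect sizes.

#' Trimmed-mean descriptive statistics
#'
#' Computes the g-times trimmed mean \eqn{M_t}, the arithmetic mean
#' \eqn{M_a}, the winsorized variance and the standard error of the trimmed
#' mean. Trimming drops \code{g = floor(n * trim)} observations from each
#' tail; winsorizing replaces them with the nearest retained order statistic.
#' The standard error is
#' \deqn{SE_t = \sqrt{s^2_w} / ((1 - 2\,trim)\sqrt{n}),}
#' with \eqn{s^2_w} the winsorized variance (n - 1 denominator).
#'
#' @param x numeric sample (NAs dropped).
#' @param trim trimming proportion per tail, in [0, 0.5).
#' @return an object of class \code{tswp_trimmed}: \code{mt}, \code{ma},
#'   \code{winsorized_variance}, \code{se_trimmed}, \code{n}, \code{g},
#'   \code{trim}.
#' @export
trimmed_stats <- function(x, trim = 0.2) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 1L) stop("empty sample")
  if (trim < 0 || trim >= 0.5) stop("trim must be in [0, 0.5)")
  g <- floor(n * trim)
  xs <- sort(x)
  mt <- mean(xs[(g + 1L):(n - g)])
  w <- winsorize(x, trim)
  wv <- if (n > 1L) stats::var(w) else 0
  structure(list(mt = mt, ma = mean(x), winsorized_variance = wv,
                 se_trimmed = sqrt(wv) / ((1 - 2 * trim) * sqrt(n)),
                 n = n, g = g, trim = trim),
            class = "tswp_trimmed")
}

#' @export
print.tswp_trimmed <- function(x, ...) {
  cat(sprintf("Mt = %.4g (Ma = %.4g), winsorized var = %.4g, SEt = %.4g, n = %d (g = %d per tail)\n",
              x$mt, x$ma, x$winsorized_variance, x$se_trimmed, x$n, x$g))
  invisible(x)
}

# Convenience accessors used throughout the pipeline.
trimmed_mean <- function(x, trim = 0.2) trimmed_stats(x, trim)$mt

winsorize <- function(x, trim = 0.2) {
  n <- length(x)
  g <- floor(n * trim)
  if (g == 0L) return(x)
  xs <- sort(x)
  pmin(pmax(x, xs[g + 1L]), xs[n - g])
}

win_var <- function(x, trim = 0.2) stats::var(winsorize(x, trim))

# Winsorized covariance matrix of the columns of m (n x K), n - 1 denominator.
wincov <- function(m, trim = 0.2) {
  stats::cov(apply(m, 2L, winsorize, trim = trim))
}

# Winsorized variance of the standard normal for a given per-tail trimming
# proportion; the AKP scaling constant is its square root (~0.6419 at 20%).
normal_win_var <- function(trim) {
  if (trim == 0) return(1)
  z <- stats::qnorm(1 - trim)
  (1 - 2 * trim) - 2 * z * stats::dnorm(z) + 2 * trim * z^2
}

#' Heteroscedastic between-by-within ANOVA on trimmed means
#'
#' Tests the between-participants main effect, the within-participants main
#' effect and their interaction on trimmed means, without assuming equal
#' variances or equal group sizes. Per group, the trimmed cell means and the
#' winsorized covariance matrix of the within-profiles are computed; each
#' contrast is then tested with a Johansen-type statistic referred to an
#' adjusted F distribution whose denominator degrees of freedom are
#' estimated from the winsorized variance structure. With \code{trim = 0}
#' and a single within level this reduces to Welch's heteroscedastic test.
#'
#' @param formula \code{response ~ between * within} (order free; the factor
#'   that is constant within each participant is taken as the between
#'   factor).
#' @param id bare name or character name of the participant identifier
#'   column in \code{data}.
#' @param data a data.frame in long format, one row per participant x within
#'   level, complete profiles.
#' @param trim trimming proportion per tail (default 0.2).
#' @return an object of class \code{tswp_anova}: a data.frame with one row
#'   per effect (statistic, df1, df2, p).
#' @export
bw_trimmed_anova <- function(formula, id, data, trim = 0.2) {
  vars <- all.vars(formula)
  if (length(vars) != 3L) stop("formula must be response ~ factorA * factorB")
  idname <- if (is.character(substitute(id))) id else deparse(substitute(id))
  if (!idname %in% names(data)) stop("id column '", idname, "' not in data")
  y <- data[[vars[1]]]
  fa <- as.factor(data[[vars[2]]])
  fb <- as.factor(data[[vars[3]]])
  pid <- as.factor(data[[idname]])

  a_between <- all(tapply(as.integer(fa), pid,
                          function(z) length(unique(z))) == 1L)
  b_between <- all(tapply(as.integer(fb), pid,
                          function(z) length(unique(z))) == 1L)
  if (a_between && b_between) {
    # a single-level within factor is constant too; the grouping factor is
    # the one that actually varies
    if (nlevels(droplevels(fb)) == 1L) b_between <- FALSE
    else if (nlevels(droplevels(fa)) == 1L) a_between <- FALSE
  }
  if (a_between && !b_between) {
    grp <- fa; wth <- fb
    names_bw <- c(vars[2], vars[3])
  } else if (b_between && !a_between) {
    grp <- fb; wth <- fa
    names_bw <- c(vars[3], vars[2])
  } else {
    stop("exactly one factor must be constant within each participant")
  }

  fit <- bwtrim_engine(y, grp, wth, pid, trim)
  out <- data.frame(
    effect = c(names_bw[1], names_bw[2],
               paste(names_bw[1], names_bw[2], sep = ":")),
    statistic = c(fit$A$stat, fit$B$stat, fit$AB$stat),
    df1 = c(fit$A$df1, fit$B$df1, fit$AB$df1),
    df2 = c(fit$A$df2, fit$B$df2, fit$AB$df2),
    p = c(fit$A$p, fit$B$p, fit$AB$p),
    stringsAsFactors = FALSE)
  attr(out, "trim") <- trim
  attr(out, "heading") <-
    sprintf("Between-by-within ANOVA on %.0f%% trimmed means (adjusted F)",
            100 * trim)
  class(out) <- c("tswp_anova", "data.frame")
  out
}

# Core engine: J groups x K within levels (K = 1 gives the between test
# only). Builds trimmed means and per-group scaled winsorized covariance
# matrices, then applies the Johansen-type test per contrast.
bwtrim_engine <- function(y, grp, wth, pid, trim) {
  grp <- droplevels(as.factor(grp))
  wth <- droplevels(as.factor(wth))
  J <- nlevels(grp); K <- nlevels(wth)
  if (J < 2L) stop("between factor needs at least 2 groups")

  tmeans <- numeric(0)
  vlist <- list()
  h <- numeric(J)
  for (j in seq_len(J)) {
    sel <- grp == levels(grp)[j]
    pj <- droplevels(as.factor(pid[sel]))
    nj <- nlevels(pj)
    m <- matrix(NA_real_, nj, K)
    rows <- split(seq_along(which(sel)), pj)
    ysel <- y[sel]; wsel <- wth[sel]
    for (i in seq_len(nj)) {
      r <- rows[[i]]
      if (length(r) != K || anyDuplicated(as.integer(wsel[r]))) {
        stop("incomplete within-profile for participant ",
             names(rows)[i])
      }
      m[i, as.integer(wsel[r])] <- ysel[r]
    }
    g <- floor(trim * nj)
    h[j] <- nj - 2 * g
    if (h[j] < 2) stop("insufficient per-group data after trimming (group '",
                       levels(grp)[j], "')")
    tmeans <- c(tmeans, apply(m, 2L, trimmed_mean, trim = trim))
    vlist[[j]] <- wincov(m, trim) * (nj - 1) / (h[j] * (h[j] - 1))
  }
  p <- J * K
  v <- matrix(0, p, p)
  for (j in seq_len(J)) {
    sel <- ((j - 1) * K + 1):(j * K)
    v[sel, sel] <- vlist[[j]]
  }

  cj <- diff_contrasts(J)
  ik <- matrix(1, 1, K)
  ij <- matrix(1, 1, J)
  res <- list(A = johansen_test(kronecker(cj, ik), tmeans, v, h, J, K))
  if (K > 1L) {
    ck <- diff_contrasts(K)
    res$B <- johansen_test(kronecker(ij, ck), tmeans, v, h, J, K)
    res$AB <- johansen_test(kronecker(cj, ck), tmeans, v, h, J, K)
  } else {
    res$B <- res$AB <- list(stat = NA_real_, df1 = NA_real_,
                            df2 = NA_real_, p = NA_real_)
  }
  res
}

# (m - 1) x m successive-difference contrast matrix.
diff_contrasts <- function(m) {
  cm <- matrix(0, m - 1L, m)
  for (i in seq_len(m - 1L)) {
    cm[i, i] <- 1
    cm[i, i + 1L] <- -1
  }
  cm
}

# Johansen-type test of C mu = 0 for a block-diagonal covariance v of the
# stacked trimmed means, with per-group effective sample sizes h.
johansen_test <- function(cmat, tmeans, v, h, J, K) {
  yvec <- matrix(tmeans, ncol = 1L)
  cvc <- cmat %*% v %*% t(cmat)
  invc <- tryCatch(solve(cvc), error = function(e) NULL)
  if (is.null(invc)) {
    # degenerate (e.g. constant) data: a null contrast is simply not
    # rejected, anything else cannot be tested
    if (max(abs(cmat %*% yvec)) < sqrt(.Machine$double.eps)) {
      return(list(stat = 0, df1 = nrow(cmat), df2 = NA_real_, p = 1))
    }
    stop("singular covariance structure in trimmed-means ANOVA")
  }
  q <- drop(t(yvec) %*% t(cmat) %*% invc %*% cmat %*% yvec)
  a <- 0
  for (j in seq_len(J)) {
    sel <- ((j - 1) * K + 1):(j * K)
    qj <- matrix(0, J * K, J * K)
    qj[sel, sel] <- diag(1, K)
    r <- v %*% t(cmat) %*% invc %*% cmat %*% qj
    a <- a + (sum(diag(r %*% r)) + sum(diag(r))^2) / (h[j] - 1)
  }
  a <- a / 2
  df1 <- nrow(cmat)
  df2 <- df1 * (df1 + 2) / (3 * a)
  cval <- df1 + 2 * a - 6 * a / (df1 + 2)
  stat <- q / cval
  list(stat = stat, df1 = df1, df2 = df2,
       p = stats::pf(stat, df1, df2, lower.tail = FALSE))
}

#' AKP robust standardized effect size
#'
#' The Algina-Keselman-Penfield robust analogue of Cohen's d: the difference
#' in trimmed means divided by a (pooled) winsorized standard deviation and
#' rescaled so that, under normality, the measure estimates the usual
#' standardized mean difference. At 20\% trimming the scaling constant is
#' \eqn{\sqrt{0.4121} \approx 0.642}; at \code{trim = 0} it is 1 and the
#' measure reduces to Cohen's d with pooled SD. Interpretation anchors 0.20
#' / 0.50 / 0.80 (small / medium / large) carry over from Cohen's d.
#'
#' @param x,y the two samples. With \code{paired = TRUE} they must have
#'   equal length and the effect is computed on the difference scores.
#' @param trim trimming proportion per tail (default 0.2).
#' @param paired treat \code{x} and \code{y} as paired (within-participant)?
#' @return the signed effect size (sign follows \code{x - y}).
#' @export
akp_effect <- function(x, y, trim = 0.2, paired = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  const <- sqrt(normal_win_var(trim))
  if (paired) {
    if (length(x) != length(y)) stop("paired samples must have equal length")
    d <- x - y
    sw <- win_var(d, trim)
    if (sw == 0) stop("zero winsorized variance")
    return(const * (trimmed_mean(d, trim)) / sqrt(sw))
  }
  n1 <- length(x); n2 <- length(y)
  sw <- ((n1 - 1) * win_var(x, trim) + (n2 - 1) * win_var(y, trim)) /
    (n1 + n2 - 2)
  if (sw == 0) stop("zero winsorized variance")
  const * (trimmed_mean(x, trim) - trimmed_mean(y, trim)) / sqrt(sw)
}

#' KMS heteroscedastic between-group effect size
#'
#' A variance-weighted standardized separation for independent groups that
#' does not assume equal variances. For two groups with means \eqn{m_1,
#' m_2}, variances \eqn{v_1, v_2} and proportions \eqn{q_j = n_j / N},
#' \deqn{\delta = (m_1 - m_2) / \sqrt{q_2 v_1 + q_1 v_2},}
#' which reduces to Cohen's d under equal variances. For more than two
#' groups the omnibus magnitude is the square root of the weighted
#' between-group variance of the means over the weighted mean variance.
#' With \code{trim > 0} the means are trimmed means and the variances are
#' winsorized variances rescaled by the normal-consistency constant, making
#' the measure a robust heteroscedastic analogue of Cohen's d.
#'
#' @param groups a list of numeric samples (at least two).
#' @param trim trimming proportion per tail (default 0: classical means and
#'   variances).
#' @return for two groups, the signed effect (sign follows group 1 minus
#'   group 2); for more, a nonnegative omnibus magnitude.
#' @export
kms_effect <- function(groups, trim = 0) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("groups must be a list of at least 2 samples")
  }
  groups <- lapply(groups, function(g) g[!is.na(g)])
  n <- vapply(groups, length, numeric(1))
  if (any(n < 2L)) stop("each group needs at least 2 observations")
  q <- n / sum(n)
  if (trim == 0) {
    m <- vapply(groups, mean, numeric(1))
    v <- vapply(groups, stats::var, numeric(1))
  } else {
    m <- vapply(groups, trimmed_mean, numeric(1), trim = trim)
    v <- vapply(groups, win_var, numeric(1), trim = trim) /
      normal_win_var(trim)
  }
  if (all(v == 0)) stop("degenerate variance in all groups")
  if (length(groups) == 2L) {
    denom <- q[2] * v[1] + q[1] * v[2]
    return((m[1] - m[2]) / sqrt(denom))
  }
  mbar <- sum(q * m)
  sqrt(sum(q * (m - mbar)^2) / sum(q * v))
}

#' @export
print.tswp_anova <- function(x, digits = 4, ...) {
  h <- attr(x, "heading")
  if (!is.null(h)) cat(h, "\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}
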