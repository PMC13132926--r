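# Robust statistics: trimmed means, the between-by-within trimmed ANOVA,
# AKP / KMS effect sizes and the classical RM ANOVA with GG correction.

test_that("trimmed mean and winsorized variance match hand computation", {
  ts <- trimmed_stats(1:10, trim = 0.2)
  expect_equal(ts$g, 2L)
  expect_equal(ts$mt, mean(3:8))   # 5.5
  expect_equal(ts$mt, 5.5)

  # winsorized sample of 1..5 at 20% is [2,2,3,4,4]: variance 4/4 = 1
  ts2 <- trimmed_stats(1:5, trim = 0.2)
  expect_equal(ts2$winsorized_variance, 1.0)
  expect_equal(ts2$se_trimmed, sqrt(1) / (0.6 * sqrt(5)))

  # constants and the trim = 0 reduction
  expect_equal(trimmed_stats(rep(7, 4))$mt, 7)
  expect_equal(trimmed_stats(rep(7, 4))$winsorized_variance, 0)
  x <- rnorm(17)
  t0 <- trimmed_stats(x, trim = 0)
  expect_equal(t0$mt, t0$ma)
  expect_equal(t0$mt, mean(x))
  expect_equal(t0$winsorized_variance, var(x))

  expect_error(trimmed_stats(numeric(0)), "empty")
  expect_error(trimmed_stats(1:5, trim = 0.5), "trim")
})

test_that("constant cells give zero statistics in the robust ANOVA", {
  d <- expand.grid(id = paste0("s", 1:10), cond = c("a", "b"))
  d$grp <- ifelse(d$id %in% paste0("s", 1:5), "g1", "g2")
  d$y <- 5
  out <- bw_trimmed_anova(y ~ grp * cond, id = "id", data = d, trim = 0.2)
  expect_equal(out$statistic, c(0, 0, 0))
})

test_that("with trim 0 and one within level the test is Welch's t^2", {
  set.seed(4)
  g1 <- rnorm(12, 0, 1)
  g2 <- rnorm(20, 0.5, 2)
  d <- data.frame(id = paste0("s", 1:32), y = c(g1, g2),
                  grp = rep(c("g1", "g2"), c(12, 20)), w = "only")
  out <- bw_trimmed_anova(y ~ grp * w, id = "id", data = d, trim = 0)
  wt <- t.test(g1, g2, var.equal = FALSE)
  expect_equal(out$statistic[1], unname(wt$statistic)^2, tolerance = 1e-10)
  expect_equal(out$df2[1], unname(wt$parameter), tolerance = 1e-8)
})

test_that("groups too small to trim are an error", {
  d <- expand.grid(id = paste0("s", 1:11), cond = c("a", "b"))
  d$grp <- ifelse(d$id %in% paste0("s", 1:5), "g1", "g2")
  d$y <- rnorm(nrow(d))
  # trimming 45% from each tail of 5 leaves a single value
  expect_error(bw_trimmed_anova(y ~ grp * cond, id = "id", data = d,
                                trim = 0.45),
               "insufficient per-group data")
})

test_that("robust ANOVA is invariant to participant order", {
  set.seed(9)
  d <- expand.grid(id = sprintf("s%02d", 1:24), cond = c("a", "b", "c"))
  d$grp <- rep(c("g1", "g2"), c(10, 14))[match(d$id, unique(d$id))]
  d$y <- rnorm(nrow(d)) + as.integer(d$cond == "b") * 0.3
  out1 <- bw_trimmed_anova(y ~ grp * cond, id = "id", data = d)
  d2 <- d[sample(nrow(d)), ]
  out2 <- bw_trimmed_anova(y ~ grp * cond, id = "id", data = d2)
  expect_equal(out1$statistic, out2$statistic, tolerance = 1e-12)
  expect_equal(out1$p, out2$p, tolerance = 1e-12)
})

test_that("AKP effect size carries the 20% trimming constant", {
  set.seed(2)
  x <- rnorm(40)
  y <- x - sqrt(win_var(x, 0.2))   # shift by one winsorized SD
  eff <- akp_effect(x, y, trim = 0.2)
  expect_equal(eff, sqrt(tswp:::normal_win_var(0.2)), tolerance = 1e-10)
  expect_equal(eff, 0.642, tolerance = 1e-3)

  expect_equal(akp_effect(x, x), 0)
  # trim 0 reduces to Cohen's d with pooled SD
  z <- rnorm(25, 1, 1)
  d_pool <- sqrt(((39) * var(x) + 24 * var(z)) / 63)
  expect_equal(akp_effect(x, z, trim = 0),
               (mean(x) - mean(z)) / d_pool, tolerance = 1e-10)
  expect_error(akp_effect(rep(1, 10), rep(1, 10)), "zero winsorized")
})

test_that("KMS effect size matches its defining formula", {
  expect_equal(kms_effect(list(1:10, 1:10)), 0)

  # independent evaluation of the published variance-weighted form
  set.seed(5)
  a <- rnorm(15, 0, 1.5)
  b <- rnorm(30, 1, 0.5)
  q <- c(15, 30) / 45
  expected <- (mean(a) - mean(b)) / sqrt(q[2] * var(a) + q[1] * var(b))
  expect_equal(kms_effect(list(a, b)), expected, tolerance = 1e-12)

  # equal variances, gap of one common SD -> Cohen's d of 1 in magnitude
  x <- rnorm(50); x <- (x - mean(x)) / sd(x)
  expect_equal(abs(kms_effect(list(x + 1, x))), 1, tolerance = 1e-10)

  # invariance under common affine rescaling
  g <- list(rnorm(12), rnorm(12, 0.7), rnorm(12, 1.2))
  expect_equal(kms_effect(g), kms_effect(lapply(g, function(v) 3 * v + 2)),
               tolerance = 1e-12)
  expect_error(kms_effect(list(rep(1, 5), rep(2, 5))), "degenerate")
})

test_that("RM ANOVA matches a manual sums-of-squares oracle", {
  # 4 participants x 3 levels, additive structure: the within effect
  # saturates the non-subject variance
  y <- c(1, 2, 3, 2, 3, 4, 1, 2, 3, 2, 3, 4)
  subj <- rep(paste0("s", 1:4), each = 3)
  w <- rep(c("l1", "l2", "l3"), 4)
  out <- rm_anova_gg(y, subj, w)
  # manual decomposition: SS_within = 8, SS_subject = 3, SS_error = 0
  grand <- mean(y)
  ss_w <- 4 * sum((tapply(y, w, mean) - grand)^2)
  ss_s <- 3 * sum((tapply(y, subj, mean) - grand)^2)
  ss_tot <- sum((y - grand)^2)
  expect_equal(ss_w, 8)
  expect_equal(ss_tot - ss_s - ss_w, 0)
  # the error SS is zero up to floating point, so F blows up
  expect_gt(out$statistic, 1e6)
  expect_equal(out$partial_eta_sq, 1, tolerance = 1e-10)

  # a noisy table against an independent in-test decomposition
  set.seed(12)
  y2 <- rnorm(12) + rep(c(0, 0.5, 1), 4)
  out2 <- rm_anova_gg(y2, subj, w)
  ss_w2 <- 4 * sum((tapply(y2, w, mean) - mean(y2))^2)
  ss_s2 <- 3 * sum((tapply(y2, subj, mean) - mean(y2))^2)
  ss_e2 <- sum((y2 - mean(y2))^2) - ss_w2 - ss_s2
  f_manual <- (ss_w2 / 2) / (ss_e2 / 6)
  expect_equal(out2$statistic, f_manual, tolerance = 1e-10)
  expect_equal(out2$partial_eta_sq, ss_w2 / (ss_w2 + ss_e2),
               tolerance = 1e-10)
})

test_that("GG epsilon is exactly 1 for two within levels", {
  set.seed(3)
  y <- rnorm(20)
  out <- rm_anova_gg(y, rep(paste0("s", 1:10), each = 2),
                     rep(c("a", "b"), 10))
  expect_equal(out$epsilon, 1)
})

test_that("reported p values are consistent with the adjusted df", {
  set.seed(8)
  y <- rnorm(30)
  subj <- rep(paste0("s", 1:10), each = 3)
  w <- rep(c("a", "b", "c"), 10)
  out <- rm_anova_gg(y, subj, w)
  expect_true(out$epsilon <= 1 && out$epsilon >= 0.5)
  expect_equal(out$df1, 2 * out$epsilon)
  expect_equal(out$p, pf(out$statistic, out$df1, out$df2,
                         lower.tail = FALSE))
})

test_that("constant data give F = 0 and zero effect size", {
  y <- rep(4, 12)
  out <- rm_anova_gg(y, rep(paste0("s", 1:4), each = 3),
                     rep(c("a", "b", "c"), 4))
  expect_equal(out$statistic, 0)
  expect_equal(out$partial_eta_sq, 0)
})

test_that("mixed RM ANOVA reproduces the split-plot decomposition", {
  set.seed(15)
  n1 <- 5; n2 <- 7
  subj <- rep(sprintf("s%02d", 1:(n1 + n2)), each = 3)
  grp <- rep(rep(c("g1", "g2"), c(n1, n2)), each = 3)
  w <- rep(c("a", "b", "c"), n1 + n2)
  y <- rnorm(length(subj)) + as.integer(grp == "g2") * 0.8 +
    rep(c(0, 0.4, 0.9), n1 + n2)
  out <- rm_anova_gg(y, subj, w, between = grp)
  expect_setequal(out$effect, c("between", "within", "between:within"))
  # between test against the classical subject-means one-way ANOVA
  sm <- tapply(y, subj, mean)
  sg <- tapply(grp, subj, `[`, 1)
  a <- anova(lm(sm ~ sg))
  expect_equal(out$statistic[out$effect == "between"], a$`F value`[1],
               tolerance = 1e-10)
  # incomplete profile errors name the participant
  expect_error(rm_anova_gg(y[-1], subj[-1], w[-1], between = grp[-1]),
               "s01")
})
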