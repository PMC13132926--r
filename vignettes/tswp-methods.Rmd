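---
title: "Fast-switch analysis of task switching with preview: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fast-switch analysis of task switching with preview}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tswp)
```

## The paradigm and the quantity being estimated

In task switching with preview (TSWP), two classification tasks — letters
as vowel/consonant, digits as odd/even — alternate in a predictable
AAABBB sequence. Each three-trial run therefore contains a *switch* trial
(position 1), a *pure-repetition* trial (position 2) and a *pre-switch*
trial (position 3). Both task stimuli are on screen together; depending on
the condition, the stimulus of the not-yet-relevant task is visible in
advance (the *preview*) for all, some, or exactly one of the three
positions. Blocks run for a fixed time (e.g. 120 s), so the number of
trials per block is endogenous: faster participants produce more trials.

People differ systematically in whether they exploit the preview. Serial
processors ignore it and pay a large switch cost; overlapping processors
preprocess it while still working on the current task and then produce
switch responses as fast as easy single-task responses. The pipeline's
central statistic is the **fast-switch rate (FSR)**: the proportion of a
participant's correct switch trials that qualify as *fast switches*. A
switch qualifies if

1. its RT is **at least as fast as** (inclusive, `<=`) the first quartile
   of the participant's correct single-task responses in the *upcoming*
   single-task block(s) of the same experimental run (single-task blocks
   are repeated after each switching block precisely so that this
   reference tracks practice effects), and
2. the speed was not bought by **compensatory prolongation** of the three
   same-task trials immediately preceding the switch. The total response
   time of that run (the *interval*) is compared with the mean interval
   preceding the participant's non-candidate switches in the same
   condition; a candidate stays fast only if
   `interval − baseline ≤ mean_single_RT − switch_RT`.

Participants are then classified from their full-preview FSR against
cutoffs anchored to a reference distribution of FSRs obtained without a
usable preview: *serial* below the reference mean + 1 SD,
*semi-overlapper* up to mean + 3 SD, *overlapper* above. The package never
hard-codes numeric cutoffs; they must be supplied explicitly or derived
from a reference sample (`derive_cutoffs()`), because published cutoffs
live with the reference datasets, not in this package.

## The exclusion cascade

Preprocessing applies, in order and each in a single pass:

* **Hard cutoff** — RTs above 5000 ms are flagged (`rt > 5000`, strict);
  the paradigm has no response deadline, so occasional extreme pauses
  occur.
* **Error removal for RT analyses** — only correct trials enter RT
  statistics; errors are kept for error-rate summaries.
* **2-SD trimming** — within each cell of trial type × experimental
  block (per participant), correct unflagged trials deviating more than
  2 sample SDs (n − 1 denominator) from the cell mean are flagged,
  strictly, without iterative re-trimming. Cells with fewer than 3
  eligible trials are left alone: an SD from one or two values carries no
  information. This conservative rule is the package's choice; it only
  matters for pathologically small cells.
* **Participant QC** — a participant is retained if every block of every
  condition has an error rate strictly below 20% and every task ×
  condition cell holds at least 40 trials.

Discard rates are reported under two accounting conventions, because the
denominator of published discard percentages is ambiguous: convention A
counts over-long trials plus 2-SD outliers over all trials of a
condition; convention B additionally counts error trials. A is the
default and both columns are always present in the per-participant table.

Warm-up switching blocks (the 60-s block opening each condition run,
which exists to prepare participants) and practice-phase trials are
excluded from all analyses by default; both exclusions are configuration
switches, since their analytic fate is a genuinely open choice.

## Numerical conventions in the fast-switch scorer

* **Quantile rule**: the threshold is the linear-interpolation quantile
  (type 7). The convention is configuration-exposed because candidate
  counts can be threshold-sensitive at small single-task samples.
* **Inclusive candidacy**: "at least as fast" means `<=`.
* **Task matching**: by default the threshold for a switch into the digit
  task comes from digit single-task responses (`task_matched`); a
  `pooled` policy is available.
* **Intervals**: the preceding interval sums all three responses,
  including error responses — it measures time spent, not accuracy.
  Intervals containing an over-long trial are discarded entirely. The
  first switch of a block has no complete preceding run; its compensation
  check is skipped and the RT criterion alone decides. Whether the
  baseline should also exclude intervals that contain error responses is
  not determined by the design; the package includes them.
* **Baseline scope**: non-candidate intervals are pooled per participant
  × condition (across that condition's analysed switching blocks), the
  widest scope consistent with the procedure, maximising baseline
  stability.
* **Single pass**: candidates that fail the compensation check do not
  re-enter the baseline. A fixed-point iteration would change very little
  and has no basis in the procedure.
* **Benefit term**: "the average single-task RT" is taken as the mean of
  all eligible single-task responses (not of the fastest quartile); this
  is configuration-visible through the annotation table, which carries
  both the threshold and the reference mean.
* **Classification boundaries**: lower-inclusive at c1, and exactly c3 is
  an overlapper. A participant with no correct switches has no FSR and is
  reported `unclassifiable`, never silently zero or serial.

## Robust statistics

Group sizes in mode-classified designs are naturally unbalanced and FSR
distributions are skewed and heteroscedastic, so the inferential layer
uses 20% trimmed means throughout:

* `trimmed_stats()` trims `g = floor(n · trim)` observations per tail;
  the winsorized variance uses the n − 1 denominator and the standard
  error of the trimmed mean is `sqrt(s²_w) / ((1 − 2·trim)·sqrt(n))`.
* `bw_trimmed_anova()` is a heteroscedastic between × within ANOVA on
  trimmed means: per group it computes the winsorized covariance matrix
  of the within-profiles, scales it by `(n−1)/(h(h−1))` with
  `h = n − 2g`, and tests each contrast with a Johansen-type statistic
  referred to an adjusted F distribution with estimated denominator
  degrees of freedom. With `trim = 0` and a single within level the
  between test reduces exactly to Welch's t²; its null calibration is
  checked by simulation in the test suite (2000 replicates, unequal group
  sizes, 4:1 variance ratio).
* `akp_effect()` is the robust analogue of Cohen's d: trimmed-mean
  difference over a pooled winsorized SD, rescaled by the winsorized SD
  of the standard normal at the same trimming (≈ 0.642 at 20%), so that
  it estimates the classical standardized difference under normality;
  interpretation anchors 0.20/0.50/0.80 carry over. A paired variant
  operates on difference scores.
* `kms_effect()` is a heteroscedastic between-group effect size: the mean
  difference standardized by the sample-size-weighted variance mix
  `q₂v₁ + q₁v₂`, which reduces to Cohen's d under equal variances; for
  more than two groups an omnibus magnitude (weighted between-group
  variance of means over weighted mean variance) is returned. Published
  variants of these measures differ in pooling details; the package
  documents its choice here rather than claiming numeric equivalence to
  any particular implementation.
* `rm_anova_gg()` covers the classical designs the pipeline needs (one
  within factor, optionally one between factor): least-squares split-plot
  sums of squares, Greenhouse–Geisser epsilon from the pooled
  within-group covariance applied to all within-effect degrees of
  freedom (exactly 1 for two levels), and partial η² per effect. The
  omnibus effect sizes attached to the robust FSR table are the package's
  own conventions: KMS on condition-averaged FSRs for the between factor,
  the mean absolute pairwise paired AKP for the within factor, and an
  AKP of the difference-of-differences when both factors are two-level.

## The synthetic cohort generator

The generator is a *measurement-level emulator*: it reproduces the
statistical structure the pipeline assumes — fixed-duration blocks,
AAABBB alternation, preview visibility per condition, mode-dependent fast
switches with optional compensatory prolongation — without any
process-level model of cognition (no evidence accumulation, no task-set
dynamics). Design and defaults:

* **Block plan** (per condition run): one 60-s warm-up switching block,
  two 120-s switching blocks, one 60-s single-task block per task.
  Condition order follows a Williams (balanced Latin square) design; in
  the preview-position experiment the full-preview condition always comes
  first because it is the classification basis. Order effects are not
  modelled in the RTs; the ordering exists to exercise the data model.
* **Fixed-time semantics**: trials are drawn until cumulative RT reaches
  the block duration and the boundary-crossing trial is kept — any
  consistent rule works, this one is simplest.
* **RT model**: single-task RTs are lognormal
  (`meanlog = log(650)`, `sdlog = 0.12`, i.e. ≈ 654 ms ± 79 ms);
  repetition and pre-switch trials add 30 and 50 ms. Non-prepared switch
  trials add a gamma-distributed switch cost — mean 450 ms (SD 330) for
  serial, 220 (200) for semi-overlapping, 60 (60) for overlapping
  processors — reflecting both the size ordering of observed switch
  costs and the well-known trial-to-trial volatility of residual costs.
* **Preview use**: a switch can be prepared only if the preview was
  visible during the preceding run; the Bernoulli success probability is
  taken at the *latest* visible position, matching the empirical finding
  that use peaks immediately before the switch and keeping the
  preview-length conditions generable from the same parameters. Prepared
  switch RTs are drawn from the fast floor of the single-task
  distribution (quantile uniform on (0, 0.01)): fast switches in real
  data are *extremely* fast, and a floor draw is what survives both the
  quartile criterion and the compensation check the way empirical fast
  switches do. With probability 0.10 a prepared switch costs 100 ms of
  compensatory time spread over the three preceding trials.
* **Individual differences**: per-mode position-3 use probabilities
  average 0.02 (serial), 0.15 (semi-overlapper) and 0.45 (overlapper).
  At cohort level they are assigned from deterministic quantile grids
  (stratified sampling), so every cohort is representative of its modes
  whatever its size; standalone participant simulation draws randomly
  instead. The serial grid is mostly exact zeros with a small number of
  occasional users (0.04 and 0.28 in a group of 16) — mirroring the long
  right tail of empirical no-preview reference distributions, which is
  what makes mean + 1/+ 3 SD cutoffs meaningful at all. The calibration
  of these constants was fixed once, against the realism bands the
  design implies (single-task trial counts per condition in [140, 220],
  switching counts in [260, 380], discard rates of a few percent, QC
  pass under defaults), and then frozen.
* **Errors** are independent Bernoulli (4.5%), matching the low error
  regime of speeded classification tasks.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: sequential dependencies and fatigue or practice
drifts within a session, speed–accuracy coupling (errors are independent
of RT), genuinely skew-heavy single-trial outliers, condition-order
carry-over effects, and any cognitive mechanism behind preview use.
Parameter-recovery results certify the *pipeline*, not any claim about
human data.

## Analysis defaults and problem sizes

`tswp_analysis()` runs QC → flags → references → annotation → FSR →
classification (basis: full-preview condition) → summary tables (20%
trimmed means with trimmed SEs, matching how such results are plotted) →
the robust mode × condition ANOVA on FSRs plus exploratory classical
one-way repeated-measures ANOVAs per mode group. The switch prolongation
Δ̂ is reported under two contrasts, because "the other trial types" is
ambiguous: against the mean of single/repetition/pre-switch trimmed means
(default) and against the switching-block trial types only; both columns
are exported and the two are mutually reproducible from the RT table.

The test suite exercises the full pipeline on a reference cohort of 16
participants per mode with the complete block plan (≈ 112,000 trials) and
uses shortened blocks (30–90 s) elsewhere; the ANOVA calibration uses
2000 null replicates. These sizes keep the whole suite at desk scale
while leaving Monte-Carlo bands comfortably interpretable. The
position-selectivity check is asserted on the overlapper subgroup — the
group for which preview use is defined — and additionally on the pooled
cohort ordering.

## Known limitations

* The compensation correction is intentionally conservative: with noisy
  intervals it declassifies a small fraction of genuinely prepared
  switches (visible in the generator's recovery error of a few
  percentage points, always negative).
* `bw_trimmed_anova()` covers exactly one between and one within factor;
  higher-order robust designs need different machinery and are out of
  scope.
* Classification accuracy against ground truth depends on the reference
  distribution supplied to `derive_cutoffs()`; with a serial reference
  lacking its empirical long right tail, the +3 SD cutoff collapses into
  the semi-overlapper range. This mirrors the method's real dependence on
  an adequate no-preview reference dataset.
* Reproducing published numbers from a deposited dataset requires that
  dataset and its original classification cutoffs; the package supplies
  the column-mapping ingestion and configurable cutoffs to do so, and its
  tests verify that externally formatted files reproduce the native
  analysis exactly on synthetic stand-ins.
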