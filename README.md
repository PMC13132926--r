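# tswp

Analysis of **task switching with preview (TSWP)** experiments in R.

In the TSWP paradigm, two speeded classification tasks (letters as
vowel/consonant, digits as odd/even) alternate in a predictable AAABBB
sequence within fixed-duration blocks, and the upcoming task's stimulus can
be visible in advance as a *preview*. People differ reliably in whether they
exploit it: *serial processors* ignore the preview and pay a large switch
cost, *overlapping processors* preprocess it in parallel with the ongoing
task and produce switch responses as fast as easy single-task responses,
*semi-overlappers* do so occasionally. The package is for researchers who
run such experiments (preview-length or preview-position designs) and need
the full trial-log-to-statistics pipeline, and for methodologists who want
to study the behaviour of the fast-switch metric itself on synthetic data.

## The statistic at the core

For participant *i* in condition *c*, the **fast-switch rate** is

FSR<sub>ic</sub> = (# correct fast switches) / (# correct switch trials),

where a correct switch trial is *fast* iff

1. RT ≤ Q<sub>.25</sub>(single-task RTs of the upcoming single-task block),
   the first RT quartile of correct single-task responses (inclusive), and
2. it survives the **compensatory-prolongation correction**: with
   *I* the summed RT of the three same-task trials preceding the switch and
   *B* the mean such interval preceding the participant's non-candidate
   switches in that condition,
   the switch stays fast iff *I* − *B* ≤ mean(single RT) − switch RT.

Participants are classified from their full-preview FSR against cutoffs
c<sub>1</sub> = mean + 1 SD and c<sub>3</sub> = mean + 3 SD of a no-preview
reference FSR distribution: serial (< c<sub>1</sub>), semi-overlapper
([c<sub>1</sub>, c<sub>3</sub>)), overlapper (≥ c<sub>3</sub>).

Preprocessing follows the field's exclusion cascade (RTs > 5000 ms, errors
for RT analyses, 2-SD trimming per trial type × block; participant QC:
< 20% errors in every block, ≥ 40 trials per task and condition), and the
inferential layer uses 20% trimmed means: a heteroscedastic between-by-within
trimmed-means ANOVA with adjusted-F degrees of freedom, AKP / KMS robust
effect sizes, and classical repeated-measures ANOVA with Greenhouse–Geisser
correction where appropriate. A synthetic-cohort generator emulates the
paradigm (fixed-time blocks, AAABBB structure, condition-dependent preview
visibility, mode-dependent preview use with ground-truth sidecars) so that
every stage is testable without any external download.

## Worked example

Simulate a small preview-position cohort and run the full analysis:

```r
library(tswp)

plan <- data.frame(
  block_kind = c("warmup_switching", "task_switching", "task_switching",
                 "single_task", "single_task"),
  duration_s = c(30, 120, 120, 60, 60))
cohort <- simulate_cohort(sim_config(experiment = "exp2", n_per_mode = 4,
                                     block_plan = plan, seed = 42))
res <- tswp_analysis(cohort$trials,
                     tswp_config(cutoffs = mode_cutoffs(0.07, 0.20)))
print(res)
```

```
TSWP analysis
  participants analysed: 12 (QC-failed: 0, unclassifiable: 0)
  mode counts: 
         serial semi_overlapper      overlapper  unclassifiable 
              4               3               5               0 

FSR (trimmed mean, by mode x condition):
           label condition n          mt  se_trimmed
          serial      full 4 0.008496732 0.008916506
 semi_overlapper      full 3 0.111394856 0.029942370
      overlapper      full 5 0.451525582 0.014870550
          serial      late 4 0.000000000 0.000000000
 semi_overlapper      late 3 0.138383213 0.018256343
      overlapper      late 5 0.389611389 0.053026799
 ...
```

The rows are 20%-trimmed mean FSRs (proportions) with trimmed standard
errors, per assigned processing mode and condition: overlappers switch fast
on ~45% of correct switches under a full preview, serials essentially never
do, and in this cohort preview use collapses in the `early`/`middle`
conditions (preview visible only at sequence positions 1/2) while staying
high in `late` — the position-selectivity signature. One simulated
semi-overlapper lands above the c3 cutoff and is classified overlapper;
with these group sizes that is expected classification noise.

The robust mode × condition ANOVA on the FSRs:

```r
print(res$anovas$fsr_robust)
```

```
Between-by-within ANOVA on 20% trimmed means (adjusted F) 
          effect statistic df1   df2         p effect_size es_kind
           label     116.5   2 2.767 2.134e-03      8.1520     KMS
       condition     148.1   3 2.606 1.987e-03      0.4844     AKP
 label:condition     388.7   6 3.419 7.153e-05          NA     AKP
```

`summary(res)` adds discard statistics and the switch-prolongation table
Δ̂ (switch-trial trimmed mean RT minus the other trial types), and
`plot(res)` draws individual FSRs with trimmed means ± 1 trimmed SE per
mode × condition. `write_analysis(res, dir)` exports every table as TSV
plus a run manifest. Real trial logs are ingested with
`read_trial_log(path, schema)`, where the schema maps external column
names and condition labels onto the package's long format.

A thin command-line front end is installed at `inst/cli/tswp.R`:

```sh
Rscript inst/cli/tswp.R simulate --config sim.yaml --out data/
Rscript inst/cli/tswp.R analyze  --in data/ --config analysis.yaml --out results/
Rscript inst/cli/tswp.R report   --in results/
```

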