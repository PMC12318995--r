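---
title: "Modelling Shape Stroop performance with the dual-stage two-phase model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Shape Stroop performance with the dual-stage two-phase model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

The dual-stage two-phase (DSTP) model explains conflict-task behaviour as a
race between two diffusion processes that both start at zero and accumulate
noisy evidence in continuous time.

The **response-selection (RS)** accumulator decides between the correct and
the incorrect response, with absorbing boundaries at `+crit_a` (correct) and
`-crit_a` (error). During the first phase its drift mixes the task-relevant
and task-irrelevant stimulus attributes: on congruent trials
`mu_target_color + mu_color_word`, on incongruent trials
`mu_target_color - mu_color_word`. The colour word therefore pulls toward
the error boundary exactly when it conflicts with the target colour.

The **stimulus-selection (SS)** accumulator models late selective attention:
it drifts at `+mu_ss` toward selecting the target, between boundaries
`+/- crit_c`. If RS reaches a boundary first, the trial ends there. If SS
finishes first, response selection enters its second phase: the RS drift is
replaced by `+mu_rs2` when the target was selected, and — when the word was
selected — by `+mu_rs2` on congruent trials or `-mu_rs2` on incongruent
trials. RS continues from its already-accumulated evidence, not from zero,
which matches the continuous-trace picture of the model: late attentional
selection redirects an ongoing decision rather than restarting it.

Observed reaction time is decision time plus the non-decision time `ter`
(encoding and motor execution). Seven parameters are free:
`mu_target_color`, `mu_color_word`, `mu_ss`, `mu_rs2`, `crit_a`, `crit_c`
and `ter`. A derived index, the interference ratio
`mu_color_word / mu_ss`, measures the distractor's pull relative to the
speed with which attention can select the target.

## Numerical scheme

Both accumulators are advanced in lockstep by an Euler–Maruyama scheme,
`X <- X + v dt + sigma sqrt(dt) z`, with independent standard-normal
increments. Defaults follow the scaling convention of the DSTP fitting
literature: `dt` = 1 ms and `sigma` = 0.1 per sqrt-second for every
accumulator; neither is identified by data, they fix the measurement scale
of drifts and boundaries.

Two numerical details matter:

* **Boundary monitoring.** A discretely monitored boundary is systematically
  harder to hit than a continuously monitored one, biasing accuracy and
  first-passage times. Each boundary check therefore uses the
  Broadie–Glasserman–Kou continuity correction, shifting the boundary inward
  by `0.5826 sigma sqrt(dt)`. With this correction, simulated choice
  probabilities and mean decision times in the single-stage regime
  (`crit_c >> crit_a`) agree with the closed forms
  `p = 1/(1 + exp(-2 v a / sigma^2))` and `E[T] = (a/v) tanh(a v / sigma^2)`
  within Monte-Carlo error at n = 100,000, and halving `dt` moves accuracy
  by well under one percentage point.
* **Ties and censoring.** If both accumulators cross in the same step, the
  response boundary wins (the trial ends). Trials still undecided at the
  response deadline (`max_decision_time`, default 5 s — the task's display
  duration) are returned with the response given by the sign of the RS
  accumulator and flagged `censored`, never dropped silently.

The compiled simulator uses its own xoshiro256+ stream with a ziggurat
normal sampler, seeded explicitly, so large runs are fast and bit-reproducible
given `(seed, n, parameters, dt)` regardless of R's RNG state.

## Estimation

Each participant and word location is fitted separately; congruency enters
as a within-fit factor, so one parameter set must jointly reproduce both
congruency conditions (the sign of `mu_color_word` is the only difference).

The objective is a likelihood-ratio chi-square over RT quantile bins.
Correct-trial RTs are binned at the 0.1, 0.3, 0.5, 0.7, 0.9 quantiles (six
bins); error RTs are binned the same way when at least 11 errors are
available, otherwise pooled into one bin — the standard treatment of sparse
error distributions. Predicted bin probabilities come from simulating the
model (`n_sim` trials per condition per evaluation, default 5,000), floored
at 1e-5 so empty bins cannot produce infinite statistics, and
`G2 = 2 sum O log(O / N p)` is summed over the bins of both conditions.

The default protocol runs 50 Nelder–Mead starts drawn uniformly within the
screening bounds, keeps the start with minimal G2, and polishes it in a
final pass whose evaluations simulate 100,000 trials. Two choices deserve
comment:

* **Common random numbers.** Within a fit, every objective evaluation
  reuses the same simulator seeds. The stochastic objective becomes
  quasi-deterministic, which Nelder–Mead requires; with fresh draws per
  evaluation it stalls on Monte-Carlo noise long before converging.
  Published DSTP fitting protocols rarely document this detail; it changes
  the optimiser's path, not the estimand.
* **Bounds.** Start values and the admissible region are
  `mu_target_color, mu_color_word` in [0, 0.6], `mu_ss` in [0.01, 2],
  `mu_rs2` in [0.05, 2.5], `crit_a` in [0.03, 0.4], `crit_c` in [0.03, 0.6]
  and `ter` in [0.1, 0.6] s — wide brackets around the magnitudes this task
  family produces. Out-of-bounds proposals are penalised, not clipped.

`dstp_fit()` also offers data-anchored starts (`starts = "anchored"`): six
of the starts form a small grid over `ter` (laddered below the fastest
observed RT, which bounds `ter` from above) crossed with a low, medium and
high response boundary. At small multi-start budgets this matters a great
deal, because the G2 surface has two persistent basins — see "Identifiability"
below — and uniform 7-dimensional starts rarely land in the correct one.
`dstp_refit()` can polish the best few screen candidates (`top`) and choose
between them by a single high-precision evaluation.

## The synthetic task and cohort

The session generator reproduces the Shape Stroop design: 18 blocks of 24
trials; per block, 18 incongruent and 6 congruent colour words, the word
equally often in the target shape, the distractor shape and the background,
each of four colours the target on 6 trials, and target shape and
orientation balanced; trial order is randomised per participant. Display
timing (500 ms fixation, 100 ms blank, 5,000 ms stimulus) and the 12-trial
colour-key practice block are carried as metadata; only the 5 s response
window affects simulation, as the censoring deadline.

The cohort generator draws per-participant parameters around group means.
Young target-location means are `mu_target_color` 0.08, `mu_color_word`
0.12, `mu_ss` 0.35, `mu_rs2` 0.9, `crit_a` 0.18, `crit_c` 0.22, `ter`
0.30 s; the old group shifts `crit_a` by +0.07, `crit_c` by +0.05, `ter` by
+0.05 s and `mu_rs2` by -0.3 — older adults set wider decision and
attentional criteria, encode more slowly, and accumulate second-phase
evidence more slowly, while first-phase drifts and the stimulus-selection
rate are age-invariant. Outside the target location `mu_color_word` drops
to 0.03: a word far from fixation barely feeds response selection, which
concentrates the congruency effect in the target location (a small residual
effect remains outside it because even a 0.03 word drift shifts the
first-phase drift noticeably when the target drift is 0.08). Between-participant
standard deviations are 15% of each mean (clamped to the fitting bounds).
These are free generative choices pitched to produce young mean RTs near
1.0 s and old near 1.3 s with accuracies in the mid-90s, the magnitudes
typical of this task; they are all exposed through `cohort_config()`.

What the generator does *not* emulate: sequential effects (post-conflict
adaptation, fatigue, learning), RT contaminants and fast guesses,
trial-to-trial parameter variability, and response-key effects. Passing
tests on synthetic cohorts therefore validate the machinery — simulator,
objective, optimiser, statistics — not the adequacy of the DSTP model for
any particular real dataset.

## Group-level statistics

Fitted parameters are screened with 1.5-IQR fences (type-7 quantiles,
pooled over the full sample per parameter by default; a `scope_by` switch
computes fences within groups instead, since published screening protocols
leave the pooling scope open). Exclusions are scoped to the offending parameter's analysis
and logged.

`mixed_anova()` implements the split-plot decomposition directly: one
between-subject factor, one or two within-subject factors, every within
effect tested against its own effect-by-subject error term. The
Greenhouse–Geisser epsilon is computed per within effect from the pooled
within-group covariance of the subject-by-cell matrix with orthonormal
contrasts, `eps = tr(M)^2 / (q tr(M^2))`, clamped to `[1/q, 1]`; numerator
and denominator degrees of freedom are multiplied by epsilon before the
p-value. Effect sizes are partial eta squared,
`SS_effect / (SS_effect + SS_error)`. The implementation is cross-checked
in the test suite against brute-force sums of squares and against
`car::Anova`'s univariate repeated-measures output. Degenerate inputs are
explicit: constant responses yield F = 0 (flagged, not NaN), incomplete
designs raise an error rather than being imputed.

Tukey comparisons use the studentized range with the error term of the
stratum being decomposed (`ptukey`), falling back to the Tukey–Kramer form
for unequal cell sizes; with two cells this reduces exactly to the pooled
t-test. Applying one stratum's error term across mixed within/between
families is an approximation, noted here because there is no single
canonical choice of error term for such comparisons.

## Identifiability and the recovery study

`recover_study()` closes the loop: draw true parameters from the two group
distributions, simulate each synthetic participant at the session's trial
mix (324 incongruent + 108 congruent trials), fit, and correlate. To keep
a 40-participant study tractable on one core it uses a reduced budget —
10 anchored starts with 600-trial evaluations and a short iteration cap,
then the two best candidates polished at 1,500-trial precision and compared
at 20,000 — chosen to finish in roughly a quarter hour; all knobs are
arguments.

A structural caveat discovered while validating this machinery, and worth
stating prominently: at session-sized data (432 trials, few errors) the G2
surface contains a second, genuinely competitive basin in which a longer
`ter` and a faster `mu_rs2` (with a slightly narrower `crit_a`) mimic the
true RT distributions almost exactly. For a substantial fraction of
simulated participants the wrong basin attains a *lower* G2 than the
generating parameters even when both candidates are fully polished and
compared at 100,000-trial precision — the global minimiser itself, not the
optimiser, sits on the wrong side. The response-selection boundary
`crit_a` survives this trade-off well and its cohort-level recovery
correlation is high; `ter` and `mu_rs2` recover their group-mean ordering
but their participant-level correlations are intrinsically limited at this
trial count, a limitation that no optimisation budget can remove and that
should temper the interpretation of individual-difference analyses of
these two parameters at similar data sizes.

## Reproducibility

Every stochastic entry point takes a seed; per-fit seeds in cohort runs
are derived deterministically from the table seed. Identical configuration
and seed give byte-identical CSV outputs. The test suite and the
acceptance script use small fixed seeds and problem sizes (e.g. a
40-participant recovery study, 100,000-trial oracle checks) chosen as
honest defaults for a desk-scale replication of the pipeline.
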