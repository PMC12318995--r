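# dstp

Simulation and estimation of the **dual-stage two-phase (DSTP) model** of
selective attention for Stroop-type conflict tasks, with a synthetic
Shape Stroop task generator and the group-level statistics used in ageing
studies of cognitive control.

## The problem

In a Shape Stroop task, participants name the colour of a target shape while
ignoring a colour word printed in the target shape, in a distractor shape,
or in the background. Mean RTs and accuracies tell you *that* groups differ
(older adults are slower and more accurate; incongruent words slow everyone
down when they sit in the target shape), but not *why*. The DSTP model
decomposes each participant's trial-level behaviour into interpretable
mechanisms: two diffusion processes race — an early **response selection**
stage whose drift mixes target colour and word,
`v1 = mu_target_color ± mu_color_word` (boundaries `±crit_a`), against a
**stimulus selection** stage with drift `mu_ss` (boundaries `±crit_c`).
When stimulus selection finishes first, response selection continues from
its accumulated state with the cleaner second-phase drift `±mu_rs2`.
Reaction time is decision time plus the non-decision time `ter`. Seven free
parameters per participant and word location, plus the derived interference
ratio `mu_color_word / mu_ss`.

Estimation minimises a likelihood-ratio chi-square over RT-quantile bins,

```
G² = 2 Σ_b O_b log( O_b / (N p̂_b) ),
```

with observed bin counts `O_b` and model-predicted proportions `p̂_b`
obtained by simulating the model (5,000 trials per evaluation during a
50-start Nelder–Mead screen, 100,000 for the final pass, by default), with
congruent and incongruent trials fitted jointly. The inferential layer
provides 1.5·IQR outlier fences, Greenhouse–Geisser-corrected split-plot
ANOVA with partial η², and Tukey (studentized-range) pairwise comparisons.

## Worked example

```r
library(dstp)

# a known parameter set: young adult, word in the target shape
truth <- dstp_params(mu_target_color = 0.08, mu_color_word = 0.12,
                     mu_ss = 0.35, mu_rs2 = 0.9,
                     crit_a = 0.18, crit_c = 0.22, ter = 0.30)

# one session's worth of trials (324 incongruent + 108 congruent)
dat <- rbind(
  cbind(congruency = "incongruent",
        simulate_dstp(truth, "incongruent", 324, sim_config(seed = 1))),
  cbind(congruency = "congruent",
        simulate_dstp(truth, "congruent", 108, sim_config(seed = 2))))

fit <- dstp_fit(dat, n_starts = 10, n_sim = 1000, maxit = 80,
                starts = "anchored", seed = 42)
fit <- dstp_refit(fit, n_sim = 5000, maxit = 200, top = 2)
summary(fit)
```

```
DSTP model fit by multi-start simulation-based G2 minimisation

Parameters:
mu_target_color   mu_color_word           mu_ss          mu_rs2          crit_a 
         0.1253          0.1307          0.3536          1.2009          0.1779 
         crit_c             ter 
         0.2384          0.3269 

Interference ratio (mu_color_word / mu_ss): 0.3696
G2 = 11.199 (best of 10 starts; start-table range 12.126-1896.102)
Trials: congruent = 108, incongruent = 324
Simulated trials per evaluation: 1000 (screen), 5000 (final)
Converged: FALSE
```

The boundary (0.178 vs 0.18), non-decision time (0.327 vs 0.30), word
drift (0.131 vs 0.12) and stimulus-selection drift (0.354 vs 0.35) are
recovered closely; a G² of ~11 over 14 bins means the model reproduces the
observed RT-quantile/accuracy structure (`Converged: FALSE` reports that
the final pass used its full iteration cap). At this data size `ter`,
`mu_rs2` and the first-phase target drift sit on a shallow trade-off ridge
— see the methods vignette — so individual estimates of those parameters
carry substantial sampling noise even when the fit is this good.

A full synthetic study runs through three more calls:

```r
co   <- simulate_cohort(cohort_config(n_young = 75, n_old = 72, seed = 1))
fits <- fit_cohort(co$trials, seed = 1)      # 3 fits per participant
out  <- analyze_params(fits)                 # IQR screen + GG mixed ANOVA
out$anova$crit_a
```

A thin command line sits over the same functions
(`inst/cli/dstp.R simulate|fit|analyze|recover`).

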