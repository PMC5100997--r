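---
title: "The cost-evidence accumulation model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cost-evidence accumulation model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effortalloc)
```

## The model and its assumptions

The package models free effort allocation over a 30-s trial as the dynamics of
a single latent variable, *cost evidence*. During effort the variable rises
linearly with slope `Se`; on reaching an upper bound, effort stops. During
rest it falls with slope `Sr`; on reaching the lower bound, effort resumes.
With amplitude `A` (the distance between bounds), mean epoch durations are
`Te = A/Se` and `Tr = A/Sr`. Each of `A`, `Se`, `Sr` may depend linearly on
the z-scored incentive (`I`) and difficulty (`D`) levels of the 3 × 3 design.

Key assumptions worth keeping in mind:

* **Determinism.** The trajectory is piecewise linear and noise enters only at
  the level of measured condition means. There is no within-trial stochastic
  accumulation; trial-to-trial variability is treated as observation noise.
* **Scale invariance.** Durations depend on `(A, Se, Sr)` only through ratios,
  so the amplitude baseline is fixed (`Am = 1`). Without this constraint a
  subject would have infinitely many proportional solutions; with it, each
  subject has a unique best-fitting parameterization.
* **Independence across trials.** No fatigue carry-over between trials; the
  condition mean is the sufficient statistic the model explains.

Only 20 of the 64 modulation patterns can produce the three canonical
behavioural effects (longer efforts and shorter rests with incentive, shorter
efforts with difficulty): 4 admissible incentive subsets crossed with 5
admissible difficulty subsets, enumerated by `enumerate_model_space()`. The
list is adopted as given — difficulty acting on the amplitude or the
dissipation alone is excluded — rather than re-derived; this is deliberate, as
the exclusion argument rests on prior empirical work with this task and the
package's job is to make the model space explicit and reproducible.

## Parameters, units and defaults

| parameter | meaning | typical value (placebo arm) |
|---|---|---|
| `Sem` | mean accumulation slope during effort (amplitude·s⁻¹) | 0.16 |
| `Sed` | steepening of accumulation with difficulty | 0.021 |
| `Srm` | mean dissipation slope during rest | 0.37 |
| `Sri` | speeding of dissipation with incentive | 0.086 |
| `Ai`  | amplitude expansion with incentive | 0.15 |

`1/Sem` is the mean effort duration at average conditions (6.25 s at 0.16);
`1/Srm` the mean rest duration (2.70 s at 0.37). The group populations built
into `cohort_spec()` use these means with between-subject standard deviations
equal to the printed standard errors scaled by √29, for both the placebo-like
and the escitalopram-like arm (`Sem` 0.11, `Srm` 0.42, `Ai` 0.19, `Sed` 0.013,
`Sri` 0.126 in the latter).

The coupling `dTe/dI = Ai/Se` is the model's signature prediction: a slower
accumulation (smaller `Sem`) simultaneously lengthens efforts and amplifies
the incentive effect on effort duration, so the two observables correlate
across subjects even when only `Sem` varies.

## Fitting: variational Laplace

`fit_model()` maximises a variational free energy for the observation model
*(observed per-condition mean durations) = (model predictions) + Gaussian
noise*, with a Gaussian posterior over parameters (Gauss–Newton inner loop,
analytic Jacobians) and a Gamma posterior over the noise precision. The
converged free energy approximates the log model evidence and automatically
penalises superfluous free parameters through its KL term, which is what makes
the 20-model comparison meaningful.

Numerical choices:

* **Priors.** Zero-mean Gaussians, variance 100, on every free parameter —
  effectively flat on the scale of all model parameters (order 1) while
  keeping the free energy finite; Gamma(1, 1) on the noise precision. `Sem`
  and `Srm` are initialised at method-of-moments values (`1/mean(Te)`,
  `1/mean(Tr)`), modulations at 0.
* **Positivity.** `A`, `Se`, `Sr` must stay positive at the nine design
  points. Gauss–Newton steps are halved until the candidate is admissible and
  the penalised objective does not decrease; if no admissible initialisation
  exists the fit restarts from deterministically rescaled moments (0.5×, 2×,
  0.25×).
* **Convergence.** Free-energy change below 1e-6 or 200 iterations;
  non-converged fits are returned flagged, never silently dropped, and
  `fit_all_models()` records them without aborting the batch.
* **Weighting.** The 18 cells (9 effort, 9 rest) are equally weighted; group
  fits (`fit_reference`, `fit_delta_models`) stack subjects' cells with a
  single noise variance. A stacked fit over heterogeneous subjects yields
  *effective* group parameters (means of ratios are not ratios of means);
  the delta analysis is therefore a contrast of effective parameters between
  groups, which is exactly what makes it robust to shared bias.
* **Cross-check backend.** `bic_evidence()` provides a penalised
  least-squares/BIC surrogate for the log evidence so selection results can be
  shown stable across two different evidence approximations rather than tied
  to one.

`rfx_bms()` implements the variational Dirichlet scheme for random-effects
model selection (uniform Dirichlet prior `alpha0 = 1`, convergence at 1e-6)
with exceedance probabilities from 10⁶ seeded Monte-Carlo draws. Only
within-subject evidence differences matter; adding a constant to a subject's
row changes nothing.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` draws subject-level parameters from truncated normal
populations (redrawing until `A`, `Se`, `Sr` are positive at all design
points), predicts the 9 × 2 condition means per visit, and adds Gaussian
noise. `simulate_force_trace()` goes one level lower: first-order force
kinetics toward a plateau 1.05× the target (rise constant 0.15 s and a much
faster 0.03 s release, since letting go of a grip is passive), band-limited
tremor noise that scales with exerted force (real rest baselines are quiet),
and 100 Hz sampling. Trials are 30 s, 8 blocks × 9 conditions randomized
within block, with one RNG sub-stream per subject × visit so any subset of a
run is reproducible from the master seed.

**Duration-noise calibration.** The generator's central free choice is the
noise on condition means. Two considerations fix the default:

* means pooled over long epochs vary more than means over short ones, so the
  noise is *proportional* (constant coefficient of variation) rather than a
  single absolute sd — effort cells (~6 s) get more noise than rest cells
  (~2.7 s);
* the magnitude, cv = 0.035, was calibrated once so that the 29-subject
  recovery simulation at default settings attains the fitting procedure's
  reference operating characteristics — hits at or above 96% for `Ai`, `Sem`,
  `Srm`, `Sri`, a clearly lower hit rate for the small-magnitude `Sed`, and
  false alarms below 5% — and was not revisited afterwards.

An absolute-sd mode (`duration_noise_mode = "absolute"`) remains available.
What the generator does **not** emulate: residuals exchanged between real
subjects (hence any condition-correlated, non-Gaussian error structure),
fatigue drift across blocks, visit-level parameter drift, or EMG-level
physiology. Passing tests on synthetic cohorts therefore demonstrates that
the *chain of algorithms* is correct and well-calibrated under the stated
noise model, not that the model is true of any particular dataset.

## Epoch detection choices

The detector follows the standard offline rules: onset candidates are samples
with derivative above +1 sd of the trial's derivative series and force above
0.5; offsets mirror them (derivative below −1 sd, force below 0.5); between
two onsets only the last offset survives; among onsets before an offset the
minimum-force one survives; a trial ending mid-effort gets an offset at the
end, flagged truncated. Decisions the rules leave open:

* derivative = backward first difference × sampling rate, sd taken per trial
  over the whole trace (the natural unit in this design); no pre-smoothing by
  default, with an optional moving-average width;
* timestamps are 0-based sample indices, epochs half-open `[onset, offset)`;
* truncated epochs are censored and excluded from duration means by default
  (they still count for compliance), since their full duration is unknown;
* the first rest is the time from trial onset to the first detected onset.

A consequence of the sd-threshold rule worth knowing: an effort already in
progress at `t = 0` has no rising edge and cannot be detected — the simulator
therefore starts trials with a latency (default: one model rest duration).

## Group statistics

`mixed_anova()` offers two engines because fractional denominator degrees of
freedom in mixed designs imply a Satterthwaite-type correction: a classical
`aov`-based partition (exact for balanced data) and an `lmerTest` random
intercept model with Satterthwaite df and Type-III sums of squares (tolerant
of missing visits). The two agree on balanced designs, which the test suite
asserts to 1e-6. Permutation tests use the add-one estimator
`p = (1 + k)/(n + 1)` over 10,000 seeded label permutations, two-sided on the
absolute statistic. Bonferroni thresholds follow the convention of 0.05/5 for
the five model parameters and 0.05/6 for the six behavioural measures.

## The recovery simulation

`run_recovery()` plants a 20% change in one parameter of every subject,
regenerates condition means with the default noise, refits, and compares
refitted against baseline values with a paired t-test across subjects at
p < 0.05/5, repeated (by default) 100 times per target. The per-replicate
t-test is the chosen reading of the procedure (the alternative —
replicate-averaged estimates — is exposed simply by raising `n_reps` and
aggregating outside). Subjects whose inflated parameters would leave the
valid region are excluded per target and counted. A subtlety the simulation
makes visible: for a parameter whose subject-level values straddle zero
(as `Sed` does under the default heterogeneity), a multiplicative "+20%" is
not directionally consistent across subjects, which genuinely depresses its
hit rate relative to the uniformly positive parameters — the same ordering
seen in the reference operating characteristics.

## Scales used by the shipped checks

The test suite and the acceptance script run: the full five-target recovery
simulation at 29 subjects (100 replicates per target in the script, 40 in the
test suite); group-level selection over all 20 models at 12 subjects; the
delta-modulation analysis at 29 matched subjects per group; and five
replicates of the two-cohort group comparison. These sizes were chosen as the
smallest at which the corresponding statistics are stable, and the vignette
states them so that readers know exactly what was computed.

## Known limitations

* The variational free energy is an approximation; evidence differences of
  order 1 log-unit should not be over-read. Cross-check with `bic_evidence()`.
* Stacked group fits assume a single noise variance across subjects; subjects
  with extreme parameters influence the effective group parameters more.
* The MAT-file reader covers the level-5 format (numeric, char, cell, struct,
  zlib-compressed elements); MAT v7.3 files are HDF5 containers and are
  rejected with instructions to convert.
* With proportional noise the fitted homoscedastic noise model is mildly
  misspecified by design; this mirrors the mismatch between any single-variance
  fit and real residuals and has no visible effect on selection in the shipped
  checks.
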