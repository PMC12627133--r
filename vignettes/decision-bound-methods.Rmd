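---
title: "Decision-bound modeling of category learning: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-bound modeling of category learning: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catbound)
```

This vignette explains the models implemented in `catbound`, the
assumptions behind them, the parameters that matter, and the design
decisions we made where the underlying experimental literature leaves the
construction open.

## Category structures

Each task defines two categories, A and B, as bivariate normal
distributions over a two-dimensional stimulus space: temporal modulation
(Hz) × spectral modulation (cycles/octave) for auditory ripples, spatial
frequency (cycles/degree) × orientation (degrees) for visual Gabor
patches. `category_distributions()` carries the distribution parameters in
physical units; all analysis happens in a *normalized* space, the unit
square $[0,1]^2$ mapped affinely onto the physical ranges
(`to_normalized()` / `to_physical()`). The normalization is our
construction: it makes the two modalities commensurate, so a single noise
scale and a single fitting configuration serve both. Rule-based (RB)
structures differ between categories only on the first dimension;
information-integration (II) structures differ on both, with positively
correlated within-category variability, so their optimal boundary is
diagonal.

`optimal_boundary()` returns the midpoint criterion on the relevant
dimension for RB pairs and the pooled-covariance Fisher linear
discriminant for II pairs. The II categories have slightly unequal
covariance matrices, so the exact likelihood-ratio boundary is weakly
quadratic; we keep the linear discriminant because the quadratic term is
negligible at these parameter values and the procedural (II-optimal)
strategy is conventionally modeled as a linear bound. For RB pairs the
discriminant and the midpoint rule coincide (the irrelevant-dimension
means are equal and the pooled covariance is diagonal there); the test
suite verifies this agreement to 1e-9.

### Stimulus sampling and the overlap constraint

Training sets contain 100 stimuli per category. Draws falling outside the
physical ranges are rejected and redrawn, since the ranges are hard limits
of the stimulus synthesis. The published sets have the property that
exactly 10 of 200 stimuli fall on the wrong side of the optimal boundary
(a 95% accuracy ceiling); whether that was engineered or a fortunate draw
is not documented, so `sample_stimuli()` enforces it by iterative repair:
if the wrong-side count exceeds the target, a random wrong-side stimulus
is redrawn from its category distribution; if it falls short, a random
right-side stimulus is redrawn; the loop stops at the exact target or
errors after `max_redraws` (1e5) attempts, reporting the achieved count.
The repair slightly perturbs the sampled distribution; the moment checks
in the test suite (sample means, SDs, covariances within four standard
errors across a 50-seed sweep) are run on unconstrained truncated samples,
and the packaged fixture sets (seed 20250925) use the repair.

Points exactly on a bound are labeled A — a measure-zero event that needs
a deterministic rule.

The generalization-test grid (`generalization_grid()`) places `n_side`²
stimuli (default 8×8 = 64) evenly over the full normalized square; the
exact grid placement used in the original experiments is not numerically
specified, so even spacing over the full range is assumed. Grid stimuli
are labeled by the task's optimal bound, since they were never trained and
have no empirical labels.

## The response model

All boundary strategies and all boundary observer models share one
response rule. For a stimulus at normalized coordinates $(x, y)$ and a
unit-normal bound $(a, b, c)$, the signed perpendicular distance is
$h = ax + by + c$ (positive on the A side) and

$$P(\text{respond A}) = (1 - \lambda)\,\Phi(h/\sigma) + \lambda/2,$$

with $\sigma$ a single perceptual-plus-criterial noise SD in normalized
units and $\lambda$ an optional lapse rate (default 0). The literature
this implements names the noise parameter but not the response rule; the
probit form above is the standard decision-bound formulation. Guessing
strategies respond A with a fixed probability. Likelihood contributions
are clamped to $[\varepsilon, 1-\varepsilon]$ with $\varepsilon =$ 1e-10
to keep logs finite; the clamp is part of the model and is applied
identically in simulation and fitting.

## Model fitting and selection

Nine observer models are fitted to every participant-block
(`model_inventory()`): unidimensional rules on x and on y, each with both
response assignments (2 free parameters: criterion, noise); the General
Linear Classifier with both assignments (3: slope, intercept, noise);
fixed guessing (0); and biased guessing constrained to $p_A \in [0.5, 1]$
or $[0, 0.5]$ (1). The free-parameter count of fixed guessing is a
documented ambiguity in the source literature ("the random models have one
free parameter" directly after describing a fixed $p = 0.5$ model); we use
$r = 0$ for the fixed model and $r = 1$ for the biased ones, and the
inventory exposes `r` so either convention can be audited.

Fits maximize the likelihood in normalized coordinates. The GLC bound is
parameterized internally as an angle $\theta \in [0, 2\pi)$ plus signed
offset of a unit-normal line, which avoids the infinite-slope singularity
of the slope/intercept form; reported parameters are converted back to
slope and intercept where finite. Because $\theta$ is free over the full
circle, the flipped-assignment GLC is the direct fit with
$\theta \to \theta + \pi$, $c \to -c$ and identical likelihood, so it is
derived analytically rather than re-optimized. Similarly, fitting both
unidimensional assignments is equivalent to one signed criterion at the
likelihood level; we fit both and report each.

### Optimizer

Each boundary model is optimized in two stages: a coarse grid over the
parameter space, scored in a single vectorized pass (criterion × noise for
unidimensional models; angle × offset × noise for the GLC), followed by
Nelder-Mead refinement from the best `n_refine` grid points (default 2),
with the noise SD optimized on the log scale. The scheme is fully
deterministic by default; `fit_control(n_random = k)` adds seeded random
restarts. We chose grid-seeded starts over purely random multi-starts
because the grid pass is cheap, covers the space systematically, and makes
batch fitting reproducible without seed bookkeeping. The test suite checks
the optimizer against an independent dense 400×400 grid search and
requires agreement within 0.5 in $-2\ln L$; in practice the refined fits
beat the dense grid.

Guessing models need no optimization: the fixed model's log-likelihood is
$N \ln\tfrac12$ exactly, and the biased models' MLE is the observed
response proportion projected into the constrained half-interval.

### The noise floor

`fit_control()` bounds $\sigma$ in $[0.01, 2]$ normalized units. The lower
bound is substantive, not numerical: when a block's responses are linearly
separable, the probit likelihood is maximized by a separating bound with
$\sigma \to 0$ and $\ln L \to 0$ — a degenerate solution in which the
three-parameter GLC can always absorb data generated by a unidimensional
rule, overwhelming the BIC penalty and destroying model identifiability.
We observed exactly this in model-recovery simulations with a floor of
1e-4. A floor of 0.01 (1% of the stimulus range, below any plausible
perceptual/criterial noise for these stimuli) excludes only the degenerate
optima: recovery of unidimensional generators rises from roughly 85% to
above 90% while GLC and guessing recovery are unaffected.

### Selection

The best model per block is the minimum-BIC fit,
$\mathrm{BIC} = r \ln N - 2 \ln L$. Ties (ΔBIC < 1e-6) are broken toward
fewer free parameters, then by a fixed inventory order (guessing <
unidimensional < GLC); the underlying literature states no tie rule, and
ties are essentially confined to exact-equivalence cases such as the two
GLC assignments. Winning families collapse to strategy labels
(`collapse_family()`): GLC → procedural, unidimensional → uni_x/uni_y,
all guessing variants → random.

## The synthetic cohort

`simulate_cohort()` emulates a two-group study (control and ADHD-like, all
four tasks per participant, all participants sharing the same stimulus
sets). Strategies are *scheduled, not learned*: each participant-task
draws an onset block, uses suboptimal behavior before it (a fair coin
between fixed guessing and an off-dimension unidimensional rule), and the
task-optimal strategy from the onset block on, including the test block.
The defaults (`cohort_config()`) encode the group structure the package is
designed to reproduce qualitatively:

- onset block uniform on 1–4 (control) vs 2–7 (ADHD-like) — later optimal
  strategy adoption;
- noise SD 0.08 vs 0.12 normalized units — less efficient use of the same
  strategy;
- ASRS symptom scores Normal(35, 6.4) truncated below 51 vs Normal(60,
  11.4) truncated at ≥ 51, respecting the diagnostic screening threshold
  of 51 and matching the reported group SDs of symptom severity (6.39 and
  11.43);
- a small within-group coupling (`sigma_asrs_slope` = 0.002 added noise SD
  per ASRS point above the group mean) so the symptom–performance
  association is not purely a between-group artifact.

Training blocks deal stimuli "randomly but evenly": within each half of
training (blocks 1–4 and 5–8) each category's 100 stimuli are shuffled and
dealt 25 per block, so each half exhausts the full set and the whole
category space has been presented after block 4. A session therefore has
400 training trials plus 64 feedback-free test trials (the source
experiment's text gives a total of 450 trials per task, which is
inconsistent with its own 8 × 50 block structure; we implement the block
structure and note the discrepancy rather than guessing its origin).

What the generator does *not* emulate: trial-level learning dynamics
(system competition, reinforcement updates), reaction times, session
timing, key counterbalancing, or within-block strategy switching. Passing
cohort-level checks therefore shows that the analysis pipeline recovers
the structure the generator put in — it does not validate the generator
against real participants, whose strategy trajectories are noisier and
whose group differences are smaller than the configured defaults.

## Metrics and reports

`strategy_metrics()` derives, per participant-task: the first training
block whose label equals the task-optimal label (coded 9 — one past the
last block — when the optimal strategy never appears; the alternative
convention of excluding such participants is available through the
`censor` argument); the count of optimal training blocks; and final-block
accuracy conditional on the final-block label being optimal (participants
whose final block is non-optimal are excluded, returning `NA`). Test-block
labels are kept in trajectories and proportions but excluded from the
first/total counts, which are defined over training. `transfer_scores()`
is test-block accuracy minus final-training-block accuracy, and
`symptom_correlation()` is the Pearson correlation between ASRS score and
the unweighted mean of the 32 participant-task-block training accuracies,
with a Fisher-z 95% CI (via `stats::cor.test`). Inferential models on real
data (mixed ANOVAs, LMMs) are deliberately out of scope — the pipeline
emits tidy CSVs that any statistics environment can consume.

## Problem sizes used by the test suite

The packaged checks run at sizes chosen to give stable Monte-Carlo
behavior on a single CPU: 50-seed sweeps for stimulus-set invariants and
moments; 100 simulated 50-trial blocks per generating family (noise 0.03)
for model recovery; 100 replicates of N = 200 (noise 0.05) for criterion
recovery; and 10 cohort seeds at 15 participants per group for the
group-ordering and correlation direction checks, with model fits on all
960 training blocks per seed.

## Known limitations

- Strategy schedules are step functions (suboptimal → optimal at onset);
  real learners mix and revisit strategies within and across blocks.
- The optimal II bound is linear; the exact unequal-covariance
  likelihood-ratio bound is weakly quadratic and is not implemented.
- Model recovery is inherently imperfect near the BIC decision margin:
  even with the noise floor, a GLC legitimately beats a true
  unidimensional generator in a few percent of blocks (the likelihood-
  ratio tail), so recovery rates plateau in the low-to-mid 90s rather
  than at 100%.
- ASRS scores enter only through group membership and the noise coupling;
  no item-level or subscale structure is modeled.
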