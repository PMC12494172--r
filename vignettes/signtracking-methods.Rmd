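---
title: "Methods: gaze-based sign-/goal-tracking and connectome-based prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze-based sign-/goal-tracking and connectome-based prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signtrack)
```

## The phenotype and its measurement model

In a food Pavlovian conditioning task, four fractal images (conditioned
stimuli, CS) each predict a fixed outcome: 2 candies, 1 candy, nothing, or
nothing plus a buzzer. After 8 shaping trials (pairings shown in descending
then ascending reward order), each CS appears 16 times in pseudorandomized
blocks of four — every CS once per block — for 64 experimental trials.
Each trial runs fixation (1.5 s), CS (3 s), double fixation (1.5 s), reward
delivery (3 s), and a 7.5 s inter-trial interval; halfway through, the
screen/dispenser orientation switches sides, which the analysis handles by
mirroring the AOI layout.

Gaze is recorded at 50 Hz and classified by a velocity-threshold (I-VT)
filter: consecutive valid samples connected by point-to-point angular
velocities below 30°/s form fixation runs, and runs spanning at least 50 ms
become fixations with a time-weighted centroid. Each fixation is assigned
by its centroid to one of three AOIs — the CS image, the reward (UCS)
location, or background. Because cue onset triggers an orienting response
common to both phenotypes, conditioned gaze is quantified over the **last
1.5 s** of the CS window only. With `p(CS)` and `p(UCS)` the percent of
valid fixation time on each AOI in that window, the per-trial gaze index is

$$GI = \frac{p(CS) - p(UCS)}{100} \in [-1, 1].$$

The last 4 trials of each CS type are excluded for data quality (fatigue,
calibration drift), leaving 12 per type (48 total). The per-participant
**ST/GT coefficient** is the OLS slope of `GI` on CS value (2, 1, 0, 0);
positive slopes indicate sign-tracking, negative goal-tracking. For
post-hoc group contrasts the sample is split by slope into the top 2/5
(ST), bottom 2/5 (GT) and middle 1/5 (intermediate), with tail size
`round(0.4 n)` — reproducing a 19/9/19 split at n = 47.

Behavioral statistics follow the estimators standard for this design:
covariate-adjusted OLS for adiposity associations (age, sex, pre-task
hunger as covariates, with standardized refits), Welch's unequal-variance
t-test for ST-vs-GT contrasts, a two-way fully within-subject ANOVA
(AOI × CS type) with Greenhouse–Geisser correction, and a two-stage
subject-slope trend test over trials.

## Connectivity processing

Node timecourses (one column per parcellation region) are taken as given.
Per node the pipeline removes a linear trend, z-scores, and jointly
regresses out 16 nuisance columns — 6 motion parameters, their first-order
derivatives, global, CSF and white-matter signals, and framewise
displacement (FD) — together with one indicator per FD > 0.5 mm volume.
Indicator regressors exactly annihilate the flagged rows, so motion spikes
are censored by regression rather than row deletion; `n_volumes_used`
reports the unflagged count. Runs with more than 25% flagged volumes are
excluded outright. Pearson correlations between all retained node pairs are
Fisher-transformed (`z = atanh(r)`, `|r|` clipped at `1 − 10⁻⁷` so
degenerate pairs remain finite while preserving order). Edges are
enumerated as the strict upper triangle in row-major order with 0-based
node indices — 24,090 edges for 220 nodes — and that convention is fixed
across all outputs.

Ordering of the cleaning steps (detrend → standardize → confound
regression, residuals not re-standardized) is a documented package choice;
correlations are invariant to the standardization step but it keeps
residual scales comparable across nodes.

## Connectome-based predictive modeling

`cpm()` is the package's central fitting function, returning a classed
object with `print`, `summary`, `coef`, `predict`, `residuals` and `plot`
methods. The estimator, per leave-one-out fold:

1. **Edge screening.** Each edge's Fisher-z values across training subjects
   are correlated with the behavioral target by *partial Spearman*
   correlation: both variables rank-transformed (average ranks on ties),
   each residualized on the covariate design (categoricals
   indicator-coded, continuous covariates unranked), residuals
   Pearson-correlated.
2. **Selection.** Edges with `ρ > 0.3` form the positive network,
   `ρ < −0.3` the negative network (strict cuts).
3. **Strength & line fit.** Per network, a subject's strength is the sum of
   z over selected edges; a univariate least-squares line of behavior on
   strength is fit on the training set.
4. **Prediction.** The held-out subject's strength over the
   training-selected edges is fed through that line.

Accuracy is Spearman's ρ between predicted and observed scores over all
subjects. Because LOOCV folds are not independent, inference uses
permutation: the behavior vector is shuffled against the matrices
(covariates stay aligned with the matrices), the *entire* pipeline is
rerun, and `p = \#(ρ_{perm} ≥ ρ_{obs})/B`. An add-one-smoothed option,
`(1 + \#)/(B + 1)`, is available because the plain proportion can return 0.
Edges selected in at least 90% of folds form the consensus network, which
is summarized by node degree, degree as a proportion of network size, the
top 10% highest-degree nodes (`round(0.1 N)`, ties at the cut included),
and a 10×10 canonical-network pair-count matrix.

Implementation note: per fold, edge ranks and the covariate
residualization are computed once and shared across all permutation
columns through matrix products. This is algebraically identical to
rerunning the pipeline per permutation — fold membership never depends on
the behavior values — and is verified in the tests against a naive
fold-by-fold reimplementation (exact agreement on an n = 12 study).

Two readings of the reference procedure were genuinely open and are
resolved as follows. First, LOOCV is deterministic, so "iterations" beyond
the folds add no variability; the implementation runs one deterministic
LOOCV and defines consensus over its folds. Second, whether shuffling the
target should also permute covariate rows is unspecified; the
implementation permutes the behavior vector only, keeping covariates
aligned with the matrices — the null tested is "no behavior–connectivity
link given the covariate structure". Empty-selection folds predict the training mean
rather than aborting, keeping the LOOCV sample intact; a warning reports
how many folds were affected.

## The synthetic-study generator

Because the underlying participant data are not publicly deposited, the
generator is a first-class, tested module that emulates every input the
pipeline consumes, with known ground truth:

- **Latent propensity.** θ ~ N(0, `propensity_sd`²) per participant. Gaze
  in the late-CS window of rewarding trials lands on the CS AOI with
  probability `plogis(θ)` (logistic link: the simplest monotone map
  covering the full gaze-index range); otherwise it favors the UCS
  location. On zero-value trials allocation is θ-independent and favors
  the UCS/background. Early-CS gaze orients to the cue regardless of θ,
  mirroring the orienting response that motivates the late-window
  analysis.
- **Gaze mechanics.** Fixation segments of 300–700 ms with within-segment
  jitter (SD 0.05°, far below the saccade threshold), instantaneous
  between-segment jumps that exceed it, and blinks as invalid runs of
  60–200 ms at Poisson times (0.15 Hz) to exercise the I-VT filter's
  invalid-sample handling. Coordinates are generated directly in visual
  degrees on a plane; scene-camera calibration is out of scope.
- **Covariates.** WHR = 0.85 + `whr_slope`·θ + N(0, 0.05); age, sex,
  hunger, scanner and run order drawn independently with healthy-adult
  marginals.
- **Timecourses.** A 10-factor latent model with block-structured loadings
  (10 contiguous "canonical network" blocks) gives realistic
  network-structured connectivity. For each planted edge (i, j), node j
  receives node i's standardized series with weight `γ·θ_std`, so the
  (i, j) correlation increases monotonically with θ. Planted edges affect
  the "sweet" run only; the "savory" run is null, mirroring a
  reward-specific association. Confounds include slow-drift motion
  parameters, derivatives, global/CSF/WM signals, and FD with a
  configurable spike fraction.

The reference task reports no effect size linking gaze behavior to
connectivity, so `planted_effect` (γ = 0.5) and `whr_slope` (0.06, giving
a WHR SD contribution comparable to its 0.05 residual SD) are free
parameters of the generator, fixed once and documented here rather than
calibrated to any published value.

What the generator does *not* emulate: pupil dynamics, smooth pursuit,
scene-camera video, head motion coupling between gaze quality and FD,
hemodynamic autocorrelation, or scanner-specific artifacts. Passing tests
therefore demonstrate correctness of the estimators under a clean
generative model, not robustness to every pathology of real recordings.

## Numerical choices and degenerate inputs

- I-VT velocity is the Euclidean angular step over consecutive valid
  samples divided by Δt; no smoothing window by default (configurable).
  Gap fill-in and adjacent-fixation merging exist but default off, since
  only the threshold (30°/s) and minimum duration (50 ms) are fixed by the
  protocol.
- Fixations straddling the analysis window contribute pro-rated overlap
  time, avoiding all-or-nothing discretization artifacts.
- Trials with no valid fixation time yield a missing gaze index and are
  dropped (not imputed); a slope requires ≥ 24 retained trials and ≥ 2
  distinct CS values.
- Group-split ties are broken by stable participant order.
- Greenhouse–Geisser ε comes from the covariance of orthonormalized
  interaction contrasts (Huynh–Feldt by flag); an all-equal cell table
  returns F = 0, p = 1 by convention, as does a zero-variance slope set in
  the trend test.
- Constant edges inside a CPM training fold get ρ = 0 (unselectable);
  a constant behavior vector is an error.
- Fisher clipping at `1 − 10⁻⁷` bounds z at ≈ 8.4 for duplicated nodes,
  which are additionally counted in the QC field `clipped`.

## Problem sizes used by the test suite

The acceptance checks run, as the package's chosen study sizes: a planted-
effect recovery study with n = 60 participants, 120 nodes, 250 volumes and
B = 500 permutations (full chain from simulated gaze to consensus
networks), and a null calibration of 50 replicate studies (γ = 0,
`whr_slope` = 0) at n = 30, 60 nodes, B = 100, whose positive-network
permutation p-values are tested for uniformity (Kolmogorov–Smirnov,
α = 0.01). Oracle-equivalence checks use an n = 12 toy study against a
naive reimplementation, and 100 noise-free planted-fixation streams for
the I-VT filter.

## Limitations

- The two-stage subject-slope trend test is a deliberate simplification of
  a mixed-effects trend model; it is conservative for balanced designs but
  does not weight participants by within-subject precision.
- Partial Spearman residualizes ranks on unranked covariates — the
  conventional CPM practice — which is not a fully rank-based partial
  correlation.
- The full-sample model used by `predict()` on new subjects is fit without
  cross-validation; its in-sample predictions must not be used to assess
  accuracy.
- AOI membership is decided by fixation centroid, not sample-level extent;
  fixations hugging an AOI border are assigned wholesale to one region.
- Consensus is defined over deterministic LOOCV folds; with small samples
  the fold networks overlap heavily and the 90% criterion is lenient
  compared to repeated random-split schemes.
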