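---
title: "Serial dependence from behavior to neural reconstructions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial dependence from behavior to neural reconstructions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

serialshift implements the analysis chain used to quantify serial dependence
in two-item retro-cue working-memory experiments: a behavioral bias model and
an inverted encoding model (IEM) of direction-tuned neural signals, with the
non-parametric inference that both require. This vignette documents the
models, their assumptions, the tunable parameters, and the design decisions
made where more than one reasonable implementation exists.

## The behavioral model

In delayed-estimation tasks, the report of the current target feature is
attracted toward the target of the previous trial. The bias as a function of
the signed circular distance $x$ (degrees, previous minus current target,
wrapped into $(-180, 180]$) is modeled by the first derivative of a Gaussian
(DoG):

$$y(x) = x\, a\, w\, c\, e^{-(wx)^2}, \qquad c = \sqrt{2}\, e^{0.5},$$

where $a$ (degrees) is the height of the curve peak, reached at
$x = 1/(w\sqrt 2)$, and $w$ (1/degrees) scales the width. The constant $c$
exists only to make $a$ the peak height. A positive $a$ means attraction.
`dog_fwhm()` converts $w$ into the full width at half maximum of the positive
lobe by root-finding on the two half-maximum crossings; the crossing
separation in $u = wx$ units is a universal constant, so FWHM is exactly
proportional to $1/w$.

**Preprocessing** (`preprocess_behavior()`) drops the first trial of each
block (no previous-trial target exists), excludes trials with response times
above 20 s or with absolute response errors more than 3 SDs above the
subject's mean absolute error, and demeans errors per subject. The exclusion
rule is read as $|e| > \overline{|e|} + 3\,\mathrm{SD}(|e|)$ per subject.
Note that this truncation slightly attenuates the fitted amplitude when the
response noise is wide (about $-0.2^\circ$ at 15$^\circ$ noise); this is a
property of the procedure itself, which any study using it inherits.

**Fitting** (`fit_dog()`) pools one data point per subject and signed
distance (the subject's mean demeaned error at that distance) and maximizes a
Gaussian log-likelihood with the residual variance profiled out, which makes
the point estimates coincide with least squares. Because the model is linear
in $a$ given $w$, the amplitude has a closed form per candidate width and the
optimization reduces to a bounded one-dimensional search over
$w \in [0.01, 0.1]$ (coarse grid of 181 points plus local refinement with
`optimize()`); a derivative-free global optimizer is unnecessary for this
two-parameter problem. $a$ is unbounded, so sign-flipped data yield exactly
the negated amplitude.

**Inference.** `bootstrap_dog()` resamples the subject-by-distance data
points with replacement (1000 draws by default) and reports the SD of the
bootstrapped amplitude. `permutation_test_dog()` flips the sign of whole
participants (one random sign per subject per permutation, applied to all of
that subject's points), refits, and reports the one-sided fraction of
permuted amplitudes at or above the observed one, floored at 1/`n_perm`.
`congruence_analysis()` fits the curve separately for trials whose current
target shares the color of the previously cued item, and tests the amplitude
difference by permuting congruence labels within subject; since no direction
is privileged for this contrast, the difference p-value is two-sided.

## The inverted encoding model

The forward model assumes each sensor measures a weighted sum of 18
direction-tuned channels spaced 20 degrees apart, each channel a half-angle
cosine to the 18th power, $\cos((\theta - \mu)/2)^{18}$ — 360-degree
periodic with one peak (the even exponent makes rectification immaterial)
and a FWHM of about 63.2 degrees. Direction space is the full circle; it is
never collapsed to 180-degree orientation space.

Training solves $B_1 = C_1 W$ by OLS,
$\hat W = (C_1^\top C_1)^{-1} C_1^\top B_1$, on one recording session;
testing inverts the model on the other session's data by least squares in
channel space, $\hat C_2 = B_2 \hat W^\top (\hat W \hat W^\top)^{-1}$.
Channel estimates are projected to direction space at 1-degree resolution by
weighting each channel's tuning curve, and each trial's profile is circularly
shifted so its labeled direction sits at the common center, 180 degrees.

Averaging follows three rules. First, trials are averaged within each
labeled direction before averaging across directions, so unequal
presentation counts cannot bias the group profile. Second, the whole
procedure runs for 20 basis-center offsets (0-19 degrees), whose average
tiles the circle with effective 1-degree channel spacing; profiles are
averaged across offsets after full processing (for these linear steps the
order does not matter). Third, the two train/test assignments of the
sessions are averaged. `reconstruct()` implements all of this per subject
and time bin; because every step after channel estimation is linear and
alignment depends only on the trial's label, the implementation aggregates
test trials by label (and CW/CCW relation) before inverting, which is
algebraically identical to per-trial processing and much faster. Per-trial
profiles are computed only when requested (`per_trial = TRUE`), as the
brain-behavior correlation needs them.

Sensor data are averaged into non-overlapping 100-ms bins over the analysis
window of each epoch: 13 bins for the S1 and S2 epochs (0-1300 ms after
stimulus onset), 15 for the retro-cue epoch (0-1500 ms), and 51 for the
epoch spanning the last second of the inter-trial interval and the whole
trial.

### Numerical choices

- The channel design for the full balanced direction set is well
  conditioned; its condition number is recorded in every `reconstruct()`
  result. Solves fall back to an SVD pseudo-inverse when the condition
  number exceeds 1e8 (this happens only in degenerate inputs such as
  zero-signal time bins of noiseless synthetic data).
- Profiles are evaluated at integer degrees; ties in the profile maximum are
  broken by the circular mean of the tied set (ties are measure-zero for
  noisy data but the rule keeps every input defined).
- A rank-deficient channel design is an error that names the dependent
  channels rather than a silent pseudo-inverse.

## Reconstruction statistics

**Fidelity** summarizes how strongly an aligned profile $r(\theta)$ points
at its center: $F = \mathrm{mean}_\theta\, r(\theta)\cos(\theta - 180)$. A
flat profile gives 0, a pure cosine centered on 180 gives 0.5.

**Cluster-based sign-flip permutation test** (`cluster_test()`): per-bin
one-sample t statistics against zero are thresholded at the one-sided
$\alpha = 0.05$ quantile (the cluster-forming threshold a standard
implementation defaults to), contiguous suprathreshold bins form clusters
scored by their summed t, and the null of the maximum cluster score is built
from whole-subject sign flips — exhaustively ($2^n$, including the identity,
hence a p floor of 1/1024 for ten subjects) up to $n = 12$, randomly above.

**Attractive shift** (`flip_and_average()`, `shift_from_max()`): trials are
split by whether the previous target was clockwise or counter-clockwise of
the labeled direction (positive or negative signed distance; trials at
exactly 180 degrees have no relation and are excluded), counter-clockwise
profiles are mirrored about the center, and the flipped profiles are
averaged within and then across labeled directions. Under this package's
axis conventions an attractive rotation then displaces the maximum above 180
degrees, and the reported shift — the signed displacement of the maximum of
the profile averaged over the time bins with significant fidelity — is
positive for attraction. If no bin reaches significance the shift is an
explicit null result (`NA`), not an error.

**Bootstrap inference** (`bootstrap_shift()`): participants are resampled
with replacement 10,000 times; each iteration records the shift of the
resampled group mean. The shift is deemed significant (one-sided, in the
attraction direction) when at least 95% of iterations give a shift of 0 or
more; the reported p is the fraction of negative iterations, floored at
1/10,000, alongside the central 95% of the bootstrap distribution. Both the
decision rule and the interval are reported without attempting to reconcile
them into a single summary.

**Brain-behavior correlation** (`circ_corr_behavior()`): the deviation of
each trial's unflipped profile maximum from its labeled direction is
correlated with the behavioral response error using the
Jammalamadaka-SenGupta circular-circular coefficient, per session and time
bin; sessions are averaged and the subject-by-bin matrix goes through the
same cluster test. For S1/S2 epochs only trials in which that item was later
cued are used, since only those have a matching report.

**Corrections**: Benjamini-Hochberg FDR across the per-epoch shift tests of
the three current-item analyses; cluster p-values above the permutation
floor are Bonferroni-multiplied by the three epochs compared.

## The synthetic-data generator

The generator exists so that every stage above is testable without any
recordings; its defaults are the study conditions of the experiment the
package models.

**Design** (`generate_design()`): 10 subjects, 2 sessions of 7 blocks by 73
trials (1022 trials per subject); motion directions from 5:10:355 (no
cardinals); the 36 signed distances (-170:10:180) of both current items to
the previous trial's target each occur exactly equally often; the two items
of a trial never share a color or a distance to the previous target; color
and temporal congruence between consecutive targets are balanced in four
equal cells. Balancing is constructive — balanced attribute pools are
shuffled and chained through the blocks, with a bounded swap-repair pass for
the distance-collision constraint — so the invariants hold exactly rather
than approximately, and generation cannot stall; the repair cap errors with
the offending seed.

**Behavior** (`generate_behavior()`): the response error is the DoG bias
evaluated at the trial's signed distance (amplitude 3.51 degrees, width
0.024 by default, plus `congruence_delta` when the target's color matches
the previously cued color) plus wrapped-normal noise. The noise SD default
of 15 degrees was chosen so simulated error spreads resemble delayed
estimation performance; no heavy-tailed guessing component is modeled, so
the generator is slightly cleaner than real behavior. First trials of a
block receive pure noise.

**Sensor epochs** (`generate_meg()`): each trial and 100-ms bin gets the
sensor vector $g(t)\, C(\theta_{\rm eff})\, W + \varepsilon$: the channel
basis evaluated at the represented direction, mixed into sensors by a fixed
standard-normal matrix per subject (with a small session-specific
perturbation, SD 0.1, so cross-session generalization is nontrivial), a
ramp-plateau temporal gain (zero before onset, linear over the first 300 ms,
then flat — direction information builds up over encoding rather than
appearing instantaneously), and iid Gaussian sensor noise with SD
$1/\mathrm{snr}$. Represented directions can be rotated toward the previous
target (`injected_shift`, per component), and the ITI+trial epoch can carry
additive previous-target reactivations in chosen windows. The S2 epoch also
carries the maintained S1 representation at half gain
(`s1_in_s2_gain = 0.5`), which reproduces the roughly halved fidelity of
that representation relative to the current item.

Two generator defaults deserve explicit justification:

- `snr = 0.035` (sensor noise SD about 29 in channel-signal units) was
  calibrated so the simulated group's plateau reconstruction fidelity lies
  around 0.12, the magnitude reported for MEG delayed-estimation data.
  Cleaner data would make every reconstruction test trivially sharp —
  and, because profile maxima live on an integer grid, would produce
  degenerate bootstrap distributions concentrated on a single value.
- `sensor_count = 30` (not the 271 of a whole-head system) keeps a full
  cohort analysis at desk scale; the full count is available via the
  configuration. With 30 sensors the half-gain S1-during-S2 representation
  sits near the fidelity-detection threshold: its cluster is not found in
  every simulated cohort, and when it is, the cluster-conditioned shift
  estimate scatters widely from cohort to cohort. Averages over many
  simulated cohorts are therefore the meaningful recovery check for that
  analysis, and checks that need per-cohort precision are run at a higher
  signal-to-noise setting.

One estimator property the simulations surface is worth knowing: when a
second, concurrently encoded representation is present in the same epoch
(the S2 stimulus during the S1-during-S2 analysis), its direction is
correlated with the clockwise/counter-clockwise flip frame through the
shared previous target, so after flipping it does not average out into a
flat background. The flip-and-average shift of the weaker representation is
then slightly inflated relative to the injected rotation even at high
signal-to-noise. Any study using this analysis on a balanced
previous-target design inherits the same property.

What the generator does **not** emulate: raw continuous recordings, realistic
forward head models, correlated sensor noise, oscillatory structure,
eye-movement confounds, or guessing behavior. Passing tests show the
analysis chain is correct and unbiased under the stated signal model; they
do not certify performance on real recordings.

## Problem sizes used by the tests and the acceptance script

Unit tests run on single subjects or hand-built fixtures. The end-to-end
recovery checks use full 10-subject cohorts: 40 simulated cohorts for the
behavioral amplitude, 20 for the congruence split, 12 for the retro-cue
shift, and 48 for the S1-during-S2 shift, whose cluster-conditioned
estimator is by far the noisiest (all defined estimates are averaged). The
test suite verifies the S1-during-S2 recovery at a higher signal-to-noise
setting (snr 0.25) where per-cohort precision supports a degree-scale
comparison. The cluster test's type-I error is checked on 200 null cohorts
of 10 subjects by 13 bins.

## Worked example

```{r example}
library(serialshift)

cfg <- sim_config(seed = 1, injected_shift = c(retrocue = 10.22))
run <- run_all(cfg, analyses = c("s1", "retrocue"), do_corr = FALSE)
print(run)
report(run, "results/demo")
```

## Known limitations

- The behavioral likelihood is Gaussian on binned means; a trial-level
  mixture model (guessing, swaps) is out of scope.
- The permutation test for the congruence difference refits both levels per
  permutation on pooled data; hierarchical or mixed-effects variants of the
  DoG are not provided.
- Regularized (ridge) IEM variants, sensor selection and source-space
  modeling are not implemented.
- Between-subject correlations of neural shifts with behavioral DoG
  parameters, and cross-reconstruction generalization analyses, are
  compositions of the exported operations left to the user.
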