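# serialshift

Serial dependence — the attraction of a current report toward what was seen
and reported on the previous trial — is a signature of how working memory
stabilizes perception over time. In two-item retro-cue delayed-estimation
experiments, the bias of the response error as a function of the signed
circular distance `x` between the previous target and the current target
follows a first-derivative-of-Gaussian (DoG) curve,

    y(x) = x a w c exp(-(w x)^2),    c = sqrt(2) e^0.5,

with peak amplitude `a` (degrees, at `x = 1/(w sqrt(2))`) and width scale
`w`. On the neural side, an inverted encoding model (IEM) with 18
direction-tuned channels (`cos((theta - mu)/2)^18`, centers every 20
degrees, 20 shifted-basis iterations) is trained by OLS on one recording
session (`W = (C1'C1)^-1 C1'B1`), inverted on the other
(`C2 = B2 W'(WW')^-1`), and the aligned direction profiles are summarized by
their fidelity `F = mean(r(theta) cos(theta - 180))` and by the displacement
of the flip-and-average profile maximum from the 180-degree center — the
neural analogue of the behavioral bias, positive for attraction toward the
previous target. Inference is non-parametric throughout: participant
sign-flip permutation tests for the DoG amplitude, cluster-based sign-flip
permutation tests over time bins for fidelity and correlations,
participant-resampling bootstrap (10,000 iterations) for the neural shift,
and BH-FDR / Bonferroni corrections across epochs.

The package is for researchers who analyze (or simulate) delayed-estimation
working-memory experiments with multivariate neural recordings. A
synthetic-data generator reproduces the balanced two-item task design (36
signed distances -170:10:180 balanced exactly, 2 sessions x 7 blocks x 73
trials, color/temporal congruence balancing) and direction-tuned sensor
epochs, so the entire chain runs and is tested without any recordings.

## Worked example

Simulate a 10-subject cohort at the study conditions with an attractive
rotation of 10.22 degrees injected into the retro-cue epoch, then run the
behavioral fit and the retro-cue reconstruction:

```r
library(serialshift)

cfg <- sim_config(seed = 1, injected_shift = c(retrocue = 10.22))
run <- run_all(cfg, analyses = c("s1", "retrocue"), do_corr = FALSE)
print(run)
```

```
serialshift pipeline run (config hash 6f3c7284, seed 1)
behavior: a = 3.31 deg (boot SD 0.312), w = 0.0263 (FWHM 43.1), perm p = 0.001
  congruence: a_same = 3.29, a_diff = 3.53, diff = -0.23 (p = 0.748)

reconstruction analyses:
 analysis    epoch label n_bins sig_from_ms sig_to_ms mean_fidelity cluster_p
       s1       s1    s1     13         200      1300         0.112  0.000977
 retrocue retrocue  cued     15         200      1500         0.114  0.000977
 shift shift_p shift_p_fdr
     0  0.3675      0.3675
    10  0.0001      0.0002
```

Reading the output: the behavioral amplitude recovers the generating 3.51
degrees up to the attenuation the 3-SD exclusion rule itself introduces, and
with no congruence modulation generated, the same/different-color amplitude
difference is just cohort noise. Both epochs carry significant direction
information (fidelity about 0.11, cluster p at the 1/1024 permutation
floor). The retro-cue reconstruction is shifted +10 degrees toward the
previous target — recovering the injected 10.22 within the 1-degree profile
resolution — and survives FDR correction, while the S1 epoch, where nothing
was injected, shows no reliable shift.

`report(run, "results/demo")` writes the same numbers as markdown and JSON,
with the generator's ground truth alongside every estimate.

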