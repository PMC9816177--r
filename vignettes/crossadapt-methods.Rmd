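---
title: "Methods: cross-feature adaptation analysis with crossadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-feature adaptation analysis with crossadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossadapt)
```

## The scientific question

When a primate explores a natural scene, successive fixations frequently land
on image patches dominated by different elementary features — one fixation on
an oriented texture, the next on a uniformly coloured region. If each fixation
acts as a brief adapting stimulus, neurons in mid-level visual cortex (area
V4) are constantly adapted *across* feature axes. `crossadapt` implements the
full analysis chain needed to study this regime: scoring image patches for
orientation and colour content, simulating statistics-driven scanpaths,
detecting fixations and extracting pseudo-trials from free-viewing sessions,
quantifying single-neuron circular tuning and its temporal dynamics, and
measuring population-level consequences (noise correlations, shared-variance
decorrelation, and decodability of neighbouring stimuli). A synthetic-data
module generates every input with known ground truth, so each stage of the
pipeline is testable by parameter recovery.

## Circular tuning statistics

A tuning curve is a set of mean responses $r_i \ge 0$ at stimulus angles
$\theta_i$ on a circle of period 360° (colour) or 180° (orientation). The
selectivity index is the normalized circular resultant

$$\mathrm{CSI} = \frac{\left|\sum_i r_i e^{\,i\phi_i}\right|}{\sum_i r_i},
\qquad \phi_i = \frac{360}{\text{period}}\,\theta_i ,$$

so orientation angles are doubled before summation and the index is well
defined on the half circle. The index is 0 for a flat curve (symmetric
cancellation), 1 when a single stimulus drives the neuron, is invariant to
response scaling, and decreases when a constant baseline is added. The
preferred angle is the argument of the same complex sum (halved for
orientation). An all-zero curve is reported as `NA` rather than 0, because
"no response" and "untuned" are different statements.

### Significance: a weighted Rayleigh test

Tuning significance uses the Rayleigh test for circular non-uniformity,
applied to the per-trial stimulus angles weighted by the trial's spike count.
Weighted circular data need an effective sample size. We use the
dispersion-corrected value

$$n_\mathrm{eff} = N\,\frac{\bar w^2}{\operatorname{Var}(w)},$$

which equals the total spike count when counts are Poisson and *shrinks* when
counts are overdispersed, so that shared trial-to-trial fluctuations do not
inflate significance. This choice is self-calibrating: under a Poisson null
the Rayleigh statistic $Z = n_\mathrm{eff}\bar R^2$ is approximately unit
exponential for any mean rate, and the package's Monte-Carlo calibration test
verifies a 5% type-I error within its binomial confidence band. A fixed cap
on $n_\mathrm{eff}$ is also available (`max_n_eff`) but is not the default: a
hard cap at the trial count makes the test arbitrarily conservative whenever
mean counts exceed one spike per trial.

### Time-resolved tuning and latency

`sliding_tuning()` evaluates CSI and the Rayleigh p-value in 200-ms windows
sliding by 5 ms, corrects the window-wise p-values with the Holm step-down
procedure (the family is all windows of one neuron in one condition), and
defines tuning latency as the first window start with corrected significance.
Latency differences between conditions are therefore resolved on the 5-ms
grid; because single-neuron latency estimates are threshold crossings they
are heavy-tailed, and the pipeline reports the across-neuron mean. The
time-resolved generator embeds the response onset well inside the epoch
(default 250 ms into a 600-ms epoch) — if the onset is too close to the
epoch start every window is significant and latency differences are
unresolvable.

## Population statistics

**Noise correlations.** Pearson correlations of trial-to-trial responses at
fixed stimulus, averaged over the stimuli of a feature. Neurons with peak
rates below 5 spikes/s are dropped; within each stimulus, trials where either
neuron of a pair has $|z| > 3$ are excluded *pairwise* (implemented as
pairwise-complete correlations over masked entries, which is exactly the
either-neuron rule). The implementation is cross-checked in the tests against
an independent two-pass Pearson computation at $10^{-12}$ tolerance.

**Projected-PC variance ratio.** Principal components are fitted to the
unadapted trials-by-neurons matrix; the activity of both conditions is
projected onto those axes and the per-axis variance ratio
(unadapted / adapted) is averaged over the leading components that capture
90% of the unadapted variance. A mean ratio above 1 indicates reduced shared
variability — decorrelation — under adaptation. Design choices worth knowing:

* Each condition is centered by its own per-neuron means, so mean-rate
  changes do not masquerade as variance changes.
* Neurons whose unadapted response variance exceeds the across-neuron mean by
  more than 2 s.d. are removed before the PCA.
* The ratio is computed on 100 subsampled repeats (80% of the smaller
  condition's trials) to obtain a resampling s.d. When both conditions have
  the same trial count the same subsample indices are used in both; for
  independent conditions this leaves the statistic's distribution unchanged,
  and it guarantees that identical inputs give a ratio of exactly 1 on every
  axis.
* Because the axes are fitted to one finite sample and evaluated in-sample
  for that condition, the statistic carries an overfitting bias above 1 at
  session-scale trial counts even for equal covariances. This is a property
  of the fit-on-control design itself; the package's null-contrast tests use
  large trial counts, where the bias vanishes, and all directional claims
  compare parameter settings under the identical protocol.

**Decoding.** Two neighbouring stimuli (22.5° apart in colour, 11.25° in
orientation) are classified from population spike counts with a linear
discriminant. The pooled within-class covariance is regularized by
Ledoit-Wolf shrinkage toward a scaled identity, so sessions with more neurons
than trials remain well conditioned. Each of 500 iterations draws a
stratified random 70/30 train/test split; accuracy is averaged and reported
above the 50% chance level. The reported standard error uses the
Nadeau-Bengio correction $s\sqrt{1/K + n_\mathrm{test}/n_\mathrm{train}}$;
the naive $s/\sqrt{K}$ ignores the overlap of repeated splits and understates
the uncertainty of the protocol by an order of magnitude. Repeated-split
cross-validation on a single null dataset is known to carry a small negative
bias (train/test anticorrelation in a finite sample), visible as null
accuracies a fraction of a percent below chance on average.

## Image-patch features

Orientation content uses a 3×3 Sobel filter on the luma image
(0.299R + 0.587G + 0.114B; the conversion is a package choice). The
per-pixel orientation is $\mathrm{atan2}(G_y, G_x)$ mapped to $[0°, 180°)$ —
the convention, fixed by hand-evaluating the kernel on a brightness ramp, is
that a ramp along x (vertical stripes) maps to 0°. Borders use symmetric
(edge-replicating) reflection. Patch statistics come from the 36-bin,
5°-wide, magnitude-weighted orientation histogram: the patch OSI and mean
orientation are the doubled-angle circular resultant of the histogram, and
orientedness is tested with the Rayleigh test using the pixel count as the
effective sample size.

A patch is **oriented** when that test is significant ($p < 0.05$) *and* the
orientation histogram has exactly one peak, peaks being circular local maxima
exceeding the mean bin weight by more than 3 s.d. — patches containing
several orientations are excluded from the oriented class. We apply this
single-peak rule to the orientation histogram itself rather than to the
distribution of sub-window OSI values: sub-window OSIs are near 1 for every
sub-window of a two-grating patch, so their distribution is unimodal exactly
when it should not be, and with 25 sub-windows the 3-s.d. peak rule is
degenerate.

A patch is **coloured** when (a) each smoothed RGB channel histogram peaks
away from black and white (within $[\Delta, 255-\Delta]$, $\Delta = 30$),
(b) the three channel peaks do not all lie within a $\Delta$-wide band of
each other (this rules out gray patches; the criterion is deliberately the
"not all three together" reading), and (c) the patch is not significantly
oriented. Channel peaks are modes of width-5 moving-average-smoothed 256-bin
histograms, ties broken toward the lower value. Everything else is
**neither**. `feature_map()` applies the classifier to 50×50 windows moved by
10 px, using only full windows.

## Scanpath simulation

`fit_saccade_model()` bins observed saccade amplitudes (0.5°) and directions
(10°) into empirical histograms; sampling draws a bin by mass and then
uniformly within it. `simulate_scanpath()` draws amplitude and direction
independently per saccade, re-samples landings that fall outside the image
(up to 20 retries, then clips), and labels the patch under each fixation —
directly, or via the nearest window of a precomputed feature map (the same
classifier either way). Iso-feature transitions join two patches of the same
feature class, cross-feature transitions join colour with orientation, and
transitions touching a `neither` patch are tallied separately; because the
denominator for the cross-feature percentage is ambiguous, both the
all-transitions and the feature-transitions-only percentages are reported.

## Eye events

Fixations are detected by thresholding eye speed (central differences at
1 kHz, 7-ms moving average) at 100 deg/s; runs shorter than 50 ms are
discarded as jitter-induced splits (both constants configurable; they are
package choices). Microsaccades are within-fixation excursions above the
fixation's mean speed + 3 s.d. that stay below the saccade threshold,
detected on the fixation interior so the sub-threshold tails of flanking
saccades are not counted. Pseudo-trials are directly consecutive fixation
pairs gray→test (unadapted) or adapter→test (adapted); a trial is kept only
when the population's aggregate receptive-field box, translated by gaze,
falls entirely inside one quadrant and inside the monitor. An intervening
fixation on the background invalidates the pair (direct succession is
required). Covariates that could confound the contrast (adapter-fixation
duration, test-fixation duration, pupil size, microsaccade counts and peak
velocities) are compared with two-sided rank-sum tests.

## The synthetic-data generator

The generator defines the study conditions for every test:

* **Tuned populations.** 40 neurons, 16 stimuli (22.5° colour steps or
  11.25° orientation steps), 28 trials per stimulus per condition (~450
  trials/condition), analysis window 200 ms. Mean rates follow a normalized
  von Mises curve `baseline + amplitude * exp(kappa*(cos(p(theta-mu))-1))`
  with baseline 10 spikes/s, amplitude 20 spikes/s, kappa 1.5, and 30% of
  neurons untuned (kappa 0). Trial fluctuations are low-rank:
  `loadings %*% latents + private noise`, with three latent dimensions, the
  first given all-positive loadings so that mean noise correlations are
  positive (~0.1, as in cortical data), latent s.d. 14 spikes/s along a
  unit-norm loading column and private s.d. 3 spikes/s. Counts are
  truncated-at-zero integerized rates — the analyses only ever see windowed
  counts, so no point process is simulated.
* **Adaptation effects** mirror the directions reported for cross-feature
  adaptation: a small gain decrease (0.967, i.e. −3.3% firing rate), a
  concentration boost of +0.4 (calibrated so the mean CSI increase is ≈0.04,
  the magnitude reported for real populations), a shared-latent shrink of
  0.7 (magnitude not reported anywhere; chosen once as a moderate
  decorrelation), and a 20-ms latency shift in the time-resolved mode.
  Because the boost applies to all neurons, initially untuned neurons gain
  tuning — the emergence phenomenon — but in the generator essentially *all*
  untuned neurons do, whereas real populations are heterogeneous (only a
  fraction becomes tuned and some neurons lose tuning). The generator
  exposes the per-neuron parameters needed to model heterogeneity but takes
  no stance on its distribution.
* **Scenes.** Gray or pink-noise backgrounds with non-overlapping achromatic
  sinusoidal gratings (oriented) and uniform colour fields (coloured); the
  grating's brightness varies along the configured angle so its Sobel
  orientation equals the ground-truth label. Scene surrogates do not
  reproduce natural-image statistics — passing tests show the pipeline's
  bookkeeping and classifier are correct, not that natural scenes contain
  any particular cross-feature fraction.
* **Eye traces.** 1-kHz gaze with log-normal fixation durations (median
  250 ms), minimum-jerk saccades whose peak velocity follows a saturating
  main sequence (so inter-quadrant saccades peak far above 100 deg/s),
  optional microsaccades (out-and-back minimum-jerk excursions, peak
  40 deg/s, below threshold), an AR(1) pupil series, and optional gaze
  noise (zero by default so detection can be validated exactly).
  Ground-truth fixation intervals are recorded as the runs where the
  analytic eye speed stays below the 100 deg/s threshold, which makes the
  truth detector-independent while remaining recoverable by any
  velocity-threshold detector.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen as the
package's own standard configurations: sessions of 40 neurons × ~900 trials;
decoding with 100–500 split iterations; PC ratios on 30–100 subsampled
repeats; scene runs of 940 images × 300 saccades (the full bookkeeping
total of 282,000 transitions); Monte-Carlo calibrations on 1,000 simulated
neurons. Degenerate inputs are handled explicitly: all-zero tuning curves
and zero-magnitude patches are `NA`/`osi = 0` cases rather than silent
zeros; a training split that would lose a class cannot occur because splits
are stratified; covariance matrices are ridge-stabilized at `1e-8` times
their mean diagonal. All randomness flows through explicit seeds, and every
generator restores the caller's RNG state.

## Known limitations

* The generator's adaptation effects are homogeneous across neurons; real
  cross-feature adaptation is heterogeneous (emergence, loss, and unchanged
  tuning coexist).
* Scene surrogates have piecewise-constant statistics; cross-feature
  fractions measured on them say nothing about natural images.
* The projected-PC ratio inherits the overfitting bias of the
  fit-on-control design at small trial counts (see above); compare
  conditions, not absolute ratios, when trials are few.
* The decoder treats stimulus pairs only; multi-class decoding is out of
  scope.
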