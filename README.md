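# crossadapt

Analysis toolkit for **rapid cross-feature adaptation** in visual cortical
population recordings. During natural viewing, successive fixations often land
on image patches dominated by *different* elementary features — an oriented
texture on one fixation, a uniformly coloured region on the next — so neurons
in mid-level visual cortex (area V4) are continually adapted across orthogonal
feature axes. `crossadapt` implements the complete analysis chain used to
study this regime, together with synthetic-data generators that emulate the
recordings with known ground truth, so every stage is testable by parameter
recovery.

The package is written tidyverse-style: analysis functions take a data frame
of trials first and return tibbles, fitted result objects have `tidy()` /
`glance()` methods and `autoplot()` panels.

## What it computes

**Single-neuron circular tuning.** For a tuning curve with responses $r_i$ at
angles $\theta_i$ (period 360° for colour, 180° for orientation), the colour /
orientation selectivity index is the normalized vector sum

$$\mathrm{CSI} = \frac{\left|\sum_i r_i\,e^{i\phi_i}\right|}{\sum_i r_i},
\qquad \phi_i = \tfrac{360}{\mathrm{period}}\,\theta_i,$$

0 for an untuned neuron and 1 for one driven by a single stimulus; the
preferred angle is the argument of the same sum. Significance uses a
rate-weighted Rayleigh test with a dispersion-corrected effective sample
size; time-resolved tuning (200-ms windows sliding by 5 ms, Holm-corrected)
yields the tuning latency.

**Population statistics.** Pairwise spike-count noise correlations
($r_{sc}$, per stimulus, with peak-rate and outlier-trial exclusions); the
projected principal-component variance ratio (PCs fitted to the unadapted
condition, both conditions projected, per-axis ratio averaged over the PCs
capturing 90% of unadapted variance — a mean ratio above 1 means the
population decorrelated under adaptation); and cross-validated linear
discriminant decoding of neighbouring stimulus pairs (shrinkage-regularized,
70/30 splits, 500 iterations, reported above the 50% chance level).

**Images, scanpaths and eye movements.** Sobel-filter orientation fields and
36-bin orientation histograms score 50×50-px patches for orientation content
(OSI) and classify them as `oriented` / `colored` / `neither`; empirical
saccade amplitude/direction models drive simulated scanpaths whose
iso-feature versus cross-feature transitions are tallied; fixations are
detected from 1-kHz eye traces by a 100 deg/s velocity threshold, and
consecutive fixation pairs (gray→test, adapter→test) become unadapted and
adapted pseudo-trials with receptive-field-confinement filtering and
confound-covariate comparisons.

Three pipelines tie it together: `run_fixation()` (passive-fixation
adaptation session), `run_freeview()` (four-quadrant free-viewing session),
and `run_scenes()` (natural-scene scanpath simulation).

## Worked example

Simulate one passive-fixation session (40 neurons, 16 colour stimuli, 28
trials per stimulus per condition) in which adaptation slightly reduces firing
rates (−3.3% gain), sharpens tuning (κ boost 0.4), and shrinks shared
variability (latent s.d. × 0.7), then run the whole analysis:

```r
library(crossadapt)
rep <- run_fixation(fixation_config(seed = 1, n_iterations_decode = 100))
glance(rep)
```

```
experiment        = fixation-color-test
delta_csi         = 0.0294     # mean CSI increase after adaptation
frac_newly_tuned  = 1          # untuned neurons that became tuned
delta_fr_pct      = -4.35      # % change in peak firing rate
delta_latency_ms  = 21.7       # tuning-latency increase (20 ms generated)
mean_rsc_unadapt  = 0.101      # mean noise correlation before adaptation
pc_mean_ratio     = 1.20       # unadapt/adapt variance along unadapted PCs
decode_unadapt    = 46.8       # % above chance, neighbouring colour pair
decode_adapt      = 48.4
decode_delta      = 1.63       # decoding improvement after adaptation
```

The session recovers the generated effect directions: tuning strengthened
(`delta_csi > 0`), population variance along the unadapted principal axes
dropped (`pc_mean_ratio > 1`, i.e. decorrelation), decoding of the
neighbouring stimulus pair improved, and the tuning latency increased by the
generated ~20 ms. `autoplot(rep$pc_ratio)` draws the per-axis ratio panel;
`tidy(rep$noise$unadapt)` returns the pairwise correlation table.

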