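---
title: "Oscillatory EEG correlates of arithmetic strategies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oscillatory EEG correlates of arithmetic strategies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

When children solve an arithmetic problem they either retrieve the answer
directly from memory or compute it with a procedure (counting,
decomposition). The two routes leave different oscillatory signatures in
the EEG: fact retrieval is accompanied by an *increase* of theta-band
power relative to a pre-stimulus baseline (event-related synchronization,
ERS), while procedural computation produces a *decrease* of alpha-band
power (event-related desynchronization, ERD) that scales with task
demands. `oscarith` implements the complete analysis chain that turns raw
multi-channel EEG plus trial events into per-condition ERD/ERS values and
mixed-effects inference — and, because raw children's EEG cannot be
bundled, a synthetic-data generator that reproduces the statistical
structure the chain assumes, so every stage is testable end to end.

## The ERD/ERS measure

For each frequency band the continuous signal is band-pass filtered and
squared, giving instantaneous band power. Per trial and channel, the
*median* power over the baseline window ([-1.25, -0.25) s before problem
onset, inside the fixation period) and over the activity window ([0, rt),
problem onset until the verbal response) are taken — *horizontal
averaging*. Within a condition (one participant, strategy, operation),
the *median across trials* of the baseline powers gives B and of the
activity powers gives A — *vertical averaging*. The condition value is

    ERD/ERS = (A - B) / B * 100%

negative for desynchronization, positive for synchronization. The order
matters: the ratio is formed **after** the across-trial medians, never
per trial. A deliberately wrong per-trial-ratio implementation fails the
fixture {(B, A)} = {(1, 5), (2, 4), (10, 11)}: medians-then-ratio gives
+150%, ratio-then-median +100%; the test suite pins the former.

Bands are theta (3-6 Hz), lower alpha (8-10 Hz), and upper alpha
(10-13 Hz). 10 Hz lies on the shared edge of the alpha bands; both
filters place their -6 dB point there, so a symmetric overlap at the
edge is accepted.

Per-channel values are averaged (arithmetic mean) within four regions of
interest per hemisphere — frontal, fronto-temporo-central,
centro-parietal, parieto-occipital. The channel-to-ROI assignment is a
reconstruction from a montage figure that shows the regions only as
colours; it is therefore an explicit, overridable argument
(`roi_map_default()`). Midline channels Fz, Cz, Pz, Oz belong to no ROI.

## Numerical choices

* **Band-pass filters** are zero-phase Hamming-windowed FIRs with a
  transition bandwidth of 25% of each band edge (1 Hz floor), applied by
  FFT convolution with the group delay removed. With this design the
  passband is flat, so a pure in-band sinusoid of amplitude *a* yields
  mean power within 2% of *a²/2* — the oracle the tests use.
* **Windows are half-open**; the sample at onset belongs to the activity
  window. Samples under the artifact mask are dropped from the medians; a
  trial is unusable when less than half of either window survives.
* **Band power is computed at 64 Hz** after zero-phase anti-alias
  decimation. All analysis bands end at 13 Hz, far below the reduced
  Nyquist of 32 Hz, and the short filters this permits keep a
  full-cohort run on one core within minutes. The decimation filter
  protects everything below 13 Hz and attenuates everything that could
  fold back onto that range.
* **Activity window is the full [0, rt)**: no post-onset latency is
  excluded. Filter-length smearing around the onset affects baseline and
  activity windows symmetrically and is part of the time-frequency
  resolution trade-off inherent to the band definitions.
* **Quartiles** use linear interpolation (type 7), and response-time
  summaries pool trials across participants within a cell, matching the
  min/max semantics of trial-level summaries.

## Cleaning pipeline

The cleaning chain mirrors standard practice: bad channels, common
average reference over good channels, artifact-segment masking, then
ICA-based ocular removal. The original channel selection and artifact
marking that this chain stands in for were manual and visual; here every
step is an automated surrogate with explicit thresholds so that runs are
reproducible:

* *Flat* channels: robust amplitude spread (MAD) below 0.5 µV.
  *Noisy* channels: robust z-score of log variance above 5, with the MAD
  denominator floored at 0.4 so that near-identical channel variances
  cannot make moderate outliers (such as blink-laden frontal channels,
  which ICA must see) look extreme.
* Artifact segments: any good channel beyond 400 µV, or sample-to-sample
  jumps above 100 µV, padded by 250 ms and merged. The amplitude cutoff
  sits above ordinary blink deflections deliberately — blinks are removed
  by ICA, not by masking.
* ICA: symmetric FastICA (logcosh), estimated on a 1 Hz high-passed,
  64 Hz decimated copy of the unmasked good channels; the unmixing matrix
  lives in channel space and is applied to the full-rate data. Component
  count equals the numerical rank of the data (one less than the
  good-channel count after common average referencing). Weights are
  estimated once per session. A component is ocular when its blink-band
  (< 3 Hz) correlation with the mean of Fp1/Fp2 exceeds 0.5 **and** its
  low-frequency power fraction exceeds 0.3; flagged components are zeroed
  and the original data back-projected.
* FastICA convergence: the global fixed-point criterion cannot settle
  when part of the whitened space is near-Gaussian (any rotation of a
  Gaussian subspace is an equally good solution, so those rows random-
  walk). The decomposition is accepted when the global criterion reaches
  1e-4 *or* every identifiable component — absolute excess kurtosis above
  0.5 — has individually stabilized; anything else is an error with
  diagnostics.

## The synthetic-data generator

The generator emulates the study conditions: 31 participants, 32
channels in an extended 10-20 montage at 512 Hz, 80 problems per child in
four blocks with 1.5 s fixation, problem until the verbal response, a
strategy-report phase, and a 1.5 s blank. Behavioral structure:

* Response times are inverse-Gaussian per strategy x operation cell with
  means 2.07, 2.18, 6.44, 10.05 s (retrieval subtraction/multiplication,
  procedural subtraction/multiplication) and shape = 3x the mean, which
  reproduces right-skewed distributions with realistic spread.
* Correctness is Bernoulli with cell probabilities 0.980, 0.978, 0.910,
  0.915.
* Verbal reports equal the size-consistent strategy except for a
  misreport probability of 0.118 and an "unknown" probability of 0.013,
  the rates implied by the observed size-by-report table.

Oscillations are carriers at the band centres (4.5, 9, 11.5 Hz), which
keeps the injected energy inside the analysis passbands. The amplitude is
`a_B` (20 µV) outside and `a_B * sqrt(1 + target/100)` inside each
activity window, with 100 ms raised-cosine ramps, so the injected ERD/ERS
equals the configured target exactly in the noiseless limit. Default
targets are the condition means per band: theta +22.0%/+11.1%
(retrieval/procedure), lower alpha +3.48%/-1.83%, upper alpha
-8.84%/-11.48%. Each channel carries its own random carrier phase: a
perfectly coherent scalp-wide oscillation would be almost entirely
subtracted by common average referencing, whereas incoherent phases make
the rhythm nearly CAR-invariant — also the physically more plausible
picture.

Background activity is 1/f noise, independent per channel (6 µV). One to
three independent ocular sources project a stereotyped ~300 ms biphasic
blink (300 µV peak, 15 blinks/min) dominantly onto Fp1/Fp2/AF3/AF4. These
signal-to-noise figures were settled once, from two constraints: they sit
inside published ranges for children's EEG (spontaneous blink rates of
roughly 8-21/min; frontal blink deflections of 100-400 µV), and they keep
the cleaning stage identifiable — the blink-band residual after *any*
spatial filter is bounded below by sigma_band/(|topography| x blink RMS),
and at these values that floor lies safely under the 10% residual the
quality checks demand. The generator documents them as conditions of the
synthetic study, not as estimates of any real dataset.

What the generator does **not** emulate: volume-conduction geometry
beyond a fixed mixing pattern, non-stationary background spectra, muscle
or movement artifacts, evoked (phase-locked) responses, behavioral
learning effects across blocks, and between-participant variability in
the ERD/ERS targets themselves (participants differ in their trials and
noise, not in their true condition effects — one consequence is that the
participant variance in the band-wise mixed models can legitimately
estimate to zero on synthetic data, triggering the logged
singular-fit refit). Consequently, passing tests demonstrate
that the pipeline recovers known structure from data with this
statistical shape — not that it is robust to everything real childrens'
EEG can contain.

## Inference

Response times (correct, consistency-retained trials) are modelled with a
generalized linear mixed model, inverse-Gaussian error and identity link;
accuracy with a binomial GLMM (logit link); both with fixed effects
strategy, operation, their interaction, and a participant random
intercept. Factors are coded sum to zero and each term is tested with a
type-III-style likelihood-ratio chi-squared test (the full model against
the model without that term's columns). If the inverse-Gaussian fit
fails, the implementation falls back — with a logged warning — to a
linear mixed model on log response times.

ERD/ERS values are analysed per band with a linear mixed model: full
factorial operation x strategy x ROI x hemisphere plus a participant
random intercept, F tests with Satterthwaite denominator degrees of
freedom. In the balanced 31-participant design each band contributes
992 records and the structural residual degrees of freedom are
992 - 32 - 30 = 930, which the tests check. Estimated marginal means and
Tukey-adjusted pairwise contrasts come from `emmeans`; the
strategy x ROI x hemisphere family has 16 cells and therefore 120
contrasts. The three bands are modelled separately with no cross-band
correction.

## Problem sizes in the test suite

The suite exercises the full chain at the scale of the study — one
31-participant run (2,976 ERD/ERS records) shared by the end-to-end
checks — plus reduced fixtures (one to two participants on subsets of the
problem set) for signal-level properties. Type-I error calibration draws
null replicates with 10 participants each and checks that every model
term rejects at the nominal 5% level within [0.02, 0.09]; the replicate
counts (800 for the 15-term ERD/ERS model, 400 for the three-term
behavioral models) keep the Monte-Carlo standard error of each estimated
rate well below a percentage point, so the check reflects calibration
rather than sampling luck. These sizes are the package's choices for a
thorough yet single-core-friendly suite.

## Known limitations

* The channel-to-ROI map is a reconstruction; analyses that depend on
  exact ROI membership should treat it as configurable input.
* Automated cleaning surrogates approximate, but cannot reproduce,
  expert visual artifact screening; thresholds are exposed in
  `preproc_config()`.
* The ocular detector keys on frontal blink topography; lateral eye
  movements with antisymmetric frontal fields would need an additional
  criterion.
* Recordings are exchanged as in-memory objects; the events table is the
  only file interface for raw data (TSV, millisecond precision).
* Reported denominator degrees of freedom use the Satterthwaite
  approximation; other software may print slightly different values for
  unbalanced data.
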