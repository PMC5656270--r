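---
title: "Counting chews from jaw-motion sensor signals: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting chews from jaw-motion sensor signals: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chewmeter)
```

## The problem and the signal model

A jaw-worn strain sensor (e.g., a piezoelectric film below the ear)
converts the bending of the jaw during mastication into a voltage time
series. Each chew — one jaw open–close cycle — appears as one
peak-and-valley excursion. Chewing is quasi-periodic at roughly 0.94–2
chews per second, interleaved with rest, talking, head motion, and other
broadband activity. The quantities of interest per chewing sequence $k$
are the chew count $CNT(k)$, its duration $D(k)$, and the chewing rate
$CR(k) = CNT(k)/D(k)$; per visit (meal) these aggregate to the cumulative
count $ACNT = \sum_k CNT(k)$ and mean rate $ACR = \tfrac1N \sum_k CR(k)$
(annotated), with $ECNT$/$ECR$ their estimated counterparts.

## The counting procedure

1. **Demean.** The whole recording has its mean subtracted; strain
   front-ends drift, and every later stage assumes a zero-mean signal.
2. **Low-pass.** A 4th-order Butterworth at 3 Hz, applied
   forward–backward. 3 Hz sits above the fastest plausible chewing
   (≈2.5 chews/s) and below speech and motion bands.
3. **Adaptive threshold.** Per segment, $T = \mathrm{quantile}(x, \alpha)$
   with $\alpha \in [0.80, 0.97]$. A fixed voltage threshold cannot work:
   amplitude varies by an order of magnitude across subjects (adiposity,
   sensor placement) and foods. A quantile threshold makes counting
   exactly invariant to positive gain — a property the test suite asserts
   over gains 0.1–10.
4. **Threshold, smooth, count.** Samples at or below $T$ are zeroed, the
   result is smoothed with a 100-sample moving average, and local maxima
   at least 0.3 s apart are counted.

The assumptions are that each chew contributes one dominant peak
surviving the 3 Hz low-pass, and that within a segment the upper
$1-\alpha$ amplitude fraction is dominated by chew peaks rather than
artifacts.

### Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `cutoff_hz` | 3 | Hz | above chewing band, below speech/motion |
| `order` | 4 | — | steep enough roll-off; stable at low normalized cutoff |
| `alpha` | 0.90 (calibrate per study) | quantile level | mid-grid neutral default; `calibrate_alpha()` should be preferred |
| `min_separation_s` | 0.3 | s | just under the period of the fastest chewing (~2.5 chews/s); without a refractory rule, ripples double-count |
| `smooth_window` | 100 | samples | small-amplitude variation suppression after thresholding |
| `epoch_s` | 5 | s | captures most chewing sequences (mean bout 7.35 ± 5.16 s) while guaranteeing several cycles per epoch even at 0.94 Hz |
| `n_hidden` | 5 | units | selected by the repeated-CV elbow rule in `select_hidden_units()` |

### Calibrating $\alpha$

`calibrate_alpha()` draws a seeded subset of visits (default 20) and runs
leave-one-visit-out: for each held-out visit, the grid value (0.80–0.97,
step 0.01) minimizing the mean absolute percent error over the remaining
visits is recorded, and the calibrated $\alpha$ is the mean of the
per-fold optima. The subset draw is seeded because a calibration that
cannot be reproduced is not a calibration. Ties on the error curve break
to the smallest $\alpha$ (lower thresholds are the safer failure mode:
extra weak peaks rather than missed chews).

The trade-off the grid search navigates: a high $\alpha$ places $T$ close
to the typical peak amplitude, so chews with below-typical peaks are
missed (undercounting); a low $\alpha$ admits secondary ripples and
artifacts (overcounting). On signals whose chew strikes are brief
relative to the chewing period — high crest factor, as strain bursts are —
the optimum sits toward the low end of the interval; on
nearly-sinusoidal signals it moves up.

## Epoch classification (fully automatic mode)

The recording is cut into non-overlapping 5-s epochs anchored at $t = 0$
(no anchor is canonical; a fixed one is deterministic), a trailing
partial epoch is discarded. Ground-truth labels follow the 50% rule: an
epoch is intake ($C_i = +1$) iff at least half of it overlaps annotated
intake intervals, computed on half-open intervals $[start, end)$ so that
epoch overlap arithmetic is unambiguous; "at least half" is inclusive.

Each epoch yields 38 features, 19 time-domain (mean absolute value, RMS,
variance, SD, peak-to-peak, median absolute deviation, skewness,
kurtosis, zero crossings, mean-crossing rate, slope-sign changes,
waveform length, log energy, 16-bin amplitude-histogram entropy, 10/25/
75/90th percentiles, IQR) and 19 frequency-domain from a Hann-windowed
periodogram (total power; relative power in 8 bands 0–1, 1–2, 2–3, 3–5,
5–10, 10–50, 50–500, 500–Nyquist Hz; dominant frequency and its power;
spectral centroid, spread, entropy; spectral edge frequencies at 50/90/
95%; spectral skewness and kurtosis). The exact membership of a
38-feature set is a design choice of this package: the split mirrors the
field's practice of pairing waveform-shape descriptors with band-energy
descriptors — chewing concentrates power at 0.94–2 Hz, while speech and
motion artifacts populate the higher bands (which is also why features
are computed on the raw demeaned epochs, not the 3 Hz-filtered ones: the
discriminative high-band content would otherwise be destroyed).

The classifier is a 38–5–1 feed-forward network, hyperbolic tangent in
both hidden and output layers; the predicted label is the sign of the
output (an output of exactly 0 breaks to $+1$). Features are z-scored
with statistics fitted per training fold only — tanh units saturate on
raw amplitude-scale features, and fitting the scaler on test data would
leak. Training is full-batch backpropagation with Rprop step-size
adaptation, early stopping on a seeded 10% validation split, at most 500
iterations; everything is deterministic given the seed. Repetition
averaging (e.g., the 10 repetitions of the 30-fold hidden-size search)
is driven by derived seeds. The hidden-layer size is chosen as the
smallest size whose mean F1 over folds × repetitions is within 0.005 of
the maximum — an explicit form of the "gains are small beyond $k$ units"
elbow rule; tolerance 0 degenerates to the argmax.

Evaluation uses $F_1 = 2PR/(P+R)$ with precision $P = TP/(TP+FP)$ and
recall $R = TP/(TP+FN)$, intake as the positive class, and the
conventions $P = R = 0$ when their denominators vanish and $F_1 = 0$ when
$P + R = 0$. Leave-one-subject-out cross-validation holds each
participant's epochs out once; no rebalancing of the intake/non-intake
prior is applied.

## Error statistics and method comparison

Per-visit signed percent error is $(ACNT - ECNT)\cdot 100 / ACNT$
(positive = undercount); the report gives the mean signed error, mean
absolute error, and a Student-$t$ interval with $M-1$ degrees of freedom
for the mean signed error (the interval construction is a package
choice; with per-visit errors approximately exchangeable it is the
standard small-sample interval). The mean absolute error always
dominates the absolute mean signed error. Method comparison uses a
standard one-way ANOVA on per-visit cumulative counts
(between/within sums of squares, $F$, $p$, 5% critical value), fitted via
`stats::aov` and cross-checked in the tests against a brute-force
decomposition.

In fully automatic mode, errors compare **visit totals**, not
per-sequence counts: an epoch grid fragments chewing sequences, so a
sequence-level comparison is not well defined. Mean estimated rates in
this mode average only predicted-intake epochs (non-intake epochs carry
no rate); boundary epochs that are partly chewing dilute per-epoch rates
downward, while epochs misclassified as intake — whose adaptive threshold
then sits on noise — inflate counts upward. Both effects are visible in
the synthetic experiments.

## The synthetic generator

`generate_meal()` emulates the laboratory protocol: rest, an eating
episode of chewing bouts separated by pauses, rest. Bout durations are
drawn from 7.35 ± 5.16 s truncated at 1.5 s and chewing frequencies
uniform on 0.94–2.0 Hz — the study conditions the generator encodes — so
annotated chewing rates fall in that range by construction. Each chew is
a 0.22-s raised-cosine strike repeated at the chewing period: burst-like
with a low duty cycle, matching the high crest factor of strain signals
and making the per-bout ground truth well defined (one strike, one
chew). Desk-scale choices fixed once: sampling rate 1000 Hz (all windows
and separations are specified in seconds, so 44.1 kHz runs are
configuration-only), 30-s lead/trail rest, 8–14 bouts per meal, 2–10 s
pauses, 0.5 V base amplitude with 15% per-chew jitter, 0.05 V slow
sinusoidal drift, 2 artifacts/min (biphasic motion spikes and 100–400 Hz
speech-band bursts), per-subject gain log-uniform on 0.3–3. All
randomness flows from one master seed; meal $(s, v)$ uses the derived
seed $(seed \cdot 10007 + 101 s + v) \bmod 2^{31}$.

What the generator does **not** emulate: food-dependent waveform shape
and within-bout amplitude decay as the bolus softens, realistic speech
prosody, chewing-while-talking overlap, swallows, or biomechanical
jaw–sensor coupling. Synthetic signals are cleaner than real recordings —
the separability of intake vs. non-intake epochs is higher, and counting
errors are smaller than what real data would produce. Passing the
recovery tests therefore demonstrates correctness of the pipeline's
mechanics (exact counting on clean pulse trains, calibrated behavior
under noise, gain invariance, no information leakage in
cross-validation), not field accuracy.

A separate constructed fixture (`generate_alpha_cohort()`) checks
calibration recovery: each visit mixes 20 strong chews, 4 weak chews at
0.56 relative amplitude, and 4 uncounted distractor bumps at 0.52,
padded so the sample mass above the weak peaks is just under 10% and
above the distractor peaks just over 10%. The quantile threshold then
crosses the distractor peaks near $\alpha = 0.894$ and the weak-chew
peaks near $\alpha = 0.906$: every grid value below 0.90 overcounts,
every one above undercounts, and only 0.90 is exact — a sharp,
analytically placed optimum the calibrator must find.

## Numerical choices

* **Filter family.** The low-pass family is unspecified by the procedure
  itself; a Butterworth was chosen for its maximally flat passband, and
  zero-phase (forward–backward) application because group delay would
  shift peak positions. Before filtering, the signal is mirror-reflected
  at both ends (10 cutoff-periods of padding) — the filtering routine
  starts from a zero state, and without padding its edge transients
  attenuate peaks near the boundaries; mirror rather than
  value-continuing reflection, because the latter injects a DC step of
  twice the endpoint value that a low-pass passes straight back into the
  signal.
* **Percentile.** The linear-interpolation order statistic
  (`stats::quantile` type 7), so a constant segment thresholds at its own
  value and counts zero peaks.
* **Peak detection.** Strict rise into the candidate, non-strict fall
  out, so plateaus (created when smoothing widens a retained nub beyond
  its support) are counted once, tie broken to the earliest sample. The
  minimum-separation rule keeps the strongest peak in any conflict,
  earlier on equal height. The implementation is cross-checked against
  `pracma::findpeaks` with a plateau-tolerant pattern.
* **Moving average.** Centered, shrink-to-valid at the edges: constants
  are preserved and no boundary peaks are fabricated.
* **Degenerate conventions.** Amplitude-histogram entropy of a constant
  epoch is 0; dominant frequency and all spectral-shape features of a
  zero-power epoch are 0; visits with no intake segments report
  $ECNT = 0$ and $ECR = 0$ and are excluded from cross-visit rate
  averaging; the relative-power band capped at Nyquist includes the
  Nyquist bin.
* **Smoothing order.** The 100-sample moving average is applied *after*
  thresholding (at 1000 Hz this is 0.1 s, a meaningful smoother; at
  44.1 kHz a 100-sample window spans only 2.3 ms, so the stage's effect
  is rate-dependent — another reason the package works natively at
  1 kHz and treats other rates as configuration).

## Problem sizes

The test suite and the acceptance script run desk-scale experiments
chosen to exercise every pipeline stage: a 30-meal cohort (10 subjects ×
3 visits, ≈3 minutes of signal per meal at 1000 Hz) with bout SNR 10 dB
for parameter recovery and leave-one-subject-out evaluation, a 20-visit
calibration subset, exactness grids over {5, 10, 20, 30} chews ×
{0.94, 1.2, 1.5, 2.0} Hz, and 1000-case random oracles for the rate,
error, and F1 formulas.

## Known limitations

* Fixed-size epochs fragment chewing sequences; chews in boundary epochs
  that fall under the 50% rule are structurally lost, which biases the
  fully automatic mode toward undercounting when the classifier is
  accurate. Segmenting variable-length chewing sequences before
  classification would remove this bias but is out of scope.
* The per-segment threshold adapts to whatever the segment contains; on
  epochs misclassified as intake it adapts to noise and fabricates
  counts. A per-participant global threshold would mitigate this at the
  cost of individual calibration.
* The counter assumes one dominant peak per chew after 3 Hz filtering;
  double-peaked strikes (hard then soft contact) would need a wider
  refractory separation.
* Synthetic validation bounds implementation correctness, not field
  performance; real recordings with video-annotated references remain
  necessary for accuracy claims.
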