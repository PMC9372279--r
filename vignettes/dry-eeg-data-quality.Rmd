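---
title: "Quantifying ERP data quality in at-home dry-EEG studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ERP data quality in at-home dry-EEG studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dryerp)
```

## The problem

Event-related potentials (ERPs) recorded at home with dry-electrode EEG are
noisier than laboratory recordings with gel electrodes, but they can be
collected near-daily by the participants themselves. The question this
package addresses is quantitative: **how many at-home trials — and therefore
recording sessions — must be aggregated before a self-administered dry-EEG
ERP score is as precise as a single supervised wet-EEG session?**

Precision is measured by the Standardized Measurement Error (SME) of a
windowed ERP amplitude score. For participant $i$ with $n_i$ usable trials
whose single-trial scores have standard deviation $\sigma_i$,

$$\mathrm{SME}_i = \frac{\sigma_i}{\sqrt{n_i}}.$$

The score is a time-window mean: for oddball target trials, the mean voltage
at Pz over 300–400 ms post-stimulus (younger adults) or 400–500 ms (older
adults, whose P300 peaks about 100 ms later); for flanker trials, the mean
voltage at FCz over 0–100 ms post-response, separately for correct responses
(correct positivity) and errors (error-related negativity). Trials are
aggregated *sequentially across sessions in recording order*, so
$\mathrm{SME}(n)$ always uses a participant's first $n$ surviving trials.
Group curves average the per-participant SMEs at each $n$ over the
participants who still have $n$ trials available; that count is reported
alongside, because it shrinks as $n$ grows.

Given the trial count $n^*$ at which the group curve crosses a wet-EEG
reference SME, the number of at-home sessions needed is projected as

$$\left\lceil \frac{n^*}{\text{trials presented per session} \times
(1 - \text{rejection fraction})} \right\rceil,$$

i.e. demand divided by the expected post-rejection yield per session.
With the published inputs this reproduces the headline projections
(2 sessions for the younger-cohort oddball target, 4 and 3 for younger
flanker correct/error, 3 for the older oddball target). The wet-EEG
reference values (SME 1.83 / 0.51 / 1.68 uV; 30.5 / 337 / 40.1 surviving
trials from 40 / 352.1 / 42 presented) come from the ERP CORE laboratory
dataset and ship as documented constants in `reference_benchmarks()` — they
are inputs, not quantities this package recomputes.

## The pipeline

1. **Filtering** — per-channel 4th-order Butterworth band-pass, 0.25–40 Hz,
   applied forward–backward (`signal::filtfilt`). Zero phase matters: the
   score windows are fixed latency bands, and a causal filter would shift
   the P300 peak into or out of them.
2. **Epoching** — one epoch per qualifying event over the half-open window
   $[-500, 1000)$ ms (375 samples at 250 Hz; the $t=0$ sample belongs to the
   epoch). Events whose window exceeds the recording are dropped with a
   warning, never zero-padded — padding would corrupt the spectral metrics.
3. **Baseline adjustment** — subtract the per-epoch, per-channel mean over
   $[-100, 0)$ ms (stimulus-locked) or $[-500, -400)$ ms (response-locked).
   Idempotent by construction.
4. **Staged rejection**, independently per channel and condition:
   a. absolute amplitude strictly above 100 uV;
   b. Pearson correlation below 0.25 against the *session average* (the
      mean of currently retained epochs of that channel and condition,
      including the epoch under test; a leave-one-out variant is available
      behind a flag but off by default);
   c. any of seven z-scored metrics — Hurst exponent, kurtosis, median
      gradient, range, variance, SD, high/low-frequency power ratio — with
      $|z| > 15$;
   d. Hurst exponent below 0.65 or spectral peak below 0.1 (absolute
      thresholds);
   e. recomputed $|z| > 4$ over the epochs that remain.
5. **Median ERPs** — pointwise medians across retained epochs (robust to a
   stray extreme epoch), and window-mean scores feeding the SME.

A session *survives* at a channel if at least one epoch of the analysis
condition is retained; per-channel survival percentages over sessions give
the channel-yield accounting.

## Numerical and definitional choices

Several quantities in the procedure are named but not fully specified in
common usage; the package fixes them as follows.

* **Hurst estimator.** Rescaled-range (R/S) over dyadic block sizes (from
  the epoch length down to 16 samples), least-squares log–log slope,
  de-biased by the Anis–Lloyd expected R/S for i.i.d. data. The plain R/S
  slope overestimates H by ≈ 0.05 at epoch length 375; the corrected
  estimator centres white noise at 0.50 (SD ≈ 0.09), integrated noise at
  ≈ 0.95, and 1/f background at ≈ 0.86, so the 0.65 threshold cleanly
  separates EEG-like epochs from noise-like ones.
* **Spectral peak.** Single-segment Hann periodogram over 0.25–40 Hz,
  normalised to unit band power; the "peak" is the maximum bin share, a
  dimensionless number in (0, 1]. Flat (noise-like) spectra give ≈ 0.07 at
  this epoch length, 1/f-dominated EEG ≈ 0.2, so the 0.1 threshold is
  attainable and meaningful under this definition.
* **HF/LF ratio.** Power above 20 Hz over power below 20 Hz from the same
  periodogram, targeting EMG-like broadband contamination.
* **z-score conventions.** Thresholds apply to $|z|$ (two-sided): gradient-
  and power-type metrics can be extreme in either direction. z-scores are
  computed within (session, channel, condition) across retained epochs, and
  *recomputed* between the gross ($|z|>15$) and final ($|z|>4$) gates so the
  final gate is not distorted by the extremes the first one removed. A
  metric that is constant across epochs yields $z = 0$ for all of them —
  degenerate distributions must not reject everything via division by zero.
* **Kurtosis** uses the standard sample estimator from `e1071`.
* **Group SME curve.** Group central tendency is the arithmetic mean of
  per-participant SMEs; the 95% band is $1.96 \times \mathrm{SD}(\mathrm{SME}_i)/\sqrt{N}$
  (the standard error across included participants). Sample SDs use the
  $n-1$ denominator throughout. The curve grid is every integer $n$ from 2
  to the largest trial count any participant reaches.
* **Sequential aggregation order** is session (by date), then within-session
  ordinal, counted from study start.
* **Mann-Whitney U** (usability comparison): exact permutation enumeration
  over the observed pooled values for combined samples up to 20 (ties handled
  exactly), normal approximation with tie-corrected variance and continuity
  correction above — the regime the studies' group sizes (32 vs 18) fall in.
* **Week alignment** for adherence uses rolling 7-day windows from each
  participant's own first session date.

## The synthetic-data generator

No raw at-home recordings are redistributable, so the package ships a
generator whose output has the statistical structure the analysis assumes,
with full ground truth. Each session is:

* **ERP templates** — sums of Gaussian-windowed components with per-channel
  gain maps: stimulus-locked readiness negativity, P1, P2, N2 on a broad
  posterior-weighted topography, plus a P300 for targets (peak 350 ms
  younger / 450 ms older, maximal at Pz); response-locked motor readiness,
  plus a fronto-central correct positivity (0–50 ms) or ERN (50–100 ms,
  maximal at FCz) followed by a posterior Pe. Amplitude and latency vary per
  participant, session, and trial at configurable jitter scales.
* **Background** — pink (1/f) noise, synthesised spectrally over
  0.5–45 Hz, plus a 10 Hz alpha sinusoid with random phase per channel.
  Band-limiting the synthesis makes the 0.25–40 Hz analysis filter nearly
  transparent to the background, which lets the generator record a
  *closed-form* SD of the window-mean score's background component
  (a sum over synthesis lines weighted by the score functional's transfer
  magnitudes); tests verify this against empirical score SDs to ~2%.
* **Artifacts**, one Bernoulli draw per type per epoch, each designed to be
  separable by the rejection machinery: frontal-dominant raised-cosine
  blinks (300 uV, AF7/AF8/FPz/Fz) and broadband 300 uV bursts are caught by
  the amplitude gate; a 1 mV low-frequency ramp ("drift", 0.3 s rise) leaves
  a post-filter onset transient of ≈ 0.26× its excursion, also above the
  gate; a flatlined channel (0.3 uV sensor noise) falls to the correlation
  stage via the r = 0 convention, with the Hurst/spectral stage as backstop.
  Default rates (blink 0.08, drift 0.05, burst 0.05, flatline 0.02) total a
  20% per-epoch contamination load.
* **Timing** — inter-stimulus intervals uniform on 1.5–3.0 s, which is
  exactly the epoch span, so epochs can never overlap; flanker trial onsets
  are spaced from the previous *response*, keeping response-locked epochs
  non-overlapping too. Event times round to integer samples.
* **Determinism** — every (participant, session, task) stream derives its
  seed from the master seed by a documented counter scheme, so a fixed seed
  reproduces recordings bit-for-bit and any single session can be
  regenerated in isolation.

The montage carries the fifteen published 10-10 positions of the dry
headset (O1, O2, P3, Pz, P4, Cz, FT7, FC3, FCz, FC4, FT8, Fz, AF7, AF8,
FPz).

### What the default regime is — and is not

The correlation-to-session-average stage is unforgiving: an epoch whose
channel carries little event-locked signal correlates near zero with the
session average and is rejected even when perfectly clean. Real dry EEG
lives in that regime — the studies discarded 43–74% of trials per session.
A generator with realistic SNR would therefore reject clean epochs en masse
and could not serve as a validation instrument for the rejection stages,
because "clean" and "should be rejected" would no longer coincide.

The defaults consequently put *every* channel and condition in a
high-SNR regime: common evoked components with gain floors around 0.85 and
background pink noise of 2.5 uV SD. Under these conditions roughly 3% of
clean epoch-channel entries are rejected (correlation tails, plus ~1–2%
Hurst/spectral losses intrinsic to 1/f noise at this epoch length) while
100% of contaminated entries are caught. Passing tests therefore certify
that the *machinery* — thresholds, stage order, bookkeeping, SME
propagation — behaves as specified on separable data; they do not certify
yields on real dry-EEG recordings, whose discard rates are an empirical
property of hardware and scalp contact, not of this code. For the same
reason the synthetic SME curves cross the wet reference values at much
smaller trial counts than the published studies did; the headline
sessions-needed numbers are recomputed from the published constants, not
from simulation.

Known additional simplifications: no learning or habituation trends across
sessions, no reaction-time model beyond correct/error labels, every
participant attempts every scheduled session (only data *completeness* is
randomised), and blink artifacts touch only the four frontal channels so
that ground-truth contamination labels stay exact.

### A numerical edge worth knowing

With all noise and jitter disabled, epochs are bit-identical and the
degenerate z-distributions remove nothing — the documented zero-noise
contract. After the 0.25 Hz zero-phase high-pass, however, each template's
DC-removal bow spreads over several seconds, so random inter-stimulus
intervals make *filtered* zero-noise epochs differ at the 1e-4 uV scale;
the $|z|>4$ gate can then fire on that microscopic variation (about 1 entry
in 2000). This is a property of z-scores on vanishing variance, not a
defect; at any realistic noise level it is irrelevant.

Similarly, a single outlying epoch among $n$ can reach at most
$|z| = (n-1)/\sqrt{n}$, so the $|z| > 15$ gate mathematically cannot fire
with fewer than ~227 epochs in a group; with session-sized groups, gross
outliers are caught by the absolute stages or the recomputed $|z| > 4$ gate
instead.

## Parameters that matter

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `filter_band` | 0.25–40 | Hz | analysis band-pass |
| epoch window | [−500, 1000) | ms | relative to locking event |
| `amplitude_uv` | 100 | uV | rejection stage (strict >) |
| `min_correlation` | 0.25 | – | vs session average |
| `z_gross`, `z_final` | 15, 4 | – | two-sided z gates |
| `hurst_min` | 0.65 | – | absolute Hurst floor |
| `spectral_peak_min` | 0.1 | – | normalised peak floor |
| `p300_latency_ms` | 350 / 450 | ms | younger / older cohorts |
| `oddball_targets` / `_nontargets` | 30 / 70 | – | stimuli per session |
| `flanker_trials`, `flanker_error_rate` | 150, 0.15 | – | trials, error rate |
| `pink_sd_uv`, `alpha_amplitude_uv` | 2.5, 0.8 | uV | background regime |
| artifact rates | 0.08/0.05/0.05/0.02 | – | blink/drift/burst/flatline |

All thresholds default to the study's printed values; all generator values
are this package's documented choices where the studies publish none.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen so every
stochastic check has comfortable statistical margin: the contamination-
recovery fixture uses 50 default-regime oddball sessions (≈ 75,000
epoch-channel entries); score-SD recovery uses 10 participants × 2
artifact-free flanker sessions evaluated at n = 100–200 trials (the
recovered quantity is the clean-trial score SD, so contamination leakage
is excluded by construction); SME Monte-Carlo checks use 1000
replicates; estimator calibrations average 200 epochs. The analysis scripts
simulate 5 participants × 4 sessions per cohort and task for the worked
workflow, and full-size manifests (30 × 23, 50 × 15) for adherence
accounting, where no signal processing is involved.

## Limitations

* The generator's high-SNR regime (above) bounds what simulation can say
  about real-world yields; rejection fractions and sessions-needed from
  simulated cohorts are structural demonstrations, not predictions.
* The Hurst threshold behaviour depends on the estimator; a different R/S
  variant (or DFA) would shift the effective operating point of the 0.65
  threshold.
* The spectral-peak threshold is meaningful only under the unit-normalised
  periodogram definition used here; other normalisations rescale it.
* EDF round-trips quantise to 16 bits over each channel's range (worst-case
  error range/65534, ~0.01 uV at typical amplitudes) — negligible for the
  analysis but visible in bit-identity comparisons across the EDF boundary.
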