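---
title: "The risk plot: token dynamics on binned RR intervals for ICU monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The risk plot: token dynamics on binned RR intervals for ICU monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskplot)
```

## The monitoring problem

Reduced heart rate variability (HRV) is a well-established marker of
deteriorating autonomic regulation in critically ill cardiovascular
patients: as a patient approaches death, the beat-to-beat dispersion of the
RR intervals collapses. `riskplot` turns a single-lead ECG into a
beat-resolved risk signal built on exactly this phenomenon, using a
deliberately mechanical mapping — the *risk plot* — rather than an opaque
classifier, so that the state of the display is itself the explanation of
the alarm.

## The risk-plot model

The RR axis is partitioned into `K` contiguous bins, the **stairs**. Each
detected beat contributes one indivisible **token** that lands on the stair
containing its RR interval (half-open bins `[e_k, e_{k+1})`, last stair
closed on the right; out-of-range intervals are clamped to the edge stair by
default, or counted and dropped). After each landing, a **spring** under
every stair throws up to `drain_rate` tokens from that stair into the
**valley of life**, the sink that accumulates successfully cleared tokens.
A stair whose occupancy reaches `capacity` is **stuck**: its spring fails
and it drains nothing further. Because a stuck stair can never fall back
below capacity by draining, stuckness is absorbing until the analysis window
ends. Every `window_beats` processed beats the whole state is reset, which
turns the machinery into a time-resolved signal rather than a single
verdict.

The state obeys an exact conservation law at every step,

```
projected = sum(occupancy) + valley + dropped,
```

which the test suite checks after every projection and drainage event and
which the production engine (C++) must reproduce bit-for-bit against an
independently written token-by-token reference simulator (`rp_reference()`).

### What the dynamics can and cannot do

With one token arriving per beat and one drainage step per beat, a single
stair receives at most one token per beat. It follows that for any
`drain_rate >= 1` the springs always keep pace: occupancy returns to zero
after every beat, nothing ever sticks, and every token reaches the valley.
This is a theorem of the dynamics, not a tuning accident, and the test suite
asserts it (the stationarity test). The stuck/valley machinery therefore
carries information in configurations with suppressed drainage
(`drain_rate = 0`, the pure-accumulation picture of a terminal state) and in
the conservation accounting, while under the default `drain_rate = 1` the
discriminative burden falls on *where* the tokens land — the dispersion of
the projection counts across stairs. The risk index below is built so that
each ingredient (accumulation, stuck springs, starved valley) contributes
one bounded term, whichever regime the configuration puts the machine in.

## The risk index

For each window, with `n_k` the number of beats projected onto stair `k`:

* **concentration** `= 1 - H / log K`, `H = -sum(p_k log p_k)`,
  `p_k = n_k / sum(n_k)` (`0 log 0 = 0`). Zero for perfectly dispersed
  projections, one when a single stair receives everything. Projection
  counts, not terminal occupancy, are used: terminal occupancy is confounded
  by drainage, whereas the counts measure the dispersion of the RR stream
  itself.
* **stuck_fraction**: the fraction of the window's beats during which at
  least one stair was stuck.
* **throughput** `= valley / projected`: the share of projected tokens that
  reached the valley.

```
risk = 0.4 * concentration + 0.4 * stuck_fraction + 0.2 * (1 - throughput)
```

clamped to `[0, 1]`. The risk is invariant under stair relabelling (entropy
symmetry) and each component is individually bounded, both property-tested.

### Why 0.01 s stairs

The stair width is the resolution limit of the instrument: the entropy of
the binned RR distribution cannot distinguish two dispersion levels that
are both far below one stair width. Near-death SDNN sits at 2–10 ms, so
0.1 s stairs would collapse the entire regime of interest onto one or two
stairs (and, when the mean RR sits on a stair edge, make the count
distribution *exactly* Binomial(W, 1/2) regardless of SDNN — provably
uninformative). The default grid is therefore 120 stairs of 0.01 s over
0.3–1.5 s: fine enough that the binned entropy still moves between 2 ms and
5 ms of SDNN, coarse enough that a 300-beat window populates the occupied
stairs densely. With this grid the median window risk is strictly
decreasing across SDNN in {2, 5, 10, 20, 40, 80} ms (Spearman -1 in the
acceptance checks).

### Alarm thresholds

Thresholds are placed between the index ranges the two regimes actually
realise under the default configuration. A healthy profile (SDNN 30–70 ms
with respiratory modulation) spreads its tokens over many stairs:
concentration ~0.3–0.45, no stuck stairs, full throughput, so
`risk ~ 0.12–0.18`. A near-death profile (SDNN 2–10 ms) concentrates on one
or two stairs: concentration ~0.7–0.9+, `risk >= ~0.27`. The defaults
`amber = 0.20`, `red = 0.25` sit in the gap with a margin on both sides;
both are configuration-exposed, and the cohort-discrimination check (AUC of
median risk, 25 vs 25 subjects) passes at 1.0 with them.

## Parameters at a glance

| parameter | default | units | role |
|---|---|---|---|
| `stair_edges` | 0.3–1.5 step 0.01 | s | RR bins; resolution of the dispersion measurement |
| `drain_rate` | 1 | tokens/beat/stair | spring strength; 0 gives the pure-accumulation regime |
| `capacity` | 8 | tokens | occupancy at which a spring fails |
| `window_beats` | 300 | beats | ~5 min at 60 bpm; alarm time resolution |
| `oor_policy` | clamp | — | edge-stair clamp vs counted drop |
| weights | 0.4/0.4/0.2 | — | concentration / stuck / throughput |
| thresholds | 0.20 / 0.25 | — | amber / red |

Windows are counted in *processed* beats: intervals flagged by the quality
mask are neither projected nor drained, and do not advance the window
clock. All sample and stair indices are 1-based.

## The ECG front end

* **Notch filter.** Second-order IIR notch (`Q = 30`) at 50 or 60 Hz.
  Because records are analysed offline, the squared magnitude response of
  the biquad is applied spectrally — the exact zero-phase (forward–backward)
  response with no start-up transient, so R-peak timing is untouched.
  Measured: >40 dB attenuation at the mains frequency, <0.001 dB ripple
  across the 5–15 Hz QRS band.
* **Wavelet denoiser.** Orthonormal periodic Daubechies DWT (db4, level 4;
  the transform is implemented in the package and pinned by
  perfect-reconstruction and energy-preservation tests). Soft thresholding
  at the universal threshold `sigma * sqrt(2 log n)`,
  `sigma = MAD(d_1)/0.6745`, applied to detail levels 1–2 only: at 256 Hz
  those bands (32–128 Hz) are dominated by broadband noise while QRS energy
  lives below. Gains >= 3 dB on ECG at 10 dB SNR while distorting clean ECG
  by < 0.5% RMS.
* **R-peak detector.** Pan–Tompkins-style: zero-phase 5–15 Hz band-pass,
  derivative, squaring, 150 ms moving integration, adaptive dual thresholds
  with a 200 ms refractory period and a search-back pass, followed by apex
  refinement to the local maximum of the input samples within ±100 ms. All
  thresholds are relative, so detection is invariant to amplitude scaling.
* **Quality mask.** Intervals outside 0.2–3.0 s, or deviating >50% from the
  median of the surrounding 11 intervals, are flagged — retained in the
  series but excluded from projection. Deleting them instead would silently
  change the dynamics; `include_flagged` in the pipeline configuration
  projects everything for sensitivity analyses.

## The synthetic generator

`generate_rri()` draws
`rr_i = mean_rr + rsa_amp * sin(2 pi rsa_freq t_i) + e_i` with Gaussian
`e_i` (SD `sdnn`, optionally drifting linearly in time), truncated at
0.25 s. This reproduces the two statistical features the method rests on —
overall dispersion and its collapse — plus a single respiratory component
for short-term structure. It makes no claim to spectral fidelity, ectopy,
atrial fibrillation, or any arrhythmia morphology; a pass on synthetic data
therefore demonstrates the mechanics of the method, not clinical
performance.

`generate_ecg()` renders each beat as five Gaussian waves (P, Q, R, S, T)
at fixed offsets from beat onset, so RR variation is absorbed by the
diastolic pause and the rendered R-to-R spacing equals the driving interval
exactly — which is what makes exact end-to-end recovery checks possible
(and is also how real cycle-length variation behaves; QRS morphology does
not stretch with heart rate). Fixed offsets rather than per-beat fractions
are essential: fractional centres would shift each R by a share of the
beat-to-beat RR difference and make sample-accurate recovery of the
generator's intervals impossible even for a perfect detector.

The default cohort emulates a 50-subject monitoring study: 25 healthy
subjects (mean RR ~ N(0.8, 0.05^2) s, SDNN ~ U(30, 70) ms, 25 ms
respiratory amplitude) and 25 high-risk subjects (SDNN ~ U(2, 10) ms,
suppressed respiration, slow negative SDNN trend), with per-subject seeds
derived from one master seed.

## Numerical choices and degenerate inputs

* Bin assignment is half-open with the last stair right-closed; ties at an
  edge go to the upper stair. Clamping is the default out-of-range policy
  so no token disappears without being counted.
* The DWT pads signals to a multiple of `2^level` by periodic wrap and
  truncates after reconstruction; the padding is never thresholded
  separately.
* Flat-line records yield zero detected peaks (not an error); records
  shorter than 2 s are rejected.
* A stream with no complete window is reported as an explicit
  `partial = TRUE` row, never silently dropped.
* Generation and the cohort are bit-reproducible from their seeds; the
  generator restores the caller's RNG state.

## Problem sizes used in the checks

The package's own validation runs at sizes chosen to exercise the
asymptotics while staying desk-scale: conservation over 10^5 random beats,
engine-vs-reference equivalence over 1000 random streams of 1000 beats
under randomised configurations, the SDNN grid at 20 seeds x 20 windows x
300 beats per SDNN level, and the 50-subject cohort at 3300 beats
(11 windows) per subject.

## Known limitations

* The risk index has not been calibrated against clinical outcomes; the
  alarm thresholds separate the synthetic regimes and are configuration,
  not clinical guidance.
* Single-lead only; no beat-type classification, so sustained arrhythmia
  will be flagged by the quality mask rather than interpreted.
* The spring/capacity machinery is inert under the default
  `drain_rate = 1` (see the theorem above); analyses that want the
  accumulation picture should run `drain_rate = 0` alongside.
* WFDB support covers the single-signal format-16 subset written by this
  package.
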