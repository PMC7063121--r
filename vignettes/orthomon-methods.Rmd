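---
title: "Methods: models, estimators and design choices in orthomon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in orthomon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthomon)
```

`orthomon` analyzes simultaneous PPG, ECG, NIRS and continuous finger-BP
recordings around postural changes, and ships a hemodynamic simulator so
that every stage of the chain can be validated against known ground truth.
This vignette documents the underlying models, the parameters that matter,
the numerical choices, and the places where the design was genuinely open.

## The measurement problem

After standing up, arterial pressure transiently drops, the baroreflex
shortens the inter-beat interval (IBI), and cerebral oxygenation follows
the perfusion pressure. Three derived quantities summarize the regulation:

* **Drop-method baroreflex sensitivity**,
  $\mathrm{BRS} = \Delta\mathrm{IBI}/\Delta\mathrm{SBP}$ (ms/mmHg), where
  each $\Delta$ is the drop from the 60-s pre-onset baseline mean to the
  post-onset minimum within 1 min, measured on 5-s moving-average-filtered
  25-Hz signals.
* **Cerebral autoregulation proxy**,
  $\mathrm{CAR} = \Delta\mathrm{O_2Hb}/\Delta\mathrm{MAP}$ (µM/mmHg), on
  the same windows.
* **PWV**, the reciprocal R-peak-to-PPG-upstroke delay (s⁻¹). This is
  physically a pulse-arrival-time reciprocal — no path length is involved —
  but the field name is retained.

Both BRS and CAR are computed twice: with the measured BP and with BP
estimated from the finger PPG by a per-participant leave-one-repeat-out
linear calibration $BP = \beta_0 + \beta_1\,\mathrm{PPG}$, fitted on the
0–30-s post-onset window of the other repeats. Agreement between the two
variants (Pearson r over participants) quantifies how far a PPG-only
wearable could go.

## The simulator

The generator is organized around deterministic closures for the continuous
MAP/SBP/DBP trajectories; beats, channels and noise draw from RNG streams
derived from the master seed and a per-channel key, so enabling noise on
one channel never shifts another, and the same seed reproduces a session
bit for bit.

**Pressure trajectory.** Baseline is constant plus a Mayer wave (default
3 mmHg at 0.1 Hz, random phase per repeat). From movement onset the
deviation follows a double exponential
$g(t) \propto e^{-t/\tau_r} - e^{-t/\tau_f}$, with the fast constant
$\tau_f$ solved numerically (uniroot on the closed-form peak location) so
the nadir falls exactly at `time_to_nadir` (default 12 s) with depth
`drop_magnitude_map` (default 25 mmHg, scaled per maneuver: 0.8 sit-to-
stand … 1.2 rapid supine-to-stand, 0.4 head-up tilt), recovering with
$\tau_r$ = `recovery_tau` (15 s; ~2.5 mmHg residual at 60 s). The 1-min
squat instead shows a smooth +20-mmHg plateau and the orthostatic drop
after release; the plateau magnitude is a package default, not a reported
value. SBP and DBP deviations are fixed multiples (1.2×, 0.9×) of the MAP
deviation so the identity MAP = DBP + (SBP − DBP)/3 holds exactly.

**Beats.** $IBI_n = IBI_0 - \mathrm{BRS}_{true}\,(SBP_0 - SBP(t_n))$, the
next beat at $t_{n-1} + IBI_n$; because $t_n$ depends on $IBI_n$ the pair
is resolved by a short fixed-point iteration (contraction factor
$\approx \mathrm{BRS}\cdot|SBP'| \ll 1$). IBI below 250 ms aborts as
nonphysiological. Because between-subject spread (truncated ±2 SD
multiplicative draws, CV 0.2) can combine high heart rate, high gain and a
deep drop, each participant's gain is capped so the worst-case SBP drop
cannot push IBI below ~300 ms — a crude baroreflex saturation; the capped
value is that participant's recorded truth, so recovery tests stay exact.

**Channels.** PPG pulses are a gamma-like template (0.25 s wide) placed at
$t_n + PTT_n$ with $PTT_n = a + b\,SBP_n$ ($b<0$), amplitude modulated by
per-beat MAP over an envelope that follows continuous MAP; the placement is
pre-corrected by the template's band-passed derivative-peak offset so that
ground-truth PTT is exactly what the PWV stage measures. ECG is a
triangular R wave per beat; NIRS O₂Hb is
$\mathrm{CAR}_{true}\,(MAP - MAP_0)$ with HHb at −0.3× that deviation
(the anti-correlated ratio is a package choice; the source data only
report HHb qualitatively); optionally the forward modified Beer–Lambert
model emits raw two-wavelength optical densities for round-trip testing.
Trunk tilt is a smooth transition between posture angles over the
maneuver's median duration. Per-device clock offsets and ppm-level drifts
are applied on rendering; a pulse-train sync channel is emitted per device
when enabled.

**What the simulator does not emulate**: respiratory modulation,
waveform-morphology changes, motion artifacts beyond flatline dropouts and
premature low-amplitude artifact beats, baroreflex nonlinearity beyond the
saturation cap, and the sympathetically driven *rise* of PWV after
standing — with PTT tied linearly to SBP, simulated PWV falls during the
pressure drop (its positive correlation with MAP is preserved). Passing
recovery tests therefore shows the chain is unbiased and self-consistent
under the stated couplings, not that it is robust to every artifact class
of ambulatory data.

## Synchronization

The shared reference line carries one 16-slot frame per minute (200-ms
slots), slot $k$ wide if bit $k$ of the minute index is set, LSB first.
Widths are 120/40 ms with an 80-ms decision threshold: at a 50-Hz device
one-sample quantization jitter (20 ms) can then never flip a bit, which a
60/20-ms code cannot guarantee (a jittered wide pulse measures exactly the
40-ms midpoint). Decoding thresholds at 0.5, groups pulses into frames by
the 200-ms spacing (±50 ms), skips and counts corrupted frames. Per
device, marker device-times are regressed on 60·minute — intercept =
clock offset, slope = 1 + drift — and channel start times/rates are
re-expressed on the reference clock. Sessions whose sidecar declares the
devices pre-aligned skip all of this.

## Preprocessing and quality gating

* PPG band-pass: Butterworth order 2 per direction, 0.05–10 Hz, applied
  forward–backward (zero phase). The order is a stability choice at the
  0.05-Hz edge. All zero-phase filtering uses odd-reflection padding
  (30 s for the band-pass, 2 s for anti-alias filters) because plain
  `filtfilt` start/end transients otherwise leak into baselines.
* Resampling to 25 Hz: zero-phase Butterworth low-pass (order 4, cutoff
  0.45 × 25 Hz) plus linear interpolation. `signal::resample` was measured
  at 2.5% RMS error on a 1-Hz tone (25% for 50→25 Hz) and was therefore
  not used. Per-beat series (SBP, DBP, MAP, IBI, PWV) go onto the grid by
  previous-value hold. NA gaps survive resampling as NA.
* Standardization: subtract the mean and divide by the SD of the 60-s
  pre-onset baseline; the 5-s moving average (125 samples at 25 Hz,
  centered, shrinking windows at the edges) is produced for both the raw
  and the standardized series. A zero-variance baseline is an error.
* Movement onset: first time the tilt angle deviates > 5° from its
  baseline median for ≥ 0.5 s (both configurable; the thresholds are
  package defaults, the source protocol used a tilt meter without printing
  numbers).
* Quality gate: a repeat is discarded when any pulsatile channel shows a
  heartbeat gap > 10 s in the 60-s baseline, > 10 s in minute 1 after
  onset, or > 20 s in minutes 2–3 (gaps clipped to the windows);
  sample-valued channels (NIRS, continuous BP) are judged by
  missing-sample runs with the same thresholds. A PPG with upstrokes for
  fewer than half the beats over the whole record (e.g. an envelope-only
  simulated PPG) is judged by the sample rule instead — the heartbeat rule
  presumes pulsatile content.

## Beat detection and two-stage PWV

R-peaks: 5–30-Hz band-pass, local maxima above 40% of the 95th percentile,
250-ms refractory (greedy by amplitude). PPG upstrokes: for each R-peak the
candidate is the maximum of the PPG first derivative in $(t_R, t_R+0.6]$ s,
accepted when it exceeds $k$ times the SD of the derivative over the
centered surrounding 5 s, $k = 3$ (high specificity) and $k = 1.5$ (high
sensitivity). Three numerical details matter:

* "SD of the surrounding 5 s" is taken on the *derivative* (thresholding a
  derivative peak against the raw-signal SD would mix units); a raw-signal
  variant is a one-line config change.
* The local SD is floored at 10% of the whole-record derivative SD:
  inside a flatlined dropout the local SD collapses and a purely relative
  threshold would accept numerical ripple as an upstroke.
* Both detectors refine peak locations by parabolic interpolation of the
  three samples around the maximum; without it, quantization alone pushes
  worst-case R-to-upstroke delay errors past one native sample.

Per beat, PWV $= 1/(t_{up} - t_R)$; non-positive delays are flagged
invalid. The merge keeps high-sensitivity values inside
$[\bar x - 3s, \bar x + 5s]$ of the high-specificity series, with mean and
SD taken over the whole repeat (a windowed variant was considered; the
whole-repeat reading is the simplest consistent one). An empty
high-specificity series falls back to the unfiltered high-sensitivity
series with a warning rather than aborting the repeat. Note the asymmetric
band intentionally trims deep genuine PWV excursions along with artifacts.

## BP estimation

Pooled OLS over the concatenated 0–30-s windows of the training repeats
(all repeats of the same participant and maneuver except the held-out one;
squat excluded; single-repeat sessions yield no estimate). The regressor is
the **raw** 5-s-smoothed finger PPG, not the per-repeat standardized
version: standardization would rescale each repeat by its own
baseline-window SD, making the PPG→BP affine map repeat-specific and
breaking cross-repeat calibration transfer — under exact linear simulated
coupling the held-out estimate then fails to reproduce the measured signal.
Units are absorbed into $\beta_1$; correlation analyses are unaffected
(Pearson r is affine-invariant).

The pipeline's measured-BP series defaults to sample-and-hold of the
per-beat SBP/MAP events (`bp_source = "beats"`, mirroring beat-to-beat
monitor output). `bp_source = "waveform"` instead resamples the continuous
BP waveform channels through exactly the path the PPG takes; this is the
right comparison when assessing estimation exactness, because the
hold-vs-continuous processing difference alone is of order 0.5–3% of the
drop.

## Outlier rule, reliability, validity

The 5-SD rule is leave-one-out and single-pass: value $v_i$ is discarded
iff $|v_i - \bar v_{-i}| > 5\,s_{-i}$, computed across the cohort within
one maneuver and quantity (the "same postural change" scope is ambiguous
in the source; across-cohort-within-maneuver is the default and
configurable by grouping). Fewer than three values: nothing is discarded.

ICC(A,1) is computed from the two-way mean squares,
$\mathrm{ICC} = (MS_R - MS_E)/(MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E))$,
complete-case over rows; the test suite checks it against an independent
`stats::aov`-based oracle. Banding uses lower-inclusive half-open bins
(0.40/0.60/0.75), resolving the overlapping printed ranges of the
conventional banding; negative ICCs are "poor". Validity is the Pearson
correlation between measured- and estimated-BP values after averaging each
participant's non-discarded repeats (per-participant pairing; per-repeat
pairing was the alternative reading).

## Sequence method

SBP ramps are maximal runs of ≥ 3 beats with monotone per-beat change
≥ 1 mmHg; the lag-shifted IBI segment (default lag 1 beat) qualifies when
every per-beat change is ≥ 1 ms in the concordant direction and the
SBP–IBI correlation is ≥ 0.8; BRS is the mean OLS slope of qualifying
sequences and BEI the fraction of ramps with a qualifying sequence. These
thresholds follow the conventional sequence-method criteria; they are
defaults, not values asserted from the source study, and all are
arguments.

## Problem sizes and determinism

The validation suite runs cohorts of 8 participants × 3 repeats for
recovery and estimation-validity properties, 16 × 3 maneuvers × 3 repeats
for the end-to-end determinism check, 100–200 random draws for the
oracle-equivalence properties (MBLL round trips, ICC vs ANOVA, ramp
scanning), and 5-min resting epochs for the sequence method — sizes chosen
so the full chain exercises every code path on a single CPU in minutes.
Determinism is by construction: every random draw derives from the master
seed and a structural key (participant/maneuver/repeat/channel), so any
subset of a cohort can be re-simulated independently and bit-identically.

## Known limitations

* The simulator's linear PTT–SBP coupling reverses the post-stand PWV
  direction seen in humans (see above); only the PWV–BP correlation sign
  is faithful.
* Squat repeats use the same post-onset drop window as other maneuvers, so
  their denominator "drop" is typically negative and squat BRS/CAR are
  flagged undefined rather than computed on the post-release window.
* ICC confidence intervals and Bland–Altman analysis are out of scope.
* The quality gate is fully automated; it replaces, and does not emulate,
  visual inspection.
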