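---
title: "Detecting gait events from foot-worn IMUs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gait events from foot-worn IMUs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitseg)
```

## The problem

Quantitative gait analysis needs the timestamps of two events per stride and
per foot: toe-off (TO), when the foot leaves the ground, and heel-strike
(HS), when it touches down again. With healthy walkers many detectors work
well; the hard case is severely degraded gait — very slow walking, strong
asymmetry, attenuated or atypical foot-ground impacts — where rule-based
detectors tuned on healthy morphology break down. `gaitseg` implements a
fully automatic, template-free-at-deployment detector for per-foot IMU
recordings (3-axis gravity-free acceleration and 3-axis angular velocity,
100 Hz): the stride template is extracted from the recording being analysed,
so no per-subject training or instrumented walkway is needed at detection
time.

## Signals of interest

Two derived channels per foot drive everything:

* the **sagittal gyration** $\Omega$: the angular velocity about the
  medio-lateral axis, read directly from the gyroscope's y channel (deg/s).
  Its dominant feature is a large positive lobe during the swing phase,
  flanked by negative lobes near TO and HS;
* the **jerk norm** $J = \lVert \dot a_{free} \rVert$: the Euclidean norm of
  the time-derivative of the three gravity-free acceleration channels
  (m/s³). It is quiet during foot-flat and shows sharp bursts at the
  foot-ground interaction events.

Raw channels are repaired (gaps up to 0.5 s filled by local quadratic
interpolation; longer gaps invalidate the recording) and low-pass filtered
with an order-8 Butterworth at 14 Hz. The filter is applied forward and
backward (zero phase): one-pass filtering would delay $\Omega$ and $J$ by
different group delays and bias every event time against gold-standard
clocks. The price is that the effective magnitude response is squared,
i.e. the -3 dB point moves slightly below 14 Hz; for signals whose energy
sits well under 10 Hz this is immaterial. Differentiation uses central
differences (second-order accurate, no lag), one-sided at the boundaries.

## The four-stage detector

**1. Stride period.** The average stride duration $L$ is the lag of the
first prominent peak of the *multiparametric autocorrelation* — the
arithmetic mean of the normalized autocorrelations of $\Omega$ and $J$
(the mean, rather than a sum, keeps the curve's scale independent of the
number of channels). The search band is 0.4–4.0 s by default: below 0.4 s
the step (half-stride) periodicity of symmetric gait would capture the
estimate, and 4 s covers even severely slow pathological cadence. A peak
qualifies if both its height and its topographic prominence reach 10% of
the band maximum. Requiring positive height is deliberate: intra-stride
event spacings (e.g. the TO-to-HS interval of the jerk bursts) produce
*negative-valued* local maxima in the combined curve, and a negative
autocorrelation cannot indicate a period. Both feet are estimated
independently and the shorter lag wins, which guards against
double-period overestimation without erasing asymmetry.

**2. Reference stride.** With window length $m = L f_s$, the matrix profile
of $\Omega$ (z-normalized Euclidean distance of each window to its nearest
neighbour, exclusion zone $m/2$) marks recurring stride-shaped windows. A
window that merely recurs is not enough: we want the swing phase centred,
so an annotation vector sums $\omega_k/\omega_{max} + j_k/j_{max}$ over the
central third of each window (offsets $\lfloor m/3\rfloor$ to
$\lfloor 2m/3\rfloor$, inclusive; $\omega_{max}$ and $j_{max}$ are the
walk-wide maxima of $|\omega|$ and $j$; gyration enters signed, so the
positive swing lobe is what scores). After min-max rescaling to $[0,1]$
(a flat vector degenerates to all ones, i.e. no correction), the corrected
matrix profile is $\mathrm{cmp} = \mathrm{mp} + (1 -
\mathrm{av})\max(\mathrm{mp})$ and the reference stride is its argmin.

**3. Annotation.** A packaged canonical stride with known FF/HO/TO/HS
offsets is linearly resampled to length $m$ (the slope constraint below is
defined for comparable lengths; event offsets rescale proportionally),
circularly shifted so its swing peak (gyration argmax) coincides with the
reference window's, and aligned to the reference by dependent multivariate
DTW: both channels are z-normalized per series, stacked into 2-D points,
and the dynamic program minimizes the summed pointwise Euclidean distance
under an Itakura parallelogram with maximum slope 2. Ties prefer the
diagonal step, then advancing the model, then the subject — a fixed order
that makes the warping path, and hence every transferred event,
reproducible. The subject's TO is the *last* sample matched to the model's
TO; HS is the *first* sample matched to the model's HS. If the circular
shift places the segmentation point between HS and the following TO the
within-window ordering can invert; this is reported by a warning, never
silently reordered.

The packaged model stride is synthetic (see below) and stands in for an
annotated healthy-subject stride; any user-supplied CSV/JSON template can
replace it.

**4. Segmentation.** The annotated reference stride becomes the template.
Candidate window starts are the local maxima of the sliding per-channel
Pearson correlation between template and walk (averaged over channels);
each candidate is re-scored by the Itakura-constrained mDTWd between
template and window, normalized by the warping-path length. Candidates
with dissimilarity $d \le \lambda = 0.4$ are accepted greedily in ascending
$d$, subject to pairwise window overlap at most $\mu m$ with $\mu = 0.1$;
TO and HS are transferred into each accepted window through its own
warping path. Candidate windows are tried at length $m$ only — the DTW
slope budget of 2 absorbs stride-length variation — and an optional
analysis interval restricts detection, mirroring walkway-bounded
evaluation protocols. If nothing is accepted the detector returns an
empty event list with a warning rather than an error.

Every constant above is a field of `gaitseg_config()`; nothing is
hard-coded. Setting `use_jerk = FALSE` switches the entire pipeline
(autocorrelation, annotation vector, DTW, correlation) to gyration-only
operation, the classical single-channel ablation.

## Evaluation metrics

Gold-standard lists carry initial/final contacts (IC/FC). Matching is per
foot and per type (TO↔FC, HS↔IC), one-to-one, greedy by ascending absolute
time difference (earlier gold event breaks ties), admitting pairs within
20% of the stride duration. Greedy matching is deterministic and agrees
with optimal assignment except in pathological overlap patterns that the
tolerance excludes. Recall is matched gold over all gold; precision is
matched detections over all detections; F1 is their harmonic mean (zero
when both vanish). Timing errors are reported in ms with medians and IQRs
— and means alongside, since published tables sometimes label one while
printing the other. The stride duration used by the tolerance comes from
the gold list's mean inter-FC interval when available, else from the
pipeline's own $L$.

## The synthetic gait generator

Real paired IMU/walkway recordings of pathological gait are not publicly
distributable, so validation runs on `synth_walk()`, which generates
two-foot walks with exact ground truth. Each stride is built from Gaussian
components implementing the morphology sketched above: a +350 deg/s swing
lobe centred between TO and HS, negative gyration lobes at TO and HS, a
small heel-off dip; jerk bursts at FF/HO/TO/HS (60/80/180/250 m/s³, widths
12–22 ms) over a quiet stance. Defaults describe a healthy 10-m walk:
9 strides per foot at 1.1 s mean stride time (≈1.1 m/s), swing fraction
0.4, stride-time CV 5%, ±15–20% per-stride amplitude jitter, white noise
at 10% of channel amplitude band-limited to 14 Hz like the real signals,
1 s quiet lead-in/out, right foot phased by half a stride. Stride times
are truncated-normal (±3 SD) to stay positive and physiological.
Impairment is emulated with three knobs: heel-strike jerk attenuation
(`hs_jerk_atten`, foot-drop-like loss of the HS impact), raised
stride-time variability, and left/right asymmetry — enough to span the
published healthy-versus-impaired speed range without claiming clinical
realism.

What the generator does *not* emulate: u-turns, gait initiation/termination
transients beyond simple quiet leads, sensor drift or re-orientation,
magnetometer channels, gravity-leakage artifacts, and the idiosyncratic
morphologies of real neurological gait (toe-strike initial contacts,
shuffling without true foot-off). Passing the synthetic suites therefore
demonstrates correct implementation and robustness to timing/amplitude
variability and noise — not clinical validity, which requires cohort data.

`render_raw_csv()` writes walks back out as raw-format CSVs whose
acceleration channel is a signed integral of the jerk track, so the entire
chain including file parsing, gap handling, filtering and differentiation
is exercised in tests.

## Numerical choices and degenerate inputs

* Matrix profile: exact blocked all-pairs computation (walks are short);
  constant windows get distance 0 to other constant windows and $\sqrt m$
  to non-constant ones; trivial matches excluded within $m/2$.
* Autocorrelation: biased estimator normalized at lag 0; a zero-variance
  channel contributes zeros beyond lag 0 instead of NaN.
* DTW: a zero-variance channel is zeroed after normalization with a
  warning; infeasible Itakura geometries raise an error naming the cause.
* Zero-phase filtering pads with odd reflection (300 samples) before the
  forward-backward passes; edge samples approach the boundary value, so
  attenuation assertions are made on interior samples.
* Quadratic gap interpolation uses up to three valid neighbours per side
  and degrades to linear when fewer than three points exist.
* Event times are seconds from recording start, $t = (i-1)/f_s$ for 1-based
  sample $i$; windows are half-open throughout.

## Problem sizes used by the shipped validation

The test-suite and the reproduction script run simulations sized for
precise yet quick checks: 20-seed cohorts for end-to-end recovery, a
50-walk grid (stride times 0.8–2.5 s, noise 10–20%) for stride-period
recovery, 50 seeds for timing-error self-consistency, and brute-force
oracle comparisons at n ≤ 400 (matrix profile) and n ≤ 8 (exhaustive DTW
path enumeration). These sizes give stable means (simulation SE well below
the asserted margins) on a single CPU.

## Known limitations

* Under extreme stride-time variability (CV ≈ 25%) with attenuated
  heel-strike bursts, the fixed operating point $\lambda = 0.4$, $\mu =
  0.1$ with windows fixed at length $m$ becomes conservative: genuinely
  matching strides whose duration differs strongly from $L$ can exceed
  $\lambda$, and consecutive short strides can violate the overlap budget.
  On such synthetic walks mean F1 falls to roughly 0.8 (healthy: 0.997)
  while precision stays near 1 — missed strides, not spurious ones — and
  median timing error of detected events remains ≈10 ms. The thresholds
  are configurable for users who prefer a more permissive operating point.
* The stride-period estimate is a single scalar per walk; strongly
  time-varying cadence is out of scope.
* Only straight-line walks are addressed; no spatial parameters (stride
  length, speed) are computed.

## Reproducing the shipped numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates every
headline quantity (worked-example F1 percentages, stride-period recovery
error, healthy/degraded end-to-end F1 and timing medians, jitter
self-consistency) from scratch using only the installed package.
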