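# gaitseg

Automatic detection of gait events — toe-off (TO) and heel-strike (HS) —
from foot-worn inertial measurement units (IMUs), built to stay reliable on
severely degraded pathological gaits (e.g. multiple sclerosis, post-stroke
equino varus foot) where detectors tuned on healthy walkers fail.

The input per foot is a 100 Hz recording of 3-axis gravity-free
acceleration and 3-axis angular velocity. Two derived channels drive the
whole method: the sagittal gyration Ω = ω_y and the jerk norm
J = ‖d a_free/dt‖. Detection is fully automatic, with no per-subject
training and no instrumented walkway at deployment:

1. **Stride period** — the lag of the first prominent peak of the
   multiparametric autocorrelation (mean of the Ω and J autocorrelations),
   per foot, keeping the shorter estimate: L.
2. **Reference stride** — matrix profile of Ω at window length m = L·fs,
   corrected by an annotation vector
   AV_i = Σ_{k=i+m/3}^{i+2m/3} (ω_k/ω_max + j_k/j_max)
   that centres the swing phase; the corrected profile's argmin is the
   subject's own reference stride.
3. **Annotation** — dependent multivariate DTW (channels stacked into 2-D
   points, z-normalized per series, Itakura slope ≤ 2) aligns a canonical
   model stride to the reference; TO is the last subject sample matched to
   the model's TO, HS the first matched to the model's HS.
4. **Segmentation** — sliding correlation proposes candidate windows;
   each is re-scored by path-length-normalized mDTWd and accepted when
   d ≤ λ = 0.4 with pairwise overlap ≤ μ·m (μ = 0.1); events are
   transferred into every accepted window.

Performance against an instrumented-walkway gold standard (IC/FC events)
is scored with one-to-one matching within 20% of the stride duration:
recall, precision, F1 = 2·recall·precision/(recall+precision), and
absolute timing errors ΔTO/ΔHS in ms (median, IQR). A synthetic gait
generator with exact ground-truth events supports validation end to end.

## Worked example

```r
library(gaitseg)

walk <- synth_walk(synth_params(n_strides = 9, stride_s = 1.1, seed = 7))
fit  <- gait_segment(walk$left, walk$right)
fit
#> Gait segmentation
#>   stride period L = 1.080 s (window m = 108 samples)
#>   left foot: 9 strides, 18 events
#>   right foot: 9 strides, 18 events

evaluate_events(fit, walk$truth)
#> Gait event evaluation
#>   recall 1.000, precision 1.000, F1 1.000 (36/36 gold matched)
#>   deltaTO: median 10 ms (IQR [10-10]), mean 12 ms over 18 events
#>   deltaHS: median 0 ms (IQR [0-0]), mean 0 ms over 18 events
```

The stride period (1.08 s) recovers the generator's 1.1 s mean cadence;
all 18 toe-offs and 18 heel-strikes per side are found (F1 = 1), with
median timing errors of 10 ms (TO) and 0 ms (HS) against the exact
synthetic ground truth — within one sample at 100 Hz.

Raw CSV recordings are handled the same way:

```r
rec_l <- read_imu_csv("left.csv",  "left")   # PacketCounter, freeAccX..Z, gyrX..Z
rec_r <- read_imu_csv("right.csv", "right")
fit   <- gait_segment(rec_l, rec_r)          # preprocesses, then detects
head(as.data.frame(fit))                     # type, foot, time_s
```

A thin command-line front end over the same functions ships at
`inst/cli/gaitseg.R` (subcommands `simulate`, `preprocess`, `period`,
`motif`, `annotate`, `detect`, `evaluate`).

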