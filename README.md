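# tactloc

Quantitative assessment of tactile mislocalization (topesthesia) on the
hand.

After a stroke or other neurological injury, patients may still *detect* a
touch but report it at the wrong place — shifted from fingertip to palm, or
smeared across neighbouring fingers. Standard clinical tools (the
localization subscale of the Nottingham Sensory Assessment, NSA) rate each
test location on a coarse 0–2 scale and routinely hit ceiling effects.
Automated assessments instead stimulate 24 well-defined sites on the volar
hand (5 repetitions each, 120 trials) and record the exact coordinates the
subject indicates on a schematic hand, giving continuous, ratio-scale
outcome measures. `tactloc` implements the analysis side of such an
assessment, plus a virtual-subject simulator that stands in for the
stimulation hardware.

## The metrics

All errors are **geodesic**: lengths of the shortest path that stays inside
the schematic hand polygon, so a response on the neighbouring fingertip is
correctly treated as far away (the path must round the web notch) even
though it is close in the plane. For stimulation site $s$ with responses
$r_1,\dots,r_n$ and response center $c$ (arithmetic centroid, clamped into
the hand), with $g(\cdot,\cdot)$ the geodesic distance:

- **distance** $= \frac{1}{n}\sum_i g(r_i, s)$ — mean error of individual
  responses (accuracy),
- **offset** $= g(c, s)$ — error of the average percept (systematic
  distortion),
- **spread** $= \frac{1}{n}\sum_i g(r_i, c)$ — dispersion around the
  percept (precision),
- **correct localization rate (CLR)** — each response is discretized to its
  nearest site; the CLR is the diagonal of the resulting 24×24 row-percentage
  confusion matrix.

Lengths are reported in cm, normalized to a reference hand of 17 cm (middle
fingertip to wrist crease) via the factor $17/\ell$ for a measured hand
length $\ell$. Geodesics are computed exactly on the simple hand polygon via
a visibility graph over reflex vertices with Dijkstra/Floyd–Warshall.

## Worked example

Simulate a subject with a 1.5 cm distal-to-proximal mislocalization of the
finger sites (a classic post-stroke pattern), score the session, and derive
the clinical subscale:

```r
library(tactloc)

ses <- simulate_session(archetype("patient1_like"),
                        config = protocol_config(seed = 42))
summarize_session(ses)
#> <assessment_summary patient1_like, left hand: 120 trials, 0 missing, normalized to 17 cm hand>
#>   mean offset    1.4 ± 0.5 cm
#>   mean spread    1.2 ± 1.0 cm
#>   mean distance  2.0 ± 1.2 cm
#>   mean CLR      42.5 ± 36.0 %

sm <- summarize_session(ses)
correct_localization_rate(sm$confusion, subset = c(1, 5, 9, 13, 17))$mean
#> [1] 12  # fingertip CLR, %: the shifted fingertips almost never localize correctly

nsa_from_session(ses)
#> <nsa_score>
#>   digit_I_distal_phalanx     1/3 correct -> 1
#>   digit_II_metacarpal        3/3 correct -> 2
#>   digit_III_distal_phalanx   1/3 correct -> 1
#>   digit_V_distal_phalanx     1/3 correct -> 1
#>   digit_V_metacarpal         3/3 correct -> 2
#>   thenar_eminence            3/3 correct -> 2
#>   Total 9 / 12
```

The mean offset recovers the programmed 1.5 cm shift diluted by the
unshifted palm sites; the fingertip CLR of 12% shows the discretized
percepts landing on more proximal sites, while the clinical scale still
awards 9/12 — the ceiling effect the continuous metrics avoid.

Plots mirror the field's standard encodings:

```r
autoplot(sm)              # distortion map: arrows site -> percept, spread circles
autoplot(sm$confusion)    # 24x24 confusion heatmap with digit-delimiting grid
render_plot(autoplot(sm), "map.svg")
```

A command-line interface wraps the same functions
(`inst/cli/tactloc simulate|score|nsa|plot|template`).

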