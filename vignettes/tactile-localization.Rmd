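---
title: "Geodesic metrics for tactile localization assessments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geodesic metrics for tactile localization assessments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tactloc)
```

## The assessment

Topesthesia — knowing *where* on the skin a touch occurred — can be impaired
after stroke even when detection is intact. An automated localization
assessment stimulates 24 sites on the volar hand (four per digit: distal,
intermediate and proximal phalanx plus distal metacarpal for digits II–V;
distal and proximal phalanx plus two metacarpal aspects for the thumb; four
palm sites), five repetitions per site in pseudo-random order, 120 trials in
total. The subject indicates each perceived location on a schematic hand;
a stimulus that is not perceived may be repeated up to three times, after
which the trial is recorded as missing. `tactloc` implements the analysis of
such sessions and a simulator that generates them with known ground truth.

## Why geodesic errors

Adjacent fingertips are close in the plane but far apart on the hand
surface. Straight-line error metrics would score a response on the wrong
fingertip as nearly correct; metrics defined along the hand do not. All
errors in `tactloc` are therefore lengths of the shortest curve between two
points that stays inside the closed hand polygon. On a simple polygon that
shortest path is a polyline bending only at reflex outline vertices (the
web notches), which makes an exact algorithm available:

1. build the visibility graph over the reflex vertices and the 24 sites
   (an edge when the connecting segment stays inside the polygon),
2. precompute all-pairs shortest paths on that small graph
   (Floyd–Warshall, ~30 nodes),
3. for a query point, one visibility scan plus table lookups gives its
   distance to any target; Dijkstra over `{p, q, reflex vertices}` realizes
   arbitrary point-to-point geodesics.

Orientation and incidence predicates use a tolerance of 1e-9 template
units; segments grazing the boundary (touching a vertex, running along an
edge) count as visible, consistent with treating the polygon as a closed
set. Results are cached per template geometry; caching cannot change
results. The engine is verified in the test suite against closed forms
(convex regions, an L-shaped polygon) and against an independent
8-connected grid-graph Dijkstra oracle, which converges to the true
geodesic from above as the grid spacing shrinks (up to the ~8.2% octile
overshoot plus an endpoint-snapping term).

## The hand template

No canonical outline geometry ships with published assessments, so the
package provides a versioned parametric template (`default_hand_template()`,
version 1.0): a simple polygon with five tapered finger lobes separated by
concave web notches, an abducted thumb, palm and wrist base, in millimetre
units on a reference hand of 17 cm measured from the middle fingertip to the
wrist crease. The origin is the wrist-crease midpoint, y increases distally,
and x increases toward the thumb on a right hand; the left template is the
exact mirror image, which makes left/right geodesics identical by
construction. All metrics are template-parametric: every function takes the
template as an argument, so a different validated outline (via
`read_hand_template()`) changes the numbers but not the code.

Two unit conventions matter:

* `units_per_cm` converts template units to the subject's physical
  centimetres; `scale_to_hand(template, hand_length_cm)` adjusts it for a
  measured hand.
* *Normalization* multiplies reported lengths by `17 / hand_length_cm` so
  subjects with different hand sizes are comparable; it is the default
  reporting convention (`summarize_session(..., normalize = TRUE)`) and a
  separate step from unit conversion.

Boundary points count as inside, which makes `clamp_to_hand()` (nearest
boundary point for outside responses) idempotent.

## Metric definitions and numerical choices

For a site $s$, responses $r_1,\dots,r_n$, response center $c$ and geodesic
distance $g$: distance $=\operatorname{mean}_i\,g(r_i,s)$, offset $=g(c,s)$,
spread $=\operatorname{mean}_i\,g(r_i,c)$. The confusion matrix assigns each
response to the site minimizing the geodesic distance; row percentages are
taken over the non-missing responses of each stimulated site, and the
diagonal is the correct localization rate (CLR).

Choices that the definitions leave open, and what this package does:

* **Response center.** The arithmetic centroid, clamped to the nearest
  boundary point when it falls outside the hand (responses on two fingers
  can average into the web notch). A geodesic (Fréchet) mean is available
  via `response_center(..., method = "geodesic_mean")` but is not the
  default: the centroid is deterministic, cheap, and identical to the
  geodesic mean whenever the responses lie in one convex neighbourhood.
* **Nearest-site rule.** Geodesic, for consistency with the error metrics;
  `confusion_matrix(..., method = "euclidean")` is available. Ties break to
  the lowest site id (deterministic).
* **Missing responses.** Excluded from all per-site metrics and confusion
  percentages, but counted and reported per row — partial data stays
  interpretable, and sessions with fewer than five repetitions per site are
  accepted with warnings rather than rejected.
* **Aggregation.** Hand-level rows are arithmetic means over the sites with
  at least one response, with sample SDs (n−1) across sites. On the
  two shipped example cases the printed ± values are matched by the sample
  SD for six of eight hands; the remaining two differ by one unit in the
  last decimal, consistent with the source having aggregated unrounded
  per-site values where only one-decimal values are available here.
* **Reporting.** One decimal for cm and percent (see
  `aggregate_site_values()`); full precision is kept internally.
* **Degenerate inputs.** A site with zero responses yields `NA` metrics
  (undefined, never zero); a single response has spread 0; `p == q` has
  geodesic distance 0.

The inequality distance ≥ offset is *not* asserted globally — it is a
Jensen-type theorem only when the responses and their center lie in a
common convex sub-region of the hand, and can fail across notches; the test
suite checks it in convex regions only.

## The clinical cross-walk

The NSA localization subscale tests six locations (distal phalanges of
digits I, III, V; distal metacarpals of digits II and V; thenar eminence),
three repetitions each, allowing a 2 cm error; per-location scores are
0 (no repetition correct), 1 (some), 2 (all), summing to 0–12 per hand.
`nsa_locations()` maps the six locations onto template sites (five coincide
with stimulation sites; the thenar center is the thenar palm site), and
`nsa_from_session()` scores an automated session by the same rule, marking a
repetition correct when its geodesic error is ≤ 2 cm and counting missing
trials as incorrect. `nsa_score_from_ratings()` rebuilds score objects from
published 0/1/2 ratings, which is how the shipped example-case totals are
reproduced.

## The simulator

`simulate_session()` replaces hardware and subject with a parametric
distortion field: the ground-truth percept center per site, plus isotropic
Gaussian noise (SD in cm) and a per-attempt lapse probability. Field kinds:

* `identity` — percept centred on the true site;
* `distoproximal_shift` — finger sites displaced a fixed length toward the
  palm along the digit's axis (fitted through the digit's site chain, since
  no axis is otherwise defined); palm sites unshifted;
* `palm_compression` — all percepts contracted toward an attractor
  (default: the palm-site centroid): `perceived = attractor +
  compression · (true − attractor)`;
* `custom` — explicit per-site displacement vectors.

The three archetypes span the clinically observed range. `healthy`
(identity, σ = 0.4 cm) represents intact localization: residual noise on
the order of the fingertip two-point threshold scale, giving high CLR.
`patient1_like` (1.5 cm distoproximal shift, σ = 0.8 cm) reproduces the
systematic distal→proximal pattern with preserved topography: one phalanx
of displacement, enough for fingertip percepts to discretize to the next
proximal site. `patient2_like` (compression 0.25 toward the palm centroid,
σ = 1.8 cm, lapse 0.25) reproduces a severely shrunken representation:
every finger percept lands in the palm/metacarpal region, spreads are
large, and some trials go missing. These constants are the package's fixed
definition of the archetypes, chosen once from the qualitative patterns
they emulate.

Noise is applied before clamping into the hand, so clamping induces a small
inward bias for sites near the boundary; parameter-recovery tests therefore
use interior mid-finger sites, where a programmed shift δ is recovered
exactly (σ = 0) or within 3σ/√5 (σ > 0, five repetitions). Two further
calibration laws are verified: for isotropic Gaussian responses in a convex
neighbourhood the spread converges to σ·√(π/2) (mean of a Rayleigh radius,
checked within 2% at n = 5000), and the missing-trial fraction converges to
lapse³ (three independent per-attempt lapses, checked against a binomial
99% CI at n = 10 000).

Randomness is counter-based: every draw re-seeds a local RNG from
(seed, stream, trial index), so any single trial is reproducible in
isolation, sessions are identical regardless of evaluation order, and the
caller's RNG state is never touched.

What the simulator does **not** model: touchscreen calibration error,
response times, attention drift over a session, anisotropic or
position-dependent noise, and biomechanical skin properties. Passing
recovery tests therefore demonstrates that the *analysis* is correct and
well-calibrated under the stated generative model — not that the model
captures every property of patient data.

## Problem sizes and runtime choices

The test and acceptance workloads use the full 120-trial protocol
everywhere; oracle comparisons use a 2 mm grid on the hand (about 6 000
nodes) with 100 random point pairs, and the closed-form spread check uses
5 000 responses — sizes at which the stochastic tolerances above are
comfortably resolvable. The sequence-constraint property is checked across
200 seeds.

## Known limitations

* The default outline is a stylized adult hand, not a subject-specific
  geometry; per-subject templates must be supplied externally.
* The geodesic engine is exact only for simple polygons; outlines with
  holes or self-intersections are rejected rather than approximated.
* Normalization is a single multiplicative factor; it does not model
  non-uniform differences in hand proportions.
* The clinical cross-walk uses the first three responses at each mapped
  site, which is a convention, not a clinical standard.
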