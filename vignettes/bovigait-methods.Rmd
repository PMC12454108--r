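---
title: "Quantifying dairy-cow lameness from overhead RGB-D: models and methods"
author: "bovigait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dairy-cow lameness from overhead RGB-D: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bovigait)
```

## The problem

Lameness is among the most costly and most under-detected welfare problems
in dairy herds. An overhead depth camera above a walkway sees every animal
unoccluded, but from that viewpoint the classical side-view cues (stride
length, hoof placement) are invisible: what remains are the posture and
motion of the back and head. `bovigait` implements a complete desk-testable
pipeline for grading cows as *sound*, *mild* or *severe* from such
recordings: depth cleaning, six quantified gait features computed from
eight back keypoints (poll, withers, left/right scapula, lumbar region,
left/right tuber coxae, sacral tuber), unbiased feature screening, and
multi-feature fusion classification. The forward mathematics of the
attention and graph-convolution blocks used by keypoint detectors in this
setting are included as pure tensor operations for verification; network
*training* and the detector itself are out of scope.

## Depth preprocessing

Raw overhead depth (mm, 16-bit; 0 marks a void) passes through a fixed
chain:

1. **Clipping** to a working range, default [1200, 2600] mm (closed
   interval; with a camera mounted at 3.2 m, this brackets the cow's back
   and the floor).
2. **Bilateral filtering** with spatial sigma 5 px and range sigma 0.1 on
   depth normalised to [0, 1] over the clip span; the kernel is truncated
   at radius `ceiling(2*sigma)` and void pixels are excluded from every
   window.
3. **3 × 3 median filtering**, again void-aware, to remove isolated
   outliers.
4. **Nearest-neighbour hole filling**: each void takes the value of its
   nearest valid pixel (Euclidean distance; ties broken by smaller row,
   then smaller column, so results are bit-reproducible).

Sequences are screened *before* filling: if the void rate inside the body
region reaches 10% in any frame (boundary inclusive — exactly 10% rejects),
the sequence is discarded. The per-frame-maximum reading is the stricter of
the two possible interpretations and is the package default. The body
foreground itself is `depth < floor - minHeight` (defaults 2500 mm and
300 mm, configurable — they follow from the mount geometry rather than from
any published value) with only the largest connected component retained.

## The six gait features

All features are computed from a `WalkingSequence`: a depth stack, the
per-frame coordinates of the eight keypoints, camera height (mm) and a
ground-plane scale (cm/px). Keypoint depth is read as the median of the
3 × 3 neighbourhood around the keypoint pixel to tolerate single-pixel
noise.

* **BC — back curvature (1/cm).** Per frame, withers, lumbar and sacral
  tuber are placed in the sagittal plane as (cumulative along-spine
  horizontal distance, height above floor) with height =
  (camera height − depth)/10. The curvature of the circle through the three
  points is `4·Area/(|a||b||c|)`; collinear points give 0. The feature is
  the per-sequence **maximum** (kyphosis is a peak posture). The sagittal
  reading is the default because the feature quantifies spinal arching and
  is reported in 1/cm; an overhead-plane variant would conflate arching
  with lateral bending of the spine projection.
* **MAI — movement asymmetry index (unitless).** Dense optical flow is
  computed between consecutive textured frames; flow magnitudes are
  averaged over the left and right body halves (the body mask split by the
  normal of the withers→lumbar axis, zero-cross pixels assigned left), and
  `MAI = |muL − muR| / (muL + muR)`, with 0 when both means vanish.
  Magnitudes are accumulated over the whole sequence before the ratio — one
  index per sequence — because a per-frame ratio is ill-conditioned in
  near-stationary frames; a per-frame-then-average option exists.
* **VOB / VOH — vertical oscillation of back / head (cm).** Temporal range
  (max − min) of depth at withers, lumbar and sacral tuber, taking the
  maximum of the three ranges; VOH is the same range for the poll alone.
* **TI — trunk inclination (cm).** Per frame, |left − right| depth
  difference at the scapulae and at the tuber coxae; maximum over frames
  and both pairs.
* **LSAS — lateral sway amplitude of the spine (cm).** Peak-to-valley range
  of the horizontal image coordinate of the scapula midpoint, the lumbar
  point and the sacral tuber (the maximum of the three), scaled to cm. Raw
  image x is used by default; a linear detrend option exists but is off,
  matching the plain peak-to-valley definition.

### Optical flow

No installed R package provides dense optical flow, so the package carries
its own implementation of the polynomial-expansion (Farneback) algorithm:
each image is locally fitted by quadratics under a Gaussian applicability,
displacements solve the accumulated normal equations over an averaging
window, and the estimate is refined iteratively over an image pyramid.
Parameters (pyramid scale 0.5, 3 levels, window 15 px, 3 iterations,
expansion neighbourhood 7 px with sigma 1.5) follow the common defaults for
this algorithm and live in the run configuration. On smooth synthetic
textures the implementation recovers imposed subpixel translations to
within a few percent (see the flow tests), which bounds the MAI error well
inside the 30% tolerance used in the round-trip checks.

## Synthetic walking sequences

Farm recordings are not publicly available, so the package includes a
first-class generator used by every downstream test:

* The published per-class mean values of the six indicators (BC 0.00021 /
  0.00054 / 0.00093 1/cm; MAI 0.012 / 0.027 / 0.064; VOB 4.72 / 8.23 /
  12.90 cm; VOH 7.92 / 10.36 / 17.28 cm; TI 3.63 / 5.18 / 6.76 cm; LSAS
  5.33 / 6.67 / 9.18 cm for sound / mild / severe) are the default
  calibration targets — `classFeatureMeans()`.
* Within-class spread is a truncated-at-zero normal per feature with a
  configurable coefficient of variation, default **cv = 0.15**. The source
  reports only class means; cv = 0.15 keeps all features positive and
  produces class overlap comparable to the published box plots. This is an
  artifact choice, flagged here and in the configuration.
* A sequence is rendered at 160 × 96 px, 1.25 cm/px, 60 frames at 30 fps by
  default, with the cow walking along the vertical image axis: a smooth
  body surface whose spine profile interpolates the keypoint depths, plus
  exact 3 × 3 depth patches at the keypoint pixels. The static arch needed
  for a target curvature comes from inverting the circumcircle relation
  `R = L²/(8δ) + δ/2` (`archSagForCurvature`). Oscillations are sampled
  sinusoids rescaled so their realised extrema hit the nominal peak-to-peak
  amplitudes exactly; that makes the depth/coordinate features *analytic*
  round trips (equal to their targets to 1e−6 and better with cv = 0).
* For MAI, checkerboard-free speckle texture (a smoothed random field —
  dense flow needs texture) is translated with the left body half faster
  than the right: speeds `v(1±m)` give an exact target ratio `m`.
* The keypoint template (poll ahead of withers, scapulae and tuber coxae
  mirrored about the spine, chord withers→sacral = 120 cm with the lumbar
  midway) is a fixed anatomical layout; no geometry is published.

What the generator does **not** emulate: real sensor noise statistics,
perspective distortion, body-shape variation between animals, udder/head
motion artefacts, or keypoint-detector localisation error. Passing
round-trip tests therefore demonstrates the *extractors'* correctness and
the pipeline's calibration, not field performance on farm video.

## Feature screening

Tree-based importances are biased toward features that merely offer many
split points, so screening is permutation-corrected:

1. Random-forest Gini (mean decrease in impurity) importance of the six
   features (ranger back-end; 500 trees, `sqrt(d)` candidate features per
   split, unlimited depth — unspecified in the source and recorded in the
   configuration).
2. **PIMP**: the sample labels are permuted B = 50 times; the forest is
   refitted each time (fresh derived seeds per permutation), building each
   feature's importance distribution under the null hypothesis.
3. The right-tail p-value uses add-one smoothing,
   `p = (1 + #{null ≥ observed}) / (1 + B)` — ties count against the
   observed value and p is never exactly 0, the standard convention for
   permutation tests.
4. **Benjamini–Hochberg** step-up adjustment; features with adjusted
   p < 0.05 are retained.

The permutation test compares **raw** impurity decreases. With fully grown
trees the decrease summed over all features telescopes to a label-invariant
constant, so only the allocation across features carries signal; comparing
raw values (equivalently, shares of that constant) makes the test powerless
at d = 1 — a structural property of impurity importance, not of this
implementation — and well-behaved for d ≥ 2. A Kruskal–Wallis inter-group
p-value per feature is reported alongside for context (no test is named in
the source for that column) but never drives retention.

On pure-noise tables the procedure retains anything at all in well under 5%
of seeded runs (the smallest achievable raw p is 1/51, so BH at 0.05 over
six features needs at least three features simultaneously above their
entire nulls), and on tables with three strong, one weak and two null
features it retains exactly the strong trio in the overwhelming majority of
runs — both properties are asserted in the test suite.

## Fusion classification and evaluation

Retained (or user-chosen) features are z-scored with statistics estimated
on the training split only, then fed to Random Forest (500 trees), KNN
(k = 5, Euclidean distance on z-scores) and an RBF-kernel SVM (C = 1,
gamma = 1/d) — hyperparameters are package defaults, configurable, as the
source specifies none. Data are split 8:2 stratified by class (the
published cohort of 741 sequences splits 593/148). Reports carry the 3 × 3
confusion matrix and metrics recomputable from it alone: accuracy,
per-class sensitivity TP/(TP+FN) and specificity TN/(TN+FP), per-class F1
and macro F1 (arithmetic mean). Degenerate conventions: F1 = 0 when
precision + recall = 0, and a zero-denominator sensitivity/specificity is
reported as 0 with a warning.

The experiment grid (`runFusionGrid`) evaluates each single feature and the
named fusions (BC+MAI+VOB, +VOH, +TI, all six) under all three learners.
Whether published grids of this kind come from one split or from
cross-validation is not stated; the package reports per-seed results and
lets the caller aggregate over seeds, which is what the acceptance tests do
(medians over 20 seeds).

## Keypoint metrics

PCK@t counts a prediction correct when its Euclidean distance to ground
truth is at most `t · max(H, W)` of the heatmap extent. AP and AR average
precision and recall over a threshold ladder; the default ladder scales
0.50–0.95 (step 0.05) by the base threshold 0.05 into normalised-distance
thresholds, since no exact ladder is published and no per-keypoint
similarity constants exist for cattle. In this fixed-set pose task every
annotated keypoint has exactly one prediction, hence FP = FN per threshold
and AP = AR unless a visibility mask excludes points — the mask is
supported for that case.

## Network forward passes

The bespoke blocks are implemented as pure, desk-testable tensor maps:

* **ASSA**: window tokens produce `S = QKᵀ/√d + B`; dense attention is a
  row softmax of S; sparse attention squares the positive part
  (`ReLU(S)²`). As printed, the sparse weights are unnormalised, so rows
  are normalised by their sum + 1e−6 to be commensurate with the dense
  branch (an all-negative row then contributes exactly zero rather than
  the uniform row a softmax would give). The two branches are fused with
  softmax weights over two learnable scalars — the simplest reading of
  "weighted fusion", which guarantees the weights sum to 1.
* **FRFN**: partial 3 × 3 convolution (first quarter of the channels),
  linear expansion with GELU, channel split, depthwise 3 × 3 convolution of
  one half gating the other **elementwise per channel** (the
  channel-matrix-multiplication glyph is read as channelwise gating, the
  standard construction in this design; flagged as an open
  interpretation), linear reduction with GELU.
* **AGC**: `Y = Σₖ Wₖ X (Aₖ + Bₖ + Cₖ) + R(X)` over Kv = 3 spatial subsets,
  with `Aₖ = Λ^{-1/2} Āₖ Λ^{-1/2}` the symmetrically normalised predefined
  adjacency, `Bₖ` a zero-initialised learnable offset and `Cₖ` a row-softmax
  embedded-Gaussian similarity graph. The residual is the identity when
  channel counts match, else a 1 × 1 aligning map. The three subsets follow
  the root / centripetal / centrifugal convention around the skeleton
  centre (the lumbar node) on the 8-keypoint cow graph (spine chain with
  scapulae at the withers and tuber coxae at the sacral tuber) — no subset
  definition is published for this skeleton.

Every forward pass is tested against an independent straight-line
evaluation of the printed equations, plus structural properties
(row-stochasticity, spectral radius of the normalised adjacency ≤ 1,
linearity with frozen graphs, pure-residual identity).

## Numerical and design notes

* All randomness flows from explicit seeds; functions that consume a seed
  restore the caller's RNG state. Cohorts, permutations and learners use
  named derived substreams, so stages are independently reproducible.
* Depth is processed in double-precision mm in memory; on disk it is
  16-bit integer mm (grayscale PNG, written by the package's own minimal
  encoder since the installed PNG writer is 8-bit only), which quantises
  features derived from depth by at most 0.1 cm.
* Problem sizes in the tests and the acceptance script (60-frame 160 × 96
  sequences; 50-tree forests inside the 100-run screening calibration;
  500-sample screening tables; 20-seed fusion medians) are the package's
  desk-scale choices: large enough for the asserted properties to be
  stable, small enough to run routinely.
* Known limitations: the simulator's analytic signals make extractor checks
  exact but optimistic; MAI depends on texture quality and is validated
  only to 30% relative error; TI and LSAS ride on edge keypoints whose
  depth is noisy in real recordings (one reason they screen out); severity
  is an ordinal scale treated as nominal by the classifiers.

## One command end to end

```{r demo, eval = FALSE}
res <- runDemo(list(nPerClass = c(sound = 8, mild = 8, severe = 8)),
               seed = 1, outDir = "demo_out")
res$screening
head(attr(res$grid, "summary"))
```

`runDemo()` simulates a cohort, runs the preprocessing chain, extracts
features, screens them and evaluates the fusion grid, writing CSV/JSON
reports plus a run log with all seeds; identical config and seed give
byte-identical outputs.
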