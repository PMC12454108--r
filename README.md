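# bovigait

Overhead-view RGB-D gait analysis and lameness severity classification for
dairy cows.

Lameness affects roughly one cow in five worldwide and is chronically
under-detected by eye. A depth camera mounted above a walkway sees every
animal without occlusion; what it can measure is the posture and motion of
the **back and head**. `bovigait` turns such recordings — depth frame
stacks, optional RGB frames, and the pixel tracks of eight back keypoints
(poll, withers, left/right scapula, lumbar region, left/right tuber coxae,
sacral tuber) — into a three-level grading: *sound*, *mild* or *severe*
lameness.

The pipeline:

1. **Depth preprocessing** — clip to [1200, 2600] mm, void-aware bilateral
   (spatial σ 5 px, range σ 0.1 on normalised depth) and 3×3 median
   filtering, nearest-neighbour hole filling; sequences with ≥ 10% body
   void rate in any frame are rejected.
2. **Six gait features** per walking sequence:
   - `BC` back curvature (1/cm): max over frames of the curvature
     `k = 1/R = 4·Area/(|a||b||c|)` of the circle through withers, lumbar
     and sacral tuber in the sagittal plane;
   - `MAI` movement asymmetry index: dense (Farneback-style polynomial
     expansion) optical flow magnitudes averaged over the left and right
     body halves, `|μL − μR| / (μL + μR)`;
   - `VOB`, `VOH` vertical oscillation of back and head (cm): temporal
     depth range at the spine keypoints (max of three) and at the poll;
   - `TI` trunk inclination (cm): max |left − right| depth difference at
     scapulae and tuber coxae;
   - `LSAS` lateral sway amplitude of the spine (cm): max peak-to-valley of
     three spine abscissae.
3. **Unbiased feature screening** — random-forest Gini importance with a
   50-permutation importance correction (PIMP): right-tail p-value
   `(1 + #{null ≥ obs}) / (1 + B)` per feature, Benjamini–Hochberg FDR at
   0.05.
4. **Fusion classification** — z-scored retained features into RF / KNN /
   SVM on a stratified 8:2 split, evaluated by accuracy, per-class
   sensitivity/specificity and macro F1 from the 3×3 confusion matrix.

Also included: PCK / AP / AR keypoint-evaluation metrics, desk-testable
forward passes of the adaptive sparse self-attention, feature-refinement
feedforward and adaptive graph-convolution blocks, and a **synthetic gait
simulator** calibrated to published per-class feature means so the whole
pipeline is testable without farm data (none is publicly deposited).

## Worked example

Simulate one noise-free severe-lameness sequence and re-extract its
features:

```r
library(bovigait)
prm <- gaitClassParams("severe", targetCv = 0)
seqv <- simulateSequence(prm, seed = 7)
seqv
#> WalkingSequence: 60 frames of 160 x 96 px
#>   label: severe | scale: 1.25 cm/px | camera: 3200 mm | fps: 30
#>   textured frames: present
round(extractFeatures(seqv), 5)
#>       BC      MAI      VOB      VOH       TI     LSAS
#>  0.00093  0.05379 12.90000 17.28000  6.76000  9.18000
```

The five depth/coordinate features come back exactly at the severe-class
calibration targets (BC 0.00093 1/cm, VOB 12.90 cm, VOH 17.28 cm, TI
6.76 cm, LSAS 9.18 cm); the flow-based MAI recovers its 0.064 target to
within the expected optical-flow error.

Screen features on a 450-sequence cohort in which BC/MAI/VOB carry the
class signal, VOH is weak, and TI/LSAS carry none:

```r
means <- classFeatureMeans(); grand <- colMeans(means)
X <- do.call(rbind, lapply(lamenessClasses(), function(cl) {
    tm <- means[cl, ]
    tm["VOH"] <- grand["VOH"] + 0.25 * (means[cl, "VOH"] - grand["VOH"])
    tm["TI"] <- means["sound", "TI"]; tm["LSAS"] <- means["sound", "LSAS"]
    sampleFeatureVectors(gaitClassParams(cl, targetMeans = tm), n = 150,
                         seed = match(cl, lamenessClasses()))
}))
screenFeatures(X[featureNames()], X$label, seed = 1)
#> ScreeningResult: B = 50 permutations, alpha = 0.05
#>  feature  gini     p_kw  p_raw  p_adj retained
#>       BC 0.319 5.50e-87 0.0196 0.0392     TRUE
#>      MAI 0.403 2.16e-87 0.0196 0.0392     TRUE
#>      VOB 0.237 1.39e-85 0.0196 0.0392     TRUE
#>      VOH 0.032 3.65e-27 1.0000 1.0000    FALSE
#>       TI 0.004 9.98e-01 1.0000 1.0000    FALSE
#>     LSAS 0.005 8.65e-01 1.0000 1.0000    FALSE
```

The three informative features sit above all 50 permutation nulls
(p_raw = 1/51 ≈ 0.0196) and survive BH at 0.05; the weak and null features
do not — note TI's Kruskal–Wallis p is ~1 here while in screening it is the
*permutation-corrected* p that decides. Classify with the retained fusion:

```r
grid <- runFusionGrid(X, subsets = list("BC+MAI+VOB" = c("BC","MAI","VOB")),
                      algos = "RF", seed = 1)
grid[["BC+MAI+VOB|RF"]]
#> ClassificationReport [ RF ] features: BC+MAI+VOB
#>   ACC: 1  Macro F1: 1
#>   SENS: sound 1  mild 1  severe 1
#>   SPEC: sound 1  mild 1  severe 1
```

`runDemo(config, seed, outDir)` chains simulate → preprocess → extract →
screen → classify and writes CSV/JSON reports; a thin CLI with the same
stages lives at `inst/cli/bovigait` (subcommands `simulate`, `preprocess`,
`extract`, `screen`, `classify`, `eval-keypoints`, `selfcheck`, `demo`).

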