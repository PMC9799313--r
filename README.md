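# spotbelief

Self-tuning detection of small fluorescent objects in 2D microscopy
images, and Dempster–Shafer belief labelling of the detected objects
against image-level labels.

## The problem

Fluorescence microscopy of small structures — sub-diffraction protein
assemblies in STED images, amyloid deposits in confocal tissue sections —
rarely comes with object-level annotation. What is available is an
image-level label (the cell line, the donor's diagnosis), and intensity
scale, background, and object density vary so much across images and
channels that any fixed detection threshold tuned on one image fails on
the next. `spotbelief` is for analysts who need (a) an object detector
whose single intent parameter behaves consistently across heterogeneous
images, and (b) per-object *graded* evidence for labels — belief,
disbelief, and uncertainty — instead of a hard classification, including
when evidence from models trained on different datasets must be fused
with an explicit measure of their conflict.

## The method

**Detection.** The response is the clamped-negative Laplacian
*V* = |min(*G*<sub>post</sub> ∗ ∇²(*G*<sub>pre</sub> ∗ *I*), 0)|, which
peaks over bell-shaped fluorescent deposits. The per-image threshold is

&nbsp;&nbsp;&nbsp;&nbsp;*T* = *μ*<sub>g</sub> · *σ*<sub>g</sub><sup> *z*/PRC</sup>,&nbsp;&nbsp; *z* = *k*<sup>1/4</sup>,

where *k* is the excess kurtosis of the positive response and
*μ*<sub>g</sub>, *σ*<sub>g</sub> its geometric mean and standard
deviation. The kurtosis tracks the tailedness of each image's response
distribution, so one PRC value (> 1 favours recall, ≤ 1 precision)
lands at comparable operating points everywhere; detections are exactly
invariant to global intensity scaling.

**Labelling.** Each object's feature descriptor (summed intensity, area,
summed response) is scored by Mahalanobis distance to a reference
population, standardized within its image, and converted to a
plausibility through Cantelli's bound Pr[*Z* ≥ *z*] ≤ 1/(1 + *z*²).
Swapped-model plausibilities yield a (*p*, *q*, *r*) belief triplet per
object, with nested-label algebra (plausibility subtraction, products of
complements) for hierarchies like background ⊂ scaffold ⊂ caveolae.

**Fusion.** Two models' masses *t*, *s* for the same object combine by
Dempster's rule: joint mass *ts*/(1 − *κ*) with conflict
*κ* = (1−*s*)*t* + (1−*t*)*s*, and weight of conflict
*W* = −ln(1 − *κ*) reported per object (infinite, and flagged, at
complete contradiction).

A simulator reproduces the in-silico validation conditions (512×512
scenes, Gaussian-PSF sources bright σ = 3 / dim σ = 6 at quarter
intensity, Gaussian + Poisson noise as fractions of the 8-bit range), so
every stage is testable with ground truth and no external data.

## Worked example

Simulate a 25 bright + 25 dim scene at the protocol noise level, detect,
and score the objects against a background model fitted on a second,
dim-only scene:

```r
library(spotbelief)

sim <- simulate_image(simulation_config(n_bright = 25, n_dim = 25,
                                        min_separation = 30, seed = 11))
cfg <- detection_config(pre_sigma = 6, post_sigma = 1, prc = 2,
                        kurtosis_fallback = "clamp")
det <- detect_objects(sim$image, cfg)
det
#> <component_set> 50 components on a 512 x 512 grid (8-connectivity)
attr(det, "threshold")
#> [1] 0.1118726
match_objects(det, sim$truth)
#> <match_result> tp 50, fp 0, fn 0; precision 1.000, recall 1.000
```

All 50 sources are recovered with no false positives; the threshold
0.112 was derived from the image itself (excess kurtosis 20.9, z = 2.14).
Now the belief stage:

```r
resp <- adaptive_threshold(compute_response(sim$image, cfg), cfg)
objects <- object_table(det, sim$image, resp, image_id = "demo")

bg <- simulate_image(simulation_config(n_bright = 0, n_dim = 60,
                                       min_separation = 12, seed = 12))
bg_objects <- object_table(detect_objects(bg$image, cfg), bg$image,
                           adaptive_threshold(compute_response(bg$image, cfg), cfg),
                           image_id = "bg")
model <- fit_reference_model(bg_objects, "background")
glance(model)
#> # A tibble: 1 × 5
#>   label      n_objects n_features ridge condition_number
#>   <chr>          <int>      <int> <dbl>            <dbl>
#> 1 background        68          3     0         2552816.

labelled <- label_objects(objects, model)
labelled[1:3, c("object_id", "mahalanobis", "z", "pl")]
#> # A tibble: 3 × 4
#>   object_id mahalanobis      z    pl
#>       <int>       <dbl>  <dbl> <dbl>
#> 1         1        1.88 -0.971 0.514
#> 2         2       19.2   1.10  0.454
#> 3         3       19.0   1.06  0.469
```

Object 1 is a dim spot: under 2 Mahalanobis units from the dim-only
background population, so the proposition "this is background" stays
plausible (pl 0.51). Objects 2–3 are bright spots roughly 19 units away;
after within-image standardization, Cantelli's bound caps the
plausibility that they are background at ≈ 0.46. A second model fitted
on a bright-only reference would convert these plausibilities into full
(*p*, *q*, *r*) triplets via `label_objects(..., swap_model = )`, and
`combine_labelled_tables()` fuses two labelled tables with per-object
conflict weights.

A command-line interface wrapping the same functions is installed at
`exec/spotbelief` (subcommands `detect`, `model`, `label`, `combine`,
`simulate`, `evaluate`, `run`).

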