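---
title: "Methods: joint DME classification and hard-exudate detection"
author: "fundusfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint DME classification and hard-exudate detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Diabetic macular edema (DME) is graded on colour fundus photographs via a
well-established proxy: hard exudates (HE), small bright lipid deposits,
found *at or within one optic-disc diameter (1DD) of the centre of the
macula* indicate DME (the ETDRS-derived criterion). This package
implements a complete, desk-scale version of a workflow built around that
criterion:

1. three human annotators draw HE bounding boxes per image, fused into a
   single ground truth by an IoU-based consensus rule;
2. a single *fusion* network with one shared convolutional backbone
   performs HE lesion detection (feature-pyramid detection head) and
   image-level DME classification (convolution → global average pooling →
   fully connected head) in one forward pass;
3. anatomical landmarks (optic disc, macula) support the geometric 1DD
   rule and a clinician-facing overlay (HE boxes in blue, disc box and
   1DD circle in white);
4. evaluation uses an image-level detection protocol plus
   sensitivity/specificity/accuracy/AUC with 95% CIs, the DeLong test for
   correlated AUCs, and the pooled two-proportion z-test.

Everything is exercised on synthetic fundus scenes so the full mechanism
is testable without any image downloads.

## Coordinate and box conventions

Boxes are stored in corner form, 0-based, continuous, half-open:
`[xmin, xmax) × [ymin, ymax)` with the origin at the top-left pixel
corner. Area is `width × height`, so a box with integer corners covers
exactly that many unit pixels and the IoU of integer boxes can be checked
*exactly* against a pixel-rasterisation oracle (the test suite does this).
Two boxes sharing only an edge have IoU 0 — forced by area arithmetic.
Annotation files on disk use the common `x, y, width, height` dialect and
are converted at the I/O boundary. Whether an annotation tool counts from
0 or 1 is immaterial to every IoU-based quantity; the package fixes
0-based and documents it.

## Annotation consensus

Two annotators' box sets are merged as follows: boxes overlapping with
**IoU > 0.15** are matched one-to-one and the **larger-area** box of each
matched pair is kept verbatim (not the union — the rule names one of the
two boxes); pairs at or below the threshold are not matched and both
boxes are retained; all unmatched boxes are retained. The three-annotator
ground truth is built pairwise: raters 1 and 2 first, then the result
against rater 3 — the `((1,2),3)` schedule. The general many-to-many case
is order dependent; the one-to-one case is not (up to equal-area ties,
which keep the first argument's box for determinism).

When one annotator's box overlaps several of the other's above threshold,
the matching is resolved by **maximising total IoU over one-to-one
matchings** (exhaustive with branch-and-bound up to 9×9 boxes, greedy
descending-IoU above that). A pure greedy rule was considered and is what
most detection toolkits use, but greedy and optimal matching can disagree
on contrived overlap patterns, and the optimal matching is the one whose
behaviour is fully characterised by the enumeration oracle in the test
suite; the two coincide on all realistic instances.

## The fusion model

One backbone of four stride-2 3×3 convolutions (widths `w, 2w, 4w, 4w`)
feeds two paths:

* **Detection path**: 1×1 lateral projections of the stride-8 and
  stride-16 feature maps into a bi-directional feature pyramid (top-down
  pass with nearest-neighbour upsampling, bottom-up pass with average
  pooling, fast normalised fusion weights `relu(w_i)/Σ relu(w_j)+ε`),
  then a shared 3×3 head producing per-anchor class logits and box
  offsets. Anchors: 3 scales × 1 aspect ratio per level (sides 0.8, 1.26,
  2.0 × the level stride); assignment IoU ≥ 0.5 positive, < 0.4 negative,
  the band between ignored, and every ground-truth box additionally
  claims its best-overlapping anchor. These are the conventional defaults
  of single-stage detection heads and are exposed in the configuration.
* **Classification path**: exactly three layers — one 3×3 convolution,
  global average pooling, and one fully connected layer with dropout —
  emitting the DME probability `p`. In the fusion model the convolution
  reads the shared trunk output: the top backbone feature concatenated
  with the matching pyramid level (both derive from the single backbone,
  so the shared-gradient coupling is preserved and strengthened); the
  standalone classifier of the dual baseline reads the backbone top
  alone. The pooled feature vector is standardised per feature by
  running (EMA) statistics before the fully connected layer — the
  desk-scale counterpart of the normalisation that full-scale backbones
  apply throughout. Without it, the read-out gradient under class
  imbalance is dominated by the overall feature mean rather than the
  between-class contrast and the head can stall on a plateau for the
  whole training budget.

The backbone is a configurable width/depth extractor rather than a
byte-faithful compound-scaled architecture: the contribution being
verified is the *fusion pattern and the fused loss*, and the topology
(shared backbone, pyramid detection path, three-layer classification
path) is preserved at every scale. The dual baseline is represented by
single-task instances of the identical components, which makes the
resource comparison exact: the fusion model is smaller than the dual
pair by precisely one backbone.

### The fused loss

$$E_{loss} = \omega_{ob} E_{ob} + \omega_{cl} E_{cl}, \qquad
E_{cl} = -\alpha (1 - p_t)^\gamma \ln p_t$$

with $p_t = p$ for a DME image and $1 - p$ otherwise. Defaults
$\alpha = 0.25$, $\gamma = 2$; the balanced weights are
$\omega_{ob} = 0.5$, $\omega_{cl} = 100$ (equal weights correspond to the
initial-training phase; an auto-balancing scheme proportional to inverse
loss magnitudes is describable but the fixed weights are the operative
setting and the package defaults). $E_{ob}$ is the standard single-stage
detection loss: per-anchor sigmoid focal classification (conventional
$\alpha_t$ weighting — $\alpha$ on positives, $1-\alpha$ on negatives)
plus Huber box regression on matched anchors, normalised by the
matched-anchor count (minimum 1, so images without lesions contribute a
pure background term). Numerical choices: natural logarithm; $p_t$
clamped to $[10^{-7}, 1-10^{-7}]$; $E_{cl}$ is **averaged** over the
minibatch (summing would couple the effective classification weight to
the batch size).

Optimisation is AdamW (decoupled weight decay 0.01), dropout 0.2, batch
size 16 and learning rate $10^{-4}$ at full scale. Training applies
random horizontal/vertical flips (probability 0.5 each, independent) to
image and boxes jointly; the DME label is flip-invariant because the 1DD
rule is a Euclidean-distance criterion. The whole engine (im2col
convolutions, explicit backward passes, AdamW) is implemented in
vectorised base R; gradient correctness is verified against central
finite differences in the test suite.

## Landmarks and the 1DD rule

The disc diameter of a detected box is the mean of its width and height
(discs are near-circular). The macula centre is the box centroid. An
image is DME iff the distance from the macula centre **to the nearest
point of any HE box** is at most one disc diameter — the boundary is
inclusive ("at or within"), and the nearest-point convention (rather than
the HE centre) errs on the side of clinical sensitivity. Missing
landmarks raise an explicit *ungradable* error, never a silent non-DME.
The rule is exactly scale invariant and monotone in the lesion set; both
properties are tested.

Landmark detection is an interface: any detector returning scored,
categorised boxes qualifies, and the reference implementation is a
single-task instance of the package's own detection head (the task
defines outputs, not a particular detector family). Landmark "accuracy"
in this package means an IoU > 0.5 match on scenes where the landmark
exists — the criterion is stated explicitly because presence-accuracy
figures are otherwise ambiguous.

## Preprocessing

Images are cropped to the tight bounding box of pixels whose channel-mean
grayscale exceeds 10/255 (a threshold robust to compression noise in dark
borders, exposed in the configuration), then resized bilinearly to the
square model input (640×640 at full scale). The tight crop may be
non-square; the default accepts anisotropic scaling since the input is
square regardless, and a pad-to-square mode is provided for isotropic
scaling. Every crop/resize returns its affine transform so detections can
be mapped back to source coordinates; boxes falling fully outside the
crop are dropped with a warning.

## The synthetic scene generator

Scenes are deliberate caricatures of a 45°-FOV fundus photograph: a dark
surround, a bright circular fundus region (radius 0.48 × side) with a
radial vignette, a bright near-circular optic disc nasally (diameter
~0.17 × side ± 5%), a darker macula ~2.5 disc diameters temporal to the
disc, and 0–5 small bright HE ellipses (sides 3.5–8% of the image). The
DME label is drawn first (default prevalence 0.42, mirroring a training
population of roughly 42% DME); a DME scene places an exudate cluster of
2–3 lesions with centres within 0.55 DD of the macula centre (DME
typically presents as clustered exudate near the fovea), while every
other lesion — in either class — keeps a nearest-point distance above
2 DD. The wide margin between the two regimes is what makes the scenes
*easy*: the class difference is a coarse spatial pattern rather than a
sub-pixel distance discrimination, which is the regime a tiny
CPU-trainable model can learn reliably. The stored label is then
**recomputed from the realised geometry** with the 1DD rule, so label
and geometry agree exactly by construction (and the class validity
enforces it). Simulated annotators see each true box with Gaussian corner jitter
(SD 2 px by default), miss it with probability 0.1, and add a spurious
box with probability 0.05; boxes are re-validated to at least 2×2 px.
Synthetic patients own 1–4 images and the train/validation/test split
partitions *patients*, never images.

What the generator does **not** emulate: photorealistic texture, vessels,
drusen or other bright-lesion mimics, illumination/quality variation, or
graded lesion conspicuity. Passing tests therefore demonstrate that the
mechanisms (consensus, fused training, 1DD rule, evaluation protocol) are
correctly implemented and learnable signal is recovered end to end — not
that any particular clinical accuracy would be reached on real fundus
photographs.

## Evaluation protocol and statistics

Image-level detection outcomes: TP if any predicted box overlaps any GT
box with IoU **> 0.15**; TN if both sets are empty; FP if GT is empty but
predictions exist; FN otherwise (no prediction, or all overlaps at or
below threshold). Score thresholding (default 0.3) and NMS (IoU 0.5) are
applied upstream at inference, so "any predicted box" means any box the
model actually reports. Sensitivity, specificity and accuracy carry 95%
CIs — Wald by default, matching the symmetric intervals usually printed;
Wilson available. A zero-denominator rate is reported absent, never 0.

AUC is the tie-corrected Mann–Whitney concordance (midranks, 0.5 per
tie), identical to trapezoidal integration of the empirical ROC; the
DeLong placement-value covariance gives the AUC CI and the correlated-AUC
z-test (degenerate variance with unequal AUCs yields `NA` with a
warning; the CI is clipped to [0, 1]). The two-proportion z-test uses the
pooled standard error without continuity correction, as named. Model
proportions on the same images are in truth paired, so a McNemar-style
comparison would also be defensible; the unpaired pooled z is what the
protocol names, and is what the package computes (significance level
0.05 throughout). The operating point for reported
sensitivity/specificity is unspecified in such protocols; the package
offers a fixed 0.5 cut and Youden-optimal thresholding on a validation
split (default Youden) and always reports the threshold-free AUC.

Messidor-style DME risk grades map 0, 1 → non-DME and 2 → DME.

## Desk-scale study sizes

The standard experiment (`runSyntheticStudy()`, also what
`scripts/acceptance.R` re-runs) uses 200 training and 100 held-out scenes
at 128×128 with a narrow backbone (8 base channels, 16 pyramid channels),
batch size 8, 20 epochs, learning rate 3e-3 — chosen as a configuration a
single CPU trains in a few minutes while leaving clear headroom over the
verification floors (held-out AUC ≥ 0.9, image-level detection
sensitivity and specificity ≥ 0.7). The learning-rate increase over the
full-scale 1e-4 reflects the ~10^4-fold smaller parameter count and
dataset; weight decay, dropout, the focal parameters and the loss weights
are kept at their full-scale values. Statistical oracles run at the sizes
their Monte-Carlo error requires: 10,000 permutation replicates for the
DeLong check, 2,000 null simulations for the z-test type-I error, 1,000
scenes for rule recovery.

## Known limitations

* The backbone is not a compound-scaled architecture and no pretraining
  is used; headline clinical accuracies are out of scope by design.
* The consensus rule inherits the order dependence of its pairwise
  schedule in many-to-many cases; this is documented rather than hidden.
* The landmark detector is trained per-task; disc-obscuring pathology
  (disc edema, myelinated fibres) has no synthetic counterpart here.
* Pixel-mask (as opposed to box) consensus, lesion-level mAP, rotated
  boxes and DICOM handling are non-goals.
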