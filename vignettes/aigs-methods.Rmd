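---
title: "Methods: models, morphometry, and phantom design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, morphometry, and phantom design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(aigs)
```

This vignette is the package's account of its science: the screening
architecture it implements, the closed-form morphometry it measures, what
the synthetic phantoms do and do not emulate, and the numerical and design
choices made where the published description left the design open.

## The screening network

The pipeline mirrors how an ophthalmologist screens a macula-centered
fundus photograph. Six lightweight models cooperate:

1. a **multi-task segmenter/classifier** (`build_mtl_unet()`) that outputs
   a 3-plane map — disc, cup, fovea heatmap — plus a direct glaucoma
   probability from a branch off its bottleneck;
2. a **cupping FFCN** (`build_ffcn(9)`) that classifies the eye from nine
   numeric disc parameters derived from the segmentation;
3. a **hemorrhage segmenter** and 4. a **mask-assisted hemorrhage
   classifier** operating on a square region of interest cropped to about
   twice the disc diameter, the classifier seeing a six-channel stack
   (ROI RGB + segmented hemorrhage mask RGB);
5. an **RNFLD classifier** on the full image; and
6. a **fusion FFCN** that combines the four binary sub-model decisions
   into the referral decision.

A case is labeled a referral if any sub-model fires (`referral_label()` is
a logical OR; the fusion FFCN learns this rule from data, which keeps the
decision robust over a wide band of fusion thresholds). The **adjusted**
rule (`adjust_decision()`) then upgrades fused-negative cases to
*glaucoma suspect* when any structural probability is high (cupping
> 0.65, RNFLD > 0.8, DH > 0.75, strict inequalities). Escalation can only
upgrade, so on any scored dataset the adjusted rule has sensitivity at
least that of the fused rule and specificity at most that of the fused
rule; setting all three escalation thresholds to 1 disables it exactly.

The fusion head consumes the four *binary* decisions by default. An
argument can be made for feeding probabilities or raw disc parameters
instead; the binary form is the default here because it is what makes the
fused decision nearly threshold-invariant (binarised inputs can produce at
most 16 distinct fused probabilities), and the alternative is a one-line
change at the `fuse_predictions()` call site.

## Model family and the parameter-count constraint

All convolutional members share one construction (`arch_config()`): a
5x5 stem convolution to `base_channels` filters, encoder stages of
(3x3 convolution doubling channels up to a cap, 2x2 max-pool), and a
bottleneck-narrowing-with-attention (BNA) block that halves the channel
count step by step, each step gated by squeeze-excitation channel
attention (global average pool, reduction-4 dense layer, sigmoid gates in
(0,1)). At the reference setting — 512x512x3 input, 16 base channels, five
stages — the encoder terminal is 16x16x256 and the BNA output 16x16x8.
Classification heads flatten that output into two fully-connected +
dropout blocks and a 2-way softmax.

The published description of the reference classifier fixes the encoder
shape, the BNA output, and the total trainable parameter count
(1,718,770), but not the widths of the two head layers or the BNA
internals. We resolved them by enumeration
(`inst/scripts/resolve_head_widths.R`): with the encoder and BNA as above,
head widths (288, 196) give the printed total exactly, and they are the
*unique* integer solution with plausible widths for this body. Cleaner
textbook variants (3x3 stem, plain dense attention) admit no plausible
integer solution at all, which is itself evidence the resolved design is
close to the intended one. The widths are recorded in `arch_config()` and
are ordinary configuration, not constants.

The multi-task model uses four encoder stages (terminal 32x32x256) with
the BNA narrowing to 16 channels, so its classification branch taps a
32x32x16 bottleneck output — the smallest array in that model — before
flatten and the head. Its decoder mirrors the encoder: nearest-neighbour
upsampling, concatenation with the stage's pre-pool feature map, and a 3x3
convolution to half the skip width (floored at the base width), closing
with a 1x1 convolution to the 3-plane sigmoid map.

Training uses Adam. Published hyperparameters are absent, so the defaults
are the field's: learning rate 1e-4 (tests use 1e-3 at their reduced
scale, where the smaller images tolerate larger steps), batch size fit to
memory, Dice loss `1 - (2*sum(pt) + 1) / (sum(p) + sum(t) + 1)` for
segmentation (the +1 smoothing keeps empty masks stable) and categorical
cross-entropy for classification. All randomness (weight init, shuffling,
dropout) draws from R's RNG, so a single seed reproduces a run bit-for-bit
on one machine.

## Morphometry

All measurements are taken on planes binarised at 0.5, keeping the largest
connected component (smaller ones are dropped); the cup is intersected
with the disc so the containment invariant and the identity
`NRRA/DA + ACDR = 1` hold exactly in pixel arithmetic.

* Vertical/horizontal CDRs are ratios of pixel extents; the major-axis CDR
  projects both components onto the disc's fitted major axis; the area CDR
  is a pixel-count ratio; the perimeter CDR a contour-length ratio.
* Perimeters are measured as the length of the boundary polygon after
  subsampling the traced contour to about 96 vertices, which suppresses
  the staircase overestimate of pixel chains; on discs of 200 px diameter
  and above this estimator is accurate to well under 1%, and circularity
  `4*pi*area/perimeter^2` of a rasterised circle comes out above 0.99.
* The ellipse fit is moment-based (with the 1/12 pixel-quantisation
  correction); the circle fit is linear least squares on the outer
  contour, with a centroid + area-equivalent-radius fallback for
  degenerate contours.
* The fovea is encoded as a Gaussian heatmap `H = exp(-(dx^2 + dy^2) /
  (2*sigma^2))` on a patch whose side is 20% of the image (rounded);
  decoding takes the intensity-weighted centroid of the half-maximum
  region around the global peak and reports the fovea absent when the
  plane maximum is below 0.2. The default sigma is 8% of the image side;
  it is a shape parameter of the training target, not a measurement.
* Sector rim ratios use a frame anchored at the measured disc centroid
  with 0 degrees pointing at the fovea (temporal) and +90 degrees
  superior (image-up). T/S/N/I are 90-degree quadrants; IT and ST are
  45-degree wedges straddling the T-I and T-S boundaries (centered at
  -67.5 and +67.5 degrees). The published material names these sectors but
  never defines their boundaries; a fovea-anchored frame is the natural
  choice because the same material uses the disc-fovea axis for its angle
  parameter. Disc size classes default to "small" above a disc size index
  of 3.0 and "large" below 2.4 (configurable; no published cutoffs exist).

When the fovea cannot be decoded, parameters that need it (disc size
index, disc-fovea angle, sector ratios) are reported absent, the cupping
FFCN receives 0 for those features, and the report is flagged — the
pipeline continues with the remaining models rather than failing the
image. A missing disc, by contrast, is a gradability failure.

## The phantom generator

Phantoms exist so that every stage has an exact oracle, not to look
photorealistic. A scene is: a reddish background with low-frequency
texture and vignetting; an elliptical disc containing an elliptical cup
(both rendered with a ~1 px anti-aliased edge); a fovea darkening; five to
seven vessel-like quadratic curves leaving the disc and arching around the
macula; optional dark-red hemorrhage blobs at the disc margin; optional
multiplicative arcuate darkening bands (contrast fraction 0.05-0.2)
running from the disc margin toward the fovea. Pixel values are quantised
to 8-bit levels at render time so the in-memory image equals its PNG round
trip, and identical (spec, seed) pairs are byte-identical.

`random_phantom_spec()` draws scenes emulating macula-centered
photographs: the fovea near the image center, the disc nasal at 2.4-3.4
disc diameters (the plausible disc size index range; laterality mirrors
the temporal direction), disc ovality up to about 1.2, glaucomatous eyes
with CDR 0.65-0.88 against 0.30-0.55 for normals. When a requested disc is
too large for that geometry to fit the frame the whole scene is translated
rigidly, which preserves the disc size index. The morphometry validation
sweep uses discs of at least 200 px diameter (where sub-pixel effects are
below the 2% agreement target) and places the fovea so its heatmap patch
stays inside the frame — a clipped patch would bias the decoded centroid,
which is a measurement artifact, not a geometry error.

What phantoms do **not** emulate: camera color response, media opacity,
myopic tigroid texture, peripapillary atrophy, realistic vessel trees, or
the label noise of human graders. Passing tests therefore demonstrate that
the pipeline's geometry, decision logic, and statistics are correct and
that the models can learn such structures; they say nothing about clinical
performance on real photographs, which requires the original datasets and
trained weights and is explicitly out of scope.

## Test-scale choices

The shipped tests run everything at reduced scale, chosen as the smallest
sizes at which each property is still meaningfully exercised: 64x64
phantoms with 8 base channels and 3 encoder stages for learning runs
(50 training images / 30 epochs for segmentation, 100 / 20 for
classification — the classification cohort uses proportionally larger
discs so the class difference spans enough pixels at 64x64); a
200-phantom sweep at 512x512 for morphometry agreement (all ratio
parameters within 2% of the analytic values); 5000 null simulations at
n = 200 for the DeLong test's type-I error (0.05 +/- 0.01); 1000
replicates with 500 bootstrap resamples for AUC confidence-interval
coverage (95% +/- 2%). Bootstrap intervals are percentile (not BCa) with
B = 2000 by default.

## Known limitations

* The training engine is single-device CPU code built for correctness,
  reproducibility, and test-scale speed, not for 512x512 production
  training.
* The BNA internals and head widths are a resolved design, exact in
  parameter count and faithful to the stated contract, but not guaranteed
  to match the original implementation layer-for-layer.
* Perimeter-based quantities (PCDR, circularity) are estimator-dependent
  for structures below ~40 px diameter; the documented accuracy targets
  hold for discs of 200 px and above.
* The hemorrhage and RNFLD classifiers ship untrained; training them to
  clinical utility requires real labeled data.
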