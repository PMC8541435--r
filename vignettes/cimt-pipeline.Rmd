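---
title: "Segmenting the intima-media complex and measuring cIMT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting the intima-media complex and measuring cIMT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Carotid intima-media thickness (cIMT) — the distance between the
lumen-intima (LI) and media-adventitia (MA) interfaces of the common carotid
artery wall in longitudinal B-mode ultrasound — is an established
cardiovascular risk marker. Manual delineation is slow and suffers
inter-observer variability, so the goal is a fully automated pipeline:
segment the intima-media complex (IMC, the band between LI and MA) as a
binary mask, then measure its thickness in millimetres.

`cimtseg` implements that pipeline end-to-end:

1. **Preprocessing** — min-max normalization, then Sobel and Prewitt 3×3
   gradient-direction images as a *dual* model input.
2. **Dual-encoder convolutional encoder-decoder** — two weight-independent
   VGG-19-style encoders (one per gradient image), channel concatenation,
   a 1×1 reduction, and a mirrored decoder with 2× upsampling; per-pixel
   softmax over background/IMC.
3. **Morphological refinement** — close (2,30), open (2,30), close (3,30)
   with flat rectangular structuring elements.
4. **Measurement** — per-column foreground run length, per-image maximum,
   cohort mean, and pixels→mm via the scanner calibration (16.66 px/mm).
5. **Evaluation** — precision/recall/F1, Dice, Jaccard with macro and micro
   averaging.

The clinical dataset this design was developed against (100 B-mode images
with two experts' point annotations) is not publicly deposited. The package
therefore ships a **synthetic phantom generator** so every stage is
trainable and testable with exact ground truth.

## The model and its loss

Each encoder block `b` stacks conv(3×3)+BN+PReLU layers (2 convs for blocks
1–2, 4 for deeper blocks) with `base_filters * 2^min(b-1, 3)` channels,
followed by 2×2 max pooling; this follows the VGG-19 channel convention
(64, 128, 256, 512, 512 at full scale). The two encoder outputs are fused by
channel concatenation and reduced with a 1×1 conv+BN+PReLU back to the
single-encoder width. The decoder mirrors the encoder, replacing pooling
with 2× nearest-neighbour upsampling; a final 1×1 convolution and softmax
give per-pixel class probabilities.

Training minimizes mean per-pixel cross-entropy,

$$\mathcal{L} = \frac{1}{N}\sum_{j=1}^{N}\sum_{i=1}^{k} y_{ji}\,
\bigl(-\log \mathrm{softmax}(p_j)_i\bigr),$$

with N the number of pixels and k = 2 classes. (The source publication's
printed formula omits the minus sign; the standard negative log-likelihood
is implemented, so the loss is nonnegative and equals ln k for uniform
predictions.) The optimizer is Adam — the reference work does not name one,
and its 1e-5 learning rate is Adam-scale. Weights use seeded He
initialization; PReLU slopes start at 0.25.

Reference protocol (the full-scale defaults of `model_config()`): batch 8,
50 epochs, 10 steps per epoch, learning rate 1e-5, batch normalization on,
80/20 train/test split, and paired augmentation (rotation ≤10°,
width/height shift ≤0.2, zoom ≤0.2) applied identically to both gradient
images and the mask — gradients resampled bilinearly with mirrored fill, the
mask by nearest neighbour and re-binarized, so labels never bleed.

### Desk-scale preset

`desk_config()` (64×128 inputs, 3 encoder blocks, 16 base filters,
15 epochs) trains on one CPU in a few minutes. Its learning rate is 1e-3,
Adam's conventional default: the reference 1e-5 is matched to a 500-step
full-resolution schedule and moves too little in the 150 desk-scale steps.
That choice was fixed a priori, not tuned against the acceptance thresholds.

### Batch-norm finalization

Batch-norm running statistics are exponential averages (momentum 0.9) of
activations produced by *past* weights. After a short, fast-moving Adam run
the lag is severe: with stale statistics, inference-mode predictions
collapse onto the few most confident pixels even though the training loss
is low. `train_model()` therefore finishes with forward-only sweeps over
the clean training set to re-estimate the running statistics under the
final weights ("precise BN" finalization). This is part of training, not a
post-hoc correction: it touches no labels, no weights, and no test data.

## What the phantom emulates — and what it does not

`generate_phantom()` renders the canonical appearance of the distal wall:
a dark lumen above a bright, slowly curving band of known thickness on a
mid-gray tissue background, with 1-px brighter LI/MA edge lines (so the
gradient operators see the double-line pattern real scans show), degraded by
multiplicative mean-1 gamma speckle. Defaults: 64×128 px at 16.66 px/mm,
thickness 0.4–1.0 mm (the physiological range the reference cohort spans),
centerline sinusoid of ±2 px over a 96 px period, speckle shape 16,
band:tissue contrast 4. The centerline is sampled at ≥10 evenly spaced
knot columns — the exported expert-style annotation — and the mask is built
from the same linear interpolation and half-up rounding that
`rasterize_mask()` applies, so the annotation rasterizes back to the mask
exactly and the per-column run length is `round(thickness_px)` (±1 where the
band curves).

Not emulated: the physics (point-spread function, attenuation, time-gain
compensation), plaque morphology, scanner UI frames, or the real images'
noise statistics, which the reference never characterizes. A green phantom
test therefore establishes that the pipeline is *internally consistent and
trainable on band-like structure* — not that it reaches any particular
accuracy on clinical scans.

## Numerical choices and conventions

- **Coordinates**: matrices are row-down; annotation files are 0-based
  `(column, row)` CSV (`interface,column,row`, interface ∈ {LI, MA}).
- **Gradient direction**: `atan2(g_y, g_x)` mapped affinely from (−π, π] to
  [0,1]; zero-magnitude pixels (flat regions) map to 0.5, the image of 0
  rad. Kernel borders are replicate-padded. Magnitudes below 1e-9 count as
  zero to absorb floating-point cancellation on flat patches.
- **Rasterization**: per-column linear interpolation of each interface,
  half-up rounding, inclusive band (identical LI and MA give a 1-px band);
  crossing interfaces are an error.
- **Morphology**: erosion is the min filter over the SE footprint
  (out-of-bounds = foreground, its neutral element), dilation the max filter
  over the *reflected* footprint (out-of-bounds = background). The
  reflection pairs them as Minkowski subtraction/addition, keeping closing
  extensive and opening anti-extensive for even SE sizes like (2,30); it
  also means a band touching the left/right image border is not eroded away
  by the 30-wide SE. The size notation is (rows, columns).
- **Binarization**: foreground iff p_fg > 0.5; ties go to background.
- **Thickness**: per-column longest foreground run; per-image maximum by
  default (`mode = "mean"` available); an empty mask is an error ("no IMC
  detected") rather than zero, so cohort means are never silently deflated.
  The reference reports 2.989 px yet 0.54 mm — inconsistent at 16.66 px/mm
  (0.54 mm ≡ 9.0 px); the run-length definition is the literal
  upper-to-lower boundary distance and is used throughout.
- **Metrics**: both macro (mean of per-image metrics, the headline) and
  micro (pooled counts) averaging exist because the reference's printed
  F1 ≠ Dice implies non-pooled aggregation without stating the scheme.
  Degenerate conventions: empty-vs-empty Dice/Jaccard = 1; 0/0 ratios in
  P/R/F1 = 0. F1 is computed from counts (`2TP/(2TP+FP+FN)`) so micro-F1
  equals micro-Dice exactly.
- **Seeding**: one master seed; per-stage child seeds derived by an integer
  mixing function kept below 2³¹. Training, augmentation, splitting and
  phantom sampling are all reproducible bit-for-bit (single-threaded BLAS).

## Worked example

```{r, eval = FALSE}
library(cimtseg)

cfg <- run_config(out_dir = tempfile("run"), n_phantoms = 30,
                  model = desk_config(epochs = 15), seed = 101)
res <- run_pipeline(cfg)
res$metrics      # macro precision/recall/F1/Dice/Jaccard on held-out phantoms
res$thickness    # per-image px, cohort mean px and mm
```

The run directory contains the dataset (PGM images, CSV annotations, JSON
manifest), the exact config used, per-epoch loss history, predicted masks,
and JSON metric/thickness reports; rerunning with the same config reproduces
them.

## Known limitations

- No transfer learning: encoders are trained from scratch (the reference
  claims no pretrained weights), so full-scale runs need the full protocol.
- Plain 2× upsampling is used; SegNet-style pooling-index unpooling is not
  implemented (the reference's "upsampling (unpooling)" is ambiguous).
- The phantom's realism ceiling (above) means clinical accuracy claims are
  out of scope; Table-level scores from the reference are not reproduced.
- Largest-component selection / ROI gating after refinement is deliberately
  absent (not part of the reference chain).
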