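---
title: "Label-free cell-death classification from quantitative phase images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free cell-death classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Distinguishing apoptotic from necroptotic cell death normally requires
fluorescent reporters, which perturb the cells and bleach over time.
Digital holographic microscopy (DHM) offers a label-free alternative: it
records, per pixel, the phase delay Δφ that transmitted light accumulates
while crossing a cell. `phasedeath` implements a complete analysis
pipeline that turns full field-of-view phase captures into per-cell
death-state calls:

1. **Optics.** Phase delay and apparent specimen height are related by
   Δφ = (2π/λ)(ηᵢ − η_media)·h, where λ is the wavelength and ηᵢ, η_media
   the refractive indices of cell and medium. The package converts in
   both directions (`phase_to_height()`, `height_to_phase()`); the inverse
   is exact by construction. The resulting *optical height* mixes physical
   thickness with refractive-index contrast — which is precisely why it
   carries death-mode information: chromatin condensation in apoptosis
   raises the intracellular refractive index (taller-looking cells), while
   membrane pore formation in necroptosis lets medium in and flattens the
   optical profile.
2. **Segmentation.** Cells are located by thresholding the phase image
   (Otsu by default) and labeling connected components; each component
   whose area lies strictly inside (80, 600) pixels and whose fixed 66×66
   crop box does not cross the image border yields one single-cell crop.
3. **Label purification (SAD).** Death induction is asynchronous, so an
   induced culture still contains alive cells. A supervised
   anomaly-detection filter — a linear SVM over crop embeddings trained on
   reference crops of known morphology (200 alive vs 100 + 100 pooled
   dead) — discards crops whose predicted state (Alive/Death) contradicts
   their capture's experimental condition, or whose prediction score does
   not exceed a threshold T = 0.01.
4. **Classifier.** The kept crops, labeled by their capture condition, are
   balanced to the smallest class, split 80/20 per class, and used to
   train a convolutional network whose final layers have been replaced by
   a new head: fully connected width 64 → ReLU → fully connected width 3 →
   softmax, over the fixed class order (alive, apoptosis, necroptosis).
5. **Evaluation.** Per-class accuracy (correct predictions over cells per
   input label), a 3×3 confusion matrix, and one-vs-rest ROC/AUC per
   class.

## Backbones and the head surgery

Two backbones implement the same contract:

* `vgg19_full` reproduces the VGG-19 arrangement: 3×3 same-padded
  convolutions with ReLU in blocks of depth 64/128/256/512/512, each block
  followed by 2×2 max pooling that halves the spatial extent
  (224 → 112 → 56 → 28 → 14 → 7), ending in a 7×7×512 feature map that is
  flattened (25,088 values) into two 4096-wide fully connected layers. The
  original classification stack (the final class-score layer, its softmax
  and the output layer) is removed and the new head attaches after the
  second 4096-wide layer. No pretrained weights are shipped or downloaded;
  the architecture is initialized with seeded He-normal draws, so the
  *transfer* aspect is structural (reuse plus head surgery), not
  pretrained-weight reuse.
* `small_cnn` is the desk-scale default used throughout the tests: three
  conv(8/16/32)+ReLU+pool blocks on the native 66×66 crops (66 → 33 → 16 →
  8, flattening to 2048) feeding the identical head. It trains in seconds
  to minutes on a single CPU, which keeps the full pipeline testable.

Preprocessing min–max normalises each crop to [0, 1], bilinearly resizes
to the backbone's input size when needed, and replicates the single phase
channel three times to satisfy the three-channel input contract. Per-crop
normalisation deliberately removes the absolute optical-height scale from
the classifier input (the SAD embeddings retain it); the classifier
therefore works from shape, size and texture. A global-scaling alternative
would preserve absolute height and is a one-line change in
`preprocess_crop()`, but per-crop scaling is the more conservative default
because it is robust to per-capture background offsets.

The head is modeled as FC-64/ReLU/FC-3 with softmax applied at
prediction; the "classification" output layer of graphical frameworks has
no parameters and is not represented explicitly.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `wavelength_um` | 0.532 | µm | conventional green illumination; not stated by any measurement in the package |
| `eta_cell`, `eta_media` | 1.380, 1.333 | – | textbook cytoplasm / aqueous-medium values; both overridable per capture |
| `crop_size_px` | 66 | px | fixed crop box; even size is centred half-open, rows (r−33)…(r+32) |
| `area_min_px`, `area_max_px` | 80, 600 | px | strict bounds on component area (">80 and <600") |
| `threshold_method` | Otsu | – | parameter-free; a fixed phase threshold is available |
| connectivity | 8 | – | diagonals connect; 4 available |
| SAD `threshold` | 0.01 | score | crops kept only when score > T; score is the probability gap p(predicted) − p(other), clipped at 0 (a documented choice — "margin" uses the absolute SVM decision value) |
| SVM kernel / C | linear / 1 | – | simplest separating model for well-separated embeddings |
| `learning_rate`, `epochs`, `batch_size` | 1e-4, 10, 32 | – | conventional fine-tuning defaults in `train_config()`; the synthetic pipeline uses 1e-3 and 15 epochs, appropriate for its few hundred training crops |
| `val_fraction` | 0.20 | – | per-class floor(n·0.2) to validation |

## The synthetic generator

No microscope data ship with the package; a seeded generator emulates
captures instead, and it is first-class, tested code. Each class renders
an optical-height patch:

* **alive** — spread, flat-topped profile (super-Gaussian) with a
  low-order angular modulation of the boundary radius (irregular outline),
  body radius 8–10 px, height scale 1.0;
* **apoptosis** — shrunken parabolic dome (radius 6–8 px) studded with 3–6
  small Gaussian blebs, height scale 1.6 (optically taller);
* **necroptosis** — large smooth dome (radius 11.5–13 px), height scale
  0.55 (optically flatter).

Peak heights are drawn from 2.5–4 µm before class scaling. The magnitudes
are invented defaults — chosen once for plausibility, class separability
and compatibility with the (80, 600) px area window — and the
`morphology_params()` validator enforces only the qualitative ordering
that is biologically anchored: apoptosis above alive above necroptosis in
optical height. Cells are placed by rejection sampling with a minimum
centre separation (40 px default), converted to phase via the
phase/height relation, and overlaid with additive Gaussian phase noise
(0.05 rad default). Induced-condition captures contain 75% induced-class
and 25% alive cells; that planted impurity is exactly what the SAD filter
is supposed to remove, and alive-condition captures are pure.

What the generator does **not** emulate: speckle and coherent-imaging
artifacts, phase wrapping, uneven illumination, touching/overlapping
cells, debris, mitosis, or time-lapse motion. Passing tests therefore
demonstrate that the pipeline's logic is correct and that the method
recovers planted, well-separated morphologies; they are not evidence
about classification accuracy on real microscope data.

## Numerical and design choices

* **Connectivity.** The component labeler is 4-connectivity at its core
  with a union-find merge of diagonally adjacent labels, giving
  8-connectivity semantics; tests cross-check against an explicit flood
  fill.
* **Centroids** are rounded pixel-coordinate means; coordinates are
  1-based (row, col) from the top-left.
* **Strictness.** Both area bounds are strict inequalities, and the SAD
  keep rule requires score strictly greater than T.
* **Ties.** Argmax ties in prediction go to the earlier class in
  (alive, apoptosis, necroptosis). Tied ROC scores are collapsed into
  single curve vertices, which makes trapezoidal integration equal the
  rank interpretation of AUC with half-credit ties; this equivalence is
  asserted to 1e-9 against exhaustive pair counting.
* **Degenerate inputs.** Equal cell and medium refractive indices raise a
  degenerate-optics error; a constant crop normalises to all zeros; a
  flat capture yields zero detections (not an error); single-class label
  sets error in both SVM training (after a non-separability warning for
  indistinguishable classes) and AUC computation.
* **Determinism.** Every stochastic step (placement, noise, subsampling,
  splitting, weight init, batch shuffling, Platt scaling) derives its
  stream from one seed; the whole pipeline is bit-reproducible, and
  seeded helpers restore the caller's RNG state.
* **File formats.** Captures are single-channel 32-bit float TIFFs with a
  JSON sidecar. The TIFF payload is min–max normalised to [0, 1] (the
  affine range lives in the sidecar) because float TIFF writers clamp
  values outside the unit interval; the round trip is lossless at float32
  precision.
* **Holdout isolation** is enforced at the capture (experiment) level by
  id disjointness, and the prediction path has no access to label
  columns.

## Problem sizes

The test suite and the acceptance script run the synthetic study at desk
scale, chosen as the package's default study conditions: 8 captures per
condition of 30 cells each (384×384 px) for training, the same volume
from disjoint seed streams for holdout, the 200 alive + 100 + 100 dead reference crops for
the SAD filter in the full run, and the small CNN for 15 epochs. At this
scale the planted-class holdout accuracy exceeds 0.85 for every class —
the desk-scale analogue of the per-class accuracy structure the method
targets — and a full train-plus-holdout run takes about two minutes on
one CPU. Orchestration tests use a further reduced configuration (2
captures per condition, 2 epochs) since they check bookkeeping, not
learning.

## Known limitations

* The VGG-19 backbone is implemented architecturally but is impractical
  to *train* in pure R at realistic dataset sizes; it exists for shape
  fidelity, forward-pass audits and as the documented attachment point of
  the head surgery. The small CNN carries the learning demonstrations.
* The SAD score is a probability gap by default; the quantity thresholded
  at T = 0.01 is a documented package choice, and "margin" scoring will
  produce differently scaled thresholds.
* The evaluation module reports one-vs-rest ROC/AUC per class only; no
  micro/macro-averaged multi-class AUC, calibration analysis or bootstrap
  intervals.
* Touching cells are not split (no watershed); each connected component
  yields at most one crop, and overlapping crop boxes are permitted.

## A worked example

```{r example}
library(phasedeath)

config <- pipeline_config(seed = 1)
result <- run_training_pipeline(config)
result$log            # per-stage input/kept/discarded counts
result$report         # validation accuracy, AUC per class

holdout <- run_holdout_evaluation(result)
tidy(holdout$report)  # per-class n, accuracy, AUC on unseen captures
autoplot(holdout$report)          # one-vs-rest ROC curves
autoplot(result$classifier)       # training history
```
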