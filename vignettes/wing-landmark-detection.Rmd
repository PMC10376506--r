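---
title: "Heatmap-based landmark detection for insect wing morphometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heatmap-based landmark detection for insect wing morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Geometric morphometrics of insect wings rests on homologous landmarks —
vein bases, crossings, bifurcations and termini — digitized as 2-D image
coordinates. Manual digitization of dozens of landmarks per wing is the
bottleneck of venation studies. `wingmark` automates it for single-wing
images: given a photograph of a beetle hindwing and a bounding box, the
package predicts the positions of K homologous landmarks (K = 36 in the
hindwing scheme it ships with, covering the humeral plate, the radial cell,
the medial veins and the cubitus-anal field).

The central difficulty is data scarcity: annotated wing corpora number in
the hundreds of images, far too few to train a deep network from scratch.
The package therefore pairs the detector with transfer learning — a backbone
pretrained on a large, visually different corpus is fine-tuned on a handful
of annotated wings, with a per-stage choice of which network segments are
retrained and which are kept as general feature extractors.

## The model

Detection is posed as heatmap regression. Each landmark k is encoded as a
2-D score map over a 4x-downsampled grid of the input crop,

$$ t_k(u, v) = \exp\!\left(-\frac{(u - u_k)^2 + (v - v_k)^2}{2\sigma^2}\right), $$

rescaled to peak value 1, and the network is trained to reproduce the stack
of K maps under a mean-squared-error loss averaged over all elements.
Decoding takes the per-channel argmax (ties broken in row-major order) and,
by default, refines it to sub-pixel precision by fitting a 1-D parabola to
the log-scores around the peak in each axis — exact for Gaussian-shaped
channels, and clamped to half a cell for arbitrary ones.

The backbone is a four-stage multi-resolution network. A stem of two
strided 3x3 convolutions brings the input to 1/4 resolution. Stage 1 is a
single high-resolution branch of four bottleneck units (1x1 reduce, 3x3,
1x1 expand by 4x, residual). Each later stage adds one parallel branch at
half the resolution and twice the channels of the previous one; branch b
carries `base_width * 2^b` channels. Stages 2-4 are built from modules of
four basic residual units (two 3x3 convolutions) per branch followed by a
fusion unit that resamples every branch to every resolution (strided 3x3
convolutions downward, 1x1 convolution plus bilinear upsampling upward) and
sums — one, four and three fusions in stages 2, 3 and 4. A representation
head bilinearly upsamples the three low-resolution branches to the
high-resolution grid and concatenates them; a 1x1 convolution maps the
concatenation to the K heatmap channels. With the full-size configuration
(`hwlfc_config()`: base width 18, 256x256 RGB input, K = 36) the head
output is a 64x64x36 stack.

Every convolution is followed by batch normalization and, except where a
residual sum intervenes, a ReLU. All parameters belong to exactly one of
six groups — `stem, stage1, stage2, stage3, stage4, head` — which is what
the transfer strategies address.

## Transfer strategies

Fine-tuning starts from a pretrained backbone checkpoint; the heatmap head
is always re-initialized randomly (normal with sd 0.001, zero biases, under
a recorded seed) because the pretraining task has a different output space.
The strategy then fixes which groups train:

* **TH** — all four stages frozen; only the head trains.
* **TS** — stem and stage 1 frozen as general feature layers; stages 2-4
  and the head retrain. This is the configuration reported as best on real
  wing data.
* **TA** — everything retrains.
* **custom** — any named mask over the six groups (the head must stay
  trainable), covering the intermediate rows of the strategy table (e.g.
  only stage 4 retrained).

Frozen groups are excluded from the optimizer, and their batch-norm layers
also stop updating running statistics and normalize with the stored ones —
otherwise a "retained" stage would silently adapt through its normalization
state. This is switchable (`apply_strategy(..., freeze_bn_stats = FALSE)`).

The strategy table has no stem column; the stem is grouped with stage 1 for
freezing, since it precedes stage 1 and is a general feature layer by the
same reasoning that freezes low stages.

## Training protocol

`train_config()` encodes the full-scale protocol: Adam (moments 0.9/0.999)
at base learning rate 1e-4, dropped to 1e-5 and 1e-6 at epochs 40 and 55,
batch size 8, 80 epochs. Epochs are 0-based, so "epoch 40" is the first
epoch run at the reduced rate; the choice is a convention, documented
rather than claimed. Termination is exactly 80 epochs; no early stopping
and no data augmentation are applied by default, since neither belongs to
the stated protocol and either would silently change reproducibility
claims.

`make_splits()` implements the evaluation protocol: a fixed test set (80
samples by default) is drawn first; training groups of sizes 1, 3, 5, 10,
50 and 100 (10 groups per size) are then drawn from the remainder. Groups
of the same size are independent draws that may overlap each other but
never the test set — with a 256-sample corpus the remainder pool holds 176
samples, so 10 disjoint groups of 100 are impossible and independence is
forced.

Evaluation uses the normalized mean error. For a specimen with reference
distance $d$ (the Euclidean distance between landmarks 1 and 18 of the
ground truth — a property of the specimen, never of the prediction),

$$ \mathrm{NME}(P, \hat P) = \frac{1}{K} \sum_{i=1}^{K}
   \frac{\lVert p_i - \hat p_i \rVert}{d}. $$

Per-sample NMEs are averaged over the test set; per-landmark profiles
average each landmark's normalized error over samples. Across the 10
groups of a size, the spread is reported as the sample (n-1) standard
deviation. Samples whose reference landmarks coincide are excluded with a
warning; landmarks whose predicted channel is all zero fall back to the
crop center rather than being dropped, since dropping would flatter
small-sample models.

## Synthetic wings

`generate_dataset()` renders wing-like images with exact ground-truth
landmarks so the whole pipeline — pretraining, transfer, evaluation — runs
with no downloads. A canonical 36-landmark template lays stylized vein
chains in a unit frame (anterior margin, radial cell, medial chain,
cubitus-anal cluster; the reference pair 1-18 spans the long axis). Each
sample jitters the landmarks (Gaussian, in frame units), applies a random
affine deformation (rotation, scale, shear, translation), and draws
anti-aliased vein segments between connected landmarks over a textured
background. Two domains share the geometry but differ visually: `source`
is high-contrast dark-on-light; `target` is low-contrast on a blotchy
darker background with distal vein traces faded. The domain gap stands in
for the natural-image-to-wing-photograph gap of real transfer learning.
Landmarks in the cubitus-anal region and distal landmarks receive elevated
jitter (2.5x and 2x) and their veins reduced contrast, reproducing
qualitatively the hard-landmark structure of real wings, where distal veins
degenerate into faint traces.

Annotation coordinates are the exact post-deformation landmark positions —
rendering introduces no annotation error — and every output byte is
determined by `(config$seed, sample_seed)`. Annotations use the top-left
pixel origin throughout; measurements taken with a lower-left origin are
converted once by `convert_measurement_origin()` (y subtracted from the
image height), which exists only at the boundary.

What the generator does *not* emulate: photographic texture, specular
artifacts, wing folding, occlusion, species-level shape variation, or any
correlation structure between landmarks beyond the shared affine. Passing
tests on synthetic wings therefore demonstrates the correctness of the
machinery (codec, optimization, freezing, metric), and the *existence* of a
small-sample transfer advantage under a controlled domain gap — not the
absolute accuracies reported on real hindwing photographs, which require
the real corpus and an ImageNet-pretrained backbone.

## Numerical and design choices

* **Input crop**: the bbox is padded 25% per side, expanded to the input
  aspect ratio, and bilinearly resampled to 256x256 (full-size) — giving
  the stated 64x64 heatmaps at the 4x stride of the high-resolution branch.
  The half-pixel sampling convention is used consistently by the resizer,
  the encoder and the decoder.
* **sigma**: 2 heatmap pixels by default — standard for 64x64 heatmap
  regression; configurable. Target peaks are rescaled to exactly 1 (not
  unit mass), matching MSE heatmap practice.
* **Decode refinement**: log-parabolic by default. A quarter-pixel shift
  toward the larger neighbor is also available, but its residual error (up
  to 0.25 heatmap cells = 1 input pixel at stride 4) cannot meet the
  sub-pixel roundtrip contract, so the parabolic fit — exact on clean
  Gaussians, standard as distribution-aware decoding — is the default.
* **Head initialization**: normal(0, 0.001), zero biases, both at build
  time and on checkpoint load. A He-scale head starts with large random
  heatmaps and wastes most of a short schedule undoing them.
* **Bottleneck expansion 4, bilinear upsampling, strided-conv transitions,
  batch-norm everywhere**: conventional choices where the architecture
  description is silent; all are named in the configuration.
* **Ties and degeneracies**: argmax ties resolve to the first cell in
  row-major order; all-zero channels decode to the crop center with an
  `undecodable` flag; a coincident reference pair raises an error at
  `reference_distance()` and excludes the sample at evaluation.
* **Checkpoints** are flat name-to-array maps (parameters plus batch-norm
  running statistics, each tagged with its group) with a metadata block,
  serialized with `saveRDS`; loaders accept checkpoints lacking the head.

## Desk-scale configuration

The package ships a tiny variant (`tiny_config()`: base width 8, 64x64
grayscale input, 2 stage-1 bottlenecks, 2 basic units per module, one
module per stage) that preserves every structural element — four stages,
parallel branches, fusions, the parameter groups — while training on a CPU
in minutes. Its codec uses 16x16 heatmaps; sigma stays at 2 cells.

The tiny variant trains from random initialization, where the full-scale
fine-tuning rate of 1e-4 moves freshly initialized weights far too little
within 80 epochs; `tiny_train_config()` therefore uses a 1e-2 base rate
with the same drop-at-40/55 shape. For from-scratch pretraining and
single-sample overfitting at this scale a constant 1e-2 works better still
(the drops exist to stabilize long fine-tuning runs, and at 80 small-batch
steps they only stall convergence), which is what the test suite uses for
those checks.

The test suite's end-to-end experiment mirrors the full protocol at desk
scale: a tiny backbone is pretrained on 200 source-domain wings (30
epochs), then fine-tuned on 3 target-domain wings for 80 epochs under TS,
against an identically-trained model from random initialization; both are
scored on 30 held-out target wings, and the comparison is repeated over 3
seeds with the median reported. The pretrained TS model wins consistently —
the qualitative small-sample transfer advantage — while absolute NMEs
remain well above the full-scale figures, as expected at this scale. These
problem sizes (200/3/30, 3 seeds) were chosen once as the smallest
configuration that exercises pretraining, freezing and evaluation
end-to-end in a few CPU-minutes.

## Limitations

* One wing per image; no multi-instance disambiguation.
* No alternative target encodings (offset maps, integral regression) and
  no PCK/AUC-style metrics — the NME machinery is the extension point.
* The residual-network baseline is not implemented; the backbone interface
  (`build_model` on a config, group-tagged parameters, checkpoints) is
  where a second backbone would plug in.
* ImageNet pretraining is consumed, not produced: full-scale checkpoints
  must come from elsewhere; the synthetic source domain substitutes only at
  desk scale.
* Downstream morphometrics (Procrustes alignment, PCA of shape) is out of
  scope; predicted landmark sets are the hand-off.
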