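---
title: "Methods: lightweight convolution-transformer classification of micronucleus images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lightweight convolution-transformer classification of micronucleus images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Micronuclei are small extranuclear chromatin bodies formed when chromosome
fragments, or whole lagging chromosomes, fail to join a daughter nucleus at
mitosis. Their frequency in stained cell preparations is a standard
biomarker of DNA damage and genotoxic exposure, so scoring cell images as
*normal* versus *micronucleus-bearing* is a recurring task in pathological
toxicology and radiation biodosimetry. The task is awkward for automated
classifiers in three ways: the discriminative object is tiny relative to
the cell, the two classes are otherwise near-identical, and positives are
rare — a realistic unaugmented pool carries roughly 6.5% positives.

`mnvit` implements a lightweight hybrid convolution/transformer classifier
for this task, together with everything needed to exercise it end-to-end
without any proprietary data: an ablation-grid model factory with exact
parameter audits, a seeded synthetic image generator, an imbalance-aware
dataset pipeline, a native training loop, and the evaluation metrics suited
to imbalanced two-class problems.

## Network architecture

The backbone is the smallest MobileViT-style macro-structure: a 3x3
stride-2 stem to 16 channels; seven MobileNetV2-type inverted-residual
(MV2) blocks at widths 16/24/24/24/48/64/80 with expansion factor 2; three
MobileViT stages interleaved at widths 48/64/80 with transformer embedding
dimensions 64/80/96 and encoder depths (2, 4, 3); a 1x1 expansion to 320
channels; global average pooling; and a linear head. Convolutions are
bias-free and followed by batch normalization and SiLU. Each transformer
encoder layer is pre-norm: LayerNorm, 4-head self-attention (joint QKV
projection with bias, output projection with bias, inner dimension equal to
the embedding dimension), then LayerNorm and a 2x feed-forward block. With
a 1000-class head this baseline counts exactly 1,272,024 trainable
parameters; `count_parameters()` reproduces that number by brute-force
enumeration of every trainable array.

Three modifications define the variant grid (`mn_presets()`):

* **Depth-Conv + PFCL decomposition.** The two 3x3 convolutions inside each
  MobileViT block — the C-to-C local-representation convolution and the
  2C-to-C fusion convolution — are replaced by a bias-free depthwise 3x3
  (one kernel per channel) followed by a pointwise 1x1 cross-channel fusion.
  Per width C this saves (8C^2 - 9C) + (16C^2 - 18C) parameters; summed over
  C in {48, 64, 80} the saving is 302,016, taking the decomposed model
  (`Model_DSC`) to exactly 970,008 parameters. The audit in
  `audit_variant_grid()` checks this identity each time it runs.
* **SEDD: squeeze-and-excitation inside MV2 blocks.** The depthwise stage
  of each inverted residual is wrapped with SE channel attention on the
  expanded channels: global average pooling per channel, a bottleneck MLP
  `C -> C/r -> C` (rectifier, then logistic squashing), and per-channel
  rescaling. The reduction ratio defaults to `r = 4` — the conventional SE
  setting, small enough to keep the parameter overhead of the whole grid
  below 2% of the backbone.
* **NAM in the MobileViT local representation.** A
  normalization-based attention operator gates the features entering the
  transformer: `x_hat = BN(x)`, `a = sigmoid(f_att(x_hat))`,
  `y = x * a`, `z = f_recon(y)`, with `f_att` and `f_recon` realized as
  1x1 channel-preserving convolutions — the cheapest operator consistent
  with the module's purpose. The functional form
  (`nam_attention()`) also offers the scale-factor variant of the original
  normalization-attention design (`variant = "bn_scale"`), which derives
  the weights from the normalization scale factors instead of a learned
  convolution; the network default is the convolutional pathway.

The dual-attention preset `MV2_SE_Mb_NAM` — SE inside every MV2 block, NAM
ahead of every MobileViT block — is the configuration the package is named
for. Its mirror image (`MV2_NAM_Mb_SE`) and all single-site and
transformer-depth variants (`*_Mb_tr1`, `*_Mb_tr3`) exist as presets so the
whole grid can be audited and trained identically.

### Design choices on genuinely open points

* *Attention placement in the local representation.* The channel attention
  sits on the block input, ahead of the 3x3 convolution (it gates what the
  transformer will see as early as possible); `attention_first = FALSE`
  applies it after the convolution instead. Both placements are exposed
  because the block diagram alone does not fix the order.
* *Decomposition kernel size.* The depthwise stage uses 3x3 kernels, which
  preserves the receptive field of the convolution it replaces and is the
  only choice consistent with the audited parameter totals above; a 1x1
  depthwise stage would collapse the spatial aperture entirely.
* *Patch size.* 2x2, the conventional MobileViT tokenization. Feature maps
  that the patches do not divide are rejected with an error rather than
  silently padded, which keeps fold-after-unfold an exact identity (tested
  bit-for-bit).
* *Head width for audits.* Parameter audits default to the 1000-class head
  so the totals are comparable to backbone tables; task models use
  `num_classes = 2`. `audit_variant_grid()` records which head it counted.
* *MAC convention.* `count_macs()` sums `k^2 * (C_in/groups) * C_out *
  H_out * W_out` over convolutions, `d_in * d_out * tokens` over linear
  layers, the two attention matrix products, and the NAM 1x1 pathways,
  during a real forward pass at the declared input size. Normalizations,
  activations and pooling are not counted. This is the standard convention;
  it is documented here precisely because MAC countings differ between
  tools.

## The synthetic data generator

The study domain's data (scanned, expert-annotated slides) is not
publicly available, so the generator emulates the features of a single-cell
crop that drive the classification task: a bright nucleus ellipse (random
semi-axes, aspect, orientation and intensity) on a darker background, and,
in positives, 1-3 small chromatin blobs placed in a ring just outside the
nucleus boundary, strictly separated from it. Defaults render at 64 px and
upscale bilinearly at load time; intensities, axis fractions, blob radii
(0.1-0.33 of the nucleus minor semi-axis, clipped below at 1.2 px so every
recorded blob rasterises), noise and blur are all settable. Everything is
drawn from a per-image seeded RNG, so a sample is bitwise reproducible from
`(spec, label, seed)`, and each sample carries its full geometry record for
exact assertions.

Two modes matter for testing. `"default"` adds mild Gaussian noise
(sd 0.02) and blur (sd 0.7 px). `"easy"` is the high-contrast, noise-free,
blur-free variant used for learnability checks: a trivial
luminance-and-blob-count heuristic (`blob_count_classifier()`) must — and
does — exceed 90% balanced accuracy on it, which certifies that the signal
a trained network is asked to find is actually present.

What the generator does **not** emulate: staining chemistry and its
variability, point-spread functions, multi-cell scenes, debris and
apoptotic fragments, focus gradients. Tests passing on synthetic images
therefore demonstrate that the architecture, pipeline and training loop
work as specified — not that any accuracy level transfers to real slides.

## Dataset pipeline

`split_dataset()` performs a stratified 6:2:2 train/validation/test split
(per-class cumulative rounding, within one sample of the exact
proportions, deterministic in the seed). `rebalance_train()` applies the
imbalance strategy to the training split only: the majority class is
randomly downsampled (optionally to a cap) and the minority class expanded
with augmented copies until the class ratio reaches the target (default
1:1, within exact integer arithmetic); unreachable targets fail with the
achievable ratio in the message. The test split is never augmented — an
invariant asserted on every manifest the pipeline emits. Augmentation
(`augment_image()`) draws a rotation within +/-30 degrees, horizontal and
vertical flips at probability 0.5 each, and a zoom in 0.8-1.2; rotation
and zoom resample bilinearly about the centre with reflection padding so
dimensions are preserved, and flips are exact index reversals. Those
parameter values are conventional light-geometric-augmentation settings;
the source design names the transform families but not their magnitudes.

Images enter the network resized bilinearly to the configured input side
and standardized per channel with fixed constants (mean 0.5, sd 0.25 on
the [0, 1] pixel scale), recorded once in the package rather than
recomputed per dataset so that checkpoints remain portable across data.

## Training and evaluation

The training loop is plain and deterministic: softmax cross-entropy, Adam
(beta 0.9/0.999), cosine learning-rate decay from 0.001, batches of 64 and
50 epochs by default — the study's configuration. The default input side
is 256 px rather than the often-quoted 224 px: the trunk downsamples by
32, so a 224 px input leaves a 7x7 map at the last transformer stage,
which 2x2 patches cannot tile; since non-divisible maps are rejected
rather than padded (the fold/unfold exactness contract), the package
standardises on the nearest admissible size. A
validation pass per epoch tracks balanced accuracy; the best-validation
weights are restored at the end and can be checkpointed together with a
JSON sidecar. `load_pretrained()` implements transfer learning by
name-and-shape matching of checkpoint tensors, reporting matched, skipped
and reinitialized tensors; the default fine-tunes everything
(`freeze_trunk = TRUE` restricts updates to the head).

One numerical choice deserves emphasis. With few optimisation steps the
exponential running estimates that batch normalization accumulates for
inference lag far behind the trained weights, so a model that separates
its training batches can still collapse at inference. After training, the
loop therefore re-estimates all running statistics with one sweep over the
training set under the final weights, setting the momentum of batch *k* to
1/*k* so the result is the exact average of per-batch statistics
(precise-BN). This is a pure re-estimation — no weight changes — and is on
by default (`recalibrate_bn`).

Metrics follow the imbalanced-task conventions: `balanced_accuracy()` is
the mean of per-class recalls (any constant classifier scores exactly 0.5,
which is also the signature by which a collapsed model is recognised);
`f1_scores()` reports per-class and macro F1, with never-predicted classes
scored 0 under a warning; `roc_auc()` uses the midrank (Wilcoxon) formula,
making it exactly the probability that a random positive outscores a
random negative and invariant under monotone score transforms. All three
are verified against independent brute-force oracles, and the AUC
additionally against an established ROC implementation.

## Problem sizes used in the checks

The test suite exercises the full architecture at reduced scale so the
whole suite runs on a single CPU: gradient-checked layers at toy sizes,
oracle comparisons on 100 seeded random maps per operator, and two short
training studies. The learning-sanity study trains the `MV2_SE_Mb_NAM`
preset (2-class head, 64 px inputs) for 5 epochs on 200 easy-mode images
and requires balanced accuracy of at least 0.9 on 60 held-out images; the
transfer study pretrains a reduced configuration (32 px, depth-1
transformers) on easy-mode images, fine-tunes for two epochs on a small
set drawn from a shifted specification (noisier, blurrier, lower
contrast), and requires the transferred model to beat the from-scratch
control at equal epochs — the ordinal property expected of transfer
learning, not a numeric target.

Two choices make these short studies informative. First, the training
pools are expanded with `expand_dihedral()` — exact quarter-turn and
mirror views — before training, exactly as the study design prescribes
augmentation for its own training data; without augmentation a network of
this capacity simply memorises 200 images (training accuracy 1.0, held-out
balanced accuracy near 0.7) instead of learning the blob feature, the same
small-data failure the design's from-scratch control exhibits. Exact views
are used rather than the stochastic policy because bilinear resampling
with reflection padding can mirror bright structures near borders into
blob-like artifacts, which on tiny renders amounts to label noise. Second,
the batch size is 8 rather than 64: with a few hundred training rows a
64-image batch would give the optimiser a handful of steps per epoch,
which measures nothing; at batch 8 the run still uses the configured
optimizer, schedule and loss unchanged.

## Known limitations

* The synthetic domain is deliberately simple; no claim about real-slide
  accuracy follows from any number this package computes.
* Attention-bearing presets audit the parameters their construction
  implies; totals involving SE/NAM sites depend on conventions (reduction
  ratio, 1x1 pathways) that published tables rarely pin down, so only the
  baseline and decomposed totals are exact identities.
* The native training loop is single-threaded BLAS-bound R; it is meant
  for desk-scale studies and tests, not for GPU-scale experiments.
* `augment_image()`'s reflection padding can mirror bright structures near
  borders; on tiny renders this occasionally fabricates blob-like
  artifacts, which is why the short training studies expand data with
  exact flips only.
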