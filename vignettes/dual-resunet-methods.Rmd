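---
title: "Dual ResUNet segmentation of zebrafish intersegmental vessels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual ResUNet segmentation of zebrafish intersegmental vessels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Zebrafish embryos expressing a fluorescent protein in their endothelium are a
standard model for vascular development and drug screening. Confocal stacks
of the trunk are collapsed to 2-D projections in which the vasculature shows
two horizontal rails — the dorsal aorta (DA) below and the dorsal
longitudinal anastomotic vessel (DLAV) above — connected by near-vertical
intersegmental vessels (ISVs). The projection discards depth, so each
foreground ISV can overlap its occluded contralateral partner; fluorescence
intensity varies along and between vessels; and the biologically interesting
phenotypes are departures from the regular ladder: short (truncated) ISVs,
irregular branches, and adhesions joining neighbouring vessels. The task this
package addresses is pixel-level segmentation of the *foreground* ISVs only,
with the background partners and the rails treated as context.

## The network

`build_network()` constructs a *Dual ResUNet*: two U-shaped sub-networks
joined by bridges. Each sub-network is an encoder–decoder:

* **Units.** The building block is a full pre-activation residual unit,
  `x + F(x)` with `F = BN → ReLU → 3×3 conv → BN → ReLU → 3×3 conv`, zero
  padding keeping the spatial size fixed. When the input and output channel
  counts differ, a 1×1 convolution projects the identity path. The
  `dual_unet_14` variant swaps in plain units (conv → BN → ReLU, twice,
  no addition) for comparison.
* **Encoder.** After each encoder unit, 2×2 max pooling with stride 2 halves
  the resolution, and the next unit doubles the channels.
* **Decoder.** A 2×2 transposed convolution with stride 2 doubles the
  resolution and halves the channels, followed by BN and ReLU; the
  same-resolution encoder output is added element-wise (the within-network
  skip), and a residual unit refines the sum.
* **Bridge.** Each decoder level of the first sub-network is concatenated
  channel-wise into the same-resolution encoder level of the second, then a
  1×1 convolution restores the channel count the encoder unit expects, so
  the second network's units are structurally identical to the first's. This
  is what distinguishes the *dual* design from simple stacking: the second
  network sees multi-scale decoded features of the first at every level.
* **Head.** A final 1×1 convolution to two channels and an element-wise
  sigmoid give per-pixel scores for ISV and non-ISV. The two channels are
  independent sigmoids, not a softmax pair; the prediction rule is
  "ISV iff the ISV score strictly exceeds the non-ISV score", ties going to
  non-ISV.

The variant name fixes the total unit count — 14 by default, with 10- and
18-unit siblings — split equally across the two sub-networks; each
sub-network distributes its units symmetrically as `E` encoder levels, one
bottleneck, and `E` decoder levels (`E` = 3, 2, 4 for the 14-, 10-, 18-unit
variants). The split is a design choice: only the totals are prescribed, and
the symmetric layout mirrors the usual encoder/decoder symmetry of U-Nets.
`single_resunet` (7 units) is the unbridged sibling. Inputs must be
divisible by `2^E`; `base_channels` (default 32) scales the width, and small
values (4) give CPU-sized networks with the identical topology — width, not
structure, is the contract.

Where multi-resolution side outputs are wanted, `fuse_feature_maps()`
bilinearly upsamples per-level maps to the finest resolution and forms their
weighted sum; it is an optional auxiliary head, not wired into the default
architecture.

Because no deep-learning framework is part of this package's dependency
footprint, the forward *and* backward passes are implemented here: a small
reverse-mode tape (`R/autodiff.R`) over C++ kernels (`src/kernels.cpp`,
im2col + BLAS convolutions, transposed convolution, pooling, batch-norm
statistics). Backward correctness is enforced by tests comparing analytic
gradients to central differences through the entire network.

## The objective

Write `y` for the ISV-channel probability and `t` for the binary target.

* **Weighted cross-entropy** (`weighted_cross_entropy()`):
  mean over pixels of `-(w_pos·t·log y + (1-t)·log(1-y))`.
* **Contour-aware term** (`contour_aware_loss()`): the ground-truth mask is
  reduced to an inner band `B_in` (object pixels within `band_width` of the
  background, an erosion residue) and an outer band `B_out` (background
  pixels within `band_width` of the object, a dilation residue), both with a
  3×3 box structuring element. The default form is class-balanced
  cross-entropy restricted to the band:
  `L_c = -(|B_in|/|I|²) Σ_{B_in} log y - (|B_out|/|I|²) Σ_{B_out} log(1-y)`,
  `|I| = |B_in| + |B_out|`. Two published readings of the band/class pairing
  exist one transposition apart; the default assigns the positive-class term
  to the object-side band — the orientation under which a perfect prediction
  drives the term to its floor and which trains stably; `swap_bands = TRUE`
  selects the transposed reading, and `mode = "emphasis"` instead applies
  the band indicator as an additive weight on full-image cross-entropy.
  Degenerate masks (no band, i.e. all-zero or all-one) fall back to plain
  weighted cross-entropy, flagged in the result.
* **Shape-constraint term** (`shape_constraint_loss()`): per pixel, the
  negative log of the correct class's *share* of the two class scores,
  `u = p_correct/(p_ISV + p_nonISV)`, averaged over pixels. The share, not
  the raw score, is used because the channels are independent sigmoids: the
  raw correct-class score never penalizes the wrong channel, leaving the
  non-ISV channel unconstrained on foreground pixels and breaking the
  channel-comparison prediction rule (in diagnostic runs the ISV channel
  separated foreground from background almost perfectly while the non-ISV
  channel saturated at 1 everywhere). The share preserves the term's
  anchors — `log 2` per pixel at a uniform 0.5 prediction, the clamping
  floor at the ground truth, strict decrease along a linear blend from
  uniform to truth — and reduces to the raw score for single-map
  predictions.
* **Arms.** `total_objective()` exposes four arms mirroring the ablation
  design: `wce`; `c` = `L_c` (the contour term is itself a cross-entropy and
  replaces the data term); `s` = `L_wce + L_s` (the shape term alone has no
  data term to replace, so it adds to the base); and the full objective
  `s+c` = `L_c + L_s`. All terms are non-negative and finite under the
  probability clamp.

Numerical choices: probabilities are clamped to `[1e-7, 1 - 1e-7]` before
any logarithm; the sigmoid output itself is clamped to
`[1e-12, 1 - 1e-12]` because float underflow at |logit| ≳ 37 would otherwise
land exactly on the boundary of the open interval; `band_width` defaults to
2 px (small enough to be a contour, exposed in configuration); `L_c` and
`L_s` are normalized (by `|I|` and the pixel count respectively) so the two
terms sit on comparable scales regardless of image size. Weight decay
(5×10⁻⁴) is applied by the optimizer as an L2 penalty on convolution
kernels and is not added to the reported loss value.

## Training protocol

`train()` implements: He-scaled Gaussian initialization (`init_weights()`;
only "Gaussian" is prescribed, the `sqrt(2/fan_in)` scale is the standard
choice for ReLU networks), seeded shuffling, minibatch SGD with momentum 0.9
and weight decay 5×10⁻⁴, a learning-rate schedule that freezes the mean
loss of the first 10 epochs as a baseline and halves the rate whenever the
epoch-to-epoch improvement falls below 1% of that baseline, and stopping
when the relative loss difference drops below 10⁻⁴ or at 150 epochs. The
halving and stopping rules compare *consecutive* epochs (a window is not
prescribed; consecutive is the simplest reading), operate on training loss,
and validation loss — when a validation set is supplied — selects the
checkpoint that is returned. The optimizer is not prescribed either; SGD
with momentum is the default as the classical companion of an explicit
halving schedule, and Adam is available in `train_config()` for very small
fixtures, where only a few hundred update steps fit and momentum-SGD cannot
reach convergence in the budget (on such fixtures the halving rule is also
best disabled by setting the baseline window beyond the epoch budget: 1% of
the early-epoch baseline is far larger than any per-epoch improvement, so
the rate would otherwise collapse geometrically and freeze learning mid-descent).

After training, batch-norm running statistics are re-estimated in one
full-batch pass over the training images (`calibrate_bn()`). Training
optimizes under within-batch statistics; with few small batches the
exponential running averages sit between batch compositions, and
evaluation-mode predictions (which use the running averages, and on which
all determinism contracts rest) can diverge from what the optimizer saw.
One-pass re-estimation closes the gap exactly for the calibration batch.

A non-finite loss aborts with the epoch named; the learning rate sequence is
non-increasing with every decrease exactly a factor of 2.

## The phantom generator

`generate_phantom()` emulates the statistical structure the method must
handle, with exact ground truth by construction:

* two horizontal rails (DA at 0.88 H, DLAV at 0.12 H) as context, excluded
  from both masks;
* `n_isv_pairs` pairs of *adjacent foreground ISVs* (two neighbouring
  somites' vessels, ~16 px apart within a pair), each a near-vertical
  polyline with slight bow and jitter, stroke width 3–4.5 px, rasterized by
  exact point-to-polyline distance (a pixel is foreground iff it lies within
  half the stroke width of the centerline) — anti-aliasing softens the
  rendered image only, never the masks;
* per-vessel abnormality with probability `p_abnormal`: `short` (the vessel
  stops 35–60% of the way up), `branching` (an oblique side branch),
  `adhesion` (a bridge joining the pair's two vessels);
* with probability `background_vessel_prob`, an occluded contralateral
  partner: offset 4–9 px, drawn *before* the foreground so the foreground
  occludes it, at 50–100% of the foreground gain — the equal-intensity end
  of that range reproduces the hardest overlap case;
* fluorescence unevenness: per-vessel gain `U(0.6, 0.95)` times a
  low-frequency sinusoid along the arclength with amplitude
  `intensity_unevenness` (default 0.3); additive Gaussian noise
  (`noise_sigma`, default 0.03) clipped to `[0, 1]`.

No quantitative morphology statistics (widths, spacings) are published for
the original data, so these defaults are chosen for visual and structural
plausibility, not fidelity — they are fixed once here and not tuned against
test outcomes. Determinism is per-seed: a dataset's sample `i` uses master
seed + `i - 1`, and identical configurations are bit-identical.

What phantoms do *not* emulate: point-spread blur and depth-dependent
attenuation of real confocal projections, autofluorescence textures,
parachordal vessels and other distractor anatomy, annotation noise. A
network that memorizes phantoms has demonstrated that the architecture,
losses, gradients and training loop work — not that it generalizes to
microscopy; results on phantoms are capacity and correctness checks, not
biology.

## Data pipeline

`crop_isv_regions()` labels foreground components (8-connectivity), orders
them by centroid x and groups consecutive components in pairs — an automatic
stand-in for the original interactive cropping — producing one crop per ISV
pair with height clamped to [120, 160] px and the crop mask restricted to
the pair's own components. `pad_to_square()` zero-pads to the longer side,
content centred (idempotent). `augment_mirror_flip()` returns the original,
its left–right mirror, its up–down flip, and both — exactly ×4, mask sums
preserved, which is the arithmetic that takes 6842 source patches to 27368.
`resize_patch()` resizes images bilinearly and masks by nearest neighbour
with re-binarization (default side 128, the published training size).
`split_folds()` resolves the "five cross-validation sessions at 60/20/20"
tension as five independently seeded re-splits at those ratios, reported as
means over sessions.

## Evaluation

Metrics are computed per image and then aggregated (median, mean, sample
standard deviation — sample, not population, where the convention is
unstated), matching per-dataset reporting: accuracy
`100·(TP+TN)/(TP+TN+FP+FN)` on the percent scale and Dice
`2TP/(2TP+FN+FP)`, with empty-vs-empty Dice defined as 1 and flagged.
`pr_curve()`/`roc_curve()` sweep 256 evenly spaced thresholds plus every
distinct score when the image has ≤ 10⁴ pixels, which makes toy curves
exact; `auc()` integrates the step curve by trapezoid, which for ROC equals
the rank-statistic (Mann–Whitney) value on distinct scores and is invariant
under strictly monotone score transformations. PR points with no predicted
positives are dropped (counted in an attribute) and the conventional
zero-recall anchor is appended. `paired_t_test()` is the two-sided paired
test at the 5% level with explicit zero-variance branches (all-zero
differences: p = 1; constant non-zero: the exact-t limit, flagged
degenerate). `render_overlay()` paints TP/FP/FN as pure red/blue/yellow over
the grayscale base so tint counts equal the confusion counts exactly.

## Problem sizes used by the tests and the acceptance script

The suite exercises full-size contracts where cheap (128×128 forward
passes) and scales stochastic checks to CPU-friendly sizes chosen once: the
overfit capacity fixture is 8 phantoms of 64×64 px with one ISV pair each
and a `base_channels = 4` Dual ResUNet-14 (~57k parameters), trained with
Adam at a constant 2×10⁻³ (100 epochs in the test; up to 400 with early
stopping in the acceptance script, since some phantom draws contain an
equal-intensity overlap that takes longer to memorize); loss-oracle
comparisons use ≤ 8×8 images against literal per-pixel loop transcriptions;
gradient checks compare central differences on 3×3 two-channel predictions
(tolerance 10⁻⁴ relative) and on sampled network parameters (10⁻³);
binomial and AUC null checks use 3σ bounds at their stated sample sizes.

## Known limitations

* The bridge channel bookkeeping (concatenate, then 1×1 back to the expected
  count) is one of several defensible wirings; the level-1 bridge squeezes
  through `in_channels` and is therefore narrow.
* The contour term supervises only the ISV channel; the non-ISV channel is
  supervised through the shape term alone.
* Training is single-threaded CPU R/C++; it is meant for method study and
  small fixtures, not for production-scale training runs.
* Phantom realism is structural, not photometric (see above); absolute
  benchmark numbers from licensed microscopy data are out of reach by
  design.
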