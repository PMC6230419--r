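---
title: "Methods: a compact SegNet for brain-tissue segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a compact SegNet for brain-tissue segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

`brainseg` assigns every pixel of a 2D, skull-stripped, T1-weighted brain MRI
slice one of four labels: background (0), cerebrospinal fluid (CSF, 1), gray
matter (GM, 2) or white matter (WM, 3). The segmenter is a compact
encoder–decoder convolutional network in the SegNet family, reduced to two
encoder blocks and two mirrored decoder blocks — 31 layers in total:

* Each encoder block applies two rounds of (3×3 same-padding convolution →
  batch normalization → ReLU) followed by 2×2, stride-2 max pooling. All
  hidden convolutions carry 64 filters.
* Each decoder block starts with **max unpooling**: the pooled activations
  are scattered back to the exact argmax positions memorized by the paired
  encoder pool (encoder1 ↔ decoder1, encoder2 ↔ decoder2), giving a sparse
  2× upsampling that preserves boundary localization without learned
  upsampling weights. Two (convolution → batch norm → ReLU) rounds then
  densify the map.
* The last decoder convolution maps to 4 channels; a pixelwise softmax turns
  scores into class probabilities, and the classification head takes the
  per-pixel argmax (ties resolve to the lowest class index, i.e.
  background).

With 64-filter hidden layers the network carries exactly 225,420 trainable
scalars: eight convolutions (one 1→64, six 64→64, one 64→4, each 3×3 with a
bias) and eight batch-norm layers (scale and shift per channel). The count
is asserted in the test suite by an independent shape sum over the layer
table.

Because the two poolings each halve the spatial dimensions, valid inputs
must be divisible by 4 in both dimensions; `pad_to_multiple()` pads
arbitrary slices symmetrically with background and returns an exact crop
record, so `predict()` works on any slice size.

## Training recipe

Fitting is plain stochastic gradient descent with momentum on a
class-weighted cross-entropy:

$$L = -\frac{1}{N}\sum_{p} w_{y(p)} \log \hat{\pi}_{y(p)}(p),$$

where the sum runs over all pixels of the minibatch, $N$ is the pixel count
and $w$ are class weights. Defaults follow the reference recipe: learning
rate 0.001, momentum 0.9, minibatch size 8, on-the-fly augmentation by a
random X-axis reflection (probability ½) and a rotation drawn uniformly from
±10°. Images are zero-centered (mean subtracted per slice) before entering
the network.

Choices the recipe leaves open, and what this package does:

* **Class weights.** Median frequency balancing:
  $w_c = \mathrm{median}(f)/f_c$ with $f_c$ the pixel frequency of class
  $c$ over the training labels. Background dominates brain slices, so its
  weight falls below 1 while rare tissue (typically CSF) is boosted. A
  uniform-weights alternative is exposed in the configuration.
* **Loss normalization.** By pixel count, not by summed weights, so the
  learning-rate scale does not change when the weight scheme does.
* **Momentum.** 0.9, the conventional default, exposed in the
  configuration.
* **Initialization.** He (fan-in-scaled) Gaussian weights,
  $\sigma^2 = 2/(9\,C_\mathrm{in})$, appropriate for ReLU stacks; zero
  biases; unit scale / zero shift for batch norm.
* **Batch norm constants.** $\varepsilon = 10^{-5}$; running statistics
  updated by an exponential moving average with factor 0.1 using the biased
  minibatch variance. Inference before any training update is an error
  rather than a silent fallback.
* **Pooling ties.** The first maximum in row-major window order wins, so
  index bookkeeping is deterministic (a constant window memorizes its
  top-left corner).
* **Convergence.** A fixed epoch cap plus early stopping: training ends
  when the epoch loss has improved by less than $10^{-4}$ for 10 consecutive
  epochs. The parameters returned are those of the best epoch by training
  loss.
* **Augmentation resampling.** Bilinear for images, nearest-neighbor for
  labels (so the label alphabet is preserved exactly); out-of-canvas pixels
  are filled with background. Augmented copies are generated on the fly per
  epoch, which keeps the dataset definition small and the run reproducible
  from one seed.

All layer primitives and their analytic gradients are implemented in the
package (the convolution inner loop is im2col plus a BLAS matrix product;
batch normalization, pooling and unpooling are single-pass compiled
kernels). Backpropagation is verified against central finite differences on
a reduced network in double precision; the suite requires a relative error
below $10^{-4}$ on at least 99% of sampled coordinates.

Determinism contract: given one seed, initialization, epoch shuffling and
augmentation draw from a single R random stream, and all arithmetic is
sequential double precision, so two runs produce bit-identical parameters
and reports.

## The synthetic phantom generator

Real, expert-labeled MRI volumes cannot ship with a package, so every
pipeline stage is exercised on synthetic skull-stripped phantoms with exact
ground truth. A phantom is built from nested ellipses: a brain ellipse whose
outermost band is CSF, a GM band inside it, a WM core, and a configurable
number of small CSF "ventricle" ellipses placed strictly inside the core.
Intensities follow T1 contrast with defaults CSF 0.2, GM 0.5, WM 0.8 (on a
0–1 scale, ordered CSF < GM < WM by construction); a single smooth Gaussian
bump with random center, scaled to 1 ± 0.2, plays the role of the scanner
bias field; Gaussian noise with σ = 0.05 is added to brain pixels — roughly
a tissue-contrast-to-noise ratio of 6, typical of a clean T1 acquisition —
and intensities are clipped to [0, 1]. Background stays exactly 0, as in
skull-stripped images. Ellipse centers, axes and orientation are jittered
±10% per phantom, and per-item seeds are derived as master seed + index so
any subset is reproducible.

What the phantoms deliberately do **not** model: cortical folding, partial
volume averaging at tissue interfaces, susceptibility or motion artifacts,
and 3D continuity. A network that segments these phantoms has demonstrated
that the architecture, loss, gradients and training loop work end to end —
not that it matches expert performance on clinical data. The package's
evaluation numbers on phantoms are therefore read as software verification,
not as clinical accuracy claims.

## Evaluation suite

For a predicted/true label pair the report assembles, per class on
one-vs-rest masks: Dice $2|x \cap y|/(|x|+|y|)$, Jaccard
$|x \cap y|/|x \cup y|$ (identically $D/(2-D)$, asserted to machine
precision), IoU from the confusion matrix (equal to Jaccard by an algebraic
identity, also asserted), recall-style class accuracy, and a boundary-F1
score; globally: the 4×4 confusion matrix, global and mean accuracy, mean
and frequency-weighted IoU, and the intensity MSE between gray-level
renderings of the two label maps (classes at the equally spaced 8-bit levels
0/85/170/255 — the rendering is configurable, so the MSE scale is tied to
this choice). Mean Dice and Jaccard are reported over the three tissue
classes, excluding background. Conventions for degenerate cases: metrics on
two empty masks return 1 ("no lesion, none predicted"); the boundary-F1
tolerance defaults to 0.75% of the image diagonal, at least 1 pixel; the
MSE uses squared differences.

## Problem sizes used by the tests and the acceptance script

The shipped verification runs use deliberately desk-scale problems: oracle
equivalence on 100 random instances per primitive; the gradient check on a
filter-width-4 network with 8×8 inputs; and one full-width (64-filter)
training run on 32 phantoms of 96×96 with 8 held-out phantoms, minibatch 8,
learning rate 0.001, momentum 0.9, at most 40 epochs. 96×96 keeps the
full-width run at workstation scale while preserving every architectural
property (the network itself accepts any divisible-by-4 size, including
208×176 slices). Reduced filter widths (2–4) are used wherever the full
width adds nothing to the property under test.

## Known limitations

* A 40-epoch budget at 4 minibatches per epoch (160 SGDM updates) is a
  short optimization schedule at learning rate 0.001: the training loss is
  still descending when the cap is reached, and both training accuracy and
  held-out Dice keep growing with additional epochs (the acceptance script
  prints both for the capped run). The cap is part of the stated training
  conditions, not a convergence point; the same architecture and loop reach
  much higher overlap when given more effective steps (more epochs or a
  larger learning rate).
* The final decoder block applies batch norm and ReLU to the 4-channel
  class scores before the softmax (faithful to the reference layer table);
  the ReLU clamps negative scores, so pixels whose correct-class score is
  negative learn only through the competing classes' gradients. A practical
  corollary: at learning rates far above the reference 0.001, early
  dynamics can drive one class's score channel negative at every pixel,
  after which that channel receives no direct gradient and the class stays
  unpredicted. At the reference learning rate this failure mode was not
  observed; demonstration runs that raise the rate should watch per-class
  Dice.
* Single-threaded CPU execution only; no GPU path.
* 2D slices only; volumes are segmented slice-wise by the caller.
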