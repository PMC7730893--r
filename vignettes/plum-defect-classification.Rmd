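---
title: "Grading green plums by surface defect: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading green plums by surface defect: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plumvision)
```

## The problem

Green plums (*Prunus mume*) are graded by surface condition into five
classes — rot, rain spot, scar, crack and clean skin — because the grade
decides what product a fruit can go into. A machine-vision grader
photographs one fruit at a time against a dark background under ring
lighting and must label the dominant defect. Two domain rules shape the
data handling:

* **Severity priority.** A fruit can carry several defects at once; it is
  labelled with the most severe one. The order is
  rot > crack > scar > rain spot > normal, implemented in
  `assign_label()`.
* **Class imbalance.** Scars and cracks are rare, so the dataset is
  expanded tenfold by mirroring and 45-degree rotations
  (`augment_image()`), and splitting happens on *original* images before
  augmentation so no variant of a test fruit leaks into training.

## Preprocessing

`preprocess_image()` crops the fruit out of the background with a fixed
deterministic operator chain: Gaussian smoothing with an 11 × 11 kernel
(sigma from the usual `0.3((k-1)/2 - 1) + 0.8` rule), grayscale
conversion (0.299/0.587/0.114 luminance), adaptive thresholding against
the local mean raised by an offset, a 3 × 3 Laplacian, Canny edge
extraction, and the minimal axis-aligned bounding rectangle of the
largest 8-connected edge component. The box is applied to the *original
RGB pixels* and the crop is stretched (bilinear, aspect ratio not
preserved) to 100 × 100.

Parameter defaults — threshold block size 101 and offset 5, Canny
thresholds (50, 150) — were chosen once as values that segment the
synthetic fixtures robustly, and are all exposed as arguments. Two
conventions worth noting: all filters reflect the image at its borders
(so constant images pass through exactly), and a pixel becomes
foreground when it is strictly brighter than its local mean *plus* the
offset, so a constant image with a positive offset yields an empty mask.
Boxes are 0-based and half-open. Ties between equally large edge
components break toward the smallest x, then smallest y.

## The classifier

`build_network()` constructs a VGG-style network with 16 weight layers:
13 convolutions (all 3 × 3, each followed by batch normalization and
ReLU) in five stages separated by 2 × 2 max pooling, then adaptive
average pooling, then three fully connected layers. At full width the
conv plan is 64-64 / 128-128 / 256-256-256 / 512-512-512 / 512-512-512
and the FC widths are 1024-1024-5. The adaptive pooling grid defaults to
1 × 1 (global average pooling), which keeps the first FC layer at
512 × 1024 weights and makes the network accept any input of at least
32 px; the grid is configurable. The final 1024 × 5 layer is the
classifier weight matrix consumed by the loss; it carries no bias, so
the same parameterization serves both the plain softmax and the
w-softmax loss. A `width_multiplier` scales every channel count (and,
by default, the FC width) for desk-scale experiments.

There is no dropout: batch normalization and the loss are the model's
regularizers. Convolution, pooling and batch-norm kernels are compiled
(RcppArmadillo; im2col plus GEMM), with analytic backward passes that
are finite-difference checked in the test suite.

## The w-softmax loss

With unit-norm class weight columns \(w_j\) and bias strength
\(\gamma \ge 0\), each negative class weight is biased toward the
positive class \(c\) and renormalized:

\[ w_i' = \frac{\gamma w_c + w_i}{\lVert \gamma w_c + w_i \rVert}, \qquad i \ne c, \]

and the per-sample loss is cross-entropy on the logits
\([\,w_c^\top x,\ \{w_j'^\top x\}\,]\). Because
\((\gamma+1)w_c / \lVert(\gamma+1)w_c\rVert = w_c\), the true-class
denominator term is consistent, and \(\gamma = 0\) recovers standard
softmax cross-entropy exactly — `wsoftmax_loss()` short-circuits that
case so the equivalence holds for gradients as well. The feature vector
is *not* normalized; its magnitude scales the logits. Probabilities for
the negative classes use the biased logits in the numerator (the only
reading under which they sum to one).

### A degeneracy, and how training avoids it

The loss as written has a spurious global optimum. If the feature
extractor maps *every* image onto one direction \(u\) with
\(w_j^\top u < 0\) for all classes, then for any sample the true-class
logit beats every biased-negative logit by a margin proportional to
\(\lVert x \rVert\) — regardless of the label. The loss falls to zero
while classification stays at chance. Training from random weights finds
this basin readily at \(\gamma = 1\): it only requires coordinating the
last layer's bias direction, which is far easier than separating
classes. (Training that starts from pretrained, already-discriminative
features — the original use of the loss — rarely encounters it.)

The package therefore trains w-softmax with a *margin warm-up*: the
first `gamma_warmup_epochs` run at \(\gamma = 0\) (plain softmax), then
\(\gamma\) ramps linearly over `gamma_ramp_epochs` to its target. In the
packaged desk study the target is \(\gamma = 0.5\), the strongest value
we observed to remain stable from random initialization; \(\gamma = 1\)
collapsed into the degenerate basin even after a warm-up. Both knobs are
exposed in `train_config()`, whose `gamma` default remains 1 for use
with pretrained weights. Reported training accuracy is always computed
from the *unbiased* scores \(W^\top x\) — the quantity `predict()` uses —
because under the degenerate optimum the label-conditioned biased
probabilities are trivially correct and would hide the failure.

## SWA: stochastic weight averaging

`train_network()` wraps momentum SGD (momentum 0.9, weight decay 1e-4,
batch 32 by default — the reference recipe). Before the SWA phase the
learning rate is constant at `base_lr`; from `swa$start_epoch` it follows
the cyclic schedule

\[ \alpha(i) = (1 - t(i))\,\alpha_1 + t(i)\,\alpha_2, \qquad
   t(i) = \tfrac{1}{c}\,(\mathrm{mod}(i-1, c) + 1), \]

descending linearly from \(\alpha_1\) to \(\alpha_2\) within each cycle
of \(c\) steps (default: one epoch). At each cycle end — where
\(\alpha = \alpha_2\) — the current weights are folded into a running
average, \(w_{\mathrm{swa}} \leftarrow (w_{\mathrm{swa}} n + w)/(n+1)\),
so after \(k\) snapshots the state holds their exact arithmetic mean.
Only two weight sets live in memory during training: the live model and
the average.

Averaged weights invalidate the batch-norm running statistics (they mix
layers from different training moments), so finalization performs one
training-mode pass over the training batches and rebuilds each layer's
running mean and variance from the per-batch statistics, combined by the
law of total variance (within-batch plus between-batch). The pass
shuffles the data deterministically first: training sets are often
stored class-sorted, and single-class batches would silently discard the
between-class activation variance — an error worth several accuracy
points at the deeper layers. `predict()` refuses to run on a model whose
average was installed but never recalibrated. Averaging covers weights,
biases and BN scale/shift, not the running statistics themselves.

## The synthetic generator

No fruit photographs ship with the package, so `generate_plum_image()`
procedurally emulates the imaging setup: an axis-aligned ellipsoidal
green fruit (semi-axes 30–38 % of the image side) with radial shading on
a near-black background (level 18), light pixel noise, and class-specific
defects painted as darker alpha-blended regions placed away from the
fruit rim:

* **rot** — one irregular dark-brown blob, 10–16 % of the fruit area,
  with a harmonic-wobble boundary;
* **scar** — one or two sharp-edged polygonal patches, 2–6 % each;
* **crack** — one thin random-walk polyline, width 2–3 px;
* **spot** — 12–40 speckles of radius 2.5–4.5 px (each well under 0.3 %
  of the fruit area);
* **normal** — clean skin. An optional stem stub (off by default)
  reproduces the known stem-versus-scar confusion as an experiment.

Every image is a pure function of `(seed, class, index)`. The morphology
scales were chosen once so that the classes remain separable by gross
pixel statistics — audited by `pixel_baseline_label()`, a deliberately
crude dark-fraction / component-count classifier that must reach 90 % on
generated images — and so that the smallest features survive the
downscaling used in the desk study. What the generator does *not*
emulate: specular highlights, stem cavities, soft defect gradations,
camera noise statistics, multi-fruit scenes. Passing tests on synthetic
data therefore demonstrate that the pipeline and optimizer work, not
that the network would reach any particular accuracy on real fruit.

## The desk-scale study

`run_desk_study()` is the package's end-to-end demonstration under a
single-CPU budget: 500 generated images per class, preprocessed to
100 × 100, split 4:1 on originals, and a width-0.25 network trained for
15 epochs on 40 × 40 inputs (batch 32, base rate 0.05, gradient-norm
clipping at 5, SWA from epoch 10 with
\(\alpha_1 = 0.02, \alpha_2 = 0.005\), \(\gamma = 0.5\) after a 5-epoch
warm-up and 3-epoch ramp), then evaluated on the held-out fifth.
The reduced width, input resolution and rates are the package's own
study sizing; the adaptive pooling layer is what makes the resolution a
free choice. The full-width defaults in `train_config()` (learning rate
0.1, SWA rate 0.05, weight decay 1e-4, batch 32) reproduce the reference
recipe for full-scale runs.

## Evaluation

`build_confusion()` tabulates true-by-predicted counts in the fixed
class order rot, spot, scar, crack, normal. `metrics_from_confusion()`
derives per-class recall (`diag / rowsum`), precision (`diag / colsum`,
0 for an empty column), F1 (harmonic mean, 0 when degenerate), macro
averages (unweighted) and micro accuracy (trace over total).
`reference_confusion()` ships the published confusion matrix of a
trained defect network on its 2500-image test set as a CSV fixture; the
test suite reproduces every per-class value of the published evaluation
table from it by integer arithmetic. One count in the spot row (a single
image of 800) is not itemized in the published narrative; it is assigned
to the crack column, the unique completion consistent with the published
crack precision 0.93 = 125/135. Neither the macro recall (90.06 %) nor
the micro accuracy (93.56 %) of that matrix equals the published 93.8 %
headline mean — the averaging behind that figure is not derivable from
the printed per-class values, and the package documents the discrepancy
rather than hiding it.

## Numerical choices and limitations

* 8-bit images are carried as doubles and re-quantized (round half up)
  after every image operation, so the preprocessing chain is
  byte-deterministic.
* Batch norm uses biased variances (divisor *m*), epsilon 1e-5, running
  momentum 0.1.
* Weight decay couples into the gradient (PyTorch-style) and applies to
  all parameters, including BN scale/shift.
* Optional global gradient-norm clipping (`clip_grad_norm`, off by
  default, 5 in the desk study): the w-softmax bias divides by
  \(\lVert \gamma w_c + w_i \rVert\), which spikes gradients when two
  classifier columns drift toward antipodal.
* He-normal initialization throughout; all randomness (initialization,
  shuffling, generation) flows from user-supplied seeds through R's RNG,
  so runs are bit-reproducible on one platform.
* The w-softmax loss is evaluated per sample (each sample biases the
  negatives toward its own class); with five classes this costs little.
* Degenerate preprocessing inputs fail loudly: an all-dark image raises
  a "no object" error naming the first empty stage.
* Known limitations: the degeneracy of the w-softmax loss at large
  \(\gamma\) from random initialization (documented above); no GPU path,
  so full-width training at publication scale is impractical in this
  implementation; the synthetic generator's realism limits (listed
  above); JPEG input requires EBImage.
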