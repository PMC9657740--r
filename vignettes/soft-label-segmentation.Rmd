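---
title: "Soft-label weight maps and the soft-weight softmax loss"
author: "slfcn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soft-label weight maps and the soft-weight softmax loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In dual-probe HER2 assays (FISH and its brightfield counterpart DISH) and in
cytology slides, the objects a segmentation model must find — amplification
signals, centromere probes, tumour regions — have boundaries that are
physically blurry: out-of-focus light, stain diffusion, and overlapping
chromatin make the "edge" of an annotation a judgement call. Hard per-pixel
labels assert certainty exactly where the annotator had none, and a model
trained against them spends much of its gradient budget fighting noise at
object borders.

`slfcn` softens the *supervision strength* instead of the labels. Each target
class keeps a hard label; what varies across the image is a per-pixel loss
weight with three tiers:

* the eroded **core** of each annotation, weighted $\Psi$ (default 2) —
  pixels the annotator was certain about;
* a **soft band** around the boundary, weighted $\Pi$ (default 1.5) — the
  pixels removed by erosion plus a dilated margin outside the annotation;
* the **background**, weighted $\aleph$ (default 1).

## The weight-map construction

For every annotated instance $r_k$ the bounding box is taken literally as
the min/max of the pixel coordinates, with width $w_k = \max i - \min i$ and
height $h_k = \max j - \min j$ (a single-pixel instance has a zero-size box).
The diagonal $\psi_k = \sqrt{w_k^2 + h_k^2}$ is pooled over the **whole
training dataset** and its median $\psi^*$ sets the morphology scale:

$$\kappa_e = \upsilon \left\lfloor \tfrac{\phi\psi^* + 1}{2} \right\rfloor + 1,
\qquad
\kappa_d = \tau \left\lfloor \tfrac{\phi\psi^* + 1}{2} \right\rfloor + 1,$$

with $\phi = 0.01$, $\upsilon = 2$, $\tau = 6$ by default. Erosion with the
all-ones $\kappa_e \times \kappa_e$ square gives the core $r^c_k$; dilating
the core by $\kappa_d$ gives an outer region $r^o_k$; the soft band is the
annotation minus its core (erosion band) united with the outer region minus
the annotation (dilation band). Presets for the half-scale
($\upsilon = 1, \tau = 3$) and double-scale ($\upsilon = 4, \tau = 12$)
region variants, and for the alternative weight triples $(2, 1, 0.1)$ and
$(4, 2, 1)$, are available via `soft_label_params()` and `weight_params()`.

```{r}
library(slfcn)
square <- instance_annotation(
  as.matrix(expand.grid(i = 24:103, j = 24:103)), "tumor", 1L)
ds <- list(img = annotation_set(list(square), c(128L, 128L)))
softened <- soften_dataset(ds)
softened$psi_star          # 111.72  (79 * sqrt(2))
softened$kernels           # kappa_e = 3, kappa_d = 7
softened$maps$img$weights[64, 64]  # 2    (core)
softened$maps$img$weights[25, 64]  # 1.5  (erosion band)
softened$maps$img$weights[1, 1]    # 1    (background)
```

Decisions the construction had to make where the recipe is silent:

* **Coordinates** are 0-based, `(i, j)` = (x/column, y/row); masks are
  row-major grids.
* **Borders**: morphology treats outside-image as background, so an
  instance touching the frame erodes from that side and dilation clips.
* **Vanishing cores**: an instance smaller than the erosion kernel has an
  empty core; the construction then covers it entirely with soft band.
  This is a direct consequence of the formulas and is kept, not "fixed".
* **Overlap**: the partition is computed jointly over all instances and a
  pixel in one instance's core and another's band gets the core weight
  (tier priority core > band > background). Labels, by contrast, reject
  overlapping instances of *different* classes outright.
* **Kernel parity**: with the default multipliers the derived kernels are
  always odd; the half-scale preset ($\upsilon = 1, \tau = 3$) can produce
  even sizes, which the square-kernel morphology rejects (a centred
  origin requires odd sides). The half-scale region variant is therefore
  only usable where $\phi\psi^*$ keeps the sizes odd.
* **Targets stay hard**: the per-pixel loss uses a single target class, so
  only weights are softened; pixels of the dilation band that lie outside
  every annotation keep the background class.

## The loss

The per-pixel class scores $z$ go through a softmax and the loss is the
weighted mean of the negative log-probability of the (hard) target class:

$$L_{sws} = -\frac{1}{M}\sum_{m=1}^{M} \omega_m \log p_m^{n_m},
\qquad p_m^n = \frac{e^{z_m^n}}{\sum_t e^{z_m^t}}.$$

With $\omega \equiv 1$ this is exactly the unweighted softmax loss; the
loss is linear in $\omega$ and its score gradient is
$\omega_m (p_m^t - [t = n_m]) / M$. Numerical notes: the per-pixel maximum
score is subtracted before exponentiation (mathematically a no-op); the
logarithm is natural; the normaliser is the pixel count $M$, not the weight
total by definition. Because the historical FCN recipe
pairs a *sum*-reduced loss with extreme learning rates (the full-scale
default here is lr $10^{-10}$, momentum 0.99, weight decay
$5\times10^{-4}$), `train_config()` exposes `reduction = "sum"` as the
full-scale default and `"mean"` for desk-scale work — switching reductions
rescales the effective learning rate by roughly $M \approx 2.6\times10^5$
for a 512-tile, so the two settings are not interchangeable without
adjusting `lr`. An optional `NA` label marks pixels (e.g. padded tile
borders) that contribute neither loss nor gradient and are excluded from
$M$.

## The network

The architecture is the FCN-32s lineage: five VGG-style stages
(2+2+3+3+3 convolutions of 3×3, ReLU, each stage closed by a 2×2 stride-2
max-pool), 7×7 and 1×1 fully-convolutional classifier layers with dropout
0.5, a 1×1 score layer to $N$ classes, one 64×64 stride-32 transposed
convolution, and a centre crop back to the input size. Three conventions
are forced by the reference 512 → 710 → … → 17 → 576 → 512 feature trace:

* the **first** convolution pads its input by 100 (all other 3×3
  convolutions pad 1, the classifier convolutions pad 0);
* all five pools round **up** (ceil mode) — the alternative stride-1
  readings of the pooling layers contradict the reference feature sizes, and the
  sizes win;
* the crop offset is 19, the canonical FCN-32s alignment.

`layer_shape_trace()` implements the arithmetic analytically and the
forward pass is tested against it shape by shape. Inputs below 26 pixels
per side are rejected with a sizing error (the conservative bound under
either pooling rounding rule); `predict()` reflect-pads smaller images and
crops back, and tiles anything larger than the configured tile side
(default 512), averaging stitched scores in overlaps. Ties in the final
argmax go to the lowest class index.

There is no pretrained VGG16 bundle shipped with the package (the weights
are ~500 MB of third-party binary data); `init_network(scheme =
"vgg16_transfer")` implements the transfer mechanics — copy supplied
weights where shapes match, fix the deconvolution at bilinear upsampling,
zero the score layer — and falls back to Kaiming initialization for
convolutions with a warning when no bundle is supplied. Kaiming, Xavier
and small-Gaussian schemes cover the ablation space; the optimizer
registry holds SGD-with-momentum, Adam, Adagrad, AdaDelta, NAG and
RMSprop. All layer mathematics (im2col convolution, ceil-mode pooling,
transposed convolution, and their gradients) is implemented natively in
RcppArmadillo; there is no deep-learning framework underneath.

## Augmentation and tiling

The default `augmentation_plan()` produces 11 samples per input: the
original, five small rotations at 5° steps (5°–25°), the three right-angle
rotations, and horizontal + vertical flips. The recipe sentence this
implements is ambiguous ("per 5° and 5 times, increment of 90°"); the
reading adopted here — small-step rotations *plus* right-angle rotations
*plus* both flips — is configurable group by group. Right-angle rotations
and flips are exact pixel permutations (and tested as such); small
rotations interpolate the image bilinearly and the categorical planes
(labels, weights) with nearest neighbour, filling rotated-in regions with
background class / background weight / black.

## The synthetic fixtures

The clinical slides behind the method are not public, so the package ships
a seeded generator instead: textured background, nucleus-like ellipses
with deliberately blurred borders, and two classes of punctate dots
("HER2-like" dark, "CEN17-like" red) placed fully inside the frame and
never overlapping each other. Shapes are rendered crisply, instance masks
are extracted, and only then is the image blurred — the ground truth stays
exact while the appearance softens. The blur σ is the difficulty dial: the
suite verifies that increasing it strictly decreases the image gradient
along annotation borders. The generator reproduces the *statistical*
structure the method targets (crisp truth under blurry appearance, small
punctate objects, two signal classes); it does not attempt stain spectra,
optics, or visual realism, so passing tests demonstrate the machinery and
the directional behaviour of soft weighting, not clinical performance.

## Desk-scale study conditions

The heavy experiments in the test suite run at sizes chosen to exercise
the full pipeline on one CPU:

* **Learning check**: fixtures of 128×128 with one nucleus of semi-axes
  36–48 px (so the pooled $\psi^*$ exceeds 100 and the derived kernels are
  a non-trivial (3, 7)), blur σ 1.5; a width-1/8 network (channel counts
  64→8, …, 4096→512), Kaiming + bilinear-deconv + zero-score
  initialization, mean reduction, lr $10^{-3}$, momentum 0.9, 300
  single-tile steps on 20 training fixtures, scored by foreground F1 on 5
  held-out fixtures.
* **Directional check**: the same geometry at blur σ 3, width 1/16, 150
  steps, 12 training / 4 held-out fixtures, three seeds, comparing the
  three-tier weights (2, 1.5, 1) against the hard-label limit obtained
  with identity kernels ($\kappa_e = \kappa_d = 1$, which the suite
  verifies reproduces hard supervision exactly).

The desk profile's momentum of 0.9 (rather than the full-scale 0.99)
pairs with the raised learning rate; 0.99 at lr $10^{-3}$ multiplies the
effective step by ~100 and is not a stable desk-scale setting.

## Limitations

* Metrics are reported per image, aggregated as mean ± sample (n−1)
  standard deviation; with empty images the zero-denominator convention
  (1 when TP+FP+FN = 0, else 0, flagged `degenerate`) applies.
* Gigapixel WSI containers, stain normalisation, probabilistic targets,
  per-class kernel sizes and the FCN-16s/8s skip variants are out of
  scope; inference operates on pre-extracted fields and tiles.
* Training is single-tile stochastic descent; there is no batching,
  mixed precision, or GPU path.
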