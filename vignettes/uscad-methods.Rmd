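---
title: "Methods: a GWO-tuned wavelet network for breast-ultrasound CAD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a GWO-tuned wavelet network for breast-ultrasound CAD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uscad)
```

`uscad` implements a complete computer-aided-diagnosis chain for
B-mode breast ultrasound: contrast enhancement and despeckling,
lesion segmentation, shape/texture feature extraction, and a wavelet
neural network classifier whose hyperparameters are selected by grey
wolf optimization. This vignette explains each model, the tunable
parameters and their defaults, the numerical choices made where the
design was genuinely open, and what the synthetic phantom suite does
and does not establish about real clinical data.

## Preprocessing

Ultrasound B-mode images carry multiplicative speckle: coherent
interference that modulates every echo by a random factor with unit
mean. The pipeline first applies a **sigmoid intensity mapping**

$$H_{enh}(x,y) = (mx - mn)\,\frac{1}{1 + e^{(\alpha - H(x,y))/\gamma}} + mn,$$

where $mn$ and $mx$ are the image's own minimum and maximum. The
transform is monotone and keeps the output inside the input's range;
its useful work is a contrast stretch around the center $\alpha$ over
a width set by $\gamma$ (both in intensity units).
`sigmoid_enhance()` defaults to $\alpha = 4$, $\gamma = 7$, a setting
that stretches the darkest part of the intensity axis and is only
meaningful for images whose mass sits near black. On ordinary 8-bit
images, a center of 4 drives every pixel above roughly 30 into
saturation and *destroys* the lesion/background contrast the later
stages depend on — so the *pipeline* default (`pipeline_config()`)
centers the sigmoid mid-range instead ($\alpha = 128$, $\gamma = 32$
on the 0–255 scale). Both parameters remain configurable at every
level.

Despeckling is the **IDAD sequence**: a $3\times3$ median filter, an
element-wise maximum of the enhanced image with its median (bright
speckle is constructive interference and is kept; dark, destructive
speckle is suppressed by the maximum), a second median pass that
removes the remaining extreme single pixels, then **Perona–Malik
anisotropic diffusion**. The diffusion PDE is discretized on the
4-neighborhood with exponential conduction
$g(\nabla) = e^{-(\nabla/\kappa)^2}$; defaults are 15 iterations,
$\kappa = 30$ (gradients well below $\kappa$ smooth, edges above it
persist) and time step 0.2, inside the $(0, 0.25]$ stability region
of the explicit scheme. Median borders are handled by edge
replication so shapes are preserved exactly.

## Segmentation

Clustering operates on intensities with a **deterministic
initialization**: with $n = \max(H) + 1$, the $M$ initial centers are
$(1\ldots M)\,n/(M+1)$. Because the start is fixed, the whole
segmentation stage is bit-reproducible — there are no random
restarts. Each outer iteration performs one hard (k-means) sweep —
nearest-center assignment, mean update — and one soft fuzzy-c-means
sweep — graded memberships
$u_{ik} = 1/\sum_j (d_{ik}/d_{jk})^{1/(f-1)}$ on squared distances,
membership-weighted centers — until the largest center movement
falls below `tol`. Defaults: $M = 3$ (lesion, parenchyma, bright
tissue), fuzzifier 2, `tol` $10^{-3}$, 100 iterations. A cluster
that empties is re-seeded at the intensity farthest from the
surviving centers.

The lesion is the cluster with the **lowest center** (breast lesions
are hypoechoic); the choice is exposed for inverted modalities. The
binary map is cleaned by keeping the largest connected component and
filling holes, which is what makes "white foreground = lesion"
well-defined on noisy masks. Binarization thresholds the *hard*
labels, not the membership map.

The boundary is refined by a **two-phase Chan–Vese level set**: a
signed field $\varphi$ (negative inside) initialized as the signed
distance to the mask boundary evolves under
$\partial_t\varphi = \delta_\varepsilon(\varphi)\,[\,(I-c_{in})^2 -
(I-c_{out})^2 - \mu\,\kappa(\varphi)\,]$ with the image normalized to
$[0,1]$, curvature weight $\mu = 0.2$ and a 200-iteration default
budget. Three numerical choices matter:

* the data force is normalized over the contour band
  ($|\varphi| < 2$) rather than the whole image, so far-field
  intensity extremes cannot stall the front and `dt` (default 0.5)
  acts as a boundary speed;
* curvature is clamped to $[-1, 1]$ — discrete curvature estimates
  blow up where $|\nabla\varphi|\to 0$;
* $\varphi$ is re-initialized to a signed distance every 20
  iterations, and convergence is declared when the mask changes on
  less than 0.1% of pixels over a whole 20-iteration cycle.
  Per-iteration sign-change counts are *bursty* (pixels flip in
  waves with roughly the re-initialization period), so a
  single-iteration stopping rule terminates slow fronts spuriously.

If the contour collapses, the pre-refinement mask is returned with a
warning. On clean two-level images the refinement recovers the true
region from badly over- or under-sized initial masks (Dice 1.0 in
the test suite); on speckled phantoms the cluster cut already sits
near the Chan–Vese equilibrium, and refinement is a no-worse
fine-tune.

## Features

Nine **morphological** descriptors are computed on the mask: area,
perimeter, circularity $4\pi A/P^2$, aspect ratio, eccentricity,
solidity, extent, convexity, and boundary roughness (coefficient of
variation of the centroid-to-boundary distance). The perimeter uses
Vossepoel–Smeulders chain-code weights (0.980 per axial step, 1.406
per diagonal), which is near-unbiased for smooth digital boundaries —
a digital disk of radius 30 scores circularity ≈ 0.93. Solidity uses
the convex hull of pixel *corners*, so a filled rectangle scores
exactly 1.

**Texture** uses grey-level co-occurrence matrices: the masked
region of interest is min–max quantized to 32 levels, and symmetric,
normalized matrices are accumulated at the four unit offsets
(0°, 45°, 90°, 135°), with both pixels of a pair required to lie in
the mask. Contrast, correlation, energy, homogeneity and entropy
(bits) are reported per offset (20 values). Four **first-order**
moments (mean, population variance, skewness, excess kurtosis)
complete the 33-feature vector; the column order is fixed by
`feature_schema()`.

Features are z-scored with statistics fitted **on training rows
only**, then reduced by PCA keeping the smallest component count
whose cumulative explained variance reaches 0.95.

## The wavelet network

The classifier is a three-layer network whose hidden units apply the
mother Haar wavelet, $\Psi(u) = -1$ on $[0,\tfrac12)$, $+1$ on
$[\tfrac12,1)$, $0$ elsewhere, to scaled/translated pre-activations:

$$y = \sum_{j=1}^{Z} W_{jk}\, \Psi\!\Big(\frac{net_j - b_j}{a_j}\Big),
\qquad net_j = \sum_i x_i W_{ij} + b^{in}_j .$$

The output layer is linear with no bias; class "malignant" is called
when the score reaches 0.5, ties to malignant. The supporting Haar
*family* on an interval (`haar_basis()`) uses breakpoints
$\xi_1 = A + 2k\mu\Delta x$, $\xi_2 = A + (2k+1)\mu\Delta x$,
$\xi_3 = A + (2k+2)\mu\Delta x$ — equal half-supports, so supports
tile the interval at every level and the family is orthogonal; the
test suite verifies the Gram matrix to $10^{-6}$ and exact
reconstruction of dyadic piecewise constants.

Training is **Levenberg–Marquardt** on all parameters
($W_{ij}, b^{in}_j, W_{jk}, a_j, b_j$). The exact Haar activation has
zero derivative almost everywhere, so Jacobians substitute a
piecewise-linear smoothed Haar with transition width
$\varepsilon = 0.1$; the loss itself is always evaluated with the
exact forward pass (a fully-smooth mode is available via
`smooth_forward = TRUE`). Steps are accepted only when the
sum-of-squares loss strictly decreases, so the recorded history is
monotone; damping multiplies by 10 on rejection and 0.2 on
acceptance.

Initialization is where hard-threshold units live or die. Input
weights are drawn from a seeded uniform
$(-1/\sqrt{F},\,1/\sqrt{F})$; output weights start at zero so the
first LM step is an exact linear solve on the hidden features. The
wavelet scales $a_j$ start at the width of the observed
pre-activation range of a forward pre-pass, with translations placed
so the sign-flip points $b_j + a_j/2$ spread uniformly over that
range: every hidden unit begins as a soft threshold at a distinct
level, and every sample lies inside every unit's support. A
unit-scale start ($a_j = 1$) was tried first and *provably stalls*:
almost all samples sit on flat pieces of the activation, the
surrogate gradient support is empty, and the initial Jacobian
gradient is exactly zero.

Two consequences of the discontinuous activation are worth stating
plainly. The network output is piecewise constant in its input, so
probability-like scores are coarse. And LM's basin of attraction is
small: the parameter-recovery suite perturbs a known network by 0.5%
and demands near-zero refit loss on at least 80% of seeded trials —
larger perturbations push samples across activation cells where no
gradient information exists at all, and recovery degrades. That is a
property of Haar networks, not of the trainer.

## Grey wolf optimization

GWO maintains a pack of $S$ wolves; the three best (alpha, beta,
delta) steer the rest. Per wolf, dimension and leader the update is
$E = 2 r_2$, $D = |E X_{leader} - X|$, $C = 2 a r_1 - a$,
$X' = X_{leader} - C D$, and the new position is the average of the
three $X'$. (This implementation keeps the coefficient names $C$ and
$E$ of the CAD formulation; the metaheuristics literature calls them
$A$ and $C$ respectively.) The schedule $a = 2(1 - t/I_{max})$ decays
linearly, exploratory early and exploitative late; $r_1, r_2$ are
redrawn per wolf, dimension *and* leader. Leaders are updated
elitistically — replaced only by strictly better wolves — which is
what makes the best-fitness history monotone. Positions are clipped
to the box bounds; non-finite fitness is treated as $+\infty$.

Hyperparameter tuning searches three dimensions: hidden-neuron count
$Z \in [2, 30]$ (rounded on decode), initial LM damping
($\log_{10}$ scale, $[-4, 1]$) and weight-init scale ($\log_{10}$,
$[-2, 0.5]$). Defaults $S = 15$, $I_{max} = 30$ give
$S(I_{max}{+}1) = 465$ fitness evaluations. Before any evaluation
the training table is split 70/30 (stratified, seeded) into
tuning-train and tuning-validation rows; a candidate's fitness is
its validation sum-of-squares after a budgeted 15-epoch training.
The final model retrains on the full training split with the best
hyperparameters. Only hyperparameters are searched by GWO; the raw
weights are left to LM (searching all weights is possible in
principle but multiplies the dimension by the network size for no
observed gain). Hidden layers are fixed at one.

Tuning earns its keep on the quantity it optimizes: across seeded
replicates the tuned candidate's validation accuracy matches or
beats a fixed default ($Z = 8$). On *held-out test* accuracy the
comparison is noisier — selecting among 465 candidates on a ~25-row
validation set adds selection variance, and a good default can tie
or occasionally win. The test suite asserts the validation
comparison; the end-to-end test-set requirement is asserted on the
full pipeline directly.

## Evaluation

Malignant is the positive class. `metrics()` reports accuracy,
sensitivity, specificity, PPV and NPV as raw fractions; zero
denominators yield `NA`, never a silent 0. Display rounding is whole
percent for accuracy and one decimal elsewhere; stored values are
never rounded. AUC is the Mann–Whitney pair statistic with half
credit for ties, which the tests verify equals the trapezoid under
the threshold-sweep ROC on ties-free data (and equals `pROC`'s
estimate including ties). The splitter produces a stratified 70/30
holdout and stratified 10-fold assignments from one seed; folds are
reported alongside, not instead of, the holdout. All preprocessing
statistics (standardization, PCA) are fitted inside the training
portion only.

## The phantom generator

`generate_phantom()` emulates the two ingredients the pipeline
feeds on: class-specific lesion *shape* and ultrasound-like
*noise*. A hypoechoic lesion (interior level = background ×
contrast, default 0.5) is placed on a brighter background (default
level 180); the boundary is an ellipse (semi-axes 22 × 15 px) for
the benign class and a spiculated star
$r(\theta) = r_0\,(1 + A\sin(p\theta + \phi) + \text{jitter})$
(base radius 18 px, 9 spikes, amplitude 0.35, two seeded low-order
harmonics) for the malignant class. The clean map is blurred with a
Gaussian of σ = 1.2 px approximating the system point-spread
function, then multiplied by gamma speckle with shape $L = 4$ and
unit mean — the L-look model, chosen over additive Gaussian noise so
the despeckling stages face multiplicative statistics with the
textbook coefficient of variation $1/\sqrt{L}$. Dataset generation
jitters geometry (±15% size, 7–12 spikes, amplitude 0.30–0.40, free
orientation) and derives per-sample seeds from one master seed.

What the phantoms do *not* emulate: log compression, depth-dependent
attenuation and focus, acoustic shadowing and enhancement behind
lesions, heterogeneous parenchyma, isoechoic lesions, and operator
variability. Passing the phantom suite therefore demonstrates that
the pipeline's machinery is correct and that it recovers a
constructed, learnable shape/texture separation — it does not
certify clinical performance, and the published real-data accuracy
of this method family is deliberately not asserted anywhere in the
package.

## Problem sizes used by the test suite

The segmentation suite uses 20 phantoms (10 per class) at 128×128;
the end-to-end classification test uses 60 + 60 phantoms with the
default 465-evaluation tuning budget; the tuned-versus-untuned
comparison runs 5 seeded replicates on the same feature table; Haar
orthogonality is checked through $M = 8$ (family size 16). These
sizes make every property measurable with comfortable margins while
keeping a full run of suite plus acceptance script in single-digit
minutes on one core.

## Known limitations

* Single lesion per image by construction; no 3-D volumes, no DICOM.
* The Chan–Vese equilibrium sits at the region-mean midpoint, which
  on blurred boundaries lies a pixel or two outside the half-blend
  contour; segmentation of diffuse boundaries inherits that bias.
* Scores from the Haar network are piecewise constant; ROC curves on
  small test sets are correspondingly coarse.
* GWO hyperparameter selection on small validation sets carries
  selection variance; with strong features a fixed sensible $Z$ is
  competitive on held-out data.
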