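---
title: "dermafuse: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dermafuse: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermafuse)
```

This vignette is the package's own account of the methods it implements:
what each stage computes, which parameters matter and why they default to
what they do, what the synthetic fixtures do and do not establish, and
where the design was genuinely open.

## 1. Hair identification and removal

Hair strands in dermoscopy are thin, elongated, and (in the regime this
method targets) darker than the surrounding skin. The detector exploits
exactly these three properties, per colour channel.

**Model.** Let $P_{CC}$ be one channel of the 8-bit image and $L_r$ the
Euclidean disk of radius $r$, $L_r = \{(x,y) : \sqrt{x^2+y^2} \le r\}$.
The stages are

1. *Closing*: $H_3 = (P_{CC} \oplus L_{r_1}) \ominus L_{r_1}$ — flat
   grayscale dilation (max over the footprint) then erosion (min). Closing
   fills dark structures narrower than the disk diameter: hair vanishes,
   the lesion (much wider than $2r_1$) survives.
2. *Residual*: $H_2 = H_3 - P_{CC}$. Non-negative by the extensivity of
   closing; large exactly where dark thin structures were filled.
3. *Threshold zeroing*: $H_1(x,y) = H_2(x,y)$ if $H_2(x,y) > K$, else $0$.
   The inequality is strict: a residual of exactly $K$ is discarded. This
   separates hair contrast from noise and lesion-texture residue.
4. *Dilation*: $H = H_1 \oplus L_{r_2}$ widens the detection so the
   anti-aliased/partial-coverage border pixels of each stroke are included.
5. *Mask*: the support $H > 0$.
6. *Inpainting*: masked pixels are replaced by the discrete harmonic
   extension of the surrounding skin (below), the channels re-merged.

**Parameters.** `r1 = 5` px (closing disk; detects strokes up to roughly
the disk diameter in width), `r2 = 3` px (border expansion), `K = 40`
intensity units (contrast floor). These are the empirically optimal
settings for the dark-hair regime and are the package defaults in
`hair_removal_config()`. Raising `K` or shrinking `r2` can only shrink the
mask (a tested monotonicity property).

**Border handling.** The question every morphology implementation must
answer: what happens at image edges? Here the footprint is clipped —
the extremum runs over in-image pixels only. This avoids having to invent a
padding value, and it makes closing exactly extensive and idempotent on the
full image, which the test suite checks against an exhaustive per-pixel
oracle on random planes.

**Inpainting.** The mask pixels are unknowns in the discrete Laplace
equation: each must equal the mean of its in-image 4-neighbours, with the
ring of unmasked pixels adjacent to the mask supplying fixed Dirichlet
data (those pixels are never modified). The system is solved directly as a
sparse linear system (`Matrix`); the harmonic residual is verified after
the solve against `inpaint_tolerance` (default `1e-3` intensity units) and
a violation is an error, not a warning. A mask covering the whole image has
no boundary data and is rejected; the degenerate fallback (a component with
no unmasked neighbour, filled with the channel's unmasked median) is kept
for safety although with 4-connectivity such a component cannot arise
unless the mask is total. Arithmetic is floating point throughout; the
final image is rounded half-up and clipped to $[0, 255]$.

**Known limitation.** Bright hair on darker skin produces a *negative*
closing residual and is invisible to this detector. That is a property of
the method, not a bug, and no test claims otherwise.

## 2. Metadata encoding

Three clinical fields are one-hot encoded and concatenated:
sex (2 categories), anatomic site (8), age group in 5-year steps 0–85
(18) — a binary vector of dimension $2+8+18 = 28$ with layout
`[sex | site | age]`. The category order is frozen in
`metadata_codebook()`: `(female, male)` — so female encodes `(1,0)` and
male `(0,1)` — sites alphabetical from *anterior torso* to *upper
extremity*, ages ascending. Encoding is a pure function of the codebook,
which serialises to JSON and back without changing a single bit of any
encoding (tested).

Two policies were open and are now fixed:

- **Missing values** encode as an all-zero block. The alternative — a
  dedicated "missing" category or a sentinel value — changes the vector
  dimension or injects an arbitrary magnitude; the zero block keeps the
  space unchanged and is linearly distinguishable from every legal value.
- **Off-grid ages are rejected**, not rounded. The source field is already
  binned in 5-year steps; silently binning `37` would hide upstream data
  errors.

## 3. Fusion model

The image branch of the bundled `small_cnn` backbone is one valid-region
convolution layer: for a $w\times w\times D$ filter with coefficients
$w^{(1)}_{ijk}$ and offset $g$,
$$P_f(x,y) = g + \sum_{i=-\frac{w-1}{2}}^{\frac{w-1}{2}}
  \sum_{j=-\frac{w-1}{2}}^{\frac{w-1}{2}} \sum_{k=0}^{D-1}
  w^{(1)}_{ijk}\, P(x+i, y+j, k),$$
followed by ReLU and $2\times2$ max-pooling. `conv2d()` implements this
formula exactly (including the additive offset) and is tested against a
triple-loop summation oracle at relative tolerance $10^{-9}$.

The metadata branch is a multilayer perceptron on the 28-dim vector
(default widths 28→32→32, ReLU). The fusion (concatenation) layer combines
the pooled feature map $\{x_{ijk}\}$ with the metadata features $m$:
$$f_l = \sum_{ijk} x_{ijk} w^{(2)}_{ijkl} + \sum_i m_i w^{(3)}_{il},$$
a bias-free joint linear map, algebraically identical to
flatten–concatenate–linear; `fuse()` is tested against an explicit
double-sum oracle. A softmax head over per-class affine scores produces the
10-category posterior, implemented as the standard softmax over per-class
affine scores with log-sum-exp stabilisation — the only formulation that
yields a probability simplex for arbitrary score magnitudes.

**Training defaults** (`model_config()`): SGD with momentum 0.9, learning
rate 0.01, batch 16, 50 epochs, seeded He-scaled Gaussian initialisation —
module policy, chosen as the most conventional settings that overfit the
synthetic fixture inside the test-time budget. Training is deterministic
given the config seed (initialisation and batch shuffling both derive from
it). Argmax prediction breaks ties toward the lowest class index.

**Backbones.** `alexnet`, `squeezenet` and `resnet101` are recognised by
`model_config()` only to validate their input-size conventions (227×227,
227×227, 224×224); `build_model()` rejects them because their value lies in
ImageNet-pretrained weights, which cannot be bundled in a text-only,
offline-installable package. Every test and example uses `small_cnn`.

## 4. Augmentation and splitting

`apply_affine()` supports rotation, shift, reflection, scaling and crop.
Right-angle rotations are exact index permutations; other angles use
bilinear interpolation with edge replication. `resize_for_backbone()` uses
bilinear resampling with half-pixel centre alignment, under which resizing
to the image's own size is exact and 2× downscaling averages 2×2 blocks
(both tested against hand-computed oracles).

`balance_classes()` tops every class up to the largest class count with
affine-transformed copies — never raw duplicates — drawn from documented
ranges: rotation ±30°, shift ±10% of each dimension, horizontal/vertical
flips, scale 0.9–1.1. These ranges are module defaults (the transform
*kinds* are given, the ranges were not). `split_train_val()` defaults to a
stratified 80/20 partition; stratification is the package's choice, needed
for 10-class stability at the small sample sizes the fixtures use.
Augmentation belongs *after* the split and only on the training side; the
package never augments validation data.

## 5. The synthetic world

`generate_lesion_image()` draws a flat skin background (default RGB
(200, 170, 150)) with an elliptical lesion (default centred, semi-axes a
quarter of each dimension, level (120, 80, 70)) plus i.i.d. Gaussian noise
(default sd 2). `overlay_hair()` rasterises quadratic Bezier chords across
the frame at integer width (default 1–3 px) with no anti-aliasing,
darkening each covered pixel by `stroke_darkness` (default 120) per
channel — hard edges are what make the ground-truth mask *exactly* the set
of changed pixels, which the tests assert pixelwise. The default fixture
sizes (128×128 for hair-removal tests, 32×32 for training tests) keep the
suite at desk scale.

`generate_dataset()` makes labels learnable by a fixed lookup: lesion mean
intensity decreases linearly with the class index and the ellipse aspect
ratio shifts with it. This is deliberate plumbing: it lets a tiny model
overfit 30 samples to ≥90% training accuracy, proving that images,
metadata, training, prediction and evaluation connect — and nothing more.
A green overfit test establishes *no* claim about performance on real
dermoscopy; the synthetic world has none of the intra-class variability,
colour texture, rulers, gel bubbles or imaging artifacts of archive data,
and its hair is geometrically simpler than real hair.

Metadata marginals default to the skew of the public archives (male
majority, posterior torso the most common site, young-adult age peak);
uniform marginals are available through the `*_probs` arguments.

## 6. Evaluation conventions

Confusion matrices are rows = true, columns = predicted. The
benign/malignant grouping is the fixed 6-vs-4 partition with actinic
keratosis malignant; grouping block-sums the matrix and conserves total
count. TPR and FPR are reported in percent. The ROC sweeps thresholds over
unique scores (tied scores form one step) and AUC is the trapezoidal
integral, which equals Mann–Whitney concordance with ties counted half —
the suite checks this identity at $10^{-12}$ on random fixtures. For
multiclass predictions the package computes the ROC on the
benign/malignant grouping with malignant positive, using the summed
malignant-class probabilities as the score: benign-vs-malignant is the
clinically meaningful binary decision in dermoscopy triage, and one summary
curve is easier to read than ten one-vs-rest curves (which remain available
by calling `roc_curve()` per class). McNemar's statistic is
$(b-c)^2/(b+c)$ over discordant counts and is undefined (an error) when
$b + c = 0$; no p-value is attached — the statistic is the reported
quantity.

## 7. Numerical and I/O choices

- All images in memory are plain `H × W × 3` double arrays on the 0–255
  scale; channel planes are matrices. No image class hierarchy — base R
  arrays compose better with `Matrix` and the test oracles.
- Disk I/O uses plain-text NetPBM (PPM/PGM): no binary codec dependency,
  diffable fixtures, exact round-trips for integer images (tested).
- Morphology returns doubles regardless of input storage mode; comparisons
  in tests are made in doubles.
- The model checkpoint is JSON (config + every tensor with its shape),
  round-tripping parameters to ~15 significant digits — ample for a
  classifier whose decisions are argmaxes.

## 8. What the acceptance suite covers

`tests/testthat/test-acceptance.R` implements twelve property-based
criteria: morphology against an exhaustive oracle (1000 random planes,
radii 1–3, exact), closing extensivity/idempotence, exhaustive threshold
semantics at `K = 40`, inpainting identity/harmonicity/ramp recovery,
hair-pixel recall ≥ 0.95 with per-fixture MAE improvement on 20 occluded
lesions, the constant-image no-op, the full one-hot coding tables with
round-trip identity, convolution and fusion against summation oracles,
softmax simplex properties, the AUC–concordance identity, McNemar's
canonical values, and the end-to-end overfit run. There are no numeric
headline targets: archive-scale accuracy figures would require real
dermoscopy data and pretrained GPU backbones, which are out of scope by
design.
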