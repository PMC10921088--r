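---
title: "Wavelet-attention skip connections for ultrasound lesion segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-attention skip connections for ultrasound lesion segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(watunet)
```

## The problem

B-mode breast ultrasound shows lesions as hypoechoic (dark) regions embedded
in a bright, speckle-textured background. Delineating the lesion boundary is
the first step of computer-aided diagnosis, and encoder–decoder networks of
the UNet family are the standard tool for it. The plain skip connections of
a UNet copy encoder features straight into the decoder; they preserve
spatial detail but pass along speckle noise unfiltered and give the decoder
no way to emphasize the salient region. This package implements a family of
skip-connection replacements, with the *wavelet-attention* combination
(WATUNet) as its centerpiece, together with everything needed to train and
compare the variants reproducibly on CPU-scale synthetic data.

## The model family

All variants share one backbone: `depth` encoder blocks (two 3×3 stride-1
convolutions each followed by batch normalization and a swish activation,
then 2×2 max pooling and dropout), a bottleneck block, and a mirrored
decoder (3×3 stride-2 transposed convolution, concatenation with the skip
tensor, a conv block, dropout), closed by a 1×1 convolution and a sigmoid
that yields a per-pixel lesion probability. The four variants differ only in
the skip tensor:

* **plain** — the encoder feature unchanged (classic UNet);
* **sharpen** — the encoder feature convolved per channel with the fixed 3×3
  Laplacian sharpening kernel `[[-1,-1,-1],[-1,9,-1],[-1,-1,-1]]`;
* **attention** — an additive attention gate over the encoder feature;
* **watunet** — the wavelet gate and the attention gate applied in parallel
  to the same encoder feature and concatenated, so the decoder receives both
  a frequency-decomposed, gated view and a spatially re-weighted view.

### The additive attention gate

For the encoder feature $x$ and a gating signal $g$ (the decoder's
upsampled feature at the same resolution), 1×1 channel projections $W_x$ and
$W_g$ are summed and passed through swish ($\sigma_1(v) = v\,\mathrm{sigmoid}(v)$);
a third projection $W_s$ reduces to a single channel and a sigmoid
$\sigma_2$ yields one coefficient per spatial site:

$$a_i = \sigma_2\!\big(W_s^{\top}\,\sigma_1(W_x^{\top}x_i + W_g^{\top}g_i + b_g) + b_s\big),
\qquad x_{\text{out}} = x_i \cdot a_i .$$

The coefficients lie strictly in $(0,1)$ and are broadcast over the
channels of $x$. Both biases are fixed at zero and are not trainable; the
intermediate projection keeps the channel count of its inputs.

### The wavelet gate

The encoder feature is decomposed per channel by a single-level 2-D discrete
wavelet transform with Daubechies-2 filters, producing four half-resolution
sub-bands: the approximation LL and the detail bands LH, HL, HH. The LL band
— the smoothed, structural view of the feature — is attention-gated, using
as gating signal the coarse decoder feature (which natively lives at exactly
LL resolution) after a 1×1 projection to the encoder channel count. The
gated LL is concatenated with the LH and HL detail bands; HH, which in
speckle imagery is dominated by noise, is discarded by default (a
`include_hh` flag keeps it). A learned 3×3 stride-2 transposed convolution
returns the 3C-channel stack to the encoder resolution.

Two design points deserve justification because the architecture leaves them
open:

* **Resolution reconciliation.** The DWT halves the skip resolution while
  the decoder concatenation expects encoder resolution. We run the gate at
  LL (half) resolution — where the coarse decoder feature already lives, so
  no information is destroyed by premature interpolation — and upsample the
  gated three-band stack with a *learned* transposed convolution rather than
  fixed interpolation. The alternative (downsampling the decoder path) would
  discard the resolution advantage the skip exists to provide.
* **Extension mode.** The DWT uses periodization, the only extension mode
  that yields exactly $N/2$-length sub-bands for Db2 and hence clean shape
  bookkeeping at every level; the transform is orthonormal, so energy is
  conserved across bands, reconstruction is exact, and backpropagation
  through the gate is simply the inverse transform of the band gradients.

In `watunet` mode the decoder level receives $4C$ skip channels
($3C$ from the wavelet gate plus $C$ from the attention gate). Wavelet
gates sit at every level by default (`wavelet_levels` selects a subset).

## Training objective and metrics

The loss is the sum (unit weights, configurable) of mean pixelwise binary
cross-entropy and the soft Dice loss

$$L_{\text{Dice}} = 1 - \frac{2\sum p\,g + s}{\sum p + \sum g + s},$$

with smoothing constant $s = 10^{-6}$ guarding the empty-mask case — common
here, since "no mass" frames have all-zero ground truth. BCE probabilities
are clipped at $10^{-7}$.

Evaluation binarizes the probability map at 0.4 with a strict `>` (the
threshold the source method selected by ROC analysis; strict comparison
makes it behave like an ROC operating point). Metrics follow standard
confusion-matrix definitions; Dice $= 2tp/(2tp+fp+fn)$ coincides with F1 on
binary masks. Test metrics are micro-averaged (confusion counts pooled over
all test pixels), matching the pixel-level framing of the model comparison;
per-image metrics are also emitted. Ratios with zero denominators are
reported as `NA`, never silently as 0.

Training uses Adam (learning rate 0.001, $\beta_1 = 0.9$, $\beta_2 = 0.9$,
$\varepsilon = 10^{-7}$), shuffling each epoch, dropout 0.1 in the encoder
and 0.5 in the decoder, and keeps the parameter state of the epoch with the
highest validation Dice. The per-epoch history records accuracy, loss, Dice
loss, Dice, sensitivity, specificity, F1 and precision on both splits. The
epoch metrics for the training split are accumulated from the training-mode
forward passes (dropout active), so early-epoch training Dice
characteristically lags validation Dice.

## Model comparison

Trained variants are compared pairwise with McNemar's test on pixel
correctness, pooled over all test images into one 2×2 discordance table per
pair: $b$ counts pixels where model A is correct and B wrong, $c$ the
reverse, and $(b-c)^2/(b+c)$ is referred to the $\chi^2_1$ distribution
(no continuity correction by default; pixel counts are large enough that it
is immaterial, and a flag enables it). With $k$ models the $\binom{k}{2}$
p-values enter the Benjamini–Hochberg step-up procedure: sorted ascending,
rank $i$ receives critical value $(i/m)\alpha$, and all ranks up to the
largest $i$ with $p_{(i)} \le (i/m)\alpha$ are declared significant. The
implementation follows the textbook step-up ordering (ranks strictly by
ascending p-value), which is the authoritative form even where published
tables list ranks in another order. A Bonferroni option (single critical
value $\alpha/m$) is provided for users who prefer family-wise error
control at the cost of power.

## The phantom generator

Desk-scale testing needs data with the right gross statistics but no
clinical provenance. Each phantom frame is built as:

* a tissue background with a mild (15 %) vertical attenuation gradient;
* multiplicative speckle: two independent Gaussian fields, blurred with a
  configurable radius (default 1.5 px) and combined as the Rayleigh-like
  envelope $\sqrt{u^2+v^2}$, normalized to unit mean — the standard
  fully-developed-speckle caricature without wave-physics simulation;
* for lesion classes, one hypoechoic region whose interior intensity is
  multiplied by `lesion_contrast` (default 0.45), with a slightly blurred
  rim to mimic partial-volume softening. *Benign* lesions are smooth
  ellipses (aspect ratio 0.55–0.95); *malignant* lesions perturb the
  elliptical radius with random angular harmonics of orders 3–8 plus 2–4
  narrow Gaussian spicules, giving the two classes distinguishable boundary
  statistics. The rasterized region is rescaled until its pixel-count area
  fraction lies in `lesion_area_range` and reduced to the single
  4-connected component containing the center.

The default class mix follows the 2048/820/950 (no mass / benign /
malignant) frame proportions of the motivating clinical dataset, apportioned
by largest remainder so totals are exact and deterministic. Every sample is
a pure function of (config, label, seed); datasets are bitwise reproducible.

What the phantoms deliberately do **not** model: acoustic shadowing and
posterior enhancement, probe-geometry fan distortion, multi-lesion frames,
cine-sweep correlation between frames, and operator variability. Passing the
phantom suite therefore demonstrates that the architecture, optimization and
statistics are implemented correctly and that the wavelet-attention skips
help on speckle-like imagery — not that clinical-grade accuracy carries
over to real ultrasound.

## Preprocessing

CLAHE runs on the 8-bit image at native resolution (tile statistics are
better defined before resampling), with clip limit 2 and an 8×8 tile grid —
common defaults for 8-bit medical images; the method's description names
CLAHE but no parameters, so both are exposed in configuration. Images are
then resized with bilinear interpolation and scaled to $[0,1]$; masks use
nearest-neighbor so values stay binary.

Augmentation draws one affine transform per pair — rotation ±15°, zoom
0.9–1.1, optional horizontal flip, shifts ±10 %, shear ±0.1 rad — applied
identically to image and mask (mask re-binarized at 0.5 after warping), plus
a brightness factor 0.8–1.2 applied to the image only. The magnitudes are
deliberately conservative: aggressive brightness or zoom changes destroy
diagnostically relevant detail in ultrasound. Out-of-frame pixels are filled
with 0, matching the black sector background. Class balancing augments each
class independently to a common target count.

## Numerical and procedural choices

* He-uniform initialization for all convolutions (standard for
  rectifier-family activations), fully seeded; two builds from one seed are
  identical, and a single master seed fans out to data, split,
  initialization and shuffle sub-seeds.
* Batch-norm uses momentum 0.9 and $\varepsilon = 10^{-5}$; evaluation mode
  uses running statistics, so per-sample predictions are independent of
  batch composition.
* The sharpening skip uses periodic boundary handling, which preserves
  constants exactly and makes the operator self-adjoint (its backward pass
  is itself).
* Split arithmetic: validation and test get $\lfloor 0.1 n \rfloor$ samples
  each (at least one when the fraction is positive), the remainder trains;
  with 3818 samples this yields 3056/381/381. Stratification by class is on
  by default; per-class shortfalls are distributed by largest fractional
  remainder, ties broken by class order.
* The bottleneck is one conv block at twice the deepest encoder width with
  encoder-rate dropout.
* Largest-remainder ties in the phantom class apportionment go to the
  earlier class index (deterministic).

## CPU-scale study conditions

The published training protocol (300 epochs, 128×128, batch 32, GPU) is out
of reach of a unit-test budget, and correctness of the architecture does not
depend on it. The package's reference study conditions, used by the test
suite and the acceptance script, are:

* **headline run** — 200 phantoms at 64×64, encoder depth 3, base width 8,
  15 epochs, batch size 4, Adam lr 0.001, CLAHE on; WATUNet reaches
  validation Dice ≈ 0.87 and test Dice ≈ 0.91 under these conditions
  (expected well above 0.6);
* **replicate ordering study** — 5 master seeds, 100 phantoms at 32×32,
  6 epochs; WATUNet's test Dice is compared with the plain UNet's trained
  under identical data/split/init/shuffle seeds, and the majority outcome is
  reported (3 of 5 under the package defaults).

A caveat the phantom suite makes visible: at the headline scale the smooth,
high-contrast phantom lesions are easy enough that the plain UNet performs
on par with WATUNet (their pixelwise McNemar comparison is not significant).
The advantage of the gated skips is expected on harder, noisier imagery;
the phantom study can demonstrate correctness and a weak ordering tendency,
not the clinical effect size.

Batch size 4 (rather than the published 32) is the deliberate choice at this
data scale: with only 160 training frames it gives 40 gradient steps per
epoch, which Adam at lr 0.001 needs to converge inside 15 epochs.

## Known limitations

* The phantom realism gap listed above; no claim of clinical performance is
  made or tested.
* Appendix-level metric definitions of the source method were not available;
  standard confusion-matrix definitions are used (the Dice/F1 identity is
  verified in the tests).
* Whether the published model upsamples the wavelet-gate output or
  downsamples the decoder path is unstated; this implementation upsamples
  (see "Resolution reconciliation" above) and treats that as its design.
* Training is single-threaded CPU R/C++; it is meant for correctness-scale
  experiments, not for 128×128 × 300-epoch production training.
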