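---
title: "Methods: thermal-image texture prognosis for venous leg ulcers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal-image texture prognosis for venous leg ulcers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermaheal)
```

## The problem

A venous leg ulcer (VLU) that has not begun a normal healing
trajectory benefits from adjuvant therapy, but current practice
detects delayed healing only after several weeks of planimetry
follow-up. Surface temperature of the wound bed carries earlier
information: wounds destined to remain open show a more heterogeneous,
more asymmetric spatial distribution of heat at first presentation.
`thermaheal` operationalises that observation as a fully computerised
chain from one week-0 pseudo-colour thermal photograph to a
probability that the wound will still be open at week 12:

1. **Pre-processing** — logo in-fill, pseudo-colour inversion to grey,
   min–max normalisation, Otsu masking with hole filling and disk
   erosion, wound-bed extraction.
2. **Texture** — a grey-level co-occurrence matrix (GLCM) at angle
   90° and distance 1 pixel, summarised by 19 scalar features.
3. **Screening** — Mann–Whitney U tests and effect sizes per feature
   between unhealed and healed groups.
4. **Compression** — covariance PCA fitted on training images only;
   the three leading scores are the classifier input.
5. **Classification** — a 3–h–1 network (tanh hidden layer, sigmoid
   output, weight decay) whose width h is chosen by the Bayesian
   evidence framework.
6. **Evaluation** — twenty random stratified 70/30 divisions,
   reporting sensitivity (correct detection of unhealed wounds, the
   positive class), specificity, ROC and AUC.

Because the clinical images are not publicly deposited, the package
includes a synthetic generator that emulates the cohort structure (47
unhealed, 17 healed, 160 × 120 rasters) so every stage is testable.

## The texture model

For quantized levels $i, j \in 1..N_g$ the co-occurrence matrix
$p(i,j)$ is the normalised count of pixel pairs at the chosen offset,
accumulated in both directions (symmetric by default) and **only over
pairs whose two endpoints lie inside the wound mask**. Masked-out
pixels are excluded rather than zero-filled: zero filling would
manufacture a high-contrast artificial edge along the mask boundary
and contaminate every feature.

The 19 features follow the Haralick/Soh/Clausi conventions with
levels indexed from 1, natural logarithms, and $0 \log 0 = 0$;
e.g. contrast $\sum (i-j)^2 p(i,j)$, cluster prominence
$\sum (i+j-\mu_x-\mu_y)^4 p(i,j)$, inverse difference moment
normalised $\sum p(i,j) / (1 + (i-j)^2/N_g^2)$. Sum variance is taken
about the sum average (the corrected form in common use), and a single
information measure of correlation,
$(H_{XY} - H_{XY1})/\max(H_X, H_Y)$, is reported. Note that with
these formulas $\mathrm{Hom} \le \mathrm{idHom}$ and
$\mathrm{idNorm} \le \mathrm{idmNorm}$ identically (the larger
denominator gives the smaller sum); published tables using other
conventions can order these pairs differently.

Tunable parameters, with defaults and rationale:

* `nLevels = 16` — grey-level quantization. Not dictated by the
  method; 16 keeps a wound bed of a few thousand pixels from starving
  the $N_g \times N_g$ matrix while retaining tonal resolution.
  Recorded in every feature table.
* `theta = 90`, `d = 1` — vertical nearest-neighbour offset, the
  configuration that performed best in the originating study; both
  are configurable and echoed in the output.
* Quantization is uniform over the min–max of the eligible pixels, so
  features are invariant to affine rescaling of wound-bed grey values
  and to translation of the bed within the frame.

## Pre-processing choices

The chain must run unattended on home-visit photographs, so every
rule is objective and parameter-free where possible:

* **Threshold**: Otsu's criterion on the normalised grey histogram by
  default (a fixed threshold is available). The wound is the warm
  object; pixels at or above threshold are kept.
* **Morphology**: flood-fill of interior holes, then erosion with a
  disk of radius 2 — large enough to remove halo pixels at the wound
  margin, small enough to preserve beds of a few hundred pixels.
* **Largest component**: one wound bed is analysed per image; the
  largest connected hot component is the least surprising
  disambiguation when reflections or a second warm object survive
  thresholding.
* **Greyscale conversion**: when the imager's palette is known, the
  monotone map is inverted exactly by nearest-neighbour palette
  lookup (`colormap_inverse`, the default here since the synthetic
  palette is declared); Rec. 709 luminance is the fallback for
  unknown palettes.
* **Logo in-fill**: the median colour of a 2-pixel ring around the
  configured rectangle, which adds no texture of its own.

## The synthetic cohort: what it emulates, and what it does not

`generateWoundImage()` renders, deterministically per seed: a warm
elliptical wound (semi-axes 22–35 px, random orientation and
position) on a cooler background carrying a smooth ambient gradient
(amplitude 0.08) and sensor noise (SD 0.02); a white vendor-logo
block; and the hot-iron pseudo-colour palette. Two structural choices
matter:

* **A radial centre-to-rim temperature drop (0.20 grey units).**
  Uniform quantization over the bed's own min–max makes texture
  features scale-free, so a pure amplitude difference between classes
  would cancel. The fixed-scale radial profile — physically, wound
  beds are warmest centrally — anchors the bed's grey range so that
  the texture amplitude becomes a genuine contrast dial (mean GLCM
  contrast rises monotonically with amplitude at the default
  geometry).
* **A hot-spot skew (0.6).** The texture field is white noise
  smoothed at the class correlation length (2 px unhealed, 3 px
  healed), then transformed $f + 0.6(f^2-1)$ and re-standardised,
  giving sparse hot spots and an asymmetric grey-tone distribution.
  Unhealed wounds get amplitude 0.10, healed 0.03. The asymmetry is
  what pushes cluster shade and cluster prominence above the healed
  class — the same mechanism clinically invoked for inflamed,
  non-healing beds — while the amplitude difference drives contrast
  up and the normalised inverse differences down.

Setting both amplitudes and both correlation lengths equal produces a
null cohort: the classes then differ only through seed noise, and the
per-feature Mann–Whitney rejection rate stays at its nominal level
(verified over 100 cohorts in the test suite).

The generator does **not** model radiometric calibration, emissivity,
multi-wound correlation within a subject, longitudinal image series,
or realistic skin texture outside the wound. A pass on synthetic data
therefore demonstrates that the pipeline recovers class structure of
the kind and direction reported clinically — not that it reproduces
any patient-data magnitude. The published medians and classification
rates were computed on 64 undeposited patient images and are out of
reach by construction; the package's evaluation quantities are
properties of its own synthetic conditions.

## Statistical screening

The Mann–Whitney U test is two-sided; the exact mode enumerates the
permutation null of the rank sum by dynamic programming over the
(possibly tied, mid-ranked) pooled ranks, and is used automatically up
to a combined n of 20; above that the tie-corrected normal
approximation with continuity correction takes over. Features are
ranked by ascending p with a raw 0.05 significance rule — no
multiplicity correction, matching the original analysis — and the
number of tests is recorded so users can correct if desired. Both
Cohen's d (pooled-SD, the conventional reading of the 0.2
"small-effect" threshold) and the rank-biserial correlation
$2U/(n_x n_y) - 1$ are reported, positive when the unhealed group is
higher. When one image per subject is requested, the first image by
subject identifier is retained — a declared deterministic rule, since
the original choice is unstated.

## PCA without standardisation

The raw features span orders of magnitude (cluster prominence
$\sim 10^2$–$10^3$, the normalised inverse differences $\sim 1$), so
covariance PCA on unscaled columns concentrates essentially all
variance in very few components — the regime in which three
components suffice and the first dominates. That matches the variance
profile reported for the clinical data, so unscaled is the default
and `standardise = TRUE` is an option. Components' signs are fixed
(largest-magnitude loading positive) for bit-reproducibility, `k = 3`
is the classifier input by default, and a cumulative-variance
threshold rule (`selectNComponents`, default 0.9999) is available.
Held-out rows are projected with training-derived centre and axes
only; nothing about the test set can alter the model, and a mutation
test asserts the trained model is bit-identical when test rows are
perturbed.

## The evidence-framework classifier

The network has $W = 5h + 1$ parameters. Training minimises
$M = G + \alpha E_W$ (cross-entropy plus $\alpha \cdot \tfrac12 \sum
w^2$) by BFGS with analytic gradients (iteration cap 500), and
re-estimates $\alpha \leftarrow \gamma / (2 E_W)$ with
$\gamma = \sum_i \lambda_i/(\lambda_i + \alpha)$ over the eigenvalues
of the data-term Hessian, iterating until $\alpha$ moves by less than
1%. The Hessian uses the Gauss–Newton outer-product form
$J^\top \mathrm{diag}(y(1-y)) J$ — positive semi-definite by
construction, which keeps $\log\det$ and $\gamma$ stable on tiny
datasets. $\alpha$ starts at 0.1; probabilities are clipped at
$10^{-12}$ in the cost.

The Laplace log evidence at the minimum is

$$\ln \mathrm{Ev} = -G - \alpha E_W - \tfrac12 \ln\det(H + \alpha I)
  + \tfrac{W}{2} \ln \alpha,$$

with eigenvalues of $H + \alpha I$ floored at $10^{-10}$. The
classical hidden-unit mode count $\ln(h!) + h\ln 2$ is **not** added
by default. The reason is empirical and structural: with re-estimated
weight decay, surplus hidden units are pruned towards zero; a pruned
unit's permutation images coincide rather than being distinct
posterior modes, so the $h!\,2^h$ factor overcounts and, because
pruned directions cost nothing through the determinant, it makes the
evidence increase monotonically with width — model selection then
always returns the widest candidate. Without the factor the evidence
shows the intended Occam trade-off: on data generated by a 2-hidden-
node teacher (n = 45), the selected width falls in 1–4 in the large
majority of seeds and the evidence profile is non-monotone. Users who
want the textbook expression can set `symmetryFactor = TRUE`.

Width selection scans h = 1..9 with random restarts per width (5 by
default in `selectArchitecture`; the 20-repetition evaluation harness
uses 3 per width as its problem-size choice), keeps each width's best
restart by evidence, and breaks ties towards the smaller width.

## Evaluation protocol

Splits are stratified by default (per class, the test share is
`floor(n_class * 0.3)`; with 47/17 this yields 45 training and 19
test images, 14 unhealed / 5 healed in the test set — the granularity
at which rates like 11/14 and 3/5 arise). Unstratified splitting is
available, as is the observation that images, not subjects, are the
split unit by default (64 images from 56 subjects in the emulated
design); a subject-grouped option is the leakage-averse alternative.
The "best" repetition is the one with maximal test sensitivity,
tie-broken by specificity — a declared rule. The ROC and AUC reported
for the best model are computed on its training set, mirroring the
originating protocol; the AUC equals the Mann–Whitney concordance of
the scores (asserted against an independent pairwise count and
against pROC in the tests).

## Numerical and degenerate-input conventions

* Constant grey image: normalisation returns zeros with a warning;
  the GLCM collapses to a delta and the features take their limit
  values (energy, maximum probability and all inverse differences 1;
  contrast, entropy, dissimilarity 0).
* Single-level wound bed: correlation and the information measure are
  reported as 0 with a degenerate flag.
* All-tied Mann–Whitney samples: p = 1 with a degenerate flag.
* Empty mask after erosion: an error instructing a smaller radius.
* Every stochastic step (generator, cohort seeds, splits, restarts)
  is a pure function of its seed; per-item seeds are derived
  arithmetically from the master seed and stay below $2^{31}$.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script runs are sized for a single CPU:
cohorts of 64 full-size (160 × 120) images for the end-to-end and
null-calibration experiments (20 and 10 repetitions respectively),
40-image small-raster (80 × 60 / 64 × 48) cohorts for module-level
properties, 100 null cohorts for the Mann–Whitney calibration of the
generator, 20 teacher-network seeds for the Occam check, and 100
random GLCMs for oracle equivalence. These sizes are the package's
declared study conditions for its own verification, chosen once.

## Known limitations

* The synthetic generator is a directional, not radiometric, stand-in
  for patient imagery; magnitudes of features and classification
  rates are properties of its parameters.
* GLCM features are computed at a single (angle, distance)
  configuration per run; rotation averaging and multi-distance fusion
  are out of scope.
* The Laplace evidence is a local approximation around one mode;
  restarts mitigate but do not eliminate local-minimum sensitivity.
* Class imbalance (47:17) is handled only through stratification;
  no reweighting or calibration of the output probabilities is
  attempted.
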