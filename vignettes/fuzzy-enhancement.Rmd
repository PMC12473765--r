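---
title: "Fuzzy-logic local contrast enhancement: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy-logic local contrast enhancement: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzimg)
```

## The problem

Medical grayscale images — CT slices, MR sections, chest radiographs —
often carry clinically relevant structure at low local contrast:
soft-tissue boundaries, tumor margins, lung opacities. Global
histogram methods stretch everything uniformly and tend to amplify
noise in flat regions while under-serving busy ones. The pipeline
implemented here instead treats each pixel as a *fuzzy* member of a
brightness set and adapts the strength of a nonlinear local-contrast
transformation to the character of each pixel's neighborhood.

One input image yields **three** enhanced variants, each driven by a
different local-contrast characteristic. Beyond enhancement per se,
this triples a training corpus for downstream learning: 300 inputs
become 900 images, 5,856 become 17,568.

## The twelve-step model

**Steps 1–3 (the shared fuzzy base).** Intensities are normalized to
$u = f/255$ (the `fullrange` mode; a `minmax` mode using the image's
own extremes is available but undefined on constant images), fuzzified
through a sigmoid membership function

$$\mu = \frac{1}{1 + e^{-a(u - b)}}, \qquad a = 10,\; b = 0.5,$$

and refined by a power law $\mu' = \mu^{\gamma}$ with $\gamma = 1.2$,
which slightly suppresses low memberships and so emphasizes edge
transitions. A rational membership shape
$\mu = 1/(1 + |u - c|/\sigma_f)$ and the classical S-shaped
intensification ($2\mu^2$ below $\tfrac12$, $1 - 2(1-\mu)^2$ above)
are selectable alternatives; refinement modes are mutually exclusive,
not composed. The refined map is defuzzified — the power law and the
sigmoid are inverted exactly — to materialize the fuzzy-enhanced
**base image** shared by all three variants. Because the inversion is
exact, fuzzify → refine → defuzzify reproduces any 8-bit image within
one gray level, a property the tests exercise on random images.

**Steps 4–10 (local characteristics → adaptive exponents).** On the
base image, sliding $n \times n$ windows ($n = 3$ by default) yield:

* **local contrast** $C = (\max - \min)/255 \in [0, 1]$;
* **histogram spread** $h = (f_{\max} - f_{\min})/h_{\max}$, with
  $h_{\max}$ the count of the window's most frequent intensity — zero
  in homogeneous windows, large in wide-range windows with no dominant
  level;
* **fuzzy entropy**
  $\varepsilon = -\frac{1}{n^2 \ln n^2}\sum_i
  \big[\mu_i \ln \mu_i + (1-\mu_i)\ln(1-\mu_i)\big]$, where $\mu_i$ is
  the relative frequency of the $i$-th element's intensity in the
  window ($0\ln 0 = 0$) — exactly 0 on homogeneous windows, maximal
  among two-valued windows at an even split;
* **fuzzy standard deviation**
  $\sigma = \sqrt{\sum_j (f_j - \bar f_W)^2 \mu_j / \sum_j \mu_j}$ in
  gray levels, the membership-weighted deviation about the window's
  arithmetic mean, with weights from the refined membership map.

Each characteristic is mapped to a per-pixel exponent field
$\alpha(x, y) \in [\alpha_{\min}, \alpha_{\max}]$ (defaults
$[0.5, 2]$):

* histogram spread through an inverted Gaussian response
  $\alpha_{\min} + (\alpha_{\max}-\alpha_{\min})
  \big(1 - e^{-(h - a_0)^2 / 2w^2}\big)^s$ — minimal where the spread
  equals the reference $a_0$ (default 0), default width $w = \pi$;
* fuzzy entropy through min–max rescaling of the map followed by the
  power $s$ — monotone nondecreasing;
* fuzzy standard deviation through
  $\alpha_{\min}v + \alpha_{\max}(1 - v)$ with
  $v = \mathrm{clip}(\sigma/255, 0, 1)^s$ — monotone nonincreasing, so
  homogeneous regions get the largest (most compressive) exponent.

The sensitivity exponents default to $s = 1.5$, $2$, and $1.2$
respectively — the values conventionally paired with each
characteristic for medical imagery (balanced enhancement,
noise-sensitive MRI, X-ray opacity detection). They are bound to the
variant, not to the input modality, and are configurable per run.

**Steps 11–12 (transform and reconstruct).** The local-contrast map is
rescaled through a two-branch power law pivoted at its mean
$\hat C$:

$$C^{*} =
\begin{cases}
B_0 + (\tfrac{R}{2} - A_0)\left(\dfrac{C - C_{\min}}{\hat C -
C_{\min}}\right)^{\alpha} & C \le \hat C,\\[1ex]
R - A_0 - (\tfrac{R}{2} - A_0)\left(\dfrac{C_{\max} - C}{C_{\max} -
\hat C}\right)^{\alpha} & C > \hat C,
\end{cases}$$

with $R = 1$ and biases $A_0 = B_0 = 0$ by default, so
$C_{\min} \mapsto 0$, $\hat C \mapsto \tfrac12$,
$C_{\max} \mapsto 1$, and the two branches agree at the pivot for any
$\alpha > 0$. $\alpha$ is read per pixel from the exponent field.
Reconstruction then moves each pixel away from its window mean by the
contrast gain:

$$f' = M_W + \frac{C^{*}}{\max(C, 1/255)}\,(f - M_W),$$

clipped to $[0, 255]$ and rounded half away from zero. The
$1/255$ floor (one gray level of contrast) guards division where the
original contrast vanishes, and $C^{*} = C$ makes the reconstruction
the identity up to quantization — the contract the tests assert.

## Design choices where the design was open

* **Pivot-continuous reading of the two-branch transform.** The
  grouping of the biases admits more than one reading; the one adopted
  is the only one that makes the branches continuous at the pivot,
  which the transform's structure clearly intends.
* **Exponent-map orientation.** The histogram-spread response is
  oriented $\alpha_{\min} + (\alpha_{\max}-\alpha_{\min})(\cdot)^s$ so
  the bounds $[\alpha_{\min}, \alpha_{\max}]$ hold for every input,
  mirroring the entropy variant's orientation; the standard-deviation
  response normalizes $\sigma$ by 255 before weighting for the same
  reason.
* **Window-local mean in the fuzzy standard deviation.** The deviation
  is taken about the window's own arithmetic mean, not a whole-image
  mean: only then is the statistic zero exactly on homogeneous
  neighborhoods, the property that makes it a useful homogeneity
  gauge. The single whole-image contrast statistic
  (`global_contrast()`) retains the image-wide membership-weighted
  mean.
* **Entropy normalization.** The entropy sum is scaled by
  $1/(n^2 \ln n^2)$ (natural logarithms) so that
  $\varepsilon \in [0, 1]$. Under this definition homogeneous windows
  have entropy 0 and mixed windows are high — the orientation the
  formulas imply, which the package follows consistently.
* **Per-pixel exponents.** $\alpha$ varies per pixel with the local
  characteristic rather than being a single per-image constant; a
  global exponent is recovered by setting
  $\alpha_{\min} = \alpha_{\max}$.
* **What feeds the transform.** All three characteristics, and the
  contrast map that is transformed, are computed on the fuzzy-enhanced
  base image (the staging places fuzzy enhancement before variant
  generation), and the base is shared by all variants.
* **Border policy.** Windows are always full-sized via reflect padding
  (replicate is available), so every map has the image's shape; maps
  are translation-equivariant away from borders.
* **Reconstruction formula.** The final step's contract — enhanced
  local contrast drives re-assembly — is realized by the window-mean
  gain scheme above, chosen because it makes "unchanged contrast ⇒
  unchanged image" a testable identity.
* **Degenerate inputs.** A constant local-contrast map makes the
  transform the identity (warned once); windows with zero total
  membership weight report a deviation of 0 (warned once per image); a
  flat entropy map falls back to $\alpha_{\min}$; `minmax`
  normalization of a constant image is an error naming the constant
  level. Constant images therefore pass through the whole pipeline
  unchanged.

## The synthetic fixtures

`make_homogeneous()`, `make_binary()` and `make_gradient()` generate
the three neighborhood archetypes that motivate the local
characteristics — near-constant, two-extreme-level, and
smooth-transition windows — and `make_phantom()` builds low-contrast
blob phantoms on a uniform background with optional Gaussian or
salt-and-pepper noise, the degradations typical of MRI and X-ray. All
generators are deterministic given a seed and leave the caller's RNG
state untouched.

What they emulate is the *local* statistical texture the pipeline
reasons about; they are not anatomically realistic, carry no scanner
artifacts (beam hardening, bias fields, streaks), and have much
simpler intensity distributions than clinical data. Passing tests on
them demonstrates that the implementation honors its mathematical
contracts — not that enhancement improves any particular clinical
task, which would require real corpora and task-level evaluation.

## Problem sizes and numerical notes

The test suite runs the oracle-equivalence checks on twenty seeded
16×16 images per feature (per-pixel naive loops versus the optimized
offset-stack maps, agreement to $10^{-9}$), the corpus-tripling checks
on 300 and 5,856 in-memory 16×16 phantoms, and the property checks
(monotonicity, continuity, identity, determinism) on dozens of seeded
random cases — sizes chosen so the whole suite completes in about a
minute and a half while still exercising every branch. All arithmetic
is double precision; comparisons against printed three-decimal values
round half away from zero, matching their print precision. Images are
written atomically (temp file, then rename), and repeated runs under
one configuration digest are byte-identical.

## Known limitations

* 8-bit grayscale only; color images and other bit depths are out of
  scope (16-bit inputs are min–max rescaled on read, volumes on
  slicing; CT Hounsfield windowing is deliberately not implemented).
* One fuzzy class per image; a multi-class fuzzy partition is not
  supported.
* BRISQUE scoring requires an external implementation and is surfaced
  as a capability error; the bundled no-reference metrics are RMS
  contrast and histogram entropy.
* Windows are square and isotropic; there is no multiscale analysis.
* The defuzzification inverse requires the sigmoid fuzzifier; the
  rational shape is not invertible and cannot anchor the base image.
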