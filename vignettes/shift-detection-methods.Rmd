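---
title: "Detecting distribution shifts in medical images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting distribution shifts in medical images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The monitoring problem

A clinically validated image classifier — here, a diabetic retinopathy (DR)
grader — is validated on data drawn from some *source* distribution
$\mathbb{P}$ and then deployed on data from a *target* distribution
$\mathbb{Q}$. If $\mathbb{Q} \neq \mathbb{P}$, the performance estimates
from validation no longer apply, and the mismatch can concentrate harm in
specific patient subgroups. The difficult case is a *subgroup shift*: every
deployment image lies inside the support of the source distribution (only
the mixture weights change), so per-image outlier detection is useless by
construction. The only way to see such a shift is to compare *samples* of
images, which is a two-sample testing problem:

$$H_0: \mathbb{P} = \mathbb{Q} \quad \text{vs.} \quad H_1: \mathbb{P} \neq \mathbb{Q}.$$

The package implements three detectors that share a common protocol: split
both samples into training and test folds, fit a feature extractor on the
training folds, compute a scalar statistic on the held-out test folds of
size $m$ each, and calibrate it with a permutation test at significance
level $\alpha = 0.05$.

## The three detectors

**C2ST (classifier two-sample test).** A binary *domain classifier*
$f_{\mathrm{C2ST}}: \mathcal{X} \to \mathbb{R}$ is trained with
cross-entropy to distinguish source from target training images. The test
statistic is the difference of mean logits on the held-out folds,
$$t(X, Y) = \frac{1}{m} \sum_i f(x_i) - \frac{1}{m} \sum_j f(y_j),$$
which is exactly antisymmetric and signed, so the permutation test is
two-sided on $|t|$. When nothing distinguishes the distributions the
classifier cannot learn anything, the held-out logits are exchangeable, and
$t$ is centred at zero.

**MMDD (deep-kernel maximum mean discrepancy).** The maximum mean
discrepancy is a kernel distance between distributions that vanishes iff
the distributions agree (for characteristic kernels). It is never computed
via its RKHS definition; what is computed is the unbiased U-statistic
estimator
$$\widehat{\mathrm{MMD}}(X, Y; k) = \frac{1}{m(m-1)} \sum_{i \neq j} H_{ij},
\qquad
H_{ij} = k(x_i, x_j) + k(y_i, y_j) - k(x_i, y_j) - k(y_i, x_j),$$
which may legitimately be negative under $H_0$. The kernel is trainable:
$$k(x, y) = \bigl((1 - \delta)\, g_a(f(x), f(y)) + \delta\bigr)\, g_b(x, y),$$
with $g_a, g_b$ unit-height Gaussians of the squared Euclidean distance
with length scales $\sigma_a$ (on a learned 128-dimensional feature
embedding $f$) and $\sigma_b$ (on raw pixels), and mixing weight
$\delta \in (0,1)$. All parameters — feature-map weights, both length
scales, $\delta$ — are fitted by maximizing
$\widehat{\mathrm{MMD}}$ on the training folds with minibatch Adam. The
test-power-normalized objective used elsewhere in the deep-kernel
literature is deliberately *not* used; the raw estimator is the objective.
The rejection region is necessarily upper-tail: a discrepancy cannot be
"significantly small".

**MUKS (multiple univariate KS tests).** The monitored task model itself is
the feature extractor: each image maps to its softmax vector
$s = f(x) \in \mathbb{R}^C$ ($C = 5$ DR grades), and a two-sample
Kolmogorov–Smirnov test per class
$$t_c(X, Y) = \sup_s |F_{X,c}(s) - F_{Y,c}(s)|$$
compares the class-$c$ marginals, with Bonferroni correction: reject iff
$\min_c p_c \le \alpha / C$. MUKS is the only detector that needs *no
training data from the target distribution* — it consults only the
(source-trained) task model and the two test folds — at the price of only
seeing shifts that move the softmax distribution.

## Permutation calibration

All p-values use the add-one estimator
$p = (1 + \#\{t_b \text{ at least as extreme as } t_{\mathrm{obs}}\}) / (1 + B)$
over $B$ random balanced re-partitions of the pooled test folds, which
guarantees $p > 0$ and finite-sample validity
($P(p \le \alpha) \le \alpha$ under exchangeability). $B$ defaults to 100:
the resulting resolution of $1/101$ is ample for decisions at
$\alpha = 0.05$, and the boundary $p = \alpha$ rejects, matching the
Bonferroni rule's $\le$. Permutations re-partition *precomputed* per-image
quantities (logits for C2ST, rows of the $(2m) \times (2m)$ kernel matrix
for MMDD); detectors are never retrained per permutation — retraining is
neither statistically required for validity under $H_0$ nor computationally
sensible. For the MMD estimator the cross terms $k(x_i, y_j)$ exclude the
positional pairing $i = j$, exactly as the $H_{ij}$ form prescribes, and
the permuted statistics inherit the positional pairing of the permuted
order; a unit test verifies that kernel-matrix re-indexing agrees with
direct recomputation on re-partitioned folds.

## The synthetic study population

Real screening data of this kind is access-restricted, so the package
ships a generator that emulates its *structure* rather than its
photorealism. Attributes are drawn independently per record from marginals
matching a large real screening population: sex ≈ 60/40 female/male (plus
a ~0.3% "other" group), a 69% Latin-American ethnicity mix, image quality
40/41/18 adequate/good/excellent, 10% co-morbidity prevalence, and a
heavily imbalanced grade distribution with 79% healthy images. Image
appearance is a deterministic-plus-noise function of the attributes: a
circular bright fundus field with an optic-disc highlight; grade-dependent
lesion-like spots (4 per grade step, growing in contrast); a diffuse haze
patch for co-morbid eyes; a global pigmentation shift per ethnicity; a
low-amplitude smooth shading asymmetry for sex; and quality-dependent
Gaussian blur (0 / 0.4 / 0.9 px at the 64-px reference scale). An
*insufficient* quality level — heavy blur (2.8 px), dimming, partial
occlusion, extra noise — exists only in a separate out-of-distribution
pool and is never sampled into the source distribution.

Two generator choices deserve comment:

* **The sex amplitude (default 0.003)** is deliberately placed near the
  detection threshold: a ridge-logistic probe on pooled features needs
  hundreds of images per class to exceed ~70% accuracy. This mirrors the
  reported regime on real fundus images, where sex is invisible to experts
  and detectable only with very large training sets. It is the one
  amplitude calibrated against a measurable criterion rather than chosen
  for visual plausibility.
* **Attributes are independent by default** (no grade–quality coupling).
  This is the simplest joint model that supports every simulated shift;
  correlations can be introduced by filtering or reweighting datasets.

What passing tests on this generator do *not* show: robustness to real
acquisition artefacts, vessel morphology, camera heterogeneity, or any
claim that sex/ethnicity manifest in retinal images the way the renderer
paints them — the renderer's choices there are stand-ins for "a weak/
moderate statistical signature", not retinal physiology.

Rendered pixels are clipped to $[0,1]$ and snapped to the 8-bit grid, so
datasets round-trip bit-exactly through the PNG + CSV disk format.

## Shift simulation and fold assembly

Shifts are declarative: `subgroup_filter` (e.g. adequate-quality-only or
female-only targets), `oversample` (weight $w \ge 1$ on one attribute
value; $w = 1$ is exactly the null, and the drawn fraction follows the
closed form $w p_0 / (w p_0 + 1 - p_0)$), `ood` (insufficient-quality
pool), and `null`. Sampling is i.i.d. with replacement everywhere,
matching a resampling evaluation protocol; held-out test folds are kept
disjoint from training folds by partitioning image ids *before* any draw.
Disjointness is at image level (synthetic patients own one image each);
patient-level separation would matter for real data with repeat imaging
and can be obtained by filtering on `patient_id` before building samplers.
Equal fold sizes for source and target are required because both the C2ST
statistic and the MMD estimator are defined for a single $m$.

## Desk-scale backbones

The package's networks are deliberately small: images default to 64×64
(32×32 in the test harness; 96×96 and larger are available via
`image_size`, since resolution measurably matters for these detectors),
and every learnable component operates on 8×8-average-pooled channel
features (192 dimensions) — a fixed first layer that preserves the
low-frequency structure the synthetic effects live in and admits exact
flip augmentation by re-indexing. On top of that sit small fully-connected
softmax networks trained with the same recipe family as the monitored
grader: cross-entropy, SGD with Nesterov momentum, learning-rate decay
×0.9 per epoch, random horizontal/vertical flips, and final-weight
selection by validation loss. The initial learning rate defaults to 0.1
rather than the 0.001 a full-size vision backbone would use — these
networks are 3–4 orders of magnitude smaller, and 0.001 leaves them
undertrained within the epoch budget. The C2ST backbone is selectable
(`linear`, `mlp`, `mlp_wide`) to expose the architecture-sensitivity knob;
the MMDD feature extractor keeps the 128-dimensional output contract of
the deep-kernel construction.

## Numerical choices

* Kernel constraints by re-parameterization: $\sigma = e^{\rho}$,
  $\delta = \mathrm{logistic}(\lambda)$, so constraints hold by
  construction. Length scales start at the median heuristic
  ($\sigma^2 = \mathrm{median}(d^2)/2$) on a warm-up batch; $\delta$
  starts at 0.5 (uninformative mixing).
* Analytic gradients for the kernel objective (including the feature-map
  weights, via the identity
  $\sum_{ij} A_{ij} (f_i - f_j)(z_i - z_j)^\top = 2 F^\top (\mathrm{diag}(r) - A) Z$
  for symmetric $A$) are verified against finite differences in the test
  suite.
* KS p-values: exact (`stats::psmirnov`) when both sizes ≤ 25, otherwise
  the asymptotic Kolmogorov distribution with the effective-sample-size
  correction $\lambda = (\sqrt{n_e} + 0.12 + 0.11/\sqrt{n_e}) D$. Ties in
  softmax values are handled by evaluating EDF differences at pooled
  unique points — deterministic, no randomized tie-breaking.
* Degenerate inputs: a constant statistic yields $p = 1$; fully separated
  folds bottom out at the add-one floor $1/(1+B)$; `mmd_unbiased` returns
  exactly 0 on element-wise identical folds; an all-saturated rendered
  image warns and clips.
* Pixel Gram matrices and pooled features are cached per dataset object,
  so repeated tests against one backing dataset featurize once.

## Power evaluation

Detection rate (test power) and type-I error are estimated by repeated
independent fold draws — C2ST/MMDD are *retrained on every repetition*,
which is the honest power estimate — with Wilson 95% intervals, which
behave sensibly at observed rates of 0 and 1. Defaults: 100 repetitions
for power (matching the 0.01 resolution at which such rates are usually
reported), 500 for type-I estimates. Sweeps iterate over a grid of
(method, shift, $w$, $n_\mathrm{train}$, $m$) cells and emit a tidy
data.frame; per-cell failures are recorded without aborting the sweep.

The packaged statistical checks use, at 32×32 resolution: a 2000-image
backing dataset with 500 null repetitions per method at
$n_\mathrm{train} = 200, m = 100$; a 3000-image dataset for the strong
co-morbidity shift (haze amplitude 0.5) at $n_\mathrm{train} = 500,
m = 500$ over 100 repetitions; and the oversampling grid
$w \in \{1, 5, 10, 100\}$ at $n_\mathrm{train} = 1000, m = 500$ with 100
repetitions per $w$. These sizes were chosen as the smallest at which the
binomial uncertainty of the estimated rates is materially below the
effects being demonstrated.

## Known limitations

* The renderer is a structural emulator; none of its attribute effects
  are validated against real fundus photographs, and absolute detection
  rates on it do not transfer to real data — only the *orderings*
  (OOD ≫ quality/co-morbidity ≫ sex; power increasing in $m$,
  $n_\mathrm{train}$, and $w$) are designed to.
* The pooled-feature backbones cannot express high-frequency texture
  signals; a shift visible only above the pooling scale would be missed.
* MUKS inherits the task model's blind spots: shifts orthogonal to the
  softmax distribution (e.g. a quality change the grader is invariant to)
  are undetectable by design.
* Oversampling weights apply to attribute values, not to joint attribute
  combinations.
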