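---
title: "One-class data description for NIR spectral authentication"
author: "nirdd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-class data description for NIR spectral authentication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirdd)
```

## The problem

Food authenticity screening asks a one-sided question: *is this sample the
genuine product or not?* Only the genuine (target) class can be sampled in
a controlled way — the space of possible fakes is open-ended — so the
problem is one-class classification ("data description") rather than
discriminant analysis: a closed acceptance region is estimated from target
samples alone, and anything outside is flagged as an outlier.

`nirdd` implements this workflow for near-infrared (NIR) absorbance
spectra, emulating a three-brand black-rice screening design: spectra of
10,000–4,000 cm⁻¹ with 1557 points per spectrum, three brands of 48/46/48
samples, each brand in turn playing the target class while the other two
simulate the fakes.

## Models

Three descriptions share one contract (`ddScore()`, `ddThreshold()`,
`ddPredict()`; *accept = target*):

**SVDD** (support vector data description) finds the minimum-volume
hypersphere around the target class in kernel feature space. With training
set $\{x_i\}_{i=1}^N$ the primal minimizes $R^2 + C\sum_i \zeta_i$ subject
to $\lVert \phi(x_i) - a\rVert^2 \le R^2 + \zeta_i$, $\zeta_i \ge 0$. The
dual is the box-constrained QP

$$\max_\alpha \sum_i \alpha_i K_{ii} - \sum_{i,j}\alpha_i\alpha_j K_{ij},
\qquad \sum_i \alpha_i = 1,\quad 0 \le \alpha_i \le C,$$

solved here by a pairwise coordinate-ascent (SMO-style) scheme that
repeatedly picks the maximally KKT-violating pair and solves the
one-dimensional subproblem in closed form. Points with $\alpha_i > 0$ are
support vectors; unbounded ones ($0 < \alpha_i < C$) lie exactly on the
sphere and define $R^2$ (their mean squared centre distance — numerically
stabler than reading a single SV, identical in exact arithmetic); bounded
ones ($\alpha_i = C$) lie outside. The penalty is parameterized by the
target rejection fraction $f$ through $C = 1/(Nf)$, so at most about
$fN$ training samples end up outside the sphere.

The RBF kernel is used **exactly as**
$K(x, y) = \exp(-\lVert x-y\rVert^2/\sigma^2)$ — the denominator is
$\sigma^2$, *not* $2\sigma^2$. Conventions differ across software; every
width in this package (including the default width grids) assumes this
form. A `linear` kernel is also provided; it yields the rigid minimum
enclosing hypersphere, which is also the $\sigma \to \infty$ limit of the
RBF fit.

**KNNDD** compares local densities through a distance ratio: accept $z$
when $\lVert z - \mathrm{NN}_k(z)\rVert \big/
\lVert \mathrm{NN}_k(z) - \mathrm{NN}_k(\mathrm{NN}_k(z))\rVert \le 1$,
where $\mathrm{NN}_k$ is the $k$-th nearest training neighbour (a training
point's own neighbour search excludes itself). Defaults: $k = 1$,
threshold 1. Conventions for degenerate ratios: $0/0 = 0$ (accept),
$x/0 = \infty$ (reject).

**GAUSS** fits a unimodal Gaussian ($\mu$ = sample mean, $\Sigma$ = sample
covariance, divisor $n-1$) and accepts $z$ when the squared Mahalanobis
distance $(z-\mu)^\top \Sigma'^{-1} (z-\mu)$ is below the $\chi^2_d$
quantile at the chosen coverage (default 0.95 → $\theta = 5.99$ for
$d = 2$). The covariance is regularized as $\Sigma' = \Sigma + \lambda I$
with the scale-aware default $\lambda = 10^{-6}\,\mathrm{tr}(\Sigma)/d$;
a near-singular $\Sigma'$ is a hard error in `regularized` mode, while
`pseudoinverse` mode (Moore–Penrose) gives finite scores on rank-deficient
data and is the right choice when fitting in the original 1557-variable
space, where $\mathrm{rank}(\Sigma) \le n - 1 \ll d$. Note that the
$\chi^2_d$ threshold is then very conservative: scores live in the
$(n-1)$-dimensional support while $\theta$ grows with $d$.

## Pipeline protocol

`runStudy()` reproduces the full experiment:

1. **SNV.** Each spectrum is standardized to zero mean, unit standard
   deviation (divisor $n - 1$, the dominant chemometrics convention). This
   removes additive offsets and multiplicative particle-size effects
   exactly; a *sloped* baseline is only attenuated, not removed.
2. **Features.** Mean-centred PCA is fitted on **all** samples jointly and
   the first two score dimensions feed the models (`featureSpace = "pc2"`);
   the original SNV spectra can be used instead (`"original"`). Joint
   fitting follows the study protocol but leaks unlabeled test structure
   into the projection; `pcaScope = "train"` provides the strict
   alternative (PCA refitted per training set; Kennard–Stone then ranks in
   SNV space, since no training set exists before the split). The
   no-leakage guarantee — perturbing outlier-class samples leaves fitted
   models bit-identical — is made, and tested, in strict mode only.
3. **Split.** Within the target class, Kennard–Stone maximin ranking
   (most representative first: start from the most distant pair, then
   repeatedly add the sample maximizing the minimum distance to those
   already chosen; ties break to the lowest index, the initial pair is
   index-ordered) selects the 30 most representative samples for training.
   Everything else — remaining target samples plus *all* other-class
   samples — is the test set.
4. **Fit and evaluate.** SVDD ($f = 0.1$, width below), KNNDD ($k = 1$),
   GAUSS (coverage 0.95) are fitted on the 30 training samples only.
   Sensitivity (% target test samples accepted) and specificity
   (% outlier test samples rejected) are computed per class at full
   precision; rounding to one decimal (half away from zero) happens only
   at report formatting, and the `Average` row averages the *unrounded*
   class values — so 17/18, 15/16, 17/18 average to 94.2, not to the
   average of the rounded cells.

## Choosing the kernel width

$\sigma$ spans a continuum from Parzen-like density estimation (small
$\sigma$: every point its own support vector) through a
mixture-of-Gaussians regime to the rigid hypersphere (large $\sigma$).
`widthScan()` documents this transition (SV counts, training rejections,
$R^2$, optional 2-D boundary grids). `autoSigma()` operationalizes the
"tightest boundary that still encloses the training set with a simple
edge" criterion deterministically, scanning a geometric grid anchored on
the training geometry (from below the average nearest-neighbour distance
to beyond the diameter) and picking the smallest width such that:

* **the edge is sparse** — at most 20% of training samples are support
  vectors. A boundary should be carried by a minority of the data; when
  almost every point is a support vector the "boundary" is a union of
  islands, and criteria like "all training samples accepted" hold
  vacuously;
* **the training centroid is accepted** — Kennard–Stone deliberately puts
  the most extreme samples into training, so a tight width around that
  shell can produce a hollow annulus;
* **training rejections are minimal** (zero when attainable — the soft
  margin often finds it profitable to leave a couple of extreme samples
  outside at every width, since $C = 1/(30 \cdot 0.1) = 1/3$).

These three conditions were chosen after the two obvious simpler rules
each failed a study condition: "smallest width accepting all training"
alone selects the island regime (near-zero test sensitivity), and without
the centroid condition exchangeable null data yields annulus boundaries.
A fixed width can always be supplied via `studyConfig(sigma = ...)`.

## The synthetic data generator

The measured spectra this design emulates are not publicly deposited, so
`simulateStudy()` generates labelled surrogates with the statistical
structure the analysis relies on:

* five shared Gaussian absorption bands at 4266, 4335 (C–H combination),
  5175 (water combination), 6930 (water/O–H first overtone) and
  ~8400 cm⁻¹ (C–H second overtone);
* brand identity as *amplitude ratios* of the shared bands — brands differ
  in constituent balance, not chemistry. A single `separation` factor
  scales the between-brand ratio offsets; `separation = 0` makes brands
  exchangeable (the sanity null), 1 is the default;
* per-sample nuisance: multiplicative scatter $U(0.7, 1.3)$, additive
  offset $U(0, 0.15)$ AU, baseline tilt $U(-0.002, 0.002)$ AU across the
  axis, white noise of sd 0.002 AU. Scatter and offset are removed exactly
  by SNV; tilt and noise are not, and together set the within-brand spread
  that survives preprocessing.

The nuisance magnitudes are a calibrated stand-in, not an estimate: no
within-/between-brand variance figures exist for the real data, so the
defaults were set once so that the default study is *well separated* —
brand clusters resolve cleanly in the two-component score space and a
tight SVDD boundary separates every brand (specificity 100% across seeds,
class-average sensitivity above 90%). An earlier, larger tilt
($\pm 0.01$ AU) made the within-brand clusters strongly anisotropic and
cost several sensitivity points to tail clipping; $\pm 0.002$ AU keeps the
tilt direction comparable to the other nuisance axes. Conclusions from
passing tests transfer to real spectra only to the extent that real
within-brand variation is similarly unimodal and SNV-removable; batch
substructure (modelled, off by default via `batchEffect`), instrument
drift and nonlinear detector effects are not represented.

All randomness flows through one explicit seed (`withSeed()`), leaving the
caller's RNG state untouched; every pipeline stage is deterministic given
the seed.

## Numerical choices

* SMO stopping rule: maximal KKT violation $< 10^{-10}$ (or $10^5$ pair
  updates). The tolerance sits two orders below the $10^{-9}$ acceptance
  guard (`distance² ≤ R² + 10^{-9}`) so that on-sphere support vectors
  classify consistently; with a looser $10^{-8}$ rule their scatter around
  the mean radius overflows the guard.
* Support-vector classification is float-safe: $\alpha < 10^{-10}C$ counts
  as zero, $\alpha > C(1 - 10^{-8})$ as bounded.
* If no unbounded SV exists, $R^2$ falls back to the maximum squared SV
  distance, with a warning.
* PCA loading signs are fixed (largest-magnitude entry positive) for
  cross-platform reproducibility.
* Degenerate inputs fail loudly and early: zero-variance spectra name the
  offending sample, singular covariances advise $\lambda > 0$ or the
  pseudoinverse, non-monotonic CSV wavenumber headers and non-numeric
  cells report the offending row.

## Problem sizes used by the test-suite

The suite exercises the solver against independent oracles (enumeration
of minimum enclosing balls, a generic interior-point QP, a ν-one-class-SVM
with matched kernel, numerical χ² CDF inversion) on instances of 5–30
points, the Gaussian coverage claim on 10,000 draws, and the full pipeline
on the 142 × 1557 synthetic study — sizes chosen so the whole suite runs
in a few minutes while every oracle comparison stays exact. Oracle
decision comparisons exclude a thin numerical tie band around each
solver's boundary, where unbounded support vectors sit exactly on the
sphere and each solver's own rounding decides the side.

## Known limitations

* The two-component projection is fixed by design; no criterion for the
  number of components is provided.
* Width selection is the deterministic grid heuristic above;
  cross-validation, bootstrapping and consistency-based selection are out
  of scope.
* GAUSS is strictly unimodal; no mixture extension.
* KNNDD stores its full training set and scores by pairwise distances —
  fine at $n = 30$, quadratic beyond.
* The generator makes no claim of radiative-transfer realism; it exists to
  give the pipeline data with the right *statistical* structure.
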