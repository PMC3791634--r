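---
title: "Methods: wavelet features, PCA reduction and a swarm-tuned kernel SVM"
author: "brainKSVM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet features, PCA reduction and a swarm-tuned kernel SVM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The classification problem

brainKSVM labels a single axial T2-weighted brain MR slice as *normal*
(-1) or *abnormal* (+1). The study design it supports is a small,
heavily imbalanced slice collection: 90 images of 256 × 256 pixels, 5
normal and 85 abnormal, evaluated by stratified 5-fold cross-validation
so that every fold holds exactly one normal and 17 abnormal slices
(360 training and 90 validation assignments across the five
experiments).

The pipeline has four stages:

1. **Wavelet features.** A decimated 2D discrete wavelet transform with
   the orthonormal Haar pair \(g = (1,1)/\sqrt2\), \(h = (1,-1)/\sqrt2\)
   is applied three times to the running approximation (LL) subband.
   The level-3 approximation block of a 256 × 256 image is 32 × 32;
   flattened row-major it gives a 1024-dimensional feature vector, a
   64-fold reduction from the 65536 raw pixels that keeps the
   low-frequency intensity structure a radiologist's eye also relies
   on.
2. **Standardization + PCA.** Features are centered and scaled to unit
   sample variance (denominator \(n-1\); zero-variance features are
   centered only) and rotated onto principal components; the smallest
   number of components whose cumulative explained-variance ratio
   reaches 0.95 is kept.
3. **Kernel SVM.** A soft-margin SVM with the radial basis function
   kernel \(k(x,z) = \exp(-\lVert x-z\rVert^2/\sigma^2)\) — note the
   \(\sigma^2\) denominator with no factor 2, so \(\gamma = 1/\sigma^2\)
   in libsvm terms — is trained by maximizing the dual
   \[\textstyle\sum_n \alpha_n - \tfrac12 \sum_{m,n}
     \alpha_m\alpha_n y_m y_n k(x_m,x_n),\qquad
     0 \le \alpha_n \le C,\ \sum_n \alpha_n y_n = 0,\]
   and predicts with \(f(x) = \sum_n \alpha_n y_n k(x_n,x) - b\)
   (ties at exactly 0 map to +1).
4. **Hyperparameter search.** A particle swarm maximizes the 5-fold
   cross-validation accuracy
   \(\tfrac1k\sum_i y_s^{(i)}/(y_s^{(i)}+y_m^{(i)})\) over the penalty
   C and kernel width σ; the final model is retrained on all data at
   the tuned (C\*, σ\*).

# The dual solver

The dual quadratic program is solved by sequential minimal optimization
(Platt's pairwise coordinate ascent) over a precomputed kernel matrix,
compiled in C++. Pair updates preserve the equality constraint exactly;
the working pair is chosen deterministically (largest \(|E_1-E_2|\)
among non-bound points, then fixed-order sweeps), so training is
reproducible. The KKT tolerance defaults to `tol = 1e-3`. The bias is
recovered by averaging \(s(x_n) - y_n\) over margin support vectors
(\(0 < \alpha_n < C\)); if every multiplier sits at a bound, the
midpoint of the KKT-feasible bias interval is used. Support vectors are
compacted at \(\alpha > 10^{-8} C\). When the kernel matrix is
(numerically) not positive semidefinite along a working pair
(\(\eta \le 0\)), the objective is evaluated at both segment ends, the
standard degenerate-step rule. In tests the solver's dual objective is
required to agree with an independent interior-point solver
(`kernlab::ipop`) to 1e-5 relative on 50-point problems, and `e1071`
(libsvm) serves as a second cross-check on predictions; both are
oracles only, never the implementation.

# The swarm search

Velocities and positions follow the canonical update
\(v \leftarrow w v + c_1 r_1 (p_{best}-p) + c_2 r_2 (g_{best}-p)\),
\(p \leftarrow p + v\), with fresh \(r_1, r_2 \sim U(0,1)\) per
particle, per dimension, per iteration (a single seeded RNG stream; the
draw order — full \(r_1\) matrix, then full \(r_2\) — is fixed and
covered by a bit-level trace test). "Best" means maximal fitness.
Defaults: 20 particles, 50 iterations, \(c_1 = c_2 = 1.49445\), and a
linearly decaying inertia weight from 0.9 to 0.4. The decaying schedule
(rather than a constant constriction weight) is the default because the
cross-validation fitness is piecewise constant — accuracy moves in
steps of 1/90 — producing broad plateaus and, on some datasets, a
deceptive basin whose best interior point lies on the search-box
boundary. Two further choices address that geometry:

* **Boundary handling:** positions are clamped to the box and the
  violating velocity component is *reflected with damping*
  (\(v \leftarrow -0.5 v\)). Zeroing the component instead turns a
  boundary-attracting surface into an absorbing state: we traced whole
  swarms collapsing onto the σ upper bound within five iterations and
  stagnating there for the rest of the run.
* **Ties:** a particle's personal best is updated on *equal* fitness
  too, so on plateaus it tracks the particle's latest position and the
  swarm keeps drifting instead of anchoring to its initial draws.

The search moves in \((\log C, \log\sigma)\) by default — the customary
scale for SVM hyperparameters, on which the useful range of σ occupies
a sensible fraction of the box; `searchScale = "linear"` reproduces a
uniform random-selection protocol on the raw intervals. The random
baseline (`randomSearch`, and the paired protocol in `compareSearch`)
always draws in the same space as the swarm so the comparison is
method-against-method at an equal evaluation budget.

## Search bounds

The default C interval is [50, 200]. The width σ is searched over
[0.25, 2] × the median pairwise Euclidean distance of the reduced
training features (the classic median heuristic; `sigmaScale =
"absolute"` disables the scaling). Anchoring σ to the data's distance
scale is essential here: after per-feature standardization and PCA the
typical inter-image distance is tens of units, and a fixed σ of order 1
would make the Gram matrix numerically an identity, collapsing the
classifier to the majority class. The lower factor 0.25 reaches the
regime where within-class kernel values stay \(O(10^{-1})\) while
cross-class values decay — at 0.5 × median the same-class kernel is
already \(e^{-4}\).

# Cross-validation protocol

`stratifiedKFold` shuffles each class independently and deals
round-robin, rotating the starting fold between classes, so fold sizes
differ by at most one overall and per class. By default the
standardization and PCA are refitted inside each fold on the training
portion only (`pcaScope = "per_fold"`), avoiding leakage of held-out
images into the feature space; `pcaScope = "global"` fits them once on
all data first, which mirrors a protocol in which feature reduction
precedes cross-validation. With equal fold sizes the mean of fold
accuracies equals the pooled accuracy — both identities are asserted in
tests. `evaluateSystem(..., repeats = R)` re-runs the whole k-fold
procedure R times with fresh fold plans and pools the held-out
predictions, so a 90-image, 5-repeat evaluation yields a 450-entry
confusion matrix; sensitivity is the true-positive rate on abnormal
(+1) and specificity the true-negative rate on normal (-1). A rate
whose reference class is absent is reported `NA`, not 0.

# The synthetic phantom generator

Real T2 slice collections of this kind are typically not
redistributable, so the package ships a seeded generator whose contract
is *statistical*, not anatomical: two image classes whose difference is
localized hyperintense structure, with controllable effect size.

A phantom is an elliptical "brain" (quadratic radial intensity profile
around 0.42 on a [0,1] scale, a bright rim, two dark ventricle shapes)
plus smooth low-frequency texture unique to each image and Gaussian
pixel noise; abnormal phantoms add 1–4 hard disks of radius 5–20 px at
+0.5 intensity, placed fully inside the brain mask. Defaults mirror
the study design (256 × 256, 5 normal / 85 abnormal, noise sd 0.05).
Two generator choices deserve explanation:

* **Texture amplitude** is U(0.001, 0.005) per wave — a per-image
  tissue inhomogeneity of a fraction of a percent, deliberately below
  the noise level. Lesions are, by definition, hyperintense *relative
  to* tissue variability; if the per-image texture rivals the smallest
  spec'd lesion (radius 5 px), the classes genuinely overlap and no
  classifier can separate them.
* **Noise is confined to the head.** Display-processed atlas slices
  have clean black air backgrounds. This matters quantitatively:
  air-background features carry noise-only variance, and the mandated
  unit-variance standardization amplifies each of them to unit scale,
  creating a between-image distance floor of order \(\sqrt{2d}\) that
  buries small-lesion energy. With a clean background those features
  are constant, the zero-variance guard leaves them unscaled, and they
  drop out of all distances.

What the phantoms do *not* emulate: inter-subject anatomical
variability (all brains share one geometry), partial-volume effects,
bias fields, Rician noise statistics, or any disease-specific
morphology such as atrophy or mass effect. A pipeline that passes on
phantoms has demonstrated its statistical machinery end to end — not
clinical validity on real MR data.

`lesionContrast = 0` produces an exact null: with zero noise the
"abnormal" image is bit-identical to its normal counterpart (lesion
placement draws still occur, after the noise draw, so the pixel
content is unchanged). The acceptance suite verifies that the tuned
pipeline's accuracy on the null stays within binomial noise of the
majority rate 85/90, and that mean accuracy is non-decreasing in
contrast over {0, 0.2, 0.5}.

# Numerical and design choices

* **Wavelet boundary:** odd-length axes are extended by one sample
  (edge replication for `"symmetric"`, wrap for `"periodic"`, zero
  padding for `"zero"`) before pairwise filtering, giving ceiling-halved
  subbands; reconstruction is exact for all three modes, and Parseval
  holds exactly on even sizes. Features are flattened row-major — the
  downstream rotation is order-invariant, but serialized models must be
  stable.
* **PCA:** computed by SVD of the centered matrix (not an explicit
  covariance eigendecomposition — safer at 1024 features ≫ 90
  samples); component signs are fixed by making each column's
  largest-magnitude loading positive. Explained-variance ratios are
  relative to the total variance, so they sum to 1 over the
  min(n−1, p) computable components.
* **Standardization example worth noting:** with the sample (n−1)
  convention the two-point feature (0, 2) standardizes to
  ±1/√2, not ±1.
* **Model files** are versioned JSON bundles written at 17 significant
  digits, so decision values survive a save/load round trip
  bit-exactly. Unknown fields under a compatible major version load
  with a warning; a different major version is an error.
* **Determinism:** a full `trainPipeline` run is a pure function of
  (data, config): the fold plan uses `seed`, the swarm `seed + 1`, and
  the SMO solver is deterministic.

# Problem sizes in the test suite

Unit tests run the wavelet stack up to 256 × 256 and the solvers on
problems of 30–60 points. The acceptance suite trains the full
pipeline on the default 90-phantom dataset at the recorded study seed
(dataset seed 1, config seed 1), repeats the contrast sweep over three
seeds at a 10 × 10 swarm budget, and runs the swarm-vs-random
comparison over 30 paired seeds at an equal budget of 300 evaluations
per arm (the default swarm size with a reduced iteration count); these
sizes keep the whole suite at a few minutes on one core while still
exercising every stage at full image resolution.

# Known limitations

* With only five normal images, specificity estimates rest on 5
  held-out normals per CV pass (25 per 5-repeat evaluation) and are
  accordingly noisy; the generator's `--balanced` option exists for
  studies of that effect.
* The cross-validation fitness is optimistically biased for the
  selected (C\*, σ\*) — the search maximizes it directly. Nested
  cross-validation would give an unbiased generalization estimate and
  is deliberately out of scope.
* The SMO solver targets problems of at most a few hundred points (the
  kernel matrix is dense); this matches the intended study size, not
  large-scale use.
* Only PNG, TIFF and plain-text rasters are read natively.
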