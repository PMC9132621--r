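---
title: "Pyramidal patch texture features with two-stage feature selection"
author: "pyratex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pyramidal patch texture features with two-stage feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

`pyratex` implements a handcrafted feature-engineering pipeline for binary
classification of ultrasound-like grayscale images, of the kind used for
automated fetal sex classification from transverse scans of the genital
region: a female fetus presents two to four parallel echogenic lines (the
labial folds), a male fetus a dome-shaped structure with a midline
echogenic streak. The pipeline turns that directional-versus-blob contrast
into a fixed-length feature vector and a shallow classifier:

1. **Standardization.** Every image is converted to single-channel
   luminance (ITU-R BT.601 weights) in $[0,1]$ and resampled to
   $256\times256$.
2. **Pyramidal decomposition.** Average pooling with block sides
   $2, 4, 8, 16$ produces levels of side $128, 64, 32, 16$; together with
   the original this is a five-level mean pyramid. Each pooled pixel is the
   exact arithmetic mean of its source block, so level $i{+}1$ can be
   derived from level $i$ (means of means over nested blocks compose).
3. **Fixed-size patch division.** Every level is tiled into non-overlapping
   $16\times16$ patches: $256 + 64 + 16 + 4 + 1 = 341$ patches per image.
   The tiling order is frozen — levels fine-to-coarse, row-major within a
   level — because downstream selected-feature indices are only meaningful
   under a fixed ordering.
4. **Hybrid per-patch descriptor.** Each patch yields a 256-bin local
   phase quantization (LPQ) histogram — a textural descriptor — followed by
   a 36-value histogram of oriented gradients (HOG) — a directional/shape
   descriptor; 292 values per patch, $341 \times 292 = 99{,}572$ per image.
5. **Two-stage selection (chi-square + iterative NCA).** A fast chi-square
   filter ranks all features and keeps the top 1000; neighborhood component
   analysis (NCA) weights those survivors; prefixes of the weight-sorted
   list over sizes 100–1000 are scored by 10-fold cross-validated 1-nearest
   neighbor misclassification, and the smallest prefix attaining the
   minimum is kept.
6. **Classification.** Five shallow families — k-nearest neighbor, linear
   discriminant, Gaussian naive Bayes, Gaussian-kernel SVM, decision
   tree — are tuned by Bayesian optimization (Gaussian-process surrogate,
   expected-improvement acquisition) of the 10-fold CV error and reported
   with confusion-matrix metrics, ROC curves and AUC.

## Descriptor details and conventions

**LPQ.** A short-term Fourier transform with a uniform $3\times3$ window is
evaluated at the four lowest non-zero frequency pairs
$\{(0,a),(a,0),(a,a),(a,-a)\}$, $a = 1/3$. Only the *valid* region is used
(no padding), so a $16\times16$ patch yields a $14\times14$ field of codes;
window contributions never cross a patch boundary, which also lets the
package evaluate whole levels in stacked band-matrix products and slice out
patch regions bit-identically. The eight real/imaginary coefficients are
whitened under an exponential spatial correlation model
($C_{ij} = \rho^{\lVert p_i - p_j\rVert}$, $\rho = 0.9$; a tiny fixed
diagonal jitter makes the eigenbasis deterministic under ties), then
sign-quantized ($\ge 0 \mapsto 1$) into an 8-bit code and histogrammed over
the 256 codes, normalized to sum 1. Because every filter has zero DC
response, the descriptor is exactly invariant to additive intensity
shifts; a constant patch produces a single-spike histogram.

**HOG.** Sobel gradients with symmetric border padding (the one-pixel pad
mirrors the edge pixel itself). The alternative reflection that omits the
edge pixel zeroes the cross-border derivative, and on $16\times16$ patches
that fabricates spurious axis-aligned orientations: oblique gratings lose
over 20% of their histogram mass to the 0°/90° bins, so the symmetric
convention is used. Orientations are unsigned ($[0°,180°)$, the standard
`atan2` convention; a printed formula with the argument ratio inverted
would merely rotate the bins by 90°, which is irrelevant after learning),
binned into 9 bins with linear interpolation between adjacent bin centers,
magnitude-weighted per $8\times8$ cell, and the single $2\times2$-cell
block is L2-Hys normalized (epsilon $10^{-12}$ in every denominator, clip
at 0.2, renormalize). A flat patch maps to the all-zero vector. This
cell/block/bin geometry is the unique common parameterization giving 36
values on a $16\times16$ patch and is frozen.

## Selector details

**Chi-square stage.** Continuous features are discretized into 10
equal-width bins over their observed range (a documented choice; the
statistic needs a contingency table and the filter must stay fast and
deterministic). Constant features score 0; cells with zero expected count
contribute nothing; score ties rank by ascending feature index.

**NCA stage.** Weights maximize the soft leave-one-out objective
$\sum_i p_i - \lambda \sum_r w_r^2$ with
$p_{ij} \propto \exp(-\sum_r w_r^2\,\lvert x_{ir}-x_{jr}\rvert)$, by
gradient ascent with backtracking step halving (max 200 iterations,
relative tolerance $10^{-6}$, $\lambda = 1/n$ by default). Features are
min-max scaled to $[0,1]$ per column first — NCA and Euclidean
nearest-neighbor are scale-sensitive, and the LPQ histogram mass
($\le 1$) and HOG block values live on different scales. Weights start
equal, scaled so the mean weighted pairwise distance is 1: a unit-weight
start over ~1000 columns puts every pairwise similarity at
$\exp(-d)$ with $d$ in the hundreds, which underflows to zero and leaves
the optimizer at a stationary dead point, so the scaled start is the
package's choice. The optimizer itself is deterministic; the seed argument
is recorded for provenance.

**Prefix sweep.** Squared Euclidean distances accumulate incrementally
over the weight-ordered columns, so the 901-point sweep costs a single
pass. The error functional is 1-nearest-neighbor with plain Euclidean
distance and no vote weighting under a seeded stratified 10-fold partition
(the parameter record of the reference procedure; a weighted-kNN variant
is available through the arguments). Argmin ties resolve to the smallest
prefix.

**Selection scope and leakage.** The reference procedure fits the selector
once on all data and then cross-validates classifiers on the selected
columns. That in-search error curve is optimistically biased as an
estimate of generalization: with $99{,}572$ candidate features and a few
dozen images, pure-noise data reaches apparent error 0. `cinca()`
therefore exposes `scope = "whole"` (the faithful default) and
`scope = "fold"`, which refits the entire selector inside each outer fold
and reports the leakage-free pooled held-out error alongside. The test
suite demonstrates both behaviors on noise, and the separability
monotonicity benchmark uses the fold-internal protocol, since under the
whole-data protocol the in-search accuracy is 1.0 at every separability
including 0.

## Classifiers and tuning

Reference defaults are reproduced verbatim: kNN $k = 70$, correlation
distance ($1 - $ Pearson correlation between feature vectors),
squared-inverse vote weights ($1/(d^2 + 10^{-12})$); linear discriminant
with $\gamma = 0$ (pooled covariance; $\gamma \in [0,1]$ blends toward a
spherical target, and a ridge engages with a warning only on singularity —
routine when more features than images survive selection); Gaussian
("normal kernel") naive Bayes with a variance-smoothing floor; SVM with
Gaussian kernel, box constraint 3 and kernel scale 5.6 (so
$\gamma_{\mathrm{rbf}} = 1/5.6^2$); decision tree with cross-entropy
("deviance") splits grown with permissive minimum node sizes
(`minsplit = 4`, `minbucket = 2`, suited to desk-scale sample sizes) and
post-pruned to at most 51 splits.

The tuner evaluates the family default first, then a seeded Latin
hypercube, then Gaussian-process/expected-improvement proposals (squared
exponential kernel on $[0,1]$-encoded coordinates, length-scale 0.25,
nugget $10^{-6}\sigma^2$). Plain expected improvement replaces
time-per-iteration acquisition variants, which are hardware-dependent and
not reproducible. Fully discrete spaces whose cardinality fits the budget
are enumerated exhaustively, and proposals never repeat a configuration.
One seeded fold partition is shared by all evaluations within a tuning run
(configurations are compared on identical folds); final reported metrics
use a fresh partition. Default search spaces: kNN $k \in [1,100]$ plus the
distance metric; SVM box constraint and kernel scale log-scaled over
$[10^{-2},10^{3}]$ and $[10^{-2},10^{2}]$; tree max splits $[2,200]$;
LD $\gamma \in [0,1]$; NB variance smoothing log-scaled over
$[10^{-12},10^{-1}]$. The default budget is 20 evaluations per family for
desk-scale runs; the full reference schedule of 100 is one argument away.

## The synthetic benchmark

The clinical dataset the method was designed for is private, so the
package ships a seeded generator of two-phenotype speckled images that
stands in for it everywhere: class `"female"` draws 2–4 bright parallel
curvilinear bands with random orientation, spacing and curvature; class
`"male"` a dome-shaped blob with a midline streak. Both share a smooth
low-frequency background with a mild vertical gain ramp, get a mild
Gaussian blur, and are multiplied by unit-mean gamma speckle
(`looks = 4`, the fully-developed-speckle model; variance $1/\text{looks}$).
Structure amplitude scales linearly with `separability` — at 0 the classes
are identically distributed by construction, at the default 0.7 the
benchmark of 60 images per class is cleanly separable. What the generator
does *not* model: beamforming, attenuation, acoustic shadowing, probe
geometry, anatomical variation beyond the two phenotypes, operator
variability. Passing the end-to-end benchmark therefore shows that the
pipeline recovers a known directional-vs-textural contrast under speckle —
it does not certify clinical performance, and the reference accuracies
(99.11% kNN and so on) are bound to the private data and are not
reproduced here.

Problem sizes used by the shipped checks, chosen as desk-scale defaults:
the recovery benchmark runs 60 images per class at separability 0.7 with
tuning budget 20; the separability sweep $\{0, 0.35, 0.7, 1\}$ runs 20
images per class with 5-fold fold-internal selection, three seeds
averaged.

## Degenerate inputs and numerical guards

Empty manifests, unreadable images, non-finite features, single-class
labels, k larger than the smallest training fold, selector ranges out of
order, and tuning budgets below 5 all fail loudly with specific errors.
Zero-variance normalization guards: min-max scaling maps constant columns
to 0; HOG and L2-Hys use $10^{-12}$ epsilons; naive Bayes adds its
variance floor; LD warns and ridges. Ties break deterministically
everywhere (ascending feature index, smallest prefix, first fold).

## Known limitations

Binary classification only; no DICOM or scanner metadata; no
anatomy-detection/zoom step (inputs are assumed already cropped to the
region of interest); no leakage-free variant of the *classifier* stage
beyond its seeded cross-validation (the fold-internal selector mode covers
the selection stage); the GP surrogate uses a fixed length-scale rather
than marginal-likelihood optimization, which is adequate for the small
budgets used here.
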