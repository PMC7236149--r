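---
title: "Activity landscape imaging and topology classification with altopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity landscape imaging and topology classification with altopo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A three-dimensional activity landscape (3D AL) visualizes the
structure-activity relationships (SARs) of a compound activity class:
chemical space, described by binary substructure fingerprints, is
projected onto a plane; compound potency (pKi) is added as the third
dimension; and a coherent potency hyper-surface is interpolated between
the measured compounds. Landscape *topology* then mirrors SAR
character: in smooth regions, gradual structural change comes with
moderate potency change (SAR continuity); in rugged regions, small
structural changes cause large potency swings (SAR discontinuity),
culminating in activity cliffs — pairs of highly similar compounds with
a large potency difference. Most real classes are heterogeneous,
mixing both.

`altopo` implements the full image-analysis route to classifying that
topology: landscape construction, reference-landscape derivation,
standardized multi-view rendering, reduced-information image variants,
and CNN / SVM / random-forest classifiers evaluated under class-disjoint
splits.

## Landscape construction

**Similarity.** Compounds are fixed-length binary fingerprints (1024
bits by default; any consistent fingerprint works, and
`circular_fingerprint()` offers a hashed circular fallback for SMILES
input). Pair similarity is the Tanimoto coefficient
`Tc = |A∩B| / (|A| + |B| − |A∩B|)`; the embedding distance is `1 − Tc`.
Classes are first cleaned with `similarity_filter()`: a compound is
kept only if its similarity to at least one classmate is ≥ 0.4, which
removes structural singletons that carry no SAR information. Because
neighbor relations are mutual, one pass suffices and the filter is
idempotent.

**Projection.** Two embeddings are provided. `mds_project()` is metric
multidimensional scaling by SMACOF stress majorization — the Guttman
transform guarantees a monotonically non-increasing stress, iterations
stop on a 1e-6 relative decrease (cap 300), and 4 seeded random
restarts keep the best configuration. `neuroscale_project()` is a
parametric alternative: a radial basis function network maps
fingerprints to the plane while minimizing the same normalized Kruskal
stress. Centers come from k-medoids on the Tanimoto distance matrix,
the bandwidth is the median center-center distance, activations are
Gaussian in Tanimoto distance (keeping a single metric throughout),
and the linear output map is initialized by least squares onto an MDS
solution and refined by BFGS with the analytic stress gradient. The
number of centers is selected by sevenfold cross-validation over a
candidate grid (default {5, 10, 20, 40} capped at n/2); held-out
stress is computed over all pairs that involve a held-out compound.
Since embeddings are defined only up to isometry, `canonical_orient()`
fixes the frame (centroid at the origin, principal axes, reflections
resolved by the sign of the coordinate skewness) so that azimuth
angles are comparable across landscapes.

**Surface.** `gpr_fit()` interpolates potency by Gaussian process
regression with a squared-exponential kernel plus white noise. The
prior mean is the mean potency; hyperparameters maximize the log
marginal likelihood (L-BFGS-B on log scale, 3 seeded restarts) inside
bounds tied to the data scale (signal variance within 1e-4–100 times
the potency variance, length scale within 1/20–20 times the median
pair distance, noise within [1e-6, 4] pKi²). The lower noise bound
doubles as jitter; if a kernel matrix is still not positive definite,
jitter escalates by decades before failing. `gpr_surface()` evaluates
the posterior mean on a regular grid (default 100 × 100) spanning the
embedding bounding box padded by 5%.

**Color.** Potency is color-coded green → yellow → red with fixed
anchors: pKi ≤ 5.75 is pure green, pKi ≥ 8.75 pure red. The default
reads the scale as a continuous piecewise-linear gradient with yellow
at the 7.25 midpoint; a flat-yellow-band alternative
(`potency_colormap(style = "band")`) is available because the interior
range can also be read as uniformly yellow. The gradient is the
default since only it makes top-down (heatmap) views informative.

## Reference landscapes

For every class two potency-based selections exaggerate one SAR
phenotype each, giving three labeled variants per class:

* **heterogeneous** — the original (filtered) class;
* **smooth** (`smooth_reference()`) — compounds inside the closed
  interquartile interval [q1, q3] of the potency distribution
  (quantiles by linear interpolation, the "type 7" rule; boundary ties
  included). Compressing the potency spread suppresses cliffs; about
  half of the compounds survive;
* **rugged** (`rugged_reference()`) — compounds sorted by potency
  (ties broken by id), split into 7 equal-count bins (remainder to the
  earliest bins), keeping bins 1, 3, 5, 7. The alternating gaps plant
  large potency differences between structural neighbors while
  retaining the original potency range; exactly 4n/7 compounds survive
  when n is divisible by 7. Equal-count binning (rather than
  potency-value boundaries) makes the 4/7 fraction exact and the
  selection deterministic under ties.

## Imaging

`render_landscape()` draws the surface off-screen with the base
perspective renderer: white background, no axes or box, facets colored
by potency, 1200 × 800 pixels by default, viewpoints from the azimuth
grid {0°, 90°, 180°, 270°} × elevation grid {0°, 35°, 65°, 90°}
(elevation 0 is a pure profile — altitude only; elevation 90 a
top-down heatmap — color only). Rendering is deterministic:
identical inputs give identical pixels.

Images are cropped and resized to 360 × 220 (bilinear, aspect not
preserved), converted to variants, and flattened. The variant ladder
successively removes information: `color` → `grayscale`
(0.299 R + 0.587 G + 0.114 B) → `bw` (Otsu's threshold on a 256-level
histogram; on a tie plateau — e.g. exactly bimodal images — the
plateau midpoint is used so the threshold separates the modes) →
`sobel` (the vertical Sobel matrix [-1,-2,-1; 0,0,0; 1,2,1], absolute
response, edge-replicated borders) and `canny` (Gaussian smoothing
with replicate padding, Sobel gradients, non-maximum suppression with
an asymmetric tie-break that keeps symmetric step edges one pixel
wide, and 100/200 double-threshold hysteresis via connected
components). `normalize_and_flatten()` produces the row-major feature
vector; at the standard resolution every image yields exactly
220 × 360 = 79,200 features.

**Cropping is fixed, not content-adaptive, inside collections.** The
generic `crop_resize()` defaults to the content bounding box (padded
2%), which is the right behavior for a single image. For *collections*
used in classification, `render_collection()` instead applies one
fixed fractional crop (8%–92%) to every image: an adaptive crop would
stretch a flat smooth landscape seen in profile to full frame,
erasing the very relief difference the classifiers must learn (we
measured the inversion: with adaptive cropping, smooth variants showed
*more* edge content than rugged ones). For the same reason, the three
variants of one class share a potency axis range (`zlim`, the range of
the original class) when rendered.

## Classification protocol

Class splits are the outermost protection against leakage:
`split_classes()` assigns half of the activity classes to training and
half to testing, so every image of a test class is unseen.

* **CNN** (`train_cnn()`): three convolutional blocks (3 × 3 filters,
  leaky ReLU, 2 × 2 max-pooling, dropout), two dense layers, softmax
  over the three topology labels; categorical cross-entropy, Adam,
  batch size 32, early stopping (patience 5) on an internal 80/20
  validation split of the training images. When image class groups are
  supplied the internal split is group-disjoint, mirroring the outer
  protocol — with 4 azimuth views per landscape an image-level split
  would leak views across the split and early stopping would reward
  memorization. Hyperparameters (leaky-ReLU slope, dropout, dense
  sizes, learning rate from the grid including deliberately extreme
  values) are searched under a configurable budget; settings whose
  validation loss turns non-finite are scored as failed and skipped,
  and a setting whose validation accuracy remains at chance is treated
  as not converged and retried from up to two further derived
  initializations (judged on validation data only). The winner is
  refit on all training images for its best epoch count. The engine is implemented in R with im2col convolutions and
  BLAS matrix products; inputs are globally mean-centered (the frames
  are mostly white, and centering stabilizes optimization). The
  reference architecture (32/64/128 filters on 220 × 360 input,
  `cnn_config_full()`) is built and shape-checked in the tests; the
  training default is a scaled profile (8/16/32 filters on 55 × 90
  input) sized for single-CPU runs.
* **SVM** (`train_svm()`): one-against-one soft-margin machines on the
  standardized 79,200-feature vectors, grid over cost
  {0.01, 0.1, 1} × kernel {linear, polynomial, radial} by seeded
  tenfold cross-validation, refit with Platt probability calibration.
  As with the CNN, supplying image class groups makes the CV folds
  group-disjoint (fold count capped at the group count); with
  image-level folds the CV estimate leaks azimuth views of the same
  landscape and systematically prefers kernels that memorize rather
  than generalize (we measured a ~0.15 test-accuracy gap between the
  two fold designs). All kernels are precomputed from one BLAS Gram product
  (1/p-normalized for conditioning; the RBF bandwidth is the
  1/(n features × mean variance) heuristic) because per-pair kernel
  evaluation inside the solver is two orders of magnitude slower at
  this dimensionality.
* **Random forest** (`train_rf()`): grid over {50, 100} trees ×
  minimum split size {2, 5} × minimum leaf size {1, 3} (the two node
  controls map onto the implementation's terminal node size as
  `max(min_leaf, floor(min_split / 2))`), tenfold cross-validation,
  probabilities as tree vote fractions.

`evaluation_report()` computes subset accuracy (exact-match mean),
support-weighted F1, the Gorodkin multiclass Matthews correlation, the
confusion matrix, and one-vs-rest ROC AUC with midrank ties plus the
micro average over all pooled (sample, class) decisions.
`aggregate_trials()` reports mean ± sample standard deviation over
independent trials and the per-cell mean confusion matrix.
`run_experiment()` orchestrates everything with per-stage seeds derived
deterministically from one master seed.

## Synthetic data

`generate_activity_class()` emulates a target-based activity class
without any external data: cluster prototypes are sampled at 10% bit
density; members apply independent 1% per-bit flips (keeping
within-cluster Tanimoto similarity around 0.6–0.8, comfortably above
the 0.4 filter); each cluster sits at a latent 2D coordinate. Potency
follows the planted topology: *smooth* classes put clusters on a
linear potency ramp across the latent space (the simplest construction
that guarantees continuity) plus N(0, 0.2 pKi) noise; *rugged* classes
split every cluster into two modes 2.5 pKi apart — and also flip 12
prototype bits in the high mode, because modes with *identical*
prototypes would co-locate in the embedding and the surface would
average the cliff away rather than display it; *heterogeneous* classes
apply the smooth rule to half of the clusters and the cliff rule to
the rest. Defaults (150 compounds, 6 clusters, pKi 5–10) describe a
mid-sized class consistent with the potency anchors of the color
scale; all sizes are parameters.

What the generator does *not* emulate: real chemistry (no valid
molecules), fingerprint bit correlations, class imbalance, assay
noise structure, or the size of curated public classes (hundreds to
thousands of compounds — available via the parameters but not the
default). Passing tests on synthetic classes therefore demonstrates
that the machinery detects planted SAR structure, not that it
reproduces results on any particular public data set.
`generate_surface_fixture()` provides analytic Gaussian-bump surfaces
for exercising the imaging stages with exactly known topology, and
`planted_cliff_count()` verifies cliff structure with the standard
(Tc ≥ 0.6, ΔpKi ≥ 2) pair criterion.

## Numerical choices and degenerate inputs

* Quantiles: linear interpolation between order statistics throughout.
* SMACOF: raw-stress convergence at 1e-6 relative decrease; the stress
  trace is exposed and asserted monotone in the tests.
* GP: Cholesky solves with escalating jitter; constant-potency classes
  yield constant surfaces by construction.
* Otsu on constant images: no separation exists; all pixels map to 0
  and the constant level is reported.
* Sobel responses below 1e-10 are zeroed (floating-point residue on
  flat regions would otherwise rescale to spurious full-intensity
  edges).
* Ties: argmax label prediction breaks toward the earlier label in
  (heterogeneous, rugged, smooth); rugged-reference binning breaks
  potency ties by compound id; Otsu plateau ties take the midpoint.
* Degenerate embeddings (all points identical) are returned unchanged
  with a warning by `canonical_orient()`.

## Problem sizes in the tests and acceptance script

The test suite and `scripts/acceptance.R` run the full pipeline at
sizes chosen for a single CPU: synthetic classes of 24–150 compounds,
surface grids of 24–48 nodes, renders of 120 × 80 to 600 × 400 pixels
for counting and training runs (collection counting is
resolution-independent; a native 1200 × 800 render verifies the
79,200-feature contract), 12-class experiments with 5 trials, and the
scaled CNN profile. The full-scale settings (38 classes, 10 trials,
full hyperparameter grids, native resolution, `cnn_config_full()`)
are reachable through the same configuration objects.

## Known limitations

* The CNN engine is plain R; it is sized for the desk-scale profile,
  not for GPU-scale training of the full 32/64/128 architecture.
* Neuroscale training uses direct stress-gradient descent on the
  composed map; the classic shadow-targets algorithm is not
  implemented (the contract — RBF map minimizing embedding stress with
  CV-selected center count — is the same).
* Rendering style is fixed (no lighting, no anti-aliasing control
  beyond the device defaults); determinism is only guaranteed within
  one graphics device implementation.
* ORB/Harris interest-point filters and GP posterior-variance
  visualization are out of scope.
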