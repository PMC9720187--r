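---
title: "Surface-based grid-searchlight MVPA: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-based grid-searchlight MVPA: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surflight)
```

## The problem

Multivariate pattern analysis (MVPA) asks where in the brain the *pattern*
of activity across nearby measurement sites carries information about an
experimental condition, rather than whether any single site responds more
strongly. A searchlight analysis repeats a decoding test in a small
neighborhood around every location, producing an information map. On the
cortical surface, searchlights respect cortical topology: two banks of a
sulcus that are millimeters apart in the volume but centimeters apart along
the sheet are never mixed into one neighborhood.

surflight implements a surface searchlight whose neighborhoods are **grids
of angular cells on the sphere**. All computations happen in the spherical
registration space in which individual cortices have been aligned to a
common template (one sphere per hemisphere, analyzed independently). Grid
searchlights have a practical advantage over geodesic disks: each one is a
small square image, so image classifiers (including convolutional networks)
apply directly.

## Templates: geodesic spheres and downsampling

The template sphere is a geodesic subdivision of the icosahedron
(`subdivide()`): each of the 30 edges is divided into $n$ equal parts,
each face is triangulated into $n^2$ subfaces, and all points are projected
to the unit sphere, giving $10n^2 + 2$ vertices, $30n^2$ edges and $20n^2$
faces. The standard high-resolution cortical template corresponds to
$n = 128$ (163,842 vertices per hemisphere). Running one decoding analysis
per high-resolution vertex would mostly recompute the same neighborhoods,
so searchlight *centers* live on a coarser sphere, $n = 40$ (16,002
vertices), and every high-resolution vertex is grouped to its nearest
coarse vertex (`nearest_assignment()`). Pattern data remain at full
resolution; only the set of searchlight centers is downsampled. With the
two spheres' resolutions of roughly 0.9 mm and 1.9 mm, the coarse grid is
still finer than typical functional resolution, so little spatial accuracy
is lost.

The subdivision is constructed combinatorially — base vertices first, then
edge points keyed by the (sorted) edge they lie on, then face-interior
points — so shared points are identified exactly, vertex order is
deterministic, and two builds are bit-identical. Nearest-vertex grouping
breaks exact ties (frequent on these highly symmetric meshes) by the lowest
candidate index, with a $10^{-9}$ tolerance so floating-point noise cannot
flip a tie.

## The grid searchlight

For a searchlight centered at vertex $p$ with spherical coordinates
$(\alpha, \beta)$, the sphere is rotated so that $p$ lands at the origin
$(0, 0)$ — the Cartesian point $(1,0,0)$ — by
$R = R_y(\beta)\,R_z(-\alpha)$ (`rotation_to_origin()`). In the rotated
frame the local metric is Euclidean to first order, and high-resolution
vertices are binned into an $n_1 \times n_1$ grid of square angular cells:
a vertex at rotated coordinates $(a, b)$ falls into cell
$(\lfloor a/c + n_1/2 \rfloor, \lfloor b/c + n_1/2 \rfloor)$, where $c$ is
the cell size. Defaults are $c = 1/35$ rad and $n_1 = 11$: on a 100 mm
sphere the searchlight radius is $100 \times \tfrac{1}{35} \times
\tfrac{11}{2} \approx 15.7$ mm (`searchlight_radius()`).

Conventions the construction pins down (the underlying geometry leaves them
open, so they are documented and fixed for reproducibility):

* **Spherical coordinates**: longitude $\alpha = \mathrm{atan2}(y, x)$,
  latitude $\beta = \arcsin(z)$.
* **Roll**: $R_y R_z$ maps $p$ to the origin with zero in-plane rotation;
  any roll would permute cell assignments near cell boundaries.
* **Axis order**: longitude indexes grid rows, latitude columns; flattening
  is row-major.
* **Mask boundary**: the circular mask keeps cells whose center is within
  $n_1/2$ cell units of the grid center, boundary cells included
  (`circular_mask()`; 97 of 121 cells for $n_1 = 11$).
* **Empty cells**: cells with no member vertex contribute 0, the same value
  as masked-out cells.

Per trial, the BOLD values of the vertices in each kept cell are averaged,
yielding an $n_1 \times n_1$ image (`searchlight_image()`); the SVM stream
flattens it to a 121-vector (`flatten()`). The full layout — per
coarse vertex: its coordinate, the $n_1^2$ cell membership lists, the
high-resolution vertices it owns, and its mesh neighbors ($n_1^2 + 3 = 124$
fields) — is built once per template and grid (`build_layout()`) and cached
under a stem encoding the parameters (`35_11` for the defaults). Own-member
lists are carried for reporting; decoding uses only the cells and the
adjacency.

## Trials and decoding

Trial patterns are single volumes sampled at a fixed latency after stimulus
onset: volume $\mathrm{round}((\text{onset} + t)/\mathrm{TR})$, with R's
round-half-to-even resolving sub-TR ambiguity (`extract_trials()`). There
is no hemodynamic model fitting; the latency (e.g. 7 s, around the
hemodynamic peak) is the user's choice. Condition code 0 is reserved for
baseline and excluded from decoding.

Decoding uses leave-one-run-out cross-validation (`loro_folds()`): each
run serves once as the test set. Fold accuracies are averaged with equal
weight per fold. The default classifier is a linear support vector machine
(`svm_decode()`, regularization constant 1, one-vs-one for multiclass, no
feature standardization — cell means enter raw). Columns that are
identically zero (masked or empty cells) are dropped before the fit, which
provably does not change a linear-kernel solution. The alternative CNN
stream (`cnn_decode()`) trains a compact network — one
$3\times3$ convolution with 8 maps and output-preserving padding, ReLU,
$2\times2$ max pooling, a fully connected layer with one unit per class,
softmax — full-batch with Adam (150 epochs, learning rate 0.01, fixed
initialization seed). These training choices are deliberately simple; the
CNN stream is provided for completeness and exposed as configuration, and
is not expected to beat the SVM at small trial counts.

Contrasts are strings: `"1 vs 4"` (two classes), `"2 3 vs 1 4"` (pooled
superclasses), `"0 1 2 3 4"` (one class per code). Chance is $1/k$ for $k$
(super)classes.

## Group inference

Per vertex, subject accuracies are tested against chance with a one-sample,
one-tailed t-test (`group_ttest()`). Vertices where every subject has the
same accuracy get $t = \pm\infty$ (or 0) — a convention, not an error,
because noise-free synthetic data saturate accuracy at 1. The map is
thresholded at a vertex-wise $-\log_{10}(p)$ level (default 3, i.e.
one-tailed $p < 0.001$), and suprathreshold vertices are grouped into
connected clusters under mesh-edge adjacency (`find_clusters()`, an
explicit-stack depth-first traversal equivalent to the recursive grouping
description but immune to recursion limits).

Cluster-level family-wise error is controlled with a max-cluster-size
permutation null (`signflip_null()`): per permutation, signs are flipped at
random, the flipped map is re-thresholded with the same one-tailed rule,
and the largest cluster size is recorded. The maxima are sorted descending;
with $N$ permutations and level $\alpha$ the size threshold is the
$\mathrm{round}(\alpha N)$-th largest maximum (the 20th of 2,000 for the
defaults), and only clusters **strictly larger** survive
(`fwe_filter()`). Null cluster sizes are measured in vertex counts;
reported cluster sizes can additionally be expressed in mm² when per-vertex
areas are supplied (`vertex_areas()`).

### Two sign-flipping modes, and when each is valid

`signflip_null()` implements two permutation schemes:

* `method = "tmap"` (default): the sign of each **vertex's t value** is
  flipped independently. This is the literal max-cluster recipe on the
  statistic map itself.
* `method = "subject"`: each **subject's** accuracy-minus-chance map is
  flipped as a whole and the t-map recomputed. This is the standard
  subject-level sign-flip test, exact whenever subject effects are
  symmetrically distributed under the null.

The two are not interchangeable, and the package's own calibration
experiments (in the test suite) quantify the difference. Per-vertex t
flipping treats vertices as exchangeable and spatially independent: under a
global null with spatially independent maps it controls FWE (empirically
conservatively, because small integer cluster sizes produce heavy ties
against the strict-inequality rule). But real searchlight maps are
spatially smooth — neighboring searchlights share most of their member
vertices — and independent vertex flips destroy that smoothness, making
the literal null *anti-conservative* on smooth maps (empirical FWE ≈ 0.3
at nominal 0.05 in our calibration at 162 vertices). Subject-level
flipping preserves each map's spatial structure and is calibrated in both
regimes (empirical FWE 0.025–0.04 at nominal 0.05).

A second, distinct scale effect matters on small templates: with per-vertex
flipping the observed signal cluster re-enters its own null with
probability $\ge (1/2)^{s}$ for a cluster of $s$ vertices. At full scale
($s$ in the hundreds) this is negligible; on a 162-vertex test sphere a
6-vertex true cluster re-appears in $\approx 1.6\%$ of permutations, which
already exceeds $\alpha = 0.01$ — the observed cluster can then *never*
survive the strict-inequality rule. For both reasons the package's
end-to-end recovery tests run group inference with `method = "subject"`,
while `"tmap"` remains the default of `signflip_null()` and
`run_pipeline()` as the method's literal form. Users working at reduced
template resolutions should prefer `method = "subject"`.

All permutation draws come from R's default generator under a caller-set
seed recorded in the output manifest; identical seeds give bit-identical
null distributions.

## The synthetic-data generator

`simulate_subject()` / `simulate_dataset()` generate ground-truth datasets:
per run, a paradigm of balanced, randomly ordered trials at fixed onsets,
and a vertex-wise time series of i.i.d. Gaussian noise in which the sampled
volume of each trial additionally carries a condition-specific pattern on
the vertices within a fixed angular radius of a chosen patch center.
Per-condition patterns are drawn once per subject (patterns are
subject-specific; only their decodability is shared across subjects —
the standard MVPA assumption). The pattern amplitude is
`effect_size * noise_sd`; with `noise_sd = 0` it is `effect_size` itself,
so noise-free separable datasets remain constructible.

Default configuration (used by the acceptance suite): `high_div = 16`
(2,562 vertices), `low_div = 4` (162 vertices), 8 subjects, 3 runs,
2 conditions, 10 trials per condition per run, TR 1 s, sampling latency
7 s, patch radius 0.25 rad (≈ 25 mm on a 100 mm sphere — a realistic
several-centimeter cortical territory), effect size 1.5, onset spacing
12 s. These sizes keep a full 40-dataset recovery-and-specificity
experiment within minutes while leaving the patch large enough to cover
several searchlight centers.

What the generator deliberately does **not** emulate: hemodynamic
convolution (the method reads one post-onset volume, so HRF shape is
orthogonal to everything under test), temporally autocorrelated or
spatially correlated noise, motion artifacts, and realistic (folded)
cortical geometry. Passing tests therefore demonstrate the correctness of
the geometry, decoding and inference machinery and the statistical
calibration under the stated noise model — not performance on real fMRI.

## Numerical and degenerate-input choices

* Subdivision, grouping, layout building, decoding and permutation are all
  deterministic given their seeds; parallel per-subject decoding reduces in
  a fixed subject order, so results are identical for any worker count.
* Vertices falling outside the grid after rotation are discarded (they are
  ≥ 80° away and cannot be neighborhood members).
* Layout files are versioned; loading validates structure and fails with a
  format error on truncation or foreign content.
* A training fold whose labels collapse to one class raises a
  degenerate-design error rather than silently predicting the majority.
* `fwe_alpha * n_perm < 1` is rejected (the rank would be 0).

## Problem sizes used by the test suite

Unit tests run on 642/42-vertex sphere pairs; oracle suites (cluster
finding vs union-find, grouping vs exhaustive search) use 1,000 random maps
on a 162-vertex sphere; the end-to-end recovery experiment uses the default
generator configuration above with 500 permutations and 20 seeds per
condition; the layout-structure check builds the full 16,002-record layout
against a reduced (10,242-vertex) pattern sphere. The full 128/40
construction is exercised only for vertex counts, which is what it pins
down.

## Known limitations

* Index-level compatibility with externally produced template spheres is
  not claimed; an external sphere file can be read (`read_freesurfer_surface()`)
  and used as the high-resolution template with its vertex order preserved.
* Only ASCII-encoded GIFTI files are read/written.
* The CNN stream's training protocol is minimal by design.
* No geodesic-disk searchlights; the grid searchlight is the method here.
* Preprocessing (motion correction, registration, smoothing) is upstream
  territory and out of scope; inputs are assumed aligned to the template.
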