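---
title: "Quantifying collective spheroid invasion and leader/follower expression differences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying collective spheroid invasion and leader/follower expression differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sagakit)
```

# Background

Collectively invading cancer cell packs are phenotypically heterogeneous:
a *leader* cell sits at the tip of each invasive chain with trailing,
less-invasive *follower* cells. Three computational problems arise in
studying them, and this package addresses each:

1. **Imaging** — quantify invasion of a 3D spheroid from 4D `(t, z, y, x)`
   time-lapse stacks: area, invasive radius, invasive area, branch number
   and circularity per frame.
2. **Tracking** — quantify invasive-chain dynamics from `(x, y)` tracks:
   path length, displacement, velocity, and their change around a
   leader-detachment event.
3. **Expression** — find genes differentially expressed between purified
   leader and follower populations while screening out expression
   changes caused by the photoconversion step used to isolate the cells
   (the populations are selected by photoconverting cells of interest
   and sorting them, so a photoconverted vs non-photoconverted control
   contrast calibrates that artifact).

Everything is testable end to end because the package ships generators
for all three data types with recorded ground truth.

# The imaging pipeline

`feature_timecourse()` composes five stages; each is exported
separately.

## Standard-deviation z-projection

A cell spans several focal planes with varying intensity, while
background is flat across z. Projecting each `(t, y, x)` column to its
sample standard deviation over z (divisor `n - 1`; `std_project()`)
therefore enhances dim invasive branches far better than a mean or
maximum projection: a noiseless background column projects to exactly
zero. The projection is order-invariant in z and non-negative.

## Smoothing

Isotropic separable Gaussian over `(t, y, x)` with replicate padding and
kernel half-width `ceiling(3*sigma)` (`smooth_series()`). Default
`sigma = 1` px: enough to suppress speckle from the projected noise
(whose z-std is chi-distributed, hence skewed) without displacing the
half-maximum boundary of structures wider than ~3 px. `sigma = 0` is the
identity.

## Segmentation

The primary method (`segment_series(method = "graphcut")`) minimizes a
two-label Markov-random-field energy over the 6-connected `(t, y, x)`
lattice:

$$E(L) = \sum_i D_i(L_i) \;+\; \lambda \sum_{(i,j)}
  e^{-(I_i - I_j)^2 / 2\beta^2}\,[L_i \neq L_j]$$

* **Unary terms** $D_i$ are negative Gaussian log-likelihoods of a
  two-class intensity model fitted to a global bimodal-threshold
  initialization. The two classes share a pooled variance: with
  unequal variances the likelihood crossover drifts toward the tighter
  class, which systematically inflates (or deflates) every object by a
  fraction of a pixel; with a shared variance the crossover sits at the
  class-mean midpoint, i.e. at the half-maximum boundary.
* **Pairwise terms** are contrast-sensitive Potts weights; `beta`
  defaults to the root-mean-square neighbour difference of the image so
  that true edges are cheap to cut and flat regions are expensive. The
  temporal edges regularize the segmentation across frames.
* The energy is minimized exactly by an s-t minimum cut, computed by a
  compiled Dinic max-flow (`src/maxflow.cpp`); a full
  `8 x 192 x 192` series solves in well under a second.

The **threshold method** is the global bimodal threshold alone. The
histogram Otsu value is refined by Ridler–Calvard intermeans iterations
(`otsu_threshold()`): with very unbalanced class masses, plain Otsu can
sit far from the midpoint between modes, cutting a blurred edge well
below half-maximum. On well-separated bimodal images graph cut and
threshold agree (Dice ≥ 0.99 in the test suite); the threshold method
therefore serves as an independent oracle for the graph cut. Constant
(unimodal) images yield an all-background mask plus a warning rather
than a spurious segmentation.

## Polishing

Per frame (`polish_masks()`): morphological closing (disk, default
radius 2 px), hole filling, then retention of a single connected
component — the one overlapping the component retained in the previous
frame (first frame: the largest; ties: larger area, then centroid
closest to the image centre). This tracks one spheroid through time and
removes specks.

## Features

Per frame (`compute_features()`), with 0-based pixel coordinates:

| feature | definition | default parameters |
|---|---|---|
| `area` | foreground pixel count (px²) | — |
| `centroid` | mean of foreground pixel coordinates | — |
| `perimeter` | boundary-chain length, diagonal steps weighted √2 | — |
| `invasive_radius` | max Euclidean distance centroid → boundary pixel | — |
| `core_area` | area of the morphological opening | opening radius 8 px |
| `invasive_area` | `area - core_area` | — |
| `branch_count` | skeleton endpoints with branch length ≥ prune length | prune 3 px |
| `circularity` | `4*pi*area / perimeter^2` | — |

Notes on the less obvious choices:

* The **core** of a spheroid (against which invasive outgrowth is
  measured) is historically traced by hand; here it is automated as the
  morphological opening with a disk whose radius (default 8 px) exceeds
  the half-width of any branch, so the opening removes the branches and
  keeps the core. `invasive_area + core_area = area` holds exactly by
  construction.
* **Branch counting** skeletonizes the mask (Zhang–Suen thinning) and
  counts endpoints (skeleton pixels with exactly one 8-connected
  neighbour). Rasterization produces spurious short spurs, so an
  endpoint only counts if its branch runs at least `spur_prune_length`
  (default 3) px before meeting a junction. This walk-based rule is
  equivalent to pruning short spurs but robust to a thinning artifact:
  literally deleting endpoint pixels repeatedly turns thick diagonal
  corners into non-endpoints and silently loses real branches. A solid
  disk reports 0 branches.
* **Circularity** uses the chain-code perimeter; discretization biases
  it by up to ~0.1 (a rasterized disk measures ≈ 0.93, a square ≈ 0.83
  against the continuous π/4 ≈ 0.785), which is why shape checks carry
  a 0.1 tolerance. Circularity is only used comparatively (sheet-like
  invasion scores high, branched invasion low), where the bias cancels.

# The spheroid phantom

`simulate_spheroid_stack()` rasterizes a bright core disk plus radial
branch rays that elongate linearly over time, with a linear intensity
ramp across z on foreground voxels (so the z-std projection works by
construction — any z-varying profile would do; the ramp keeps the truth
analytic) and additive Gaussian noise. Design choices:

* Frames are 1-based; at frame `t` a ray's furthest extent is exactly
  `core_radius + branch_growth_rate * t`, the recorded truth invasive
  radius. The tip is a half-disk cap whose centre sits `width/2` inside
  that extent.
* Branch angles are evenly spaced with a random global rotation:
  always distinct, and rotationally balanced so the phantom's centroid
  coincides with the core centre at every frame. This matters because
  the invasive radius is *defined* from the centroid: with jittered
  angles the centroid drifts as rays grow and the truth value
  `core + rate*t` would be wrong by several pixels.
* Truth invasive area is the closed form
  `n_branches * ((len - w/2) * w + pi (w/2)^2 / 2)`.
* Defaults (8 frames, 4 z-planes, 192² px, core 16 px, 5 branches
  growing 8 px/frame, width 5 px, intensities 100 vs 10, noise sd 4
  ≈ 4.4% of contrast) describe a spheroid that fills a 10× field over a
  time-lapse; the noise level is typical of background-subtracted
  fluorescence confocal data.

What the phantom does **not** emulate: the microscope PSF,
photobleaching, intensity decay with depth, curved or branching chains,
drift, or multiple spheroids per field. Passing the recovery tests shows
the pipeline's geometry and statistics are right, not that it handles
arbitrary real microscopy.

# Track metrics

`track_metrics()` reports per track: path length (sum of consecutive
Euclidean steps), displacement (first-to-last distance), duration, and
two velocity readings: `mean_velocity = path / time` (the default
reading) and `displacement_velocity = displacement / time` — both are
emitted because either definition is in common use. Missing frames
inside a track are treated as a single straight step, matching step-sum
tracking tools. `split_at_event()` computes both halves around a
leader-detachment frame (shared event sample); `distance_profile()`
gives the cumulative-path curve whose plateau shows chain arrest;
`relative_positions()` re-expresses a detached leader's track relative
to its chain.

A caution encoded in the tests: the path-length estimator is upward
biased by localization noise (each jittered step adds
`O(noise_sd)` of spurious path), so a 4:1 pre/post speed ratio is
recovered exactly without noise but degrades as noise approaches the
slower segment's step length; at noise = 25% of the post-detachment
step the ratio is still recovered within 25%. At noise comparable to
the slow step itself, no step-sum estimator can recover it.

# The permutation differential-expression test

## Design and statistics

Twelve samples in four groups of three: leader (L), follower (F),
photoconverted invasive control (IR) and non-photoconverted control
(NG). For each gene the `3 x 3 = 9` pairwise differences
`L_i - F_j` form the treatment set and the 9 differences `IR_i - NG_j`
the control set (signed; `make_difference_pairs()`). Two statistics per
gene and direction (`gene_stats()`):

* `t_one`: one-sample t of the treatment differences against zero
  ("the leader-follower difference exceeds zero");
* `t_two`: two-sample pooled-variance t (Welch optional) of the
  treatment differences against the *absolute* control differences
  ("the leader-follower difference exceeds the photoconversion
  artifact"). The absolute value applies to the control role only.

Zero-variance degeneracies map to ±Inf by the sign of the numerator
(0 when it is also 0), and ties — including Inf vs Inf — count as
exceedance, the conservative reading. The follower direction negates
the treatment differences.

## Permutation scheme

A gene should be called leader-specific only if its signal cannot be
explained by photoconversion. The sharp form of that null hypothesis is
*"L is distributed like IR, and F like NG"* — under it the group labels
are exchangeable **within photoconversion status**. The default scheme
(`perm_params(scheme = "status")`) therefore relabels which 3 of the 6
photoconverted samples are "leaders" and which 3 of the 6
non-photoconverted samples are "followers", rebuilding both difference
sets each time: `choose(6,3)^2 = 400` assignments, enumerated
exhaustively (sampled without replacement if `B` is set below the
count). Two properties follow by construction and are verified by the
test suite:

* genes with no group structure at all are selected at rate α, and
* artifact genes — equal shift in L and IR — are *also* exact nulls of
  this ensemble, so they are selected at rate α rather than leaking
  through.

Both statistics must be extreme jointly. The marginal permutation
p-values `p1, p2` are combined as `S = max(p1, p2)` and `S` is then
calibrated against its own permutation distribution (single-step max-p
calibration). This keeps the "permuted data must exceed both observed
statistics" logic while making the joint p-value exact: a plain
intersection-union `max(p1, p2)` is conservative, and counting joint
exceedances directly as a p-value is anti-conservative (a bivariate
survival probability is smaller than either marginal).

An alternative difference-level formulation is retained as
`scheme = "pairs"` and as `permutation_p()`: pool the 18 signed
differences, reassign 9 to each role (at most `choose(18, 9)`
assignments, enumerable exhaustively on reduced designs — e.g.
`choose(8, 4) = 70` with two replicates per group, which the test suite
uses as an enumeration oracle for the sampled estimator), and count
permutations jointly exceeding both observed statistics with add-one
smoothing `(count + 1) / (B + 1)`. It is not the default because the
pairwise differences are strongly dependent (9 values built from 6
numbers): reassigning them individually breaks that dependence, making
permuted statistics under-dispersed relative to the observed ones and
the resulting p-values anti-conservative. The machinery is kept because
it is exact on its own terms (sampled vs exhaustive agreement), useful
for methodological comparison, and cheap.

Selection uses the raw p-value at `alpha` (default 0.05);
Benjamini–Hochberg q-values are emitted as supplementary columns only.
One shared permutation plan (seeded) applies to all genes and both
directions, and its digest is recorded in the result metadata.

## Normalization

The test presupposes a normalized gene-level log2 matrix. The helpers
`log2_transform()`, `quantile_normalize()` (rank-mean quantile
normalization via limma, ties averaged) and `summarize_probesets()`
(mean over probes per gene) cover the standard preprocessing chain;
vendor-specific raw-file correction is out of scope and the pipeline
ingests a numeric matrix.

# Reproducibility machinery

Every generator takes a mandatory seed and restores the caller's RNG
state; fixed seeds give bit-identical outputs. `run_pipeline()`
validates its config (unknown keys rejected) and the existence of all
inputs *before* any stage runs, executes the requested stages, and
writes a manifest with parameters, seed, package version and MD5
checksums of every output; identical config + seed reproduce identical
tables. `inst/cli/sagakit.R` is a thin command-line wrapper over the
same function.

# Problem sizes

The test suite and the acceptance script run, by choice, at: 50 random
phantoms of `8 x 4 x 192 x 192` voxels (3–8 branches, noise 4.4% of
contrast) for feature recovery; 1000 random-walk tracks plus 100 noisy
detachment tracks; and expression matrices of 2000 genes × 12 samples
(three seeds) for the null-calibration checks, with 300–400 genes for
power and artifact-exclusion checks. These sizes give binomial standard
errors comfortably below the margins being tested while keeping a full
run in a few minutes on one CPU.

# Known limitations

* The imaging pipeline assumes one spheroid per field and a bimodal
  intensity distribution after projection; it does not deconvolve,
  correct drift, or render 3D surfaces.
* Circularity and perimeter carry rasterization bias (see above); they
  are comparative measures, not absolute shape coefficients.
* Branch counting reports skeleton endpoints: crossing or merging
  chains in a real image can under- or over-count relative to a visual
  chain count.
* The expression test is built for the balanced four-group design; it
  requires equal replicate counts per group.
* With only three replicates per group the status-permutation ensemble
  has 400 elements, so the smallest attainable p-value is 1/400 —
  ample for selection at 0.05, but q-values saturate accordingly.
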