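---
title: "Quantifying microglial morphology and activity markers in 3D"
author: "mgmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglial morphology and activity markers in 3D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgmorph)
```

## The measurement problem

Microglia — the resident immune cells of the brain — signal their
activation state through their shape. A surveilling microglial cell is
highly ramified: a small soma with long, thin, branched processes. Upon
activation (with age, injury, or inflammation) cells de-ramify, their
somata enlarge, lysosomal activity (CD68) rises, and the autofluorescent
age pigment lipofuscin accumulates. `mgmorph` reimplements, as tested
reusable R code, a complete single-cell quantification chain for such
studies: confocal z-stacks of Iba1-stained microglia are segmented into
single-cell 3D masks, each mask is reduced to a vector of morphometric
indices, punctate markers (CD68, lipofuscin) are quantified inside soma
outlines, and behavioural indices from the accompanying partner-recognition
paradigm are scored and screened for outliers.

Because the original study's raw images are not deposited, the package
carries its own oracle: a synthetic-data module that generates
confocal-like stacks of branched cells with *exactly known* volume,
surface, branch topology, asymmetry and marker content. Every downstream
stage is validated against that ground truth.

## The segmentation chain

Segmentation follows the original toolbox step for step. The stack is
converted to 8 bits (parameter-free min-max linear mapping — the original
ImageJ conversion depends on the interactive display range, which is not
reproducible), maximum-intensity projected, scaled by 0.5 (2x2 block
averaging, i.e. bilinear at half-pixel centres), and an automatic threshold
is computed on the scaled projection with the Huang fuzzy-entropy
criterion. For a threshold $t$ the gray levels are split at $t$, each class
is summarized by its mean, every level $g$ receives a membership
$u(g) = 1/(1 + |g - \mu_{class}|/C)$, and the histogram-weighted Shannon
entropy of the memberships is the "fuzziness" of the split; the minimizing
$t$ is chosen, ties broken toward the lower level. The implementation uses
cumulative-sum recurrences but is exhaustively checked against a naive
re-implementation of the objective in the test suite — agreement is exact
on every tested histogram.

The threshold is then mapped back through the 8-bit conversion and applied
to the *unmodified* 3D image with a strict `>` comparison (fixed so that
masks are bit-reproducible), and 26-connected components below 10,000
voxels are discarded. Which voxel grid the 10,000-voxel cutoff refers to is
ambiguous in the original description (acquisition at 0.18 µm/px versus
the half-scaled 0.3608 µm/px analysis grid); `mgmorph` records calibration
per stage, applies the filter on the grid the mask lives on, and exposes
the cutoff as a parameter.

## Morphometric indices

For a single-cell mask with calibration $(s_{xy}, s_z)$:

* **Volume** $V$ is the voxel count times $s_{xy}^2 s_z$.
* **Surface area** $A$ is measured on a triangulated iso-surface: marching
  tetrahedra on the binary mask, followed by Taubin's shrink-compensating
  mesh smoothing (80 iterations, $\lambda = 0.5$, $\mu = -0.53$). Counting
  exposed voxel faces would overestimate a sphere's area by ~50% and
  destroy the ramification index's calibration; smoothing the *mesh*
  rather than the voxel field keeps flat faces exact while flattening
  staircase oscillation. On digitized test solids the estimator is within
  ~2% for spheres (radius ≥ 10 voxels) and ~3% for cuboids. The
  face-counting estimator remains available for comparison with voxel-based
  toolboxes.
* **Ramification index** $RI = A / \left(4\pi\,((3V)/(4\pi))^{2/3}\right)$,
  the cell's surface relative to the volume-matched sphere: exactly 1 for a
  sphere, larger for ramified shapes, scale-invariant.
* **Mean marker intensity** is the arithmetic mean of the original image
  over mask voxels (the Iba1 activity proxy).
* **Polarity index**: the displacement between the cell's unweighted
  centre of mass and the centroid of its convex hull, normalized by the
  diameter of the sphere having the hull's volume,
  $p = \|\mathbf{com} - \mathbf{c}_{hull}\| \,/\, \left(2\,((3 V_{hull})/(4\pi))^{1/3}\right)$.
  The printed normalization in the source protocol is typographically
  garbled ("2·3·spanned volume/4π3"); the hull-equivalent-diameter reading
  is the one that makes the index dimensionless, and "spanned volume" is
  taken as the convex-hull volume of the whole cell — the hull is the only
  spanning construct the protocol names. Whether the original toolbox
  excluded the soma is unknown; the whole cell is used, with an `exclude`
  argument for soma-free variants. The hull itself is computed by an
  incremental 3D convex-hull routine over per-slice hull candidates of the
  voxel cloud.

## Skeleton metrics

Branch number, tree length and average branch length are measured on a
centerline skeleton. The mask is first smoothed per plane (Gaussian,
sigma 1.0 px in xy and 0.0 in z, re-binarized at 0.5, as in the original
chain), then thinned by *distance-ordered homotopic thinning*: foreground
voxels are deleted in increasing order of their anisotropic Euclidean
distance to the background, and only while they are topologically simple
points (deletion preserves both foreground 26-topology and background
6-topology) and not curve end points. Deleting in distance order makes the
surviving curves run along the distance ridge — the centerline — and
erodes blobs (the soma) cleanly toward their centres instead of freezing
boundary bumps into spurious branches, which a plain directional thinning
does.

The skeleton is decomposed by classifying voxels on their 26-neighbour
count (end point, slab, junction), merging adjacent junction voxels into
junction nodes and tracing slab paths between terminals. Two measurement
choices matter and are deliberate deviations from a naive re-reading of
the original plugins:

* **Branch length** is the length of a polyline through anchor voxels
  four steps apart rather than the sum of raw inter-voxel steps. Raw
  Euclidean step sums overestimate slanted digital lines by up to ~20%
  (staircase effect, aggravated by 0.18 vs 0.5 µm anisotropy and boundary
  noise); with anchors, straight tubes measure within a few percent and
  straight 1-voxel lines are exact.
* **Artifact cleaning**: terminal branches shorter than `prune_um`
  (default 2.8 µm, about 2.5 process diameters under the default
  geometry) are removed, junction–junction stubs below the same cutoff
  (split junction clusters inside the soma) are contracted, and junctions
  thereby reduced to two branches are dissolved. Thinning a union of
  tubes *necessarily* leaves sub-diameter stubs at junction caps; these
  are properties of the centerline construction, not processes. With
  cleaning enabled the measured branch count equals the generative truth
  on essentially every synthetic cell; `prune_um = 0` restores the raw
  decomposition.

A skeleton-path subtlety fixed the ground-truth convention: the skeleton
of a star-shaped cell runs from each process tip *through the soma* to a
central junction, so the generator defines primary-process length from the
soma centre, and the truth tree length is the sum of segment lengths on
that same construct.

## Puncta and soma-ROI quantification

Somata are simple polygons in pixel coordinates (drawn manually in the
original study; emitted from the generative soma ellipse for synthetic
data). Soma size is the shoelace polygon area times the squared pixel
size; mean gray value averages pixels whose centres fall inside the
polygon (even-odd rule, via `mgcv::in.out`) — the rule is fixed so tests
can be exact.

CD68 is quantified as the percent area fraction of the binarized
maximum projection inside each soma. The binarization threshold is
*cohort-fixed*: the mean of per-image Huang thresholds over the reference
(control) group, then held constant for every group, so group contrasts
cannot arise from adaptive thresholding. Neuronal lipofuscin uses a
7-plane maximum projection with a defined start plane (a required
parameter — the original protocol does not define the start; synthetic
truth uses the soma-centre plane), binarized per image, and counts
8-connected particles of calibrated area strictly greater than 0.5 µm²
("particles > 0.5 µm" is read as a projected-area cutoff — the named 2D
particle analyzer filters by area, and a length cutoff is ill-defined for
particles; the boundary case at exactly 0.5 µm² is excluded and tested).
Microglial somatic lipofuscin reuses the CD68 machinery on the full-stack
projection, flagging mice contributing fewer than 12 cells. Whether the
original lipofuscin binarization used the cohort-fixed or per-image
threshold is not stated; per-image is the default and both are exposed.

## Behavioural indices and outlier screening

Sociability ($T_p/(T_p+T_c) \cdot 100$) and preference
($T_n/(T_f+T_n) \cdot 100$) are chance-level-50% percentages; mice with
sociability ≤ 55% (inclusive — the boundary case is tested) or aggressive
partners are excluded, with every removal logged. Group-versus-chance
testing is the standard two-sided one-sample t-test (hypothetical mean
50%, or 22.5 s for the water-maze probe trial).

The ROUT outlier screen is implemented from its published description,
specialized to a constant-only model: robust location is the median,
robust scale is the RSDR (the 68.27th percentile of absolute residuals
with the small-sample correction $n/(n-K)$, $K = 1$), each point gets a
two-tailed t probability of its standardized residual, and points are
tested from the largest residual inward with step-down thresholds
$\alpha_i = Q\,(n-i+1)/n$, stopping at the first non-outlier. On clean
normal samples ($n = 20$) the mean flagged fraction stays below the
nominal $Q$; a gross planted outlier is flagged at $Q = 5\%$. Flags are
returned, never silently dropped. The cohort pipeline applies the screen
per group and metric with $Q = 5\%$ for single-cell metrics (the original
analysis used $Q = 10\%$ for expression tables; the parameter is
per-analysis).

Routine group-level statistics (two-way ANOVA, Sidak post-hoc tests,
repeated-measures ANOVA) are intentionally *not* reimplemented: the
pipeline emits tidy per-cell and per-mouse tables for standard tools.

## What the synthetic data emulates — and what it does not

The generator reproduces the acquisition geometry of the study it mirrors:
0.18 µm/px laterally, 0.5 µm z-steps, 16-bit stacks (the half-scaled
0.3608 µm/px analysis calibration is also built in). A cell is a soma
ellipsoid (semi-axes ~3.4 × 3.0 × 2.6 µm, with mild lognormal
size and shape jitter, ~7% CV on soma area — small enough that group
truth means track planted effect sizes at cohort sample sizes) plus 4–6 primary processes of 8–13 µm
(tube radius 0.9–1.2 µm) that bifurcate once with probability 0.5 into
5–8 µm daughters. Primary directions keep ≥ 40° pairwise separation,
non-adjacent branches keep a 3 µm clearance so the skeleton topology is
identifiable, arbors are z-flattened (axial direction component halved)
and hard extent bounds keep whole cells inside a 224 × 224 × 48 stack —
single-cell crops of the kind the original single-cell selection step
produces. These sizes clear the pipeline's fixed 10,000-voxel particle
filter, as real microglia do. Rendering applies a Gaussian point spread
(sigma 1 px lateral, 0.6 voxel axial), a background of 20 and foreground
of 120 photon counts with Poisson shot noise — mid-range confocal
signal-to-noise.

Ground-truth volume and centre of mass come from Monte-Carlo integration
over the tube/ellipsoid union with overlap rejection; surface area from
area-uniform surface sampling with rejection of samples inside other
primitives (ellipsoid area via the Thomsen approximation). With the
default 8,000 samples per primitive these truths are accurate to ~1–2%
(documented tolerance 2%); topological truths (branch count, segment
lengths, mid-plane soma area $\pi a b$) are exact. Puncta are placed
non-overlapping in the xy-projection by construction, so planted counts
and projected area fractions are unambiguous.

The simulation deliberately omits spectral bleed-through, depth-dependent
attenuation and scattering, touching cells, and irregular soma shapes.
Passing the recovery tests therefore demonstrates that the *measurement
chain* is faithful on well-posed single-cell images — not that
segmentation would survive densely packed tissue or heavy optical
aberration.

## Numerical choices and degenerate inputs

Thresholding uses strict `>`; ties in the Huang objective break toward the
lower level; constant stacks 8-bit-convert to 0 and constant histograms
raise a degenerate-histogram error. The particle filter errors when
nothing survives ("no cell survives filter") and warns when more than one
component does. Coplanar masks make the convex hull degenerate and raise
an error rather than returning a polarity of 0/0. Empty skeletons return
zero metrics with a warning. ROUT requires $n \ge 3$; the chance test
requires $n \ge 2$ and non-zero variance (except in the exact-null case,
where $t = 0$, $p = 1$). RNG: every generator is a pure function of
(parameters, seed); cohorts derive per-cell streams from one root seed by
a documented linear splitting rule, so regeneration is file-hash
identical.

## Problem sizes used in validation

The bundled validation (test suite and `scripts/acceptance.R`) runs, per
choice, at desk scale: a 60-cell noisy cohort for skeleton recovery
(branch count exact for ≥ 90% of cells, tree length within 10% median
absolute relative error), five noiseless fixtures for exact segmentation
recovery, a two-group cohort of 3 mice × 4 cells per group with a +30%
soma-size effect for end-to-end effect recovery, 150 random histograms
for the Huang oracle, and 1,000 replicates of $n = 20$ for the ROUT
false-positive rate. These sizes were chosen to exercise every code path
with comfortable statistical margins.

## A worked example

```{r example, eval = FALSE}
library(mgmorph)

cal <- calibration()                       # 0.18 um/px, 0.5 um z-step
cell <- generate_cell(cell_params(), seed = 11, center_um = c(20, 20, 12))
mask <- rasterize_cell(cell$spec, cal, c(224, 224, 48))
stack <- render_stack(list(iba1 = mask), noise_model(seed = 11), cal)

cm  <- segment_cell(stack)                 # Huang threshold + particle filter
rec <- compute_morphometry(stack$voxels, cm, cell_id = "demo")
rec[, c("volume_um3", "ramification_index", "branch_count", "tree_length_um")]
cell$truth[, c("volume_um3", "branch_count", "tree_length_um")]
```

## Known limitations

Touching cells are not split (single-cell crops are assumed, as in the
original workflow); processes thinner than ~2 rasterized pixels can
disconnect and are excluded by the generator's constraints; branch
cleaning assumes processes at least ~2 µm in diameter-scale separation
from the artifact regime, and should be re-tuned (or disabled) for
substantially finer arbors; the surface estimator's accuracy degrades for
structures only 1–2 voxels thick; and the ROUT specialization covers the
constant-only (univariate sample) case, not regression models.
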