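---
title: "Hierarchical random-walker segmentation and vessel morphometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical random-walker segmentation and vessel morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiervess)
```

# The problem

Light-sheet fluorescence microscopy of optically cleared organs produces 3D
stacks of hundreds of gigabytes in which a stained vascular tree spans
radii from large feeding vessels down to capillaries near the resolution
limit. Because vessel walls rather than lumina are stained, vessels often
appear as hollow tubes ("double lines" in cross-section), which defeats
simple intensity thresholding. `hiervess` implements a semi-automatic
pipeline for this setting: seeded random-walker segmentation made scalable
by a bricked octree hierarchy, binary-mask clean-up, centerline graph
extraction, scale-independent pruning, and vessel morphometrics. Everything
is validated against synthetic phantoms with exact ground truth.

# The random-walker model

Given user-labeled foreground (vessel) and background voxels, the
random-walker model assigns every voxel the probability that a random
walker released there reaches a foreground seed before a background seed.
On the 6-connected voxel lattice with edge weights

$$ w_{ij} = \exp\!\left[-\beta \left(\frac{I_i - I_j}{s}\right)^2\right] + w_{\min}, $$

divided additionally by the squared physical edge length on anisotropic
grids, this probability field is the discrete harmonic function of the
weighted graph Laplacian with seeds as Dirichlet data: each unlabeled
voxel's probability is the weight-weighted mean of its neighbors'. The
reduced linear system is symmetric positive definite and is solved with a
Jacobi-preconditioned conjugate-gradient iteration.

Parameter choices (none of these is prescribed by the underlying method;
all are exposed in `rw_config()`):

* `beta = 90` with intensities normalized by the global intensity range
  `s` — strong enough that a clean vessel wall is effectively insulating,
  while plausible noise (sigma up to ~20% of contrast) leaves homogeneous
  regions well connected;
* `w_min = 1e-5`, a weight floor that keeps the lattice connected so the
  system stays non-singular;
* relative residual tolerance `1e-6`, iteration cap 2000, deterministic
  initial guess of 0.5 on all unknowns (no randomized state anywhere in
  the solver).

The monolithic solver (`flat_rw_oracle()`) builds one system over the whole
volume. Its memory footprint grows with the volume, which is exactly what
the hierarchy removes; it is retained as the reference implementation that
the hierarchical scheme is tested against.

# The octree hierarchy

`build_octree()` subdivides the volume into cubic bricks (default
`32^3`) and builds coarser levels by averaging 2x2x2 voxel groups until
one brick holds the whole volume; partial groups at volume borders average
the existing voxels only, so borders are not darkened. Bricks live on disk
and all access flows through an LRU cache holding at most `cache_budget`
bricks, giving bounded memory regardless of volume size; instrumentation
(`brick_cache_stats()`) exposes the peak residency so the bound is testable
rather than asserted.

`run_hierarchical_rw()` then refines coarse to fine:

1. the coarsest level is solved with the hard seeds integer-scaled to that
   level (coordinates divided by `2^level`; a coarse voxel receiving both
   labels keeps neither);
2. each finer brick is solved with the hard seeds inside it plus the
   parent level's probabilities clamped as soft Dirichlet values on a
   one-voxel halo ring just outside the brick (trilinear upsampling by
   default). Clamping the halo rather than the brick's own shell means
   every voxel of the output map was solved at its own resolution — the
   coarse level supplies boundary conditions, the fine level refines the
   border region of the structure. Volume-border faces carry no halo, so
   the free boundary matches the monolithic solve;
3. a brick whose parent footprint is uniformly probable (all values within
   `homogeneity_eps = 0.01` of 0 or 1) and which contains no contradicting
   seed is decided immediately and its whole subtree is skipped;
4. thresholding at 0.5 (ties to foreground) yields the binary mask.

Bricks within one level exchange no information — all cross-brick coupling
flows through the coarser level — so the result is independent of brick
order, which a shuffled-order test asserts. Re-runs after a seed edit
(`incremental_update()`) re-solve a brick only when its seed content
changed or its halo values moved by more than `reuse_eps = 0.01` in
maximum norm; an unchanged problem reuses every brick verbatim and is
bit-identical.

## What the hierarchy can and cannot reproduce

The coarse-to-fine design implies two intrinsic limits, both visible in the
test suite and worth stating plainly:

* **Voxel-level probabilities near object surfaces.** The halo values are
  an interpolation of a half-resolution field that is discontinuous at the
  vessel surface, so wherever a surface crosses a brick face the clamped
  values carry an O(1) pointwise error which the highly conductive
  background spreads a few voxels inward. Thresholded *masks* agree with
  the monolithic solver to well under 1% of voxels (differences confined
  to the surface shell), and single-brick volumes are bit-identical, but
  the pointwise maximum probability difference on multi-brick volumes is
  of order 0.1–1 at isolated surface voxels. A multi-sweep domain
  decomposition would remove this at the cost of intra-level coupling and
  order dependence; it was deliberately not adopted.
* **Vessels thinner than a coarse voxel.** A branch whose radius falls
  below the coarsest level's voxel size is invisible to the root solve; if
  it also contains no seed, its bricks can be classified background. This
  is inherent to the method and is why the original workflow is
  interactive: the user adds seeds where the segmentation is incomplete.
  The phantom conditions for the equivalence tests therefore keep tube
  radii at or above about two voxels at the coarsest level used.

# Post-processing

`median_smooth()` applies a cubic majority filter (ties to foreground),
implemented by integral-volume window counts and therefore identical to
the brute-force majority vote the tests compare against.
`connected_components()` labels the volume brick by brick with local flood
fills, merges labels across one-voxel border slabs of all adjacent brick
pairs (including diagonal pairs for 26-connectivity) with a union-find,
and relabels — the structure required for volumes that do not fit in
memory. `remove_spurious_and_fill()` keeps the largest foreground
component (26-connectivity) and fills background components not connected
to the volume hull (6-connectivity): cavities, notably the lumen of hollow
vessels, must be solid before thinning.

# Skeleton, graph, and pruning

`skeletonize()` is a border-sequential 6-subiteration thinning: per
direction, simple non-endpoint border voxels are collected and deleted
sequentially with re-checking. Point simplicity uses the
connectivity-number characterization — exactly one 26-connected foreground
component in the 26-neighborhood and exactly one 6-connected background
component in the 18-neighborhood touching the center — which deletes the
same class of points as the Euler-table formulation and preserves
components and tunnels exactly. The fixed direction order makes the result
deterministic.

`extract_graph()` classifies skeleton voxels by 26-neighbor count
(1 endpoint, >= 3 branch), collapses adjacent branch voxels to one node at
the cluster centroid (snapped to a cluster voxel), and traces maximal
two-neighbor chains into segments. Two clean-up rules absorb
discretization artifacts of voxel skeletons: branch–branch edges shorter
than about one junction-blob diameter are contracted (diagonal stepping
can split one anatomical junction into two or three nearby branch nodes),
and the longer of two parallel edges whose combined circumference is below
$2\pi r$ of the local radius is removed — a loop smaller than the vessel's
own girth cannot be a real anastomosis and arises from 26-connectivity
handles in the digitization.

Per centerline point the radius is the anisotropy-aware Euclidean distance
transform of the mask, plus a quarter-voxel correction: the sample point
(a skeleton voxel center) sits off the true axis by up to half a voxel
diagonal while the distance overshoot to the nearest background voxel
center only partly compensates, leaving a net expected bias near minus a
quarter voxel (measured on tubes with randomized sub-voxel axis
placement). Residual radius uncertainty is about ±0.3 voxel, which bounds
the accuracy of all diameter-derived quantities. Centerlines are lightly
Laplacian-smoothed (two passes, endpoints fixed) because digital paths
zigzag between voxel centers, inflating arc length.

**Bulge size** of a segment at a bifurcation is

$$ b = \frac{\max(0,\; L - r_{\text{parent}})}{d_{\text{bif}}}, $$

the proper length (total length minus the parent vessel's radius at the
branching point, clamped at zero so the statistic stays monotone for
stubs) divided by the segment's diameter at the bifurcation. It is
dimensionless, hence independent of the true vessel size, which makes one
threshold usable across radii spanning orders of magnitude. Two
measurement choices are interpretations (the quantity's sampling points
are not standardized): the parent radius is the branch node's inscribed
radius, and the diameter at the bifurcation is twice the median
distance-transform value over centerline points farther from the node than
that radius — points inside the junction blob report the junction's
inscribed sphere, roughly twice the child caliber, and would otherwise
halve the bulge of true branches.

`prune_graph()` iterates to a fixpoint at threshold 3 (the default; the
exact value is not critical for well-resolved vessels): the leaf segment
with the lowest bulge below threshold is deleted, the resulting degree-2
node is merged (lengths add, centerlines join, radius samples
concatenate), and the scan repeats. Deleting one leaf at a time, lowest
bulge first, matters: when a spurious micro-twig has split a true tip, the
twig and the orphaned tip piece are both below threshold, and simultaneous
deletion would discard the true tip — sequential deletion removes the twig
first and the re-merged branch then passes. Segments whose both ends are
endpoints have no parent vessel and are never pruned.

# Morphometrics

`summarize_graph()` reports the diameter frequency distribution
(left-closed 2-micrometer bins from zero; counts sum to the segment
count), caliber classes small (d < 0.02 mm), medium (0.02 mm <= d <
0.1 mm) and large (0.1 mm <= d) with per-class median/quartile/1.5-IQR
summaries of length and straightness, and global totals. Straightness is
the endpoint chord divided by the centerline arc length (1 = perfectly
straight). Vessel volume integrates $\pi r^2\,ds$ along the centerline
with the exact conical-frustum rule per step — exact for cylinders and
cones at any sampling and first-order convergent for general vessels — so
the reported volume reflects the graph actually measured; the voxel-count
volume of the mask is available separately via the mask itself. The
per-segment representative diameter is twice the mean radius sample (mean
rather than median or local maximum; for near-constant-caliber segments
they coincide).

# The phantom generator

`phantom_spec()`/`generate_tree()`/`rasterize_phantom()` produce the study
conditions for all validation: a recursive binary tree grown from a root
by splitting the thickest tip, child radii scaled by `radius_decay`,
branch angles 20–60 degrees off the parent axis with daughters on opposite
azimuths at least 40 degrees apart (near-parallel daughters are degenerate
geometry whose overlapping tubes would swallow the junction), and segment
lengths that scale with the square root of the radius so thicker vessels
run longer, as in real vascular trees. True branches are kept at proper
length at least about six diameters — comfortably above the pruning
threshold's regime — and candidates clipped by the volume border below
that are rejected rather than emitted short, so the realized tree (whose
bifurcation count is recorded in the ground truth) always satisfies the
generator's own contract. Optional stub injection adds short spurious
leaves (proper length 1.5 diameters by default) on interior segments for
pruning tests. Tubes render as solid capsules or, in hollow mode, as
bright walls around a background-intensity lumen, reproducing the
double-line appearance of wall-stained vessels; additive Gaussian noise is
the only noise model — light-sheet PSF blur, shot-noise statistics and
stripe artifacts are out of scope, so passing tests speak to the
algorithms' correctness on well-contrasted data, not to robustness against
those acquisition effects. All randomness derives from the spec's single
seed; the same spec is always the same phantom, bit for bit.

Derived seed strokes (`make_seed_file()`) sample the true centerline of
the thickest vessels (foreground) and guaranteed-background positions at a
safety margin (background), standing in for the interactive seed painting
of the original workflow.

# Problem sizes and determinism

The shipped tests run phantoms from 16^3 to 240^3 voxels: single-brick
volumes exercise the exact-equivalence path, 64^3–128^3 the hierarchy and
pruning, one 192^3 volume the out-of-core contract (cache capped at 16
bricks, peak residency instrumented), and up to 240^3 the ten-bifurcation
topology recovery. These sizes were chosen so that every claim is
exercised at the smallest scale at which it is non-trivial. Every
computation in the package is deterministic given the configuration: brick
order is irrelevant by construction, the solver has no random state, and
all phantom randomness flows through explicit seeds.
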