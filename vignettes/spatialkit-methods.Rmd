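---
title: "spatialkit: data model, transformation algebra and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spatialkit: data model, transformation algebra and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialkit)
```

This vignette documents the conventions, models and numerical choices behind
`spatialkit`, in the spirit of a methods section: what the operations
compute, which decisions were genuinely open and how they were fixed, and
what the synthetic fixtures do and do not demonstrate about real data.

## The element model and its conventions

A dataset is a named collection of five element kinds — images, label masks,
points, shapes and annotation tables — each a thin, validated wrapper over a
standard R payload (arrays, data frames, `Matrix` matrices). Two conventions
remove a whole class of axis-order bugs:

* **Raster axis order is `(c, z, y, x)`** (subsets thereof), while vector
  coordinates are columns named `x`, `y`, `z`. The two conventions meet only
  inside the transforms module, which resolves axes **by name, never by
  position**. A transformation that does not mention an axis passes it
  through unchanged, so a 2D map applies cleanly to a `(c, y, x)` raster.
* **Pixel geometry**: the pixel at (1-based) row $i$, column $j$ occupies
  the half-open square $[i-1, i) \times [j-1, j)$ in intrinsic $(y, x)$
  units; its center is $(i - 0.5,\, j - 0.5)$. With this convention a
  factor-2 scale maps pyramid level $k{+}1$ pixel centers onto level-$k$
  block centers exactly, so scale transforms commute with pyramid levels.

Instance identity is the glue between geometry and annotation: label masks
are identified by their nonzero pixel values, points and shapes by an
explicit integer id vector (defaulting to the row index) that every
operation preserves verbatim. A table annotates an element through the
`(region, region_key, instance_key)` triple; `validate_dataset()` checks
that every annotated id resolves, and returns violations as data rather than
raising, so a container can be inspected wholesale.

**Multiscale pyramids** use factor-2 mean pooling for images and stride-2
subsampling for labels (which therefore can only ever contain level-0 ids).
Levels are appended while the largest spatial dimension is at least 64
pixels; odd trailing rows/columns are dropped exactly. Mean pooling
conserves the global mean exactly when dimensions are powers of two, which
the tests exploit as a cheap integrity check.

## The transformation algebra

Transformations are algebraic objects: `identity`, per-axis `scale` and
`translation`, homogeneous `affine`, and `sequence`. Everything reduces to a
homogeneous matrix via `to_affine_matrix()`, which is also how equality and
invertibility are defined.

* **Sequence order**: members apply **left-to-right** — the first listed
  acts first, i.e. `compose_transforms(f, g)` is $g \circ f$. Nothing forces
  this choice; it was fixed once (it reads in application order, like a
  pipeline) and is pinned by tests such as `scale(2)` then `translate(1)`
  mapping $x = 1$ to $3$.
* **Singularity**: inversion and raster resampling refuse linear parts with
  $|\det| < 10^{-12}$; transform-equality assertions throughout use
  $10^{-9}$. Both thresholds sit far from the scales of realistic microscopy
  transforms (pixel sizes, stage offsets) and far above double-precision
  noise from a handful of matrix products.
* **Circles under anisotropic maps**: an anisotropic linear map sends a
  circle to an ellipse, which the shape model deliberately does not include.
  The radius is instead multiplied by the geometric mean of the absolute
  singular values of the linear part, the unique choice that preserves area
  ($\pi r'^2 = |\det| \, \pi r^2$). For the similarity transforms produced
  by landmark alignment this is exact.

Raster resampling (`transform_raster()`) uses inverse mapping: each output
pixel center is pulled back through the inverse transform and the input is
sampled there, nearest-neighbour or $n$-linear; label masks force nearest.
Out-of-bounds samples fill with 0, the universal background value.

## Landmark registration

Landmarks are ordered, 1-to-1 corresponding coordinate lists living in named
coordinate systems — never pixels, so the fit touches no raster data. Two
models are offered:

* **affine** (default): the homogeneous least-squares fit via QR. The
  default suits consecutive tissue sections, where cutting and mounting
  introduce shear that a rigid model cannot absorb. Rank below $d + 1$
  (collinear/coplanar landmarks, tolerance $10^{-10}$) is an error.
* **similarity**: the orthogonal-Procrustes closed form (SVD of the
  cross-covariance, Umeyama scale). Reflections are forbidden by default —
  serial sections are not mirrored by imaging — by flipping the sign of the
  smallest singular vector pair; `allow_reflection = TRUE` overrides.

The reported RMSD is $\sqrt{\tfrac1n \sum_i \lVert \hat A m_i - r_i
\rVert^2}$ after fitting. `align_elements_using_landmarks()` stores the
composed element→CCS map as an explicit affine rather than a sequence, to
keep on-disk metadata flat. With three or more exact, non-collinear
landmarks the true transform is recovered to $10^{-8}$ (tested); with noisy
landmarks the fit is the maximum-likelihood affine under isotropic Gaussian
noise, and the test suite checks its calibration (translation error below
0.6 in at least 95% of replicates at noise sd 0.5 with 20 pairs drawn from
$[-10, 10]^2$ — a centered, well-conditioned design chosen to represent
interactive landmark picking).

## Queries

Interval conventions are fixed globally and never re-decided per call:

* box containment of points and pixel centers is **half-open** `[min, max)`
  per axis (so adjacent boxes tile without double-counting);
* polygon membership is **closed** (a point on an edge or vertex is kept),
  using the even-odd rule, so holes work by parity.

Shapes survive a query when their geometry **intersects** the region:
a region of interest should capture cells partially inside it, which is what
area-weighted downstream aggregation expects. `mode = "centroid"` switches
to centroid containment for counting-style semantics. Circle–box tests are
exact (clamp the center into the box); circle–polygon tests fall back to a
64-gon approximation of the circle.

Raster queries **never resample**: a bounding-box query crops to the pixels
whose centers fall inside the inverse-transformed box's axis-aligned bounds
and prepends the crop offset to every stored transformation, so the crop
occupies its original position in every coordinate system. For polygon
regions the crop is additionally masked — pixels whose centers fall outside
the polygon are set to 0. Masking (rather than merely cropping) was an open
behavioural choice; it was adopted because it makes raster and vector
queries agree on what is "inside", and it is flagged here as such.

Correctness of both query types is defined by brute-force containment
oracles (naive $O(nm)$ loops re-implemented independently in the tests), to
which the implementation must agree exactly over randomized problems.

## Aggregation

`aggregate_points_by_shapes()` assigns each point to every target instance
containing it (overlapping targets each count it; targets are not required
to tile anything), yielding counts per category for a categorical value
column, or sums/means for a numeric one.

`aggregate_shapes_by_shapes()` computes the weight of source $i$ on target
$j$ as
$$w_{ij} = \frac{\mathrm{area}(s_i \cap t_j)}{\mathrm{area}(s_i)},$$
with the **source** area as denominator. The alternative normalizations
(target area, total covered area) were considered; source-normalization was
chosen because it bounds each source's total contribution at 1 — a cell
straddling two capture locations is split, never double-counted — and the
subsequent `fractions = TRUE` row normalization then yields exactly "the
composition fractions of the location". The choice is isolated in one
internal function (`shape_overlap_weights()`) so alternatives remain
switchable. Rows with zero overlap stay all-zero and are flagged in
`obs$covered`. A display-rule helper, `filter_fraction_table()`, zeroes
categories below 5% per row and renormalizes.

**Intersection areas.** No polygon-clipping package is available to this
package's dependency set, so the geometry is built in: Sutherland–Hodgman
clipping against convex polygons, and for concave–concave pairs an exact
signed-triangle decomposition (both polygons fanned into signed triangles
from the origin; the intersection area is the signed sum of pairwise
triangle-intersection areas — valid for simple polygons, with holes encoded
by ring orientation). Circle pairs use the analytic lens formula. Mixed
circle–polygon problems polygonize circles as regular 64-gons (maximum area
error below 0.17%). Within one aggregation call the same discretization is
used for numerators and denominators — otherwise a source exactly tiled by
targets would sum to the 64-gon/circle area ratio (≈ 0.9984) instead of 1;
with consistent discretization the conservation identity holds to clipping
precision.

Label masks can be aggregated without vectorization by pixel counting
(`aggregate_labels_by_shapes()`): the weight of label $i$ on target $j$ is
the fraction of $i$'s pixel centers, mapped into the query frame, that fall
inside $t_j$. This is a deliberately simple fallback; its resolution is the
pixel grid.

## Storage

A dataset persists as one hierarchical Zarr-v2 directory store: kind groups
`images/ labels/ points/ shapes/ tables/`, one child group per element, a
root format-version marker, and per-element metadata in `.zattrs`. Design
points:

* **Rasters** are chunked (256 per spatial axis — a power of two, friendly
  to the factor-2 pyramid), uncompressed, C-order, little-endian, with
  NGFF-style `multiscales` metadata (named axes, per-level scale factors).
  The full transformation records — including affines, for which core NGFF
  0.4 defines no standard encoding — travel in a separate `spatialkit`
  extension attribute that strict NGFF readers simply ignore; a generic
  Zarr/NGFF reader can open every raster group (the test suite verifies this
  with an independent reader).
* **Points** and attribute tables are columnar Parquet, preserving
  categorical types exactly; a CSV path exists for interchange but is
  documented as lossy for categoricals.
* **Shapes** store polygons as standard WKB and circles as typed
  (center, radius) records — circles are never polygonized on disk.
* **Tables** store `X` dense (a Zarr array) or sparse as CSR triplets
  (`data`/`indices`/`indptr`), plus Parquet `obs`/`var` and named layers.
* **Atomicity**: each element is staged under a hidden name and renamed into
  place, so a failure mid-write leaves no half-written element group. No
  file is rewritten in place after finalization except the small `.zattrs`
  metadata documents (transformation write-back), which keeps the layout
  compatible with object storage in principle.

Lazy reading (`read_store(lazy = TRUE)`, the default) defers raster payloads
behind handles that record shape/dtype/chunking from metadata alone. The
contract — listing a store, reading all vector/tabular content and all
transformation metadata performs **zero** raster chunk reads — is not a
promise but an instrumented invariant: every chunk read increments a counter
(`chunk_read_count()`) that the tests assert on.

This on-disk dialect is an independent, documented layout honoring Zarr v2
and NGFF principles; byte-level compatibility with any other tool's store is
explicitly not claimed.

## The synthetic fixtures

`generate_blobs()` emulates the *structure* of an imaging-based spatial
transcriptomics experiment on a small canvas: a sum of Gaussian bumps plus
Gaussian noise (image), connected components above the image's 80th
intensity percentile (labels; the percentile is arbitrary but pinned for
reproducibility), uniform points whose category is the nearest bump's — so
categories form spatial territories like cell types do — with a
misassignment probability tied to the noise setting, a hexagonal lattice of
circular capture locations with center spacing 2.4× radius (echoing
capture-array geometry: adjacent spots don't touch, but one cell can
straddle several), octagonal bump outlines, and a table annotating the label
mask. Bump centers are rejection-sampled to at least $3\sigma$ apart so each
territory is distinct — this is what makes "the dominant category inside
each outline is pure at zero noise" true by construction. Everything flows
from one seed through R's default generator; the ambient RNG state is saved
and restored.

Defaults (128×128 canvas, 5 bumps, 1000 points, 4 categories, 12 circles,
noise 0.05) were chosen once as a desk-scale caricature of tissue with a few
cell-type territories and are used unchanged by the demo, the tests and the
acceptance script.

`generate_aligned_pair()` produces a second modality by pushing all vector
elements through a supplied invertible transform and resampling the rasters
through it, returning bump centers as matched landmark sets in both frames
plus the ground-truth moving→reference matrix (`$true_matrix`, the inverse
of the supplied transform). Because the resampled mask can lose a
boundary-grazing component, the moving table is filtered to surviving ids so
both datasets always validate.

What passing fixtures-based tests does **not** show: robustness to real
segmentation errors, transcript count distributions, optical distortions
beyond affine, or instrument-specific file quirks — the generator simulates
none of these, and vendor-format parsing is out of scope by design
(interchange happens via CSV/GeoJSON/TIFF and the store).

## Problem sizes and tolerances used by the checks

The test suite and `scripts/acceptance.R` run randomized checks at fixed
sizes chosen to exercise every code path while staying desk-scale: 100
random transform sequences (equality to $10^{-9}$), 50 exact landmark
recoveries (to $10^{-8}$) plus 200 noisy replicates, 50 randomized query
problems against exact brute-force oracles, a 1000-point × 10-circle
aggregation against an exact count oracle, conservation over a 3×2 disjoint
tile grid ($\le 1 + 10^{-6}$, $= 1$ for covered sources), fraction row sums
to $10^{-9}$, a circle–square weight within 1% of the analytic
circular-segment value, a full store round trip (rasters bitwise,
transforms to $10^{-12}$, zero lazy chunk reads) and the two-replicate
alignment/aggregation workflow (ground-truth matrix to $10^{-8}$;
per-location fraction correlation $\ge 0.95$ — with exact landmarks the
measured value is 1).

## Known limitations

* No nonlinear/deformable registration, no time axis, and no transformation
  graph search: each element stores a direct map per coordinate system.
* Shapes are circles and polygons only; ellipses (the closed image of a
  circle under anisotropic maps) are approximated by the area-preserving
  radius rule.
* Polygon clipping is exact but $O(n_e m_e)$ per pair in the concave case;
  it is intended for capture locations and ROIs, not for millions of cell
  boundaries at once.
* The store targets local filesystems in this version; the layout avoids
  in-place rewrites so remote/object storage remains reachable, but no
  remote I/O is implemented.
* A table may declare multiple annotated regions, and validation handles
  them, but the join helper (`match_table_to_element()`) restricts to one
  element at a time; multi-target joins are a documented extension point.
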