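---
title: "Counting capillary loops: methods, parameters and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting capillary loops: methods, parameters and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acntopo)
```

## The model

The alveolar capillary network (ACN) is modelled as a spatial multigraph:
nodes are branching points of the vessel lumen, edges are capillary
segments, and parallel edges and self-loops are legitimate topology (two
segments can connect the same pair of branch points around a small tissue
pillar). For a connected network the Euler number

$$\chi = N_\mathrm{nodes} - N_\mathrm{edges}$$

is non-positive, and the number of septal capillary loops — the shortest
cycles around tissue pillars — is

$$N_\mathrm{SCL} = |\chi| + 1 .$$

This is the cycle rank of a connected graph, $1 - \chi$. The package
computes the same quantity by a second, independent route: the size of a
cycle basis, counted as the non-forest edges of a union-find spanning
forest ($E - V + C$). `scl_from_euler()` deliberately *refuses* positive
$\chi$ (a tree has one more node than edges and zero loops, where
$|\chi|+1$ would return 2) and disconnected inputs;
`scl_from_cycle_basis()` handles any multigraph per component. Their
agreement on connected, $\chi \le 0$ graphs is asserted property-style on
hundreds of random multigraphs in the test suite.

Loop counts are converted to numerical densities $N_V = N_\mathrm{SCL}/V$,
with $V$ always computed from voxel counts times spacing (a
$1000^3$-voxel subregion at 150 nm is $(150\,\mu m)^3 = 3.375\times
10^{-3}\,mm^3$) — never taken from a rounded shorthand.

## From volume to graph

1. **Postprocessing.** `fill_holes()` relabels background components that
   do not reach the volume border (foreground 26-connected, background
   6-connected — the complementary pairing that avoids the
   digital-topology paradox, and the convention of the standard ITK hole
   filler). `largest_component()` keeps one connected segmentation, with
   a deterministic lexicographic-(z,y,x) tie-break.
2. **Skeletonization.** `skeletonize()` performs distance-ordered
   homotopic thinning in compiled code: voxels are removed in increasing
   chamfer-(3,4,5)-distance order, only if they are *simple points* under
   the Bertrand–Malandain 26/6 characterization, with curve endpoints
   (exactly one foreground neighbour) anchored. Simple-point deletion
   provably preserves component count, tunnels and cavities, so the
   skeleton has exactly the cycle rank of the input object.
3. **Spur handling.** Endpoint anchoring leaves short artifact spurs at
   junctions and ring corners. Deleting a leaf voxel is always homotopic,
   so after thinning the skeleton is eroded at its tips for up to
   `spur_length_vx` (default 3, comparable to the tube radii the method
   targets) alternating with re-thinning; re-thinning dissolves the
   zero-area triangles a removed spur can leave behind at a junction.
   The cost is that genuine dead-end branches shorten by up to 3 voxels —
   harmless here, because dead ends are pruned entirely at the graph
   stage.
4. **Graph extraction.** `build_graph()` classifies skeleton voxels by
   26-neighbour count (1 endpoint / 2 path / >= 3 branch), merges
   26-connected branch clusters into one node at the cluster centroid,
   and traces edges along path voxels. An isolated closed curve becomes
   one node with a self-loop so that its cycle survives ($\chi = 0$,
   rank 1). Multiple direct voxel contacts between the same two junction
   clusters collapse to one edge: they represent a single junction
   contact, and counting them separately would fabricate cycles.
5. **Pruning.** `prune_degree_one()` deletes dead ends *to a fixpoint*
   (a single pass exposes new dead ends, which would corrupt $\chi$),
   then removes isolated nodes; a self-loop counts degree 2, so pure
   cycles are never pruned. `dissolve_degree_two()` then merges chain
   nodes so surviving nodes are true branch points; each dissolution
   removes one node and one edge, leaving $\chi$ unchanged.

## The stereological verification arm

`disector_estimate()` implements the digital physical disector. For slice
pairs $(z, z + \Delta)$, $\Delta = h_\mathrm{dis}/\text{z-spacing}$
(required integral within 1%), profiles are 8-connected components;
comparing look-up to reference, an **island** is a look-up profile
overlapping no reference foreground and a look-up profile overlapping
$k \ge 2$ reference profiles contributes $k-1$ **bridges** — this
multiplicity makes islands-minus-bridges additive in the component-count
change. Events are counted in both directions of every pair and

$$\chi_\mathrm{stereol} = \sum \mathrm{islands} - \sum \mathrm{bridges},
\qquad
N_{V,\mathrm{stereol}} = \frac{-\chi_\mathrm{stereol}}
{2 \cdot \sum n_\mathrm{par} \cdot a_\mathrm{frame} \cdot h_\mathrm{dis}},$$

the factor 2 compensating the bidirectional count (a unidirectional mode
with divisor 1 exists for sensitivity checks). Frames are either the full
slice or a guarded frame with the standard unbiased-counting exclusion
(events from look-up profiles touching the left or bottom frame edge are
discarded) — the estimator itself does not specify border handling, so
standard stereological practice is adopted.

Two design notes:

- The estimator as printed counts islands and bridges only. The classical
  Euler–Poincaré disector has a third event, a newly *enclosed background
  profile* inside a look-up profile (an in-plane loop closure). This is
  available behind `count_holes = TRUE`, **off by default**. Sweeping a
  solid torus with its axis along z fixes the sign: the annulus appears as
  one island and its hole must cancel that $+1$, so a hole contributes
  $-1$ to $\chi$ (not $+1$). With the default phantom orientation (sheet
  tilted 30 degrees, below) no loop lies in-plane and the event never
  fires, which is why the two-event estimator is exact there.
- When fewer than 100 events are registered — the conventional minimum —
  the estimate is flagged with a warning rather than rejected.

## The phantom generator: what it emulates and what it does not

`make_lattice_network()` builds a rows-by-cols planar grid — short tube
segments around square "pillars" — embedded in 3D and tilted 30 degrees
about the x-axis by default, so that no capillary loop lies within a
single slicing plane (otherwise the two-event disector would need the
hole event it deliberately omits). `voxelize_network()` rasterizes the
network as capsules of radius `radius_vx` (default 2 voxels) at 150 nm
isotropic spacing, refusing any geometry that touches a volume face.
Defaults: pitch 1800 nm (12 voxels), radius 2–3 voxels. These reproduce
the *structural* regime the method targets — tubes a few voxels thick,
loops an order of magnitude wider — at miniature absolute scale; real
alveolar capillaries are an order of magnitude wider than 300 nm, so
phantom densities are far higher than physiological values and are never
compared against published tissue densities. No grayscale texture, noise
in the imaging sense, or erythrocyte appearance is simulated: degradation
is purely binary (`degrade_segmentation()`): mid-edge occlusions emulate
fully blocking blood cells (with the expected rank change logged:
$-1$ for a cycle edge, $0$ for a bridge), enclosed cavities emulate the
holes that hole filling must close, and salt specks emulate disconnected
false labels.

A green phantom test therefore establishes that the *computational
pipeline* — voxelization, postprocessing, thinning, graph extraction,
counting — is exact on known topology. It does not establish anything
about segmentation quality on real electron-microscopy data, which is
why the per-slice evaluation module (SEN/SPE/PPV/NPV/DSC against ground
truth) exists as a separate concern; published metric values for real
data require the original imagery and are out of scope here.

Note one subtlety validated in the tests: severing a *bridge* edge splits
the phantom in two. The logged expectation (rank unchanged) refers to the
global cycle rank summed over components; a pipeline configured to keep
only the largest component will, correctly, report the rank of that
component alone.

## Numerical and interface choices

- Axis order is (z, y, x), 0-based voxel indexing at module boundaries;
  all physical quantities are carried in nm internally and converted to
  um/mm only in reports. Percentages and displayed densities round to 2
  decimals; internal values are full precision.
- Resampling maps output voxel centres to input continuous indices
  (`floor(extent/target)` output sizes); linear interpolation is refused
  on binary input unless an explicit 0.5 threshold is requested, nearest
  neighbour is the mask default.
- Lattice node/edge ground truth vs. recovered graphs: lattice *corners*
  are degree-2 points, which no skeleton-based extractor can represent as
  nodes; recovered counts are compared against the degree-2-dissolved
  truth (nodes $-4$, edges $-4$), while the cycle rank — the quantity all
  downstream statistics use — is compared exactly.
- The slice-rejection of artifact slices in real acquisitions is exposed
  as explicit subregion selection, not automated.
- All randomness (jitter, salt noise, systematic disector start) is
  controlled by one explicit integer seed per operation; pipeline runs
  with equal seeds are byte-identical, and the run directory carries a
  manifest with the configuration hash.
- TIFF support is a minimal baseline codec (uncompressed, single-sample,
  8-bit write / 8- and 16-bit read) written for this package because the
  target R stack ships no TIFF reader; it is cross-checked against an
  external reference implementation in the tests. MetaImage headers store
  spacing in mm per the format's convention; the package converts to nm.

## Known limitations

- Thinning anchors curve endpoints; objects whose medial structure is a
  surface rather than a curve network (plates, shells) are outside the
  intended domain and would thin to curve approximations.
- Genuine parallel capillaries joining the same two junctions with *both*
  contacts only one voxel long would be collapsed to a single edge by the
  junction-contact rule; at realistic tube radii such geometry does not
  survive voxelization anyway.
- The disector assumes no loop lies entirely within one slice plane
  unless `count_holes = TRUE`; tilted phantoms and real, curved tissue
  sheets satisfy this, a perfectly slice-aligned synthetic sheet would
  not.
- `voxelize_network()` assumes isotropic spacing (the analysis pipeline
  itself accepts anisotropic volumes; resample first, as real workflows
  do).
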