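---
title: "Constrained distance transforms: model, algorithms, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained distance transforms: model, algorithms, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdt)
```

# The problem and the model

Spatial atlas systems map assay images (often of gene-expression signal whose
intensities say little about anatomy) onto a reference model. The transforms
involved are non-rigid and frequently enormous — pose correction of a curled
embryo tail, articulation of limbs — and intensity-driven registration fails
precisely where the biology is most interesting. An expert can, however,
place corresponding landmarks quickly. `cdt` interpolates a displacement
field from such landmarks with radial basis functions (RBFs):

$$\Delta u_j(\mathbf{x}) = P_j(\mathbf{x}) +
  \sum_{i=1}^{N} \lambda_{i,j}\, \phi\big(d(\mathbf{x}, \mathbf{x}_i)\big),$$

with $P_j$ a first-order polynomial and $\phi$ one of `tps`
($r^2\log r$), `mq` ($\sqrt{r^2+c^2}$), `imq` ($1/\sqrt{r^2+c^2}$) or
`wendland` ($(1-r/c)^4(4r/c+1)$ on $[0,c]$, zero beyond). The coefficients
solve a block design system whose zero upper block enforces
$\sum_i \lambda_{i,j} = 0$ and $\sum_i \lambda_{i,j}\mathbf{x}_i = 0$, so the
far field is controlled by the polynomial alone.

A conventional RBF takes $d$ Euclidean. The **constrained distance
transform** instead takes $d$ to be the *geodesic inside the object's
domain*, computed on a simplicial mesh conforming to that domain. Two points
close in space but far apart along the object are then far apart for the
transform, so the deformation respects object boundaries: the tail can be
straightened without the head noticing. Displacements are evaluated only at
mesh nodes and interpolated barycentrically inside elements, which makes the
transform cheap and piecewise-invertible; pulling values back through a mesh
defined on the atlas domain also segments the assay to the atlas, because
locations outside the mesh are simply never mapped.

# Tunable parameters

| parameter | units | default | meaning |
|---|---|---|---|
| `kind` | — | `imq` | basis; `mq` for the locality comparison, `imq` for atlas registration |
| `delta` | — | 0.05 | support factor; $c = \delta\, r_\max$ with $r_\max$ the largest axis extent of the domain. Useful range 0.001–0.5 (warned beyond); small $\delta$ sharpens, large $\delta$ smooths |
| `use_los` | — | `TRUE` | run the line-of-sight initialisation stage |
| `constrained` | — | `TRUE` | geodesic ($\Rightarrow$ CDT) vs Euclidean distances |
| `target_edge` | length | — | mesh lattice edge; node count scales as (extent/edge)^dim |
| `interp` | — | `linear` | value interpolation; `nearest` for label images |
| `fill` | value | 0 | background for unmapped locations (an `unmapped` mask is always returned as well, since silently absent regions invite wrong conclusions) |

All coordinates are world units: voxel centres sit at
`origin + (index - 1) * spacing`, and every distance, edge length and
displacement is metric, never voxel counts.

# Geodesic distances on the mesh

Stage one (`line_of_sight_init()`) grows a region of elements visible from
the seed. An element queue starts at the seed's element; a queued element's
unvalued node is accepted when the ray from it towards the seed leaves the
element through a facet whose opposite element is already classified visible
— a purely local test. Accepted nodes receive their *exact* Euclidean
distance. The marked set is deliberately conservative (a subset of the truly
visible nodes). Two implementation details matter:

* an element whose nodes all already have distances would never be
  classified by the node rule and could stall the growth even on convex
  domains; such elements are classified by the same ray test from their
  centroid, and neighbours are re-queued whenever an element becomes
  visible. On convex meshes every node is then marked, and the field is
  exact to machine precision.
* ray–facet intersections use a 1e-9 tolerance and test all facets, so
  grazing hits resolve by accepting any qualifying facet.

Stage two (`fast_march()`) propagates first arrivals through the remaining
mesh with a binary-heap fast-marching sweep. The local update at an unknown
node $u$ from the known nodes $p_i$ (distances $d_i$) of one simplex is the
exact minimiser of

$$f(\boldsymbol\lambda) = \textstyle\sum_i \lambda_i d_i +
  \big\lVert x_u - \sum_i \lambda_i p_i \big\rVert,
  \qquad \boldsymbol\lambda \in \Delta,$$

whose interior optimum is the plane-wave (unit-speed Eikonal) arrival and
whose boundary optima are the edge and single-node fallbacks used when the
characteristic leaves the simplex. For obtuse configurations the classical
repair interpolates a virtual node at the perpendicular foot on the known
edge or face; that update is exactly $f$ evaluated at one feasible point, so
the minimisation returns the same or a tighter value while preserving the
two bounds that the tests assert everywhere: every candidate is
$\ge$ the Euclidean distance to the seed (by convexity of the norm) and
$\le$ the edge-graph Dijkstra distance (single-node updates are included in
the minimum). Line-of-sight distances are frozen — they are exact by
construction, so stage two never overwrites them.

Seeds need not be nodes: a seed within $10^{-6}$ of the local edge length of
a node snaps to it; otherwise the containing element's nodes are initialised
with Euclidean distances.

**Why the first stage matters.** A bare point source is a singular
initialisation for any first-order Eikonal solver: the error committed in the
first ring of elements decays only slowly under refinement and is advected
outward. On a convex domain the no-LOS solver converges in the mean but not
uniformly near the seed, whereas the LOS path is exact at every node. On the
corridor fixtures the LOS stage reduces the mean absolute error by an order
of magnitude (0.07% vs 0.8% at $10^4$ nodes), mirroring the morphological
baselines' 2–13% errors — the raster `c4`/`c8`/`oct` region-growing metrics
are provided for exactly this comparison, with the standard calibrations
(city block, chessboard, and strict alternation starting with the full
neighbourhood; isotropic spacing required, since "iteration count × spacing"
is meaningless for anisotropic voxels).

# Meshing

Meshes are generated from binary masks by clipping a structured lattice —
equilateral triangles in 2D, the Freudenthal six-tetrahedra-per-cube
decomposition in 3D — to the domain: elements are kept when their centroid
lies within the one-voxel-dilated mask (dilation computed geometrically, so
it extends past the raster bounds), nodes left outside the mask are snapped
to the nearest foreground-voxel box (capped at two lattice edges), nodes
brought into coincidence by snapping are merged, and elements degenerated or
inverted by snapping are dropped. The result is conforming by construction
and is audited (`audit_conformity()`): positive measures, facets shared by
at most two elements, symmetric neighbour relation.

A constrained Delaunay triangulation of the extracted boundary contour would
give prettier 2D boundaries, but no triangulation library is available in
this toolchain, and the lattice approach has compensating virtues: identical
logic in 2D and 3D, interior triangles exactly equilateral (the friendliest
shape for fast marching), and predictable node-count scaling. External
meshes (e.g. from Netgen or Gmsh) can be imported from Gmsh `.msh` v2, VTK
legacy ASCII or OFF; mixed-element or non-simplicial files are rejected.

# The warp, resampling, and non-bijectivity

`build_warp()` fits the RBF with the appropriate centre–centre distance
matrix — per-landmark geodesic fields evaluated at the other centres and
symmetrised as $(M + M^\top)/2$, since fast marching breaks exact symmetry at
discretisation level — and evaluates it at every node (the polynomial term
always uses coordinates, never distances). Distance fields are cached per
centre, so interactively editing one landmark recomputes exactly one field.

`pullback_resample()` (mesh on the target/atlas) scans each element's raster
cells, interpolates the displaced position barycentrically and samples the
source there; ties on shared facets go to the lowest element index, unmapped
cells get `fill` plus a flag, and the output domain is the mesh footprint —
the segmentation contract. `forward_transform()` (mesh on the source)
rasterises each *displaced* element by scanline and inverts barycentrically;
overlapping displaced elements are resolved last-written-wins in ascending
element order. Fold-overs are permitted by design: one-to-many (duplicated
tail texture) and many-to-one (fused regions) mappings are legitimate
outcomes, and no diffeomorphism is claimed.

# Synthetic fixtures and what they do (not) show

The corridor fixtures (`make_corridor_domain()`) are axis-aligned L- and
U-shaped tubes chosen because their geodesics have closed forms: the
shortest in-domain path is a taut string around the known inner corners, so
`analytic_distance()` is an exact oracle (cross-checked in the tests against
mask-restricted grid Dijkstra from below and Euclidean distances from
above). The raster is constructed so the union of foreground voxel boxes
*equals* the stated rectangles, making oracle and mesh geometry consistent
to machine precision. The tail fixture (`make_tail_fixture()`) is a body
disc plus a curled tail whose tip is ~8× closer to the head in Euclidean
than in geodesic terms, with zero-displacement landmarks around the body and
tail and displaced landmarks at the tip.

These fixtures emulate the *geometric* difficulty of atlas registration —
non-convexity, pose, Euclid-vs-geodesic locality — under exactly known
ground truth. They do not emulate intensity noise, anatomical variability,
imaging artefacts, or landmark placement error; a passing suite certifies
the algorithms' numerical behaviour, not end-to-end accuracy on real
embryos.

The displacement-error study (`displacement_error_study()`) rebuilds the
mesh at several resolutions, fixes one random landmark set (75 landmarks,
displacements uniform in a ball of radius $0.1\,r_\max$, inverse
multiquadric, $\delta = 0.05$ — the atlas-registration configuration) and
compares the RBF evaluated directly at element centroids with the
barycentric interpolation from nodes. Two error definitions circulate for
this comparison; both are computed, with
$\varepsilon = (l_{RBF} - l_{MESH})/l_{RBF}$ (difference of lengths over the
direct length) primary and the normalised error-vector length reported
alongside. The study uses Euclidean distances throughout, because the direct
RBF evaluation at arbitrary interior points is only defined for a distance
function available off-node (constrained distances are computed at mesh
nodes only — a deliberate non-goal). Mean $\varepsilon$ decreases
monotonically with node count and correlates with $N^{-1/3}$ at about 0.97
across five resolutions spanning $8\times10^3$–$10^6$ nodes; the acceptance
script reproduces this end to end (~3 minutes on one CPU; the test suite
runs a slightly reduced top resolution for speed).

# Numerical choices and degenerate inputs

* Design system solved by SVD with a relative cutoff of $10^{-12}$ after
  isotropic rescaling of coordinates and distances to the unit box (the
  anisotropic alternative would distort radial symmetry); rank deficiency
  after the cutoff (e.g. collinear centres with `tps`) is an error, not a
  silent pseudo-inverse.
* Landmarks closer than $10^{-9}$ of the extent, empty domains, degenerate
  (single-row) domains, seeds outside the mesh or mask, anisotropic spacing
  in the raster metrics, and non-positive spacing all fail fast with
  messages naming the offending input.
* `locate_point()` breaks shared-facet ties by lowest element index;
  rasterisation uses the same rule; fold-over resolution is ascending
  element order. All algorithms are deterministic: identical inputs produce
  bit-identical fields, warps and tables, which the tests assert.
* Heap ties in fast marching break by node index; acceptance order is
  monotone up to a relative $10^{-12}$ float tolerance.

# Known limitations

* Geodesic distances exist at mesh nodes only; off-node queries interpolate.
* Mesh quality at snapped boundaries is lattice-limited; no smoothing or
  edge flipping is performed, and image-adaptive refinement is out of scope.
* The corridor geodesic oracle covers rectilinear corridors with up to two
  inner corners per path — exactly what the fixtures need, not a general
  polygon geodesic engine.
* No regularised (approximating) spline option: interpolation is exact at
  landmarks, so landmark errors propagate undamped.
* Timing is reported for orientation only; no performance contract is
  asserted beyond the suite's own budgets.
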