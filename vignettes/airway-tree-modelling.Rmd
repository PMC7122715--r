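---
title: "Modelling extended bronchial trees: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling extended bronchial trees: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lungtree` builds patient-scale structural models of the human conducting
airways. Clinical CT resolves only the first three to four airway
generations; everything distal to that must be inferred. The package takes
the two pieces of information imaging can provide — a binary lung-volume
mask and a short centerline of the visible airways — and from them produces
an extended bifurcating tree, per-generation spatial probability maps,
watertight airway surfaces suitable as CFD boundary conditions, simulated
broncho-constriction, and the morphometric statistics used to judge whether
a generated tree is anatomically plausible.

This vignette documents the algorithms, their tunable parameters, the
numerical choices, and the limits of what the bundled synthetic anatomy can
demonstrate.

## 1. From centerline to rooted tree

The centerline is an undirected spatial graph $G = \{V, E\}$ with vertices
in world millimetres. Three conventions apply throughout the package:

* all geometry is stored in world mm; voxel indices never leave the image
  readers (one unit system prevents silent scale bugs between the image,
  graph and mesh domains);
* indices are 0-based with axis order (x, y, z) in world space, whatever
  the on-disk format's memory order (`read_image()` normalizes MetaImage
  and NIfTI to the same mapping
  `world = origin + direction %*% (index * spacing)`);
* generations count from the trachea at 0, incrementing at every branching
  node.

The inlet (trachea end) is found by walking every chain of degree-$\le 2$
vertices attached to a branching vertex (degree $> 2$) and returning the
free end of the longest such chain, length measured in chain vertices. The
trachea is, anatomically, the longest unbranched run of the centerline
ending at a leaf, so this needs no intensity or orientation information.
Ties break to the lowest terminal vertex id, making the result reproducible
under relabelling up to genuine ties; a pure path (no branching vertex)
falls back to the endpoint on the longer arc side of the path's middle
vertex, with a warning, since the rule's premise is absent.

`to_directed()` orients edges away from the inlet breadth-first, rejects
cycles, and merges degree-2 chains into branch polylines whose arc length
is the branch length. `prune(tree, n)` removes generations beyond `n` and
then trims terminal branches that are only children: every retained distal
branch then ends either at a true endpoint or at a complete bifurcation,
which is what the volume-filling growth needs as seeds.

## 2. Volume-filling tree extension

Each lung is filled independently. The algorithm, per lung:

1. sample `points_per_lung` points uniformly over the labelled lung volume
   (voxel chosen uniformly, position uniform within the voxel);
2. assign every point to the nearest distal branch (Euclidean distance to
   the branch's distal point; ties to the lowest branch id);
3. for each seed branch, split its point set by a plane through the set's
   centroid containing the branch direction $d$: the plane normal is
   $d \times (d \times u_m)$ with $u_m$ the principal eigenvector of the
   covariance of the centred points. Splitting across the direction of
   greatest variance keeps both halves compact and suppresses very long
   branches;
4. for each half, grow one child from the seed's distal point
   `branch_fraction` (default 0.4) of the way to the half's centroid;
5. a child shorter than `terminal_length_mm` (default 2 mm) is terminal:
   it is kept as a branch but its points leave the pool;
6. a child whose distal point or midpoint leaves the lung label is not
   created and its half's points are discarded;
7. repeat until no seed points remain, or until a generation cap (with a
   $2^{n+1}$ bifurcation safety counter) is hit.

Parameter notes:

* `points_per_lung = 30000`. The sample density sets the spatial
  resolution of the growth: the mean inter-point spacing $(V/n)^{1/3}$ is
  about 4.6 mm for a 3 L lung, and termination happens when 40% of the
  tip-to-centroid distance falls below 2 mm, i.e. when a seed's cluster
  has shrunk to a few points. Whether the reference value is per lung or
  per lung pair is ambiguous in the morphometry literature; per lung is
  the default and a single argument switches it.
* `branch_fraction = 0.4` applies at every depth; nothing in the
  underlying model suggests adapting it near terminals, and a constant
  keeps the generator a two-parameter model.
* points are consumed, never reassigned: a terminal or discarded branch
  removes its half from the pool. Reassignment rules would couple distant
  subtrees and make the result order-dependent.
* one integer seed governs the point sampling and every stochastic choice,
  so a run is bit-reproducible.
* `plane_method = "random"` replaces the PCA normal by a random direction
  perpendicular to the branch, for ablation: random planes produce
  measurably longer branches (mean and 99th percentile of grown branch
  length increase), which is the failure mode the PCA plane exists to
  prevent. They also produce more branches overall, so mean point-to-tree
  distance is *not* a faithful metric of this effect; the test suite
  guards the branch-length property instead.

Degenerate point sets are handled explicitly: a single-point seed grows a
single child toward that point; a two-point seed splits along the segment
between them; a principal direction parallel to the branch (cross product
below $10^{-8}$) falls back to a fixed perpendicular with a warning.

### Left/right lung assignment

`split_lungs()` separates the two 26-connected foreground components and
names them with the one piece of airway topology that distinguishes the
sides: the path from the carina to the next bifurcation (the main-bronchus
arc length) is longer on the left. The component nearest the distal point
of the longer first-generation branch becomes label 2 (left); the other,
label 1 (right). Internally the mask is eroded with the strict
26-neighbour rule, the cores are labelled by deterministic region growing,
and the eroded boundary layer is restored by nearest-label propagation
(ties to the lower label), which keeps the foreground volume unchanged and
makes the labelling independent of any visit order. A mask without exactly
two components, or a tree without second-generation bifurcations, is an
error rather than a guess.

## 3. Spatial probability maps

For generation $g$, every voxel $x$ of the reference grid gets
$W_g(x) = \frac{1}{\sigma\sqrt{2\pi}} e^{-d^2/2\sigma^2}$, with $d$ the
distance from the voxel centre to the closest generation-$g$ centerline
*segment* (not vertex). $\sigma$ defaults to 1 and is in millimetres, so
the map is resolution-independent; a voxel-unit $\sigma$ would change
meaning with every resampling. The computation is exact (every segment is
scanned); no per-generation normalization is applied, because the map is a
per-generation density, but `normalize_map()` rescales to $[0,1]$ for
overlay export.

## 4. Diameters and surfaces

Two diameter models are provided. The symmetric power law
$d_z = d_0 \cdot 2^{-z/3}$ makes diameter a function of generation alone
(per-generation ratio exactly $2^{1/3}$). The asymmetric model applies,
at each bifurcation, the cross-section conservation law
$d_0^n = d_1^n + d_2^n$ with the asymmetry ratio $r = d_1/d_2$ taken from
the terminal counts of the two child subtrees (a flow proxy: the larger
subtree receives the larger child). The exponent defaults to $n = 2$, the
printed area-conserving form; $n = 3$ selects the classic cube law, under
which an equal split reproduces the power law exactly.

A caveat worth documenting: the branching-angle relation
$d_0^2/\sin(\theta_1+\theta_2) = d_1^2/\sin\theta_1 = d_2^2/\sin\theta_2$
is the law of sines of a triangle with sides $(d_0^2, d_1^2, d_2^2)$, and
it only has a solution with angles in $(0°, 90°)$ when
$d_1^2 + d_2^2 > d_0^2$ *strictly*. Diameters that satisfy the $n = 2$
conservation law exactly therefore admit only the degenerate zero-angle
solution; `solve_branching_angles()` reports this as an error, and
`kamiya_children()` degrades to zero angles with a warning. The solver is
intended for measured diameter triples, which in real airways satisfy the
strict inequality. Note also that, as printed, the relation gives the
*larger* child the larger angle.

Surface generation samples a point cloud uniformly on each branch's
cylinder (count ∝ lateral area $\pi d L$ at `density` points/mm²,
default 40), with outward radial normals, plus sampled end-cap disks at
the trachea inlet and terminal outlets so the cloud bounds a closed
volume. The cleanup step deletes points lying strictly inside another
branch's tube — distance to that branch's centerline below its *radius*
(a point at exactly one radius is on the surface, so "radius" rather than
"diameter" is the geometrically consistent reading) less a $10^{-6}$ mm
tolerance — leaving the outer envelope of the union of tubes.

Reconstruction proceeds from the oriented cloud: bilateral normal
smoothing (spatial Gaussian times a normal-similarity Gaussian,
neighbours facing the opposite way excluded, so creases survive while
junction noise is averaged out), then a signed scalar field on a regular
grid — the distance to the nearest surfel, signed by that surfel's normal
— polygonized at its zero level set by marching tetrahedra. Each grid cube
splits into the six tetrahedra around its main diagonal, a decomposition
whose face diagonals agree between neighbouring cubes, and iso-vertices
are shared exactly through grid-edge keys, so the output is watertight by
construction whenever the level set stays inside the grid. Two numerical
guards matter: iso-vertices are clamped a fraction $10^{-3}$ into their
grid edge, so vertices of different edges can never coincide and produce
zero-area faces that would open the surface; and the outermost grid layer
(which lies beyond the padding, hence outside the cloud) is pinned
positive, because the single-nearest-surfel sign is unreliable far from
the surface at grazing angles. Spurious far-field blobs become closed
shells and are removed with all but the largest connected component. The
screened-Poisson family of reconstructions would serve the same role;
the signed-field-plus-polygonizer route was chosen because it is exact,
dependency-free and adequate for tubular geometry, and the package's own
contribution here is the sampling, cleanup and normal handling either
way.

Grid spacing defaults to 1/80 of the largest cloud extent (bounded below
by half the median point spacing); finer grids recover thin branches at
cubically growing cost. Surfaces for CFD normally use the first 5–7
generations.

## 5. Broncho-constriction

Constriction is a constrained Laplacian contraction. The operator is the
cotangent Laplacian: $\delta = LV$ approximates $-4A_i\kappa_i n_i$ (area
times mean-curvature normal), which is insensitive to mesh density. One
step solves the stacked least-squares system
$\left[\begin{smallmatrix}W_L L\\ W_H\end{smallmatrix}\right] V' =
\left[\begin{smallmatrix}0\\ W_H V\end{smallmatrix}\right]$
via its normal equations (one sparse SPD solve per coordinate), then
updates $W_L \leftarrow s_L W_L$ and
$W_{H,i} \leftarrow W_{H,i}^0 \, A_i^0/A_i^t$. Defaults: $W_L$ starts at
$k \bar A$ with $k = 10^{-3}$ and $\bar A$ the mean face area; $W_H$
starts at the identity; $s_L = 2$ (the value used throughout the
contraction-skeleton literature this operator family comes from — the
update rule itself does not fix it). The attachment term is implemented
as the squared norm $\|V - V_a\|^2$; only the squared form yields the
stated linear system. The area-ratio update is applied as printed; a
square-root variant common in prior work sits behind `wh_sqrt = TRUE`.
One-ring areas are barycentric (a third of incident face area) rather
than Voronoi: they are strictly positive for obtuse triangles, and the
area definition only scales the curvature magnitude and the $W_H$ update,
not the flow direction.

Diameter monitoring uses the shape diameter function: rays from each face
centroid into a 120° cone (30 rays, deterministic spiral, uniform in
angle) around the inward normal; the face's value is the inverse-angle
weighted median of the exit distances, so near-axial rays — the local
diameter — dominate over oblique chords. `constrict()` pins all vertices
outside the chosen region (attachment weight $10^8$; they move by less
than $10^{-6}$ mm), iterates, and stops once the region's median SDF
falls to `target_fraction` of its initial value; SDF is the primary
criterion, with the enclosed volume logged per iteration. A step that
overshoots the target by more than the tolerance is retried from the
previous state with half the contraction weight, so the achieved fraction
lands near the request. With the gentle default $k$, the first iterations
move the surface imperceptibly and narrowing accelerates as $W_L$ doubles;
a near-unity target therefore takes several iterations to register rather
than terminating immediately. On large meshes the monitor evaluates an
evenly-spaced subsample of at most `max_monitor_faces` region faces —
the median over 400 faces is the same statistic at a fraction of the
ray-casting cost. The region must be a connected patch: pinning the
complement of a scattered face set freezes it. It should also be at least
a few lumen diameters long: with both ends of the region pinned, the
limiting shape of the contraction is a smooth waist spanning the pinned
rings, so a band much shorter than its diameter stalls at a shallow
narrowing (the attachment weights, which grow with the inverse one-ring
area ratio, then hold it there), while a longer band narrows to deep
fractions of the initial diameter.

## 6. Morphometry

Terminal branches have order 1 in both ordering schemes; a Strahler
parent takes the larger child order when the children differ and
increments it when they agree, while a Horsfield parent is always one
plus the maximum child order (so Strahler ≤ Horsfield everywhere, and a
chain of single children keeps its Strahler order but climbs in
Horsfield). Branching, diameter and length ratios are the antilog of the
log-linear regression slope of (count, mean diameter, mean length)
against order — the standard morphometric convention; a
mean-of-successive-ratios estimator is available via `method =
"successive"` for sensitivity checks, since published tables rarely state
which was used. The per-generation diameter decline is the mean over
generations of mean-diameter$(g{+}1)$/mean-diameter$(g)$ (matching the
mean ± sd form such tables print); for purely generation-determined
power-law diameters this is exactly $2^{-1/3} \approx 0.794$ at every
generation, which is the analytic floor of that statistic. Branching
angles pool both children of every bifurcation (angle between child and
parent chord directions, degrees).

## 7. The synthetic anatomy, and what it can and cannot show

`make_phantom()` builds two half-ellipsoid lungs (flat faces medial,
30 mm mediastinal gap; craniocaudal and anteroposterior semi-axes 1.85×
and 1.35× the lateral one — loose adult proportions) whose voxelized
volume must match the request within 2%, plus a seed tree with a ~100 mm
trachea and bifurcating generations down to depth 3, the left
main-bronchus path longer than the right as in real anatomy. Everything
the test-suite and the acceptance script measure runs on this phantom at
6 L total volume, 2 mm spacing, 30000 points per lung.

What the phantom reproduces: adult-scale volumes and branch lengths, the
left/right asymmetry the splitting rule needs, a seed tree whose distal
points all lie inside the mask. What it does not: lobar boundaries and
fissures, the concave diaphragmatic and mediastinal surfaces, cartilage
rings, and the deeper (6–7 generation) seed trees obtainable from good
CT. Consequences observed with the identical algorithms: branching
ratios, diameter ratios, diameter decline and mean branching angle land
within a few percent of CT-derived reference values, but the terminal
count settles around twenty thousand rather than the low thirties of
thousands — on a convex volume each terminal event absorbs a ~3-point
cluster, which bounds terminals near one third of the sample size.
Passing the phantom-scale checks therefore demonstrates algorithmic
correctness and the right statistical regime, not patient-level
anatomical fidelity.

Problem sizes used by the checks were chosen to keep a full run on one
CPU in the low minutes: 6 L phantom at 2 mm (~0.75M foreground voxels),
five growth replicates of 60000 points each, reconstruction grids near
one million cells, SDF monitoring on a few hundred faces.

## 8. Known limitations

* Growth is purely geometric: no host-specific asymmetry constraints, no
  lobar-boundary awareness, no gravity or posture effects.
* The signed-field reconstruction needs a sampling density high enough
  that the nearest surfel is unambiguous at the grid scale; severely
  under-sampled clouds produce open shells, reported as errors rather
  than repaired.
* Trifurcations in the input seed are preserved by the graph layer
  (generation still increments once per branching node) but the grower
  and the asymmetric diameter model treat only the two largest subtrees
  specially.
* The constriction solver assumes a manifold mesh; non-manifold input
  fails at the Laplacian stage.

## 9. A minimal end-to-end run

```{r example}
library(lungtree)

ph <- make_phantom(total_volume = 6, spacing = 2, depth = 3)
tree <- extend_tree(ph$mask, ph$tree, points_per_lung = 30000, seed = 1)
tree <- assign_diameters(tree, d0 = 16, mode = "murray")
summarize_morphometry(tree)

pm <- generation_map(tree, ph$mask, g = 4, sigma = 1)
write_image(normalize_map(pm), "w4.nii.gz")

proximal <- assign_diameters(prune(tree, 3), d0 = 16)
cloud <- cleanup_inner_points(sample_tube_cloud(proximal, density = 40,
                                                seed = 1), proximal)
mesh <- reconstruct_surface(cloud)
write_mesh(mesh, "airway.ply")
```
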