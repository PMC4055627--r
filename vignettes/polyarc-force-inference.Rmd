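---
title: "Inferring cellular forces from curved cell boundaries"
author: "arcforce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cellular forces from curved cell boundaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcforce)
```

## The model

arcforce treats a planar cell monolayer as a quasi-static mechanical system
governed by exactly two kinds of forces: a uniform contractile tension
$\gamma_{ij}$ along each cell--cell interface, and a uniform effective
pressure $p_i$ within each cell.  Viscous forces, tractions and
out-of-plane loads are assumed negligible; these assumptions restrict the
method to slowly deforming tissues and exclude, for example, ablation
recoil transients.

Two families of equilibrium statements follow.  At every junction the
limiting tangent vectors $\hat{u}$ of the incident edges, each pulling away
from the junction with magnitude $\gamma$, must balance:
$$\sum_{\text{edges } ij \ni A} \gamma_{ij}\, \hat{u}_{ij}^A = \mathbf{0},$$
giving two scalar equations (x and y) per junction.  Along every interface
the Laplace relation couples the pressure jump to tension and curvature:
$$p_i - p_j = \gamma_{ij} / \rho_{ij} = \gamma_{ij}\,\kappa_{ij},$$
with $\rho$ the arc radius, positive when the edge bulges into cell $j$.
Because the edges are curved, the junction system is generally
*overdetermined* (each new cell closes a loop that adds more equations than
unknowns), which is what makes the inverse problem stable; straight-edge
(minimal polygon) approximations lose both the pressure equations and much
of this redundancy.

Both systems are scale-deficient: the tension equations are homogeneous,
and the pressure equations determine only differences.  We therefore solve

$$\min_\gamma \|G_\gamma \gamma\|^2 \ \text{s.t.}\ \bar\gamma = 1,
\qquad
\min_p \|G_p p - q\|^2 \ \text{s.t.}\ \bar p = 0,$$

via the KKT block system
$\begin{pmatrix}2G^TG & c\\ c^T & 0\end{pmatrix}
 \begin{pmatrix}x\\ \lambda\end{pmatrix} =
 \begin{pmatrix}2G^Tq\\ d\end{pmatrix}$,
with $c = \mathbf{1}/N$ so that the Lagrange multipliers are well scaled
(they are exported with the solution).  The results are the *Standard
Tensions* $\gamma^*$ (mean one) and *Standard Pressures* $p^*$ (mean
zero); every physically consistent solution is
$\gamma = \alpha\gamma^*$, $p = \alpha p^* + \beta$, where the tension
scale $\alpha$ and pressure offset $\beta$ must come from information
external to the image (`generalSolution()`, `standardizeSolution()`).
Tensions and pressures are solved sequentially, never jointly; junctions
connected through retained edges form one tension system each, and
pressure systems are assembled only from edges within a single tension
component (mixing components would mix normalization gauges).  A dense KKT
solve is the primary path, with a singular-value fallback when the KKT
matrix is ill-conditioned; truly rank-deficient geometry raises an error
carrying the condition number.  Negative inferred tensions are reported
with a warning, never clipped, so that diagnostics stay unbiased.

## Geometry extraction

Each edge is an ordered chain of nodes.  A circular arc is fitted to the
chain by the Kasa algebraic fit refined with one Gauss--Newton pass on the
geometric distances; an edge is straight when it has two points, is
collinear within tolerance, or its sagitta-to-chord ratio falls below
`straightnessTol` (default `1e-3`, dimensionless; exposed everywhere).
The limiting tangent at a junction is the tangent of the fitted circle at
its closest approach to the junction, oriented away from it; the
orientation is disambiguated against a point about 30% along the chain,
which is robust to pixel-staircase noise yet safe for any edge up to a
semicircle (cell edges in this model never exceed a semicircle).  Two
coarser angle variants are provided for comparison studies:
`closest_segment` (direction of the chain segment adjacent to the
junction) and `minimal_polygon` (the straight chord).  Chains with only
two nodes are straight by construction and carry no usable curvature, so
they never contribute pressure equations.

## Quality diagnostics

`diagnoseSolution()` reports, per connected component, the condition
number of the constraint-augmented matrix $[G; c^T]$ (the mean constraint
removes the intrinsic rank deficiency of one; the full KKT conditioning is
tracked separately inside the solver), per-junction tension residual
vectors normalized by the mean tension, per-edge pressure residuals
converted to forces by the edge chord length, and covariance standard
errors.  For the standard errors the constraint is eliminated by an
orthonormal reduced parametrization ($n-1$ effective parameters), the
residual variance is $\hat\sigma^2 = \|r\|^2/(m - (n-1))$, and the
covariance is mapped back to the full parameter set; systems with
$m \le n-1$ are flagged rather than reported.  The display convention for
residual rendering (a normalized residual of one spans one mean cell
radius, computed as the mean of $\sqrt{A/\pi}$ over complete cells) is
reported as a scale factor alongside the numbers.

## The synthetic forward model

Validation needs tissues whose true forces are known.  `syntheticTissue()`
builds them in four stages.

1. **Tessellation.** `nCells` seed points are placed uniformly in a square
   of side $\sqrt{n}$ (unit mean cell area) and regularized by two Lloyd
   steps to avoid sliver cells; the bounded Voronoi diagram becomes the
   initial mesh, with (by default) 4 intermediate nodes per edge.
2. **Types and tensions.** Cells are assigned i.i.d. uniformly to three
   types; the six unordered type pairs map to interface tensions
   5:6:7:10:11:12 (sorted-pair order 1-1, 1-2, 1-3, 2-2, 2-3, 3-3, a
   convention exposed through `tensionTable`).  Medium-facing edges take
   the homotypic value of their cell — they are rare because analyses use
   interior regions.
3. **Annealing.** Node positions are relaxed to a minimum of
   $E = \sum_e \gamma_e \ell_e + \sum_c \tfrac{k}{2}(A_c - A_{0,c})^2/A_{0,c}$
   by L-BFGS-B with analytic gradients, the patch boundary pinned so that
   interior equilibria exist.  The emergent pressures are
   $p_c = k (A_{0,c}-A_c)/A_{0,c}$.  Area stiffness $k = 100$ (tension
   units per length) makes inter-cell area deviations of a few percent
   carry pressure differences of order $\gamma$ over a cell diameter, i.e.
   clearly visible but moderate edge curvatures, as in epithelia.
   Because node spacing along an edge is energetically indifferent, chains
   are re-sampled to uniform spacing between optimization rounds; counts
   never shrink, and the default spacing includes a 0.72 shrinkage
   allowance so the equilibrated tissue averages about 4 intermediate
   nodes per edge.  Heterotypic tension ratios drive some edges to zero
   length, where no fixed-topology equilibrium exists; such edges undergo
   a T1 neighbour exchange (contract, re-open perpendicular, re-assign the
   interface tension from the new type pair), with contraction into a quad
   junction or rosette as the fallback for edges that keep flip-flopping.
   Both outcomes are genuine equilibria and both junction types are fully
   supported by the inference equations.  Convergence demands a maximum
   residual nodal force below `forceTol` (default $10^{-3}$) times the
   mean tension; non-convergence is an error.
4. **Extraction.** A centered window sized to retain a target number of
   complete cells (default 50) is cut out: neighbour cells become partial,
   continuation edges hanging off retained junctions are kept but
   truncated shortly outside the window, producing the characteristic
   frayed boundary of stub edges.  Every retained junction keeps its full
   complement of edges — anything less would silently violate its force
   balance.  The ground truth is restricted to the kept edges and cells.

What the generator does *not* emulate: real segmentation artifacts
(mis-tracked membranes, over/under-segmentation), curvature of the tissue
out of plane, tractions, and temporal dynamics.  Passing the synthetic
checks therefore demonstrates correctness of the inverse machinery and its
noise response, not robustness to every failure mode of real imaging.

## Measurement noise and error metrics

Noise level $x$ adds independent Gaussian errors of RMS $x$ degrees to
every limiting-angle measurement (each edge end separately) and
multiplicative Gaussian errors of RMS $x$ percent to every curvature —
perturbing the measurements, not the node coordinates.  Accuracy is
summarized by the RMS difference between inferred and true Standard
Tensions as a percentage of the mean true tension, and the RMS pressure
difference as a percentage of the RMS true pressure; both sides are
standardized over the compared sets first.  When exclusions fragment the
mesh, the comparison is restricted to the largest connected component:
relative scales between disconnected components are not knowable from an
image, so mixing them would conflate gauge freedom with error.

`runValidation()` sweeps angle methods (including polyarc with
no-intermediate-node edges excluded) against noise levels
$\{0, 1, 2, 5\}$ with seeded replicate noise draws and reports
mean $\pm$ sd of both metrics.

## Rasterization and re-digitization

To emulate pixelation, `rasterizeRedigitize()` draws every edge as a dense
spline onto an image covering the extraction window (the frame truncates
the frayed continuations, as a micrograph would), labels the enclosed
regions (4-connected), grows the labels over the one-pixel lines by
Voronoi propagation (watershed-style relabeling), matches regions to the
original cells — grid samples inside complete-cell polygons, points just
inside each kept edge for partial cells — and re-extracts a mesh from the
label image.  Unmatched slivers are treated like the out-of-frame
sentinel, so their boundaries never become spurious edges.

Boundary chains recovered from pixels are one-pixel staircases, so
`meshFromLabels()` applies endpoint-preserving 1-2-1 smoothing (default 16
passes, an effective Gaussian of roughly 2.8 px) before arc fitting, and
the re-digitization analysis additionally (i) excludes edges shorter than
10 px or with arc-fit RMS above 0.7 px — the "short, poorly defined or
crenulated" exclusions the overdetermined equations are designed to
absorb, (ii) trims 3 chain points at each end before fitting (corners
adjacent to a junction are the least reliable), and (iii) uses no
curvature from edges shorter than 30 px for pressure equations, the same
reliability logic that excludes stubs.  These pixel-scale defaults were
chosen once on synthetic round trips at 675 px width and are all exposed
as arguments.  Pressures inferred on a pixel mesh are per pixel and are
converted through the mesh `lengthScale` before any comparison.

## Numerical choices and degenerate inputs

* Junction identity: edge endpoints sharing a node id (mesh input) or the
  same lattice corner (image input) are one junction; sub-pixel
  coincidence after segmentation is not meaningful.
* Double junctions contribute two equations over two unknowns; collinear
  tangents there reduce to one effective equation, absorbed by least
  squares.  Junctions left with fewer than two retained edges after
  exclusions are dropped with a warning.
* The medium, when present, is the single partial cell with id 0.
* Stub edges keep their tension unknowns (their junction equations cost
  nothing) but never enter pressure equations.
* All angles are radians internally; meshes live in mathematical (y-up)
  coordinates, and image readers flip the row axis.

## Problem sizes used in the shipped checks

The validation ensembles regenerate the study design — 120-cell annealed
patches, three cell types, tensions 5:6:7:10:11:12, windows retaining
about 50 complete cells with roughly 200 edges — with 10 tissues for the
noise-free ensembles, 100 seeded draws for the noise-5 protocol on one
tissue, and one 675-px re-digitization round trip.  Unit tests use smaller
tissues (about 15 complete cells) where only correctness, not ensemble
statistics, is at stake.

## Known limitations

* The quasi-static, tensions-plus-pressures model: no viscosity,
  tractions, stress-fiber anisotropy or 3-D effects.
* Forces are relative: $\alpha$ and $\beta$ require external calibration.
* Island topologies (a cell fully enclosed by another) are flagged and the
  enclosing cell demoted to partial rather than modeled.
* The annealer resolves persistent short-edge instabilities by T1 exchange
  or rosette formation; it does not follow the physical dynamics of the
  transition, only its equilibrium outcome.
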