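---
title: "Laplace-Dirichlet rule-based fiber generation: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laplace-Dirichlet rule-based fiber generation: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldrbm)
```

## The problem

Cardiac electrophysiology and mechanics models need the local myofiber
architecture — the cardiomyocyte long-axis direction $\mathbf{f}$, the sheet
direction $\mathbf{s}$ and the sheet-normal $\mathbf{n}$ — at every point of a
patient- or template-specific myocardial mesh. Direct imaging of fibers is
rarely available, so rule-based surrogates are standard practice.
Laplace-Dirichlet Rule-Based Methods (LDRBMs) derive the anatomical reference
directions from harmonic potentials with Dirichlet data on labeled anatomical
surfaces, then rotate them to match histological observations. This package
implements that pipeline for labeled tetrahedral and hexahedral meshes of
ventricular and spherical slabs, based and complete left ventricles, and left
atria.

## The model

All variants share five steps.

**1. Labeled mesh.** The myocardial domain $\Omega$ comes with a boundary
partition $\partial\Omega = \Gamma_\mathrm{epi} \cup \Gamma_\mathrm{endo}
\cup \Gamma_\mathrm{base} \cup \Gamma_\mathrm{apex}$ (plus valve/vein rings
for atria and complete ventricles), encoded as integer facet labels.

**2. Transmural direction.** The wall-depth potential $\phi$ solves
$-\Delta\phi = 0$ in $\Omega$ with $\phi = 1$ on $\Gamma_\mathrm{epi}$,
$\phi = 0$ on $\Gamma_\mathrm{endo}$ and homogeneous Neumann conditions
elsewhere; the unit transmural direction is
$\hat{e}_t = \nabla\phi / \lVert\nabla\phi\rVert$.

**3. Apico-basal (normal) direction.** A vector field $\mathbf{k}$ pointing
from apex to base, computed by one of four approaches:

* *Rossi-Lassila (RL)*: $\mathbf{k} = \mathbf{n}_\mathrm{base}$, the constant
  outward normal to the basal plane;
* *Bayer-Trayanova (BT)*: $\mathbf{k} = \nabla\psi$ with $\psi$ harmonic,
  $\psi = 1$ on the base and $\psi = 0$ at the apex (surfaces or points);
* *Doste*: $\mathbf{k} = w\,\nabla\psi_\mathrm{ab} +
  (1-w)\,\nabla\psi_\mathrm{ot}$, blending the mitral-ring-driven and
  aortic-ring-driven potentials with a harmonic weight $w$ ($w = 1$ on the
  mitral ring and at the apex, $w = 0$ on the aortic ring);
* *atrial bundles*: three auxiliary potentials assign each vertex to the
  mitral, left-vein, right-vein or default bundle and pick the matching
  gradient (details below).

**4. Local frame.** Per vertex,
$\hat{e}_n = (\mathbf{k} - (\mathbf{k}\cdot\hat{e}_t)\hat{e}_t) /
\lVert\cdot\rVert$ and $\hat{e}_l = \hat{e}_n \times \hat{e}_t$, giving the
orthonormal right-handed triad $Q = [\hat{e}_l, \hat{e}_n, \hat{e}_t]$.

**5. Axis rotation.** $\hat{e}_l$ rotates counter-clockwise about
$\hat{e}_t$ by the helical angle $\alpha$, and the transmural direction
rotates counter-clockwise about the longitudinal axis by the sheetlet angle
$\beta$, producing $[\mathbf{f}, \mathbf{n}, \mathbf{s}]$. Both angles vary
linearly across the wall: $\alpha(\phi) = \alpha_\mathrm{endo}(1-\phi) +
\alpha_\mathrm{epi}\phi$, likewise for $\beta$. Atrial runs skip the
rotation entirely: $[\mathbf{f}, \mathbf{n}, \mathbf{s}] =
[\hat{e}_l, \hat{e}_n, \hat{e}_t]$.

## Parameters that matter

| Parameter | Units | Default | Notes |
|---|---|---|---|
| `alpha endo`, `alpha epi` | degrees | −60, +60 | physiological transmural helical range (endocardium to epicardium) |
| `beta endo`, `beta epi` | degrees | 0, 0 | sheetlet inclination |
| `alpha/beta * OT` | degrees | same as standard | outflow-tract variants (complete LV) |
| `Tau bundle MV/LPV/RPV` | – | 0.15 | atrial bundle extents, in [0, 1] |
| `Scaling factor` | – | 1 | unit conversion on mesh read (1e-3 for mm meshes) |
| `Tolerance`, `Max iterations` | – | 1e-10, 10⁴ | CG solver controls |

All quantities are treated as SI (meters) after scaling. Angles are degrees
in every user-facing interface and radians internally.

## Numerical choices

* **Discretization.** Continuous degree-1 finite elements only: P1 on
  tetrahedra (closed-form constant gradients) and Q1 trilinear on hexahedra
  with 2×2×2 Gauss quadrature. Higher degrees are rejected with a clear
  error; nothing in the pipeline needs them, and degree 1 keeps gradient
  recovery simple and exactly linear-preserving — which is what makes the
  analytic slab checks sharp.
* **Linear solver.** Jacobi-preconditioned conjugate gradients on the
  symmetrically reduced system (Dirichlet rows/columns eliminated), zero
  initial guess, relative residual tolerance $10^{-10}$, at most $10^4$
  iterations. Deterministic by construction; two runs on the same inputs are
  bit-identical.
* **Point constraints.** Apex and pole conditions are prescribed at the mesh
  vertex nearest to the given coordinate, one degree of freedom each.
* **Gradient recovery.** Cell gradients (quadrature-averaged on hexahedra)
  are averaged to vertices with cell-volume weights — the standard lumped
  recovery, exact for globally linear fields.
* **Degenerate frames.** Where $\mathbf{k}$ is numerically parallel to
  $\hat{e}_t$ (relative tolerance $10^{-10}$), $\mathbf{k}$ is replaced by
  the average over adjacent non-degenerate vertices. At structurally
  singular vertices — the apex of an axisymmetric ventricle, where the
  neighbor average itself cancels to a transmural vector — the normal
  direction is chosen deterministically by projecting the first coordinate
  axis not parallel to $\hat{e}_t$. Such vertices stay flagged in the
  result's degeneracy mask; the triad remains orthonormal there, but its
  azimuth is a convention, as it must be at a singularity of the rule.
* **Rotation convention.** "Counter-clockwise" is the right-hand rule about
  the stated axis, implemented with the Rodrigues formula. The $\beta$
  rotation is applied about the $\alpha$-rotated longitudinal axis
  $\mathbf{f}$ (not the unrotated $\hat{e}_l$): this keeps the map
  $Q \mapsto [\mathbf{f},\mathbf{n},\mathbf{s}]$ a pure rotation, hence the
  output triad exactly orthonormal, and coincides with rotating about
  $\hat{e}_l$ whenever $\alpha = 0$. The alternative reading (rotating about
  the unrotated axis) differs only at third order in the angles and does not
  preserve orthonormality when composed naively.
* **Angle law coordinate.** The rotation laws are evaluated directly in the
  computed potential $\phi$, not in a re-parametrized wall-depth coordinate;
  the laws are stated in $\phi$ and the two coincide on slabs.

## Atrial bundle scheme

The published unified-LDRBM literature defers the atrial bundle-selection
details to its source reference; the scheme below is this package's
documented convention. Three potentials are solved: $\psi_\mathrm{ab}$
(1 on the mitral ring, 0 at the apex point), $\psi_v$ (1 on the left vein
ring, 0 on the right), and $\psi_r$ (1 on the mitral ring, 0 on both vein
rings). Each vertex is then classified in fixed order with thresholds
$\tau \in [0,1]$:

1. mitral bundle if $\psi_r > 1 - \tau_\mathrm{mv}$, with
   $\mathbf{k} = \nabla\psi_r$;
2. else left-vein bundle if $\psi_v > 1 - \tau_\mathrm{lpv}$, with
   $\mathbf{k} = \nabla\psi_v$;
3. else right-vein bundle if $\psi_v < \tau_\mathrm{rpv}$, with
   $\mathbf{k} = \nabla\psi_v$;
4. else the default apico-basal bundle, $\mathbf{k} = \nabla\psi_\mathrm{ab}$.

The comparisons are strict, so a threshold of zero disables its bundle
entirely (every vertex falls through to the default), which gives the scheme
a clean degenerate limit. For the idealized atrium (no appendage) the apex
point defaults to the mesh vertex farthest from the mitral-ring centroid; an
explicit `Apex` parameter always takes precedence.

For the complete left ventricle, the outflow-tract angle variants are
blended with the same Doste weight: the effective endpoint angles are
$w\cdot(\text{standard}) + (1-w)\cdot(\text{OT})$ per vertex, so the OT
values take over smoothly near the aortic ring where $w \to 0$. The
published description states that OT-specific angles exist but not how they
are blended; the harmonic weight is the natural interpolant already present
in the model.

## Synthetic geometries

The package generates its own labeled meshes so the entire pipeline is
testable without external data:

* `make_slab()` — structured axis-aligned slab; endocardium/epicardium on
  the lateral walls ($x = 0$ / $x = L_x$), base-up/base-down on the top and
  bottom faces. Defaults: 24 mm wall thickness, 40×40 mm in plane — a
  ventricular-wall-like block whose 6 mm coarse discretization has a
  four-element transmural resolution, matching the scale regime of published
  slab benchmarks (the literature does not print the slab's physical
  dimensions, so these are the package's fixed choice). The tetrahedral
  variant splits each hexahedron into six tetrahedra with the Kuhn
  decomposition, whose translation-invariant face diagonals make structured
  grids conform.
* `make_shell()` — spherical shell from a pole-aligned subdivided
  icosahedron, radially extruded into prisms and split to tetrahedra with an
  index-consistent rule; optional spherical-cap holes with labeled rims model
  the mitral and pulmonary-vein rings of an idealized atrium.
* `make_lv()` — truncated-ellipsoid left ventricle on a structured
  (transmural, colatitude, longitude) grid with a collapsed apex pole,
  labeled endo/epi/base, with the epicardial apex coordinate reported.

What these fixtures emulate is the boundary-label topology and the harmonic
structure of the real geometries; what they do not emulate is anatomical
irregularity — wall-thickness variation, trabeculation, non-axisymmetric
valve rings, mesh-quality heterogeneity of image-derived meshes. Tests
passing on the fixtures therefore validate the algorithmic pipeline and its
convergence behaviour, not anatomical fidelity on patient data.

## The mesh-sensitivity protocol

Because the output triads are orthonormal, two discretizations of the same
problem can only differ in orientation, so the natural error measure is the
angle $\Delta\theta = |\arccos(\mathbf{f}_i \cdot \mathbf{f}_\mathrm{ref})|$
between a coarse fiber field and the field on the finest mesh of a
refinement family, evaluated at the finest mesh's vertices.
`sensitivity_study()` runs the generator on each level, interpolates each
coarse field to the reference vertices (element shape functions, then
renormalization — the direction of an interpolated orientation field is the
meaningful quantity) and reports average and maximum $\Delta\theta$ per
level, together with the average edge length in millimeters and the vertex
(dof) count.

Two protocol details are deliberate:

* Coarse fields are evaluated at fine vertices, not vice versa: the
  reference is defined pointwise where it is richest.
* The default slab refinement family (`scripts/acceptance.R` and the
  acceptance tests) uses subdivision counts $(4,7,15,31)\times(7,13,27,53)^2$
  — levels that approximately halve the edge length but are *not* nested.
  On a structured box, both potentials are linear and every level's nodal
  fiber field is exact; with exactly nested grids each fine vertex sits at a
  coarse node or cell midpoint, where renormalized interpolation of the
  rotating field is exact by symmetry, and $\Delta\theta$ collapses to
  solver round-off with no meaningful trend. Non-nested levels place fine
  vertices at generic positions inside coarse cells, so $\Delta\theta$
  measures the genuine interpolation error of the rotating orientation
  field, which decays at second to third order — the convergent behaviour
  the protocol exists to demonstrate.

A related numerical floor: for two bit-identical unit vectors,
$\arccos(\mathbf{a}\cdot\mathbf{b})$ evaluated in double precision can
return up to $\approx 10^{-6}$ degrees rather than zero (the arccosine is
infinitely steep at 1). Tests that assert "no difference" therefore check
the vector fields componentwise and treat angular values below $10^{-5}$
degrees as zero.

## Problem sizes used by the tests

The acceptance tests and `scripts/acceptance.R` run the slab family up to
$31\times53\times53$ cells ($\approx 9.3\times10^4$ vertices, half a million
tetrahedra in the tetrahedral variant) — comfortably in the asymptotic
regime for this problem while keeping a full suite run around a minute on
one core. The shell convergence study uses icosphere subdivisions 2–4 with
proportionally refined radial layers. These sizes are the package's choice
of a demonstrative resolution ladder; the pipeline itself has no intrinsic
size limits beyond memory.

## Known limitations

* Degree-1 elements only; no adaptive refinement, no parallel assembly.
* ASCII Gmsh `.msh` input only (versions 2.2 and 4.1); binary files are
  rejected with a message.
* Output is ASCII VTU (ParaView-native XML); one file per run.
* The atrial bundle scheme and the OT angle blending are documented
  conventions of this package (see above), not reproductions of unpublished
  details.
* Bi-ventricular support is by tag composition on the based-ventricle RL
  path (treat the right septal endocardium as epicardium), not a dedicated
  geometry type.
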