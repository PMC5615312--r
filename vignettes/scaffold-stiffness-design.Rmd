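---
title: "Designing porous scaffolds by voxel FE homogenization: methods and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing porous scaffolds by voxel FE homogenization: methods and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`scaffoldFE` estimates the effective Young's modulus of porous
tissue-engineering scaffolds built from cubic unit cells, and maps each
design onto the matrix-stiffness bands that direct mesenchymal stem-cell
differentiation (neurogenic 0.1–1 kPa, myogenic 8–17 kPa, osteogenic
≥ 25 kPa). This vignette is the package's account of its model, its
parameters, and the choices made where the design space was genuinely
open.

## The mechanical model and its assumptions

The scaffold is treated as a small-strain, isotropic, linear-elastic
solid. That buys three strong properties the package leans on:

* **Linearity in load.** The effective modulus is independent of the
  imposed strain; the default 1% strain is a reproducibility convention,
  not a physical claim (strains above 5% are rejected as outside the
  regime the model can speak for).
* **Linearity in material stiffness.** At fixed geometry and Poisson
  ratio, the whole displacement field scales with the bulk modulus `E_o`.
  Sweeps therefore solve each geometry once per Poisson ratio and rescale
  exactly across materials — chitosan and PCL (both ν = 0.3) share
  geometry solves, as do the three gelatins (ν = 0.4).
* **Scale invariance.** Multiplying all lengths by a constant leaves the
  effective modulus unchanged, so results depend only on the shape ratios
  `p : d` and the layout counts.

Not modelled, deliberately: viscoelasticity and degradation of the
hydrogels, geometric or material nonlinearity, buckling and failure,
fabrication artifacts (filament sag, fusion necks, surface roughness), and
any biochemical cue. The stiffness bands themselves come from 2-D
substrate experiments; applying them to 3-D scaffold surfaces is the
design hypothesis the package operationalizes, not a validated law.

## Geometry: two dialects for an under-specified cell

A cubic cell with pore side `p` and fiber width `d` has side
`L = p + 2d`. The literature rarely pins down the solid geometry of "a
cubic unit cell", so two concrete dialects are implemented:

* `channel_cell` (default): a cube of side `L` with three orthogonal
  square through-channels of side `p`. Porosity
  `φ = (3p²L − 2p³)/L³`. Chosen as default because its pores
  interconnect along all three axes (what macroporous scaffolds are for)
  and its cubic symmetry yields `E_xx = E_yy = E_zz` exactly.
* `strut_frame`: square beams of section `d × d` along the 12 cube edges;
  `φ = 1 − (12d²L − 16d³)/L³`. Stiffer pore walls, much higher attainable
  porosity.

Both closed forms are strictly monotone (decreasing in `d` at fixed `p`,
increasing in `p` at fixed `d`), so prescribing any two of `{p, d, φ}`
determines the third; the inversion is a monotone bisection to 1e-10
relative.

One published parameter combination deserves a flag: a cell with
`p = 200 µm` and `d = 80 µm` is sometimes quoted at 80% porosity, but no
simple cubic-cell closed form reproduces all three values (the
channel-cell porosity of that pair is 58.3%). The package gives `(p, d)`
precedence and reports the recomputed porosity rather than hiding the
discrepancy; sweeps that prescribe porosity invert the free parameter
instead. Absolute stiffness values from studies built on that geometry can
therefore differ from this package's output even at convergence — the
trends and bounds are the comparable quantities.

Cells tile face-to-face at pitch `L` (interior walls are `2d` thick,
following the convention that the multi-cell span is the cell side times
the cell count), and layers stack along z at the same pitch.

## Voxelization

The voxel size is `d / resolution`, so fibers are always exactly resolved;
the pore side is snapped to the nearest voxel multiple, with a warning
reporting the realized pore side whenever the snap is not exact. The
measured porosity of the grid equals the closed form of the *snapped*
geometry to machine precision, and converges to the requested geometry's
closed form as resolution grows (within 2% absolute at resolution 4,
0.5% at 8, for the presets' parameter ranges). Resolution 1 is rejected:
a single-voxel fiber cannot represent bending at all.

## The finite-element solver

Each solid voxel is one 8-node trilinear hexahedral element; the element
matrix is the standard 2×2×2 Gauss quadrature of `BᵀCB` (exact for cubic
elements — a 4×4×4 rule is kept as an independent cross-check), scaling
linearly in `E_o` and in the element size. Solid material not
face-connected to both loading faces cannot carry load; it is removed
before assembly (and reported). If nothing connects the faces, the package
raises a "no load path" error instead of returning a spurious modulus.

Boundary conditions come in two support dialects:

* `homogenization_rollers` (default): the constrained face is fixed only
  axially; lateral contraction is free. A homogeneous block then
  reproduces the affine uniform-strain field exactly (the patch test), so
  the dense-block identity `E_eff = E_o` holds to solver precision.
  Rigid-body modes left by the rollers are removed by minimal corner pins
  chosen so the affine field satisfies them; pins are applied per
  node-connected solid component, since disconnected components (e.g.
  parallel struts) each carry their own rigid modes.
* `fixed_face`: the constrained face is clamped in all three
  components, as a fully-bonded ABAQUS-style support. For ν > 0 this
  over-stiffens short blocks (Poisson confinement), which is why the
  analytic identities are stated under rollers; the two dialects are one
  flag apart.

Loading is displacement control by default (imposed axial strain, modulus
from the reaction sum — the definition is then exact by construction).
Pressure control is provided for completeness, with `ΔL` taken as the
maximum axial displacement of the loaded face (the convention used when
reading deformation plots; a face-average rule is the alternative).

Systems up to 15,000 degrees of freedom are solved by sparse Cholesky
factorization; larger ones by a matrix-free element-by-element
Jacobi-preconditioned conjugate gradient (C++), initialized with the
affine field of the homogeneous problem and iterated to a relative
residual of 1e-8 (configurable) against the zero-guess residual norm.
Node ordering is lexicographic and fixed, so results are run-to-run
deterministic on one platform. The iteration cap is `50·√dof`.

### Exact symmetry reduction

Scaffold tilings are mirror-symmetric about their mid-planes. For roller
displacement control the package verifies the voxel pattern's mirror
symmetry explicitly (an array flip comparison) and, where it holds and the
voxel count is even, solves on the half domain per symmetric axis: the cut
plane normal to the load becomes the loaded face at the same imposed
strain, and cut planes transverse to the load get zero normal
displacement. The restriction of the full solution to the half domain
satisfies exactly these conditions, so the reduced modulus is identical
(tests assert agreement at solver tolerance) while cost drops up to
8-fold. This is how the multi-layer sweeps stay desk-scale.

## Effective modulus and lineage bands

`E_eff = (F/A)·(L/ΔL)` uses the **gross** bounding-face area, voids
included. Gross area is the only convention under which the dense-block
identity holds and under which scaffold-level moduli compare directly with
the lineage bands (a net-area convention would report the fiber material's
apparent stiffness instead of the matrix stiffness a cell layer
experiences). Two invariant bounds are asserted in the test suite for
every porous solve: `0 < E_eff < E_o`, and the Voigt bound
`E_eff ≤ E_o (1 − φ)` within a 2% discretization allowance.

Band edges are inclusive (0.1–1, 8–17, ≥ 25 kPa); moduli in the gaps
(below 0.1, 1–8, 17–25 kPa) return `"indeterminate"` rather than snapping
to the nearest band, because the underlying experiments assign those
ranges to no lineage.

The convergence study reports the first resolution at which the
successive relative change in `E_eff` drops below 2% — chosen to be
smaller than any band's relative width at its edges, so a "converged"
classification cannot flip from discretization error alone.

## The design sweeps

Five presets reproduce the standard parametric studies: fiber width
(50–100 µm in 10 µm steps at `p = 200 µm`, single layer, 16 cells),
porosity (30–90% in 10% steps at `d = 100 µm`), cells per layer (1, 4,
16, 36, 64, 100 at `p = 200`, `d = 80`), layers (1, 5, 10, 20, 30 at
porosities 70/90/95%), and material (chitosan and PCL at porosities
70/80/90%). Where a preset prescribes porosity, the free geometric
parameter is inverted and the realized value is recorded in the output
(the fiber widths behind the 70/80/90% presets — 57.0, 40.3 and 24.3 µm —
are printed in every results table, since they are derived, not given).

Multi-layer scaffolds are loaded in-plane by default (the single-layer
loading setup extended in z); through-thickness loading is one argument
away, since the multi-layer loading axis is not standardized. Failed
design points (infeasible geometry, no load path, non-convergence) appear
as flagged rows with their error message, never as silent drops.

Two quantified conventions: "insensitive to cells per layer" is measured
as the relative spread `(max − min)/mean` of `E_eff` across the preset,
with 20% as the threshold and the measured value always printed (the
observed spread at resolution 4 is under 2%); the layer-count trend is
summarized by the layer count at which the successive change falls below
5%. The guideline report also flags designs thicker than 500 µm, the
conventional depth beyond which hypoxic gradients threaten cell
metabolism in static culture.

## Problem sizes and runtime conventions

All shipped runs are desk-scale by design: sweeps default to 4 voxels per
fiber width (with an optional convergence pass at 8), and the
chitosan/PCL material study is exercised at layer counts 1/5/10 — the
layer asymptote is already flat at 10 layers (successive change well
under 1%), so the 20- and 30-layer points add cost without information
for the bound checks. At these sizes the largest solve (90% porosity,
10 layers, 16 cells per layer) runs in about a minute on one CPU via the
symmetry-reduced conjugate gradient; the full acceptance computation
takes a few minutes.

## What the geometry generator does and does not emulate

The parametric generator stands in for the CAD-plus-meshing stage of a
commercial-FEA workflow: it produces ideal, perfectly periodic, sharp-edged
cubic lattices at exactly the nominal dimensions. Real printed scaffolds
have rounded fiber cross-sections, strand fusion at junctions, dimensional
error of the order of the nozzle diameter, and stochastic pore defects —
all of which move the effective modulus, typically downward. Passing
tests therefore certify the *model pipeline* (geometry → porosity →
discretization → solve → classification), and the design *trends* and
*material bounds*; they do not certify absolute agreement with any
fabricated scaffold, nor with CAD geometries whose solid model differs
from the two dialects shipped here.

## Numerical edge cases

* Degenerate grids (no solid voxels) are rejected at construction.
* Voids spanning the full cross-section trigger the no-load-path error.
* Floating solid (not connected to both faces) is dropped and logged; the
  solution equals that of the cleaned geometry exactly.
* Conjugate-gradient breakdown (non-positive-definite operator, e.g. from
  an unpinned rigid mode) aborts with a solver error rather than
  returning a field.
* Porosity targets outside (0, 1) raise an infeasibility error naming the
  attainable interval; over- or under-determined `{p, d, φ}` inputs are
  configuration errors.

## Known limitations

Only the axial effective modulus is homogenized — no shear moduli, no
effective Poisson ratio, no full orthotropic tensor (that would need six
load cases). The two cell dialects cannot represent hexagonal or graded
pore architectures. The fully-clamped dialect's apparent modulus depends
on specimen aspect ratio, which is physical for that support but means
its numbers are not material properties. And the lineage map is a
step-function reading of band experiments: real dose-response is smooth,
cell-type-specific, and modulated by chemistry the model does not see.
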