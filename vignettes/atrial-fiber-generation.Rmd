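---
title: "Rule-based atrial fiber generation: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based atrial fiber generation: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
harmonic-coordinate fiber model and its assumptions, the parameters that
matter, what the synthetic geometries do and do not emulate, and the
numerical choices made where the design was genuinely open.

## The model

Atrial myocardium is a thin, multiply-connected shell whose fiber bundles
(Bachmann's bundle, crista terminalis, pectinate muscles, the venous
sleeves, the valvular vestibules, ...) run in locally coherent but globally
intricate directions, with distinct sub-endocardial and sub-epicardial
layers. The method prescribes fibers in three stages.

**Harmonic distances.** Every spatial coordinate the rules need is a
harmonic function: a P1 finite-element solution of $-\Delta\chi = 0$ with
piecewise-constant Dirichlet data on named boundary partitions and
zero-flux conditions elsewhere. The catalog comprises the inter-atrial
coordinate $\xi$ (+1 on the LA endocardium, −1 on the RA endocardium), the
transmural coordinate $\phi$ (endocardia ±1, epicardium 0, with per-chamber
variants $\phi_{la} = 1-\phi$, $\phi_{ra} = 1+\phi$), and per chamber the
intra-atrial fields $\psi_{ab}, \psi_v, \psi_r, \psi_w, \psi_t, \psi_a,
\psi_{aa}$ plus $\psi_s$ (LA only) and $\psi_{ct}$ (RA only). Their
Dirichlet data live on the 22 canonical boundary tags (vein rings, valve
ring sectors, endocardial bands, epicardial top bands) and four landmark
points (appendage apices, fossa ovalis centre, coronary sinus apex), each
realized as a single Dirichlet node. Harmonicity gives two structural
guarantees the rules rely on: the discrete maximum principle (every field
stays inside its data range) and smooth interior gradients.

**Bundle selection.** A per-node decision ladder — inter-atrial connections
first, then the LA ladder for $\xi > 0$ nodes and the RA ladder for the
rest — assigns exactly one bundle per node, reading threshold parameters
$\tau$ in the *raw* Dirichlet units of the fields (fields are never
rescaled). Rules are evaluated top-to-bottom, first match wins; the printed
comparison operators (strict vs non-strict) are implemented exactly as
typed, and rule order is stored as data so it is testable. Each matched
rule records the tuple $(\gamma, k, \alpha_{endo}, \alpha_{epi},
\mathrm{flip})$: which field's gradient supplies the transmural direction,
which the in-wall normal, and the two layer rotation angles. The pectinate
muscles are striped arithmetically along $\psi_{aa}$: stripe $n$ occupies
$[\tau_{raa} + (n-1)(tk+rg),\; \tau_{raa} + (n-1)(tk+rg) + tk]$ for $n =
1..N_{pm}$, gaps and out-of-range values falling to the lateral wall. A
node beyond the last stripe but inside the printed range bound matches no
printed branch; for totality it is treated like a gap (lateral wall).

**Frames and rotation.** Per node, $e_t = \gamma/\|\gamma\|$, $e_n$ is the
Gram-Schmidt complement of $k$, and $e_l = e_n \times e_t$. The bridge
bundles (Bachmann's and coronary-sinus inter-atrial connections) flip $e_l$
and $e_t$ after the frame build and before rotation. The fiber triad is
$f = \cos\alpha\, e_l + \sin\alpha\, e_n$, $n = -\sin\alpha\, e_l +
\cos\alpha\, e_n$, $s = e_t$, with $\alpha$ chosen per transmural layer —
producing a volumetric two-layer wall.

### The layer split

The printed two-layer rule ("$\alpha_{endo}$ for $|\phi| > 0$,
$\alpha_{epi}$ for $|\phi| \le 0$") is degenerate on a volumetric mesh,
where $\phi = 0$ only *on* the epicardial surface. The package therefore
exposes the split as a threshold `tauLayer` on the normalized transmural
coordinate $t = |\phi| \in [0, 1]$ ($t = 1$ endocardium, $t = 0$
epicardium): a node is sub-endocardial iff $t > \texttt{tauLayer}$, default
0.5 (mid-wall). The same indicator resolves the layer-conditional normal
fields of the posterior-wall and Bachmann-bundle rules, written in the
ladder as a sub-endo/sub-epi *pair* of gradients: the two gradients are
alternatives per layer (a hard switch), not a sum — summing would blend
directions only on the interface. Whether the split surface should be
bundle-specific is unknown; it is a single global parameter here.

## Parameters

* **Thresholds $\tau$** (dimensionless, in each field's Dirichlet units):
  bundle extents. The shipped defaults are a mid-range profile chosen once
  for the synthetic bi-atrial toy so that all 30 bundles are populated;
  real anatomies need per-geometry profiles (YAML, `readBundleConfig()`).
  Point-landmark fields ($\psi_{aa}$) decay steeply near their source, so
  appendage thresholds sit closer to the field's interior range on the toy
  than they would on an anatomy with a true appendage lobe.
* **Angles $\alpha_{endo}, \alpha_{epi}$** (degrees, per bundle): fiber
  rotation per layer. The defaults are illustrative placeholders in the
  field's typical ranges (circumferential vestibules, longitudinal roof
  and crista, oblique anterior wall); they are configuration, not anatomy.
  Bundles whose printed rule supplies a single angle for both layers
  (the inter-atrial bridges with their epicardial angle, crista terminalis
  and pectinate muscles with their endocardial one, and the zero-angle
  coronary-sinus bridge, plus the septal rule that reuses the inter-caval
  pair) are implemented verbatim.
* **EP parameters**: $c_f = 100\,s^{-1/2}$, $\sigma_f = 10^{-4}$,
  $\sigma_s = \sigma_n = 0.16\times10^{-4}\, m^2/s$, giving planar speeds
  $c_f\sqrt{\sigma} = 1$ and $0.4\, m/s$ along and across fibers; stimulus
  radius $2\times10^{-3}\,m$; pseudo-time step $\Delta t = 10^{-3}\,s$ with
  BDF2.

## Numerical choices

* **Laplace solves**: exact per-tet P1 gradients, Dirichlet elimination,
  sparse Cholesky; relative residual verified to $10^{-10}$. Gradient
  recovery is tet-volume-weighted cell-to-node averaging; a node is
  *degenerate* when its averaged gradient norm falls below
  $10^{-12} \cdot \mathrm{range}(\chi)/\mathrm{diag(bbox)}$. Degenerate
  nodes inherit the nearest same-bundle frame by breadth-first search over
  mesh edges (lowest-index donor, deterministic); unrepairable nodes above
  1% abort, as that signals broken labels.
* **Chamber sub-domains**: intra-atrial fields are solved on the
  $\{\xi \ge 0\}$ / $\{\xi \le 0\}$ sub-meshes (interface nodes in both).
  Because the inter-atrial-connection rules read chamber fields inside an
  $\xi$ window that spans both chambers, each chamber field and its
  gradient are extended across the interface by breadth-first nearest-value
  fill. A landmark Dirichlet point that sits just across the interface
  (e.g. a fossa ovalis centre voxel on the RA side) is snapped to the
  nearest in-chamber node rather than silently dropped.
* **Multi-set Dirichlet data**: the four-valued problems ($\psi_{ab}$,
  $\psi_s$, ...) are solved as one Laplace problem with all sets imposed
  simultaneously. Where thin adjacent tag bands share nodes, the first
  listed set keeps them (fixed, documented order).
* **Eikonal-diffusion**: steady state of
  $-\nabla\cdot(D\nabla u) + c_f\sqrt{\nabla u\cdot D\nabla u} = 1$ by
  pseudo-time relaxation (lumped mass, BDF2, implicit diffusion). The
  eikonal term is 1-homogeneous in $\nabla u$, so its linearization
  $a(u^k)\cdot\nabla u^{k+1}$ with $a = c_f D\nabla u^k/|\nabla u^k|_D$ is
  exact at the fixed point; treating it implicitly keeps the iteration
  stable at pseudo-time steps far above the explicit CFL limit, at the cost
  of one nonsymmetric sparse solve per step. Convergence is declared when
  the relaxation rate $\max|\Delta u|/\Delta t$ (the unit source drives the
  field at rate 1) falls below `tol` (default $10^{-3}$). A pure-eikonal
  mode (no diffusion matrix) is available for speed; both modes satisfy the
  dispersion relation (planar speed $c_f\sqrt{d\cdot Dd}$) to well within
  5% at the reference resolution. Relative activation-time errors are
  normalized by the reference map's total activation time (global
  normalization; pointwise available as an option).
* **Angle statistics**: fibers are axial data, so means and deviations use
  doubled angles: $\bar R = |\langle e^{2i\alpha}\rangle|$, mean
  $= \arg/2$ folded to $(-90°, 90°]$, SD $= \sqrt{-2\ln\bar R}/2$.
  Histogram bins default to 10° (the binning behind a reported mode is
  rarely published; it is configuration here); modal ties resolve toward
  0°. The default "good agreement" cutoff for field comparison is 30°,
  also configuration — agreement percentages depend on it and on the
  dataset, and are not comparable across studies without it.
* **Field transfer** (`projectField`): an external per-point fiber cloud is
  transferred by nearest-source-point lookup with unit renormalization
  (exact pass-through when the cloud *is* the mesh's node set). A
  cell-based linear interpolant would need source connectivity, which a
  point cloud does not carry.

## Synthetic geometries, and what passing tests mean

Three deterministic (RNG-free) generators emulate the labeling contract:

* `makeSlab()` — structured Kuhn-subdivided box; affine harmonic solutions
  are reproduced exactly, and planar-front experiments have a closed-form
  speed, so solver errors cannot hide.
* `makeAtrialShell()` — icosphere × radial-layer prisms (split by the
  smallest-index diagonal rule, face-conformal), nodes exactly on
  concentric spheres: the radial harmonic closed form applies and the
  observed convergence order under refinement is ≈ 2 in the node-wise
  maximum norm. Orifices are cut as cones; exposed cut faces become the
  ring tags.
* `makeBiatrialToy()` — two hollow-sphere chambers plus a septal wall
  block carved from one structured grid (cell-indicator voxelization), so
  the mesh is conformal and watertight and carries all 22 tags and 4
  landmarks. Boundary faces are tagged by the *reason* the neighbouring
  cell is absent (cavity → endocardium, orifice cone → ring, otherwise →
  epicardium with band arcs), which keeps tag borders consistent with the
  geometry at any resolution. The default wall (10→16 mm radii, 2 mm
  cells, ~4.8k nodes) keeps the full pipeline under a few seconds.

The toy is topologically faithful but geometrically crude: staircase
surfaces, no appendage lobes, no trabeculation, a single rectangular
septal bridge rather than distinct Bachmann/fossa/coronary-sinus
connections. Tests passing on it demonstrate the *mechanics* — label
handling, field catalog, ladder totality, frame algebra, closure of
generation vs measurement, dispersion of the EP solver — not anatomical
fidelity of any particular τ/α profile. Profiles for real meshes remain
user configuration by design.

The problem sizes used throughout (toy at 2 mm cells; dispersion slab at
the 6e-4 m reference edge length; shell convergence at icosphere levels 3
and 4) were chosen as the smallest sizes at which the asymptotic behaviour
under test is already visible.

## Known limitations

* No inter-bundle smoothing: frames change discontinuously across bundle
  borders, exactly as the per-bundle rules prescribe. Within a bundle the
  field is smooth in the bulk, but near the ring and landmark Dirichlet
  sets the harmonic gradients rotate rapidly (fibers encircle a vein
  orifice; a point landmark radiates), so adjacent-node fiber angles are
  only bounded away from those singularities.
* The mono-atrial mode reuses the same machinery with the chamber's
  reduced tag set; inter-atrial connections are only defined in bi-atrial
  mode.
* The eikonal-diffusion solver targets activation times only; no ionic
  model, restitution or repolarization.
* `projectField`'s nearest-point transfer is first-order; for smooth
  measured fields on comparable resolutions this is adequate, but it will
  not anti-alias a much denser source cloud.
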