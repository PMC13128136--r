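---
title: "A multicellular phase-field model of border cell migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multicellular phase-field model of border cell migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

borderfield simulates the collective migration of the border cell cluster
through the *Drosophila* egg chamber. Each cell is a diffuse-interface
(phase-field) scalar: `phi ~ 1` inside the cell, `~ 0` outside, with a thin
transition layer in between. The scene holds a static epithelial boundary
field `phi0` (0 inside the chamber, 1 outside), six nurse cells, one
oocyte, and one border cell cluster, all on a uniform square grid over
`[0,5]^2` with mesh size `h = 5/(M+1)` (reference `M = 99`, `h = 0.05`).

This vignette records the model, the numerical choices, and the design
decisions made where the problem was genuinely open. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The free energy

Every dynamic cell `m` contributes four kinds of energy:

* **Interface + bulk:** `int eps_m^2/2 |grad phi_m|^2 + g(phi_m)` with the
  double well `g(phi) = phi^2 (1-phi)^2 / 4`, whose minima at 0 and 1 keep
  the field two-phase. `eps_m^2` sets the interface width (about
  `5.7 sqrt(eps2)`): 0.001 for nurse cells and the oocyte, 0.0005 for the
  cluster.
* **Volume penalty:** `alpha_m (V_m - Vbar_m)^2` with
  `V_m = int h(phi_m)`, `h(phi) = phi^2 (3 - 2 phi)` the smooth indicator,
  and `alpha_m = 100`. This is by far the stiffest term in the system.
* **Exclusion:** `beta0 sum_m int h(phi0) h(phi_m) + sum_{m != n} beta(m,n)
  int h(phi_m) h(phi_n)` — overlap costs energy. The double sum counts
  every unordered pair twice; the tabulated intensities (nurse-nurse and
  nurse-cluster 0.25, nurse-oocyte 0.25, cluster-oocyte 0.3, epithelium
  0.9) are defined under that convention.
* **Global filling:** `alpha0 (int (1 - h(phi0)) - sum_m V_m)^2` — the
  cells jointly fill the chamber interior (`alpha0 = 0.02`).
* **Adhesion:** `gamma0 sum_m int grad h(phi0) . grad h(phi_m) +
  sum_{m != n} gamma(m,n) int grad h(phi_m) . grad h(phi_n)`. Abutting
  interfaces have opposing indicator gradients, so positive `gamma`
  rewards contact.

Each field evolves by explicit gradient flow,
`dphi_m/dt = -mu dE/dphi_m`, with mobility `mu`; the epithelium `phi0` is
prescribed and static. Every right-hand-side term is derived as the exact
variational derivative of the energy above, and the test suite verifies
this term by term against finite-difference directional derivatives.

### Stability-bounded parameter choices

Three parameter groups have no single defensible value and were fixed by
explicit stability analysis; they are deliberate package choices:

* **Mobility `mu = 0.05`.** The volume penalty gives the explicit scheme a
  stiff global mode with rate `lambda ~ 2 alpha_m mu int h'(phi)^2 ds`
  along each cell's interface, roughly `250 mu` for equilibrated cell
  perimeters. Forward Euler requires `dt lambda < 2`; at the reference
  `dt = 0.05` this caps `mu` near 0.15. The default 0.05 keeps a 2.5x
  margin (0.25 diverges immediately; 0.05 and 0.1 descend monotonically).
* **Adhesion magnitudes.** The adhesion force on cell `m` carries
  `gamma lap h(phi_n)`, and `|lap h|` at a resolved interface is of order
  `0.1/eps2 ~ 100-200`. Once `6 gamma |lap h|` exceeds the double-well
  slope (about 0.5), `phi = 0` becomes linearly unstable next to any
  partner interface: partner fields nucleate there and the interfaces foam
  (checkerboards of interleaved fields are energetically unbounded for the
  gradient coupling). The defaults keep the relative strengths
  nurse-nurse : nurse-cluster : cluster-oocyte : nurse-oocyte = 3 : 4 : 5 : 8
  and the epithelial coupling at `1e-4`, all inside the bound.
* **Domain extension of `h` and a containment well.** The cubic indicator
  is non-monotone outside `[0,1]`; under a guidance force that pushes
  `phi` past 1 inside an overlap zone, the exclusion energy would then
  *decrease* with further growth and descent itself diverges. `h` is
  therefore clamped to the C1 smoothstep (0 below 0, 1 above 1), and a
  quadratic containment well (stiffness 300, zero on `[0,1]`) bounds the
  excursions that forces can drive. Neither changes the model on the
  physically meaningful range.

## Initialization and equilibration

Cells start as circular tanh discs. Target volumes are the roster disc
areas rescaled to sum exactly to the chamber interior area, so the global
filling constraint and the per-cell targets are mutually consistent. Two
initialization routes exist:

* At target volume (`init_scale = 1`): used for the small fixture scenes.
* Quasi-static growth (scenario pipeline): discs start at 55% of the
  volume-matched radius and the targets are ramped linearly over the first
  600 time units of equilibration. Starting small avoids a large initial
  deficit in the stiff volume penalty, and growing into contact avoids
  deep field overlap — the exclusion force is gated by `h'(phi)` and
  vanishes in overlapped bulk, so deeply merged cells cannot separate.

Equilibration runs force-free to `t = 2000` and reaches per-cell volume
errors below 1% at the reference resolution, with the total energy
non-increasing at every record.

## Chemoattractant landscapes

The ligand is secreted at the oocyte's anterior face (`x = 3.2`),
diffuses and degrades in the extracellular channel of half-width `r(x)`,
giving the steady balance `D (A c')' = k A c` with `A = 2 r`, zero flux at
the anterior end and fixed concentration at the source. The solver is a
conservative second-order finite-volume scheme (face-averaged `A`,
tridiagonal solve), verified against the constant-`A` cosh closed form.
The 1D profile is copied across `y` and continued as a plateau posterior
of the source face, with a short Gaussian smoothing (sd 0.12) so the
clamped junction does not act as a spurious force-divergence line.

The default channel geometry shapes the profile (`D = 1`, `k = 1`,
`c` at the source `= 2`):

* a tight neck where the anterior epithelium meets the first nurse cells
  (`x ~ 0.5`): the steady flux through it supports a steep concentration
  jump, so receptor activation is negligible in the anterior basal region
  (`rho ~ 0.1`) yet near-saturated where the cluster starts (`rho ~ 0.8`);
* widenings at the two three-cell junctions (`x ~ 1.8`, `2.75`), which
  locally dilute the signal and flatten the gradient;
* a sigmoidal opening toward the oocyte face: flux balance gives
  `dc/dx ~ 1/A`, so without the opening the gradient steepens sharply at
  the source and pulls a migrating cluster's leading edge much harder than
  its rear, tearing it into a finger.

Receptor activation is the saturating response
`rho(c) = s c^3 / ((c^2 + Gamma)(c + ell))` with `s = 1`, `Gamma = 0.01`,
`ell = 0.05` — negligible at basal concentrations, steeply increasing over
the transition range, saturated near the source.

The dorsal-turn landscape is analytic:
`c(x, y) = cosh(1.5 x) + 1e-4 cosh(y)`, with `x` from the anterior edge
and `y` from the ventral edge so the second term is a monotone dorsal
bias. It saturates the receptor along the whole path; the dorsal component
matters only where the interface tangent turns perpendicular to the A-P
axis, i.e. on the oocyte's anterior face.

## Guidance forces

The classical chemotaxis force `F_chem = -mu_c div(phi_c grad c)` advects
the cluster up-gradient with strength proportional to the local gradient
(`mu_c = 0.045`).

The tangential interface migration (TIM) force is
`F_TIM = -mubar_c div(rho(c) phi_c Phi_sub sgn(grad c . t) t)` with
`t = perp(grad phi_c)` the interface tangent and `Phi_sub` the summed
substrate fields (nurse cells plus the oocyte). Traction exists only where
the cluster overlaps a substrate cell, its direction follows the sign of
the chemoattractant gradient projected on the tangent, and its magnitude
is set by the saturating receptor activation, not the gradient magnitude.
`sgn(0) = 0`, so a uniform field produces an exactly zero force.

### Discretization of the TIM divergence

The integrator does not discretize the divergence literally. Expanding it
with `a = rho Phi_sub phi_c` gives
`div(a s t) = s (grad a . t) + a (grad s . t)` (the discrete `div t` of a
rotated gradient is identically zero for the commuting central stencils),
and the self-gradient part of `grad a . t` vanishes identically because
`grad phi_c . perp(grad phi_c) = 0`. The integrator therefore applies

```
F = -mubar_c * phi_c * [ s (grad(rho Phi_sub) . t) + rho Phi_sub (grad s . t) ]
```

The first term transports the cluster skin along the contact arc; the
second is the flip-line contribution where the sign factor reverses — the
tangential flux from both halves of a contact arc converges at its
up-gradient pole, and that pile-up is the propulsive protrusion.
Discretizing the unexpanded divergence instead leaves an O(1) product-rule
residue at grid-scale roughness of `phi_c` which feeds back through the
force's own `grad phi_c` factor and diverges in finite time; the expanded
form transports roughness instead of amplifying it. The literal divergence
form (`f_tim`) and inner-product form (`f_tim_inner`) remain available and
are cross-checked against each other in the tests; they agree to stencil
accuracy wherever the sign factor is locally constant and differ on the
flip-line set, which is exactly the jump term above.

Two numerical guards apply to the traction: amplitude factors are clamped
to `[0,1]` (where the overlap density is meaningful), and the traction is
zeroed where `phi_c Phi_sub < 0.01` — without that floor the exponential
tails of the cluster field act as a surface conveyor that ratchets stray
mass far ahead of the cluster body.

### Force strengths

Strengths are quoted in the convention where the guidance force adds
directly to `dphi/dt` while the variational terms carry the mobility; a
sensitivity stated relative to the mobility-scaled variational rate
corresponds to `mu` times a value in this convention. The chemotaxis
default is `mu_c = 0.045`. The TIM default `mubar_c = 0.02` is calibrated
so the TIM baseline reaches the oocyte slightly before the chemotaxis
baseline, as the model's reference behavior requires; the dorsal preset
uses 0.008 because its landscape saturates `rho` along the whole path
(comparable `mubar * rho` products). Stronger traction either drives the
cluster through the oocyte's exclusion wall (dorsal landscape) or excites
the flip-line roughness.

## Scenario presets

All presets equilibrate (or reuse) the same reference scene, then switch
on a landscape and a force:

| preset | landscape | force | window |
|---|---|---|---|
| `baseline_chem` | geometry-shaped | chemotaxis | 4000 |
| `baseline_tim` | geometry-shaped | TIM | 4000 |
| `uniform_c` | uniform | TIM | 2000 |
| `shallow_chem` | source x 0.1 | chemotaxis | 2500 |
| `shallow_tim` | source x 0.1 | TIM | 2500 |
| `dorsal_turn` | analytic two-cue | TIM | 4000 |

The windows are chosen to span the transit and attachment phases of the
completing runs; an attached cluster under a persistent cue eventually
wanders along the oocyte face, which is outside the scope of the presets.
The shallow factor 0.1 (an order-of-magnitude weaker source) leaves the
start region above the receptor activation threshold — the saturating
`rho` barely changes there — while the chemotactic propulsion, which
scales linearly with the source, falls below the depinning level and the
cluster sits mid-chamber for the whole window.

Scenarios run at the reference resolution `M = 99`. Coarser grids
under-resolve the cluster interface (at `M = 63` it spans ~1.6 cells); the
interface then pins to the lattice and no force below the tearing level
can move it. This is a real limitation: scaled-down grids are available
for the small fixture scenes but not for the migration experiments.

## What the synthetic scenes do and do not show

The generator emulates: a closed, filled epithelial chamber; heterogeneous
deformable nurse cells with a midline channel; a steep-then-flattening
secreted gradient shaped by extracellular geometry; saturating receptor
readout; and contact-dependent tangential traction. It does not emulate:
individual border cells within the cluster (one field represents the
cluster), protrusion-scale actin dynamics, ligand consumption or
time-dependent ligand transport, 3D geometry, or physical units — times
and lengths are model units, and the mobility convention makes absolute
timescales a free choice. Passing tests therefore support the *relative*
statements (TIM completes where chemotaxis stalls; traction requires
substrate contact; saturation decouples traction from gradient magnitude)
rather than quantitative predictions about real egg chambers.

## Numerical summary

* Grid: interior nodes at `(ih, jh)`, `h = 5/(M+1)`; mirrored-ghost
  zero-flux closure; 5-point Laplacian, central gradients; all integrals
  by midpoint quadrature.
* Energy gradient-square terms use face (forward) differences, which makes
  the 5-point Laplacian the exact discrete functional derivative — energy
  descent and the directional-derivative oracle hold to roundoff.
* Explicit forward Euler, `dt = 0.05` at `h = 0.05`, guarded by
  `dt <= h^2/(2 mu eps2)` (the engine refuses violations) and by the
  stiffness bound on `mu` above.
* Determinism: no stochastic terms by default; identical configurations
  reproduce trajectories bit-for-bit.
* Degenerate inputs: vanished cluster makes the centroid undefined
  (error); non-finite fields abort the run and return the last recorded
  state; `sgn(0) = 0` resolves the uniform-field tie exactly.
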