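---
title: "Mechano-sensing cell fate: model and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechano-sensing cell fate: model and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mechanofate simulates how extracellular-matrix stiffness steers the fate of a
migrating mesenchymal stem cell (MSC). The package couples three layers: a 3D
linear-elastic finite element substrate, a spherical cell agent that probes the
substrate mechanically, and a rule layer that converts the probed deformation
into maturation, differentiation, proliferation and apoptosis. This vignette
documents the model, its assumptions, the tunable parameters, and every
numerical choice that was genuinely open.

## The mechano-sensing loop

The substrate is an axis-aligned box of isotropic linear-elastic material
(Young's modulus $E$, Poisson ratio $\nu = 0.3$), discretised into regular
8-node trilinear hexahedra of 10 µm edge. All boundary surfaces are free; the
default geometry (400 × 200 × 200 µm, 40 × 20 × 20 divisions) yields 16,000
elements and 18,081 nodes. The cell is a rigid sphere of radius $r$ = 20 µm with
$n$ = 24 membrane nodes at fixed unit directions $\mathbf{e}_i$ from its
centroid.

During sensing the cell pulls each active membrane node toward its centroid
with force $f_i = \sigma(\varepsilon_i)\,S$, where $S = 4\pi r^2/n$ is the
per-node share of the membrane area and $\sigma$ is the contractile stress law

$$
\sigma(\varepsilon) =
\begin{cases}
K_\text{pas}\varepsilon & \varepsilon < \varepsilon_\min \text{ or } \varepsilon > \varepsilon_\max\\[2pt]
\dfrac{K_\text{act}\sigma_\max(\varepsilon_\min-\varepsilon)}{K_\text{act}\varepsilon_\min-\sigma_\max} + K_\text{pas}\varepsilon & \varepsilon_\min \le \varepsilon \le \tilde\varepsilon\\[6pt]
\dfrac{K_\text{act}\sigma_\max(\varepsilon_\max-\varepsilon)}{K_\text{act}\varepsilon_\max-\sigma_\max} + K_\text{pas}\varepsilon & \tilde\varepsilon \le \varepsilon \le \varepsilon_\max
\end{cases}
$$

with $\tilde\varepsilon = \sigma_\max/K_\text{act}$: a tent-shaped active
(actin-myosin) term superposed on a passive (microtubule/membrane) line,
continuous at all three breakpoints. The substrate deformation feeds back into
the force: the internal deformation at node $i$ is the contraction ratio
MN/OM, the nodal displacement projected on the inward direction divided by the
cell radius.

**Sign convention.** The stored ratio is positive under contraction, but the 1D
stress law is evaluated at the *signed* axial strain, which is negative in
contraction. This choice matters: with the opposite sign the loop has positive
feedback (loop gain $\approx K_\text{pas}\times$ substrate compliance, which
exceeds 1 for $E \lesssim 5$ kPa) and no fixed point on soft gels, and traction
would fall with stiffness. With the compression-negative convention the
sensed stress rises monotonically with stiffness and saturates near
$\sigma(0) \approx 0.095$ kPa on rigid substrates, the behaviour expected of
durotactic cells.

**Exact fixed-point solve.** Force and deformation are coupled linearly except
for the piecewise-linear stress law, so instead of damped Picard iteration
(which diverges on soft substrates for the same loop-gain reason) the package
solves the coupled system exactly: a 24-column influence matrix
$M_{ij}$ — contraction at node $i$ per unit inward force at node $j$ — is
built from one multi-right-hand-side solve with the cached Cholesky
factorization, and the active-set system
$(I + S\,M\,\mathrm{diag}(b))\,\varepsilon = S\,M\,a$ is iterated over the
stress-law branch assignments (coefficients $a, b$ per branch; at most 50
branch updates, in practice 1–3). The result satisfies the nominal $10^{-6}$
self-consistency tolerance to machine precision at every stiffness.

**Rigid-body handling.** Free-floating elasticity has a 6-dimensional
nullspace. Sensing loads are self-equilibrated (zero net force by symmetry of
the template, zero net torque because all forces are central), so suppressing
the nullspace by the standard 3-2-1 rule (three translations at one corner
node, two at the corner along +x, one at the corner along +y) only fixes the
gauge; tests verify that strain fields are insensitive to the choice of corner
at the 1% level. Point loads are distributed to the containing element's nodes
by trilinear shape-function weights (no nearest-node snapping), and strains
are recovered from the trilinear gradients at the query point's local
coordinates.

**Membrane template.** Only the node count (24) and sphericity are prescribed,
so the template is a design choice: the 24 vertices of a rhombicuboctahedron.
It is vertex-transitive under the octahedral group, antipodally symmetric
(directions sum to zero exactly) and a spherical 2-design
($\sum_i (\mathbf{e}_i\cdot\mathbf{p})^2 = 8$ for every unit $\mathbf{p}$),
so a cell in a homogeneous medium senses no artificial directional bias. With
the contact tolerance $\delta_c = 0.25\,r$ this template reproduces the
expected contact geometry: two touching cells share between 1 and 4 "common
nodes" depending on the contact direction (4 along the octahedral axes, fewer
elsewhere).

## Migration

Traction on the cell acts outward along each node direction with magnitude
$\sigma(\varepsilon_i)\,S\,\hat\zeta_i$: the cell pulls itself toward its
adhesions, the reaction on the substrate pointing inward. $\hat\zeta$ is the
*relative* adhesivity $\zeta/\zeta_\text{back}$ with
$\zeta = k\,n_r\,\psi$ (binding constant × receptor count × ligand
concentration): 1.5 on the membrane half facing the previous polarisation
(front receptors $1.5\times10^5$ vs. $10^5$), 1 on the rear half. The raw
adhesivity ($1.5\times10^8$) is reported by `adhesivity()` but enters the
force only through this ratio; using it as an absolute prefactor would produce
forces of order $10^9$ nN, far outside the nN regime the rest of the model
(and the Stokes drag) is written in.

A random protrusion force with magnitude $\kappa\,\lVert
\mathbf{F}^\text{trac}_\text{net}\rVert$, $\kappa\sim U[0,1)$, and uniformly
random direction models actin-polymerisation exploration. Inertia is
negligible, so drag closes the balance
$\mathbf{F}^\text{trac}_\text{net}+\mathbf{F}^\text{prot}+\mathbf{F}^\text{drag}=0$;
the cell polarises against the drag ($\mathbf{e}_\text{pol} =
-\mathbf{F}^\text{drag}/\lVert\mathbf{F}^\text{drag}\rVert$), moves at the
Stokes speed $v = \lVert\mathbf{F}^\text{drag}\rVert/(6\pi r\eta)$ with
$\eta$ = 1000 Pa s, and translocates $v\,\tau\,\mathbf{e}_\text{pol}$ per
$\tau$ = 6 h step.

**Step limiter.** The front/back adhesivity asymmetry alone produces net
tractions of tens of nN, i.e. Stokes speeds of hundreds of µm/h — the box
would be crossed within a single step. The applied translocation is therefore
capped at `d_max` (default $r/2$ = 10 µm per step, ~1.7 µm/h), the typical
3D mesenchymal speed scale. The cap is a numerical/biophysical limiter applied
at the translocation stage; `resolve_motion()` itself stays exactly linear in
the forces (halving with doubled viscosity, etc.). Direction dynamics — the
persistent, noisy polarisation — are unaffected.

Cells may not approach closer than one diameter; violations after a step are
resolved by symmetric pairwise projection (id-ordered sweeps), and centroids
are clamped one radius inside the box faces. At contact, membrane nodes within
$r + \delta_c$ of the partner's centroid stop sensing (no pseudopod into an
occupied region) but keep their traction; they reactivate on separation.

## Fate rules

The decision variable is the mechanical signal
$\gamma = \lvert\sum_i \mathbf{e}_\text{pol}\!\cdot\!\epsilon_i\!\cdot\!
\mathbf{e}_\text{pol}\rvert$, the substrate strain tensors at the membrane
nodes projected on the polarisation direction and summed. Under contraction
the raw sum is negative while all thresholds are positive; the absolute value
makes the thresholds actionable (an open question recorded as such).

Maturation: $t_\text{mat}(\gamma) = t_\min + t_p\,\gamma$ with $t_\min$ = 4
days, $t_p$ = 200 days. The maturation index accrues incrementally,
$\Delta MI = \tau / t_\text{mat}(\gamma(t))$, capped at 1 — for constant
$\gamma$ this is exactly the ratio form $t/t_\text{mat}$, and it honours
irreversibility for time-varying signals. MI resets to 0 only on phenotype
change (implemented as: reset first, accrue from the next step).

A fully mature MSC commits according to half-open signal bands: osteoblast for
$0.005 < \gamma \le 0.04$, chondrocyte for $0.04 < \gamma \le 0.1$, neuroblast
for $0.1 < \gamma \le 0.5$; apoptosis for $\gamma > 1$ at any maturity; no
event otherwise. Any mature cell with $\gamma \le \gamma^\text{prof}$ divides:
one daughter in place, the other one diameter away along a uniformly random
direction (redrawn up to 100 times to satisfy the box and separation
constraints, else deferred one step), both daughters non-mature. When a mature
MSC satisfies both rules at once the processes occur congruently: the default
resolution is division with both daughters carrying the new phenotype
(configurable to "differentiate only" or a 50/50 coin flip). The proliferation
limit is 0.2 for MSCs; limits for committed phenotypes are not part of the
reference table and default to the same value.

**Phenotype contractility.** Committed cells differ from progenitors only
through a multiplier on $\sigma_\max$: osteoblast 1.5, chondrocyte 1.25,
neuroblast 0.6 (MSC 1). These factors are invented — no reference values
exist — and were fixed once from the qualitative observation that osteogenic
and chondrogenic commitment raises traction while neurogenic commitment
lowers it, with the osteogenic increase the strongest. They also feed back
into the signal after differentiation (a more contractile phenotype deforms
the substrate more), which lengthens the post-commitment maturation period on
the same substrate.

## What the scenarios emulate, and what they do not

The six presets (0.1, 1, 20, 25, 30, 45 kPa) emulate culture of a single MSC
in homogeneous gels spanning neurogenic to osteogenic stiffness. The model
assumes: no nutrient or oxygen limitation, no matrix degradation or
remodelling, no chemotaxis, a permanently spherical cell, purely elastic
substrate response to sensing (viscosity enters only through drag), no
cyclic-strain fatigue apoptosis, and no myogenic/adipogenic lineages. Passing
tests therefore demonstrate internal consistency of the mechano-regulation
model under these idealisations, not quantitative agreement with any
particular culture protocol.

Two emergent properties of this implementation deserve explicit notice, since
they bound what the scenario suite can show:

* The signal gap between 25 and 30 kPa is only ~20% (the sensed stress
  saturates above ~10 kPa, so $\gamma \sim \sigma^*(E)/E$), while the
  chondrocyte/osteoblast band edge at 0.04 would need a ~2× separation.
  Whether intermediate-stiffness runs commit to chondrocyte or osteoblast is
  thus decided by the absolute signal scale, which is set by the near-field
  of the discrete point loads and is not mesh-convergent (the strain at a
  loaded point grows as the element size shrinks; the 10 µm element is part
  of the model definition, as in the original discrete approach).
* On the softest substrate (0.1 kPa) the signal can exceed the neuroblast
  band ceiling $\gamma_u = 0.5$ while staying below the apoptosis threshold,
  a dead zone of the fate rules in which the cell neither differentiates,
  divides, nor dies.

## Problem sizes

The package default is the full 400 × 200 × 200 µm box. The bundled study
runner (`run_stiffness_study()`), the test suite and the acceptance script use
a 200 × 100 × 100 µm box meshed 20 × 10 × 10 — the same 10 µm element — with
10 replicates per scenario, horizons of 35 days (stiff), 120 days (1 kPa) and
130 days (0.1 kPa), and early stopping once a differentiated cell has divided.
The element size is preserved because the signal scale is pinned to it; the
box is shrunk because the operator factorization and per-step solves dominate
the cost, and both grow much faster than linearly with the node count. A
corner-seeded cell in the desk box senses a slightly softer far field than in
the full box, while the near-field that dominates the signal is unchanged.

## Numerical choices, collected

* Element: trilinear hex, 2×2×2 Gauss quadrature; regular grid, so one
  reference element stiffness is replicated across the mesh.
* Sparse Cholesky (CHOLMOD through Matrix) factorized once per scenario and
  shared across replicates, steps and cells.
* Sensing solved exactly per branch assignment (above); convergence flag and
  iteration count stored on the cell.
* RNG: one seed per replicate (`seed + k - 1` within a scenario;
  `seed + 1000k + j` across the study), draws in fixed per-cell order
  (protrusion magnitude, protrusion direction, then any division
  direction), making runs bitwise reproducible.
* Ties and degenerate inputs: zero drag keeps the previous polarisation and
  produces no motion; the first step (no polarisation yet) uses front
  adhesivity everywhere; an unresolvable packing freezes positions for one
  step and logs it; placement failure defers division by one step.
* Units: µm, kPa, nN, hours internally (kPa·µm² = nN exactly); days in
  reports; the single Pa·s → nN·h/µm² conversion lives in the drag
  coefficient.

## Known limitations

Single-phenotype contractility multipliers are the only mechanical difference
between lineages; daughters re-probe the substrate independently (no inherited
stress state); cell-cell mechanics is purely geometric (no junction forces,
no force transmission through neighbours); the substrate never remodels; and
the mechanical signal is not mesh-convergent by construction, so comparisons
across element sizes are not meaningful.
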