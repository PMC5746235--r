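---
title: "Multi-species colony dynamics on a Vectorizable Random Lattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-species colony dynamics on a Vectorizable Random Lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vortexsim)
```

## The biological model

The package simulates a shared colony of two (optionally three)
micro-organisms on an agar dish containing ampicillin and limited
nutrients:

* **P. vortex** (`b1`): a swarmer whose motility is phenotype-dependent.
  In the *builder* phase motility requires locally extracted lubricant, so
  diffusion is degenerate (porous-medium type, `∇·[D₁b₁∇b₁]`), giving
  compact colonies with sharp edges. In the *explorer* phase diffusion is
  linear and fast. It is killed by ampicillin at rate
  `μ₁(n,a) = 0.3a/(1+4n)` — starved cells are more susceptible.
* **E. coli** (`b2`): non-motile in practice (`D₂ = 10⁻⁴`), but carried
  with the swarm down the P. vortex density gradient through
  `∇·[C₂ b₂ ∇b₁]` with `C₂ = 6 ≫ D₂`. It degrades the antibiotic
  (`−p·a·b₂`) and dies of starvation at `μ₂(n) = 1/(1+4n)`.
* **Nutrient** `n` and **antibiotic** `a` diffuse freely
  (`Dₙ = Dₐ = 0.25`); initial conditions are uniform (`n₀`, `a₀`).
* **Alga** `X` (three-species variant): advected like E. coli
  (`C_X = 10`), fixing carbon that multiplies both bacterial reproduction
  rates by `(1 + r_X X)`, while competing for nutrients (`−λ_X(n)X`) and
  dying at constant rate `μ_X = 0.1`.

**Linear rate laws.** This model family specifies only that reproduction,
nutrient consumption and antibiotic degradation are "linear" in their
driving concentration; this package fixes them as proportional laws `β(n) = βn`, `λ(n) = λn`, `p(a) = pa`.
This is the only reading in which growth stops exactly when nutrients are
exhausted and `a` remains non-negative, and it makes the tabulated
constants the slopes. This interpretation is load-bearing and is recorded
here deliberately.

**Phase switching.** The builder/explorer transition is a *global*,
colony-wide event with hysteresis. The control variable is the mean
density over the colony support,

\[
\bar b_1 \;=\; \frac{\int_B b_1\,dA}{\int_B dA},
\qquad B=\{(x,y)\mid b_1 > 10^{-6}\},
\]

computed discretely with clipped Voronoi cell areas as `dA`. Builders turn
explorers when `b̄₁ > 0.033`, explorers revert when `b̄₁ < 0.007`; the
switch swaps `(D₁, β₁, k)` jointly, treating `β₁` as part of the
phenotype (a package choice). All bacteria start as builders. A variant rule uses `b₁+b₂` with
thresholds 0.029/0.066 (`phase_config(rule = "b1_plus_b2")`). In the
two-colony scenario each connected component of the support carries its own
phase while separated; a merged component adopts the phase holding the
majority of its mass (another package decision; the only hard requirement
is that merged colonies share one phase).

**Dead mass.** `dsᵢ/dt = μᵢbᵢ` is accumulated explicitly with
start-of-step mortality; `sᵢ + bᵢ` (live plus dead) is the quantity whose
radial structure shows the rings. Under pure death the discrete update
conserves `sᵢ + bᵢ` exactly, which the tests assert.

## Units, domain and the time step

Lengths are measured in reference-lattice units (`h = 1`): the domain is
`nx × ny` units, nominally 90 mm across, and one simulation time unit is
about 0.5 h. With these units the tabulated time step `Δt = 0.001` is
comfortably inside the explicit stability limit (`fe_stable_dt()` gives
the Gershgorin bound `1/(D·max Zᵢᵢ)`, ≈ 0.4 for the fastest field).

An alternative convention — unit domain with `h = 1/nx` — is *not* viable
as a scenario default: at 64×64 it puts `D₁Δt/h² ≈ 1.4`, far beyond
explicit stability, and makes the explorer front cross the whole dish in
under one time unit. The unit-domain convention is still what the
convergence study uses (`mesh_spec(nx, nx, h = 1/nx)`), where `dt` is tied
to the stability bound. The conversion "diffusion ≈ 1.5·10⁻⁶ m/sec²" sometimes quoted for this
model is dimensionally inconsistent with domain = 90 mm and 0.5 h per
time unit; the package exposes lattice units and the 90 mm/0.5 h
conversions and does not attempt to reconcile that figure.

## The Vectorizable Random Lattice

One node is drawn uniformly in every cell of an `nx × ny` reference
lattice. If two nodes in cells adjacent along axis *i* lie closer than
`d_i` (Euclidean distance — the per-axis-component reading is also
defensible; this package fixes the Euclidean one), *both* are redrawn; sweeps repeat until clean,
with a hard guard of 10⁵ sweeps. `d = 0` is maximal randomness; as
`d → h` the lattice approaches the rectangular grid, but the acceptance
probability of the redraw chain collapses, so the exact rectangular limit
is provided directly by `regular_mesh()`. The package default is
`d = 0.5h`.

The natural-neighbor (Delaunay) structure and all finite-volume
quantities come from a *Voronoi-first* construction: each node's cell is
the intersection of the domain rectangle with bisector half-planes of
candidate neighbors from a window of reference cells, certified by the
bound `R_max ≤ k·h/2` (cell vertices closer than half the guaranteed
distance to any excluded node) and escalated to an all-pairs clip when the
bound fails. This handles cocircular degeneracies (including the exact
regular grid) without jitter: degenerate faces simply come out with length
zero and are dropped (`f ≤ 10⁻¹²h`). The test suite validates the edge set
against a brute-force empty-circumcircle oracle and the geometry against
an independent all-pairs clipper.

The weights are `w_ij = f_ij/(l_ij A_i)` (shared face length, node
distance, clipped cell area). Because Voronoi faces are perpendicular
bisectors, the two-point flux is exact for linear fields, and the discrete
Laplacian `Σ_j w_ij(φ_j−φ_i)` annihilates linear fields at interior nodes
to rounding — asserted at `10⁻¹⁰`. Boundary faces carry zero flux; that
single rule is the entire no-flux boundary implementation.

Lattice statistics (interior nodes only, to avoid clipping bias): mean
coordination ≈ 6 (forced asymptotically by Euler's formula), fraction of
nodes with a neighbor beyond `4h` ≪ 1%. Bond probabilities are reported
by reference-cell offset shell — shell 1 `(±1,0),(0,±1)`, shell 2
`(±1,±1)`, shell 3 `(±2,0),(0,±2)`, with the full offset table available
because the literature's "next-next-nearest" is ambiguous. Measured at
`d = 0.5h`, the shell-3 probability is ≈ 3·10⁻² and falls below 10⁻⁴ only
for `d ≳ 0.9h` (or for the diagonal `(2,2)` shell, which is already ≲10⁻⁵
at `d = 0.5h`); the acceptance suite records this discrepancy honestly
rather than tuning `d`.

## Spatial operators and time integration

The generic diffusion/advection building block is the averaged two-point
flux form

\[
\nabla\!\cdot[\psi\nabla\varphi](v_i) \approx
\tfrac12\sum_{j\in\mu_i} w_{ij}\,(\psi_j+\psi_i)(\varphi_j-\varphi_i),
\]

used with `ψ = D₁b₁ᵏ` (nonlinear self-diffusion; `ψ ≡ D` for `k = 0`,
including at `b = 0`), and with `ψ = C₂b₂, φ = b₁` for the advection term.
There is **no upwinding** anywhere — the edge average is used verbatim for
advection as well; stability is the time step's job. The area-weighted
flux is skew-symmetric by construction, so every diffused or advected
quantity is conserved to rounding (asserted at `10⁻¹⁰` over 10³ steps).

*Forward Euler* (default, `Δt = 0.001`) advances everything explicitly.
*Crank–Nicolson* treats diffusion implicitly — reactions and advection
stay explicit, since the implicit relation covers diffusion alone — with
`k = 0` solved as one sparse linear system and `k = 1` by the
Gauss–Seidel-split iteration in component form:

\[
\varphi_i \leftarrow
\frac{\mathrm{rhs}_i + c\sum_j w_{ij}\varphi_j^2}{1 + c\,Z_{ii}\,\varphi_i^{\text{prev}}},
\qquad c = \tfrac{D\Delta t}{4},
\]

sweeping nodes in index order (row-major; the order does not affect the
fixed point), with latest neighbor values within a sweep and initial guess
`V⁽⁰⁾ = φⁿ`. Convergence is declared on the successive-iterate max-norm
(`gs_tol`, default 10⁻⁹; cap 500 iterations, error on failure). A dense
Newton solve of the same nonlinear relation agrees to better than 10⁻⁸ in
the tests; iteration counts shrink with `Δt`.

Numerical housekeeping: negative densities from explicit reactions are
clipped to zero with the clipped mass logged (`diagnostics$clipped`);
field values below 10⁻²⁸⁰ are flushed to zero (270 orders of magnitude
below the support threshold — physically meaningless, and subnormal
arithmetic is pathologically slow); coincident nodes or zero-area cells
abort mesh construction with an informative error.

**Accuracy.** The scheme's solution-level accuracy is measured, not
assumed: linear diffusion of a narrow Gaussian against the free-space heat
kernel at `h ∈ {1/32, 1/64, 1/128}` gives empirical orders ≈ 2.1–2.4 on
the random lattice (the suite asserts ≥ 1.5; claimed pointwise
second-order behavior on a random mesh is a solution-level phenomenon, so
the pointwise rate is recorded but not hard-asserted). *Stability:* CN
with `k = 0` at 100× the explicit limit keeps the area-weighted L2 norm
monotone (the operator is symmetric in the `A`-inner product) and the
max-norm bounded; the max-norm itself is **not** monotone for rough data
(measured transients up to +9%) — Crank–Nicolson is A-stable, not
L∞-stable, so the suite asserts the energy norm.

## Scenarios and measurement instruments

`make_scenario()` reproduces the simulation experiments: each species
alone, the mixed ring-forming colony, two separated colonies (merge and
phase synchronization), an antibiotic half-plane (`a = 1` on the left,
smoothed over `2h` — amplitude 1 as literally specified for this
experiment, not `a₀ = 2`), the three-species system, the `b₁+b₂`
switching rule, and the ±20–50% parameter sweep. Initial colonies are
smoothed disks: a C² quintic ramp (`10s³−15s⁴+6s⁵`) of width `2h`
centered on `r₀ = 0.15 ×` the domain size, so the disk mass equals
`πr₀²` to `O(band²)`.

Instruments (all package choices, fixed before the acceptance
measurements):

* **Colony radius** — 95th percentile of node distances from the *fixed*
  inoculation center over the support `{b₁+b₂ > 10⁻⁶}` (robust to stray
  nodes; for two disjoint colonies it deliberately covers both).
* **Ring count** — alternating-band count of the area-weighted radial
  profile of `s+b`: local maxima whose two-sided prominence exceeds 10% of
  the profile maximum, after a 3-bin running mean, with zero density as
  the baseline trough (so an isolated blob counts as one band).
* **Grid-artifact metric** — amplitude of the `cos 4θ` Fourier mode of the
  sector-wise front radius of a porous-medium disk; raw angular variance
  is dominated by random-lattice jitter and cannot separate the meshes,
  while the 4-fold mode isolates the rectangular-grid artifact (measured
  ≈ 2.3× larger on the regular grid).
* **Synchronization** — connected components of the support under
  natural-neighbor adjacency; merge time is when the count first reaches 1.

Determinism: a mesh spec (including seed) yields a bit-identical mesh
(the only randomness in the pipeline), and a (config, mesh) pair yields
bit-identical diagnostics; the RNG state of the caller is left untouched.

## What a green test does and does not establish

The synthetic scenarios state the model's world exactly: smoothed-disk
inocula, uniform `n₀`/`a₀`, no-flux walls, the tabulated constants, and
the reduced scale (64×64 lattice, horizon 20 time units) used by the
acceptance suite. Green numerics tests establish that the discrete
operators, conservation, the nonlinear solver and the convergence order
are correct on this lattice family. They do *not* establish biological
realism: there is no cell-level stochasticity, no unloading of cargo
species, no transport-capacity limit, no chemotaxis toward nutrients, and
densities are unbounded area fractions (no crowding term), so local values
can exceed 1.

## Known limitations

With the default constants the model cannot reproduce several qualitative
behaviors attributed to it, and the acceptance suite leaves those checks
red rather than tuning parameters:

* In untouched territory the P. vortex growth rate is `β₁n₀ = 1.4`/t.u.
  while the worst-case antibiotic mortality is `μ₁(n₀,a₀) = 0.067`/t.u.
  Antibiotic death is therefore a 5% perturbation at the colony front:
  P. vortex alone expands essentially as fast as the mixed colony, and an
  antibiotic half-plane biases growth by only a few percent, not the
  multi-fold confinement the ring narrative requires.
* After the immediate builder→explorer switch (the amplitude-1 inoculum
  starts far above `b̄max`), the support-mean density equilibrates near
  0.2 — more than an order of magnitude above `b̄min = 0.007` — because
  front growth outpaces support dilution. The hysteresis loop therefore
  does not cycle at the reduced scale; a second switch occurs only in the
  terminal die-off after global nutrient exhaustion. Accordingly the
  accumulated-density profile shows the inoculum band plus one strong
  front band (ring count 2 at the 10% prominence instrument) rather than
  3+ rings. The three-species parameter set (`n₀ = 0.5`), where growth
  and mortality are nearly balanced, *does* cycle (2 switches in 20 time
  units) — consistent with the mechanism, and evidence that the tabulated
  two-species constants are not the ones behind the canonical ring
  pictures.
* E. coli alone does not translocate, but its support creeps outward by a
  few lattice units over 20 time units (nutrient-fed rim growth feeding
  the diffusive tail), slightly exceeding a 10% radius-change budget.

These are properties of the stated model, measured by the package's own
tests; the numerical layer beneath them is independently validated by the
operator, solver and convergence oracles above.
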