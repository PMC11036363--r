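---
title: "Methods: alchemical NPT crystal polymorph search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alchemical NPT crystal polymorph search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xtalpath)
```

## The model

`xtalpath` searches for crystal polymorphs of a rigid or flexible organic
molecule by sampling the isothermal–isobaric ensemble along an alchemical
deposition/sublimation path. The simulation state is the asymmetric unit
(ASU) of a space group: one molecule (Z′ = 1), a unit cell, and a coupling
variable λ ∈ [0, 1]. At λ = 0 the molecule is fully uncoupled from its
symmetry mates (an isolated vacuum molecule inside a fluctuating cell); at
λ = 1 it is the fully interacting crystal. Sampling λ as a dynamical variable
lets a single trajectory repeatedly deposit into, and sublime out of,
candidate packings while the cell itself fluctuates under a barostat.

### Surrogate potential

The potential is a pairwise surrogate with the same alchemical structure as
production polarizable force fields:

* **Bonded terms** — harmonic bonds $k_b (b-b_0)^2$, harmonic angles
  $k_\theta (\theta-\theta_0)^2$, cosine torsions
  $A\,(1+\cos(n\phi - \delta))$. Always fully coupled (a vacuum molecule at
  λ = 0 keeps its internal energetics). Bond–angle cross-terms and
  out-of-plane bending are deliberately omitted; they contribute nothing to
  the sampling machinery under test.
* **Van der Waals** — the buffered 14-7 form
  $\varepsilon\,\bigl(\tfrac{1.07}{\rho+0.07}\bigr)^{7}
  \bigl(\tfrac{1.12}{\rho^{7}+0.12}-2\bigr)$, which equals $-\varepsilon$ at
  $\rho = r/r_0 = 1$. Alchemical softcore: the reduced distance is buffered as
  $\rho_{\mathrm{soft}}^{7} = \alpha(1-\lambda)^2 + (r/r_0)^7$ and the pair
  energy is scaled by $\lambda^n$ (defaults $\alpha = 0.7$, $n = 5$). The
  form is endpoint-correct (plain 14-7 at λ = 1, exactly zero at λ = 0),
  finite at $r = 0$ for λ < 1, and with $n \ge 2$ gives
  $\partial U/\partial\lambda = 0$ at λ = 0.
* **Electrostatics** — damped shifted-force (Wolf-style) point charges:
  $q_iq_j\,[\mathrm{erfc}(\kappa r)/r - c_0 + c_1 (r-R_c)]$ with the shift
  constants chosen so the energy and force vanish at the cutoff
  ($\kappa$ = 0.2 Å⁻¹ by default, selectable off). This is a real-space
  surrogate for Ewald summation: it preserves the short-range screening
  structure but has no reciprocal-space term. The same softcore buffering and
  $\lambda^n$ scaling apply.
* **Truncation** — a quintic switching window over the last 1 Å before the
  12 Å cutoff (7 Å for the bundled toys), applied in the *physical* distance
  so smoothness at the cutoff is independent of λ.

Only symmetry-mate (intermolecular) interactions are λ-scaled; intramolecular
nonbonded pairs beyond three bonds are always fully coupled. This matches the
path concept — the vacuum endpoint is a real molecule, not a partially
decoupled one. Units are kcal/mol, Å, degrees and amu, with
$k_B = 1.987204\times10^{-3}$ kcal/mol/K and
1 atm·Å³ = $1.4584\times10^{-5}$ kcal/mol.

### Space-group energetics

Energies are evaluated on the ASU: the molecule interacts with every
symmetry-mate image within the cutoff, generated from an explicit operator
table for the 15 most common space groups of organic crystals (P1, P1̄, P2₁,
C2, Cc, P2/c, P2₁/c, C2/c, P2₁2₁2₁, Pca2₁, Pna2₁, Pbcn, Pbca, Pnma, and R3̄
in the hexagonal setting). External-image pairs carry weight ½ (each pair is
shared between two cells), in-cell pairs between distinct molecules weight 1;
the result is the lattice energy per molecule, and it is identical — to
floating-point precision, tested to 10⁻⁶ kcal/mol — for the ASU, its P1
expansion, and any supercell replication. Gradients carry the symmetry chain
rule (the Cartesian rotation of each operator), and the translation image box
is recentered per operator because fractional coordinates are never wrapped
during dynamics. Cells too small for the cutoff are handled by automatic
internal replication of images, never silent truncation.

The payoff of the ASU representation is the degree-of-freedom count: for a
43-atom molecule, 129 DoF instead of 258 (P1 cell of P1̄), 516 (P1 cell of
P2₁/c) or 6966/9288 for the supercells a minimum-image calculation would
need.

### Orthogonal space tempering

A first-order bias along λ alone leaves "hidden" barriers orthogonal to the
path (torsional rearrangements, packing changes). OST biases jointly on λ and
the generalized force $F_\lambda = \partial U/\partial\lambda$:

* 2D Gaussian hills over $(\lambda, F_\lambda)$, bin widths 0.005 and 2
  kcal/mol, standard deviations of two bins per axis ($w_1 = 0.01$,
  $w_2 = 4$ kcal/mol), truncated after five bins. Hills are accumulated at
  the center of the bin containing the deposition point (grid-snapped), and
  evaluated as smooth analytic Gaussian sums, so the bias and its partials
  are exact derivatives of one another (tested against finite differences to
  10⁻⁸).
* Transition tempering: the hill height stays at $h_0$ (0.05 kcal/mol
  default) until the coverage statistic — for each λ bin take the maximum
  deposited bias over $F_\lambda$, then take the minimum over λ — exceeds
  $V_{th}$ (1 kcal/mol), after which
  $h = h_0\,e^{-(V-V_{th})/(\Delta T\,k_BT)}$ with $\Delta T = 2\,k_BT$. The
  threshold semantics force the entire path to be at least lightly covered
  before decay begins.
* A 1D bias along λ derived by thermodynamic integration: per λ bin, the
  bias-reweighted average of the sampled $F_\lambda$ (weights ∝ visit count ×
  $e^{\beta g_m}$) is integrated from 0; the *applied* 1D bias is the
  negative of that profile, so the biased landscape flattens and the profile
  itself is the free-energy estimate. The package exposes both:
  `ost_lambda_profile()` returns $G(\lambda)=\int_0^\lambda\langle
  F\rangle\,d\lambda'$ and `one_d_bias()` returns $-G(\lambda)$. (The two
  conventions are easy to conflate; the sign here is fixed by requiring that
  $U + f_m$ be flat and that $-f_m$ reproduce the free-energy profile.)
  Never-visited λ bins inherit their nearest visited neighbour and are
  flagged. During dynamics the 1D bias is refreshed every `fm_stride` hill
  depositions and interpolated in between.
* The force on coordinates gains the chain-rule term
  $(\partial g_m/\partial F_\lambda)\,\partial^2U/\partial\lambda\,\partial x$,
  and the force on λ the corresponding
  $(\partial g_m/\partial F_\lambda)\,\partial^2U/\partial\lambda^2$ term;
  both mixed derivatives are analytic in the surrogate.

The F-axis of the bias grid starts at ±100 kcal/mol and doubles outward on
demand; expansion preserves previously deposited bias bit-exactly (the smooth
cache is rebuilt by convolution). Multiple walkers are independent by
default; their checkpoints (versioned plain text) can be merged additively.

### λ-dynamics and the thermostat

Coordinates follow BAOAB Langevin dynamics (1 fs timestep, 10 ps⁻¹ friction
by default; friction 0 reduces exactly to velocity Verlet, and NVE drift on
a toy crystal is below 10⁻⁴ kcal/mol/ps per DoF). λ is propagated as an
auxiliary particle through λ = sin²θ, whose chain rule dλ/dθ = sin 2θ
vanishes at both endpoints — bounds are enforced smoothly, with no
reflection. The fictitious θ mass (default 10⁵ kcal/mol·fs²) sets the λ
diffusion time; the default gives ~10 ps flat-landscape crossings at room
temperature. One consequence of the mapping deserves note: even on a
perfectly flat biased landscape, the stationary *λ*-histogram is not uniform
— it is the image of a uniform θ distribution, with density
$\propto 1/\sqrt{\lambda(1-\lambda)}$. Flat-histogram checks in the tests
therefore compare λ-bin occupancies against the θ measure of each bin.

### Monte Carlo barostat

Every MD step, with probability 1/interval (default 1/10), one free lattice
degree of freedom is chosen uniformly at random. Length moves change the
asymmetric-unit volume by $\Delta V = v_{max}(2x-1)$ ($v_{max}$ = 1 Å³),
applied by scaling the chosen axis (or the constrained axis group in
tandem); angle moves change the angle (group) by $a_{max}(2x-1)$
($a_{max}$ = 0.5°) followed by uniform rescaling of all lengths so the volume
is unchanged. Molecules are rigidly translated so their centers of mass keep
their fractional coordinates. The move is accepted if
$\Delta E = \Delta U + p\Delta V - n_{mol}k_BT\ln(V'/V) < 0$, else with
probability $e^{-\Delta E/k_BT}$; proposals outside the density band
(0.75–1.6 g/cm³ by default) are rejected *before* any energy evaluation —
the band exists because volume changes cost nothing near the vacuum end of
the path. Because proposals live in the constrained parameterization of the
lattice system, all Table-style constraints hold exactly (bit-for-bit) after
any number of moves; the tests verify this for all seven systems, and verify
detailed balance on the noninteracting system, whose stationary
asymmetric-unit volume law $p(V)\propto V^{n}e^{-\beta pV}$ (mean
$(n{+}1)k_BT/p$) is analytic.

The free-parameter counts used by the barostat and minimizer are those
implied by the constraint sets: triclinic 6, monoclinic 4 (α = γ = 90° with
unique axis b), orthorhombic 3, tetragonal 2, rhombohedral 2, hexagonal 2,
cubic 1. Published tabulations sometimes print 5 and 4 for monoclinic and
orthorhombic (counting conventions differ); this implementation uses the
constraint-implied counts throughout.

### Snapshots, minimization, filtering, comparison, clustering

During a walk, a structure is considered every `snapshot_stride` steps
(10 ps at the default timestep) and saved iff λ > 0.8 *and* its locally
minimized energy (rms gradient 0.1 kcal/mol/Å, the "search" preset) is
within 10 kcal/mol of the lowest minimized energy seen so far. Saved
snapshots are re-minimized post hoc to rms gradient 0.03 kcal/mol/Å
("posthoc" preset) over coordinates *and* free lattice parameters — the
optimizer works in the constrained lattice parameterization (L-BFGS-B;
lattice gradient by 5-point finite differences of the analytic-gradient
energy), so constraints are preserved by construction, and convergence is
judged on the full gradient so that even a monatomic crystal (zero
coordinate gradient by translation symmetry) relaxes its cell.

Filtering keeps snapshots with density above 1.25 g/cm³ and energy within
10 kcal/mol of the most stable survivor. Packing similarity rmsd$_N$
(N = 20 by default) builds, for each crystal, the N-molecule shells of
lowest heavy-atom radius of gyration (up to 5 candidate central molecules),
matches molecules greedily by center-of-mass distance after superposing the
central molecules, and reports the heavy-atom rmsd of the Kabsch
superposition, minimized over the tried centers. This is a documented
simplification of packing-alignment algorithms, validated by its contract
properties (zero on identity, lattice-shift invariance, symmetry) and by
exhaustive small-N oracles — not by equivalence to any reference program.
Duplicate removal repeats the random-seed absorption pass (absorb everything
within 0.5 Å of a random unclustered seed) 1000 times and keeps the
clustering with fewest clusters; a 6-structure chain fixture is checked
against exhaustive enumeration. Predictions are classified against a
reference as a match (rmsd₂₀ ≤ 1.0 Å), promotable (≤ 1.5 Å — structures in
that band have historically refined below 1.0 Å after dispersion-corrected
DFT minimization), or a miss.

## What the toy fixtures emulate — and what they do not

* `make_lj_monatomic()` — a single buffered-14-7 atom (ε = 0.4 kcal/mol,
  r₀ = 3.8 Å, mass 24.3 amu, 7 Å cutoff). Its global minimum among
  one-molecule-per-cell lattices is the fcc packing, inside the rhombohedral
  family a = b = c, α = β = γ, so a 2D documented grid scan
  (a ∈ 0.92–1.08 r₀ by 0.0025 r₀, α ∈ 50–120° by 1°) provides a brute-force
  global minimum that the full pipeline must recover within 0.05 kcal/mol.
  At 298 K the toy crystal is soft (kT ≈ 0.6 vs 2.8 kcal/mol binding), which
  is deliberate: deposition and sublimation both happen in short runs.
* `make_rigid_ring()` — a planar n-ring with alternating charges; bonds and
  angles are at their minima in the construction geometry, so the bonded
  energy is zero by construction and electrostatics is exercised.
* `make_analytic_lambda_well()` — $U(\lambda) = \Delta G\,s(\lambda) +
  16\,B\,\lambda^2(1-\lambda)^2$ with the smoothstep $s = 3\lambda^2 -
  2\lambda^3$: closed-form ΔG, endpoint-flat, a barrier of amplitude B in
  between. It stands in for the crystal energy in `run_ost_lambda()` so the
  OST estimators are tested against an exact answer.

These fixtures validate the machinery, not chemistry: they have no torsional
landscape, no competing polymorphs separated by subtle energy differences,
and no long-range electrostatic frustration. A passing suite demonstrates
that the sampling, bias, barostat and bookkeeping are correct — it does not
demonstrate force-field accuracy on real molecules, where a surrogate
pairwise model would be far from adequate.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen so the
whole suite completes in minutes on one CPU: toy searches use 3 walkers ×
6000 steps, OST validation 1.2×10⁵ λ-steps, the barostat checks 10⁵ trials
(volume law) and 10⁵ accepted moves per lattice system. For those runs the
fixture bias is made stronger than the production default (h₀ = 0.25
kcal/mol, deposition every 5 steps, θ mass 5×10³) so coverage and tempering
are reached quickly; the estimators and acceptance rules are identical to
the production path, and all production defaults remain the package
defaults.

Other numerical choices:

* Degenerate cells (volume factor ≤ 10⁻¹⁰) are rejected at construction;
  image boxes are capped at 2×10⁶ images with an explicit error, so a
  collapsing cell fails loudly rather than exhausting memory.
* Exact atom overlaps (possible under the softcore at λ < 1) contribute
  finite energy and zero direction-undefined force.
* The softcore detour: because $\rho_{\mathrm{soft}} > \rho$ for λ < 1, a
  clashing pair briefly traverses the attractive basin of the buffered 14-7
  form at small λ. The excursion is scaled by $\lambda^n$ and stays below
  a few hundredths of a kcal/mol on the clash fixtures (three orders of
  magnitude below the clash energy); beyond it U(λ) rises strictly. This
  is a property of the standard softcore form, not an artifact.
* Barostat proposals that would make a length nonpositive or an angle leave
  (1°, 179°) are auto-rejected, as are density-band violations — before any
  energy call.
* Clustering ties are broken by first occurrence under the seeded restart
  order; identical seeds give identical clusterings, trajectories and
  search results end-to-end.
* The walker terminates with nonzero status and an error message on
  non-finite energies (a state dump accompanies the condition).

## Open design choices made here

* The λ initialization of each walker is the vacuum end (λ = 0), matching
  the deposition reading of the path; random rigid-body coordinates and
  cells are drawn uniformly within the density band, with uniform random
  quaternion rotations.
* The search temperature and pressure default to 298.15 K and 1 atm; the
  timestep (1 fs) and friction (10 ps⁻¹) are conventional values, stated as
  package defaults rather than inferences.
* Hill deposition every 10 MD steps by default; walkers independent, with
  file-based checkpoint merging available for shared-bias workflows.
* "R3̄ hexagonal setting" is the interpretation adopted for the rhombohedral
  member of the 15-group list; it carries hexagonal lattice constraints
  (a = b, α = β = 90°, γ = 120°).
* Whether post hoc minimization should relax constrained lattice angles is
  answered here by construction: constraints are never relaxed.

## Known limitations

* Z′ = 1 only; special Wyckoff positions are not handled (molecules on
  special positions overlap their own images — detected and warned).
* The surrogate potential omits permanent multipoles, polarization and
  reciprocal-space electrostatics; lattice energies for real molecules will
  be wrong in detail even when the sampling is right.
* rmsd_N uses identity atom correspondence within a molecule; enantiomeric
  shells related by improper operations are not specially handled.
* The iterative clustering is stochastic; only the best-of-k count is
  guaranteed nonincreasing in k.
* Pressure is isotropic; no constant-stress (cell-shear) dynamics.
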