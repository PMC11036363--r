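# xtalpath

Crystal polymorph search in the NPT ensemble along an alchemical
vacuum–crystal path.

## The problem

Organic molecules — active pharmaceutical ingredients in particular — can
crystallize in several distinct packings (polymorphs) with different
stabilities, solubilities and processing behaviour. Computational crystal
structure prediction (CSP) tries to enumerate the low-energy packings of a
molecule before experiment finds them. Most CSP searches minimize static
lattice energies; `xtalpath` instead samples the isothermal–isobaric (NPT)
ensemble directly, so temperature and pressure enter the search itself.

The package is a desk-scale, fully tested implementation of that search for
single-molecule asymmetric units (Z′ = 1), with a surrogate pairwise force
field in place of a polarizable multipole model. It is aimed at method
developers and students who want every stage — symmetry energetics, the
alchemical path, the bias, the barostat, the filtering and clustering — as
inspectable, unit-tested R code.

## The method

A coupling variable λ connects an isolated vacuum molecule (λ = 0) to the
fully interacting crystal (λ = 1). Intermolecular (symmetry-mate)
interactions are scaled by λⁿ with a softcore so the path is smooth;
intramolecular terms stay fully coupled. Sampling combines:

- **Space-group energetics on the asymmetric unit.** Energies, Cartesian
  gradients, ∂U/∂λ and ∂²U/∂λ∂x are evaluated on one molecule interacting
  with its symmetry mates and periodic images; per-molecule energies are
  identical for the ASU, its P1 expansion and any replication, which makes
  the ASU representation a drastic shortcut (129 vs 6966 degrees of freedom
  for a 43-atom molecule in a 3×3×3 P1̄ supercell).
- **Orthogonal space tempering (OST).** A 2D metadynamics bias over
  (λ, F_λ = ∂U/∂λ) with transition-tempered hill heights
  (h = h₀ e^{−(V−V_th)/ΔT·k_BT} once the coverage statistic V(t) — the
  min-over-λ of the max-over-F deposited bias — exceeds V_th) plus a 1D bias
  along λ equal to the negative of the thermodynamic-integration free-energy
  profile.
- **A lattice-constrained Monte Carlo barostat.** Trial moves perturb one
  free lattice degree of freedom at a time (ΔV = v_max(2x−1) on the
  asymmetric-unit volume for lengths; Δα = a_max(2x−1) with volume-preserving
  rescaling for angles) and are accepted with the Metropolis rule on
  ΔE = ΔU + pΔV − n_mol k_BT ln(V′/V). The seven lattice systems keep their
  constraints *exactly*, by construction.
- **Langevin (BAOAB) dynamics** on coordinates and on λ through the bounded
  mapping λ = sin²θ.
- **Post-processing.** Snapshots (λ > 0.8, minimized energy within 10
  kcal/mol of the running best) are re-minimized (rms gradient 0.03
  kcal/mol/Å), filtered by density (> 1.25 g/cm³ by default) and relative
  energy (≤ 10 kcal/mol), compared by rmsd_N over N-molecule packing shells
  (Kabsch superposition of heavy atoms, N = 20 by default), and de-duplicated
  by iterative minimum-cluster-count clustering (0.5 Å cutoff, best of 1000
  restarts).

The production-scale defaults of the method (bin widths 0.005 and 2
kcal/mol, hill height 0.05 kcal/mol, widths of two bins, five-bin truncation,
V_th = 1 kcal/mol, ΔT = 2 k_BT, ρ ∈ [0.75, 1.6] g/cm³, v_max = 1 Å³,
a_max = 0.5°, barostat interval 10 steps, 10 ps snapshot stride) are the
package defaults.

## Worked example

An end-to-end search on the monatomic toy in P1, checked against a
brute-force lattice-grid scan:

```r
library(xtalpath)

lj <- make_lj_monatomic()          # eps = 0.4 kcal/mol, r0 = 3.8 A
res <- run_polymorph_search(
  lj$topology, lj$coords, sg = "P1",
  n_walkers = 3, n_steps = 6000, seed = 11,
  aparams = lj$params,
  ostp = ost_params(h0 = 0.25, stride = 5, fm_stride = 10),
  dynp = dynamics_params(lambda_mass = 5e3, snapshot_stride = 1000),
  rho_cut = 0.8, n_mol = 12, restarts = 200)

res$best_energy
#> [1] -2.816444
lattice_grid_minimum(lj)$energy    # independent brute-force scan
#> [1] -2.816444
res$report
#>   space_group snapshots energy_density packing_similarity
#> 1          P1         2              2                  1
#> 2       total         2              2                  1
```

The walkers start from random cells and rigid-body placements, cross the
deposition path under the OST bias, and every saved snapshot minimizes into
the close-packed fcc lattice (a = b = c = 3.686 Å, α = β = γ = 60°, −2.816
kcal/mol per molecule, 1.14 g/cm³); the brute-force scan over the documented
rhombohedral grid finds the same packing, and clustering collapses the
duplicates to a single representative. The reduction report counts survivors
per pipeline stage, per space group.

Free-energy machinery on the analytic λ-well (closed-form ΔG = −3 kcal/mol):

```r
well <- make_analytic_lambda_well(-3, 5)
fit <- run_ost_lambda(well, ostp = ost_params(h0 = 0.25, stride = 5,
                                              fm_stride = 10),
                      dynp = dynamics_params(n_steps = 120000,
                                             lambda_mass = 5e3, seed = 2))
fit$delta_g
#> [1] -2.997342
```

## Command line

A thin dispatcher is installed as `exec/xtalpath`:

```
xtalpath prepare-space-groups --params mol.prm --xyz mol.xyz --out search/
xtalpath thermodynamics-search --params mol.prm --xyz mol.xyz --sg P1 --steps 6000
xtalpath minimize-crystals --params mol.prm --cif snap.cif --rms posthoc
xtalpath superpose-crystals --params mol.prm A.cif B.cif --n 20
xtalpath cluster --matrix sim.tsv --cutoff 0.5 --restarts 1000
```

## Scope

Single-molecule asymmetric units; the 15 space groups that cover the large
majority of organic crystal structures; a surrogate pairwise potential
(buffered 14-7 vdW with alchemical softcore, damped shifted-force point
charges). Polarizable multipoles, Ewald summation, Z′ > 1 and DFT rescoring
are out of scope. See `vignettes/xtalpath-methods.Rmd` for the model,
numerical choices and limitations.
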