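---
title: "First-order SAPT from active-space quantum density matrices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{First-order SAPT from active-space quantum density matrices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by **saptvqe**, its
assumptions, the numerical choices, and what the test suite does and does
not establish.

## The model

Two closed-shell (singlet) monomers A and B interact through the
intermolecular potential `V` (electron–electron, electron–nucleus in both
directions, nucleus–nucleus).  With `|Ψ_A Ψ_B>` the product of monomer
ground states, symmetrized perturbation theory gives at first order

* the electrostatic (polarization) energy `E1_pol = <V>`, and
* the exchange energy, approximated at second order in the intermolecular
  overlap (the S² approximation) as
  `E1_exch(S2) = -( <V P1> - <V> <P1> )`,
  where `P1 = Σ_{i∈A, j∈B} P_ij` interchanges one electron pair.

Expanding `<V P1>` over the cases "the interaction touches the exchanged
pair / one spectator / two spectators" produces exactly five contraction
groups, which the package reports as `T1..T5`:

| group | contents | density matrices |
|-------|----------|------------------|
| T1 | interaction on the exchanged pair | γA, γB |
| T2 | interaction on an A spectator | ΓA, γB |
| T3 | interaction on a B spectator | γA, ΓB |
| T4 | interaction on spectators of both monomers | ΓA, ΓB |
| T5 | norm correction `(E1_pol − V_nn) tr(γA S γB Sᵀ)/2` | γA, γB |

All contractions involve only the spin-summed 1- and 2-RDMs.  For singlet
monomers the spin algebra closes exactly on spin-summed quantities: every
exchange contraction constrains the overlapped index pairs to a common spin
channel, and summing the free spin labels yields the spatial formula with a
single global factor 1/2.  No spin-resolved density blocks are needed; the
test suite verifies this against direct spin-resolved statevector
contractions and against a first-quantized brute-force evaluation of
`<V P1>` (see *Oracles* below).

**Assumptions.** Real orbitals; singlet monomers (an RHF monomer is the
special case of an empty active space); monomer-centered basis sets — each
monomer is described only in its own AO basis, so no counterpoise
machinery exists or is needed; the S² truncation of exchange; first order
only (induction and dispersion, which require response quantities, are out
of scope).

## Active-space embedding

Canonical RHF orbitals are split into `N_c` core, `N_a` active and
virtual sets; the active window is taken symmetrically around the Fermi
level (`select_window`), e.g. `(6e, 6o)` = HOMO−2..LUMO+2, with
deterministic (energy, index) tie-breaking.  The doubly occupied core is
folded in the AO basis, `h~ = h + 2J_c − K_c`, and transformed to the
active MO block; the scalar core energy is the MO-diagonal closed form
`E_core = Σ_{i∈core}(h_ii + h~_ii) + E_nn`, fixed by the requirement that
`E_core` plus the active eigenvalue equal a frozen-core CI of the full
system (asserted in the tests against an independent frozen-core CI built
from unfolded integrals with the core frozen in the determinant strings).

Full-orbital-space density matrices are reassembled from active-space ones
with the closed-shell core block structure (core 1-RDM `2δ`; core–core
2-RDM `4δδ − 2δδ`; Coulomb-type core–active block `2δ·γ`; exchange-type
block `−δ·γ`; all else zero).  The exact normalization of the mixed
blocks is pinned operationally by two oracles — total-energy
reconstruction through unfolded full-space integrals, and agreement of the
full-space exchange contraction with the occupied-space path — rather
than transcribed.

## The exchange engine: optimized path and oracle

The production path (`e1_exch_s2`) evaluates the five groups restricted to
each monomer's occupied+active MO set (γ and Γ vanish on virtuals).
Generalized two-electron integrals are therefore only formed over MO sets
of size `N_c + N_a` (tens), in four classes — `(AA|BB)`, `(AB|AB)`,
`(AA|AB)`, `(AB|BB)` — by direct shell-quartet passes with on-the-fly MO
transformation; nothing of AO-product dimensionality is ever stored.  This
realizes the same bookkeeping as an explicit core/active term expansion
(six T2-type and sixteen T4-type terms) in a form that is uniformly
correct for any partition, including the RHF (core-only) and full-active
limits.

The validation path (`e1_exch_s2_oracle`) contracts the identical master
expression over the *entire* MO spaces with dense full-space RDMs — no
occupied restriction, no analytic core blocks — and must agree to 1e−9
hartree.  Electrostatics are evaluated in the AO basis, either through the
dense cross-ERI tensor (small systems) or a direct generalized-Coulomb
build (`cpp_cross_j`); `build_generalized_jk` exposes the generalized
J̃/K̃ matrices whose γ-contractions reproduce `E1_pol` and the T1 term.

## Oracles

Because the package carries its own integrals engine, the tests anchor it
independently at several levels:

1. **Closed-form s-primitive integrals** (overlap, kinetic, attraction,
   ERI) written directly from the Gaussian product theorem in plain R.
2. **Literature RHF energies** (He/6-31G, H₂/STO-3G, H₂O/6-31G) at loose
   tolerances; higher-angular-momentum attraction is cross-checked against
   the point-charge limit of a tight-exponent ERI.
3. **A first-quantized brute-force expansion** of `<P1>`, `<V>`, `<V P1>`
   for two-electron monomers whose wavefunctions are explicit sums of
   spin-orbital products.  This is the exact reference for the S²
   exchange, for RHF *and* CASCI monomer states, and matches the engine to
   1e−9 hartree.
4. **The Heitler–London identity.**  The energy of the antisymmetrized
   product of the monomer RHF determinants (nonorthogonal Slater rules in
   the dimer AO basis) satisfies
   `E_HL − E_A − E_B = E1_pol + E1_exch(S2) + Δ + O(S⁴)`,
   where `Δ = −<(H_A−E_A)P1> − <(H_B−E_B)P1>` collects single excitations
   of one monomer into the *partner's* orbital space.  In a finite
   monomer-centered basis Brillouin's theorem does not remove Δ, so naive
   HL-vs-S² agreement is **not** a valid oracle at long range; the test
   suite evaluates Δ explicitly by the brute-force expansion and asserts
   the full identity (closure to ~1e−7 hartree on H₂–H₂, the residual
   being genuine O(S⁴)).
5. **Exact S² homogeneity**: scaling every overlap-carrying ingredient by
   λ scales the exchange by exactly λ².

## The statevector solver

The active space is simulated exactly (no sampling noise) as a real
amplitude vector of length `2^(2 N_a)` in blocked α-then-β Jordan–Wigner
mode order.  Gates are defined fermionically (JW parities computed from
bit masks), so all physical outputs are independent of the mode-ordering
convention by construction.  The k-muCJ ansatz applies, per layer, a
spin-restricted orbital rotation `exp(K)` — compiled by QR-Givens
decomposition into two-level rotations, with paired −1 diagonal residues
folded into π rotations — followed by four-qubit pair-exchange gates over
all nearest-neighbor spatial pairs (even-start pairs, then odd-start
pairs; `N_a − 1` angles per layer), and closes with a trailing rotation.
Consecutive-layer rotations are kept separate (the redundancy is harmless
and keeps the parameter layout uniform).  The pair-exchange gate rotates
the doubly-occupied/doubly-empty closed-shell pair configurations and is
the identity elsewhere, so particle numbers and S² are conserved exactly;
the circuit therefore stays in the singlet sector of its reference.

RDMs come from direct statevector contraction: `γ = <E_pq>` and
`Γ = <E_pp' E_rr'> − δ γ` via cached `E_rr'|ψ>` vectors.

**Solvers.**  CASCI diagonalizes the embedded Hamiltonian densely in the
fixed-(n_α, n_β) determinant basis (Slater–Condon build; determinant cap
20000 — every in-scope space is ≤ 400 determinants) and reuses the
statevector RDM machinery through a phase-consistent embedding.  VQE
minimizes the statevector energy with L-BFGS-B from all-zero parameters
(the identity circuit, i.e. the RHF reference), with central
finite-difference gradients (step 1e−5, `pgtol` 1e−6) — the simplest
correct choice for an ideal simulator, documented as swappable.  Optional
seeded restarts perturb the start by Gaussian noise of scale 1e−2 to
escape local minima; the best run is kept.  Tiny numerical perturbations
can steer L-BFGS-B between near-degenerate local minima, which moves the
VQE total-energy error a little; the error-contraction *ratios* the
benchmarks assert are robust to this.

## Measurement-basis optimization for the electrostatics

When only monomer A is quantum, `E1_pol` needs no 2-RDM: the package
folds the nuclear–nuclear and core(A)↔B pieces into a classical scalar,
projects the AO image of B's electrostatic potential into A's active MO
block, and diagonalizes it.  In this "electrostatic-potential natural
orbital" basis the remaining quantum piece is `Σ_s w_s <n_s>` — a
weighted sum of occupation numbers, i.e. a *single commuting group* of
Z-basis measurements (one measurement circuit on hardware).  The ideal
simulator evaluates the same structure by rotating the state with the
principal logarithm of the eigenvector matrix; equality with the direct
electrostatics to 1e−9 hartree and invariance under joint basis rotations
are asserted in the tests.  The analogous reduction for the exchange
expression is out of scope.

## Fixtures: what they emulate and what they do not

The generators are pure functions of their arguments (bitwise reproducible).

* `make_water_dimer(r_oh)` — a hydrogen-bonded water dimer (O–O 2.91 Å,
  collinear O–H⋯O, donor at the equilibrium monomer geometry r_OH =
  0.9572 Å, ∠HOH = 104.52°); the *acceptor's* two O–H bonds are
  symmetrically stretched to `r_oh` with fixed angle and orientation, its
  hydrogens pointing away from the donor so the intermonomer separation is
  fixed for every stretch.  Double O–H dissociation gives the monomer
  strong multireference character while RHF fails qualitatively.
* `make_benzene_pbenzyne_tshape(R)` — benzene at a standard D6h geometry
  (r_CC 1.397 Å, r_CH 1.084 Å) and *p*-benzyne (the same ring minus the
  two para hydrogens; a low-spin singlet biradical) with perpendicular
  ring planes and centroids exactly `R` apart.  Textbook geometries stand
  in for published supplementary structures, so dissociation-curve shapes
  are reproduced qualitatively, not point-for-point; the error-contraction
  ratios that the benchmarks assert are insensitive to these geometric
  details.
* `make_toy_dimer` — H₂–H₂ (collinear) and He–He at arbitrary separation,
  for limits and oracles.

Passing tests on these fixtures demonstrate the correctness of the
machinery and the error-contraction phenomenon under controlled
multireference conditions; they do not by themselves establish accuracy
for condensed-phase or metal-containing systems (no AVAS-style active
space construction, no natural-orbital truncation, no geometry
preparation pipeline).

## Numerical choices

* Lengths in bohr internally (CODATA bohr radius for Å conversion);
  energies in hartree with kcal/mol = 627.509474 Eh reported alongside.
* Cartesian (6-component) d shells; each Cartesian component is
  unit-normalized.  Basis tables (STO-3G, 6-31G, cc-pVDZ; H/He/C/N/O) are
  plain text under `inst/extdata/basis`.
* Integrals by McMurchie–Davidson with a series/downward-recursion Boys
  function and primitive-pair + Schwarz screening at 1e−12.
* RHF: symmetric orthogonalization, core-Hamiltonian guess, DIIS (8
  vectors), convergence |ΔE| < 1e−10 and max orbital gradient < 1e−7,
  cap 200 iterations; linear dependence rejected below an overlap
  eigenvalue of 1e−10.
* Dense in-core monomer ERIs (8-fold packed).  Cross-monomer ERI tensors
  are materialized only below ~0.5 GB; larger systems use direct builds
  and MO-restricted transforms.
* ESP natural orbitals sorted by nonincreasing eigenvalue with index
  tie-breaking.

**Problem sizes in the default test run** (the package's own choice so a
full check stays interactive): the stretched-water benchmark runs at its
full published conditions (6-31G, (6e,6o), k = 1); the benzene /
*p*-benzyne error-contraction test runs the identical protocol in 6-31G,
while `scripts/acceptance.R` recomputes the cc-pVDZ benchmark (about
fifteen minutes on one CPU).  Measured at both scales, the component
errors sit 2.8–3.5 orders of magnitude below the VQE total-energy error
(cc-pVDZ: 2.85 for the electrostatics, 3.52 for the exchange).

## Known limitations

* First order only; no induction/dispersion, no response equations, no
  δHF correction, no dimer-centered-basis mode.
* Exchange truncated at S²; the package reports no S⁴ estimate.
* Elements limited to H–Ar nuclear charges and the shipped basis tables;
  no effective core potentials, no UHF/ROHF references.
* The VQE optimizer is a local quasi-Newton method; convergence to the
  global parameter optimum is not guaranteed (mirrored by the restart
  option).
* No integral caching across runs: every quantity is recomputed (an
  earlier design sketch of a binary integral cache was dropped as
  unnecessary at in-scope system sizes).
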