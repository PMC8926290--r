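# Heitler-London first-order reference: the energy of the antisymmetrized
# product of the two monomer RHF determinants, evaluated with nonorthogonal
# Slater rules in the combined (dimer) AO basis.  It shares no code path
# with the density-matrix SAPT engine and anchors its validation.
#
# Relation to the perturbative quantities: E_HL - E_A - E_B = E1_pol +
# E1_exch(S2) + <(H_A - E_A) + (H_B - E_B) | single exchange> + O(S^4).
# The middle term -- single excitations of one monomer into the *partner's*
# orbital space, not removed by Brillouin's theorem in a finite
# monomer-centered basis -- is O(S^2) and must be accounted for when using
# this quantity as an oracle (the test suite evaluates it explicitly by a
# first-quantized expansion on the toy dimers).

#' Heitler-London first-order interaction energy (RHF monomers)
#'
#' Energy of the antisymmetrized product of the two monomer RHF
#' determinants minus the monomer energies: the complete (all orders in the
#' intermolecular overlap) first-order interaction energy of the
#' determinant product, including the intramonomer relaxation couplings
#' described in the source comments.
#'
#' @param dimer a `dimer_system` (small systems: the dimer-basis ERI tensor
#'   is computed in core).
#' @return list with `e_hl` (energy of the antisymmetrized product),
#'   `e_a`, `e_b` (monomer RHF energies) and `e1_total = e_hl - e_a - e_b`.
#' @export
heitler_london_first_order <- function(dimer) {
  ia <- compute_monomer_integrals(dimer$monomer_a, dimer$basis_a)
  ib <- compute_monomer_integrals(dimer$monomer_b, dimer$basis_b)
  sa <- run_rhf(ia); sb <- run_rhf(ib)
  sh <- shell_concat(ia$shells, ib$shells)
  nA <- ia$n_basis; nB <- ib$n_basis; n <- nA + nB
  S <- cpp_overlap(sh, sh)
  Tk <- cpp_kinetic(sh, sh)
  coords <- rbind(dimer$monomer_a$coords, dimer$monomer_b$coords)
  Z <- c(nuclear_charges(dimer$monomer_a), nuclear_charges(dimer$monomer_b))
  V <- cpp_nuclear(sh, sh, Z, coords)
  h <- Tk + V
  eri <- cpp_eri_packed(sh)
  # combined occupied block (nonorthogonal between monomers)
  occ <- cbind(rbind(sa$mo_coeff[, seq_len(sa$n_occ), drop = FALSE],
                     matrix(0, nB, sa$n_occ)),
               rbind(matrix(0, nA, sb$n_occ),
                     sb$mo_coeff[, seq_len(sb$n_occ), drop = FALSE]))
  M <- t(occ) %*% S %*% occ
  rho <- occ %*% solve(M) %*% t(occ)   # per-spin projector onto the occupieds
  D <- 2 * rho
  jk <- cpp_fock_jk(eri, D)
  e_hl <- sum(D * h) + 0.5 * sum(D * jk$J) - 0.25 * sum(D * jk$K) +
    nuclear_repulsion_energy(Z, coords)
  list(e_hl = e_hl, e_a = sa$e_total, e_b = sb$e_total,
       e1_total = e_hl - sa$e_total - sb$e_total)
}
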