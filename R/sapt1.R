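# First-order density-matrix SAPT: electrostatics E1_pol and the
# S^2-approximate exchange E1_exch(S2) assembled as T1 + ... + T5 from the
# spin-summed monomer density matrices.
#
# Derivation used throughout (real orbitals, singlet monomers): with the
# single-exchange operator P1 = sum_{i in A, j in B} P_ij,
#   E1_exch(S2) = -( <V P1> - <V> <P1> ),
# and every contraction spin-sums to spatial quantities with a global 1/2:
#   T1 = -1/2 gA.gB [(p'q|pq') + S vB + S vA]          (exchanged pair)
#   T2 = -1/2 GA.gB S [(rr'|p'q) + S vB_AA]            (A spectator pair)
#   T3 = -1/2 gA.GB S [(pq'|tt') + S vA_BB]            (B spectator pair)
#   T4 = -1/2 GA.GB S S (rr'|tt')                      (both spectators)
#   T5 = +1/2 (E1_pol - V_nn) tr(gA S gB S^T)          (norm correction)
# where (pq|..) with mixed indices are generalized two-electron integrals
# over hybrid A-B charge distributions.

#' Full AO density matrix of a monomer (core + active)
#'
#' @param scf `scf_state`.
#' @param part `orbital_partition`.
#' @param rdm active-space `rdm_pair` (NULL for an RHF monomer whose
#'   partition has an empty active set).
#' @return AO-basis spin-summed density matrix.
#' @export
ao_density <- function(scf, part, rdm = NULL) {
  C <- scf$mo_coeff
  Cc <- C[, part$core, drop = FALSE]
  D <- 2 * Cc %*% t(Cc)
  if (length(part$active)) {
    if (is.null(rdm)) stop("active partition needs active RDMs")
    Ca <- C[, part$active, drop = FALSE]
    D <- D + Ca %*% rdm$gamma %*% t(Ca)
  }
  D
}

#' First-order electrostatic (polarization) energy
#'
#' Classical Coulomb interaction of the two monomer charge distributions:
#' electron-electron (cross-ERI contraction), electron-nucleus in both
#' directions, and nucleus-nucleus, evaluated directly in the AO basis.
#'
#' @param gamma_a_ao,gamma_b_ao AO-basis spin-summed density matrices
#'   including core and active contributions.
#' @param cross `cross_integrals`.
#' @param jx optional precomputed [cross_coulomb()] matrix of
#'   `gamma_b_ao` (reused when only monomer A's density changes).
#' @return E1_pol in hartree.
#' @export
e1_pol <- function(gamma_a_ao, gamma_b_ao, cross, jx = NULL) {
  check_density_trace(gamma_a_ao, cross$shells_a, cross$n_a_elec, "A")
  check_density_trace(gamma_b_ao, cross$shells_b, cross$n_b_elec, "B")
  if (is.null(jx)) jx <- cross_coulomb(cross, gamma_b_ao)
  sum(gamma_a_ao * jx) + sum(gamma_a_ao * cross$v_b_on_a) +
    sum(gamma_b_ao * cross$v_a_on_b) + cross$v_nn
}

#' Coulomb matrix of monomer B's density over monomer A's AO basis
#'
#' `J[mu,mu'] = sum (mu mu'|nu nu') gamma_B[nu,nu']`, via the dense cross
#' tensor when materialized, by a direct shell-quartet pass otherwise.
#'
#' @param cross `cross_integrals`.
#' @param gamma_b_ao AO density of monomer B.
#' @return matrix over monomer A's AO basis.
#' @export
cross_coulomb <- function(cross, gamma_b_ao) {
  if (!is.null(cross$eri_cross)) {
    nA <- cross$shells_a$nbf
    Em <- matrix(cross$eri_cross, nrow = nA * nA)
    matrix(Em %*% as.numeric(gamma_b_ao), nA, nA)
  } else {
    cpp_cross_j(cross$shells_a, cross$shells_b, gamma_b_ao)
  }
}

check_density_trace <- function(D, shells, n_elec, side) {
  S <- cpp_overlap(shells, shells)
  tr <- sum(D * S)
  if (abs(tr - n_elec) > 1e-6)
    stop(sprintf("monomer %s density traces to %.8f electrons, declared %d",
                 side, tr, n_elec))
  invisible(tr)
}

#' Generalized Coulomb and exchange matrices
#'
#' AO-basis analogues of the ordinary J/K builds with the two-electron
#' integrals replaced by their generalized counterparts, which dress the
#' plain cross-ERI contraction with the partner monomer's nuclear attraction
#' and the overlap-carried nuclear/nuclear-nuclear terms (normalized by the
#' partner electron count).  Contracting `j_tilde` with monomer A's density
#' reproduces [e1_pol()]; contracting `k_tilde` gives the T1 exchange term.
#'
#' @param cross `cross_integrals` (dense cross tensors required, so small
#'   systems only).
#' @param gamma_other_ao AO density of the partner monomer (on side B).
#' @return a `generalized_jk` list: `j_tilde`, `k_tilde` over monomer A's
#'   AO basis.
#' @export
build_generalized_jk <- function(cross, gamma_other_ao) {
  if (is.null(cross$eri_cross))
    stop("dense cross tensors not materialized for this system size")
  check_density_trace(gamma_other_ao, cross$shells_b, cross$n_b_elec, "B")
  nA <- cross$shells_a$nbf; nB <- cross$shells_b$nbf
  gB <- gamma_other_ao
  Em <- matrix(cross$eri_cross, nrow = nA * nA)
  SA <- cpp_overlap(cross$shells_a, cross$shells_a)
  jx <- matrix(Em %*% as.numeric(gB), nA, nA)
  j_tilde <- jx + cross$v_b_on_a +
    SA * ((sum(gB * cross$v_a_on_b) + cross$v_nn) / cross$n_a_elec)
  # hybrid (A B|A B) tensor for the exchange pattern
  IA <- diag(nA); IB <- diag(nB)
  hyb <- cpp_eri_mo(cross$shells_a, IA, cross$shells_b, IB,
                    cross$shells_a, IA, cross$shells_b, IB,
                    sym_bra = FALSE, sym_ket = FALSE)
  # K[p,p'] = sum_{q q'} gB[q,q'] (p' q | p q') + S gB vB^T + (vB gB S^T-type)
  Hm <- aperm(hyb, c(3, 2, 1, 4))  # [p, q, p', q']
  Km <- matrix(0, nA, nA)
  for (q in seq_len(nB))
    Km <- Km + Hm[, q, , ] %res% gB[q, ]
  k_tilde <- Km + cross$v_b_mixed %*% gB %*% t(cross$s_ab) +
    cross$s_ab %*% gB %*% t(cross$v_a_mixed)
  list(j_tilde = j_tilde, k_tilde = k_tilde)
}

# tensor-contraction helper: contract last index of a 3-d array with a vector
`%res%` <- function(A, v) {
  d <- dim(A)
  matrix(matrix(A, nrow = d[1] * d[2]) %*% v, d[1], d[3])
}

# occupied-space (core + active) spin-summed RDMs of one monomer, as the
# closed-shell-core block assembly over the nc + na orbital set
occ_space_rdms <- function(part, rdm) {
  nc <- length(part$core); na <- length(part$active)
  ne <- part$n_active_elec
  sub <- orbital_partition(core = seq_len(nc),
                           active = if (na) nc + seq_len(na) else integer(0),
                           virtual = integer(0),
                           n_active_elec = ne)
  act <- if (na) list(gamma = rdm$gamma, gamma2 = rdm$gamma2)
         else list(gamma = matrix(0, 0, 0), gamma2 = array(0, c(0, 0, 0, 0)))
  assemble_full_space_rdms(act, sub)
}

# MO-transformed cross tensors over given coefficient blocks CA (on A) and
# CB (on B); the four generalized-integral classes plus the one-electron
# matrices the exchange contractions need
cross_mo_tensors <- function(cross, CA, CB) {
  shA <- cross$shells_a; shB <- cross$shells_b
  list(
    S = t(CA) %*% cross$s_ab %*% CB,
    vB = t(CA) %*% cross$v_b_mixed %*% CB,
    vA = t(CA) %*% cross$v_a_mixed %*% CB,
    vB_AA = t(CA) %*% cross$v_b_on_a %*% CA,
    vA_BB = t(CB) %*% cross$v_a_on_b %*% CB,
    G1 = cpp_eri_mo(shA, CA, shB, CB, shA, CA, shB, CB, FALSE, FALSE),
    G2a = cpp_eri_mo(shA, CA, shA, CA, shA, CA, shB, CB, TRUE, FALSE),
    G2b = cpp_eri_mo(shA, CA, shB, CB, shB, CB, shB, CB, FALSE, TRUE),
    G3 = cpp_eri_mo(shA, CA, shA, CA, shB, CB, shB, CB, TRUE, TRUE))
}

# the five-term S^2 exchange contraction over arbitrary orbital sets;
# gA/G2A live on the A set, gB/G2B on the B set, mo holds the transformed
# integrals over those sets.  Returns the T-breakdown.
exch_contract <- function(gA, G2A, gB, G2B, mo, e1pol_minus_vnn) {
  S <- mo$S
  # T1
  t1a <- sum(aperm(mo$G1, c(3, 2, 1, 4)) *
             aperm(outer(gA, gB), c(1, 3, 2, 4)))
  gSg <- gA %*% S %*% gB
  t1 <- -0.5 * (t1a + sum(mo$vB * gSg) + sum(mo$vA * gSg))
  # T2
  Y2 <- S %*% gB                                   # [p, q]
  nA <- nrow(gA); nB <- nrow(gB)
  Z2 <- array(matrix(mo$G2a, nrow = nA * nA * nA) %*% t(Y2),
              c(nA, nA, nA, nA))                   # [r, r', p', p]
  t2a <- sum(G2A * aperm(Z2, c(4, 3, 1, 2)))
  W2 <- Y2 %*% t(S)                                # S gB S^T, [p, p']
  t2b <- drop(as.numeric(W2) %*% matrix(G2A, nA * nA) %*% as.numeric(mo$vB_AA))
  t2 <- -0.5 * (t2a + t2b)
  # T3
  P3 <- gA %*% S                                   # [p, q]
  Q3 <- array(t(P3) %*% matrix(mo$G2b, nrow = nA), c(nB, nB, nB, nB))
  t3a <- sum(G2B * Q3)
  W3 <- t(S) %*% gA %*% S                          # [q, q']
  t3b <- drop(as.numeric(W3) %*% matrix(G2B, nB * nB) %*% as.numeric(mo$vA_BB))
  t3 <- -0.5 * (t3a + t3b)
  # T4
  K4 <- matrix(aperm(outer(S, S), c(4, 2, 1, 3)), nB * nB, nA * nA)
  F4 <- t(matrix(G2B, nB * nB)) %*% K4             # [(t,t'), (p,p')]
  G3F <- matrix(mo$G3, nA * nA) %*% F4             # [(r,r'), (p,p')]
  t4 <- -0.5 * sum(matrix(G2A, nA * nA) * t(G3F))
  # T5
  t5 <- 0.5 * e1pol_minus_vnn * sum(gA * (S %*% gB %*% t(S)))
  structure(list(t1 = t1, t2 = t2, t3 = t3, t4 = t4, t5 = t5,
                 total = t1 + t2 + t3 + t4 + t5),
            class = "exchange_breakdown")
}

#' @export
#' @method print exchange_breakdown
print.exchange_breakdown <- function(x, ...) {
  cat(sprintf("<E1_exch(S2) = %.10f hartree; T1..T5 = %s>\n", x$total,
              paste(sprintf("%.3e", c(x$t1, x$t2, x$t3, x$t4, x$t5)),
                    collapse = ", ")))
  invisible(x)
}

#' S^2-approximate first-order exchange energy (optimized path)
#'
#' Evaluates the five exchange contractions restricted to each monomer's
#' occupied + active molecular orbitals (the density matrices vanish on
#' virtuals), with the closed-shell core blocks of the two-particle density
#' assembled analytically.  Generalized two-electron integrals are formed
#' only over these small MO sets, never over the full AO product space.
#'
#' @param rdms_a,rdms_b active-space `rdm_pair`s (ignored for a monomer
#'   whose partition has no active orbitals).
#' @param part_a,part_b `orbital_partition`s.
#' @param scf_a,scf_b `scf_state`s.
#' @param cross `cross_integrals`.
#' @param e1pol the electrostatic energy (enters the T5 norm correction);
#'   computed on the fly when NULL.
#' @param mo optional precomputed [exchange_mo_tensors()]: when the same
#'   orbitals are contracted against several density-matrix sets (e.g. a
#'   CASCI reference and a VQE state), the expensive integral transforms
#'   can be done once and reused.
#' @return an `exchange_breakdown` with fields `t1`..`t5`, `total`.
#' @export
e1_exch_s2 <- function(rdms_a, rdms_b, part_a, part_b, scf_a, scf_b, cross,
                       e1pol = NULL, mo = NULL) {
  rA <- occ_space_rdms(part_a, rdms_a)
  rB <- occ_space_rdms(part_b, rdms_b)
  if (is.null(e1pol)) {
    DA <- ao_density(scf_a, part_a, rdms_a)
    DB <- ao_density(scf_b, part_b, rdms_b)
    e1pol <- e1_pol(DA, DB, cross)
  }
  if (is.null(mo))
    mo <- exchange_mo_tensors(cross, part_a, part_b, scf_a, scf_b)
  exch_contract(rA$gamma, rA$gamma2, rB$gamma, rB$gamma2, mo,
                e1pol - cross$v_nn)
}

#' MO-transformed cross tensors for the exchange contractions
#'
#' The overlap, nuclear-attraction and generalized two-electron integrals
#' over the occupied+active MO sets of the two monomers.  Depends only on
#' the orbitals (not on the correlated density matrices), so it can be
#' computed once and passed to [e1_exch_s2()] for several solver states.
#'
#' @param cross `cross_integrals`.
#' @param part_a,part_b `orbital_partition`s.
#' @param scf_a,scf_b `scf_state`s.
#' @return an opaque tensor bundle for [e1_exch_s2()].
#' @export
exchange_mo_tensors <- function(cross, part_a, part_b, scf_a, scf_b) {
  CA <- scf_a$mo_coeff[, c(part_a$core, part_a$active), drop = FALSE]
  CB <- scf_b$mo_coeff[, c(part_b$core, part_b$active), drop = FALSE]
  cross_mo_tensors(cross, CA, CB)
}

#' S^2 exchange by naive full-orbital-space contraction (oracle)
#'
#' Ground-truth evaluation used to validate the optimized path: the same
#' master expression contracted over the monomers' *entire* MO spaces with
#' dense full-space density matrices (from [assemble_full_space_rdms()]) and
#' full generalized integrals -- no restriction to occupied orbitals, no
#' analytic core blocks.  O(N^4) storage; guarded to small systems.
#'
#' @param gamma_full_a,gamma2_full_a,gamma_full_b,gamma2_full_b full
#'   MO-space spin-summed RDMs.
#' @param scf_a,scf_b `scf_state`s (full coefficient matrices).
#' @param cross `cross_integrals`.
#' @param e1pol electrostatic energy for the T5 term (computed when NULL
#'   from the full-space densities).
#' @param max_nbf guard on the larger monomer basis size.
#' @return E1_exch(S2) in hartree.
#' @export
e1_exch_s2_oracle <- function(gamma_full_a, gamma2_full_a, gamma_full_b,
                              gamma2_full_b, scf_a, scf_b, cross,
                              e1pol = NULL, max_nbf = 40L) {
  CA <- scf_a$mo_coeff; CB <- scf_b$mo_coeff
  if (ncol(CA) > max_nbf || ncol(CB) > max_nbf)
    stop("system too large for the dense full-space oracle")
  if (is.null(e1pol)) {
    DA <- CA %*% gamma_full_a %*% t(CA)
    DB <- CB %*% gamma_full_b %*% t(CB)
    e1pol <- e1_pol(DA, DB, cross)
  }
  mo <- cross_mo_tensors(cross, CA, CB)
  exch_contract(gamma_full_a, gamma2_full_a, gamma_full_b, gamma2_full_b,
                mo, e1pol - cross$v_nn)$total
}
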