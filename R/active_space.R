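# Orbital-space partitioning and the core-folded (embedded) active-space
# Hamiltonian, plus reassembly of full-orbital-space density matrices from
# active-space ones.

#' Select an active-space window of canonical RHF orbitals
#'
#' The active orbitals are the energy-ordered canonical RHF MOs from
#' HOMO-(n_elec/2 - 1) up to LUMO+(n_orb - n_elec/2 - 1); all lower occupied
#' orbitals form the core and the remainder are virtual.  Ties in orbital
#' energy are broken deterministically by orbital index (the order returned
#' by the SCF diagonalization is stable).
#'
#' @param scf an `scf_state`.
#' @param n_elec even number of active electrons.
#' @param n_orb number of active spatial orbitals.
#' @return an `orbital_partition`: 1-based index vectors `core`, `active`,
#'   `virtual`, plus `n_active_elec`.
#' @export
select_window <- function(scf, n_elec, n_orb) {
  if (n_elec %% 2L != 0L) stop("active electron count must be even")
  if (n_elec <= 0L || n_elec > 2L * n_orb)
    stop("need 0 < n_elec <= 2 * n_orb")
  nbf <- length(scf$mo_energy)
  nocc <- scf$n_occ
  first <- nocc - n_elec %/% 2L + 1L
  last <- first + n_orb - 1L
  if (first < 1L)
    stop("active window extends below the lowest occupied orbital")
  if (last > nbf) stop("active window exceeds the basis size")
  part <- structure(list(core = seq_len(first - 1L),
                         active = first:last,
                         virtual = if (last < nbf) (last + 1L):nbf else integer(0),
                         n_active_elec = as.integer(n_elec)),
                    class = "orbital_partition")
  validate_partition(part, nbf, 2L * length(part$core) + n_elec)
  part
}

#' Explicit orbital partition
#'
#' @param core,active,virtual disjoint 1-based orbital index vectors covering
#'   all orbitals.
#' @param n_active_elec even active electron count.
#' @return an `orbital_partition`.
#' @export
orbital_partition <- function(core, active, virtual, n_active_elec) {
  part <- structure(list(core = as.integer(core), active = as.integer(active),
                         virtual = as.integer(virtual),
                         n_active_elec = as.integer(n_active_elec)),
                    class = "orbital_partition")
  nbf <- length(core) + length(active) + length(virtual)
  validate_partition(part, nbf, NULL)
  part
}

validate_partition <- function(part, nbf, n_elec_total) {
  idx <- c(part$core, part$active, part$virtual)
  if (length(idx) != nbf || !setequal(idx, seq_len(nbf)) ||
      anyDuplicated(idx))
    stop("core/active/virtual must partition 1..n_basis")
  ne <- part$n_active_elec
  if (ne %% 2L != 0L || ne < 0L || ne > 2L * length(part$active))
    stop("invalid active electron count")
  if (!is.null(n_elec_total) &&
      2L * length(part$core) + ne != n_elec_total)
    stop("partition electron count inconsistent with total")
  invisible(part)
}

#' Core environment of an active space
#'
#' The doubly-occupied core is folded into an effective one-electron
#' operator: h-tilde = h + 2 J_c - K_c evaluated in the AO basis from the
#' core density, together with the scalar core energy
#' E_core = sum_i (h_ii + h-tilde_ii) + E_nn (MO diagonal over core
#' orbitals), chosen so that E_core plus the active-space eigenvalue equals
#' the frozen-core CI energy of the full system.
#'
#' @param ints `monomer_integrals`.
#' @param scf `scf_state` on those integrals.
#' @param part `orbital_partition`.
#' @return a `core_environment`: `d_core` (AO, traces to 2 N_c), `j_core`,
#'   `k_core` (built from the per-spin core density), `h_tilde_ao`, `e_core`.
#' @export
build_core_environment <- function(ints, scf, part) {
  n <- ints$n_basis
  Cc <- scf$mo_coeff[, part$core, drop = FALSE]
  d_core <- 2 * Cc %*% t(Cc)
  if (length(part$core) == 0L) {
    j_core <- k_core <- matrix(0, n, n)
  } else {
    jk <- cpp_fock_jk(ints$eri, d_core / 2)  # per-spin core density
    j_core <- jk$J; k_core <- jk$K
  }
  h_tilde_ao <- ints$core_h + 2 * j_core - k_core
  # MO-diagonal closed form for the core energy
  e_core <- ints$nuclear_repulsion
  if (length(part$core) > 0L) {
    hmo <- t(Cc) %*% ints$core_h %*% Cc
    htmo <- t(Cc) %*% h_tilde_ao %*% Cc
    e_core <- e_core + sum(diag(hmo) + diag(htmo))
  }
  structure(list(d_core = d_core, j_core = j_core, k_core = k_core,
                 h_tilde_ao = h_tilde_ao, e_core = e_core),
            class = "core_environment")
}

#' Embedded active-space Hamiltonian
#'
#' One-electron matrix h-tilde in the active MO basis (core-folded), the
#' active-space two-electron tensor in chemists' notation, and the constant
#' core energy.
#'
#' @param ints `monomer_integrals`.
#' @param scf `scf_state`.
#' @param part `orbital_partition`.
#' @return an `active_hamiltonian`: `h_tilde` (N_a x N_a), `eri_active`
#'   (N_a^4 array, (tt'|uu')), `e_core`, `n_active_elec`, `n_active_orb`,
#'   plus the coefficient block `c_active` and the originating objects.
#' @export
build_active_hamiltonian <- function(ints, scf, part) {
  env <- build_core_environment(ints, scf, part)
  Ca <- scf$mo_coeff[, part$active, drop = FALSE]
  h_tilde <- t(Ca) %*% env$h_tilde_ao %*% Ca
  h_tilde <- (h_tilde + t(h_tilde)) / 2
  sh <- ints$shells
  eri_active <- cpp_eri_mo(sh, Ca, sh, Ca, sh, Ca, sh, Ca,
                           sym_bra = TRUE, sym_ket = TRUE)
  structure(list(h_tilde = h_tilde, eri_active = eri_active,
                 e_core = env$e_core,
                 n_active_elec = part$n_active_elec,
                 n_active_orb = length(part$active),
                 c_active = Ca, core_env = env, part = part, scf = scf,
                 ints = ints),
            class = "active_hamiltonian")
}

#' @export
#' @method print active_hamiltonian
print.active_hamiltonian <- function(x, ...) {
  cat(sprintf("<active Hamiltonian: (%de, %do), E_core = %.8f hartree>\n",
              x$n_active_elec, x$n_active_orb, x$e_core))
  invisible(x)
}

#' Full-orbital-space density matrices from active-space ones
#'
#' Reassembles the spin-summed one- and two-particle density matrices over
#' the whole MO space from an active-space pair, using the closed-shell core
#' block structure: the core 1-RDM is 2 on the diagonal; the core-core,
#' core-active and active-active blocks of the 2-RDM are
#' Gamma(ii'jj') = 4 d(ii')d(jj') - 2 d(ij')d(i'j),
#' Gamma(ii'tt') = 2 d(ii') gamma(tt') (Coulomb-type),
#' Gamma(it'ti') = -d(ii') gamma(tt') (exchange-type), and the active block
#' is the input.  Every other block vanishes.
#'
#' @param rdm list with `gamma` (N_a x N_a) and `gamma2` (N_a^4 array).
#' @param part `orbital_partition`.
#' @return list `gamma` (n x n), `gamma2` (n^4 array) over all orbitals,
#'   ordered as in the SCF MO basis.
#' @export
assemble_full_space_rdms <- function(rdm, part) {
  na <- length(part$active)
  if (!is.null(rdm$gamma) &&
      (nrow(rdm$gamma) != na || ncol(rdm$gamma) != na))
    stop("active 1-RDM dimension does not match the partition")
  n <- length(part$core) + na + length(part$virtual)
  g <- matrix(0, n, n)
  G2 <- array(0, c(n, n, n, n))
  co <- part$core; ac <- part$active
  if (length(co)) g[cbind(co, co)] <- 2
  g[ac, ac] <- rdm$gamma
  # core-core
  for (i in co) for (j in co) {
    G2[i, i, j, j] <- G2[i, i, j, j] + 4
    G2[i, j, j, i] <- G2[i, j, j, i] - 2
  }
  # core-active (all four index placements)
  if (length(co)) {
    for (i in co) {
      G2[i, i, ac, ac] <- G2[i, i, ac, ac] + 2 * rdm$gamma
      G2[ac, ac, i, i] <- G2[ac, ac, i, i] + 2 * rdm$gamma
      # exchange-type: Gamma(i t', t i') = -(1/2) * 2 * gamma(t t')
      G2[i, ac, ac, i] <- G2[i, ac, ac, i] - t(rdm$gamma)
      G2[ac, i, i, ac] <- G2[ac, i, i, ac] - rdm$gamma
    }
  }
  # active-active
  G2[ac, ac, ac, ac] <- rdm$gamma2
  list(gamma = g, gamma2 = G2)
}
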