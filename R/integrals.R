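# Atomic-orbital integrals and restricted Hartree-Fock.  This is the only
# module that touches the Gaussian integral kernels.

#' Intra-monomer AO integrals
#'
#' Overlap, core Hamiltonian (kinetic + attraction to the monomer's own
#' nuclei), the full two-electron repulsion tensor in 8-fold packed storage,
#' and the nuclear repulsion energy, all in the monomer-centered AO basis.
#'
#' @param mol a `molecule`.
#' @param basis basis-set name.
#' @return an object of class `monomer_integrals` with fields `overlap`,
#'   `core_h`, `kinetic`, `eri` (packed vector), `nuclear_repulsion`,
#'   `n_basis`, `shells`, `mol`, `basis`.
#' @export
compute_monomer_integrals <- function(mol, basis) {
  sh <- shell_list(mol, basis)
  S <- cpp_overlap(sh, sh)
  Tk <- cpp_kinetic(sh, sh)
  Z <- nuclear_charges(mol)
  V <- cpp_nuclear(sh, sh, Z, mol$coords)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10)
    stop(sprintf("linearly dependent basis: smallest overlap eigenvalue %.3e",
                 min(ev)))
  eri <- cpp_eri_packed(sh)
  enn <- nuclear_repulsion_energy(Z, mol$coords)
  structure(list(overlap = S, core_h = Tk + V, kinetic = Tk, eri = eri,
                 nuclear_repulsion = enn, n_basis = sh$nbf, shells = sh,
                 mol = mol, basis = basis),
            class = "monomer_integrals")
}

nuclear_repulsion_energy <- function(Z, coords) {
  n <- length(Z); e <- 0
  if (n < 2) return(0)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      e <- e + Z[i] * Z[j] / sqrt(sum((coords[i, ] - coords[j, ])^2))
  e
}

#' Cross-monomer AO integrals
#'
#' All atomic-orbital ingredients of the intermolecular potential in
#' monomer-centered bases: the rectangular A-B overlap, nuclear-attraction
#' matrices of each monomer's nuclei in the other monomer's basis and in the
#' mixed A-B pair basis, the intermolecular nuclear repulsion, and (for
#' small systems) dense cross ERI tensors.
#'
#' Tensors kept:
#' \describe{
#'   \item{s_ab}{overlap (mu on A | nu on B).}
#'   \item{v_a_on_b}{attraction to A's nuclei over B-B AO pairs.}
#'   \item{v_b_on_a}{attraction to B's nuclei over A-A AO pairs.}
#'   \item{v_a_mixed, v_b_mixed}{attraction matrices over mixed A-B pairs.}
#'   \item{eri_cross}{(mu mu'|nu nu') with the bra pair on A and the ket
#'     pair on B, as a 4-d array; only materialized when
#'     `n_A^2 n_B^2 <= max_dense` (default caps memory at ~0.5 GB).}
#' }
#'
#' @param dimer a `dimer_system`.
#' @param max_dense maximum element count for dense cross-ERI storage.
#' @return an object of class `cross_integrals`.
#' @export
compute_cross_integrals <- function(dimer, max_dense = 6e7) {
  shA <- shell_list(dimer$monomer_a, dimer$basis_a)
  shB <- shell_list(dimer$monomer_b, dimer$basis_b)
  ZA <- nuclear_charges(dimer$monomer_a)
  ZB <- nuclear_charges(dimer$monomer_b)
  cA <- dimer$monomer_a$coords; cB <- dimer$monomer_b$coords
  s_ab <- cpp_overlap(shA, shB)
  v_a_on_b <- cpp_nuclear(shB, shB, ZA, cA)
  v_b_on_a <- cpp_nuclear(shA, shA, ZB, cB)
  v_a_mixed <- cpp_nuclear(shA, shB, ZA, cA)
  v_b_mixed <- cpp_nuclear(shA, shB, ZB, cB)
  v_nn <- 0
  for (i in seq_along(ZA))
    for (j in seq_along(ZB))
      v_nn <- v_nn + ZA[i] * ZB[j] / sqrt(sum((cA[i, ] - cB[j, ])^2))
  eri_cross <- NULL
  if (as.numeric(shA$nbf)^2 * as.numeric(shB$nbf)^2 <= max_dense) {
    IA <- diag(shA$nbf); IB <- diag(shB$nbf)
    eri_cross <- cpp_eri_mo(shA, IA, shA, IA, shB, IB, shB, IB,
                            sym_bra = TRUE, sym_ket = TRUE)
  }
  structure(list(s_ab = s_ab, v_a_on_b = v_a_on_b, v_b_on_a = v_b_on_a,
                 v_a_mixed = v_a_mixed, v_b_mixed = v_b_mixed,
                 eri_cross = eri_cross, v_nn = v_nn,
                 n_a_elec = n_electrons(dimer$monomer_a),
                 n_b_elec = n_electrons(dimer$monomer_b),
                 shells_a = shA, shells_b = shB, dimer = dimer),
            class = "cross_integrals")
}

#' Restricted Hartree-Fock
#'
#' Closed-shell RHF with a symmetric-orthogonalization core-Hamiltonian
#' initial guess and DIIS acceleration.  Deterministic given the integrals.
#'
#' @param ints `monomer_integrals`.
#' @param n_elec even electron count (defaults to the molecule's).
#' @param conv_e,conv_grad convergence thresholds on the energy change
#'   (hartree) and the maximum orbital-gradient element (FDS - SDF).
#' @param max_iter iteration cap.
#' @return an object of class `scf_state`: `mo_coeff`, `mo_energy`, `n_occ`,
#'   `e_total`, `converged`, plus the Fock and density matrices.
#' @export
run_rhf <- function(ints, n_elec = n_electrons(ints$mol), conv_e = 1e-10,
                    conv_grad = 1e-7, max_iter = 200L) {
  if (n_elec %% 2L != 0L) stop("RHF needs an even electron count")
  n <- ints$n_basis
  nocc <- n_elec %/% 2L
  if (nocc > n) stop("more occupied orbitals than basis functions")
  S <- ints$overlap; h <- ints$core_h
  es <- eigen(S, symmetric = TRUE)
  X <- es$vectors %*% diag(1 / sqrt(es$values), n) %*% t(es$vectors)
  F_ <- h
  e_old <- Inf; D <- matrix(0, n, n)
  diis_F <- list(); diis_e <- list()
  converged <- FALSE; e_elec <- 0; C <- NULL; eps <- NULL; gmax <- Inf
  for (it in seq_len(max_iter)) {
    Fp <- t(X) %*% F_ %*% X
    ef <- eigen((Fp + t(Fp)) / 2, symmetric = TRUE)
    ord <- order(ef$values)  # eigen() returns decreasing; occupy lowest
    C <- X %*% ef$vectors[, ord, drop = FALSE]
    eps <- ef$values[ord]
    Cocc <- C[, seq_len(nocc), drop = FALSE]
    D <- 2 * Cocc %*% t(Cocc)
    jk <- cpp_fock_jk(ints$eri, D)
    F_ <- h + jk$J - 0.5 * jk$K
    e_elec <- 0.5 * sum(D * (h + F_))
    grad <- F_ %*% D %*% S - S %*% D %*% F_
    gmax <- max(abs(grad))
    if (abs(e_elec - e_old) < conv_e && gmax < conv_grad) {
      converged <- TRUE
      break
    }
    e_old <- e_elec
    # DIIS on the orthonormal-basis gradient
    diis_F[[length(diis_F) + 1L]] <- F_
    diis_e[[length(diis_e) + 1L]] <- t(X) %*% grad %*% X
    if (length(diis_F) > 8) {
      diis_F <- diis_F[-1]; diis_e <- diis_e[-1]
    }
    m <- length(diis_F)
    if (m >= 2) {
      B <- matrix(0, m + 1, m + 1)
      for (i in seq_len(m))
        for (j in seq_len(m))
          B[i, j] <- sum(diis_e[[i]] * diis_e[[j]])
      B[m + 1, seq_len(m)] <- -1; B[seq_len(m), m + 1] <- -1
      rhs <- c(rep(0, m), -1)
      cf <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
      if (!is.null(cf)) {
        F_ <- Reduce(`+`, Map(`*`, diis_F, cf))
      }
    }
  }
  e_total <- e_elec + ints$nuclear_repulsion
  if (!converged)
    warning(sprintf("RHF not converged in %d iterations (last E = %.10f, grad %.2e)",
                    max_iter, e_total, gmax))
  structure(list(mo_coeff = C, mo_energy = eps, n_occ = nocc,
                 e_total = e_total, converged = converged, fock = F_,
                 density = D, ints = ints),
            class = "scf_state")
}

#' @export
#' @method print scf_state
print.scf_state <- function(x, ...) {
  cat(sprintf("<RHF: E = %.10f hartree, %d occupied of %d orbitals, %s>\n",
              x$e_total, x$n_occ, length(x$mo_energy),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Supermolecular RHF interaction energy
#'
#' E_int = E_AB - E_A - E_B at the frozen dimer geometry (no deformation
#' energy), with monomer energies in monomer-centered bases.  No
#' counterpoise correction is applied; this is the subtractive scheme the
#' perturbative route avoids.
#'
#' @param dimer a `dimer_system`.
#' @return interaction energy in hartree.
#' @export
supermolecular_rhf_interaction <- function(dimer) {
  a <- dimer$monomer_a; b <- dimer$monomer_b
  na <- n_electrons(a); nb <- n_electrons(b)
  if ((na + nb) %% 2L != 0L) stop("combined system must be closed-shell")
  ia <- compute_monomer_integrals(a, dimer$basis_a)
  ib <- compute_monomer_integrals(b, dimer$basis_b)
  ea <- run_rhf(ia)$e_total
  eb <- run_rhf(ib)$e_total
  eab <- dimer_rhf_energy(dimer)
  eab - ea - eb
}

# RHF of the combined system in the union basis
dimer_rhf_energy <- function(dimer) {
  shA <- shell_list(dimer$monomer_a, dimer$basis_a)
  shB <- shell_list(dimer$monomer_b, dimer$basis_b)
  sh <- shell_concat(shA, shB)
  els <- c(dimer$monomer_a$elements, dimer$monomer_b$elements)
  coords <- rbind(dimer$monomer_a$coords, dimer$monomer_b$coords)
  Z <- unname(ELEMENTS[els])
  S <- cpp_overlap(sh, sh)
  Tk <- cpp_kinetic(sh, sh)
  V <- cpp_nuclear(sh, sh, Z, coords)
  eri <- cpp_eri_packed(sh)
  ints <- structure(list(overlap = S, core_h = Tk + V, kinetic = Tk,
                         eri = eri,
                         nuclear_repulsion = nuclear_repulsion_energy(Z, coords),
                         n_basis = sh$nbf, shells = sh,
                         mol = list(label = "dimer"), basis = dimer$basis_a),
                    class = "monomer_integrals")
  ne <- n_electrons(dimer$monomer_a) + n_electrons(dimer$monomer_b)
  run_rhf(ints, n_elec = ne)$e_total
}

# expand a packed monomer ERI vector into a dense 4-d array (small systems)
eri_unpack <- function(eri, n) {
  g <- array(0, c(n, n, n, n))
  idx <- function(i, j) if (i >= j) i * (i + 1) / 2 + j else j * (j + 1) / 2 + i
  for (mu in 0:(n - 1)) for (nu in 0:mu) {
    P <- idx(mu, nu)
    for (la in 0:mu) {
      for (si in 0:(if (la == mu) nu else la)) {
        Q <- idx(la, si)
        v <- eri[P * (P + 1) / 2 + Q + 1]
        for (q in list(c(mu, nu, la, si), c(nu, mu, la, si),
                       c(mu, nu, si, la), c(nu, mu, si, la),
                       c(la, si, mu, nu), c(si, la, mu, nu),
                       c(la, si, nu, mu), c(si, la, nu, mu)))
          g[q[1] + 1, q[2] + 1, q[3] + 1, q[4] + 1] <- v
      }
    }
  }
  g
}
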