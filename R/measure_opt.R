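# Measurement-basis optimization for the electrostatic energy: fold every
# classical piece (nuclear-nuclear and core<->partner contributions) into a
# scalar offset, project the partner monomer's electrostatic potential into
# the active MO space, and diagonalize it.  In the resulting "electrostatic
# potential natural orbital" basis the remaining quantum contribution is a
# weighted sum of occupation numbers -- a single commuting group of Z-basis
# measurements.

#' Build the electrostatic-potential measurement plan
#'
#' Monomer B is classical (fixed AO density); monomer A is the quantum
#' monomer with an active space.
#'
#' @param cross `cross_integrals`.
#' @param part_a `orbital_partition` of monomer A.
#' @param scf_a `scf_state` of monomer A.
#' @param gamma_b_ao AO density matrix of monomer B.
#' @return an `esp_plan`: `w_active` (active-MO ESP image), `eigvals`
#'   (nonincreasing), `eigvecs` (orthogonal rotation U), `classical_offset`.
#' @export
build_esp_plan <- function(cross, part_a, scf_a, gamma_b_ao) {
  # AO-basis image of B's electrostatic potential on A:
  # W_ao = J_x[gamma_B] + V_B  (electron-electron + electron-nucleus)
  if (!is.null(cross$eri_cross)) {
    nA <- cross$shells_a$nbf
    Em <- matrix(cross$eri_cross, nrow = nA * nA)
    jx <- matrix(Em %*% as.numeric(gamma_b_ao), nA, nA)
  } else {
    jx <- cpp_cross_j(cross$shells_a, cross$shells_b, gamma_b_ao)
  }
  w_ao <- jx + cross$v_b_on_a
  # classical pieces: nuclei(A)<->B and core(A)<->B
  offset <- cross$v_nn + sum(gamma_b_ao * cross$v_a_on_b)
  Cc <- scf_a$mo_coeff[, part_a$core, drop = FALSE]
  if (length(part_a$core))
    offset <- offset + sum((2 * Cc %*% t(Cc)) * w_ao)
  Ca <- scf_a$mo_coeff[, part_a$active, drop = FALSE]
  w_active <- t(Ca) %*% w_ao %*% Ca
  w_active <- (w_active + t(w_active)) / 2
  ev <- eigen(w_active, symmetric = TRUE)
  ord <- order(ev$values, decreasing = TRUE)  # deterministic tie-break by index
  vec <- ev$vectors[, ord, drop = FALSE]
  # orient to a proper rotation (occupations are column-sign invariant)
  if (det(vec) < 0) vec[, 1] <- -vec[, 1]
  structure(list(w_active = w_active, eigvals = ev$values[ord],
                 eigvecs = vec,
                 classical_offset = offset, w_ao = w_ao),
            class = "esp_plan")
}

#' @export
#' @method print esp_plan
print.esp_plan <- function(x, ...) {
  cat(sprintf("<ESP measurement plan: %d natural-potential orbitals, offset %.8f Eh>\n",
              length(x$eigvals), x$classical_offset))
  invisible(x)
}

#' Electrostatic energy from the measurement plan
#'
#' Rotates the active-space state into the ESP natural-orbital basis and
#' accumulates sum_s w_s <n_s> + offset.  All measured operators are
#' occupation numbers in one basis and hence mutually commuting: a single
#' measurement circuit suffices.
#'
#' @param sv_a `statevector` of monomer A's active space.
#' @param plan an `esp_plan`.
#' @return E1_pol in hartree.
#' @export
e1_pol_from_plan <- function(sv_a, plan) {
  n <- sv_a$n_orb
  if (length(plan$eigvals) != n) stop("plan/state dimension mismatch")
  U <- plan$eigvecs
  # rotate the state by U^T so that occupations refer to the ESP basis:
  # gamma' = U^T gamma U
  K <- logm_orthogonal(U)
  svr <- apply_orbital_rotation(sv_a, -K)
  occ <- diag(cpp_sv_gamma(svr$amps, n))
  sum(plan$eigvals * occ) + plan$classical_offset
}

# principal logarithm of a proper orthogonal matrix (real Schur form)
logm_orthogonal <- function(U) {
  n <- nrow(U)
  if (max(abs(t(U) %*% U - diag(n))) > 1e-8) stop("not orthogonal")
  sch <- Matrix::Schur(U)
  Q <- sch$Q; Tm <- sch$T
  K <- matrix(0, n, n)
  neg <- integer(0)
  i <- 1L
  while (i <= n) {
    if (i < n && abs(Tm[i + 1, i]) > 1e-12) {
      th <- atan2(Tm[i + 1, i], Tm[i, i])
      K[i, i + 1] <- -th; K[i + 1, i] <- th
      i <- i + 2L
    } else {
      if (Tm[i, i] < 0) neg <- c(neg, i)
      i <- i + 1L
    }
  }
  # -1 eigenvalues come in pairs for det +1: fold each pair into a pi rotation
  if (length(neg) %% 2L != 0L) stop("improper rotation (det = -1)")
  for (k in seq_len(length(neg) %/% 2L)) {
    i <- neg[2 * k - 1]; j <- neg[2 * k]
    K[i, j] <- -pi; K[j, i] <- pi
  }
  Q %*% K %*% t(Q)
}
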