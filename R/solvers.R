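# Ground-state solvers over an embedded active-space Hamiltonian: exact
# diagonalization in the fixed-(n_alpha, n_beta) determinant basis (CASCI)
# and the variational statevector optimizer (VQE) over the k-muCJ ansatz.

# dense determinant-space Hamiltonian + index map into the statevector
sector_basis <- function(ham, n_alpha, n_beta) {
  n <- ham$n_active_orb
  da <- cpp_det_strings(n, n_alpha)
  db <- cpp_det_strings(n, n_beta)
  H <- cpp_casci_h(ham$h_tilde, as.numeric(ham$eri_active), da, db, n)
  # statevector amplitude index (1-based) of determinant (ia, ib)
  idx <- as.vector(outer(da, db * 2^n, `+`)) + 1L
  list(dets_a = da, dets_b = db, H = H, sv_index = idx)
}

#' Exact active-space CI (CASCI)
#'
#' Lowest eigenpair of the embedded active Hamiltonian in the
#' fixed-(n_alpha, n_beta) determinant basis by dense symmetric
#' diagonalization (determinant-space cap 20000), with spin-summed RDMs
#' computed from the CI vector.
#'
#' @param ham an `active_hamiltonian`.
#' @param n_alpha,n_beta spin occupations (default: split
#'   `n_active_elec` evenly, singlet).
#' @return a `casci_result`: `energy` (includes the core constant),
#'   `ci_vector`, `rdms`, `sector`.
#' @export
casci_solve <- function(ham, n_alpha = ham$n_active_elec %/% 2L,
                        n_beta = ham$n_active_elec %/% 2L) {
  n <- ham$n_active_orb
  dim <- choose(n, n_alpha) * choose(n, n_beta)
  if (dim > 20000) stop("determinant space too large for dense CASCI (cap 20000)")
  sec <- sector_basis(ham, n_alpha, n_beta)
  ev <- eigen((sec$H + t(sec$H)) / 2, symmetric = TRUE)
  ord <- which.min(ev$values)
  ci <- ev$vectors[, ord]
  # deterministic global phase: largest coefficient positive
  ci <- ci * sign(ci[which.max(abs(ci))])
  sv <- structure(list(amps = replace(numeric(2^(2 * n)), sec$sv_index, ci),
                       n_orb = n), class = "statevector")
  rdms <- compute_rdms(sv)
  structure(list(energy = min(ev$values) + ham$e_core, ci_vector = ci,
                 rdms = rdms, statevector = sv,
                 sector = c(n_alpha = n_alpha, n_beta = n_beta)),
            class = "casci_result")
}

#' @export
#' @method print casci_result
print.casci_result <- function(x, ...) {
  cat(sprintf("<CASCI: E = %.10f hartree, sector (%d, %d), %d determinants>\n",
              x$energy, x$sector[1], x$sector[2], length(x$ci_vector)))
  invisible(x)
}

#' VQE objective function
#'
#' Energy of the k-muCJ state prepared from the RHF-like reference, as a
#' deterministic function of the flat parameter vector.
#'
#' @param par flat parameter vector (see [n_mucj_params()]).
#' @param ham an `active_hamiltonian`.
#' @param k circuit repetition factor.
#' @param sector optional precomputed `sector_basis` (internal reuse).
#' @return total energy in hartree (including the core constant).
#' @export
vqe_objective <- function(par, ham, k = 1L, sector = NULL) {
  n <- ham$n_active_orb
  na <- ham$n_active_elec %/% 2L
  params <- mucj_unpack(par, n, k)
  sv <- apply_mucj(prepare_reference(n, na, na), params)
  if (is.null(sector)) return(expectation(sv, ham))
  v <- sv$amps[sector$sv_index]
  drop(v %*% sector$H %*% v) + ham$e_core
}

#' VQE ground-state optimization
#'
#' L-BFGS-B quasi-Newton minimization of the k-muCJ energy starting from
#' all-zero parameters (the identity circuit, i.e. the RHF-like reference),
#' with central finite-difference gradients (step 1e-5).  Optional seeded
#' random restarts (perturbation scale 1e-2) guard against local minima;
#' the best run is returned.
#'
#' @param ham an `active_hamiltonian`.
#' @param k circuit repetition factor (layers of the entangler).
#' @param seed integer seed for the restart perturbations.
#' @param n_restarts number of optimizations (1 = the deterministic
#'   zero-start only).
#' @param maxit L-BFGS-B iteration cap.
#' @param fd_step central-difference step.
#' @return a `vqe_result`: `params` (`ansatz_params`), `par` (flat vector),
#'   `energy`, `rdms`, `n_iterations`, `trace` (running best energy per
#'   evaluation), `converged`.
#' @export
vqe_optimize <- function(ham, k = 1L, seed = 1L, n_restarts = 1L,
                         maxit = 2000L, fd_step = 1e-5) {
  if (k < 1L) stop("k must be >= 1")
  n <- ham$n_active_orb
  na2 <- ham$n_active_elec %/% 2L
  np <- n_mucj_params(n, k)
  sec <- sector_basis(ham, na2, na2)
  evals <- new.env(parent = emptyenv())
  evals$trace <- numeric(0)
  fn <- function(p) {
    e <- vqe_objective(p, ham, k, sec)
    evals$trace <- c(evals$trace,
                     if (length(evals$trace)) min(tail(evals$trace, 1), e) else e)
    e
  }
  gr <- function(p) {
    g <- numeric(np)
    for (i in seq_len(np)) {
      dp <- numeric(np); dp[i] <- fd_step
      g[i] <- (vqe_objective(p + dp, ham, k, sec) -
               vqe_objective(p - dp, ham, k, sec)) / (2 * fd_step)
    }
    g
  }
  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    p0 <- numeric(np)
    if (r > 1L) {
      set.seed(seed + r - 1L)
      p0 <- rnorm(np, sd = 1e-2)
    }
    opt <- optim(p0, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = maxit, factr = 1e4, pgtol = 1e-6))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  params <- mucj_unpack(best$par, n, k)
  sv <- apply_mucj(prepare_reference(n, na2, na2), params)
  rdms <- compute_rdms(sv)
  structure(list(params = params, par = best$par, energy = best$value,
                 rdms = rdms, statevector = sv,
                 n_iterations = best$counts[1],
                 trace = evals$trace,
                 converged = best$convergence == 0),
            class = "vqe_result")
}

#' @export
#' @method print vqe_result
print.vqe_result <- function(x, ...) {
  cat(sprintf("<VQE: E = %.10f hartree, %d fn evaluations, %s>\n",
              x$energy, x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
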