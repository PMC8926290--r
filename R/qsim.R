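# Ideal statevector simulation of the active space: reference preparation,
# spin-restricted orbital rotations compiled to Givens fabrics, four-qubit
# pair-exchange gates, the layered unitary cluster-Jastrow (k-muCJ) ansatz,
# expectation values and spin-summed 1-/2-RDM extraction.
#
# All in-scope circuits are real and conserve the alpha/beta particle
# numbers and S^2, so amplitudes are stored as a real vector of length
# 2^(2 N_a) in blocked alpha-then-beta Jordan-Wigner mode order.

#' Prepare a computational-basis reference determinant
#'
#' Occupies the lowest `n_alpha` alpha and `n_beta` beta spin orbitals.
#'
#' @param n_orb number of spatial orbitals N_a.
#' @param n_alpha,n_beta spin-orbital occupation counts.
#' @return a `statevector` (fields `amps`, `n_orb`).
#' @export
prepare_reference <- function(n_orb, n_alpha, n_beta) {
  if (n_alpha > n_orb || n_beta > n_orb || n_alpha < 0 || n_beta < 0)
    stop("occupation counts exceed the orbital range [0, n_orb]")
  structure(list(amps = cpp_sv_reference(n_orb, n_alpha, n_beta),
                 n_orb = as.integer(n_orb)),
            class = "statevector")
}

#' @export
#' @method print statevector
print.statevector <- function(x, ...) {
  cat(sprintf("<statevector: %d spatial orbitals (%d amplitudes), norm %.6f>\n",
              x$n_orb, length(x$amps), sqrt(sum(x$amps^2))))
  invisible(x)
}

#' Four-qubit pair-exchange gate
#'
#' Rotates the doubly-occupied/doubly-empty closed-shell configurations of
#' two adjacent spatial orbitals (t, t+1) into one another with cos/sin
#' amplitudes; identity on every other sector of the four-qubit space.
#'
#' @param sv a `statevector`.
#' @param pair 1-based index `t` of the lower spatial orbital of the pair.
#' @param theta rotation angle (radians).
#' @return the transformed `statevector`.
#' @export
apply_pair_exchange <- function(sv, pair, theta) {
  if (pair < 1L || pair + 1L > sv$n_orb) stop("pair index out of range")
  sv$amps <- cpp_apply_pairx(sv$amps, sv$n_orb, pair - 1L, theta)
  sv
}

#' Spin-restricted orbital rotation
#'
#' Applies the one-body rotation exp(K) generated by a real antisymmetric
#' matrix kappa, with identical angles for alpha and beta spin orbitals.
#' The orbital-space orthogonal U = expm(kappa) is compiled to a fabric of
#' two-level Givens rotations (QR elimination order) whose composition
#' realizes exactly the one-body unitary; residual -1 diagonal entries are
#' folded into pi rotations (det U = +1 guarantees an even number).
#'
#' @param sv a `statevector`.
#' @param kappa real antisymmetric N_a x N_a generator.
#' @return the transformed `statevector`.
#' @export
apply_orbital_rotation <- function(sv, kappa) {
  ops <- rotation_compile(kappa, sv$n_orb)
  sv$amps <- cpp_apply_ops(sv$amps, sv$n_orb, ops$type, ops$p, ops$q, ops$theta)
  sv
}

# compile exp(kappa) into an ordered Givens gate list (0-based orbitals)
rotation_compile <- function(kappa, n) {
  kappa <- as.matrix(kappa)
  if (any(dim(kappa) != n)) stop("kappa dimension mismatch")
  if (max(abs(kappa + t(kappa))) > 1e-10)
    stop("kappa is not antisymmetric")
  U <- expm_skew((kappa - t(kappa)) / 2)
  rots <- givens_decompose(U)
  # U = G_1 ... G_m D; the circuit applies D first, then G_m ... G_1
  type <- integer(0); p <- integer(0); q <- integer(0); th <- numeric(0)
  for (pr in rev(rots$pi_pairs)) {
    type <- c(type, 0L); p <- c(p, pr[1] - 1L); q <- c(q, pr[2] - 1L)
    th <- c(th, pi)
  }
  for (k in rev(seq_along(rots$rot))) {
    r <- rots$rot[[k]]
    type <- c(type, 0L); p <- c(p, r$i - 1L); q <- c(q, r$j - 1L)
    th <- c(th, r$theta)
  }
  list(type = type, p = p, q = q, theta = th)
}

# matrix exponential of a (small) real skew-symmetric matrix by scaling and
# squaring with a Taylor series; exact orthogonality to machine precision
# is not required (the Givens fabric realizes whatever U is passed)
expm_skew <- function(K) {
  n <- nrow(K)
  nrm <- max(abs(K))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300) / 0.25)))
  A <- K / 2^s
  U <- diag(n); term <- diag(n)
  for (k in 1:14) {
    term <- term %*% A / k
    U <- U + term
    if (max(abs(term)) < 1e-17) break
  }
  for (k in seq_len(s)) U <- U %*% U
  U
}

# QR-style Givens decomposition of a real orthogonal matrix with det +1:
# returns rotations G(i, j, theta) such that U = G_1 ... G_m D with D the
# identity up to paired -1 entries (returned as pi_pairs).
givens_decompose <- function(U) {
  n <- nrow(U)
  W <- U
  rot <- vector("list", n * (n - 1L) / 2L)
  nrot <- 0L
  for (cc in seq_len(n - 1)) {
    for (rr in n:(cc + 1)) {
      a <- W[rr - 1, cc]; b <- W[rr, cc]
      if (abs(b) < 1e-15) next
      th <- atan2(b, a)
      cth <- cos(th); sth <- sin(th)
      # rotate rows (rr-1, rr) in place: G^T W
      r1 <- W[rr - 1, ]; r2 <- W[rr, ]
      W[rr - 1, ] <- cth * r1 + sth * r2
      W[rr, ] <- -sth * r1 + cth * r2
      nrot <- nrot + 1L
      rot[[nrot]] <- list(i = rr - 1L, j = rr, theta = th)
    }
  }
  rot <- rot[seq_len(nrot)]
  d <- diag(W)
  if (max(abs(W - diag(d, n))) > 1e-8)
    stop("Givens decomposition failed to triangularize an orthogonal matrix")
  neg <- which(d < 0)
  if (length(neg) %% 2L != 0L)
    stop("odd reflection count: input was not a proper rotation")
  pi_pairs <- if (length(neg)) split(neg, rep(seq_len(length(neg) / 2), each = 2)) else list()
  # rotation convention check happens in tests (Thouless oracle)
  list(rot = rot, pi_pairs = pi_pairs, resid = d)
}

#' Parameters of the k-muCJ ansatz
#'
#' One layer holds a real antisymmetric orbital-rotation generator `kappa`
#' (N_a x N_a) and a vector `tau` of pair-exchange angles over the
#' alternating nearest-neighbor pair pattern (even-start pairs (1,2), (3,4),
#' ... followed by odd-start pairs (2,3), (4,5), ..., N_a - 1 angles in
#' total); a trailing `kappa_final` closes the circuit.
#'
#' @param layers list of `list(kappa=, tau=)` entries.
#' @param kappa_final trailing orbital-rotation generator.
#' @return an `ansatz_params` object.
#' @export
ansatz_params <- function(layers, kappa_final) {
  for (ly in layers) {
    if (max(abs(ly$kappa + t(ly$kappa))) > 1e-12)
      stop("layer kappa is not antisymmetric")
  }
  if (max(abs(kappa_final + t(kappa_final))) > 1e-12)
    stop("kappa_final is not antisymmetric")
  structure(list(layers = layers, kappa_final = kappa_final),
            class = "ansatz_params")
}

# nearest-neighbor pair pattern for one entangler layer: even-start pairs
# then odd-start pairs (1-based lower indices)
mucj_pairs <- function(n_orb) {
  even <- seq(1L, n_orb - 1L, by = 2L)
  odd <- if (n_orb >= 3L) seq(2L, n_orb - 1L, by = 2L) else integer(0)
  c(even, odd)
}

#' Number of parameters of a k-muCJ ansatz
#' @param n_orb active orbital count.
#' @param k circuit repetition factor.
#' @return integer parameter count.
#' @export
n_mucj_params <- function(n_orb, k) {
  nk <- (n_orb * (n_orb - 1L)) %/% 2L
  as.integer((k + 1L) * nk + k * (n_orb - 1L))
}

# pack/unpack a flat parameter vector (lower triangles of the kappas and
# the tau vectors, layer by layer, then the trailing kappa)
mucj_unpack <- function(par, n_orb, k) {
  nk <- (n_orb * (n_orb - 1L)) %/% 2L
  npair <- n_orb - 1L
  stopifnot(length(par) == n_mucj_params(n_orb, k))
  pos <- 0L
  tri <- function(v) {
    m <- matrix(0, n_orb, n_orb)
    m[lower.tri(m)] <- v
    m - t(m)
  }
  layers <- vector("list", k)
  for (l in seq_len(k)) {
    kap <- tri(par[pos + seq_len(nk)]); pos <- pos + nk
    tau <- par[pos + seq_len(npair)]; pos <- pos + npair
    layers[[l]] <- list(kappa = kap, tau = tau)
  }
  kf <- tri(par[pos + seq_len(nk)])
  ansatz_params(layers, kf)
}

#' Apply the k-muCJ circuit
#'
#' Per layer: an orbital rotation followed by the pair-exchange entangler
#' over the alternating pair pattern; a trailing orbital rotation closes the
#' circuit.  All-zero parameters give the identity, so the reference
#' determinant is preserved.
#'
#' @param sv a `statevector` (typically the RHF reference).
#' @param params an `ansatz_params`.
#' @return the transformed `statevector`.
#' @export
apply_mucj <- function(sv, params) {
  n <- sv$n_orb
  prs <- mucj_pairs(n)
  type <- integer(0); p <- integer(0); q <- integer(0); th <- numeric(0)
  add <- function(ops) {
    type <<- c(type, ops$type); p <<- c(p, ops$p); q <<- c(q, ops$q)
    th <<- c(th, ops$theta)
  }
  for (ly in params$layers) {
    if (length(ly$tau) != length(prs))
      stop("tau length does not match the pair pattern")
    add(rotation_compile(ly$kappa, n))
    add(list(type = rep(1L, length(prs)), p = prs - 1L,
             q = prs, theta = ly$tau))
  }
  add(rotation_compile(params$kappa_final, n))
  sv$amps <- cpp_apply_ops(sv$amps, n, type, p, q, th)
  sv
}

#' Spin-summed reduced density matrices of a statevector
#'
#' gamma_pq = <E_pq>; Gamma_pp'rr' = <E_pp' E_rr'> - delta_p'r gamma_pr'
#' (chemists' index pairing), by direct statevector contraction.
#'
#' @param sv a `statevector`.
#' @return an `rdm_pair`: `gamma`, `gamma2`, `n_elec`.
#' @export
compute_rdms <- function(sv) {
  n <- sv$n_orb
  g <- cpp_sv_gamma(sv$amps, n)
  W <- cpp_sv_epq_all(sv$amps, n)  # column p + q*n holds E_pq|psi>
  M <- crossprod(W)
  G2 <- array(0, c(n, n, n, n))
  for (p in 1:n) for (pp in 1:n) for (r in 1:n) for (rp in 1:n) {
    G2[p, pp, r, rp] <- M[(pp - 1) + (p - 1) * n + 1, (r - 1) + (rp - 1) * n + 1] -
      (if (pp == r) g[p, rp] else 0)
  }
  structure(list(gamma = (g + t(g)) / 2, gamma2 = G2,
                 n_elec = round(sum(diag(g)))),
            class = "rdm_pair")
}

#' Energy expectation of a statevector under an active Hamiltonian
#'
#' <psi|H_active|psi> + E_core via the reduced-density-matrix contraction
#' E = sum h-tilde gamma + 1/2 sum (tt'|uu') Gamma + E_core.
#'
#' @param sv a `statevector`.
#' @param ham an `active_hamiltonian`.
#' @return energy in hartree.
#' @export
expectation <- function(sv, ham) {
  if (sv$n_orb != ham$n_active_orb) stop("dimension mismatch")
  rdm <- compute_rdms(sv)
  rdm_energy(rdm, ham)
}

#' Energy from density matrices
#' @param rdm an `rdm_pair` over the active space.
#' @param ham an `active_hamiltonian`.
#' @return energy in hartree (including the core constant).
#' @export
rdm_energy <- function(rdm, ham) {
  sum(ham$h_tilde * rdm$gamma) + 0.5 * sum(ham$eri_active * rdm$gamma2) +
    ham$e_core
}

# expectation values of number operators and S^2 (symmetry diagnostics)
sv_symmetries <- function(sv) {
  n <- sv$n_orb
  dim <- length(sv$amps)
  idx <- 0:(dim - 1)
  amask <- 2^n - 1
  na_bits <- vapply(idx, function(b) sum(bitwAnd(b, amask) %/% 2^(0:(n - 1)) %% 2), 0)
  nb_bits <- vapply(idx, function(b) {
    hb <- b %/% 2^n
    sum(hb %/% 2^(0:(n - 1)) %% 2)
  }, 0)
  w <- sv$amps^2
  n_alpha <- sum(w * na_bits); n_beta <- sum(w * nb_bits)
  # S^2 = S- S+ + Sz(Sz + 1); S+ = sum_p a^+_{p alpha} a_{p beta}
  spl <- numeric(dim)
  for (p in 0:(n - 1))
    spl <- spl + cpp_apply_ccop(sv$amps, p, n + p)
  sz <- (na_bits - nb_bits) / 2
  s2 <- sum(spl^2) + sum(w * sz * (sz + 1))
  list(n_alpha = n_alpha, n_beta = n_beta, s2 = s2)
}
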