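# Independent oracles.
#
# (1) Closed-form integrals over s-type Gaussian primitives, written directly
#     from the Gaussian product theorem in plain R: cross-checks the
#     McMurchie-Davidson kernels without sharing any code with them.
# (2) A first-quantized brute-force evaluation of <P1>, <V>, <V P1> for two
#     two-electron monomers whose wavefunctions are explicit sums of
#     spin-orbital products: the exact reference for the S^2 exchange
#     -(<V P1> - <V><P1>) for both RHF and CASCI monomer states.

# ---- (1) s-primitive closed forms -----------------------------------------
erf0 <- function(x) 2 * pnorm(x * sqrt(2)) - 1
f0 <- function(t) ifelse(t < 1e-12, 1 - t / 3, 0.5 * sqrt(pi / t) * erf0(sqrt(t)))

snorm <- function(a) (2 * a / pi)^0.75

s_overlap <- function(a, A, b, B) {
  p <- a + b; q <- a * b / p
  snorm(a) * snorm(b) * (pi / p)^1.5 * exp(-q * sum((A - B)^2))
}
s_kinetic <- function(a, A, b, B) {
  p <- a + b; q <- a * b / p; r2 <- sum((A - B)^2)
  q * (3 - 2 * q * r2) * snorm(a) * snorm(b) * (pi / p)^1.5 * exp(-q * r2)
}
s_nuclear <- function(a, A, b, B, Z, C) {
  p <- a + b; q <- a * b / p
  P <- (a * A + b * B) / p
  -Z * snorm(a) * snorm(b) * (2 * pi / p) * exp(-q * sum((A - B)^2)) *
    f0(p * sum((P - C)^2))
}
s_eri <- function(a, A, b, B, c_, C, d, D) {
  p <- a + b; q <- c_ + d
  P <- (a * A + b * B) / p; Q <- (c_ * C + d * D) / q
  w <- p * q / (p + q)
  snorm(a) * snorm(b) * snorm(c_) * snorm(d) *
    2 * pi^2.5 / (p * q * sqrt(p + q)) *
    exp(-a * b / p * sum((A - B)^2)) * exp(-c_ * d / q * sum((C - D)^2)) *
    f0(w * sum((P - Q)^2))
}

# single-primitive s shell in the layout the kernels expect
s_shell <- function(a, A) {
  list(l = 0L, x = A[1], y = A[2], z = A[3], nprim = 1L, pstart = 0L,
       pexp = a, pcoef = 1.0, nbf = 1L)
}

# ---- (2) brute-force first-order quantities for 2+2 electrons -------------
# Orbital model: a small set of spatial orbitals, the first `mA` on monomer
# A, the rest on monomer B, given by AO coefficient blocks.  Wavefunctions
# are lists of products: list(c = coef, so = list(c(orbital, spin), ...))
# with one spin-orbital per electron (2 electrons per monomer; electrons
# 1:2 on A, 3:4 on B).  Returns <P1>, <V>, <V P1> and the S^2 exchange.

bf_orbital_integrals <- function(dimer, CA, CB) {
  ia <- compute_monomer_integrals(dimer$monomer_a, dimer$basis_a)
  ib <- compute_monomer_integrals(dimer$monomer_b, dimer$basis_b)
  cr <- compute_cross_integrals(dimer)
  shA <- ia$shells; shB <- ib$shells
  mA <- ncol(CA); mB <- ncol(CB); m <- mA + mB
  ZA <- saptvqe:::nuclear_charges(dimer$monomer_a)
  ZB <- saptvqe:::nuclear_charges(dimer$monomer_b)
  S <- matrix(0, m, m); vA <- matrix(0, m, m); vB <- matrix(0, m, m)
  TkAA <- saptvqe:::cpp_kinetic(shA, shA)
  TkBB <- saptvqe:::cpp_kinetic(shB, shB)
  TkAB <- saptvqe:::cpp_kinetic(shA, shB)
  iA <- seq_len(mA); iB <- mA + seq_len(mB)
  S[iA, iA] <- t(CA) %*% saptvqe:::cpp_overlap(shA, shA) %*% CA
  S[iB, iB] <- t(CB) %*% saptvqe:::cpp_overlap(shB, shB) %*% CB
  S[iA, iB] <- t(CA) %*% cr$s_ab %*% CB; S[iB, iA] <- t(S[iA, iB])
  vA[iA, iA] <- t(CA) %*% saptvqe:::cpp_nuclear(shA, shA, ZA, dimer$monomer_a$coords) %*% CA
  vA[iB, iB] <- t(CB) %*% cr$v_a_on_b %*% CB
  vA[iA, iB] <- t(CA) %*% cr$v_a_mixed %*% CB; vA[iB, iA] <- t(vA[iA, iB])
  vB[iB, iB] <- t(CB) %*% saptvqe:::cpp_nuclear(shB, shB, ZB, dimer$monomer_b$coords) %*% CB
  vB[iA, iA] <- t(CA) %*% cr$v_b_on_a %*% CA
  vB[iA, iB] <- t(CA) %*% cr$v_b_mixed %*% CB; vB[iB, iA] <- t(vB[iA, iB])
  Tk <- matrix(0, m, m)
  Tk[iA, iA] <- t(CA) %*% TkAA %*% CA
  Tk[iB, iB] <- t(CB) %*% TkBB %*% CB
  Tk[iA, iB] <- t(CA) %*% TkAB %*% CB; Tk[iB, iA] <- t(Tk[iA, iB])
  sh <- list(shA, shB)[c(rep(1, mA), rep(2, mB))]
  cl <- c(lapply(iA, function(i) CA[, i, drop = FALSE]),
          lapply(seq_len(mB), function(i) CB[, i, drop = FALSE]))
  g <- array(0, c(m, m, m, m))
  for (i in 1:m) for (j in 1:m) for (k in 1:m) for (l in 1:m)
    g[i, j, k, l] <- saptvqe:::cpp_eri_mo(sh[[i]], cl[[i]], sh[[j]], cl[[j]],
                                          sh[[k]], cl[[k]], sh[[l]], cl[[l]],
                                          FALSE, FALSE)[1, 1, 1, 1]
  list(S = S, vA = vA, vB = vB, Tk = Tk, g = g, v_nn = cr$v_nn,
       e_nn_a = ia$nuclear_repulsion, e_nn_b = ib$nuclear_repulsion)
}

# determinant (2-electron, alpha/beta spatial orbitals p, q) -> product terms
bf_det2 <- function(p, q, coef = 1) {
  list(list(c = coef / sqrt(2), so = list(c(p, 1L), c(q, 2L))),
       list(c = -coef / sqrt(2), so = list(c(q, 2L), c(p, 1L))))
}

# CI vector over the (1 alpha, 1 beta) sector of 2 orbitals -> product list;
# `orbs` maps the two active orbitals to global orbital indices
bf_ci_products <- function(ci, dets_a, dets_b, orbs) {
  out <- list()
  na <- length(dets_a)
  for (ib in seq_along(dets_b)) for (ia in seq_along(dets_a)) {
    c0 <- ci[ia + (ib - 1) * na]
    if (abs(c0) < 1e-14) next
    p <- orbs[which(bitwAnd(dets_a[ia], c(1L, 2L)) > 0)]
    q <- orbs[which(bitwAnd(dets_b[ib], c(1L, 2L)) > 0)]
    out <- c(out, bf_det2(p, q, c0))
  }
  out
}

bf_first_order <- function(ints, prodsA, prodsB) {
  S <- ints$S; vA <- ints$vA; vB <- ints$vB; g <- ints$g
  kets <- list()
  for (ta in prodsA) for (tb in prodsB)
    kets[[length(kets) + 1]] <- list(c = ta$c * tb$c, so = c(ta$so, tb$so))
  mel <- function(op, i = NULL, j = NULL, pi_ = NULL, pj_ = NULL,
                  hmat = NULL) {
    tot <- 0
    for (kb in kets) for (kk in kets) {
      so_ket <- kk$so
      if (!is.null(pi_)) {
        tmp <- so_ket[[pi_]]; so_ket[[pi_]] <- so_ket[[pj_]]
        so_ket[[pj_]] <- tmp
      }
      ok <- TRUE
      for (e in 1:4) if (kb$so[[e]][2] != so_ket[[e]][2]) { ok <- FALSE; break }
      if (!ok) next
      ovl <- vapply(1:4, function(e) S[kb$so[[e]][1], so_ket[[e]][1]], 0)
      cf <- kb$c * kk$c
      if (op == "unit") {
        tot <- tot + cf * prod(ovl)
      } else if (op == "one") {
        tot <- tot + cf * hmat[kb$so[[i]][1], so_ket[[i]][1]] * prod(ovl[-i])
      } else {  # two-electron 1/r_ij
        tot <- tot + cf * prod(ovl[-c(i, j)]) *
          g[kb$so[[i]][1], so_ket[[i]][1], kb$so[[j]][1], so_ket[[j]][1]]
      }
    }
    tot
  }
  P1 <- 0; VP1 <- 0
  for (i in 1:2) for (j in 3:4) {
    P1 <- P1 + mel("unit", pi_ = i, pj_ = j)
    for (k in 1:2) VP1 <- VP1 + mel("one", i = k, pi_ = i, pj_ = j, hmat = vB)
    for (l in 3:4) VP1 <- VP1 + mel("one", i = l, pi_ = i, pj_ = j, hmat = vA)
    for (k in 1:2) for (l in 3:4)
      VP1 <- VP1 + mel("two", i = k, j = l, pi_ = i, pj_ = j)
    VP1 <- VP1 + ints$v_nn * mel("unit", pi_ = i, pj_ = j)
  }
  Vx <- 0
  for (k in 1:2) Vx <- Vx + mel("one", i = k, hmat = vB)
  for (l in 3:4) Vx <- Vx + mel("one", i = l, hmat = vA)
  for (k in 1:2) for (l in 3:4) Vx <- Vx + mel("two", i = k, j = l)
  Vx <- Vx + ints$v_nn
  # intramonomer Hamiltonian couplings through the single exchange
  hA <- ints$Tk + ints$vA; hB <- ints$Tk + ints$vB
  melH <- function(hmat, elecs, pi_, pj_) {
    tot <- 0
    for (e in elecs) tot <- tot + mel("one", i = e, pi_ = pi_, pj_ = pj_, hmat = hmat)
    tot + mel("two", i = elecs[1], j = elecs[2], pi_ = pi_, pj_ = pj_)
  }
  HA_P1 <- 0; HB_P1 <- 0
  for (i in 1:2) for (j in 3:4) {
    HA_P1 <- HA_P1 + melH(hA, c(1, 2), i, j)
    HB_P1 <- HB_P1 + melH(hB, c(3, 4), i, j)
  }
  list(P1 = P1, V = Vx, VP1 = VP1, exch_s2 = -(VP1 - Vx * P1),
       HA_P1 = HA_P1, HB_P1 = HB_P1)
}
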