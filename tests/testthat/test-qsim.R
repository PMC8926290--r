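# Statevector machinery: reference states, gates, the k-muCJ circuit,
# symmetry conservation and density-matrix extraction.

test_that("reference preparation yields the documented determinants", {
  sv <- prepare_reference(2, 1, 1)
  expect_equal(sum(sv$amps != 0), 1L)
  expect_equal(sum(sv$amps^2), 1)
  sy <- saptvqe:::sv_symmetries(sv)
  expect_equal(sy$n_alpha, 1)
  expect_equal(sy$n_beta, 1)
  sv0 <- prepare_reference(3, 0, 0)
  expect_equal(which(sv0$amps != 0), 1L)  # the all-zeros state
  expect_error(prepare_reference(2, 3, 0), "exceed")
})

test_that("the pair-exchange gate is the documented four-qubit rotation", {
  # dense matrix on a 2-orbital register
  dim <- 2^4
  U <- vapply(seq_len(dim), function(i) {
    v <- numeric(dim); v[i] <- 1
    saptvqe:::cpp_apply_pairx(v, 2L, 0L, 0.3)
  }, numeric(dim))
  expect_lt(max(abs(t(U) %*% U - diag(dim))), 1e-12)
  # mixing the doubly-occupied pair: |1100> (both spins orbital 1) with
  # |0011>; amplitude pattern cos/sin; identity on every other sector
  i20 <- 1 + 1 + 4   # bits alpha_0 and beta_0 (positions 0 and 2)
  i02 <- 1 + 2 + 8
  expect_equal(U[i20, i20], cos(0.3), tolerance = 1e-14)
  expect_equal(abs(U[i02, i20]), sin(0.3), tolerance = 1e-14)
  off <- setdiff(seq_len(dim), c(i20, i02))
  expect_lt(max(abs(U[off, off] - diag(length(off)))), 1e-14)
  # theta = 0 is the identity; theta and -theta invert each other
  sv <- prepare_reference(2, 1, 1)
  expect_identical(apply_pair_exchange(sv, 1, 0)$amps, sv$amps)
  svr <- apply_pair_exchange(apply_pair_exchange(sv, 1, 0.7), 1, -0.7)
  expect_lt(max(abs(svr$amps - sv$amps)), 1e-12)
  expect_error(apply_pair_exchange(sv, 2, 0.1), "out of range")
})

test_that("orbital rotations realize the one-body exponential (Thouless)", {
  set.seed(31)
  for (n in c(2L, 4L)) {
    K <- matrix(rnorm(n * n), n); K <- K - t(K)
    sv0 <- prepare_reference(n, n %/% 2, n %/% 2)
    sv1 <- apply_orbital_rotation(sv0, K)
    U <- saptvqe:::expm_skew(K)
    g0 <- compute_rdms(sv0)$gamma
    g1 <- compute_rdms(sv1)$gamma
    expect_lt(max(abs(g1 - U %*% g0 %*% t(U))), 1e-9)
    expect_equal(sum(sv1$amps^2), 1, tolerance = 1e-12)
  }
  # 2-orbital closed form: occupations rotate as cos^2 / sin^2
  th <- 0.4
  K <- matrix(c(0, -th, th, 0), 2)
  sv <- apply_orbital_rotation(prepare_reference(2, 1, 1), K)
  occ <- diag(compute_rdms(sv)$gamma)
  expect_equal(occ, c(2 * cos(th)^2, 2 * sin(th)^2), tolerance = 1e-10)
  expect_error(apply_orbital_rotation(prepare_reference(2, 1, 1),
                                      matrix(1, 2, 2)), "antisymmetric")
  # kappa = 0 is the identity
  sv0 <- prepare_reference(3, 2, 1)
  expect_lt(max(abs(apply_orbital_rotation(sv0, matrix(0, 3, 3))$amps -
                    sv0$amps)), 1e-15)
})

test_that("the muCJ circuit preserves the symmetries and the reference at zero", {
  n <- 4L
  sv0 <- prepare_reference(n, 2, 2)
  zero <- saptvqe:::mucj_unpack(numeric(n_mucj_params(n, 2L)), n, 2L)
  expect_lt(max(abs(apply_mucj(sv0, zero)$amps - sv0$amps)), 1e-12)
  set.seed(41)
  for (k in 1:2) {
    par <- rnorm(n_mucj_params(n, k), sd = 0.4)
    sv <- apply_mucj(sv0, saptvqe:::mucj_unpack(par, n, k))
    sy <- saptvqe:::sv_symmetries(sv)
    expect_equal(sy$n_alpha, 2, tolerance = 1e-9)
    expect_equal(sy$n_beta, 2, tolerance = 1e-9)
    expect_equal(sy$s2, 0, tolerance = 1e-9)
    expect_equal(sum(sv$amps^2), 1, tolerance = 1e-10)
  }
})

test_that("a single pair-exchange angle sweeps the (2e,2o) closed-shell space", {
  # overlap with the doubly-excited determinant spans [-1, 1]
  sv0 <- prepare_reference(2, 1, 1)
  idx_excited <- 1 + 2 + 8  # both spins in orbital 2
  overlaps <- vapply(seq(-pi, pi, length.out = 41), function(th)
    apply_pair_exchange(sv0, 1, th)$amps[idx_excited], 0)
  expect_equal(max(overlaps), 1, tolerance = 1e-6)
  expect_equal(min(overlaps), -1, tolerance = 1e-6)
})

test_that("density matrices have the documented structure and close the energy", {
  sv0 <- prepare_reference(2, 1, 1)
  r0 <- compute_rdms(sv0)
  expect_equal(r0$gamma, diag(c(2, 0)), tolerance = 1e-12)
  expect_equal(r0$n_elec, 2)
  ham <- fix_h2_ham()
  set.seed(51)
  par <- rnorm(n_mucj_params(2L, 1L), sd = 0.5)
  sv <- apply_mucj(sv0, saptvqe:::mucj_unpack(par, 2L, 1L))
  rdm <- compute_rdms(sv)
  expect_equal(sum(diag(rdm$gamma)), 2, tolerance = 1e-9)
  ev <- eigen(rdm$gamma, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-9 & ev < 2 + 1e-9))
  expect_equal(rdm_energy(rdm, ham), expectation(sv, ham), tolerance = 1e-12)
  # full check of Gamma against a direct spin-resolved contraction built
  # from elementary annihilators (independent of the E_pq route)
  n <- 2L
  ann <- function(v, mode) {
    out <- numeric(length(v))
    for (b in seq_along(v)) {
      bits <- b - 1L
      if (bitwAnd(bits, bitwShiftL(1L, mode)) == 0L) next
      below <- sum(bitwAnd(bits, bitwShiftL(1L, seq_len(mode) - 1L)) > 0)
      sgn <- if (mode == 0L) 1 else (-1)^below
      out[bitwXor(bits, bitwShiftL(1L, mode)) + 1L] <-
        out[bitwXor(bits, bitwShiftL(1L, mode)) + 1L] + sgn * v[b]
    }
    out
  }
  gamma2_direct <- array(0, c(n, n, n, n))
  for (p in 1:n) for (pp in 1:n) for (r in 1:n) for (rp in 1:n) {
    acc <- 0
    for (s1 in 0:1) for (s2 in 0:1) {
      wket <- ann(ann(sv$amps, (rp - 1L) + s2 * n), (pp - 1L) + s1 * n)
      wbra <- ann(ann(sv$amps, (r - 1L) + s2 * n), (p - 1L) + s1 * n)
      acc <- acc + sum(wbra * wket)
    }
    gamma2_direct[p, pp, r, rp] <- acc
  }
  expect_lt(max(abs(gamma2_direct - rdm$gamma2)), 1e-10)
  # trace identity of the spin-summed 2-RDM
  tr2 <- sum(vapply(1:n, function(p) sum(vapply(1:n, function(r)
    rdm$gamma2[p, p, r, r], 0)), 0))
  expect_equal(tr2, 2 * (2 - 1), tolerance = 1e-9)
})
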