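# Orbital partitioning, core folding, the embedded Hamiltonian, and the
# full-space density-matrix reassembly.

test_that("select_window picks the documented canonical-orbital window", {
  rep <- fix_water_rhf_report()
  scf <- rep$monomer_a$scf
  part <- select_window(scf, 6L, 6L)
  # water: 5 occupied; (6e,6o) spans HOMO-2 .. LUMO+2 -> core = 2
  expect_equal(part$core, 1:2)
  expect_equal(part$active, 3:8)
  expect_equal(part$virtual, 9:13)
  # full-space window
  full <- select_window(scf, 10L, 13L)
  expect_equal(length(full$core), 0L)
  expect_equal(length(full$virtual), 0L)
  expect_error(select_window(scf, 6L, 20L), "exceeds the basis")
  expect_error(select_window(scf, 12L, 6L))
  expect_error(select_window(scf, 5L, 6L), "even")
  # deterministic: repeated calls give identical partitions
  expect_identical(select_window(scf, 6L, 6L), select_window(scf, 6L, 6L))
})

test_that("core environment folds the core as documented", {
  rep <- fix_water_rhf_report()
  ints <- rep$monomer_a$ints; scf <- rep$monomer_a$scf
  part <- select_window(scf, 6L, 6L)
  env <- build_core_environment(ints, scf, part)
  S <- ints$overlap
  # idempotency and electron count of the core density
  expect_lt(max(abs(env$d_core %*% S %*% env$d_core - 2 * env$d_core)), 1e-8)
  expect_equal(sum(env$d_core * S), 2 * length(part$core), tolerance = 1e-9)
  expect_lt(max(abs(env$h_tilde_ao - t(env$h_tilde_ao))), 1e-10)
  # empty core: h-tilde reduces to the bare core Hamiltonian
  full <- select_window(scf, 10L, 13L)
  env0 <- build_core_environment(ints, scf, full)
  expect_equal(max(abs(env0$j_core)), 0)
  expect_equal(max(abs(env0$k_core)), 0)
  expect_lt(max(abs(env0$h_tilde_ao - ints$core_h)), 1e-12)
  expect_equal(env0$e_core, ints$nuclear_repulsion, tolerance = 1e-12)
})

test_that("embedded CASCI equals an independent frozen-core CI", {
  # water / STO-3G: frozen-core CI built directly in the *full* MO space
  # from unfolded integrals, with the core orbitals frozen in the
  # determinant strings -- an independent route to the same energy.
  w <- fix_water_eq()$monomer_a
  ints <- compute_monomer_integrals(w, "sto-3g")
  scf <- run_rhf(ints)
  part <- select_window(scf, 4L, 4L)   # (4e,4o), core = 3
  ham <- build_active_hamiltonian(ints, scf, part)
  cas <- casci_solve(ham)
  n <- ints$n_basis
  C <- scf$mo_coeff
  hmo <- t(C) %*% ints$core_h %*% C
  gmo <- saptvqe:::cpp_eri_mo(ints$shells, C, ints$shells, C,
                              ints$shells, C, ints$shells, C, TRUE, TRUE)
  core_mask <- sum(2^(part$core - 1))
  act_strings <- saptvqe:::cpp_det_strings(length(part$active), 2L)
  dets <- as.integer(core_mask + act_strings * 2^length(part$core))
  # frozen-core determinant basis over all orbitals, unfolded integrals
  H <- saptvqe:::cpp_casci_h(hmo, as.numeric(gmo), dets, dets, n)
  e_frozen <- min(eigen((H + t(H)) / 2, symmetric = TRUE,
                        only.values = TRUE)$values) + ints$nuclear_repulsion
  expect_equal(cas$energy, e_frozen, tolerance = 1e-8)
})

test_that("embedded Hamiltonian invariants hold", {
  rep <- fix_water_rhf_report()
  ints <- rep$monomer_a$ints; scf <- rep$monomer_a$scf
  part <- select_window(scf, 6L, 6L)
  ham <- build_active_hamiltonian(ints, scf, part)
  expect_lt(max(abs(ham$h_tilde - t(ham$h_tilde))), 1e-10)
  g <- ham$eri_active
  expect_lt(max(abs(g - aperm(g, c(2, 1, 3, 4)))), 1e-10)
  expect_lt(max(abs(g - aperm(g, c(3, 4, 1, 2)))), 1e-10)
  # reference determinant through the embedding reproduces the RHF energy
  sv0 <- prepare_reference(6, 3, 3)
  expect_equal(expectation(sv0, ham), scf$e_total, tolerance = 1e-8)
  # full-space partition: h_tilde is the plain MO one-electron matrix
  full <- select_window(scf, 10L, 13L)
  ham_full <- build_active_hamiltonian(ints, scf, full)
  hmo <- t(scf$mo_coeff) %*% ints$core_h %*% scf$mo_coeff
  expect_lt(max(abs(ham_full$h_tilde - hmo)), 1e-9)
  # invariance under unitary mixing of the core orbitals
  set.seed(21)
  Q <- qr.Q(qr(matrix(rnorm(4), 2)))
  scf_rot <- scf
  scf_rot$mo_coeff[, part$core] <- scf$mo_coeff[, part$core] %*% Q
  ham_rot <- build_active_hamiltonian(ints, scf_rot, part)
  expect_lt(max(abs(ham_rot$h_tilde - ham$h_tilde)), 1e-9)
  expect_equal(ham_rot$e_core, ham$e_core, tolerance = 1e-9)
})

test_that("full-space density matrices reassemble correctly", {
  cas <- fix_water_casci()
  ham <- fix_water_ham()
  part <- ham$part
  full <- assemble_full_space_rdms(cas$rdms, part)
  n <- length(part$core) + length(part$active) + length(part$virtual)
  expect_equal(sum(diag(full$gamma)), 10, tolerance = 1e-9)
  # energy reconstruction through unfolded full-space integrals
  ints <- ham$ints; scf <- ham$scf
  C <- scf$mo_coeff
  hmo <- t(C) %*% ints$core_h %*% C
  gmo <- saptvqe:::cpp_eri_mo(ints$shells, C, ints$shells, C,
                              ints$shells, C, ints$shells, C, TRUE, TRUE)
  e <- sum(hmo * full$gamma) + 0.5 * sum(gmo * full$gamma2) +
    ints$nuclear_repulsion
  expect_equal(e, cas$energy, tolerance = 1e-8)
  # virtual blocks vanish
  virt <- part$virtual
  expect_equal(max(abs(full$gamma[virt, ])), 0)
  expect_equal(max(abs(full$gamma2[virt, , , ])), 0)
  # empty active space: closed-shell core expressions only
  part0 <- orbital_partition(core = 1:2, active = integer(0), virtual = 3:4,
                             n_active_elec = 0L)
  f0 <- assemble_full_space_rdms(list(gamma = matrix(0, 0, 0),
                                      gamma2 = array(0, c(0, 0, 0, 0))), part0)
  expect_equal(diag(f0$gamma), c(2, 2, 0, 0))
  expect_equal(f0$gamma2[1, 1, 2, 2], 4)
  expect_equal(f0$gamma2[1, 2, 2, 1], -2)
  expect_equal(sum(f0$gamma2[1, 1, 1, 1]), 2)
})
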