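# The first-order SAPT engine: electrostatics, the S^2 exchange and its
# oracles.  The exact reference for the exchange is the first-quantized
# brute-force evaluation of -(<V P1> - <V><P1>) in helper-oracles.R.

test_that("electrostatics matches a term-by-term independent evaluation", {
  rep <- fix_water_rhf_report()
  cr <- rep$cross
  DA <- ao_density(rep$monomer_a$scf, rep$monomer_a$part)
  DB <- ao_density(rep$monomer_b$scf, rep$monomer_b$part)
  # independent: explicit loop over the four classical pieces
  nA <- nrow(DA)
  Em <- matrix(cr$eri_cross, nrow = nA * nA)
  ee <- drop(as.numeric(DA) %*% Em %*% as.numeric(DB))
  en <- sum(DA * cr$v_b_on_a) + sum(DB * cr$v_a_on_b)
  expect_equal(rep$e1_pol, ee + en + cr$v_nn, tolerance = 1e-12)
  # density with a wrong trace is rejected
  expect_error(e1_pol(2 * DA, DB, cr), "traces to")
})

test_that("both first-order components vanish at 50 Angstrom", {
  far <- sapt_report(make_toy_dimer("hehe", 50))
  expect_lt(abs(far$e1_pol), 1e-8)
  expect_lt(abs(far$e1_exch_s2), 1e-10)
  farh <- sapt_report(make_toy_dimer("h2h2", 50, basis = "sto-3g"))
  expect_lt(abs(farh$e1_exch_s2), 1e-10)
})

test_that("generalized J/K matrices satisfy their contraction identities", {
  rep <- fix_water_rhf_report()
  cr <- rep$cross
  DA <- ao_density(rep$monomer_a$scf, rep$monomer_a$part)
  DB <- ao_density(rep$monomer_b$scf, rep$monomer_b$part)
  jk <- build_generalized_jk(cr, DB)
  expect_equal(sum(DA * jk$j_tilde), rep$e1_pol, tolerance = 1e-10)
  expect_equal(-0.5 * sum(DA * jk$k_tilde), rep$breakdown$t1, tolerance = 1e-10)
  # zeroing the overlap and nuclear dressing reduces J-tilde to the plain
  # cross-ERI Coulomb build
  cr0 <- cr
  cr0$s_ab[] <- 0; cr0$v_a_on_b[] <- 0; cr0$v_b_on_a[] <- 0
  cr0$v_a_mixed[] <- 0; cr0$v_b_mixed[] <- 0; cr0$v_nn <- 0
  jk0 <- build_generalized_jk(cr0, DB)
  nA <- nrow(DA)
  jx <- matrix(matrix(cr$eri_cross, nrow = nA * nA) %*% as.numeric(DB), nA, nA)
  expect_lt(max(abs(jk0$j_tilde - jx)), 1e-12)
})

test_that("RHF exchange matches the brute-force first-order expansion", {
  d <- fix_h2h2()
  r <- sapt_report(d)
  ia <- compute_monomer_integrals(d$monomer_a, d$basis_a)
  ib <- compute_monomer_integrals(d$monomer_b, d$basis_b)
  CA <- run_rhf(ia)$mo_coeff[, 1, drop = FALSE]
  CB <- run_rhf(ib)$mo_coeff[, 1, drop = FALSE]
  ints <- bf_orbital_integrals(d, CA, CB)
  bf <- bf_first_order(ints, bf_det2(1, 1), bf_det2(2, 2))
  expect_equal(r$e1_pol, bf$V, tolerance = 1e-9)
  expect_equal(r$e1_exch_s2, bf$exch_s2, tolerance = 1e-9)
})

test_that("correlated (CASCI) exchange matches the brute-force expansion", {
  d <- fix_h2h2()
  # (2e,2o) CASCI on each monomer
  solveA <- function(mol) {
    ints <- compute_monomer_integrals(mol, d$basis_a)
    scf <- run_rhf(ints)
    part <- select_window(scf, 2L, 2L)
    ham <- build_active_hamiltonian(ints, scf, part)
    list(ints = ints, scf = scf, part = part, ham = ham,
         cas = casci_solve(ham))
  }
  A <- solveA(d$monomer_a); B <- solveA(d$monomer_b)
  cr <- compute_cross_integrals(d)
  DA <- ao_density(A$scf, A$part, A$cas$rdms)
  DB <- ao_density(B$scf, B$part, B$cas$rdms)
  pol <- e1_pol(DA, DB, cr)
  brk <- e1_exch_s2(A$cas$rdms, B$cas$rdms, A$part, B$part, A$scf, B$scf,
                    cr, e1pol = pol)
  # brute force with the CI wavefunctions (2 orbitals per monomer)
  CA <- A$scf$mo_coeff[, A$part$active, drop = FALSE]
  CB <- B$scf$mo_coeff[, B$part$active, drop = FALSE]
  ints_o <- bf_orbital_integrals(d, CA, CB)
  da <- saptvqe:::cpp_det_strings(2L, 1L)
  prodsA <- bf_ci_products(A$cas$ci_vector, da, da, orbs = c(1, 2))
  prodsB <- bf_ci_products(B$cas$ci_vector, da, da, orbs = c(3, 4))
  bf <- bf_first_order(ints_o, prodsA, prodsB)
  expect_equal(pol, bf$V, tolerance = 1e-9)
  expect_equal(brk$total, bf$exch_s2, tolerance = 1e-9)
})

test_that("the Heitler-London decomposition identity closes", {
  # E_HL - E_A - E_B = E1_pol + E1_exch(S2) + <(H_A-E_A + H_B-E_B) P1-part>
  # up to O(S^4); the middle term comes from the brute-force expansion
  # (separation chosen where the S^4 residue sits below the tolerance).
  d <- fix_h2h2(4)
  r <- sapt_report(d)
  hl <- heitler_london_first_order(d)
  ia <- compute_monomer_integrals(d$monomer_a, d$basis_a)
  ib <- compute_monomer_integrals(d$monomer_b, d$basis_b)
  sa <- run_rhf(ia); sb <- run_rhf(ib)
  CA <- sa$mo_coeff[, 1, drop = FALSE]
  CB <- sb$mo_coeff[, 1, drop = FALSE]
  ints <- bf_orbital_integrals(d, CA, CB)
  bf <- bf_first_order(ints, bf_det2(1, 1), bf_det2(2, 2))
  EA <- sa$e_total - ints$e_nn_a
  EB <- sb$e_total - ints$e_nn_b
  delta <- -(bf$HA_P1 - EA * bf$P1) - (bf$HB_P1 - EB * bf$P1)
  lhs <- hl$e1_total - r$e1_pol
  rhs <- r$e1_exch_s2 + delta
  expect_lt(abs(lhs - rhs), 1e-7)
  # and at the water dimer the S^2 exchange carries the right sign and size
  rw <- fix_water_rhf_report()
  hlw <- heitler_london_first_order(fix_water_eq())
  expect_gt(rw$e1_exch_s2, 0)
  expect_gt(hlw$e1_total - rw$e1_pol, 0)
  expect_lt(abs((hlw$e1_total - rw$e1_pol) / rw$e1_exch_s2 - 1), 0.6)
})

test_that("optimized exchange equals the naive full-space oracle", {
  # RHF monomers (trivial active spaces) on H2-H2
  d <- fix_h2h2()
  r <- sapt_report(d)
  fa <- assemble_full_space_rdms(list(gamma = matrix(0, 0, 0),
                                      gamma2 = array(0, c(0, 0, 0, 0))),
                                 r$monomer_a$part)
  fb <- assemble_full_space_rdms(list(gamma = matrix(0, 0, 0),
                                      gamma2 = array(0, c(0, 0, 0, 0))),
                                 r$monomer_b$part)
  eo <- e1_exch_s2_oracle(fa$gamma, fa$gamma2, fb$gamma, fb$gamma2,
                          r$monomer_a$scf, r$monomer_b$scf, r$cross)
  expect_equal(eo, r$e1_exch_s2, tolerance = 1e-9)
  # correlated monomer A on the stretched water dimer, (6e,6o)
  rc <- fix_water_casci_report()
  A <- rc$monomer_a; B <- rc$monomer_b
  cas <- fix_water_casci()
  fa <- assemble_full_space_rdms(cas$rdms, A$part)
  fb <- assemble_full_space_rdms(list(gamma = matrix(0, 0, 0),
                                      gamma2 = array(0, c(0, 0, 0, 0))),
                                 B$part)
  eo <- e1_exch_s2_oracle(fa$gamma, fa$gamma2, fb$gamma, fb$gamma2,
                          A$scf, B$scf, rc$cross)
  expect_equal(eo, rc$e1_exch_s2, tolerance = 1e-9)
})

test_that("the exchange scales as the square of the intermonomer overlap", {
  d <- fix_h2h2()
  r <- sapt_report(d)
  A <- r$monomer_a; B <- r$monomer_b
  occA <- c(A$part$core, A$part$active)
  occB <- c(B$part$core, B$part$active)
  CA <- A$scf$mo_coeff[, occA, drop = FALSE]
  CB <- B$scf$mo_coeff[, occB, drop = FALSE]
  rA <- saptvqe:::occ_space_rdms(A$part, NULL)
  rB <- saptvqe:::occ_space_rdms(B$part, NULL)
  mo <- saptvqe:::cross_mo_tensors(r$cross, CA, CB)
  scale_mo <- function(mo, lam) {
    mo$S <- lam * mo$S; mo$vB <- lam * mo$vB; mo$vA <- lam * mo$vA
    mo$G1 <- lam^2 * mo$G1; mo$G2a <- lam * mo$G2a; mo$G2b <- lam * mo$G2b
    mo
  }
  val <- function(lam)
    saptvqe:::exch_contract(rA$gamma, rA$gamma2, rB$gamma, rB$gamma2,
                            scale_mo(mo, lam),
                            r$e1_pol - r$cross$v_nn)$total
  lam <- 1e-3
  expect_equal(val(lam), lam^2 * val(1), tolerance = 1e-12 * abs(val(1)))
  # zero overlap input: exactly zero
  expect_equal(val(0), 0)
})

test_that("the full report is symmetric under monomer relabeling", {
  rw <- fix_water_rhf_report()
  d <- fix_water_eq()
  swapped <- sapt_report(dimer_system(d$monomer_b, d$monomer_a,
                                      d$basis_b, d$basis_a))
  expect_equal(swapped$e1_pol, rw$e1_pol, tolerance = 1e-9)
  expect_equal(swapped$e1_exch_s2, rw$e1_exch_s2, tolerance = 1e-9)
  # T-breakdown sums to the total and units convert consistently
  brk <- rw$breakdown
  expect_equal(brk$t1 + brk$t2 + brk$t3 + brk$t4 + brk$t5, brk$total,
               tolerance = 1e-12)
  expect_equal(rw$e1_exch_s2_kcal, rw$e1_exch_s2 * 627.509474, tolerance = 1e-9)
})
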