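# Integral kernels against independent closed forms, literature energies,
# and structural invariants; RHF and the supermolecular reference.

test_that("s-primitive kernels match the independent closed forms", {
  set.seed(11)
  for (rep in 1:5) {
    a <- runif(1, 0.2, 3); b <- runif(1, 0.2, 3)
    A <- rnorm(3); B <- rnorm(3); C <- rnorm(3)
    sa <- s_shell(a, A); sb <- s_shell(b, B)
    expect_equal(saptvqe:::cpp_overlap(sa, sb)[1, 1], s_overlap(a, A, b, B),
                 tolerance = 1e-12)
    expect_equal(saptvqe:::cpp_kinetic(sa, sb)[1, 1], s_kinetic(a, A, b, B),
                 tolerance = 1e-12)
    expect_equal(saptvqe:::cpp_nuclear(sa, sb, 2.0, matrix(C, 1))[1, 1],
                 s_nuclear(a, A, b, B, 2.0, C), tolerance = 1e-12)
    cc <- runif(1, 0.2, 3); dd <- runif(1, 0.2, 3)
    Cc <- rnorm(3); Dd <- rnorm(3)
    sc <- s_shell(cc, Cc); sd <- s_shell(dd, Dd)
    eri <- saptvqe:::cpp_eri_mo(sa, matrix(1), sb, matrix(1), sc, matrix(1),
                                sd, matrix(1), FALSE, FALSE)[1, 1, 1, 1]
    expect_equal(eri, s_eri(a, A, b, B, cc, Cc, dd, Dd), tolerance = 1e-12)
  }
})

test_that("higher-angular-momentum attraction agrees with the tight-ERI point-charge limit", {
  w <- fix_water_eq()$monomer_a
  sh <- saptvqe:::shell_list(w, "6-31g")
  V <- saptvqe:::cpp_nuclear(sh, sh, saptvqe:::nuclear_charges(w), w$coords)
  Vtest <- matrix(0, sh$nbf, sh$nbf)
  I <- diag(sh$nbf)
  for (k in 1:3) {
    tight <- s_shell(1e9, w$coords[k, ])
    g <- saptvqe:::cpp_eri_mo(sh, I, sh, I, tight, matrix(1), tight, matrix(1),
                              TRUE, FALSE)
    Vtest <- Vtest - saptvqe:::nuclear_charges(w)[k] * g[, , 1, 1]
  }
  expect_lt(max(abs(V - Vtest)), 1e-5)
})

test_that("monomer integrals satisfy their structural invariants", {
  w <- fix_water_eq()$monomer_a
  ints <- compute_monomer_integrals(w, "6-31g")
  expect_equal(ints$n_basis, 13L)
  S <- ints$overlap
  expect_lt(max(abs(S - t(S))), 1e-12)
  expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 1e-10)
  # 8-fold permutational symmetry of the packed ERI via the unpacked tensor
  g <- saptvqe:::eri_unpack(ints$eri, 13)
  expect_lt(max(abs(g - aperm(g, c(2, 1, 3, 4)))), 1e-10)
  expect_lt(max(abs(g - aperm(g, c(3, 4, 1, 2)))), 1e-10)
  # H atom, minimal basis: S is the 1x1 identity
  h <- molecule("H", matrix(0, 1, 3), multiplicity = 2L)
  expect_equal(compute_monomer_integrals(h, "sto-3g")$overlap[1, 1], 1,
               tolerance = 1e-12)
  # atom permutation leaves the overlap spectrum unchanged
  w2 <- molecule(w$elements[c(2, 1, 3)], w$coords[c(2, 1, 3), ] *
                   saptvqe:::BOHR_ANGSTROM, label = "permuted")
  S2 <- compute_monomer_integrals(w2, "6-31g")$overlap
  expect_equal(eigen(S, only.values = TRUE)$values,
               eigen(S2, only.values = TRUE)$values, tolerance = 1e-10)
})

test_that("RHF reproduces literature energies and closed forms", {
  he <- molecule("He", matrix(0, 1, 3))
  e_he <- run_rhf(compute_monomer_integrals(he, "6-31g"))$e_total
  expect_equal(e_he, -2.85516043, tolerance = 1e-7)
  h2 <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.7414)))
  e_h2 <- run_rhf(compute_monomer_integrals(h2, "sto-3g"))$e_total
  expect_equal(e_h2, -1.11668, tolerance = 1e-4)
  w <- fix_water_eq()$monomer_a
  e_w <- run_rhf(compute_monomer_integrals(w, "6-31g"))$e_total
  expect_equal(e_w, -75.984, tolerance = 5e-3)
  # 2 electrons in a 1-function basis: closed-form single-orbital energy
  hm <- molecule("H", matrix(0, 1, 3), charge = -1L)
  ints <- compute_monomer_integrals(hm, "sto-3g")
  scf <- run_rhf(ints)
  h11 <- ints$core_h[1, 1]
  g1111 <- saptvqe:::eri_unpack(ints$eri, 1)[1, 1, 1, 1]
  expect_equal(scf$e_total, 2 * h11 + g1111, tolerance = 1e-10)
  # orthonormality and energy ordering
  C <- scf$mo_coeff
  expect_lt(max(abs(t(C) %*% ints$overlap %*% C - diag(ints$n_basis))), 1e-8)
  w_scf <- run_rhf(compute_monomer_integrals(w, "6-31g"))
  expect_true(all(diff(w_scf$mo_energy) > -1e-12))
  expect_error(run_rhf(ints, n_elec = 4L), "more occupied")
  expect_error(run_rhf(ints, n_elec = 3L), "even")
})

test_that("cross integrals have the documented limits and symmetries", {
  # two H nuclei at 10 bohr: v_nn exactly 0.1
  hA <- molecule("H", matrix(c(0, 0, 0), 1), multiplicity = 2L)
  hB <- molecule("H", matrix(c(0, 0, 10 * saptvqe:::BOHR_ANGSTROM), 1),
                 multiplicity = 2L)
  cr <- compute_cross_integrals(dimer_system(hA, hB, "sto-3g"))
  expect_equal(cr$v_nn, 0.1, tolerance = 1e-12)
  # He-He at 50 A: overlap decays away
  far <- compute_cross_integrals(make_toy_dimer("hehe", 50))
  expect_lt(max(abs(far$s_ab)), 1e-8)
  # H2-H2 at 20 A: leading cross-ERI element approaches the point-charge limit
  d20 <- make_toy_dimer("h2h2", 20, basis = "sto-3g")
  cr20 <- compute_cross_integrals(d20)
  ia <- compute_monomer_integrals(d20$monomer_a, "sto-3g")
  sa <- run_rhf(ia)
  co <- sa$mo_coeff[, 1]
  Em <- matrix(cr20$eri_cross, nrow = 4)
  DA <- co %*% t(co)
  ee <- drop(as.numeric(DA) %*% Em %*% as.numeric(DA))  # (aa|bb) per unit charge
  Rb <- 20 / saptvqe:::BOHR_ANGSTROM
  expect_equal(ee, 1 / Rb, tolerance = 0.01)
  # (A,B) and (B,A) cross blocks are transposes
  d <- fix_h2h2()
  crAB <- compute_cross_integrals(d)
  crBA <- compute_cross_integrals(dimer_system(d$monomer_b, d$monomer_a,
                                               d$basis_b, d$basis_a))
  expect_lt(max(abs(crAB$s_ab - t(crBA$s_ab))), 1e-12)
  expect_lt(max(abs(crAB$v_b_on_a - crBA$v_a_on_b)), 1e-12)
})

test_that("integrals and interaction energies are translation invariant", {
  d <- make_toy_dimer("h2h2", 3, basis = "sto-3g")
  shift <- c(1.3, -0.7, 2.1)
  d2 <- dimer_system(translate_molecule(d$monomer_a, shift),
                     translate_molecule(d$monomer_b, shift),
                     d$basis_a, d$basis_b)
  i1 <- compute_monomer_integrals(d$monomer_a, "sto-3g")
  i2 <- compute_monomer_integrals(d2$monomer_a, "sto-3g")
  expect_lt(max(abs(i1$overlap - i2$overlap)), 1e-10)
  expect_lt(max(abs(i1$core_h - i2$core_h)), 1e-10)
  r1 <- sapt_report(d); r2 <- sapt_report(d2)
  expect_equal(r1$e1_pol, r2$e1_pol, tolerance = 1e-9)
  expect_equal(r1$e1_exch_s2, r2$e1_exch_s2, tolerance = 1e-9)
  e1 <- supermolecular_rhf_interaction(d)
  e2 <- supermolecular_rhf_interaction(d2)
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("supermolecular RHF interaction has the right limits", {
  far <- make_toy_dimer("hehe", 50)
  expect_lt(abs(supermolecular_rhf_interaction(far)), 1e-6)
  # water dimer at equilibrium is bound
  expect_lt(supermolecular_rhf_interaction(fix_water_eq()), 0)
})
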