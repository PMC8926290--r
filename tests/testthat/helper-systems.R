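# Lazily computed, cached fixtures shared across test files (expensive
# SCF/solver results are computed once per test run).

.fix <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(expr)
  .fix[[name]]
}

fix_h2h2 <- function(R = 3) fixture(paste0("h2h2_", R), make_toy_dimer("h2h2", R, basis = "6-31g"))

fix_water_eq <- function() fixture("water_eq", make_water_dimer(0.9572))
fix_water_stretch <- function() fixture("water_st", make_water_dimer(2.0))

# both-RHF SAPT report on the equilibrium water dimer
fix_water_rhf_report <- function() fixture("water_rhf_rep", sapt_report(fix_water_eq()))

# stretched water: monomer A solved by CASCI (6e,6o), B at RHF
fix_water_casci_report <- function() fixture("water_cas_rep",
  sapt_report(fix_water_stretch(),
              solver_a = solver_spec("casci", n_elec = 6, n_orb = 6),
              solver_b = solver_spec("rhf")))

# small (2e,2o) H2 active-space Hamiltonian (full space of a minimal basis)
fix_h2_ham <- function() fixture("h2_ham", {
  h2 <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.7414)))
  ints <- compute_monomer_integrals(h2, "sto-3g")
  scf <- run_rhf(ints)
  build_active_hamiltonian(ints, scf, select_window(scf, 2L, 2L))
})

# stretched-water embedded Hamiltonian and solver results
fix_water_ham <- function() fixture("water_ham", {
  rep <- fix_water_casci_report()
  rep$monomer_a$ham
})
fix_water_casci <- function() fixture("water_casci", casci_solve(fix_water_ham()))
fix_water_vqe_k1 <- function() fixture("water_vqe1",
  vqe_optimize(fix_water_ham(), k = 1L, seed = 1L))
fix_water_vqe_k2 <- function() fixture("water_vqe2",
  vqe_optimize(fix_water_ham(), k = 2L, seed = 1L))
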