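# Shared builders and a run cache so expensive simulations are computed
# once per test session.

# independent Coulomb term in kBT, assembled from raw constants (used as an
# oracle; deliberately not pair_energy())
coulomb_kbt <- function(z1, z2, r_ang, epsilon, temperature = 298) {
  e <- 1.602176634e-19
  eps0 <- 8.8541878128e-12
  kB <- 1.380649e-23
  z1 * z2 * e^2 / (4 * pi * eps0 * epsilon * r_ang * 1e-10) / (kB * temperature)
}

# small neutral system: macroion -n, n monovalent counterions
tiny_system <- function(n = 10, epsilon = 78, cell = 100) {
  system_spec(solvent_spec(epsilon), macroion_spec(20, -n),
              list(ion_species("counterion", 2, 1L, as.integer(n))),
              cell_radius = cell)
}

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(eps, beta, zc, mpp, seed, sample_interval = 100,
                       equil = NULL) {
  key <- paste(eps, beta, zc, mpp, seed, sample_interval,
               if (is.null(equil)) "d" else equil, sep = "_")
  if (is.null(.run_cache[[key]])) {
    spec <- build_system(eps, beta, zc)
    .run_cache[[key]] <- run_simulation(
      spec, mc_schedule(mpp, equilibration_moves_per_particle = equil,
                        sample_interval = sample_interval, seed = seed))
  }
  .run_cache[[key]]
}

cached_summary <- function(eps, beta, zc, mpp, seed, sample_interval = 100,
                           equil = NULL) {
  key <- paste("sum", eps, beta, zc, mpp, seed, sample_interval,
               if (is.null(equil)) "d" else equil, sep = "_")
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- summarize(
      cached_run(eps, beta, zc, mpp, seed, sample_interval, equil))
  .run_cache[[key]]
}
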