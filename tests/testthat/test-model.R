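# Analytic layer: Bjerrum length, surface charge density, coupling
# parameter, salt stoichiometry, pair and total energies.

test_that("Bjerrum length has the right magnitude and scaling", {
  expect_equal(bjerrum_length(solvent_spec(20)), 28.0, tolerance = 0.1 / 28)
  expect_equal(bjerrum_length(solvent_spec(40)), 14.0, tolerance = 0.1 / 14)
  # inverse proportionality in epsilon
  s1 <- solvent_spec(33); s2 <- solvent_spec(66)
  expect_equal(bjerrum_length(s2), bjerrum_length(s1) / 2)
  # two unit charges at l_B interact with exactly kBT
  lb <- bjerrum_length(solvent_spec(78))
  expect_equal(coulomb_kbt(1, 1, lb, 78), 1, tolerance = 1e-12)
})

test_that("surface charge density matches the canonical macroion", {
  expect_equal(surface_charge_density(macroion_spec(20, -60)), 0.19,
               tolerance = 0.005 / 0.19)
  expect_equal(surface_charge_density(macroion_spec(20, 0)), 0)
  # 1/R^2 scaling
  expect_equal(surface_charge_density(macroion_spec(40, -60)),
               surface_charge_density(macroion_spec(20, -60)) / 4)
})

test_that("coupling parameter reproduces the water column and Z^{3/2} scaling", {
  s78 <- solvent_spec(78)
  expect_equal(round(coupling_parameter(1, s78, 0.19), 1), 0.8)
  expect_equal(round(coupling_parameter(3, s78, 0.19), 1), 4.1)
  # Gamma ~ Z^2 lB / sqrt(Z) = Z^(3/2)
  expect_equal(coupling_parameter(4, s78, 0.19) /
                 coupling_parameter(1, s78, 0.19), 8, tolerance = 1e-12)
  # monotone in 1/epsilon at fixed Z, and in Z at fixed epsilon
  g1 <- sapply(c(78, 68, 54, 40, 30, 20),
               function(e) coupling_parameter(1, solvent_spec(e), 0.19))
  expect_true(all(diff(g1) > 0))
  gz <- sapply(1:5, function(z) coupling_parameter(z, s78, 0.19))
  expect_true(all(diff(gz) > 0))
})

test_that("salt composition follows the beta stoichiometry", {
  mac <- macroion_spec(20, -60)
  expect_equal(unname(salt_composition(1, mac, 3)), c(20, 60))
  expect_equal(unname(salt_composition(0, mac, 3)), c(0, 0))
  expect_equal(unname(salt_composition(6.25, mac, 3)), c(125, 375))
  expect_equal(unname(salt_composition(6.25, mac, 5)), c(75, 375))
  expect_error(salt_composition(0.21, mac, 3), "non-integer")
})

test_that("assembled systems are exactly electroneutral or refuse to build", {
  for (beta in c(0, 0.15, 1, 6.25)) {
    spec <- build_system(54, beta, 3)
    total <- spec$macroion$valence +
      sum(vapply(spec$species, function(s) s$count * s$valence, numeric(1)))
    expect_true(total == 0)
  }
  expect_error(
    system_spec(solvent_spec(78), macroion_spec(20, -60),
                list(ion_species("counterion", 2, 1L, 59L))),
    "electroneutral")
})

test_that("pair energy is hard-sphere plus Coulomb and symmetric", {
  s <- solvent_spec(78)
  lb <- bjerrum_length(s)
  # definitional check: unit charges at l_B
  expect_equal(pair_energy(lb, 1, 1, 0.1, 0.1, s), 1)
  # overlap sentinel
  expect_identical(pair_energy(3.9, 1, 1, 2, 2, s), Inf)
  # macroion-counterion at contact, oracle value from raw constants
  expect_equal(pair_energy(22, -60, 1, 20, 2, s),
               coulomb_kbt(-60, 1, 22, 78), tolerance = 1e-12)
  expect_equal(pair_energy(22, -60, 1, 20, 2, s), -19.5, tolerance = 0.02)
  # symmetry in the two particles
  expect_equal(pair_energy(30, -3, 5, 2, 4, s), pair_energy(30, 5, -3, 4, 2, s))
})

test_that("total energy reduces to single pairs and matches fixtures", {
  spec1 <- system_spec(solvent_spec(78), macroion_spec(20, -60),
                       list(ion_species("counterion", 2, 1L, 1L)),
                       allow_net_charge = TRUE)
  cfg <- configuration(matrix(c(22, 0, 0), 1, 3), spec1)
  u <- total_energy(cfg)
  expect_equal(u$total, coulomb_kbt(-60, 1, 22, 78), tolerance = 1e-12)
  expect_equal(u$ion_ion, 0)
  # empty system
  spec0 <- system_spec(solvent_spec(78), macroion_spec(20, -60), list(),
                       allow_net_charge = TRUE)
  expect_equal(total_energy(configuration(matrix(numeric(0), 0, 3), spec0))$total, 0)
  # three-ion fixture against its hand-summed expectation
  f <- make_energy_fixtures()$collinear_triple
  expect_equal(total_energy(fixture_configuration(f))$total,
               f$expected_total_kbt, tolerance = 1e-12)
})

test_that("total energy is invariant under relabeling and rigid rotation", {
  set.seed(4)
  spec <- tiny_system(8)
  cfg <- initial_configuration(spec, seed = 5)
  u0 <- total_energy(cfg)$total
  # permute identical ions
  perm <- sample(8)
  cfg_p <- configuration(cfg$positions[perm, ], spec)
  expect_equal(total_energy(cfg_p)$total, u0, tolerance = 1e-12)
  # rigid rotation about the cell centre
  th <- 0.73
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  cfg_r <- configuration(cfg$positions %*% rot, spec)
  expect_equal(total_energy(cfg_r)$total, u0, tolerance = 1e-10)
})

test_that("overlapping configurations carry the overlap sentinel", {
  f <- make_energy_fixtures()$overlapping_pair
  u <- total_energy(fixture_configuration(f, validate = FALSE))
  expect_true(u$overlap_flag)
  expect_identical(u$total, Inf)
  expect_error(fixture_configuration(f, validate = TRUE), "overlap")
})
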