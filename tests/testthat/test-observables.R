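# Observables: RDF normalisation, accumulated charge (counting vs
# quadrature), potential integration, summaries.

test_that("uncharged ions give a flat RDF across the accessible shell", {
  # effectively uncharged system: epsilon so large that l_B ~ 1e-6 Å,
  # leaving pure hard spheres in the cell (ideal-gas structure at this
  # packing fraction)
  spec <- system_spec(solvent_spec(1e8), macroion_spec(20, -60),
                      list(ion_species("counterion", 2, 1L, 60L)))
  tr <- run_simulation(spec, mc_schedule(2e4, sample_interval = 50, seed = 71))
  g <- radial_distribution(tr, "counterion", bin_width = 1)
  inside <- g$r > 22.5 & g$r < 97.5
  expect_true(all(abs(g$value[inside] - 1) <= 3 * g$stderr[inside]))
  # and bins outside the accessible shell are empty
  expect_true(all(g$value[g$r < 21.5 | g$r > 98.5] == 0))
})

test_that("RDF normalisation conserves the species count", {
  tr <- cached_run(30, 1, 3, 2000, 31, 50)
  spec <- tr$spec
  for (sp in spec$species) {
    g <- radial_distribution(tr, sp$label, bin_width = 0.5)
    vol <- 4 / 3 * pi * diff(g$bin_edges^3)
    rho <- sp$count / edlmc:::accessible_volume(spec, sp$radius)
    expect_equal(sum(g$value * rho * vol), sp$count, tolerance = 1e-9)
  }
  expect_error(radial_distribution(tr, "nonexistent"), "not present")
})

test_that("accumulated charge is exact at both endpoints", {
  tr <- cached_run(30, 1, 3, 2000, 31, 50)
  z <- accumulated_charge(tr, bin_width = 0.5)
  expect_identical(z$value[1], -60)          # no ion centre below contact
  expect_identical(z$value[length(z$value)], 0)  # electroneutrality
})

test_that("counting and RDF-quadrature routes to Z_acc agree", {
  tr <- cached_run(30, 1, 3, 2000, 31, 50)
  spec <- tr$spec
  rdfs <- setNames(
    lapply(spec$species, function(s) radial_distribution(tr, s$label, 0.5)),
    vapply(spec$species, `[[`, character(1), "label"))
  z_quad <- accumulated_charge_from_rdf(rdfs, spec)
  z_count <- accumulated_charge(tr, bin_width = 0.5)
  expect_equal(z_quad$value, z_count$value, tolerance = 1e-9)
})

test_that("fixture charge profiles reproduce the hand-counted steps", {
  for (f in make_profile_fixtures()) {
    tr <- fixture_trajectory(f, n_copies = 1)
    z <- accumulated_charge(tr, bin_width = 0.5)
    # expected value at each bin edge from the step function
    expected <- vapply(z$r, function(r) {
      f$step_values[max(which(f$step_radii <= r + 1e-12))]
    }, numeric(1))
    expect_equal(z$value, expected, tolerance = 1e-12)
  }
})

test_that("potential of a constant charge profile matches the closed form", {
  s <- solvent_spec(78)
  lb <- bjerrum_length(s)
  q <- -60
  r <- seq(20, 60, by = 0.02)
  prof <- edlmc:::radial_profile(r, rep(q, length(r)), quantity = "Z_acc",
                                 units = "e", convention = "edge")
  phi <- mean_potential(prof, s, upper_cutoff = 60)
  exact <- thermal_voltage_mV(298) * lb * q * (1 / phi$r - 1 / 60)
  expect_equal(phi$value, exact, tolerance = 1e-6)
  # zero charge, zero potential
  prof0 <- edlmc:::radial_profile(r, rep(0, length(r)), quantity = "Z_acc",
                                  units = "e", convention = "edge")
  expect_true(all(mean_potential(prof0, s, 60)$value == 0))
})

test_that("potential of step-function fixtures matches the piecewise integral", {
  for (f in make_profile_fixtures()) {
    # exact step-function profile: fine grid plus doubled abscissae at the
    # steps, so the trapezoid integrates the steps exactly
    base <- seq(20, 60, by = 0.01)
    r <- sort(c(base, f$step_radii[f$step_radii > 20 & f$step_radii < 60]))
    r <- sort(c(r, f$step_radii[f$step_radii > 20 & f$step_radii < 60]))
    val <- vapply(seq_along(r), function(i) {
      k <- which(f$step_radii <= r[i] + 1e-12)
      # at a doubled abscissa the first copy takes the pre-step value
      if (i > 1 && r[i] == r[i - 1]) k <- which(f$step_radii < r[i] - 1e-12)
      f$step_values[max(k, 1)]
    }, numeric(1))
    prof <- edlmc:::radial_profile(r, val, quantity = "Z_acc", units = "e",
                                   convention = "edge")
    phi <- mean_potential(prof, solvent_spec(78), upper_cutoff = 60)
    probe <- c(21.1, 24.9, 30.3, 45.7)
    got <- suppressWarnings(approx(phi$r, phi$value, xout = probe)$y)
    expect_equal(got, f$phi_exact(probe, 60), tolerance = 1e-6)
  }
})

test_that("summaries carry finite errors and respect the charge bounds", {
  s <- cached_summary(78, 0, 3, 3000, 51, 100)
  expect_true(all(c(s$surface_potential_se, s$zeta_potential_se,
                    s$effective_charge_se, s$reduced_energy_se) >= 0))
  expect_gt(s$effective_charge_e, s$spec$macroion$valence)
  expect_lt(s$effective_charge_e, abs(s$spec$macroion$valence))
  expect_lt(s$zeta_potential_mV, 0)
  expect_lt(s$surface_potential_mV, s$zeta_potential_mV)
  expect_equal(s$zeta_plane, 24)
  expect_equal(s$charge_plane, 26)
})

test_that("summarize refuses runs with too few samples for blocking", {
  spec <- tiny_system(5)
  tr <- run_simulation(spec, mc_schedule(500, sample_interval = 100, seed = 81))
  expect_error(summarize(tr), "too few")
})

test_that("potential signs are consistent with the accumulated charge", {
  tr <- cached_run(78, 0, 3, 3000, 51, 100)
  z <- accumulated_charge(tr, 0.5)
  phi <- mean_potential(z, tr$spec$solvent, 60)
  # phi vanishes at the cutoff by construction and shares the sign of the
  # enclosed charge just outside contact in salt-free systems
  expect_equal(phi$value[length(phi$value)], 0)
  expect_lt(phi$value[1], 0)
  expect_equal(sign(phi$value[5]), sign(z$value[5]))
  # |phi| decreases monotonically toward the cutoff for this profile
  expect_true(all(diff(abs(phi$value)) <= 1e-9))
})
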