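# Metropolis engine: placement, incremental energies, constraints,
# reproducibility, audits, and the weak-coupling limit.

test_that("initial placement respects all constraints and the seed", {
  spec <- build_system(78, 0)
  cfg <- initial_configuration(spec, seed = 3)
  r <- sqrt(rowSums(cfg$positions^2))
  expect_equal(nrow(cfg$positions), 60)
  expect_true(all(r >= 22 & r <= 98))
  expect_null(edlmc:::check_configuration(cfg))
  # determinism
  cfg2 <- initial_configuration(spec, seed = 3)
  expect_identical(cfg$positions, cfg2$positions)
  # different seed, different configuration
  expect_false(identical(cfg$positions,
                         initial_configuration(spec, seed = 4)$positions))
  # empty system
  spec0 <- system_spec(solvent_spec(78), macroion_spec(20, -60), list(),
                       allow_net_charge = TRUE)
  expect_equal(nrow(initial_configuration(spec0, seed = 1)$positions), 0)
})

test_that("incremental move energies match the brute-force oracle", {
  spec <- tiny_system(10)
  cfg <- initial_configuration(spec, seed = 11)
  tr <- metropolis_trace(cfg, n_moves = 400, max_displacement = 15, seed = 12)
  prev <- cfg$positions
  u_prev <- total_energy(configuration(prev, spec, validate = FALSE))$total
  n_checked <- 0
  for (m in seq_len(400)) {
    cur <- tr$positions[, , m]
    if (tr$accepted[m]) {
      u_cur <- total_energy(configuration(cur, spec, validate = FALSE))$total
      expect_equal(tr$delta_u[m], u_cur - u_prev, tolerance = 1e-9)
      u_prev <- u_cur
      n_checked <- n_checked + 1
    } else {
      expect_identical(cur, prev)
      if (tr$hard_reject[m]) expect_true(is.na(tr$delta_u[m]))
    }
    prev <- cur
  }
  expect_gt(n_checked, 50) # the trace actually exercised accepted moves
})

test_that("downhill overlap-free trials are always accepted", {
  spec <- tiny_system(10)
  cfg <- initial_configuration(spec, seed = 21)
  tr <- metropolis_trace(cfg, n_moves = 300, max_displacement = 8, seed = 22)
  finite <- !is.na(tr$delta_u)
  expect_true(all(tr$accepted[finite & tr$delta_u <= 0]))
  # and every hard rejection left the state untouched
  expect_true(all(!tr$accepted[tr$hard_reject]))
})

test_that("stored samples never violate hard constraints", {
  tr <- cached_run(30, 1, 3, 2000, 31, sample_interval = 50)
  spec <- tr$spec
  ions <- edlmc:::ion_vectors(spec)
  for (s in seq_len(dim(tr$configurations)[3])) {
    pos <- tr$configurations[, , s]
    r <- sqrt(rowSums(pos^2))
    expect_true(all(r >= spec$macroion$radius + ions$radius - 1e-9))
    expect_true(all(r <= spec$cell_radius - ions$radius + 1e-9))
    d <- as.matrix(dist(pos)); diag(d) <- Inf
    expect_true(all(d >= outer(ions$radius, ions$radius, `+`) - 1e-9))
  }
})

test_that("trajectories are bit-identical for identical seeds", {
  a <- run_simulation(build_system(54, 0), mc_schedule(500, seed = 9))
  b <- run_simulation(build_system(54, 0), mc_schedule(500, seed = 9))
  expect_identical(a$configurations, b$configurations)
  expect_identical(a$energies, b$energies)
  c <- run_simulation(build_system(54, 0), mc_schedule(500, seed = 10))
  expect_false(identical(a$configurations, c$configurations))
})

test_that("running energy stays within audit tolerance of recomputation", {
  tr <- run_simulation(build_system(20, 0),
                       mc_schedule(2000, sample_interval = 100, seed = 41),
                       audit_interval = 1e4, audit_tolerance = 1e-6)
  expect_lt(tr$max_audit_deviation, 1e-6)
  expect_true(all(is.finite(tr$energies)))
})

test_that("acceptance rate is strictly between 0 and 1 for canonical systems", {
  for (s in list(cached_summary(78, 0, 3, 3000, 51, 100),
                 cached_summary(20, 0, 3, 3000, 52, 100))) {
    expect_gt(s$acceptance_rate, 0)
    expect_lt(s$acceptance_rate, 1)
  }
})

test_that("a weakly coupled macroion matches the two-ion quadrature oracle", {
  # |Z_M| = 2 with two monovalent counterions: the exact canonical average
  # is a 3-d integral over (r1, r2, cos theta) with Boltzmann weight
  # exp(2 lB/r1 + 2 lB/r2 - lB/r12); computed here by trapezoidal
  # quadrature, fully independently of the sampler.
  spec <- system_spec(solvent_spec(78), macroion_spec(20, -2),
                      list(ion_species("counterion", 2, 1L, 2L)))
  lb <- bjerrum_length(spec$solvent)
  r_grid <- seq(22, 98, length.out = 250)
  c_grid <- seq(-1, 1, length.out = 101)
  w1 <- r_grid^2 * exp(2 * lb / r_grid)
  # E[ indicator(r1 <= r) ] under the pair measure
  r12 <- function(r1, r2, cth) sqrt(outer(r1^2, r2^2, `+`) -
                                      2 * outer(r1, r2) * cth)
  acc <- matrix(0, length(r_grid), length(r_grid))
  for (k in seq_along(c_grid)) {
    d <- r12(r_grid, r_grid, c_grid[k])
    f <- exp(-lb / d) * (d >= 4)
    wk <- if (k == 1 || k == length(c_grid)) 0.5 else 1
    acc <- acc + wk * f
  }
  acc <- acc * diff(c_grid)[1]
  wgt <- outer(w1, w1) * acc
  z_tot <- sum(wgt)
  p_below <- function(r) sum(wgt[r_grid <= r, ]) / z_tot
  zacc_exact <- function(r) -2 + 2 * p_below(r)

  tr <- run_simulation(spec, mc_schedule(2e5, sample_interval = 20, seed = 61))
  z <- accumulated_charge(tr, bin_width = 0.5)
  for (rq in c(30, 50, 70)) {
    i <- which.min(abs(z$r - rq))
    expect_equal(z$value[i], zacc_exact(rq),
                 tolerance = (3 * z$stderr[i] + 0.02) / abs(zacc_exact(rq)))
  }
})
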