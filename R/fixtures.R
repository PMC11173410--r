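# Deterministic toy systems with independently computed expected values.
#
# Every expected value here is produced by code paths that do NOT go
# through pair_energy()/total_energy() or the sampling engine: energies are
# hand-assembled from explicit pair distances and the raw Coulomb formula,
# charge profiles by direct counting, and potentials by the exact piecewise
# 1/r integral of a step function. The fixtures therefore serve as oracles
# for the implementation, not mirrors of it.

# raw Coulomb term in kBT from first principles (not via pair_energy)
.coulomb_kbt <- function(z1, z2, r_ang, epsilon, temperature = 298) {
  e <- 1.602176634e-19; eps0 <- 8.8541878128e-12; kB <- 1.380649e-23
  z1 * z2 * e^2 / (4 * pi * eps0 * epsilon * r_ang * 1e-10) /
    (kB * temperature)
}

#' Energy fixtures with hand-assembled expected values
#'
#' Small (<= 4 ion) configurations at exact geometric positions whose total
#' Coulomb energies are assembled term by term from the pair distances.
#' Geometries are collinear or axis-aligned so every distance is exact.
#'
#' @return list of fixtures; each has `name`, `spec`, `positions` and
#'   `expected_total_kbt` (or `expected_overlap = TRUE`).
#' @export
make_energy_fixtures <- function() {
  s78 <- solvent_spec(78)
  mac <- macroion_spec(20, -60)
  ion <- function(n, z = 1L) ion_species("counterion", 2, z, n)
  toy_spec <- function(n, z = 1L, eps = 78)
    system_spec(solvent_spec(eps), mac, list(ion(n, z)),
                cell_radius = 100, allow_net_charge = TRUE)

  f <- list()

  # single counterion at contact: macroion term only
  f$single_contact <- list(
    name = "single_contact",
    spec = toy_spec(1),
    positions = matrix(c(22, 0, 0), 1, 3),
    expected_total_kbt = .coulomb_kbt(-60, 1, 22, 78))

  # two counterions diametrically opposed at 24 Å: two macroion terms plus
  # the ion-ion term at 48 Å
  f$diametric_pair <- list(
    name = "diametric_pair",
    spec = toy_spec(2),
    positions = matrix(c(24, 0, 0, -24, 0, 0), 2, 3, byrow = TRUE),
    expected_total_kbt = 2 * .coulomb_kbt(-60, 1, 24, 78) +
      .coulomb_kbt(1, 1, 48, 78))

  # three collinear ions at 22, 30, 44 Å on +x: three macroion terms and
  # three ion-ion terms at separations 8, 22, 14
  f$collinear_triple <- list(
    name = "collinear_triple",
    spec = toy_spec(3),
    positions = matrix(c(22, 0, 0, 30, 0, 0, 44, 0, 0), 3, 3, byrow = TRUE),
    expected_total_kbt =
      .coulomb_kbt(-60, 1, 22, 78) + .coulomb_kbt(-60, 1, 30, 78) +
      .coulomb_kbt(-60, 1, 44, 78) +
      .coulomb_kbt(1, 1, 8, 78) + .coulomb_kbt(1, 1, 22, 78) +
      .coulomb_kbt(1, 1, 14, 78))

  # mixed valences on orthogonal axes: distances by Pythagoras
  f$orthogonal_mixed <- list(
    name = "orthogonal_mixed",
    spec = system_spec(s78, mac,
                       list(ion_species("salt_cation", 2, 3L, 1L),
                            ion_species("salt_anion", 2, -1L, 1L)),
                       cell_radius = 100, allow_net_charge = TRUE),
    positions = matrix(c(25, 0, 0, 0, 40, 0), 2, 3, byrow = TRUE),
    expected_total_kbt =
      .coulomb_kbt(-60, 3, 25, 78) + .coulomb_kbt(-60, -1, 40, 78) +
      .coulomb_kbt(3, -1, sqrt(25^2 + 40^2), 78))

  # a pair closer than one ion diameter: hard-sphere overlap
  f$overlapping_pair <- list(
    name = "overlapping_pair",
    spec = toy_spec(2),
    positions = matrix(c(30, 0, 0, 33.5, 0, 0), 2, 3, byrow = TRUE),
    expected_overlap = TRUE)

  f
}

# exact potential (mV) of a right-continuous step function Z_acc:
# Z_acc(r) = values[k] on [radii[k], radii[k+1]), integrated against
# l_B/r^2 from r to cutoff, segment by segment
phi_step_exact <- function(r, step_radii, step_values, solvent, cutoff) {
  lb <- bjerrum_length(solvent)
  kbt_mv <- thermal_voltage_mV(solvent$temperature)
  edges <- c(step_radii, Inf)
  vapply(r, function(r0) {
    total <- 0
    for (k in seq_along(step_values)) {
      a <- max(edges[k], r0)
      b <- min(edges[k + 1], cutoff)
      if (b > a) total <- total + step_values[k] * (1 / a - 1 / b)
    }
    kbt_mv * lb * total
  }, numeric(1))
}

#' Charge-profile and potential fixtures
#'
#' Configurations with ions at listed radii; the expected accumulated
#' charge is the hand-counted step function and the expected potential the
#' exact piecewise 1/r integral of that step function. Ion radii are
#' chosen never to fall on a default 0.5 Å bin edge.
#'
#' @return list of fixtures with `spec`, `positions`, `step_radii`,
#'   `step_values` (value of Z_acc from each radius on) and `phi_exact`, a
#'   function of (r, cutoff) in mV.
#' @export
make_profile_fixtures <- function() {
  mac <- macroion_spec(20, -60)
  s78 <- solvent_spec(78)
  f <- list()

  # no ions at all: bare macroion, Z_acc identically Z_M
  f$bare_macroion <- list(
    name = "bare_macroion",
    spec = system_spec(s78, mac, list(), cell_radius = 100,
                       allow_net_charge = TRUE),
    positions = matrix(numeric(0), 0, 3),
    step_radii = 20, step_values = -60,
    phi_exact = function(r, cutoff = 60)
      phi_step_exact(r, 20, -60, s78, cutoff))

  # full neutralising shell just off contact: Z_acc jumps -60 -> 0 at
  # 23.3 Å, and the potential vanishes outside the shell
  sh <- shell_positions(60, 23.3)
  f$neutral_shell <- list(
    name = "neutral_shell",
    spec = system_spec(s78, mac,
                       list(ion_species("counterion", 2, 1L, 60L)),
                       cell_radius = 100),
    positions = sh,
    step_radii = c(20, 23.3), step_values = c(-60, 0),
    phi_exact = function(r, cutoff = 60)
      phi_step_exact(r, c(20, 23.3), c(-60, 0), s78, cutoff))

  # mixed valences at staggered radii: hand-counted steps
  # +3 at 26.2, -1 at 33.7, +1 at 41.1 (net charge not neutral: toy)
  f$mixed_steps <- list(
    name = "mixed_steps",
    spec = system_spec(s78, mac,
                       list(ion_species("counterion", 2, 1L, 1L),
                            ion_species("salt_cation", 2, 3L, 1L),
                            ion_species("salt_anion", 2, -1L, 1L)),
                       cell_radius = 100, allow_net_charge = TRUE),
    positions = matrix(c(0, 0, 41.1,      # counterion
                         26.2, 0, 0,      # trivalent cation
                         0, 33.7, 0),     # anion
                       3, 3, byrow = TRUE),
    step_radii = c(20, 26.2, 33.7, 41.1),
    step_values = c(-60, -57, -58, -57),
    phi_exact = function(r, cutoff = 60)
      phi_step_exact(r, c(20, 26.2, 33.7, 41.1), c(-60, -57, -58, -57),
                     s78, cutoff))

  f
}

# n points spread over a sphere of radius r (Fibonacci lattice: distinct,
# well-separated, deterministic)
shell_positions <- function(n, r) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  r * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Turn a fixture into a configuration object
#'
#' @param fixture one element of [make_energy_fixtures()] or
#'   [make_profile_fixtures()].
#' @param validate forwarded to [configuration()]; overlap fixtures must
#'   pass `FALSE`.
#' @return a [configuration()].
#' @export
fixture_configuration <- function(fixture, validate = TRUE) {
  configuration(fixture$positions, fixture$spec, validate = validate)
}

#' Wrap a fixture configuration as a one-sample trajectory
#'
#' Lets the trajectory-based observables run on a deterministic single
#' configuration.
#'
#' @param fixture a fixture from this module.
#' @param n_copies replicate the configuration this many times (profiles
#'   built from identical samples are exact, and >= 10 copies satisfies the
#'   blocking requirement of [summarize()]).
#' @return a `trajectory_samples` object.
#' @export
fixture_trajectory <- function(fixture, n_copies = 1) {
  cfg <- fixture_configuration(fixture, validate = FALSE)
  n <- nrow(cfg$positions)
  a <- array(rep(cfg$positions, n_copies), dim = c(n, 3, n_copies))
  structure(list(
    configurations = a,
    energies = rep(if (n > 0) total_energy(cfg)$total else 0, n_copies),
    acceptance_rate = NA_real_,
    tuned_displacement = NA_real_,
    max_audit_deviation = 0,
    species_index = cfg$ions$species_index,
    spec = fixture$spec,
    schedule = NULL
  ), class = "trajectory_samples")
}

#' Export a fixture as XYZ plus a JSON expected-value sidecar
#'
#' @param fixture a fixture from this module.
#' @param dir output directory.
#' @return invisibly, the two paths written.
#' @export
export_fixture <- function(fixture, dir = ".") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  xyz <- file.path(dir, paste0(fixture$name, ".xyz"))
  write_xyz(fixture_configuration(fixture, validate = FALSE), xyz,
            comment = fixture$name)
  side <- file.path(dir, paste0(fixture$name, ".json"))
  expected <- fixture[setdiff(names(fixture), c("spec", "positions",
                                                "phi_exact"))]
  jsonlite::write_json(expected, side, auto_unbox = TRUE, digits = NA)
  invisible(c(xyz, side))
}

#' Seeded, scaled-down reference runs of the canonical systems
#'
#' Named presets pinning the qualitative regimes: `"saltfree-78"` (weak
#' coupling, zeta around -100 mV), `"saltfree-20"` (strong coupling, small
#' |zeta|), `"salt31-b6.25-20"` (charge inversion with trivalent salt).
#' Schedules are reduced relative to full production runs; the summaries
#' are regression anchors, not publication-quality estimates.
#'
#' @param preset preset name.
#' @param moves_per_particle production length (default 1e4).
#' @param seed RNG seed (default 42).
#' @return a `summary_result`.
#' @export
reduced_reference_run <- function(preset = c("saltfree-78", "saltfree-20",
                                             "salt31-b6.25-20"),
                                  moves_per_particle = 1e4, seed = 42L) {
  preset <- match.arg(preset)
  spec <- switch(preset,
                 "saltfree-78" = build_system(78, 0),
                 "saltfree-20" = build_system(20, 0),
                 "salt31-b6.25-20" = build_system(20, 6.25, 3))
  sched <- mc_schedule(moves_per_particle, sample_interval = 50, seed = seed)
  summarize(run_simulation(spec, sched))
}
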