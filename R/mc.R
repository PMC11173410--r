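# Canonical Metropolis Monte Carlo sampling of ion positions in the cell.

#' Monte Carlo schedule
#'
#' Move counts are expressed per particle, the convention in which run
#' lengths for these systems are usually quoted (a canonical production run
#' is 1e6 moves per particle; desk-scale runs of 1e4-1e5 are adequate for
#' the 60-ion salt-free systems).
#'
#' @param production_moves_per_particle attempted single-ion translations
#'   per mobile ion in the production phase.
#' @param equilibration_moves_per_particle discarded equilibration moves
#'   per particle; default 10% of production.
#' @param sample_interval attempted moves per particle between stored
#'   samples (default 100).
#' @param max_displacement half-width in Å of the cubic trial-displacement
#'   window (default 10).
#' @param adapt_displacement tune `max_displacement` toward a 40-60%
#'   acceptance rate during equilibration only; the step is frozen before
#'   production so detailed balance holds throughout sampling.
#' @param seed integer RNG seed; the trajectory is bit-reproducible from
#'   (spec, schedule, seed).
#' @return object of class `mc_schedule`.
#' @export
mc_schedule <- function(production_moves_per_particle = 2e4,
                        equilibration_moves_per_particle = NULL,
                        sample_interval = 100,
                        max_displacement = 10,
                        adapt_displacement = TRUE,
                        seed = 1L) {
  if (is.null(equilibration_moves_per_particle))
    equilibration_moves_per_particle <-
      max(1, round(0.1 * production_moves_per_particle))
  stopifnot(production_moves_per_particle >= 1,
            equilibration_moves_per_particle >= 1,
            sample_interval >= 1,
            sample_interval <= production_moves_per_particle,
            max_displacement > 0)
  structure(list(
    production_moves_per_particle = production_moves_per_particle,
    equilibration_moves_per_particle = equilibration_moves_per_particle,
    sample_interval = sample_interval,
    max_displacement = max_displacement,
    adapt_displacement = isTRUE(adapt_displacement),
    seed = as.numeric(seed)
  ), class = "mc_schedule")
}

#' Named schedule presets
#'
#' `"desk"` is the default exploration scale (2e4 moves/particle);
#' `"paper"` is the full production scale of 1e6 moves/particle.
#'
#' @param name `"desk"` or `"paper"`.
#' @param seed RNG seed passed through to [mc_schedule()].
#' @return an [mc_schedule()].
#' @export
schedule_preset <- function(name = c("desk", "paper"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
         desk = mc_schedule(2e4, seed = seed),
         paper = mc_schedule(1e6, seed = seed))
}

#' Random initial configuration
#'
#' Places every ion uniformly at random in its accessible shell
#' \eqn{R_M + R_i \le |r| \le R_{cell} - R_i} by rejection sampling,
#' rejecting hard-sphere overlaps with already-placed ions. Deterministic
#' given the seed.
#'
#' @param spec a [system_spec()].
#' @param seed integer seed.
#' @param max_attempts rejection attempts per ion before declaring the
#'   packing infeasible.
#' @return a [configuration()].
#' @export
initial_configuration <- function(spec, seed = 1L, max_attempts = 100000L) {
  ions <- ion_vectors(spec)
  pos <- cpp_place_ions(ions$radius, spec$macroion$radius, spec$cell_radius,
                        as.numeric(seed), as.integer(max_attempts))
  configuration(pos, spec, validate = FALSE)
}

#' Run a canonical Metropolis Monte Carlo simulation
#'
#' Single-particle translation moves on the mobile ions; the macroion is
#' fixed at the centre. Trials that overlap a hard sphere or leave the cell
#' are rejected outright; otherwise the Metropolis criterion
#' \eqn{\min(1, e^{-\Delta U / k_B T})} is applied with \eqn{\Delta U}
#' computed from the moved ion's pair terms only (an O(N) update). The
#' running total energy is audited against a full recomputation every
#' `audit_interval` moves and the run aborts if the bookkeeping drifts
#' beyond `audit_tolerance`.
#'
#' @param spec a [system_spec()].
#' @param schedule an [mc_schedule()].
#' @param initial optional starting [configuration()]; by default a fresh
#'   random placement drawn from the schedule seed.
#' @param audit_interval moves between energy audits (default 1e5).
#' @param audit_tolerance maximum tolerated |running - recomputed| energy
#'   deviation per audit window, in kBT (default 1e-6).
#' @return object of class `trajectory_samples`: a 3-d array of stored
#'   configurations (`n_ions` x 3 x `n_samples`), per-sample total energies
#'   in kBT, the production acceptance rate, the (possibly tuned) step
#'   size, the worst audit deviation, and the spec/schedule echoes.
#' @export
run_simulation <- function(spec, schedule = mc_schedule(), initial = NULL,
                           audit_interval = 1e5, audit_tolerance = 1e-6) {
  stopifnot(inherits(spec, "system_spec"), inherits(schedule, "mc_schedule"))
  n <- n_ions(spec)
  ions <- ion_vectors(spec)
  if (is.null(initial)) {
    # placement and trajectory use decorrelated streams of the same seed
    initial <- initial_configuration(spec, seed = schedule$seed)
  } else {
    stopifnot(inherits(initial, "configuration"))
    bad <- check_configuration(initial)
    if (!is.null(bad)) stop("invalid initial configuration: ", bad)
  }
  lb <- bjerrum_length(spec$solvent)
  res <- cpp_run_mc(
    initial$positions, as.numeric(ions$valence), ions$radius,
    as.numeric(spec$macroion$valence), spec$macroion$radius,
    spec$cell_radius, lb,
    n_equil_moves = schedule$equilibration_moves_per_particle * max(n, 1),
    n_prod_moves = schedule$production_moves_per_particle * max(n, 1),
    sample_every = schedule$sample_interval * max(n, 1),
    max_disp = schedule$max_displacement,
    adapt = schedule$adapt_displacement,
    seed = schedule$seed + 0x5851f42d, # offset the placement stream
    audit_every = audit_interval,
    audit_tol = audit_tolerance,
    record_moves = FALSE)
  ns <- as.integer(res$n_samples)
  configs <- if (n > 0 && ns > 0) {
    array(res$samples[seq_len(ns * n * 3)], dim = c(n, 3, ns))
  } else {
    array(numeric(0), dim = c(n, 3, 0))
  }
  structure(list(
    configurations = configs,
    energies = res$energies[seq_len(max(ns, 0))],
    acceptance_rate = res$acceptance_rate,
    tuned_displacement = res$tuned_displacement,
    max_audit_deviation = res$max_audit_deviation,
    species_index = ions$species_index,
    spec = spec,
    schedule = schedule
  ), class = "trajectory_samples")
}

#' @export
print.trajectory_samples <- function(x, ...) {
  cat(sprintf(
    "trajectory_samples: %d ions, %d stored samples, acceptance %.2f\n",
    dim(x$configurations)[1], dim(x$configurations)[3],
    x$acceptance_rate))
  cat(sprintf("  <U> = %.2f kBT, step = %.2f Å, worst audit dev = %.2e kBT\n",
              mean(x$energies), x$tuned_displacement, x$max_audit_deviation))
  invisible(x)
}

#' Record a short Metropolis trace for diagnostics
#'
#' Runs `n_moves` attempted moves from a given configuration with no
#' equilibration/production split and records, per attempted move, the
#' proposed ion, the energy change, the hard-rejection flag, the acceptance
#' flag and the full configuration after the move. Intended for small
#' systems (the trace stores every configuration).
#'
#' @param config starting [configuration()].
#' @param n_moves attempted moves to record.
#' @param max_displacement trial half-width in Å.
#' @param seed RNG seed.
#' @return list with `delta_u`, `accepted`, `hard_reject`, `ion` (1-based
#'   moved-ion index) and `positions` (n x 3 x n_moves array of
#'   post-move configurations).
#' @export
metropolis_trace <- function(config, n_moves = 100, max_displacement = 10,
                             seed = 1L) {
  spec <- config$spec
  ions <- config$ions
  n <- nrow(config$positions)
  res <- cpp_run_mc(
    config$positions, as.numeric(ions$valence), ions$radius,
    as.numeric(spec$macroion$valence), spec$macroion$radius,
    spec$cell_radius, bjerrum_length(spec$solvent),
    n_equil_moves = 0, n_prod_moves = n_moves,
    sample_every = n_moves, max_disp = max_displacement,
    adapt = FALSE, seed = as.numeric(seed),
    audit_every = 1e5, audit_tol = 1e-6, record_moves = TRUE)
  tr <- res$trace
  tr$positions <- array(tr$positions, dim = c(n, 3, n_moves))
  tr
}
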