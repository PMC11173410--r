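# Plain-text input/output: YAML system configs, CSV profiles, JSON
# summaries, XYZ snapshots, RDS checkpoints.

#' Write a system specification to a YAML config file
#'
#' Field names match the constructor arguments of [system_spec()] and
#' friends, so a config round-trips exactly.
#'
#' @param spec a [system_spec()].
#' @param path output file path.
#' @export
write_system_config <- function(spec, path) {
  x <- list(
    solvent = spec$solvent[c("epsilon_r", "temperature")],
    macroion = spec$macroion[c("radius", "valence")],
    cell_radius = spec$cell_radius,
    beta = spec$beta,
    species = lapply(spec$species, function(s)
      s[c("label", "radius", "valence", "count")])
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a system specification from a YAML config file
#'
#' @param path config file written by [write_system_config()] (or by hand
#'   in the same layout).
#' @return a [system_spec()].
#' @export
read_system_config <- function(path) {
  x <- yaml::read_yaml(path)
  system_spec(
    solvent = solvent_spec(x$solvent$epsilon_r, x$solvent$temperature),
    macroion = macroion_spec(x$macroion$radius, x$macroion$valence),
    species = lapply(x$species, function(s)
      ion_species(s$label, s$radius, s$valence, s$count)),
    cell_radius = x$cell_radius,
    beta = if (is.null(x$beta)) 0 else x$beta)
}

#' Write a radial profile as CSV
#'
#' Columns: `r` (Å), `value`, `stderr`.
#'
#' @param profile a `radial_profile`.
#' @param path output path.
#' @export
write_profile_csv <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Write a summary as a JSON record
#'
#' Keyed by (epsilon, beta, salt valence, seed) alongside the scalar
#' observables and their standard errors.
#'
#' @param summary a `summary_result` from [summarize()].
#' @param path output path.
#' @export
write_summary_json <- function(summary, path) {
  spec <- summary$spec
  salt <- Filter(function(s) s$label == "salt_cation", spec$species)
  rec <- list(
    epsilon = spec$solvent$epsilon_r,
    beta = spec$beta,
    salt_valence = if (length(salt)) salt[[1]]$valence else NULL,
    seed = summary$schedule$seed,
    surface_potential_mV = summary$surface_potential_mV,
    surface_potential_se = summary$surface_potential_se,
    zeta_potential_mV = summary$zeta_potential_mV,
    zeta_potential_se = summary$zeta_potential_se,
    effective_charge_e = summary$effective_charge_e,
    effective_charge_se = summary$effective_charge_se,
    reduced_energy = summary$reduced_energy,
    reduced_energy_se = summary$reduced_energy_se,
    contact_gMI = summary$contact_gMI,
    zacc_extremum_e = summary$zacc_extremum_e,
    zacc_extremum_r = summary$zacc_extremum_r,
    acceptance_rate = summary$acceptance_rate)
  rec <- Filter(Negate(is.null), rec)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a configuration (or stored sample) in XYZ format
#'
#' One frame per call: atom count, comment line, then one line per
#' particle with a species letter and Cartesian coordinates in Å. The
#' fixed macroion is written first with label `M`; counterions are `C`,
#' salt cations `X`, salt anions `A`. Suitable for quick visual checks in
#' any molecular viewer.
#'
#' @param config a [configuration()], or a `trajectory_samples` with
#'   `sample` giving the stored frame to export.
#' @param path output path.
#' @param sample stored-sample index when `config` is a trajectory.
#' @param comment comment line content.
#' @export
write_xyz <- function(config, path, sample = NULL, comment = "edlmc snapshot") {
  if (inherits(config, "trajectory_samples")) {
    stopifnot(!is.null(sample))
    pos <- config$configurations[, , sample, drop = FALSE][, , 1]
    if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3)
    spec <- config$spec
    labels <- ion_vectors(spec)$label
  } else {
    pos <- config$positions
    spec <- config$spec
    labels <- config$ions$label
  }
  letter <- c(counterion = "C", salt_cation = "X", salt_anion = "A")[labels]
  lines <- c(
    as.character(nrow(pos) + 1), comment,
    sprintf("M %12.5f %12.5f %12.5f", 0, 0, 0),
    sprintf("%s %12.5f %12.5f %12.5f", letter, pos[, 1], pos[, 2], pos[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Write a restartable checkpoint of a finished run
#'
#' Stores the spec, schedule, final configuration and sampling summaries
#' as an RDS file from which a follow-up run can be started via the
#' `initial` argument of [run_simulation()].
#'
#' @param samples a `trajectory_samples`.
#' @param path output path (`.rds`).
#' @export
write_checkpoint <- function(samples, path) {
  ns <- dim(samples$configurations)[3]
  final_pos <- samples$configurations[, , ns, drop = FALSE][, , 1]
  if (is.null(dim(final_pos))) final_pos <- matrix(final_pos, ncol = 3)
  final <- configuration(final_pos, samples$spec, validate = FALSE)
  saveRDS(list(spec = samples$spec, schedule = samples$schedule,
               final_configuration = final,
               acceptance_rate = samples$acceptance_rate,
               tuned_displacement = samples$tuned_displacement), path)
  invisible(path)
}

#' Read a checkpoint written by [write_checkpoint()]
#' @param path checkpoint path.
#' @return the checkpoint list.
#' @export
read_checkpoint <- function(path) readRDS(path)
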