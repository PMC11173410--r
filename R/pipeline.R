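# Sweep orchestration over (dielectric constant x salt ratio x salt valence).

#' Assemble the canonical cell-model system for one grid cell
#'
#' The canonical system is a macroion of radius 20 Å and valence -60 fixed
#' in a 100 Å cell (macroion volume fraction 0.008), neutralised by 60
#' monovalent counterions of radius 2 Å, plus a z:1 salt whose content is
#' set by the salt ratio beta. Electroneutral by construction.
#'
#' @param epsilon solvent dielectric constant.
#' @param beta salt ratio (0 for salt-free).
#' @param cation_valence salt cation valence (3 or 5); ignored when
#'   `beta = 0`.
#' @param defaults optional overrides: a list with any of `temperature`,
#'   `macroion_radius`, `macroion_valence`, `ion_radius`, `cell_radius`.
#' @return a [system_spec()].
#' @examples
#' build_system(78, 6.25, 3) # 60 counterions + 125 trivalent + 375 anions
#' @export
build_system <- function(epsilon, beta = 0, cation_valence = 3,
                         defaults = list()) {
  d <- modifyList(list(temperature = 298, macroion_radius = 20,
                       macroion_valence = -60, ion_radius = 2,
                       cell_radius = 100), defaults)
  mac <- macroion_spec(d$macroion_radius, d$macroion_valence)
  species <- list(ion_species("counterion", d$ion_radius, +1L,
                              abs(d$macroion_valence)))
  if (beta > 0) {
    comp <- salt_composition(beta, mac, cation_valence)
    species <- c(species, list(
      ion_species("salt_cation", d$ion_radius, as.integer(cation_valence),
                  comp[["n_cation"]]),
      ion_species("salt_anion", d$ion_radius, -1L, comp[["n_anion"]])))
  }
  system_spec(solvent_spec(epsilon, d$temperature), mac, species,
              cell_radius = d$cell_radius, beta = beta)
}

#' Derive an independent per-cell seed
#'
#' Mixes a base seed with the grid coordinates through a small
#' multiplicative hash so that every sweep cell gets a decorrelated,
#' individually reproducible seed below 2^31.
#'
#' @param base_seed integer base seed.
#' @param epsilon,beta,cation_valence grid coordinates.
#' @return integer seed.
#' @export
cell_seed <- function(base_seed, epsilon, beta, cation_valence = 0) {
  mix <- function(h, x) {
    for (b in as.integer(charToRaw(format(x, digits = 12))))
      h <- (h * 31 + b) %% 2147483629
    h
  }
  h <- mix(as.numeric(base_seed) %% 2147483629, epsilon)
  h <- mix(h, beta)
  h <- mix(h, cation_valence)
  as.integer(h %% 2147483629 + 1)
}

#' Sweep grid definition
#'
#' @param epsilons dielectric constants (default the six canonical
#'   solvents 78, 68, 54, 40, 30, 20).
#' @param betas salt ratios (default 0, 0.15, 0.45, 1, 4, 6.25); every
#'   value must yield an integer salt composition for every valence.
#' @param cation_valences salt valences to sweep (subset of {3, 5}).
#' @param schedule template [mc_schedule()]; each cell reuses it with its
#'   own derived seed.
#' @param base_seed base seed for [cell_seed()].
#' @return object of class `sweep_grid`.
#' @export
sweep_grid <- function(epsilons = c(78, 68, 54, 40, 30, 20),
                       betas = c(0, 0.15, 0.45, 1, 4, 6.25),
                       cation_valences = 3,
                       schedule = mc_schedule(),
                       base_seed = 1L) {
  stopifnot(length(epsilons) > 0, length(betas) > 0,
            all(cation_valences %in% c(3, 5)))
  structure(list(epsilons = epsilons, betas = betas,
                 cation_valences = cation_valences, schedule = schedule,
                 base_seed = base_seed),
            class = "sweep_grid")
}

#' Run a full sweep
#'
#' Runs one independent, individually seeded simulation per grid cell and
#' collects the scalar summaries into a data frame. Per-cell failures
#' (e.g. a beta value with no integer salt composition for some valence)
#' are recorded and the sweep continues. When `output_dir` is given, each
#' completed cell is written as a JSON record and re-running the sweep
#' skips cells whose record already exists (resumability).
#'
#' @param grid a [sweep_grid()].
#' @param bin_width,cutoff observable settings forwarded to [summarize()].
#' @param output_dir optional directory for per-cell JSON records.
#' @param verbose log per-cell progress to stderr.
#' @return object of class `sweep_report`: list with `results` (data
#'   frame), `failures` (data frame) and `provenance`.
#' @export
run_sweep <- function(grid, bin_width = 0.5, cutoff = 60, output_dir = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(grid, "sweep_grid"))
  cells <- expand.grid(epsilon = grid$epsilons, beta = grid$betas,
                       valence = grid$cation_valences,
                       KEEP.OUT.ATTRS = FALSE)
  # a salt-free cell does not depend on the salt valence: run it once
  cells <- cells[!(cells$beta == 0 & duplicated(cells[c("epsilon", "beta")])), ]
  rows <- list()
  fails <- list()
  for (i in seq_len(nrow(cells))) {
    eps <- cells$epsilon[i]; b <- cells$beta[i]; zc <- cells$valence[i]
    seed <- cell_seed(grid$base_seed, eps, b, if (b > 0) zc else 0)
    tag <- sprintf("eps%g_beta%g_z%g_seed%d", eps, b, if (b > 0) zc else 0, seed)
    record_path <- if (!is.null(output_dir))
      file.path(output_dir, paste0(tag, ".json")) else NULL
    if (!is.null(record_path) && file.exists(record_path)) {
      rows[[tag]] <- as.data.frame(jsonlite::read_json(record_path,
                                                       simplifyVector = TRUE))
      if (verbose) message("skipping completed cell ", tag)
      next
    }
    res <- tryCatch({
      spec <- build_system(eps, b, zc)
      sched <- grid$schedule
      sched$seed <- as.numeric(seed)
      samples <- run_simulation(spec, sched)
      s <- summarize(samples, bin_width = bin_width, cutoff = cutoff)
      data.frame(
        epsilon = eps, beta = b,
        cation_valence = if (b > 0) zc else NA_real_, seed = seed,
        n_ions = n_ions(spec),
        surface_potential_mV = s$surface_potential_mV,
        surface_potential_se = s$surface_potential_se,
        zeta_potential_mV = s$zeta_potential_mV,
        zeta_potential_se = s$zeta_potential_se,
        effective_charge_e = s$effective_charge_e,
        effective_charge_se = s$effective_charge_se,
        reduced_energy = s$reduced_energy,
        reduced_energy_se = s$reduced_energy_se,
        contact_gMI = s$contact_gMI,
        zacc_extremum_e = s$zacc_extremum_e,
        zacc_extremum_r = s$zacc_extremum_r,
        acceptance_rate = s$acceptance_rate)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[tag]] <- data.frame(epsilon = eps, beta = b, cation_valence = zc,
                                 message = conditionMessage(res))
      if (verbose) message("cell ", tag, " failed: ", conditionMessage(res))
      next
    }
    if (!is.null(record_path)) {
      dir.create(dirname(record_path), recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(res, record_path, auto_unbox = TRUE, digits = NA)
    }
    rows[[tag]] <- res
    if (verbose)
      message(sprintf("cell %s: zeta = %.1f mV, Zeff = %.1f e", tag,
                      res$zeta_potential_mV, res$effective_charge_e))
  }
  structure(list(
    results = if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
              else data.frame(),
    failures = if (length(fails)) do.call(rbind, c(fails, make.row.names = FALSE))
               else data.frame(),
    provenance = list(base_seed = grid$base_seed,
                      schedule = grid$schedule,
                      package_version = as.character(utils::packageVersion("edlmc")),
                      timestamp = format(Sys.time(), tz = "UTC"))
  ), class = "sweep_report")
}

#' @export
print.sweep_report <- function(x, ...) {
  cat(sprintf("sweep_report: %d cells completed, %d failed\n",
              nrow(x$results), nrow(x$failures)))
  if (nrow(x$results)) {
    print(x$results[, c("epsilon", "beta", "cation_valence",
                        "zeta_potential_mV", "effective_charge_e",
                        "reduced_energy")], digits = 3)
  }
  invisible(x)
}
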