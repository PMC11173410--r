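# System description: solvent, macroion, ion species, full cell-model spec.

#' Solvent specification
#'
#' The solvent enters the primitive model only through its relative
#' dielectric constant at a fixed temperature.
#'
#' @param epsilon_r relative dielectric constant (> 1); e.g. 78 for water,
#'   20 for ethanol.
#' @param temperature temperature in kelvin (default 298).
#' @return object of class `solvent_spec`.
#' @export
solvent_spec <- function(epsilon_r, temperature = 298) {
  stopifnot(is.numeric(epsilon_r), length(epsilon_r) == 1, epsilon_r > 1,
            is.numeric(temperature), length(temperature) == 1, temperature > 0)
  structure(list(epsilon_r = epsilon_r, temperature = temperature),
            class = "solvent_spec")
}

#' Macroion specification
#'
#' A hard sphere fixed at the centre of the cell.
#'
#' @param radius hard-sphere radius in Å.
#' @param valence signed charge in units of e (typically negative).
#' @return object of class `macroion_spec`.
#' @export
macroion_spec <- function(radius = 20, valence = -60) {
  stopifnot(radius > 0, valence == round(valence))
  structure(list(radius = radius, valence = as.integer(valence)),
            class = "macroion_spec")
}

#' Mobile ion species
#'
#' @param label one of `"counterion"`, `"salt_cation"`, `"salt_anion"`.
#' @param radius hard-sphere radius in Å.
#' @param valence signed integer charge in units of e (non-zero).
#' @param count number of ions of this species.
#' @return object of class `ion_species`.
#' @export
ion_species <- function(label = c("counterion", "salt_cation", "salt_anion"),
                        radius = 2, valence = 1L, count = 0L) {
  label <- match.arg(label)
  stopifnot(radius > 0, valence == round(valence), valence != 0,
            count == round(count), count >= 0)
  structure(list(label = label, radius = radius,
                 valence = as.integer(valence), count = as.integer(count)),
            class = "ion_species")
}

#' Full cell-model system specification
#'
#' Assembles solvent, macroion and ion species into one closed spherical
#' cell. By default the total charge must vanish exactly (integer
#' arithmetic); toy diagnostic systems used by the fixture generators may
#' opt out with `allow_net_charge = TRUE`.
#'
#' @param solvent a [solvent_spec()].
#' @param macroion a [macroion_spec()].
#' @param species list of [ion_species()].
#' @param cell_radius cell radius in Å; must exceed the macroion radius plus
#'   the largest ion radius.
#' @param beta salt ratio \eqn{\beta} (total added cation charge over total
#'   macroion charge magnitude); bookkeeping metadata, 0 for salt-free.
#' @param allow_net_charge allow a non-neutral toy system (default FALSE).
#' @return object of class `system_spec`.
#' @export
system_spec <- function(solvent, macroion, species, cell_radius = 100,
                        beta = 0, allow_net_charge = FALSE) {
  stopifnot(inherits(solvent, "solvent_spec"),
            inherits(macroion, "macroion_spec"),
            is.list(species),
            all(vapply(species, inherits, logical(1), "ion_species")),
            beta >= 0)
  max_ri <- if (length(species)) max(vapply(species, `[[`, numeric(1), "radius")) else 0
  if (cell_radius <= macroion$radius + max_ri)
    stop("cell_radius must exceed macroion radius + largest ion radius")
  net <- macroion$valence +
    sum(vapply(species, function(s) s$count * s$valence, numeric(1)))
  if (!allow_net_charge && net != 0)
    stop("system is not electroneutral: net charge ", net, " e")
  structure(list(solvent = solvent, macroion = macroion, species = species,
                 cell_radius = cell_radius, beta = beta, net_charge = net),
            class = "system_spec")
}

#' @export
print.system_spec <- function(x, ...) {
  cat(sprintf("Spherical cell model: R_cell = %g Å, eps_r = %g, T = %g K\n",
              x$cell_radius, x$solvent$epsilon_r, x$solvent$temperature))
  cat(sprintf("  macroion: R_M = %g Å, Z_M = %+d (sigma = %.3f C/m2)\n",
              x$macroion$radius, x$macroion$valence,
              surface_charge_density(x$macroion)))
  for (s in x$species)
    cat(sprintf("  %-11s n = %4d, Z = %+d, R = %g Å\n",
                s$label, s$count, s$valence, s$radius))
  cat(sprintf("  beta = %g, l_B = %.2f Å, net charge = %d e\n",
              x$beta, bjerrum_length(x$solvent), x$net_charge))
  invisible(x)
}

#' Number of mobile ions in a system
#' @param spec a [system_spec()].
#' @return integer count of all mobile ions.
#' @export
n_ions <- function(spec) {
  sum(vapply(spec$species, `[[`, integer(1), "count"))
}

# per-ion expansion used by the engine and the observables
ion_vectors <- function(spec) {
  counts <- vapply(spec$species, `[[`, integer(1), "count")
  idx <- rep(seq_along(spec$species), counts)
  list(
    valence = vapply(spec$species, `[[`, integer(1), "valence")[idx],
    radius  = vapply(spec$species, `[[`, numeric(1), "radius")[idx],
    species_index = idx,
    label = vapply(spec$species, `[[`, character(1), "label")[idx]
  )
}

#' Salt composition from the salt ratio
#'
#' The salt content is parameterised by
#' \eqn{\beta = Z_c \rho_c / |Z_M \rho_M|}: the total added cation charge
#' over the macroion charge. For a z:1 salt the cation count is
#' \eqn{n_c = \beta |Z_M| / Z_c} and each cation brings \eqn{Z_c}
#' monovalent anions, so the cell with its \eqn{|Z_M|} monovalent
#' counterions stays exactly neutral.
#'
#' @param beta salt ratio (>= 0).
#' @param macroion a [macroion_spec()].
#' @param cation_valence salt cation valence (3 or 5 in the canonical
#'   systems; any positive integer accepted).
#' @return named integer vector `c(n_cation, n_anion)`.
#' @examples
#' salt_composition(6.25, macroion_spec(), 3) # 125 cations, 375 anions
#' @export
salt_composition <- function(beta, macroion, cation_valence) {
  stopifnot(beta >= 0, cation_valence > 0,
            cation_valence == round(cation_valence))
  n_c_real <- beta * abs(macroion$valence) / cation_valence
  n_c <- round(n_c_real)
  if (abs(n_c_real - n_c) > 1e-6)
    stop(sprintf(
      "beta = %g with Z_c = %d gives a non-integer cation count (%.6f)",
      beta, as.integer(cation_valence), n_c_real))
  c(n_cation = as.integer(n_c), n_anion = as.integer(n_c * cation_valence))
}
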