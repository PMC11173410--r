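# Configurations and the reference (brute-force) energy evaluation.
# total_energy() is the oracle against which the engine's incremental
# bookkeeping is audited; it is deliberately a plain double loop over pairs.

#' Ion configuration
#'
#' Positions of all mobile ions at one Monte Carlo state, in a
#' macroion-centred frame (Å).
#'
#' @param positions numeric N x 3 matrix of ion centres.
#' @param spec the [system_spec()] the configuration belongs to; row order
#'   must follow the species order of the spec.
#' @param validate check hard-sphere and cell constraints (default TRUE).
#' @return object of class `configuration`.
#' @export
configuration <- function(positions, spec, validate = TRUE) {
  positions <- as.matrix(positions)
  if (length(positions) == 0) positions <- matrix(numeric(0), 0, 3)
  stopifnot(ncol(positions) == 3, nrow(positions) == n_ions(spec))
  cfg <- structure(list(positions = positions, spec = spec,
                        ions = ion_vectors(spec)),
                   class = "configuration")
  if (validate) {
    bad <- check_configuration(cfg)
    if (!is.null(bad)) stop("invalid configuration: ", bad)
  }
  cfg
}

# NULL if valid, otherwise a message
check_configuration <- function(cfg) {
  pos <- cfg$positions
  n <- nrow(pos)
  if (n == 0) return(NULL)
  spec <- cfg$spec
  r <- sqrt(rowSums(pos^2))
  ri <- cfg$ions$radius
  if (any(r < spec$macroion$radius + ri - 1e-9))
    return("ion overlaps the macroion")
  if (any(r > spec$cell_radius - ri + 1e-9))
    return("ion sticks out of the cell")
  if (n > 1) {
    d <- as.matrix(stats::dist(pos))
    min_sep <- outer(ri, ri, `+`)
    diag(d) <- Inf
    if (any(d < min_sep - 1e-9)) return("ion-ion hard-sphere overlap")
  }
  NULL
}

#' Pair interaction energy of the primitive model
#'
#' Hard-sphere plus bare Coulomb: infinite on overlap
#' (\eqn{r < R_i + R_j}), otherwise \eqn{Z_i Z_j l_B / r} in units of
#' \eqn{k_B T}.
#'
#' @param r centre-centre separation in Å.
#' @param z_i,z_j signed valences in units of e.
#' @param r_i,r_j hard-sphere radii in Å.
#' @param solvent a [solvent_spec()].
#' @return energy in kBT; `Inf` for an overlapping pair.
#' @examples
#' s <- solvent_spec(78)
#' pair_energy(bjerrum_length(s), 1, 1, 0.1, 0.1, s) # 1 kBT by definition
#' @export
pair_energy <- function(r, z_i, z_j, r_i, r_j, solvent) {
  stopifnot(r > 0)
  ifelse(r < r_i + r_j, Inf, z_i * z_j * bjerrum_length(solvent) / r)
}

#' Total configurational energy by explicit pair summation
#'
#' Sums [pair_energy()] over every distinct pair, including each ion's pair
#' with the fixed central macroion. This is the reference evaluation used
#' to audit the engine's O(N) incremental updates.
#'
#' @param config a [configuration()].
#' @param spec a [system_spec()]; defaults to the one stored in `config`.
#' @return list of class `energy_breakdown` with components `total`,
#'   `macroion_ion`, `ion_ion` (kBT) and `overlap_flag`.
#' @export
total_energy <- function(config, spec = config$spec) {
  pos <- config$positions
  n <- nrow(pos)
  lb <- bjerrum_length(spec$solvent)
  zi <- config$ions$valence
  ri <- config$ions$radius
  zm <- spec$macroion$valence
  rm <- spec$macroion$radius
  u_mi <- 0
  u_ii <- 0
  overlap <- FALSE
  if (n > 0) {
    for (i in seq_len(n)) {
      r <- sqrt(sum(pos[i, ]^2))
      if (r < rm + ri[i]) overlap <- TRUE
      u_mi <- u_mi + zm * zi[i] * lb / r
      if (i < n) for (j in seq(i + 1, n)) {
        rij <- sqrt(sum((pos[i, ] - pos[j, ])^2))
        if (rij < ri[i] + ri[j]) overlap <- TRUE
        u_ii <- u_ii + zi[i] * zi[j] * lb / rij
      }
    }
  }
  structure(list(
    total = if (overlap) Inf else u_mi + u_ii,
    macroion_ion = if (overlap) Inf else u_mi,
    ion_ion = if (overlap) Inf else u_ii,
    overlap_flag = overlap
  ), class = "energy_breakdown")
}
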