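# Structural and electrostatic observables of the double layer.
#
# All radial profiles live on [R_M, R_cell]. The accumulated charge and the
# potential are evaluated at bin EDGES (where counting is exact); the RDF is
# a per-bin histogram reported at bin midpoints.

radial_profile <- function(r, value, stderr = NULL, quantity, units,
                           convention = c("edge", "midpoint"),
                           bin_edges = NULL) {
  convention <- match.arg(convention)
  stopifnot(length(r) == length(value),
            is.null(stderr) || length(stderr) == length(value))
  structure(list(r = r, value = value, stderr = stderr, quantity = quantity,
                 units = units, convention = convention,
                 bin_edges = bin_edges),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("radial_profile '%s' [%s], %d points on [%.1f, %.1f] Å (%s)\n",
              x$quantity, x$units, length(x$r), min(x$r), max(x$r),
              x$convention))
  invisible(x)
}

#' @export
as.data.frame.radial_profile <- function(x, ...) {
  data.frame(r = x$r, value = x$value,
             stderr = if (is.null(x$stderr)) NA_real_ else x$stderr)
}

# radii of every ion in every sample: n_ions x n_samples matrix
sample_radii <- function(samples) {
  a <- samples$configurations
  if (dim(a)[3] == 0) stop("no stored samples")
  r <- sqrt(a[, 1, , drop = FALSE]^2 + a[, 2, , drop = FALSE]^2 +
              a[, 3, , drop = FALSE]^2)
  matrix(r, nrow = dim(a)[1], ncol = dim(a)[3])
}

# accessible volume for centres of a species of radius ri (Å^3)
accessible_volume <- function(spec, ri) {
  4 / 3 * pi * ((spec$cell_radius - ri)^3 - (spec$macroion$radius + ri)^3)
}

#' Macroion-ion radial distribution function
#'
#' Histogram of macroion-ion centre distances for one species, normalised
#' by the exact spherical-shell volume of each bin and by the species'
#' uniform density over its accessible shell, so that an uncorrelated
#' (uncharged) system gives g = 1 inside the shell.
#'
#' @param samples a `trajectory_samples` object from [run_simulation()].
#' @param species species label (`"counterion"`, `"salt_cation"`,
#'   `"salt_anion"`).
#' @param bin_width bin width in Å (default 0.5).
#' @return a `radial_profile` (midpoint convention) covering
#'   \[R_M, R_cell\], with block-averaged standard errors.
#' @export
radial_distribution <- function(samples, species = "counterion",
                                bin_width = 0.5) {
  spec <- samples$spec
  labels <- vapply(spec$species, `[[`, character(1), "label")
  k <- which(labels == species)
  if (length(k) != 1 || spec$species[[k]]$count == 0)
    stop("species '", species, "' not present in the system")
  sel <- samples$species_index == k
  rmat <- sample_radii(samples)[sel, , drop = FALSE]
  edges <- seq(spec$macroion$radius, spec$cell_radius, by = bin_width)
  if (max(edges) < spec$cell_radius) edges <- c(edges, spec$cell_radius)
  nb <- length(edges) - 1
  ns <- ncol(rmat)
  # per-sample bin counts
  counts <- vapply(seq_len(ns), function(s) {
    tabulate(findInterval(rmat[, s], edges, rightmost.closed = TRUE),
             nbins = nb)
  }, numeric(nb))
  counts <- matrix(counts, nrow = nb)
  vol <- 4 / 3 * pi * diff(edges^3)
  rho <- spec$species[[k]]$count /
    accessible_volume(spec, spec$species[[k]]$radius)
  norm <- rho * vol
  g_per_sample <- counts / norm
  g <- rowMeans(g_per_sample)
  se <- block_se_matrix(g_per_sample)
  radial_profile(r = (edges[-1] + edges[-length(edges)]) / 2, value = g,
                 stderr = se, quantity = paste0("g_MI:", species),
                 units = "dimensionless", convention = "midpoint",
                 bin_edges = edges)
}

#' Accumulated running charge profile
#'
#' \eqn{Z_{acc}(r)} is the macroion charge plus the mean net ionic charge
#' within radius r, computed by direct counting over the stored samples and
#' evaluated at bin edges (where the counting is exact). It equals
#' \eqn{Z_M} at contact and 0 at the cell boundary (electroneutrality).
#'
#' @param samples a `trajectory_samples`.
#' @param bin_width grid spacing in Å (default 0.5).
#' @return a `radial_profile` (edge convention) of the charge in units of
#'   e on \[R_M, R_cell\], with block-averaged standard errors.
#' @export
accumulated_charge <- function(samples, bin_width = 0.5) {
  spec <- samples$spec
  grid <- seq(spec$macroion$radius, spec$cell_radius, by = bin_width)
  if (max(grid) < spec$cell_radius) grid <- c(grid, spec$cell_radius)
  per_sample <- zacc_per_sample(samples, grid)
  radial_profile(r = grid, value = rowMeans(per_sample),
                 stderr = block_se_matrix(per_sample),
                 quantity = "Z_acc", units = "e", convention = "edge")
}

# Z_acc evaluated at `grid` for each stored sample: length(grid) x n_samples
zacc_per_sample <- function(samples, grid) {
  spec <- samples$spec
  zm <- spec$macroion$valence
  val <- ion_vectors(spec)$valence
  rmat <- sample_radii(samples)
  if (is.null(dim(rmat))) rmat <- matrix(rmat, ncol = dim(samples$configurations)[3])
  ns <- ncol(rmat)
  out <- vapply(seq_len(ns), function(s) {
    ord <- order(rmat[, s])
    csum <- cumsum(val[ord])
    idx <- findInterval(grid, rmat[ord, s])
    zm + ifelse(idx == 0, 0, csum[pmax(idx, 1)])
  }, numeric(length(grid)))
  matrix(out, nrow = length(grid))
}

#' Accumulated charge via quadrature of binned RDFs
#'
#' The integral route to \eqn{Z_{acc}(r)}: the sum over species of
#' \eqn{Z_i \rho_i g_i} integrated over spherical shells out to r, added to
#' \eqn{Z_M}. With exact shell volumes this is algebraically identical to
#' the counting route at bin edges; kept as an independent cross-check.
#'
#' @param rdfs named list of `radial_profile` RDFs, one per species present,
#'   all on the same bin grid.
#' @param spec the [system_spec()].
#' @return a `radial_profile` (edge convention).
#' @export
accumulated_charge_from_rdf <- function(rdfs, spec) {
  labels <- vapply(spec$species, `[[`, character(1), "label")
  edges <- rdfs[[1]]$bin_edges
  vol <- 4 / 3 * pi * diff(edges^3)
  dq <- numeric(length(edges) - 1)
  for (k in seq_along(spec$species)) {
    s <- spec$species[[k]]
    if (s$count == 0) next
    g <- rdfs[[s$label]]
    stopifnot(!is.null(g), isTRUE(all.equal(g$bin_edges, edges)))
    rho <- s$count / accessible_volume(spec, s$radius)
    dq <- dq + s$valence * rho * g$value * vol
  }
  radial_profile(r = edges, value = spec$macroion$valence + c(0, cumsum(dq)),
                 quantity = "Z_acc(rdf)", units = "e", convention = "edge")
}

#' Mean electrostatic potential profile
#'
#' Integrates the accumulated charge,
#' \eqn{\varphi(r) = \frac{k_B T}{e} \, l_B \int_r^{r_c} Z_{acc}(r')/r'^2 \, dr'},
#' by trapezoidal quadrature on the binned profile, and reports the result
#' in mV. The upper cutoff \eqn{r_c} (default 60 Å) sets the potential
#' zero: \eqn{\varphi(r_c) = 0} by construction.
#'
#' @param zacc `radial_profile` of the accumulated charge (edge convention).
#'   Repeated grid points are allowed and integrate as exact jumps, so a
#'   step-function profile with doubled abscissae is integrated exactly.
#' @param solvent a [solvent_spec()].
#' @param upper_cutoff integration cutoff in Å; must lie inside the profile
#'   support.
#' @return a `radial_profile` of the potential in mV on
#'   \[min(zacc$r), upper_cutoff\].
#' @export
mean_potential <- function(zacc, solvent, upper_cutoff = 60) {
  r <- zacc$r
  if (upper_cutoff > max(r) + 1e-9 || upper_cutoff < min(r))
    stop("upper_cutoff outside the profile support")
  keep <- r <= upper_cutoff + 1e-9
  r <- r[keep]
  z <- zacc$value[keep]
  appended <- FALSE
  if (abs(r[length(r)] - upper_cutoff) > 1e-9) {
    z <- c(z, approx(zacc$r, zacc$value, xout = upper_cutoff)$y)
    r <- c(r, upper_cutoff)
    appended <- TRUE
  }
  f <- z / r^2
  dr <- diff(r)
  seg <- dr * (f[-1] + f[-length(f)]) / 2
  # integral from r_k to cutoff = total minus integral up to r_k
  cum <- c(0, cumsum(seg))
  integral <- cum[length(cum)] - cum
  phi_mv <- thermal_voltage_mV(solvent$temperature) *
    bjerrum_length(solvent) * integral
  se <- NULL
  if (!is.null(zacc$stderr) && !appended) {
    # propagate bin SEs through the (linear) quadrature, assuming
    # independent bins (an underestimate for correlated bins; indicative)
    sev <- zacc$stderr[keep]
    w <- dr / 2
    var_seg <- (w * sev[-length(sev)] / r[-length(r)]^2)^2 +
      (w * sev[-1] / r[-1]^2)^2
    cumv <- c(0, cumsum(var_seg))
    se <- thermal_voltage_mV(solvent$temperature) * bjerrum_length(solvent) *
      sqrt(pmax(cumv[length(cumv)] - cumv, 0))
  }
  radial_profile(r = r, value = phi_mv, stderr = se, quantity = "phi",
                 units = "mV", convention = zacc$convention)
}

# block-averaged standard error of the mean for each row of a
# (quantity x sample) matrix
block_se_matrix <- function(m, n_blocks = 20) {
  ns <- ncol(m)
  if (ns < 2) return(rep(NA_real_, nrow(m)))
  if (ns < n_blocks) n_blocks <- max(2, ns)
  blk <- cut(seq_len(ns), breaks = n_blocks, labels = FALSE)
  means <- vapply(seq_len(n_blocks),
                  function(b) rowMeans(m[, blk == b, drop = FALSE]),
                  numeric(nrow(m)))
  means <- matrix(means, nrow = nrow(m))
  apply(means, 1, sd) / sqrt(n_blocks)
}

block_se <- function(x, n_blocks = 20) {
  block_se_matrix(matrix(x, nrow = 1), n_blocks)
}

#' Scalar summary of one simulation
#'
#' Computes the headline scalars of a run: the surface potential
#' \eqn{\varphi_s = \varphi(R_M)}; the zeta potential
#' \eqn{\xi = \varphi(R_M + 2 R_I)} at the slipping plane one ionic
#' diameter from the macroion surface; the effective macroion charge
#' \eqn{Z_M^{eff}}, the accumulated charge one ionic diameter beyond the
#' contact separation (\eqn{r = R_M + 3 R_I}, i.e. 26 Å for the canonical
#' geometry — the plane at which the charge fractions 0.54/0.07 of the
#' water/ethanol systems are quoted); the reduced energy
#' \eqn{U / N k_B T}; the contact value of the counterion RDF; and the
#' maximum of \eqn{Z_{acc}} between the slipping plane and the integration
#' cutoff (positive when the macroion is charge-inverted; the search stops
#' at the cutoff to exclude the neutral-boundary cation buildup at the
#' cell wall). Standard errors are block averages over `n_blocks`
#' contiguous sample blocks.
#'
#' @param samples a `trajectory_samples`.
#' @param bin_width profile resolution in Å (default 0.5).
#' @param cutoff potential integration cutoff in Å (default 60).
#' @param n_blocks blocks for error estimation (default 20; at least 10
#'   samples per scalar are required).
#' @param energy_norm `"ions"` divides U by the number of mobile small
#'   ions; `"counterions"` by the (salt-independent) number of
#'   counterions, the normalisation under which the reduced energy
#'   decreases monotonically with salt content; `"all"` counts every
#'   particle including the macroion.
#' @param zeta_plane radius of the slipping plane in Å (default
#'   \eqn{R_M + 2 R_I}).
#' @param charge_plane radius at which the effective charge is read off,
#'   in Å (default \eqn{R_M + 3 R_I}).
#' @return object of class `summary_result`.
#' @export
summarize <- function(samples, bin_width = 0.5, cutoff = 60, n_blocks = 20,
                      energy_norm = c("ions", "counterions", "all"),
                      zeta_plane = NULL, charge_plane = NULL) {
  energy_norm <- match.arg(energy_norm)
  spec <- samples$spec
  ns <- dim(samples$configurations)[3]
  n_blocks <- min(n_blocks, ns)
  if (n_blocks < 10)
    stop("too few stored samples (", ns, ") for block averaging")
  r_zeta <- if (is.null(zeta_plane))
    spec$macroion$radius + 2 * max_ion_radius(spec) else zeta_plane
  r_eff <- if (is.null(charge_plane))
    spec$macroion$radius + 3 * max_ion_radius(spec) else charge_plane
  grid <- sort(unique(c(
    seq(spec$macroion$radius, spec$cell_radius, by = bin_width),
    spec$cell_radius, r_zeta, r_eff, cutoff)))
  per_sample <- zacc_per_sample(samples, grid)
  zmean <- rowMeans(per_sample)
  zacc <- radial_profile(grid, zmean, stderr = block_se_matrix(per_sample, n_blocks),
                         quantity = "Z_acc", units = "e", convention = "edge")
  phi <- mean_potential(zacc, spec$solvent, cutoff)

  # per-sample scalars for blocking
  i_eff <- which.min(abs(grid - r_eff))
  zeff_s <- per_sample[i_eff, ]
  phi_of <- function(zvec, at) {
    p <- mean_potential(radial_profile(grid, zvec, quantity = "Z_acc",
                                       units = "e", convention = "edge"),
                        spec$solvent, cutoff)
    approx(p$r, p$value, xout = at)$y
  }
  blk <- cut(seq_len(ns), breaks = n_blocks, labels = FALSE)
  blocks <- function(scalars) sd(vapply(seq_len(n_blocks), function(b)
    mean(scalars[blk == b]), numeric(1))) / sqrt(n_blocks)
  # potential scalars are linear in Z_acc, so block means of per-block
  # profiles equal per-block scalar means
  phis_b <- vapply(seq_len(n_blocks), function(b)
    phi_of(rowMeans(per_sample[, blk == b, drop = FALSE]), spec$macroion$radius),
    numeric(1))
  zeta_b <- vapply(seq_len(n_blocks), function(b)
    phi_of(rowMeans(per_sample[, blk == b, drop = FALSE]), r_zeta),
    numeric(1))

  n_small <- n_ions(spec)
  n_norm <- switch(energy_norm,
    ions = n_small,
    counterions = sum(vapply(spec$species, function(s)
      if (s$label == "counterion") s$count else 0L, numeric(1))),
    all = n_small + 1)
  u_red <- mean(samples$energies) / n_norm

  beyond <- grid > r_zeta + 1e-9 & grid <= cutoff + 1e-9
  zmax <- max(zmean[beyond])
  i_zmax <- which(beyond)[which.max(zmean[beyond])]

  g_ct <- tryCatch(radial_distribution(samples, "counterion", bin_width),
                   error = function(e) NULL)
  contact <- if (!is.null(g_ct)) {
    r_ct <- spec$macroion$radius +
      spec$species[[which(vapply(spec$species, `[[`, character(1), "label")
                          == "counterion")]]$radius
    g_ct$value[which(g_ct$bin_edges[-length(g_ct$bin_edges)] >= r_ct - 1e-9)[1]]
  } else NA_real_

  structure(list(
    surface_potential_mV = approx(phi$r, phi$value, xout = spec$macroion$radius)$y,
    surface_potential_se = sd(phis_b) / sqrt(n_blocks),
    zeta_potential_mV = approx(phi$r, phi$value, xout = r_zeta)$y,
    zeta_potential_se = sd(zeta_b) / sqrt(n_blocks),
    effective_charge_e = mean(zeff_s),
    effective_charge_se = blocks(zeff_s),
    reduced_energy = u_red,
    reduced_energy_se = blocks(samples$energies / n_norm),
    contact_gMI = contact,
    zacc_extremum_e = zmax,
    zacc_extremum_r = grid[i_zmax],
    zeta_plane = r_zeta,
    charge_plane = r_eff,
    cutoff = cutoff,
    acceptance_rate = samples$acceptance_rate,
    spec = spec,
    schedule = samples$schedule
  ), class = "summary_result")
}

max_ion_radius <- function(spec) {
  max(vapply(spec$species, `[[`, numeric(1), "radius"))
}

#' @export
print.summary_result <- function(x, ...) {
  cat(sprintf("summary_result (eps_r = %g, beta = %g):\n",
              x$spec$solvent$epsilon_r, x$spec$beta))
  cat(sprintf("  phi_s   = %8.2f +/- %.2f mV\n",
              x$surface_potential_mV, x$surface_potential_se))
  cat(sprintf("  zeta    = %8.2f +/- %.2f mV  (at %g Å, cutoff %g Å)\n",
              x$zeta_potential_mV, x$zeta_potential_se, x$zeta_plane,
              x$cutoff))
  cat(sprintf("  Z_eff   = %8.2f +/- %.2f e   (Z_eff/Z_M = %.3f, at %g Å)\n",
              x$effective_charge_e, x$effective_charge_se,
              x$effective_charge_e / x$spec$macroion$valence, x$charge_plane))
  cat(sprintf("  U/NkBT  = %8.3f +/- %.3f\n",
              x$reduced_energy, x$reduced_energy_se))
  cat(sprintf("  max Z_acc beyond slip plane = %+.2f e at r = %.1f Å\n",
              x$zacc_extremum_e, x$zacc_extremum_r))
  cat(sprintf("  contact g_MI = %.1f, acceptance = %.2f\n",
              x$contact_gMI, x$acceptance_rate))
  invisible(x)
}
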