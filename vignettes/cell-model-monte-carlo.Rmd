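---
title: "Monte Carlo simulation of spherical electric double layers in the primitive model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo simulation of spherical electric double layers in the primitive model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`edlmc` simulates the electric double layer (EDL) around a single highly
charged colloidal sphere — a *macroion* — in the primitive model: all ions
are charged hard spheres, and the solvent enters only through its relative
dielectric constant $\varepsilon_r$ at fixed temperature $T$. The macroion
(radius $R_M$, valence $Z_M$) is fixed at the centre of a closed spherical
cell of radius $R_{cell}$; the cell radius encodes the colloid
concentration (for the canonical geometry, $R_M = 20$ Å in a 100 Å cell, a
macroion volume fraction of $(R_M/R_{cell})^3 = 0.008$). The mobile ions
are the macroion's monovalent counterions plus, optionally, a z:1 salt
with multivalent cations ($Z_c \in \{3, 5\}$) and monovalent anions. Every
system is assembled exactly electroneutral by integer arithmetic.

Two particles $i, j$ interact through

$$
u_{ij}(r) \;=\;
\begin{cases}
\infty, & r < R_i + R_j,\\[2pt]
\dfrac{Z_i Z_j \, l_B}{r}\, k_B T, & r \ge R_i + R_j,
\end{cases}
$$

where $l_B = e^2 / (4 \pi \varepsilon_0 \varepsilon_r k_B T)$ is the
Bjerrum length (7.2 Å in water at 298 K, 28 Å in ethanol with
$\varepsilon_r = 20$). There are no periodic images and no Ewald sums: the
cell is a closed container and the Coulomb sum runs over all particles in
it. Internally all lengths are in Å, energies in $k_B T$ and charges in
units of $e$; potentials are converted to mV on output with
$k_B T / e \approx 25.7$ mV at 298 K. Physical constants are CODATA 2018
values.

The strength of ion–ion correlations on the macroion surface is summarised
by the coupling parameter $\Gamma = Z^2 l_B / a_Z$ with
$a_Z = \sqrt{Z e / \sigma}$ the spacing of $Z$-valent counterions on a
surface of charge density $\sigma$; correlation phenomena such as charge
inversion set in around $\Gamma \gtrsim 2$. For the canonical macroion
($\sigma \approx 0.19$ C/m²) monovalent counterions in water sit at
$\Gamma \approx 0.8$ (weak coupling), while trivalent ions in
$\varepsilon_r = 20$ reach $\Gamma \approx 16$.

The amount of added salt is expressed by the salt ratio
$\beta = Z_c \rho_c / |Z_M \rho_M|$ — total added cation charge over
macroion charge. $\beta = 1$ is stoichiometric neutralisation by the salt
cations alone; $\beta > 1$ is the overcharging regime.

## Sampling

`run_simulation()` performs canonical (NVT) Metropolis Monte Carlo with
single-particle translations. A trial move displaces one uniformly chosen
ion inside a cube of half-width `max_displacement`; trials that overlap
any hard sphere or push the ion's surface outside the cell
($|r| > R_{cell} - R_i$; the whole ion must stay inside) are rejected
outright, all others are accepted with probability
$\min(1, e^{-\Delta U / k_B T})$. $\Delta U$ is computed from the moved
ion's pair terms only — an $O(N)$ update — and the running total is
audited against a full $O(N^2)$ recomputation every $10^5$ moves; the run
aborts if the bookkeeping drifts by more than $10^{-6}\,k_B T$ per audit
window (observed drift is orders of magnitude below this).

Choices that matter:

* **Step size.** Default `max_displacement` 10 Å. With
  `adapt_displacement = TRUE` (default) the step is tuned during
  equilibration toward a 40–60% acceptance rate and then frozen, so
  detailed balance holds exactly throughout production.
* **Schedule.** Move counts are quoted per particle. The `"desk"` preset
  runs $2 \times 10^4$ moves/particle; the `"paper"` preset
  $10^6$. Equilibration defaults to 10% of production and is discarded.
* **Sampling.** A configuration is stored every `sample_interval`
  (default 100) moves per particle, balancing decorrelation against
  storage.
* **Reproducibility.** The engine uses its own xoshiro256++ generator
  seeded from the schedule seed; a trajectory is bit-identical given
  (system, schedule, seed) and independent of R's RNG state.
* **Initial state.** Ions are placed uniformly at random in their
  accessible shell by rejection sampling, also deterministically from the
  seed.

## Observables

All radial profiles are measured from the macroion centre on
$[R_M, R_{cell}]$ with bin width 0.5 Å by default.

* **Radial distribution function** $g_{MI}(r)$: distance histogram
  normalised by the exact spherical-shell volume of each bin and by the
  species' mean density over its *accessible* shell
  $[R_M + R_I, R_{cell} - R_I]$, so an ideal (uncharged) system gives
  exactly 1. The literature sometimes normalises by the whole-cell
  density instead; that convention rescales $g$ by a constant
  ($\approx 1.07$ for the canonical geometry) and is why absolute contact
  values (e.g. peak heights quoted as 505 or 120) are only compared as
  ratios and orderings, never absolutely.
* **Accumulated running charge** $Z_{acc}(r)$: the macroion valence plus
  the mean net ionic charge within $r$, computed by direct counting at
  bin edges (where counting is exact). It equals $Z_M$ at contact and 0
  at the cell boundary. An equivalent quadrature route through the binned
  RDFs (`accumulated_charge_from_rdf()`, using exact shell volumes) is
  retained as a cross-check; the two agree to machine precision on shared
  samples.
* **Mean electrostatic potential**
  $\varphi(r) = \frac{k_B T}{e} l_B \int_r^{r_c} Z_{acc}(r')/r'^2\,dr'$,
  integrated by the trapezoidal rule on the binned profile. The upper
  cutoff $r_c$ (default 60 Å) sets the potential zero. Repeated
  abscissae integrate as exact jumps, so step-function test profiles are
  integrated exactly.
* **Scalars** (`summarize()`): surface potential
  $\varphi_s = \varphi(R_M)$; zeta potential
  $\xi = \varphi(R_M + 2R_I)$ at the slipping plane one ionic diameter
  from the macroion surface (24 Å canonically); effective charge
  $Z_M^{eff} = Z_{acc}(R_M + 3R_I)$, the accumulated charge one ionic
  diameter beyond the *contact separation* $R_M + R_I$ (26 Å
  canonically); reduced energy $U / N k_B T$, where $N$ is by default
  the number of mobile ions ("number of ionic species" is ambiguous in
  parts of the literature, so `energy_norm` also offers normalisation by
  the salt-independent counterion count — the convention under which the
  reduced energy decreases monotonically with salt content, since added
  neutral salt increases the particle count faster than it deepens the
  energy — or by every particle including the macroion); the contact
  value of the counterion RDF; and the maximum of $Z_{acc}$ between the
  slipping plane and the cutoff — positive when the macroion is
  charge-inverted. The extremum search deliberately stops at the cutoff:
  near the cell wall the profile shows a separate neutral build-up of
  expelled cations that is not part of the inversion peak.

The two planes deserve a remark, because the slipping plane and the
effective-charge plane are *not* the same here. With the canonical
geometry, $\xi$ evaluated at 24 Å reproduces the known salt-free water
value ($\approx -110$ mV), while the effective-charge fractions commonly
quoted for this system (0.54 of $Z_M$ in water, 0.07 at
$\varepsilon_r = 20$) are reproduced at 26 Å — one ionic diameter beyond
contact — and not at 24 Å (which gives 0.67/0.12). Both planes are
configurable (`zeta_plane`, `charge_plane`).

Standard errors for every scalar come from block averaging over 20
contiguous blocks of samples (blocking absorbs sample-to-sample
correlation; at least 10 blocks are required or `summarize()` refuses).

## Synthetic data and what the tests show

The package analyses no external data: its inputs are parameter sets, and
the fixtures module generates everything the tests need.

* **Energy fixtures** place up to four ions at exact collinear or
  axis-aligned positions; expected energies are assembled term by term
  from raw constants, independently of the package's energy code.
* **Profile fixtures** place ions at known radii (never on a default bin
  edge); expected charge profiles are hand-counted step functions and
  expected potentials their exact piecewise $1/r$ integrals.
* **A two-ion quadrature oracle** (a weakly charged macroion with two
  counterions) provides an exact canonical average via 3-d numerical
  integration, against which the sampler is checked end to end.
* **Reduced reference runs** pin the qualitative regimes (weak coupling,
  strong coupling, charge inversion) at desk scale.

These fixtures exercise the full code path on configurations whose answers
are known exactly. What they do not show is agreement with any *real*
electrolyte: the primitive model itself neglects solvent structure,
dielectric inhomogeneity (image charges at the macroion surface), ion
polarisability and specific-ion chemistry, so the package's outputs are
statements about the model, not about a particular experimental system.

## Numerical choices and degenerate inputs

* Trapezoidal quadrature on 0.5 Å bins discretises $\varphi$ to well
  under 1 mV for canonical profiles; fixture tests run the same code on
  fine grids where the error bound is $10^{-6}$ relative.
* Overlapping configurations carry an explicit `Inf` sentinel energy and
  an `overlap_flag`; the sampler can never store one (trials are
  rejected before any energy arithmetic).
* Zero-ion systems are legal throughout (profiles reduce to the bare
  macroion forms); single-sample "trajectories" yield profiles with `NA`
  standard errors rather than fabricated ones.
* `salt_composition()` refuses a $\beta$ that does not give an integer
  cation count (tolerance $10^{-6}$), which catches mis-specified sweep
  grids before any simulation time is spent.
* Dielectric constants for "water" differ across sources (78 vs 78.4);
  both are accepted and produce Bjerrum lengths within 0.04 Å of each
  other. Defaults use whichever the calling context specifies.

## Problem sizes and convergence

The canonical salt-free system (60 counterions) decorrelates quickly:
$10^5$ moves/particle reproduces the converged ($10^6$ moves/particle)
zeta potential and effective charge to well within one standard error, in
seconds of CPU time. The $\beta = 6.25$ salt systems (510–560 ions) are
much harder at low $\varepsilon_r$: trivalent contact pairs are bound by
tens of $k_B T$ and the adsorbed layer orders slowly under single-particle
moves, so the energy plateaus long before the inversion peak height
stops growing. The package's acceptance script runs the
$\varepsilon_r = 78$ salt systems at $3 \times 10^4$ moves/particle
(fully converged: the inversion maximum changes by < 5% when the schedule
is tripled) and the $\varepsilon_r = 20$ system at $6 \times 10^4$
moves/particle with $4 \times 10^4$ of equilibration. At
$\varepsilon_r = 20$ the inversion maximum still rises with schedule
length (two independent protocols at twice this length agree near +26 e
but have not plateaued), so the reported value should be read as a lower
bound — a known limitation of local-move Metropolis sampling in the
strong-coupling regime, which cluster or swap moves (out of scope here)
would address.

## Known limitations

* Closed-cell geometry: results at fixed $\beta$ depend (weakly) on the
  cell radius; there is no extrapolation to infinite dilution.
* No dielectric discontinuity at the macroion surface; the solvent
  dielectric constant fills all space.
* Single-particle translations only; no cluster, swap or grand-canonical
  moves, so low-$\varepsilon_r$, high-valence systems converge slowly
  (see above).
* The potential cutoff convention ($\varphi(r_c) = 0$ at $r_c = 60$ Å)
  matters in salt-free systems, where the accumulated charge reaches zero
  only at the cell boundary; `summarize()` exposes the cutoff so its
  sensitivity can be reported alongside $\xi$.
* In salt-free systems $|\xi|$ is *not* strictly monotone in
  $\varepsilon_r$ at the high-polarity end: lowering $\varepsilon_r$
  simultaneously scales up the Coulomb prefactor and deepens counterion
  condensation, and near water-like polarity the two effects cancel
  almost exactly, leaving $\xi$ flat (within ~1 mV) between
  $\varepsilon_r = 54$ and 78 before $|\xi|$ collapses at strong
  coupling.
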