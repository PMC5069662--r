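## Equilibrium binding chemistry, electrostatic surface partition and
## channel hydrodynamics shared by the forward simulator and the
## inverse analyses.

#' Channel geometry and buffer description
#'
#' The microfluidic cell: a parallel-plate channel of height `2L` (the
#' electrode sits at x = 0, the channel centre at x = L), width `w`, a
#' planar sensing electrode of area `A`, filled with an aqueous buffer.
#'
#' @param half_height_m half channel height L, m. Default 15e-6 (30 um
#'   channel).
#' @param width_m channel width, m. Default 0.5e-3, calibrated so that a
#'   30 uL/min flow produces a 6.67 Pa wall shear in a 30 um channel.
#' @param electrode_area_m2 sensing electrode area, m^2. Default 1e-6
#'   (1 x 1 mm^2).
#' @param viscosity_pa_s buffer dynamic viscosity, Pa s. Default 1.0e-3
#'   (water at room temperature).
#' @param temperature_k absolute temperature, K. Default 298.
#' @param zeta_potential_v zeta potential of the electrode/liquid
#'   interface, V. Default -0.01.
#' @param ionic_strength_mol_m3 buffer ionic strength, mol/m^3 (5 mM
#'   Tris-HCl ~ 5 mol/m^3). Default 5.
#' @param relative_permittivity buffer relative permittivity. Default 78.5.
#' @return An object of class `channel_geometry` (named list).
#' @export
channel_geometry <- function(half_height_m = 15e-6,
                             width_m = 0.5e-3,
                             electrode_area_m2 = 1e-6,
                             viscosity_pa_s = 1.0e-3,
                             temperature_k = 298,
                             zeta_potential_v = -0.01,
                             ionic_strength_mol_m3 = 5,
                             relative_permittivity = 78.5) {
  g <- list(L = half_height_m, w = width_m, A = electrode_area_m2,
            mu = viscosity_pa_s, T = temperature_k, zeta = zeta_potential_v,
            ionic_strength = ionic_strength_mol_m3,
            eps_r = relative_permittivity)
  for (f in c("L", "w", "A", "mu", "T", "eps_r"))
    if (!is.numeric(g[[f]]) || g[[f]] <= 0)
      stop("channel_geometry: '", f, "' must be strictly positive")
  structure(g, class = "channel_geometry")
}

#' Equilibrium concentrations for first-order binding
#'
#' For Ligand + Protein <-> Complex with dissociation constant
#' `K_D = n_P n_L / n_C`, starting from initial protein `x` and ligand
#' `y`, mass balance gives the quadratic
#' `n_C^2 - (x + y + K_D) n_C + x y = 0`. The physically admissible
#' root is the smaller one (the larger exceeds `min(x, y)`), computed
#' in the Citardauq form `2xy / (b + sqrt(b^2 - 4xy))` to avoid
#' cancellation when `K_D << x, y`.
#'
#' All concentrations share one unit (use mol/m^3 internally); the
#' result is unit-consistent with the inputs. Inputs are recycled.
#'
#' @param x initial (total) protein concentration, >= 0.
#' @param y initial (total) ligand concentration, >= 0.
#' @param K_D dissociation constant, > 0, same unit as `x`, `y`.
#' @return A list of class `equilibrium_state` with fields `n_P`, `n_L`,
#'   `n_C` (free protein, free ligand, complex).
#' @examples
#' eq <- equilibrium_complex(0.1, 0.2, 34.7e-3) # 100 uM, 200 uM, 34.7 uM
#' with(eq, n_P * n_L / n_C)                    # recovers K_D
#' @export
equilibrium_complex <- function(x, y, K_D) {
  if (any(x < 0) || any(y < 0)) stop("initial concentrations must be >= 0")
  if (any(K_D <= 0)) stop("K_D must be > 0")
  b <- x + y + K_D
  # disc = (x - y)^2 + 2 K (x + y) + K^2: assembled in that form so it
  # never suffers the b^2 - 4xy cancellation
  disc <- (x - y)^2 + 2 * K_D * (x + y) + K_D^2
  if (any(disc < 0))
    stop("negative discriminant: impossible for real inputs (internal bug)")
  s <- sqrt(disc)
  n_C <- 2 * x * y / (b + s)
  # the minority free species is a difference of nearly equal numbers
  # when binding is nearly complete; its conjugate (rationalised) form
  # x - n_C = 4 K x y / ((b + s)(s - (x - y + K))) is exact and stable
  d <- x - y + K_D
  e <- y - x + K_D
  n_P <- ifelse(d <= 0, 4 * K_D * x * y / ((b + s) * (s - d)), x - n_C)
  n_L <- ifelse(e <= 0, 4 * K_D * x * y / ((b + s) * (s - e)), y - n_C)
  structure(list(n_P = pmax(n_P, 0), n_L = pmax(n_L, 0),
                 n_C = pmin(n_C, pmin(x, y))),
            class = "equilibrium_state")
}

#' Boltzmann partition factor at the electrode surface
#'
#' A molecule of net charge `Ze` (in units of the elementary charge)
#' near the electrode sees the interfacial potential, approximately the
#' zeta potential; its equilibrium concentration just outside the Debye
#' layer is the bulk concentration times
#' `gamma = exp(-Ze e zeta / (kB T))`. `gamma` is treated as a constant
#' per species and buffer.
#'
#' @param Ze net charge in multiples of the elementary charge (signed).
#' @param zeta zeta potential, V.
#' @param temperature_k absolute temperature, K.
#' @return gamma, dimensionless and strictly positive.
#' @examples
#' boltzmann_partition(0, -0.01)  # neutral species: 1
#' @export
boltzmann_partition <- function(Ze, zeta, temperature_k = 298) {
  if (any(temperature_k <= 0)) stop("temperature must be > 0")
  exp(-Ze * times_constants$e * zeta /
        (times_constants$kB * temperature_k))
}

#' Wall shear stress in a parallel-plate channel
#'
#' Plane Poiseuille flow at volumetric rate `Q` through a channel of
#' height `h = 2L` and width `w` exerts a wall shear
#' `tau_w = 6 mu Q / (w h^2)`, linear in `Q`.
#'
#' @param Q_m3_s volumetric flow rate, m^3/s (30 uL/min = 5e-10 m^3/s).
#' @param geometry a [channel_geometry()].
#' @return wall shear stress, Pa.
#' @examples
#' g <- channel_geometry()
#' wall_shear_stress(5e-10, g) # 30 uL/min -> ~6.67 Pa
#' @export
wall_shear_stress <- function(Q_m3_s, geometry = channel_geometry()) {
  if (any(Q_m3_s < 0)) stop("flow rate must be >= 0")
  h <- 2 * geometry$L
  6 * geometry$mu * Q_m3_s / (geometry$w * h^2)
}

#' Convert a flow rate in uL/min to m^3/s
#' @param Q_ul_min flow rate, uL/min.
#' @return flow rate, m^3/s.
#' @export
flow_ul_min_to_si <- function(Q_ul_min) Q_ul_min * 1e-9 / 60

#' Debye screening length of a symmetric 1:1 electrolyte
#'
#' `lambda_D = sqrt(eps_r eps0 kB T / (2 e^2 NA I))` with ionic strength
#' `I` in mol/m^3. Order 1 nm for typical buffers.
#'
#' @param ionic_strength_mol_m3 ionic strength, mol/m^3.
#' @param temperature_k absolute temperature, K.
#' @param relative_permittivity relative permittivity of the solvent.
#' @return Debye length, m.
#' @examples
#' debye_length(100) # 100 mM electrolyte: ~0.96 nm
#' @export
debye_length <- function(ionic_strength_mol_m3, temperature_k = 298,
                         relative_permittivity = 78.5) {
  if (any(ionic_strength_mol_m3 <= 0)) stop("ionic strength must be > 0")
  cc <- times_constants
  sqrt(relative_permittivity * cc$eps0 * cc$kB * temperature_k /
         (2 * cc$e^2 * cc$N_A * ionic_strength_mol_m3))
}
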