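## Per-species physical descriptions: diffusivity, charge, surface
## partition, induced-charge kernel and Langmuir kinetics.

#' Per-molecule induced-charge kernel template
#'
#' The single-molecule impulse response q(t): the charge induced on the
#' electrode by one molecule arriving at the surface. Measured traces
#' are biphasic -- a fast dip as the dipole aligns with the interfacial
#' field, then a slower overshoot as the departing molecule drags its
#' counter-ions away -- so the template is a difference of two
#' gamma-shaped pulses plus a saturating plateau
#' `q(t) = -A_dip h(u/tau_dip) + A_over h(u/tau_over) + A_inf (1 - exp(-u/tau_over))`
#' with `u = t - t0` and `h(u) = u exp(1 - u)` (unit peak at u = 1,
#' h(0) = 0). It satisfies q(0) = 0 and tends to the finite plateau
#' `A_inf`: the persistent image charge induced while the molecule
#' stays adsorbed (this is what makes the measured current track the
#' adsorption/desorption transient at long times). The polarity flag
#' flips the sign convention.
#'
#' @param dip_amplitude_c dip amplitude, C (> 0; enters negatively).
#' @param dip_tau_s dip time constant, s.
#' @param overshoot_amplitude_c overshoot amplitude, C (>= 0).
#' @param overshoot_tau_s overshoot time constant, s.
#' @param plateau_amplitude_c persistent induced charge A_inf, C
#'   (signed; 0 gives a purely transient kernel).
#' @param onset_delay_s onset delay t0, s (default 0: delays are short
#'   compared with the 1 ms timing resolution).
#' @param polarity +1 (default, dip-first negative lobe) or -1.
#' @return Object of class `charge_kernel`.
#' @export
charge_kernel <- function(dip_amplitude_c, dip_tau_s,
                          overshoot_amplitude_c = 0,
                          overshoot_tau_s = dip_tau_s * 4,
                          plateau_amplitude_c = 0,
                          onset_delay_s = 0, polarity = 1) {
  stopifnot(dip_amplitude_c >= 0, overshoot_amplitude_c >= 0,
            dip_tau_s > 0, overshoot_tau_s > 0, onset_delay_s >= 0,
            polarity %in% c(-1, 1))
  structure(list(a_dip = dip_amplitude_c, tau_dip = dip_tau_s,
                 a_over = overshoot_amplitude_c, tau_over = overshoot_tau_s,
                 a_inf = plateau_amplitude_c,
                 t0 = onset_delay_s, polarity = polarity),
            class = "charge_kernel")
}

gamma_pulse <- function(u) ifelse(u >= 0, u * exp(1 - u), 0)
gamma_pulse_deriv <- function(u) ifelse(u >= 0, (1 - u) * exp(1 - u), 0)

#' Evaluate a charge kernel q(t)
#' @param kernel a [charge_kernel()].
#' @param t times, s.
#' @return q(t), C.
#' @export
kernel_charge <- function(kernel, t) {
  u <- t - kernel$t0
  kernel$polarity *
    (-kernel$a_dip * gamma_pulse(u / kernel$tau_dip) +
       kernel$a_over * gamma_pulse(u / kernel$tau_over) +
       kernel$a_inf * ifelse(u >= 0, 1 - exp(-u / kernel$tau_over), 0))
}

#' Evaluate the time derivative dq/dt of a charge kernel
#' @inheritParams kernel_charge
#' @return dq/dt, C/s (analytic derivative of the template).
#' @export
kernel_charge_deriv <- function(kernel, t) {
  u <- t - kernel$t0
  kernel$polarity *
    (-kernel$a_dip / kernel$tau_dip * gamma_pulse_deriv(u / kernel$tau_dip) +
       kernel$a_over / kernel$tau_over * gamma_pulse_deriv(u / kernel$tau_over) +
       kernel$a_inf / kernel$tau_over * ifelse(u >= 0, exp(-u / kernel$tau_over), 0))
}

#' Langmuir surface kinetics parameters
#'
#' Adsorption to and desorption from the electrode. `K_plus` has units
#' of velocity (m/s): the adsorption flux onto empty sites is
#' `K_plus * gamma * n(0, t) * (1 - theta)` with `n` a number density
#' (1/m^3). `K_minus` has units of flux (1/(m^2 s)): the desorption
#' flux is `K_minus * theta`. `N_s` is the monolayer site density
#' (1/m^2) and `theta` the occupied fraction.
#'
#' @param K_plus_m_s adsorption rate constant, m/s, >= 0.
#' @param K_minus_per_m2_s desorption rate constant, 1/(m^2 s), >= 0.
#' @param N_s_per_m2 monolayer site density, 1/m^2, > 0.
#' @param theta0 initial coverage in [0, 1].
#' @return Object of class `surface_kinetics`.
#' @export
surface_kinetics <- function(K_plus_m_s, K_minus_per_m2_s, N_s_per_m2,
                             theta0 = 0) {
  stopifnot(K_plus_m_s >= 0, K_minus_per_m2_s >= 0, N_s_per_m2 > 0,
            theta0 >= 0, theta0 <= 1)
  structure(list(K_plus = K_plus_m_s, K_minus = K_minus_per_m2_s,
                 N_s = N_s_per_m2, theta0 = theta0),
            class = "surface_kinetics")
}

#' Physical description of one molecular species
#'
#' Bundles everything the forward model needs for a protein, ligand or
#' complex: diffusivity, net charge (hence the Boltzmann surface
#' partition), the induced-charge kernel and the Langmuir kinetics.
#'
#' @param name species label.
#' @param diffusivity_m2_s diffusivity D, m^2/s, > 0.
#' @param effective_charge net charge Ze in multiples of e (signed
#'   integer-valued; need not be an integer).
#' @param kernel a [charge_kernel()].
#' @param kinetics a [surface_kinetics()].
#' @param partition_gamma optional fixed partition factor; if `NULL`
#'   (default) it is computed from `effective_charge` and the geometry's
#'   zeta potential at run time.
#' @return Object of class `species_params`.
#' @export
species_params <- function(name, diffusivity_m2_s, effective_charge,
                           kernel, kinetics, partition_gamma = NULL) {
  stopifnot(diffusivity_m2_s > 0, inherits(kernel, "charge_kernel"),
            inherits(kinetics, "surface_kinetics"))
  if (!is.null(partition_gamma) && partition_gamma <= 0)
    stop("partition_gamma must be > 0")
  structure(list(name = name, D = diffusivity_m2_s, Ze = effective_charge,
                 kernel = kernel, kinetics = kinetics,
                 gamma = partition_gamma),
            class = "species_params")
}

#' Resolve a species' partition factor against a geometry
#' @param species a [species_params()].
#' @param geometry a [channel_geometry()].
#' @return gamma, dimensionless.
#' @export
species_gamma <- function(species, geometry) {
  if (!is.null(species$gamma)) return(species$gamma)
  boltzmann_partition(species$Ze, geometry$zeta, geometry$T)
}
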