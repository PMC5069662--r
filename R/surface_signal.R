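## Langmuir adsorption/desorption on the electrode and the forward map
## from molecular flux to induced current through the per-molecule
## charge kernel.

#' Monolayer coverage dynamics
#'
#' Integrates the Langmuir coverage ODE
#' `N_s dtheta/dt = K_plus gamma n(0,t) (1 - theta) - K_minus theta`
#' with `theta(0) = theta0`. For constant `n(0,t) = n_o` the closed
#' form is `theta(t) = theta_eq + (theta0 - theta_eq) exp(-t / tau)`
#' with `theta_eq = K+ g n_o / (K+ g n_o + K-)` and
#' `tau = N_s / (K+ g n_o + K-)` (see [coverage_closed_form()]).
#'
#' @param kinetics a [surface_kinetics()].
#' @param gamma Boltzmann partition factor of the species.
#' @param n_surface near-electrode number density n(0, t), 1/m^3:
#'   either a numeric vector on `t_grid` or a function of time.
#' @param t_grid times, s.
#' @param linearised if `TRUE`, drop the `(1 - theta)` saturation term
#'   (dilute regime; the superposition model used for mixtures).
#' @return theta(t) on `t_grid`, guaranteed within [0, 1].
#' @export
coverage_dynamics <- function(kinetics, gamma, n_surface, t_grid,
                              linearised = FALSE) {
  stopifnot(inherits(kinetics, "surface_kinetics"), gamma > 0)
  nfun <- if (is.function(n_surface)) n_surface else {
    stopifnot(length(n_surface) == length(t_grid))
    if (any(n_surface < 0)) stop("n_surface must be >= 0")
    stats::approxfun(t_grid, n_surface, rule = 2)
  }
  kp <- kinetics$K_plus * gamma
  km <- kinetics$K_minus
  Ns <- kinetics$N_s
  rhs <- if (linearised) {
    function(t, y, parms) list((kp * nfun(t) - km * y[1]) / Ns)
  } else {
    function(t, y, parms) list((kp * nfun(t) * (1 - y[1]) - km * y[1]) / Ns)
  }
  sol <- deSolve::lsoda(c(theta = kinetics$theta0), t_grid, rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  theta <- sol[, "theta"]
  if (!linearised && (any(theta < -1e-6) || any(theta > 1 + 1e-6)))
    stop("coverage_dynamics: theta left [0,1] beyond solver tolerance")
  pmin(pmax(theta, 0), if (linearised) Inf else 1)
}

#' Closed-form Langmuir coverage at constant bulk concentration
#'
#' @inheritParams coverage_dynamics
#' @param n_o constant near-electrode number density, 1/m^3.
#' @param t times, s.
#' @return theta(t).
#' @export
coverage_closed_form <- function(kinetics, gamma, n_o, t) {
  r_on <- kinetics$K_plus * gamma * n_o
  denom <- r_on + kinetics$K_minus
  stopifnot(denom > 0)
  theta_eq <- r_on / denom
  tau <- kinetics$N_s / denom
  theta_eq + (kinetics$theta0 - theta_eq) * exp(-t / tau)
}

#' Net molecular flux onto the electrode
#'
#' `J(t) = K+ gamma n(0,t) (1 - theta) - K- theta`, equal to
#' `N_s dtheta/dt`; units 1/(m^2 s) with number densities in.
#'
#' @inheritParams coverage_dynamics
#' @param theta coverage series matching `n_surface`.
#' @return J(t), 1/(m^2 s).
#' @export
net_flux <- function(kinetics, gamma, n_surface, theta,
                     linearised = FALSE) {
  sat <- if (linearised) 1 else (1 - theta)
  kinetics$K_plus * gamma * n_surface * sat - kinetics$K_minus * theta
}

#' Average surface dwell time
#'
#' The relaxation time of the adsorption transient,
#' `tau_s = N_s / (K+ gamma n_o + K-)`; in the desorption-dominated
#' (dilute) limit `tau_s -> N_s / K-`. This is the quantity that
#' decreases with wall shear stress when desorption is shear-activated.
#'
#' @inheritParams coverage_closed_form
#' @return tau_s, s.
#' @examples
#' k <- surface_kinetics(1, 5e16, 3e16)
#' dwell_time(k, 1, 5e16) # denominator 1e17 -> 0.3 s
#' @export
dwell_time <- function(kinetics, gamma, n_o) {
  denom <- kinetics$K_plus * gamma * n_o + kinetics$K_minus
  if (denom <= 0) stop("dwell_time undefined: K+ gamma n_o + K- must be > 0")
  kinetics$N_s / denom
}

#' Induced current from a molecular flux and a charge kernel
#'
#' The electrode charge is the convolution of the single-molecule
#' kernel with the arrival flux, `Q(t) = A int_0^t q(t - t') J(t') dt'`,
#' and the measured current is `i = dQ/dt`. Two equivalent numerical
#' paths are provided: `"deriv"` convolves the analytic kernel
#' derivative with the flux (`i = A (dq/dt * J)`, exact since
#' q(0) = 0), and `"charge"` forms Q by discrete convolution and
#' differentiates centrally. The two agree to discretisation error.
#'
#' @param kernel a [charge_kernel()].
#' @param J flux series on `t_grid`, 1/(m^2 s).
#' @param t_grid uniform time grid, s.
#' @param A electrode area, m^2.
#' @param method `"deriv"` (default) or `"charge"`.
#' @return current i(t), A, on `t_grid`.
#' @export
induced_current <- function(kernel, J, t_grid, A, method = c("deriv", "charge")) {
  method <- match.arg(method)
  stopifnot(length(J) == length(t_grid))
  dt <- t_grid[2] - t_grid[1]
  if (method == "deriv") {
    qd <- kernel_charge_deriv(kernel, t_grid)
    A * conv_causal(qd, J, dt)
  } else {
    q <- kernel_charge(kernel, t_grid)
    Q <- A * conv_causal(q, J, dt)
    grad_uniform(Q, dt)
  }
}

#' Superposed mixture signal in the dilute (linear) regime
#'
#' In the regime where each species' contribution is linear in its
#' equilibrium concentration (coverage far from saturation, times
#' shorter than the adsorption time), the measured current is
#' `i(t) = n_P G_P(t) + n_L G_L(t) + n_C G_C(t)` where `G_s(t)` is the
#' per-unit-concentration response of species s and the equilibrium
#' concentrations follow from [equilibrium_complex()].
#'
#' @param G_P,G_L,G_C unit-concentration responses on a common grid,
#'   A per (mol/m^3).
#' @param x,y initial protein and ligand concentrations, mol/m^3.
#' @param K_D dissociation constant, mol/m^3.
#' @return current series i(t), A.
#' @export
mixture_signal <- function(G_P, G_L, G_C, x, y, K_D) {
  stopifnot(length(G_P) == length(G_L), length(G_L) == length(G_C))
  eq <- equilibrium_complex(x, y, K_D)
  eq$n_P * G_P + eq$n_L * G_L + eq$n_C * G_C
}

#' Per-unit-concentration species response G(t)
#'
#' The current produced by a species at unit bulk concentration
#' (1 mol/m^3) in the dilute linear regime: the near-electrode
#' concentration from the transport model (times the Boltzmann factor
#' gamma), the linearised coverage/flux transient, and convolution with
#' the kernel derivative. These G(t) absorb the non-identifiable
#' product of electrode area, gamma and kernel scale; mixtures are then
#' exactly linear in species concentrations (the superposition model).
#'
#' @param species a [species_params()].
#' @param geometry a [channel_geometry()].
#' @param t_grid uniform time grid, s.
#' @param initial `"prefilled"` (near-electrode concentration at bulk
#'   from t = 0) or `"empty"` (diffusion-front ramp).
#' @return G(t), A per (mol/m^3), on `t_grid`.
#' @export
unit_response <- function(species, geometry, t_grid,
                          initial = c("prefilled", "empty")) {
  initial <- match.arg(initial)
  g <- species_gamma(species, geometry)
  t_D <- diffusion_time(geometry$L, species$D)
  # number density at the surface for 1 mol/m^3 bulk
  n0 <- surface_concentration_quasisteady(times_constants$N_A, t_grid, t_D,
                                          initial = initial)
  kin <- species$kinetics
  if (initial == "prefilled") {
    # closed-form linearised transient: J = K+ g n0 exp(-K- t / N_s)
    J <- kin$K_plus * g * n0 * exp(-kin$K_minus * t_grid / kin$N_s)
  } else {
    theta <- coverage_dynamics(kin, g, n0, t_grid, linearised = TRUE)
    J <- net_flux(kin, g, n0, theta, linearised = TRUE)
  }
  induced_current(species$kernel, J, t_grid, geometry$A)
}
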