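## Seeded synthetic experiment generator: stands in for the instrument,
## producing noisy multi-condition current traces with the statistical
## structure the inverse analyses assume.

#' Default species parameter sets
#'
#' Physically plausible defaults for a ~35 kDa protein, a small-molecule
#' ligand and their complex: protein-scale diffusivities (1e-10 m^2/s),
#' small positive net charges, biphasic induced-charge kernels
#' (dip-then-overshoot), and Langmuir kinetics giving dilute-limit
#' dwell times N_s/K_minus of several hundred ms. The complex differs
#' from the protein in kernel shape, amplitude and polarity: binding is
#' taken to reorient and enhance the dipole signature, so the complex
#' dominates the mixture signal and the binding-difference response
#' G_C - G_P - G_L is well separated from the single-species responses.
#' Ligand kernels are small but nonzero (small dipole); pass
#' `silent_ligand = TRUE` to zero the ligand response.
#'
#' @param silent_ligand zero out the ligand kernel.
#' @return named list of [species_params()]: `protein`, `ligand`,
#'   `complex`.
#' @export
default_species <- function(silent_ligand = FALSE) {
  lig_scale <- if (silent_ligand) 0 else 1
  list(
    protein = species_params(
      "protein", diffusivity_m2_s = 1e-10, effective_charge = 2,
      kernel = charge_kernel(1.0e-19, 4e-3, 0.4e-19, 15e-3,
                             plateau_amplitude_c = 0.8e-19),
      kinetics = surface_kinetics(1e-6, 5e16, 3e16)),
    ligand = species_params(
      "ligand", diffusivity_m2_s = 5e-10, effective_charge = 0,
      kernel = charge_kernel(0.06e-19 * lig_scale, 2e-3,
                             0.03e-19 * lig_scale, 8e-3,
                             plateau_amplitude_c = 0.01e-19 * lig_scale),
      kinetics = surface_kinetics(2e-6, 3e17, 3e16)),
    complex = species_params(
      "complex", diffusivity_m2_s = 0.9e-10, effective_charge = 1,
      kernel = charge_kernel(2.4e-18, 10e-3, 1.9e-18, 30e-3,
                             plateau_amplitude_c = 0.85e-18,
                             polarity = -1),
      kinetics = surface_kinetics(3e-6, 3e16, 3e16))
  )
}

#' Scenario configuration for the synthetic generator
#'
#' Everything needed to emulate one bench experiment: the binding pair
#' and its ground-truth dissociation constant, the concentration design
#' (which must include the protein-only and ligand-only conditions),
#' flow rate, geometry, acquisition parameters and the noise model
#' (white Gaussian current noise at a signal-to-noise ratio defined
#' against the peak of the protein-only trace).
#'
#' @param name scenario label.
#' @param species list with `protein`, `ligand`, `complex`
#'   ([species_params()]); defaults to [default_species()].
#' @param K_D ground-truth dissociation constant (mol/m^3 or a string
#'   like `"34.7 uM"`).
#' @param design list of `c(x, y)` pairs (mol/m^3 or strings); must
#'   include one `y = 0` and one `x = 0` condition.
#' @param flow_ul_min flow rate applied to all conditions, uL/min.
#' @param geometry a [channel_geometry()].
#' @param sampling_rate_hz acquisition rate, Hz.
#' @param duration_s record length, s.
#' @param snr_db signal-to-noise ratio in dB relative to the peak
#'   protein-only current (`Inf` = noiseless); ignored when
#'   `noise_sd_a` is given.
#' @param noise_sd_a absolute current noise sd, A (overrides `snr_db`).
#' @param initial transport initial condition, `"prefilled"` or
#'   `"empty"` (see [surface_concentration_quasisteady()]).
#' @param seed default RNG seed used when none is passed to
#'   [generate_experiment_set()].
#' @return Object of class `times_scenario`.
#' @export
times_scenario <- function(name, K_D, design,
                           species = default_species(),
                           flow_ul_min = 30,
                           geometry = channel_geometry(),
                           sampling_rate_hz = 1000, duration_s = 1,
                           snr_db = 20, noise_sd_a = NULL,
                           initial = "prefilled", seed = 1L) {
  stopifnot(sampling_rate_hz > 0, duration_s > 0)
  K_D <- concentration_si(K_D)
  stopifnot(K_D > 0)
  design <- lapply(design, function(d) {
    d <- concentration_si(d)
    stopifnot(length(d) == 2, all(d >= 0)); d
  })
  xs <- vapply(design, `[`, numeric(1), 1)
  ys <- vapply(design, `[`, numeric(1), 2)
  if (sum(xs > 0 & ys == 0) != 1 || sum(xs == 0 & ys > 0) != 1)
    stop("design must include exactly one protein-only and one ligand-only condition")
  for (s in c("protein", "ligand", "complex"))
    stopifnot(inherits(species[[s]], "species_params"))
  structure(list(name = name, species = species, K_D = K_D,
                 design = design, flow_ul_min = flow_ul_min,
                 geometry = geometry, sampling_rate = sampling_rate_hz,
                 duration = duration_s, snr_db = snr_db,
                 noise_sd_a = noise_sd_a, initial = initial, seed = seed),
            class = "times_scenario")
}

#' @export
print.times_scenario <- function(x, ...) {
  cat(sprintf("<times_scenario '%s': K_D = %s, %d conditions, %g Hz x %g s, SNR %g dB>\n",
              x$name, format_conc(x$K_D), length(x$design),
              x$sampling_rate, x$duration, x$snr_db))
  invisible(x)
}

scenario_time_grid <- function(scenario)
  seq(0, scenario$duration - 1 / scenario$sampling_rate,
      by = 1 / scenario$sampling_rate)

#' Generate a synthetic experiment set from a scenario
#'
#' For each condition of the design: species equilibrium concentrations
#' at the ground-truth K_D, per-unit-concentration responses G(t) from
#' the transport + surface-kinetics + kernel forward chain
#' ([unit_response()]), superposition of the three species
#' contributions, and additive white Gaussian noise at the configured
#' SNR. Deterministic given the seed.
#'
#' @param scenario a [times_scenario()].
#' @param seed RNG seed; defaults to the scenario's.
#' @param keep_noiseless attach the noiseless traces in the metadata.
#' @return A [times_experiment()]; its `metadata` records the scenario
#'   name, seed, ground truth and noise sd.
#' @export
generate_experiment_set <- function(scenario, seed = scenario$seed,
                                    keep_noiseless = FALSE) {
  stopifnot(inherits(scenario, "times_scenario"))
  t <- scenario_time_grid(scenario)
  G <- lapply(scenario$species[c("protein", "ligand", "complex")],
              unit_response, geometry = scenario$geometry, t_grid = t,
              initial = scenario$initial)
  clean <- lapply(scenario$design, function(d)
    mixture_signal(G$protein, G$ligand, G$complex, d[1], d[2], scenario$K_D))
  xs <- vapply(scenario$design, `[`, numeric(1), 1)
  ys <- vapply(scenario$design, `[`, numeric(1), 2)
  ref <- which(xs > 0 & ys == 0)[1]
  sd_a <- if (!is.null(scenario$noise_sd_a)) scenario$noise_sd_a
          else if (is.infinite(scenario$snr_db)) 0
          else max(abs(clean[[ref]])) * 10^(-scenario$snr_db / 20)

  set.seed(seed)
  conds <- lapply(seq_along(scenario$design), function(j) {
    noisy <- clean[[j]] + if (sd_a > 0) stats::rnorm(length(t), 0, sd_a) else 0
    md <- list(x_mol_m3 = xs[j], y_mol_m3 = ys[j],
               flow_ul_min = scenario$flow_ul_min, seed = seed,
               scenario = scenario$name, noise_sd_a = sd_a)
    if (keep_noiseless) md$noiseless <- clean[[j]]
    list(x = xs[j], y = ys[j], flow_ul_min = scenario$flow_ul_min,
         name = sprintf("x=%.4g y=%.4g", xs[j], ys[j]),
         trace = signal_trace(t, noisy, md))
  })
  times_experiment(conds, geometry = scenario$geometry,
                   metadata = list(scenario = scenario$name, seed = seed,
                                   K_D_truth = scenario$K_D,
                                   noise_sd_a = sd_a))
}

#' Shear sweep: traces of one species across flow rates
#'
#' Emulates the shear-stress dependence of the surface dwell time:
#' desorption is shear-activated through a Bell model,
#' `K_minus(tau_w) = K_minus0 exp(tau_w / tau0_pa)`, so higher flow
#' (larger wall shear) shortens the dwell time. One protein-only trace
#' is generated per flow rate, with the wall shear stress recorded in
#' the metadata. The Bell coupling is a conventional emulation device,
#' not a measured mechanism.
#'
#' @param scenario a [times_scenario()]; its protein species and first
#'   protein-only design condition are used.
#' @param flow_ul_min vector of flow rates, uL/min.
#' @param bell_tau0_pa Bell stress scale tau0, Pa, default 40 (`Inf` decouples
#'   desorption from shear).
#' @param species which species to sweep (`"protein"` or `"complex"`).
#' @param seed RNG seed.
#' @return list with one element per flow rate: `trace`
#'   ([signal_trace()]), `tau_w_pa`, `tau_s_true` (dilute-limit
#'   dwell time N_s/K_minus at that shear), `flow_ul_min`.
#' @export
shear_sweep <- function(scenario, flow_ul_min = c(30, 60, 120, 240, 350, 450),
                        bell_tau0_pa = 40, species = "protein",
                        seed = scenario$seed) {
  stopifnot(all(flow_ul_min > 0))
  sp <- scenario$species[[species]]
  xs <- vapply(scenario$design, `[`, numeric(1), 1)
  ys <- vapply(scenario$design, `[`, numeric(1), 2)
  conc <- xs[which(xs > 0 & ys == 0)[1]]
  t <- scenario_time_grid(scenario)
  set.seed(seed)
  lapply(flow_ul_min, function(Q) {
    tau_w <- wall_shear_stress(flow_ul_min_to_si(Q), scenario$geometry)
    kin <- sp$kinetics
    kin$K_minus <- kin$K_minus * exp(tau_w / bell_tau0_pa)
    sp_mod <- sp; sp_mod$kinetics <- kin
    G <- unit_response(sp_mod, scenario$geometry, t,
                       initial = scenario$initial)
    clean <- conc * G
    sd_a <- if (is.infinite(scenario$snr_db)) 0
            else max(abs(clean)) * 10^(-scenario$snr_db / 20)
    tr <- signal_trace(t, clean + if (sd_a > 0)
      stats::rnorm(length(t), 0, sd_a) else 0,
      list(flow_ul_min = Q, tau_w_pa = tau_w, species = species,
           x_mol_m3 = conc, noise_sd_a = sd_a))
    list(trace = tr, tau_w_pa = tau_w, flow_ul_min = Q,
         tau_s_true = kin$N_s / kin$K_minus)
  })
}

#' Reference scenario presets
#'
#' Named presets mirroring the two demonstration binding pairs and the
#' shear sweep:
#' \describe{
#'   \item{trypsin_paba}{100 uM trypsin with 0/50/100/200 uM
#'     p-aminobenzamidine (plus a 200 uM ligand-only condition);
#'     ground-truth K_D 34.7 uM (the single-run histogram mode).}
#'   \item{thermolysin_phosphoramidon}{300 nM thermolysin with
#'     0/150/300/600 nM phosphoramidon (plus a 600 nM ligand-only
#'     condition); ground-truth K_D 32.1 nM (the replicate average).}
#'   \item{shear_sweep}{the trypsin-like species swept over
#'     30-450 uL/min.}
#' }
#' All presets acquire at 1 kHz for 1 s at SNR 20 dB.
#'
#' @return named list of [times_scenario()] objects.
#' @export
reference_scenarios <- function() {
  list(
    trypsin_paba = times_scenario(
      "trypsin_paba", K_D = "34.7 uM",
      design = list(c("100 uM", "0 uM"), c("0 uM", "200 uM"),
                    c("100 uM", "50 uM"), c("100 uM", "200 uM"),
                    c("100 uM", "100 uM")),
      snr_db = 20, seed = 7L),
    thermolysin_phosphoramidon = times_scenario(
      "thermolysin_phosphoramidon", K_D = "32.1 nM",
      design = list(c("300 nM", "0 nM"), c("0 nM", "600 nM"),
                    c("300 nM", "150 nM"), c("300 nM", "600 nM"),
                    c("300 nM", "300 nM")),
      snr_db = 20, seed = 7L),
    shear_sweep = times_scenario(
      "shear_sweep", K_D = "34.7 uM",
      design = list(c("100 uM", "0 uM"), c("0 uM", "200 uM"),
                    c("100 uM", "100 uM")),
      snr_db = 25, seed = 7L)
  )
}

#' Simulate method for scenarios
#'
#' `simulate()` on a [times_scenario()] returns a list of `nsim`
#' independent synthetic experiment sets with seeds derived from
#' `seed`.
#'
#' @param object a [times_scenario()].
#' @param nsim number of replicate experiment sets.
#' @param seed base seed; replicate j uses `seed + j - 1`.
#' @param ... unused.
#' @return list of [times_experiment()] objects.
#' @export
simulate.times_scenario <- function(object, nsim = 1, seed = object$seed, ...) {
  lapply(seq_len(nsim) - 1L, function(j)
    generate_experiment_set(object, seed = seed + j))
}
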