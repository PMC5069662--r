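# Shared fixtures: small, fast scenarios built in code.

# a short-record scenario for unit tests (0.3 s @ 500 Hz keeps the
# per-timepoint solve cheap); design mirrors the trypsin-like layout
quick_scenario <- function(K_D = "34.7 uM", snr_db = Inf, seed = 1L,
                           duration_s = 0.3, sampling_rate_hz = 500) {
  times_scenario(
    "quick", K_D = K_D,
    design = list(c("100 uM", "0 uM"), c("0 uM", "200 uM"),
                  c("100 uM", "50 uM"), c("100 uM", "200 uM"),
                  c("100 uM", "100 uM")),
    sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
    snr_db = snr_db, seed = seed)
}

# protein-only trace whose linearised dwell time N_s/K_minus is tau_s
tau_trace <- function(tau_s = 0.3, snr_db = 25, seed = 1L) {
  sp <- default_species()
  sp$protein$kinetics$K_minus <- sp$protein$kinetics$N_s / tau_s
  scen <- times_scenario("tau", K_D = "34.7 uM",
                         design = list(c("100 uM", "0 uM"),
                                       c("0 uM", "200 uM")),
                         species = sp, snr_db = snr_db, seed = seed)
  generate_experiment_set(scen, seed = seed)$conditions[[1]]$trace
}
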