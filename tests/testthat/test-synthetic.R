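test_that("generation is deterministic given the seed", {
  scen <- quick_scenario(snr_db = 20)
  e1 <- generate_experiment_set(scen, seed = 11)
  e2 <- generate_experiment_set(scen, seed = 11)
  for (j in seq_along(e1$conditions))
    expect_identical(e1$conditions[[j]]$trace$current,
                     e2$conditions[[j]]$trace$current)
  e3 <- generate_experiment_set(scen, seed = 12)
  expect_false(identical(e1$conditions[[1]]$trace$current,
                         e3$conditions[[1]]$trace$current))
})

test_that("noiseless generation equals the forward model; 1 kHz x 1 s gives 1000 samples", {
  scen <- reference_scenarios()$trypsin_paba
  scen$snr_db <- Inf
  e <- generate_experiment_set(scen, seed = 1, keep_noiseless = TRUE)
  expect_length(e$conditions[[1]]$trace$t, 1000)
  for (cd in e$conditions)
    expect_identical(cd$trace$current, cd$trace$metadata$noiseless)
})

test_that("empirical noise sd matches the configured level within 5%", {
  scen <- reference_scenarios()$trypsin_paba  # 1000 samples, SNR 20 dB
  e <- generate_experiment_set(scen, seed = 21, keep_noiseless = TRUE)
  tr <- e$conditions[[1]]$trace
  resid <- tr$current - tr$metadata$noiseless
  expect_equal(stats::sd(resid), e$metadata$noise_sd_a, tolerance = 0.05)
  # and the SNR definition: sd = peak protein-only current / 10^(SNR/20)
  peak <- max(abs(e$conditions[[1]]$trace$metadata$noiseless))
  expect_equal(e$metadata$noise_sd_a, peak * 10^(-20 / 20), tolerance = 1e-10)
})

test_that("generated sets satisfy the experiment invariants", {
  for (scen in reference_scenarios()) {
    e <- generate_experiment_set(scen, seed = 2)
    cls <- timesig:::classify_conditions(e)
    expect_length(cls$protein_only, 1)
    expect_length(cls$ligand_only, 1)
    t0 <- e$conditions[[1]]$trace$t
    for (cd in e$conditions) expect_equal(cd$trace$t, t0)
  }
})

test_that("reference presets carry the published designs and truths", {
  scens <- reference_scenarios()
  tp <- scens$trypsin_paba
  expect_equal(tp$K_D, concentration_si("34.7 uM"))
  ys <- sort(vapply(tp$design, `[`, numeric(1), 2))
  expect_equal(concentration_as(ys, "uM"), c(0, 50, 100, 200, 200))
  xs <- vapply(tp$design, `[`, numeric(1), 1)
  expect_true(all(xs[xs > 0] == concentration_si("100 uM")))

  th <- scens$thermolysin_phosphoramidon
  expect_equal(th$K_D, concentration_si("32.1 nM"))
  ys <- sort(vapply(th$design, `[`, numeric(1), 2))
  expect_equal(concentration_as(ys, "nM"), c(0, 150, 300, 600, 600))

  # at least two mixture conditions sit in the recommended
  # 0.1 K_D < x, y < 10 K_D sensitivity window
  for (scen in scens[1:2]) {
    xs <- vapply(scen$design, `[`, numeric(1), 1)
    ys <- vapply(scen$design, `[`, numeric(1), 2)
    mix <- xs > 0 & ys > 0
    inwin <- xs[mix] > 0.1 * scen$K_D & xs[mix] < 10 * scen$K_D &
      ys[mix] > 0.1 * scen$K_D & ys[mix] < 10 * scen$K_D
    expect_gte(sum(inwin), 2)
  }
  # acquisition defaults mirror the instrument protocol
  for (scen in scens) {
    expect_equal(scen$sampling_rate, 1000)
    expect_equal(scen$duration, 1)
  }
})

test_that("scenario validation rejects malformed designs", {
  expect_error(times_scenario("bad", K_D = "10 uM",
                              design = list(c("1 uM", "1 uM"))),
               "protein-only")
  expect_error(times_scenario("bad", K_D = 0,
                              design = list(c("1 uM", "0 uM"),
                                            c("0 uM", "1 uM"))))
})

test_that("shear sweep couples desorption to wall shear through the Bell model", {
  scen <- reference_scenarios()$shear_sweep
  flows <- c(30, 60, 120, 240, 350, 450)
  sw <- shear_sweep(scen, flows, bell_tau0_pa = 40, seed = 3)
  tau_w <- vapply(sw, `[[`, numeric(1), "tau_w_pa")
  expect_equal(tau_w[1], 6.67, tolerance = 2e-3)
  expect_equal(tau_w[6], 100, tolerance = 5e-3)
  # generated ground-truth dwell times strictly decrease with shear
  tau_true <- vapply(sw, `[[`, numeric(1), "tau_s_true")
  expect_true(all(diff(tau_true) < 0))
  # decoupled limit: tau0 -> Inf makes dwell time flow-independent
  sw0 <- shear_sweep(scen, flows, bell_tau0_pa = Inf, seed = 3)
  tau0 <- vapply(sw0, `[[`, numeric(1), "tau_s_true")
  expect_equal(max(tau0) - min(tau0), 0)
  # protein vs complex sweeps give distinct dwell-time curves
  swc <- shear_sweep(scen, flows, bell_tau0_pa = 40, species = "complex",
                     seed = 3)
  tau_c <- vapply(swc, `[[`, numeric(1), "tau_s_true")
  expect_true(all(tau_c != tau_true))
})

test_that("simulate() returns independent replicate sets", {
  scen <- quick_scenario(snr_db = 30)
  reps <- simulate(scen, nsim = 3, seed = 5)
  expect_length(reps, 3)
  expect_false(identical(reps[[1]]$conditions[[1]]$trace$current,
                         reps[[2]]$conditions[[1]]$trace$current))
  expect_equal(vapply(reps, function(e) e$metadata$seed, numeric(1)),
               c(5, 6, 7))
})
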