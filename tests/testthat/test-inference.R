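test_that("deconvolution with an impulse flux is the convolution identity", {
  t <- seq(0, 0.2, by = 1e-3)
  dt <- diff(t)[1]
  A <- 1e-6
  ker <- charge_kernel(1e-19, 5e-3, 0.5e-19, 20e-3,
                       plateau_amplitude_c = 0.3e-19)
  # discrete unit impulse under the trapezoid weighting (area 1 per
  # m^2): the convolution operator collapses to the identity, so the
  # recovered kernel equals Q/A sample for sample
  J <- c(2 / dt, rep(0, length(t) - 1))
  i <- A * kernel_charge_deriv(ker, t)   # current of a single arrival
  est <- deconvolve_kernel(signal_trace(t, i), J, A, lambda = 0)
  Q <- c(0, cumsum((i[-1] + i[-length(i)]) / 2)) * dt
  expect_equal(est$q_raw, Q / A, tolerance = 1e-10)
  # and Q/A is the kernel itself up to quadrature error at the onset
  q_true <- kernel_charge(ker, t)
  expect_lt(max(abs(est$q_raw - q_true)) / max(abs(q_true)), 0.03)
  expect_equal(est$q, est$q_raw / max(abs(est$q_raw)), tolerance = 1e-12)
})

test_that("deconvolution round-trips a forward simulation at 30 dB SNR", {
  t <- seq(0, 0.5, by = 1e-3)
  A <- 1e-6
  ker <- charge_kernel(1e-19, 5e-3, 0.6e-19, 20e-3,
                       plateau_amplitude_c = 0.4e-19)
  J <- 1e16 * exp(-t / 0.25)
  i_clean <- induced_current(ker, J, t, A)
  set.seed(3)
  sd_a <- max(abs(i_clean)) * 10^(-30 / 20)
  tr <- signal_trace(t, i_clean + stats::rnorm(length(t), 0, sd_a))
  q_true <- kernel_charge(ker, t)
  q_true <- q_true / max(abs(q_true))
  scale <- max(abs(A * diff(t)[1] * J[1]))
  est <- deconvolve_kernel(tr, J, A, lambda = 0.3 * scale)
  rms <- sqrt(mean((est$q - q_true)^2))
  expect_lt(rms, 0.05)  # RMS error < 5% of (unit) peak
  # regularisation limit: very large lambda shrinks the estimate to 0
  est_big <- deconvolve_kernel(tr, J, A, lambda = 1e6 * scale)
  expect_lt(max(abs(est_big$q_raw)), 1e-6 * max(abs(q_true)))
  # more regularisation -> larger residual
  expect_gt(est_big$residual_norm, est$residual_norm)
})

test_that("deconvolution rejects degenerate flux and flags ill-conditioning", {
  t <- seq(0, 0.1, by = 1e-3)
  tr <- signal_trace(t, sin(t * 50) * 1e-9)
  expect_error(deconvolve_kernel(tr, rep(0, length(t)), 1e-6),
               "identically zero")
  # condition estimate is reported and triggers the warning threshold
  J <- rep(1e16, length(t))  # cumulative operator: condition grows with n
  expect_warning(deconvolve_kernel(tr, J, 1e-6, lambda = 0,
                                   condition_warn = 10),
                 "ill-conditioned")
})

test_that("dwell-time fit is exact on a pure exponential and flags degenerate inputs", {
  t <- seq(0, 1, by = 1e-3)
  tf <- fit_tau(signal_trace(t, 2e-9 * exp(-t / 0.3) + 1e-10))
  expect_true(tf$ok)
  expect_equal(tf$tau_s, 0.3, tolerance = 1e-6)
  expect_equal(tf$c, 1e-10, tolerance = 1e-4)
  expect_equal(unname(coef(tf)["tau_s"]), tf$tau_s)

  # white noise only: no relaxation to fit
  set.seed(2)
  tf_noise <- fit_tau(signal_trace(t, stats::rnorm(length(t), 0, 1e-10)))
  expect_false(tf_noise$ok)
  expect_true(is.na(tf_noise$tau_s))
  # flat signal
  expect_false(fit_tau(signal_trace(t, rep(0, length(t))))$ok)
})

test_that("dwell-time fit recovers the generating tau_s from biphasic traces", {
  tr <- tau_trace(tau_s = 0.3, snr_db = 25, seed = 4)
  tf <- fit_tau(tr)
  expect_true(tf$ok)
  expect_equal(tf$tau_s, 0.3, tolerance = 0.05)
  expect_lt(tf$se / tf$tau_s, 0.5)
  expect_equal(length(residuals(tf)),
               diff(tf$segment) + 1L)
})

test_that("unit responses from singles divide out the loadings", {
  t <- seq(0, 0.3, by = 1e-3)
  g <- sin(t * 20) * 1e-8
  h <- cos(t * 15) * 1e-10
  tr_p <- signal_trace(t, 0.1 * g)
  tr_l <- signal_trace(t, 0.2 * h)
  u <- unit_responses_from_singles(tr_p, 0.1, tr_l, 0.2)
  expect_equal(u$G_P, g)
  expect_equal(u$G_L, h)
  # unit response invariant under rescaling the loading
  u2 <- unit_responses_from_singles(signal_trace(t, 0.2 * g), 0.2, tr_l, 0.2)
  expect_equal(u2$G_P, u$G_P)
  expect_error(unit_responses_from_singles(tr_p, 0, tr_l, 0.2), "> 0")
})

test_that("per-timepoint K_D solve is exact on noiseless mixtures and scale invariant", {
  t <- seq(0, 0.3, by = 1e-3)
  K_true <- 34.7e-3
  G_P <- (1 - exp(-t / 0.02)) * 1e-8 * exp(-t / 0.4)
  G_L <- (1 - exp(-t / 0.01)) * 1e-10 * exp(-t / 0.2)
  G_C <- -(1 - exp(-t / 0.03)) * 2e-7 * exp(-t / 0.5)
  x1 <- 0.1; y1 <- 0.05; x2 <- 0.1; y2 <- 0.2
  i1 <- mixture_signal(G_P, G_L, G_C, x1, y1, K_true)
  i2 <- mixture_signal(G_P, G_L, G_C, x2, y2, K_true)
  sol <- solve_kd_timepoint(i1[-1], i2[-1], G_P[-1], G_L[-1],
                            x1, y1, x2, y2)
  expect_true(all(sol$flag == "ok"))
  expect_lt(max(abs(sol$kd / K_true - 1)), 1e-6)
  # common gain on all currents leaves K_D untouched
  sol_g <- solve_kd_timepoint(7 * i1[-1], 7 * i2[-1], 7 * G_P[-1],
                              7 * G_L[-1], x1, y1, x2, y2)
  expect_equal(sol_g$kd, sol$kd, tolerance = 1e-9)
  # degenerate designs rejected
  expect_error(solve_kd_timepoint(i1, i2, G_P, G_L, 0.1, 0, 0.1, 0.2),
               "both mixtures")
  expect_error(solve_kd_timepoint(i1, i2, G_P, G_L, 0.1, 0.05, 0.1, 0.05),
               "must differ")
})

test_that("per-timepoint solve discards timepoints without a bracketed root", {
  t <- seq(0, 0.1, by = 1e-3)
  n <- length(t)
  set.seed(9)
  # pure noise signals: most timepoints cannot bracket a root
  sol <- solve_kd_timepoint(stats::rnorm(n, 0, 1e-9), stats::rnorm(n, 0, 1e-9),
                            stats::rnorm(n, 0, 1e-9), stats::rnorm(n, 0, 1e-10),
                            0.1, 0.05, 0.1, 0.2)
  expect_true(any(is.na(sol$kd)))
  expect_equal(sol$discarded, sum(is.na(sol$kd)))
  expect_true(all(sol$flag[is.na(sol$kd)] %in% c("no_root", "edge")))
})

test_that("histogram mode estimator is robust and respects its contracts", {
  # all samples equal: mode is that value
  h <- kd_histogram_mode(rep(0.02, 100))
  expect_equal(h$kd_mode, 0.02)
  # 950 samples near v, 50 spikes 100x larger: mode stays in the v bin
  set.seed(5)
  v <- 3e-2
  samples <- c(v * exp(stats::rnorm(950, 0, 0.05)),
               v * 100 * exp(stats::rnorm(50, 0, 0.3)))
  h <- kd_histogram_mode(samples)
  expect_equal(h$kd_mode, v, tolerance = 0.05)
  expect_equal(h$n, 1000)
  expect_equal(sum(h$counts), 1000)
  expect_equal(length(h$breaks), length(h$counts) + 1)
  # NAs (discarded timepoints) are excluded before binning
  h2 <- kd_histogram_mode(c(samples, rep(NA, 200)))
  expect_equal(h2$n, 1000)
  # too few samples errors with the count
  expect_error(kd_histogram_mode(rep(1, 10)), "too few")
})
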