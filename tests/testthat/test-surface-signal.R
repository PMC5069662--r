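test_that("coverage ODE matches the closed-form Langmuir solution to 1e-6", {
  kin <- surface_kinetics(1e-6, 5e16, 3e16, theta0 = 0.1)
  gam <- 2
  n_o <- 6e22
  t <- seq(0, 1, by = 1e-3)
  theta_num <- coverage_dynamics(kin, gam, rep(n_o, length(t)), t)
  theta_ref <- coverage_closed_form(kin, gam, n_o, t)
  expect_lt(max(abs(theta_num - theta_ref)) / max(theta_ref), 1e-6)
})

test_that("coverage equilibrium and degenerate limits behave", {
  t <- seq(0, 0.5, by = 1e-3)
  # no adsorption, empty surface: stays empty
  kin0 <- surface_kinetics(0, 1e17, 3e16)
  expect_equal(coverage_dynamics(kin0, 1, rep(1e20, length(t)), t),
               rep(0, length(t)))
  # symmetric rates: theta_eq = 1/2
  kin <- surface_kinetics(1e-6, 5e16, 3e16)
  n_half <- kin$K_minus / (kin$K_plus * 1)  # K+ gamma n = K-
  th <- coverage_closed_form(kin, 1, n_half, 10)  # >> tau
  expect_equal(th, 0.5, tolerance = 1e-10)
})

test_that("coverage stays within [0,1] across randomised parameters", {
  set.seed(11)
  t <- seq(0, 0.5, by = 2e-3)
  for (i in 1:25) {
    kin <- surface_kinetics(10^stats::runif(1, -8, -5),
                            10^stats::runif(1, 15, 18),
                            10^stats::runif(1, 15, 17),
                            theta0 = stats::runif(1))
    gam <- 10^stats::runif(1, -1, 1)
    n_o <- 10^stats::runif(1, 18, 23)
    th <- coverage_dynamics(kin, gam, rep(n_o, length(t)), t)
    expect_true(all(th >= 0 & th <= 1))
  }
})

test_that("net flux equals N_s dtheta/dt and integrates to the coverage change", {
  kin <- surface_kinetics(1e-6, 5e16, 3e16)
  gam <- 1.5; n_o <- 5e21
  t <- seq(0, 8, by = 2e-3)  # ~15 relaxation times
  th <- coverage_closed_form(kin, gam, n_o, t)
  J <- net_flux(kin, gam, rep(n_o, length(t)), th)
  # J(0) is the bare adsorption flux onto the empty surface
  expect_equal(J[1], kin$K_plus * gam * n_o, tolerance = 1e-12)
  # steady state: zero net flux
  th_eq <- kin$K_plus * gam * n_o / (kin$K_plus * gam * n_o + kin$K_minus)
  expect_equal(net_flux(kin, gam, n_o, th_eq), 0, tolerance = 1e-9)
  # integral of J equals N_s (theta_eq - theta0), here over ~13 tau
  int_J <- sum((J[-1] + J[-length(J)]) / 2) * diff(t)[1]
  expect_equal(int_J, kin$N_s * (th_eq - 0), tolerance = 1e-5)
})

test_that("dwell time is the coverage relaxation time with its limits", {
  kin <- surface_kinetics(1, 5e16, 3e16)
  expect_equal(dwell_time(kin, 1, 5e16), 0.3)           # denominator 1e17
  kin0 <- surface_kinetics(0, 5e16, 3e16)
  expect_equal(dwell_time(kin0, 1, 1e20), 3e16 / 5e16)  # pure desorption
  # doubling both rates halves tau_s
  kin2 <- surface_kinetics(2, 1e17, 3e16)
  expect_equal(dwell_time(kin2, 1, 5e16) / dwell_time(kin, 1, 5e16), 0.5)
  kinz <- surface_kinetics(0, 0, 3e16)
  expect_error(dwell_time(kinz, 1, 0), "undefined")
})

test_that("induced current is linear, causal and matches both numerical paths", {
  t <- seq(0, 0.5, by = 5e-4)
  A <- 1e-6
  ker <- charge_kernel(1e-19, 5e-3, 0.5e-19, 20e-3,
                       plateau_amplitude_c = 0.4e-19)
  J1 <- 1e16 * exp(-t / 0.1)
  J2 <- 5e15 * (1 - exp(-t / 0.05))
  expect_equal(induced_current(ker, rep(0, length(t)), t, A),
               rep(0, length(t)))
  # superposition to machine precision of the scheme
  i12 <- induced_current(ker, J1 + J2, t, A)
  expect_equal(i12,
               induced_current(ker, J1, t, A) + induced_current(ker, J2, t, A),
               tolerance = 1e-12)
  expect_equal(induced_current(ker, 3 * J1, t, A),
               3 * induced_current(ker, J1, t, A), tolerance = 1e-12)
  # derivative-convolution and differentiated-charge paths agree to
  # discretisation error (away from the onset kink, fine grid)
  tf <- seq(0, 0.3, by = 1e-4)
  Jf <- 1e16 * exp(-tf / 0.1)
  ia <- induced_current(ker, Jf, tf, A, method = "deriv")
  ib <- induced_current(ker, Jf, tf, A, method = "charge")
  expect_lt(max(abs(ia - ib)[6:(length(tf) - 2)]) / max(abs(ia)), 1e-3)
})

test_that("convolution of exponential flux and exponential kernel derivative matches the closed form", {
  # plateau-only kernel: dq/dt = (a/tau_q) exp(-t/tau_q); for flux
  # J0 exp(-t/tau_J), i(t) = A a J0 (exp(-t/tau_J) - exp(-t/tau_q)) /
  # (tau_J - tau_q) * tau_J ... computed directly below
  a <- 2e-19; tau_q <- 0.02; tau_J <- 0.08; J0 <- 1e16; A <- 1e-6
  t <- seq(0, 0.6, by = 2e-4)
  ker <- charge_kernel(0, 1e-3, 0, tau_q, plateau_amplitude_c = a)
  i_num <- induced_current(ker, J0 * exp(-t / tau_J), t, A)
  i_ref <- A * a / tau_q * J0 * (exp(-t / tau_J) - exp(-t / tau_q)) /
    (1 / tau_q - 1 / tau_J)
  expect_lt(max(abs(i_num - i_ref)) / max(abs(i_ref)), 1e-4)
})

test_that("charge conservation: integral of current equals the convolved charge", {
  t <- seq(0, 1, by = 1e-3)
  A <- 1e-6
  ker <- charge_kernel(1e-19, 4e-3, 0.4e-19, 15e-3,
                       plateau_amplitude_c = 0.8e-19)
  J <- 1e16 * exp(-t / 0.3)
  i <- induced_current(ker, J, t, A)
  Q_from_i <- sum((i[-1] + i[-length(i)]) / 2) * diff(t)[1]
  # independent direct quadrature of Q(T) = A int q(T - s) J(s) ds
  q <- kernel_charge(ker, t)
  n <- length(t)
  w <- rep(1, n); w[c(1, n)] <- 0.5
  Q_direct <- A * diff(t)[1] * sum(w * rev(q) * J)
  expect_equal(Q_from_i, Q_direct, tolerance = 1e-3)
})

test_that("kernel template satisfies its invariants", {
  ker <- charge_kernel(1e-19, 4e-3, 0.5e-19, 15e-3,
                       plateau_amplitude_c = 0.3e-19)
  expect_identical(kernel_charge(ker, 0), 0)
  tt <- seq(0, 2, by = 1e-3)
  q <- kernel_charge(ker, tt)
  expect_equal(q[length(q)], 0.3e-19, tolerance = 1e-4)  # finite plateau
  expect_true(q[which.min(abs(tt - 4e-3))] < 0)           # dip-first
  # polarity flips the sign convention
  kerm <- charge_kernel(1e-19, 4e-3, 0.5e-19, 15e-3,
                        plateau_amplitude_c = 0.3e-19, polarity = -1)
  expect_equal(kernel_charge(kerm, tt), -q)
  # numerical derivative of q matches the analytic derivative (fine
  # grid, away from the onset kink)
  ttf <- seq(0, 0.2, by = 2e-4)
  qf <- kernel_charge(ker, ttf)
  qd <- kernel_charge_deriv(ker, ttf)
  mid <- (diff(qf)[-1] + diff(qf)[-(length(ttf) - 1)]) / (2 * diff(ttf)[1])
  keep <- 10:(length(ttf) - 2)
  expect_lt(max(abs(qd[keep] - mid[keep - 1])) / max(abs(qd)), 1e-3)
})

test_that("mixture signal reproduces the single-species boundary conditions", {
  t <- seq(0, 0.3, by = 1e-3)
  G_P <- sin(t * 10) * 1e-8
  G_L <- cos(t * 12) * 1e-10
  G_C <- -sin(t * 7) * 1e-7
  # protein only / ligand only are exact linear reads
  expect_equal(mixture_signal(G_P, G_L, G_C, 0.1, 0, 0.03), 0.1 * G_P)
  expect_equal(mixture_signal(G_P, G_L, G_C, 0, 0.2, 0.03), 0.2 * G_L)
  # K_D -> infinity: no complex forms
  expect_equal(mixture_signal(G_P, G_L, G_C, 0.1, 0.2, 1e9),
               0.1 * G_P + 0.2 * G_L, tolerance = 1e-9)
})

test_that("unit responses are positive-homogeneous in concentration by construction", {
  g <- channel_geometry()
  sp <- default_species()$protein
  t <- seq(0, 0.3, by = 2e-3)
  G <- unit_response(sp, g, t)
  expect_equal(length(G), length(t))
  expect_lt(max(abs(G[1])), max(abs(G)))  # starts near zero, builds up
  # front-arrival variant is damped relative to prefilled early on
  G_front <- unit_response(sp, g, t, initial = "empty")
  expect_lt(max(abs(G_front[t < 0.05])), max(abs(G[t < 0.05])))
})
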