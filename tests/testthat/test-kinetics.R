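test_that("tau recovery on deterministic two-state traces is unbiased", {
  mod <- toy_model(tau_min = 2)
  for (V in c(20, 40, 60, 80, 100)) {
    g <- hvephys:::gating_rates(mod, V)
    prot <- single_step_protocol(V = V, pulse_ms = max(8 * g$tau, 40),
                                 dt = 0.2)
    det <- simulate_ensemble(mod, recording_artifacts(), prot,
                             mode = "deterministic")
    f <- fit_activation_tau(det)
    expect_rel(f$tau_act, g$tau, 0.02)
  }
})

test_that("equal opening and closing rates give tau = 1/(2 alpha)", {
  # at V_half the rates are equal; tau = 1/(alpha+beta) = 1/(2 alpha)
  mod <- toy_model(V_half = 30, tau_min = 0, P_open_max = 1)
  g <- hvephys:::gating_rates(mod, 30)
  expect_equal(g$alpha, g$beta, tolerance = 1e-12)
  expect_equal(g$tau, 1 / (2 * g$alpha), tolerance = 1e-12)
  expect_equal(g$p_eq, 0.5, tolerance = 1e-12)
})

test_that("the 20%-rise rule absorbs the sigmoidal delay", {
  mod2 <- toy_model(n_gating_steps = 2, tau_min = 4, rate_scale = 0.02)
  # at the midpoint the chain eigenvalues are well separated (3x), so a
  # single exponential from the 20% rise isolates the dominant mode
  g <- hvephys:::gating_rates(mod2, 0)
  f <- 2 * g$alpha; b <- 2 * g$beta
  Q <- matrix(c(-f, f, 0, b, -(f + b), f, 0, b, -b), 3, byrow = TRUE)
  tau_dom <- 1 / sort(abs(eigen(Q)$values))[2]
  prot <- single_step_protocol(V = 0, pulse_ms = 12 * tau_dom, dt = 0.2)
  det <- simulate_ensemble(mod2, recording_artifacts(), prot,
                           mode = "deterministic")
  f20 <- fit_activation_tau(det)
  f0 <- fit_activation_tau(det, fit_start = 0)
  expect_rel(f20$tau_act, tau_dom, 0.10)
  # fitting through the delay biases tau high
  expect_gt(f0$tau_act, f20$tau_act)
})

test_that("tau-V curves match the rate model across voltages", {
  mod <- toy_model(tau_min = 2)
  prot <- make_protocol("step_family", V_from = 20, V_to = 100, dV = 20,
                        pre_ms = 10, pulse_ms = 150, tail_ms = 10,
                        sample_interval = 0.2)
  det <- simulate_ensemble(mod, recording_artifacts(), prot,
                           mode = "deterministic")
  tv <- tau_v_curve(det)
  truth <- hvephys:::gating_rates(mod, tv$V)$tau
  expect_true(all(abs(tv$tau / truth - 1) < 0.05))
  # activation-dominated range: tau falls with depolarization
  expect_true(all(diff(tv$tau) < 0))
})

test_that("three-exponential decomposition recovers well-separated taus", {
  tt <- seq(0, 2000, by = 1)
  taus <- c(10, 60, 400)
  I0 <- 20 - 5 * exp(-tt / 10) - 5 * exp(-tt / 60) - 5 * exp(-tt / 400)
  set.seed(12)
  I <- I0 + stats::rnorm(length(tt), sd = 0.05)  # 1% of the 5-pA amplitudes
  fit <- decompose_exponentials(tt, I, 3, seed = 4)
  expect_true(all(abs(fit$taus / taus - 1) < 0.10))
  expect_true(all(abs(fit$amplitudes + 5) < 0.5))
  expect_equal(fit$offset, 20, tolerance = 0.1)
})

test_that("residuals fall monotonically with component count on 3-exp data", {
  tt <- seq(0, 2000, by = 2)
  I <- 20 - 6 * exp(-tt / 12) - 5 * exp(-tt / 80) - 4 * exp(-tt / 500)
  r <- vapply(1:3, function(k) {
    suppressWarnings(decompose_exponentials(tt, I, k, seed = 2))$residual_rms
  }, numeric(1))
  expect_true(all(diff(r) < 0))
  expect_lt(r[3], 1e-4)
})

test_that("single-exponential input flags merged components", {
  tt <- seq(0, 500, by = 1)
  I <- 10 - 8 * exp(-tt / 50)
  expect_warning(decompose_exponentials(tt, I, 3, seed = 3),
                 "merged components")
})

test_that("decomposition of a simulated isoform mixture preserves tau ordering", {
  # three components with rate scales separated ~5-fold
  ms <- list(toy_model(N_channels = 3000, rate_scale = 0.10, tau_min = 0),
             toy_model(N_channels = 3000, rate_scale = 0.02, tau_min = 0),
             toy_model(N_channels = 3000, rate_scale = 0.004, tau_min = 0))
  taus_true <- vapply(ms, function(m) hvephys:::gating_rates(m, 60)$tau,
                      numeric(1))
  prot <- single_step_protocol(V = 60, pulse_ms = 6 * max(taus_true), dt = 0.5)
  mix <- mixture_current(ms, protocol = prot, mode = "deterministic")
  w <- hvephys:::segment_window(prot, 2, 1)
  tt <- mix$time[w] - mix$time[w[1]]
  fit <- decompose_exponentials(tt, mix$sweeps[1, w], 3, seed = 11)
  expect_true(all(abs(fit$taus / sort(taus_true) - 1) < 0.10))
  labs <- assign_taus(fit, c(fast = taus_true[1], mid = taus_true[2],
                             slow = taus_true[3]))
  expect_equal(labs, c("fast", "mid", "slow"))
})
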