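test_that("saturated channels give the deterministic ceiling current", {
  # drive the open probability to ~1 and remove every artifact
  cond <- dpH1()
  mod <- channel_model(N_channels = 200, gamma = 200, z_delta = 2,
                       V_half = -150, rate_scale = 0.05, condition = cond,
                       P_open_max = 1, tau_min = 3)
  prot <- single_step_protocol(V = 100, pulse_ms = 100, dt = 0.5)
  ens <- simulate_ensemble(mod, recording_artifacts(), prot, n_sweeps = 3,
                           seed = 1)
  v_rev <- nernst_potential(cond)
  expected <- 200 * 200 * (100 - v_rev) * 1e-6
  w <- hvephys:::segment_window(prot, 2, 1)
  expect_equal(unname(ens$sweeps[2, utils::tail(w, 50)]),
               rep(expected, 50), tolerance = 1e-3)
})

test_that("steady mean current matches N * i * P_max for the worked example", {
  mod <- hv12_model()
  prot <- single_step_protocol(V = 100, pulse_ms = 200)
  ens <- simulate_ensemble(mod, recording_artifacts(), prot, n_sweeps = 24,
                           seed = 4)
  w <- hvephys:::segment_window(prot, 2, 1)
  steady <- mean(ens$sweeps[, utils::tail(w, 500)])
  # N * i * P_max = 9477 * 28 fA * 0.82 = 218 pA
  expect_rel(steady, 9477 * 0.028 * 0.82, 0.03)
})

test_that("equilibrium open-count variance is binomial", {
  # P_open = 0.5 at V = V_half: variance N/4 in open counts
  mod <- channel_model(N_channels = 400, gamma = 1000, z_delta = 2,
                       V_half = 0, rate_scale = 0.5, condition = dpH1(),
                       P_open_max = 1, tau_min = 3)
  prot <- single_step_protocol(V = 0, pulse_ms = 400, dt = 0.5)
  ens <- simulate_ensemble(mod, recording_artifacts(), prot, n_sweeps = 64,
                           seed = 8)
  v_rev <- nernst_potential(dpH1())
  i <- 1000 * (0 - v_rev) * 1e-6
  w <- hvephys:::segment_window(prot, 2, 1)
  n_open <- ens$sweeps[, w[seq(100, length(w), by = 20)]] / i
  v_hat <- stats::var(as.vector(n_open))
  se <- 100 * sqrt(2 / length(n_open))  # crude chi-square bound on N/4
  expect_lt(abs(v_hat - 100), 3 * se + 5)
})

test_that("identical seeds give bit-identical ensembles", {
  mod <- toy_model()
  prot <- single_step_protocol(V = 60, pulse_ms = 50)
  art <- recording_artifacts(thermal_noise_sd = 1, leak_conductance = 0.2)
  a <- simulate_ensemble(mod, art, prot, n_sweeps = 5, seed = 123)
  b <- simulate_ensemble(mod, art, prot, n_sweeps = 5, seed = 123)
  expect_identical(a$sweeps, b$sweeps)
  c <- simulate_ensemble(mod, art, prot, n_sweeps = 5, seed = 124)
  expect_false(identical(a$sweeps, c$sweeps))
})

test_that("stochastic mean trace converges to the deterministic limit", {
  mod <- toy_model(N_channels = 1e5)
  prot <- single_step_protocol(V = 60, pulse_ms = 60, dt = 0.5)
  det <- simulate_ensemble(mod, recording_artifacts(), prot,
                           mode = "deterministic")
  sto <- simulate_ensemble(mod, recording_artifacts(), prot, n_sweeps = 8,
                           seed = 2)
  w <- hvephys:::segment_window(prot, 2, 1)
  w <- w[-(1:10)]
  rel <- abs(colMeans(sto$sweeps[, w]) - det$sweeps[1, w]) /
    max(abs(det$sweeps[1, w]))
  expect_lt(mean(rel), 0.01)
})

test_that("undersized time steps are rejected, oversized flagged", {
  mod <- toy_model(tau_min = 0.05, rate_scale = 2)
  prot <- single_step_protocol(V = 100, pulse_ms = 10, dt = 0.2)
  expect_error(simulate_ensemble(mod, recording_artifacts(), prot,
                                 n_sweeps = 2, seed = 1),
               "time-step")
  mod2 <- toy_model(tau_min = 1)
  prot2 <- single_step_protocol(V = 100, pulse_ms = 10, dt = 0.4)
  expect_warning(simulate_ensemble(mod2, recording_artifacts(), prot2,
                                   n_sweeps = 2, seed = 1),
                 "transition probability")
})

test_that("multi-step gating produces a sigmoidal activation delay", {
  m1 <- toy_model(n_gating_steps = 1)
  m2 <- toy_model(n_gating_steps = 2)
  prot <- single_step_protocol(V = 80, pulse_ms = 80, dt = 0.2)
  d1 <- simulate_ensemble(m1, recording_artifacts(), prot, mode = "deterministic")
  d2 <- simulate_ensemble(m2, recording_artifacts(), prot, mode = "deterministic")
  w <- hvephys:::segment_window(prot, 2, 1)
  # normalized current shortly after the step: the two-step trace rises
  # quadratically (delay), the one-step trace linearly
  at <- w[3]
  n1 <- d1$sweeps[1, at] / max(d1$sweeps[1, w])
  n2 <- d2$sweeps[1, at] / max(d2$sweeps[1, w])
  expect_lt(n2, 0.3 * n1)
})

test_that("mixture current is the sum of its components", {
  m1 <- toy_model(N_channels = 1000, rate_scale = 0.05)
  m2 <- toy_model(N_channels = 1000, rate_scale = 0.002)
  prot <- single_step_protocol(V = 60, pulse_ms = 100, dt = 0.5)
  # degenerate mixture equals plain simulation
  solo <- simulate_ensemble(m1, recording_artifacts(), prot, n_sweeps = 2,
                            seed = 5)
  mix1 <- mixture_current(list(m1), protocol = prot, n_sweeps = 2, seed = 5)
  expect_equal(solo$sweeps, mix1$sweeps)
  # zero-weight components drop out
  mix0 <- mixture_current(list(m1, m2), weights = c(1, 0), protocol = prot,
                          n_sweeps = 2, seed = 5)
  expect_equal(mix0$sweeps, solo$sweeps)
  expect_error(mixture_current(list(), protocol = prot), "empty")
  # deterministic mixture = sum of deterministic components
  d1 <- simulate_ensemble(m1, recording_artifacts(), prot, n_sweeps = 1,
                          mode = "deterministic")
  d2 <- simulate_ensemble(m2, recording_artifacts(), prot, n_sweeps = 1,
                          mode = "deterministic")
  dm <- mixture_current(list(m1, m2), protocol = prot, n_sweeps = 1,
                        mode = "deterministic")
  expect_equal(dm$sweeps, d1$sweeps + d2$sweeps, tolerance = 1e-12)
})

test_that("condition shift moves the midpoint by dV_half_per_pH", {
  m <- toy_model(V_half = 10)
  m2 <- shift_condition(m, ph_condition(6, 8))
  expect_equal(m2$V_half, 10 + m$dV_half_per_pH * 1)
  expect_equal(m2$condition$delta_pH, 2)
})
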