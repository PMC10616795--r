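family_protocol <- function(dt = 0.5, tail_V = -100) {
  make_protocol("step_family", V_from = -60, V_to = 100, dV = 10,
                pre_ms = 20, pulse_ms = 150, tail_ms = 60, tail_V = tail_V,
                sample_interval = dt)
}

test_that("leak subtraction recovers a known linear leak", {
  prot <- family_protocol()
  art <- recording_artifacts(leak_conductance = 0.5, leak_reversal = -10,
                             residual_capacitive = 2, thermal_noise_sd = 0.5)
  # channel silent below -20 mV so the subthreshold window is pure leak
  ens <- simulate_ensemble(toy_model(V_half = 40), art, prot, seed = 11)
  sub <- subtract_leak(ens, c(-60, -30))
  expect_rel(sub$metadata$leak_fit$G_Leak, 0.5, 0.02)
  # residual subthreshold currents are flat around zero
  iv <- extract_iv(sub)
  expect_lt(max(abs(iv$I_end[iv$V <= -30])), 3 * 0.5 / sqrt(50))
})

test_that("pure-leak ensembles are nulled and zero-leak inputs unchanged", {
  prot <- family_protocol()
  silent <- toy_model(N_channels = 1, gamma = 1e-3)
  leak_only <- simulate_ensemble(
    silent,
    recording_artifacts(leak_conductance = 1, thermal_noise_sd = 0.2),
    prot, seed = 2)
  sub <- subtract_leak(leak_only, c(-60, 0))
  expect_lt(max(abs(extract_iv(sub)$I_end)), 0.3)

  clean <- simulate_ensemble(silent, recording_artifacts(), prot,
                             mode = "deterministic")
  sub2 <- subtract_leak(clean, c(-60, -40))
  expect_equal(sub2$sweeps, clean$sweeps, tolerance = 1e-6)
  expect_error(subtract_leak(clean, c(-60, -60)), "singular")
})

test_that("end-pulse extraction reaches the exponential asymptote", {
  mod <- toy_model(tau_min = 5)
  # pulse of 8 tau: end-window mean within 1% of the asymptote
  prot <- family_protocol()
  det <- simulate_ensemble(mod, recording_artifacts(), prot,
                           mode = "deterministic")
  iv <- extract_iv(det)
  g <- hvephys:::gating_rates(mod, 100)
  v_rev <- nernst_potential(dpH1())
  asym <- 5000 * g$p_eq * 150 * (100 - v_rev) * 1e-6
  expect_rel(iv$I_end[iv$V == 100], asym, 0.01)
  expect_error(extract_iv(det, end_window_fraction = 0.001), "3 samples")
})

test_that("Boltzmann fit is a fixed point on its own curve", {
  V <- seq(-60, 140, 10)
  y <- boltzmann_curve(V, 250, 1.30, 43.38)
  f <- fit_boltzmann_iv(data.frame(V = V, I_end = y))
  expect_rel(f$z_delta, 1.30, 1e-6)
  expect_rel(f$V_half, 43.38, 1e-6)
  expect_rel(f$amplitude_max, 250, 1e-6)
  expect_lt(f$residual_rms, 1e-6)
})

test_that("midpoints outside the sampled range trigger a warning", {
  V <- seq(-60, 20, 10)
  y <- boltzmann_curve(V, 100, 1.3, 60)
  expect_warning(fit_boltzmann_iv(data.frame(V = V, I_end = y)),
                 "outside the sampled range")
})

test_that("noisy IV recovery stays within 2 mV of the generative midpoint", {
  V <- seq(-60, 140, 10)
  y0 <- boltzmann_curve(V, 250, 1.30, 43.38)
  set.seed(99)
  y <- y0 + stats::rnorm(length(V), sd = 0.01 * 250)
  f <- fit_boltzmann_iv(data.frame(V = V, I_end = y))
  expect_lt(abs(f$V_half - 43.38), 2)
})

test_that("tail GV and ON GV agree for a two-state channel", {
  prot <- family_protocol()
  det <- simulate_ensemble(toy_model(), recording_artifacts(), prot,
                           mode = "deterministic")
  tail_fit <- fit_boltzmann_gv(extract_tail_gv(det, isochrone_ms = 0.5))
  on_fit <- fit_boltzmann_gv(
    setNames(extract_on_gv(det), c("V", "G_tail")))
  expect_rel(tail_fit$z_delta, 2, 0.01)
  expect_lt(abs(tail_fit$V_half - on_fit$V_half), 0.5)
})

test_that("tail conversion refuses a tail potential at the reversal", {
  prot <- family_protocol(tail_V = -58.36)
  det <- simulate_ensemble(toy_model(), recording_artifacts(), prot,
                           mode = "deterministic")
  expect_error(extract_tail_gv(det, V_rev = -58.36), "equals V_rev")
})

test_that("mixture ON-GV fits a single Boltzmann with intermediate midpoint", {
  m1 <- toy_model(V_half = -20, rate_scale = 0.05)
  m2 <- toy_model(V_half = 30, rate_scale = 0.05)
  prot <- make_protocol("step_family", V_from = -80, V_to = 120, dV = 10,
                        pre_ms = 10, pulse_ms = 200, tail_ms = 20,
                        sample_interval = 0.5)
  mix <- mixture_current(list(m1, m2), protocol = prot,
                         mode = "deterministic")
  f <- fit_boltzmann_gv(setNames(extract_on_gv(mix), c("V", "G_tail")))
  expect_gt(f$V_half, -20)
  expect_lt(f$V_half, 30)
})
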