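slow_ramp_ensemble <- function(z_delta = 4.19, V_half = 0, rate = 1,
                               V_from = -120, V_to = 80, tau_min = 5) {
  cond <- ph_condition(6, 8)
  mod <- channel_model(N_channels = 1e4, gamma = 100, z_delta = z_delta,
                       V_half = V_half, rate_scale = 0.05, condition = cond,
                       P_open_max = 1, tau_min = tau_min)
  prot <- make_protocol("slow_ramp", V_from = V_from, V_to = V_to,
                        rate = rate, sample_interval = 20)
  simulate_ensemble(mod, recording_artifacts(), prot, mode = "deterministic")
}

test_that("preprocessing yields at most the requested bin count and flat curves stay flat", {
  ens <- slow_ramp_ensemble()
  curve <- preprocess_ramp(ens)
  expect_lte(nrow(curve), 100)
  # constant-conductance input: replace current with G0 * (V - V_rev)
  v_rev <- nernst_potential(ens$condition)
  V <- protocol_voltage(ens$protocol)[1, ]
  flat <- ens
  flat$sweeps <- matrix(2 * (V - v_rev), 1)
  cf <- preprocess_ramp(flat)
  expect_equal(cf$G, rep(2, nrow(cf)), tolerance = 1e-9)
})

test_that("binned noiseless conductance matches the closed-form Boltzmann", {
  ens <- slow_ramp_ensemble(z_delta = 2, V_half = -10)
  curve <- preprocess_ramp(ens)
  g_max <- 1e4 * 100 * 1e-6
  expected <- boltzmann_curve(curve$V, g_max, 2, -10)
  expect_lt(max(abs(curve$G - expected) / g_max), 1e-3)
})

test_that("limiting slope recovers the printed dimer gating charge", {
  ens <- slow_ramp_ensemble(z_delta = 4.19)
  curve <- preprocess_ramp(ens)
  fit <- fit_limiting_slope(curve, Po_threshold = 0.01)
  expect_rel(fit$zdelta_eff, 4.19, 0.02)
  expect_rel(fit$zdelta_exp_fit, 4.19, 0.02)
  expect_rel(fit$zdelta_boltzmann, 4.19, 0.02)
})

test_that("z_delta(V) profile has the two-state limits", {
  ens <- slow_ramp_ensemble(z_delta = 3, V_half = 0, V_from = -150)
  curve <- preprocess_ramp(ens)
  fit <- suppressWarnings(fit_limiting_slope(curve))
  prof <- fit$zdelta_profile
  # z(V) -> z monotonically toward hyperpolarization...
  low <- prof[prof$V < -80 & is.finite(prof$zdelta), ]
  expect_true(all(abs(low$zdelta - 3) < 0.05))
  # ...and equals z/2 at the midpoint
  at_half <- prof$zdelta[which.min(abs(prof$V - 0))]
  expect_lt(abs(at_half - 1.5), 0.1)
  # profile decreases with V (within binning wiggle)
  sm <- prof$zdelta[is.finite(prof$zdelta)]
  expect_lt(sum(diff(sm) > 0.02), 3)
})

test_that("voltage-independent conductance has zero limiting slope", {
  ens <- slow_ramp_ensemble()
  v_rev <- nernst_potential(ens$condition)
  V <- protocol_voltage(ens$protocol)[1, ]
  flat <- ens
  flat$sweeps <- matrix(0.5 * (V - v_rev), 1)
  curve <- preprocess_ramp(flat)
  prof_ok <- is.finite(curve$G) & curve$G > 0
  vt <- thermal_voltage(294.15)
  lnG <- log(curve$G[prof_ok])
  z <- vt * diff(lnG) / diff(curve$V[prof_ok])
  expect_lt(max(abs(z)), 1e-6)
})

test_that("filtering and decimation leave the noiseless plateau unchanged", {
  ens <- slow_ramp_ensemble(z_delta = 4.19)
  f_plain <- fit_limiting_slope(preprocess_ramp(ens))
  f_filt <- fit_limiting_slope(preprocess_ramp(ens, filter_hz = 10))
  f_dec1 <- fit_limiting_slope(preprocess_ramp(ens, decimate = 1))
  expect_rel(f_filt$zdelta_eff, f_plain$zdelta_eff, 0.005)
  expect_rel(f_dec1$zdelta_eff, f_plain$zdelta_eff, 0.005)
})

test_that("two-component mixtures plateau toward the steeper charge", {
  # monomer (2 e0) + dimer (4 e0): d(lnG)/dV at extreme hyperpolarization
  # is dominated by the steeper (faster-vanishing) component's neighbour;
  # analytically the mixture slope sits between the components and above
  # the shallow one
  vt <- thermal_voltage(294.15)
  V <- seq(-150, 50, by = 2)
  G <- 0.5 * boltzmann_curve(V, 1, 2, 0) + 0.5 * boltzmann_curve(V, 1, 4, 0)
  fit <- suppressWarnings(
    fit_limiting_slope(data.frame(V = V, G = G), Po_threshold = 0.01))
  expect_gt(fit$zdelta_eff, 2)
  expect_lt(fit$zdelta_eff, 4)
})

test_that("log-domain and threshold guards fire", {
  V <- seq(-100, 50, 2)
  G <- boltzmann_curve(V, 1, 2, 0)
  G[3] <- -1e-9
  expect_error(suppressWarnings(fit_limiting_slope(data.frame(V = V, G = G))),
               "non-positive")
  shallow <- data.frame(V = seq(-20, 20, 2),
                        G = boltzmann_curve(seq(-20, 20, 2), 1, 1, 0))
  expect_error(suppressWarnings(fit_limiting_slope(shallow)), "too few bins")
})
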