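# Shared fixtures: small channel models and protocols used across tests.

dpH1 <- function() ph_condition(6, 7)

# mHv1.2-like generative model from the noise-analysis worked example:
# 9,477 channels of 176.8 fS (28 fA at +100 mV, dpH 1), P_max 0.82, with
# the tail-GV Boltzmann (z 2.10, V_half -0.77 mV).
hv12_model <- function(N = 9477) {
  channel_model(N_channels = N, gamma = 176.8, z_delta = 2.10,
                V_half = -0.77, rate_scale = 0.01, condition = dpH1(),
                P_open_max = 0.82)
}

# generic fast-converging two-state model for deterministic checks
toy_model <- function(...) {
  args <- list(N_channels = 5000, gamma = 150, z_delta = 2, V_half = 0,
               rate_scale = 0.02, condition = dpH1(), tau_min = 5)
  args[names(list(...))] <- list(...)
  do.call(channel_model, args)
}

single_step_protocol <- function(V = 100, pulse_ms = 400, dt = 0.2) {
  make_protocol("step_family", V_from = V, V_to = V, dV = 10, pre_ms = 10,
                pulse_ms = pulse_ms, tail_ms = 5, sample_interval = dt)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
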