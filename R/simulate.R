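#' Generative two-state channel model
#'
#' Parameters of the stochastic ensemble simulator. The gating scheme is a
#' two-state (closed/open) voltage-dependent Markov chain with a Boltzmann
#' equilibrium: the opening and closing rates alpha(V), beta(V) satisfy
#' alpha/(alpha+beta) = P_open_max * Boltzmann(V; z_delta, V_half) and
#' 1/(alpha+beta) = tau(V), with tau(V) derived from a symmetric charge
#' split (alpha and beta each carry half of z_delta) and scaled so that the
#' opening rate at 0 mV equals \code{rate_scale}. With
#' \code{n_gating_steps >= 2} the channel must traverse that many identical
#' sequential transitions before opening, producing the sigmoidal
#' activation delay characteristic of dimeric Hv1 channels.
#'
#' @param N_channels number of channels in the patch (>= 1).
#' @param gamma unitary conductance, fS.
#' @param z_delta effective gating charge, e0 units.
#' @param V_half Boltzmann midpoint at the model's \code{condition}, mV.
#' @param dV_half_per_pH shift of V_half per unit delta_pH, mV (default -40:
#'   midpoints move toward hyperpolarized voltages as the outward gradient
#'   grows).
#' @param rate_scale opening rate at 0 mV, ms^-1.
#' @param condition \code{\link{ph_condition}} at which \code{V_half} is
#'   specified.
#' @param P_open_max asymptotic maximal open probability in (0, 1],
#'   implemented as a voltage-independent factor on the Boltzmann
#'   equilibrium.
#' @param n_gating_steps number of identical sequential activation
#'   transitions (1 = pure two-state).
#' @param tau_min floor on the relaxation time 1/(alpha+beta), ms (default
#'   0.5). The symmetric-split rate model grows exponentially away from
#'   V_half; real conformational rates saturate, and the floor keeps the
#'   far-from-midpoint kinetics physical (equilibrium is unaffected).
#' @return An object of class \code{channel_model}.
#' @export
channel_model <- function(N_channels, gamma, z_delta, V_half,
                          dV_half_per_pH = -40, rate_scale = 0.2,
                          condition = ph_condition(6, 7),
                          P_open_max = 1, n_gating_steps = 1,
                          tau_min = 0.5) {
  stopifnot(N_channels >= 1, gamma > 0, rate_scale > 0,
            P_open_max > 0, P_open_max <= 1, n_gating_steps >= 1,
            tau_min >= 0)
  structure(
    list(N_channels = as.integer(round(N_channels)), gamma = gamma,
         z_delta = z_delta, V_half = V_half,
         dV_half_per_pH = dV_half_per_pH, rate_scale = rate_scale,
         condition = condition, P_open_max = P_open_max,
         n_gating_steps = as.integer(n_gating_steps), tau_min = tau_min),
    class = "channel_model"
  )
}

#' @export
print.channel_model <- function(x, ...) {
  cat(sprintf(paste0("channel model: N = %d, gamma = %.3g fS, z_delta = %.3g e0, ",
                     "V_half = %.3g mV, P_open_max = %.3g, %d gating step(s)\n"),
              x$N_channels, x$gamma, x$z_delta, x$V_half, x$P_open_max,
              x$n_gating_steps))
  invisible(x)
}

#' Re-reference a channel model to a different pH gradient
#'
#' Shifts V_half linearly by \code{dV_half_per_pH} times the change in
#' delta_pH and installs the new condition.
#'
#' @param model a \code{channel_model}.
#' @param condition the new \code{\link{ph_condition}}.
#' @return The shifted \code{channel_model}.
#' @export
shift_condition <- function(model, condition) {
  d <- condition$delta_pH - model$condition$delta_pH
  model$V_half <- model$V_half + model$dV_half_per_pH * d
  model$condition <- condition
  model
}

#' Recording artifacts for the simulator
#'
#' Linear leak, constant per-sweep offset (remnant capacitive / constant
#' leak current), white Gaussian instrumentation noise, and optional
#' multiplicative rundown across sweeps.
#'
#' @param leak_conductance leak conductance G_Leak, nS.
#' @param leak_reversal leak equilibrium potential V_Leak, mV.
#' @param residual_capacitive constant current offset per sweep, pA.
#' @param thermal_noise_sd white Gaussian noise SD, pA.
#' @param rundown_per_sweep fractional decay of channel current per sweep,
#'   in [0, 0.05].
#' @return An object of class \code{recording_artifacts}.
#' @export
recording_artifacts <- function(leak_conductance = 0, leak_reversal = 0,
                                residual_capacitive = 0,
                                thermal_noise_sd = 0,
                                rundown_per_sweep = 0) {
  stopifnot(leak_conductance >= 0, residual_capacitive >= 0 || TRUE,
            thermal_noise_sd >= 0,
            rundown_per_sweep >= 0, rundown_per_sweep <= 0.05)
  structure(
    list(leak_conductance = leak_conductance, leak_reversal = leak_reversal,
         residual_capacitive = residual_capacitive,
         thermal_noise_sd = thermal_noise_sd,
         rundown_per_sweep = rundown_per_sweep),
    class = "recording_artifacts"
  )
}

# Two-state gating rates at voltage V (vectorized).
# Returns list(alpha, beta, p_eq, tau) in ms^-1 / ms.
gating_rates <- function(model, V, temperature = hv_constants$T_default) {
  vt <- thermal_voltage(temperature)
  u <- model$z_delta * (V - model$V_half) / vt
  u0 <- model$z_delta * (0 - model$V_half) / vt
  a0 <- model$rate_scale * exp(-u0 / 2)
  alpha_b <- a0 * exp(u / 2)
  beta_b <- a0 * exp(-u / 2)
  tau <- pmax(1 / (alpha_b + beta_b), model$tau_min %||% 0)
  p_eq <- model$P_open_max / (1 + exp(-u))
  list(alpha = p_eq / tau, beta = (1 - p_eq) / tau, p_eq = p_eq, tau = tau)
}

#' Unitary current of a model at a voltage
#'
#' i = gamma (V - V_rev), in femtoamperes.
#'
#' @param model a \code{channel_model}.
#' @param V voltage, mV.
#' @param temperature temperature, K.
#' @return Unitary current, fA.
#' @export
unitary_current <- function(model, V, temperature = hv_constants$T_default) {
  v_rev <- nernst_potential(model$condition, temperature)
  model$gamma * (V - v_rev) * 1e-3  # fS * mV = 1e-3 fA
}

# Recycle a protocol's per-sweep segments to n sweeps.
recycle_protocol <- function(protocol, n_sweeps) {
  if (n_sweeps == protocol$sweep_count) return(protocol)
  idx <- ((seq_len(n_sweeps) - 1) %% protocol$sweep_count) + 1
  new_protocol(protocol$kind, protocol$holding_V, protocol$sample_interval,
               protocol$segments[idx], protocol$info)
}

#' Simulate a sweep ensemble of voltage-gated channels
#'
#' Aggregate binomial-update Markov-chain simulation: at each time step the
#' per-state channel counts evolve by binomial draws with transition
#' probabilities 1 - exp(-rate * dt) (competing forward/backward moves for
#' multi-step schemes). The macroscopic current is
#' n_open * gamma * (V - V_rev) plus leak, per-sweep offset and white
#' Gaussian noise. Identical seeds give identical ensembles.
#'
#' @param model a \code{\link{channel_model}}.
#' @param artifacts a \code{\link{recording_artifacts}} (default: none).
#' @param protocol a \code{\link{make_protocol}} object.
#' @param n_sweeps number of sweeps; defaults to the protocol's sweep
#'   count. A single-sweep protocol is repeated; a protocol family is
#'   recycled.
#' @param seed integer RNG seed (ignored in deterministic mode).
#' @param mode \code{"stochastic"} (binomial chain) or
#'   \code{"deterministic"} (expected-occupancy propagation, no channel
#'   noise and no instrumentation noise).
#' @param temperature temperature, K.
#' @return A \code{\link{sweep_ensemble}}; metadata records the generative
#'   parameters.
#' @export
simulate_ensemble <- function(model, artifacts = recording_artifacts(),
                              protocol, n_sweeps = protocol$sweep_count,
                              seed = 1,
                              mode = c("stochastic", "deterministic"),
                              temperature = hv_constants$T_default) {
  mode <- match.arg(mode)
  protocol <- recycle_protocol(protocol, n_sweeps)
  Vmat <- protocol_voltage(protocol)
  tt <- protocol_time(protocol)
  dt <- protocol$sample_interval
  n_t <- length(tt)
  m <- model$n_gating_steps
  N <- model$N_channels
  v_rev <- nernst_potential(model$condition, temperature)

  stochastic <- mode == "stochastic"
  if (stochastic) {
    # time-step sanity for the binomial updates: total leaving rate per state
    # (the deterministic expectation update is exact for the two-state chain
    # at any step size)
    r_max <- max_total_rate(model, Vmat)
    if (r_max * dt >= 1) {
      stop(sprintf("time-step error: rate*dt = %.3g >= 1; reduce sample_interval",
                   r_max * dt))
    }
    if (1 - exp(-r_max * dt) > 0.2) {
      warning("per-step transition probability exceeds 0.2; consider a smaller sample interval")
    }
    set.seed(as.integer(seed))
  }

  # state occupancy: counts (stochastic) or fractions (deterministic),
  # [n_sweeps x (m+1)] over states 0..m; open state = m + 1 column
  occ <- init_occupancy(model, Vmat[, 1], stochastic, temperature)
  n_open <- matrix(0, n_sweeps, n_t)
  n_open[, 1] <- occ[, m + 1]

  for (j in 2:n_t) {
    occ <- step_occupancy(model, occ, Vmat[, j], dt, stochastic, temperature)
    n_open[, j] <- occ[, m + 1]
  }

  i_pA <- model$gamma * (Vmat - v_rev) * 1e-6  # fS * mV = 1e-6 pA
  chan <- n_open * i_pA
  if (!stochastic) chan <- N * chan / 1  # occ already counts; see init

  if (artifacts$rundown_per_sweep > 0) {
    chan <- chan * (1 - artifacts$rundown_per_sweep)^(seq_len(n_sweeps) - 1)
  }
  leak <- artifacts$leak_conductance * (Vmat - artifacts$leak_reversal)
  sweeps <- chan + leak + artifacts$residual_capacitive
  if (stochastic && artifacts$thermal_noise_sd > 0) {
    sweeps <- sweeps + matrix(stats::rnorm(length(sweeps),
                                           sd = artifacts$thermal_noise_sd),
                              n_sweeps, n_t)
  }

  sweep_ensemble(protocol, sweeps, tt, condition = model$condition,
                 temperature = temperature,
                 metadata = list(generative_model = model,
                                 artifacts = artifacts, seed = seed,
                                 mode = mode))
}

max_total_rate <- function(model, Vmat) {
  vr <- range(Vmat)
  g <- gating_rates(model, seq(vr[1], vr[2], length.out = 64))
  m <- model$n_gating_steps
  max(m * g$alpha + m * g$beta)
}

# Equilibrium initial occupancy at the starting voltage.
init_occupancy <- function(model, V0, stochastic, temperature) {
  m <- model$n_gating_steps
  n_sweeps <- length(V0)
  g <- gating_rates(model, V0, temperature)
  occ <- matrix(0, n_sweeps, m + 1)
  # sequential chain with per-step forward m*alpha, backward m*beta:
  # stationary distribution proportional to (alpha/beta)^s
  for (k in seq_len(n_sweeps)) {
    r <- (g$alpha[k] / g$beta[k])
    w <- r^(0:m)
    p <- w / sum(w)
    if (stochastic) {
      occ[k, ] <- stats::rmultinom(1, model$N_channels, p)[, 1]
    } else {
      occ[k, ] <- p
    }
  }
  if (!stochastic) occ else occ
}

# One binomial (or expected-value) update of the state occupancy.
# Moves are drawn with the common total rate f + b and split by the rate
# shares; at the boundary states the disallowed direction's share stays
# put. For the two-state chain this reproduces the exact propagator
# (stationary ratio f/b and relaxation exp(-(f+b) dt)) at any step size.
step_occupancy <- function(model, occ, V, dt, stochastic, temperature) {
  m <- model$n_gating_steps
  g <- gating_rates(model, V, temperature)
  f <- m * g$alpha   # per-step forward rate
  b <- m * g$beta    # per-step backward rate
  tot <- f + b
  p_move <- 1 - exp(-tot * dt)
  share_up <- f / tot
  share_dn <- b / tot
  new_occ <- occ * 0
  for (s in 0:m) {
    n_s <- occ[, s + 1]
    if (stochastic) {
      movers <- stats::rbinom(length(n_s), n_s, p_move)
      up <- if (s < m) stats::rbinom(length(movers), movers, share_up) else 0
      down <- if (s > 0) {
        if (s < m) movers - up
        else stats::rbinom(length(movers), movers, share_dn)
      } else 0
    } else {
      movers <- n_s * p_move
      up <- if (s < m) movers * share_up else 0
      down <- if (s > 0) movers * share_dn else 0
    }
    new_occ[, s + 1] <- new_occ[, s + 1] + n_s - up - down
    if (s < m) new_occ[, s + 2] <- new_occ[, s + 2] + up
    if (s > 0) new_occ[, s] <- new_occ[, s] + down
  }
  new_occ
}

#' Simulate a mixed-isoform current ensemble
#'
#' Sum of independent component ensembles, emulating a membrane expressing
#' several channel isoforms (e.g. the three Hv1 isoforms of a native cell).
#'
#' @param models list of \code{\link{channel_model}}s (>= 1).
#' @param weights non-negative weights scaling each component's channel
#'   count (default all 1).
#' @param artifacts \code{\link{recording_artifacts}} applied once to the
#'   summed current (noise and leak are not duplicated per component).
#' @param protocol a voltage protocol.
#' @param n_sweeps sweeps per component.
#' @param seed integer seed; component k uses \code{seed + k - 1}.
#' @param mode passed to \code{\link{simulate_ensemble}}.
#' @param temperature temperature, K.
#' @return A \code{\link{sweep_ensemble}} of the summed current.
#' @export
mixture_current <- function(models, weights = rep(1, length(models)),
                            artifacts = recording_artifacts(),
                            protocol, n_sweeps = protocol$sweep_count,
                            seed = 1, mode = "stochastic",
                            temperature = hv_constants$T_default) {
  if (length(models) < 1) stop("empty component list")
  if (length(weights) != length(models)) stop("one weight per model required")
  clean <- recording_artifacts()
  total <- NULL
  out <- NULL
  for (k in seq_along(models)) {
    mk <- models[[k]]
    Nk <- round(weights[k] * mk$N_channels)
    if (Nk < 1) next
    mk$N_channels <- as.integer(Nk)
    ens <- simulate_ensemble(mk, clean, protocol, n_sweeps,
                             seed = seed + k - 1, mode = mode,
                             temperature = temperature)
    total <- if (is.null(total)) ens$sweeps else total + ens$sweeps
    out <- ens
  }
  if (is.null(total)) stop("all mixture components have zero channels")
  Vmat <- protocol_voltage(out$protocol)
  total <- total +
    artifacts$leak_conductance * (Vmat - artifacts$leak_reversal) +
    artifacts$residual_capacitive
  if (mode == "stochastic" && artifacts$thermal_noise_sd > 0) {
    set.seed(as.integer(seed) + length(models))
    total <- total + matrix(stats::rnorm(length(total),
                                         sd = artifacts$thermal_noise_sd),
                            nrow(total), ncol(total))
  }
  sweep_ensemble(out$protocol, total, out$time, condition = out$condition,
                 temperature = temperature,
                 metadata = list(mixture_models = models, weights = weights,
                                 artifacts = artifacts, seed = seed,
                                 mode = mode))
}
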