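#' Build a voltage-clamp protocol
#'
#' Three protocol families are supported, mirroring common Hv1 macro-patch
#' designs:
#' \describe{
#'   \item{\code{step_family}}{holding, a family of depolarizing steps at a
#'     fixed increment, then a common tail potential (for IV curves, tail
#'     GV curves, tau-V curves and noise analysis).}
#'   \item{\code{pulse_with_ramp}}{a depolarizing pulse of (optionally
#'     per-sweep variable) duration followed by a fast linear voltage ramp
#'     from depolarized to hyperpolarized potentials (for reversal-potential
#'     estimation by the current-crossing / variance-minimum method).
#'     Sweeps are left-padded at holding so the ramp is sample-aligned
#'     across sweeps.}
#'   \item{\code{slow_ramp}}{a slow symmetric up-down voltage ramp
#'     (0.5--1 mV/s) that keeps gating at equilibrium (for the limiting
#'     slope method).}
#' }
#'
#' @param kind one of \code{"step_family"}, \code{"pulse_with_ramp"},
#'   \code{"slow_ramp"}.
#' @param ... kind-specific parameters, see Details.
#'
#' @details
#' \code{step_family} parameters: \code{V_from} (-80), \code{V_to} (+100),
#' \code{dV} (10) mV; \code{pre_ms} (20), \code{pulse_ms} (200),
#' \code{tail_ms} (50) ms; \code{tail_V} (-100), \code{holding_V} (-80) mV;
#' \code{sample_interval} (0.5 ms).
#'
#' \code{pulse_with_ramp} parameters: \code{pulse_V} (+100 mV),
#' \code{pulse_ms} (vector of per-sweep pulse durations, default
#' \code{c(50, 100, 150, 200, 250)}), \code{ramp_from} (+100),
#' \code{ramp_to} (-100) mV, \code{ramp_ms} (50), \code{pre_ms} (10),
#' \code{post_ms} (10) ms, \code{holding_V} (-60 mV),
#' \code{sample_interval} (0.1 ms).
#'
#' \code{slow_ramp} parameters: \code{V_from} (-120), \code{V_to} (+80) mV,
#' \code{rate} (1 mV/s), \code{symmetric} (TRUE), \code{holding_V}
#' (\code{V_from}), \code{sample_interval} (20 ms).
#'
#' @return An object of class \code{voltage_protocol}: fields \code{kind},
#'   \code{holding_V}, \code{sample_interval} (ms), \code{sweep_count},
#'   \code{segments} (per-sweep list of data frames with columns
#'   \code{duration}, \code{V_start}, \code{V_end}) and kind-specific
#'   \code{info}.
#' @export
make_protocol <- function(kind = c("step_family", "pulse_with_ramp", "slow_ramp"),
                          ...) {
  kind <- match.arg(kind)
  switch(kind,
    step_family = protocol_step_family(...),
    pulse_with_ramp = protocol_pulse_with_ramp(...),
    slow_ramp = protocol_slow_ramp(...)
  )
}

new_protocol <- function(kind, holding_V, sample_interval, segments, info) {
  stopifnot(sample_interval > 0)
  durs <- vapply(segments, function(s) sum(s$duration), numeric(1))
  if (any(vapply(segments, function(s) any(s$duration <= 0), logical(1)))) {
    stop("all segment durations must be positive")
  }
  if (max(durs) - min(durs) > 1e-9) {
    stop("inconsistent segment spec: sweeps differ in total duration")
  }
  structure(
    list(kind = kind, holding_V = holding_V,
         sample_interval = sample_interval,
         sweep_count = length(segments),
         segments = segments, info = info),
    class = "voltage_protocol"
  )
}

protocol_step_family <- function(V_from = -80, V_to = 100, dV = 10,
                                 pre_ms = 20, pulse_ms = 200, tail_ms = 50,
                                 tail_V = -100, holding_V = -80,
                                 sample_interval = 0.5) {
  if (dV == 0 || (V_to - V_from) / dV < 0) stop("inconsistent step range")
  step_V <- seq(V_from, V_to, by = dV)
  segments <- lapply(step_V, function(v) {
    data.frame(duration = c(pre_ms, pulse_ms, tail_ms),
               V_start = c(holding_V, v, tail_V),
               V_end = c(holding_V, v, tail_V))
  })
  new_protocol("step_family", holding_V, sample_interval, segments,
               info = list(step_V = step_V, pre_ms = pre_ms,
                           pulse_ms = pulse_ms, tail_ms = tail_ms,
                           tail_V = tail_V))
}

protocol_pulse_with_ramp <- function(pulse_V = 100,
                                     pulse_ms = c(50, 100, 150, 200, 250),
                                     ramp_from = 100, ramp_to = -100,
                                     ramp_ms = 50, pre_ms = 10, post_ms = 10,
                                     holding_V = -60, sample_interval = 0.1) {
  if (length(pulse_ms) < 1 || any(pulse_ms <= 0)) stop("invalid pulse durations")
  max_pulse <- max(pulse_ms)
  segments <- lapply(pulse_ms, function(d) {
    pad <- pre_ms + (max_pulse - d)
    data.frame(duration = c(pad, d, ramp_ms, post_ms),
               V_start = c(holding_V, pulse_V, ramp_from, holding_V),
               V_end = c(holding_V, pulse_V, ramp_to, holding_V))
  })
  new_protocol("pulse_with_ramp", holding_V, sample_interval, segments,
               info = list(pulse_V = pulse_V, pulse_ms = pulse_ms,
                           ramp_from = ramp_from, ramp_to = ramp_to,
                           ramp_ms = ramp_ms, pre_ms = pre_ms,
                           post_ms = post_ms, max_pulse = max_pulse))
}

protocol_slow_ramp <- function(V_from = -120, V_to = 80, rate = 1,
                               symmetric = TRUE, holding_V = V_from,
                               sample_interval = 20) {
  if (rate <= 0) stop("ramp rate must be positive")
  if (rate < 0.5 || rate > 1) {
    warning(sprintf("slow ramp rate %.3g mV/s outside the usual 0.5-1 mV/s range", rate))
  }
  dur_ms <- abs(V_to - V_from) / rate * 1000
  seg <- data.frame(duration = dur_ms, V_start = V_from, V_end = V_to)
  if (symmetric) {
    seg <- rbind(seg, data.frame(duration = dur_ms, V_start = V_to, V_end = V_from))
  }
  new_protocol("slow_ramp", holding_V, sample_interval, list(seg),
               info = list(rate = rate, symmetric = symmetric,
                           V_from = V_from, V_to = V_to))
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("voltage protocol '%s': %d sweep(s), %.4g ms sample interval, %.4g ms/sweep\n",
              x$kind, x$sweep_count, x$sample_interval,
              sum(x$segments[[1]]$duration)))
  invisible(x)
}

#' Time base of a protocol
#'
#' @param protocol a \code{voltage_protocol}.
#' @return Sample times in ms, 0-based at sweep start.
#' @export
protocol_time <- function(protocol) {
  total <- sum(protocol$segments[[1]]$duration)
  n <- floor(total / protocol$sample_interval + 1e-9)
  seq(0, by = protocol$sample_interval, length.out = n)
}

#' Command-voltage matrix of a protocol
#'
#' @param protocol a \code{voltage_protocol}.
#' @return Matrix [sweep_count x n_samples] of command voltage (mV).
#' @export
protocol_voltage <- function(protocol) {
  tt <- protocol_time(protocol)
  V <- matrix(NA_real_, protocol$sweep_count, length(tt))
  for (k in seq_len(protocol$sweep_count)) {
    seg <- protocol$segments[[k]]
    bounds <- cumsum(c(0, seg$duration))
    idx <- findInterval(tt, bounds, rightmost.closed = TRUE)
    idx[idx > nrow(seg)] <- nrow(seg)
    frac <- (tt - bounds[idx]) / seg$duration[idx]
    V[k, ] <- seg$V_start[idx] + (seg$V_end[idx] - seg$V_start[idx]) * frac
  }
  V
}

# Sample-index window of segment `segment` for sweep `sweep`.
segment_window <- function(protocol, segment, sweep = 1) {
  seg <- protocol$segments[[sweep]]
  stopifnot(segment >= 1, segment <= nrow(seg))
  bounds <- cumsum(c(0, seg$duration))
  tt <- protocol_time(protocol)
  which(tt >= bounds[segment] - 1e-9 & tt < bounds[segment + 1] - 1e-9)
}

#' Construct a sweep ensemble
#'
#' The central data container: a family of aligned repeated current sweeps
#' plus the voltage protocol that elicited them.
#'
#' @param protocol a \code{voltage_protocol}.
#' @param sweeps numeric matrix [n_sweeps x n_samples] of current, pA.
#' @param time sample times in ms (defaults to the protocol time base).
#' @param condition a \code{\link{ph_condition}}.
#' @param temperature temperature, K.
#' @param metadata free-form named list of labels.
#' @return An object of class \code{sweep_ensemble}.
#' @export
sweep_ensemble <- function(protocol, sweeps, time = protocol_time(protocol),
                           condition = ph_condition(7, 7),
                           temperature = hv_constants$T_default,
                           metadata = list()) {
  sweeps <- as.matrix(sweeps)
  if (nrow(sweeps) < 1) stop("ensemble needs at least one sweep")
  if (ncol(sweeps) != length(time)) stop("sweeps and time base disagree in length")
  if (length(time) >= 2) {
    dt <- diff(time)
    if (any(dt <= 0)) stop("time must be strictly increasing")
    if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
      stop("time base must be uniformly spaced")
    }
  }
  structure(
    list(protocol = protocol, sweeps = sweeps, time = time,
         condition = condition, temperature = temperature,
         metadata = metadata),
    class = "sweep_ensemble"
  )
}

#' @export
print.sweep_ensemble <- function(x, ...) {
  cat(sprintf("sweep ensemble: %d sweep(s) x %d samples (%.4g ms), protocol '%s'\n",
              nrow(x$sweeps), ncol(x$sweeps),
              utils::tail(x$time, 1), x$protocol$kind))
  print(x$condition)
  invisible(x)
}

#' @export
dim.sweep_ensemble <- function(x) dim(x$sweeps)
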