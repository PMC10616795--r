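#' Off-line linear leak subtraction
#'
#' Fits a linear leak I = G_Leak (V - V_Leak) to the end-pulse steady
#' currents of subthreshold sweeps (voltages where the channel stays
#' closed), subtracts it from every sweep using the command voltage, and
#' removes the remaining constant offset by re-baselining each sweep on its
#' pre-pulse holding period.
#'
#' @param ensemble a step-family \code{\link{sweep_ensemble}}.
#' @param subthreshold_window numeric length-2: voltage range (mV) whose
#'   steps are treated as pure leak (>= 2 step voltages must fall inside).
#' @param end_window_fraction fraction of the pulse used for the steady
#'   current (default 0.05).
#' @return The leak-subtracted ensemble; \code{metadata$leak_fit} records
#'   the fitted \code{G_Leak} (nS) and \code{V_Leak} (mV).
#' @export
subtract_leak <- function(ensemble, subthreshold_window,
                          end_window_fraction = 0.05) {
  iv <- extract_iv(ensemble, end_window_fraction)
  sel <- iv$V >= subthreshold_window[1] & iv$V <= subthreshold_window[2]
  if (sum(sel) < 2) {
    stop("leak fit is singular: need >= 2 subthreshold step voltages")
  }
  lf <- stats::lm(I_end ~ V, data = iv[sel, ])
  g_leak <- unname(stats::coef(lf)[2])
  v_leak <- if (abs(g_leak) > 1e-12) -unname(stats::coef(lf)[1]) / g_leak else 0
  Vmat <- protocol_voltage(ensemble$protocol)
  corrected <- ensemble$sweeps - g_leak * (Vmat - v_leak)
  # re-baseline on the pre-pulse holding segment
  for (k in seq_len(nrow(corrected))) {
    w <- segment_window(ensemble$protocol, 1, k)
    if (length(w) >= 1) corrected[k, ] <- corrected[k, ] - mean(corrected[k, w])
  }
  out <- ensemble
  out$sweeps <- corrected
  out$metadata$leak_fit <- list(G_Leak = g_leak, V_Leak = v_leak,
                                n_subthreshold = sum(sel))
  out
}

#' Extract the end-pulse current-voltage relation
#'
#' Mean current over the last \code{end_window_fraction} of each
#' depolarizing pulse, per step voltage.
#'
#' @param ensemble a step-family \code{\link{sweep_ensemble}}.
#' @param end_window_fraction fraction of the pulse averaged (default 5\%).
#' @return Data frame with columns \code{V} (step voltage, mV) and
#'   \code{I_end} (pA).
#' @export
extract_iv <- function(ensemble, end_window_fraction = 0.05) {
  if (ensemble$protocol$kind != "step_family") {
    stop("extract_iv requires a step_family protocol")
  }
  n_sweeps <- nrow(ensemble$sweeps)
  if (n_sweeps < 1) stop("empty sweep set")
  V <- numeric(n_sweeps); I_end <- numeric(n_sweeps)
  for (k in seq_len(n_sweeps)) {
    w <- segment_window(ensemble$protocol, 2, k)
    n_keep <- max(floor(length(w) * end_window_fraction), 1)
    if (n_keep < 3) stop("end-of-pulse window shorter than 3 samples")
    w <- utils::tail(w, n_keep)
    seg <- ensemble$protocol$segments[[k]]
    V[k] <- seg$V_start[2]
    I_end[k] <- mean(ensemble$sweeps[k, w])
  }
  agg <- stats::aggregate(I_end, list(V = V), mean)
  data.frame(V = agg$V, I_end = agg$x)
}

#' Boltzmann fit of an IV relation
#'
#' Fits the normalized Boltzmann current-voltage relation
#' I = I_max / (1 + exp(-z_delta F (V - V_0.5)/RT)) to end-pulse currents.
#'
#' @param points data frame from \code{\link{extract_iv}} (columns \code{V},
#'   \code{I_end}).
#' @param temperature temperature, K.
#' @param weights optional fit weights.
#' @return A \code{\link{fit_boltzmann}} object.
#' @export
fit_boltzmann_iv <- function(points, temperature = hv_constants$T_default,
                             weights = NULL) {
  fit_boltzmann(points$V, points$I_end, temperature, weights,
                response = "current")
}

#' Extract an isochronal tail-conductance GV relation
#'
#' Reads the tail-current amplitude at a fixed isochrone after the step to
#' the common tail potential (skipping the capacitive settle) and converts
#' it to conductance, G = I_tail / (V_tail - V_rev): a driving-force-free
#' readout of the open probability reached at each step voltage.
#'
#' @param ensemble a step-family \code{\link{sweep_ensemble}} whose
#'   protocol has a common tail potential.
#' @param isochrone_ms time after the tail step at which the amplitude is
#'   read (default 0.5 ms).
#' @param V_rev reversal potential, mV; defaults to the Nernst potential of
#'   the ensemble's pH condition.
#' @param window_ms averaging window around the isochrone (default one
#'   sample).
#' @return Data frame with columns \code{V} (step voltage), \code{I_tail}
#'   (pA) and \code{G_tail} (nS).
#' @export
extract_tail_gv <- function(ensemble, isochrone_ms = 0.5, V_rev = NULL,
                            window_ms = 0) {
  if (ensemble$protocol$kind != "step_family") {
    stop("extract_tail_gv requires a step_family protocol")
  }
  v_tail <- ensemble$protocol$info$tail_V
  if (is.null(v_tail)) stop("protocol lacks a common tail potential")
  if (is.null(V_rev)) {
    V_rev <- nernst_potential(ensemble$condition, ensemble$temperature)
  }
  if (abs(v_tail - V_rev) < 1e-9) {
    stop("tail potential equals V_rev: conductance undefined")
  }
  n_sweeps <- nrow(ensemble$sweeps)
  dt <- ensemble$protocol$sample_interval
  V <- numeric(n_sweeps); I_tail <- numeric(n_sweeps)
  for (k in seq_len(n_sweeps)) {
    w <- segment_window(ensemble$protocol, 3, k)
    i0 <- w[1] + round(isochrone_ms / dt)
    i1 <- i0 + max(round(window_ms / dt), 0)
    i1 <- min(i1, utils::tail(w, 1))
    if (i0 > utils::tail(w, 1)) stop("isochrone falls beyond the tail segment")
    V[k] <- ensemble$protocol$segments[[k]]$V_start[2]
    I_tail[k] <- mean(ensemble$sweeps[k, i0:i1])
  }
  agg <- stats::aggregate(I_tail, list(V = V), mean)
  data.frame(V = agg$V, I_tail = agg$x, G_tail = agg$x / (v_tail - V_rev))
}

#' Boltzmann fit of a tail-conductance GV relation
#'
#' Fits G = G_max / (1 + exp(-z_delta F (V - V_0.5)/RT)) to isochronal tail
#' conductances.
#'
#' @param points data frame with columns \code{V} and \code{G_tail} (or
#'   \code{G}).
#' @param temperature temperature, K.
#' @param weights optional fit weights.
#' @return A \code{\link{fit_boltzmann}} object.
#' @export
fit_boltzmann_gv <- function(points, temperature = hv_constants$T_default,
                             weights = NULL) {
  g <- if (!is.null(points$G_tail)) points$G_tail else points$G
  fit_boltzmann(points$V, g, temperature, weights, response = "conductance")
}

#' GV relation from ON (end-pulse) currents
#'
#' Whole-cell-style conversion of end-pulse currents to conductance by
#' Ohm's law, G = I_end / (V - V_rev), excluding voltages within
#' \code{exclude_mV} of the reversal potential where the driving force is
#' ill-conditioned.
#'
#' @param ensemble a step-family \code{\link{sweep_ensemble}}.
#' @param V_rev reversal potential, mV (default: Nernst of the condition).
#' @param end_window_fraction passed to \code{\link{extract_iv}}.
#' @param exclude_mV half-width of the excluded band around V_rev.
#' @return Data frame with columns \code{V} and \code{G}.
#' @export
extract_on_gv <- function(ensemble, V_rev = NULL, end_window_fraction = 0.05,
                          exclude_mV = 10) {
  if (is.null(V_rev)) {
    V_rev <- nernst_potential(ensemble$condition, ensemble$temperature)
  }
  iv <- extract_iv(ensemble, end_window_fraction)
  keep <- abs(iv$V - V_rev) > exclude_mV
  data.frame(V = iv$V[keep], G = iv$I_end[keep] / (iv$V[keep] - V_rev))
}
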