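#' Reversal potential from the variance minimum of fast-ramp currents
#'
#' Sweeps with different pre-ramp activation levels (variable-duration
#' pulses) carry different channel conductances into the fast ramp, so
#' their currents diverge everywhere except at the reversal potential,
#' where the driving force -- and hence every channel's current -- is zero
#' and the traces cross. The across-sweep variance along the ramp is
#' therefore minimal at V = V_rev.
#'
#' The first \code{discard_fraction} of the ramp is dropped (residual
#' capacitive transient at the ramp onset) and the variance profile is
#' smoothed with a centered moving average of width \code{window_mV} before
#' locating the minimum. Ties are broken by the voltage closest to the
#' median of all minimizing samples.
#'
#' @param ensemble a \code{\link{sweep_ensemble}} with a
#'   \code{pulse_with_ramp} protocol, leak-subtracted.
#' @param window_mV smoothing width in mV (default 0.5).
#' @param discard_fraction fraction of ramp samples dropped at the ramp
#'   onset (default 0.05).
#' @return Object of class \code{vrev_estimate}: \code{V_rev} (mV), the
#'   \code{variance_profile} (data frame of V, variance), \code{window_mV}
#'   and the ensemble's pH \code{condition}.
#' @export
estimate_vrev_crossing <- function(ensemble, window_mV = 0.5,
                                   discard_fraction = 0.05) {
  if (ensemble$protocol$kind != "pulse_with_ramp") {
    stop("estimate_vrev_crossing requires a pulse_with_ramp protocol")
  }
  if (nrow(ensemble$sweeps) < 3) {
    stop("need >= 3 sweeps with distinct activation levels")
  }
  w <- segment_window(ensemble$protocol, 3, 1)  # ramp is segment 3
  drop_n <- floor(length(w) * discard_fraction)
  if (drop_n > 0) w <- w[-seq_len(drop_n)]
  Vramp <- protocol_voltage(ensemble$protocol)[1, w]
  v <- apply(ensemble$sweeps[, w, drop = FALSE], 2, stats::var)
  if (max(v) - min(v) < max(1e-20, 1e-6 * stats::median(v))) {
    stop("no-crossing error: flat variance profile (sweeps indistinguishable)")
  }
  dV <- abs(stats::median(diff(Vramp)))
  k <- max(1, round(window_mV / dV))
  if (k %% 2 == 0) k <- k + 1
  sv <- if (k > 1) stats::filter(v, rep(1 / k, k), sides = 2) else v
  sv <- as.numeric(sv)
  valid <- which(is.finite(sv))
  mins <- valid[sv[valid] == min(sv[valid])]
  target <- stats::median(Vramp[mins])
  best <- mins[which.min(abs(Vramp[mins] - target))]
  if (best <= valid[1] || best >= valid[length(valid)]) {
    warning("variance minimum lies at the ramp boundary; V_rev may be outside the ramp span")
  }
  structure(
    list(V_rev = Vramp[best],
         variance_profile = data.frame(V = Vramp, variance = v),
         window_mV = window_mV, condition = ensemble$condition),
    class = "vrev_estimate"
  )
}

#' @export
print.vrev_estimate <- function(x, ...) {
  cat(sprintf("reversal potential estimate: V_rev = %.2f mV (delta pH = %+.2f, %.2g mV smoothing)\n",
              x$V_rev, x$condition$delta_pH, x$window_mV))
  invisible(x)
}

#' @export
plot.vrev_estimate <- function(x, ...) {
  graphics::plot(x$variance_profile$V, x$variance_profile$variance,
                 type = "l", xlab = "V (mV)", ylab = "across-sweep variance (pA^2)",
                 ...)
  graphics::abline(v = x$V_rev, lty = 2)
  invisible(x)
}

#' Nernst-slope regression of reversal potentials across pH gradients
#'
#' Ordinary least squares of V_rev on delta_pH. A purely proton-selective
#' channel gives the Nernstian slope -ln(10) RT/F (about -58.4 mV per
#' delta_pH unit at 294.15 K); mixed selectivity flattens the slope.
#'
#' @param estimates list of \code{vrev_estimate}s, or a data frame with
#'   columns \code{delta_pH} and \code{V_rev}.
#' @return Object of class \code{nernst_regression}: \code{slope} (mV per
#'   delta_pH unit), \code{intercept} (mV), standard errors and the
#'   underlying \code{lm} fit.
#' @export
nernst_regression <- function(estimates) {
  if (is.data.frame(estimates)) {
    d <- estimates
  } else {
    d <- data.frame(
      delta_pH = vapply(estimates, function(e) e$condition$delta_pH, numeric(1)),
      V_rev = vapply(estimates, function(e) e$V_rev, numeric(1))
    )
  }
  if (nrow(d) < 2) stop("need at least 2 reversal-potential points")
  if (length(unique(d$delta_pH)) < 3) {
    warning("fewer than 3 distinct pH gradients: slope weakly constrained")
  }
  lf <- stats::lm(V_rev ~ delta_pH, data = d)
  cf <- stats::coef(lf)
  se <- tryCatch(suppressWarnings(summary(lf)$coefficients[, "Std. Error"]),
                 error = function(e) c(NA, NA))
  structure(
    list(slope = unname(cf[2]), intercept = unname(cf[1]),
         se_slope = unname(se[2]), se_intercept = unname(se[1]),
         data = d, fit = lf),
    class = "nernst_regression"
  )
}

#' @export
print.nernst_regression <- function(x, ...) {
  cat(sprintf("Nernst-slope regression: slope %.2f mV/delta_pH (SE %.3g), intercept %.2f mV, n = %d\n",
              x$slope, x$se_slope, x$intercept, nrow(x$data)))
  invisible(x)
}

#' @export
coef.nernst_regression <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}
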