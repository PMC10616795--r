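#' Fit a Boltzmann activation curve to amplitude-voltage data
#'
#' Nonlinear least squares (Levenberg-Marquardt) fit of
#' y = amplitude_max / (1 + exp(-z_delta F (V - V_half) / RT)) to measured
#' currents or conductances. Starting values are derived from the data
#' (amplitude from the largest response, midpoint from linear interpolation
#' of the half-maximal crossing, charge from a logit-linear regression).
#'
#' @param V voltages, mV (>= 5 points recommended, spanning the midpoint).
#' @param y amplitudes: currents (pA) or conductances (nS).
#' @param temperature temperature, K.
#' @param weights optional least-squares weights (default unweighted).
#' @param response label, \code{"current"} or \code{"conductance"}.
#' @return Object of class \code{boltzmann_fit} with fields
#'   \code{amplitude_max}, \code{z_delta}, \code{V_half}, standard errors
#'   \code{se_amplitude}, \code{se_z_delta}, \code{se_V_half},
#'   \code{residual_rms}, the underlying \code{nls} fit and the data.
#' @export
fit_boltzmann <- function(V, y, temperature = hv_constants$T_default,
                          weights = NULL,
                          response = c("current", "conductance")) {
  response <- match.arg(response)
  ok <- is.finite(V) & is.finite(y)
  V <- V[ok]; y <- y[ok]
  if (length(V) < 5) stop("need at least 5 finite points to fit a Boltzmann")
  vt <- thermal_voltage(temperature)
  start <- boltzmann_start(V, y, vt)
  dat <- data.frame(V = V, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ amp / (1 + exp(-z * (V - vh) / vt)),
      data = dat, start = start,
      lower = c(amp = 0, z = 1e-3, vh = -Inf),
      weights = if (is.null(weights)) rep(1, length(y)) else weights,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop(sprintf(
      "Boltzmann fit failed: %s (start: amp %.3g, z %.3g, vh %.3g)",
      conditionMessage(e), start$amp, start$z, start$vh))
  )
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  if (cf[["vh"]] < min(V) || cf[["vh"]] > max(V)) {
    warning(sprintf("fitted V_half (%.1f mV) lies outside the sampled range [%.0f, %.0f]: estimates poorly constrained",
                    cf[["vh"]], min(V), max(V)))
  }
  structure(
    list(amplitude_max = unname(cf["amp"]), z_delta = unname(cf["z"]),
         V_half = unname(cf["vh"]),
         se_amplitude = unname(se["amp"]), se_z_delta = unname(se["z"]),
         se_V_half = unname(se["vh"]),
         residual_rms = sqrt(mean(stats::residuals(fit)^2)),
         temperature = temperature, response = response,
         data = dat, fit = fit),
    class = "boltzmann_fit"
  )
}

boltzmann_start <- function(V, y, vt) {
  o <- order(V)
  V <- V[o]; y <- y[o]
  amp <- max(y)
  if (amp <= 0) amp <- max(abs(y)) + .Machine$double.eps
  half <- amp / 2
  above <- which(y >= half)
  vh <- if (length(above) && above[1] > 1) {
    i <- above[1]
    V[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (V[i] - V[i - 1])
  } else stats::median(V)
  # logit-linear slope -> z/vt
  p <- pmin(pmax(y / (amp * 1.001), 1e-4), 1 - 1e-4)
  sl <- stats::coef(stats::lm(stats::qlogis(p) ~ V))[2]
  z <- max(min(unname(sl) * vt, 20), 0.2)
  list(amp = amp * 1.02, z = z, vh = vh)
}

#' @export
print.boltzmann_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Boltzmann fit (%s)\n", x$response))
  unit <- if (x$response == "current") "pA" else "nS"
  cat(sprintf("  %s_max : %s %s (SE %s)\n",
              if (x$response == "current") "I" else "G",
              format(x$amplitude_max, digits = digits), unit,
              format(x$se_amplitude, digits = 3)))
  cat(sprintf("  z_delta: %s e0 (SE %s)\n",
              format(x$z_delta, digits = digits), format(x$se_z_delta, digits = 3)))
  cat(sprintf("  V_half : %s mV (SE %s)\n",
              format(x$V_half, digits = digits), format(x$se_V_half, digits = 3)))
  cat(sprintf("  residual RMS: %s %s on %d points\n",
              format(x$residual_rms, digits = 3), unit, nrow(x$data)))
  invisible(x)
}

#' @export
summary.boltzmann_fit <- function(object, ...) {
  est <- c(amplitude_max = object$amplitude_max, z_delta = object$z_delta,
           V_half = object$V_half)
  se <- c(object$se_amplitude, object$se_z_delta, object$se_V_half)
  out <- list(coefficients = cbind(Estimate = est, `Std. Error` = se),
              residual_rms = object$residual_rms, n = nrow(object$data),
              response = object$response)
  class(out) <- "summary.boltzmann_fit"
  out
}

#' @export
print.summary.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann fit (%s), %d points, residual RMS %.4g\n",
              x$response, x$n, x$residual_rms))
  stats::printCoefmat(x$coefficients)
  invisible(x)
}

#' @export
coef.boltzmann_fit <- function(object, ...) {
  c(amplitude_max = object$amplitude_max, z_delta = object$z_delta,
    V_half = object$V_half)
}

#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  V <- if (is.null(newdata)) object$data$V
       else if (is.list(newdata)) newdata$V else newdata
  boltzmann_curve(V, object$amplitude_max, object$z_delta, object$V_half,
                  object$temperature)
}

#' @export
residuals.boltzmann_fit <- function(object, ...) {
  object$data$y - predict(object)
}

#' @export
plot.boltzmann_fit <- function(x, ...) {
  unit <- if (x$response == "current") "pA" else "nS"
  graphics::plot(x$data$V, x$data$y, xlab = "V (mV)",
                 ylab = sprintf("%s (%s)", x$response, unit), ...)
  vv <- seq(min(x$data$V), max(x$data$V), length.out = 200)
  graphics::lines(vv, predict(x, vv))
  graphics::abline(v = x$V_half, lty = 3)
  invisible(x)
}
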