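#' Preprocess a slow-ramp recording into a conductance-voltage curve
#'
#' The limiting-slope pipeline: optional 10 Hz low-pass filtering (4-pole
#' digital filter, applied forward-backward for zero phase; used when
#' external noise contaminates the recording), 5-point block averaging
#' (decimation), Ohmic conversion to conductance with the known reversal
#' potential, and mean-binning into 100 equal-voltage bins. Only the
#' rising (hyperpolarized to depolarized) limb of the symmetric ramp is
#' used.
#'
#' @param ensemble a \code{\link{sweep_ensemble}} with a \code{slow_ramp}
#'   protocol, leak-subtracted.
#' @param V_rev reversal potential, mV (default: Nernst of the condition).
#' @param filter_hz optional low-pass cutoff in Hz (e.g. 10); NULL skips
#'   filtering.
#' @param decimate block size for the decimating average (default 5).
#' @param bins number of equal-voltage mean bins (default 100).
#' @return Data frame with columns \code{V} (mV) and \code{G} (nS), at most
#'   \code{bins} rows.
#' @export
preprocess_ramp <- function(ensemble, V_rev = NULL, filter_hz = NULL,
                            decimate = 5, bins = 100) {
  if (ensemble$protocol$kind != "slow_ramp") {
    stop("preprocess_ramp requires a slow_ramp protocol")
  }
  rate <- ensemble$protocol$info$rate
  if (!is.null(rate) && rate > 2) {
    warning("ramp faster than 2 mV/s: gating may not be at equilibrium")
  }
  if (is.null(V_rev)) {
    V_rev <- nernst_potential(ensemble$condition, ensemble$temperature)
  }
  seg <- ensemble$protocol$segments[[1]]
  rising <- which(seg$V_end > seg$V_start)[1]
  if (is.na(rising)) rising <- 1
  w <- segment_window(ensemble$protocol, rising, 1)
  V <- protocol_voltage(ensemble$protocol)[1, w]
  I <- colMeans(ensemble$sweeps[, w, drop = FALSE])
  if (!is.null(filter_hz)) {
    fs <- 1000 / ensemble$protocol$sample_interval  # Hz
    wn <- min(filter_hz / (fs / 2), 0.99)
    bf <- signal::butter(4, wn, type = "low")
    I <- as.numeric(signal::filtfilt(bf, I))
  }
  if (decimate > 1) {
    n <- floor(length(I) / decimate) * decimate
    grp <- rep(seq_len(n / decimate), each = decimate)
    I <- tapply(I[seq_len(n)], grp, mean)
    V <- tapply(V[seq_len(n)], grp, mean)
  }
  keep <- abs(V - V_rev) > 1e-9
  G <- I[keep] / (V[keep] - V_rev)
  V <- V[keep]
  cut_id <- cut(V, breaks = bins, labels = FALSE)
  data.frame(
    V = as.numeric(tapply(V, cut_id, mean)),
    G = as.numeric(tapply(G, cut_id, mean))
  )
}

#' Limiting-slope estimate of the effective gating charge
#'
#' At very low open probability the logarithmic voltage sensitivity of the
#' conductance converges to the total gating charge:
#' z_delta(V) = (kT/e0) d(ln G)/dV approaches z_delta_eff as the open
#' probability vanishes. The profile is computed by central finite
#' differences of ln G on the binned curve; the plateau value is the
#' median of z_delta(V) over the region G/G_max below \code{Po_threshold}.
#' Two companion estimates are reported: the slope of the log-linear
#' exponential fit G = G0 exp(z_delta F V / RT) over the same region, and
#' the steepness of a Boltzmann fit of the full curve.
#'
#' @param curve data frame from \code{\link{preprocess_ramp}} (columns
#'   \code{V}, \code{G}).
#' @param Po_threshold open-probability ceiling defining the limiting
#'   region (default 0.01).
#' @param temperature temperature, K.
#' @return Object of class \code{limslope_fit}: \code{zdelta_profile}
#'   (data frame V, zdelta), plateau \code{zdelta_eff} (e0),
#'   \code{zdelta_exp_fit}, \code{G0} (nS), \code{zdelta_boltzmann},
#'   \code{G_max}, \code{Po_threshold} and \code{bins_used}.
#' @export
fit_limiting_slope <- function(curve, Po_threshold = 0.01,
                               temperature = hv_constants$T_default) {
  stopifnot(all(c("V", "G") %in% names(curve)))
  curve <- curve[is.finite(curve$V) & is.finite(curve$G), ]
  curve <- curve[order(curve$V), ]
  vt <- thermal_voltage(temperature)
  bfit <- tryCatch(fit_boltzmann(curve$V, curve$G, temperature,
                                 response = "conductance"),
                   error = function(e) NULL)
  g_max <- if (!is.null(bfit)) bfit$amplitude_max else max(curve$G)
  low <- which(curve$G / g_max < Po_threshold)
  if (length(low) < 3) {
    stop("too few bins below the open-probability threshold; extend the ramp to more hyperpolarized voltages")
  }
  if (length(low) < 10) {
    warning(sprintf("only %d bins below Po threshold %.3g; plateau weakly determined",
                    length(low), Po_threshold))
  }
  if (any(curve$G[low] <= 0)) {
    stop("non-positive conductance in the limiting region: cannot take log")
  }
  lnG <- log(curve$G)
  V <- curve$V
  n <- length(V)
  dlnG <- rep(NA_real_, n)
  dlnG[2:(n - 1)] <- (lnG[3:n] - lnG[1:(n - 2)]) / (V[3:n] - V[1:(n - 2)])
  zprof <- vt * dlnG
  z_eff <- stats::median(zprof[low], na.rm = TRUE)
  lf <- stats::lm(lnG[low] ~ V[low])
  z_exp <- unname(stats::coef(lf)[2]) * vt
  G0 <- exp(unname(stats::coef(lf)[1]))
  structure(
    list(zdelta_profile = data.frame(V = V, zdelta = zprof),
         zdelta_eff = z_eff, zdelta_exp_fit = z_exp, G0 = G0,
         zdelta_boltzmann = if (!is.null(bfit)) bfit$z_delta else NA_real_,
         G_max = g_max, Po_threshold = Po_threshold,
         bins_used = length(low), boltzmann_fit = bfit),
    class = "limslope_fit"
  )
}

#' @export
print.limslope_fit <- function(x, digits = 4, ...) {
  cat("Limiting-slope gating-charge estimate\n")
  cat(sprintf("  zdelta_eff (plateau median): %s e0 over %d bins (G/Gmax < %.3g)\n",
              format(x$zdelta_eff, digits = digits), x$bins_used, x$Po_threshold))
  cat(sprintf("  zdelta (log-linear exp fit): %s e0, G0 = %s nS\n",
              format(x$zdelta_exp_fit, digits = digits), format(x$G0, digits = 3)))
  cat(sprintf("  zdelta (full-curve Boltzmann): %s e0\n",
              format(x$zdelta_boltzmann, digits = digits)))
  invisible(x)
}

#' @export
coef.limslope_fit <- function(object, ...) {
  c(zdelta_eff = object$zdelta_eff, zdelta_exp_fit = object$zdelta_exp_fit,
    zdelta_boltzmann = object$zdelta_boltzmann, G0 = object$G0)
}

#' @export
plot.limslope_fit <- function(x, ...) {
  graphics::plot(x$zdelta_profile$V, x$zdelta_profile$zdelta, type = "l",
                 xlab = "V (mV)", ylab = "z_delta(V) (e0)", ...)
  graphics::abline(h = x$zdelta_eff, lty = 2)
  invisible(x)
}
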