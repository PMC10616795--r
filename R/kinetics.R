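#' Fit a single-exponential activation time constant
#'
#' Fits I(t) = a exp(-(t - t0)/tau) + C to a macroscopic ON current over a
#' depolarizing pulse (for a rising activation current the amplitude a is
#' negative and C is the steady current). By default the fit starts at the
#' time the current has completed 20\% of its rise, skipping the sigmoidal
#' activation delay of multi-step gating; \code{fit_start = 0} fits from
#' the pulse onset.
#'
#' @param ensemble a \code{\link{sweep_ensemble}} (or a single sweep of
#'   one); the pulse segment of \code{sweep} is fitted.
#' @param sweep sweep index (default 1).
#' @param segment protocol segment holding the pulse (default 2).
#' @param fit_start start of the fit in ms after pulse onset, or NULL for
#'   the 20\%-rise rule.
#' @param rise_fraction rise fraction defining the default fit start.
#' @param temperature unused; kept for interface symmetry.
#' @return Object of class \code{exp_fit}: \code{tau_act} (ms),
#'   \code{amplitude} (pA), \code{offset} (pA), \code{fit_start} (ms from
#'   pulse onset) and \code{residual_rms}.
#' @export
fit_activation_tau <- function(ensemble, sweep = 1, segment = 2,
                               fit_start = NULL, rise_fraction = 0.2,
                               temperature = NULL) {
  w <- segment_window(ensemble$protocol, segment, sweep)
  tt <- ensemble$time[w] - ensemble$time[w[1]]
  I <- ensemble$sweeps[sweep, w]
  fit_exponential_relaxation(tt, I, fit_start, rise_fraction)
}

# Core single-exponential fit on a (t, I) trace, t from 0.
fit_exponential_relaxation <- function(tt, I, fit_start = NULL,
                                       rise_fraction = 0.2) {
  n <- length(tt)
  if (n < 10) stop("trace too short for an exponential fit")
  n_tail <- max(round(0.1 * n), 3)
  plateau <- mean(utils::tail(I, n_tail))
  I0 <- mean(utils::head(I, max(round(0.02 * n), 2)))
  span <- plateau - I0
  if (is.null(fit_start)) {
    # smooth lightly before locating the rise to resist noise
    k <- max(1, min(round(n / 50), 25)); if (k %% 2 == 0) k <- k + 1
    sm <- if (k > 1) as.numeric(stats::filter(I, rep(1 / k, k), sides = 2)) else I
    frac <- (sm - I0) / span
    idx <- which(is.finite(frac) & frac >= rise_fraction)[1]
    if (is.na(idx)) {
      warning("trace never reaches the rise fraction; fitting from t = 0")
      idx <- 1
    }
    fit_start <- tt[idx]
  }
  keep <- tt >= fit_start
  t_f <- tt[keep] - fit_start
  I_f <- I[keep]
  # gross non-monotonicity check (noise-level wiggles are expected and ignored)
  if (span != 0) {
    q <- stats::quantile((I_f - I0) / span, c(0.02, 0.98), na.rm = TRUE)
    if (q[1] < -0.5 || q[2] > 2) {
      warning("fit segment is strongly non-monotone relative to the rise")
    }
  }
  tau0 <- max(t_f[which((I_f - I_f[1]) / (plateau - I_f[1] + .Machine$double.eps) >= 0.63)][1],
              diff(range(t_f)) / 10, na.rm = TRUE)
  dat <- data.frame(t = t_f, I = I_f)
  fit <- minpack.lm::nlsLM(I ~ a * exp(-t / tau) + c, data = dat,
                           start = list(a = I_f[1] - plateau, tau = tau0,
                                        c = plateau),
                           lower = c(a = -Inf, tau = 1e-6, c = -Inf),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  structure(
    list(tau_act = unname(cf["tau"]), amplitude = unname(cf["a"]),
         offset = unname(cf["c"]), fit_start = fit_start,
         se_tau = unname(se["tau"]),
         residual_rms = sqrt(mean(stats::residuals(fit)^2)), fit = fit),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, digits = 4, ...) {
  cat(sprintf("exponential fit: tau_act = %s ms (SE %s), amplitude %s pA, offset %s pA, fit from %.3g ms\n",
              format(x$tau_act, digits = digits), format(x$se_tau, digits = 3),
              format(x$amplitude, digits = 3), format(x$offset, digits = 3),
              x$fit_start))
  invisible(x)
}

#' @export
coef.exp_fit <- function(object, ...) {
  c(tau_act = object$tau_act, amplitude = object$amplitude,
    offset = object$offset)
}

#' Activation time constants against voltage
#'
#' Fits \code{\link{fit_activation_tau}} to the ensemble-averaged pulse
#' current at each step voltage of a step-family ensemble.
#'
#' @param ensemble a step-family \code{\link{sweep_ensemble}}.
#' @param ... passed to \code{\link{fit_activation_tau}}.
#' @return Data frame with columns \code{V} (mV), \code{tau} (ms) and
#'   \code{se_tau}.
#' @export
tau_v_curve <- function(ensemble, ...) {
  if (ensemble$protocol$kind != "step_family") {
    stop("tau_v_curve requires a step_family protocol")
  }
  step_V <- vapply(ensemble$protocol$segments, function(s) s$V_start[2],
                   numeric(1))
  uv <- unique(step_V)
  out <- data.frame(V = uv, tau = NA_real_, se_tau = NA_real_)
  for (j in seq_along(uv)) {
    rows <- which(step_V == uv[j])
    avg <- ensemble
    avg$sweeps <- matrix(colMeans(ensemble$sweeps[rows, , drop = FALSE]),
                         nrow = 1)
    avg$protocol <- recycle_protocol(ensemble$protocol, nrow(ensemble$sweeps))
    avg$protocol$segments <- ensemble$protocol$segments[rows[1]]
    avg$protocol$sweep_count <- 1L
    f <- tryCatch(fit_activation_tau(avg, sweep = 1, ...),
                  error = function(e) NULL)
    if (!is.null(f)) {
      out$tau[j] <- f$tau_act
      out$se_tau[j] <- f$se_tau
    }
  }
  out
}

#' Multi-exponential decomposition of a relaxation
#'
#' Fits I(t) = sum_j a_j exp(-t/tau_j) + C by separable (variable
#' projection) least squares: for any candidate set of time constants the
#' amplitudes and offset are the linear least-squares solution, and the
#' time constants are optimized on a log scale from multiple log-spaced
#' starts (best residual kept; deterministic given \code{seed}). Intended
#' for mixed-isoform currents whose relaxation is a sum of three
#' exponentials, one per isoform.
#'
#' @param tt time, ms (from relaxation start).
#' @param I current, pA.
#' @param n_components number of exponentials (default 3).
#' @param n_starts number of multi-start initializations (default 20).
#' @param tau_bounds time-constant bounds, ms (default 0.1 to 10x trace
#'   length).
#' @param seed RNG seed for the randomized starts.
#' @return Object of class \code{multiexp_fit}: \code{taus} (ascending,
#'   ms), \code{amplitudes} (pA, same order), \code{offset} (pA),
#'   \code{residual_rms}; a warning marks near-degenerate pairs
#'   (tau ratio < 1.5).
#' @export
decompose_exponentials <- function(tt, I, n_components = 3, n_starts = 20,
                                   tau_bounds = c(0.1, 10 * max(tt)),
                                   seed = 1) {
  stopifnot(length(tt) == length(I), n_components >= 1)
  if (max(tt) < 5 * tau_bounds[1]) stop("trace too short for the requested components")
  lb <- log(tau_bounds[1]); ub <- log(tau_bounds[2])
  obj <- function(ltau) {
    rss_for_taus(exp(ltau), tt, I)$rss
  }
  set.seed(as.integer(seed))
  starts <- vector("list", n_starts)
  # one deterministic log-spaced start, the rest randomized
  starts[[1]] <- seq(lb + 0.15 * (ub - lb), ub - 0.3 * (ub - lb),
                     length.out = n_components)
  for (s in seq_len(n_starts - 1)) {
    starts[[s + 1]] <- sort(stats::runif(n_components, lb, ub))
  }
  best <- NULL
  for (st in starts) {
    o <- tryCatch(
      stats::optim(st, obj, method = "L-BFGS-B",
                   lower = rep(lb, n_components), upper = rep(ub, n_components),
                   control = list(maxit = 300)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("multi-exponential fit failed from every start")
  taus <- sort(exp(best$par))
  sol <- rss_for_taus(taus, tt, I)
  if (n_components >= 2 && any(taus[-1] / taus[-n_components] < 1.5)) {
    warning("merged components: some time constants differ by less than a factor 1.5")
  }
  structure(
    list(taus = taus, amplitudes = sol$amps, offset = sol$offset,
         residual_rms = sqrt(sol$rss / length(I)),
         n_components = n_components),
    class = "multiexp_fit"
  )
}

# Linear amplitude/offset solution for fixed time constants.
rss_for_taus <- function(taus, tt, I) {
  X <- cbind(vapply(taus, function(tau) exp(-tt / tau),
                    numeric(length(tt))), 1)
  fit <- stats::lm.fit(X, I)
  list(rss = sum(fit$residuals^2),
       amps = unname(fit$coefficients[seq_along(taus)]),
       offset = unname(fit$coefficients[length(taus) + 1]))
}

#' @export
print.multiexp_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%d-exponential decomposition (residual RMS %.4g pA)\n",
              x$n_components, x$residual_rms))
  for (j in seq_along(x$taus)) {
    cat(sprintf("  tau_%d = %s ms, amplitude %s pA\n", j,
                format(x$taus[j], digits = digits),
                format(x$amplitudes[j], digits = 3)))
  }
  cat(sprintf("  offset %s pA\n", format(x$offset, digits = 3)))
  invisible(x)
}

#' @export
coef.multiexp_fit <- function(object, ...) {
  stats::setNames(c(object$taus, object$amplitudes, object$offset),
                  c(paste0("tau_", seq_along(object$taus)),
                    paste0("a_", seq_along(object$amplitudes)), "offset"))
}

#' Assign decomposed time constants to reference isoforms
#'
#' Maps each fitted time constant to the label of the nearest reference
#' value (log-scale distance).
#'
#' @param fit a \code{multiexp_fit}.
#' @param reference named numeric vector of reference time constants (ms).
#' @return Character vector of labels, one per fitted tau.
#' @export
assign_taus <- function(fit, reference) {
  stopifnot(!is.null(names(reference)))
  vapply(fit$taus, function(tau) {
    names(reference)[which.min(abs(log(tau) - log(reference)))]
  }, character(1))
}
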