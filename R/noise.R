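#' Ensemble mean and variance time courses
#'
#' Pointwise first two moments across repeated sweeps. The
#' \code{"direct"} method is the plain sample mean/variance (n-1
#' denominator). The \code{"pairwise"} method estimates the variance from
#' successive sweep differences, Var(t) = <(I_k+1(t) - I_k(t))^2> / 2,
#' which is insensitive to slow drift (rundown) across the ensemble.
#'
#' @param ensemble a \code{\link{sweep_ensemble}} of repeated sweeps.
#' @param method \code{"pairwise"} (default, drift-robust) or
#'   \code{"direct"}.
#' @return List with \code{mean} and \code{variance} traces (length
#'   n_samples), \code{method} and \code{n_sweeps}.
#' @export
ensemble_moments <- function(ensemble, method = c("pairwise", "direct")) {
  method <- match.arg(method)
  x <- ensemble$sweeps
  n <- nrow(x)
  if (n < 2) stop("ensemble moments need at least 2 sweeps")
  if (n < 11) {
    warning(sprintf("only %d sweeps: noise analysis is usually run on >= 11", n))
  }
  mu <- colMeans(x)
  v <- if (method == "direct") {
    apply(x, 2, stats::var)
  } else {
    d <- x[-1, , drop = FALSE] - x[-n, , drop = FALSE]
    colMeans(d^2) / 2
  }
  list(mean = mu, variance = v, method = method, n_sweeps = n)
}

#' Fit the variance-mean parabola of nonstationary noise analysis
#'
#' Least-squares fit of sigma^2 = i <I> - <I>^2 / N to ensemble variance
#' against mean current. The model is linear in (i, 1/N), so the fit is an
#' ordinary linear least squares on the basis (<I>, -<I>^2); standard
#' errors come from the linear-model covariance (delta method for N).
#' Baseline (closed-channel) variance is subtracted before fitting.
#'
#' @param mean mean-current trace, pA.
#' @param variance variance trace, pA^2.
#' @param baseline_variance closed-channel variance to subtract, pA^2.
#' @param V test potential, mV (for the unitary conductance; NA to skip).
#' @param V_rev reversal potential, mV.
#' @param I_end steady (end-pulse) mean current, pA; default: mean of the
#'   top 5\% of \code{mean}.
#' @param bins optional number of equal-mean bins (default NULL: fit raw
#'   points).
#' @param n_sweeps number of sweeps behind the moments (bookkeeping).
#' @return Object of class \code{noise_fit}: unitary current \code{i_unitary}
#'   (fA), channel count \code{N_channels}, \code{P_open_max}, unitary
#'   conductance \code{gamma} (fS), standard errors \code{se_i} (fA) and
#'   \code{se_N}, and the fitted \code{variance_curve}.
#' @export
fit_variance_parabola <- function(mean, variance, baseline_variance = 0,
                                  V = NA, V_rev = NA, I_end = NULL,
                                  bins = NULL, n_sweeps = NA) {
  ok <- is.finite(mean) & is.finite(variance)
  mu <- mean[ok]
  v <- variance[ok] - baseline_variance
  if (length(mu) < 5) stop("too few points for the parabola fit")
  if (is.null(I_end)) {
    I_end <- base::mean(mu[mu >= stats::quantile(mu, 0.95)])
  }
  if (!is.null(bins)) {
    cut_id <- cut(mu, breaks = bins, labels = FALSE)
    mu_b <- tapply(mu, cut_id, base::mean)
    v_b <- tapply(v, cut_id, base::mean)
    keep <- is.finite(mu_b) & is.finite(v_b)
    mu <- as.numeric(mu_b[keep]); v <- as.numeric(v_b[keep])
  }
  # biphasic check: band-averaged variance must fall from mid-range means
  # to the largest means (requires P_end > 0.5)
  top <- max(mu)
  mid_band <- mu > 0.4 * top & mu < 0.6 * top
  top_band <- mu > 0.9 * top
  biphasic <- sum(mid_band) >= 3 && sum(top_band) >= 3 &&
    base::mean(v[mid_band]) > base::mean(v[top_band])
  if (!biphasic) {
    warning("variance is not clearly biphasic over the sampled range; parabola fit may be poorly constrained")
  }
  x2 <- -mu^2
  lf <- stats::lm(v ~ 0 + mu + x2)
  # variance of a sample variance scales with sigma^4: iterate
  # inverse-square weights on the fitted curve (plus the baseline floor)
  for (it in 1:4) {
    pred <- pmax(stats::fitted(lf), 1e-3) + max(baseline_variance, 1e-3)
    lf <- stats::lm(v ~ 0 + mu + x2, weights = 1 / pred^2)
  }
  cf <- stats::coef(lf)
  i_pA <- unname(cf["mu"])
  inv_N <- unname(cf["x2"])
  if (inv_N <= 0 || i_pA <= 0) {
    stop("parabola fit returned non-positive unitary current or channel count")
  }
  N <- 1 / inv_N
  se <- suppressWarnings(summary(lf)$coefficients[, "Std. Error"])
  se_i <- unname(se["mu"])
  se_N <- unname(se["x2"]) / inv_N^2
  p_max <- I_end / (i_pA * N)
  gamma <- if (is.finite(V) && is.finite(V_rev)) {
    ohmic_conductance(i_pA * 1000, V, V_rev, unitary = TRUE)
  } else NA_real_
  structure(
    list(i_unitary = i_pA * 1000, N_channels = N, P_open_max = p_max,
         gamma = gamma, se_i = se_i * 1000, se_N = se_N,
         I_end = I_end, V = V, V_rev = V_rev, biphasic = biphasic,
         n_sweeps_used = n_sweeps,
         variance_curve = data.frame(mean = mu, variance = v),
         fit = lf),
    class = "noise_fit"
  )
}

#' Nonstationary noise analysis of a sweep ensemble
#'
#' Convenience wrapper: computes ensemble moments over the depolarizing
#' pulse, estimates the baseline variance on the pre-pulse holding segment,
#' and fits the variance-mean parabola. The test potential is taken from
#' the protocol and the reversal potential from the Nernst relation of the
#' ensemble's pH condition (override via \code{V_rev}).
#'
#' @param ensemble a step-family \code{\link{sweep_ensemble}} of repeated
#'   sweeps at one test potential.
#' @param method variance estimator, see \code{\link{ensemble_moments}}.
#' @param end_window_fraction end-pulse window for the steady current.
#' @param V_rev reversal potential, mV (default: Nernst).
#' @param bins optional equal-mean binning for the parabola fit.
#' @return A \code{noise_fit} (see \code{\link{fit_variance_parabola}});
#'   also carries the \code{moments} time courses.
#' @export
noise_analysis <- function(ensemble, method = c("pairwise", "direct"),
                           end_window_fraction = 0.05, V_rev = NULL,
                           bins = NULL) {
  method <- match.arg(method)
  mom <- ensemble_moments(ensemble, method)
  pre <- segment_window(ensemble$protocol, 1, 1)
  pulse <- segment_window(ensemble$protocol, 2, 1)
  baseline <- base::mean(mom$variance[pre])
  base_mu <- base::mean(mom$mean[pre])
  if (is.null(V_rev)) {
    V_rev <- nernst_potential(ensemble$condition, ensemble$temperature)
  }
  V <- ensemble$protocol$segments[[1]]$V_start[2]
  n_keep <- max(floor(length(pulse) * end_window_fraction), 1)
  I_end <- base::mean(mom$mean[utils::tail(pulse, n_keep)]) - base_mu
  res <- fit_variance_parabola(mom$mean[pulse] - base_mu,
                               mom$variance[pulse],
                               baseline_variance = baseline,
                               V = V, V_rev = V_rev, I_end = I_end,
                               bins = bins, n_sweeps = mom$n_sweeps)
  res$moments <- mom
  res$method <- method
  res
}

#' @export
print.noise_fit <- function(x, digits = 4, ...) {
  cat("Nonstationary noise analysis (variance-mean parabola)\n")
  cat(sprintf("  unitary current i : %s fA (SE %s)\n",
              format(x$i_unitary, digits = digits), format(x$se_i, digits = 3)))
  cat(sprintf("  channel count N   : %s (SE %s)\n",
              format(x$N_channels, digits = digits), format(x$se_N, digits = 3)))
  cat(sprintf("  P_open_max        : %s\n", format(x$P_open_max, digits = digits)))
  if (is.finite(x$gamma)) {
    cat(sprintf("  unitary gamma     : %s fS at %.4g mV (V_rev %.4g mV)\n",
                format(x$gamma, digits = digits), x$V, x$V_rev))
  }
  if (!is.na(x$n_sweeps_used)) {
    cat(sprintf("  sweeps used       : %d (%s variance)\n", x$n_sweeps_used,
                if (!is.null(x$method)) x$method else "supplied"))
  }
  invisible(x)
}

#' @export
coef.noise_fit <- function(object, ...) {
  c(i_unitary = object$i_unitary, N_channels = object$N_channels,
    P_open_max = object$P_open_max, gamma = object$gamma)
}

#' @export
plot.noise_fit <- function(x, ...) {
  graphics::plot(x$variance_curve$mean, x$variance_curve$variance,
                 xlab = "mean current (pA)", ylab = "variance (pA^2)", ...)
  mu <- seq(0, max(x$variance_curve$mean), length.out = 200)
  graphics::lines(mu, (x$i_unitary / 1000) * mu - mu^2 / x$N_channels)
  invisible(x)
}
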