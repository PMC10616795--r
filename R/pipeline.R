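#' Run a configured simulate-and-analyze pipeline
#'
#' Executes a list of analysis stages against a simulated or loaded sweep
#' ensemble and writes JSON results plus a reproducibility manifest
#' (package version, seed, config hash). The configuration is a named list
#' (or path to a YAML file) with elements:
#' \describe{
#'   \item{seed}{integer seed used for every stochastic stage.}
#'   \item{stages}{character vector drawn from \code{"simulate"},
#'     \code{"iv"}, \code{"gv"}, \code{"noise"}, \code{"vrev"},
#'     \code{"limslope"}, \code{"kinetics"}, \code{"decompose"}.}
#'   \item{input}{path to an ATF or CSV trace file (alternative to the
#'     simulate stage).}
#'   \item{simulate}{parameter block: \code{model} (arguments of
#'     \code{\link{channel_model}}), \code{artifacts} (arguments of
#'     \code{\link{recording_artifacts}}), \code{protocol} (\code{kind}
#'     plus \code{\link{make_protocol}} arguments), \code{n_sweeps}.}
#'   \item{...}{optional per-stage parameter blocks named after the
#'     stage.}
#' }
#'
#' @param config named list or path to a YAML config file.
#' @param out_dir output directory (created if missing); NULL to skip
#'   writing files.
#' @return Named list of stage results, invisibly; written to
#'   \code{results.json} with \code{manifest.json} alongside when
#'   \code{out_dir} is given.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  known <- c("simulate", "iv", "gv", "noise", "vrev", "limslope",
             "kinetics", "decompose")
  stages <- config$stages
  if (is.null(stages) || length(stages) == 0) stop("config lists no stages")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    stop(sprintf("unknown stage(s): %s (known: %s)",
                 paste(bad, collapse = ", "), paste(known, collapse = ", ")))
  }
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  state <- new.env(parent = emptyenv())
  if (!is.null(config$input)) {
    state$ensemble <- if (grepl("\\.csv$", config$input, ignore.case = TRUE)) {
      read_sweep_csv(config$input)
    } else read_atf(config$input)
  }
  results <- list()
  for (st in stages) {
    res <- tryCatch(
      run_stage(st, config[[st]], state, seed),
      error = function(e) {
        flush_results(results, config, seed, out_dir)
        stop(sprintf("stage '%s' failed: %s", st, conditionMessage(e)),
             call. = FALSE)
      })
    results[[st]] <- res
  }
  flush_results(results, config, seed, out_dir)
  invisible(results)
}

run_stage <- function(stage, params, state, seed) {
  params <- if (is.null(params)) list() else params
  need_ensemble <- function() {
    if (is.null(state$ensemble)) {
      stop("no ensemble available (add a simulate stage or an input file)")
    }
    state$ensemble
  }
  switch(stage,
    simulate = {
      margs <- params$model
      if (!is.null(margs$condition) && !inherits(margs$condition, "ph_condition")) {
        margs$condition <- do.call(ph_condition, as.list(margs$condition))
      }
      model <- do.call(channel_model, margs)
      artifacts <- do.call(recording_artifacts,
                           if (is.null(params$artifacts)) list() else params$artifacts)
      pp <- params$protocol
      protocol <- do.call(make_protocol, pp)
      n_sweeps <- if (!is.null(params$n_sweeps)) params$n_sweeps
                  else protocol$sweep_count
      state$ensemble <- simulate_ensemble(model, artifacts, protocol,
                                          n_sweeps, seed = seed)
      list(n_sweeps = nrow(state$ensemble$sweeps),
           n_samples = ncol(state$ensemble$sweeps),
           protocol = state$ensemble$protocol$kind)
    },
    iv = {
      pts <- extract_iv(need_ensemble(),
                        end_window_fraction = params$end_window_fraction %||% 0.05)
      fit <- fit_boltzmann_iv(pts)
      c(as.list(coef(fit)),
        list(se_z_delta = fit$se_z_delta, se_V_half = fit$se_V_half,
             residual_rms = fit$residual_rms))
    },
    gv = {
      pts <- extract_tail_gv(need_ensemble(),
                             isochrone_ms = params$isochrone_ms %||% 0.5)
      fit <- fit_boltzmann_gv(pts)
      c(as.list(coef(fit)),
        list(se_z_delta = fit$se_z_delta, se_V_half = fit$se_V_half,
             residual_rms = fit$residual_rms))
    },
    noise = {
      nf <- noise_analysis(need_ensemble(),
                           method = params$method %||% "pairwise")
      list(i_unitary_fA = nf$i_unitary, N_channels = nf$N_channels,
           P_open_max = nf$P_open_max, gamma_fS = nf$gamma,
           se_i = nf$se_i, se_N = nf$se_N,
           variance_curve = nf$variance_curve)
    },
    vrev = {
      est <- estimate_vrev_crossing(need_ensemble(),
                                    window_mV = params$window_mV %||% 0.5)
      list(V_rev_mV = est$V_rev, delta_pH = est$condition$delta_pH)
    },
    limslope = {
      curve <- preprocess_ramp(need_ensemble(),
                               filter_hz = params$filter_hz,
                               decimate = params$decimate %||% 5,
                               bins = params$bins %||% 100)
      fit <- fit_limiting_slope(curve,
                                Po_threshold = params$Po_threshold %||% 0.01)
      as.list(coef(fit))
    },
    kinetics = {
      tv <- tau_v_curve(need_ensemble())
      list(tau_v = tv)
    },
    decompose = {
      ens <- need_ensemble()
      w <- segment_window(ens$protocol, 2, 1)
      tt <- ens$time[w] - ens$time[w[1]]
      fit <- decompose_exponentials(tt, colMeans(ens$sweeps[, w, drop = FALSE]),
                                    n_components = params$n_components %||% 3,
                                    seed = seed)
      list(taus_ms = fit$taus, amplitudes_pA = fit$amplitudes,
           offset_pA = fit$offset, residual_rms = fit$residual_rms)
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

flush_results <- function(results, config, seed, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, dataframe = "columns")
  cfg_file <- tempfile()
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  manifest <- list(
    package = "hvephys",
    version = as.character(utils::packageVersion("hvephys")),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
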