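#' Single-device characterization sweeps
#'
#' Measures the weight change of one pulse while sweeping (a) the pulse
#' width at fixed magnitude and (b) the pulse magnitude at fixed width,
#' with the common mode held fixed, and fits the expected response shapes:
#' the width response is linear and the magnitude response exponential
#' (tunneling flow is exponential in the node potential).
#'
#' @param params an \code{fn_device}; the \code{"characterize"} preset uses
#'   100 ms pulses.
#' @param pulse_widths widths to sweep (s); non-empty.
#' @param pulse_magnitudes magnitudes to sweep (V); non-empty.
#' @param fixed_magnitude magnitude held during the width sweep (V).
#' @param fixed_width width held during the magnitude sweep (s).
#' @param wc common-mode potential held during the sweeps (V).
#' @return object of class \code{fn_characterization}: list with the two
#'   sweep tables (\code{width_sweep}, \code{magnitude_sweep}), the fits
#'   (\code{width_fit}: lm; \code{magnitude_fit}: nls) and their R^2.
#' @export
characterize <- function(params = fn_device_preset("characterize"),
                         pulse_widths = seq(0.02, 0.5, by = 0.02),
                         pulse_magnitudes = seq(2, 5, by = 0.2),
                         fixed_magnitude = 4, fixed_width = 0.1,
                         wc = params$Wc0) {
  if (length(pulse_widths) == 0 || length(pulse_magnitudes) == 0)
    stop("characterize: sweep lists must be non-empty")
  ws <- data.frame(width = pulse_widths,
                   dwd = pulse_response(pulse_widths, fixed_magnitude,
                                        params, wc))
  ms <- data.frame(magnitude = pulse_magnitudes,
                   dwd = pulse_response(fixed_width, pulse_magnitudes,
                                        params, wc))
  wfit <- stats::lm(dwd ~ width, data = ws)
  # the model sweep is exactly linear; compute R^2 directly
  r2_w <- 1 - sum(stats::residuals(wfit)^2) / sum((ws$dwd - mean(ws$dwd))^2)
  # y = exp(a x + b) + d
  mfit <- minpack.lm::nlsLM(
    dwd ~ exp(a * magnitude + b) + d, data = ms,
    start = list(a = 2, b = log(max(ms$dwd)) - 2 * max(ms$magnitude), d = 0))
  r2_m <- 1 - sum(stats::residuals(mfit)^2) /
    sum((ms$dwd - mean(ms$dwd))^2)
  structure(list(width_sweep = ws, magnitude_sweep = ms,
                 width_fit = wfit, width_r2 = r2_w,
                 magnitude_fit = mfit, magnitude_r2 = r2_m,
                 fixed_magnitude = fixed_magnitude,
                 fixed_width = fixed_width, wc = wc),
            class = "fn_characterization")
}

#' @export
print.fn_characterization <- function(x, ...) {
  cat("FN-synapse characterization\n")
  cat(sprintf(
    "  width sweep at %g V: linear fit slope %.4g V/s, R^2 = %.5f\n",
    x$fixed_magnitude, stats::coef(x$width_fit)[["width"]], x$width_r2))
  cat(sprintf(
    "  magnitude sweep at %g s: exponential fit rate %.4g 1/V, R^2 = %.5f\n",
    x$fixed_width, stats::coef(x$magnitude_fit)[["a"]], x$magnitude_r2))
  invisible(x)
}

#' Load a run configuration
#'
#' Reads a YAML or JSON configuration (chosen by file extension) with an
#' optional \code{device} block (either a preset name or explicit
#' [fn_device()] fields), an \code{experiment} name, a \code{seed}, an
#' output directory and experiment-specific settings.
#'
#' @param path configuration file path.
#' @return a named list with a parsed \code{device} (\code{fn_device}).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$device <- device_from_config(cfg$device)
  cfg
}

device_from_config <- function(dev) {
  if (is.null(dev)) return(fn_device())
  if (is.character(dev)) return(fn_device_preset(dev))
  if (inherits(dev, "fn_device")) return(dev)
  preset <- dev$preset %||% "default"
  dev$preset <- NULL
  known <- names(formals(fn_device))
  bad <- setdiff(names(dev), known)
  if (length(bad) > 0)
    stop("device config: unknown fields: ", paste(bad, collapse = ", "))
  do.call(fn_device_preset, c(list(name = preset), dev))
}

#' Run a configured experiment
#'
#' Dispatches to the module drivers by the \code{experiment} field of the
#' configuration (\code{characterize}, \code{consolidate},
#' \code{modulate}, \code{stochastic} or \code{continual}), writes the
#' result tables as CSV/JSON into the output directory together with a
#' metadata record (configuration echo, seed, package version), and
#' returns the result object invisibly.  Identical configuration and seed
#' give byte-identical outputs.
#'
#' @param config a configuration list (see [load_config()]) or a path to
#'   a configuration file.
#' @param out_dir output directory; overrides the configuration entry.
#' @return the experiment result object, invisibly.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- load_config(config)
  known <- c("experiment", "device", "seed", "out_dir", "N", "patterns",
             "mc_runs", "profile", "tracked_pattern", "balanced", "engine",
             "amplitude", "observe_every", "threshold", "n_pulses", "seeds",
             "pulse_widths", "pulse_magnitudes", "fixed_magnitude",
             "fixed_width", "scheme", "method", "hyper", "n_tasks",
             "n_classes", "dim", "n_train", "n_test", "separation")
  bad <- setdiff(names(config), known)
  if (length(bad) > 0)
    stop("run_experiment: unknown config keys: ", paste(bad, collapse = ", "))
  exp_name <- config$experiment
  if (is.null(exp_name) ||
      !exp_name %in% c("characterize", "consolidate", "modulate",
                       "stochastic", "continual"))
    stop("run_experiment: experiment must be one of characterize, ",
         "consolidate, modulate, stochastic, continual")
  out_dir <- out_dir %||% config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1
  params <- config$device
  res <- switch(exp_name,
    characterize = {
      r <- characterize(params,
                        pulse_widths = config$pulse_widths %||%
                          seq(0.02, 0.5, by = 0.02),
                        pulse_magnitudes = config$pulse_magnitudes %||%
                          seq(2, 5, by = 0.2),
                        fixed_magnitude = config$fixed_magnitude %||% 4,
                        fixed_width = config$fixed_width %||% 0.1)
      utils::write.csv(r$width_sweep,
                       file.path(out_dir, "width_sweep.csv"),
                       row.names = FALSE)
      utils::write.csv(r$magnitude_sweep,
                       file.path(out_dir, "magnitude_sweep.csv"),
                       row.names = FALSE)
      r
    },
    consolidate = ,
    modulate = {
      prof <- config$profile %||% if (exp_name == "modulate") "m1" else NULL
      profile <- if (!is.null(prof) && !identical(prof, "none"))
        modulation_profile(prof) else NULL
      r <- snr_experiment(N = config$N %||% 100,
                          n_patterns = config$patterns %||% 100,
                          n_mc = config$mc_runs %||% 1000,
                          params = params, profile = profile,
                          tracked_pattern = config$tracked_pattern %||% 1,
                          balanced = config$balanced %||% FALSE,
                          engine = config$engine %||% "deterministic",
                          pulse_amplitude = config$amplitude %||% 3e-4,
                          seed = seed)
      utils::write.csv(as.data.frame(r), file.path(out_dir, "snr.csv"),
                       row.names = FALSE)
      if (!is.null(profile))
        utils::write.csv(
          data.frame(update_index = seq_along(increments_log(profile)),
                     increment_volts = increments_log(profile)),
          file.path(out_dir, "increments.csv"), row.names = FALSE)
      r
    },
    stochastic = {
      r <- compare_to_deterministic(
        n_pulses = config$n_pulses %||% 100, params = params,
        seeds = seed + seq_len(config$seeds %||% 20) - 1)
      jsonlite::write_json(
        list(max_dev_volts = r$max_dev, per_seed_volts = r$per_seed),
        file.path(out_dir, "stochastic_deviation.json"),
        digits = NA, auto_unbox = TRUE)
      r
    },
    continual = {
      stream <- build_task_stream(
        source = "synthetic", scheme = config$scheme %||% "split",
        seed = seed, n_classes = config$n_classes %||% 10,
        dim = config$dim %||% 64, n_train = config$n_train %||% 500,
        n_test = config$n_test %||% 100,
        separation = config$separation %||% 3,
        n_tasks = config$n_tasks %||% 10)
      r <- train_stream(stream, method = config$method %||% "fn_sgd",
                        hyper = config$hyper %||% list(), seed = seed)
      jsonlite::write_json(
        list(method = attr(r, "method"),
             accuracy_matrix = unclass(r)[, ],
             overall_average = attr(r, "overall_average")),
        file.path(out_dir, "accuracy_matrix.json"),
        digits = NA, auto_unbox = TRUE)
      r
    })
  meta <- list(experiment = exp_name, seed = seed,
               config = config[setdiff(names(config), "device")],
               device = config$device[c("k1", "k0", "Wc0", "k2", "Cc",
                                        "Cfg", "dt_pulse")],
               package_version = as.character(utils::packageVersion("fnsynapse")))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
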