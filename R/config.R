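#' Default run configuration
#'
#' One nested list drives the whole pipeline.  All numeric defaults are
#' either the published design constants (sampling rates, band edges, trial
#' counts, feedback proportions) or generator/observer constants calibrated
#' once during development against the published behavioural benchmarks and
#' then frozen (see the methods vignette).  Every random stage derives its
#' seed from the single global `seed`.
#'
#' @param seed global integer seed (default 42).
#' @return nested list of class `cbl_config` with blocks `stimulus`,
#'   `generator`, `preprocess`, `decoder`, `schedule`, `observer`,
#'   `metrics`, `analysis` plus `n_participants`, `n_train_trials`,
#'   `n_control_participants` and `seed`.
#' @export
default_config <- function(seed = 42L) {
  structure(list(
    stimulus = list(f0 = 1.875, waveform = "sinusoid"),
    generator = list(n_channels = 64, fs_raw = 2048, attended_gain = 1,
                     unattended_gain = 0.4, noise_sd = 13.2,
                     noise_spectrum = "white", switch_prob = 0.55,
                     attention_strength = c(1.3, 1.0),
                     lead_in_s = 2, channel_lag_jitter_ms = 0),
    preprocess = list(fs_out = 256, lo = 1, hi = 30, order = 6),
    decoder = list(max_lag_s = 0.5, lag_step_s = 0.0625, ridge_lambda = 0.01,
                   n_last = 6),
    schedule = list(n_main_trials = 480, p_deceptive = 0.25,
                    report_fraction_informative = 1 / 3,
                    n_control_trials = 160, control_report_fraction = 0.5,
                    n_blocks = 3, trial_duration = 5, feedback_duration = 0.5,
                    control_position = "end"),
    observer = list(w_int = 2.57, w_cue = 0.11, sigma_obs = 1,
                    conf_thresholds = c(0.54, 1.08, 1.83), kappa = 0.05,
                    conf_congruence = 0.39, cue_weighting = "reliability",
                    introspection_window = 0.65),
    metrics = list(n_boot = 1000, accumulation_window = 3,
                   boot_stat = "mean_var"),
    analysis = list(n_boot = 1000, ci_level = 0.95),
    n_participants = 30, n_train_trials = 30, n_control_participants = 16,
    seed = as.integer(seed)), class = "cbl_config")
}

.required_blocks <- c("stimulus", "generator", "preprocess", "decoder",
                      "schedule", "observer", "metrics", "analysis")

#' Validate a run configuration
#'
#' Checks that every parameter block is present and that block contents
#' satisfy the constructors' invariants.  Errors name the offending block.
#'
#' @param config a configuration list (see [default_config()]).
#' @return the validated config, invisibly, with class `cbl_config`.
#' @export
validate_config <- function(config) {
  missing <- setdiff(.required_blocks, names(config))
  if (length(missing) > 0)
    cbl_stop("config is missing required block(s): %s",
             paste(missing, collapse = ", "), class = "cbl_config_error")
  if (is.null(config$seed)) cbl_stop("config is missing 'seed'",
                                     class = "cbl_config_error")
  # constructors enforce the invariants
  do.call(eeg_gen_params, config$generator)
  do.call(observer_params, config$observer)
  do.call(schedule_config, config$schedule)
  make_templates(config$stimulus$f0, config$preprocess$fs_out, 1,
                 config$stimulus$waveform)
  if (config$decoder$ridge_lambda < 0)
    cbl_stop("decoder block: ridge_lambda must be >= 0",
             class = "cbl_config_error")
  class(config) <- "cbl_config"
  invisible(config)
}

#' Write / read a configuration as a JSON text file
#'
#' JSON is used as the text-config dialect (no TOML/YAML parser is available
#' in the supported dependency set); configs round-trip losslessly.
#'
#' @param config a config list.
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   validated `cbl_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(cfg)
}
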