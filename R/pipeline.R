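# Stage helpers shared by run_pipeline() and the CLI.

.cfg_gen <- function(config, participant) {
  g <- config$generator
  eeg_gen_params(n_channels = g$n_channels, fs_raw = g$fs_raw,
                 attended_gain = g$attended_gain,
                 unattended_gain = g$unattended_gain, noise_sd = g$noise_sd,
                 noise_spectrum = g$noise_spectrum,
                 switch_prob = g$switch_prob,
                 attention_strength = g$attention_strength,
                 lead_in_s = g$lead_in_s,
                 channel_lag_jitter_ms = g$channel_lag_jitter_ms,
                 mixing_seed = derive_seed(config$seed, "mixing", participant),
                 noise_seed = 0L)
}

.cfg_observer <- function(config) do.call(observer_params, config$observer)

.cfg_lags <- function(config)
  seq(0, config$decoder$max_lag_s, by = config$decoder$lag_step_s)

.cfg_stimulus <- function(config)
  make_templates(config$stimulus$f0, config$preprocess$fs_out,
                 config$schedule$trial_duration, config$stimulus$waveform)

#' Train one simulated participant's backward model
#'
#' Simulates the labeled training phase for participant `participant` under
#' `config` and fits the lagged ridge backward model.
#'
#' @param config a validated [default_config()] list.
#' @param participant participant index (drives the mixing seed).
#' @return a `cbl_model`.
#' @export
train_participant_model <- function(config, participant = 1L) {
  gen <- .cfg_gen(config, participant)
  ts <- simulate_training_set(gen, .cfg_stimulus(config),
                              n_trials = config$n_train_trials,
                              seed = derive_seed(config$seed, "train", participant),
                              trial_duration = config$schedule$trial_duration,
                              fs_model = config$preprocess$fs_out)
  train_backward_model(ts$trials, ts$templates, .cfg_lags(config),
                       config$decoder$ridge_lambda)
}

#' Simulate one participant's main (and optional control) session
#'
#' @param config a validated config.
#' @param participant participant index.
#' @param model optional pre-trained model (trained if omitted).
#' @param include_control also run the no-feedback control block.
#' @return data.frame of trial records with a `participant` column.
#' @export
simulate_participant <- function(config, participant = 1L, model = NULL,
                                 include_control = FALSE) {
  if (is.null(model)) model <- train_participant_model(config, participant)
  gen <- .cfg_gen(config, participant)
  observer <- .cfg_observer(config)
  tmpl <- .cfg_stimulus(config)
  scfg <- do.call(schedule_config, c(config$schedule,
                                     seed = derive_seed(config$seed, "sched",
                                                        participant)))
  rec <- run_session(build_schedule(scfg), model, gen, observer, tmpl,
                     seed = derive_seed(config$seed, "session", participant),
                     trial_duration = config$schedule$trial_duration,
                     n_boot = config$metrics$n_boot,
                     n_last = config$decoder$n_last)
  if (include_control) {
    ctl <- run_control_session(build_control_schedule(scfg), model, gen,
                               observer, tmpl,
                               seed = derive_seed(config$seed, "control",
                                                  participant),
                               trial_duration = config$schedule$trial_duration,
                               n_boot = config$metrics$n_boot,
                               n_last = config$decoder$n_last)
    rec <- rbind(rec, ctl)
  }
  cbind(participant = sprintf("p%02d", participant), rec)
}

#' Run the full simulation + analysis pipeline
#'
#' Per participant: train the backward model on a simulated training phase,
#' run the 480-trial main session (and the 160-trial control block for the
#' first `n_control_participants` participants), then aggregate the summary
#' tables and the fixed-effects logistic fit across participants.  All
#' outputs are deterministic functions of `config$seed`; rerunning with the
#' same config reproduces the CSVs byte-identically.  If `out_dir` is given,
#' per-participant CSVs, summary CSVs, the logistic fit JSON and a
#' provenance JSON are written there; existing per-participant CSVs are
#' reused (resume) unless `resume = FALSE`.
#'
#' @param config a config list (validated on entry).
#' @param out_dir optional output directory.
#' @param resume reuse existing per-participant session CSVs (default TRUE).
#' @param progress print one line per participant (default FALSE).
#' @return list with `records` (all trials), `summary` (a
#'   [summarize_session()] list), `fit` (a [fit_logistic_accuracy()] fit)
#'   and `paths` (written files, if any).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         resume = TRUE, progress = FALSE) {
  config <- validate_config(config)
  paths <- character(0)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  all_rec <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    csv <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("session_p%02d.csv", p)) else NULL
    if (resume && !is.null(csv) && file.exists(csv)) {
      all_rec[[p]] <- read.csv(csv, stringsAsFactors = FALSE)
    } else {
      all_rec[[p]] <- simulate_participant(
        config, p, include_control = p <= config$n_control_participants)
      if (!is.null(csv)) {
        write.csv(all_rec[[p]], csv, row.names = FALSE)
        paths <- c(paths, csv)
      }
    }
    if (progress) cat(sprintf("participant %d/%d done\n", p,
                              config$n_participants))
  }
  records <- do.call(rbind, all_rec)
  main <- records[records$phase == "main", , drop = FALSE]
  summary <- summarize_session(main, n_boot = config$analysis$n_boot,
                               seed = derive_seed(config$seed, "summary"),
                               level = config$analysis$ci_level)
  fit <- fit_logistic_accuracy(main)
  if (!is.null(out_dir)) {
    for (nm in names(summary)) {
      if (is.null(summary[[nm]])) next
      f <- file.path(out_dir, paste0(nm, ".csv"))
      write.csv(summary[[nm]], f, row.names = FALSE)
      paths <- c(paths, f)
    }
    fit_path <- file.path(out_dir, "logistic_fit.json")
    jsonlite::write_json(lapply(unclass(fit), function(x)
      if (is.numeric(x)) unname(x) else x), fit_path, auto_unbox = TRUE,
      digits = NA)
    prov <- file.path(out_dir, "provenance.json")
    jsonlite::write_json(
      list(seed = config$seed,
           config_digest = sum(utf8ToInt(jsonlite::toJSON(
             unclass(config), auto_unbox = TRUE, digits = NA))),
           n_participants = config$n_participants,
           r_version = R.version.string,
           package_version = as.character(utils::packageVersion("cbloop"))),
      prov, auto_unbox = TRUE)
    paths <- c(paths, fit_path, prov)
  }
  list(records = records, summary = summary, fit = fit, paths = paths)
}
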