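#' Simulate a labeled BCI training set
#'
#' Emulates the decoder-training phase: `n_trials` trials with an assigned
#' target (balanced face/spiral, order shuffled), constant attention for the
#' whole trial, simulated with the participant's mixing vector and a
#' stimulation lead-in, preprocessed, and cropped to the decision phase.
#'
#' @param gen an [eeg_gen_params()] object (the participant).
#' @param templates a [make_templates()] stimulus spec (any rate; the raw
#'   and model-rate drives are regenerated internally).
#' @param n_trials number of training trials (default 30).
#' @param seed integer seed.
#' @param trial_duration seconds per trial (default 5).
#' @param fs_model model sampling rate (default 256).
#' @return list with `trials` (list of `seg`/`label`/`offset` entries ready
#'   for [train_backward_model()]) and `templates` at the model rate.
#' @export
simulate_training_set <- function(gen, templates, n_trials = 30, seed = 1L,
                                  trial_duration = 5, fs_model = 256) {
  stopifnot(inherits(gen, "cbl_gen_params"))
  if (n_trials %% 2 != 0) cbl_stop("n_trials must be even (balanced labels)")
  dur_total <- gen$lead_in_s + trial_duration
  tmpl_raw <- make_templates(templates$f0, gen$fs_raw, dur_total,
                             templates$waveform)
  tmpl_mod <- make_templates(templates$f0, fs_model, dur_total,
                             templates$waveform)
  lead_n <- round(gen$lead_in_s * fs_model)
  dur_n <- round(trial_duration * fs_model)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "trainlabels"))
  labels <- sample(rep(c("face", "spiral"), n_trials / 2))
  q <- if (is.null(gen$attention_strength)) rep(1, n_trials)
       else stats::rbeta(n_trials, gen$attention_strength[1],
                         gen$attention_strength[2])
  trials <- lapply(seq_len(n_trials), function(i) {
    trace <- structure(list(initial = labels[i], switch_time = NA_real_,
                            duration = dur_total, strength = q[i]),
                       class = "cbl_trace")
    eeg <- simulate_trial_eeg(tmpl_raw, trace, gen,
                              derive_seed(seed, "trainnoise", i))
    proc <- preprocess_chain(eeg, fs_out = fs_model)
    seg <- cbl_eeg(proc$data[(lead_n + 1L):(lead_n + dur_n), , drop = FALSE],
                   fs_model, colnames(proc$data))
    list(seg = seg, label = labels[i], offset = lead_n)
  })
  list(trials = trials, templates = tmpl_mod)
}

#' Run a closed-loop simulated session
#'
#' For every scheduled trial: sample the latent attention trace, simulate
#' raw EEG (with stimulation lead-in), preprocess, stream correlation
#' scores, decode the attended item, derive internal evidence and
#' consistency, and show informative (decoded), deceptive (opposite) or no
#' feedback according to the pre-assigned plan.  Signed internal evidence is
#' then z-scored across the session's trials and, on report-requested
#' trials, the cue-integration observer produces the report and confidence.
#'
#' @param schedule a [build_schedule()] or [build_control_schedule()]
#'   data.frame.
#' @param model a trained [train_backward_model()] model.
#' @param gen an [eeg_gen_params()] object.
#' @param observer an [observer_params()] object.
#' @param templates a [make_templates()] stimulus spec.
#' @param seed integer session seed.
#' @param trial_duration seconds of decision phase per trial (default 5).
#' @param n_boot bootstrap iterations for the consistency index.
#' @param n_last score pairs entering the decision and internal evidence.
#' @param observer_evidence what the observer introspects: `"latent"`
#'   (default) feeds her `q * (signed attended fraction over the
#'   introspection window)` — her own readout of the latent state that the
#'   BCI measures through noisy EEG; `"decoded"` feeds her the decoder's
#'   z-scored signed internal evidence instead (shares the decoder's
#'   measurement noise and cannot produce confident confabulation; see the
#'   methods vignette).
#' @param introspection_window seconds of the trial's end covered by the
#'   observer's introspective readout (default: the observer's
#'   `introspection_window`); deliberately shorter than the 4.5 s of data
#'   behind the decoder's decision.
#' @return data.frame of trial records (one row per trial) with schedule
#'   fields plus `decoded`, `feedback_shown`, `true_initial`,
#'   `true_switch_time`, `late_switch`, `att_strength`, `z_obs`, `ie`,
#'   `signed_ie`, `ie_z`, `consistency`, `boot_seed`, `report`,
#'   `confidence`, `accuracy`, `introspection`.
#' @export
run_session <- function(schedule, model, gen, observer, templates, seed,
                        trial_duration = 5, n_boot = 1000, n_last = 6,
                        observer_evidence = c("latent", "decoded"),
                        introspection_window = NULL) {
  observer_evidence <- match.arg(observer_evidence)
  if (is.null(introspection_window))
    introspection_window <- observer$introspection_window %||% 0.65
  stopifnot(inherits(model, "cbl_model"), inherits(gen, "cbl_gen_params"),
            inherits(observer, "cbl_observer"))
  n <- nrow(schedule)
  dur_total <- gen$lead_in_s + trial_duration
  tmpl_raw <- make_templates(templates$f0, gen$fs_raw, dur_total,
                             templates$waveform)
  tmpl_mod <- make_templates(templates$f0, model$fs, dur_total,
                             templates$waveform)
  decoded <- character(n)
  ie <- signed_ie <- cons <- numeric(n)
  true_initial <- character(n)
  true_switch <- numeric(n)
  att_strength <- z_obs <- numeric(n)
  boot_seed <- integer(n)
  # Signed attended fraction (+1 = face) over the observer's introspection
  # window: the participant reports what she attended just before feedback,
  # so her readout covers only the trial's final moments, while the decoder
  # integrates 4.5 s of history.  A late attention switch therefore
  # decouples strong introspective evidence from the decoded item — the
  # experiment's own late-decision-change caveat.
  win_s <- introspection_window
  for (i in seq_len(n)) {
    trace <- sample_attention_trace(trial_duration, gen$switch_prob,
                                    derive_seed(seed, "trace", i),
                                    strength_shape = gen$attention_strength)
    eeg <- simulate_trial_eeg(tmpl_raw, extend_trace(trace, gen$lead_in_s),
                              gen, derive_seed(seed, "noise", i))
    proc <- preprocess_chain(eeg, fs_out = model$fs)
    stream <- tryCatch(
      stream_scores(model, proc, tmpl_mod),
      error = function(e) cbl_stop("decoding failed on trial %d: %s",
                                   i, conditionMessage(e)))
    decoded[i] <- decide(stream, n_last)
    m <- internal_evidence(stream, n_last)
    ie[i] <- m$ie; signed_ie[i] <- m$signed_ie
    boot_seed[i] <- derive_seed(seed, "boot", i)
    cons[i] <- consistency(stream, n_boot = n_boot, seed = boot_seed[i],
                           n_last = n_last)
    true_initial[i] <- trace$initial
    true_switch[i] <- trace$switch_time
    att_strength[i] <- trace$strength
    tgrid <- seq(trial_duration - win_s, trial_duration, by = 1 / 64)
    frac_face <- mean(attended_at(trace, tgrid) == "face")
    z_obs[i] <- trace$strength * (2 * frac_face - 1)
  }
  feedback_shown <- ifelse(
    schedule$feedback_type == "none", "none",
    ifelse(schedule$feedback_type == "informative", decoded,
           ifelse(decoded == "face", "spiral", "face")))
  ie_z <- if (sd(signed_ie) > 0) (signed_ie - mean(signed_ie)) / sd(signed_ie)
          else signed_ie * 0

  report <- rep(NA_character_, n)
  confidence <- rep(NA_integer_, n)
  req <- which(schedule$report_requested)
  if (length(req) > 0) {
    cue <- ifelse(feedback_shown[req] == "none", 0,
                  ifelse(feedback_shown[req] == "face", 1, -1))
    ev <- if (observer_evidence == "latent") z_obs[req] else ie_z[req]
    obs <- observe_and_report(ev, cue, observer,
                              derive_seed(seed, "report"))
    report[req] <- obs$report
    confidence[req] <- obs$confidence
  }
  accuracy <- rep(NA_character_, n)
  accuracy[req] <- label_accuracy(report[req], decoded[req])
  introspection <- rep(NA_character_, n)
  introspection[req] <- label_introspection(schedule$feedback_type[req],
                                            accuracy[req])
  cbind(schedule,
        data.frame(decoded = decoded, feedback_shown = feedback_shown,
                   true_initial = true_initial, true_switch_time = true_switch,
                   late_switch = !is.na(true_switch) &
                     true_switch > trial_duration - 1.5,
                   att_strength = att_strength, z_obs = z_obs,
                   ie = ie, signed_ie = signed_ie, ie_z = ie_z,
                   consistency = cons, boot_seed = boot_seed,
                   report = report, confidence = confidence,
                   accuracy = accuracy, introspection = introspection))
}

#' Run a no-feedback control session
#'
#' Identical to [run_session()] except that `feedback_shown` is `"none"` on
#' every trial and the observer receives a zero cue.
#'
#' @inheritParams run_session
#' @param schedule_control a [build_control_schedule()] data.frame.
#' @return data.frame of trial records.
#' @export
run_control_session <- function(schedule_control, model, gen, observer,
                                templates, seed, trial_duration = 5,
                                n_boot = 1000, n_last = 6,
                                observer_evidence = c("latent", "decoded")) {
  if (!all(schedule_control$feedback_type == "none"))
    cbl_stop("control schedule must have feedback_type == 'none'")
  run_session(schedule_control, model, gen, observer, templates, seed,
              trial_duration, n_boot, n_last, observer_evidence)
}
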