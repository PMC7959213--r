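#' Schedule configuration for the main experimental phase
#'
#' Defaults reproduce the published design: 480 main trials in 3 blocks of
#' 160, feedback deceptive on exactly 25% of trials, reports requested on
#' all deceptive trials and on one-third of the informative trials (so 120
#' deceptive and 120 informative reports per session), plus a separate
#' 160-trial no-feedback control block with reports on half the trials.
#' Counts are realized exactly (fixed counts shuffled), not by per-trial
#' coin flips, and are balanced within blocks.
#'
#' @param n_main_trials number of main-phase trials (default 480).
#' @param p_deceptive fraction of deceptive trials (default 0.25).
#' @param report_fraction_informative fraction of informative trials with a
#'   report request (default 1/3).
#' @param n_control_trials control-phase trials (default 160).
#' @param control_report_fraction fraction of control trials with a report
#'   request (default 0.5).
#' @param n_blocks main-phase blocks (default 3); counts must split evenly.
#' @param trial_duration,feedback_duration seconds (5 and 0.5).
#' @param control_position where the control block is inserted (metadata
#'   only): `"third"`, `"two_thirds"` or `"end"`.
#' @param seed integer seed for the trial-order permutation.
#' @return object of class `cbl_schedule_config`.
#' @export
schedule_config <- function(n_main_trials = 480, p_deceptive = 0.25,
                            report_fraction_informative = 1 / 3,
                            n_control_trials = 160,
                            control_report_fraction = 0.5,
                            n_blocks = 3, trial_duration = 5,
                            feedback_duration = 0.5,
                            control_position = c("end", "third", "two_thirds"),
                            seed = 1L) {
  control_position <- match.arg(control_position)
  if (!is_count(n_main_trials) || !is_count(n_blocks))
    cbl_stop("trial and block counts must be positive integers")
  if (p_deceptive < 0 || p_deceptive > 1 ||
      report_fraction_informative < 0 || report_fraction_informative > 1)
    cbl_stop("fractions must be in [0, 1]")
  if (trial_duration <= 0) cbl_stop("trial_duration must be > 0")
  structure(list(n_main_trials = as.integer(n_main_trials),
                 p_deceptive = p_deceptive,
                 report_fraction_informative = report_fraction_informative,
                 n_control_trials = as.integer(n_control_trials),
                 control_report_fraction = control_report_fraction,
                 n_blocks = as.integer(n_blocks),
                 trial_duration = trial_duration,
                 feedback_duration = feedback_duration,
                 control_position = control_position,
                 seed = as.integer(seed)),
            class = "cbl_schedule_config")
}

.whole <- function(x, what) {
  if (abs(x - round(x)) > 1e-9)
    cbl_stop("%s = %g is not a whole number; adjust fractions", what, x)
  as.integer(round(x))
}

#' Build the main-phase trial schedule
#'
#' Feedback validity and report requests are assigned before any decoding,
#' with exact counts balanced within each block, and the within-block order
#' permuted from `cfg$seed`.  Receiving a report request is independent of
#' feedback validity by design.
#'
#' @param cfg a [schedule_config()] object.
#' @return data.frame with columns `trial`, `block`, `phase`,
#'   `feedback_type` (`"informative"`/`"deceptive"`), `report_requested`.
#' @export
build_schedule <- function(cfg) {
  stopifnot(inherits(cfg, "cbl_schedule_config"))
  n <- cfg$n_main_trials
  per_block <- .whole(n / cfg$n_blocks, "trials per block")
  dec_block <- .whole(n * cfg$p_deceptive / cfg$n_blocks,
                      "deceptive trials per block")
  inf_block <- per_block - dec_block
  rep_inf_block <- .whole(inf_block * cfg$report_fraction_informative,
                          "informative report trials per block")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  blocks <- lapply(seq_len(cfg$n_blocks), function(bl) {
    fb <- c(rep("deceptive", dec_block), rep("informative", inf_block))
    rq <- c(rep(TRUE, dec_block),
            rep(TRUE, rep_inf_block), rep(FALSE, inf_block - rep_inf_block))
    set.seed(derive_seed(cfg$seed, "schedule", bl))
    ord <- sample.int(per_block)
    data.frame(block = bl, feedback_type = fb[ord], report_requested = rq[ord])
  })
  out <- do.call(rbind, blocks)
  out <- cbind(trial = seq_len(n), phase = "main", out)
  out[, c("trial", "block", "phase", "feedback_type", "report_requested")]
}

#' Build the no-feedback control schedule
#'
#' @param cfg a [schedule_config()] object (uses the control fields).
#' @return data.frame as [build_schedule()] with `feedback_type = "none"`.
#' @export
build_control_schedule <- function(cfg) {
  stopifnot(inherits(cfg, "cbl_schedule_config"))
  n <- cfg$n_control_trials
  n_rep <- .whole(n * cfg$control_report_fraction, "control report trials")
  rq <- c(rep(TRUE, n_rep), rep(FALSE, n - n_rep))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, "schedule", "control"))
  rq <- rq[sample.int(n)]
  data.frame(trial = seq_len(n), block = 1L, phase = "control",
             feedback_type = "none", report_requested = rq)
}
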