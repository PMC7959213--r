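#' Cue-integration observer parameters
#'
#' The simulated participant integrates her internal decision evidence with
#' the external feedback cue, weighting each source by its reliability.
#' The decision variable is
#' `L = w_int * z + w_cue * cue / (|z| + kappa) + eps`,
#' `eps ~ N(0, sigma_obs^2)`, where `z` is the signed internal evidence
#' (positive = face) and `cue` is the feedback cue (+1 face, -1 spiral,
#' 0 none).  With `cue_weighting = "reliability"` (default) the cue's
#' effective weight grows as internal evidence weakens — cues are combined
#' with internal evidence in inverse proportion to the internal evidence's
#' availability; `"fixed"` uses the plain linear form `w_cue * cue`.
#'
#' The report is face iff `L >= 0` (exact ties resolve to face and are
#' logged).  Confidence reads out the congruence-weighted decision
#' evidence: `C = |L| + conf_congruence * cue * sign(L)`, i.e. confidence
#' is boosted when the external cue agrees with the emerging report and
#' dampened when the report contradicts the cue (decision-congruent
#' evidence weighting).  The 4-level rating is `1 +` the number of
#' `conf_thresholds` below `C`.
#'
#' All defaults were calibrated once during development against the
#' published behavioural means and then frozen (methods vignette).
#'
#' @param w_int weight on signed internal evidence (>= 0).
#' @param w_cue weight on the feedback cue (>= 0).
#' @param sigma_obs report-noise SD (> 0).
#' @param conf_thresholds 3 strictly increasing cutoffs on the confidence
#'   statistic mapping to ratings 1-4.
#' @param kappa reliability floor in the cue weight denominator (> 0;
#'   ignored for `cue_weighting = "fixed"`).
#' @param conf_congruence confidence boost per unit of cue-report
#'   congruence (>= 0).
#' @param cue_weighting `"reliability"` (default) or `"fixed"`.
#' @param introspection_window seconds of the trial's end covered by the
#'   observer's introspective readout of the attention state (used by
#'   [run_session()]).
#' @return object of class `cbl_observer`.
#' @export
observer_params <- function(w_int = 2.57, w_cue = 0.11, sigma_obs = 1,
                            conf_thresholds = c(0.54, 1.08, 1.83),
                            kappa = 0.05, conf_congruence = 0.39,
                            cue_weighting = c("reliability", "fixed"),
                            introspection_window = 0.65) {
  cue_weighting <- match.arg(cue_weighting)
  if (w_int < 0 || w_cue < 0) cbl_stop("weights must be >= 0")
  if (sigma_obs <= 0) cbl_stop("sigma_obs must be > 0")
  if (kappa <= 0) cbl_stop("kappa must be > 0")
  if (conf_congruence < 0) cbl_stop("conf_congruence must be >= 0")
  if (length(conf_thresholds) != 3 || any(diff(conf_thresholds) <= 0) ||
      any(conf_thresholds < 0))
    cbl_stop("conf_thresholds must be 3 strictly increasing non-negative values")
  if (introspection_window <= 0) cbl_stop("introspection_window must be > 0")
  structure(list(w_int = w_int, w_cue = w_cue, sigma_obs = sigma_obs,
                 conf_thresholds = conf_thresholds, kappa = kappa,
                 conf_congruence = conf_congruence,
                 cue_weighting = cue_weighting,
                 introspection_window = introspection_window),
            class = "cbl_observer")
}

# effective cue weight per trial
.cue_weight <- function(params, z) {
  if (params$cue_weighting == "reliability")
    params$w_cue / (abs(z) + params$kappa)
  else rep(params$w_cue, length(z))
}

#' Generate an introspective report and confidence
#'
#' Vectorized over trials: `z` and `cue` may be vectors of equal length.
#'
#' @param z signed internal evidence (positive = face).
#' @param cue feedback cue: +1 (face shown), -1 (spiral shown), 0 (none).
#' @param params an [observer_params()] object.
#' @param seed integer seed.
#' @return data.frame with columns `report` (`"face"`/`"spiral"`) and
#'   `confidence` (integer 1-4).
#' @export
observe_and_report <- function(z, cue, params, seed) {
  stopifnot(inherits(params, "cbl_observer"))
  if (!all(cue %in% c(-1, 0, 1))) cbl_stop("cue must be -1, 0 or +1")
  n <- max(length(z), length(cue))
  z <- rep_len(z, n); cue <- rep_len(cue, n)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  L <- params$w_int * z + .cue_weight(params, z) * cue +
    rnorm(n, 0, params$sigma_obs)
  if (any(L == 0)) cbl_log("decision variable exactly 0; tie resolved to face",
                           class = "cbl_tie")
  report <- ifelse(L >= 0, "face", "spiral")
  s <- ifelse(L >= 0, 1, -1)
  C <- abs(L) + params$conf_congruence * cue * s
  thr <- params$conf_thresholds
  confidence <- 1L + (C > thr[1]) + (C > thr[2]) + (C > thr[3])
  data.frame(report = report, confidence = as.integer(confidence))
}

#' Fit observer parameters by maximum likelihood
#'
#' Recovers `(w_int, w_cue, sigma_obs)` from observed reports and
#' confidences, treating the confidence thresholds, `kappa` and
#' `conf_congruence` as known (reports alone identify the model only up to
#' scale).  Each (report, confidence) pair pins the Gaussian decision
#' variable into a signed interval, so the likelihood is a difference of
#' normal CDFs, maximized by Nelder-Mead on log-parameters.
#'
#' @param z,cue trial predictors as in [observe_and_report()].
#' @param report,confidence observed responses.
#' @param params an [observer_params()] carrying the known constants
#'   (thresholds, `kappa`, `conf_congruence`, `cue_weighting`).
#' @param init starting values `c(w_int, w_cue, sigma_obs)`.
#' @return list with `w_int`, `w_cue`, `sigma_obs`, `logLik`,
#'   `convergence`.
#' @export
fit_observer <- function(z, cue, report, confidence,
                         params = observer_params(), init = c(1, 0.2, 1)) {
  s <- ifelse(report == "face", 1, -1)
  # confidence statistic bounds -> |L| bounds (clamped at 0)
  edges <- c(-Inf, params$conf_thresholds, Inf)  # C itself may be negative
  shift <- params$conf_congruence * cue * s
  lo_abs <- pmax(0, edges[confidence] - shift)
  hi_abs <- pmax(0, edges[confidence + 1L] - shift)
  lo <- ifelse(s > 0, lo_abs, -hi_abs)
  hi <- ifelse(s > 0, hi_abs, -lo_abs)
  relw <- if (params$cue_weighting == "reliability")
    1 / (abs(z) + params$kappa) else rep(1, length(z))
  nll <- function(par) {
    w_int <- exp(par[1]); w_cue <- exp(par[2]); sig <- exp(par[3])
    m <- w_int * z + w_cue * relw * cue
    p <- pnorm((hi - m) / sig) - pnorm((lo - m) / sig)
    -sum(log(pmax(p, 1e-300)))
  }
  fit <- optim(log(init), nll, control = list(maxit = 2000, reltol = 1e-10))
  list(w_int = exp(fit$par[1]), w_cue = exp(fit$par[2]),
       sigma_obs = exp(fit$par[3]), logLik = -fit$value,
       convergence = fit$convergence)
}
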