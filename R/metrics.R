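#' Internal evidence of a decision
#'
#' Accumulated difference between the face and spiral correlation scores
#' over the last `n_last` score pairs (default 6, the last 1.5 s of the
#' decision phase at a 250 ms hop; with 3 s windows this spans 4.5 s of
#' data).  `ie` is the absolute value; `signed_ie` keeps the direction
#' (positive = face).
#'
#' @param stream a [stream_scores()] data.frame.
#' @param n_last number of trailing score pairs to accumulate.
#' @return list with `ie` (>= 0) and `signed_ie`.
#' @export
internal_evidence <- function(stream, n_last = 6) {
  if (nrow(stream) < n_last)
    cbl_stop("stream has %d pairs but n_last = %d", nrow(stream), n_last)
  idx <- (nrow(stream) - n_last + 1L):nrow(stream)
  signed <- sum(stream$c_face[idx] - stream$c_spiral[idx])
  list(ie = abs(signed), signed_ie = signed)
}

#' Consistency of internal decision evidence
#'
#' Ratio of internal-evidence strength to its variability: the numerator is
#' [internal_evidence()] over the last 1.5 s, the denominator the
#' bootstrapped variance of the per-window correlation differences over the
#' accumulation period (the 3 s before feedback, i.e. 12 score pairs at a
#' 250 ms hop).  The bootstrap resamples the differences with replacement
#' `n_boot` times; by default the summary is the mean of the resampled
#' variances (`boot_stat = "mean_var"`); `"var_of_means"` is available as an
#' alternative reading.  A near-zero denominator is floored at `eps` and
#' logged.
#'
#' @param stream a [stream_scores()] data.frame.
#' @param accumulation_window variance window in seconds (default 3).
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param n_last score pairs entering the numerator (default 6).
#' @param boot_stat bootstrap summary, see above.
#' @param eps denominator floor (default 1e-8).
#' @return consistency value (>= 0) with attribute `denominator`.
#' @export
consistency <- function(stream, accumulation_window = 3.0, n_boot = 1000,
                        seed = 1L, n_last = 6, eps = 1e-8,
                        boot_stat = c("mean_var", "var_of_means")) {
  boot_stat <- match.arg(boot_stat)
  hop <- attr(stream, "hop") %||% 0.25
  m <- round(accumulation_window / hop)
  if (nrow(stream) < m)
    cbl_stop("stream has %d pairs; accumulation window needs %d", nrow(stream), m)
  idx <- (nrow(stream) - m + 1L):nrow(stream)
  d <- stream$c_face[idx] - stream$c_spiral[idx]
  num <- internal_evidence(stream, n_last)$ie
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draws <- matrix(d[sample.int(m, m * n_boot, replace = TRUE)], nrow = m)
  den <- if (boot_stat == "mean_var") {
    mu <- colMeans(draws)
    mean((colSums(draws^2) - m * mu^2) / (m - 1))
  } else {
    var(colMeans(draws))
  }
  if (den < eps) {
    cbl_log("degenerate score-difference variance (%g); floored at %g",
            den, eps, class = "cbl_degenerate")
    den_used <- eps
  } else den_used <- den
  structure(num / den_used, denominator = den)
}

#' Label report accuracy
#'
#' A report is correct when it matches the item decoded by the BCI (not the
#' latent attended state, which is unobservable in the real experiment).
#'
#' @param report,decoded `"face"`/`"spiral"` (vectorized).
#' @return `"correct"`/`"incorrect"`.
#' @export
label_accuracy <- function(report, decoded) {
  stopifnot(all(report %in% c("face", "spiral")),
            all(decoded %in% c("face", "spiral")))
  ifelse(report == decoded, "correct", "incorrect")
}

#' Label the introspective mechanism
#'
#' Only deceptive trials disambiguate introspection: a correct report
#' despite the deceptive cue is genuine introspection, an incorrect one a
#' confabulation.  On informative (or no-feedback) trials accuracy does not
#' identify the mechanism, so the label is `"n/a"`.
#'
#' @param feedback_type `"informative"`, `"deceptive"` or `"none"`
#'   (vectorized).
#' @param accuracy `"correct"`/`"incorrect"` from [label_accuracy()].
#' @return `"genuine"`, `"confabulation"` or `"n/a"`.
#' @export
label_introspection <- function(feedback_type, accuracy) {
  stopifnot(all(feedback_type %in% c("informative", "deceptive", "none")))
  n <- max(length(feedback_type), length(accuracy))
  feedback_type <- rep_len(feedback_type, n)
  accuracy <- rep_len(accuracy, n)
  out <- rep("n/a", n)
  dec <- feedback_type == "deceptive"
  if (any(dec & !accuracy %in% c("correct", "incorrect")))
    cbl_stop("accuracy must be defined on deceptive trials")
  out[dec & accuracy == "correct"] <- "genuine"
  out[dec & accuracy == "incorrect"] <- "confabulation"
  out
}
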