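#' EEG generator parameters
#'
#' Forward model for synthetic ssVEP EEG: the attended and unattended
#' template drives are combined with gains `attended_gain` and
#' `unattended_gain`, projected onto the channels through one fixed random
#' spatial mixing vector per participant, and embedded in broadband noise.
#' `noise_sd` was calibrated once during development so that
#' leave-one-trial-out decoding on a 30-trial training session averages the
#' published benchmark accuracy, then frozen (see the methods vignette).
#'
#' @param n_channels number of EEG channels (default 64).
#' @param fs_raw raw sampling rate, samples/s (default 2048).
#' @param attended_gain,unattended_gain drive gains; attended must exceed
#'   unattended, both non-negative.
#' @param noise_sd per-channel noise standard deviation (> 0).
#' @param noise_spectrum `"white"` (default) or `"one_over_f"` (approximate
#'   1/f shaping through a fixed pinking cascade).
#' @param switch_prob probability of a single mid-trial attention switch.
#' @param attention_strength length-2 Beta shape parameters of the per-trial
#'   latent attention strength `q` in \[0, 1\].  `q` scales the
#'   attended/unattended gain contrast around its midpoint (`q = 1`
#'   reproduces the nominal gains, `q = 0` removes the attentional
#'   modulation entirely), so weak-attention trials are hard for the decoder
#'   *and* carry weak introspective evidence — the coupling that produces
#'   choice-blindness episodes.  Set to `NULL` to fix `q = 1`.
#' @param lead_in_s seconds of continued stimulation simulated before each
#'   trial's decision phase (the experiment's stimulation is continuous
#'   across trials); also absorbs filter onset transients.
#' @param channel_lag_jitter_ms optional per-channel response latency jitter,
#'   drawn uniformly in `[0, channel_lag_jitter_ms]` from `mixing_seed`.
#' @param mixing_seed,noise_seed integer seeds for the spatial mixing vector
#'   and the noise stream.
#' @return object of class `cbl_gen_params`.
#' @export
eeg_gen_params <- function(n_channels = 64, fs_raw = 2048,
                           attended_gain = 1, unattended_gain = 0.4,
                           noise_sd = 13.2, noise_spectrum = c("white", "one_over_f"),
                           switch_prob = 0.55, attention_strength = c(1.3, 1.0),
                           lead_in_s = 2,
                           channel_lag_jitter_ms = 0,
                           mixing_seed = 1L, noise_seed = 1L) {
  noise_spectrum <- match.arg(noise_spectrum)
  if (!(attended_gain > unattended_gain && unattended_gain >= 0))
    cbl_stop("need attended_gain > unattended_gain >= 0")
  if (!(noise_sd > 0)) cbl_stop("noise_sd must be > 0")
  if (!(switch_prob >= 0 && switch_prob <= 1))
    cbl_stop("switch_prob must be in [0, 1]")
  if (n_channels < 2) cbl_stop("need at least 2 channels")
  if (!is.null(attention_strength) &&
      (length(attention_strength) != 2 || any(attention_strength <= 0)))
    cbl_stop("attention_strength must be two positive Beta shapes or NULL")
  structure(list(n_channels = as.integer(n_channels), fs_raw = fs_raw,
                 attended_gain = attended_gain,
                 unattended_gain = unattended_gain, noise_sd = noise_sd,
                 noise_spectrum = noise_spectrum, switch_prob = switch_prob,
                 attention_strength = attention_strength,
                 lead_in_s = lead_in_s,
                 channel_lag_jitter_ms = channel_lag_jitter_ms,
                 mixing_seed = as.integer(mixing_seed),
                 noise_seed = as.integer(noise_seed)),
            class = "cbl_gen_params")
}

#' Sample a latent attention trace
#'
#' Piecewise-constant attended category over one trial: the initial state is
#' equiprobable, and with probability `switch_prob` a single switch occurs at
#' a uniformly random time in `(0, duration)`.  If `strength_shape` is given,
#' a per-trial latent attention strength `q ~ Beta(shape1, shape2)` is also
#' drawn (otherwise `q = 1`).
#'
#' @param duration trial duration in seconds.
#' @param switch_prob probability of a mid-trial switch.
#' @param seed integer seed.
#' @param strength_shape optional length-2 Beta shapes for the attention
#'   strength `q`.
#' @return object of class `cbl_trace`: `initial`, `switch_time` (NA if
#'   none), `duration`, `strength`.
#' @export
sample_attention_trace <- function(duration, switch_prob, seed,
                                   strength_shape = NULL) {
  if (!(duration > 0)) cbl_stop("duration must be > 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  initial <- if (runif(1) < 0.5) "face" else "spiral"
  switch_time <- if (runif(1) < switch_prob) runif(1, 0, duration) else NA_real_
  strength <- if (is.null(strength_shape)) 1
              else stats::rbeta(1, strength_shape[1], strength_shape[2])
  structure(list(initial = initial, switch_time = switch_time,
                 duration = duration, strength = strength),
            class = "cbl_trace")
}

# save/restore R's RNG state so package internals never disturb user RNG
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Attended category at given times
#' @param trace a [sample_attention_trace()] object.
#' @param t numeric vector of times in seconds.
#' @return character vector `"face"`/`"spiral"`.
#' @export
attended_at <- function(trace, t) {
  other <- if (trace$initial == "face") "spiral" else "face"
  out <- rep(trace$initial, length(t))
  if (!is.na(trace$switch_time)) out[t >= trace$switch_time] <- other
  out
}

# prepend lead-in time to a trace (attended state extended backwards)
extend_trace <- function(trace, lead_in_s) {
  structure(list(initial = trace$initial,
                 switch_time = if (is.na(trace$switch_time)) NA_real_
                               else trace$switch_time + lead_in_s,
                 duration = trace$duration + lead_in_s,
                 strength = trace$strength %||% 1), class = "cbl_trace")
}

#' Simulate raw EEG for one trial
#'
#' Builds the 1-D source `s(t) = g_att * y_attended(t) + g_unatt *
#' y_unattended(t)` following the attention trace, projects it through the
#' participant's fixed random spatial mixing vector (standard normal over
#' channels, scaled by `1/sqrt(n_channels)`), optionally applies per-channel
#' latency jitter, and adds Gaussian noise.  Deterministic given
#' `params$mixing_seed` and `seed`.  A degenerate all-zero mixing vector is
#' regenerated from `mixing_seed + 1` and logged.
#'
#' @param templates a [make_templates()] object at `params$fs_raw` covering
#'   the trace duration.
#' @param trace a [sample_attention_trace()] object.
#' @param params an [eeg_gen_params()] object.
#' @param seed integer seed for the noise stream.
#' @return a raw [cbl_eeg()] segment at `params$fs_raw`.
#' @export
simulate_trial_eeg <- function(templates, trace, params, seed) {
  stopifnot(inherits(templates, "cbl_templates"),
            inherits(trace, "cbl_trace"), inherits(params, "cbl_gen_params"))
  if (abs(templates$fs - params$fs_raw) > 1e-9)
    cbl_stop("templates at %g Hz but generator expects fs_raw = %g Hz",
             templates$fs, params$fs_raw)
  n <- round(trace$duration * params$fs_raw)
  if (length(templates$y_face) < n)
    cbl_stop("templates (%d samples) shorter than trace (%d samples)",
             length(templates$y_face), n)
  t <- (seq_len(n) - 1) / params$fs_raw
  att <- attended_at(trace, t)
  face_attended <- att == "face"
  # latent attention strength q scales the gain contrast around its midpoint
  q <- trace$strength %||% 1
  mid <- (params$attended_gain + params$unattended_gain) / 2
  half <- (params$attended_gain - params$unattended_gain) / 2
  g_att <- mid + q * half
  g_unatt <- mid - q * half
  g_f <- ifelse(face_attended, g_att, g_unatt)
  g_s <- ifelse(face_attended, g_unatt, g_att)
  src <- g_f * templates$y_face[seq_len(n)] + g_s * templates$y_spiral[seq_len(n)]

  mix <- .mixing_vector(params)
  shifts <- .channel_shifts(params)
  src_pad <- c(numeric(max(shifts)), src)
  data <- cpp_mix_noise(src_pad, mix, shifts, n,
                        if (params$noise_spectrum == "white") params$noise_sd else 1,
                        as.double(seed %% 2^31))
  if (params$noise_spectrum == "one_over_f") {
    # shape an extra unit-variance stream through a fixed pinking cascade,
    # rescaled to noise_sd RMS, added to the clean projection
    clean <- outer(src, mix)
    white <- data - clean
    pink <- sos_filter(white, .pink_sos)
    pink <- pink * (params$noise_sd / .pink_gain())
    data <- clean + pink
  }
  cbl_eeg(data, params$fs_raw)
}

.mixing_vector <- function(params) {
  draw <- function(s) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(s)
    rnorm(params$n_channels) / sqrt(params$n_channels)
  }
  mix <- draw(params$mixing_seed)
  if (sum(abs(mix)) < 1e-12) {
    cbl_log("degenerate all-zero mixing vector; regenerating from seed + 1",
            class = "cbl_degenerate")
    mix <- draw(params$mixing_seed + 1L)
  }
  mix
}

.channel_shifts <- function(params) {
  if (params$channel_lag_jitter_ms <= 0)
    return(integer(params$n_channels))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(params$mixing_seed, "lagjitter"))
  as.integer(round(runif(params$n_channels, 0,
                         params$channel_lag_jitter_ms / 1000) * params$fs_raw))
}

# fixed -3 dB/octave pinking approximation (one-pole cascade); the white
# noise gain of the cascade is cached on first use so the shaped noise can
# be rescaled back to noise_sd RMS
.pink_sos <- rbind(
  c(1, -0.98820, 0, 1, -0.99572, 0),
  c(1, -0.83246, 0, 1, -0.94791, 0),
  c(1, -0.43046, 0, 1, -0.53567, 0))

.pink_cache <- new.env(parent = emptyenv())

.pink_gain <- function() {
  if (is.null(.pink_cache$g)) {
    h <- matrix(0, 8192, 1); h[1] <- 1
    .pink_cache$g <- sqrt(sum(sos_filter(h, .pink_sos)^2))
  }
  .pink_cache$g
}
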