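#' Abstract 1-D stimulus templates
#'
#' The decoder never sees images: each visual stream is represented by a 1-D
#' oscillation with one value per time sample.  Face and spiral drives share
#' the same frequency (default 1.875 Hz) but are in temporal phase
#' opposition; for the sinusoidal realization `y_spiral = -y_face`
#' pointwise.  The phase convention is fixed: the face drive starts at phase
#' 0, the spiral at phase pi.
#'
#' @param f0 oscillation frequency in Hz (default 1.875).
#' @param fs sampling rate in samples/s (default 256).
#' @param duration duration in seconds; `duration * fs` must be a whole
#'   number of samples.
#' @param waveform `"sinusoid"` (default) or `"sweep"`, a periodic
#'   sawtooth-shaped scrambling envelope with period `1/f0` mimicking a
#'   sweep-type periodic drive.
#' @return an object of class `cbl_templates`: list with `y_face`,
#'   `y_spiral`, `fs`, `f0`, `duration`, `waveform`.
#' @export
#' @examples
#' tmpl <- make_templates(1.875, 256, 5)
#' cor(tmpl$y_face, tmpl$y_spiral)  # -1
make_templates <- function(f0 = 1.875, fs = 256, duration = 5,
                           waveform = c("sinusoid", "sweep")) {
  waveform <- match.arg(waveform)
  if (!is.finite(f0) || f0 <= 0) cbl_stop("f0 must be positive, got %s", f0)
  if (!is.finite(duration) || duration <= 0)
    cbl_stop("duration must be positive, got %s", duration)
  if (f0 >= fs / 2) cbl_stop("f0 = %g not below Nyquist %g", f0, fs / 2)
  n <- duration * fs
  if (abs(n - round(n)) > 1e-9)
    cbl_stop("duration * fs = %g is not a whole number of samples", n)
  n <- round(n)
  t <- (seq_len(n) - 1) / fs
  if (waveform == "sinusoid") {
    y_face <- sin(2 * pi * f0 * t)
    y_spiral <- -y_face
  } else {
    # periodic sawtooth envelope, face at phase 0 and spiral shifted by half
    # a period; the half-sample phase offset keeps the sampled waveform
    # exactly zero-mean over integer cycles
    saw <- function(ph) 2 * (ph - floor(ph + 0.5))
    off <- f0 / (2 * fs)
    y_face <- saw(f0 * t + off)
    y_spiral <- saw(f0 * t + 0.5 + off)
  }
  structure(list(y_face = y_face, y_spiral = y_spiral, fs = fs, f0 = f0,
                 duration = duration, waveform = waveform),
            class = "cbl_templates")
}

#' @export
print.cbl_templates <- function(x, ...) {
  cat(sprintf("<cbl_templates> %s, f0 = %g Hz, fs = %g Hz, %g s (%d samples)\n",
              x$waveform, x$f0, x$fs, x$duration, length(x$y_face)))
  invisible(x)
}

#' Dominant spectral peak of a signal
#'
#' Peak frequency of the magnitude spectrum, refined beyond the raw FFT bin
#' width by Hann windowing, zero-padding and parabolic interpolation of the
#' log-magnitude around the peak bin.  Needed because template durations are
#' generally not an integer number of cycles, so the oscillation frequency
#' falls between raw FFT bins (the Hann window suppresses the leakage that
#' would otherwise bias the interpolation).
#'
#' @param y numeric signal.
#' @param fs sampling rate, samples/s.
#' @param pad_factor zero-padding factor (default 64).
#' @return peak frequency in Hz.
#' @export
template_peak_frequency <- function(y, fs, pad_factor = 64) {
  n <- length(y)
  nfft <- 2^ceiling(log2(n * pad_factor))
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  spec <- Mod(fft(c((y - mean(y)) * w, numeric(nfft - n))))[seq_len(nfft %/% 2)]
  i <- which.max(spec)
  # parabolic interpolation on log magnitude (guard the spectrum edges)
  if (i > 1 && i < length(spec)) {
    la <- log(spec[i - 1]); lb <- log(spec[i]); lc <- log(spec[i + 1])
    d <- 0.5 * (la - lc) / (la - 2 * lb + lc)
  } else d <- 0
  (i - 1 + d) * fs / nfft
}

#' Fraction of spectral energy at the fundamental
#'
#' @param y numeric signal; `fs` sampling rate; `f0` fundamental in Hz;
#'   `tol_hz` half-width of the band counted as "at f0".
#' @return fraction in \[0, 1\].
#' @export
spectral_energy_fraction <- function(y, fs, f0, tol_hz = 0.25) {
  n <- length(y)
  spec <- Mod(fft(y - mean(y)))^2
  freqs <- (seq_len(n) - 1) * fs / n
  # fold: consider both f and fs - f
  at <- (abs(freqs - f0) <= tol_hz) | (abs(freqs - (fs - f0)) <= tol_hz)
  sum(spec[at]) / sum(spec)
}

#' Export templates as two-column CSV files
#'
#' Writes `time_s,value` rows for each category.
#'
#' @param templates a [make_templates()] object.
#' @param face_path,spiral_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_templates_csv <- function(templates, face_path, spiral_path) {
  stopifnot(inherits(templates, "cbl_templates"))
  t <- (seq_along(templates$y_face) - 1) / templates$fs
  write.csv(data.frame(time_s = t, value = templates$y_face),
            face_path, row.names = FALSE)
  write.csv(data.frame(time_s = t, value = templates$y_spiral),
            spiral_path, row.names = FALSE)
  invisible(c(face_path, spiral_path))
}
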