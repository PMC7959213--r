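#' EEG segment container
#'
#' A minimal time-by-channel container with sampling-rate metadata: raw
#' segments are 2048 Hz, processed segments 256 Hz by default.
#'
#' @param data numeric matrix, time in rows, channels in columns.
#' @param fs sampling rate in samples/s.
#' @param channel_names optional channel labels.
#' @return object of class `cbl_eeg`.
#' @export
cbl_eeg <- function(data, fs, channel_names = NULL) {
  data <- as.matrix(data)
  if (nrow(data) < 1) cbl_stop("EEG segment must contain at least 1 sample")
  if (anyNA(data)) cbl_stop("EEG segment contains NA/NaN")
  if (!is.finite(fs) || fs <= 0) cbl_stop("fs must be positive")
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(ncol(data)))
  colnames(data) <- channel_names
  structure(list(data = data, fs = fs), class = "cbl_eeg")
}

#' @export
print.cbl_eeg <- function(x, ...) {
  cat(sprintf("<cbl_eeg> %d samples x %d channels @ %g Hz (%.3f s)\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs))
  invisible(x)
}

n_samples <- function(seg) nrow(seg$data)

#' Downsample an EEG segment
#'
#' Causal anti-alias low-pass (order-8 Butterworth at `0.4 * fs_out`)
#' followed by decimation.  The target rate must divide the input rate.
#'
#' @param seg a [cbl_eeg()] segment.
#' @param fs_out target sampling rate (default 256).
#' @return downsampled `cbl_eeg`.
#' @export
eeg_downsample <- function(seg, fs_out = 256) {
  stopifnot(inherits(seg, "cbl_eeg"))
  r <- seg$fs / fs_out
  if (abs(r - round(r)) > 1e-9)
    cbl_stop("fs_out = %g does not divide fs = %g", fs_out, seg$fs)
  r <- round(r)
  if (r == 1) return(seg)
  sos <- butter_sos(8, 0.4 * fs_out, seg$fs, "low")
  y <- sos_filter(seg$data, sos)
  idx <- seq(1, by = r, length.out = floor(nrow(y) / r))
  cbl_eeg(y[idx, , drop = FALSE], fs_out, colnames(seg$data))
}

#' Band-pass filter an EEG segment
#'
#' One-pass (causal, forward-only) Butterworth band-pass, as used by a
#' real-time decoder; no zero-phase filtering.
#'
#' @param seg a [cbl_eeg()] segment.
#' @param lo,hi band edges in Hz (defaults 1 and 30).
#' @param order prototype filter order (default 6).
#' @return filtered `cbl_eeg`.
#' @export
eeg_bandpass <- function(seg, lo = 1, hi = 30, order = 6) {
  stopifnot(inherits(seg, "cbl_eeg"))
  if (!(lo > 0 && lo < hi && hi < seg$fs / 2))
    cbl_stop("invalid band (%g, %g) for fs = %g", lo, hi, seg$fs)
  sos <- butter_sos(order, c(lo, hi), seg$fs, "band")
  cbl_eeg(sos_filter(seg$data, sos), seg$fs, colnames(seg$data))
}

#' Re-reference to the common average
#'
#' Subtracts the across-channel mean from every channel at each sample.
#'
#' @param seg a [cbl_eeg()] segment with at least 2 channels.
#' @return re-referenced `cbl_eeg`.
#' @export
eeg_rereference <- function(seg) {
  stopifnot(inherits(seg, "cbl_eeg"))
  if (ncol(seg$data) < 2) cbl_stop("average reference needs >= 2 channels")
  cbl_eeg(seg$data - rowMeans(seg$data), seg$fs, colnames(seg$data))
}

#' Online preprocessing chain
#'
#' Applies the decoder-side chain in order: downsample to `fs_out`,
#' band-pass `lo`-`hi` Hz (one-pass Butterworth of the given order), then
#' common average reference.
#'
#' @inheritParams eeg_downsample
#' @inheritParams eeg_bandpass
#' @return processed `cbl_eeg` at `fs_out`.
#' @export
preprocess_chain <- function(seg, fs_out = 256, lo = 1, hi = 30, order = 6) {
  eeg_rereference(eeg_bandpass(eeg_downsample(seg, fs_out), lo, hi, order))
}
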