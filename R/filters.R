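# Butterworth IIR design via the classic analog-prototype + bilinear
# transform route, returned as second-order sections for numerically safe
# cascade filtering.  Implemented here because no DSP package is available
# in the locked-down environment; validated in the tests against the
# analytic Butterworth magnitude response.

#' Design a Butterworth filter as second-order sections
#'
#' Designs a causal digital Butterworth low-pass or band-pass filter by
#' bilinear transform of the analog prototype with frequency pre-warping.
#' Band-pass design of prototype order `n` yields `2n` poles (`n` biquads),
#' the convention used by standard DSP toolboxes.
#'
#' @param order prototype filter order.
#' @param w cutoff frequency in Hz (low-pass) or length-2 band edges
#'   (band-pass).
#' @param fs sampling rate in samples/s.
#' @param type `"low"` or `"band"`.
#' @return matrix with 6 columns `(b0, b1, b2, 1, a1, a2)`, one row per
#'   second-order section.
#' @export
butter_sos <- function(order, w, fs, type = c("low", "band")) {
  type <- match.arg(type)
  if (!is_count(order)) cbl_stop("order must be a positive integer")
  if (any(w <= 0) || any(w >= fs / 2))
    cbl_stop("band edges must lie in (0, fs/2); got %s at fs = %g",
             paste(w, collapse = ", "), fs)
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order)) # left half-plane
  if (type == "low") {
    wc <- warp(w)
    poles <- wc * proto
    num <- c(1, 2, 1)                      # all zeros at z = -1
    ref_w <- 0                             # unit gain at DC
  } else {
    if (length(w) != 2 || w[2] <= w[1]) cbl_stop("band must be (lo, hi), lo < hi")
    wl <- warp(w[1]); wh <- warp(w[2])
    B <- wh - wl; w0 <- sqrt(wl * wh)
    bp <- B * proto
    disc <- sqrt(as.complex(bp^2 - 4 * w0^2))
    poles <- c((bp + disc) / 2, (bp - disc) / 2)
    num <- c(1, 0, -1)                     # zeros at z = 1 and z = -1
    ref_w <- 2 * atan(w0 / (2 * fs))       # warped centre (digital rad/sample)
  }
  zp <- (2 * fs + poles) / (2 * fs - poles)
  # pair poles into conjugate (or real) pairs
  tol <- 1e-9
  cplx <- zp[Im(zp) > tol]
  realp <- Re(zp[abs(Im(zp)) <= tol])
  sections <- lapply(cplx, function(p) c(1, -2 * Re(p), Mod(p)^2))
  if (length(realp) %% 2 != 0) cbl_stop("internal: unpaired real pole")
  if (length(realp) > 0) {
    realp <- sort(realp)
    for (i in seq(1, length(realp), by = 2)) {
      r1 <- realp[i]; r2 <- realp[i + 1]
      sections <- c(sections, list(c(1, -(r1 + r2), r1 * r2)))
    }
  }
  dens <- do.call(rbind, sections)
  # order sections by pole radius ascending (closest to unit circle last)
  dens <- dens[order(sqrt(pmax(dens[, 3], 0))), , drop = FALSE]
  L <- nrow(dens)
  sos <- cbind(matrix(rep(num, each = L), nrow = L), dens)
  # normalize overall gain at the reference frequency
  g <- Mod(sos_response(sos, ref_w))
  sos[1, 1:3] <- sos[1, 1:3] / g
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  sos
}

#' Complex frequency response of an SOS cascade
#'
#' @param sos SOS matrix from [butter_sos()].
#' @param w digital frequency in radians/sample (vectorized).
#' @return complex response values.
#' @export
sos_response <- function(sos, w) {
  z1 <- exp(-1i * w)
  h <- rep(1 + 0i, length(w))
  for (s in seq_len(nrow(sos))) {
    h <- h * (sos[s, 1] + sos[s, 2] * z1 + sos[s, 3] * z1^2) /
      (sos[s, 4] + sos[s, 5] * z1 + sos[s, 6] * z1^2)
  }
  unname(h)
}

#' Causal SOS cascade filtering of a time-by-channel matrix
#'
#' Direct form II transposed, zero initial state, channel by channel.
#'
#' @param x numeric matrix (time in rows) or vector.
#' @param sos SOS matrix from [butter_sos()].
#' @return filtered matrix of the same dimensions.
#' @export
sos_filter <- function(x, sos) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  cpp_sosfilt(x, sos)
}
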