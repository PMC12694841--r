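#' Band-pass filter specification
#'
#' Defaults follow the standard blink-extraction passband: 0.5-20 Hz,
#' 4th-order Butterworth prototype, applied forward-backward (zero phase) so
#' blink peak amplitudes and latencies are preserved.
#'
#' @param low_cut,high_cut band edges in Hz; must satisfy
#'   `0 < low_cut < high_cut < fs/2` at filtering time.
#' @param order Butterworth prototype order (the band-pass transfer has
#'   twice this many poles).
#' @param zero_phase apply the filter forward and backward (`TRUE`, default)
#'   or forward only.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_cut = 0.5, high_cut = 20, order = 4, zero_phase = TRUE) {
  if (!is_scalar_number(low_cut) || low_cut <= 0) stop("`low_cut` must be > 0", call. = FALSE)
  if (!is_scalar_number(high_cut) || high_cut <= low_cut)
    stop("`high_cut` must exceed `low_cut`", call. = FALSE)
  if (!is_scalar_number(order) || order < 1) stop("`order` must be >= 1", call. = FALSE)
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 order = as.integer(order), zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Design a Butterworth band-pass filter as second-order sections
#'
#' Analog Butterworth prototype, lowpass-to-bandpass transform with
#' prewarped edges, bilinear transform, conjugate pole pairing into biquads
#' with one zero at z = +1 and one at z = -1 per section, and unit gain at
#' the geometric-mean center frequency.
#'
#' @param order prototype order.
#' @param low,high band edges (Hz).
#' @param fs sampling rate (Hz); requires `high < fs/2`.
#' @return Numeric matrix with `order` rows and columns
#'   `b0 b1 b2 a0 a1 a2` (`a0` = 1).
#' @export
butter_bandpass_sos <- function(order, low, high, fs) {
  if (fs <= 2 * high)
    stop(sprintf("Nyquist error: fs = %g Hz must exceed 2 x high_cut = %g Hz",
                 fs, 2 * high), call. = FALSE)
  stopifnot(order >= 1, low > 0, high > low)
  n <- as.integer(order)
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # LHP prototype poles
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)
  w2 <- fs2 * tan(pi * high / fs)
  bw <- w2 - w1
  w0sq <- w1 * w2
  s <- complex(0)
  for (pk in p) {
    d <- sqrt((pk * bw)^2 - 4 * w0sq + 0i)
    s <- c(s, (pk * bw + d) / 2, (pk * bw - d) / 2)
  }
  z <- (fs2 + s) / (fs2 - s)                      # bilinear transform
  zp <- z[Im(z) > 0]
  if (length(zp) != n) zp <- z[order(-Im(z))][seq_len(n)]
  sos <- matrix(0, nrow = n, ncol = 6,
                dimnames = list(NULL, c("b0", "b1", "b2", "a0", "a1", "a2")))
  for (i in seq_len(n))
    sos[i, ] <- c(1, 0, -1, 1, -2 * Re(zp[i]), Mod(zp[i])^2)
  wc <- 2 * pi * sqrt(low * high) / fs
  sos[1, 1:3] <- sos[1, 1:3] / Mod(sos_response(sos, wc))
  sos
}

# Complex frequency response of an SOS cascade at digital frequencies w
# (radians/sample).
sos_response <- function(sos, w) {
  ejw <- exp(-1i * outer(w, 0:2))
  h <- rep(1 + 0i, length(w))
  for (i in seq_len(nrow(sos)))
    h <- h * drop(ejw %*% sos[i, 1:3]) / drop(ejw %*% sos[i, 4:6])
  h
}

# One biquad, zero initial state, via stats::filter (C implementation).
biquad_filt <- function(x, b, a) {
  v <- stats::filter(c(0, 0, x), b, method = "convolution", sides = 1)[-(1:2)]
  as.numeric(stats::filter(v, -a[2:3], method = "recursive"))
}

sos_filt <- function(sos, x) {
  for (i in seq_len(nrow(sos))) x <- biquad_filt(x, sos[i, 1:3], sos[i, 4:6])
  x
}

#' Apply the band-pass filter to a bipolar VEOG segment
#'
#' Zero-phase mode runs the second-order-section cascade forward and
#' backward over the signal after odd-reflection padding at both ends
#' (padding length `ceiling(6 * fs / low_cut)` samples, capped at the signal
#' length minus one), so 2- and 5-minute segments do not lose boundary
#' blinks to edge transients. Filtering is per segment; do not filter across
#' segment joins.
#'
#' @param signal a [bipolar_veog()], or a numeric vector with `fs` given.
#' @param spec a [filter_spec()].
#' @param fs sampling rate, only when `signal` is a bare vector.
#' @return Same type as `signal`, filtered.
#' @export
bandpass_filter <- function(signal, spec = filter_spec(), fs = NULL) {
  is_veog <- inherits(signal, "bipolar_veog")
  x <- if (is_veog) signal$samples else as.numeric(signal)
  fs <- if (is_veog) signal$fs else fs
  if (is.null(fs)) stop("`fs` is required when filtering a bare vector", call. = FALSE)
  if (fs <= 2 * spec$high_cut)
    stop(sprintf("Nyquist error: fs = %g Hz must exceed 2 x high_cut = %g Hz",
                 fs, 2 * spec$high_cut), call. = FALSE)
  nx <- length(x)
  if (nx <= 3 * (2 * spec$order + 1))
    stop(sprintf("signal too short to filter: %d samples", nx), call. = FALSE)
  sos <- butter_bandpass_sos(spec$order, spec$low_cut, spec$high_cut, fs)
  padlen <- min(nx - 1L, as.integer(ceiling(6 * fs / spec$low_cut)))
  xp <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[nx] - x[(nx - 1):(nx - padlen)])
  y <- sos_filt(sos, xp)
  if (spec$zero_phase) y <- rev(sos_filt(sos, rev(y)))
  y <- y[(padlen + 1):(padlen + nx)]
  if (is_veog) { signal$samples <- y; signal } else y
}
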