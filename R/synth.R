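#' Blink waveform parameters
#'
#' Describes the stereotyped blink deflection injected into synthetic VEOG.
#' A spontaneous blink lasts roughly 100-400 ms; the default rise/fall of
#' 110/170 ms gives a 280 ms asymmetric wave.
#'
#' @param rise_ms time from onset to peak, milliseconds.
#' @param fall_ms time from peak back to baseline, milliseconds.
#' @param peak_uv nominal peak amplitude in microvolts (individual events
#'   are rescaled to their sampled amplitudes).
#' @param shape `"gaussianlike"` (raised-cosine rise and fall, zero-valued
#'   and smooth at both ends) or `"asymmetric_gamma"` (gamma-density-shaped,
#'   fast rise and slower tail).
#' @return An object of class `waveform_params`.
#' @export
waveform_params <- function(rise_ms = 110, fall_ms = 170, peak_uv = 250,
                            shape = c("gaussianlike", "asymmetric_gamma")) {
  shape <- match.arg(shape)
  total <- rise_ms + fall_ms
  if (total < 50 || total > 600)
    stop("total waveform duration must lie in [50, 600] ms", call. = FALSE)
  if (peak_uv <= 0) stop("`peak_uv` must be > 0", call. = FALSE)
  structure(list(rise_ms = rise_ms, fall_ms = fall_ms, peak_uv = peak_uv,
                 shape = shape), class = "waveform_params")
}

# Sampled unit-peak waveform plus the 1-based index of its peak sample.
blink_waveform <- function(wp, fs) {
  rise <- wp$rise_ms / 1000
  fall <- wp$fall_ms / 1000
  t <- seq(-rise, fall, by = 1 / fs)
  w <- numeric(length(t))
  if (wp$shape == "gaussianlike") {
    up <- t <= 0
    w[up] <- 0.5 * (1 + cos(pi * t[up] / rise))
    w[!up] <- 0.5 * (1 + cos(pi * t[!up] / fall))
  } else {
    # gamma density with mode at t = 0 (shape 3), time offset so support
    # starts at -rise; truncated at +fall and tapered to zero there
    a <- 3
    sc <- rise / (a - 1)
    tt <- t + rise
    w <- stats::dgamma(tt, shape = a, scale = sc)
    w <- w / max(w)
    taper_from <- 0.9 * (rise + fall)
    tail_i <- tt > taper_from
    w[tail_i] <- w[tail_i] *
      0.5 * (1 + cos(pi * (tt[tail_i] - taper_from) / (rise + fall - taper_from)))
  }
  list(w = w, peak = which.max(w))
}

#' Blink-process parameters
#'
#' Governs synthetic blink timing and amplitude: a gamma renewal process for
#' the inter-blink intervals (IBI mean `60/rate`, shape `ibi_shape`, so the
#' long-run BRV is `1/sqrt(ibi_shape)`), lognormal per-blink peak
#' amplitudes, additive Gaussian sensor noise and an optional slow sinusoid
#' drift. IBIs are clamped below at `min_ibi` so generated events stay
#' resolvable under the 250 ms refractory rule.
#'
#' Defaults are calibrated to resting-state descriptives from the anxiety
#' cohort this pipeline targets: 16.9 blinks/min, and amplitudes well above
#' the 100 uV detection threshold.
#'
#' @param rate blink rate, blinks per minute.
#' @param ibi_shape gamma shape k of the IBI distribution (CV = 1/sqrt(k)).
#' @param amp_log_mu,amp_log_sigma log-scale mean and SD of per-blink peak
#'   amplitudes (microvolts); the default `amp_log_mu` gives a 250 uV mean.
#' @param noise_sigma additive Gaussian noise SD, microvolts.
#' @param drift_uv,drift_hz amplitude and frequency of an optional slow
#'   sinusoidal drift (0 = off).
#' @param min_ibi lower clamp for generated IBIs, seconds.
#' @param amp_min_uv lower clamp for sampled amplitudes (0 = off).
#' @return An object of class `process_params`.
#' @export
process_params <- function(rate = 16.9, ibi_shape = 4,
                           amp_log_mu = log(250) - 0.35^2 / 2,
                           amp_log_sigma = 0.35, noise_sigma = 10,
                           drift_uv = 0, drift_hz = 0.1,
                           min_ibi = 0.3, amp_min_uv = 0) {
  if (rate <= 0) stop("`rate` must be > 0", call. = FALSE)
  if (ibi_shape <= 0) stop("`ibi_shape` must be > 0", call. = FALSE)
  structure(list(rate = rate, ibi_shape = ibi_shape, amp_log_mu = amp_log_mu,
                 amp_log_sigma = amp_log_sigma, noise_sigma = noise_sigma,
                 drift_uv = drift_uv, drift_hz = drift_hz,
                 min_ibi = min_ibi, amp_min_uv = amp_min_uv),
            class = "process_params")
}

#' Sample blink event times from a gamma renewal process
#'
#' IBIs are i.i.d. gamma with mean `60/rate` and shape `ibi_shape`, clamped
#' below at `min_ibi`; event times are their cumulative sums, kept within
#' `[0, duration)`. The first event is placed one IBI after segment start.
#'
#' @param params a [process_params()].
#' @param duration segment duration, seconds.
#' @param seed optional integer seed (same seed, same event list).
#' @return Strictly increasing numeric vector of event times in seconds.
#' @export
sample_blink_times <- function(params, duration, seed = NULL) {
  stopifnot(inherits(params, "process_params"), duration > 0)
  with_seed(seed, {
    mean_ibi <- 60 / params$rate
    times <- numeric(0)
    t_cur <- 0
    # draw in chunks to avoid sample-by-sample loops
    repeat {
      n_draw <- max(16L, ceiling((duration - t_cur) / mean_ibi * 1.5) + 8L)
      ibis <- pmax(stats::rgamma(n_draw, shape = params$ibi_shape,
                                 scale = mean_ibi / params$ibi_shape),
                   params$min_ibi)
      tt <- t_cur + cumsum(ibis)
      times <- c(times, tt[tt < duration])
      if (tt[n_draw] >= duration) break
      t_cur <- tt[n_draw]
    }
    times
  })
}

#' Synthesize a bipolar VEOG trace with known ground truth
#'
#' Each event contributes one waveform scaled to its sampled lognormal
#' amplitude; overlapping waveforms are summed and flagged in the ground
#' truth. Additive Gaussian noise and optional sinusoidal drift complete
#' the trace.
#'
#' @param times event times in seconds (e.g. from [sample_blink_times()]).
#' @param waveform a [waveform_params()].
#' @param params a [process_params()] (amplitude and noise fields are used).
#' @param fs sampling rate in Hz (>= 100).
#' @param duration trace duration, seconds.
#' @param seed optional integer seed.
#' @return A list: `signal` (a [bipolar_veog()]) and `truth`, a data frame
#'   with one row per event (`time` = exact peak-sample time, `amplitude` =
#'   noiseless peak amplitude in uV, `peak_index` 0-based, `overlapped`).
#' @export
synth_trace <- function(times, waveform, params, fs, duration, seed = NULL) {
  stopifnot(inherits(waveform, "waveform_params"),
            inherits(params, "process_params"))
  if (fs < 100) stop("`fs` must be >= 100 Hz", call. = FALSE)
  n <- round(duration * fs)
  with_seed(seed, {
    wf <- blink_waveform(waveform, fs)
    nev <- length(times)
    amps <- if (nev) pmax(stats::rlnorm(nev, params$amp_log_mu,
                                        params$amp_log_sigma),
                          params$amp_min_uv) else numeric(0)
    x <- numeric(n)
    peak_idx <- integer(nev)
    for (k in seq_len(nev)) {
      p <- round(times[k] * fs) + 1L          # peak sample, 1-based
      peak_idx[k] <- p
      from <- p - wf$peak + 1L
      to <- from + length(wf$w) - 1L
      wlo <- max(1L, from); whi <- min(n, to)
      if (wlo <= whi)
        x[wlo:whi] <- x[wlo:whi] + amps[k] * wf$w[(wlo - from + 1L):(whi - from + 1L)]
    }
    overlapped <- rep(FALSE, nev)
    if (nev > 1L) {
      support_s <- (length(wf$w) - 1L) / fs
      close_next <- diff(times) < support_s
      overlapped[which(close_next)] <- TRUE
      overlapped[which(close_next) + 1L] <- TRUE
    }
    if (params$noise_sigma > 0) x <- x + stats::rnorm(n, 0, params$noise_sigma)
    if (params$drift_uv > 0) {
      ph <- stats::runif(1, 0, 2 * pi)
      x <- x + params$drift_uv * sin(2 * pi * params$drift_hz * seq_len(n) / fs + ph)
    }
    truth <- data.frame(time = (peak_idx - 1L) / fs, amplitude = amps,
                        peak_index = peak_idx - 1L, overlapped = overlapped)
    list(signal = bipolar_veog(x, fs), truth = truth)
  })
}
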