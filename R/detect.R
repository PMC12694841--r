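#' Construct a blink event series
#'
#' Usually produced by [detect_blinks()]; the constructor is exported so
#' ground-truth event tables (e.g. from the synthetic generator) can be fed
#' straight into the metrics layer.
#'
#' @param peak_time event peak times, seconds from segment start, strictly
#'   increasing.
#' @param peak_amplitude peak amplitudes in microvolts.
#' @param duration segment duration in seconds.
#' @param peak_index optional 0-based sample indices of the peaks.
#' @param segment optional 1-row [segment_spec()].
#' @param min_interval refractory interval the series claims to honor
#'   (seconds); stored for downstream checks.
#' @return An object of class `blink_series`.
#' @export
blink_series <- function(peak_time, peak_amplitude, duration,
                         peak_index = NA_integer_, segment = NULL,
                         min_interval = 0.25) {
  n <- length(peak_time)
  if (length(peak_amplitude) != n)
    stop("peak_time and peak_amplitude lengths differ", call. = FALSE)
  if (n > 1L && any(diff(peak_time) <= 0))
    stop("peak_time must be strictly increasing", call. = FALSE)
  if (!is_scalar_number(duration) || duration <= 0)
    stop("`duration` must be a positive number of seconds", call. = FALSE)
  ev <- data.frame(peak_time = as.numeric(peak_time),
                   peak_amplitude = as.numeric(peak_amplitude),
                   peak_index = rep_len(as.integer(peak_index), n))
  structure(list(events = ev, duration = duration, segment = segment,
                 min_interval = min_interval),
            class = "blink_series")
}

#' @export
print.blink_series <- function(x, ...) {
  cat(sprintf("<blink_series> %d event(s) over %.1f s (%.1f blinks/min)\n",
              nrow(x$events), x$duration,
              nrow(x$events) / (x$duration / 60)))
  invisible(x)
}

# Local maxima of a numeric vector: samples strictly greater than both
# neighbors; plateaus bounded by rises on both sides resolve to the plateau
# midpoint (lower middle for even plateaus). Endpoints never qualify, but
# the first/last *interior* sample can. Returns 1-based indices.
find_local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  s <- sign(d)
  # carry the sign of the last nonzero difference across plateaus
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  filled <- s
  idx <- cumsum(nz)
  last_nz <- c(0, s[nz])[idx + 1L]
  filled[!nz] <- last_nz[!nz]
  drops <- which(filled[-1L] < 0 & filled[-(n - 1L)] > 0) + 1L  # peak sample/plateau end
  out <- integer(length(drops))
  for (k in seq_along(drops)) {
    i <- drops[k]
    j <- i
    while (j > 1L && x[j - 1L] == x[i]) j <- j - 1L
    out[k] <- (i + j) %/% 2L
  }
  out
}

# Greedy refractory suppression: accept candidates in decreasing amplitude
# order (ties broken by earlier time); a candidate is dropped when an
# already-accepted peak lies strictly closer than min_interval.
refractory_prune <- function(times, amps, min_interval) {
  ord <- order(-amps, times)
  kept_t <- numeric(0)
  keep <- logical(length(times))
  for (i in ord) {
    if (!length(kept_t) || all(abs(kept_t - times[i]) >= min_interval - 1e-12)) {
      keep[i] <- TRUE
      kept_t <- c(kept_t, times[i])
    }
  }
  which(keep)
}

#' Detect blinks by thresholded peak-picking with a refractory interval
#'
#' Finds local maxima of the (filtered, blink-positive) bipolar VEOG that
#' reach `threshold` microvolts, then enforces the refractory rule: when two
#' supra-threshold maxima fall closer than `min_interval`, the larger is
#' kept (earlier on amplitude ties). Peaks are sought on the positive-going
#' signal only; the signal is not rectified.
#'
#' @param signal a [bipolar_veog()] (ideally band-pass filtered), or a
#'   numeric vector with `fs` supplied.
#' @param threshold detection threshold in microvolts (default 100).
#' @param min_interval minimum interval between consecutive blinks in
#'   seconds (default 0.25).
#' @param fs sampling rate, only for bare-vector input.
#' @param segment optional 1-row [segment_spec()] recorded in the result.
#' @param filtered set to `FALSE` to flag that the input skipped the
#'   band-pass stage; detection still runs but emits a warning, since the
#'   100 uV threshold is calibrated for the filtered trace.
#' @return A [blink_series()]; empty input yields an empty series.
#' @export
detect_blinks <- function(signal, threshold = 100, min_interval = 0.25,
                          fs = NULL, segment = NULL, filtered = TRUE) {
  if (!isTRUE(filtered))
    warning("detecting on a trace flagged as unfiltered; the threshold is ",
            "calibrated for the band-passed signal", call. = FALSE)
  is_veog <- inherits(signal, "bipolar_veog")
  x <- if (is_veog) signal$samples else as.numeric(signal)
  fs <- if (is_veog) signal$fs else fs
  if (is.null(fs)) stop("`fs` is required for bare-vector input", call. = FALSE)
  if (!is_scalar_number(threshold) || threshold <= 0)
    stop("`threshold` must be > 0", call. = FALSE)
  if (!is_scalar_number(min_interval) || min_interval <= 0)
    stop("`min_interval` must be > 0", call. = FALSE)
  duration <- max(length(x) / fs, 1 / fs)
  idx <- find_local_maxima(x)
  idx <- idx[x[idx] >= threshold]
  if (!length(idx))
    return(blink_series(numeric(0), numeric(0), duration,
                        segment = segment, min_interval = min_interval))
  times <- (idx - 1L) / fs
  amps <- x[idx]
  keep <- refractory_prune(times, amps, min_interval)
  keep <- keep[order(times[keep])]
  blink_series(times[keep], amps[keep], duration,
               peak_index = idx[keep] - 1L, segment = segment,
               min_interval = min_interval)
}

#' Inter-blink intervals of a series
#'
#' Successive differences of the event peak times; a series with fewer than
#' two events yields an empty vector.
#'
#' @param series a [blink_series()].
#' @return Numeric vector of IBIs in seconds (length `n - 1`).
#' @export
compute_ibis <- function(series) {
  stopifnot(inherits(series, "blink_series"))
  t <- series$events$peak_time
  if (length(t) < 2L) return(numeric(0))
  diff(t)
}
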