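#' Blink rate of a segment
#'
#' Blinks per minute: event count divided by segment duration in minutes.
#'
#' @param series a [blink_series()].
#' @return Blinks per minute.
#' @export
blink_rate <- function(series) {
  stopifnot(inherits(series, "blink_series"))
  if (series$duration <= 0) stop("segment duration must be > 0", call. = FALSE)
  nrow(series$events) / (series$duration / 60)
}

#' Blink amplitude of a segment
#'
#' Mean peak voltage (microvolts) over the segment's detected blinks;
#' `NA` when the segment has no blinks.
#'
#' @param series a [blink_series()].
#' @return Mean peak amplitude in microvolts, or `NA`.
#' @export
blink_amplitude <- function(series) {
  stopifnot(inherits(series, "blink_series"))
  if (nrow(series$events) < 1L) return(NA_real_)
  mean(series$events$peak_amplitude)
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean. The
#' dimensionless dispersion measure behind BRV (over inter-blink intervals)
#' and BAV (over peak amplitudes).
#'
#' @param values numeric vector of positive values.
#' @return SD/mean; `NA` for fewer than two values.
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) return(NA_real_)
  m <- mean(values)
  if (m <= 0) stop("coefficient of variation needs a positive mean", call. = FALSE)
  stats::sd(values) / m
}

#' Compute the four blink indices for one segment
#'
#' BR (blinks/min), BA (mean peak voltage, uV), BRV (CV of inter-blink
#' intervals) and BAV (CV of peak amplitudes). Indices below their minimum
#' event count are `NA`: BA needs at least 1 blink, BAV at least 2, BRV at
#' least 3 (two IBIs). Degenerate inputs never error.
#'
#' @param series a [blink_series()].
#' @return An object of class `blink_metrics`: a list with `br`, `ba`,
#'   `brv`, `bav`, `n_blinks`, `duration`.
#' @export
compute_metrics <- function(series) {
  stopifnot(inherits(series, "blink_series"))
  n <- nrow(series$events)
  structure(list(
    br = blink_rate(series),
    ba = blink_amplitude(series),
    brv = if (n >= 3L) coefficient_of_variation(compute_ibis(series)) else NA_real_,
    bav = if (n >= 2L) coefficient_of_variation(series$events$peak_amplitude) else NA_real_,
    n_blinks = n,
    duration = series$duration), class = "blink_metrics")
}

#' @export
print.blink_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)
  cat(sprintf("<blink_metrics> n = %d over %.1f s | BR %s /min, BA %s uV, BRV %s, BAV %s\n",
              x$n_blinks, x$duration, fmt(x$br), fmt(x$ba), fmt(x$brv), fmt(x$bav)))
  invisible(x)
}

#' @export
as.data.frame.blink_metrics <- function(x, ...) {
  data.frame(n_blinks = x$n_blinks, duration_s = x$duration,
             br = x$br, ba_uv = x$ba, brv = x$brv, bav = x$bav)
}

#' Average per-clip blink metrics within a participant
#'
#' Unweighted mean of each index over the clips where it is defined
#' (missing values are skipped per index, not listwise); blink counts are
#' summed. This is how a film session of many short clips is collapsed to
#' one row per participant.
#'
#' @param per_clip list of [compute_metrics()] results, one per clip.
#' @return A `blink_metrics` object; an index missing in every clip stays
#'   `NA`.
#' @export
aggregate_films <- function(per_clip) {
  stopifnot(length(per_clip) >= 1L,
            all(vapply(per_clip, inherits, logical(1), "blink_metrics")))
  g <- function(f) vapply(per_clip, `[[`, numeric(1), f)
  m <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  structure(list(br = m(g("br")), ba = m(g("ba")), brv = m(g("brv")),
                 bav = m(g("bav")),
                 n_blinks = sum(g("n_blinks")),
                 duration = sum(g("duration"))), class = "blink_metrics")
}
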