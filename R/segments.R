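#' Construct a bipolar VEOG signal
#'
#' @param samples numeric vector, microvolts.
#' @param fs sampling rate in Hz.
#' @param derivation character of length 2, the (upper, lower) electrode
#'   labels the signal was derived from; optional.
#' @param t0 start offset in seconds.
#' @return An object of class `bipolar_veog`.
#' @export
bipolar_veog <- function(samples, fs, derivation = c(NA, NA), t0 = 0) {
  if (!is.numeric(samples)) stop("`samples` must be numeric", call. = FALSE)
  if (!is_scalar_number(fs) || fs <= 0) stop("`fs` must be positive (Hz)", call. = FALSE)
  structure(list(samples = as.numeric(samples), fs = fs,
                 derivation = as.character(derivation), t0 = t0),
            class = "bipolar_veog")
}

#' @export
print.bipolar_veog <- function(x, ...) {
  der <- if (!anyNA(x$derivation))
    sprintf(" (%s - %s)", x$derivation[1], x$derivation[2]) else ""
  cat(sprintf("<bipolar_veog>%s %d samples @ %g Hz (%.2f s)\n",
              der, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Derive the bipolar VEOG from two channels
#'
#' Subtracts the lower-electrode channel from the upper-electrode channel,
#' elementwise. With an upper-minus-lower derivation, eye blinks appear as
#' positive deflections, which is what the downstream peak detector assumes.
#'
#' @param trace a [signal_trace()].
#' @param upper,lower channel labels of the electrodes above and below the
#'   eye.
#' @return A [bipolar_veog()].
#' @export
derive_bipolar <- function(trace, upper, lower) {
  stopifnot(inherits(trace, "signal_trace"))
  missing <- setdiff(c(upper, lower), trace$channel_labels)
  if (length(missing))
    stop(sprintf("channel(s) not found: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  bipolar_veog(trace$samples[, upper] - trace$samples[, lower],
               fs = trace$fs, derivation = c(upper, lower), t0 = trace$t0)
}

#' Build a segment specification table
#'
#' A segment spec names an analysis window: a label, its onset in seconds
#' from recording start, its duration, and an optional condition category
#' (e.g. the emotional film type). Windows are half-open
#' `[onset, onset + duration)`.
#'
#' @param label character vector of segment labels.
#' @param onset_s onsets in seconds from recording start (>= 0).
#' @param duration_s durations in seconds (> 0).
#' @param condition optional condition category per segment (`NA` for none).
#' @return A data frame of class `segment_spec`.
#' @export
segment_spec <- function(label, onset_s, duration_s, condition = NA) {
  n <- length(label)
  out <- data.frame(label = as.character(label),
                    onset_s = as.numeric(onset_s),
                    duration_s = as.numeric(duration_s),
                    condition = rep_len(as.character(condition), n),
                    stringsAsFactors = FALSE)
  if (any(out$onset_s < 0)) stop("segment onset must be >= 0", call. = FALSE)
  if (any(out$duration_s <= 0)) stop("segment duration must be > 0", call. = FALSE)
  class(out) <- c("segment_spec", class(out))
  out
}

#' Read a segment table from CSV
#'
#' Expects columns `label`, `onset_s`, `duration_s` and optionally
#' `condition`.
#'
#' @param path CSV file path.
#' @return A [segment_spec()] table.
#' @export
read_segment_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  dt <- data.table::fread(path)
  need <- c("label", "onset_s", "duration_s")
  missing <- setdiff(need, names(dt))
  if (length(missing))
    stop(sprintf("segment table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  segment_spec(dt$label, dt$onset_s, dt$duration_s,
               if ("condition" %in% names(dt)) dt$condition else NA)
}

#' Slice a recording into analysis segments
#'
#' Each returned segment holds `round(duration_s * fs)` samples taken from
#' the half-open window `[onset, onset + duration)`. Stretches not covered
#' by any spec (e.g. the 30-s inter-clip baselines) are simply not returned.
#'
#' @param signal a [bipolar_veog()] (or [signal_trace()] with one channel).
#' @param specs a [segment_spec()] table.
#' @return A list with one element per spec row: `list(spec = <1-row spec>,
#'   signal = <bipolar_veog>)`.
#' @export
extract_segments <- function(signal, specs) {
  if (inherits(signal, "signal_trace")) {
    if (ncol(signal$samples) != 1L)
      stop("extract_segments needs a single-channel signal", call. = FALSE)
    signal <- bipolar_veog(signal$samples[, 1L], signal$fs, t0 = signal$t0)
  }
  stopifnot(inherits(signal, "bipolar_veog"))
  n <- length(signal$samples)
  fs <- signal$fs
  total_s <- n / fs
  out <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, , drop = FALSE]
    if (sp$onset_s < 0 || sp$onset_s + sp$duration_s > total_s + 1e-9)
      stop(sprintf("segment '%s' out of bounds: [%g, %g) s on a %g s recording",
                   sp$label, sp$onset_s, sp$onset_s + sp$duration_s, total_s),
           call. = FALSE)
    from <- round(sp$onset_s * fs) + 1L
    len <- round(sp$duration_s * fs)
    seg <- bipolar_veog(signal$samples[from:(from + len - 1L)], fs,
                        derivation = signal$derivation,
                        t0 = signal$t0 + sp$onset_s)
    out[[i]] <- list(spec = sp, signal = seg)
  }
  out
}
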