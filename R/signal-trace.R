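#' Construct a multichannel signal trace
#'
#' A `signal_trace` holds uniformly sampled multichannel data (EOG/EEG) in
#' microvolts, together with its sampling rate and channel labels. All
#' channels must have the same length; time coordinates are seconds from
#' recording start, sample indices are 0-based.
#'
#' @param samples numeric matrix or data frame, one column per channel, one
#'   row per sample, amplitudes in microvolts.
#' @param fs sampling rate in Hz (single positive number).
#' @param channel_labels character vector of channel names; defaults to the
#'   column names of `samples`.
#' @param t0 recording start offset in seconds (default 0).
#' @return An object of class `signal_trace`.
#' @export
signal_trace <- function(samples, fs, channel_labels = NULL, t0 = 0) {
  if (is.data.frame(samples)) samples <- as.matrix(samples)
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("`samples` must be a numeric matrix (samples x channels)", call. = FALSE)
  if (nrow(samples) < 1L) stop("a signal_trace needs at least 1 sample", call. = FALSE)
  if (!is_scalar_number(fs) || fs <= 0) stop("`fs` must be a positive number (Hz)", call. = FALSE)
  channel_labels <- channel_labels %||% colnames(samples) %||%
    paste0("ch", seq_len(ncol(samples)))
  if (length(channel_labels) != ncol(samples))
    stop("`channel_labels` must have one entry per channel", call. = FALSE)
  colnames(samples) <- channel_labels
  structure(list(samples = samples, fs = fs,
                 channel_labels = as.character(channel_labels), t0 = t0),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
              ncol(x$samples), nrow(x$samples), x$fs, nrow(x$samples) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Read a raw trace from EDF or delimited text
#'
#' Reads the requested channels from an EDF/EDF+ file or a delimited text
#' file (header row of channel labels, one row per sample). Amplitudes are
#' interpreted as microvolts; for text input a `scale` factor converts other
#' units on ingest, for EDF the declared physical dimension is honored
#' (`mV` is rescaled to microvolts).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"edf"` or `"csv"` (any delimited
#'   text; the delimiter is sniffed by [data.table::fread()]).
#' @param channels channel labels to return, in order; `NULL` returns all.
#' @param fs sampling rate in Hz; required for text input, ignored for EDF
#'   (the EDF header is authoritative).
#' @param scale multiplicative factor applied to text-input amplitudes to
#'   convert them to microvolts (default 1, i.e. the file is already in uV).
#' @return A [signal_trace()].
#' @export
read_trace <- function(path, format = c("auto", "csv", "edf"), channels = NULL,
                       fs = NULL, scale = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "edf") return(read_edf(path, channels = channels))
  if (is.null(fs)) stop("`fs` is required for delimited-text input", call. = FALSE)
  dt <- data.table::fread(path, header = TRUE)
  lens <- vapply(dt, length, integer(1))
  if (length(unique(lens)) > 1L)
    stop("format error: unequal channel lengths in delimited input", call. = FALSE)
  labels <- names(dt)
  if (!is.null(channels)) {
    missing <- setdiff(channels, labels)
    if (length(missing))
      stop(sprintf("channel(s) not found: %s", paste(missing, collapse = ", ")),
           call. = FALSE)
    dt <- dt[, channels, with = FALSE]
    labels <- channels
  }
  m <- as.matrix(dt) * scale
  signal_trace(m, fs = fs, channel_labels = labels)
}

#' Write a signal trace to delimited text
#'
#' One column per channel with a header row of labels; values in microvolts.
#' Together with [read_trace()] this round-trips samples to numeric-text
#' precision.
#'
#' @param trace a [signal_trace()].
#' @param path output file path.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "signal_trace"))
  data.table::fwrite(data.table::as.data.table(trace$samples), path)
  invisible(path)
}
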