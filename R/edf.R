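# Minimal EDF/EDF+ support. Only the parts of the format the pipeline needs:
# the fixed 256-byte header, per-signal headers, contiguous 16-bit
# little-endian data records, and physical/digital scaling. Annotations
# channels ("EDF Annotations") are skipped on read.

edf_field <- function(raw, from, len) {
  trimws(rawToChar(raw[from:(from + len - 1L)]))
}

#' Read an EDF/EDF+ file
#'
#' Returns the requested channels as a [signal_trace()] in microvolts. The
#' EDF physical dimension is honored: channels declared in `mV` are rescaled
#' by 1000, `uV` (or an empty dimension) are taken as-is. All requested
#' channels must share one sampling rate.
#'
#' @param path EDF file path.
#' @param channels labels to return in order; `NULL` for all data channels.
#' @return A [signal_trace()].
#' @export
read_edf <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 256L)
  n_records <- as.integer(edf_field(hdr, 237L, 8L))
  rec_dur <- as.numeric(edf_field(hdr, 245L, 8L))
  ns <- as.integer(edf_field(hdr, 253L, 4L))
  sig <- readBin(con, "raw", 256L * ns)
  fld <- function(off, len, i) edf_field(sig, (off - 1L) * ns + (i - 1L) * len + 1L, len)
  labels <- vapply(seq_len(ns), function(i) fld(1L, 16L, i), character(1))
  phys_dim <- vapply(seq_len(ns), function(i) fld(97L, 8L, i), character(1))
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) fld(105L, 8L, i), character(1)))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) fld(113L, 8L, i), character(1)))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) fld(121L, 8L, i), character(1)))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) fld(129L, 8L, i), character(1)))
  spr <- as.integer(vapply(seq_len(ns), function(i) fld(217L, 8L, i), character(1)))

  keep <- which(labels != "EDF Annotations")
  if (!is.null(channels)) {
    idx <- match(channels, labels)
    if (anyNA(idx))
      stop(sprintf("channel(s) not found: %s",
                   paste(channels[is.na(idx)], collapse = ", ")), call. = FALSE)
    keep <- idx
  }
  data <- vector("list", ns)
  for (i in keep) data[[i]] <- numeric(n_records * spr[i])
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      vals <- readBin(con, "integer", n = spr[i], size = 2L,
                      signed = TRUE, endian = "little")
      if (i %in% keep)
        data[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <- vals
    }
  }
  fs <- spr[keep] / rec_dur
  if (length(unique(fs)) > 1L)
    stop("requested channels have differing sampling rates", call. = FALSE)
  out <- matrix(0, nrow = n_records * spr[keep[1L]], ncol = length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    x <- (data[[i]] - dig_min[i]) * gain + phys_min[i]
    unit <- tolower(phys_dim[i])
    if (unit == "mv") x <- x * 1000
    else if (unit == "v") x <- x * 1e6
    out[, j] <- x
  }
  signal_trace(out, fs = fs[1L], channel_labels = labels[keep])
}

# Write a signal_trace as a plain EDF file (one data record per second by
# default). Quantization to 16 bits uses the observed per-channel range
# padded by 1%. Used by the simulator and by tests to build EDF fixtures in
# code; not a general-purpose EDF writer.
write_edf <- function(trace, path, physical_dim = "uV", record_s = 1) {
  stopifnot(inherits(trace, "signal_trace"))
  x <- trace$samples
  fs <- trace$fs
  spr <- as.integer(round(fs * record_s))
  if (abs(spr - fs * record_s) > 1e-9)
    stop("fs * record_s must be an integer number of samples", call. = FALSE)
  n_rec <- ceiling(nrow(x) / spr)
  if (n_rec * spr > nrow(x)) { # pad final record with the last value
    pad <- matrix(rep(x[nrow(x), ], each = n_rec * spr - nrow(x)),
                  ncol = ncol(x))
    x <- rbind(x, pad)
  }
  nc <- ncol(x)
  pmin_ <- apply(x, 2, min); pmax_ <- apply(x, 2, max)
  span <- pmax(pmax_ - pmin_, 1e-6)
  pmin_ <- pmin_ - 0.01 * span; pmax_ <- pmax_ + 0.01 * span
  dmin <- -32768; dmax <- 32767

  pad_field <- function(s, n) {
    s <- substr(format(s), 1L, n)
    paste0(s, strrep(" ", n - nchar(s)))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad_field("0", 8L), pad_field("X X X X", 80L), pad_field("Startdate X X X X", 80L),
    pad_field("01.01.20", 8L), pad_field("00.00.00", 8L),
    pad_field(256L * (1L + nc), 8L), pad_field("", 44L),
    pad_field(n_rec, 8L), pad_field(format(record_s), 8L), pad_field(nc, 4L)),
    con, eos = NULL)
  sig_field <- function(f, n) writeChar(paste0(vapply(f, pad_field, "", n = n),
                                               collapse = ""), con, eos = NULL)
  sig_field(trace$channel_labels, 16L)
  sig_field(rep("", nc), 80L)
  sig_field(rep(physical_dim, nc), 8L)
  sig_field(formatC(pmin_, format = "g", digits = 6), 8L)
  sig_field(formatC(pmax_, format = "g", digits = 6), 8L)
  sig_field(rep(format(dmin), nc), 8L)
  sig_field(rep(format(dmax), nc), 8L)
  sig_field(rep("", nc), 80L)
  sig_field(rep(format(spr), nc), 8L)
  sig_field(rep("", nc), 32L)
  # re-read the header's physical min/max so read/write use identical scaling
  pmin_w <- as.numeric(formatC(pmin_, format = "g", digits = 6))
  pmax_w <- as.numeric(formatC(pmax_, format = "g", digits = 6))
  gain <- (dmax - dmin) / (pmax_w - pmin_w)
  for (r in seq_len(n_rec)) {
    for (j in seq_len(nc)) {
      seg <- x[((r - 1L) * spr + 1L):(r * spr), j]
      dig <- as.integer(round((seg - pmin_w[j]) * gain[j] + dmin))
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}
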