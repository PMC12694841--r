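# Flat key/value run configuration. The format is a YAML-style subset —
# one `key: value` pair per line, `#` comments, blank lines allowed —
# chosen because it round-trips losslessly and is echoed verbatim into the
# run manifest for auditability. Nested structures are spelled with dotted
# keys (e.g. `filter.low_cut_hz: 0.5`).

#' Read a flat key/value config file
#'
#' Values are coerced: `true`/`false` to logical, numbers to numeric,
#' everything else kept as character.
#'
#' @param path config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- !grepl(":", lines, fixed = TRUE)
  if (any(bad))
    stop(sprintf("config line without 'key: value': %s", lines[bad][1]),
         call. = FALSE)
  keys <- trimws(sub(":.*$", "", lines))
  vals <- trimws(sub("^[^:]*:", "", lines))
  coerce <- function(v) {
    if (tolower(v) %in% c("true", "yes")) return(TRUE)
    if (tolower(v) %in% c("false", "no")) return(FALSE)
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(num)
    v
  }
  stats::setNames(lapply(vals, coerce), keys)
}

#' Write a flat key/value config file
#'
#' @param config named list (scalar entries).
#' @param path output path.
#' @export
write_config <- function(config, path) {
  fmt <- function(v) {
    if (is.logical(v)) return(if (v) "true" else "false")
    format(v, scientific = FALSE)
  }
  writeLines(sprintf("%s: %s", names(config),
                     vapply(config, fmt, character(1))), path)
  invisible(path)
}
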