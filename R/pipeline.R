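# End-to-end orchestration: read -> derive -> segment -> filter -> detect ->
# metrics -> analyze, or simulate -> analyze, with a manifest for
# reproducibility audits.

#' Detect blinks in one recording, per segment
#'
#' Runs the standard acquisition chain on a single recording: read, derive
#' the bipolar VEOG, slice into segments, band-pass filter each segment,
#' and detect blinks. Filtering is strictly per segment.
#'
#' @param path recording file (EDF or delimited text).
#' @param segments a [segment_spec()] table or path to one.
#' @param upper,lower electrode labels for the bipolar derivation; when
#'   `lower` is absent from the file but equals `""`, the single `upper`
#'   channel is taken as an already-derived VEOG.
#' @param format,fs,scale passed to [read_trace()].
#' @param filter a [filter_spec()].
#' @param threshold,min_interval passed to [detect_blinks()].
#' @return List with `events` (data frame: segment, condition, peak_time_s,
#'   peak_amplitude_uv) and `metrics` (one row per segment).
#' @export
detect_file <- function(path, segments, upper, lower = "",
                        format = "auto", fs = NULL, scale = 1,
                        filter = filter_spec(),
                        threshold = 100, min_interval = 0.25) {
  if (is.character(segments)) segments <- read_segment_table(segments)
  chans <- if (nzchar(lower)) c(upper, lower) else upper
  trace <- read_trace(path, format = format, channels = chans,
                      fs = fs, scale = scale)
  veog <- if (nzchar(lower)) derive_bipolar(trace, upper, lower)
          else bipolar_veog(trace$samples[, 1L], trace$fs)
  segs <- extract_segments(veog, segments)
  ev_list <- vector("list", length(segs))
  me_list <- vector("list", length(segs))
  for (i in seq_along(segs)) {
    sg <- segs[[i]]
    filtered <- bandpass_filter(sg$signal, filter)
    series <- detect_blinks(filtered, threshold = threshold,
                            min_interval = min_interval, segment = sg$spec)
    m <- compute_metrics(series)
    ev <- series$events
    ev_list[[i]] <- if (nrow(ev)) data.frame(
      segment = sg$spec$label, condition = sg$spec$condition,
      peak_time_s = ev$peak_time, peak_amplitude_uv = ev$peak_amplitude)
      else NULL
    me_list[[i]] <- cbind(data.frame(segment = sg$spec$label,
                                     condition = sg$spec$condition),
                          as.data.frame(m))
  }
  list(events = do.call(rbind, ev_list), metrics = do.call(rbind, me_list))
}

#' Statistical analysis of a cohort metrics table
#'
#' Given per-(subject, segment) blink metrics and a subject table with STAI
#' scores, reproduces the standard biomarker analyses: Pearson correlation
#' matrices (rest and film-averaged), random-intercept mixed models of each
#' blink index on each anxiety score over the film clips, film-type
#' interaction models, the trait-state-amplitude mediation model, and a
#' Welch t comparison of STAI-S between screening groups when a `group`
#' column is present.
#'
#' @param metrics data frame with columns `subject`, `segment`,
#'   `condition`, `br`, `ba_uv`, `brv`, `bav` (e.g. from
#'   [simulate_cohort_metrics()] or stacked [detect_file()] outputs).
#' @param subjects data frame with columns `subject`, `stai_s`, `stai_t`
#'   and optionally `group`.
#' @param boot bootstrap replicates for the mediation CI.
#' @param seed integer seed for the bootstrap.
#' @return List of class `blink_analysis`: `film_cor`, `rest_cor`
#'   ([pearson_matrix()] objects or NULL), `mixed` (named list of
#'   [fit_random_intercept()] fits), `type_models`, `mediation_ba`,
#'   `welch_group`.
#' @export
analyze_cohort <- function(metrics, subjects, boot = 5000, seed = NULL) {
  need <- setdiff(c("subject", "stai_s", "stai_t"), names(subjects))
  if (length(need))
    stop(sprintf("subject table lacks column(s): %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  keep <- intersect(c("subject", "group", "stai_s", "stai_t"), names(subjects))
  metrics <- merge(metrics[, setdiff(names(metrics),
                                     c("group", "stai_s", "stai_t"))],
                   subjects[, keep], by = "subject")
  idx <- c("br", "ba_uv", "brv", "bav")
  film <- metrics[grepl("^film", metrics$segment), , drop = FALSE]
  rest <- metrics[metrics$segment == "rest", , drop = FALSE]

  film_sum <- if (nrow(film)) subject_film_summary(metrics) else NULL
  film_cor <- if (!is.null(film_sum))
    pearson_matrix(film_sum, c(idx, "stai_s", "stai_t")) else NULL
  rest_cor <- if (nrow(rest))
    pearson_matrix(merge(rest, subjects[, keep], by = "subject",
                         suffixes = c("", ".y")),
                   c(idx, "stai_s", "stai_t")) else NULL

  mixed <- list()
  type_models <- list()
  if (nrow(film) && length(unique(film$subject)) >= 3L) {
    for (bm in idx) for (sc in c("stai_s", "stai_t")) {
      ok <- is.finite(film[[bm]])
      mixed[[paste(bm, sc, sep = "~")]] <-
        tryCatch(fit_random_intercept(film[ok, ], bm, sc),
                 error = function(e) NULL)
    }
    if (length(unique(film$condition)) > 1L) for (bm in idx) {
      ok <- is.finite(film[[bm]])
      type_models[[bm]] <-
        tryCatch(fit_type_interaction(film[ok, ], bm, "stai_s"),
                 error = function(e) NULL)
    }
  }
  mediation_ba <- if (!is.null(film_sum) && nrow(film_sum) >= 10L)
    mediation(film_sum$stai_t, film_sum$stai_s, film_sum$ba_uv,
              boot = boot, seed = seed) else NULL
  welch_group <- if ("group" %in% names(subjects) &&
                     length(unique(subjects$group)) == 2L) {
    gs <- split(subjects$stai_s, subjects$group)
    if (all(lengths(gs) >= 2L)) welch_t(gs[[1L]], gs[[2L]]) else NULL
  } else NULL
  structure(list(film_cor = film_cor, rest_cor = rest_cor, mixed = mixed,
                 type_models = type_models, mediation_ba = mediation_ba,
                 welch_group = welch_group, film_summary = film_sum),
            class = "blink_analysis")
}

# Serialize an analysis into plain files under out_dir.
write_analysis <- function(an, out_dir) {
  outs <- character(0)
  wr_cor <- function(cm, name) {
    if (is.null(cm)) return(invisible(NULL))
    f <- file.path(out_dir, paste0(name, ".csv"))
    data.table::fwrite(data.table::as.data.table(round(cm$r, 6),
                                                 keep.rownames = "variable"), f)
    outs <<- c(outs, f)
  }
  wr_cor(an$film_cor, "correlations_film")
  wr_cor(an$rest_cor, "correlations_rest")
  rep <- list(
    mixed = lapply(an$mixed, function(m) if (is.null(m)) NULL else list(
      beta = as.list(m$beta), u0_var = m$u0_var, resid_var = m$resid_var,
      r2_marginal = m$r2_marginal, f_tests = m$f_tests)),
    type_models = lapply(an$type_models, function(m) if (is.null(m)) NULL else
      list(f_tests = m$f_tests, r2_marginal = m$r2_marginal)),
    mediation_ba = if (!is.null(an$mediation_ba))
      unclass(an$mediation_ba) else NULL,
    welch_group = an$welch_group)
  f <- file.path(out_dir, "analysis.json")
  jsonlite::write_json(rep, f, auto_unbox = TRUE, digits = 10, null = "null")
  outs <- c(outs, f)
  outs
}

#' Run the full pipeline from a config
#'
#' Orchestrates an end-to-end run described by a flat key/value config (see
#' [read_config()]). Two modes:
#'
#' * `mode: detect` — `recordings` points to a CSV with columns `subject`,
#'   `path` (one recording per subject); `segments` to a segment table;
#'   optional `subjects` table with STAI scores enables the analysis stage.
#'   Keys `upper`, `lower`, `fs`, `format`, `scale`, `threshold_uv`,
#'   `min_interval_ms`, `filter.low_cut_hz`, `filter.high_cut_hz`,
#'   `filter.order`, `filter.zero_phase` configure the chain.
#' * `mode: simulate` — generates a cohort ([synth_cohort()]) with
#'   `n_subjects` and `seed`, simulates its metrics, and analyzes them.
#'
#' Outputs under `out_dir`: `events.csv` (detect mode), `metrics.csv`,
#' `subjects.csv` (simulate mode), analysis CSV/JSON reports, and
#' `manifest.json` echoing the config with MD5 hashes of every input and
#' output. Identical config + seed reproduce metric outputs byte for byte.
#'
#' @param config named list or path to a config file.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  raw_cfg <- NULL
  if (is.character(config)) {
    raw_cfg <- readLines(config, warn = FALSE)
    config <- read_config(config)
  }
  cfg <- config
  mode <- cfg$mode %||% "detect"
  out_dir <- cfg$out_dir %||% stop("config needs `out_dir`", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed %||% 1
  inputs <- character(0)
  outs <- character(0)

  if (mode == "simulate") {
    n <- as.integer(cfg$n_subjects %||% 50)
    cp <- cohort_params(n_subjects = n)
    cohort <- synth_cohort(cp, seed = seed)
    metrics <- simulate_cohort_metrics(cohort, seed = child_seed(seed, 1))
    subjects <- attr(cohort, "subjects")[, c("subject", "group",
                                             "stai_s", "stai_t")]
    f_sub <- file.path(out_dir, "subjects.csv")
    data.table::fwrite(subjects, f_sub)
    outs <- c(outs, f_sub)
  } else {
    for (key in c("recordings", "segments"))
      if (is.null(cfg[[key]]))
        stop(sprintf("validation error: config needs `%s`", key), call. = FALSE)
    for (f in c(cfg$recordings, cfg$segments, cfg$subjects))
      if (!file.exists(f))
        stop(sprintf("validation error: missing input file %s", f), call. = FALSE)
    recs <- data.table::fread(cfg$recordings)
    if (!all(c("subject", "path") %in% names(recs)))
      stop("recordings table needs columns subject, path", call. = FALSE)
    for (f in recs$path) if (!file.exists(f))
      stop(sprintf("validation error: missing recording %s", f), call. = FALSE)
    inputs <- c(inputs, cfg$recordings, cfg$segments, cfg$subjects, recs$path)
    segs <- read_segment_table(cfg$segments)
    fl <- filter_spec(cfg$`filter.low_cut_hz` %||% 0.5,
                      cfg$`filter.high_cut_hz` %||% 20,
                      cfg$`filter.order` %||% 4,
                      cfg$`filter.zero_phase` %||% TRUE)
    ev_all <- list(); me_all <- list()
    for (i in seq_len(nrow(recs))) {
      res <- tryCatch(
        detect_file(recs$path[i], segs,
                    upper = cfg$upper, lower = cfg$lower %||% "",
                    format = cfg$format %||% "auto", fs = cfg$fs,
                    scale = cfg$scale %||% 1, filter = fl,
                    threshold = cfg$threshold_uv %||% 100,
                    min_interval = (cfg$min_interval_ms %||% 250) / 1000),
        error = function(e) stop(sprintf(
          "detect stage failed for subject %s (%s): %s",
          recs$subject[i], recs$path[i], conditionMessage(e)), call. = FALSE))
      if (!is.null(res$events))
        ev_all[[i]] <- cbind(subject = recs$subject[i], res$events)
      me_all[[i]] <- cbind(subject = recs$subject[i], res$metrics)
    }
    events <- do.call(rbind, ev_all)
    metrics <- do.call(rbind, me_all)
    f_ev <- file.path(out_dir, "events.csv")
    data.table::fwrite(events, f_ev)
    outs <- c(outs, f_ev)
    subjects <- if (!is.null(cfg$subjects)) as.data.frame(
      data.table::fread(cfg$subjects)) else NULL
  }

  f_me <- file.path(out_dir, "metrics.csv")
  data.table::fwrite(metrics, f_me)
  f_mj <- file.path(out_dir, "metrics.json")  # JSON mirror for programmatic use
  jsonlite::write_json(metrics, f_mj, dataframe = "rows", digits = 10,
                       na = "null")
  outs <- c(outs, f_me, f_mj)

  if (mode == "simulate" || !is.null(cfg$subjects)) {
    an <- analyze_cohort(metrics, subjects,
                         boot = as.integer(cfg$boot %||% 1000),
                         seed = child_seed(seed, 2))
    outs <- c(outs, write_analysis(an, out_dir))
  }

  manifest <- list(
    tool = "blinkr",
    version = as.character(utils::packageVersion("blinkr")),
    config = if (!is.null(raw_cfg)) raw_cfg else
      sprintf("%s: %s", names(cfg), vapply(cfg, format, character(1))),
    seed = seed,
    inputs = lapply(stats::setNames(nm = inputs), function(f)
      unname(tools::md5sum(f))),
    outputs = lapply(stats::setNames(nm = outs), function(f)
      unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
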