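#' Cohort-generator parameters
#'
#' Describes a synthetic cohort in which subject-level blink parameters and
#' anxiety questionnaire scores share a configurable correlation structure.
#' Subjects get STAI-S/STAI-T scores and latent blink parameters (mean
#' blink amplitude BA, blink rate BR, blink-timing CV BRV) drawn from a
#' Gaussian copula: normal margins for the STAI scores, lognormal margins
#' for BA and BR, and a logit-scaled margin for BRV. Latent correlations
#' are moment-adjusted so the configured `effects` are hit on the
#' *observed* (Pearson) scale for the lognormal margins.
#'
#' Under `mediation = TRUE` (default) trait anxiety is linked to the blink
#' parameters only through state anxiety: the latent trait-blink
#' correlation is the product `trait_state_corr * corr(S, blink)`, which
#' makes the partial correlation of STAI-T with any blink parameter given
#' STAI-S zero by construction.
#'
#' Defaults are calibrated to the film-session effect sizes and descriptives
#' of the anxiety cohort this package models: corr(STAI-S, BA) = 0.557,
#' corr(STAI-S, BR) = 0.418, corr(STAI-S, BRV) = -0.349, trait-state
#' correlation 0.686, BR mean 16.9 and between-subject SD 9.28 blinks/min.
#' STAI margins use college-female norms (S: 38.8 +/- 11.9, T: 40.4 +/-
#' 10.2) since the source cohort reports none.
#'
#' @param n_subjects number of subjects.
#' @param stai_s_mean,stai_s_sd,stai_t_mean,stai_t_sd STAI score margins.
#' @param trait_state_corr correlation between STAI-T and STAI-S.
#' @param effects named vector of target Pearson correlations between
#'   STAI-S and the subject-level blink parameters (`ba`, `br`, `brv`).
#' @param blink_corr named vector of target Pearson correlations among the
#'   blink parameters (`ba_br`, `ba_brv`, `br_brv`).
#' @param mediation if `TRUE`, STAI-T acts on blink parameters only via
#'   STAI-S; otherwise supply `trait_effects` (same names as `effects`).
#' @param trait_effects direct STAI-T-to-blink correlations, only used when
#'   `mediation = FALSE`.
#' @param ba_mean_uv,ba_log_sd lognormal margin of subject mean blink
#'   amplitude (mean in uV; log-scale SD).
#' @param br_mean,br_sd blink-rate margin (blinks/min; between-subject SD).
#' @param brv_mean,brv_sd BRV margin (logit-scaled within `(0, brv_max)`).
#' @param brv_max upper bound of the BRV margin.
#' @param amp_log_sigma within-subject log-scale SD of per-blink peak
#'   amplitudes (sets the long-run BAV to `sqrt(exp(sigma^2) - 1)`).
#' @param noise_sigma trace noise SD in uV (used when rasterizing traces).
#' @param n_films,film_s,rest_s film-session layout: number of 2-min clips
#'   and the resting-segment length, seconds.
#' @param conditions film-type labels recycled over clips (6 levels: 3
#'   negative, 2 positive, 1 neutral by default, 3 clips each).
#' @param type_effects optional named multiplicative film-type offsets on
#'   the blink rate (the per-condition rate hook); `NULL` = none.
#' @param clip_log_rate_sd within-subject across-clip lognormal jitter of
#'   the rate (log-scale SD; mean-one).
#' @param min_ibi lower clamp for generated IBIs, seconds.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 50,
                          stai_s_mean = 38.8, stai_s_sd = 11.9,
                          stai_t_mean = 40.4, stai_t_sd = 10.2,
                          trait_state_corr = 0.686,
                          effects = c(ba = 0.557, br = 0.418, brv = -0.349),
                          blink_corr = c(ba_br = 0.574, ba_brv = -0.547,
                                         br_brv = -0.694),
                          mediation = TRUE, trait_effects = NULL,
                          ba_mean_uv = 250, ba_log_sd = 0.3,
                          br_mean = 16.9, br_sd = 9.28,
                          brv_mean = 0.55, brv_sd = 0.15, brv_max = 1.5,
                          amp_log_sigma = 0.35, noise_sigma = 10,
                          n_films = 18, film_s = 120, rest_s = 300,
                          conditions = c("fear", "sad", "disgust",
                                         "amusement", "tender", "neutral"),
                          type_effects = NULL, clip_log_rate_sd = 0.1,
                          min_ibi = 0.3) {
  stopifnot(n_subjects >= 1)
  p <- mget(names(formals()))
  if (any(abs(c(trait_state_corr, effects, blink_corr)) >= 1))
    stop("all target correlations must lie in (-1, 1)", call. = FALSE)
  if (!all(c("ba", "br", "brv") %in% names(effects)))
    stop("`effects` needs names ba, br, brv", call. = FALSE)
  structure(p, class = "cohort_params")
}

# Pearson-to-latent moment adjustments for the Gaussian copula.
adj_normal_lognormal <- function(r, sigma) r * sqrt(exp(sigma^2) - 1) / sigma
adj_lognormal_pair <- function(r, s1, s2)
  log(1 + r * sqrt((exp(s1^2) - 1) * (exp(s2^2) - 1))) / (s1 * s2)

# Latent 5x5 correlation matrix over (STAI-T, STAI-S, zBA, zBR, zBRV).
cohort_latent_corr <- function(p) {
  s_ba <- p$ba_log_sd
  s_br <- sqrt(log(1 + (p$br_sd / p$br_mean)^2))
  e <- p$effects
  sb <- c(ba = adj_normal_lognormal(e[["ba"]], s_ba),
          br = adj_normal_lognormal(e[["br"]], s_br),
          brv = e[["brv"]])
  tb <- if (p$mediation) p$trait_state_corr * sb else {
    te <- p$trait_effects
    if (is.null(te)) stop("`trait_effects` required when mediation = FALSE", call. = FALSE)
    c(ba = adj_normal_lognormal(te[["ba"]], s_ba),
      br = adj_normal_lognormal(te[["br"]], s_br),
      brv = te[["brv"]])
  }
  bc <- p$blink_corr
  R <- diag(5)
  dimnames(R) <- list(c("t", "s", "ba", "br", "brv"),
                      c("t", "s", "ba", "br", "brv"))
  R["t", "s"] <- p$trait_state_corr
  R["t", c("ba", "br", "brv")] <- tb
  R["s", c("ba", "br", "brv")] <- sb
  R["ba", "br"] <- adj_lognormal_pair(bc[["ba_br"]], s_ba, s_br)
  R["ba", "brv"] <- adj_normal_lognormal(bc[["ba_brv"]], s_ba)
  R["br", "brv"] <- adj_normal_lognormal(bc[["br_brv"]], s_br)
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("infeasible correlation structure: latent matrix is not positive definite",
         call. = FALSE)
  R
}

#' Generate a synthetic cohort table
#'
#' Draws subject-level anxiety scores and blink parameters from the copula
#' described by [cohort_params()], then expands them into a long table of
#' subjects x segments (one resting segment plus `n_films` film clips)
#' carrying the per-segment blink-process parameters. Film-type offsets and
#' across-clip rate jitter are applied per segment. Feed the result to
#' [simulate_cohort_metrics()] for event-level metrics, or rasterize
#' individual segments with [synth_trace()].
#'
#' @param params a [cohort_params()].
#' @param seed integer seed (mandatory; the generator is fully
#'   deterministic given `params` and `seed`).
#' @return A data frame of class `cohort_table`; one row per subject x
#'   segment with columns `subject`, `group`, `stai_s`, `stai_t`,
#'   `segment`, `condition`, `duration_s`, and the per-segment process
#'   parameters (`rate`, `ibi_shape`, `amp_log_mu`, `amp_log_sigma`,
#'   `min_ibi`). Subject-level true parameters are attached as attribute
#'   `"subjects"`.
#' @export
synth_cohort <- function(params, seed) {
  stopifnot(inherits(params, "cohort_params"))
  if (missing(seed) || is.null(seed))
    stop("`seed` is mandatory for synth_cohort", call. = FALSE)
  p <- params
  R <- cohort_latent_corr(p)
  with_seed(seed, {
    n <- p$n_subjects
    Z <- matrix(stats::rnorm(n * 5), n, 5) %*% chol(R)
    stai_t <- p$stai_t_mean + p$stai_t_sd * Z[, 1]
    stai_s <- p$stai_s_mean + p$stai_s_sd * Z[, 2]
    s_ba <- p$ba_log_sd
    s_br <- sqrt(log(1 + (p$br_sd / p$br_mean)^2))
    ba <- exp(log(p$ba_mean_uv) - s_ba^2 / 2 + s_ba * Z[, 3])
    br <- exp(log(p$br_mean) - s_br^2 / 2 + s_br * Z[, 4])
    pr <- p$brv_mean / p$brv_max
    l_mu <- stats::qlogis(pr)
    l_sd <- p$brv_sd / (p$brv_max * pr * (1 - pr))
    brv <- p$brv_max * stats::plogis(l_mu + l_sd * Z[, 5])
    # two screening groups split on an anxiety-correlated selection variable
    splitter <- stai_s + stats::rnorm(n, 0, p$stai_s_sd)
    group <- ifelse(splitter > stats::median(splitter), "high", "low")

    subjects <- data.frame(subject = sprintf("s%03d", seq_len(n)),
                           group = group, stai_s = stai_s, stai_t = stai_t,
                           ba_uv = ba, br = br, brv = brv,
                           ibi_shape = 1 / brv^2,
                           amp_log_mu = log(ba) - p$amp_log_sigma^2 / 2)

    conds <- rep(p$conditions, length.out = p$n_films)
    seg_lab <- c("rest", sprintf("film%02d", seq_len(p$n_films)))
    seg_cond <- c(NA_character_, conds)
    seg_dur <- c(p$rest_s, rep(p$film_s, p$n_films))
    nseg <- length(seg_lab)

    tab <- subjects[rep(seq_len(n), each = nseg),
                    c("subject", "group", "stai_s", "stai_t")]
    tab$segment <- rep(seg_lab, n)
    tab$condition <- rep(seg_cond, n)
    tab$duration_s <- rep(seg_dur, n)
    base_rate <- rep(br, each = nseg)
    mult <- rep(1, nseg)
    if (!is.null(p$type_effects)) {
      m <- p$type_effects[seg_cond]
      mult <- ifelse(is.na(m), 1, m)
    }
    jitter <- exp(stats::rnorm(n * nseg, 0, p$clip_log_rate_sd) -
                    p$clip_log_rate_sd^2 / 2)
    jitter[rep(c(TRUE, rep(FALSE, nseg - 1L)), n)] <- 1  # rest: no clip jitter
    tab$rate <- base_rate * rep(mult, n) * jitter
    tab$ibi_shape <- rep(subjects$ibi_shape, each = nseg)
    tab$amp_log_mu <- rep(subjects$amp_log_mu, each = nseg)
    tab$amp_log_sigma <- p$amp_log_sigma
    tab$min_ibi <- p$min_ibi
    rownames(tab) <- NULL
    attr(tab, "subjects") <- subjects
    attr(tab, "params") <- p
    class(tab) <- c("cohort_table", class(tab))
    tab
  })
}

# fast sample CV (n - 1 denominator), NA below the definedness threshold
cv_or_na <- function(x, min_n) {
  if (length(x) < min_n) return(NA_real_)
  stats::sd(x) / mean(x)
}

#' Simulate per-segment blink metrics for a cohort
#'
#' Samples event times (gamma renewal) and per-blink amplitudes (lognormal)
#' for every row of a [synth_cohort()] table and computes the four indices
#' directly from the event lists — the event-level shortcut that, by the
#' pipeline-closure property, equals detection on noiseless rasterized
#' traces. Definedness rules match [compute_metrics()].
#'
#' @param cohort a `cohort_table` from [synth_cohort()].
#' @param seed integer seed (mandatory).
#' @return The cohort table with columns `n_blinks`, `br`, `ba_uv`, `brv`,
#'   `bav` appended (process-parameter columns dropped).
#' @export
simulate_cohort_metrics <- function(cohort, seed) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (missing(seed) || is.null(seed))
    stop("`seed` is mandatory for simulate_cohort_metrics", call. = FALSE)
  n <- nrow(cohort)
  res <- matrix(NA_real_, n, 5)
  with_seed(seed, {
    for (i in seq_len(n)) {
      dur <- cohort$duration_s[i]
      mean_ibi <- 60 / cohort$rate[i]
      n_draw <- ceiling(dur / mean_ibi * 1.6) + 12L
      ibis <- pmax(stats::rgamma(n_draw, shape = cohort$ibi_shape[i],
                                 scale = mean_ibi / cohort$ibi_shape[i]),
                   cohort$min_ibi[i])
      tt <- cumsum(ibis)
      while (tt[length(tt)] < dur) {  # rare top-up
        more <- pmax(stats::rgamma(n_draw, shape = cohort$ibi_shape[i],
                                   scale = mean_ibi / cohort$ibi_shape[i]),
                     cohort$min_ibi[i])
        tt <- c(tt, tt[length(tt)] + cumsum(more))
      }
      tt <- tt[tt < dur]
      k <- length(tt)
      amps <- stats::rlnorm(k, cohort$amp_log_mu[i], cohort$amp_log_sigma[i])
      res[i, ] <- c(k, k / (dur / 60),
                    if (k >= 1L) mean(amps) else NA_real_,
                    if (k >= 3L) cv_or_na(diff(tt), 2L) else NA_real_,
                    cv_or_na(amps, 2L))
    }
  })
  out <- cohort[, c("subject", "group", "stai_s", "stai_t", "segment",
                    "condition", "duration_s")]
  out$n_blinks <- as.integer(res[, 1])
  out$br <- res[, 2]
  out$ba_uv <- res[, 3]
  out$brv <- res[, 4]
  out$bav <- res[, 5]
  class(out) <- c("cohort_metrics", "data.frame")
  out
}

#' Collapse film-session metrics to one row per participant
#'
#' Per-index unweighted mean over the film clips where the index is
#' defined (the [aggregate_films()] rule), carrying the STAI scores and
#' group label along. Rest segments are excluded.
#'
#' @param metrics a `cohort_metrics` table from [simulate_cohort_metrics()]
#'   or an equivalently shaped data frame.
#' @return One row per subject with columns `subject`, `group`, `stai_s`,
#'   `stai_t`, `n_blinks`, `br`, `ba_uv`, `brv`, `bav`.
#' @export
subject_film_summary <- function(metrics) {
  film <- metrics[grepl("^film", metrics$segment), , drop = FALSE]
  dt <- data.table::as.data.table(film)
  out <- dt[, list(group = group[1L], stai_s = stai_s[1L], stai_t = stai_t[1L],
                   n_blinks = sum(n_blinks),
                   br = mean(br, na.rm = TRUE),
                   ba_uv = mean(ba_uv, na.rm = TRUE),
                   brv = mean(brv, na.rm = TRUE),
                   bav = mean(bav, na.rm = TRUE)),
            by = "subject"]
  as.data.frame(out)
}
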