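# Independent reference implementations used as oracles. These are written
# from the definitions, deliberately not sharing code with the package.

# Brute-force peak picking: scan every sample, collect strict local maxima
# (plateaus -> lower-middle sample), threshold, then greedy suppression in
# decreasing-amplitude order (ties -> earlier), O(n^2).
oracle_find_peaks <- function(x, threshold, min_dist) {
  n <- length(x)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) {
        cand <- c(cand, (i + j) %/% 2L)
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  cand <- cand[x[cand] >= threshold]
  if (!length(cand)) return(integer(0))
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (c_ in ord) {
    ok <- TRUE
    for (k_ in kept) if (abs(c_ - k_) < min_dist) { ok <- FALSE; break }
    if (ok) kept <- c(kept, c_)
  }
  sort(kept)
}

# |H(e^{j 2 pi f / fs})| evaluated by Horner's rule on the full numerator /
# denominator polynomials of the SOS cascade.
oracle_sos_gain <- function(sos, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  horner <- function(coef, z) {  # coef[1] + coef[2] z + coef[3] z^2
    acc <- 0 + 0i
    for (c_ in rev(coef)) acc <- acc * z + c_
    acc
  }
  h <- 1 + 0i
  for (r in seq_len(nrow(sos)))
    h <- h * horner(sos[r, 1:3], z) / horner(sos[r, 4:6], z)
  Mod(h)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - sum(x) / n) * (y - sum(y) / n))
  sxx <- sum((x - sum(x) / n)^2)
  syy <- sum((y - sum(y) / n)^2)
  r <- sxy / sqrt(sxx * syy)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

oracle_cv <- function(v) {
  m <- sum(v) / length(v)
  s <- sqrt(sum((v - m)^2) / (length(v) - 1))
  s / m
}

oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

oracle_sobel_z <- function(a, se_a, b, se_b)
  (a * b) / sqrt(a^2 * se_b^2 + b^2 * se_a^2)

# Partial correlation of x and y given z, from the pairwise correlations.
oracle_partial_cor <- function(x, y, z) {
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# Place raised-cosine test pulses (width_s total) of given peak amplitudes
# at given times on a flat trace; independent of the package's waveform
# machinery.
make_pulse_signal <- function(fs, duration, times, amps, width_s = 0.2) {
  n <- round(duration * fs)
  x <- numeric(n)
  half <- width_s / 2
  for (k in seq_along(times)) {
    idx <- which(abs((seq_len(n) - 1) / fs - times[k]) <= half)
    tt <- (idx - 1) / fs - times[k]
    x[idx] <- x[idx] + amps[k] * 0.5 * (1 + cos(pi * tt / half))
  }
  x
}

# Match detected events against ground truth within a +/- window; returns
# sensitivity and precision.
match_events <- function(truth_times, det_times, window = 0.05) {
  if (!length(truth_times))
    return(list(sens = NA_real_, prec = if (length(det_times)) 0 else NA_real_))
  hit <- vapply(truth_times, function(t)
    length(det_times) && min(abs(det_times - t)) <= window, logical(1))
  fp <- vapply(det_times, function(t)
    !length(truth_times) || min(abs(truth_times - t)) > window, logical(1))
  list(sens = mean(hit), prec = 1 - mean(fp))
}

# Small balanced random-intercept dataset generator used by the mixed-model
# tests: between-subject predictor x, slope beta1, intercept variance
# u0_var, residual variance resid_var.
sim_lmm_data <- function(n_subj, n_clip, beta1, u0_var = 1, resid_var = 1) {
  x <- rnorm(n_subj)
  u <- rnorm(n_subj, 0, sqrt(u0_var))
  data.frame(
    subject = rep(sprintf("s%03d", seq_len(n_subj)), each = n_clip),
    x = rep(x, each = n_clip),
    y = rep(10 + beta1 * x + u, each = n_clip) +
      rnorm(n_subj * n_clip, 0, sqrt(resid_var)))
}
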