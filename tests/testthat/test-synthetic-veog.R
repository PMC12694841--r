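test_that("renewal sampling is deterministic and hits its IBI statistics", {
  pp1 <- process_params(rate = 17, ibi_shape = 1)
  expect_identical(sample_blink_times(pp1, 600, seed = 7),
                   sample_blink_times(pp1, 600, seed = 7))

  t1 <- sample_blink_times(pp1, 36000, seed = 8)
  ibi1 <- diff(t1)
  expect_equal(sd(ibi1) / mean(ibi1), 1, tolerance = 0.04)  # exp: CV 1 (clamp bias < 0.02)

  pp4 <- process_params(rate = 17, ibi_shape = 4)
  t4 <- sample_blink_times(pp4, 36000, seed = 9)
  ibi4 <- diff(t4)
  expect_equal(sd(ibi4) / mean(ibi4), 0.5, tolerance = 0.03)
  expect_true(all(ibi4 >= 0.3 - 1e-6))
  expect_true(all(diff(t1) >= 0.3 - 1e-6))

  # long-run rate within 1 blink/min of configured
  expect_equal(length(t4) / 600, 17, tolerance = 1 / 17)
})

test_that("noiseless traces reproduce sampled amplitudes at the event times", {
  pp <- process_params(noise_sigma = 0)
  tr <- synth_trace(c(1, 3.2, 6.5), waveform_params(), pp, fs = 500,
                    duration = 10, seed = 21)
  expect_equal(nrow(tr$truth), 3)
  for (k in 1:3) {
    peak_val <- tr$signal$samples[tr$truth$peak_index[k] + 1L]
    expect_equal(peak_val, tr$truth$amplitude[k], tolerance = 0.01 * tr$truth$amplitude[k])
  }
  expect_false(any(tr$truth$overlapped))

  # overlapping events are summed and flagged
  tro <- synth_trace(c(2, 2.1), waveform_params(), pp, fs = 500,
                     duration = 5, seed = 22)
  expect_true(all(tro$truth$overlapped))

  # both waveform shapes peak where they should
  trg <- synth_trace(2, waveform_params(shape = "asymmetric_gamma"), pp,
                     fs = 500, duration = 5, seed = 23)
  expect_equal(trg$truth$time, 2, tolerance = 1e-9)
  expect_equal(which.max(trg$signal$samples), trg$truth$peak_index + 1L)
})

test_that("pipeline closure: detection on noiseless traces equals ground truth", {
  pp <- process_params(rate = 16, ibi_shape = 4, noise_sigma = 0, min_ibi = 0.5,
                       amp_log_mu = log(250), amp_log_sigma = 0.25)
  times <- sample_blink_times(pp, 120, seed = 24)
  tr <- synth_trace(times, waveform_params(), pp, fs = 500, duration = 120,
                    seed = 25)
  det <- detect_blinks(tr$signal, threshold = 100, min_interval = 0.25)
  expect_equal(det$events$peak_time, tr$truth$time, tolerance = 1e-9)
  # unfiltered noiseless trace: peak values equal sampled amplitudes
  m_det <- compute_metrics(det)
  m_truth <- compute_metrics(blink_series(tr$truth$time, tr$truth$amplitude,
                                          duration = 120))
  expect_equal(m_det$br, m_truth$br)
  expect_equal(m_det$ba, m_truth$ba, tolerance = 1e-6)
  expect_equal(m_det$brv, m_truth$brv, tolerance = 1e-9)
  expect_equal(m_det$bav, m_truth$bav, tolerance = 1e-6)
})

test_that("cohort generation is deterministic and hits correlation targets", {
  cp <- cohort_params(n_subjects = 1500)
  co <- synth_cohort(cp, seed = 26)
  co2 <- synth_cohort(cp, seed = 26)
  expect_identical(co$rate, co2$rate)
  expect_error(synth_cohort(cp, seed = NULL), "seed")

  su <- attr(co, "subjects")
  # MC SE of r at n = 1500 is ~0.02; allow 4 SE
  expect_equal(cor(su$stai_s, su$ba_uv), 0.557, tolerance = 0.08)
  expect_equal(cor(su$stai_s, su$br), 0.418, tolerance = 0.08)
  expect_equal(cor(su$stai_s, su$brv), -0.349, tolerance = 0.09)
  expect_equal(cor(su$stai_t, su$stai_s), 0.686, tolerance = 0.06)
  expect_equal(mean(su$br), 16.9, tolerance = 0.06 * 16.9)
  expect_equal(sd(su$br), 9.28, tolerance = 0.15 * 9.28)

  # mediation structure: no trait-blink association beyond state
  expect_lt(abs(oracle_partial_cor(su$stai_t, su$ba_uv, su$stai_s)), 0.06)

  # layout: 1 rest + 18 films per subject, 6 condition levels, 3 clips each
  one <- co[co$subject == "s001", ]
  expect_equal(nrow(one), 19)
  expect_equal(sum(grepl("^film", one$segment)), 18)
  expect_equal(one$duration_s[one$segment == "rest"], 300)
  expect_equal(as.integer(table(one$condition[!is.na(one$condition)])),
               rep(3L, 6))
})

test_that("null cohorts carry no anxiety-blink association", {
  cp0 <- cohort_params(n_subjects = 1500,
                       effects = c(ba = 0, br = 0, brv = 0),
                       blink_corr = c(ba_br = 0, ba_brv = 0, br_brv = 0))
  su0 <- attr(synth_cohort(cp0, seed = 27), "subjects")
  expect_lt(abs(cor(su0$stai_s, su0$ba_uv)), 0.07)
  expect_lt(abs(cor(su0$stai_s, su0$br)), 0.07)
})

test_that("infeasible correlation structures are rejected", {
  cp_bad <- cohort_params(trait_state_corr = 0.95,
                          effects = c(ba = 0.95, br = 0.9, brv = -0.9),
                          blink_corr = c(ba_br = -0.9, ba_brv = 0.9,
                                         br_brv = 0.9))
  expect_error(synth_cohort(cp_bad, seed = 1), "positive definite")
  expect_error(cohort_params(effects = c(ba = 1.2, br = 0, brv = 0)),
               "correlations")
})

test_that("amplitude margins respect their lognormal parameters", {
  cp <- cohort_params(n_subjects = 4000)
  su <- attr(synth_cohort(cp, seed = 28), "subjects")
  expect_equal(mean(su$ba_uv), 250, tolerance = 0.05 * 250)
  expect_equal(sd(log(su$ba_uv)), 0.3, tolerance = 0.03)
})
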