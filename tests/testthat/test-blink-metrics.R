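series_of <- function(times, amps, duration)
  blink_series(times, amps, duration = duration)

test_that("blink rate and amplitude follow their definitions", {
  expect_equal(blink_rate(series_of(seq_len(85) * 3.5, rep(150, 85), 300)), 17)
  expect_equal(blink_rate(series_of(numeric(0), numeric(0), 300)), 0)
  expect_equal(blink_rate(series_of(seq_len(36) * 3, rep(150, 36), 120)), 18)

  expect_equal(blink_amplitude(series_of(c(1, 2), c(150, 250), 10)), 200)
  expect_equal(blink_amplitude(series_of(1, 180, 10)), 180)
  expect_equal(blink_amplitude(series_of(1:4, c(120, 140, 160, 180), 10)), 150)
  expect_true(is.na(blink_amplitude(series_of(numeric(0), numeric(0), 10))))
})

test_that("coefficient of variation uses sample SD over mean", {
  expect_equal(coefficient_of_variation(c(2, 2, 2, 2)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2, tolerance = 1e-10)
  expect_equal(coefficient_of_variation(c(100, 200, 300)), 0.5)
  expect_true(is.na(coefficient_of_variation(5)))
  expect_error(coefficient_of_variation(c(-3, 1)), "positive mean")
  # against the independent direct-formula oracle on fuzzed inputs
  set.seed(401)
  for (i in 1:25) {
    v <- rlnorm(sample(2:40, 1), 5, 0.7)
    expect_equal(coefficient_of_variation(v), oracle_cv(v), tolerance = 1e-12)
  }
})

test_that("compute_metrics applies the definedness thresholds", {
  m2 <- compute_metrics(series_of(c(1, 2), c(150, 160), 60))
  expect_false(is.na(m2$br) || is.na(m2$ba) || is.na(m2$bav))
  expect_true(is.na(m2$brv))  # a single IBI has no dispersion

  m1 <- compute_metrics(series_of(3, 200, 60))
  expect_true(is.na(m1$bav) && is.na(m1$brv))
  expect_equal(m1$ba, 200)

  # perfectly periodic identical blinks: zero variation in both domains
  mp <- compute_metrics(series_of(seq(1, 59, by = 2), rep(180, 30), 60))
  expect_equal(mp$brv, 0)
  expect_equal(mp$bav, 0)

  m0 <- compute_metrics(series_of(numeric(0), numeric(0), 60))
  expect_equal(m0$br, 0)
  expect_true(is.na(m0$ba))
})

test_that("metrics from ground-truth events equal direct computation", {
  set.seed(402)
  pp <- process_params(noise_sigma = 0)
  times <- sample_blink_times(pp, 300, seed = 31)
  amps <- rlnorm(length(times), pp$amp_log_mu, pp$amp_log_sigma)
  m <- compute_metrics(blink_series(times, amps, duration = 300))
  expect_equal(m$br, length(times) / 5)
  expect_equal(m$ba, mean(amps))
  expect_equal(m$brv, sd(diff(times)) / mean(diff(times)))
  expect_equal(m$bav, sd(amps) / mean(amps))
})

test_that("BRV and BAV are scale invariant in their own domains", {
  set.seed(403)
  times <- cumsum(runif(40, 0.5, 5))
  amps <- rlnorm(40, log(200), 0.4)
  base <- compute_metrics(blink_series(times, amps, duration = max(times) + 1))
  for (s in c(0.25, 3, 12)) {
    mt <- compute_metrics(blink_series(times * s, amps,
                                       duration = (max(times) + 1) * s))
    expect_equal(mt$brv, base$brv, tolerance = 1e-12)
    ma <- compute_metrics(blink_series(times, amps * s,
                                       duration = max(times) + 1))
    expect_equal(ma$bav, base$bav, tolerance = 1e-12)
  }
})

test_that("film aggregation averages defined indices and sums counts", {
  a <- compute_metrics(series_of(seq(2, 118, by = 10), rep(150, 12), 120))
  b <- compute_metrics(series_of(seq(2, 118, by = 6.45), rep(250, 18), 120))
  ag <- aggregate_films(list(a, b))
  expect_equal(ag$br, mean(c(a$br, b$br)))
  expect_equal(ag$ba, 200)
  expect_equal(ag$n_blinks, 30)
  expect_equal(aggregate_films(list(a))$brv, a$brv)  # identity on one clip

  # missing-skip rule: brv defined in only some clips
  c2 <- compute_metrics(series_of(c(1, 2), c(150, 150), 120))
  ag2 <- aggregate_films(list(a, b, c2))
  expect_equal(ag2$brv, mean(c(a$brv, b$brv)))
  ag3 <- aggregate_films(list(c2))
  expect_true(is.na(ag3$brv))
})
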