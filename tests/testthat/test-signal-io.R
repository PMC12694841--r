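test_that("csv traces round-trip and respect length/fs arithmetic", {
  set.seed(101)
  m <- cbind(Fp1 = rnorm(1000, 0, 50), Ve1 = rnorm(1000, 0, 50))
  tr <- signal_trace(m, fs = 500)
  expect_equal(nrow(tr$samples) / tr$fs, 2)  # 1000 rows at 500 Hz = 2 s

  f <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  back <- read_trace(f, format = "csv", fs = 500)
  expect_equal(back$samples, tr$samples, tolerance = 1e-12)
  expect_identical(back$channel_labels, c("Fp1", "Ve1"))

  # channel selection preserves request order; missing channel is named
  sel <- read_trace(f, format = "csv", channels = c("Ve1", "Fp1"), fs = 500)
  expect_identical(sel$channel_labels, c("Ve1", "Fp1"))
  expect_error(read_trace(f, format = "csv", channels = "Io2", fs = 500), "Io2")

  # unit scale factor applies on ingest
  mv <- read_trace(f, format = "csv", fs = 500, scale = 1000)
  expect_equal(mv$samples[1, 1], tr$samples[1, 1] * 1000)
})

test_that("EDF files round-trip through the reader, honoring physical units", {
  set.seed(102)
  m <- cbind(Fp1 = rnorm(1500, 0, 120), Ve1 = 60 * sin(2 * pi * 3 * (1:1500) / 500))
  tr <- signal_trace(m, fs = 500)
  f <- withr::local_tempfile(fileext = ".edf")
  blinkr:::write_edf(tr, f)
  back <- read_trace(f)  # format sniffed from extension
  expect_identical(back$channel_labels, c("Fp1", "Ve1"))
  expect_equal(back$fs, 500)
  # 16-bit quantization over a ~ +/-500 uV range: << 0.1 uV error
  expect_lt(max(abs(back$samples - tr$samples)), 0.1)

  # mV declared in the EDF header is rescaled to uV
  f2 <- withr::local_tempfile(fileext = ".edf")
  tr_mv <- signal_trace(m / 1000, fs = 500, channel_labels = c("Fp1", "Ve1"))
  blinkr:::write_edf(tr_mv, f2, physical_dim = "mV")
  back2 <- read_edf(f2, channels = c("Fp1", "Ve1"))
  expect_equal(back2$samples[, "Fp1"], back$samples[, "Fp1"], tolerance = 1e-3)
  expect_error(read_edf(f, channels = "Io2"), "Io2")
})

test_that("derive_bipolar subtracts elementwise and is antisymmetric", {
  tr <- signal_trace(cbind(up = c(10, 20), lo = c(5, 5)), fs = 100)
  expect_equal(derive_bipolar(tr, "up", "lo")$samples, c(5, 15))
  expect_equal(derive_bipolar(tr, "up", "up")$samples, c(0, 0))
  expect_equal(derive_bipolar(tr, "lo", "up")$samples,
               -derive_bipolar(tr, "up", "lo")$samples)
  expect_error(derive_bipolar(tr, "up", "Io2"), "Io2")

  # a pulse injected on the upper channel only survives derivation intact
  set.seed(103)
  n <- 2000
  pulse <- make_pulse_signal(500, 4, times = 2, amps = 180)
  tr2 <- signal_trace(cbind(up = pulse + 30, lo = rep(30, n)), fs = 500)
  bp <- derive_bipolar(tr2, "up", "lo")
  expect_equal(max(bp$samples), 180, tolerance = 1e-9)
})

test_that("segment extraction honors bounds, sizes and sample conservation", {
  set.seed(104)
  fs <- 500
  x <- rnorm(300 * fs)
  veog <- bipolar_veog(x, fs)
  segs <- segment_spec("rest", 0, 300)
  out <- extract_segments(veog, segs)
  expect_length(out, 1)
  expect_length(out[[1]]$signal$samples, 150000)  # 300 s x 500 Hz

  # 18 films of 120 s with 30 s baselines would overrun a 300 s trace
  film <- segment_spec(sprintf("film%02d", 1:18), seq(0, by = 150, length.out = 18),
                       120, condition = rep(c("neg", "pos", "neutral"), 6))
  expect_error(extract_segments(veog, film), "out of bounds")

  # contiguous half-open windows tile the trace exactly
  tiles <- segment_spec(c("a", "b", "c"), c(0, 100, 200), 100)
  parts <- extract_segments(veog, tiles)
  expect_equal(unlist(lapply(parts, function(p) p$signal$samples)),
               x, tolerance = 0)
  expect_error(extract_segments(veog, segment_spec("late", 290, 20)), "late")
})

test_that("segment tables read from csv with conditions", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,onset_s,duration_s,condition",
               "rest,0,300,", "film01,330,120,fear"), f)
  st <- read_segment_table(f)
  expect_equal(nrow(st), 2)
  expect_equal(st$duration_s, c(300, 120))
  expect_true(is.na(st$condition[1]) || st$condition[1] == "")
  expect_identical(st$condition[2], "fear")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("label,start", f2)
  expect_error(read_segment_table(f2), "onset_s")
})
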