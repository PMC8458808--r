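test_that("bandpass rejects DC and stopband tones, passes mid-band tones", {
  fs <- 1000
  tt <- seq(0, 5 - 1/fs, by = 1/fs)
  # constant input: DC lies below the 1 Hz edge
  y <- bandpass_filter(rep(0.7, length(tt)), fs)
  mid <- y[(fs):(4 * fs)]  # past the edge transient
  expect_lt(max(abs(mid)), 1e-3)
  # unit 10 Hz tone passes with gain near 1
  y10 <- bandpass_filter(sin(2 * pi * 10 * tt), fs)
  amp10 <- max(abs(y10[(fs):(4 * fs)]))
  expect_gt(amp10, 0.95)
  expect_lt(amp10, 1.05)
  # 100 Hz (2x the upper edge) is strongly attenuated
  y100 <- bandpass_filter(sin(2 * pi * 100 * tt), fs)
  expect_lt(max(abs(y100[(fs):(4 * fs)])), 0.1)
})

test_that("filter is linear and zero-phase", {
  fs <- 500
  set.seed(11)
  x <- rnorm(4 * fs)
  y <- rnorm(4 * fs)
  lhs <- bandpass_filter(2 * x + 3 * y, fs)
  rhs <- 2 * bandpass_filter(x, fs) + 3 * bandpass_filter(y, fs)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-9)
  # zero-phase: cross-correlation of a mid-band tone with its filtered
  # version peaks at lag 0
  tt <- seq(0, 4 - 1/fs, by = 1/fs)
  tone <- sin(2 * pi * 8 * tt)
  ft <- bandpass_filter(tone, fs)
  cc <- ccf(ft, tone, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("sampling rate below twice the upper edge is a configuration error", {
  expect_error(bandpass_filter(rnorm(1000), sampling_rate = 90, high = 50),
               "twice")
})

test_that("normalize_01 is the session-wide affine map to [0, 1]", {
  expect_equal(normalize_01(c(-2, 0, 2)), c(0, 0.5, 1))
  x <- c(0, 0.25, 1, 0.5)
  expect_equal(normalize_01(x), x)  # already spanning [0, 1]
  expect_error(normalize_01(rep(3, 10)), "degenerate")
})

test_that("epoching tiles the recording and drops the partial tail", {
  rec <- cached_session(1)
  ep <- make_epochs(rec)  # 420-s session at 500 Hz
  expect_equal(nrow(ep$samples), 84)
  expect_equal(ep$meta$start_time_s, seq(0, by = 5, length.out = 84))
  # partition: concatenating epoch rows reproduces the head of the signal
  expect_identical(as.numeric(t(ep$samples)), rec$eeg[1:(84 * 2500)])
  # 12-s recording at 500 Hz: 2 epochs, 2-s remainder dropped
  rec12 <- signal_as_recording(rnorm(12 * 500), 500)
  ep12 <- make_epochs(rec12)
  expect_equal(nrow(ep12$samples), 2)
  # shorter than one epoch: empty result with a warning
  rec3 <- signal_as_recording(rnorm(3 * 500), 500)
  expect_warning(ep3 <- make_epochs(rec3), "shorter")
  expect_equal(nrow(ep3$samples), 0)
})

test_that("temperature rounding is half-up with discard outside 37-42", {
  at <- assign_temperature(c(41.5, 36.4, 36.6, 39.2, 42.5, 37.0))
  expect_equal(at$rounded_temp_c, c(42L, 36L, 37L, 39L, 43L, 37L))
  expect_equal(at$kept, c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
})

test_that("kept epochs always carry integer temperatures in range", {
  ep <- preprocess_session(cached_session(2, key = "default2"))
  kept <- ep$meta[ep$meta$kept, ]
  expect_true(all(kept$rounded_temp_c %in% 37:42))
  expect_true(all(abs(kept$mean_temp_c - kept$rounded_temp_c) <= 0.5))
  # normalized signal spans [0, 1]
  expect_equal(range(ep$samples)[1], 0, tolerance = 1e-3)
  expect_equal(range(ep$samples)[2], 1, tolerance = 1e-3)
})
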