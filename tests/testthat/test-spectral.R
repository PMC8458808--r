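test_that("Welch spectrum localizes a pure tone and nulls silence", {
  fs <- 500
  tt <- seq(0, 5 - 1/fs, by = 1/fs)
  rec <- signal_as_recording(sin(2 * pi * 6 * tt), fs)
  ep <- make_epochs(rec)
  spec <- epoch_power_spectrum(ep)
  expect_equal(diff(spec$freq)[1], 0.5)  # 2-s segments -> 0.5 Hz resolution
  bands <- eeg_bands()
  p <- session_band_powers(spec, bands)
  # >= 90% of the 1-30 Hz power of a 6 Hz tone lies in theta
  expect_gt(p[1, "theta"] / sum(p[1, ]), 0.9)
  # all-zero epoch gives an all-zero spectrum
  zero <- epoch_power_spectrum(make_epochs(signal_as_recording(
    numeric(5 * fs), fs)))
  expect_true(all(zero$psd == 0))
})

test_that("Welch spectrum satisfies Parseval on white noise", {
  fs <- 500
  set.seed(21)
  ratios <- replicate(100, {
    x <- rnorm(5 * fs)
    w <- welch_psd(x, fs)
    # trapezoidal integral over [0, Nyquist] vs signal variance
    sum(diff(w$freq) * (head(w$psd, -1) + w$psd[-1]) / 2) / var(x)
  })
  expect_lt(abs(mean(ratios) - 1), 0.1)
})

test_that("band integration is exact on a flat PSD and errors on empty bands", {
  freq <- seq(0, 250, by = 0.5)
  flat <- rep(1, length(freq))
  expect_equal(band_power(flat, freq, 1, 4), 3)
  expect_equal(band_power(flat, freq, 12, 30), 18)
  expect_error(band_power(flat, freq, 8, 8), "empty band")
  expect_error(band_power(flat, freq, 200, 300), "outside")
})

test_that("half-open bands partition 1-30 Hz exactly", {
  fs <- 500
  set.seed(22)
  w <- welch_psd(rnorm(5 * fs), fs)
  bands <- eeg_bands()
  parts <- vapply(seq_len(nrow(bands)), function(i)
    band_power(w$psd, w$freq, bands$low[i], bands$high[i]), numeric(1))
  total <- band_power(w$psd, w$freq, 1, 30)
  expect_equal(sum(parts), total, tolerance = 1e-12)
})

test_that("white-noise band powers scale with bandwidth", {
  fs <- 500
  set.seed(23)
  ratio <- mean(replicate(100, {
    w <- welch_psd(rnorm(5 * fs), fs)
    band_power(w$psd, w$freq, 12, 30) / band_power(w$psd, w$freq, 1, 4)
  }))
  expect_lt(abs(ratio / 6 - 1), 0.2)  # bandwidth 18 vs 3 Hz
})

test_that("band-power normalization maps session extremes to 0 and 1", {
  P <- cbind(delta = c(2, 4, 3), theta = c(1, 5, 3))
  N <- normalize_band_powers(P)
  expect_equal(N[, "delta"], c(0, 1, 0.5))
  expect_equal(range(N), c(0, 1))
  # all-equal band: zeros plus a warning
  P2 <- cbind(delta = c(2, 2, 2), theta = c(1, 5, 3))
  expect_warning(N2 <- normalize_band_powers(P2), "zero range")
  expect_true(all(N2[, "delta"] == 0))
  # monotone map: ordering of raw powers is preserved
  set.seed(31)
  raw <- sort(rexp(20), decreasing = TRUE)
  N3 <- normalize_band_powers(cbind(delta = raw))
  expect_equal(cor(raw, N3[, 1], method = "spearman"), 1)
})

test_that("normalized band summaries are invariant to signal scale", {
  rec <- cached_session(3, key = "default3")
  ep <- preprocess_session(rec)
  s1 <- spectral_session(ep)$summary
  rec2 <- rec
  rec2$eeg <- rec2$eeg * 37.5
  s2 <- spectral_session(preprocess_session(rec2))$summary
  expect_equal(s1$mean, s2$mean, tolerance = 1e-9)
})

test_that("summaries cover kept epochs per band and temperature", {
  rec <- cached_session(3, key = "default3")
  ep <- preprocess_session(rec)
  sp <- spectral_session(ep)
  expect_true(all(sp$normalized[ep$meta$kept, ] >= 0 &
                  sp$normalized[ep$meta$kept, ] <= 1))
  # both endpoints attained per band
  expect_equal(unname(apply(sp$normalized[ep$meta$kept, ], 2, min)),
               rep(0, 4))
  expect_equal(unname(apply(sp$normalized[ep$meta$kept, ], 2, max)),
               rep(1, 4))
  expect_equal(sum(sp$summary$n[sp$summary$band == "delta"]),
               sum(ep$meta$kept))
})
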