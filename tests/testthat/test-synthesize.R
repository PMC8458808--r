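test_that("identical config and seed give bit-identical recordings", {
  prof <- make_temperature_profile(short_protocol())
  gen <- generator_config(sampling_rate = 500)
  a <- synthesize_eeg(prof, gen, seed = 7)
  b <- synthesize_eeg(prof, gen, seed = 7)
  expect_identical(a$eeg, b$eeg)
  c <- synthesize_eeg(prof, gen, seed = 8)
  expect_false(identical(a$eeg, c$eeg))
})

test_that("all-zero gains yield an all-zero recording", {
  prof <- make_temperature_profile(short_protocol())
  gen <- generator_config(sampling_rate = 500,
                          band_gains = c(delta = 0, theta = 0, alpha = 0,
                                         beta = 0),
                          noise_gain = 0)
  rec <- synthesize_eeg(prof, gen, seed = 1)
  expect_true(all(rec$eeg == 0))
})

test_that("recording length matches protocol duration times sampling rate", {
  prof <- make_temperature_profile(short_protocol())
  rec <- synthesize_eeg(prof, generator_config(sampling_rate = 500), seed = 1)
  expect_equal(length(rec$eeg), round(max(prof$time_s) * 500))
})

test_that("hold-phase RMS attenuation follows the closed-form envelope", {
  # with no band slopes, no transients, no bursts, the RMS ratio between the
  # 42 C hold and the 37 C baseline is E(42)/E(37)
  gen <- quiet_gen(envelope_slope = -0.06)
  prof <- make_temperature_profile(short_protocol())
  rec <- synthesize_eeg(prof, gen, seed = 3)
  tt <- (seq_along(rec$eeg) - 1) / rec$sampling_rate
  phase <- prof$phase[findInterval(tt, prof$time_s)]
  ratio <- sd(rec$eeg[phase == "hold"]) / sd(rec$eeg[phase == "baseline"])
  expected <- envelope_at(gen, 42) / envelope_at(gen, 37)
  expect_lt(abs(ratio / expected - 1), 0.15)
  expect_lt(ratio, 1)
})

test_that("negative envelope slope makes per-temperature RMS decline", {
  gen <- quiet_gen(envelope_slope = -0.05)
  prof <- make_temperature_profile(short_protocol())
  rms_by_temp <- do.call(rbind, lapply(1:19, function(i) {
    rec <- synthesize_eeg(prof, gen, seed = i)
    ep <- make_epochs(rec)
    m <- ep$meta[ep$meta$kept, ]
    rms <- sqrt(rowMeans(ep$samples^2))[ep$meta$kept]
    data.frame(temp = m$rounded_temp_c, rms = rms)
  }))
  agg <- aggregate(rms ~ temp, rms_by_temp, mean)
  ct <- suppressWarnings(cor.test(agg$temp, agg$rms, method = "spearman"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("non-positive envelope over the protocol range is rejected", {
  prof <- make_temperature_profile(short_protocol())
  gen <- generator_config(sampling_rate = 500, envelope_slope = -0.3)
  expect_error(synthesize_eeg(prof, gen, seed = 1), "positive")
})

test_that("synthesis does not disturb the caller's RNG stream", {
  set.seed(42)
  before <- .Random.seed
  invisible(cached_session(1))
  expect_identical(.Random.seed, before)
})
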