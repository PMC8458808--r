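test_that("max peak-to-peak equals the pairwise-difference oracle", {
  expect_equal(max_peak_to_peak(rep(0.3, 100)), 0)
  # analytic extremes of a sinusoid
  tt <- seq(0, 1, by = 1/500)
  expect_equal(max_peak_to_peak(0.5 + 0.3 * sin(2 * pi * 6 * tt)), 0.6,
               tolerance = 1e-3)
  # O(n^2) pairwise-scan oracle on random vectors
  set.seed(5)
  for (i in 1:200) {
    x <- rnorm(10)
    oracle <- max(outer(x, x, `-`))
    expect_identical(max_peak_to_peak(x), oracle)
  }
  expect_error(max_peak_to_peak(numeric(0)), "empty")
})

test_that("peak-to-peak is shift invariant", {
  set.seed(6)
  x <- rnorm(500)
  expect_equal(max_peak_to_peak(x + 17.3), max_peak_to_peak(x))
})

test_that("session summary computes mean/SD/n per temperature", {
  amp <- data.frame(session_id = "s", epoch_index = 0:2,
                    start_time_s = c(0, 5, 10),
                    mean_temp_c = c(37.1, 37.2, 39.0),
                    rounded_temp_c = c(37L, 37L, 39L),
                    kept = TRUE, amplitude = c(0.4, 0.5, 0.7))
  s <- summarize_session(amp)
  expect_equal(s$mean[s$temperature_c == 37], 0.45)
  expect_equal(s$sd[s$temperature_c == 37], sd(c(0.4, 0.5)))
  expect_equal(s$n[s$temperature_c == 37], 2)
  # single epoch at a temperature: SD undefined, not zero
  expect_true(is.na(s$sd[s$temperature_c == 39]))
  expect_error(summarize_session(amp[amp$kept == FALSE, ]), "kept")
})

test_that("study summary averages session means with equal weight", {
  s1 <- data.frame(temperature_c = c(37, 42), mean = c(0.4, 0.3),
                   sd = 0.05, n = 10)
  s2 <- data.frame(temperature_c = c(37, 41), mean = c(0.5, 0.35),
                   sd = 0.05, n = 12)
  st <- summarize_study(list(s1, s2))
  expect_equal(st$mean[st$temperature_c == 37], 0.45)
  expect_equal(st$n_sessions[st$temperature_c == 37], 2)
  # temperatures present in one session only are kept with n = 1, SD NA
  expect_equal(st$n_sessions[st$temperature_c == 42], 1)
  expect_true(is.na(st$sd[st$temperature_c == 42]))
  # single-session study: study mean equals the session mean
  one <- summarize_study(list(s1))
  expect_equal(one$mean, s1$mean)
  expect_true(all(is.na(one$sd)))
})

test_that("percent reduction matches hand arithmetic in both modes", {
  st <- data.frame(temperature_c = 37:42,
                   mean = c(0.461, 0.436, 0.429, 0.357, 0.365, 0.341))
  red <- percent_reduction(st, mode = "study")
  expect_equal(red$reduction_pct[red$temperature_c == 37], 0)
  expect_equal(red$reduction_pct[red$temperature_c == 42],
               100 * (0.461 - 0.341) / 0.461)  # 26.03
  s1 <- data.frame(temperature_c = c(37, 42), mean = c(0.4, 0.3))
  s2 <- data.frame(temperature_c = c(37, 42), mean = c(0.5, 0.45))
  ps <- percent_reduction(list(s1, s2), mode = "per_session")
  expect_equal(ps$reduction_pct[ps$temperature_c == 42],
               mean(c(25, 10)))
  expect_equal(ps$reduction_sd[ps$temperature_c == 42], sd(c(25, 10)))
  expect_error(percent_reduction(st[st$temperature_c > 38, ]), "reference")
})

test_that("linear fit recovers exact coefficients and rejects tiny inputs", {
  temps <- 37:42
  exact <- data.frame(temperature_c = temps, mean = -0.025 * temps + 1.4)
  f <- fit_linear(exact)
  expect_equal(f$slope, -0.025)
  expect_equal(f$intercept, 1.4)
  expect_equal(f$r_squared, 1)
  expect_error(fit_linear(exact[1:2, ]), "at least 3")
})
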