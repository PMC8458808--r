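small_study <- function(n = 3, seed = 10)
  simulate_study(n, short_protocol(), generator_config(sampling_rate = 500),
                 seed = seed)

small_params <- function() study_params(n_iterations = 400)

test_that("study runner is deterministic and writes byte-identical outputs", {
  sessions <- small_study()
  r1 <- run_study(sessions, small_params(), seed = 5)
  r2 <- run_study(sessions, small_params(), seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study_results(r1, d1)
  write_study_results(r2, d2)
  for (f in list.files(d1)) {
    expect_true(file.exists(file.path(d2, f)))
    expect_identical(readBin(file.path(d1, f), raw(),
                             file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), raw(),
                             file.size(file.path(d2, f))),
                     label = paste("bytes of", f))
  }
})

test_that("session order does not change study-level summaries", {
  sessions <- small_study()
  r1 <- run_study(sessions, small_params(), seed = 5)
  r2 <- run_study(rev(sessions), small_params(), seed = 5)
  expect_equal(r1$amplitude_summary, r2$amplitude_summary)
  expect_equal(r1$band_summary, r2$band_summary)
  expect_equal(r1$fits$study$slope, r2$fits$study$slope)
})

test_that("every reported p-value carries backend, iterations and seed", {
  r <- run_study(small_study(), small_params(), seed = 5)
  expect_true(all(c("p_value", "backend", "n_iterations", "seed") %in%
                    names(r$tests)))
  expect_true(all(r$tests$backend %in% c("monte_carlo", "exact")))
  expect_true(all(r$tests$p_value > 0 & r$tests$p_value <= 1))
  # amplitude comparisons exist in both units for every non-reference temp
  amp <- r$tests[r$tests$measure == "amplitude", ]
  expect_setequal(unique(amp$unit), c("session_means", "pooled_epochs"))
})

test_that("report mirrors the published table layouts", {
  r <- run_study(small_study(), small_params(), seed = 5)
  rep <- make_report(r)
  # six temperature rows, with the reference row's p blank
  amp_rows <- grep("^(37|38|39|40|41|42) ", rep, value = TRUE)
  expect_length(amp_rows, 6)
  expect_match(amp_rows[1], "-$")
  # four band rows
  expect_length(grep("^(delta|theta|alpha|beta) ", rep), 4)
  # provenance embedded
  expect_true(any(grepl("config hash", rep)))
  expect_true(any(grepl("study seed: 5", rep)))
})

test_that("a single-session study degrades gracefully", {
  r <- run_study(small_study(1), small_params(), seed = 5)
  expect_true(all(is.na(r$amplitude_summary$sd)))
  expect_equal(r$amplitude_summary$n_sessions, rep(1, 6))
  # across-session comparisons are impossible; only pooled-epoch tests remain
  expect_false("session_means" %in% r$tests$unit)
  expect_true(all(r$tests$measure == "amplitude"))
})

test_that("a study with unreadable sessions aborts listing them", {
  dir <- withr::local_tempdir()
  rec <- cached_session(1)
  df <- data.frame(session_id = c("good", "bad"),
                   eeg_path = file.path(dir, c("g.edf", "b.edf")),
                   temp_path = file.path(dir, c("g.csv", "b.csv")),
                   seed = 1:2, stringsAsFactors = FALSE)
  write_session(rec, df$eeg_path[1], df$temp_path[1])
  write_session(rec, df$eeg_path[2], df$temp_path[2])
  # corrupt the second session's temperature channel
  half <- rec$temperature[rec$temperature$time_s <= 100, ]
  write_temperature_csv(half, df$temp_path[2])
  mpath <- file.path(dir, "study.yaml")
  write_manifest(df, small_params(), mpath)
  expect_error(run_study(read_manifest(mpath), seed = 1),
               "failing sessions: bad")
})

test_that("a study can be run from a manifest on disk", {
  dir <- withr::local_tempdir()
  sessions <- small_study(2)
  df <- data.frame(session_id = c("S01", "S02"),
                   eeg_path = file.path(dir, c("s1.edf", "s2.edf")),
                   temp_path = file.path(dir, c("s1.csv", "s2.csv")),
                   seed = 11:12, stringsAsFactors = FALSE)
  for (i in 1:2)
    write_session(sessions[[i]], df$eeg_path[i], df$temp_path[i])
  mpath <- file.path(dir, "study.yaml")
  write_manifest(df, small_params(), mpath)
  man <- read_manifest(mpath)
  r_disk <- run_study(man, seed = 5)
  r_mem <- run_study(sessions, small_params(), seed = 5)
  expect_equal(r_disk$amplitude_summary$mean, r_mem$amplitude_summary$mean,
               tolerance = 1e-3)
})
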