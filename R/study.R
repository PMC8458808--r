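# Study orchestration: simulate -> preprocess -> amplitude + spectral
# analyses -> permutation inference -> tables and report, deterministically
# from one study seed.

#' Analysis parameters of a study
#'
#' @param epoch_length Epoch length, seconds.
#' @param filter_low,filter_high Bandpass edges, Hz.
#' @param temp_range Inclusive integer temperature range analysed, degC.
#' @param n_iterations Permutation iterations for each comparison.
#' @param ref_temp Reference temperature for comparisons and reductions.
#' @return A list of class `study_params`.
#' @export
study_params <- function(epoch_length = 5, filter_low = 1, filter_high = 50,
                         temp_range = c(37, 42), n_iterations = 20000,
                         ref_temp = 37) {
  structure(list(epoch_length = epoch_length, filter_low = filter_low,
                 filter_high = filter_high,
                 temp_range = as.numeric(unlist(temp_range)),
                 n_iterations = n_iterations, ref_temp = ref_temp,
                 bands = eeg_bands()),
            class = c("study_params", "list"))
}

#' Simulate a multi-session study
#'
#' Generates `n_sessions` independent sessions under the same protocol and
#' generator configuration. All randomness flows from the study seed:
#' session `i` uses seed `seed + i`.
#'
#' @param n_sessions Number of sessions (the reference design uses 19).
#' @param protocol A [protocol_config()].
#' @param gen A [generator_config()].
#' @param seed Integer study seed.
#' @return A list of `session_recording` objects.
#' @export
simulate_study <- function(n_sessions = 19, protocol = protocol_config(),
                           gen = generator_config(), seed = 1) {
  profile <- make_temperature_profile(protocol)
  lapply(seq_len(n_sessions), function(i)
    synthesize_eeg(profile, gen, session_id = sprintf("S%02d", i),
                   seed = seed + i))
}

# Preprocess + summarize every session; shared by run_study() and the
# calibration loop.
.analyze_sessions <- function(sessions, params) {
  per <- lapply(sessions, function(rec) {
    ep <- preprocess_session(rec, low = params$filter_low,
                             high = params$filter_high,
                             epoch_length = params$epoch_length,
                             temp_range = params$temp_range)
    amp <- epoch_amplitudes(ep)
    spec <- spectral_session(ep, params$bands)
    list(session_id = rec$session_id,
         amplitudes = amp,
         amp_summary = summarize_session(amp),
         band_summary = spec$summary,
         fit = tryCatch(fit_linear(summarize_session(amp)),
                        error = function(e) NULL))
  })
  names(per) <- vapply(per, function(s) s$session_id, "")
  per
}

#' Run the full study pipeline
#'
#' Preprocesses every session, computes per-session and study-level
#' amplitude summaries, the amplitude-temperature regression, per-band
#' normalized power summaries, percent reductions (both computation orders),
#' and permutation tests: each temperature against the reference for
#' amplitude (on session means and on pooled epochs, both reported) and
#' peak-vs-reference per band (on session means). Deterministic given the
#' sessions and seed; session order does not affect study-level summaries.
#'
#' @param sessions A list of `session_recording` objects (e.g. from
#'   [simulate_study()]), or a `study_manifest` from [read_manifest()], in
#'   which case the sessions are loaded from disk.
#' @param params A [study_params()].
#' @param seed Integer seed for the permutation tests.
#' @return An object of class `study_result`; see Details. Fields:
#'   `amplitude_summary` (study level), `session_summaries`,
#'   `band_summary` (study level), `session_band_summaries`, `fits`
#'   (per-session and study-level [fit_linear()] results), `reductions`
#'   (both modes), `tests` (data frame with one row per comparison), and
#'   `provenance`.
#' @export
run_study <- function(sessions, params = NULL, seed = 1) {
  if (inherits(sessions, "study_manifest")) {
    params <- params %||% sessions$params
    man <- sessions$sessions
    loaded <- lapply(seq_len(nrow(man)), function(i)
      tryCatch(read_session(man$eeg_path[i], man$temp_path[i],
                            session_id = man$session_id[i],
                            epoch_length = params$epoch_length),
               error = function(e) structure(conditionMessage(e),
                                             class = "session_failure")))
    failed <- vapply(loaded, inherits, logical(1), "session_failure")
    if (any(failed))
      stop("study aborted; failing sessions: ",
           paste(sprintf("%s (%s)", man$session_id[failed],
                         unlist(loaded[failed])), collapse = "; "),
           call. = FALSE)
    if (!is.null(man$seed))
      loaded <- Map(function(rec, sd) { rec$seed <- as.integer(sd); rec },
                    loaded, man$seed)
    sessions <- loaded
  }
  params <- params %||% study_params()
  stopifnot(length(sessions) >= 1)

  per <- .analyze_sessions(sessions, params)
  per <- per[order(names(per))]  # merge-order independence

  session_summaries <- lapply(per, function(s) s$amp_summary)
  amplitude_summary <- summarize_study(session_summaries)
  session_band_summaries <- lapply(per, function(s) s$band_summary)
  band_summary <- summarize_band_study(session_band_summaries)

  fits <- list(study = tryCatch(fit_linear(amplitude_summary),
                                error = function(e) NULL),
               sessions = lapply(per, function(s) s$fit))

  reductions <- list(
    study = tryCatch(percent_reduction(amplitude_summary,
                                       params$ref_temp, "study"),
                     error = function(e) NULL),
    per_session = tryCatch(percent_reduction(session_summaries,
                                             params$ref_temp, "per_session"),
                           error = function(e) NULL))

  ref <- params$ref_temp
  temps <- setdiff(amplitude_summary$temperature_c, ref)
  peak <- max(amplitude_summary$temperature_c)
  tests <- list()
  k <- 0
  grab_means <- function(tc) unlist(lapply(session_summaries, function(s)
    s$mean[s$temperature_c == tc]))
  grab_pooled <- function(tc) unlist(lapply(per, function(s)
    s$amplitudes$amplitude[s$amplitudes$kept &
                           s$amplitudes$rounded_temp_c == tc]))
  add_test <- function(comparison, measure, unit, a, b) {
    k <<- k + 1
    if (length(a) < 1 || length(b) < 1 || length(a) + length(b) < 3)
      return(invisible(NULL))
    pt <- permutation_test(a, b, n_iterations = params$n_iterations,
                           seed = seed + 101L * k)
    tests[[length(tests) + 1]] <<- data.frame(
      comparison = comparison, measure = measure, unit = unit,
      observed_stat = pt$observed_stat, p_value = pt$p_value,
      backend = pt$backend, n_iterations = pt$n_iterations,
      seed = seed + 101L * k, stringsAsFactors = FALSE)
    invisible(NULL)
  }
  for (tc in temps) {
    add_test(sprintf("%d_vs_%d", tc, ref), "amplitude", "session_means",
             grab_means(ref), grab_means(tc))
    add_test(sprintf("%d_vs_%d", tc, ref), "amplitude", "pooled_epochs",
             grab_pooled(ref), grab_pooled(tc))
  }
  for (b in params$bands$band) {
    a <- unlist(lapply(session_band_summaries, function(s)
      s$mean[s$band == b & s$temperature_c == ref]))
    bb <- unlist(lapply(session_band_summaries, function(s)
      s$mean[s$band == b & s$temperature_c == peak]))
    add_test(sprintf("%d_vs_%d", peak, ref), b, "session_means", a, bb)
  }
  tests <- if (length(tests)) do.call(rbind, tests) else NULL

  structure(list(amplitude_summary = amplitude_summary,
                 session_summaries = session_summaries,
                 band_summary = band_summary,
                 session_band_summaries = session_band_summaries,
                 fits = fits, reductions = reductions, tests = tests,
                 provenance = list(
                   study_seed = seed,
                   session_seeds = vapply(sessions, function(s)
                     as.integer(s$seed), integer(1)),
                   config_hash = rlang::hash(list(
                     params = unclass(params),
                     gen = lapply(sessions, function(s)
                       if (is.null(s$config)) NA else unclass(s$config)))),
                   package_version = as.character(
                     utils::packageVersion("thermoEEG")))),
            class = "study_result")
}

#' Write study result tables to a directory
#'
#' Emits `table1.csv` (amplitude per temperature with p-values vs the
#' reference), `table2.csv` (band powers at reference and peak temperature
#' with p-values), `fits.csv`, `tests.csv`, `reductions.csv` and a
#' `run_log.txt` with provenance. Output is byte-identical across runs with
#' the same input and seed.
#'
#' @param result A `study_result`.
#' @param outdir Output directory (created if needed).
#' @param ref_temp,peak_temp Temperatures used for the table layouts.
#' @return `outdir`, invisibly.
#' @export
write_study_results <- function(result, outdir, ref_temp = 37,
                                peak_temp = 42) {
  stopifnot(inherits(result, "study_result"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  amp <- result$amplitude_summary
  tst <- result$tests
  pcol <- vapply(amp$temperature_c, function(tc) {
    if (tc == ref_temp || is.null(tst)) return(NA_real_)
    i <- tst$comparison == sprintf("%d_vs_%d", tc, ref_temp) &
      tst$measure == "amplitude" & tst$unit == "session_means"
    if (any(i)) tst$p_value[i][1] else NA_real_
  }, numeric(1))
  t1 <- data.frame(temperature_c = amp$temperature_c, mean = amp$mean,
                   sd = amp$sd, n = amp$n_sessions, p_vs_37 = pcol)
  utils::write.csv(t1, file.path(outdir, "table1.csv"), row.names = FALSE)

  bs <- result$band_summary
  t2 <- do.call(rbind, lapply(unique(bs$band), function(b) {
    r <- function(tc, col) {
      v <- bs[[col]][bs$band == b & bs$temperature_c == tc]
      if (length(v)) v else NA_real_
    }
    pv <- NA_real_
    if (!is.null(tst)) {
      i <- tst$measure == b & tst$unit == "session_means"
      if (any(i)) pv <- tst$p_value[i][1]
    }
    data.frame(band = b, mean_37 = r(ref_temp, "mean"),
               sd_37 = r(ref_temp, "sd"), mean_42 = r(peak_temp, "mean"),
               sd_42 = r(peak_temp, "sd"), p = pv, stringsAsFactors = FALSE)
  }))
  utils::write.csv(t2, file.path(outdir, "table2.csv"), row.names = FALSE)

  fit_row <- function(level, id, f) {
    if (is.null(f)) return(NULL)
    data.frame(level = level, session_id = id, slope = f$slope,
               intercept = f$intercept, r_squared = f$r_squared,
               stringsAsFactors = FALSE)
  }
  fits <- rbind(fit_row("study", "", result$fits$study),
                do.call(rbind, Map(fit_row, "session",
                                   names(result$fits$sessions),
                                   result$fits$sessions)))
  utils::write.csv(fits, file.path(outdir, "fits.csv"), row.names = FALSE)
  if (!is.null(result$tests))
    utils::write.csv(result$tests, file.path(outdir, "tests.csv"),
                     row.names = FALSE)
  if (!is.null(result$reductions$per_session))
    utils::write.csv(result$reductions$per_session,
                     file.path(outdir, "reductions.csv"), row.names = FALSE)
  writeLines(make_report(result), file.path(outdir, "run_log.txt"))
  invisible(outdir)
}

#' Render a human-readable study report
#'
#' @param result A `study_result`.
#' @param ref_temp,peak_temp Temperatures used for the layouts.
#' @return A character vector of report lines.
#' @export
make_report <- function(result, ref_temp = 37, peak_temp = 42) {
  stopifnot(inherits(result, "study_result"))
  fmt <- function(x, d = 3) ifelse(is.na(x), "-", sprintf("%.*f", d, x))
  amp <- result$amplitude_summary
  tst <- result$tests
  lines <- c("EEG amplitude vs core temperature",
             sprintf("%-16s %-8s %-8s %-4s %s",
                     "Temperature (C)", "Mean", "SD", "n", "p (vs. 37C)"))
  for (i in seq_len(nrow(amp))) {
    tc <- amp$temperature_c[i]
    p <- "-"
    if (tc != ref_temp && !is.null(tst)) {
      j <- tst$comparison == sprintf("%d_vs_%d", tc, ref_temp) &
        tst$measure == "amplitude" & tst$unit == "session_means"
      if (any(j)) p <- fmt(tst$p_value[j][1], 4)
    }
    lines <- c(lines, sprintf("%-16d %-8s %-8s %-4d %s", tc,
                              fmt(amp$mean[i]), fmt(amp$sd[i]),
                              amp$n_sessions[i], p))
  }
  bs <- result$band_summary
  lines <- c(lines, "",
             sprintf("Normalized band power at %dC vs %dC", ref_temp,
                     peak_temp),
             sprintf("%-8s %-8s %-8s %-8s %-8s %s", "Band",
                     paste0("M", ref_temp), paste0("SD", ref_temp),
                     paste0("M", peak_temp), paste0("SD", peak_temp), "p"))
  for (b in unique(bs$band)) {
    g <- function(tc, col) {
      v <- bs[[col]][bs$band == b & bs$temperature_c == tc]
      if (length(v)) v else NA_real_
    }
    p <- "-"
    if (!is.null(tst)) {
      j <- tst$measure == b & tst$unit == "session_means"
      if (any(j)) p <- fmt(tst$p_value[j][1], 4)
    }
    lines <- c(lines, sprintf("%-8s %-8s %-8s %-8s %-8s %s", b,
                              fmt(g(ref_temp, "mean")), fmt(g(ref_temp, "sd")),
                              fmt(g(peak_temp, "mean")),
                              fmt(g(peak_temp, "sd")), p))
  }
  f <- result$fits$study
  if (!is.null(f))
    lines <- c(lines, "", sprintf(
      "Study regression: y = %.4fx + %.4f; R2 = %.3f",
      f$slope, f$intercept, f$r_squared))
  red <- result$reductions$per_session
  if (!is.null(red)) {
    for (tc in intersect(c(ref_temp + 1, peak_temp), red$temperature_c)) {
      i <- red$temperature_c == tc
      lines <- c(lines, sprintf(
        "Reduction %d -> %d C: %.2f%% (+/- %.2f, per-session)",
        ref_temp, tc, red$reduction_pct[i], red$reduction_sd[i]))
    }
  }
  pr <- result$provenance
  c(lines, "",
    sprintf("study seed: %d; session seeds: %s", pr$study_seed,
            paste(pr$session_seeds, collapse = ",")),
    sprintf("config hash: %s; thermoEEG %s", pr$config_hash,
            pr$package_version))
}

#' @export
print.study_result <- function(x, ...) {
  cat(make_report(x), sep = "\n")
  invisible(x)
}
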