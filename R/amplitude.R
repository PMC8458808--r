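# Per-epoch maximum peak-to-peak amplitude, per-temperature summaries,
# percent reductions and the amplitude-vs-temperature linear regression.

#' Maximum peak-to-peak amplitude of a signal slice
#'
#' @param x Non-empty numeric vector.
#' @return `max(x) - min(x)`.
#' @export
max_peak_to_peak <- function(x) {
  if (length(x) == 0) stop("empty epoch", call. = FALSE)
  if (!all(is.finite(x))) stop("epoch contains non-finite values",
                               call. = FALSE)
  max(x) - min(x)
}

#' Per-epoch amplitudes of an epoch set
#'
#' @param epochs An `epoch_set` from [make_epochs()] or
#'   [preprocess_session()].
#' @return The `meta` data frame with an extra `amplitude` column (computed
#'   for every epoch, kept or not).
#' @export
epoch_amplitudes <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  meta <- epochs$meta
  meta$amplitude <- apply(epochs$samples, 1, max_peak_to_peak)
  meta
}

#' Session-level amplitude summary per integer temperature
#'
#' Mean, sample SD (n - 1 denominator; `NA` when a temperature has a single
#' epoch) and epoch count of the per-epoch maximum peak-to-peak amplitude,
#' grouped by rounded temperature over the kept epochs.
#'
#' @param epochs An `epoch_set`, or a data frame from [epoch_amplitudes()].
#' @return A data frame with columns `temperature_c` (ascending), `mean`,
#'   `sd`, `n`.
#' @export
summarize_session <- function(epochs) {
  amp <- if (inherits(epochs, "epoch_set")) epoch_amplitudes(epochs)
         else epochs
  amp <- amp[amp$kept, , drop = FALSE]
  if (nrow(amp) == 0) stop("no kept epochs to summarize", call. = FALSE)
  temps <- sort(unique(amp$rounded_temp_c))
  out <- do.call(rbind, lapply(temps, function(tc) {
    v <- amp$amplitude[amp$rounded_temp_c == tc]
    data.frame(temperature_c = tc, mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               n = length(v))
  }))
  rownames(out) <- NULL
  out
}

#' Study-level amplitude summary across sessions
#'
#' For each temperature, the mean and SD of the session-level means, every
#' session weighted equally. Temperatures absent from all sessions are
#' omitted; SD is `NA` when only one session contributes.
#'
#' @param session_summaries List of [summarize_session()] data frames.
#' @return A data frame with columns `temperature_c`, `mean`, `sd`,
#'   `n_sessions`.
#' @export
summarize_study <- function(session_summaries) {
  stopifnot(is.list(session_summaries), length(session_summaries) >= 1)
  temps <- sort(unique(unlist(lapply(session_summaries,
                                     function(s) s$temperature_c))))
  out <- do.call(rbind, lapply(temps, function(tc) {
    v <- unlist(lapply(session_summaries, function(s) {
      m <- s$mean[s$temperature_c == tc]
      if (length(m)) m else NULL
    }))
    data.frame(temperature_c = tc, mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               n_sessions = length(v))
  }))
  rownames(out) <- NULL
  out
}

#' Percent reduction of amplitude relative to a reference temperature
#'
#' Two computation orders are exposed because they answer different
#' questions: `"study"` computes `100 * (mean_ref - mean_T) / mean_ref` on
#' the study-level (or a single session's) means; `"per_session"` computes
#' the reduction within each session first and then reports the mean and SD
#' of those per-session reductions, which is the natural reading of an
#' "x% (+/- y)" reduction quoted with a spread.
#'
#' @param x For `mode = "study"` a summary data frame
#'   ([summarize_session()] / [summarize_study()]); for
#'   `mode = "per_session"` a list of session summary data frames.
#' @param ref_temp Reference temperature, degC (default 37).
#' @param mode `"study"` or `"per_session"`.
#' @return A data frame with `temperature_c` and `reduction_pct`
#'   (plus `reduction_sd` and `n_sessions` in `"per_session"` mode).
#' @export
percent_reduction <- function(x, ref_temp = 37,
                              mode = c("study", "per_session")) {
  mode <- match.arg(mode)
  if (mode == "study") {
    ref <- x$mean[x$temperature_c == ref_temp]
    if (length(ref) != 1) stop("reference temperature not present",
                               call. = FALSE)
    if (ref == 0) stop("reference mean is zero", call. = FALSE)
    data.frame(temperature_c = x$temperature_c,
               reduction_pct = 100 * (ref - x$mean) / ref)
  } else {
    per <- lapply(x, function(s) {
      ref <- s$mean[s$temperature_c == ref_temp]
      if (length(ref) != 1 || ref == 0) return(NULL)
      data.frame(temperature_c = s$temperature_c,
                 reduction_pct = 100 * (ref - s$mean) / ref)
    })
    per <- per[!vapply(per, is.null, logical(1))]
    if (!length(per)) stop("reference temperature not present in any session",
                           call. = FALSE)
    temps <- sort(unique(unlist(lapply(per, function(s) s$temperature_c))))
    out <- do.call(rbind, lapply(temps, function(tc) {
      v <- unlist(lapply(per, function(s)
        s$reduction_pct[s$temperature_c == tc]))
      data.frame(temperature_c = tc, reduction_pct = mean(v),
                 reduction_sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                 n_sessions = length(v))
    }))
    rownames(out) <- NULL
    out
  }
}

#' Ordinary least squares fit of mean amplitude on temperature
#'
#' Fits `mean ~ temperature_c` by OLS on the per-temperature means (one
#' point per integer temperature, unweighted), as used for the
#' amplitude-decline regression.
#'
#' @param summary A summary data frame with at least 3 temperature levels
#'   (columns `temperature_c`, `mean`).
#' @return An object of class `linear_fit`: list with `slope` (normalized
#'   amplitude per degC), `intercept`, `r_squared` and `n_points`.
#' @export
fit_linear <- function(summary) {
  ok <- is.finite(summary$mean)
  if (sum(ok) < 3)
    stop("need at least 3 temperature levels for the regression",
         call. = FALSE)
  fit <- stats::lm(mean ~ temperature_c, data = summary[ok, , drop = FALSE])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n_points = sum(ok)),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> y = %.4fx + %.4f; R2 = %.3f (%d points)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}
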