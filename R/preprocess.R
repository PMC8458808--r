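# Signal conditioning and epoching: zero-phase 1-50 Hz bandpass, session-wide
# 0-1 normalization, contiguous 5-s epochs, per-epoch temperature rounding
# and keep/discard rules.

#' Zero-phase Butterworth bandpass filter
#'
#' A 4th-order Butterworth bandpass (two poles per edge) applied
#' forward-backward, so the net phase response is zero and peak timing is
#' preserved. The signal is padded by odd reflection (three high-pass time
#' constants long) before filtering to suppress edge transients.
#'
#' @param x Numeric signal.
#' @param sampling_rate Sampling rate, Hz. Must exceed `2 * high`.
#' @param low,high Passband edges, Hz (defaults 1 and 50).
#' @return The filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, sampling_rate, low = 1, high = 50) {
  if (sampling_rate <= 2 * high)
    stop("`sampling_rate` must exceed twice the upper band edge",
         call. = FALSE)
  if (low <= 0 || low >= high)
    stop("band edges must satisfy 0 < low < high", call. = FALSE)
  n <- length(x)
  bf <- signal::butter(2, c(low, high) / (sampling_rate / 2), type = "pass")
  pad <- min(n - 1, max(9L, round(3 * sampling_rate / low)))
  if (n <= 3 * length(bf$b))
    stop("signal too short for the filter order", call. = FALSE)
  xp <- c(2 * x[1] - x[(pad + 1):2],
          x,
          2 * x[n] - x[(n - 1):(n - pad)])
  y <- as.numeric(signal::filter(bf, xp))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[(pad + 1):(pad + n)]
}

#' Min-max normalization to the unit interval
#'
#' Affine map sending the signal's minimum to 0 and maximum to 1. Applied
#' once per session, after filtering, so that amplitudes from the same
#' session share a common scale.
#'
#' @param x Numeric signal with `max(x) > min(x)`.
#' @return The rescaled signal.
#' @export
normalize_01 <- function(x) {
  if (!all(is.finite(x))) stop("signal contains non-finite values",
                               call. = FALSE)
  r <- range(x)
  if (r[2] <= r[1])
    stop("degenerate range: signal is constant, cannot normalize",
         call. = FALSE)
  (x - r[1]) / (r[2] - r[1])
}

#' Round epoch temperatures and apply the keep/discard rule
#'
#' Temperatures are rounded half-up to the nearest integer degC and the epoch
#' is kept only if the rounded value lies inside the analysis range, so e.g.
#' 36.6 degC rounds to 37 and is kept while 36.4 degC rounds to 36 and is
#' discarded.
#'
#' @param mean_temp Numeric vector of epoch-mean temperatures, degC.
#' @param temp_range Inclusive integer range of temperatures to keep
#'   (default `c(37, 42)`).
#' @return A data frame with columns `rounded_temp_c` (integer) and `kept`
#'   (logical).
#' @export
assign_temperature <- function(mean_temp, temp_range = c(37, 42)) {
  if (!all(is.finite(mean_temp)))
    stop("epoch temperatures must be finite", call. = FALSE)
  rounded <- floor(mean_temp + 0.5)
  data.frame(rounded_temp_c = as.integer(rounded),
             kept = rounded >= temp_range[1] & rounded <= temp_range[2])
}

#' Cut a recording into contiguous fixed-length epochs
#'
#' Epochs start at t = 0 and tile the recording without overlap; a trailing
#' partial epoch is dropped. Each epoch gets the mean of the temperature
#' channel (linearly interpolated onto the EEG time axis) over its samples,
#' plus the rounded temperature and keep flag from [assign_temperature()].
#'
#' @param rec A `session_recording` (the `eeg` field is sliced as-is; apply
#'   [bandpass_filter()] and [normalize_01()] first, or use
#'   [preprocess_session()]).
#' @param epoch_length Epoch length, seconds (default 5).
#' @param temp_range Passed to [assign_temperature()].
#' @return An object of class `epoch_set`: a list with `meta` (data frame:
#'   `session_id`, `epoch_index` 0-based, `start_time_s`, `mean_temp_c`,
#'   `rounded_temp_c`, `kept`), `samples` (matrix, one row per epoch),
#'   `sampling_rate` and `session_id`. Zero epochs yields an empty `epoch_set`
#'   with a warning.
#' @export
make_epochs <- function(rec, epoch_length = 5, temp_range = c(37, 42)) {
  stopifnot(inherits(rec, "session_recording"))
  if (epoch_length <= 0) stop("`epoch_length` must be positive", call. = FALSE)
  fs <- rec$sampling_rate
  n_per <- round(epoch_length * fs)
  n_ep <- length(rec$eeg) %/% n_per
  if (n_ep < 1) {
    warning("recording shorter than one epoch; returning no epochs")
    meta <- data.frame(session_id = character(), epoch_index = integer(),
                       start_time_s = numeric(), mean_temp_c = numeric(),
                       rounded_temp_c = integer(), kept = logical())
    return(structure(list(meta = meta,
                          samples = matrix(numeric(), nrow = 0, ncol = n_per),
                          sampling_rate = fs, session_id = rec$session_id),
                     class = "epoch_set"))
  }
  used <- n_ep * n_per
  samples <- matrix(rec$eeg[seq_len(used)], nrow = n_ep, byrow = TRUE)
  tt <- (seq_len(used) - 1) / fs
  temps <- stats::approx(rec$temperature$time_s, rec$temperature$temp_c,
                         xout = tt, rule = 2)$y
  mean_temp <- rowMeans(matrix(temps, nrow = n_ep, byrow = TRUE))
  at <- assign_temperature(mean_temp, temp_range)
  meta <- data.frame(session_id = rec$session_id,
                     epoch_index = seq_len(n_ep) - 1L,
                     start_time_s = (seq_len(n_ep) - 1) * epoch_length,
                     mean_temp_c = mean_temp,
                     rounded_temp_c = at$rounded_temp_c,
                     kept = at$kept,
                     stringsAsFactors = FALSE)
  structure(list(meta = meta, samples = samples, sampling_rate = fs,
                 session_id = rec$session_id),
            class = "epoch_set")
}

#' Full preprocessing of one session
#'
#' Applies the analysis conditioning in order: zero-phase 1-50 Hz bandpass,
#' session-wide 0-1 normalization, then 5-s epoching with temperature
#' assignment.
#'
#' @param rec A `session_recording`.
#' @param low,high Bandpass edges, Hz.
#' @param epoch_length Epoch length, seconds.
#' @param temp_range Inclusive temperature range kept, degC.
#' @return An `epoch_set` of the normalized signal; see [make_epochs()].
#' @export
preprocess_session <- function(rec, low = 1, high = 50, epoch_length = 5,
                               temp_range = c(37, 42)) {
  stopifnot(inherits(rec, "session_recording"))
  x <- bandpass_filter(rec$eeg, rec$sampling_rate, low, high)
  x <- normalize_01(x)
  rec2 <- rec
  rec2$eeg <- x
  make_epochs(rec2, epoch_length = epoch_length, temp_range = temp_range)
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %s: %d epochs x %d samples, %d kept\n",
              x$session_id, nrow(x$samples), ncol(x$samples),
              sum(x$meta$kept)))
  invisible(x)
}
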