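# Per-epoch Welch power spectra, half-open band integration for
# delta/theta/alpha/beta, per-band 0-1 normalization across a session's
# epochs, and per-temperature band summaries.

#' Canonical EEG band definitions
#'
#' Half-open intervals `[low, high)` so that the shared edges at 4, 8 and
#' 12 Hz are never counted twice: delta `[1,4)`, theta `[4,8)`, alpha
#' `[8,12)`, beta `[12,30)`.
#'
#' @return A data frame with columns `band`, `low`, `high` (Hz).
#' @export
eeg_bands <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta"),
             low = c(1, 4, 8, 12),
             high = c(4, 8, 12, 30),
             stringsAsFactors = FALSE)
}

# Welch PSD of the rows of a matrix: seg-second Hann segments, 50% overlap,
# per-segment demeaning, one-sided density. Returns freq + psd (rows =
# epochs).
.welch_matrix <- function(S, fs, seg_seconds = 2, overlap = 0.5) {
  L <- round(seg_seconds * fs)
  if (ncol(S) < L)
    stop("epoch shorter than one Welch segment", call. = FALSE)
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, ncol(S) - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  U <- sum(w^2)
  nf <- L %/% 2 + 1
  acc <- matrix(0, nf, nrow(S))
  for (s0 in starts) {
    seg <- t(S[, s0:(s0 + L - 1), drop = FALSE])
    seg <- seg - rep(colMeans(seg), each = L)
    X <- stats::mvfft(seg * w)[seq_len(nf), , drop = FALSE]
    acc <- acc + Mod(X)^2
  }
  psd <- acc * (2 / (fs * U * length(starts)))
  psd[1, ] <- psd[1, ] / 2
  if (L %% 2 == 0) psd[nf, ] <- psd[nf, ] / 2
  list(freq = (0:(nf - 1)) * fs / L, psd = t(psd))
}

#' Welch power spectral density of one epoch
#'
#' Averaged modified periodograms: 2-s Hann-windowed segments with 50%
#' overlap, demeaned per segment, one-sided density. With 2-s segments the
#' frequency resolution is 0.5 Hz.
#'
#' @param x Numeric signal (one epoch).
#' @param sampling_rate Sampling rate, Hz.
#' @param seg_seconds Segment length, seconds.
#' @param overlap Fractional overlap between segments.
#' @return A list with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, sampling_rate, seg_seconds = 2, overlap = 0.5) {
  r <- .welch_matrix(matrix(x, nrow = 1), sampling_rate, seg_seconds, overlap)
  list(freq = r$freq, psd = as.numeric(r$psd))
}

#' Welch spectra of every epoch in an epoch set
#'
#' @param epochs An `epoch_set`.
#' @param seg_seconds,overlap Welch settings; see [welch_psd()].
#' @return A list with `freq` (Hz), `psd` (matrix, one row per epoch) and
#'   `settings` (recorded estimator parameters).
#' @export
epoch_power_spectrum <- function(epochs, seg_seconds = 2, overlap = 0.5) {
  stopifnot(inherits(epochs, "epoch_set"))
  r <- .welch_matrix(epochs$samples, epochs$sampling_rate, seg_seconds,
                     overlap)
  r$settings <- list(estimator = "welch", window = "hann",
                     seg_seconds = seg_seconds, overlap = overlap,
                     sampling_rate = epochs$sampling_rate)
  r
}

# Trapezoid quadrature weights for the integral of the linear interpolant of
# (freq, y) over [lo, hi]. Integration over the continuous interval means
# adjacent bands sharing an edge never double-count power.
.band_weights <- function(freq, lo, hi) {
  w <- numeric(length(freq))
  for (i in seq_len(length(freq) - 1)) {
    f1 <- freq[i]; f2 <- freq[i + 1]
    a <- max(f1, lo); b <- min(f2, hi)
    if (b <= a) next
    d <- f2 - f1
    ca <- 1 - (a - f1) / d
    cb <- 1 - (b - f1) / d
    w[i] <- w[i] + (b - a) / 2 * (ca + cb)
    w[i + 1] <- w[i + 1] + (b - a) / 2 * ((1 - ca) + (1 - cb))
  }
  w
}

#' Band power by trapezoidal integration of a PSD
#'
#' Integrates the (linearly interpolated) PSD over `[low, high)`; because
#' integration over the half-open continuous interval carries no mass at the
#' shared edge, adjacent bands partition the spectrum exactly.
#'
#' @param psd PSD values: a vector, or a matrix with one row per epoch.
#' @param freq Frequency grid, Hz (ascending).
#' @param low,high Band edges, Hz; must lie within the grid and satisfy
#'   `low < high`.
#' @return Band power (variance units): scalar, or one value per row.
#' @export
band_power <- function(psd, freq, low, high) {
  if (low >= high) stop("empty band: `low` must be below `high`",
                        call. = FALSE)
  if (low < min(freq) || high > max(freq))
    stop("band outside the frequency grid", call. = FALSE)
  w <- .band_weights(freq, low, high)
  if (is.matrix(psd)) as.numeric(psd %*% w) else sum(psd * w)
}

#' Per-epoch band powers for the four canonical bands
#'
#' @param spectrum Result of [epoch_power_spectrum()].
#' @param bands Band table; defaults to [eeg_bands()].
#' @return A matrix (epochs x bands) of raw band powers, columns named by
#'   band.
#' @export
session_band_powers <- function(spectrum, bands = eeg_bands()) {
  P <- matrix(0, nrow(spectrum$psd), nrow(bands),
              dimnames = list(NULL, bands$band))
  for (i in seq_len(nrow(bands)))
    P[, i] <- band_power(spectrum$psd, spectrum$freq, bands$low[i],
                         bands$high[i])
  P
}

#' Min-max normalize band powers across a session's kept epochs
#'
#' Per band, the minimum over the kept epochs maps to 0 and the maximum to 1.
#' A band with zero range is set to all zeros with a warning.
#'
#' @param P Matrix of raw band powers (epochs x bands).
#' @param kept Logical vector of epochs used to define the min/max (defaults
#'   to all).
#' @return Matrix of the same shape with values in `[0, 1]` for kept rows.
#' @export
normalize_band_powers <- function(P, kept = rep(TRUE, nrow(P))) {
  stopifnot(is.matrix(P), length(kept) == nrow(P))
  if (sum(kept) < 2) stop("need at least 2 kept epochs", call. = FALSE)
  out <- P
  for (j in seq_len(ncol(P))) {
    r <- range(P[kept, j])
    if (r[2] <= r[1]) {
      warning(sprintf("band %s has zero range; normalized values set to 0",
                      colnames(P)[j] %||% j))
      out[, j] <- 0
    } else {
      out[, j] <- (P[, j] - r[1]) / (r[2] - r[1])
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Session-level band-power summary per temperature
#'
#' Mean normalized power per band per rounded temperature over kept epochs.
#'
#' @param normP Normalized band-power matrix from [normalize_band_powers()].
#' @param meta Epoch metadata (`epoch_set$meta`), aligned with `normP` rows.
#' @return A data frame with `band`, `temperature_c`, `mean`, `n`.
#' @export
summarize_bands <- function(normP, meta) {
  stopifnot(nrow(normP) == nrow(meta))
  keep <- meta$kept
  temps <- sort(unique(meta$rounded_temp_c[keep]))
  out <- do.call(rbind, lapply(colnames(normP), function(b) {
    do.call(rbind, lapply(temps, function(tc) {
      v <- normP[keep & meta$rounded_temp_c == tc, b]
      data.frame(band = b, temperature_c = tc, mean = mean(v), n = length(v),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Study-level band-power summary across sessions
#'
#' Mean and SD across the session-level means, each session weighted
#' equally.
#'
#' @param session_band_summaries List of [summarize_bands()] data frames.
#' @return A data frame with `band`, `temperature_c`, `mean`, `sd`,
#'   `n_sessions`.
#' @export
summarize_band_study <- function(session_band_summaries) {
  stopifnot(is.list(session_band_summaries),
            length(session_band_summaries) >= 1)
  all <- do.call(rbind, session_band_summaries)
  keys <- unique(all[, c("band", "temperature_c")])
  keys <- keys[order(match(keys$band, eeg_bands()$band), keys$temperature_c), ]
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    v <- all$mean[all$band == keys$band[i] &
                  all$temperature_c == keys$temperature_c[i]]
    data.frame(band = keys$band[i], temperature_c = keys$temperature_c[i],
               mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               n_sessions = length(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Spectral pipeline for one preprocessed session
#'
#' Convenience wrapper: Welch spectra per epoch, band integration,
#' per-session min-max normalization over kept epochs, and the session-level
#' per-temperature summary.
#'
#' @param epochs An `epoch_set` from [preprocess_session()].
#' @param bands Band table; defaults to [eeg_bands()].
#' @return A list with `powers` (raw), `normalized`, and `summary`
#'   (session-level band summary).
#' @export
spectral_session <- function(epochs, bands = eeg_bands()) {
  spec <- epoch_power_spectrum(epochs)
  P <- session_band_powers(spec, bands)
  normP <- normalize_band_powers(P, epochs$meta$kept)
  list(powers = P, normalized = normP,
       summary = summarize_bands(normP, epochs$meta))
}
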