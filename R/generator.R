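# Synthetic temperature-coupled EEG generator.
#
# The signal model is a sum of narrowband stochastic oscillators (one per
# canonical EEG band), a 1/f (pink) aperiodic background, a slow positive
# burst modulator shared by all components, sparse sharp transients, and a
# linear temperature envelope E(T) = b0 + b1*T applied to everything.
# Per-band fractional slopes let individual rhythms decline faster or slower
# than the global envelope as temperature rises.

#' Configuration of the synthetic EEG generator
#'
#' Holds every tunable of the session generator. The defaults are the
#' package's calibrated configuration: they were fixed once, by running
#' [calibrate_generator()] against the amplitude and band-power summaries the
#' analysis pipeline is expected to recover on a 19-session study, and are
#' shipped as constants.
#'
#' @param sampling_rate EEG sampling rate, Hz. 1000 by default; 20000 is
#'   supported. Must be at least 250 so the 1-50 Hz analysis band is
#'   representable.
#' @param band_gains Named amplitude gains (arbitrary units, RMS of each
#'   oscillator at 37 degC) for `delta`, `theta`, `alpha`, `beta`.
#' @param band_centers Named center frequencies, Hz, of the narrowband
#'   oscillators.
#' @param band_widths Named full bandwidths, Hz, of the oscillators.
#' @param noise_gain Amplitude of the pink (1/f) background at 37 degC.
#' @param envelope_slope Slope b1 of the linear signal envelope
#'   `E(T) = b0 + b1 * T` (envelope multiplier per degC); negative values make
#'   the whole signal shrink as temperature rises.
#' @param envelope_intercept Intercept b0 of the envelope; defaults to
#'   `1 - 37 * envelope_slope` so that `E(37) = 1`.
#' @param per_band_slopes Named fractional gain change per degC for each band,
#'   applied on top of the envelope as `1 + slope * (T - 37)` (floored at 0).
#' @param noise_slope Fractional gain change per degC of the pink background.
#' @param burst_sd Log-scale SD of the slow multiplicative burst modulator
#'   (0 disables bursting).
#' @param burst_timescale Correlation timescale of the burst modulator, s.
#' @param transient_rate Rate of sharp high-amplitude transients, events/min
#'   (0 disables them).
#' @param transient_gain Median transient peak amplitude in units of the
#'   background RMS.
#' @param transient_jitter Log-scale SD of transient amplitudes.
#' @param transient_freq Carrier frequency of the transient wavelet, Hz.
#' @param transient_width Gaussian half-width of the transient wavelet, s.
#' @param session_jitter_sd Log-scale SD of the per-session multiplicative
#'   jitter applied to each band gain (between-session variability).
#' @param slope_jitter_sd Log-scale SD of the per-session multiplicative
#'   jitter applied to the envelope and band slopes (between-session
#'   variability of heat sensitivity).
#' @param amplitude_scale Overall output scale, microvolts (the analysis
#'   pipeline is scale-invariant; this only matters for file export).
#' @param seed Default integer seed used when [synthesize_eeg()] is called
#'   without one.
#'
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(sampling_rate = 1000,
                             band_gains = c(delta = 1.00, theta = 0.55,
                                            alpha = 0.40, beta = 0.30),
                             band_centers = c(delta = 2.5, theta = 6,
                                              alpha = 10, beta = 21),
                             band_widths = c(delta = 3, theta = 4,
                                             alpha = 4, beta = 18),
                             noise_gain = 2.32,
                             envelope_slope = -0.050,
                             envelope_intercept = 1 - 37 * envelope_slope,
                             per_band_slopes = c(delta = 0.1436,
                                                 theta = 0.1224,
                                                 alpha = 0.1436,
                                                 beta = -0.0717),
                             noise_slope = -0.1228,
                             burst_sd = 0,
                             burst_timescale = 8,
                             transient_rate = 2,
                             transient_gain = 2.84,
                             transient_jitter = 0.45,
                             transient_freq = 35,
                             transient_width = 0.03,
                             session_jitter_sd = 0.12,
                             slope_jitter_sd = 0.20,
                             amplitude_scale = 150,
                             seed = 1L) {
  bands <- c("delta", "theta", "alpha", "beta")
  if (!all(bands %in% names(band_gains)) ||
      !all(bands %in% names(band_centers)) ||
      !all(bands %in% names(band_widths)) ||
      !all(bands %in% names(per_band_slopes)))
    stop("band parameters must be named delta/theta/alpha/beta", call. = FALSE)
  if (sampling_rate < 250)
    stop("`sampling_rate` must be at least 250 Hz", call. = FALSE)
  if (any(band_gains < 0) || noise_gain < 0)
    stop("gains must be non-negative", call. = FALSE)
  if (burst_sd < 0 || transient_rate < 0 || session_jitter_sd < 0 ||
      slope_jitter_sd < 0)
    stop("variability parameters must be non-negative", call. = FALSE)
  structure(list(sampling_rate = sampling_rate,
                 band_gains = band_gains[bands],
                 band_centers = band_centers[bands],
                 band_widths = band_widths[bands],
                 noise_gain = noise_gain,
                 envelope_slope = envelope_slope,
                 envelope_intercept = envelope_intercept,
                 per_band_slopes = per_band_slopes[bands],
                 noise_slope = noise_slope,
                 burst_sd = burst_sd,
                 burst_timescale = burst_timescale,
                 transient_rate = transient_rate,
                 transient_gain = transient_gain,
                 transient_jitter = transient_jitter,
                 transient_freq = transient_freq,
                 transient_width = transient_width,
                 session_jitter_sd = session_jitter_sd,
                 slope_jitter_sd = slope_jitter_sd,
                 amplitude_scale = amplitude_scale,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Linear temperature envelope of a generator
#'
#' @param gen A [generator_config()].
#' @param temp_c Temperature(s), degC.
#' @return `envelope_intercept + envelope_slope * temp_c`.
#' @export
envelope_at <- function(gen, temp_c) {
  gen$envelope_intercept + gen$envelope_slope * temp_c
}

# --- FFT-domain noise shaping -------------------------------------------

# Frequency magnitude (two-sided axis folded to [0, fs/2]) for n samples.
.fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  pmin(k, n - k) * fs / n
}

# Gaussian noise shaped to a raised-cosine band [lo, hi] (transition tw),
# unit RMS. Deterministic under the ambient RNG state.
.band_noise <- function(n, fs, lo, hi, tw = 0.5) {
  fa <- .fft_freqs(n, fs)
  g <- numeric(n)
  g[fa >= lo & fa <= hi] <- 1
  lo_t <- fa > lo - tw & fa < lo
  hi_t <- fa > hi & fa < hi + tw
  g[lo_t] <- 0.5 * (1 - cos(pi * (fa[lo_t] - (lo - tw)) / tw))
  g[hi_t] <- 0.5 * (1 + cos(pi * (fa[hi_t] - hi) / tw))
  x <- stats::rnorm(n)
  y <- Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

# Pink (1/f amplitude spectral density ~ f^(-1/2) in power ... here 1/f power)
# background: PSD proportional to 1/f above f_floor, flat below, zero DC.
.pink_noise <- function(n, fs, f_floor = 0.5) {
  fa <- .fft_freqs(n, fs)
  g <- 1 / sqrt(pmax(fa, f_floor))
  g[1] <- 0
  x <- stats::rnorm(n)
  y <- Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Slow unit-variance Gaussian process (Gaussian spectral envelope with the
# given correlation timescale in seconds).
.slow_noise <- function(n, fs, timescale) {
  fa <- .fft_freqs(n, fs)
  g <- exp(-0.5 * (fa * timescale)^2)
  g[1] <- 0
  x <- stats::rnorm(n)
  y <- Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthesize one temperature-coupled EEG session
#'
#' Generates a single-channel EEG trace over the whole temperature protocol.
#' The output is `amplitude_scale * E(T(t)) * (m(t) * (sum of band oscillators
#' + pink background) + transients)`, where `E` is the linear envelope, `m` a
#' slow log-normal burst modulator, each oscillator is a narrowband Gaussian
#' process scaled by its band gain and per-band temperature slope, and the
#' transients are sparse sharp wavelets whose largest members set the
#' session-wide signal range. Bit-identical output for identical inputs and
#' seed.
#'
#' @param profile A [make_temperature_profile()] result.
#' @param gen A [generator_config()].
#' @param session_id Identifier stored in the recording.
#' @param seed Integer seed; defaults to `gen$seed`.
#'
#' @return An object of class `session_recording`: a list with `eeg` (numeric,
#'   microvolts, of length `round(total_duration * sampling_rate)`),
#'   `sampling_rate`, `temperature` (the profile), `session_id`, `seed`, and
#'   `config`.
#' @export
synthesize_eeg <- function(profile, gen = generator_config(),
                           session_id = "S01", seed = gen$seed) {
  stopifnot(inherits(profile, "temperature_profile"),
            inherits(gen, "generator_config"))
  fs <- gen$sampling_rate
  total <- max(profile$time_s)
  n <- round(total * fs)
  if (n < 1) stop("protocol duration too short for one sample", call. = FALSE)
  tt <- (seq_len(n) - 1) / fs
  Tt <- stats::approx(profile$time_s, profile$temp_c, xout = tt, rule = 2)$y

  env_check <- envelope_at(gen, range(profile$temp_c))
  if (any(env_check <= 0))
    stop("envelope E(T) must stay positive over the protocol's ",
         "temperature range", call. = FALSE)

  .with_seed(seed, {
    # per-session jitter: band gains, and a common heat-sensitivity factor
    gains <- gen$band_gains *
      exp(stats::rnorm(4, 0, gen$session_jitter_sd))
    sens <- exp(stats::rnorm(1, 0, gen$slope_jitter_sd))
    e37 <- envelope_at(gen, 37)
    env <- pmax(e37 + sens * gen$envelope_slope * (Tt - 37), 1e-6)

    core <- numeric(n)
    for (b in names(gen$band_gains)) {
      hw <- gen$band_widths[[b]] / 2
      osc <- .band_noise(n, fs, gen$band_centers[[b]] - hw,
                         gen$band_centers[[b]] + hw)
      mod <- pmax(1 + sens * gen$per_band_slopes[[b]] * (Tt - 37), 0)
      core <- core + gains[[b]] * mod * osc
    }
    if (gen$noise_gain > 0) {
      nmod <- pmax(1 + sens * gen$noise_slope * (Tt - 37), 0)
      core <- core + gen$noise_gain * nmod * .pink_noise(n, fs)
    }
    if (gen$burst_sd > 0) {
      z <- .slow_noise(n, fs, gen$burst_timescale)
      core <- core * exp(gen$burst_sd * z - gen$burst_sd^2 / 2)
    }

    rms <- stats::sd(core)
    if (gen$transient_rate > 0 && rms > 0) {
      n_ev <- stats::rpois(1, gen$transient_rate * total / 60)
      if (n_ev > 0) {
        t0 <- sort(stats::runif(n_ev, 0, total))
        amp <- gen$transient_gain * rms *
          exp(stats::rnorm(n_ev, 0, gen$transient_jitter))
        w <- gen$transient_width
        half <- ceiling(4 * w * fs)
        for (k in seq_len(n_ev)) {
          i0 <- round(t0[k] * fs) + 1L
          idx <- max(1L, i0 - half):min(n, i0 + half)
          dt <- tt[idx] - t0[k]
          core[idx] <- core[idx] +
            amp[k] * exp(-dt^2 / (2 * w^2)) *
            cos(2 * pi * gen$transient_freq * dt)
        }
      }
    }

    eeg <- gen$amplitude_scale * env * core
    structure(list(eeg = eeg, sampling_rate = fs, temperature = profile,
                   session_id = session_id, seed = as.integer(seed),
                   config = gen),
              class = "session_recording")
  })
}

#' Simulate one session (protocol + EEG) in a single call
#'
#' @param protocol A [protocol_config()].
#' @param gen A [generator_config()].
#' @param session_id Identifier for the session.
#' @param seed Integer seed.
#' @return A `session_recording`; see [synthesize_eeg()].
#' @export
simulate_session <- function(protocol = protocol_config(),
                             gen = generator_config(),
                             session_id = "S01", seed = gen$seed) {
  synthesize_eeg(make_temperature_profile(protocol), gen,
                 session_id = session_id, seed = seed)
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> %s: %d samples @ %g Hz (%.1f s), seed %d\n",
              x$session_id, length(x$eeg), x$sampling_rate,
              length(x$eeg) / x$sampling_rate, x$seed))
  invisible(x)
}
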