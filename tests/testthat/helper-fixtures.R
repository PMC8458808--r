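# Small fixtures shared across test files. Everything is generated in code;
# the short protocol keeps per-test synthesis around a second.

# 7-min session: 1 min baseline, 2.5 min ramp (2 C/min), 1 min hold,
# 2.5 min cool-down.
short_protocol <- function(...) {
  protocol_config(baseline_duration = 60, ramp_rate = 2,
                  hold_duration = 60, cooldown_rate = 2, ...)
}

quiet_gen <- function(...) {
  # low-variability generator for sharp numeric checks: no jitter, no
  # transients, no bursts, no per-component temperature slopes
  generator_config(sampling_rate = 500, session_jitter_sd = 0,
                   slope_jitter_sd = 0, transient_rate = 0, burst_sd = 0,
                   per_band_slopes = c(delta = 0, theta = 0, alpha = 0,
                                       beta = 0),
                   noise_slope = 0, ...)
}

# one cached short session per (seed, gen variant) to keep the suite fast
.session_cache <- new.env(parent = emptyenv())
cached_session <- function(seed = 1, gen = generator_config(sampling_rate = 500),
                           key = paste0("default", seed)) {
  if (is.null(.session_cache[[key]]))
    .session_cache[[key]] <- simulate_session(short_protocol(), gen,
                                              session_id = sprintf("S%02d", seed),
                                              seed = seed)
  .session_cache[[key]]
}

# session_recording wrapper around an arbitrary signal, with a flat 37 C
# temperature channel
signal_as_recording <- function(x, fs, session_id = "T01") {
  dur <- length(x) / fs
  profile <- data.frame(time_s = seq(0, ceiling(dur)), temp_c = 37,
                        phase = "baseline")
  class(profile) <- c("temperature_profile", "data.frame")
  structure(list(eeg = x, sampling_rate = fs, temperature = profile,
                 session_id = session_id, seed = NA_integer_, config = NULL),
            class = "session_recording")
}
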