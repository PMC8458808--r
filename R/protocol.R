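#' Configuration of the core-temperature protocol
#'
#' Defines the four-phase heating protocol applied to an anesthetized animal:
#' a constant baseline at `baseline_temp`, a linear ramp at `ramp_rate` up to
#' `peak_temp`, a constant hold at the peak, and a linear cool-down back to
#' baseline. The defaults describe a 25-min session: 5 min at 37 degC, a
#' 0.5 degC/min ramp to 42 degC, 5 min at 42 degC, and a 1 degC/min cool-down.
#'
#' @param baseline_temp Baseline core temperature, degC.
#' @param peak_temp Peak core temperature, degC; must exceed `baseline_temp`.
#' @param baseline_duration Length of the baseline phase, seconds.
#' @param ramp_rate Heating rate, degC per minute (> 0).
#' @param hold_duration Length of the hold phase at `peak_temp`, seconds.
#' @param cooldown_rate Cooling rate, degC per minute (> 0).
#' @param sample_interval Spacing of the emitted temperature samples, seconds.
#'
#' @return An object of class `protocol_config`.
#' @seealso [make_temperature_profile()]
#' @export
#' @examples
#' cfg <- protocol_config()
#' protocol_durations(cfg)$total # 1500 s = 25 min
protocol_config <- function(baseline_temp = 37, peak_temp = 42,
                            baseline_duration = 300, ramp_rate = 0.5,
                            hold_duration = 300, cooldown_rate = 1.0,
                            sample_interval = 1) {
  if (!is.numeric(peak_temp) || !is.numeric(baseline_temp) ||
      peak_temp <= baseline_temp)
    stop("`peak_temp` must exceed `baseline_temp`", call. = FALSE)
  if (ramp_rate <= 0 || cooldown_rate <= 0)
    stop("`ramp_rate` and `cooldown_rate` must be positive (degC/min)",
         call. = FALSE)
  if (baseline_duration < 0 || hold_duration < 0)
    stop("phase durations must be non-negative", call. = FALSE)
  if (sample_interval <= 0)
    stop("`sample_interval` must be positive", call. = FALSE)
  structure(list(baseline_temp = baseline_temp, peak_temp = peak_temp,
                 baseline_duration = baseline_duration, ramp_rate = ramp_rate,
                 hold_duration = hold_duration, cooldown_rate = cooldown_rate,
                 sample_interval = sample_interval),
            class = "protocol_config")
}

#' Phase durations implied by a protocol configuration
#'
#' @param config A [protocol_config()].
#' @return A list with elements `baseline`, `ramp`, `hold`, `cooldown` and
#'   `total`, all in seconds. Ramp and cool-down durations are
#'   `60 * (peak - baseline) / rate`.
#' @export
protocol_durations <- function(config) {
  stopifnot(inherits(config, "protocol_config"))
  span <- config$peak_temp - config$baseline_temp
  ramp <- 60 * span / config$ramp_rate
  cool <- 60 * span / config$cooldown_rate
  list(baseline = config$baseline_duration, ramp = ramp,
       hold = config$hold_duration, cooldown = cool,
       total = config$baseline_duration + ramp + config$hold_duration + cool)
}

#' Build the piecewise-linear core-temperature profile
#'
#' Concatenates the four protocol phases into a sampled temperature time
#' series. Within each phase the temperature is piecewise linear in time;
#' each sample is labelled with its phase. Phase boundaries belong to the
#' later phase, so with a zero-length baseline the first sample is `ramp`.
#'
#' @param config A [protocol_config()].
#' @return A data frame of class `temperature_profile` with columns `time_s`
#'   (monotone increasing, from 0 to the total protocol duration), `temp_c`,
#'   and `phase` (one of `"baseline"`, `"ramp"`, `"hold"`, `"cooldown"`).
#' @export
#' @examples
#' prof <- make_temperature_profile(protocol_config())
#' range(prof$temp_c)     # 37 42
#' max(prof$time_s)       # 1500
make_temperature_profile <- function(config = protocol_config()) {
  stopifnot(inherits(config, "protocol_config"))
  d <- protocol_durations(config)
  b1 <- d$baseline
  b2 <- b1 + d$ramp
  b3 <- b2 + d$hold
  times <- seq(0, d$total, by = config$sample_interval)
  temps <- numeric(length(times))
  phase <- character(length(times))

  i_base <- times < b1
  i_ramp <- times >= b1 & times < b2
  i_hold <- times >= b2 & times < b3
  i_cool <- times >= b3

  temps[i_base] <- config$baseline_temp
  temps[i_ramp] <- config$baseline_temp +
    (times[i_ramp] - b1) * config$ramp_rate / 60
  temps[i_hold] <- config$peak_temp
  temps[i_cool] <- pmax(config$baseline_temp,
                        config$peak_temp -
                          (times[i_cool] - b3) * config$cooldown_rate / 60)
  phase[i_base] <- "baseline"
  phase[i_ramp] <- "ramp"
  phase[i_hold] <- "hold"
  phase[i_cool] <- "cooldown"

  out <- data.frame(time_s = times, temp_c = temps, phase = phase,
                    stringsAsFactors = FALSE)
  class(out) <- c("temperature_profile", "data.frame")
  attr(out, "config") <- config
  out
}
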