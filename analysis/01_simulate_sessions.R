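#!/usr/bin/env Rscript
# Step 1 — simulate the 19-session hyperthermia-EEG study and write it to
# disk in interchange formats (EDF + temperature CSV + YAML manifest).
#
# Each 25-min session: 5 min baseline at 37 C, 0.5 C/min ramp to 42 C,
# 5 min hold, 1 C/min cool-down; single EEG channel at 1 kHz coupled to the
# temperature through the calibrated generator defaults.
#
# Binary session files go under scratch/ (they are reproducible from the
# seed); the manifest records paths, seeds and analysis parameters.

library(thermoEEG)

seed <- 1
outdir <- "scratch/study"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

message("Simulating 19 sessions with the calibrated generator (seed ", seed,
        ") ...")
sessions <- simulate_study(19, protocol_config(), generator_config(),
                           seed = seed)

df <- data.frame(
  session_id = vapply(sessions, function(s) s$session_id, ""),
  eeg_path = file.path(outdir, sprintf("session%02d.edf", 1:19)),
  temp_path = file.path(outdir, sprintf("session%02d_temp.csv", 1:19)),
  seed = vapply(sessions, function(s) s$seed, integer(1)),
  stringsAsFactors = FALSE)

for (i in seq_along(sessions))
  write_session(sessions[[i]], df$eeg_path[i], df$temp_path[i])
write_manifest(df, study_params(), file.path(outdir, "study.yaml"))

dur <- vapply(sessions, function(s) length(s$eeg) / s$sampling_rate,
              numeric(1))
message(sprintf("Wrote %d sessions (%.0f s each) and %s",
                nrow(df), unique(dur), file.path(outdir, "study.yaml")))
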