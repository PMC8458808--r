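# thermoEEG

Hyperthermia depresses the EEG of anesthetized mice: as core temperature is
driven from 37 to 42 °C, the signal envelope shrinks roughly linearly and
normalized power falls across the delta (1–4 Hz), theta (4–8 Hz), alpha
(8–12 Hz) and beta (12–30 Hz) bands. **thermoEEG** implements the full
analysis used to quantify this effect, plus a calibrated synthetic-session
generator, so the pipeline can be developed, tested and benchmarked without
animal recordings (no public dataset exists for this preparation). It is
aimed at electrophysiologists and methods developers who need a tested
reference implementation of this analysis — or temperature-coupled
synthetic EEG with known ground truth.

## The analysis

For each 25-min session (5 min baseline at 37 °C, 0.5 °C/min ramp to
42 °C, 5 min hold, cool-down):

1. bandpass the EEG to 1–50 Hz (zero-phase Butterworth) and min–max
   normalize the whole session to [0, 1];
2. cut into non-overlapping 5-s epochs; round each epoch's mean core
   temperature half-up to an integer °C and discard epochs outside
   37–42 °C;
3. **amplitude**: the maximum peak-to-peak amplitude per epoch,
   `max(x) − min(x)`; mean ± SD per temperature per session, then across
   sessions (n = 19, equal weights); OLS regression of the six
   per-temperature means on temperature, `y = a·T + b` with its R²;
4. **spectra**: Welch PSD per epoch (2-s Hann segments, 50 % overlap),
   band power as the trapezoidal integral over half-open bands `[low,
   high)`, min–max normalized per band across each session's epochs, then
   summarized per temperature and across sessions;
5. **inference**: two-sample permutation tests (statistic
   `|mean(a) − mean(b)|`, two-sided, 20,000 Monte-Carlo iterations with
   add-one smoothing `(b+1)/(m+1)`, or exact enumeration for small
   groups) comparing each temperature against 37 °C.

The synthetic generator couples a delta-dominated anesthesia EEG model
(narrowband band oscillators + 1/f background + sparse sharp transients)
to the temperature profile through a linear envelope `E(T)` with per-band
slopes. Its defaults are calibrated so that the full pipeline on 19
synthetic sessions reproduces the reference summary statistics (mean
normalized amplitude ≈ 0.46 at 37 °C and ≈ 0.34 at 42 °C, slope ≈ −0.025
per °C, mid-scale normalized band powers). See the methods vignette
(`vignettes/thermoeeg-methods.Rmd`) for the model, the calibration
procedure and its limitations.

## Worked example

```r
library(thermoEEG)

# one synthetic session under the default 25-min protocol
rec <- simulate_session(protocol_config(), generator_config(), seed = 1)
ep  <- preprocess_session(rec)          # filter, normalize, 5-s epochs
summarize_session(ep)                   # amplitude mean/SD/n per deg C

# the full 19-session study
sessions <- simulate_study(19, seed = 1)
res <- run_study(sessions, study_params(), seed = 1)
print(res)
```

The report printed by `print(res)` for study seed 1:

```
EEG amplitude vs core temperature
Temperature (C)  Mean     SD       n    p (vs. 37C)
37               0.456    0.062    19   -
38               0.421    0.058    19   0.0810
39               0.390    0.055    19   0.0010
40               0.362    0.050    19   0.0001
41               0.343    0.047    19   0.0000
42               0.330    0.048    19   0.0000

Normalized band power at 37C vs 42C
Band     M37      SD37     M42      SD42     p
delta    0.416    0.047    0.327    0.055    0.0000
theta    0.484    0.055    0.262    0.052    0.0000
alpha    0.486    0.044    0.241    0.064    0.0000
beta     0.727    0.049    0.032    0.013    0.0000

Study regression: y = -0.0255x + 1.3908; R2 = 0.975
Reduction 37 -> 38 C: 7.63% (+/- 3.70, per-session)
Reduction 37 -> 42 C: 27.60% (+/- 4.19, per-session)
```

Reading it: the mean normalized epoch amplitude declines roughly linearly
with temperature — the regression slope says the signal loses ≈ 2.5 % of
the session's normalization range per °C — and the across-session
permutation tests are significant from 39 °C on. The band table shows the
same story per band: normalized power sits mid-scale at 37 °C and drops
substantially by 42 °C (the beta band declines much more strongly in the
synthetic data than real recordings suggest; see the vignette's
limitations section).

## The analysis workflow

Numbered drivers under `analysis/` run the whole study and write tables
under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate_sessions.R` | simulate 19 sessions; write EDF + temperature CSV + YAML manifest |
| `02_calibration_check.R` | verify the shipped generator calibration is a fixed point |
| `03_run_study.R` | run the pipeline; write `table1.csv`, `table2.csv`, `fits.csv`, `tests.csv` |
| `04_permutation_calibration.R` | type-I error and power of the permutation test |

Run them from the repository root, e.g. `Rscript analysis/03_run_study.R`.

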