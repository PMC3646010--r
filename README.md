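# sonarthreat

Acoustic-kinematic analysis of bat echolocation attacks and the defensive
clicking thresholds of sonar-jamming tiger moths.

## The problem

An echolocating bat reveals its stage of attack through its own sonar:
slow *search* calls (7–12 calls/s), an *approach* phase with shrinking
pulse intervals after prey detection, beam-locking onto the target, an
intensity ramp while localizing followed by automatic gain control
(emission intensity reduced so the level at the target stays near
constant), and a *terminal buzz* near 160 calls/s. An eared moth that
jams bat sonar must decide from two cues — pulse interval and received
intensity — whether *it* is the target (a real threat) or whether the bat
is attacking a neighbor (a false threat), and click at the right moment.

`sonarthreat` provides, for researchers in sensory ecology and
bioacoustics:

* **The calibration chain** from a level recorded on a microphone tethered
  near a moth to the bat's source level and the level at the moth:

  `L_mic = L_rec + C_mic(f, θ)`,
  `SL = L_mic + 20·log10(d_mic/0.1) + α(f)·(d_mic − 0.1) + 3 dB`,
  `L_moth = SL − 20·log10(d_moth/0.1) − α(f)·(d_moth − 0.1)`,

  with microphone frequency/directionality corrections, ISO 9613-1
  atmospheric absorption, and phase-dependent sonar-beam directivity
  (−6 dB full widths: 80° search/approach, 180° buzz).
* **3-D kinematics**: quintic smoothing splines for videogrammetry tracks
  (GCV-selected smoothing, analytic velocities), approach angles, and the
  wand calibration-error check.
* **A generative attack model** (phase schedule, localization ramp,
  automatic gain control holding 95.3 dB peSPL at the target) and a
  seeded synthetic-scenario generator for real threats, false threats and
  non-attack passes, plus the laboratory 5 dB/s ramp playbacks
  (70–120 dB, nine pulse intervals from 4–100 ms).
* **Decision analyses**: clicking-threshold extraction from ramps,
  per-phase mean thresholds, two-class Gaussian (quadratic discriminant)
  optimal threat boundaries at posterior p = 0.5 / 0.75 over
  (log10 pulse interval, intensity), ROC/AUR separability by pairwise
  enumeration, and forward-stepwise discriminant classification of
  clicking vs non-clicking passes with PPV/NPV.

## Worked example

Simulate a real attack, forward-model what the tethered microphone
records (1 dB measurement noise), and run the calibration inverse:

```r
library(sonarthreat)
scn <- make_attack_scenario("real", seed = 42)
scn
#> <attack_scenario> real threat: 64 calls over 1.40 s (seed 42)

rl  <- simulate_received_levels(scn, noise_sd_dB = 1, seed = 42)
cal <- calibrate_received_levels(rl, scn$mic, scn$env)
tail(cal[, c("time_s", "pulse_interval_ms", "phase", "d_bat_moth_m",
             "est_source_level_db", "est_spl_at_moth_db")], 3)
#>  time_s pulse_interval_ms phase d_bat_moth_m est_source_level_db est_spl_at_moth_db
#>   1.377             6.202  buzz        0.206             103.408             96.980
#>   1.383             6.251  buzz        0.171             101.863             97.116
#>   1.390             6.223  buzz        0.136             100.312             97.617
```

The final calls are terminal buzz (pulse intervals ≈ 6 ms); the estimated
source level falls as the bat closes in (automatic gain control) while
the estimated level at the moth stays near the 95.3 dB setpoint.

Run the full pipeline on an ensemble with the field design (5 real, 9
false attacks) and ask how well each echolocation phase separates real
from false threats:

```r
report <- run_pipeline(run_config(seed = 1, n_real = 5, n_false = 9,
                                  noise_sd_dB = 1))
sapply(report$roc, function(r) round(r$aur, 3))
#>   search approach     buzz
#>    0.684    0.950    0.988

round(report$curves$p0.5$threshold_dB, 1)   # optimal p = 0.5 curve, 4-100 ms
#> [1] 95.7 92.0 88.5 85.1 82.4 79.7 77.8 75.8 74.3
```

Search-phase calls barely separate the two conditions (AUR ≈ 0.68) while
approach and buzz calls separate them strongly — the information a moth
needs to identify a real threat first exists in early approach phase. The
threshold curve gives, per pulse interval, the lowest intensity at which
a call is more likely from a real than a false threat.

A thin command-line wrapper over these functions ships at
`inst/scripts/sonarthreat-cli.R` (subcommands `simulate`, `calibrate`,
`ramp`, `analyze`, `run`).

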