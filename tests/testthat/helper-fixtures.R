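# Shared fixtures: small seeded scenarios and reference values computed
# from independent oracles (frozen where noted).

ENV_REF <- environment_conditions(20, 50)

# ISO 9613-1 pure-tone absorption, frozen from an independently coded
# evaluation of the published analytic form (dB/m)
ALPHA_REF <- list("40_20_50" = 1.3182, "20_20_50" = 0.5242,
                  "60_25_30" = 1.8989)

quick_scenario <- function(type = "real", seed = 1L) {
  make_attack_scenario(type, scenario_params(), seed = seed)
}

# calibrated table for one scenario under the stated forward conventions
calibrated_scenario <- function(scn, noise_sd_dB = 0, idealized = FALSE,
                                seed = 1L) {
  rl <- simulate_received_levels(scn, noise_sd_dB = noise_sd_dB,
                                 idealized = idealized, seed = seed)
  calibrate_received_levels(rl, scn$mic, scn$env)
}

# a well-separated two-class Gaussian threat model whose p = 0.75 curve
# exists at every ramp pulse interval (equal covariances by construction)
separated_model <- function(delta_db = 15, seed = 42L) {
  set.seed(seed)
  n <- 200
  lp <- runif(n, log10(4), log10(100))
  base <- 82 + 6 * (lp - 1) + rnorm(n, 0, 3)
  real <- threat_points(10^lp, base + delta_db)
  false <- threat_points(10^lp, base)  # identical spread, shifted mean
  fit_discrimination(real, false)
}
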