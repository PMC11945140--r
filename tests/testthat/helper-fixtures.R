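# Shared fixtures: randomized scenario configs for property tests and the
# calibration fixture with identifiable stress structure.

# a randomized but always-valid scenario; duration/temperature kept so the
# season's thermal time comfortably exceeds the default gdd_m = 256
random_scenario_cfg <- function(seed) {
  set.seed(seed)
  windows <- NULL
  if (stats::runif(1) < 0.5) {
    s <- sample(5:20, 1)
    windows <- data.frame(start = s, end = s + sample(3:10, 1),
                          water_ratio = stats::runif(1, 0.3, 1),
                          n_depression = stats::runif(1, 0, 0.6))
  }
  scenario_config(
    duration = sample(35:60, 1),
    topwt_at_anthesis = stats::runif(1, 4000, 7000),
    topwt_final = stats::runif(1, 9000, 15000),
    growth_midpoint = sample(12:22, 1),
    growth_rate = stats::runif(1, 0.12, 0.25),
    remob_onset_day = sample(14:25, 1),
    remobilization_fraction = stats::runif(1, 0.1, 0.4),
    gna_final = stats::runif(1, 50, 100),
    gna_rate = stats::runif(1, 0.15, 0.3),
    gna_midpoint = sample(12:22, 1),
    temp_mean = stats::runif(1, 21, 26),
    temp_amplitude = stats::runif(1, 0, 3),
    temp_noise_sd = stats::runif(1, 0, 1),
    stress_windows = windows,
    sp = stats::runif(1, 2e5, 6e5),
    ng = stats::runif(1, 1000, 3000),
    seed = seed)
}

# fixture with distinct stress levels at sampled days so that (npf0, delta)
# and (alpha, beta) are identifiable from sparse observations
calibration_scenario <- function(seed = 11L) {
  scenario_config(
    stress_windows = data.frame(start = c(10, 25), end = c(18, 32),
                                water_ratio = c(0.6, 1),
                                n_depression = c(0, 0.35)),
    temp_noise_sd = 0.5, seed = seed)
}

table3_protein <- function() protein_params(npf0 = 5.83, delta = 0.18)
table3_starch <- function() starch_params()
table3_partition <- function() partition_params(alpha = 0.4, beta = 2.1)
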