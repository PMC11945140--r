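# Seeded synthetic crop-state generator emulating the daily outputs of a
# process-based cereal growth model over grain filling, plus a sparse noisy
# observation sampler. Every downstream stage is testable on these
# trajectories without a crop-model run or field data.

#' Scenario configuration for the synthetic generator
#'
#' Defaults describe a plausible irrigated foxtail millet grain-filling
#' season: 45 days anthesis to maturity, aboveground biomass rising
#' logistically from 6 to 12 t/ha, about 30 percent of the anthesis
#' vegetative dry weight remobilized to grains after the onset day, grain
#' nitrogen accumulating logistically to 80 kg/ha, and a late-summer
#' temperature course around 22 degrees C.
#'
#' @param duration days anthesis to maturity; >= 3.
#' @param topwt_at_anthesis,topwt_final aboveground dry weight anchors,
#'   kg/ha.
#' @param growth_midpoint,growth_rate logistic biomass parameters
#'   (day, 1/day).
#' @param remob_onset_day day the vegetative dry weight starts declining;
#'   choose consistently with the `gdd_m` used in simulation when building
#'   calibration fixtures.
#' @param remobilization_fraction fraction of the onset-day vegetative dry
#'   weight transferred to grains by maturity, in `[0, 1]`.
#' @param gna_final,gna_rate,gna_midpoint logistic grain-N parameters
#'   (kg/ha, 1/day, day).
#' @param temp_mean,temp_amplitude,temp_noise_sd daily mean temperature
#'   course, degrees C: mean plus a seasonal half-sine of the given
#'   amplitude plus Gaussian noise.
#' @param stress_windows data.frame with columns `start, end, water_ratio,
#'   n_depression`: inside `[start, end]` the transpiration ratio ta/tp is
#'   `water_ratio` and the nitrogen-stress factor is depressed to
#'   `1 - n_depression`; NULL for a stress-free scenario.
#' @param sp panicle number, spikes/ha.
#' @param ng grain number, grains/spike.
#' @param cnp0,mnp0 anchor critical and minimum plant N concentrations
#'   (fractions) at anthesis; both decline smoothly toward maturity with
#'   `cnp > mnp` throughout.
#' @param gdd_base base temperature for thermal time, degrees C.
#' @param seed integer seed; identical seeds give identical series.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(duration = 45,
                            topwt_at_anthesis = 6000, topwt_final = 12000,
                            growth_midpoint = 18, growth_rate = 0.18,
                            remob_onset_day = 21,
                            remobilization_fraction = 0.3,
                            gna_final = 80, gna_rate = 0.22,
                            gna_midpoint = 18,
                            temp_mean = 22, temp_amplitude = 2,
                            temp_noise_sd = 0.5,
                            stress_windows = NULL,
                            sp = 4e5, ng = 2000,
                            cnp0 = 0.02, mnp0 = 0.008,
                            gdd_base = 10, seed = 1L) {
  cfg <- structure(as.list(environment()), class = "scenario_config")
  validate_scenario_config(cfg)
  cfg
}

validate_scenario_config <- function(cfg) {
  with(cfg, {
    stopifnot(duration >= 3,
              topwt_at_anthesis >= 0, topwt_final >= topwt_at_anthesis,
              remobilization_fraction >= 0, remobilization_fraction <= 1,
              remob_onset_day >= 0, remob_onset_day <= duration,
              gna_final >= 0, temp_noise_sd >= 0,
              sp > 0, ng > 0, cnp0 > mnp0, mnp0 > 0, gdd_base >= 0)
  })
  if (!is.null(cfg$stress_windows)) {
    sw <- cfg$stress_windows
    stopifnot(is.data.frame(sw),
              all(c("start", "end", "water_ratio", "n_depression") %in%
                    names(sw)),
              all(sw$start >= 0), all(sw$end <= cfg$duration),
              all(sw$start <= sw$end),
              all(sw$water_ratio >= 0 & sw$water_ratio <= 1),
              all(sw$n_depression >= 0 & sw$n_depression <= 1))
  }
  invisible(cfg)
}

# run code with a private, seeded RNG stream; the caller's RNG state is
# untouched
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic crop-state series
#'
#' Daily trajectories from anthesis (day 0) to maturity: logistic
#' aboveground biomass; vegetative dry weight equal to the total before
#' the remobilization onset, then declining along a smooth half-cosine by
#' the configured fraction of its onset value (so the grain-mass proxy
#' `topwt - vwt` is nondecreasing); logistic grain nitrogen; a seasonal
#' sinusoid-plus-noise temperature course; unit transpiration ratio and
#' unstressed plant nitrogen outside the configured stress windows.
#' Identical seeds give identical series.
#'
#' @param cfg a [scenario_config()].
#' @return A validated [crop_state_series()].
#' @export
generate_scenario <- function(cfg = scenario_config()) {
  stopifnot(inherits(cfg, "scenario_config"))
  validate_scenario_config(cfg)
  day <- 0:cfg$duration
  n <- length(day)

  with_local_seed(cfg$seed, {
    # temperature: seasonal half-sine bump plus noise
    tavg <- cfg$temp_mean +
      cfg$temp_amplitude * sin(pi * day / cfg$duration) +
      stats::rnorm(n, 0, cfg$temp_noise_sd)

    # aboveground biomass: plain logistic between the anchors
    logis <- function(d) {
      1 / (1 + exp(-cfg$growth_rate * (d - cfg$growth_midpoint)))
    }
    topwt <- cfg$topwt_at_anthesis +
      (cfg$topwt_final - cfg$topwt_at_anthesis) * logis(day)

    # vegetative dry weight: equals topwt pre-onset, then sheds the
    # configured fraction of its onset value along a half-cosine
    onset <- cfg$remob_onset_day
    vwt <- topwt
    post <- day >= onset
    if (any(post) && onset < cfg$duration) {
      v_onset <- cfg$topwt_at_anthesis +
        (cfg$topwt_final - cfg$topwt_at_anthesis) * logis(onset)
      s <- (1 - cos(pi * (day[post] - onset) /
                      (cfg$duration - onset))) / 2
      vwt[post] <- v_onset - cfg$remobilization_fraction * v_onset * s
    }

    # grain nitrogen: normalized logistic, exactly 0 at anthesis
    gl <- function(d) 1 / (1 + exp(-cfg$gna_rate * (d - cfg$gna_midpoint)))
    gna <- cfg$gna_final * (gl(day) - gl(0)) / (gl(cfg$duration) - gl(0))

    # transpiration and plant N status; stress windows override
    tp <- rep(5, n)
    water_ratio <- rep(1, n)
    n_dep <- rep(0, n)
    if (!is.null(cfg$stress_windows)) {
      for (k in seq_len(nrow(cfg$stress_windows))) {
        w <- cfg$stress_windows[k, ]
        in_w <- day >= w$start & day <= w$end
        water_ratio[in_w] <- pmin(water_ratio[in_w], w$water_ratio)
        n_dep[in_w] <- pmax(n_dep[in_w], w$n_depression)
      }
    }
    ta <- tp * water_ratio

    # smooth nitrogen dilution: cnp and mnp decline, cnp > mnp throughout;
    # unstressed plants sit 5% above critical; depression d places the
    # plant at fn = 1 - d on the linear ramp
    frac <- day / cfg$duration
    cnp <- cfg$cnp0 * (1 - 0.4 * frac)
    mnp <- cfg$mnp0 * (1 - 0.2 * frac)
    anp <- ifelse(n_dep > 0,
                  mnp + (1 - n_dep) * (cnp - mnp),
                  1.05 * cnp)

    days <- data.frame(day_index = day, tavg = tavg, topwt = topwt,
                       vwt = vwt, gna = gna, ta = ta, tp = tp,
                       anp = anp, cnp = cnp, mnp = mnp)
    days$gdd <- compute_gdd(days$tavg, cfg$gdd_base)
    crop_state_series(days, sp = cfg$sp, ng = cfg$ng,
                      scenario_meta = list(generator = "synthetic",
                                           seed = cfg$seed))
  })
}

#' Sample sparse noisy observations from a simulated series
#'
#' Emulates destructive field sampling at regular intervals from anthesis,
#' always including the final (maturity) day. Each sampled value is the
#' simulated truth times `1 + N(0, noise_cv)`, floored at 0; `noise_cv = 0`
#' returns the truth exactly. The nominal standard deviation
#' `truth * noise_cv` is reported alongside.
#'
#' @param qs a quality series (from [simulate_quality()]) or any
#'   data.frame with `day_index` and the requested variable's column; for
#'   `GNA`, pass the `days` table of a [crop_state_series()].
#' @param variable one of `"GPA", "GSA", "GASA", "GAPA", "GNA"`.
#' @param sampling_interval days between samples (field practice: 7-10).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @return Object of class `observation_set`: list with `variable` and
#'   `samples`, a data.frame `day_index, value, sd`.
#' @export
make_observations <- function(qs, variable, sampling_interval = 7,
                              noise_cv = 0, seed = 1L) {
  stopifnot(is.data.frame(qs), nrow(qs) > 0, noise_cv >= 0,
            sampling_interval >= 1)
  variable <- toupper(variable)
  col <- c(GPA = "gpa", GSA = "gsa", GASA = "gasa", GAPA = "gapa",
           GNA = "gna")[variable]
  if (is.na(col) || !col %in% names(qs)) {
    stop("unknown or unavailable observation variable: ", variable)
  }
  last <- max(qs$day_index)
  sample_days <- seq(0, last, by = sampling_interval)
  if (sample_days[length(sample_days)] != last) {
    sample_days <- c(sample_days, last)
  }
  truth <- qs[[col]][match(sample_days, qs$day_index)]
  value <- with_local_seed(seed, {
    pmax(0, truth * (1 + stats::rnorm(length(truth), 0, noise_cv)))
  })
  structure(list(variable = variable,
                 samples = data.frame(day_index = sample_days,
                                      value = value,
                                      sd = truth * noise_cv)),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("<observation_set> %s, %d samples on days %s\n", x$variable,
              nrow(x$samples),
              paste(x$samples$day_index, collapse = ", ")))
  invisible(x)
}

#' Write an observation set to CSV (`day_index,value,sd`)
#' @param obs an [make_observations()] result.
#' @param path output file path.
#' @export
write_observations_csv <- function(obs, path) {
  stopifnot(inherits(obs, "observation_set"))
  utils::write.csv(format(obs$samples, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
}

#' Read an observation set from CSV
#' @param path CSV with columns `day_index,value,sd`.
#' @param variable variable name to attach.
#' @return An `observation_set`.
#' @export
read_observations_csv <- function(path, variable) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  stopifnot(all(c("day_index", "value") %in% names(df)))
  if (!"sd" %in% names(df)) df$sd <- NA_real_
  structure(list(variable = toupper(variable),
                 samples = df[, c("day_index", "value", "sd")]),
            class = "observation_set")
}
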