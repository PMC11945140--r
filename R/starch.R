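# Grain-starch module: per-grain Michaelis-Menten starch synthesis limited
# by enzyme activity (thermal-time lifecycle, cardinal temperatures, water
# and nitrogen stress), carbon supply from current photosynthesis and
# vegetative remobilization, and amylose/amylopectin partitioning.

#' Grain-starch module parameters
#'
#' Defaults are the calibrated values for foxtail millet. `gdd_m` is the
#' thermal time from anthesis to peak grain synthetic amylase activity; it
#' also marks the onset of assimilate remobilization from vegetative
#' organs. Cardinal temperatures bound the temperature response of starch
#' formation (minimum, optimal-lower, optimal-upper, maximum).
#'
#' @param igsa0 initial starch content per grain, mg; >= 0.
#' @param istr_m maximum starch accumulation rate per grain, mg/day; > 0.
#' @param km Michaelis constant, mg per grain; > 0.
#' @param gdd_m thermal time anthesis to peak amylase activity,
#'   degree-days; > 0.
#' @param gamma sensitivity of amylase activity to thermal-time
#'   accumulation, 1/(degree-day); > 0.
#' @param tb,tol,toh,tm cardinal temperatures, degrees C, with
#'   `tb < tol <= toh < tm`.
#' @param cap_rate_to_supply if TRUE, additionally cap the daily per-grain
#'   rate at the day's available carbon (`istr <= gca`); default FALSE
#'   (pure Michaelis-Menten kinetics).
#' @return Object of class `starch_params`.
#' @export
starch_params <- function(igsa0 = 0.1, istr_m = 1.2, km = 0.7,
                          gdd_m = 256, gamma = 0.002,
                          tb = 7, tol = 22, toh = 27, tm = 60,
                          cap_rate_to_supply = FALSE) {
  stopifnot(igsa0 >= 0, istr_m > 0, km > 0, gdd_m > 0, gamma > 0)
  if (!(tb < tol && tol <= toh && toh < tm)) {
    stop("cardinal temperatures must satisfy tb < tol <= toh < tm")
  }
  structure(list(igsa0 = igsa0, istr_m = istr_m, km = km, gdd_m = gdd_m,
                 gamma = gamma, tb = tb, tol = tol, toh = toh, tm = tm,
                 cap_rate_to_supply = isTRUE(cap_rate_to_supply)),
            class = "starch_params")
}

#' Amylose-partition parameters
#'
#' The amylose share of total starch grows with the natural logarithm of
#' accumulated thermal time, scaled by `alpha`, offset by `beta`, and
#' damped by nitrogen stress.
#'
#' @param alpha scaling factor on `ln(gdd)`, dimensionless; >= 0.
#' @param beta baseline correction, dimensionless.
#' @return Object of class `partition_params`.
#' @export
partition_params <- function(alpha = 0.4, beta = 2.1) {
  stopifnot(alpha >= 0)
  structure(list(alpha = alpha, beta = beta), class = "partition_params")
}

#' Daily carbon supply to the grains
#'
#' Before the remobilization onset (accumulated thermal time below
#' `gdd_m`) grains receive only current photosynthate:
#' `gcp = dTOPWT - dVWT`, `gct = 0`. From the onset on, all new
#' aboveground growth goes to grains (`gcp = dTOPWT`) plus the decline of
#' vegetative dry weight (`gct = VWT[i-1] - VWT[i]`). Both fluxes are
#' floored at 0 (senescence can drive the raw differences negative; the
#' synthesis kinetics need a nonnegative substrate); the raw values are
#' retained in `gcp_raw`/`gct_raw`. The per-grain supply converts canopy
#' flux to mg per grain: `gca = 1e6 * (gcp + gct) / (sp * ng)`.
#'
#' @param series a [crop_state_series()].
#' @param gdd_m remobilization-onset thermal time, degree-days.
#' @return data.frame with columns `day_index, gcp, gct, gca, gcp_raw,
#'   gct_raw` (kg/ha except `gca` in mg per grain); day 0 rows are 0.
#' @export
carbon_supply <- function(series, gdd_m = starch_params()$gdd_m) {
  stopifnot(inherits(series, "crop_state_series"))
  if (series$sp * series$ng <= 0) stop("sp * ng must be positive")
  d <- series$days
  n <- nrow(d)
  d_top <- c(0, diff(d$topwt))
  d_vwt <- c(0, diff(d$vwt))
  pre <- d$gdd < gdd_m
  gcp_raw <- ifelse(pre, d_top - d_vwt, d_top)
  gct_raw <- ifelse(pre, 0, -d_vwt)
  gcp_raw[1] <- 0
  gct_raw[1] <- 0
  gcp <- pmax(0, gcp_raw)
  gct <- pmax(0, gct_raw)
  gca <- 1e6 * (gcp + gct) / (series$sp * series$ng)
  data.frame(day_index = d$day_index, gcp = gcp, gct = gct, gca = gca,
             gcp_raw = gcp_raw, gct_raw = gct_raw)
}

#' Lifecycle (thermal-time) factor of amylase activity
#'
#' Enzyme activity rises with accumulated thermal time after anthesis,
#' peaks at `gdd_m` with value 1, and declines linearly to 0 at maturity:
#' exponential-modulated rise `(gdd/gdd_m) * exp(gamma * (gdd_m - gdd))`
#' for `gdd <= gdd_m`, then `(gdd_am - gdd) / (gdd_am - gdd_m)`. Clamped
#' to `[0, 1]` (inert for the calibrated parameters, where
#' `gamma * gdd_m < 1`).
#'
#' @param gdd accumulated thermal time, degree-days; in `[0, gdd_am]`.
#' @param gdd_m peak-activity thermal time, degree-days.
#' @param gamma sensitivity coefficient, 1/(degree-day).
#' @param gdd_am anthesis-to-maturity thermal time, degree-days;
#'   must exceed `gdd_m`.
#' @return Activity factor in `[0, 1]`. Vectorized over `gdd`.
#' @export
lifecycle_factor <- function(gdd, gdd_m, gamma, gdd_am) {
  if (gdd_m >= gdd_am) stop("gdd_m must be smaller than gdd_am")
  f <- ifelse(gdd <= gdd_m,
              (gdd / gdd_m) * exp(gamma * (gdd_m - gdd)),
              (gdd_am - gdd) / (gdd_am - gdd_m))
  pmin(1, pmax(0, f))
}

#' Cardinal-temperature factor of starch formation
#'
#' Sine-shaped rise from the minimum temperature `tb` to the lower optimum
#' `tol`, a plateau at 1 up to the upper optimum `toh`, a sine-shaped fall
#' to the maximum `tm`, and 0 outside `[tb, tm]`; continuous at all four
#' breakpoints.
#'
#' @param t daily mean air temperature, degrees C.
#' @param params a [starch_params()] supplying the cardinal temperatures.
#' @return Temperature factor in `[0, 1]`. Vectorized over `t`.
#' @export
temperature_factor <- function(t, params = starch_params()) {
  tb <- params$tb; tol <- params$tol; toh <- params$toh; tm <- params$tm
  if (!(tb < tol && tol <= toh && toh < tm)) {
    stop("cardinal temperatures must satisfy tb < tol <= toh < tm")
  }
  f <- numeric(length(t))
  rise <- t >= tb & t < tol
  flat <- t >= tol & t < toh
  fall <- t >= toh & t <= tm
  f[rise] <- sin((t[rise] - tb) / (tol - tb) * pi / 2)
  f[flat] <- 1
  f[fall] <- sin((tm - t[fall]) / (tm - toh) * pi / 2)
  f
}

#' Enzyme-activity limiting factor
#'
#' Product of the lifecycle, temperature, water-stress and nitrogen-stress
#' factors; each must lie in `[0, 1]`, so the product does too.
#'
#' @param f_gdd,f_t,fw,fn component factors, each in `[0, 1]`.
#' @return Activity factor in `[0, 1]`. Vectorized.
#' @export
enzyme_activity <- function(f_gdd, f_t, fw, fn) {
  for (v in list(f_gdd, f_t, fw, fn)) {
    if (any(v < 0 | v > 1)) stop("activity factors must lie in [0, 1]")
  }
  f_gdd * f_t * fw * fn
}

#' Per-grain starch accumulation rate
#'
#' Michaelis-Menten kinetics in the available carbon, scaled by enzyme
#' activity: `istr = istr_m * eact * gca / (km + gca)`. Bounded above by
#' `istr_m`; optionally also by the day's supply (`istr <= gca`) when the
#' mass-balance cap is enabled.
#'
#' @param gca available carbon per grain, mg; >= 0.
#' @param eact enzyme-activity factor in `[0, 1]`.
#' @param istr_m maximum rate, mg/day.
#' @param km Michaelis constant, mg.
#' @param cap_rate_to_supply cap `istr` at `gca` (default FALSE).
#' @return Rate in mg/day per grain. Vectorized.
#' @examples
#' starch_rate(0.7, 1)  # half-saturation: 0.6 with the defaults
#' @export
starch_rate <- function(gca, eact, istr_m = 1.2, km = 0.7,
                        cap_rate_to_supply = FALSE) {
  if (any(gca < 0)) stop("available carbon must be nonnegative")
  if (any(eact < 0 | eact > 1)) stop("eact must lie in [0, 1]")
  istr <- istr_m * eact * gca / (km + gca)
  if (isTRUE(cap_rate_to_supply)) istr <- pmin(istr, gca)
  istr
}

#' Amylose share of total starch
#'
#' `ra = (alpha * ln(gdd) - beta) * fn`, clamped to `[0, 1]` and defined
#' as 0 at `gdd = 0` (anthesis). Nitrogen stress (`fn < 1`) lowers the
#' amylose share.
#'
#' @param gdd accumulated thermal time, degree-days; >= 0.
#' @param fn nitrogen-stress factor in `[0, 1]`.
#' @param pparams a [partition_params()].
#' @return Amylose fraction in `[0, 1]`. Vectorized.
#' @export
amylose_ratio <- function(gdd, fn, pparams = partition_params()) {
  if (any(gdd < 0)) stop("gdd must be nonnegative")
  if (any(fn < 0 | fn > 1)) stop("fn must lie in [0, 1]")
  raw <- ifelse(gdd > 0, (pparams$alpha * log(gdd) - pparams$beta) * fn, 0)
  pmin(1, pmax(0, raw))
}

#' Simulate daily grain quality from a crop-state series
#'
#' Runs the full daily chain from anthesis (day 0) to maturity: stress
#' factors, nitrogen-to-protein conversion and protein accumulation,
#' carbon supply, enzyme-activity limitation, Michaelis-Menten starch
#' synthesis per grain, canopy scale-up `gsa = sp * ng * igsa * 1e-6`, and
#' the amylose/amylopectin split `gasa = gsa * ra`, `gapa = gsa * (1 - ra)`.
#' Per-grain starch integrates the daily rate: `igsa[0] = igsa0`,
#' `igsa[i] = igsa[i-1] + istr[i]`.
#'
#' @param series a [crop_state_series()].
#' @param pparams a [protein_params()].
#' @param sparams a [starch_params()].
#' @param partition a [partition_params()].
#' @return data.frame of class `quality_series` with the canonical columns
#'   `day_index, gdd, fw, fn, npf, gpa, gcp, gct, gca, f_gdd, f_t, eact,
#'   istr, igsa, gsa, ra, gasa, gapa`; attributes `sp` and `ng` carry the
#'   scenario scalars.
#' @export
simulate_quality <- function(series,
                             pparams = protein_params(),
                             sparams = starch_params(),
                             partition = partition_params()) {
  stopifnot(inherits(series, "crop_state_series"))
  if (series$gdd_am <= sparams$gdd_m) {
    stop("gdd_am must exceed gdd_m (maturity after peak amylase activity)")
  }
  d <- series$days
  prot <- protein_accumulation(series, pparams)
  supply <- carbon_supply(series, sparams$gdd_m)
  f_gdd <- lifecycle_factor(d$gdd, sparams$gdd_m, sparams$gamma,
                            series$gdd_am)
  f_t <- temperature_factor(d$tavg, sparams)
  eact <- enzyme_activity(f_gdd, f_t, prot$fw, prot$fn)
  istr <- starch_rate(supply$gca, eact, sparams$istr_m, sparams$km,
                      sparams$cap_rate_to_supply)
  igsa <- sparams$igsa0 + cumsum(istr)  # istr[day 0] = 0, so igsa[0] = igsa0
  gsa <- series$sp * series$ng * igsa * 1e-6
  ra <- amylose_ratio(d$gdd, prot$fn, partition)
  gasa <- gsa * ra
  gapa <- gsa * (1 - ra)
  qs <- data.frame(day_index = d$day_index, gdd = d$gdd,
                   fw = prot$fw, fn = prot$fn, npf = prot$npf,
                   gpa = prot$gpa,
                   gcp = supply$gcp, gct = supply$gct, gca = supply$gca,
                   f_gdd = f_gdd, f_t = f_t, eact = eact,
                   istr = istr, igsa = igsa, gsa = gsa,
                   ra = ra, gasa = gasa, gapa = gapa)
  attr(qs, "sp") <- series$sp
  attr(qs, "ng") <- series$ng
  class(qs) <- c("quality_series", "data.frame")
  qs
}

#' Simulate the grain-starch module
#'
#' Convenience wrapper around [simulate_quality()] for callers interested
#' only in the starch chain; the protein columns are computed with the
#' default calibrated protein parameters.
#'
#' @param series a [crop_state_series()].
#' @param sparams a [starch_params()].
#' @param pparams a [partition_params()] (amylose partition).
#' @return Quality series, as [simulate_quality()].
#' @export
simulate_starch <- function(series, sparams = starch_params(),
                            pparams = partition_params()) {
  simulate_quality(series, sparams = sparams, partition = pparams)
}
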