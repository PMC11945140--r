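test_that("carbon supply switches from current photosynthate to remobilization", {
  # two-day micro-series around the onset, built directly
  mk <- function(topwt, vwt, gdd) {
    d <- data.frame(day_index = seq_along(topwt) - 1, tavg = 22,
                    topwt = topwt, vwt = vwt, gna = 0, ta = 5, tp = 5,
                    anp = 0.021, cnp = 0.02, mnp = 0.008, gdd = gdd)
    crop_state_series(d, sp = 4e5, ng = 2000, check = FALSE)
  }
  # pre-onset day: gcp = dTOPWT - dVWT, gct = 0
  pre <- carbon_supply(mk(c(8000, 8150), c(7800, 7900), c(0, 100)),
                       gdd_m = 256)
  expect_equal(pre$gcp[2], 50)
  expect_equal(pre$gct[2], 0)
  # post-onset day: gcp = dTOPWT, gct = -dVWT
  post <- carbon_supply(mk(c(8000, 8120), c(7800, 7770), c(250, 270)),
                        gdd_m = 256)
  expect_equal(post$gcp[2], 120)
  expect_equal(post$gct[2], 30)
  # unit conversion: 80 kg/ha over 8e8 grains is 0.1 mg per grain
  conv <- carbon_supply(mk(c(8000, 8080), c(7800, 7800), c(250, 270)),
                        gdd_m = 256)
  expect_equal(conv$gca[2], 0.1)
  # day 0 carries no flux
  expect_equal(pre$gcp[1], 0)
  expect_equal(pre$gca[1], 0)
  # senescing biomass is floored at zero, raw values kept
  sen <- carbon_supply(mk(c(8000, 7950), c(7800, 7790), c(100, 120)),
                       gdd_m = 256)
  expect_equal(sen$gcp[2], 0)
  expect_equal(sen$gcp_raw[2], -40)
})

test_that("lifecycle factor peaks at one and declines linearly to maturity", {
  expect_equal(lifecycle_factor(256, 256, 0.002, 600), 1)
  expect_equal(lifecycle_factor(128, 256, 0.002, 600), 0.5 * exp(0.256))
  expect_equal(lifecycle_factor(600, 256, 0.002, 600), 0)
  expect_equal(lifecycle_factor(0, 256, 0.002, 600), 0)
  expect_error(lifecycle_factor(100, 600, 0.002, 600), "gdd_am")
  # both branches meet at the peak
  eps <- 1e-8
  expect_lt(abs(lifecycle_factor(256 - eps, 256, 0.002, 600) -
                  lifecycle_factor(256 + eps, 256, 0.002, 600)), 1e-7)
  # with the calibrated parameters the [0,1] clamp is inert below the peak
  g <- seq(0, 256, length.out = 500)
  raw <- (g / 256) * exp(0.002 * (256 - g))
  expect_true(all(raw <= 1 + 1e-12))
  expect_equal(lifecycle_factor(g, 256, 0.002, 600), raw)
})

test_that("temperature factor follows the cardinal-temperature sine plateau", {
  p <- starch_params()
  expect_equal(temperature_factor(25, p), 1)
  expect_equal(temperature_factor(14.5, p), sin(pi / 4))
  expect_equal(temperature_factor(5, p), 0)
  expect_equal(temperature_factor(65, p), 0)
  # continuity at the four breakpoints (one-sided limits)
  eps <- 1e-9
  for (tc in c(7, 22, 27, 60)) {
    lo <- temperature_factor(tc - eps, p)
    hi <- temperature_factor(tc + eps, p)
    expect_lt(abs(lo - temperature_factor(tc, p)), 1e-8)
    expect_lt(abs(hi - temperature_factor(tc, p)), 1e-8)
  }
  expect_error(starch_params(tb = 30, tol = 22), "cardinal")
})

test_that("enzyme activity is the product of its four factors", {
  expect_equal(enzyme_activity(1, 1, 1, 1), 1)
  expect_equal(enzyme_activity(1, 1, 0.8, 0.5), 0.4)
  expect_equal(enzyme_activity(0, 1, 1, 1), 0)
  expect_error(enzyme_activity(1.5, 1, 1, 1), "\\[0, 1\\]")
})

test_that("starch rate is Michaelis-Menten in the carbon supply", {
  expect_equal(starch_rate(0.7, 1), 0.6)  # half-saturation
  expect_equal(starch_rate(0, 1), 0)
  big <- starch_rate(0.7e6, 1)
  expect_lt(big, 1.2)
  expect_gt(big, 1.2 - 1e-5)
  # optional mass-balance cap
  expect_equal(starch_rate(0.01, 1, cap_rate_to_supply = TRUE), 0.01)
  expect_error(starch_rate(-1, 1), "nonnegative")
  # monotone in supply
  gca <- sort(runif(100, 0, 3))
  expect_true(all(diff(starch_rate(gca, 1)) >= 0))
})

test_that("amylose share grows with log thermal time and drops with N stress", {
  expect_equal(amylose_ratio(500, 1), 0.4 * log(500) - 2.1)
  expect_equal(amylose_ratio(100, 1), 0)  # negative raw value clamps
  expect_equal(amylose_ratio(500, 0), 0)
  expect_equal(amylose_ratio(0, 1), 0)    # defined at anthesis
  expect_true(all(amylose_ratio(seq(0, 5000, 10), 1) <= 1))
})

test_that("frozen kinetics leave per-grain starch at its initial value", {
  s <- generate_scenario(scenario_config(
    stress_windows = data.frame(start = 0, end = 45, water_ratio = 1,
                                n_depression = 1),
    seed = 21))
  qs <- simulate_quality(s)
  expect_true(all(qs$fn == 0))
  expect_true(all(qs$eact == 0))
  expect_true(all(qs$igsa == 0.1))
  expect_equal(unique(qs$gsa), s$sp * s$ng * 0.1 * 1e-6)
})

test_that("canopy scale-up and per-grain conversion are exact inverses", {
  # 5 mg per grain at 4e5 spikes x 2000 grains is 4000 kg/ha
  expect_equal(4e5 * 2000 * 5 * 1e-6, 4000)
  set.seed(3)
  for (k in 1:20) {
    sp <- runif(1, 1e5, 1e6); ng <- runif(1, 500, 4000)
    flux <- runif(1, 0, 500)
    expect_equal(1e6 * flux / (sp * ng) * sp * ng * 1e-6, flux)
  }
})

test_that("conservation, telescoping and monotonicity hold on random scenarios", {
  for (seed in 1:25) {
    qs <- simulate_quality(generate_scenario(random_scenario_cfg(seed)))
    expect_lt(max(abs(qs$gasa + qs$gapa - qs$gsa)), 1e-9)
    n <- nrow(qs)
    expect_lt(abs(qs$igsa[n] - (0.1 + sum(qs$istr))), 1e-9)
    expect_true(all(diff(qs$gsa) >= 0))
    expect_true(all(qs$istr <= 1.2 + 1e-12))
    expect_true(all(qs$eact >= 0 & qs$eact <= 1))
  }
})

test_that("extra assimilate on one day never lowers final starch", {
  s <- generate_scenario(scenario_config(temp_noise_sd = 0, seed = 30))
  base <- simulate_quality(s)
  for (j in c(10, 25, 40)) {
    bumped <- s
    # raise aboveground growth from day j on: only day j's increment changes
    sel <- bumped$days$day_index >= j
    bumped$days$topwt[sel] <- bumped$days$topwt[sel] + 200
    qs <- simulate_quality(bumped)
    expect_gte(qs$gsa[nrow(qs)], base$gsa[nrow(base)] - 1e-12)
  }
})

test_that("simulation rejects a season shorter than the activity peak", {
  s <- generate_scenario(scenario_config(seed = 2))
  expect_error(simulate_quality(s, sparams = starch_params(gdd_m = 1e4)),
               "gdd_am")
})
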