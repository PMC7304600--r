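test_that("kJ/day converts to weight by the steady-state coefficient", {
  p <- energy_balance_params()
  expect_equal(kj_to_weight(0, "adult", p), 0)
  expect_equal(kj_to_weight(-94, "adult", p), -1)
  expect_equal(kj_to_weight(-470, "adult", p), -5)
  expect_equal(kj_to_weight(-100, "child", p), -1)
})

test_that("weight converts to BMI through height squared", {
  expect_equal(weight_to_bmi_delta(0, 1.7), 0)
  expect_equal(weight_to_bmi_delta(-1, 1), -1)
  expect_equal(weight_to_bmi_delta(-2.5, 1.75), -2.5 / 3.0625)
  expect_error(weight_to_bmi_delta(1, 0), "height")
})

test_that("z-score changes map to BMI through the LMS transform", {
  gr <- data.frame(age = 10, sex = "female", L = 1, M = 16, S = 0.1)
  expect_equal(zscore_delta_to_bmi_delta(0, 0, 10, "female", gr), 0)
  # L = 1 reduces the transform to M * S * delta_z
  expect_equal(zscore_delta_to_bmi_delta(0, -0.25, 10, "female", gr), -0.4)
  gr0 <- data.frame(age = 10, sex = "female", L = 0, M = 16, S = 0.1)
  expect_equal(zscore_delta_to_bmi_delta(0, -0.25, 10, "female", gr0),
               16 * (exp(-0.025) - 1))
  expect_error(zscore_delta_to_bmi_delta(0, -0.25, 30, "female", gr),
               "ages 2-17")
  expect_error(zscore_delta_to_bmi_delta(4, 1, 10, "female", gr), "-4, 4")
})

test_that("MET-minutes convert to kJ/day expenditure, linearly", {
  p <- energy_balance_params()
  expect_equal(met_to_kj_per_day(0, 70, p), 0)
  expect_equal(met_to_kj_per_day(600, 70, p),
               600 * 70 * 0.0175 * 4.184 / 7)
  expect_equal(met_to_kj_per_day(1200, 70, p),
               2 * met_to_kj_per_day(600, 70, p))
  expect_equal(met_to_kj_per_day(600, 70, p, net_mets = TRUE,
                                 met_intensity = 4),
               met_to_kj_per_day(600, 70, p) * 0.75)
})

test_that("maintenance profiles scale the effect over time as specified", {
  sus <- list(maintenance = "sustained", implementation_years = 1,
              maintenance_end_year = NA)
  expect_equal(effect_at_time(sus, 70), 1)
  stz <- list(maintenance = "step_to_zero", implementation_years = 3,
              maintenance_end_year = 3)
  expect_equal(effect_at_time(stz, c(0, 2, 3, 5)), c(1, 1, 0, 0))
  dec <- list(maintenance = "linear_decay", implementation_years = 5,
              maintenance_end_year = 11)
  expect_equal(effect_at_time(dec, 8), 0.5)
  expect_equal(effect_at_time(dec, c(0, 4, 5, 11, 40)), c(1, 1, 1, 0, 0))
  expect_error(effect_at_time(sus, -1), ">= 0")
})

test_that("risk deltas compose the conversion chain with targeting and uptake", {
  b <- toy_bundle()
  spec <- b$interventions[1, ]
  eb <- energy_balance_params()

  z <- spec; z$uptake <- 0
  d0 <- build_risk_deltas(z, b$population, b$growth_reference, eb)
  expect_true(all(d0$bmi_shift == 0))

  d1 <- build_risk_deltas(spec, b$population, b$growth_reference, eb)
  expect_true(all(d1$bmi_shift[, 1] == -2))  # bmi_delta passes through

  kj <- spec; kj$effect_type <- "kj_per_day"; kj$effect_size <- -94
  pop1 <- b$population; pop1$mean_height <- 1
  dk <- build_risk_deltas(kj, pop1, b$growth_reference, eb)
  expect_equal(unique(dk$bmi_shift[, 1]), -1)  # -94 kJ / 94 / 1m^2

  out <- spec; out$target_age_lo <- 60; out$target_age_hi <- 70
  dt <- build_risk_deltas(out, b$population, b$growth_reference, eb)
  expect_true(all(dt$bmi_shift[b$population$age < 60, ] == 0))
  expect_true(all(dt$bmi_shift[b$population$age %in% 60:70, 1] != 0))

  zz <- spec; zz$effect_type <- "bmi_z_delta"
  expect_error(build_risk_deltas(zz, b$population, b$growth_reference, eb),
               "adults")
})

test_that("conversions are linear in effect size and never harm under the sign convention", {
  b <- toy_bundle()
  eb <- energy_balance_params()
  spec <- b$interventions[1, ]
  spec$effect_type <- "kj_per_day"
  set.seed(42)
  for (k in runif(5, 0.1, 4)) {
    s1 <- spec; s1$effect_size <- -30
    s2 <- spec; s2$effect_size <- -30 * k
    d1 <- build_risk_deltas(s1, b$population, b$growth_reference, eb)
    d2 <- build_risk_deltas(s2, b$population, b$growth_reference, eb)
    expect_equal(d2$bmi_shift, d1$bmi_shift * k, tolerance = 1e-12)
  }
  expect_true(all(d1$bmi_shift <= 0))  # beneficial kJ reduction
})

test_that("activity effects raise band occupancy and optionally shift BMI", {
  b <- toy_bundle()
  eb <- energy_balance_params()
  met <- b$interventions[1, ]
  met$effect_type <- "met_min_per_week"; met$effect_size <- 600
  d <- build_risk_deltas(met, b$population, b$growth_reference, eb)
  expect_true(all(d$pa_frac[, 1] > 0))
  expect_true(all(d$bmi_shift[, 1] < 0))  # uncompensated energy deficit
  d2 <- build_risk_deltas(met, b$population, b$growth_reference, eb,
                          pa_affects_bmi = FALSE)
  expect_true(all(d2$bmi_shift == 0))
  p1 <- pmslt:::shift_pa_prevalence(c(0.3, 0.3, 0.25, 0.15), 0.2)
  expect_equal(sum(p1), 1)
  expect_lt(p1[1], 0.3)
  expect_gt(p1[4], 0.15)
})
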