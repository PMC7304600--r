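test_that("disease process reproduces the hand-iterated update", {
  tr <- run_disease_process(0.01, 0.1, 0, n_years = 2,
                            convert_rates = FALSE)
  expect_equal(tr$C[1], 0.01)
  expect_equal(tr$S[1], 0.99)
  expect_equal(tr$C[2], 0.01 * 0.9 + 0.99 * 0.01)
  expect_equal(tr$d_mort[2], 0.01 * 0.1)
})

test_that("disease process null and scaling behaviour", {
  tr0 <- run_disease_process(0, 0.1, 0, n_years = 10, C0 = 0)
  expect_true(all(tr0$C == 0))
  tr_half <- run_disease_process(0.02, 0.05, 0, n_years = 5,
                                 incidence_scale = 0.5,
                                 convert_rates = FALSE)
  tr_full <- run_disease_process(0.02, 0.05, 0, n_years = 5,
                                 convert_rates = FALSE)
  expect_equal(tr_half$new_cases[1], tr_full$new_cases[1] / 2)
  # with zero incidence, prevalence is non-increasing
  trd <- run_disease_process(0, 0.05, 0.01, n_years = 20, C0 = 0.3,
                             S0 = 0.7)
  expect_true(all(diff(trd$C) <= 1e-15))
  expect_error(run_disease_process(1.5, 0.8, 0.8, n_years = 3,
                                   convert_rates = FALSE),
               "negative compartment")
})

test_that("disease process conserves mass to 1e-9", {
  set.seed(11)
  for (k in 1:20) {
    i <- runif(1, 0, 0.2); f <- runif(1, 0, 0.3); r <- runif(1, 0, 0.1)
    tr <- run_disease_process(i, f, r, n_years = 60)
    expect_lt(abs(tr$S[60] + tr$C[60] + sum(tr$d_mort) - 1), 1e-9)
  }
})

test_that("engine prevalence matches the single-cohort R reference", {
  b <- toy_bundle()
  base <- run_lifetable(b)
  s0 <- which(b$population$count > 0)
  for (d in 1:2) {
    ref <- run_disease_process(
      b$disease_rates$incidence[b$disease_rates$disease_id ==
                                  b$diseases$disease_id[d]][1],
      b$disease_rates$case_fatality[b$disease_rates$disease_id ==
                                      b$diseases$disease_id[d]][1],
      0, n_years = 50)
    prev_ref <- ref$C / (ref$S + ref$C)
    # engine stores start-of-year prevalence; year y+1 start equals the
    # reference state after y updates
    expect_lt(max(abs(base$P[s0, d, 2:51] - prev_ref)), 1e-12)
  }
})

test_that("a zero PIF table reproduces baseline exactly", {
  b <- toy_bundle()
  base <- run_lifetable(b)
  pif0 <- array(0, c(nrow(b$population), 2, base$engine$Y))
  scen <- run_lifetable(b, pif = pif0, baseline = base)
  expect_lt(abs(scen$total_halys - base$total_halys) /
              base$total_halys, 1e-12)
  expect_lt(abs(scen$total_cost - base$total_cost) / base$total_cost,
            1e-12)
})

test_that("survival and person-years follow the closed-form annuities", {
  # zero mortality, zero morbidity, 3-year horizon, 3% discounting
  b <- toy_bundle(start_age = 98, count = 1000)
  b$population$mortality_all_cause <- 1e-12
  b$population$yld_all_cause <- 0
  b$disease_rates$incidence <- 0
  b$disease_rates$case_fatality <- 0
  base <- run_lifetable(b, discount_rate = 0.03)
  expect_equal(base$total_halys, 1000 * (1 + 1 / 1.03 + 1 / 1.03^2),
               tolerance = 1e-9)
  base0 <- run_lifetable(b, discount_rate = 0)
  expect_equal(base0$total_halys, 3000, tolerance = 1e-9)
})

test_that("terminal mortality earns the half-cycle person-years", {
  # survivor curve held at 1 for ten years, then certain death at 100:
  # person-years 9 x 1 + 0.5 (half-cycle) = 9.5 per person
  b <- toy_bundle(start_age = 91, count = 1000)
  b$population$mortality_all_cause <-
    ifelse(b$population$age == 100, 1e9, 1e-12)
  b$population$yld_all_cause <- 0
  b$disease_rates$incidence <- 0
  b$disease_rates$case_fatality <- 0
  base <- run_lifetable(b, discount_rate = 0)
  expect_equal(base$total_halys, 9500, tolerance = 1e-9)
})

test_that("zero-effect interventions change nothing; beneficial ones help", {
  b <- toy_bundle()
  base <- run_lifetable(b)
  z <- b$interventions[1, ]; z$effect_size <- 0
  ev0 <- evaluate_intervention(b, z, baseline = base)
  expect_equal(ev0$halys_gained, 0)
  expect_equal(ev0$cost_offsets, 0)
  ev <- evaluate_intervention(b, "toy_iv", baseline = base)
  expect_gt(ev$halys_gained, 0)
  expect_gt(ev$cost_offsets, 0)
})

test_that("HALY gains grow with disability weight and with effect size", {
  b <- toy_bundle()
  ev <- evaluate_intervention(b, "toy_iv")
  b2 <- toy_bundle()
  b2$diseases$disability_weight <- b2$diseases$disability_weight * 2
  ev2 <- evaluate_intervention(b2, "toy_iv")
  expect_gt(ev2$halys_gained, ev$halys_gained)

  gains <- vapply(c(-0.5, -1, -2, -3), function(e) {
    evaluate_intervention(toy_bundle(effect_size = e),
                          "toy_iv")$halys_gained
  }, numeric(1))
  expect_true(all(diff(gains) > 0))
})

test_that("child HRQoL decrement responds to child BMI shifts", {
  b <- generate_bundle(default_config(), seed = 1)
  base <- run_lifetable(b)
  ev_with <- evaluate_intervention(b, "tv_ad_restrictions",
                                   baseline = base)
  ev_without <- evaluate_intervention(b, "tv_ad_restrictions",
                                      child_hrql_coeff = 0)
  expect_gt(ev_with$halys_gained, ev_without$halys_gained)
})
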